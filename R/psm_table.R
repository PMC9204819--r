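#' PSM-level quantification tables
#'
#' A `psm_table` holds one row per peptide spectrum match (PSM) with
#' per-channel reporter intensities and the quality metrics used for
#' filtering: Sequest Delta CN, co-isolation interference (%) and average
#' reporter signal/noise. Missing reporter intensities are stored as `NA`.
#'
#' @param psms A data frame with columns `psm_id`, `sequence`,
#'   `master_proteins` (";"-separated accessions), `species`, `delta_cn`,
#'   `coisolation_pct`, `avg_sn`, plus one numeric column per channel label.
#' @param channels A [channel_set()].
#' @param provenance Free-text description of where the table came from.
#' @return An object of class `psm_table`.
#' @export
psm_table <- function(psms, channels = channel_set(), provenance = "") {
  psms <- tibble::as_tibble(psms)
  meta <- c("psm_id", "sequence", "master_proteins", "species",
            "delta_cn", "coisolation_pct", "avg_sn")
  missing_cols <- setdiff(c(meta, channels$labels), names(psms))
  if (length(missing_cols)) {
    stop("psm table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  psms <- psms[, c(meta, channels$labels)]
  x <- structure(list(psms = psms, channels = channels,
                      provenance = provenance),
                 class = "psm_table")
  validate_psm_table(x)
  x
}

validate_psm_table <- function(x) {
  p <- x$psms
  dcn <- p$delta_cn[!is.na(p$delta_cn)]
  if (any(dcn < 0 | dcn > 1)) stop("delta_cn must lie in [0, 1]")
  ci <- p$coisolation_pct[!is.na(p$coisolation_pct)]
  if (any(ci < 0 | ci > 100)) stop("coisolation_pct must lie in [0, 100]")
  im <- intensity_matrix(x)
  if (any(im <= 0, na.rm = TRUE)) stop("intensities must be positive or NA")
  invisible(x)
}

#' @export
print.psm_table <- function(x, ...) {
  cat("<psm_table> ", nrow(x$psms), " PSMs x ", length(x$channels$labels),
      " channels", if (nzchar(x$provenance)) paste0(" (", x$provenance, ")"),
      "\n", sep = "")
  print(utils::head(x$psms))
  invisible(x)
}

#' @export
dim.psm_table <- function(x) c(nrow(x$psms), length(x$channels$labels))

#' Extract the reporter intensity matrix of a PSM table
#'
#' @param x A `psm_table`.
#' @param log2 Return log2 intensities instead of raw intensities.
#' @return Numeric matrix, PSMs in rows (named by `psm_id`), channels in
#'   columns; missing values are `NA`.
#' @export
intensity_matrix <- function(x, log2 = FALSE) {
  m <- as.matrix(x$psms[, x$channels$labels])
  rownames(m) <- x$psms$psm_id
  if (log2) m <- safe_log2(m)
  m
}

# Internal: replace the intensity columns from a matrix (NA = missing).
set_intensities <- function(x, m) {
  stopifnot(nrow(m) == nrow(x$psms), ncol(m) == length(x$channels$labels))
  x$psms[, x$channels$labels] <- tibble::as_tibble(m, .name_repair = "minimal")
  x
}

# Internal: keep rows by logical/integer index, preserving order.
subset_psms <- function(x, keep) {
  x$psms <- x$psms[keep, , drop = FALSE]
  x
}

#' Column dialects for PSM exports
#'
#' A dialect maps the semantic fields of a PSM table to the column names of a
#' particular export format. `pd_dialect()` is the Proteome Discoverer text
#' export dialect; `canonical_dialect()` matches the columns written by
#' [write_psm_table()].
#'
#' @param channels A [channel_set()].
#' @return A named list with entries `psm_id`, `sequence`, `master_proteins`,
#'   `species`, `delta_cn`, `coisolation_pct`, `avg_sn` (each a column name or
#'   `NULL` when absent from the format) and `abundance`, a named character
#'   vector mapping channel labels to abundance column names.
#' @export
pd_dialect <- function(channels = channel_set()) {
  list(
    psm_id = NULL,
    sequence = "Annotated Sequence",
    master_proteins = "Master Protein Accessions",
    species = NULL,
    delta_cn = "DeltaCn",
    coisolation_pct = "Isolation Interference [%]",
    avg_sn = "Average Reporter SN",
    abundance = stats::setNames(paste0("Abundance: ", channels$labels),
                                channels$labels)
  )
}

#' @rdname pd_dialect
#' @export
canonical_dialect <- function(channels = channel_set()) {
  list(
    psm_id = "psm_id",
    sequence = "sequence",
    master_proteins = "master_proteins",
    species = "species",
    delta_cn = "delta_cn",
    coisolation_pct = "coisolation_pct",
    avg_sn = "avg_sn",
    abundance = stats::setNames(channels$labels, channels$labels)
  )
}

#' Read a delimited PSM-level quantification table
#'
#' Reads a tab- or comma-delimited PSM export with a header row. Blank or
#' non-positive abundance cells become missing (`NA`). Quality-metric columns
#' absent from the dialect or the file default to pass-all values (Delta CN 1,
#' co-isolation 0, average S/N `Inf`) with a warning.
#'
#' @param path Path to the delimited file.
#' @param channels A [channel_set()].
#' @param dialect Column-name map, see [pd_dialect()].
#' @param delim Field delimiter; `NULL` guesses from the header line.
#' @return A [psm_table()].
#' @export
read_psm_table <- function(path, channels = channel_set(),
                           dialect = pd_dialect(channels), delim = NULL) {
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (lengths(regmatches(hdr, gregexpr("\t", hdr))) > 0) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  mandatory <- c(sequence = dialect$sequence, dialect$abundance)
  absent <- setdiff(unname(mandatory), names(raw))
  if (length(absent)) {
    stop("mandatory column(s) not found: ", paste(absent, collapse = ", "))
  }
  n <- nrow(raw)

  parse_num <- function(col, what, lo = -Inf, hi = Inf) {
    v <- trimws(raw[[col]])
    v[v == "" | is.na(v)] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop("non-numeric ", what, " in column '", col, "' at row ", bad[1])
    }
    num
  }

  abund <- vapply(dialect$abundance, function(col) {
    v <- parse_num(col, "abundance")
    v[!is.na(v) & v <= 0] <- NA  # non-positive exports are not quantifiable
    v
  }, numeric(n))
  if (n == 1L) abund <- matrix(abund, nrow = 1L,
                               dimnames = list(NULL, names(dialect$abundance)))
  colnames(abund) <- names(dialect$abundance)

  opt_metric <- function(field, default, lo, hi) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      warning("column for '", field, "' not mapped; defaulting to pass-all (",
              default, ")", call. = FALSE)
      return(rep(default, n))
    }
    v <- parse_num(col, field)
    v[is.na(v)] <- default
    v
  }

  chr_field <- function(field, default) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(raw)) return(rep(default, n))
    v <- as.character(raw[[col]])
    v[is.na(v)] <- default
    v
  }

  psms <- tibble::tibble(
    psm_id = if (!is.null(dialect$psm_id) && dialect$psm_id %in% names(raw)) {
      as.character(raw[[dialect$psm_id]])
    } else sprintf("PSM%06d", seq_len(n)),
    sequence = as.character(raw[[dialect$sequence]]),
    master_proteins = chr_field("master_proteins", ""),
    species = chr_field("species", "unknown"),
    delta_cn = opt_metric("delta_cn", 1, 0, 1),
    coisolation_pct = opt_metric("coisolation_pct", 0, 0, 100),
    avg_sn = opt_metric("avg_sn", Inf, 0, Inf)
  )
  psms <- dplyr::bind_cols(psms, tibble::as_tibble(abund))
  psm_table(psms, channels, provenance = path)
}

#' Write a PSM table to a tab-delimited file
#'
#' Writes the canonical column layout read back by [read_psm_table()] with
#' [canonical_dialect()]. Numeric values are written with full precision so a
#' write/read round trip reproduces finite values exactly and preserves
#' missingness.
#'
#' @param x A `psm_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(x, path) {
  out <- x$psms
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- NA
    s
  })
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Annotate PSMs with their species of origin
#'
#' Assigns each PSM a species from its full matched-accession list:
#' `contaminant` when any accession is in the contaminant set, `ambiguous`
#' when mapped accessions cover more than one species (regardless of master
#' protein assignment), `unknown` when no accession maps, otherwise the single
#' mapped species.
#'
#' @param x A `psm_table`.
#' @param species_map Named character vector, accession -> species
#'   (e.g. `"human"`, `"yeast"`).
#' @param contaminants Character vector of contaminant accessions (e.g. the
#'   cRAP database accessions).
#' @return The annotated `psm_table`.
#' @export
annotate_species <- function(x, species_map, contaminants = character()) {
  if (length(species_map) == 0 || is.null(names(species_map))) {
    stop("`species_map` must be a non-empty named accession -> species vector")
  }
  accs <- strsplit(x$psms$master_proteins, ";\\s*")
  x$psms$species <- vapply(accs, function(a) {
    a <- a[!is.na(a) & nzchar(a)]
    if (length(a) == 0) return("unknown")
    if (any(a %in% contaminants)) return("contaminant")
    sp <- unique(unname(species_map[a[a %in% names(species_map)]]))
    if (length(sp) == 0) return("unknown")
    if (length(sp) > 1) return("ambiguous")
    sp
  }, character(1))
  x
}

#' Remove PSMs that cannot be used for quantification
#'
#' Drops contaminant, ambiguous-species and unknown-species PSMs, keeping the
#' input order of the survivors, and reports how many rows each exclusion
#' reason removed.
#'
#' @param x A species-annotated `psm_table`.
#' @return A list with `table` (the filtered `psm_table`) and `counts` (named
#'   integer vector of removals by reason).
#' @export
exclude_nonquantifiable <- function(x) {
  reasons <- c("ambiguous", "contaminant", "unknown")
  sp <- x$psms$species
  sp[is.na(sp)] <- "unknown"
  drop <- sp %in% reasons
  counts <- vapply(reasons, function(r) sum(sp == r), integer(1))
  list(table = subset_psms(x, !drop), counts = counts[counts > 0])
}
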