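#' @importFrom dplyr .data
#' @keywords internal
"_PACKAGE"

# Internal: map each aggregation-eligible PSM to its feature. At protein
# level, PSMs matching more than one master protein are dropped (avoids
# double counting); at peptide level the plain sequence is the key. Only
# complete PSMs (no missing channel) are eligible.
aggregation_members <- function(x, level = c("protein", "peptide")) {
  level <- match.arg(level)
  complete <- rowSums(is.na(intensity_matrix(x))) == 0
  if (level == "protein") {
    multi <- grepl(";", x$psms$master_proteins)
    eligible <- complete & !multi
    feature <- x$psms$master_proteins
  } else {
    eligible <- complete
    feature <- x$psms$sequence
  }
  out <- tibble::tibble(row = which(eligible),
                        psm_id = x$psms$psm_id[eligible],
                        feature_id = feature[eligible],
                        species = x$psms$species[eligible])
  attr(out, "n_multi_master_dropped") <- sum(complete) - sum(eligible)
  out
}

#' Aggregate PSM intensities to peptide- or protein-level features
#'
#' Follows the benchmark aggregation rules: PSMs containing any missing
#' reporter value are removed first; features with fewer than `min_psms`
#' remaining PSMs are dropped; per-channel intensities are summed. At
#' protein level, PSMs matching multiple master proteins are excluded (their
#' count is reported as an attribute). Species is inherited from the member
#' PSMs and must be unique within a feature.
#'
#' @param x A quantifiable `psm_table`.
#' @param level `"protein"` (key: master protein accession) or `"peptide"`
#'   (key: plain sequence).
#' @param min_psms Minimum complete PSMs per retained feature.
#' @return An object of class `feature_matrix`: a list with `features`
#'   (tibble: `feature_id`, `species`, `n_psms`, one column per channel),
#'   `channels` and `level`.
#' @export
aggregate_psms <- function(x, level = c("protein", "peptide"), min_psms = 2L) {
  level <- match.arg(level)
  members <- aggregation_members(x, level)
  m <- intensity_matrix(x)[members$row, , drop = FALSE]
  sp_by_feat <- tapply(members$species, members$feature_id,
                       function(s) unique(s), simplify = FALSE)
  mixed <- names(sp_by_feat)[lengths(sp_by_feat) > 1]
  if (length(mixed)) {
    stop("mixed-species members within feature(s): ",
         paste(utils::head(mixed, 3), collapse = ", "))
  }
  counts <- table(members$feature_id)
  keep_feat <- names(counts)[counts >= min_psms]
  sums <- rowsum(m, group = members$feature_id, reorder = TRUE)
  sums <- sums[keep_feat, , drop = FALSE]
  features <- tibble::tibble(
    feature_id = keep_feat,
    species = vapply(sp_by_feat[keep_feat], identity, character(1)),
    n_psms = as.integer(counts[keep_feat])
  )
  features <- dplyr::bind_cols(
    features, tibble::as_tibble(sums, .name_repair = "minimal"))
  structure(list(features = features, channels = x$channels, level = level,
                 n_multi_master_dropped = attr(members, "n_multi_master_dropped")),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$features), " ", x$level, "-level features x ",
      length(x$channels$labels), " channels\n", sep = "")
  print(utils::head(x$features))
  invisible(x)
}

#' Extract the per-channel sums of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param log2 Return log2 of the summed intensities.
#' @return Numeric matrix, features in rows (named by `feature_id`).
#' @export
feature_intensity_matrix <- function(fm, log2 = FALSE) {
  m <- as.matrix(fm$features[, fm$channels$labels])
  rownames(m) <- fm$features$feature_id
  if (log2) m <- safe_log2(m)
  m
}

#' Per-feature exposure to sub-notch PSM intensities
#'
#' For each feature in the matrix and each channel, the fraction of member
#' PSM intensities (the complete PSMs that were summed) whose log2 value is
#' below the notch upper boundary, plus the per-feature maximum over
#' channels.
#'
#' @param x The `psm_table` the matrix was aggregated from.
#' @param fm The [aggregate_psms()] output.
#' @param notch A [notch_region()].
#' @return Tibble with `feature_id`, one fraction column per channel, and
#'   `max_fraction`.
#' @export
notch_exposure <- function(x, fm, notch) {
  members <- aggregation_members(x, fm$level)
  members <- members[members$feature_id %in% fm$features$feature_id, ]
  below <- intensity_matrix(x, log2 = TRUE)[members$row, , drop = FALSE] <
    notch$upper
  frac <- rowsum(below + 0, group = members$feature_id, reorder = TRUE) /
    as.vector(table(members$feature_id))
  frac <- frac[fm$features$feature_id, , drop = FALSE]
  out <- tibble::tibble(feature_id = fm$features$feature_id)
  out <- dplyr::bind_cols(out, tibble::as_tibble(frac, .name_repair = "minimal"))
  out$max_fraction <- unname(apply(frac, 1, max))
  out
}
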