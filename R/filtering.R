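#' One PSM filtering schema
#'
#' Combines the four PSM quality filters: minimum Sequest Delta CN (strict
#' `>`), maximum co-isolation interference (strict `<`), minimum average
#' reporter S/N (`>=`, so 0 is the pass-all level) and whether PSMs with any
#' reporter intensity below the notch upper boundary are removed.
#'
#' @param min_delta_cn Minimum Delta CN in `[0, 1]`.
#' @param max_coisolation Maximum co-isolation percentage in `(0, 100]`.
#' @param min_avg_sn Minimum average reporter S/N (non-negative).
#' @param remove_notch Remove PSMs with any sub-notch intensity?
#' @return An object of class `filter_schema`.
#' @export
filter_schema <- function(min_delta_cn = 0, max_coisolation = 100,
                          min_avg_sn = 0, remove_notch = FALSE) {
  if (min_delta_cn < 0 || min_delta_cn > 1)
    stop("min_delta_cn must lie in [0, 1]")
  if (max_coisolation <= 0 || max_coisolation > 100)
    stop("max_coisolation must lie in (0, 100]")
  if (min_avg_sn < 0) stop("min_avg_sn must be non-negative")
  structure(list(min_delta_cn = min_delta_cn,
                 max_coisolation = max_coisolation,
                 min_avg_sn = min_avg_sn,
                 remove_notch = isTRUE(remove_notch)),
            class = "filter_schema")
}

#' @export
format.filter_schema <- function(x, ...) {
  sprintf("dcn%g_co%g_sn%g_%s", x$min_delta_cn, x$max_coisolation,
          x$min_avg_sn, if (x$remove_notch) "rm" else "keep")
}

#' @export
print.filter_schema <- function(x, ...) {
  cat("<filter_schema> ", format(x), "\n", sep = "")
  invisible(x)
}

#' The benchmark grid of 36 filtering schemas
#'
#' The Cartesian product of Delta CN > {0, 0.2, 0.5}, co-isolation
#' < {100, 50, 10}%, average S/N >= {0, 10} and notch PSMs kept or removed:
#' 36 distinct schemas in a fixed deterministic order.
#'
#' @return A named list of 36 [filter_schema()] objects.
#' @export
schema_grid <- function() {
  levels <- expand.grid(remove_notch = c(FALSE, TRUE),
                        min_avg_sn = c(0, 10),
                        max_coisolation = c(100, 50, 10),
                        min_delta_cn = c(0, 0.2, 0.5),
                        KEEP.OUT.ATTRS = FALSE)
  schemas <- lapply(seq_len(nrow(levels)), function(i) {
    filter_schema(levels$min_delta_cn[i], levels$max_coisolation[i],
                  levels$min_avg_sn[i], levels$remove_notch[i])
  })
  names(schemas) <- vapply(schemas, format, character(1))
  schemas
}

#' Apply one filtering schema to a PSM table
#'
#' Keeps PSMs with `delta_cn > min_delta_cn`, `coisolation_pct <
#' max_coisolation` and `avg_sn >= min_avg_sn`; when `remove_notch` is set,
#' additionally drops PSMs with any non-missing reporter intensity whose log2
#' value is below the notch upper boundary. Removal is attributed to the
#' first failing metric in the order Delta CN, co-isolation, S/N, notch.
#'
#' @param x A quantifiable `psm_table`.
#' @param schema A [filter_schema()].
#' @param notch A [notch_region()]; required when `schema$remove_notch`.
#' @return A list with `table` (the filtered `psm_table`) and `report`
#'   (`input_count`, `removed_by_metric`, `output_count`).
#' @export
apply_filters <- function(x, schema, notch = NULL) {
  stopifnot(inherits(schema, "filter_schema"))
  if (schema$remove_notch && is.null(notch)) {
    stop("`notch` boundaries are required when `remove_notch` is set")
  }
  p <- x$psms
  pass_dcn <- p$delta_cn > schema$min_delta_cn
  pass_coi <- p$coisolation_pct < schema$max_coisolation
  pass_sn <- p$avg_sn >= schema$min_avg_sn
  pass_notch <- if (schema$remove_notch) {
    lm2 <- intensity_matrix(x, log2 = TRUE)
    rowSums(lm2 < notch$upper, na.rm = TRUE) == 0
  } else {
    rep(TRUE, nrow(p))
  }
  fail_first <- function(...) {
    fails <- !cbind(...)
    apply(fails, 1, function(f) if (any(f)) which(f)[1] else 0L)
  }
  first <- fail_first(pass_dcn, pass_coi, pass_sn, pass_notch)
  removed <- c(delta_cn = sum(first == 1L), coisolation = sum(first == 2L),
               avg_sn = sum(first == 3L), notch = sum(first == 4L))
  keep <- first == 0L
  list(table = subset_psms(x, keep),
       report = list(input_count = nrow(p),
                     removed_by_metric = removed,
                     output_count = sum(keep)))
}

#' Log center-median normalize reporter intensities
#'
#' Shifts each channel on the log2 scale so that every channel median equals
#' the grand median of the original channel medians, then exponentiates back
#' to the intensity scale. Missing values are untouched. This removes small
#' per-channel loading differences while preserving the overall intensity
#' scale and the within-channel rank order of PSMs.
#'
#' @param x A `psm_table` with at least one non-missing value per channel.
#' @return The normalized `psm_table`.
#' @export
center_median_normalize <- function(x) {
  m <- intensity_matrix(x, log2 = TRUE)
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0)) {
    stop("channel(s) entirely missing: ",
         paste(x$channels$labels[n_obs == 0], collapse = ", "))
  }
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  target <- stats::median(med)
  m <- sweep(m, 2, med - target, "-")
  set_intensities(x, 2^m)
}
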