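#' Per-channel and overall sub-notch intensity fractions
#'
#' For each channel and overall, the fraction of non-missing reporter
#' intensities whose log2 value lies below the notch upper boundary, and the
#' fraction inside the band `[lower, upper)`.
#'
#' @param x A non-empty `psm_table`.
#' @param notch A [notch_region()].
#' @return Tibble with columns `channel` (labels plus `"overall"`), `n`
#'   (non-missing values), `frac_below_upper` and `frac_in_band`.
#' @export
notch_stats <- function(x, notch) {
  m <- intensity_matrix(x, log2 = TRUE)
  if (nrow(m) == 0) stop("empty PSM table")
  one <- function(v) {
    v <- v[!is.na(v)]
    tibble::tibble(n = length(v),
                   frac_below_upper = mean(v < notch$upper),
                   frac_in_band = mean(v >= notch$lower & v < notch$upper))
  }
  per <- dplyr::bind_rows(lapply(seq_len(ncol(m)), function(j) one(m[, j])))
  per$channel <- x$channels$labels
  overall <- one(as.vector(m))
  overall$channel <- "overall"
  dplyr::bind_rows(per, overall)[, c("channel", "n", "frac_below_upper",
                                     "frac_in_band")]
}

#' Detect a depleted band in an intensity distribution
#'
#' Histograms log2 intensities at a fixed bin width and searches for the
#' widest contiguous run of bins whose counts fall below a fraction `theta`
#' of the mean count in the two flanking windows, provided the run is at
#' least `min_width` wide and both windows flanking the run lie inside the
#' data range with non-trivial density. An automated surrogate for the
#' visual boundary assessment used in practice.
#'
#' @param intensities Positive intensities (raw scale).
#' @param bin_width Histogram bin width, log2 units.
#' @param theta Depletion threshold relative to the flanking mean count.
#' @param flank_width Width of each flanking window, log2 units.
#' @param min_width Minimum band width to report, log2 units.
#' @return A [notch_region()] with the detected boundaries, or `NULL` when
#'   no depleted band is found.
#' @export
detect_notch <- function(intensities, bin_width = 0.1, theta = 0.25,
                         flank_width = 1, min_width = 0.5) {
  x <- intensities[!is.na(intensities)]
  if (length(x) == 0) stop("no intensities supplied")
  if (length(x) < 1000) {
    warning("fewer than 1000 intensities; boundary detection is unreliable")
  }
  lx <- safe_log2(x)
  lo <- floor(min(lx) / bin_width) * bin_width
  hi <- ceiling(max(lx) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  counts <- tabulate(findInterval(lx, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  nb <- length(counts)
  nf <- max(1L, round(flank_width / bin_width))

  flank_mean <- function(i_lo, i_hi) {
    left <- (i_lo - nf):(i_lo - 1L)
    right <- (i_hi + 1L):(i_hi + nf)
    if (min(left) < 1L || max(right) > nb) return(NULL)
    c(mean(counts[left]), mean(counts[right]))
  }

  depleted <- vapply(seq_len(nb), function(i) {
    fl <- flank_mean(i, i)
    if (is.null(fl)) return(FALSE)
    avg <- mean(fl)
    avg > 0 && counts[i] < theta * avg
  }, logical(1))

  runs <- rle(depleted)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values & runs$lengths * bin_width >= min_width)
  if (length(cand) == 0) return(NULL)

  # A genuine band must sit between populated flanks, not in a bare tail.
  min_density <- max(1, 0.02 * mean(counts))
  valid <- vapply(cand, function(k) {
    fl <- flank_mean(starts[k], ends[k])
    !is.null(fl) && all(fl >= min_density)
  }, logical(1))
  cand <- cand[valid]
  if (length(cand) == 0) return(NULL)
  best <- cand[which.max(runs$lengths[cand])]
  notch_region(lower = breaks[starts[best]], upper = breaks[ends[best] + 1L])
}

#' Predict expected reporter intensities from redundant PSMs
#'
#' PSMs sharing a peptide sequence are grouped; singleton groups and groups
#' whose highest-intensity PSM (largest total over its non-missing channels,
#' ties broken by input order) has any missing channel are dropped. For each
#' remaining non-top PSM, an adjustment factor is computed as the ratio of
#' its summed intensity to the top PSM's summed intensity over the PSM's
#' non-missing channels; predictions are the top PSM's intensities scaled by
#' that factor, on the intensity scale.
#'
#' @param x A quantifiable `psm_table`.
#' @return Tibble with one row per predicted cell: `sequence`, `top_psm_id`,
#'   `psm_id`, `channel`, `observed`, `predicted`.
#' @export
predict_expected <- function(x) {
  m <- intensity_matrix(x)
  seqs <- x$psms$sequence
  ids <- x$psms$psm_id
  groups <- split(seq_along(seqs), seqs)
  out <- vector("list", length(groups))
  k <- 0L
  for (g in groups) {
    if (length(g) < 2L) next
    sub <- m[g, , drop = FALSE]
    tot <- rowSums(sub, na.rm = TRUE)
    top <- which.max(tot)  # which.max takes the first maximum: stable ties
    top_row <- sub[top, ]
    if (anyNA(top_row)) next
    others <- g[-top]
    rows <- lapply(seq_along(others), function(j) {
      obs <- sub[-top, , drop = FALSE][j, ]
      cj <- which(!is.na(obs))
      if (length(cj) == 0) return(NULL)
      r <- sum(obs[cj]) / sum(top_row[cj])
      tibble::tibble(sequence = seqs[g[top]],
                     top_psm_id = ids[g[top]],
                     psm_id = ids[others[j]],
                     channel = x$channels$labels[cj],
                     observed = unname(obs[cj]),
                     predicted = unname(r * top_row[cj]))
    })
    k <- k + 1L
    out[[k]] <- dplyr::bind_rows(rows)
  }
  if (k == 0L) {
    return(tibble::tibble(sequence = character(), top_psm_id = character(),
                          psm_id = character(), channel = character(),
                          observed = numeric(), predicted = numeric()))
  }
  dplyr::bind_rows(out[seq_len(k)])
}

#' Fraction of observations below their prediction, by predicted intensity
#'
#' Bins prediction entries by log2 predicted intensity and reports, per bin,
#' the number of entries and the fraction with observed strictly below
#' predicted (ties count as not-below). Empty bins are omitted.
#'
#' @param preds Output of [predict_expected()].
#' @param bin_width Bin width in log2 units.
#' @return Tibble with `bin_lower`, `bin_mid`, `n`, `frac_below`.
#' @export
underestimation_fraction <- function(preds, bin_width = 0.5) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be positive")
  }
  if (nrow(preds) == 0) stop("no prediction entries supplied")
  lp <- safe_log2(preds$predicted)
  bin <- floor(lp / bin_width) * bin_width
  dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(bin_lower = bin, below = preds$observed < preds$predicted),
      .data$bin_lower),
    n = dplyr::n(), frac_below = mean(.data$below), .groups = "drop"
  ) |>
    dplyr::mutate(bin_mid = .data$bin_lower + bin_width / 2, .after = "bin_lower") |>
    dplyr::arrange(.data$bin_lower)
}

#' Difference between single tag intensities and a comparator group mean
#'
#' For each PSM and each non-missing target channel, computes the log2 tag
#' intensity minus the mean log2 intensity over the non-missing comparator
#' channels; PSMs with no non-missing comparator value are skipped. Also
#' returns binned medians of the difference by target log2 intensity.
#'
#' @param x A `psm_table`.
#' @param target_channels,comparator_channels Disjoint channel label subsets;
#'   the comparator must be non-empty.
#' @param bin_width Bin width (log2 units) for the binned medians.
#' @return A list with `diffs` (tibble: `psm_id`, `channel`, `target_log2`,
#'   `diff`) and `binned` (tibble: `bin_lower`, `bin_mid`, `n`,
#'   `median_diff`).
#' @export
tag_vs_comparator <- function(x, target_channels, comparator_channels,
                              bin_width = 0.5) {
  if (length(comparator_channels) == 0) stop("comparator set is empty")
  if (length(intersect(target_channels, comparator_channels)) > 0) {
    stop("target and comparator channel sets must be disjoint")
  }
  stopifnot(all(c(target_channels, comparator_channels) %in%
                  x$channels$labels))
  m <- intensity_matrix(x, log2 = TRUE)
  comp_mean <- rowMeans(m[, comparator_channels, drop = FALSE], na.rm = TRUE)
  ok <- is.finite(comp_mean)
  rows <- lapply(target_channels, function(ch) {
    v <- m[, ch]
    use <- ok & !is.na(v)
    tibble::tibble(psm_id = x$psms$psm_id[use], channel = ch,
                   target_log2 = v[use], diff = v[use] - comp_mean[use])
  })
  diffs <- dplyr::bind_rows(rows)
  binned <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(diffs,
                    bin_lower = floor(.data$target_log2 / bin_width) * bin_width),
      .data$bin_lower),
    n = dplyr::n(), median_diff = stats::median(.data$diff), .groups = "drop"
  ) |>
    dplyr::mutate(bin_mid = .data$bin_lower + bin_width / 2,
                  .after = "bin_lower") |>
    dplyr::arrange(.data$bin_lower)
  list(diffs = diffs, binned = binned)
}
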