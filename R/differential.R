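#' Benjamini-Hochberg step-up q-values
#'
#' Standard BH step-up: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1. Input order is
#' preserved in the output.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Internal: invert the trigamma function by Newton iteration (monotone
# decreasing on (0, Inf)), as needed for prior-df moment matching.
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 50L) {
  vapply(y, function(yi) {
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in seq_len(max_iter)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) / x < tol) break
    }
    x
  }, numeric(1))
}

# Internal: squeeze per-feature variances toward an intensity trend.
# s2: residual variances; df: their residual degrees of freedom (scalar);
# amean: mean log2 intensity per feature. Returns prior df d0, the prior
# variance s0^2 per feature, and the posterior variances.
squeeze_variances <- function(s2, df, amean, trend = TRUE, span = 0.4) {
  n <- length(s2)
  ok <- s2 > 0 & is.finite(s2)
  if (!any(ok)) {
    # all features fit exactly (noise-free data): no variance to moderate
    eps <- .Machine$double.eps
    return(list(df_prior = Inf, s0_sq = rep(eps, n), s2_post = rep(eps, n)))
  }
  # E[log s^2] = log sigma^2 + digamma(df/2) - log(df/2) under the chi^2 model
  bias <- digamma(df / 2) - log(df / 2)
  if (trend && sum(ok) >= 30) {
    fit <- stats::loess(log(s2[ok]) ~ amean[ok], span = span, degree = 1,
                        family = "symmetric",
                        control = stats::loess.control(iterations = 2))
    log_trend <- rep(NA_real_, n)
    log_trend[ok] <- fit$fitted
    # extrapolate flat for features excluded from the fit
    if (any(!ok)) {
      log_trend[!ok] <- stats::predict(
        fit, newdata = data.frame(amean = pmin(pmax(amean[!ok],
                                                    min(amean[ok])),
                                               max(amean[ok]))))
    }
  } else {
    log_trend <- rep(mean(log(s2[ok])), n)
  }
  s0_sq <- exp(log_trend - bias)
  z <- log(s2[ok] / s0_sq[ok])
  evar <- stats::var(z) - trigamma(df / 2)
  d0 <- if (is.na(evar) || evar <= 0) Inf else 2 * trigamma_inverse(evar)
  s2_post <- if (is.infinite(d0)) s0_sq else (d0 * s0_sq + df * s2) / (d0 + df)
  list(df_prior = d0, s0_sq = s0_sq, s2_post = s2_post)
}

#' Moderated differential-abundance test with an intensity variance trend
#'
#' Empirical-Bayes moderated t-tests on a log2 feature matrix. Per feature,
#' group means and the residual variance `s^2` (df `= n_channels -
#' n_groups`) are computed; a robust local regression of `log s^2` on the
#' mean log2 intensity gives the intensity-dependent prior variance
#' `s0^2(intensity)`; the prior degrees of freedom `d0` are estimated by
#' moment-matching `log(s^2 / s0^2)` against its theoretical log-F
#' distribution (trigamma inversion); posterior variances `(d0 s0^2 + d s^2)
#' / (d0 + d)` yield moderated t-statistics with `d0 + d` degrees of
#' freedom. q-values are BH-adjusted within each contrast.
#'
#' @param fm A [aggregate_psms()] feature matrix, or a numeric matrix of
#'   log2 intensities (features x channels) when `groups` is supplied.
#' @param groups Named character vector channel -> group; defaults to the
#'   channel set's groups when `fm` is a `feature_matrix`.
#' @param contrasts List of group pairs `c(numerator, denominator)`.
#' @param trend Fit the intensity variance trend (`TRUE`) or use a constant
#'   prior variance.
#' @param prior_df Optional override of the estimated prior df; `0` gives
#'   the ordinary per-feature equal-variance t-test.
#' @param log2_input Set to `TRUE` when `fm` is already on the log2 scale
#'   (always the case for a plain matrix input).
#' @return Tibble with one row per feature and contrast: `feature_id`,
#'   `species`, `contrast`, `mean_log2`, `log2fc`, `t`, `df_resid`,
#'   `df_prior`, `df_total`, `p`, `q`.
#' @export
fit_moderated_test <- function(fm, groups = NULL,
                               contrasts = list(c("2x", "1x"), c("6x", "1x")),
                               trend = TRUE, prior_df = NULL,
                               log2_input = FALSE) {
  if (inherits(fm, "feature_matrix")) {
    y <- feature_intensity_matrix(fm, log2 = !log2_input)
    groups <- groups %||% fm$channels$groups
    species <- fm$features$species
  } else {
    y <- as.matrix(fm)
    if (is.null(groups)) stop("`groups` is required for a plain matrix input")
    species <- rep(NA_character_, nrow(y))
  }
  if (is.null(names(groups))) names(groups) <- colnames(y)
  groups <- groups[colnames(y)]
  glev <- unique(groups)
  gsize <- table(factor(groups, levels = glev))
  if (any(gsize < 2)) stop("every group needs at least 2 channels")
  n <- ncol(y)
  k <- length(glev)
  d <- n - k
  if (d <= 0) stop("no residual degrees of freedom")

  gm <- vapply(glev, function(g) {
    rowMeans(y[, groups == g, drop = FALSE])
  }, numeric(nrow(y)))
  fitted <- gm[, match(groups, glev), drop = FALSE]
  s2 <- rowSums((y - fitted)^2) / d
  amean <- rowMeans(y)

  sq <- squeeze_variances(s2, d, amean, trend = trend)
  d0 <- prior_df %||% sq$df_prior
  s2_post <- if (!is.null(prior_df)) {
    if (prior_df == 0) s2
    else if (is.infinite(prior_df)) sq$s0_sq
    else (prior_df * sq$s0_sq + d * s2) / (prior_df + d)
  } else sq$s2_post
  df_total <- d0 + d

  rows <- lapply(contrasts, function(ct) {
    a <- ct[1]; b <- ct[2]
    if (!all(c(a, b) %in% glev)) stop("unknown group in contrast")
    fc <- gm[, match(a, glev)] - gm[, match(b, glev)]
    se <- sqrt(s2_post * (1 / gsize[[a]] + 1 / gsize[[b]]))
    tstat <- fc / se
    p <- 2 * stats::pt(-abs(tstat), df = df_total)
    tibble::tibble(feature_id = rownames(y) %||% as.character(seq_len(nrow(y))),
                   species = species,
                   contrast = paste0(a, "_vs_", b),
                   mean_log2 = unname(amean),
                   log2fc = unname(fc), t = unname(tstat),
                   df_resid = d, df_prior = d0, df_total = df_total,
                   p = unname(p), q = bh_fdr(unname(p)))
  })
  dplyr::bind_rows(rows)
}
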