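#' Score differential-abundance calls against the spike-in ground truth
#'
#' Every feature in a spike-in design is truly changed, so there are no true
#' negatives: a feature significant (`q < fdr_threshold`, strict) in its
#' species' expected direction for the contrast is a true positive, a
#' significant call in the opposite direction is a false positive, and a
#' non-significant feature is a false negative. Precision is
#' `TP / (TP + FP)`, recall `TP / (TP + FN)` and F1 their harmonic mean
#' (0 when a denominator is 0).
#'
#' @param results A [fit_moderated_test()] result tibble (one or more
#'   contrasts).
#' @param truth Ground truth as returned by [simulate_experiment()] (uses
#'   `truth$expected`: per-contrast, per-species log2 fold changes).
#' @param fdr_threshold Significance threshold on the BH q-value.
#' @return Tibble with one row per contrast: counts, precision, recall, F1,
#'   `n_features`, and per-species median log2 fold changes and median
#'   absolute fold-change errors.
#' @export
classify_and_score <- function(results, truth, fdr_threshold = 0.01) {
  if (anyNA(results$species) ||
      !all(results$species %in% truth$expected$species)) {
    stop("every scored feature needs a species present in the ground truth")
  }
  prf <- function(sig, hit) {
    tp <- sum(sig & hit)
    fp <- sum(sig) - tp
    fn <- sum(!sig)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    list(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f1 = f1)
  }
  one_contrast <- function(res) {
    exp_ct <- truth$expected[truth$expected$contrast == res$contrast[1], ]
    if (nrow(exp_ct) == 0) stop("contrast missing from ground truth: ",
                                res$contrast[1])
    truth_fc <- stats::setNames(exp_ct$log2fc, exp_ct$species)
    expected_sign <- sign(truth_fc)[res$species]
    sig <- res$q < fdr_threshold
    hit <- sign(res$log2fc) == expected_sign & expected_sign != 0
    all_s <- prf(sig, hit)
    by_sp <- lapply(c(yeast = "yeast", human = "human"), function(sp) {
      i <- res$species == sp
      if (any(i)) prf(sig[i], hit[i]) else NULL
    })
    med <- function(sp, v) {
      if (any(res$species == sp)) stats::median(v[res$species == sp]) else NA_real_
    }
    tibble::tibble(
      contrast = res$contrast[1], n_features = nrow(res),
      tp = all_s$tp, fp = all_s$fp, fn = all_s$fn,
      precision = all_s$precision, recall = all_s$recall, f1 = all_s$f1,
      f1_yeast = by_sp$yeast$f1 %||% NA_real_,
      f1_human = by_sp$human$f1 %||% NA_real_,
      median_log2fc_yeast = med("yeast", res$log2fc),
      median_log2fc_human = med("human", res$log2fc),
      median_abs_error_yeast = med("yeast",
                                   abs(res$log2fc - truth_fc[res$species])),
      median_abs_error_human = med("human",
                                   abs(res$log2fc - truth_fc[res$species]))
    )
  }
  dplyr::bind_rows(lapply(split(results, results$contrast), one_contrast))
}

#' Run the full 36-schema filtering benchmark
#'
#' For every schema in the grid: filter the (already normalized, annotated,
#' quantifiable) PSM table, aggregate to features, fit the moderated test
#' and score against the ground truth; one summary row per (schema,
#' contrast). Schemas leaving fewer than 10 features are flagged and their
#' scores set to `NA` rather than raising an error.
#'
#' @param x A normalized, quantifiable `psm_table`.
#' @param notch A [notch_region()].
#' @param truth Ground truth from [simulate_experiment()].
#' @param level Aggregation level, `"protein"` or `"peptide"`.
#' @param schemas List of [filter_schema()]; defaults to the 36-schema grid.
#' @param contrasts Group contrasts to test.
#' @param fdr_threshold Significance threshold.
#' @param min_psms Minimum complete PSMs per feature.
#' @return Tibble of evaluation summaries with the schema thresholds,
#'   `n_psms` surviving, and a `flagged` column.
#' @export
run_grid <- function(x, notch, truth, level = c("protein", "peptide"),
                     schemas = schema_grid(),
                     contrasts = list(c("2x", "1x"), c("6x", "1x")),
                     fdr_threshold = 0.01, min_psms = 2L) {
  level <- match.arg(level)
  rows <- lapply(names(schemas), function(nm) {
    sc <- schemas[[nm]]
    filt <- apply_filters(x, sc, notch = notch)
    fm <- aggregate_psms(filt$table, level = level, min_psms = min_psms)
    base <- tibble::tibble(
      schema = nm, level = level,
      min_delta_cn = sc$min_delta_cn, max_coisolation = sc$max_coisolation,
      min_avg_sn = sc$min_avg_sn, remove_notch = sc$remove_notch,
      n_psms = filt$report$output_count
    )
    if (nrow(fm$features) < 10) {
      scores <- tibble::tibble(
        contrast = vapply(contrasts, function(ct) paste0(ct[1], "_vs_", ct[2]),
                          character(1)),
        n_features = nrow(fm$features), tp = NA_integer_, fp = NA_integer_,
        fn = NA_integer_, precision = NA_real_, recall = NA_real_,
        f1 = NA_real_, f1_yeast = NA_real_, f1_human = NA_real_,
        median_log2fc_yeast = NA_real_,
        median_log2fc_human = NA_real_, median_abs_error_yeast = NA_real_,
        median_abs_error_human = NA_real_)
      flagged <- TRUE
    } else {
      res <- fit_moderated_test(fm, contrasts = contrasts)
      scores <- classify_and_score(res, truth, fdr_threshold)
      flagged <- FALSE
    }
    dplyr::bind_cols(base[rep(1, nrow(scores)), ], scores,
                     tibble::tibble(flagged = flagged))
  })
  dplyr::bind_rows(rows)
}

#' Per-feature change in fold-change error due to notch filtering
#'
#' For features affected by the notch (at least one member PSM intensity
#' below the upper boundary), compares the absolute fold-change error with
#' and without notch filtering: `delta = |log2FC_without - truth| -
#' |log2FC_with - truth|`, so positive values mean notch filtering moved the
#' estimate closer to the ground truth. Affected features present only in
#' the unfiltered results are reported separately as lost to filtering.
#'
#' @param with_filter,without_filter [fit_moderated_test()] results from the
#'   runs with and without notch filtering.
#' @param truth Ground truth from [simulate_experiment()].
#' @param affected Character vector of affected feature ids (see
#'   [notch_exposure()]).
#' @return A list with `delta` (tibble: `feature_id`, `species`, `contrast`,
#'   `log2fc_with`, `log2fc_without`, `truth_log2fc`, `delta`) and `lost`
#'   (tibble of affected features absent from the filtered run).
#' @export
compare_notch_filtering <- function(with_filter, without_filter, truth,
                                    affected) {
  wo <- without_filter[without_filter$feature_id %in% affected, ]
  wi <- with_filter[with_filter$feature_id %in% affected, ]
  joined <- dplyr::inner_join(
    wo[, c("feature_id", "species", "contrast", "log2fc")],
    wi[, c("feature_id", "contrast", "log2fc")],
    by = c("feature_id", "contrast"), suffix = c("_without", "_with"))
  tf <- truth$expected
  key <- paste(tf$contrast, tf$species)
  truth_fc <- stats::setNames(tf$log2fc, key)
  joined$truth_log2fc <- unname(truth_fc[paste(joined$contrast, joined$species)])
  joined$delta <- abs(joined$log2fc_without - joined$truth_log2fc) -
    abs(joined$log2fc_with - joined$truth_log2fc)
  lost_ids <- setdiff(unique(wo$feature_id), unique(wi$feature_id))
  list(delta = tibble::as_tibble(joined[, c("feature_id", "species",
                                            "contrast", "log2fc_with",
                                            "log2fc_without", "truth_log2fc",
                                            "delta")]),
       lost = wo[wo$feature_id %in% lost_ids,
                 c("feature_id", "species", "contrast", "log2fc")])
}
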