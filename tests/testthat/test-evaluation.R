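mock_truth <- function() {
  list(expected = expected_log2fc(build_mix_design()))
}

mock_results <- function(species, log2fc, q, contrast = "6x_vs_1x") {
  tibble::tibble(feature_id = sprintf("F%03d", seq_along(species)),
                 species = species, contrast = contrast,
                 log2fc = log2fc, q = q)
}

test_that("precision, recall and F1 follow their closed forms", {
  truth <- mock_truth()
  # one TP (yeast up), one FP (yeast down), one FN (not significant)
  res <- mock_results(c("yeast", "yeast", "yeast"),
                      c(2.5, -1, 2.5), c(0.001, 0.001, 0.5))
  s <- classify_and_score(res, truth)
  expect_equal(s[, c("tp", "fp", "fn")],
               tibble::tibble(tp = 1L, fp = 1L, fn = 1L), ignore_attr = TRUE)
  expect_equal(s$precision, 0.5)
  expect_equal(s$recall, 0.5)
  expect_equal(s$f1, 0.5)  # F1 = precision = recall when they agree

  # perfect classifier: all yeast up, all human down, all significant
  res2 <- mock_results(c("yeast", "yeast", "human"),
                       c(2.5, 2.6, -0.4), c(1e-4, 1e-4, 1e-4))
  s2 <- classify_and_score(res2, truth)
  expect_equal(c(s2$precision, s2$recall, s2$f1), c(1, 1, 1))
})

test_that("significance uses a strict q-value threshold", {
  truth <- mock_truth()
  res <- mock_results("yeast", 2.5, 0.01)
  s <- classify_and_score(res, truth)
  expect_equal(s$tp, 0L)   # q = 0.01 is NOT below the 1% threshold
  expect_equal(s$fn, 1L)
  s2 <- classify_and_score(mock_results("yeast", 2.5, 0.00999), truth)
  expect_equal(s2$tp, 1L)
})

test_that("scores are permutation-invariant and species are validated", {
  truth <- mock_truth()
  set.seed(20)
  res <- mock_results(sample(c("yeast", "human"), 50, TRUE),
                      rnorm(50), runif(50, 0, 0.05))
  perm <- res[sample(nrow(res)), ]
  expect_equal(classify_and_score(res, truth),
               classify_and_score(perm, truth))
  bad <- mock_results("mouse", 1, 0.001)
  expect_error(classify_and_score(bad, truth), "species")
})

test_that("a noise-free undistorted benchmark yields a perfect 6x contrast", {
  d <- build_mix_design()
  p <- sim_params(reporter_noise_sd = 0.02, psm_scale_sd = 0.5,
                  interference_dist = function(n) rep(0, n),
                  missing_rate = 0, notch = NULL,
                  n_yeast_proteins = 40, n_human_proteins = 60, seed = 21)
  sim <- simulate_experiment(d, p)
  fm <- aggregate_psms(sim$table, "protein")
  res <- fit_moderated_test(fm)
  s <- classify_and_score(res, sim$truth)
  expect_equal(s$f1[s$contrast == "6x_vs_1x"], 1)
})

test_that("the grid produces one scored row per schema and contrast", {
  sim <- ref_sim(seed = 23, n_yeast_proteins = 60, n_human_proteins = 140)
  nr <- notch_region()
  norm <- center_median_normalize(sim$table)
  g <- run_grid(norm, nr, sim$truth, "protein")
  expect_equal(nrow(g), 72L)
  expect_equal(length(unique(g$schema)), 36L)
  # notch removal never gains features at fixed thresholds
  wide <- tidyr::pivot_wider(
    g[g$contrast == "6x_vs_1x",
      c("min_delta_cn", "max_coisolation", "min_avg_sn", "remove_notch",
        "n_features")],
    names_from = "remove_notch", values_from = "n_features")
  expect_true(all(wide$`TRUE` <= wide$`FALSE`))
  # determinism
  g2 <- run_grid(norm, nr, sim$truth, "protein")
  expect_identical(g, g2)
})

test_that("schemas leaving too few features are flagged, not fatal", {
  cs <- toy_channels(10)
  m <- 2^matrix(rnorm(40, 9, 1), 4, 10)
  tab <- toy_table(m, channels = channel_set(),
                   species = "yeast", master = c("A", "A", "B", "B"))
  truth <- list(expected = expected_log2fc(build_mix_design()))
  g <- run_grid(tab, notch_region(), truth, "protein")
  expect_true(all(g$flagged))
  expect_true(all(is.na(g$f1)))
})

test_that("the notch-filtering comparison covers exactly the affected features", {
  truth <- mock_truth()
  without <- mock_results(c("yeast", "yeast", "yeast"),
                          c(2.7, 2.0, 2.5), c(0.001, 0.001, 0.001))
  with <- without
  with$log2fc <- c(2.4, 2.0, 2.5)
  with <- with[1:2, ]  # F003 lost to filtering
  cmp <- compare_notch_filtering(with, without, truth,
                                 affected = c("F001", "F002", "F003"))
  # F001: |2.7 - log2 6| - |2.4 - log2 6| : filtering moved it further away
  expect_equal(cmp$delta$delta[cmp$delta$feature_id == "F001"],
               abs(2.7 - log2(6)) - abs(2.4 - log2(6)))
  expect_equal(cmp$delta$delta[cmp$delta$feature_id == "F002"], 0)
  expect_equal(cmp$lost$feature_id, "F003")

  # unaffected features never enter the comparison
  cmp2 <- compare_notch_filtering(with, without, truth, affected = "F002")
  expect_equal(cmp2$delta$feature_id, "F002")
})
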