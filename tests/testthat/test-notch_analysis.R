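test_that("notch fractions count non-missing values below the boundaries", {
  nr <- notch_region()
  m <- 2^matrix(c(rep(9, 17), 5.0, 4.0, 3.0), 4, 5)
  tab <- toy_table(m, channels = toy_channels(5))
  st <- notch_stats(tab, nr)
  overall <- st[st$channel == "overall", ]
  expect_equal(overall$frac_below_upper, 3 / 20)
  expect_equal(overall$frac_in_band, 1 / 20)   # only the 5.0 lies in the band

  high <- toy_table(2^matrix(9, 3, 3))
  st_high <- notch_stats(high, nr)
  expect_true(all(st_high$frac_below_upper == 0))
})

test_that("notch fractions are invariant under matched global scaling", {
  sim <- ref_sim()
  nr <- notch_region()
  st1 <- notch_stats(sim$table, nr)
  scaled <- set_intensities_for_test(sim$table, intensity_matrix(sim$table) * 8)
  st2 <- notch_stats(scaled, notch_region(nr$lower + 3, nr$upper + 3))
  expect_equal(st1$frac_below_upper, st2$frac_below_upper)
  expect_equal(st1$frac_in_band, st2$frac_in_band)
})

test_that("boundary detection recovers an injected band and rejects smooth data", {
  # a hard empty band carved between 4 and 6
  set.seed(5)
  x <- rnorm(50000, 8, 2.5)
  x <- x[x < 4 | x > 6]
  nr <- detect_notch(2^x)
  expect_false(is.null(nr))
  expect_gte(nr$lower, 4 - 0.1)
  expect_lte(nr$upper, 6 + 0.1)

  # unimodal log-normal data has no band
  set.seed(6)
  expect_null(detect_notch(2^rnorm(50000, 11, 2.5)))
  expect_error(detect_notch(numeric()), "no intensities")
  expect_warning(detect_notch(2^rnorm(100, 8, 1)), "1000")
})

test_that("boundary detection is reliable over seeded artifact replicates", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    lx <- apply_notch_artifact(rnorm(20000, 11, 2.5), notch_region(), 1)
    nr <- detect_notch(2^lx)
    if (!is.null(nr) && abs(nr$lower - 4.25) <= 0.25 &&
        abs(nr$upper - 5.75) <= 0.25) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 45L)  # >= 90% of 50 replicates
})

test_that("redundant-PSM prediction matches the hand-computed oracle", {
  cs <- toy_channels(3)
  m <- matrix(c(100, 200, 300,
                60, 90, NA,
                10, 20, 30), 3, 3, byrow = TRUE)
  tab <- toy_table(m, channels = cs, sequence = c("AAA", "AAA", "AAA"))
  preds <- predict_expected(tab)
  # top PSM (total 600) contributes no entries
  expect_false("P001" %in% preds$psm_id)
  p2 <- preds[preds$psm_id == "P002", ]
  # r = (60 + 90) / (100 + 200) = 0.5 over the shared channels
  expect_equal(p2$predicted, c(50, 100))
  expect_equal(p2$observed, c(60, 90))
  p3 <- preds[preds$psm_id == "P003", ]
  # exactly proportional PSM: predictions equal observations
  expect_equal(p3$predicted, p3$observed)
})

test_that("prediction drops singleton groups and incomplete top PSMs", {
  cs <- toy_channels(3)
  m <- matrix(c(100, 200, 300,
                500, NA, 600,
                50, 60, 70), 3, 3, byrow = TRUE)
  tab <- toy_table(m, channels = cs, sequence = c("SOLO", "TOPNA", "TOPNA"))
  preds <- predict_expected(tab)
  expect_equal(nrow(preds), 0L)  # singleton excluded; top of TOPNA has NA
})

test_that("prediction is scale-equivariant in any non-top PSM", {
  sim <- ref_sim(seed = 31, n_yeast_proteins = 40, n_human_proteins = 40)
  preds <- predict_expected(sim$table)
  target <- preds$psm_id[1]
  tab2 <- sim$table
  i <- which(tab2$psms$psm_id == target)
  labs <- tab2$channels$labels
  tab2$psms[i, labs] <- tab2$psms[i, labs] * 0.5  # stays non-top
  preds2 <- predict_expected(tab2)
  expect_equal(preds2$predicted[preds2$psm_id == target],
               0.5 * preds$predicted[preds$psm_id == target])
  others <- setdiff(unique(preds$psm_id), target)
  expect_equal(preds2$predicted[preds2$psm_id %in% others],
               preds$predicted[preds$psm_id %in% others])
})

test_that("underestimation fractions use strict inequality and honest bins", {
  preds <- tibble::tibble(sequence = "S", top_psm_id = "T", psm_id = "P",
                          channel = "A", observed = 32, predicted = 32)
  uf <- underestimation_fraction(preds, 0.5)
  expect_equal(uf$frac_below, 0)  # tie counts as not-below
  expect_error(underestimation_fraction(preds, 0), "positive")

  # symmetric multiplicative noise without a notch: fractions near 1/2
  sim <- ref_sim(seed = 17, notch = NULL)
  uf2 <- underestimation_fraction(predict_expected(sim$table), 1)
  big <- uf2[uf2$n >= 200, ]
  expect_true(all(abs(big$frac_below - 0.5) < 3 * sqrt(0.25 / big$n)))
})

test_that("tag-vs-comparator differences recover the design contrast", {
  d <- build_mix_design()
  p <- sim_params(reporter_noise_sd = 0, psm_scale_sd = 0,
                  interference_dist = function(n) rep(0, n),
                  missing_rate = 0, notch = NULL,
                  n_yeast_proteins = 15, n_human_proteins = 15, seed = 3)
  sim <- simulate_experiment(d, p)
  ytab <- sim$table
  ytab$psms <- ytab$psms[ytab$psms$species == "yeast", ]
  tvc <- tag_vs_comparator(ytab, "130N", c("126", "127N", "127C", "128N"))
  expect_equal(unique(round(tvc$diffs$diff, 10)), round(log2(6), 10))

  flat <- toy_table(matrix(100, 2, 3))
  tvc0 <- tag_vs_comparator(flat, "A", c("B", "C"))
  expect_true(all(tvc0$diffs$diff == 0))
  expect_error(tag_vs_comparator(flat, "A", c("A", "B")), "disjoint")
  expect_error(tag_vs_comparator(flat, "A", character()), "empty")
})
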