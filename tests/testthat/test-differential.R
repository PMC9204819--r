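brute_force_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    r <- rank(p, ties.method = "max")[i]
    min(1, min(vapply(which(rank(p, ties.method = "max") >= r), function(j) {
      m * p[j] / rank(p, ties.method = "max")[j]
    }, numeric(1))))
  }, numeric(1))
}

test_that("BH q-values match the step-up definition and brute force", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, brute_force_bh(p))
    expect_equal(q, p.adjust(p, "BH"))
    # q monotone non-decreasing in p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("with zero prior df the moderated t equals the two-sample t-test", {
  set.seed(8)
  cs <- channel_set(LETTERS[1:6],
                    stats::setNames(rep(c("1x", "2x"), each = 3), LETTERS[1:6]))
  y <- matrix(rnorm(20 * 6, 8, 1), 20, 6,
              dimnames = list(sprintf("F%02d", 1:20), cs$labels))
  res <- fit_moderated_test(y, groups = cs$groups,
                            contrasts = list(c("2x", "1x")), prior_df = 0)
  for (i in 1:20) {
    tt <- t.test(y[i, 4:6], y[i, 1:3], var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("adding a constant to all cells changes no statistic", {
  set.seed(9)
  y <- matrix(rnorm(200 * 10, 10, 1), 200, 10,
              dimnames = list(NULL, channel_set()$labels))
  r1 <- fit_moderated_test(y, groups = channel_set()$groups)
  r2 <- fit_moderated_test(y + 5, groups = channel_set()$groups)
  expect_equal(r1$t, r2$t)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$df_prior, r2$df_prior)
})

test_that("prior df is recovered on data simulated with known d0", {
  set.seed(10)
  n <- 5000
  d0 <- 4
  s0 <- 0.05
  sig2 <- d0 * s0 / rchisq(n, d0)
  y <- matrix(rnorm(n * 10, 0, sqrt(rep(sig2, 10))), n, 10,
              dimnames = list(NULL, channel_set()$labels))
  res <- fit_moderated_test(y, groups = channel_set()$groups)
  expect_lt(abs(res$df_prior[1] - d0) / d0, 0.3)
})

test_that("the null type-I error is calibrated at nominal level", {
  set.seed(77)
  n <- 2000
  sig2 <- 6 * 0.04 / rchisq(n, 6)
  y <- matrix(rnorm(n * 10, 0, sqrt(rep(sig2, 10))), n, 10,
              dimnames = list(NULL, channel_set()$labels))
  res <- fit_moderated_test(y, groups = channel_set()$groups)
  frac <- mean(res$p[res$contrast == "6x_vs_1x"] < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
})

test_that("large prior df shrinks every variance to the trend", {
  set.seed(11)
  y <- matrix(rnorm(100 * 10, 10, 1), 100, 10,
              dimnames = list(NULL, channel_set()$labels))
  res <- fit_moderated_test(y, groups = channel_set()$groups,
                            prior_df = Inf, trend = FALSE)
  # with a constant prior variance all features share one standard error,
  # so |t| must be proportional to |log2FC| within a contrast
  r6 <- res[res$contrast == "6x_vs_1x", ]
  expect_lt(max(abs(r6$t / r6$log2fc - (r6$t / r6$log2fc)[1])), 1e-8)
})

test_that("moderated results agree with an independent implementation", {
  skip_if_not_installed("limma")
  set.seed(12)
  n <- 1500
  sig2 <- 8 * 0.03 / rchisq(n, 8)
  means <- rnorm(n, 10, 2)
  y <- matrix(rnorm(n * 10, rep(means, 10), sqrt(rep(sig2, 10))), n, 10,
              dimnames = list(NULL, channel_set()$labels))
  res <- fit_moderated_test(y, groups = channel_set()$groups)
  r6 <- res[res$contrast == "6x_vs_1x", ]

  grp <- factor(channel_set()$groups, levels = c("1x", "2x", "6x"))
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- c("g1", "g2", "g6")
  fit <- limma::lmFit(y, design)
  cb <- limma::contrasts.fit(fit, limma::makeContrasts(g6 - g1,
                                                       levels = design))
  eb <- limma::eBayes(cb, trend = TRUE)
  expect_equal(r6$log2fc, unname(eb$coefficients[, 1]), tolerance = 1e-12)
  expect_gt(cor(r6$t, eb$t[, 1]), 0.999)
  expect_lt(abs(r6$df_prior[1] - eb$df.prior) / eb$df.prior, 0.25)
})

test_that("design degeneracies are rejected", {
  y <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, LETTERS[1:4]))
  expect_error(fit_moderated_test(y, groups = c(A = "a", B = "a", C = "b",
                                                D = "c")),
               "at least 2 channels")
  expect_error(fit_moderated_test(y), "groups")
})
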