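test_that("hdi and rope_test reproduce textbook cases", {
  expect_error(hdi(rnorm(5)), "too few")
  set.seed(1)
  draws <- rnorm(2e5)
  h <- hdi(draws)
  expect_equal(h, c(-1.96, 1.96), tolerance = 0.03)
  # point mass outside the ROPE passes
  r <- rope_test(rep(1, 1000) + rnorm(1000, 0, 1e-9), 0.2)
  expect_equal(r$decision, "outside")
  # tight null posterior is inside
  r0 <- rope_test(rnorm(5e4, 0, 0.01), 0.2)
  expect_equal(r0$decision, "inside")
  expect_gt(r0$hdi_fraction_in_rope, 0.99)
  # normal-quantile oracle: N(0.25, 0.05) -> HDI ~ [0.152, 0.348]; entirely
  # outside a ROPE of half-width 0.15, but overlapping one of 0.2 (the
  # decision requires the whole interval outside the region)
  dr <- rnorm(2e5, 0.25, 0.05)
  r1 <- rope_test(dr, 0.15)
  expect_equal(r1$decision, "outside")
  expect_equal(r1$hdi[1], 0.25 - 1.96 * 0.05, tolerance = 0.01)
  expect_equal(r1$hdi[2], 0.25 + 1.96 * 0.05, tolerance = 0.01)
  expect_equal(rope_test(dr, 0.2)$decision, "overlap")
})

test_that("Savage-Dickey Bayes factor matches the conjugate closed form", {
  # oracle: marginal likelihood ratio for y_bar under known-sigma normal
  # data with a N(0, s^2) prior on the mean
  sigma <- 1; n <- 20; s <- 2
  se <- sigma / sqrt(n)
  set.seed(33)
  for (eff in c(0, 0.5, 1, 2)) {
    ybar <- eff * se
    v <- 1 / (n / sigma^2 + 1 / s^2)
    m <- v * n * ybar / sigma^2
    bf_oracle <- dnorm(ybar, 0, sqrt(s^2 + se^2)) / dnorm(ybar, 0, se)
    draws <- rnorm(4e4, m, sqrt(v))
    bf <- bayes_factor_directional(draws, prior_sd = s)
    expect_equal(bf$bf_10, bf_oracle, tolerance = 0.05)
  }
})

test_that("prior-as-posterior gives BF near 1; decisive data give a huge BF_+0", {
  set.seed(4)
  prior_draws <- rnorm(4e4, 0, 1.5)
  bf <- bayes_factor_directional(prior_draws, prior_sd = 1.5)
  expect_equal(bf$bf_10, 1, tolerance = 0.05)
  strong <- rnorm(4e4, 20, 1)
  bf2 <- bayes_factor_directional(strong, prior_sd = 5)
  expect_gt(bf2$bf_plus0, 1e3)
  # kernel path falls back with a warning when no draws lie near zero
  expect_warning(
    bayes_factor_directional(strong, prior_sd = 5, density_method = "kernel"),
    "falling back")
})

test_that("cell-means model recovers a known mean and concentrates on null data", {
  tab <- sim_c1_table(n = 15, cond_means = list(CC = c(V = 2)),
                      electrodes = "O1", participant_sd = 0.3,
                      resid_sd = 1, seed = 2)
  fit <- fit_cell_means(tab, test_spec(seed = 2))
  s <- fit$summary
  expect_true(s$hdi_lower <= 2 && 2 <= s$hdi_upper)
  expect_equal(s$mean, 2, tolerance = 0.8)
  expect_equal(s$decision, "present")
  # identically-zero responses concentrate at zero
  tab0 <- tab; tab0$delta_c1 <- 0
  fit0 <- fit_cell_means(tab0, test_spec(seed = 3))
  expect_lt(abs(fit0$summary$mean), 1e-3)
  expect_error(fit_cell_means(tab[tab$participant == "CC01", ], test_spec()),
               ">= 2 participants")
})

test_that("posterior means are scale-equivariant under the prior rule", {
  tab <- sim_c1_table(n = 10, cond_means = list(CC = c(V = 1, AV_i = 0.4, AV_c = 0.1)),
                      seed = 6)
  tab2 <- tab; tab2$delta_c1 <- 2 * tab$delta_c1
  f1 <- fit_cell_means(tab, test_spec(draws = 1500, seed = 9))
  f2 <- fit_cell_means(tab2, test_spec(draws = 1500, seed = 9))
  expect_equal(f2$summary$mean, 2 * f1$summary$mean, tolerance = 1e-8)
})

test_that("fixed seed makes the full inference bit-reproducible", {
  tab <- sim_c1_table(n = 8, seed = 7)
  f1 <- fit_cell_means(tab, test_spec(draws = 1200, seed = 5))
  f2 <- fit_cell_means(tab, test_spec(draws = 1200, seed = 5))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$summary, f2$summary)
})

test_that("planned contrasts detect a large suppression and not a self-contrast", {
  tab <- sim_c1_table(
    n = 14,
    cond_means = list(CC = c(V = 2, AV_i = 1, AV_c = 0),
                      MCC = c(V = 2, AV_i = 2, AV_c = 2)),
    seed = 10)
  ct <- test_contrasts(tab, spec = test_spec(seed = 10))
  s <- ct$summary
  vavc <- s[s$contrast == "CC:V-AV_c" & s$electrode == "O1", ]
  expect_true(vavc$substantial)
  expect_equal(vavc$estimate, 2, tolerance = 0.7)
  # between-group AV_c contrast must also be substantial
  bg <- s[s$contrast == "AV_c:MCC-CC" & s$electrode == "O1", ]
  expect_true(bg$substantial)
  # a cell against itself is degenerate: identically zero, BF_10 = 0
  cells <- attr(delta_c1_contrast_matrix("CC", "MCC"), "cells")
  self <- stats::setNames(numeric(6), cells)
  ct2 <- test_contrasts(tab, contrasts = list(self = self,
                                              real = delta_c1_contrast_matrix("CC", "MCC")[[2]]),
                        spec = test_spec(draws = 1500, seed = 4))
  sc <- ct2$summary[ct2$summary$contrast == "self", ]
  expect_true(all(sc$estimate == 0))
  expect_true(all(sc$bf_10 < 1))
  # a rank-deficient real contrast set errors
  dup <- delta_c1_contrast_matrix("CC", "MCC")[c(1, 1)]
  expect_error(test_contrasts(tab, contrasts = dup, spec = test_spec()),
               "rank-deficient")
})

test_that("ordered-factor trend test recovers linear and quadratic structure", {
  spec <- test_spec(seed = 11)
  lin <- linear_trend_test(
    sim_c1_table(n = 14, cond_means = list(CC = c(V = 2, AV_i = 1, AV_c = 0)),
                 resid_sd = 0.3, seed = 11), spec)
  s <- lin$summary
  expect_true(s$substantial[s$component == "linear_decline"])
  expect_gt(s$estimate[s$component == "linear_decline"], 0)
  flat <- linear_trend_test(
    sim_c1_table(n = 14, cond_means = list(CC = c(V = 1, AV_i = 1, AV_c = 1)),
                 resid_sd = 0.3, seed = 12), spec)
  expect_lt(flat$summary$bf_10[flat$summary$component == "linear_decline"], 1)
  vshape <- linear_trend_test(
    sim_c1_table(n = 14, cond_means = list(CC = c(V = 0, AV_i = 1, AV_c = 0)),
                 resid_sd = 0.2, seed = 13), spec)
  sv <- vshape$summary
  expect_lt(abs(sv$estimate[sv$component == "linear_decline"]), 0.25)
  expect_true(sv$bf_10[sv$component == "quadratic"] > 3)
  expect_error(linear_trend_test(
    sim_c1_table(n = 5, cond_means = list(CC = c(V = 1, AV_i = 1))), spec),
    "must be present")
})

test_that("the presence decision rate is monotone in the true effect", {
  effects <- c(0, 0.6, 1.2)
  reps <- 100
  rate <- numeric(length(effects))
  for (k in seq_along(effects)) {
    hits <- 0L
    for (r in seq_len(reps)) {
      tab <- sim_c1_table(n = 12, cond_means = list(CC = c(V = effects[k])),
                          electrodes = "O1", participant_sd = 0.3,
                          resid_sd = 0.5, seed = 1000 * k + r)
      fit <- fit_cell_means(tab, model_spec(draws = 1200, seed = r))
      hits <- hits + (fit$summary$decision == "present")
    }
    rate[k] <- hits / reps
  }
  expect_true(all(diff(rate) >= -0.05))   # monotone up to MC noise
  expect_lt(rate[1], 0.2)
  expect_gt(rate[3], 0.8)
})
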