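test_that("deterministic channels reduce the race to a minimum of constants", {
  cfg <- rt_sim_config(channel_params = list(A = c(mu = 500, sigma = 0, tau = 0),
                                             V = c(mu = 450, sigma = 0, tau = 0)),
                       n_trials = 20, n_participants = 2, miss_rate = 0, seed = 1)
  rt <- simulate_rt_dataset(cfg)
  av <- rt$rt[rt$target_class == "AV_double"]
  expect_true(all(av == 450))
  expect_true(all(rt$rt[rt$stim_type == "A" & rt$target_class == "A_only"] == 500))
})

test_that("a zero coactivation shift reproduces the independent race exactly", {
  base <- list(A = c(mu = 350, sigma = 40, tau = 90),
               V = c(mu = 380, sigma = 40, tau = 90))
  r1 <- simulate_rt_dataset(rt_sim_config(model = "race_independent",
                                          channel_params = base,
                                          n_trials = 50, n_participants = 3,
                                          seed = 5))
  r2 <- simulate_rt_dataset(rt_sim_config(model = "coactivation",
                                          coactivation_shift = 0,
                                          channel_params = base,
                                          n_trials = 50, n_participants = 3,
                                          seed = 5))
  expect_identical(r1, r2)
})

test_that("rt generator is deterministic and validates its configuration", {
  cfg <- rt_sim_config(n_trials = 10, n_participants = 2, seed = 2)
  expect_identical(simulate_rt_dataset(cfg), simulate_rt_dataset(cfg))
  expect_error(rt_sim_config(model = "telepathy"), "arg")
  expect_error(rt_sim_config(coactivation_shift = -5), ">= 0")
  expect_error(rt_sim_config(target_prob = 0), "target_prob")
})

test_that("mean audiovisual RT matches an independent Monte-Carlo oracle", {
  cfg <- rt_sim_config(channel_params = list(A = c(mu = 300, sigma = 30, tau = 100),
                                             V = c(mu = 300, sigma = 30, tau = 100)),
                       n_trials = 10000, n_participants = 1, miss_rate = 0,
                       seed = 3)
  rt <- simulate_rt_dataset(cfg)
  av <- rt$rt[rt$target_class == "AV_double"]
  # brute-force oracle: fresh large samples of the min distribution
  set.seed(1234)
  n_o <- 2e5
  oracle <- pmin(rnorm(n_o, 300, 30) + rexp(n_o, 1 / 100),
                 rnorm(n_o, 300, 30) + rexp(n_o, 1 / 100))
  sem <- sqrt(var(av) / length(av) + var(oracle) / n_o)
  expect_lt(abs(mean(av) - mean(oracle)), 2 * sem)
})

test_that("independent race satisfies the race bound on analytic CDFs", {
  set.seed(8)
  for (i in 1:20) {
    mu <- runif(2, 250, 500); sig <- runif(2, 5, 60); tau <- runif(2, 20, 150)
    t <- seq(100, 1500, by = 10)
    fa <- pexgauss(t, mu[1], sig[1], tau[1])
    fv <- pexgauss(t, mu[2], sig[2], tau[2])
    fav <- 1 - (1 - fa) * (1 - fv)      # independent-race min distribution
    expect_true(all(fav <= fa + fv + 1e-12))
  }
})

test_that("misses delete responses at the configured rate and counts are exact", {
  cfg <- rt_sim_config(n_trials = 500, n_participants = 2, miss_rate = 0.1,
                       seed = 6)
  rt <- simulate_rt_dataset(cfg)
  tgt <- rt[rt$is_target, ]
  expect_true(all(is.na(tgt$rt[!tgt$responded])))
  expect_equal(mean(!tgt$responded), 0.1, tolerance = 0.02)
  cnt <- table(tgt$target_class, tgt$congruence)
  expect_equal(unname(cnt["AV_double", "congruent"]), 2 * 500)
  # standards accompany targets at the 80/20 ratio
  expect_equal(sum(!rt$is_target), 4 * sum(rt$is_target))
})

test_that("ex-Gaussian CDF matches simulation", {
  set.seed(9)
  x <- rexgauss(2e5, 400, 50, 120)
  for (q in c(450, 550, 700)) {
    expect_equal(mean(x <= q), pexgauss(q, 400, 50, 120), tolerance = 0.005)
  }
  expect_equal(pexgauss(qexgauss(0.3, 400, 50, 120), 400, 50, 120), 0.3,
               tolerance = 1e-6)
})
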