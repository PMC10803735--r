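test_that("performance rates follow their definitions exactly", {
  rt <- data.frame(
    participant = "P1",
    target_class = c(rep("V_only", 10), rep("standard", 20)),
    is_target = c(rep(TRUE, 10), rep(FALSE, 20)),
    responded = c(rep(TRUE, 9), FALSE, rep(FALSE, 20)),
    rt = c(rnorm(9, 500, 10), rep(NA, 21)),
    correct = TRUE)
  pr <- performance_rates(rt)
  expect_equal(pr$hits$hit_rate, 0.9)
  expect_equal(pr$false_positives$fp_rate, 0)
  rt$responded[11] <- TRUE; rt$rt[11] <- 400
  expect_equal(performance_rates(rt)$false_positives$fp_rate, 1 / 20)
})

test_that("hit rate of a simulated miss process is binomially consistent", {
  cfg <- rt_sim_config(n_trials = 1250, n_participants = 1, miss_rate = 0.1,
                       seed = 14)
  pr <- performance_rates(simulate_rt_dataset(cfg))
  n <- sum(pr$hits$n_targets)
  p_hat <- sum(pr$hits$hit_rate * pr$hits$n_targets) / n
  se <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(p_hat - 0.9), 3 * se)
})

test_that("redundancy gain is the min-of-means arithmetic", {
  mk <- function(stim, cls, cong, m, n = 20) data.frame(
    participant = "P1", group = "G", stim_type = stim, target_class = cls,
    congruence = cong, is_target = TRUE, responded = TRUE,
    rt = rep(m, n), correct = TRUE)
  rt <- rbind(mk("A", "A_only", "none", 500),
              mk("AV", "A_only", "congruent", 520),
              mk("V", "V_only", "none", 450),
              mk("AV", "V_only", "congruent", 480),
              mk("AV", "AV_double", "congruent", 400))
  g <- redundancy_gain(rt)
  expect_equal(g$gain_av, 50)
  rt2 <- rt; rt2$rt[rt2$target_class == "AV_double"] <- 450
  expect_equal(redundancy_gain(rt2)$gain_av, 0)
  rt3 <- rt; rt3$rt[rt3$target_class == "AV_double"] <- 470
  expect_equal(redundancy_gain(rt3)$gain_av, -20)   # may be negative
  expect_error(redundancy_gain(rt[rt$target_class != "A_only", ]),
               "empty target class")
})

test_that("empirical quantiles and CDFs use the interpolation conventions", {
  rt <- data.frame(
    participant = "P1", group = "G",
    stim_type = rep(c("A", "V", "AV"), each = 3),
    target_class = rep(c("A_only", "V_only", "AV_double"), each = 3),
    congruence = "congruent",
    is_target = TRUE, responded = TRUE,
    rt = c(400, 500, 600, 400, 500, 600, 400, 500, 600), correct = TRUE)
  cdfs <- estimate_cdfs(rt, grid = 0.5, min_trials = 3)
  expect_equal(cdfs$t, 500)            # type-7 median of odd n
  expect_equal(cdfs$f_a, 0.5)
  # identical RTs give a step CDF
  rt$rt <- 300
  cdfs2 <- estimate_cdfs(rt, grid = c(0.25, 0.5), min_trials = 3)
  expect_true(all(cdfs2$t == 300))
  expect_true(all(cdfs2$f_av == 1))
  # insufficient trials exclude the participant with a logged reason
  expect_error(estimate_cdfs(rt, min_trials = 10), "no participant")
})

test_that("exponential 25th percentile matches the closed form within 3 SE", {
  set.seed(15)
  n <- 1e4
  x <- rexp(n, 1 / 200)
  q <- quantile(x, 0.25, type = 7, names = FALSE)
  q_true <- -200 * log(0.75)
  se <- sqrt(0.25 * 0.75 / n) / ((1 / 200) * 0.75)   # asymptotic quantile SE
  expect_lt(abs(q - q_true), 3 * se)
})

test_that("violation area: bound met with equality gives 0; rectangle gives its area", {
  fa <- function(t) pmin(pmax(t / 1000, 0), 1)
  fv <- function(t) pmin(pmax((t - 100) / 1000, 0), 1)
  fav_eq <- function(t) pmin(1, fa(t) + fv(t))
  expect_equal(rmi_violation_area(fa, fv, fav_eq, range = c(0, 2000)), 0)
  # excess of exactly 0.1 over a 50 ms stretch -> area 5 ms; all three
  # step functions are monotone: F_AV jumps at 300, F_A catches up at 350
  fa_s <- function(t) 0.2 + 0.1 * (t >= 350)
  fv_s <- function(t) rep(0.2, length(t))
  fav_s <- function(t) 0.4 + 0.1 * (t >= 300)
  expect_equal(rmi_violation_area(fa_s, fv_s, fav_s, range = c(0, 600)), 5,
               tolerance = 0.03)
  bad <- function(t) 1 - fa(t)
  expect_error(rmi_violation_area(fa, fv, bad, range = c(0, 2000)),
               "non-monotone")
})

test_that("violation area is invariant to a common time shift", {
  set.seed(16)
  a <- rexgauss(200, 300, 30, 80)
  v <- rexgauss(200, 320, 30, 80)
  av <- pmin(a[sample(200)], v[sample(200)]) - 15
  a0 <- rmi_violation_area(a, v, av)
  a1 <- rmi_violation_area(a + 250, v + 250, av + 250)
  expect_equal(a0, a1, tolerance = 1e-9)
})

test_that("cluster permutation test: null profiles, uniform violation, exhaustive oracle", {
  # all-zero profiles: no cluster anywhere
  res0 <- cluster_permutation_test(matrix(0, 10, 6), n_perm = 501, seed = 1)
  expect_equal(nrow(res0$clusters), 0)
  # uniform positive profiles: smallest attainable p
  res1 <- cluster_permutation_test(matrix(10, 12, 6), n_perm = 10001, seed = 2)
  expect_equal(nrow(res1$clusters), 1)
  expect_gte(res1$clusters$p, 2 / 10002)
  expect_lt(res1$clusters$p, 0.002)
  # exhaustive sign-flip oracle at n = 5
  set.seed(17)
  d <- matrix(rnorm(5 * 4, mean = c(1.2, 1.2, 0.2, 0), sd = 0.8), 5, 4,
              byrow = FALSE)
  d <- sweep(matrix(rnorm(20, 0, 0.8), 5, 4), 2, c(1.5, 1.5, 0.2, 0), "+")
  thr <- qt(0.95, 4)
  tfun <- function(x) {
    m <- colMeans(x); v <- apply(x, 2, var)
    t <- m / sqrt(v / nrow(x)); t[v == 0] <- 0; t
  }
  mass <- function(t) {
    above <- t > thr
    if (!any(above)) return(0)
    r <- rle(above); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    max(vapply(which(r$values), function(k) sum(t[starts[k]:ends[k]]), 0))
  }
  obs <- mass(tfun(d))
  skip_if(obs == 0)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
  null_mass <- apply(signs, 1, function(s) mass(tfun(d * s)))
  p_exact <- mean(null_mass >= obs)
  res <- cluster_permutation_test(d, n_perm = 8001, seed = 3)
  expect_equal(max(res$clusters$p), p_exact, tolerance = 0.02)
})

test_that("Benjamini-Hochberg equals the brute-force step-up rule", {
  # step-up by hand: 0.01 <= 1/4*.05, 0.02 <= 2/4*.05, but 0.04 > 3/4*.05,
  # so exactly the first two are rejected
  p <- c(0.01, 0.02, 0.04, 0.80)
  bh <- bh_correct(p, 0.05)
  expect_equal(bh$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_correct(0.03, 0.05)$reject, TRUE)
  expect_false(any(bh_correct(rep(1, 5), 0.05)$reject))
  expect_error(bh_correct(numeric(0)), "empty")
  expect_error(bh_correct(c(0.5, 0)), "\\(0, 1\\]")
  # random inputs against the definition
  set.seed(18)
  for (i in 1:50) {
    m <- sample(1:15, 1)
    p <- runif(m)^2
    q <- 0.05
    srt <- sort(p)
    kmax <- suppressWarnings(max(which(srt <= seq_len(m) / m * q)))
    brute <- if (is.finite(kmax)) p <= srt[kmax] else rep(FALSE, m)
    expect_identical(bh_correct(p, q)$reject, brute)
  }
})

test_that("exponential-null test separates genuine areas from all-zero areas", {
  set.seed(19)
  areas <- data.frame(participant = sprintf("P%02d", 1:12),
                      area = rexp(12, 1 / 30))
  res <- exponential_null_test(areas, test_spec(seed = 19))
  expect_gt(res$intercept$bf_10, 3)
  expect_equal(res$intercept$rope_decision, "outside")
  zero <- data.frame(participant = sprintf("P%02d", 1:12), area = 0)
  res0 <- exponential_null_test(zero, test_spec(seed = 20))
  expect_lt(res0$intercept$bf_10, 1 / 3)
  expect_error(exponential_null_test(data.frame(participant = "a", area = -1)),
               "nonnegative")
})

test_that("factorial model flags an injected group difference and not a null one", {
  set.seed(21)
  areas <- rbind(
    data.frame(participant = sprintf("A%02d", 1:12), group = "CC",
               congruence = rep(c("congruent", "incongruent"), each = 6),
               area = rexp(12, 1 / 60)),
    data.frame(participant = sprintf("B%02d", 1:12), group = "MCC",
               congruence = rep(c("congruent", "incongruent"), each = 6),
               area = rexp(12, 1 / 5)))
  res <- exponential_null_test(areas, test_spec(seed = 21))
  expect_gt(res$factorial$bf_10[res$factorial$term == "group1"], 3)
})
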