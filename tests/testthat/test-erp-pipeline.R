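test_that("band-pass filter passes the band, stops the stopband, kills DC", {
  srate <- 500
  times <- seq(-100, 299, by = 1000 / srate)   # 0.4 s -> integer cycles
  s5 <- sin(2 * pi * 5 * times / 1000)
  s100 <- sin(2 * pi * 100 * times / 1000)
  f5 <- bandpass_filter(make_wave_epochs(s5, srate = srate), 0.1, 40)
  f100 <- bandpass_filter(make_wave_epochs(s100, srate = srate), 0.1, 40)
  expect_gt(max(abs(f5$data[1, 1, ])) / max(abs(s5)), 0.99)
  expect_lt(max(abs(f100$data[1, 1, ])) / max(abs(s100)), 0.05)
  dc <- bandpass_filter(make_wave_epochs(rep(3, length(times)), srate = srate),
                        0.1, 40)
  expect_lt(max(abs(dc$data)), 1e-10)
  expect_error(bandpass_filter(make_wave_epochs(s5, srate = srate), 0.1, 300),
               "srate/2")
})

test_that("ocular rejection flags exactly the spiked trial and honors limits", {
  set.seed(21)
  ep <- make_tiny_epochs(n_trials = 100, srate = 40)
  # bounded background noise: per-trial maxima concentrate, so the
  # median + 5 MAD threshold separates the spike deterministically
  ep$data <- array(runif(length(ep$data), -5, 5), dim(ep$data))
  fp1 <- match("FP1", ep$channel_names)
  spike_at <- which(ep$times >= 0)[1]
  ep$data[17, fp1, spike_at] <- 500
  res <- reject_ocular_epochs(ep)
  expect_identical(which(res$rejected), 17L)
  expect_equal(dim(res$epochs$data)[1], 99)
  # k -> Inf disables the rule
  res_inf <- reject_ocular_epochs(ep, blink_k = Inf, saccade_k = Inf)
  expect_false(any(res_inf$rejected))
  # all-zero data reject nothing
  ep0 <- ep; ep0$data[] <- 0
  expect_false(any(reject_ocular_epochs(ep0)$rejected))
  expect_error(reject_ocular_epochs(subset_trials(ep, integer(0))), "empty")
})

test_that("motor rejection removes only early responses", {
  ep <- make_tiny_epochs(n_trials = 3)
  ep$trial_table$response_latency_ms <- c(300, 700, NA)
  kept <- reject_motor_epochs(ep, 500)
  expect_equal(kept$trial_table$response_latency_ms, c(700, NA))
  expect_equal(dim(reject_motor_epochs(ep, 0)$data)[1], 3)
  expect_error(reject_motor_epochs(ep, -1), ">= 0")
})

test_that("mirror remap is an involution, fixes the midline, swaps pairs, relabels", {
  ep <- make_tiny_epochs(n_trials = 6, seed = 3)
  sel <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  twice <- mirror_remap(mirror_remap(ep, select = sel), select = sel)
  expect_equal(twice$data, ep$data)
  expect_equal(twice$trial_table, ep$trial_table)
  # midline fixed point / pair swap
  ch <- c("O1", "O2", "Pz", "Fz", "FP1", "FP2", "F9", "F10", "Cz", "FCz",
          "P3", "P4")
  times <- seq(-100, 200, by = 50)
  data <- array(0, c(1, length(ch), length(times)))
  data[1, match("O2", ch), ] <- 1
  data[1, match("Pz", ch), ] <- 7
  tt <- data.frame(participant = "P", condition = "AV_c",
                   visual_field = "LVF", visual_side = "left",
                   sound_side = "left", is_target = FALSE)
  ep2 <- epoch_set(data, times, ch, tt)
  m <- mirror_remap(ep2)
  expect_equal(m$data[1, match("O1", ch), ], rep(1, length(times)))
  expect_equal(m$data[1, match("O2", ch), ], rep(0, length(times)))
  expect_equal(m$data[1, match("Pz", ch), ], rep(7, length(times)))
  expect_equal(m$trial_table$visual_side, "right")
  expect_equal(m$trial_table$sound_side, "right")  # congruence preserved
  # channel missing from map is an error
  bad_map <- mirror_map(pairs = rbind(c("O1", "O2")), midline = "Pz")
  expect_error(mirror_remap(ep2, map = bad_map), "missing from mirror map")
})

test_that("mirror remap preserves the multiset of values per trial", {
  for (s in 1:5) {
    ep <- make_tiny_epochs(n_trials = 3, seed = s)
    m <- mirror_remap(ep, select = rep(TRUE, 3))
    for (i in 1:3) {
      expect_equal(sort(as.vector(m$data[i, , ])), sort(as.vector(ep$data[i, , ])))
    }
  }
})

test_that("baseline correction subtracts the prestimulus mean and is idempotent", {
  times <- seq(-100, 200, by = 50)
  wave <- ifelse(times <= 0, 1, 4)
  ep <- make_wave_epochs(wave, srate = 20)
  b <- baseline_correct(ep)
  expect_equal(b$data[1, 1, times > 0], rep(3, sum(times > 0)))
  ep3 <- make_wave_epochs(rep(3, length(times)), srate = 20)
  expect_true(all(abs(baseline_correct(ep3)$data) < 1e-12))
  expect_equal(baseline_correct(b)$data, b$data)
})

test_that("average ERP is the standards-only arithmetic mean", {
  ep <- make_tiny_epochs(n_trials = 4, seed = 5)
  ep$trial_table$condition <- "V"
  ep$trial_table$visual_field <- "LVF"
  ep$trial_table$is_target <- c(FALSE, FALSE, FALSE, TRUE)
  ep$data[4, , ] <- 1e6                      # target must not contaminate
  avg <- average_erp(ep, "V", "LVF")
  expect_equal(unclass(avg), colMeans(ep$data[1:3, , , drop = FALSE], dims = 1),
               ignore_attr = TRUE)
  expect_equal(attr(avg, "n_trials"), 3L)
  # two opposite trials cancel
  ep2 <- make_tiny_epochs(n_trials = 2)
  ep2$trial_table$condition <- "V"; ep2$trial_table$visual_field <- "UVF"
  ep2$trial_table$is_target <- FALSE
  ep2$data[1, , ] <- 1; ep2$data[2, , ] <- -1
  expect_true(all(average_erp(ep2, "V", "UVF") == 0))
  expect_error(average_erp(ep2, "AV_c", "LVF"), "no standard trials")
})

test_that("difference wave: equal ERPs give zero; offsets pass through; window inclusive", {
  times <- seq(-100, 200, by = 2)
  chans <- c("O1", "O2", "P3", "P4", "Pz")
  base <- matrix(rnorm(length(chans) * length(times)), length(chans))
  uvf <- make_erp(base, times, chans, visual_field = "UVF")
  lvf0 <- make_erp(base, times, chans)
  expect_true(all(compute_delta_c1(lvf0, uvf)$delta_c1 == 0))
  shifted <- base; shifted[1, ] <- shifted[1, ] + 1.5
  lvf <- make_erp(shifted, times, chans)
  dc <- compute_delta_c1(lvf, uvf)
  expect_equal(dc$delta_c1[dc$electrode == "O1"], 1.5)
  # endpoints 50 and 100 ms are included at sample resolution
  edge <- base
  edge[1, times %in% c(50, 100)] <- edge[1, times %in% c(50, 100)] + 1
  lvf_e <- make_erp(edge, times, chans)
  n_win <- sum(times >= 50 & times <= 100)
  expect_equal(compute_delta_c1(lvf_e, uvf)$delta_c1[1], 2 / n_win)
  expect_error(compute_delta_c1(lvf, uvf, electrodes = "Oz"), "absent")
})

test_that("difference wave cancels any activity common to both fields", {
  cfg0 <- eeg_sim_config(n_participants = 1, trials_per_cell = 6,
                         c1_amplitude = 2, noise_sd = 0, auditory_amplitude = 0,
                         blink_rate = 0, saccade_rate = 0, participant_sd = 0,
                         seed = 31)
  cfg1 <- eeg_sim_config(n_participants = 1, trials_per_cell = 6,
                         c1_amplitude = 2, noise_sd = 0, auditory_amplitude = 8,
                         blink_rate = 0, saccade_rate = 0, participant_sd = 0,
                         seed = 31)
  t0 <- delta_c1_table(simulate_eeg_dataset(cfg0), band = NULL,
                       reject_ocular = FALSE, motor_window_ms = 0)
  t1 <- delta_c1_table(simulate_eeg_dataset(cfg1), band = NULL,
                       reject_ocular = FALSE, motor_window_ms = 0)
  expect_equal(t1$delta_c1, t0$delta_c1, tolerance = 1e-10)
})

test_that("pipeline records its stage order and is reproducible", {
  cfg <- eeg_sim_config(n_participants = 1, trials_per_cell = 8, seed = 12)
  eps <- simulate_eeg_dataset(cfg)
  t1 <- delta_c1_table(eps)
  t2 <- delta_c1_table(simulate_eeg_dataset(cfg))
  expect_identical(t1, t2)
  expect_equal(attr(t1, "stages")[1], "rereference")
  expect_true("mirror_remap" %in% attr(t1, "stages"))
})
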