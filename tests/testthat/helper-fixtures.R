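# Small programmatic fixtures shared across the test files.

# Minimal valid epoch set: full montage, low sampling rate, random data.
make_tiny_epochs <- function(n_trials = 4, seed = 1,
                             channels = default_montage(), srate = 20,
                             data = NULL) {
  set.seed(seed)
  times <- seq(-100, 200, by = 1000 / srate)
  n_ch <- length(channels)
  n_s <- length(times)
  if (is.null(data)) {
    data <- array(rnorm(n_trials * n_ch * n_s), c(n_trials, n_ch, n_s))
  }
  conds <- c("V", "AV_i", "AV_c")
  tt <- data.frame(
    participant = "P01", group = "G1",
    condition = rep_len(conds, n_trials),
    visual_field = rep_len(c("UVF", "LVF"), n_trials),
    visual_side = rep_len(c("left", "right"), n_trials),
    stringsAsFactors = FALSE)
  tt$sound_side <- ifelse(tt$condition == "AV_c", tt$visual_side,
                   ifelse(tt$condition == "AV_i",
                          ifelse(tt$visual_side == "left", "right", "left"),
                          "none"))
  tt$is_target <- FALSE
  epoch_set(data, times, channels, tt)
}

# Single-trial epoch set with an arbitrary waveform on selected channels.
make_wave_epochs <- function(wave, channel = "O1", srate = 500,
                             channels = c("O1", "O2", "Pz")) {
  times <- seq(-100, by = 1000 / srate, length.out = length(wave))
  stopifnot(max(times) >= 175)
  data <- array(0, c(1, length(channels), length(wave)))
  data[1, match(channel, channels), ] <- wave
  tt <- data.frame(participant = "P01", condition = "V",
                   visual_field = "LVF", visual_side = "right",
                   sound_side = "none", is_target = FALSE,
                   stringsAsFactors = FALSE)
  epoch_set(data, times, channels, tt)
}

# Difference-wave table simulated directly at the participant level:
# cond_means is a named list group -> c(V=, AV_i=, AV_c=) (recycled over
# electrodes); participant intercepts are shared across cells.
sim_c1_table <- function(n = 14, cond_means = list(CC = c(V = 2, AV_i = 1, AV_c = 0)),
                         electrodes = c("O1", "O2", "P3", "P4", "Pz"),
                         participant_sd = 0.5, resid_sd = 0.5, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (grp in names(cond_means)) {
    mus <- cond_means[[grp]]
    ids <- sprintf("%s%02d", grp, seq_len(n))
    icpt <- rnorm(n, 0, participant_sd)
    for (i in seq_len(n)) {
      for (cond in names(mus)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant = ids[i], group = grp, condition = cond,
          electrode = electrodes,
          delta_c1 = mus[[cond]] + icpt[i] +
            rnorm(length(electrodes), 0, resid_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# ERP object helper for compute_delta_c1 tests.
make_erp <- function(mat, times, channels, n_trials = 10,
                     condition = "V", visual_field = "LVF") {
  structure(mat, class = "erp", times = times, channel_names = channels,
            n_trials = n_trials, condition = condition,
            visual_field = visual_field)
}

# Reduced-budget model spec for tests.
test_spec <- function(draws = 4000, seed = 1) {
  model_spec(draws = draws, seed = seed)
}
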