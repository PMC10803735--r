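#' Scalp projection of the simulated retinotopic C1 source
#'
#' Fixed forward-projection weight vector for the early retinotopic source:
#' maximal at the occipital electrode contralateral to the stimulated
#' hemifield and decaying toward parietal sites.  For right-hemifield
#' stimulation the maximum is at O1; left-hemifield stimulation uses the
#' mirror image of the same vector, so that after nasion-inion remapping the
#' two topographies coincide.  The weights carry the polarity flip between
#' upper and lower visual field externally (see [simulate_eeg_dataset()]).
#'
#' @param channels Channel names for which weights are returned.
#' @param side `"right"` (default) or `"left"`: side of visual stimulation.
#' @return Named numeric vector of unitless gains in `[0, 1]`.
#' @export
c1_projection_weights <- function(channels = default_montage(),
                                  side = c("right", "left")) {
  side <- match.arg(side)
  base <- c(O1 = 1, O2 = 0.55, P3 = 0.5, Pz = 0.45, P7 = 0.35, P4 = 0.3,
            CP1 = 0.2, CP5 = 0.15, CP2 = 0.1)
  if (side == "left") {
    map <- default_mirror_map()
    swapped <- names(base)
    for (i in seq_len(nrow(map$pairs))) {
      l <- map$pairs[i, 1L]; r <- map$pairs[i, 2L]
      swapped[names(base) == l] <- r
      swapped[names(base) == r] <- l
    }
    names(base) <- swapped
  }
  w <- stats::setNames(numeric(length(channels)), channels)
  hit <- intersect(names(base), channels)
  w[hit] <- base[hit]
  w
}

#' Time course of the simulated C1 source
#'
#' Raised-cosine waveform supported on 50-100 ms, normalized so that its
#' continuous-time mean over the 50-100 ms analysis window is exactly 1.
#' The downstream window-mean amplitude therefore recovers the configured
#' source strength directly (up to sampling of the template).
#'
#' @param times Sample times in ms.
#' @return Numeric vector, same length as `times`.
#' @export
c1_template <- function(times) {
  ifelse(times >= 50 & times <= 100,
         1 - cos(2 * pi * (times - 50) / 50), 0)
}

# Auditory evoked waveform shared by UVF and LVF trials of a sound-carrying
# condition; fronto-central negativity peaking ~110 ms.  Cancels exactly in
# the C1 difference wave.
.auditory_template <- function(times) {
  ifelse(times >= 60 & times <= 160,
         -sin(pi * (times - 60) / 100), 0)
}

.auditory_weights <- function(channels) {
  base <- c(Cz = 1, FCz = 0.9, Fz = 0.7, FC1 = 0.6, FC2 = 0.6,
            C3 = 0.5, C4 = 0.5, CP1 = 0.4, CP2 = 0.4, Pz = 0.3)
  w <- stats::setNames(numeric(length(channels)), channels)
  hit <- intersect(names(base), channels)
  w[hit] <- base[hit]
  w
}

.blink_weights <- function(channels) {
  base <- c(FP1 = 1, FP2 = 1, Fz = 0.5, F3 = 0.5, F4 = 0.5,
            F7 = 0.4, F8 = 0.4, F9 = 0.45, F10 = 0.45, FC1 = 0.25, FC2 = 0.25)
  w <- stats::setNames(numeric(length(channels)), channels)
  hit <- intersect(names(base), channels)
  w[hit] <- base[hit]
  w
}

# Saccades project with opposite signs onto the two periocular channels.
.saccade_weights <- function(channels) {
  base <- c(F9 = 1, F10 = -1, F7 = 0.5, F8 = -0.5, FP1 = 0.3, FP2 = -0.3)
  w <- stats::setNames(numeric(length(channels)), channels)
  hit <- intersect(names(base), channels)
  w[hit] <- base[hit]
  w
}

#' Configuration of the synthetic EEG generator
#'
#' Describes a multi-participant epoched EEG dataset containing a
#' polarity-inverting retinotopic component, condition-specific suppression
#' of that component, 1/f background noise and ocular artifacts.
#'
#' @param n_participants Number of participants.
#' @param trials_per_cell Trials per collapsed condition x visual-field cell
#'   (split evenly between left- and right-side stimulation, so mirroring and
#'   collapsing recovers exactly this count).
#' @param channels Channel names; defaults to the 32-channel montage.
#' @param srate Sampling rate in Hz.  The default (250 Hz) is a desk-scale
#'   reduction of typical 1 kHz acquisition.
#' @param epoch_window Epoch limits in ms; must contain `[-100, 100]`.
#' @param c1_amplitude Signed source strength in microvolts.  The injected
#'   C1 difference wave at O1 (before average re-referencing) has a 50-100 ms
#'   window mean of `c1_amplitude`.
#' @param polarity_flip If `TRUE` (default) the component projects with
#'   opposite sign for upper vs lower visual field, emulating the calcarine
#'   dipole flip.
#' @param suppression Named multiplicative factors in `[0, 1]` applied to
#'   `c1_amplitude` per condition, e.g. `c(V = 1, AV_i = 0.5, AV_c = 0)`
#'   for a congenital-cataract-like group; all 1 emulates controls.
#' @param noise_sd Background noise standard deviation in microvolts.
#' @param pink_exponent Spectral slope of the 1/f^a background noise.
#' @param shared_noise_frac Fraction of noise variance shared across
#'   channels (spatially correlated background activity).
#' @param blink_rate,saccade_rate Per-trial artifact probabilities.
#' @param participant_sd Between-participant SD (microvolts) of the C1
#'   source amplitude.
#' @param auditory_amplitude Amplitude (microvolts) of a fronto-central
#'   auditory evoked wave added to all sound-carrying trials; identical for
#'   UVF and LVF and therefore cancelled by the difference wave.
#' @param target_prob Probability that a trial is a rare target (targets are
#'   excluded from ERP averaging and carry a response latency).
#' @param group Group label written to the trial table.
#' @param seed Integer seed; fixed seed implies bit-identical output.
#' @return An object of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(n_participants = 14,
                           trials_per_cell = 200,
                           channels = default_montage(),
                           srate = 250,
                           epoch_window = c(-100, 300),
                           c1_amplitude = 2,
                           polarity_flip = TRUE,
                           suppression = c(V = 1, AV_i = 1, AV_c = 1),
                           noise_sd = 5,
                           pink_exponent = 1,
                           shared_noise_frac = 0.25,
                           blink_rate = 0.05,
                           saccade_rate = 0.05,
                           participant_sd = 0.5,
                           auditory_amplitude = 3,
                           target_prob = 0,
                           group = "CTRL",
                           seed = 1) {
  if (trials_per_cell < 1) stop("trials_per_cell must be >= 1")
  if (is.null(names(suppression)) || any(!nzchar(names(suppression)))) {
    stop("`suppression` must be a named vector")
  }
  unknown <- setdiff(names(suppression), c("V", "AV_i", "AV_c"))
  if (length(unknown) > 0L) {
    stop("unknown condition key(s) in suppression map: ",
         paste(unknown, collapse = ", "))
  }
  if (any(suppression < 0 | suppression > 1)) {
    stop("suppression values must lie in [0, 1]")
  }
  if (epoch_window[1L] > -100 || epoch_window[2L] < 100) {
    stop("epoch_window must contain [-100, 100] ms")
  }
  if (epoch_window[2L] < 175) {
    stop("epoch window too short for the -25..175 ms artifact window")
  }
  full <- c(V = 1, AV_i = 1, AV_c = 1)
  full[names(suppression)] <- suppression
  structure(list(
    n_participants = as.integer(n_participants),
    trials_per_cell = as.integer(trials_per_cell),
    channels = channels, srate = srate, epoch_window = epoch_window,
    c1_amplitude = c1_amplitude, polarity_flip = isTRUE(polarity_flip),
    suppression = full, noise_sd = noise_sd, pink_exponent = pink_exponent,
    shared_noise_frac = shared_noise_frac,
    blink_rate = blink_rate, saccade_rate = saccade_rate,
    participant_sd = participant_sd,
    auditory_amplitude = auditory_amplitude,
    target_prob = target_prob, group = group, seed = as.integer(seed)),
    class = "eeg_sim_config")
}

# 1/f^a - shaped Gaussian noise, one series per column, unit variance in
# expectation before scaling.
.pink_noise <- function(n_samples, n_series, exponent, srate) {
  if (n_series == 0L) return(matrix(0, n_samples, 0L))
  x <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  if (exponent == 0) return(x)
  f <- c(0, seq_len(n_samples - 1L)) / n_samples * srate
  f <- pmin(f, srate - f)               # two-sided spectrum
  g <- c(0, f[-1L]^(-exponent / 2))     # kill DC
  g <- g / sqrt(mean(g^2))              # unit output variance (Parseval)
  xf <- stats::mvfft(x) * g
  Re(stats::mvfft(xf, inverse = TRUE)) / n_samples
}

#' Simulate a multi-participant epoched EEG dataset
#'
#' Generates one [epoch_set] per participant with the structure the ERP
#' pipeline assumes: three conditions (`V`, `AV_i`, `AV_c`) crossed with
#' upper/lower visual field and left/right stimulus side, a retinotopic
#' component injected at occipital channels with opposite polarity for UVF
#' vs LVF and scaled by `suppression[condition]`, spatially structured
#' 1/f background noise, and blink/saccade artifacts whose amplitudes exceed
#' the default rejection thresholds of [reject_ocular_epochs()].
#'
#' @param config An [eeg_sim_config()].
#' @return Named list of `epoch_set` objects, one per participant.
#' @export
simulate_eeg_dataset <- function(config) {
  stopifnot(inherits(config, "eeg_sim_config"))
  set.seed(config$seed)
  ch <- config$channels
  n_ch <- length(ch)
  dt <- 1000 / config$srate
  times <- seq(config$epoch_window[1L], config$epoch_window[2L], by = dt)
  n_s <- length(times)
  tmpl <- c1_template(times)
  aud <- .auditory_template(times)
  w_right <- c1_projection_weights(ch, "right")
  w_left <- c1_projection_weights(ch, "left")
  w_aud <- .auditory_weights(ch)
  w_blink <- .blink_weights(ch)
  w_sacc <- .saccade_weights(ch)

  conds <- c("V", "AV_i", "AV_c")
  cell <- expand.grid(visual_side = c("left", "right"),
                      visual_field = c("UVF", "LVF"),
                      condition = conds,
                      stringsAsFactors = FALSE)
  n_left <- config$trials_per_cell %/% 2L
  n_right <- config$trials_per_cell - n_left
  cell$n <- ifelse(cell$visual_side == "left", n_left, n_right)
  cell <- cell[cell$n > 0L, , drop = FALSE]

  out <- vector("list", config$n_participants)
  ids <- sprintf("%s%02d", config$group, seq_len(config$n_participants))
  for (p in seq_len(config$n_participants)) {
    tt <- cell[rep(seq_len(nrow(cell)), cell$n), c("condition", "visual_field", "visual_side")]
    n_tr <- nrow(tt)
    rownames(tt) <- NULL
    # congruent sound from the visual side, incongruent from the opposite
    opposite <- c(left = "right", right = "left")
    tt$sound_side <- ifelse(tt$condition == "AV_c", tt$visual_side,
                     ifelse(tt$condition == "AV_i", opposite[tt$visual_side],
                            "none"))
    tt$is_target <- stats::runif(n_tr) < config$target_prob
    tt$response_latency_ms <- ifelse(
      tt$is_target, pmax(150, stats::rnorm(n_tr, 500, 100)), NA_real_)
    tt$participant <- ids[p]
    tt$group <- config$group
    tt$has_blink <- stats::runif(n_tr) < config$blink_rate
    tt$has_saccade <- stats::runif(n_tr) < config$saccade_rate

    # background noise: shared across channels + channel-independent part
    sh <- sqrt(config$shared_noise_frac)
    ind <- sqrt(1 - config$shared_noise_frac)
    noise_i <- .pink_noise(n_s, n_tr * n_ch, config$pink_exponent, config$srate)
    noise_s <- .pink_noise(n_s, n_tr, config$pink_exponent, config$srate)
    dat <- array(config$noise_sd *
                   (ind * noise_i + sh * noise_s[, rep(seq_len(n_tr), times = n_ch)]),
                 dim = c(n_s, n_tr, n_ch))

    amp_p <- config$c1_amplitude + stats::rnorm(1, 0, config$participant_sd)
    fld <- ifelse(tt$visual_field == "LVF", 0.5,
                  if (config$polarity_flip) -0.5 else 0.5)
    gain <- amp_p * fld * config$suppression[tt$condition]
    lft <- tt$visual_side == "left"
    for (k in seq_len(n_ch)) {
      wk <- ifelse(lft, w_left[k], w_right[k])
      scl <- gain * wk
      if (any(scl != 0)) dat[, , k] <- dat[, , k] + outer(tmpl, scl)
      if (config$auditory_amplitude != 0) {
        av <- tt$condition %in% c("AV_i", "AV_c")
        if (w_aud[k] != 0 && any(av)) {
          dat[, av, k] <- dat[, av, k] +
            outer(aud, rep(config$auditory_amplitude * w_aud[k], sum(av)))
        }
      }
    }

    # ocular artifacts, large enough to trip the default thresholds
    for (i in which(tt$has_blink)) {
      t0 <- stats::runif(1, -125, 50)
      shape <- ifelse(times >= t0 & times <= t0 + 400,
                      0.5 * (1 - cos(2 * pi * (times - t0) / 400)), 0)
      a <- stats::rnorm(1, 150, 20)
      dat[, i, ] <- dat[, i, ] + outer(shape, a * w_blink)
    }
    for (i in which(tt$has_saccade)) {
      t0 <- stats::runif(1, -25, 150)
      shape <- as.numeric(times >= t0)
      a <- sample(c(-1, 1), 1) * stats::rnorm(1, 60, 8)
      dat[, i, ] <- dat[, i, ] + outer(shape, a * w_sacc)
    }

    out[[p]] <- epoch_set(aperm(dat, c(2L, 3L, 1L)), times, ch, tt)
  }
  names(out) <- ids
  out
}
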