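#' Zero-phase band-pass filter
#'
#' Filters every trial and channel with a zero-phase frequency-domain
#' filter: the epoch spectrum is multiplied by a real transfer function that
#' is 0 at DC, rises to 1 over a raised-cosine transition ending at
#' `low_hz`, stays at 1 through `high_hz`, and falls back to 0 over a
#' raised-cosine transition.  Zero phase holds by construction (the
#' transfer function is real), and the DC component is always removed.
#' Filtering is circular per epoch; epochs are demeaned first so wrap-around
#' effects are limited to the (narrow) transition bands.
#'
#' @param epochs An [epoch_set].
#' @param low_hz,high_hz Pass-band edges in Hz; `0 < low < high < srate/2`.
#' @param trans_low Width (Hz) of the rising transition, ending at `low_hz`
#'   (default `low_hz / 2`, i.e. the response is 0 below `low_hz/2`).
#' @param trans_high Width (Hz) of the falling transition, starting at
#'   `high_hz` (default `0.25 * high_hz`, clipped to Nyquist).
#' @return The filtered `epoch_set`.
#' @export
bandpass_filter <- function(epochs, low_hz = 0.1, high_hz = 40,
                            trans_low = NULL, trans_high = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$srate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("need 0 < low_hz < high_hz < srate/2 (= ", nyq, " Hz)")
  }
  if (is.null(trans_low)) trans_low <- low_hz / 2
  if (is.null(trans_high)) trans_high <- 0.25 * high_hz
  hi_stop <- min(high_hz + trans_high, nyq * 0.999)
  d <- dim(epochs$data)
  n_s <- d[3L]
  f <- (seq_len(n_s) - 1L) / n_s * epochs$srate
  f <- pmin(f, epochs$srate - f)
  H <- numeric(n_s)
  rise <- f >= (low_hz - trans_low) & f < low_hz
  H[f >= low_hz & f <= high_hz] <- 1
  H[rise] <- 0.5 * (1 - cos(pi * (f[rise] - (low_hz - trans_low)) / trans_low))
  fall <- f > high_hz & f <= hi_stop
  H[fall] <- 0.5 * (1 + cos(pi * (f[fall] - high_hz) / (hi_stop - high_hz)))
  H[f == 0] <- 0
  m <- matrix(aperm(epochs$data, c(3L, 1L, 2L)), nrow = n_s)
  m <- sweep(m, 2L, colMeans(m))
  mf <- stats::mvfft(m) * H
  m <- Re(stats::mvfft(mf, inverse = TRUE)) / n_s
  epochs$data <- aperm(array(m, c(n_s, d[1L], d[2L])), c(2L, 3L, 1L))
  epochs
}

#' Reject epochs containing blinks or saccades
#'
#' Applies the threshold rule for ocular artifacts: for every trial the
#' maximal absolute amplitude within `window` is taken over the blink
#' channels (frontopolar) and over the saccade channels (periocular).
#' A trial is rejected when its maximum exceeds
#' `median + k * robust SD` of the per-trial maxima of the corresponding
#' channel set, with `k = blink_k` (default 5) for blinks and
#' `k = saccade_k` (default 3) for saccades.  The robust SD is the
#' MAD-based estimate (`stats::mad`), computed per dataset (typically one
#' participant).  Centering on the median makes the rule an outlier test on
#' the maxima, which is required when the rule is applied to raw channels
#' rather than to isolated ocular component traces.
#'
#' @param epochs An [epoch_set]; must be non-empty.
#' @param blink_channels,saccade_channels Channel names monitored for
#'   blinks (default FP1/FP2) and saccades (default F9/F10).
#' @param blink_k,saccade_k Threshold multipliers; `Inf` disables the rule.
#' @param window ms pair scanned for artifacts (default -25..175).
#' @return List with elements `epochs` (clean trials), `rejected` (logical
#'   mask over input trials) and `thresholds` (named numeric, microvolts).
#' @export
reject_ocular_epochs <- function(epochs,
                                 blink_channels = c("FP1", "FP2"),
                                 saccade_channels = c("F9", "F10"),
                                 blink_k = 5, saccade_k = 3,
                                 window = c(-25, 175)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[1L] == 0L) stop("empty epoch set")
  idx <- .window_index(epochs$times, window)
  maxima <- function(chs) {
    ci <- match(chs, epochs$channel_names)
    if (anyNA(ci)) stop("channel(s) not present: ",
                        paste(chs[is.na(ci)], collapse = ", "))
    x <- abs(epochs$data[, ci, idx, drop = FALSE])
    apply(x, 1L, max)
  }
  flag <- function(m, k) {
    if (!is.finite(k)) return(list(rej = rep(FALSE, length(m)), thr = Inf))
    thr <- stats::median(m) + k * stats::mad(m)
    list(rej = m > thr, thr = thr)
  }
  b <- flag(maxima(blink_channels), blink_k)
  s <- flag(maxima(saccade_channels), saccade_k)
  rejected <- b$rej | s$rej
  list(epochs = subset_trials(epochs, !rejected),
       rejected = rejected,
       thresholds = c(blink = b$thr, saccade = s$thr))
}

#' Reject epochs contaminated by button presses
#'
#' Removes trials whose recorded response latency is below `window_ms`
#' (default 500 ms), i.e. trials where a motor response occurred close
#' enough to stimulus onset to contaminate the ERP.
#'
#' @param epochs An [epoch_set] whose trial table carries
#'   `response_latency_ms`.
#' @param window_ms Nonnegative duration in ms; 0 keeps everything.
#' @return The `epoch_set` without the contaminated trials.
#' @export
reject_motor_epochs <- function(epochs, window_ms = 500) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (window_ms < 0) stop("window_ms must be >= 0")
  lat <- epochs$trial_table$response_latency_ms
  drop <- !is.na(lat) & lat < window_ms
  subset_trials(epochs, !drop)
}

#' Mirror selected trials across the nasion-inion axis
#'
#' For the selected trials, the recordings of each left/right channel pair
#' are swapped and midline channels are left untouched, reflecting the
#' scalp topography across the anterior-posterior axis.  Trial labels are
#' updated accordingly: `visual_side` and `sound_side` flip between left
#' and right, which preserves spatial congruence.  After mirroring, left-
#' and right-side cells can be collapsed (done implicitly by
#' [average_erp()], which ignores `visual_side`), doubling the trial count
#' per collapsed cell.
#'
#' Applying the function twice with the same explicit selection restores
#' the original epoch set.
#'
#' @param epochs An [epoch_set].
#' @param map A [mirror_map] covering every channel.
#' @param select Logical vector over trials, or `NULL` for the standard
#'   rule: visual or audiovisual trials with left visual-field stimulation,
#'   plus auditory-only trials with a left sound side.
#' @return The remapped `epoch_set`.
#' @export
mirror_remap <- function(epochs, map = default_mirror_map(), select = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  perm <- .mirror_permutation(map, epochs$channel_names)
  tt <- epochs$trial_table
  if (is.null(select)) {
    select <- (tt$visual_side == "left") |
      (tt$condition == "A" & tt$sound_side == "left")
  }
  if (!is.logical(select) || length(select) != nrow(tt)) {
    stop("`select` must be a logical vector with one entry per trial")
  }
  if (any(select)) {
    epochs$data[select, , ] <- epochs$data[select, perm, , drop = FALSE]
    swap <- function(x) ifelse(x == "left", "right",
                        ifelse(x == "right", "left", x))
    tt$visual_side[select] <- swap(tt$visual_side[select])
    tt$sound_side[select] <- swap(tt$sound_side[select])
    epochs$trial_table <- tt
  }
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window (default -100..0 ms, endpoint-inclusive).  Idempotent.
#'
#' @param epochs An [epoch_set].
#' @param window ms pair within the epoch.
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- .window_index(epochs$times, window)
  m <- rowSums(epochs$data[, , idx, drop = FALSE], dims = 2L) / length(idx)
  epochs$data <- epochs$data - as.vector(m)
  epochs
}

#' Average ERP of one collapsed condition cell
#'
#' Arithmetic mean across the standard (non-target) trials of a collapsed
#' `condition` x `visual_field` cell, ignoring the stimulus side (left and
#' right trials are pooled, assuming [mirror_remap()] has been applied).
#'
#' @param epochs An [epoch_set].
#' @param condition One of `"V"`, `"AV_i"`, `"AV_c"`, `"A"`.
#' @param visual_field `"UVF"`, `"LVF"` or `"none"`.
#' @return A channels x samples matrix of class `erp` with attributes
#'   `times`, `channel_names`, `n_trials`, `condition`, `visual_field`.
#' @export
average_erp <- function(epochs, condition, visual_field) {
  stopifnot(inherits(epochs, "epoch_set"))
  tt <- epochs$trial_table
  sel <- tt$condition == condition & tt$visual_field == visual_field &
    !tt$is_target
  if (!any(sel)) {
    stop("no standard trials in cell ", condition, " x ", visual_field)
  }
  m <- colMeans(epochs$data[sel, , , drop = FALSE], dims = 1L)
  structure(m, class = "erp", times = epochs$times,
            channel_names = epochs$channel_names, n_trials = sum(sel),
            condition = condition, visual_field = visual_field)
}

#' C1 difference wave amplitudes
#'
#' The C1 difference wave is defined as the lower-visual-field ERP minus the
#' upper-visual-field ERP; subtracting cancels all activity common to the
#' two fields and isolates the polarity-inverting retinotopic component.
#' Its amplitude is the mean over the analysis window (default 50-100 ms,
#' both endpoints included at sample resolution) at each requested
#' electrode.
#'
#' @param erp_lvf,erp_uvf `erp` objects (see [average_erp()]) with matching
#'   channels and times.
#' @param window ms pair, default `c(50, 100)`.
#' @param electrodes Electrodes to report (default O1, O2, P3, P4, Pz).
#' @return Data frame with columns `electrode`, `delta_c1` (microvolts),
#'   `n_trials_lvf`, `n_trials_uvf`.
#' @export
compute_delta_c1 <- function(erp_lvf, erp_uvf, window = c(50, 100),
                             electrodes = c("O1", "O2", "P3", "P4", "Pz")) {
  times <- attr(erp_lvf, "times")
  chans <- attr(erp_lvf, "channel_names")
  if (!identical(times, attr(erp_uvf, "times")) ||
      !identical(chans, attr(erp_uvf, "channel_names"))) {
    stop("LVF and UVF ERPs must share times and channels")
  }
  ci <- match(electrodes, chans)
  if (anyNA(ci)) {
    stop("electrode(s) absent: ", paste(electrodes[is.na(ci)], collapse = ", "))
  }
  idx <- .window_index(times, window)
  diffw <- unclass(erp_lvf) - unclass(erp_uvf)
  vals <- rowMeans(diffw[ci, idx, drop = FALSE])
  data.frame(electrode = electrodes, delta_c1 = as.numeric(vals),
             n_trials_lvf = attr(erp_lvf, "n_trials"),
             n_trials_uvf = attr(erp_uvf, "n_trials"),
             stringsAsFactors = FALSE)
}

#' Full ERP pipeline: epochs to a participant x electrode x condition table
#'
#' Runs, per participant: optional common-average re-referencing, zero-phase
#' band-pass filtering, ocular and motor epoch rejection, nasion-inion
#' mirroring of left-side trials (collapsing sides), baseline correction,
#' standards-only averaging per condition x visual field, and the
#' difference-wave amplitude at the requested electrodes.
#'
#' @param epochs_list An `epoch_set` or a (named) list of them, one per
#'   participant.
#' @param conditions Conditions to report (default `V`, `AV_i`, `AV_c`).
#' @param band Filter pass band in Hz, or `NULL` to skip filtering.
#' @param blink_k,saccade_k,ocular_window Ocular rejection settings
#'   (see [reject_ocular_epochs()]); `reject_ocular = FALSE` skips the step.
#' @param motor_window_ms Motor rejection window (0 skips).
#' @param mirror_map Mirror map used for remapping.
#' @param baseline Baseline window in ms.
#' @param window Analysis window in ms.
#' @param electrodes Electrodes to report.
#' @param rereference Apply common-average re-referencing first
#'   (default `TRUE`).
#' @param reject_ocular Apply the ocular rejection step (default `TRUE`).
#' @return Data frame (the difference-wave table) with columns
#'   `participant`, `group`, `condition`, `electrode`, `delta_c1`,
#'   `n_trials_lvf`, `n_trials_uvf`.  The pipeline stage order is recorded
#'   in the `"stages"` attribute.
#' @export
delta_c1_table <- function(epochs_list,
                           conditions = c("V", "AV_i", "AV_c"),
                           band = c(0.1, 40),
                           blink_k = 5, saccade_k = 3,
                           ocular_window = c(-25, 175),
                           motor_window_ms = 500,
                           mirror_map = default_mirror_map(),
                           baseline = c(-100, 0),
                           window = c(50, 100),
                           electrodes = c("O1", "O2", "P3", "P4", "Pz"),
                           rereference = TRUE,
                           reject_ocular = TRUE) {
  if (inherits(epochs_list, "epoch_set")) epochs_list <- list(epochs_list)
  rows <- vector("list", length(epochs_list))
  for (i in seq_along(epochs_list)) {
    ep <- epochs_list[[i]]
    stopifnot(inherits(ep, "epoch_set"))
    if (rereference) ep <- rereference(ep)
    if (!is.null(band)) ep <- bandpass_filter(ep, band[1L], band[2L])
    if (reject_ocular) {
      ep <- reject_ocular_epochs(ep, blink_k = blink_k, saccade_k = saccade_k,
                                 window = ocular_window)$epochs
    }
    if (motor_window_ms > 0) ep <- reject_motor_epochs(ep, motor_window_ms)
    ep <- mirror_remap(ep, mirror_map)
    ep <- baseline_correct(ep, baseline)
    pid <- ep$trial_table$participant[1L]
    grp <- ep$trial_table$group[1L]
    res <- lapply(conditions, function(cond) {
      dc <- compute_delta_c1(average_erp(ep, cond, "LVF"),
                             average_erp(ep, cond, "UVF"),
                             window = window, electrodes = electrodes)
      dc$condition <- cond
      dc
    })
    res <- do.call(rbind, res)
    res$participant <- pid
    res$group <- grp
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  out <- out[, c("participant", "group", "condition", "electrode",
                 "delta_c1", "n_trials_lvf", "n_trials_uvf")]
  rownames(out) <- NULL
  attr(out, "stages") <- c(
    if (rereference) "rereference",
    if (!is.null(band)) "bandpass_filter",
    if (reject_ocular) "reject_ocular_epochs",
    if (motor_window_ms > 0) "reject_motor_epochs",
    "mirror_remap", "baseline_correct", "average_erp", "compute_delta_c1")
  out
}
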