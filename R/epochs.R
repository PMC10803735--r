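#' Epoched EEG container
#'
#' An `epoch_set` holds epoched multi-channel EEG in microvolts as a
#' trials x channels x samples array, a strictly increasing uniform time
#' axis in milliseconds relative to stimulus onset, channel names, and a
#' per-trial metadata table.
#'
#' The trial table must contain the columns `participant`, `condition`
#' (one of `"V"`, `"AV_c"`, `"AV_i"`, `"A"`), `visual_field` (`"UVF"`,
#' `"LVF"`, `"none"`), `visual_side` and `sound_side` (`"left"`, `"right"`,
#' `"none"`) and the logical `is_target`.  A `group` column and a numeric
#' `response_latency_ms` column (NA when no response was given) are added
#' when absent.  The time axis must cover at least -100..175 ms so that
#' baseline correction and the ocular rejection window are always available.
#'
#' @param data Numeric array, trials x channels x samples, in microvolts.
#' @param times Numeric vector of sample times in ms; uniformly spaced,
#'   strictly increasing, length equal to `dim(data)[3]`.
#' @param channel_names Character vector of unique channel names, length
#'   equal to `dim(data)[2]`.
#' @param trial_table Data frame with one row per trial.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, channel_names, trial_table) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a trials x channels x samples array")
  }
  d <- dim(data)
  times <- as.numeric(times)
  if (length(times) != d[3L]) stop("length(times) must equal the sample dimension")
  dt <- diff(times)
  if (any(dt <= 0)) stop("`times` must be strictly increasing")
  if (length(dt) > 1L && max(abs(dt - dt[1L])) > 1e-6 * dt[1L]) {
    stop("`times` must be uniformly spaced")
  }
  if (min(times) > -100 || max(times) < 175) {
    stop("epoch times must cover at least [-100, 175] ms")
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != d[2L]) {
    stop("length(channel_names) must equal the channel dimension")
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  trial_table <- as.data.frame(trial_table, stringsAsFactors = FALSE)
  if (nrow(trial_table) != d[1L]) {
    stop("trial table has ", nrow(trial_table), " rows but data has ",
         d[1L], " trials")
  }
  req <- c("participant", "condition", "visual_field", "visual_side",
           "sound_side", "is_target")
  miss <- setdiff(req, names(trial_table))
  if (length(miss) > 0L) {
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(trial_table$condition), c("V", "AV_c", "AV_i", "A"))
  if (length(bad) > 0L) stop("unknown condition value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(trial_table$visual_field), c("UVF", "LVF", "none"))
  if (length(bad) > 0L) stop("unknown visual_field value(s): ", paste(bad, collapse = ", "))
  if (!"group" %in% names(trial_table)) trial_table$group <- "unknown"
  if (!"response_latency_ms" %in% names(trial_table)) {
    trial_table$response_latency_ms <- NA_real_
  }
  structure(
    list(data = data, times = times, channel_names = channel_names,
         trial_table = trial_table,
         srate = 1000 / if (length(dt) > 0L) dt[1L] else NA_real_),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1L], " trials x ", d[2L], " channels x ", d[3L],
      " samples (", round(x$srate), " Hz, ",
      min(x$times), "..", max(x$times), " ms)\n", sep = "")
  tab <- table(x$trial_table$condition, x$trial_table$visual_field)
  print(tab)
  invisible(x)
}

#' Keep a subset of trials of an epoch set
#'
#' @param epochs An `epoch_set`.
#' @param keep Logical or integer index over trials.
#' @return An `epoch_set` restricted to the selected trials.
#' @export
subset_trials <- function(epochs, keep) {
  stopifnot(inherits(epochs, "epoch_set"))
  data <- epochs$data[keep, , , drop = FALSE]
  tt <- epochs$trial_table[keep, , drop = FALSE]
  rownames(tt) <- NULL
  epochs$data <- data
  epochs$trial_table <- tt
  epochs
}

#' Re-reference epochs to the common average
#'
#' Subtracts, per trial and sample, the mean over all channels.  Synthetic
#' data are generated reference-free; re-referencing mimics the offline
#' average reference used with recorded data and is the default first step
#' of [delta_c1_table()].
#'
#' @param epochs An `epoch_set`.
#' @return The re-referenced `epoch_set`.
#' @export
rereference <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  m <- rowSums(aperm(epochs$data, c(1L, 3L, 2L)), dims = 2L) / d[2L]
  epochs$data <- epochs$data - aperm(array(m, c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
  epochs
}

# Index of samples with window[1] <= t <= window[2] (endpoint-inclusive).
.window_index <- function(times, window) {
  if (length(window) != 2L || window[2L] < window[1L]) {
    stop("window must be an increasing ms pair")
  }
  tol <- 1e-9
  idx <- which(times >= window[1L] - tol & times <= window[2L] + tol)
  if (length(idx) == 0L) stop("window [", window[1L], ", ", window[2L],
                              "] ms contains no samples")
  idx
}
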