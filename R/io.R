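#' Write an epoch set in the portable epoch format
#'
#' The portable format is a language-neutral triplet: `<prefix>.dat`
#' (raw little-endian float32, sample-fastest, then channel, then trial),
#' `<prefix>.json` (dimensions, channel names, time axis, sampling rate)
#' and `<prefix>_trials.csv` (the trial table).
#'
#' @param epochs An [epoch_set].
#' @param prefix Path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(epochs$data, c(3L, 2L, 1L))), con,
           size = 4L, endian = "little")
  side <- list(format = "epochs-v1",
               n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
               order = "sample,channel,trial (fastest first)",
               dtype = "float32le", unit = "uV",
               srate = epochs$srate, times_ms = epochs$times,
               channels = epochs$channel_names)
  jsonlite::write_json(side, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(epochs$trial_table, paste0(prefix, "_trials.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' Read an epoch set
#'
#' Reads either the portable epoch format written by [write_epochs()] or a
#' BrainVision triplet (`.vhdr` header, binary `.eeg` data, `.vmrk`
#' markers), which is epoched on the fly around stimulus markers.
#'
#' For BrainVision input, `events` maps marker descriptions (e.g.
#' `"S  1"`) to trial metadata: a data frame with a `marker` column plus
#' any of `condition`, `visual_field`, `visual_side`, `sound_side`,
#' `is_target`.  Markers without a mapping are ignored.  Channel names are
#' matched against `channels_expected` (case-normalized); an unknown
#' channel is an error naming the channel.
#'
#' @param path For `"portable"`: the prefix or the `.json` sidecar path.
#'   For `"brainvision"`: the `.vhdr` path.
#' @param format `"portable"` or `"brainvision"`.
#' @param events Marker mapping (BrainVision only).
#' @param epoch_window ms pair around each marker (BrainVision only).
#' @param participant,group Labels for the trial table (BrainVision only).
#' @param channels_expected Permitted channel vocabulary.
#' @return An [epoch_set].
#' @export
read_epochs <- function(path, format = c("portable", "brainvision"),
                        events = NULL, epoch_window = c(-100, 300),
                        participant = "P01", group = "unknown",
                        channels_expected = default_montage()) {
  format <- match.arg(format)
  if (format == "portable") {
    prefix <- sub("\\.json$", "", path)
    side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
    if (!identical(side$format, "epochs-v1")) stop("malformed sidecar: ", prefix)
    n <- side$n_trials * side$n_channels * side$n_samples
    con <- file(paste0(prefix, ".dat"), "rb")
    on.exit(close(con))
    raw <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
    if (length(raw) != n) stop("data file truncated: ", prefix, ".dat")
    data <- aperm(array(raw, c(side$n_samples, side$n_channels, side$n_trials)),
                  c(3L, 2L, 1L))
    tt <- utils::read.csv(paste0(prefix, "_trials.csv"),
                          stringsAsFactors = FALSE)
    return(epoch_set(data, side$times_ms, side$channels, tt))
  }
  .read_brainvision_epochs(path, events, epoch_window, participant, group,
                           channels_expected)
}

# Minimal INI parser for BrainVision .vhdr/.vmrk files.
.read_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(section)) {
      kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1L]]
      out[[section]][[trimws(kv[1L])]] <- trimws(kv[2L])
    }
  }
  out
}

.read_brainvision_epochs <- function(vhdr_path, events, epoch_window,
                                     participant, group, channels_expected) {
  if (!file.exists(vhdr_path)) stop("no such file: ", vhdr_path)
  hdr <- .read_ini(vhdr_path)
  ci <- hdr[["Common Infos"]]
  if (is.null(ci) || is.null(ci$DataFile) || is.null(ci$SamplingInterval)) {
    stop("malformed BrainVision header: ", vhdr_path)
  }
  if (!is.null(ci$DataFormat) && toupper(ci$DataFormat) != "BINARY") {
    stop("only BINARY BrainVision data are supported")
  }
  if (!is.null(ci$DataOrientation) &&
      toupper(ci$DataOrientation) != "MULTIPLEXED") {
    stop("only MULTIPLEXED BrainVision data are supported")
  }
  n_ch <- as.integer(ci$NumberOfChannels)
  srate <- 1e6 / as.numeric(ci$SamplingInterval)
  binfmt <- hdr[["Binary Infos"]]$BinaryFormat
  if (is.null(binfmt)) binfmt <- "IEEE_FLOAT_32"
  chinfo <- hdr[["Channel Infos"]]
  chans <- character(n_ch); resol <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    entry <- chinfo[[paste0("Ch", i)]]
    if (is.null(entry)) stop("malformed header: missing Ch", i)
    parts <- strsplit(entry, ",", fixed = TRUE)[[1L]]
    chans[i] <- parts[1L]
    if (length(parts) >= 3L && nzchar(parts[3L])) resol[i] <- as.numeric(parts[3L])
  }
  # normalize case against the expected vocabulary
  norm <- channels_expected[match(toupper(chans), toupper(channels_expected))]
  if (anyNA(norm)) {
    stop("unknown channel(s) in BrainVision file: ",
         paste(chans[is.na(norm)], collapse = ", "))
  }
  chans <- norm
  dir <- dirname(vhdr_path)
  eeg_path <- file.path(dir, ci$DataFile)
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (toupper(binfmt) == "IEEE_FLOAT_32") {
    raw <- readBin(con, numeric(), n = sz / 4L, size = 4L, endian = "little")
  } else if (toupper(binfmt) == "INT_16") {
    raw <- readBin(con, integer(), n = sz / 2L, size = 2L, endian = "little",
                   signed = TRUE)
    raw <- as.numeric(raw)
  } else stop("unsupported BinaryFormat: ", binfmt)
  n_samp <- length(raw) %/% n_ch
  cont <- matrix(raw[seq_len(n_samp * n_ch)], nrow = n_ch)  # multiplexed
  cont <- cont * resol

  vmrk_path <- file.path(dir, ci$MarkerFile)
  mrk <- .read_ini(vmrk_path)[["Marker Infos"]]
  if (is.null(mrk)) stop("malformed marker file: ", vmrk_path)
  marks <- do.call(rbind, lapply(mrk, function(m) {
    parts <- strsplit(m, ",", fixed = TRUE)[[1L]]
    data.frame(type = parts[1L], description = parts[2L],
               position = as.integer(parts[3L]), stringsAsFactors = FALSE)
  }))
  if (is.null(events) || !"marker" %in% names(events)) {
    stop("`events` mapping with a `marker` column is required for BrainVision input")
  }
  marks <- marks[marks$description %in% events$marker, , drop = FALSE]
  if (nrow(marks) == 0L) stop("no mapped stimulus markers found")
  dt <- 1000 / srate
  pre <- round(epoch_window[1L] / dt)
  post <- round(epoch_window[2L] / dt)
  rel <- seq(pre, post)
  times <- rel * dt
  keep <- marks$position + pre >= 1L & marks$position + post <= n_samp
  marks <- marks[keep, , drop = FALSE]
  n_tr <- nrow(marks)
  data <- array(NA_real_, c(n_tr, n_ch, length(rel)))
  for (i in seq_len(n_tr)) {
    data[i, , ] <- cont[, marks$position[i] + rel]
  }
  ev <- events[match(marks$description, events$marker), , drop = FALSE]
  tt <- data.frame(participant = participant, group = group,
                   condition = if ("condition" %in% names(ev)) ev$condition else "V",
                   visual_field = if ("visual_field" %in% names(ev)) ev$visual_field else "none",
                   visual_side = if ("visual_side" %in% names(ev)) ev$visual_side else "none",
                   sound_side = if ("sound_side" %in% names(ev)) ev$sound_side else "none",
                   is_target = if ("is_target" %in% names(ev)) ev$is_target else FALSE,
                   stringsAsFactors = FALSE)
  epoch_set(data, times, chans, tt)
}

# BrainVision writer for continuous data; used to build test fixtures and
# to round-trip the reader.  Not part of the public interface.
.write_brainvision <- function(cont, channels, srate, markers, prefix) {
  base <- basename(prefix)
  vhdr <- paste0(prefix, ".vhdr")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", length(channels)),
    paste0("SamplingInterval=", format(1e6 / srate, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    paste0("Ch", seq_along(channels), "=", channels, ",,1,µV")),
    vhdr)
  con <- file(paste0(prefix, ".eeg"), "wb")
  writeBin(as.numeric(cont), con, size = 4L, endian = "little")
  close(con)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(markers)),
            markers$description, markers$position)),
    paste0(prefix, ".vmrk"))
  invisible(vhdr)
}

#' Write a table with a provenance header
#'
#' Writes a CSV preceded by `#`-prefixed provenance comment lines (seed,
#' package version, stage, configuration digest), so every output artifact
#' records how it was produced.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param provenance Named list of scalar fields.
#' @return `path`, invisibly.
#' @export
write_table_with_provenance <- function(x, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance)) {
    writeLines(paste0("# ", nm, ": ", provenance[[nm]]), con)
  }
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table_with_provenance()]
#'
#' @param path CSV path.
#' @return Data frame; the provenance fields are in the `"provenance"`
#'   attribute.
#' @export
read_table_with_provenance <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  prov <- list()
  for (h in hdr) {
    kv <- sub("^# *", "", lines[h])
    i <- regexpr(": ", kv, fixed = TRUE)
    if (i > 0) prov[[substr(kv, 1, i - 1)]] <- substr(kv, i + 2, nchar(kv))
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                     collapse = "\n"),
                        stringsAsFactors = FALSE)
  attr(df, "provenance") <- prov
  df
}

# Recursive schema check: every key in `config` must exist in `template`.
.check_config_keys <- function(config, template, path = "") {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(config[[nm]])) {
      if (identical(names(template[[nm]]), "ANY")) next
      .check_config_keys(config[[nm]], template[[nm]],
                         paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Read and validate a pipeline run configuration
#'
#' Accepts YAML or JSON (by extension).  The configuration is validated
#' against the known-key schema before any stage runs; unknown keys are
#' rejected with an error naming them.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or an already
#'   parsed list.
#' @return The validated configuration list.
#' @seealso [run_pipeline()]
#' @export
read_run_config <- function(path) {
  config <- if (is.list(path)) {
    path
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json")
  .check_config_keys(config, .config_template())
  if (is.null(config$seed)) stop("config must set a seed")
  config
}

.config_template <- function() {
  group_tpl <- list(ANY = NULL)
  list(
    seed = NULL, out_dir = NULL,
    simulate = list(
      eeg = list(groups = group_tpl, n_participants = NULL,
                 trials_per_cell = NULL, srate = NULL, c1_amplitude = NULL,
                 noise_sd = NULL, pink_exponent = NULL, blink_rate = NULL,
                 saccade_rate = NULL, participant_sd = NULL,
                 auditory_amplitude = NULL, target_prob = NULL),
      rt = list(groups = group_tpl, n_trials = NULL, n_participants = NULL,
                model = NULL, coactivation_shift = NULL, miss_rate = NULL,
                channel_params = list(A = NULL, V = NULL))),
    erp = list(band = NULL, blink_k = NULL, saccade_k = NULL,
               ocular_window = NULL, motor_window_ms = NULL,
               baseline = NULL, window = NULL, electrodes = NULL,
               rereference = NULL),
    infer = list(draws = NULL, rope_scale = NULL, deprived_group = NULL,
                 control_group = NULL),
    rmi = list(grid_percentiles = NULL, n_perm = NULL, q = NULL,
               min_trials = NULL))
}
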