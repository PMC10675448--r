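#' Continuous multichannel EEG recording
#'
#' @param data `channel x sample` numeric matrix, microvolts.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param channel_names Character vector, one name per channel.
#' @param events Optional list with `event_samples` (1-based sample indices,
#'   strictly increasing) and `event_labels` (0 = correct, 1 = erroneous).
#' @return Object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, sampling_rate_hz, channel_names = NULL,
                                 events = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stopf("channel_names length (%d) does not match channel count (%d)",
          length(channel_names), nrow(data))
  }
  if (!is.null(events)) {
    ev <- as.integer(events$event_samples)
    if (length(ev) > 1 && any(diff(ev) <= 0)) {
      stopf("event samples must be strictly increasing")
    }
    if (length(ev) && (min(ev) < 1 || max(ev) > ncol(data))) {
      stopf("events fall outside the recorded sample range")
    }
    if (length(events$event_labels) != length(ev)) {
      stopf("event_labels length must match event_samples")
    }
    events <- list(event_samples = ev,
                   event_labels = as.integer(events$event_labels))
  }
  structure(list(data = data, sampling_rate_hz = sampling_rate_hz,
                 channel_names = channel_names, events = events),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              length(x$events$event_samples)))
  invisible(x)
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels.
#' Idempotent; undefined for a single channel.
#'
#' @param recording A [continuous_recording()].
#' @return The re-referenced recording.
#' @export
car_rereference <- function(recording) {
  stopifnot(inherits(recording, "continuous_recording"))
  if (nrow(recording$data) < 2) {
    stopf("common average reference is undefined for fewer than 2 channels")
  }
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording
}

#' Zero-phase FIR band-pass filter
#'
#' Designs a linear-phase window-method FIR band-pass and applies it
#' forward-backward ([signal::filtfilt()]) so that ErrP peak latencies are
#' not shifted. Default band 1-40 Hz, the slow-cortical-potential band in
#' which the ErrP lives.
#'
#' @param recording A [continuous_recording()].
#' @param band_hz `c(low, high)` passband edges, Hz; must satisfy
#'   `0 < low < high < fs / 2`.
#' @param n_taps FIR length (order + 1); default `round(3 * fs / low)` forced
#'   odd, long enough to resolve the 1 Hz edge.
#' @return The filtered recording.
#' @export
bandpass_fir <- function(recording, band_hz = c(1, 40), n_taps = NULL) {
  stopifnot(inherits(recording, "continuous_recording"))
  fs <- recording$sampling_rate_hz
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[2] <= band_hz[1] ||
      band_hz[2] >= fs / 2) {
    stopf("band edges must satisfy 0 < low < high < fs/2 (fs = %g)", fs)
  }
  if (is.null(n_taps)) n_taps <- round(3 * fs / band_hz[1])
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  if (ncol(recording$data) <= 3 * n_taps) {
    stopf("recording too short (%d samples) for a %d-tap zero-phase filter",
          ncol(recording$data), n_taps)
  }
  h <- signal::fir1(n_taps - 1, band_hz / (fs / 2), type = "pass")
  recording$data <- t(apply(recording$data, 1,
                            function(x) signal::filtfilt(as.numeric(h), 1, x)))
  recording
}

#' Downsample a recording
#'
#' Integer-factor decimation with an internal zero-phase anti-alias low-pass
#' at 0.45 of the target Nyquist-pair rate; event indices are rescaled.
#'
#' @param recording A [continuous_recording()].
#' @param target_hz Target rate; must divide the current rate.
#' @return The downsampled recording.
#' @export
resample_recording <- function(recording, target_hz) {
  stopifnot(inherits(recording, "continuous_recording"))
  fs <- recording$sampling_rate_hz
  if (target_hz > fs) stopf("upsampling is not supported (fs = %g, target = %g)",
                            fs, target_hz)
  if (target_hz == fs) return(recording)
  fac <- fs / target_hz
  if (abs(fac - round(fac)) > 1e-9) {
    stopf("target rate must divide the sampling rate (fs = %g, target = %g)",
          fs, target_hz)
  }
  fac <- as.integer(round(fac))
  # anti-alias: zero-phase low-pass below the new Nyquist
  n_taps <- 8L * fac + 1L
  h <- signal::fir1(n_taps - 1, 0.9 / fac, type = "low")
  dat <- t(apply(recording$data, 1, function(x) signal::filtfilt(as.numeric(h), 1, x)))
  keep <- seq(1L, ncol(dat), by = fac)
  recording$data <- dat[, keep, drop = FALSE]
  recording$sampling_rate_hz <- target_hz
  if (!is.null(recording$events)) {
    ev0 <- recording$events$event_samples - 1L       # 0-based scaling
    recording$events$event_samples <- as.integer(floor(ev0 / fac)) + 1L
  }
  recording
}

#' Epoch set locked to feedback events
#'
#' @param data `epoch x channel x sample` array (post-event window).
#' @param labels Binary vector, one per epoch (1 = ErrP).
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param window_s `c(start, end)` of the full window relative to the event.
#' @param prestim `epoch x channel x sample` array for the pre-stimulus
#'   window, or `NULL`.
#' @param channel_names Channel names.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, sampling_rate_hz, window_s = c(-1, 1),
                      prestim = NULL, channel_names = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != length(labels)) {
    stopf("labels length (%d) must equal epoch count (%d)",
          length(labels), dim(data)[1])
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dim(data)[2]))
  }
  structure(list(data = data, labels = as.integer(labels),
                 sampling_rate_hz = sampling_rate_hz, window_s = window_s,
                 prestim = prestim, channel_names = channel_names),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz (%d ErrP)\n",
              d[1], d[2], d[3], x$sampling_rate_hz, sum(x$labels == 1L)))
  invisible(x)
}

n_epochs <- function(x) dim(x$data)[1]

# Subset an epoch set by epoch index, keeping prestim and labels aligned.
#' Subset an epoch set by epoch index
#' @param epochs An [epoch_set()].
#' @param idx Integer epoch indices.
#' @return The subset `epoch_set`.
#' @export
subset_epochs <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$labels <- epochs$labels[idx]
  if (!is.null(epochs$prestim)) {
    epochs$prestim <- epochs$prestim[idx, , , drop = FALSE]
  }
  epochs
}

#' Extract event-locked epochs from a continuous recording
#'
#' The post-event second `[0, 1)` becomes the analysis window; the
#' pre-stimulus second `[-1, 0)` is stored alongside for background
#' (noise-covariance) estimation. Events without full window support are
#' dropped with a warning. Time 0 is the event sample itself.
#'
#' @param recording A [continuous_recording()] with events.
#' @param window_s Window relative to the event, seconds; default `c(-1, 1)`.
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(recording, window_s = c(-1, 1)) {
  stopifnot(inherits(recording, "continuous_recording"))
  if (is.null(recording$events)) stopf("recording carries no events")
  fs <- recording$sampling_rate_hz
  n_pre <- round(-window_s[1] * fs)
  n_post <- round(window_s[2] * fs)
  ev <- recording$events$event_samples
  lab <- recording$events$event_labels
  ok <- (ev - n_pre) >= 1 & (ev + n_post - 1) <= ncol(recording$data)
  if (any(!ok)) {
    warnf("dropping %d event(s) without full [%g, %g] s window support",
          sum(!ok), window_s[1], window_s[2])
  }
  ev <- ev[ok]; lab <- lab[ok]
  n_ch <- nrow(recording$data)
  post <- array(0, c(length(ev), n_ch, n_post))
  pre <- array(0, c(length(ev), n_ch, n_pre))
  for (i in seq_along(ev)) {
    post[i, , ] <- recording$data[, ev[i]:(ev[i] + n_post - 1L)]
    pre[i, , ] <- recording$data[, (ev[i] - n_pre):(ev[i] - 1L)]
  }
  epoch_set(post, lab, fs, window_s = window_s, prestim = pre,
            channel_names = recording$channel_names)
}

#' Run the standard preprocessing chain
#'
#' Common average reference, zero-phase FIR band-pass, downsampling and
#' epoching, in that order.
#'
#' @param recording A [continuous_recording()].
#' @param band_hz Band-pass edges, Hz.
#' @param target_hz Post-decimation rate, Hz.
#' @param window_s Epoch window, seconds.
#' @return An [epoch_set()].
#' @export
preprocess_recording <- function(recording, band_hz = c(1, 40),
                                 target_hz = 64, window_s = c(-1, 1)) {
  rec <- car_rereference(recording)
  rec <- bandpass_fir(rec, band_hz)
  rec <- resample_recording(rec, target_hz)
  extract_epochs(rec, window_s)
}

#' Read / write recordings
#'
#' Two dialects are supported. `synthetic-native` is the package's own
#' container (an RDS serialisation of a [continuous_recording()]); it
#' round-trips bit-exactly. `bnci-matrix` reads a session of the BNCI
#' "monitoring error-related potentials" corpus converted to RDS: a list of
#' run structures, each with a `samples x channels` signal matrix (`signal`
#' or `X`), a sampling rate (`fs`), event positions (`event_pos` or
#' `trig_pos`) and event types (`event_typ` or `trig_typ`); conversion from
#' the original MATLAB containers is done outside this package. Event types
#' are mapped to labels with `error_types`.
#'
#' @param path File path.
#' @param dialect `"synthetic-native"` or `"bnci-matrix"`.
#' @param error_types Event-type codes counted as erroneous feedback for the
#'   `bnci-matrix` dialect.
#' @param feedback_types Event-type codes that are feedback events at all;
#'   others (block starts etc.) are ignored.
#' @return A [continuous_recording()].
#' @export
load_recording <- function(path, dialect = c("synthetic-native", "bnci-matrix"),
                           error_types = c(5, 10), feedback_types = c(4, 5, 9, 10)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stopf("cannot read %s: %s", path,
                                            conditionMessage(e)))
  if (dialect == "synthetic-native") {
    if (!inherits(obj, "continuous_recording")) {
      stopf("%s does not contain a continuous_recording", path)
    }
    return(obj)
  }
  runs <- if (!is.null(obj$signal) || !is.null(obj$X)) list(obj) else obj
  field <- function(run, names) {
    for (nm in names) if (!is.null(run[[nm]])) return(run[[nm]])
    NULL
  }
  datas <- list(); evs <- integer(); labs <- integer(); offset <- 0L; fs <- NULL
  for (run in runs) {
    sig <- field(run, c("signal", "X"))
    if (is.null(sig)) stopf("%s: run has no signal matrix", path)
    sig <- as.matrix(sig)
    fs_run <- field(run, c("fs", "sampling_rate"))
    if (is.null(fs_run)) stopf("%s: run has no sampling rate", path)
    pos <- field(run, c("event_pos", "trig_pos"))
    typ <- field(run, c("event_typ", "trig_typ"))
    if (is.null(pos) || is.null(typ)) {
      stopf("%s: run has no event positions/types", path)
    }
    fs <- fs_run
    keep <- typ %in% feedback_types
    evs <- c(evs, as.integer(pos[keep]) + offset)
    labs <- c(labs, as.integer(typ[keep] %in% error_types))
    datas[[length(datas) + 1L]] <- t(sig)        # to channel x sample
    offset <- offset + ncol(datas[[length(datas)]])
  }
  continuous_recording(do.call(cbind, datas), fs,
                       events = list(event_samples = evs, event_labels = labs))
}

#' @rdname load_recording
#' @param recording A [continuous_recording()] to write (`synthetic-native`).
#' @export
save_recording <- function(recording, path) {
  stopifnot(inherits(recording, "continuous_recording"))
  saveRDS(recording, path)
  invisible(path)
}
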