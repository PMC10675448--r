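#' Stereotyped ErrP waveform template
#'
#' An error-related potential is modelled as a sum of Gaussian-shaped
#' deflections, one per peak. The canonical fronto-central ErrP shows a
#' negative peak near 250 ms after the erroneous feedback, a positive peak
#' near 320 ms and a second negative peak near 450 ms; those latencies are
#' the defaults of [default_errp_template()].
#'
#' @param peak_latencies_s Peak times relative to the event, seconds,
#'   strictly increasing.
#' @param peak_amplitudes Signed peak amplitudes (microvolts), one per peak.
#' @param peak_widths_s Gaussian SD of each peak, seconds, all positive.
#' @param duration_s Support of the template; the waveform is zero outside
#'   `[0, duration_s]`.
#' @return An object of class `errp_template`.
#' @export
errp_template <- function(peak_latencies_s, peak_amplitudes, peak_widths_s,
                          duration_s = 1) {
  if (length(peak_latencies_s) != length(peak_amplitudes) ||
      length(peak_latencies_s) != length(peak_widths_s)) {
    stopf("latencies, amplitudes and widths must have equal length")
  }
  if (length(peak_latencies_s) > 1 && any(diff(peak_latencies_s) <= 0)) {
    stopf("peak latencies must be strictly increasing")
  }
  if (any(peak_widths_s <= 0)) stopf("all peak widths must be > 0")
  assert_scalar_num(duration_s, "duration_s", lower = 1e-9)
  structure(list(peak_latencies_s = as.numeric(peak_latencies_s),
                 peak_amplitudes = as.numeric(peak_amplitudes),
                 peak_widths_s = as.numeric(peak_widths_s),
                 duration_s = duration_s),
            class = "errp_template")
}

#' @rdname errp_template
#' @export
default_errp_template <- function() {
  errp_template(peak_latencies_s = c(0.25, 0.32, 0.45),
                peak_amplitudes = c(-1, 1, -0.6),
                peak_widths_s = c(0.04, 0.04, 0.06),
                duration_s = 1)
}

#' Sample an ErrP template on a regular time grid
#'
#' @param template An [errp_template()].
#' @param sampling_rate_hz Sampling rate, Hz.
#' @return Numeric vector of `round(duration_s * sampling_rate_hz)` samples;
#'   sample i corresponds to time `(i - 1) / sampling_rate_hz`.
#' @export
make_template <- function(template, sampling_rate_hz) {
  stopifnot(inherits(template, "errp_template"))
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  n <- round(template$duration_s * sampling_rate_hz)
  t <- (seq_len(n) - 1) / sampling_rate_hz
  w <- numeric(n)
  for (i in seq_along(template$peak_latencies_s)) {
    w <- w + template$peak_amplitudes[i] *
      exp(-(t - template$peak_latencies_s[i])^2 /
            (2 * template$peak_widths_s[i]^2))
  }
  w
}

#' Autoregressive background-EEG model
#'
#' Background (non event-related) EEG is modelled as coloured Gaussian
#' noise: per-source AR-filtered white innovations, optionally mixed across
#' channels by a spatial mixing matrix.
#'
#' @param ar_coefficients Numeric vector of AR coefficients shared by all
#'   sources (the convention is `x_t = sum_j a_j x_{t-j} + e_t`), or a list
#'   with one coefficient vector per source. Empty vector = white noise.
#' @param innovation_std Innovation SD, microvolts (>= 0; 0 gives silence).
#' @param spatial_mixing Optional channel x source mixing matrix; `NULL`
#'   means one independent source per channel (identity mixing).
#' @return An object of class `bg_model`.
#' @export
background_model <- function(ar_coefficients = c(1.2, -0.5),
                             innovation_std = 1,
                             spatial_mixing = NULL) {
  if (!is.list(ar_coefficients)) ar_coefficients <- list(ar_coefficients)
  for (a in ar_coefficients) {
    if (length(a) && !ar_is_stable(a)) {
      stopf("AR polynomial is unstable (roots must lie inside the unit circle)")
    }
  }
  assert_scalar_num(innovation_std, "innovation_std", lower = 0)
  if (!is.null(spatial_mixing)) spatial_mixing <- as.matrix(spatial_mixing)
  structure(list(ar_coefficients = ar_coefficients,
                 innovation_std = innovation_std,
                 spatial_mixing = spatial_mixing),
            class = "bg_model")
}

# Stability of x_t = sum a_j x_{t-j} + e_t: roots of 1 - sum a_j z^-j.
ar_is_stable <- function(a) {
  if (!length(a)) return(TRUE)
  all(Mod(polyroot(c(1, -a))) > 1)
}

#' Simulate coloured multichannel background EEG
#'
#' @param model A [background_model()].
#' @param n_samples Samples per channel.
#' @param n_channels Number of output channels.
#' @param seed Integer seed; the same seed reproduces the same matrix.
#' @return `n_channels x n_samples` matrix (microvolts).
#' @export
simulate_background <- function(model, n_samples, n_channels, seed = NULL) {
  stopifnot(inherits(model, "bg_model"))
  n_samples <- as.integer(n_samples); n_channels <- as.integer(n_channels)
  mix <- model$spatial_mixing
  n_sources <- if (is.null(mix)) n_channels else ncol(mix)
  if (!is.null(mix) && nrow(mix) != n_channels) {
    stopf("spatial_mixing has %d rows but n_channels = %d", nrow(mix), n_channels)
  }
  with_seed(seed, {
    src <- matrix(0, n_sources, n_samples)
    if (model$innovation_std > 0) {
      for (s in seq_len(n_sources)) {
        a <- model$ar_coefficients[[((s - 1L) %% length(model$ar_coefficients)) + 1L]]
        e <- rnorm(n_samples, sd = model$innovation_std)
        src[s, ] <- if (length(a)) {
          as.numeric(stats::filter(e, a, method = "recursive"))
        } else e
      }
    }
    if (is.null(mix)) src else mix %*% src
  })
}

#' Simulation configuration for a synthetic ErrP session
#'
#' The defaults reproduce the monitoring paradigm the pipeline targets:
#' feedback events every 2 s, each erroneous with probability 0.2
#' independently of the others.
#'
#' @param n_events Number of feedback events.
#' @param error_probability Probability that an event is erroneous (carries
#'   an ErrP); default 0.2.
#' @param sampling_rate_hz Sampling rate, Hz (default 64, the post-decimation
#'   rate of the preprocessing pipeline; use 512 to emulate raw acquisition).
#' @param n_channels Number of EEG channels.
#' @param snr_db Target single-trial SNR in dB: 10 log10 of template power
#'   over the first post-event second at the template's strongest channel,
#'   divided by the background power at that channel. `Inf` is accepted as a
#'   noise-free sentinel (requires `innovation_std = 0` in the background
#'   model, and applies the template at unit gain).
#' @param topography Per-channel template scaling; `NULL` gives a Gaussian
#'   falloff centred on a fronto-central ("FCz-like") channel.
#' @param fcz_channel Index of the channel on which the default topography
#'   is centred.
#' @param inter_event_s Spacing between events, seconds (default 2, one
#'   cursor step of the monitoring paradigm).
#' @param seed Integer master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_events = 200, error_probability = 0.2,
                       sampling_rate_hz = 64, n_channels = 8,
                       snr_db = 0, topography = NULL,
                       fcz_channel = NULL, inter_event_s = 2, seed = 1L) {
  assert_scalar_num(n_events, "n_events", lower = 1)
  assert_scalar_num(error_probability, "error_probability", lower = 0, upper = 1)
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  assert_scalar_num(n_channels, "n_channels", lower = 1)
  assert_scalar_num(inter_event_s, "inter_event_s", lower = 1e-9)
  if (is.null(fcz_channel)) fcz_channel <- max(1L, ceiling(n_channels / 3))
  if (is.null(topography)) {
    ch <- seq_len(n_channels)
    topography <- exp(-(ch - fcz_channel)^2 / (2 * (n_channels / 4)^2))
  }
  if (length(topography) != n_channels) {
    stopf("topography must have one weight per channel")
  }
  structure(list(n_events = as.integer(n_events),
                 error_probability = error_probability,
                 sampling_rate_hz = sampling_rate_hz,
                 n_channels = as.integer(n_channels),
                 snr_db = snr_db, topography = as.numeric(topography),
                 fcz_channel = as.integer(fcz_channel),
                 inter_event_s = inter_event_s,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a continuous synthetic ErrP session
#'
#' Generates coloured background EEG, a regular event stream with
#' i.i.d. Bernoulli(`error_probability`) labels, and adds the sampled ErrP
#' template at each label-1 event, scaled per channel by the topography and
#' globally so that the strongest channel attains `snr_db`.
#'
#' @param config A [sim_config()].
#' @param template An [errp_template()]; default [default_errp_template()].
#' @param background A [background_model()].
#' @return List with `recording` (a [continuous_recording()]) and `events`
#'   (list with `event_samples`, 1-based, and `event_labels`).
#' @export
simulate_session <- function(config, template = default_errp_template(),
                             background = background_model()) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate_hz
  step <- round(config$inter_event_s * fs)
  wave <- make_template(template, fs)
  if (step < length(wave)) {
    stopf("inter-event spacing (%d samples) shorter than the template (%d)",
          step, length(wave))
  }
  # first event leaves a full pre-stimulus second; pad one step at the end
  first <- step + 1L
  event_samples <- first + (seq_len(config$n_events) - 1L) * step
  n_samples <- as.integer(event_samples[config$n_events] + step)

  labels <- with_seed(sub_seed(config$seed, 1L),
                      rbinom(config$n_events, 1L, config$error_probability))
  noise <- simulate_background(background, n_samples, config$n_channels,
                               seed = sub_seed(config$seed, 2L))

  gain <- template_gain(wave, noise, config)
  data <- noise
  scaled <- outer(config$topography * gain, wave)   # channel x sample
  for (i in which(labels == 1L)) {
    idx <- event_samples[i]:(event_samples[i] + length(wave) - 1L)
    data[, idx] <- data[, idx] + scaled
  }
  rec <- continuous_recording(
    data = data, sampling_rate_hz = fs,
    channel_names = sprintf("ch%02d", seq_len(config$n_channels)),
    events = list(event_samples = event_samples, event_labels = labels))
  list(recording = rec, events = rec$events)
}

# Gain applied to the unit template so that the strongest channel reaches
# the configured SNR against the realised background power on that channel.
template_gain <- function(wave, noise, config) {
  peak_ch <- which.max(abs(config$topography))
  p_bg <- mean(noise[peak_ch, ]^2)
  if (!is.finite(config$snr_db) || p_bg == 0) return(1)
  p_tmpl <- mean((config$topography[peak_ch] * wave)^2)
  sqrt(10^(config$snr_db / 10) * p_bg / p_tmpl)
}

#' Write / read an event stream as a plain-text table
#'
#' Two tab-separated columns: `sample_index` (1-based) and `label`.
#'
#' @param events List with `event_samples` and `event_labels`.
#' @param path Output file.
#' @export
write_events <- function(events, path) {
  utils::write.table(
    data.frame(sample_index = events$event_samples, label = events$event_labels),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  list(event_samples = as.integer(df$sample_index),
       event_labels = as.integer(df$label))
}
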