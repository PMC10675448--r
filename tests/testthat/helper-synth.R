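# Shared fixtures: everything is generated in code, nothing is stored.

# A small preprocessed-scale epoch set straight from the generator
# (64 Hz, 1 s windows), bypassing the filter chain for speed.
small_epochs <- function(n_events = 120, n_channels = 4, snr_db = 0,
                         seed = 42, error_probability = 0.2) {
  ses <- simulate_session(sim_config(
    n_events = n_events, n_channels = n_channels, snr_db = snr_db,
    seed = seed, error_probability = error_probability))
  suppressWarnings(extract_epochs(ses$recording))
}

# Single-channel epochs: template + AR background at a given SNR.
channel_epochs <- function(n_events = 200, snr_db = 0, seed = 7) {
  ses <- simulate_session(sim_config(
    n_events = n_events, n_channels = 1, snr_db = snr_db, seed = seed,
    topography = 1, fcz_channel = 1))
  suppressWarnings(extract_epochs(ses$recording))
}

ref_template <- function(fs = 64) make_template(default_errp_template(), fs)

# Mean correlation of label-1 epochs (one channel) with the true template.
mean_template_cor <- function(epochs, channel = 1, labels = 1L) {
  idx <- which(epochs$labels == labels)
  tmpl <- ref_template(epochs$sampling_rate_hz)
  m <- matrix(epochs$data[idx, channel, ], nrow = length(idx))
  mean(apply(m, 1, stats::cor, y = tmpl))
}

# Tiny linearly separable two-class epoch set for classifier sanity checks.
toy_classification_set <- function(n = 40, n_channels = 4, n_samples = 32,
                                   seed = 1, noise_sd = 0.3) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    dat <- array(stats::rnorm(n * n_channels * n_samples, sd = noise_sd),
                 c(n, n_channels, n_samples))
    lab <- rep(c(0L, 1L), length.out = n)
    sig <- sin(2 * pi * seq_len(n_samples) / 16)
    for (i in which(lab == 1L)) dat[i, 2, ] <- dat[i, 2, ] + sig
    epoch_set(dat, lab, 32)
  })
}
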