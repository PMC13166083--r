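# Shared fixtures, built in code at test time.

FS <- 20000

# band-limited background noise matching the basal generator's spectrum
make_noise <- function(n, fs = FS, sd_uv = 4, seed = 1) {
  set.seed(seed)
  bf <- signal::butter(2, c(300, 6000) / (fs / 2), "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x * (sd_uv / sd(x))
}

# smooth bi-exponential artifact decaying from `peak`
make_artifact <- function(n, fs = FS, peak = 400, tau_fast = 0.3, tau_slow = 8) {
  t_ms <- (seq_len(n) - 1) / fs * 1e3
  peak * (exp(-t_ms / tau_fast) - 0.15 * exp(-t_ms / tau_slow))
}

# a recording with one artifact per onset plus noise
make_channel <- function(duration = 5, fs = FS, n_stims = 40, peak = 400,
                         noise_sd = 4, seed = 1) {
  n <- duration * fs
  onsets <- as.integer(round(seq(0.2, duration - 0.2, length.out = n_stims) * fs))
  sig <- make_noise(n, fs, noise_sd, seed)
  for (o in onsets) {
    len <- min(ms_to_samples(50, fs), n - o + 1L)
    sig[o:(o + len - 1L)] <- sig[o:(o + len - 1L)] + make_artifact(len, fs, peak)
  }
  list(rec = recording(sig, fs), stims = stim_train(onsets, n))
}

default_cfg <- loglira_config()

make_dict_channel <- function(n_stims, fs = FS, n_families = 1, seed = 1) {
  # channel whose artifacts form `n_families` tight waveform families
  tmpl <- gen_templates(max(n_families, 2), fs = fs, jitter = 0.02, seed = seed)
  iai <- ms_to_samples(60, fs)
  onsets <- (seq_len(n_stims) - 1L) * iai + 100L
  n <- max(onsets) + iai
  sig <- make_noise(n, fs, 2, seed)
  ids <- rep_len(seq_len(n_families), n_stims)
  for (k in seq_len(n_stims)) {
    w <- tmpl[[ids[k]]]
    len <- min(length(w), iai)
    idx <- onsets[k]:(onsets[k] + len - 1L)
    sig[idx] <- sig[idx] + w[1:len]
  }
  list(rec = recording(sig, fs), stims = stim_train(onsets, n), tmpl = tmpl)
}

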