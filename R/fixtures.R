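# Synthetic fixtures: basal extracellular-like activity with known spike
# times, parametric artifact templates, and heavy-tailed stimulus trains.
# These stand in for real recordings so the whole pipeline is testable
# without any data download.

# Biphasic/triphasic ~1 ms extracellular spike prototypes, peak-normalised to
# -1 at the main (negative) lobe. `shift` perturbs lobe widths per prototype.
spike_prototype <- function(fs, width_ms = 1, shape = 1) {
  n <- ms_to_samples(width_ms, fs)
  n <- max(n, 8L)
  t <- seq(-1, 1, length.out = n)
  s1 <- 0.18 + 0.04 * shape
  s2 <- 0.45 + 0.05 * shape
  wav <- -exp(-(t / s1)^2) + 0.45 * exp(-((t - 2.2 * s1) / s2)^2) +
    0.12 * exp(-((t + 2.6 * s1) / s2)^2)
  wav / max(abs(wav))
}

#' Generate basal (stimulation-free) ground-truth activity
#'
#' Band-limited Gaussian background noise (300-6000 Hz) plus biphasic spike
#' waveforms of roughly 1 ms inserted at gamma-distributed inter-spike
#' intervals with an absolute refractory period. Draws are repeated until the
#' realised mean firing rate (spike count over duration) is within
#' `mfr_tol` of the target. By construction the returned signal equals
#' noise plus the inserted spike track exactly.
#'
#' @param duration length in seconds.
#' @param fs sampling rate (Hz).
#' @param mfr_target target mean firing rate (Hz); 0 inserts no spikes.
#' @param mfr_tol tolerance on the realised rate (Hz).
#' @param noise_std background noise standard deviation (microvolts).
#' @param spike_amplitude_range peak spike amplitudes, drawn uniformly
#'   (microvolts).
#' @param refractory absolute refractory period (ms).
#' @param seed random seed.
#' @return object of class `basal_ground_truth`: `signal`, `noise`,
#'   `spike_track`, `spikes` (peak-aligned sample indices), `waveform_ids`,
#'   `realized_mfr`, `fs`, `duration`.
#' @export
gen_basal <- function(duration = 150, fs = 20000, mfr_target = 10,
                      mfr_tol = 0.5, noise_std = 4,
                      spike_amplitude_range = c(30, 120), refractory = 2,
                      seed = 1L) {
  set.seed(seed)
  n <- as.integer(round(duration * fs))
  noise <- if (noise_std > 0) {
    bf <- signal::butter(2, c(300, min(6000, 0.45 * fs)) / (fs / 2), "pass")
    raw <- signal::filtfilt(bf, rnorm(n))
    raw * (noise_std / sd(raw))
  } else numeric(n)
  spikes <- integer(0)
  ids <- integer(0)
  track <- numeric(n)
  if (mfr_target > 0) {
    refr_s <- refractory * 1e-3
    if (1 / mfr_target <= refr_s)
      stop("gen_basal: target MFR unreachable under the refractory period")
    mean_isi <- 1 / mfr_target
    for (attempt in 1:200) {
      isi <- refr_s + rgamma(ceiling(duration * mfr_target * 2) + 20,
                             shape = 2, scale = (mean_isi - refr_s) / 2)
      tt <- cumsum(isi)
      tt <- tt[tt < duration - 2e-3]
      realized <- length(tt) / duration
      if (abs(realized - mfr_target) <= mfr_tol) break
      if (attempt == 200) stop("gen_basal: could not realise the target MFR")
    }
    protos <- lapply(1:3, function(s) spike_prototype(fs, shape = s))
    half <- vapply(protos, function(p) length(p) %/% 2L, integer(1))
    spikes <- as.integer(round(tt * fs)) + 1L
    ids <- sample.int(3L, length(spikes), replace = TRUE)
    amps <- runif(length(spikes), spike_amplitude_range[1],
                  spike_amplitude_range[2])
    for (k in seq_along(spikes)) {
      p <- protos[[ids[k]]] * amps[k]
      # align the main lobe (waveform minimum) with the spike time
      pk <- which.min(p)
      idx <- spikes[k] - pk + seq_along(p)
      keep <- idx >= 1 & idx <= n
      track[idx[keep]] <- track[idx[keep]] + p[keep]
    }
  }
  structure(list(signal = noise + track, noise = noise, spike_track = track,
                 spikes = spikes, waveform_ids = ids,
                 realized_mfr = length(spikes) / duration,
                 fs = fs, duration = duration, seed = seed),
            class = "basal_ground_truth")
}

#' @export
print.basal_ground_truth <- function(x, ...) {
  cat(sprintf("<basal_ground_truth: %.3g s @ %g Hz, %d spikes (MFR %.2f Hz)>\n",
              x$duration, x$fs, length(x$spikes), x$realized_mfr))
  invisible(x)
}

#' Generate parametric stimulation-artifact templates
#'
#' Each template is a sharp biphasic onset transient followed by a
#' bi-exponential decay (fast and slow time constants), optionally
#' sign-flipped, with per-template jitter of amplitudes and time constants.
#' When `saturation` is on, the first `plateau_ms` of the template clips
#' exactly at the amplifier limit before the decay begins.
#'
#' @param n_templates number of templates.
#' @param fs sampling rate (Hz).
#' @param duration_ms template length (ms).
#' @param peak_amplitude nominal decay amplitude (microvolts).
#' @param decay_time_constants fast and slow decay constants (ms).
#' @param tail_fraction relative amplitude of the opposite-sign slow tail.
#' @param saturation logical: clip the initial portion at `amp_limit`.
#' @param plateau_ms saturation plateau duration (ms).
#' @param amp_limit amplifier operating limit (microvolts), required when
#'   `saturation` is on.
#' @param jitter relative per-template perturbation of parameters.
#' @param seed random seed.
#' @return list of class `artifact_templates`, one numeric waveform per
#'   element, with `fs` attribute.
#' @export
gen_templates <- function(n_templates = 5L, fs = 20000, duration_ms = 50,
                          peak_amplitude = 450,
                          decay_time_constants = c(0.3, 8),
                          tail_fraction = 0.15,
                          saturation = FALSE, plateau_ms = 2,
                          amp_limit = 5000, jitter = 0.15, seed = 1L) {
  set.seed(seed)
  n <- ms_to_samples(duration_ms, fs)
  if (saturation && ms_to_samples(plateau_ms, fs) >= n)
    stop("gen_templates: plateau must be shorter than the template")
  t_ms <- (seq_len(n) - 1L) / fs * 1e3
  out <- vector("list", n_templates)
  # spread the families deterministically so a dictionary built from the
  # channel holds genuinely distinct shapes (polarity, decay speed, tail)
  spread <- if (n_templates > 1) seq(0.6, 1.8, length.out = n_templates) else 1
  for (k in seq_len(n_templates)) {
    tf <- decay_time_constants[1] * spread[k] * (1 + jitter * rnorm(1))
    tsl <- decay_time_constants[2] * spread[n_templates - k + 1L] *
      (1 + jitter * rnorm(1))
    A <- peak_amplitude * (1 + jitter * rnorm(1))
    sgn <- if (k %% 2L == 0L) 1 else -1
    if (saturation) {
      p <- ms_to_samples(plateau_ms, fs)
      wav <- numeric(n)
      wav[1:p] <- sgn * amp_limit
      td <- t_ms[(p + 1L):n] - t_ms[p + 1L]
      tail_amp <- tail_fraction * (1 + jitter * rnorm(1))
      wav[(p + 1L):n] <- sgn * amp_limit *
        ((1 + tail_amp) * exp(-td / max(tsl / 4, 1)) -
           tail_amp * exp(-td / tsl))
    } else {
      tail_amp <- tail_fraction * (1 + jitter * rnorm(1))
      # cap the slow constant so the tail is below 1 uV by the template end
      ts_cap <- 0.95 * duration_ms / log(max(abs(tail_amp) * A, 2))
      tsl <- min(tsl, ts_cap)
      wav <- sgn * A * (exp(-t_ms / max(tf, 0.05)) -
                          tail_amp * exp(-t_ms / max(tsl, 0.5)))
      # sharp biphasic pulse within the first 0.3 ms
      pulse <- which(t_ms < 0.3)
      wav[pulse] <- wav[pulse] +
        sgn * 0.8 * A * sin(2 * pi * t_ms[pulse] / 0.6)
    }
    out[[k]] <- wav
  }
  structure(out, fs = fs, duration_ms = duration_ms, seed = seed,
            saturation = saturation,
            amp_limit = if (saturation) amp_limit else NA_real_,
            class = "artifact_templates")
}

#' Generate a stimulus onset train with heavy-tailed intervals
#'
#' Inter-artifact intervals are drawn from a log-normal distribution and
#' rescaled so the realised mean artifact rate `1/median(IAI)` lies within
#' `tol` of the target; onsets are the cumulative sums truncated at the
#' requested duration. `constant = TRUE` gives the degenerate evenly spaced
#' train.
#'
#' @param mar_target target mean artifact rate (Hz).
#' @param duration length in seconds.
#' @param fs sampling rate (Hz).
#' @param seed random seed.
#' @param sdlog log-normal shape parameter of the IAI distribution.
#' @param tol tolerance on the realised MAR (Hz).
#' @param constant use a constant IAI equal to `1/mar_target`.
#' @return a [stim_train()] with attributes `realized_mar` and `iai`.
#' @export
gen_stim_onsets <- function(mar_target, duration, fs, seed = 1L, sdlog = 0.5,
                            tol = 0.1, constant = FALSE) {
  stopifnot(mar_target > 0)
  if (duration <= 2 / mar_target)
    stop("gen_stim_onsets: duration too short for at least 2 onsets")
  set.seed(seed)
  if (constant) {
    onsets_s <- seq(1 / mar_target, duration, by = 1 / mar_target)
  } else {
    med <- 1 / mar_target
    for (attempt in 1:100) {
      iai <- rlnorm(ceiling(duration * mar_target * 2) + 10,
                    meanlog = log(med), sdlog = sdlog)
      iai <- iai * (med / median(iai))    # force the median onto target
      onsets_s <- cumsum(iai)
      onsets_s <- onsets_s[onsets_s < duration]
      if (length(onsets_s) >= 2 &&
          abs(1 / median(diff(c(0, onsets_s))) - mar_target) <= tol) break
      if (attempt == 100) stop("gen_stim_onsets: target MAR not realised")
    }
  }
  n_total <- as.integer(round(duration * fs))
  onsets <- unique(as.integer(round(onsets_s * fs)) + 1L)
  onsets <- onsets[onsets <= n_total]
  st <- stim_train(onsets, n_samples = n_total)
  attr(st, "realized_mar") <- 1 / median(diff(onsets) / fs)
  attr(st, "iai") <- diff(onsets) / fs
  st
}

#' Insert stimulus-locked evoked spikes into a basal ground truth
#'
#' Optional evoked mode: after each stimulus onset a spike is inserted with
#' probability `response_prob` at a short latency (default 1-5 ms) with
#' per-trial jitter, emulating monosynaptically evoked responses — the
#' scenario random basal activity cannot model. Returns a new ground truth
#' whose spike train includes the evoked events.
#'
#' @param basal a `basal_ground_truth` from [gen_basal()].
#' @param stims a [stim_train()] aligned to the same sampling rate.
#' @param latency_range evoked-spike latency window after the onset (ms).
#' @param jitter_ms SD of the per-trial latency jitter (ms).
#' @param response_prob probability that a stimulus evokes a spike.
#' @param amplitude evoked spike peak amplitude (microvolts).
#' @param seed random seed.
#' @return a `basal_ground_truth` with added `evoked` (sample indices of the
#'   inserted evoked spikes).
#' @export
gen_evoked_spikes <- function(basal, stims, latency_range = c(1, 5),
                              jitter_ms = 0.3, response_prob = 0.7,
                              amplitude = 80, seed = 1L) {
  stopifnot(inherits(basal, "basal_ground_truth"))
  set.seed(seed)
  fs <- basal$fs
  n <- length(basal$signal)
  onsets <- as.integer(stims)
  respond <- runif(length(onsets)) < response_prob
  base_lat <- runif(1, latency_range[1], latency_range[2])
  lat_ms <- pmax(latency_range[1],
                 pmin(latency_range[2],
                      base_lat + rnorm(length(onsets), 0, jitter_ms)))
  times <- onsets[respond] + ms_to_samples(1, fs) * lat_ms[respond]
  times <- as.integer(round(times))
  proto <- spike_prototype(fs, shape = 2)
  pk <- which.min(proto)
  track <- basal$spike_track
  keep <- logical(length(times))
  for (k in seq_along(times)) {
    idx <- times[k] - pk + seq_along(proto)
    ok <- idx >= 1 & idx <= n
    if (!any(ok)) next
    keep[k] <- TRUE
    track[idx[ok]] <- track[idx[ok]] + amplitude * proto[ok]
  }
  times <- times[keep]
  out <- basal
  out$spike_track <- track
  out$signal <- basal$noise + track
  out$spikes <- sort(unique(c(basal$spikes, times)))
  out$evoked <- sort(times)
  out$realized_mfr <- length(out$spikes) / basal$duration
  out
}

#' Generate a full synthetic stimulated channel
#'
#' Convenience wrapper combining background activity, a stimulus train and
#' per-stimulus artifact waveforms (a randomly chosen template per onset),
#' used for dictionary-building tests and desk-scale benchmarks.
#'
#' @param duration seconds.
#' @param fs Hz.
#' @param templates an `artifact_templates` object.
#' @param stims optional [stim_train()]; generated at `mar` when missing.
#' @param mar target MAR (Hz) when `stims` is missing.
#' @param basal optional `basal_ground_truth` to superimpose; plain noise
#'   when missing.
#' @param noise_std background noise SD when `basal` is missing.
#' @param amp_limits recording amplifier limits.
#' @param seed random seed.
#' @return list: `recording`, `stims`, `template_ids`, `basal`.
#' @export
gen_synthetic_channel <- function(duration = 20, fs = 20000, templates,
                                  stims = NULL, mar = 10, basal = NULL,
                                  noise_std = 4, amp_limits = NULL,
                                  seed = 1L) {
  set.seed(seed)
  n <- as.integer(round(duration * fs))
  if (is.null(stims)) stims <- gen_stim_onsets(mar, duration, fs, seed = seed + 1L)
  base_sig <- if (!is.null(basal)) basal$signal[seq_len(n)] else {
    bf <- signal::butter(2, c(300, min(6000, 0.45 * fs)) / (fs / 2), "pass")
    raw <- signal::filtfilt(bf, rnorm(n))
    raw * (noise_std / sd(raw))
  }
  track <- numeric(n)
  ids <- sample.int(length(templates), length(stims), replace = TRUE)
  onsets <- as.integer(stims)
  nexts <- c(onsets[-1], n + 1L)
  for (k in seq_along(onsets)) {
    tmpl <- templates[[ids[k]]]
    len <- min(length(tmpl), nexts[k] - onsets[k])
    if (len < 1) next
    idx <- onsets[k]:(onsets[k] + len - 1L)
    track[idx] <- track[idx] + tmpl[1:len]
  }
  list(recording = recording(base_sig + track, fs, amp_limits = amp_limits),
       stims = stims, template_ids = ids, basal = basal)
}
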