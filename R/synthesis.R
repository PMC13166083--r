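# Semisynthetic benchmark synthesis: per-channel artifact template
# dictionaries, inter-artifact-interval resampling to a target rate, and
# snippet construction (windowed templates + basal ground truth).

#' Build an artifact-template dictionary from a stimulated channel
#'
#' All artifact waveforms are extracted at the stimulus onsets with a common
#' length set by the minimum inter-artifact interval, embedded in 2-D
#' (correlation distance) and grouped by density-based merging. Each cluster
#' with at least `min_members` members contributes one template: the
#' per-sample median of its members smoothed by a lowpass FIR filter
#' (~2 kHz cutoff). For clusters containing saturated waveforms the raw
#' median and the smoothed version are merged at the last time point where
#' their absolute difference exceeds `merge_factor` times its median,
#' preserving the fast onset transient and clip edges while suppressing
#' residual neural variability.
#'
#' @param rec a [recording()].
#' @param stims a [stim_train()] with at least `min_members` onsets.
#' @param min_members minimum cluster membership for an accepted template.
#' @param lowpass_hz smoothing filter cutoff (Hz).
#' @param merge_factor threshold multiplier for the saturated-template merge.
#' @param sat_fraction saturation threshold fraction (of amplifier limit or
#'   channel maximum).
#' @param seed passed to the embedding (deterministic; kept for interface
#'   stability).
#' @return list of class `template_dictionary`: `templates`, `source_onsets`,
#'   `fs`, `channel_id`, `cluster_sizes`.
#' @export
build_dictionary <- function(rec, stims, min_members = 100L,
                             lowpass_hz = 2000, merge_factor = 2.5,
                             sat_fraction = 0.95, seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  onsets <- as.integer(stims)
  K <- length(onsets)
  if (K < min_members)
    stop(sprintf("build_dictionary: %d artifacts < %d required", K, min_members))
  len <- min(diff(onsets))
  keep <- onsets + len - 1L <= length(rec$samples)
  onsets <- onsets[keep]
  if (length(onsets) < min_members)
    stop("build_dictionary: too few full-length artifact waveforms")
  W <- t(vapply(onsets, function(o) rec$samples[o:(o + len - 1L)],
                numeric(len)))
  emb <- embed_windows(W, seed = seed)
  zv <- attr(emb, "zero_var")
  labels <- rep(0L, nrow(W))
  if (sum(!zv) >= 2) {
    ca <- cluster_density(emb[!zv, , drop = FALSE], theta = min_members)
    labels[!zv] <- ca$labels
  }
  if (sum(zv) >= min_members) labels[zv] <- max(labels) + 1L
  retained <- sort(unique(labels[labels > 0L]))
  if (length(retained) == 0)
    stop("build_dictionary: no cluster reaches the required membership")
  sb <- saturation_bounds(rec$samples, rec$amp_limits, sat_fraction)
  fs <- rec$fs
  templates <- lapply(retained, function(cl) {
    med <- apply(W[labels == cl, , drop = FALSE], 2, median)
    sm <- fir_lowpass(med, fs, lowpass_hz)
    saturated <- any(med <= sb[["lo"]] | med >= sb[["hi"]])
    if (!saturated) return(sm)
    d <- abs(med - sm)
    thr <- merge_factor * median(d)
    idx <- which(d > thr)
    if (length(idx) == 0) return(sm)
    cut <- max(idx)
    c(med[1:cut], if (cut < len) sm[(cut + 1L):len])
  })
  structure(list(templates = templates,
                 source_onsets = stim_train(as.integer(stims)),
                 fs = fs, channel_id = rec$channel_id,
                 cluster_sizes = as.integer(table(labels[labels > 0L]))),
            class = "template_dictionary")
}

# Zero-phase FIR lowpass used for template smoothing. The order adapts to
# the waveform length so short templates remain filterable.
fir_lowpass <- function(x, fs, cutoff_hz) {
  ord <- min(64L, 2L * (length(x) %/% 6L))
  if (ord < 4L || cutoff_hz >= fs / 2) return(x)
  b <- signal::fir1(ord, cutoff_hz / (fs / 2))
  as.numeric(signal::filtfilt(b, x))
}

#' @export
print.template_dictionary <- function(x, ...) {
  cat(sprintf("<template_dictionary '%s': %d templates of %d samples @ %g Hz>\n",
              x$channel_id, length(x$templates),
              length(x$templates[[1]]), x$fs))
  invisible(x)
}

#' Resample inter-artifact intervals to a target mean artifact rate
#'
#' The source IAIs are first adjusted: shifted rightward by a constant when
#' the target MAR is below the source MAR, or trimmed of their largest values
#' (2% per iteration) when it is above — the minimum IAI stays in place.
#' A kernel density estimate (Silverman bandwidth) of the adjusted set is
#' then sampled, truncated to the adjusted range, accumulating intervals
#' until their sum covers the requested duration; draws are repeated until
#' the realised `1/median` is within `tol` of the target.
#'
#' @param iai source intervals (seconds), length >= 2.
#' @param mar_target target rate (Hz).
#' @param duration span the cumulative intervals must reach (seconds).
#' @param seed random seed.
#' @param tol realised-rate tolerance (Hz).
#' @param trim_frac fraction of largest IAIs removed per shrink iteration.
#' @param max_retry bound on redraw attempts.
#' @return numeric IAI sequence (seconds) with attribute `adjusted` (the
#'   shifted/trimmed source set).
#' @export
resample_iai <- function(iai, mar_target, duration, seed = 1L, tol = 0.1,
                         trim_frac = 0.02, max_retry = 200L) {
  stopifnot(length(iai) >= 2, all(iai > 0), mar_target > 0)
  if (mar_target > 1 / min(iai))
    stop("resample_iai: target MAR above 1/min(IAI) is unreachable")
  set.seed(seed)
  adj <- sort(iai)
  cur <- 1 / median(adj)
  if (mar_target < cur - tol) {
    adj <- adj + (1 / mar_target - median(adj))   # rightward shift
  } else if (mar_target > cur + tol) {
    while (1 / median(adj) < mar_target - tol && length(adj) > 3) {
      drop_n <- max(1L, floor(trim_frac * length(adj)))
      adj <- adj[seq_len(length(adj) - drop_n)]   # remove largest
    }
    # discrete removal steps rarely land on the target exactly: finish with
    # an affine shrink towards the minimum, which stays in place
    med <- median(adj); m0 <- min(adj)
    if (abs(1 / med - mar_target) > tol && med > m0 && 1 / mar_target > m0) {
      adj <- m0 + (adj - m0) * (1 / mar_target - m0) / (med - m0)
    }
    if (abs(1 / median(adj) - mar_target) > tol)
      stop("resample_iai: target MAR not reachable by trimming")
  }
  lo <- min(adj); hi <- max(adj)
  if (hi - lo < 1e-12) {
    # degenerate constant-interval source: the KDE support is a point
    m <- ceiling(duration / adj[1]) + 1L
    iais <- rep(adj[1], m)
    iais <- iais[seq_len(which(cumsum(iais) >= duration)[1])]
    attr(iais, "adjusted") <- adj
    return(iais)
  }
  bw <- stats::bw.nrd0(adj)
  draw_one <- function(m) {
    out <- numeric(0)
    tries <- 0L
    while (length(out) < m) {
      cand <- sample(adj, m, replace = TRUE) + rnorm(m, 0, bw)
      out <- c(out, cand[cand >= lo & cand <= hi])
      tries <- tries + 1L
      if (tries > 1000L) stop("resample_iai: truncated KDE rejects all draws")
    }
    out[seq_len(m)]
  }
  chunk <- max(16L, ceiling(duration * mar_target))
  for (attempt in seq_len(max_retry)) {
    iais <- draw_one(chunk)
    while (sum(iais) < duration) iais <- c(iais, draw_one(chunk %/% 2L + 1L))
    iais <- iais[seq_len(which(cumsum(iais) >= duration)[1])]
    if (length(iais) >= 2 &&
        abs(1 / median(iais) - mar_target) <= tol) {
      attr(iais, "adjusted") <- adj
      return(iais)
    }
  }
  stop("resample_iai: realised MAR not within tolerance after retries")
}

#' Synthesize a semisynthetic snippet
#'
#' An artifact track is built by placing randomly picked dictionary templates
#' at onsets derived from resampled IAIs; each insertion is multiplied by the
#' decaying half of a Blackman window (raised to a random exponent in
#' [0.5, 2] for template variability), which forces it to zero at its end so
#' the track is free of discontinuities. Templates longer than the current
#' interval are truncated at the next onset before windowing. The basal
#' ground-truth signal is then superimposed: by construction
#' `signal - artifact_track` equals the basal signal exactly and the
#' ground-truth spike train is untouched by template placement.
#'
#' @param dict a `template_dictionary`.
#' @param basal a `basal_ground_truth` of at least `duration` seconds.
#' @param mar_target target mean artifact rate (Hz).
#' @param duration snippet length (seconds).
#' @param seed random seed.
#' @param mar_tol realised-MAR tolerance (Hz).
#' @param alpha_range exponent range applied to the window's decaying half.
#' @return object of class `snippet`: `signal`, `basal_signal` (the exact
#'   superimposed ground-truth component), `artifact_track`, `stims`,
#'   `spikes`, `template_ids`, `realized_mar`, `realized_mfr`, `fs`.
#' @export
synthesize_snippet <- function(dict, basal, mar_target, duration = 150,
                               seed = 1L, mar_tol = 0.1,
                               alpha_range = c(0.5, 2)) {
  stopifnot(inherits(dict, "template_dictionary"),
            inherits(basal, "basal_ground_truth"))
  if (length(dict$templates) == 0) stop("synthesize_snippet: empty dictionary")
  if (basal$duration < duration)
    stop("synthesize_snippet: basal segment shorter than the snippet")
  fs <- dict$fs
  stopifnot(fs == basal$fs)
  src_iai <- iai_of(dict$source_onsets, fs)
  n <- as.integer(round(duration * fs))
  # the tolerance must hold for the realised onset train (after truncation
  # at the snippet end and rounding to samples), not just the drawn IAIs
  for (attempt in 0:50) {
    iais <- resample_iai(src_iai, mar_target, duration,
                         seed = seed + attempt * 1009L, tol = mar_tol)
    onsets_s <- cumsum(iais)
    onsets_s <- onsets_s[onsets_s < duration]
    onsets <- unique(as.integer(round(onsets_s * fs)) + 1L)
    onsets <- onsets[onsets <= n]
    if (length(onsets) >= 2 &&
        abs(1 / median(diff(onsets) / fs) - mar_target) <= mar_tol) break
    if (attempt == 50)
      stop("synthesize_snippet: realised MAR not within tolerance")
  }
  set.seed(seed + 1L)
  ids <- sample.int(length(dict$templates), length(onsets), replace = TRUE)
  alphas <- runif(length(onsets), alpha_range[1], alpha_range[2])
  track <- numeric(n)
  nexts <- c(onsets[-1], n + 1L)
  for (k in seq_along(onsets)) {
    tmpl <- dict$templates[[ids[k]]]
    len <- min(length(tmpl), nexts[k] - onsets[k], n - onsets[k] + 1L)
    if (len < 2) next
    w <- blackman_decay(len)^alphas[k]
    idx <- onsets[k]:(onsets[k] + len - 1L)
    track[idx] <- track[idx] + tmpl[1:len] * w
  }
  stims <- stim_train(onsets, n_samples = n)
  basal_signal <- basal$signal[seq_len(n)]
  structure(list(signal = basal_signal + track,
                 basal_signal = basal_signal,
                 artifact_track = track,
                 stims = stims,
                 spikes = basal$spikes[basal$spikes <= n],
                 template_ids = ids,
                 realized_mar = 1 / median(diff(onsets) / fs),
                 realized_mfr = sum(basal$spikes <= n) / duration,
                 fs = fs, duration = duration, seed = seed),
            class = "snippet")
}

# Decaying half of a Blackman window: weight 1 at the first sample, exactly
# 0 at the last.
blackman_decay <- function(len) {
  full <- 2L * len - 1L
  k <- (len:full) - 1L
  w <- 0.42 - 0.5 * cos(2 * pi * k / (full - 1L)) + 0.08 * cos(4 * pi * k / (full - 1L))
  pmax(w, 0)  # guard: the zero endpoint can round to -1e-17
}

#' @export
print.snippet <- function(x, ...) {
  cat(sprintf("<snippet: %.3g s @ %g Hz, K = %d (MAR %.2f Hz), %d spikes (MFR %.2f Hz)>\n",
              x$duration, x$fs, length(x$stims), x$realized_mar,
              length(x$spikes), x$realized_mfr))
  invisible(x)
}

#' Build a full benchmark dataset over the MFR x MAR grid
#'
#' One snippet per (MFR, MAR) combination per subset; the default full grid
#' gives 5 x 10 = 50 snippets per subset. Each subset uses one dictionary
#' (recycled over subsets when fewer dictionaries are supplied) and a fresh
#' basal segment per cell; seeds for every cell derive deterministically from
#' `seed` and are recorded in the manifest.
#'
#' @param dictionaries list of `template_dictionary` objects (>= 1).
#' @param mfr_grid mean firing rates (Hz).
#' @param mar_grid mean artifact rates (Hz).
#' @param n_subsets number of subsets.
#' @param duration snippet duration (seconds).
#' @param fs sampling rate, must match the dictionaries.
#' @param seed master seed.
#' @param basal_args extra arguments passed to [gen_basal()].
#' @return object of class `benchmark_set`: `manifest` (tibble) and
#'   `snippets` (list, one per manifest row).
#' @export
build_benchmark <- function(dictionaries, mfr_grid = c(5, 10, 15, 20, 25),
                            mar_grid = seq(2, 20, by = 2), n_subsets = 1L,
                            duration = 150, fs = 20000, seed = 1L,
                            basal_args = list()) {
  stopifnot(length(dictionaries) >= 1, length(mfr_grid) >= 1,
            length(mar_grid) >= 1)
  rows <- list(); snippets <- list(); r <- 0L
  for (s in seq_len(n_subsets)) {
    dict <- dictionaries[[(s - 1L) %% length(dictionaries) + 1L]]
    if (dict$fs != fs) stop("build_benchmark: dictionary sampling rate mismatch")
    for (mfr in mfr_grid) for (mar in mar_grid) {
      r <- r + 1L
      cell_seed <- (seed * 10007L + r * 131L) %% .Machine$integer.max
      basal <- do.call(gen_basal, c(list(duration = duration, fs = fs,
                                         mfr_target = mfr,
                                         seed = cell_seed),
                                    basal_args))
      snip <- synthesize_snippet(dict, basal, mar, duration = duration,
                                 seed = cell_seed + 1L)
      snippets[[r]] <- snip
      rows[[r]] <- tibble::tibble(
        id = sprintf("s%02d_mfr%02d_mar%02d", s, mfr, mar),
        subset = s, mfr_target = mfr, mar_target = mar,
        seed = cell_seed,
        realized_mfr = snip$realized_mfr, realized_mar = snip$realized_mar,
        k_stimuli = length(snip$stims), n_spikes = length(snip$spikes))
    }
  }
  structure(list(manifest = dplyr::bind_rows(rows), snippets = snippets,
                 fs = fs, duration = duration, seed = seed),
            class = "benchmark_set")
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat(sprintf("<benchmark_set: %d snippets of %.3g s @ %g Hz>\n",
              nrow(x$manifest), x$duration, x$fs))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.benchmark_set <- function(x, ...) x$manifest
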