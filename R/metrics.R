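# Benchmark metrics: zero-phase bandpass, SWTTEO spike detection,
# RMSE, jitter-matched FP/FN, zero-lag spike-train cross-correlation with a
# coincidence window, PSTH, and the harness that runs suppressors over a
# benchmark set.

#' Zero-phase Butterworth bandpass filter
#'
#' Forward-backward (zero phase distortion) 4th-order Butterworth bandpass,
#' 300-7000 Hz by default. When the sampling rate cannot support the upper
#' cutoff it is reduced to `0.45 * fs` with a warning.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param low,high cutoff frequencies (Hz).
#' @param order filter order.
#' @return filtered numeric signal, same length.
#' @export
bandpass <- function(x, fs, low = 300, high = 7000, order = 4) {
  if (high >= fs / 2) {
    warning(sprintf("bandpass: reducing upper cutoff to %.0f Hz", 0.45 * fs))
    high <- 0.45 * fs
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# sym4 decomposition filters (least-asymmetric Daubechies, 4 vanishing
# moments); standard published coefficients.
sym4_dec_lo <- c(-0.0757657147892733, -0.0296355276459985, 0.4976186676320155,
                 0.8037387518059161, 0.2978577956052774, -0.0992195435768472,
                 -0.0126039672620378, 0.0322231006040427)
sym4_dec_hi <- c(-0.0322231006040427, -0.0126039672620378, 0.0992195435768472,
                 0.2978577956052774, -0.8037387518059161, 0.4976186676320155,
                 0.0296355276459985, -0.0757657147892733)

# Centered same-length convolution with symmetric edge padding. Direct FIR
# (stats::filter) rather than FFT: filters are short and signals long.
conv_same <- function(x, f) {
  m <- length(f)
  pad <- min(m, length(x))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(length(x) - pad + 1L):length(x)]))
  y <- stats::filter(xp, f, method = "convolution", sides = 2)
  as.numeric(y[(pad + 1L):(pad + length(x))])
}

# A-trous (undecimated) stationary wavelet transform: detail coefficients at
# each level, computed with filters upsampled by 2^(level-1).
swt_details <- function(x, levels = 2L) {
  a <- x
  out <- vector("list", levels)
  for (l in seq_len(levels)) {
    up <- 2L^(l - 1L)
    hi <- lo <- numeric(8L * up - up + 1L)
    hi[seq(1L, length(hi), by = up)] <- sym4_dec_hi
    lo[seq(1L, length(lo), by = up)] <- sym4_dec_lo
    out[[l]] <- conv_same(a, hi)
    a <- conv_same(a, lo)
  }
  out
}

# Teager energy operator psi[n] = y[n]^2 - y[n-1] y[n+1].
teager <- function(y) {
  n <- length(y)
  psi <- numeric(n)
  if (n >= 3) psi[2:(n - 1)] <- y[2:(n - 1)]^2 - y[1:(n - 2)] * y[3:n]
  psi
}

#' SWTTEO spike detection
#'
#' Stationary wavelet transform (sym4) detail coefficients are passed through
#' the Teager energy operator, smoothed with a Hamming window and summed
#' across decomposition levels; peaks of this energy feature above a robust
#' threshold (`threshold_mult` x `median(|feature|)/0.6745`), separated by a
#' dead time, are reported as spike times. The algorithm is fully
#' deterministic.
#'
#' @param x filtered numeric signal.
#' @param fs sampling rate (Hz).
#' @param levels wavelet decomposition levels.
#' @param smooth_ms energy smoothing window (ms).
#' @param threshold_mult threshold multiplier on the robust noise estimate.
#' @param dead_ms minimum separation between detections (ms).
#' @return object of class `spike_train`: sorted integer sample indices with
#'   an `fs` attribute.
#' @export
detect_spikes_swtteo <- function(x, fs, levels = 2L, smooth_ms = 1,
                                 threshold_mult = 5, dead_ms = 1) {
  if (all(x == 0) || sd(x) == 0) return(spike_train_obj(integer(0), fs))
  details <- swt_details(x, levels)
  w <- max(3L, ms_to_samples(smooth_ms, fs))
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(w - 1L)) / (w - 1L))
  ham <- ham / sum(ham)
  energy <- 0
  for (d in details) energy <- energy + conv_same(teager(d), ham)
  thr <- threshold_mult * median(abs(energy)) / 0.6745
  dead <- ms_to_samples(dead_ms, fs)
  above <- which(energy > thr)
  if (length(above) == 0) return(spike_train_obj(integer(0), fs))
  # greedy peak picking by decreasing energy with dead-time suppression
  cand <- above[order(-energy[above])]
  taken <- integer(0)
  blocked <- logical(length(x))
  for (p in cand) {
    if (blocked[p]) next
    taken <- c(taken, p)
    blocked[max(1L, p - dead):min(length(x), p + dead)] <- TRUE
  }
  spike_train_obj(sort(taken), fs)
}

spike_train_obj <- function(times, fs) {
  structure(as.integer(times), fs = fs, class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d events @ %g Hz>\n", length(x), attr(x, "fs")))
  invisible(x)
}

#' Root-mean-square error between two equal-length signals
#'
#' `sqrt(sum((x - y)^2) / S)` with `S` the number of samples.
#'
#' @param x,y numeric signals of equal length.
#' @return RMSE in the signals' units (microvolts).
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("rmse: length mismatch")
  sqrt(sum((x - y)^2) / length(x))
}

#' Jitter-matched spike classification
#'
#' Greedy one-to-one matching of nearest pairs within `jitter_ms`; unmatched
#' detections are false positives, unmatched ground-truth events false
#' negatives. Percentages are normalised by the number of ground-truth
#' spikes (and not capped at 100). With an empty ground truth the
#' percentages are undefined and reported as `NA` with the counts intact.
#'
#' @param gt,det spike trains (integer sample indices).
#' @param fs sampling rate (Hz).
#' @param jitter_ms matching window half-width (ms).
#' @return tibble: n_gt, n_det, matched, fp, fn, fp_pct, fn_pct.
#' @export
match_spikes <- function(gt, det, fs, jitter_ms = 0.2) {
  gt <- sort(as.integer(gt)); det <- sort(as.integer(det))
  tol <- ms_to_samples(jitter_ms, fs)
  matched <- 0L
  if (length(gt) > 0 && length(det) > 0) {
    # candidate pairs: each detection against its two nearest gt events
    pos <- findInterval(det, gt)
    cand <- rbind(
      cbind(d = seq_along(det), g = pmax(pos, 1L)),
      cbind(d = seq_along(det), g = pmin(pos + 1L, length(gt))))
    dt <- abs(det[cand[, "d"]] - gt[cand[, "g"]])
    keep <- dt <= tol
    cand <- cand[keep, , drop = FALSE]
    dt <- dt[keep]
    ord <- order(dt, gt[cand[, "g"]])   # nearest first, ties to earlier gt
    used_d <- logical(length(det)); used_g <- logical(length(gt))
    for (k in ord) {
      d <- cand[k, "d"]; g <- cand[k, "g"]
      if (!used_d[d] && !used_g[g]) {
        used_d[d] <- TRUE; used_g[g] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  fp <- length(det) - matched
  fn <- length(gt) - matched
  tibble::tibble(
    n_gt = length(gt), n_det = length(det), matched = matched,
    fp = fp, fn = fn,
    fp_pct = if (length(gt) > 0) 100 * fp / length(gt) else NA_real_,
    fn_pct = if (length(gt) > 0) 100 * fn / length(gt) else NA_real_)
}

#' Zero-lag spike-train cross-correlation with a coincidence window
#'
#' Counts coincidences of each event in `x` with events in `y` within a
#' closed window of half-width `delta_ms / 2`, normalised by
#' `sqrt(Nx * Ny)` and clipped to [0, 1]. Identical non-empty trains score
#' exactly 1; either train empty returns 0.
#'
#' @param x,y spike trains (integer sample indices).
#' @param fs sampling rate (Hz).
#' @param delta_ms total coincidence tolerance window (ms); the default
#'   0.4 ms accounts for positive and negative jitters of 0.2 ms.
#' @return numeric in [0, 1].
#' @export
c0 <- function(x, y, fs, delta_ms = 0.4) {
  x <- sort(as.integer(x)); y <- sort(as.integer(y))
  if (length(x) == 0 || length(y) == 0) return(structure(0, empty = TRUE))
  h <- ms_to_samples(delta_ms / 2, fs)
  count <- sum(findInterval(x + h, y) - findInterval(x - h - 1L, y))
  min(1, count / sqrt(length(x) * length(y)))
}

#' Post-stimulus time histogram
#'
#' Spike latencies relative to each stimulus onset, binned at `bin_ms`
#' (default 0.25 ms) over `[0, window_ms)` and summed across trials.
#'
#' @param spikes spike train (integer sample indices).
#' @param onsets stimulus onsets (integer sample indices).
#' @param fs sampling rate (Hz).
#' @param bin_ms bin width (ms).
#' @param window_ms latency window (ms).
#' @return tibble: bin_start_ms, bin_end_ms, count.
#' @export
psth <- function(spikes, onsets, fs, bin_ms = 0.25, window_ms = 10) {
  breaks <- seq(0, window_ms, by = bin_ms)
  counts <- integer(length(breaks) - 1L)
  spikes <- sort(as.integer(spikes))
  win <- ms_to_samples(window_ms, fs)
  for (on in as.integer(onsets)) {
    sel <- spikes[spikes >= on & spikes < on + win]
    if (length(sel) == 0) next
    lat <- (sel - on) / fs * 1e3
    counts <- counts + tabulate(findInterval(lat, breaks,
                                             rightmost.closed = FALSE),
                                nbins = length(counts))
  }
  tibble::tibble(bin_start_ms = breaks[-length(breaks)],
                 bin_end_ms = breaks[-1], count = counts)
}

#' Score one recovered signal against its ground truth
#'
#' The single-pair form of the benchmark: both signals are bandpass
#' filtered identically, spikes are detected on both with the same SWTTEO
#' parameters, and RMSE, jitter-matched FP/FN and the zero-lag
#' cross-correlation are reported.
#'
#' @param truth numeric ground-truth signal (microvolts).
#' @param recovered numeric suppressor output, same length.
#' @param fs sampling rate (Hz).
#' @param detect_args list of SWTTEO parameter overrides.
#' @return one-row tibble: rmse_uv, n_gt, n_det, fp_pct, fn_pct, c0.
#' @export
evaluate_pair <- function(truth, recovered, fs, detect_args = list()) {
  if (length(truth) != length(recovered))
    stop("evaluate_pair: length mismatch")
  tf <- bandpass(truth, fs)
  rf <- bandpass(recovered, fs)
  gt <- do.call(detect_spikes_swtteo, c(list(x = tf, fs = fs), detect_args))
  det <- do.call(detect_spikes_swtteo, c(list(x = rf, fs = fs), detect_args))
  ms <- match_spikes(gt, det, fs)
  tibble::tibble(rmse_uv = rmse(tf, rf), n_gt = ms$n_gt, n_det = ms$n_det,
                 fp_pct = ms$fp_pct, fn_pct = ms$fn_pct,
                 c0 = as.numeric(c0(gt, det, fs)))
}

#' Run suppressors over a benchmark set
#'
#' For every snippet and suppressor: clean the snippet (timed per artifact),
#' bandpass filter the output and the ground-truth basal signal identically,
#' detect spikes with SWTTEO using the same parameters on both, and score
#' RMSE, jitter-matched FP/FN, the zero-lag cross-correlation and blanking
#' statistics. Ground-truth spike trains are the detections on the filtered
#' basal signal, so a perfect reconstruction scores FP = FN = 0 and C0 = 1.
#' Failures on a snippet are recorded as missing rows; the run continues.
#'
#' @param bench a `benchmark_set` (the snippets carry their ground truth).
#' @param methods character vector of suppressor names (see
#'   [get_suppressor()]) and/or `suppressor` objects.
#' @param cfg a [loglira_config()] used by the `loglira` method.
#' @param detect_args list of SWTTEO parameter overrides, applied to both
#'   ground truth and suppressor output.
#' @return object of class `benchmark_report`: tibble with one row per
#'   snippet x suppressor (snippet, suppressor, rmse_uv, fp_pct, fn_pct, c0,
#'   time_ms_per_artifact, median_blank_ms).
#' @export
run_benchmark <- function(bench, methods = c("loglira", "dynavg", "polyfit"),
                          cfg = loglira_config(), detect_args = list()) {
  stopifnot(inherits(bench, "benchmark_set"))
  sups <- lapply(methods, function(m) {
    if (inherits(m, "suppressor")) m
    else if (m == "loglira") get_suppressor("loglira", cfg = cfg)
    else get_suppressor(m)
  })
  rows <- list(); r <- 0L
  for (i in seq_len(nrow(bench$manifest))) {
    snip <- bench$snippets[[i]]
    fs <- snip$fs
    gt <- if (!is.null(snip$basal_signal)) snip$basal_signal else
      snip$signal - snip$artifact_track
    basal_filt <- bandpass(gt, fs)
    gt_train <- do.call(detect_spikes_swtteo,
                        c(list(x = basal_filt, fs = fs), detect_args))
    rec <- recording(snip$signal, fs, channel_id = bench$manifest$id[i])
    for (sup in sups) {
      r <- r + 1L
      rows[[r]] <- tryCatch({
        t0 <- proc.time()[["elapsed"]]
        res <- suppressWarnings(sup$clean(rec, snip$stims))
        dt_ms <- (proc.time()[["elapsed"]] - t0) * 1e3 / length(snip$stims)
        out_filt <- bandpass(res$recording$samples, fs)
        det <- do.call(detect_spikes_swtteo,
                       c(list(x = out_filt, fs = fs), detect_args))
        ms <- match_spikes(gt_train, det, fs)
        tibble::tibble(
          snippet = bench$manifest$id[i], suppressor = sup$name,
          rmse_uv = rmse(basal_filt, out_filt),
          fp_pct = ms$fp_pct, fn_pct = ms$fn_pct,
          c0 = as.numeric(c0(gt_train, det, fs)),
          time_ms_per_artifact = dt_ms,
          median_blank_ms = median(res$blanking$beta_ms))
      }, error = function(e) {
        warning(sprintf("benchmark: %s failed on %s: %s", sup$name,
                        bench$manifest$id[i], conditionMessage(e)))
        NULL
      })
    }
  }
  structure(dplyr::bind_rows(rows), class = c("benchmark_report",
                                              class(tibble::tibble())))
}

#' @exportS3Method generics::glance
glance.benchmark_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$suppressor),
    dplyr::across(c("rmse_uv", "fp_pct", "fn_pct", "c0",
                    "time_ms_per_artifact", "median_blank_ms"),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sd = ~sd(.x, na.rm = TRUE))),
    .groups = "drop")
}
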