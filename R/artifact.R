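# Stage 1: per-trial artifact shape estimation.
#
# Landmarks are stored as counts of samples from the trial start, so with
# 1-based R vectors the blanked region is 1:n_s, the recovery region is
# (n_s + 1):n_e, and everything after n_e is untouched.

#' Decide whether a trial holds an artifact transient
#'
#' Compares two windows (default 5 ms) taken immediately before the stimulus
#' onset and immediately after the default blanking period. When both mean
#' and standard deviation are similar — the mean difference within
#' `mean_k` pre-window SDs and the SD ratio inside `sd_ratio_range` — no
#' transient is assumed and only the minimum blanking is applied. Trials too
#' short to hold the post window (or lacking a usable pre window) are
#' conservatively treated as containing a transient.
#'
#' @param trial numeric trial segment (microvolts).
#' @param pre numeric samples immediately preceding the stimulus onset.
#' @param cfg a [loglira_config()].
#' @param fs sampling rate (Hz).
#' @return logical: `TRUE` if a transient is present.
#' @export
detect_transient <- function(trial, pre, cfg, fs) {
  w <- ms_to_samples(cfg$transient_window, fs)
  b0 <- ms_to_samples(cfg$beta0, fs)
  if (length(trial) < b0 + w) return(TRUE)          # degenerate length rule
  if (length(pre) < max(4L, w %/% 2L)) return(TRUE) # no usable pre window
  pre <- tail(pre, w)
  post <- trial[(b0 + 1L):(b0 + w)]
  m_ok <- abs(mean(post) - mean(pre)) <= cfg$mean_k * sd(pre)
  s_pre <- sd(pre); s_post <- sd(post)
  s_ok <- if (s_pre == 0 && s_post == 0) TRUE
          else if (s_pre == 0) FALSE
          else {
            r <- s_post / s_pre
            r >= cfg$sd_ratio_range[1] && r <= cfg$sd_ratio_range[2]
          }
  !(m_ok && s_ok)
}

# Centered moving average with edge truncation (shrinking window at the
# boundaries) — avoids the phase lag of a causal filter that would bias n_e.
moving_average <- function(x, width) {
  n <- length(x)
  half <- max(0L, as.integer(width) %/% 2L)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Locate the end of the artifact transient
#'
#' A centered 5 ms moving-average of the trial is compared with the median
#' steady-state value (computed from samples after the settling time); the
#' first post-blanking sample where the filtered trace enters a
#' `steady_tol` (1 microvolt) band around that median is the transient end
#' `n_e`. Trials shorter than the settling time return their last sample.
#'
#' @inheritParams detect_transient
#' @param n_s number of blanked samples (scan starts after it).
#' @return integer `n_e` (samples from trial start).
#' @export
find_transient_end <- function(trial, cfg, fs, n_s = 0L) {
  n <- length(trial)
  settle <- ms_to_samples(cfg$settling_time, fs)
  if (n <= settle) return(n)
  med <- median(trial[(settle + 1L):n])
  ma <- moving_average(trial, ms_to_samples(cfg$transient_window, fs))
  from <- min(n, max(n_s + 1L, 1L))
  hit <- which(abs(ma[from:n] - med) < cfg$steady_tol)
  if (length(hit) == 0) n else from + hit[1L] - 1L
}

# Saturation thresholds for a channel: per-side 95% of the amplifier
# operating range, or 95% of the channel's maximum absolute voltage when the
# range is unknown (whole channel, not per trial).
saturation_bounds <- function(samples, amp_limits, sat_fraction) {
  if (!is.null(amp_limits)) {
    c(lo = sat_fraction * amp_limits[1], hi = sat_fraction * amp_limits[2])
  } else {
    m <- max(abs(samples))
    c(lo = -sat_fraction * m, hi = sat_fraction * m)
  }
}

#' Find the recovery start and actual blanking period
#'
#' The recovery starts at the first sample after the default blanking
#' interval or, when saturation persists beyond it, after the last saturated
#' sample (multiple saturated stretches are concatenated). Saturation is any
#' sample at or beyond `sat_fraction` of the operating limit.
#'
#' @inheritParams detect_transient
#' @param sat_bounds length-2 numeric `c(lo, hi)` saturation thresholds from
#'   `saturation_bounds()`.
#' @return list with `n_s` (blanked samples), `beta_ms` and `saturated`.
#' @export
find_recovery_start <- function(trial, cfg, fs, sat_bounds) {
  b0 <- min(ms_to_samples(cfg$beta0, fs), length(trial))
  sat <- which(trial <= sat_bounds[["lo"]] | trial >= sat_bounds[["hi"]])
  saturated <- length(sat) > 0 && max(sat) > b0
  n_s <- if (saturated) max(sat) else b0
  n_s <- min(n_s, length(trial))
  list(n_s = as.integer(n_s), beta_ms = n_s / fs * 1e3, saturated = saturated)
}

#' Build the logarithmic interpolation grid
#'
#' Grid times follow `t_j = 10^(j/(P-1) * log10(T)) - 1` for
#' `j = 0, ..., P-1`, spanning 0 to `T - 1` ms, then convert to samples as
#' `round(t_j * 1e-3 * fs)`, shift right by the blanking interval and drop
#' points at or beyond the transient end. Duplicate sample indices arising
#' from rounding are collapsed.
#'
#' @param cfg a [loglira_config()].
#' @param fs sampling rate (Hz).
#' @param n_s blanked samples (grid shift).
#' @param n_e transient end (samples); points beyond it are discarded.
#' @return list of class `log_grid` with `t_ms` (all P grid times), `nodes`
#'   (retained 1-based sample indices within the trial) and `eps`
#'   (neighbourhood half-width schedule, in samples).
#' @export
build_log_grid <- function(cfg, fs, n_s = 0L, n_e = Inf) {
  j <- 0:(cfg$P - 1L)
  t_ms <- 10^(j / (cfg$P - 1L) * log10(cfg$T_ms)) - 1
  n_j <- as.integer(round(t_ms * 1e-3 * fs))
  nodes <- unique(n_j + as.integer(n_s) + 1L)  # 1-based sample indices
  nodes <- nodes[nodes <= n_e]                 # keep nodes inside [n_s, n_e)
  eps <- integer(length(nodes))
  if (length(nodes) >= 2) {
    d <- diff(nodes)
    for (k in seq_along(nodes)) {
      if (k == 1L) {
        e <- d[1L]
      } else if (k == length(nodes)) {
        e <- d[length(d)]
      } else {
        e <- min((nodes[k + 1L] - nodes[k - 1L]) %/% 2L, cfg$eps_cap * d[k])
      }
      eps[k] <- as.integer(max(0L, e))
    }
  }
  structure(list(t_ms = t_ms, nodes = nodes, eps = eps,
                 n_s = as.integer(n_s),
                 n_e = if (is.finite(n_e)) as.integer(n_e) else NA_integer_),
            class = "log_grid")
}

#' Mean signal value in a grid-point neighbourhood
#'
#' Arithmetic mean of the samples within `eps/2` of the grid node, clipped to
#' the recovery region.
#'
#' @param trial numeric trial segment.
#' @param node 1-based sample index of the grid point.
#' @param eps neighbourhood width (samples); `eps = 0` returns the sample.
#' @param lo,hi 1-based bounds of the recovery region used for clipping.
#' @return mean voltage (microvolts).
#' @export
neighborhood_mean <- function(trial, node, eps, lo = 1L, hi = length(trial)) {
  half <- as.integer(eps) %/% 2L
  idx <- (node - half):(node + half)
  idx <- idx[idx >= lo & idx <= hi]
  if (length(idx) == 0) stop("neighborhood_mean: empty neighbourhood")
  mean(trial[idx])
}

#' Estimate the artifact waveform of one trial
#'
#' The artifact estimate equals the raw trial over the blanked region, the
#' piecewise-linear interpolant through the neighbourhood means `g(n_j)` over
#' the recovery region, and zero beyond the transient end (so subtraction
#' leaves that region untouched).
#'
#' @param trial numeric trial segment.
#' @param grid a `log_grid` from [build_log_grid()].
#' @param n_s,n_e landmarks (samples from trial start).
#' @return list of class `trial_fit`: `artifact` (same length as the trial),
#'   `n_s`, `n_e`, `beta_ms`, `g` (node values), plus flags filled in by the
#'   caller.
#' @export
estimate_artifact <- function(trial, grid, n_s, n_e) {
  n <- length(trial)
  if (length(grid$nodes) == 0) stop("estimate_artifact: empty grid")
  art <- numeric(n)
  if (n_s >= 1) art[1:n_s] <- trial[1:n_s]  # blanked portion pasted as-is
  g <- vapply(seq_along(grid$nodes), function(k) {
    neighborhood_mean(trial, grid$nodes[k], grid$eps[k],
                      lo = n_s + 1L, hi = n_e)
  }, numeric(1))
  if (n_e > n_s) {
    xs <- (n_s + 1L):n_e
    if (length(grid$nodes) == 1L) {
      art[xs] <- g[1L]
    } else {
      art[xs] <- approx(grid$nodes, g, xout = xs, rule = 2)$y
    }
  }
  structure(list(artifact = art, n_s = as.integer(n_s), n_e = as.integer(n_e),
                 beta_ms = NA_real_, g = g, nodes = grid$nodes,
                 transient = TRUE, saturated = FALSE),
            class = "trial_fit")
}

#' Subtract the artifact estimate and bridge the discontinuities
#'
#' The artifact estimate is subtracted from the trial; then a line is traced
#' from the sample preceding the stimulation onset to the sample following
#' the transient end, and the recovered segment is superimposed on that line
#' so the output is continuous at both ends. The blanked region carries the
#' bridging line alone.
#'
#' @param trial numeric trial segment.
#' @param fit a `trial_fit` from [estimate_artifact()] (or a blank-only fit).
#' @param pre_value voltage of the sample immediately preceding the onset;
#'   defaults to the first post-bridge anchor when unavailable.
#' @return numeric clean trial, same length.
#' @export
subtract_and_bridge <- function(trial, fit, pre_value = NULL) {
  n <- length(trial)
  n_e <- min(fit$n_e, n)
  clean <- trial - fit$artifact
  anchor_r <- if (n_e < n) trial[n_e + 1L] else trial[n]
  anchor_l <- if (is.null(pre_value) || !is.finite(pre_value)) anchor_r else pre_value
  if (n_e >= 1) {
    # line from position 0 (pre-onset sample) to position n_e + 1
    line <- anchor_l + (anchor_r - anchor_l) * (1:n_e) / (n_e + 1)
    clean[1:n_e] <- clean[1:n_e] + line
  }
  clean
}

# Blank-only fit: paste the raw signal over the first n_s samples so that
# subtraction zeroes the blank and bridging fills it with the line.
blank_only_fit <- function(trial, n_s, beta_ms, transient, saturated) {
  art <- numeric(length(trial))
  n_s <- min(n_s, length(trial))
  if (n_s >= 1) art[1:n_s] <- trial[1:n_s]
  structure(list(artifact = art, n_s = as.integer(n_s),
                 n_e = as.integer(n_s), beta_ms = beta_ms, g = numeric(0),
                 nodes = integer(0), transient = transient,
                 saturated = saturated),
            class = "trial_fit")
}

# Full stage-1 treatment of one trial. Returns list(clean, fit).
clean_trial <- function(trial, pre, cfg, fs, sat_bounds) {
  b0 <- min(ms_to_samples(cfg$beta0, fs), length(trial))
  if (!detect_transient(trial, pre, cfg, fs)) {
    fit <- blank_only_fit(trial, b0, b0 / fs * 1e3,
                          transient = FALSE, saturated = FALSE)
    return(list(clean = subtract_and_bridge(trial, fit, tail(pre, 1)),
                fit = fit))
  }
  rs <- find_recovery_start(trial, cfg, fs, sat_bounds)
  n_e <- find_transient_end(trial, cfg, fs, n_s = rs$n_s)
  n_e <- max(n_e, rs$n_s)
  grid <- build_log_grid(cfg, fs, rs$n_s, n_e)
  if (rs$n_s >= length(trial) || n_e <= rs$n_s || length(grid$nodes) == 0) {
    # fully saturated or degenerate: blanking-only treatment
    fit <- blank_only_fit(trial, rs$n_s, rs$beta_ms,
                          transient = TRUE, saturated = rs$saturated)
    return(list(clean = subtract_and_bridge(trial, fit, tail(pre, 1)),
                fit = fit))
  }
  fit <- estimate_artifact(trial, grid, rs$n_s, n_e)
  fit$beta_ms <- rs$beta_ms
  fit$saturated <- rs$saturated
  list(clean = subtract_and_bridge(trial, fit, tail(pre, 1)), fit = fit)
}

#' Suppress stimulation artifacts from a whole channel
#'
#' Runs the two-stage pipeline: each stimulus artifact is addressed
#' individually — transient detection, dynamic blanking with saturation
#' handling, artifact estimation on the logarithmic grid, subtraction and
#' bridging — and then the post-blanking windows of all trials are clustered
#' so that deterministic residual (secondary) artifacts can be removed by
#' cluster-mean subtraction (skipped when fewer than `theta` trials exist).
#' Samples before the first onset pass through untouched.
#'
#' @param rec a [recording()].
#' @param stims a [stim_train()]; an empty train returns the input unchanged.
#' @param cfg a [loglira_config()].
#' @param secondary run the secondary-artifact mitigation stage.
#' @return an object of class `loglira_result`: list with `recording` (clean
#'   [recording()]), `fits` (tibble of per-trial metadata: trial, onset,
#'   beta_ms, n_s, n_e, transient, saturated), `secondary` (diagnostics from
#'   the mitigation stage or `NULL`) and `config`.
#' @export
loglira_clean <- function(rec, stims, cfg = loglira_config(),
                          secondary = TRUE) {
  stopifnot(inherits(rec, "recording"))
  if (length(stims) == 0) {
    return(structure(list(recording = rec,
                          fits = empty_fit_table(),
                          secondary = NULL, config = cfg),
                     class = "loglira_result"))
  }
  ts <- segment_trials(rec, stims)
  fs <- rec$fs
  sat_bounds <- saturation_bounds(rec$samples, rec$amp_limits, cfg$sat_fraction)
  w_pre <- ms_to_samples(cfg$transient_window, fs)
  K <- length(ts$trials)
  clean_trials <- vector("list", K)
  fits <- vector("list", K)
  for (i in seq_len(K)) {
    on <- ts$onsets[i]
    pre <- if (on > 1L) rec$samples[max(1L, on - w_pre):(on - 1L)] else numeric(0)
    res <- tryCatch(
      clean_trial(ts$trials[[i]], pre, cfg, fs, sat_bounds),
      error = function(e) {
        warning(sprintf("trial %d left unmodified: %s", i, conditionMessage(e)))
        list(clean = ts$trials[[i]],
             fit = blank_only_fit(ts$trials[[i]], 0L, 0, FALSE, FALSE))
      })
    clean_trials[[i]] <- res$clean
    fits[[i]] <- res$fit
  }
  sec <- NULL
  if (secondary && K >= cfg$theta) {
    mit <- mitigate_secondary(clean_trials, fits, cfg, fs)
    clean_trials <- mit$trials
    sec <- mit$diagnostics
  }
  out <- rec
  out$samples <- c(ts$prefix, unlist(clean_trials, use.names = FALSE))
  structure(
    list(recording = out,
         fits = tibble::tibble(
           trial = seq_len(K),
           onset = ts$onsets,
           beta_ms = vapply(fits, `[[`, numeric(1), "beta_ms"),
           n_s = vapply(fits, `[[`, integer(1), "n_s"),
           n_e = vapply(fits, `[[`, integer(1), "n_e"),
           transient = vapply(fits, `[[`, logical(1), "transient"),
           saturated = vapply(fits, `[[`, logical(1), "saturated")),
         secondary = sec, config = cfg),
    class = "loglira_result"
  )
}

empty_fit_table <- function() {
  tibble::tibble(trial = integer(0), onset = integer(0),
                 beta_ms = numeric(0), n_s = integer(0), n_e = integer(0),
                 transient = logical(0), saturated = logical(0))
}

#' @export
print.loglira_result <- function(x, ...) {
  cat(sprintf("<loglira_result: %d trials, median blanking %.2f ms, %d with transient, %d saturated>\n",
              nrow(x$fits),
              if (nrow(x$fits)) median(x$fits$beta_ms) else NA_real_,
              sum(x$fits$transient), sum(x$fits$saturated)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.loglira_result <- function(x, ...) x$fits

#' @exportS3Method generics::glance
glance.loglira_result <- function(x, ...) {
  tibble::tibble(
    k_trials = nrow(x$fits),
    median_beta_ms = if (nrow(x$fits)) median(x$fits$beta_ms) else NA_real_,
    n_transient = sum(x$fits$transient),
    n_saturated = sum(x$fits$saturated),
    n_clusters = if (is.null(x$secondary)) 0L else length(x$secondary$retained)
  )
}
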