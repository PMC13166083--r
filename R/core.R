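#' loglira: stimulation-artifact suppression for short-latency spike recovery
#'
#' Tools to remove intracortical-microstimulation (ICMS) artifacts from
#' single-channel extracellular recordings one stimulus at a time, plus the
#' semisynthetic benchmark machinery (ground-truth basal activity, artifact
#' template dictionaries, snippet synthesis) and evaluation metrics used to
#' compare artifact-suppression algorithms.
#'
#' @keywords internal
#' @importFrom stats approx cor density filter lm.fit median poly quantile
#'   rgamma rlnorm rnorm runif sd setNames
#' @importFrom utils head tail
#' @importFrom rlang .data
"_PACKAGE"

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Convert a duration in milliseconds to samples
#'
#' All durations in the package are configured in milliseconds and converted
#' to samples as `round(ms * 1e-3 * fs)`, keeping behaviour consistent across
#' acquisition systems with different sampling rates.
#'
#' @param ms duration in milliseconds.
#' @param fs sampling rate in Hz.
#' @return integer number of samples.
#' @export
ms_to_samples <- function(ms, fs) {
  as.integer(round(ms * 1e-3 * fs))
}

#' Continuous single-channel recording
#'
#' @param samples numeric voltage series in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param amp_limits optional length-2 numeric `c(lower, upper)` amplifier
#'   operating range in microvolts (`lower < upper`). Used for saturation
#'   detection; when absent the saturation threshold falls back to a fraction
#'   of the channel's maximum absolute voltage.
#' @param channel_id opaque channel label.
#' @return an object of class `recording`.
#' @export
recording <- function(samples, fs, amp_limits = NULL, channel_id = "ch0") {
  samples <- as.numeric(samples)
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  if (!is.null(amp_limits)) {
    stopifnot(length(amp_limits) == 2, amp_limits[1] < amp_limits[2])
    ok <- is.finite(samples)
  } else {
    ok <- is.finite(samples)
  }
  if (!all(ok)) stop("recording: samples must be finite")
  structure(
    list(samples = samples, fs = fs, amp_limits = amp_limits,
         channel_id = channel_id),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording '%s': %d samples @ %g Hz (%.2f s)%s>\n",
              x$channel_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$amp_limits)) ""
              else sprintf(", limits [%g, %g] uV",
                           x$amp_limits[1], x$amp_limits[2])))
  invisible(x)
}

#' @export
length.recording <- function(x) length(x$samples)

#' Stimulation onset train
#'
#' @param onsets strictly increasing stimulus onset sample indices (1-based).
#' @param n_samples optional recording length for bounds checking.
#' @return an object of class `stim_train` (integer vector with attributes).
#' @export
stim_train <- function(onsets, n_samples = NULL) {
  onsets <- as.integer(onsets)
  if (length(onsets) == 0) stop("stim_train: empty onset list")
  if (any(diff(onsets) <= 0)) stop("stim_train: onsets must be strictly increasing")
  if (any(onsets < 1)) stop("stim_train: onsets must be >= 1")
  if (!is.null(n_samples) && any(onsets > n_samples)) {
    stop("stim_train: onset beyond recording end")
  }
  structure(onsets, class = "stim_train")
}

#' @export
print.stim_train <- function(x, ...) {
  cat(sprintf("<stim_train: K = %d stimuli, first @ %d>\n",
              length(x), unclass(x)[1]))
  invisible(x)
}

#' Inter-artifact intervals of a stimulus train
#'
#' Successive onset differences in seconds. The mean artifact rate (MAR) is
#' defined as the reciprocal of the median of these intervals.
#'
#' @param stims a [stim_train()] (or integer onset vector).
#' @param fs sampling rate in Hz.
#' @return numeric vector of length `K - 1`, all positive, in seconds.
#' @export
iai_of <- function(stims, fs) {
  onsets <- as.integer(stims)
  if (length(onsets) < 2) stop("iai_of: need at least 2 onsets")
  diff(onsets) / fs
}

#' Mean artifact rate of a stimulus train
#'
#' @inheritParams iai_of
#' @return MAR in Hz: `1 / median(IAI)`.
#' @export
mar_of <- function(stims, fs) 1 / median(iai_of(stims, fs))

#' Segment a recording into per-stimulus trials
#'
#' Trial `i` spans from onset `i` up to (but excluding) onset `i + 1`; the
#' last trial runs to the end of the recording. Concatenating the
#' pre-first-onset prefix with all trials reconstructs the recording exactly.
#'
#' @param rec a [recording()].
#' @param stims a [stim_train()].
#' @return an object of class `trial_set`: list with `trials` (list of K
#'   numeric vectors), `lengths`, `onsets`, `prefix` (samples before the first
#'   onset) and `fs`.
#' @export
segment_trials <- function(rec, stims) {
  stopifnot(inherits(rec, "recording"))
  onsets <- as.integer(stims)
  n <- length(rec$samples)
  if (length(onsets) == 0) stop("segment_trials: empty onset list")
  if (any(onsets > n)) stop("segment_trials: onset beyond recording end")
  if (any(diff(onsets) <= 0)) stop("segment_trials: onsets not strictly increasing")
  ends <- c(onsets[-1] - 1L, n)
  trials <- lapply(seq_along(onsets), function(i) rec$samples[onsets[i]:ends[i]])
  structure(
    list(trials = trials,
         lengths = ends - onsets + 1L,
         onsets = onsets,
         prefix = if (onsets[1] > 1) rec$samples[1:(onsets[1] - 1L)] else numeric(0),
         fs = rec$fs),
    class = "trial_set"
  )
}

#' Reassemble a recording from a trial set
#'
#' Inverse of [segment_trials()]: prefix followed by all trials.
#'
#' @param ts a `trial_set`.
#' @return numeric vector of samples.
#' @export
rejoin_trials <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  c(ts$prefix, unlist(ts$trials, use.names = FALSE))
}

#' Algorithm configuration
#'
#' Tunable parameters of the artifact-suppression pipeline. Durations are in
#' milliseconds and converted to samples per channel sampling rate.
#'
#' @param beta0 default blanking period after each stimulus onset (ms).
#' @param P number of logarithmic interpolation grid points.
#' @param T_ms span of the grid: points cover 0 to `T_ms - 1` ms.
#' @param settling_time time after which the trial is assumed to have settled,
#'   used for the steady-state median (ms).
#' @param steady_tol tolerance for the moving-average/median intersection that
#'   marks the transient's end (microvolts).
#' @param sat_fraction saturation threshold as a fraction of the amplifier
#'   operating limit (or of the channel's maximum absolute voltage when the
#'   limit is unknown).
#' @param transient_window width of the pre/post windows compared to decide
#'   whether a trial holds an artifact transient (ms).
#' @param secondary_window width of the post-blanking window clustered during
#'   secondary-artifact mitigation (ms).
#' @param theta minimum cluster membership for a secondary-artifact cluster
#'   mean to be subtracted.
#' @param mean_k no-transient test: the pre/post window means must differ by
#'   at most `mean_k` pre-window standard deviations.
#' @param sd_ratio_range no-transient test: allowed post/pre standard
#'   deviation ratio.
#' @param eps_cap cap on the interpolation neighbourhood half-width, as a
#'   multiple of the local grid spacing.
#' @param saddle_ratio density-based merging: two density modes are merged
#'   when their separating saddle density exceeds this fraction of the lower
#'   peak.
#' @param include_no_transient include windows from trials without a detected
#'   transient in the secondary-artifact clustering.
#' @param seed random seed recorded with results (the pipeline itself is
#'   deterministic).
#' @return an object of class `loglira_config`.
#' @export
loglira_config <- function(beta0 = 1, P = 42L, T_ms = 50, settling_time = 40,
                           steady_tol = 1, sat_fraction = 0.95,
                           transient_window = 5, secondary_window = 2,
                           theta = 20L, mean_k = 2, sd_ratio_range = c(0.5, 2),
                           eps_cap = 2, saddle_ratio = 0.5,
                           include_no_transient = TRUE, seed = 1L) {
  stopifnot(P >= 2, T_ms > 1, sat_fraction > 0, sat_fraction <= 1, theta >= 1,
            beta0 > 0, settling_time > 0, transient_window > 0,
            secondary_window > 0, steady_tol > 0,
            length(sd_ratio_range) == 2, sd_ratio_range[1] < sd_ratio_range[2])
  structure(
    list(beta0 = beta0, P = as.integer(P), T_ms = T_ms,
         settling_time = settling_time, steady_tol = steady_tol,
         sat_fraction = sat_fraction, transient_window = transient_window,
         secondary_window = secondary_window, theta = as.integer(theta),
         mean_k = mean_k, sd_ratio_range = sd_ratio_range, eps_cap = eps_cap,
         saddle_ratio = saddle_ratio,
         include_no_transient = isTRUE(include_no_transient),
         seed = as.integer(seed)),
    class = "loglira_config"
  )
}

#' @export
print.loglira_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<loglira_config: beta0 = %g ms, P = %d, T = %g ms, theta = %d,\n",
    "  settling = %g ms, sat = %g, windows %g/%g ms>\n"),
    x$beta0, x$P, x$T_ms, x$theta, x$settling_time, x$sat_fraction,
    x$transient_window, x$secondary_window))
  invisible(x)
}
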