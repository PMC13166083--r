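test_that("transient detection separates matching-statistics windows from steps", {
  set.seed(2)
  # both windows i.i.d. noise from the same distribution: no transient
  pre <- rnorm(ms_to_samples(5, FS), sd = 4)
  trial <- rnorm(ms_to_samples(30, FS), sd = 4)
  expect_false(detect_transient(trial, pre, default_cfg, FS))

  # +200 uV step decaying over 20 ms after the blanking period: transient
  t_ms <- (seq_along(trial) - 1) / FS * 1e3
  expect_true(detect_transient(trial + 200 * exp(-t_ms / 8), pre,
                               default_cfg, FS))

  # degenerate short trial is conservatively treated as a transient
  expect_true(detect_transient(rnorm(ms_to_samples(3, 30000)), pre,
                               default_cfg, 30000))
})

test_that("transient end matches a brute-force moving-average scan", {
  # independently coded centered moving average + first-crossing scan
  oracle_ne <- function(trial, fs, n_s, settle_ms = 40, w_ms = 5, tol = 1) {
    n <- length(trial)
    settle <- round(settle_ms * 1e-3 * fs)
    if (n <= settle) return(n)
    med <- median(trial[(settle + 1):n])
    half <- floor(round(w_ms * 1e-3 * fs) / 2)
    ma <- vapply(seq_len(n), function(i) {
      mean(trial[max(1, i - half):min(n, i + half)])
    }, numeric(1))
    for (i in (n_s + 1):n) if (abs(ma[i] - med) < tol) return(i)
    n
  }
  trial <- 500 * exp(-(0:(ms_to_samples(60, FS) - 1)) / FS * 1e3 / 2)
  n_s <- ms_to_samples(1, FS)
  expect_equal(find_transient_end(trial, default_cfg, FS, n_s),
               oracle_ne(trial, FS, n_s))

  # trial shorter than the settling time: n_e is the last sample
  short <- 500 * exp(-(0:(ms_to_samples(30, FS) - 1)) / FS * 1e3 / 2)
  expect_equal(find_transient_end(short, default_cfg, FS, n_s), length(short))

  # constant trial is already at its median right after the scan start
  expect_equal(find_transient_end(rep(3, ms_to_samples(60, FS)),
                                  default_cfg, FS, n_s), n_s + 1L)
})

test_that("recovery start extends blanking over concatenated saturated stretches", {
  fs <- FS
  b0 <- ms_to_samples(1, fs)
  sb <- c(lo = -0.95 * 5000, hi = 0.95 * 5000)
  n <- ms_to_samples(20, fs)

  # no saturation: n_s at the default blanking, beta = 1 ms
  quiet <- rep(10, n)
  rs <- find_recovery_start(quiet, default_cfg, fs, sb)
  expect_equal(rs$n_s, b0)
  expect_equal(rs$beta_ms, 1)
  expect_false(rs$saturated)

  # plateau over 0-3 ms: first non-saturated sample ~3 ms
  plat <- quiet
  plat[1:ms_to_samples(3, fs)] <- 5000
  rs2 <- find_recovery_start(plat, default_cfg, fs, sb)
  expect_equal(rs2$n_s, ms_to_samples(3, fs))
  expect_equal(rs2$beta_ms, 3)
  expect_true(rs2$saturated)

  # stretches at 0-1.5 ms and 2-2.5 ms concatenate: n_s after 2.5 ms
  two <- quiet
  two[1:ms_to_samples(1.5, fs)] <- -5000
  two[ms_to_samples(2, fs):ms_to_samples(2.5, fs)] <- 5000
  rs3 <- find_recovery_start(two, default_cfg, fs, sb)
  expect_equal(rs3$n_s, ms_to_samples(2.5, fs))

  # whole trial saturated: fully blanked and flagged
  rs4 <- find_recovery_start(rep(5000, n), default_cfg, fs, sb)
  expect_equal(rs4$n_s, n)
  expect_true(rs4$saturated)
})

test_that("logarithmic grid matches its defining equations", {
  g <- build_log_grid(default_cfg, FS)
  expect_length(g$t_ms, 42)
  expect_equal(g$t_ms[1], 0)
  expect_equal(g$t_ms[42], 49)
  expect_true(all(diff(g$t_ms) > 0))

  g2 <- build_log_grid(loglira_config(P = 2, T_ms = 10), FS)
  expect_equal(g2$t_ms, c(0, 9))

  # 0.5 ms at 30 kHz converts to 15 samples before shifting
  expect_equal(round(0.5 * 1e-3 * 30000), 15)

  # consecutive node spacing is non-decreasing (log spacing: denser early);
  # exact on the millisecond grid, within one sample after rounding
  expect_true(all(diff(diff(g$t_ms)) > 0))
  g3 <- build_log_grid(default_cfg, 30000, n_s = 30L, n_e = 1500L)
  expect_true(all(diff(diff(g3$nodes)) >= -1))

  # shift and truncation keep all nodes inside the recovery region
  expect_true(all(g3$nodes >= 31 & g3$nodes <= 1500))
})

test_that("neighbourhood means reduce to the sample, the constant, and the ramp centre", {
  expect_equal(neighborhood_mean(rep(7, 100), 50, 0), 7)
  expect_equal(neighborhood_mean(rep(7, 100), 50, 8), 7)
  s <- as.numeric(1:100)            # brute force over {8..12} gives 10
  expect_equal(neighborhood_mean(s, 10, 8), mean(8:12))
  expect_equal(neighborhood_mean(s, 10, 0), 10)
  expect_error(neighborhood_mean(s, 10, 0, lo = 50, hi = 60), "empty")
})

test_that("piecewise-linear trials over the grid nodes are reproduced exactly", {
  n_s <- 20L; n_e <- 900L
  g <- build_log_grid(default_cfg, FS, n_s, n_e)
  g$eps[] <- 0L
  set.seed(4)
  trial <- approx(g$nodes, rnorm(length(g$nodes), sd = 100), xout = 1:1000,
                  rule = 2)$y
  fit <- estimate_artifact(trial, g, n_s, n_e)
  expect_lt(max(abs((trial - fit$artifact)[(n_s + 1):n_e])), 1e-9)

  # constant trial: estimate equals the constant, residual zero
  fitc <- estimate_artifact(rep(42, 1000), build_log_grid(default_cfg, FS, n_s, n_e),
                            n_s, n_e)
  expect_lt(max(abs((rep(42, 1000) - fitc$artifact)[(n_s + 1):n_e])), 1e-9)
})

test_that("artifact estimate preserves the raw blank and leaves the tail untouched", {
  n_s <- 20L; n_e <- 600L
  trial <- make_artifact(1000) + make_noise(1000, seed = 9)
  g <- build_log_grid(default_cfg, FS, n_s, n_e)
  fit <- estimate_artifact(trial, g, n_s, n_e)
  expect_identical(fit$artifact[1:n_s], trial[1:n_s])
  expect_true(all(fit$artifact[(n_e + 1):1000] == 0))
})

test_that("subtraction with bridging is continuous and spans the stated endpoints", {
  # zero trial stays zero
  z <- numeric(500)
  fitz <- estimate_artifact(z, build_log_grid(default_cfg, FS, 20L, 400L), 20L, 400L)
  expect_equal(subtract_and_bridge(z, fitz, 0), z)

  # pure two-point line: pre-onset 10 uV, post-n_e -10 uV
  n <- 500L; n_e <- 400L
  tr <- numeric(n); tr[(n_e + 1):n] <- -10
  fit <- estimate_artifact(tr, build_log_grid(default_cfg, FS, 20L, n_e), 20L, n_e)
  out <- subtract_and_bridge(tr, fit, pre_value = 10)
  line <- 10 + (-10 - 10) * (1:n_e) / (n_e + 1)
  expect_equal(out[1:n_e], line, tolerance = 1e-9)
  expect_identical(out[(n_e + 1):n], tr[(n_e + 1):n])

  # a step at n_e is smoothed to noise-floor first differences
  set.seed(11)
  noise <- make_noise(2000, seed = 11)
  art <- make_artifact(2000)
  trial <- art + noise
  res <- loglira:::clean_trial(trial, make_noise(100, seed = 12),
                               default_cfg, FS, c(lo = -1e6, hi = 1e6))
  d <- abs(diff(res$clean))
  near_ne <- (res$fit$n_e - 5):(res$fit$n_e + 5)
  expect_lt(max(d[near_ne]), 10 * max(abs(diff(noise))))
})

test_that("artifact-free recordings are modified only inside the default blanks", {
  set.seed(5)
  n <- 3 * FS
  rec <- recording(make_noise(n, seed = 5), FS)
  onsets <- as.integer(seq(0.5, 2.5, by = 0.25) * FS)
  res <- loglira_clean(rec, stim_train(onsets, n), secondary = FALSE)
  expect_false(any(res$fits$transient))
  expect_equal(res$fits$beta_ms, rep(1, length(onsets)))
  b0 <- ms_to_samples(1, FS)
  touched <- unlist(lapply(onsets, function(o) o:(o + b0 - 1L)))
  expect_identical(res$recording$samples[-touched], rec$samples[-touched])
})

test_that("an empty stimulus train leaves the recording identical", {
  rec <- recording(make_noise(1000), FS)
  res <- loglira_clean(rec, integer(0))
  expect_identical(res$recording$samples, rec$samples)
  expect_equal(nrow(res$fits), 0)
})

test_that("inserted spikes on a smooth artifact survive cleaning", {
  # spike preservation: spikes >= 5 ms post-onset recovered with bounded
  # amplitude error and preserved detectability, checked over many trials
  set.seed(21)
  fs <- FS
  n_trials <- 120
  trial_len <- ms_to_samples(80, fs)
  proto <- loglira:::spike_prototype(fs, shape = 1)
  pk <- which.min(proto)
  sig <- make_noise(n_trials * trial_len + fs, seed = 21)
  onsets <- (seq_len(n_trials) - 1L) * trial_len + fs %/% 2L
  spike_times <- integer(n_trials)
  for (i in seq_len(n_trials)) {
    o <- onsets[i]
    idx <- o:(o + trial_len - 1L)
    sig[idx] <- sig[idx] + make_artifact(trial_len, fs)
    lat <- ms_to_samples(runif(1, 5, 40), fs)
    spike_times[i] <- o + lat
    sidx <- spike_times[i] - pk + seq_along(proto)
    sig[sidx] <- sig[sidx] + 80 * proto
  }
  rec <- recording(sig, fs)
  res <- loglira_clean(rec, stim_train(onsets, length(sig)))
  # amplitude at the spike peaks is preserved within half the spike height
  amp_err <- abs(res$recording$samples[spike_times] - sig[spike_times] +
                   make_artifact(trial_len, fs)[spike_times - onsets + 1L])
  expect_lt(median(amp_err), 40)
  det <- detect_spikes_swtteo(bandpass(res$recording$samples, fs), fs)
  m <- match_spikes(spike_times, det, fs)
  expect_gt(m$matched / n_trials, 0.9)
})
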