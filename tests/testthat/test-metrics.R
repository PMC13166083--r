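test_that("the bandpass filter is zero-phase with the stated band", {
  fs <- FS
  n <- fs
  t <- seq_len(n) / fs
  # DC is strongly attenuated
  dc <- bandpass(rep(100, n), fs)
  expect_lt(max(abs(dc[2000:(n - 2000)])), 100 * 10^(-60 / 20))
  # a 1 kHz sinusoid passes with its amplitude preserved
  s <- sin(2 * pi * 1000 * t)
  out <- bandpass(s, fs)
  expect_equal(max(abs(out[2000:(n - 2000)])), 1, tolerance = 0.05)
  # impulse response is symmetric around the impulse (zero phase)
  imp <- numeric(n); imp[n / 2] <- 1
  h <- bandpass(imp, fs)
  k <- 200
  expect_equal(h[(n / 2 - k):(n / 2 - 1)], rev(h[(n / 2 + 1):(n / 2 + k)]),
               tolerance = 1e-6)
  expect_warning(bandpass(rnorm(1000), 10000), "upper cutoff")
})

test_that("spike detection finds high-SNR spikes, is deterministic and quiet on silence", {
  fs <- FS
  expect_length(detect_spikes_swtteo(numeric(fs), fs), 0)

  noise <- make_noise(2 * fs, fs, 4, seed = 1)
  proto <- loglira:::spike_prototype(fs, shape = 1)
  pk <- which.min(proto)
  times <- as.integer(seq(0.15, 1.95, by = 0.2) * fs)
  sig <- noise
  for (t0 in times) {
    idx <- t0 - pk + seq_along(proto)
    sig[idx] <- sig[idx] + 80 * proto
  }
  det <- detect_spikes_swtteo(bandpass(sig, fs), fs)
  m <- match_spikes(times, det, fs)
  expect_equal(m$matched, 10L)
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)
  expect_identical(as.integer(detect_spikes_swtteo(bandpass(sig, fs), fs)),
                   as.integer(det))
})

test_that("rmse follows its formula and behaves as a metric", {
  expect_equal(rmse(1:10, 1:10), 0)
  expect_equal(rmse(rep(0, 4), rep(5, 4)), 5)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_error(rmse(1:3, 1:4), "length")
  # brute-force oracle on random pairs + symmetry + triangle inequality
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(100); y <- rnorm(100); z <- rnorm(100)
    expect_equal(rmse(x, y), sqrt(mean((x - y)^2)))
    expect_equal(rmse(x, y), rmse(y, x))
    expect_lte(rmse(x, z), rmse(x, y) + rmse(y, z) + 1e-12)
  }
})

test_that("spike matching respects the jitter window and conserves counts", {
  fs <- FS
  gt <- as.integer(c(1000, 3000, 5000, 9000))
  m0 <- match_spikes(gt, gt, fs)
  expect_equal(c(m0$fp, m0$fn), c(0L, 0L))

  # 0.1 ms shift stays within the +/-0.2 ms window
  m1 <- match_spikes(gt, gt + ms_to_samples(0.1, fs), fs)
  expect_equal(c(m1$fp, m1$fn), c(0L, 0L))

  # 0.5 ms shift falls outside: one FP and one FN
  m2 <- match_spikes(1000L, 1000L + ms_to_samples(0.5, fs), fs)
  expect_equal(c(m2$fp, m2$fn), c(1L, 1L))

  # conservation: matched + FP = detections, matched + FN = ground truth
  set.seed(43)
  gt3 <- sort(sample.int(10 * fs, 200))
  det3 <- sort(sample.int(10 * fs, 150))
  m3 <- match_spikes(gt3, det3, fs)
  expect_equal(m3$matched + m3$fp, 150L)
  expect_equal(m3$matched + m3$fn, 200L)

  # empty ground truth: percentages undefined but counts intact
  me <- match_spikes(integer(0), det3, fs)
  expect_true(is.na(me$fp_pct))
  expect_equal(me$fp, 150L)
})

test_that("the zero-lag cross-correlation honours its identities", {
  fs <- 50000
  set.seed(44)
  x <- sort(sample.int(10 * fs, 100))
  expect_equal(as.numeric(c0(x, x, fs)), 1)
  # disjoint trains (all gaps above the window) score zero
  y <- x + ms_to_samples(5, fs)
  expect_equal(as.numeric(c0(x, y, fs)), 0)
  # 4 events vs 1, a single coincidence: 1/sqrt(4) = 0.5
  expect_equal(as.numeric(c0(c(1000, 5000, 9000, 13000), 1000, fs)), 0.5)
  # symmetry of the coincidence count
  set.seed(45)
  a <- sort(sample.int(fs, 50)); b <- sort(sample.int(fs, 70))
  expect_equal(as.numeric(c0(a, b, fs)), as.numeric(c0(b, a, fs)))
  # empty train: zero with a flag
  z <- c0(integer(0), x, fs)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "empty"))
})

test_that("the coincidence window is 0.4 ms wide, recovered behaviourally", {
  fs <- 50000
  x <- as.integer(seq(1000, 400000, by = 4000))
  shifts <- 1:15
  scores <- vapply(shifts, function(s) as.numeric(c0(x, x + s, fs)), numeric(1))
  full <- max(shifts[scores >= 1])
  expect_equal(2 * full / fs * 1e3, 0.4)
})

test_that("the PSTH bins latencies at 0.25 ms and conserves counts", {
  fs <- FS
  onsets <- as.integer(seq(1, 100) * 2000)
  h0 <- psth(integer(0), onsets, fs)
  expect_true(all(h0$count == 0))

  # one spike at 1.1 ms latency in every trial lands in the [1.0, 1.25) bin
  spikes <- onsets + ms_to_samples(1.1, fs)
  h <- psth(spikes, onsets, fs)
  expect_equal(h$count[h$bin_start_ms == 1.0], 100)
  expect_equal(sum(h$count), 100)
})

test_that("the harness scores a perfect and an identity suppressor correctly", {
  fs <- FS
  basal <- gen_basal(duration = 5, fs = fs, mfr_target = 15, seed = 51)
  ch <- make_dict_channel(120, seed = 51)
  dict <- build_dictionary(ch$rec, ch$stims, seed = 51)
  snip <- synthesize_snippet(dict, basal, mar_target = 8, duration = 5,
                             seed = 52)

  # artifact-free snippet: identity reconstructs perfectly
  free <- snip
  free$signal <- snip$signal - snip$artifact_track
  free$artifact_track <- numeric(length(snip$signal))
  bench <- structure(list(
    manifest = tibble::tibble(id = c("free", "art")),
    snippets = list(free, snip), fs = fs, duration = 5, seed = 1),
    class = "benchmark_set")
  rep <- run_benchmark(bench, methods = "identity")
  expect_equal(nrow(rep), 2)
  perfect <- rep[rep$snippet == "free", ]
  expect_equal(perfect$rmse_uv, 0)
  expect_equal(perfect$fp_pct, 0)
  expect_equal(perfect$fn_pct, 0)
  expect_equal(perfect$c0, 1)
  # with artifacts left in, the identity suppressor scores worse
  corrupted <- rep[rep$snippet == "art", ]
  expect_gt(corrupted$rmse_uv, perfect$rmse_uv)
  expect_lt(corrupted$c0, 1)
})
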