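# Reference baseline suppressors and the common suppressor interface used by
# the benchmark harness. All suppressors take (recording, stim_train) and
# return a same-length clean recording plus per-trial blanking metadata.

#' Dynamic-averaging artifact suppression
#'
#' The artifact template of stimulus `i` is the mean of its `n_neighbors`
#' temporally nearest trials (excluding the trial itself), truncated to the
#' shortest involved trial, and is subtracted from trial `i`. A fixed blank
#' is applied after each onset. When `K <= n_neighbors` the method falls back
#' to the global average over all trials (including the current one) with a
#' warning.
#'
#' @param rec a [recording()].
#' @param stims a [stim_train()].
#' @param n_neighbors number of temporally adjacent trials averaged.
#' @param blank_ms fixed post-onset blank (ms), written as zeros.
#' @return list of class `suppressor_result`: `recording`, `blanking`
#'   (tibble: trial, onset, beta_ms).
#' @export
dynamic_averaging <- function(rec, stims, n_neighbors = 10L, blank_ms = 1) {
  ts <- segment_trials(rec, stims)
  K <- length(ts$trials)
  b <- ms_to_samples(blank_ms, rec$fs)
  global <- K <= n_neighbors
  if (global) {
    warning("dynamic_averaging: K <= n_neighbors, falling back to global average")
    L <- min(ts$lengths)
    tmpl_global <- rowMeans(vapply(ts$trials, function(tr) tr[1:L],
                                   numeric(L)))
  }
  clean <- vector("list", K)
  for (i in seq_len(K)) {
    tr <- ts$trials[[i]]
    if (global) {
      L <- length(tmpl_global)
      tmpl <- tmpl_global
    } else {
      nb <- setdiff(order(abs(ts$onsets - ts$onsets[i])), i)[seq_len(n_neighbors)]
      L <- min(ts$lengths[c(i, nb)])
      tmpl <- rowMeans(vapply(ts$trials[nb], function(x) x[1:L], numeric(L)))
    }
    Lu <- min(L, length(tr))
    tr[1:Lu] <- tr[1:Lu] - tmpl[1:Lu]
    if (b >= 1) tr[1:min(b, length(tr))] <- 0
    clean[[i]] <- tr
  }
  out <- rec
  out$samples <- c(ts$prefix, unlist(clean, use.names = FALSE))
  structure(list(recording = out,
                 blanking = tibble::tibble(trial = seq_len(K),
                                           onset = ts$onsets,
                                           beta_ms = rep(blank_ms, K))),
            class = "suppressor_result")
}

#' Global polynomial-fit artifact suppression
#'
#' Per trial, a polynomial of the given order is least-squares fit to the
#' post-blanking artifact span and subtracted; the remainder of the trial is
#' untouched. Trials with fewer samples than `order + 2` in the span are
#' skipped with a warning.
#'
#' @inheritParams dynamic_averaging
#' @param order polynomial order (>= 0).
#' @param fit_span_ms span after the onset over which the fit is computed and
#'   subtracted (ms).
#' @param blank_ms fixed post-onset blank (ms), written as zeros.
#' @return list of class `suppressor_result`.
#' @export
global_polyfit <- function(rec, stims, order = 8L, fit_span_ms = 10,
                           blank_ms = 0.5) {
  stopifnot(order >= 0)
  ts <- segment_trials(rec, stims)
  K <- length(ts$trials)
  b <- ms_to_samples(blank_ms, rec$fs)
  span <- ms_to_samples(fit_span_ms, rec$fs)
  clean <- vector("list", K)
  skipped <- 0L
  for (i in seq_len(K)) {
    tr <- ts$trials[[i]]
    hi <- min(span, length(tr))
    idx <- if (b + 1L <= hi) seq.int(b + 1L, hi) else integer(0)
    if (length(idx) < order + 2L) {
      skipped <- skipped + 1L
    } else {
      x <- (idx - idx[1]) / max(1L, length(idx) - 1L)   # scaled for conditioning
      X <- if (order >= 1) cbind(1, poly(x, degree = order))
           else matrix(1, length(idx), 1L)
      fitv <- X %*% qr.coef(qr(X), tr[idx])
      tr[idx] <- tr[idx] - as.numeric(fitv)
    }
    if (b >= 1) tr[1:min(b, length(tr))] <- 0
    clean[[i]] <- tr
  }
  if (skipped > 0)
    warning(sprintf("global_polyfit: %d trial(s) skipped (too short for fit)", skipped))
  out <- rec
  out$samples <- c(ts$prefix, unlist(clean, use.names = FALSE))
  structure(list(recording = out,
                 blanking = tibble::tibble(trial = seq_len(K),
                                           onset = ts$onsets,
                                           beta_ms = rep(blank_ms, K))),
            class = "suppressor_result")
}

#' Look up a suppressor by name
#'
#' Returns a suppressor object — a `name` plus a function
#' `clean(rec, stims, ...)` returning a `suppressor_result` — so that the
#' benchmark harness runs unchanged over the full method set. Available:
#' `"loglira"`, `"dynavg"`, `"polyfit"` and `"identity"` (a no-op control).
#'
#' @param name method name.
#' @param ... default arguments bound to the method.
#' @return list of class `suppressor`.
#' @export
get_suppressor <- function(name, ...) {
  defaults <- list(...)
  fn <- switch(
    name,
    loglira = function(rec, stims, ...) {
      args <- utils::modifyList(defaults, list(...))
      cfg <- if (!is.null(args$cfg)) args$cfg else loglira_config()
      res <- loglira_clean(rec, stims, cfg)
      structure(list(recording = res$recording,
                     blanking = res$fits[, c("trial", "onset", "beta_ms")],
                     fits = res$fits),
                class = "suppressor_result")
    },
    dynavg = function(rec, stims, ...) {
      args <- utils::modifyList(defaults, list(...))
      args <- args[intersect(names(args), names(formals(dynamic_averaging)))]
      do.call(dynamic_averaging, c(list(rec = rec, stims = stims), args))
    },
    polyfit = function(rec, stims, ...) {
      args <- utils::modifyList(defaults, list(...))
      args <- args[intersect(names(args), names(formals(global_polyfit)))]
      do.call(global_polyfit, c(list(rec = rec, stims = stims), args))
    },
    identity = function(rec, stims, ...) {
      structure(list(recording = rec,
                     blanking = tibble::tibble(trial = seq_along(stims),
                                               onset = as.integer(stims),
                                               beta_ms = 0)),
                class = "suppressor_result")
    },
    stop(sprintf("unknown suppressor '%s'; available: loglira, dynavg, polyfit, identity",
                 name))
  )
  structure(list(name = name, clean = fn), class = "suppressor")
}

#' Wrap an external command as a suppressor
#'
#' File-based plug-in contract: the harness writes the recording and onsets
#' to a temporary directory, invokes `command <signal file> <onsets file>
#' <output file>`, and reads back a clean recording of identical length.
#'
#' @param name label for the report.
#' @param command executable invoked per channel.
#' @param blank_ms blanking reported for each trial (the external tool's
#'   own metadata, if any, is not parsed).
#' @return list of class `suppressor`.
#' @export
external_suppressor <- function(name, command, blank_ms = NA_real_) {
  fn <- function(rec, stims, ...) {
    dir <- tempfile("extsup")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    sig <- file.path(dir, "signal.bin")
    ons <- file.path(dir, "onsets.txt")
    out <- file.path(dir, "clean.bin")
    write_recording(rec, sig)
    write_onsets(stims, rec$fs, ons)
    status <- system2(command, c(sig, ons, out))
    if (status != 0) stop(sprintf("external suppressor '%s' failed (%d)", name, status))
    clean <- read_recording(out)
    if (length(clean$samples) != length(rec$samples))
      stop("external suppressor returned a recording of different length")
    structure(list(recording = clean,
                   blanking = tibble::tibble(trial = seq_along(stims),
                                             onset = as.integer(stims),
                                             beta_ms = blank_ms)),
              class = "suppressor_result")
  }
  structure(list(name = name, clean = fn), class = "suppressor")
}
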