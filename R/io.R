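# File formats: raw little-endian binary recordings with a JSON sidecar,
# plain one-column text for toy cases, one-onset-per-line stimulus and spike
# trains with an "# fs=<Hz>" header, and JSON manifests.

#' Write a recording to disk
#'
#' Binary mode writes little-endian float32 samples plus a JSON sidecar
#' (`<file>.json`) holding `fs`, `units`, `amp_limits` and `channel_id`.
#' Files ending in `.txt` are written as plain one-sample-per-line text with
#' the sidecar alongside.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (grepl("\\.txt$", path)) {
    writeLines(format(rec$samples, digits = 10, trim = TRUE, scientific = FALSE),
               path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(rec$samples), con, size = 4L, endian = "little")
  }
  meta <- list(fs = rec$fs, units = "uV", dtype = "float32",
               n_samples = length(rec$samples),
               amp_limits = rec$amp_limits, channel_id = rec$channel_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path file path; the JSON sidecar `<path>.json` must exist.
#' @return a [recording()].
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  samples <- if (grepl("\\.txt$", path)) {
    as.numeric(readLines(path))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, numeric(), n = meta$n_samples, size = 4L, endian = "little")
  }
  recording(samples, fs = meta$fs,
            amp_limits = if (length(meta$amp_limits)) meta$amp_limits else NULL,
            channel_id = if (!is.null(meta$channel_id)) meta$channel_id else "ch0")
}

#' Write an onset or spike train to a text file
#'
#' One integer sample index (1-based) per line, preceded by a header line
#' `# fs=<Hz>`.
#'
#' @param times integer sample indices ([stim_train()] or `spike_train`).
#' @param fs sampling rate (Hz).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_onsets <- function(times, fs, path) {
  writeLines(c(sprintf("# fs=%g", fs), format(as.integer(times))), path)
  invisible(path)
}

#' Read an onset or spike train text file
#'
#' @param path file path.
#' @return integer sample indices with attribute `fs` (NA when the header is
#'   missing).
#' @export
read_onsets <- function(path) {
  lines <- readLines(path)
  fs <- NA_real_
  hdr <- grepl("^#", lines)
  m <- regmatches(lines[hdr], regexec("fs=([0-9.eE+-]+)", lines[hdr]))
  if (length(m) && length(m[[1]]) == 2) fs <- as.numeric(m[[1]][2])
  times <- as.integer(trimws(lines[!hdr & nzchar(trimws(lines))]))
  structure(times, fs = fs)
}

#' Write a snippet and its ground truth to a directory
#'
#' Writes `signal.bin` (+ sidecar), `onsets.txt`, `spikes.txt`,
#' `artifact_track.bin` and a `manifest.json` recording the generation
#' parameters and realised rates.
#'
#' @param snip a `snippet`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_snippet <- function(snip, dir) {
  stopifnot(inherits(snip, "snippet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_recording(recording(snip$signal, snip$fs), file.path(dir, "signal.bin"))
  write_recording(recording(snip$artifact_track, snip$fs),
                  file.path(dir, "artifact_track.bin"))
  write_onsets(snip$stims, snip$fs, file.path(dir, "onsets.txt"))
  write_onsets(snip$spikes, snip$fs, file.path(dir, "spikes.txt"))
  jsonlite::write_json(
    list(fs = snip$fs, duration = snip$duration, seed = snip$seed,
         realized_mar = snip$realized_mar, realized_mfr = snip$realized_mfr,
         k_stimuli = length(snip$stims), n_spikes = length(snip$spikes)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a snippet directory written by [write_snippet()]
#'
#' @param dir snippet directory.
#' @return a `snippet`.
#' @export
read_snippet <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  sig <- read_recording(file.path(dir, "signal.bin"))
  track <- read_recording(file.path(dir, "artifact_track.bin"))
  onsets <- read_onsets(file.path(dir, "onsets.txt"))
  spikes <- read_onsets(file.path(dir, "spikes.txt"))
  structure(list(signal = sig$samples,
                 # reconstructed: exact only to float32 storage precision
                 basal_signal = sig$samples - track$samples,
                 artifact_track = track$samples,
                 stims = stim_train(onsets, length(sig$samples)),
                 spikes = as.integer(spikes),
                 template_ids = NULL,
                 realized_mar = meta$realized_mar,
                 realized_mfr = meta$realized_mfr,
                 fs = meta$fs, duration = meta$duration, seed = meta$seed),
            class = "snippet")
}
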