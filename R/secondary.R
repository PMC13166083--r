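# Stage 2: secondary-artifact mitigation.
#
# The 2 ms windows immediately following each trial's blanking interval are
# embedded in 2-D (correlation distance) and grouped by density-based
# merging; each sufficiently large cluster's mean waveform — a deterministic
# residual of the interpolation step — is subtracted from its member trials.

#' Extract the post-blanking windows of all trials
#'
#' Row `i` is the `secondary_window` (2 ms) stretch of cleaned trial `i`
#' starting immediately after that trial's own blanking interval. Trials too
#' short to hold the window are masked out.
#'
#' @param trials list of cleaned trial vectors.
#' @param n_s integer vector of per-trial blanked sample counts.
#' @param cfg a [loglira_config()].
#' @param fs sampling rate (Hz).
#' @return list with `windows` (K x w matrix, masked rows NA) and `valid`
#'   (logical mask).
#' @export
extract_windows <- function(trials, n_s, cfg, fs) {
  w <- ms_to_samples(cfg$secondary_window, fs)
  K <- length(trials)
  valid <- vapply(seq_len(K), function(i) {
    length(trials[[i]]) >= n_s[i] + w
  }, logical(1))
  windows <- matrix(NA_real_, nrow = K, ncol = w)
  for (i in which(valid)) {
    windows[i, ] <- trials[[i]][(n_s[i] + 1L):(n_s[i] + w)]
  }
  list(windows = windows, valid = valid, w = w)
}

#' Embed waveform windows into two dimensions
#'
#' Classical multidimensional scaling (principal coordinates) of the pairwise
#' correlation distance `1 - r` between rows. The embedding is deterministic;
#' the correlation metric makes it scale-invariant, so windows are used raw.
#' Zero-variance rows (correlation undefined) are pinned at the origin and
#' flagged so downstream density estimation can exclude them.
#'
#' @param windows numeric matrix, one waveform per row.
#' @param seed unused (kept for interface stability; the embedding is
#'   deterministic).
#' @return K x 2 coordinate matrix with attribute `zero_var` (logical).
#' @export
embed_windows <- function(windows, seed = NULL) {
  K <- nrow(windows)
  if (is.null(K) || K < 2) stop("embed_windows: need at least 2 windows")
  sds <- apply(windows, 1, sd)
  zv <- !is.finite(sds) | sds == 0
  coords <- matrix(0, nrow = K, ncol = 2)
  live <- which(!zv)
  if (length(live) >= 2) {
    r <- suppressWarnings(cor(t(windows[live, , drop = FALSE])))
    d <- 1 - r
    d[!is.finite(d)] <- 2
    d[d < 0] <- 0
    if (max(d) < 1e-12) {
      # all windows effectively identical: coincident coordinates
      emb <- matrix(0, nrow = length(live), ncol = 2)
    } else {
      emb <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = 2))
      if (ncol(emb) < 2) emb <- cbind(emb, 0)
    }
    coords[live, ] <- emb[, 1:2]
  }
  attr(coords, "zero_var") <- zv
  coords
}

#' Cluster a 2-D embedding by density-based merging
#'
#' Kernel density estimation on a grid, assignment of every point to a local
#' density mode by hill-climbing, and merging of modes whose separating
#' saddle density exceeds `saddle_ratio` of the lower peak. No cluster count
#' is specified a priori; clusters with fewer than `theta` members are
#' discarded (label 0 = noise).
#'
#' @param embedding K x 2 coordinate matrix (principal coordinates of the
#'   correlation distance, so absolute scale is meaningful: coordinates live
#'   in `1 - r` units).
#' @param theta minimum retained cluster size.
#' @param saddle_ratio mode-merging threshold (fraction of the lower peak).
#' @param grid_n KDE grid resolution per axis.
#' @param same_shape_tol when every pairwise distance in the embedding is
#'   below this value the windows are one waveform family by definition
#'   (all mutual correlations near 1) and density estimation — which would
#'   otherwise resolve sampling noise into spurious modes — is skipped.
#' @return list of class `cluster_assignment`: `labels` (integer, 0 = noise),
#'   `retained` (ids with >= theta members), `sizes`.
#' @export
cluster_density <- function(embedding, theta = 20L, saddle_ratio = 0.5,
                            grid_n = 64L, same_shape_tol = 0.1) {
  K <- nrow(embedding)
  x <- embedding[, 1]; y <- embedding[, 2]
  spread <- c(sd(x), sd(y))
  if (all(!is.finite(spread)) || all(spread < 1e-12) ||
      (diff(range(x))^2 + diff(range(y))^2) < same_shape_tol^2) {
    labels <- rep(1L, K)  # one family: all windows essentially identical
  } else {
    hx <- MASS::bandwidth.nrd(x); hy <- MASS::bandwidth.nrd(y)
    if (!is.finite(hx) || hx <= 0) hx <- max(spread[1], 1e-6)
    if (!is.finite(hy) || hy <= 0) hy <- max(spread[2], 1e-6)
    padx <- max(hx, diff(range(x)) * 0.05, 1e-9)
    pady <- max(hy, diff(range(y)) * 0.05, 1e-9)
    kd <- MASS::kde2d(x, y, h = c(hx, hy), n = grid_n,
                      lims = c(range(x) + c(-padx, padx),
                               range(y) + c(-pady, pady)))
    basin <- kde_basins(kd$z, saddle_ratio)
    ix <- pmin(pmax(findInterval(x, kd$x, all.inside = TRUE), 1L), grid_n - 1L)
    iy <- pmin(pmax(findInterval(y, kd$y, all.inside = TRUE), 1L), grid_n - 1L)
    # snap to the nearer grid line
    ix <- ix + as.integer(x - kd$x[ix] > kd$x[ix + 1L] - x)
    iy <- iy + as.integer(y - kd$y[iy] > kd$y[iy + 1L] - y)
    labels <- basin[cbind(ix, iy)]
    labels <- match(labels, sort(unique(labels)))
  }
  sizes <- table(labels)
  keep <- as.integer(names(sizes)[sizes >= theta])
  labels[!(labels %in% keep)] <- 0L
  # relabel retained clusters 1..m by decreasing size
  if (length(keep)) {
    ord <- keep[order(-sizes[as.character(keep)])]
    labels <- ifelse(labels == 0L, 0L, match(labels, ord))
  }
  structure(list(labels = as.integer(labels),
                 retained = if (length(keep)) seq_along(keep) else integer(0),
                 sizes = table(labels[labels > 0L])),
            class = "cluster_assignment")
}

# Hill-climbing basin assignment on a density grid plus saddle merging.
# Returns an integer matrix of basin ids, same shape as z.
kde_basins <- function(z, saddle_ratio) {
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  ord <- order(z, decreasing = TRUE)   # process cells from densest down
  basin <- integer(n)
  peak <- numeric(0)
  nbr_offsets <- expand.grid(di = -1:1, dj = -1:1)
  nbr_offsets <- nbr_offsets[!(nbr_offsets$di == 0 & nbr_offsets$dj == 0), ]
  parent <- integer(0)
  find_root <- function(b) { while (parent[b] != b) b <- parent[b]; b }
  for (cell in ord) {
    i <- (cell - 1L) %% nr + 1L
    j <- (cell - 1L) %/% nr + 1L
    best <- 0L; best_z <- z[cell]
    seen <- integer(0)
    for (k in seq_len(nrow(nbr_offsets))) {
      ii <- i + nbr_offsets$di[k]; jj <- j + nbr_offsets$dj[k]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      ncell <- (jj - 1L) * nr + ii
      if (basin[ncell] != 0L) {
        seen <- c(seen, basin[ncell])
        if (z[ncell] > best_z) { best_z <- z[ncell]; best <- basin[ncell] }
      }
    }
    if (best == 0L) {
      # new local mode
      b <- length(peak) + 1L
      peak <- c(peak, z[cell])
      parent <- c(parent, b)
      basin[cell] <- b
    } else {
      basin[cell] <- best
      # this cell is a potential saddle between the basins that touch it
      roots <- unique(vapply(seen, find_root, integer(1)))
      if (length(roots) > 1) {
        for (r in roots[-1]) {
          r1 <- find_root(roots[1]); r2 <- find_root(r)
          if (r1 != r2 &&
              z[cell] >= saddle_ratio * min(peak[r1], peak[r2])) {
            lo <- if (peak[r1] >= peak[r2]) r2 else r1
            hi <- if (peak[r1] >= peak[r2]) r1 else r2
            parent[lo] <- hi
          }
        }
      }
    }
  }
  roots <- vapply(basin, find_root, integer(1))
  matrix(roots, nrow = nr, ncol = nc)
}

#' Subtract retained cluster-mean waveforms from member trials
#'
#' For each retained cluster the member rows' mean waveform — the estimate of
#' the shared deterministic secondary artifact — is subtracted in place from
#' the corresponding trial segment immediately after its blanking interval.
#' Noise-labelled and masked trials are untouched.
#'
#' @param trials list of cleaned trial vectors.
#' @param n_s per-trial blanked sample counts.
#' @param windows K x w window matrix from [extract_windows()].
#' @param assignment a `cluster_assignment`.
#' @return list with `trials` (modified) and `means` (one row per retained
#'   cluster).
#' @export
subtract_cluster_means <- function(trials, n_s, windows, assignment) {
  w <- ncol(windows)
  means <- NULL
  for (cl in assignment$retained) {
    rows <- which(assignment$labels == cl)
    mu <- colMeans(windows[rows, , drop = FALSE])
    means <- rbind(means, mu)
    for (i in rows) {
      idx <- (n_s[i] + 1L):(n_s[i] + w)
      trials[[i]][idx] <- trials[[i]][idx] - mu
    }
  }
  list(trials = trials, means = means)
}

# Orchestrates stage 2 over the cleaned trials. Identity when fewer than two
# usable windows exist or no cluster reaches theta members.
mitigate_secondary <- function(trials, fits, cfg, fs) {
  n_s <- vapply(fits, `[[`, integer(1), "n_s")
  use <- rep(TRUE, length(trials))
  if (!cfg$include_no_transient) {
    use <- vapply(fits, `[[`, logical(1), "transient")
  }
  ew <- extract_windows(trials, n_s, cfg, fs)
  valid <- ew$valid & use
  diagnostics <- list(valid = valid, labels = rep(0L, length(trials)),
                      retained = integer(0), embedding = NULL, means = NULL)
  if (sum(valid) < 2) {
    warning("secondary mitigation skipped: fewer than 2 usable windows")
    return(list(trials = trials, diagnostics = diagnostics))
  }
  W <- ew$windows[valid, , drop = FALSE]
  emb <- embed_windows(W, seed = cfg$seed)
  zv <- attr(emb, "zero_var")
  labels_v <- rep(0L, nrow(W))
  if (sum(!zv) >= 2) {
    ca <- cluster_density(emb[!zv, , drop = FALSE], theta = cfg$theta,
                          saddle_ratio = cfg$saddle_ratio)
    labels_v[!zv] <- ca$labels
  }
  # identical flat windows form their own cluster when numerous enough
  if (sum(zv) >= cfg$theta) {
    labels_v[zv] <- max(labels_v) + 1L
  }
  retained <- sort(unique(labels_v[labels_v > 0L]))
  labels <- rep(0L, length(trials))
  labels[which(valid)] <- labels_v
  assignment <- structure(list(labels = labels, retained = retained),
                          class = "cluster_assignment")
  sub <- subtract_cluster_means(trials, n_s, ew$windows, assignment)
  diagnostics$labels <- labels
  diagnostics$retained <- retained
  diagnostics$embedding <- emb
  diagnostics$means <- sub$means
  list(trials = sub$trials, diagnostics = diagnostics)
}

#' Export secondary-mitigation diagnostics as tabular text
#'
#' Writes the 2-D embedding coordinates with cluster labels
#' (`embedding.tsv`) and the subtracted cluster-mean waveforms, one per
#' column (`cluster_means.tsv`).
#'
#' @param result a `loglira_result` with a non-`NULL` `secondary` element.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_secondary_diagnostics <- function(result, dir) {
  stopifnot(inherits(result, "loglira_result"))
  sec <- result$secondary
  if (is.null(sec)) stop("no secondary-mitigation diagnostics to export")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  valid <- which(sec$valid)
  emb <- data.frame(trial = valid,
                    dim1 = sec$embedding[, 1], dim2 = sec$embedding[, 2],
                    label = sec$labels[valid])
  utils::write.table(emb, file.path(dir, "embedding.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(sec$means)) {
    mm <- t(sec$means)
    colnames(mm) <- paste0("cluster_", seq_len(ncol(mm)))
    utils::write.table(mm, file.path(dir, "cluster_means.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
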