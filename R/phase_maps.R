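# Rotation-polarization phase-space summaries: binned occupancy and
# conditional-mean maps, bilinear refinement, averaged transition paths and
# coarse-grained phase-velocity fields.
#
# Axis convention: O_r on the first axis (rows), O_p on the second
# (columns). Bins are half-open [a, b) except the last, which is closed so
# a value of exactly 1 lands in bin 30.

phase_bin_index <- function(v, n_bins = 30L) {
  pmin(floor(v * n_bins) + 1L, n_bins)
}

new_phase_grid <- function(value, support, min_count, mode, n_bins = 30L) {
  structure(
    list(value = value, support = support, mask = support < min_count,
         min_count = min_count, mode = mode,
         edges = seq(0, 1, length.out = n_bins + 1L)),
    class = "phase_grid")
}

#' @export
print.phase_grid <- function(x, ...) {
  nb <- nrow(x$value)
  cat(sprintf("<phase_grid %dx%d, mode=%s> %d supported bins (min_count=%d)\n",
              nb, nb, x$mode, sum(!x$mask), x$min_count))
  invisible(x)
}

check_phase_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("phase points must have two columns (o_r, o_p)")
  if (anyNA(points) || any(points < 0) || any(points > 1)) {
    stop("phase points must lie in [0, 1] x [0, 1]")
  }
  points
}

#' Phase-space occupancy histogram
#'
#' Counts `(O_r, O_p)` samples over a 30x30 grid of the unit square. Bins
#' supported by fewer than `min_count` samples are masked (they render as
#' the no-data regions of a density plot and are never interpolated from).
#'
#' @param points two-column matrix or data.frame of `(o_r, o_p)` values in
#'   `[0, 1]`.
#' @param min_count support threshold (default 100; use 20 for
#'   transition-conditioned maps).
#' @param n_bins grid resolution per axis (default 30).
#' @return A `phase_grid` whose `value` matrix holds counts (rows = O_r
#'   bins, columns = O_p bins).
#' @export
phase_histogram <- function(points, min_count = 100, n_bins = 30L) {
  points <- check_phase_points(points)
  i <- phase_bin_index(points[, 1], n_bins)
  j <- phase_bin_index(points[, 2], n_bins)
  counts <- matrix(0, n_bins, n_bins)
  t <- table(factor(i, levels = seq_len(n_bins)),
             factor(j, levels = seq_len(n_bins)))
  counts[] <- as.numeric(t)
  new_phase_grid(counts, counts, min_count, "count", n_bins)
}

#' Phase-space conditional-mean map
#'
#' Per-bin arithmetic mean of a scalar (speed, packing fraction, boundary
#' distance, ...) conditioned on the `(O_r, O_p)` bin of each sample.
#'
#' @inheritParams phase_histogram
#' @param values scalar value per point (same length as rows of `points`).
#' @return A `phase_grid` with per-bin means (`NA` where masked).
#' @export
phase_mean_map <- function(points, values, min_count = 100, n_bins = 30L) {
  points <- check_phase_points(points)
  if (length(values) != nrow(points)) {
    stop("values must have one entry per phase point")
  }
  i <- phase_bin_index(points[, 1], n_bins)
  j <- phase_bin_index(points[, 2], n_bins)
  cell <- (j - 1L) * n_bins + i
  sums <- rep(0, n_bins * n_bins)
  cnts <- rep(0, n_bins * n_bins)
  agg_s <- tapply(values, cell, sum)
  agg_n <- tapply(values, cell, length)
  sums[as.integer(names(agg_s))] <- agg_s
  cnts[as.integer(names(agg_n))] <- agg_n
  value <- matrix(ifelse(cnts > 0, sums / cnts, NA_real_), n_bins, n_bins)
  support <- matrix(cnts, n_bins, n_bins)
  g <- new_phase_grid(value, support, min_count, "mean", n_bins)
  g$value[g$mask] <- NA_real_
  g
}

#' Refine a phase grid to a finer mesh
#'
#' Bilinear interpolation of the unmasked coarse-bin values (taken at bin
#' centers) onto an `n_fine x n_fine` mesh. Interpolation never extends
#' beyond the supported region: fine points whose containing coarse bin is
#' masked are `NA`, and where a neighboring bin needed for interpolation is
#' masked the containing bin's own value is used, so refined values never
#' exceed the range of the contributing coarse bins.
#'
#' @param grid a `phase_grid`.
#' @param n_fine fine mesh resolution (default 300).
#' @return `n_fine x n_fine` matrix (rows = O_r, columns = O_p).
#' @export
refine_grid <- function(grid, n_fine = 300L) {
  stopifnot(inherits(grid, "phase_grid"))
  if (all(grid$mask)) stop("all bins masked: nothing to refine")
  nb <- nrow(grid$value)
  val <- grid$value
  val[grid$mask] <- NA_real_
  f <- (seq_len(n_fine) - 0.5) / n_fine      # fine-point coordinates
  u <- f * nb + 0.5                          # coarse center-index space
  i0 <- pmin(pmax(floor(u), 1L), nb - 1L)
  tt <- pmin(pmax(u - i0, 0), 1)
  bin <- phase_bin_index(f, nb)              # containing coarse bin
  out <- matrix(NA_real_, n_fine, n_fine)
  for (a in seq_len(n_fine)) {
    ia <- i0[a]; ta <- tt[a]; ba <- bin[a]
    v00 <- val[ia, i0]; v10 <- val[ia + 1L, i0]
    v01 <- val[ia, i0 + 1L]; v11 <- val[ia + 1L, i0 + 1L]
    bil <- (1 - ta) * ((1 - tt) * v00 + tt * v01) +
      ta * ((1 - tt) * v10 + tt * v11)
    own <- val[ba, bin]
    res <- ifelse(is.na(bil), own, bil)
    res[is.na(own)] <- NA_real_
    out[a, ] <- res
  }
  out
}

#' Conditional-mean curves of speed versus local order
#'
#' Two complementary summaries of the joint distribution of individual
#' speed and local polarization: the mean speed for each value of the order
#' parameter (binning the order parameter over `[0, 1]`) and the mean order
#' parameter for each value of the speed (binning speed over its observed
#' range). Empty bins are omitted.
#'
#' @param speed per-fish speed samples (cm/s).
#' @param local_o_p paired per-fish local polarization samples in `[0, 1]`.
#' @param n_bins bins per axis (default 30).
#' @return List with data.frames `by_order` (`local_o_p`, `mean_speed`,
#'   `n`) and `by_speed` (`speed`, `mean_local_o_p`, `n`).
#' @export
conditional_mean_curves <- function(speed, local_o_p, n_bins = 30L) {
  if (length(speed) != length(local_o_p)) stop("inputs must be paired")
  ok <- is.finite(speed) & is.finite(local_o_p)
  speed <- speed[ok]; local_o_p <- local_o_p[ok]
  if (length(unique(speed)) < 2L) {
    stop("insufficient data: fewer than 2 distinct speed values")
  }
  yb <- phase_bin_index(local_o_p, n_bins)
  by_order <- do.call(rbind, lapply(sort(unique(yb)), function(b) {
    sel <- yb == b
    data.frame(local_o_p = (b - 0.5) / n_bins,
               mean_speed = mean(speed[sel]), n = sum(sel))
  }))
  rng <- range(speed)
  w <- diff(rng)
  xb <- if (w > 0) pmin(floor((speed - rng[1]) / w * n_bins) + 1L, n_bins)
  else rep(1L, length(speed))
  by_speed <- do.call(rbind, lapply(sort(unique(xb)), function(b) {
    sel <- xb == b
    data.frame(speed = rng[1] + (b - 0.5) / n_bins * w,
               mean_local_o_p = mean(local_o_p[sel]), n = sum(sel))
  }))
  list(by_order = by_order, by_speed = by_speed)
}

#' Resample a phase-space path to a common length
#'
#' Linear interpolation of a `(O_r, O_p)` path in normalized time `[0, 1]`;
#' endpoints are preserved exactly.
#'
#' @param path two-column matrix of `(o_r, o_p)` points, length >= 2.
#' @param length_out number of resampled points (default 100).
#' @return `length_out x 2` matrix.
#' @export
resample_path <- function(path, length_out = 100L) {
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop("degenerate path: fewer than 2 points")
  t_in <- seq(0, 1, length.out = nrow(path))
  t_out <- seq(0, 1, length.out = length_out)
  cbind(stats::approx(t_in, path[, 1], xout = t_out)$y,
        stats::approx(t_in, path[, 2], xout = t_out)$y)
}

event_paths <- function(events) {
  if (inherits(events, "transition_events")) {
    if (!"path" %in% names(events)) {
      stop("events carry no paths; call completed_transitions() with the series")
    }
    events$path
  } else if (is.list(events) && !is.data.frame(events)) {
    events
  } else {
    stop("expected a transition_events table or a list of paths")
  }
}

#' Average transition path
#'
#' Resamples every event's phase-space path to a common length and takes
#' the pointwise mean: the typical route a group follows between two
#' states.
#'
#' @param events a `transition_events` table with paths (see
#'   [completed_transitions()]) or a plain list of two-column path
#'   matrices; usually pre-filtered to one `from -> to` type.
#' @param length_out resampled path length (default 100).
#' @return `length_out x 2` matrix of mean `(o_r, o_p)` points.
#' @export
average_transition_path <- function(events, length_out = 100L) {
  paths <- event_paths(events)
  if (length(paths) == 0L) stop("no events to average")
  res <- lapply(paths, resample_path, length_out = length_out)
  Reduce(`+`, res) / length(res)
}

#' Coarse-grained phase-space velocity field
#'
#' Forward finite differences of the resampled transition paths, assigned
#' to the bin of their starting point and averaged per bin: the mean local
#' direction of motion through the rotation-polarization plane during
#' transitions.
#'
#' @inheritParams average_transition_path
#' @param min_count support mask threshold (default 20).
#' @param n_bins grid resolution (default 30).
#' @return List of class `phase_vector_field`: matrices `u` (mean
#'   delta-O_r), `v` (mean delta-O_p), `support` and `mask`.
#' @export
phase_velocity_field <- function(events, min_count = 20, n_bins = 30L,
                                 length_out = 100L) {
  paths <- event_paths(events)
  if (length(paths) == 0L) stop("no events")
  su <- matrix(0, n_bins, n_bins); sv <- matrix(0, n_bins, n_bins)
  supp <- matrix(0, n_bins, n_bins)
  for (p in paths) {
    r <- resample_path(p, length_out)
    d <- diff(r)
    i <- phase_bin_index(pmin(pmax(r[-nrow(r), 1], 0), 1), n_bins)
    j <- phase_bin_index(pmin(pmax(r[-nrow(r), 2], 0), 1), n_bins)
    for (k in seq_along(i)) {
      su[i[k], j[k]] <- su[i[k], j[k]] + d[k, 1]
      sv[i[k], j[k]] <- sv[i[k], j[k]] + d[k, 2]
      supp[i[k], j[k]] <- supp[i[k], j[k]] + 1
    }
  }
  u <- ifelse(supp > 0, su / supp, NA_real_)
  v <- ifelse(supp > 0, sv / supp, NA_real_)
  mask <- supp < min_count
  u[mask] <- NA_real_; v[mask] <- NA_real_
  structure(list(u = u, v = v, support = supp, mask = mask,
                 min_count = min_count),
            class = "phase_vector_field")
}
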