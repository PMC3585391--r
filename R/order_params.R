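# Global and local order parameters of a school.
#
# The group configuration is summarized by two dimensionless numbers:
# polarization O_p = |(1/N) sum_i u_i|, the magnitude of the mean unit
# heading, and rotation O_r = |(1/N) sum_i (r_hat_i x u_i) . z|, the
# magnitude of the mean normalized angular momentum about the group center
# of mass. Both live in [0, 1]. Positive signed rotation is
# counter-clockwise.

#' Polarization order parameter of one frame
#'
#' The magnitude of the mean unit heading over the valid individuals:
#' 1 when all fish point the same way, near 0 for incoherent headings.
#'
#' @param frame data.frame with `heading_x`, `heading_y` and optionally
#'   `valid` columns (see [derive_kinematics()], [make_archetype()]).
#' @return Scalar in `[0, 1]`, or `NA` if no individual is valid (the frame
#'   is then skipped downstream).
#' @export
polarization <- function(frame) {
  v <- frame_valid(frame)
  if (!any(v)) return(NA_real_)
  hx <- mean(frame$heading_x[v])
  hy <- mean(frame$heading_y[v])
  sqrt(hx^2 + hy^2)
}

#' Rotation (milling) order parameter of one frame
#'
#' The mean normalized angular momentum about the group center of mass:
#' for each valid fish the z-component of `r_hat x u`, where `r_hat` is the
#' unit vector from the center of mass to the fish and `u` its heading.
#' A fish exactly at the center of mass contributes 0. Positive sign is
#' counter-clockwise.
#'
#' @inheritParams polarization
#' @return Named numeric `c(signed = ..., magnitude = ...)`; magnitude in
#'   `[0, 1]`. Both `NA` when fewer than 2 individuals are valid.
#' @export
rotation <- function(frame) {
  v <- frame_valid(frame)
  n <- sum(v)
  if (n < 2) return(c(signed = NA_real_, magnitude = NA_real_))
  cx <- mean(frame$x[v]); cy <- mean(frame$y[v])
  rx <- frame$x[v] - cx; ry <- frame$y[v] - cy
  d <- sqrt(rx^2 + ry^2)
  cr <- numeric(n)
  nz <- d > 0
  cr[nz] <- (rx[nz] * frame$heading_y[v][nz] -
               ry[nz] * frame$heading_x[v][nz]) / d[nz]
  s <- mean(cr)
  c(signed = s, magnitude = abs(s))
}

#' Centered moving average with symmetric edge truncation
#'
#' Smooths a per-frame scalar series with a centered moving average. Even
#' spans are reduced by one frame so the window stays centered. Near the
#' edges the half-width shrinks symmetrically, so output length equals input
#' length. If the (adjusted) span is at least the series length the global
#' mean is returned at every frame. `NA` entries are ignored inside windows
#' but preserved at their own positions (they mark gaps).
#'
#' @param x numeric vector.
#' @param span window width in frames (default 30, i.e. 1 s at 30 fps).
#' @return Numeric vector of the same length as `x`.
#' @export
smooth_series <- function(x, span = 30) {
  if (!is.numeric(span) || length(span) != 1 || span < 1) {
    stop("span must be a scalar >= 1")
  }
  n <- length(x)
  if (n == 0L) return(x)
  span <- as.integer(span)
  if (span %% 2L == 0L) span <- span - 1L
  if (span >= n) {
    out <- rep(mean(x, na.rm = TRUE), n)
    out[is.na(x)] <- NA_real_
    return(out)
  }
  h <- (span - 1L) %/% 2L
  xx <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(xx))
  cc <- c(0, cumsum(cnt))
  i <- seq_len(n)
  hi <- pmin(h, i - 1L, n - i)
  lo <- i - hi
  up <- i + hi
  m <- cc[up + 1L] - cc[lo]
  out <- ifelse(m > 0, (cs[up + 1L] - cs[lo]) / m, NA_real_)
  out[is.na(x)] <- NA_real_
  out
}

#' Local polarization around a focal individual
#'
#' Polarization restricted to the valid individuals (including the focal)
#' within a given distance of the focal fish. The default radius of 15.6 cm
#' is about three body lengths of a golden shiner.
#'
#' @inheritParams polarization
#' @param focal_id id of the focal individual (must be valid).
#' @param radius neighborhood radius in cm.
#' @return Scalar in `[0, 1]`; 1 if the focal fish is alone in its
#'   neighborhood.
#' @export
local_polarization <- function(frame, focal_id, radius = 15.6) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  k <- which(frame$id == focal_id)
  if (length(k) != 1L) stop("unknown focal id: ", focal_id)
  v <- frame_valid(frame)
  if (!v[k]) stop("focal individual has no valid heading")
  d <- sqrt((frame$x - frame$x[k])^2 + (frame$y - frame$y[k])^2)
  sel <- v & d <= radius
  polarization(frame[sel, , drop = FALSE])
}

#' Radial shell decomposition of the milling state
#'
#' For each frame, the group is divided into `n_shells` concentric shells
#' around its center of mass. The outer radius R is the median distance of
#' the five most peripheral fish; each shell has width `R / n_shells`, and
#' the outermost shell also absorbs fish beyond R. Per shell, the mean
#' individual speed and the rotation order restricted to that shell's fish
#' (with the radial unit vectors still taken from the full-group center of
#' mass) are computed, then averaged over frames weighted by shell
#' occupancy.
#'
#' @param frames a list of frame data.frames (a window of frames), or a
#'   single frame data.frame.
#' @param n_shells number of shells (default 6).
#' @return An object of class `shell_profile`: a data.frame with columns
#'   `shell`, `count`, `mean_speed`, `rotation_order`, plus attribute
#'   `outer_radius` (mean R over frames, cm).
#' @export
shell_profile <- function(frames, n_shells = 6) {
  if (is.data.frame(frames)) frames <- list(frames)
  if (length(frames) == 0L) stop("empty frame window")
  count <- numeric(n_shells)
  speed_sum <- numeric(n_shells)
  rot_wsum <- numeric(n_shells)
  r_sum <- 0
  for (fr in frames) {
    v <- frame_valid(fr)
    if (sum(v) < 5) stop("shell profile needs at least 5 fish per frame")
    x <- fr$x[v]; y <- fr$y[v]
    hx <- fr$heading_x[v]; hy <- fr$heading_y[v]
    sp <- if ("speed" %in% names(fr)) fr$speed[v] else sqrt(fr$vx[v]^2 + fr$vy[v]^2)
    cx <- mean(x); cy <- mean(y)
    rx <- x - cx; ry <- y - cy
    d <- sqrt(rx^2 + ry^2)
    R <- stats::median(sort(d, decreasing = TRUE)[1:5])
    if (R <= 0) stop("degenerate group: all fish at the center of mass")
    r_sum <- r_sum + R
    shell <- pmax(1L, pmin(ceiling(d / (R / n_shells)), n_shells))
    cr <- numeric(length(d))
    nz <- d > 0
    cr[nz] <- (rx[nz] * hy[nz] - ry[nz] * hx[nz]) / d[nz]
    for (s in unique(shell)) {
      sel <- shell == s
      ns <- sum(sel)
      count[s] <- count[s] + ns
      speed_sum[s] <- speed_sum[s] + sum(sp[sel])
      rot_wsum[s] <- rot_wsum[s] + ns * abs(mean(cr[sel]))
    }
  }
  out <- data.frame(
    shell = seq_len(n_shells),
    count = count,
    mean_speed = ifelse(count > 0, speed_sum / count, NA_real_),
    rotation_order = ifelse(count > 0, rot_wsum / count, NA_real_)
  )
  attr(out, "outer_radius") <- r_sum / length(frames)
  class(out) <- c("shell_profile", "data.frame")
  out
}

#' Per-frame order-parameter series of a dataset
#'
#' Computes, for every frame: polarization `o_p`, signed rotation
#' `signed_r`, rotation magnitude `o_r`, mean individual speed and the
#' number of valid individuals. Frames with no valid individual (for
#' `o_p`) or fewer than two (for rotation) hold `NA` -- they are gaps.
#'
#' @param dataset a [trajectory_dataset()] with kinematics derived.
#' @return data.frame of class `order_series` with columns `frame`, `o_p`,
#'   `signed_r`, `o_r`, `mean_speed`, `n_valid`; attribute `fps` carries the
#'   frame rate and `smoothed` is `FALSE`.
#' @seealso [smooth_order_series()]
#' @export
order_series <- function(dataset) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  if (!"valid" %in% names(dataset$frames)) {
    stop("derive kinematics first (see derive_kinematics())")
  }
  fr <- dataset$frames
  idx <- sort(unique(fr$frame))
  split_fr <- split(fr, fr$frame)
  res <- lapply(split_fr, function(f) {
    op <- polarization(f)
    rot <- rotation(f)
    v <- frame_valid(f)
    c(op, rot[["signed"]], rot[["magnitude"]],
      if (any(v)) mean(f$speed[v]) else NA_real_, sum(v))
  })
  m <- do.call(rbind, res)
  out <- data.frame(frame = idx, o_p = m[, 1], signed_r = m[, 2],
                    o_r = m[, 3], mean_speed = m[, 4], n_valid = m[, 5])
  rownames(out) <- NULL
  attr(out, "fps") <- dataset$fps
  attr(out, "smoothed") <- FALSE
  class(out) <- c("order_series", "data.frame")
  out
}

#' Smooth an order-parameter series
#'
#' Applies the centered moving average to `o_p`, `signed_r`, `o_r` and
#' `mean_speed`. The rotation magnitude `o_r` is smoothed from its own raw
#' magnitude series (not recomputed as the absolute smoothed signed
#' rotation), so a mill that flips handedness does not register as a drop
#' to zero rotation.
#'
#' @param series an `order_series` from [order_series()].
#' @param span smoothing span in frames (default 30, i.e. 1 s at 30 fps).
#' @return The smoothed series, with attributes `smoothed = TRUE` and
#'   `smoothing_span`.
#' @export
smooth_order_series <- function(series, span = 30) {
  stopifnot(inherits(series, "order_series"))
  for (cc in c("o_p", "signed_r", "o_r", "mean_speed")) {
    series[[cc]] <- smooth_series(series[[cc]], span)
  }
  attr(series, "smoothed") <- TRUE
  attr(series, "smoothing_span") <- span
  series
}

#' Per-fish local polarization and speed samples
#'
#' Evaluates [local_polarization()] for every valid fish in every frame,
#' paired with that fish's speed -- the raw material of the
#' speed-versus-local-order conditional curves.
#'
#' @inheritParams order_series
#' @param radius neighborhood radius in cm (default 15.6).
#' @return data.frame with columns `frame`, `id`, `speed`, `local_o_p`.
#' @export
local_polarization_series <- function(dataset, radius = 15.6) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  fr <- dataset$frames
  if (!"valid" %in% names(fr)) stop("derive kinematics first")
  out <- lapply(split(fr, fr$frame), function(f) {
    v <- frame_valid(f)
    if (!any(v)) return(NULL)
    x <- f$x; y <- f$y
    lp <- vapply(which(v), function(k) {
      d <- sqrt((x - x[k])^2 + (y - y[k])^2)
      sel <- v & d <= radius
      polarization(f[sel, , drop = FALSE])
    }, numeric(1))
    data.frame(frame = f$frame[v], id = f$id[v], speed = f$speed[v],
               local_o_p = lp)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
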