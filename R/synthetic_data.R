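# Synthetic-data generators: analytic archetype frames, scripted
# state-switching order-parameter series, and noisy bounded-tank school
# trajectories. They make every pipeline stage testable without any
# experimental recording.

# default (o_p, o_r) anchors: centers of the high-density regions of the
# three states in the rotation-polarization plane
default_anchors <- function() {
  list(P = c(o_p = 0.85, o_r = 0.10),
       M = c(o_p = 0.10, o_r = 0.85),
       S = c(o_p = 0.15, o_r = 0.15))
}

#' Archetypal single-frame configurations
#'
#' Builds an idealized frame of each collective state: `"polarized"` (one
#' common heading, jittered positions), `"mill"` (fish on concentric rings
#' with tangential headings of one handedness) and `"swarm"` (uniform
#' positions in a disc with independent uniform headings).
#'
#' @param kind one of `"polarized"`, `"mill"`, `"swarm"`.
#' @param n number of fish (`>= 3` for a mill).
#' @param center group center, length-2 numeric (cm).
#' @param radius group radius in cm (disc radius, or outermost ring).
#' @param heading travel direction in radians (polarized only).
#' @param handedness `+1` for counter-clockwise, `-1` for clockwise (mill
#'   only).
#' @param rings number of concentric rings for the mill (default 1).
#' @param speed individual speed in cm/s written into the velocity columns.
#' @return A frame data.frame with columns `id`, `x`, `y`, `vx`, `vy`,
#'   `heading_x`, `heading_y`, `speed`, `valid`.
#' @export
make_archetype <- function(kind = c("polarized", "mill", "swarm"), n,
                           center = c(0, 0), radius = 20, heading = 0,
                           handedness = 1, rings = 1, speed = 5) {
  kind <- match.arg(kind)
  if (kind == "mill" && n < 3) stop("a mill needs at least 3 fish")
  if (n < 1) stop("n must be >= 1")
  if (kind == "polarized") {
    r <- radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    x <- center[1] + r * cos(th)
    y <- center[2] + r * sin(th)
    hx <- rep(cos(heading), n); hy <- rep(sin(heading), n)
  } else if (kind == "mill") {
    ring <- rep(seq_len(rings), length.out = n)
    ring <- sort(ring)
    x <- y <- hx <- hy <- numeric(n)
    for (k in seq_len(rings)) {
      idx <- which(ring == k)
      m <- length(idx)
      rad <- radius * k / rings
      phi <- 2 * pi * (seq_len(m) - 1) / m + (k - 1) * pi / (4 * rings)
      x[idx] <- center[1] + rad * cos(phi)
      y[idx] <- center[2] + rad * sin(phi)
      hx[idx] <- -sin(phi) * handedness
      hy[idx] <- cos(phi) * handedness
    }
  } else {
    r <- radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    x <- center[1] + r * cos(th)
    y <- center[2] + r * sin(th)
    ang <- stats::runif(n, 0, 2 * pi)
    hx <- cos(ang); hy <- sin(ang)
  }
  data.frame(id = seq_len(n), x = x, y = y,
             vx = speed * hx, vy = speed * hy,
             heading_x = hx, heading_y = hy,
             speed = rep(speed, n), valid = TRUE)
}

#' Scripted state-switching order-parameter series
#'
#' Generates an order-parameter time series that dwells near each scripted
#' state's anchor point with Gaussian fluctuations and ramps linearly
#' between anchors over a fixed transition duration, together with the
#' ground-truth per-frame labels (ramp frames are labeled `T`).
#'
#' @param script data.frame with columns `label` (each of `"S"`, `"P"`,
#'   `"M"`) and `dwell_s` (seconds, > 0).
#' @param fps frame rate (default 30).
#' @param anchors named list of `(o_p, o_r)` anchor points per label; the
#'   defaults sit in the centers of the three state regions.
#' @param sd Gaussian fluctuation standard deviation (default 0.02; values
#'   are clipped to `[0, 1]`).
#' @param ramp_s transition ramp duration in seconds (default 2).
#' @param handedness sign of the signed rotation during milling (default
#'   `+1`, counter-clockwise; recycled over milling segments).
#' @param speeds named numeric: mean individual speed (cm/s) written into
#'   the series per state (defaults S = 2, P = 10, M = 8).
#' @return List with `series` (an unsmoothed `order_series`) and `truth`
#'   (character vector of per-frame ground-truth labels).
#' @export
make_state_series <- function(script, fps = 30, anchors = default_anchors(),
                              sd = 0.02, ramp_s = 2, handedness = 1,
                              speeds = c(S = 2, P = 10, M = 8)) {
  if (!all(c("label", "dwell_s") %in% names(script))) {
    stop("script needs columns label and dwell_s")
  }
  if (any(script$dwell_s <= 0)) stop("dwell times must be > 0")
  k_default <- 0.35
  for (j in seq_len(nrow(script))) {
    lab <- script$label[j]
    if (!lab %in% names(anchors)) stop("no anchor for label ", lab)
    a <- anchors[[lab]]
    if (classify_point(a[["o_p"]], a[["o_r"]], k_default) != lab) {
      stop("anchor for ", lab, " lies outside its state region")
    }
  }
  hand <- rep_len(handedness, sum(script$label == "M"))
  m_seen <- 0L
  o_p <- o_r <- spd <- numeric(0)
  truth <- character(0)
  prev <- NULL
  for (j in seq_len(nrow(script))) {
    lab <- script$label[j]
    a <- anchors[[lab]]
    nf <- max(1L, round(script$dwell_s[j] * fps))
    if (!is.null(prev) && ramp_s > 0) {
      nr <- max(1L, round(ramp_s * fps))
      w <- seq_len(nr) / (nr + 1)
      o_p <- c(o_p, prev[["o_p"]] + w * (a[["o_p"]] - prev[["o_p"]]))
      o_r <- c(o_r, prev[["o_r"]] + w * (a[["o_r"]] - prev[["o_r"]]))
      spd <- c(spd, prev_speed + w * (speeds[[lab]] - prev_speed))
      truth <- c(truth, rep("T", nr))
    }
    o_p <- c(o_p, rep(a[["o_p"]], nf))
    o_r <- c(o_r, rep(a[["o_r"]], nf))
    spd <- c(spd, rep(speeds[[lab]], nf))
    truth <- c(truth, rep(lab, nf))
    prev <- a
    prev_speed <- speeds[[lab]]
  }
  n <- length(o_p)
  if (sd > 0) {
    o_p <- pmin(pmax(o_p + stats::rnorm(n, 0, sd), 0), 1)
    o_r <- pmin(pmax(o_r + stats::rnorm(n, 0, sd), 0), 1)
  }
  sign_vec <- rep(1, n)
  if (m_seen <- any(script$label == "M")) {
    # assign the scripted handedness to milling frames in order
    m_runs <- rle(truth == "M")
    ends <- cumsum(m_runs$lengths)
    starts <- ends - m_runs$lengths + 1L
    mi <- 0L
    for (q in seq_along(m_runs$values)) {
      if (!m_runs$values[q]) next
      mi <- mi + 1L
      sign_vec[starts[q]:ends[q]] <- hand[mi]
    }
  }
  series <- data.frame(frame = seq_len(n) - 1L, o_p = o_p,
                       signed_r = sign_vec * o_r, o_r = o_r,
                       mean_speed = spd, n_valid = NA_real_)
  attr(series, "fps") <- fps
  attr(series, "smoothed") <- FALSE
  class(series) <- c("order_series", "data.frame")
  list(series = series, truth = truth)
}

# phyllotaxis disc packing: n deterministic offsets with ~equal spacing
sunflower_offsets <- function(n, radius) {
  k <- seq_len(n)
  r <- radius * sqrt((k - 0.5) / n)
  th <- k * pi * (3 - sqrt(5))
  cbind(r * cos(th), r * sin(th))
}

reflect_into <- function(v, lo, hi) {
  # reflect a scalar into [lo, hi]; returns c(value, flipped)
  flipped <- FALSE
  while (v < lo || v > hi) {
    if (v < lo) v <- 2 * lo - v else v <- 2 * hi - v
    flipped <- !flipped
  }
  c(v, flipped)
}

#' Scripted bounded-tank school trajectories
#'
#' Generates a full trajectory table realizing a state script inside a
#' rectangular tank: milling segments rotate the group about a slowly
#' drifting center, polarized segments translate the group and reflect it
#' off the walls, swarm segments jitter at low speed with shrunken
#' spacing, and segments are joined by linear position ramps (ground truth
#' `T`). Swarm speed is lower than polarized/milling speed, reproducing
#' the state-speed association of real schools.
#'
#' @param script data.frame with columns `label`, `dwell_s`.
#' @param tank a [tank_geometry()] (default 210 x 120 cm).
#' @param n number of fish (default 60).
#' @param fps frame rate (default 30).
#' @param speeds named numeric of target speeds in cm/s per state
#'   (defaults S = 2, P = 10, M = 8).
#' @param spacing typical inter-fish spacing in cm (default 4); the group
#'   radius scales as `spacing * sqrt(n / pi)`.
#' @param ramp_s duration of the inter-state ramps in seconds (default 2).
#' @return List with `dataset` (a [trajectory_dataset()]) and `truth`
#'   (per-frame ground-truth labels, one per frame of the dataset).
#' @export
make_bounded_school <- function(script, tank = tank_geometry(210, 120),
                                n = 60, fps = 30,
                                speeds = c(S = 2, P = 10, M = 8),
                                spacing = 4, ramp_s = 2) {
  stopifnot(inherits(tank, "tank_geometry"))
  r_g <- spacing * sqrt(n / pi)
  margin <- r_g + 2 * spacing
  if (2 * margin >= tank$width || 2 * margin >= tank$height) {
    stop("tank too small for a group of this size and spacing")
  }
  offsets <- sunflower_offsets(n, r_g)
  center <- c(tank$width / 2, tank$height / 2)
  theta <- stats::runif(1, 0, 2 * pi)
  pos_list <- list()
  truth <- character(0)
  last_pos <- NULL

  segment_positions <- function(lab, nf, center0, theta0) {
    # returns list(pos = list of n x 2, center, theta)
    cen <- center0; th <- theta0
    out <- vector("list", nf)
    if (lab == "P") {
      step_len <- speeds[["P"]] / fps
      for (t in seq_len(nf)) {
        th <- th + stats::rnorm(1, 0, 0.02)
        cen <- cen + step_len * c(cos(th), sin(th))
        rx <- reflect_into(cen[1], margin, tank$width - margin)
        if (rx[2] == 1) th <- pi - th
        cen[1] <- rx[1]
        ry <- reflect_into(cen[2], margin, tank$height - margin)
        if (ry[2] == 1) th <- -th
        cen[2] <- ry[1]
        out[[t]] <- sweep(offsets, 2, cen, `+`)
      }
    } else if (lab == "M") {
      rad <- pmax(0.35 * r_g, sqrt(offsets[, 1]^2 + offsets[, 2]^2))
      phi <- atan2(offsets[, 2], offsets[, 1])
      omega <- speeds[["M"]] / (0.7 * r_g) / fps   # rad per frame
      for (t in seq_len(nf)) {
        cen <- cen + stats::rnorm(2, 0, 0.05)
        cen[1] <- reflect_into(cen[1], margin, tank$width - margin)[1]
        cen[2] <- reflect_into(cen[2], margin, tank$height - margin)[1]
        phi <- phi + omega
        out[[t]] <- cbind(cen[1] + rad * cos(phi), cen[2] + rad * sin(phi))
      }
    } else {  # swarm: shrunken blob, slow independent jitter
      e <- matrix(0, n, 2)
      target <- speeds[["S"]] / fps
      for (t in seq_len(nf)) {
        e <- 0.85 * e + matrix(stats::rnorm(2 * n, 0, 1.2 * target), n, 2)
        out[[t]] <- sweep(0.6 * offsets + e, 2, cen, `+`)
      }
    }
    list(pos = out, center = cen, theta = th)
  }

  for (j in seq_len(nrow(script))) {
    lab <- script$label[j]
    nf <- max(1L, round(script$dwell_s[j] * fps))
    seg <- segment_positions(lab, nf, center, theta)
    if (!is.null(last_pos) && ramp_s > 0) {
      nr <- max(1L, round(ramp_s * fps))
      first <- seg$pos[[1]]
      for (t in seq_len(nr)) {
        w <- t / (nr + 1)
        pos_list[[length(pos_list) + 1L]] <- (1 - w) * last_pos + w * first
        truth <- c(truth, "T")
      }
    }
    pos_list <- c(pos_list, seg$pos)
    truth <- c(truth, rep(lab, nf))
    center <- seg$center
    theta <- seg$theta
    last_pos <- seg$pos[[nf]]
  }

  nfr <- length(pos_list)
  px <- vapply(pos_list, function(p) p[, 1], numeric(n))
  py <- vapply(pos_list, function(p) p[, 2], numeric(n))
  px <- pmin(pmax(px, 0), tank$width)
  py <- pmin(pmax(py, 0), tank$height)
  vx <- cbind(t(apply(px, 1, diff)) * fps)
  vy <- cbind(t(apply(py, 1, diff)) * fps)
  vx <- cbind(vx, vx[, ncol(vx)])
  vy <- cbind(vy, vy[, ncol(vy)])
  frames <- data.frame(
    frame = rep(seq_len(nfr) - 1L, each = n),
    id = rep(seq_len(n), nfr),
    x = as.vector(px), y = as.vector(py),
    vx = as.vector(vx), vy = as.vector(vy))
  ds <- trajectory_dataset(frames, fps = fps, tank_width = tank$width,
                           tank_height = tank$height)
  list(dataset = ds, truth = truth)
}
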