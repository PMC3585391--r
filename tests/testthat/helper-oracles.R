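# Independent brute-force oracles used to cross-check the implementation.

# random frame of n fish with unit headings
random_frame <- function(n, seed = NULL, box = 50) {
  if (!is.null(seed)) set.seed(seed)
  ang <- runif(n, 0, 2 * pi)
  data.frame(id = seq_len(n),
             x = runif(n, 0, box), y = runif(n, 0, box),
             heading_x = cos(ang), heading_y = sin(ang),
             speed = runif(n, 1, 10), valid = TRUE)
}

# per-fish loop evaluation of the polarization order parameter
op_oracle <- function(frame) {
  sx <- 0; sy <- 0; n <- 0
  for (k in seq_len(nrow(frame))) {
    if (!frame$valid[k]) next
    sx <- sx + frame$heading_x[k]
    sy <- sy + frame$heading_y[k]
    n <- n + 1
  }
  sqrt((sx / n)^2 + (sy / n)^2)
}

# per-fish loop evaluation of the signed rotation order parameter
rot_oracle <- function(frame) {
  sel <- frame$valid
  cx <- mean(frame$x[sel]); cy <- mean(frame$y[sel])
  s <- 0; n <- 0
  for (k in seq_len(nrow(frame))) {
    if (!frame$valid[k]) next
    rx <- frame$x[k] - cx; ry <- frame$y[k] - cy
    d <- sqrt(rx^2 + ry^2)
    if (d > 0) s <- s + (rx * frame$heading_y[k] - ry * frame$heading_x[k]) / d
    n <- n + 1
  }
  s / n
}

# brute-force transition scan: drop T and NA from the raw label sequence,
# collapse repeats, count changes
label_scan_oracle <- function(labels) {
  core <- labels[!is.na(labels) & labels != "T"]
  if (length(core) == 0) return(character(0))
  core <- rle(core)$values
  if (length(core) < 2) return(character(0))
  paste(core[-length(core)], core[-1], sep = "->")
}

# Monte-Carlo area of a group_shape by point-in-kept-triangle sampling
mc_area_oracle <- function(shape, n_samples = 200000, seed = 1) {
  set.seed(seed)
  pts <- shape$points
  tri <- shape$triangles
  if (nrow(tri) == 0) return(0)
  bx <- range(pts$x); by <- range(pts$y)
  qx <- runif(n_samples, bx[1], bx[2])
  qy <- runif(n_samples, by[1], by[2])
  inside <- rep(FALSE, n_samples)
  for (k in seq_len(nrow(tri))) {
    ax <- pts$x[tri[k, 1]]; ay <- pts$y[tri[k, 1]]
    bxx <- pts$x[tri[k, 2]]; byy <- pts$y[tri[k, 2]]
    cx <- pts$x[tri[k, 3]]; cy <- pts$y[tri[k, 3]]
    d1 <- (qx - bxx) * (ay - byy) - (ax - bxx) * (qy - byy)
    d2 <- (qx - cx) * (byy - cy) - (bxx - cx) * (qy - cy)
    d3 <- (qx - ax) * (cy - ay) - (cx - ax) * (qy - ay)
    neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
    pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
    inside <- inside | !(neg & pos)
  }
  mean(inside) * diff(bx) * diff(by)
}

# convex hull area by the shoelace formula
hull_area_oracle <- function(x, y) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# one synchronous noise-free zonal-model step in plain R, built on the
# exported desired_direction() reference
r_step_oracle <- function(positions, headings, cfg) {
  n <- nrow(positions)
  turn_max <- cfg$turn_rate * cfg$dt * pi / 180
  new_head <- headings
  for (i in seq_len(n)) {
    des <- desired_direction(i, positions, headings, cfg)
    cur <- atan2(headings[i, 2], headings[i, 1])
    dth <- atan2(des[2], des[1]) - cur
    dth <- ((dth + pi) %% (2 * pi)) - pi
    dth <- max(min(dth, turn_max), -turn_max)
    new_head[i, ] <- c(cos(cur + dth), sin(cur + dth))
  }
  list(positions = positions + cfg$speed * cfg$dt * new_head,
       headings = new_head)
}

# tiny trajectory CSV on disk for reader tests
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

default_meta <- function() {
  list(fps = 30, tank_width_cm = 210, tank_height_cm = 120,
       body_length_cm = 5.2)
}
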