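# Constant-speed zonal agent-based model.
#
# Each agent carries three concentric behavioral zones: repulsion (radius
# 1), orientation (3) and attraction (15), in model length units, with a
# 270 degree field of perception (a 90 degree blind sector behind the
# agent applies to every zone). Any visible neighbor inside the repulsion
# zone overrides all else; otherwise the normalized orientation and
# attraction responses are averaged. The desired direction is perturbed by
# Gaussian angular noise, the heading rotates toward it no faster than the
# turn-rate limit, and the agent advances at constant speed.

#' Zonal-model configuration
#'
#' @param n number of agents.
#' @param speed agent speed in model length units per unit time.
#' @param steps number of time steps (default 2500).
#' @param r_repulsion,r_orientation,r_attraction zone radii (defaults 1, 3,
#'   15 model units; must be strictly increasing).
#' @param field_of_perception visual field in degrees (default 270; the
#'   remaining sector behind the agent is blind).
#' @param turn_rate maximum turning rate in degrees per unit time (default
#'   60, i.e. 6 degrees per step at `dt = 0.1`).
#' @param noise_sd standard deviation of the Gaussian angular noise applied
#'   to the desired direction, in radians (default 0.2).
#' @param dt time step (default 0.1).
#' @param seed optional integer seed used by [run_sim()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n, speed, steps = 2500, r_repulsion = 1,
                       r_orientation = 3, r_attraction = 15,
                       field_of_perception = 270, turn_rate = 60,
                       noise_sd = 0.2, dt = 0.1, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be a positive integer")
  if (!is.numeric(speed) || speed <= 0) stop("speed must be > 0")
  if (!(r_repulsion > 0 && r_repulsion < r_orientation &&
        r_orientation < r_attraction)) {
    stop("zone radii must satisfy 0 < repulsion < orientation < attraction")
  }
  if (field_of_perception <= 0 || field_of_perception > 360) {
    stop("field_of_perception must lie in (0, 360]")
  }
  structure(
    list(n = as.integer(n), speed = speed, steps = as.integer(steps),
         r_repulsion = r_repulsion, r_orientation = r_orientation,
         r_attraction = r_attraction,
         field_of_perception = field_of_perception,
         turn_rate = turn_rate, noise_sd = noise_sd, dt = dt, seed = seed,
         dimension = 2L),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> n=%d speed=%.2f steps=%d zones=%.1f/%.1f/%.1f fop=%.0f deg turn=%.0f deg/t noise=%.2f rad dt=%.2f\n",
    x$n, x$speed, x$steps, x$r_repulsion, x$r_orientation, x$r_attraction,
    x$field_of_perception, x$turn_rate, x$noise_sd, x$dt))
  invisible(x)
}

#' Desired direction of one agent (reference implementation)
#'
#' Plain-R statement of the zonal interaction rule, used to document and
#' cross-check the compiled simulation core. Neighbors outside the field of
#' perception are invisible for every zone. If any visible neighbor lies
#' within the repulsion radius, the desired direction is the normalized sum
#' of the unit vectors pointing away from those neighbors, overriding all
#' else. Otherwise the mean heading of visible orientation-zone neighbors
#' and the normalized attraction vector toward visible attraction-zone
#' neighbors are each normalized and averaged (each term only if its
#' neighbor set is non-empty). With no visible neighbors, or a
#' zero-magnitude response, the current heading is retained.
#'
#' @param i focal agent index.
#' @param positions n x 2 matrix of agent positions.
#' @param headings n x 2 matrix of unit headings.
#' @param cfg a [sim_config()].
#' @return Unit vector of length 2.
#' @export
desired_direction <- function(i, positions, headings, cfg) {
  n <- nrow(positions)
  if (i < 1 || i > n) stop("focal index out of range")
  cos_blind <- cos(cfg$field_of_perception / 2 * pi / 180)
  rep_v <- c(0, 0); ori_v <- c(0, 0); att_v <- c(0, 0)
  has_rep <- has_ori <- has_att <- FALSE
  for (j in seq_len(n)) {
    if (j == i) next
    d_ij <- positions[j, ] - positions[i, ]
    d <- sqrt(sum(d_ij^2))
    if (d > cfg$r_attraction || d < 1e-9) next
    if (sum(headings[i, ] * d_ij) < cos_blind * d) next
    if (d <= cfg$r_repulsion) {
      rep_v <- rep_v - d_ij / d; has_rep <- TRUE
    } else if (d <= cfg$r_orientation) {
      ori_v <- ori_v + headings[j, ]; has_ori <- TRUE
    } else {
      att_v <- att_v + d_ij / d; has_att <- TRUE
    }
  }
  normalize <- function(v) {
    m <- sqrt(sum(v^2))
    if (m > 1e-9) v / m else NULL
  }
  des <- if (has_rep) {
    normalize(rep_v)
  } else if (has_ori || has_att) {
    parts <- list()
    if (has_ori) parts <- c(parts, list(normalize(ori_v)))
    if (has_att) parts <- c(parts, list(normalize(att_v)))
    parts <- Filter(Negate(is.null), parts)
    if (length(parts) > 0) normalize(Reduce(`+`, parts)) else NULL
  } else NULL
  if (is.null(des)) headings[i, ] else des
}

init_agents <- function(cfg) {
  r <- cfg$r_attraction * sqrt(stats::runif(cfg$n))
  th <- stats::runif(cfg$n, 0, 2 * pi)
  ang <- stats::runif(cfg$n, 0, 2 * pi)
  list(positions = cbind(r * cos(th), r * sin(th)),
       headings = cbind(cos(ang), sin(ang)))
}

#' Run one zonal-model simulation
#'
#' Agents are initialized uniformly at random in a disc of radius
#' `r_attraction` with uniform random headings, stepped for `cfg$steps`
#' steps, and the order parameters of the final step are returned.
#'
#' @param cfg a [sim_config()].
#' @param record if `TRUE`, also return the per-step `(O_p, signed
#'   rotation)` series.
#' @param init optional list with `positions` and `headings` matrices,
#'   overriding the random initialization.
#' @return List with `o_p`, `o_r`, `signed_r` (final step), the final
#'   `frame` (data.frame usable by [polarization()] / [rotation()]), and
#'   `series` (data.frame `step`, `o_p`, `signed_r`) when recorded.
#' @export
run_sim <- function(cfg, record = FALSE, init = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(init)) init <- init_agents(cfg)
  res <- zonal_run_cpp(
    init$positions, init$headings, cfg$steps, cfg$speed, cfg$dt,
    cfg$r_repulsion, cfg$r_orientation, cfg$r_attraction,
    cos(cfg$field_of_perception / 2 * pi / 180),
    cfg$turn_rate * cfg$dt * pi / 180, cfg$noise_sd, record)
  frame <- data.frame(
    id = seq_len(cfg$n),
    x = res$positions[, 1], y = res$positions[, 2],
    heading_x = res$headings[, 1], heading_y = res$headings[, 2],
    speed = cfg$speed, valid = TRUE)
  rot <- rotation(frame)
  out <- list(o_p = polarization(frame), o_r = rot[["magnitude"]],
              signed_r = rot[["signed"]], frame = frame)
  if (record) {
    out$series <- data.frame(step = seq_len(cfg$steps),
                             o_p = res$series[, 1],
                             signed_r = res$series[, 2])
  }
  out
}

#' Speed-sweep experiment
#'
#' Runs independent replicates of the zonal model across a grid of speeds
#' and records the final-step order parameters of each run -- the raw
#' material of the speed-order phase diagrams.
#'
#' @param cfg a [sim_config()] providing all parameters except speed.
#' @param speeds speed grid (default `seq(0.1, 4.1, by = 0.1)`).
#' @param replicates independent replicates per speed (default 500).
#' @param base_seed integer; replicate seeds are derived from it by a
#'   counter, so the whole sweep is reproducible.
#' @return data.frame with columns `speed`, `replicate`, `o_p`, `o_r`,
#'   `signed_r`, `state` (classification of the final point at the default
#'   threshold).
#' @export
speed_sweep <- function(cfg, speeds = seq(0.1, 4.1, by = 0.1),
                        replicates = 500, base_seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (replicates < 1) stop("replicates must be >= 1")
  counter <- 0L
  rows <- vector("list", length(speeds) * replicates)
  for (s in speeds) {
    for (r in seq_len(replicates)) {
      counter <- counter + 1L
      cfg_r <- cfg
      cfg_r$speed <- s
      cfg_r$seed <- as.integer(base_seed) + counter
      res <- run_sim(cfg_r)
      rows[[counter]] <- data.frame(
        speed = s, replicate = r, o_p = res$o_p, o_r = res$o_r,
        signed_r = res$signed_r, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$state <- classify_point(pmin(out$o_p, 1), pmin(out$o_r, 1))
  rownames(out) <- NULL
  out
}
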