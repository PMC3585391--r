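# End-to-end analysis pipeline: one call from a trajectory table to the
# full bundle of state, transition, geometry and phase-space summaries.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default: state
#' threshold `k = 0.35`, smoothing span 30 frames (1 s at 30 fps), local
#' polarization radius 15.6 cm (~3 body lengths), alpha probe radius one
#' body length, fish body area 3.38 cm^2, phase-map support thresholds
#' 100 (occupancy/mean maps) and 20 (transition maps), and a 1 s minimum
#' transitional-visit duration.
#'
#' @param k state threshold in `(0, 0.5)`.
#' @param smooth_span smoothing span in frames.
#' @param local_radius local polarization neighborhood radius (cm).
#' @param alpha_radius alpha-shape probe radius (cm).
#' @param body_area fish body area (cm^2).
#' @param min_count,min_count_transition phase-map support thresholds.
#' @param min_t_duration_s minimum qualifying transitional-visit duration (s).
#' @param speed_floor heading-defining speed floor (cm/s).
#' @param seed optional integer seed recorded in the manifest.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(k = 0.35, smooth_span = 30, local_radius = 15.6,
                            alpha_radius = 5.2, body_area = 3.38,
                            min_count = 100, min_count_transition = 20,
                            min_t_duration_s = 1, speed_floor = 1e-6,
                            seed = NULL) {
  structure(
    list(k = k, smooth_span = smooth_span, local_radius = local_radius,
         alpha_radius = alpha_radius, body_area = body_area,
         min_count = min_count, min_count_transition = min_count_transition,
         min_t_duration_s = min_t_duration_s, speed_floor = speed_floor,
         seed = seed),
    class = "analysis_config")
}

# deterministic FNV-1a style hash of the configuration, stamped into every
# export header so reruns are identifiable
manifest_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    collapse = ";")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' From a trajectory dataset (or a file path plus metadata) computes: the
#' smoothed order-parameter series with per-frame geometry (packing
#' fraction and boundary distance), state labels, visits, completed
#' transitions with phase-space paths, summary statistics (state time
#' fractions, transition rate and destination fractions, completion
#' fraction, milling handedness, persistence curves), the phase-space
#' occupancy map, a mean-speed map, the speed-versus-local-order
#' conditional curves, and the radial shell profile of the milling frames.
#'
#' @param x a [trajectory_dataset()] or a file path for
#'   [load_trajectories()].
#' @param config an [analysis_config()].
#' @param meta metadata list, required when `x` is a path.
#' @param geometry if `TRUE` (default), compute per-frame alpha-shape
#'   packing fraction and boundary distance (cost grows as the square of
#'   the group size per frame).
#' @param local if `TRUE` (default), compute per-fish local polarization
#'   samples and the conditional curves.
#' @return List of class `school_analysis` with elements `series`,
#'   `labels`, `visits`, `events`, `summary`, `occupancy`, `speed_map`,
#'   `curves`, `shells`, `manifest`.
#' @export
analyze <- function(x, config = analysis_config(), meta = NULL,
                    geometry = TRUE, local = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  ds <- if (inherits(x, "trajectory_dataset")) x else load_trajectories(x, meta)
  ds <- derive_kinematics(ds, config$speed_floor)
  ser <- order_series(ds)

  tank <- tank_geometry(ds$tank_width, ds$tank_height)
  if (geometry) {
    frames <- split(ds$frames, ds$frames$frame)
    geo <- vapply(frames, function(f) {
      pf <- tryCatch(packing_fraction(f, config$body_area,
                                      config$alpha_radius),
                     error = function(e) NA_real_)
      db <- tryCatch(boundary_distance(f, tank),
                     error = function(e) NA_real_)
      c(pf, db)
    }, numeric(2))
    ser$packing_fraction <- geo[1, ]
    ser$d_b <- geo[2, ]
  }

  raw_ser <- ser
  ser <- smooth_order_series(ser, config$smooth_span)
  labels <- label_series(ser, config$k)
  visits <- extract_visits(labels, attr(ser, "fps"))
  events <- completed_transitions(visits, ser)
  total_min <- sum(visits$duration) / 60

  summary <- list(
    n_frames = nrow(ser),
    total_duration_min = total_min,
    state_fractions = state_time_fractions(visits),
    transition = transition_stats(events, total_min),
    completion = tryCatch(
      transition_completion_fraction(visits, config$min_t_duration_s),
      error = function(e) NULL),
    handedness = milling_handedness(ser$signed_r, visits),
    persistence = lapply(
      setNames(nm = intersect(c("S", "P", "M", "T"), visits$label)),
      function(l) persistence_survival(visits, l))
  )

  ok <- !is.na(ser$o_r) & !is.na(ser$o_p)
  pts <- cbind(pmin(ser$o_r[ok], 1), pmin(ser$o_p[ok], 1))
  occupancy <- phase_histogram(pts, config$min_count)
  speed_map <- phase_mean_map(pts, ser$mean_speed[ok], config$min_count)

  curves <- NULL
  if (local) {
    lp <- local_polarization_series(ds, config$local_radius)
    curves <- tryCatch(
      conditional_mean_curves(lp$speed, pmin(lp$local_o_p, 1)),
      error = function(e) NULL)
  }

  shells <- NULL
  m_frames <- ser$frame[!is.na(labels) & labels == "M"]
  if (length(m_frames) > 0) {
    fl <- split(ds$frames, ds$frames$frame)
    fl <- fl[as.character(m_frames)]
    fl <- Filter(function(f) sum(frame_valid(f)) >= 5, fl)
    if (length(fl) > 0) {
      shells <- tryCatch(shell_profile(fl), error = function(e) NULL)
    }
  }

  structure(
    list(series = ser, raw_series = raw_ser, labels = labels,
         visits = visits, events = events, summary = summary,
         occupancy = occupancy, speed_map = speed_map, curves = curves,
         shells = shells,
         manifest = list(config = config, seed = config$seed,
                         hash = manifest_hash(config),
                         package_version =
                           as.character(utils::packageVersion("schoolstates")))),
    class = "school_analysis")
}

#' @export
print.school_analysis <- function(x, ...) {
  sf <- x$summary$state_fractions
  cat(sprintf(
    "<school_analysis> %d frames (%.1f min), %d visits, %d completed transitions\n",
    x$summary$n_frames, x$summary$total_duration_min, nrow(x$visits),
    nrow(x$events)))
  cat(sprintf("  time fractions: S %.2f  P %.2f  M %.2f  T %.2f\n",
              sf[["S"]], sf[["P"]], sf[["M"]], sf[["T"]]))
  cat(sprintf("  transition rate: %.2f / min   manifest %s\n",
              x$summary$transition$rate_per_min, x$manifest$hash))
  invisible(x)
}

#' Write the analysis bundle as delimited text files
#'
#' Exports the order series, visits, transitions, summary key-value
#' report, phase occupancy and mean-speed grids, conditional curves and
#' shell profile. Every file starts with a comment header carrying the
#' manifest hash and the axis convention (O_r first axis, O_p second).
#'
#' @param analysis a `school_analysis` from [analyze()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "school_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# manifest %s; axes: o_r first, o_p second",
                 analysis$manifest$hash)
  put <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
    close(con)
  }
  put(as.data.frame(analysis$series), "order_series.csv")
  put(as.data.frame(analysis$visits), "visits.csv")
  ev <- analysis$events
  ev$path <- NULL
  put(as.data.frame(ev), "transitions.csv")
  s <- analysis$summary
  kv <- c(
    sprintf("n_frames=%d", s$n_frames),
    sprintf("total_duration_min=%.6f", s$total_duration_min),
    sprintf("fraction_%s=%.6f", names(s$state_fractions), s$state_fractions),
    sprintf("rate_per_min=%.6f", s$transition$rate_per_min),
    if (!is.null(s$completion)) c(
      sprintf("completion_fraction=%.6f", s$completion$fraction),
      sprintf("n_completed=%d", s$completion$n_completed),
      sprintf("n_t_visits=%d", s$completion$n_visits)),
    sprintf("handedness_cw=%d", s$handedness[["n_clockwise"]]),
    sprintf("handedness_ccw=%d", s$handedness[["n_counterclockwise"]]))
  writeLines(c(hdr, kv), file.path(dir, "summary.txt"))
  put(as.data.frame(analysis$occupancy$value), "phase_occupancy.csv")
  put(as.data.frame(analysis$speed_map$value), "phase_speed.csv")
  if (!is.null(analysis$curves)) {
    put(analysis$curves$by_speed, "curve_by_speed.csv")
    put(analysis$curves$by_order, "curve_by_order.csv")
  }
  if (!is.null(analysis$shells)) {
    put(as.data.frame(analysis$shells), "shell_profile.csv")
  }
  invisible(dir)
}

#' Speed sweeps and phase maps across group sizes
#'
#' Runs the zonal-model speed sweep for several group sizes and bins each
#' group's final-state order parameters into a phase-space occupancy map.
#'
#' @param n_values group sizes (default `c(30, 70, 150, 300)`).
#' @param speeds speed grid passed to [speed_sweep()].
#' @param replicates replicates per speed.
#' @param steps simulation steps per run (default 2500).
#' @param base_seed integer seed; each group size uses an offset block.
#' @param min_count support threshold for the occupancy maps (default 1:
#'   simulated points are few compared with experimental frame counts).
#' @return List with `sweep` (row-bound sweep tables with an `n` column)
#'   and `grids` (named list of `phase_grid`s, one per group size).
#' @export
sweep_and_phase <- function(n_values = c(30, 70, 150, 300),
                            speeds = seq(0.1, 4.1, by = 0.1),
                            replicates = 500, steps = 2500, base_seed = 1L) {
  tabs <- list()
  grids <- list()
  for (i in seq_along(n_values)) {
    n <- n_values[i]
    cfg <- sim_config(n = n, speed = 1, steps = steps)
    tab <- speed_sweep(cfg, speeds, replicates,
                       base_seed = as.integer(base_seed) + (i - 1L) * 100000L)
    tab$n <- n
    tabs[[i]] <- tab
    grids[[as.character(n)]] <- phase_histogram(
      cbind(pmin(tab$o_r, 1), pmin(tab$o_p, 1)), min_count = 1)
  }
  list(sweep = do.call(rbind, tabs), grids = grids)
}
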