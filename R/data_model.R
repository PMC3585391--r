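# Trajectory data model: per-frame positions and velocities of identified
# individuals in a rectangular tank, with derived headings and speeds.
#
# Units are centimetres and seconds throughout; frame indices are integers
# (0-based by convention, but any strictly ordered integers work) and the
# time of frame f is f / fps.

#' Construct a trajectory dataset
#'
#' Bundles a per-frame trajectory table with its acquisition metadata and
#' validates the basic invariants: positive metadata, positions inside the
#' tank, unique individual ids within each frame.
#'
#' @param frames data.frame with columns `frame`, `id`, `x`, `y`, `vx`, `vy`
#'   (positions in cm, velocities in cm/s). Extra columns are preserved.
#' @param fps frame rate in frames per second.
#' @param tank_width,tank_height tank dimensions in cm; the coordinate origin
#'   is one tank corner, so all positions must lie in
#'   `[0, tank_width] x [0, tank_height]`.
#' @param body_length typical fish body length in cm (default 5.2).
#' @param report optional load report (list) attached by [load_trajectories()].
#' @return An object of class `trajectory_dataset`: a list with elements
#'   `frames`, `fps`, `tank_width`, `tank_height`, `body_length`, `report`.
#' @seealso [load_trajectories()], [derive_kinematics()], [frame_view()]
#' @export
trajectory_dataset <- function(frames, fps, tank_width, tank_height,
                               body_length = 5.2, report = NULL) {
  if (!is.data.frame(frames)) stop("`frames` must be a data.frame")
  required <- c("frame", "id", "x", "y", "vx", "vy")
  missing_cols <- setdiff(required, names(frames))
  if (length(missing_cols) > 0) {
    stop("trajectory table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (p in c(fps = fps, tank_width = tank_width, tank_height = tank_height,
              body_length = body_length)) {
    if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p <= 0) {
      stop("fps, tank dimensions and body_length must be positive scalars")
    }
  }
  bad <- which(frames$x < 0 | frames$x > tank_width |
                 frames$y < 0 | frames$y > tank_height)
  if (length(bad) > 0) {
    stop("position outside tank bounds in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L) else "")
  }
  if (anyDuplicated(frames[, c("frame", "id")]) > 0) {
    stop("duplicate individual id within a frame")
  }
  frames <- frames[order(frames$frame, frames$id), , drop = FALSE]
  rownames(frames) <- NULL
  structure(
    list(frames = frames, fps = fps, tank_width = tank_width,
         tank_height = tank_height, body_length = body_length,
         report = report),
    class = "trajectory_dataset"
  )
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  nf <- length(unique(x$frames$frame))
  ni <- length(unique(x$frames$id))
  cat(sprintf(
    "<trajectory_dataset> %d rows, %d frames, %d ids, %.0f fps, tank %.0f x %.0f cm\n",
    nrow(x$frames), nf, ni, x$fps, x$tank_width, x$tank_height))
  if (!is.null(x$report) && !is.null(x$report$dropped)) {
    cat(sprintf("  load report: %d row(s) dropped\n", x$report$dropped))
  }
  if ("valid" %in% names(x$frames)) {
    cat(sprintf("  kinematics derived: %d/%d rows valid\n",
                sum(x$frames$valid), nrow(x$frames)))
  }
  invisible(x)
}

#' Load a trajectory table from delimited text
#'
#' Reads a comma- or tab-separated file with a header row and columns exactly
#' `frame, id, x, y, vx, vy`. Rows containing non-finite or non-numeric
#' values are dropped and counted in the attached load report.
#'
#' @param path path to the delimited file.
#' @param meta list of metadata: `fps`, `tank_width_cm`, `tank_height_cm` and
#'   optionally `body_length_cm` (plain `tank_width` etc. also accepted).
#' @return A [trajectory_dataset()] whose `report` element records
#'   `n_rows_read` and `dropped`.
#' @export
load_trajectories <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) stop("empty input file: ", path)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("frame", "id", "x", "y", "vx", "vy")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("trajectory table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty input file: ", path)
  n_read <- nrow(df)
  num <- df
  for (cc in c("frame", "x", "y", "vx", "vy")) {
    num[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  ok <- is.finite(num$frame) & is.finite(num$x) & is.finite(num$y) &
    is.finite(num$vx) & is.finite(num$vy) & !is.na(df$id)
  dropped <- sum(!ok)
  num <- num[ok, required, drop = FALSE]
  if (nrow(num) == 0L) stop("no valid rows in input file: ", path)
  get_meta <- function(...) {
    for (nm in c(...)) if (!is.null(meta[[nm]])) return(meta[[nm]])
    stop("metadata field missing: ", ..1)
  }
  trajectory_dataset(
    num,
    fps = get_meta("fps"),
    tank_width = get_meta("tank_width_cm", "tank_width"),
    tank_height = get_meta("tank_height_cm", "tank_height"),
    body_length = tryCatch(get_meta("body_length_cm", "body_length"),
                           error = function(e) 5.2),
    report = list(n_rows_read = n_read, dropped = dropped)
  )
}

#' Write a trajectory dataset to delimited text
#'
#' Writes the `frame, id, x, y, vx, vy` columns as CSV with 17 significant
#' digits, so that [load_trajectories()] round-trips positions and
#' velocities exactly at double precision.
#'
#' @param dataset a [trajectory_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(dataset, path) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  fr <- dataset$frames[, c("frame", "id", "x", "y", "vx", "vy")]
  out <- data.frame(
    frame = format(fr$frame, trim = TRUE, scientific = FALSE),
    id = fr$id,
    x = sprintf("%.17g", fr$x), y = sprintf("%.17g", fr$y),
    vx = sprintf("%.17g", fr$vx), vy = sprintf("%.17g", fr$vy),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive per-individual headings and speeds
#'
#' Adds `speed`, `heading_x`, `heading_y` and `valid` columns. For each
#' record, `speed = |v|`; when `speed >= speed_floor` the heading is the
#' velocity unit vector. Below the floor (effectively stationary fish) the
#' most recent valid heading of that individual is carried forward; records
#' with no prior valid heading are flagged `valid = FALSE` and excluded from
#' order-parameter sums.
#'
#' @param dataset a [trajectory_dataset()].
#' @param speed_floor minimum speed (cm/s) at which a velocity defines a
#'   heading; the default is a machine-noise guard only.
#' @return The dataset with kinematic columns added. Idempotent.
#' @export
derive_kinematics <- function(dataset, speed_floor = 1e-6) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  if (!is.numeric(speed_floor) || length(speed_floor) != 1 || speed_floor < 0) {
    stop("speed_floor must be a non-negative scalar")
  }
  fr <- dataset$frames
  sp <- sqrt(fr$vx^2 + fr$vy^2)
  has_heading <- sp >= speed_floor & sp > 0
  hx <- ifelse(has_heading, fr$vx / sp, NA_real_)
  hy <- ifelse(has_heading, fr$vy / sp, NA_real_)
  # carry the last valid heading forward within each id (frames are sorted)
  ord <- order(fr$id, fr$frame)
  hx_o <- hx[ord]; hy_o <- hy[ord]; id_o <- fr$id[ord]
  last_id <- NULL; last_hx <- NA_real_; last_hy <- NA_real_
  for (k in seq_along(hx_o)) {
    if (is.null(last_id) || !identical(id_o[k], last_id)) {
      last_id <- id_o[k]; last_hx <- NA_real_; last_hy <- NA_real_
    }
    if (is.na(hx_o[k])) {
      hx_o[k] <- last_hx; hy_o[k] <- last_hy
    } else {
      last_hx <- hx_o[k]; last_hy <- hy_o[k]
    }
  }
  hx[ord] <- hx_o; hy[ord] <- hy_o
  fr$speed <- sp
  fr$heading_x <- hx
  fr$heading_y <- hy
  fr$valid <- !is.na(hx)
  dataset$frames <- fr
  dataset
}

#' Extract one frame of a trajectory dataset
#'
#' @param dataset a [trajectory_dataset()].
#' @param frame_index the frame to extract.
#' @return data.frame of the individuals recorded in that frame.
#' @export
frame_view <- function(dataset, frame_index) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  out <- dataset$frames[dataset$frames$frame == frame_index, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# rows of `frame` usable in heading averages; frames without a derived
# `valid` column are taken at face value
frame_valid <- function(frame) {
  if ("valid" %in% names(frame)) frame$valid else rep(TRUE, nrow(frame))
}
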