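# State classification and transition statistics.
#
# The rotation-polarization plane is partitioned by a single threshold k
# (default 0.35) into: polarized P (O_p > 1-k, O_r < k), milling M
# (O_p < k, O_r > 1-k), swarm S (O_p < k, O_r < k) and the transitional
# region T everywhere else. Inequalities are strict: points exactly on a
# threshold are transitional.

STATE_LABELS <- c("S", "P", "M", "T")

#' Classify one point of the rotation-polarization plane
#'
#' @param o_p polarization in `[0, 1]`.
#' @param o_r rotation magnitude in `[0, 1]`.
#' @param k state threshold, in `(0, 0.5)` so the three state regions are
#'   disjoint (default 0.35).
#' @return One of `"S"`, `"P"`, `"M"`, `"T"` (vectorized over `o_p`/`o_r`;
#'   `NA` inputs give `NA`).
#' @export
classify_point <- function(o_p, o_r, k = 0.35) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0 || k >= 0.5) {
    stop("k must lie strictly between 0 and 0.5")
  }
  if (any(stats::na.omit(c(o_p, o_r)) < 0) ||
      any(stats::na.omit(c(o_p, o_r)) > 1)) {
    stop("order parameters must lie in [0, 1]")
  }
  out <- rep(NA_character_, length(o_p))
  known <- !is.na(o_p) & !is.na(o_r)
  lab <- rep("T", sum(known))
  p <- o_p[known]; r <- o_r[known]
  lab[p > 1 - k & r < k] <- "P"
  lab[p < k & r > 1 - k] <- "M"
  lab[p < k & r < k] <- "S"
  out[known] <- lab
  out
}

#' Label every frame of a smoothed order-parameter series
#'
#' Applies [classify_point()] to the smoothed `o_p`/`o_r` columns. Frames
#' with undefined order parameters get `NA` labels (gaps) and are excluded
#' from duration accounting downstream.
#'
#' @param series an `order_series`, smoothed with [smooth_order_series()].
#' @param k state threshold (default 0.35).
#' @return Character vector of labels, one per frame, with `fps` attribute.
#' @export
label_series <- function(series, k = 0.35) {
  stopifnot(inherits(series, "order_series"))
  if (!isTRUE(attr(series, "smoothed"))) {
    warning("labeling an unsmoothed series; smooth_order_series() first")
  }
  # averaging unit-vector sums can overshoot 1 by machine epsilon
  clamp <- function(v) pmin(pmax(v, 0), 1)
  labels <- classify_point(clamp(series$o_p), clamp(series$o_r), k)
  attr(labels, "fps") <- attr(series, "fps")
  labels
}

#' Run-length encode state labels into visits
#'
#' A visit is a maximal run of one label. `NA` gaps shorter than
#' `max_gap_s` flanked by the same label on both sides are bridged by that
#' label; longer gaps split the series into independent segments (visits
#' are never merged, and transitions never counted, across them).
#'
#' @param labels character vector of per-frame labels (may contain `NA`).
#' @param fps frame rate; taken from the labels' `fps` attribute if absent.
#' @param max_gap_s longest tracking gap, in seconds, bridged when both
#'   sides carry the same label (default 1).
#' @return data.frame of class `state_visits` with columns `label`,
#'   `start`, `end` (frame positions, inclusive), `duration` (s) and
#'   `segment`.
#' @export
extract_visits <- function(labels, fps = NULL, max_gap_s = 1) {
  if (is.null(fps)) fps <- attr(labels, "fps")
  if (is.null(fps)) stop("fps must be supplied")
  n <- length(labels)
  if (n == 0L) stop("empty label sequence")
  labels <- as.character(labels)
  # bridge short gaps with agreeing flanks
  r <- rle(is.na(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    if (r$lengths[j] > max_gap_s * fps) next
    if (starts[j] == 1L || ends[j] == n) next
    before <- labels[starts[j] - 1L]
    after <- labels[ends[j] + 1L]
    if (!is.na(before) && identical(before, after)) {
      labels[starts[j]:ends[j]] <- before
    }
  }
  # split at remaining gaps, rle within each segment
  seg_id <- cumsum(c(TRUE, is.na(labels[-n]) != is.na(labels[-1L])))
  out <- NULL
  seg_counter <- 0L
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    if (is.na(labels[idx[1L]])) next
    seg_counter <- seg_counter + 1L
    rr <- rle(labels[idx])
    e <- idx[1L] - 1L + cumsum(rr$lengths)
    b <- e - rr$lengths + 1L
    out <- rbind(out, data.frame(
      label = rr$values, start = b, end = e,
      duration = rr$lengths / fps, segment = seg_counter,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "fps") <- fps
  class(out) <- c("state_visits", "data.frame")
  out
}

#' Completed state-to-state transitions
#'
#' A transition is completed when the group moves from one of S/P/M to a
#' *different* one of S/P/M; excursions into the transitional region that
#' return to the previous state do not count. Transitions are detected
#' between consecutive non-T visits within a contiguous tracking segment,
#' whether or not T frames intervene.
#'
#' @param visits a `state_visits` table from [extract_visits()].
#' @param series optional smoothed `order_series`; when given, each event
#'   carries its phase-space `path`: the `(o_r, o_p)` points from the last
#'   frame of the source visit through any T frames to the first frame of
#'   the destination visit.
#' @return data.frame of class `transition_events` with columns
#'   `from`, `to`, `from_end`, `to_start` (frame positions); when `series`
#'   is supplied, a list-column `path` of two-column matrices `(o_r, o_p)`.
#' @export
completed_transitions <- function(visits, series = NULL) {
  stopifnot(inherits(visits, "state_visits"))
  ev <- NULL
  for (s in unique(visits$segment)) {
    vs <- visits[visits$segment == s & visits$label != "T", , drop = FALSE]
    if (nrow(vs) < 2L) next
    for (j in seq_len(nrow(vs) - 1L)) {
      if (vs$label[j] != vs$label[j + 1L]) {
        ev <- rbind(ev, data.frame(
          from = vs$label[j], to = vs$label[j + 1L],
          from_end = vs$end[j], to_start = vs$start[j + 1L],
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(ev)) {
    ev <- data.frame(from = character(0), to = character(0),
                     from_end = integer(0), to_start = integer(0),
                     stringsAsFactors = FALSE)
  }
  if (!is.null(ev) && !is.null(series) && nrow(ev) > 0L) {
    ev$path <- lapply(seq_len(nrow(ev)), function(j) {
      idx <- ev$from_end[j]:ev$to_start[j]
      cbind(o_r = series$o_r[idx], o_p = series$o_p[idx])
    })
  }
  rownames(ev) <- NULL
  class(ev) <- c("transition_events", "data.frame")
  ev
}

#' Fraction of time spent in each state
#'
#' @param visits a `state_visits` table.
#' @return Named numeric vector over `S, P, M, T`, summing to 1 (gap frames
#'   are excluded from the denominator).
#' @export
state_time_fractions <- function(visits) {
  stopifnot(inherits(visits, "state_visits"))
  total <- sum(visits$duration)
  if (!isTRUE(total > 0)) stop("zero total duration")
  out <- vapply(STATE_LABELS, function(l) {
    sum(visits$duration[visits$label == l]) / total
  }, numeric(1))
  out
}

#' Transition rate and destination fractions
#'
#' @param events a `transition_events` table.
#' @param total_duration_min observation time in minutes.
#' @return List with `rate_per_min` (completed transitions per minute) and
#'   `fractions`, a 3x3 matrix (rows = source S/P/M, columns = destination)
#'   whose off-diagonal rows sum to 1; a source with no outgoing events has
#'   an all-`NA` row.
#' @export
transition_stats <- function(events, total_duration_min) {
  stopifnot(inherits(events, "transition_events"))
  if (!is.numeric(total_duration_min) || total_duration_min <= 0) {
    stop("total_duration_min must be > 0")
  }
  states <- c("S", "P", "M")
  frac <- matrix(NA_real_, 3, 3, dimnames = list(from = states, to = states))
  for (a in states) {
    sub <- events[events$from == a, , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (b in states) {
      if (a == b) next
      frac[a, b] <- sum(sub$to == b) / nrow(sub)
    }
  }
  list(rate_per_min = nrow(events) / total_duration_min, fractions = frac)
}

#' Empirical persistence (survival) curve of one state
#'
#' Probability of remaining in a state longer than a dwell time `t` before
#' moving into a different regime, estimated from that state's visit
#' durations.
#'
#' @param visits a `state_visits` table.
#' @param label one of `"S"`, `"P"`, `"M"`, `"T"`.
#' @return A function `f(t) = P(T_s > t)` (vectorized, monotone
#'   non-increasing, `f(0) = 1`), with the sorted visit durations attached
#'   as attribute `durations`.
#' @export
persistence_survival <- function(visits, label) {
  stopifnot(inherits(visits, "state_visits"))
  d <- sort(visits$duration[visits$label == label])
  if (length(d) == 0L) stop("no visits with label ", label)
  f <- function(t) vapply(t, function(tt) mean(d > tt), numeric(1))
  attr(f, "durations") <- d
  f
}

#' Fraction of transitional-region visits that complete a transition
#'
#' Among visits to the transitional region T lasting longer than
#' `min_t_duration_s` and flanked by defined states on both sides, the
#' fraction whose flanking states differ (i.e. that are part of a completed
#' transition rather than an excursion-and-return).
#'
#' @param visits a `state_visits` table.
#' @param min_t_duration_s minimum qualifying T-visit duration in seconds
#'   (default 1; strictly longer visits qualify).
#' @return List `fraction`, `n_completed`, `n_visits`.
#' @export
transition_completion_fraction <- function(visits, min_t_duration_s = 1) {
  stopifnot(inherits(visits, "state_visits"))
  n_visits <- 0L
  n_completed <- 0L
  for (s in unique(visits$segment)) {
    vs <- visits[visits$segment == s, , drop = FALSE]
    if (nrow(vs) < 3L) next
    for (j in 2:(nrow(vs) - 1L)) {
      if (vs$label[j] != "T") next
      if (vs$duration[j] <= min_t_duration_s) next
      if (vs$label[j - 1L] == "T" || vs$label[j + 1L] == "T") next
      n_visits <- n_visits + 1L
      if (vs$label[j - 1L] != vs$label[j + 1L]) n_completed <- n_completed + 1L
    }
  }
  if (n_visits == 0L) stop("no qualifying transitional-region visits")
  list(fraction = n_completed / n_visits,
       n_completed = n_completed, n_visits = n_visits)
}

#' Handedness of milling visits
#'
#' Each milling visit is assigned the sign of its mean signed rotation:
#' negative = clockwise, positive = counter-clockwise. An exactly zero mean
#' (a probability-zero event) is tie-broken to counter-clockwise with a
#' message.
#'
#' @param signed_rotation per-frame signed rotation series aligned with the
#'   frame positions in `visits`.
#' @param visits a `state_visits` table.
#' @return Named integer vector `c(n_clockwise = ..., n_counterclockwise = ...)`.
#' @export
milling_handedness <- function(signed_rotation, visits) {
  stopifnot(inherits(visits, "state_visits"))
  m <- visits[visits$label == "M", , drop = FALSE]
  n_cw <- 0L; n_ccw <- 0L
  for (j in seq_len(nrow(m))) {
    s <- mean(signed_rotation[m$start[j]:m$end[j]], na.rm = TRUE)
    if (s < 0) {
      n_cw <- n_cw + 1L
    } else {
      if (s == 0) message("milling visit with exactly zero mean rotation; ",
                          "tie-broken to counter-clockwise")
      n_ccw <- n_ccw + 1L
    }
  }
  c(n_clockwise = n_cw, n_counterclockwise = n_ccw)
}
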