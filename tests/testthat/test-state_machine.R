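test_that("point classification: regions, strict thresholds, alternative k", {
  expect_equal(classify_point(0.9, 0.1), "P")
  expect_equal(classify_point(0.1, 0.9), "M")
  expect_equal(classify_point(0.1, 0.1), "S")
  expect_equal(classify_point(0.5, 0.5), "T")
  # exact threshold values are transitional (strict inequalities)
  expect_equal(classify_point(0.35, 0.35), "T")
  expect_equal(classify_point(0.65, 0.1), "T")
  # alternative threshold k = 0.25
  expect_equal(classify_point(0.2, 0.8, k = 0.25), "M")
  expect_equal(classify_point(0.2, 0.8, k = 0.15), "T")
  # vectorized with NA passthrough
  expect_equal(classify_point(c(0.9, NA), c(0.1, 0.5)), c("P", NA))
  expect_error(classify_point(1.2, 0.1), "\\[0, 1\\]")
  expect_error(classify_point(0.5, 0.5, k = 0.6), "between 0 and 0.5")
})

fake_series <- function(o_p, o_r, fps = 30) {
  s <- data.frame(frame = seq_along(o_p) - 1L, o_p = o_p,
                  signed_r = o_r, o_r = o_r,
                  mean_speed = 5, n_valid = 10)
  attr(s, "fps") <- fps
  attr(s, "smoothed") <- TRUE
  class(s) <- c("order_series", "data.frame")
  s
}

test_that("series labeling and visit extraction with run-length encoding", {
  s <- fake_series(rep(0.9, 5), rep(0.1, 5))
  l <- label_series(s)
  attributes(l) <- NULL
  expect_equal(l, rep("P", 5))

  labels <- c("P", "P", "P", "T", "T", "M")
  attr(labels, "fps") <- 30
  v <- extract_visits(labels)
  expect_equal(v$label, c("P", "T", "M"))
  expect_equal(v$duration, c(3, 2, 1) / 30, tolerance = 1e-12)

  v1 <- extract_visits(c("S"), fps = 30)
  expect_equal(nrow(v1), 1)

  v2 <- extract_visits(c("P", "T", "P", "T"), fps = 30)
  expect_equal(nrow(v2), 4)

  # short same-label gaps are bridged; long gaps split segments
  lab_gap <- c("P", "P", NA, "P", "P")
  vg <- extract_visits(lab_gap, fps = 30)
  expect_equal(nrow(vg), 1)
  expect_equal(vg$duration, 5 / 30)
  lab_long <- c(rep("P", 3), rep(NA, 40), rep("P", 3))
  vl <- extract_visits(lab_long, fps = 30)
  expect_equal(nrow(vl), 2)
  expect_equal(unique(vl$label), "P")
  expect_equal(vl$segment, c(1, 2))
  # differing flanks are never bridged
  vd <- extract_visits(c("P", NA, "M"), fps = 30)
  expect_equal(vd$label, c("P", "M"))
  expect_equal(sum(vd$duration), 2 / 30)
})

test_that("completed transitions: excursion-and-return does not count", {
  mk <- function(labels) extract_visits(labels, fps = 30)
  # P, T, P -> no events
  expect_equal(nrow(completed_transitions(mk(c("P", "T", "P")))), 0)
  # P, T, M, S -> P->M and M->S
  ev <- completed_transitions(mk(c("P", "T", "M", "S")))
  expect_equal(paste(ev$from, ev$to, sep = "->"), c("P->M", "M->S"))
  # direct change without an intervening T frame still counts
  ev2 <- completed_transitions(mk(c("P", "M")))
  expect_equal(paste(ev2$from, ev2$to, sep = "->"), "P->M")
  # no transitions across an unbridgeable gap
  ev3 <- completed_transitions(mk(c(rep("P", 3), rep(NA, 40), rep("M", 3))))
  expect_equal(nrow(ev3), 0)
})

test_that("transition extraction agrees with a brute-force label scan", {
  set.seed(42)
  for (rep in 1:200) {
    labels <- sample(c("S", "P", "M", "T"), sample(5:60, 1), replace = TRUE)
    v <- extract_visits(labels, fps = 30)
    ev <- completed_transitions(v)
    got <- if (nrow(ev) > 0) paste(ev$from, ev$to, sep = "->") else character(0)
    expect_identical(got, label_scan_oracle(labels))
    # events never exceed non-T visits minus one
    expect_lte(nrow(ev), max(0, sum(v$label != "T") - 1))
  }
})

test_that("event paths run from source exit to destination entry", {
  o_p <- c(0.9, 0.9, 0.5, 0.2, 0.2)
  o_r <- c(0.1, 0.1, 0.5, 0.8, 0.8)
  s <- fake_series(o_p, o_r)
  labels <- label_series(s)
  v <- extract_visits(labels)
  ev <- completed_transitions(v, s)
  expect_equal(nrow(ev), 1)
  path <- ev$path[[1]]
  expect_equal(nrow(path), 3)          # last P frame, T frame, first M frame
  expect_equal(path[1, ], c(o_r = 0.1, o_p = 0.9))
  expect_equal(path[3, ], c(o_r = 0.8, o_p = 0.2))
})

test_that("occupancy fractions, transition rates and destination fractions", {
  v <- structure(
    data.frame(label = c("P", "M"), start = c(1, 901), end = c(900, 3000),
               duration = c(30, 70), segment = 1),
    class = c("state_visits", "data.frame"))
  f <- state_time_fractions(v)
  expect_equal(unname(f[c("P", "M", "S", "T")]), c(0.3, 0.7, 0, 0))

  vt <- structure(
    data.frame(label = "T", start = 1, end = 100, duration = 100, segment = 1),
    class = c("state_visits", "data.frame"))
  expect_equal(unname(state_time_fractions(vt)[["T"]]), 1)

  v3 <- structure(
    data.frame(label = c("P", "T", "S"), start = c(1, 31, 61),
               end = c(30, 60, 120), duration = c(1, 1, 2), segment = 1),
    class = c("state_visits", "data.frame"))
  expect_equal(unname(state_time_fractions(v3)[c("P", "T", "S")]),
               c(0.25, 0.25, 0.5))

  ev <- structure(
    data.frame(from = c("P", "P", "P"), to = c("M", "S", "S"),
               from_end = 1:3, to_start = 2:4),
    class = c("transition_events", "data.frame"))
  ts <- transition_stats(ev, total_duration_min = 1.5)
  expect_equal(ts$rate_per_min, 2)
  expect_equal(ts$fractions["P", "M"], 1 / 3)
  expect_equal(ts$fractions["P", "S"], 2 / 3)
  # a source with no outgoing events is flagged undefined
  expect_true(all(is.na(ts$fractions["M", ])))

  # 10 events in 5 minutes -> 2 per minute
  ev10 <- structure(
    data.frame(from = rep("P", 10), to = rep("S", 10),
               from_end = 1:10, to_start = 2:11),
    class = c("transition_events", "data.frame"))
  expect_equal(transition_stats(ev10, 5)$rate_per_min, 2)
})

test_that("persistence survival curves are valid empirical survivals", {
  v <- structure(
    data.frame(label = rep("M", 3), start = c(1, 100, 200),
               end = c(30, 160, 320), duration = c(1, 2, 4), segment = 1),
    class = c("state_visits", "data.frame"))
  surv <- persistence_survival(v, "M")
  expect_equal(surv(0), 1)
  expect_equal(surv(1.5), 2 / 3)
  expect_equal(surv(10), 0)
  # monotone non-increasing
  tt <- seq(0, 5, by = 0.25)
  expect_true(all(diff(surv(tt)) <= 0))

  v1 <- v[1, , drop = FALSE]
  class(v1) <- c("state_visits", "data.frame")
  s1 <- persistence_survival(v1, "M")
  expect_equal(s1(0.99), 1)
  expect_equal(s1(1.01), 0)

  expect_error(persistence_survival(v, "S"), "no visits")
})

test_that("completion fraction counts qualifying transitional visits only", {
  mk_visits <- function(labels, durs, fps = 1) {
    structure(
      data.frame(label = labels,
                 start = cumsum(c(1, durs[-length(durs)])),
                 end = cumsum(durs), duration = durs, segment = 1),
      class = c("state_visits", "data.frame"))
  }
  # P, T(2 s), M, T(1.5 s), M: one change of two qualifying T visits
  v <- mk_visits(c("P", "T", "M", "T", "M"), c(5, 2, 5, 1.5, 5))
  cf <- transition_completion_fraction(v)
  expect_equal(cf$fraction, 0.5)
  expect_equal(cf$n_completed, 1)
  expect_equal(cf$n_visits, 2)

  # a 0.5 s transitional visit is excluded by the 1 s rule
  v2 <- mk_visits(c("P", "T", "M", "T", "P"), c(5, 0.5, 5, 2, 5))
  cf2 <- transition_completion_fraction(v2)
  expect_equal(cf2$n_visits, 1)
  expect_equal(cf2$fraction, 1)

  expect_error(
    transition_completion_fraction(mk_visits(c("P", "M"), c(5, 5))),
    "no qualifying")
})

test_that("milling handedness follows the sign of the mean rotation", {
  signed <- c(rep(-0.8, 50), rep(0, 10), rep(0.7, 40))
  v <- structure(
    data.frame(label = c("M", "S", "M"), start = c(1, 51, 61),
               end = c(50, 60, 100), duration = c(50, 10, 40) / 30,
               segment = 1),
    class = c("state_visits", "data.frame"))
  h <- milling_handedness(signed, v)
  expect_equal(unname(h), c(1, 1))

  # exactly zero mean is tie-broken to counter-clockwise, with a message
  v0 <- v[1, , drop = FALSE]
  class(v0) <- c("state_visits", "data.frame")
  expect_message(
    h0 <- milling_handedness(rep(0, 50), v0), "tie-broken")
  expect_equal(unname(h0), c(0, 1))
})
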