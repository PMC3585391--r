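test_that("phase histogram: counts, masking and the closed upper edge", {
  pts <- matrix(rep(c(0.52, 0.77), each = 1000), ncol = 2)
  g <- phase_histogram(pts, min_count = 100)
  expect_equal(sum(g$value), 1000)
  expect_equal(g$value[16, 24], 1000)  # bin of (0.52, 0.77)
  expect_equal(sum(!g$mask), 1)

  # a value of exactly 1.0 lands in the last bin
  g1 <- phase_histogram(matrix(c(1, 1), ncol = 2), min_count = 1)
  expect_equal(g1$value[30, 30], 1)

  # uniform points: per-bin counts near the multinomial expectation
  set.seed(21)
  u <- matrix(runif(2 * 90000), ncol = 2)
  gu <- phase_histogram(u, min_count = 1)
  expect_equal(sum(gu$value), 90000)
  expect_true(all(abs(gu$value - 100) < 60))  # ~6 sd of Binomial(9e4, 1/900)

  expect_error(phase_histogram(matrix(c(1.2, 0.5), ncol = 2)), "\\[0, 1\\]")
  # input order does not matter
  p2 <- u[sample(nrow(u)), ]
  expect_identical(phase_histogram(p2, 1)$value, gu$value)
})

test_that("phase mean map: per-bin means with support masking", {
  pts <- rbind(c(0.1, 0.1), c(0.1, 0.1), c(0.9, 0.9))
  m <- phase_mean_map(pts, c(2, 4, 7), min_count = 2)
  expect_equal(m$value[4, 4], 3)      # mean of 2 and 4
  expect_true(is.na(m$value[28, 28])) # single point masked at min_count 2

  # constant values fill every supported bin with the constant
  set.seed(22)
  pc <- matrix(runif(2000), ncol = 2)
  mc <- phase_mean_map(pc, rep(3.5, 1000), min_count = 1)
  expect_true(all(mc$value[!mc$mask] == 3.5))

  expect_error(phase_mean_map(pts, 1:2), "one entry per")
})

test_that("grid refinement: constants, no extrapolation, bilinear exactness", {
  set.seed(23)
  pc <- matrix(runif(8000), ncol = 2)
  g <- phase_mean_map(pc, rep(2.5, 4000), min_count = 1)
  r <- refine_grid(g)
  expect_true(all(r[!is.na(r)] == 2.5))

  # a single unmasked bin refines only inside that bin's footprint
  one <- phase_histogram(matrix(rep(c(0.5, 0.5), each = 200), ncol = 2),
                         min_count = 100)
  r1 <- refine_grid(one)
  filled <- which(!is.na(r1), arr.ind = TRUE)
  expect_true(all(filled[, 1] %in% 151:160))
  expect_true(all(filled[, 2] %in% 151:160))

  # linear ramp: bilinear interpolation reproduces it exactly (interior)
  centers <- (seq_len(30) - 0.5) / 30
  ramp <- outer(centers, centers, function(a, b) 2 * a + 3 * b)
  gr <- structure(
    list(value = ramp, support = matrix(1000, 30, 30),
         mask = matrix(FALSE, 30, 30), min_count = 1, mode = "mean",
         edges = seq(0, 1, length.out = 31)),
    class = "phase_grid")
  rr <- refine_grid(gr)
  fine <- (seq_len(300) - 0.5) / 300
  interior <- fine > centers[1] & fine < centers[30]
  want <- outer(fine[interior], fine[interior], function(a, b) 2 * a + 3 * b)
  expect_equal(rr[interior, interior], want, tolerance = 1e-6,
               ignore_attr = TRUE)

  allmask <- phase_histogram(matrix(c(0.5, 0.5), ncol = 2), min_count = 100)
  expect_error(refine_grid(allmask), "all bins masked")
})

test_that("conditional mean curves recover functional relationships", {
  # constant order parameter -> flat by_speed curve
  set.seed(24)
  sp <- runif(500, 1, 10)
  cc <- conditional_mean_curves(sp, rep(0.42, 500))
  expect_true(all(abs(cc$by_speed$mean_local_o_p - 0.42) < 1e-12))

  # y = x on [0, 1] with matched grids: both curves on the diagonal
  x <- runif(3000)
  cxy <- conditional_mean_curves(x, x)
  expect_equal(cxy$by_order$mean_speed, cxy$by_order$local_o_p,
               tolerance = 1 / 30)
  expect_equal(cxy$by_speed$mean_local_o_p, cxy$by_speed$speed,
               tolerance = 1 / 30)

  expect_error(conditional_mean_curves(rep(1, 10), runif(10)),
               "distinct speed")
})

test_that("path resampling preserves endpoints and polylines", {
  p2 <- rbind(c(0.1, 0.9), c(0.8, 0.2))
  r <- resample_path(p2, 100)
  expect_equal(nrow(r), 100)
  expect_equal(r[1, ], p2[1, ], ignore_attr = TRUE)
  expect_equal(r[100, ], p2[2, ], ignore_attr = TRUE)
  # collinear and evenly spaced
  d <- diff(r)
  expect_true(all(abs(d[, 2] / d[, 1] - (0.2 - 0.9) / (0.8 - 0.1)) < 1e-9))

  # a path already at the target length is unchanged
  pl <- cbind(seq(0, 1, length.out = 100), seq(1, 0, length.out = 100)^2)
  expect_equal(resample_path(pl, 100), pl, tolerance = 1e-12,
               ignore_attr = TRUE)

  # resampled points stay on the polyline
  pw <- rbind(c(0, 0), c(0.5, 1), c(1, 0))
  rw <- resample_path(pw, 51)
  on_poly <- abs(rw[, 2] - (1 - 2 * abs(rw[, 1] - 0.5))) < 1e-9
  expect_true(all(on_poly))

  expect_error(resample_path(matrix(c(0.5, 0.5), ncol = 2)), "degenerate")
})

test_that("average transition paths: identity, symmetry, common endpoints", {
  p <- rbind(c(0.1, 0.9), c(0.5, 0.5), c(0.8, 0.2))
  expect_equal(average_transition_path(list(p, p)),
               resample_path(p, 100), tolerance = 1e-12)

  # two paths mirror-symmetric about the diagonal average onto the diagonal
  pa <- rbind(c(0.2, 0.2), c(0.3, 0.6), c(0.8, 0.8))
  pb <- pa[, 2:1]
  avg <- average_transition_path(list(pa, pb))
  expect_equal(avg[, 1], avg[, 2], tolerance = 1e-12)

  # straight paths sharing endpoints average to the same straight path
  q1 <- rbind(c(0, 0), c(1, 1))
  q2 <- rbind(c(0, 0), c(0.5, 0.5), c(1, 1))
  expect_equal(average_transition_path(list(q1, q2)),
               resample_path(q1, 100), tolerance = 1e-12)

  expect_error(average_transition_path(list()), "no events")
})

test_that("phase velocity field: constant paths, cancellation, circle tangents", {
  # one straight constant-speed path -> the same vector in every supported bin
  p <- rbind(c(0.05, 0.05), c(0.95, 0.95))
  vf <- phase_velocity_field(list(p), min_count = 1)
  ok <- !is.na(vf$u)
  expect_gt(sum(ok), 10)
  expect_true(all(abs(vf$u[ok] - 0.9 / 99) < 1e-12))
  expect_true(all(abs(vf$v[ok] - 0.9 / 99) < 1e-12))

  # two events with opposite difference vectors in one bin average to zero
  pa <- rbind(c(0.51, 0.51), c(0.52, 0.52))
  pb <- rbind(c(0.51, 0.51), c(0.50, 0.50))
  vf0 <- phase_velocity_field(list(pa, pb), min_count = 1)
  ok0 <- !is.na(vf0$u)
  expect_equal(sum(ok0), 1)
  expect_true(all(abs(vf0$u[ok0]) < 1e-12))
  expect_true(all(abs(vf0$v[ok0]) < 1e-12))

  # circular path in phase space: finite differences align with analytic tangents
  th <- seq(0, 2 * pi, length.out = 401)[-401]
  circ <- cbind(0.5 + 0.3 * cos(th), 0.5 + 0.3 * sin(th))
  vfc <- phase_velocity_field(list(circ), min_count = 1, length_out = 400)
  idx <- which(!is.na(vfc$u), arr.ind = TRUE)
  centers <- (seq_len(30) - 0.5) / 30
  for (k in seq_len(nrow(idx))) {
    pos <- c(centers[idx[k, 1]], centers[idx[k, 2]]) - 0.5
    tangent <- c(-pos[2], pos[1])
    vec <- c(vfc$u[idx[k, 1], idx[k, 2]], vfc$v[idx[k, 1], idx[k, 2]])
    cosang <- sum(tangent * vec) /
      sqrt(sum(tangent^2) * sum(vec^2))
    expect_gt(cosang, 0.9)
  }
})
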