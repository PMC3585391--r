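# Group geometry: center of mass, alpha-shape area, packing fraction and
# distance from the group center to the tank boundary.
#
# The alpha shape is computed from a 2D Delaunay triangulation
# (Bowyer-Watson insertion) by keeping the triangles whose circumradius is
# at most the probe radius alpha; the group area is the total area of the
# kept triangles, which converges to the convex-hull area as alpha grows.

#' Tank geometry
#'
#' @param width,height tank dimensions in cm; origin at one corner.
#' @return List of class `tank_geometry`.
#' @export
tank_geometry <- function(width, height) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0) {
    stop("tank dimensions must be positive")
  }
  structure(list(width = width, height = height), class = "tank_geometry")
}

#' Group center of mass
#'
#' Unweighted mean position of the recorded fish.
#'
#' @param frame data.frame with `x`, `y` columns.
#' @return Numeric `c(x = ..., y = ...)` in cm.
#' @export
center_of_mass <- function(frame) {
  if (nrow(frame) == 0L) stop("empty frame: center of mass undefined")
  c(x = mean(frame$x), y = mean(frame$y))
}

# Bowyer-Watson Delaunay triangulation of 2D points, with the incircle
# determinant predicate (counter-clockwise triangles) for numerical
# robustness. Returns list(triangles = n_tri x 3 index matrix,
# r = circumradii, area = triangle areas). Assumes >= 3 distinct points.
delaunay_triangulation <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n)
  minx <- min(x); maxx <- max(x); miny <- min(y); maxy <- max(y)
  dmax <- max(maxx - minx, maxy - miny, 1e-9)
  midx <- (minx + maxx) / 2; midy <- (miny + maxy) / 2
  # auxiliary bounding vertices; far enough that every circumcircle of a
  # triangle touching them covers the whole point cloud, so they never
  # block a proper hull triangle
  big <- 1e5 * dmax
  px <- c(x, midx - big, midx, midx + big)
  py <- c(y, midy - 0.5 * big, midy + big, midy - 0.5 * big)
  orient_ccw <- function(tri) {
    # ensure counter-clockwise vertex order per triangle (rows)
    cross <- (px[tri[, 2]] - px[tri[, 1]]) * (py[tri[, 3]] - py[tri[, 1]]) -
      (px[tri[, 3]] - px[tri[, 1]]) * (py[tri[, 2]] - py[tri[, 1]])
    flip <- cross < 0
    if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
    tri
  }
  tri <- orient_ccw(matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3))
  for (p in seq_len(n)) {
    # incircle determinant: > 0 when p lies inside the circumcircle of a
    # CCW triangle; on-circle points are treated as inside
    adx <- px[tri[, 1]] - px[p]; ady <- py[tri[, 1]] - py[p]
    bdx <- px[tri[, 2]] - px[p]; bdy <- py[tri[, 2]] - py[p]
    cdx <- px[tri[, 3]] - px[p]; cdy <- py[tri[, 3]] - py[p]
    ad2 <- adx^2 + ady^2; bd2 <- bdx^2 + bdy^2; cd2 <- cdx^2 + cdy^2
    det <- adx * (bdy * cd2 - cdy * bd2) -
      ady * (bdx * cd2 - cdx * bd2) +
      ad2 * (bdx * cdy - cdx * bdy)
    scale <- abs(adx * bdy * cd2) + abs(ady * bdx * cd2) +
      abs(ad2 * bdx * cdy) + 1e-300
    bad <- which(det > -1e-12 * scale)
    if (length(bad) == 0L) next  # duplicate point guard
    edges <- rbind(tri[bad, c(1, 2), drop = FALSE],
                   tri[bad, c(2, 3), drop = FALSE],
                   tri[bad, c(3, 1), drop = FALSE])
    edges_s <- cbind(pmin(edges[, 1], edges[, 2]),
                     pmax(edges[, 1], edges[, 2]))
    key <- paste(edges_s[, 1], edges_s[, 2])
    once <- names(which(table(key) == 1L))
    boundary <- edges[key %in% once, , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    if (nrow(boundary) > 0L) {
      # boundary edges keep their cavity orientation; appending p preserves CCW
      tri <- rbind(tri, orient_ccw(cbind(boundary, p)))
    }
  }
  keep <- tri[, 1] <= n & tri[, 2] <= n & tri[, 3] <= n
  tri <- tri[keep, , drop = FALSE]
  ax <- px[tri[, 1]]; ay <- py[tri[, 1]]
  bx <- px[tri[, 2]]; by <- py[tri[, 2]]
  cx <- px[tri[, 3]]; cy <- py[tri[, 3]]
  dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / dd
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / dd
  r <- sqrt((ux - ax)^2 + (uy - ay)^2)
  r[!is.finite(r)] <- Inf
  area <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
  list(triangles = tri, r = r, area = area)
}

# minimal union-find for component counting
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Alpha-shape area of a group
#'
#' Area spanned by the group, measured with a 2D alpha shape: the union of
#' the Delaunay triangles whose circumradius is at most `alpha_radius`. For
#' a large probe radius this equals the convex-hull area; smaller radii
#' follow concavities and may split the shape into several components
#' (points are considered connected when a Delaunay edge of length at most
#' `2 * alpha_radius` joins them).
#'
#' @param frame data.frame with `x`, `y` columns (duplicate positions are
#'   collapsed).
#' @param alpha_radius probe radius in cm; defaults to one body length of a
#'   golden shiner (5.2 cm).
#' @return List of class `group_shape`: `area` (cm^2), `n_components`,
#'   `alpha_radius`, and the kept `triangles` with point coordinates
#'   (`points`) for downstream point-in-shape queries.
#' @export
group_area <- function(frame, alpha_radius = 5.2) {
  if (!is.numeric(alpha_radius) || alpha_radius <= 0) {
    stop("alpha_radius must be > 0")
  }
  pts <- unique(data.frame(x = frame$x, y = frame$y))
  if (nrow(pts) < 3L) stop("degenerate geometry: fewer than 3 distinct fish")
  # collinearity check via convex hull area (shoelace)
  h <- grDevices::chull(pts$x, pts$y)
  hx <- pts$x[h]; hy <- pts$y[h]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (hull_area <= 0) stop("degenerate geometry: all fish collinear")
  dt <- delaunay_triangulation(pts$x, pts$y)
  keep <- dt$r <= alpha_radius
  area <- sum(dt$area[keep])
  # connectivity: Delaunay edges no longer than the probe diameter
  edges <- rbind(dt$triangles[, c(1, 2), drop = FALSE],
                 dt$triangles[, c(2, 3), drop = FALSE],
                 dt$triangles[, c(3, 1), drop = FALSE])
  len2 <- (pts$x[edges[, 1]] - pts$x[edges[, 2]])^2 +
    (pts$y[edges[, 1]] - pts$y[edges[, 2]])^2
  edges <- edges[len2 <= (2 * alpha_radius)^2, , drop = FALSE]
  structure(
    list(area = area, n_components = uf_components(nrow(pts), edges),
         alpha_radius = alpha_radius,
         triangles = dt$triangles[keep, , drop = FALSE],
         points = pts),
    class = "group_shape")
}

#' Packing fraction of a group
#'
#' Number of fish divided by the alpha-shape area of the group, multiplied
#' by the area of one fish body: the fraction of the occupied area covered
#' by fish.
#'
#' @param frame data.frame with `x`, `y` columns.
#' @param body_area area of one fish body in cm^2. The default 3.38 cm^2
#'   is a 5.2 cm x 0.65 cm body (8:1 aspect); any constant rescales the
#'   packing fraction uniformly.
#' @param alpha_radius probe radius passed to [group_area()].
#' @return Dimensionless packing fraction.
#' @export
packing_fraction <- function(frame, body_area = 3.38, alpha_radius = 5.2) {
  shape <- group_area(frame, alpha_radius)
  if (shape$area <= 0) stop("alpha shape has zero area; increase alpha_radius")
  nrow(frame) * body_area / shape$area
}

#' Distance from the group center of mass to the tank boundary
#'
#' @param frame data.frame with `x`, `y` columns, or a length-2 numeric
#'   center-of-mass point.
#' @param tank a [tank_geometry()].
#' @return Smallest distance (cm) from the center of mass to the four tank
#'   edges.
#' @export
boundary_distance <- function(frame, tank) {
  stopifnot(inherits(tank, "tank_geometry"))
  com <- if (is.data.frame(frame)) center_of_mass(frame) else frame
  cx <- com[[1]]; cy <- com[[2]]
  if (cx < 0 || cx > tank$width || cy < 0 || cy > tank$height) {
    stop("center of mass lies outside the tank")
  }
  min(cx, tank$width - cx, cy, tank$height - cy)
}
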