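# Chain closure: turning an open subchain into a closed polygon.
#
# The stochastic scheme connects both termini to two distinct vertices
# of a randomly rotated truncated icosahedron sitting on a large sphere
# that encloses the chain, joining the two surface points by a
# great-circle arc. Because every closure vertex lies on the sphere and
# the chain is strictly inside, the closure can never pierce the chain.

#' Run an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded library calls do not
#' disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Smallest practical sphere enclosing a chain
#'
#' Center is the vertex centroid; the radius is the maximal
#' centroid-vertex distance inflated by a safety factor so that all
#' chain vertices are strictly inside.
#'
#' @param chain a `knot_chain` or an N x 3 coordinate matrix.
#' @param inflation dimensionless factor > 1 (default 10).
#' @return list with `center` (length-3 numeric) and `radius`.
#' @export
enclosing_sphere <- function(chain, inflation = 10) {
  pts <- if (inherits(chain, "knot_chain")) chain$vertices else as.matrix(chain)
  if (nrow(pts) < 2L) stop("need at least two vertices")
  if (inflation <= 1) stop("inflation must exceed 1")
  center <- colMeans(pts)
  rmax <- sqrt(max(rowSums(sweep(pts, 2L, center)^2)))
  radius <- inflation * rmax
  if (radius < 1) radius <- 1  # degenerate chain: 1 Angstrom floor
  list(center = as.numeric(center), radius = radius)
}

# 60 vertices of the canonical truncated icosahedron, built by
# trisecting the 30 icosahedron edges (two cuts per edge). All 60
# points are equidistant from the origin by vertex-transitivity.
tico_canonical <- function() {
  phi <- (1 + sqrt(5)) / 2
  base <- rbind(
    c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
    c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1)
  )
  d <- as.matrix(dist(base))
  pts <- matrix(0, 0, 3L)
  for (i in 1:11) for (j in (i + 1):12) {
    if (abs(d[i, j] - 2) < 1e-9) { # icosahedron edge
      pts <- rbind(pts,
                   (2 * base[i, ] + base[j, ]) / 3,
                   (base[i, ] + 2 * base[j, ]) / 3)
    }
  }
  pts / sqrt(sum(pts[1L, ]^2)) # unit sphere
}

# uniformly random rotation matrix (draws from the current RNG stream)
random_rotation <- function() {
  m <- matrix(rnorm(9L), 3L, 3L)
  qr_d <- qr(m)
  q <- qr.Q(qr_d)
  q <- q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Closure points on an enclosing sphere
#'
#' The 60 vertices of a truncated icosahedron (the C60 fullerene
#' geometry), uniformly randomly rotated, scaled to the sphere radius
#' and translated to its center.
#'
#' @param sphere result of [enclosing_sphere()].
#' @param orientation_seed integer seed determining the rotation.
#' @return 60 x 3 matrix of closure points.
#' @export
truncated_icosahedron_points <- function(sphere, orientation_seed = 1L) {
  rot <- with_seed(orientation_seed, random_rotation())
  pts <- tico_canonical() %*% t(rot) * sphere$radius
  sweep(pts, 2L, sphere$center, "+")
}

# as above but drawing the rotation from the current RNG stream
tico_points_stream <- function(sphere) {
  rot <- random_rotation()
  pts <- tico_canonical() %*% t(rot) * sphere$radius
  sweep(pts, 2L, sphere$center, "+")
}

#' Close a subchain through two sphere surface points
#'
#' Appends to the open subchain a segment from its C-end to surface
#' point A, a discretized great-circle arc from A to B (consecutive arc
#' points subtend at most `arc_step_deg` degrees at the center), and a
#' segment from B back to the N-start. Nearly antipodal pairs make the
#' great-circle arc ambiguous and raise a redraw condition.
#'
#' @param subchain N x 3 coordinate matrix (N >= 2).
#' @param points closure point set from [truncated_icosahedron_points()].
#' @param rng_draw integer pair of distinct point indices (1-based).
#' @param sphere the enclosing sphere the points sit on.
#' @param arc_step_deg maximal arc step in degrees (default 10).
#' @return a `closed_polygon` (list of `vertices`, `provenance`).
#' @export
random_closure <- function(subchain, points, rng_draw, sphere,
                           arc_step_deg = 10) {
  subchain <- as.matrix(subchain)
  if (nrow(subchain) < 2L) stop("subchain needs at least two vertices")
  i <- rng_draw[1L]; j <- rng_draw[2L]
  if (i == j) stop("closure point indices must be distinct")
  ua <- (points[i, ] - sphere$center) / sphere$radius
  ub <- (points[j, ] - sphere$center) / sphere$radius
  if (sum(ua * ub) < -0.995)
    stop("closure points nearly antipodal: redraw", call. = FALSE)
  poly <- build_closure_cpp(subchain, points[i, ], points[j, ],
                            sphere$center, sphere$radius, arc_step_deg)
  structure(list(vertices = poly, provenance = "random_closure"),
            class = "closed_polygon")
}

#' Close a subchain by joining its termini directly
#'
#' @param subchain N x 3 coordinate matrix (N >= 3).
#' @return a `closed_polygon` with provenance `"direct_closure"`.
#' @export
direct_closure <- function(subchain) {
  subchain <- as.matrix(subchain)
  if (nrow(subchain) < 3L) stop("need at least three vertices")
  n <- nrow(subchain)
  if (sqrt(sum((subchain[1L, ] - subchain[n, ])^2)) < 1e-9)
    subchain <- subchain[-n, , drop = FALSE]
  structure(list(vertices = subchain, provenance = "direct_closure"),
            class = "closed_polygon")
}

#' Treat an already-closed curve as a closed polygon
#'
#' @param vertices N x 3 coordinate matrix of a closed curve (the last
#'   vertex is adjacent to the first).
#' @return a `closed_polygon` with provenance `"native_closed"`.
#' @export
as_closed_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("need at least three vertices")
  structure(list(vertices = vertices, provenance = "native_closed"),
            class = "closed_polygon")
}

#' @export
print.closed_polygon <- function(x, ...) {
  cat(sprintf("<closed_polygon> %d vertices (%s)\n",
              nrow(x$vertices), x$provenance))
  invisible(x)
}
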