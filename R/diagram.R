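# Crossing diagrams: a planar projection of a closed polygon encoded as
# a signed Gauss code -- the cyclic sequence of crossing passages along
# the curve, each tagged over/under and with the crossing's right-hand
# sign. All polynomial invariants are computed from this encoding.

#' Construct a crossing diagram from a signed Gauss code
#'
#' @param gauss integer matrix with one row per passage, in curve
#'   order, and columns `crossing` (1..n, each id appearing exactly
#'   twice: once over, once under), `over` (1/0) and `sign` (+1/-1).
#' @return object of class `crossing_diagram` with fields `gauss`,
#'   `n_crossings` and `n_arcs`.
#' @export
new_crossing_diagram <- function(gauss) {
  gauss <- as.matrix(gauss)
  storage.mode(gauss) <- "integer"
  if (nrow(gauss) %% 2L != 0L) stop("malformed Gauss code: odd passage count")
  n <- nrow(gauss) / 2L
  if (n > 0L) {
    colnames(gauss) <- c("crossing", "over", "sign")
    tab <- table(factor(gauss[, 1L], levels = seq_len(n)), gauss[, 2L])
    if (!all(tab == 1L))
      stop("malformed Gauss code: each crossing needs one over and one under passage")
  }
  structure(list(gauss = gauss, n_crossings = as.integer(n),
                 n_arcs = as.integer(n)),
            class = "crossing_diagram")
}

#' @export
print.crossing_diagram <- function(x, ...) {
  cat(sprintf("<crossing_diagram> %d crossings, writhe %d\n",
              x$n_crossings, diagram_writhe(x)))
  invisible(x)
}

#' Sum of crossing signs of a diagram
#' @param diagram a `crossing_diagram`.
#' @return integer writhe.
#' @export
diagram_writhe <- function(diagram) {
  g <- diagram$gauss
  if (nrow(g) == 0L) return(0L)
  as.integer(sum(g[!duplicated(g[, 1L]), 3L]))
}

#' Project a closed polygon to a generic crossing diagram
#'
#' Orthogonal projection along a seeded random direction; over/under is
#' decided by depth. Directions giving a non-generic picture (an edge
#' nearly parallel to the view axis, a crossing at a vertex, a depth
#' tie or a near triple point) are rejected and redrawn, up to
#' `max_tries` attempts.
#'
#' @param polygon a `closed_polygon` or N x 3 matrix.
#' @param direction_seed integer seed for the direction draws.
#' @param max_tries bound on redraws (default 100).
#' @param tol degeneracy tolerance.
#' @return a `crossing_diagram`.
#' @export
project_to_diagram <- function(polygon, direction_seed = 1L,
                               max_tries = 100L, tol = 1e-9) {
  pts <- polygon_coords(polygon)
  if (nrow(pts) < 3L) stop("polygon needs at least three vertices")
  with_seed(direction_seed, {
    for (i in seq_len(max_tries)) {
      d <- rnorm(3L)
      l <- sqrt(sum(d^2))
      if (l < 1e-9) next
      res <- project_gauss_cpp(pts, d / l, tol)
      if (isTRUE(res$ok)) return(new_crossing_diagram(res$gauss))
    }
    stop("no generic projection found")
  })
}

#' Mirror image of a crossing diagram
#'
#' Reflection through the projection plane: every passage swaps
#' over/under and every crossing sign flips.
#'
#' @param diagram a `crossing_diagram`.
#' @return the mirrored `crossing_diagram`.
#' @export
mirror_diagram <- function(diagram) {
  g <- diagram$gauss
  if (nrow(g) > 0L) {
    g[, 2L] <- 1L - g[, 2L]
    g[, 3L] <- -g[, 3L]
  }
  new_crossing_diagram(g)
}

#' Mirror a polygon by negating one coordinate
#'
#' @param polygon a `closed_polygon` or coordinate matrix.
#' @param axis coordinate to negate (default 3, the z axis).
#' @return object of the same kind with the axis negated.
#' @export
mirror_polygon <- function(polygon, axis = 3L) {
  pts <- polygon_coords(polygon)
  pts[, axis] <- -pts[, axis]
  if (inherits(polygon, "closed_polygon")) {
    polygon$vertices <- pts
    polygon
  } else pts
}

#' Gauss code of a braid closure
#'
#' Builds the signed Gauss code of the trace closure of a braid word.
#' Letter `i > 0` is the positive generator crossing strands in slots
#' `i` and `i+1` (sign +1); negative letters give the inverse crossing.
#'
#' @param word integer vector of nonzero letters.
#' @param n_strands number of strands; default `max(abs(word)) + 1`.
#' @return a `crossing_diagram`.
#' @export
braid_diagram <- function(word, n_strands = max(abs(word)) + 1L) {
  if (any(word == 0L)) stop("braid letters must be nonzero")
  k <- n_strands
  perm <- seq_len(k)                    # slot -> strand id
  passages <- vector("list", k)         # per strand, rows (crossing, over, sign)
  for (idx in seq_along(word)) {
    i <- abs(word[idx]); s <- sign(word[idx])
    if (i >= k) stop("braid letter exceeds strand count")
    a <- perm[i]; b <- perm[i + 1L]
    over_a <- if (s > 0L) 1L else 0L
    passages[[a]] <- rbind(passages[[a]], c(idx, over_a, s))
    passages[[b]] <- rbind(passages[[b]], c(idx, 1L - over_a, s))
    perm[c(i, i + 1L)] <- perm[c(i + 1L, i)]
  }
  # trace closure: top slot s joins bottom slot s; follow the cycle
  top_slot <- match(seq_len(k), perm)   # strand -> its final slot
  visited <- logical(k)
  gauss <- NULL
  strand <- 1L
  repeat {
    visited[strand] <- TRUE
    gauss <- rbind(gauss, passages[[strand]])
    strand <- top_slot[strand]
    if (strand == 1L) break
    if (visited[strand]) stop("braid closure is not a single component")
  }
  if (!all(visited)) stop("braid closure is not a single component")
  if (is.null(gauss)) gauss <- matrix(integer(), 0L, 3L)
  new_crossing_diagram(gauss)
}
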