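# KMT chain reduction: iterated elimination of vertices whose triangle
# (formed with the two neighbours) is pierced by no other chain
# segment. The result is a much shorter polygon of identical knot type,
# which makes the polynomial invariants cheap.

#' Conservative segment-triangle intersection test
#'
#' True when the closed segment meets the closed triangle. Any contact
#' within the tolerance of a boundary or degenerate case is reported as
#' an intersection, so that a vertex is never removed when removal
#' could change the topology.
#'
#' @param seg 2 x 3 matrix (segment endpoints).
#' @param tri 3 x 3 matrix (triangle vertices).
#' @param tol dimensionless tolerance (default 1e-9), applied relative
#'   to the local geometry scale.
#' @return logical.
#' @export
segment_triangle_intersects <- function(seg, tri, tol = 1e-9) {
  seg <- as.matrix(seg); tri <- as.matrix(tri)
  seg_tri_intersect_cpp(seg[1L, ], seg[2L, ], tri[1L, ], tri[2L, ], tri[3L, ], tol)
}

#' Reduce a closed polygon by triangle elimination
#'
#' Repeatedly scans consecutive vertex triples and removes the middle
#' vertex whenever the spanned triangle is intersected by no other
#' chain segment; passes are iterated until a fixed point. The two
#' segments adjacent to a triangle (those sharing one of its corners)
#' are tested away from the shared corner rather than skipped, so a
#' strand hugging the triangle still blocks removal.
#'
#' @param polygon a `closed_polygon` or N x 3 coordinate matrix.
#' @param tol conservative intersection tolerance (default 1e-9).
#' @return list with `polygon` (a `closed_polygon`), `removed_count`
#'   and `passes`.
#' @export
kmt_reduce <- function(polygon, tol = 1e-9) {
  pts <- polygon_coords(polygon)
  res <- kmt_reduce_cpp(pts, tol)
  prov <- if (inherits(polygon, "closed_polygon")) polygon$provenance else "native_closed"
  list(
    polygon = structure(list(vertices = res$polygon, provenance = prov),
                        class = "closed_polygon"),
    removed_count = nrow(pts) - nrow(res$polygon),
    passes = res$passes
  )
}

polygon_coords <- function(polygon) {
  if (inherits(polygon, "closed_polygon")) polygon$vertices
  else as.matrix(polygon)
}
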