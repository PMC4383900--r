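# Single-polygon classification and probabilistic knot typing of open
# chains.

#' Classify a closed polygon
#'
#' KMT-reduces the polygon, projects it to a generic diagram, computes
#' the Alexander signature and looks it up in the built-in table; for
#' chiral knots the HOMFLY polynomial of the reduced diagram resolves
#' the +/- sign. Mirroring the polygon flips the sign and nothing else.
#'
#' @param polygon a `closed_polygon` or N x 3 coordinate matrix.
#' @param seed integer seed for the projection direction draws.
#' @param with_chirality resolve chirality via HOMFLY (default TRUE).
#' @param max_homfly_crossings bound above which chirality is left
#'   undetermined (default 16).
#' @return a [knot_label()].
#' @export
classify_full <- function(polygon, seed = 1L, with_chirality = TRUE,
                          max_homfly_crossings = 16L) {
  red <- kmt_reduce(polygon)$polygon
  dia <- project_to_diagram(red, direction_seed = seed)
  lab <- classify_by_alexander(alexander_signature(dia))
  if (with_chirality && !is.na(lab$crossing_number) &&
      lab$crossing_number > 0L && lab$chirality == "undetermined") {
    name <- label_base(lab$display)
    chir <- chirality_from_homfly(dia, name, max_homfly_crossings)
    lab <- knot_label(lab$crossing_number, lab$table_index, chir)
  }
  lab
}

# deterministic per-cell seed; equals `seed` for the full chain (k = 1,
# l = N) so that a fingerprint cell and a standalone call agree
cell_seed <- function(seed, k, l, n) {
  as.integer((seed + 131 * (k - 1) + 257 * (n - l)) %% 2147483647L)
}

# signatures -> display names, vectorized over the rows of `sigs`
signatures_to_names <- function(sigs) {
  key <- paste(sigs[, 1L], sigs[, 2L])
  uk <- unique(key)
  lut <- vapply(uk, function(kk) {
    d <- as.numeric(strsplit(kk, " ")[[1L]])
    classify_by_alexander(list(d1 = d[1L], d2 = d[2L]))$display
  }, character(1))
  unname(lut[key])
}

#' Dominant knot type of an open subchain
#'
#' Closes the subchain `n_closures` times through random pairs of
#' closure points, classifies every closure, and returns the plurality
#' label together with the full frequency map. A tie involving the
#' unknot resolves to the unknot; other ties resolve to the
#' lower-crossing-number label.
#'
#' @param subchain N x 3 coordinate matrix (or `knot_chain`).
#' @param n_closures number of random closures (default 200).
#' @param seed integer seed governing all draws.
#' @param points optional shared closure point set (60 x 3); built from
#'   `seed` when missing.
#' @param sphere enclosing sphere the points sit on; built from the
#'   subchain when missing.
#' @param inflation sphere inflation factor (default 10).
#' @param arc_step_deg closure-arc discretization (default 10 degrees).
#' @param pairs optional explicit matrix of closure point index pairs,
#'   overriding the random draws (used to enumerate closures).
#' @return list with `label` (a [knot_label()]), `frequencies` (named
#'   fractions summing to 1), `n_closures` and `seed`.
#' @export
dominant_knot <- function(subchain, n_closures = 200L, seed = 1L,
                          points = NULL, sphere = NULL, inflation = 10,
                          arc_step_deg = 10, pairs = NULL) {
  pts <- if (inherits(subchain, "knot_chain")) subchain$vertices else as.matrix(subchain)
  if (nrow(pts) < 3L) {
    return(list(label = knot_label(0L, 1L, "achiral"),
                frequencies = c("0_1" = 1), n_closures = 0L, seed = seed))
  }
  if (is.null(sphere)) sphere <- enclosing_sphere(pts, inflation)
  if (is.null(points)) points <- truncated_icosahedron_points(sphere, seed)
  sigs <- with_seed(seed,
    closure_signatures_cpp(pts, points, sphere$center, sphere$radius,
                           as.integer(n_closures), arc_step_deg, 1e-9, 100L,
                           pairs))
  labs <- signatures_to_names(sigs)
  freq <- table(labs) / length(labs)
  freq <- setNames(as.numeric(freq), names(freq))
  best <- names(freq)[freq == max(freq)]
  pick <- if ("0_1" %in% best) "0_1" else {
    cr <- suppressWarnings(as.integer(sub("_.*", "", best)))
    ti <- suppressWarnings(as.integer(sub(".*_", "", best)))
    cr[is.na(cr)] <- .Machine$integer.max
    ti[is.na(ti)] <- .Machine$integer.max
    best[order(cr, ti)][1L]
  }
  lab <- if (pick == "0_1") knot_label(0L, 1L, "achiral")
         else if (pick == "unknown") unknown_label()
         else {
           parts <- as.integer(strsplit(pick, "_")[[1L]])
           tab <- knot_signature_table()
           chir <- if (isTRUE(tab$chiral[tab$name == pick])) "undetermined" else "achiral"
           knot_label(parts[1L], parts[2L], chir)
         }
  list(label = lab, frequencies = freq,
       n_closures = if (is.null(pairs)) as.integer(n_closures) else nrow(pairs),
       seed = seed)
}
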