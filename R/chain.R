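#' Construct a polymer chain object
#'
#' A `knot_chain` is an ordered alpha-carbon (or generic vertex) trace:
#' an N x 3 coordinate matrix in Angstroms plus residue bookkeeping and
#' chain-break annotations.
#'
#' @param vertices numeric N x 3 matrix of coordinates (Angstrom).
#' @param residue_ids integer vector of length N, strictly increasing.
#'   Defaults to `1:N`.
#' @param residue_names character vector of 3-letter residue codes
#'   (empty strings for coordinate-only input).
#' @param chain_id single chain identifier string.
#' @param model_index model number the trace was taken from (1 for
#'   non-NMR input).
#' @param breaks data frame with columns `after_index` (vertex position
#'   preceding the break), `kind` (`"numbering_gap"` or
#'   `"distance_gap"`) and `span_residues` (number of missing residues,
#'   0 if unknown).
#' @param orig_residue_ids residue identifiers as authored in the source
#'   file (kept when insertion codes force renumbering).
#'
#' @return An object of class `knot_chain`.
#' @export
new_chain <- function(vertices,
                      residue_ids = seq_len(nrow(vertices)),
                      residue_names = rep("", nrow(vertices)),
                      chain_id = "A",
                      model_index = 1L,
                      breaks = empty_breaks(),
                      orig_residue_ids = residue_ids) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have three columns")
  n <- nrow(vertices)
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != n || length(residue_names) != n)
    stop("residue_ids and residue_names must match the number of vertices")
  if (n > 1L && any(diff(residue_ids) <= 0L))
    stop("residue_ids must be strictly increasing")
  chain <- structure(
    list(
      vertices = vertices,
      residue_ids = residue_ids,
      residue_names = as.character(residue_names),
      chain_id = as.character(chain_id),
      model_index = as.integer(model_index),
      breaks = breaks,
      bridged = rep(FALSE, max(n - 1L, 0L)),
      orig_residue_ids = orig_residue_ids
    ),
    class = "knot_chain"
  )
  validate_chain(chain)
}

empty_breaks <- function() {
  data.frame(after_index = integer(), kind = character(),
             span_residues = integer(), stringsAsFactors = FALSE)
}

validate_chain <- function(chain) {
  n <- nrow(chain$vertices)
  b <- chain$breaks
  if (nrow(b) > 0L) {
    if (any(b$after_index < 1L | b$after_index >= n))
      stop("break after_index must refer to an adjacent vertex pair")
    if (!all(b$kind %in% c("numbering_gap", "distance_gap")))
      stop("unknown break kind")
  }
  chain
}

#' @export
print.knot_chain <- function(x, ...) {
  cat(sprintf("<knot_chain> %d vertices, chain '%s', model %d\n",
              nrow(x$vertices), x$chain_id, x$model_index))
  if (nrow(x$breaks) > 0L)
    cat(sprintf("  breaks: %d (%s)\n", nrow(x$breaks),
                paste(x$breaks$kind, collapse = ", ")))
  if (any(x$bridged))
    cat(sprintf("  bridged segments: %d (results will be putative)\n",
                sum(x$bridged)))
  invisible(x)
}

#' @export
length.knot_chain <- function(x) nrow(x$vertices)

#' Extract the coordinates of a subchain
#'
#' @param chain a `knot_chain`.
#' @param k,l first and last vertex positions (1-based, `k < l`).
#' @return numeric matrix of subchain coordinates.
#' @export
subchain_coords <- function(chain, k, l) {
  n <- nrow(chain$vertices)
  if (k < 1L || l > n || k >= l) stop("need 1 <= k < l <= N")
  chain$vertices[k:l, , drop = FALSE]
}

#' Does a chain carry any bridged (reconstructed) segment?
#'
#' Chains whose breaks have been bridged by straight segments yield
#' results that must be interpreted with care; this predicate is the
#' machine-readable "putative" flag propagated to all downstream output.
#'
#' @param chain a `knot_chain`.
#' @return logical flag.
#' @export
is_putative <- function(chain) any(chain$bridged)
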