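# Alexander polynomial classification.
#
# The Alexander matrix is assembled from the Wirtinger presentation of
# the diagram (one relation per crossing, one generator per arc); one
# row and one column are deleted and the determinant is computed by
# fraction-free elimination over Z[t] in exact integer arithmetic. The
# polynomial is normalized to its minimal-degree representative with
# value +1 at t = 1, which removes the usual +/- t^k ambiguity. Two
# integer evaluations, |D(-1)| and |D(-2)|, separate all knot types
# handled by the built-in table.

#' Normalized Alexander polynomial of a diagram
#'
#' @param diagram a `crossing_diagram`.
#' @return integer coefficient vector, constant term first; the unknot
#'   gives `1`.
#' @export
alexander_poly <- function(diagram) {
  as.numeric(alexander_coeffs_cpp(diagram$gauss))
}

#' Evaluate the Alexander polynomial at an integer
#'
#' @param diagram a `crossing_diagram`.
#' @param t nonzero integer evaluation point.
#' @return `|D(t)|` of the normalized polynomial, an exact integer.
#' @export
alexander_eval <- function(diagram, t) {
  if (t == 0) stop("t must be nonzero")
  co <- alexander_poly(diagram)
  abs(sum(co * t^(seq_along(co) - 1L)))
}

#' Alexander signature (|D(-1)|, |D(-2)|) of a diagram
#'
#' @param diagram a `crossing_diagram`.
#' @return list with integer fields `d1` and `d2`.
#' @export
alexander_signature <- function(diagram) {
  co <- alexander_poly(diagram)
  pw <- seq_along(co) - 1L
  list(d1 = abs(sum(co * (-1)^pw)), d2 = abs(sum(co * (-2)^pw)))
}

#' Construct a knot label
#'
#' @param crossing_number minimal crossing number (0 for the unknot).
#' @param table_index index within the standard table.
#' @param chirality one of `"plus"`, `"minus"`, `"achiral"`,
#'   `"undetermined"`.
#' @return object of class `knot_label`.
#' @export
knot_label <- function(crossing_number, table_index,
                       chirality = "undetermined") {
  display <- if (is.na(crossing_number)) "unknown"
  else {
    suffix <- switch(chirality, plus = "+", minus = "-", "")
    sprintf("%d_%d%s", crossing_number, table_index, suffix)
  }
  structure(list(crossing_number = crossing_number,
                 table_index = table_index,
                 chirality = chirality,
                 display = display),
            class = "knot_label")
}

unknown_label <- function() knot_label(NA_integer_, NA_integer_)

#' @export
print.knot_label <- function(x, ...) {
  cat(x$display, "\n")
  invisible(x)
}

#' @export
format.knot_label <- function(x, ...) x$display

# label name ("3_1") without chirality suffix
label_base <- function(display) sub("[+-]$", "", display)

#' Classify an Alexander signature against the built-in table
#'
#' Looks up (|D(-1)|, |D(-2)|) among the signatures of the tabulated
#' prime knots. Chirality is left undetermined at this stage (the
#' signature cannot see it); unmatched signatures -- including those of
#' composite knots, whose polynomial is a product -- give `"unknown"`.
#'
#' @param sig list with `d1`, `d2` (from [alexander_signature()]), or a
#'   numeric vector of length two.
#' @return a [knot_label()].
#' @export
classify_by_alexander <- function(sig) {
  if (!is.list(sig)) sig <- list(d1 = sig[1L], d2 = sig[2L])
  if (sig$d1 == 1 && sig$d2 == 1) return(knot_label(0L, 1L, "achiral"))
  tab <- knot_signature_table()
  hit <- which(tab$d1 == sig$d1 & tab$d2 == sig$d2)
  if (length(hit) != 1L) return(unknown_label())
  knot_label(tab$crossing_number[hit], tab$table_index[hit],
             if (tab$chiral[hit]) "undetermined" else "achiral")
}
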