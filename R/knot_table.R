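# Built-in table of prime knots and the reference curves that generate
# them.
#
# Every table entry carries a constructive reference: either a rational
# (2-bridge) plat, identified by the positive continued-fraction vector
# of its Schubert fraction p/q, or a braid word whose trace closure is
# the knot. Reference signatures are regenerated from these curves at
# first use, never stored as magic numbers, and the 2-bridge entries
# are independently checkable because |D(-1)| must equal the continuant
# p of the fraction.

# ---------------------------------------------------------------- curves

half_twist_arc <- function(y_lo, y_hi, x0, x1, dir, start_low, n_seg = 5L,
                           h = 0.45) {
  # one half-twist of a strand between slots y_lo/y_hi over x in [x0,x1];
  # start_low: does this strand start at y_lo? dir = +-1 sets handedness.
  ym <- (y_lo + y_hi) / 2
  r <- (y_hi - y_lo) / 2
  th0 <- if (start_low) pi else 0
  tt <- seq(0, 1, length.out = n_seg + 1L)
  th <- th0 + dir * pi * tt
  cbind(x0 + (x1 - x0) * tt, ym + r * cos(th), h * sin(th))
}

#' Closed curve realizing the trace closure of a braid word
#'
#' Strands run along x in integer slots; each letter contributes one
#' geometric half twist of the adjacent pair (positive letters rotate
#' one way, negative the other), and the trace closure returns every
#' strand to its starting slot well below the braid plane.
#'
#' @param word integer vector of nonzero braid letters.
#' @param n_strands strand count; default `max(abs(word)) + 1`.
#' @return N x 3 coordinate matrix of a closed polygonal curve.
#' @export
braid_closure_curve <- function(word, n_strands = max(abs(word)) + 1L) {
  k <- n_strands
  L <- length(word)
  perm <- seq_len(k)                 # slot -> strand
  paths <- lapply(seq_len(k), function(s) matrix(c(0, s, 0), 1L, 3L))
  for (idx in seq_along(word)) {
    i <- abs(word[idx]); s <- sign(word[idx])
    a <- perm[i]; b <- perm[i + 1L]
    x0 <- idx - 1; x1 <- idx
    arc_a <- half_twist_arc(i, i + 1L, x0, x1, s, start_low = TRUE)
    arc_b <- half_twist_arc(i, i + 1L, x0, x1, s, start_low = FALSE)
    paths[[a]] <- rbind(paths[[a]], arc_a[-1L, , drop = FALSE])
    paths[[b]] <- rbind(paths[[b]], arc_b[-1L, , drop = FALSE])
    for (other in setdiff(seq_len(k), c(i, i + 1L)))
      paths[[perm[other]]] <- rbind(paths[[perm[other]]], c(x1, other, 0))
    perm[c(i, i + 1L)] <- perm[c(i + 1L, i)]
  }
  top_slot <- match(seq_len(k), perm)
  # assemble: strand, then its return path at a strand-specific depth
  visited <- logical(k)
  curve <- NULL
  strand <- 1L
  repeat {
    visited[strand] <- TRUE
    p <- paths[[strand]]
    slot_end <- top_slot[strand]
    z_ret <- -(1.2 + 0.45 * strand)
    ret <- rbind(c(L + 1, slot_end, z_ret),
                 c(-1, slot_end, z_ret),
                 c(0, slot_end, 0))
    curve <- rbind(curve, p, ret)
    strand <- slot_end
    if (strand == 1L) break
    if (visited[strand]) stop("braid closure is not a single component")
  }
  if (!all(visited)) stop("braid closure is not a single component")
  dedupe_curve(curve)
}

dedupe_curve <- function(curve) {
  n <- nrow(curve)
  keep <- c(TRUE, rowSums((curve[-1L, , drop = FALSE] -
                           curve[-n, , drop = FALSE])^2) > 1e-18)
  curve <- curve[keep, , drop = FALSE]
  n <- nrow(curve)
  if (sum((curve[1L, ] - curve[n, ])^2) < 1e-18)
    curve <- curve[-n, , drop = FALSE]
  curve
}

#' Closed curve of a 2-bridge (rational) knot
#'
#' Builds the standard 4-plat: four strands capped pairwise at both
#' ends, with the twist regions prescribed by the positive continued
#' fraction `b` of the Schubert fraction p/q (p odd for a knot). Box
#' parity alternates between the middle pair and an outer pair, with
#' alternating handedness, which yields the alternating diagram.
#'
#' @param b integer vector of positive continued-fraction terms.
#' @return N x 3 coordinate matrix of a closed polygonal curve.
#' @export
rational_knot_curve <- function(b) {
  if (any(b < 1L)) stop("continued-fraction terms must be positive")
  # plat closure needs an odd number of twist boxes; rewrite the
  # fraction ([..., k] == [..., k-1, 1], trailing 1 merges) until odd
  while (length(b) %% 2L == 0L) {
    m <- length(b)
    b <- if (b[m] > 1L) c(b[seq_len(m - 1L)], b[m] - 1L, 1L)
         else c(b[seq_len(m - 2L)], b[m - 1L] + 1L)
  }
  paths <- lapply(1:4, function(s) matrix(c(0, s, 0), 1L, 3L))
  perm <- 1:4                        # slot -> strand
  x <- 0
  for (j in seq_along(b)) {
    pair <- if (j %% 2L == 1L) 2L else 1L       # slots (2,3) or (1,2)
    dir <- if (j %% 2L == 1L) 1 else -1
    for (tw in seq_len(b[j])) {
      a <- perm[pair]; bb <- perm[pair + 1L]
      arc_a <- half_twist_arc(pair, pair + 1L, x, x + 1, dir, TRUE)
      arc_b <- half_twist_arc(pair, pair + 1L, x, x + 1, dir, FALSE)
      paths[[a]] <- rbind(paths[[a]], arc_a[-1L, , drop = FALSE])
      paths[[bb]] <- rbind(paths[[bb]], arc_b[-1L, , drop = FALSE])
      for (other in setdiff(1:4, c(pair, pair + 1L)))
        paths[[perm[other]]] <- rbind(paths[[perm[other]]], c(x + 1, other, 0))
      perm[c(pair, pair + 1L)] <- perm[c(pair + 1L, pair)]
      x <- x + 1
    }
  }
  # plat closure: caps join slots (1,2) and (3,4) at both ends
  ends <- match(1:4, perm)           # strand -> final slot
  cap_mate <- c(2L, 1L, 4L, 3L)
  cap_arc <- function(y1, y2, x0, bulge) {
    th <- seq(0, pi, length.out = 7L)
    mid <- (y1 + y2) / 2; r <- abs(y2 - y1) / 2
    cbind(x0 + bulge * sin(th), mid - r * cos(th) * sign(y2 - y1), 0)
  }
  # walk: strand up, top cap, strand down, bottom cap, ...
  curve <- NULL
  strand <- 1L
  going_up <- TRUE
  visited <- logical(4L)
  repeat {
    if (visited[strand]) stop("plat closure is not a single component (p even?)")
    visited[strand] <- TRUE
    if (going_up) {
      curve <- rbind(curve, paths[[strand]])
      s_end <- ends[strand]
      mate_slot <- cap_mate[s_end]
      cap <- cap_arc(s_end, mate_slot, x, 1.2)
      curve <- rbind(curve, cap[-c(1L, nrow(cap)), , drop = FALSE])
      strand <- perm[mate_slot]
      going_up <- FALSE
    } else {
      p <- paths[[strand]]
      curve <- rbind(curve, p[rev(seq_len(nrow(p))), , drop = FALSE])
      mate_slot <- cap_mate[strand]  # starting slot == strand id
      cap <- cap_arc(strand, mate_slot, 0, -1.2)
      curve <- rbind(curve, cap[-c(1L, nrow(cap)), , drop = FALSE])
      strand <- mate_slot
      going_up <- TRUE
      if (strand == 1L) break
    }
  }
  if (!all(visited)) stop("plat closure is not a single component (p even?)")
  dedupe_curve(curve)
}

#' Continuant fraction of a positive continued fraction
#'
#' Returns `c(p, q)` with `p/q = b1 + 1/(b2 + 1/(...))`, the Schubert
#' fraction of the rational knot built from `b`. Used as an arithmetic
#' cross-check: the knot determinant must equal `p`.
#'
#' @param b integer vector of positive terms.
#' @return integer vector `c(p, q)` in lowest terms.
#' @export
cf_fraction <- function(b) {
  p <- b[length(b)]; q <- 1
  for (i in rev(seq_len(length(b) - 1L))) {
    tmp <- p
    p <- b[i] * p + q
    q <- tmp
  }
  c(p, q)
}

# ----------------------------------------------------------------- table

# Reference constructions. cf: positive continued fraction (Schubert
# fraction p/q); braid: trace-closure word. The amphichiral knots
# through 8 crossings are 4_1, 6_3, 8_3, 8_9, 8_12, 8_17, 8_18.
knot_table_entries <- function() {
  list(
    list(name = "3_1",  cf = c(3)),
    list(name = "4_1",  cf = c(2, 2), achiral = TRUE),
    list(name = "5_1",  cf = c(5)),
    list(name = "5_2",  cf = c(3, 2)),
    list(name = "6_1",  cf = c(4, 2)),
    list(name = "6_2",  cf = c(3, 1, 2)),
    list(name = "6_3",  cf = c(2, 1, 1, 2), achiral = TRUE),
    list(name = "7_1",  cf = c(7)),
    list(name = "7_2",  cf = c(5, 2)),
    list(name = "7_3",  cf = c(3, 4)),
    list(name = "7_4",  cf = c(3, 1, 3)),
    list(name = "7_5",  cf = c(2, 2, 3)),
    list(name = "7_6",  cf = c(2, 2, 1, 2)),
    list(name = "7_7",  cf = c(2, 1, 1, 1, 2)),
    list(name = "8_1",  cf = c(6, 2)),
    list(name = "8_2",  cf = c(5, 1, 2)),
    list(name = "8_3",  cf = c(4, 4), achiral = TRUE),
    list(name = "8_4",  cf = c(4, 1, 3)),
    list(name = "8_5",  braid = c(1, 1, 1, -2, 1, 1, 1, -2)),
    list(name = "8_6",  cf = c(2, 3, 3)),
    list(name = "8_7",  cf = c(2, 1, 1, 4)),
    list(name = "8_8",  cf = c(2, 1, 3, 2)),
    list(name = "8_9",  cf = c(3, 1, 1, 3), achiral = TRUE),
    list(name = "8_11", cf = c(3, 2, 1, 2)),
    list(name = "8_12", cf = c(2, 2, 2, 2), achiral = TRUE),
    list(name = "8_13", cf = c(2, 1, 1, 1, 3)),
    list(name = "8_14", cf = c(2, 1, 1, 2, 2)),
    list(name = "8_16", braid = c(1, 1, -2, 1, 1, -2, 1, -2)),
    list(name = "8_17", braid = c(1, 1, -2, 1, -2, 1, -2, -2), achiral = TRUE),
    list(name = "8_18", braid = rep(c(1, -2), 4L), achiral = TRUE),
    list(name = "8_19", braid = rep(c(1, 2), 4L))
  )
}

#' Reference closed curve for a tabulated knot
#'
#' @param name knot name such as `"6_2"`.
#' @return N x 3 coordinate matrix (the `+` representative of chiral
#'   entries, in this package's convention).
#' @export
reference_curve <- function(name) {
  entries <- knot_table_entries()
  nm <- vapply(entries, `[[`, "", "name")
  e <- entries[[match(name, nm)]]
  if (is.null(e)) stop(sprintf("no reference curve for '%s'", name))
  if (!is.null(e$cf)) rational_knot_curve(e$cf) else braid_closure_curve(e$braid)
}

# reduce + project a reference curve with fixed, deterministic seeds
reference_diagram <- function(curve) {
  red <- kmt_reduce_cpp(curve, 1e-9)$polygon
  project_to_diagram(red, direction_seed = 42L)
}

#' Signature table of the built-in knots
#'
#' Regenerates (on first use, then cached) the Alexander signature
#' (|D(-1)|, |D(-2)|) of every tabulated knot from its reference curve.
#'
#' @return data frame with columns `name`, `crossing_number`,
#'   `table_index`, `chiral`, `d1`, `d2`.
#' @export
knot_signature_table <- function() {
  cached <- .knotscan_cache$signature_table
  if (!is.null(cached)) return(cached)
  entries <- knot_table_entries()
  rows <- lapply(entries, function(e) {
    curve <- if (!is.null(e$cf)) rational_knot_curve(e$cf)
             else braid_closure_curve(e$braid)
    sig <- alexander_signature(reference_diagram(curve))
    parts <- as.integer(strsplit(e$name, "_")[[1L]])
    data.frame(name = e$name, crossing_number = parts[1L],
               table_index = parts[2L],
               chiral = !isTRUE(e$achiral),
               d1 = sig$d1, d2 = sig$d2, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  dup <- duplicated(tab[, c("d1", "d2")])
  if (any(dup))
    warning("signature collision in knot table: ",
            paste(tab$name[dup], collapse = ", "))
  .knotscan_cache$signature_table <- tab
  tab
}
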