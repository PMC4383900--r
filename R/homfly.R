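# HOMFLY polynomial by skein recursion.
#
# Convention: v^{-1} P(L+) - v P(L-) = z P(L0), unknot = 1, so a split
# k-component unlink has P = delta^{k-1} with delta = (v^{-1} - v)/z.
# The recursion switches or smooths the first crossing whose first
# passage along the (based, ordered) traversal goes under; a diagram
# with no such crossing is descending, hence an unlink. Laurent
# polynomials in (v, z) are stored as named numeric vectors with names
# "i,j" for v^i z^j.

hp_zero <- function() setNames(numeric(0), character(0))
hp_term <- function(vi, zi, coef = 1) setNames(coef, paste0(vi, ",", zi))

hp_add <- function(a, b) {
  keys <- union(names(a), names(b))
  out <- setNames(numeric(length(keys)), keys)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out[abs(out) > 1e-9]
}

hp_shift <- function(p, vi, zi, coef = 1) {
  if (length(p) == 0L) return(p)
  ex <- do.call(rbind, lapply(strsplit(names(p), ","), as.integer))
  setNames(as.numeric(p) * coef, paste0(ex[, 1L] + vi, ",", ex[, 2L] + zi))
}

hp_mul <- function(a, b) {
  out <- hp_zero()
  if (length(a) == 0L || length(b) == 0L) return(out)
  ea <- do.call(rbind, lapply(strsplit(names(a), ","), as.integer))
  for (i in seq_along(a))
    out <- hp_add(out, hp_shift(b, ea[i, 1L], ea[i, 2L], a[i]))
  out
}

hp_delta <- function() hp_add(hp_term(-1L, -1L, 1), hp_term(1L, -1L, -1))

hp_delta_pow <- function(k) {
  out <- hp_term(0L, 0L, 1)
  if (k > 0L) for (i in seq_len(k)) out <- hp_mul(out, hp_delta())
  out
}

# canonical string of a component list (crossings relabelled by first
# appearance) for memoization
comps_key <- function(comps) {
  relab <- integer(0)
  parts <- character(length(comps))
  for (ci in seq_along(comps)) {
    m <- comps[[ci]]
    if (nrow(m) == 0L) { parts[ci] <- "o"; next }
    ids <- integer(nrow(m))
    for (r in seq_len(nrow(m))) {
      c_old <- m[r, 1L]
      pos <- match(c_old, relab)
      if (is.na(pos)) { relab <- c(relab, c_old); pos <- length(relab) }
      ids[r] <- pos
    }
    parts[ci] <- paste(ids, m[, 2L], m[, 3L], sep = ".", collapse = ";")
  }
  paste(parts, collapse = "|")
}

homfly_rec <- function(comps, memo) {
  # split off crossing-free components
  free <- vapply(comps, nrow, 0L) == 0L
  n_free <- sum(free)
  comps <- comps[!free]
  if (length(comps) == 0L) return(hp_delta_pow(max(n_free - 1L, 0L)))
  base <- if (n_free > 0L) hp_delta_pow(n_free) else NULL

  key <- comps_key(comps)
  cached <- memo[[key]]
  if (!is.null(cached)) {
    return(if (is.null(base)) cached else hp_mul(base, cached))
  }

  # first bad crossing along the based traversal
  seen <- integer(0)
  bad <- NULL
  for (ci in seq_along(comps)) {
    m <- comps[[ci]]
    for (r in seq_len(nrow(m))) {
      cr <- m[r, 1L]
      if (!(cr %in% seen)) {
        seen <- c(seen, cr)
        if (m[r, 2L] == 0L) { bad <- c(ci, r); break }
      }
    }
    if (!is.null(bad)) break
  }

  if (is.null(bad)) {
    val <- hp_delta_pow(length(comps) - 1L)
  } else {
    ci <- bad[1L]; ri <- bad[2L]
    cr <- comps[[ci]][ri, 1L]
    s <- comps[[ci]][ri, 3L]
    # locate the partner passage
    pj <- NULL
    for (cj in seq_along(comps)) {
      rows <- which(comps[[cj]][, 1L] == cr)
      rows <- rows[!(cj == ci & rows == ri)]
      if (length(rows) > 0L) { pj <- c(cj, rows[1L]); break }
    }
    # switched diagram
    sw <- comps
    for (p in list(c(ci, ri), pj)) {
      sw[[p[1L]]][p[2L], 2L] <- 1L - sw[[p[1L]]][p[2L], 2L]
      sw[[p[1L]]][p[2L], 3L] <- -s
    }
    # smoothed diagram (oriented smoothing removes the crossing)
    sm <- comps
    if (pj[1L] == ci) {
      m <- comps[[ci]]
      i <- min(ri, pj[2L]); j <- max(ri, pj[2L])
      c1 <- m[seq(i + 1L, length.out = j - i - 1L), , drop = FALSE]
      keep <- setdiff(seq_len(nrow(m)), i:j)
      c2 <- m[c(keep[keep > j], keep[keep < i]), , drop = FALSE]
      sm[[ci]] <- c1
      sm <- c(sm, list(c2))
    } else {
      a <- comps[[ci]]; b <- comps[[pj[1L]]]
      i <- ri; j <- pj[2L]
      merged <- rbind(a[seq_len(i - 1L), , drop = FALSE],
                      b[seq(j + 1L, length.out = nrow(b) - j), , drop = FALSE],
                      b[seq_len(j - 1L), , drop = FALSE],
                      a[seq(i + 1L, length.out = nrow(a) - i), , drop = FALSE])
      sm[[ci]] <- merged
      sm[[pj[1L]]] <- NULL
    }
    val <- if (s > 0L) {
      # current is L-: P(L-) = v^-2 P(L+) ... no: bad passage under, sign s.
      # s > 0: current diagram is L+ at this crossing:
      # P(L+) = v^2 P(L-) + v z P(L0)
      hp_add(hp_shift(homfly_rec(sw, memo), 2L, 0L),
             hp_shift(homfly_rec(sm, memo), 1L, 1L))
    } else {
      # P(L-) = v^-2 P(L+) - v^-1 z P(L0)
      hp_add(hp_shift(homfly_rec(sw, memo), -2L, 0L),
             hp_shift(homfly_rec(sm, memo), -1L, 1L, coef = -1))
    }
  }
  memo[[key]] <- val
  if (is.null(base)) val else hp_mul(base, val)
}

#' HOMFLY polynomial of a crossing diagram
#'
#' Computed by skein-relation recursion with memoization on simplified
#' sub-diagrams, in the convention `v^-1 P(L+) - v P(L-) = z P(L0)`
#' with `P(unknot) = 1`. Mirror images map to each other under
#' `v -> -v^-1` (equivalently `v -> v^-1, z -> -z` up to sign
#' bookkeeping), so chiral knots get distinct polynomials.
#'
#' @param diagram a `crossing_diagram` (from a KMT-reduced polygon;
#'   large diagrams are refused).
#' @param max_crossings refuse diagrams above this crossing count
#'   (default 16); the caller then falls back to chirality
#'   "undetermined".
#' @return named numeric vector: coefficients keyed by `"i,j"` meaning
#'   `v^i z^j`.
#' @export
homfly <- function(diagram, max_crossings = 16L) {
  if (diagram$n_crossings > max_crossings)
    stop("diagram too large for HOMFLY (", diagram$n_crossings, " crossings)")
  if (diagram$n_crossings == 0L) return(hp_term(0L, 0L, 1))
  memo <- new.env(parent = emptyenv())
  val <- homfly_rec(list(diagram$gauss), memo)
  val[order(names(val))]
}

hp_equal <- function(a, b) {
  length(a) == length(b) && all(names(a) %in% names(b)) &&
    isTRUE(all.equal(as.numeric(a[order(names(a))]),
                     as.numeric(b[order(names(b))])))
}

# Reference HOMFLY pair for a chiral table knot. The "+" form is the
# reference diagram if its writhe is positive, otherwise its mirror
# (for the alternating table knots the reduced-diagram writhe sign is a
# reliable handedness proxy; the assignment is this package's
# convention and is applied consistently).
reference_homfly <- function(name) {
  key <- paste0("homfly_", name)
  cached <- .knotscan_cache[[key]]
  if (!is.null(cached)) return(cached)
  dia <- reference_diagram(reference_curve(name))
  p_as_built <- homfly(dia, max_crossings = 24L)
  p_mirror <- homfly(mirror_diagram(dia), max_crossings = 24L)
  if (diagram_writhe(dia) >= 0L)
    out <- list(plus = p_as_built, minus = p_mirror)
  else
    out <- list(plus = p_mirror, minus = p_as_built)
  .knotscan_cache[[key]] <- out
  out
}

# Resolve chirality of a diagram already classified as `name`.
chirality_from_homfly <- function(diagram, name, max_crossings = 16L) {
  tab <- knot_signature_table()
  row <- tab[tab$name == name, ]
  if (nrow(row) == 0L) return("undetermined")
  if (!row$chiral) return("achiral")
  p <- tryCatch(homfly(diagram, max_crossings), error = function(e) NULL)
  if (is.null(p)) return("undetermined")
  ref <- reference_homfly(name)
  if (hp_equal(p, ref$plus)) "plus"
  else if (hp_equal(p, ref$minus)) "minus"
  else "undetermined"
}
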