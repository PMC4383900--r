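# Knotting fingerprints: the upper-triangular matrix assigning a
# dominant knot type (with detection frequencies) to every subchain
# (k, l), and everything derived from it -- knot cores, tails, slipknot
# loops, and the K/S/U topological notation.

#' Compute the knotting fingerprint of a chain
#'
#' For a chain of length N every subchain spanned between vertices k
#' and l (1 <= k < l <= N, on the chosen grid) is closed stochastically
#' and assigned its dominant knot type. One enclosing sphere and one
#' rotated closure point set (both derived from the full chain and the
#' master seed) are shared by all cells; each cell draws its closures
#' from a deterministic per-cell seed, so the full matrix is
#' reproducible bit for bit and cell (1, N) agrees exactly with
#' [dominant_knot()] of the whole chain at the same seed.
#'
#' @param chain a `knot_chain` (or N x 3 matrix).
#' @param n_closures random closures per cell (default 200).
#' @param seed master seed.
#' @param stride grid stride; 1 scans all subchains, larger values
#'   coarsen the grid for long chains (endpoints always included).
#' @param inflation,arc_step_deg closure geometry parameters.
#' @param min_len subchains shorter than this are recorded as unknots
#'   without sampling (default 3; a two-vertex chain cannot knot).
#' @return object of class `fingerprint_matrix`: list with `n`,
#'   `cells` (data frame k, l, dominant, frequency, masked), `dom`
#'   (n x n character matrix, NA off grid), `freq_maps` (per-cell
#'   frequency vectors keyed `"k,l"`), `putative`, `masked_cells`,
#'   `seed`, `params`.
#' @export
compute_fingerprint <- function(chain, n_closures = 200L, seed = 1L,
                                stride = 1L, inflation = 10,
                                arc_step_deg = 10, min_len = 3L) {
  pts <- if (inherits(chain, "knot_chain")) chain$vertices else as.matrix(chain)
  n <- nrow(pts)
  if (n < 3L) stop("chain needs at least three vertices")
  bridged <- if (inherits(chain, "knot_chain")) chain$bridged else rep(FALSE, n - 1L)
  sphere <- enclosing_sphere(pts, inflation)
  points <- truncated_icosahedron_points(sphere, seed)

  ks <- unique(c(seq(1L, n, by = stride), 1L))
  ls <- unique(c(seq(n, 1L, by = -stride), n))
  dom <- matrix(NA_character_, n, n)
  freq_maps <- list()
  rows_k <- integer(0); rows_l <- integer(0)
  rows_dom <- character(0); rows_f <- numeric(0); rows_m <- logical(0)

  for (k in sort(ks)) for (l in sort(ls)) {
    if (l <= k) next
    masked <- any(bridged[k:(l - 1L)])
    if (l - k + 1L < min_len) {
      dom[k, l] <- "0_1"
      fr <- c("0_1" = 1)
    } else {
      res <- dominant_knot(pts[k:l, , drop = FALSE], n_closures,
                           seed = cell_seed(seed, k, l, n),
                           points = points, sphere = sphere,
                           arc_step_deg = arc_step_deg)
      dom[k, l] <- res$label$display
      fr <- res$frequencies
    }
    freq_maps[[paste(k, l, sep = ",")]] <- fr
    rows_k <- c(rows_k, k); rows_l <- c(rows_l, l)
    rows_dom <- c(rows_dom, dom[k, l])
    rows_f <- c(rows_f, max(fr))
    rows_m <- c(rows_m, masked)
  }

  cells <- data.frame(k = rows_k, l = rows_l, dominant = rows_dom,
                      frequency = rows_f, masked = rows_m,
                      stringsAsFactors = FALSE)
  structure(list(
    n = n, cells = cells, dom = dom, freq_maps = freq_maps,
    putative = any(bridged),
    masked_cells = cells[cells$masked, c("k", "l")],
    seed = seed,
    params = list(n_closures = n_closures, stride = stride,
                  inflation = inflation, arc_step_deg = arc_step_deg)
  ), class = "fingerprint_matrix")
}

#' Render a fingerprint matrix
#'
#' Draws the upper-triangular (k, l) grid with one color per dominant
#' knot type, intensity scaled by detection frequency; masked cells
#' are overdrawn with crosses.
#'
#' @param x a `fingerprint_matrix`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.fingerprint_matrix <- function(x, ...) {
  cells <- x$cells
  labs <- setdiff(unique(cells$dominant), "0_1")
  pal <- setNames(grDevices::rainbow(max(length(labs), 1L)), labs)
  graphics::plot(NA, xlim = c(1, x$n), ylim = c(1, x$n), xlab = "k",
                 ylab = "l", main = "knotting fingerprint", asp = 1, ...)
  nt <- cells[cells$dominant != "0_1", , drop = FALSE]
  if (nrow(nt) > 0L) {
    alpha <- pmax(0.2, pmin(1, nt$frequency))
    cols <- vapply(seq_len(nrow(nt)), function(i)
      grDevices::adjustcolor(pal[[nt$dominant[i]]], alpha.f = alpha[i]),
      character(1))
    graphics::points(nt$k, nt$l, pch = 15, col = cols,
                     cex = max(0.3, 30 / x$n))
    graphics::legend("bottomright", legend = names(pal), col = pal, pch = 15)
  }
  if (nrow(x$masked_cells) > 0L)
    graphics::points(x$masked_cells$k, x$masked_cells$l, pch = 4, cex = 0.3,
                     col = "grey40")
  invisible(x)
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  nt <- x$cells[!(x$cells$dominant %in% c("0_1", "unknown")), ]
  cat(sprintf("<fingerprint_matrix> N = %d, %d cells (stride %d), %d knotted%s\n",
              x$n, nrow(x$cells), x$params$stride, nrow(nt),
              if (x$putative) ", PUTATIVE (bridged segments)" else ""))
  invisible(x)
}

# connected components (4-connectivity in the (k,l) grid) of cells
# sharing a nontrivial dominant label; islands below min_cells are
# dropped as closure noise
fingerprint_regions <- function(fp, min_cells = 3L) {
  cells <- fp$cells[!(fp$cells$dominant %in% c("0_1", "unknown")), , drop = FALSE]
  if (nrow(cells) == 0L) return(list())
  stride <- fp$params$stride
  regions <- list()
  for (lab in unique(cells$dominant)) {
    sub <- cells[cells$dominant == lab, , drop = FALSE]
    key <- paste(sub$k, sub$l)
    seen <- rep(FALSE, nrow(sub))
    for (s in seq_len(nrow(sub))) {
      if (seen[s]) next
      queue <- s; seen[s] <- TRUE; comp <- s
      while (length(queue) > 0L) {
        cur <- queue[[1L]]; queue <- queue[-1L]
        nb <- c(paste(sub$k[cur] + stride, sub$l[cur]),
                paste(sub$k[cur] - stride, sub$l[cur]),
                paste(sub$k[cur], sub$l[cur] + stride),
                paste(sub$k[cur], sub$l[cur] - stride))
        hits <- which(!seen & key %in% nb)
        seen[hits] <- TRUE
        queue <- c(queue, hits)
        comp <- c(comp, hits)
      }
      cc <- sub[comp, , drop = FALSE]
      if (nrow(cc) < min_cells) next
      len <- cc$l - cc$k
      core_i <- which(len == min(len))
      core_i <- core_i[which.min(cc$k[core_i])]
      regions[[length(regions) + 1L]] <- list(
        label = lab,
        cells = cc,
        size = max(cc$l - cc$k + 1L),
        core = c(cc$k[core_i], cc$l[core_i])
      )
    }
  }
  regions[order(-vapply(regions, `[[`, 0, "size"))]
}

#' Extract knot cores, tails and slipknot elements from a fingerprint
#'
#' The knot core of a region is its shortest knotted subchain (ties
#' broken toward the N terminus). On each side of the core the track
#' is, for a knotted chain, a knot tail (terminus to core); for a
#' slipknotted side, the longest terminal segment whose removal leaves
#' the full-chain topology unchanged is the slipknot tail and the
#' remainder up to the core is the slipknot loop. Tails shorter than
#' 10 residues are shallow, others deep.
#'
#' @param fp a `fingerprint_matrix` (stride 1 for exact element
#'   boundaries).
#' @param min_cells region islands smaller than this are ignored
#'   (default 3).
#' @param depth_threshold tail length separating shallow from deep
#'   (default 10).
#' @return object of class `topology_elements`: list with `regions`
#'   (all knotted regions, largest first), and for the primary region
#'   `knot_core`, `knot_tails`, `slipknot_tails`, `slipknot_loops`
#'   (each a list of `c(start, end)` spans), `depth_class`, and a
#'   per-vertex `track` of element codes (C core, T knot tail,
#'   S slipknot tail, L slipknot loop, '.' outside).
#' @export
extract_elements <- function(fp, min_cells = 3L, depth_threshold = 10L) {
  n <- fp$n
  regions <- fingerprint_regions(fp, min_cells)
  empty <- structure(list(regions = list(), knot_core = NULL,
                          knot_tails = list(), slipknot_tails = list(),
                          slipknot_loops = list(), depth_class = list(),
                          track = rep(".", n), putative = fp$putative),
                     class = "topology_elements")
  if (length(regions) == 0L) return(empty)

  full_label <- fp$dom[1L, n]
  # primary region: the one containing (1,N) when the chain is knotted,
  # otherwise the largest (most complicated slipknot)
  primary <- regions[[1L]]
  if (!(full_label %in% c("0_1", "unknown"))) {
    holds_full <- vapply(regions, function(r)
      any(r$cells$k == 1L & r$cells$l == n), logical(1))
    if (any(holds_full)) primary <- regions[[which(holds_full)[1L]]]
  }
  a <- primary$core[1L]; b <- primary$core[2L]
  lab <- primary$label

  knot_tails <- list(); slip_tails <- list(); slip_loops <- list()
  track <- rep(".", n)
  track[a:b] <- "C"

  # N-side elements
  if (a > 1L) {
    if (full_label == lab) {
      knot_tails$N <- c(1L, a - 1L); track[1:(a - 1L)] <- "T"
    } else {
      kstar <- NA_integer_
      for (k in 2L:a) {
        v <- fp$dom[k, n]
        if (!is.na(v) && v != full_label) { kstar <- k; break }
      }
      if (!is.na(kstar) && kstar > 1L) {
        slip_tails$N <- c(1L, kstar - 1L); track[1:(kstar - 1L)] <- "S"
        if (kstar <= a - 1L) { slip_loops$N <- c(kstar, a - 1L); track[kstar:(a - 1L)] <- "L" }
      } else {
        slip_tails$N <- c(1L, a - 1L); track[1:(a - 1L)] <- "S"
      }
    }
  }
  # C-side elements
  if (b < n) {
    if (full_label == lab) {
      knot_tails$C <- c(b + 1L, n); track[(b + 1L):n] <- "T"
    } else {
      lstar <- NA_integer_
      for (l in (n - 1L):b) {
        v <- fp$dom[1L, l]
        if (!is.na(v) && v != full_label) { lstar <- l; break }
      }
      if (!is.na(lstar) && lstar < n) {
        slip_tails$C <- c(lstar + 1L, n); track[(lstar + 1L):n] <- "S"
        if (b + 1L <= lstar) { slip_loops$C <- c(b + 1L, lstar); track[(b + 1L):lstar] <- "L" }
      } else {
        slip_tails$C <- c(b + 1L, n); track[(b + 1L):n] <- "S"
      }
    }
  }

  span_len <- function(sp) sp[2L] - sp[1L] + 1L
  depth <- lapply(c(knot_tails, slip_tails), function(sp)
    if (span_len(sp) < depth_threshold) "shallow" else "deep")

  structure(list(regions = regions, knot_core = c(a, b),
                 knot_tails = knot_tails, slipknot_tails = slip_tails,
                 slipknot_loops = slip_loops, depth_class = depth,
                 track = track, putative = fp$putative),
            class = "topology_elements")
}

#' @export
print.topology_elements <- function(x, ...) {
  if (is.null(x$knot_core)) { cat("<topology_elements> trivial\n"); return(invisible(x)) }
  cat(sprintf("<topology_elements> core %d-%d; %d region(s)%s\n",
              x$knot_core[1L], x$knot_core[2L], length(x$regions),
              if (x$putative) " [putative]" else ""))
  invisible(x)
}

#' Topological notation of a fingerprint
#'
#' Lists the distinct knotted territories of the matrix, ordered by
#' decreasing size of the subchain forming each knot; the prefix is K
#' for a knotted chain, S for an unknotted chain containing a slipknot,
#' and the string is "U" for a trivial matrix (e.g. "K4_1_3_1",
#' "S3_1").
#'
#' @param fp a `fingerprint_matrix`.
#' @param min_cells region islands smaller than this are ignored.
#' @return object of class `knot_notation`: list with `text`,
#'   `regions` (label + representative span per region), `putative`.
#' @export
topological_notation <- function(fp, min_cells = 3L) {
  regions <- fingerprint_regions(fp, min_cells)
  full_label <- fp$dom[1L, fp$n]
  knotted <- !(full_label %in% c("0_1", "unknown"))
  text <- if (knotted) {
    paste0("K", paste(vapply(regions, `[[`, "", "label"), collapse = "_"))
  } else if (length(regions) > 0L) {
    paste0("S", paste(vapply(regions, `[[`, "", "label"), collapse = "_"))
  } else "U"
  structure(list(
    text = text,
    regions = lapply(regions, function(r)
      list(label = r$label, core = r$core, size = r$size)),
    putative = fp$putative
  ), class = "knot_notation")
}

#' @export
print.knot_notation <- function(x, ...) {
  cat(x$text, if (x$putative) "[putative]" else "", "\n")
  invisible(x)
}

#' Dominant knot type and core span along a trajectory
#'
#' @param frames list of `knot_chain` objects (or coordinate matrices)
#'   sharing one vertex count.
#' @param n_closures closures per dominant-knot call.
#' @param seed master seed (per-frame seeds derived deterministically).
#' @param locate_core also estimate the knot core per frame by greedy
#'   trimming (default TRUE).
#' @return data frame: frame, label, frequency, core_start, core_end.
#' @export
analyze_trajectory <- function(frames, n_closures = 100L, seed = 1L,
                               locate_core = TRUE) {
  if (length(frames) == 0L)
    return(data.frame(frame = integer(), label = character(),
                      frequency = numeric(), core_start = integer(),
                      core_end = integer(), stringsAsFactors = FALSE))
  mats <- lapply(frames, function(f)
    if (inherits(f, "knot_chain")) f$vertices else as.matrix(f))
  sizes <- vapply(mats, nrow, 0L)
  if (length(unique(sizes)) != 1L)
    stop("trajectory frames must share one vertex count")
  out <- lapply(seq_along(mats), function(i) {
    fseed <- as.integer((seed + 7919 * (i - 1)) %% 2147483647L)
    res <- dominant_knot(mats[[i]], n_closures, seed = fseed)
    core <- c(NA_integer_, NA_integer_)
    if (locate_core && res$label$display != "0_1" &&
        res$label$display != "unknown")
      core <- core_span_estimate(mats[[i]], res$label$display,
                                 n_closures, fseed)
    data.frame(frame = i, label = res$label$display,
               frequency = max(res$frequencies),
               core_start = core[1L], core_end = core[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Refine a knot-core span to stride-1 resolution
#'
#' Starting from a (possibly coarse-grid) core estimate, expands the
#' span until its dominant label matches the region label, then
#' shrinks each end while the label survives, giving a minimal core:
#' removing one more residue from either end leaves a different
#' (trivial) dominant type.
#'
#' @param pts chain coordinates (N x 3) the fingerprint was computed on.
#' @param label the region's knot label display string (e.g. "3_1").
#' @param core integer `c(k, l)` initial estimate.
#' @param n_closures,seed sampling settings for the re-tests.
#' @return refined integer span `c(k, l)`.
#' @export
refine_core_span <- function(pts, label, core, n_closures = 100L, seed = 1L) {
  pts <- if (inherits(pts, "knot_chain")) pts$vertices else as.matrix(pts)
  n <- nrow(pts)
  sphere <- enclosing_sphere(pts)
  points <- truncated_icosahedron_points(sphere, seed)
  lab_of <- function(k, l) dominant_knot(pts[k:l, , drop = FALSE], n_closures,
                                         seed = cell_seed(seed, k, l, n),
                                         points = points,
                                         sphere = sphere)$label$display
  a <- core[1L]; b <- core[2L]
  while (lab_of(a, b) != label && (a > 1L || b < n)) {
    a <- max(1L, a - 1L); b <- min(n, b + 1L)
  }
  if (lab_of(a, b) != label) stop("region label not recovered around the core")
  while (a + 2L < b && lab_of(a + 1L, b) == label) a <- a + 1L
  while (b - 2L > a && lab_of(a, b - 1L) == label) b <- b - 1L
  c(a, b)
}

# greedy trim: advance each terminus while the dominant label of the
# remaining subchain is unchanged
core_span_estimate <- function(pts, label, n_closures, seed) {
  n <- nrow(pts)
  sphere <- enclosing_sphere(pts)
  points <- truncated_icosahedron_points(sphere, seed)
  lab_of <- function(k, l) dominant_knot(pts[k:l, , drop = FALSE], n_closures,
                                         seed = cell_seed(seed, k, l, n),
                                         points = points,
                                         sphere = sphere)$label$display
  a <- 1L
  while (a + 2L < n && lab_of(a + 1L, n) == label) a <- a + 1L
  b <- n
  while (b - 2L > a && lab_of(a, b - 1L) == label) b <- b - 1L
  c(a, b)
}

# ------------------------------------------------------------- writers

#' Write a fingerprint matrix as TSV
#'
#' One line per grid cell: k, l, dominant label, detection frequency,
#' masked flag (cell overlaps a bridged segment).
#'
#' @param fp a `fingerprint_matrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fingerprint_tsv <- function(fp, path) {
  write.table(fp$cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON analysis summary
#'
#' @param fp a `fingerprint_matrix`.
#' @param elements result of [extract_elements()].
#' @param notation result of [topological_notation()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_summary_json <- function(fp, elements, notation, path) {
  summary <- list(
    notation = notation$text,
    putative = fp$putative,
    n = fp$n,
    seed = fp$seed,
    params = fp$params,
    full_chain = fp$dom[1L, fp$n],
    regions = lapply(notation$regions, function(r)
      list(label = r$label, core = r$core, size = r$size)),
    elements = list(
      knot_core = elements$knot_core,
      knot_tails = elements$knot_tails,
      slipknot_tails = elements$slipknot_tails,
      slipknot_loops = elements$slipknot_loops,
      depth_class = elements$depth_class
    )
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Write the annotated sequence track
#'
#' One character per residue over the authored residue range: C knot
#' core, T knot tail, S slipknot tail, L slipknot loop, '.' other,
#' '-' missing residues (numbering gaps).
#'
#' @param chain the analyzed `knot_chain`.
#' @param elements result of [extract_elements()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sequence_track <- function(chain, elements, path) {
  ids <- chain$residue_ids
  full <- seq(min(ids), max(ids))
  codes <- rep("-", length(full))
  codes[match(ids, full)] <- elements$track
  lines <- c(sprintf("# residues %d..%d%s", min(ids), max(ids),
                     if (elements$putative) " [putative]" else ""),
             paste(codes, collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
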