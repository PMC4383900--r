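# Parametric fixture curves with known topology. Everything every
# other module needs for testing is generated here, from closed-form
# parametrizations -- no structure files required.

#' Parametric torus knot curve
#'
#' Points `((2+cos(q s)) cos(p s), (2+cos(q s)) sin(p s), sin(q s))`
#' for `s` over `[0, 2 pi (1 - open_gap)]`; coprime `p, q >= 2` give
#' the (p,q) torus knot: (2,3) the trefoil, (2,5) the 5_1, (2,7) the
#' 7_1. A positive `open_gap` leaves the chain open for closure
#' experiments.
#'
#' @param p,q coprime torus winding numbers.
#' @param n_points number of vertices (>= 30).
#' @param open_gap fraction of the parameter circle left out (0 gives
#'   the closed curve).
#' @return a `knot_chain`.
#' @export
torus_knot_curve <- function(p, q, n_points = 120L, open_gap = 0) {
  if (n_points < 30L) stop("n_points must be at least 30")
  if (open_gap < 0 || open_gap >= 1) stop("open_gap must be in [0, 1)")
  g <- function(a, b) if (b == 0L) a else g(b, a %% b)
  if (g(as.integer(p), as.integer(q)) != 1L)
    stop("p and q must be coprime (otherwise the curve is a link)")
  smax <- 2 * pi * (1 - open_gap)
  s <- if (open_gap == 0) seq(0, smax, length.out = n_points + 1L)[seq_len(n_points)]
       else seq(0, smax, length.out = n_points)
  new_chain(cbind((2 + cos(q * s)) * cos(p * s),
                  (2 + cos(q * s)) * sin(p * s),
                  sin(q * s)), chain_id = "F")
}

#' Parametric figure-eight knot curve
#'
#' Points `((2+cos 2s) cos 3s, (2+cos 2s) sin 3s, sin 4s)`; the closed
#' curve is the 4_1 knot (achiral).
#'
#' @param n_points number of vertices (>= 40).
#' @param open_gap fraction of the parameter circle left out.
#' @return a `knot_chain`.
#' @export
figure8_curve <- function(n_points = 160L, open_gap = 0) {
  if (n_points < 40L) stop("n_points must be at least 40")
  smax <- 2 * pi * (1 - open_gap)
  s <- if (open_gap == 0) seq(0, smax, length.out = n_points + 1L)[seq_len(n_points)]
       else seq(0, smax, length.out = n_points)
  new_chain(cbind((2 + cos(2 * s)) * cos(3 * s),
                  (2 + cos(2 * s)) * sin(3 * s),
                  sin(4 * s)), chain_id = "F")
}

#' Open chain containing a trefoil slipknot
#'
#' An open trefoil whose terminal segment is retracted back through
#' the knotted loop along a parallel offset path and led away: the
#' full chain closes to the unknot while the subchain that stops
#' before the retraction is a trefoil, so the knotting fingerprint has
#' notation "S3_1". Construction parameters were chosen once for this
#' geometry and are fixed.
#'
#' @param n_points approximate number of vertices of the forward
#'   (trefoil-forming) part (default 90).
#' @param retract_frac fraction of the forward path the hairpin
#'   retraces (default 0.35).
#' @param offset lateral offset of the retraced strand (default 0.35).
#' @return a `knot_chain`.
#' @export
slipknot_curve <- function(n_points = 90L, retract_frac = 0.35,
                           offset = 0.35) {
  if (n_points < 45L) stop("n_points must be at least 45")
  smax <- 2 * pi * 0.94
  s <- seq(0, smax, length.out = n_points)
  fwd <- cbind((2 + cos(3 * s)) * cos(2 * s),
               (2 + cos(3 * s)) * sin(2 * s),
               sin(3 * s))
  # retrace alongside the forward path, pushed outward radially
  nb <- max(6L, round(n_points * retract_frac))
  back_idx <- seq(n_points, n_points - nb + 1L)
  radial <- fwd[back_idx, 1:2]
  rn <- sqrt(rowSums(radial^2))
  back <- fwd[back_idx, ] + cbind(radial / rn * offset, offset)
  # exit: run radially outward, away from the tangle
  last <- back[nrow(back), ]
  dir <- c(last[1L], last[2L], 0)
  dir <- dir / sqrt(sum(dir^2))
  exit <- t(vapply(seq_len(6L), function(i) last + dir * (0.8 * i) + c(0, 0, 0.25 * i),
                   numeric(3L)))
  new_chain(rbind(fwd, back, exit), chain_id = "F")
}

#' Minimal 6-stick trefoil polygon
#'
#' A closed hexagonal polygon realizing the trefoil at its stick
#' number: no KMT triangle is removable and every generic projection
#' yields the trefoil signature. Coordinates were located once by
#' seeded random search over hexagons and verified, then frozen.
#'
#' @return 6 x 3 coordinate matrix (a closed polygon).
#' @export
hexagonal_trefoil <- function() {
  matrix(c(
    0.177608, 0.275011, -0.362694,
    -0.979314, 0.057566, 0.739778,
    -0.286494, 0.206751, 0.961530,
    -0.055912, 0.727667, -0.494304,
    -0.253039, -0.433494, -0.208001,
    -0.223028, 0.575979, 0.359352
  ), ncol = 3L, byrow = TRUE)
}

#' Unknotted reference curves
#'
#' A planar circle (`kind = "circle"`) or a straight rod
#' (`kind = "straight"`).
#'
#' @param n_points number of vertices.
#' @param kind `"circle"` or `"straight"`.
#' @return a `knot_chain`.
#' @export
unknot_curve <- function(n_points = 40L, kind = c("circle", "straight")) {
  kind <- match.arg(kind)
  if (kind == "circle") {
    s <- seq(0, 2 * pi, length.out = n_points + 1L)[seq_len(n_points)]
    new_chain(cbind(cos(s), sin(s), 0), chain_id = "F")
  } else {
    new_chain(cbind(seq_len(n_points) * 3.8, 0, 0), chain_id = "F")
  }
}

#' Add Gaussian coordinate noise to a chain
#'
#' @param chain a `knot_chain`.
#' @param sigma standard deviation of the i.i.d. offsets (same units
#'   as the coordinates). Small sigma relative to the minimal
#'   inter-strand distance preserves the topology.
#' @param seed integer seed.
#' @return the perturbed `knot_chain`.
#' @export
perturb <- function(chain, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(chain)
  n <- nrow(chain$vertices)
  chain$vertices <- chain$vertices +
    with_seed(seed, matrix(rnorm(3L * n, sd = sigma), n, 3L))
  chain
}

#' Write the standard fixture set as x-y-z files
#'
#' Emits the named parametric fixtures (trefoil, figure-8, 5_1, 7_1,
#' their opened variants, a slipknot and a straight rod) into a
#' directory, one x-y-z file each.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths.
#' @export
write_fixture_set <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fixtures <- list(
    trefoil_closed = torus_knot_curve(2, 3, 120L),
    trefoil_open = torus_knot_curve(2, 3, 120L, open_gap = 0.02),
    figure8_closed = figure8_curve(160L),
    figure8_open = figure8_curve(160L, open_gap = 0.02),
    k5_1_closed = torus_knot_curve(2, 5, 140L),
    k7_1_closed = torus_knot_curve(2, 7, 160L),
    slipknot = slipknot_curve(),
    straight = unknot_curve(30L, "straight")
  )
  paths <- vapply(names(fixtures), function(nm) {
    p <- file.path(dir, paste0(nm, ".xyz"))
    write_xyz(fixtures[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
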