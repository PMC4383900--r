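test_that("enclosing sphere centers on the centroid with inflated radius", {
  sph <- enclosing_sphere(rbind(c(0, 0, 0), c(2, 0, 0)), inflation = 10)
  expect_equal(sph$center, c(1, 0, 0))
  expect_equal(sph$radius, 10)

  # unit cube corners: radius = inflation x corner distance from center
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  sph2 <- enclosing_sphere(cube, inflation = 2)
  expect_equal(sph2$radius, 2 * sqrt(3) / 2)

  # degenerate chain: radius floor of 1
  sph3 <- enclosing_sphere(rbind(c(1, 1, 1), c(1, 1, 1)), inflation = 10)
  expect_equal(sph3$radius, 1)
})

test_that("truncated icosahedron gives 60 distinct points on the sphere", {
  sph <- enclosing_sphere(torus_knot_curve(2, 3, 60)$vertices)
  pts <- truncated_icosahedron_points(sph, orientation_seed = 5L)
  expect_equal(nrow(pts), 60L)
  r <- sqrt(rowSums(sweep(pts, 2, sph$center)^2))
  expect_equal(r, rep(sph$radius, 60), tolerance = 1e-9)
  expect_equal(nrow(unique(round(pts, 6))), 60L)
})

test_that("different orientation seeds give rigidly rotated point sets", {
  sph <- list(center = c(0, 0, 0), radius = 5)
  a <- truncated_icosahedron_points(sph, 1L)
  b <- truncated_icosahedron_points(sph, 2L)
  expect_false(isTRUE(all.equal(a, b)))
  # rigid motion preserves the pairwise distance multiset
  da <- sort(as.numeric(dist(a)))
  db <- sort(as.numeric(dist(b)))
  expect_equal(da, db, tolerance = 1e-9)
})

test_that("random closure builds a sphere-arc polygon", {
  ch <- torus_knot_curve(2, 3, 60, open_gap = 0.05)$vertices
  sph <- enclosing_sphere(ch)
  pts <- truncated_icosahedron_points(sph, 1L)
  poly <- random_closure(ch, pts, c(1L, 30L), sph)
  expect_s3_class(poly, "closed_polygon")
  expect_equal(poly$provenance, "random_closure")
  v <- poly$vertices
  expect_gt(nrow(v), nrow(ch))
  # every added vertex sits on the sphere
  extra <- v[(nrow(ch) + 1):nrow(v), , drop = FALSE]
  r <- sqrt(rowSums(sweep(extra, 2, sph$center)^2))
  expect_equal(r, rep(sph$radius, nrow(extra)), tolerance = 1e-6)
  # consecutive arc points subtend at most 10 degrees
  u <- sweep(extra, 2, sph$center) / sph$radius
  if (nrow(u) > 1) {
    cosang <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
    expect_true(all(acos(pmin(1, cosang)) <= 10 * pi / 180 + 1e-6))
  }
  expect_error(random_closure(ch, pts, c(3L, 3L), sph), "distinct")
})

test_that("direct closure keeps the subchain and drops coincident termini", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  poly <- direct_closure(sq)
  expect_equal(nrow(poly$vertices), 4L)
  expect_equal(poly$provenance, "direct_closure")

  dup <- rbind(sq, c(0, 0, 0))
  expect_equal(nrow(direct_closure(dup)$vertices), 4L)

  expect_error(direct_closure(sq[1:2, ]), "three")
})

test_that("direct closure of a near-closed trefoil curve is a trefoil", {
  ch <- torus_knot_curve(2, 3, 120, open_gap = 0.02)$vertices
  lab <- classify_full(direct_closure(ch), seed = 2, with_chirality = FALSE)
  expect_equal(lab$display, "3_1")
})

test_that("with radially exposed termini every closure pair matches direct closure", {
  # open trefoil whose termini run far out radially: no closure can
  # alter the knot type
  ch <- torus_knot_curve(2, 3, 80, open_gap = 0.04)$vertices
  head_dir <- ch[1, ] / sqrt(sum(ch[1, ]^2))
  tail_dir <- ch[nrow(ch), ] / sqrt(sum(ch[nrow(ch), ]^2))
  ext <- function(p, d) t(sapply(seq_len(4), function(i) p + d * 2 * i))
  pts <- rbind(ext(ch[1, ], head_dir)[4:1, ], ch, ext(ch[nrow(ch), ], tail_dir))
  direct_lab <- classify_full(direct_closure(pts), seed = 3,
                              with_chirality = FALSE)$display
  expect_equal(direct_lab, "3_1")
  sph <- enclosing_sphere(pts)
  cp <- truncated_icosahedron_points(sph, 3L)
  pairs <- t(utils::combn(60L, 2L))
  # exact antipodal pairs make the surface arc ill-defined and are
  # redrawn by the sampler; exclude them from the enumeration
  u <- sweep(cp, 2, sph$center) / sph$radius
  keep <- rowSums(u[pairs[, 1], ] * u[pairs[, 2], ]) > -0.995
  res <- dominant_knot(pts, seed = 3, points = cp, sphere = sph,
                       pairs = pairs[keep, ])
  expect_equal(unname(res$frequencies[direct_lab]), 1)
})

test_that("rigid motions of chain and closure frame leave frequencies unchanged", {
  ch <- torus_knot_curve(2, 3, 60, open_gap = 0.05)$vertices
  sph <- enclosing_sphere(ch)
  pts <- truncated_icosahedron_points(sph, 9L)
  res1 <- dominant_knot(ch, n_closures = 60, seed = 9, points = pts, sphere = sph)
  # co-rotate chain and closure points: per-closure knot types must be
  # invariant, so the frequency map is identical
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(5, -3, 2)
  ch2 <- sweep(ch %*% t(R), 2, shift, "+")
  pts2 <- sweep(pts %*% t(R), 2, shift, "+")
  sph2 <- list(center = as.numeric(R %*% sph$center) + shift, radius = sph$radius)
  res2 <- dominant_knot(ch2, n_closures = 60, seed = 9, points = pts2, sphere = sph2)
  expect_equal(res1$label$display, res2$label$display)
  expect_equal(res1$frequencies, res2$frequencies)
})
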