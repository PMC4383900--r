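test_that("segment-triangle intersection handles the canonical cases", {
  tri <- rbind(c(-1, -1, 0), c(1, -1, 0), c(0, 1, 0))
  expect_true(segment_triangle_intersects(rbind(c(0, 0, -1), c(0, 0, 1)), tri))
  expect_false(segment_triangle_intersects(rbind(c(0, 0, 5), c(1, 1, 5)), tri))
  # touching a triangle vertex exactly: conservative true
  expect_true(segment_triangle_intersects(rbind(c(0, 1, -1), c(0, 1, 1)), tri))
  # coplanar but far away: false
  expect_false(segment_triangle_intersects(rbind(c(5, 5, 0), c(6, 5, 0)), tri))
  # coplanar passing through the interior: true
  expect_true(segment_triangle_intersects(rbind(c(-2, -0.5, 0), c(2, -0.5, 0)), tri))
})

test_that("a convex planar octagon reduces to a triangle", {
  oct <- cbind(cos(2 * pi * (0:7) / 8), sin(2 * pi * (0:7) / 8), 0)
  res <- kmt_reduce(oct)
  expect_equal(nrow(res$polygon$vertices), 3L)
  expect_equal(res$removed_count, 5L)
  expect_gte(res$passes, 1L)
})

test_that("the hexagonal trefoil is irreducible and keeps its signature", {
  hexa <- hexagonal_trefoil()
  res <- kmt_reduce(hexa)
  expect_equal(nrow(res$polygon$vertices), 6L)
  sig <- alexander_signature(project_to_diagram(hexa, 4L))
  expect_equal(sig, list(d1 = 3, d2 = 7))
})

test_that("a dense trefoil reduces drastically with invariants preserved", {
  tre <- torus_knot_curve(2, 3, 200L)$vertices
  res <- kmt_reduce(tre)
  m <- nrow(res$polygon$vertices)
  expect_gte(m, 6L)
  expect_lte(m, 20L)
  sig_before <- alexander_signature(project_to_diagram(tre, 5L))
  sig_after <- alexander_signature(project_to_diagram(res$polygon, 5L))
  expect_equal(sig_before, list(d1 = 3, d2 = 7))
  expect_equal(sig_after, sig_before)
})

test_that("reduction is monotone and idempotent", {
  for (pts in list(torus_knot_curve(2, 5, 120L)$vertices,
                   figure8_curve(120L)$vertices)) {
    res <- kmt_reduce(pts)
    expect_lte(nrow(res$polygon$vertices), nrow(pts))
    res2 <- kmt_reduce(res$polygon)
    expect_equal(res2$removed_count, 0L)
    expect_equal(res2$polygon$vertices, res$polygon$vertices)
  }
})

test_that("scan order may change the polygon but not the classification", {
  # reversing vertex order reverses the sweep; knot type must agree
  pts <- perturb(figure8_curve(100L), sigma = 0.02, seed = 3)$vertices
  fwd <- kmt_reduce(pts)$polygon
  bwd <- kmt_reduce(pts[rev(seq_len(nrow(pts))), ])$polygon
  s1 <- alexander_signature(project_to_diagram(fwd, 6L))
  s2 <- alexander_signature(project_to_diagram(bwd, 6L))
  expect_equal(s1, s2)
  expect_equal(s1, list(d1 = 5, d2 = 11))
})

test_that("noisy polygons keep their Alexander signature through reduction", {
  # smaller version of the topology-preservation sweep (the acceptance
  # suite runs the full 100-polygon version)
  specs <- list(list(gen = function() torus_knot_curve(2, 3, 90L)$vertices, sig = c(3, 7)),
                list(gen = function() figure8_curve(110L)$vertices, sig = c(5, 11)),
                list(gen = function() unknot_curve(60L)$vertices, sig = c(1, 1)))
  for (sp in specs) {
    base <- sp$gen()
    edge <- mean(sqrt(rowSums((base[-1, ] - base[-nrow(base), ])^2)))
    for (s in 1:5) {
      noisy <- perturb(new_chain(base), sigma = 0.05 * edge, seed = s)$vertices
      before <- alexander_signature(project_to_diagram(noisy, s))
      after <- alexander_signature(project_to_diagram(kmt_reduce(noisy)$polygon, s))
      expect_equal(after, before)
      expect_equal(unname(unlist(before)), sp$sig)
    }
  }
})
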