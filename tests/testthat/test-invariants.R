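test_that("Alexander evaluations match the closed-form values", {
  # standard braid codes; expected values from the torus/twist-knot
  # closed forms of the Alexander polynomial
  tre <- braid_diagram(c(1, 1, 1))
  expect_equal(alexander_eval(tre, -1), 3)
  expect_equal(alexander_eval(tre, -2), 7)
  expect_equal(alexander_poly(tre), c(1, -1, 1))

  f8 <- braid_diagram(c(1, -2, 1, -2))
  expect_equal(alexander_eval(f8, -1), 5)
  expect_equal(alexander_eval(f8, -2), 11)

  # unknot: trivial polynomial in any diagram (single-kink closure)
  expect_equal(alexander_poly(braid_diagram(c(1))), 1)
  expect_equal(alexander_eval(new_crossing_diagram(matrix(integer(), 0, 3)), -2), 1)
  expect_error(alexander_eval(tre, 0), "nonzero")
})

test_that("signature lookup labels the protein-relevant knot types", {
  expect_equal(classify_by_alexander(c(1, 1))$display, "0_1")
  expect_equal(classify_by_alexander(c(3, 7))$display, "3_1")
  expect_equal(classify_by_alexander(c(5, 11))$display, "4_1")
  expect_equal(classify_by_alexander(c(5, 31))$display, "5_1")
  expect_equal(classify_by_alexander(c(7, 16))$display, "5_2")
  expect_equal(classify_by_alexander(c(9, 20))$display, "6_1")
  expect_equal(classify_by_alexander(c(7, 127))$display, "7_1")
  expect_equal(classify_by_alexander(c(17, 94))$display, "7_5")
  expect_equal(classify_by_alexander(c(17, 251))$display, "8_2")
  # d1 ties broken by d2 throughout
  expect_equal(classify_by_alexander(c(17, 38))$display, "8_3")
  # unmatched signatures (here: a granny/square-knot product) stay unknown
  expect_equal(classify_by_alexander(c(9, 49))$display, "unknown")
  expect_equal(classify_by_alexander(c(1000, 1))$display, "unknown")
})

test_that("every table signature is regenerated from its stored reference code", {
  tab <- knot_signature_table()
  expect_gte(nrow(tab), 25L)
  expect_false(any(duplicated(tab[, c("d1", "d2")])))
  for (i in seq_len(nrow(tab))) {
    curve <- reference_curve(tab$name[i])
    # independent projection seed, full pipeline re-run
    dia <- project_to_diagram(kmt_reduce(curve)$polygon, direction_seed = 1234L)
    expect_equal(alexander_eval(dia, -1), tab$d1[i], label = tab$name[i])
    expect_equal(alexander_eval(dia, -2), tab$d2[i], label = tab$name[i])
  }
  # 2-bridge entries: determinant equals the continuant of the fraction
  for (e in knotscan:::knot_table_entries()) {
    if (!is.null(e$cf)) {
      p <- cf_fraction(e$cf)[1]
      expect_equal(tab$d1[tab$name == e$name], p, label = e$name)
    }
  }
})

test_that("projection is generic and direction-independent", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(project_to_diagram(tri, 1L)$n_crossings, 0L)

  for (fix in list(list(c = torus_knot_curve(2, 3, 120L)$vertices, sig = c(3, 7)),
                   list(c = figure8_curve(160L)$vertices, sig = c(5, 11)),
                   list(c = torus_knot_curve(2, 5, 140L)$vertices, sig = c(5, 31)))) {
    red <- kmt_reduce(fix$c)$polygon
    sigs <- vapply(1:25, function(s)
      unlist(alexander_signature(project_to_diagram(red, s))), numeric(2))
    expect_true(all(sigs[1, ] == fix$sig[1]))
    expect_true(all(sigs[2, ] == fix$sig[2]))
  }

  # hexagonal trefoil: a generic direction yields >= 3 crossings
  expect_gte(project_to_diagram(hexagonal_trefoil(), 2L)$n_crossings, 3L)
})

test_that("HOMFLY distinguishes mirrors and fixes the achiral figure-8", {
  unk <- new_crossing_diagram(matrix(integer(), 0, 3))
  expect_equal(homfly(unk), c("0,0" = 1))

  tre <- braid_diagram(c(1, 1, 1))
  p <- homfly(tre)
  pm <- homfly(mirror_diagram(tre))
  expect_false(knotscan:::hp_equal(p, pm))
  # mirroring swaps v -> -v^-1: exponents negate
  flip <- function(q) {
    ex <- do.call(rbind, lapply(strsplit(names(q), ","), as.integer))
    out <- setNames(as.numeric(q), paste0(-ex[, 1], ",", ex[, 2]))
    out[order(names(out))]
  }
  expect_equal(flip(p), pm[order(names(pm))])

  f8 <- braid_diagram(c(1, -2, 1, -2))
  expect_true(knotscan:::hp_equal(homfly(f8), homfly(mirror_diagram(f8))))

  big <- braid_diagram(rep(c(1, 1, 1, -2), 5))
  expect_error(homfly(big, max_crossings = 16L), "too large")
})

test_that("classify_full assigns chirality and flips it under mirroring", {
  tre <- torus_knot_curve(2, 3, 120L)$vertices
  lab <- classify_full(tre, seed = 3)
  lab_m <- classify_full(mirror_polygon(tre), seed = 3)
  expect_equal(label_base <- sub("[+-]$", "", lab$display), "3_1")
  expect_true(lab$chirality %in% c("plus", "minus"))
  expect_equal(sort(c(lab$chirality, lab_m$chirality)), c("minus", "plus"))

  f8 <- figure8_curve(160L)$vertices
  expect_equal(classify_full(f8, seed = 3)$display, "4_1")
  expect_equal(classify_full(mirror_polygon(f8), seed = 3)$display, "4_1")

  # Alexander signature is blind to mirroring
  s1 <- alexander_signature(project_to_diagram(kmt_reduce(tre)$polygon, 8L))
  s2 <- alexander_signature(project_to_diagram(kmt_reduce(mirror_polygon(tre))$polygon, 8L))
  expect_equal(s1, s2)
})

test_that("classification commutes with KMT reduction", {
  for (pts in list(torus_knot_curve(2, 5, 140L)$vertices,
                   figure8_curve(160L)$vertices)) {
    red <- kmt_reduce(pts)$polygon
    expect_equal(classify_full(pts, seed = 11, with_chirality = FALSE)$display,
                 classify_full(red, seed = 11, with_chirality = FALSE)$display)
  }
})

test_that("a spherical-cap polygon is unknotted", {
  # ten points on a cap are convex-position: closure is trivial
  set.seed(99)
  th <- sort(runif(10, 0, 0.4 * pi))
  ph <- runif(10, 0, 2 * pi)
  cap <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  expect_equal(classify_full(cap, seed = 1)$display, "0_1")
})
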