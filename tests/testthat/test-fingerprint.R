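test_that("a straight chain fingerprints as all-trivial with notation U", {
  ch <- unknot_curve(10L, "straight")
  fp <- compute_fingerprint(ch, n_closures = 20, seed = 2)
  expect_true(all(fp$cells$dominant == "0_1"))
  expect_false(fp$putative)
  nt <- topological_notation(fp)
  expect_equal(nt$text, "U")
  el <- extract_elements(fp)
  expect_null(el$knot_core)
  expect_equal(length(el$regions), 0L)
})

test_that("dominant knot of trivial or tiny subchains is the unknot", {
  r <- dominant_knot(matrix(0, 2, 3))
  expect_equal(r$label$display, "0_1")
  expect_equal(unname(r$frequencies["0_1"]), 1)

  straight <- cbind(1:10 * 3.8, 0, 0)
  r2 <- dominant_knot(straight, n_closures = 50, seed = 1)
  expect_equal(r2$label$display, "0_1")
  expect_equal(unname(r2$frequencies["0_1"]), 1)
})

test_that("fingerprint cell (1,N) matches the standalone dominant knot", {
  ch <- torus_knot_curve(2, 3, 50L, open_gap = 0.05)
  fp <- compute_fingerprint(ch, n_closures = 30, seed = 17, stride = 5)
  alone <- dominant_knot(ch$vertices, n_closures = 30, seed = 17)
  expect_equal(fp$dom[1L, fp$n], alone$label$display)
  expect_equal(fp$freq_maps[[paste(1, fp$n, sep = ",")]], alone$frequencies)
})

test_that("fingerprints are deterministic in seed and params", {
  ch <- torus_knot_curve(2, 3, 40L, open_gap = 0.05)
  fp1 <- compute_fingerprint(ch, n_closures = 20, seed = 5, stride = 4)
  fp2 <- compute_fingerprint(ch, n_closures = 20, seed = 5, stride = 4)
  expect_identical(fp1$cells, fp2$cells)
  expect_identical(fp1$freq_maps, fp2$freq_maps)
})

test_that("an open trefoil yields a knotted fingerprint and notation K3_1", {
  ch <- torus_knot_curve(2, 3, 60L, open_gap = 0.05)
  fp <- compute_fingerprint(ch, n_closures = 40, seed = 3, stride = 2)
  expect_equal(fp$dom[1L, fp$n], "3_1")
  # some interior cells are trivial
  expect_true(any(fp$cells$dominant == "0_1"))
  nt <- topological_notation(fp)
  expect_equal(nt$text, "K3_1")
  el <- extract_elements(fp)
  expect_false(is.null(el$knot_core))
  # dominant containment: cells containing the core carry the label
  core <- el$knot_core
  inside <- fp$cells$k <= core[1] & fp$cells$l >= core[2]
  expect_true(mean(fp$cells$dominant[inside] == "3_1") > 0.9)
})

test_that("bridged segments mask overlapping cells and mark results putative", {
  ch <- torus_knot_curve(2, 3, 40L, open_gap = 0.05)
  ch$breaks <- data.frame(after_index = 20L, kind = "numbering_gap",
                          span_residues = 2L, stringsAsFactors = FALSE)
  ch <- bridge_breaks(ch)
  fp <- compute_fingerprint(ch, n_closures = 10, seed = 2, stride = 4)
  expect_true(fp$putative)
  expect_gt(nrow(fp$masked_cells), 0L)
  spans <- fp$cells$k <= 20L & fp$cells$l >= 21L
  expect_equal(fp$cells$masked, spans)
})

test_that("element extraction derives tails, cores and depth classes", {
  # knotted chain, core at (5,55) on N = 60: tails of 4 and 5 residues
  fp <- fake_fingerprint(60L, list(list(k = c(1, 5), l = c(55, 60), label = "3_1")),
                         full_label = "3_1")
  el <- extract_elements(fp)
  expect_equal(el$knot_core, c(5L, 55L))
  expect_equal(el$knot_tails$N, c(1L, 4L))
  expect_equal(el$knot_tails$C, c(56L, 60L))
  expect_equal(el$depth_class$N, "shallow")
  expect_equal(el$depth_class$C, "shallow")
  expect_equal(sum(el$track == "C"), 51L)
  expect_equal(sum(el$track == "T"), 9L)

  # tails of 9 vs 11 residues: shallow vs deep around the threshold
  fp2 <- fake_fingerprint(80L, list(list(k = c(1, 10), l = c(69, 80), label = "3_1")),
                          full_label = "3_1")
  el2 <- extract_elements(fp2)
  expect_equal(el2$knot_tails$N, c(1L, 9L))
  expect_equal(el2$knot_tails$C, c(70L, 80L))
  expect_equal(el2$depth_class$N, "shallow")
  expect_equal(el2$depth_class$C, "deep")
})

test_that("slipknot matrices yield slipknot tails and loops", {
  # full chain trivial; subchains (k <= 20, l in 40..70) knotted; the
  # retracted tail occupies 71..80
  fp <- fake_fingerprint(80L, list(list(k = c(1, 20), l = c(40, 70), label = "3_1")))
  el <- extract_elements(fp)
  expect_equal(el$knot_core, c(20L, 40L))
  expect_equal(length(el$knot_tails), 0L)
  expect_equal(el$slipknot_tails$C, c(71L, 80L))
  expect_equal(el$slipknot_loops$C, c(41L, 70L))
  nt <- topological_notation(fp)
  expect_equal(nt$text, "S3_1")
})

test_that("notation lists disjoint territories largest-first", {
  fp <- fake_fingerprint(100L, list(
    list(k = c(1, 10), l = c(90, 100), label = "4_1"),
    list(k = c(30, 40), l = c(60, 70), label = "3_1")
  ), full_label = "4_1")
  nt <- topological_notation(fp)
  expect_equal(nt$text, "K4_1_3_1")
  expect_equal(vapply(nt$regions, `[[`, "", "label"), c("4_1", "3_1"))
  expect_true(nt$regions[[1]]$size > nt$regions[[2]]$size)

  # small islands are ignored as closure noise
  fp2 <- fake_fingerprint(60L, list(
    list(k = c(1, 8), l = c(50, 60), label = "3_1"),
    list(k = c(25, 25), l = c(35, 35), label = "5_2")
  ), full_label = "3_1")
  expect_equal(topological_notation(fp2)$text, "K3_1")
})

test_that("trajectory analysis labels frames and finds stable cores", {
  tre <- torus_knot_curve(2, 3, 50L, open_gap = 0.05)
  frames <- list(tre, tre, tre)
  res <- analyze_trajectory(frames, n_closures = 30, seed = 4)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$label == "3_1"))
  expect_true(all(res$core_start >= 1 & res$core_end <= 50))

  # mixed unknot/trefoil frames keep per-frame labels
  mixed <- list(unknot_curve(50L, "straight"), tre)
  res2 <- analyze_trajectory(mixed, n_closures = 30, seed = 4)
  expect_equal(res2$label, c("0_1", "3_1"))

  expect_equal(nrow(analyze_trajectory(list())), 0L)
  expect_error(analyze_trajectory(list(tre, unknot_curve(20L))), "share")
})

test_that("writers emit the documented formats", {
  ch <- torus_knot_curve(2, 3, 40L, open_gap = 0.05)
  fp <- compute_fingerprint(ch, n_closures = 20, seed = 2, stride = 4)
  el <- extract_elements(fp)
  nt <- topological_notation(fp)
  dir <- withr::local_tempdir()

  tsv <- write_fingerprint_tsv(fp, file.path(dir, "m.tsv"))
  m <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(names(m), c("k", "l", "dominant", "frequency", "masked"))
  expect_equal(nrow(m), nrow(fp$cells))

  js <- write_summary_json(fp, el, nt, file.path(dir, "s.json"))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$notation, nt$text)
  expect_equal(parsed$n, 40L)

  seq_path <- write_sequence_track(ch, el, file.path(dir, "seq.txt"))
  lines <- readLines(seq_path)
  expect_equal(nchar(lines[2]), 40L)

  # numbering gaps appear as '-' in the track
  ch2 <- ch
  ch2$residue_ids <- c(1:20, 24:43)
  track <- readLines(write_sequence_track(ch2, el, file.path(dir, "s2.txt")))[2]
  expect_equal(nchar(track), 43L)
  expect_equal(substr(track, 21, 23), "---")
})
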