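test_that("PDB reading extracts the alpha-carbon trace", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(p)
  ch <- read_pdb_chain(p, "A")
  expect_s3_class(ch, "knot_chain")
  expect_equal(length(ch), 5L)
  expect_equal(nrow(ch$breaks), 0L)
  expect_equal(ch$residue_ids, 1:5)
  expect_equal(ch$vertices[, 1], 3.8 * (1:5))
})

test_that("modified residues such as MSE are retained as chain members", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(p, resnames = c("ALA", "GLY", "MSE", "SER", "LEU"),
                 records = c("ATOM", "ATOM", "HETATM", "ATOM", "ATOM"))
  ch <- read_pdb_chain(p, "A")
  expect_equal(length(ch), 5L)
  expect_equal(ch$residue_names[3], "MSE")
  expect_equal(nrow(ch$breaks), 0L)
})

test_that("numbering gaps become breaks and missing chains error", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(p, resnames = rep("ALA", 4L), resnos = c(1L, 2L, 4L, 5L))
  ch <- read_pdb_chain(p, "A")
  expect_equal(length(ch), 4L)
  expect_equal(nrow(ch$breaks), 1L)
  expect_equal(ch$breaks$kind, "numbering_gap")
  expect_equal(ch$breaks$after_index, 2L)
  expect_equal(ch$breaks$span_residues, 1L)
  expect_error(read_pdb_chain(p, "Z"), "chain not found")
})

test_that("NMR multi-model files yield the requested model", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(p, models = 2L)
  ch1 <- read_pdb_chain(p, "A")          # default: first model
  ch2 <- read_pdb_chain(p, "A", model = 2L)
  expect_equal(ch1$vertices[1, 1], 3.8)
  expect_equal(ch2$vertices[1, 1], 103.8)
  expect_error(read_pdb_chain(p, "A", model = 3L), "model")
})

test_that("xyz reading parses coordinates and flags bad input", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 0 0", "1 1 0", "0 1 0"), p)
  ch <- read_xyz_chain(p)
  expect_equal(length(ch), 4L)
  expect_equal(ch$residue_ids, 1:4)
  expect_true(all(ch$residue_names == ""))

  writeLines(character(0), p)
  expect_error(read_xyz_chain(p), "no coordinates")

  writeLines(c("0 0 0", "a b c"), p)
  expect_error(read_xyz_chain(p), "line 2")

  # extra columns and comma separators are tolerated
  writeLines(c("# comment", "0, 0, 0, 9", "1 0 0 extra"), p)
  expect_equal(length(read_xyz_chain(p)), 2L)
})

test_that("xyz round trip preserves coordinates", {
  ch <- torus_knot_curve(2, 3, 40L, open_gap = 0.1)
  p <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(ch, p)
  back <- read_xyz_chain(p)
  expect_equal(back$vertices, ch$vertices, tolerance = 1e-6)
})

test_that("distance break detection is idempotent and threshold-exact", {
  pts <- cbind(c(0, 3.8, 7.6, 19.6, 23.4), 0, 0)  # one 12 A jump
  ch <- new_chain(pts)
  ch1 <- detect_distance_breaks(ch, cutoff = 4.5)
  expect_equal(nrow(ch1$breaks), 1L)
  expect_equal(ch1$breaks$kind, "distance_gap")
  expect_equal(ch1$breaks$after_index, 3L)
  ch2 <- detect_distance_breaks(ch1, cutoff = 4.5)
  expect_identical(ch1$breaks, ch2$breaks)

  # all bonds exactly at 3.8 with a slack cutoff: no breaks
  reg <- new_chain(cbind(3.8 * (0:4), 0, 0))
  expect_equal(nrow(detect_distance_breaks(reg, 4.5)$breaks), 0L)

  # single-vertex chain unchanged
  one <- new_chain(matrix(0, 1, 3))
  expect_equal(nrow(detect_distance_breaks(one, 4.5)$breaks), 0L)
})

test_that("bridging marks one segment per break and sets the putative flag", {
  pts <- cbind(c(0, 3.8, 7.6, 19.6, 31.6), 0, 0)  # two jumps
  ch <- detect_distance_breaks(new_chain(pts), 4.5)
  ch <- bridge_breaks(ch)
  expect_equal(sum(ch$bridged), nrow(ch$breaks))
  expect_equal(sum(ch$bridged), 2L)
  expect_true(is_putative(ch))

  clean <- bridge_breaks(new_chain(cbind(3.8 * (0:4), 0, 0)))
  expect_false(is_putative(clean))
})
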