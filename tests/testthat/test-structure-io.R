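test_that("single-model and multi-model PDB files read as ensembles", {
  atoms <- c(pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
             pdb_line(2, "CA", "ALA", "A", 1, 1.4, 0, 0),
             pdb_line(3, "C", "ALA", "A", 1, 2.0, 1.2, 0))
  p1 <- write_toy_pdb(c(atoms, "END"))
  ens <- read_pdb(p1)
  expect_equal(n_frames(ens), 1L)
  expect_equal(nrow(ens), 3L)
  expect_equal(ens$resno, rep(1L, 3))

  blocks <- unlist(lapply(1:5, function(m) {
    c(sprintf("MODEL     %4d", m), atoms, "ENDMDL")
  }))
  p5 <- write_toy_pdb(c(blocks, "END"))
  ens5 <- read_pdb(p5)
  expect_equal(n_frames(ens5), 5L)
  expect_equal(nrow(ens5), 15L)
  expect_equal(n_frames(read_pdb(p5, model_policy = "first")), 1L)
})

test_that("a model with a mismatched atom set is rejected, naming the model", {
  atoms <- c(pdb_line(1, "N", "GLY", "A", 1, 0, 0, 0),
             pdb_line(2, "CA", "GLY", "A", 1, 1.4, 0, 0))
  bad <- c("MODEL        1", atoms, "ENDMDL",
           "MODEL        2", atoms[1], "ENDMDL", "END")
  expect_error(read_pdb(write_toy_pdb(bad)), "model 2")
})

test_that("malformed coordinate fields raise a parse error naming the line", {
  lines <- c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
             "ATOM      2  CA  GLY A   2      bad_xx   0.000   0.000  1.00  0.00           C",
             "END")
  expect_error(read_pdb(write_toy_pdb(lines)), "line 2")
})

test_that("alternate locations resolve by occupancy then altloc code", {
  lines <- c(
    pdb_line(1, "CA", "SER", "A", 5, 0, 0, 0, occ = 0.4, altloc = "A"),
    pdb_line(2, "CA", "SER", "A", 5, 9, 9, 9, occ = 0.6, altloc = "B"),
    pdb_line(3, "CB", "SER", "A", 5, 1, 1, 1, occ = 0.5, altloc = "B"),
    pdb_line(4, "CB", "SER", "A", 5, 2, 2, 2, occ = 0.5, altloc = "A"),
    "END")
  ens <- read_pdb(write_toy_pdb(lines))
  expect_equal(nrow(ens), 2L)
  expect_equal(ens$x[ens$atom == "CA"], 9)   # higher occupancy wins
  expect_equal(ens$x[ens$atom == "CB"], 2)   # tie -> alphabetical altloc
})

test_that("write/read round trip preserves identity and 3-decimal coordinates", {
  ens <- perturb_ensemble(make_helix(helix_spec(n_residues = 6,
                                                sequence = "ALA")),
                          sigma = 0.5, n_frames = 3, seed = 2)
  path <- tempfile(fileext = ".pdb")
  write_pdb(ens, path)
  back <- read_pdb(path)
  expect_equal(n_frames(back), 3L)
  expect_equal(back$atom, ens$atom)
  expect_equal(back$resno, ens$resno)
  expect_equal(back$resname, ens$resname)
  expect_equal(back$x, round(ens$x, 3), tolerance = 1e-9)
  expect_equal(back$z, round(ens$z, 3), tolerance = 1e-9)
  unlink(path)
})

test_that("parsed coordinates agree with the bio3d reader", {
  h <- make_helix(helix_spec(n_residues = 8, sequence = "ALA"))
  path <- tempfile(fileext = ".pdb")
  write_pdb(h, path)
  ours <- read_pdb(path)
  ref <- bio3d::read.pdb(path)
  expect_equal(ours$x, ref$atom$x, tolerance = 1e-6)
  expect_equal(ours$y, ref$atom$y, tolerance = 1e-6)
  expect_equal(ours$z, ref$atom$z, tolerance = 1e-6)
  expect_equal(ours$resno, ref$atom$resno)
  unlink(path)
})

test_that("C-beta points use explicit CB atoms where present", {
  h <- make_helix(helix_spec(n_residues = 5, sequence = "ALA"))
  pts <- cbeta_points(h)
  expect_true(all(pts$source == "CB"))
  cb <- h[h$atom == "CB" & h$resno == 3, ]
  expect_equal(unlist(pts[pts$resno == 3, c("x", "y", "z")], use.names = FALSE),
               c(cb$x, cb$y, cb$z))
})

test_that("glycine gets a deterministic virtual C-beta 1.53 A from C-alpha", {
  h <- make_helix(helix_spec(n_residues = 5, sequence = "GLY"))
  pts <- cbeta_points(h)
  expect_true(all(pts$source == "virtual"))
  ca <- h[h$atom == "CA", ]
  d <- sqrt((pts$x - ca$x)^2 + (pts$y - ca$y)^2 + (pts$z - ca$z)^2)
  expect_equal(d, rep(1.53, 5), tolerance = 1e-9)
  # deterministic: same input, same output
  expect_identical(pts, cbeta_points(h))
  # tetrahedral take-off: angle N-CA-CB near 110 degrees
  nn <- h[h$atom == "N" & h$resno == 3, ]
  cab <- unlist(pts[pts$resno == 3, c("x", "y", "z")], use.names = FALSE) -
    unlist(ca[ca$resno == 3, c("x", "y", "z")], use.names = FALSE)
  can <- c(nn$x, nn$y, nn$z) -
    unlist(ca[ca$resno == 3, c("x", "y", "z")], use.names = FALSE)
  ang <- acos(sum(cab * can) / sqrt(sum(cab^2) * sum(can^2))) * 180 / pi
  expect_gt(ang, 100)
  expect_lt(ang, 120)
})

test_that("a residue with only C-alpha falls back to C-alpha, flagged", {
  lines <- c(pdb_line(1, "CA", "GLY", "A", 7, 1, 2, 3), "END")
  ens <- read_pdb(write_toy_pdb(lines))
  pts <- cbeta_points(ens)
  expect_equal(pts$source, "CA-fallback")
  expect_equal(c(pts$x, pts$y, pts$z), c(1, 2, 3))
})

test_that("requesting a residue absent from the ensemble errors", {
  h <- make_helix(helix_spec(n_residues = 4))
  expect_error(cbeta_points(h, residues = tibble::tibble(chain = "A",
                                                         resno = 99L)),
               "not found")
})

test_that("segment selection honours ranges, chains and atom filters", {
  ch <- make_channel(channel_spec(n_residues = 9))
  m <- segment_map(mid = c(4, 6),
                   chainA = data.frame(chain = "A", start = 1, end = 9))
  sel <- select_segment(ch, m, "mid", atoms = "CA")
  expect_true(all(sel$resno %in% 4:6))
  expect_true(all(sel$atom == "CA"))
  expect_equal(nrow(sel), 3 * length(unique(ch$chain)))
  selA <- select_segment(ch, m, "chainA", atoms = "backbone")
  expect_true(all(selA$chain == "A"))
  expect_setequal(unique(selA$atom), c("N", "CA", "C", "O"))
  expect_error(select_segment(ch, m, "nope"), "unknown segment")
})

test_that("segment selection commutes with frame subsetting", {
  ens <- perturb_ensemble(make_channel(channel_spec(n_residues = 9)),
                          sigma = 0.2, n_frames = 4, seed = 9)
  m <- segment_map(mid = c(3, 7))
  a <- select_segment(get_frame(ens, 3), m, "mid", atoms = "CA")
  b <- get_frame(select_segment(ens, m, "mid", atoms = "CA"), 3)
  expect_equal(a$x, b$x)
  expect_equal(a$resno, b$resno)
})

test_that("segment maps round trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("segments:",
               "  TMH6: [330, 360]",
               "  TMH12: [1118, 1155]",
               "membrane_z: [-15, 15]"), path)
  m <- read_segment_map(path)
  expect_equal(names(m$segments), c("TMH6", "TMH12"))
  expect_equal(m$segments$TMH6$start, 330L)
  expect_equal(m$membrane_z, c(-15, 15))
  unlink(path)
})

test_that("radius tables validate their range and supply fallbacks", {
  tab <- default_radius_table()
  expect_true(all(tab$radius > 0.5 & tab$radius < 3))
  r <- atom_radii(tibble::tibble(element = c("C", "N", "ZZ")))
  expect_equal(r, c(1.85, 1.75, 1.85))
  bad <- tempfile(fileext = ".yaml")
  writeLines("C: 5.0", bad)
  expect_error(read_radius_table(bad), "0.5, 3.0")
  unlink(bad)
})
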