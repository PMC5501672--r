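test_that("superposition is exact for identical and rigidly moved sets", {
  set.seed(1)
  A <- matrix(rnorm(30), 10, 3)
  self <- superpose(A, A)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)

  for (i in 1:20) {
    R <- random_rotation()
    t <- rnorm(3, 0, 10)
    B <- A %*% R + matrix(t, 10, 3, byrow = TRUE)
    s <- superpose(A, B)
    expect_lt(s$rmsd, 1e-8)
    expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  }
  expect_error(superpose(A[1:2, ], A[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD matches the quaternion-method oracle", {
  set.seed(2)
  for (i in 1:200) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    expect_equal(superpose(A, B)$rmsd, quaternion_rmsd(A, B),
                 tolerance = 1e-8)
  }
})

test_that("superposed RMSD behaves as a metric on test frames", {
  set.seed(3)
  mats <- lapply(1:6, function(i) matrix(rnorm(45), 15, 3))
  for (i in 1:6) {
    for (j in 1:6) {
      dij <- superpose(mats[[i]], mats[[j]])$rmsd
      dji <- superpose(mats[[j]], mats[[i]])$rmsd
      expect_equal(dij, dji, tolerance = 1e-6)
      for (k in 1:6) {
        dik <- superpose(mats[[i]], mats[[k]])$rmsd
        dkj <- superpose(mats[[k]], mats[[j]])$rmsd
        expect_lte(dij, dik + dkj + 1e-6)
      }
    }
  }
})

test_that("alignment-guided RMSD recovers correspondence across numbering", {
  spec <- helix_spec(n_residues = 30,
                     sequence = c(rep(c("ALA", "LEU", "SER", "VAL", "PHE",
                                        "ILE", "THR", "GLY", "MET", "TRP"),
                                      3)))
  a <- make_helix(spec, chain = "A", first_resno = 101L)
  # homolog: shifted numbering, a few substitutions, mild coordinate noise
  spec_b <- spec
  spec_b$sequence[c(5, 12, 21)] <- c("GLY", "ALA", "LYS")
  b <- make_helix(spec_b, chain = "A", first_resno = 501L)
  b <- perturb_ensemble(b, sigma = 0.2, n_frames = 1, seed = 4)
  map <- correspondence_map(a, b)
  expect_equal(nrow(map), 30L)
  expect_equal(map$resno_b - map$resno_a, rep(400L, 30))
  expect_equal(attr(map, "coverage"), 1)

  sup <- align_structures(a, b, map, selection = "CA")
  expect_lt(sup$rmsd, 1.7)
  # reversed direction gives the same rmsd
  sup_rev <- align_structures(b, a, correspondence_map(b, a), selection = "CA")
  expect_equal(sup$rmsd, sup_rev$rmsd, tolerance = 1e-6)
})

test_that("identity-mapped self-comparison is zero", {
  ch <- make_channel(channel_spec(n_residues = 9))
  sup <- align_structures(ch, ch)
  expect_equal(sup$rmsd, 0, tolerance = 1e-10)
})

test_that("segment RMSD localises a planted helix displacement", {
  ch <- make_channel(channel_spec(n_residues = 11))
  moved <- ch
  idx <- moved$chain == "A"
  moved$x[idx] <- moved$x[idx] + 3
  moved$z[idx] <- moved$z[idx] + 4    # 5 A rigid displacement of helix A
  segs <- segment_map(
    helixA = data.frame(chain = "A", start = 1, end = 11),
    helixB = data.frame(chain = "B", start = 1, end = 11),
    helixG = data.frame(chain = "G", start = 1, end = 11))
  zeros <- segment_rmsd(ch, ch, segs)
  expect_true(all(zeros$fit_global < 1e-9))
  tab <- segment_rmsd(ch, moved, segs, selection = "CA")
  a_row <- tab[tab$segment == "helixA", ]
  other <- tab[tab$segment != "helixA", ]
  expect_equal(a_row$fit_global, 5, tolerance = 0.8)
  expect_true(all(other$fit_global < 1.5))
  expect_true(all(tab$fit_local <= tab$fit_global + 1e-9))
  expect_lt(a_row$fit_local, 1e-6)    # displacement is rigid
})

test_that("RMSD series against first and last references behave as expected", {
  base <- make_helix(helix_spec(n_residues = 10))
  static <- perturb_ensemble(base, sigma = 0, n_frames = 5, seed = 1)
  s0 <- rmsd_timeseries(static, "first")
  expect_true(all(s0$rmsd < 1e-10))

  # converging drift: frames approach the final structure
  n <- 15
  frames <- lapply(seq_len(n), function(f) {
    fr <- base
    fr$frame <- f
    fr$x <- fr$x + 5 * (n - f) / n  # linear approach, non-rigid? rigid shift
    fr$y <- fr$y + 3 * (n - f) / n * fr$z / max(fr$z)  # shear: non-rigid
    fr
  })
  conv <- dplyr::bind_rows(frames)
  s1 <- rmsd_timeseries(conv, "last")
  expect_true(all(diff(s1$rmsd) < 1e-6))
  expect_lt(s1$rmsd[n], 1e-9)
})

test_that("equilibration onset is found on plateaus and refused on ramps", {
  flat <- tibble::tibble(frame = 1:60, rmsd = 2 + rnorm(60, 0, 0.01))
  expect_equal(detect_equilibration(flat, window = 10), 1L)

  ramp <- tibble::tibble(frame = 1:60, rmsd = seq(0, 30, length.out = 60))
  expect_true(is.na(detect_equilibration(ramp, window = 10,
                                         slope_tol = 0.02)))

  for (k in c(20, 40)) {
    s <- ramp_plateau_series(n = 80, k = k, seed = k)
    onset <- detect_equilibration(s, window = 10, slope_tol = 0.02)
    expect_false(is.na(onset))
    expect_lte(abs(onset - k), 10)
  }
  expect_error(detect_equilibration(flat, window = 100), "window")
})

test_that("identical frames collapse to one cluster", {
  ens <- perturb_ensemble(make_helix(helix_spec(n_residues = 8)),
                          sigma = 0, n_frames = 6, seed = 1)
  cl <- cluster_frames(ens, threshold = 2)
  expect_equal(length(unique(cl$assignment$cluster)), 1L)
  expect_equal(cl$centroids, 1)
})

test_that("a generous threshold merges everything into one cluster", {
  pe <- planted_conformer_ensemble(n_conformers = 3, n_frames = 12, seed = 7)
  cl <- cluster_frames(pe$ensemble, threshold = 1e6)
  expect_equal(length(unique(cl$assignment$cluster)), 1L)
})

test_that("planted conformers are recovered exactly at the 2 A threshold", {
  pe <- planted_conformer_ensemble(n_conformers = 3, n_frames = 24, seed = 5)
  cl <- cluster_frames(pe$ensemble, threshold = 2, selection = "backbone")
  expect_equal(length(unique(cl$assignment$cluster)), 3L)
  tab <- table(pe$truth, cl$assignment$cluster)
  expect_true(all(rowSums(tab > 0) == 1))   # each planted state -> one cluster
  expect_true(all(colSums(tab > 0) == 1))
  # centroids belong to their clusters
  for (k in seq_along(cl$centroids)) {
    expect_equal(cl$assignment$cluster[cl$assignment$frame == cl$centroids[k]],
                 k)
  }
})

test_that("clustering is invariant to frame relabeling up to id permutation", {
  pe <- planted_conformer_ensemble(n_conformers = 3, n_frames = 12, seed = 9)
  cl1 <- cluster_frames(pe$ensemble, threshold = 2)
  perm <- c(7:12, 1:6)
  rel <- pe$ensemble
  rel$frame <- perm[rel$frame]
  cl2 <- cluster_frames(rel, threshold = 2)
  part1 <- split(cl1$assignment$frame, cl1$assignment$cluster)
  part2 <- split(perm[cl2$assignment$frame], cl2$assignment$cluster)
  norm <- function(p) unname(lapply(p, sort))[order(sapply(lapply(p, sort), min))]
  expect_equal(norm(part1), norm(part2))
})

test_that("two-state mixtures recover their weights within the binomial CI", {
  pe <- planted_conformer_ensemble(n_conformers = 2, n_frames = 40, seed = 21)
  # assignment alternates, so the planted weight is 0.5
  cl <- cluster_frames(pe$ensemble, threshold = 2)
  sizes <- sort(as.integer(table(cl$assignment$cluster)))
  expect_equal(length(sizes), 2L)
  ci <- prop.test(sizes[1], 40)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})
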