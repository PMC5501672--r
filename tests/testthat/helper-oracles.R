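# Independent oracles and small builders shared across the test suite.

# Horn quaternion-method superposition RMSD: an independent check on the
# SVD-based Kabsch implementation. Returns the minimised RMSD.
quaternion_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  S <- t(Bc) %*% Ac
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sq <- (sum(Ac^2) + sum(Bc^2) - 2 * lam) / n
  sqrt(max(sq, 0))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1-2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
    2*(x*y + w*z), 1-2*(x^2+z^2), 2*(y*z - w*x),
    2*(x*z - w*y), 2*(y*z + w*x), 1-2*(x^2+y^2)
  ), 3, 3, byrow = TRUE)
}

# Minimal PDB text builder for parser tests.
pdb_line <- function(serial, atom, resname, chain, resno, x, y, z,
                     occ = 1, altloc = " ", element = substr(atom, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(atom) >= 4, atom, paste0(" ", atom)),
          altloc, resname, chain, resno, x, y, z, occ, 0, element)
}

write_toy_pdb <- function(lines) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Ring of m atoms in the z = z0 plane, circle radius rr, as an atom tibble.
atom_ring <- function(rr, z0, m = 8, element = "C") {
  ang <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  tibble::tibble(frame = 1L, serial = seq_len(m), atom = "CA", altloc = "",
                 resname = "RNG", chain = "A", resno = 1L,
                 x = rr * cos(ang), y = rr * sin(ang), z = z0,
                 occupancy = 1, element = element)
}

# 100-frame ensemble drawn from k well-separated planted conformers of the
# synthetic channel (rigid helix displacements across conformers, small iid
# noise within), plus the true assignment.
planted_conformer_ensemble <- function(n_conformers = 5, n_frames = 100,
                                       seed = 1, intra_sigma = 0.25) {
  base <- make_channel(channel_spec(), "open")
  conformers <- lapply(seq_len(n_conformers), function(k) {
    perturb_ensemble(base, sigma = 2.5, n_frames = 1,
                     seed = seed * 1000 + k, mode = "rigid_helix")
  })
  assign_true <- rep(seq_len(n_conformers), length.out = n_frames)
  frames <- lapply(seq_len(n_frames), function(f) {
    fr <- perturb_ensemble(conformers[[assign_true[f]]], sigma = intra_sigma,
                           n_frames = 1, seed = seed * 5000 + f, mode = "iid")
    fr$frame <- f
    fr
  })
  list(ensemble = dplyr::bind_rows(frames), truth = assign_true)
}

# Synthetic RMSD trace: linear ramp to height `amp` reaching a plateau at
# frame k, with Gaussian observation noise.
ramp_plateau_series <- function(n = 120, k = 50, amp = 3, noise = 0.05,
                                seed = 1) {
  set.seed(seed)
  tibble::tibble(frame = seq_len(n),
                 rmsd = amp * pmin(seq_len(n), k) / k + rnorm(n, 0, noise))
}
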