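#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `coords_b`
#' onto `coords_a`, via singular value decomposition of the covariance matrix
#' with the determinant correction that forbids reflections.
#'
#' @param coords_a,coords_b Matched n x 3 coordinate matrices (n >= 3).
#' @return Object of class `plx_superposition`: `rotation` (3 x 3, proper),
#'   `translation` (length 3), `rmsd` (A, the minimised value), `n_atoms`.
#'   The fitted transform is `x_b %*% rotation + translation`.
#' @export
superpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (nrow(A) != nrow(B) || ncol(A) != 3 || ncol(B) != 3) {
    abort("superpose needs matched n x 3 coordinate matrices")
  }
  n <- nrow(A)
  if (n < 3) abort("superposition needs at least 3 atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (max(svd(Ac)$d) < 1e-9 || max(svd(Bc)$d) < 1e-9) {
    abort("degenerate coordinates: all atoms coincide")
  }
  H <- crossprod(Bc, Ac)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)       # B %*% R approximates A
  fitted <- Bc %*% R
  rmsd <- sqrt(sum((fitted - Ac)^2) / n)
  t_vec <- ca - cb %*% R
  structure(list(rotation = R, translation = as.numeric(t_vec),
                 rmsd = rmsd, n_atoms = n),
            class = "plx_superposition")
}

#' @export
print.plx_superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d atoms, rmsd %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' @method tidy plx_superposition
#' @export
tidy.plx_superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms = x$n_atoms,
         det_rotation = det(x$rotation),
         coverage = x$coverage %||% NA_real_)
}

apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% sup$rotation, 2, sup$translation, "+")
}

rmsd_between <- function(A, B, refit = TRUE) {
  if (refit) superpose(A, B)$rmsd
  else sqrt(mean(rowSums((A - B)^2)))
}

aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O")

structure_sequence <- function(frame, chain) {
  res <- frame %>%
    filter(.data$atom == "CA", .data$chain == !!chain) %>%
    distinct(.data$resno, .data$resname) %>%
    arrange(.data$resno)
  aa <- aa_three_to_one[res$resname]
  aa[is.na(aa)] <- "X"
  list(seq = paste(aa, collapse = ""), resno = res$resno)
}

#' Residue correspondence between two structures by sequence alignment
#'
#' Extracts each chain's sequence from the C-alpha records and aligns the
#' chains pairwise (global alignment, BLOSUM62, affine gaps) to build a
#' one-to-one, order-preserving residue correspondence — the route for
#' comparing structures across species or numbering schemes.
#'
#' @param struct_a,struct_b Atom tibbles (single frames).
#' @param chains_a,chains_b Chains to align, matched positionally; default
#'   the common/first chains of each structure.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Tibble of class `plx_correspondence`: `chain_a`, `resno_a`,
#'   `chain_b`, `resno_b`; attribute `coverage` = matched fraction of the
#'   shorter sequence.
#' @export
correspondence_map <- function(struct_a, struct_b,
                               chains_a = NULL, chains_b = NULL,
                               gap_opening = 10, gap_extension = 0.5) {
  if (is.null(chains_a)) chains_a <- sort(unique(struct_a$chain))
  if (is.null(chains_b)) chains_b <- sort(unique(struct_b$chain))
  k <- min(length(chains_a), length(chains_b))
  maps <- map(seq_len(k), function(i) {
    sa <- structure_sequence(struct_a, chains_a[i])
    sb <- structure_sequence(struct_b, chains_b[i])
    aln <- Biostrings::pairwiseAlignment(
      sa$seq, sb$seq, type = "global",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension)
    pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
    ia <- ib <- 0L
    rows <- vector("list", length(pa))
    for (j in seq_along(pa)) {
      if (pa[j] != "-") ia <- ia + 1L
      if (pb[j] != "-") ib <- ib + 1L
      if (pa[j] != "-" && pb[j] != "-") {
        rows[[j]] <- tibble(chain_a = chains_a[i], resno_a = sa$resno[ia],
                            chain_b = chains_b[i], resno_b = sb$resno[ib])
      }
    }
    list_rbind(rows[!vapply(rows, is.null, logical(1))]) %>%
      mutate(coverage_denom = min(length(sa$resno), length(sb$resno)))
  })
  out <- list_rbind(maps)
  cov <- nrow(out) / sum(vapply(maps, function(m) m$coverage_denom[1], numeric(1)))
  out$coverage_denom <- NULL
  attr(out, "coverage") <- cov
  class(out) <- c("plx_correspondence", class(out))
  out
}

#' Identity correspondence map
#'
#' Pairs residues with equal chain and residue number — the correspondence
#' for structures sharing one numbering scheme.
#' @param struct_a,struct_b Atom tibbles.
#' @return A `plx_correspondence` tibble.
#' @export
identity_map <- function(struct_a, struct_b) {
  ra <- distinct(filter(struct_a, .data$atom == "CA"), .data$chain, .data$resno)
  rb <- distinct(filter(struct_b, .data$atom == "CA"), .data$chain, .data$resno)
  out <- inner_join(ra, rb, by = c("chain", "resno")) %>%
    transmute(chain_a = .data$chain, resno_a = .data$resno,
              chain_b = .data$chain, resno_b = .data$resno)
  attr(out, "coverage") <- nrow(out) / min(nrow(ra), nrow(rb))
  class(out) <- c("plx_correspondence", class(out))
  out
}

# Matched coordinate matrices for mapped residues under an atom selection.
mapped_coords <- function(struct_a, struct_b, map, selection = c("CA", "backbone")) {
  selection <- match.arg(selection)
  sel_atoms <- if (selection == "CA") "CA" else c("N", "CA", "C", "O")
  fa <- filter(struct_a, .data$atom %in% sel_atoms)
  fb <- filter(struct_b, .data$atom %in% sel_atoms)
  ka <- paste(fa$chain, fa$resno, fa$atom)
  kb <- paste(fb$chain, fb$resno, fb$atom)
  rows <- tidyr::crossing(atom = sel_atoms, idx = seq_len(nrow(map))) %>%
    arrange(.data$idx, .data$atom)
  key_a <- paste(map$chain_a[rows$idx], map$resno_a[rows$idx], rows$atom)
  key_b <- paste(map$chain_b[rows$idx], map$resno_b[rows$idx], rows$atom)
  ia <- match(key_a, ka); ib <- match(key_b, kb)
  ok <- !is.na(ia) & !is.na(ib)
  list(A = coords_mat(fa)[ia[ok], , drop = FALSE],
       B = coords_mat(fb)[ib[ok], , drop = FALSE],
       map_idx = rows$idx[ok])
}

#' Alignment-guided superposition and RMSD
#'
#' Superposes two structures on the atoms of their mapped residues and
#' reports the RMSD, e.g. a homology model against a cryo-EM structure of
#' another species.
#'
#' @param struct_a,struct_b Atom tibbles (single frames).
#' @param map Correspondence from [correspondence_map()]; default
#'   [identity_map()].
#' @param selection `"CA"` or `"backbone"`.
#' @return A `plx_superposition` with an added `coverage` element.
#' @export
align_structures <- function(struct_a, struct_b, map = NULL,
                             selection = c("CA", "backbone")) {
  selection <- match.arg(selection)
  if (is.null(map)) map <- identity_map(struct_a, struct_b)
  if (nrow(map) == 0) abort("correspondence map is empty")
  mc <- mapped_coords(struct_a, struct_b, map, selection)
  if (nrow(mc$A) == 0) abort("no mapped atoms after selection")
  sup <- superpose(mc$A, mc$B)
  sup$coverage <- attr(map, "coverage") %||% NA_real_
  sup$selection <- selection
  sup
}

#' Per-segment RMSD between two structures
#'
#' Measures each named segment's RMSD in two modes: `fit_global` superposes
#' once on all mapped atoms and then measures each segment in that frame
#' (sensitive to rigid displacement of a segment), while `fit_local` refits
#' per segment (sensitive only to internal deformation). `fit_local` can
#' never exceed `fit_global`.
#'
#' @param struct_a,struct_b Atom tibbles.
#' @param segments A [segment_map()]; segment ranges are looked up on
#'   structure A and carried through the correspondence.
#' @param map Correspondence map; default [identity_map()].
#' @param selection `"CA"` or `"backbone"`.
#' @return Tibble: `segment`, `n_atoms`, `fit_global`, `fit_local` (A).
#'   Segments with fewer than 3 mapped residues are skipped with a warning.
#' @export
segment_rmsd <- function(struct_a, struct_b, segments, map = NULL,
                         selection = c("CA", "backbone")) {
  selection <- match.arg(selection)
  if (is.null(map)) map <- identity_map(struct_a, struct_b)
  mc <- mapped_coords(struct_a, struct_b, map, selection)
  global <- superpose(mc$A, mc$B)
  B_fit <- apply_superposition(global, mc$B)

  out <- map(names(segments$segments), function(nm) {
    rng <- segments$segments[[nm]]
    in_seg <- rep(FALSE, nrow(map))
    for (i in seq_len(nrow(rng))) {
      m <- map$resno_a >= rng$start[i] & map$resno_a <= rng$end[i]
      if (!is.na(rng$chain[i])) m <- m & map$chain_a == rng$chain[i]
      in_seg <- in_seg | m
    }
    rows <- which(in_seg[mc$map_idx])
    if (length(unique(mc$map_idx[rows])) < 3) {
      warn(paste0("segment ", nm, " has fewer than 3 mapped residues; skipped"))
      return(NULL)
    }
    A <- mc$A[rows, , drop = FALSE]
    tibble(segment = nm, n_atoms = length(rows),
           fit_global = sqrt(mean(rowSums((A - B_fit[rows, , drop = FALSE])^2))),
           fit_local = superpose(A, mc$B[rows, , drop = FALSE])$rmsd)
  }) %>% list_rbind()
  out
}

#' RMSD time series of an ensemble against a reference
#'
#' Superposes every frame onto a reference frame and records the RMSD — the
#' standard equilibration diagnostic for a trajectory.
#'
#' @param ensemble Atom tibble with >= 2 frames.
#' @param reference `"first"`, `"last"`, or an atom tibble (single frame with
#'   the same atom table).
#' @param selection `"CA"`, `"backbone"`, `"heavy"` or `"all"`.
#' @return Tibble of class `plx_rmsd_series`: `frame`, `rmsd`.
#' @export
rmsd_timeseries <- function(ensemble, reference = c("first", "last"),
                            selection = "backbone") {
  frames <- sort(unique(ensemble$frame))
  sub <- filter_atoms(ensemble, selection)
  ref_coords <- if (is.character(reference)) {
    reference <- match.arg(reference)
    f <- if (reference == "first") frames[1] else frames[length(frames)]
    coords_mat(get_frame(sub, f))
  } else {
    coords_mat(filter_atoms(as_tibble(reference), selection))
  }
  out <- tibble(
    frame = frames,
    rmsd = map_dbl(frames, function(f) {
      superpose(ref_coords, coords_mat(get_frame(sub, f)))$rmsd
    }))
  class(out) <- c("plx_rmsd_series", class(out))
  out
}

#' @method autoplot plx_rmsd_series
#' @export
autoplot.plx_rmsd_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$rmsd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' Detect the equilibration onset of an RMSD series
#'
#' Makes the visual "plateau" criterion explicit: the series is equilibrated
#' from the earliest frame after which every moving window of `window` frames
#' has (a) absolute linear slope within `slope_tol` and (b) a value range
#' within `range_tol` (the plateau band; trajectories whose RMSD still drifts
#' more than ~2 A are not equilibrated).
#'
#' @param series Tibble with columns `frame`, `rmsd` (see
#'   [rmsd_timeseries()]).
#' @param window Moving-window width in frames.
#' @param slope_tol Max absolute slope (A per frame).
#' @param range_tol Max range within a window (A).
#' @return The onset frame label, or `NA` if the series never equilibrates.
#' @export
detect_equilibration <- function(series, window = 20, slope_tol = 0.02,
                                 range_tol = 2) {
  s <- arrange(as_tibble(series), .data$frame)
  n <- nrow(s)
  if (window >= n) abort("window must be shorter than the series")
  n_win <- n - window + 1
  ok <- logical(n_win)
  xs <- seq_len(window)
  sxx <- sum((xs - mean(xs))^2)
  for (i in seq_len(n_win)) {
    y <- s$rmsd[i:(i + window - 1)]
    slope <- sum((xs - mean(xs)) * (y - mean(y))) / sxx
    ok[i] <- abs(slope) <= slope_tol && (max(y) - min(y)) <= range_tol
  }
  # earliest window start from which every later window is flat
  rev_ok <- rev(cumprod(rev(ok)))
  idx <- which(rev_ok == 1)
  if (length(idx) == 0) return(NA_integer_)
  s$frame[idx[1]]
}

#' Quality-threshold clustering of ensemble frames
#'
#' Clusters frames on the matrix of pairwise superposed RMSDs (backbone atoms
#' by default): iteratively extract the frame with the most neighbours within
#' `threshold` together with those neighbours as one cluster (ties broken by
#' lowest frame index), until all frames are assigned. Each cluster's
#' representative is its centroid: the member frame minimising the total
#' within-cluster RMSD.
#'
#' @param ensemble Atom tibble.
#' @param threshold RMSD threshold in Angstrom (default 2).
#' @param selection Atom selection for the RMSD (default `"backbone"`).
#' @param refit Recompute the optimal superposition for every frame pair
#'   (default); `FALSE` measures RMSD after superposing all frames onto the
#'   first (gromos-style single-reference fit).
#' @return Object of class `plx_clusters`: `assignment` tibble (`frame`,
#'   `cluster`), `centroids` (frame per cluster), `threshold`, `rmsd_matrix`.
#' @export
cluster_frames <- function(ensemble, threshold = 2, selection = "backbone",
                           refit = TRUE) {
  frames <- sort(unique(ensemble$frame))
  sub <- filter_atoms(ensemble, selection)
  mats <- map(frames, function(f) coords_mat(get_frame(sub, f)))
  nf <- length(frames)
  if (!refit) {
    ref <- mats[[1]]
    mats <- map(mats, function(m) apply_superposition(superpose(ref, m), m))
  }
  D <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in seq_len(nf - 1)) {
      for (j in (i + 1):nf) {
        D[i, j] <- D[j, i] <- rmsd_between(mats[[i]], mats[[j]], refit = refit)
      }
    }
  }
  remaining <- seq_len(nf)
  cluster <- integer(nf)
  cl_id <- 0L
  while (length(remaining) > 0) {
    cl_id <- cl_id + 1L
    counts <- vapply(remaining, function(i) {
      sum(D[i, remaining] <= threshold)
    }, numeric(1))
    seed <- remaining[which.max(counts)]      # which.max: lowest index on ties
    members <- remaining[D[seed, remaining] <= threshold]
    cluster[members] <- cl_id
    remaining <- setdiff(remaining, members)
  }
  centroids <- vapply(seq_len(cl_id), function(k) {
    mem <- which(cluster == k)
    tot <- vapply(mem, function(i) sum(D[i, mem]), numeric(1))
    frames[mem[which.min(tot)]]
  }, numeric(1))
  structure(list(assignment = tibble(frame = frames, cluster = cluster),
                 centroids = centroids, threshold = threshold,
                 selection = selection, rmsd_matrix = D),
            class = "plx_clusters")
}

#' @export
print.plx_clusters <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  cat("<frame clustering>", length(sizes), "clusters at threshold",
      x$threshold, "A\n  sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy plx_clusters
#' @export
tidy.plx_clusters <- function(x, ...) x$assignment

#' @method glance plx_clusters
#' @export
glance.plx_clusters <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  tibble(n_clusters = length(sizes),
         n_frames = nrow(x$assignment),
         largest_cluster = max(sizes),
         threshold = x$threshold)
}
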