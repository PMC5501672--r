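# Cylindrical lattice of the stylised alpha-helix emitted by make_helix().
# Backbone atoms sit on per-class cylinders around the helix axis; the
# C-alpha cylinder radius (2.3 A) defines the helix envelope used for the
# analytic pore ground truth. Offsets are phase (deg) and rise (A) relative
# to each residue's C-alpha.
helix_lattice <- function() {
  tibble(
    atom = c("N", "CA", "C", "O"),
    element = c("N", "C", "C", "O"),
    r = c(1.60, 2.30, 1.90, 2.00),
    dphi = c(-28, 0, 33, 36),
    dz = c(-0.90, 0, 0.85, 2.05)
  )
}

#' Specification of one ideal synthetic helix
#'
#' @param n_residues Number of residues (>= 4).
#' @param rise Rise per residue along the helix axis (A; 1.5 for an
#'   alpha-helix).
#' @param twist Twist per residue (degrees; 100 for an alpha-helix).
#' @param sequence Residue name recycled along the helix (default `"GLY"`:
#'   backbone only, no C-beta emitted) or a vector of 3-letter codes of
#'   length `n_residues`.
#' @return A list of class `plx_helix_spec`.
#' @export
helix_spec <- function(n_residues = 27, rise = 1.5, twist = 100,
                       sequence = "GLY") {
  stopifnot(n_residues >= 4, rise > 0)
  seqv <- rep(sequence, length.out = n_residues)
  structure(list(n_residues = as.integer(n_residues), rise = rise,
                 twist = twist, sequence = seqv),
            class = "plx_helix_spec")
}

#' Build one ideal helix
#'
#' Emits backbone atoms (N, CA, C, O) on the helical lattice, with the helix
#' axis along z and residue `i` centred at `z = (i - 1) * rise + z0`.
#' Consecutive C-alpha distances come out near 3.8 A (the chord of a 2.3 A
#' radius, 1.5 A rise, 100 degree helix). Non-glycine residues additionally
#' get a C-beta from the ideal tetrahedral construction.
#'
#' @param spec A [helix_spec()].
#' @param chain Chain identifier.
#' @param phi0 Initial phase in degrees (azimuth of residue 1's C-alpha).
#' @param z0 Axial position of residue 1's C-alpha.
#' @param first_resno Author number of residue 1.
#' @return Atom tibble (single frame).
#' @export
make_helix <- function(spec = helix_spec(), chain = "A", phi0 = 0, z0 = 0,
                       first_resno = 1L) {
  lat <- helix_lattice()
  rows <- vector("list", spec$n_residues)
  for (i in seq_len(spec$n_residues)) {
    phi <- phi0 + (i - 1) * spec$twist
    zc <- z0 + (i - 1) * spec$rise
    ang <- (phi + lat$dphi) * pi / 180
    at <- tibble(
      frame = 1L, serial = 0L,
      atom = lat$atom, altloc = "",
      resname = spec$sequence[i], chain = chain,
      resno = first_resno + i - 1L,
      x = lat$r * cos(ang), y = lat$r * sin(ang), z = zc + lat$dz,
      occupancy = 1, element = lat$element)
    if (spec$sequence[i] != "GLY") {
      nca <- at[at$atom %in% c("N", "CA", "C"), ]
      p <- virtual_cbeta(
        c(nca$x[nca$atom == "N"], nca$y[nca$atom == "N"], nca$z[nca$atom == "N"]),
        c(nca$x[nca$atom == "CA"], nca$y[nca$atom == "CA"], nca$z[nca$atom == "CA"]),
        c(nca$x[nca$atom == "C"], nca$y[nca$atom == "C"], nca$z[nca$atom == "C"]))
      at <- dplyr::bind_rows(at, tibble(
        frame = 1L, serial = 0L, atom = "CB", altloc = "",
        resname = spec$sequence[i], chain = chain,
        resno = first_resno + i - 1L,
        x = p[1], y = p[2], z = p[3], occupancy = 1, element = "C"))
    }
    rows[[i]] <- at
  }
  out <- list_rbind(rows)
  out$serial <- seq_len(nrow(out))
  out
}

#' Specification of a synthetic helix-bundle channel
#'
#' A stylised 12-helix membrane bundle with an axial pore, emulating the
#' transmembrane domain of an ABC-type channel. Six pore-lining helices sit
#' on an inner ring whose radial distance from the channel axis follows the
#' piecewise-linear `radius_profile` (an hourglass: wide vestibules, narrow
#' selectivity filter at z = 0); the other six back the bundle on an outer
#' ring (`backing_offset` farther out). The closed state displaces the
#' `displaced_helices` radially inward by `delta_r` (optionally rotating them
#' about the channel axis by `delta_theta`), pinching the filter shut —
#' emulating the gating rearrangement of a subset of helices.
#'
#' Helix self-phases are chosen so that each pore-lining helix presents an
#' exactly axis-facing C-alpha near the filter, with those contact points
#' staggered evenly in z across helices (opposite helices adjacent in the
#' stagger); this makes the analytic envelope radius an accurate ground
#' truth for the computed profile.
#'
#' @param n_helices Total helix count (default 12; must be even).
#' @param n_residues Residues per helix.
#' @param filter_radius Analytic pore radius at the filter (A) in the open
#'   state.
#' @param mouth_radius Analytic pore radius at the mouths (A).
#' @param filter_halfwidth Half-width of the flat filter plateau (A).
#' @param backing_offset Extra radial distance of the outer ring (A).
#' @param displaced_helices Indices (into the pore-lining ring, 1..6) of the
#'   helices displaced in the closed state.
#' @param delta_r Inward radial displacement in the closed state (A).
#' @param delta_theta Azimuthal rotation of displaced helices (degrees).
#' @param reporter_resname Residue name given to reporter residues
#'   (`"ALA"` emits an explicit C-beta; glycine reporters use the virtual
#'   construction downstream).
#' @return A list of class `plx_channel_spec`.
#' @export
channel_spec <- function(n_helices = 12, n_residues = 27,
                         filter_radius = 2.5, mouth_radius = 7,
                         filter_halfwidth = 3, backing_offset = 4,
                         displaced_helices = c(1, 3, 5), delta_r = 1.8,
                         delta_theta = 0, reporter_resname = "ALA") {
  stopifnot(n_helices %% 2 == 0, n_helices >= 4, filter_radius > 0,
            mouth_radius >= filter_radius)
  structure(list(n_helices = as.integer(n_helices),
                 n_residues = as.integer(n_residues),
                 filter_radius = filter_radius, mouth_radius = mouth_radius,
                 filter_halfwidth = filter_halfwidth,
                 backing_offset = backing_offset,
                 displaced_helices = as.integer(displaced_helices),
                 delta_r = delta_r, delta_theta = delta_theta,
                 reporter_resname = reporter_resname),
            class = "plx_channel_spec")
}

# Envelope reach of the stylised helix: the largest per-class cylinder
# radius plus that class's vdW radius. With a glycine backbone the C-alpha
# class binds (2.3 + 1.85 A).
helix_reach <- function(radius_table = default_radius_table()) {
  lat <- helix_lattice()
  max(lat$r + atom_radii(tibble(element = lat$element), radius_table))
}

# Piecewise-linear inner-ring radius: rho(z) = truth(z) + reach.
channel_rho <- function(spec, reach) {
  hw <- spec$filter_halfwidth
  zmax <- (spec$n_residues - 1) * 1.5 / 2 + 3
  ctrl_z <- c(-zmax, -hw, hw, zmax)
  ctrl_r <- c(spec$mouth_radius, spec$filter_radius, spec$filter_radius,
              spec$mouth_radius) + reach
  function(z) approx(ctrl_z, ctrl_r, xout = pmin(pmax(z, -zmax), zmax),
                     rule = 2)$y
}

#' Build a synthetic channel in one conformational state
#'
#' Places the helices of a [channel_spec()] around the z axis and returns the
#' structure with its analytic ground truth attached: the envelope pore
#' radius profile, the analytic filter minimum, and exact C-beta--C-beta
#' distances for the reporter residue pairs.
#'
#' @param spec A [channel_spec()].
#' @param state `"open"` or `"closed"`.
#' @param radius_table Radius table used for the analytic envelope (must
#'   match the one later used for profiling).
#' @return Atom tibble (single frame) with attribute `truth`: a list with
#'   `state`, `reach`, `profile` (tibble `z`, `radius`), `min_radius`,
#'   `z_filter`, `reporters` (tibble with exact distances), and `segments`
#'   (a [segment_map()] with the membrane window).
#' @export
make_channel <- function(spec = channel_spec(), state = c("open", "closed"),
                         radius_table = default_radius_table()) {
  state <- match.arg(state)
  reach <- helix_reach(radius_table)
  rho <- channel_rho(spec, reach)
  nh <- spec$n_helices
  n_inner <- nh %/% 2
  theta_inner <- (seq_len(n_inner) - 1) * 360 / n_inner
  theta_outer <- theta_inner + 360 / nh

  # stagger of exact axis-facing C-alpha contacts: period (360/twist)*rise
  # in z, split evenly over opposite helix PAIRS. Opposite helices share an
  # offset, so each contact plane is pinned from both sides (the probe
  # cannot slide away from a one-sided contact) and the bundle carries no
  # z-dipole that would tilt the auto-detected principal axis.
  twist <- 100; rise <- 1.5
  period <- 360 / twist * rise                      # 5.4 A
  n_pairs <- n_inner %/% 2
  o_pair <- (seq_len(n_pairs) - (n_pairs + 1) / 2) * period / n_pairs
  o_k <- o_pair[((seq_len(n_inner) - 1) %% n_pairs) + 1]

  i_mid <- ceiling(spec$n_residues / 2)
  hspec <- helix_spec(n_residues = spec$n_residues, rise = rise,
                      twist = twist, sequence = "GLY")

  displaced <- if (state == "closed") spec$displaced_helices else integer(0)

  helices <- vector("list", nh)
  for (k in seq_len(nh)) {
    inner <- k <= n_inner
    theta <- if (inner) theta_inner[k] else theta_outer[k - n_inner]
    is_disp <- inner && (k %in% displaced)
    if (is_disp) theta <- theta + spec$delta_theta
    # z placement: residue i_mid sits at the pair's stagger offset (inner)
    z_mid <- if (inner) o_k[k] else 0
    z0 <- z_mid - (i_mid - 1) * rise
    # self-phase: residue i_mid's C-alpha faces the channel axis exactly
    phi0 <- (theta + 180) - (i_mid - 1) * twist
    h <- make_helix(hspec, chain = LETTERS[k], phi0 = phi0, z0 = z0)
    # radial placement: shift each atom outward by the ring radius at its z
    roff <- if (inner) rho(h$z) else rho(h$z) + spec$backing_offset
    if (is_disp) roff <- roff - spec$delta_r
    th <- theta * pi / 180
    h$x <- h$x + roff * cos(th)
    h$y <- h$y + roff * sin(th)
    helices[[k]] <- h
  }
  out <- list_rbind(helices)
  out$serial <- seq_len(nrow(out))

  # overlap guard: helix axes closer than twice the C-alpha envelope
  check_helix_overlap(spec, state, rho)

  # reporter residues: substitutions on selected helices (mouth region) plus
  # one glycine pair across the filter (virtual C-beta downstream)
  rep_def <- tibble(
    id = c("adjacent-mouth", "across-mouth", "across-filter"),
    chain_a = c("A", "A", "A"), resno_a = c(3L, 3L, i_mid),
    chain_b = c("B", "D", "D"), resno_b = c(3L, 3L, i_mid))
  sub <- rep_def %>%
    tidyr::pivot_longer(cols = c("chain_a", "chain_b", "resno_a", "resno_b"),
                        names_to = c(".value", "side"), names_sep = "_") %>%
    distinct(.data$chain, .data$resno) %>%
    filter(.data$resno != i_mid)          # filter reporters stay glycine
  for (j in seq_len(nrow(sub))) {
    idx <- out$chain == sub$chain[j] & out$resno == sub$resno[j]
    out$resname[idx] <- spec$reporter_resname
    if (spec$reporter_resname != "GLY") {
      res <- out[idx, ]
      p <- virtual_cbeta(
        unlist(res[res$atom == "N", c("x", "y", "z")]),
        unlist(res[res$atom == "CA", c("x", "y", "z")]),
        unlist(res[res$atom == "C", c("x", "y", "z")]))
      out <- dplyr::bind_rows(out, tibble(
        frame = 1L, serial = max(out$serial) + 1L, atom = "CB", altloc = "",
        resname = spec$reporter_resname, chain = sub$chain[j],
        resno = sub$resno[j], x = p[1], y = p[2], z = p[3],
        occupancy = 1, element = "C"))
    }
  }
  out <- arrange(out, .data$chain, .data$resno,
                 match(.data$atom, c("N", "CA", "C", "O", "CB")))
  out$serial <- seq_len(nrow(out))

  # analytic truth
  zg <- seq(-spec$filter_halfwidth - 6, spec$filter_halfwidth + 6, by = 0.25)
  open_truth <- rho(zg) - reach
  truth_profile <- if (state == "open") {
    tibble(z = zg, radius = open_truth)
  } else {
    tibble(z = zg, radius = pmin(open_truth, rho(zg) - spec$delta_r - reach))
  }
  reporters <- exact_reporter_distances(out, rep_def)
  zspan <- (spec$n_residues - 1) * 1.5 / 2
  truth <- list(
    state = state, reach = reach,
    profile = truth_profile,
    min_radius = min(truth_profile$radius),
    z_filter = 0,
    reporters = reporters,
    segments = segment_map(
      pore_lining = data.frame(chain = LETTERS[seq_len(n_inner)],
                               start = 1, end = spec$n_residues),
      membrane_z = c(-min(10, zspan - 2), min(10, zspan - 2))))
  attr(out, "truth") <- truth
  out
}

check_helix_overlap <- function(spec, state, rho) {
  n_inner <- spec$n_helices %/% 2
  zs <- seq(-spec$filter_halfwidth, spec$filter_halfwidth, by = 1)
  th_in <- (seq_len(n_inner) - 1) * 360 / n_inner
  disp <- if (state == "closed") spec$displaced_helices else integer(0)
  for (z in zs) {
    r <- rep(rho(z), n_inner)
    r[disp] <- r[disp] - spec$delta_r
    th <- th_in * pi / 180
    pos <- cbind(r * cos(th), r * sin(th))
    d <- as.matrix(stats::dist(pos))
    diag(d) <- Inf
    if (min(d) < 2 * 2.3) {
      abort(sprintf(
        "helix axes come within %.2f A (< %.1f A envelope contact) at z = %.1f: channel spec produces overlapping helices",
        min(d), 2 * 2.3, z))
    }
  }
  invisible(TRUE)
}

# Exact reporter C-beta distances straight from the constructed coordinates
# (explicit CB when present, otherwise the virtual construction).
exact_reporter_distances <- function(structure, rep_def) {
  point <- function(chain, resno) {
    res <- structure[structure$chain == chain & structure$resno == resno, ]
    if (any(res$atom == "CB")) {
      unlist(res[res$atom == "CB", c("x", "y", "z")])
    } else {
      virtual_cbeta(
        unlist(res[res$atom == "N", c("x", "y", "z")]),
        unlist(res[res$atom == "CA", c("x", "y", "z")]),
        unlist(res[res$atom == "C", c("x", "y", "z")]))
    }
  }
  rep_def %>%
    mutate(distance = pmap(list(.data$chain_a, .data$resno_a,
                                .data$chain_b, .data$resno_b),
                           function(ca, ra, cb, rb) {
                             vnorm(point(ca, ra) - point(cb, rb))
                           }) %>% unlist())
}

#' Build a stacked-ring test channel
#'
#' Rings of identical atoms centred on the z axis: the simplest geometry with
#' an exact analytic pore radius (`ring_radius - vdw_radius` at each ring
#' plane). Used to validate the profiler against closed-form expectations.
#'
#' @param z Ring axial positions (A).
#' @param ring_radius Ring radius per z (recycled).
#' @param n_atoms Atoms per ring.
#' @param vdw_radius Van der Waals radius assigned to every ring atom; the
#'   matching single-element radius table is attached as attribute
#'   `radius_table`.
#' @return Atom tibble with attributes `truth` (tibble `z`, `radius`) and
#'   `radius_table`.
#' @export
make_ring_channel <- function(z = seq(-8, 8, by = 0.5), ring_radius = 4.5,
                              n_atoms = 24, vdw_radius = 1.5) {
  rr <- rep(ring_radius, length.out = length(z))
  ang <- seq(0, 2 * pi, length.out = n_atoms + 1)[-(n_atoms + 1)]
  rows <- map(seq_along(z), function(i) {
    tibble(frame = 1L, serial = 0L, atom = "CA", altloc = "",
           resname = "RNG", chain = "A", resno = i,
           x = rr[i] * cos(ang), y = rr[i] * sin(ang), z = z[i],
           occupancy = 1, element = "C")
  })
  out <- list_rbind(rows)
  out$serial <- seq_len(nrow(out))
  # exact largest-sphere radius at each ring plane: adjacent rings of a
  # tapering stack can undercut the in-plane ring
  truth_r <- vapply(z, function(z0) {
    min(sqrt((z0 - z)^2 + rr^2)) - vdw_radius
  }, numeric(1))
  attr(out, "truth") <- tibble(z = z, radius = truth_r)
  attr(out, "radius_table") <- tibble(element = "C", radius = vdw_radius)
  out
}

#' Perturb a structure into a multi-frame ensemble
#'
#' Generates reproducible noisy conformer ensembles standing in for MD
#' snapshots. `"iid"` adds isotropic Gaussian noise independently to every
#' atom; `"rigid_helix"` applies a small random rigid motion (rotation about
#' the chain centroid plus translation) per chain and frame, preserving local
#' geometry.
#'
#' @param structure Single-frame atom tibble.
#' @param sigma Noise scale in Angstrom (translation scale for
#'   `"rigid_helix"`; the rotation angle scale is `2 * sigma` degrees).
#' @param n_frames Number of frames to generate.
#' @param seed Integer seed; fixed seeds give bit-identical ensembles.
#' @param mode `"iid"` or `"rigid_helix"`.
#' @return Atom tibble with `n_frames` frames.
#' @export
perturb_ensemble <- function(structure, sigma, n_frames, seed = 1L,
                             mode = c("iid", "rigid_helix")) {
  mode <- match.arg(mode)
  stopifnot(sigma >= 0, n_frames >= 1)
  base <- as_tibble(structure)
  base$frame <- 1L
  with_seed(derive_seed(seed, 421L), {
    frames <- map(seq_len(n_frames), function(f) {
      fr <- base
      fr$frame <- f
      if (sigma > 0) {
        if (mode == "iid") {
          n <- nrow(fr)
          fr$x <- fr$x + rnorm(n, 0, sigma)
          fr$y <- fr$y + rnorm(n, 0, sigma)
          fr$z <- fr$z + rnorm(n, 0, sigma)
        } else {
          for (ch in unique(fr$chain)) {
            idx <- fr$chain == ch
            xyz <- coords_mat(fr[idx, ])
            ctr <- colMeans(xyz)
            ax <- unit(rnorm(3))
            ang <- rnorm(1, 0, 2 * sigma * pi / 180)
            R <- rotation_about(ax, ang)
            shift <- rnorm(3, 0, sigma)
            new <- sweep(sweep(xyz, 2, ctr) %*% R, 2, ctr + shift, "+")
            fr$x[idx] <- new[, 1]; fr$y[idx] <- new[, 2]; fr$z[idx] <- new[, 3]
          }
        }
      }
      fr
    })
    list_rbind(frames)
  })
}

rotation_about <- function(axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Simulate a cross-linking observation table from ground truth
#'
#' Applies the package's span-compatibility classification to the
#' ground-truth distances of a two-state conformer mixture and emits a
#' (pair, reagent) outcome table, optionally corrupted by symmetric label
#' noise: with probability `error_rate` a pair's observed aggregate outcome
#' is flipped (cross-linking pairs lose all cross-linking; non-cross-linking
#' pairs gain a full outcome for the longest reagent), so the number of
#' discordant pairs is Binomial(n_pairs, error_rate).
#'
#' @param truth_distances Tibble with columns `id`, `state`, `mean` (A)
#'   giving ground-truth distances per conformational state (a `min` column
#'   is optional and defaults to `mean`).
#' @param panel Reagent panel from [reagent_panel()].
#' @param state_mix Fraction of the ensemble in the first state; states with
#'   zero weight are absent and cannot be captured by the reagents.
#' @param error_rate Pair-level label-noise probability.
#' @param seed Integer seed.
#' @param ... Passed to [classify_crosslink()] (tolerances, d_ss).
#' @return Observation tibble (`id`, `reagent`, `observed`) with attribute
#'   `truth_calls` (the noise-free per-state calls).
#' @export
simulate_observations <- function(truth_distances, panel = reagent_panel(),
                                  state_mix = 0.5, error_rate = 0,
                                  seed = 1L, ...) {
  stopifnot(state_mix >= 0, state_mix <= 1,
            error_rate >= 0, error_rate <= 1)
  td <- as_tibble(truth_distances)
  if (!"min" %in% names(td)) td$min <- td$mean
  states <- unique(td$state)
  present <- states
  if (length(states) == 2) {
    w <- c(state_mix, 1 - state_mix)
    present <- states[w > 0]
  }
  calls <- classify_crosslink(filter(td, .data$state %in% present),
                              panel, ...)
  obs <- calls %>%
    group_by(.data$id, .data$reagent) %>%
    summarise(call = .data$call[which.max(call_rank(.data$call))],
              .groups = "drop") %>%
    mutate(observed = dplyr::case_when(
      .data$call %in% c("spontaneous_disulfide", "bridgeable_full") ~ "full",
      .data$call == "bridgeable_partial" ~ "partial",
      TRUE ~ "none"))

  if (error_rate > 0) {
    pan <- filter(as_tibble(panel), !.data$monofunctional)
    longest <- pan$reagent[which.max(pan$span_max)]
    ids <- unique(obs$id)
    with_seed(derive_seed(seed, 77L), {
      flip <- runif(length(ids)) < error_rate
    })
    for (pid in ids[flip]) {
      rows <- obs$id == pid
      if (any(obs$observed[rows] != "none")) {
        obs$observed[rows] <- "none"
      } else {
        obs$observed[rows & obs$reagent == longest] <- "full"
      }
    }
  }
  out <- select(obs, "id", "reagent", "observed")
  attr(out, "truth_calls") <- calls
  out
}
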