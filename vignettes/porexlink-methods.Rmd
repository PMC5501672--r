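---
title: "Methods: pore profiling, cross-link compatibility, and ensemble comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore profiling, cross-link compatibility, and ensemble comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porexlink)
```

porexlink implements the computational side of a common validation strategy
for competing conformational models of an ion channel (the motivating system
is CFTR, an ABC-family chloride channel with outward-facing/conducting and
inward-facing/non-conducting states): profile the pore geometry of each
model, measure inter-residue distances over a conformer ensemble, translate
cross-linker chemistry into distance windows, and reconcile the predicted
bridging outcomes with cysteine cross-linking experiments. This vignette
records the models, the tunable parameters, and the design decisions behind
each stage.

## Pore radius profiling

The pore radius at an axial position $z_0$ is defined as the radius of the
largest probe sphere centred in the plane $z = z_0$ that overlaps no atom:

$$R_\mathrm{pore}(z_0) = \max_{p \,\in\, \Pi(z_0)} \; \min_i \left( \lVert p - x_i \rVert - r_i \right),$$

where $x_i$ are atom centres, $r_i$ their van der Waals radii, and $\Pi(z_0)$
the slice plane. This is the classic HOLE-style definition. The inner
minimum (the *clearance* field) is piecewise smooth and 1-Lipschitz; its
in-plane maximum is located by simulated annealing (3 restarts, 250
iterations, Gaussian proposals of 0.4 Å, geometric cooling 0.97) followed by
a Nelder–Mead polish. Every random draw comes from a stream derived from a
single user seed, so identical seeds give bit-identical profiles, and
because the polish converges to the local optimum, different seeds agree to
well under 0.05 Å on all test geometries.

Two guards keep the search honest:

* **Trust region** (`trust_radius`, default 6 Å): the probe centre may move
  at most this far from the slice seed (the previous slice's centre). The
  clearance field grows without bound outside the helix bundle, so an
  unconstrained maximiser would step through the wall gaps and report bulk
  space. The trust region is the formalisation of "stay in the pore".
* **Radius cap** (`r_max_cap`, default 15 Å): a slice whose clearance
  reaches the cap is flagged `capped` and treated as a pore mouth. The
  reported profile is trimmed to the maximal contiguous uncapped run
  containing the membrane window.

The channel axis is either supplied explicitly or auto-detected as the
principal inertial axis of the C-alpha atoms. Auto-detection assumes the
structure is elongated along the pore (true for a transmembrane bundle); for
squat test geometries an explicit axis should be passed. The walk proceeds
from low to high $z$ in `z_step` (default 0.5 Å) increments, each slice
seeded from the previous centre.

Default van der Waals radii are a united-atom style set (C 1.85, N 1.75,
O 1.65, S 2.00, P 1.90, H 1.00 Å); hydrogens are excluded by default, their
bulk being absorbed into the heavy-atom radii. The set is overridable via
`read_radius_table()` since published profiling tools differ in their radii.

Ensemble profiles are means over per-frame profiles on a common axis
(resolved once, from the first frame, so all frames share one $z$ grid);
capped slices are excluded from the statistics rather than imputed, and the
spread is reported as a population standard deviation. Conductance calls
compare the minimum mean radius inside a window against the hydrated
chloride radius, ~1.6–1.9 Å: at least 1.9 Å is *open*, below 1.6 Å
*closed*, between the two *marginal*. Whether a channel's reported minimum
should be the ensemble mean or a per-frame minimum is ambiguous in practice;
`ensemble_profile()` retains the per-frame profiles so both are available.

An exhaustive grid search (`slice_radius_grid()`, 0.05 Å grid over the same
trust disc) serves as the reference oracle. It uses a coarse-to-fine scheme
with an atom prefilter that is provably exact: an atom whose clearance
contribution exceeds the coarse maximum plus 1 Å everywhere in the disc can
never bind the optimum (the field is 1-Lipschitz and the coarse grid
underestimates the maximum by at most 0.36 Å).

## C-beta distances

Cross-linking geometry is referenced to the side-chain take-off, so all
inter-residue distances are C-beta–C-beta. Glycine (and any residue with a
missing C-beta but complete backbone) gets a **virtual C-beta** constructed
from N, C-alpha and C with ideal tetrahedral geometry, L-chirality and a
1.53 Å bond; a residue with only a C-alpha falls back to it, flagged, never
silently. Distance series are summarised as mean, population SD (the
sample/population distinction is immaterial at the 100–200 frames these
ensembles carry), minimum and maximum; state labels (OWF/IWF) are user
metadata, never inferred from coordinates. An interface is called stable
when every pair's SD stays at or below 1.5 Å — the operational version of
"small standard deviations mean the dimerised interface holds".

## Cross-linker span model

Bifunctional methanethiosulfonate reagents M$n$M carry an $n$-methylene
spacer. The two published short anchors (M3M ≈ 6.5 Å, M8M ≈ 13 Å) fix the
linear law

$$\mathrm{span}_{\max}(n) = 2.6 + 1.3\,n \;\text{Å},$$

which independently reproduces the long anchor (M17M = 24.7 Å). Spans for
the untabulated reagents (M1M 3.9, M2M 5.2, M5M 9.1 Å) are derived from the
same line and overridable. `span_min` defaults to half the maximal span: a
flexible chain can fold back and bridge closer pairs, at reduced efficiency,
so distances below `span_min` are called *partial* rather than *full*.

Classification of a pair/reagent combination by the ensemble mean distance
$d$:

| call | condition |
|---|---|
| `spontaneous_disulfide` | $d \le 2.1$ Å (direct S–S bond, DMSO-only condition) |
| `bridgeable_full` | $\mathrm{span}_{\min} \le d \le \mathrm{span}_{\max} + 0.2$ Å |
| `bridgeable_partial` | $d < \mathrm{span}_{\min}$ (fold-back) or $d \le \mathrm{span}_{\max} + 0.2$ Å |
| `not_bridgeable` | beyond every window |

The upper tolerances are deliberately tight (0.2 Å, printed-value
rounding): a fully extended linker cannot span farther than its length, and
a pair at 25 Å must stay out of reach of the 24.7 Å reagent. Experimentally,
pairs whose *mean* separation modestly exceeds a span are still sometimes
cross-linked — transient approaches during dynamics bring the cysteines into
range. That effect is a property of the distance *distribution*, not of the
reagent, so it is served by the `use = "min"` mode (classify by the
per-frame minimum) rather than by widening the static windows. This is a
known limitation of any single-threshold rule: no monotone tolerance can
simultaneously reproduce a full cross-link at 0.5 Å over one span and a
failure at 0.3 Å over another; the package keeps the physics clean and
pushes dynamics into `use = "min"`.

Predictions are conformer-resolved: each state is classified separately and
the aggregate per-reagent call is the best across states, annotated with the
supporting state(s). A long reagent can thereby bridge only the closed
conformer of a pair that is too far apart in the open one — exactly the
situation that makes cross-linking informative about which states exist in
the population. Concordance against an observation table is scored at the
pair level ("any reagent predicted bridgeable" vs "any reagent observed to
cross-link"), the level at which the qualitative full/partial boundary on a
western blot does not matter. Monofunctional reagents are carried in
observation tables but excluded from distance-based prediction: their
inhibitory effect is pore blockage, not bridging.

## Structure and ensemble comparison

* **Superposition** is the SVD-based Kabsch solution with the determinant
  correction that forbids reflections; coordinates are unweighted. The test
  suite checks it against an independent quaternion-eigendecomposition
  oracle to 1e-8 Å.
* **Cross-numbering/cross-species comparison** builds a residue
  correspondence by global pairwise sequence alignment (BLOSUM62, affine
  gaps 10/0.5) of the chains' C-alpha sequences, then superposes on the
  mapped C-alpha or backbone atoms.
* **Segment RMSD** reports both `fit_global` (one superposition on all
  mapped atoms, then per-segment RMSD — sensitive to rigid displacement of
  a helix) and `fit_local` (refit per segment — sensitive only to internal
  deformation); `fit_local` is never larger.
* **Equilibration detection** replaces plateau-by-eye with an explicit
  criterion: the earliest frame after which every moving window (default 20
  frames) has absolute linear slope within `slope_tol` and range within
  `range_tol` (default 2 Å, the plateau band one accepts as "no longer
  drifting"). A series that never satisfies this returns `NA`.
* **Clustering** is quality-threshold clustering on the pairwise
  superposed-RMSD matrix (backbone atoms, 2 Å threshold by default):
  repeatedly extract the frame with the most neighbours within the
  threshold together with those neighbours; ties break to the lowest frame
  index, making the partition deterministic. Each cluster's representative
  is its centroid — the member minimising total within-cluster RMSD.
  Pairwise RMSDs are refit per pair by default (`refit = FALSE` gives a
  single-reference gromos-style variant).

## The synthetic channel generator

Because the real system's coordinates are an external download, every stage
is exercised on synthetic helix-bundle channels with analytic ground truth.
The generator emulates the architecture that matters for the computations —
an axial pore through a 12-helix transmembrane bundle, two conformational
states differing by rigid displacement of a helix subset, thermal scatter
around each state, and cross-linking outcome tables derived from the
ground-truth distances:

* **Helices** are stylised alpha-helices: backbone atoms on per-class
  cylinders around the helix axis (C-alpha at 2.3 Å; rise 1.5 Å, twist
  100°), giving consecutive C-alpha distances of 3.8 Å. The default
  sequence is glycine. That choice is deliberate: a C-beta sits ~3.4 Å from
  the helix axis and would overtake the C-alpha lattice as the pore-facing
  envelope, making the documented analytic radius wrong. With a
  backbone-only lattice, the envelope reach is exactly
  $\max_a (r_a^{\mathrm{lattice}} + r_a^{\mathrm{vdW}})$ = 2.3 + 1.85 Å.
  Reporter residues (for distance tests) are alanine substitutions placed
  in the mouth region, where their C-beta cannot perturb the filter.
* **The bundle** places six pore-lining helices on an inner ring whose
  radius follows a piecewise-linear hourglass (flat filter plateau at
  $z=0$), and six backing helices 4 Å farther out. Helix self-phases are
  solved so that each pore-lining helix presents an exactly axis-facing
  C-alpha near the filter; opposite helices share the same contact plane
  (so the probe is pinned from both sides and the bundle carries no
  z-dipole that would tilt the auto-detected axis), and contact planes are
  staggered evenly in $z$ across helix pairs. The analytic truth
  $R(z) = \rho(z) - \mathrm{reach}$ is then exact at the contact planes:
  the computed minimum lands within 0.05 Å of the built 2.5 Å filter
  radius. Between contact planes and near the plateau kinks the discrete
  lattice leaves the bound one-sided, so pointwise agreement is asserted at
  0.1 Å on the plateau interior only — a property of any finite-atom
  realisation of a continuous envelope, not of the profiler.
* **The closed state** displaces three of the six pore-lining helices
  (emulating the helix subset whose rearrangement gates the channel)
  inward by 1.8 Å, taking the analytic envelope minimum to 0.7 Å. Three
  displaced "posts" do not form a complete ring, so the discrete max-ball
  settles slightly above the envelope (~1.0 Å) — still far below the 1.6 Å
  closed threshold, which is what the contrast test asserts.
* **Ensembles** add either i.i.d. Gaussian atomic noise or small rigid
  per-helix motions (preserving local geometry); both are seeded and
  bit-reproducible. **Observation tables** apply the package's own
  classification to the ground-truth distances of a two-state mixture and
  optionally flip each pair's aggregate outcome with probability
  `error_rate`, making the discordant-pair count exactly binomial — the
  closed loop behind the concordance tests.

What the generator does *not* emulate: side chains beyond C-beta, sequence
realism, lipids, solvent, electrostatics, or physically realistic dynamics.
Passing tests therefore demonstrate the correctness of the geometry and
statistics pipeline, not the biological accuracy of any particular channel
model.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately desk-scale conditions chosen
once: 12-helix channels of 27 residues per helix (~1300 atoms), 0.5 Å slice
steps, ensembles of up to 100 frames for clustering, 30 reporter pairs and
200 noise replicates for the concordance loop, 1000 random instances for
the superposition oracle, and 150 planted series for equilibration
detection. Ties break deterministically everywhere (lowest $z$ for profile
minima, lowest frame index for cluster seeds and centroids); degenerate
inputs (coincident atoms, coplanar axes, under-length windows, duplicate
observations) raise informative errors rather than propagating NaNs. All
randomness flows from one integer seed per entry point.

## Known limitations

* The probe walk assumes a single, roughly straight pore; curved or
  branched pathways would need a steerable axis.
* The span model treats the linker as a straight line between C-beta
  atoms; linker conformational sampling is out of scope.
* Mean-distance classification understates bridging for highly dynamic
  pairs (see `use = "min"` above).
* Auto axis detection requires an elongated structure.
* The equilibration criterion is a moving-window heuristic: it formalises
  the plateau-by-eye convention rather than performing statistical
  change-point inference.
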