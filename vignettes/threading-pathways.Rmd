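---
title: "Mapping threading pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping threading pathways: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rotapath maps minimum-energy pathways for supramolecular threading — a
macrocyclic host sliding over the bulky terminus of a dumbbell-shaped guest
to form a rotaxane-like complex — and turns the converged pathway into the
analysis products used in this field: an energy profile along a normalized
displacement coordinate, a four-stage mechanistic segmentation with a
barrier, geometric descriptors of the host–guest arrangement, grid-based
noncovalent-interaction (NCI) maps, and a steric/electrostatic/quantum
energy decomposition. This vignette explains the models, the tunable
parameters, the numerical choices, and what the desk-scale validation does
and does not establish.

## The chain-of-states engine

The path search is a climbing-image nudged elastic band (CI-NEB). A path
between two relaxed endpoint structures is discretized into a chain of
images, linearly interpolated in the full 3N-dimensional configuration
space. Each optimization step:

1. redistributes images to equal arc length (string-method step; see below),
2. evaluates energies and forces from the active potential,
3. forms per-image tangents by the improved-tangent rule — the
   uphill-neighbour difference vector, with an energy-difference-weighted
   blend of both neighbour vectors at local extrema,
4. projects forces: ordinary images feel the true force perpendicular to
   the tangent plus a spring term `k(|d_next| − |d_prev|)` along it; the
   current highest-energy interior image (the climbing image) feels the
   true force with its parallel component inverted and no spring, so it
   ascends to the saddle,
5. takes a damped L-BFGS step.

Convergence requires the largest per-atom effective-force norm over movable
images to fall below `fmax_band` (default 0.1 eV/Å). Because the climbing
image's effective force has the same norm as its true force, a converged
climbing image is a first-order saddle approximation. Endpoints are
relaxed separately to `fmax_endpoint` (default 1e-4 eV/Å) and can be
verified as true minima by finite-difference frequency analysis
(`frequency_check()`), which mass-weights the Hessian and tolerates
near-zero eigenvalues (|λ| < 1e-4 in eV/Å²·amu units) for free
translations, rotations, and the soft inter-fragment modes typical of
weakly bound supramolecular pairs.

Defaults mirror a high-resolution threading protocol: 125 interior images
per segment and a two-segment run over three structures — reactant,
a shared intermediate, product — stitched into a single band (`P_1` …
`P_253` for 127-image segments) with the duplicated junction image dropped.
Per-segment step counts and wall times are reported separately, since the
approach segment typically converges much faster than the assembly segment.

### Optimizer details

The L-BFGS driver is shared by band optimization and structure relaxation
(the chain's effective force is not the gradient of any scalar function, so
a generic scalar minimizer cannot drive it):

* two-loop recursion, history 25, curvature pairs with `s·y ≤ 1e-12`
  skipped (damping);
* the initial inverse-Hessian scale is the Barzilai–Borwein ratio
  `s·y / y·y` of the latest pair. A fixed scale cannot serve both a
  molecular force field (forces ~1 eV/Å) and a stiff analytic benchmark
  (forces ~10³); the adaptive scale handles both without tuning;
* no line search; instead a per-atom displacement cap (default 0.2 Å;
  0.05 Å is a good choice for stiff coarse-grained threading runs). When
  the largest force exceeds 10 eV/Å — an image inside a repulsive wall —
  the cap is tightened by `sqrt(10/max|F|)`, floored at 20 % of its value,
  so the quasi-Newton step cannot punch through the wall yet wall escape
  does not stall.

The string-method redistribution (iterated cubic reparameterization along
cumulative arc length, run to a fixed point so inter-image chords equalise
to 1e-8 relative) is applied during the first ten steps only, before the
climbing image activates. Redistributing every iteration and climbing are
jointly unstable at practical image counts: redistribution keeps moving
images tangentially, the projected force at the reshuffled positions never
falls below the threshold, and the band stalls an order of magnitude above
`fmax_band`. Equilibrating spacing early and then letting the projected
forces relax meets both the spacing and the force contracts.

Divergence is a scientific result, not a crash: the threading model checks
its bonded topology every step (any ring bond stretched past three
equilibrium lengths raises an error labelled `MB`, macrocycle breaking;
axle bonds analogously), and an absolute 10⁶ eV/Å force bound guards
against numerical overflow. Transient forces of 10³–10⁴ eV/Å are *not*
treated as divergence — they occur routinely, and relax away, while a
tight macrocycle squeezes over a bulky terminus.

### Validation surfaces

Three analytic benchmark surfaces with exact gradients are wrapped as
potentials on fictitious atoms: the 1D quartic double well (saddle at 0,
barrier exactly 1), the Müller–Brown surface (standard four-Gaussian
constants), and a LEPS-type surface coupled to a harmonic oscillator (the
standard chain-method test; the plain two-bond LEPS form has no bound
minima, so the oscillator-coupled variant is used). These surfaces are
frame-fixed functions of absolute coordinates — unlike the molecular
models they are deliberately not invariant under rigid motion.

The Müller–Brown saddle oracle never comes from memory: tests flood a
2000×2000 energy grid, bisecting on the level at which the sub-level set
connects the two endpoint basins (connected-component labelling). That
watershed level is the saddle energy; the converged climbing image matches
it to ~2×10⁻⁴ energy units.

## The coarse-grained threading model

The synthetic stand-in for an expensive molecular potential is a bead-
spring model built to reproduce the *structure* of the threading problem,
not its chemistry:

* **host**: a 6-bead ring, equilibrium bond 1.2 Å (cavity radius 1.2 Å),
  harmonic bonds (10 eV/Å²) and angles (2 eV/rad²); every third bead is an
  "oxygen" carrying −0.2 e (the rest +0.1 e; the ring is net-neutral),
  annotated in the `ring_oxygens` group so descriptor code runs unchanged;
* **guest**: a 7-bead axle; bead 1 is the bulky terminus whose
  Lennard-Jones σ (`terminal_radius`, default 1.5 Å) is the steric dial;
  bead 2 is the donor "nitrogen" carrying the declared charge state (0,
  +1 or +2 e);
* **interactions**: host–guest only — Lennard-Jones (ε = 0.02 eV, 12 Å
  energy-shifted cutoff; ring beads are wide, σ = 1.4 Å) plus Coulomb with
  a relative dielectric and no cutoff. Bonded terms are intramolecular, so
  fragment energies are exact and `interaction_energy()` is a clean
  complex-minus-fragments subtraction: at 50 Å separation a neutral pair
  interacts by exactly zero, the initialization-stage check.

Ring beads are wide by design: with slim beads the optimizer discovers a
tilted, bead-by-bead passage over a small terminus that erases the barrier
entirely — a real feature of a slim discrete ring, but not of a macrocycle
with a continuous rim. Wide beads make every passage mode repulsive, so
the barrier grows strictly with `terminal_radius` (109.5, 373.5,
807.0 kJ/mol at 1.5, 2.0, 2.5 Å under the default two-segment protocol —
large numbers, as expected for a stiff model with a deliberately
exaggerated steric series). The charged variants relax into tilted,
claw-like complex minima whose energies decrease strictly with charge
magnitude, mirroring an electrostatically assisted stability series.

The generated endpoints are: `unthreaded` (ring on the axle axis 8 Å
before the terminus), `midpoint` (the pre-barrier contact complex at
−2 Å — the first segment then covers only the approach), and `threaded`
(one axle corrugation pocket past the first post-barrier minimum, so the
final descent exhibits a distinct stabilization stage). A seeded 0.01 Å
jitter breaks exact cylindrical symmetry; all geometry is bit-reproducible
from the seed, which is recorded in run manifests.

## Profiles, stages, barriers, descriptors

The normalized displacement coordinate (NDC) of image *i* is the
cumulative Euclidean inter-image distance over all 3N coordinates divided
by the total path length: `ndc_1 = 0`, `ndc_K = 1`, non-decreasing.
Energies are reported relative to the first image in kJ/mol
(1 eV = 96.4853 kJ/mol). By default distances are taken in raw
configuration space, matching the chain formulation; `align = TRUE`
superposes each image on its predecessor first (Kabsch least-squares with
the proper-rotation constraint) and is recorded in the profile metadata.

The four-stage segmentation formalizes a reading that is usually done by
eye, and is flagged as such in the output:

* **initialization** — the maximal leading run with |ΔE| ≤ `eps_flat`
  (default 1 kJ/mol): host and guest effectively non-interacting;
* **preparation** — from there to the last local minimum before the global
  maximum: attractive approach, ending in the pre-barrier dip;
* **activation** — the ascent-to-descent window around the global maximum,
  bounded exclusively by the flanking local minima;
* **stabilization** — from the first post-barrier minimum to the end.

The flanking minima are assigned to preparation and stabilization rather
than activation on purpose: the barrier is defined as the activation-stage
maximum minus the preparation-stage minimum, so the pre-barrier dip must
close preparation for that arithmetic to mean what it says, and the
post-barrier complex minima belong with the stabilization-stage
rearrangements. Extrema are located on the raw, unsmoothed profile;
plateau ties break toward the lower index. A profile whose global maximum
sits at an endpoint, or that the flatness threshold swallows entirely, has
no barrier and raises an error rather than returning a number.

Three geometric descriptors are computed wherever the needed atom groups
are annotated: the macrocycle-opening descriptor (for each ring oxygen its
maximum distance to any other ring oxygen, averaged over oxygens — one
defensible reading of an "average maximum O–O distance", fixed here and
stated in the docs), the donor–acceptor hydrogen-bond distance (minimum
N⋯O over ring oxygens), and the distance between mass-weighted phenyl-ring
centroids. All are validated against brute-force pairwise oracles at
1e-12.

## Grid NCI on promolecular densities

The NCI analysis detects weak interactions as regions where the reduced
density gradient `s = |∇ρ| / (2(3π²)^{1/3} ρ^{4/3})` falls toward zero at
low density. Self-consistent densities are out of scope; the package uses
the standard download-free surrogate, a promolecular superposition of
spherical exponential-shell atom densities `ρ_A(r) = Σ c_k e^{−r/ζ_k}`
(H, C, N, O). Shell coefficients are normalised analytically
(`c_k = N_k / 8πζ_k³`), so every atom integrates to its neutral electron
count exactly; hydrogen is the exact hydrogenic density `e^{−2r}/π`.
Core decay lengths follow screened-nuclear-charge estimates; valence
decay lengths are scaled by 1.3 to emulate the flatter interstitial tails
of fitted free-atom densities — without that, the low-`s` disc of a
hydrogen bond is thinner than one 0.1 Å voxel and an axis-aligned grid
can miss it entirely. For the same reason the packaged water-dimer
fixture is generated in a generic, non-axis-aligned orientation.

Gradients and Hessians of the density are analytic; the signed density
`sign(λ₂)·ρ` takes λ₂ from a vectorised closed-form symmetric 3×3
eigensolver (verified against `eigen()` pointwise). `nci_summary()`
extracts connected components (6-neighbour) of grid points with
`s < iso_s` (default 0.3, the conventional choice; configurable) inside a
density window (default 10⁻³–0.05 a.u.), labels each basin inter- or
intramolecular from the two atoms nearest its most attractive voxel, and
returns a tibble sorted by basin volume. Everything is in atomic units
internally (1 Å = 1.8897261254578281 bohr); fields write to standard
Gaussian cube files.

## Energy decomposition

The decomposition partitions a supplied total energy as
`E_t = E_s + E_e + E_q`:

* `E_s` — the Weizsäcker functional `(1/8)∫|∇ρ|²/ρ dr` by midpoint
  quadrature; exact for one-orbital densities (the hydrogenic fixture
  integrates to 0.4999 hartree vs the exact 0.5);
* `E_e` — the classical Coulomb self-repulsion `½∬ρρ'/|r−r'|` by a direct
  O(M²) cell sum. The singular same-cell pair is replaced by its analytic
  mean: ⟨1/r⟩ for two points uniform in the same cubic cell is
  1.88231264/h, which removes the divergence with an O(h²) error. Grids
  beyond 64³ points are refused unless down-sampling is requested;
* `E_q` — defined as the remainder `E_t − E_s − E_e`. In pipeline use
  `E_t` comes from the active potential model converted to hartree. This
  is a consistent convention, not a reconstruction of the exchange–
  correlation and charge-transfer content a self-consistent quantum
  calculation would give; the sum identity is exact by construction
  (to double-precision rounding) and deltas against a reference image
  (conventionally `P_1`) are the meaningful quantities.

A known limitation: heavy-atom core spikes (decay ~0.065 bohr) are
sub-voxel at any practical grid spacing, so *absolute* `E_s` values for
C/N/O-containing systems carry a quadrature error that shifts with the
grid offset (about 20 % under an arbitrary rigid rotation). Differences
between images evaluated on a common grid are far better behaved, and the
rotation-invariance property is tight (1 %) on hydrogen densities, whose
cores the grid resolves.

## Reproducibility and scale

Every stochastic element (endpoint jitter, test geometries) derives from
an explicit integer seed; solvers are deterministic, so identical
configuration plus seed reproduces bands, profiles and fixtures
bit-exactly — this is itself an acceptance check. Output directories carry
a manifest (config hash, seed, versions) and all writers are atomic
(temp-file-then-rename).

The validation suite runs at desk scale by choice: 11–25 interior images
on analytic surfaces and the coarse-grained model, 127-image segments only
for the stitching contract, 0.1 Å NCI grids on six-atom fixtures, and a
2000×2000 oracle grid. Passing it establishes that the engine finds true
saddles on nontrivial surfaces, that the analysis layer reproduces
closed-form and brute-force oracles, and that the threading model recovers
the expected steric and electrostatic orderings. It does not establish
chemical accuracy for any real rotaxane: that requires an external
quantum-quality calculator plugged in through `external_adapter()`, and
the coarse-grained barriers (hundreds of kJ/mol for an exaggerated steric
series) are not comparable to experimental activation energies. Solvent,
temperature and free-energy effects are out of scope throughout.

## A worked sketch

```{r, eval = FALSE}
library(rotapath)

tm <- build_threading_model(threading_config(terminal_radius = 2.0))
a <- optimize_structure(tm$endpoints$unthreaded, tm$model, fmax = 1e-4)
m <- optimize_structure(tm$endpoints$midpoint,   tm$model, fmax = 1e-4)
b <- optimize_structure(tm$endpoints$threaded,   tm$model, fmax = 1e-4)

band <- run_two_segment(a, m, b, tm$model,
                        neb_config(n_images = 25, max_step = 0.05))
profile <- build_profile(band)
glance(profile)          # barrier, stage boundaries
autoplot(profile)        # energy vs NDC, coloured by stage

basins <- nci_summary(generate_fixture("water_dimer"))
```
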