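---
title: "Methods: quantifying ice nucleation at monolayer-coated water interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ice nucleation at monolayer-coated water interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slabice)
```

slabice implements the analysis layer used to study heterogeneous ice
nucleation at surfactant-coated water interfaces: droplet-freezing-assay
statistics under the singular model, detection and spatial profiling of
pre-critical ice nuclei in slab simulations, topological classification of
water cages, and interfacial thermodynamic and orientational order metrics.
This vignette records the models, the tunable parameters, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## Units and geometry conventions

All lengths are in angstrom, times in ps, temperatures in K (assay
temperatures in degrees Celsius, since cold-stage instruments report them
that way), pressures in bar, surface tensions in mN/m.  Conversions happen
only at I/O boundaries: GRO files store nm, and the pressure-to-tension
integral uses 1 bar A = 0.01 mN/m.

Boxes are orthorhombic only; triclinic input is rejected at the parser.
Slabs follow the convention that `z` is the non-periodic interface normal,
stored explicitly as per-axis periodicity flags `(TRUE, TRUE, FALSE)` rather
than implied.  Minimum-image displacements respect those flags, so the same
code handles fully periodic lattices (`(T, T, T)`) and open clusters
(`(F, F, F)`).

## Droplet-freezing statistics (singular model)

A cold-stage assay cools `n` droplets (default 96) from 0 to -30 C at
1 K/min.  Under the singular (site-specific) interpretation, each droplet
carries a Poisson number of active sites with cumulative mean
$\lambda(T) = X \, n_{\mathrm{mol}}(T)$, where $X$ is the number of
substrate molecules per droplet, and freezes at the characteristic
temperature of its most active site.  The observables are

* fraction frozen $f(T)$ — droplets frozen at or above $T$, with censored
  (never-frozen) droplets kept in the denominator, the standard cold-stage
  convention;
* cumulative nucleation sites per substrate molecule
  $n_{\mathrm{mol}}(T) = -\ln(1 - f(T)) / X$.

Grid points where $f = 1$ are undefined under this model and are reported
as `NA` and flagged, never as infinities.

Confidence bands follow the Poisson Monte-Carlo recipe: the data are
binned into 0.5 K intervals, the observed event count in each interval is
taken as the Poisson expectation, 1000 replicate event tables are drawn,
accumulated into replicate $n_{\mathrm{mol}}$ curves, and the band is the
10th-90th percentile range per grid point.  The seed is recorded in every
result.

Two properties of this construction are worth stating plainly, because the
test suite asserts them:

* On a single bin with $k$ observed events the replicate percentiles
  converge to the analytic Poisson quantiles (for $k = 4$: 2 and 7).
* For cumulative curves the band is *conservative*: it resamples around
  the observed counts (adding the sampling variance of $k$ itself on top
  of the replicate variance), and the true cumulative frozen count is
  Binomial with variance below Poisson at moderate-to-high $f$.  Measured
  on simulated assays, the 10-90 band covers the generating site density
  at well above its nominal 80% of grid points.  The suite therefore
  checks that the band attains *at least* nominal coverage; a two-sided
  "exactly 80%" check is analytically unattainable for cumulative curves
  under this band construction.

Background subtraction operates on the differential (per-bin) site
spectra — subtract, floor at zero, re-accumulate — because subtraction of
cumulative curves is otherwise ill-defined; bins dominated by background
are flagged.  Both curves must share a grid and a normalisation; the band
is not propagated through subtraction.

### Simulator

`simulate_freezing_assay()` draws per-droplet, per-interval Poisson site
increments from a prescribed cumulative site density plus an optional
per-droplet background, on the measurement grid (not continuous time).
By construction $f(T) = 1 - \exp(-\lambda(T))$ in expectation, and the
output depends only on $\lambda$, so doubling $X$ while halving the site
density leaves results bit-identical — the rescaling symmetry the tests
assert.  The recovery studies use a site density rising linearly from zero
at -5 C to $\lambda = 4$ at -30 C with $X = 10^{15}$, so that ~94 of 96
droplets freeze and $f < 1$ over nearly the whole grid, mirroring the
shape of a real cold-stage curve while keeping $n_{\mathrm{mol}}$ defined.

## Steinhardt order parameters and ice classification

Each water molecule is represented by its oxygen; hydrogens are ignored
for order parameters.  On the O-O neighbour graph (inclusive cutoff,
default 3.5 A — the first minimum of the water O-O correlation),

$$q_{lm}(i) = \frac{1}{N_b(i)} \sum_{j \in N(i)} Y_{lm}(\hat r_{ij}),
\qquad
q_l(i) = \sqrt{\frac{4\pi}{2l+1} \sum_{m=-l}^{l} |q_{lm}(i)|^2}.$$

Only $m \ge 0$ is stored; the negative orders follow from
$Y_{l,-m} = (-1)^m \overline{Y_{lm}}$, a linear relation that survives
neighbourhood averaging.  Molecules with no neighbours are flagged
undefined, never silently zero.  The classifier is the locally averaged
variant: coefficient vectors are averaged over $\{i\} \cup N(i)$ before
the modulus, which sharpens the ice/liquid separation; it is not
idempotent, and every result carries a `variant` tag (`"q"` vs `"qbar"`)
so plain and averaged values are never conflated.  This thresholded
locally-averaged $\bar q_6$ is this package's classifier, standing in for
kernel-based local-environment classifiers used elsewhere in the
literature whose exact parameterisation is not reproduced here.

Two numerical facts drive the classification design:

* A molecule with a single bond has $q_l = 1$ for every $l$ (the
  spherical-harmonic addition theorem), so under-coordinated molecules at
  slab surfaces would trivially exceed any threshold.  Ice labels
  therefore additionally require a complete first shell
  (`min_neighbors = 4` by default).
* `calibrate_threshold()` places the cut midway between the 1st
  percentile of an ice fixture's distribution and the 99th percentile of
  a liquid fixture's (after the same coordination gate), and refuses to
  calibrate if they overlap.  The shipped calibration fixtures are a
  thermally noised lattice (Gaussian displacement sigma 0.12 A) and a
  generated liquid slab; at cutoff 3.5 A this yields thresholds near
  0.43.

$q_l$ is invariant under global rotations, rigid translations (with
periodic re-wrap) and atom relabelling; the suite checks rotation
invariance to 1e-8 against independently generated rotation matrices, and
checks $q_6$ on ideal lattices against independently computed
spherical-harmonic sums (tetrahedral first shell: 0.6285393610547;
fcc 12-neighbour shell: 0.5745242597141).

## Nuclei, COM-z profiles, cages

Ice nuclei are connected components of the neighbour graph restricted to
ice-like molecules; the largest is selected with ties broken by smallest
member index (deterministic and order-independent).  The centre of mass
of a nucleus unwraps members along periodic axes relative to a seed
member before averaging, so clusters straddling the xy boundary are
handled; `z` is taken raw on the non-periodic axis.

The spatial profile `P(COM_z)` histograms largest-nucleus COM positions,
by default folding the two equivalent interfaces onto each other about
the slab midplane.  The density is normalised so its mean over a bulk
baseline window equals one, and shifted so the peak bin inside the
interface window sits at zero.  Defaults: 0.5 A bins; baseline and
interface windows are explicit arguments, since they depend on slab
geometry.  The interfacial enhancement is the mean normalised density
over the interface window; a flat profile gives 1 by construction.  One
practical caution the acceptance work surfaced: the interface window must
match the support of the interfacial population — padding it with empty
bins beyond the slab edge dilutes the window mean and biases the ratio
low.

Rings are all primitive six-membered cycles (primitive: no pair of ring
members is connected by a shorter path through the graph than along the
ring).  Cages are detected topologically on the ring set:

* **HC** (hexagonal cage, the building block of hexagonal ice): two
  vertex-disjoint primitive 6-rings whose inter-ring bonds are exactly
  three, form a matching, and attach to alternating members of each ring.
* **DDC** (double-diamond cage, the building block of cubic ice): an
  equatorial primitive 6-ring plus two caps, each cap being three bridge
  molecules bonded to alternating ring members and to one shared apex —
  14 molecules, two fused adamantane-like halves.

A note on an alternative HC formulation ("two rings joined by a perfect
matching of six inter-ring bonds"): that motif is impossible in any
girth-6 graph — a 6-edge matching between two 6-rings always closes a
4- or 5-cycle — and both ice networks have girth 6, so the
three-bond alternating form above is the one with the correct fixed
points (ideal hexagonal ice contains HCs and no DDCs; ideal cubic ice the
reverse).  On wrap-free supercells the detector finds 16 primitive rings
and 16 DDCs per 8-oxygen conventional cell of cubic ice, and 16 rings and
4 HCs per 8-oxygen orthorhombic cell of hexagonal ice, constants the
tests pin against independent exhaustive pattern searches.  Supercells
must be large enough that no six-bond walk wraps the periodic box
(cubic >= 2x2x2 cells, hexagonal >= 4x2x2 orthorhombic cells); smaller
boxes create spurious periodic-image cycles.

## Interfacial thermodynamics and orientation

Surface tension from a pressure-tensor trace of a two-interface slab:

$$\gamma = \frac{L_z}{2} \left( \langle P_{zz} \rangle -
\frac{\langle P_{xx} \rangle + \langle P_{yy} \rangle}{2} \right),$$

with block-averaged standard errors (5 contiguous blocks by default; the
literature gives no single error rule, and block averaging is the field
standard for correlated series).  Surface pressure of the coated
interface is $\pi = \gamma_{\mathrm{wv}} - 2\gamma$, the factor two
counting the two coated interfaces of the slab; the clean-interface
reference defaults to $\gamma_{\mathrm{wv}} = 80.1$ mN/m (the TIP4P/Ice
value at ambient conditions) and is overridable.  Every emitted result
carries both $\gamma$ and $\pi$, so the identity holds by construction.
The area per molecule is $L_x L_y / n_{\mathrm{leaflet}}$.

Orientations are measured per leaflet so the two interfaces superpose
onto one distribution: the surrogate-cholesterol tilt is the angle
between the molecular axis (tail carbon C25 to head carbon C3) and the
leaflet's water-ward normal, making an upright molecule 0 degrees and an
in-plane one 90; dipole vectors (water O to H-midpoint bisector;
hydroxyl O to H) are measured against the outward normal of the nearer
interface.  Orientation densities are per-degree and integrate to one;
the default mode has no solid-angle correction (the shape convention of
interfacial orientation plots), and a tagged `jacobian = "sin"` mode
divides by $\sin\theta$, under which isotropic orientations are flat.
Interfacial water is any water whose oxygen lies within 7 A (inclusive,
minimum image) of a surrogate hydroxyl oxygen; selections are nested and
stable for cutoffs of roughly 5-10 A.

## Synthetic data: what it emulates, what it does not

Every generator is a pure function of its seed, restores the caller's RNG
state, and emits planted ground truth alongside the data.

* `build_ice_lattice()` — ideal oxygen sublattices of cubic and hexagonal
  ice built on an O-O distance of 2.75 A (standard ice geometry), with
  optional Gaussian thermal noise, and optional ice-rule proton
  decoration: every O-O contact is oriented (donor carries the H), then
  randomised repair passes run until every oxygen donates exactly twice.
  The repair is restarted with a fresh orientation if it stalls; the
  decoration errors out if noise has broken the 4-regular contact graph.
  Hydrogens sit 0.9572 A along the bond; intramolecular H-O-H geometry is
  not that of a rigid water model, which is irrelevant downstream because
  order parameters use oxygens only.
* `build_liquid_slab()` — random sequential insertion of rigid, randomly
  oriented waters with a pairwise O-O floor (default 2.5 A) under xy
  periodicity.  This is a structureless stand-in for liquid water: it has
  no hydrogen-bond network, its coordination statistics are Poissonian
  rather than tetrahedral, and its density is capped by the insertion
  process well below experimental water.  It is deliberately *easier* to
  tell apart from ice than real supercooled water is, so a passing
  classification test shows the machinery separates planted order from
  disorder — not that the threshold transfers to a real TIP4P/Ice
  trajectory, where it would need recalibration on real fixtures.
* `build_monolayer_slab()` — two leaflets of two-site rods with hydroxyl
  heads toward the water, at in-plane edge
  $\sqrt{n_{\mathrm{chl}} S_A/\mathrm{mol}}$ (64 molecules per leaflet at
  70 A^2 per molecule give the ~67 A box of the reference setup), heads
  3 A off the water surface, axis polar angles drawn from a wrapped
  Gaussian cone about the prescribed tilt (concentration kappa;
  `Inf` is deterministic).  A rod is not a sterol: only the C25-to-C3 axis
  and the hydroxyl positions are meaningful downstream.
* `plant_nuclei_trajectory()` — each frame embeds a randomly rotated
  compact cluster carved from ideal cubic ice into the base slab at a z
  drawn from a prescribed density, removing overlapping waters.  Because a
  trajectory requires a constant atom count, every frame removes the same
  total number of waters, padding with randomly chosen far-from-nucleus
  molecules (a two-pass construction).  Planted member ids and COM
  positions are returned as ground truth.
* `generate_pressure_trace()` — i.i.d. Gaussian diagonal pressure
  components with the analytic $\gamma$ implied by the means attached; no
  autocorrelation, so block-averaged errors are exact rather than merely
  asymptotic.
* `simulate_freezing_assay()` — described above.

## Problem sizes and numerical choices in the shipped suite

The test-suite and acceptance-script sizes are chosen so the whole suite
runs in a couple of minutes on one CPU while keeping every statistical
assertion inside pre-stated tolerance bands derived from planted-count
sampling errors (3-sigma unless noted):

* profile recovery: a 520-water slab (22 x 22 x 72 A, water z 6-66 A),
  36-molecule nuclei, 400 frames, planted 10:1 interface:bulk density;
* classification fixtures: 64-molecule noisy lattices (sigma 0.12 A)
  against 420-water liquid slabs;
* cage counting: cubic 2x2x2 (64 oxygens) and hexagonal 4x2x2
  (128 oxygens) supercells, plus one larger cell per polytype for the
  per-cell-constancy check;
* assay statistics: 96 droplets, 0 to -30 C, 0.5 K bins, 1000 Monte-Carlo
  draws (20000 where percentile convergence to analytic quantiles is
  asserted), a few hundred replicate assays for coverage;
* surface tension: 200 independent traces of 1500 samples for the
  unbiasedness check.

Ties at cutoffs are kept (inclusive conventions throughout).  Degenerate
inputs fail loudly: empty configurations cannot be written, empty nuclei
have no COM, empty baseline windows cannot normalise a profile, and
saturated assay bins are flagged rather than propagated as infinities.

## Known limitations

* The liquid generator's lack of hydrogen-bond structure means
  classification thresholds calibrated on it are specific to synthetic
  fixtures (see above).
* Cage detection is topological only; no geometric (angle or planarity)
  filters are applied, which is the appropriate convention for ideal and
  mildly perturbed networks but will over-count in strongly distorted
  ones.
* The background-subtraction convention (differential spectra, floored at
  zero) introduces a small positive bias in the re-accumulated curve when
  the background is comparable to the signal; affected bins are flagged.
* Binary trajectory formats (XTC/TRR/DCD), velocities, triclinic cells
  and force-field energetics are out of scope.
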