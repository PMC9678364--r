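---
title: "Mechanochemical simulation of actomyosin rings and clusters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanochemical simulation of actomyosin rings and clusters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actoring)
```

# The scientific problem

Confined networks of treadmilling actin filaments and non-muscle myosin II
(NMII) motors adopt qualitatively different architectures depending on how
fast the filaments turn over.  When treadmilling is slow, motor-driven
contraction wins and the network collapses centripetally into dense
clusters; when treadmilling is fast, filaments continuously escape the
contractile traps, accumulate at the confinement boundary, and condense
into a peripheral ring (or, in spherical volumes, a cortex-like shell) —
the geometry of the actin ring at the immune synapse of activated T cells.
`actoring` implements a desk-scale mechanochemical simulation of this
tug of war, together with the quantification pipeline used to classify the
resulting morphologies, so that the ring-versus-cluster phase behavior can
be reproduced and probed with modest hardware.

The simulation couples three layers, iterated in a fixed protocol:

1. **Stochastic chemistry.** All reactions are propagated exactly with the
   Next Reaction Method (NRM), a variant of the Gillespie algorithm that
   assigns each channel an absolute firing time `t + Exp(1)/a` and rescales
   pending times when propensities change.
2. **Quasi-static mechanics.** After every chemistry window (10 ms of
   simulated time) the total potential energy of the polymeric phase is
   minimized; the network is assumed to relax much faster than chemical
   events occur.
3. **Mechanochemical feedback.** The post-minimization force field modifies
   the reaction rates of the next window: a Brownian ratchet suppresses
   polymerization under boundary load, crosslinkers unbind as slip bonds,
   motor ensembles unbind as catch bonds, and motor walking follows a Hill
   force–velocity relation.

# State representation

Filaments are chains of connected cylinders.  Each cylinder holds 1–40
actin monomers and has equilibrium length 2.7 nm per monomer (so at most
108 nm); only the terminal cylinders may be partially filled.
Polymerization extends the terminal cylinder's rest length and rolls over
into a new collinear cylinder at 40 monomers; depolymerization reverses
this.  A filament's barbed end is either free (`BE`) or bound by the
nucleator formin (`FBE`); the pointed end is always `PE`.

Bound motors and crosslinkers are two-point harmonic springs attached to
binding sites on cylinders.  Four sites per cylinder at fractional
positions 1/8, 3/8, 5/8, 7/8 of the axis (about 27 nm apart on full
cylinders) are used; each site holds at most one element per species
class.  Motor ensembles carry 15–30 heads, drawn uniformly at binding.

Soluble species (G-actin, formin, the nucleation intermediate, NMII,
crosslinker) live as integer copy numbers on a compartment grid.  The
compartment edge follows the Kuramoto length of G-actin and defaults to
500 nm.  At the desk scales this package targets (disks of a few
micrometers), the volume spans only a few compartments, so production-like
runs default to a single well-mixed compartment; the multi-compartment
diffusion engine (single-molecule hops at rate `D/l^2` per neighbor) is
fully implemented and exercised on toy grids.  `D` is 20 µm²/s.

The mechanical boundary is an oblate cylinder (diameter 4 µm, height
400 nm by default) or a sphere.  The exponential repulsion
`eps * exp(-(d - a0)/lambda)` (amplitude 100 pN·nm, screening length
2.7 nm) is shifted inward by `a0` = 100 nm, so the effective confinement
is 3.8 µm × 200 nm.

# Energy model

Five terms, in pN and nm units throughout:

* stretching `U = 1/2 K_str (l - l0)^2` per cylinder, `K_str` = 100 pN/nm;
* bending `U = K_bend (1 - cos(theta))` per junction, `K_bend` = 672 pN·nm
  (straight equilibrium), which reproduces the ~17 µm persistence length of
  F-actin at 108 nm discretization;
* motor/linker springs `U = 1/2 K (l - l0)^2` with `K` = 8 pN/nm for
  crosslinkers and 2.5 pN/nm **per head** for motors.  Heads act
  mechanically in parallel, so the ensemble stiffness is the per-head
  constant times the head count.  The rest length is fixed when the
  element binds (the current site separation, so a fresh element is
  relaxed);
* boundary repulsion as above, sampled at three points per cylinder (both
  endpoints and the midpoint), appropriate for thin elements;
* an optional pairwise excluded-volume term, the double line integral of
  an `r^-4` kernel over non-adjacent cylinder pairs, evaluated with a
  16×16 Gauss–Legendre tensor rule inside a 100 nm neighbor cutoff.  The
  term is **off by default**: steric interactions carry a prohibitive cost
  at network scale and the ring/cluster phase behavior does not depend on
  them.  Both modes are supported and the quadrature is validated against
  an independent adaptive integrator.

Minimization uses L-BFGS-B on the analytic gradient (a compiled kernel,
cross-checked against a pure-R reference implementation and against
central finite differences at 1e-5 relative accuracy).  The FIRE
inertial algorithm is available via `config = list(minimizer = "fire")`.
Convergence demands a maximum residual force component below 1 pN
(configurable); on non-convergence within the iteration cap the
best-so-far configuration is returned and flagged.  Minimization never
touches chemistry-owned quantities (monomer counts, topology, bound
elements).

# Chemistry

The reaction set is the four-reaction treadmilling reduction plus
nucleation, destruction, and motor/linker dynamics:

* **End kinetics.** Barbed and pointed ends polymerize at
  `k_on * [G-actin]` ((µM·s)^-1 constants: barbed 11.6–34.8, pointed 1.3)
  and depolymerize at fixed rates (barbed 1.4 s^-1, pointed 0.8–2.4 s^-1).
  At kinetic steady state the soluble pool settles at
  `G_ss = (k_off_BE + k_off_PE) / (k_on_BE + k_on_PE)` and the net barbed
  elongation rate — the treadmilling rate `r_TM` — equals
  `k_on_BE G_ss - k_off_BE`.  The baseline constants give
  `r_TM ≈ 0.58 s^-1`; scaling `k_on_BE` and `k_off_PE` jointly by 3 (the
  effect of treadmilling promoters such as formin and ADF/cofilin) gives
  `≈ 2.26 s^-1` (`treadmilling_scale()`).
* **Nucleation** is a two-step formin pathway: a rate-limiting capture of
  one G-actin (`k_nu` = 0.005 s^-1 per eligible free formin) forms a
  diffusing intermediate, which then rapidly converts into a 3-monomer
  filament with formin retained on the barbed end.  The fast step consumes
  two further G-actin, so a nucleus carries exactly the three monomers it
  drew from the soluble pool and total actin is conserved event by event
  (the package treats this conservation as a hard invariant; see the test
  suite).  Formin dissociates from barbed ends at 0.01 s^-1.
* **Destruction** removes filaments that have shrunk to two monomers
  (rate 1.0–1.9 s^-1), releasing two G-actin; this balances ongoing
  nucleation and fixes the steady-state filament count.  A formin-bound
  2-monomer filament must first lose its formin.
* **Binding.** Candidate site pairs on *distinct* filaments with
  separation inside the species window (motors 175–225 nm, crosslinkers
  30–40 nm) are enumerated with a uniform spatial hash (validated against
  a brute-force all-pairs scan).  Each admissible free pair acts as a
  binding channel, so the total propensity is mass action in the soluble
  species times the candidate-pair count — `k_on_linker [linker] P` for
  crosslinkers (0.7 (µM·s)^-1) and `n_heads k_on_head [NMII] P` for
  motors (0.2 s^-1 per head, heads drawn uniformly on 15–30).  Without
  the pair-count factor the stated concentrations would leave the network
  essentially uncrosslinked, which contradicts the motor-driven collapse
  the model exists to capture.  The pair list is cached and refreshed
  every 10 chemistry windows (0.1 s; positions move only at
  minimization), pruned incrementally by bindings; a firing whose sampled
  pair has gone stale is a null event.  Unbinding (0.3 s^-1 linkers,
  per-head 1.7 s^-1 motors in the catch-bond form below) returns the
  element to the soluble pool.
* **Walking.** Each motor end independently steps one binding site toward
  the barbed end of its filament at an unloaded rate `k_walk0` = 7.4 s^-1,
  chosen so the unloaded ensemble velocity is ≈ 0.2 µm/s at the 27 nm
  site spacing (neither the step rate nor the step size is tabulated in
  standard parameter sets; both are config-exposed).  The spring rest
  length is *not* reset when a motor walks: the attachment moves, the
  realized extension changes, and the resulting tension is what transmits
  contractile stress to the network.  Resetting the rest length to the
  realized separation at each step would erase motor tension as fast as
  walking builds it and the ensemble could never drive the centripetal
  collapse that defines the cluster phase, so the package deliberately
  keeps the rest length fixed at its binding-time value.

All chemistry is propagated with the NRM over an explicit channel table;
propensity updates after each event are incremental but exactly equal to a
from-scratch recomputation (asserted in the tests), and the engine is
validated distributionally against a direct-SSA reference on toy networks.
Because the exponential distribution is memoryless, the channel table may
be rebuilt (or all pending times redrawn) at any deterministic time
boundary without statistical error; the engine does this at protocol
windows, which is also when force-dependent rates change.

# Mechanochemical feedback

After each minimization:

* every filament end receives the boundary-repulsion gradient projected on
  its outward growth direction as a compressive load `F_ext`, and its
  polymerization constant is scaled by `exp(-F_ext / 1.5 pN)` (Brownian
  ratchet);
* every crosslinker unbinds at `k0 * exp(max(F, 0) / 17.2 pN)` (slip
  bond; compression does not accelerate unbinding);
* every motor ensemble unbinds at
  `beta k0 / N * exp(-F / (N * F_unbind))` with `beta` = 0.2 and
  `F_unbind` = 20 pN (catch bond, parallel-cluster form: load stabilizes
  the ensemble).  The characteristic force is taken as `1/gamma` with
  `gamma` = 0.05 pN^-1, the only tabulated parameter with matching units
  whose role is otherwise unstated — an inference, flagged here;
* each motor end walks at
  `k0 (F_stall - F/N) / (F_stall + F/(N xi))`, floored at zero, with
  per-head stall force 12.62 pN and force-sharing factor `xi` = 0.1.
  The pulling force is the spring tension projected on that end's
  barbed-ward step direction, counted only when a step would stretch the
  spring further.  The printed form of this law distinguishes an `F_ext`
  from an `F_pulling`; both are read as this same projected tension, as
  no independent definition is available.

Rates are updated **only** at protocol boundaries, never mid-window.

# Protocol and scenarios

`run_simulation()` iterates chemistry window → minimization → rate update
until the configured time.  The standard de novo protocol initializes
seed filaments, 40 µM G-actin and 100 nM formin, lets the network
assemble for 300 s, then adds 0.06 µM NMII and 4 µM alpha-actinin.
`scenario()` packages the named experiments: the slow/intermediate/fast
treadmilling baselines, treadmilling inhibition of an established ring
(at 800 s, weak: `k_on_BE` 11.6 (µM·s)^-1, `k_off_BE` 2.1 s^-1,
`k_off_PE` 2.4 s^-1; strong: 3.48, 11.2, 4.8; pointed-end constant fixed
at 1.3), and motor perturbations of a preformed dense ring (80 µM actin,
0.18 µM NMII, 4 µM crosslinker; `init_preformed_ring()` builds the ring
directly because growing it de novo at doubled actin would be
prohibitively slow, mirroring the original experimental-modeling
shortcut).  Motor enhancement adds soluble copies; motor inhibition
removes them, digging into bound motors at random once the soluble pool
is exhausted.

Seed filaments default to 20 filaments of 30 monomers at full scale (the
seed count is not specified in standard protocols; it only bridges the
nucleation transient).  The desk-scale mode (`scaled_down = TRUE`)
shrinks the disk to 2 µm effective diameter with all concentrations
preserved and uses 60 seed filaments: the absolute nucleator count in the
small volume is low, so seeds must carry the filament number density if
the steady-state mean filament length is to stay near one fifth of the
disk diameter as it is at full scale.  Without this scaling the few
filaments grow comparable to the disk itself, wrap along the boundary,
and the morphology readout saturates at ring-like values regardless of
kinetics.

# Morphology quantification

* `radial_density()` bins polymerized monomers (each monomer weighted
  equally, spread uniformly along its cylinder) by in-plane radius,
  normalizes per annulus area and to unit integral.
* `r_median()` is the monomer-radial median divided by the effective
  radius: 1/sqrt(2) ≈ 0.707 for a uniform disk, → 1 for peripheral rings,
  → 0 for central clusters.  Whether the original analysis weighted
  monomers or cylinder midpoints is not stated; monomer weighting is the
  natural reading of a density of polymerized actin.
* `remodeling_rate()` fits the linear part of the `R_median` time series
  after motor addition.  The segmentation rule (ours; none is stated in
  the source analyses): the longest window of at least 50 s whose linear
  fit has R² ≥ 0.9 *and* whose two halves agree in slope within 5% (or
  within the half-fit noise), which rejects ramp-plus-plateau windows
  that an R² criterion alone would accept.
* `treadmilling_rate()` reports the net barbed-end elongation rate per
  filament from the cumulative end-event counters (additions minus
  removals), which at kinetic steady state equals the net pointed-end
  shrinkage rate; `steady_state_onset()` operationalizes steady state as
  a <2% change of the rolling-mean filament length per 100 s.
* `turnover_halftime()` mimics a FRAP measurement: all polymerized
  monomers are labeled at a chosen time (a `"label"` schedule action);
  barbed-end additions pile unlabeled material on one side, pointed-end
  loss consumes the labeled block, and the halftime is the first
  (interpolated) time the labeled polymerized fraction falls to 0.5.
* `detect_clusters()` bins monomers into 100 nm × 100 nm columns through
  the effective height, thresholds at 160 µM, groups 4-connected bins
  (edge-sharing; the connectivity convention is ours) and discards
  components smaller than 4 bins; `local_concentration()` averages the
  member bins.  Rings and clusters are measured identically.
* `orientation_distribution()` folds each cylinder's angle to the local
  boundary tangent into [0°, 90°].
* `mechanical_energy_series()` reports `U_Mech`, the sum of filament
  bending and the stretching energies of filaments, motors and linkers —
  the boundary and excluded-volume terms are excluded by definition.

# Image quantification

The TIRF-like pipeline mirrors the live-cell analysis: background
subtraction with clipping at zero, a cell mask from Otsu's threshold on a
lightly smoothed frame (or a fixed minimum intensity) keeping the largest
connected component, the intensity-unweighted mask centroid, and 50
uniformly spaced rays sampled bilinearly to the mask edge with per-ray
distance normalization.  The image-side radial median weights pooled ray
samples by intensity *times radius*: rays sample uniformly per unit
radius, so the annulus Jacobian restores per-area mass weighting and the
statistic estimates the same quantity as the simulation-side `r_median`
(a uniform disk again gives 1/sqrt(2)).  The center-to-plateau slope
normalizes each frame by its mean cell intensity (removing global
photobleaching), estimates the plateau as the mean over the outer 20% of
radii, and fits the transition region between 10% and 90% of the plateau
level; these fractions are our operationalization and are arguments of
`plateau_slope()`.

# Synthetic data

`make_snapshot()` builds networks of straight filaments with prescribed
morphology (uniform / ring / clusters) whose analytic radial statistics
are known by construction; filaments default to one full cylinder so the
fixtures are independent of mechanics.  Near the rim, uniform-morphology
filaments are laid tangentially so that no mass leaves the boundary
while the center distribution stays area-uniform.  `render_image()`
renders snapshots into TIRF-like frames: pixel binning, Gaussian PSF,
Poisson shot noise after the PSF (no Gaussian read noise), flat
background, and an optional per-frame bleaching factor.
`make_event_log()` and `make_turnover_log()` produce counter streams
with known rates for the kinetic estimators.  All generators are
deterministic under a fixed seed.

What passing fixture tests show — and what they do not: the fixtures
emulate the *geometry* and the *photon statistics* of the data, not
mechanical plausibility (no minimization, no connectivity), detector
artifacts, drift, or the heterogeneity of real cells.  Agreement on
fixtures validates the estimators, not the biology.

# Numerical choices and problem sizes

Everything is in pN/nm/s units.  The chemistry window is 10 ms; snapshot
cadence 1 s.  The minimizer tolerance is 1 pN on the largest force
component.  Random numbers come from R's global stream, seeded once per
run, so runs are exactly reproducible; the channel table redraw at window
boundaries is exact by memorylessness.  Nucleation placement rejection
sampling retries 50 times before deferring the event.

The test suite and the acceptance script run everything at desk scale:
disks of 1.2–2.2 µm mechanical diameter, a 100 s assembly phase, and
motor phases of 150–350 s, one seed per arm; in the desk-scale mode the
per-window minimizer evaluation budget is 200 (relaxation continues
across windows and an unconverged window is flagged).  Both arms
collapse centripetally when motors arrive; the fast-treadmilling arm
then escapes the cluster trap and remodels centrifugally over a few
hundred seconds, so the paired comparison evaluates each arm in its own
quasi-stationary regime: the cluster arm in its stationary clustered
window and the ring arm after its escape (a longer run).  These sizes were chosen so a full paired
ring-versus-cluster comparison completes on a laptop-class single core;
the full-scale protocol (3.8–10 µm disks, 2000 s, five replicates) is
the same code with the full-scale `scenario()` presets and is intended
for offline batch use.  At desk scale the comparisons are directional
(ring arm above cluster arm in `R_median`, below it in `U_Mech`) rather
than quantitative reproductions of full-scale values.

Image-pipeline cross-checks use a 10 µm disk so the PSF is small
relative to the cell, and sparse morphologies ride on a diffuse
cytoplasmic actin floor so the cell mask covers the confinement, as it
does in real cells; thresholding a floor-free synthetic image at the
background level would dilate or fragment the mask and bias the
normalized radius.

# Known limitations

* Mechanics is strictly quasi-static: no thermal fluctuations, no
  hydrodynamics, no inertial dynamics.
* No explicit nucleotide states on subunits; treadmilling is the
  four-reaction reduction.
* Arp2/3-mediated branching and membrane/filament tethering are out of
  scope; the boundary is a passive repulsive wall.
* The excluded-volume term is off by default; dense-phase packing is
  therefore not sterically limited.
* The well-mixed default ignores diffusion gradients, which is adequate
  only while the system spans a few Kuramoto lengths.
* Desk-scale geometry compresses the separation between filament length
  and system size; quantitative observables (local concentrations,
  absolute energies) should be interpreted at full scale only.
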