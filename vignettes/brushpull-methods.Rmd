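---
title: "Methods: DPD simulation of bottlebrush pulling across a supported bilayer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DPD simulation of bottlebrush pulling across a supported bilayer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

brushpull simulates a coarse-grained bottlebrush polymer dragged by a
constant per-bead force across a substrate-supported phospholipid bilayer,
using dissipative particle dynamics (DPD), and computes the observables that
characterize the process: the brush radius of gyration, its gyration-tensor
shape factor, x-binned P2 orientational order profiles of the membrane, and
landmark times of the observable traces. This vignette is the package's
account of the model, its parameters, the numerical choices, and what the
scaled-down test systems do and do not demonstrate.

## The model

### Forces

Every pair of beads closer than the cutoff rc interacts through the three
standard DPD terms. With `w(r) = 1 - r/rc` inside the cutoff and zero beyond:

* conservative: `a_ij w(r) r_hat` — a soft repulsion of maximum strength
  `a_ij`; negative `a_ij` gives adhesion;
* dissipative: `-gamma w(r)^2 (r_hat . v_ij) r_hat` — pairwise friction on
  the radial relative velocity;
* random: `sigma w(r) zeta_ij dt^(-1/2) r_hat` — a pairwise kick with
  `zeta_ij` symmetric in (i, j), zero mean and unit variance, redrawn every
  step.

The dissipative/random pair is a momentum-conserving thermostat; the
fluctuation-dissipation relation `sigma^2 = 2 gamma kBT` is enforced at
construction time (`dpd_params()` rejects violating inputs). Defaults are
gamma = 4.5 and sigma = 3.0, so kBT = 1.

Chain connectivity adds harmonic bonds, `F = ks (1 - r/rs) r_hat`, and
harmonic bending potentials `ktheta (theta - theta0)^2` on consecutive bond
pairs. An external constant force F along +x on every brush bead models the
pulling (a body force, as realized for polyelectrolytes in an electric
field).

All quantities are in reduced units: m = kBT = rc = 1, time unit
tau = rc sqrt(m/kBT). The physical mapping (reporting only) follows from the
bead volume: `rc_physical = (rho Vb)^(1/3)` which is about 0.448 nm at
Vb = 0.03 nm^3 and rho = 3.

### Species and interaction table

Five bead species: lipid HEAD and TAIL, BRUSH_BACKBONE and BRUSH_SIDE, and
SOLVENT. The repulsion table (reduced units):

* membrane: 25 between identical lipid species, 100 between head and tail;
* brush: 15 between identical brush species, 50 between backbone and
  sidechain;
* brush-HEAD: the adsorption parameter aBM, -5 in the weak and -20 in the
  strong regime, applied to both brush species (the model's text leaves open
  whether tails are included; the package default targets heads only and the
  table is fully configurable);
* brush-TAIL: 50 (repulsive);
* solvent: 25 against everything except lipid tails (100) — the standard
  hydrophilic/hydrophobic convention, consistent with the 25/100 membrane
  pattern. The solvent entries are not stated by the source model and are a
  documented default.

### Topologies

A lipid is one head chain (3 beads) and two tails (4 beads each) — the
smallest architecture compatible with the bending rules, since those are
stated over "three consecutive" head or tail beads; counts are configurable.
Membrane bonds use ks = 120, rs = 0.7; brush bonds ks = 200, rs = 0.5.
Bending: ktheta = 6 with theta0 = pi for pure head or tail triples and
theta0 = 2 pi/3 for the triples spanning the head-tail connective point;
brush triples use ktheta = 4.5, theta0 = pi.

The bilayer is built on a jittered square lattice (1 rc^2 leaflet area per
lipid, jitter ±0.1 rc — free choices, unstated in the source model), two
leaflets tail-to-tail. The membrane is supported: the two head beads of each
lower-leaflet lipid nearest the substrate plane are fixed — they exert
forces but never move.

The bottlebrush has an NM-bead backbone with one NS-bead sidechain grafted
to every interior backbone bead (nS = NM - 2 enforced). Full scale:
NM = 100, nS = 98, NS = 10 (1080 beads).

### Initial tail tilt and the t = 0 order parameter

The freshly generated membrane is *not* perfectly aligned: the study's
initial order profile sits near 0.25 because the membrane is generated with
a random arrangement. The builder therefore draws each tail's straight
initial direction uniformly from a cone about the leaflet normal. For a cone
with minimum cosine c (cosine of the half-angle), the expected P2 of a
straight tail is `(c + c^2)/2`; the default `c = (sqrt(3) - 1)/2` is the
value whose expectation is exactly 0.25, i.e. the generator is calibrated
analytically to the stated initial condition, not fitted to simulation
output. `tilt_cos_min = 1` builds a perfectly aligned membrane (used by the
analytic test fixtures).

### Brush initial layout

Two layouts: a deterministic serpentine comb (useful for exact count/layout
tests) and the default preset layout, a compact self-avoiding persistent
random walk ("coil") for backbone and sidechains. The coil emulates the
relaxed, randomly distributed brush the experiments start from: in the
small preset it reaches its plateau size (Rg about 2.7 rc, shape factor
about 0.2) within roughly 10 tau of equilibration, whereas the serpentine
needs several tens of tau. Both layouts respect the contracts: exact bead
counts, grafting to interior beads only, bonds at rs, minimum separation
0.1 rc.

### Assembly

`assemble_system()` merges membrane and brush (brush placed just above the
upper leaflet, center of mass within the first 10% of the x-range), fills
the box to `round(rho V)` beads with solvent placed outside 0.5 rc exclusion
shells, draws Gaussian velocities at kBT (the source model is silent on
initialization), zeroes the net momentum of the free beads, and keeps fixed
beads at rest.

## Integration

The equations of motion are integrated with the Groot-Warren modified
velocity-Verlet scheme: half kick, drift, a lambda-predicted velocity for
the single force evaluation per step, then the final velocity correction.
lambda defaults to 0.5, the standard choice at these gamma, sigma and
dt = 0.005 tau. At these parameters the fluid holds a kinetic temperature
within a few percent of kBT = 1 (a small positive bias at finite dt is
expected and tolerated in the tests' 5% band).

Pair search uses a cell list (27-cell stencil, periodic wrap, cells >= rc)
feeding a Verlet neighbor list with a 0.4 rc skin, rebuilt when any bead has
moved far enough that two beads could have closed the skin gap. Boxes
narrower than three cells fall back to an O(N^2) minimum-image scan. The
enumerated pair set is identical to the brute-force scan (tested), and the
per-pair noise is keyed on (seed, step, unordered pair) with a counter-based
hash, so force evaluations are independent of enumeration order and
bit-reproducible from the master seed — two runs of the same protocol and
seed produce identical trajectories. (Splitting a run into chunks keeps the
physics and the noise stream but re-orders the neighbor-list summation, so a
chunked run matches an unchunked one to floating-point rounding, not bit for
bit.)

All three box directions are periodic. The study box (400 x 30 x 20 rc,
rho = 3, 720,000 beads) is long enough in x that the brush never re-enters
its own wake; the package keeps x periodic and relies on box length, and
run termination fires before the brush reaches the +x edge (5 rc margin).

## Observables

* `radius_of_gyration()`: root mean squared distance to the center of mass,
  on unwrapped coordinates (wrapped input is detected and rejected).
* `shape_factor()`: eigenvalues L1^2 >= L2^2 >= L3^2 of the gyration tensor;
  `delta = 1 - 3 (L1^2 L2^2 + L2^2 L3^2 + L1^2 L3^2) / (L1^2+L2^2+L3^2)^2`.
  delta is 0 for equal eigenvalues, 1 for a line. Note: direct evaluation
  for a planar ring (two equal eigenvalues, third zero) gives 0.25, although
  descriptions sometimes quote 0.5 for "circular" objects; the package
  follows the formula, and its tests pin the 0.25 value.
* `order_parameter()` / `order_profile()`: mean second Legendre polynomial
  `(3 cos^2 theta - 1)/2` of the angle between a chain vector and z. The
  chain vector is the lipid tail end-to-end vector (first to last tail
  bead), two samples per lipid, assigned to x-bins (default width 5 rc) by
  midpoint; empty bins are flagged, not zero-filled. The choice of tail
  end-to-end vectors (rather than per-bond vectors or whole-lipid axes) is a
  package decision — the source model does not define "chain direction";
  alternatives change the absolute level but not the spatial structure.
* `detect_landmarks()`: a centered moving average (window 5 tau by default)
  followed by the first strict local minimum (T1), the first subsequent
  strict local maximum (T2), and the trace end (Te). Extrema are assessed
  against every sample within half a smoothing window on each side — a
  plain one-sample neighborhood latches onto residual noise wiggles —
  and constructed landmarks are recovered within one window at noise levels
  up to a few percent of the trace amplitude. Monotone traces report T1/T2
  as absent.
* `brush_head_contacts()`: the number of brush-bead/HEAD-bead pairs within
  rc — the operational measure of adsorption.

## The pulling pipeline

`run_pull()` applies the per-bead force to every brush bead, samples the
observables at the protocol stride, and stops at `max_time`, when the brush
center of mass comes within 5 rc of the +x box edge, or when any 2 x 2 rc
column of the x-y pore grid stays empty of TAIL beads for 5 consecutive
samples (a persistent pore). The composite rule is the package's
operationalization of "run ends when the membrane is broken or the polymer
has crossed"; the source model gives no explicit criterion.

`run_sweep()` runs one experiment per force value with a fresh build and
equilibration, and reports post-transient time averages over
[0.2 Te, Te] with their window and sample counts. By default the same seed
is used for every force (a paired design: identical build and thermal noise,
so differences are attributable to F alone); unpaired seeds are a flag.
One replicate per condition is the default, matching the single-run design
of the study; replicates are a configuration knob.

Equilibration before pulling defaults to 10,000 steps (50 tau) — a package
choice, the study does not describe its relaxation protocol. After
equilibration the kinetic temperature must lie within 5% of kBT and the two
leaflets must remain separated by at least one tail contour length,
otherwise a model-parameter error is raised.

## Presets and problem sizes

`preset_system("full")` reproduces the full-scale setup (400 x 30 x 20 rc,
720,000 beads, NM = 100 brush). `preset_system("small")` is the desk-scale
system used throughout the tests: 60 x 20 x 16 rc (57,600 beads), 2,400
lipids, an NM = 30 / nS = 28 / NS = 5 brush at the same densities and
interaction parameters. The test suite's physical checks use the small
preset with short schedules (about 4-10 tau of settling, 6-10 tau of
pulling); the tiny pipeline fixtures (BILAYER_PATCH, MINI_BRUSH_ON_PATCH,
12 x 12 x 14 rc) cover contracts where full hydrodynamics is unnecessary.
These sizes were chosen so the whole suite runs comfortably on one CPU.

What the scaled-down runs show: thermostat fidelity, exact force/neighbor
equivalences, momentum conservation, the adsorption-strength ordering of
brush-membrane contacts, and the qualitative force-sweep structure (Rg
non-increasing with F under weak adsorption; shape factor and membrane P2
flat). What they do not show: the full-scale single-run trace shapes and
absolute landmark times (T1, T2, Te at 720,000 beads), pore morphologies,
or any quantity that depends on the 400 rc membrane length. The full-scale
preset exists for exactly those questions and runs for hours on one CPU.

## Numerical choices and degenerate inputs

* zeta_ij is uniform on [-sqrt(3), sqrt(3)] (zero mean, unit variance),
  drawn once per pair per step via a splitmix64 counter-based hash on
  (seed, step, unordered pair).
* Bonded pairs also feel DPD pair forces (no exclusions), the common DPD
  convention; the source model is silent.
* Zero-length bonds (r < 1e-9) and zero-length angle arms are hard errors;
  the angle force uses a guarded 1/sin(theta) (floor 1e-8) so the
  equilibrium-at-pi case is smooth.
* A bead displacing more than half the smallest box edge in one step raises
  an instability error (with the step and bead reported).
* Observable degenerate cases: all-coincident beads have no shape
  (`shape_factor()` errors), zero chain vectors are rejected, and monotone
  traces report absent landmarks rather than erroring.
* Trajectory text precision is 6 decimals; checkpoints are full-precision
  binary; reruns from a manifest (parameters + master seed) are
  bit-identical, which is the reproducibility contract the tests enforce.
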