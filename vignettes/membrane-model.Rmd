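---
title: "A solvent-free coarse-grained membrane under a rotating spiky nanoparticle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A solvent-free coarse-grained membrane under a rotating spiky nanoparticle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`spinpore` simulates a planar lipid bilayer with the classic solvent-free
three-bead lipid representation: each lipid is a head bead and two tail
beads held together by two FENE bonds plus a harmonic "straightening"
spring between the head and the second tail bead (rest length 4 sigma,
beyond the maximal FENE extension, so it always pulls the chain
straight). Excluded volume is a WCA repulsion with length 0.95 sigma for
head–head and head–tail contacts and 1.0 sigma for tail–tail contacts.
Because there is no explicit water, membrane cohesion comes entirely
from an attractive tail–tail potential: a flat well of depth one epsilon
for `r < rc = 2^(1/6)` sigma that tapers to zero as `-cos^2` over a
width `wc = 1.7` sigma. At `kB T = 1.1` epsilon and `wc = 1.7` sigma
this model self-assembles into a fluid bilayer.

All dynamics are integrated in reduced units (sigma, tau, epsilon, bead
mass m = 1, fixed — a single bead mass keeps the interpretation of tau
unambiguous). Matching membrane thickness (5 nm versus 5 sigma), lipid
diffusion (5 um^2/s versus 1e-2 sigma^2/tau) and temperature (310 K
versus 1.1 epsilon/kB) gives sigma = 1 nm, tau = 2 ns and
epsilon = 3.89e-21 J (`derive_unit_system()`). Note that under this
mapping the 2D-modulus unit epsilon/sigma^2 evaluates to 3.89 mN/m;
conversions in this package are always computed from the unit system,
never hard-coded.

Nanoparticles — free cargo beads (2 sigma, model drugs) and the beads
tiling the rigid spiky particle — interact with membrane beads through a
truncated-and-shifted 12-6 Lennard-Jones potential with well depth
0.2 epsilon, length `b_np = 2^(7/6)` sigma and cutoff `3 b_np`,
mimicking a coating that favours membrane wrapping. A configurable
fraction of upper-leaflet heads are labelled receptors and feel a deeper
(2 epsilon, configurable) well toward spike beads, a deliberately
phenomenological stand-in for ligand–receptor adhesion: no binding
parameters are available for it, so its strength is a model choice,
flagged as such, chosen so receptors visibly follow the spikes.

### Two repulsion variants

The default excluded-volume strength is `eps_rep = 1` epsilon with the
truncation shift (energy continuous at the cutoff). A literal variant
with `eps_rep = 0.01` and no shift is selectable
(`forcefield_params(paper_literal = TRUE)`) for documentation; a
repulsion of 0.01 epsilon cannot stabilise a bilayer against the
1-epsilon tail cohesion at `kB T = 1.1`, so nothing else in the package
uses it. Its cutoff discontinuity of `-eps_rep` is also documented in
the tests.

## Integration and ensembles

Langevin dynamics use the BAOAB splitting with friction
`gamma = 1/thermostat_tc` (default `tc = 0.5` tau = 100 timesteps) and
fluctuation–dissipation-matched noise; with the thermostat off the
scheme reduces to velocity Verlet. The timestep is 0.005 tau; that value
is also the tested maximum. Noise is generated by a counter-based
splitmix64 hash keyed on (seed, step, bead), so trajectories are
deterministic for a given seed and independent of iteration order.

The tensionless ensemble is realised by an in-plane weak-coupling
barostat (time constant 5 tau = 1000 timesteps) that rescales the
lateral box and coordinates toward zero lateral pressure; the virial
pressure uses the full box volume, and the membrane tension convention
is `Sigma = -(P_xx + P_yy)/2 * L_z`. For a self-bound membrane in
vacuum the normal pressure averages to zero, so zero lateral pressure
is the tensionless state. The coupling adds a stochastic
cell-rescaling-type term (default on) so that projected-area
fluctuations are canonical — without it a weak-coupling barostat
suppresses Var(A) and the area-fluctuation estimator of the stretching
modulus is invalid. The compressibility prefactor (default 15
sigma^3/epsilon) sets the area relaxation time to a few tau in the
default geometry; it affects dynamics only, not the sampled
distribution.

Two numerical guards abort a run with the frames collected so far:
FENE overstretch (the classic too-large-timestep failure, reported with
the bond and step) and a barostat rescale factor outside [0.9, 1.1].

The rigid spiky particle is never integrated: its beads follow exact
prescribed kinematics — rotation by `angle0 + 2 pi f (t - t0)` about a
fixed axis through its center (the angle accumulates continuously
across run phases), plus an optional constant-velocity center
translation used for indentation and traversal ramps. Forces on the
robot are
computed and logged but do not alter its motion: the experimental
magnetic drive imposes the rotation rate, so the membrane must not slow
the particle down.

## Builders

`build_bilayer()` places lipids on a square lattice (tails inward,
midplane at z = 0) with Maxwell–Boltzmann velocities and zero net
momentum. The initial area per lipid (default 1.2 sigma^2) is only a
starting guess: the barostat finds the tensionless area (about
1.14 sigma^2 per lipid at desk scale), so the guess affects
equilibration time only.

`build_spiky_robot()` tiles a spherical core with beads (Fibonacci
sphere at the configured spacing) and adds tapered conical spikes:
lengths and full apex angles drawn uniformly from configured ranges
(apex default 5–20 degrees, the measured morphology of the fabricated
particles), directions near-uniform. The simulated particle must be
scaled down with the membrane patch — a literal 500-nm particle would
exceed even the full 200-sigma membrane — so core radius and spike
lengths are configurable, with desk-scale studies using cores of
1.5–2 sigma and spikes of 3–6 sigma.

`assemble_scene()` centers the robot above the bilayer with its lowest
bead at the robot–membrane LJ contact distance (gap 2.5 sigma ~
`2^(1/6) b_np`); starting closer would place lipids deep inside the
repulsive core and detonate the first step. Cargo is scattered on the
cis side with hard-sphere rejection sampling.

## Observables

* **Density and pores.** Lipid beads are counted on a 2-sigma grid;
  pores are 4-connected components of cells below 25% of the intact
  reference density (both threshold and cell size are recorded in the
  output). Total and largest-component areas are both reported since a
  "pore" in a figure may mean either.
* **Penetration.** A cargo bead counts as penetrated when its unwrapped
  z lies more than 1 sigma below the per-frame mean lower-leaflet head
  plane; the cumulative count is monotone (ever-crossed).
* **MSD and diffusion.** Multiple-time-origin MSD over any bead
  selection and axis mask, on unwrapped coordinates; D is the fitted
  slope over a window in the diffusive regime divided by `2 d`.
* **Stretching modulus.** `K_A = kB T <A> / Var(A)` from the projected
  area of a barostatted run, with a blocked jackknife standard error.
* **Bending stiffness.** Height fields (per-cell mean z of lipid beads,
  empty cells neighbour-interpolated) are Fourier transformed and the
  low-q spectrum inverted. The default fit includes both the `q^4`
  (bending) and a `q^2` (tension-like) coefficient by weighted least
  squares: in patches tens of sigma across, the fluctuation spectrum
  carries a residual `q^2` component even when the virial frame tension
  is zero, and a pure `q^-4` inversion then overestimates kappa by
  nearly a factor of two. Modes with wavelengths shorter than 6 sigma
  are excluded (protrusion regime). A diagnostic log–log slope flags
  spectra that are not `q^-4`-like (for example white noise).

## Calibration workflow

`calibrate_membrane()` chains three segments: (1) equilibration under
thermostat + barostat; (2) a barostatted production segment whose area
series gives `K_A` and the tensionless mean area; (3) a constant-area
production at that mean area for the height spectrum (kappa) and
head-bead lateral MSD (D). The spectrum is collected at fixed area
because the weak-coupling area dynamics measurably perturb the softest
undulation modes of a small patch; Var(A) conversely requires the
barostatted ensemble — each estimator runs in the ensemble where it is
valid.

Desk-scale problem sizes (chosen once as this package's working scale):
a 20 x 20-lipid-per-leaflet patch (2,400 beads), 2e4–3e4 equilibration
steps, and production segments between 8e4 + 1.2e5 (test suite) and
1.2e5 + 2.4e5 (analysis scripts) steps. At that scale the package's
runs read kappa 10–30% below the full-scale reference 7.8 epsilon
(the sigma/kappa decomposition of the spectrum is intrinsically
scale-limited in a patch with only a handful of q-shells) and lateral
diffusion within a factor two of 1e-2 sigma^2/tau. The
stretching modulus of the small patch comes out at 32–38
epsilon/sigma^2, systematically above the full-scale reference
26.4: a patch this small supports only a handful of undulation modes,
so less projected area is stored in (and exchanged with) undulations
and the membrane appears stiffer. This is a physical finite-size
effect, not an estimator artifact — an independent stress–strain sweep
(fixed-area runs at imposed strains, slope of tension versus strain)
gives the same 33–35 at this size, and matches the canonical Var(A)
sampled by the stochastic-rescaling barostat.

## The rotating-particle study

`run_condition()` realises one experimental condition: `no_robot` (free
diffusion control), `static` (driven through the membrane without
spinning), `f_15000` and `f_5000` (rotation at 1/15000 and
1/5000 tau^-1 about the membrane normal — the default axis; an in-plane
axis, i.e. rolling, is also supported). For the robot conditions the
production window contains the traversal event itself: after
tensionless relaxation with the particle at the LJ contact distance,
the rigid body descends at constant speed so that it pierces, crosses
and exits the bilayer within the first ~35% of the window, rotating at
the condition's frequency throughout (or not, for the static-drive
control, which is pressed through identically). This mirrors the
reference scenario in which the particle crosses the membrane over the
observation period. Transport is then cargo crossing through the
traversal wound.

Two desk-scale choices make this well posed. First, the z center of
mass of the lipid subsystem is constrained (its net z velocity is
removed each step): a patch tens of sigma across otherwise simply
translates with the driven body instead of being pierced by it — the
constraint emulates the embedding of the patch in a macroscopic
membrane and is standard practice for membrane simulations under
external forcing. Second, production runs at the relaxed fixed area for
every condition: in the barostatted ensemble the wound is simply
rescaled away (and strong adhesion can even feed the whole patch onto
the body), whereas at the fixed relaxed area the post-traversal
membrane is slightly stretched and the wound persists on the
observation timescale, as it would in a large membrane whose distant
lipid reservoir cannot instantly reseal it. The intact reference
density for pore detection comes from the relaxed pre-traversal
membrane.

At desk scale one rotation period at f = 1/5000 tau^-1 is 5000 tau
(1e6 timesteps), so production windows cover a fraction of a turn; with
n spikes the rim of the wound is swept after only 2 pi / n of rotation,
which is what makes fractional-turn windows informative. What passing
desk-scale tests show is the qualitative mechanism — rotation-dependent
wound growth and enhanced transmembrane transport, with the expected
ordering across conditions and the two-regime (plateau, then growth)
transport kinetics — not the quantitative pore kinetics of the
full-scale system, which has hundreds of times more lipids, a much
larger particle, and multi-turn trajectories.

## What the synthetic systems do not capture

The builders emulate the simulated study conditions, not real
membranes: single-species lipids, no cholesterol or asymmetry, no
explicit solvent (so no hydrodynamic flows around the spinning
particle), phenomenological adhesion instead of discrete
ligand–receptor bonds, and a rigid particle whose rotation rate is
imposed rather than arising from a torque balance. Passing tests
therefore validate the model's internal mechanics and estimators, not
quantitative agreement with experiments.

## Known limitations

* Desk-scale K_A overshoots the full-scale reference (see above); the
  full 200 x 200 sigma system is supported by the same code but is a
  cluster-sized job.
* The Berendsen-type barostat detail of the original protocol is not
  fully specified upstream; the implementation here (weak coupling with
  optional stochastic rescaling) matches its stated contract — zero
  in-plane pressure with a 5-tau time constant — but not necessarily
  its exact update rule.
* Pore detection on a 2-sigma grid cannot resolve defects smaller than
  about a grid cell; reported pore areas are threshold- and
  grid-dependent (both recorded in outputs).
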