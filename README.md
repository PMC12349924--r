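# spinpore

Coarse-grained molecular dynamics of a lipid bilayer perturbed by a
rotating spiky nanoparticle, in R (with a compiled Rcpp core).

Magnetically driven spiky nanoparticles ("nanorobots") pressed against a
cell membrane and rotated at a prescribed frequency can open transient
pores and dramatically enhance transmembrane transport of small cargo.
`spinpore` implements the standard solvent-free three-bead lipid model
used to study this mechanism — WCA excluded volume, a cosine-squared
tail–tail attraction replacing solvent, FENE bonds and a harmonic
head–tail straightening spring, plus a truncated Lennard-Jones
nanoparticle–membrane attraction — together with everything needed to
run and analyse the simulations:

* builders for planar bilayers, rigid spiky particles with sampled spike
  lengths and apex angles, and cargo nanoparticles;
* a BAOAB Langevin integrator (timestep 0.005 tau, thermostat time
  constant 0.5 tau, T = 1.1 epsilon/kB) with an in-plane weak-coupling
  barostat for the tensionless-membrane ensemble, deterministic
  counter-based noise, and exact prescribed kinematics for the rigid
  particle (rotation about the membrane normal at f = 1/5000 or
  1/15000 tau^-1 in the reference study; traversal and
  indentation ramps);
* estimators for the membrane constants and the mechanistic
  observables: bending stiffness from the height-fluctuation spectrum
  (`<|h_q|^2> = kB T / (A (kappa q^4 + sigma q^2))`), stretching modulus
  from projected-area fluctuations (`K_A = kB T <A> / Var(A)`), lipid
  diffusion from MSD, lipid number-density maps, pore areas
  (thresholded, 4-connected components) and penetrated-cargo counts;
* the reduced-unit/SI mapping (sigma = 1 nm, tau = 2 ns,
  epsilon = 3.89e-21 J from matching thickness, diffusion and
  temperature).

Reference values for the model: kappa = 7.8 epsilon,
K_A = 26.4 epsilon/sigma^2, D = 1e-2 sigma^2/tau.

## Worked example

A shortened tensionless-membrane calibration on the standard
20 x 20-lipid-per-leaflet patch (about five minutes on one core; the
analysis-grade segment lengths live in `analysis/02_calibration.R`):

```r
library(spinpore)

cal <- calibrate_membrane(nx = 20, n_equil = 20000L, n_area = 50000L,
                          n_spectrum = 60000L, seed = 1)
cat(sprintf("kappa = %.1f eps, K_A = %.1f eps/sigma^2, D = %.4f sigma^2/tau\n",
            cal$kappa, cal$K_A, cal$D_lipid))
#> kappa = 7.6 eps, K_A = 33.2 eps/sigma^2, D = 0.0061 sigma^2/tau
```

`kappa` is the bending stiffness from the low-q undulation spectrum of
the fixed-area production segment (the reference full-scale value is
7.8 epsilon); `K_A` is the area-compressibility modulus from the
barostatted segment's area fluctuations — small patches read stiffer
than the full-scale 26.4 because they support few undulation modes —
and `D` is the lipid lateral diffusion coefficient (reference 1e-2).

The four-condition transport study (free-diffusion control,
static-drive control, rotation at 1/15000 and 1/5000 tau^-1) is driven by
`run_condition()` / `pipeline()`; see `analysis/03_robot_conditions.R`.

## Analysis workflow

Numbered drivers under `analysis/` reproduce the study end to end,
writing tables under `results/`:

1. `01_units.R` — the SI interpretation of the reduced units.
2. `02_calibration.R` — kappa, K_A, D at desk scale (20 x 20 lipids per
   leaflet).
3. `03_robot_conditions.R` — pore area and penetrated-cargo counts
   across the four conditions, three replicas each.

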