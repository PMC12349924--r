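#' Force-field constants
#'
#' All interaction constants of the model, in reduced units. The defaults
#' are the calibrated set: excluded-volume lengths 0.95 sigma
#' (head–head/head–tail) and 1.0 sigma (tail–tail), cosine attraction with
#' `rc = 2^(1/6)` and `wc = 1.7`, FENE bonds `k = 30, r_inf = 1.5`,
#' straightening spring `k = 10` with rest length 4 sigma, and a 0.2-depth
#' Lennard-Jones nanoparticle–membrane attraction with length
#' `b_np = 2^(7/6)` truncated at `3 b_np`.
#'
#' `paper_literal = TRUE` selects the variant with repulsion strength
#' 0.01 and no truncation shift. That variant is retained for
#' documentation and comparison; it does not hold a bilayer together at
#' the working temperature and is not used by the builders or the
#' pipeline.
#'
#' @param ... named overrides of any default listed below.
#' @param paper_literal use the weak unshifted repulsion variant.
#' @return a named list of class `forcefield_params`.
#' @export
forcefield_params <- function(..., paper_literal = FALSE) {
  p <- list(
    b_head_head = 0.95,
    b_head_tail = 0.95,
    b_tail_tail = 1.0,
    eps_rep = 1.0,
    rep_shifted = TRUE,
    eps_cos = 1.0,
    rc = 2^(1 / 6),
    wc = 1.7,
    k_fene = 30,
    r_inf = 1.5,
    k_bend = 10,
    r0_bend = 4,
    eps_np = 0.2,
    b_np = 2^(7 / 6),
    rcut_np = 3 * 2^(7 / 6),
    eps_receptor = 2.0,
    b_cargo = 2.0)
  if (paper_literal) {
    p$eps_rep <- 0.01
    p$rep_shifted <- FALSE
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("forcefield_params: unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$rc > 0, p$wc > 0, p$r_inf > 0, p$rcut_np > p$b_np,
            p$b_head_head > 0, p$b_tail_tail > 0, p$k_fene > 0)
  class(p) <- c("forcefield_params", "list")
  p
}

#' Simulation protocol parameters
#'
#' Integration and ensemble settings, in reduced units. Defaults follow
#' the working protocol: timestep 0.005 tau, Langevin thermostat time
#' constant 0.5 tau (100 timesteps), in-plane barostat time constant
#' 5.0 tau (1000 timesteps) targeting zero lateral pressure, temperature
#' 1.1 epsilon/kB, out-of-plane box length 400 sigma, cargo diameter
#' 2 sigma. The two study rotation frequencies are 1/5000 and
#' 1/15000 tau^-1.
#'
#' `baro_compressibility` is the weak-coupling compressibility prefactor
#' (sigma^3/epsilon); with the default box it makes the area relaxation
#' time comparable to `barostat_tc`. `baro_stochastic = TRUE` adds the
#' fluctuation term of the stochastic cell-rescaling form so projected-area
#' fluctuations are canonical (required by the area-fluctuation estimator
#' of the stretching modulus).
#'
#' @param ... named overrides of any default.
#' @return a named list of class `protocol_params`.
#' @export
protocol_params <- function(...) {
  p <- list(
    dt = 0.005,
    thermostat_tc = 0.5,
    barostat_tc = 5.0,
    temperature = 1.1,
    box_z = 400,
    n_steps = 10000L,
    seed = 1L,
    rotation_frequency = 0,
    robot_enabled = FALSE,
    robot_static = FALSE,
    robot_axis = c(0, 0, 1),
    robot_center_velocity = c(0, 0, 0),
    cargo_count = 100L,
    cargo_diameter = 2,
    receptor_fraction = 0.1,
    thermostat = TRUE,
    barostat = TRUE,
    baro_compressibility = 15,
    baro_stochastic = TRUE,
    baro_target = 0,
    baro_max_step = 0.002,
    fix_membrane_com_z = FALSE,
    skin = 0.4,
    sample_every = 50L,
    frame_every = 500L)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("protocol_params: unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$dt > 0, p$dt <= 0.005 + 1e-12, p$thermostat_tc > 0,
            p$temperature > 0, p$box_z > 0, p$cargo_diameter > 0)
  if (p$barostat && p$barostat_tc < 10 * p$dt)
    stop("protocol_params: barostat_tc must be at least 10 * dt")
  class(p) <- c("protocol_params", "list")
  p
}

#' Spiky-robot geometry
#'
#' Geometry of the rigid spiky particle: a spherical bead shell of radius
#' `core_radius` carrying `n_spikes` tapered conical spikes whose lengths
#' and apex (tip) angles are drawn uniformly from the configured ranges;
#' spike directions are near-uniform on the sphere. The measured
#' morphology of the fabricated particles motivates the apex-angle default
#' (5–20 degrees); lengths are expressed relative to the core since the
#' simulated particle is scaled down with the membrane patch.
#'
#' @param core_radius core shell radius, sigma.
#' @param n_spikes number of spikes.
#' @param spike_length_range `c(min, max)` spike lengths, sigma.
#' @param apex_angle_range `c(min, max)` full tip angles, degrees.
#' @param bead_spacing spacing of the beads tiling the surface, sigma
#'   (at most 1 for a contiguous surface).
#' @param seed RNG seed controlling the sampled morphology.
#' @return a list of class `robot_geometry`.
#' @export
robot_geometry <- function(core_radius = 5, n_spikes = 12,
                           spike_length_range = c(10, 20),
                           apex_angle_range = c(5, 20),
                           bead_spacing = 1, seed = 1L) {
  stopifnot(length(spike_length_range) == 2, length(apex_angle_range) == 2,
            bead_spacing > 0, bead_spacing <= 1, n_spikes >= 0)
  if (core_radius < bead_spacing)
    stop("robot_geometry: core_radius must be at least bead_spacing")
  structure(list(core_radius = core_radius, n_spikes = as.integer(n_spikes),
                 spike_length_range = spike_length_range,
                 apex_angle_range = apex_angle_range,
                 bead_spacing = bead_spacing, seed = as.integer(seed)),
            class = c("robot_geometry", "list"))
}
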