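#' Run a molecular-dynamics trajectory
#'
#' Integrates a [particle_system()] with the compiled BAOAB Langevin
#' engine. The thermostat uses friction `1/thermostat_tc` with matched
#' noise; the in-plane barostat rescales the lateral box (and mobile-bead
#' x, y coordinates) toward zero lateral pressure, with an optional
#' stochastic rescaling term that makes area fluctuations canonical.
#' Robot beads are never integrated: their positions follow the exact
#' prescribed kinematics `angle = angle0 + 2 pi f (t - t0)` about the
#' stored axis (the angle accumulates continuously across phases), plus
#' an optional constant-velocity center translation
#' (`protocol$robot_center_velocity`) used for indentation and traversal
#' ramps.
#'
#' Positions are unwrapped throughout (periodicity enters only through
#' minimum-image distances), so displacement-based observables need no
#' image bookkeeping.
#'
#' @param system a [particle_system()].
#' @param protocol a [protocol_params()]; `n_steps`, `dt`, thermostat and
#'   barostat settings, rotation frequency and sampling cadences are read
#'   from it.
#' @param forcefield a [forcefield_params()].
#' @param t0 simulation time at the first step, tau.
#' @param brute_neighbors use the all-pairs reference path instead of the
#'   cell/Verlet list (testing only).
#' @return an object of class `trajectory`: frame positions (unwrapped),
#'   per-frame box and time, sampled series (kinetic temperature,
#'   potential energy, projected area, lateral pressure, tension, net
#'   force on the robot), the final [particle_system()], and the run
#'   status (`"ok"`, `"fene_overstretch"` or `"barostat_instability"`;
#'   on failure the frames collected so far are preserved).
#' @export
run_simulation <- function(system, protocol = protocol_params(),
                           forcefield = forcefield_params(), t0 = 0,
                           brute_neighbors = FALSE) {
  stopifnot(inherits(system, "particle_system"))
  rg <- system$rigid
  f_rot <- if (isTRUE(protocol$robot_static)) 0 else protocol$rotation_frequency
  opts <- list(
    n_steps = as.numeric(protocol$n_steps),
    dt = protocol$dt,
    thermostat = isTRUE(protocol$thermostat),
    thermostat_tc = protocol$thermostat_tc,
    temperature = protocol$temperature,
    barostat = isTRUE(protocol$barostat),
    barostat_tc = protocol$barostat_tc,
    baro_compressibility = protocol$baro_compressibility,
    baro_stochastic = isTRUE(protocol$baro_stochastic),
    baro_target = protocol$baro_target,
    baro_max_step = protocol$baro_max_step,
    fix_membrane_com_z = isTRUE(protocol$fix_membrane_com_z),
    sample_every = as.numeric(protocol$sample_every),
    frame_every = as.numeric(protocol$frame_every),
    seed = as.numeric(protocol$seed),
    rotation_frequency = f_rot,
    t0 = t0,
    skin = protocol$skin,
    brute_neighbors = isTRUE(brute_neighbors),
    robot_indices = if (is.null(rg)) integer() else as.integer(rg$indices),
    robot_reference = if (is.null(rg)) matrix(0, 0, 3) else rg$reference,
    robot_center = if (is.null(rg)) c(0, 0, 0) else rg$center,
    robot_axis = if (is.null(rg)) c(0, 0, 1) else rg$axis,
    robot_center_velocity = as.numeric(protocol$robot_center_velocity),
    robot_angle0 = if (is.null(rg) || is.null(rg$angle)) 0 else rg$angle)
  res <- cpp_run(system$positions, system$velocities, kind_code(system$kinds),
                 system$bonds, system$box, unclass(forcefield), opts)
  nf <- as.integer(res$n_frames)
  frames <- res$frames
  d <- dim(frames)
  frames <- frames[, , seq_len(nf), drop = FALSE]
  final <- particle_system(res$positions, res$velocities, system$kinds,
                           system$bonds, system$molecule_id, res$box,
                           system$rigid)
  if (!is.null(final$rigid)) {
    angle0 <- if (is.null(system$rigid$angle)) 0 else system$rigid$angle
    final$rigid$angle <- angle0 + 2 * pi * f_rot * res$steps_done * protocol$dt
    final$rigid$center <- final$rigid$center +
      protocol$robot_center_velocity * res$steps_done * protocol$dt
  }
  traj <- structure(list(
    frames = frames,                       # dim (3, N, n_frames), unwrapped
    frame_box = res$frame_box[seq_len(nf), , drop = FALSE],
    frame_time = res$frame_time[seq_len(nf)],
    frame_step = res$frame_step[seq_len(nf)],
    kinds = system$kinds,
    molecule_id = system$molecule_id,
    series = as.data.frame(res$series),
    final = final,
    status = res$status,
    steps_done = res$steps_done,
    protocol = protocol,
    forcefield = forcefield), class = "trajectory")
  if (res$status == "fene_overstretch")
    warning(sprintf("FENE bond overstretched at step %.0f (beads %d-%d); run aborted, %d frames kept",
                    res$bad_step, res$bad_bond[1], res$bad_bond[2], nf))
  if (res$status == "barostat_instability")
    warning("barostat rescale factor left [0.9, 1.1]; run aborted, frames kept")
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames of %d beads, %.0f steps (%.1f tau), status '%s'\n",
              n_frames(x), dim(x$frames)[2], x$steps_done,
              x$steps_done * x$protocol$dt, x$status))
  invisible(x)
}

#' Trajectory accessors
#'
#' @param traj a trajectory.
#' @param i frame index.
#' @return `frame_positions()` returns an N x 3 matrix of unwrapped
#'   positions; `n_frames()` the number of stored frames.
#' @export
frame_positions <- function(traj, i) {
  t(traj$frames[, , i])
}

#' @rdname frame_positions
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Advance a system by Langevin steps
#'
#' Thin wrapper over the engine for stepping a system without barostat or
#' frame output: one (or a few) BAOAB steps with friction `1/tc`. With
#' `thermostat = FALSE` the step reduces to velocity-Verlet NVE
#' integration.
#'
#' @param system a [particle_system()].
#' @param dt timestep, tau (at most 0.005).
#' @param tc thermostat time constant, tau.
#' @param temperature target temperature, epsilon/kB.
#' @param n_steps number of steps.
#' @param seed noise-stream seed.
#' @param thermostat logical.
#' @param forcefield a [forcefield_params()].
#' @return the advanced [particle_system()].
#' @export
langevin_step <- function(system, dt = 0.005, tc = 0.5, temperature = 1.1,
                          n_steps = 1L, seed = 1L, thermostat = TRUE,
                          forcefield = forcefield_params()) {
  pr <- protocol_params(dt = dt, thermostat_tc = tc, temperature = temperature,
                        n_steps = as.integer(n_steps), seed = seed,
                        thermostat = thermostat, barostat = FALSE,
                        sample_every = 0L, frame_every = 0L)
  run_simulation(system, pr, forcefield)$final
}

#' Instantaneous in-plane pressure and membrane tension
#'
#' Virial-based per-axis lateral pressure
#' `P_aa = (sum m v_a^2 + W_aa) / V` over the full box volume, and the
#' membrane tension under the convention
#' `Sigma = -(P_xx + P_yy)/2 * L_z` (the normal pressure of a self-bound
#' membrane in vacuum is zero on average, so zero lateral pressure is the
#' tensionless state).
#'
#' @param system a [particle_system()].
#' @param forcefield a [forcefield_params()].
#' @return list with `P_xx`, `P_yy`, `tension`.
#' @export
inplane_pressure <- function(system, forcefield = forcefield_params()) {
  ef <- cpp_energy_forces(system$positions, kind_code(system$kinds),
                          system$bonds, system$box, unclass(forcefield))
  mob <- !is_robot_kind(system$kinds)
  V <- prod(system$box)
  kxx <- sum(system$velocities[mob, 1]^2)
  kyy <- sum(system$velocities[mob, 2]^2)
  pxx <- (kxx + ef$virial[1]) / V
  pyy <- (kyy + ef$virial[2]) / V
  list(P_xx = pxx, P_yy = pyy, tension = -(pxx + pyy) / 2 * system$box[3])
}

#' One deterministic in-plane Berendsen rescale
#'
#' Applies a single weak-coupling update toward the target lateral
#' pressure: lateral box lengths and mobile-bead x, y coordinates are
#' scaled by `mu = exp(dlnA/2)` with
#' `dlnA = (beta_T / tc) (P_lat - target) dt`; z and the rigid robot
#' reference are untouched. Compressive lateral pressure (positive
#' `P_lat`) expands the box.
#'
#' @param system a [particle_system()].
#' @param target target lateral pressure, epsilon/sigma^3.
#' @param tc barostat time constant, tau.
#' @param dt timestep, tau.
#' @param compressibility weak-coupling prefactor, sigma^3/epsilon.
#' @param forcefield a [forcefield_params()].
#' @return the rescaled [particle_system()].
#' @export
berendsen_rescale <- function(system, target = 0, tc = 5, dt = 0.005,
                              compressibility = 15,
                              forcefield = forcefield_params()) {
  pr <- inplane_pressure(system, forcefield)
  plat <- (pr$P_xx + pr$P_yy) / 2
  mu <- exp(0.5 * (compressibility / tc) * (plat - target) * dt)
  if (mu < 0.9 || mu > 1.1)
    stop(sprintf("berendsen_rescale: scale factor %.3f outside [0.9, 1.1] (instability)", mu))
  mob <- !is_robot_kind(system$kinds)
  system$positions[mob, 1:2] <- system$positions[mob, 1:2] * mu
  system$box[1:2] <- system$box[1:2] * mu
  system
}

#' Place the rigid robot at its prescribed angle
#'
#' Exact kinematic driving: the stored body-frame geometry is rotated by
#' `2 pi f t` about the axis through the body center and written into
#' the bead positions (`t` measured from rotation onset). `f = 0`
#' reproduces the static-robot control.
#'
#' @param system a [particle_system()] with a rigid group.
#' @param f rotation frequency, 1/tau.
#' @param t simulation time, tau.
#' @param axis optional unit axis override.
#' @return the system with robot beads repositioned.
#' @export
drive_robot <- function(system, f, t, axis = NULL) {
  rg <- system$rigid
  if (is.null(rg) || length(rg$indices) == 0)
    stop("drive_robot: system has no rigid robot group")
  ax <- if (is.null(axis)) rg$axis else axis
  if (sqrt(sum(ax^2)) <= 0) stop("drive_robot: zero-length rotation axis")
  ang <- 2 * pi * f * t
  system$positions[rg$indices, ] <-
    cpp_rotate_about_axis(rg$reference, rg$center, ax, ang)
  system
}

#' Total potential energy and forces
#'
#' Evaluates all nonbonded and bonded interactions for a system, by the
#' production cell/Verlet path or the brute-force all-pairs reference.
#'
#' @param system a [particle_system()].
#' @param forcefield a [forcefield_params()].
#' @param brute use the all-pairs reference path.
#' @return list with `energy` (epsilon), `forces` (N x 3, epsilon/sigma)
#'   and the per-axis pair virial.
#' @export
energy_forces <- function(system, forcefield = forcefield_params(), brute = FALSE) {
  cpp_energy_forces(system$positions, kind_code(system$kinds), system$bonds,
                    system$box, unclass(forcefield), brute = brute)
}

#' Kinetic temperature of the mobile beads
#'
#' @param system a [particle_system()].
#' @return epsilon/kB.
#' @export
kinetic_temperature <- function(system) {
  mob <- !is_robot_kind(system$kinds)
  sum(system$velocities[mob, ]^2) / (3 * sum(mob))
}
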