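#' Membrane property calibration from a tensionless simulation
#'
#' Runs the full calibration workflow on a freshly built bilayer and
#' returns the three membrane constants the model is characterised by:
#'
#' 1. equilibration under the Langevin thermostat and the in-plane
#'    barostat (tensionless ensemble);
#' 2. a barostatted production segment whose projected-area series gives
#'    the stretching modulus `K_A = kB T <A> / Var(A)` and the
#'    tensionless mean area;
#' 3. a constant-area production segment at that mean area whose
#'    height-fluctuation spectrum gives the bending stiffness kappa
#'    (tension-corrected low-q fit, see [bending_stiffness()]) and whose
#'    head-bead lateral MSD gives the lipid diffusion coefficient.
#'
#' The spectrum is collected at fixed area because the weak-coupling
#' area dynamics measurably distort the softest undulation modes of a
#' small patch, while `Var(A)` requires the barostatted ensemble; the
#' two segments therefore use the two ensembles where each estimator is
#' valid.
#'
#' @param nx lipids per leaflet row (patch is `nx` x `nx` per leaflet).
#' @param n_equil equilibration steps.
#' @param n_area barostatted production steps (area fluctuations).
#' @param n_spectrum constant-area production steps (spectrum + MSD).
#' @param seed base seed; the three segments use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param protocol base [protocol_params()] (temperature, timestep,
#'   coupling constants).
#' @param forcefield a [forcefield_params()].
#' @param frame_every frame cadence of the spectrum segment, steps.
#' @param msd_fit_window lag-time window (tau) for the diffusion fit;
#'   default spans the diffusive regime of the spectrum segment.
#' @return list with `kappa`, `kappa_se`, `sigma_fluct`, `K_A`, `K_A_se`,
#'   `D_lipid`, `mean_area`, `area_per_lipid`, `mean_tension`,
#'   `mean_T_kin`, and the two production trajectories.
#' @export
calibrate_membrane <- function(nx = 20, n_equil = 30000L, n_area = 100000L,
                               n_spectrum = 120000L, seed = 1L,
                               protocol = protocol_params(),
                               forcefield = forcefield_params(),
                               frame_every = 400L, msd_fit_window = NULL) {
  sys <- build_bilayer(nx, nx, area_per_lipid = 1.2, box_z = protocol$box_z,
                       temperature = protocol$temperature, seed = seed)
  pr_eq <- protocol
  pr_eq$n_steps <- as.integer(n_equil); pr_eq$seed <- seed
  pr_eq$sample_every <- 100L; pr_eq$frame_every <- 0L
  eq <- run_simulation(sys, pr_eq, forcefield)
  if (eq$status != "ok") stop("calibrate_membrane: equilibration failed: ", eq$status)

  pr_area <- protocol
  pr_area$n_steps <- as.integer(n_area); pr_area$seed <- seed + 1L
  pr_area$sample_every <- 25L; pr_area$frame_every <- 0L
  tr_area <- run_simulation(eq$final, pr_area, forcefield,
                            t0 = n_equil * protocol$dt)
  if (tr_area$status != "ok") stop("calibrate_membrane: area segment failed: ", tr_area$status)
  area <- tr_area$series$area
  ka <- stretching_modulus(area, temperature = protocol$temperature)

  sys_nvt <- set_projected_area(tr_area$final, ka$mean_area)
  pr_spec <- protocol
  pr_spec$barostat <- FALSE
  pr_spec$n_steps <- as.integer(n_spectrum); pr_spec$seed <- seed + 2L
  pr_spec$sample_every <- 100L
  pr_spec$frame_every <- as.integer(frame_every)
  tr_spec <- run_simulation(sys_nvt, pr_spec, forcefield,
                            t0 = (n_equil + n_area) * protocol$dt)
  if (tr_spec$status != "ok") stop("calibrate_membrane: spectrum segment failed: ", tr_spec$status)

  ks <- bending_stiffness(tr_spec, min_frames = 50,
                          temperature = protocol$temperature)
  m2 <- msd(tr_spec, "HEAD", axis_mask = c(TRUE, TRUE, FALSE),
            origin_stride = 2L)
  dd <- diffusion_coefficient(m2, dimensionality = 2,
                              fit_window = msd_fit_window)

  list(kappa = ks$kappa, kappa_se = ks$se, sigma_fluct = ks$sigma_fluct,
       spectrum_slope = ks$slope,
       K_A = ka$K_A, K_A_se = ka$se,
       D_lipid = dd$D,
       mean_area = ka$mean_area,
       area_per_lipid = ka$mean_area / (nx * nx),   # per leaflet lipid
       mean_tension = mean(tr_spec$series$tension),
       mean_T_kin = mean(tr_spec$series$T_kin),
       trajectory_area = tr_area, trajectory_spectrum = tr_spec)
}
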