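#' Run one experimental condition
#'
#' Builds the scene for a named condition, equilibrates it under the
#' tensionless barostat with the robot held static, then runs production
#' with the condition's rotation frequency and computes the observable
#' series: pore area (against the intact reference density of the first
#' production frame), instantaneous and cumulative penetrated-cargo
#' counts, and the transmembrane cargo MSD.
#'
#' For the robot conditions the production window contains the membrane
#' traversal itself: after tensionless relaxation with the particle at
#' contact, the rigid body is driven downward at constant speed so that
#' it pierces, crosses and exits the bilayer within the first
#' `traverse_frac` of the window — rotating at the condition's frequency
#' throughout, or not at all for the static-drive control, which is
#' pressed through identically. Production runs at the relaxed fixed
#' area for every condition, so the traversal wound is not simply
#' rescaled away and the conditions share matched ensembles; transport
#' is then cargo crossing through the wound. The intact reference
#' density for pore detection is taken from the relaxed pre-traversal
#' membrane.
#'
#' @param condition one of `"no_robot"`, `"static"`, `"f_15000"`
#'   (f = 1/15000 tau^-1), `"f_5000"` (f = 1/5000 tau^-1).
#' @param protocol a [protocol_params()]; `n_steps` is the production
#'   length.
#' @param geometry a [robot_geometry()].
#' @param nx,ny,area_per_lipid bilayer size.
#' @param n_equil membrane relaxation steps before production.
#' @param traverse_frac fraction of the production window over which the
#'   body crosses the membrane.
#' @param clearance distance below the lower head plane at which the
#'   body's top bead counts as having exited, sigma.
#' @param seed replica seed (builder and noise stream).
#' @param forcefield a [forcefield_params()].
#' @param pore_cell,pore_threshold pore-detection grid cell (sigma) and
#'   threshold fraction.
#' @param margin penetration margin below the lower head plane, sigma.
#' @return list with `condition`, `observables` (long data.frame),
#'   `summary` (one-row data.frame), and the production `trajectory`.
#' @export
run_condition <- function(condition, protocol = protocol_params(),
                          geometry = robot_geometry(), nx = 16, ny = nx,
                          area_per_lipid = 1.2, n_equil = 5000L,
                          traverse_frac = 0.55, clearance = 2,
                          seed = protocol$seed,
                          forcefield = forcefield_params(),
                          pore_cell = 2, pore_threshold = 0.25, margin = 1) {
  condition <- match.arg(condition, c("no_robot", "static", "f_15000", "f_5000"))
  f <- switch(condition, no_robot = 0, static = 0,
              f_15000 = 1 / 15000, f_5000 = 1 / 5000)
  robot_on <- condition != "no_robot"
  pr_build <- protocol
  pr_build$robot_enabled <- robot_on
  pr_build$seed <- seed
  # a small patch must not translate bodily with the driven particle
  pr_build$fix_membrane_com_z <- TRUE
  scene <- assemble_scene(pr_build, geometry, nx = nx, ny = ny,
                          area_per_lipid = area_per_lipid, seed = seed)
  pr_eq <- pr_build
  pr_eq$n_steps <- as.integer(n_equil)
  pr_eq$rotation_frequency <- 0
  pr_eq$frame_every <- 0L
  eq <- run_simulation(scene, pr_eq, forcefield)
  if (eq$status != "ok") stop("run_condition: equilibration failed: ", eq$status)
  state <- eq$final
  t_now <- n_equil * protocol$dt
  # intact reference density from the relaxed membrane (pre-traversal)
  ref_density <- mean(lipid_density_map(eq$final$positions, eq$final$kinds,
                                        eq$final$box, cell = pore_cell))
  pr_prod <- pr_build
  pr_prod$rotation_frequency <- f
  pr_prod$robot_static <- condition == "static"
  pr_prod$seed <- seed + 1000L
  pr_prod$barostat <- FALSE
  if (robot_on) {
    # constant-speed traversal: the body's top bead clears the lower head
    # plane by `clearance` within the first traverse_frac of the window
    heads <- is_head_kind(state$kinds) & state$molecule_id > 0
    mid <- mean(state$positions[is_lipid_kind(state$kinds), 3])
    lower_head <- mean(state$positions[heads & state$positions[, 3] < mid, 3])
    top <- max(state$positions[is_robot_kind(state$kinds), 3])
    drop <- top - (lower_head - clearance)
    t_cross <- traverse_frac * protocol$n_steps * protocol$dt
    pr_prod$robot_center_velocity <- c(0, 0, -drop / t_cross)
  }
  traj <- run_simulation(state, pr_prod, forcefield, t0 = t_now)
  nf <- n_frames(traj)
  pore_total <- numeric(nf); pore_largest <- numeric(nf)
  for (i in seq_len(nf)) {
    dm <- lipid_density_map(frame_positions(traj, i), traj$kinds,
                            traj$frame_box[i, ], cell = pore_cell)
    pa <- pore_area(dm, pore_threshold, reference_density = ref_density)
    pore_total[i] <- pa$total; pore_largest[i] <- pa$largest
  }
  pen <- penetrated_series(traj, margin = margin)
  has_cargo <- any(traj$kinds == "CARGO")
  msd_z <- if (has_cargo && nf > 3)
    msd(traj, "CARGO", axis_mask = c(FALSE, FALSE, TRUE)) else NULL
  obs <- rbind(
    data.frame(series = "pore_area_total", time = traj$frame_time, value = pore_total),
    data.frame(series = "pore_area_largest", time = traj$frame_time, value = pore_largest),
    data.frame(series = "penetrated_instantaneous", time = pen$time, value = pen$instantaneous),
    data.frame(series = "penetrated_cumulative", time = pen$time, value = pen$cumulative),
    if (!is.null(msd_z))
      data.frame(series = "msd_z_cargo", time = msd_z$lag_time, value = msd_z$msd))
  last_q <- seq.int(max(1L, nf - nf %/% 4L), nf)
  summary <- data.frame(
    condition = condition, seed = seed,
    frequency = f, robot = robot_on,
    pore_area_final = pore_total[nf],
    pore_area_late_mean = mean(pore_total[last_q]),
    penetrated_final = pen$cumulative[nf],
    mean_tension = mean(traj$series$tension),
    mean_T_kin = mean(traj$series$T_kin))
  list(condition = condition, observables = obs, summary = summary, trajectory = traj)
}

#' Full pipeline over the study conditions
#'
#' Runs every requested condition and replica from one configuration,
#' writes per-condition observable CSVs, a summary table and a JSON
#' manifest under `out_dir`, and computes the membrane calibration
#' (bending stiffness, stretching modulus, lateral lipid diffusion) from
#' the first no-robot replica when that condition is present and long
#' enough.
#'
#' @param out_dir output directory (created if needed).
#' @param conditions character vector of condition names.
#' @param replicas replicas per condition; replica `i` uses seed
#'   `seed + i - 1`.
#' @param seed base seed.
#' @param protocol,geometry,forcefield see [run_condition()].
#' @param nx,area_per_lipid,n_equil,traverse_frac,clearance see
#'   [run_condition()].
#' @param calibrate compute kappa / K_A / D from the first no-robot run.
#' @param keep_trajectories also write per-run extended-XYZ files.
#' @return list with `summary` (data.frame), `calibration` (or NULL) and
#'   the paths written.
#' @export
pipeline <- function(out_dir,
                     conditions = c("no_robot", "static", "f_15000", "f_5000"),
                     replicas = 1L, seed = 1L,
                     protocol = protocol_params(),
                     geometry = robot_geometry(),
                     forcefield = forcefield_params(),
                     nx = 16, area_per_lipid = 1.2, n_equil = 5000L,
                     traverse_frac = 0.55, clearance = 2,
                     calibrate = TRUE, keep_trajectories = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); files <- character(); calib <- NULL
  for (cond in conditions) {
    for (r in seq_len(replicas)) {
      res <- run_condition(cond, protocol, geometry, nx = nx,
                           area_per_lipid = area_per_lipid,
                           n_equil = n_equil, traverse_frac = traverse_frac,
                           clearance = clearance, seed = seed + r - 1L,
                           forcefield = forcefield)
      obs <- res$observables
      obs$replica <- r
      fcsv <- file.path(out_dir, sprintf("observables_%s_r%d.csv", cond, r))
      write.csv(obs, fcsv, row.names = FALSE)
      files <- c(files, fcsv)
      row <- res$summary
      row$replica <- r
      rows[[length(rows) + 1L]] <- row
      if (calibrate && cond == "no_robot" && r == 1L) {
        traj <- res$trajectory
        calib <- tryCatch({
          ks <- bending_stiffness(traj, min_frames = 20)
          area <- traj$series$area[-seq_len(length(traj$series$area) %/% 4)]
          ka <- stretching_modulus(area, temperature = protocol$temperature)
          m2 <- msd(traj, "HEAD", axis_mask = c(TRUE, TRUE, FALSE))
          dd <- diffusion_coefficient(m2, dimensionality = 2)
          list(kappa = ks$kappa, kappa_se = ks$se,
               K_A = ka$K_A, K_A_se = ka$se,
               D_lipid = dd$D)
        }, error = function(e) {
          warning("pipeline: calibration skipped: ", conditionMessage(e))
          NULL
        })
      }
      if (keep_trajectories) {
        fx <- file.path(out_dir, sprintf("traj_%s_r%d.xyz", cond, r))
        write_xyz(res$trajectory, fx)
        files <- c(files, fx)
      }
    }
  }
  summary <- do.call(rbind, rows)
  if (!is.null(calib)) {
    summary$kappa <- calib$kappa; summary$K_A <- calib$K_A
    summary$D_lipid <- calib$D_lipid
  }
  fsum <- file.path(out_dir, "summary.csv")
  write.csv(summary, fsum, row.names = FALSE)
  files <- c(files, fsum)
  fman <- file.path(out_dir, "manifest.json")
  write_manifest(fman,
                 config = list(protocol = unclass(protocol),
                               forcefield = unclass(forcefield),
                               robot = unclass(geometry),
                               builder = list(nx = nx, area_per_lipid = area_per_lipid,
                                              n_equil = n_equil),
                               conditions = conditions, replicas = replicas),
                 seed = seed, files = files)
  list(summary = summary, calibration = calib, files = c(files, fman))
}
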