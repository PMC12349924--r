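test_that("thermostatted free particles equilibrate to the target temperature", {
  sys <- ideal_gas(400, 60, seed = 31)
  pr <- protocol_params(n_steps = 10000L, barostat = FALSE, seed = 32,
                        sample_every = 20L, frame_every = 0L)
  tr <- run_simulation(sys, pr)
  # mean kinetic energy per degree of freedom = T/2 within 3%
  tmean <- mean(tr$series$T_kin[-(1:50)])
  expect_equal(tmean, 1.1, tolerance = 0.03)
})

test_that("thermostat noise has zero mean momentum drift", {
  sys <- ideal_gas(300, 60, seed = 41)
  pr <- protocol_params(n_steps = 5000L, barostat = FALSE, seed = 42,
                        sample_every = 0L, frame_every = 0L)
  tr <- run_simulation(sys, pr)
  drift <- colMeans(tr$final$velocities)
  # standard error of the mean of 300 thermal velocities ~ sqrt(1.1/300) = 0.06
  expect_lt(max(abs(drift)), 4 * sqrt(1.1 / 300))
})

test_that("ideal-gas lateral pressure matches rho kB T", {
  sys <- ideal_gas(400, 40, seed = 51)
  pr <- protocol_params(n_steps = 10000L, barostat = FALSE, seed = 52,
                        sample_every = 20L, frame_every = 0L)
  tr <- run_simulation(sys, pr)
  rho <- 400 / 40^3
  p_expected <- rho * 1.1
  p_measured <- mean(tr$series$p_lateral[-(1:50)])
  expect_equal(p_measured, p_expected, tolerance = 0.05)
})

test_that("NVE integration conserves energy on a relaxed lipid patch", {
  sys <- build_bilayer(5, 5, seed = 61)    # 50 lipids
  pr_relax <- protocol_params(n_steps = 5000L, seed = 62, sample_every = 0L,
                              frame_every = 0L)
  relaxed <- run_simulation(sys, pr_relax)$final
  pr_nve <- protocol_params(n_steps = 10000L, thermostat = FALSE,
                            barostat = FALSE, seed = 63,
                            sample_every = 10L, frame_every = 0L)
  tr <- run_simulation(relaxed, pr_nve)
  expect_equal(tr$status, "ok")
  n_mob <- nrow(relaxed$positions)
  etot <- tr$series$pe + 1.5 * n_mob * tr$series$T_kin
  drift <- abs(etot[length(etot)] - etot[1]) / abs(mean(etot))
  expect_lt(drift, 1e-3)
})

test_that("cell-list and brute-force neighbour paths give the same trajectory", {
  sys <- build_bilayer(5, 5, seed = 71)
  pr <- protocol_params(n_steps = 100L, seed = 72, sample_every = 0L,
                        frame_every = 0L)
  a <- run_simulation(sys, pr)
  b <- run_simulation(sys, pr, brute_neighbors = TRUE)
  expect_lt(max(abs(a$final$positions - b$final$positions)), 1e-8)
})

test_that("runs are deterministic given the seed", {
  sys <- build_bilayer(6, 6, seed = 81)
  pr <- protocol_params(n_steps = 500L, seed = 82, sample_every = 100L,
                        frame_every = 250L)
  a <- run_simulation(sys, pr)
  b <- run_simulation(sys, pr)
  expect_identical(a$final$positions, b$final$positions)
  expect_identical(a$series, b$series)
})

test_that("zero steps returns the input as a single-frame trajectory", {
  sys <- build_bilayer(4, 4, seed = 91)
  pr <- protocol_params(n_steps = 0L, seed = 92)
  tr <- run_simulation(sys, pr)
  expect_equal(n_frames(tr), 1L)
  expect_equal(frame_positions(tr, 1), unname(sys$positions))
})

test_that("FENE overstretch aborts the run and identifies the bond", {
  # two bonded beads flying apart faster than the thermostat can stop
  pos <- rbind(c(5, 5, 5), c(6.2, 5, 5))
  vel <- rbind(c(-30, 0, 0), c(30, 0, 0))
  sys <- particle_system(pos, vel, c("TAIL1", "TAIL2"),
                         rbind(c(1L, 2L, 1L)), c(1L, 1L), c(20, 20, 20))
  pr <- protocol_params(n_steps = 200L, barostat = FALSE, seed = 2,
                        sample_every = 0L, frame_every = 0L)
  expect_warning(tr <- run_simulation(sys, pr), "overstretch")
  expect_equal(tr$status, "fene_overstretch")
  expect_lt(tr$steps_done, 200)
})

test_that("overdamped limit stays finite and still thermalises", {
  pos <- rbind(c(5, 5, 5), c(5.97, 5, 5))
  sys <- particle_system(pos, matrix(0, 2, 3), c("TAIL1", "TAIL2"),
                         rbind(c(1L, 2L, 1L)), c(1L, 1L), c(20, 20, 20))
  pr <- protocol_params(n_steps = 5000L, thermostat_tc = 0.01,  # gamma = 100
                        barostat = FALSE, seed = 3, sample_every = 10L,
                        frame_every = 0L)
  tr <- run_simulation(sys, pr)
  expect_equal(tr$status, "ok")
  expect_true(all(is.finite(tr$final$positions)))
  expect_equal(mean(tr$series$T_kin[-(1:100)]), 1.1, tolerance = 0.15)
})

test_that("in-plane pressure is symmetric for mirrored configurations", {
  sys <- random_config(120, c(10, 10, 10), seed = 101)
  pr <- inplane_pressure(sys)
  mirrored <- sys
  mirrored$positions <- sys$positions[, c(2, 1, 3)]
  mirrored$velocities <- sys$velocities[, c(2, 1, 3)]
  pm <- inplane_pressure(mirrored)
  expect_equal(pr$P_xx, pm$P_yy, tolerance = 1e-10)
  expect_equal(pr$P_yy, pm$P_xx, tolerance = 1e-10)
})

test_that("berendsen rescale has the fixed point and sign convention", {
  # static beads far apart: zero pressure, scale exactly 1
  pos <- rbind(c(2, 2, 2), c(8, 8, 8))
  sys <- particle_system(pos, matrix(0, 2, 3), c("HEAD", "HEAD"), NULL,
                         c(0L, 0L), c(12, 12, 12))
  out <- berendsen_rescale(sys)
  expect_equal(out$box, sys$box)
  expect_equal(out$positions, sys$positions)
  # compressed pair: positive lateral pressure, box must expand
  p <- forcefield_params()
  sys2 <- particle_system(rbind(c(5, 5, 5), c(5 + 0.9 * p$b_head_head, 5, 5)),
                          matrix(0, 2, 3), c("HEAD", "HEAD"), NULL, c(0L, 0L),
                          c(12, 12, 12))
  out2 <- berendsen_rescale(sys2, tc = 5, dt = 0.005, compressibility = 15)
  expect_gt(out2$box[1], sys2$box[1])
  expect_equal(out2$box[3], sys2$box[3])     # z untouched
})

test_that("robot kinematics are exact: periodicity, half turn, static control", {
  g <- robot_geometry(core_radius = 2, n_spikes = 4,
                      spike_length_range = c(2, 3), seed = 5)
  pr <- protocol_params(robot_enabled = TRUE, cargo_count = 0L,
                        receptor_fraction = 0)
  sc <- assemble_scene(pr, g, nx = 10, seed = 5)
  idx <- sc$rigid$indices
  f <- 1 / 5000
  # f = 0: positions constant
  s0 <- drive_robot(sc, 0, t = 12345)
  expect_equal(s0$positions[idx, ], sc$positions[idx, ], tolerance = 1e-12)
  # full turn recovers the reference geometry
  s1 <- drive_robot(sc, f, t = 1 / f)
  expect_lt(max(abs(s1$positions[idx, ] - sc$positions[idx, ])), 1e-10)
  # half turn equals a 180-degree rotation about z through the center
  s2 <- drive_robot(sc, f, t = 2500)
  ref <- sc$rigid$reference
  ctr <- sc$rigid$center
  expected <- cbind(ctr[1] - ref[, 1], ctr[2] - ref[, 2], ctr[3] + ref[, 3])
  expect_lt(max(abs(s2$positions[idx, ] - expected)), 1e-10)
  # rotation-matrix oracle for an arbitrary axis and angle
  ax <- c(1, 2, 3) / sqrt(14); th <- 0.7
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  got <- spinpore:::cpp_rotate_about_axis(ref, ctr, ax, th)
  want <- sweep(ref %*% t(R), 2, ctr, "+")
  expect_lt(max(abs(got - want)), 1e-10)
  expect_error(drive_robot(sc, f, t = 1, axis = c(0, 0, 0)), "zero")
})

test_that("driven robot in a run follows the prescribed angle exactly", {
  g <- robot_geometry(core_radius = 2, n_spikes = 3,
                      spike_length_range = c(2, 3), seed = 6)
  pr <- protocol_params(robot_enabled = TRUE, cargo_count = 0L,
                        receptor_fraction = 0,
                        rotation_frequency = 1 / 200,   # fast spin for the check
                        n_steps = 2000L, seed = 7,
                        sample_every = 0L, frame_every = 1000L)
  sc <- assemble_scene(pr, g, nx = 10, seed = 6)
  tr <- run_simulation(sc, pr)
  idx <- sc$rigid$indices
  t_end <- 2000 * pr$dt
  expected <- drive_robot(sc, pr$rotation_frequency, t_end)$positions[idx, ]
  expect_lt(max(abs(tr$final$positions[idx, ] - expected)), 1e-9)
  # static-robot flag overrides the frequency
  pr2 <- pr; pr2$robot_static <- TRUE; pr2$n_steps <- 300L
  tr2 <- run_simulation(sc, pr2)
  expect_equal(tr2$final$positions[idx, ], unname(sc$positions[idx, ]),
               tolerance = 1e-12)
})
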