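test_that("bilayer builder produces the right bookkeeping", {
  sys <- build_bilayer(10, 10, area_per_lipid = 1.2, box_z = 400, seed = 5)
  expect_equal(nrow(sys$positions), 600)          # 200 lipids x 3 beads
  expect_equal(sum(sys$kinds == "HEAD"), 200)
  expect_equal(nrow(sys$bonds), 600)              # 2 FENE + 1 spring per lipid
  expect_equal(sum(sys$bonds[, 3] == 1L), 400)
  expect_equal(sum(sys$bonds[, 3] == 2L), 200)
  expect_equal(sys$box[1], 10 * sqrt(1.2))
  # equal leaflet populations, tails inward
  heads_up <- sum(sys$kinds == "HEAD" & sys$positions[, 3] > 0)
  expect_equal(heads_up, 100)
  up <- sys$positions[, 3] > 0
  expect_true(all(abs(sys$positions[sys$kinds == "HEAD", 3]) >
                  abs(sys$positions[sys$kinds == "TAIL2", 3])))
  # every lipid is HEAD-TAIL1-TAIL2 with the spring between head and tail2
  for (lip in c(1, 57, 200)) {
    beads <- which(sys$molecule_id == lip)
    expect_equal(sys$kinds[beads], c("HEAD", "TAIL1", "TAIL2"))
  }
  expect_error(build_bilayer(3, 3), "nx")
})

test_that("generated velocities are Maxwell-Boltzmann at the target temperature", {
  sys <- build_bilayer(12, 12, seed = 9)           # 864 beads
  expect_equal(kinetic_temperature(sys), 1.1, tolerance = 0.05)
  expect_equal(colMeans(sys$velocities), c(0, 0, 0), tolerance = 1e-12)
})

test_that("bilayer builder is deterministic and a full-scale box needs ~33k lipids per leaflet", {
  a <- build_bilayer(8, 8, seed = 3)
  b <- build_bilayer(8, 8, seed = 3)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  # documents why desk runs use reduced boxes: 200^2 / 1.2 lipids per leaflet
  expect_equal(round(200^2 / 1.2), 33333)
})

test_that("spiky robot geometry respects its configured ranges and is reproducible", {
  g <- robot_geometry(core_radius = 3, n_spikes = 8,
                      spike_length_range = c(4, 7),
                      apex_angle_range = c(5, 20), seed = 21)
  rb <- build_spiky_robot(g)
  expect_true(all(rb$spike_length >= 4 & rb$spike_length <= 7))
  expect_true(all(rb$apex_angle >= 5 & rb$apex_angle <= 20))
  # spike tips reach core_radius + length
  rmax <- max(sqrt(rowSums(rb$positions^2)))
  expect_equal(rmax, 3 + max(rb$spike_length), tolerance = 1)
  rb2 <- build_spiky_robot(g)
  expect_identical(rb$positions, rb2$positions)
  # bare shell when no spikes
  shell <- build_spiky_robot(robot_geometry(core_radius = 3, n_spikes = 0))
  expect_true(all(shell$kinds == "ROBOT_CORE"))
  rr <- sqrt(rowSums(shell$positions^2))
  expect_equal(max(abs(rr - 3)), 0, tolerance = 1e-9)
  expect_error(robot_geometry(core_radius = 0.5, bead_spacing = 1), "core_radius")
  expect_error(robot_geometry(bead_spacing = 1.5), "bead_spacing")
})

test_that("cargo placement honours the exclusion constraints", {
  sys <- build_bilayer(8, 8, seed = 2)
  expect_identical(add_cargo(sys, 0, region = c(5, 10)), sys)
  sys2 <- add_cargo(sys, 12, diameter = 2, region = c(6, 14), seed = 4)
  cargo <- sys2$kinds == "CARGO"
  expect_equal(sum(cargo), 12)
  head_top <- max(sys$positions[sys$kinds == "HEAD", 3])
  expect_true(all(sys2$positions[cargo, 3] > head_top))
  cz <- sys2$positions[cargo, , drop = FALSE]
  dmin <- min(dist(cz))
  expect_gte(dmin, 2)
  expect_error(add_cargo(sys, 5, region = c(-1, 1)), "intersects")
  # impossible packing errors out rather than hanging
  expect_error(add_cargo(sys, 500, diameter = 2, region = c(6, 6.5),
                         max_tries = 50), "packing|place")
})

test_that("assembled scenes satisfy the system invariants", {
  pr <- protocol_params(robot_enabled = TRUE, cargo_count = 10L,
                        receptor_fraction = 0.2)
  g <- robot_geometry(core_radius = 2, n_spikes = 6,
                      spike_length_range = c(2.5, 4),
                      apex_angle_range = c(5, 20), seed = 3)
  sc <- assemble_scene(pr, g, nx = 10, seed = 7)
  expect_s3_class(sc, "particle_system")
  expect_true(any(spinpore:::is_robot_kind(sc$kinds)))
  expect_true(any(sc$kinds == "RECEPTOR_HEAD"))
  expect_true(any(sc$kinds == "CARGO"))
  # receptors only on the upper leaflet
  expect_true(all(sc$positions[sc$kinds == "RECEPTOR_HEAD", 3] > 0))
  # robot's lowest bead starts at the LJ contact gap above the head plane
  head_plane <- max(sc$positions[spinpore:::is_head_kind(sc$kinds) &
                                   sc$molecule_id > 0, 3])
  rob_low <- min(sc$positions[spinpore:::is_robot_kind(sc$kinds), 3])
  expect_equal(rob_low - head_plane, 2.5, tolerance = 0.3)
  # rigid beads never bonded
  expect_false(any(sc$bonds[, 1] %in% sc$rigid$indices))
  # no-robot control has no robot beads and no receptors
  pr2 <- protocol_params(robot_enabled = FALSE, cargo_count = 5L)
  sc2 <- assemble_scene(pr2, g, nx = 10, seed = 7)
  expect_false(any(spinpore:::is_robot_kind(sc2$kinds)))
  expect_false(any(sc2$kinds == "RECEPTOR_HEAD"))
  # zero receptor fraction
  pr3 <- protocol_params(robot_enabled = TRUE, cargo_count = 0L,
                         receptor_fraction = 0)
  sc3 <- assemble_scene(pr3, g, nx = 10, seed = 7)
  expect_false(any(sc3$kinds == "RECEPTOR_HEAD"))
  # oversized robot is rejected
  gbig <- robot_geometry(core_radius = 5, n_spikes = 4,
                         spike_length_range = c(10, 12), seed = 1)
  expect_error(assemble_scene(pr, gbig, nx = 6, seed = 1), "larger than")
})

test_that("a freshly built bilayer stays a connected fluid bilayer when relaxed", {
  sys <- build_bilayer(8, 8, seed = 14)
  pr <- protocol_params(n_steps = 5000L, seed = 15, sample_every = 500L,
                        frame_every = 0L)
  tr <- run_simulation(sys, pr)
  expect_equal(tr$status, "ok")
  fin <- tr$final
  # no lipid evaporates: every tail bead keeps a tail neighbour within rc + wc
  p <- forcefield_params()
  tails <- which(fin$kinds %in% c("TAIL1", "TAIL2"))
  pos <- fin$positions[tails, ]
  box <- fin$box
  cut <- p$rc + p$wc
  nn <- vapply(seq_len(nrow(pos)), function(k) {
    d <- sweep(pos[-k, , drop = FALSE], 2, pos[k, ])
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    min(sqrt(rowSums(d^2)))
  }, numeric(1))
  expect_lt(max(nn), cut)
})
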