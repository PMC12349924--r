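test_that("density map conserves bead counts and is near-uniform for intact bilayers", {
  sys <- build_bilayer(16, 16, seed = 3)
  dm <- lipid_density_map(sys$positions, sys$kinds, sys$box, cell = 2)
  total <- sum(dm) * attr(dm, "cell_area")
  expect_equal(total, sum(spinpore:::is_lipid_kind(sys$kinds)))
  # a thermalised fluid bilayer is close to uniform (sub-Poisson counting)
  pr <- protocol_params(n_steps = 2000L, seed = 4, sample_every = 0L,
                        frame_every = 0L)
  fin <- run_simulation(sys, pr)$final
  dmr <- lipid_density_map(fin$positions, fin$kinds, fin$box, cell = 2)
  expect_lt(sd(dmr) / mean(dmr), 0.3)
  # empty box
  dm0 <- lipid_density_map(matrix(numeric(), 0, 3), character(), c(10, 10, 10))
  expect_true(all(dm0 == 0))
})

test_that("pore area detects constructed depletions exactly", {
  # 20 x 20 grid of uniform density 2.5 with a 5 x 5 empty block, cell = 2
  g <- matrix(2.5, 20, 20)
  g[6:10, 6:10] <- 0
  attr(g, "cell_area") <- 4
  pa <- pore_area(g, threshold_fraction = 0.25, reference_density = 2.5)
  expect_equal(pa$total, 100)
  expect_equal(pa$largest, 100)
  expect_equal(pa$n_components, 1L)
  # intact grid scores zero
  gi <- matrix(2.5, 10, 10); attr(gi, "cell_area") <- 4
  expect_equal(pore_area(gi, 0.25, 2.5)$total, 0)
  # fully empty grid scores the whole box area
  ge <- matrix(0, 10, 10); attr(ge, "cell_area") <- 4
  expect_equal(pore_area(ge, 0.25, 2.5)$total, 400)
  # two separate blocks, wrap-around component counted once
  g2 <- matrix(2.5, 12, 12)
  g2[1:2, 3:4] <- 0; g2[12, 3:4] <- 0     # wraps across the x boundary
  g2[7:8, 9] <- 0
  attr(g2, "cell_area") <- 4
  pa2 <- pore_area(g2, 0.25, 2.5)
  expect_equal(pa2$n_components, 2L)
  expect_equal(pa2$largest, 6 * 4)
  expect_error(pore_area(matrix(1, 1, 2), 0.25), "degenerate")
  expect_error(pore_area(g, 1.5), "threshold_fraction")
})

test_that("penetration counting uses the lower head plane minus the margin", {
  sys <- build_bilayer(8, 8, seed = 5)
  sys <- add_cargo(sys, 6, region = c(6, 10), seed = 6)
  expect_equal(penetrated_count(sys$positions, sys$kinds, margin = 1), 0L)
  # move three cargo beads below the lower leaflet
  pos <- sys$positions
  cargo_idx <- which(sys$kinds == "CARGO")
  pos[cargo_idx[1:3], 3] <- -8
  expect_equal(penetrated_count(pos, sys$kinds, margin = 1), 3L)
  # margin larger than the box makes the threshold unreachable
  expect_equal(penetrated_count(pos, sys$kinds, margin = 1000), 0L)
  expect_error(penetrated_count(pos[cargo_idx, , drop = FALSE],
                                sys$kinds[cargo_idx]), "lipid")
})

test_that("penetration series is monotone in its cumulative count", {
  sys <- build_bilayer(6, 6, seed = 7)
  sys <- add_cargo(sys, 4, region = c(6, 9), seed = 8)
  n <- nrow(sys$positions)
  cargo_idx <- which(sys$kinds == "CARGO")
  fr <- array(rep(t(sys$positions), 3), dim = c(3, n, 3))
  fr[3, cargo_idx[1], 2] <- -9          # dips below in frame 2
  fr[3, cargo_idx[1], 3] <- 8           # returns in frame 3
  fr[3, cargo_idx[2], 3] <- -9
  tr <- fake_traj(fr, sys$kinds, sys$box)
  ps <- penetrated_series(tr, margin = 1)
  expect_equal(ps$instantaneous, c(0L, 1L, 1L))
  expect_equal(ps$cumulative, c(0L, 1L, 2L))
  expect_true(all(diff(ps$cumulative) >= 0))
})

test_that("MSD closed forms: static, ballistic and Brownian motion", {
  n <- 50; nf <- 21
  # static: identically zero
  pos0 <- matrix(runif(3 * n) * 10, 3, n)
  fr <- array(rep(pos0, nf), dim = c(3, n, nf))
  tr <- fake_traj(fr, rep("CARGO", n), c(10, 10, 400))
  m <- msd(tr, "CARGO")
  expect_true(all(m$msd == 0))
  # ballistic r = v t: MSD = v^2 t^2 exactly
  v <- 0.3
  frb <- fr
  for (k in seq_len(nf)) frb[3, , k] <- pos0[3, ] + v * (k - 1)
  trb <- fake_traj(frb, rep("CARGO", n), c(10, 10, 400))
  mb <- msd(trb, "CARGO", axis_mask = c(FALSE, FALSE, TRUE))
  expect_equal(mb$msd, (v * mb$lag_time)^2, tolerance = 1e-12)
  # Brownian walkers along z with known D recover D within 10%
  D <- 0.05; dt <- 1; nw <- 500; nfb <- 200
  set.seed(99)
  steps <- matrix(rnorm(nw * (nfb - 1), sd = sqrt(2 * D * dt)), nw)
  zs <- cbind(0, t(apply(steps, 1, cumsum)))
  frw <- array(0, dim = c(3, nw, nfb))
  frw[3, , ] <- zs
  trw <- fake_traj(frw, rep("CARGO", nw), c(10, 10, 400),
                   times = (seq_len(nfb) - 1) * dt)
  mw <- msd(trw, "CARGO", axis_mask = c(FALSE, FALSE, TRUE), max_lag = 50)
  dd <- diffusion_coefficient(mw, dimensionality = 1,
                              fit_window = c(5, 50))
  expect_equal(dd$D, D, tolerance = 0.10)
  expect_error(msd(tr, integer(0)), "empty")
})

test_that("diffusion fits handle exact lines and degenerate windows", {
  t <- seq(0, 10, by = 0.5)
  series <- data.frame(lag_time = t, msd = 4 * 0.01 * t)
  d <- diffusion_coefficient(series, dimensionality = 2)
  expect_equal(d$D, 0.01, tolerance = 1e-12)
  expect_error(diffusion_coefficient(series, 2, fit_window = c(3.1, 3.2)),
               "fewer than 2")
  neg <- data.frame(lag_time = t, msd = -0.1 * t)
  expect_warning(dn <- diffusion_coefficient(neg, 1), "non-positive")
})

test_that("height field grids the midplane and flags interpolated cells", {
  sys <- build_bilayer(12, 12, seed = 11)
  hf <- height_field(sys$positions, sys$kinds, sys$box, cell = 2)
  expect_equal(dim(hf), c(round(sys$box[1] / 2), round(sys$box[2] / 2)))
  expect_lt(max(abs(hf)), 0.5)       # flat initial bilayer, midplane ~ 0
  expect_equal(attr(hf, "n_interpolated"), 0)
  # remove a column of lipids to force interpolation
  keep <- !(sys$positions[, 1] < 2.2)
  hf2 <- height_field(sys$positions[keep, ], sys$kinds[keep], sys$box, cell = 2)
  expect_gt(attr(hf2, "n_interpolated"), 0)
  expect_false(anyNA(hf2))
})

test_that("bending stiffness estimator recovers a known Helfrich surface", {
  kappa_in <- 10; L <- 40; ng <- 20
  fr <- helfrich_frames(300, L, ng, kappa_in, 1.1, seed = 123)
  tr <- fake_traj(fr, rep("HEAD", ng^2), c(L, L, 400))
  est <- bending_stiffness(tr, cell = L / ng, min_frames = 100, n_boot = 100)
  expect_equal(est$kappa, kappa_in, tolerance = 0.15)
  expect_false(attr(est, "non_helfrich"))
  expect_equal(est$slope, -4, tolerance = 0.8)
  # doubling the box at fixed kappa leaves the estimate unchanged
  fr2 <- helfrich_frames(300, 2 * L, 2 * ng, kappa_in, 1.1, seed = 124, n_mode = 16)
  tr2 <- fake_traj(fr2, rep("HEAD", (2 * ng)^2), c(2 * L, 2 * L, 400))
  est2 <- bending_stiffness(tr2, cell = L / ng, min_frames = 100, n_boot = 50)
  expect_equal(est2$kappa, kappa_in, tolerance = 0.15)
  expect_error(bending_stiffness(tr, min_frames = 1000), "frames")
})

test_that("white-noise surfaces are flagged as non-Helfrich", {
  L <- 40; ng <- 20; nf <- 150
  set.seed(7)
  fr <- array(0, dim = c(3, ng^2, nf))
  xy <- (seq_len(ng) - 0.5) * L / ng
  fr[1, , ] <- rep(xy, ng); fr[2, , ] <- rep(xy, each = ng)
  fr[3, , ] <- rnorm(ng^2 * nf, sd = 0.3)
  tr <- fake_traj(fr, rep("HEAD", ng^2), c(L, L, 400))
  est <- bending_stiffness(tr, cell = L / ng, min_frames = 100, n_boot = 50)
  expect_true(attr(est, "non_helfrich"))
})

test_that("stretching modulus follows the area-fluctuation closed form", {
  set.seed(17)
  # series built to the calibrated example: <A> = 1000, Var = 41.7
  a <- rnorm(20000, mean = 1000, sd = sqrt(41.7))
  ka <- stretching_modulus(a, temperature = 1.1)
  expect_equal(ka$K_A, 1.1 * 1000 / 41.7, tolerance = 0.05)
  expect_equal(ka$K_A, 26.4, tolerance = 0.08)
  # halving the variance doubles K_A (same mean)
  a2 <- 1000 + (a - mean(a)) / sqrt(2)
  ka2 <- stretching_modulus(a2, temperature = 1.1)
  expect_equal(ka2$K_A / ka$K_A, 2, tolerance = 0.02)
  expect_error(stretching_modulus(rep(5, 100)), "variance")
})

test_that("estimators are invariant under rigid translation and relabeling", {
  sys <- build_bilayer(10, 10, seed = 19)
  sys <- add_cargo(sys, 8, region = c(6, 12), seed = 20)
  dm1 <- lipid_density_map(sys$positions, sys$kinds, sys$box)
  pa1 <- pore_area(dm1, 0.25, reference_density = mean(dm1))
  pc1 <- penetrated_count(sys$positions, sys$kinds)
  # translate everything rigidly (z included) and permute bead order
  shift <- c(3.3, -2.1, 5.5)
  pos2 <- sweep(sys$positions, 2, shift, "+")
  perm <- sample(nrow(pos2))
  dm2 <- lipid_density_map(pos2[perm, ], sys$kinds[perm], sys$box)
  pa2 <- pore_area(dm2, 0.25, reference_density = mean(dm2))
  pc2 <- penetrated_count(pos2[perm, ], sys$kinds[perm])
  expect_equal(pa2$total, pa1$total)
  expect_equal(pc2, pc1)
  expect_equal(sum(dm2), sum(dm1), tolerance = 1e-10)
})
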