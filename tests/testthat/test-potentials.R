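# frozen expected values computed from direct evaluation of the closed forms

test_that("WCA repulsion has the right zeros, minimum and cutoff behaviour", {
  p_unsh <- forcefield_params(eps_rep = 1, rep_shifted = FALSE)
  p_sh <- forcefield_params(eps_rep = 1, rep_shifted = TRUE)
  b <- 0.95
  expect_equal(u_rep(b, b, p_unsh), 0)
  expect_equal(u_rep(2^(1 / 6) * b, b, p_unsh), -1)      # 4(1/4 - 1/2)
  expect_equal(u_rep(2^(1 / 6) * b, b, p_sh), 0)
  expect_equal(u_rep(2^(1 / 6) * b + 1e-9, b, p_sh), 0)  # beyond cutoff
  # unshifted variant is discontinuous by -eps_rep at the cutoff
  expect_equal(u_rep(2^(1 / 6) * b - 1e-12, b, p_unsh), -1, tolerance = 1e-6)
  expect_equal(u_rep(2^(1 / 6) * b + 1e-12, b, p_unsh), 0)
  # monotone decreasing on (0, cutoff)
  r <- seq(0.7, 2^(1 / 6) * b, length.out = 200)
  expect_true(all(diff(u_rep(r, b, p_sh)) < 0))
  expect_error(u_rep(0, b, p_sh), "positive")
})

test_that("tail attraction is a flat well with a smooth cosine taper", {
  p <- forcefield_params()
  expect_equal(u_cos(p$rc, p), -1)
  expect_equal(u_cos(p$rc / 2, p), -1)
  expect_equal(u_cos(p$rc + p$wc, p), 0, tolerance = 1e-15)
  expect_equal(u_cos(p$rc + p$wc / 2, p), -0.5)          # cos^2(pi/4)
  expect_equal(u_cos(p$rc + p$wc + 0.5, p), 0)
  # continuity across both boundaries
  eps <- 1e-8
  expect_equal(u_cos(p$rc - eps, p), u_cos(p$rc + eps, p), tolerance = 1e-6)
  expect_equal(u_cos(p$rc + p$wc - eps, p), 0, tolerance = 1e-6)
})

test_that("FENE bond is zero at rest, strictly increasing and diverges at r_inf", {
  p <- forcefield_params()
  expect_equal(u_fene(0, p), 0)
  # oracle: -0.5 * 30 * 1.5^2 * log(1 - 0.25) = 9.7092703...
  expect_equal(u_fene(0.75, p), -0.5 * 30 * 1.5^2 * log(0.75), tolerance = 1e-12)
  expect_true(is.finite(u_fene(1.499, p)) && u_fene(1.499, p) > 100)
  r <- seq(0, 1.49, length.out = 300)
  expect_true(all(diff(u_fene(r, p)) > 0))
  expect_error(u_fene(1.5, p), "overstretch")
})

test_that("straightening spring is harmonic about 4 sigma", {
  p <- forcefield_params()
  expect_equal(u_bend(4, p), 0)
  expect_equal(u_bend(5, p), 5)      # 0.5 * 10 * 1
  expect_equal(u_bend(3, p), 5)      # symmetric
})

test_that("nanoparticle LJ well has depth eps_np at 2^(1/6) b_np", {
  p <- forcefield_params()
  expect_equal(u_np(p$b_np, p), 0, tolerance = 2e-3)     # truncation shift only
  # well depth eps_np, offset by the small truncation shift at 3 b_np
  # (4 * 0.2 * ((1/3)^12 - (1/3)^6) = -0.0011)
  expect_equal(u_np(2^(1 / 6) * p$b_np, p), -0.2, tolerance = 6e-3)
  expect_equal(u_np(p$rcut_np + 0.1, p), 0)
  # continuity at the cutoff
  expect_equal(u_np(p$rcut_np - 1e-9, p), 0, tolerance = 1e-6)
})

test_that("pair forces equal minus the numerical energy derivative", {
  p <- forcefield_params()
  h <- 1e-6
  cases <- list(
    list(pot = "rep", r = seq(0.75, 1.05, by = 0.05), u = function(r) u_rep(r, p$b_tail_tail, p)),
    list(pot = "cos", r = seq(1.2, 2.7, by = 0.1), u = function(r) u_cos(r, p)),
    list(pot = "fene", r = seq(0.1, 1.3, by = 0.1), u = function(r) u_fene(r, p)),
    list(pot = "bend", r = seq(1, 6, by = 0.5), u = function(r) u_bend(r, p)),
    list(pot = "np", r = seq(2.0, 6.0, by = 0.25), u = function(r) u_np(r, p)))
  for (cs in cases) {
    fd <- (cs$u(cs$r - h) - cs$u(cs$r + h)) / (2 * h)
    an <- pair_force(cs$pot, cs$r, p)
    expect_equal(an, fd, tolerance = 1e-5,
                 label = paste("force of", cs$pot))
  }
  # stationary points and plateaus are exactly zero
  expect_equal(pair_force("rep", 2^(1 / 6) * 1.0, p, b = 1.0), 0, tolerance = 1e-12)
  expect_equal(pair_force("cos", 1.0, p), 0)
  expect_equal(pair_force("bend", 4, p), 0)
})

test_that("tail-tail energy is cohesive: minimum between b and the outer cutoff", {
  p <- forcefield_params()
  r <- seq(0.9, p$rc + p$wc, length.out = 2000)
  utot <- u_rep(r, p$b_tail_tail, p) + u_cos(r, p)
  rmin <- r[which.min(utot)]
  expect_gt(rmin, p$b_tail_tail)
  expect_lt(rmin, p$rc + p$wc)
  expect_lt(min(utot), -0.9)
})

test_that("pair rule table is symmetric and carries the calibrated lengths", {
  tab <- pair_rule_table()
  hh <- tab[tab$kind_a == "HEAD" & tab$kind_b == "HEAD", ]
  expect_equal(hh$b, 0.95)
  expect_equal(hh$potential, "WCA")
  ht <- tab[tab$kind_a == "HEAD" & tab$kind_b == "TAIL1", ]
  expect_equal(ht$b, 0.95)
  tt <- tab[tab$kind_a == "TAIL1" & tab$kind_b == "TAIL2", ]
  expect_equal(tt$b, 1.0)
  expect_equal(tt$potential, "WCA+COS")
  rec <- tab[tab$kind_a == "ROBOT_SPIKE" & tab$kind_b == "RECEPTOR_HEAD" |
             tab$kind_a == "RECEPTOR_HEAD" & tab$kind_b == "ROBOT_SPIKE", ]
  expect_equal(rec$potential, "NP_LJ")
  expect_gt(rec$epsilon, forcefield_params()$eps_np)
  rr <- tab[tab$kind_a == "ROBOT_CORE" & tab$kind_b == "ROBOT_SPIKE", ]
  expect_equal(rr$potential, "NONE")
  f <- tempfile(fileext = ".csv")
  pair_rule_table(file = f)
  expect_true(file.exists(f))
  expect_equal(nrow(read.csv(f)), nrow(tab))
})
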