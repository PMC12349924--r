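# random mixed-kind configurations with a minimum separation (keeps the
# divergent cores out of play so energies are comparable at tight tolerance)
random_config <- function(n, box, seed, kinds_pool = c("HEAD", "TAIL1", "TAIL2", "CARGO"),
                          min_sep = 0.9) {
  spinpore:::with_seed(seed, {
    pos <- matrix(numeric(), 0, 3)
    while (nrow(pos) < n) {
      cand <- runif(3) * box
      ok <- TRUE
      if (nrow(pos) > 0) {
        d <- sweep(pos, 2, cand)
        d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
        ok <- min(rowSums(d^2)) > min_sep^2
      }
      if (ok) pos <- rbind(pos, cand)
    }
    kinds <- sample(kinds_pool, n, replace = TRUE)
    particle_system(pos, matrix(0, n, 3), kinds, NULL, rep(0L, n), box)
  })
}


# dilute cargo gas in a large box: effectively an ideal gas (jittered
# grid placement keeps initial overlaps out of the excluded-volume core)
ideal_gas <- function(n, box_l, seed, temperature = 1.1) {
  spinpore:::with_seed(seed, {
    m <- ceiling(n^(1 / 3))
    a <- box_l / m
    grid <- expand.grid(x = seq_len(m), y = seq_len(m), z = seq_len(m))[seq_len(n), ]
    pos <- (as.matrix(grid) - 0.5) * a +
      matrix(runif(3 * n, -0.2 * a, 0.2 * a), n, 3)
    vel <- matrix(rnorm(3 * n, sd = sqrt(temperature)), n, 3)
    particle_system(pos, vel, rep("CARGO", n), NULL, rep(0L, n),
                    rep(box_l, 3))
  })
}


# minimal trajectory object from raw frame data (observables only need
# frames, kinds, times and boxes)
fake_traj <- function(frames, kinds, box, times = seq_len(dim(frames)[3]) - 1,
                      temperature = 1.1) {
  structure(list(
    frames = frames,
    frame_box = matrix(rep(box, each = dim(frames)[3]), ncol = 3),
    frame_time = times,
    frame_step = seq_along(times) - 1L,
    kinds = kinds,
    molecule_id = rep(0L, length(kinds)),
    series = NULL, status = "ok", steps_done = length(times) - 1,
    protocol = protocol_params(temperature = temperature)),
    class = "trajectory")
}


# independent Helfrich-surface generator: explicit mode sum with the
# continuum amplitude, evaluated directly on the grid (no FFT involved)
helfrich_frames <- function(n_frames, L, n_grid, kappa, temperature, seed,
                            n_mode = 8) {
  set.seed(seed)
  xy <- (seq_len(n_grid) - 0.5) * L / n_grid
  A <- L^2
  frames <- array(0, dim = c(3, n_grid^2, n_frames))
  gx <- rep(xy, n_grid); gy <- rep(xy, each = n_grid)
  for (f in seq_len(n_frames)) {
    h <- numeric(n_grid^2)
    for (nx in -n_mode:n_mode) for (ny in -n_mode:n_mode) {
      if (nx == 0 && ny == 0) next
      if (nx < 0 || (nx == 0 && ny < 0)) next   # one of each +-q pair
      q <- 2 * pi / L * sqrt(nx^2 + ny^2)
      amp <- sqrt(temperature / (A * kappa * q^4))
      a <- rnorm(1, sd = amp / sqrt(2)); b <- rnorm(1, sd = amp / sqrt(2))
      phase <- 2 * pi / L * (nx * gx + ny * gy)
      # h_q e^{iqr} + c.c. for the conjugate mode
      h <- h + 2 * (a * cos(phase) - b * sin(phase))
    }
    frames[1, , f] <- gx; frames[2, , f] <- gy; frames[3, , f] <- h
  }
  frames
}

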