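#' Lipid number-density map
#'
#' Projects lipid beads onto the membrane plane and counts them on a
#' square grid, returning number density per cell (sigma^-2). The
#' membrane conformation — and in particular depleted (pore) regions —
#' shows up directly in this map.
#'
#' @param positions N x 3 bead positions (any wrapping), sigma.
#' @param kinds length-N kind labels.
#' @param box length-3 box.
#' @param cell grid cell edge, sigma (between 1 and 5).
#' @return matrix of densities with attributes `cell`, `box`,
#'   `cell_area`.
#' @export
lipid_density_map <- function(positions, kinds, box, cell = 2) {
  stopifnot(cell >= 1, cell <= 5)
  nx <- max(1L, round(box[1] / cell)); ny <- max(1L, round(box[2] / cell))
  lip <- is_lipid_kind(kinds)
  grid <- matrix(0, nx, ny)
  if (any(lip)) {
    x <- positions[lip, 1] %% box[1]
    y <- positions[lip, 2] %% box[2]
    ix <- pmin(nx, floor(x / box[1] * nx) + 1L)
    iy <- pmin(ny, floor(y / box[2] * ny) + 1L)
    tab <- table(factor(ix, levels = seq_len(nx)), factor(iy, levels = seq_len(ny)))
    grid <- matrix(as.numeric(tab), nx, ny)
  }
  cell_area <- (box[1] / nx) * (box[2] / ny)
  structure(grid / cell_area, cell = cell, box = box, cell_area = cell_area)
}

# label 4-connected components of a logical matrix on a periodic grid
label_components <- function(mask, periodic = TRUE) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  for (i0 in seq_len(nx)) for (j0 in seq_len(ny)) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i0, j0), 1, 2)
    lab[i0, j0] <- cur
    while (nrow(queue) > 0) {
      i <- queue[1, 1]; j <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (periodic) {
          ii <- ((ii - 1L) %% nx) + 1L
          jj <- ((jj - 1L) %% ny) + 1L
        } else if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
        if (mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

#' Membrane pore area from a density map
#'
#' Thresholds the lipid number-density grid at a fraction of the intact
#' (reference) density, labels 4-connected sub-threshold components, and
#' reports their total and largest areas. An intact membrane scores
#' approximately zero.
#'
#' @param density a density grid from [lipid_density_map()].
#' @param threshold_fraction fraction of the reference density below
#'   which a cell counts as depleted (strictly between 0 and 1).
#' @param reference_density mean density of the intact membrane; defaults
#'   to the mean of the supplied grid (pass the intact value explicitly
#'   when pores are large).
#' @return list with `total` and `largest` pore areas (sigma^2),
#'   `n_components`, and the `threshold` used (metadata for provenance).
#' @export
pore_area <- function(density, threshold_fraction = 0.25,
                      reference_density = NULL) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  if (length(density) < 4) stop("pore_area: degenerate density grid")
  if (is.null(reference_density)) reference_density <- mean(density)
  thr <- threshold_fraction * reference_density
  cell_area <- attr(density, "cell_area")
  if (is.null(cell_area)) stop("pore_area: density grid lacks cell_area attribute")
  mask <- density < thr
  if (!any(mask))
    return(list(total = 0, largest = 0, n_components = 0L, threshold = thr))
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  list(total = sum(sizes) * cell_area,
       largest = max(sizes) * cell_area,
       n_components = length(sizes),
       threshold = thr)
}

# per-frame membrane reference planes from lipid beads
membrane_planes <- function(positions, kinds) {
  lip <- is_lipid_kind(kinds)
  if (!any(lip)) stop("no lipid beads in frame; cannot locate the membrane")
  mid <- mean(positions[lip, 3])
  heads <- is_head_kind(kinds)
  lower <- heads & positions[, 3] < mid
  upper <- heads & positions[, 3] >= mid
  list(mid = mid,
       lower_head = mean(positions[lower, 3]),
       upper_head = mean(positions[upper, 3]))
}

#' Count cargo beads that have crossed the membrane
#'
#' A cargo bead counts as penetrated when its (unwrapped) z coordinate
#' lies more than `margin` below the mean lower-leaflet head plane of the
#' same frame.
#'
#' @param positions N x 3 unwrapped positions.
#' @param kinds length-N kind labels.
#' @param margin distance below the lower head plane, sigma.
#' @return integer count.
#' @export
penetrated_count <- function(positions, kinds, margin = 1) {
  pl <- membrane_planes(positions, kinds)
  cargo <- kinds == "CARGO"
  if (!any(cargo)) return(0L)
  sum(positions[cargo, 3] < pl$lower_head - margin)
}

#' Penetration time series over a trajectory
#'
#' @param traj a trajectory.
#' @param margin sigma below the lower head plane.
#' @return data.frame with `time`, `instantaneous` count and the
#'   monotone `cumulative` count (beads that have ever crossed).
#' @export
penetrated_series <- function(traj, margin = 1) {
  nf <- n_frames(traj)
  cargo <- traj$kinds == "CARGO"
  inst <- integer(nf)
  ever <- logical(sum(cargo))
  cum <- integer(nf)
  for (i in seq_len(nf)) {
    pos <- frame_positions(traj, i)
    pl <- membrane_planes(pos, traj$kinds)
    below <- pos[cargo, 3] < pl$lower_head - margin
    inst[i] <- sum(below)
    ever <- ever | below
    cum[i] <- sum(ever)
  }
  data.frame(time = traj$frame_time, instantaneous = inst, cumulative = cum)
}

#' Mean-square displacement
#'
#' Multiple-time-origin MSD over a bead selection, restricted to the
#' masked axes (`c(FALSE, FALSE, TRUE)` for the transmembrane direction;
#' `c(TRUE, TRUE, FALSE)` for lateral lipid diffusion). Uses the
#' unwrapped frame positions.
#'
#' @param traj a trajectory.
#' @param selection integer bead indices, or a kind label (e.g. `"HEAD"`,
#'   `"CARGO"`).
#' @param axis_mask logical length-3 axis selector.
#' @param max_lag maximum lag in frames (default: half the trajectory).
#' @param origin_stride spacing of time origins in frames.
#' @return data.frame with `lag_time` (tau) and `msd` (sigma^2).
#' @export
msd <- function(traj, selection, axis_mask = c(TRUE, TRUE, TRUE),
                max_lag = NULL, origin_stride = 1L) {
  if (is.character(selection)) selection <- which(traj$kinds %in% selection)
  if (length(selection) == 0) stop("msd: empty bead selection")
  nf <- n_frames(traj)
  if (nf < 2) stop("msd: need at least two frames")
  if (is.null(max_lag)) max_lag <- max(1L, nf %/% 2L)
  max_lag <- min(max_lag, nf - 1L)
  ax <- which(axis_mask)
  # sub-array: axes x beads x frames
  sub <- traj$frames[ax, selection, , drop = FALSE]
  out <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    orgs <- seq(1L, nf - lag, by = origin_stride)
    acc <- 0
    for (o in orgs) {
      d <- sub[, , o + lag] - sub[, , o]
      acc <- acc + mean(colSums(matrix(d, nrow = length(ax))^2))
    }
    out[lag] <- acc / length(orgs)
  }
  dt_frame <- if (nf >= 2) diff(traj$frame_time[1:2]) else NA_real_
  data.frame(lag_time = seq_len(max_lag) * dt_frame, msd = out)
}

#' Diffusion coefficient from an MSD series
#'
#' Least-squares slope of MSD versus lag time over the fit window,
#' divided by `2 * dimensionality`.
#'
#' @param msd_series data.frame from [msd()].
#' @param dimensionality number of axes the MSD was accumulated over.
#' @param fit_window `c(tmin, tmax)` in tau; defaults to the second half
#'   of the series (the late, diffusive regime).
#' @return list with `D` (sigma^2/tau), `slope`, `n_points`; a
#'   non-positive slope is flagged with a warning attribute
#'   `subdiffusive`.
#' @export
diffusion_coefficient <- function(msd_series, dimensionality,
                                  fit_window = NULL) {
  if (is.null(fit_window)) {
    tmax <- max(msd_series$lag_time)
    fit_window <- c(tmax / 2, tmax)
  }
  sel <- msd_series$lag_time >= fit_window[1] & msd_series$lag_time <= fit_window[2]
  if (sum(sel) < 2) stop("diffusion_coefficient: fit window contains fewer than 2 points")
  fit <- lm(msd ~ lag_time, data = msd_series[sel, ])
  slope <- unname(coef(fit)[2])
  out <- list(D = slope / (2 * dimensionality), slope = slope,
              n_points = sum(sel))
  if (slope <= 0) {
    warning("diffusion_coefficient: non-positive MSD slope; result flagged")
    attr(out, "subdiffusive") <- TRUE
  }
  out
}

#' Midplane height field of the bilayer
#'
#' Grids the membrane plane and averages the z coordinate of lipid beads
#' per cell; empty cells are filled by iterative neighbour averaging and
#' counted in the `n_interpolated` attribute.
#'
#' @param positions N x 3 positions.
#' @param kinds kind labels.
#' @param box length-3 box.
#' @param cell grid cell edge, sigma.
#' @return matrix of heights (sigma) with attributes.
#' @export
height_field <- function(positions, kinds, box, cell = 2) {
  nx <- max(2L, round(box[1] / cell)); ny <- max(2L, round(box[2] / cell))
  lip <- is_lipid_kind(kinds)
  if (!any(lip)) stop("height_field: no lipid beads")
  x <- positions[lip, 1] %% box[1]
  y <- positions[lip, 2] %% box[2]
  z <- positions[lip, 3]
  ix <- pmin(nx, floor(x / box[1] * nx) + 1L)
  iy <- pmin(ny, floor(y / box[2] * ny) + 1L)
  idx <- (iy - 1L) * nx + ix
  sums <- tapply(z, factor(idx, levels = seq_len(nx * ny)), sum)
  cnts <- tapply(rep(1, length(z)), factor(idx, levels = seq_len(nx * ny)), sum)
  h <- matrix(as.numeric(sums) / as.numeric(cnts), nx, ny)
  n_empty <- sum(is.na(h))
  guard <- 0L
  while (anyNA(h) && guard < 100L) {
    guard <- guard + 1L
    nbr_mean <- (h[c(2:nx, 1), ] + h[c(nx, 1:(nx - 1)), ] +
                 h[, c(2:ny, 1)] + h[, c(ny, 1:(ny - 1))])
    nbr_cnt <- (!is.na(h[c(2:nx, 1), ])) + (!is.na(h[c(nx, 1:(nx - 1)), ])) +
               (!is.na(h[, c(2:ny, 1)])) + (!is.na(h[, c(ny, 1:(ny - 1))]))
    nbr_mean[is.na(nbr_mean)] <- 0
    fill <- is.na(h) & nbr_cnt > 0
    vals <- (ifelse(is.na(h[c(2:nx, 1), ]), 0, h[c(2:nx, 1), ]) +
             ifelse(is.na(h[c(nx, 1:(nx - 1)), ]), 0, h[c(nx, 1:(nx - 1)), ]) +
             ifelse(is.na(h[, c(2:ny, 1)]), 0, h[, c(2:ny, 1)]) +
             ifelse(is.na(h[, c(ny, 1:(ny - 1))]), 0, h[, c(ny, 1:(ny - 1))])) / nbr_cnt
    h[fill] <- vals[fill]
  }
  structure(h, cell = cell, box = box, n_interpolated = n_empty)
}

#' Bending stiffness from the height-fluctuation spectrum
#'
#' Estimates the bending modulus kappa from the squared Fourier
#' amplitudes of the midplane height field accumulated over frames. In
#' the low-q window (`q <= q_max`, excluding short wavelengths where
#' protrusions dominate) the thermal-undulation spectrum is
#' `<|h_q|^2> = kB T / (A (kappa q^4 + sigma q^2))`. By default both
#' kappa and the effective tension-like coefficient sigma are fitted
#' (weighted least squares on `kB T / (A S(q))`, weights reflecting the
#' constant relative error of each mode): in finite patches the
#' fluctuation spectrum carries a residual q^2 component even when the
#' mechanical frame tension is zero, and ignoring it biases kappa
#' upward. With `fit_tension = FALSE` the estimate reduces to the mean
#' of the per-mode `kB T / (A q^4 S(q))`. The standard error comes from
#' a bootstrap over frames; a diagnostic free fit of the spectral slope
#' flags spectra that are not q^-4-like.
#'
#' @param traj a trajectory from a tensionless (barostatted) run.
#' @param cell height-field cell edge, sigma.
#' @param q_max upper end of the fit window, 1/sigma (default
#'   `2*pi/6`: wavelengths of at least 6 sigma).
#' @param min_frames required number of frames.
#' @param n_boot bootstrap resamples.
#' @param temperature epsilon/kB.
#' @param discard initial fraction of frames discarded as equilibration.
#' @param fit_tension also fit the effective q^2 coefficient.
#' @return list with `kappa` (epsilon), `se`, `sigma_fluct` (the fitted
#'   q^2 coefficient, epsilon/sigma^2; NA when not fitted), `n_modes`,
#'   `slope` (diagnostic log-log spectral slope) and `spectrum`
#'   (data.frame of q, S(q)); the logical attribute `non_helfrich` marks
#'   slopes far from -4.
#' @export
bending_stiffness <- function(traj, cell = 2, q_max = 2 * pi / 6,
                              min_frames = 50, n_boot = 200,
                              temperature = traj$protocol$temperature,
                              discard = 0, fit_tension = TRUE) {
  nf0 <- n_frames(traj)
  use <- seq_len(nf0) > floor(discard * nf0)
  frames <- which(use)
  if (length(frames) < min_frames)
    stop("bending_stiffness: need at least ", min_frames, " frames, have ",
         length(frames))
  box <- colMeans(traj$frame_box[frames, , drop = FALSE])
  nx <- max(2L, round(box[1] / cell)); ny <- max(2L, round(box[2] / cell))
  A <- box[1] * box[2]
  qx <- 2 * pi / box[1] * c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1))[1:nx]
  qy <- 2 * pi / box[2] * c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1))[1:ny]
  qmat <- sqrt(outer(qx^2, qy^2, "+"))
  per_frame <- matrix(0, length(frames), nx * ny)
  for (k in seq_along(frames)) {
    pos <- frame_positions(traj, frames[k])
    h <- height_field(pos, traj$kinds, traj$frame_box[frames[k], ], cell = cell)
    h <- h - mean(h)
    H <- fft(h) / (nx * ny)
    per_frame[k, ] <- as.vector(Mod(H)^2)
  }
  S <- colMeans(per_frame)
  selq <- qmat > 1e-12 & qmat <= q_max
  if (!any(selq)) stop("bending_stiffness: no modes below q_max; enlarge the system")
  qs <- qmat[selq]
  estimate <- function(Svec) {
    if (fit_tension) {
      y <- temperature / (A * Svec)
      fit <- lm(y ~ 0 + I(qs^4) + I(qs^2), weights = 1 / y^2)
      unname(coef(fit))
    } else {
      c(mean(temperature / (A * qs^4 * Svec)), NA_real_)
    }
  }
  point <- estimate(S[selq])
  kappa <- point[1]
  boot <- replicate(n_boot, {
    idx <- sample(nrow(per_frame), replace = TRUE)
    Sb <- colMeans(per_frame[idx, , drop = FALSE])
    estimate(Sb[selq])[1]
  })
  # diagnostic slope over the same window
  lf <- lm(log(S[selq]) ~ log(qs))
  slope <- unname(coef(lf)[2])
  out <- list(kappa = kappa, se = sd(boot), sigma_fluct = point[2],
              n_modes = sum(selq), slope = slope,
              spectrum = data.frame(q = qs, S = S[selq]))
  attr(out, "non_helfrich") <- abs(slope + 4) > 1.5
  out
}

#' Rescale a system laterally to a target projected area
#'
#' Affinely scales the lateral box lengths and all mobile-bead x, y
#' coordinates so the projected box area equals `area`; used to fix the
#' box at the tensionless mean area found by a barostatted run before a
#' constant-area production run.
#'
#' @param system a [particle_system()].
#' @param area target projected area, sigma^2.
#' @return the rescaled system.
#' @export
set_projected_area <- function(system, area) {
  stopifnot(area > 0)
  mu <- sqrt(area / (system$box[1] * system$box[2]))
  mob <- !is_robot_kind(system$kinds)
  system$positions[mob, 1:2] <- system$positions[mob, 1:2] * mu
  system$box[1:2] <- system$box[1:2] * mu
  system
}

#' Stretching modulus from projected-area fluctuations
#'
#' For a tensionless barostatted run,
#' `K_A = kB T * <A> / Var(A)` from the time series of the projected box
#' area, with a blocked (jackknife over blocks) standard error.
#'
#' @param area numeric vector of projected areas, sigma^2 (one entry per
#'   sample after equilibration).
#' @param temperature epsilon/kB.
#' @param n_blocks number of blocks for the error estimate.
#' @return list with `K_A` (epsilon/sigma^2), `se`, `mean_area`,
#'   `var_area`.
#' @export
stretching_modulus <- function(area, temperature = 1.1, n_blocks = 10) {
  if (length(area) < 2 || var(area) == 0)
    stop("stretching_modulus: area series has zero variance (is the barostat on?)")
  KA <- temperature * mean(area) / var(area)
  blocks <- split(area, cut(seq_along(area), n_blocks, labels = FALSE))
  jack <- vapply(seq_len(n_blocks), function(b) {
    a <- unlist(blocks[-b], use.names = FALSE)
    temperature * mean(a) / var(a)
  }, numeric(1))
  se <- sqrt((n_blocks - 1) / n_blocks * sum((jack - mean(jack))^2))
  list(K_A = KA, se = se, mean_area = mean(area), var_area = var(area))
}
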