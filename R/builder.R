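#' Particle systems
#'
#' A `particle_system` bundles everything the engine integrates: unwrapped
#' bead positions and velocities (N x 3, sigma and sigma/tau), bead kind
#' labels, the bond list (1-based indices, type 1 = FENE, type 2 =
#' head–tail2 straightening spring), per-bead molecule ids, the periodic
#' box lengths, and — when a rigid robot is present — the rigid-group
#' bookkeeping (bead indices, body-frame reference coordinates, center and
#' rotation axis).
#'
#' @param positions N x 3 numeric matrix, sigma.
#' @param velocities N x 3 numeric matrix, sigma/tau.
#' @param kinds length-N character vector of bead kinds.
#' @param bonds integer matrix with columns (i, j, type); may have 0 rows.
#' @param molecule_id length-N integer vector (0 for non-lipid beads).
#' @param box numeric length-3 box edge lengths, sigma.
#' @param rigid `NULL` or `list(indices, reference, center, axis)`.
#' @return an object of class `particle_system`.
#' @export
particle_system <- function(positions, velocities, kinds, bonds, molecule_id,
                            box, rigid = NULL) {
  positions <- as.matrix(positions); velocities <- as.matrix(velocities)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, all(dim(velocities) == c(n, 3)),
            length(kinds) == n, length(molecule_id) == n, length(box) == 3,
            all(box > 0))
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- matrix(integer(), 0, 3)
  } else {
    bonds <- as.matrix(bonds)
    stopifnot(ncol(bonds) == 3, all(bonds[, 1:2] >= 1), all(bonds[, 1:2] <= n),
              all(bonds[, 3] %in% c(1L, 2L)))
  }
  kind_code(kinds)  # validates labels
  if (!is.null(rigid)) {
    stopifnot(is.list(rigid), all(c("indices", "reference", "center", "axis") %in% names(rigid)))
    stopifnot(length(rigid$indices) >= 1, all(rigid$indices >= 1),
              all(rigid$indices <= n),
              nrow(rigid$reference) == length(rigid$indices))
    if (nrow(bonds) > 0 && any(bonds[, 1] %in% rigid$indices | bonds[, 2] %in% rigid$indices))
      stop("particle_system: rigid-group beads must not appear in bonds")
  }
  structure(list(positions = positions, velocities = velocities,
                 kinds = kinds, bonds = bonds,
                 molecule_id = as.integer(molecule_id), box = as.numeric(box),
                 rigid = rigid),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  tab <- table(x$kinds)
  cat(sprintf("particle_system: %d beads, %d bonds, box %.2f x %.2f x %.2f sigma\n",
              nrow(x$positions), nrow(x$bonds), x$box[1], x$box[2], x$box[3]))
  cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$rigid))
    cat(sprintf("  rigid robot: %d beads, center (%.1f, %.1f, %.1f)\n",
                length(x$rigid$indices), x$rigid$center[1], x$rigid$center[2],
                x$rigid$center[3]))
  invisible(x)
}

# Maxwell-Boltzmann velocities at kT, net momentum removed
mb_velocities <- function(n, temperature) {
  v <- matrix(rnorm(3 * n, sd = sqrt(temperature)), n, 3)
  sweep(v, 2, colMeans(v))
}

#' Build a planar three-bead bilayer
#'
#' Places `nx * ny` lipids per leaflet on a square lattice, tails inward,
#' midplane at z = 0, with head–tail1–tail2 chains bonded by two FENE
#' bonds and one straightening spring. Lateral box lengths follow from the
#' requested area per lipid; velocities are Maxwell–Boltzmann at the given
#' temperature with zero net momentum. The initial area per lipid is only
#' a guess — under the tensionless barostat the box relaxes to the
#' stress-free area.
#'
#' @param nx,ny lipids per leaflet row/column (at least 4).
#' @param area_per_lipid initial projected area per lipid, sigma^2
#'   (between 1 and 2).
#' @param box_z out-of-plane box length, sigma.
#' @param temperature kinetic temperature for initial velocities,
#'   epsilon/kB.
#' @param seed RNG seed.
#' @return a [particle_system()] with `2 * nx * ny` lipids.
#' @export
build_bilayer <- function(nx, ny = nx, area_per_lipid = 1.2, box_z = 400,
                          temperature = 1.1, seed = 1L) {
  stopifnot(nx >= 4, ny >= 4, area_per_lipid >= 1.0, area_per_lipid <= 2.0)
  a <- sqrt(area_per_lipid)
  Lx <- nx * a; Ly <- ny * a
  n_lip <- 2L * nx * ny
  n <- 3L * n_lip
  pos <- matrix(0, n, 3)
  kinds <- character(n)
  mol <- integer(n)
  bonds <- matrix(0L, 3L * n_lip, 3)
  # chain geometry: bead spacing 0.95 along z, head outermost
  zs_up <- c(2.40, 1.45, 0.50)
  with_seed(seed, {
    jit <- matrix(runif(2 * n_lip, -0.05, 0.05), n_lip, 2)
    idx <- 0L
    for (leaflet in c(1, -1)) {
      for (i in seq_len(nx)) for (j in seq_len(ny)) {
        lip <- idx / 3L + 1L
        x0 <- (i - 0.5) * a + jit[lip, 1]
        y0 <- (j - 0.5) * a + jit[lip, 2]
        for (k in 1:3) {
          pos[idx + k, ] <- c(x0, y0, leaflet * zs_up[k])
        }
        kinds[idx + 1:3] <- c("HEAD", "TAIL1", "TAIL2")
        mol[idx + 1:3] <- lip
        b0 <- (lip - 1L) * 3L
        bonds[b0 + 1L, ] <- c(idx + 1L, idx + 2L, 1L)
        bonds[b0 + 2L, ] <- c(idx + 2L, idx + 3L, 1L)
        bonds[b0 + 3L, ] <- c(idx + 1L, idx + 3L, 2L)
        idx <- idx + 3L
      }
    }
    vel <- mb_velocities(n, temperature)
  })
  # placement sanity: nearest-neighbour distance on the lattice
  if (a - 0.1 < 0.8)
    stop("build_bilayer: lattice spacing too small, beads would overlap (< 0.8 sigma)")
  particle_system(pos, vel, kinds, bonds, mol, c(Lx, Ly, box_z))
}

# deterministic near-uniform directions on the unit sphere (Fibonacci)
fibonacci_sphere <- function(n) {
  if (n == 0) return(matrix(numeric(), 0, 3))
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build the rigid spiky particle
#'
#' Constructs the bead representation of the spiky nanoparticle in its
#' body frame (center at the origin): a spherical shell of core beads plus
#' tapered conical spikes. Each spike is a line of axis beads from the
#' core surface outward, decorated with rings whose radius shrinks
#' linearly from `L * tan(apex/2)` at the base to zero at the tip, so the
#' sampled apex angle sets the cone. Spike directions are near-uniform on
#' the sphere; lengths and apex angles are drawn uniformly from the
#' configured ranges. Identical geometry (seed included) yields an
#' identical bead set.
#'
#' @param geometry a [robot_geometry()].
#' @return a list with `positions` (body frame), `kinds`
#'   (`ROBOT_CORE`/`ROBOT_SPIKE`), and sampled `spike_length`,
#'   `apex_angle`, `directions`.
#' @export
build_spiky_robot <- function(geometry = robot_geometry()) {
  stopifnot(inherits(geometry, "robot_geometry"))
  g <- geometry
  sp <- g$bead_spacing
  n_core <- max(12L, round(4 * pi * g$core_radius^2 / sp^2))
  core <- fibonacci_sphere(n_core) * g$core_radius
  pos <- core
  kinds <- rep("ROBOT_CORE", nrow(core))
  lens <- numeric(0); angs <- numeric(0); dirs <- NULL
  if (g$n_spikes > 0) {
    dirs <- fibonacci_sphere(g$n_spikes)
    with_seed(g$seed, {
      lens <- runif(g$n_spikes, g$spike_length_range[1], g$spike_length_range[2])
      angs <- runif(g$n_spikes, g$apex_angle_range[1], g$apex_angle_range[2])
    })
    for (s in seq_len(g$n_spikes)) {
      d <- dirs[s, ]
      # orthonormal frame transverse to the spike axis
      ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- ref - sum(ref * d) * d; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(d[2] * e1[3] - d[3] * e1[2],
              d[3] * e1[1] - d[1] * e1[3],
              d[1] * e1[2] - d[2] * e1[1])
      L <- lens[s]
      rho0 <- L * tan(angs[s] / 2 * pi / 180)
      stations <- seq(0, L, by = sp)
      for (t in stations) {
        center <- d * (g$core_radius + t)
        pos <- rbind(pos, center)
        kinds <- c(kinds, "ROBOT_SPIKE")
        rho <- rho0 * (1 - t / L)
        n_ring <- floor(2 * pi * rho / sp)
        if (rho >= sp / 2 && n_ring >= 2) {
          th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
          ring <- t(vapply(th, function(a)
            center + rho * (cos(a) * e1 + sin(a) * e2), numeric(3)))
          pos <- rbind(pos, ring)
          kinds <- c(kinds, rep("ROBOT_SPIKE", n_ring))
        }
      }
    }
  }
  rownames(pos) <- NULL
  list(positions = pos, kinds = kinds,
       spike_length = lens, apex_angle = angs, directions = dirs)
}

#' Add cargo nanoparticles on the cis side
#'
#' Scatters `n` cargo beads uniformly in a z-interval above the upper
#' leaflet, rejecting placements closer than `diameter` to already-placed
#' cargo or closer than `2^(1/6) b_np` to any existing bead (lipid or
#' robot). Cargo velocities are Maxwell–Boltzmann at the given
#' temperature.
#'
#' @param system a [particle_system()].
#' @param n number of cargo beads.
#' @param diameter cargo diameter, sigma.
#' @param region `c(zmin, zmax)` placement interval; must lie above the
#'   bilayer slab.
#' @param temperature epsilon/kB for cargo velocities.
#' @param seed RNG seed.
#' @param max_tries placement attempts per bead before giving up.
#' @return the extended [particle_system()].
#' @export
add_cargo <- function(system, n, diameter = 2, region, temperature = 1.1,
                      seed = 1L, max_tries = 2000L) {
  stopifnot(inherits(system, "particle_system"), n >= 0)
  if (n == 0) return(system)
  lipid <- is_lipid_kind(system$kinds)
  if (any(lipid)) {
    top <- max(system$positions[lipid, 3])
    if (region[1] <= top)
      stop("add_cargo: placement region intersects the bilayer slab")
  }
  clearance <- 2^(1 / 6) * forcefield_params()$b_np
  placed <- matrix(numeric(), 0, 3)
  other <- system$positions
  box <- system$box
  # squared minimum-image distances from a candidate point to a point set
  min_image_d2 <- function(pts, cand) {
    d <- sweep(pts, 2, cand)
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    rowSums(d^2)
  }
  with_seed(seed, {
    for (k in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- c(runif(1, 0, box[1]), runif(1, 0, box[2]),
                  runif(1, region[1], region[2]))
        if (nrow(placed) > 0 && min(min_image_d2(placed, cand)) < diameter^2) next
        if (min(min_image_d2(other, cand)) < clearance^2) next
        placed <- rbind(placed, cand)
        ok <- TRUE
        break
      }
      if (!ok) stop("add_cargo: could not place cargo bead ", k,
                    " after ", max_tries, " attempts (packing error)")
    }
    vel_new <- mb_velocities(n, temperature)
  })
  rownames(placed) <- NULL
  particle_system(
    rbind(system$positions, placed),
    rbind(system$velocities, vel_new),
    c(system$kinds, rep("CARGO", n)),
    system$bonds,
    c(system$molecule_id, rep(0L, n)),
    system$box,
    system$rigid)
}

#' Assemble the full simulation scene
#'
#' Composes bilayer, rigid spiky robot and cargo into one system: the
#' robot is centered laterally and lowered until its lowest bead sits
#' `contact_gap` above the upper head plane; a configurable fraction of
#' upper-leaflet heads is relabelled `RECEPTOR_HEAD` (these adhere to
#' spike beads); cargo is scattered above the membrane. With
#' `protocol$robot_enabled = FALSE` the scene is the free-diffusion
#' control (bilayer + cargo only).
#'
#' @param protocol a [protocol_params()].
#' @param geometry a [robot_geometry()] (ignored when the robot is
#'   disabled).
#' @param nx,ny,area_per_lipid,seed passed to [build_bilayer()].
#' @param contact_gap initial gap between lowest robot bead and the upper
#'   head plane, sigma. The default is just inside the robot--membrane LJ
#'   contact distance `2^(1/6) b_np` (about 2.52 sigma), i.e. the robot
#'   starts in mechanical contact; much smaller gaps would start lipids
#'   deep inside the repulsive core.
#' @param cargo_region optional `c(zmin, zmax)`; default spans 2 to 10
#'   sigma above the upper head plane.
#' @return a [particle_system()].
#' @export
assemble_scene <- function(protocol = protocol_params(),
                           geometry = robot_geometry(),
                           nx = 20, ny = nx, area_per_lipid = 1.2,
                           seed = protocol$seed, contact_gap = 2.5,
                           cargo_region = NULL) {
  sys <- build_bilayer(nx, ny, area_per_lipid, box_z = protocol$box_z,
                       temperature = protocol$temperature, seed = seed)
  head_plane <- max(sys$positions[is_head_kind(sys$kinds), 3])
  if (isTRUE(protocol$robot_enabled)) {
    rb <- build_spiky_robot(geometry)
    # the rotating body must not see its own periodic image laterally
    lateral_span <- 2 * max(sqrt(rowSums(rb$positions[, 1:2, drop = FALSE]^2)))
    if (lateral_span + 1 > min(sys$box[1], sys$box[2]))
      stop("assemble_scene: robot larger than the lateral box")
    lowest <- min(rb$positions[, 3])
    center <- c(sys$box[1] / 2, sys$box[2] / 2, head_plane + contact_gap - lowest)
    n0 <- nrow(sys$positions)
    nrob <- nrow(rb$positions)
    rob_pos <- sweep(rb$positions, 2, center, "+")
    sys <- particle_system(
      rbind(sys$positions, rob_pos),
      rbind(sys$velocities, matrix(0, nrob, 3)),
      c(sys$kinds, rb$kinds),
      sys$bonds,
      c(sys$molecule_id, rep(0L, nrob)),
      sys$box,
      rigid = list(indices = n0 + seq_len(nrob), reference = rb$positions,
                   center = center, axis = protocol$robot_axis))
    # relabel receptor heads on the upper leaflet
    fr <- protocol$receptor_fraction
    if (fr > 0) {
      upper_heads <- which(sys$kinds == "HEAD" & sys$positions[, 3] > 0)
      n_rec <- round(fr * length(upper_heads))
      if (n_rec > 0) {
        sel <- with_seed(seed + 7L, sample(upper_heads, n_rec))
        sys$kinds[sel] <- "RECEPTOR_HEAD"
      }
    }
  }
  if (protocol$cargo_count > 0) {
    if (is.null(cargo_region)) {
      # size the slab so random sequential placement stays well below jamming
      h <- max(8, 3.5 * protocol$cargo_count * protocol$cargo_diameter^3 /
                 (sys$box[1] * sys$box[2]))
      cargo_region <- head_plane + c(2, 2 + h)
    }
    sys <- add_cargo(sys, protocol$cargo_count, protocol$cargo_diameter,
                     region = cargo_region, temperature = protocol$temperature,
                     seed = seed + 13L)
  }
  sys
}
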