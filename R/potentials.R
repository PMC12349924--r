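#' Pair and bond potentials of the three-bead lipid model
#'
#' Reference (vectorised R) implementations of the interactions that define
#' the model; the compiled engine carries its own optimised copies, and the
#' two are cross-checked in the test suite.
#'
#' * `u_rep()` — Weeks–Chandler–Andersen excluded-volume repulsion between
#'   all lipid beads, truncated at `2^(1/6) b`. With `rep_shifted = TRUE`
#'   (the default) the potential is raised by `eps_rep` so it is continuous
#'   (zero) at the cutoff; the unshifted variant retains the bare 12-6 form.
#' * `u_cos()` — the cosine-squared tail–tail attraction that replaces
#'   solvent: a flat `-eps_cos` well for `r < rc`, a smooth taper to zero
#'   over width `wc`.
#' * `u_fene()` — finitely extensible nonlinear elastic bond holding the
#'   three beads of a lipid together; diverges at `r_inf`.
#' * `u_bend()` — harmonic straightening spring between the head bead and
#'   the second tail bead, rest length `r0_bend` (4 sigma, beyond the
#'   maximal FENE extension, so it always pulls the lipid straight).
#' * `u_np()` — Lennard-Jones attraction between a nanoparticle bead
#'   (cargo or robot) and membrane beads, truncated and shifted at
#'   `rcut_np`.
#'
#' @param r distance(s) between the two beads, in sigma. Must be positive
#'   for the divergent potentials.
#' @param b length parameter of the 12-6 form, in sigma.
#' @param params a [forcefield_params()] list.
#' @return energy in epsilon (vectorised over `r`).
#' @examples
#' p <- forcefield_params()
#' u_rep(2^(1/6) * 0.95, b = 0.95, params = p)   # zero at the WCA cutoff
#' u_cos(p$rc, params = p)                        # bottom of the well: -1
#' u_fene(0.75, params = p)                       # ~9.709
#' @export
u_rep <- function(r, b, params = forcefield_params()) {
  stopifnot(b > 0)
  if (any(r <= 0)) stop("u_rep: r must be strictly positive (divergent at r = 0)")
  rcut <- 2^(1 / 6) * b
  s6 <- (b / r)^6
  u <- 4 * params$eps_rep * (s6^2 - s6)
  if (isTRUE(params$rep_shifted)) u <- u + params$eps_rep
  u[r > rcut] <- 0
  u
}

#' @rdname u_rep
#' @export
u_cos <- function(r, params = forcefield_params()) {
  if (any(r <= 0)) stop("u_cos: r must be strictly positive")
  rc <- params$rc; wc <- params$wc; eps <- params$eps_cos
  u <- numeric(length(r))
  u[r < rc] <- -eps
  mid <- r >= rc & r <= rc + wc
  u[mid] <- -eps * cos(pi * (r[mid] - rc) / (2 * wc))^2
  u
}

#' @rdname u_rep
#' @export
u_fene <- function(r, params = forcefield_params()) {
  if (any(r < 0)) stop("u_fene: r must be non-negative")
  if (any(r >= params$r_inf))
    stop(sprintf("FENE bond overstretched: r = %.4f >= r_inf = %.4f (typical of too-large timesteps)",
                 max(r), params$r_inf))
  -0.5 * params$k_fene * params$r_inf^2 * log(1 - (r / params$r_inf)^2)
}

#' @rdname u_rep
#' @export
u_bend <- function(r, params = forcefield_params()) {
  if (any(r < 0)) stop("u_bend: r must be non-negative")
  0.5 * params$k_bend * (r - params$r0_bend)^2
}

#' @rdname u_rep
#' @export
u_np <- function(r, params = forcefield_params()) {
  if (any(r <= 0)) stop("u_np: r must be strictly positive")
  b <- params$b_np; eps <- params$eps_np; rcut <- params$rcut_np
  s6 <- (b / r)^6
  s6c <- (b / rcut)^6
  u <- 4 * eps * (s6^2 - s6) - 4 * eps * (s6c^2 - s6c)
  u[r > rcut] <- 0
  u
}

#' Analytic pair force along the bead–bead axis
#'
#' Returns `-dU/dr` for the named potential: positive values push the pair
#' apart, negative values pull it together.
#'
#' @param potential one of `"rep"`, `"cos"`, `"fene"`, `"bend"`, `"np"`.
#' @param r distance(s), sigma.
#' @param params a [forcefield_params()] list.
#' @param b length parameter for `"rep"` (ignored otherwise).
#' @return force in epsilon/sigma, vectorised over `r`.
#' @export
pair_force <- function(potential, r, params = forcefield_params(), b = params$b_tail_tail) {
  potential <- match.arg(potential, c("rep", "cos", "fene", "bend", "np"))
  switch(potential,
    rep = {
      if (any(r <= 0)) stop("pair_force: r must be strictly positive")
      rcut <- 2^(1 / 6) * b
      s6 <- (b / r)^6
      f <- 24 * params$eps_rep * (2 * s6^2 - s6) / r
      f[r > rcut] <- 0
      f
    },
    cos = {
      rc <- params$rc; wc <- params$wc
      f <- numeric(length(r))
      mid <- r >= rc & r <= rc + wc
      x <- pi * (r[mid] - rc) / (2 * wc)
      f[mid] <- -params$eps_cos * (pi / (2 * wc)) * sin(2 * x)
      f
    },
    fene = {
      if (any(r >= params$r_inf)) stop("pair_force: FENE bond overstretched")
      -params$k_fene * r / (1 - (r / params$r_inf)^2)
    },
    bend = -params$k_bend * (r - params$r0_bend),
    np = {
      if (any(r <= 0)) stop("pair_force: r must be strictly positive")
      s6 <- (params$b_np / r)^6
      f <- 24 * params$eps_np * (2 * s6^2 - s6) / r
      f[r > params$rcut_np] <- 0
      f
    })
}

#' Kind-pair interaction rule table
#'
#' Enumerates, for every unordered pair of bead kinds, which nonbonded
#' potential applies and with which effective length, depth and cutoff.
#' Receptor heads behave as ordinary heads toward lipids and additionally
#' feel the adhesion well toward robot spike beads.
#'
#' @param params a [forcefield_params()] list.
#' @param file optional path; when given the table is also written as CSV
#'   for audit.
#' @return a data.frame with columns `kind_a`, `kind_b`, `potential`,
#'   `b`, `epsilon`, `cutoff`.
#' @export
pair_rule_table <- function(params = forcefield_params(), file = NULL) {
  kinds <- .kind_levels
  rows <- list()
  headlike <- function(k) k %in% c("HEAD", "RECEPTOR_HEAD")
  tailk <- function(k) k %in% c("TAIL1", "TAIL2")
  lip <- function(k) headlike(k) || tailk(k)
  rob <- function(k) k %in% c("ROBOT_CORE", "ROBOT_SPIKE")
  for (i in seq_along(kinds)) for (j in i:length(kinds)) {
    a <- kinds[i]; b <- kinds[j]
    pot <- "NONE"; bb <- NA_real_; ee <- NA_real_; cut <- NA_real_
    if (lip(a) && lip(b)) {
      if (tailk(a) && tailk(b)) {
        pot <- "WCA+COS"; bb <- params$b_tail_tail; ee <- params$eps_rep
        cut <- params$rc + params$wc
      } else if (headlike(a) && headlike(b)) {
        pot <- "WCA"; bb <- params$b_head_head; ee <- params$eps_rep
        cut <- 2^(1 / 6) * bb
      } else {
        pot <- "WCA"; bb <- params$b_head_tail; ee <- params$eps_rep
        cut <- 2^(1 / 6) * bb
      }
    } else if ((a == "CARGO" && lip(b)) || (lip(a) && b == "CARGO")) {
      pot <- "NP_LJ"; bb <- params$b_np; ee <- params$eps_np; cut <- params$rcut_np
    } else if ((rob(a) && lip(b)) || (lip(a) && rob(b))) {
      spike <- if (rob(a)) a else b
      lipk <- if (rob(a)) b else a
      if (spike == "ROBOT_SPIKE" && lipk == "RECEPTOR_HEAD") {
        pot <- "NP_LJ"; bb <- params$b_np; ee <- params$eps_receptor; cut <- params$rcut_np
      } else {
        pot <- "NP_LJ"; bb <- params$b_np; ee <- params$eps_np; cut <- params$rcut_np
      }
    } else if (a == "CARGO" && b == "CARGO") {
      pot <- "WCA"; bb <- params$b_cargo; ee <- params$eps_rep; cut <- 2^(1 / 6) * bb
    } else if ((a == "CARGO" && rob(b)) || (rob(a) && b == "CARGO")) {
      pot <- "WCA"; bb <- params$b_np; ee <- params$eps_rep; cut <- 2^(1 / 6) * bb
    }
    rows[[length(rows) + 1L]] <- data.frame(
      kind_a = a, kind_b = b, potential = pot, b = bb, epsilon = ee, cutoff = cut,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
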