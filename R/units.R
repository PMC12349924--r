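#' Reduced-unit system and SI mapping
#'
#' The dynamics are integrated in reduced units: length sigma, time tau,
#' energy epsilon, bead mass m = 1. A `unit_system` records what one
#' reduced unit is worth in SI.
#'
#' @param sigma_SI length of one sigma, metres.
#' @param tau_SI duration of one tau, seconds.
#' @param epsilon_SI energy of one epsilon, joules.
#' @return an object of class `unit_system`.
#' @examples
#' u <- unit_system()            # the calibrated mapping: 1 nm, 2 ns, 3.89e-21 J
#' convert_units(1, "pressure_2d", "to_SI", u)   # epsilon/sigma^2 in N/m
#' @export
unit_system <- function(sigma_SI = 1e-9, tau_SI = 2e-9,
                        epsilon_SI = 1.380649e-23 * 310 / 1.1) {
  kB <- 1.380649e-23
  vals <- c(sigma_SI = sigma_SI, tau_SI = tau_SI, epsilon_SI = epsilon_SI,
            boltzmann_SI = kB)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("unit_system: all unit scales must be strictly positive and finite")
  structure(list(sigma_SI = sigma_SI, tau_SI = tau_SI,
                 epsilon_SI = epsilon_SI, boltzmann_SI = kB),
            class = "unit_system")
}

#' @export
print.unit_system <- function(x, ...) {
  cat("Reduced-unit mapping:\n")
  cat(sprintf("  sigma   = %.6g m  (%.4g nm)\n", x$sigma_SI, x$sigma_SI * 1e9))
  cat(sprintf("  tau     = %.6g s  (%.4g ns)\n", x$tau_SI, x$tau_SI * 1e9))
  cat(sprintf("  epsilon = %.6g J\n", x$epsilon_SI))
  cat(sprintf("  eps/sigma^2 = %.4g mN/m   (2D modulus unit)\n",
              x$epsilon_SI / x$sigma_SI^2 * 1e3))
  cat(sprintf("  sigma^2/tau = %.4g um^2/s (diffusion unit)\n",
              x$sigma_SI^2 / x$tau_SI * 1e12))
  invisible(x)
}

#' Derive the unit system by matching simulation to experiment
#'
#' The length scale comes from matching membrane thickness, the time scale
#' from matching the lipid diffusion coefficient, and the energy scale
#' from matching temperature:
#' `sigma_SI = thickness_phys / thickness_model`,
#' `tau_SI = D_model * sigma_SI^2 / D_phys`,
#' `epsilon_SI = kB * T_phys / T_model`.
#'
#' @param thickness_phys membrane thickness, metres (mammalian membranes:
#'   about 5e-9).
#' @param thickness_model membrane thickness in the simulation, sigma.
#' @param D_phys lipid diffusion coefficient, m^2/s (experiments: about
#'   5e-12, i.e. 5 um^2/s).
#' @param D_model lipid diffusion coefficient in the simulation, sigma^2/tau.
#' @param T_phys temperature, kelvin.
#' @param T_model temperature in the simulation, epsilon/kB.
#' @return a [unit_system()].
#' @examples
#' derive_unit_system(5e-9, 5, 5e-12, 1e-2, 310, 1.1)  # 1 nm, 2 ns, 3.89e-21 J
#' @export
derive_unit_system <- function(thickness_phys, thickness_model,
                               D_phys, D_model, T_phys, T_model) {
  args <- c(thickness_phys, thickness_model, D_phys, D_model, T_phys, T_model)
  if (any(!is.finite(args)) || any(args <= 0))
    stop("derive_unit_system: all arguments must be strictly positive")
  sigma <- thickness_phys / thickness_model
  tau <- D_model * sigma^2 / D_phys
  eps <- 1.380649e-23 * T_phys / T_model
  unit_system(sigma_SI = sigma, tau_SI = tau, epsilon_SI = eps)
}

.dimension_factors <- function(units) {
  list(
    length = units$sigma_SI,
    time = units$tau_SI,
    energy = units$epsilon_SI,
    pressure_2d = units$epsilon_SI / units$sigma_SI^2,
    diffusion = units$sigma_SI^2 / units$tau_SI)
}

#' Convert a value between reduced and SI units
#'
#' @param value numeric scalar or vector in the source unit system.
#' @param dimension one of `"length"`, `"time"`, `"energy"`,
#'   `"pressure_2d"` (epsilon/sigma^2, an interfacial-modulus unit, N/m in
#'   SI) or `"diffusion"` (sigma^2/tau, m^2/s in SI).
#' @param direction `"to_SI"` (reduced -> SI) or `"to_reduced"`.
#' @param units a [unit_system()].
#' @return converted value(s).
#' @export
convert_units <- function(value, dimension, direction = c("to_SI", "to_reduced"),
                          units = unit_system()) {
  direction <- match.arg(direction)
  fac <- .dimension_factors(units)
  if (!dimension %in% names(fac))
    stop("convert_units: unknown dimension '", dimension,
         "'; supported: ", paste(names(fac), collapse = ", "))
  if (direction == "to_SI") value * fac[[dimension]] else value / fac[[dimension]]
}
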