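#' Define a polyelectrolyte solution mixture
#'
#' A mixture of fully charged polyanion (PA) chains of length `n_a` (charge
#' -1 per monomer), polycation (PC) chains of length `n_c` (charge +1 per
#' monomer) and a neutral monomeric solvent S, in the restricted primitive
#' model: all spheres share one diameter `d` and the background is a uniform
#' dielectric.  Composition is given as volume fractions; global
#' electroneutrality forces `phi_c == phi_a`, so a mixture is fully specified
#' by `(n_a, n_c, phi_a)`.
#'
#' @param n_a,n_c Integer chain lengths (>= 1) of the polyanion and
#'   polycation.
#' @param phi_a Volume fraction of the polyanion component.
#' @param phi_s Volume fraction of solvent.  Defaults to `1 - 2 * phi_a`.
#' @param phi_c Volume fraction of the polycation.  Must equal `phi_a`;
#'   present so that deliberately broken compositions are rejected loudly
#'   rather than silently repaired.
#'
#' @return An object of class `pel_mixture`: a list with elements `n_a`,
#'   `n_c`, `n_s` (always 1), `z_a` (-1), `z_c` (+1), `z_s` (0), `phi_a`,
#'   `phi_c`, `phi_s`.
#' @examples
#' mixture(n_a = 50, n_c = 1, phi_a = 0.05, phi_s = 0.9)
#' mixture(n_a = 1, n_c = 1, phi_a = 0)          # pure solvent
#' @export
mixture <- function(n_a, n_c, phi_a, phi_s = NULL, phi_c = NULL) {
  if (is.null(phi_c)) phi_c <- phi_a
  if (is.null(phi_s)) phi_s <- 1 - phi_a - phi_c
  mx <- structure(
    list(n_a = n_a, n_c = n_c, n_s = 1L,
         z_a = -1, z_c = +1, z_s = 0,
         phi_a = phi_a, phi_c = phi_c, phi_s = phi_s),
    class = "pel_mixture")
  validate_mixture(mx)
}

#' Validate a mixture description
#'
#' Checks the model invariants: integer chain lengths >= 1, non-negative
#' volume fractions summing to one (tolerance 1e-12), and electroneutrality
#' `phi_a * z_a + phi_c * z_c == 0`, which for the fully charged restricted
#' model means `phi_c == phi_a`.
#'
#' @param mx A `pel_mixture` or a bare list with the same fields.
#' @return The validated `pel_mixture` (invisibly usable in pipelines).
#' @export
validate_mixture <- function(mx) {
  for (f in c("n_a", "n_c", "phi_a", "phi_c", "phi_s"))
    if (is.null(mx[[f]]) || !is.numeric(mx[[f]]) || length(mx[[f]]) != 1L)
      stop("mixture field '", f, "' must be a single number", call. = FALSE)
  if (mx$n_a < 1 || mx$n_c < 1 || mx$n_a != round(mx$n_a) || mx$n_c != round(mx$n_c))
    stop("chain lengths n_a, n_c must be integers >= 1", call. = FALSE)
  if (min(mx$phi_a, mx$phi_c, mx$phi_s) < 0)
    stop("volume fractions must be non-negative", call. = FALSE)
  if (abs(mx$phi_a * -1 + mx$phi_c * +1) > 1e-12)
    stop("electroneutrality broken: phi_c must equal phi_a", call. = FALSE)
  if (abs(mx$phi_a + mx$phi_c + mx$phi_s - 1) > 1e-12)
    stop("volume fractions must sum to 1", call. = FALSE)
  if (!inherits(mx, "pel_mixture")) class(mx) <- "pel_mixture"
  mx
}

#' @export
print.pel_mixture <- function(x, ...) {
  cat("PA/PC/S mixture (restricted primitive model)\n")
  cat(sprintf("  N_A = %d (z = -1), N_C = %d (z = +1), N_S = 1 (neutral)\n",
              x$n_a, x$n_c))
  cat(sprintf("  phi_A = %g, phi_C = %g, phi_S = %g\n",
              x$phi_a, x$phi_c, x$phi_s))
  invisible(x)
}

#' Reduced thermodynamic state of a mixture
#'
#' Collects the dimensionless state variables used throughout: the total
#' packing fraction eta, partial packing fractions `eta_k = phi_k * eta`, the
#' reduced Bjerrum length `lb = L_B / d` (the inverse-temperature-like
#' coupling, L_B = e^2 / (eps kT)), and the derived Debye-Hueckel screening
#' strength `kappa` (kappa * d), from
#' \deqn{\kappa^2 d^2 = 4\pi L_B d^2 (\rho_T - \rho_S) = 24\, l_b\, (\eta - \eta_S).}
#' All quantities are reduced with the sphere diameter d = 1; densities per
#' sphere volume use v* = pi d^3 / 6.
#'
#' @param mx A `pel_mixture`.
#' @param eta Total packing fraction, in (0, 1).
#' @param lb Reduced Bjerrum length L_B/d, >= 0.
#' @return An object of class `pel_state`: a list with `mixture`, `eta`,
#'   `eta_a`, `eta_c`, `eta_s`, `lb`, `kappa`, `rho_total` (= 6 eta / pi),
#'   `rho_s`, `navg` (number-average chain length) and `vstar_over_d3`
#'   (= pi/6).
#' @examples
#' st <- reduced_state(mixture(50, 1, 0.05), eta = 0.3, lb = 4)
#' st$kappa   # sqrt(24 * 4 * 0.03)
#' @export
reduced_state <- function(mx, eta, lb) {
  mx <- validate_mixture(mx)
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0 || eta >= 1)
    stop("eta must be a single value in (0, 1)", call. = FALSE)
  if (!is.numeric(lb) || length(lb) != 1L || lb < 0)
    stop("lb must be a single value >= 0", call. = FALSE)
  eta_k <- c(a = mx$phi_a, c = mx$phi_c, s = mx$phi_s) * eta
  structure(
    list(mixture = mx, eta = eta,
         eta_a = eta_k[["a"]], eta_c = eta_k[["c"]], eta_s = eta_k[["s"]],
         lb = lb,
         kappa = sqrt(24 * lb * (eta - eta_k[["s"]])),
         rho_total = 6 * eta / pi,
         rho_s = 6 * eta_k[["s"]] / pi,
         navg = number_average_n(mx),
         vstar_over_d3 = pi / 6),
    class = "pel_state")
}

#' @export
print.pel_state <- function(x, ...) {
  cat("Reduced state:\n")
  cat(sprintf("  eta = %g (A %g, C %g, S %g), L_B/d = %g, kappa d = %g\n",
              x$eta, x$eta_a, x$eta_c, x$eta_s, x$lb, x$kappa))
  cat(sprintf("  number-average N = %g\n", x$navg))
  invisible(x)
}
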