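#' Number-average chain length of a mixture
#'
#' `1/N = phi_A/N_A + phi_C/N_C + phi_S`, i.e. the harmonic volume-fraction
#' average of chain sizes (the solvent counts with length 1).
#'
#' @param mx A `pel_mixture`.
#' @return The number-average chain length, in `[1, max(N_A, N_C)]`.
#' @examples
#' number_average_n(mixture(50, 1, 0.05))   # 1 / 0.951
#' @export
number_average_n <- function(mx) {
  1 / (mx$phi_a / mx$n_a + mx$phi_c / mx$n_c + mx$phi_s)
}

#' Hard-sphere-chain pressure (Baxter-Chiew reference)
#'
#' Reduced pressure of the athermal hard-sphere-chain mixture,
#' \deqn{\beta P_{HSC} v^* = \frac{\eta + \eta^2 + \eta^3}{(1-\eta)^3}
#'   - \Big(1 - \frac1N\Big)\frac{\eta + \eta^2/2}{(1-\eta)^2},}
#' obtained from the Percus-Yevick compressibility route for adhesive hard
#' spheres with the covalent-bond (connectivity) constraint; ternary contact
#' probability is neglected.  At `navg = 1` this is the Percus-Yevick
#' compressibility hard-sphere pressure.
#'
#' @param eta Packing fraction(s), in `[0, 1)`.
#' @param navg Number-average chain length (see [number_average_n()]).
#' @return `beta * P_HSC * vstar` (dimensionless), vectorised over `eta`.
#' @export
pressure_hsc <- function(eta, navg) {
  if (any(eta < 0 | eta >= 1)) stop("eta must be in [0, 1)", call. = FALSE)
  (eta + eta^2 + eta^3) / (1 - eta)^3 -
    (1 - 1 / navg) * (eta + eta^2 / 2) / (1 - eta)^2
}

#' Hard-sphere-chain excess Helmholtz free energy density
#'
#' `beta * A_ex * vstar / V` for the hard-sphere-chain reference, obtained by
#' density integration of the pressure.  The first bracket is the unbonded
#' hard-sphere excess; the second, proportional to `eta - eta/N`, is the
#' covalent-bonding (chain-formation) part and vanishes for monomers.
#'
#' @inheritParams pressure_hsc
#' @return `beta * A_ex * vstar / V`, vectorised over `eta`.
#' @export
helmholtz_ex_hsc <- function(eta, navg) {
  if (any(eta < 0 | eta >= 1)) stop("eta must be in [0, 1)", call. = FALSE)
  (1.5 * eta / (1 - eta)^2 - eta * (log1p(-eta) + 1.5)) -
    (eta - eta / navg) * (1.5 * eta / (1 - eta) - log1p(-eta))
}

#' Ideal chain-mixture free energy density
#'
#' `beta * A_id * vstar / V = sum_j (eta_j / N_j) log(eta_j / N_j)`.
#' The species molecular constants only shift chemical potentials by
#' composition-independent amounts (they cancel in any phase-equilibrium
#' condition) and are set to 1.  Terms with `eta_j = 0` contribute 0 by the
#' `x log x -> 0` continuity convention.
#'
#' @param eta_k Numeric vector of partial packing fractions.
#' @param n_k Numeric vector of matching chain lengths.
#' @return `beta * A_id * vstar / V`.
#' @export
helmholtz_id <- function(eta_k, n_k) {
  x <- eta_k / n_k
  sum(ifelse(x > 0, x * log(x), 0))
}

#' Hard-sphere-chain reference summary
#'
#' @param mx A `pel_mixture`.
#' @param eta Packing fraction in `[0, 1)`.
#' @return A list with `a_id`, `a_ex`, `p` (all in v*-units) and `navg`.
#' @export
hsc_eos <- function(mx, eta) {
  mx <- validate_mixture(mx)
  navg <- number_average_n(mx)
  eta_k <- c(mx$phi_a, mx$phi_c, mx$phi_s) * eta
  list(a_id = helmholtz_id(eta_k, c(mx$n_a, mx$n_c, 1)),
       a_ex = helmholtz_ex_hsc(eta, navg),
       p = pressure_hsc(eta, navg),
       navg = navg)
}
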