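#' MSA shielding parameter
#'
#' The renormalised screening parameter Gamma*d of the mean spherical
#' approximation for equal-size charged hard spheres, the positive root of
#' `2 Gamma d (1 + Gamma d) = kappa d`:
#' \deqn{\Gamma d = \tfrac12\big(\sqrt{1 + 2\kappa d} - 1\big).}
#' The closed quadratic is used rather than the equivalent nested radical;
#' the identity `2 Gamma (1 + Gamma) = kappa` then holds to machine
#' precision.
#'
#' @param kappa Reduced screening strength kappa*d, >= 0 (vectorised).
#' @return Gamma*d, >= 0.
#' @examples
#' shielding_gamma(4)   # exactly 1
#' @export
shielding_gamma <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  0.5 * (sqrt(1 + 2 * kappa) - 1)
}

# connectivity weight: sum_k (eta_k / N_k) (N_k - 1) over charged chain
# species (adjacent-bead charge product is +1 along a fully charged chain)
.bs_bond_weight <- function(state) {
  mx <- state$mixture
  state$eta_a / mx$n_a * (mx$n_a - 1) + state$eta_c / mx$n_c * (mx$n_c - 1)
}

#' Electrostatic free energy, Method I (Blum-Stell)
#'
#' Charge contribution to the Helmholtz free energy density in v*-units,
#' the sum of three closed-form terms:
#' \deqn{\beta\,\Delta A_{el} v^*/V =
#'   -l_b \sum_k \eta_k z_k^2 \frac{\Gamma d}{1+\Gamma d}
#'   + \frac{(\Gamma d)^3}{18}
#'   - l_b \sum_k \frac{\eta_k}{N_k}(N_k-1)
#'     \Big(1 - \frac{1}{(1+\Gamma d)^2}\Big),}
#' i.e. the MSA internal-energy term for unbonded charged spheres, the
#' entropic Gamma^3 term, and the chain-connectivity correction obtained
#' through Stell's cavity-function route (adjacent beads on a fully charged
#' chain have charge product +1, so each chain contributes `N_k - 1` bonded
#' pairs).
#'
#' @param state A `pel_state` (see [reduced_state()]).
#' @param units `"vstar"` (default) for `beta A v*/V` or `"d3"` for
#'   `beta A d^3/V` (conversion factor `6/pi`).
#' @return The electrostatic free-energy density (<= 0 in practice; exactly
#'   0 at kappa = 0).
#' @export
a_el_method1 <- function(state, units = c("vstar", "d3")) {
  units <- match.arg(units)
  g <- shielding_gamma(state$kappa)
  a <- -state$lb * (state$eta_a + state$eta_c) * g / (1 + g) +
    g^3 / 18 -
    state$lb * .bs_bond_weight(state) * (1 - 1 / (1 + g)^2)
  if (units == "d3") a * 6 / pi else a
}

#' Connectivity-only electrostatic free energy, Method I
#'
#' The third (cavity-function) term of [a_el_method1()] alone: the change in
#' electrostatic free energy due purely to bonding charged spheres into
#' chains.  Zero for monomeric electrolytes (`N_A = N_C = 1`) and at
#' `kappa = 0`.
#'
#' @inheritParams a_el_method1
#' @return The polymeric connectivity part of the electrostatic free energy.
#' @export
a_el_pol_method1 <- function(state, units = c("vstar", "d3")) {
  units <- match.arg(units)
  g <- shielding_gamma(state$kappa)
  a <- -state$lb * .bs_bond_weight(state) * (1 - 1 / (1 + g)^2)
  if (units == "d3") a * 6 / pi else a
}

#' Electrostatic pressure, Method I (Blum-Stell)
#'
#' `beta * DeltaP_el * vstar` by the thermodynamic route
#' `eta d(a_el)/d(eta) - a_el` at fixed composition, evaluated in closed
#' form.  The unbonded MSA part reduces exactly to `-(Gamma d)^3 / 18`; the
#' connectivity part uses the chain rule on `kappa ~ sqrt(eta)`,
#' `d(Gamma d)/d(eta) = kappa / (4 eta (1 + 2 Gamma d))`.
#'
#' @inheritParams a_el_method1
#' @return `beta * DeltaP_el * vstar` (or `* d^3` with `units = "d3"`).
#' @export
p_el_method1 <- function(state, units = c("vstar", "d3")) {
  units <- match.arg(units)
  g <- shielding_gamma(state$kappa)
  p <- -g^3 / 18 -
    state$lb * .bs_bond_weight(state) * state$kappa /
      (2 * (1 + g)^3 * (1 + 2 * g))
  if (units == "d3") p * 6 / pi else p
}

# analytic composition gradients of the Method I free energy (v*-units):
# the closed form depends on the charged density S = eta_A + eta_C only
# (kappa^2 = 24 lb S), so d/d(eta_S) = 0.  Written without divisions by
# kappa so the uncharged limit is exact.
.a_el1_grad <- function(state) {
  mx <- state$mixture
  k <- state$kappa
  if (k == 0) return(list(da = 0, dc = 0, ds = 0))
  lb <- state$lb
  g <- shielding_gamma(k)
  u <- g / (1 + g)
  s_gs <- k / (4 * (1 + 2 * g))          # S * dGamma/dS
  gs <- 6 * lb / (k * (1 + 2 * g))       # dGamma/dS
  s <- state$eta_a + state$eta_c
  b <- .bs_bond_weight(state)
  w <- 1 - 1 / (1 + g)^2
  d12 <- -lb * u - lb * s_gs / (1 + g)^2 + g^2 / 6 * gs
  d3 <- function(n) -lb * ((n - 1) / n * w + (b / s) * 2 / (1 + g)^3 * s_gs)
  list(da = d12 + d3(mx$n_a), dc = d12 + d3(mx$n_c), ds = 0)
}

#' Full Method I result
#'
#' @inheritParams a_el_method1
#' @return A list with `gamma` (Gamma d), `a_el`, `a_el_pol`, `p_el`
#'   (v*-units).
#' @export
method1_result <- function(state) {
  list(gamma = shielding_gamma(state$kappa),
       a_el = a_el_method1(state),
       a_el_pol = a_el_pol_method1(state),
       p_el = p_el_method1(state))
}
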