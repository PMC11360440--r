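# ---- internal free-energy plumbing ------------------------------------------

.a_el_vstar <- function(state, method) {
  switch(method,
         method1 = a_el_method1(state),
         method2 = a_el_method2(state, units = "vstar"),
         dh = dh_free_energy(state$kappa) * pi / 6,
         none = 0,
         stop("unknown method '", method, "'", call. = FALSE))
}

.p_el_vstar <- function(state, method) {
  switch(method,
         method1 = p_el_method1(state),
         method2 = p_el_method2(state, units = "vstar"),
         # eta da/deta = e_el for DH, so p = e_el - a_el = -dh_diff
         dh = -dh_diff(state$kappa) * pi / 6,
         none = 0,
         stop("unknown method '", method, "'", call. = FALSE))
}

# per-species gradients of the electrostatic free energy (v*-units)
.a_el_grad_vstar <- function(state, method) {
  zero <- list(da = 0, dc = 0, ds = 0)
  switch(method,
         method1 = .a_el1_grad(state),
         method2 = lapply(.a_el2_grad(state), `*`, pi / 6),
         dh = {
           k <- state$kappa
           d <- -state$lb * k / (2 * (1 + k))
           list(da = d, dc = d, ds = 0)
         },
         none = zero,
         stop("unknown method '", method, "'", call. = FALSE))
}

# per-species gradients of the chain excess free energy: with
# Q = sum_j eta_j / N_j, a_ex = F1(eta) - (eta - Q) F2(eta), so
# d(a_ex)/d(eta_j) = F1'(eta) - (1 - 1/N_j) F2(eta) - (eta - Q) F2'(eta)
.a_ex_grad_j <- function(eta, q, n_j) {
  f1p <- 1.5 * (1 + eta) / (1 - eta)^3 - log1p(-eta) +
    eta / (1 - eta) - 1.5
  f2 <- 1.5 * eta / (1 - eta) - log1p(-eta)
  f2p <- 1.5 / (1 - eta)^2 + 1 / (1 - eta)
  f1p - (1 - 1 / n_j) * f2 - (eta - q) * f2p
}

.methods <- c("method1", "method2", "dh", "none")

# ---- public surface ----------------------------------------------------------

#' Total Helmholtz free-energy density
#'
#' `beta * A * vstar / V = a_id + a_ex + a_el` for the selected
#' electrostatic treatment: `"method1"` (Blum-Stell), `"method2"`
#' (multi-density Ornstein-Zernike, converted from d^3- to v*-units),
#' `"dh"` (Debye-Hueckel limiting law) or `"none"` (athermal hard-sphere
#' chains).
#'
#' @param mx A `pel_mixture`.
#' @param eta Total packing fraction in (0, 1).
#' @param lb Reduced Bjerrum length L_B/d.
#' @param method One of `"method1"`, `"method2"`, `"dh"`, `"none"`.
#' @return `beta * A * vstar / V`.
#' @export
total_free_energy <- function(mx, eta, lb, method = .methods) {
  method <- match.arg(method)
  st <- reduced_state(mx, eta, lb)
  helmholtz_id(c(st$eta_a, st$eta_c, st$eta_s), c(mx$n_a, mx$n_c, 1)) +
    helmholtz_ex_hsc(eta, st$navg) + .a_el_vstar(st, method)
}

#' Total reduced pressure
#'
#' `beta * P * vstar = p_HSC + DeltaP_el`, the hard-sphere-chain reference
#' pressure plus the electrostatic pressure of the selected method (each in
#' closed form, consistent with the free energy through
#' `p = eta da/deta - a`).
#'
#' @inheritParams total_free_energy
#' @return `beta * P * vstar`.
#' @export
total_pressure <- function(mx, eta, lb, method = .methods) {
  method <- match.arg(method)
  st <- reduced_state(mx, eta, lb)
  pressure_hsc(eta, st$navg) + .p_el_vstar(st, method)
}

#' Chemical potentials
#'
#' Reduced chemical potentials as derivatives of the free-energy density
#' with respect to the partial packing fractions,
#' `mu_k / (N_k kT) = d(beta A vstar / V) / d(eta_k)`, evaluated
#' analytically for all three parts (ideal, chain excess, electrostatic).
#' The electrostatic closed forms depend on composition through the total
#' charged density `eta_A + eta_C` (they are derived under
#' electroneutrality), so the reported per-species values are the
#' derivatives of that analytic continuation; the combinations entering
#' any phase-equilibrium condition --- the effective polymer chemical
#' potential `mu_eff = mu_A,eff / N_A = mu_A / N_A + mu_C / N_C` and the
#' solvent `mu_s` --- only ever involve the electroneutral direction.
#'
#' @inheritParams total_free_energy
#' @return A list with `mu_eff`, `mu_s`, `mu_a`, `mu_c` (per monomer, i.e.
#'   `mu_k / (N_k kT)`; `-Inf` for an absent species).
#' @export
chemical_potentials <- function(mx, eta, lb, method = .methods) {
  method <- match.arg(method)
  st <- reduced_state(mx, eta, lb)
  q <- eta / st$navg
  del <- .a_el_grad_vstar(st, method)
  mu_a <- if (st$eta_a > 0)
    (log(st$eta_a / mx$n_a) + 1) / mx$n_a +
      .a_ex_grad_j(eta, q, mx$n_a) + del$da
  else -Inf
  mu_c <- if (st$eta_c > 0)
    (log(st$eta_c / mx$n_c) + 1) / mx$n_c +
      .a_ex_grad_j(eta, q, mx$n_c) + del$dc
  else -Inf
  mu_s <- if (st$eta_s > 0)
    log(st$eta_s) + 1 + .a_ex_grad_j(eta, q, 1) + del$ds
  else -Inf
  list(mu_eff = mu_a + mu_c, mu_s = mu_s, mu_a = mu_a, mu_c = mu_c)
}

#' Gibbs free-energy density
#'
#' `g = (beta A vstar / V + beta P vstar) / eta`, the Gibbs free energy per
#' sphere in kT units.  Satisfies the Euler identity
#' `g = phi_A * mu_eff + phi_S * mu_s`.
#'
#' @inheritParams total_free_energy
#' @return The reduced Gibbs free-energy density.
#' @export
gibbs_density <- function(mx, eta, lb, method = .methods) {
  method <- match.arg(method)
  (total_free_energy(mx, eta, lb, method) +
     total_pressure(mx, eta, lb, method)) / eta
}

#' Solve the packing fraction at fixed reduced pressure
#'
#' Finds `eta` with `total_pressure(mx, eta, lb, method) == p_target`.
#' Candidate roots are bracketed on a scan of (0, 0.74] (the physical
#' validity range of the equation of state, capped near random close
#' packing), refined by [stats::uniroot()] and Newton-polished to a
#' pressure residual below 1e-12.  Mechanically unstable roots
#' (`dP/deta <= 0`, possible below the critical temperature where the
#' isotherm develops a loop) are discarded; among multiple stable roots the
#' one with the lowest Gibbs density is returned, which is the equilibrium
#' branch.
#'
#' @inheritParams total_free_energy
#' @param p_target Target reduced pressure `beta P vstar`, > 0.
#' @param eta_init Optional warm start; when supplied, a local Newton
#'   iteration is tried first and the global scan is used as fallback.
#' @param interval Search interval for `eta`.
#' @return The packing fraction (a single number), with attributes
#'   `residual` (pressure mismatch) and `dp_deta` (local slope, > 0).
#' @export
solve_eta_at_pressure <- function(mx, lb, method = .methods, p_target = 1,
                                  eta_init = NULL,
                                  interval = c(1e-9, 0.74)) {
  method <- match.arg(method)
  if (p_target <= 0) stop("p_target must be > 0", call. = FALSE)
  mx <- validate_mixture(mx)
  # scans cross unphysical density ranges while bracketing; diagnostics
  # (such as the MDOZ |H| >= 1 warning) are only meaningful at the root
  fr <- function(e) suppressWarnings(total_pressure(mx, e, lb, method)) - p_target
  slope <- function(e) {
    h <- 1e-7 * max(e, 1e-2)
    (fr(e + h) - fr(e - h)) / (2 * h)
  }
  polish <- function(e) {
    for (i in 1:4) {
      de <- fr(e) / slope(e)
      if (!is.finite(de)) break
      e2 <- e - de
      if (e2 <= interval[1] || e2 >= interval[2]) break
      e <- e2
      if (abs(de) < 1e-15 * max(e, 1e-3)) break
    }
    e
  }
  out <- function(e) {
    structure(e, residual = fr(e), dp_deta = slope(e))
  }
  if (!is.null(eta_init) &&
      eta_init > interval[1] && eta_init < interval[2]) {
    e <- polish(eta_init)
    if (abs(fr(e)) < 1e-12 && slope(e) > 0) return(out(e))
  }
  grid <- seq(interval[1], interval[2], length.out = 160)
  v <- vapply(grid, fr, numeric(1))
  idx <- which(v[-1] * v[-length(v)] < 0)
  if (length(idx) == 0)
    stop("no root: pressure never crosses p_target on the search interval",
         call. = FALSE)
  roots <- vapply(idx, function(i)
    polish(stats::uniroot(fr, c(grid[i], grid[i + 1]), tol = 1e-14)$root),
    numeric(1))
  roots <- roots[vapply(roots, slope, numeric(1)) > 0]
  if (length(roots) == 0)
    stop("all candidate roots are mechanically unstable", call. = FALSE)
  if (length(roots) > 1) {
    gs <- vapply(roots, function(e) gibbs_density(mx, e, lb, method),
                 numeric(1))
    roots <- roots[which.min(gs)]
  }
  out(roots)
}

#' Thermodynamic state table
#'
#' Convenience wrapper evaluating the full thermodynamics on a grid of
#' packing fractions at fixed composition and coupling; the natural format
#' for isochore/isobar tables.
#'
#' @inheritParams total_free_energy
#' @param eta Vector of packing fractions.
#' @return A data.frame with columns `eta`, `phi_a`, `lb`, `p_vstar`,
#'   `a_vstar`, `mu_s`, `mu_a_eff`, `g`.
#' @export
thermo_table <- function(mx, eta, lb, method = .methods) {
  method <- match.arg(method)
  rows <- lapply(eta, function(e) {
    mu <- chemical_potentials(mx, e, lb, method)
    data.frame(eta = e, phi_a = mx$phi_a, lb = lb,
               p_vstar = total_pressure(mx, e, lb, method),
               a_vstar = total_free_energy(mx, e, lb, method),
               mu_s = mu$mu_s, mu_a_eff = mu$mu_eff,
               g = gibbs_density(mx, e, lb, method))
  })
  do.call(rbind, rows)
}
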