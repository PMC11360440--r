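# ---- deterministic validation fixtures --------------------------------------

#' Deterministic grid of validation states
#'
#' A fixed grid of mixtures and reduced conditions spanning the regimes the
#' theory covers: monomeric electrolytes, symmetric and asymmetric chain
#' pairs, dilute to dense packing and weak to strong coupling.  Used by the
#' cross-method and limit-law test harness.
#'
#' @return A data.frame with columns `n_a`, `n_c`, `phi_a`, `phi_s`, `eta`,
#'   `lb`.
#' @export
fixture_grid <- function() {
  sys <- data.frame(n_a = c(1, 1, 8, 50, 16, 50),
                    n_c = c(1, 1, 8, 1, 1, 10),
                    phi_a = c(0.05, 0.25, 0.1, 0.05, 0.2, 0.15))
  cond <- expand.grid(eta = c(1e-4, 0.05, 0.2, 0.35, 0.5),
                      lb = c(0.1, 1, 4, 10))
  out <- merge(sys, cond)
  out$phi_s <- 1 - 2 * out$phi_a
  out[, c("n_a", "n_c", "phi_a", "phi_s", "eta", "lb")]
}

#' Cross-method and limit-law validation suite
#'
#' Runs the structural identities that tie the two electrostatic methods
#' together and to the Debye-Hueckel limit:
#' \itemize{
#'   \item monomeric equivalence: for `N_A = N_C = 1` the Blum-Stell and
#'     MDOZ free energies agree (in v*-units) on the whole fixture grid;
#'   \item the shielding identity `a_el - e_el = Gamma^3 / (3 pi)` at
#'     `m = 1` on a kappa grid;
#'   \item Debye-Hueckel series agreement of the monomeric MDOZ free energy
#'     through order kappa^4 (numerically extracted Taylor coefficients)
#'     and disagreement at order kappa^5;
#'   \item thermodynamic consistency `p = eta da/deta - a` (central finite
#'     differences) and the Euler identity
#'     `g = phi_A mu_eff + phi_S mu_s` for every method on the grid.
#' }
#'
#' @param tol_equiv Tolerance for the monomeric method-equivalence check.
#' @param tol_thermo Tolerance for the consistency identities.
#' @return A data.frame with columns `check`, `max_err`, `tol`, `pass`;
#'   attribute `pass` gives the overall outcome.
#' @export
limit_suite <- function(tol_equiv = 1e-10, tol_thermo = 1e-6) {
  grid <- fixture_grid()
  res <- list()

  mono <- grid[grid$n_a == 1 & grid$n_c == 1, ]
  err <- max(vapply(seq_len(nrow(mono)), function(i) {
    st <- reduced_state(mixture(1, 1, mono$phi_a[i]), mono$eta[i],
                        mono$lb[i])
    abs(a_el_method1(st) - a_el_method2(st, units = "vstar"))
  }, numeric(1)))
  res$method_equivalence_m1 <- c(err, tol_equiv)

  kgrid <- 10^seq(-2, 1, length.out = 13)
  err <- max(abs(-big_d(kgrid, 1, 0) / (12 * pi) -
                   (kgrid / (4 * pi)) * (-kgrid - 1 + sqrt(1 + 2 * kgrid)) -
                   shielding_gamma(kgrid)^3 / (3 * pi)))
  res$gamma_cubed_identity <- c(err, 1e-12)

  # Taylor coefficients of the monomeric MDOZ free energy at small kappa
  a_m1 <- function(k) -big_d(k, 1, 0) / (12 * pi)
  co <- .taylor_coeffs(a_m1, orders = 3:5)
  err <- max(abs(co[1] - (-1 / (12 * pi))) / (1 / (12 * pi)),
             abs(co[2] - (1 / (16 * pi))) / (1 / (16 * pi)))
  res$dh_series_match_k3_k4 <- c(err, 1e-4)
  # kappa^5: MDOZ gives -1/(16 pi), DH gives -1/(20 pi) -- they must differ
  sep <- abs(co[3] - (-1 / (16 * pi))) < abs(co[3] - (-1 / (20 * pi)))
  res$dh_series_differ_k5 <- c(as.numeric(!sep), 0.5)

  # thermodynamic consistency on the grid
  err_p <- 0; err_g <- 0
  for (i in seq_len(nrow(grid))) {
    mx <- mixture(grid$n_a[i], grid$n_c[i], grid$phi_a[i])
    for (method in c("method1", "method2", "dh", "none")) {
      e <- grid$eta[i]; lb <- grid$lb[i]
      h <- 1e-5 * e
      da <- (total_free_energy(mx, e + h, lb, method) -
               total_free_energy(mx, e - h, lb, method)) / (2 * h)
      p <- total_pressure(mx, e, lb, method)
      err_p <- max(err_p, abs(e * da - total_free_energy(mx, e, lb, method) -
                                p) / max(abs(p), 1))
      mu <- chemical_potentials(mx, e, lb, method)
      g <- gibbs_density(mx, e, lb, method)
      euler <- mx$phi_a * mu$mu_eff + mx$phi_s * mu$mu_s
      err_g <- max(err_g, abs(g - euler) / max(abs(g), 1))
    }
  }
  res$pressure_consistency <- c(err_p, tol_thermo)
  res$euler_identity <- c(err_g, tol_thermo)

  out <- data.frame(check = names(res),
                    max_err = vapply(res, `[`, numeric(1), 1),
                    tol = vapply(res, `[`, numeric(1), 2))
  out$pass <- out$max_err < out$tol
  attr(out, "pass") <- all(out$pass)
  rownames(out) <- NULL
  out
}

# Taylor coefficients of f (with f(0) = 0) at 0 by Richardson-extrapolated
# polynomial fitting on a shrinking kappa grid
.taylor_coeffs <- function(f, orders = 3:5, k0 = 1e-2) {
  k <- k0 * seq(0.2, 1, length.out = 12)
  y <- vapply(k, f, numeric(1))
  # the series starts at kappa^3 for the electrostatic free energies
  x <- stats::lm(y ~ 0 + I(k^3) + I(k^4) + I(k^5) + I(k^6) + I(k^7))
  unname(stats::coef(x)[orders - 2])
}

#' Regenerate the package's reference figure tables
#'
#' Deterministic tables underlying the three reference comparisons:
#' \describe{
#'   \item{fig1}{Connectivity-only electrostatic free energy for
#'     `N_A = 50`, `N_C = 10`, `phi_S = 0.6` at `L_B/d = 5.516`, against
#'     packing fraction, for both methods and both unit conventions.}
#'   \item{fig2}{Pressure isochore `beta P d^3` against number density
#'     `6 eta / pi` for the salt-free polyanion/counterion solution
#'     `N_A = 16`, `N_C = 1` at `L_B/d = 0.833` (the solvent fraction is
#'     taken as 1e-10 to realise the salt-free limit without an empty
#'     component), both methods.}
#'   \item{fig3}{Binodal lines of the `N_A = 50`, `N_C = 1` solution at
#'     `beta P v* = 1` for both methods (expensive: two critical-point
#'     searches plus continuation traces).}
#' }
#'
#' @param which One of `"fig1"`, `"fig2"`, `"fig3"`.
#' @param n_points Grid resolution.
#' @return A data.frame (contents depend on `which`).
#' @export
figure_fixtures <- function(which = c("fig1", "fig2", "fig3"),
                            n_points = 40) {
  which <- match.arg(which)
  if (which == "fig1") {
    eta <- seq(0.01, 0.5, length.out = n_points)
    mx <- mixture(50, 10, phi_a = 0.2)   # phi_S = 0.6
    rows <- lapply(eta, function(e) {
      st <- reduced_state(mx, e, 5.516)
      data.frame(eta = e,
                 a_pol_bs_vstar = a_el_pol_method1(st),
                 a_pol_mdoz_vstar = a_el_pol_method2(st, units = "vstar"),
                 a_pol_bs_d3 = a_el_pol_method1(st, units = "d3"),
                 a_pol_mdoz_d3 = a_el_pol_method2(st))
    })
    return(do.call(rbind, rows))
  }
  if (which == "fig2") {
    rho <- seq(0.01, 0.45, length.out = n_points)
    eta <- rho * pi / 6
    mx <- mixture(16, 1, phi_a = (1 - 1e-10) / 2)
    rows <- lapply(eta, function(e)
      data.frame(rho = 6 * e / pi, eta = e,
                 p_d3_bs = total_pressure(mx, e, 0.833, "method1") * 6 / pi,
                 p_d3_mdoz = total_pressure(mx, e, 0.833, "method2") * 6 / pi))
    return(do.call(rbind, rows))
  }
  # fig3
  template <- mixture(50, 1, 0.05)
  out <- lapply(c("method1", "method2"), function(m) {
    cp <- find_critical_point(template, m)
    lb_grid <- cp$lb_cp / (1 - seq(0.02, 0.30, length.out = n_points %/% 2))
    tr <- trace_binodal(template, lb_grid, m)
    tr$method <- m
    tr$lb_cp <- cp$lb_cp
    tr$phi_cp <- cp$phi_cp
    tr
  })
  do.call(rbind, out)
}
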