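# ---- critical exponents by log-log regression --------------------------------
#
# The reduced temperature is t = L_B,cp / L_B - 1: the Bjerrum length is
# L_B = e^2 / (eps kT), so at fixed dielectric constant T is proportional
# to 1 / L_B and t has the conventional sign (t < 0 in the two-phase
# region, where L_B > L_B,cp).

.new_exponent <- function(name, x, y) {
  fit <- stats::lm(log(y) ~ log(x))
  ss_tot <- sum((log(y) - mean(log(y)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(name = name,
                 value = unname(stats::coef(fit)[2]),
                 fit_range = range(x),
                 n_points = length(x),
                 r_squared = r2),
            class = "pel_exponent")
}

#' @export
print.pel_exponent <- function(x, ...) {
  cat(sprintf("%s = %.4f  (%d points, |x| in [%.3g, %.3g], R^2 = %.6f)\n",
              x$name, x$value, x$n_points, x$fit_range[1], x$fit_range[2],
              x$r_squared))
  invisible(x)
}

#' Binodal trace for order-parameter scaling
#'
#' Solves the coexistence gap `dphi = phi_b - phi_a` on a log-spaced grid
#' of reduced temperatures `|t|` on the two-phase side
#' (`L_B = L_B,cp / (1 - |t|)`), for use with [fit_beta()].
#'
#' @param template A `pel_mixture` supplying chain lengths.
#' @param cp A `pel_critical_point` from [find_critical_point()].
#' @param method Electrostatic method.
#' @param p_target Fixed reduced pressure.
#' @param window Range of `|t|`.
#' @param n_points Number of log-spaced points.
#' @return A data.frame with columns `abs_t`, `lb`, `phi_a`, `phi_b`,
#'   `dphi`, `residual`, `converged`.
#' @export
binodal_scaling_trace <- function(template, cp, method = .methods,
                                  p_target = 1, window = c(1e-4, 1e-2),
                                  n_points = 20) {
  method <- match.arg(method)
  abs_t <- exp(seq(log(window[2]), log(window[1]), length.out = n_points))
  rows <- vector("list", n_points)
  guess <- NULL
  for (i in seq_along(abs_t)) {
    lb <- cp$lb_cp / (1 - abs_t[i])
    bp <- binodal_at_lb(template, lb, method, p_target, guess = guess)
    if (bp$two_phase && bp$converged) {
      # continuation guess: shrink the gap by the mean-field sqrt scaling
      shrink <- if (i < n_points) sqrt(abs_t[i + 1] / abs_t[i]) else 1
      guess <- c(cp$phi_cp - (cp$phi_cp - bp$phi_a) * shrink,
                 cp$phi_cp + (bp$phi_b - cp$phi_cp) * shrink)
    } else {
      guess <- NULL
    }
    rows[[i]] <- data.frame(abs_t = abs_t[i], lb = lb,
                            phi_a = bp$phi_a, phi_b = bp$phi_b,
                            dphi = bp$phi_b - bp$phi_a,
                            residual = bp$residual,
                            converged = isTRUE(bp$converged) & bp$two_phase)
  }
  do.call(rbind, rows)
}

#' Inverse-susceptibility trace along the critical isochore
#'
#' Evaluates `chi^-1 = d^2 g / d phi_A^2` at `phi_A = phi_cp` on the
#' one-phase side (`t > 0`, `L_B = L_B,cp / (1 + t)`), for [fit_gamma()].
#'
#' @inheritParams binodal_scaling_trace
#' @return A data.frame with columns `t`, `lb`, `chi_inv`.
#' @export
susceptibility_trace <- function(template, cp, method = .methods,
                                 p_target = 1, window = c(1e-4, 1e-2),
                                 n_points = 20) {
  method <- match.arg(method)
  t <- exp(seq(log(window[1]), log(window[2]), length.out = n_points))
  chi <- vapply(t, function(tt)
    inverse_susceptibility(template, cp$phi_cp, cp$lb_cp / (1 + tt),
                           method, p_target), numeric(1))
  data.frame(t = t, lb = cp$lb_cp / (1 + t), chi_inv = chi)
}

#' Effective-field trace along the critical isotherm
#'
#' Evaluates the change of the effective polymer chemical potential
#' `dmu = mu_eff(phi_A) - mu_eff(phi_cp)` at `L_B = L_B,cp` (the `t = 0`
#' isotherm) for `phi_A - phi_cp` on a log grid, for [fit_delta()].
#'
#' @inheritParams binodal_scaling_trace
#' @param window Range of `phi_A - phi_cp`.
#' @return A data.frame with columns `dphi` (= phi_A - phi_cp), `phi_a`,
#'   `dmu`.
#' @export
isotherm_trace <- function(template, cp, method = .methods, p_target = 1,
                           window = c(1e-4, 1e-3), n_points = 20) {
  method <- match.arg(method)
  mu_at <- function(phi) {
    mx <- mixture(template$n_a, template$n_c, phi)
    e <- solve_eta_at_pressure(mx, cp$lb_cp, method, p_target)
    chemical_potentials(mx, as.numeric(e), cp$lb_cp, method)$mu_eff
  }
  mu0 <- mu_at(cp$phi_cp)
  x <- exp(seq(log(window[1]), log(window[2]), length.out = n_points))
  dmu <- vapply(x, function(xx) mu_at(cp$phi_cp + xx) - mu0, numeric(1))
  data.frame(dphi = x, phi_a = cp$phi_cp + x, dmu = dmu)
}

#' Order-parameter exponent beta
#'
#' Least-squares slope of `ln |phi_b - phi_a|` against `ln |t|` over the
#' fit window; mean-field theories give 1/2.
#'
#' @param trace A data.frame with columns `abs_t` and `dphi` (e.g. from
#'   [binodal_scaling_trace()]).
#' @param window Fit window on `|t|`.
#' @return A `pel_exponent` with fields `value`, `fit_range`, `n_points`,
#'   `r_squared`.
#' @export
fit_beta <- function(trace, window = c(1e-4, 1e-2)) {
  keep <- is.finite(trace$dphi) & trace$dphi > 0 &
    trace$abs_t >= window[1] * (1 - 1e-9) &
    trace$abs_t <= window[2] * (1 + 1e-9)
  if (sum(keep) < 5) stop("need at least 5 binodal points in the window",
                          call. = FALSE)
  .new_exponent("beta", trace$abs_t[keep], trace$dphi[keep])
}

#' Susceptibility exponent gamma
#'
#' Slope of `ln chi^-1` against `ln t` on the one-phase side; mean-field
#' theories give 1.
#'
#' @param trace A data.frame with columns `t` and `chi_inv` (e.g. from
#'   [susceptibility_trace()]).
#' @param window Fit window on `t`.
#' @return A `pel_exponent`.
#' @export
fit_gamma <- function(trace, window = c(1e-4, 1e-2)) {
  keep <- is.finite(trace$chi_inv) & trace$chi_inv > 0 &
    trace$t >= window[1] * (1 - 1e-9) & trace$t <= window[2] * (1 + 1e-9)
  if (sum(keep) < 5) stop("need at least 5 points in the window",
                          call. = FALSE)
  .new_exponent("gamma", trace$t[keep], trace$chi_inv[keep])
}

#' Critical-isotherm exponent delta
#'
#' Slope of `ln dmu` against `ln (phi_A - phi_cp)` along the critical
#' isotherm, with the effective chemical potential playing the role of the
#' ordering field; mean-field theories give 3 (reciprocal-slope
#' convention: the reported exponent is 1 / slope of M vs H).
#'
#' @param trace A data.frame with columns `dphi` and `dmu` (e.g. from
#'   [isotherm_trace()]).
#' @param window Fit window on `phi_A - phi_cp`.
#' @return A `pel_exponent`.
#' @export
fit_delta <- function(trace, window = c(1e-4, 1e-3)) {
  keep <- is.finite(trace$dmu) & trace$dmu > 0 &
    trace$dphi >= window[1] * (1 - 1e-9) &
    trace$dphi <= window[2] * (1 + 1e-9)
  if (sum(keep) < 5) stop("need at least 5 points in the window",
                          call. = FALSE)
  .new_exponent("delta", trace$dphi[keep], trace$dmu[keep])
}

#' All three critical exponents of a system
#'
#' Orchestrates [find_critical_point()] (unless `cp` is supplied),
#' [binodal_scaling_trace()], [susceptibility_trace()] and
#' [isotherm_trace()], then fits beta, gamma and delta over the default
#' windows.
#'
#' @inheritParams binodal_scaling_trace
#' @param cp Optional precomputed `pel_critical_point`.
#' @param n_points Points per trace.
#' @return A list with `beta`, `gamma`, `delta` (`pel_exponent`s), the
#'   three traces, and `cp`.
#' @export
critical_exponents <- function(template, method = .methods, p_target = 1,
                               cp = NULL, n_points = 20) {
  method <- match.arg(method)
  if (is.null(cp)) cp <- find_critical_point(template, method, p_target)
  tr_b <- binodal_scaling_trace(template, cp, method, p_target,
                                n_points = n_points)
  tr_g <- susceptibility_trace(template, cp, method, p_target,
                               n_points = n_points)
  tr_d <- isotherm_trace(template, cp, method, p_target,
                         n_points = n_points)
  list(beta = fit_beta(tr_b), gamma = fit_gamma(tr_g),
       delta = fit_delta(tr_d),
       binodal_trace = tr_b, chi_trace = tr_g, isotherm = tr_d, cp = cp)
}
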