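# ---- fixed-pressure Gibbs density and its composition derivatives -----------

# Gibbs density at fixed pressure as a function of the PA volume fraction
# (electroneutral two-component reduction: phi_C = phi_A, phi_S = 1 - 2 phi_A).
# A per-call environment carries the last solved eta as a warm start.
.g_fp_maker <- function(n_a, n_c, lb, method, p_target) {
  env <- new.env(parent = emptyenv())
  env$eta <- NULL
  function(phi_a, lb_override = NULL) {
    lbv <- if (is.null(lb_override)) lb else lb_override
    mx <- mixture(n_a, n_c, phi_a)
    e <- solve_eta_at_pressure(mx, lbv, method, p_target, eta_init = env$eta)
    env$eta <- as.numeric(e)
    (total_free_energy(mx, e, lbv, method) + p_target) / as.numeric(e)
  }
}

# five-point central stencil: second and third derivative of g(phi) at phi_a
.g_d23 <- function(gfun, phi_a, h = NULL) {
  if (is.null(h)) h <- max(1e-5, 1e-3 * phi_a)
  gv <- vapply(c(-2, -1, 0, 1, 2), function(i) gfun(phi_a + i * h),
               numeric(1))
  list(d2 = (-gv[1] + 16 * gv[2] - 30 * gv[3] + 16 * gv[4] - gv[5]) /
         (12 * h^2),
       d3 = (-gv[1] + 2 * gv[2] - 2 * gv[4] + gv[5]) / (-2 * h^3),
       h = h)
}

#' Inverse osmotic susceptibility
#'
#' `chi^-1 = d^2 g / d phi_A^2` at fixed reduced pressure (the packing
#' fraction is re-solved at every composition), along the electroneutral
#' line `phi_C = phi_A`.  Vanishes at the critical point, is positive in
#' the one-phase region and negative inside the spinodal (a warning is
#' attached in that case).
#'
#' @param template A `pel_mixture` supplying the chain lengths (its volume
#'   fractions are ignored).
#' @param phi_a PA volume fraction at which to evaluate.
#' @param lb Reduced Bjerrum length.
#' @param method Electrostatic method (see [total_free_energy()]).
#' @param p_target Fixed reduced pressure `beta P vstar`.
#' @return `chi^-1` (a single number).
#' @export
inverse_susceptibility <- function(template, phi_a, lb,
                                   method = .methods, p_target = 1) {
  method <- match.arg(method)
  gfun <- .g_fp_maker(template$n_a, template$n_c, lb, method, p_target)
  chi <- .g_d23(gfun, phi_a)$d2
  if (is.finite(chi) && chi < 0)
    warning("state is inside the spinodal (chi^-1 < 0)", call. = FALSE)
  chi
}

# minimum of g'' over phi at given lb; list(phi, value)
.chi_min <- function(n_a, n_c, lb, method, p_target,
                     phi_box = c(5e-4, 0.15), tol = 1e-10) {
  gfun <- .g_fp_maker(n_a, n_c, lb, method, p_target)
  op <- stats::optimize(function(p) .g_d23(gfun, p)$d2,
                        interval = phi_box, tol = tol)
  list(phi = op$minimum, value = op$objective)
}

# spinodal compositions (roots of g'' = 0) bracketing phi_hint; NULL if the
# state is single-phase at this lb
.spinodal_pair <- function(n_a, n_c, lb, method, p_target,
                           phi_box = c(5e-4, 0.3), phi_hint = NULL) {
  gfun <- .g_fp_maker(n_a, n_c, lb, method, p_target)
  d2 <- function(p) .g_d23(gfun, p)$d2
  if (is.null(phi_hint)) {
    cm <- .chi_min(n_a, n_c, lb, method, p_target, phi_box)
    if (cm$value >= 0) return(NULL)
    phi_hint <- cm$phi
  } else if (d2(phi_hint) >= 0) {
    cm <- .chi_min(n_a, n_c, lb, method, p_target, phi_box)
    if (cm$value >= 0) return(NULL)
    phi_hint <- cm$phi
  }
  # walk outward until g'' turns positive on each side; the entropic
  # 1/phi divergence guarantees a dilute-side crossing above the smallest
  # composition the derivative stencil can resolve (~3e-5)
  floor_phi <- 3e-5
  lo <- phi_hint
  while (lo / 2 > floor_phi && d2(lo / 2) < 0) lo <- lo / 2
  s1 <- stats::uniroot(d2, c(max(floor_phi, lo / 2), phi_hint),
                       tol = 1e-12)$root
  hi <- phi_hint; step <- 0.5 * phi_hint
  while (hi + step < 0.45 && d2(hi + step) < 0) step <- 2 * step
  s2 <- stats::uniroot(d2, c(phi_hint, min(0.45, hi + step)),
                       tol = 1e-12)$root
  c(s1, s2)
}

# ---- two-phase coexistence ---------------------------------------------------

# coexistence residuals at fixed pressure: equality of the effective polymer
# chemical potential and of the solvent chemical potential between the
# supernatant (a) and coacervate (b) phases
.binodal_residual <- function(phi_pair, n_a, n_c, lb, method, p_target,
                              eta_hint = c(NA, NA)) {
  mu <- lapply(seq_along(phi_pair), function(i) {
    mx <- mixture(n_a, n_c, phi_pair[i])
    e <- solve_eta_at_pressure(mx, lb, method, p_target,
                               eta_init = if (is.finite(eta_hint[i]))
                                 eta_hint[i] else NULL)
    c(chemical_potentials(mx, as.numeric(e), lb, method)[c("mu_eff", "mu_s")],
      eta = as.numeric(e))
  })
  list(r = c(mu[[2]]$mu_eff - mu[[1]]$mu_eff, mu[[2]]$mu_s - mu[[1]]$mu_s),
       eta = c(mu[[1]]$eta, mu[[2]]$eta),
       mu = mu)
}

#' Two-phase coexistence at one coupling strength
#'
#' Solves the complex-coacervation equilibrium between a solvent-rich
#' supernatant phase (a) and a polyelectrolyte-rich coacervate phase (b) at
#' fixed reduced pressure: equal effective polymer chemical potential
#' `mu_A/N_A + mu_C/N_C` and equal solvent chemical potential, with
#' electroneutral composition `phi_C = phi_A` in each phase and each
#' phase's packing fraction re-solved at `p_target`.  A damped Newton
#' iteration runs on the midpoint/half-gap parameterisation; the initial
#' gap is taken from the spinodal pair scaled by the mean-field factor
#' sqrt(3), or from `guess` when supplied.
#'
#' @param template A `pel_mixture` supplying chain lengths.
#' @param lb Reduced Bjerrum length (above the critical coupling for a
#'   two-phase result).
#' @param method Electrostatic method.
#' @param p_target Fixed reduced pressure.
#' @param guess Optional length-2 vector `c(phi_a, phi_b)` of starting
#'   compositions.
#' @param tol Convergence tolerance on the chemical-potential residuals.
#' @return An object of class `pel_binodal_point`: list with `lb`, `phi_a`,
#'   `phi_b`, `eta_a`, `eta_b`, `residual`, `two_phase`, `converged`.
#'   Below the critical coupling `two_phase` is `FALSE` and the
#'   compositions are `NA`.
#' @export
binodal_at_lb <- function(template, lb, method = .methods, p_target = 1,
                          guess = NULL, tol = 1e-9) {
  method <- match.arg(method)
  n_a <- template$n_a; n_c <- template$n_c
  out <- function(phi = c(NA, NA), eta = c(NA, NA), res = NA,
                  two_phase = FALSE, converged = FALSE)
    structure(list(lb = lb, phi_a = phi[1], phi_b = phi[2],
                   eta_a = eta[1], eta_b = eta[2], residual = res,
                   two_phase = two_phase, converged = converged),
              class = "pel_binodal_point")

  sp <- NULL
  if (is.null(guess)) {
    sp <- .spinodal_pair(n_a, n_c, lb, method, p_target)
    if (is.null(sp)) return(out())            # single phase
    mid <- (sp[1] + sp[2]) / 2
    hw <- sqrt(3) * (sp[2] - sp[1]) / 2
    guess <- c(max(mid - hw, sp[1] / 20), min(mid + hw, 0.45))
  }
  solve_from <- function(guess) .binodal_newton(guess, n_a, n_c, lb,
                                                method, p_target, tol)
  sol <- solve_from(guess)
  # a collapsed gap means the iteration slid onto the trivial equal-
  # composition family; retry from a deliberately wide bracket
  collapsed <- function(s) is.null(s) ||
    (s$phi[2] - s$phi[1]) < 1e-5 * s$phi[2]
  if (collapsed(sol)) {
    if (is.null(sp))
      sp <- .spinodal_pair(n_a, n_c, lb, method, p_target)
    if (is.null(sp)) return(out())
    sol <- solve_from(c(sp[1] * 1e-2, min(2.5 * sp[2], 0.45)))
  }
  if (collapsed(sol)) return(out(res = if (is.null(sol)) NA else sol$res))
  out(sol$phi, sol$eta, sol$res, two_phase = TRUE,
      converged = sol$res < tol)
}

# damped Newton on the coexistence conditions in log-composition
# variables (the supernatant composition is exponentially small deep in
# the two-phase region, where mu_eff is linear in log phi)
.binodal_newton <- function(guess, n_a, n_c, lb, method, p_target, tol) {
  w <- log(pmax(guess, 1e-300))
  w_max <- log(0.45)
  clamp <- function(w) {
    w[2] <- min(w[2], w_max)
    w[1] <- min(w[1], w[2] - 1e-8)
    w
  }
  w <- clamp(w)
  eta_hint <- c(NA, NA)
  resid <- function(w, eta_hint)
    .binodal_residual(exp(w), n_a, n_c, lb, method, p_target, eta_hint)
  rs <- tryCatch(resid(w, eta_hint), error = function(e) NULL)
  if (is.null(rs)) return(NULL)
  for (iter in 1:80) {
    eta_hint <- rs$eta
    if (max(abs(rs$r)) < tol) break
    hj <- 1e-6
    jac <- matrix(0, 2, 2)
    for (j in 1:2) {
      wp <- w; wp[j] <- wp[j] - hj   # inward step respects the clamp
      rp <- resid(wp, eta_hint)
      jac[, j] <- (rs$r - rp$r) / hj
    }
    dw <- tryCatch(solve(jac, -rs$r), error = function(e) NULL)
    if (is.null(dw) || !all(is.finite(dw))) return(NULL)
    # cap the log step and damp
    dw <- dw * min(1, 3 / max(abs(dw)))
    lam <- 1
    repeat {
      w_new <- clamp(w + lam * dw)
      rs_new <- tryCatch(resid(w_new, eta_hint), error = function(e) NULL)
      if (!is.null(rs_new) && all(is.finite(rs_new$r)) &&
          (sum(rs_new$r^2) < sum(rs$r^2) || lam < 1 / 128)) break
      lam <- lam / 2
    }
    if (is.null(rs_new) || !all(is.finite(rs_new$r))) return(NULL)
    w <- w_new; rs <- rs_new
  }
  list(phi = exp(w), eta = rs$eta, res = max(abs(rs$r)))
}

#' @export
print.pel_binodal_point <- function(x, ...) {
  if (!x$two_phase) {
    cat(sprintf("single phase at L_B/d = %g\n", x$lb))
  } else {
    cat(sprintf(
      "binodal at L_B/d = %g: phi_a = %.6g (eta %.6g), phi_b = %.6g (eta %.6g), residual %.2e%s\n",
      x$lb, x$phi_a, x$eta_a, x$phi_b, x$eta_b, x$residual,
      if (x$converged) "" else " [NOT CONVERGED]"))
  }
  invisible(x)
}

#' Trace a binodal in the coupling-composition plane
#'
#' Solves [binodal_at_lb()] over a grid of couplings, using each converged
#' solution (gap-rescaled) as the starting guess for the next
#' (continuation).  The grid is processed in decreasing-gap order
#' internally but returned sorted by `lb` ascending.
#'
#' @inheritParams binodal_at_lb
#' @param lb_grid Vector of couplings.
#' @return A data.frame with columns `lb`, `phi_a`, `phi_b`, `eta_a`,
#'   `eta_b`, `residual`, `converged`.
#' @export
trace_binodal <- function(template, lb_grid, method = .methods,
                          p_target = 1, tol = 1e-9) {
  method <- match.arg(method)
  lb_sorted <- sort(lb_grid, decreasing = TRUE)
  rows <- vector("list", length(lb_sorted))
  prev <- NULL
  for (i in seq_along(lb_sorted)) {
    guess <- if (!is.null(prev) && prev$two_phase && prev$converged)
      c(prev$phi_a, prev$phi_b) else NULL
    bp <- binodal_at_lb(template, lb_sorted[i], method, p_target,
                        guess = NULL, tol = tol)
    # spinodal-based initialisation is robust; fall back to continuation
    if (bp$two_phase && !bp$converged && !is.null(guess))
      bp <- binodal_at_lb(template, lb_sorted[i], method, p_target,
                          guess = guess, tol = tol)
    prev <- bp
    rows[[i]] <- data.frame(lb = bp$lb, phi_a = bp$phi_a, phi_b = bp$phi_b,
                            eta_a = bp$eta_a, eta_b = bp$eta_b,
                            residual = bp$residual,
                            converged = isTRUE(bp$converged) & bp$two_phase)
  }
  df <- do.call(rbind, rows)
  df[order(df$lb), , drop = FALSE]
}

# ---- critical point ----------------------------------------------------------

# Polish a critical-point estimate on its defining conditions expressed
# through the effective chemical potential: at the critical point both
# d(mu_eff)/d(phi) and d^2(mu_eff)/d(phi)^2 vanish (they are (1 - 2 phi)
# times the second and third Gibbs-density derivatives there).  mu_eff is a
# single finite difference of the free energy, so its stencil derivatives
# are far less noise-limited than those of g and pin the critical
# coordinates to ~1e-8, which the scaling analyses close to the critical
# point require.
.refine_critical <- function(n_a, n_c, phi, lb, method, p_target) {
  mu_of <- function(p, l) {
    mx <- mixture(n_a, n_c, p)
    e <- solve_eta_at_pressure(mx, l, method, p_target)
    chemical_potentials(mx, as.numeric(e), l, method)$mu_eff
  }
  h <- 3e-4
  mu1 <- function(p, l) {   # Richardson first derivative
    d1 <- (mu_of(p + h, l) - mu_of(p - h, l)) / (2 * h)
    d2 <- (mu_of(p + h / 2, l) - mu_of(p - h / 2, l)) / h
    (4 * d2 - d1) / 3
  }
  mu2 <- function(p, l) {   # five-point second derivative
    v <- vapply(c(-2, -1, 0, 1, 2), function(i) mu_of(p + i * h, l),
                numeric(1))
    (-v[1] + 16 * v[2] - 30 * v[3] + 16 * v[4] - v[5]) / (12 * h^2)
  }
  for (it in 1:3) {
    dp <- 0.3 * phi
    phi_new <- tryCatch(
      stats::uniroot(function(p) mu2(p, lb), c(phi - dp, phi + dp),
                     tol = 1e-11, extendInt = "yes")$root,
      error = function(e) phi)
    dl <- 0.01 * lb
    lb_new <- tryCatch(
      stats::uniroot(function(l) mu1(phi_new, l), c(lb - dl, lb + dl),
                     tol = 1e-11, extendInt = "yes")$root,
      error = function(e) lb)
    moved <- max(abs(phi_new - phi) / phi, abs(lb_new - lb) / lb)
    phi <- phi_new; lb <- lb_new
    if (moved < 1e-9) break
  }
  list(phi = phi, lb = lb)
}

#' Locate the critical point of complex coacervation
#'
#' At fixed reduced pressure the critical (continuous-transition) point is
#' where the second and third composition derivatives of the Gibbs density
#' vanish simultaneously.  Equivalently, the minimum over `phi_A` of
#' `chi^-1(phi_A; lb)` crosses zero as the coupling grows: the outer root
#' `min_phi chi^-1 = 0` is solved in `lb` by bisection, the inner argmin
#' (where `d^3 g / d phi^3 = 0`) by golden-section search.  This
#' formulation avoids root-finding on the noisier third derivative.
#'
#' @inheritParams inverse_susceptibility
#' @param phi_box Composition search interval.
#' @param lb_box Coupling search interval.
#' @return An object of class `pel_critical_point`: list with `phi_cp`,
#'   `lb_cp`, `eta_cp`, `chi_inv` (residual inverse susceptibility at the
#'   solution) and `method`.
#' @export
find_critical_point <- function(template, method = .methods, p_target = 1,
                                phi_box = c(5e-4, 0.15),
                                lb_box = c(0.5, 20)) {
  method <- match.arg(method)
  n_a <- template$n_a; n_c <- template$n_c
  mfun <- function(lb)
    .chi_min(n_a, n_c, lb, method, p_target, phi_box)$value
  # bracket the sign change of the susceptibility minimum
  grid <- exp(seq(log(lb_box[1]), log(lb_box[2]), length.out = 13))
  vals <- vapply(grid, mfun, numeric(1))
  i <- which(vals[-1] * vals[-length(vals)] < 0)
  if (length(i) == 0)
    stop("no critical point in the search box", call. = FALSE)
  i <- i[1]
  lb_cp <- stats::uniroot(mfun, c(grid[i], grid[i + 1]), tol = 1e-7)$root
  cm <- .chi_min(n_a, n_c, lb_cp, method, p_target, phi_box, tol = 1e-10)
  ref <- .refine_critical(n_a, n_c, cm$phi, lb_cp, method, p_target)
  mx <- mixture(n_a, n_c, ref$phi)
  eta_cp <- as.numeric(solve_eta_at_pressure(mx, ref$lb, method, p_target))
  gfun <- .g_fp_maker(n_a, n_c, ref$lb, method, p_target)
  structure(list(phi_cp = ref$phi, lb_cp = ref$lb, eta_cp = eta_cp,
                 chi_inv = .g_d23(gfun, ref$phi)$d2, method = method,
                 p_target = p_target, n_a = n_a, n_c = n_c),
            class = "pel_critical_point")
}

#' @export
print.pel_critical_point <- function(x, ...) {
  cat(sprintf(
    "critical point (%s, N_A = %d, N_C = %d, beta P v* = %g):\n",
    x$method, x$n_a, x$n_c, x$p_target))
  cat(sprintf("  phi_cp = %.6g, L_B/d = %.6g, eta_cp = %.6g\n",
              x$phi_cp, x$lb_cp, x$eta_cp))
  invisible(x)
}
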