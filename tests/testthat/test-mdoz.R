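test_that("MDOZ chain parameters follow their closed forms", {
  st <- reduced_state(mixture(1, 1, 0.25), 0.3, 2)
  pr <- mdoz_params(st)
  expect_equal(c(pr$m, pr$f, pr$h), c(1, 1, 0))

  # asymmetric 50/1 pair: 1/m = (1 + 1/50)/2
  st2 <- reduced_state(mixture(50, 1, 5 / 12), 0.12, 1.5)  # eta_s = 0.02
  pr2 <- mdoz_params(st2)
  expect_equal(pr2$m, 1.96078431372549, tolerance = 1e-12)
  expect_equal(pr2$f, 0.5376488615285356, tolerance = 1e-12)
  expect_equal(pr2$h, -0.2522386363636364, tolerance = 1e-12)
  # omega0 diagnostic ties back to kappa: omega0 (rhoT - rhoS) = sqrt(f) kappa
  expect_equal(pr2$omega0 * (st2$rho_total - st2$rho_s),
               sqrt(pr2$f) * st2$kappa, tolerance = 1e-12)

  # f stays in (2/5, 1] as chains grow
  fs <- vapply(c(1, 2, 5, 20, 200), function(n)
    mdoz_params(reduced_state(mixture(n, n, 0.2), 0.3, 1))$f, numeric(1))
  expect_true(all(fs > 0.4 & fs <= 1))
  expect_true(all(diff(fs) < 0))

  # H = 0 for symmetric chains and in the uncharged limit
  expect_equal(mdoz_params(reduced_state(mixture(8, 8, 0.2), 0.4, 2))$h, 0)
  expect_equal(mdoz_params(reduced_state(mixture(50, 1, 0), 0.4, 2))$h, 0)
})

test_that("D function matches direct arithmetic and the Blum identity at m = 1", {
  expect_identical(big_d(0, 1, 0), 0)
  expect_equal(big_d(4, 1, 0), 20)  # 24 + 48 - 2*27 + 2
  # cross-method value: a_el = -20/(12 pi) = -5/(3 pi)
  expect_equal(-big_d(4, 1, 0) / (12 * pi), -5 / (3 * pi), tolerance = 1e-14)
  expect_error(big_d(-1, 1, 0), "kappa")
  expect_error(big_d(1, 1.5, 0), "f")
})

test_that("monomeric MDOZ energy and free energy obey the shielding identity", {
  # build states on a log grid of kappa via lb (eta - eta_S = 0.3 here)
  for (kap in 10^seq(-2, 1, length.out = 9)) {
    lb <- kap^2 / (24 * 0.3)
    stk <- reduced_state(mixture(1, 1, 0.5, 0), 0.3, lb)
    expect_equal(stk$kappa, kap, tolerance = 1e-12)
    a <- a_el_method2(stk); e <- e_el_method2(stk)
    g <- shielding_gamma(kap)
    expect_lt(abs(a - e - g^3 / (3 * pi)), 1e-13)
  }
  # frozen spot values at kappa = 4
  st4 <- reduced_state(mixture(1, 1, 0.5, 0), 0.3, 16 / (24 * 0.3))
  expect_equal(e_el_method2(st4), -2 / pi, tolerance = 1e-12)
  expect_equal(a_el_method2(st4) - e_el_method2(st4), 1 / (3 * pi),
               tolerance = 1e-12)
})

test_that("MDOZ free energy is Gibbs-Helmholtz consistent with its energy", {
  # beta A(kappa) = (1/4pi) int_0^kappa 8 pi e_el(k')/k' dk' for fixed (f, H)
  for (case in list(c(f = 1, h = 0), c(f = 0.55, h = -0.25),
                    c(f = 0.45, h = 0.6))) {
    kmax <- 3
    integrand <- function(k) {
      sf <- sqrt(case[["f"]])
      rm <- (1 - case[["h"]])^2 + 2 * k / sf
      rp <- (1 + case[["h"]])^2 + 2 * k / sf
      (-2 * k - 2 * sf + sf * sqrt(rp) + sf * sqrt(rm)) / (4 * pi)
    }
    a_int <- stats::integrate(integrand, 0, kmax, rel.tol = 1e-12)$value
    expect_rel_equal(a_int, -big_d(kmax, case[["f"]], case[["h"]]) / (12 * pi),
                     1e-9)
  }
})

test_that("MDOZ pressure equals the density derivative of the free energy", {
  cases <- random_states(8, seed = 11)
  for (i in seq_len(nrow(cases))) {
    mx <- mixture(cases$n_a[i], cases$n_c[i], cases$phi_a[i])
    a <- function(e) a_el_method2(reduced_state(mx, e, cases$lb[i]))
    e0 <- cases$eta[i]
    p_fd <- e0 * fd_deriv(a, e0) - a(e0)
    expect_rel_equal(p_el_method2(reduced_state(mx, e0, cases$lb[i])),
                     p_fd, 1e-6)
  }
})

test_that("MDOZ results are invariant under anion/cation relabelling", {
  # relabelling flips the sign of H and leaves all observables unchanged
  st_ac <- reduced_state(mixture(50, 10, 0.15), 0.35, 5)
  st_ca <- reduced_state(mixture(10, 50, 0.15), 0.35, 5)
  expect_equal(mdoz_params(st_ac)$h, -mdoz_params(st_ca)$h)
  expect_equal(a_el_method2(st_ac), a_el_method2(st_ca), tolerance = 1e-14)
  expect_equal(e_el_method2(st_ac), e_el_method2(st_ca), tolerance = 1e-14)
  expect_equal(p_el_method2(st_ac), p_el_method2(st_ca), tolerance = 1e-14)
})

test_that("connectivity part of the MDOZ free energy vanishes for monomers", {
  st1 <- reduced_state(mixture(1, 1, 0.3), 0.25, 6)
  expect_equal(a_el_pol_method2(st1), 0, tolerance = 1e-15)
  expect_identical(a_el_pol_method2(reduced_state(mixture(50, 10, 0), 0.25, 6)), 0)
  # chain systems: finite and negative over the liquid range
  mx <- mixture(50, 10, 0.2)   # phi_S = 0.6
  apol <- vapply(seq(0.02, 0.5, length.out = 12), function(e)
    a_el_pol_method2(reduced_state(mx, e, 5.516)), numeric(1))
  expect_true(all(is.finite(apol)))
  expect_true(all(apol < 0))
})

test_that("series coefficients reproduce the limiting-law values", {
  co <- series_coeffs(1, 0)
  expect_equal(co$d1, 0)
  expect_equal(co$d2, 0)
  expect_equal(co$d3, -1 / (12 * pi), tolerance = 1e-14)
  expect_equal(co$d4, 1 / (16 * pi), tolerance = 1e-14)
  expect_equal(co$s3, 1 / (24 * pi), tolerance = 1e-14)
  expect_equal(co$s4, -1 / (16 * pi), tolerance = 1e-14)
  # D1 vanishes identically for |H| < 1
  for (h in c(-0.9, -0.3, 0, 0.5, 0.99))
    expect_equal(series_coeffs(0.6, h)$d1, 0)
  expect_error(series_coeffs(0.6, 1), "singular")

  # numerically extracted Taylor coefficients of -D/(12 pi) match the
  # closed forms at a generic (f, H)
  f <- 0.55; h <- -0.35
  co2 <- series_coeffs(f, h)
  k <- 1e-2 * seq(0.2, 1, length.out = 10)
  y <- -big_d(k, f, h) / (12 * pi)
  fit <- stats::lm(y ~ 0 + I(k) + I(k^2) + I(k^3) + I(k^4) + I(k^5))
  cf <- unname(stats::coef(fit))
  expect_equal(cf[1], co2$d1, tolerance = 1e-8)
  expect_equal(cf[2], co2$d2, tolerance = 1e-6)
  expect_rel_equal(cf[3], co2$d3, 1e-4)
  expect_rel_equal(cf[4], co2$d4, 1e-2)
})
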