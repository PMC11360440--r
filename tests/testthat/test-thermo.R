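test_that("total free energy assembles reference plus electrostatics", {
  mx <- mixture(50, 1, 0.05, 0.9)
  # uncharged coupling: all methods coincide with the athermal reference
  for (m in c("method1", "method2", "dh"))
    expect_equal(total_free_energy(mx, 0.3, 0, m),
                 total_free_energy(mx, 0.3, 0, "none"), tolerance = 1e-14)
  # monomeric systems: Method I and Method II totals agree
  mx1 <- mixture(1, 1, 0.2)
  for (e in c(0.05, 0.2, 0.45)) for (lb in c(0.5, 3))
    expect_equal(total_free_energy(mx1, e, lb, "method1"),
                 total_free_energy(mx1, e, lb, "method2"),
                 tolerance = 1e-12)
  expect_error(total_free_energy(mx, 0.3, 1, "bogus"), "arg")
})

test_that("pressure, free energy and chemical potentials are mutually consistent", {
  cases <- random_states(6, seed = 99)
  for (i in seq_len(nrow(cases))) {
    mx <- mixture(cases$n_a[i], cases$n_c[i], cases$phi_a[i])
    e0 <- cases$eta[i]; lb <- cases$lb[i]
    for (m in c("method1", "method2", "dh", "none")) {
      a <- function(e) total_free_energy(mx, e, lb, m)
      p <- total_pressure(mx, e0, lb, m)
      expect_rel_equal(e0 * fd_deriv(a, e0) - a(e0), p, 1e-6)
      # Euler identity g = phi_A mu_eff + phi_S mu_s
      mu <- chemical_potentials(mx, e0, lb, m)
      g <- gibbs_density(mx, e0, lb, m)
      expect_rel_equal(mx$phi_a * mu$mu_eff + mx$phi_s * mu$mu_s, g, 1e-6)
    }
  }
})

test_that("chemical potentials recover the ideal and hard-sphere limits", {
  # dilute monomeric solvent: mu -> ln(eta) + 1
  mx <- mixture(1, 1, 0)
  mu <- chemical_potentials(mx, 1e-5, 0, "none")
  expect_equal(mu$mu_s, log(1e-5) + 1, tolerance = 1e-4)

  # dense uncharged monomers: excess mu matches the quadrature of the
  # compressibility equation of state, mu_ex = a_ex/eta + (Z - 1) with
  # Z - 1 integrated from the pressure (independent route)
  e0 <- 0.35
  mu_ex_pkg <- chemical_potentials(mx, e0, 0, "none")$mu_s - (log(e0) + 1)
  zm1 <- function(e) pressure_hsc(e, 1) / e - 1
  mu_ex_quad <- stats::integrate(function(e) zm1(e) / e, 0, e0,
                                 rel.tol = 1e-10)$value + zm1(e0)
  expect_rel_equal(mu_ex_pkg, mu_ex_quad, 1e-7)

  # the uncharged method also reports per-species potentials
  mx2 <- mixture(8, 2, 0.2)
  mus <- chemical_potentials(mx2, 0.3, 0, "none")
  expect_equal(mus$mu_a + mus$mu_c, mus$mu_eff, tolerance = 1e-9)
})

test_that("packing fraction solves to the target pressure on the stable branch", {
  mx <- mixture(1, 1, 0)
  e <- solve_eta_at_pressure(mx, 0, "none", p_target = 1)
  expect_equal(as.numeric(e), 0.2778800910751648, tolerance = 1e-9)
  expect_lt(abs(attr(e, "residual")), 1e-10)
  expect_gt(attr(e, "dp_deta"), 0)

  # p -> 0 sends eta -> 0
  e_small <- solve_eta_at_pressure(mx, 0, "none", p_target = 1e-6)
  expect_lt(as.numeric(e_small), 1e-5)

  # warm start converges to the same root
  e_warm <- solve_eta_at_pressure(mx, 0, "none", 1, eta_init = 0.25)
  expect_equal(as.numeric(e_warm), as.numeric(e), tolerance = 1e-10)

  # charged chain system below/above criticality still solves at p = 1
  mxc <- mixture(50, 1, 0.01)
  for (m in c("method1", "method2")) {
    ec <- solve_eta_at_pressure(mxc, 5, m, 1)
    expect_lt(abs(attr(ec, "residual")), 1e-10)
    expect_gt(attr(ec, "dp_deta"), 0)
  }
  expect_error(solve_eta_at_pressure(mx, 0, "none", p_target = -1),
               "p_target")
})

test_that("thermo tables carry the full state and round-trip via CSV", {
  mx <- mixture(16, 1, 0.05)
  tab <- thermo_table(mx, eta = c(0.1, 0.2, 0.3), lb = 0.833, "method2")
  expect_equal(nrow(tab), 3)
  expect_true(all(c("eta", "p_vstar", "a_vstar", "mu_s", "mu_a_eff", "g")
                  %in% names(tab)))
  path <- tempfile(fileext = ".csv")
  write_table(tab, path)
  back <- utils::read.csv(path)
  expect_equal(back$p_vstar, tab$p_vstar, tolerance = 1e-11)
  expect_equal(back$g, tab$g, tolerance = 1e-11)
})
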