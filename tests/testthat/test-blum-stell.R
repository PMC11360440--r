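test_that("shielding parameter satisfies its defining quadratic exactly", {
  expect_identical(shielding_gamma(0), 0)
  expect_equal(shielding_gamma(4), 1)   # perfect square
  kgrid <- 10^seq(-6, 2, length.out = 40)
  g <- shielding_gamma(kgrid)
  expect_equal(2 * g * (1 + g), kgrid, tolerance = 1e-14)
  expect_error(shielding_gamma(-0.1), "kappa")
})

# reference state: N_A = 50, N_C = 1, phi = (0.05, 0.05, 0.9), eta = 0.3,
# L_B/d = 4 -> kappa = 1.697056, Gamma = 0.548107
ref_state <- reduced_state(mixture(50, 1, 0.05, 0.9), 0.3, 4)

test_that("Method I free energy reproduces its three closed-form terms", {
  # pure solvent: no charges, no electrostatics
  expect_identical(a_el_method1(reduced_state(mixture(1, 1, 0), 0.3, 4)), 0)

  # term-by-term high-precision arithmetic (frozen)
  expect_equal(a_el_method1(ref_state),
               -0.04248597454844302 + 0.00914794142356171 - 0.03426560142137278,
               tolerance = 1e-12)
  expect_equal(a_el_pol_method1(ref_state), -0.03426560142137278,
               tolerance = 1e-12)

  # monomeric electrolyte: connectivity term vanishes and the unbonded
  # Blum form beta dE + Gamma^3/(3 pi) (in d3-units) remains
  st1 <- reduced_state(mixture(1, 1, 0.25), 0.3, 4)
  g <- shielding_gamma(st1$kappa)
  expect_identical(a_el_pol_method1(st1), 0)
  expect_equal(a_el_method1(st1, units = "d3"),
               -4 * (6 * (st1$eta - st1$eta_s) / pi) * g / (1 + g) +
                 g^3 / (3 * pi),
               tolerance = 1e-12)

  # unit conversion is the exact factor pi/6
  expect_equal(a_el_method1(ref_state), a_el_method1(ref_state, "d3") * pi / 6)
})

test_that("Method I free energy is symmetric under anion/cation relabelling", {
  # swapping chain lengths swaps the species labels; only z^2 enters
  st_ac <- reduced_state(mixture(50, 10, 0.1), 0.25, 3)
  st_ca <- reduced_state(mixture(10, 50, 0.1), 0.25, 3)
  expect_equal(a_el_method1(st_ac), a_el_method1(st_ca), tolerance = 1e-14)
  expect_equal(p_el_method1(st_ac), p_el_method1(st_ca), tolerance = 1e-14)
})

test_that("Method I pressure equals the density derivative of the free energy", {
  cases <- random_states(8, seed = 7)
  for (i in seq_len(nrow(cases))) {
    mx <- mixture(cases$n_a[i], cases$n_c[i], cases$phi_a[i])
    a <- function(e) a_el_method1(reduced_state(mx, e, cases$lb[i]))
    e0 <- cases$eta[i]
    p_fd <- e0 * fd_deriv(a, e0) - a(e0)
    expect_rel_equal(p_el_method1(reduced_state(mx, e0, cases$lb[i])),
                     p_fd, 1e-6)
  }
  # kappa = 0 edge
  expect_identical(p_el_method1(reduced_state(mixture(1, 1, 0), 0.2, 4)), 0)
})
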