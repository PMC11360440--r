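template <- mixture(50, 1, 0.05)

test_that("coexistence at strong coupling satisfies all equilibrium conditions", {
  bp <- binodal_at_lb(template, lb = 4.5, method = "method1", p_target = 1)
  expect_true(bp$two_phase)
  expect_true(bp$converged)
  expect_lt(bp$residual, 1e-9)
  expect_lt(bp$phi_a, bp$phi_b)

  # both phases sit at the target pressure
  for (phi in c(bp$phi_a, bp$phi_b)) {
    mx <- mixture(50, 1, phi)
    e <- solve_eta_at_pressure(mx, 4.5, "method1", 1)
    expect_lt(abs(total_pressure(mx, as.numeric(e), 4.5, "method1") - 1), 1e-10)
  }

  # common-tangent equivalence via an independent finite-difference route:
  # equal slope dg/dphi and equal intercept g - phi dg/dphi across phases
  gfun <- function(phi) {
    mx <- mixture(50, 1, phi)
    e <- as.numeric(solve_eta_at_pressure(mx, 4.5, "method1", 1))
    (total_free_energy(mx, e, 4.5, "method1") + 1) / e
  }
  slope <- vapply(c(bp$phi_a, bp$phi_b), function(p)
    fd_deriv(gfun, p, h = 1e-6), numeric(1))
  icept <- vapply(seq(2), function(i)
    gfun(c(bp$phi_a, bp$phi_b)[i]) - c(bp$phi_a, bp$phi_b)[i] * slope[i],
    numeric(1))
  expect_lt(abs(slope[1] - slope[2]), 1e-5)
  expect_lt(abs(icept[1] - icept[2]), 1e-7)
})

test_that("weak coupling yields a single phase", {
  bp <- binodal_at_lb(template, lb = 2, method = "method1")
  expect_false(bp$two_phase)
  expect_true(is.na(bp$phi_a))
})

test_that("strong segregation drives the supernatant towards pure solvent", {
  b1 <- binodal_at_lb(template, 6, "method1")
  b2 <- binodal_at_lb(template, 12, "method1")
  expect_lt(b2$phi_a, b1$phi_a)
  expect_gt(b2$phi_b, b1$phi_b)
  expect_lt(b2$phi_a, 1e-3)
})

test_that("binodal traces narrow monotonically towards weak coupling", {
  tr <- trace_binodal(template, lb_grid = c(4.5, 5, 6, 8), "method1")
  expect_true(all(tr$converged))
  gap <- tr$phi_b - tr$phi_a
  expect_true(all(diff(gap) > 0))   # sorted by lb ascending
  # CSV round-trip at 12 digits
  path <- tempfile(fileext = ".csv")
  write_table(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back$phi_b, tr$phi_b, tolerance = 1e-11)
})

test_that("susceptibility is positive and entropy-dominated when dilute", {
  # far below the critical coupling the solution is stable everywhere
  for (phi in c(0.005, 0.02, 0.08))
    expect_gt(inverse_susceptibility(template, phi, lb = 1, "method1"), 0)
  # ideal-dilute divergence: chi^-1 ~ 1/phi as phi -> 0 (entropic), so
  # phi * chi^-1 approaches a finite constant from above
  phis <- c(2e-4, 1e-4, 5e-5)
  v <- vapply(phis, function(p)
    p * inverse_susceptibility(template, p, 1, "method1"), numeric(1))
  expect_true(all(v > 0))
  expect_lt(diff(range(v)) / mean(v), 0.25)
})

test_that("no critical point exists for the uncharged athermal solution", {
  expect_error(find_critical_point(template, "none", lb_box = c(0.5, 5)),
               "no critical point")
})
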