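# shared helpers: deterministic random states and finite-difference probes

random_states <- function(n = 12, seed = 421) {
  set.seed(seed)
  data.frame(
    n_a = sample(c(1L, 2L, 8L, 16L, 50L), n, replace = TRUE),
    n_c = sample(c(1L, 2L, 10L), n, replace = TRUE),
    phi_a = runif(n, 0.01, 0.45),
    eta = runif(n, 0.02, 0.55),
    lb = runif(n, 0.1, 8))
}

# central finite-difference derivative of f at x
fd_deriv <- function(f, x, h = 1e-6 * max(abs(x), 1e-2)) {
  (f(x + h) - f(x - h)) / (2 * h)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
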