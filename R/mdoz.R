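#' Chain-length parameters of the multi-density Ornstein-Zernike theory
#'
#' Method II describes the charged chains through three composition-level
#' parameters:
#' \itemize{
#'   \item `m`: the number-average chain length of the charged species.
#'     Electroneutrality makes the bonded-monomer densities of the two
#'     charged species equal, so `1/m = (1/m_plus + 1/m_minus) / 2`.
#'   \item `f`: the coupling factor `2 m^2 / (5 m^2 - 2 m - 1)`, which is 1
#'     for monomers and decreases towards 2/5 for long chains.
#'   \item `h`: the chain-asymmetry parameter
#'     `3 (1 + m)(m_plus - m_minus)(eta - eta_S) /
#'      (2 m (1 - eta) m_minus m_plus)`, zero for symmetric chains or in the
#'     uncharged limit.
#' }
#' `omega0 = sqrt(f * alpha^2 / (rho_T - rho_S))` with `alpha^2 = 4 pi L_B`
#' is reported as a diagnostic only; all public results are parameterised by
#' `(kappa, f, h)`.
#'
#' @param state A `pel_state`.
#' @return A list with `m_minus`, `m_plus`, `m`, `f`, `h`, `omega0`
#'   (`omega0` is `NA` when `eta == eta_S`, where it is undefined).
#' @export
mdoz_params <- function(state) {
  mx <- state$mixture
  m_minus <- mx$n_a
  m_plus <- mx$n_c
  m <- 2 / (1 / m_plus + 1 / m_minus)
  f <- 2 * m^2 / (5 * m^2 - 2 * m - 1)
  d_eta <- state$eta - state$eta_s
  h <- if (d_eta > 0)
    3 * (1 + m) * (m_plus - m_minus) * d_eta /
      (2 * m * (1 - state$eta) * m_minus * m_plus)
  else 0
  if (abs(h) >= 1)
    warning("MDOZ asymmetry parameter |H| >= 1: series coefficients are singular",
            call. = FALSE)
  omega0 <- if (d_eta > 0)
    sqrt(f * 4 * pi * state$lb / (state$rho_total - state$rho_s))
  else NA_real_
  list(m_minus = m_minus, m_plus = m_plus, m = m, f = f, h = h,
       omega0 = omega0)
}

#' The D function of the multi-density Ornstein-Zernike free energy
#'
#' The electrostatic free-energy density of Method II is
#' `beta DeltaA_el d^3 / V = -D(kappa) / (12 pi)` with
#' \deqn{D(\kappa) = 6\sqrt f\,\kappa + 3\kappa^2
#'  - f\big[R_-^{3/2} + R_+^{3/2}\big] + f\big[|1-H|^3 + |1+H|^3\big],
#'  \qquad R_\pm = (1 \pm H)^2 + \frac{2\kappa}{\sqrt f}.}
#' The `sqrt(f)` scaling of the radical argument and of the linear term
#' follows from `omega0 (rho_T - rho_S) = sqrt(f) * kappa`; it is the unique
#' convention that is Gibbs-Helmholtz consistent with [e_el_method2()],
#' reduces at `m = 1` to the monomeric closed form
#' `6 kappa + 3 kappa^2 - 2 (1 + 2 kappa)^{3/2} + 2`, and starts at order
#' `kappa^3` (the Debye-Hueckel limiting law) for every `f`.
#'
#' @param kappa Reduced screening strength (vectorised).
#' @param f Coupling factor in (0, 1].
#' @param h Asymmetry parameter.
#' @return `D(kappa)`.
#' @examples
#' big_d(4, 1, 0)   # 24 + 48 - 2 * 27 + 2 = 20
#' @export
big_d <- function(kappa, f, h) {
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  if (f <= 0 || f > 1) stop("f must be in (0, 1]", call. = FALSE)
  sf <- sqrt(f)
  rm <- (1 - h)^2 + 2 * kappa / sf
  rp <- (1 + h)^2 + 2 * kappa / sf
  6 * sf * kappa + 3 * kappa^2 - f * (rm^1.5 + rp^1.5) +
    f * (abs(1 - h)^3 + abs(1 + h)^3)
}

# dD/dkappa and dD/dH, used by the analytic pressure
.big_d_grad <- function(kappa, f, h) {
  sf <- sqrt(f)
  rm <- (1 - h)^2 + 2 * kappa / sf
  rp <- (1 + h)^2 + 2 * kappa / sf
  list(dk = 6 * sf + 6 * kappa - 3 * sf * (sqrt(rm) + sqrt(rp)),
       dh = 3 * f * ((1 + h) * abs(1 + h) - (1 - h) * abs(1 - h) -
                       (1 + h) * sqrt(rp) + (1 - h) * sqrt(rm)))
}

#' Electrostatic free energy, Method II (MDOZ)
#'
#' `beta DeltaA_el d^3 / V = -D(kappa) / (12 pi)` with `(f, h)` from
#' [mdoz_params()]; see [big_d()].
#'
#' @param state A `pel_state`.
#' @param units `"d3"` (native, default) or `"vstar"` (multiplies by pi/6).
#' @return The electrostatic free-energy density.
#' @export
a_el_method2 <- function(state, units = c("d3", "vstar")) {
  units <- match.arg(units)
  pr <- mdoz_params(state)
  a <- -big_d(state$kappa, pr$f, pr$h) / (12 * pi)
  if (units == "vstar") a * pi / 6 else a
}

#' Electrostatic internal energy, Method II (MDOZ)
#'
#' \deqn{\beta\,\Delta E_{el} d^3/V = \frac{\kappa}{8\pi}\Big(
#'   -2\kappa - 2\sqrt f + \sqrt f\,\sqrt{R_+} + \sqrt f\,\sqrt{R_-}\Big)}
#' with the same radicals as [big_d()].  At `m = 1` this reduces to
#' `kappa/(4 pi) (-kappa - 1 + sqrt(1 + 2 kappa))`, and the difference
#' `a_el - e_el` equals `Gamma^3 / (3 pi)` with Gamma from
#' [shielding_gamma()], the Blum-Stell identity.
#'
#' @inheritParams a_el_method2
#' @return The electrostatic internal-energy density.
#' @export
e_el_method2 <- function(state, units = c("d3", "vstar")) {
  units <- match.arg(units)
  pr <- mdoz_params(state)
  sf <- sqrt(pr$f)
  k <- state$kappa
  rm <- (1 - pr$h)^2 + 2 * k / sf
  rp <- (1 + pr$h)^2 + 2 * k / sf
  e <- k / (8 * pi) * (-2 * k - 2 * sf + sf * sqrt(rp) + sf * sqrt(rm))
  if (units == "vstar") e * pi / 6 else e
}

#' Electrostatic pressure, Method II (MDOZ)
#'
#' The thermodynamic route `eta d(a)/d(eta) - a` at fixed composition,
#' evaluated analytically.  At fixed composition `kappa ~ sqrt(eta)` and the
#' asymmetry parameter obeys `eta dH/d(eta) = H / (1 - eta)`, so
#' \deqn{\beta\,\Delta P_{el} d^3 = -\frac{1}{12\pi}\Big(
#'   \frac{\kappa}{2}\frac{\partial D}{\partial\kappa}
#'   + \frac{H}{1-\eta}\frac{\partial D}{\partial H} - D\Big).}
#'
#' @inheritParams a_el_method2
#' @return `beta * DeltaP_el * d^3` (or v*-units).
#' @export
p_el_method2 <- function(state, units = c("d3", "vstar")) {
  units <- match.arg(units)
  pr <- mdoz_params(state)
  k <- state$kappa
  d <- big_d(k, pr$f, pr$h)
  gr <- .big_d_grad(k, pr$f, pr$h)
  p <- -(gr$dk * k / 2 + gr$dh * pr$h / (1 - state$eta) - d) / (12 * pi)
  if (units == "vstar") p * pi / 6 else p
}

#' Connectivity-only electrostatic free energy, Method II
#'
#' The part of the MDOZ electrostatic free energy due purely to chain
#' connectivity, obtained by subtracting the monomeric (`m = 1`) limit at
#' the same kappa:
#' \deqn{\beta\,\Delta A_{el-pol} d^3/V = -\frac{D(\kappa)}{12\pi}
#'   + \frac{1}{12\pi}\big[6\kappa + 3\kappa^2 - 2(1+2\kappa)^{3/2} + 2\big].}
#' Zero when `m = 1` and at `kappa = 0`.
#'
#' @inheritParams a_el_method2
#' @return The polymeric connectivity part of the MDOZ free energy.
#' @export
a_el_pol_method2 <- function(state, units = c("d3", "vstar")) {
  units <- match.arg(units)
  pr <- mdoz_params(state)
  k <- state$kappa
  a <- (-big_d(k, pr$f, pr$h) +
          (6 * k + 3 * k^2 - 2 * (1 + 2 * k)^1.5 + 2)) / (12 * pi)
  if (units == "vstar") a * pi / 6 else a
}

#' Small-kappa series coefficients of the MDOZ theory
#'
#' Coefficients of `beta DeltaA_el d^3/V = D1 k + D2 k^2 + D3 k^3 + D4 k^4
#' + O(k^5)` and of `beta (DeltaA_el - DeltaE_el) d^3/V = S1 k + S3 k^3 +
#' S4 k^4 + O(k^5)`, in closed form:
#' \deqn{D_1 = \frac{\sqrt f}{4\pi}(-2 + |1-H| + |1+H|),\quad
#'   D_2 = \frac{1}{8\pi}\Big(-2 + \frac{1}{|1-H|} + \frac{1}{|1+H|}\Big),}
#' \deqn{D_3 = -\frac{1}{24\pi\sqrt f}\Big(\frac{1}{|1-H|^3} +
#'   \frac{1}{|1+H|^3}\Big),\quad
#'   D_4 = \frac{1}{32\pi f}\Big(\frac{1}{|1-H|^5} + \frac{1}{|1+H|^5}\Big),}
#' and `S1 = D1/2`, `S3 = -D3/2`, `S4 = -D4`.  For `|H| <= 1` the first
#' coefficient `D1` vanishes identically, and at `f = 1, H = 0` the series
#' reproduces the Debye-Hueckel limiting law through order kappa^4
#' (`D3 = -1/(12 pi)`, `D4 = 1/(16 pi)`).
#'
#' @param f Coupling factor in (0, 1].
#' @param h Asymmetry parameter; `|h| = 1` is a singular input (division by
#'   zero in `D2`..`D4`) and raises an error.
#' @return A list with `d1`, `d2`, `d3`, `d4`, `s1`, `s3`, `s4`.
#' @export
series_coeffs <- function(f, h) {
  if (f <= 0 || f > 1) stop("f must be in (0, 1]", call. = FALSE)
  cm <- abs(1 - h); cp <- abs(1 + h)
  if (cm < 1e-12 || cp < 1e-12)
    stop("singular input: |h| = 1 makes the series coefficients diverge",
         call. = FALSE)
  sf <- sqrt(f)
  d1 <- sf / (4 * pi) * (-2 + cm + cp)
  d2 <- 1 / (8 * pi) * (-2 + 1 / cm + 1 / cp)
  d3 <- -1 / (24 * pi * sf) * (1 / cm^3 + 1 / cp^3)
  d4 <- 1 / (32 * pi * f) * (1 / cm^5 + 1 / cp^5)
  list(d1 = d1, d2 = d2, d3 = d3, d4 = d4,
       s1 = d1 / 2, s3 = -d3 / 2, s4 = -d4)
}

# analytic composition gradients of the MDOZ free energy (d^3-units).
# With S = eta_A + eta_C: kappa^2 = 24 lb S, H = C S / (1 - eta) with a
# composition-independent C, and f, m fixed by the chain lengths, so both
# charged species carry the same gradient.
.a_el2_grad <- function(state) {
  k <- state$kappa
  if (k == 0) return(list(da = 0, dc = 0, ds = 0))
  pr <- mdoz_params(state)
  gr <- .big_d_grad(k, pr$f, pr$h)
  s <- state$eta_a + state$eta_c
  h_over_s <- pr$h / s                     # = C / (1 - eta), finite
  a_s <- -(gr$dk * 12 * state$lb / k + gr$dh * h_over_s) / (12 * pi)
  a_eta <- -(gr$dh * pr$h / (1 - state$eta)) / (12 * pi)
  list(da = a_s + a_eta, dc = a_s + a_eta, ds = a_eta)
}

#' Full Method II result
#'
#' @param state A `pel_state`.
#' @return A list with the MDOZ parameters and `a_el`, `e_el`, `p_el`,
#'   `a_el_pol` (d^3-units) plus the series coefficients.
#' @export
method2_result <- function(state) {
  pr <- mdoz_params(state)
  c(pr,
    list(a_el = a_el_method2(state),
         e_el = e_el_method2(state),
         p_el = p_el_method2(state),
         a_el_pol = a_el_pol_method2(state),
         series = series_coeffs(pr$f, pr$h)))
}
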