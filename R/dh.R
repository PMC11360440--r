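#' Debye-Hueckel limiting-law free energy
#'
#' Classic Debye-Hueckel electrostatic free-energy density for point-like
#' electrolytes,
#' \deqn{\beta\,\Delta A_{el} d^3/V = -\frac{1}{4\pi}\Big[\ln(1+\kappa d)
#'   - \kappa d + \frac{\kappa^2 d^2}{2}\Big]
#'   = -\frac{\kappa^3}{12\pi} + \frac{\kappa^4}{16\pi}
#'     - \frac{\kappa^5}{20\pi} + O(\kappa^6).}
#' Used as the small-kappa reference: the MDOZ monomeric theory shares these
#' series coefficients through order kappa^4 and first differs at kappa^5
#' (-1/(16 pi) instead of -1/(20 pi)).
#'
#' @param kappa Reduced screening strength, >= 0 (vectorised).
#' @return `beta * DeltaA_el * d^3 / V`, <= 0.
#' @export
dh_free_energy <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  -(log1p(kappa) - kappa + kappa^2 / 2) / (4 * pi)
}

#' Debye-Hueckel internal energy
#'
#' \deqn{\beta\,\Delta E_{el} d^3/V = -\frac{\kappa}{8\pi}
#'   \Big(-1 + \kappa + \frac{1}{1+\kappa}\Big)
#'   = -\frac{\kappa^3}{8\pi(1+\kappa)}.}
#'
#' @inheritParams dh_free_energy
#' @return `beta * DeltaE_el * d^3 / V`.
#' @export
dh_energy <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  -kappa^3 / (8 * pi * (1 + kappa))
}

#' Debye-Hueckel free-energy/energy difference
#'
#' The closed form of `a_el - e_el`,
#' \deqn{\frac{\kappa(2+\kappa) - 2(1+\kappa)\ln(1+\kappa)}{8\pi(1+\kappa)}
#'   = \frac{\kappa^3}{24\pi} - \frac{\kappa^4}{16\pi} + O(\kappa^5).}
#'
#' @inheritParams dh_free_energy
#' @return `a_el - e_el` (>= 0).
#' @export
dh_diff <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  (kappa * (2 + kappa) - 2 * (1 + kappa) * log1p(kappa)) /
    (8 * pi * (1 + kappa))
}

#' Debye-Hueckel reference summary
#'
#' @inheritParams dh_free_energy
#' @return A list with `a_el`, `e_el` and `diff = a_el - e_el` (d^3-units).
#' @export
dh_result <- function(kappa) {
  list(a_el = dh_free_energy(kappa), e_el = dh_energy(kappa),
       diff = dh_diff(kappa))
}
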