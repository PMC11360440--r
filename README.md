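# polyeos

Closed-form molecular equations of state for polyelectrolyte solutions,
and the phase behaviour built on them: complex coacervation, critical
points, and critical exponents.

## The problem

Solutions of oppositely charged polymers — polyanions (PA) and polycations
(PC) in a neutral solvent (S) — demix at strong Coulomb coupling into a
polymer-rich *coacervate* and a solvent-rich *supernatant*.  Describing
that equilibrium quantitatively needs a free energy that keeps both chain
connectivity and excluded volume, the two ingredients that simple
Voorn–Overbeek-type theories drop.  `polyeos` implements two analytical
integral-equation free energies for the restricted primitive model of
fully charged chains (equal sphere diameters `d`, charges ±1 per monomer,
uniform dielectric background), for users studying coacervation
thermodynamics, salt-free polyelectrolyte equations of state, or critical
behaviour of charged-chain models.

With packing fraction η, reduced Bjerrum length `l_b = L_B/d` (the inverse
temperature: `L_B = e²/ε kT`) and screening strength
`κ²d² = 24 l_b (η − η_S)`, the total free energy is
`A = A_id + A_ex + ΔA_el` where

* `A_ex` is the Baxter–Chiew hard-sphere-chain excess (Percus–Yevick
  adhesive spheres + covalent-bond constraint), with pressure
  `βP_HSC v* = (η+η²+η³)/(1−η)³ − (1−1/N)(η+η²/2)/(1−η)²`;
* **Method I (Blum–Stell)**: MSA electrostatics through the shielding
  parameter Γ (`2Γd(1+Γd) = κd`) plus a cavity-function connectivity term
  for charged chains;
* **Method II (MDOZ)**: Wertheim multi-density Ornstein–Zernike closed
  forms, `βΔA_el d³/V = −D(κ)/12π` with
  `D(κ) = 6√f κ + 3κ² − f[R₋^{3/2} + R₊^{3/2}] + f[|1−H|³ + |1+H|³]`,
  `R± = (1±H)² + 2κ/√f`, where `f` and `H` are chain-length and asymmetry
  parameters;
* the classic Debye–Hückel limiting law is included as a baseline.

On top of the free energies the package provides analytic pressures and
chemical potentials, fixed-pressure density solving, two-phase coexistence
(`binodal_at_lb()`, `trace_binodal()`), critical-point location
(`find_critical_point()`), and critical-exponent extraction by log–log
regression (`critical_exponents()`).  See the vignette
(`vignettes/polyelectrolyte-eos.Rmd`) for the model, conventions and
numerics.

## A worked example

```r
library(polyeos)

# a solution of 50-mer polyanions with monomeric counterions in solvent
mx <- mixture(n_a = 50, n_c = 1, phi_a = 0.02)

# density at fixed reduced pressure, Blum-Stell electrostatics
eta <- solve_eta_at_pressure(mx, lb = 4, method = "method1", p_target = 1)
round(as.numeric(eta), 6)
#> [1] 0.279831

# two-phase coexistence at stronger coupling
binodal_at_lb(mixture(50, 1, 0.05), lb = 4.5, method = "method1")
#> binodal at L_B/d = 4.5: phi_a = 0.000825411 (eta 0.27795),
#>   phi_b = 0.0932241 (eta 0.287665), residual 2.14e-10

# the critical point of the same system
find_critical_point(mixture(50, 1, 0.05), method = "method1")
#> critical point (method1, N_A = 50, N_C = 1, beta P v* = 1):
#>   phi_cp = 0.0162512, L_B/d = 4.01574, eta_cp = 0.279456
```

The supernatant (`phi_a`) and coacervate (`phi_b`) compositions satisfy
equal effective polymer and solvent chemical potentials at the common
reduced pressure `βPv* = 1`; the critical point is where the coexistence
gap closes (second and third composition derivatives of the Gibbs density
vanish).

A JSON-configured command-line driver is included:

```sh
Rscript inst/cli/polyel-eos.R critical --config config.json --out results/
```

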