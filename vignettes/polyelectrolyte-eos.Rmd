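---
title: "Equations of state for polyelectrolyte solutions: models, numerics and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equations of state for polyelectrolyte solutions: models, numerics and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyeos)
```

## The physical model

`polyeos` describes a solution of fully charged polyanions (PA, chains of
$N_A$ spheres each carrying charge $-1$), polycations (PC, $N_C$ spheres of
charge $+1$) and a neutral monomeric solvent S, in the *restricted primitive
model*: every sphere has the same diameter $d$, the solvent background is a
uniform dielectric of constant $\varepsilon$, and the interactions are hard
cores plus Coulomb forces (plus the short-ranged adhesive contact that
generates permanent chain bonds).  Such mixtures demix at strong Coulomb
coupling into a polymer-rich *coacervate* and a solvent-rich *supernatant* —
complex coacervation — and the package's purpose is to compute that
thermodynamics from closed-form free energies.

Everything is dimensionless.  With $d = 1$:

* $\eta$ — total packing fraction; $\eta_k = \phi_k \eta$ with volume
  fractions $\phi_k$.  Electroneutrality of fully charged chains forces
  $\phi_C = \phi_A$, so a composition is a single number $\phi_A$.
* $l_b = L_B/d$ — reduced Bjerrum length, $L_B = e^2/\varepsilon k_B T$.
  Since $T \propto 1/L_B$ at fixed $\varepsilon$, $l_b$ is the inverse
  temperature of the model.  A dielectric constant never enters separately.
* $\kappa d$ — Debye screening strength,
  $\kappa^2 d^2 = 24\, l_b\, (\eta - \eta_S)$.
* Densities per volume are reported in $v^*$-units ($v^* = \pi d^3/6$, the
  sphere volume) and $d^3$-units, interconvertible by the exact factor
  $\pi/6$.  Both conventions appear in the literature, so every
  electrostatic function takes a `units` argument.

The Helmholtz free-energy density is assembled as
$A = A_{id} + A_{ex} + \Delta A_{el}$ and the pressure as
$P = P_{HSC} + \Delta P_{el}$.

### The hard-sphere-chain reference

The athermal reference is the Baxter adhesive-sphere solution in the
Percus–Yevick closure with Chiew's connectivity constraint, which gives the
compact pressure

$$\beta P_{HSC} v^* = \frac{\eta + \eta^2 + \eta^3}{(1-\eta)^3}
 - \Big(1 - \frac1N\Big) \frac{\eta + \eta^2/2}{(1-\eta)^2},$$

with $N$ the number-average chain length
$1/N = \phi_A/N_A + \phi_C/N_C + \phi_S$, and by density integration the
excess free energy implemented in `helmholtz_ex_hsc()`.  Ternary contact
probability (relevant only for gelation) is neglected.  The ideal part is
$\sum_j (\eta_j/N_j)\ln(\eta_j/N_j)$ with the species molecular constants
set to 1 — they shift each chemical potential by a composition-independent
constant that cancels identically in two-phase equality and in every
composition derivative used here, and $x\ln x$ is continued by 0 at $x=0$.

### Method I: Blum–Stell

The first electrostatic treatment solves charged hard spheres in the mean
spherical approximation (MSA).  Everything is controlled by the shielding
parameter $\Gamma d$, the positive root of
$2\Gamma d\,(1+\Gamma d) = \kappa d$ (`shielding_gamma()`; the closed
quadratic is used instead of the equivalent nested radical).  Chain
connectivity of charged spheres is added through the cavity-function route:
along a fully charged chain each adjacent pair contributes its contact
cavity-function increment, giving

$$\frac{\beta \Delta A_{el} v^*}{V} =
 -l_b \sum_k \eta_k z_k^2 \frac{\Gamma d}{1+\Gamma d}
 + \frac{(\Gamma d)^3}{18}
 - l_b \sum_k \frac{\eta_k}{N_k}(N_k - 1)
   \Big(1 - \frac{1}{(1+\Gamma d)^2}\Big).$$

The pressure is taken by the thermodynamic route
$\beta P = \eta\, \partial a/\partial\eta - a$ at fixed composition, which
evaluates in closed form (the unbonded part collapses exactly to
$-(\Gamma d)^3/18$); the chain rule uses
$\partial(\Gamma d)/\partial\eta = \kappa d / (4\eta\,(1+2\kappa d)^{1/2})$
from $\kappa \propto \sqrt\eta$.

### Method II: multi-density Ornstein–Zernike (MDOZ)

The second treatment solves charged spheres carrying two adhesive bonding
sites in Wertheim's multi-density Ornstein–Zernike formalism with a
PY/MSA-like closure.  After the hierarchy is closed, only three
composition-level parameters survive (`mdoz_params()`):

* $m$ — number-average charged chain length,
  $1/m = \tfrac12(1/N_A + 1/N_C)$ (the bonded-site densities of the two
  charged species are equal by electroneutrality);
* $f = 2m^2/(5m^2 - 2m - 1) \in (2/5, 1]$ — the coupling factor;
* $H = 3(1+m)(N_C-N_A)(\eta-\eta_S) / (2m(1-\eta) N_A N_C)$ — a chain
  asymmetry parameter, zero for $N_A = N_C$ and odd under relabelling
  (observables depend on $|1 \pm H|$ only).

The free energy is $\beta\Delta A_{el} d^3/V = -D(\kappa)/12\pi$ with

$$D(\kappa) = 6\sqrt f\,\kappa + 3\kappa^2
 - f\big[R_-^{3/2} + R_+^{3/2}\big] + f\big[|1-H|^3 + |1+H|^3\big],
 \qquad R_\pm = (1\pm H)^2 + \frac{2\kappa}{\sqrt f},$$

and the internal energy is
$\beta\Delta E_{el} d^3/V = (\kappa/8\pi)\,(-2\kappa - 2\sqrt f +
\sqrt f \sqrt{R_+} + \sqrt f \sqrt{R_-})$.

A word on the $\sqrt f$ scaling, because it is the one place where the
source displays are typographically ambiguous about $f$-powers inside and
in front of the radicals.  The combination that actually enters the
derivation is $\omega_0(\rho_T-\rho_S)$, and from
$\omega_0^2 = f\alpha^2/(\rho_T-\rho_S)$ with
$\kappa^2 = \alpha^2(\rho_T-\rho_S)$ one has
$\omega_0(\rho_T-\rho_S) = \sqrt f\,\kappa$ identically.  The forms above
are the unique ones that simultaneously (i) reduce at $m = 1$ to the
monomeric closed forms, (ii) satisfy the Gibbs–Helmholtz relation
$\beta\Delta A = \int \Delta E\, \mathrm d\beta$ exactly (asserted
numerically in the test suite by quadrature), (iii) start at order
$\kappa^3$ — the Debye–Hückel limiting law — for *every* $f$, and (iv)
reproduce the known small-$\kappa$ series coefficients.  Any $f$- or
$f^2$-variant fails at least one of these checks (and shifts the predicted
critical point far from the reference values that the acceptance analysis
reproduces).

`series_coeffs()` returns the closed-form series coefficients
$D_1 \ldots D_4$, $S_1, S_3, S_4$; for $|H| \le 1$, $D_1 = 0$ identically
and at $m = 1$ the series matches Debye–Hückel theory through order
$\kappa^4$ ($-1/12\pi$, $+1/16\pi$), first deviating at $\kappa^5$
($-1/16\pi$ versus $-1/20\pi$).  For $N_A = N_C = 1$ the whole Method II
free energy coincides with Method I through the identity
$a_{el} - e_{el} = \Gamma^3/3\pi$; the test suite holds this to machine
precision across a state grid.  The two methods differ only in their
charged-*chain* connectivity contribution (`a_el_pol_method1()`,
`a_el_pol_method2()`), the MDOZ correction being the smaller in magnitude
— which is why Method II needs a noticeably larger coupling to demix even
though both predict nearly the same critical composition.

The Debye–Hückel limiting law itself (`dh_free_energy()`) is included as a
third, baseline "method" for comparisons.

## Thermodynamics, coexistence, criticality

Chemical potentials $\mu_k/(N_k k_B T) = \partial(\beta A v^*/V)/
\partial\eta_k$ are evaluated **analytically**: the ideal part exactly, the
chain-excess part from its linear-in-$Q$ structure
($a_{ex} = F_1(\eta) - (\eta - Q)F_2(\eta)$, $Q = \sum\eta_j/N_j$), and
the electrostatic parts through their closed-form gradients in the charged
density $S = \eta_A + \eta_C$.  Analytic derivatives matter here: deep in
the two-phase region the supernatant charged density falls below
$10^{-10}$, where any finite-difference step either leaves the physical
domain or is destroyed by cancellation.  Finite differences are retained
throughout the test suite as the independent oracle (pressure–free-energy
consistency and the Euler identity
$g = \phi_A\,\mu_{A,eff}/N_A + \phi_S\,\mu_S$ are checked to $10^{-6}$ on
a randomized state grid).

Since the electrostatic closed forms are derived under electroneutrality,
the physically meaningful composition derivatives are the electroneutral
ones; every equilibrium condition uses only
$\mu_{A,eff}/N_A = \mu_A/N_A + \mu_C/N_C$ and $\mu_S$.

Working at fixed reduced pressure (all reference phase behaviour is at
$\beta P v^* = 1$) requires inverting $P(\eta)$: `solve_eta_at_pressure()`
brackets all roots on $\eta \in (0, 0.74]$ (capped near random close
packing, the physical validity limit of the reference EOS), polishes them
to residuals $\sim 10^{-13}$, discards mechanically unstable roots
($\partial P/\partial\eta \le 0$, which occur on sub-critical isotherms),
and among multiple stable roots returns the one of lowest Gibbs density
$g = (a + \beta P v^*)/\eta$ — the equilibrium branch.  Which root to take
inside a loop is not specified by the theory itself; minimum-$g$ is this
package's rule.

**Coexistence** (`binodal_at_lb()`) solves
$\mu_{A,eff}^a = \mu_{A,eff}^b$, $\mu_S^a = \mu_S^b$ with each phase's
$\eta$ re-solved at the target pressure.  The Newton iteration runs in
log-composition variables — the supernatant composition is exponentially
small at strong coupling and $\mu_{A,eff}$ is linear in $\ln\phi$ there,
so the log parameterisation stays well-conditioned from slightly
super-critical couplings down to $\phi_a \sim 10^{-10}$.  Initial guesses
come from the spinodal pair (roots of $\partial^2 g/\partial\phi_A^2 = 0$)
expanded by the mean-field binodal/spinodal width ratio $\sqrt 3$; a
collapse onto the trivial equal-composition family is detected and retried
from a deliberately wide bracket.  Converged points satisfy the
chemical-potential equalities to $10^{-9}$ and both phases sit at the
target pressure to $10^{-10}$.

**The critical point** (`find_critical_point()`) is where
$\partial^2 g/\partial\phi_A^2 = \partial^3 g/\partial\phi_A^3 = 0$ at
fixed pressure.  Rather than root-finding on the noisier third derivative,
the implementation tracks $\min_\phi \chi^{-1}(\phi; l_b)$ — the minimum
over composition of the inverse susceptibility
$\chi^{-1} = \partial^2 g/\partial\phi_A^2$ — and bisects its sign change
in $l_b$; the inner argmin is exactly the vanishing-third-derivative
locus.  $g$-derivatives use five-point central stencils with step
$h = \max(10^{-5}, 10^{-3}\phi_A)$, with the inner $\eta$-solve converged
to machine precision so that stencil noise stays near $10^{-6}$ in
$\chi^{-1}$.  The estimate is then polished on the equivalent conditions
$\partial\mu_{A,eff}/\partial\phi_A = \partial^2\mu_{A,eff}/\partial\phi_A^2 = 0$
— single-difference quantities with far lower noise — pinning the critical
coordinates to about $10^{-8}$.  That precision is not cosmetic: the
scaling analyses below probe reduced temperatures down to $10^{-4}$ and
would inherit any critical-point bias.

**Critical exponents** (`critical_exponents()`).  The reduced temperature
is $t = l_{b,cp}/l_b - 1$ (recall $T \propto 1/l_b$).  Defaults, each a
20-point log-spaced grid:

* $\beta$: slope of $\ln|\phi_b - \phi_a|$ vs $\ln|t|$ on the two-phase
  side, $|t| \in [10^{-4}, 10^{-2}]$, binodals by continuation with
  $\sqrt{|t|}$-scaled guesses;
* $\gamma$: slope of $\ln\chi^{-1}$ vs $\ln t$ at $\phi_A = \phi_{cp}$ on
  the one-phase side, same window (the path along the critical
  composition is the standard critical-isochore analogue; the theory
  leaves it open);
* $\delta$: slope of $\ln\Delta\mu_{A,eff}$ vs $\ln(\phi_A - \phi_{cp})$
  on the $t = 0$ isotherm, $\phi_A - \phi_{cp} \in [10^{-4}, 10^{-3}]$.

The $\delta$ window deserves its own note.  The local log-slope of
$\Delta\mu_{A,eff}$ is $3 - O(\phi_A - \phi_{cp})$: about $2.99$ at
displacement $10^{-4}$, $2.93$ at $10^{-3}$, $2.80$ at $3\times10^{-3}$,
and it keeps falling as corrections to scaling grow.  A wide window such
as $[10^{-3}, 3\times10^{-2}]$ therefore *underestimates* $\delta$ by
$0.3$–$0.4$ and sits outside the asymptotic regime entirely; the default
decade $[10^{-4}, 10^{-3}]$ is the widest one that is both asymptotic and
above the numerical noise floor (near $5\times10^{-5}$, set by the
machine-precision $\eta$-solves inside $\mu$).  The $\beta$ and $\gamma$
windows are far less sensitive: their local slopes vary by under $0.01$
per decade.  All three fits report $R^2$ and their window so that this
sensitivity stays visible, and `fit_beta()`/`fit_gamma()`/`fit_delta()`
accept any window on a user-supplied trace.

## A small worked example

Monomeric electrolytes make the two methods coincide:

```{r}
st <- reduced_state(mixture(n_a = 1, n_c = 1, phi_a = 0.25), eta = 0.3, lb = 2)
c(method1 = a_el_method1(st),
  method2 = a_el_method2(st, units = "vstar"))
```

A chain system at the conditions used throughout the package's reference
analyses ($N_A = 50$, $N_C = 1$, $\beta P v^* = 1$):

```{r}
mx <- mixture(n_a = 50, n_c = 1, phi_a = 0.02)
eta <- solve_eta_at_pressure(mx, lb = 4, method = "method1", p_target = 1)
c(eta = as.numeric(eta),
  g = gibbs_density(mx, as.numeric(eta), 4, "method1"))
```

The expensive drivers (`find_critical_point()`, `critical_exponents()`)
are exercised in `tests/testthat/test-acceptance.R` and in
`scripts/acceptance.R`, which reproduce the critical points of both
methods and the mean-field exponents; they are not run while building this
document.

## What the validation fixtures do and do not show

`limit_suite()` and `fixture_grid()` verify *structural* identities on a
deterministic grid: monomeric method equivalence at machine precision, the
Gibbs–Helmholtz and $\Gamma^3/3\pi$ identities, Debye–Hückel series
agreement through $\kappa^4$ and the required disagreement at $\kappa^5$,
thermodynamic consistency and the Euler identity for all methods.
`figure_fixtures()` regenerates the package's reference curves: the
connectivity free-energy comparison ($N_A=50$, $N_C=10$, $\phi_S=0.6$,
$l_b = 5.516$), the salt-free pressure isochore ($N_A=16$, $N_C=1$,
$l_b = 0.833$; the salt-free limit is realised as $\phi_S = 10^{-10}$ to
avoid an empty component in the composition bookkeeping), and the
fixed-pressure binodals of both methods.

These checks validate the implementation against its own mathematical
structure and against published reference coordinates — not against
nature.  The model ignores solvent structure, dielectric inhomogeneity,
counterion condensation beyond the linear screening built into MSA,
charge-sequence effects (chains are uniformly, fully charged), added salt
as a fourth species, and all nanoscale (microphase) organisation;
correlation functions and structure factors are outside the package's
scope.  Mean-field critical exponents are a *property of these closed
forms*, not a prediction about real coacervates, whose asymptotic
criticality is Ising-like.

## Numerical choices, in one place

* Problem sizes: reference analyses use the $N_A=50/N_C=1$ system; a
  critical-point search costs a few seconds and the full three-exponent
  analysis runs from a warm critical point in a few more.
* $\eta$-solves: bracket scan of 160 points, `uniroot` at tolerance
  $10^{-14}$, Newton polish; warm starts thread through all stencils and
  traces.
* Degenerate inputs: $\kappa = 0$ (uncharged or pure solvent) returns
  exact zeros everywhere; absent species give $\mu = -\infty$; $|H| = 1$
  is a singular input for the series coefficients and raises an error,
  while $|H| \ge 1$ states (reachable only at extreme density/asymmetry)
  carry a diagnostic warning.
* Binodal convergence tolerance $10^{-9}$ on both chemical-potential
  residuals; traces continue from the previous solution.
* All tabular output is written at 12 significant digits with LF line
  endings; identical configurations give byte-identical files.
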