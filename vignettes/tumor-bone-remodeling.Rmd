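---
title: "Modeling tumor-coupled bone remodeling with osteodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor-coupled bone remodeling with osteodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteodyn)
```

## The model

A basic multicellular unit (BMU) — the transient team of osteoclasts
and osteoblasts that executes one remodeling cycle at a bone site — is
described by the power-law system

$$
\frac{dx_1}{dt} = \alpha_1 x_1^{g_{11}} x_2^{g_{21}} - \beta_1 x_1,
\qquad
\frac{dx_2}{dt} = \alpha_2 x_1^{g_{12}} x_2^{g_{22}} - \beta_2 x_2 ,
$$

where $x_1$ is the osteoclast and $x_2$ the osteoblast count, the
$\alpha_i$ (day$^{-1}$, cell scale) are production and the $\beta_i$
(day$^{-1}$) removal rates, and the dimensionless exponents $g_{ij}$
summarize the net autocrine ($g_{ii}$) and paracrine ($g_{ij}$)
signaling between the two populations. Bone mass $z$ (percent of its
initial value) responds only to cells in excess of the nontrivial
steady state $\bar{x}_i$:

$$
\frac{dz}{dt} = -k_1 y_1 + k_2 y_2,
\qquad y_i = \max(x_i - \bar{x}_i,\, 0),
$$

with resorption and formation activities $k_1, k_2$ in percent per cell
per day. A tumor enters as a normalized burden $D \in [0, 1)$ (cell
count over carrying limit) following Gompertz growth
$dD/dt = \mu D \log_{10}(\sigma / D)$, which rises monotonically from
any $D_0 \in (0, \sigma)$ to the asymptote $\sigma < 1$.

Three couplings are implemented:

* **model 1** — each rate constant is replaced by itself, by
  $\gamma_i (1 - D)$, or by $\gamma_i / (1 - D)$, in nine fixed
  scenarios (`scenario_forms()`); scenario 0 is the uncoupled system.
* **model 2** — the production terms gain factors $D^{g_{31}}$ and
  $D^{g_{32}}$ (a tumor "paracrine" action on each lineage).
* **model 3** — the exponents themselves drift with the relative
  burden: $g_{11}(1 + r_{11} D/\sigma)$, $g_{21}(1 + r_{21} D/\sigma)$,
  $g_{12}/(1 + r_{12} D/\sigma)$, $g_{22} - r_{22} D/\sigma$.

All three share one algebraic skeleton, which the implementation
exploits: at any burden $D$ the cell equations have coefficients
$(A_i(D), B_i(D))$ and exponents $(G_{ij}(D))$, and one internal
evaluation of these (plus their $D$-derivatives) feeds the right-hand
sides, the closed-form steady states, and the analytic Jacobian alike.
This removes any possibility of the three disagreeing by transcription.

## Parameters

The canonical physiological set (`default_params()`) is
$\alpha = (3, 4)$, $\beta = (0.2, 0.02)$,
$g = (g_{11}, g_{21}, g_{12}, g_{22}) = (1.1, -0.5, 1, 0)$,
$k = (0.093, 0.0008)$, $\mu = 0.005$/day. Its coupling determinant
$\gamma = g_{12} g_{21} - (1 - g_{11})(1 - g_{22}) = -0.4$ is safely
away from the degenerate $\gamma = 0$ at which no nontrivial fixed
point exists. The tumor asymptote $\sigma$ is deliberately a run-level
setting, not part of the default bundle: the analyses this package
supports sweep $\sigma \in \{0.05, 0.10, 0.20, 0.40, 0.80, 0.99\}$.

The initial burden $D_0$ is genuinely unconstrained by the biology
beyond $0 < D_0 \le \sigma$; `tumor_params()` defaults to
$D_0 = 0.005\,\sigma$, a small seed two decades below the asymptote, so
that the tumor transient (time constant $\ln 10 / \mu \approx 460$
days) is fully visible in a run. Results that depend on $D_0$ only
through the transient are insensitive to this choice; it is exposed as
an argument.

## Steady states and a closed-form subtlety

For the base model,

$$
\bar{x}_1 = \left(\tfrac{\beta_1}{\alpha_1}\right)^{(1-g_{22})/\gamma}
            \left(\tfrac{\beta_2}{\alpha_2}\right)^{g_{21}/\gamma},
\qquad
\bar{x}_2 = \left(\tfrac{\beta_1}{\alpha_1}\right)^{g_{12}/\gamma}
            \left(\tfrac{\beta_2}{\alpha_2}\right)^{(1-g_{11})/\gamma},
$$

evaluated as $\exp(e \log r)$ on strictly positive ratios (negative
bases are a validation error, never silently complex). Model-1 steady
states reuse this form with the scenario-modulated ratios at
$D = \sigma$ — the single scenario table is the only encoding of the
nine modulation rows, and the $(1-\sigma)$-power factors quoted per
scenario in the literature fall out identically (they are verified
against the table in the test suite). Scenarios where the same
$(1 - D)$ factor hits $\alpha_i$ and $\beta_i$ cancel entirely, which
is why scenarios 1 and 2 keep the tumor-free fixed point. Model-3
steady states are again the same form with the effective exponents at
$D = \sigma$ and determinant
$\Lambda = \frac{g_{12}}{1+r_{12}} g_{21}(1+r_{21}) -
(1 - g_{11}(1+r_{11}))(1 - g_{22} + r_{22})$.

Model 2 needs care. The closed form in which its steady states are
conventionally quoted multiplies the base fixed point by
$\sigma^{(g_{31} - g_{31} g_{22} - g_{21} g_{32})/\gamma}$ (osteoclasts)
and $\sigma^{(g_{32} g_{11} - g_{31} g_{12} - g_{32})/\gamma}$
(osteoblasts). Solving the model-2 equations directly, however, gives
the osteoclast exponent $(g_{31} g_{22} - g_{31} - g_{21} g_{32})/\gamma$
— the $g_{31}$ terms carry the opposite sign (the osteoblast exponent
is correct). With the physiological set, $g_{31} = -0.1$,
$g_{32} = 0$, $\sigma = 0.05$, the conventional form gives
$(0.5479, 490.04)$ while the actual fixed point of the ODE is
$(2.4502, 490.04)$; the former leaves a 14% relative residual in the
osteoclast equation. `model2_steady_state()` therefore returns the
conventional form by default — it is the reference point on which the
quoted worked examples and stability regions for this variant are built
— and the algebraic fixed point under `consistent = TRUE`. The
fixed-point-residual and root-finding cross-checks in the test suite
certify the consistent form; the simulator also anchors its bone-mass
rule to the consistent fixed point for this variant, because that is
the attractor the trajectory actually approaches.

## Stability analysis

The tumor equation depends on $D$ alone, so the system Jacobian at
$(\bar{x}_1, \bar{x}_2, \sigma)$ is block triangular with third row
$(0, 0, -\mu/\ln 10)$: the base-10 logarithm in the Gompertz law is
what makes $J_{33} = -\mu/\ln 10$ rather than $-\mu$, and this value is
an exact eigenvalue of every variant's Jacobian. The remaining pair are
the eigenvalues of the $2 \times 2$ cell block. Entries are derived
analytically from the implemented right-hand sides — coefficient
$D$-derivatives for models 1 and 2, exponent $D$-derivatives (with
$\ln \bar{x}_i$ factors) for model 3 — and validated against central
finite differences on randomized parameter sets, rather than
transcribed from quoted formulas, some of which contain evident copy
errors.

Stability is decided two independent ways, and the test suite holds
them to agreement: the Routh–Hurwitz conditions
$a_1 > 0,\ a_3 > 0,\ a_1 a_2 - a_3 > 0$ on the characteristic
polynomial computed from the matrix
($a_1 = -\mathrm{tr}\,J$, $a_2$ = sum of principal minors,
$a_3 = -\det J$), and direct eigenvalue decomposition. The taxonomy
follows the regimes the models exhibit: `center_like` (a rounding-level
real part with a nonzero imaginary pair — the physiological limit
cycle; the cell block of the base model has exactly zero trace, so this
class is structurally exact but floating-point fuzzy), `stable_spiral`
(damped oscillation), `stable_node`, `unstable`. The zero tolerance is
$10^{-9} \max(1, \lVert J \rVert_\infty)$ for single-point reports and
a coarser $10^{-6}$ for region scans; boundary ties resolve to the
marginal class, never silently to "stable". With the physiological
parameters this reproduces the qualitative pattern of the nine model-1
scenarios: 2, 3 and 6 attracting (damped oscillations) at moderate
$\sigma$, 1, 4 and 8 repelling at every $\sigma$, 0, 5 and 7 on
centers. Because the cell-block eigenvalues of model 1 depend on the
modulated $\beta_i$ only (the $\alpha_i$ cancel at the fixed point),
scenarios that touch only production rates (5, 7) cannot change
stability class in this linearization, whatever $\sigma$.

## Time integration and diagnostics

`simulate_remodeling()` integrates $(x_1, x_2, D, z)$ with `lsoda`
(deSolve), relative tolerance $10^{-8}$, on an output grid of 1 day.
Default runs span 1000–6000 days: one remodeling cycle of the
physiological limit cycle is $\approx 273$ days, and damped scenarios
converge only as fast as the tumor transient (460-day time constant)
lets the moving quasi-steady state settle, so runs meant to reach the
fixed point use $t_{end} \ge 6000$ days. The default initial state is
the tumor-free fixed point perturbed by +10 osteoclasts.

Fractional powers make the positive orthant a hard domain boundary. The
solver never clamps: if an output point leaves the orthant the run is
retried once with 100-fold tighter tolerances and otherwise aborted
with the partial trajectory attached to the condition. (Analytically,
trajectories cannot reach zero in finite time — removal is at most
exponential — so only numerical undershoot is at stake.)

`diagnose_trajectory()` replaces eyeballing with fixed rules, applied
in order: converged (last 10% of samples within 1% of the reference
steady state), sustained oscillation (at least five osteoclast peaks,
last five peak amplitudes within 2%; peaks located by discrete sign
changes with quadratic refinement — adequate for these smooth
oscillations and dependency-free), divergent (a cell count exceeds 100
times its initial value), collapsed (both counts below $10^{-3}$ of the
steady state), otherwise undetermined with diagnostics. On the
physiological set these verdicts match the eigenvalue classes across
the scenario/$\sigma$ sweep. For scenario 2 — whose fixed point is
$\sigma$-independent — the accompanying bone-mass trace at
$\sigma = 0.05$ declines from 100% and settles near 90% once the damped
oscillation has died out, the transient osteoclast excess having
outweighed the cheap osteoblast surplus ($k_1/k_2 \approx 116$).

## Randomized fixtures

`fixture_params()` drives the property tests: rates and exponents are
drawn uniformly in broad windows around the physiological values
($\alpha_1 \in [0.5, 6]$, $g_{11} \in [0.7, 1.3]$, etc.),
$\sigma \in (0.02, 0.95)$, couplings $g_{3i} \in [-0.3, 0.3]$ and
$r_{ij} \in [-0.4, 0.4]$. Draws are rejected while
$|\gamma| < 0.05$ or, for the model-3 effective exponents,
$|\Lambda| < 0.05$: closed-form exponents scale like $1/\gamma$, and
near-degenerate determinants push steady states outside the range where
double-precision fixed points are even representable, which would turn
the closed-form-versus-root-finder comparison into a test of overflow
behavior. The threshold is an argument for studies that want weaker
coupling. These fixtures emulate parameter uncertainty around one
biological operating point; they do not emulate measurement noise,
state stochasticity, or structural misspecification, so passing
property tests certify the mathematics (fixed points, Jacobians,
classifications), not the biological adequacy of the model.

Even within the accepted region, random draws can produce fixed points
of $10^{-13}$ or $10^{11}$ cells. The finite-difference certification
of the Jacobian therefore judges each cell-row entry relative to that
row's term scale $\beta_i \bar{x}_i / (1 - \sigma)$: at a fixed point
the $D$-derivative entries sit on an exact cancellation of terms of
that scale, and no floating-point evaluation — analytic or differenced
— can pin them down more tightly than the term scale times machine
rounding.

## Known limitations

* The models are spatially lumped (one BMU); no spatial or
  continuum extension, mechanical loading, or treatment scheduling is
  included.
* Model 2 cannot start at $D = 0$ with negative tumor exponents (the
  production term diverges); the burden must be seeded positive.
* The bone-mass rule references a constant steady state over a run;
  a time-varying reference (tracking the quasi-steady state as $D$
  grows) is a plausible alternative reading and would change $z$
  trajectories, though not cell dynamics. The `reference` argument of
  `simulate_remodeling()` at least allows anchoring to the tumor-free
  fixed point instead.
* Center-class (zero real part) verdicts are tolerance decisions on a
  structurally exact property; at scan resolution they appear only
  where the class is exact on the grid point, so center bands thinner
  than the grid spacing can be missed.
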