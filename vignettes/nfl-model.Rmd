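---
title: "A negative-feedback-loop model of aerobic glycolysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A negative-feedback-loop model of aerobic glycolysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warburgnfl)
```

## The model

Proliferating cells ferment glucose to lactate even in the presence of
oxygen (aerobic glycolysis, the Warburg effect). This package implements a
minimal kinetic explanation built on a negative feedback loop between two
state variables: cell proliferation $C_P$ (fold increase in cell number
from a single cell, dimensionless) and cytoplasmic NADH concentration $N$:

$$\frac{dC_P}{dt} = \frac{k_1 C_P N}{k_2 + N} - k_{d1} C_P, \qquad
  \frac{dN}{dt} = \frac{k_3}{k_4 + C_P} - k_{d2} N.$$

The positive arm: NADH licenses cell-cycle progression (mechanistically,
NADH-dependent CtBP dimerisation represses the CDK inhibitor CDKN1A), a
saturating drive with half-saturation scale $k_2$ and maximal rate $k_1$,
opposed by cell-cycle-dependent apoptosis $k_{d1}$. The negative arm:
glycolysis injects NADH at flux $k_3$, but proliferation dilutes and
consumes it (the $k_4 + C_P$ denominator, where $k_4$ is the fold decrease
in the flux due to pyruvate-to-lactate conversion), and the remaining
NADH/NADH-equivalent drains to mitochondrial oxidative phosphorylation at
first-order rate $k_{d2} N$.

All quantities are in arbitrary but mutually consistent units: the model
fixes no absolute time or concentration scale, and the package's tests
verify the corresponding invariances (a common rescaling of $k_2$, $k_3$,
the redox pool and $N$ leaves $C_P$ dynamics and IPPI unchanged; a common
rescaling of the four rate-type constants with time leaves trajectories
unchanged).

A note on $k_2$: the modelling tradition the equations come from glosses
$k_2$ as the basal (NADH-independent) apoptosis scale while placing it in
the saturation denominator. The implementation follows the equation, not
the gloss: $k_2$ acts as the NADH half-saturation scale of the
proliferation term.

## Steady states, IPPI, and quiescence

Setting $dC_P/dt = 0$ with $C_P > 0$ pins the NADH level from the
cell-cycle constants alone, and setting $dN/dt = 0$ then yields the
steady proliferation:

$$N^{*} = \frac{k_{d1} k_2}{k_1 - k_{d1}}, \qquad
  C_P^{*} = \frac{k_3}{k_{d2} N^{*}} - k_4.$$

`steady_states()` reports both fixed-point branches: the quiescent branch
($C_P = 0$, $N = k_3/(k_4 k_{d2})$), which always exists because $C_P = 0$
is dynamically absorbing, and the proliferative branch above when
$k_1 > k_{d1}$. A proliferative branch whose algebraic $C_P^{*}$ is
negative is labelled `negative-algebraic` and reported as-is: it solves
the steady-state algebra and matters for interpretation (raising the redox
ratio can drive net population decline) but is unreachable from
non-negative initial conditions, since the dynamics conserve the
non-negative orthant. The package deliberately reports both views rather
than reconciling them.

The single governing dimensionless number is
$$\mathrm{IPPI} = \frac{k_3}{k_4\, k_{d2}\, N_0},$$
the ratio of the glycolytic NADH inflow to the lactate-amplified
mitochondrial outflow at baseline NADH $N_0$. At any self-consistent
baseline with $C_{P0} \ge 0$, $\mathrm{IPPI} = (k_4 + C_{P0})/k_4 \ge 1$;
equality is quiescence. `classify_regime()` grants only floating-point
slack ($10^{-9}$ relative, the default `tol`) around 1 because the
quiescence condition is exact algebra, not an estimate.

Stability is not part of the closed-form analysis; `steady_states()`
computes the eigenvalues of the $2\times2$ Jacobian numerically at each
branch and reports `stable`/`unstable`/`unknown` as a diagnostic. In
practice the proliferative branch is stable whenever it is feasible with
positive $C_P^{*}$, and the quiescent branch is then a repeller; the
diagnostic makes that visible rather than assumed.

## The redox-ratio map and relative proliferation

The experimentally meaningful control variable is the NADH/NAD$^+$ ratio
$r$, not $N$. With a conserved total pool $T = \mathrm{NADH} +
\mathrm{NAD}^+$, $N = T\,r/(1+r)$ (`ratio_to_concentration()`). This is a
modelling choice: it is the unique mapping under pool conservation, and it
reproduces exactly the closed-form relative-proliferation curve

$$\frac{C_P}{C_{P0}} =
  \frac{\mathrm{IPPI}\cdot\frac{r+1}{r_0+1}\cdot\frac{r_0}{r} - 1}
       {\mathrm{IPPI} - 1},$$

which the test suite verifies algebraically against two independent
steady-state evaluations at pool-mapped NADH levels (to $10^{-10}$). The
pool size $T$ cancels from the ratio, so `pool_total` (default 1) only
matters when converting to absolute concentrations.

Physiologically the cytoplasmic ratio lies between roughly 1/700 and 1/60.
The package flags, with a warning rather than an error, any evaluation at
$r \ge 1/60$: the algebra stays valid (and the large-$r$ invariance
$C_P/C_{P0} \to 1$ is itself a checked property) but biological
conclusions should not be drawn there.

Quiescence from a proliferating baseline requires raising the ratio to
$r \approx \mathrm{IPPI}\cdot r_0$. The un-approximated condition is
linear in $r$, so `quiescence_ratio()` returns the exact root
$r = \mathrm{IPPI}\,r_0/(1 + r_0 - \mathrm{IPPI}\,r_0)$ alongside the
small-ratio approximation; both are reported because the approximation's
validity condition ($r, r_0 \ll 1$) is itself part of the model's stated
regime. When $1 + r_0 - \mathrm{IPPI}\,r_0 \le 0$ no positive root exists
and the target is flagged unattainable.

## Numerical integration

`simulate_trajectory()` integrates with the stiffness-switching `lsoda`
method at `rtol = 1e-8`, `atol = 1e-10`: the system is two-dimensional and
cheap, so conservative tolerances cost essentially nothing and make the
simulator usable as a brute-force oracle for the closed forms (matching to
$10^{-6}$ relative on converged runs is a tested invariant). Convergence is
declared when the relative derivatives fall below $10^{-8}$; the default
horizon is $50/\min(k_{d1}, k_{d2})$ — fifty times the slowest linear
relaxation time — with up to four automatic doublings. The equations
preserve non-negativity analytically, so the solver clamps round-off
undershoots at zero but raises an error if a state falls below $-$`atol`,
treating that as a numerical failure rather than a model behaviour.

One degenerate case deserves mention: when the two branches coincide
(IPPI exactly 1) the fixed point is marginal and the approach is algebraic
($C_P \sim 1/t$), not exponential, so derivative-based convergence is
slow; the tests for that case assert decay toward zero over a long fixed
horizon instead of demanding the usual residual threshold.

## Parameter sweeps

`ratio_sweep()` materialises the relative-proliferation curve families as
a tidy table (one row per (IPPI, $r$) cell, each reproducible by a single
`relative_proliferation()` call — a tested invariant to prevent caching
drift). The exact grids behind the published curve families are not
printed anywhere, so the defaults are representative, not pixel-matched:
$r_0 = 1/100$ (inside the physiological window), $r$ log-spaced over
$[r_0/10,\,10 r_0]$ with 201 points, and IPPI in $\{1.05, 1.5, 2, 5,
10\}$, with 2.0 matching the one value the source material states for its
two-panel curve.

`hypoxia_scenario()` implements the hypoxia thought experiment as a grid:
hypoxia scales $k_{d2}$ down (less oxidative phosphorylation) while
lactate production $k_4$ rises. Because the baseline NADH level $N^{*}$
depends only on the cell-cycle constants, IPPI scales as
$1/(k_4 k_{d2})$ across the grid, so $k_4 \propto 1/k_{d2}$ traces an
iso-IPPI contour — the compensation path along which cells remain
simultaneously highly proliferative and close to the quiescence condition
$r/r_0 = \mathrm{IPPI}$. No spatial structure (lactate gradients within a
tumour) is modelled.

## Synthetic data

No experimental trajectories exist for this model, so the inference stage
is exercised on synthetic data from the model itself
(`generate_dataset()`). Observation noise is multiplicative log-normal —
both observables are positive (a fold-change and a concentration), and
relative error is the natural scale for such measurements — with
$\sigma = 0.05$ (≈5% error) as the default, a typical relative precision
for quantitative imaging or plate-reader readouts. The default design
uses three initial conditions straddling the steady state on a 50-point
grid over $[0, 25]$ time units (several relaxation times of the default
parameter sets): transients are what carry information about $k_1$, $k_2$
and $k_{d1}$, which all enter only through dynamics off steady state. A
single master seed deterministically spawns per-series substreams,
recorded in the dataset manifest, so datasets are bit-reproducible.

What passing the recovery tests does *not* show about real data: the
generator emulates neither systematic errors (calibration drift, offsets),
nor sampling irregularity, nor model misspecification — the fitted model
is exactly the generating model. Recovery results are therefore a
consistency check on the implementation as an inferential object, not a
claim about practical identifiability in any assay.

## Parameter recovery

`fit_parameters()` minimises the sum of squared log-residuals (matched to
the multiplicative noise model) jointly over all series, in log-parameter
space — which enforces positivity and roughly equalises scales — using
Levenberg–Marquardt least squares. All series share one parameter vector,
so they are integrated as a single stacked ODE system per objective
evaluation. The start schedule is the user's guess plus seeded log-normal
perturbations (sd 0.5); because the landscape is smooth and
low-dimensional, the schedule stops early once two starts agree on the
optimum (within 0.1% of the best loss) or a start reaches an exact
zero-residual fit, and is otherwise capped at `n_restarts` (default 10).

Identifiability is reported, not assumed: the fit computes the central
second difference of the loss along each log-parameter (step 0.05) and
flags near-zero curvature as a flat profile. The canonical degenerate
design — series pinned at the quiescent steady state, where $C_P \equiv 0$
and the proliferation-arm constants never enter the likelihood — raises
flags for $k_1$, $k_2$, $k_{d1}$, as the tests verify. Derived quantities
are often better determined than raw constants; `recovery_report()`
therefore reports errors for IPPI, $N^{*}$ and $C_P^{*}$ alongside the six
constants.

Problem sizes used by the recovery study: 3 series × 50 time points,
$\sigma = 0.05$, 10 replicates, 10 restarts — small enough to run in
seconds while leaving the transient-rich design that identifiability
requires.

## Pipeline and reproducibility

`load_config()` reads a YAML/JSON configuration (rate constants plus
optional stage, grid, noise and fit blocks; violations are reported per
key), and `run_pipeline()` executes the stages in dependency order,
writing TSV/CSV/JSON artifacts plus a manifest of MD5 content hashes;
reruns with the same configuration and seed are bit-identical at the
manifest level. The package is a library-first analysis tool: the exported
functions are the interface, and the pipeline runner is their scripted
composition rather than a separate command-line program.

## Known limitations

* Endoreplication (cell mass as a distinct variable from cell number) is
  noted in the source model but given no proportionality constant; it is
  not implemented.
* The stability labels come from linearisation only; no bifurcation
  continuation or global analysis is attempted.
* The dynamics are deterministic; no stochastic (birth–death) simulation
  is provided, matching the model's formulation.
* The hypoxia scenario is a parameter sweep; spatial lactate gradients in
  solid tumours are outside scope.
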