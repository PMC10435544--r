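---
title: "Correlating drug solubility in supercritical CO2: models, fitting and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlating drug solubility in supercritical CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsolub)
```

## The problem

Supercritical CO2 is a tunable-density solvent: above its critical point
(304.2 K, 7.38 MPa) small changes in pressure move its density — and with
it its solvating power — over a wide range. Micronization processes for
poorly water-soluble drugs (RESS and anti-solvent families) are designed
around the drug's equilibrium mole-fraction solubility $y_2(T,P)$ in
SC-CO2, so measured solubility tables are routinely correlated with
density-based semi-empirical models and with expanded-liquid
activity-coefficient models. This package implements that workflow for
the aripiprazole/CO2 system, whose bundled dataset spans 308–338 K and
12–30 MPa (4 temperatures by 7 pressures, 28 records) with $y_2$ between
$1.83\times10^{-6}$ and $1.036\times10^{-5}$.

Units are fixed package-wide: temperature in K, pressure in MPa, density
in kg·m$^{-3}$, mass solubility in g·L$^{-1}$, $y_2$ dimensionless. All
fitted coefficients are reported under this convention; coefficient
scales change if pressure is expressed in bar, which matters most for the
Jouyban model where $P$ enters quadratically and reciprocally.

## Data model and conversions

A dataset couples the record table with the solute and solvent constants.
The mass solubility follows from the mole fraction as
$$S = \frac{\rho\, M_S\, y_2}{M_{CO_2}(1-y_2)},$$
and the package keeps the exact algebraic inverse so models fitted in
$\ln s$ space can always be scored on mole fractions. Validation enforces
positivity, $0 < y_2 < 1$, no duplicated $(T,P)$ conditions, and — when a
mass-solubility column is present — agreement with this conversion to 1%
relative. For the bundled table the largest disagreement is below the
printed rounding (±0.002 on the $S\times10$ scale), which pins the
reading of the conversion formula.

The expanded uncertainty of a record combines the relative standard
uncertainties of $(y_2, T, P)$ in quadrature with sensitivity powers
(default all 1, as the source table's footnote gives no values) and a
coverage factor $k = 2$. The sampling-loop mole-balance conversion
(vial concentration to mole fraction) is provided as a documented
utility; the headline pipeline starts from tabulated $y_2$ because the
vial volume is not fully specified in the source.

## The correlation models

Six density-based correlations are fitted in their natural "fit spaces"
(see the README table). Two of them are printed ambiguously in parts of
the literature, and the package takes an explicit, flagged position:

* **Bartle**: the conventional left-hand side $\ln(y_2 P / P_{ref})$ with
  $P_{ref} = 0.1$ MPa and density offset $(\rho - 700)$ is the default;
  a literal reading that divides by $\rho_{ref}$ instead is available via
  `bartle_form = "literal"`. The conventional form is standard and makes
  $a_2 = -\Delta H_{vap}/R$ meaningful.
* **Méndez-Santiago–Teja**: the classic form $T\ln(y_2 P) = a_0 + a_1\rho
  + a_2 T$ is the default. The decision is empirical: refitting both
  variants on the bundled data, the classic form's optimum (AARD 9.33,
  coefficients $\approx(-8327, 2.9, 9.8)$) reproduces the published MST
  row for this system almost verbatim, while the plain $\ln(y_2P)$
  reading cannot get below AARD 10.5. `mst_classic = FALSE` restores the
  plain reading.

The Sodeifian model is conventionally counted as a six-parameter model
although its written form carries five coefficients; the package fits
the five coefficients and uses $Z = 6$ in the AARD denominator, matching
the convention under which its published fit quality is reported.

## The modified Wilson expanded-liquid model

The supercritical phase is treated as an expanded liquid and the solute,
present at $y_2 \sim 10^{-6}$, at infinite dilution:
$$y_2 = \frac{1}{\gamma_2^\infty}
  \exp\!\left[\frac{-\Delta H_f}{R}\Big(\frac 1T - \frac 1{T_m}\Big)\right],
\qquad \ln\gamma_2^\infty = 1 - \Lambda_{12} - \ln\Lambda_{21},$$
with
$\Lambda_{12} = \vartheta_2\,\rho_{cl}\,\rho_r e^{-\lambda'_{12}/T_r}$,
$\Lambda_{21} = e^{-\lambda'_{21}/T_r}/(\vartheta_2\,\rho_{cl}\,\rho_r)$
and the linear molar-volume rule $\vartheta_2 = \alpha\rho_r + \beta$.
Dimensional bookkeeping: $\rho_r$ is the mass-basis reduced density
($\rho/467.6$ kg·m$^{-3}$) while $\vartheta_2\rho_{cl}$ uses the molar
critical density ($\rho_{cl} = 10\,625$ mol·m$^{-3}$); this is the only
combination that keeps the $\Lambda$s dimensionless with $\alpha, \beta$
in m$^3$·mol$^{-1}$ on the scales their published values have.

Aripiprazole's fusion enthalpy is not publicly reported. The default is
Walden's rule ($\Delta S_f \approx 56.5$ J·mol$^{-1}$K$^{-1}$ at
$T_m = 415.11$ K, i.e. $\Delta H_f \approx 23.45$ kJ·mol$^{-1}$); setting
`wilson_fit_dhf = TRUE` instead fits it as a fifth parameter bounded to
20–70 kJ·mol$^{-1}$. The second route is used for headline comparisons,
because the published fit quality depends on an unreported choice and a
bounded free parameter makes the comparison an upper bound rather than a
guess. The five-parameter fit is warm-started from the four-parameter
solution, so freeing the enthalpy can never worsen the optimum.

## Parameter estimation

The objective is exactly the reported statistic: AARD% on mole fractions
with the $N - Z$ denominator. Since $Z$ is constant per model this equals
minimizing mean absolute relative error; it is non-smooth (an $L_1$-type
criterion whose optimum tends to interpolate $Z$ records exactly), which
is why the package pairs a global stochastic search with a
derivative-free polish rather than gradient methods.

Fitting runs best-of-`n_restarts` simulated annealing (geometric cooling,
default $T_0 = 10$ objective units, factor 0.95, 50 proposals per level,
stop at $10^{-4}$) followed by Nelder–Mead. Three numerical choices
matter:

* **Preconditioning.** The raw coefficients of every density model are
  strongly collinear (e.g. intercept vs $\ln\rho$ slope), so isotropic
  coordinate proposals stall. Proposals are instead drawn in the
  fit-space prediction metric — steps are $V\,\mathrm{diag}(s/d)\,z$ from
  the SVD of the fit-space design matrix, scaled by the least-squares
  residual spread $s$. Restart 1 starts at the fit-space least-squares
  solution; the others are spread around it. The Wilson model, which has
  no linear fit space, is preconditioned by the Jacobian of its log
  prediction.
* **Bounds and penalties.** Default search boxes are centred on the
  least-squares anchor (half-width $3|\theta| + 1$ per coordinate);
  Wilson uses static physically motivated bounds, including
  $\vartheta_2 > 0$ over the data's reduced-density range. Parameter
  vectors producing non-finite or non-positive predictions receive a
  large finite penalty ($10^6$) so the walk can traverse them; the
  simplex sees the objective through a clamp so it cannot leave the box.
* **Determinism and nesting.** Each fit seeds its own RNG stream and
  restores the caller's; identical (seed, options, data) give
  bit-identical results. Restart starting points are a prefix of a
  fixed-size Latin-hypercube pool, so increasing `n_restarts` extends a
  run rather than reshuffling it — the best-of-restarts objective is
  non-increasing in the restart count by construction. Ties between
  restarts keep the earliest index.

Each restart ends with a short simplex descent and the overall best gets
a full polish. On the bundled data the density-model optima found this
way are stable to all digits across seeds and coincide with an
independent combinatorial check (enumerating interpolation vertices); the
Wilson optimum retains a seed spread of a few tenths of an AARD point,
which is documented rather than hidden because its multimodality is real.

## Fit quality and enthalpies

$R^2$ is the squared Pearson correlation of calculated vs experimental
mole fractions on the linear scale (switchable in principle; correlation
is scale-invariant, which is why the 45-degree diagnostic below exists),
and $R_{adj} = \sqrt{|R^2 - Q(1-R^2)/(N-Q-1)|}$ uses the model's count of
independent variables ($Q = 2$ for the density/temperature models, 3 for
Jouyban where pressure enters independently).

The Chrastil temperature coefficient obeys $a_2 = \Delta H_{total}/R$ and
the Bartle coefficient $a_2 = -\Delta H_{vap}/R$; the package reports
magnitudes with a positive-endothermic convention (the fitted $a_2$ are
negative) and keeps the raw coefficients alongside. The solvation
enthalpy is $\Delta H_{sol} = \Delta H_{total} - \Delta H_{vap}$ by
Hess's law, negative here — exothermic solute–solvent interaction.

## Diagnostics

`crossover_region()` classifies each isobar's temperature trend by the
sign of the Spearman correlation of $y_2$ with $T$ and brackets the
crossover at the adjacent pressure pair where the trend flips from
decreasing to increasing. The bracket is reported as a grid interval, not
a point, because the data only localize it between isobars; on the
bundled data the flip sits between 15 and 18 MPa. Non-monotone isobars
are excluded with a warning.

`self_consistency()` scores calculated-vs-experimental agreement on the
45-degree line with the identity-line $R^2$,
$1 - \sum(y^{calc}-y^{exp})^2 / \sum(y^{exp}-\bar y^{exp})^2$ —
deliberately not a Pearson correlation, since the 45-degree test must
penalize bias. The default consistency threshold is 0.95.

## The synthetic-data generator

`generate_dataset()` draws $y_2 = y_2^{model}(T,P,\rho)\,e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma^2)$, on a $(T,P)$ grid with densities from
a bilinear surrogate of the bundled 4×7 density table (exact at the
nodes, refusing extrapolation unless asked). Multiplicative lognormal
noise is the assumed error model because the experimental replicate
standard deviations scale roughly with $y_2$ (about 3–7% relative);
$\sigma = 0.05$ is the default noise scale and the default grid mirrors
the experimental 4×7 design so synthetic and real analyses are directly
comparable.

What the generator emulates: the design, the density field, the
multiplicative error structure. What it does not: temperature-dependent
error variance, correlated errors within an isotherm, calibration-curve
nonlinearity, and any model misspecification — synthetic data are drawn
from the fitted family itself. Passing parameter-recovery tests therefore
demonstrates the estimator's correctness, not the physical truth of any
correlation on real measurements.

`simulate_recover()` runs generate-and-refit replicates and reports
per-coefficient relative bias and RMSE; the test suite uses 12–20
replicates at $\sigma = 0.05$ with a shortened annealing schedule, and
the zero-noise case is required to recover truth to $10^{-3}$ relative.

## Problem sizes and runtime choices

The package's own tests fit at two settings: a light schedule (4
restarts, $T_0 = 1$, stop at $10^{-3}$) for structural checks, and the
production default (40 restarts) for the checks that compare against
published fit quality. A full seven-model production run on the
28-record dataset takes a few minutes on one core; the light schedule
fits in about a second per model. These sizes are the package's choice of
a reasonable desk-scale experiment for a 28-point dataset.

## Known limitations

* Densities are inputs; no equation of state is bundled. The surrogate
  interpolates the experimental grid and any serious extrapolation needs
  an external density provider.
* AARD-optimal coefficients are not least-squares coefficients;
  comparisons with fits produced under squared-error objectives will
  disagree in the second digit even for the same model and data.
* The Wilson model's fit quality for this system is conditional on the
  fusion-enthalpy policy, and its optimum has genuine seed-to-seed
  spread of a few tenths of a point at the default budget.
* $R^2$ on the linear mole-fraction scale is dominated by the largest
  solubilities; the AARD and the identity-line diagnostic carry the
  low-solubility information.
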