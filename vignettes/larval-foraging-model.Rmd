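---
title: "A trait-based model of larval fish foraging and growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A trait-based model of larval fish foraging and growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvforage)
```

## The model

`larvforage` simulates one day in the life of a young, exogenously feeding
marine fish larva. A larval type is a list of sixteen biological traits
(`builtin_types()`); everything else — temperature, photoperiod, turbulence
and the prey field — is environment. The model is fully deterministic:
stochastic processes such as individual prey encounters are represented by
their expected rates.

The day is resolved in 24 hourly steps, one night followed by one day
(daylight occupies the final `photoperiod` hours). The state variables are
standard length $L$ (mm) and dry mass $M$ (µg), initialized as
$L_0 = x_\mathrm{len}$ and $M_0 = x_\mathrm{body} L_0^3$, where
$x_\mathrm{body}$ caps Fulton's condition factor $M/L^3$. Each hour,

$$M' = M + y_\mathrm{eff}\, I - A\, R,
\qquad L' = \max\!\big(L, (M'/x_\mathrm{body})^{1/3}\big),$$

so growth in length is isometric and a loss of mass never shortens the
larva. Routine respiration is a fraction of body mass per hour with a Q10
temperature correction, doubled (by default, $y_\mathrm{act}=2$) during
daylight to pay for foraging activity; temperatures above the thermal
tolerance $x_\mathrm{tol}$ exclude the larva with an error. Ingestion in a
lit hour is the lesser of digestive capacity $D$ (also mass-proportional
and Q10-corrected) and the foraging capacity $F$ integrated over the lit
fraction of the hour, $I = \min(D,\, 3600\,\lambda_t F)$.

### Prey fields

Prey from 0.04 to 2 mm are held in 196 bins of 0.01 mm. We take bin edges
at 0.04, 0.05, …, 2.00 mm and centres at the midpoints 0.045 … 1.995 mm.
Dry mass follows a power law $m = a\,l^{b}$ with defaults $a = 2.5$ µg (a
typical 1-mm copepod) and $b = 2.03$. The biomass $b_\mathrm{total}$ is
distributed across bins as a normalized biomass size spectrum of slope $s$:
biomass density per unit body mass $\propto m^{s}$, integrated analytically
over each bin's edge masses (the $s = -1$ log case included) and normalized
so the bin biomasses sum exactly to $b_\mathrm{total}$. Numeric
concentrations are $c_i = b_i/m_i$. Two consequences worth knowing:

* the *relative* biomass distribution over length is independent of the
  mass-law coefficient $a$, so clearance-type results do not depend on it —
  only handling-time saturation and count-based diagnostics do;
* a log–log regression of normalized bin biomass on bin mass recovers $s$.
  Because bins are uniform in length, not in log mass, the regression
  abscissa matters at steep slopes: the geometric mean of the edge masses
  (the log-midpoint) recovers $s$ to better than $10^{-3}$ across
  $s \in [-3, 0]$, while the centre-length mass drifts to
  $\sim 2\times10^{-3}$ at $s=-3$. The tests use the log-midpoint.

### Foraging

Foraging follows a predation sequence. Prey pass through an effective
visual cylinder of radius $y_\mathrm{vis} L$ at the combined speed
$V = \sqrt{u^2 + v^2 + w^2}$ of larval swimming ($u = y_\mathrm{swim} L$),
prey swimming ($v$, linear in prey length at 3 body lengths s⁻¹ by
default), and turbulence. The root-mean-square turbulent velocity at the
encounter separation $d = y_\mathrm{dist} L$ follows inertial-subrange
scaling, $w = \sqrt{1.62\,(\varepsilon d)^{2/3}}$ with $\varepsilon$ in
mm² s⁻³ and 1.62 = (55/18) × 0.53 from the universal Kolmogorov constant.
Detection is a type-2 saturating response of prey length
($O = l/(l + y_\mathrm{det})$); pursuit success declines linearly to zero
at the corrigible turbulent velocity $y_\mathrm{turb} L$; capture success
declines linearly to zero at the maximum ingestible length
$x_\mathrm{ing} L$. Encounters are
$E_i = c_i\, \pi (y_\mathrm{vis} L)^2\, V_i\, O_i$ and the expected gain
per encounter is $e_i = P\, C_i\, m_i$.

Foraging capacity is a Holling disk rate over an *optimal diet* $S$:

$$F = \frac{\sum_{i\in S} E_i e_i}{1 + y_\mathrm{hand} \sum_{i\in S} E_i},$$

with bins admitted in decreasing profitability $e_i/y_\mathrm{hand}$ while
the rate strictly increases. With a common handling time this greedy prefix
is the global maximum over all subsets, which the tests verify against an
exhaustive-subset oracle on small fields. Ties in profitability are broken
toward the smaller bin, for determinism. Handling time is charged once per
encounter with any diet-included prey, whether or not pursuit succeeds —
the standard disk-equation convention.

Two structural consequences: turbulence helps encounters ($V$ rises) but
hurts pursuit ($P$ falls), and at the parameterized swimming speeds
(≥ 4 mm s⁻¹) the product $V \cdot P$ is strictly decreasing in $w$, so the
net effect of turbulence is negative for every built-in type and the
optimal dissipation rate is 0. And because prey requirement is governed by
clearance $\propto (y_\mathrm{vis} L)^2$, the prey concentration needed for
a fixed growth rate scales almost exactly as $y_\mathrm{vis}^{-2}$ — which
pins the ±10 % sensitivity bounds of the visual radius at
$100/\sqrt{1.1} \approx 95.3\,\%$ and $100/\sqrt{0.9} \approx 105.4\,\%$
regardless of any metabolic calibration.

## Calibration of the metabolic rates

The trait table lists routine respiration ($x_\mathrm{res}$, 2–4 % of $M$)
and digestive throughput ($y_\mathrm{dig}$, 2.5 % of $M$) "per hour" at
10 °C, with metabolic efficiency 67.5 % and daytime respiration doubled.
Read literally per hour, the budget cannot close: the best possible hourly
gain $y_\mathrm{eff}\, y_\mathrm{dig} M \approx 0.017 M$ is below the
daytime respiration $2 x_\mathrm{res} M \ge 0.04 M$ for every type at every
temperature, so growth would be negative everywhere — contradicting both
observation and the intent of the parameterization. We therefore expose two
global knobs, `respiration_scale` and `digestion_scale`, and default
`respiration_scale = 1/24`: the routine-loss percentages are read as daily
losses, applied uniformly over the 24 hourly steps. This yields growth
potentials of roughly 10–35 % d⁻¹ across the built-in types at their
seasonal reference conditions — the right order for young larvae — and
positive-growth prey thresholds of order 1–10 mg m⁻³. Users who prefer a
different metabolic calibration can set the scales in `model_config()` or
in the `[model]` section of a config file; none of the package's
geometry-level results (clearance rates, optimal prey sizes, Chesson's α,
the visual-radius sensitivity bounds) depend on this choice. Absolute
starvation/satiation levels and growth potentials do, and should be read as
calibration-dependent.

The oxygen-to-dry-mass conversion (0.85 µg µl⁻¹) used when the respiration
traits were estimated is kept in `model_config()` for documentation only;
runtime respiration is already mass-based.

## Experiment drivers

* `growth_potential()` — ad libitum growth: ingestion forced to digestive
  capacity in every lit hour; independent of the prey field by
  construction.
* `starvation_point()`, `satiation_point()`, `prey_requirement()` —
  smallest total prey biomass with $G \ge 0$, $G \ge G_\mathrm{pot} -
  10^{-6}$, and $G \ge$ a target (default 5 % d⁻¹). All solve by bisection
  on $\log_{10} b_\mathrm{total}$ over $[10^{-3}, 10^{4}]$ mg m⁻³ to a
  relative tolerance of $10^{-4}$, returning `Inf` with a diagnostic when
  the target is unattainable. The satiation tolerance $10^{-6}$ d⁻¹ is far
  below any reporting precision.
* `sensitivity_range()` — for one trait or environmental factor, the
  multiplicative perturbation interval within which an output (growth
  potential or prey requirement) stays within ±10 % of its reference:
  $|\Phi(r\theta) - \Phi_0| < 0.1|\Phi_0|$, both directions, bisected to
  0.05 % of the reference parameter; a direction is open (reported 0 or
  `Inf`) when a tenfold perturbation stays inside the band. Temperature is
  perturbed on its numeric °C value.
* `optimal_prey_length()` — argmax over bins of $m_i C_i$ (pursuit and
  handling are constant across bins). In the continuous limit the optimum
  of $l^{b}(1 - l/l_\mathrm{max})$ sits at $l_\mathrm{max}\, b/(b+1)$; with
  $b = 2.03$ that is 67 % of the maximum ingestible length, and the binned
  argmax lands within half a bin of it for all four types.
* `optimal_spectrum_slope()` — golden-section minimization of the
  starvation (or satiation) point over $s \in [-4, 0]$ to 0.01, ties
  resolved leftward so flat stretches return deterministically.
* `turbulence_response()` — starvation and satiation points over an
  $\varepsilon$ grid; infeasible rows (pursuit zero everywhere) are
  `Inf`.

## The fixture generator

`generate_fixtures(seed, n)` emits deterministic synthetic scenarios for
testing: half built-in types, half random trait sets drawn uniformly within
±50 % of the built-in trait ranges (nudged back into the validity domain
where a draw would violate an invariant), paired with environments spanning
temperature 3–24 °C (capped at the type's tolerance), photoperiod 9–24 h,
dissipation 10⁻¹²–10⁻⁵ W kg⁻¹ and biomass 0.1–100 mg m⁻³ (both
log-uniform), slope −2.5 to −0.5. This emulates the *envelope* of
conditions young larvae plausibly meet, not any particular sea: scenarios
are independent draws with constant conditions over the day, no
field-realistic covariance between temperature, season and prey, and no
measurement error. Passing tests on these fixtures demonstrates numerical
and structural correctness of the model machinery, not skill against field
data.

## Numerical choices and degenerate inputs

* Explicit Euler on the hourly grid, all rates from start-of-hour state —
  the model's definition, not an approximation to a continuous system.
* A mass update that would reach $M \le 0$ flags the larva dead and floors
  $M$ at $10^{-12}$ µg so the daily $G$ remains reportable.
* $G = \ln(M_{24}/M_0)$ by default; an arithmetic variant
  $(M_{24}-M_0)/M_0$ sits behind `model_config(growth_def =
  "arithmetic")`.
* In a fractional dawn hour, ad libitum ingestion is the full hourly $D$
  (the $\min$ with $3600\lambda F$ is vacuous as $F \to \infty$); at finite
  prey the lit fraction scales the foraging term only.
* Zero total biomass is a valid prey field (all rates zero); an all-zero
  field makes Chesson's α undefined and raises an error.
* Problem sizes: the test suite runs the full 196-bin model; the
  exhaustive-subset diet oracle uses ≤ 10 bins (2¹⁰ subsets); sensitivity
  and slope optimizations in tests use single types and coarse turbulence
  grids, which keeps the whole suite under a minute without changing any
  default model constant.

## Known limitations

* No gut-content state: larvae cannot bank a full gut across hours, and
  digestion-limited intake is memoryless.
* Light is binary (night/day); no light-intensity continuum, turbidity,
  salinity or oxygen effects; no vertical behaviour, so depth-varying
  turbulence is out of reach.
* Thermal tolerance is a hard threshold, so growth rises with temperature
  until just below `x_tol` — unrealistically.
* The traits parameterize larvae within ~2 mm of their initial length;
  24-hour snapshots keep them in that window, and multi-day trajectories
  would require length-varying traits.
* The combined-velocity and prey-speed forms (root-sum-of-squares;
  $v = 3l$ BL s⁻¹) are reconstructions constrained by published clearance
  rates (any prey-speed coefficient in \[0, 4\] reproduces them at printed
  rounding); the Gerritsen–Strickler exact encounter-speed form is a known
  alternative with negligible effect at these speeds.

## A worked example

```{r}
cod <- larval_type("cod")
env <- foraging_env(temperature = 5.1, photoperiod = 11.8,
                    epsilon = 1e-7, b_total = 15, s = -1.2)
res <- simulate_day(cod, env)
glance(res)

growth_potential(cod, 5.1, 11.8)
starvation_point(cod, env)
prey_requirement(cod, env)
optimal_prey_length(cod)
```
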