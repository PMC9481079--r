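---
title: "Lives-saved projection: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lives-saved projection: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livessaved)
```

## What the model computes

The package answers one question: given a setting's baseline mortality and
a plan to raise intervention coverage, how many stillbirths and maternal,
neonatal and child deaths would be averted, and by which interventions?
This is the class of deterministic, cohort-style lives-saved models used
throughout RMNCH&N program planning: no transmission dynamics, no
individual simulation — cause-specific death counts scaled by survival
multipliers that are transparent functions of coverage, efficacy and risk
exposure.

A projection runs year by year from a fixed baseline (year 0) to a
horizon. Baseline deaths per cell (year, group, cause) are

$$D_0(t, g, c) = N_g(t)\; \frac{r_g}{u_g}\; f_{g,c},$$

with denominator $N_g(t)$ (live births; pregnancies for stillbirths),
baseline rate $r_g$ in the group's conventional units $u_g$, and
cause-of-death fraction $f_{g,c}$. Rates are held constant at baseline:
the model's working assumption is that distal drivers (income, education)
act on mortality *through* intervention coverage, so everything that moves
deaths is an explicit multiplier. Denominators may grow or shrink over the
horizon; deaths are linear in them.

### Direct effects: the residual-mortality multiplier

An intervention received by a fraction $c$ of those in need, with efficacy
$e$ (proportional reduction in amenable deaths among the covered) and
affected fraction $AF$ (the share of the cause's deaths it can act on at
all), leaves the survival multiplier

$$m(c_0 \to c_t) = 1 - \frac{e\,AF\,(c_t - c_0)}{1 - e\,AF\,c_0}.$$

The denominator is the residual: observed baseline deaths already exclude
what baseline coverage $c_0$ averts, so only the coverage *increment* acts,
scaled up to the deaths that remain. Consequences worth knowing:

* $m = 1$ exactly when coverage does not move — a null scenario changes
  nothing, to the last bit.
* $m > 1$ when coverage falls: losing coverage restores mortality. This is
  permitted (and logged when `options(livessaved.verbose = TRUE)`), not an
  error.
* $m = 0$ in the limit $e = AF = 1$, $c_0 = 0 \to c_t = 1$: every amenable
  death averted.
* If $e\,AF\,c_0 \ge 1$ the residual is empty and the model refuses to run
  (`ls_saturation_error`, reported with the intervention and cause). In
  [rank_missed_opportunities()] a saturated intervention scores zero with
  a warning instead of aborting the whole ranking.

Multipliers from different interventions on the same cause combine as an
independence product. The affected fraction is the modeller's guard
against double counting: two interventions that can each avert the same
deaths should not both carry $AF = 1$.

### Indirect effects: risk-factor mediation

A risk factor is a categorical exposure (breastfeeding practice, stunting,
anemia, ...) with an ordered state list whose *last* state is the
non-exposed reference, a baseline prevalence over states, and per-state
relative risks for the (group, cause) cells it modulates. Interventions
targeting the factor shift exposure with the same residual form: their
combined multiplier $q$ defines a shifted fraction $f = 1 - q$, and a
fraction $f$ of each harmful state's baseline prevalence moves to the
reference state. The mortality consequence is the comparative-risk ratio

$$M = \frac{\sum_s p_t(s)\,RR(s)}{\sum_s p_0(s)\,RR(s)},$$

which multiplies the affected cells alongside the direct multipliers.
Flat relative risks make $M = 1$ identically — a factor that does not
discriminate risk cannot move mortality, however much its prevalence
shifts. States without a listed RR for a cell default to RR 1; the
reference state must have RR 1 wherever it appears (validated).

### Quality-adjusted coverage

Where service contact alone does not deliver the intervention (antenatal
and childbirth care especially), coverage is quality-adjusted: effective
coverage is utilization × readiness, applied at every year *including the
baseline*, so that $c_0$ and $c_t$ live on the same scale. The
scenario-interpolated contact path plays the role of utilization. An
intervention may instead carry an explicit per-year utilization series
(measured-coverage mode, e.g. when replaying survey-measured coverage for
a modeled-vs-measured comparison); that series then *replaces* the
interpolated path, and a scenario target for the same intervention is
ignored with a log message. This resolution keeps the two coverage sources
from silently multiplying.

### Attribution

Total lives saved in a cell are $D_0 (1 - \prod_i m_i^{dir} \prod_r M_r)$.
To split that total by intervention, each intervention gets a combined
multiplier: its own direct multipliers times, for every risk factor it
feeds, a share of that factor's loss $1 - M$ split proportionally to the
feeders' own losses $1 - q_i$. The cell total is then divided
proportionally to $1 - m_i$. Two properties motivated this rule over
sequential (order-dependent) or marginal (non-conserving) attribution: it
is order-free, and it conserves the cell total exactly by construction —
the per-intervention multipliers are used only to form shares, never to
recompute the total (their product does not generally equal the true joint
multiplier when several interventions feed one risk factor; the engine's
totals always use the direct × risk product).

When no intervention moves a cell, every share is zero — nothing is
attributed out of nothing.

## Parameters that matter

| Parameter | Units / range | Default | Why |
|---|---|---|---|
| `horizon` | years ≥ 1 | profile-defined | projection length; year 0 is baseline and never altered |
| `base_rate` | group units (per 1,000 or 100,000) | — | converted to absolute deaths internally |
| `efficacy`, `affected_fraction` | proportions | — | the intervention evidence base |
| `scale_up_start/end` | year offsets, 1 ≤ start ≤ end ≤ horizon | — | linear ramp; `start == end` is a step |
| `standard_target` (ranking) | proportion | 0.9 | a conventional program coverage target; overridable |
| pregnancies | count | live births × 1.03 | a pure denominator convention for stillbirths when not supplied |

Two child age bands only (neonatal, 1–59 months) are modelled; finer bands
multiply data requirements without changing the mechanics. Denominator
units are fixed per group (maternal per 100,000 live births, the
conventional MMR denominator; stillbirths per 1,000 pregnancies; neonatal
and child per 1,000 live births) so that document values are unambiguous.

## The synthetic generator

Real country databases are proprietary-scale and irrelevant to testing the
*mechanics*, so the package ships a seeded generator
([generator_config()], [generate_profile()], [generate_scenario()]) that
emulates the shape of real inputs: cause fractions from a symmetric flat
simplex, efficacies uniform on [0.1, 0.9], affected fractions on
[0.3, 1.0], baseline coverages on [0.05, 0.8], risk-factor relative risks
log-uniform on [1, 4] with reference 1, plausible rate ranges per group.
Generation is a pure function of the seed (the caller's RNG stream is
saved and restored) and every generated profile passes full validation.

What it does *not* emulate: correlation between causes and interventions
seen in real settings, secular trends, subnational heterogeneity,
measurement error in coverage surveys. Green property tests therefore
certify the engine's mathematics — conservation, monotonicity,
order-invariance, oracle equivalence — not the realism of any particular
country's inputs.

The fixed [demo_profile()] preset anchors the 1–59-month band at 60 deaths
per 1,000 live births — the under-five scale at which a 5% proportional
reduction is 3 deaths per 1,000 ([proportional_to_absolute()]), the
arithmetic evaluators use to size mortality surveys. Every other demo
value (cause mix, the breastfeeding factor's prevalences and RRs, the four
interventions) is an illustrative invention at realistic orders of
magnitude.

## Numerical choices

* Conservation and simplex checks use a 1e-9 relative tolerance;
  attribution conservation is asserted at 1e-6 absolute in tests.
* Proportions are validated, never silently clipped, at document load and
  constructor time; the engine assumes validated inputs.
* Result tables are written with 17 significant digits so
  `load_result(save_result(x))` is lossless to double precision.
* Ranking ties break lexicographically by intervention id, making the
  ranking deterministic. Interventions already at or above the standard
  target are clamped to their baseline (zero headroom, zero score) rather
  than projected downward.
* Degenerate inputs: an empty intervention list projects zero lives saved
  and yields an empty ranking; an empty multiplier list combines to 1; an
  empty result writes a header-only table; a measured series with no
  overlapping years is an alignment error, and missing interior years are
  dropped, never interpolated.
* Test problem sizes: the brute-force oracle sweep uses 200 profiles of at
  most 3 interventions, 2 causes per group and 3 years — small enough that
  a nested-loop composition of the formulas is obviously correct and the
  whole suite runs in seconds; the monotonicity sweep samples 1,000
  single-target increases.

## Known limitations

* No herd or indirect vaccine effects; multiplier independence is a
  modelling convention, not an epidemiological claim about interactions.
* No demographic feedback: births are exogenous inputs, so family-planning
  effects on the denominator are out of scope.
* No uncertainty propagation — outputs are point projections; treat them
  as best-case, evidence-weighted expectations, not forecasts with
  intervals.
* Mortality rates frozen at baseline mean long horizons understate secular
  decline not mediated by the modelled interventions.
* The residual-product equations are this package's declared contract,
  chosen for transparency and testability; other implementations of the
  same modelling tradition need not be bit-identical.
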