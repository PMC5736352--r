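---
title: "Floral temperature patterns and bumblebee conditioning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floral temperature patterns and bumblebee conditioning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floraltherm)
```

Flowers often hold spatial structure in their surface temperature — a warm
centre against a cool periphery, a heated ring at the petal edge — and
bumblebees, which sense temperature through their antennae and tarsi, can
learn to use such within-flower *temperature patterns* as a cue to which
flowers reward. `floraltherm` implements the analysis chain for
differential-conditioning experiments probing this ability, together with a
synthetic-data generator that stands in for raw visit records, and a
thermograph module for the temperature-pattern statistics themselves.

This vignette documents the models, the generator, the numerical choices,
and the places where the design was genuinely open.

## The learning-curve model family

The response analysed is a bee's foraging success in consecutive blocks of
ten counted flower visits, transformed to the variance-stabilised arcsine
square-root scale, $y = \arcsin\sqrt{p} \in [0, \pi/2]$. For bee $n$ of a
given test group after $x$ counted visits, the full model is

$$
y_{nx} = i + l\,\ln x
  + T\,(s_t + c_t \ln x)
  + C\,(s_c + c_c \ln x)
  + b_n + r_n \ln x + \varepsilon_{nx},
$$

where

* $i$ is the initial arcsine success of the baseline (bar-rewards) group
  and $l$ its learning speed (radians per $\ln$-visit);
* $T$ and $C$ are Boolean indicators for the circle/cross-rewards group and
  the control group; $s_t, s_c$ shift the intercept and $c_t, c_c$ the
  learning speed of those groups relative to the baseline;
* $b_n \sim N(0, \sigma^2_b)$ and $r_n \sim N(0, \sigma^2_r)$ are
  independent per-bee random deviations in intercept and slope;
* $\varepsilon_{nx} \sim N(0, \sigma^2)$ is the residual.

The predictor is the natural logarithm of the visit count — conditioning
curves gain most from early experience — with an `identity` alternative
available through `model_spec(predictor_transform = )` for sensitivity
checks. The group indicators multiply the slope terms as well as the
intercept terms: the interaction terms are $T \ln x \cdot c_t$ and
$C \ln x \cdot c_c$, which is what "change in learning speed relative to
the baseline" requires.

`fit_ml()` maximises the Gaussian *marginal* likelihood: the fixed effects
are profiled out by generalised least squares and the residual variance
analytically, leaving an optimisation over at most two variance *ratios*
(bee-intercept and bee-slope variance relative to residual variance). The
ratios are optimised on the log scale, floored at $10^{-10}$ to avoid
boundary pathologies, by golden-section search (one ratio) or Nelder–Mead
from a fixed grid of four starting points (two ratios), so a fit is
deterministic given the data. ML rather than REML is used throughout:
information criteria are compared across fixed-effect structures, which
REML likelihoods do not support. In the test suite the fitter is checked
against `lme4::lmer(REML = FALSE)` (agreement in log-likelihood,
coefficients and variance components) and, with variance components
absent, against ordinary least squares to $10^{-8}$.

Model size is counted as $k =$ active fixed effects $+$ active bee variance
components $+ 1$ residual variance, the deviance is $-2\,\hat\ell$ with all
Gaussian constants included, and $\mathrm{AIC} = \mathrm{deviance} + 2k$
exactly — so for two nested fits
$\Delta\mathrm{AIC} = \Delta\mathrm{deviance} - 2\,\Delta k$, the
arithmetic that published comparison tables of this form obey.

Indicator columns for groups absent from a data set are dropped at design
time (a two-group experiment has one indicator, not two zero-padded ones),
and a rank-deficient design is an error naming the collinear columns.

## The simplification ladder

`run_ladder()` executes paired comparisons in a fixed order, starting from
the full model; at each rung the simpler model becomes the standing best
model unless its AIC exceeds the fuller model's by more than
`aic_threshold` (default 2; 6 is the stricter published alternative). The
chi-square upper-tail p-value of the deviance change (df = parameters
removed) is reported alongside, but the *decision* follows AIC.

1. **random_slopes** — drop $r_n$ (are bees heterogeneous in learning
   speed, or only in baseline success?);
2. **interactions** — drop $c_t, c_c$ (does the shape of the curve differ
   between groups?);
3. **groups** — only reached when rung 2 accepted the no-interaction
   model: drop $s_t, s_c$;
4. **learning** — drop $l$.

When rung 2 retains the interactions, rungs 3–4 are skipped and each
group's curve is tested separately with the per-group model
$y_{nx} = i + l \ln x + b_n$ against its slope-free reduction
(`per_group_learning_test()`). Dropping the $r_n$ variance component is
treated as an ordinary 1-df chi-square; no boundary (mixture) correction
is applied, matching the plain df convention of the reports this package
emulates. The ladder never compares non-nested specifications, and
`compare_models()` refuses fits that do not differ in parameter count.

Calibration, measured by the test suite rather than asserted: on
slope-free cohorts at the 12-bee design the per-group test rejects at the
nominal rate (4.5% over 1000 replicates in a side measurement; the
acceptance test checks 5% ± 2 points over 200); under a strong interaction
(pattern groups reaching near-perfect terminal discrimination, control
flat) the ladder retains the interaction terms in more than 90% of
replicates.

## The test phase

After training, bees forage on a fresh, uniformly nonrewarding array;
a landing is correct when the bee probes a flower whose pattern *had been*
rewarding (or withholds probing on the previously nonrewarding pattern).
Each bee contributes one success proportion over its 20 test landings.
`testphase_anova()` compares the arcsine success between groups by one-way
ANOVA — with one observation per bee, including bee identity as a random
factor is equivalent to the plain one-way analysis, which is what is
computed. With $g$ groups of $m$ bees the df are $(g-1,\; gm-g)$: the
canonical three-by-twelve design gives $(2, 33)$. `tukey_groups()` runs
all pairwise Tukey HSD comparisons (studentized range at the within-group
df) and assigns compact letters by insert-and-absorb: groups not
significantly different share a letter, letters ordered by descending
group mean from "a". If between-group variation is exactly zero the F
statistic is reported as 0 with p = 1 rather than 0/0.

## What the simulator emulates

`simulate_cohort()` generates visit-level records with the structure the
analysis assumes:

* **Design.** Three test groups — control, bar-rewards, circle- (small
  flowers) or cross-rewards (large) — with `bees_per_group` bees (default
  12) drawn round-robin from `n_nests` nests (default 4); 60 counted
  landings in the learning phase and 20 in the test phase.
* **Arenas.** The small-flower arena has 16 flowers (8 rewarding, 8 not);
  a probed flower stays empty until the end of the foraging bout, and
  landings on an emptied flower are not counted. The large-flower arena
  has 6 flowers, refilled and moved shortly after the bee departs; only an
  immediate return to the flower just left is uncounted. The refill latency
  is not observable in the records this emulates, so "refilled and moved
  while the bee was elsewhere" is modelled as: the bee has landed on a
  different flower in between.
* **Bouts.** Lengths are Poisson draws truncated at 1, with means 10.53
  (small) and 6.97 (large) — the observed per-bout landing means of the
  two designs. The distribution itself is a modelling choice; only the
  mean is constrained by the emulated experiments.
* **Curves.** Success is generated on the arcsine scale,
  $\theta(x) = i + l\ln x + \dots$ clamped to $[0, \pi/2]$, and mapped to
  probability by $\sin^2\theta$. The control group's generative slope is
  pinned at zero: its flowers present no pattern, so there is nothing to
  learn. Defaults: $i = \pi/4$ (chance), $l = 0.08$ for pattern groups
  (success rising from 0.5 to roughly 0.8 over 60 visits, the shape of a
  typical conditioning curve), zero intercept/slope offsets between the
  two pattern groups (learning is symmetric in which pattern rewards), and
  per-bee deviations with SDs 0.1 (intercept) and 0.02 (slope).
* **Outcomes.** Each counted landing is correct or incorrect; the probe
  flag is then derived from the landed flower's (designated) reward role,
  so that re-scoring the records reproduces the generated outcomes and the
  full scoring path is exercised end to end.
* **Block anchoring.** By default the per-visit probability is held
  constant within each 10-visit block at the value $p^\*$ solving
  $\mathrm{E}[\arcsin\sqrt{X/10}] = \theta(\text{block end})$ for
  $X \sim \mathrm{Bin}(10, p^\*)$ (a `uniroot` on the binomial
  expectation). The naive anchor $p = \sin^2\theta$ leaves a
  $\theta$-dependent transform bias of up to ~0.03 rad in the block
  estimate, which propagates into a measurable (~10%) relative bias in
  recovered slopes; the unbiased anchor makes the fitted block-level model
  correctly specified in its mean, which is the point of generating on the
  arcsine scale in the first place. `prob_anchor = "block"` and
  `"visit"` switch to the plain readings.
* **Test phase.** Landings are generated at the success level reached at
  the end of learning ($\theta$ at $x = 60$), held flat, with the unbiased
  anchor at $n = 20$. All flowers are nonrewarding; designated roles
  travel with the patterns (or, for the control group, the flower
  positions) so the scorer can apply the learned scheme.
* **Spatial bias.** `spatial_bias` (default 0) mixes location-based
  success into the outcome with weight growing linearly over the
  experiment, and tilts flower choice towards rewarding positions — the
  mechanism by which a control group in a small arena with few, seldom
  rearranged flowers can improve without any pattern cue. It is off in
  every default analysis.
* **Seeding.** One global cohort seed; each bee's stream (deviation draws,
  bout lengths, choices, outcomes) is derived deterministically from it,
  so single bees are reproducible regardless of cohort composition.

What the generator does *not* emulate: flight paths and handling times,
scent marks, inter-visit dependence beyond the depletion bookkeeping,
nest-level effects on behaviour (nest ids are recorded but do not enter
the generative model), and any drift in motivation over bouts. Passing
tests therefore certify the statistical machinery — scoring rules,
transform, fitter, ladder, ANOVA — under the model's own assumptions, not
the behavioural realism of any particular data set.

## Thermographs and the survey statistics

`generate_thermograph()` renders a circular flower as a temperature grid
plus mask: a hot and a cold plateau (defaults 33 °C / 25 °C, the
artificial-flower values; ~8 °C contrast) arranged as an edge-hot ring, a
central bar, a centre-radiating cross, a hot centre disc, or a uniform
field, blended by a logistic edge profile of configurable width (default
1 mm; the profile is a modelling choice, no measured profile constrains
it) and optionally overlaid with Gaussian measurement noise.

Two numerical choices matter here. First, the hot region is sized on the
*discrete* grid: the shape's margin field is thresholded at the value
whose exceedance count best matches the requested area fraction, so
differently shaped patterns heat the same number of pixels — the
equal-heated-area / equal-overall-temperature "no other cue" constraint
the conditioning experiments rely on. Second, patterns are rendered at a
default 10° rotation relative to the pixel axes: a bar aligned with pixel
rows can only change its heated count in steps of whole rows (several
percent of the heated area), whereas no real camera is axis-aligned with
the pattern anyway.

`within_flower_range()` is the hottest minus the coldest masked pixel —
point measurements idealised as exact pixel extrema; camera spot-size
averaging is out of scope. `survey_summary()` counts species whose range
reaches a detectability threshold (default 2 °C, *inclusive*, reading "at
least"), and reports the mean and sample (n−1) SD of the range *within*
the detectable subset. `simulate_survey()` emulates a field survey: each
species draws a pattern shape (15% patternless), a log-normal hot–cold
contrast (meanlog 0.75, sdlog 0.95 — roughly half the species clear the
2 °C threshold, and detectable contrasts average a few degrees, the regime
such surveys report), a diameter and a base temperature, and the range is
then *measured* from a rendered thermograph rather than copied from the
contrast parameter. One range value per species is taken as given;
whether a real survey would average several thermographs per species is
outside this module.

## Degenerate inputs and tie-breaks

* Proportions outside $[0, 1]$, visit counts below 1, empty masks, empty
  range lists, unknown group labels, non-nested comparisons and unordered
  landing records are errors, not warnings.
* `filter_revisits()` is idempotent, and re-applying it to simulator
  output is a no-op — the generator and the filter implement the same
  rules.
* Blocks beyond the last full window are dropped; the canonical 60/20
  totals are exact multiples, so this only affects nonstandard designs.
* A group with a single bee yields a missing SEM (with a warning), not an
  error, in figure-data summaries.
* All-equal ANOVA inputs return F = 0, p = 1.
* In `tukey_groups()` ties in group means are broken by factor level
  order; letters depend only on the pairwise significance structure, not
  on input row order.

## Problem sizes and determinism

The test suite fits models on cohorts of 6–12 bees per group (36–216
block observations), runs 100 simulated cohorts for parameter recovery,
200 replicates for the type-I calibration of the per-group test and 50
for the ladder's interaction-retention power; these sizes give
Monte-Carlo standard errors small enough for 3-SE recovery checks and
±2-point calibration bands while keeping a full run in a few minutes.
Every stochastic step — cohort simulation, survey generation, thermograph
noise — flows from explicit integer seeds, and `run_pipeline()` writes the
seed and a configuration hash into every output file header, so reruns are
byte-identical.

## Known limitations

* The Gaussian block-level model ignores the mild heteroskedasticity of
  arcsine-transformed binomial proportions near the scale ends; this is a
  property of the emulated analysis itself, and the calibration checks
  quantify its practical effect (small at the canonical design).
* The likelihood for dropping a variance component is tested against a
  plain chi-square; near the boundary this is conservative in theory, and
  no mixture correction is attempted.
* Published comparison tables of this form occasionally contain tuples
  that violate the ΔAIC/Δdeviance/df identity (a transcription hazard the
  identity makes detectable); this package reports all three quantities
  per rung precisely so the arithmetic can be checked.
* `heated_area_stats()` uses a hard temperature cut; anti-aliased
  (area-weighted) pixel accounting is not implemented.
* No radiometric file formats, emissivity correction or heat-diffusion
  physics: thermographs here are idealised temperature fields.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- run_config(seed = 1, outdir = "ft-run",
                  cohort = list(bees_per_group = 12))
res <- run_pipeline(cfg)
res$ladder$comparisons     # the simplification ladder
res$testphase              # Tukey letters per group
head(res$curve_summary)    # figure data: mean success ± SEM per block
```
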