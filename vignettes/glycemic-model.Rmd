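---
title: "Modelling glycemic index and glycemic load from macronutrients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glycemic index and glycemic load from macronutrients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyco)
```

## The model

The glycemic index (GI) of a food is the incremental blood-glucose area it
produces relative to the same mass of glucose (glucose = 100). Classical
meal-level prediction averages the table GIs of the constituent *foods*,
weighted by their glycemic-carbohydrate grams. That approach inherits two
problems: table GIs do not reflect the actual product (white bread alone
spans roughly 59–89 depending on flour and process), and non-glycemic
components — the butter on the bread — lower the meal's GI without
contributing any carbohydrate, so a carbohydrate-weighted average cannot see
them.

`glyco` instead applies the weighted-average logic to *nutrients*. For a
product with glycemic-carbohydrate amounts $x_i$ (g per 100 g) and
non-glycemic amounts $x_j$,

$$
GI \;=\; \frac{\sum_i x_i\, a_i\, GI_i}
             {\sum_i x_i \;+\; \sum_j x_j\, b_j},
$$

where

* $GI_i$ is the tabulated GI of each glycemic carbohydrate (glucose 100,
  fructose 20, sucrose 62, lactose 47, starch and maltodextrin 110, ...;
  partially glycemic sugar alcohols are included, maltitol 35 and
  xylitol 12);
* $a_i$ is an availability factor, 1 for everything except starch, for which
  it is the rapidly digestible starch (RDS) fraction — botanical origin and
  processing change how fast starch releases glucose;
* $b_j$ is an empirical GI-lowering coefficient for each non-glycemic
  nutrient (bundled defaults: β-glucan, fat and protein 0.6, soluble fiber
  0.3, insoluble fiber and ash 0.1, water 0).

The numerator is fully deterministic; the denominator's $b_j$ are the
empirical part, fitted from in-vivo GI observations. With no non-glycemic
nutrients and all $a_i = 1$ the formula reduces to the plain
carbohydrate-weighted mean, so sugar syrups and honey-like mixes are handled
with no free parameters at all. The ratio is invariant to uniform rescaling
of all amounts, which is why the g/100 g basis is a convention rather than a
constraint, and why water (with $b = 0$) is exactly neutral.

Glycemic load for a serving of $s$ grams is
$GL = GI \times (\text{glycemic carbohydrate in the serving, g}) / 100$, in
grams of glucose equivalent. Availability affects GI only — the
carbohydrate mass in the GL formula is unweighted. Whether the mass of
sugar alcohols should count toward the GL carbohydrate grams is
physiologically ambiguous; they do by default, and
`count_sugar_alcohols = FALSE` excludes them.

```{r}
predict_gi(whole_milk())
predict_gi(composition(glucose = 50, protein = 50))
```

## Meals

A meal is pooled nutrient-by-nutrient (mass-weighted) before prediction:

```{r}
cereal <- composition(sucrose = 11.8, starch = 61.2, fiber_sol = 2.4,
                      fiber_ins = 7.1, fat = 2.2, protein = 9.1,
                      starch_availability = 0.88, serving_g = 30)
meal <- combine_compositions(list(cereal, whole_milk()), c(30, 125 * 1.03))
predict_gi(meal)
```

Pooling — not GI-averaging — is the point: the milk's protein and fat enter
the denominator against the cereal's starch, so the meal's GL is below the
sum of the two separate GLs. `fao_meal_gi()` implements the classical
carbohydrate-weighted average as a comparator; it is blind to this
cross-component dilution (butter on bread leaves its prediction unchanged).
The milk volume-to-mass conversion uses 1.03 g/mL by default.

## Parameters that matter

* **Starch availability** (fraction in [0, 1], dimensionless). Resolution
  order: an explicit `starch_availability` on the composition, then a
  process preset, then 1 with a warning. The preset anchors are granola 0.65
  and extruded 0.88 — the RDS range observed across breakfast-cereal
  processes; the intermediate presets (muesli 0.70, bar 0.75, flakes 0.80)
  are this package's interpolation, ordered by how aggressively the process
  gelatinises starch, and are configurable. When an observed GI is
  available, `solve_starch_availability()` inverts the model for the
  availability instead (the inversion is exact; out-of-range solutions are
  returned with a warning because they are diagnostic, meaning no RDS
  fraction can reconcile composition and GI).
* **GI-lowering coefficients** `b` (dimensionless, ≥ 0). The bundled values
  were fitted for starch-based products; they should be re-estimated per
  product category with `calibrate_b()` when data allow. Fiber is split
  into β-glucan / soluble / insoluble because a single "fiber" nutrient
  proved too coarse once fiber types vary — the split is an indirect proxy
  for viscosity.
* **Serving size** (g): 30 g is the breakfast-cereal standard and the
  default in the file-based commands.
* **Unknown nutrients** are a hard error by default; `unknown = "inert"`
  (b = 0, with a warning) supports adapted nutrient lists.
* **Rounding**: raw GI is kept at full precision; integer display rounds
  half away from zero (62.5 → 63). A truncation mode exists because
  worked examples in the source literature are inconsistent between the two
  conventions (one truncates 51.5 to 51, another rounds 62.5 to 63).
* **Ash**: the default b = 0.1 follows the published coefficient table; a
  published milk example instead used 0 — the predictions round to the same
  integer GI of 26 either way.

## Calibration

Writing $N_p = \sum_i x_{pi} a_{pi} GI_i$ for product $p$'s numerator, the
model rearranges exactly to

$$
\frac{N_p}{GI_p} - \sum_i x_{pi} \;=\; \sum_j x_{pj}\, b_j ,
$$

a linear regression through the origin (the model has no intercept) of a
computable response on the lowering-nutrient amounts. Nutrients held fixed
keep their table $b$ and are subtracted from the response. Because the
measurement noise sits on $GI_p$, the linearized response is
heteroscedastic with SD approximately $(N_p/GI_p^2)\,\sigma$; the default
fit therefore uses variance-stabilizing weights $(GI_p^2/N_p)^2$.
`weights = "none"` gives the plain unweighted fit and
`method = "nonlinear"` refits by least squares on GI itself
(quasi-Newton from the linearized solution). All variants coincide on
noiseless data; on noisy data the weighted and nonlinear fits are markedly
more efficient for the small-amount nutrients. Negative estimates are
reported with a warning, never clipped — clipping would hide an
ill-conditioned design. Rank deficiency is detected on the scaled design at
a relative singular-value tolerance of 1e-10 and reported with the aliased
nutrient names. Observations with $GI_p \le 0$ are refused rather than
silently dropped.

```{r}
panel <- generate_panel(60, noise_sd = 0, seed = 1)
calibrate_b(panel)
```

## What the synthetic panels emulate — and what they do not

The empirical coefficients in the source work were fitted on a
heterogeneous proprietary set of 60 in-vivo studies spanning infant
cereals, cereal bars, biscuits and dairy beverages, with GI ranging from
about 15 to 95 and a typical in-vivo standard error of 3.5 GI points. That
dataset is not public, so `generate_panel()` emulates its *statistical
shape*: compositions drawn uniformly and independently per nutrient over
category-spanning ranges (sucrose 0–60, starch 0–75, lactose 0–10, soluble
fiber 0–8, insoluble fiber 0–15, fat 0–30, protein 0–25 g/100 g — chosen
once to cover the named product categories; the resulting true GIs span
roughly 20–95), starch availability uniform on [0.65, 0.88], and additive
Gaussian GI noise with SD 3.5. Amounts are deliberately not renormalised to
100 g: the model is scale-invariant and water absorbs the remainder.
`benchmark_ranges()` provides the narrower 42-cereal bounds for
cereal-only panels.

Real data differ in ways the generator does not capture: nutrient amounts
co-vary within recipes (soluble and insoluble fiber are strongly
correlated in practice, which worsens identifiability), noise is not
exactly Gaussian nor homoscedastic across studies, and products with
unusual ingredients (nuts, quinoa, cocoa — rich in specific fat types and
polyphenols) deviate from the model systematically, as the three
Bland–Altman outliers in the bundled benchmark show. Passing
parameter-recovery tests on these panels therefore demonstrates that the
estimator is correct and efficient under the model's own assumptions, not
that real calibrations will reach the same precision.

A sampling fact worth knowing: at n = 60 products and noise SD 3.5, the
soluble-fiber coefficient is intrinsically hard to pin down — its amounts
rarely exceed 8 g/100 g, and even an efficient estimator has a sampling SD
near 0.2 on that coefficient (the information bound, not an implementation
limit). Fat and protein, with larger and more variable amounts, are
recovered several times more precisely. Tests at n of 20, 60 and 200
check that estimates concentrate as panels grow.

## Validation statistics

`agreement_report()` computes Pearson r, means and sample (n−1) SDs of
both vectors, the median absolute residual (mid-point convention for even
n), and Bland–Altman limits of agreement at mean ± 2 SD of the per-item
differences. Differences are taken as observed − predicted, so an
under-predicted product sits above zero. The multiplier is literally 2 by
default (`sd_multiplier = 1.96` gives the classical 95% limits). Points
strictly outside the limits are listed as outliers.

On the bundled 42-cereal benchmark (30 g servings), the report reproduces
the published summary: median |GI residual| 2.0, median |GL residual|
0.40 g, observed GI mean 68 / SD 9.2, GL correlation 0.96, and exactly
three Bland–Altman outliers (P04, P29, P32 — the inclusion-rich products,
off by 9–11 GI points). The GI correlation computed from the *printed*
columns is 0.894: the published 0.90 was evidently computed on unrounded
predictions, which the table does not carry. Problem sizes throughout the
test suite are those of the study itself (42 benchmark products; panels of
20–200 with 15 replicate seeds for the consistency checks) — large enough
to exercise every statistic at its published precision.

## Known limitations

Starch digestibility is a single global factor regardless of mechanism;
ingredient effects on enzyme access (particle size, format, specific
inclusions) are out of scope. All GI-lowering nutrients act through one
dilution mechanism — insulinogenic amino-acid effects, viscosity and
gastric-emptying differences are not separately modelled, so `b` values
are category-specific in practice. No incremental-AUC computation from
blood-glucose curves is provided: the model starts from tabulated GIs and
composition, and ends at predicted GI/GL.
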