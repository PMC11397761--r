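---
title: "Assessing the macronutrient adequacy of emergency food baskets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the macronutrient adequacy of emergency food baskets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(canasta)
```

## The problem

Emergency food assistance is often delivered as a *basic family basket*: a
fixed set of foods a municipality buys and hands to vulnerable households.
Whether such a basket is nutritionally balanced can be judged without any
intake survey, because the basket itself is the exposure: convert each
food's mass to energy and macronutrients, express each macronutrient as a
share of total energy, and compare those shares with an Acceptable
Macronutrient Distribution Range (AMDR). `canasta` implements that
evaluation for registries shaped like Peru's COVID-19 municipal basket
reports, together with the sampling design and nonparametric comparisons
such a study uses.

## Model and procedure

**Energy accounting.** For a basket with total protein $P$, fat $F$ and
carbohydrate $C$ (grams, summed over all foods without exclusion), energy
is the Atwater sum $E = 4P + 9F + 4C$ kcal, and the caloric distribution is

$$\text{pct}_m = 100 \cdot \frac{k_m \, g_m}{E}, \qquad k = (4, 9, 4).$$

Using the Atwater sum as the denominator (rather than the composition
table's energy column, which reflects heats of combustion and other
conventions) makes the three percentages sum to exactly 100 for every
basket — a property the classification depends on. The table's energy
column is still accumulated and reported per basket
(`table_energy_kcal`) so the two conventions can be compared; published
stratified medians need not sum to 100 either way, because medians of
components are not the median of a composition.

**Classification.** An AMDR standard assigns each macronutrient a
$[\text{low}, \text{high}]$ band in percent of energy. A value strictly
below the band is a *deficit*, strictly above is an *excess*, and the
bounds themselves are *adequate*: the published cutpoints are strict
inequalities (e.g. protein deficit $<10\%$, fat excess $>25\%$), so ties
at a bound fall inside. A basket is *overall adequate* when all three
macronutrients are adequate. Protein excess ($>15\%$) is implemented even
though it is rarely observed in cereal-based baskets; the label set must
be complete. The two bundled standards are INCAP (protein 10–15, fat
20–25, carbohydrate 60–70) and INDECI (protein 10–15, fat 20–35,
carbohydrate 50–65); INCAP's fat band nests inside INDECI's and the
protein bands coincide, which the tests assert as invariants. Standards
live in JSON (`amdr_standards.json`) so further AMDRs can be added
without code changes.

**Ingest.** One basket represents each municipality: the variant
distributed to the most beneficiaries, ties broken by the smallest basket
id so selection is order-independent. Items registered in "units" without
a weight are converted through market prices:
$\text{mass} = q \cdot \text{unit price} / \bar{p}$, with $\bar{p}$ the
mean of wholesale and retail prices per kg — the same approximation the
original data cleaning applied, and flagged per item
(`weight_approximated`) so its prevalence can be audited. Free-text food
names resolve to composition codes by exact normalized match first
(lowercase, accents stripped, punctuation and whitespace collapsed), then
by a token-set edit-distance similarity restricted to the hinted food
group, with a floor of 0.6 and ties broken by the smallest code. The
token-set form scores "canned tuna in oil" high against "canned fish" —
the canonical case, since canned fish varieties dominate both weight and
similarity approximations in this kind of registry — while unrelated
names stay below the floor.

**Inclusion/exclusion.** A basket is analyzed when at least three distinct
foods resolve, no single item exceeds the per-item ceiling, the basket
total stays under the basket ceiling, and at most 20% of its items are
unresolvable. Reasons are machine-readable (`unresolved_items` is checked
first, then `too_few_foods`, then `extreme_value`) and kept/excluded
always partition the input, which the pipeline manifest asserts as flow
conservation.

**Sampling design and tests.** `sample_size_fpc()` is the standard
finite-population calculation $n_0 = z^2 p (1-p) / d^2$,
$n = \lceil n_0 / (1 + (n_0 - 1)/N) \rceil$; on a frame of 1874
municipalities at $p = 0.5$, 95% confidence ($z = 1.96$) and $d = 0.05$
it gives 319, and a 30% loss allowance (rounded half up) gives 415 —
the worked numbers of the design this package mirrors. Group contrasts
use Kruskal–Wallis (tie-corrected, $\chi^2_{k-1}$ reference) followed by
Dunn's all-pairs $z$ tests on mean ranks with Holm adjustment by default,
displayed as compact letters (insert-and-absorb). The original analysis
names "Dunnett's test" after Kruskal–Wallis, but Dunnett compares
against a control while the published tables show all-pairs letter
groupings; all-pairs Dunn comparisons are the procedure consistent with
that output, and the naming discrepancy is deliberate here.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `item_ceiling_kg` | 100 | kg/item | "excessive quantity" screen; generous, every exclusion is logged |
| `basket_ceiling_kg` | 500 | kg/basket | same screen at basket level |
| `max_unresolved_frac` | 0.2 | — | basket dropped when more than 20% of items cannot be resolved |
| `similarity_floor` | 0.6 | — | below it a name is unresolved rather than guessed |
| `densities` | 1 g/mL | g/mL | volumes convert at unit density; per-group overrides available |
| `alpha` | 0.05 | — | significance level for all group comparisons |

Quartiles use linear interpolation (`stats::quantile` type 7) throughout;
other software's default differs only in how the quartile between order
statistics is interpolated, which is negligible at these sample sizes but
is fixed here for reproducibility.

## What the generator emulates

`generator_config()` defaults encode the study conditions: a frame of
1874 municipalities over four geographic domains (weights 0.05 / 0.25 /
0.50 / 0.20 for Metropolitan Lima, rest of the coast, highlands, jungle —
highlands dominate Peruvian municipality counts) and four budget groups
(uniform, since the real joint distribution is unpublished); 53% of
municipalities with 2–3 basket variants; ~10% of item rows as "unit"
records allocated so that 52.2% of them fall in meats; 2% of baskets with
an extreme error (the basket's largest item recorded 1000-fold, a kg-for-g
staple typo, which guarantees the error trips the ceilings so truth labels
round-trip).

Group quantities are log-normal. Per basket and core group $g$:

$$\log q_{g} = \log m_g + s_{d(g)} + s_{b(g)} + \sigma_0 Z_{\text{basket}}
  + \sigma_g Z_{g},$$

where $m_g$ are the configured national medians (defaults: sugar 5.0,
meats 0.7, cereals 13.1, oils 2.0, dairy 1.6, legumes 2.0 — kg, oils in
L), $\sigma_0 = 0.25$ is a shared basket-size factor (it cancels from
caloric percentages), and $\sigma_g$ is solved from the published
stratified IQRs via $\log(q_3/q_1) = 2 \cdot 0.6745 \, \sigma$ with a
0.10 floor. Domain and budget shifts $s$ are log-ratios of published
stratum medians to the national medians, *median-centered*: for each
group the offset $c$ solving
$\sum_i w_i \Phi((c - s_i)/\sigma_{\text{tot}}) = 1/2$ is subtracted, so
the configured national medians are the medians of the generated mixture
(mean-centering would bias them, noticeably for sugar, whose stratum
ratios are strongly asymmetric). Each group's mass splits across a fixed
menu (rice-led cereals, canned-fish-led meats, and so on); minor groups
(fruits, eggs, vegetables, tubers) appear in 15% of baskets with ~1–2 kg,
matching registries where their medians are zero. Unit records carry a
per-unit price backed out of the market price table, so weight
approximation recovers the drawn mass exactly and injected records are
identifiable only via the truth sidecar.

What the generator does **not** emulate: price econometrics, seasonal or
supplier structure, correlated food choices beyond the fixed menus, the
real (unpublished) domain-by-budget joint distribution, or name
misspellings — registry names always match the composition table, so the
similarity path is exercised by tests rather than by generated data.
Passing recovery tests therefore shows the pipeline is faithful to this
generative structure, not that it would be unbiased on the real registry.

## Verification choices and problem sizes

- Classification is checked against a brute-force re-implementation of
  the cutpoint inequalities on the full 0.5-step grid of percent triples
  summing to 100 (~20,000 cases per standard).
- Quantity-median recovery runs the full pipeline (errors on) on a
  366-municipality registry and asks each core-group median to land
  within ±10% of its configured target; caloric-distribution medians are
  checked on 1000 municipalities with errors off, within ±0.5 percentage
  points of an *independent* oracle that simulates the configured
  distributions directly (60,000 draws) without touching the registry or
  pipeline code paths.
- Kruskal–Wallis size is calibrated under a 4-group null (25
  observations per group, 5000 replicates) against the nominal 5% level.
- Degenerate inputs are defined, not crashed: all-identical samples give
  $H = 0, p = 1$; zero-energy baskets raise a flagged error instead of
  silently producing a 0/0 distribution; an empty registry or an
  analysis set emptied by exclusion yields an explicit "no baskets
  survived" report; a single-stratum comparison reports medians with no
  test.

## Limitations

- The bundled composition table is a synthetic 40-food stand-in
  transcribed from public references; per-basket kcal totals depend on
  it and should not be read as estimates for any real program.
- The evaluation is of the basket *as delivered*: no per-capita or
  per-day scaling, no requirement coverage, no micronutrients.
- Population-expanded counts require externally supplied expansion
  weights ($N_h/n_h$); none are bundled because the original weights are
  not published, so `adequacy_summary()` defaults to sample proportions.
- Normality pre-checks are omitted by design; the pipeline is
  nonparametric throughout.
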