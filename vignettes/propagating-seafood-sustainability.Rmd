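---
title: "Propagating fisheries-management scores through the seafood trade network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating fisheries-management scores through the seafood trade network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seatrace)
library(dplyr)
```

## The problem

A country's seafood *production* sustainability is commonly proxied by the
Fisheries Management Index (FMI), a 0–1 expert-survey score of national
fisheries research, management, enforcement and socioeconomics. What a
country *consumes*, however, is a mixture of its own production and imports
sourced through a global trade network, so consumption is governed by other
countries' management as much as by its own. `seatrace` estimates the
sustainability of consumption (`FMI_C`) per country from production scores
(`FMI_P`) and bilateral trade flows, and quantifies the disparity between
the two.

The central obstacle is provenance: when imported product is processed and
exported again, customs records attribute it to the processing country, not
the harvesting country. Three quantities are therefore unobservable — the
domestic share of consumption, the domestic share of each partner's
exports, and the origin of re-exported product — and the model handles each
with an explicit, replaceable assumption.

## The model

Everything is computed per ISSCAAP product group, pooling quantities over
the analysis year window (default 2012–2017), then aggregated.

**Consumption identity.** From the food-balance sheet,
`C = P + I − E` (tonnes live weight). Reported sheets can have
`E > P + I`; we floor the result at zero with a logged warning so
aggregation weights stay non-negative.

**Consumption blend.** For reporter *r*,

```
FMI_C,r = pPC_r · FMI_P,r + (1 − pPC_r) · FMI_I,r
```

where `pPC_r` is the domestic share of consumption. Three *derivations*
bracket the unobservable `pPC`:

| derivation | `pPC` | rationale |
|---|---|---|
| proportional | `P/(P+I)` per country × group | consumption drawn proportionally from supply |
| gephart | 0.365 everywhere | US-based estimate that corrects for re-exports |
| guillen | 0.74 everywhere | global multi-region input–output estimate |

The headline `FMI_C` is the unweighted mean of the three aggregate
derivations, with their min–max range retained as an uncertainty band.

**Import mix.** For each partner *j* with import share `pI_rj` (live-weight
trade shares — only *relative* shares are used, because the two data
sources disagree in magnitude),

```
FMI_I,r = Σ_j pI_rj · ( pPE_j · FMI_P,j + pIE_j · FMI_glbl )
```

`pPE_j = P_j/(P_j+I_j)` is the assumed own-production share of partner
*j*'s exports (proportionality assumption, computed from balance-sheet
quantities); the complementary `pIE_j` share is untraceable re-export and
is regularized to `FMI_glbl`, the production-share-weighted mean FMI of all
producers of the group. Every step is a convex combination, so all outputs
stay inside the range of the `FMI_P` values that enter them, and raising
any partner's score can only raise downstream scores.

**Disparity.** `percent_change = (FMI_P − mean FMI_C)/FMI_P × 100`;
positive values flag countries consuming below their production standard.
The shipped worked example (`worked_example_fmi()`) applies this to
published score pairs for the 25 largest producers and reproduces the
reported disparities (USA ≈ 20.4%, Iceland ≈ 7.3%, Norway ≈ 6.9%) up to
rounding of the three-decimal inputs.

## Gap-filling missing FMI

Countries without a released score are filled by OLS of
`fmi ~ spi + geo_region` (Social Progress Index, 0–100, plus treatment-coded
region offsets) fitted on the released countries — the same structure used
to extend FMI coverage in global ocean-health assessments. Predictions are
clamped to [0, 1]: the index is defined on that interval, and we prefer a
logged clamp to an out-of-range score (with a single training region the
region term folds into the intercept). A country missing SPI, or in a
region with no training observation, is a hard error: such cases must be
resolved explicitly in the harmonization table, never silently imputed.
Aggregate trade partners (customs unions, territories) are scored as the
unweighted mean of their members, a singleton member list encoding "most
closely related country".

## What the synthetic world emulates

Licensed bilateral trade data cannot be redistributed, so the package
ships a provenance-tracked generator (`generate_world()`) whose defaults
define the validation conditions:

* a closed economy — every consumed tonne was produced somewhere, so
  `C + E = P + I` holds exactly and a complete origin ledger exists;
* heavy-tailed production volumes (log-normal, sdlog 1.3);
* three country roles: *exporters* sell only their own production,
  *importers* do not export, and *processing hubs* import and re-export
  75% of their inflow under their own flag — the published estimate of the
  re-export share for the largest processing nation. Hubs consume their
  own production; their exports are pure re-export. This two-tier chain is
  the simplest structure that reproduces the provenance ambiguity, and it
  makes zero re-export a sharp reference point: with
  `reexport_fraction = 0` no country both imports and exports, so
  `pPC = P/(P+I)` and `pPE = 1` are exact and the proportional derivation
  must equal the ledger ground truth to machine precision — a property the
  test suite verifies over 20 seeds;
* an SPI-linked FMI rule (`0.004·SPI + region offset + N(0, 0.05)`,
  clamped), with 25% of countries masked for the gap-filling path;
* per-importer multiplicative disagreement (log-normal, median 1.6×)
  between trade-record and balance-sheet magnitudes, applied to the trade
  table only — mirroring the observed direction of disagreement between
  the two real sources while leaving relative partner shares untouched;
* farmed-product labelling on 10% of flows and a 5% admixture of non-food
  records, exercising the aquaculture-exclusion and filtering rules.

What it does **not** emulate: real tonnage calibration, prices, year
trends, multi-hop processing chains deeper than two stages (configurable,
but truth is always ledger-defined), transshipment, and misreporting.
Passing tests on these worlds therefore demonstrates correctness of the
estimator mechanics and its behaviour under re-export ambiguity — not that
the fixed-share derivations are accurate for any real country.

## Numerical choices

* Weight vectors are validated to sum to 1 within 1e-9; production shares
  are renormalized only inside that tolerance, otherwise the run errors.
* Zero-import countries have `pPC` forced to 1 under *every* derivation
  (the fixed literature shares presuppose imports exist); the override is
  flagged per row.
* Cells with `P + I = 0` have no consumption basis and are omitted, with
  the omission visible as a missing row rather than a zero.
* Duplicate trade rows are summed (preserving totals); unmapped partner
  names are hard errors, since silently dropping them would bias import
  shares; ranking ties break lexicographically by country id.
* Conversion-factor precedence is longest code-prefix, then description
  keyword, then the mandatory default of 1 — an explicit, auditable
  encoding of "most closely related product" that deliberately avoids
  taxonomic inference.
* All randomness flows from one mandatory integer seed through a fixed
  iteration order (countries, then groups, then years), so every table is
  byte-identical across re-runs.

## A small worked run

```{r example}
w <- generate_world(world_config(n_countries = 10, n_groups = 3,
                                 n_hubs = 2, seed = 1))
inputs <- prepare_world_inputs(w)
res <- run_derivations(inputs$balance, inputs$trade, inputs$fmi)
disparity_table(res$summary)
fit_fmi_relationship(res$aggregates)
```

Validation against the ledger truth:

```{r truth}
truth <- true_consumption_fmi(w$ledger, w$truth$fmi) |>
  filter(product_group == "AGGREGATE")
left_join(res$summary, truth, by = "country_id") |>
  mutate(err = mean_fmi_c - fmi_true_c) |>
  select(country_id, fmi_p, mean_fmi_c, fmi_true_c, err)
```

And the estimator-bias study over re-export intensity (the validation
harness generalizing the sensitivity analysis):

```{r bias}
estimator_bias_study(
  world_config(n_countries = 12, n_groups = 3, n_hubs = 2,
               years = 2012:2013, seed = 1),
  reexport_fractions = c(0, 0.4, 0.75), seeds = 1:3
)
```

## Problem sizes used in the shipped checks

The test suite and the acceptance script validate on worlds of 3–12
countries, 1–3 product groups and 2–3 years (100 worlds for the
equation-expansion cross-check, 20 seeds each for the exactness,
conservation and monotonicity suites), and a 21-country star world for the
closed-form regression property. These sizes give machine-precision
discrimination for every property checked; the pipeline itself is
vectorized and runs comfortably at the scale of the real system
(~200 countries × 8 groups × 6 years).

## Known limitations

* The fixed-share derivations apply one country's (or the globe's)
  domestic-consumption share to all countries; they are sensitivity
  brackets, not estimates.
* `FMI_glbl` regularizes re-exports toward the global production-weighted
  mean; in worlds (or regions) where hub inflows are very unrepresentative
  of global production, residual bias remains — the bias study quantifies
  this.
* FMI is static over the year window; no year-resolved propagation.
* The gap-fill model is a two-variable OLS; it inherits whatever bias the
  SPI–FMI relationship carries for unsurveyed countries.
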