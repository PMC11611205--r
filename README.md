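# seatrace

Countries that manage their fisheries well do not necessarily *consume*
well-managed seafood: consumption is a blend of domestic production and
imports sourced through a global trade network in which processed
re-exports obscure the true country of origin. `seatrace` propagates
country-level Fisheries Management Index scores (FMI, a 0–1 proxy for
production sustainability, `FMI_P`) through bilateral trade flows to
estimate the sustainability of each country's seafood *consumption*
(`FMI_C`), and quantifies the production-versus-consumption disparity.
It is written for fisheries and food-systems researchers working with
food-balance-sheet and customs-record style data.

## The model

Per country *r* and ISSCAAP product group, with quantities pooled over the
analysis window (default 2012–2017):

```
C = P + I − E                                       (consumption identity)
FMI_C,r = pPC_r · FMI_P,r + (1 − pPC_r) · FMI_I,r   (consumption blend)
FMI_I,r = Σ_j pI_rj ( pPE_j FMI_P,j + pIE_j FMI_glbl )   (import mix)
FMI_glbl = Σ_k pPglbl_k FMI_P,k                     (re-export regularizer)
```

- `pI_rj` — partner *j*'s share of *r*'s live-weight imports (relative
  shares only; the trade-record and balance-sheet sources disagree in
  magnitude).
- `pPE_j = P_j/(P_j+I_j)` — assumed own-production share of partner
  exports; the remainder is untraceable re-export, scored at the global
  production-weighted mean `FMI_glbl`.
- `pPC_r` — the unobservable domestic share of consumption, bracketed by
  three derivations: **proportional** (`P/(P+I)`), **gephart** (0.365
  everywhere) and **guillen** (0.74 everywhere). The headline `FMI_C` is
  their mean; their spread is the uncertainty band.
- Disparity: `percent_change = (FMI_P − mean FMI_C)/FMI_P × 100`.

Countries without a released FMI are gap-filled by OLS on the Social
Progress Index with geo-region offsets; aggregate partners (e.g. customs
unions) get unweighted member means. Because real bilateral trade data are
licensed, the package ships a provenance-tracked synthetic world generator
(closed economy, heavy-tailed volumes, processing hubs that re-export 75%
of inflow under their own flag) whose origin ledger provides exact ground
truth for estimator validation.

## Worked example

The shipped reference table carries published production / consumption
score pairs for the 25 largest seafood producers:

```r
library(seatrace)
ref <- worked_example_fmi()
pc  <- percent_change(ref$fmi_p, ref$mean_fmi_c)
head(tibble::tibble(country = ref$country, fmi_p = ref$fmi_p,
                    mean_fmi_c = ref$mean_fmi_c,
                    percent_change = round(pc, 2)), 3)
#> # A tibble: 3 × 4
#>   country                  fmi_p mean_fmi_c percent_change
#>   <chr>                    <dbl>      <dbl>          <dbl>
#> 1 United States of America 0.932      0.742          20.4
#> 2 Iceland                  0.929      0.861           7.32
#> 3 Norway                   0.865      0.805           6.94
```

The USA produces at `FMI_P = 0.932` but consumes at `0.742` — a 20.4%
drop, the largest disparity among the top producers; Iceland and Norway,
with comparable production scores, lose far less by trading.

A full synthetic run, from generation to disparity and regression:

```r
w      <- generate_world(world_config(n_countries = 10, n_groups = 3,
                                      n_hubs = 2, seed = 1))
inputs <- prepare_world_inputs(w)   # filter, convert, classify, gap-fill
res    <- run_derivations(inputs$balance, inputs$trade, inputs$fmi)
disparity_table(res$summary)
#> # A tibble: 10 × 6
#>    country_id fmi_p mean_fmi_c min_fmi_c max_fmi_c percent_change
#>  1 C07        0.657      0.657     0.657     0.657         0
#>  2 C04        0.654      0.596     0.559     0.615         8.86
#>  3 C06        0.651      0.651     0.651     0.651         0
#>  4 C09        0.630      0.587     0.567     0.604         6.74
#>  ...
#> 10 C02        0.256      0.341     0.296     0.408       -33.2
```

High-FMI importers (C04, C09) consume below their production standard
(positive percent change); low-FMI importers gain by importing
better-managed product; autarkic countries (C07, C06) sit exactly at
their own score. `fit_fmi_relationship(res$aggregates)` regresses
`FMI_C` on `FMI_P` per derivation; `true_consumption_fmi(w$ledger,
w$truth$fmi)` gives the ledger ground truth the estimates are validated
against, and `estimator_bias_study()` maps estimator error as a function
of re-export intensity. `run_full_analysis()` writes the complete report
bundle (disparity, regression, trade rankings, partner breakdowns,
manifest) in core and aquaculture-exclusion modes.

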