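# osteocea

A lifetime cohort Markov model for the cost-effectiveness of osteoporosis
treatments in elderly men, from a US payer perspective. The package
compares denosumab with generic alendronate, risedronate, ibandronate,
zoledronate and teriparatide for a cohort of 78-year-old osteoporotic men
(23% with a prevalent vertebral fracture), simulated in 6-month cycles to
age 110.

It is written for health-economics researchers and modellers who need a
tested, config-driven reimplementation of this model family: every
parameter lives in a YAML + CSV configuration, placeholder inputs are
explicitly flagged, and the engine, accounting and sensitivity layers are
covered by property-based tests.

## The model in brief

* **States**: `well`; per fracture site (hip, clinical vertebral,
  nonhip-nonvertebral) a two-cycle first-year tunnel and a post-fracture
  state; absorbing `dead` — 11 states. The hierarchy forbids milder
  fractures after a worse one (post-hip patients can only refracture at
  the hip; vertebral patients at hip or spine).
* **Transitions**: annual incidence and life-table mortality converted to
  6-month probabilities via 1 − (1 − p)^(1/2); death assigned first,
  fracture probabilities scaled by cycle survival; post-fracture mortality
  relative risks by state (first year vs later).
* **Treatment**: site-specific fracture relative risks while on treatment;
  persistence via six 6-month discontinuation probabilities with a
  proportional-hazards adjustment (HR 0.5) for injectables; after stopping,
  efficacy wanes linearly over an offset capped at time on treatment.
* **Outcomes**: discounted (3%/yr) lifetime costs by component (drug,
  administration + monitoring, first-year fracture, subsequent hip,
  long-term care), QALYs from age-specific baseline utilities times
  fracture-state multipliers, LYs, and 10-year fracture risks.
* **CEA**: strategies ranked by cost; dominated strategies pruned;
  successive ICERs (incremental cost per QALY gained); net monetary
  benefit; one-way DSA (±25%), scenario presets, probabilistic SA with
  cost-effectiveness acceptability curves.

## Worked example

```r
library(osteocea)

cfg <- default_config()     # packaged base case (YAML + CSV under inst/extdata)
cea <- run_cea(cfg)
print(cea$frontier)
```

```
            strategy   cost    lys  qalys      status icer_per_qaly
 generic_alendronate  $8207 7.0821 5.3024   reference          ref.
         ibandronate $11444 7.0725 5.2923   dominated     dominated
         risedronate $11826 7.0768 5.2969   dominated     dominated
         zoledronate $11915 7.0889 5.3091 on_frontier       $558200
           denosumab $12154 7.1047 5.3255 on_frontier        $14500
        teriparatide $27179 7.0945 5.3159   dominated     dominated
```

Reading this: under the packaged inputs generic alendronate is the cheapest
strategy and denosumab yields the most QALYs (5.3255 discounted QALYs,
7.1047 discounted life-years); ibandronate, risedronate and teriparatide
cost more and deliver fewer QALYs than a cheaper comparator and are
dominated. Zoledronate survives simple dominance but is flagged as
extendedly dominated (its ICER of ~$558,200/QALY exceeds denosumab's next
step of ~$14,500/QALY). Absolute cost levels depend on clearly flagged
placeholder fixtures (life table, persistence tail, post-fracture mortality
RRs, baseline utilities, long-term-care admission fraction — see the
methods vignette), so comparisons, not absolute totals, are the meaningful
output here.

Frontier arithmetic on the published base-case totals, which ship with the
package as a reference table:

```r
ft <- frontier(load_reference_totals())
ft[ft$strategy == "denosumab", c("inc_cost", "inc_qalys", "icer_qaly")]
#>   inc_cost inc_qalys icer_qaly
#> 2      878     0.052  16884.62
round_icer(16884.62)   # display convention: nearest $100
#> [1] 16900
```

So denosumab costs $878 more than generic alendronate over a lifetime,
gains 0.052 QALYs, and its ICER is $16,900 per QALY gained after
nearest-$100 rounding — far below a $100,000/QALY willingness to pay.

Persistence machinery (one-year denosumab persistence from the oral
discontinuation schedule and the HR 0.5 transform):

```r
one_year_persistence(cfg$strategies$denosumab, cfg$persistence)
#> [1] 0.7360706
```

Sensitivity analysis:

```r
tor  <- one_way_dsa(cfg)                       # tornado table
psa1 <- psa(cfg, n_draws = 200, seed = 42)     # probabilistic draws
cc   <- ceac(psa1)                             # acceptability curves
```

A thin command-line wrapper over the same functions ships at
`inst/cli/osteocea.R`:

```sh
Rscript inst/cli/osteocea.R run --out results_dir
Rscript inst/cli/osteocea.R psa --draws 200 --seed 42 --out results_dir
Rscript inst/cli/osteocea.R fixtures --out fixtures_dir --seed 1
```

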