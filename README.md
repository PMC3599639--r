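# adhereCEA

Cost-effectiveness and cost-utility modelling for a one-hour,
computer-delivered health-literacy intervention that improves
antiretroviral medication adherence in people treated for HIV. The package
is aimed at health-economics analysts who want a tested, reusable version
of this decision model: every cost ledger, the health-state model and the
QALY layer are ordinary R functions operating on small delimited-text
parameter tables, so each assumption can be inspected, overridden and
swept. All currency is 2012 USD; the perspective is societal.

## The model

Disease severity is stratified into five CD4-count states (<50, 50–199,
200–349, 350–499, ≥500 cells/mm³), each with an annual non-antiretroviral
care cost `c_i` and a utility `u_i`. An effectiveness scenario assigns each
stratum a probability `p_i` of moving one state up in response to the
intervention (no worsening transitions). The per-capita effects are the
probability-weighted deltas averaged over the four transitions:

    ΔC = (1/4) Σ p_i (c_i − c_{i+1})      [USD per person-year]
    ΔU = (1/4) Σ p_i (u_{i+1} − u_i)      [utility per person-year]

For `n` users and an effect duration `d` (years):

    net cost = development + deployment + medication increase
               (+ lost wages, web mode) − n·ΔC·d − return-to-work benefit
    QALYs    = n · ΔU · d
    ICER     = net cost / QALYs,  judged against $50,000/QALY

Development costs apply a 44.8% administrative rate on direct costs;
deployment is ledgered semiannually for a clinic kiosk (540 or 1,620
users/6 months) or a web application; medication consumption rises with
adherence ($22,675/person-year at full adherence × 10% gain × the
scenario's unrounded mean probability); 15% of health responders return to
full-time work. A threshold solver finds the development-cost multiplier
at which the ICER hits the benchmark, and `run_sweep()` crosses scenarios,
deployments, durations (1–12 months) and cost multipliers. A seeded
synthetic-cohort generator (`generate_cohort()`) supplies patient-level
inputs for testing every stage. See the methods vignette
(`vignettes/cost-utility-model.Rmd`) for the calibration story and known
errata in the source tables.

## Worked example

```r
library(adhereCEA)

res <- cea_run("kiosk", "low", "moderately", duration_months = 6,
               mode = "replication")
res[, c("net_cost", "cost_per_user", "qalys", "cost_per_qaly",
        "threshold_dev_multiplier")]
#>   net_cost cost_per_user qalys cost_per_qaly threshold_dev_multiplier
#> 1 124094.4           230  3.78       32829.2                 1.218971

format_usd(res$cost_per_qaly)
#> [1] "$32,829"
```

Read: deploying the intervention as a clinic kiosk to 540 users over six
months under moderate effectiveness costs $124,094 net (development
$296,411 + deployment $32,507 + extra medication $30,611, minus $152,861
in avoided care costs and $82,575 in regained wages), buys 3.78 QALYs, and
therefore costs about $32,829 per QALY — cost-effective at the $50,000
benchmark, with headroom for development costs to grow to ~122% before
crossing it. Under high effectiveness the same deployment is net-saving
(`format_usd()` renders savings in parentheses, e.g. `($59,443)`).

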