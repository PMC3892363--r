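# mesoflux

Chamber-based carbon flux estimation and mesocosm carbon-budget closure.

## What this is for

Automated closed dynamic chambers (paired transparent NEE and opaque
respiration chambers over sown grass mesocosms) promise something rare in
ecosystem science: a carbon balance you can check. `mesoflux` implements the
full analysis chain for such an experiment and validates it end to end on a
forward simulator with enforced carbon mass conservation:

* **Trace → flux**: OLS slope of 1 Hz CO2 over the calculation window
  (20 s dead band + 90 s for transparent chambers, 50 s + 90 s for opaque
  ones), converted with the ideal-gas closed-chamber equation
  `F = m·PV/(RTA)`; explicit fit failures, night/rain/poor-fit QC flags.
* **Lid light correction**: lid PAR transmission τ from a through-origin
  regression of inside on outside PAR; logarithmic NEE light response
  `uptake = a·ln(PAR) + c`; correction offset
  `Δ = f(PAR/τ) − f(PAR) = a·ln(1/τ)` (constant in PAR for the log form)
  added to daytime NEE from the net-uptake onset.
* **Respiration analysis**: temperature-driver selection, stage-wise
  exponential fits `R = a·e^(bT)` with `Q10 = e^(10b)` and delta-method
  errors, day/night suppression of dark respiration, GPP = Reco − NEE
  partitioning.
* **Budget closure**: cumulative hourly NEE carbon
  (`ΣF·3600·12.011e-6·A` g C) plus leached DOC versus the stock inventory
  `Stock = −(ΔC_soil + C_shoot + C_root + C_DOC − C_seed)`, compared per
  collar and per treatment (paired t, RMSE about the 1:1 line, OLS slope,
  one-way ANOVAs).
* **Synthetic mesocosm**: 12 collars in a 2×2 chamber/nutrient design,
  hourly paired closures over a winter season, logistic ryegrass growth,
  noisy traces with mixing/drawdown transients, DOC leaching events and a
  conservation-exact stock inventory — the ground truth the pipeline is
  tested against.

The repository is an analysis workflow: `analysis/01_simulate.R` …
`analysis/05_budget.R` run the stages on the default simulated study and
write their artifacts under `results/pipeline/`; every computation lives in
the package under `R/` and is unit-tested. See the methods vignette
(`vignettes/mesocosm-carbon-closure.Rmd`) for the models, assumptions and
known limitations.

## Worked example

```r
library(mesoflux)

cfg <- sim_config(rng_seed = 1)       # the default simulated study
res <- run_pipeline(cfg, "results/pipeline")
res$comparison$fit$slope              # flux-vs-stock OLS slope
```

Running the numbered analysis scripts prints, for the default seed:

```
$ Rscript analysis/05_budget.R
paired mean difference: 0.0021 +/- 0.0059 g C (t = 1.213, df = 11, p = 0.251)
RMSE about the 1:1 line: 0.0060 g C
flux ~ stock OLS: slope 0.931, intercept -0.0191, r2 0.992
...
flux balance:  -0.304 +/- 0.051 g C per mesocosm (n = 12)
stock balance: -0.306 +/- 0.054 g C per mesocosm
closure validation: 12/12 collars within tolerance
```

i.e. over the 85-day simulated season each mesocosm gained ≈ 0.30 g C, the
two independent balance estimates agree within their noise (paired p = 0.25,
slope 0.93 on the 1:1 line), and with all measurement artifacts switched off
(`noise_free(cfg, transmission = 1)`) the two balances agree to < 10⁻⁶ g C
on every collar. The respiration stage (`analysis/04_respiration.R`) prints
the stage-wise Q10 table — the pre-sowing soil-only stage refits its
generating sensitivity (Q10 ≈ 2.44 against 5 cm soil temperature) — and the
day:night respiration ratio at equal temperature (0.798 ± 0.004 for a
simulated suppression of 0.8). The correction stage reports the recovered
lid transmission (τ̂ = 0.660 for a simulated 0.66, a 34 % PAR reduction).

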