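# wormrisk

Bioaccessibility-based probabilistic health-risk assessment of
potentially toxic elements (Cd, As, Hg, Cu) in medicinal earthworms.

Dried earthworms are a common animal-derived traditional medicine, and
they bioaccumulate soil contaminants.  Risk assessments based on
*total* element concentrations overstate the absorbable dose, and
deterministic point estimates hide population variability.  `wormrisk`
addresses both: exposure is driven by the **bioaccessible** fraction
measured with a two-phase in-vitro gastrointestinal extraction (PBET),

    Bioaccessibility % = (gastric + intestinal soluble content) / total content × 100,

and uncertainty in exposure frequency (EF), ingestion rate (IR) and
concentrations (C) is propagated by seeded Monte Carlo through the
exposure/risk kernel

    EDI = EF · Ed · IR · C · BA / (AT · W)            [µg/kg/day]
    HQ  = EDI · SF · 0.001 / RfD        HI  = Σ HQ_e
    CR  = EDI · CSF · 0.001             TCR = CR_Cd + CR_As

with Ed = 20 y, AT = 365 × 70 d, W = 67.0 / 56.7 kg (male/female),
SF = 10, and IR ~ Uniform(5, 10) g/day.  Outputs are percentile tables
(min, P25, mean, P50, P75, P90, P95, P99, max), exceedance
probabilities (HI > 1, CR > 1e-6), and variance-based (Sobol) main-
and total-effect sensitivity indices of HI, estimated on a Saltelli
design built from a Joe–Kuo Sobol' low-discrepancy sequence with
Jansen estimators.

The package is aimed at food-safety / pharmacognosy risk assessors who
have per-batch total + gastric + intestinal concentration tables and
questionnaire-derived exposure factors.  A synthetic-data generator
(`generator_spec()`, `generate_samples()`, `generate_questionnaire()`)
emulates a realistic 42-batch, 20,917-respondent scenario so the whole
pipeline is runnable and testable without any external data.

## Worked example

```r
library(wormrisk)

# QA/QC: spike recovery for the ICP-MS determination
recovery_stats(c(0.95, 1.01), c(1, 1), "Cd")
#> Recovery Cd: 98.0% +/- 4.24% (n = 2)

# Full pipeline on the packaged synthetic scenario
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "out"))
print(res)
#> <pipeline_result>
#>   mean bioaccessibility (%): Cd 45.1, As 37.1, Cu 26.8, Hg 25.4
#> <risk_simulation> male, 20000 iterations, seed 1
#>   mean HI 0.456, P90 HI 1.13, P(HI > 1) = 11.6%
#> <risk_simulation> female, 20000 iterations, seed 1
#>   mean HI 0.539, P90 HI 1.33, P(HI > 1) = 13.8%
```

Mean gastrointestinal bioaccessibility ranks Cd > As > Cu > Hg: less
than half of each element's total content is actually solubilised, so
risk computed on totals would be 2–4× too high.  The mean hazard index
is below 1 (acceptable for the average consumer) but the upper tail
crosses 1 around the 90th percentile — roughly one consumer in eight
in this scenario exceeds the non-cancer threshold, driven by arsenic:

```r
s <- res$simulations$male$summary
s[s$metric %in% c("HQ_As", "HI", "TCR"), c("metric", "P25", "Mean", "P50", "P90", "P95")]
#>  metric      P25     Mean      P50      P90      P95
#>   HQ_As 5.61e-02 4.16e-01 1.58e-01 1.04e+00 1.700000
#>      HI 6.77e-02 4.56e-01 1.80e-01 1.13e+00 1.830000
#>     TCR 6.07e-06 3.35e-05 1.49e-05 8.32e-05 0.000131

rank_drivers(res$sobol$male)[1:3, 1:3]
#>  variable main_effect total_effect
#>        EF  0.62990715   0.87866060
#>      C_As  0.09625927   0.33286651
#>        IR -0.01142445   0.05274734
```

The mean TCR (~3e-5) sits well above the 1e-6 de-minimis level, so
carcinogenic co-exposure to As and Cd is a genuine concern even for
average consumers.  Sensitivity analysis ranks exposure frequency
first and bioaccessible arsenic concentration second — refining how
often people actually take the preparation, and monitoring As, are the
two most effective levers on the risk estimate.

`out/` then contains the origin summary ("Mean ± SD" per origin and
element), per-sex risk-summary and exceedance CSVs, HI/TCR draw
tables, Sobol index CSVs and figures, and a JSON manifest (seed,
iteration count, profile, draw-sharing policy, input hashes) from
which every number can be regenerated.

A thin CLI wraps the same function:

```sh
Rscript inst/scripts/wormrisk_pipeline.R --seed 1 --out-dir out
```

## Package layout

| Area | Functions |
| --- | --- |
| I/O and QC | `read_samples()`, `read_respondents()`, `recovery_stats()` |
| Bioaccessibility | `bioaccessible_content()`, `summarize_by_origin()`, `mean_bioaccessibility()` |
| Distribution fitting | `fit_dist()`, `select_best()`, `sample_dist()`, `quantile_dist()` |
| Risk kernel | `edi()`, `hq()`, `hi()`, `cr()`, `tcr()`, `tox_profile()` |
| Monte Carlo | `simulation_config()`, `run_simulation()`, `percentile()`, `exceedance()` |
| Sensitivity | `saltelli_design()`, `sobol_indices()`, `sobol_risk()`, `rank_drivers()`, `tornado_risk()` |
| Synthetic data | `generator_spec()`, `generate_samples()`, `generate_questionnaire()`, `lognormal_moment_match()` |
| Orchestration | `pipeline_config()`, `run_pipeline()` |

The methods vignette (`vignettes/bioaccessibility-risk.Rmd`) documents
the model, the calibration of the synthetic scenario, the two shipped
toxicological profiles and why they differ, and the numerical
conventions.
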