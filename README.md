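# hgbiomonitor

Mercury biomonitoring analysis for mother–infant cohorts: exceedance
classification against permissible limits, deterministic USEPA-style
exposure/risk computation, Monte Carlo uncertainty propagation,
mother–infant transfer statistics and GeoJSON export — with a calibrated
synthetic-cohort generator so the full pipeline runs without access to
raw survey data.

## The problem

Field campaigns in mercury-affected regions measure total mercury in
breastmilk, blood and urine of lactating mothers, in the urine of their
infants, and in household staple food (wheat). Public-health questions
follow a standard sequence:

1. **Exceedance** — what fraction of each matrix is above its permissible
   limit (breastmilk 1.7 µg/L, blood 20 µg/L, urine 10 µg/L, food
   100 µg/kg)?
2. **Exposure and risk** — for each receptor, the Average Daily Dose

   `ADD = C × IR × EF × ED / (BW × AT)`   [mg/kg/day]

   and the non-carcinogenic Hazard Quotient `HQ = ADD / RfD`, where `C`
   is the route concentration (wheat for the mother, breastmilk for the
   breastfed infant), `IR` the intake rate, `EF`/`ED` exposure frequency
   and duration, `BW` body weight, `AT` averaging time and `RfD` the oral
   reference dose (0.0003 mg/kg/day). `HQ > 1` flags potential risk.
3. **Uncertainty** — propagate the fitted concentration distribution
   (lognormal, with a point mass at zero for non-detects) through the HQ
   equation by seeded Monte Carlo (10,000 draws by default).
4. **Transfer** — how strongly does milk mercury predict infant (and
   maternal) urinary mercury? Simple OLS plus the fixed-factor
   general-linear-model variant, with its saturation caveat made
   explicit.
5. **Mapping** — per-sample GeoJSON point layers with exceedance flags.

Because such campaigns rarely deposit raw data, the package ships a
seeded generator whose lognormal margins are *calibrated* so that the
probability of exceeding the limit and the expected sample maximum match
the published summary counts exactly, with a Gaussian copula on the log
scale inducing the milk–urine dependence.

## Worked example

```r
library(hgbiomonitor)

# deterministic risk at the maximum measured wheat concentration
adult <- exposure_parameters("adult_mother")
add <- compute_add(44.44, "food", adult)   # 4.6529e-05 mg/kg/day
hq  <- compute_hq(add, adult$RfD)          # 0.1551

# a synthetic cohort with the study's structure
ds  <- generate_cohort(generator_config(seed = 1))
cls <- classify_exceedance(ds)
cls$summary[, c("matrix", "n_total", "n_above_limit", "exceedance_percent")]
#>        matrix n_total n_above_limit exceedance_percent
#>         blood      70            12                 17
#>    breastmilk     181           140                 77
#>   child_urine     172            80                 47
#>          food      53             0                  0
#>  mother_urine     224           110                 49

risk_table(ds)$summary[, c("receptor", "n", "HQ_max", "HQ_mean")]
#>      receptor   n  HQ_max HQ_mean
#>  adult_mother  53  0.1551 0.03406
#>        infant 172 17.5204 1.89515

mc <- run_mc(fit_concentration(ds, "breastmilk"),
             exposure_parameters("infant"), n_draws = 10000, seed = 1)
mc$HQ$mean        # 1.92
mc$prob_hq_gt_1   # 0.539
```

Reading: the mother's dietary HQ stays well below 1 even at the maximum
wheat concentration (0.1551), while the breastfed infant's HQ
distribution has most of its mass near or above 1 — the infant route
dominates. The per-seed exceedance percentages scatter binomially around
the calibrated fractions (74 % for milk); seed 1 happens to draw 77 %.

The one-command pipeline:

```r
run_pipeline(generator_config(seed = 1), "out/")
# -> cohort.csv, classification.csv, risk.csv, mc.json, stats.json,
#    layers/*.geojson, manifest.json
```

or from a shell: `Rscript inst/scripts/hgbiomonitor.R run --seed 1
--out-dir out/`.

## Documentation

See the methods vignette (`vignettes/risk-assessment-methods.Rmd`) for
the model, its assumptions, the calibration procedure, what the
generator does and does not emulate, and known limitations.
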