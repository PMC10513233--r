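# sedbouts

Quantify how daytime inactivity accumulates from wrist actigraphy, and
compare it between groups.

Wrist actigraphs integrate limb acceleration into one activity count per
1-minute epoch. An epoch with fewer than 100 counts per minute (cpm) is
*sedentary*; a maximal run of sedentary epochs is a *sedentary bout*. Total
sedentary time alone hides whether inactivity comes as many brief pauses or
a few long stretches, so this package bins bout durations into the classes
used in activity epidemiology — short (1–3, 4–5 min), medium (6–30,
31–60 min) and long (>60 min) — over the daytime window [08:00, 22:00)
(840 epochs/day), and compares the resulting per-subject features between
an acute-insomnia (AI) group and healthy controls (HC).

The statistical core:

* **Exponential dwell-time fits.** Bout-time features are modelled as
  exponential, f(x|λ) = λe^(−λx); the fitted mean is the sample mean
  (μ̂ = 1/λ̂) with exact 95% bounds from the chi-square pivot
  [2nμ̂/χ²₀.₉₇₅,₂ₙ, 2nμ̂/χ²₀.₀₂₅,₂ₙ].
* **Two-sample Kolmogorov–Smirnov tests.** D = supₓ|F_X(x) − F_Y(x)| over
  pooled values of right-continuous ECDFs, p from the asymptotic Kolmogorov
  series at λ = √(n₁n₂/(n₁+n₂))·D.
* **Logistic regression.** ln(p/(1−p)) = β₀ + Σβⱼxⱼ of the group label
  (0 = AI, 1 = HC) on the five bin features, fitted by IRLS with Wald
  standard errors and p-values; negative slopes mean more time in that bin
  lowers the probability of the healthy label.

A calibrated synthetic cohort generator (alternating renewal process with
exponential dwell times, state-conditional counts respecting the 100-cpm
partition) makes the entire pipeline runnable and testable without access
to clinical recordings. The intended users are researchers processing
epoch-level accelerometry for sedentary-behaviour epidemiology.

## Worked example

Simulate the default cohort (15 AI and 22 HC subjects, 7 days each,
starting on a Monday, ~1% missing epochs), run the full pipeline in
memory, and look at the all-days group comparison:

```r
library(sedbouts)

cohort <- simulate_cohort(rng_seed = 42)
res <- suppressWarnings(run_pipeline(run_config(), cohort = cohort))
comp <- res$comparisons[res$comparisons$day_subset == "all7",
                        c("feature", "ai_mean", "hc_mean", "ks_D", "ks_p")]
print(as.data.frame(comp), digits = 3, row.names = FALSE)
#>          feature ai_mean hc_mean  ks_D     ks_p
#>    sed_bouts_1_3    22.0  82.584 1.000 3.58e-08
#>    sed_bouts_4_5    24.4  72.468 1.000 3.58e-08
#>   sed_bouts_6_30   335.4 303.416 0.394 1.26e-01
#>  sed_bouts_31_60   112.4   7.221 1.000 3.58e-08
#>   sed_bouts_gt60    16.7   0.396 0.555 8.29e-03
#>        sed_total   510.9 466.084 0.503 2.19e-02
#>       wake_total   329.1 373.916 0.503 2.19e-02
```

Reading the rows: the AI group accumulates about 511 sedentary minutes per
daytime day against 466 for controls (the daily identity
`sed_total + wake_total = 840` holds row-wise), and the excess sits in the
medium and long bins — 112 vs 7 minutes in 31–60-minute bouts, 17 vs 0.4
in >60-minute bouts — while controls log far more time in the short 1–3
and 4–5-minute bins (frequent brief pauses rather than long sits). The
`ks_p` column gives the two-sample K-S p-value per feature; the `suppressWarnings`
wrapper silences the (deliberate) quasi-separation warning from the
37-subject logistic fit, whose convergence flag is part of the output.

With files instead of in-memory objects: `write_cohort(cohort, "data/")`
emits `manifest.csv`, one `timestamp,count` epoch CSV per subject and a
ground-truth bout JSON; `run_pipeline(run_config(manifest =
"data/manifest.csv", out_dir = "reports/"))` writes per-subject features,
daily summaries, descriptive statistics, group comparisons with 95%
bounds, the logistic coefficient table, 2-hour aggregates and a run log.
The same two steps are available from a shell via `inst/exec/sedbouts
synth|run`.

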