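# signtrack

Phenotyping humans as **sign-trackers**, **intermediates** or
**goal-trackers** from eye-tracking data collected during Pavlovian
conditioning — and testing whether the phenotype distribution differs
between the sexes.

## The problem

When a conditioned stimulus (CS) reliably predicts a reward delivered at a
different screen location, some participants' gaze dwells on the cue itself
(sign-tracking: high incentive salience attributed to the CS) while others'
gaze moves to the upcoming reward location (goal-tracking). The standard
oculomotor phenotyping statistic is the **gaze index**

```
g = (T_cs − T_reward) / (T_cs + T_reward + T_background)  ∈ [−1, 1]
```

computed from area-of-interest dwell times over the last 4 s of the CS
window (the first second is excluded to remove the orienting response),
using CS+ trials from the second half of the task. Participants are ranked
by the index and split into equal-count tertiles: top third sign-trackers,
middle third intermediates, bottom third goal-trackers. The associated
battery tests sex differences three ways: Pearson χ² on the sex × phenotype
table, a pooled-variance t-test of the index with Cohen's *d*, and a mixed
2 × 2 ANOVA (CS type within, sex between) with partial η² as an
attentional-bias control.

The package implements all of this plus a seeded synthetic cohort
generator (latent tracking trait per participant, softmax AOI emission,
orienting response, 80%-rewarded CS+ trials) so the full pipeline runs and
is testable without raw recordings. See the vignette
(`vignettes/signtrack-methods.Rmd`) for the model and every methodological
choice.

## Worked example

```r
library(signtrack)

cohort <- simulate_cohort(sim_config(seed = 7), output = "dwell")
fit <- signtrack(cohort)
fit
#> Sign-/goal-tracking phenotyping
#>   232 participants (232 classified, 0 insufficient data)
#>          sign_tracker intermediate goal_tracker
#>   female           46           40           33
#>   male             32           37           44
#>   CS+ gaze index: M = 0.598, SD = 0.376; outliers flagged: 16

summary(fit)
#> Pearson chi-squared: X2(2) = 4.05, p = 0.132
#>
#> CS+ gaze index, female vs male:
#>   t(230) = 2.02, p = 0.044, d = 0.27 (M = 0.65 vs 0.55)
#>   excluding outliers: t(214) = 2.06, p = 0.041, d = 0.28
#>
#> Mixed 2 x 2 ANOVA (unweighted means); n = 119 + 113
#>          term        SS  df       MS       F         p     pes
#>       between  1.300000   1 1.300000   4.427 3.645e-02 0.01889
#>      subjects 67.530000 230 0.293600      NA        NA      NA
#>        within  0.248800   1 0.248800 143.500 5.161e-26 0.38420
#>   interaction  0.004862   1 0.004862   2.804 9.537e-02 0.01205
#>  within_error  0.398800 230 0.001734      NA        NA      NA
```

Reading the output: this simulated cohort of 232 (119 female) shows the
expected pattern — a higher female share among sign-trackers, a
significant sex difference in the gaze index of d ≈ 0.27 (robust to
removing Tukey-flagged outliers), a CS+ > CS− main effect, and no
sex × CS interaction (i.e., the sex difference is not a general
attentional bias). The χ² on the categorical phenotype is not significant
here; at a continuous effect of d ≈ 0.3 the tertile test has roughly
coin-flip power (see the vignette).

`plot(fit)` draws the per-sex index boxplots and phenotype counts.
`run_pipeline(out_dir, ...)` writes the whole artifact set (dwell
summaries, phenotypes, flat and human-readable reports, reproducibility
manifest), and works equally on user-supplied `gaze.csv`/`trials.csv`
files — see `?run_pipeline` for the schemas, or use the CLI:

```sh
Rscript inst/cli/signtrack.R simulate --out-dir runs/demo --seed 7
Rscript inst/cli/signtrack.R analyze --out-dir runs/real \
    --gaze gaze.csv --trials trials.csv
```

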