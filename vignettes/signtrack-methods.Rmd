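---
title: "Phenotyping sign- and goal-trackers from eye-gaze dwell times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping sign- and goal-trackers from eye-gaze dwell times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The behavioural question

When a cue reliably predicts a reward, individuals split in how much
motivational value — incentive salience — they attribute to the cue itself.
In the Pavlovian conditioned-approach literature, *sign-trackers* approach
and engage the reward-predictive cue (the conditioned stimulus, CS), while
*goal-trackers* orient to the location where the reward will be delivered.
In humans this distinction can be measured oculomotorically: during CS
presentation, the eyes of a sign-tracker dwell on the CS, those of a
goal-tracker on the (still empty) reward location. Sign-tracking has been
repeatedly linked to impulsivity- and addiction-related vulnerability, and
sex differences in its prevalence are of direct translational interest.

`signtrack` implements that phenotyping pipeline end to end: per-trial
area-of-interest (AOI) dwell times, a gaze index, a rank-based tertile
classification, outlier flagging, and the statistical battery used to test
for sex differences.

## The gaze index

Each gaze sample during the CS window falls on one of three AOIs — the CS
location, the reward location, or the background. With dwell times
$T_{cs}$, $T_{rew}$, $T_{bg}$ accumulated over the analysis window, the
per-trial index is

$$ g = \frac{T_{cs} - T_{rew}}{T_{cs} + T_{rew} + T_{bg}} \in [-1, 1], $$

so $g = 1$ means the whole window was spent on the CS and $g = -1$ that it
was all spent on the reward location. Dwell time is accounted as
(sample count) × (sample period); no fixation-event parsing is attempted,
because the quantity of interest is dwell, and event detection would add
detector-specific degrees of freedom.

Three windowing rules define the classification pathway:

* the analysis window is $[1, 5)$ s from CS onset — the first second is
  excluded because stimulus onset reflexively captures gaze (the orienting
  response) regardless of phenotype;
* only CS+ trials (cue predictive of reward) enter the classification;
* only trials from the second half of each participant's sequence are used,
  when the CS-reward contingencies have been learned. "Second half" is
  defined over the participant's presentation order.

The CS− pathway (same window, second-half CS− trials) is computed alongside
as an attentional-bias control: if the index merely reflected a bias toward
the upper screen half, it would be equally present on CS− trials.

### From trials to participants

The reported index is one value per participant, but the aggregation
from trials is not uniquely determined by the definition. The default is
the unweighted mean of per-trial indices, which gives every usable trial
the same influence; the alternative (`aggregate = "pooled"`) sums dwell
across trials before forming the ratio, which weights trials by their
usable (non-missing) time. The two coincide without missing data and
diverge under unequal missingness; both are implemented and unit-tested,
and the default is the mean because it treats the trial, not the second,
as the unit of behaviour.

A trial with a zero dwell denominator (everything missing) yields `NA` and
is excluded; a trial with more than 50% of the window missing is dropped
(`max_missing`, configurable — the threshold is this package's choice, as
blink handling is rarely reported); a participant with fewer than
`min_trials = 5` usable trials is excluded from classification and
reported as such rather than silently dropped.

## Classification and outliers

Participants are ranked by CS+ index (descending) and split into
equal-count thirds: sign-trackers on top, intermediates, goal-trackers at
the bottom. Rank-based tertiles (rather than equal index-range bins)
guarantee balanced groups, matching how conditioned-approach phenotypes
are conventionally partitioned. Two tie/remainder rules make the split
total and deterministic:

* remainder 1 → the extra participant goes to the top (sign-tracker)
  tertile; remainder 2 → top and bottom. Arbitrary, but documented and
  tested (232 participants split 78/77/77).
* ties are broken by participant id in sorted order, so labels are
  invariant to row order; a tie straddling a boundary raises a warning.

Outliers are flagged per sex with the Tukey boxplot rule — outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, quartiles by
linear interpolation (type 7) — because a boxplot is what such figures
display and no explicit rule is usually reported. The flagged participants
are never removed from classification; the t-test is simply run a second
time without them.

## The statistical battery

* **Sex × phenotype:** Pearson $\chi^2 = \sum (O-E)^2/E$ on the 2 × 3
  table, $df = 2$, no continuity correction (undefined beyond 2 × 2).
* **Sex difference in the index:** pooled-variance two-sample t
  ($df = n_1 + n_2 - 2$) with Cohen's $d$ from the pooled SD. The pooled
  (not Welch) form is used because reported degrees of freedom in this
  literature are $n_1 + n_2 - 2$; with it, $d = t\sqrt{1/n_1 + 1/n_2}$
  holds as an identity, which the tests exploit.
* **Attentional-bias control:** mixed 2 × 2 ANOVA with CS type within and
  sex between subjects. The between effect is tested against subjects
  within sex; the within effect and interaction against
  CS × subjects-within-sex. With two within levels, sphericity holds
  trivially. Effect sizes are partial
  $\eta^2 = SS_{\text{effect}} / (SS_{\text{effect}} + SS_{\text{error}})$.

With unequal sex group sizes the hypothesis sums of squares are computed
by default from unweighted cell means with the harmonic mean group size
(`ss_type = "unweighted"`, a Type-III-like solution, appropriate when the
imbalance is incidental rather than meaningful). A fully additive weighted
(hierarchical) decomposition is also available; the two coincide for
balanced groups. One numerical convention: an effect with exactly zero
sum of squares reports $F = 0$ (rather than 0/0) so that degenerate inputs
— e.g. every participant's CS+ index equal to their CS− index — behave as
expected.

The implementation is validated three ways: against `aov()` with an
`Error()` stratum on balanced designs, against the exact closed forms of
the unweighted tests (each unweighted $F$ equals a pooled $t^2$ on
difference or average scores), and against exhaustive brute-force
$\sum (O-E)^2/E$ evaluation for the $\chi^2$.

## The synthetic cohort generator

No raw gaze recordings ship with the package, so a seeded generator
reproduces the task's statistical structure: interleaved CS+ and CS−
trials (20 each by default — trial counts are rarely reported, so this is
a configurable choice), 5 s CS windows sampled at 60 Hz, CS+ rewarded with
probability 0.8, CS− never, and the first half of each participant's
sequence labelled phase 1.

Each participant carries a latent tracking trait $\theta$, Gaussian per
sex with common SD — the simplest model consistent with a standardized
mean difference between sexes. Within a trial, every sample's AOI is an
independent draw from a 3-way categorical with probabilities

$$ p \propto \left( e^{\theta/2},\; e^{-\theta/2},\; w_{bg} \right), $$

so the CS-vs-reward log-odds equal $\theta$ and the index saturates at
$\pm 1$ as $\theta \to \pm\infty$. The softmax (rather than a fixed
background probability) is deliberate: with a constant background share
the index could never reach its defining anchors of $\pm 1$, which are
part of the index's published interpretation. During the first second,
samples are instead drawn with a fixed CS probability of 0.8 for everyone
— giving the orienting-response exclusion something real to remove. A
small additive trait shift on CS+ trials (`cs_effect`) models greater
engagement with the reward-predictive cue and produces the CS+ > CS−
index difference seen in real cohorts.

Randomness is split per participant: the master seed draws one sub-seed
per participant, so cohorts are byte-reproducible and participant streams
independent of generation order. The generator has two output modes:
`"samples"` emits the raw per-sample stream; `"dwell"` draws the same AOI
counts and emits per-trial dwell summaries directly. Because the sample
stream is a uniformly random arrangement of multinomially drawn counts,
the two modes are the same probability law, and under a shared seed the
dwell mode equals the dwell table computed from the sample stream exactly
— a property the unit tests assert. Monte-Carlo studies use the dwell
mode; nothing about the law changes, only the cost.

### Calibration of the defaults

The default parameters were calibrated once against the descriptive
statistics a large human conditioning cohort reports: CS+ index mean
≈ 0.6, SD ≈ 0.36, CS− mean ≈ 0.55, and a between-sex standardized
difference d ≈ 0.3 with more women among sign-trackers. With
$w_{bg} = 0.4$, trait SD 1.7, trial-level trait noise SD 0.5, sex means
2.375/1.825 and `cs_effect = 0.25`, 150-cohort simulations reproduce all
four quantities (CS+ M = 0.599, SD = 0.371, CS− M = 0.549, d = 0.303).
The calibration targeted those descriptives only, never the outcome of
any test.

### What the generator does and does not emulate

It emulates the marginal structure the analysis consumes: the task
contingencies, the orienting response, a realistic index distribution
(left-skewed, ceiling at 1) and a sex-shifted trait. It does **not**
emulate learning dynamics within the task (trait is constant across
trials), fixation durations or saccade structure (samples are
exchangeable within a trial), blinks/missing data (none are generated;
missing handling is exercised with constructed inputs), or screen
coordinates (AOI labels are emitted directly; coordinate-to-AOI
assignment is exercised separately). One consequence worth knowing:
because CS+ and CS− indices share one latent trait, their within-subject
correlation is higher than in real data, so the generator's CS main
effect is much easier to detect than a real one — fine for calibrating
test size (which is what the null studies check), not a statement about
realistic ANOVA power.

Passing tests therefore show that the pipeline is correct and calibrated
under these assumptions; they cannot show robustness to drift, blinks, or
non-Gaussian trait distributions.

## Monte-Carlo design and problem sizes

Two simulation studies back the package's claims, both run by the test
suite and by `scripts/acceptance.R`:

* **Null calibration** — 2000 cohorts of 232 participants with equal sex
  trait means and no CS effect; the rejection rate of each battery test at
  $\alpha = 0.05$ must fall inside the binomial 99% CI around 0.05.
* **Parameter recovery** — 200 cohorts at the calibrated defaults
  (d = 0.3); the mean recovered d must lie within ±0.05 of 0.3, and the
  direction of the phenotype pattern (more female sign-trackers) must
  recover in a majority of cohorts.

These sizes give a CI half-width of ≈ 0.013 on a 5% rate and ≈ 0.01 on
the mean d — tight enough to detect meaningful miscalibration.

A caveat the recovery study makes visible: at d = 0.3 the sex × tertile
$\chi^2$ test has power close to one half — the chi-squared-significant
fraction the acceptance script reports hovers around 0.5. Under any pure
location-shift model, tertile assortment is driven by the standardized
shift alone, and d ≈ 0.3 buys a noncentrality of only ≈ 4–5 at df 2. A
single real cohort can of course land above that (significantly so), but
a mean-shift world at d = 0.3 does not make that the typical outcome —
useful context when interpreting categorical phenotype tests of small
continuous effects.

## Known limitations

* The tertile split discards information relative to treating the index
  continuously; it is implemented because it is the field's convention,
  not because it is statistically optimal.
* The Tukey rule flags ≈ 1% of participants in any Gaussian-tailed cohort;
  "outlier" here means "boxplot-extreme", not "invalid".
* The unweighted-means ANOVA sums of squares are not additive under
  unequal group sizes (no Type-III-like decomposition is); the weighted
  variant is provided where exact additivity matters.
* The generator's per-sample independence understates the autocorrelation
  of real gaze streams; dwell-time *totals* are unaffected, but any
  fixation-level analysis would need a different emission model.
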