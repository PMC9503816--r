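# weartime

How many days does a patient need to wear a sensor before the measures you
compute from it are trustworthy? Free-living gait and postural-sway
monitoring with wearable accelerometers routinely spans weeks, but most of
that burden may be unnecessary — or, worse, a too-short protocol may yield
summaries that do not represent the patient. `weartime` implements a
three-stage statistical framework for determining the minimum wear duration
needed to capture a digital mobility measure *and its variability*, aimed at
researchers designing remote-monitoring studies in populations such as
persons with multiple sclerosis.

## What it does

For each candidate wear duration *d* (1 day, 2 days, ..., 6 weeks) and each
feature summary (median, 95th percentile, coefficient of variation
CV = s/|x̄|), compared against a one-week baseline window:

1. **Stage 1 — difference testing.** Two-sided Wilcoxon rank-sum test of the
   across-subject summary vectors, exact for small samples; a duration
   "agrees" when no significant difference (α = 0.05) remains.
2. **Stage 2 — reliability.** Two-way consistency intraclass correlation of
   average measures,
   ICC(C,k) = (MS_R − MS_E) / MS_R,
   between the *d*-day and baseline summaries; ICC ≥ 0.70 counts as strong.
3. **Stage 3 — clinical anchoring.** Spearman correlations between the
   *d*-day summaries (d = 1..14) and patient-reported measures (daily ABC
   balance confidence, summarized as the biweekly median; end-of-cycle MFIS
   fatigue). A feature is clinically anchored at the first day whose
   significant correlation persists with similar strength
   (|ρ(d′) − ρ(d)| ≤ 0.10) through day 14.

The **days required** for a feature is the smallest *d* at which all three
summary statistics simultaneously pass Stages 1 and 2; across features,
days required is regressed on the log CV and the daily observation count:

    days_required ~ 1 + log(CV) + count + log(CV) × count

so sparse, highly variable measures (e.g., Lyapunov-exponent gait stability,
computable only from rare 60 s walking bouts) predictably demand longer wear
than dense, stable ones (e.g., stride duration). A subject-level bootstrap
(1000 replicates) quantifies the stability of any duration-pair ICC.

Upstream of the statistics, the package computes the features themselves
from tri-axial accelerometer bouts (31.25 Hz convention): 13 stabilogram
sway metrics from standing bouts ≥ 30 s (sway area and path per second, RMS,
range, distance, jerk, mean velocity, and Welch spectral-moment summaries —
power, f50, f95, centroidal frequency, frequency dispersion), with
percentile-based filtering of too-still / too-erratic bouts (1.5th and
98.5th percentiles of sway distance over 10,000 sampled bouts); and 14 gait
metrics from stride-event-annotated walking bouts (temporal parameters,
L1-norm asymmetry |R−L|/(0.5(|R|+|L|)), correlation asymmetry
0.5(1−corr), ensemble acceleration asymmetry, AP RMS, ML frequency
dispersion, trunk/thigh sample-entropy ratio for bouts > 30 s, and
Rosenstein largest Lyapunov exponents for bouts > 60 s).

Because no public dataset accompanies this design, the package ships a
hierarchical synthetic cohort generator (`generate_cohort()`): bout values
x_ijb = μ + a_i + d_ij + e_ijb with between-subject, between-day and
within-day components, Poisson daily bout counts, cohort attrition
(22 subjects; 21 complete five weeks, 19 all six), and PRM scores tied to a
latent impairment trait — together with closed-form expected-reliability
curves used as oracles by the test suite.

## Worked example

```r
library(weartime)

cohort <- generate_cohort(cohort_params(), seed = 42)
cohort
#> <synthetic_cohort> 22 subjects, 27 features, 685058 observations (seed 42)

analysis <- estimate_days_required(cohort$observations)
analysis$regression
#> Wear-duration regression: days_required ~ 1 + log_cv + count + interaction
#>         term estimate std_error   p_value
#>    intercept  4.34224   0.68532 1.824e-06
#>       log_cv  1.29770   0.44171 7.390e-03
#>        count -0.21715   0.06302 2.199e-03
#>  interaction -0.08214   0.02204 1.104e-03
#> R-squared: 0.567; adjusted R-squared: 0.511; n = 27
```

All 27 features reach a qualifying duration inside the baseline week; dense
gait features need a single day while the sparse, high-variability gated
features (entropy ratio, Lyapunov exponents) need up to 4 days in this
cohort. The positive `log_cv` coefficient and negative `count` coefficient
say exactly what the framework predicts: more variability → more days,
more daily observations → fewer.

A bootstrap power analysis of one sway feature's 2-day vs 1-week ICC:

```r
base <- summarize_windows(partition_windows(cohort$observations,
                                            duration_spec("1w", 7, baseline = TRUE)))
two  <- summarize_windows(partition_windows(cohort$observations,
                                            duration_spec("2d", 2)))
bootstrap_power(two, base, "distance", "median", B = 1000, seed = 7)
#> Bootstrap ICC power analysis: distance (median), 2d vs 1w
#>   B = 1000 (seed 7, 0 dropped), point ICC 0.908
#>   mean 0.896, 95% CI [0.716, 0.982], P(ICC >= 0.7) = 0.978
```

So two days of monitoring already give a strong, bootstrap-stable estimate
of this subject's typical sway distance relative to a full week.

A thin command-line wrapper lives at `inst/cli/weartime.R` with
`simulate`, `features`, `analyze`, `regress` and `report` subcommands, each
taking `--seed`, `--config` and `--out`.

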