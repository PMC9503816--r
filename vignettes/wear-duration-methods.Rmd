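---
title: "Determining minimum wear duration for free-living gait and sway monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining minimum wear duration for free-living gait and sway monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weartime)
```

## The problem and the model

Wearable accelerometers let us measure gait and postural sway while people
live their lives, but every extra monitoring day costs participant burden,
battery swaps and study money. The question this package answers is: *how
many days are enough for a given digital measure to represent a subject and
their day-to-day variability?*

The framework treats a bout-level feature stream hierarchically. A
feature observation from subject $i$, day $j$, bout $b$ is modelled as

$$x_{ijb} = \mu + a_i + d_{ij} + e_{ijb},$$

with between-subject effects $a_i \sim N(0, \sigma_a^2)$, day effects
$d_{ij} \sim N(0, \sigma_d^2)$ and within-day bout noise
$e_{ijb} \sim N(0, \sigma_e^2)$, and the number of qualifying bouts on a
day Poisson with rate $\lambda$. A $d$-day summary (we use the median, the
interpolated 95th percentile, and the coefficient of variation
$\mathrm{CV} = s / |\bar x|$) has reliability

$$\rho(d) = \frac{\sigma_a^2}{\sigma_a^2 + \bigl(\sigma_d^2 +
\sigma_e^2 / (\lambda\kappa)\bigr) / d},$$

where $\kappa$ is the fraction of bouts surviving quality filtering. This
closed form (exposed as `expected_reliability()`) is monotone in $d$ and is
the engine behind the whole enterprise: measures with small $\lambda$ or
large $\sigma_d, \sigma_e$ need more days.

The three decision stages compare each candidate duration against a
one-week baseline taken from the same monitoring period (windows are
anchored at the start of monitoring, so shorter windows nest inside the
baseline):

* **Stage 1** — two-sided Wilcoxon rank-sum test on the across-subject
  summary vectors, exact when the combined sample is 20 or fewer without
  ties, normal approximation with tie and continuity correction otherwise.
  The groups are treated as unpaired, as the framework prescribes, even
  though the same subjects appear on both sides; with nested windows this
  makes the test conservative, which is the safe direction for an
  agreement check.
* **Stage 2** — ICC(C,k): the two-way consistency intraclass correlation
  for average measures, $(\mathrm{MS}_R - \mathrm{MS}_E)/\mathrm{MS}_R$,
  with $k = 2$ measurements (window and baseline) and pairwise deletion of
  subjects missing either side. Consistency rather than absolute agreement
  is deliberate: a fixed offset between a short window and the baseline
  should not count against reliability. The 0.70 threshold for "strong" is
  the field's convention.
* **Stage 3** — Spearman correlations between the summaries at 1–14 days
  and patient-reported measures: the ABC balance-confidence scale
  (administered daily, summarized as the biweekly median) and the MFIS
  fatigue scale (sampled at the end of each two-week cycle). A
  feature–PRM pair is *stable* from the first day whose significant
  correlation stays significant with strength drifting no more than
  $\varepsilon = 0.10$ through day 14. The framework's stability notion is
  qualitative ("similar strength"); 0.10 is this package's declared
  operationalization, chosen to sit below the ~0.18 coefficient drop that
  the framework treats as a failed emergence, and it is configurable.

**Days required** for a feature is the smallest $d \in 1..7$ at which the
median, 95th percentile and CV all pass Stages 1 and 2 simultaneously. The
grid stops at the baseline length because, with nested windows, $d = 7$
compares the baseline with itself and passes trivially; features that fail
every smaller $d$ are reported as not reached rather than extrapolated.
Across features, days required is regressed on $\log \mathrm{CV}$ (natural
log; the CV is pooled per subject over the first two monitoring days, then
averaged over subjects), the mean daily observation count from the same two
days, and their interaction, by ordinary least squares.

## Feature computation

Sway metrics come from standing bouts of at least 30 s. The bout-mean
acceleration vector estimates gravity; the minimal rotation aligning it
with the vertical removes static tilt, and the mean-removed AP/ML
components form the planar sway signal. Time-domain metrics follow the
standard stabilogram family; two choices deserve a note:

* *Sway area* is the swept area — the summed triangle areas between
  successive planar vectors — divided by bout duration. The alternative
  95% confidence-ellipse area is not duration-normalizable (a stationary
  signal's ellipse does not grow with time), and the framework's required
  invariance of per-second metrics under bout-length changes singles out
  the swept-area definition.
* Frequency-domain metrics (total power, f50, f95, centroidal frequency
  $\sqrt{\mu_2/\mu_0}$, dispersion $1 - \mu_1^2/(\mu_0\mu_2)$) use the sum
  of the per-axis Welch spectra, not the spectrum of the rectified planar
  magnitude: rectification would double the frequency of a pure AP
  oscillation, and a 1 Hz sway should register at 1 Hz.

The Welch estimator uses 10 s Hann-windowed segments with 50% overlap,
which resolves 0.1 Hz on the shortest admissible (30 s) bout at 31.25 Hz.
Bout filtering removes standing bouts whose sway distance falls strictly
below the 1.5th or strictly above the 98.5th percentile of 10,000 randomly
sampled bouts; boundary values are retained because the percentile
endpoints are themselves data points. Bouts whose mean acceleration
magnitude leaves [0.5, 1.5] g are rejected before any metric is computed.

Gait metrics consume stride-event annotations (event detection from raw
thigh acceleration is a separate, upstream problem). Strides outside
0.4–2.5 s are deemed invalid and excluded; bouts need two valid strides.
Double support is computed by intersecting the two feet's stance
intervals. The sample-entropy ratio uses $m = 2$ and $r = 0.2\,\mathrm{SD}$
(community defaults, configurable) on bouts longer than 30 s; the largest
Lyapunov exponent uses the Rosenstein divergence method (embedding
dimension 5, least-squares slope of the mean log divergence over a 0.5 s
window by default) on bouts longer than 60 s. The embedding delay is the
first autocorrelation minimum *capped at the 1/e decorrelation lag*: on
broadband signals the first ACF minimum can sit several oscillation
periods out, stretching the embedding window far beyond the dynamics'
coherence time; with the cap, the estimate on a chaotic reference signal
agrees with a twin-trajectory divergence oracle to within a few percent
(see `test-gait.R`), while without it the estimate is biased low by
roughly a quarter.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` emulates the study design the framework targets:
22 subjects monitored for 6 weeks, with 21 completing five weeks and 19
all six (attrition truncates randomly chosen subjects' streams; everyone
keeps at least two weeks); 27 features spanning 10 dense gait measures,
13 wider-distributed sway measures, and 4 gated measures with few daily
observations; daily ABC and biweekly MFIS scores linked to a standard
normal latent impairment trait shared by all features' subject effects
(ABC slope −20 points/SD with subject SD 8 and daily SD 4 around a mean of
77.6; MFIS slope +14 with SD 8 around 28.3 — giving score dispersions in
the tens of points, as published cohort summaries report).

Default variance components were calibrated once, a priori, through the
closed-form reliability curves to the study conditions the framework
describes: gait features reliable from about one day (relative SDs
0.10/0.02/0.06 for subject/day/within, 60 bouts/day), sway features from
two to three days (0.10/0.07/0.18, 12 qualifying bouts/day), entropy-ratio
features gated to ~5 long bouts/day, and Lyapunov features slowest of all
(0.06/0.05/0.35, 2 one-minute bouts/day). One parameter goes beyond the
additive model: a per-subject log-normal multiplier
$m_i = \exp(\tau z_i)$, $\tau = 0.4$, scales each subject's within-subject
SDs. Without it every subject shares a single true CV and Stage-2 CV ICCs
would have no between-subject signal to detect — contradicting the strong
CV reliabilities real cohorts show. The truth curves absorb it through
$E[m_i^2] = e^{2\tau^2}$.

Two honest caveats about the truth curves, both verified numerically in
the test suite. First, the pipeline's central summary is the median, whose
asymptotic variance for Gaussian noise is $\pi/2$ times the mean's;
`expected_icc()` therefore inflates the bout-level noise term by $\pi/2$
(at 2000 subjects the adjusted curve and the pipeline agree to three
decimals). Second, the curves describe the homoscedastic model: with
$\tau > 0$ the 22-subject ICC estimator's left tail drags its mean a few
hundredths below the population value, and with 2 bouts/day the minimum
observation rule censors subjects at short durations. The
expected-agreement test therefore runs on the homoscedastic gait and sway
archetypes — the curve's domain of validity — while the data-starved gated
configs are exercised by the days-required ordering test, which is about
exactly that starvation.

The generator does *not* emulate: circadian or weekday/weekend structure
(weekday and weekend windows draw from the same distribution, so those
comparisons are null by construction); disease progression or any drift
over the six weeks; non-Gaussian bout noise beyond the optional log-normal
value distribution; or correlated missingness (attrition is random
truncation, and within a monitored day bouts are never selectively
missing). Passing tests therefore demonstrate that the machinery measures
what it claims under the stated hierarchical model — not that any
particular real cohort satisfies that model.

## Numerical choices and degenerate inputs

* Quantiles (95th percentile, sway thresholds) use the linear-interpolation
  definition (R type 7).
* CV is SD over the *absolute* mean, returned missing when
  $|\bar x| < 10^{-8} s$; summaries need at least 3 observations
  (configurable).
* Day boundaries fall at subject-local midnight via a configurable UTC
  offset; a partial wear day counts as a monitoring day if it contains at
  least one observation.
* Duplicate PRM administrations keep the last record, with a warning.
* ICC is flagged undefined when the between-subject mean square is zero;
  bootstrap replicates with a degenerate resample are dropped and counted.
* Stage-1 exactness switches to the normal approximation above a combined
  n of 20 or in the presence of ties. Spearman p-values come from
  `stats::cor.test` (exact for small tie-free samples, asymptotic
  otherwise); full permutation enumeration at the cohort sizes involved
  (n! at n ≥ 10) is not computationally meaningful.
* "1 day" means the first monitored day (windows anchored at the start of
  monitoring); a seeded `random_contiguous` anchor exists for sensitivity
  analysis, and weekday/weekend anchors pool Mon–Fri and Sat–Sun.
* The regression refuses rank-deficient designs, naming the collinear
  column, and reports $R^2 = 0$ for a constant response.

## Test design and problem sizes

The suite validates every stage against an independent oracle: ICC against
explicit `aov()` mean squares (2000 random matrices), exact rank-sum
p-values against full enumeration of all group splits up to n = 8, sample
entropy against brute-force template counting, the Lyapunov estimator
against twin-trajectory divergence on 120 s of Lorenz dynamics, spectral
summaries against analytic line and flat spectra, and the full pipeline
against the closed-form reliability curves. Simulation-based checks use
5000 replicates for the Stage-1 type-I error, 100 cohorts for the
expected-ICC agreement and the regression sign structure, 50 cohorts for
the days-required ordering, and single-week cohorts wherever the analysis
only consumes the baseline week — sizes chosen to keep Monte-Carlo error
well inside each test's tolerance while the whole suite runs in a few
minutes on one core.

## Limitations

The package consumes classified activity bouts and stride events; activity
classification and gait-event detection are out of scope, as are spatial
gait parameters (not computable from thigh/chest accelerometry alone),
EMG channels, and vendor cloud formats. The framework's conclusions are
conditional on the chosen baseline (one week) being itself representative;
when that assumption is doubtful, the regression route — predicting days
required from two days of covariates — is the intended fallback.
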