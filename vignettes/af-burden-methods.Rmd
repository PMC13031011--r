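---
title: "Quantifying AF burden from per-minute wearable rhythm streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AF burden from per-minute wearable rhythm streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afburden)
```

## The problem

Paroxysmal atrial fibrillation (AF) comes and goes: what matters clinically
is not only *whether* a patient fibrillates but *how much*, *in how long
episodes*, *how clustered in time*, *with what circadian structure*, and *at
what ventricular rate*. Wrist-worn photoplethysmography (PPG) devices can
label heart rhythm minute by minute for weeks, but their streams are
interrupted by motion artifact and their per-epoch classifications are noisy.
This package implements an analysis chain for such streams:

1. **Fusion** — quality-gate each 1-minute epoch, then calibrate each
   epoch's AF probability by its temporal context (`fuse_stream()`);
2. **5-dimensional feature extraction** — 15 spatiotemporal metrics of AF
   burden grouped into episode-frequency, duration, temporal-clustering,
   circadian and tachycardia dimensions (`extract_features()`);
3. **Composite scoring** — a weighted sum of min–max-normalized features
   with a Youden-index cutoff against clinical events
   (`fit_score_model()`);
4. **Method agreement** — MAE, Pearson/Spearman/Kendall correlations, R²,
   ICC(A,1), per-epoch confusion metrics with Wilson intervals, ROC/PR
   curves and Kruskal–Wallis tests comparing the wearable with a
   synchronized Holter reference (`build_report()`).

Because no patient-level data are distributed with the package, a seeded
synthetic-cohort generator (`simulate_cohort()`) provides paired
wearable/Holter streams with the statistical structure the analysis assumes.

## Epoch streams and episodes

The unit of analysis is the **epoch**: a left-closed 1-minute window with a
rhythm label (`AF`, `SINUS`, `INVALID`), an optional AF probability, a mean
pulse rate and a quality score. Timestamps are local clock time because the
circadian features are clock-time constructs. Readers gap-fill missing
minutes with `INVALID` epochs so every ratio has a well-defined total-time
denominator; an `INVALID` epoch contributes to total monitoring time but
never to *valid* time, which is the denominator of every burden metric.

An **episode** is a maximal run of AF epochs. Runs separated only by at most
`bridging_gap_max` consecutive `INVALID` epochs are merged (default 3 min):
a short unreadable stretch should not split one physiological episode. A
confirmed `SINUS` epoch always terminates an episode, however short the gap —
a rhythm change is evidence, signal loss is not. Bridged invalid minutes
inflate an episode's *duration* but never its AF-epoch count, so burden is
never inflated by artifact. Whether an artifact-interrupted episode is one
episode or two is not observable from the stream; the bridging rule is this
package's explicit construction, and `bridging_gap_max = 0` recovers
classical run extraction.

The day window is [06:00, 22:00) and the night window its complement. (The
two plausible conventions differ by whether the night ends at 06:00 or
18:00; an 18:00 end would make "night" a 20-hour window, so we use 06:00.)

## The fusion stage

Each valid epoch carries an AF probability from an upstream per-epoch
classifier. The package deliberately treats that classifier as a *contract*
(any epoch with ≥ 12 interbeat intervals → a probability) and ships
`classify_epoch_reference()` as a documented stand-in: a deterministic
irregularity score combining the RMS of circular normalized successive
interbeat-interval differences with the entropy of their histogram, squashed
through a fixed logistic. Circular differences (wrapping last → first) make
the score exactly invariant under duplication of the interval sequence,
which is the natural length-invariance contract for a rhythm property. It is
*not* a trained clinical detector and is flagged as such wherever it appears.

Contextual fusion exploits the temporal continuity of AF: the fused
probability of epoch *i* is the weighted mean of the valid probabilities in
a symmetric window of half-width *W*,

$$\tilde p_i \;=\; \frac{\sum_{|k| \le W,\; i+k\ \mathrm{valid}} w_{|k|}\, p_{i+k}}
                        {\sum_{|k| \le W,\; i+k\ \mathrm{valid}} w_{|k|}},$$

and the label is AF iff $\tilde p_i \ge$ the decision threshold (default
0.5). Invalid neighbors are excluded from numerator and denominator, and an
`INVALID` epoch is never revalidated. Defaults are $W = 2$ with triangular
weights (3, 2, 1): a 5-minute window encodes continuity while staying
shorter than the 6-minute "sustained episode" stratum, so genuine episodes
of ≥ 2 minutes remain detectable (isolated single-minute episodes are the
price of smoothing, and the tests measure that trade-off explicitly). Fusion
operates on probabilities and falls back to the 0/1 label encoding when
probabilities are absent, degrading gracefully to weighted majority voting.

The **yield rate** — the fraction of the monitoring period with a valid
AF/non-AF decision, overall and by day/night window — is the fusion stage's
tolerance metric for motion artifact.

## The five feature dimensions

All denominators use *valid* epochs/time (total-time variants would be
biased by artifact burden, which differs systematically between day and
night).

* **Episode frequency** (`number_features()`): AF epochs, episodes ≥ 6 min,
  and episodes ≥ 1 h, each per valid epoch. Strata are closed (≥ 6, ≥ 60).
* **Duration** (`duration_features()`): overall AF burden and its
  restriction to episodes ≥ 6 min and ≥ 1 h. These are nested, so
  `burden_all ≥ burden_ge6 ≥ burden_ge1h` on every input — a property the
  tests enforce on random streams.
* **Temporal clustering** (`af_density()`): a Lorenz-type concentration
  index. With $u \in [0,1]$ indexing valid time and $C(u)$ the fraction of
  AF time accumulated by $u$,
  $$\mathrm{density} = \frac{\int_0^1 |C(u) - u|\,\mathrm{d}u}{(1-b)/2},$$
  where $b$ is overall burden and $(1-b)/2$ is the integral attained when
  all AF forms one block at either end of monitoring. The index is 0 for
  perfectly uniform accumulation, exactly 1 for a single terminal block,
  and for perfectly alternating AF/sinus epochs it equals the reciprocal of
  the episode count, vanishing as streams grow. The integral is evaluated
  exactly on the piecewise-linear $C$ (sign crossings split into
  triangles). Several competing "burst-iness" definitions exist; this one
  was chosen because it is bounded, reversal-invariant and reduces to
  established temporal-persistence indices.
* **Circadian rhythm** (`circadian_features()`): the CV of episode-onset
  clock times (linear minutes after midnight — a circular statistic would
  change the scale of the reported CV, and the plain CV is the convention
  this feature set follows); the **variation of the mean (VOM)**, defined
  here as the signed symmetric contrast
  $(f_{day}-f_{night})/(f_{day}+f_{night}) \in [-1,1]$ of AF-epoch
  frequency, negative under nocturnal dominance; day-to-day burden SD when
  ≥ 2 days carry ≥ 12 h of valid data each, else the SD of the hourly
  burden series (the 24-hour Holter case); the SD of hourly burden within
  each clock window; and the **average real variability (ARV)**, the mean
  absolute successive difference of hourly burden over consecutive hours.
  Exact formulas for this family are not standardized across the
  literature; the definitions above are this package's documented choices,
  and each has a hand-derivable test case.
* **Tachycardia** (`tachycardia_features()`): fraction of valid time/epochs
  with pulse strictly > 120 bpm — the zone linked to tachycardia-induced
  cardiomyopathy. With 1-minute epochs the duration ratio and epoch ratio
  coincide identically, and the tests assert that identity.

Features that need more data than a stream provides (CV of onset with < 2
episodes, variabilities with < 2 windows, pulse ratios without pulse data)
are *missing*, never silently zero; a zero-valid stream yields an all-missing
feature vector.

## Composite score and cutoff

Features are min–max normalized on the training cohort so the score and its
cutoff live on an interpretable [0, 1] scale (z-scores would not). Weights
integrate the three agreement ingredients per feature — $|r|$, $R^2$ and
$\max(\mathrm{ICC}, 0)$ — by their arithmetic mean, renormalized to sum
to 1; the mean is the minimal symmetric choice given three named ingredients
and no stated operator, and a geometric-mean mode plus user-supplied weights
are provided. A feature the reference cannot corroborate therefore earns no
weight. The score is the clamped weighted sum, monotone in every feature.

The diagnostic cutoff maximizes Youden's $J = \mathrm{sens} +
\mathrm{spec} - 1$ over midpoints between consecutive sorted unique scores
(plus sentinels), classifying positive at score ≥ cutoff; ties break toward
the smallest cutoff, the most sensitive maximizer. The implementation is
verified against exhaustive enumeration on every random instance the tests
draw.

## Agreement statistics

`concordance_table()` compares each feature across devices by MAE
($\sum_i |p_i - g_i| / n$), the Pearson/Spearman/Kendall battery (through
the standard `stats::cor.test` machinery), $R^2$ of the regression of
reference on index values with a seeded percentile bootstrap CI, and
ICC(A,1) — the two-way random-effects, absolute-agreement, single-measure
intraclass correlation

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
   {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

which, unlike Pearson correlation, penalizes fixed between-device bias. Its
CI uses the F-based interval with Satterthwaite degrees of freedom for
$n \ge 10$ and a subject bootstrap below that (the F interval is unreliable
at very small $n$). Confusion metrics exclude epochs invalid on *either*
device (only valid classification output is scored) and carry Wilson 95%
intervals without continuity correction. ROC curves use a threshold sweep
with tied scores moving together and trapezoid AUC — equal to the
Mann–Whitney statistic, which the tests assert to 1e-12 — and the PR curve
reports step-wise average precision. Kruskal–Wallis tests compare feature
distributions across clinical categories. Two-sided α = 0.05 throughout; no
multiplicity correction is applied, and reports should be read accordingly.

## The synthetic cohort: what it emulates, and what it does not

`simulate_subject()` draws AF episode onsets from an inhomogeneous Poisson
process with rate
$\lambda(t) = \lambda_0 (1 + A \cos 2\pi (t - \phi)/24\mathrm{h})$
(defaults $A = 0.5$, $\phi = 3$ h: nocturnal onset dominance, which
produces the negative day/night VOM typical of paroxysmal AF), durations
from a three-component lognormal mixture targeting the < 6 min / 6 min–1 h /
≥ 1 h strata (weights 0.35/0.40/0.25, medians ≈ 2/20/180 min), overlapping
episodes merged, and pulse rates per epoch from state-dependent normals
(sinus 75 ± 10, AF 105 ± 22 bpm, so a realistic minority of AF minutes
exceeds 120 bpm). A lognormal subject-level frailty (sdlog 1.5) on the onset
rate produces the wide between-subject dispersion — many near-zero, some
near-persistent — without which cohort-level agreement statistics would be
degenerate.

`degrade_to_device()` is the observation channel: epochs masked `INVALID`
independently at day/night artifact rates, and surviving epochs given the
classifier's clean operating probability (0.85 for AF, 0.15 for sinus)
plus Gaussian noise (sd 0.15), clamped to [0, 1]. The clean margin matters:
a channel that emitted exact 0/1 probabilities would make per-epoch noise
at sd 0.15 almost never decision-relevant, and the fusion stage would have
nothing to correct. The default index-device artifact rates (0.10 day,
0.02 night) represent *residual* masking after upstream signal-quality
optimization — raw motion-artifact exposure in wearables is several-fold
higher, but waveform-level recovery is out of scope here — and produce
overall/day/night yields near 0.93/0.90/0.98 with the daytime-dominant
pattern wearable studies report. The reference channel uses a 1% artifact
rate and no classifier noise. Clinical labels close the loop:
`event_flag ~ Bernoulli(logit^{-1}(-2 + 4 b))` on true burden $b$ (≈ 30%
prevalence with a strong burden gradient), EHRA symptom class by monotone
quartile binning of positive burden with 10% ordinal jitter, class 0 at
zero burden.

All randomness derives from one master seed via fixed per-subject
substreams, so cohorts are bit-reproducible and independent of evaluation
order; generators save and restore the caller's RNG state.

What the generator does **not** emulate: waveform-level PPG noise,
autocorrelated artifact bouts, classifier errors correlated with rhythm or
rate, atrial flutter or ectopy mimics, device clock drift, or treatment
effects on burden. Passing tests therefore demonstrate the *pipeline's*
correctness and calibration under a plausible generative model — not
clinical performance of any device.

## Numerical and degenerate-input choices

* Ratios against zero valid time are missing, never 0; single-class label
  sets make cutoffs and ROC undefined errors; a one-subject cohort produces
  an all-missing concordance table without crashing.
* Zero-variance features are dropped from normalization with a warning;
  missing feature values are imputed as 0 *after* normalization with the
  missingness pattern retained.
* Degenerate Kruskal–Wallis input (all values identical) returns
  $H = 0,\ p = 1$ by convention.
* Wilson bounds are pinned exactly to 0/1 at boundary counts to avoid
  floating-point residue.
* Tie-breaks: Youden cutoff → smallest maximizing cutoff; ROC → tied scores
  cross thresholds together.

## Problem sizes used by the checks

The test-suite properties run at sizes chosen to make each check sharp but
quick: exhaustive episode-oracle comparison over all label strings of
length ≤ 8 (and 200 random longer ones), 1000 random streams for burden
monotonicity, 200 simulated days for the fusion-gain property, n = 1000 for
cutoff recovery (± 0.05 around a programmed 0.59 threshold), and 2000 null
replicates for Kruskal–Wallis type-I calibration. The end-to-end
`scripts/acceptance.R` run uses the full 110-subject, 24-hour design.

## Known limitations

* The reference per-epoch classifier is a stand-in satisfying the contract,
  not a validated detector; absolute sensitivity/specificity on real PPG
  are outside what this package can claim.
* The composite score's weights depend on the cohort used to derive them;
  no shrinkage or cross-validation is applied, so small cohorts overfit the
  cutoff (the cutoff-recovery test quantifies this at n = 1000, not below).
* Circadian features assume the device clock is local time; shift workers
  and travel across time zones violate the day/night windows.
* Burden ratios treat all valid epochs equally; differential missingness
  correlated with AF itself (e.g., symptomatic motion during episodes)
  would bias burden downward, and no inverse-probability correction is
  attempted.
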