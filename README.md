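# afburden

Quantify atrial fibrillation (AF) burden and its progression from
per-minute rhythm epoch streams recorded by wrist-worn photoplethysmography
(PPG) devices, validated against a synchronized ambulatory Holter reference.

Paroxysmal AF is poorly summarized by a single "AF yes/no" or even by total
AF time. `afburden` implements a wearable-oriented analysis chain for
long-term rhythm streams:

1. **Contextual fusion** of noisy per-epoch AF probabilities. After quality
   gating, each valid epoch's probability is re-estimated as the weighted
   mean of its neighborhood (default: half-width *W* = 2 epochs, triangular
   weights 3:2:1), exploiting the temporal continuity of AF episodes:

   p̃ᵢ = Σ_{|k|≤W, valid} w₍|k|₎ p₍i+k₎ / Σ_{|k|≤W, valid} w₍|k|₎,  label AF ⇔ p̃ᵢ ≥ 0.5

2. **A 5-dimensional spatiotemporal feature set** (15 metrics): episode
   frequency (AF epochs, episodes ≥ 6 min, episodes ≥ 1 h per valid epoch),
   duration burden (overall and restricted to ≥ 6 min / ≥ 1 h episodes),
   temporal clustering (a Lorenz-type AF *density* index on [0, 1]),
   circadian variability (CV of episode onset, signed day/night VOM
   contrast, day-to-day and hourly burden SDs, average real variability),
   and tachycardia burden (valid time with pulse > 120 bpm).

3. **A composite burden score**: min–max-normalized features weighted by
   the per-feature agreement with the reference — mean of |r|, R² and
   ICC⁺ — with the diagnostic cutoff chosen by Youden-index maximization
   against clinical events.

4. **A method-agreement suite**: MAE, Pearson/Spearman/Kendall battery, R²
   with bootstrap CI, ICC(A,1) (two-way random effects, absolute agreement)
   with F-based CI, per-epoch sensitivity/specificity/accuracy with Wilson
   95% intervals, ROC/PR curves (trapezoid AUC = Mann–Whitney), and
   Kruskal–Wallis tests across clinical categories.

Because no patient data ship with the package, a seeded synthetic-cohort
generator produces paired wearable/Holter epoch streams with circadian
episode onsets, a three-stratum episode-duration mixture, tachycardic AF
pulse rates, daytime-dominant artifact masking and per-epoch classifier
noise, so the entire pipeline runs end to end out of the box. See the
methods vignette (`vignettes/af-burden-methods.Rmd`) for the model, the
formula choices and their rationale.

## Worked example

```r
library(afburden)

res <- run_pipeline(sim_params(n_subjects = 60), seed = 42)

res$report
#> <concordance_report> 60 subjects, 79306 epoch pairs
#>   per-epoch sens 0.997 spec 1.000 acc 1.000
#>   ROC-AUC 1.000, PR-AUC 1.000
#>                 feature  n      mae     r r_squared   icc
#> 1        af_epoch_ratio 60 1.43e-03 1.000     1.000 1.000
#> 4            burden_all 60 1.43e-03 1.000     1.000 1.000
#> 7            af_density 60 3.01e-02 0.906     0.822 0.907
#> 9                   vom 60 3.67e-02 0.948     0.899 0.947
#> 13                  arv 60 5.56e-04 1.000     1.000 1.000
#> ...

round(c(colMeans(res$yield[-1])), 3)
#> overall    day  night
#>   0.927  0.901  0.980
```

Reading the output: the wearable channel loses ~7% of minutes to residual
motion artifact, predominantly in the daytime (day yield 0.90 vs night
0.98). After contextual fusion, per-epoch rhythm labels agree almost
perfectly with the reference, and duration-dimension features are
interchangeable between devices (ICC ≈ 1), while the clustering (`af_density`)
and day/night-contrast (`vom`) features — which amplify epoch-level
disagreements — agree more moderately (ICC ≈ 0.91, 0.95). The fitted score
model gives the cutoff and its operating point:

```r
c(cutoff = res$score$cutoff,
  sens = res$score$cutoff_sensitivity, spec = res$score$cutoff_specificity)
#>    cutoff      sens      spec
#> 0.4113007 0.3636364 0.9183673

kruskal_wallis(res$features_index$burden_all, res$clinical$ehra_class)
#> $h [1] 55.7   $df [1] 4   $p [1] 2.3e-11
```

The Kruskal–Wallis test confirms the simulated burden–symptom gradient
across EHRA classes. A thin command-line front end wraps the same
functions; after installation:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","afburden",package="afburden"))')" \
  run --out out/ --seed 7 --subjects 20
```

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "afburden", load_package = "installed")'
```

The suite verifies each statistic against an independent oracle (exhaustive
episode-run scans, O(n²) Kendall pair counting, from-scratch ANOVA mean
squares for the ICC, Mann–Whitney AUC, exhaustive Youden enumeration,
Riemann-sum AF-density integration), property-based invariants on random
streams, and the end-to-end determinism of pipeline artifacts.
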