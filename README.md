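# pulsevar

Beat-wise harmonic variability analysis of arterial pulse waveforms.

## The problem

A one-minute noninvasive pulse recording — radial blood-pressure waveform
(BPW) or photoplethysmogram (PPG) — carries information about vascular
stiffness, pulse transmission and cardiovascular regulation. `pulsevar`
implements a frequency-domain pipeline for such recordings, aimed at
detecting *changes in vascular condition between two measurement sessions*
(e.g. before and about a week after an exposure such as a vaccination):

1. **Beat segmentation.** Beat onsets ("feet") are located by the
   intersecting-tangent construction (horizontal line through the
   pre-upstroke minimum ∩ tangent at maximum upslope). Foot-to-foot
   intervals give HR and its coefficient of variation,
   HR_CV = 100·sd(RR)/mean(RR).
2. **Per-beat harmonic decomposition.** Each beat is expanded at exact
   multiples of its own fundamental: aₙ = (2/N)·Σₜ s[t]·e^(−i2πnt/N),
   n = 1..10. Aggregating over the beats of one recording yields the **40
   harmonic indices**: amplitude proportions Cₙ = 100·|aₙ|/Σₖ|aₖ| (mean over
   beats), their beat-to-beat coefficients of variation CVₙ, circular mean
   phases Pₙ (degrees, referenced to the foot) and circular phase dispersions
   Pₙ_SD.
3. **Pulse-variability score.** For paired sessions M0 (pre) and M1 (post),
   the score is the product of post/pre ratios of the six most responsive
   variability indices:

   score = (CV₂·P₁_SD·P₂_SD·P₃_SD·P₄_SD·P₅_SD)ᴹ¹ ⁄ (CV₂·P₁_SD·…·P₅_SD)ᴹ⁰

   Identical sessions give 1; a uniform doubling gives 2⁶ = 64. Subjects are
   classified by a single threshold (positive iff score > θ) or by a
   two-threshold rule with an ambiguity band (no call for low ≤ score ≤ high).
4. **Metrics.** Confusion counts, accuracy over adopted subjects,
   specificity, sensitivity, single-operating-point AUC = (sens + spec)/2,
   positive likelihood ratio LR+ = sens/(1 − spec), rank (Mann–Whitney) AUC,
   and adopted/excluded proportions.
5. **ML baseline.** Eight classifiers (SVM, MLP, GNB, DT, RF, LR, LDA, KNN)
   with stratified threefold cross-validation on the 40-index feature table.
6. **Synthetic cohorts.** A seeded generator produces paired recordings with
   known harmonic content, beat-interval/amplitude/phase jitter and a
   group-dependent "vascular" post-session perturbation, so the whole
   pipeline is testable with exact ground truth.

## Worked example

```r
library(pulsevar)

spec <- cohort_spec(n_per_group = c(N = 28, C = 0, V = 11),
                    effect_post_phase_sd = 2, duration_s = 30, fs = 250)
cohort   <- simulate_cohort(spec, seed = 42)
profiles <- profiles_table(cohort)                  # 40 indices + HR per recording
scores   <- merge(score_table(profiles), cohort$labels, by = "subject")

round(tapply(scores$score, scores$group, median), 2)
#>     N     V
#>  1.07 39.68

report <- confusion(classify_single(scores$score, threshold = 17.1),
                    scores$group == "V")
report
#> <classification_report>
#>      decision
#> truth negative positive
#>     0       28        0
#>     1        2        9
#> excluded: 0 of 39 (adopted 100.0%)
#> accuracy 94.87%  specificity 1.00  sensitivity 0.82  AUC 0.91  LR+ Inf

rank_auc(scores$score, scores$group == "V")
#> [1] 1
```

Unexposed subjects score near 1 (their two sessions differ only by sampling
variability of the variability indices), while subjects with the simulated
vascular effect — phase jitter doubled across all ten harmonics at M1 —
score an order of magnitude higher, so a threshold in the tens separates the
groups almost perfectly on clean synthetic data.

## Command-line interface

```sh
Rscript inst/cli/pulsevar.R simulate --config cohort.yaml --out dir/ --seed 1
Rscript inst/cli/pulsevar.R segment  dir/S001_M0.csv
Rscript inst/cli/pulsevar.R profile  dir/ --out features.csv
Rscript inst/cli/pulsevar.R score    features.csv --low 0.4 --high 40 --out scores.csv
Rscript inst/cli/pulsevar.R evaluate scores.csv dir/labels.csv
Rscript inst/cli/pulsevar.R ml       features.csv dir/labels.csv --target cv_flag --seed 7
```

Recordings are two-column CSVs (`time_s,amplitude`) with a
`# fs=<Hz> channel=<BPW|PPG> subject=<id> session=<M0|M1>` header line.

## Documentation

The methods vignette (`vignettes/pulse-variability.Rmd`) describes the
model, the index definitions and their numerical conventions, what the
synthetic-data generator does and does not emulate, and the package's design
decisions.
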