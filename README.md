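# oculopd

Saccade and pupillometry analysis for early-stage Parkinson's disease (PD)
screening with VR eye tracking.

Early PD alters oculomotor behaviour: pro-saccades (reflexive gaze shifts
toward a stimulus) lose velocity and accuracy and take longer to complete,
and erroneous anti-saccades (reflexive glances at a stimulus the subject was
told to look away from) are corrected less often. The pupil's constriction
trace during the task carries complementary frequency-domain signal.
`oculopd` implements the complete analysis chain for a 40-trial
pro-/anti-saccade protocol (1 s fixation, 1.2 s lateral stimulus, 2 s rest):

* **synthetic cohorts** — minimum-jerk saccades with group-dependent
  latency/velocity/gain and behavioural error rates, band-structured pupil
  oscillations, blinks;
* **preprocessing** — blink/artifact masks, short-gap interpolation
  (pupil only), per-trial exclusion;
* **saccade metrics** — velocity-threshold detection with hysteresis and the
  14 standard per-subject parameters, e.g. latency
  (stimulus onset → first supra-threshold saccade), anti-saccade error
  correction rate (corrected / direction-error trials);
* **pupil spectra** — amplitude spectra `2/N·|DFT|` on a 0.1 Hz grid up to
  19 Hz over 10 s windows, band-labelled low (0–6 Hz), medium (7–12 Hz),
  high (13–19 Hz);
* **statistics** — Shapiro–Wilk-gated pooled *t* vs Mann–Whitney U per
  feature at α = 0.05, band-wise significant-frequency counts with both-eye
  totals, pooled `t = (m₁−m₂)/(s_p·√(1/n₁+1/n₂))` recomputable from printed
  summaries;
* **diagnosis** — a built-in random forest (500 CART trees, √p feature
  subsampling) evaluated by repeated stratified cross-validation over six
  feature-set configurations, with in-fold significance-based feature
  selection.

## Worked example

```r
library(oculopd)

## printed-summary verification: pooled t from group means/SDs (n = 43/25)
t_from_summary(206.5, 107.1, 43, 279.5, 105.6, 25)$t
#> [1] -2.723897

## simulate a small cohort and run the full pipeline
cfg <- cohort_config(n_pd = 16, n_control = 12, seed = 42)
res <- run_pipeline(cfg, folds = 4, repeats = 3, ntree = 300)

res$tables$saccadic[c(1, 5, 11), c("feature_id", "test_used", "p_value",
                                   "mean_pd", "mean_control", "significant")]
#>                  feature_id test_used  p_value mean_pd mean_control significant
#> 1          pro_accuracy_pct  pooled_t 7.33e-06    81.7         94.1        TRUE
#> 5           pro_vel_avg_dps  pooled_t 8.13e-04   188.4        222.0        TRUE
#> 11 anti_correction_rate_pct  pooled_t 1.65e-04    26.9         45.3        TRUE

res$tables$band_counts
#>           task   eye low medium high
#> 1  pro_saccade  left  11     26   17
#> 2  pro_saccade right   4     29   11
#> 3  pro_saccade  both  15     55   28
#> 4 anti_saccade  left  31     22   11
#> 5 anti_saccade right  35     24    8
#> 6 anti_saccade  both  66     46   19

res$classifiers$table
#>             model accuracy precision recall    f1
#> 1           basic    0.905     0.912  0.896 0.904
#> 2        freq_pro    0.821     0.818  0.819 0.819
#> 3       freq_anti    0.738     0.735  0.722 0.729
#> 4  freq_pro+basic    0.869     0.868  0.868 0.868
#> 5 freq_anti+basic    0.774     0.770  0.767 0.769
#> 6             all    0.798     0.795  0.799 0.797
```

Reading the output: the simulated PD group is less accurate on pro-saccades
(81.7% vs 94.1%), slower (188 vs 222 °/s average saccade velocity) and
corrects fewer anti-saccade errors (26.9% vs 45.3%) — all significant at
α = 0.05. Band counts tally how many 0.1 Hz bins differ significantly per
frequency band, per eye and summed over eyes. The classifier table compares
feature sets; at this small n the single-seed ordering is noisy (the
all-vs-basic ordering is a multi-seed mean property, see the methods
vignette).

`run_pipeline(cfg, out_dir = "out/")` additionally writes CSV tables, PNG
figures (trial-locked pupil trajectories, group-average amplitude spectra)
and a JSON run log. A command-line driver with `simulate`, `analyze`,
`report` and `dump-config` subcommands is installed at
`inst/scripts/oculopd`.

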