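# cllscore

Flow-cytometry immunophenotyping is the workhorse for separating chronic
lymphocytic leukemia (CLL) from the other B-cell chronic lymphoproliferative
disorders (B-CLPD: mantle cell, marginal zone and follicular lymphoma, hairy
cell leukemia, and rarer entities), because treatment differs sharply across
these diagnoses. `cllscore` is an R package for hemato-pathology and
biostatistics users that implements the complete scoring pipeline — and a
synthetic listmode-data generator that makes every stage testable without
patient data:

1. **Simulation** — per-patient marker profiles and per-cell event tables
   (FSC, SSC, CD45, CD19 and an eight-marker panel) with matched
   isotype-control tubes, emulating a 252-patient B-CLPD cohort
   (199 CLL including 10 atypical, 20 MCL, 17 MZL, 8 HCL, 3 FL, 5 other).
2. **Gating and quantification** — CD45-high/SSC-low lymphocyte gate, CD19+
   B-cell selection against the isotype threshold (99.5th percentile), then
   per marker: percent-positive, mean fluorescence intensity ratio
   (MFIR = MFI sample / MFI isotype), and the log-decade intensity pattern
   (weak / moderate / strong).
3. **Scoring** — three systems per sample, each marker contributing a 0/1
   point:

   | system | markers | range | CLL screen |
   |---|---|---|---|
   | classical Matutes score (MS) | CD5≥30%, CD23≥30%, FMC7<30%, CD79b<30%, sIgM weak | 0–5 | score ≥ 4 |
   | CD200-augmented MS | classical + CD200≥30% | 0–6 | score ≥ 4 |
   | four-marker MS | CD5, CD23, sIgM, CD200 | 0–4 | score ≥ 4 |

   Score ≥ 4 is typical CLL, score 3 atypical CLL, ≤ 2 non-CLL. CD200 can
   optionally be scored by MFIR ≥ 18 instead of percent-positive.
4. **Diagnostic accuracy** — confusion counts at the ≥ 4 screen, exact
   Clopper–Pearson 95% intervals for sensitivity/specificity/overall
   proportion, tie-corrected rank AUC (the normalised Mann–Whitney
   statistic) with DeLong intervals, Youden-optimal ROC cutoffs, McNemar
   tests between paired score systems and Mann–Whitney tests for continuous
   marker comparisons.

The synthetic cohort is designed so the CD200 biology of the emulated study
holds by construction: every CLL case is CD200-positive (so the 10 atypical
CLL at classical score 3 are rescued to 4 by the CD200 point), no MCL case
reaches 30% CD200, and exactly one non-CLL case (an HCL) reaches the
augmented screen.

## Worked example

```r
library(cllscore)

cfg <- run_config(composition = c("CLL-typical" = 6, "CLL-atypical" = 2,
                                  MCL = 4, MZL = 3, HCL = 2),
                  events_per_sample = 5000, isotype_events = 2000,
                  master_seed = 42, outdir = tempfile("run"))
out <- run_pipeline(cfg)
out$tables$cd200_by_diagnosis
#> # A tibble: 5 × 10
#>   subtype          n median_pct min_pct max_pct n_pct_ge30 median_mfir min_mfir
#> 1 CLL-atypical     2      65.9    58.6     73.1          2       53.9     51.6
#> 2 CLL-typical      6      98.3    90.7     99.3          6       57.9     48.3
#> 3 HCL              2      27.5    12.9     42.2          1       17.5      3.75
#> 4 MCL              4       2.00    1.49    12.0          0        7.29     2.96
#> 5 MZL              3      71.8    59.5     78.6          3       21.3     20.9
out$accuracy
#> Diagnostic accuracy: 8 CLL vs 9 non-CLL (screen: score >= 4)
#>       system sensitivity specificity auc
#>    classical        0.75           1   1
#>    augmented        1.00           1   1
#>  four_marker        0.75           1   1
#> McNemar vs classical:
#>                comparison b c p_value
#>    classical vs augmented 0 2     0.5
#>  classical vs four_marker 0 0     1.0
```

Reading the output: all eight CLL samples (including both atypical ones) are
CD200 ≥ 30% while no MCL sample is; the two atypical CLL score 3 classically
(missed by the classical screen, sensitivity 0.75) and 4 with CD200 added
(augmented sensitivity 1.00), at no cost in specificity. `autoplot()` on the
accuracy object, `plot_cd200_distribution()` and `plot_score_distribution()`
draw the corresponding figures, and `tidy()`/`glance()` return the estimates
as tibbles.

Every run writes a complete CSV audit trail (`manifest.csv`, per-sample
event/isotype/truth tables, `results.csv`, `scores.csv`, `accuracy.csv`, and
report tables) under `outdir`, and `inst/cli/bclpd_pipeline.R` exposes the
stages (`simulate`, `analyze`, `score`, `evaluate`, `report`, `all`) as a
shell tool.

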