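# biochemom

Biochemometric prioritization of bioactive metabolite features from
untargeted LC-MS extract panels.

## The problem

Natural-product discovery from crude extracts traditionally relies on
bioassay-guided fractionation: repeatedly fractionate, re-assay, and
isolate. Biochemometrics replaces much of that loop with statistics — it
fuses an aligned untargeted metabolomics feature table (peak area per
*m/z* × retention-time feature per sample) with a per-sample bioassay
readout (here, cytotoxic IC50 from an MTT viability assay) and asks which
features' abundances track the activity. `biochemom` implements that
workflow end to end for R users working with extract panels assayed for
dose-dependent activity:

1. **Dose-response** — four-parameter logistic fits
   `y = d + (a − d) / (1 + (x/c)^b)` per sample/plate; IC50 is the dose
   where fitted viability crosses 50%, summarized over replicates and
   modeled as `ln IC50`.
2. **Preprocessing** — zero replacement (0.001), zero-variance removal,
   Hellinger transform `h_ij = √(x_ij / Σ_j x_ij)`, auto or Pareto
   scaling with train-fitted state, Shapiro–Wilk normality screening, and
   SVD PCA.
3. **Bespoke filters** — a 5-fold blank filter (feature kept only when
   its area exceeds 5× the mean blank area in at least half of the
   smaller source group) and a source-group presence filter (kept when
   present in all samples or in ≥ half of *each* group), both with full
   removal traces and a Pearson audit of everything discarded.
4. **Modeling** — balanced 80:20 split stratified on log IC50;
   coordinate-descent LASSO `(1/2n)‖y − Xβ‖² + λ‖β‖₁` with
   leave-one-out-CV λ selection as a preselection stage; NIPALS PLS1
   regression on the surviving features with LOO-CV component choice;
   RMSE and CV% validation.
5. **Feature importance** — VIP,
   `VIP_j = √( p · Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a )`, and the
   Selectivity Ratio from the target projection `t_TP = Xb/‖b‖`,
   `SR_j = v_explained,j / v_residual,j`; candidates are the union of
   `VIP > 1` and `SR > 0.5`, each labeled with its direction of effect by
   comparing raw areas in the 5 most vs. 5 least active samples.
6. **Annotation** — precursor-screened, √intensity cosine matching of
   candidate MS2 spectra (MGF) against a library, plus mirror-plot export.

A seeded synthetic-data generator (`scenario_spec()` /
`generate_dataset()`) emulates a 40-sample, two-source extract panel with
1600 heavy-tailed features, structured missingness, blank channels,
blank-borne contaminants, and spiked bioactivity-linked features, so the
whole chain is benchmarkable by spike-in recovery without any download.

## Worked example

```r
library(biochemom)

d   <- generate_dataset(scenario_spec(seed = 7))
res <- run_pipeline(d$table, d$metadata, d$bio, seed = 7)
print(res)
#> biochemometric pipeline result
#>   features: aligned=1600 -> blank_filter=1436 -> source_filter=336 -> zero_variance=336 -> lasso=29
#>   PLS components: 10 | LOO RMSE 0.0255 | test RMSE 0.1063
#>   candidates: 7 (mode union)

head(res$candidates[, c("feature_id", "mz", "rt", "vip", "sr", "direction")])
#>   feature_id  mz   rt  vip    sr         direction
#> 1      F1271 509 8.10 2.07 1.535 negative_activity
#> 2      F1382 928 7.93 2.04 1.456 positive_activity
#> 3      F1510 130 5.57 1.99 1.340 negative_activity
#> 4      F1095 112 5.87 1.80 0.817 positive_activity
#> 5      F0645 334 8.85 1.42 0.409 positive_activity
#> 6      F1345 167 6.00 1.12 0.207 negative_activity

sum(d$truth$active_ids %in% res$candidates$feature_id)
#> [1] 4
```

Reading the output: the stepwise ledger shows 1600 aligned features
reduced to 336 by the blank and source-group filters and to 29 by LASSO
preselection; the final PLS model predicts held-out log IC50
with RMSE 0.106 (log units); 7 features pass the VIP/SR union, and all 4
features the generator spiked to covary with activity (|r| = 0.8 against
log IC50) are among them. `positive_activity` means higher peak area in
the more active (lower-IC50) samples. `write_candidate_report()` emits
the ranked TSV; the `inst/exec/biochemom` script wraps the same functions
as `simulate` / `ic50` / `run` / `annotate` subcommands.

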