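---
title: "Biochemometric feature prioritization: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biochemometric feature prioritization: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biochemom)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The modeling problem

An extract panel is a set of $n$ crude extracts, each measured twice: an
aligned untargeted LC-MS feature table $X$ ($n$ samples $\times$ $p$
features, raw peak areas, zeros meaning "not detected") and a per-sample
bioactivity summary $y$ — here the natural log of the IC50 from an MTT
viability assay, so *smaller $y$ means more active*. The goal is a short,
ranked list of features whose abundance explains the variation in $y$,
with a direction of effect, suitable for targeted isolation. With
$p \gg n$ (hundreds to thousands of features against a few dozen
extracts) the workflow leans on aggressive, assay-aware feature
reduction before any regression is trusted.

## Dose-response and IC50

Viability at dose $x$ is modeled by the four-parameter logistic
$$y = d + \frac{a - d}{1 + (x/c)^b},$$
with lower asymptote $d$, upper asymptote $a$, Hill slope $b > 0$, and
inflection $c$. Fitting is multi-start Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`; starts $b \in \{0.5, 1, 2, 4\}$, $c$ at the
geometric mean of the positive doses, asymptotes at the observed
viability extremes), with a Nelder–Mead fallback when the gradient-based
fits all fail (e.g. perfectly flat data). Zero-dose wells anchor the
upper asymptote and are excluded from the power term, since $(0/c)^b$ is
only well-behaved for $b > 0$; the model value at $x = 0$ is $a$.

The IC50 is the *absolute* 50%-viability crossing,
$c \, ((a - 50)/(50 - d))^{1/b}$, reported only when 50% lies strictly
between the fitted asymptotes — a curve that never crosses 50% has no
IC50, and the fit is flagged rather than extrapolated. Replicate IC50s
are averaged (sample SD, $n-1$ denominator), and the response used
everywhere downstream is $\ln(\overline{\mathrm{IC50}})$; natural log is
used because the workflow's reference arithmetic (e.g. an IC50 of
57.21 µg/ml mapping to 4.05 log units) is reproduced by $\ln$ and not by
$\log_{10}$. Curves are fitted per plate replicate by default (a
`per_plate = FALSE` flag pools wells instead), because per-plate fits
yield a dispersion estimate for the summary.

## Preprocessing

- **Zero replacement.** Zeros encode non-detection; before
  transformation they are replaced by $\varepsilon = 0.001$ on the raw
  area scale. $\varepsilon$ is deliberately tiny relative to real peak
  areas (typically $10^3$–$10^6$); a warning fires if it is not.
- **Zero-variance removal** drops features that are constant across
  samples (they carry no information and break scaling).
- **Hellinger transform.** $h_{ij} = \sqrt{x_{ij} / \sum_j x_{ij}}$ —
  the square root of the within-sample relative abundance, the standard
  community-ecology definition. Rows land on the unit sphere, removing
  per-injection total-signal differences and damping the dominance of
  large peaks.
- **Scaling.** Auto-scaling (center, divide by SD) or Pareto
  ($\sqrt{\mathrm{SD}}$ divisor). The scaler is *always fitted on
  training samples only* and applied frozen to test samples; this is the
  single most important leakage guard in the pipeline.
- **Normality screen.** `normality_screen()` ranks
  hellinger/log × auto/Pareto combinations by median per-feature
  Shapiro–Wilk $W$. Note that $W$ is location/scale invariant, so the
  auto and Pareto variants of the same transform tie exactly; both are
  reported so the output table mirrors the candidate set a user expects,
  but the screen genuinely discriminates only between transforms.
- **PCA** (SVD via `prcomp`) is run on the full Hellinger + auto-scaled
  dataset *before* any model-driven filtering, as an unsupervised look
  at structure such as source-group separation.

## The filters

Both filters act on **raw areas** — fold-change and presence thresholds
are meaningless after row normalization.

**Blank filter.** A feature is kept only if its area exceeds
`fold` (default 5) times its mean area across all blank injections
(zeros included in the mean) in at least `min_samples` non-blank
samples. `min_samples = "auto"` is $\lceil$ smaller source group / 2
$\rceil$. A blank mean of zero makes any positive area qualify. This
removes instrument noise and extraction contaminants.

**Source presence filter.** Keep a feature if it is present
(area $> \varepsilon$) in every sample, *or* present in at least half of
*each* source group (ceiling on odd sizes). The "each group" reading is
the default because the alternative parse ("not present in at least half
of either group" as a removal rule) collapses to "present everywhere"
and contradicts the intent of keeping features with some missing values;
`mode = "any-group"` exposes the other reading rather than silently
resolving the ambiguity.

**Audit.** Before anything is discarded, every removed feature's raw
area vector is correlated (Pearson) with $y$; any $|r| \ge 0.5$ is
flagged as a possibly discarded active. Filters are set-monotone in
their thresholds, and a stepwise trace (counts in/out, per-feature
reasons, parameters) is attached to every run.

## Split, LASSO preselection, PLS

**Balanced split.** 80:20 train/test, stratified by $y$ above/below its
mean so both activity levels appear in both sets; per-stratum test
counts are floors plus largest-fraction remainders, keeping every
stratum within one sample of the global test fraction. The split is the
pipeline's only randomness and is fully determined by `seed`.

**LASSO.** Coordinate descent (C++ via Rcpp) on
$\tfrac{1}{2n}\lVert y - X\beta\rVert^2 + \lambda\lVert\beta\rVert_1$,
cyclic with soft-thresholding, warm starts down a 100-point log grid
from $\lambda_{\max} = \max_j |x_j^\top y| / n$ to
$10^{-4}\lambda_{\max}$ when $n > p$ and $10^{-2}\lambda_{\max}$ when
$p \ge n$ (below that the path enters the interpolation regime, which
cross-validation never selects but which dominates solver time —
the same floor standard lasso solvers use), convergence when the
largest coefficient change
in a sweep falls below $10^{-7}$, with active-set iteration between full
sweeps. $\lambda$ is chosen by leave-one-out CV on the shared grid
(ties to the larger, sparser $\lambda$); the model is refit on the full
training set at $\lambda^\*$ and the nonzero features pass on. If the
selection is empty, the nearest $\lambda$ with a nonzero coefficient is
used, with a warning. The LASSO consumes the already-scaled training
matrix and does not re-standardize internally.

**PLS1 (NIPALS).** Per component:
$w_a = X^\top y / \lVert X^\top y\rVert$, $t_a = X w_a$,
$p_a = X^\top t_a / t_a^\top t_a$, $q_a = y^\top t_a / t_a^\top t_a$,
then deflation of both $X$ and $y$. The regression vector is
$b = W (P^\top W)^{-1} q$. Final coefficients are *refit by PLS on the
LASSO-selected columns* (not recycled from the LASSO), because the
preselection and the interpretable model answer different questions.
The component count is the LOO-CV RMSE argmin with ties to fewer
components; each LOO fold refits the scaler on its $n-1$ samples — a
stricter no-leakage discipline than toolchains that scale once, and one
that can shift the CV curve slightly. Model error is reported as RMSE in
log-IC50 units and as CV%, $100 \times \mathrm{RMSE} / \mathrm{range}(y)$
over the full modeled cohort.

A note on component selection: the strict argmin is noisy when the CV
curve is nearly flat past the true dimensionality. In simulations with
two informative latent variables the argmin recovers the true rank as
its median choice and almost never undershoots, but overshoots by one or
two components in roughly a fifth of runs; the package keeps the argmin
rule (with the parsimony tie-break) rather than adding a one-standard-
error heuristic, because the downstream VIP/SR scores are stable under
mild overshoot.

## VIP, Selectivity Ratio, direction

$$\mathrm{VIP}_j = \sqrt{p \, \frac{\sum_a \mathrm{SSY}_a \,(w_{ja}/\lVert w_a\rVert)^2}{\sum_a \mathrm{SSY}_a}},
\qquad \mathrm{SSY}_a = q_a^2 \, t_a^\top t_a,$$
normalized so the mean squared VIP is 1; the conventional influence cut
is VIP $> 1$. The Selectivity Ratio projects the training matrix onto
the normalized regression vector ($t_{TP} = X b / \lVert b \rVert$,
loadings $p_{TP} = X^\top t_{TP} / t_{TP}^\top t_{TP}$) and scores each
feature by explained over residual variance under that rank-one model.
Features whose residual is numerically zero get a capped SR of $10^6$
and a "perfect" flag rather than an infinity. SR is computed on the
training matrix the model saw — it is a diagnostic of the fitted model,
not of new data — and uses the full $A^\*$-component coefficient vector.

The default candidate set is the **union** of VIP $> 1$ and SR $> 0.5$
(both thresholds configurable; the SR cut is descriptive practice, not
theory). Direction of effect compares each candidate's mean raw area in
the $k = 5$ most active (lowest IC50) vs. $k$ least active samples:
higher in the actives reads as `positive_activity`; exact ties resolve
conservatively to `negative_activity` with a warning.

## Annotation

Candidate MS2 spectra are matched against a library by precursor
tolerance screening followed by cosine similarity on square-root
intensities (each spectrum normalized to unit norm, peaks greedily
paired best-product-first within the fragment tolerance, each peak used
once). √-intensity weighting de-emphasizes base peaks, standard practice
in spectral matching. No neutral-loss or modified-cosine shifting is
attempted — matching is same-mass by design, and a cosine score is
never a claim of compound identity. `export_mirror()` writes mirror-plot
data (query up, library negated, base peak 100).

## The synthetic generator

`scenario_spec()` defaults define the study conditions the pipeline is
benchmarked under:

| parameter | default | rationale |
|---|---|---|
| samples | 24 + 16 in two source groups, 3 blanks | typical two-source extract panel |
| features | 1600 | post-alignment table size |
| areas | log-normal, meanlog 10, sdlog 1.2 | heavy-tailed peak areas |
| batch shift | per-feature-per-group, sdlog 0.8 | drives the PCA group separation seen in real panels |
| missingness | 20% of background features "core" (5% missing); the rest patchy, presence 0–30% in one group, 20–100% in the other | group-dependent, so the each-group presence clause is genuinely exercised; leaves ~300–340 features after filtering |
| active spikes | 4, $\lvert r\rvert = 0.8$ to log IC50 (two of each sign), present everywhere, absent from blanks | the recovery targets |
| contaminants | 30, blank mean ≈ sample mean | designed to fail the 5-fold blank filter |
| IC50 | uniform on $\ln(57, 117)$ µg/ml | a broad medium-activity range without clustering; uniform stresses the regression across the whole range |
| viability noise | SD 2 percentage points, 5-dose grid {0, 25, 50, 100, 200} µg/ml, 3 plates | realistic MTT plate noise |

Active spikes are calibrated *exactly*: the noise component is
orthogonalized against the standardized signal and mixed as
$r\,s + \sqrt{1-r^2}\,e$, so the realized in-sample correlation equals
the target to machine precision, making recovery benchmarks
interpretable directly in $|r|$ units. Everything is driven by a single
integer seed and is bit-reproducible.

What the generator does **not** emulate: correlated feature blocks
(adducts, isotopologues, in-source fragments of one compound),
retention-time drift, censored (limit-of-detection) rather than
missing-at-random zeros, plate/batch effects in the bioassay, and
nonlinear concentration–activity relationships. Passing the spike-in
benchmark therefore shows the chain recovers *linear, well-detected*
activity signals against realistic background structure — it does not
show robustness to correlated redundancy or detection censoring in real
data.

## Numerical choices and degenerate inputs

- SDs use the $n-1$ denominator everywhere, matching common
  chemometrics software.
- PLS stops early (with a warning) if the deflated response becomes
  orthogonal to the remaining predictors; LOO folds that stop early
  reuse their last usable component.
- Lasso coefficients at $\lambda = \lambda_{\max}$ can carry
  $\sim 10^{-16}$ floating-point dust because the subgradient condition
  holds with equality there; callers counting nonzeros should threshold
  at, e.g., $10^{-10}$.
- The number of lasso nonzeros is monotone in $\lambda$ only for
  orthogonal designs; correlated designs can genuinely drop and
  re-admit a variable along the path (standard solvers reproduce the
  same behavior). Tests therefore check KKT conditions on general
  designs and monotonicity where it is a theorem.
- An all-constant table, a zero row sum in the Hellinger transform, a
  stratum too small to split, an empty lasso selection, and a feature
  set emptied by filtering all fail loudly with named offenders rather
  than propagating NaNs.
- `cv_percent` is undefined (NA with warning) when the observed range
  is zero; SR is undefined when $b = 0$ (error).

## Problem sizes used in the test suite

Oracle comparisons run on tiny instances (6×3 to 14×4) where brute-force
enumeration, normal equations, or naive refit loops are exact;
statistical properties use 20–100 seeded replicates at the panel scale
(40 samples, up to 1600 features); the end-to-end benchmark runs the
full pipeline across 20 generator seeds. These sizes were chosen so the
whole suite exercises every claim at the scale the method targets while
remaining comfortably reproducible on a laptop.

## Known limitations

- The filters' thresholds (5-fold, half-group presence) are assay-panel
  conventions, not optimized quantities; the trace and audit exist so a
  user can see what each choice cost.
- A single 80:20 split (not nested CV) reproduces the workflow it
  implements; reported test RMSEs are split-dependent.
- VIP/SR carry no significance calibration (no permutation test); they
  rank, they do not test.
- Annotation is similarity-only; identity requires standards or
  orthogonal evidence.
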