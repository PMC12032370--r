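---
title: "Statistical methods behind metabocross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind metabocross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabocross)
```

`metabocross` re-implements, as reusable and tested components, the
statistical pipeline of a targeted-metabolomics crossover trial comparing
occasional and chronic cannabis users under placebo-controlled acute
dosing: double cross-validated PLS-DA fingerprinting of user groups,
AR(1) mixed-model metabolite kinetics, change-score association models
linking metabolite shifts to attention and subjective intoxication, and
two-level hierarchical FDR control. Because trials of this kind rarely
deposit raw data, the package ships a synthetic-study generator that
emulates the design, so every stage can be exercised, calibrated, and
stress-tested end to end.

This vignette explains the models, the defaults and why they were chosen,
the numerical decisions, and what the simulation-based checks do and do not
establish.

## The synthetic study generator

`generate_study()` draws a complete two-group crossover: by default 18
occasional and 17 chronic users, each measured under placebo and active
treatment at 0, 10, 30, 50 and 70 minutes, over a 91-metabolite panel plus
22 ratio features.

**Baseline concentrations** are log-normal with moments matched to each
metabolite's configured per-group mean and SD (ng/mL): for target mean $m$
and SD $s$, $\sigma^2_{tot} = \log(1 + s^2/m^2)$ and
$\mu = \log m - \sigma^2_{tot}/2$. Concentrations are positive and
right-skewed, and several configured SDs approach or exceed half their
means, which rules out Gaussian draws. The total log-scale variance is
split into a between-subject random intercept and a within-subject
(measurement-to-measurement) part derived from `residual_cv` (default 0.1,
a typical targeted LC–MS/MS repeatability); the observed cross-sectional SD
of baseline draws therefore matches the configured value exactly. Fourteen
panel members carry the published per-group baseline means and SDs of the
discriminant metabolites; **every other parameter in the default panel is a
synthetic stand-in** (the trial's supplementary panel is not reproduced)
and is documented as such.

**Within-series noise** is stationary AR(1) on the log scale with lag-one
correlation `ar1_rho` (default 0.4, a moderate serial correlation for
blood draws 10–20 minutes apart). **Kinetic treatment effects** are
additive log-scale shifts at post-dose timepoints under the active
treatment: transient organic-acid elevations in occasional users (largest
for the ketone body, sustained across 10–70 min) and late-rising amino
acid elevations in chronic users, mirroring the qualitative kinetics the
trial reported.

**Behaviour**: attentional lapses are Poisson counts whose mean combines a
subject intercept, group-by-treatment multipliers (occasional users lapse
~2.5-fold more under active treatment, chronic users are nearly tolerant),
and — where configured — an *additive* coupling to the subject's
metabolite change score. Subjective high is a truncated linear 0–10
rating. The additive (identity-scale) coupling is a deliberate choice: the
downstream association models are Gaussian identity-link regressions of
Δ-behaviour on Δ-metabolite, and an additive generative coupling makes
their coefficient a well-defined estimand that simulation can verify with
proper confidence-interval coverage. A log-link coupling would make the
"true" coefficient depend on every subject's baseline rate and leave
nothing exact to recover.

What the generator does *not* emulate: instrument drift and batch
structure, missingness that is informative beyond left-censoring,
pharmacokinetics of the dosed compound (baseline THC is drawn log-normally
for chronic users only, as a covariate), correlated metabolite panels
(features are independent given group), and any real biochemical coupling
between panel members. Passing tests therefore demonstrate that the
*statistics* behave as designed under the assumed data-generating
mechanisms — not that the biology of a real cohort is captured.

## Preprocessing

The pipeline order is fixed and recorded: ratio features on the raw
concentration scale, natural log, Pareto scaling, then imputation —
matching the convention of imputing on log-transformed Pareto-scaled data.
Zeros are treated as below-quantification artefacts and set missing before
the log; negative values are schema errors. Pareto scaling divides each
centred feature by the square root of its sample SD (n−1 denominator), the
standard compromise that keeps high-abundance metabolites from dominating
without amplifying near-constant ones; constant features are dropped with
a warning. The recorded centres and scales invert the transform for
observed cells to within 1e−10 relative error.

Missing cells are filled by `impute_ppca()`, an EM algorithm around a
truncated SVD: the E-step replaces missing cells by their current
rank-$k$ reconstruction, the M-step refits the SVD (default $k$ = 5,
tolerance 1e−6 on the RMS change of imputed cells). Observed cells are
never altered, bit for bit. On noiseless low-rank data the completion is
exact; on correlated MCAR data it beats column-mean imputation — both
properties are asserted in the suite.

## PLS-DA, VIP, and the rdCV engine

`plsda()` fits two-class PLS-DA by NIPALS on the ±1 class coding
(occasional −1, chronic +1; prediction threshold 0, with exact zeros
falling to the majority training class — the groups are near-balanced at
17/18). For a single response the weight step is closed form,
$w_a \propto X_a' y_a$, followed by score computation and deflation of
both blocks. Each weight vector is sign-fixed (largest element positive)
so fits are reproducible. Per-component explained class variance is taken
from the deflation sequence, $SSY_a = q_a^2\, t_a' t_a$, and Variable
Importance in Projection is
$$\mathrm{VIP}_j = \sqrt{p \sum_a SSY_a\, w_{aj}^2 \Big/ \sum_a SSY_a},$$
whose squares average to one over the $p$ features. Both the NIPALS
decomposition and VIP are verified against independent oracles (explicit
eigen-decomposition PLS; brute-force formula re-evaluation) to 1e−8 and
1e−10.

`rdcv_plsda()` wraps this in repeated double cross-validation with
recursive feature elimination: 20 repetitions of 7 stratified outer folds;
within each outer training set, 6 inner folds walk an elimination ladder
that keeps the top 80% of features by VIP per step down to a 2-feature
floor. The panel size and component count (up to 3) are chosen jointly as
the pair minimising mean inner misclassification, with ties resolved to
the smaller panel and then the simpler model; the chosen panel is refit on
the outer training set and applied to the held-out subjects. Fold counts
follow from the cohort size: 7 outer folds keep at least two subjects per
class in every training set at n = 35. Aggregation is per-sample majority
vote across repetitions; the 95% interval is the 2.5/97.5 percentile range
of per-repetition rates (a resampling interval, not a binomial one); the
consensus ranking is the mean elimination rank over all 140 outer models;
and the consensus panel size is the median of the 140 chosen sizes.

Two behaviours of this procedure deserve honesty. First, the
majority-vote rate typically sits at or above the upper percentile of
per-repetition rates — the vote washes out fold noise — so the point
estimate and the interval answer slightly different questions. Second,
with ~30 training subjects an inner validation fold resolves error only in
steps of 1/30, so the inner error curve is flat and noisy across panel
sizes; the argmin therefore varies widely between outer folds (single-run
medians from 6 to 36 under the default conditions). The procedure ranks
informative features far above noise very reliably, but the *size* at the
error minimum is only loosely identified at this cohort size — a known
property of minimum-CV-error selection, not an implementation defect.

`permutation_test()` re-runs the whole engine under uniformly permuted
labels (5 repetitions per permutation, 200 permutations) and reports
$p = (1 + \#\{\text{permuted} \ge \text{observed}\})/(201)$, floored at
1/201 by construction.

## Metabolite kinetics: AR(1) mixed models

`fit_metabolite_mixed()` models one metabolite's post-dose log
concentrations within one user group: fixed effects for Treatment,
categorical Time and their interaction, a subject random intercept, and
AR(1) correlation within each subject-by-treatment series, fit by REML via
`nlme::lme`. The trial's description lists Time with five levels
*including* baseline while also using the baseline as a covariate, which
is collinear; the package resolves this by modelling post-dose times
(10–70 min) and offering the series' time-0 value either as a covariate
(default) or subtracted from the response (`baseline_mode = "subtract"`,
the baseline-corrected analysis). Neither is asserted to be the original
model. With a single post-dose timepoint the Time terms drop and the AR(1)
structure is omitted (one observation per series).

Each fixed term is summarised by a Wald chi-square
$W = \hat\beta' V^{-1} \hat\beta$; Gaussianity on the log scale is assumed
(the concentration response is conventionally log-normal), and no
denominator-degree-of-freedom correction is applied. The headline p-value
of `run_timeseries_screen()` is the Treatment main effect (df 1), with the
interaction reported and adjusted alongside: the reported statistics of
the trial (e.g. W ≈ 7.4 printed with an FDR-adjusted p ≈ 0.03) are only
arithmetically consistent with a 1-df term, since a 4-df interaction with
that W has raw p ≈ 0.11, which no adjustment can lower. Per-timepoint
active-minus-placebo contrasts are formed from the coefficient covariance
when the interaction is significant.

One subtlety: when the baseline covariate is itself a noisy draw of the
series (as in the generator), conditioning on it leaves a small
series-level correlation that the AR(1) term legitimately absorbs, so the
estimated rho exceeds the generator's noise rho. The estimator is
validated against an explicit GLS oracle (block covariance built from the
fitted variance components) to 1e−4, and its rho is checked on a
correctly specified design.

## Change-score associations

`compute_deltas()` forms active-minus-placebo behavioural change scores
(lapses at 10/30 min, subjective high at 20/40 min) and post-minus-baseline
metabolite change scores within the active session at 10/30 min (a
placebo-corrected variant is available; the original computation is
ambiguous on this point and neither mode is asserted). Subjective-high
deltas at 20/40 min are paired with the metabolite deltas at the nearest
preceding blood draw (10/30 min). `fit_delta_association()` regresses the
behavioural delta on the metabolite delta with age, sex and baseline THC
as covariates — Gaussian identity link, since deltas are signed and no
family was specified for the original models. Constant covariates (THC is
identically zero in occasional users) are dropped and recorded; strata
with fewer than 6 complete cases are reported as not estimable rather than
fitted.

## Hierarchical FDR

`hierarchical_fdr()` implements the two-level family-wise scheme: family
p-values by Simes combination, Benjamini–Hochberg across families at
q = 0.05, then BH within selected families at level
$q \cdot n_{selected}/n_{families}$. Families default to the panel's
chemical family labels (aromatic amino acid metabolism, ceramides,
endocannabinoids, ...), a configurable choice since the original family
partition is unstated. Simes is valid under within-family positive
dependence, which is the expected regime for co-regulated metabolites.
With a single family the procedure reduces bitwise to plain BH. Reported
per-hypothesis adjusted values are within-family BH values inflated by
$n_{families}/n_{selected}$ and floored at the family-level adjusted p, so
`p_adj <= q` reproduces the selection-path rejections exactly.

## Problem sizes, seeds, and what the checks mean

All randomness flows from explicit seeds; study generation, the rdCV
engine, and the permutation test draw from named substreams so stages are
independently reproducible. The simulation suites run at sizes chosen to
make their Monte-Carlo error small relative to the tolerance being
asserted: 10,000 draws for generator moment matching (3 standard errors),
10,000 series for AR(1) calibration (±0.02), 200 replicates for
confidence-interval coverage, 500 replicates for FDR-control proportions,
and 60 replicates for mixed-model type-I calibration.

Because a single 35-subject study is itself a noisy draw — observed
classification rates across seeds span the mid-60s to 100% — the headline
classification-rate check summarises ten independent study draws by their
median rather than betting on one seed; the panel-size check uses the same
ten draws. Exact panel-size recovery (selecting precisely the 14
informative features) is *not* achieved by minimum-inner-error selection
at this cohort size, for the flat-error-curve reason described above; the package reports
this honestly rather than tuning the generator or the selection rule
toward it.

## Known limitations

- Feature panels are simulated independent within group; correlated
  metabolite blocks (which would make VIP ranks less stable) are not
  emulated.
- The permutation test reuses reduced repetitions (5) per permutation for
  tractability; a sensitivity run at the full 20 is a config change away.
- No Kenward–Roger/Satterthwaite corrections; Wald chi-squares are mildly
  liberal at these group sizes.
- The EM-PCA imputer assumes approximately low-rank structure after
  scaling; rank selection is fixed (default 5), not cross-validated per
  dataset.
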