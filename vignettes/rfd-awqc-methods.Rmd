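---
title: "From molecular descriptors to water quality criteria: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From molecular descriptors to water quality criteria: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfdcriteria)
```

## The problem

Oral reference doses (RfD, mg·kg⁻¹·d⁻¹) anchor non-carcinogenic human
health risk assessment, but deriving one experimentally takes years of
animal dosing studies; only a few hundred chemicals have one. For
pesticide-class chemicals, toxicity tracks molecular structure closely
enough that a quantitative structure–activity relationship (QSAR) can
stand in where data are missing. `rfdcriteria` implements that chain
end to end: a screened stepwise multiple linear regression (MLR) of
−log₁₀(RfD) on molecular descriptors, a validation suite, and the
regulatory downstream — ambient water quality criteria (AWQC) through
trophic-level bioaccumulation factors, and hazard-quotient risk
categories for monitoring data.

## The regression model

The response is y = −log₁₀(RfD): doses span four-plus orders of
magnitude and multiplicative errors are the natural scale. The model is
affine in raw (unstandardized) descriptor values,

$$ y = \beta_0 + \sum_j \beta_j x_j + \varepsilon,
   \qquad \varepsilon \sim N(0, \sigma^2), $$

fitted by ordinary least squares via QR decomposition. Descriptors are
left unstandardized because published equations of this kind print
coefficients on raw descriptor units; `published_rfd_model()` ships one
such 12-descriptor equation (intercept 1.468) exactly as printed, for
use as a preset when the descriptor table supplies its terms.

### Descriptor screening

Descriptor generators emit hundreds of columns, many degenerate. Three
rules run, in order, before any model building:

1. **zero variance** — sample variance ≤ `variance_epsilon` (default 0);
2. **sparsity** — fraction of non-zero entries strictly below
   `nonzero_fraction_min` (default 10%; entries with |x| ≤ 1e−12 count
   as zero to absorb float dust). The boundary is strict, so a column
   with exactly 10% non-zeros is retained;
3. **correlation** — pairs with |Pearson r| > `corr_threshold` (default
   0.90, absolute value: a −0.95 correlation duplicates information as
   much as +0.95) lose one member.

Which member of a correlated pair to drop is a genuine design choice,
as the rule itself underdetermines it. We drop the member with the
smaller |correlation to the response| when a response is supplied
(keeping the more predictive column), otherwise the member with the
larger mean absolute correlation to everything else; remaining ties
drop the lexicographically later name under C-locale ordering, so the
result is identical across platforms. Pairs are scanned greedily in
column order and dropped columns leave the scan. The composition is
idempotent, and a column removable by two rules is attributed to the
earliest stage — both properties are asserted in the test suite.

### Stepwise selection

`fit_stepwise()` is classical forward–backward selection driven by
partial-F p-values (equivalently squared-t, 1 numerator df): the best
excluded descriptor enters while its p-value is below `p_enter`
(default 0.05), and after each entry any included descriptor with
p above `p_remove` (default 0.10) leaves, worst first. The defaults are
the long-standing defaults of mainstream statistics packages for this
procedure; entry must be stricter than removal or a term could cycle.
Ties among candidates break by larger |t|, then column order. Every
move is logged with its p-value and the adjusted R² after the move;
`model_size_curve()` exposes the adjusted-R²-versus-size path used to
judge where additional terms stop paying for themselves.

**What "recovery" means here.** On synthetic data with a known sparse
truth, one should ask of stepwise selection that it find every true
term, not that it find *only* the true terms. Each entry scan compares
the minimum of m null p-values against `p_enter`, so even a perfect
dataset admits a spurious term with probability ≈ 1 − (1 −
p_enter)^m per scan; with 35 noise candidates at p_enter = 0.05 the
probability of a completely clean selection is about 0.17, and no
threshold choice fixes this without also throwing away weak true terms.
Our recovery tests therefore assert (a) the true support is contained
in the selection in ≥ 90% of seeds, (b) coefficient RMSE on the true
terms ≤ 0.1, and (c) the spurious-term count stays near the
m·p_enter rate — the three properties a practitioner actually relies
on.

### Predictions and adoption

`predict_neg_log_rfd()` refuses missing descriptors rather than
zero-filling: a zero is a valid descriptor value, so silence would be a
wrong answer, not a default. `neg_log_to_rfd()` inverts the transform
and `adopt_rfd()` rounds to one significant figure, the convention
under which a predicted 0.01271 mg·kg⁻¹·d⁻¹ is adopted as 0.01. No
applicability-domain check is applied — the upstream method defines
none — so predictions for chemicals far outside the training space are
the caller's responsibility.

## Validation statistics

All diagnostics are computed from first principles and each is tested
against an independently coded oracle (explicit refit loops, `lm()`
auxiliary regressions, closed forms):

* R², adjusted R² and RMSE from their definitions; RMSEP is the test-set
  RMSE, reported separately from training RMSE.
* Durbin–Watson `Σ(eₜ−eₜ₋₁)²/Σeₜ²` for residual serial correlation;
  ~2 means none, 1.5–2.5 is the customary acceptance band.
* Variance inflation factors 1/(1−R²ⱼ); perfect collinearity reports
  `Inf` rather than erroring, since an infinite VIF *is* the diagnosis.
  (Source material in this field sometimes writes "VIP" while
  describing variance inflation with a threshold of 5; VIP proper is a
  PLS quantity that has no place in an OLS pipeline, so the function is
  named `vif`.)
* q² = 1 − PRESS/SS_tot over the training set. Leave-one-out is the
  default scheme because it is deterministic; k-fold is available with
  a recorded seed. The implementation refits per fold; the test oracle
  is a separate explicit loop.
* Roy's k and k′, the origin-forced slopes of observed-on-predicted and
  predicted-on-observed. Bounds default to [0.85, 1.15], the standard
  form of the criterion; both bounds are configurable and recorded in
  the pass flag's metadata.
* Fold coverage: the fraction of chemicals with
  max(pred/obs, obs/pred) ≤ f, boundary inclusive ("within a factor of
  f" is read inclusively, which makes >95%-within-10× claims
  well-defined). Coverage is non-decreasing in f by construction.

## Criteria derivation

For a non-ionic organic chemical, the human-health criterion aggregates
drinking water and aquatic-product consumption:

$$ AWQC = \frac{RfD \cdot RSC \cdot BW}{DI + \sum_{i=2}^{4} FI_i \cdot BAF_i} $$

with body weight BW (kg), drinking-water intake DI (L·d⁻¹), intake FIᵢ
(kg·d⁻¹) and bioaccumulation factor BAFᵢ (L·kg⁻¹) per trophic level
i ∈ {2,3,4}, and relative source contribution RSC allocating a fraction
of the RfD to waterborne routes. The BAFs come from laboratory
bioconcentration factors via lipid and freely-dissolved normalization:

$$ f_{fd} = \frac{1}{1 + POC \cdot K_{ow} + 0.08 \cdot DOC \cdot K_{ow}},
\qquad BL_{BAF} = FCM \cdot \left(\frac{BCF}{f_{fd}} - 1\right) \frac{1}{f_l},
\qquad F_{BAF} = (BL_{BAF} \cdot f_l + 1) \, f_{fd}. $$

Two numerical choices deserve note:

* **The baseline-BAF parenthesization** is not typographically
  recoverable from the source material. The form above is adopted
  because it is the only placement under which a *single* back-solved
  BCF per chemical reproduces all six published baseline-BAF cells of
  the worked example (two chemicals × three trophic levels) within
  0.5%; the alternatives fail that consistency check by orders of
  magnitude. `solve_bcf_from_baseline()` performs the inversion and the
  acceptance suite re-runs the full check.
* **POC/DOC are config inputs**, never defaulted silently: the worked
  examples publish only the resulting freely dissolved fractions, from
  which only the combined term POC + 0.08·DOC is recoverable
  (`solve_organic_carbon_term()`). `derive_criteria()` therefore also
  accepts a published `f_fd` directly. Back-solving the term from one
  chemical predicts the other chemical's published fraction within
  2.5%, which is the self-consistency the tests assert.

The adopted criterion is reported in µg·L⁻¹ at one significant figure
alongside the exact mg·L⁻¹ value. Published worked examples mix rounded
and unrounded RfDs between chemicals (one criterion needs the unrounded
model prediction 0.01271, the other the adopted 0.0002); `derive_awqc()`
takes whatever RfD the caller supplies and the shipped fixture files
encode each chemical's published choice, with comments.

## Risk categorization

HQ = EEC/AWQC after an internal ng→µg conversion (monitoring tables are
ng·L⁻¹, criteria µg·L⁻¹; the units are fixed deliberately). The four
bins are [0, 0.1) no risk, [0.1, 1) low, [1, 10] intermediate,
(10, ∞) high. The published bin statement overlaps at 1 and 10; we
resolve boundaries upward, to the more protective category, and record
the rule identifier in every summary output. Site summaries report
per-category fractions (which sum to one exactly) and the HQ of the
median concentration — midpoint convention for even counts — as the
headline exposure level. Note that the source material's running text
and conclusions disagree about which worked-example chemical is "no
risk" versus "lower risk"; under the stated bins, HQ 0.13 is low risk
and HQ 0.08 is no risk, and that is what `classify_risk()` returns.

## The synthetic world

`synthetic_spec()` states the conditions the pipeline assumes rather
than tuning toward any outcome: 109 chemicals (the modelled dataset
size), Gaussian noise with SD 0.434 on the −log₁₀ scale (the reported
external prediction error, i.e. tests run at the real problem's
difficulty), intercept 1.468, a 3-term support with coefficients of
order 1 (the magnitude range of the published equation), and 50
descriptor columns — a deliberate scale-down from the several hundred
of a real descriptor export, chosen to keep the 50-seed recovery
experiment inside seconds; the screening rules and selection mechanics
are column-count-agnostic. Degenerate columns (3 constant, 4 sparse at
5% support, 5 exact duplicates) exercise every screening rule;
duplicates copy *trailing* regular columns so a support column can
never lose its name to its own duplicate in the correlation filter.
Five columns are Poisson counts, mimicking atom-count descriptors.
Marginals are otherwise Gaussian — real descriptors are mixed-type and
heavy-tailed, but screening and OLS are distribution-agnostic, so a
green test here establishes correctness of the mechanics, not
performance on any real chemical space. Monitoring concentrations are
lognormal with defaults spanning roughly 0.002–140 ng·L⁻¹, the span of
published organochlorine surveys, so generated tables straddle several
risk bins.

Every generator is a pure function of its spec and seed (response noise
uses `seed + 1` so matrix and response draws never alias).

## Known limitations

* The package consumes descriptor tables; it does not compute
  descriptors from structures (SMILES handling and descriptor physics
  are out of scope).
* No applicability-domain machinery, regularized alternatives, or
  Y-randomization; stepwise MLR is implemented as practiced, with its
  known appetite for a few spurious terms.
* Published data-dependent statistics of the original 109-compound
  model (R² 0.762, q² 0.648, etc.) cannot be reproduced without that
  dataset; the tests instead prove every statistic against independent
  oracles and run the pipeline on the synthetic stated world.
* Carcinogenic (slope-factor) criteria, field-measured BAF routes, and
  probabilistic exposure assessment are out of scope.
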