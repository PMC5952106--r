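---
title: "Methods: imputation and classification of reading profiles under missingness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imputation and classification of reading profiles under missingness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multi-site behavioral datasets assembled retrospectively — for instance
reading-disability cohorts pooled across research sites — rarely have a
complete test battery for every child, because assessment plans differed by
site. Children with reading disability are heterogeneous: some show a
specific phonological decoding deficit (Poor Decoders), some a
comprehension-specific deficit with relatively preserved decoding (Poor
Comprehenders), some low performance across reading and cognitive measures
including Verbal IQ (Generally Poor Readers), alongside typically reading
Controls. Classifying these profiles requires the joint pattern across
tests, so a single missing score can be critical; listwise deletion discards
large, non-random portions of the sample.

`miprofile` implements a simulation framework to quantify that problem and
an analysis pipeline to address it: generate labeled cohorts with a known
profile structure, remove scores under a controlled missing-at-random (MAR)
mechanism, impute with competing methods, classify with a random forest, and
pool multiply-imputed results with Rubin's rules.

## Data model

One row per participant: a unique `id`; always-observed covariates `sex`
(F/M) and `site` (8 levels by default, up to 11 supported); `age` in years;
five classification scores on the standardized mean-100 / SD-15 scale
(`pseudoword_id`, `real_word_id`, `passage_comp`, `verbal_iq`, `ran`);
optional validation scores (`piq`, `spelling`, `elision`, `digit_span`); an
optional 4-level profile label. Missing cells are explicit `NA`s,
serialized as empty strings in CSV ("NA"/"NaN" accepted on read). Scores
stay continuous throughout — imputed values are never rounded, because
pooled estimates are fractional by nature.

## The cohort generator

`generate_profile_cohort()` draws each profile's (age, five scores) from a
multivariate normal. The default configuration emulates a training cohort of
198 children (58 Poor Decoders, 27 Poor Comprehenders, 14 Generally Poor
Readers, 99 Controls; 78 female; 8 sites; ages centered at 9.6 y, SD 1.6).
Published sources for such cohorts report the profile structure graphically
rather than as tables of means, so the default mean vectors are a design
choice that encodes the qualitative structure:

* Poor Decoder (76, 87, 90, 100, 92): decoding deficit with pseudoword
  reading lowest, preserved Verbal IQ.
* Poor Comprehender (95, 95, 80, 88, 92): passage comprehension primary,
  decoding relatively preserved, mild oral-language weakness.
* Generally Poor Reader (76, 82, 78, 80, 88): parallel to the Poor Decoder
  profile on decoding and rapid naming but with distinctly low Verbal IQ —
  Verbal IQ is what separates these two profiles, so its absence should be
  (and is) the costly one.
* Control (104, 105, 104, 104, 103): at or above the population mean on
  every measure, hence redundantly separated from each disability profile —
  no single missing score is critical for Controls.

Within-profile SDs are 9 score points (narrower than the population 15,
as expected within diagnostic groups). Tests correlate at 0.5, the decoding
pair (pseudoword/real word) at 0.7 — typical magnitudes for standardized
reading and cognitive batteries, and deliberately informative: covariance
between tests is exactly what imputation exploits. Age correlates with the
standardized scores at only 0.1 (standardization removes most age effects).
Sites shift all five test means by at most ±3 points (0.2 population SD),
enough to make site a usable covariate without disturbing the profile
structure; sex and site are assigned independently of the scores so that
covariate-driven missingness is MAR by construction, not MNAR.

The one free scalar is `separation_scale`, a multiplier on every profile's
test-mean deviation from 100. `calibrate_separability()` fixes it by
bisection so that the leave-one-out accuracy of the reference classifier
(mtry = 2, 500 trees) on a generated 198-row cohort hits a target — 0.94 by
default, anchoring the generator's free parameters to the one printed
accuracy figure available. The bisection tolerance is 0.01 (about two
misclassified children out of 198); the search is deterministic given the
seed and errors out, reporting the best value reached, if the target is
unreachable.

## Synthetic replicate datasets

`synthesize_dataset()` produces datasets of 500 rows (125 per profile, by
default) from a source cohort by sequential conditional synthesis, the
regression-based scheme used by data-synthesis tools: labels first, then
sex and site drawn frequency-matched within label, then age and the five
tests in a fixed order, each modeled within label by linear regression on
the previously visited continuous variables and drawn as fitted value plus
a resampled residual. Normal-linear conditionals with residual resampling
were chosen over tree-based conditionals because their moments can be
checked in closed form against the source (the tests do exactly that); the
source's within-profile means, variances and correlations are preserved in
expectation. A disclosure guard redraws any synthetic row whose five test
scores coincide exactly with a source row — with continuous residuals this
is a vanishingly rare event, but the property is asserted, not assumed.

## The MAR mechanism

Exactly three of the six classification features (age + five tests) carry
missingness in any one simulated dataset; with only three eligible columns,
no participant can lose more than three values. For each selected variable,
each cell is missing independently with probability
`plogis(intercept + 0.8 * female + site_effect)`, with per-site log-odds
spread evenly over [-1, 1] by default. The intercept is solved by bisection
(tolerance 1e-6) so the expected missing fraction per selected variable
equals the target rate, one of {0, 0.1, 0.2, 0.3, 0.4, 0.5}. "Percent
missingness" is interpreted per selected variable (so 50% is feasible under
the three-variable design); a `rate_denominator` reading over all six
features would halve the nominal levels and can be emulated by doubling the
rate. The three variables are re-drawn per simulated dataset by default;
fixed selections are supported for conditional analyses and null
calibrations.

`verify_mar()` fits logistic regressions of each missingness indicator on
sex and site, reporting likelihood-ratio p-values per term and Nagelkerke's
R². Because the three selected variables share a single propensity model,
an `overall` fit on the stacked indicators is also reported; this
mechanism-level test has three times the effective sample size and is the
one used to assert that sex and site predict missingness at p < 0.01 — at a
10% rate a per-variable fit has only ~50 events and unreliable power at the
default coefficient sizes. Complete separation (e.g., missingness fully
determined by site) is detected and flagged; the pseudo-R² is then computed
from a ridge-penalized fit (IRLS, penalty 1e-3) so it remains finite, and
the default coefficients were chosen large enough that verification
succeeds reliably at N = 500 without being degenerate.

## Imputation methods

All three methods see age, the five tests, sex and site — never the profile
labels and never the validation scores. That concealment is structural (the
internal imputation frame simply does not contain those columns) and
asserted by tests: imputations are bit-identical when labels are shuffled
or validation columns added.

**Mean replacement** substitutes the observed mean of each variable;
deterministic, one completed dataset. Its efficiency (below) is
analytically ≈ 1 − rate, which the tests use as an oracle.

**Predictive mean matching** is a chained-equations scheme: initialize
missing cells with random draws from the observed values; for 5 cycles,
regress each incomplete variable on the other features (current completed
values), perturb the coefficients with a normal draw from their estimated
sampling covariance, and replace each missing cell with the observed value
of one of the 5 donors with nearest perturbed predictions, drawn uniformly.
Donor count and cycle count are the conventional chained-equations
defaults. Rank-deficient regressions are ridge-stabilized and flagged.
Imputed values are always members of the observed-value set.

**Iterative random-forest imputation** (missForest-style): initialize with
observed means, order incomplete variables by ascending missingness, and
sweep: fit a random-forest regression of each incomplete variable on the
others and re-predict its missing cells. After each sweep the change
statistic Δ = Σ(x_new − x_old)² / Σ x_new² over imputed cells is computed;
iteration stops when Δ first increases, returning the previous sweep's
values (or at `max_iter`). The algorithm is natively single-imputation; the
m = 10 datasets are independent runs differing only in the forests' RNG
streams, which is the only mechanism consistent with the method's
definition. Defaults are 100 trees and at most 10 sweeps per forest;
imputation quality is flat in tree count well below that, which is why the
desk-scale grids use smaller forests (below).

**Efficiency** is the full-column variance of an imputed variable divided
by the variance of the original complete variable (1 is ideal; < 1 means
variance shrinkage), averaged over the m completed tables of a set.
Full-column rather than imputed-cells-only variance matches the diagnostic
this ratio is meant to reproduce.

## The classifier

A random forest over age and the five test scores only — sex and site
inform imputation but never classification. Default hyperparameters are
mtry = 2 and 500 trees; `train_classifier()` can instead tune mtry over
1–6 by stratified 5-fold cross-validation repeated 10 times. Multiply
imputed datasets are classified per imputation; consensus labels are the
modal label per row with ties broken by the fixed priority Control >
PoorDecoder > PoorComprehender > GenerallyPoorReader (ties are counted and
reported). Per-imputation profile counts are summarized as mean ± SD, which
is the natural multiply-imputed summary; both per-imputation and consensus
labels are emitted because published analyses do not always say which was
used. Confusion metrics are one-vs-rest sensitivity and specificity per
class plus overall accuracy; a class absent from the truth yields NA
sensitivity rather than a silent 0. Class imbalance (99 vs 14 in the
training cohort) is deliberately left unweighted.

## Pooling rules

`rubin_pool()` combines m estimates and within-imputation variances:
Q̄ = mean, W = mean variance, B = between-imputation variance,
T = W + (1 + 1/m)B. Degrees of freedom use the small-sample
(Barnard–Rubin) adjustment with r = (1 + 1/m)B/T:
ν_large = (m − 1)/r², ν_obs = ((ν_com + 1)/(ν_com + 3)) ν_com (1 − r),
ν = ν_large ν_obs / (ν_large + ν_obs) — fractional df, as pooled analyses
report. B = 0 reproduces complete-data inference exactly; m = 1 warns and
falls back to the complete-data test (Welch t, Pearson r with n − 2 df),
which the tests check against the textbook implementations.

Pooled t-tests use the Welch variance per imputation by default (a
pooled-variance option exists, under which F = t² for two groups — an
identity the tests exploit). Cohen's d is the mean difference over the
pooled-across-groups SD, averaged over imputations; the d variant is not
standardized in the literature this mirrors, so the simplest one is used.
Correlations are pooled on the Fisher-z scale with variance 1/(n − 3),
keeping |r| ≤ 1 after back-transform. One-way ANOVAs are pooled by
reporting the across-imputation mean F (with its SD) and mean η²; a
multivariate combining rule would be less transparent about between-
imputation spread, and the η² effect size is the quantity of scientific
interest. Post-hoc profile orderings use Tukey HSD at α = 0.05, retaining
relations that hold in at least half the imputations.

## The simulation grid

`run_simulation_grid()` crosses replicate synthetic datasets with
missingness rates and imputation methods. Per replicate: synthesize
N = 500; classify the complete data once (the shared 0% baseline for all
methods); per rate, induce MAR with a per-replicate variable selection and
a per-rate intercept; per method, impute (m = 10 for the two
multiple-imputation methods), classify each completed table, and average
metrics over imputations. Failures are isolated per grid cell. Everything
derives from one root seed through a fixed splitting scheme
(`child_seed()`), so the entire grid is bit-reproducible.
`conditional_accuracy()` pools per-profile accuracy reductions over the
replicates in which a given variable was among the selected missing
variables (marginal attribution; a replicate missing three variables
contributes to all three cells — the joint/marginal distinction is an open
choice, and the underlying per-replicate records are kept so either can be
computed). `run_real_style_pipeline()` applies the same machinery to a
train/test split with real-style missingness, alongside a complete-case
(listwise-deletion) branch and pooled validation ANOVAs.

## Problem sizes and numerical choices

The reference study design uses 1,000 replicate datasets. The package's own
verification runs at desk scale: 100 replicates, rates {0.2, 0.3, 0.5},
m = 10, imputation forests of 25 trees with at most 5 sweeps in the test
suite (50 trees, 10 sweeps in the acceptance script); standard errors are
therefore about √10 larger than at full scale, and the tests' margins
account for that. The null-calibration check (type-I error of pooled
t-tests under MAR at 30% with PMM, m = 10) runs its full 1,000 replicates
because each is cheap. Other numerical choices: MAR intercepts by bisection
to 1e-6; PMM ridge stabilization triggered only on Cholesky failure;
separation in logistic verification detected via the glm warning or
coefficients beyond ±15; label ties broken by the fixed priority above;
zero-variance originals yield NA efficiency rather than an error.

## What the generator does and does not emulate

The synthetic cohorts reproduce: the four-profile mean structure and its
calibrated separability, multivariate-normal within-profile covariance,
realistic test intercorrelations, multi-site nuisance shifts, sex/site
covariates independent of scores, and MAR missingness driven by those
covariates. They do not reproduce: skewed or floor-censored score
distributions, site-by-profile confounding (sites sample profiles
identically here), age-varying profile structure, MNAR mechanisms
(explicitly out of scope), or item-level missingness within a test.
Passing results therefore show that the pipeline behaves correctly under
the stated MAR model — not that imputation is safe when missingness depends
on the unobserved values themselves, and not that any individual child can
be classified clinically: the pipeline is designed for group-level
inference only.

One structural property of the default generator is worth knowing when
interpreting conditional-accuracy surfaces: the Poor Decoder profile sits
on two discriminative axes — pseudoword reading separates it from Poor
Comprehenders, Verbal IQ from Generally Poor Readers — so the accuracy
cost of losing pseudoword reading and of losing Verbal IQ are comparable
for that profile (the simulation grids measure them as statistically
indistinguishable). For Poor Comprehenders, pseudoword reading is
unambiguously the costliest missing variable; for Generally Poor Readers,
Verbal IQ is.
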