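# miprofile

Reading-profile classification under missing data, with multiple
imputation.

Children with reading disability are heterogeneous: Poor Decoders
(phonological decoding deficit with preserved Verbal IQ), Poor
Comprehenders (comprehension-specific deficit), Generally Poor Readers
(low across reading and cognitive measures) and Controls. The profiles can
be classified from five standardized scores — pseudoword reading, real-word
reading, passage comprehension, Verbal IQ, rapid naming — but retrospective
multi-site datasets are riddled with missing scores, and listwise deletion
discards much of the sample non-randomly. `miprofile` is a simulation and
analysis framework for that setting, aimed at biostatisticians and reading
researchers working with pooled multi-site cohorts.

The package provides, end to end:

* a labeled cohort generator with four-profile multivariate-normal
  structure, whose between-profile separation is **calibrated** so that a
  random forest (mtry = 2, 500 trees) reaches a target leave-one-out
  accuracy (default 94%) on a 198-row training cohort;
* synthpop-style sequential-conditional **synthesis** of replicate datasets
  (default N = 500, 125 per profile) preserving the source's correlation
  structure, with a disclosure guard;
* a logistic **missing-at-random mechanism**: exactly 3 of the 6
  classification features carry missingness, with propensity
  `logit(p) = α + 0.8·female + site effect`, intercept solved so the
  expected missing fraction equals a target rate in {0, 0.1, …, 0.5}, plus
  statistical verification (likelihood-ratio tests, Nagelkerke R²);
* three **imputation methods** behind one interface — mean replacement,
  predictive mean matching by chained equations, and iterative
  random-forest imputation with the Δ-increase stopping rule — with the
  efficiency diagnostic `E_v = Var(imputed v) / Var(original v)`;
* a random-forest **profile classifier** (features: age + 5 scores; never
  sex/site/labels), per-imputation and consensus labels, and one-vs-rest
  confusion metrics;
* **Rubin's-rules pooling** (`T = W + (1 + 1/m)B`, Barnard–Rubin fractional
  df) for t-tests, Fisher-z correlations, one-way ANOVA/η² and group means;
* an **experiment orchestrator** crossing replicates × rates × methods,
  with conditional (profile × missing-variable) accuracy surfaces and a
  real-style train/impute/classify pipeline with a complete-case branch.

## Worked example

```r
library(miprofile)

cal <- calibrate_separability(default_cohort_config(), target_accuracy = 0.94)
#> calibrated separation scale: 1.375 (LOO accuracy 0.939)
cohort <- generate_profile_cohort(cal$config, seed = child_seed(cal$config$seed, 1))
cohort
#> <behavioral_table> 198 participants, 8 sites; profiles: PoorDecoder=58
#> PoorComprehender=27 GenerallyPoorReader=14 Control=99; missing cells: 0

model <- train_classifier(cohort, seed = 404, mtry = 2)
syn <- synthesize_dataset(cohort, seed = 42)        # N = 500, 125/profile
mr <- induce_mar(syn, mar_mechanism(0.3, seed = 43))
mr$mechanism$selected_variables
#> real_word_id verbal_iq age            # 3 variables, re-drawn per dataset
verify_mar(mr)$overall
#>      p_sex   p_site nagelkerke separation
#> 1 2.22e-13 1.71e-22      0.152      FALSE

imps <- impute_missforest(mr$table, m = 10, seed = 44)
round(efficiency(imps, syn, mr$mechanism$selected_variables), 3)
#> real_word_id    verbal_iq          age
#>        0.898        0.914        0.697

res <- classify_imputed(model, imps, baseline = syn)
res$profile_counts
#>                 profile mean    sd
#>             PoorDecoder  121 0.789
#>        PoorComprehender  121 0.483
#>     GenerallyPoorReader  127 0.000
#>                 Control  132 0.527
```

Reading the output: the calibrated generator puts the training cohort at
93.9% leave-one-out accuracy; sex and site strongly predict the induced
missingness (p ≪ 0.01, MAR verified) while the mechanism never looks at
the scores themselves; forest imputation retains ~90% of the original
score variance at a 30% missing rate; and the per-imputation profile
counts are stable across the 10 imputations (SD ≤ 0.8 of a count). On this
dataset the classification accuracy fell from 0.950 on the complete data
to 0.943 averaged over the 10 imputed versions — a 0.7-point cost for 30%
missingness in three variables.

For a full study, `run_simulation_grid()` repeats this over many synthetic
datasets and all rates/methods, and `summary()` / `conditional_accuracy()`
/ `report()` produce the efficiency curves, degradation curves and
profile-by-variable surfaces.

## Scope

The package studies missing-at-random mechanisms only (missingness driven
by observed covariates); MNAR is out of scope by design. It is built for
group-level inference — it is not a clinical instrument for classifying an
individual child.
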