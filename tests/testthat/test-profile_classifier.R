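test_that("confusion metrics agree with brute-force counting", {
  with_seed(77, {
    for (i in 1:5) {
      truth <- sample(profile_levels(), 60, replace = TRUE)
      pred <- sample(profile_levels(), 60, replace = TRUE)
      cm <- confusion_metrics(pred, truth)
      expect_equal(cm$accuracy, sum(pred == truth) / 60)
      for (cl in profile_levels()) {
        tp <- sum(pred == cl & truth == cl)
        fn <- sum(pred != cl & truth == cl)
        fp <- sum(pred == cl & truth != cl)
        tn <- sum(pred != cl & truth != cl)
        if (tp + fn > 0) {
          expect_equal(unname(cm$sensitivity[cl]), tp / (tp + fn))
        }
        expect_equal(unname(cm$specificity[cl]), tn / (tn + fp))
      }
    }
  })
})

test_that("degenerate predictions give the expected metrics", {
  truth <- rep(profile_levels(), each = 10)
  pred <- rep("Control", 40)
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$accuracy, 0.25)
  expect_equal(unname(cm$sensitivity["Control"]), 1)
  expect_equal(unname(cm$specificity["Control"]), 0)
  expect_equal(unname(cm$sensitivity["PoorDecoder"]), 0)
  # class absent from truth -> sensitivity undefined
  cm2 <- confusion_metrics(rep("Control", 10), rep("Control", 10))
  expect_true(is.na(cm2$sensitivity["PoorDecoder"]))
  expect_equal(cm2$accuracy, 1)
})

test_that("a perfectly separated cohort is classified perfectly", {
  coh <- generate_profile_cohort(toy_separated_config(n_per_profile = 20))
  model <- train_classifier(coh, seed = 2, mtry = 2)
  expect_equal(confusion_metrics(classify(model, coh), coh$label)$accuracy, 1)
  # one row at a profile's exact mean vector gets that profile's label
  for (p in profile_levels()) {
    spec <- toy_separated_config()$profile_specs[[p]]
    row <- data.frame(id = "q", sex = "F", site = "S1", age = spec$age_mean)
    for (i in seq_along(classification_vars())) {
      row[[classification_vars()[i]]] <- spec$mean_vector[i]
    }
    tb <- behavioral_table(row, site_levels = paste0("S", 1:8))
    expect_equal(as.character(classify(model, tb)), p)
  }
})

test_that("training and prediction are deterministic given the seed", {
  coh <- training_cohort()
  syn <- synthesize_dataset(coh, n_per_profile = 25, seed = 6)
  m1 <- train_classifier(coh, seed = 10, mtry = 2)
  m2 <- train_classifier(coh, seed = 10, mtry = 2)
  expect_identical(classify(m1, syn), classify(m2, syn))
  expect_error(train_classifier(syn[1:50, ], seed = 1, mtry = 2),
               "2 rows per class")
})

test_that("row order does not change what the classifier learns", {
  coh <- generate_profile_cohort(toy_separated_config(n_per_profile = 20))
  probe <- generate_profile_cohort(toy_separated_config(n_per_profile = 10),
                                   seed = 123)
  perm <- with_seed(9, sample(nrow(coh)))
  m1 <- train_classifier(coh, seed = 1, mtry = 2)
  m2 <- train_classifier(coh[perm, ], seed = 1, mtry = 2)
  expect_identical(classify(m1, probe), classify(m2, probe))
})

test_that("resubstitution accuracy on the training cohort is near-perfect", {
  coh <- training_cohort()
  model <- fixture_classifier()
  expect_gte(confusion_metrics(classify(model, coh), coh$label)$accuracy,
             0.95)
})

test_that("classification refuses tables with missing features", {
  tb <- small_table(missing = list(verbal_iq = 2))
  expect_error(classify(fixture_classifier(), tb), "impute")
})

test_that("pooled labels are the modal vote with the fixed tie-break", {
  lm <- rbind(c("Control", "PoorDecoder"),
              c("PoorComprehender", "GenerallyPoorReader"),
              c("GenerallyPoorReader", "GenerallyPoorReader"))
  pooled <- pool_labels(lm)
  expect_equal(as.character(pooled),
               c("Control", "PoorComprehender", "GenerallyPoorReader"))
  expect_equal(attr(pooled, "n_ties"), 2L)
  # pooled label always appears among the row's per-imputation labels
  with_seed(31, {
    big <- matrix(sample(profile_levels(), 50 * 7, replace = TRUE), 50)
    p <- pool_labels(big)
    for (i in 1:50) expect_true(as.character(p[i]) %in% big[i, ])
  })
})

test_that("classifying an imputation set pools labels and counts", {
  coh <- generate_profile_cohort(toy_separated_config(n_per_profile = 20))
  model <- train_classifier(coh, seed = 2, mtry = 2)
  mr <- induce_mar(coh, mar_mechanism(0.2, seed = 3))
  imps <- impute_pmm(mr$table, m = 4, seed = 4)
  cr <- classify_imputed(model, imps, baseline = coh)
  expect_equal(dim(cr$per_imputation_labels), c(80, 4))
  expect_equal(sum(cr$profile_counts$mean), 80)
  expect_equal(length(cr$baseline_labels), 80)
  # m identical tables -> zero SD in every profile count
  same <- impute_mean(mr$table)
  same$tables <- rep(same$tables, 3)
  same$m <- 3L
  cr_same <- classify_imputed(model, same)
  expect_true(all(cr_same$profile_counts$sd == 0))
  expect_identical(cr_same$pooled_labels[seq_len(80)],
                   classify(model, same$tables[[1]]))
})

test_that("mtry tuning explores the grid and records accuracies", {
  coh <- generate_profile_cohort(toy_separated_config(n_per_profile = 12))
  model <- train_classifier(coh, seed = 5, tune_grid = c(2, 4),
                            repeats = 2, num_trees = 100)
  expect_equal(model$tuning_record$mtry, c(2, 4))
  expect_true(all(model$tuning_record$cv_accuracy > 0.9))
  expect_true(model$mtry %in% c(2, 4))
})
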