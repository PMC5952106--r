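test_that("default cohort reproduces the training-cohort structure", {
  coh <- generate_profile_cohort(default_cohort_config())
  expect_equal(nrow(coh), 198)
  cnt <- table(coh$label)
  expect_equal(unname(cnt[profile_levels()]),
               c(58, 27, 14, 99), ignore_attr = TRUE)
  expect_equal(nlevels(coh$site), 8)
  expect_equal(missingness_summary(coh)$total, 0)
  # bit-reproducible given (config, seed)
  expect_identical(coh, generate_profile_cohort(default_cohort_config()))
})

test_that("degenerate zero-covariance profiles collapse onto their means", {
  cfg <- default_cohort_config()
  for (p in profile_levels()) {
    cfg$profile_specs[[p]]$covariance <- matrix(0, 6, 6)
    cfg$profile_specs[[p]]$age_sd <- 0
  }
  cfg$site_effects <- rep(0, 8)
  coh <- generate_profile_cohort(cfg)
  pd <- coh[coh$label == "PoorDecoder", ]
  expect_true(all(abs(as.matrix(pd[classification_vars()]) -
                      rep(cfg$profile_specs$PoorDecoder$mean_vector,
                          each = nrow(pd))) < 1e-10))
})

test_that("sample covariance converges to the configured covariance", {
  cfg <- default_cohort_config()
  cfg$site_effects <- rep(0, 8)
  frob <- function(n) {
    cfg$profile_specs$Control$prevalence_count <- n
    coh <- generate_profile_cohort(cfg, seed = 2024)
    ctl <- coh[coh$label == "Control", c("age", classification_vars())]
    sqrt(sum((stats::cov(ctl) - cfg$profile_specs$Control$covariance)^2))
  }
  d_small <- frob(300)
  d_big <- frob(10000)
  expect_lt(d_big, d_small)
  expect_lt(d_big, 6)  # Frobenius norm over a 6x6 with entries O(80)
})

test_that("non-positive-definite covariance is rejected", {
  S <- diag(6); S[1, 2] <- S[2, 1] <- 2
  expect_error(profile_spec("Control", rep(100, 5), 9, 1, S, 10),
               "positive semi-definite")
})

test_that("validation scores encode the expected profile orderings", {
  cfg <- default_cohort_config()
  for (p in profile_levels()) cfg$profile_specs[[p]]$prevalence_count <- 2500
  coh <- generate_profile_cohort(cfg, seed = 31)
  val <- generate_validation_scores(coh, seed = 32)
  mean_by <- function(v) tapply(val[[v]], val$label, mean)
  for (v in validation_vars()) {
    m <- mean_by(v)
    expect_true(all(m["Control"] > m[setdiff(profile_levels(), "Control")]))
  }
  expect_gt(mean_by("elision")["PoorComprehender"],
            mean_by("elision")["PoorDecoder"])
  expect_true(all(mean_by("piq")["GenerallyPoorReader"] <
                  mean_by("piq")[c("PoorDecoder", "PoorComprehender")]))
  expect_true(all(mean_by("digit_span")["GenerallyPoorReader"] <
                  mean_by("digit_span")[c("PoorDecoder", "PoorComprehender")]))
  # sample means within 3 SE of the configured means
  vc <- default_validation_config()
  for (p in profile_levels()) {
    rows <- val$label == p
    for (v in validation_vars()) {
      se <- stats::sd(val[[v]][rows]) / sqrt(sum(rows))
      expect_lt(abs(mean(val[[v]][rows]) - vc$means[p, v]), 3 * se + 0.2)
    }
  }
})

test_that("a zero-noise validation model returns the configured means exactly", {
  coh <- generate_profile_cohort(toy_separated_config())
  vc <- default_validation_config(coupling = 0, noise_sd = 0)
  val <- generate_validation_scores(coh, config = vc, seed = 5)
  for (v in validation_vars()) {
    expect_equal(val[[v]], unname(vc$means[as.character(val$label), v]))
  }
  expect_error(generate_validation_scores(small_table()), "labeled")
})

test_that("synthesis yields 500 rows, 125 per profile, matching source moments", {
  src <- training_cohort()
  syn <- synthesize_dataset(src, seed = 77)
  expect_equal(nrow(syn), 500)
  expect_true(all(table(syn$label) == 125))
  expect_identical(syn, synthesize_dataset(src, seed = 77))
  for (p in profile_levels()) {
    s_rows <- syn$label == p
    o_rows <- src$label == p
    for (v in classification_vars()) {
      se <- stats::sd(syn[[v]][s_rows]) / sqrt(sum(s_rows))
      expect_lt(abs(mean(syn[[v]][s_rows]) - mean(src[[v]][o_rows])),
                3 * se + 1.5)  # extra slack: the source group mean is itself noisy
    }
  }
})

test_that("synthesis preserves the correlational structure of the source", {
  src <- training_cohort()
  vars <- classification_vars()
  src_cor <- stats::cor(as.matrix(src[vars]))
  acc <- matrix(0, 5, 5)
  n_syn <- 100
  for (i in seq_len(n_syn)) {
    syn <- synthesize_dataset(src, seed = child_seed(55, i))
    acc <- acc + stats::cor(as.matrix(syn[vars]))
  }
  expect_lt(max(abs(acc / n_syn - src_cor)), 0.15)
})

test_that("no synthetic row reproduces a source row's test scores", {
  src <- training_cohort()
  syn <- synthesize_dataset(src, seed = 91)
  src_scores <- as.matrix(src[classification_vars()])
  syn_scores <- as.matrix(syn[classification_vars()])
  for (i in seq_len(nrow(syn_scores))) {
    expect_gt(min(rowSums(abs(sweep(src_scores, 2, syn_scores[i, ])))), 0)
  }
  src_na <- src
  src_na$ran[1] <- NA
  expect_error(synthesize_dataset(src_na, seed = 1), "complete")
})

test_that("separability calibration is monotone and hits trivial targets", {
  cfg <- default_cohort_config()
  accs <- vapply(c(0.4, 1, 2.2), function(s) {
    cfg$separation_scale <- s
    coh <- generate_profile_cohort(cfg, seed = child_seed(cfg$seed, 1))
    loo_accuracy(coh, num_trees = 150, seed = child_seed(cfg$seed, 2))
  }, 0)
  expect_true(all(diff(accs) > -0.02))

  toy <- toy_separated_config()
  cal <- calibrate_separability(toy, target_accuracy = 1, tol = 0.005,
                                num_trees = 100)
  expect_equal(cal$achieved, 1)
  expect_error(
    calibrate_separability(toy, target_accuracy = 0.4, tol = 0.001,
                           num_trees = 50, max_eval = 4),
    "calibration error.*best achieved")
})
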