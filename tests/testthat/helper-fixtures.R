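# Shared fixtures, computed lazily and cached for the whole test run. The
# calibrated cohort is the expensive one (repeated leave-one-out forests);
# every file that needs it reuses the same object.
.fixture_cache <- new.env(parent = emptyenv())

calibrated_fixture <- function() {
  if (is.null(.fixture_cache$cal)) {
    .fixture_cache$cal <- calibrate_separability(default_cohort_config(),
                                                 target_accuracy = 0.94)
  }
  .fixture_cache$cal
}

training_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    cal <- calibrated_fixture()
    .fixture_cache$cohort <- generate_profile_cohort(
      cal$config, seed = child_seed(cal$config$seed, 1))
  }
  .fixture_cache$cohort
}

fixture_classifier <- function() {
  if (is.null(.fixture_cache$model)) {
    .fixture_cache$model <- train_classifier(training_cohort(),
                                             seed = 404, mtry = 2)
  }
  .fixture_cache$model
}

# Four profiles separated by ~10 within-profile SDs on every test: trivially
# separable, used for limit-case checks.
toy_separated_config <- function(n_per_profile = 15, test_sd = 3) {
  Sigma <- diag(c(1.6, rep(test_sd, 5))^2)
  mk <- function(name, level, n) {
    profile_spec(name, rep(level, 5), age_mean = 9.6, age_sd = 1.6,
                 covariance = Sigma, prevalence_count = n)
  }
  cohort_config(
    profile_specs = list(mk("PoorDecoder", 40, n_per_profile),
                         mk("PoorComprehender", 80, n_per_profile),
                         mk("GenerallyPoorReader", 120, n_per_profile),
                         mk("Control", 160, n_per_profile)),
    n_sites = 8, sex_balance = 0.5, site_effects = rep(0, 8), seed = 99L)
}

feature_vals <- function(tb) {
  as.matrix(as.data.frame(tb)[eligible_missing_vars()])
}

# Small complete table for IO / imputation unit tests.
small_table <- function(n = 12, seed = 3, missing = NULL) {
  tb <- with_seed(seed, {
    df <- data.frame(
      id = sprintf("X%02d", seq_len(n)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      site = sample(paste0("S", 1:3), n, replace = TRUE),
      age = round(runif(n, 7, 12), 2))
    for (v in classification_vars()) df[[v]] <- round(rnorm(n, 100, 15), 1)
    df
  })
  tb <- behavioral_table(tb, site_levels = paste0("S", 1:3))
  if (!is.null(missing)) {
    for (v in names(missing)) tb[[v]][missing[[v]]] <- NA
  }
  tb
}
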