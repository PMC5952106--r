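test_that("Rubin pooling matches hand-computed examples", {
  p0 <- rubin_pool(c(2, 2, 2), c(1, 1, 1))
  expect_equal(p0$point, 2)
  expect_equal(p0$within, 1)
  expect_equal(p0$between, 0)
  expect_equal(p0$total, 1)

  p1 <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p1$point, 2)
  expect_equal(p1$between, 1)
  expect_equal(p1$total, 7 / 3)

  # small-sample adjusted df, evaluated from its defining pieces
  p2 <- rubin_pool(c(1, 2, 3), c(1, 1, 1), df_complete = 10)
  r <- (4 / 3) / (7 / 3)
  nu_large <- 2 / r^2
  nu_obs <- (11 / 13) * 10 * (1 - r)
  expect_equal(p2$df, nu_large * nu_obs / (nu_large + nu_obs))
  expect_equal(rubin_pool(c(1, 2, 3), c(1, 1, 1))$df, nu_large)
})

test_that("pooling is linear in the variances and safe at B = 0", {
  a <- rubin_pool(c(1, 2, 3), c(1, 2, 3))
  b <- rubin_pool(c(1, 2, 3), c(2, 4, 6))
  expect_equal(b$within, 2 * a$within)
  expect_equal(b$total - (1 + 1 / 3) * b$between,
               2 * (a$total - (1 + 1 / 3) * a$between))
  z <- rubin_pool(c(5, 5), c(0.5, 0.5), df_complete = 20)
  expect_equal(z$total, z$within)
  expect_equal(z$df, 20)
  expect_warning(rubin_pool(2, 1), "single imputation")
})

test_that("a single imputation reduces to the classic complete-data tests", {
  tb <- small_table(n = 40, seed = 8)
  g <- factor(rep(c("a", "b"), 20))
  ours <- pooled_t_test(tb, g, "a", "b", "verbal_iq")
  ref <- stats::t.test(tb$verbal_iq[g == "a"], tb$verbal_iq[g == "b"])
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p, ref$p.value)

  ours_r <- pooled_correlation(tb, "verbal_iq", "ran")
  ref_r <- stats::cor.test(tb$verbal_iq, tb$ran)
  expect_equal(ours_r$r, unname(ref_r$estimate))
  expect_equal(ours_r$df, unname(ref_r$parameter))
  expect_equal(ours_r$p, ref_r$p.value)
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  tb <- small_table(n = 30, seed = 9)
  g <- factor(rep(c("a", "b"), 15))
  tt <- pooled_t_test(tb, g, "a", "b", "ran", var_equal = TRUE)
  av <- pooled_anova(tb, g, "ran")
  expect_equal(av$F, tt$t^2)
  expect_equal(av$p, tt$p, tolerance = 1e-10)
})

test_that("identical groups give t = 0 and d = 0", {
  tb <- small_table(n = 20, seed = 10)
  tb2 <- tb
  tb2$ran <- rep(tb$ran[1:10], 2)
  g <- factor(rep(c("a", "b"), each = 10))
  res <- pooled_t_test(tb2, g, "a", "b", "ran")
  expect_equal(res$t, 0)
  expect_equal(res$cohens_d, 0)
})

test_that("Fisher-z pooling keeps r inside [-1, 1]", {
  tb <- small_table(n = 50, seed = 11)
  tb$piq <- tb$verbal_iq + with_seed(2, rnorm(50, 0, 0.01))
  imps <- structure(list(method = "pmm", m = 3,
                         tables = list(tb, tb, tb)),
                    class = "imputation_set")
  res <- pooled_correlation(imps, "verbal_iq", "piq")
  expect_true(abs(res$r) <= 1)
  expect_gt(res$r, 0.99)
  # exact copy, single table
  tb$piq <- tb$verbal_iq
  expect_equal(pooled_correlation(tb, "verbal_iq", "piq")$r, 1)
})

test_that("pooled group means reduce correctly and recover the generator", {
  tb <- small_table(n = 40, seed = 12)
  g <- factor(rep(c("a", "b"), 20))
  one <- pooled_profile_means(tb, g, variables = "verbal_iq")
  expect_equal(one$mean[1], mean(tb$verbal_iq[g == "a"]))
  expect_equal(one$sem[1],
               stats::sd(tb$verbal_iq[g == "a"]) / sqrt(20))
  imps <- structure(list(method = "x", m = 4,
                         tables = rep(list(tb), 4)),
                    class = "imputation_set")
  four <- pooled_profile_means(imps, g, variables = "verbal_iq")
  expect_equal(four$mean, one$mean)
  expect_equal(four$sem, one$sem)  # zero between-imputation variance

  # coverage: pooled means fall within 3 pooled SEM of the generator means
  cfg <- toy_separated_config(n_per_profile = 60)
  hits <- 0; total <- 0
  for (i in 1:20) {
    coh <- generate_profile_cohort(cfg, seed = child_seed(900, i))
    mr <- induce_mar(coh, mar_mechanism(0.3, seed = child_seed(901, i)))
    pm <- pooled_profile_means(impute_pmm(mr$table, m = 5,
                                          seed = child_seed(902, i)),
                               coh$label)
    for (k in seq_len(nrow(pm))) {
      spec <- cfg$profile_specs[[pm$group[k]]]
      mu <- spec$mean_vector[match(pm$variable[k], classification_vars())]
      total <- total + 1
      if (abs(pm$mean[k] - mu) <= 3 * pm$sem[k]) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("pooled ANOVA recovers the validation-score profile ordering", {
  cfg <- default_cohort_config()
  for (p in profile_levels()) cfg$profile_specs[[p]]$prevalence_count <- 150
  coh <- generate_profile_cohort(cfg, seed = 41)
  val <- generate_validation_scores(coh, seed = 42)
  for (v in validation_vars()) {
    res <- pooled_anova(val, val$label, v)
    expect_lt(res$p, 1e-6)
    expect_gt(res$eta_squared, 0.05)
    rel <- res$pairwise$relation
    for (other in setdiff(profile_levels(), "Control")) {
      expect_true(paste("Control >", other) %in% rel)
    }
  }
  res_el <- pooled_anova(val, val$label, "elision")
  expect_true("PoorComprehender > PoorDecoder" %in% res_el$pairwise$relation)
})
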