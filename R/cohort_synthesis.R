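#' Specification of one reading profile for cohort generation
#'
#' Scores for a profile are drawn from a multivariate normal over
#' (age, pseudoword_id, real_word_id, passage_comp, verbal_iq, ran). Test
#' scores are on the standardized mean-100 / SD-15 scale; within-profile
#' spread is narrower than the population SD.
#'
#' @param name one of [profile_levels()].
#' @param mean_vector numeric(5): means of the five classification scores.
#' @param age_mean,age_sd age distribution in years.
#' @param covariance 6x6 symmetric positive semi-definite matrix over
#'   (age, five tests).
#' @param prevalence_count number of participants with this profile in a
#'   generated cohort.
#' @return a `profile_spec` list.
#' @export
profile_spec <- function(name, mean_vector, age_mean, age_sd, covariance,
                         prevalence_count) {
  name <- match.arg(name, profile_levels())
  stopifnot(length(mean_vector) == 5, all(is.finite(mean_vector)),
            prevalence_count >= 1)
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8))) {
    stop("config error: covariance must be symmetric")
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("config error: covariance not positive semi-definite")
  }
  structure(list(name = name, mean_vector = as.numeric(mean_vector),
                 age_mean = age_mean, age_sd = age_sd,
                 covariance = covariance,
                 prevalence_count = as.integer(prevalence_count)),
            class = "profile_spec")
}

# Default within-profile covariance: tests share moderate positive
# correlation, the decoding pair (pseudoword/real word) correlates more
# strongly, age is nearly independent of the standardized scores.
default_profile_covariance <- function(age_sd = 1.6, test_sd = 9,
                                       r_tests = 0.5, r_decoding = 0.7,
                                       r_age = 0.1) {
  R <- diag(6)
  R[2:6, 2:6] <- r_tests
  R[2, 3] <- R[3, 2] <- r_decoding
  R[1, 2:6] <- R[2:6, 1] <- r_age
  diag(R) <- 1
  D <- diag(c(age_sd, rep(test_sd, 5)))
  D %*% R %*% D
}

#' Default cohort configuration emulating the training cohort
#'
#' 198 children from 8 research sites with profile counts 58 Poor Decoders,
#' 27 Poor Comprehenders, 14 Generally Poor Readers and 99 Controls. Profile
#' mean vectors encode the qualitative structure of the four profiles: Poor
#' Decoders low on pseudoword/real-word reading with preserved Verbal IQ,
#' Poor Comprehenders low on passage comprehension with relatively preserved
#' decoding, Generally Poor Readers low on everything including Verbal IQ,
#' Controls at or above 100 throughout. `separation_scale` multiplies each
#' profile's test-mean deviation from 100 and is the single free parameter
#' that [calibrate_separability()] adjusts to hit a target leave-one-out
#' classification accuracy. Site effects are small (at most 0.2 population
#' SD) mean shifts so that site is a usable, weak predictor of scores.
#'
#' @param separation_scale multiplier on profile mean deviations from 100.
#' @param seed root seed stored with the configuration.
#' @return a `cohort_config` list.
#' @export
default_cohort_config <- function(separation_scale = 1, seed = 198L) {
  Sigma <- default_profile_covariance()
  mk <- function(name, mv, n) {
    profile_spec(name, mv, age_mean = 9.6, age_sd = 1.6,
                 covariance = Sigma, prevalence_count = n)
  }
  cohort_config(
    profile_specs = list(
      mk("PoorDecoder",        c(76, 87, 90, 100, 92), 58),
      mk("PoorComprehender",   c(95, 95, 80, 88, 92),  27),
      mk("GenerallyPoorReader", c(76, 82, 78, 80, 88), 14),
      mk("Control",            c(104, 105, 104, 104, 103), 99)),
    n_sites = 8,
    site_allocation = rep(1 / 8, 8),
    sex_balance = 78 / 198,
    site_effects = seq(-3, 3, length.out = 8),
    separation_scale = separation_scale,
    seed = seed)
}

#' Assemble a cohort configuration
#'
#' @param profile_specs list of 4 [profile_spec()]s, one per profile.
#' @param n_sites number of research sites.
#' @param site_allocation probability of each site (sums to 1).
#' @param sex_balance probability that a participant is female.
#' @param site_effects per-site additive mean shift (score points) applied
#'   to the five test scores; keeps site a weak nuisance predictor.
#' @param separation_scale multiplier on test-mean deviations from 100.
#' @param seed integer seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(profile_specs, n_sites = 8,
                          site_allocation = rep(1 / n_sites, n_sites),
                          sex_balance = 0.5,
                          site_effects = rep(0, n_sites),
                          separation_scale = 1, seed = 1L) {
  stopifnot(length(profile_specs) == 4,
            all(vapply(profile_specs, inherits, TRUE, "profile_spec")),
            length(site_allocation) == n_sites,
            length(site_effects) == n_sites,
            sex_balance >= 0, sex_balance <= 1,
            all(site_allocation >= 0))
  if (abs(sum(site_allocation) - 1) > 1e-8) {
    stop("config error: site_allocation must sum to 1")
  }
  names(profile_specs) <- vapply(profile_specs, `[[`, "", "name")
  if (!setequal(names(profile_specs), profile_levels())) {
    stop("config error: need exactly one spec per profile")
  }
  structure(list(profile_specs = profile_specs[profile_levels()],
                 n_sites = as.integer(n_sites),
                 site_allocation = site_allocation,
                 sex_balance = sex_balance,
                 site_effects = site_effects,
                 separation_scale = separation_scale,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

scaled_means <- function(spec, scale) {
  100 + scale * (spec$mean_vector - 100)
}

#' Generate a complete, labeled cohort
#'
#' Draws each profile's (age, five scores) from its multivariate normal with
#' the configured separation scale applied to the test means, then assigns
#' sex and site independently of the scores (so that covariate-driven
#' missingness is MAR, not MNAR) and adds the per-site mean shift to the
#' test scores. Deterministic given `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed seed; defaults to `config$seed`.
#' @return a complete labeled [behavioral_table()].
#' @export
generate_profile_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    parts <- lapply(config$profile_specs, function(spec) {
      n <- spec$prevalence_count
      mu <- c(spec$age_mean, scaled_means(spec, config$separation_scale))
      Sigma <- spec$covariance
      Sigma[1, 1] <- spec$age_sd^2
      draws <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
      draws <- matrix(draws, nrow = n)
      df <- as.data.frame(draws)
      names(df) <- c("age", classification_vars())
      df$label <- spec$name
      df
    })
    df <- do.call(rbind, parts)
    n <- nrow(df)
    df$sex <- ifelse(stats::runif(n) < config$sex_balance, "F", "M")
    site_idx <- sample.int(config$n_sites, n, replace = TRUE,
                           prob = config$site_allocation)
    df$site <- paste0("S", site_idx)
    for (v in classification_vars()) {
      df[[v]] <- df[[v]] + config$site_effects[site_idx]
    }
    df$id <- sprintf("P%03d", seq_len(n))
    behavioral_table(df, site_levels = paste0("S", seq_len(config$n_sites)))
  })
}

#' Default validation-score model
#'
#' Per-profile means of the four validation measures encode the orderings
#' observed across profiles: Controls highest on all four; Generally Poor
#' Readers lowest on Performance IQ and Digit Span; Poor Comprehenders above
#' Poor Decoders and Generally Poor Readers on Elision and Spelling.
#' `coupling` ties each validation score to the participant's average
#' within-profile test-score deviation so validation and classification
#' measures correlate; `noise_sd` is the residual SD in score points.
#'
#' @param coupling regression weight on the mean classification-score
#'   deviation.
#' @param noise_sd residual SD of the validation scores.
#' @return a `validation_config` list.
#' @export
default_validation_config <- function(coupling = 0.4, noise_sd = 8) {
  means <- rbind(
    PoorDecoder         = c(piq = 98, spelling = 85, elision = 84, digit_span = 96),
    PoorComprehender    = c(piq = 97, spelling = 92, elision = 94, digit_span = 95),
    GenerallyPoorReader = c(piq = 86, spelling = 80, elision = 82, digit_span = 85),
    Control             = c(piq = 104, spelling = 104, elision = 104, digit_span = 104))
  structure(list(means = means, coupling = coupling, noise_sd = noise_sd),
            class = "validation_config")
}

#' Add validation scores to a labeled cohort
#'
#' @param table labeled [behavioral_table()] (no missing labels).
#' @param config a [default_validation_config()].
#' @param seed integer seed.
#' @return the table with `piq`, `spelling`, `elision`, `digit_span` added.
#' @export
generate_validation_scores <- function(table, config = default_validation_config(),
                                       seed = 1L) {
  stopifnot(inherits(table, "behavioral_table"))
  if (!"label" %in% names(table) || any(is.na(table$label))) {
    stop("validation scores require a fully labeled table")
  }
  tests <- as.matrix(as.data.frame(table)[classification_vars()])
  dev <- tests
  for (p in profile_levels()) {
    rows <- table$label == p
    if (any(rows)) {
      dev[rows, ] <- sweep(tests[rows, , drop = FALSE], 2,
                           colMeans(tests[rows, , drop = FALSE], na.rm = TRUE))
    }
  }
  # rows with missing test scores contribute whatever deviations are observed
  dev_bar <- rowMeans(dev, na.rm = TRUE)
  dev_bar[is.nan(dev_bar)] <- 0
  with_seed(seed, {
    for (v in validation_vars()) {
      mu <- config$means[as.character(table$label), v]
      table[[v]] <- mu + config$coupling * dev_bar +
        stats::rnorm(nrow(table), 0, config$noise_sd)
    }
  })
  behavioral_table(as.data.frame(table), site_levels = levels(table$site))
}

#' Synthesize a new dataset preserving a source table's structure
#'
#' Sequential conditional synthesis in the style of regression-based data
#' synthesis tools: profile labels are assigned first (`n_per_profile`
#' each), then variables are visited in the fixed order sex, site, age and
#' the five test scores. Sex and site are drawn frequency-matched within
#' label; each continuous variable is modeled within label by linear
#' regression on the previously visited continuous variables and drawn as
#' fitted value plus a resampled residual, which preserves the source's
#' within-profile means, variances and correlations. No synthetic row
#' reproduces a source row's five test scores exactly.
#'
#' @param source complete, labeled [behavioral_table()].
#' @param n_per_profile rows per profile in the output (default 125, giving
#'   N = 500).
#' @param seed integer seed.
#' @return a complete labeled [behavioral_table()] with
#'   `4 * n_per_profile` rows.
#' @export
synthesize_dataset <- function(source, n_per_profile = 125, seed = 1L) {
  stopifnot(inherits(source, "behavioral_table"))
  if (!"label" %in% names(source) || any(is.na(source$label))) {
    stop("synthesis requires a labeled source table")
  }
  cont_order <- c("age", classification_vars())
  if (missingness_summary(source)$total > 0 ||
      any(is.na(as.matrix(source[cont_order])))) {
    stop("synthesis requires complete data in the source table")
  }
  with_seed(seed, {
    out <- vector("list", 4)
    for (pi in seq_along(profile_levels())) {
      p <- profile_levels()[pi]
      src <- source[source$label == p, , drop = FALSE]
      n <- n_per_profile
      syn <- data.frame(
        sex = sample(as.character(src$sex), n, replace = TRUE),
        site = sample(as.character(src$site), n, replace = TRUE),
        stringsAsFactors = FALSE)
      for (k in seq_along(cont_order)) {
        v <- cont_order[k]
        preds <- cont_order[seq_len(k - 1)]
        draw_var <- function() {
          if (length(preds) == 0) {
            fit <- stats::lm(stats::reformulate("1", response = v), data = src)
            mu <- rep(stats::coef(fit)[1], n)
          } else {
            fit <- stats::lm(stats::reformulate(preds, response = v), data = src)
            mu <- drop(cbind(1, as.matrix(syn[preds])) %*% stats::coef(fit))
          }
          res <- stats::residuals(fit)
          mu + sample(res, n, replace = TRUE)
        }
        syn[[v]] <- draw_var()
      }
      # disclosure guard: redraw any row whose five test scores coincide
      # with a source row (vanishingly rare with continuous residuals)
      src_scores <- as.matrix(source[classification_vars()])
      for (tries in 1:10) {
        syn_scores <- as.matrix(syn[classification_vars()])
        dup <- apply(syn_scores, 1, function(r) {
          any(rowSums(abs(sweep(src_scores, 2, r))) == 0)
        })
        if (!any(dup)) break
        for (v in classification_vars()) {
          syn[[v]][dup] <- syn[[v]][dup] + stats::rnorm(sum(dup), 0, 1e-6)
        }
      }
      syn$label <- p
      out[[pi]] <- syn
    }
    df <- do.call(rbind, out)
    df$id <- sprintf("SYN%04d", seq_len(nrow(df)))
    behavioral_table(df, site_levels = levels(source$site))
  })
}

#' Calibrate profile separability to a target classification accuracy
#'
#' Scales the between-profile test-mean separation (holding covariances
#' fixed) by bisection until the leave-one-out accuracy of the random-forest
#' classifier (mtry = 2, 500 trees) on a generated cohort is within `tol` of
#' `target_accuracy`. Deterministic given `seed`.
#'
#' @param config a [cohort_config()].
#' @param target_accuracy target LOO accuracy in (0, 1].
#' @param tol acceptable deviation from the target (default 0.01, about two
#'   misclassified cases on a 198-row cohort).
#' @param seed integer seed.
#' @param mtry,num_trees classifier hyperparameters used during calibration.
#' @param max_eval maximum number of LOO evaluations.
#' @return a list with the adjusted `config`, `achieved` accuracy, selected
#'   `scale` and the `evaluations` trace.
#' @export
calibrate_separability <- function(config, target_accuracy = 0.94, tol = 0.01,
                                   seed = config$seed, mtry = 2,
                                   num_trees = 500, max_eval = 12) {
  stopifnot(target_accuracy > 0, target_accuracy <= 1)
  evals <- data.frame(scale = numeric(0), accuracy = numeric(0))
  f <- function(scale) {
    cfg <- config
    cfg$separation_scale <- scale
    cohort <- generate_profile_cohort(cfg, seed = child_seed(seed, 1))
    acc <- loo_accuracy(cohort, mtry = mtry, num_trees = num_trees,
                        seed = child_seed(seed, 2))
    evals <<- rbind(evals, data.frame(scale = scale, accuracy = acc))
    acc
  }
  lo <- 0.15; hi <- 4
  scale <- config$separation_scale
  acc <- f(scale)
  while (abs(acc - target_accuracy) > tol && nrow(evals) < max_eval) {
    if (acc > target_accuracy) hi <- scale else lo <- scale
    scale <- (lo + hi) / 2
    acc <- f(scale)
  }
  best <- evals[which.min(abs(evals$accuracy - target_accuracy)), ]
  if (abs(best$accuracy - target_accuracy) > tol) {
    stop(sprintf(
      "calibration error: target %.3f unreachable; best achieved %.3f at scale %.3f",
      target_accuracy, best$accuracy, best$scale))
  }
  out <- config
  out$separation_scale <- best$scale
  list(config = out, achieved = best$accuracy, scale = best$scale,
       target = target_accuracy, evaluations = evals)
}
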