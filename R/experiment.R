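grid_control <- function(control = list(), n_sites = 8) {
  defaults <- list(pmm_k = 5, pmm_cycles = 5,
                   mf_ntree = 100, mf_max_iter = 10,
                   sex_coefficient = 0.8,
                   site_coefficients = seq(-1, 1, length.out = n_sites),
                   fixed_variables = NULL)
  defaults[names(control)] <- control
  defaults
}

impute_with <- function(method, table, m, seed, ctl) {
  switch(method,
         mean_replacement = impute_mean(table),
         pmm = impute_pmm(table, m = m, k_donors = ctl$pmm_k,
                          n_cycles = ctl$pmm_cycles, seed = seed),
         missforest = impute_missforest(table, m = m,
                                        max_iter = ctl$mf_max_iter,
                                        ntree = ctl$mf_ntree, seed = seed),
         stop("unknown imputation method: ", method))
}

#' Run the full simulation grid
#'
#' For each of `n_datasets` replicates: synthesize an `4 * n_per_profile`-row
#' dataset from the source cohort, classify it complete (the shared 0%
#' baseline), then for every missingness rate induce MAR in three selected
#' variables (re-drawn per replicate unless `control$fixed_variables` pins
#' them) and for every method impute, classify each completed table against
#' the propagated labels, and average metrics over the m imputations.
#' Failures in a grid cell are recorded and the grid continues.
#'
#' @param source complete labeled [behavioral_table()] (the calibrated
#'   training cohort).
#' @param classifier optional pre-trained [train_classifier()] model;
#'   trained on `source` (mtry = 2, 500 trees) when `NULL`.
#' @param n_datasets replicate count (default 100).
#' @param rates missingness levels, fractions in `[0, 0.5]`.
#' @param methods subset of `mean_replacement`, `pmm`, `missforest`.
#' @param m imputations per multiple-imputation method (default 10; mean
#'   replacement always has m = 1).
#' @param n_per_profile synthetic rows per profile (default 125).
#' @param seed root seed; the whole grid is reproducible from it.
#' @param control list overriding `pmm_k`, `pmm_cycles`, `mf_ntree`,
#'   `mf_max_iter`, `sex_coefficient`, `site_coefficients`,
#'   `fixed_variables`.
#' @return a `simulation_report` with tidy data frames `metrics`,
#'   `profile_accuracy`, `efficiency`, `selection`, `baseline`, `failures`.
#' @export
run_simulation_grid <- function(source, classifier = NULL, n_datasets = 100,
                                rates = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                                methods = c("mean_replacement", "pmm",
                                            "missforest"),
                                m = 10, n_per_profile = 125, seed = 1L,
                                control = list()) {
  stopifnot(inherits(source, "behavioral_table"))
  ctl <- grid_control(control, n_sites = nlevels(source$site))
  if (is.null(classifier)) {
    classifier <- train_classifier(source, seed = child_seed(seed, 1),
                                   mtry = 2)
  }
  metrics <- list(); prof <- list(); eff <- list(); sel <- list()
  base <- list(); fails <- list()
  for (rep_i in seq_len(n_datasets)) {
    syn <- synthesize_dataset(source, n_per_profile = n_per_profile,
                              seed = child_seed(seed, rep_i, 2))
    truth <- syn$label
    base_cm <- confusion_metrics(classify(classifier, syn), truth)
    base[[rep_i]] <- data.frame(replicate = rep_i,
                                accuracy = base_cm$accuracy,
                                macro_sensitivity = base_cm$macro_sensitivity,
                                macro_specificity = base_cm$macro_specificity)
    selected <- ctl$fixed_variables
    if (is.null(selected)) {
      selected <- with_seed(child_seed(seed, rep_i, 3),
                            sample(eligible_missing_vars(), 3))
    }
    sel[[rep_i]] <- data.frame(replicate = rep_i, variable = selected)
    for (rate in rates) {
      if (rate == 0) {
        for (method in methods) {
          metrics[[length(metrics) + 1]] <- data.frame(
            replicate = rep_i, rate = 0, method = method,
            accuracy = base_cm$accuracy,
            macro_sensitivity = base_cm$macro_sensitivity,
            macro_specificity = base_cm$macro_specificity,
            accuracy_reduction = 0, sensitivity_reduction = 0,
            specificity_reduction = 0)
          eff[[length(eff) + 1]] <- data.frame(
            replicate = rep_i, rate = 0, method = method,
            variable = selected, efficiency = 1)
        }
        next
      }
      mech <- mar_mechanism(rate, selected_variables = selected,
                            sex_coefficient = ctl$sex_coefficient,
                            site_coefficients = ctl$site_coefficients,
                            seed = child_seed(seed, rep_i, 4, round(rate * 100)))
      mr <- induce_mar(syn, mech)
      for (method in methods) {
        res <- tryCatch({
          imps <- impute_with(method, mr$table, m,
                              seed = child_seed(seed, rep_i, 5,
                                                round(rate * 100),
                                                match(method, methods)),
                              ctl)
          cr <- classify_imputed(classifier, imps)
          per_imp <- lapply(seq_len(imps$m), function(j) {
            confusion_metrics(cr$per_imputation_labels[, j], truth)
          })
          acc <- mean(vapply(per_imp, `[[`, 0, "accuracy"))
          msn <- mean(vapply(per_imp, `[[`, 0, "macro_sensitivity"))
          msp <- mean(vapply(per_imp, `[[`, 0, "macro_specificity"))
          sens_mat <- vapply(per_imp, `[[`, numeric(4), "sensitivity")
          e <- efficiency(imps, syn, variables = selected)
          list(metrics = data.frame(
                 replicate = rep_i, rate = rate, method = method,
                 accuracy = acc, macro_sensitivity = msn,
                 macro_specificity = msp,
                 accuracy_reduction = base_cm$accuracy - acc,
                 sensitivity_reduction = base_cm$macro_sensitivity - msn,
                 specificity_reduction = base_cm$macro_specificity - msp),
               prof = data.frame(
                 replicate = rep_i, rate = rate, method = method,
                 profile = profile_levels(),
                 accuracy = rowMeans(sens_mat),
                 reduction = base_cm$sensitivity - rowMeans(sens_mat)),
               eff = data.frame(
                 replicate = rep_i, rate = rate, method = method,
                 variable = selected, efficiency = unname(e)))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          fails[[length(fails) + 1]] <- data.frame(
            replicate = rep_i, rate = rate, method = method,
            message = conditionMessage(res))
        } else {
          metrics[[length(metrics) + 1]] <- res$metrics
          prof[[length(prof) + 1]] <- res$prof
          eff[[length(eff) + 1]] <- res$eff
        }
      }
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  structure(list(metrics = bind(metrics), profile_accuracy = bind(prof),
                 efficiency = bind(eff), selection = bind(sel),
                 baseline = bind(base), failures = bind(fails),
                 n_datasets = n_datasets, rates = rates, methods = methods,
                 m = m, seed = seed, control = ctl),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat("<simulation_report> ", x$n_datasets, " replicates, rates {",
      paste(x$rates, collapse = ", "), "}, methods {",
      paste(x$methods, collapse = ", "), "}",
      if (!is.null(x$failures)) paste0(", ", nrow(x$failures), " failed cells"),
      "\n", sep = "")
  invisible(x)
}

#' Aggregate a simulation report into mean +/- SEM curves
#'
#' @param object a `simulation_report`.
#' @param ... unused.
#' @return list of data frames: `reduction_curves` (per rate x method) and
#'   `efficiency_curves` (per rate x method), each with means and SEMs over
#'   replicates.
#' @export
summary.simulation_report <- function(object, ...) {
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  mtr <- object$metrics
  red <- do.call(rbind, lapply(split(mtr, list(mtr$rate, mtr$method)),
    function(d) data.frame(
      rate = d$rate[1], method = d$method[1], n = nrow(d),
      accuracy_reduction = mean(d$accuracy_reduction),
      accuracy_reduction_sem = sem(d$accuracy_reduction),
      sensitivity_reduction = mean(d$sensitivity_reduction),
      sensitivity_reduction_sem = sem(d$sensitivity_reduction),
      specificity_reduction = mean(d$specificity_reduction),
      specificity_reduction_sem = sem(d$specificity_reduction))))
  ef <- object$efficiency
  effc <- do.call(rbind, lapply(split(ef, list(ef$rate, ef$method)),
    function(d) data.frame(
      rate = d$rate[1], method = d$method[1], n = nrow(d),
      efficiency = mean(d$efficiency),
      efficiency_sem = sem(d$efficiency))))
  rownames(red) <- rownames(effc) <- NULL
  list(reduction_curves = red[order(red$method, red$rate), ],
       efficiency_curves = effc[order(effc$method, effc$rate), ])
}

#' Per-profile accuracy reduction conditional on the missing variable
#'
#' For each (profile, variable, rate): the mean accuracy reduction for rows
#' of that true profile, over the replicates in which the variable was among
#' the three selected missing variables. Cells where a variable was never
#' selected are `NA`.
#'
#' @param report a [run_simulation_grid()] result.
#' @param method imputation method to condition on (default missforest).
#' @return data frame: profile, variable, rate, reduction, n_replicates.
#' @export
conditional_accuracy <- function(report, method = "missforest") {
  stopifnot(inherits(report, "simulation_report"))
  pa <- report$profile_accuracy
  pa <- pa[pa$method == method, ]
  if (!nrow(pa)) stop("no grid cells for method ", method)
  sel <- report$selection
  out <- list()
  for (v in eligible_missing_vars()) {
    reps_v <- sel$replicate[sel$variable == v]
    sub <- pa[pa$replicate %in% reps_v, ]
    for (p in profile_levels()) {
      for (rate in sort(unique(pa$rate))) {
        d <- sub[sub$profile == p & sub$rate == rate, ]
        out[[length(out) + 1]] <- data.frame(
          profile = p, variable = v, rate = rate,
          reduction = if (nrow(d)) mean(d$reduction) else NA_real_,
          n_replicates = nrow(d))
      }
    }
  }
  do.call(rbind, out)
}

#' Train/impute/classify pipeline in the style of a real multi-site analysis
#'
#' Trains the classifier on a complete labeled training table, imputes the
#' test table with iterative random forests (m imputations), classifies each
#' completed dataset and pools labels; in parallel runs the complete-case
#' branch (listwise deletion of rows with any missing classifier feature).
#' Emits per-profile count summaries, pooled per-profile means, and - when
#' validation scores are present - per-variable ANOVA comparisons of the
#' profiles for both branches (validation scores are never imputed; each
#' per-imputation ANOVA uses that imputation's labels).
#'
#' @param train complete labeled [behavioral_table()].
#' @param test [behavioral_table()], may contain missing classification
#'   cells; ids must be disjoint from `train`.
#' @param m imputations (default 10).
#' @param seed integer seed.
#' @param classifier optional pre-trained model.
#' @param mf_ntree,mf_max_iter imputation-forest size and sweep cap.
#' @return a `real_style_result` list: `counts`, `mi` (the
#'   `classification_result`), `aca_labels`, `aca_rows`, `pooled_means`,
#'   `validation`, `classifier`.
#' @export
run_real_style_pipeline <- function(train, test, m = 10, seed = 1L,
                                    classifier = NULL, mf_ntree = 100,
                                    mf_max_iter = 10) {
  stopifnot(inherits(train, "behavioral_table"),
            inherits(test, "behavioral_table"))
  if (length(intersect(train$id, test$id))) {
    stop("train and test tables must be row-disjoint (shared ids found)")
  }
  if (is.null(classifier)) {
    classifier <- train_classifier(train, seed = child_seed(seed, 1),
                                   mtry = 2)
  }
  imps <- impute_missforest(test, m = m, max_iter = mf_max_iter,
                            ntree = mf_ntree, seed = child_seed(seed, 2))
  mi <- classify_imputed(classifier, imps)
  complete_rows <- stats::complete.cases(feature_frame(test))
  aca_labels <- classify(classifier, test[complete_rows, , drop = FALSE])
  counts <- data.frame(
    approach = c("MI_mean", "MI_sd", "ACA"),
    rbind(mi$profile_counts$mean, mi$profile_counts$sd,
          as.integer(table(factor(aca_labels, levels = profile_levels())))))
  names(counts)[-1] <- profile_levels()
  counts$total <- c(nrow(test), NA, sum(complete_rows))
  validation <- NULL
  val_present <- intersect(validation_vars(), names(test))
  if (length(val_present)) {
    rows <- list()
    for (v in val_present) {
      yv <- test[[v]]
      mi_stats <- t(vapply(seq_len(m), function(j) {
        g <- factor(mi$per_imputation_labels[, j], levels = profile_levels())
        ok <- !is.na(yv)
        an <- summary(stats::aov(yv[ok] ~ droplevels(g[ok])))[[1]]
        c(F = an$`F value`[1],
          eta = an$`Sum Sq`[1] / sum(an$`Sum Sq`),
          df1 = an$Df[1], df2 = an$Df[2], n = sum(ok))
      }, numeric(5)))
      yv_c <- yv[complete_rows]
      ok_c <- !is.na(yv_c)
      an_aca <- summary(stats::aov(yv_c[ok_c] ~ droplevels(aca_labels[ok_c])))[[1]]
      rows[[length(rows) + 1]] <- data.frame(
        variable = v,
        approach = c("MI", "ACA"),
        n = c(mean(mi_stats[, "n"]), sum(ok_c)),
        F = c(mean(mi_stats[, "F"]), an_aca$`F value`[1]),
        eta_squared = c(mean(mi_stats[, "eta"]),
                        an_aca$`Sum Sq`[1] / sum(an_aca$`Sum Sq`)),
        p = c(stats::pf(mean(mi_stats[, "F"]), mi_stats[1, "df1"],
                        mean(mi_stats[, "df2"]), lower.tail = FALSE),
              stats::pf(an_aca$`F value`[1], an_aca$Df[1], an_aca$Df[2],
                        lower.tail = FALSE)))
    }
    validation <- do.call(rbind, rows)
  }
  structure(list(counts = counts, mi = mi, aca_labels = aca_labels,
                 aca_rows = which(complete_rows),
                 pooled_means = pooled_profile_means(imps, mi$pooled_labels),
                 validation = validation, classifier = classifier),
            class = "real_style_result")
}

#' Write tidy CSV summaries (and optionally plots) of a simulation report
#'
#' Writes `reduction_curves.csv`, `efficiency_curves.csv`,
#' `conditional_accuracy.csv` and a `manifest.json` (seed, grid layout,
#' package and R versions) into `dir`. Re-running with the same report
#' reproduces the CSVs byte-identically. If ggplot2 is installed and
#' `plots = TRUE`, reduction and efficiency curve PNGs are written too.
#'
#' @param report a [run_simulation_grid()] result.
#' @param dir output directory (created if needed).
#' @param plots write PNG figures when ggplot2 is available.
#' @return invisibly, the written file paths.
#' @export
report <- function(report, dir, plots = FALSE) {
  stopifnot(inherits(report, "simulation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- summary(report)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(sm$reduction_curves, "reduction_curves.csv")
  wr(sm$efficiency_curves, "efficiency_curves.csv")
  if ("missforest" %in% report$methods) {
    wr(conditional_accuracy(report), "conditional_accuracy.csv")
  }
  manifest <- list(seed = report$seed, n_datasets = report$n_datasets,
                   rates = report$rates, methods = report$methods,
                   m = report$m,
                   package_version = as.character(utils::packageVersion("miprofile")),
                   r_version = R.version.string)
  mp <- file.path(dir, "manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(utils::capture.output(utils::str(manifest)), mp)
  }
  paths <- c(paths, mp)
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    g <- ggplot2::ggplot(sm$reduction_curves,
                         ggplot2::aes(x = rate, y = accuracy_reduction,
                                      colour = method)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = accuracy_reduction - accuracy_reduction_sem,
        ymax = accuracy_reduction + accuracy_reduction_sem), width = 0.01) +
      ggplot2::labs(x = "missingness rate",
                    y = "accuracy reduction vs complete data")
    p <- file.path(dir, "reduction_curves.png")
    ggplot2::ggsave(p, g, width = 6, height = 4, dpi = 120)
    paths <- c(paths, p)
  }
  invisible(paths)
}
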