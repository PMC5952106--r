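#' Combine estimates across imputations with Rubin's rules
#'
#' Pools m point estimates and their within-imputation variances: the pooled
#' point is the mean of the estimates, the within variance W the mean of the
#' variances, the between variance B the sample variance of the estimates,
#' and the total variance `T = W + (1 + 1/m) B`. Degrees of freedom use the
#' small-sample (Barnard-Rubin) adjustment when a finite complete-data df is
#' supplied: with `r = (1 + 1/m) B / T`,
#' `nu_large = (m - 1) / r^2` and
#' `nu_obs = ((df_complete + 1) / (df_complete + 3)) * df_complete * (1 - r)`,
#' the adjusted df is `nu_large * nu_obs / (nu_large + nu_obs)`.
#'
#' @param estimates numeric vector of m point estimates.
#' @param variances numeric vector of m within-imputation variances.
#' @param df_complete complete-data degrees of freedom (may be `Inf`, in
#'   which case the classic large-sample df is used).
#' @return a `pooled_estimate` list: `point`, `within`, `between`, `total`,
#'   `df`, `m`, `r`.
#' @export
#' @examples
#' rubin_pool(c(1, 2, 3), c(1, 1, 1))  # point 2, total 7/3
rubin_pool <- function(estimates, variances, df_complete = Inf) {
  m <- length(estimates)
  stopifnot(m >= 1, length(variances) == m, all(variances >= 0))
  point <- mean(estimates)
  W <- mean(variances)
  if (m == 1) {
    warning("single imputation: between-imputation variance is undefined; ",
            "returning complete-data inference")
    return(structure(list(point = point, within = W, between = NA_real_,
                          total = W, df = df_complete, m = 1L, r = 0),
                     class = "pooled_estimate"))
  }
  B <- stats::var(estimates)
  total <- W + (1 + 1 / m) * B
  if (B == 0 || total == 0) {
    r <- 0
    df <- df_complete
  } else {
    r <- (1 + 1 / m) * B / total
    nu_large <- (m - 1) / r^2
    if (is.finite(df_complete)) {
      nu_obs <- ((df_complete + 1) / (df_complete + 3)) * df_complete * (1 - r)
      df <- nu_large * nu_obs / (nu_large + nu_obs)
    } else {
      df <- nu_large
    }
  }
  structure(list(point = point, within = W, between = B, total = total,
                 df = df, m = as.integer(m), r = r),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("<pooled_estimate> point=%.4g total_var=%.4g df=%.1f (m=%d)\n",
              x$point, x$total, x$df, x$m))
  invisible(x)
}

imputation_tables <- function(x) {
  if (inherits(x, "imputation_set")) x$tables
  else if (inherits(x, "behavioral_table")) list(x)
  else stop("expected an imputation_set or behavioral_table")
}

#' Pooled two-group t-test across imputations
#'
#' Per imputation, the group mean difference and its variance (Welch by
#' default, pooled-variance with `var_equal = TRUE`) are computed, then
#' combined with [rubin_pool()]; `t = point / sqrt(total)` with the adjusted
#' df. With m = 1 this reduces exactly to the ordinary two-sample t-test.
#' Cohen's d uses the pooled-across-groups SD, averaged over imputations.
#'
#' @param imps an `imputation_set` (or a single table).
#' @param groups factor aligned with the rows.
#' @param group_a,group_b the two levels to compare (a minus b).
#' @param variable score column to test.
#' @param var_equal use the pooled-variance t instead of Welch.
#' @return list with `t`, `df`, `p`, `cohens_d`, `estimate`, and the
#'   underlying `pooled` object.
#' @export
pooled_t_test <- function(imps, groups, group_a, group_b, variable,
                          var_equal = FALSE) {
  tables <- imputation_tables(imps)
  groups <- as.factor(groups)
  est <- var_w <- dfc <- dvec <- numeric(length(tables))
  for (j in seq_along(tables)) {
    x <- tables[[j]][[variable]][groups == group_a]
    y <- tables[[j]][[variable]][groups == group_b]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    na <- length(x); nb <- length(y)
    if (na < 2 || nb < 2) stop("both groups need at least 2 observations")
    va <- stats::var(x); vb <- stats::var(y)
    if (va == 0 && vb == 0) stop("degenerate group variance")
    est[j] <- mean(x) - mean(y)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (var_equal) {
      var_w[j] <- sp2 * (1 / na + 1 / nb)
      dfc[j] <- na + nb - 2
    } else {
      var_w[j] <- va / na + vb / nb
      dfc[j] <- var_w[j]^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
    dvec[j] <- est[j] / sqrt(sp2)
  }
  pooled <- suppressWarnings(rubin_pool(est, var_w, df_complete = mean(dfc)))
  t_stat <- pooled$point / sqrt(pooled$total)
  list(t = t_stat, df = pooled$df,
       p = 2 * stats::pt(-abs(t_stat), pooled$df),
       cohens_d = mean(dvec), estimate = pooled$point, pooled = pooled)
}

#' Pooled Pearson correlation across imputations
#'
#' Per-imputation correlations are mapped to Fisher's z (variance
#' `1/(n - 3)`), pooled with [rubin_pool()], and back-transformed, which
#' keeps the pooled r in `[-1, 1]`. With m = 1 the ordinary Pearson test
#' with `n - 2` df is returned.
#'
#' @param imps an `imputation_set` (or a single table).
#' @param var_x,var_y score columns to correlate.
#' @param groups,group optional factor and level restricting the rows.
#' @return list with `r`, `df`, `p` and the pooled z-scale object.
#' @export
pooled_correlation <- function(imps, var_x, var_y, groups = NULL,
                               group = NULL) {
  tables <- imputation_tables(imps)
  keep <- if (is.null(groups)) rep(TRUE, nrow(tables[[1]]))
          else as.factor(groups) == group
  rs <- zs <- vs <- ns <- numeric(length(tables))
  for (j in seq_along(tables)) {
    x <- tables[[j]][[var_x]][keep]
    y <- tables[[j]][[var_y]][keep]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 4) stop("need at least 4 complete pairs")
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      stop("zero variance in ", if (stats::var(x) == 0) var_x else var_y)
    }
    rs[j] <- stats::cor(x, y)
    zs[j] <- atanh(min(max(rs[j], -1 + 1e-12), 1 - 1e-12))
    vs[j] <- 1 / (length(x) - 3)
    ns[j] <- length(x)
  }
  if (length(tables) == 1) {
    n <- ns[1]; r <- rs[1]
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    return(list(r = r, df = n - 2, p = 2 * stats::pt(-abs(t_stat), n - 2),
                pooled = NULL))
  }
  pooled <- rubin_pool(zs, vs, df_complete = mean(ns) - 3)
  t_stat <- pooled$point / sqrt(pooled$total)
  list(r = tanh(pooled$point), df = pooled$df,
       p = 2 * stats::pt(-abs(t_stat), pooled$df), pooled = pooled)
}

#' Pooled one-way ANOVA across imputations
#'
#' Per imputation: one-way ANOVA F and `eta^2 = SS_between / SS_total`.
#' Reported F is the across-imputation mean (with its SD) and eta-squared
#' the across-imputation mean; the p-value is evaluated from the mean F at
#' the per-imputation degrees of freedom. Pairwise profile orderings come
#' from Tukey HSD at `alpha`, keeping relations that hold (same sign,
#' significant) in at least half of the imputations.
#'
#' @param imps an `imputation_set` (or a single table).
#' @param groups factor aligned with rows.
#' @param variable score column to test.
#' @param alpha significance level for the post-hoc comparisons.
#' @return list with `F`, `F_sd`, `eta_squared`, `df1`, `df2`, `p`,
#'   `pairwise` (data frame of retained relations) and per-imputation stats.
#' @export
pooled_anova <- function(imps, groups, variable, alpha = 0.05) {
  tables <- imputation_tables(imps)
  groups <- as.factor(groups)
  m <- length(tables)
  Fs <- etas <- numeric(m)
  df1 <- df2 <- NA
  rel_list <- list()
  for (j in seq_len(m)) {
    y <- tables[[j]][[variable]]
    ok <- !is.na(y) & !is.na(groups)
    g <- droplevels(groups[ok])
    if (nlevels(g) < 2 || any(table(g) < 2)) {
      stop("need >= 2 groups with >= 2 rows each")
    }
    fit <- stats::aov(y[ok] ~ g)
    an <- summary(fit)[[1]]
    Fs[j] <- an$`F value`[1]
    etas[j] <- an$`Sum Sq`[1] / sum(an$`Sum Sq`)
    df1 <- an$Df[1]; df2 <- an$Df[2]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    sig <- tk[, "p adj"] < alpha
    if (any(sig)) {
      cmp <- rownames(tk)[sig]
      hi_lo <- t(vapply(seq_along(cmp), function(i) {
        ab <- strsplit(cmp[i], "-", fixed = TRUE)[[1]]
        if (tk[cmp[i], "diff"] > 0) ab else rev(ab)
      }, character(2)))
      rel_list[[j]] <- paste(hi_lo[, 1], ">", hi_lo[, 2])
    } else rel_list[[j]] <- character(0)
  }
  all_rel <- table(unlist(rel_list))
  kept <- names(all_rel)[all_rel >= m / 2]
  list(F = mean(Fs), F_sd = stats::sd(Fs), eta_squared = mean(etas),
       df1 = df1, df2 = df2,
       p = stats::pf(mean(Fs), df1, df2, lower.tail = FALSE),
       pairwise = data.frame(relation = kept,
                             support = as.integer(all_rel[kept])),
       per_imputation = data.frame(F = Fs, eta_squared = etas))
}

#' Pooled per-profile means with Rubin-combined SEM
#'
#' Group means are computed per imputation and combined with [rubin_pool()]
#' using `var(group)/n` as the within-imputation variance; the SEM is the
#' square root of the pooled total variance.
#'
#' @param imps an `imputation_set` (or a single table).
#' @param groups factor aligned with rows (e.g. profile labels).
#' @param variables score columns (default the five classification scores).
#' @return tidy data frame: group, variable, mean, sem, df.
#' @export
pooled_profile_means <- function(imps, groups,
                                 variables = classification_vars()) {
  tables <- imputation_tables(imps)
  groups <- as.factor(groups)
  out <- list()
  for (g in levels(groups)) {
    for (v in variables) {
      est <- vr <- numeric(length(tables))
      for (j in seq_along(tables)) {
        y <- tables[[j]][[v]][groups == g]
        y <- y[!is.na(y)]
        est[j] <- mean(y)
        vr[j] <- stats::var(y) / length(y)
      }
      pl <- suppressWarnings(
        rubin_pool(est, vr, df_complete = sum(groups == g) - 1))
      out[[length(out) + 1]] <- data.frame(
        group = g, variable = v, mean = pl$point,
        sem = sqrt(pl$total), df = pl$df)
    }
  }
  do.call(rbind, out)
}
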