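#' Define a missing-at-random mechanism
#'
#' Exactly three of the six classification-feature variables (age plus the
#' five test scores) carry missingness. For each selected variable, each
#' participant's cell is missing with probability
#' `plogis(intercept + sex_coefficient * female + site_coefficients[site])`;
#' the intercept is solved per table so the expected missing fraction within
#' each selected variable equals `target_rate`. Because the propensity
#' depends only on the always-observed covariates sex and site, the
#' mechanism is MAR by construction.
#'
#' @param target_rate missing fraction per selected variable, in `[0, 0.5]`.
#' @param selected_variables character(3) subset of
#'   [eligible_missing_vars()], or `NULL` to draw 3 at random from `seed`.
#' @param sex_coefficient log-odds shift for female participants.
#' @param site_coefficients per-site log-odds shifts; recycled/truncated to
#'   the table's site count when applied. Defaults to 8 evenly spaced values
#'   in `[-1, 1]`.
#' @param seed integer seed.
#' @return a `mar_mechanism` list.
#' @export
mar_mechanism <- function(target_rate, selected_variables = NULL,
                          sex_coefficient = 0.8,
                          site_coefficients = seq(-1, 1, length.out = 8),
                          seed = 1L) {
  if (target_rate < 0 || target_rate > 0.5) {
    stop("config error: target_rate must be in [0, 0.5]")
  }
  if (is.null(selected_variables)) {
    selected_variables <- with_seed(child_seed(seed, 11),
                                    sample(eligible_missing_vars(), 3))
  }
  stopifnot(length(selected_variables) == 3,
            !anyDuplicated(selected_variables),
            all(selected_variables %in% eligible_missing_vars()))
  structure(list(target_rate = target_rate,
                 selected_variables = selected_variables,
                 sex_coefficient = sex_coefficient,
                 site_coefficients = site_coefficients,
                 intercept = NA_real_, seed = as.integer(seed)),
            class = "mar_mechanism")
}

# Per-row linear predictor without intercept, for a given table.
mar_linear_predictor <- function(mechanism, table) {
  sc <- mechanism$site_coefficients
  n_sites <- nlevels(table$site)
  if (length(sc) < n_sites) sc <- rep_len(sc, n_sites)
  mechanism$sex_coefficient * (table$sex == "F") +
    sc[as.integer(table$site)]
}

# Solve the intercept so mean(plogis(a + lp)) == rate, by bisection.
solve_mar_intercept <- function(lp, rate, tol = 1e-6) {
  if (rate <= 0) return(-Inf)
  f <- function(a) mean(stats::plogis(a + lp)) - rate
  lo <- -30; hi <- 30
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Induce missing-at-random cells in a complete table
#'
#' Draws an independent Bernoulli missingness indicator for each (row,
#' selected variable) cell at the covariate-dependent propensity. The
#' per-row missing count is structurally capped at 3 because only the three
#' selected variables are eligible. The complete input is retained in the
#' result for later efficiency and accuracy scoring.
#'
#' @param table [behavioral_table()] complete in age and the classification
#'   variables.
#' @param mechanism a [mar_mechanism()].
#' @return a `mar_result` list: `table` (with `NA` cells), `mask` (0/1
#'   matrix, rows x eligible variables), `mechanism` (with the solved
#'   intercept and realized rate), `original`.
#' @export
induce_mar <- function(table, mechanism) {
  stopifnot(inherits(table, "behavioral_table"),
            inherits(mechanism, "mar_mechanism"))
  vars <- eligible_missing_vars()
  if (any(is.na(as.matrix(table[vars])))) {
    stop("induce_mar requires a table with complete classification features")
  }
  n <- nrow(table)
  mask <- matrix(0L, n, length(vars), dimnames = list(NULL, vars))
  mechanism$intercept <- NA_real_
  if (mechanism$target_rate > 0) {
    lp <- mar_linear_predictor(mechanism, table)
    a <- solve_mar_intercept(lp, mechanism$target_rate)
    mechanism$intercept <- a
    p <- stats::plogis(a + lp)
    with_seed(child_seed(mechanism$seed, 17), {
      for (v in mechanism$selected_variables) {
        mask[, v] <- as.integer(stats::runif(n) < p)
      }
    })
  }
  out <- table
  for (v in mechanism$selected_variables) out[[v]][mask[, v] == 1] <- NA
  mechanism$realized_rate <- sum(mask) / (3 * n)
  structure(list(table = out, mask = mask, mechanism = mechanism,
                 original = table),
            class = "mar_result")
}

nagelkerke_r2 <- function(fit, null_fit, n) {
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null_fit))
  (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
}

fit_mar_glm <- function(y, sex, site) {
  dat <- data.frame(y = y, sex = sex, site = droplevels(site))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ sex + site, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!sep && any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) sep <- TRUE
  null_fit <- stats::glm(y ~ 1, family = stats::binomial(), data = dat)
  fit_sex <- suppressWarnings(
    stats::glm(y ~ sex, family = stats::binomial(), data = dat))
  fit_site <- suppressWarnings(
    stats::glm(y ~ site, family = stats::binomial(), data = dat))
  full_dev <- fit$deviance
  full_df <- fit$df.residual
  lr_p <- function(small) {
    stat <- small$deviance - full_dev
    df <- small$df.residual - full_df
    if (df <= 0) return(NA_real_)
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
  p_sex <- lr_p(fit_site)
  p_site <- lr_p(fit_sex)
  if (sep) {
    # complete separation: the unpenalized MLE diverges. Refit with a small
    # ridge penalty by IRLS so the pseudo-R2 stays finite; p-values from the
    # (conservative) likelihood-ratio statistics of the unpenalized fits.
    fit <- ridge_logistic(stats::model.matrix(~ sex + site, dat), y)
  }
  list(p_sex = p_sex,
       p_site = p_site,
       nagelkerke = if (sep) {
         n <- length(y)
         ll1 <- fit$loglik
         ll0 <- as.numeric(stats::logLik(null_fit))
         (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
       } else {
         nagelkerke_r2(fit, null_fit, length(y))
       },
       separation = sep)
}

# Minimal ridge-penalized logistic regression (IRLS), used only as a
# fallback under complete separation.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 50) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < 1e-8) { beta <- new; break }
    beta <- new
  }
  eta <- drop(X %*% beta)
  list(coef = drop(beta),
       loglik = sum(y * eta - log1p(exp(eta))))
}

#' Verify that induced missingness is predicted by sex and site
#'
#' Fits, for each selected variable, a logistic regression of the
#' missingness indicator on sex and site, reporting likelihood-ratio
#' p-values per term and Nagelkerke's pseudo-R-squared. Because the three
#' selected variables share one propensity model, an `overall` fit on the
#' stacked indicators is also reported; it is the natural mechanism-level
#' verification and has three times the effective sample size.
#'
#' @param mask a `mar_result` from [induce_mar()], or its 0/1 mask matrix.
#' @param table the behavioral table (needed when `mask` is a bare matrix).
#' @return a `mar_verification` list with `per_variable` (data frame) and
#'   `overall` (one-row data frame).
#' @export
verify_mar <- function(mask, table = NULL) {
  if (inherits(mask, "mar_result")) {
    if (is.null(table)) table <- mask$original
    mech_vars <- mask$mechanism$selected_variables
    mask <- mask$mask
  } else {
    mech_vars <- colnames(mask)[colSums(mask) > 0]
  }
  stopifnot(!is.null(table))
  rows <- lapply(mech_vars, function(v) {
    y <- mask[, v]
    if (sum(y) == 0 || sum(y) == length(y)) {
      stop("verify_mar needs both missing and observed cells in ", v)
    }
    r <- fit_mar_glm(y, table$sex, table$site)
    data.frame(variable = v, p_sex = r$p_sex, p_site = r$p_site,
               nagelkerke = r$nagelkerke, separation = r$separation)
  })
  y_all <- as.vector(mask[, mech_vars])
  r_all <- fit_mar_glm(y_all, rep(table$sex, length(mech_vars)),
                       rep(table$site, length(mech_vars)))
  structure(list(
    per_variable = do.call(rbind, rows),
    overall = data.frame(p_sex = r_all$p_sex, p_site = r_all$p_site,
                         nagelkerke = r_all$nagelkerke,
                         separation = r_all$separation)),
    class = "mar_verification")
}
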