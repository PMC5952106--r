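# Internal numeric view used by every imputer: the six continuous features
# (age + five tests) as a matrix, plus the sex/site design columns. Labels
# and validation scores never enter this frame, so they are structurally
# concealed from the imputation models.
imputation_frame <- function(table) {
  stopifnot(inherits(table, "behavioral_table"))
  vars <- eligible_missing_vars()
  X <- as.matrix(as.data.frame(table)[vars])
  storage.mode(X) <- "double"
  Z <- stats::model.matrix(~ sex + site, data = table)[, -1, drop = FALSE]
  miss <- is.na(X)
  for (v in vars) {
    if (all(miss[, v])) stop("cannot impute fully missing column ", v)
  }
  list(X = X, Z = Z, miss = miss, vars = vars)
}

new_imputation_set <- function(method, tables, seed = NULL,
                               convergence = NULL, params = list()) {
  structure(list(method = method, m = length(tables), tables = tables,
                 convergence = convergence, seed = seed, params = params),
            class = "imputation_set")
}

set_filled <- function(table, X) {
  for (v in colnames(X)) table[[v]] <- X[, v]
  table
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> method=", x$method, ", m=", x$m, ", n=",
      nrow(x$tables[[1]]), "\n", sep = "")
  invisible(x)
}

#' Mean replacement imputation
#'
#' Every missing cell of a variable is replaced by the observed mean of that
#' variable. Deterministic, single completed dataset (m = 1).
#'
#' @param table [behavioral_table()] with missing cells.
#' @return an `imputation_set` with `m = 1`.
#' @export
impute_mean <- function(table) {
  fr <- imputation_frame(table)
  X <- fr$X
  for (v in fr$vars) {
    mis <- fr$miss[, v]
    if (any(mis)) X[mis, v] <- mean(X[!mis, v])
  }
  new_imputation_set("mean_replacement", list(set_filled(table, X)))
}

# Draw one donor value per missing row: k observed cases with the nearest
# perturbed predictions, one chosen uniformly. The k nearest of each row lie
# inside a window of 2k+1 sorted observed predictions around the insertion
# point, so selection is vectorized over missing rows.
pmm_draw <- function(pred_obs, y_obs, pred_mis, k) {
  ord <- order(pred_obs)
  po <- pred_obs[ord]
  yo <- y_obs[ord]
  n <- length(po)
  k <- min(k, n)
  nm <- length(pred_mis)
  pos <- findInterval(pred_mis, po)
  cand <- pmin(pmax(outer(pos, (-k):k, "+"), 1L), n)
  d <- abs(matrix(po[cand], nm) - pred_mis)
  sel <- matrix(0L, nm, k)
  rows <- seq_len(nm)
  for (s in seq_len(k)) {     # s-th nearest candidate per row
    j <- max.col(-d, ties.method = "first")
    sel[, s] <- j
    d[cbind(rows, j)] <- Inf
  }
  pick <- sel[cbind(rows, sample.int(k, nm, replace = TRUE))]
  yo[cand[cbind(rows, pick)]]
}

#' Multiple imputation by predictive mean matching
#'
#' Chained-equations scheme: missing cells are initialized with random draws
#' from the observed values; for `n_cycles` sweeps each incomplete variable
#' is regressed (on the current completed values of the other continuous
#' features plus sex and site), the coefficients are perturbed by a draw
#' from their estimated sampling distribution, and each missing cell copies
#' the observed value of one of the `k_donors` cases with the nearest
#' perturbed predictions. The `m` imputations run on independent sub-seed
#' streams. A rank-deficient regression is ridge-stabilized and flagged in
#' the result's `params$ridged`.
#'
#' @param table [behavioral_table()] with missing cells.
#' @param m number of imputations (default 10).
#' @param k_donors donor pool size (default 5).
#' @param n_cycles chained-equation sweeps (default 5).
#' @param seed integer seed.
#' @return an `imputation_set`. Imputed values are always members of the
#'   observed-value set of their variable.
#' @export
impute_pmm <- function(table, m = 10, k_donors = 5, n_cycles = 5, seed = 1L) {
  fr <- imputation_frame(table)
  incomplete <- fr$vars[colSums(fr$miss) > 0]
  incomplete <- incomplete[order(colSums(fr$miss)[incomplete])]
  ridged <- FALSE
  tables <- vector("list", m)
  for (j in seq_len(m)) {
    X <- fr$X
    with_seed(child_seed(seed, 101, j), {
      for (v in incomplete) {
        mis <- fr$miss[, v]
        if (sum(!mis) < k_donors) stop("fewer observed rows than donors in ", v)
        X[mis, v] <- sample(X[!mis, v], sum(mis), replace = TRUE)
      }
      for (cyc in seq_len(n_cycles)) {
        for (v in incomplete) {
          mis <- fr$miss[, v]
          D <- cbind(1, X[, setdiff(fr$vars, v), drop = FALSE], fr$Z)
          Do <- D[!mis, , drop = FALSE]
          yo <- fr$X[!mis, v]
          XtX <- crossprod(Do)
          R <- tryCatch(chol(XtX), error = function(e) NULL)
          if (is.null(R)) {
            ridged <- TRUE
            R <- chol(XtX + diag(1e-6 * pmax(diag(XtX), 1)))
          }
          beta <- backsolve(R, forwardsolve(t(R), crossprod(Do, yo)))
          resid <- yo - drop(Do %*% beta)
          sigma2 <- sum(resid^2) / max(nrow(Do) - ncol(Do), 1)
          beta_star <- beta + sqrt(sigma2) *
            backsolve(R, stats::rnorm(ncol(Do)))
          pred <- drop(D %*% beta_star)
          X[mis, v] <- pmm_draw(pred[!mis], yo, pred[mis], k_donors)
        }
      }
    })
    tables[[j]] <- set_filled(table, X)
  }
  new_imputation_set("pmm", tables, seed = seed,
                     params = list(k_donors = k_donors, n_cycles = n_cycles,
                                   ridged = ridged))
}

#' Multiple imputation by iterative random forests
#'
#' Per imputation: missing cells are initialized with observed means;
#' incomplete variables are visited in order of ascending missingness; each
#' sweep fits a random-forest regression of every incomplete variable on the
#' other continuous features plus sex and site (rows where the variable is
#' observed) and predicts its missing cells. After each sweep the change
#' statistic `delta = sum((x_new - x_old)^2) / sum(x_new^2)` over imputed
#' cells is computed; iteration stops when `delta` increases (the previous
#' sweep's values are returned) or `max_iter` is reached. The `m`
#' imputations differ only in the forests' RNG streams.
#'
#' @param table [behavioral_table()] with missing cells.
#' @param m number of imputations (default 10).
#' @param max_iter maximum sweeps (default 10).
#' @param ntree trees per imputation forest (default 100).
#' @param seed integer seed.
#' @return an `imputation_set` with per-imputation convergence traces.
#' @export
impute_missforest <- function(table, m = 10, max_iter = 10, ntree = 100,
                              seed = 1L) {
  fr <- imputation_frame(table)
  incomplete <- fr$vars[colSums(fr$miss) > 0]
  incomplete <- incomplete[order(colSums(fr$miss)[incomplete])]
  covars <- data.frame(sex = table$sex, site = table$site)
  tables <- vector("list", m)
  traces <- vector("list", m)
  for (j in seq_len(m)) {
    X <- fr$X
    for (v in incomplete) {
      mis <- fr$miss[, v]
      X[mis, v] <- mean(X[!mis, v])
    }
    trace <- numeric(0)
    if (length(incomplete)) {
      delta_prev <- Inf
      for (it in seq_len(max_iter)) {
        X_old <- X
        for (v in incomplete) {
          mis <- fr$miss[, v]
          dat <- cbind(as.data.frame(X[, setdiff(fr$vars, v), drop = FALSE]),
                       covars)
          fit <- ranger::ranger(
            x = dat[!mis, , drop = FALSE], y = fr$X[!mis, v],
            num.trees = ntree, num.threads = 1,
            seed = child_seed(seed, 202, j, it, match(v, fr$vars)))
          X[mis, v] <- stats::predict(fit, data = dat[mis, , drop = FALSE],
                                      num.threads = 1)$predictions
        }
        imp_cells <- fr$miss[, incomplete, drop = FALSE]
        new_vals <- X[, incomplete, drop = FALSE][imp_cells]
        old_vals <- X_old[, incomplete, drop = FALSE][imp_cells]
        delta <- sum((new_vals - old_vals)^2) / sum(new_vals^2)
        trace <- c(trace, delta)
        if (delta > delta_prev) {
          X <- X_old
          break
        }
        delta_prev <- delta
      }
    }
    tables[[j]] <- set_filled(table, X)
    traces[[j]] <- trace
  }
  new_imputation_set("missforest", tables, seed = seed, convergence = traces,
                     params = list(max_iter = max_iter, ntree = ntree))
}

#' Imputation efficiency: variance ratio to the original data
#'
#' For each variable, the full-column variance of the imputed data divided
#' by the full-column variance of the original complete data; 1 is ideal,
#' values below 1 indicate variance shrinkage. For an `imputation_set` the
#' ratio is averaged over its m completed tables.
#'
#' @param imputed an `imputation_set` or a single completed
#'   [behavioral_table()].
#' @param original the row-aligned complete table.
#' @param variables variables to evaluate (default the six continuous
#'   features).
#' @return named numeric vector of variance ratios; `NA` where the original
#'   variance is zero.
#' @export
efficiency <- function(imputed, original, variables = eligible_missing_vars()) {
  stopifnot(inherits(original, "behavioral_table"))
  tables <- if (inherits(imputed, "imputation_set")) imputed$tables
            else list(imputed)
  stopifnot(all(vapply(tables, nrow, 0L) == nrow(original)))
  orig_var <- vapply(variables, function(v) stats::var(original[[v]]), 0)
  ratios <- sapply(tables, function(tb) {
    vapply(variables, function(v) stats::var(tb[[v]]), 0) / orig_var
  })
  ratios <- matrix(ratios, nrow = length(variables),
                   dimnames = list(variables, NULL))
  out <- rowMeans(ratios)
  out[orig_var == 0] <- NA_real_
  out
}
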