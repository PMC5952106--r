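#' Variable vocabularies of the behavioral data model
#'
#' The data model has a fixed set of roles: `id`, two always-observed
#' covariates (`sex`, `site`), `age`, five standardized classification test
#' scores, four optional standardized validation scores, and an optional
#' reading-profile label. All scores are on a mean-100 / SD-15 scale.
#'
#' @return character vectors of column names / factor levels.
#' @export
classification_vars <- function() {
  c("pseudoword_id", "real_word_id", "passage_comp", "verbal_iq", "ran")
}

#' @rdname classification_vars
#' @export
validation_vars <- function() {
  c("piq", "spelling", "elision", "digit_span")
}

#' @rdname classification_vars
#' @export
eligible_missing_vars <- function() {
  c("age", classification_vars())
}

#' @rdname classification_vars
#' @export
profile_levels <- function() {
  c("PoorDecoder", "PoorComprehender", "GenerallyPoorReader", "Control")
}

# Fixed tie-break priority used when pooling labels across imputations.
profile_priority <- function() {
  c("Control", "PoorDecoder", "PoorComprehender", "GenerallyPoorReader")
}

sex_levels <- function() c("F", "M")

canonical_column_order <- function(nms) {
  ord <- c("id", "sex", "site", "age", classification_vars(),
           validation_vars(), "label")
  c(intersect(ord, nms), setdiff(nms, ord))
}

#' Construct and validate a behavioral table
#'
#' A `behavioral_table` is a data frame with one row per participant:
#' character `id` (unique), factor `sex` and `site`, numeric `age`, the five
#' classification scores, optionally the four validation scores, and
#' optionally a `label` factor over the four reading profiles. Missing cells
#' are `NA`; every non-missing score must be finite. Columns are kept in a
#' canonical order so that read/write round-trips are stable.
#'
#' @param df a data frame with at least `id`, `sex`, `site`, `age` and the
#'   five classification score columns.
#' @param site_levels optional character vector declaring the site
#'   vocabulary; defaults to the levels present.
#' @return the validated data frame with class `behavioral_table`.
#' @export
behavioral_table <- function(df, site_levels = NULL) {
  stopifnot(is.data.frame(df))
  needed <- c("id", "sex", "site", "age", classification_vars())
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("schema error: duplicate participant id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (!is.factor(df$sex)) df$sex <- factor(df$sex, levels = sex_levels())
  if (any(is.na(df$sex))) stop("schema error: unknown sex level")
  if (is.null(site_levels)) {
    site_levels <- if (is.factor(df$site)) levels(df$site) else
      sort(unique(as.character(df$site)))
  }
  site_chr <- as.character(df$site)
  if (nrow(df) && any(!site_chr %in% site_levels)) {
    stop("schema error: unknown site level(s): ",
         paste(setdiff(unique(site_chr), site_levels), collapse = ", "))
  }
  df$site <- factor(site_chr, levels = site_levels)
  num_cols <- intersect(c("age", classification_vars(), validation_vars()),
                        names(df))
  for (v in num_cols) {
    df[[v]] <- as.numeric(df[[v]])
    bad <- !is.na(df[[v]]) & !is.finite(df[[v]])
    if (any(bad)) {
      stop("non-finite value in ", v, " at row ", which(bad)[1])
    }
  }
  if ("label" %in% names(df) && nrow(df)) {
    df$label <- factor(as.character(df$label), levels = profile_levels())
    if (any(is.na(df$label) & !is.na(as.character(df$label)))) {
      stop("schema error: unknown profile label")
    }
  } else if ("label" %in% names(df)) {
    df$label <- factor(character(0), levels = profile_levels())
  }
  df <- df[, canonical_column_order(names(df)), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("behavioral_table", "data.frame")
  df
}

#' Read a behavioral table from CSV
#'
#' Missing cells may be encoded as the empty string, `NA` or `NaN`; they
#' become `NA`. Any other non-numeric token in a score column is a parse
#' error naming the offending row and column. Duplicate ids and undeclared
#' sex/site levels are schema errors.
#'
#' @param path CSV file with a header row.
#' @param site_levels optional declared site vocabulary.
#' @return a [behavioral_table()].
#' @export
read_behavioral_table <- function(path, site_levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  na_tokens <- c("", "NA", "NaN")
  num_cols <- intersect(c("age", classification_vars(), validation_vars()),
                        names(raw))
  for (v in num_cols) {
    tok <- raw[[v]]
    tok[tok %in% na_tokens] <- NA_character_
    parsed <- suppressWarnings(as.numeric(tok))
    bad <- !is.na(tok) & is.na(parsed)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("parse error: non-numeric value ", dQuote(tok[i]),
           " in column ", sQuote(v), ", row ", i)
    }
    raw[[v]] <- parsed
  }
  if ("label" %in% names(raw)) raw$label[raw$label %in% na_tokens] <- NA
  behavioral_table(raw, site_levels = site_levels)
}

#' Write a behavioral table to CSV
#'
#' Deterministic canonical column order; missing cells are written as empty
#' strings; numeric cells are rendered with enough digits that a
#' read/write/read round trip reproduces the table exactly.
#'
#' @param table a [behavioral_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_behavioral_table <- function(table, path) {
  stopifnot(inherits(table, "behavioral_table"))
  out <- as.data.frame(table)
  for (v in names(out)) {
    col <- out[[v]]
    out[[v]] <- if (is.numeric(col)) {
      ifelse(is.na(col), "", sprintf("%.17g", col))
    } else {
      ifelse(is.na(col), "", as.character(col))
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  invisible(path)
}

#' Summarize missingness in a behavioral table
#'
#' @param table a [behavioral_table()].
#' @return a list with `per_variable` (fraction of missing cells per numeric
#'   variable), `per_row` (missing-cell count per participant) and `total`
#'   (total missing cells), computed over age, classification and any
#'   validation columns present.
#' @export
missingness_summary <- function(table) {
  stopifnot(inherits(table, "behavioral_table"))
  vars <- intersect(c("age", classification_vars(), validation_vars()),
                    names(table))
  miss <- sapply(vars, function(v) is.na(table[[v]]))
  if (nrow(table) == 1) miss <- matrix(miss, nrow = 1, dimnames = list(NULL, vars))
  if (nrow(table) == 0) miss <- matrix(FALSE, 0, length(vars), dimnames = list(NULL, vars))
  list(per_variable = colMeans(miss),
       per_row = as.integer(rowSums(miss)),
       total = sum(miss))
}

#' @export
print.behavioral_table <- function(x, ...) {
  cat("<behavioral_table> ", nrow(x), " participants, ",
      nlevels(x$site), " sites", sep = "")
  if ("label" %in% names(x) && any(!is.na(x$label))) {
    cnt <- table(x$label)
    cat("; profiles: ", paste(names(cnt), cnt, sep = "=", collapse = " "),
        sep = "")
  }
  ms <- missingness_summary(x)
  cat("; missing cells: ", ms$total, "\n", sep = "")
  invisible(x)
}
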