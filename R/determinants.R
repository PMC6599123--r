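# Reference levels mirror the determinant-regression convention: male sex,
# the most mature GA stratum and non-depleted birth-weight z (>= 0) are the
# baselines, so every printed coefficient is the adjusted excess difference.
.default_refs <- c(sex = "male", ga_stratum = "31-32", bwz_stratum = ">=0")

#' Design matrix for the determinant regression
#'
#' Treatment (dummy) coding of the requested terms with an intercept column.
#' Categorical terms use the conventional reference levels (male sex,
#' 31-32 wk gestational-age stratum, birth-weight z >= 0) unless overridden;
#' numeric terms enter linearly. Rows with missing values in any term are
#' dropped (complete-case), with the dropped count attached.
#'
#' @param data data.frame holding the terms.
#' @param terms character vector of column names.
#' @param refs named character vector of reference levels for categorical
#'   terms (defaults applied where the name matches).
#' @return list: `X` (numeric matrix, intercept first), `map` (data.frame
#'   column -> term/level), `rows` (row indices of `data` used),
#'   `n_dropped`.
#' @export
design_matrix <- function(data, terms, refs = .default_refs) {
  if (anyDuplicated(terms)) stop("duplicated terms")
  missing_terms <- setdiff(terms, names(data))
  if (length(missing_terms))
    stop("term(s) absent from data: ", paste(missing_terms, collapse = ", "))
  df <- as.data.frame(data)[terms]
  cc <- stats::complete.cases(df)
  if (!any(cc)) stop("no complete cases for terms")
  df <- df[cc, , drop = FALSE]
  for (tm in terms) {
    v <- df[[tm]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) {
      v <- droplevels(v)
      if (tm %in% names(refs) && refs[[tm]] %in% levels(v))
        v <- stats::relevel(v, ref = refs[[tm]])
      df[[tm]] <- v
    }
  }
  # a factor observed at a single level (e.g. an all-reference cohort) spans
  # no contrast; it contributes no column rather than breaking the fit
  used <- terms[vapply(df[terms], function(v) !is.factor(v) || nlevels(v) >= 2L,
                       logical(1))]
  X <- if (length(used))
    stats::model.matrix(stats::reformulate(used), data = df)
  else
    stats::model.matrix(~1, data = df)
  term_of <- attr(X, "assign")
  map <- data.frame(
    column = colnames(X),
    term = c("(Intercept)", used)[term_of + 1L],
    level = vapply(seq_along(colnames(X)), function(j) {
      tm <- c("(Intercept)", used)[term_of[j] + 1L]
      if (term_of[j] == 0L || !is.factor(df[[tm]])) NA_character_
      else sub(tm, "", colnames(X)[j], fixed = TRUE)
    }, character(1)),
    row.names = NULL)
  list(X = X, map = map, rows = which(cc), n_dropped = sum(!cc))
}

#' Ordinary least squares with confidence intervals
#'
#' Least-squares fit of `y` on a full-rank design matrix; 95% confidence
#' intervals use the t(0.975, n - p) quantile and two-sided p-values the
#' matching t distribution.
#'
#' @param X numeric design matrix (include an intercept column if wanted).
#' @param y numeric response, length `nrow(X)`.
#' @return data.frame: `term`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `p_value`; attributes `sigma`, `r_squared`, `df_residual`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("singular fit: collinear column(s) ", paste(dropped, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than columns")
  fit <- stats::lm.fit(X, y)
  est <- fit$coefficients
  rss <- sum(fit$residuals^2)
  dfres <- n - p
  sigma2 <- rss / dfres
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  tcrit <- stats::qt(0.975, dfres)
  tval <- ifelse(se > 0, est / se, Inf * sign(est))
  out <- data.frame(term = colnames(X), estimate = est, se = se,
                    ci_low = est - tcrit * se, ci_high = est + tcrit * se,
                    p_value = 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE),
                    row.names = NULL)
  tss <- sum((y - mean(y))^2)
  attr(out, "sigma") <- sqrt(sigma2)
  attr(out, "r_squared") <- if (tss > 0) 1 - rss / tss else NA_real_
  attr(out, "df_residual") <- dfres
  out
}

r2_of <- function(data, outcome, terms, refs) {
  dm <- design_matrix(data, terms, refs)
  y <- data[[outcome]][dm$rows]
  attr(fit_ols(dm$X, y), "r_squared")
}

#' Variance in the method difference explained by one variable
#'
#' Two complementary readings of "variable X explained f% of the variance":
#' the univariate R-squared of a model containing only X, and the
#' incremental R-squared gained when X is added last to the model holding
#' all remaining terms. Both are reported because they answer different
#' questions when terms are correlated.
#'
#' @param data data.frame with the outcome and all terms.
#' @param outcome outcome column name (the per-infant difference `d`).
#' @param terms full term list of the model.
#' @param variable the term to decompose; must be among `terms`.
#' @param refs reference levels, as in [design_matrix()].
#' @return named list: `univariate`, `incremental`, `full_r_squared`.
#' @export
variance_explained <- function(data, outcome, terms, variable,
                               refs = .default_refs) {
  if (!variable %in% terms) stop("'", variable, "' is not among the terms")
  full <- r2_of(data, outcome, terms, refs)
  uni <- r2_of(data, outcome, variable, refs)
  rest <- setdiff(terms, variable)
  reduced <- if (length(rest)) r2_of(data, outcome, rest, refs) else 0
  list(univariate = uni, incremental = full - reduced, full_r_squared = full)
}

#' Determinants of the method difference
#'
#' Multivariable OLS regression of the per-infant difference between observed
#' EM velocity and EM velocity predicted from the z-score metric on infant
#' characteristics, with treatment coding (reference levels: male, 31-32 wk,
#' birth-weight z >= 0) and a per-variable variance-explained decomposition.
#' The default term set is the printed determinant table's: sex,
#' gestational-age stratum, birth-weight z-score stratum; any columns of the
#' fit's data (e.g. extra covariates) may be supplied instead.
#'
#' @param object a [gv_agreement()] fit, or a data.frame already holding a
#'   `d` column plus the terms.
#' @param terms covariate column names.
#' @param refs reference levels for categorical terms.
#' @return object of class `gv_determinants`: `coefficients` (data.frame
#'   with estimates, 95% CI, p-values), `variance_explained` (data.frame),
#'   `n`, `n_dropped`, `r_squared`.
#' @export
difference_determinants <- function(object,
                                    terms = c("sex", "ga_stratum",
                                              "bwz_stratum"),
                                    refs = .default_refs) {
  if (inherits(object, "gv_agreement")) {
    data <- object$data
    data$d <- object$differences
  } else {
    data <- as.data.frame(object)
    if (!"d" %in% names(data)) stop("data need a 'd' outcome column")
  }
  dm <- design_matrix(data, terms, refs)
  y <- data$d[dm$rows]
  tab <- fit_ols(dm$X, y)
  tab$variable <- dm$map$term
  tab$level <- dm$map$level
  ve <- do.call(rbind, lapply(terms, function(tm) {
    v <- variance_explained(data, "d", terms, tm, refs)
    data.frame(variable = tm, univariate_r2 = v$univariate,
               incremental_r2 = v$incremental)
  }))
  structure(list(coefficients = tab, variance_explained = ve,
                 n = length(y), n_dropped = dm$n_dropped,
                 r_squared = attr(tab, "r_squared"),
                 terms = terms, refs = refs),
            class = "gv_determinants")
}

#' @export
print.gv_determinants <- function(x, ...) {
  cat("Determinants of the EM-ZS method difference (n = ", x$n,
      if (x$n_dropped) paste0(", ", x$n_dropped, " incomplete rows dropped"),
      ")\n", sep = "")
  tab <- x$coefficients
  for (i in seq_len(nrow(tab))) {
    lab <- if (is.na(tab$level[i])) tab$term[i]
           else paste0(tab$variable[i], " = ", tab$level[i])
    cat(sprintf("  %-24s %7.2f [%6.2f, %6.2f]  p %s\n", lab, tab$estimate[i],
                tab$ci_low[i], tab$ci_high[i],
                format.pval(tab$p_value[i], digits = 2, eps = 1e-3)))
  }
  cat(sprintf("Model R^2 = %.3f\n", x$r_squared))
  cat("Variance explained (univariate / added-last):\n")
  ve <- x$variance_explained
  for (i in seq_len(nrow(ve)))
    cat(sprintf("  %-12s %.1f%% / %.1f%%\n", ve$variable[i],
                100 * ve$univariate_r2[i], 100 * ve$incremental_r2[i]))
  invisible(x)
}

#' @export
coef.gv_determinants <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}
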