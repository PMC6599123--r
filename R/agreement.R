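#' Bland-Altman limits of agreement
#'
#' Mean, sample standard deviation (n-1 denominator) and the 95% limits
#' `mean +/- 1.96 * sd` of a vector of per-subject differences between two
#' measurement methods.
#'
#' @param d numeric vector of differences, length >= 2.
#' @return named list: `mean`, `sd`, `low`, `high`.
#' @export
limits_of_agreement <- function(d) {
  if (!is.numeric(d) || length(d) < 2L)
    stop("limits of agreement need at least 2 differences")
  if (any(!is.finite(d))) stop("differences must be finite")
  m <- mean(d)
  s <- stats::sd(d)
  list(mean = m, sd = s, low = m - 1.96 * s, high = m + 1.96 * s)
}

#' Tiered agreement classification
#'
#' Classifies each per-infant difference (g/kg/d) between the observed
#' exponential-model velocity and the velocity predicted from the z-score
#' metric: `fair` when |d| < t1, `poor` when t1 <= |d| < t2, `disagreement`
#' when |d| >= t2. Default thresholds 2 and 4 g/kg/d.
#'
#' @param d numeric vector of differences (g/kg/d), finite.
#' @param thresholds increasing pair `c(t1, t2)`, both positive.
#' @return factor with levels "fair", "poor", "disagreement".
#' @export
classify_agreement <- function(d, thresholds = c(2, 4)) {
  if (length(thresholds) != 2L || !all(thresholds > 0) ||
      thresholds[1] >= thresholds[2])
    stop("'thresholds' must be an increasing positive pair")
  if (any(!is.finite(d))) stop("differences must be finite")
  a <- abs(d)
  f <- ifelse(a < thresholds[1], "fair",
              ifelse(a < thresholds[2], "poor", "disagreement"))
  factor(f, levels = c("fair", "poor", "disagreement"))
}

#' Fit the velocity method-comparison model
#'
#' The central analysis: given per-infant exponential-model velocity (EM,
#' g/kg/d) and z-score velocity (ZS, z units), fits the calibration
#' regression `EM ~ ZS` by ordinary least squares, so the ZS metric is
#' expressed in g/kg/d units, then assesses agreement through the per-infant
#' differences `d = EM - (intercept + slope * ZS)`: Bland-Altman 95% limits
#' of agreement, skewness/excess-kurtosis of d (normality check), and a
#' tiered fair/poor/disagreement classification at the configured
#' thresholds.
#'
#' @param results data.frame with columns `em_velocity` and `zs_change`
#'   (e.g. from [cohort_velocities()] or [simulate_velocity_pairs()]);
#'   at least 3 rows. Additional columns (`id`, `sex`, `ga_stratum`,
#'   `bwz_stratum`, ...) are carried along for subgroup summaries.
#' @param thresholds class boundaries in g/kg/d, default `c(2, 4)`.
#' @param shapiro if `TRUE` and n is within 3..5000, also run a Shapiro-Wilk
#'   test on the differences.
#' @return object of class `gv_agreement` with components `coefficients`
#'   (intercept, slope), `r_squared`, `n`, `differences`, `loa`,
#'   `classification` (factor), `class_counts`, `class_props`, `normality`,
#'   `thresholds`, `data` and the underlying `lm` fit.
#' @seealso [limits_of_agreement()], [classify_agreement()],
#'   [subgroup_differences()], [scatter_export()]
#' @export
gv_agreement <- function(results, thresholds = c(2, 4), shapiro = FALSE) {
  need <- c("em_velocity", "zs_change")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols))
    stop("results lack column(s): ", paste(missing_cols, collapse = ", "))
  results <- as.data.frame(results)
  n <- nrow(results)
  if (n < 3L) stop("calibration needs at least 3 infants")
  em <- results$em_velocity
  zs <- results$zs_change
  if (any(!is.finite(em)) || any(!is.finite(zs)))
    stop("velocities must be finite")
  if (stats::var(zs) == 0)
    stop("degenerate fit: z-score velocity has zero variance")
  fit <- stats::lm(em ~ zs)
  coefs <- stats::coef(fit)
  names(coefs) <- c("intercept", "slope")
  d <- as.numeric(em - (coefs["intercept"] + coefs["slope"] * zs))
  tss <- sum((em - mean(em))^2)
  r2 <- if (tss > 0) 1 - sum(d^2) / tss else NA_real_
  loa <- limits_of_agreement(d)
  cls <- classify_agreement(d, thresholds)
  counts <- table(cls)
  normality <- list(
    skewness = e1071::skewness(d),
    excess_kurtosis = e1071::kurtosis(d),
    shapiro_p = if (shapiro && n >= 3L && n <= 5000L)
      stats::shapiro.test(d)$p.value else NA_real_)
  structure(list(
    call = match.call(),
    coefficients = coefs,
    r_squared = r2,
    n = n,
    differences = d,
    loa = loa,
    classification = cls,
    class_counts = counts,
    class_props = as.numeric(counts) / n,
    normality = normality,
    thresholds = thresholds,
    data = results,
    fit = fit), class = "gv_agreement")
}

#' Differences from a calibration fit
#'
#' `d_i = em_i - (intercept + slope * zs_i)` for an existing fit; on the
#' calibration sample these are the OLS residuals and average exactly zero.
#'
#' @param object a `gv_agreement` fit.
#' @param em,zs optional new data (equal-length vectors); defaults to the
#'   calibration sample.
#' @return numeric vector of differences in g/kg/d.
#' @export
gv_differences <- function(object, em = NULL, zs = NULL) {
  stopifnot(inherits(object, "gv_agreement"))
  if (is.null(em) && is.null(zs)) return(object$differences)
  if (length(em) != length(zs)) stop("'em' and 'zs' must have equal length")
  cf <- object$coefficients
  em - (cf["intercept"] + cf["slope"] * zs)
}

#' @export
coef.gv_agreement <- function(object, ...) object$coefficients

#' @export
residuals.gv_agreement <- function(object, ...) object$differences

#' @export
fitted.gv_agreement <- function(object, ...)
  as.numeric(stats::fitted(object$fit))

#' Predict EM velocity from ZS velocity
#'
#' @param object a `gv_agreement` fit.
#' @param newdata numeric vector of z-score velocities, or a data.frame with
#'   a `zs_change` column; omitted means the calibration sample.
#' @param ... unused.
#' @return predicted exponential-model velocities in g/kg/d.
#' @export
predict.gv_agreement <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  zs <- if (is.data.frame(newdata)) newdata$zs_change else newdata
  cf <- object$coefficients
  as.numeric(cf["intercept"] + cf["slope"] * zs)
}

#' @export
print.gv_agreement <- function(x, ...) {
  cf <- x$coefficients
  cat("Growth-velocity method comparison (n = ", x$n, ")\n", sep = "")
  cat(sprintf("Calibration: EM = %.3f %+.3f * ZS   (R^2 = %.3f)\n",
              cf["intercept"], cf["slope"], x$r_squared))
  cat(sprintf("Differences: mean %.2f, sd %.2f g/kg/d; 95%% LoA [%.2f, %.2f]\n",
              x$loa$mean, x$loa$sd, x$loa$low, x$loa$high))
  p <- 100 * x$class_props
  cat(sprintf("Agreement (|d| < %g / < %g g/kg/d): fair %.1f%%, poor %.1f%%, disagreement %.1f%%\n",
              x$thresholds[1], x$thresholds[2], p[1], p[2], p[3]))
  invisible(x)
}

#' @export
summary.gv_agreement <- function(object, ...) {
  out <- object[c("coefficients", "r_squared", "n", "loa", "class_counts",
                  "class_props", "normality", "thresholds")]
  out$difference_quartiles <- stats::quantile(object$differences,
                                              c(0.25, 0.5, 0.75), type = 7)
  class(out) <- "summary.gv_agreement"
  out
}

#' @export
print.summary.gv_agreement <- function(x, ...) {
  cat("Growth-velocity method comparison, n =", x$n, "\n")
  cat("Calibration coefficients (g/kg/d):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("R^2 = %.4f\n", x$r_squared))
  cat(sprintf("Differences: mean %.4f, sd %.4f\n", x$loa$mean, x$loa$sd))
  cat(sprintf("95%% limits of agreement: [%.4f, %.4f] g/kg/d\n",
              x$loa$low, x$loa$high))
  cat(sprintf("Skewness %.3f, excess kurtosis %.3f",
              x$normality$skewness, x$normality$excess_kurtosis))
  if (!is.na(x$normality$shapiro_p))
    cat(sprintf(", Shapiro-Wilk p = %.3g", x$normality$shapiro_p))
  cat("\nClasses:\n")
  print(x$class_counts)
  invisible(x)
}

#' Simulate velocity pairs from a fitted comparison
#'
#' Draws new exponential-model velocities on the fit's own z-score values:
#' `EM* = intercept + slope * ZS + N(0, sd_diff)`, one data.frame per
#' replicate.
#'
#' @param object a `gv_agreement` fit.
#' @param nsim number of replicates.
#' @param seed optional integer seed (restores the RNG state on exit).
#' @param ... unused.
#' @return list of `nsim` data.frames with columns `em_velocity`, `zs_change`.
#' @export
simulate.gv_agreement <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  zs <- object$data$zs_change
  cf <- object$coefficients
  lapply(seq_len(nsim), function(i)
    data.frame(em_velocity = cf["intercept"] + cf["slope"] * zs +
                 stats::rnorm(length(zs), 0, object$loa$sd),
               zs_change = zs, row.names = NULL))
}

#' Bland-Altman style plots
#'
#' `which = 1`: observed EM velocity against the velocity predicted from the
#' z-score metric, points coloured by agreement class, with the identity line
#' and the identity shifted by the 95% limits of agreement. `which = 2`:
#' classical difference-vs-mean plot with the mean difference and limits.
#'
#' @param x a `gv_agreement` fit.
#' @param which 1, 2 or both.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gv_agreement <- function(x, which = 1, ...) {
  pred <- fitted(x)
  em <- x$data$em_velocity
  cols <- c(fair = "forestgreen", poor = "goldenrod",
            disagreement = "firebrick")[as.character(x$classification)]
  if (1 %in% which) {
    graphics::plot(pred, em, col = cols, pch = 16, cex = 0.5,
                   xlab = "EM velocity predicted from ZS (g/kg/d)",
                   ylab = "Observed EM velocity (g/kg/d)", ...)
    graphics::abline(0, 1)
    graphics::abline(x$loa$low, 1, lty = 2)
    graphics::abline(x$loa$high, 1, lty = 2)
  }
  if (2 %in% which) {
    graphics::plot((pred + em) / 2, x$differences, col = cols, pch = 16,
                   cex = 0.5, xlab = "Mean of methods (g/kg/d)",
                   ylab = "Difference (g/kg/d)", ...)
    graphics::abline(h = c(x$loa$mean, x$loa$low, x$loa$high),
                     lty = c(1, 2, 2))
  }
  invisible(x)
}

#' Subgroup summaries of the differences
#'
#' Summarises the per-infant differences by sex, gestational-age stratum or
#' birth-weight z-score stratum (the groupings inspected for determinants of
#' disagreement).
#'
#' @param object a `gv_agreement` fit whose data carry the grouping column.
#' @param by one of "sex", "ga_stratum", "bwz_stratum".
#' @return data.frame: group, n, mean, sd, q25, median, q75 of d.
#' @export
subgroup_differences <- function(object,
                                 by = c("sex", "ga_stratum", "bwz_stratum")) {
  stopifnot(inherits(object, "gv_agreement"))
  by <- match.arg(by)
  g <- object$data[[by]]
  if (is.null(g)) stop("fit data carry no '", by, "' column")
  if (anyNA(g)) stop("grouping '", by, "' has missing values")
  g <- if (is.factor(g)) droplevels(g) else factor(g)
  d <- object$differences
  res <- lapply(split(d, g), function(di) {
    q <- stats::quantile(di, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(n = length(di), mean = mean(di),
               sd = if (length(di) > 1) stats::sd(di) else NA_real_,
               q25 = q[1], median = q[2], q75 = q[3])
  })
  out <- do.call(rbind, res)
  out <- data.frame(group = names(res), out, row.names = NULL)
  stopifnot(sum(out$n) == object$n)
  out
}

#' Per-infant table for scatter plotting
#'
#' One row per infant: observed EM velocity, EM predicted from ZS, their
#' difference and the agreement class (for green/yellow/red rendering).
#'
#' @param object a `gv_agreement` fit.
#' @return data.frame with columns `id`, `em`, `predicted_em`, `diff`,
#'   `class`.
#' @export
scatter_export <- function(object) {
  stopifnot(inherits(object, "gv_agreement"))
  id <- object$data$id
  if (is.null(id)) id <- as.character(seq_len(object$n))
  data.frame(id = id, em = object$data$em_velocity,
             predicted_em = fitted(object), diff = object$differences,
             class = as.character(object$classification),
             row.names = NULL)
}
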