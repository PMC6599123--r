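#' Exponential-model growth velocity (g/kg/d)
#'
#' The exponential model assumes weight grows at a constant fraction of the
#' current weight, so the average daily rate between two weights W1 and Wn
#' taken `days` apart is `1000 * ln(Wn / W1) / days` grams per kilogram per
#' day. This is the standard two-point metric for preterm weight-gain
#' velocity over the hospital stay.
#'
#' @param w1 initial (birth) weight in grams, positive.
#' @param wn final (discharge) weight in grams, positive.
#' @param days elapsed days, at least 1.
#' @return velocity in g/kg/d; zero iff `wn == w1`.
#' @examples
#' em_velocity(1320, 2520, 57)
#' @export
em_velocity <- function(w1, wn, days) {
  stopifnot(is.numeric(w1), is.numeric(wn), is.numeric(days))
  if (any(!is.finite(w1)) || any(w1 <= 0) || any(!is.finite(wn)) || any(wn <= 0))
    stop("weights must be positive and finite")
  if (any(!is.finite(days)) || any(days < 1))
    stop("'days' must be >= 1")
  1000 * log(wn / w1) / days
}

# GA strata of Table-1 style summaries, completed weeks: [23,27), [27,29),
# [29,31), [31,33) weeks. Ages below 23 wk fall outside and map to NA.
#' Gestational-age stratum
#'
#' Buckets gestational age at birth (days) into the four strata used
#' throughout: 23-26, 27-28, 29-30 and 31-32 completed weeks.
#'
#' @param ga_days gestational age at birth in days.
#' @return factor with levels "23-26", "27-28", "29-30", "31-32".
#' @export
ga_stratum <- function(ga_days) {
  cut(ga_days, breaks = c(23, 27, 29, 31, 33) * 7, right = FALSE,
      labels = c("23-26", "27-28", "29-30", "31-32"))
}

#' Birth-weight stratum
#'
#' Buckets birth weight (g) into <1000, 1000-1500 (closed at both ends) and
#' >1500 g.
#'
#' @param bw birth weight in grams.
#' @return factor with levels "<1000", "1000-1500", ">1500".
#' @export
bw_stratum <- function(bw) {
  f <- ifelse(bw < 1000, "<1000", ifelse(bw <= 1500, "1000-1500", ">1500"))
  factor(f, levels = c("<1000", "1000-1500", ">1500"))
}

#' Birth-weight z-score stratum
#'
#' Buckets the birth-weight z-score into < -2, [-2,-1), [-1,0) and >= 0.
#'
#' @param z birth-weight z-score.
#' @return factor with levels "<-2", "[-2,-1)", "[-1,0)", ">=0".
#' @export
bwz_stratum <- function(z) {
  cut(z, breaks = c(-Inf, -2, -1, 0, Inf), right = FALSE,
      labels = c("<-2", "[-2,-1)", "[-1,0)", ">=0"))
}

#' Per-infant growth velocities by both methods
#'
#' For each infant computes the exponential-model velocity from birth and
#' discharge weights, and the weight z-scores at birth (chart at
#' postmenstrual age = gestational age) and at discharge (chart at
#' gestational age + stay). The z-score velocity is the difference
#' `z_discharge - z_birth`.
#'
#' @param cohort data.frame with columns `id`, `sex`, `ga_days`,
#'   `birth_weight`, `discharge_weight`, `stay_days` (see [read_cohort()]).
#' @param chart a [growth_chart()] covering every infant's birth and
#'   discharge postmenstrual age.
#' @param on_error "abort" (default) stops at the first infant whose age is
#'   outside the chart; "skip" drops such infants with a message listing
#'   their ids.
#' @return data.frame: the cohort columns plus `em_velocity`, `z_birth`,
#'   `z_discharge`, `zs_change`, `ga_stratum`, `bwz_stratum`.
#' @export
cohort_velocities <- function(cohort, chart, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  need <- c("id", "sex", "ga_days", "birth_weight", "discharge_weight",
            "stay_days")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0L) {
    out <- cohort
    out$em_velocity <- out$z_birth <- out$z_discharge <- out$zs_change <- numeric(0)
    out$ga_stratum <- ga_stratum(numeric(0))
    out$bwz_stratum <- bwz_stratum(numeric(0))
    return(out)
  }
  if (on_error == "skip") {
    ok <- vapply(seq_len(nrow(cohort)), function(i) {
      !inherits(tryCatch({
        chart_lookup(chart, cohort$sex[i], cohort$ga_days[i])
        chart_lookup(chart, cohort$sex[i], cohort$ga_days[i] + cohort$stay_days[i])
      }, error = identity), "error")
    }, logical(1))
    if (!all(ok))
      message(sum(!ok), " infant(s) outside chart range skipped: ",
              paste(cohort$id[!ok], collapse = ", "))
    cohort <- cohort[ok, , drop = FALSE]
    if (nrow(cohort) == 0L) stop("no infant inside chart range")
  }
  z_b <- chart_zscore(chart, cohort$sex, cohort$ga_days, cohort$birth_weight)
  z_d <- chart_zscore(chart, cohort$sex, cohort$ga_days + cohort$stay_days,
                      cohort$discharge_weight)
  out <- cohort
  out$em_velocity <- em_velocity(cohort$birth_weight, cohort$discharge_weight,
                                 cohort$stay_days)
  out$z_birth <- z_b
  out$z_discharge <- z_d
  out$zs_change <- z_d - z_b
  out$ga_stratum <- ga_stratum(cohort$ga_days)
  out$bwz_stratum <- bwz_stratum(z_b)
  rownames(out) <- NULL
  out
}

med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

count_prop <- function(f) {
  tab <- table(f)
  data.frame(level = names(tab), n = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab), row.names = NULL)
}

#' Cohort characteristics summary
#'
#' Median and interquartile range (linear-interpolation quantiles) of birth
#' and discharge weights, z-scores, exponential-model velocity and z-score
#' change, plus counts and proportions by sex, gestational-age stratum and
#' birth-weight stratum.
#'
#' @param results output of [cohort_velocities()] (or any data.frame with the
#'   same columns); must be non-empty.
#' @return object of class `cohort_summary`: a list with `n`, `continuous`
#'   (data.frame of median/q25/q75) and `categorical` (list of count tables).
#' @export
cohort_summary <- function(results) {
  if (nrow(results) == 0L) stop("empty cohort")
  vars <- c(birth_weight = "birth_weight", discharge_weight = "discharge_weight",
            z_birth = "z_birth", z_discharge = "z_discharge",
            em_velocity = "em_velocity", zs_change = "zs_change")
  vars <- vars[vars %in% names(results)]
  cont <- do.call(rbind, lapply(vars, function(v) med_iqr(results[[v]])))
  cont <- data.frame(variable = names(vars), cont, row.names = NULL)
  cat_list <- list(sex = count_prop(factor(results$sex,
                                           levels = c("male", "female"))))
  if ("ga_stratum" %in% names(results))
    cat_list$ga_stratum <- count_prop(results$ga_stratum)
  if ("birth_weight" %in% names(results))
    cat_list$bw_stratum <- count_prop(bw_stratum(results$birth_weight))
  structure(list(n = nrow(results), continuous = cont,
                 categorical = cat_list),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n = ", x$n, ")\n\nMedian [IQR]:\n", sep = "")
  cc <- x$continuous
  for (i in seq_len(nrow(cc)))
    cat(sprintf("  %-17s %8.2f [%.2f, %.2f]\n", cc$variable[i],
                cc$median[i], cc$q25[i], cc$q75[i]))
  cat("\nCounts:\n")
  for (nm in names(x$categorical)) {
    tab <- x$categorical[[nm]]
    cat("  ", nm, ": ",
        paste(sprintf("%s %d (%.1f%%)", tab$level, tab$n,
                      100 * tab$proportion), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
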