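# round every numeric leaf to 10 significant digits so that identical inputs
# give byte-identical report files across platforms' printf quirks
round_leaves <- function(x) {
  if (is.list(x)) return(lapply(x, round_leaves))
  if (is.double(x)) return(signif(x, 10))
  x
}

#' Run the full method-comparison pipeline
#'
#' Composes the whole analysis: read (or accept) a cohort and a growth
#' chart, compute per-infant velocities by both methods, summarise the
#' population, fit the calibration and agreement model, summarise the
#' differences by subgroup, and fit the determinant regression. Writes
#' `report.json` (population summary, calibration, limits of agreement,
#' classes, normality, subgroups, determinants) and `scatter.csv`
#' (`id,em,predicted_em,diff,class`) into `out_dir`.
#'
#' The report is deterministic: identical inputs and configuration yield
#' byte-identical files (numbers fixed to 10 significant digits).
#'
#' @param cohort cohort data.frame or path to a cohort CSV.
#' @param chart a [growth_chart()] or path to a chart CSV.
#' @param out_dir output directory (created if needed); `NULL` writes no
#'   files.
#' @param thresholds agreement class boundaries in g/kg/d, `0 < t1 < t2`.
#' @param terms covariates of the determinant regression; `NULL` skips it.
#' @param on_error chart-range policy for [cohort_velocities()].
#' @param shapiro passed to [gv_agreement()].
#' @return invisibly, a list: `report` (the JSON content as a list),
#'   `results`, `agreement`, `determinants`.
#' @export
run_pipeline <- function(cohort, chart, out_dir = NULL,
                         thresholds = c(2, 4),
                         terms = c("sex", "ga_stratum", "bwz_stratum"),
                         on_error = c("abort", "skip"), shapiro = FALSE) {
  if (length(thresholds) != 2L || !all(thresholds > 0) ||
      thresholds[1] >= thresholds[2])
    stop("'thresholds' must satisfy 0 < t1 < t2")
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(chart)) chart <- read_growth_chart(chart)
  results <- cohort_velocities(cohort, chart, on_error = match.arg(on_error))
  summ <- cohort_summary(results)
  agr <- gv_agreement(results, thresholds = thresholds, shapiro = shapiro)
  subgroups <- lapply(c(sex = "sex", ga_stratum = "ga_stratum",
                        bwz_stratum = "bwz_stratum"),
                      function(by) subgroup_differences(agr, by))
  det <- if (!is.null(terms)) difference_determinants(agr, terms = terms)
  report <- list(
    n = summ$n,
    population = list(continuous = summ$continuous,
                      categorical = summ$categorical),
    calibration = list(intercept = unname(agr$coefficients["intercept"]),
                       slope = unname(agr$coefficients["slope"]),
                       r_squared = agr$r_squared, n = agr$n),
    limits_of_agreement = agr$loa,
    classes = list(thresholds = thresholds,
                   counts = as.list(stats::setNames(as.integer(agr$class_counts),
                                                    names(agr$class_counts))),
                   proportions = as.list(stats::setNames(agr$class_props,
                                                         names(agr$class_counts)))),
    normality = agr$normality,
    subgroups = subgroups)
  if (!is.null(det))
    report$determinants <- list(
      coefficients = det$coefficients[c("term", "variable", "level",
                                        "estimate", "ci_low", "ci_high",
                                        "p_value")],
      variance_explained = det$variance_explained,
      r_squared = det$r_squared, n = det$n, n_dropped = det$n_dropped)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(round_leaves(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    sc <- scatter_export(agr)
    sc[sapply(sc, is.double)] <- lapply(sc[sapply(sc, is.double)], signif, 10)
    utils::write.csv(sc, file.path(out_dir, "scatter.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(report = report, results = results, agreement = agr,
                 determinants = det))
}
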