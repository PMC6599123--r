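#' Configuration for the synthetic chart and cohort generator
#'
#' Bundles every distributional knob of the generator together with the
#' seed. Defaults emulate a large very-preterm cohort: gestational-age
#' stratum shares 7.1/17.3/26.3/49.3% over 23-26/27-28/29-30/31-32 completed
#' weeks, 53.1% male, birth-weight z centred at -0.45 (sd 0.9), a z-score
#' decline during the stay of mean 0.7 (sd 0.4, truncated so no infant gains
#' z by default), and discharge at a postmenstrual age of 38 +/- 1.5 weeks.
#' The reference chart is a smooth LMS surface with weekly fractional growth
#' declining with age (see [synthetic_chart()]); `chart_m23` and
#' `chart_growth` are calibrated so that the default cohort's median birth
#' weight and median exponential-model velocity sit near 1320 g and
#' 11.4 g/kg/d. `em_zs_noise_sd` is the residual scale (g/kg/d) injected
#' between the two velocity metrics by [simulate_velocity_pairs()]; the
#' stratum effects on the method difference default to the magnitudes of the
#' determinant regression the package is designed around.
#'
#' @param seed integer RNG seed.
#' @param n cohort size.
#' @param ga_strata_probs four probabilities for the GA strata, summing to 1.
#' @param p_male probability of male sex.
#' @param birth_z_mean,birth_z_sd birth-weight z-score distribution.
#' @param z_drop_mean,z_drop_sd z-score decline during the stay (truncated
#'   at 0 from below: declines only).
#' @param discharge_pma_weeks_mean,discharge_pma_weeks_sd discharge
#'   postmenstrual age (weeks), truncated to at least one week after birth
#'   and to the chart range.
#' @param em_zs_noise_sd residual scale (g/kg/d) between EM velocity and its
#'   linear prediction from ZS velocity, used by the pair-level simulator.
#' @param chart_m23 median weight (g) at 23 weeks.
#' @param chart_growth weekly fractional growth of the median at 23 weeks.
#' @param chart_growth_decline per-week decline of the weekly log-growth
#'   rate; 0 gives the strictly geometric curve `M23 * (1+growth)^(wk-23)`.
#' @param chart_s,chart_l constant S and L of the synthetic chart.
#' @param chart_sex_gap fractional male-female gap in M (males heavier).
#' @param em_center central EM velocity (g/kg/d) of the pair simulator.
#' @param pair_slope calibration slope (g/kg/d per z-unit) of the pair
#'   simulator.
#' @param zs_mean,zs_sd z-score velocity distribution of the pair simulator.
#' @param ga_effects,female_effect,bwz_effects additive effects (g/kg/d) on
#'   the method difference by GA stratum, female sex and birth-weight-z
#'   stratum in the pair simulator.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1L,
                             n = 3954L,
                             ga_strata_probs = c(0.071, 0.173, 0.263, 0.493),
                             p_male = 0.531,
                             birth_z_mean = -0.45, birth_z_sd = 0.9,
                             z_drop_mean = 0.7, z_drop_sd = 0.4,
                             discharge_pma_weeks_mean = 38,
                             discharge_pma_weeks_sd = 1.5,
                             em_zs_noise_sd = 1.0,
                             chart_m23 = 521,
                             chart_growth = 0.1617,
                             chart_growth_decline = 0.005,
                             chart_s = 0.13, chart_l = 1,
                             chart_sex_gap = 0.04,
                             em_center = 11.4,
                             pair_slope = 2.4,
                             zs_mean = -0.7, zs_sd = 0.667,
                             ga_effects = c("23-26" = 3.53, "27-28" = 2.76,
                                            "29-30" = 1.72, "31-32" = 0),
                             female_effect = 0.22,
                             bwz_effects = c("<-2" = 5.09, "[-2,-1)" = 3.02,
                                             "[-1,0)" = 1.1, ">=0" = 0)) {
  cfg <- as.list(environment())
  if (length(cfg$ga_strata_probs) != 4L || any(cfg$ga_strata_probs < 0) ||
      abs(sum(cfg$ga_strata_probs) - 1) > 1e-6)
    stop("'ga_strata_probs' must be 4 non-negative probabilities summing to 1")
  if (cfg$n < 1L) stop("'n' must be >= 1")
  if (cfg$p_male < 0 || cfg$p_male > 1) stop("'p_male' must be in [0, 1]")
  sds <- c(cfg$birth_z_sd, cfg$z_drop_sd, cfg$discharge_pma_weeks_sd,
           cfg$em_zs_noise_sd, cfg$zs_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$chart_m23 <= 0 || cfg$chart_growth <= 0 ||
      cfg$chart_growth_decline < 0 || cfg$chart_s <= 0)
    stop("chart parameters must be positive (decline may be 0)")
  if (length(cfg$ga_effects) != 4L || length(cfg$bwz_effects) != 4L)
    stop("'ga_effects' and 'bwz_effects' need 4 values")
  cfg$seed <- as.integer(cfg$seed)
  cfg$n <- as.integer(cfg$n)
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> n =", x$n, ", seed =", x$seed,
      ", chart M23 =", x$chart_m23, "g, weekly growth =", x$chart_growth,
      "(decline", x$chart_growth_decline, "/wk)\n")
  invisible(x)
}

# run draws under the config seed, restoring the caller's RNG state
with_config_seed <- function(config, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(config$seed)
  expr
}

#' Generate a synthetic LMS growth chart
#'
#' Weekly grid from 22 to 44 weeks postmenstrual age, both sexes. The median
#' follows `log M(t) = log M23 + log(1+growth) * (t-23) - decline * (t-23)^2 / 2`
#' (weeks), i.e. a weekly log-growth rate that declines linearly with age as
#' fetal fractional growth does; `decline = 0` recovers the geometric curve
#' `M23 * (1+growth)^(t-23)`. S and L are constant; males are shifted up and
#' females down by half the configured sex gap. Deterministic given the
#' config.
#'
#' @param config a [synthetic_config()].
#' @return a [growth_chart()] named "synthetic".
#' @export
synthetic_chart <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  wk <- 22:44
  r0 <- log(1 + config$chart_growth)
  if (r0 - config$chart_growth_decline * (max(wk) - 23) <= 0)
    stop("growth parameters yield a non-increasing median curve at high ages")
  logm <- log(config$chart_m23) + r0 * (wk - 23) -
    config$chart_growth_decline * (wk - 23)^2 / 2
  entries <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    mult <- 1 + ifelse(sx == "male", 0.5, -0.5) * config$chart_sex_gap
    data.frame(sex = sx, pma_days = wk * 7, L = config$chart_l,
               M = exp(logm) * mult, S = config$chart_s)
  }))
  growth_chart(entries, name = "synthetic")
}

draw_ga_days <- function(n, probs) {
  lo <- c(23, 27, 29, 31) * 7
  width <- c(4, 2, 2, 2) * 7
  stratum <- sample.int(4L, n, replace = TRUE, prob = probs)
  lo[stratum] + floor(stats::runif(n) * width[stratum])
}

#' Generate a synthetic preterm cohort
#'
#' Per infant: GA stratum from the configured shares with GA uniform (by
#' day) within the stratum; sex Bernoulli; birth-weight z Gaussian; birth
#' weight by inverting the chart at GA; discharge postmenstrual age Gaussian
#' truncated to at least 7 days after birth and to the chart range;
#' discharge z = birth z minus a non-negative Gaussian decline; discharge
#' weight by inverting the chart at discharge age. Generating weights by
#' chart inversion guarantees that z-scoring the cohort against the same
#' chart reproduces the sampled z values exactly, the property real chart
#' data cannot give a test suite. Reproducible under the config seed.
#'
#' @param config a [synthetic_config()].
#' @param chart the reference chart; defaults to [synthetic_chart()] of the
#'   same config.
#' @return data.frame with columns `id`, `sex`, `ga_days`, `birth_weight`,
#'   `discharge_weight`, `stay_days`; the config is attached as attribute
#'   `config`.
#' @export
synthetic_cohort <- function(config, chart = synthetic_chart(config)) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n
  with_config_seed(config, {
    ga <- draw_ga_days(n, config$ga_strata_probs)
    sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
    z_b <- stats::rnorm(n, config$birth_z_mean, config$birth_z_sd)
    dmax <- max(chart$entries$pma_days)
    dpma <- round(stats::rnorm(n, config$discharge_pma_weeks_mean * 7,
                               config$discharge_pma_weeks_sd * 7))
    bad <- which(dpma < ga + 7 | dpma > dmax)
    tries <- 0L
    while (length(bad) && tries < 1000L) {
      dpma[bad] <- round(stats::rnorm(length(bad),
                                      config$discharge_pma_weeks_mean * 7,
                                      config$discharge_pma_weeks_sd * 7))
      bad <- bad[dpma[bad] < ga[bad] + 7 | dpma[bad] > dmax]
      tries <- tries + 1L
    }
    if (length(bad))
      stop("infeasible discharge-age truncation: discharge PMA cannot exceed ",
           "birth PMA + 7 days within the chart range")
    drop <- pmax(0, stats::rnorm(n, config$z_drop_mean, config$z_drop_sd))
    z_d <- z_b - drop
    pb <- chart_lookup(chart, sex, ga)
    pd <- chart_lookup(chart, sex, dpma)
    cohort <- data.frame(
      id = sprintf("S%05d", seq_len(n)),
      sex = sex,
      ga_days = as.integer(ga),
      birth_weight = lms_inverse(z_b, pb$L, pb$M, pb$S),
      discharge_weight = lms_inverse(z_d, pd$L, pd$M, pd$S),
      stay_days = as.integer(dpma - ga))
    attr(cohort, "config") <- config
    cohort
  })
}

#' Simulate velocity metric pairs with a configured residual scale
#'
#' Draws per-infant (EM, ZS) velocity pairs directly at the metric level:
#' `EM = intercept + pair_slope * ZS + effects + N(0, em_zs_noise_sd)`,
#' where the effects are the configured additive shifts by GA stratum,
#' female sex and birth-weight-z stratum, and the intercept is set so the
#' population centre of EM is `em_center`. This is the generator used to
#' study the agreement stage itself: because both velocity metrics computed
#' from a single weight table against a single chart are structurally locked
#' (any weight perturbation moves them along the infant's own calibration
#' line), an independent residual scale between the metrics can only be
#' realised at the pair level. With all effects zero, the differences from
#' [gv_agreement()] have standard deviation `em_zs_noise_sd` up to sampling
#' error.
#'
#' @param config a [synthetic_config()].
#' @return data.frame: `id`, `sex`, `ga_days`, `ga_stratum`, `z_birth`,
#'   `bwz_stratum`, `zs_change`, `em_velocity`.
#' @export
simulate_velocity_pairs <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n
  with_config_seed(config, {
    ga <- draw_ga_days(n, config$ga_strata_probs)
    gs <- ga_stratum(ga)
    sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
    z_b <- stats::rnorm(n, config$birth_z_mean, config$birth_z_sd)
    bs <- bwz_stratum(z_b)
    zs <- stats::rnorm(n, config$zs_mean, config$zs_sd)
    # expected effect under the config, so em_center is the population centre
    bwz_probs <- diff(stats::pnorm(c(-Inf, -2, -1, 0, Inf),
                                   config$birth_z_mean, config$birth_z_sd))
    mean_eff <- sum(config$ga_strata_probs * config$ga_effects) +
      (1 - config$p_male) * config$female_effect +
      sum(bwz_probs * config$bwz_effects)
    intercept <- config$em_center - config$pair_slope * config$zs_mean - mean_eff
    eff <- config$ga_effects[as.integer(gs)] +
      ifelse(sex == "female", config$female_effect, 0) +
      config$bwz_effects[as.integer(bs)]
    em <- intercept + config$pair_slope * zs + eff +
      stats::rnorm(n, 0, config$em_zs_noise_sd)
    data.frame(id = sprintf("P%05d", seq_len(n)), sex = sex,
               ga_days = as.integer(ga), ga_stratum = gs, z_birth = z_b,
               bwz_stratum = bs, zs_change = zs, em_velocity = em,
               row.names = NULL)
  })
}

#' Write a synthetic study to disk
#'
#' Writes `chart.csv` (the [read_growth_chart()] dialect), `cohort.csv` (the
#' [read_cohort()] dialect) and `provenance.json` echoing the full config
#' including the seed, into `dir`.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_synthetic_study <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  chart <- synthetic_chart(config)
  cohort <- synthetic_cohort(config, chart)
  paths <- c(chart = file.path(dir, "chart.csv"),
             cohort = file.path(dir, "cohort.csv"),
             provenance = file.path(dir, "provenance.json"))
  write_growth_chart(chart, paths["chart"])
  write_cohort(cohort, paths["cohort"])
  jsonlite::write_json(unclass(config), paths["provenance"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
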