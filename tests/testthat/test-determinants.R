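make_det_data <- function(n, seed = 1, beta_ga = c(3.5, 2.8, 1.7, 0)) {
  set.seed(seed)
  ga <- sample(c("23-26", "27-28", "29-30", "31-32"), n, TRUE)
  data.frame(
    d = beta_ga[match(ga, c("23-26", "27-28", "29-30", "31-32"))] +
      rnorm(n, 0, 1),
    sex = sample(c("male", "female"), n, TRUE),
    ga_stratum = factor(ga),
    bwz_stratum = bwz_stratum(rnorm(n, -0.5, 1)))
}

test_that("design matrix applies treatment coding with the expected references", {
  df <- make_det_data(60, seed = 2)
  dm <- design_matrix(df, c("sex", "ga_stratum", "bwz_stratum"))
  expect_equal(colnames(dm$X)[1], "(Intercept)")
  expect_false(any(c("sexmale", "ga_stratum31-32", "bwz_stratum>=0") %in%
                     colnames(dm$X)))
  expect_true("sexfemale" %in% colnames(dm$X))
  expect_equal(sum(dm$map$term == "ga_stratum"), 3)  # 4 levels -> 3 dummies
  expect_setequal(dm$map$level[dm$map$term == "ga_stratum"],
                  c("23-26", "27-28", "29-30"))
  # an all-reference cohort spans no contrast: intercept-only design
  allref <- data.frame(sex = rep("male", 5),
                       ga_stratum = factor(rep("31-32", 5),
                                           levels = levels(df$ga_stratum)))
  dm0 <- design_matrix(allref, c("sex", "ga_stratum"))
  expect_equal(colnames(dm0$X), "(Intercept)")
  expect_error(design_matrix(df, c("sex", "sex")), "duplicated")
  expect_error(design_matrix(df, "apgar5"), "absent")
  dfm <- df; dfm$sex[1:7] <- NA
  dmm <- design_matrix(dfm, "sex")
  expect_equal(dmm$n_dropped, 7)
})

test_that("OLS estimates match a normal-equations solve", {
  set.seed(14)
  for (i in 1:5) {
    n <- 40
    X <- cbind(1, matrix(rnorm(n * 3), n, 3))
    colnames(X) <- c("(Intercept)", "x1", "x2", "x3")
    y <- X %*% c(2, -1, 0.5, 0) + rnorm(n)
    fit <- fit_ols(X, y)
    beta <- solve(t(X) %*% X, t(X) %*% y)  # normal equations, by hand
    expect_equal(fit$estimate, as.numeric(beta), tolerance = 1e-8)
    rss <- sum((y - X %*% beta)^2)
    se <- sqrt(rss / (n - 4) * diag(solve(t(X) %*% X)))
    expect_equal(fit$se, as.numeric(se), tolerance = 1e-8)
    expect_equal(fit$ci_high - fit$estimate, qt(0.975, n - 4) * fit$se,
                 tolerance = 1e-10)
    expect_true(all(fit$ci_low <= fit$estimate & fit$estimate <= fit$ci_high))
  }
})

test_that("exact linear responses collapse the intervals; collinearity is named", {
  n <- 30
  X <- cbind(`(Intercept)` = 1, x = seq_len(n))
  fit <- fit_ols(X, 3 + 2 * seq_len(n))
  expect_equal(fit$estimate, c(3, 2), tolerance = 1e-10)
  expect_lt(attr(fit, "sigma"), 1e-10)
  expect_equal(fit$ci_low, fit$estimate, tolerance = 1e-8)
  Xs <- cbind(X, dup = 2 * seq_len(n))
  expect_error(fit_ols(Xs, rnorm(n)), "collinear.*dup")
})

test_that("simulated coefficients are recovered within three standard errors", {
  set.seed(77)
  n <- 5000
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  colnames(X) <- c("(Intercept)", "x", "g")
  beta <- c(1.5, -0.8, 0.3)
  y <- as.numeric(X %*% beta) + rnorm(n, 0, 2)
  fit <- fit_ols(X, y)
  expect_true(all(abs(fit$estimate - beta) < 3 * fit$se))
})

test_that("variance explained is reported both univariately and added-last", {
  df <- make_det_data(4000, seed = 5)
  v <- variance_explained(df, "d", c("sex", "ga_stratum", "bwz_stratum"),
                          "ga_stratum")
  expect_gt(v$univariate, 0.3)
  expect_lte(v$incremental, v$full_r_squared)
  # a variable independent of the outcome explains ~nothing
  v0 <- variance_explained(df, "d", c("sex", "ga_stratum", "bwz_stratum"),
                           "bwz_stratum")
  expect_lt(v0$univariate, 0.01)
  expect_lt(v0$incremental, 0.01)
  # a copy of the outcome explains everything
  df$dd <- df$d
  v1 <- variance_explained(df, "d", c("dd", "sex"), "dd")
  expect_equal(v1$univariate, 1, tolerance = 1e-10)
  # full-model R^2 non-decreasing in added terms
  r1 <- variance_explained(df, "d", "sex", "sex")$full_r_squared
  r2 <- variance_explained(df, "d", c("sex", "ga_stratum"),
                           "sex")$full_r_squared
  expect_gte(r2, r1)
  expect_error(variance_explained(df, "d", "sex", "ga_stratum"),
               "not among")
})

test_that("predictions are invariant to the reference-level choice", {
  df <- make_det_data(300, seed = 9)
  fit_a <- difference_determinants(df, terms = c("sex", "ga_stratum"))
  fit_b <- difference_determinants(df, terms = c("sex", "ga_stratum"),
                                   refs = c(sex = "female",
                                            ga_stratum = "23-26"))
  pred <- function(fit, df) {
    dm <- design_matrix(df, fit$terms, fit$refs)
    as.numeric(dm$X %*% fit$coefficients$estimate)
  }
  expect_equal(pred(fit_a, df), pred(fit_b, df), tolerance = 1e-8)
})

test_that("determinant regression recovers the generator's configured effects", {
  cfg <- synthetic_config(seed = 13, n = 4000)
  a <- gv_agreement(simulate_velocity_pairs(cfg))
  det <- difference_determinants(a)
  cc <- det$coefficients
  ga <- cc[cc$variable == "ga_stratum", ]
  expected <- cfg$ga_effects[ga$level]
  expect_true(all(abs(ga$estimate - expected) < 0.3))
  fem <- cc[cc$variable == "sex" & cc$level == "female", ]
  expect_lt(abs(fem$estimate - cfg$female_effect), 0.15)
  expect_equal(det$n, 4000)
  expect_output(print(det), "Variance explained")
})
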