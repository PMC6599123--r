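test_that("calibration recovers an exact line and the textbook 3-point fit", {
  zs <- c(0, 1, 2, 3)
  perfect <- data.frame(em_velocity = 2 * zs + 1, zs_change = zs)
  a <- gv_agreement(perfect)
  expect_equal(unname(coef(a)), c(1, 2), tolerance = 1e-12)
  expect_equal(residuals(a), rep(0, 4), tolerance = 1e-12)
  expect_equal(unlist(a$loa), c(mean = 0, sd = 0, low = 0, high = 0),
               tolerance = 1e-12)
  expect_equal(as.character(a$classification), rep("fair", 4))

  three <- data.frame(em_velocity = c(1, 2, 4), zs_change = c(0, 1, 2))
  b <- gv_agreement(three)
  expect_equal(unname(coef(b)), c(5 / 6, 3 / 2), tolerance = 1e-12)
  expect_equal(residuals(b), c(1 / 6, -1 / 3, 1 / 6), tolerance = 1e-12)

  expect_error(gv_agreement(data.frame(em_velocity = 1:3,
                                       zs_change = rep(1, 3))),
               "degenerate")
  expect_error(gv_agreement(three[1:2, ]), "at least 3")
})

test_that("OLS residual identities hold on random samples", {
  set.seed(31)
  for (i in 1:5) {
    n <- 200
    df <- data.frame(zs_change = rnorm(n, -0.7, 0.5))
    df$em_velocity <- 11 + 2.4 * df$zs_change + rnorm(n, 0, 2)
    a <- gv_agreement(df)
    d <- residuals(a)
    scale <- mean(abs(df$em_velocity))
    expect_lt(abs(sum(d)), 1e-8 * n * scale)
    expect_lt(abs(sum(d * df$zs_change)), 1e-8 * n * scale)
    expect_equal(d, df$em_velocity - predict(a), tolerance = 1e-12)
  }
})

test_that("limits of agreement use the sample sd and 1.96 multiplier", {
  expect_equal(unlist(limits_of_agreement(rep(0, 4))),
               c(mean = 0, sd = 0, low = 0, high = 0))
  l <- limits_of_agreement(c(-1, 1))
  expect_equal(l$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(l$high, 2.77185858225127, tolerance = 1e-10)
  expect_equal(l$low, -l$high, tolerance = 1e-12)
  expect_error(limits_of_agreement(0.5), "at least 2")
  # shift equivariance: adding c moves mean and limits, leaves sd alone
  set.seed(8)
  d <- rnorm(100, 0, 2)
  l0 <- limits_of_agreement(d)
  l3 <- limits_of_agreement(d + 3)
  expect_equal(l3$mean, l0$mean + 3)
  expect_equal(l3$low, l0$low + 3)
  expect_equal(l3$high, l0$high + 3)
  expect_equal(l3$sd, l0$sd)
  expect_equal(l0$high - l0$mean, 1.96 * l0$sd, tolerance = 1e-12)
})

test_that("classification uses half-open bands on |d|", {
  expect_equal(as.character(classify_agreement(c(1.5, -3, 4.5))),
               c("fair", "poor", "disagreement"))
  expect_equal(as.character(classify_agreement(c(-2, 2, 4, -4))),
               c("poor", "poor", "disagreement", "disagreement"))
  expect_error(classify_agreement(c(1, NA)), "finite")
  expect_error(classify_agreement(1, thresholds = c(4, 2)), "increasing")
  set.seed(12)
  d <- rnorm(500, 0, 2.5)
  cls <- classify_agreement(d)
  brute <- vapply(d, function(x)
    if (abs(x) < 2) "fair" else if (abs(x) < 4) "poor" else "disagreement",
    character(1))
  expect_equal(as.character(cls), brute)
  expect_equal(sum(table(cls)), 500)
})

test_that("the fitted comparison composes calibration, limits and classes", {
  cfg <- synthetic_config(seed = 5, n = 1500)
  pairs <- simulate_velocity_pairs(cfg)
  a <- gv_agreement(pairs)
  expect_s3_class(a, "gv_agreement")
  expect_equal(sum(a$class_counts), a$n)
  expect_equal(sum(a$class_props), 1)
  expect_equal(as.numeric(a$class_counts),
               as.numeric(table(classify_agreement(residuals(a)))))
  expect_equal(a$loa$high - a$loa$mean, 1.96 * a$loa$sd)
  s <- summary(a)
  expect_s3_class(s, "summary.gv_agreement")
  expect_true(is.finite(s$normality$skewness))
  expect_true(is.finite(s$normality$excess_kurtosis))
  sh <- gv_agreement(pairs, shapiro = TRUE)
  expect_true(sh$normality$shapiro_p >= 0 && sh$normality$shapiro_p <= 1)
  expect_output(print(a), "Calibration")
})

test_that("subgroup summaries partition the cohort", {
  cfg <- synthetic_config(seed = 6, n = 800)
  a <- gv_agreement(simulate_velocity_pairs(cfg))
  for (by in c("sex", "ga_stratum", "bwz_stratum")) {
    sg <- subgroup_differences(a, by)
    expect_equal(sum(sg$n), a$n)
  }
  expect_error(subgroup_differences(a, "apgar"), "'arg' should be one of")
  one <- data.frame(em_velocity = rnorm(10, 11), zs_change = rnorm(10),
                    sex = "male")
  a1 <- gv_agreement(one)
  sg1 <- subgroup_differences(a1, "sex")
  expect_equal(sg1$mean, mean(residuals(a1)))
  expect_equal(sg1$n, 10L)
  # two groups with identical difference profiles have equal means
  two <- rbind(transform(one, sex = "male"), transform(one, sex = "female"))
  a2 <- gv_agreement(two)
  sg2 <- subgroup_differences(a2, "sex")
  expect_equal(sg2$mean[1], sg2$mean[2], tolerance = 1e-10)
})

test_that("scatter export mirrors the fit row by row", {
  cfg <- synthetic_config(seed = 9, n = 300)
  a <- gv_agreement(simulate_velocity_pairs(cfg))
  sc <- scatter_export(a)
  expect_equal(nrow(sc), a$n)
  expect_equal(sc$class, as.character(classify_agreement(sc$diff)))
  expect_equal(sc$em - sc$predicted_em, sc$diff, tolerance = 1e-12)
  expect_equal(sc$id, a$data$id)
})

test_that("prediction and simulation use the fitted calibration", {
  cfg <- synthetic_config(seed = 10, n = 2000)
  a <- gv_agreement(simulate_velocity_pairs(cfg))
  cf <- coef(a)
  expect_equal(predict(a, c(-1, 0, 1)),
               cf[["intercept"]] + cf[["slope"]] * c(-1, 0, 1))
  sim1 <- simulate(a, nsim = 2, seed = 42)
  sim2 <- simulate(a, nsim = 2, seed = 42)
  expect_identical(sim1, sim2)
  resid_sd <- sd(sim1[[1]]$em_velocity -
                   predict(a, sim1[[1]]$zs_change))
  expect_lt(abs(resid_sd / a$loa$sd - 1), 0.1)
})
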