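# toy chart: weekly grid 23-42 wk, known analytic LMS surface
toy_chart <- function(l = 1, s = 0.1, m23 = 600, growth = 0.1) {
  wk <- 23:42
  entries <- do.call(rbind, lapply(c("male", "female"), function(sx)
    data.frame(sex = sx, pma_days = wk * 7, L = l,
               M = m23 * (1 + growth)^(wk - 23) * ifelse(sx == "male", 1.02, 0.98),
               S = s)))
  growth_chart(entries, name = "toy")
}

# cohort lying exactly on the median curve of `chart`
median_curve_cohort <- function(chart, ga_wk = c(25, 28, 31), stay = 42) {
  ga <- ga_wk * 7
  sex <- rep_len(c("male", "female"), length(ga))
  b <- chart_lookup(chart, sex, ga)
  d <- chart_lookup(chart, sex, ga + stay)
  data.frame(id = paste0("m", seq_along(ga)), sex = sex, ga_days = ga,
             birth_weight = b$M, discharge_weight = d$M, stay_days = stay)
}

random_lms <- function(n) {
  data.frame(L = sample(c(-1.5, -0.5, 0, 0.7, 1, 2), n, replace = TRUE),
             M = runif(n, 400, 4000), S = runif(n, 0.05, 0.2))
}
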