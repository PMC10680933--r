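test_that("Kaplan-Meier matches hand-computed product limits", {
  # all events: empirical survival function
  km <- km_estimate(c(5, 10, 15), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring at 10: risk set at 15 is a single patient
  km2 <- km_estimate(c(5, 10, 15), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 5], 2 / 3)
  expect_equal(km2$surv[km2$time == 15], 0)
  expect_equal(km_survival_at(km2, 12), 2 / 3)
  expect_equal(km_survival_at(km2, 2), 1)
  # all censored
  km3 <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), class = "tsrq_data_error")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(5)
  t <- round(rexp(40, 0.05), 1)
  km <- km_estimate(t, rep(1, 40))
  for (i in seq_along(km$time))
    expect_equal(km$surv[i], mean(t > km$time[i]))
})

test_that("log-rank matches the hand-computed hypergeometric oracle", {
  lr <- logrank_test(list(list(times = c(1, 2, 3), events = c(1, 1, 1)),
                          list(times = c(4, 5, 6), events = c(1, 1, 1))))
  expect_equal(lr$chi2, hand_logrank_chi2(c(1, 2, 3), c(1, 1, 1),
                                          c(4, 5, 6), c(1, 1, 1)))
  expect_equal(lr$chi2, 3.4225 / 0.6775)  # worked by hand: O=3, E=1.15, V=0.6775
  expect_equal(lr$df, 1L)
  # with censoring and ties, still equal to the naive oracle
  set.seed(31)
  t1 <- round(rexp(30, 0.1), 1); e1 <- rbinom(30, 1, 0.8)
  t2 <- round(rexp(30, 0.2), 1); e2 <- rbinom(30, 1, 0.8)
  lr2 <- logrank_test(list(list(times = t1, events = e1),
                           list(times = t2, events = e2)))
  expect_equal(lr2$chi2, hand_logrank_chi2(t1, e1, t2, e2), tolerance = 1e-8)
})

test_that("log-rank: identical groups give chi2 0; k groups give df k-1", {
  g <- list(times = c(2, 4, 6, 8), events = c(1, 1, 0, 1))
  lr <- logrank_test(list(g, g))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  lr3 <- logrank_test(list(g, g, g))
  expect_equal(lr3$df, 2L)
  expect_equal(lr3$chi2, 0, tolerance = 1e-12)
  expect_error(logrank_test(list(g)), class = "tsrq_parameter_error")
  expect_error(logrank_test(list(list(times = 1:3, events = rep(0, 3)),
                                 list(times = 1:3, events = rep(0, 3)))),
               class = "tsrq_parameter_error")
})

test_that("Cox fit recovers null and non-null hazards in simulation", {
  # null covariate, n = 2000: |log HR| small
  set.seed(71)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  df <- data.frame(os_months = rexp(n, 0.02), os_event = 1L, x = x)
  fit <- cox_fit(df, "OS", "x")
  expect_lt(abs(log(fit$table$hr)), 0.1)
  expect_equal(fit$ties, "efron")
  # true HR 1.6 with 20% uniform censoring
  set.seed(72)
  rich <- rbinom(n, 1, 0.4)
  death <- rexp(n, 0.02 * 1.6^rich)
  cens <- runif(n, 0, 200)
  df2 <- data.frame(os_months = pmin(death, cens),
                    os_event = as.integer(death <= cens), rich = rich)
  fit2 <- cox_fit(df2, "OS", "rich")
  expect_gt(fit2$table$hr, 1.45)
  expect_lt(fit2$table$hr, 1.77)
  expect_true(fit2$table$ci_low <= fit2$table$hr &
                fit2$table$hr <= fit2$table$ci_high)
  # no events -> FitError; constant covariate -> FitError
  df3 <- data.frame(os_months = rexp(10, 0.1), os_event = 0L,
                    x = rbinom(10, 1, 0.5))
  expect_error(cox_fit(df3, "OS", "x"), class = "tsrq_fit_error")
  df3$os_event <- 1L; df3$x <- 1
  expect_error(cox_fit(df3, "OS", "x"), class = "tsrq_fit_error")
})

test_that("screening and backward selection force the exposure", {
  set.seed(81)
  n <- 400
  rich <- rbinom(n, 1, 0.4)
  conf <- rbinom(n, 1, 0.3)          # strong confounder, HR 2.5
  noise1 <- rbinom(n, 1, 0.5)        # null candidates
  noise2 <- runif(n)
  death <- rexp(n, 0.02 * 2.5^conf)  # exposure truly null
  df <- data.frame(os_months = death, os_event = 1L, rich = rich,
                   conf = conf, noise1 = noise1, noise2 = noise2)
  fit <- screen_and_select(df, "OS", c("conf", "noise1", "noise2"),
                           exposure = "rich")
  expect_true("rich" %in% fit$covariates)       # forced despite null effect
  expect_true("conf" %in% fit$covariates)       # strong confounder retained
  expect_s3_class(fit, "cox_result")
  expect_true(all(c("step", "action", "covariate", "p") %in%
                    names(fit$selection_trace)))
  # screened-out or dropped candidates are visible in the trace
  expect_true(all(c("conf", "noise1", "noise2") %in%
                    fit$selection_trace$covariate))
})

test_that("null candidates are mostly eliminated while the exposure persists", {
  keeps_noise <- 0L; keeps_exposure <- 0L
  reps <- 40
  for (s in seq_len(reps)) {
    set.seed(9000 + s)
    n <- 150
    df <- data.frame(os_months = rexp(n, 0.03), os_event = 1L,
                     rich = rbinom(n, 1, 0.4), n1 = rbinom(n, 1, 0.5),
                     n2 = runif(n))
    fit <- screen_and_select(df, "OS", c("n1", "n2"), exposure = "rich")
    if ("rich" %in% fit$covariates) keeps_exposure <- keeps_exposure + 1L
    if (any(c("n1", "n2") %in% fit$covariates)) keeps_noise <- keeps_noise + 1L
  }
  expect_equal(keeps_exposure, reps)            # forcing rule is absolute
  expect_lte(keeps_noise, 0.2 * reps)           # ~10% per null candidate
})

test_that("association test dispatches on expected counts and matches printed tables", {
  # all expected counts >= 5: chi-square without continuity correction
  res <- association_test(matrix(c(70, 23, 46, 2), 2))
  expect_equal(res$test_name, "chi_square")
  expect_equal(round(res$p, 3), 0.002)
  expect_true(all(res$expected >= 5))
  # no association
  expect_equal(association_test(matrix(5, 2, 2))$p, 1)
  # expected counts (1.5, 8.5, 1.5, 8.5): 50% < 5 -> Fisher
  res2 <- association_test(matrix(c(1, 2, 9, 8), 2))
  expect_equal(res2$test_name, "fisher_exact")
  expect_true(is.na(res2$statistic))
  # dispatch is a pure function of the expected-count matrix
  res3 <- association_test(10 * matrix(c(1, 2, 9, 8), 2))
  expect_equal(res3$test_name, "chi_square")
  expect_error(association_test(matrix(c(0, 0, 3, 4), 2)),
               class = "tsrq_data_error")
  expect_error(association_test(matrix(c(1.5, 2, 3, 4), 2)),
               class = "tsrq_data_error")
})

test_that("TIL count binning and per-patient maxima", {
  expect_equal(til_bin(c(0, 1, 5, 6, 19, 20, 49, 50, 100, 101, 500)),
               c(0, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5))
  expect_equal(max(til_bin(c(3, 80, 12))), 4)  # highest count per tumor
  expect_error(til_bin(-1), class = "tsrq_data_error")
})

test_that("TIL categorization follows the quartile threshold with tied mass up", {
  bins <- c(0, 0, 1, 1, 2, 2, 3, 3)
  cats <- categorize_til(bins, "quartile_binary")
  expect_equal(unname(attr(cats, "thresholds")), 3)  # ceil(2.25)
  expect_equal(cats[bins == 3], rep("HIGH", 2))
  expect_equal(cats[bins < 3], rep("LOW", 6))
  # tied mass at the top goes entirely to HIGH
  bins2 <- c(5, 5, 5, 0, 0, 0, 0, 0)
  cats2 <- categorize_til(bins2, "quartile_binary")
  expect_equal(sum(cats2 == "HIGH"), 3L)
  # degenerate all-equal input
  cats3 <- categorize_til(rep(2, 6), "quartile_binary")
  expect_true(all(cats3 == "LOW"))
  expect_true(attr(cats3, "degenerate"))
  # three-way scheme keeps the same threshold rule at both ends
  cats4 <- categorize_til(c(0, 0, 1, 2, 3, 4, 5, 5), "tertile_3way")
  expect_setequal(unique(cats4), c("LOW", "MEDIUM", "HIGH"))
  expect_error(categorize_til(numeric(0)), class = "tsrq_data_error")
  expect_error(categorize_til(c(1, 2, 7, 3)), class = "tsrq_parameter_error")
})

test_that("joint risk groups implement the three-tier mapping", {
  expect_equal(joint_risk_group("STROMA_POOR", "HIGH"), "LOW")
  expect_equal(joint_risk_group("STROMA_RICH", "LOW"), "HIGH")
  expect_equal(joint_risk_group("STROMA_POOR", "LOW"), "MEDIUM")
  expect_equal(joint_risk_group("STROMA_RICH", "HIGH"), "MEDIUM")
  expect_equal(joint_risk_group(c("STROMA_RICH", "STROMA_POOR"),
                                c("LOW", "HIGH")), c("HIGH", "LOW"))
  expect_error(joint_risk_group("STROMA_RICH", NA), class = "tsrq_data_error")
  expect_error(joint_risk_group("rich", "LOW"), class = "tsrq_parameter_error")
})

test_that("cohort CSV round trip and schema validation", {
  co <- generate_cohort(cohort_spec(n_patients = 40, seed = 12))
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort(co$records, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 40)
  expect_equal(back$os_months, co$records$os_months, tolerance = 1e-12)
  bad <- co$records
  bad$os_months[3] <- -1
  expect_error(tsrquant:::validate_cohort(bad), "rows 3", class = "tsrq_data_error")
  bad2 <- co$records
  bad2$pfs_months[5] <- bad2$os_months[5] + 10
  expect_error(tsrquant:::validate_cohort(bad2), class = "tsrq_data_error")
})
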