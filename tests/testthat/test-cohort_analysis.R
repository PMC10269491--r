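# Viral-load floor, normality gate, two-group tests, polynomial and
# linear fits, relation scan.

test_that("the viral-load floor maps the undetectable range to 10", {
  expect_identical(pvl_floor(0), 10)
  expect_identical(pvl_floor(19), 10)
  expect_identical(pvl_floor(20), 20)
  expect_identical(pvl_floor(3940000), 3940000)
  expect_identical(pvl_floor(c(0, 5, 19.99, 20, 1e6, NA)),
                   c(10, 10, 10, 20, 1e6, NA))
  # idempotent
  x <- c(0, 3, 10, 19, 20, 250)
  expect_identical(pvl_floor(pvl_floor(x)), pvl_floor(x))
  expect_error(pvl_floor(-1), "negative")
})

test_that("the Lilliefors statistic matches an independent implementation", {
  # D frozen from statsmodels.stats.diagnostic.lilliefors on the same draws
  set.seed(5)
  x1 <- rnorm(200)
  x2 <- rexp(80)
  expect_equal(unname(lilliefors_test(x1)$statistic), 0.05253579200591896,
               tolerance = 1e-12)
  expect_equal(unname(lilliefors_test(x2)$statistic), 0.22013686144946376,
               tolerance = 1e-12)
  expect_gt(lilliefors_test(x1)$p.value, 0.05)   # statsmodels: p = 0.209
  expect_lt(lilliefors_test(x2)$p.value, 0.001)  # statsmodels: p = 2.5e-10
})

test_that("the normality gate separates normal from skewed samples", {
  set.seed(11)
  expect_identical(as.character(normality_gate(rnorm(10000))), "normal")
  expect_identical(as.character(normality_gate(rexp(10000))), "non_normal")
  expect_error(normality_gate(c(1, 2, 3)), "at least 4")
  expect_warning(g <- normality_gate(rep(1, 10)), "constant")
  expect_identical(as.character(g), "non_normal")
})

test_that("the gate's type-I rate is near its alpha level", {
  set.seed(21)
  calls <- replicate(400, as.character(normality_gate(rnorm(100))))
  rate <- mean(calls == "non_normal")
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("identical samples compare as a zero statistic with p = 1", {
  set.seed(13)
  x <- rnorm(50)
  cmp <- compare_groups(x, x)
  expect_equal(cmp$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp$p.value, 1, tolerance = 1e-12)
  expect_error(compare_groups(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("the pooled t statistic matches its closed form on exact-moment samples", {
  a <- exact_moment_sample(50, 0.83, 0.36, seed = 101)
  b <- exact_moment_sample(50, 0.69, 0.24, seed = 102)
  cmp <- compare_groups(a, b, labels = c("younger", "older"),
                        variable = "rtl")
  expect_identical(cmp$test, "t_test")
  pooled <- sqrt((49 * 0.36^2 + 49 * 0.24^2) / 98)
  t_closed <- (0.83 - 0.69) / (pooled * sqrt(2 / 50))
  expect_equal(cmp$statistic, t_closed, tolerance = 1e-9)
  expect_equal(cmp$statistic, 2.288, tolerance = 5e-4)
  expect_identical(cmp$df, 98)
  expect_identical(cmp$summary_type, "mean_sd")
  expect_equal(cmp$location, c(0.83, 0.69), tolerance = 1e-12)
})

test_that("a ten-pooled-SD shift is detected at vanishing p", {
  set.seed(17)
  a <- rnorm(40)
  cmp <- compare_groups(a, a + 10)
  expect_lt(cmp$p.value, 1e-6)
})

test_that("Mann-Whitney is used for skewed data and is rank-invariant", {
  set.seed(19)
  a <- rexp(120); b <- rexp(120) * 1.8
  cmp <- compare_groups(a, b)
  expect_identical(cmp$test, "mann_whitney")
  expect_identical(cmp$summary_type, "median_iqr")
  # a strictly increasing transform of the pooled data preserves U and p
  # (squaring keeps both groups skewed, so the gate still picks U)
  cmp2 <- compare_groups(a^2, b^2)
  expect_identical(cmp2$test, "mann_whitney")
  expect_equal(cmp2$statistic, cmp$statistic, tolerance = 1e-12)
  expect_equal(cmp2$p.value, cmp$p.value, tolerance = 1e-12)
})

test_that("t-test rejection rate matches closed-form power at the study effect size", {
  # HIV-negative younger vs older telomere comparison scale: means
  # 0.83/0.69, SDs 0.36/0.24, n = 50 per group (Cohen d ~ 0.46)
  pooled <- sqrt((0.36^2 + 0.24^2) / 2)
  ncp <- (0.83 - 0.69) / (pooled * sqrt(2 / 50))
  tcrit <- qt(0.975, 98)
  power_closed <- 1 - pt(tcrit, 98, ncp) + pt(-tcrit, 98, ncp)
  set.seed(23)
  rej <- replicate(2000, {
    a <- rnorm(50, 0.83, 0.36); b <- rnorm(50, 0.69, 0.24)
    stats::t.test(a, b, var.equal = TRUE)$p.value < 0.05
  })
  expect_lt(abs(mean(rej) - power_closed), 0.03)
})

test_that("quadratic fits recover exact and noisy coefficients", {
  a <- seq(20, 70, by = 2)
  y <- 2 + 0 * a + 0.5 * a^2
  f <- polyfit2(a, y)
  expect_equal(unname(f$coefficients), c(2, 0, 0.5), tolerance = 1e-9)
  f <- polyfit2(a, rep(7, length(a)))
  expect_equal(unname(f$coefficients), c(7, 0, 0), tolerance = 1e-9)
  expect_error(polyfit2(c(20, 20, 30), c(1, 2, 3)), "distinct")

  set.seed(29)
  a <- runif(1000, 20, 77)
  y <- 5 - 0.3 * a + 0.01 * a^2 + rnorm(1000, 0, 2)
  f <- polyfit2(a, y)
  fit <- stats::lm(y ~ a + I(a^2))
  se <- summary(fit)$coefficients[, 2]
  truth <- c(5, -0.3, 0.01)
  expect_true(all(abs(unname(f$coefficients) - truth) < 3 * se))
})

test_that("polyfit2 with no curvature reduces to the shared linear fit", {
  a <- seq(19, 35, length.out = 30)
  y <- -5 + 0.2 * a
  f2 <- polyfit2(a, y)
  f1 <- fit_normalized_slope(a, y)
  expect_equal(unname(f2$coefficients[["c1"]]), f1$k_X, tolerance = 1e-9)
  expect_equal(unname(f2$coefficients[["c0"]]), f1$n_X, tolerance = 1e-9)
  expect_lt(abs(f2$coefficients[["c2"]]), 1e-12)
})

test_that("scoring the referent with adjustments off gives the identity fit", {
  pop <- generate_referent(referent_spec("younger", n = 3000, seed = 37))
  cal <- calibrate(pop, quiet = TRUE)
  bt <- bioage_table(referent_as_subjects(pop),
                     constants = list(younger = cal, older = cal),
                     policy = adjustment_policy(FALSE, FALSE))
  fits <- bioage_fits(bt)
  ref <- fits[fits$group == "referent", ]
  neg <- fits[fits$group == "negative", ]
  expect_identical(ref$slope, 1)
  expect_lt(abs(neg$slope - 1), 1e-6)
  expect_lt(abs(neg$intercept), 1e-4)
})

test_that("groups with identical biomarkers differ by exactly the HIV line", {
  set.seed(41)
  n <- 60
  ages <- runif(n, 20, 35)
  base <- data.frame(subject_id = sprintf("n%02d", 1:n), age = ages,
                     hiv_status = "negative", rtl = runif(n, 0.4, 1.4),
                     serum_iron = runif(n, 60, 150),
                     tibc = runif(n, 250, 450), ferritin = runif(n, 2, 200))
  twin <- base
  twin$subject_id <- sprintf("p%02d", 1:n)
  twin$hiv_status <- "positive"
  bt <- bioage_table(rbind(base, twin))
  fits <- bioage_fits(bt)
  dslope <- fits$slope[fits$group == "positive"] -
    fits$slope[fits$group == "negative"]
  dint <- fits$intercept[fits$group == "positive"] -
    fits$intercept[fits$group == "negative"]
  expect_equal(dslope, 0.194, tolerance = 1e-9)
  expect_equal(dint, -20 * 0.194, tolerance = 1e-9)
})

test_that("single-group tables yield one fit plus the referent line", {
  pop <- generate_referent(referent_spec("younger", n = 50, seed = 43))
  bt <- bioage_table(referent_as_subjects(pop))
  fits <- bioage_fits(bt)
  expect_identical(fits$group, c("referent", "negative"))
  one <- bt[1:3, ]
  one$age <- 25
  expect_warning(f <- bioage_fits(one), "fewer than 2 distinct")
  expect_identical(f$group, "referent")
})

test_that("the relation scan recovers null and injected relations", {
  expect_identical(nrow(relation_scan(data.frame())), 0L)

  # default cohort has no built-in RTL-viral-load or RTL-duration relation
  cohort <- generate_cohort(cohort_spec(seed = 47))
  rep_ <- relation_scan(cohort)
  expect_true(all(c("rtl", "serum_iron", "ferritin") %in% rep_$response))
  for (row in which(rep_$response == "rtl")) {
    sub <- rep_[row, ]
    x <- if (sub$predictor == "pvl") pvl_floor(cohort$pvl) else
      cohort[[sub$predictor]]
    keep <- !is.na(x) & !is.na(cohort$rtl)
    se <- summary(stats::lm(cohort$rtl[keep] ~ x[keep]))$coefficients[2, 2]
    expect_lt(abs(sub$slope), 3 * se)
  }

  # inject a negative RTL-vs-duration trend and recover its sign
  cs <- cohort_spec(seed = 53, groups = list(younger_pos = list(n = 1000)))
  big <- generate_cohort(cs)
  trt <- !is.na(big$therapy_duration)
  big$rtl[trt] <- big$rtl[trt] - 0.001 * big$therapy_duration[trt]
  rep2 <- relation_scan(big)
  got <- rep2[rep2$response == "rtl" & rep2$predictor == "therapy_duration", ]
  expect_lt(got$slope, 0)
  expect_equal(got$slope, -0.001, tolerance = 1)
})
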