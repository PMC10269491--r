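# The composite formula, life-expectancy adjustments, cohort scoring.

test_that("the population adjustment matches its defining ratio", {
  expect_equal(delta_hiv_neg(72.9, 76.1), (72.9 - 76.1) / 72.9,
               tolerance = 1e-15)
  expect_identical(round(delta_hiv_neg(72.9, 76.1), 3), -0.044)
  expect_equal(delta_hiv_neg(70, 70), 0)
  expect_equal(delta_hiv_neg(80, 76), 0.05, tolerance = 1e-12)
  expect_error(delta_hiv_neg(0, 76.1), "> 0")
})

test_that("the HIV adjustment matches its defining ratio", {
  expect_equal(delta_hiv_pos(76.1, 67), (76.1 - 67) / (67 - 20),
               tolerance = 1e-15)
  expect_identical(round(delta_hiv_pos(76.1, 67), 3), 0.194)
  expect_equal(delta_hiv_pos(67, 67), 0)
  expect_equal(delta_hiv_pos(70, 45), 1, tolerance = 1e-12)
  expect_error(delta_hiv_pos(76.1, 20), "> 20")
})

test_that("set_adjustments fills the delta fields from life expectancies", {
  pop <- generate_referent(referent_spec("younger", n = 100, seed = 1))
  cal <- calibrate(pop, quiet = TRUE)
  expect_identical(cal$delta_hiv_neg, 0)
  cal <- set_adjustments(cal, life_expectancy_set())
  expect_equal(cal$delta_hiv_neg, delta_hiv_neg(72.9, 76.1))
  expect_equal(cal$delta_hiv_pos, delta_hiv_pos(76.1, 67))
})

test_that("an all-means subject with adjustments off scores exactly C", {
  for (band in c("younger", "older")) {
    cc <- reference_constants(band)
    r <- biological_age(all_means_subject(band), cc,
                        adjustment_policy(FALSE, FALSE))
    expect_equal(r$a_bio, cc$C, tolerance = 1e-12)
    expect_equal(unname(r$term_contributions), rep(0, 5))
  }
})

test_that("adjustment arithmetic matches the published worked values", {
  # HIV-negative at the younger band mean age, population adjustment on
  r <- biological_age(all_means_subject("younger", age = 27.477),
                      reference_constants("younger"),
                      adjustment_policy(TRUE, FALSE))
  expect_equal(r$a_bio, 27.4907 - 27.477 * 0.044, tolerance = 1e-9)
  expect_equal(r$a_bio, 26.2817, tolerance = 5e-4)
  # all-mean younger subject, HIV-positive, age 30, both adjustments
  s <- all_means_subject("younger", hiv_status = "positive", age = 30)
  r <- biological_age(s, reference_constants("younger"), adjustment_policy())
  expect_equal(r$a_bio,
               27.4907 + (30 - 27.4770) / 4.7178 * 2.7681 +
                 30 * (-0.044) + 10 * 0.194,
               tolerance = 1e-9)
  # at the mean age instead, the age term vanishes and only the
  # adjustments shift C
  s$age <- 27.4770
  r <- biological_age(s, reference_constants("younger"), adjustment_policy())
  expect_equal(r$a_bio, 27.4907 + 27.4770 * (-0.044) + 7.4770 * 0.194,
               tolerance = 1e-9)
})

test_that("a one-SD shift in any biomarker moves the score by exactly +/- k", {
  for (band in c("younger", "older")) {
    cc <- reference_constants(band)
    base <- biological_age(all_means_subject(band), cc,
                           adjustment_policy(FALSE, FALSE))$a_bio
    fields <- c(RTL = "rtl", Fe = "serum_iron", TIBC = "tibc", F = "ferritin")
    for (v in names(fields)) {
      s <- all_means_subject(band)
      s[[fields[[v]]]] <- s[[fields[[v]]]] + cc$sigma[[v]]
      r <- biological_age(s, cc, adjustment_policy(FALSE, FALSE))
      expected_sign <- sign(cc$slope[[v]])
      expect_equal(r$a_bio - base, expected_sign * cc$k, tolerance = 1e-9)
    }
  }
  # longer telomeres by one SD subtract k years (worked value)
  s <- all_means_subject("younger")
  s$rtl <- s$rtl + 0.2699
  r <- biological_age(s, reference_constants("younger"),
                      adjustment_policy(FALSE, FALSE))
  expect_equal(r$a_bio, 27.4907 - 2.7681, tolerance = 1e-9)
})

test_that("the score is monotone in each input with the calibrated signs", {
  cc <- reference_constants("younger")
  pol <- adjustment_policy(FALSE, FALSE)
  base <- all_means_subject("younger")
  dirs <- c(rtl = -1, serum_iron = -1, tibc = -1, ferritin = 1, age = 1)
  for (f in names(dirs)) {
    lo <- base; hi <- base
    hi[[f]] <- hi[[f]] * 1.05
    expect_identical(sign(biological_age(hi, cc, pol)$a_bio -
                            biological_age(lo, cc, pol)$a_bio),
                     unname(dirs[f]))
  }
})

test_that("HIV status changes the score by exactly (a - 20) * delta_hiv_pos", {
  set.seed(31)
  for (i in 1:10) {
    age <- runif(1, 20, 35)
    s_neg <- all_means_subject("younger", "negative", age = age)
    s_pos <- all_means_subject("younger", "positive", age = age)
    s_neg$rtl <- s_pos$rtl <- runif(1, 0.4, 1.6)
    d <- biological_age(s_pos)$a_bio - biological_age(s_neg)$a_bio
    expect_equal(d, (age - 20) * 0.194, tolerance = 1e-9)
  }
  # naive subjects can be excluded from the HIV term by policy
  s <- all_means_subject("younger", "positive", age = 30)
  s$regimen <- "naive"
  r <- biological_age(s, policy = adjustment_policy(adjust_naive = FALSE))
  expect_identical(r$adjustment_pos, 0)
})

test_that("the decomposition reconstructs the total to 1e-9 years", {
  set.seed(77)
  for (i in 1:20) {
    s <- list(age = runif(1, 20, 34), rtl = runif(1, 0.3, 2),
              serum_iron = runif(1, 40, 200), tibc = runif(1, 200, 500),
              ferritin = runif(1, 1, 400),
              hiv_status = sample(c("negative", "positive"), 1))
    r <- biological_age(s)
    expect_equal(r$a_bio,
                 r$k * sum(r$term_contributions) + r$C +
                   r$adjustment_neg + r$adjustment_pos,
                 tolerance = 1e-9)
  }
})

test_that("missing formula inputs and out-of-band ages are rejected by name", {
  s <- all_means_subject("younger")
  s$ferritin <- NA
  expect_error(biological_age(s), "ferritin")
  s <- all_means_subject("younger", age = 42)
  expect_error(biological_age(s), "outside")
  expect_warning(r <- biological_age(s, allow_out_of_band = TRUE), "nearest")
  expect_identical(r$band, "younger")
  # (a - 20) may be negative below age 20, as the formula dictates
  r <- biological_age(all_means_subject("younger", "positive", age = 19))
  expect_equal(r$adjustment_pos, -0.194, tolerance = 1e-12)
})

test_that("bioage_table vectorizes the formula with per-row diagnostics", {
  empty <- bioage_table(data.frame())
  expect_identical(nrow(empty), 0L)
  expect_identical(nrow(attr(empty, "excluded")), 0L)

  s <- all_means_subject("younger")
  cohort <- do.call(rbind, lapply(1:5, function(i) {
    as.data.frame(s[c("age", "rtl", "serum_iron", "tibc", "ferritin",
                      "hiv_status")])
  }))
  cohort$subject_id <- sprintf("c%d", 1:5)
  bt <- bioage_table(cohort, policy = adjustment_policy(FALSE, FALSE))
  expect_identical(length(unique(bt$a_bio)), 1L)
  expect_equal(bt$a_bio[1], 27.4907, tolerance = 1e-9)

  cohort$age[2] <- 40            # excluded-gap age
  cohort$rtl[4] <- NA            # missing input
  bt <- bioage_table(cohort)
  expect_identical(bt$subject_id, c("c1", "c3", "c5"))
  ex <- attr(bt, "excluded")
  expect_identical(ex$subject_id, c("c2", "c4"))
  expect_match(ex$reason[1], "outside")
  expect_match(ex$reason[2], "rtl")
  # scalar and vectorized paths agree
  r1 <- biological_age(as.list(cohort[1, ]))
  expect_equal(bt$a_bio[1], r1$a_bio, tolerance = 1e-12)
})

test_that("extreme z-scores are flagged as outliers but never altered", {
  s <- all_means_subject("younger")
  cohort <- as.data.frame(s[c("age", "rtl", "serum_iron", "tibc",
                              "ferritin", "hiv_status")])
  cohort <- rbind(cohort, cohort)
  cohort$subject_id <- c("ok", "hot")
  cohort$ferritin[2] <- 141.099 + 6 * 87.18172   # six referent SDs up
  bt <- bioage_table(cohort, policy = adjustment_policy(FALSE, FALSE))
  out <- attr(bt, "outliers")
  expect_identical(out$subject_id, "hot")
  expect_identical(out$variable, "F")
  expect_equal(out$z, 6, tolerance = 1e-9)
  # the flagged value still enters the score unmodified
  expect_equal(bt$a_bio[2] - bt$a_bio[1], 6 * 2.7681, tolerance = 1e-9)
})
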