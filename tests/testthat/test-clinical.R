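test_that("summary-statistic ANOVA reproduces published demographic p-values", {
  demo <- ckd_demographics("summary")
  age <- demo[demo$variable == "age", ]
  res <- anova_from_summary(age)
  expect_equal(res$p_value, 0.01348664, tolerance = 1e-6)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 76)

  crea <- anova_from_summary(demo[demo$variable == "creatinine", ])
  expect_lt(crea$p_value, 0.001)
})

test_that("summary ANOVA handles null and degenerate groups", {
  same <- data.frame(n = c(10, 12), mean = c(5, 5), sd = c(1, 1.2))
  res <- anova_from_summary(same)
  expect_equal(res$f_stat, 0)
  expect_equal(res$p_value, 1)
  expect_error(anova_from_summary(data.frame(n = 10, mean = 5, sd = 1)), "two groups")
  expect_error(anova_from_summary(data.frame(n = c(1, 5), mean = c(1, 2), sd = c(0, 1))),
               "n >= 2")
})

test_that("summary ANOVA is algebraically identical to raw-data ANOVA", {
  set.seed(30)
  g <- rep(c("a", "b", "c"), times = c(12, 9, 15))
  y <- rnorm(length(g), mean = as.integer(factor(g)))
  summ <- dplyr::summarise(dplyr::group_by(data.frame(g, y), g),
                           n = dplyr::n(), mean = mean(y), sd = sd(y))
  mine <- anova_from_summary(summ)
  ref <- summary(aov(y ~ g))[[1]]
  expect_equal(mine$f_stat, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("chi-squared reproduces published categorical p-values", {
  expect_equal(chi_squared_test(demographic_counts_matrix("diabetes"))$p_value,
               0.01245729, tolerance = 1e-6)
  expect_equal(chi_squared_test(demographic_counts_matrix("gender"))$p_value,
               0.3649702, tolerance = 1e-6)
})

test_that("chi-squared basics: proportional tables, permutations, Fisher agreement", {
  prop <- rbind(c(10, 20, 30), c(5, 10, 15))
  res <- chi_squared_test(prop)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_error(chi_squared_test(matrix(0, 2, 2)), "Empty")

  tab <- demographic_counts_matrix("diabetes")
  perm <- tab[2:1, c(2, 3, 1)]
  expect_equal(chi_squared_test(tab)$p_value, chi_squared_test(perm)$p_value)

  # balanced n = 80 tables with a clear association: the asymptotic chi-squared
  # p agrees with the exact (Fisher) p to within 0.02 and in direction
  for (a in c(26, 28, 30, 32)) {
    t22 <- matrix(c(a, 40 - a, 40 - a, a), 2, 2)
    p_chi <- chi_squared_test(t22)$p_value
    p_fis <- fisher.test(t22)$p.value
    expect_lt(abs(p_chi - p_fis), 0.02)
    expect_equal(p_chi < 0.05, p_fis < 0.05)
  }
})

test_that("MDRD eGFR matches its closed form and is monotone", {
  expect_equal(mdrd_egfr(88.4, 50, "male"), 79.0947, tolerance = 1e-4)
  expect_equal(mdrd_egfr(88.4, 50, "female"), 79.0947 * 0.742, tolerance = 1e-4)
  expect_equal(mdrd_egfr(88.4, 50, "male", black = TRUE), 79.0947 * 1.212,
               tolerance = 1e-4)
  crea <- seq(60, 400, by = 20)
  expect_true(all(diff(mdrd_egfr(crea, 50, "male")) < 0))
  ages <- seq(25, 85, by = 5)
  expect_true(all(diff(mdrd_egfr(100, ages, "male")) < 0))
  expect_error(mdrd_egfr(-1, 50, "male"), "positive")
  expect_error(mdrd_egfr(88.4, 0, "male"), "positive")
})

test_that("KDIGO staging bins eGFR as published and maps to severity groups", {
  expect_equal(as.character(kdigo_stage(c(95, 60, 50, 44.9, 29, 14.9, 15, 90))),
               c("G1", "G2", "G3a", "G3b", "G4", "G5", "G4", "G1"))
  expect_equal(as.character(severity_group(c("G2", "G3a", "G3b", "G4", "G5"))),
               c("mild", "mild", "moderate", "severe", "severe"))
  expect_error(severity_group("G6"), "Unknown")
})

test_that("trajectory regression handles exact fits and degenerate outcomes", {
  cl <- tibble::tibble(patient_id = sprintf("P%02d", 1:10),
                       egfr_followup = 2^seq(4, 6, length.out = 10),
                       creatinine_followup = rep(100, 10))
  npx <- tibble::tibble(patient_id = cl$patient_id,
                        lin = 10 - 2 * log2(cl$egfr_followup))
  fit <- suppressWarnings( # lm flags the exact fit as "essentially perfect"
    trajectory_regression(npx, cl, "lin", "egfr_followup"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$slope, -2, tolerance = 1e-10)
  expect_error(trajectory_regression(npx, cl, "lin", "creatinine_followup"),
               "constant")
})

test_that("panel proteins track declining renal function in the synthetic cohort", {
  co <- fixture_strong()
  tr <- trajectory_regression(co$npx, co$clinical, co$truth$informative,
                              "egfr_followup")
  expect_true(all(tr$slope < 0))
  expect_true(all(tr$r_squared > 0.5))
  expect_true(all(tr$p_value < 1e-4))
  trc <- trajectory_regression(co$npx, co$clinical, co$truth$informative,
                               "creatinine_followup")
  expect_true(all(trc$slope > 0)) # creatinine rises as eGFR falls
})

test_that("cohort clinical contrasts run in the expected directions and invert on swap", {
  co <- fixture_strong()
  asg <- truth_assignment(co)
  cmp <- cohort_clinical_compare(co$clinical, asg)
  dir <- setNames(cmp$direction, cmp$variable)
  expect_equal(dir[["age"]], "higher_in_severe")
  expect_equal(dir[["urea"]], "higher_in_severe")
  expect_equal(dir[["creatinine_baseline"]], "higher_in_severe")
  expect_equal(dir[["creatinine_followup"]], "higher_in_severe")
  expect_equal(dir[["egfr_baseline"]], "lower_in_severe")
  expect_equal(dir[["egfr_followup"]], "lower_in_severe")

  swapped <- asg
  swapped$cohort <- ifelse(asg$cohort == "severe", "mild", "severe")
  cmp2 <- cohort_clinical_compare(co$clinical, swapped)
  expect_true(all(cmp2$direction != cmp$direction))
  expect_equal(cmp2$t_stat, -cmp$t_stat, tolerance = 1e-12)
})
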