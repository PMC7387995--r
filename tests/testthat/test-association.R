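test_that("univariate odds ratios reproduce the published closed-form values", {
  tabs <- table1_tables()
  girls <- univariate_or(tabs$gender, "girl")
  expect_equal(round(girls$estimate, 2), 3.26)
  expect_equal(round(girls$ci_low, 2), 2.69)
  expect_equal(round(girls$ci_high, 2), 3.96)
  expect_lt(girls$p_value, 0.001)
  expect_equal(round(univariate_or(tabs$scapular_tilt, "right")$estimate, 2), 16.55)
  expect_false(girls$corrected)
})

test_that("odds-ratio edge cases: symmetry, zero cells, bad levels", {
  flat <- contingency_table("x", c("a", "b"), c(25, 25), c(25, 25))
  e <- univariate_or(flat, "b")
  expect_equal(e$estimate, 1)
  expect_equal(log(e$ci_high), -log(e$ci_low), tolerance = 1e-12)
  zero <- contingency_table("x", c("a", "b"), c(30, 0), c(20, 10))
  cz <- univariate_or(zero, "b")
  expect_true(cz$corrected)
  expect_true(is.finite(cz$estimate) && cz$estimate > 1)
  expect_error(univariate_or(flat, "a"), "reference")
  expect_error(univariate_or(flat, "c"), "not in table")
})

test_that("closed-form OR equals exp(slope) of a one-predictor logistic fit", {
  set.seed(33)
  for (i in 1:10) {
    cts <- rpois(4, 60) + 5  # control_ref, control_lvl, case_ref, case_lvl
    tab <- contingency_table("x", c("a", "b"), cts[1:2], cts[3:4])
    closed <- univariate_or(tab, "b")$estimate
    # same 2x2 pushed through the logistic route, using a unit-spaced
    # numeric covariate so exp(slope) is the per-level OR
    n <- sum(cts)
    cohort <- manual_cohort(
      n,
      ais = rep(c(0, 0, 1, 1), cts),
      age = rep(c(10, 11, 10, 11), cts)
    )
    logistic <- univariate_or_continuous(cohort, "age")$estimate
    expect_equal(logistic, closed, tolerance = 1e-6)
  }
})

test_that("continuous OR: null calibration and recovery of a known slope", {
  set.seed(44)
  covered_null <- vapply(1:100, function(i) {
    cohort <- manual_cohort(400, ais = rbinom(400, 1, 0.5),
                            age = rnorm(400, 13, 2))
    e <- univariate_or_continuous(cohort, "age")
    e$ci_low <= 1 && 1 <= e$ci_high
  }, logical(1))
  expect_gt(mean(covered_null), 0.88)

  covered_true <- vapply(1:40, function(i) {
    age <- rnorm(1779, 12.9, 1.9)
    y <- rbinom(1779, 1, plogis(-1.69 + log(1.14) * age))
    e <- univariate_or_continuous(manual_cohort(1779, ais = y, age = age), "age")
    e$ci_low <= 1.14 && 1.14 <= e$ci_high
  }, logical(1))
  expect_gte(mean(covered_true), 0.9)

  same <- manual_cohort(50, ais = rep(1, 50), age = rnorm(50, 12, 1))
  expect_error(univariate_or_continuous(same, "age"), "constant")
})

test_that("multivariate fit recovers known coefficients and satisfies the score equation", {
  set.seed(55)
  n <- 5000
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.2 + 0.7 * x1 - 0.5 * x2))
  cohort <- manual_cohort(n, ais = y,
                          gender = c("boy", "girl")[x1 + 1],
                          flat_back = c("normal", "abnormal")[x2 + 1])
  fit <- suppressWarnings(fit_multivariate(cohort, encoding = "dummy_expanded",
                                           drop_constant = TRUE))
  expect_lt(abs(fit$coefficients[["gender:girl"]] - 0.7),
            3 * fit$se[["gender:girl"]])
  expect_lt(abs(fit$coefficients[["flat_back:abnormal"]] - (-0.5)),
            3 * fit$se[["flat_back:abnormal"]])
  # with an intercept, mean fitted probability equals the case fraction
  expect_equal(mean(predict_probability(fit, cohort)), mean(y), tolerance = 1e-8)
})

test_that("the fitted optimum beats every point of a coarse likelihood grid", {
  toy <- manual_cohort(
    20,
    ais = c(0, 0, 0, 0, 0, 1, 0, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 1, 1, 1),
    gender = rep(c("boy", "girl"), each = 10),
    age = c(10, 11, 12, 13, 14, 15, 10, 11, 12, 13,
            11, 12, 13, 14, 15, 10, 12, 13, 14, 15)
  )
  fit <- suppressWarnings(fit_multivariate(toy, encoding = "single_score",
                                           drop_constant = TRUE))
  best <- model_loglik(fit, toy)
  grid_model <- fit
  for (b0 in seq(-8, 4, 2)) {
    for (bg in seq(-2, 3, 0.5)) {
      for (ba in seq(-0.8, 0.8, 0.2)) {
        grid_model$intercept <- b0
        grid_model$coefficients[] <- 0
        grid_model$coefficients["X1"] <- bg
        grid_model$coefficients["X2"] <- ba
        expect_lte(model_loglik(grid_model, toy), best + 1e-8)
      }
    }
  }
})

test_that("fit guards: constant outcome, rank deficiency, separation warning", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 61)
  all_case <- cohort[cohort$ais == 1, ]
  expect_error(suppressWarnings(fit_multivariate(all_case)), "constant")
  const <- cohort
  const$gender <- "boy"
  expect_error(suppressWarnings(fit_multivariate(const, "single_score")),
               "rank deficient")
  fit <- suppressWarnings(fit_multivariate(const, "single_score",
                                           drop_constant = TRUE))
  expect_equal(fit$coefficients[["X1"]], 0)
  sep <- manual_cohort(40, ais = rep(c(0, 1), each = 20),
                       gender = rep(c("boy", "girl"), each = 20),
                       age = rnorm(40, 12, 1))
  w <- capture_warnings(fit_multivariate(sep, "single_score", drop_constant = TRUE))
  expect_true(any(grepl("separation", w)))
})

test_that("association report aligns univariate and adjusted estimates", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 71)
  rep <- suppressWarnings(associate_cohort(cohort))
  expect_true(all(c("or_estimate", "aor_estimate") %in% names(rep)))
  expect_equal(nrow(rep), 19)  # 17 non-reference sign levels + gender + age
  expect_true(all(rep$or_estimate > 0))
  expect_false(anyNA(rep$aor_estimate))
  # univariate and adjusted girls' effects are both positive risk factors
  girl <- rep[rep$level == "girl", ]
  expect_gt(girl$or_estimate, 1)
  expect_gt(girl$aor_estimate, 1)
})
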