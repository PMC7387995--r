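test_that("published equations carry their exact printed coefficients", {
  eq1 <- printed_equation(1)
  expect_equal(eq1$intercept, -7.124)
  expect_equal(eq1$coefficients[["X12"]], 1.471)
  expect_equal(eq1$provenance, "printed_equation")
  expect_equal(printed_equation(2)$intercept, -3.648)
  expect_equal(printed_equation(4)$intercept, -3.648)
  expect_equal(printed_equation(3)$coefficients[["X11"]], 1.420)
  expect_error(printed_equation(5), "must be 1, 2, 3 or 4")
})

test_that("predicted probabilities follow the logistic form", {
  eq1 <- printed_equation(1)
  zero <- stats::setNames(rep(0, 12), names(eq1$coefficients))
  expect_equal(predict_probability(eq1, zero), 1 / (1 + exp(7.124)))
  # strictly increasing in a positive-coefficient covariate
  probs <- vapply(0:2, function(v) {
    x <- zero
    x["X12"] <- v
    predict_probability(eq1, x)
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  cohort <- generate_cohort(default_cohort_spec(), seed = 23)
  p <- predict_probability(eq1, cohort)
  expect_true(all(p > 0 & p < 1))
  wrong <- encode_covariates(cohort, "dummy_expanded")
  expect_error(predict_probability(eq1, wrong), "encoding")
})

test_that("classification threshold semantics and monotone sweep", {
  expect_equal(classify(0.5), 1L)  # boundary classifies positive
  expect_equal(classify(c(0, 1)), c(0L, 1L))
  expect_error(classify(0.5, threshold = 0), "inside")
  set.seed(29)
  p <- runif(200)
  positives <- vapply(seq(0.05, 0.95, 0.05),
                      function(t) sum(classify(p, t)), numeric(1))
  expect_true(all(diff(positives) <= 0))
})

test_that("uniform weights are the identity and weight scale is irrelevant", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 37)
  base <- suppressWarnings(fit_multivariate(cohort, "single_score"))
  uniform <- stats::setNames(rep(2, 12), ais_covariates())
  w1 <- apply_weighting(base, uniform, "aor_weighted")
  expect_equal(w1$coefficients, base$coefficients)
  expect_equal(w1$intercept, base$intercept, tolerance = 1e-6)
  raw <- aor_weights(base)
  a <- apply_weighting(base, raw, "aor_weighted")
  b <- apply_weighting(base, raw * 7, "aor_weighted")
  expect_equal(a$coefficients, b$coefficients)
  expect_equal(a$intercept, b$intercept, tolerance = 1e-10)
  expect_error(apply_weighting(base, raw[-1], "aor_weighted"), "missing weight")
  bad <- raw; bad[1] <- 0
  expect_error(apply_weighting(base, bad, "aor_weighted"), "positive")
})

test_that("weighted models stay calibrated in the large on training data", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 41)
  base <- suppressWarnings(fit_multivariate(cohort, "single_score"))
  for (w in list(aor_weights(base), auc_weights(cohort))) {
    m <- apply_weighting(base, w, "auc_weighted")
    expect_equal(mean(predict_probability(m, cohort)), mean(cohort$ais),
                 tolerance = 1e-8)
  }
})

test_that("non-uniform weights can reorder subjects; uniform weights cannot", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 43)
  base <- suppressWarnings(fit_multivariate(cohort, "single_score"))
  p0 <- predict_probability(base, cohort)
  uniform <- stats::setNames(rep(1, 12), ais_covariates())
  pu <- predict_probability(apply_weighting(base, uniform, "aor_weighted"), cohort)
  expect_equal(order(pu), order(p0))
  # a deliberately lopsided weight vector flips at least one pair
  lopsided <- uniform
  lopsided["atr_lumbar"] <- 10
  pl <- predict_probability(apply_weighting(base, lopsided, "aor_weighted"), cohort)
  ranks_differ <- !identical(order(pl), order(p0))
  expect_true(ranks_differ)
})

test_that("weight vectors live on the probability scale and combine by product", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 47)
  base <- suppressWarnings(fit_multivariate(cohort, "single_score"))
  wa <- aor_weights(base)
  wu <- auc_weights(cohort)
  expect_equal(names(wa), ais_covariates())
  expect_true(all(wa > 0 & wa < 1))
  expect_true(all(wu > 0 & wu < 1))
  expect_equal(aor_to_weight(1), 0.5)
  expect_error(aor_to_weight(-2), "positive")
  both <- combine_weights(wa, wu)
  expect_equal(unname(both["gender"]),
               unname((wa / mean(wa))["gender"] * (wu / mean(wu))["gender"]))
  # printed weights cover the same variables; the three flags whose AUCs
  # were unpublished sit at ~0.5 (no stand-alone discrimination)
  expect_equal(names(printed_aor_weights()), ais_covariates())
  wp <- printed_auc_weights()
  expect_true(all(wp > 0 & wp <= 1))
  expect_lt(max(abs(wp[c("flat_back", "thoracic_kyphosis", "lumbar_kyphosis")] -
                      0.5)), 0.02)
})
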