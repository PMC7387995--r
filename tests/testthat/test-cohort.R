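test_that("default spec reproduces the published group-conditional frequencies", {
  spec <- default_cohort_spec()
  expect_equal(spec$n_controls + spec$n_cases, 1779)
  expect_equal(unname(spec$category_probs$gender$case),
               c(311 / 884, 573 / 884))
  expect_equal(unname(spec$category_probs$scapular_tilt$control),
               c(764, 85, 46) / 895)
  for (v in ais_variables()) {
    for (grp in c("control", "case")) {
      p <- spec$category_probs[[v]][[grp]]
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("spec validation rejects malformed inputs", {
  spec <- default_cohort_spec()
  expect_error(cohort_spec(-1, 10, spec$category_probs, spec$age_params),
               "non-negative")
  bad <- spec$category_probs
  bad$gender$case <- c(0.6, 0.6)
  expect_error(cohort_spec(10, 10, bad, spec$age_params), "sum to 1")
  k <- length(latent_order())
  not_psd <- diag(k)
  not_psd[1, 2] <- not_psd[2, 1] <- 1
  not_psd[1, 3] <- not_psd[3, 1] <- 1
  not_psd[2, 3] <- not_psd[3, 2] <- -1
  expect_error(cohort_spec(10, 10, spec$category_probs, spec$age_params,
                           dependence = not_psd),
               "positive semi-definite")
})

test_that("generated cohorts have exact group sizes, valid levels, truncated ages", {
  spec <- default_cohort_spec()
  cohort <- generate_cohort(spec, seed = 99)
  expect_equal(sum(cohort$ais == 0), 895)
  expect_equal(sum(cohort$ais == 1), 884)
  expect_true(all(cohort$age >= 6 & cohort$age <= 19))
  for (v in ais_variables()) {
    expect_true(all(cohort[[v]] %in% ais_levels(v)))
  }
  empty <- cohort_spec(0, 0, spec$category_probs, spec$age_params)
  expect_equal(nrow(generate_cohort(empty, seed = 1)), 0)
})

test_that("the same seed reproduces a cohort byte-for-byte", {
  spec <- default_cohort_spec()
  a <- generate_cohort(spec, seed = 7)
  b <- generate_cohort(spec, seed = 7)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(generate_cohort(spec, seed = 8), a))
})

test_that("empirical level frequencies recover the spec probabilities", {
  spec <- default_cohort_spec()
  big <- spec
  big$n_controls <- 10000L
  big$n_cases <- 10000L
  cohort <- generate_cohort(big, seed = 31)
  for (v in c("gender", "scapular_tilt", "atr_thoracic", "lumbar_kyphosis")) {
    for (grp in c(0, 1)) {
      sub <- cohort[cohort$ais == grp, v]
      p <- spec$category_probs[[v]][[if (grp == 0) "control" else "case"]]
      for (l in seq_along(p)) {
        se <- sqrt(p[l] * (1 - p[l]) / 10000)
        expect_lt(abs(mean(sub == ais_levels(v)[l]) - p[l]), 3 * se + 1e-12)
      }
    }
  }
  # spec'd law-of-large-numbers example: case-group right thoracic rotation
  # at 10x the default size
  big10 <- spec
  big10$n_controls <- 8950L
  big10$n_cases <- 8840L
  c10 <- generate_cohort(big10, seed = 32)
  p <- 229 / 884
  freq <- mean(c10$atr_thoracic[c10$ais == 1] == "right_gt5")
  expect_lt(abs(freq - p), 3 * sqrt(p * (1 - p) / 8840))
})

test_that("latent draws are uncorrelated without dependence, correlated with it", {
  spec <- default_cohort_spec()
  spec$n_controls <- 4000L
  spec$n_cases <- 0L
  cohort <- generate_cohort(spec, seed = 5, keep_latent = TRUE)
  z <- attr(cohort, "latent")
  cors <- cor(z)
  off <- cors[upper.tri(cors)]
  # per-pair 3-SE check, with a 4-SE cap on the worst of the 78 pairs to
  # account for multiplicity
  expect_gte(mean(abs(off) < 3 / sqrt(4000)), 0.95)
  expect_lt(max(abs(off)), 4 / sqrt(4000))

  k <- length(latent_order())
  dep <- diag(k)
  i <- match("scapular_tilt", latent_order())
  j <- match("shoulder_height_diff", latent_order())
  dep[i, j] <- dep[j, i] <- 0.6
  spec_dep <- cohort_spec(4000, 0, spec$category_probs, spec$age_params,
                          dependence = dep)
  cd <- generate_cohort(spec_dep, seed = 5, keep_latent = TRUE)
  zd <- attr(cd, "latent")
  expect_equal(cor(zd[, i], zd[, j]), 0.6, tolerance = 0.05)
  # marginals are preserved under dependence
  p_norm <- spec$category_probs$scapular_tilt$control[1]
  expect_lt(abs(mean(cd$scapular_tilt == "normal") - p_norm),
            3 * sqrt(p_norm * (1 - p_norm) / 4000))
})
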