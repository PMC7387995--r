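test_that("cohort CSV round-trips losslessly and validates on read", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 81)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back$age, cohort$age, tolerance = 1e-12)
  for (v in ais_variables()) expect_equal(back[[v]], cohort[[v]])
  expect_equal(back$ais, as.integer(cohort$ais))
})

test_that("reader normalizes letter case and rejects malformed files", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 83)[1:5, ]
  cohort$gender <- "boy"
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  txt <- readLines(path)
  txt[2] <- sub("^boy", "Boy", txt[2])
  writeLines(txt, path)
  expect_warning(back <- read_cohort(path), "letter case")
  expect_true(all(back$gender %in% c("boy", "girl")))

  writeLines(character(), path)
  expect_error(read_cohort(path), "empty cohort file")
  writeLines(c("gender,age", "boy,12"), path)
  expect_error(read_cohort(path), "missing column")
  write_cohort(cohort, path)
  txt <- readLines(path)
  txt[1] <- sub("^gender", "ais", txt[1])
  writeLines(txt, path)
  expect_error(read_cohort(path), "duplicated column")
  write_cohort(cohort, path)
  txt <- readLines(path)
  txt[2] <- sub("^([^,]*),[^,]*", "\\1,twelve", txt[2])
  writeLines(txt, path)
  expect_error(read_cohort(path), "non-numeric age")
  expect_error(read_cohort(tempfile("nope")), "no such file")
})

test_that("unknown level strings are rejected with the offending rows", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 85)[1:4, ]
  cohort$scapular_tilt <- as.character(cohort$scapular_tilt)
  cohort$scapular_tilt[2] <- "sideways"
  expect_error(tabulate_by_status(cohort, "scapular_tilt"), "row")
})

test_that("run configuration demands exactly one cohort source", {
  expect_error(run_config(), "exactly one")
  expect_error(run_config(input = "a.csv", synthetic = default_cohort_spec()),
               "exactly one")
  cfg <- run_config(synthetic = default_cohort_spec(), seed = 5)
  expect_s3_class(cfg, "run_config")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("synthetic: default", "seed: 5", "out_dir: /tmp/x"), path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$seed, 5L)
  expect_s3_class(cfg2$synthetic, "cohort_spec")
})

test_that("identical config and seed give a byte-identical report bundle", {
  spec <- default_cohort_spec()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- suppressWarnings(run_pipeline(run_config(synthetic = spec, seed = 11,
                                                 out_dir = d1)))
  r2 <- suppressWarnings(run_pipeline(run_config(synthetic = spec, seed = 11,
                                                 out_dir = d2)))
  for (f in basename(r1$paths)) {
    f1 <- list.files(d1, pattern = paste0("^", f), full.names = TRUE)
    f2 <- list.files(d2, pattern = paste0("^", f), full.names = TRUE)
    for (i in seq_along(f1)) {
      expect_identical(unname(tools::md5sum(f1[i])), unname(tools::md5sum(f2[i])),
                       info = f)
    }
  }
  d3 <- withr::local_tempdir()
  r3 <- suppressWarnings(run_pipeline(run_config(synthetic = spec, seed = 12,
                                                 out_dir = d3)))
  expect_false(identical(unname(tools::md5sum(file.path(d1, "cohort.csv"))),
                         unname(tools::md5sum(file.path(d3, "cohort.csv")))))
})

test_that("stage gating emits only the requested reports", {
  cohort <- generate_cohort(default_cohort_spec(), seed = 87)[c(1, 2, 1000), ]
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, csv)
  d <- withr::local_tempdir()
  res <- run_pipeline(run_config(input = csv, stages = "describe",
                                 seed = 1, out_dir = d))
  files <- list.files(d)
  expect_true("descriptive.tsv" %in% files)
  expect_false(any(grepl("^model_|^evaluation", files)))
  expect_named(res$results, "describe")
})

test_that("the full pipeline evaluates all four models and records provenance", {
  d <- withr::local_tempdir()
  res <- suppressWarnings(run_pipeline(run_config(
    synthetic = default_cohort_spec(), seed = 21, out_dir = d)))
  expect_length(res$results$evaluate$models, 4)
  summ <- jsonlite::read_json(file.path(d, "summary.json"), simplifyVector = TRUE)
  expect_equal(summ$seed, 21)
  expect_equal(summ$n_records, 1779)
  expect_true(all(c("plain", "aor_auc_weighted") %in% names(summ$evaluation)))
  m <- jsonlite::read_json(file.path(d, "model_plain.json"))
  expect_equal(m$scheme, "plain")
  expect_length(m$coefficients, 12)
})

test_that("model JSON serialization preserves coefficients exactly", {
  eq3 <- printed_equation(3)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(eq3, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$intercept, -3.787)
  expect_equal(unlist(back$coefficients), eq3$coefficients)
  expect_equal(back$provenance, "printed_equation")
})

test_that("reproduce_paper re-derives every published worked example", {
  rep <- reproduce_paper()
  expect_s3_class(rep, "reproduction_report")
  expect_gte(nrow(rep), 15)
  expect_true(all(rep$pass))
})
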