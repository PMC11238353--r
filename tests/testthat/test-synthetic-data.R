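test_that("cohort outcome margins are exact for every seed", {
  for (seed in c(1, 7, 123)) {
    coh <- generate_cohort(142, 148, 24, 42, seed = seed)
    expect_equal(nrow(coh), 290)
    expect_equal(sum(coh$truth), 66)
    expect_equal(sum(coh$truth[coh$arm == "SW"]), 24)
    expect_equal(sum(coh$truth[coh$arm == "NSE"]), 42)
  }
  expect_equal(sum(generate_cohort(10, 10, 0, 0, seed = 1)$truth), 0)
  expect_equal(sum(generate_cohort(5, 5, 5, 5, seed = 7)$truth), 10)
  expect_error(generate_cohort(10, 10, 11, 0, seed = 1), "arm size")
})

test_that("cohort covariates follow the configured distributions", {
  coh <- generate_cohort(1000, 1000, 100, 200, seed = 3)
  expect_true(all(coh$age >= 18 & coh$age <= 89))
  expect_lt(abs(median(coh$age) - 29), 3)
  expect_lt(abs(mean(coh$pain) - 103 / 290), 0.04)
  expect_gt(mean(coh$tooth_class == "molar"), 0.45)
  coh2 <- generate_cohort(100, 100, 10, 10, covariates = list(pain_prob = 1),
                          seed = 3)
  expect_true(all(coh2$pain == 1))
})

test_that("generation is bit-identical given the seed", {
  a <- generate_cohort(50, 50, 10, 15, seed = 99)
  b <- generate_cohort(50, 50, 10, 15, seed = 99)
  expect_identical(a, b)
  prof <- list(rater_profile("R1", 0.7, 0.8), rater_profile("R2", 0.6, 0.9))
  ma <- generate_rater_responses(a, prof, seed = 5)
  mb <- generate_rater_responses(b, prof, seed = 5)
  expect_identical(ma, mb)
  expect_identical(generate_ai_predictions(a, prof[[1]], seed = 6),
                   generate_ai_predictions(a, prof[[1]], seed = 6))
})

test_that("degenerate rater profiles reproduce or invert truth", {
  coh <- generate_cohort(10, 10, 3, 4, seed = 2)
  m <- generate_rater_responses(coh, list(rater_profile("perfect", 1, 1),
                                          rater_profile("anti", 0, 0)),
                                seed = 4)
  expect_equal(unname(m$responses[, "perfect"]), coh$truth)
  expect_equal(unname(m$responses[, "anti"]), 1L - coh$truth)
  expect_equal(generate_ai_predictions(coh, rater_profile("AI", 1, 1), seed = 8),
               coh$truth)
  expect_error(rater_profile("bad", 1.2, 0.5), "probability")
})

test_that("realized operating characteristics converge to the profile", {
  coh <- generate_cohort(50000, 50000, 11500, 11500, seed = 10) # prevalence 0.23
  m <- generate_rater_responses(coh, list(rater_profile("R1", 0.7, 0.8)),
                                seed = 11)
  r <- m$responses[, 1]
  expect_lt(abs(mean(r[coh$truth == 1] == 1) - 0.7), 0.01)
  expect_lt(abs(mean(r[coh$truth == 0] == 0) - 0.8), 0.01)
  ai <- generate_ai_predictions(coh, rater_profile("AI", 0.5, 0.5), seed = 12)
  expect_lt(abs(balanced_accuracy(ai, coh$truth) - 0.5), 0.01)
})

test_that("rater errors are conditionally independent given truth by default", {
  coh <- generate_cohort(50000, 50000, 23000, 23000, seed = 20)
  m <- generate_rater_responses(coh, list(rater_profile("R1", 0.7, 0.8),
                                          rater_profile("R2", 0.6, 0.75)),
                                seed = 21)
  e1 <- m$responses[, 1] != coh$truth
  e2 <- m$responses[, 2] != coh$truth
  for (t in 0:1) {
    sel <- coh$truth == t
    expect_lt(abs(cor(e1[sel], e2[sel])), 0.02)
  }
})

test_that("shared difficulty induces positive error correlation when enabled", {
  coh <- generate_cohort(20000, 20000, 9000, 9000, seed = 30)
  m <- generate_rater_responses(coh, list(rater_profile("R1", 0.7, 0.8),
                                          rater_profile("R2", 0.7, 0.8)),
                                seed = 31, difficulty_sd = 1.5)
  e1 <- m$responses[, 1] != coh$truth
  e2 <- m$responses[, 2] != coh$truth
  sel <- coh$truth == 1
  expect_gt(cor(e1[sel], e2[sel]), 0.05)
})

test_that("pool calibration hits targets and rejects unreachable ones", {
  coh <- generate_cohort(142, 148, 24, 42, seed = 1)
  perfect <- calibrate_pool(1.0, 5, coh, seed = 2)
  for (p in perfect) {
    expect_equal(p$sensitivity, 1)
    expect_equal(p$specificity, 1)
  }
  single <- calibrate_pool(0.71, 1, coh, seed = 3)
  expect_equal(length(single), 1)
  expect_lt(abs(attr(single, "achieved_mean_f1") - 0.71), 0.02)
  pool <- calibrate_pool(0.586, 25, coh, seed = 4)
  expect_equal(length(pool), 25)
  expect_lt(abs(attr(pool, "achieved_mean_f1") - 0.586), 0.02)
  expect_error(calibrate_pool(0.01, 5, coh, seed = 5), "unreachable")
})

test_that("response matrices round-trip through CSV and JSON config", {
  coh <- generate_cohort(15, 15, 4, 5, seed = 7)
  prof <- list(rater_profile("R01", 0.7, 0.8), rater_profile("R02", 0.65, 0.7))
  m <- set_ai_predictions(generate_rater_responses(coh, prof, seed = 8),
                          generate_ai_predictions(coh, rater_profile("AI", 0.8, 0.85),
                                                  seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses_csv(m, coh, path)
  back <- read_responses_csv(path)
  expect_equal(back$matrix$responses, m$responses)
  expect_equal(back$matrix$ai, m$ai)
  expect_equal(back$cohort$truth, coh$truth)
  expect_equal(as.character(back$cohort$arm), as.character(coh$arm))

  cfg_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_sw = 20, n_nse = 20, exposures_sw = 5,
                            exposures_nse = 6, seed = 11,
                            target_mean_f1 = 0.6, n_raters = 4,
                            ai_target_f1 = 0.75),
                       cfg_path, auto_unbox = TRUE)
  study <- generate_study(read_generator_config(cfg_path))
  expect_equal(nrow(study$cohort), 40)
  expect_equal(ncol(study$matrix$responses), 4)
  expect_false(is.null(study$matrix$ai))
})
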