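test_that("agreement stratification partitions cases with a strict threshold", {
  truth <- c(1, 0, 1, 0)
  qa <- c(1, 1, 0, 0)
  m_all <- toy_matrix(truth, list(A = qa, B = qa, C = qa), ai = qa)
  g <- stratify_agreement(m_all)
  expect_equal(g$ha_cases, m_all$case_id)
  expect_length(g$la_cases, 0)
  m_none <- toy_matrix(truth, list(A = qa, B = qa, C = qa), ai = 1 - qa)
  g2 <- stratify_agreement(m_none)
  expect_length(g2$ha_cases, 0)
  # strictness: agreement exactly at the threshold lands in LA
  m_tie <- toy_matrix(truth, list(A = qa, B = qa, C = qa, D = qa, E = 1 - qa),
                      ai = qa)
  g3 <- stratify_agreement(m_tie, threshold = 0.8)
  expect_length(g3$ha_cases, 0)
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    p <- small_panel()
    gp <- stratify_agreement(p$matrix, thr)
    expect_equal(length(gp$ha_cases) + length(gp$la_cases),
                 length(p$matrix$case_id))
    expect_length(intersect(gp$ha_cases, gp$la_cases), 0)
  }
})

test_that("synthetic panels show higher AI accuracy in the high-agreement group", {
  cohort <- generate_cohort(142, 148, 24, 42, seed = 51)
  pool <- calibrate_pool(0.586, 25, cohort, seed = 52)
  m <- generate_rater_responses(cohort, pool, seed = 53)
  ai <- generate_ai_predictions(cohort,
                                calibrate_pool(0.71, 1, cohort, seed = 54)[[1]],
                                seed = 55)
  m <- set_ai_predictions(m, ai)
  g <- stratify_agreement(m)
  expect_equal(length(g$ha_cases) + length(g$la_cases), 290)
  cmp <- compare_groups(g, cohort, m)
  acc <- cmp[cmp$variable == "ai_accuracy", ]
  expect_gt(acc$ha, acc$la)
})

test_that("group comparisons detect a planted age shift and reject degenerate input", {
  base_cohort <- generate_cohort(100, 100, 20, 30, seed = 60)
  # identical groups: zero effect, all p-values are 1
  m_id <- generate_rater_responses(base_cohort,
                                   list(rater_profile("R1", 0.7, 0.7),
                                        rater_profile("R2", 0.7, 0.7)),
                                   seed = 61)
  m_id <- set_ai_predictions(m_id, generate_ai_predictions(
    base_cohort, rater_profile("AI", 0.8, 0.8), seed = 62))
  half <- rep(c(TRUE, TRUE, FALSE, FALSE), 50)
  g_same <- structure(list(ha_cases = base_cohort$case_id[half],
                           la_cases = base_cohort$case_id[!half],
                           per_case_agreement = NULL, threshold = 0.7),
                      class = "agreement_groups")
  coh_same <- base_cohort
  coh_same$age <- rep(c(30L, 40L), 100)
  coh_same$pain <- rep(c(0L, 1L), 100)
  # by construction both groups contain the same age/pain composition
  cmp <- compare_groups(g_same, coh_same, m_id)
  expect_true(all(cmp$p_value[cmp$variable != "ai_accuracy"] > 0.05))

  # planted 3.4-year shift at group sizes 171/119, age sd ~ 12
  set.seed(63)
  detected <- 0
  for (rep in 1:30) {
    n <- 290
    coh <- toy_cohort(rbinom(n, 1, 0.23))
    is_ha <- c(rep(TRUE, 171), rep(FALSE, 119))
    coh$age <- as.integer(round(rnorm(n, ifelse(is_ha, 34.6, 31.2), 12)))
    g <- structure(list(ha_cases = coh$case_id[is_ha],
                        la_cases = coh$case_id[!is_ha],
                        per_case_agreement = NULL, threshold = 0.7),
                   class = "agreement_groups")
    mm <- toy_matrix(coh$truth, list(A = coh$truth, B = coh$truth),
                     ai = coh$truth)
    mm$case_id <- coh$case_id
    cmp <- compare_groups(g, coh, mm)
    detected <- detected + cmp$significant[cmp$variable == "age_mean"]
  }
  expect_gt(detected, 15)

  g_empty <- structure(list(ha_cases = base_cohort$case_id,
                            la_cases = character(0),
                            per_case_agreement = NULL, threshold = 0.7),
                       class = "agreement_groups")
  expect_error(compare_groups(g_empty, base_cohort, m_id), "nonempty")
})

test_that("switch accounting matches a hand-counted instance and edge cases", {
  truth <- c(1, 1, 0, 0, 1, 0)
  baseline <- c(1, 0, 1, 0, 0, 0)
  # consultations at cases 1-3; flips at 2 (to correct) and 3 (stays wrong?)
  final <- c(1, 1, 1, 0, 0, 0) # case 2 flips 0->1 (correct), case 3 unchanged
  consulted <- list("B", "B", "C", character(0), character(0), character(0))
  res <- protocol_result("A", final, consulted, "second_opinion")
  rep1 <- switch_analysis(baseline, res, truth)
  expect_equal(rep1$altered_fraction, 1 / 3)
  expect_equal(rep1$correct_switch_fraction, 1 / 3)
  expect_equal(rep1$incorrect_switch_fraction, 0)
  # two flips, one correct and one incorrect
  baseline2 <- c(1, 0, 0, 0, 0, 0) # case 3 was right, flips wrong
  rep2 <- switch_analysis(baseline2, res, truth)
  expect_equal(rep2$altered_fraction, 2 / 3)
  expect_equal(rep2$correct_switch_fraction, 1 / 3)
  expect_equal(rep2$incorrect_switch_fraction, 1 / 3)
  expect_lte(rep2$correct_switch_fraction + rep2$incorrect_switch_fraction,
             rep2$altered_fraction)
  # alternative denominator: cases initially called positive
  rep3 <- switch_analysis(baseline2, res, truth,
                          denominator = "predicted_exposure")
  expect_equal(rep3$altered_fraction, 2 / 1)
  # empty consulted set
  res0 <- protocol_result("A", baseline, rep(list(character(0)), 6),
                          "second_opinion")
  rep0 <- switch_analysis(baseline, res0, truth)
  expect_equal(rep0$altered_fraction, 0)
  # all-wrong baseline fully corrected
  resall <- protocol_result("A", truth, as.list(rep("B", 6)), "second_opinion")
  repall <- switch_analysis(1 - truth, resall, truth)
  expect_equal(repall$correct_switch_fraction, 1)
})

test_that("the AI-accuracy sweep is monotone and propagates protocol errors", {
  p <- small_panel()
  sw <- sensitivity_sweep(p$matrix, targets = c(0.6, 0.8, 1.0),
                          n_trials = 300, seed = 70)
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$mean_f1) > -0.005)) # non-decreasing within MC error
  expect_error(sensitivity_sweep(p$matrix, targets = c(0.4), n_trials = 10,
                                 seed = 1), "out of scope")
  single <- toy_matrix(c(1, 0), list(A = c(1, 0)))
  expect_error(sensitivity_sweep(single, targets = 1, n_trials = 2, seed = 1),
               "at least 2 raters")
})

test_that("the published per-participant table reproduces its printed aggregates", {
  fx <- table2_fixture()
  expect_equal(nrow(fx), 25)
  expect_false(is.unsorted(fx$student))
  agg <- reproduce_table2(fx)
  expect_equal(round(agg$baseline_mean, 3), 0.586)
  expect_equal(round(agg$second_opinion_mean, 3), 0.645)
  expect_equal(round(agg$majority_mean, 3), 0.608)
})
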