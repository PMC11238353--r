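# Programmatic fixtures shared across test files.

# A tiny cohort with a chosen truth vector (covariates filled arbitrarily).
toy_cohort <- function(truth) {
  n <- length(truth)
  structure(
    data.frame(case_id = sprintf("c%02d", seq_len(n)),
               truth = as.integer(truth),
               arm = factor(rep(c("SW", "NSE"), length.out = n),
                            levels = c("SW", "NSE")),
               age = rep(30L, n),
               pain = rep(0L, n),
               tooth_class = factor(rep("molar", n),
                                    levels = c("molar", "premolar", "incisor", "canine")),
               stringsAsFactors = FALSE),
    class = c("cohort", "data.frame"))
}

# A response matrix assembled directly from explicit columns.
toy_matrix <- function(truth, responses, ai = NULL) {
  resp <- do.call(cbind, responses)
  colnames(resp) <- names(responses)
  response_matrix(toy_cohort(truth), resp, ai = ai)
}

# A random small instance (for property/oracle tests).
random_tiny_matrix <- function(n_cases, n_raters) {
  truth <- rbinom(n_cases, 1, 0.5)
  resp <- matrix(rbinom(n_cases * n_raters, 1, 0.5), n_cases, n_raters)
  colnames(resp) <- sprintf("R%d", seq_len(n_raters))
  response_matrix(toy_cohort(truth), resp, ai = rbinom(n_cases, 1, 0.5))
}

# A heterogeneous synthetic panel for behavioural tests: moderate size so
# suites stay fast.
small_panel <- function(seed = 42, n_raters = 8, n_sw = 40, n_nse = 40,
                        exp_sw = 8, exp_nse = 12) {
  cohort <- generate_cohort(n_sw, n_nse, exp_sw, exp_nse, seed = seed)
  profiles <- lapply(seq_len(n_raters), function(k)
    rater_profile(sprintf("R%02d", k),
                  0.45 + 0.05 * k / n_raters + 0.3 * (k - 1) / (n_raters - 1),
                  0.55 + 0.3 * (n_raters - k) / (n_raters - 1)))
  m <- generate_rater_responses(cohort, profiles, seed = seed + 1)
  ai <- generate_ai_predictions(cohort, rater_profile("AI", 0.75, 0.8),
                                seed = seed + 2)
  list(cohort = cohort, matrix = set_ai_predictions(m, ai),
       profiles = profiles)
}
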