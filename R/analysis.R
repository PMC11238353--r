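# Downstream analyses: AI-accuracy sensitivity sweep, agreement
# stratification with group comparisons, decision-switch accounting, and
# reproduction of the published per-participant summary table.

#' Sweep the AI's balanced accuracy through the second-opinion protocol
#'
#' For each target balanced accuracy `b`, the AI prediction vector is
#' replaced by a synthetic classifier with sensitivity = specificity = `b`
#' drawn against truth (`b = 1` uses truth itself, the perfect classifier),
#' the second-opinion simulation is rerun, and the panel-mean macro-F1 is
#' summarised across raters with a t-based CI. All targets share the same
#' simulation seed (common random numbers), so the sweep isolates the effect
#' of AI accuracy.
#'
#' @param matrix A `response_matrix` (its `ai` field is ignored and
#'   replaced per target).
#' @param targets Balanced-accuracy targets in `[0.5, 1]`; include 1 for the
#'   perfect-AI ceiling.
#' @param n_trials Trials per rater per target.
#' @param seed Master seed.
#' @return data.frame with one row per target: `target`, `mean_f1`, `sd_f1`,
#'   `n_raters`, `ci_low`, `ci_high` (summary over per-rater mean F1).
#' @export
sensitivity_sweep <- function(matrix, targets, n_trials, seed) {
  if (any(targets < 0.5) || any(targets > 1))
    stop("targets must lie in [0.5, 1]; a worse-than-chance AI is out of scope",
         call. = FALSE)
  rows <- lapply(seq_along(targets), function(k) {
    b <- targets[k]
    ai_new <- if (b == 1) matrix$truth
              else .with_seed(.mix_seed(seed, 900000L + k),
                              .draw_responses(matrix$truth, b, b))
    m2 <- set_ai_predictions(matrix, ai_new)
    trials <- run_simulation(m2, "second_opinion", n_trials, seed)
    per <- vapply(split(trials$f1, trials$rater_id), mean, numeric(1))
    s <- summarize_trials(unname(per))
    data.frame(target = b, mean_f1 = s$mean_f1, sd_f1 = s$sd_f1,
               n_raters = s$n_trials, ci_low = s$ci_low, ci_high = s$ci_high)
  })
  do.call(rbind, rows)
}

#' Stratify cases by panel-AI agreement
#'
#' Per-case agreement is the fraction of raters whose response matches the
#' AI prediction. Cases with agreement strictly above `threshold` form the
#' high-agreement (HA) group; the rest are low-agreement (LA). The published
#' analysis used the "more than 70%" rule, hence the strict inequality.
#'
#' @param matrix A `response_matrix` with AI predictions.
#' @param threshold Agreement threshold (default 0.70).
#' @return An object of class `agreement_groups`: list with `ha_cases`,
#'   `la_cases` (disjoint, jointly exhaustive case-id sets),
#'   `per_case_agreement` (named fractions) and `threshold`.
#' @export
stratify_agreement <- function(matrix, threshold = 0.70) {
  .require_ai(matrix)
  agree <- rowMeans(matrix$responses == matrix$ai)
  names(agree) <- matrix$case_id
  structure(list(ha_cases = matrix$case_id[agree > threshold],
                 la_cases = matrix$case_id[agree <= threshold],
                 per_case_agreement = agree,
                 threshold = threshold),
            class = "agreement_groups")
}

#' @export
print.agreement_groups <- function(x, ...) {
  cat(sprintf("agreement groups at threshold %.2f: %d HA, %d LA cases\n",
              x$threshold, length(x$ha_cases), length(x$la_cases)))
  invisible(x)
}

.prop_row <- function(variable, x_ha, n_ha, x_la, n_la, alpha) {
  pt <- suppressWarnings(prop.test(c(x_ha, x_la), c(n_ha, n_la), correct = FALSE))
  data.frame(variable = variable, ha = x_ha / n_ha, la = x_la / n_la,
             ha_ci_low = NA_real_, ha_ci_high = NA_real_,
             la_ci_low = NA_real_, la_ci_high = NA_real_,
             p_value = pt$p.value, significant = pt$p.value < alpha,
             stringsAsFactors = FALSE)
}

#' Compare clinical covariates and AI accuracy across agreement groups
#'
#' Mean age is compared with a two-sample Student's t-test (equal
#' variances) with per-group t-based CIs; the preoperative-pain share, the
#' stepwise-excavation share and the AI's accuracy are compared with
#' two-proportion z-tests (chi-squared without continuity correction).
#'
#' @param groups An `agreement_groups` object.
#' @param cohort The `cohort` the matrix was generated from.
#' @param matrix The `response_matrix` (for AI accuracy per group).
#' @param alpha Significance level for the `significant` flag.
#' @return data.frame with one row per compared variable: group values,
#'   per-group CIs where applicable, p-value and significance flag.
#' @export
compare_groups <- function(groups, cohort, matrix, alpha = 0.05) {
  if (length(groups$ha_cases) == 0 || length(groups$la_cases) == 0)
    stop("both agreement groups must be nonempty", call. = FALSE)
  ha <- cohort[cohort$case_id %in% groups$ha_cases, ]
  la <- cohort[cohort$case_id %in% groups$la_cases, ]
  tt <- t.test(ha$age, la$age, var.equal = TRUE)
  ci_ha <- t.test(ha$age)$conf.int
  ci_la <- t.test(la$age)$conf.int
  age_row <- data.frame(variable = "age_mean",
                        ha = mean(ha$age), la = mean(la$age),
                        ha_ci_low = ci_ha[1], ha_ci_high = ci_ha[2],
                        la_ci_low = ci_la[1], la_ci_high = ci_la[2],
                        p_value = tt$p.value,
                        significant = tt$p.value < alpha,
                        stringsAsFactors = FALSE)
  ai_ok <- matrix$ai == matrix$truth
  in_ha <- matrix$case_id %in% groups$ha_cases
  rows <- rbind(
    age_row,
    .prop_row("pain_share", sum(ha$pain), nrow(ha), sum(la$pain), nrow(la), alpha),
    .prop_row("sw_share", sum(ha$arm == "SW"), nrow(ha),
              sum(la$arm == "SW"), nrow(la), alpha),
    .prop_row("ai_accuracy", sum(ai_ok[in_ha]), sum(in_ha),
              sum(ai_ok[!in_ha]), sum(!in_ha), alpha)
  )
  rownames(rows) <- NULL
  rows
}

#' Switch accounting for a second-opinion trial
#'
#' Among the consulted cases of one protocol trial, tallies how often the
#' final response differed from the primary's (`altered`), and how often
#' such alterations corrected an error (`correct`: final matches truth,
#' primary did not) or introduced one (`incorrect`: primary matched truth,
#' final does not). The denominator is selectable because the published
#' percentages do not pin it down: `"consulted"` (default) divides by the
#' number of consulted cases, `"predicted_exposure"` by the number of cases
#' the primary initially called positive.
#'
#' @param baseline Primary rater's original binary predictions.
#' @param result A `protocol_result` from the same matrix.
#' @param truth Binary ground-truth vector.
#' @param denominator `"consulted"` or `"predicted_exposure"`.
#' @return An object of class `switch_report`: list with
#'   `altered_fraction`, `correct_switch_fraction`,
#'   `incorrect_switch_fraction`, `denominator`, `n_consulted`, `n_altered`.
#'   Under the `"consulted"` denominator, correct + incorrect <= altered.
#' @export
switch_analysis <- function(baseline, result, truth,
                            denominator = c("consulted", "predicted_exposure")) {
  denominator <- match.arg(denominator)
  baseline <- .check_binary(baseline, "baseline")
  truth <- .check_binary(truth, "truth")
  final <- result$final_predictions
  consulted <- lengths(result$consulted) > 0
  den <- switch(denominator,
                consulted = sum(consulted),
                predicted_exposure = sum(baseline == 1L))
  altered <- consulted & final != baseline
  correct <- altered & final == truth & baseline != truth
  incorrect <- altered & baseline == truth & final != truth
  frac <- function(x) if (den > 0) sum(x) / den else 0
  structure(list(altered_fraction = frac(altered),
                 correct_switch_fraction = frac(correct),
                 incorrect_switch_fraction = frac(incorrect),
                 denominator = denominator,
                 n_consulted = sum(consulted),
                 n_altered = sum(altered)),
            class = "switch_report")
}

#' @export
print.switch_report <- function(x, ...) {
  cat(sprintf(paste0("switch report (%s denominator): altered %.1f%%, ",
                     "correct %.1f%%, incorrect %.1f%%\n"),
              x$denominator, 100 * x$altered_fraction,
              100 * x$correct_switch_fraction,
              100 * x$incorrect_switch_fraction))
  invisible(x)
}

#' Published per-participant F1 table
#'
#' Loads the packaged copy of the published per-participant summary: for
#' each of the 25 dental students, the unassisted macro-F1 (`student`), the
#' 1000-trial mean and SD under the AI-triggered second-opinion protocol,
#' and under three-reader majority voting. Rows are sorted by unassisted
#' performance, as printed.
#'
#' @return data.frame with columns `participant`, `student`,
#'   `second_opinion_mean`, `second_opinion_sd`, `majority_mean`,
#'   `majority_sd`.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_participant_f1.csv",
                      package = "secondopinion", mustWork = TRUE)
  fx <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(fx) == 25, !is.unsorted(fx$student))
  fx
}

#' Recompute the published aggregates from the per-participant table
#'
#' From a per-participant F1 table (by default the packaged copy of the
#' published one) computes the column means, the t-based 95% CI of the
#' unassisted-column mean, and the Pearson correlation between unassisted F1
#' and the second-opinion improvement.
#'
#' @param fixture data.frame shaped like [table2_fixture()].
#' @return List with `baseline_mean`, `second_opinion_mean`,
#'   `majority_mean`, `baseline_ci` (length-2 vector), `pearson_r`, `n`.
#' @export
reproduce_table2 <- function(fixture = table2_fixture()) {
  s <- summarize_trials(fixture$student)
  list(baseline_mean = mean(fixture$student),
       second_opinion_mean = mean(fixture$second_opinion_mean),
       majority_mean = mean(fixture$majority_mean),
       baseline_ci = c(s$ci_low, s$ci_high),
       pearson_r = pearson(fixture$student,
                           fixture$second_opinion_mean - fixture$student),
       n = nrow(fixture))
}
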