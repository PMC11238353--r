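# Independent correctness oracles for the protocol engine: closed-form
# expected response rates under the conditional-independence rater model,
# and exhaustive enumeration of the second-opinion draw on tiny instances.
# The conditional-independence assumption lives only on this side — the
# Monte-Carlo engine operates on recorded responses and never assumes it.

#' Analytic final-response rates for the second-opinion protocol
#'
#' Under the conditional-independence model, the probability that the
#' protocol's final response is 1 given each true class. With primary
#' sensitivity/specificity (sA, cA), AI (sM, cM) and pool-average second
#' reader (sB, cB):
#' \deqn{rate_{pos} = s_A s_M + [s_A(1-s_M) + (1-s_A)s_M]\, s_B}
#' \deqn{rate_{neg} = (1-c_A)(1-c_M) + [(1-c_A)c_M + c_A(1-c_M)](1-c_B)}
#' Because the second reader enters linearly, using the arithmetic pool mean
#' (sB, cB) is exactly equivalent to averaging the rates rater-by-rater over
#' a heterogeneous pool.
#'
#' @param sA,cA Primary rater sensitivity and specificity.
#' @param sM,cM AI sensitivity and specificity.
#' @param sB,cB Pool-average second-reader sensitivity and specificity.
#' @return An object of class `hybrid_rates`: list with `rate_pos` =
#'   P(final = 1 | truth = 1) and `rate_neg` = P(final = 1 | truth = 0).
#' @examples
#' expected_second_opinion_rates(0.6, 0.7, 0.8, 0.9, 0.65, 0.75)
#' @export
expected_second_opinion_rates <- function(sA, cA, sM, cM, sB, cB) {
  for (p in list(sA, cA, sM, cM, sB, cB)) .check_prob(p, "probability")
  structure(list(
    rate_pos = sA * sM + (sA * (1 - sM) + (1 - sA) * sM) * sB,
    rate_neg = (1 - cA) * (1 - cM) + ((1 - cA) * cM + cA * (1 - cM)) * (1 - cB)
  ), class = "hybrid_rates")
}

#' Analytic final-response rate for three-reader majority voting
#'
#' Probability that the majority of \{primary, two i.i.d. pool readers\}
#' votes 1, given the per-class vote-1 probabilities `a` (primary) and `b`
#' (pool): `a(1 - (1-b)^2) + (1-a) b^2`.
#'
#' @param a Primary rater's P(vote = 1 | class).
#' @param b Pool reader's P(vote = 1 | class).
#' @return Probability of a majority-1 final response.
#' @export
expected_majority_rate <- function(a, b) {
  .check_prob(a, "a"); .check_prob(b, "b")
  a * (1 - (1 - b)^2) + (1 - a) * b^2
}

#' Majority rate under an explicit heterogeneous pool
#'
#' Exact mixture version of [expected_majority_rate()]: the two additional
#' readers are a uniform unordered pair without replacement from the pool,
#' so pair products are averaged over all distinct pairs rather than squared
#' pool means.
#'
#' @param a Primary rater's P(vote = 1 | class).
#' @param b_pool Vector of pool readers' P(vote = 1 | class), length >= 2.
#' @return Probability of a majority-1 final response.
#' @export
expected_majority_rate_pool <- function(a, b_pool) {
  .check_prob(a, "a"); .check_prob(b_pool, "b_pool")
  if (length(b_pool) < 2)
    stop("majority voting needs at least 2 pool readers", call. = FALSE)
  pairs <- combn(b_pool, 2)
  both1 <- mean(pairs[1, ] * pairs[2, ])
  both0 <- mean((1 - pairs[1, ]) * (1 - pairs[2, ]))
  a * (1 - both0) + (1 - a) * both1
}

#' Plug-in macro-F1 from analytic rates
#'
#' Builds the expected confusion counts at prevalence `prevalence` —
#' E\[TP\] = n pi rate_pos, E\[FP\] = n(1-pi) rate_neg, E\[FN\] =
#' n pi (1-rate_pos), E\[TN\] = n(1-pi)(1-rate_neg) — and evaluates macro-F1
#' on them. This is the large-n limit of the mean Monte-Carlo macro-F1, not
#' the finite-n expectation (macro-F1 is a nonlinear function of the
#' counts).
#'
#' @param rates A `hybrid_rates` object (or list with `rate_pos`,
#'   `rate_neg`). For a single unaided rater use rate_pos = sensitivity,
#'   rate_neg = 1 - specificity.
#' @param prevalence Positive-class prevalence pi in (0, 1).
#' @param n Nominal case count (cancels out of macro-F1; kept for
#'   readability of the expected counts).
#' @return Plug-in macro-F1 in `[0, 1]`.
#' @export
plugin_macro_f1 <- function(rates, prevalence, n = 1) {
  .check_prob(rates$rate_pos, "rate_pos")
  .check_prob(rates$rate_neg, "rate_neg")
  if (prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must be strictly inside (0, 1)", call. = FALSE)
  .macro_f1_counts(tp = n * prevalence * rates$rate_pos,
                   fp = n * (1 - prevalence) * rates$rate_neg,
                   fn = n * prevalence * (1 - rates$rate_pos),
                   tn = n * (1 - prevalence) * (1 - rates$rate_neg))
}

#' Exhaustive enumeration of the second-opinion protocol
#'
#' Enumerates every assignment of second readers to the primary rater's
#' disagreement cases — (|D|-1)^k equiprobable outcomes for k disagreement
#' cases — and returns the exact outcome distribution and exact mean
#' macro-F1. Intended for tiny instances as an independent oracle for the
#' Monte-Carlo engine.
#'
#' @param matrix A small `response_matrix` with AI predictions.
#' @param primary Primary rater id.
#' @param max_outcomes Refuse instances with more than this many outcomes
#'   (default 1e6) and instruct Monte-Carlo use instead.
#' @return List with `mean_f1` (exact), `outcomes` (data.frame of
#'   `probability`, `f1`), `finals` (cases x outcomes matrix of final
#'   predictions), `p_final_one` (exact per-case P(final = 1)) and
#'   `n_disagreements`.
#' @export
enumerate_second_opinion <- function(matrix, primary, max_outcomes = 1e6) {
  .require_ai(matrix)
  D <- raters(matrix)
  if (length(D) < 2)
    stop("second-opinion protocol needs at least 2 raters", call. = FALSE)
  ri <- .primary_index(matrix, primary)
  qa <- matrix$responses[, ri]
  others <- seq_along(D)[-ri]
  m <- length(others)
  dis <- which(qa != matrix$ai)
  k <- length(dis)
  if (m^k > max_outcomes)
    stop(sprintf("instance too large to enumerate (%d^%d outcomes); use the Monte-Carlo engine",
                 m, k), call. = FALSE)
  n_out <- m^k
  grid <- if (k == 0) matrix(integer(0), nrow = 1, ncol = 0)
          else as.matrix(expand.grid(rep(list(seq_len(m)), k)))
  finals <- matrix(rep(qa, n_out), nrow = length(qa))
  f1s <- numeric(n_out)
  tr <- matrix$truth == 1L
  for (r in seq_len(n_out)) {
    final <- qa
    if (k > 0)
      final[dis] <- matrix$responses[cbind(dis, others[grid[r, ]])]
    finals[, r] <- final
    f1s[r] <- .macro_f1_counts(sum(final == 1L & tr), sum(final == 1L & !tr),
                               sum(final == 0L & tr), sum(final == 0L & !tr))
  }
  list(mean_f1 = mean(f1s),
       outcomes = data.frame(probability = rep(1 / n_out, n_out), f1 = f1s),
       finals = finals,
       p_final_one = rowMeans(finals == 1L),
       n_disagreements = k)
}
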