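# Decision protocols and the Monte-Carlo trial engine.
#
# The second-opinion protocol keeps the AI hidden: its prediction only
# decides WHETHER a second reader is consulted, never WHAT the final answer
# is. The final answer is always a human response — the primary rater's when
# it agrees with the AI, otherwise that of a second rater drawn uniformly
# from the rest of the panel, independently per case.

#' Protocol trial result
#'
#' @param primary_rater Primary rater id.
#' @param final_predictions Integer 0/1 vector over cases.
#' @param consulted List (one element per case) of the additional rater ids
#'   consulted for that case; `character(0)` when the primary's answer stood
#'   alone.
#' @param protocol Protocol label.
#' @param trial_index Trial number.
#' @return An object of class `protocol_result`.
#' @export
protocol_result <- function(primary_rater, final_predictions, consulted,
                            protocol, trial_index = 1L) {
  final_predictions <- .check_binary(final_predictions, "final_predictions")
  if (length(consulted) != length(final_predictions))
    stop("`consulted` must have one entry per case", call. = FALSE)
  structure(list(primary_rater = primary_rater,
                 trial_index = as.integer(trial_index),
                 final_predictions = final_predictions,
                 consulted = consulted,
                 protocol = protocol),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("%s trial %d (primary %s): %d cases, %d consultations\n",
              x$protocol, x$trial_index, x$primary_rater,
              length(x$final_predictions), sum(lengths(x$consulted) > 0)))
  invisible(x)
}

.require_ai <- function(matrix) {
  if (is.null(matrix$ai))
    stop("response matrix has no AI predictions; see set_ai_predictions()",
         call. = FALSE)
}

.primary_index <- function(matrix, primary) {
  D <- raters(matrix)
  i <- match(primary, D)
  if (is.na(i)) stop(sprintf("unknown primary rater '%s'", primary), call. = FALSE)
  i
}

#' One trial of the AI-triggered second-opinion protocol
#'
#' For each case the primary rater's answer is compared with the hidden AI
#' prediction. On agreement it is final; on disagreement a second rater is
#' drawn uniformly from the remaining panel (independently per case by
#' default) and that rater's recorded answer becomes final. The AI value is
#' never itself a final response.
#'
#' @param matrix A `response_matrix` with AI predictions.
#' @param primary Primary rater id (must be in the panel).
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @param fixed_b If `TRUE`, a single second rater is drawn once per trial
#'   and used for every disagreement case (study variant; default `FALSE`,
#'   i.e. an independent draw per case).
#' @return A `protocol_result`; `consulted` is empty exactly at cases where
#'   the primary agreed with the AI.
#' @export
second_opinion_trial <- function(matrix, primary, seed = NULL, fixed_b = FALSE) {
  .require_ai(matrix)
  D <- raters(matrix)
  if (length(D) < 2)
    stop("second-opinion protocol needs at least 2 raters", call. = FALSE)
  ri <- .primary_index(matrix, primary)
  qa <- matrix$responses[, ri]
  others <- D[-ri]
  dis <- which(qa != matrix$ai)
  final <- qa
  consulted <- rep(list(character(0)), length(qa))
  if (length(dis) > 0) {
    pick <- .with_seed(seed, {
      if (fixed_b) rep(sample.int(length(others), 1L), length(dis))
      else sample.int(length(others), length(dis), replace = TRUE)
    })
    b_ids <- others[pick]
    final[dis] <- matrix$responses[cbind(dis, match(b_ids, D))]
    consulted[dis] <- as.list(b_ids)
  }
  protocol_result(primary, final, consulted, "second_opinion")
}

#' One trial of the three-reader majority-vote protocol
#'
#' The primary rater's answer is always supplemented by two additional
#' readers drawn uniformly without replacement from the remaining panel,
#' independently per case; the final answer is the majority of the three
#' (no ties are possible).
#'
#' @inheritParams second_opinion_trial
#' @return A `protocol_result` with two consulted raters per case.
#' @export
majority_vote_trial <- function(matrix, primary, seed = NULL) {
  D <- raters(matrix)
  if (length(D) < 3)
    stop("majority-vote protocol needs at least 3 raters", call. = FALSE)
  ri <- .primary_index(matrix, primary)
  qa <- matrix$responses[, ri]
  others <- D[-ri]
  m <- length(others)
  n <- length(qa)
  draws <- .with_seed(seed, {
    i <- sample.int(m, n, replace = TRUE)
    j <- sample.int(m - 1L, n, replace = TRUE)
    list(i = i, j = j + (j >= i))
  })
  oi <- match(others, D)
  v1 <- matrix$responses[cbind(seq_len(n), oi[draws$i])]
  v2 <- matrix$responses[cbind(seq_len(n), oi[draws$j])]
  final <- as.integer(qa + v1 + v2 >= 2L)
  consulted <- lapply(seq_len(n), function(k) c(others[draws$i[k]], others[draws$j[k]]))
  protocol_result(primary, final, consulted, "majority_vote")
}

# Vectorised per-rater engine: returns n_trials macro-F1 values. Uses the
# current RNG stream (callers seed it).
.simulate_rater_f1 <- function(resp, truth, ai, ri, protocol, n_trials, fixed_b) {
  qa <- resp[, ri]
  others <- seq_len(ncol(resp))[-ri]
  m <- length(others)
  n <- length(qa)
  tr <- truth == 1L
  if (protocol == "second_opinion") {
    if (m < 1) stop("second-opinion protocol needs at least 2 raters", call. = FALSE)
    dis <- which(qa != ai)
    k <- length(dis)
    final <- matrix(rep(qa, n_trials), nrow = n)
    if (k > 0) {
      sub <- resp[dis, others, drop = FALSE]
      if (fixed_b) {
        b <- sample.int(m, n_trials, replace = TRUE)
        final[dis, ] <- sub[, b, drop = FALSE]
      } else {
        bm <- sample.int(m, k * n_trials, replace = TRUE)
        final[dis, ] <- sub[cbind(rep.int(seq_len(k), n_trials), bm)]
      }
    }
  } else {
    if (m < 2) stop("majority-vote protocol needs at least 3 raters", call. = FALSE)
    ro <- resp[, others, drop = FALSE]
    i <- sample.int(m, n * n_trials, replace = TRUE)
    j <- sample.int(m - 1L, n * n_trials, replace = TRUE)
    j <- j + (j >= i)
    rows <- rep.int(seq_len(n), n_trials)
    votes <- rep.int(qa, n_trials) + ro[cbind(rows, i)] + ro[cbind(rows, j)]
    final <- matrix(votes >= 2L, nrow = n)
  }
  .macro_f1_cols(final == 1L, tr)
}

#' Monte-Carlo simulation of a decision protocol over the whole panel
#'
#' Runs `n_trials` independent protocol trials with every rater (or a chosen
#' subset) as the primary reader and scores each trial's final predictions
#' against truth with macro-F1. Each (rater, protocol) combination uses an
#' independently derived RNG sub-stream from the master seed, so results for
#' a given rater are unchanged when raters are added to the run.
#'
#' @param matrix A `response_matrix` with AI predictions (AI is unused by
#'   the majority-vote protocol but the matrix is validated identically).
#' @param protocol `"second_opinion"` or `"majority_vote"`.
#' @param n_trials Number of trials per primary rater (>= 1).
#' @param seed Master integer seed.
#' @param primaries Rater ids to use as primary readers; default the whole
#'   panel.
#' @param cases Optional case subset (indices or case ids) to simulate over,
#'   e.g. to emulate per-rater reading loads; default all cases.
#' @param fixed_b Second-opinion variant with one second rater per trial
#'   (default `FALSE`).
#' @return A data.frame with columns `rater_id`, `trial`, `protocol`, `f1`.
#' @export
run_simulation <- function(matrix, protocol = c("second_opinion", "majority_vote"),
                           n_trials, seed, primaries = NULL, cases = NULL,
                           fixed_b = FALSE) {
  protocol <- match.arg(protocol)
  if (n_trials < 1) stop("`n_trials` must be at least 1", call. = FALSE)
  D <- raters(matrix)
  if (is.null(primaries)) primaries <- D
  idx <- if (is.null(cases)) seq_along(matrix$case_id)
         else if (is.character(cases)) match(cases, matrix$case_id)
         else as.integer(cases)
  if (anyNA(idx) || any(idx < 1) || any(idx > length(matrix$case_id)))
    stop("`cases` contains unknown cases", call. = FALSE)
  truth <- matrix$truth[idx]
  resp <- matrix$responses[idx, , drop = FALSE]
  if (protocol == "second_opinion") {
    .require_ai(matrix)
    ai <- matrix$ai[idx]
  } else ai <- NULL
  offset <- if (protocol == "second_opinion") 0L else 500000L
  out <- lapply(primaries, function(r) {
    ri <- .primary_index(matrix, r)
    f1 <- .with_seed(.mix_seed(seed, ri + offset),
                     .simulate_rater_f1(resp, truth, ai, ri, protocol,
                                        n_trials, fixed_b))
    data.frame(rater_id = r, trial = seq_len(n_trials), protocol = protocol,
               f1 = f1, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
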