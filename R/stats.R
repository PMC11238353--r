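# Inferential toolkit: trial summaries with t-based confidence intervals,
# pairwise paired t-tests with Bonferroni correction, Pearson correlation.

#' Summarise per-trial (or per-rater) scores
#'
#' Sample mean, sample standard deviation (n-1 denominator) and a t-based
#' confidence interval with n-1 degrees of freedom.
#'
#' @param x Numeric vector of scores (e.g. per-trial macro-F1).
#' @param level Confidence level (default 0.95).
#' @param rater_id,protocol Optional labels carried into the output row.
#' @return One-row data.frame with columns `rater_id`, `protocol`,
#'   `mean_f1`, `sd_f1`, `n_trials`, `ci_low`, `ci_high`.
#' @export
summarize_trials <- function(x, level = 0.95, rater_id = NA_character_,
                             protocol = NA_character_) {
  if (length(x) < 1) stop("need at least one value", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  n <- length(x)
  m <- mean(x)
  s <- if (n > 1) sd(x) else NA_real_
  half <- if (n > 1) qt((1 + level) / 2, df = n - 1) * s / sqrt(n) else NA_real_
  data.frame(rater_id = rater_id, protocol = protocol,
             mean_f1 = m, sd_f1 = s, n_trials = n,
             ci_low = m - half, ci_high = m + half,
             stringsAsFactors = FALSE)
}

#' Per-rater trial summaries
#'
#' Applies [summarize_trials()] to each (rater, protocol) group of a
#' simulation result.
#'
#' @param trials data.frame as returned by [run_simulation()].
#' @param level Confidence level.
#' @return data.frame with one summary row per rater and protocol, in the
#'   panel's original rater order.
#' @export
summarize_by_rater <- function(trials, level = 0.95) {
  groups <- split(trials, list(trials$rater_id, trials$protocol), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g)
    summarize_trials(g$f1, level, rater_id = g$rater_id[1],
                     protocol = g$protocol[1])))
  rownames(out) <- NULL
  out[order(match(out$rater_id, unique(trials$rater_id))), , drop = FALSE]
}

#' Pairwise paired t-tests with Bonferroni correction
#'
#' Two-sided paired t-tests between every pair of groups, pairing by index
#' (e.g. by participant). Adjusted p-values are `min(1, raw_p * m)` with `m`
#' the number of pairwise comparisons. A pair whose differences are all
#' exactly zero is degenerate and reported with p = 1; a nonzero constant
#' difference is reported with p = 0.
#'
#' @param samples Named list of >= 2 equal-length numeric vectors.
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05).
#' @return An object of class `comparison_report`: list with `pairs`
#'   (data.frame of `group_a`, `group_b`, `t_statistic`, `raw_p`,
#'   `adjusted_p`, `significant`), `correction` and `alpha`.
#' @export
paired_t_bonferroni <- function(samples, alpha = 0.05) {
  if (length(samples) < 2 || is.null(names(samples)) || any(names(samples) == ""))
    stop("`samples` must be a named list of at least 2 groups", call. = FALSE)
  lens <- lengths(samples)
  if (length(unique(lens)) != 1)
    stop("all groups must have the same length (pairing is by index)", call. = FALSE)
  idx <- combn(names(samples), 2)
  m <- ncol(idx)
  rows <- lapply(seq_len(m), function(k) {
    a <- samples[[idx[1, k]]]
    b <- samples[[idx[2, k]]]
    d <- a - b
    if (sd(d) == 0) {
      tstat <- if (all(d == 0)) 0 else sign(mean(d)) * Inf
      p <- if (all(d == 0)) 1 else 0
    } else {
      tt <- t.test(a, b, paired = TRUE)
      tstat <- unname(tt$statistic)
      p <- tt$p.value
    }
    data.frame(group_a = idx[1, k], group_b = idx[2, k],
               t_statistic = tstat, raw_p = p,
               adjusted_p = min(1, p * m),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs$significant <- pairs$adjusted_p < alpha
  structure(list(pairs = pairs, correction = "bonferroni", alpha = alpha),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("pairwise paired t-tests, %s correction (m = %d), alpha = %g\n",
              x$correction, nrow(x$pairs), x$alpha))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] that rejects constant inputs, for
#' which the coefficient is undefined.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("Pearson correlation is undefined for constant input", call. = FALSE)
  cor(x, y)
}
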