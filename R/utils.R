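# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. seed = NULL uses the current stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Counter-based derivation of independent sub-stream seeds from one master
# seed, so per-rater (or per-stage) streams do not perturb one another.
# Kept strictly below 2^31 - 1.
.mix_seed <- function(seed, counter) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(counter) * 16807) %% 2147483629)
}

# Division defined as 0 when the denominator is 0 (degenerate confusion
# cells); vectorised.
.sdiv <- function(num, den) ifelse(den > 0, num / den, 0)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.check_binary <- function(x, name) {
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop(sprintf("`%s` must contain only 0/1 values with no missing entries", name),
         call. = FALSE)
  invisible(as.integer(x))
}

.check_prob <- function(p, name) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  invisible(p)
}
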