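# CSV / JSON interchange for cohorts, response matrices and generator
# configuration.

#' Write a cohort and response matrix to one CSV
#'
#' Columns: `case_id`, `truth`, `arm`, `age`, `pain`, `tooth_class`, one
#' `rater_<id>` column per rater, and `ai` (if present). Binary columns hold
#' 0/1 values.
#'
#' @param matrix A `response_matrix`.
#' @param cohort The matching `cohort` (same cases, same order).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_responses_csv <- function(matrix, cohort, path) {
  if (!identical(as.character(cohort$case_id), matrix$case_id))
    stop("cohort and matrix must list the same cases in the same order",
         call. = FALSE)
  df <- data.frame(cohort, check.names = FALSE, stringsAsFactors = FALSE)
  resp <- as.data.frame(matrix$responses)
  names(resp) <- paste0("rater_", colnames(matrix$responses))
  df <- cbind(df, resp)
  if (!is.null(matrix$ai)) df$ai <- matrix$ai
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort and response matrix from CSV
#'
#' Inverse of [write_responses_csv()].
#'
#' @param path CSV file path.
#' @return List with elements `cohort` and `matrix`.
#' @export
read_responses_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("case_id", "truth", "arm", "age", "pain", "tooth_class")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  cohort <- structure(
    data.frame(case_id = as.character(df$case_id),
               truth = as.integer(df$truth),
               arm = factor(df$arm, levels = c("SW", "NSE")),
               age = as.integer(df$age),
               pain = as.integer(df$pain),
               tooth_class = factor(df$tooth_class),
               stringsAsFactors = FALSE),
    class = c("cohort", "data.frame"))
  rater_cols <- grep("^rater_", names(df), value = TRUE)
  if (length(rater_cols) == 0)
    stop("no rater_<id> columns found", call. = FALSE)
  resp <- as.matrix(df[rater_cols])
  colnames(resp) <- sub("^rater_", "", rater_cols)
  ai <- if ("ai" %in% names(df)) as.integer(df$ai) else NULL
  list(cohort = cohort, matrix = response_matrix(cohort, resp, ai = ai))
}

#' Read a generator configuration from JSON
#'
#' @param path JSON file path. Recognised fields: `n_sw`, `n_nse`,
#'   `exposures_sw`, `exposures_nse`, `seed`, `covariates` (optional),
#'   and either explicit `profiles` / `ai` (sensitivity/specificity records)
#'   or calibration targets `target_mean_f1` + `n_raters` /
#'   `ai_target_f1`.
#' @return Named list.
#' @export
read_generator_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Generate a full synthetic study from a configuration
#'
#' Builds a cohort, a rater panel (explicit profiles or a pool calibrated to
#' a target mean macro-F1), an AI classifier (explicit profile or calibrated
#' to a target F1), and assembles the response matrix. All stages draw from
#' sub-streams of `config$seed`.
#'
#' @param config List as returned by [read_generator_config()].
#' @return List with `cohort`, `matrix` (with AI predictions attached),
#'   `profiles` and `ai_profile`.
#' @export
generate_study <- function(config) {
  stopifnot(!is.null(config$seed))
  seed <- as.integer(config$seed)
  cohort <- generate_cohort(
    n_sw = config$n_sw %||% 142, n_nse = config$n_nse %||% 148,
    exposures_sw = config$exposures_sw %||% 24,
    exposures_nse = config$exposures_nse %||% 42,
    covariates = config$covariates %||% list(),
    seed = .mix_seed(seed, 1L))
  profiles <- if (!is.null(config[["profiles"]])) {
    pf <- config[["profiles"]]
    if (is.data.frame(pf)) pf <- split(pf, seq_len(nrow(pf)))
    lapply(seq_along(pf), function(k)
      rater_profile(pf[[k]][["rater_id"]] %||% sprintf("R%02d", k),
                    pf[[k]][["sensitivity"]], pf[[k]][["specificity"]]))
  } else {
    calibrate_pool(config[["target_mean_f1"]], config[["n_raters"]] %||% 25,
                   cohort, seed = .mix_seed(seed, 2L))
  }
  ai_profile <- if (!is.null(config[["ai"]])) {
    rater_profile("AI", config[["ai"]][["sensitivity"]],
                  config[["ai"]][["specificity"]])
  } else {
    calibrate_pool(config[["ai_target_f1"]], 1, cohort,
                   seed = .mix_seed(seed, 3L))[[1]]
  }
  m <- generate_rater_responses(cohort, profiles, seed = .mix_seed(seed, 4L),
                                difficulty_sd = config$difficulty_sd %||% 0)
  ai <- generate_ai_predictions(cohort, ai_profile, seed = .mix_seed(seed, 5L))
  list(cohort = cohort, matrix = set_ai_predictions(m, ai),
       profiles = profiles, ai_profile = ai_profile)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
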