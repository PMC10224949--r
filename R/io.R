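#' Write a cohort trial table to delimited text
#'
#' Tab-separated UTF-8 with a versioned comment header recording the schema
#' and any seed attribute, readable by [read_trials()].
#'
#' @param cohort Trial table (stacked participants).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(cohort, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# outlierlift trial table v1",
               paste0("# seed: ", attr(cohort, "seed") %||% NA)), con)
  utils::write.table(cohort, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.trial_cols <- c("participant", "condition", "trial", "block",
                 "object_height_cm", "object_mass_g", "response_cm")
.numeric_trial_cols <- c("trial", "block", "object_height_cm",
                         "object_mass_g", "response_cm",
                         "presented_mass_g", "response_time_s", "points")

#' Read a cohort trial table from delimited text
#'
#' Parses the tab-separated trial-table schema written by [write_trials()].
#' Required columns: `participant`, `condition`, `trial`, `block`,
#' `object_height_cm`, `object_mass_g`, `response_cm`; additional columns
#' (`presented_mass_g`, `response_time_s`, `points`, `is_outlier`) are kept
#' when present. Malformed numeric cells are reported with their file line
#' numbers.
#'
#' @param path Input file path.
#' @return Trial table data frame.
#' @export
read_trials <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           colClasses = "character", check.names = TRUE)
  missing <- setdiff(.trial_cols, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_header_lines <- length(readLines(path, n = 50L)[
    startsWith(readLines(path, n = 50L), "#")]) + 1L
  for (col in intersect(.numeric_trial_cols, names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]) & raw[[col]] != "NA")
    if (length(bad)) {
      stop(sprintf("malformed numeric value in column '%s' at file line %d: '%s'",
                   col, bad[1] + n_header_lines, raw[[col]][bad[1]]),
           call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  for (col in c("trial", "block")) raw[[col]] <- as.integer(raw[[col]])
  if (!is.null(raw$is_outlier)) raw$is_outlier <- as.logical(raw$is_outlier)
  raw
}

#' Run the full analysis pipeline on two simulated conditions
#'
#' Simulates a comparison-condition cohort and a reference cohort, applies
#' trial and participant exclusion, computes per-participant encoding
#' strengths, and runs the directional Bayes-factor test of the comparison
#' against the reference, with the half-normal scale derived from the
#' reference cohort's mean via [hn_scale()]. All randomness derives from
#' `seed`.
#'
#' @param reference,condition Condition names (see [condition_names()]).
#' @param reference_params,condition_params [behavior_params()] objects or
#'   samplers for the two cohorts.
#' @param n Participants per cohort (default 20).
#' @param direction Hypothesized direction of the condition relative to the
#'   reference.
#' @param seed Integer seed.
#' @param bootstrap_reps Resamples for the condition-mean SEMs.
#' @return List of class `pipeline_report`: per-cohort encoding tables,
#'   `summary` (means, bootstrapped SEMs, exclusion counts), and `bayes`
#'   (a `bayes_result`).
#' @export
#' @examples
#' rep <- run_pipeline("same_color", "small_family",
#'                     behavior_params(latent_ce = 89),
#'                     behavior_params(latent_ce = 44),
#'                     n = 8, direction = "decrease", seed = 7)
#' rep$bayes
run_pipeline <- function(reference, condition,
                         reference_params = behavior_params(),
                         condition_params = behavior_params(),
                         n = 20L, direction = c("decrease", "increase"),
                         seed = 1L, bootstrap_reps = 1000L) {
  direction <- match.arg(direction)
  seed <- as.integer(seed)
  local_rng(seed)
  seeds <- sample.int(.Machine$integer.max - 2L, 4L)
  ref_spec <- make_condition(reference)
  cond_spec <- make_condition(condition)
  ref_cohort <- simulate_cohort(ref_spec, reference_params, n, seed = seeds[1],
                                id_prefix = "R")
  cond_cohort <- simulate_cohort(cond_spec, condition_params, n, seed = seeds[2],
                                 id_prefix = "C")
  ref_enc <- cohort_encoding(ref_cohort, ref_spec)
  cond_enc <- cohort_encoding(cond_cohort, cond_spec)
  ref_mean <- mean(ref_enc$ce_percent)
  sigma <- hn_scale(ref_mean, direction)
  stats <- welch_summary(ref_enc$ce_percent, cond_enc$ce_percent)
  bf <- bayes_factor(stats, hypothesis_pair(sigma, direction))
  summary <- data.frame(
    cohort = c(reference, condition),
    role = c("reference", "condition"),
    n_retained = c(nrow(ref_enc), nrow(cond_enc)),
    n_excluded = c(length(attr(ref_enc, "excluded")),
                   length(attr(cond_enc, "excluded"))),
    mean_ce = c(ref_mean, mean(cond_enc$ce_percent)),
    sem_ce = c(bootstrap_sem(ref_enc$ce_percent, bootstrap_reps, seed = seeds[3]),
               bootstrap_sem(cond_enc$ce_percent, bootstrap_reps, seed = seeds[4]))
  )
  structure(list(reference = ref_enc, condition = cond_enc,
                 summary = summary, bayes = bf,
                 sigma = sigma, direction = direction, seed = seed),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Outlier-paradigm pipeline report\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("Half-normal scale %.2f (%s); ", x$sigma, x$direction))
  print(x$bayes)
  invisible(x)
}
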