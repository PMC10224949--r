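#' Scaled median absolute deviation
#'
#' MAD about the median, multiplied by the normal-consistency constant
#' 1.4826, the robust spread estimate behind the trial and participant
#' exclusion thresholds.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Scaled MAD (same units as `values`).
#' @export
#' @examples
#' scaled_mad(c(1, 2, 3, 4, 100))  # 1.4826
scaled_mad <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values", call. = FALSE)
  1.4826 * stats::median(abs(values - stats::median(values)))
}

#' Flag outlying trials within one participant's table
#'
#' For each family object, flags responses more than `threshold` (default 4)
#' scaled MADs from that participant-by-object cell's median response.
#' Outlier-object trials are never flagged, since learning can produce large
#' genuine jumps there. The criterion is applied in a single pass: medians
#' and MADs are not recomputed after removal. Cells with fewer than 3 trials
#' are exempt (the MAD is degenerate there) and reported in the output.
#'
#' @param table One participant's trial table (as from
#'   [simulate_participant()] or [read_trials()]).
#' @param threshold Exclusion threshold in scaled MADs (default 4).
#' @return List of class `trial_exclusions`: `flagged` (logical per row),
#'   `reason` (character per row, `NA` where unflagged), `n_flagged`,
#'   `fraction` (of family-object trials), `small_cells` (heights of exempt
#'   cells).
#' @export
exclude_trials <- function(table, threshold = 4) {
  stopifnot(length(unique(table$participant)) == 1L)
  is_out <- .outlier_rows(table)
  flagged <- logical(nrow(table))
  small <- numeric(0)
  for (h in unique(table$object_height_cm[!is_out])) {
    cell <- which(!is_out & table$object_height_cm == h)
    if (length(cell) < 3L) {
      small <- c(small, h)
      next
    }
    x <- table$response_cm[cell]
    s <- scaled_mad(x)
    flagged[cell] <- abs(x - stats::median(x)) > threshold * s
  }
  if (length(small)) {
    warning("cells with < 3 trials exempt from exclusion (heights: ",
            paste(small, collapse = ", "), ")", call. = FALSE)
  }
  structure(list(
    flagged = flagged,
    reason = ifelse(flagged, sprintf("> %g scaled MADs from cell median", threshold), NA),
    n_flagged = sum(flagged),
    fraction = sum(flagged) / max(sum(!is_out), 1L),
    small_cells = small
  ), class = "trial_exclusions")
}

# Identify outlier-object rows. Uses an is_outlier column when present,
# otherwise the 800 g nominal mass of the standard designs.
.outlier_rows <- function(table) {
  if (!is.null(table$is_outlier)) as.logical(table$is_outlier)
  else table$object_mass_g == 800
}

#' Flag low-effort participants within a condition cohort
#'
#' Computes each participant's mean family-object response over the blocks
#' from the outlier's introduction onward (the `participant_window` of
#' [analysis_windows()]; block 11 onward in the standard design) and flags
#' participants whose mean is more than `threshold` (default 5) scaled MADs
#' from the cohort median. Trials already flagged by [exclude_trials()] can
#' be removed beforehand by the caller; the rule itself is robust either way.
#'
#' @param cohort Stacked trial tables of >= 3 participants, one condition.
#' @param spec The cohort's `condition_spec` (for the block window). If
#'   `NULL`, blocks >= 11 are used.
#' @param threshold Exclusion threshold in scaled MADs (default 5).
#' @return List of class `participant_exclusions`: `means` (named per
#'   participant), `flagged` (named logical), `excluded` (ids).
#' @export
exclude_participants <- function(cohort, spec = NULL, threshold = 5) {
  ids <- unique(cohort$participant)
  if (length(ids) < 3L) stop("need at least 3 participants", call. = FALSE)
  from_block <- if (is.null(spec)) 11L else min(analysis_windows(spec)$participant_window)
  is_out <- .outlier_rows(cohort)
  keep <- !is_out & cohort$block >= from_block
  means <- tapply(cohort$response_cm[keep], cohort$participant[keep], mean)
  means <- means[ids]
  s <- scaled_mad(means)
  flagged <- abs(means - stats::median(means)) > threshold * s
  structure(list(
    means = means,
    flagged = flagged,
    excluded = names(flagged)[flagged]
  ), class = "participant_exclusions")
}

#' Family regression: spring length on object height
#'
#' Ordinary least squares of the family-object responses (cm) on object
#' height (cm) over the trials of the given block window, the per-participant
#' linear model of the learned size-weight mapping.
#'
#' @param table One participant's trial table, ideally after trial exclusion.
#' @param window Integer vector of block indices.
#' @param drop_flagged Optional logical vector from [exclude_trials()] marking
#'   rows to drop.
#' @return List with `slope` (cm/cm), `intercept` (cm), `r_squared`, `n`,
#'   and `predict(h)`.
#' @export
family_regression <- function(table, window, drop_flagged = NULL) {
  is_out <- .outlier_rows(table)
  keep <- !is_out & table$block %in% window
  if (!is.null(drop_flagged)) keep <- keep & !drop_flagged
  h <- table$object_height_cm[keep]
  y <- table$response_cm[keep]
  if (length(y) == 0L || length(unique(h)) < 2L) {
    stop("family regression degenerate: ", length(y), " usable trials over ",
         length(unique(h)), " heights in window", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, h), y)
  b <- unname(fit$coefficients)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = b[2], intercept = b[1],
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n = length(y),
       predict = function(hh) b[1] + b[2] * hh)
}

#' Strength of categorical encoding for one participant
#'
#' The central per-participant statistic of the paradigm. Over the
#' post-introduction analysis window, the outlier's mean response is compared
#' with the family regression's prediction at the outlier's height, and the
#' gap is normalized by the true separation between the outlier's equilibrium
#' length and its length were it a true family member:
#'
#' \deqn{CE = 100 \left(1 - \frac{\bar r_{out} - \hat r_{fam}(h_{out})}
#'   {L_{out} - \hat L_{fam}(h_{out})}\right)}
#'
#' 100% means the outlier response sits on the family regression line (pure
#' categorical encoding, no learning of the outlier); 0% means both the
#' family and the outlier were learned perfectly.
#'
#' @param table One participant's trial table.
#' @param spec The participant's `condition_spec`.
#' @param apply_trial_exclusion Run [exclude_trials()] first and drop flagged
#'   family trials (default TRUE).
#' @return One-row data.frame of class `encoding_result`: `participant`,
#'   `condition`, `slope`, `intercept`, `r_squared`,
#'   `outlier_mean_response`, `family_predicted`, `true_outlier_length`,
#'   `true_family_predicted`, `ce_percent`, `n_outlier_trials`.
#' @export
#' @examples
#' spec <- make_condition("same_color")
#' tab <- simulate_participant(spec, behavior_params(latent_ce = 90), seed = 3)
#' encoding_strength(tab, spec)
encoding_strength <- function(table, spec, apply_trial_exclusion = TRUE) {
  stopifnot(inherits(spec, "condition_spec"))
  win <- analysis_windows(spec)$post_window
  drop <- if (apply_trial_exclusion) exclude_trials(table)$flagged else NULL
  fit <- family_regression(table, win, drop_flagged = drop)
  is_out <- .outlier_rows(table)
  out_rows <- is_out & table$block %in% win
  if (sum(out_rows) < 1L) {
    stop("no outlier trials in the analysis window", call. = FALSE)
  }
  h_out <- spec$objects$height_cm[spec$objects$is_outlier]
  out_mean <- mean(table$response_cm[out_rows])
  fam_pred <- fit$predict(h_out)
  true_out <- equilibrium_length(spec$objects$mass_g[spec$objects$is_outlier])
  true_fam <- true_family_line(spec)$predict(h_out)
  denom <- true_out - true_fam
  if (abs(denom) < .Machine$double.eps) {
    stop("degenerate design: outlier not separated from the family", call. = FALSE)
  }
  res <- data.frame(
    participant = table$participant[1],
    condition = spec$name,
    slope = fit$slope, intercept = fit$intercept, r_squared = fit$r_squared,
    outlier_mean_response = out_mean,
    family_predicted = fam_pred,
    true_outlier_length = true_out,
    true_family_predicted = true_fam,
    ce_percent = 100 * (1 - (out_mean - fam_pred) / denom),
    n_outlier_trials = sum(out_rows)
  )
  class(res) <- c("encoding_result", "data.frame")
  res
}

#' Check the regression-equals-family-mean equivalence
#'
#' In the symmetric standard design — family heights balanced around the
#' outlier's height with equal per-object trial counts — the family
#' regression's prediction at the outlier's height equals the plain mean of
#' the family responses. This verifies that equivalence on a table; with
#' unbalanced counts or asymmetric heights the check is skipped.
#'
#' @param table One participant's trial table.
#' @param spec The `condition_spec`.
#' @param tol Equality tolerance in cm (default 1e-9).
#' @return List: `applicable` (symmetric balanced design?), `holds`,
#'   `difference` (cm).
#' @export
family_mean_equivalence <- function(table, spec, tol = 1e-9) {
  win <- analysis_windows(spec)$post_window
  is_out <- .outlier_rows(table)
  keep <- !is_out & table$block %in% win
  h <- table$object_height_cm[keep]
  h_out <- spec$objects$height_cm[spec$objects$is_outlier]
  counts <- table(h)
  symmetric <- length(unique(counts)) == 1L &&
    isTRUE(all.equal(mean(unique(h)), h_out)) &&
    isTRUE(all.equal(sum(unique(h) - h_out), 0))
  if (!symmetric) {
    return(list(applicable = FALSE, holds = NA, difference = NA_real_))
  }
  fit <- family_regression(table, win)
  d <- fit$predict(h_out) - mean(table$response_cm[keep])
  list(applicable = TRUE, holds = abs(d) < tol, difference = d)
}

#' Family-regression slope before and after the outlier's introduction
#'
#' Fits the family regression over the pre-introduction window (blocks 6-10
#' in the standard design) and the post-introduction window (blocks 12-22)
#' and returns the slope change, the signature of the outlier "pulling up"
#' the category representation.
#'
#' @param table One participant's trial table.
#' @param spec The `condition_spec`.
#' @param apply_trial_exclusion Drop trials flagged by [exclude_trials()].
#' @return List with `pre` and `post` regression fits and
#'   `delta = post$slope - pre$slope`.
#' @export
slope_shift <- function(table, spec, apply_trial_exclusion = TRUE) {
  win <- analysis_windows(spec)
  drop <- if (apply_trial_exclusion) exclude_trials(table)$flagged else NULL
  pre <- family_regression(table, win$pre_window, drop_flagged = drop)
  post <- family_regression(table, win$post_window, drop_flagged = drop)
  list(pre = pre, post = post, delta = post$slope - pre$slope)
}

#' Bootstrapped standard error of the mean
#'
#' Standard deviation of resampled means: `reps` bootstrap resamples of
#' `values` with replacement.
#'
#' @param values Numeric vector (>= 2 values).
#' @param reps Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return Bootstrap SEM estimate.
#' @export
bootstrap_sem <- function(values, reps = 1000L, seed = 1L) {
  stopifnot(length(values) >= 2L, reps >= 100L)
  local_rng(as.integer(seed))
  n <- length(values)
  means <- vapply(seq_len(reps),
                  function(i) mean(values[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  stats::sd(means)
}

#' Per-participant encoding results for a whole cohort
#'
#' Applies trial exclusion, participant exclusion, and the encoding metric to
#' a stacked cohort table, returning one `encoding_result` row per retained
#' participant.
#'
#' @param cohort Stacked trial tables for one condition.
#' @param spec The `condition_spec`.
#' @param exclude Apply the participant-exclusion rule (default TRUE; needs
#'   >= 3 participants).
#' @return Data frame of encoding results; attribute `excluded` lists dropped
#'   participant ids.
#' @export
cohort_encoding <- function(cohort, spec, exclude = TRUE) {
  ids <- unique(cohort$participant)
  dropped <- character(0)
  if (exclude && length(ids) >= 3L) {
    pex <- exclude_participants(cohort, spec)
    dropped <- pex$excluded
    ids <- setdiff(ids, dropped)
  }
  res <- do.call(rbind, lapply(ids, function(id) {
    encoding_strength(cohort[cohort$participant == id, , drop = FALSE], spec)
  }))
  rownames(res) <- NULL
  attr(res, "excluded") <- dropped
  res
}
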