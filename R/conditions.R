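#' Names of the twelve task conditions
#'
#' Lower-snake-case identifiers for the twelve conditions of the outlier
#' paradigm. The three color conditions (`same_color`, `similar_colors`,
#' `distinct_colors`) serve as reference conditions; the remainder each
#' manipulate a single factor relative to one of them.
#'
#' @return Character vector of the twelve condition identifiers.
#' @export
#' @examples
#' condition_names()
condition_names <- function() {
  c("same_color", "similar_colors", "distinct_colors",
    "small_family", "frequent_outlier", "nonlinear", "concurrent",
    "added_noise", "speeded_response", "one_by_one",
    "nonlinear_plus", "concurrent_plus")
}

# Heights (cm) and masses (g) per condition. Family density is constant
# (100 g/cm of height) except in the sigmoidal-family conditions. The outlier
# is always the middle-height object at 800 g.
.object_sets <- function(name) {
  std_h <- c(5, 6, 7, 8, 9)
  lin_m <- c(300, 400, 800, 600, 700)
  sig_m <- c(300, 320, 800, 680, 700)
  switch(name,
    small_family = list(height = c(6, 7, 8), mass = c(400, 800, 600)),
    nonlinear = ,
    nonlinear_plus = list(height = std_h, mass = sig_m),
    list(height = std_h, mass = lin_m)
  )
}

#' Construct the specification for one task condition
#'
#' Builds the full design of a condition: its object set (heights, masses,
#' outlier identity), trial count, the trial at which the outlier may first
#' appear, the number of outlier presentations per post-introduction block,
#' the half-width of the uniform mass perturbation, and the speeded and
#' persistent-display flags. Color manipulations are recorded as a metadata
#' tag only; they have no numeric effect on the simulated task.
#'
#' All conditions run 100 trials except `frequent_outlier` (103). The outlier
#' is withheld for the first 40 trials except in the concurrent conditions,
#' where all objects are interleaved from the start.
#'
#' @param name One of [condition_names()].
#' @return An object of class `condition_spec`: a list with elements
#'   `name`, `objects` (data.frame: `height_cm`, `radius_cm`, `mass_g`,
#'   `is_outlier`), `n_trials`, `outlier_intro_trial`, `outlier_per_block`,
#'   `mass_noise_halfwidth`, `speeded`, `persistent_display`, `color_scheme`,
#'   and `blocks` (per-block object counts; see [block_structure()]).
#' @export
#' @examples
#' spec <- make_condition("same_color")
#' spec$objects
make_condition <- function(name) {
  if (length(name) != 1L || !is.character(name) || !(name %in% condition_names())) {
    stop("unknown condition ", deparse(name), "; valid identifiers are: ",
         paste(condition_names(), collapse = ", "), call. = FALSE)
  }
  objs <- .object_sets(name)
  objects <- data.frame(
    height_cm = objs$height,
    radius_cm = 3.5,
    mass_g = objs$mass,
    is_outlier = objs$mass == 800
  )
  stopifnot(sum(objects$is_outlier) == 1L)
  concurrent <- name %in% c("concurrent", "concurrent_plus")
  spec <- structure(list(
    name = name,
    objects = objects,
    n_trials = if (name == "frequent_outlier") 103L else 100L,
    outlier_intro_trial = if (concurrent) 1L else 41L,
    outlier_per_block = if (name == "frequent_outlier") 3L else 1L,
    mass_noise_halfwidth = if (name == "added_noise") 150 else 0,
    speeded = name == "speeded_response",
    persistent_display = name != "one_by_one",
    color_scheme = switch(name,
      similar_colors = "similar",
      distinct_colors = ,
      added_noise = ,
      speeded_response = ,
      one_by_one = ,
      nonlinear_plus = ,
      concurrent_plus = "distinct",
      "same")
  ), class = "condition_spec")
  spec$blocks <- block_structure(spec)
  spec
}

#' Per-block composition of a condition's schedule
#'
#' Returns, for each block, how many trials of each object it contains.
#' Pre-introduction blocks contain one trial per family object; once the
#' outlier is introduced each block additionally contains it
#' `outlier_per_block` times. The structures are:
#'
#' * standard five-object conditions: 10 family blocks of 4, then 12 full
#'   blocks of 5 (total 100);
#' * `small_family`: 20 family blocks of 2, then 20 full blocks of 3
#'   (total 100);
#' * `frequent_outlier`: 10 family blocks of 4, then 9 blocks of 7
#'   (4 family + 3 outlier; total 103);
#' * concurrent conditions: 20 full blocks of 5 (total 100).
#'
#' @param spec A `condition_spec`.
#' @return Data frame with columns `block`, `n_family` (trials per family
#'   object, always 1), `n_outlier`, `first_trial`, `last_trial`.
#' @export
block_structure <- function(spec) {
  stopifnot(inherits(spec, "condition_spec"))
  n_family <- sum(!spec$objects$is_outlier)
  pre_trials <- spec$outlier_intro_trial - 1L
  stopifnot(pre_trials %% n_family == 0L)
  n_pre <- pre_trials %/% n_family
  post_block_size <- n_family + spec$outlier_per_block
  post_trials <- spec$n_trials - pre_trials
  stopifnot(post_trials %% post_block_size == 0L)
  n_post <- post_trials %/% post_block_size
  blocks <- data.frame(
    block = seq_len(n_pre + n_post),
    n_family = 1L,
    n_outlier = rep(c(0L, spec$outlier_per_block), c(n_pre, n_post))
  )
  sizes <- n_family + blocks$n_outlier
  blocks$last_trial <- cumsum(sizes)
  blocks$first_trial <- blocks$last_trial - sizes + 1L
  blocks
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("Condition:", x$name, "\n")
  cat(sprintf("  %d objects (%d family + outlier %dg at %g cm), %d trials in %d blocks\n",
              nrow(x$objects), sum(!x$objects$is_outlier),
              x$objects$mass_g[x$objects$is_outlier],
              x$objects$height_cm[x$objects$is_outlier],
              x$n_trials, nrow(x$blocks)))
  cat(sprintf("  outlier from trial %d (%d per block); mass noise +/-%g g; speeded: %s\n",
              x$outlier_intro_trial, x$outlier_per_block,
              x$mass_noise_halfwidth, x$speeded))
  invisible(x)
}

#' Generate a randomized trial schedule for a condition
#'
#' Randomizes object order within each block subject to the boundary
#' constraint that the last object of block *t* is never the first object of
#' block *t* + 1, so no object is presented on consecutive trials. In the
#' `frequent_outlier` condition the outlier appears three times per
#' post-introduction block and may repeat consecutively; family objects still
#' may not. Randomization is rejection sampling of within-block permutations.
#'
#' @param spec A `condition_spec` from [make_condition()].
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return Data frame of class `trial_schedule` with columns `trial`, `block`,
#'   `object` (row index into `spec$objects`), `object_height_cm`,
#'   `object_mass_g`, `is_outlier`, plus attributes `condition` and `seed`.
#' @export
#' @examples
#' sched <- generate_schedule(make_condition("same_color"), seed = 1)
#' head(sched)
generate_schedule <- function(spec, seed) {
  stopifnot(inherits(spec, "condition_spec"))
  seed <- as.integer(seed)
  family_idx <- which(!spec$objects$is_outlier)
  outlier_idx <- which(spec$objects$is_outlier)
  if (length(family_idx) < 2L) {
    stop("schedule constraints unsatisfiable: need at least two family objects",
         call. = FALSE)
  }
  allow_outlier_repeat <- spec$name == "frequent_outlier"
  rng <- local_rng(seed)
  order_all <- integer(0)
  prev_last <- NA_integer_
  for (b in seq_len(nrow(spec$blocks))) {
    pool <- c(family_idx, rep(outlier_idx, spec$blocks$n_outlier[b]))
    repeat {
      perm <- sample(pool)
      ok <- (is.na(prev_last) || perm[1L] != prev_last)
      if (ok && length(perm) > 1L) {
        rep_pair <- perm[-length(perm)] == perm[-1L]
        if (any(rep_pair)) {
          ok <- allow_outlier_repeat && all(perm[which(rep_pair)] == outlier_idx)
        }
      }
      if (ok) break
    }
    order_all <- c(order_all, perm)
    prev_last <- perm[length(perm)]
  }
  sched <- data.frame(
    trial = seq_along(order_all),
    block = rep(spec$blocks$block, spec$blocks$last_trial - spec$blocks$first_trial + 1L),
    object = order_all,
    object_height_cm = spec$objects$height_cm[order_all],
    object_mass_g = spec$objects$mass_g[order_all],
    is_outlier = spec$objects$is_outlier[order_all]
  )
  class(sched) <- c("trial_schedule", "data.frame")
  attr(sched, "condition") <- spec$name
  attr(sched, "seed") <- seed
  sched
}

# Run sampling under a private RNG state, restoring the caller's stream.
local_rng <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  parent <- parent.frame()
  defer_expr <- if (has) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(defer_expr, add = TRUE), envir = parent)
  invisible(seed)
}

#' Block and trial windows used by the categorical-encoding analyses
#'
#' Defines, for a condition, the three analysis windows:
#'
#' * `post_window`: blocks used for the family regression and the outlier
#'   mean — all blocks after the first outlier-containing block (standard
#'   conditions: blocks 12 to the end; concurrent conditions: blocks 11
#'   onward, i.e. after the tenth block);
#' * `pre_window`: the family-only blocks spanning trials 21-40 (the second
#'   half of pre-training; five blocks of four in the standard design), used
#'   by the pre-introduction regression of [slope_shift()];
#' * `participant_window`: blocks from the first outlier block onward
#'   (concurrent: block 11 onward), over which each participant's mean
#'   family response is computed for the participant-exclusion rule.
#'
#' @param spec A `condition_spec`.
#' @return List with integer-vector elements `pre_window`, `post_window`,
#'   and `participant_window` (block indices).
#' @export
#' @examples
#' analysis_windows(make_condition("same_color"))
analysis_windows <- function(spec) {
  stopifnot(inherits(spec, "condition_spec"))
  blocks <- spec$blocks
  n_blocks <- nrow(blocks)
  if (spec$outlier_intro_trial == 1L) {
    # outlier present throughout: measurement window is after the tenth block
    first_out_block <- 10L
  } else {
    first_out_block <- blocks$block[match(TRUE, blocks$n_outlier > 0L)]
  }
  post <- seq.int(first_out_block + 1L, n_blocks)
  # pre-introduction blocks covering trials 21-40 (second half of family
  # pre-training); concurrent conditions have no family-only phase, so the
  # corresponding interleaved blocks 6-10 stand in
  if (spec$outlier_intro_trial == 1L) {
    pre <- 6:10
  } else {
    pre_trials <- blocks$last_trial[first_out_block - 1L]
    pre <- which(blocks$last_trial <= pre_trials &
                 blocks$last_trial > pre_trials - 20L)
  }
  list(
    pre_window = pre,
    post_window = post,
    participant_window = seq.int(max(first_out_block, 11L), n_blocks)
  )
}
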