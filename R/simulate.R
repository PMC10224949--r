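#' Behavioral parameters of a synthetic participant
#'
#' Parameters of the package's generative model of a participant in the
#' outlier paradigm. The model is deliberately minimal plumbing for testing
#' the analysis pipeline: each participant carries an internal linear
#' size-to-spring-length mapping (the category representation) that is
#' acquired exponentially over family encounters, plus a latent
#' categorical-encoding strength that mixes the outlier response between the
#' category prediction and the outlier's true equilibrium length.
#'
#' @param latent_ce Latent strength of categorical encoding, percent in
#'   \[0, 100\]. 100: the outlier response sits on the participant's family
#'   line; 0: the outlier is learned perfectly.
#' @param motor_noise_sd Additive Gaussian motor noise on every spring-length
#'   response (cm).
#' @param learning_rate Per-encounter fraction by which the internal mapping's
#'   error decays during family acquisition, in \[0, 1\]. 1 means one
#'   encounter per object suffices.
#' @param category_update_gain Gain of the delta-rule update with which each
#'   outlier feedback error pulls the internal family line up and steepens
#'   it (per cm of error per encounter; 0 disables the pull).
#' @param rt_log_mean,rt_log_sd Log-scale parameters of the log-normal
#'   response-time distribution (s); defaults give a median near 2.3 s.
#' @return List of class `behavior_params`.
#' @export
behavior_params <- function(latent_ce = 89, motor_noise_sd = 0.4,
                            learning_rate = 0.5, category_update_gain = 0.0005,
                            rt_log_mean = log(2.33), rt_log_sd = 0.25) {
  stopifnot(latent_ce >= 0, latent_ce <= 100, motor_noise_sd >= 0,
            learning_rate >= 0, learning_rate <= 1,
            category_update_gain >= 0, rt_log_sd >= 0)
  structure(list(latent_ce = latent_ce, motor_noise_sd = motor_noise_sd,
                 learning_rate = learning_rate,
                 category_update_gain = category_update_gain,
                 rt_log_mean = rt_log_mean, rt_log_sd = rt_log_sd),
            class = "behavior_params")
}

#' True family line of a condition
#'
#' Ordinary least squares of the family objects' equilibrium spring lengths
#' on their heights: the size-to-length mapping a perfect learner of the
#' family would hold. For the linear (constant-density) families the fit is
#' exact; for the sigmoidal family it is the best linear summary.
#'
#' @param spec A `condition_spec`.
#' @param params A [physics_params()] object.
#' @return List with `intercept` (cm), `slope` (cm per cm of height), and
#'   `predict(h)`.
#' @export
true_family_line <- function(spec, params = physics_params()) {
  fam <- spec$objects[!spec$objects$is_outlier, ]
  eq <- equilibrium_length(fam$mass_g, params)
  fit <- stats::lm.fit(cbind(1, fam$height_cm), eq)
  b <- unname(fit$coefficients)
  list(intercept = b[1], slope = b[2],
       predict = function(h) b[1] + b[2] * h)
}

#' Simulate one synthetic participant
#'
#' Generates a full trial table for one participant under the generative
#' model described in [behavior_params()]. The internal family line starts
#' flat at the equilibrium length of the mean family mass and its error
#' (relative to the true family line) decays by `learning_rate` at each
#' family encounter. Responses:
#'
#' * family object at height h: the internal (category) line at h, including
#'   any outlier-driven drift, plus motor noise;
#' * outlier: the category prediction at the outlier's height plus
#'   `1 - latent_ce/100` times the true family-outlier separation, plus motor
#'   noise — at 100% latent strength the response sits on the category line,
#'   at 0% it reaches the outlier's true equilibrium length (exactly so once
#'   acquisition is complete and the update gain is zero). Each outlier
#'   encounter then updates the category line by a delta rule on the raw
#'   regressors (1, h): intercept `+ gain * err`, slope `+ gain * err * h`,
#'   with `err` the feedback error at the outlier — so repeated outlier
#'   errors pull the line up and, as observed empirically, steepen it.
#'
#' In the added-noise condition the presented mass is perturbed before
#' feedback is computed; responses are unaffected (anticipation precedes the
#' perturbed outcome). Response times are log-normal, and in the speeded
#' condition are resampled truncated below the time limit for all but a
#' handful of trials to mimic compliant participants.
#'
#' @param spec A `condition_spec`.
#' @param params A [behavior_params()] object.
#' @param seed Integer seed.
#' @param id Participant identifier string.
#' @return Data frame with one row per trial: `participant`, `condition`,
#'   `trial`, `block`, `object_height_cm`, `object_mass_g` (nominal),
#'   `is_outlier`, `presented_mass_g` (post-perturbation), `response_cm`,
#'   `response_time_s`, `points`.
#' @export
#' @examples
#' tab <- simulate_participant(make_condition("same_color"),
#'                             behavior_params(latent_ce = 95), seed = 1)
#' head(tab)
simulate_participant <- function(spec, params = behavior_params(), seed,
                                 id = "P01") {
  stopifnot(inherits(spec, "condition_spec"), inherits(params, "behavior_params"))
  seed <- as.integer(seed)
  local_rng(seed)
  sched <- generate_schedule(spec, seed = sample.int(.Machine$integer.max, 1L))
  n <- nrow(sched)
  tl <- true_family_line(spec)
  h_out <- spec$objects$height_cm[spec$objects$is_outlier]
  out_true <- equilibrium_length(spec$objects$mass_g[spec$objects$is_outlier])
  fam_h <- spec$objects$height_cm[!spec$objects$is_outlier]

  # internal line = true line + decay * (initial - true); initial is flat at
  # the mean-family-mass equilibrium, so the error is a pure slope error that
  # vanishes at the mean family height
  init_int <- equilibrium_length(mean(spec$objects$mass_g[!spec$objects$is_outlier]))
  err_int0 <- init_int - tl$intercept
  err_slope0 <- -tl$slope

  decay <- 1            # remaining fraction of the initial mapping error
  drift_a <- 0          # outlier-driven intercept shift (cm)
  drift_b <- 0          # outlier-driven slope shift (cm/cm)
  true_sep <- out_true - tl$predict(h_out)

  response <- numeric(n)
  noise <- stats::rnorm(n, 0, params$motor_noise_sd)
  rt <- stats::rlnorm(n, params$rt_log_mean, params$rt_log_sd)
  if (spec$speeded) {
    over <- which(rt > 2.25)
    keep <- utils::head(over, 2L)   # median participant times out twice
    fix <- setdiff(over, keep)
    if (length(fix)) rt[fix] <- stats::runif(length(fix), 1.0, 2.2)
  }
  presented <- sched$object_mass_g
  if (spec$mass_noise_halfwidth > 0) {
    presented <- presented +
      stats::runif(n, -spec$mass_noise_halfwidth, spec$mass_noise_halfwidth)
  }

  for (i in seq_len(n)) {
    h <- sched$object_height_cm[i]
    internal <- function(hh) {
      tl$intercept + tl$slope * hh + decay * (err_int0 + err_slope0 * hh) +
        drift_a + drift_b * hh
    }
    if (sched$is_outlier[i]) {
      pred <- internal(h_out)
      response[i] <- pred + (1 - params$latent_ce / 100) * true_sep
      err_fb <- equilibrium_length(presented[i]) - pred
      drift_a <- drift_a + params$category_update_gain * err_fb
      drift_b <- drift_b + params$category_update_gain * err_fb * h_out
    } else {
      # respond from the current mapping; learning updates it afterwards,
      # one decay step per family encounter
      response[i] <- internal(h)
      decay <- decay * (1 - params$learning_rate)
    }
  }
  response <- pmax(response + noise, 0)
  err <- response - equilibrium_length(presented)
  data.frame(
    participant = id,
    condition = spec$name,
    trial = sched$trial,
    block = sched$block,
    object_height_cm = sched$object_height_cm,
    object_mass_g = sched$object_mass_g,
    is_outlier = sched$is_outlier,
    presented_mass_g = presented,
    response_cm = response,
    response_time_s = rt,
    points = score_points(err)
  )
}

#' Simulate a cohort of synthetic participants
#'
#' Draws `n` independent participants for one condition. Participant-level
#' behavioral parameters come from `params_sampler`, a function of the
#' participant index returning a [behavior_params()] object (a fixed
#' `behavior_params` object is accepted and used for everyone).
#'
#' @param spec A `condition_spec`.
#' @param params_sampler A `behavior_params` object, or
#'   `function(i) behavior_params(...)`. The sampler is called under the
#'   cohort's seeded RNG stream, so random samplers are reproducible.
#' @param n Number of participants (>= 1).
#' @param seed Integer seed for the whole cohort.
#' @param id_prefix Prefix for participant identifiers.
#' @return Data frame of all participants' trial tables stacked; attribute
#'   `latent_ce` holds the per-participant latent values.
#' @export
#' @examples
#' coh <- simulate_cohort(make_condition("distinct_colors"),
#'                        behavior_params(latent_ce = 60), n = 4, seed = 2)
#' table(coh$participant)
simulate_cohort <- function(spec, params_sampler, n, seed,
                            id_prefix = "P") {
  stopifnot(n >= 1)
  seed <- as.integer(seed)
  local_rng(seed)
  if (inherits(params_sampler, "behavior_params")) {
    fixed <- params_sampler
    params_sampler <- function(i) fixed
  }
  ids <- sprintf("%s%02d", id_prefix, seq_len(n))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- vector("list", n)
  latent <- numeric(n)
  for (i in seq_len(n)) {
    p <- params_sampler(i)
    latent[i] <- p$latent_ce
    out[[i]] <- simulate_participant(spec, p, seed = seeds[i], id = ids[i])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "latent_ce") <- stats::setNames(latent, ids)
  attr(res, "seed") <- seed
  res
}

#' Inject a low-effort responder into a cohort
#'
#' Replaces one participant's responses with constant max-stretch (or
#' min-stretch) spring lengths plus small jitter, emulating the low-effort
#' response patterns that the participant-exclusion rule must catch.
#'
#' @param cohort Trial table from [simulate_cohort()].
#' @param participant Identifier of the participant to overwrite.
#' @param type `"max"` (always near `at_cm`) or `"min"` (near 0).
#' @param at_cm Spring length for the `"max"` type (default 15 cm).
#' @param jitter_sd Gaussian jitter (cm) so responses are not exactly tied.
#' @param seed Integer seed.
#' @return The modified cohort.
#' @export
inject_low_effort <- function(cohort, participant, type = c("max", "min"),
                              at_cm = 15, jitter_sd = 0.05, seed = 1) {
  type <- match.arg(type)
  rows <- cohort$participant == participant
  if (!any(rows)) stop("no such participant: ", participant, call. = FALSE)
  local_rng(as.integer(seed))
  level <- if (type == "max") at_cm else 0.1
  cohort$response_cm[rows] <-
    pmax(level + stats::rnorm(sum(rows), 0, jitter_sd), 0)
  cohort
}
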