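#' Define a scenario for the simulation-based power analysis
#'
#' A power scenario draws two groups of `n` participant-level encoding
#' strengths from normal distributions — group 0 from `N(mu0, sd0)`, group 1
#' from `N(mu1, sd1)` — and runs the directional Bayes-factor test on each
#' simulated experiment. Setting `mu1 = mu0`, `sd1 = sd0` simulates a true
#' null. The reference-group SDs of the pilot conditions behind the original
#' design are unpublished, so `sd0`/`sd1` are required inputs, not defaults.
#'
#' @param mu0,sd0 Mean and SD (percent) of the reference-group outcome
#'   distribution.
#' @param mu1,sd1 Mean and SD of the comparison-group distribution.
#' @param n Participants per group.
#' @param reps Number of simulated experiments (default 10000).
#' @param direction Direction of the alternative (`"increase"` or
#'   `"decrease"` of group 1 relative to group 0).
#' @param sigma Half-normal scale of the alternative; default derives it
#'   from `mu0` via [hn_scale()].
#' @param bf_upper,bf_lower Decision thresholds (default 3 and 1/3).
#' @param hypothesis Which hypothesis is true in the scenario: `"alternative"`
#'   (power = fraction of B10 > `bf_upper`) or `"null"` (power = fraction of
#'   B10 < `bf_lower`).
#' @return List of class `power_scenario`.
#' @export
power_scenario <- function(mu0, sd0, mu1, sd1, n = 20L, reps = 10000L,
                           direction = c("increase", "decrease"),
                           sigma = NULL, bf_upper = 3, bf_lower = 1 / 3,
                           hypothesis = c("alternative", "null")) {
  direction <- match.arg(direction)
  hypothesis <- match.arg(hypothesis)
  stopifnot(sd0 > 0, sd1 > 0, n >= 2, reps >= 1, bf_upper > 1, bf_lower < 1)
  if (is.null(sigma)) sigma <- hn_scale(mu0, direction)
  structure(list(mu0 = mu0, sd0 = sd0, mu1 = mu1, sd1 = sd1, n = as.integer(n),
                 reps = as.integer(reps), direction = direction, sigma = sigma,
                 bf_upper = bf_upper, bf_lower = bf_lower,
                 hypothesis = hypothesis),
            class = "power_scenario")
}

#' Estimate power by simulating Bayesian experiments
#'
#' Simulates `scenario$reps` experiments. In each, two groups of `n` outcomes
#' are drawn, Welch summary statistics computed, and the directional
#' Bayes factor evaluated. Power is the proportion of experiments whose
#' Bayes factor crosses the decision threshold appropriate to the scenario:
#' above `bf_upper` when the alternative is true, below `bf_lower` when the
#' null is true.
#'
#' @param scenario A [power_scenario()].
#' @param seed Integer seed.
#' @return List of class `power_estimate`: `power`, `se` (binomial
#'   Monte-Carlo standard error), `reps`, `n`, and the `scenario`.
#' @export
#' @examples
#' sc <- power_scenario(mu0 = 47, sd0 = 28, mu1 = 84, sd1 = 22,
#'                      n = 20, reps = 200)
#' estimate_power(sc, seed = 1)
estimate_power <- function(scenario, seed) {
  stopifnot(inherits(scenario, "power_scenario"))
  local_rng(as.integer(seed))
  hyp <- hypothesis_pair(scenario$sigma, scenario$direction)
  hits <- 0L
  for (r in seq_len(scenario$reps)) {
    g0 <- stats::rnorm(scenario$n, scenario$mu0, scenario$sd0)
    g1 <- stats::rnorm(scenario$n, scenario$mu1, scenario$sd1)
    b <- bayes_factor(welch_summary(g0, g1), hyp)$b10
    crossed <- if (scenario$hypothesis == "alternative") b > scenario$bf_upper
               else b < scenario$bf_lower
    hits <- hits + crossed
  }
  p <- hits / scenario$reps
  structure(list(power = p, se = sqrt(p * (1 - p) / scenario$reps),
                 reps = scenario$reps, n = scenario$n, scenario = scenario),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Power %.3f (MC SE %.3f) at n = %d per group, %d simulated experiments\n",
              x$power, x$se, x$n, x$reps))
  invisible(x)
}
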