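#' Spring-mass-damper parameters of the lifting task
#'
#' The task simulates each release as a mass on a damped spring. Defaults are
#' the task's values: spring constant k = 100, damping coefficient c = 3,
#' gravity g = 9.81. The package interprets k and c in SI units (N/m and
#' N s/m) with masses in kg internally; lengths are reported in cm, which
#' puts the equilibrium stretches of the 300-800 g objects at 2.9-7.8 cm,
#' commensurate with the 2.5 cm and 6 cm error scales of the score and
#' time-penalty functions.
#'
#' @param k Spring stiffness (N/m), > 0.
#' @param c Damping coefficient (N s/m), >= 0.
#' @param g Gravitational acceleration magnitude (m/s^2), > 0.
#' @return List of class `physics_params`.
#' @export
physics_params <- function(k = 100, c = 3, g = 9.81) {
  if (!is.numeric(k) || k <= 0) stop("spring stiffness k must be > 0", call. = FALSE)
  if (!is.numeric(c) || c < 0) stop("damping coefficient c must be >= 0", call. = FALSE)
  if (!is.numeric(g) || g <= 0) stop("gravity g must be > 0", call. = FALSE)
  structure(list(k = k, c = c, g = g), class = "physics_params")
}

#' Equilibrium spring length for a given mass
#'
#' The stretch at which the spring force exactly balances the object's
#' weight: m g / k, returned in cm.
#'
#' @param mass_g Object mass in grams, >= 0. Vectorized.
#' @param params A [physics_params()] object.
#' @return Equilibrium length(s) in cm.
#' @export
#' @examples
#' equilibrium_length(400)  # 3.924 cm
equilibrium_length <- function(mass_g, params = physics_params()) {
  if (any(mass_g < 0)) stop("mass must be >= 0", call. = FALSE)
  (mass_g / 1000) * params$g / params$k * 100
}

#' Trial score as a function of spring-length error
#'
#' Inverted truncated quadratic loss on the signed spring-length error e (cm):
#' `100 * (1 - min((|e| / 2.5)^2, 1))`, rounded to the nearest integer
#' (half away from zero).
#'
#' @param e Spring-length error in cm. Vectorized.
#' @return Integer points in 0-100.
#' @export
#' @examples
#' score_points(c(0, 1.25, 2.5, 4))
score_points <- function(e) {
  stopifnot(all(is.finite(e)))
  y <- 100 * (1 - pmin((abs(e) / 2.5)^2, 1))
  as.integer(floor(y + 0.5))
}

#' Release-phase duration as a function of spring-length error
#'
#' Truncated quadratic time penalty on the signed error e (cm):
#' `1 + 5 * min((|e| / 6)^2, 1)` seconds, so the release phase lasts between
#' 1 s (perfect) and 6 s.
#'
#' @param e Spring-length error in cm. Vectorized.
#' @return Duration in seconds, in \[1, 6\].
#' @export
time_penalty <- function(e) {
  stopifnot(all(is.finite(e)))
  1 + 5 * pmin((abs(e) / 6)^2, 1)
}

# Analytic solution of m x'' + c x' + k x = 0, x(0) = x0, x'(0) = 0,
# where x is displacement (cm) from the equilibrium stretch. Handles the
# underdamped, critically damped, and overdamped branches; task parameters
# (300-800 g, k = 100, c = 3) are always underdamped.
damped_displacement <- function(t, x0, mass_kg, params) {
  k <- params$k; cc <- params$c
  w0 <- sqrt(k / mass_kg)
  zeta <- cc / (2 * sqrt(k * mass_kg))
  if (zeta < 1) {
    wd <- w0 * sqrt(1 - zeta^2)
    exp(-zeta * w0 * t) * (x0 * cos(wd * t) + (zeta * w0 * x0 / wd) * sin(wd * t))
  } else if (zeta == 1) {
    exp(-w0 * t) * (x0 + w0 * x0 * t)
  } else {
    r1 <- -w0 * (zeta - sqrt(zeta^2 - 1))
    r2 <- -w0 * (zeta + sqrt(zeta^2 - 1))
    a <- x0 * r2 / (r2 - r1)
    b <- x0 - a
    a * exp(r1 * t) + b * exp(r2 * t)
  }
}

#' Simulate the release phase of one trial
#'
#' On release, the object moves under gravity and the fixed spring: a damped
#' oscillation about the equilibrium stretch, starting from the
#' participant-set spring length with zero velocity. The trajectory is the
#' closed-form solution of the damped oscillator; the signed spring-length
#' error, points, and release-phase duration are computed from it.
#'
#' The object's vertical position offset equals minus the spring
#' displacement: if the spring was stretched less than equilibrium the
#' object falls.
#'
#' @param mass_g Object mass in grams (> 0).
#' @param set_length_cm Spring length set by the participant (cm, >= 0).
#' @param params A [physics_params()] object.
#' @param duration Sampled trajectory length in seconds.
#' @param step Sampling interval in seconds (> 0).
#' @return List of class `release_outcome` with elements `error_cm` (set
#'   length minus equilibrium length), `points`, `duration_s` (release-phase
#'   duration from [time_penalty()]), and `trajectory` (data.frame `time_s`,
#'   `position_cm`: object vertical offset from its clamped position).
#' @export
#' @examples
#' out <- simulate_release(800, set_length_cm = 4.9)
#' out$error_cm  # negative: under-anticipated, object falls
simulate_release <- function(mass_g, set_length_cm, params = physics_params(),
                             duration = 2, step = 0.01) {
  if (mass_g <= 0) stop("mass must be > 0", call. = FALSE)
  if (set_length_cm < 0) stop("set_length_cm must be >= 0", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  eq <- equilibrium_length(mass_g, params)
  e <- set_length_cm - eq
  t <- seq(0, duration, by = step)
  x <- damped_displacement(t, x0 = e, mass_kg = mass_g / 1000, params = params)
  structure(list(
    error_cm = e,
    points = score_points(e),
    duration_s = time_penalty(e),
    trajectory = data.frame(time_s = t, position_cm = -(x - e))
  ), class = "release_outcome")
}

#' @export
print.release_outcome <- function(x, ...) {
  cat(sprintf("Release: error %+.3f cm, %d points, %.2f s release phase\n",
              x$error_cm, x$points, x$duration_s))
  invisible(x)
}

#' Perturb an object mass with uniform noise
#'
#' Draws the presented mass from Uniform(mass - halfwidth, mass + halfwidth),
#' as in the added-noise manipulation (halfwidth 150 g).
#'
#' @param mass_g Nominal mass in grams.
#' @param halfwidth_g Half-width of the uniform perturbation (g, >= 0).
#' @param n Number of draws.
#' @return Perturbed mass(es) in grams.
#' @export
perturb_mass <- function(mass_g, halfwidth_g, n = 1L) {
  if (halfwidth_g < 0) stop("halfwidth must be >= 0", call. = FALSE)
  if (mass_g - halfwidth_g <= 0) {
    stop("perturbation could produce non-positive mass", call. = FALSE)
  }
  if (halfwidth_g == 0) return(rep(mass_g, n))
  stats::runif(n, mass_g - halfwidth_g, mass_g + halfwidth_g)
}

#' Outcome of the speeded-response time limit
#'
#' In the speeded condition, responses after the first 12 trials must be
#' completed within 2.25 s. A violation releases the object automatically,
#' costs 100 points, and incurs a timeout that starts at 6 s and grows by
#' 2 s with each subsequent violation.
#'
#' @param response_time_s Response time in seconds (>= 0).
#' @param prior_timeouts Number of timeouts already incurred.
#' @param trial Trial index; the limit applies only after trial 12.
#' @param limit_s Time limit in seconds (default 2.25).
#' @return List with `timed_out` (logical), `points_delta` (0 or -100), and
#'   `timeout_s` (0 if no violation, else 6 + 2 * prior_timeouts).
#' @export
#' @examples
#' speeded_outcome(2.3, prior_timeouts = 2)  # third violation: 10 s timeout
speeded_outcome <- function(response_time_s, prior_timeouts = 0L, trial = 13L,
                            limit_s = 2.25) {
  stopifnot(response_time_s >= 0, prior_timeouts >= 0)
  if (trial <= 12L || response_time_s <= limit_s) {
    return(list(timed_out = FALSE, points_delta = 0L, timeout_s = 0))
  }
  list(timed_out = TRUE, points_delta = -100L,
       timeout_s = 6 + 2 * prior_timeouts)
}
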