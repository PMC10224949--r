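test_that("scaled MAD uses the 1.4826 normal-consistency constant", {
  expect_equal(scaled_mad(c(5, 5, 5, 5)), 0)
  expect_equal(scaled_mad(c(1, 2, 3, 4, 100)), 1.4826)
  set.seed(31)
  expect_equal(scaled_mad(rnorm(1e5)), 1, tolerance = 0.02)
  expect_error(scaled_mad(numeric(0)), "finite")
})

test_that("trial exclusion flags only genuine spikes, never outlier trials", {
  spec <- make_condition("same_color")
  set.seed(12)
  tab <- simulate_participant(spec, behavior_params(latent_ce = 85,
                                                    motor_noise_sd = 0.3),
                              seed = 12)
  clean <- exclude_trials(tab)
  # a clean synthetic participant rarely crosses 4 scaled MADs
  expect_lt(clean$fraction, 0.08)

  # inject a 10-MAD spike into one family trial
  cell <- which(!tab$is_outlier & tab$object_height_cm == 5)
  s <- scaled_mad(tab$response_cm[cell])
  spiked <- tab
  spiked$response_cm[cell[4]] <- median(tab$response_cm[cell]) + 10 * s
  rep_s <- exclude_trials(spiked)
  expect_true(rep_s$flagged[cell[4]])
  expect_equal(sum(rep_s$flagged) - sum(clean$flagged), 1L)

  # the same spike on outlier trials is never flagged
  out_rows <- which(tab$is_outlier)
  spiked_out <- tab
  spiked_out$response_cm[out_rows[3]] <- 50
  expect_equal(sum(exclude_trials(spiked_out)$flagged[out_rows]), 0L)

  # constant responses: nothing to flag
  const <- tab
  const$response_cm <- 5
  expect_equal(exclude_trials(const)$n_flagged, 0L)
})

test_that("small cells are exempt from trial exclusion with a warning", {
  spec <- make_condition("same_color")
  tab <- simulate_participant(spec, behavior_params(), seed = 1)
  short <- tab[tab$trial <= 8, ]   # two blocks: 2 trials per object
  expect_warning(rep_s <- exclude_trials(short), "exempt")
  expect_equal(rep_s$n_flagged, 0L)
})

test_that("participant exclusion flags nobody in a homogeneous cohort", {
  spec <- make_condition("same_color")
  coh <- simulate_cohort(spec, behavior_params(latent_ce = 80), n = 12, seed = 4)
  expect_length(exclude_participants(coh, spec)$excluded, 0)
  expect_error(exclude_participants(coh[coh$participant %in% c("P01", "P02"), ], spec),
               "3 participants")
})

test_that("family regression matches the normal-equations oracle", {
  spec <- make_condition("same_color")
  win <- analysis_windows(spec)$post_window
  set.seed(21)
  for (i in 1:10) {
    tab <- build_table(spec, function(h, is_out, block) {
      2 + 0.5 * h + rnorm(1, 0, 0.4)
    })
    fit <- family_regression(tab, win)
    keep <- !tab$is_outlier & tab$block %in% win
    x <- tab$object_height_cm[keep]; y <- tab$response_cm[keep]
    slope_o <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
    int_o <- mean(y) - slope_o * mean(x)
    expect_equal(fit$slope, slope_o, tolerance = 1e-10)
    expect_equal(fit$intercept, int_o, tolerance = 1e-10)
  }
  # exact line: R^2 = 1 and exact coefficients
  lin <- build_table(spec, line_responder(1.2, 0.7, 6))
  fit <- family_regression(lin, win)
  expect_equal(fit$slope, 0.7, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
})

test_that("noiseless responses at sigmoidal equilibria leave residual nonlinearity", {
  spec <- make_condition("nonlinear")
  win <- analysis_windows(spec)$post_window
  tab <- build_table(spec, function(h, is_out, block) {
    equilibrium_length(spec$objects$mass_g[match(h, spec$objects$height_cm)])
  })
  fit <- family_regression(tab, win)
  expect_lt(fit$r_squared, 1)
  expect_gt(fit$r_squared, 0.8)
})

test_that("encoding strength reproduces its defining identities", {
  spec <- make_condition("same_color")
  # outlier response on the family regression line: exactly 100%
  on_line <- build_table(spec, line_responder(0.2, 0.6, 0.2 + 0.6 * 7))
  r100 <- encoding_strength(on_line, spec, apply_trial_exclusion = FALSE)
  expect_equal(r100$ce_percent, 100, tolerance = 1e-9)

  # all responses at true equilibrium lengths: exactly 0%
  perfect <- build_table(spec, function(h, is_out, block) {
    equilibrium_length(spec$objects$mass_g[match(h, spec$objects$height_cm)])
  })
  r0 <- encoding_strength(perfect, spec, apply_trial_exclusion = FALSE)
  expect_equal(r0$ce_percent, 0, tolerance = 1e-9)

  # halfway between the family prediction and the true outlier length: 50%
  # (true separation for this design is 7.848 - 4.905 = 2.943 cm)
  half <- build_table(spec, line_responder(0.2, 0.6, 0.2 + 0.6 * 7 + 2.943 / 2))
  r50 <- encoding_strength(half, spec, apply_trial_exclusion = FALSE)
  expect_equal(r50$ce_percent, 50, tolerance = 1e-9)
})

test_that("encoding strength is invariant to translating all heights", {
  spec <- make_condition("same_color")
  set.seed(77)
  tab <- simulate_participant(spec, behavior_params(latent_ce = 64), seed = 77)
  base <- encoding_strength(tab, spec)$ce_percent
  shifted <- tab
  shifted$object_height_cm <- shifted$object_height_cm + 100
  spec2 <- spec
  spec2$objects$height_cm <- spec2$objects$height_cm + 100
  expect_equal(encoding_strength(shifted, spec2)$ce_percent, base,
               tolerance = 1e-9)
})

test_that("regression prediction at the outlier height equals the family mean", {
  spec <- make_condition("same_color")
  set.seed(14)
  tab <- build_table(spec, function(h, is_out, block) 1 + 0.5 * h + rnorm(1, 0, 0.3))
  chk <- family_mean_equivalence(tab, spec)
  expect_true(chk$applicable)
  expect_true(chk$holds)
  expect_lt(abs(chk$difference), 1e-9)

  # two symmetric heights (small family) also qualify
  sf <- make_condition("small_family")
  tab_sf <- build_table(sf, function(h, is_out, block) 2 + 0.4 * h + rnorm(1, 0, 0.2))
  chk_sf <- family_mean_equivalence(tab_sf, sf)
  expect_true(chk_sf$applicable)
  expect_true(chk_sf$holds)

  # unbalanced trial counts break the equivalence and the check is skipped
  win_rows <- which(!tab$is_outlier & tab$object_height_cm == 5 &
                      tab$block %in% analysis_windows(spec)$post_window)
  unbal <- tab[-win_rows[1:6], ]
  chk_u <- family_mean_equivalence(unbal, spec)
  expect_false(chk_u$applicable)
  win <- analysis_windows(spec)$post_window
  keep <- !unbal$is_outlier & unbal$block %in% win
  fit <- family_regression(unbal, win)
  expect_gt(abs(fit$predict(7) - mean(unbal$response_cm[keep])), 1e-9)
})

test_that("slope shift isolates the outlier's pull on the category line", {
  spec <- make_condition("same_color")
  # noiseless fully acquired responder with no update gain: delta exactly 0
  p0 <- behavior_params(latent_ce = 90, motor_noise_sd = 0,
                        learning_rate = 1, category_update_gain = 0)
  tab0 <- simulate_participant(spec, p0, seed = 4)
  expect_equal(slope_shift(tab0, spec, apply_trial_exclusion = FALSE)$delta, 0,
               tolerance = 1e-12)
  # positive update gain steepens the post-introduction regression
  deltas <- vapply(1:8, function(s) {
    pg <- behavior_params(latent_ce = 90, motor_noise_sd = 0.2,
                          category_update_gain = 0.0005)
    slope_shift(simulate_participant(spec, pg, seed = s), spec)$delta
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("bootstrap SEM approximates the analytic standard error", {
  expect_equal(bootstrap_sem(rep(3, 10), reps = 200, seed = 1), 0)
  set.seed(2)
  x <- rnorm(400, 50, 12)
  sem <- bootstrap_sem(x, reps = 2000, seed = 3)
  expect_equal(sem, sd(x) / sqrt(length(x)), tolerance = 0.1)
  expect_identical(bootstrap_sem(x, reps = 500, seed = 7),
                   bootstrap_sem(x, reps = 500, seed = 7))
})
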