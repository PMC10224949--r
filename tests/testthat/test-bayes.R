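test_that("half-normal scale rule reproduces the published prior scales", {
  expect_equal(hn_scale(89.1, "decrease"), 34.58, tolerance = 0.05 / 34.58)
  expect_equal(hn_scale(59.5, "increase"), 15.71, tolerance = 0.05 / 15.71)
  expect_equal(hn_scale(89.1, "increase"), 4.24, tolerance = 0.05 / 4.24)
  # 99% of the half-normal mass falls inside the admissible range
  s <- hn_scale(89.1, "decrease")
  expect_equal(2 * (pnorm(89.1 / s) - 0.5), 0.99, tolerance = 1e-10)
  expect_error(hn_scale(100, "increase"), "no room")
})

test_that("Welch summaries agree with the t.test oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(welch_summary(x, x)$mean_diff, 0)
  # equal sample variances, n = 20 each: df reduces to 38
  a <- rnorm(20); a <- (a - mean(a)) / sd(a)
  b <- rnorm(20); b <- (b - mean(b)) / sd(b) * sd(a)
  expect_equal(welch_summary(a, b + 1)$df, 38)
  set.seed(55)
  for (i in 1:25) {
    g1 <- rnorm(sample(5:40, 1), 50, runif(1, 5, 30))
    g2 <- rnorm(sample(5:40, 1), 60, runif(1, 5, 30))
    ws <- welch_summary(g1, g2)
    tt <- t.test(g2, g1, var.equal = FALSE)
    expect_equal(ws$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(ws$mean_diff / ws$se_diff, unname(tt$statistic), tolerance = 1e-10)
  }
  expect_error(welch_summary(c(1, 1), c(1, 1)), "zero variance")
})

test_that("the engine reproduces every published Bayes factor", {
  tab <- reproduce_reported_bfs()
  expect_equal(nrow(tab), 15L)
  # agreement within 1% relative error, or to the printed 2-decimal
  # precision for the smallest values, whichever is looser
  tol <- pmax(0.01 * tab$published_b10, 0.005)
  expect_true(all(abs(tab$b10 - tab$published_b10) <= tol))
  # the flagship comparisons meet the plain 1% bound
  flagship <- tab$published_b10 %in% c(494.92, 17.33, 7.76, 10.80, 2.16)
  expect_true(all(abs(tab$b10[flagship] - tab$published_b10[flagship]) <=
                    0.01 * tab$published_b10[flagship]))
})

test_that("Bayes factor limits, symmetry, and monotonicity hold", {
  s <- list(mean_diff = -20, se_diff = 8, df = 30)
  # vanishing prior scale collapses the alternative onto the null
  expect_equal(bayes_factor(s, hypothesis_pair(1e-4, "decrease"))$b10, 1,
               tolerance = 1e-3)
  # sign symmetry
  s_pos <- list(mean_diff = 20, se_diff = 8, df = 30)
  expect_equal(bayes_factor(s, hypothesis_pair(15, "decrease"))$b10,
               bayes_factor(s_pos, hypothesis_pair(15, "increase"))$b10,
               tolerance = 1e-8)
  # monotone in the effect magnitude along the prior's direction
  b <- vapply(seq(0, 40, by = 5), function(m) {
    bayes_factor(list(mean_diff = -m, se_diff = 8, df = 30),
                 hypothesis_pair(15, "decrease"))$b10
  }, numeric(1))
  expect_true(all(diff(b) > 0))
})

test_that("quadrature agrees with a Monte-Carlo prior-averaging oracle", {
  set.seed(88)
  for (i in 1:5) {
    m <- runif(1, -40, 40); se <- runif(1, 5, 15)
    df <- runif(1, 10, 60); sigma <- runif(1, 5, 35)
    dir <- sample(c("decrease", "increase"), 1)
    q <- bayes_factor(list(mean_diff = m, se_diff = se, df = df),
                      hypothesis_pair(sigma, dir))$b10
    d <- abs(rnorm(2e5, 0, sigma)) * (if (dir == "decrease") -1 else 1)
    liks <- dt((m - d) / se, df) / se
    null_lik <- dt(m / se, df) / se
    mc <- mean(liks) / null_lik
    mc_se <- sd(liks) / sqrt(length(liks)) / null_lik
    expect_lt(abs(q - mc), 3 * mc_se + 1e-12)
  }
})

test_that("evidence labels follow the conventional bands", {
  expect_match(classify_bf(0.25), "moderate evidence for H0")
  expect_match(classify_bf(1.7), "anecdotal evidence for H1")
  expect_match(classify_bf(494.92), "extreme evidence for H1")
  expect_match(classify_bf(17.33), "strong evidence for H1")
  expect_match(classify_bf(0.004), "extreme evidence for H0")
  expect_identical(classify_bf(1), "no evidence")
})

test_that("combined comparisons center, pool, and mix the prior variances", {
  expect_equal(sqrt((4.24^2 + 15.71^2) / 2), 11.51, tolerance = 0.01 / 11.51)
  set.seed(60)
  p1 <- list(condition = rnorm(20, 99, 20), reference = rnorm(20, 89, 22),
             sigma = 4.24)
  p2 <- list(condition = rnorm(20, 71, 25), reference = rnorm(20, 60, 26),
             sigma = 15.71)
  res <- combined_comparison(p1, p2, "increase")
  expect_equal(res$hypothesis$sigma, sqrt((4.24^2 + 15.71^2) / 2))
  # centering: pooled reference mean is exactly zero
  pooled_ref <- c(p1$reference - mean(p1$reference),
                  p2$reference - mean(p2$reference))
  expect_equal(mean(pooled_ref), 0, tolerance = 1e-12)
  expect_equal(res$stats$df, welch_summary(pooled_ref,
    c(p1$condition - mean(p1$reference), p2$condition - mean(p2$reference)))$df)
})
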