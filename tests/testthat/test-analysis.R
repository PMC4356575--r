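test_that("equilibrium fit recovers noiseless curves to 1e-6", {
  d <- 1:20
  truth <- list(C = 0.9, B = -0.2, F = 0.5)
  fit <- fit_equilibrium(d, truth$C + truth$B * exp(-d * truth$F))
  expect_true(fit$converged)
  expect_lt(abs(fit$C - truth$C), 1e-6)
  expect_lt(abs(fit$B - truth$B), 1e-6)
  expect_lt(abs(fit$F - truth$F), 1e-6)

  # property sweep over the admissible parameter box
  set.seed(5)
  for (i in 1:10) {
    C <- runif(1, 0, 1); B <- runif(1, -1, 1); F <- runif(1, 0.05, 2)
    y <- C + B * exp(-d * F)
    fit <- fit_equilibrium(d, y)
    expect_lt(abs(fit$C - C), 1e-6)
    expect_lt(max(abs(predict(fit) - y)), 1e-6)
  }
})

test_that("equilibrium fit handles degenerate inputs sanely", {
  expect_error(fit_equilibrium(1:3, c(0.1, 0.2, 0.3)), "at least 4")
  expect_error(fit_equilibrium(c(1, 2, 2, 3), rep(0.5, 4)), "distinct")
  expect_error(fit_equilibrium(c(-1, 1, 2, 3), rep(0.5, 4)), "positive")

  fit <- fit_equilibrium(1:10, rep(0.8, 10))
  expect_equal(fit$C, 0.8)
  expect_equal(fit$B, 0)
  expect_true(fit$converged)
  # at d = 0 the model value is C + B
  expect_equal(predict(fit, 0), fit$C + fit$B)
  f2 <- fit_equilibrium(1:20, 0.7 - 0.3 * exp(-(1:20) * 0.4))
  expect_equal(predict(f2, 0), f2$C + f2$B, tolerance = 1e-8)
})

test_that("noisy curves recover C within 3 sigma most of the time", {
  d <- 1:20
  sigma <- 0.01
  set.seed(21)
  hits <- vapply(1:30, function(i) {
    y <- 0.85 - 0.25 * exp(-d * 0.4) + rnorm(length(d), 0, sigma)
    fit <- fit_equilibrium(d, y)
    abs(fit$C - 0.85) < 3 * sigma
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("learning curves: cooperative types constant, type 1 slowest", {
  counts <- allocate_type_counts(sweden_pct(), 75)
  lc <- learning_curves(counts, h = 0.5, d_values = c(2, 10), n_reps = 30,
                        n_agents = 75, n_days = 40, counts = TRUE)
  expect_true(all(lc$mean[lc$type %in% c(2, 3, 7)] == 1))
  for (dd in c(2, 10)) {
    sub <- lc[lc$d == dd, ]
    expect_lt(sub$mean[sub$type == 1],
              min(sub$mean[sub$type %in% c(4, 5, 6)]))
  }
  # habit duration helps the steadfast type
  t4 <- lc$mean[lc$type == 4]
  expect_gt(t4[2], t4[1])
})

test_that("(h, d) sweep has the right shape and responds to h", {
  sw <- sweden_pct()
  grid <- sweep_hd(sw, h_grid = c(0.3, 0.7), d_grid = c(2, 6), n_reps = 40,
                   n_days = 60)
  expect_s3_class(grid, "tp_sweep")
  expect_equal(nrow(grid), 4)
  expect_true(all(grid$mean >= 0 & grid$mean <= 1))
  # stronger policing beats weaker policing at the same duration
  at_d6 <- grid[grid$d == 6, ]
  expect_gt(at_d6$mean[at_d6$h == 0.7], at_d6$mean[at_d6$h == 0.3])
})

test_that("cooperation index is 1 for an all-cooperative village", {
  fit <- cooperation_index(c(0, 5, 5, 0, 0, 0, 5), d_max = 4, n_reps = 2,
                           n_days = 10, counts = TRUE)
  expect_equal(fit$C, 1)
  expect_equal(fit$B, 0)
})

test_that("moving mass from laborious to opportunistic lowers the index", {
  a <- c(15, 15, 25, 15, 15, 10, 5)
  b <- a + c(10, 0, -10, 0, 0, 0, 0)
  fa <- cooperation_index(a, d_max = 8, n_reps = 20, n_days = 50,
                          base_seed = 77)
  fb <- cooperation_index(b, d_max = 8, n_reps = 20, n_days = 50,
                          base_seed = 77)
  expect_lt(fb$C, fa$C)
})

test_that("index is stable in the replicate count once converged", {
  sw <- sweden_pct()
  f1 <- cooperation_index(sw, d_max = 8, n_reps = 40, n_days = 50,
                          base_seed = 88)
  f2 <- cooperation_index(sw, d_max = 8, n_reps = 160, n_days = 50,
                          base_seed = 88)
  expect_lt(abs(f1$C - f2$C), 0.02)
})

test_that("at weak policing the d-gain saturates early", {
  sw <- sweden_pct()
  fit <- cooperation_index(sw, h = 0.3, d_max = 12, n_reps = 30,
                           n_days = 60, base_seed = 91)
  gain_early <- predict(fit, 6) - predict(fit, 1)
  gain_late <- predict(fit, 20) - predict(fit, 6)
  expect_lt(gain_late, 0.5 * gain_early)
})

test_that("country ranking is ordered, de-aggregated and seeded", {
  dists <- load_country_distributions()
  three <- dists[dists$country %in% c("Sweden", "UK", "Total sample"), ]
  rk <- rank_countries(three, d_max = 6, n_reps = 10, n_days = 40,
                       base_seed = 10)
  expect_equal(nrow(rk), 2)                     # aggregate excluded
  expect_false("Total sample" %in% rk$country)
  expect_true(all(diff(rk$index) <= 0))         # descending
  rk_all <- rank_countries(three, d_max = 6, n_reps = 10, n_days = 40,
                           base_seed = 10, include_aggregate = TRUE)
  expect_equal(nrow(rk_all), 3)
  # reruns with the same seeds are identical
  rk2 <- rank_countries(three, d_max = 6, n_reps = 10, n_days = 40,
                        base_seed = 10)
  expect_identical(rk, rk2)
  # single-distribution input yields a single-row table
  one <- rank_countries(dists[dists$country == "Sweden", ], d_max = 6,
                        n_reps = 5, n_days = 30)
  expect_equal(nrow(one), 1)
})
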