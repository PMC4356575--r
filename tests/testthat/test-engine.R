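test_that("runs are seeded, conservative and bounded", {
  cfg <- sim_config(sweden_pct(), n_days = 30, h = 0.5, d = 5, seed = 7)
  ts1 <- run_simulation(cfg)
  ts2 <- run_simulation(cfg)
  expect_identical(ts1$overall, ts2$overall)       # bit-identical rerun
  expect_identical(ts1$by_type, ts2$by_type)

  expect_length(ts1$overall, 31)                   # day 0 .. n_days
  expect_true(all(ts1$overall >= 0 & ts1$overall <= 1))
  expect_true(all(ts1$by_type >= 0 & ts1$by_type <= 1, na.rm = TRUE))
  # the per-type series recompose the overall fraction exactly
  recomposed <- as.vector(ts1$by_type %*% ts1$type_counts) / 150
  expect_equal(recomposed, ts1$overall, tolerance = 1e-12)
  # profile multiset is invariant: per-type denominators never change
  expect_equal(sum(ts1$type_counts), 150)

  ref <- run_simulation(cfg, engine = "reference")
  ref2 <- run_simulation(cfg, engine = "reference")
  expect_identical(ref$overall, ref2$overall)
  expect_true(all(ref$overall >= 0 & ref$overall <= 1))
})

test_that("cooperative-only villages are absorbed at full cooperation", {
  cfg <- counts_config(c(0, 5, 6, 0, 0, 0, 4), n_days = 40)
  for (eng in c("compiled", "reference")) {
    ts <- run_simulation(cfg, engine = eng)
    expect_true(all(ts$overall == 1))
    expect_true(all(ts$by_type[, c(2, 3, 7)] == 1))
  }
})

test_that("an all-opportunistic village never cooperates", {
  cfg <- counts_config(c(10, 0, 0, 0, 0, 0, 0), n_days = 40, h = 0.9)
  for (eng in c("compiled", "reference")) {
    ts <- run_simulation(cfg, engine = eng)
    expect_true(all(ts$overall == 0))
  }
})

test_that("with h = 0 policing is inert: enforcer/defector standoff", {
  # 5 committed vs 5 opportunistic, h = 0: police events fire but never
  # convert, temptation cannot touch the committed, majority stays tied
  cfg <- counts_config(c(5, 0, 0, 0, 0, 0, 5), n_days = 30, h = 0, d = 10)
  for (eng in c("compiled", "reference")) {
    ts <- run_simulation(cfg, engine = eng)
    expect_true(all(ts$overall == 0.5))
    expect_true(all(ts$by_type[, 1] == 0))
    expect_true(all(ts$by_type[, 7] == 1))
  }
})

test_that("a two-agent enforcer/defector pair cycles with period d at h = 1", {
  # committed polices the opportunist every day with certainty: the
  # opportunist cooperates for d days, lapses for the day its timer
  # expires, and is re-policed the next day
  cfg <- counts_config(c(1, 0, 0, 0, 0, 0, 1), n_days = 12, h = 1, d = 3)
  for (eng in c("compiled", "reference")) {
    ts <- run_simulation(cfg, engine = eng)
    expected <- c(0.5, rep(c(1, 1, 0.5), 4))       # day 0, then period 3
    expect_equal(ts$overall, expected)
  }
})

test_that("compiled and reference engines agree statistically", {
  counts <- allocate_type_counts(sweden_pct(), 75)
  cfg <- counts_config(counts, n_days = 30, h = 0.5, d = 5)
  n_reps <- 60
  fast <- run_replicates(cfg, n_reps, base_seed = 10, engine = "compiled")
  slow <- run_replicates(cfg, n_reps, base_seed = 10, engine = "reference")
  last <- 31
  joint_se <- sqrt(fast$overall_se[last]^2 + slow$overall_se[last]^2)
  expect_lt(abs(fast$overall_mean[last] - slow$overall_mean[last]),
            4 * joint_se)
  # per-type agreement for the responsive types
  for (k in c(1, 4, 5, 6)) {
    jse <- sqrt(fast$by_type_se[last, k]^2 + slow$by_type_se[last, k]^2)
    expect_lt(abs(fast$by_type_mean[last, k] - slow$by_type_mean[last, k]),
              4 * jse + 0.02)
  }
})

test_that("replicate summaries average correctly and shrink like 1/sqrt(n)", {
  cfg <- sim_config(sweden_pct(), n_days = 20, h = 0.5, d = 5)
  one <- run_replicates(cfg, 1, base_seed = 55)
  cfg1 <- cfg; cfg1$seed <- 56L
  single <- run_simulation(cfg1)
  expect_equal(one$overall_mean, single$overall)   # n_reps = 1 is the run

  # deterministic composition (no type 6, h = 0 blocks police draws):
  # all-cooperative village has zero spread
  det <- run_replicates(counts_config(c(0, 3, 3, 0, 0, 0, 3), n_days = 10),
                        10, base_seed = 1)
  expect_true(all(det$overall_se == 0))

  s25 <- run_replicates(cfg, 25, base_seed = 300)
  s400 <- run_replicates(cfg, 400, base_seed = 300)
  ratio <- s25$overall_se[21] / s400$overall_se[21]
  expect_gt(ratio, 2.0)                            # expected 4 = sqrt(16)
  expect_lt(ratio, 8.0)
})

test_that("the engine's exact outcome law matches brute-force enumeration", {
  # one opportunist, one steadfast, one committed; every random branch
  # of two days enumerated exactly and compared with engine sampling
  types <- c(1L, 4L, 7L)
  h <- 0.6; d <- 2; n_days <- 2
  exact <- enumerate_village(types, c("D", "D", "C"), c(0, 0, 0),
                             h, d, n_days)
  expect_equal(sum(exact), 1, tolerance = 1e-9)

  n_runs <- 4000
  cfg <- counts_config(c(1, 0, 0, 1, 0, 0, 1), n_days = n_days,
                       h = h, d = d)
  keys <- vapply(seq_len(n_runs), function(r) {
    cfg$seed <- 7000L + r
    ts <- run_simulation(cfg)
    paste(ifelse(ts$by_type[n_days + 1, c(1, 4, 7)] == 1, "C", "D"),
          collapse = "")
  }, character(1))
  for (key in names(exact)) {
    p <- exact[[key]]
    p_hat <- mean(keys == key)
    se <- sqrt(p * (1 - p) / n_runs)
    expect_lt(abs(p_hat - p), 4 * se + 1e-9, label = paste("config", key))
  }
  # nothing outside the enumerated support
  expect_true(all(keys %in% names(exact)))
})

test_that("time series tidy export and manifest round-trip", {
  cfg <- sim_config(sweden_pct(), n_days = 10, h = 0.5, d = 5, seed = 3)
  ts <- run_simulation(cfg)
  long <- as.data.frame(ts)
  expect_named(long, c("day", "type", "frac_cooperators"))
  expect_equal(long$frac_cooperators[long$type == "all"], ts$overall)

  path <- file.path(tempdir(), "run.csv")
  write_timeseries(ts, path)
  expect_true(file.exists(path))
  man <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_equal(man$seed, 3)
  expect_equal(man$h, 0.5)
  expect_equal(man$n_days, 10)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(long))
})
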