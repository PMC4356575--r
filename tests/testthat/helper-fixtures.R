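# Shared fixtures for the suite.

uniform_pct <- function() rep(100 / 7, 7)

sweden_pct <- function() {
  country_distribution(load_country_distributions(), "Sweden")
}

make_agent <- function(type, state, timer = 0L) {
  list(type = as.integer(type), state = state, timer = as.integer(timer))
}

# A village given directly as counts, bypassing apportionment.
counts_config <- function(counts, n_days = 20, h = 0.5, d = 5, seed = 1) {
  sim_config(counts, n_days = n_days, h = h, d = d, seed = seed,
             counts = TRUE)
}

# Write a distribution CSV for parse tests.
write_dist_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("country,t1,t2,t3,t4,t5,t6,t7", rows), path)
  path
}
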