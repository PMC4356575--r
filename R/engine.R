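#' Simulation configuration
#'
#' Bundles everything a run needs: the village composition (either a
#' 7-vector of percentages or of integer counts), the village size, the
#' number of simulated days, the control parameters and the seed.
#'
#' @param distribution Either a 7-vector of percentages (summing to 100,
#'   apportioned with [allocate_type_counts()]) or, if `counts = TRUE`,
#'   a 7-vector of integer type counts used as-is.
#' @param n_agents Village size (default 150); ignored when counts are
#'   given.
#' @param n_days Number of simulated days (default 100).
#' @param h,d Control parameters, see [control_params()].
#' @param seed Integer seed making the whole run reproducible.
#' @param counts Logical; `distribution` is a count vector.
#' @return An object of class `tp_config`.
#' @examples
#' sweden <- country_distribution(load_country_distributions(), "Sweden")
#' sim_config(sweden, h = 0.5, d = 10, seed = 1)
#' @export
sim_config <- function(distribution, n_agents = 150, n_days = 100,
                       h = 0.5, d = 10, seed = 1, counts = FALSE) {
  stopifnot(length(distribution) == 7, n_days >= 1)
  if (counts) {
    stopifnot(all(distribution >= 0),
              all(distribution == as.integer(distribution)))
    type_counts <- as.integer(distribution)
    names(type_counts) <- paste0("t", 1:7)
    n_agents <- sum(type_counts)
  } else {
    stopifnot(n_agents >= 7)
    type_counts <- allocate_type_counts(distribution, n_agents)
  }
  structure(list(type_counts = type_counts, n_agents = n_agents,
                 n_days = as.integer(n_days),
                 params = control_params(h, d),
                 seed = as.integer(seed),
                 country = attr(distribution, "country")),
            class = "tp_config")
}

#' @export
print.tp_config <- function(x, ...) {
  cat(sprintf("Village of %d agents%s, %d days, h = %.2f, d = %d, seed = %d\n",
              x$n_agents,
              if (is.null(x$country)) "" else paste0(" (", x$country, ")"),
              x$n_days, x$params$h, x$params$d, x$seed))
  cat("Type counts:", paste(x$type_counts, collapse = " "), "\n")
  invisible(x)
}

#' Advance the village by one day (reference implementation)
#'
#' Random sequential updating: agents are visited once each in a fresh
#' uniformly-random order; each focal agent meets one partner drawn
#' uniformly from the other agents, the focal's rule-table row is
#' applied against the partner's current state, and any emitted events
#' (police / offer / tempt) act on the partner immediately. After all
#' meetings, habit timers expire via [expire_timer()]. The majority
#' signal is held fixed for the whole day.
#'
#' This is the readable reference path; [run_simulation()] uses a
#' compiled equivalent by default.
#'
#' @param agents Agent roster data frame (see [build_village()]).
#' @param majority `"C"`, `"D"` or `"tie"`.
#' @param params A [control_params()] object.
#' @return The end-of-day agent roster.
#' @export
step_day <- function(agents, majority, params) {
  check_agents(agents)
  n <- nrow(agents)
  type <- agents$type
  state <- agents$state
  timer <- agents$timer
  order_today <- sample.int(n)
  for (f in order_today) {
    q <- sample.int(n - 1L, 1L)
    if (q >= f) q <- q + 1L
    focal <- as_agent(type[f], state[f], timer[f])
    out <- meeting_outcome(focal, state[q], majority, params)
    state[f] <- out$agent$state
    timer[f] <- out$agent$timer
    if (length(out$events)) {
      target <- as_agent(type[q], state[q], timer[q])
      for (ev in out$events) {
        target <- switch(ev,
          police = apply_police(target, majority, params),
          offer  = apply_offer(target, majority, params),
          tempt  = apply_tempt(target, majority, params))
      }
      state[q] <- target$state
      timer[q] <- target$timer
    }
  }
  for (i in seq_len(n)) {
    a <- expire_timer(as_agent(type[i], state[i], timer[i]))
    state[i] <- a$state
    timer[i] <- a$timer
  }
  agents$state <- state
  agents$timer <- timer
  agents
}

#' Run one seeded simulation
#'
#' Builds the initial village from the configured type counts (type-6
#' coin flips included in the seeded stream), then simulates
#' `n_days` days. Day 0 is the initial village; the majority signal for
#' day t comes from day t-1's end-of-day cooperator fraction.
#'
#' @param config A [sim_config()] object.
#' @param engine `"compiled"` (default, C++ core) or `"reference"`
#'   (pure-R path through [step_day()]). The two are statistically
#'   equivalent but consume random draws differently, so they do not
#'   reproduce each other run-for-run.
#' @return An object of class `tp_timeseries`: list with `day`
#'   (0..n_days), `overall` (cooperator fraction per day), `by_type`
#'   ((n_days+1) x 7 matrix of per-type cooperator fractions, `NaN` for
#'   absent types), `type_counts` and `config`.
#' @examples
#' sweden <- country_distribution(load_country_distributions(), "Sweden")
#' ts <- run_simulation(sim_config(sweden, h = 0.5, d = 10, seed = 1))
#' ts$overall[ts$day == 100]
#' @export
run_simulation <- function(config, engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "tp_config"))
  set.seed(config$seed)
  agents <- build_village(config$type_counts)
  n <- nrow(agents)
  counts <- config$type_counts
  if (engine == "compiled") {
    res <- .run_sim_cpp(agents$type, as.integer(agents$state == "C"),
                        agents$timer, config$params$h, config$params$d,
                        config$n_days)
    coop <- res$coop_by_type
  } else {
    coop <- matrix(0L, config$n_days + 1L, 7L)
    tally <- function(a) vapply(1:7, function(k)
      sum(a$state == "C" & a$type == k), integer(1))
    coop[1L, ] <- tally(agents)
    majority <- majority_from_fraction(sum(coop[1L, ]) / n)
    for (day in seq_len(config$n_days)) {
      agents <- step_day(agents, majority, config$params)
      coop[day + 1L, ] <- tally(agents)
      majority <- majority_from_fraction(sum(coop[day + 1L, ]) / n)
    }
  }
  by_type <- sweep(coop, 2L, counts, "/")  # NaN where a type is absent
  overall <- rowSums(coop) / n
  structure(list(day = 0:config$n_days, overall = overall,
                 by_type = by_type, type_counts = counts,
                 config = config, engine = engine),
            class = "tp_timeseries")
}

#' @export
print.tp_timeseries <- function(x, ...) {
  nd <- length(x$day) - 1L
  cat(sprintf("Cooperation time series: %d agents, day 0..%d (%s engine)\n",
              sum(x$type_counts), nd, x$engine))
  cat(sprintf("  day 0 fraction %.3f -> day %d fraction %.3f\n",
              x$overall[1], nd, x$overall[nd + 1L]))
  invisible(x)
}

#' Tidy one run (or replicate summary) into a long data frame
#'
#' @param x A `tp_timeseries` or `tp_timeseries_summary`.
#' @param ... Unused.
#' @return Data frame with columns `day`, `type` (`"all"` or `"1"`..`"7"`),
#'   `frac_cooperators` and, for summaries, `se`.
#' @export
as.data.frame.tp_timeseries <- function(x, ...) {
  long <- data.frame(
    day = rep(x$day, 8L),
    type = rep(c("all", as.character(1:7)), each = length(x$day)),
    frac_cooperators = c(x$overall, as.vector(x$by_type)),
    stringsAsFactors = FALSE)
  long[!is.nan(long$frac_cooperators), , drop = FALSE]
}

#' Average a batch of seeded replicate runs
#'
#' Replicate r uses seed `base_seed + r` (r = 1..n_reps). Returns the
#' pointwise mean and standard error of the overall and per-type
#' cooperator fractions.
#'
#' @param config A [sim_config()]; its own seed field is ignored.
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Base for the replicate seeds.
#' @param engine Passed to [run_simulation()].
#' @return Object of class `tp_timeseries_summary`: list with `day`,
#'   `overall_mean`, `overall_se`, `by_type_mean`, `by_type_se`,
#'   `n_reps`, `type_counts`, `config`.
#' @export
run_replicates <- function(config, n_reps, base_seed = 1000,
                           engine = "compiled") {
  stopifnot(n_reps >= 1)
  nd <- config$n_days + 1L
  sum_o <- sq_o <- numeric(nd)
  sum_t <- sq_t <- matrix(0, nd, 7L)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r)
    ts <- run_simulation(cfg, engine = engine)
    sum_o <- sum_o + ts$overall
    sq_o <- sq_o + ts$overall^2
    bt <- ts$by_type
    bt[is.nan(bt)] <- 0
    sum_t <- sum_t + bt
    sq_t <- sq_t + bt^2
  }
  mean_o <- sum_o / n_reps
  mean_t <- sum_t / n_reps
  se <- function(s2, m) {
    v <- pmax(s2 / n_reps - m^2, 0) * n_reps / max(n_reps - 1L, 1L)
    sqrt(v / n_reps)
  }
  absent <- config$type_counts == 0L
  mean_t[, absent] <- NaN
  structure(list(day = 0:config$n_days,
                 overall_mean = mean_o, overall_se = se(sq_o, mean_o),
                 by_type_mean = mean_t, by_type_se = se(sq_t, mean_t),
                 n_reps = n_reps, type_counts = config$type_counts,
                 config = config),
            class = "tp_timeseries_summary")
}

#' @export
print.tp_timeseries_summary <- function(x, ...) {
  nd <- length(x$day) - 1L
  cat(sprintf("Replicate mean (%d runs): day %d overall %.3f (se %.4f)\n",
              x$n_reps, nd, x$overall_mean[nd + 1L], x$overall_se[nd + 1L]))
  invisible(x)
}

#' @rdname as.data.frame.tp_timeseries
#' @export
as.data.frame.tp_timeseries_summary <- function(x, ...) {
  long <- data.frame(
    day = rep(x$day, 8L),
    type = rep(c("all", as.character(1:7)), each = length(x$day)),
    frac_cooperators = c(x$overall_mean, as.vector(x$by_type_mean)),
    se = c(x$overall_se, as.vector(x$by_type_se)),
    stringsAsFactors = FALSE)
  long[!is.nan(long$frac_cooperators), , drop = FALSE]
}

#' Write a time series (and its manifest) to disk
#'
#' Writes the tidy long-format CSV plus a JSON sidecar echoing the
#' configuration and seed(s), sufficient to re-execute the run.
#'
#' @param x A `tp_timeseries` or `tp_timeseries_summary`.
#' @param path Output CSV path; the manifest is written next to it with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  cfg <- x$config
  manifest <- list(
    package = "tpvillage",
    version = as.character(utils::packageVersion("tpvillage")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    n_agents = cfg$n_agents, n_days = cfg$n_days,
    h = cfg$params$h, d = cfg$params$d,
    type_counts = as.integer(cfg$type_counts),
    country = cfg$country,
    seed = cfg$seed, n_reps = x$n_reps,
    output = basename(path))
  jsonlite::write_json(manifest, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
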