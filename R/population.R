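#' Load country-level distributions of the seven profiles
#'
#' Reads a table of profile percentages, one row per country sample, and
#' validates each row: seven non-negative percentages summing to 100
#' within a 0.1 rounding allowance, every profile strictly represented.
#' The packaged table holds 24 survey samples from 22 countries (China
#' and Greece contribute two samples each) plus an aggregate
#' "Total sample" row, which is flagged so that country-level analyses
#' can exclude it by default.
#'
#' @param source Path to a CSV with header `country,t1,...,t7`, or
#'   `"builtin"` (default) for the packaged table.
#' @return A data frame of class `tp_distributions` with columns
#'   `country`, `t1`..`t7` and logical `aggregate`.
#' @examples
#' dists <- load_country_distributions()
#' dists[dists$country == "Sweden", ]
#' @export
load_country_distributions <- function(source = "builtin") {
  path <- if (identical(source, "builtin")) {
    system.file("extdata", "country_type_distributions.csv",
                package = "tpvillage", mustWork = TRUE)
  } else source
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  expect_cols <- c("country", paste0("t", 1:7))
  if (!identical(names(raw), expect_cols))
    stop("distribution file must have header ",
         paste(expect_cols, collapse = ","))
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    pct <- suppressWarnings(as.numeric(row[paste0("t", 1:7)]))
    if (anyNA(pct))
      stop("non-numeric percentage in row '", row$country, "'")
    if (any(pct <= 0))
      stop("every profile must have positive share; violated in row '",
           row$country, "'")
    if (abs(sum(pct) - 100) > 0.1)
      stop("percentages in row '", row$country, "' sum to ",
           format(sum(pct)), ", not 100 (within 0.1)")
  }
  raw$aggregate <- raw$country == "Total sample"
  class(raw) <- c("tp_distributions", "data.frame")
  raw
}

#' Extract one sample's distribution as a named percentage vector
#'
#' @param dists A `tp_distributions` table (or any data frame with the
#'   same columns).
#' @param country Sample name, e.g. `"Sweden"` or `"China-1"`.
#' @return Named numeric vector of 7 percentages with a `country`
#'   attribute.
#' @examples
#' country_distribution(load_country_distributions(), "Sweden")
#' @export
country_distribution <- function(dists, country) {
  hit <- which(dists$country == country)
  if (length(hit) != 1)
    stop("unknown sample '", country, "'; valid names: ",
         paste(dists$country, collapse = ", "))
  pct <- as.numeric(dists[hit, paste0("t", 1:7)])
  names(pct) <- paste0("t", 1:7)
  attr(pct, "country") <- country
  pct
}

#' Apportion a percentage distribution into integer type counts
#'
#' Largest-remainder (Hamilton) apportionment of `pct * n / 100`: each
#' type first receives the floor of its quota, then the remaining seats
#' go to the largest fractional remainders, ties broken in favour of the
#' lower type id. Deterministic: the same (distribution, n) always gives
#' the same counts.
#'
#' @param pct Numeric vector of 7 positive percentages (summing to 100
#'   within 0.1).
#' @param n Village size, an integer >= 7.
#' @return Integer vector of 7 counts summing exactly to `n`.
#' @examples
#' sweden <- country_distribution(load_country_distributions(), "Sweden")
#' allocate_type_counts(sweden, 150)
#' @export
allocate_type_counts <- function(pct, n) {
  stopifnot(length(pct) == 7, is.numeric(pct))
  if (any(pct <= 0))
    stop("every profile must have a positive percentage")
  if (abs(sum(pct) - 100) > 0.1)
    stop("percentages must sum to 100 within 0.1")
  if (n < 7)
    stop("village size must be at least 7 so every profile is represented")
  quota <- pct * n / 100
  base <- floor(quota)
  rem <- quota - base
  seats <- n - sum(base)
  counts <- as.integer(base)
  if (seats > 0) {
    ord <- order(-rem, seq_len(7))  # largest remainder, then lower id
    counts[ord[seq_len(seats)]] <- counts[ord[seq_len(seats)]] + 1L
  }
  stopifnot(sum(counts) == n)
  names(counts) <- paste0("t", 1:7)
  counts
}

#' Build the initial agent roster of a village
#'
#' Creates `counts[k]` agents of each profile k with their initial
#' states: types 2, 3 and 7 start cooperating, types 1, 4 and 5 start
#' defecting, and each type-6 agent starts cooperating with probability
#' one half (the coin flips consume the session RNG stream, so a seed
#' set before the call makes the roster reproducible). All habit timers
#' start at zero.
#'
#' @param counts Integer vector of 7 type counts.
#' @return Data frame with columns `id`, `type`, `state`, `timer`.
#' @examples
#' set.seed(1)
#' village <- build_village(c(23, 28, 32, 15, 31, 12, 9))
#' table(village$type, village$state)
#' @export
build_village <- function(counts) {
  stopifnot(length(counts) == 7, all(counts >= 0),
            all(counts == as.integer(counts)))
  type <- rep(1:7, times = counts)
  n <- length(type)
  init <- tp_profiles()$initial_state[type]
  state <- ifelse(init == "coin",
                  ifelse(stats::runif(n) < 0.5, "C", "D"),
                  init)
  agents <- data.frame(id = seq_len(n), type = as.integer(type),
                       state = state, timer = 0L,
                       stringsAsFactors = FALSE)
  check_agents(agents)
}

#' Draw a synthetic profile distribution
#'
#' Samples seven strictly positive percentages summing to 100 from a
#' symmetric Dirichlet distribution (via normalised gamma draws). Used
#' to generate test fixtures and hypothetical populations; larger
#' `concentration` pulls the draw towards the uniform 100/7 split.
#'
#' @param concentration Positive Dirichlet concentration parameter.
#' @return Named numeric vector of 7 percentages summing to 100.
#' @examples
#' set.seed(42)
#' synthesize_distribution(concentration = 50)
#' @export
synthesize_distribution <- function(concentration = 10) {
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      is.na(concentration) || concentration <= 0)
    stop("concentration must be a positive number")
  g <- stats::rgamma(7, shape = concentration, rate = 1)
  # guard against numerically-zero gamma draws at tiny concentration
  while (any(g == 0)) g <- stats::rgamma(7, shape = concentration, rate = 1)
  pct <- 100 * g / sum(g)
  names(pct) <- paste0("t", 1:7)
  pct
}

#' Write distributions in the packaged CSV dialect
#'
#' @param dists Data frame with columns `country`, `t1`..`t7`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distributions <- function(dists, path) {
  utils::write.csv(dists[, c("country", paste0("t", 1:7))], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
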