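#' Per-type learning curves over the habit duration d
#'
#' For each habit duration in `d_values`, simulates the village and
#' records the final-day cooperator fraction of each profile, averaged
#' over replicates. The unconditional cooperators (types 2, 3, 7) are
#' constant at 1; the curves of interest are types 1, 4, 5 and 6.
#'
#' @param pct 7-vector of profile percentages (e.g. from
#'   [country_distribution()]).
#' @param h Policing efficiency, held fixed.
#' @param d_values Positive integer habit durations to scan.
#' @param n_reps Replicates per duration.
#' @param n_agents,n_days Village size and length of each run.
#' @param base_seed Seed base; the same replicate seeds are reused for
#'   every `d` (common random numbers).
#' @param counts Logical; treat `pct` as integer type counts instead of
#'   percentages (see [sim_config()]).
#' @return Data frame with columns `d`, `type`, `mean`, `se` where
#'   `mean` is the final-day cooperator fraction of the profile.
#' @examples
#' \donttest{
#' sweden <- country_distribution(load_country_distributions(), "Sweden")
#' lc <- learning_curves(sweden, h = 0.5, d_values = c(1, 5, 10),
#'                       n_reps = 20)
#' }
#' @export
learning_curves <- function(pct, h = 0.5, d_values = 1:20, n_reps = 100,
                            n_agents = 150, n_days = 100,
                            base_seed = 2000, counts = FALSE) {
  stopifnot(all(d_values >= 1), all(d_values == as.integer(d_values)))
  out <- lapply(d_values, function(d) {
    cfg <- sim_config(pct, n_agents = n_agents, n_days = n_days,
                      h = h, d = d, counts = counts)
    rs <- run_replicates(cfg, n_reps, base_seed = base_seed)
    last <- n_days + 1L
    data.frame(d = d, type = 1:7,
               mean = as.numeric(rs$by_type_mean[last, ]),
               se = as.numeric(rs$by_type_se[last, ]))
  })
  do.call(rbind, out)
}

#' Sweep the (h, d) control-parameter plane
#'
#' Replicate-mean overall cooperator fraction at the final day for every
#' grid cell, the quantity behind the contour view of the model: raising
#' either the policing efficiency or the habit duration raises overall
#' cooperation, with saturation in `d` at low `h`.
#'
#' @inheritParams learning_curves
#' @param h_grid Policing efficiencies in \[0, 1\].
#' @param d_grid Positive integer habit durations.
#' @return Data frame of class `tp_sweep` with columns `h`, `d`, `mean`,
#'   `se`.
#' @export
sweep_hd <- function(pct, h_grid, d_grid, n_reps = 100, n_agents = 150,
                     n_days = 100, base_seed = 3000, counts = FALSE) {
  stopifnot(length(h_grid) >= 1, length(d_grid) >= 1,
            all(h_grid >= 0 & h_grid <= 1), all(d_grid >= 1))
  grid <- expand.grid(d = d_grid, h = h_grid)[, c("h", "d")]
  res <- mapply(function(h, d) {
    cfg <- sim_config(pct, n_agents = n_agents, n_days = n_days,
                      h = h, d = d, counts = counts)
    rs <- run_replicates(cfg, n_reps, base_seed = base_seed)
    last <- n_days + 1L
    c(rs$overall_mean[last], rs$overall_se[last])
  }, grid$h, grid$d)
  grid$mean <- res[1, ]
  grid$se <- res[2, ]
  class(grid) <- c("tp_sweep", "data.frame")
  grid
}

#' Fit the exponential saturation curve y(d) = C + B exp(-d F)
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of the
#' equilibrium model: `C` is the limiting cooperation level as the habit
#' duration d grows, `B` the initial offset (y(0) = C + B) and `F` the
#' steepness of the approach. Three fixed starting points guard against
#' the flat-likelihood region at small `F`; the best converged fit wins.
#' A near-constant series short-circuits to `C = mean(y)`, `B = 0`
#' (the exponential is unidentifiable there).
#'
#' @param d_values Distinct positive durations (>= 4 points).
#' @param y_values Cooperation fractions observed at `d_values`.
#' @return Object of class `tp_eqfit`: list with `C`, `B`, `F`,
#'   `residual_norm`, `converged`, plus the input data. `C` outside
#'   \[0, 1\] is flagged via a warning for cooperation data.
#' @examples
#' d <- 1:20
#' fit_equilibrium(d, 0.9 - 0.2 * exp(-d * 0.5))
#' @export
fit_equilibrium <- function(d_values, y_values) {
  stopifnot(length(d_values) == length(y_values))
  if (length(d_values) < 4) stop("need at least 4 points to fit")
  if (any(d_values <= 0)) stop("d values must be positive")
  if (anyDuplicated(d_values)) stop("d values must be distinct")
  d <- as.numeric(d_values); y <- as.numeric(y_values)

  done <- function(C, B, F, rn, conv) {
    if (conv && (C < -1e-8 || C > 1 + 1e-8))
      warning("fitted equilibrium level C = ", format(C),
              " lies outside [0, 1]")
    structure(list(C = C, B = B, F = F, residual_norm = rn,
                   converged = conv, d = d, y = y),
              class = "tp_eqfit")
  }

  if (stats::sd(y) < 1e-12)
    return(done(mean(y), 0, NA_real_, 0, TRUE))

  starts <- list(c(B = y[1] - mean(y), F = 0.1),
                 c(B = y[1] - y[length(y)], F = 0.5),
                 c(B = -0.5, F = 1))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ C + B * exp(-d * F),
        start = c(C = mean(y[d >= stats::median(d)]), s),
        lower = c(C = 0, B = -2, F = 1e-4),
        upper = c(C = 1.5, B = 2, F = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::residuals(fit)^2))
    if (is.null(best) || rn < best$rn)
      best <- list(coef = stats::coef(fit), rn = rn)
  }
  if (is.null(best))
    return(done(NA_real_, NA_real_, NA_real_, NA_real_, FALSE))
  co <- best$coef
  done(unname(co["C"]), unname(co["B"]), unname(co["F"]), best$rn, TRUE)
}

#' @export
print.tp_eqfit <- function(x, ...) {
  cat("Equilibrium fit y(d) = C + B exp(-d F)\n")
  cat(sprintf("  C = %.4f  B = %.4f  F = %s  (residual norm %.2e%s)\n",
              x$C, x$B,
              if (is.na(x$F)) "NA" else sprintf("%.4f", x$F),
              x$residual_norm,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Evaluate a fitted equilibrium curve
#'
#' @param object A `tp_eqfit`.
#' @param d Durations at which to evaluate; defaults to the fitted ones.
#' @param ... Unused.
#' @return Predicted cooperation fractions.
#' @export
predict.tp_eqfit <- function(object, d = object$d, ...) {
  if (is.na(object$F)) rep(object$C, length(d))
  else object$C + object$B * exp(-d * object$F)
}

#' Cooperation index of a profile distribution
#'
#' Simulates the final-day overall cooperator fraction for habit
#' durations d = 1..d_max at fixed policing efficiency `h`, fits the
#' saturation curve [fit_equilibrium()], and returns the fit. The
#' cooperation index is the fitted equilibrium level `C`: the limiting
#' cooperation the population would reach with arbitrarily durable
#' habits.
#'
#' @inheritParams learning_curves
#' @param d_max Largest habit duration scanned (>= 4).
#' @return A `tp_eqfit` whose `C` slot is the cooperation index; the
#'   per-duration means are kept in `$y`.
#' @export
cooperation_index <- function(pct, h = 0.5, d_max = 20, n_reps = 100,
                              n_agents = 150, n_days = 100,
                              base_seed = 4000, counts = FALSE) {
  if (d_max < 4) stop("d_max must be at least 4")
  d_values <- seq_len(d_max)
  y <- vapply(d_values, function(d) {
    cfg <- sim_config(pct, n_agents = n_agents, n_days = n_days,
                      h = h, d = d, counts = counts)
    rs <- run_replicates(cfg, n_reps, base_seed = base_seed)
    rs$overall_mean[n_days + 1L]
  }, numeric(1))
  fit_equilibrium(d_values, y)
}

#' Rank country samples by cooperation index
#'
#' Computes [cooperation_index()] for every sample and orders the table
#' by descending index, ties broken alphabetically. All samples share
#' the same replicate seed set (common random numbers), which sharpens
#' between-country contrasts without changing any one country's
#' expectation. The aggregate "Total sample" row is excluded by default.
#'
#' @param dists A `tp_distributions` table from
#'   [load_country_distributions()], or any data frame with columns
#'   `country`, `t1`..`t7`.
#' @inheritParams cooperation_index
#' @param include_aggregate Keep rows flagged as aggregates?
#' @return Data frame with columns `country`, `index` (= fitted C),
#'   `B`, `F`, `converged`, ordered by decreasing index.
#' @export
rank_countries <- function(dists, h = 0.5, d_max = 20, n_reps = 100,
                           n_agents = 150, n_days = 100,
                           base_seed = 4000, include_aggregate = FALSE) {
  stopifnot(nrow(dists) >= 1)
  if (!include_aggregate && "aggregate" %in% names(dists))
    dists <- dists[!dists$aggregate, , drop = FALSE]
  rows <- lapply(seq_len(nrow(dists)), function(i) {
    pct <- as.numeric(dists[i, paste0("t", 1:7)])
    fit <- cooperation_index(pct, h = h, d_max = d_max, n_reps = n_reps,
                             n_agents = n_agents, n_days = n_days,
                             base_seed = base_seed)
    data.frame(country = dists$country[i], index = fit$C, B = fit$B,
               F = fit$F, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$index, out$country), , drop = FALSE]
  rownames(out) <- NULL
  out
}
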