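#' Plot a cooperation time series
#'
#' Overall and per-type cooperator fractions against time, on a
#' logarithmic day axis (day 0 is dropped for the log scale).
#'
#' @param x A `tp_timeseries` or `tp_timeseries_summary`.
#' @param types Profile ids to draw alongside the overall curve.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.tp_timeseries <- function(x, types = 1:7, ...) {
  keep <- x$day >= 1
  y <- cbind(all = x$overall[keep], x$by_type[keep, types, drop = FALSE])
  graphics::matplot(x$day[keep], y, type = "l", log = "x", lty = 1,
                    col = c("black", grDevices::hcl.colors(length(types))),
                    xlab = "day", ylab = "fraction of cooperators",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = c("all", paste0("type ", types)),
                   lty = 1, cex = 0.7,
                   col = c("black", grDevices::hcl.colors(length(types))))
  invisible(x)
}

#' @rdname plot.tp_timeseries
#' @export
plot.tp_timeseries_summary <- function(x, types = 1:7, ...) {
  keep <- x$day >= 1
  y <- cbind(all = x$overall_mean[keep],
             x$by_type_mean[keep, types, drop = FALSE])
  graphics::matplot(x$day[keep], y, type = "l", log = "x", lty = 1,
                    col = c("black", grDevices::hcl.colors(length(types))),
                    xlab = "day", ylab = "fraction of cooperators",
                    ylim = c(0, 1), ...)
  invisible(x)
}

#' Contour view of an (h, d) parameter sweep
#'
#' @param x A `tp_sweep` from [sweep_hd()].
#' @param ... Passed to [graphics::filled.contour()].
#' @return `x`, invisibly.
#' @export
plot.tp_sweep <- function(x, ...) {
  hs <- sort(unique(x$h)); ds <- sort(unique(x$d))
  z <- matrix(NA_real_, length(ds), length(hs))
  z[cbind(match(x$d, ds), match(x$h, hs))] <- x$mean
  graphics::filled.contour(ds, hs, z, xlab = "d (days)",
                           ylab = "h (policing efficiency)", ...)
  invisible(x)
}

#' Bar view of a country ranking
#'
#' @param ranking Output of [rank_countries()].
#' @param ... Passed to [graphics::barplot()].
#' @return The ranking, invisibly.
#' @export
plot_ranking <- function(ranking, ...) {
  graphics::barplot(rev(ranking$index), names.arg = rev(ranking$country),
                    horiz = TRUE, las = 1, cex.names = 0.6,
                    xlab = "cooperation index (fitted C)", ...)
  invisible(ranking)
}
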