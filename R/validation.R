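#' Correlate the cooperation index with country-level indicators
#'
#' Pairwise-complete Pearson correlations between the simulated
#' cooperation index and user-supplied indicators (e.g. HDI, EPI,
#' Hofstede culture dimensions, democracy scores). Indicator values are
#' not bundled: editions drift and licences vary, so the user provides
#' a CSV with a `country` column matching the index names (after any
#' explicit aliasing, see [average_duplicate_samples()]).
#'
#' Missing values are handled by pairwise deletion, and the number of
#' complete pairs behind every cell is reported. Cells with fewer than
#' 3 complete pairs or a zero-variance variable are `NA` and flagged.
#'
#' @param index_by_country Named numeric vector: cooperation index per
#'   country.
#' @param indicators Data frame with a `country` column and one numeric
#'   column per indicator; missing values allowed.
#' @return List of class `tp_correlations` with matrices `r`, `n`,
#'   `p` over variables `index` + each indicator, and a character
#'   vector `flagged` naming undefined cells.
#' @examples
#' idx <- c(A = 0.8, B = 0.6, C = 0.9)
#' ind <- data.frame(country = c("A", "B", "C"), hdi = c(0.8, 0.7, 0.9))
#' correlate_index(idx, ind)$r
#' @export
correlate_index <- function(index_by_country, indicators) {
  stopifnot(!is.null(names(index_by_country)),
            "country" %in% names(indicators))
  common <- intersect(names(index_by_country), indicators$country)
  if (length(common) < 3)
    stop("need at least 3 countries shared between index and indicators")
  vars <- setdiff(names(indicators), "country")
  m <- cbind(index = index_by_country[common],
             as.matrix(indicators[match(common, indicators$country),
                                  vars, drop = FALSE]))
  k <- ncol(m)
  r <- n <- p <- matrix(NA_real_, k, k,
                        dimnames = list(colnames(m), colnames(m)))
  flagged <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(m[, i], m[, j])
    n[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; next }
    lab <- paste(colnames(m)[i], colnames(m)[j], sep = " ~ ")
    if (sum(ok) < 3) {
      flagged <- c(flagged, paste0(lab, " (fewer than 3 complete pairs)"))
      next
    }
    if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) {
      flagged <- c(flagged, paste0(lab, " (zero variance)"))
      next
    }
    ct <- stats::cor.test(m[ok, i], m[ok, j])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  structure(list(r = r, n = n, p = p, flagged = unique(flagged)),
            class = "tp_correlations")
}

#' @export
print.tp_correlations <- function(x, digits = 2, ...) {
  cat("Pairwise Pearson correlations (pairwise-complete):\n")
  print(round(x$r, digits))
  if (length(x$flagged))
    cat("Undefined cells:", paste(x$flagged, collapse = "; "), "\n")
  invisible(x)
}

#' Quadratic regression of the index on uncertainty avoidance
#'
#' Ordinary least squares of the cooperation index on an indicator and
#' its square, the test for an inverted-U association: a negative
#' quadratic coefficient means cooperation peaks at intermediate
#' indicator values. Reports the overall-model F statistic with
#' (2, n - 3) degrees of freedom and the R-squared.
#'
#' @param index_by_country Named numeric vector of cooperation indices.
#' @param ua_scores Named numeric vector of indicator scores (e.g.
#'   Hofstede uncertainty avoidance), matched by name.
#' @return List of class `tp_quadfit`: `F`, `df1`, `df2`, `p`,
#'   `r_squared`, `coefficients` (intercept, linear, quadratic),
#'   `inverted_u` (logical), `n`, and the underlying `lm` fit.
#' @export
quadratic_fit <- function(index_by_country, ua_scores) {
  stopifnot(!is.null(names(index_by_country)), !is.null(names(ua_scores)))
  common <- intersect(names(index_by_country), names(ua_scores))
  dat <- data.frame(idx = index_by_country[common],
                    ua = ua_scores[common])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 5) stop("need at least 5 complete pairs")
  if (stats::sd(dat$ua) == 0)
    stop("degenerate input: indicator has zero variance")
  fit <- stats::lm(idx ~ ua + I(ua^2), data = dat)
  if (anyNA(stats::coef(fit)))
    stop("degenerate input: collinear design (too few distinct values)")
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(F = unname(fstat["value"]),
                 df1 = unname(fstat["numdf"]), df2 = unname(fstat["dendf"]),
                 p = unname(stats::pf(fstat["value"], fstat["numdf"],
                                      fstat["dendf"], lower.tail = FALSE)),
                 r_squared = sm$r.squared,
                 coefficients = stats::coef(fit),
                 inverted_u = unname(stats::coef(fit)[3] < 0),
                 n = n, fit = fit),
            class = "tp_quadfit")
}

#' @export
print.tp_quadfit <- function(x, ...) {
  cat(sprintf(
    "Quadratic fit: F(%d, %d) = %.2f, p = %.3g, R^2 = %.2f, %s association\n",
    x$df1, x$df2, x$F, x$p, x$r_squared,
    if (x$inverted_u) "inverted-U" else "U-shaped / convex"))
  invisible(x)
}

#' Collapse duplicate country samples to one index per country
#'
#' Some countries contribute two survey samples (e.g. `China-1` and
#' `China-2`). For correlation against one-row-per-country indicators
#' the duplicate indices must be collapsed; the mapping is explicit --
#' the package does not guess -- and the collapsed value is the mean of
#' the mapped samples.
#'
#' @param index_by_sample Named numeric vector, one entry per sample.
#' @param sample_to_country Named character vector mapping sample names
#'   to country names, e.g. `c("China-1" = "China", "China-2" = "China")`.
#'   Samples not named in the map keep their own name.
#' @return Named numeric vector with one entry per country.
#' @examples
#' average_duplicate_samples(
#'   c("China-1" = 0.5, "China-2" = 0.6, Sweden = 0.7),
#'   c("China-1" = "China", "China-2" = "China"))
#' @export
average_duplicate_samples <- function(index_by_sample, sample_to_country) {
  stopifnot(!is.null(names(index_by_sample)))
  nm <- names(index_by_sample)
  mapped <- ifelse(nm %in% names(sample_to_country),
                   sample_to_country[nm], nm)
  out <- tapply(index_by_sample, mapped, mean)
  res <- as.numeric(out)
  names(res) <- names(out)
  res
}
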