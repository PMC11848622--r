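# Compositional Dispersity Index: how tightly the per-chain composition
# scatter hugs the ideal stoichiometric line through the origin.
#
# The statistic is R^2 about a FIXED line (no fitting): residuals are taken
# against the line's predictions while the total sum of squares is about
# the sample mean of y. This R^2 can be negative when the scatter is wider
# than the line explains, which is exactly what makes |1/R^2| > 1 a useful
# dispersity scale.

#' Slope of the ideal copolymer line
#'
#' For a feed of (major, minor) mole fractions, a compositionally ideal
#' chain has minor/major counts in the feed ratio, so the ideal line
#' through the origin in (major count, minor count) space has slope
#' minor_fraction / major_fraction (e.g. 0.23/0.77 = 0.299).
#'
#' @param major_fraction,minor_fraction Positive fractions summing to 1.
#' @return The slope (dimensionless).
#' @export
#' @examples
#' ideal_slope(0.77, 0.23)   # 0.299 to 3 decimals
ideal_slope <- function(major_fraction, minor_fraction) {
  check_number(major_fraction, "major_fraction")
  check_number(minor_fraction, "minor_fraction")
  if (major_fraction <= 0) stopf("major_fraction must be positive")
  if (minor_fraction <= 0) stopf("minor_fraction must be positive")
  if (abs(major_fraction + minor_fraction - 1) > 1e-9) {
    stopf("fractions must sum to 1")
  }
  minor_fraction / major_fraction
}

#' Coefficient of determination about a fixed origin line
#'
#' R^2 = 1 - sum((y_i - s x_i)^2) / sum((y_i - mean(y))^2) where `s` is the
#' given slope. No parameter is fitted; values below 0 (gross misfit) are
#' legitimate and returned as-is.
#'
#' @param x,y Non-negative counts of the major and minor monomer per chain
#'   (`>= 3` points).
#' @param slope Positive slope of the ideal line through the origin.
#' @return R^2 (a real `<= 1`, possibly negative).
#' @export
#' @examples
#' r_squared_about_line(c(10, 20, 10), c(3, 6, 5), 0.3)
r_squared_about_line <- function(x, y, slope) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 points")
  if (any(x < 0) || any(y < 0)) stopf("counts must be non-negative")
  check_number(slope, "slope", positive = TRUE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stopf("degenerate scatter: all y values identical (zero total sum of squares)")
  }
  1 - sum((y - slope * x)^2) / ss_tot
}

#' Compositional dispersity index
#'
#' CDI = |1 / R^2| with R^2 taken about the ideal line
#' ([r_squared_about_line]). CDI = 1 means every chain sits exactly on the
#' ideal composition; larger values mean broader per-chain compositional
#' scatter, on a scale analogous to molecular-weight dispersity. A scatter
#' with R^2 = 0 yields `cdi = Inf` (flagged, not an error).
#'
#' @inheritParams r_squared_about_line
#' @return A `cdi_result` list: `r_squared`, `cdi`, `slope`, `n_chains`.
#' @export
#' @examples
#' cdi(c(10, 20, 10), c(3, 6, 5), 0.3)   # CDI = 7.00
cdi <- function(x, y, slope) {
  r2 <- r_squared_about_line(x, y, slope)
  value <- if (r2 == 0) Inf else abs(1 / r2)
  structure(list(r_squared = r2, cdi = value, slope = slope,
                 n_chains = length(x)),
            class = "cdi_result")
}

#' @export
print.cdi_result <- function(x, ...) {
  cat(sprintf("CDI = %.2f  (R^2 = %.4f about line y = %.4g x, n = %d chains)\n",
              x$cdi, x$r_squared, x$slope, x$n_chains))
  invisible(x)
}

#' CDI of a simulated chain ensemble
#'
#' Convenience wrapper: takes the per-chain (major count, minor count)
#' scatter from a [simulate_ensemble] result and the ideal-line slope from
#' the feed fractions, then computes [cdi]. The major monomer (x axis) is
#' the one with the larger feed fraction.
#'
#' @param ensemble A `chain_ensemble` or an ensemble chains data frame.
#' @param slope Optional slope override; default is [ideal_slope] of the
#'   config feed fractions (only available for a full `chain_ensemble`).
#' @param digits Rounding applied to the default slope, mirroring the
#'   3-decimal convention of the printed ideal slope (0.299). Use `NULL`
#'   for the exact ratio.
#' @return A `cdi_result`.
#' @export
cdi_of_ensemble <- function(ensemble, slope = NULL, digits = 3) {
  if (inherits(ensemble, "chain_ensemble")) {
    chains <- ensemble$chains
    feeds <- vapply(ensemble$config$monomers, `[[`, numeric(1),
                    "feed_fraction")
    major <- which.max(feeds)
  } else {
    chains <- ensemble
    ccols <- which(startsWith(names(chains), "count_"))
    major <- which.max(colSums(chains[ccols]))
    feeds <- colSums(chains[ccols]) / sum(chains[ccols])
  }
  ccols <- which(startsWith(names(chains), "count_"))
  minor <- setdiff(seq_along(ccols), major)
  if (is.null(slope)) {
    s <- ideal_slope(max(feeds), min(feeds))
    slope <- if (is.null(digits)) s else round(s, digits)
  }
  cdi(chains[[ccols[major]]], chains[[ccols[minor]]], slope)
}

#' Write a CDI result as a one-row CSV
#'
#' Columns: `n_chains,slope,r_squared,cdi`.
#'
#' @param result A `cdi_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cdi_csv <- function(result, path) {
  stopifnot(inherits(result, "cdi_result"))
  df <- data.frame(n_chains = result$n_chains, slope = result$slope,
                   r_squared = result$r_squared, cdi = result$cdi)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
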