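# T10 aggregation-onset extraction from turbidity (A540) time series.
#
# Convention: the threshold is anchored to the initial reading, i.e.
# threshold = baseline + 0.10 * (max - baseline). With a zero blank this is
# exactly "10% of maximum absorbance"; with a non-zero plate blank it stays
# robust to the instrument offset. T10 is the first threshold crossing,
# linearly interpolated between the bracketing samples.

#' Construct a turbidity assay curve
#'
#' @param times Sampling times in hours, strictly increasing, `>= 2` points.
#' @param absorbance Absorbance at 540 nm, finite, same length as `times`.
#' @param replicate_id Identifier of the technical replicate.
#' @param metadata Optional named list (formulation label, excipient
#'   concentration, temperature, ...).
#' @return An `assay_curve` list.
#' @export
assay_curve <- function(times, absorbance, replicate_id = 1L,
                        metadata = list()) {
  if (length(times) < 2L) stopf("need at least 2 samples")
  if (length(absorbance) != length(times)) {
    stopf("times and absorbance must have equal length")
  }
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (!all(is.finite(absorbance))) stopf("absorbance must be finite")
  structure(list(times = as.numeric(times),
                 absorbance = as.numeric(absorbance),
                 replicate_id = replicate_id, metadata = metadata),
            class = "assay_curve")
}

#' T10 aggregation-onset time of a turbidity curve
#'
#' The onset of aggregation is the time at which absorbance first reaches
#' 10% of its maximum rise above baseline: with baseline `b` (the t = 0
#' reading) and maximum `m`, threshold = `b + 0.10 (m - b)`; the crossing
#' time is linearly interpolated between the bracketing samples. A curve
#' that never rises (`m == b`) carries no aggregation signal and is
#' reported censored at the last time point. Later re-crossings are
#' ignored.
#'
#' @param curve An [assay_curve].
#' @return An `aggregation_result` list: `t10` (hours), `max_absorbance`,
#'   `threshold_absorbance`, `censored` (logical), `replicate_id`.
#' @export
#' @examples
#' t10_time(assay_curve(0:20, (0:20) / 20))   # linear ramp: t10 = 2 h
t10_time <- function(curve) {
  stopifnot(inherits(curve, "assay_curve"))
  a <- curve$absorbance
  t <- curve$times
  baseline <- a[1]
  m <- max(a)
  if (m <= baseline) {
    return(structure(list(t10 = t[length(t)], max_absorbance = m,
                          threshold_absorbance = NA_real_, censored = TRUE,
                          replicate_id = curve$replicate_id),
                     class = "aggregation_result"))
  }
  threshold <- baseline + 0.10 * (m - baseline)
  idx <- which(a >= threshold)[1]
  t10 <- if (idx == 1L) {
    0
  } else {
    t[idx - 1] + (threshold - a[idx - 1]) / (a[idx] - a[idx - 1]) *
      (t[idx] - t[idx - 1])
  }
  structure(list(t10 = t10, max_absorbance = m,
                 threshold_absorbance = threshold, censored = FALSE,
                 replicate_id = curve$replicate_id),
            class = "aggregation_result")
}

#' @export
print.aggregation_result <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("T10: censored at %.2f h (no rise above baseline)\n", x$t10))
  } else {
    cat(sprintf("T10 = %.2f h (threshold A540 = %.4f, max = %.4f)\n",
                x$t10, x$threshold_absorbance, x$max_absorbance))
  }
  invisible(x)
}

#' Replicate mean and standard error of T10
#'
#' Censored replicates (curves that never crossed threshold) are excluded
#' with a message; the mean and SEM (sample SD / sqrt(n)) are computed over
#' the remainder. With a single usable replicate the SEM is undefined (NA).
#'
#' @param results List of `aggregation_result` objects (or a numeric vector
#'   of T10 values).
#' @return List: `mean_t10`, `sem_t10`, `n`, `n_censored`.
#' @export
#' @examples
#' aggregate_replicates(c(11, 12, 13, 14))
aggregate_replicates <- function(results) {
  if (is.numeric(results)) {
    t10 <- results
    cens <- rep(FALSE, length(results))
  } else {
    t10 <- vapply(results, `[[`, numeric(1), "t10")
    cens <- vapply(results, `[[`, logical(1), "censored")
  }
  if (length(t10) < 1L) stopf("need at least one replicate")
  n_cens <- sum(cens)
  if (n_cens > 0) {
    message(sprintf("excluding %d censored replicate(s)", n_cens))
    t10 <- t10[!cens]
  }
  if (length(t10) == 0L) stopf("all replicates censored")
  list(mean_t10 = mean(t10), sem_t10 = sem(t10),
       n = length(t10), n_censored = n_cens)
}

#' Fold change in aggregation time
#'
#' @param test,reference Mean T10 values (hours); `reference > 0`.
#' @return The dimensionless ratio `test / reference`.
#' @export
#' @examples
#' fold_change(24.37, 12.08)   # ~2-fold from end-group optimization
fold_change <- function(test, reference) {
  check_number(test, "test")
  check_number(reference, "reference")
  if (reference <= 0) stopf("reference T10 must be positive")
  test / reference
}

#' Read turbidity assay curves from CSV
#'
#' Expects long format with a header and columns `time_h`, `a540`,
#' `replicate` (comma-separated, decimal point); one file per formulation.
#'
#' @param path CSV file path.
#' @param metadata Optional named list attached to every curve.
#' @return A list of [assay_curve] objects, one per replicate.
#' @export
read_assay_csv <- function(path, metadata = list()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "a540", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("assay CSV missing column(s): %s",
                          paste(miss, collapse = ", "))
  lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$time_h), ]
    assay_curve(d$time_h, d$a540, replicate_id = d$replicate[1],
                metadata = metadata)
  })
}

#' Write aggregation results as CSV
#'
#' @param results List of `aggregation_result` objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_aggregation_csv <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(replicate = r$replicate_id, t10_h = r$t10,
               max_absorbance = r$max_absorbance,
               threshold_absorbance = r$threshold_absorbance,
               censored = r$censored)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
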