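# Dynamic surface-tension analysis: one-phase exponential-decay fit of the
# early equilibration transient (rate constant k) and the late-time
# equilibrium tension.
#
# Model: gamma(t) = gamma_eq + (gamma0 - gamma_eq) * exp(-k t).
# The fit is a damped Gauss-Newton least-squares iteration written out
# explicitly so the initialization and convergence contract is under our
# control (and can be cross-checked against an independent grid-search
# oracle). The (gamma0, gamma_eq, k) parameterization makes the fitted
# plateau directly comparable to the raw 5000-s equilibrium tension.

#' Construct a surface-tension trace
#'
#' @param times Seconds, strictly increasing from about 0; `>= 10` samples.
#' @param tension Surface tension in mN/m, positive and finite.
#' @param label Trace label (e.g. formulation name).
#' @param concentration Solute concentration in wt.% (informational).
#' @return A `tension_trace` list.
#' @export
tension_trace <- function(times, tension, label = "", concentration = NA) {
  if (length(times) < 10L) stopf("need at least 10 samples")
  if (length(tension) != length(times)) {
    stopf("times and tension must have equal length")
  }
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (!all(is.finite(tension)) || any(tension <= 0)) {
    stopf("tension must be positive and finite")
  }
  structure(list(times = as.numeric(times), tension = as.numeric(tension),
                 label = label, concentration = concentration),
            class = "tension_trace")
}

# Model prediction and residuals.
decay_model <- function(p, t) p[2] + (p[1] - p[2]) * exp(-p[3] * t)

#' Fit a one-phase exponential decay to a tension trace
#'
#' Minimizes the sum of squared residuals of
#' `gamma_eq + (gamma0 - gamma_eq) exp(-k t)` over `(gamma0, gamma_eq, k)`
#' by damped Gauss-Newton iteration with analytic Jacobian.
#' Initialization: `gamma0` = first sample in window, `gamma_eq` = last
#' sample in window, `k = ln(2) / (window midpoint)`. Convergence when the
#' relative SSE change drops below 1e-10, capped at 500 iterations;
#' non-convergence is reported in the `converged` flag rather than by
#' error. A trace that rises instead of decays triggers a sign-anomaly
#' warning but is still fitted; a flat trace is flagged degenerate with
#' `k = NA`.
#'
#' @param trace A [tension_trace].
#' @param window Numeric `c(start, end)` in seconds; default `c(0, 300)`,
#'   the early transient over which the single-exponential model holds.
#' @return A `surface_fit` list: `gamma0`, `gamma_eq`, `k` (1/s),
#'   `fit_window`, `sse`, `converged`, `degenerate`, `sign_anomaly`,
#'   `unreliable`, `iterations`, `label`.
#' @export
#' @examples
#' t <- 0:300
#' tr <- tension_trace(t, 50 + 22 * exp(-0.005 * t))
#' fit_exponential_decay(tr)
fit_exponential_decay <- function(trace, window = c(0, 300)) {
  stopifnot(inherits(trace, "tension_trace"))
  if (length(window) != 2L || window[2] <= window[1]) {
    stopf("`window` must be c(start, end) seconds with end > start")
  }
  inw <- trace$times >= window[1] & trace$times <= window[2]
  t <- trace$times[inw]
  y <- trace$tension[inw]
  if (length(t) < 3L) stopf("need at least 3 samples inside the fit window")

  out <- list(fit_window = window, label = trace$label,
              degenerate = FALSE, sign_anomaly = FALSE, unreliable = FALSE)
  if (max(y) - min(y) < .Machine$double.eps^0.5 * max(abs(y))) {
    # flat trace (e.g. pure buffer): no decay to fit
    out <- c(out, list(gamma0 = y[1], gamma_eq = mean(y), k = NA_real_,
                       sse = sum((y - mean(y))^2), converged = TRUE,
                       iterations = 0L))
    out$degenerate <- TRUE
    return(structure(out, class = "surface_fit"))
  }
  if (y[length(y)] > y[1]) {
    warning("tension rises over the fit window (sign anomaly); ",
            "fit returned but the decay model may not apply")
    out$sign_anomaly <- TRUE
  }

  p <- c(y[1], y[length(y)], log(2) / mean(window))
  resid <- y - decay_model(p, t)
  sse <- sum(resid^2)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < 500L) {
    iter <- iter + 1L
    e <- exp(-p[3] * t)
    jac <- cbind(e, 1 - e, -(p[1] - p[2]) * t * e)
    g <- crossprod(jac, resid)
    h <- crossprod(jac)
    step <- tryCatch(
      solve(h + lambda * diag(diag(h), nrow = 3L), g),
      error = function(e) NULL)
    if (is.null(step)) { lambda <- lambda * 10; next }
    cand <- p + as.numeric(step)
    cand[3] <- max(cand[3], 1e-12)      # keep the rate physical
    r_new <- y - decay_model(cand, t)
    sse_new <- sum(r_new^2)
    if (sse_new <= sse) {
      rel <- (sse - sse_new) / max(sse, .Machine$double.xmin)
      p <- cand; resid <- r_new; sse <- sse_new
      lambda <- max(lambda / 10, 1e-12)
      if (rel < 1e-10) { converged <- TRUE; break }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
  }
  out <- c(out, list(gamma0 = p[1], gamma_eq = p[2], k = p[3], sse = sse,
                     converged = converged, iterations = iter))
  if (p[3] <= 1e-10 || p[3] >= 1 / diff(range(t)) * 1e6) out$unreliable <- TRUE
  structure(out, class = "surface_fit")
}

#' @export
print.surface_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Surface fit [%s]: flat trace, gamma = %.3f mN/m, no decay\n",
                x$label, x$gamma_eq))
    return(invisible(x))
  }
  cat(sprintf(
    "Surface fit [%s]: gamma0 = %.3f, gamma_eq = %.3f mN/m, k = %.4g 1/s (%.3f x 1e-3/s)\n",
    x$label, x$gamma0, x$gamma_eq, x$k, rate_in_table_units(x)))
  cat(sprintf("  window [%g, %g] s, SSE = %.4g, converged: %s%s\n",
              x$fit_window[1], x$fit_window[2], x$sse, x$converged,
              if (x$sign_anomaly) " [SIGN ANOMALY]" else ""))
  invisible(x)
}

#' Equilibrium surface tension from the trace tail
#'
#' The plateau tension is the mean of the samples in the final 5% of the
#' time axis (e.g. the last 250 s of a 5000-s trace), with the SEM of those
#' samples as uncertainty. Taken from the raw trace, not the fitted
#' asymptote, because the exponential fit is restricted to early times.
#'
#' @param trace A [tension_trace] whose sampling extends to at least 90% of
#'   its final timestamp (i.e. no large trailing gap).
#' @return List: `gamma_eq` (mN/m), `sem`, `n`.
#' @export
equilibrium_tension <- function(trace) {
  stopifnot(inherits(trace, "tension_trace"))
  t_end <- trace$times[length(trace$times)]
  second_last <- trace$times[length(trace$times) - 1L]
  if (second_last < 0.9 * t_end) {
    stopf("trace does not sample the final 10%% of its time axis")
  }
  tail_idx <- trace$times >= 0.95 * t_end
  y <- trace$tension[tail_idx]
  if (length(y) < 3L) stopf("fewer than 3 samples in the final 5%% tail")
  list(gamma_eq = mean(y), sem = sem(y), n = length(y))
}

#' Rate constant in reporting units
#'
#' Converts a fitted rate constant from 1/s to the tabulated
#' 10^-3 1/s convention, rounded to 3 decimals (so k = 0.004551 1/s reads
#' 4.551).
#'
#' @param fit A `surface_fit` (or a bare k in 1/s).
#' @return k in units of 10^-3 1/s.
#' @export
rate_in_table_units <- function(fit) {
  k <- if (inherits(fit, "surface_fit")) fit$k else fit
  if (!is.finite(k)) stopf("rate constant is not finite")
  round(k * 1e3, 3)
}

#' Read a surface-tension trace from CSV
#'
#' Expects columns `time_s`, `tension_mN_m`, and optionally `replicate`.
#'
#' @param path CSV file path.
#' @param label Trace label.
#' @return A list of [tension_trace] objects (one per replicate; a single
#'   trace if no replicate column).
#' @export
read_tension_csv <- function(path, label = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "tension_mN_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("tension CSV missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$time_s), ]
    tension_trace(d$time_s, d$tension_mN_m, label = label)
  })
}

#' Export a surface fit as JSON
#'
#' Record fields: `label`, `gamma0`, `gamma_eq`, `k_per_s`, `k_1e3_per_s`,
#' `window_s`, `sse`, `converged`.
#'
#' @param fit A `surface_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "surface_fit"))
  rec <- list(label = fit$label, gamma0 = fit$gamma0,
              gamma_eq = fit$gamma_eq, k_per_s = fit$k,
              k_1e3_per_s = if (is.finite(fit$k)) rate_in_table_units(fit) else NA,
              window_s = fit$fit_window, sse = fit$sse,
              converged = fit$converged, degenerate = fit$degenerate)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
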