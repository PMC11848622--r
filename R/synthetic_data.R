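# Seeded generators for every input the pipeline consumes: sigmoidal
# turbidity curves (flat lag, sharp rise, plateau, additive noise),
# exponential-decay tension traces with plateau noise, and the re-entered
# excipient characterization table. Each generator is a pure function of
# its parameter record (seed included), so all downstream stages are
# testable without external data.

#' Parameters for a synthetic turbidity curve
#'
#' The curve is logistic,
#' `A(t) = baseline + amplitude / (1 + exp(-(t - t_mid)/width))` plus
#' additive Gaussian noise clipped at 0 - the lag / sharp-rise / plateau
#' morphology of an agitated insulin aggregation assay read at 540 nm.
#'
#' @param baseline Pre-aggregation absorbance (plate blank), default 0.05.
#' @param amplitude Plateau rise above baseline, default 1.
#' @param t_mid Aggregation midpoint in hours, default 12.
#' @param width Logistic width in hours (rise sharpness), default 0.5.
#' @param noise_sd SD of additive Gaussian noise, default 0.01.
#' @param n_points Number of samples, default 201.
#' @param t_end Last sampling time in hours, default 24.
#' @param seed Integer seed.
#' @return A `turbidity_params` list.
#' @export
turbidity_params <- function(baseline = 0.05, amplitude = 1, t_mid = 12,
                             width = 0.5, noise_sd = 0.01, n_points = 201,
                             t_end = 24, seed = 1L) {
  check_number(amplitude, "amplitude", positive = TRUE)
  check_number(width, "width", positive = TRUE)
  check_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  check_number(t_end, "t_end", positive = TRUE)
  check_number(n_points, "n_points", positive = TRUE)
  structure(list(baseline = baseline, amplitude = amplitude, t_mid = t_mid,
                 width = width, noise_sd = noise_sd,
                 n_points = as.integer(n_points), t_end = t_end,
                 seed = as.integer(seed)),
            class = "turbidity_params")
}

#' Generate a synthetic turbidity curve
#'
#' @param params A [turbidity_params] record.
#' @param replicate_id Replicate identifier stamped on the curve.
#' @return An [assay_curve].
#' @export
#' @examples
#' t10_time(make_turbidity_curve(turbidity_params(noise_sd = 0)))
make_turbidity_curve <- function(params, replicate_id = 1L) {
  stopifnot(inherits(params, "turbidity_params"))
  with_local_seed(params$seed, {
    t <- seq(0, params$t_end, length.out = params$n_points)
    a <- params$baseline +
      params$amplitude / (1 + exp(-(t - params$t_mid) / params$width))
    if (params$noise_sd > 0) {
      a <- pmax(a + stats::rnorm(length(t), 0, params$noise_sd), 0)
    }
    assay_curve(t, a, replicate_id = replicate_id,
                metadata = list(params = unclass(params)))
  })
}

#' Analytic T10 of a noiseless logistic turbidity curve
#'
#' Closed-form threshold crossing of the continuous-time logistic model
#' restricted to the sampled interval `[0, t_end]`: the baseline is the
#' t = 0 reading and the maximum is the t = t_end reading, as the discrete
#' extractor sees them. Used as the independent oracle for [t10_time].
#'
#' @param params A [turbidity_params] record (noise ignored).
#' @return The continuous-time T10 in hours.
#' @export
logistic_t10 <- function(params) {
  stopifnot(inherits(params, "turbidity_params"))
  logis <- function(t) {
    params$baseline +
      params$amplitude / (1 + exp(-(t - params$t_mid) / params$width))
  }
  a0 <- logis(0)
  amax <- logis(params$t_end)
  thr <- a0 + 0.10 * (amax - a0)
  # invert: thr = baseline + amplitude / (1 + exp(-(t - t_mid)/width))
  frac <- (thr - params$baseline) / params$amplitude
  if (frac <= 0 || frac >= 1) stopf("threshold outside the logistic range")
  params$t_mid - params$width * log(1 / frac - 1)
}

#' Parameters for a synthetic surface-tension trace
#'
#' `gamma(t) = gamma_eq + (gamma0 - gamma_eq) exp(-k t)` plus Gaussian
#' plateau noise. Defaults emulate a 0.02 wt.% surfactant trace: start at
#' the clean-buffer tension 71.96 mN/m, equilibrate near 50 mN/m with
#' k of a few 1e-3 1/s over 5000 s. A buffer-only control is
#' `gamma0 = gamma_eq = 71.96` (no decay).
#'
#' @param gamma0 Tension at t = 0 in mN/m, default 71.96.
#' @param gamma_eq Plateau tension in mN/m, default 49.88;
#'   `gamma0 >= gamma_eq > 0`.
#' @param k Decay rate in 1/s, default 4.551e-3; `k >= 0` (0 only for the
#'   flat control).
#' @param noise_sd SD of additive Gaussian noise in mN/m, default 0.05.
#' @param sampling_rate Samples per second, default 1.
#' @param t_end Trace end in seconds, default 5000.
#' @param seed Integer seed.
#' @return A `tension_params` list.
#' @export
tension_params <- function(gamma0 = 71.96, gamma_eq = 49.88, k = 4.551e-3,
                           noise_sd = 0.05, sampling_rate = 1,
                           t_end = 5000, seed = 1L) {
  check_number(gamma0, "gamma0", positive = TRUE)
  check_number(gamma_eq, "gamma_eq", positive = TRUE)
  if (gamma_eq > gamma0) stopf("gamma_eq must not exceed gamma0")
  check_number(k, "k")
  if (k < 0) stopf("k must be >= 0")
  if (k == 0 && gamma0 != gamma_eq) {
    stopf("k = 0 requires gamma0 == gamma_eq (flat control)")
  }
  check_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  check_number(t_end, "t_end", positive = TRUE)
  structure(list(gamma0 = gamma0, gamma_eq = gamma_eq, k = k,
                 noise_sd = noise_sd, sampling_rate = sampling_rate,
                 t_end = t_end, seed = as.integer(seed)),
            class = "tension_params")
}

#' Generate a synthetic surface-tension trace
#'
#' @param params A [tension_params] record.
#' @param label Trace label.
#' @return A [tension_trace].
#' @export
#' @examples
#' fit_exponential_decay(make_tension_trace(tension_params(noise_sd = 0)))
make_tension_trace <- function(params, label = "synthetic") {
  stopifnot(inherits(params, "tension_params"))
  with_local_seed(params$seed, {
    t <- seq(0, params$t_end, by = 1 / params$sampling_rate)
    g <- params$gamma_eq +
      (params$gamma0 - params$gamma_eq) * exp(-params$k * t)
    if (params$noise_sd > 0) {
      g <- g + stats::rnorm(length(t), 0, params$noise_sd)
    }
    tension_trace(t, pmax(g, .Machine$double.eps), label = label,
                  concentration = 0.02)
  })
}

#' Bundled excipient characterization table
#'
#' Returns the re-entered characterization table for the
#' acryloylmorpholine / N-isopropylacrylamide excipient library: seven
#' polymer rows (2-20 kDa with V-70 end groups plus the 8 kDa AIBN
#' variant) and the clean-buffer control, with equilibrium surface tension,
#' equilibration rate constant, compositional dispersity index, and T10
#' aggregation time as printed (no re-derivation). This is the fixture the
#' regime regressions and the design screen operate on.
#'
#' @return An [excipient_records] data frame with 8 rows.
#' @export
#' @examples
#' make_table4_fixture()
make_table4_fixture <- function() {
  path <- system.file("extdata", "table4_excipients.csv",
                      package = "copolex", mustWork = TRUE)
  read_records_csv(path)
}
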