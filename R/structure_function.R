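# Three-regime structure-function framework: at low molecular weight
# (<= 8 kDa) compositional dispersity governs excipient performance, at
# high molecular weight (>= 12 kDa) the equilibrium surface tension does,
# and for the intermediate set of near-identical polymers the surface
# equilibration rate constant does. Each regime gets a single-predictor
# ordinary-least-squares model of the T10 aggregation time, and the
# design screen turns the framework into a-priori pass/fail criteria.

REGIMES <- c("low_mw_cdi", "high_mw_tension", "mid_mw_kinetics")

# Predictor column per regime.
regime_predictor <- c(low_mw_cdi = "cdi",
                      high_mw_tension = "gamma_eq",
                      mid_mw_kinetics = "k_1e3_per_s")

# The intermediate-regime membership is pinned to the explicit set of
# near-identical polymers (same composition, dispersity < 3, tensions
# within 1 mN/m) rather than derived from thresholds.
MID_REGIME_SET <- c("2-V70" = FALSE, "8-V70" = TRUE, "12-V70" = TRUE,
                    "16-V70" = TRUE, "8-AIBN" = TRUE)

#' Construct an excipient record table
#'
#' One row per excipient, mirroring the characterization-table layout:
#' label, number-average molecular weight (kDa), end group, equilibrium
#' surface tension (mN/m), surface-kinetics rate constant (10^-3 1/s),
#' compositional dispersity index, and T10 aggregation time (hours), with
#' standard errors for the measured quantities.
#'
#' @param label Character vector of excipient labels.
#' @param mn_kda Number-average molecular weight in kDa.
#' @param end_group One of `"AIBN"`, `"V70"`, `"VA044"`, `"ACVA"`,
#'   `"CPDT"`, `"none"`.
#' @param gamma_eq,gamma_eq_se Equilibrium surface tension and SE (mN/m).
#' @param k_1e3_per_s,k_se Rate constant and SE (10^-3 1/s).
#' @param cdi Compositional dispersity index (dimensionless).
#' @param t10_h,t10_se T10 aggregation time and SE (hours).
#' @param dispersity Optional molecular-weight dispersity (Mw/Mn).
#' @return A data frame of class `excipient_records`.
#' @export
excipient_records <- function(label, mn_kda, end_group, gamma_eq,
                              gamma_eq_se = NA, k_1e3_per_s = NA,
                              k_se = NA, cdi = NA, t10_h = NA,
                              t10_se = NA, dispersity = NA) {
  eg <- c("AIBN", "V70", "VA044", "ACVA", "CPDT", "none")
  if (!all(end_group %in% eg)) {
    stopf("end_group must be one of: %s", paste(eg, collapse = ", "))
  }
  quant <- list(mn_kda = mn_kda, gamma_eq = gamma_eq,
                k_1e3_per_s = k_1e3_per_s, cdi = cdi, t10_h = t10_h)
  for (nm in names(quant)) {
    v <- quant[[nm]]
    if (any(!is.na(v) & v <= 0)) stopf("`%s` must be positive when present", nm)
  }
  df <- data.frame(label = label, mn_kda = mn_kda, end_group = end_group,
                   gamma_eq = gamma_eq, gamma_eq_se = gamma_eq_se,
                   k_1e3_per_s = k_1e3_per_s, k_se = k_se, cdi = cdi,
                   t10_h = t10_h, t10_se = t10_se, dispersity = dispersity,
                   stringsAsFactors = FALSE)
  class(df) <- c("excipient_records", "data.frame")
  df
}

#' Assign molecular-weight regimes to an excipient
#'
#' Regimes deliberately overlap: `low_mw_cdi` for Mn <= 8 kDa,
#' `high_mw_tension` for Mn >= 12 kDa, `mid_mw_kinetics` for
#' 8 <= Mn <= 16 kDa. A record can carry one or two labels (e.g. 8 kDa is
#' both low and intermediate).
#'
#' @param mn_kda Number-average molecular weight in kDa (scalar).
#' @return Character vector of regime labels.
#' @export
#' @examples
#' assign_regimes(8)    # low_mw_cdi + mid_mw_kinetics
assign_regimes <- function(mn_kda) {
  check_number(mn_kda, "mn_kda", positive = TRUE)
  out <- character(0)
  if (mn_kda <= 8) out <- c(out, "low_mw_cdi")
  if (mn_kda >= 12) out <- c(out, "high_mw_tension")
  if (mn_kda >= 8 && mn_kda <= 16) out <- c(out, "mid_mw_kinetics")
  out
}

# Rows of `records` belonging to a regime, for fitting purposes. The low-
# and high-MW regressions isolate the molecular-weight effect, so they are
# fit on the matched V-70 end-group series only; end-group variants (e.g.
# the AIBN twin of the 8 kDa polymer, identical CDI but different T10)
# enter only the kinetics regime, where end-group effects are the point.
regime_members <- function(records, regime) {
  if (regime == "mid_mw_kinetics") {
    keep <- records$label %in% names(MID_REGIME_SET)[MID_REGIME_SET]
  } else {
    keep <- vapply(records$mn_kda,
                   function(m) !is.na(m) && regime %in% assign_regimes(m),
                   logical(1))
    if ("end_group" %in% names(records)) {
      keep <- keep & records$end_group == "V70"
    }
  }
  records[keep, , drop = FALSE]
}

#' Fit a regime's single-predictor linear model
#'
#' Ordinary least squares (with intercept) of the T10 aggregation time on
#' the regime's predictor: CDI in the low-MW regime, equilibrium surface
#' tension in the high-MW regime, and the equilibration rate constant in
#' the intermediate regime (whose membership is the pinned four-polymer
#' set of near-identical chains). The low- and high-MW fits use the
#' matched V-70 end-group series so only molecular weight varies across
#' the fitted points. R^2 is the squared Pearson correlation.
#'
#' @param records An [excipient_records] data frame.
#' @param regime One of `"low_mw_cdi"`, `"high_mw_tension"`,
#'   `"mid_mw_kinetics"`.
#' @return A `regime_model` list: `regime`, `predictor`, `slope`,
#'   `intercept`, `r_squared`, `n`, `labels`.
#' @export
#' @examples
#' fit_regime(make_table4_fixture(), "low_mw_cdi")
fit_regime <- function(records, regime = REGIMES) {
  regime <- match.arg(regime)
  pred <- regime_predictor[[regime]]
  mem <- regime_members(records, regime)
  mem <- mem[!is.na(mem[[pred]]) & !is.na(mem$t10_h), , drop = FALSE]
  if (nrow(mem) < 3L) {
    stopf("regime '%s' has %d usable records; need at least 3",
          regime, nrow(mem))
  }
  x <- mem[[pred]]
  y <- mem$t10_h
  fit <- stats::lm(y ~ x)
  structure(list(regime = regime, predictor = pred,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(x, y)^2,
                 n = nrow(mem), labels = mem$label),
            class = "regime_model")
}

#' @export
print.regime_model <- function(x, ...) {
  cat(sprintf("Regime %s: T10 = %.3f + %.3f * %s  (R^2 = %.1f%%, n = %d)\n",
              x$regime, x$intercept, x$slope, x$predictor,
              100 * x$r_squared, x$n))
  invisible(x)
}

#' Percent variance explained, rounded half-up
#'
#' Reporting convenience: R^2 as an integer percent with half-up rounding
#' (so 0.9896 reads 99).
#'
#' @param model A `regime_model` (or a bare R^2 fraction).
#' @return Integer percent.
#' @export
r_squared_percent <- function(model) {
  r2 <- if (inherits(model, "regime_model")) model$r_squared else model
  floor(100 * r2 + 0.5)
}

#' Predict T10 from a fitted regime model
#'
#' Linear read-out `slope * x + intercept`; a negative prediction is
#' physically meaningless and is clamped to 0 with a warning.
#'
#' @param model A `regime_model`.
#' @param predictor_value Value(s) of the regime predictor.
#' @return Predicted T10 in hours.
#' @export
predict_t10 <- function(model, predictor_value) {
  stopifnot(inherits(model, "regime_model"))
  y <- model$slope * predictor_value + model$intercept
  if (any(y < 0)) {
    warning("negative T10 prediction clamped to 0 (outside the model's range)")
    y <- pmax(y, 0)
  }
  y
}

#' Design-screen thresholds
#'
#' Defaults encode the a-priori criteria distilled from the excipient
#' library: compositional dispersity index below 3 and a surface
#' equilibration rate constant of at least 4.3 x 10^-3 1/s.
#'
#' @param cdi_max Maximum admissible CDI (default 3).
#' @param k_min_1e3_per_s Minimum rate constant in 10^-3 1/s (default 4.3).
#' @return A `design_criteria` list.
#' @export
design_criteria <- function(cdi_max = 3, k_min_1e3_per_s = 4.3) {
  check_number(cdi_max, "cdi_max", positive = TRUE)
  check_number(k_min_1e3_per_s, "k_min_1e3_per_s", positive = TRUE)
  structure(list(cdi_max = cdi_max, k_min_1e3_per_s = k_min_1e3_per_s),
            class = "design_criteria")
}

#' Screen an excipient candidate against the design criteria
#'
#' Pass requires BOTH low compositional dispersity (`cdi < cdi_max`) and
#' fast surface engagement (`k >= k_min`). The quadrant label places the
#' candidate on the CDI-vs-rate design plot (high performers sit in the
#' low-CDI / fast quadrant).
#'
#' @param cdi Compositional dispersity index of the candidate.
#' @param k_1e3_per_s Equilibration rate constant in 10^-3 1/s.
#' @param criteria A [design_criteria] object.
#' @return A `screen_result` list: `pass`, `cdi_ok`, `kinetics_ok`,
#'   `quadrant`, `criteria`.
#' @export
#' @examples
#' screen_candidate(1.64, 4.6)    # a de-novo design that passes
screen_candidate <- function(cdi, k_1e3_per_s, criteria = design_criteria()) {
  check_number(cdi, "cdi", positive = TRUE)
  check_number(k_1e3_per_s, "k_1e3_per_s", positive = TRUE)
  stopifnot(inherits(criteria, "design_criteria"))
  cdi_ok <- cdi < criteria$cdi_max
  kin_ok <- k_1e3_per_s >= criteria$k_min_1e3_per_s
  quadrant <- paste0(if (cdi_ok) "low-CDI" else "high-CDI", "/",
                     if (kin_ok) "fast" else "slow")
  structure(list(pass = cdi_ok && kin_ok, cdi_ok = cdi_ok,
                 kinetics_ok = kin_ok, quadrant = quadrant,
                 criteria = criteria),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Design screen: %s (quadrant %s)\n",
              if (x$pass) "PASS" else "FAIL", x$quadrant))
  cat(sprintf("  CDI < %.3g: %s | k >= %.3g x 1e-3/s: %s\n",
              x$criteria$cdi_max, x$cdi_ok,
              x$criteria$k_min_1e3_per_s, x$kinetics_ok))
  invisible(x)
}

#' Read / write excipient record tables as CSV
#'
#' Column order mirrors the characterization table: label, Mn, end group,
#' tension, kinetics, CDI, T10 (each measured quantity with its SE).
#'
#' @param records An [excipient_records] data frame.
#' @param path File path.
#' @return `write_records_csv` returns `path` invisibly;
#'   `read_records_csv` returns an [excipient_records] data frame.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "mn_kda", "end_group", "gamma_eq", "k_1e3_per_s",
            "cdi", "t10_h")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("records CSV missing column(s): %s",
                          paste(miss, collapse = ", "))
  do.call(excipient_records, df[intersect(
    c("label", "mn_kda", "end_group", "gamma_eq", "gamma_eq_se",
      "k_1e3_per_s", "k_se", "cdi", "t10_h", "t10_se", "dispersity"),
    names(df))])
}

#' Export fitted regime models as JSON
#'
#' @param models A list of `regime_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regime_json <- function(models, path) {
  recs <- lapply(models, function(m) {
    list(regime = m$regime, predictor = m$predictor, slope = m$slope,
         intercept = m$intercept, r_squared = m$r_squared,
         r_squared_percent = r_squared_percent(m), n = m$n,
         labels = m$labels)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
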