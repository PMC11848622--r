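# Three-regime framework and the design screen.

test_that("regime assignment is overlapping and total on 2-20 kDa", {
  expect_setequal(assign_regimes(8), c("low_mw_cdi", "mid_mw_kinetics"))
  expect_setequal(assign_regimes(12), c("high_mw_tension", "mid_mw_kinetics"))
  expect_equal(assign_regimes(20), "high_mw_tension")
  expect_equal(assign_regimes(2), "low_mw_cdi")
  # totality: every molecular weight in the library range has >= 1 regime
  for (mn in seq(2, 20, by = 0.5)) {
    expect_gte(length(assign_regimes(mn)), 1)
  }
})

test_that("bundled excipient table carries the printed values", {
  tab <- make_table4_fixture()
  expect_equal(nrow(tab), 8)
  r8 <- tab[tab$label == "8-V70", ]
  expect_equal(r8$k_1e3_per_s, 4.551)
  expect_equal(r8$t10_h, 24.37)
  expect_equal(r8$cdi, 2.10)
  buffer <- tab[tab$label == "Humalog Buffer", ]
  expect_equal(buffer$gamma_eq, 71.96)
  expect_true(is.na(buffer$cdi) && is.na(buffer$k_1e3_per_s) &&
                is.na(buffer$t10_h))
})

test_that("regime fits on the bundled table explain 99/99/96 percent", {
  tab <- make_table4_fixture()
  low <- fit_regime(tab, "low_mw_cdi")
  high <- fit_regime(tab, "high_mw_tension")
  mid <- fit_regime(tab, "mid_mw_kinetics")
  expect_equal(r_squared_percent(low), 99)
  expect_equal(r_squared_percent(high), 99)
  expect_equal(r_squared_percent(mid), 96)
  # membership: low/high are the V-70 molecular-weight series; mid is the
  # pinned near-identical four-polymer set
  expect_setequal(low$labels, c("2-V70", "4-V70", "8-V70"))
  expect_setequal(high$labels, c("12-V70", "16-V70", "20-V70"))
  expect_setequal(mid$labels, c("8-V70", "12-V70", "16-V70", "8-AIBN"))
  expect_error(fit_regime(tab[1:2, ], "low_mw_cdi"), "at least 3")
})

test_that("OLS agrees with the normal-equation oracle to 1e-10", {
  set.seed(99)
  x <- rnorm(10, 5, 2)
  y <- 3 + 1.7 * x + rnorm(10, 0, 0.5)
  recs <- excipient_records(label = sprintf("p%d", 1:10), mn_kda = 5,
                            end_group = "V70", gamma_eq = 50,
                            cdi = x, t10_h = y)
  m <- fit_regime(recs, "low_mw_cdi")
  # oracle: closed-form normal equations
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  int_o <- mean(y) - slope_o * mean(x)
  expect_lt(abs(m$slope - slope_o), 1e-10)
  expect_lt(abs(m$intercept - int_o), 1e-10)
  # R^2 equals squared Pearson correlation (identity for 1-predictor OLS)
  ybar <- int_o + slope_o * x
  r2_anova <- sum((ybar - mean(y))^2) / sum((y - mean(y))^2)
  expect_equal(m$r_squared, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(m$r_squared, r2_anova, tolerance = 1e-12)
})

test_that("any three collinear points give R^2 = 1", {
  recs <- excipient_records(label = c("a", "b", "c"), mn_kda = 4,
                            end_group = "V70", gamma_eq = 50,
                            cdi = c(1, 2, 4), t10_h = c(10, 8, 4))
  expect_equal(fit_regime(recs, "low_mw_cdi")$r_squared, 1,
               tolerance = 1e-12)
})

test_that("predict_t10 reads out the line and clamps below zero", {
  tab <- make_table4_fixture()
  low <- fit_regime(tab, "low_mw_cdi")
  # in-sample prediction at the 8 kDa CDI lands within the residual
  pred <- predict_t10(low, 2.10)
  resid <- max(abs(low$intercept + low$slope * c(7.86, 5.54, 2.10) -
                     c(11.42, 15.46, 24.37)))
  expect_lt(abs(pred - 24.37), resid + 1e-9)
  # constant model
  const <- low; const$slope <- 0; const$intercept <- 12
  expect_equal(predict_t10(const, 123), 12)
  # clamping
  expect_warning(z <- predict_t10(low, 100), "clamped")
  expect_equal(z, 0)
})

test_that("design screen enforces both criteria with quadrant labels", {
  pass <- screen_candidate(1.64, 4.6)
  expect_true(pass$pass)
  expect_equal(pass$quadrant, "low-CDI/fast")
  f1 <- screen_candidate(7.86, 5.878)
  expect_false(f1$pass)
  expect_false(f1$cdi_ok)
  expect_true(f1$kinetics_ok)
  expect_equal(f1$quadrant, "high-CDI/fast")
  f2 <- screen_candidate(1.2, 1.0)
  expect_false(f2$pass)
  expect_true(f2$cdi_ok)
  expect_false(f2$kinetics_ok)
  expect_equal(f2$quadrant, "low-CDI/slow")
  # custom thresholds
  crit <- design_criteria(cdi_max = 2, k_min_1e3_per_s = 5)
  expect_false(screen_candidate(2.5, 5.5, crit)$pass)
})

test_that("records CSV and regime JSON round-trip", {
  tab <- make_table4_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(tab, path)
  back <- read_records_csv(path)
  expect_equal(back$t10_h, tab$t10_h)
  expect_equal(back$label, tab$label)
  models <- lapply(c("low_mw_cdi", "high_mw_tension", "mid_mw_kinetics"),
                   function(r) fit_regime(back, r))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_regime_json(models, jpath)
  rec <- jsonlite::read_json(jpath)
  expect_equal(vapply(rec, `[[`, integer(1), "r_squared_percent"),
               c(99L, 99L, 96L))
  bad <- withr::local_tempfile(lines = "label,foo\na,1")
  expect_error(read_records_csv(bad), "missing column")
})
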