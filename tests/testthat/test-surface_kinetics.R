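# One-phase exponential-decay fitting and equilibrium tension.

# Independent oracle: dense grid search over (k, gamma_eq, gamma0)
# minimizing the same SSE the iterative fit minimizes.
grid_fit <- function(t, y, k_grid, g0_grid, geq_grid) {
  best <- list(sse = Inf)
  for (k in k_grid) for (g0 in g0_grid) for (geq in geq_grid) {
    sse <- sum((y - (geq + (g0 - geq) * exp(-k * t)))^2)
    if (sse < best$sse) best <- list(g0 = g0, geq = geq, k = k, sse = sse)
  }
  best
}

test_that("noiseless traces are recovered to 1e-6 relative", {
  t <- 0:300
  tr <- tension_trace(t, 50 + 22 * exp(-0.005 * t))
  fit <- fit_exponential_decay(tr)
  expect_true(fit$converged)
  expect_lt(abs(fit$gamma0 - 72) / 72, 1e-6)
  expect_lt(abs(fit$gamma_eq - 50) / 50, 1e-6)
  expect_lt(abs(fit$k - 0.005) / 0.005, 1e-6)
})

test_that("noisy-trace k lands within 5% and beats the grid oracle", {
  params <- tension_params(gamma0 = 72, gamma_eq = 50, k = 0.005,
                           noise_sd = 0.2, t_end = 300, seed = 8)
  tr <- make_tension_trace(params)
  fit <- fit_exponential_decay(tr)
  expect_lt(abs(fit$k - 0.005) / 0.005, 0.05)
  inw <- tr$times <= 300
  oracle <- grid_fit(tr$times[inw], tr$tension[inw],
                     k_grid = seq(0.003, 0.007, by = 5e-5),
                     g0_grid = seq(71, 73, by = 0.05),
                     geq_grid = seq(49, 51, by = 0.05))
  expect_lt(abs(fit$k - oracle$k), 1e-4 + 5e-5)
  expect_lte(fit$sse, oracle$sse * (1 + 1e-3))
})

test_that("iterative fit never loses to the grid oracle over 20 seeds", {
  for (seed in 1:20) {
    tr <- make_tension_trace(tension_params(gamma0 = 72, gamma_eq = 50,
                                            k = 0.005, noise_sd = 0.2,
                                            t_end = 300, seed = seed))
    fit <- fit_exponential_decay(tr)
    oracle <- grid_fit(tr$times, tr$tension,
                       k_grid = seq(0.002, 0.01, by = 2e-4),
                       g0_grid = seq(71.5, 72.5, by = 0.1),
                       geq_grid = seq(49.5, 50.5, by = 0.1))
    expect_lte(fit$sse, oracle$sse * (1 + 1e-3),
               label = sprintf("seed %d SSE", seed))
  }
})

test_that("fit is idempotent on its own prediction", {
  tr <- make_tension_trace(tension_params(noise_sd = 0.1, t_end = 300,
                                          seed = 5))
  fit <- fit_exponential_decay(tr)
  pred <- fit$gamma_eq + (fit$gamma0 - fit$gamma_eq) *
    exp(-fit$k * tr$times)
  refit <- fit_exponential_decay(tension_trace(tr$times, pred))
  expect_lt(abs(refit$gamma0 - fit$gamma0) / abs(fit$gamma0), 1e-9)
  expect_lt(abs(refit$gamma_eq - fit$gamma_eq) / abs(fit$gamma_eq), 1e-9)
  expect_lt(abs(refit$k - fit$k) / abs(fit$k), 1e-9)
})

test_that("window choice does not move a noiseless fit", {
  t <- seq(0, 600)
  tr <- tension_trace(t, 49.88 + 22.08 * exp(-0.004551 * t))
  f300 <- fit_exponential_decay(tr, window = c(0, 300))
  f600 <- fit_exponential_decay(tr, window = c(0, 600))
  expect_equal(f300$k, f600$k, tolerance = 1e-6)
  expect_equal(f300$gamma_eq, f600$gamma_eq, tolerance = 1e-6)
})

test_that("flat and rising traces are flagged, not crashed", {
  flat <- tension_trace(0:100, rep(71.96, 101))
  fit <- fit_exponential_decay(flat)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$k))
  expect_error(rate_in_table_units(fit), "finite")
  rising <- tension_trace(0:100, 50 + 0.1 * (0:100))
  expect_warning(fit2 <- fit_exponential_decay(rising), "sign anomaly")
  expect_true(fit2$sign_anomaly)
})

test_that("equilibrium tension reads the 5%-tail of the raw trace", {
  # residual decay at 5000 s with k = 4.551e-3 is exp(-22.8), i.e. nil,
  # so the tail mean estimates the plateau directly
  tr <- make_tension_trace(tension_params(gamma_eq = 49.88, k = 4.551e-3,
                                          noise_sd = 0.05, seed = 2))
  eq <- equilibrium_tension(tr)
  expect_lt(abs(eq$gamma_eq - 49.88), 0.1)
  expect_gt(eq$n, 3)
  # exact plateau: zero SEM
  const <- tension_trace(seq(0, 1000, by = 10), rep(50, 101))
  eq2 <- equilibrium_tension(const)
  expect_equal(eq2$gamma_eq, 50)
  expect_equal(eq2$sem, 0)
  # replicate consistency: two noise seeds agree within 3 pooled SEMs
  eqa <- equilibrium_tension(make_tension_trace(
    tension_params(gamma_eq = 49.88, k = 4.551e-3, noise_sd = 0.05,
                   seed = 21)))
  eqb <- equilibrium_tension(make_tension_trace(
    tension_params(gamma_eq = 49.88, k = 4.551e-3, noise_sd = 0.05,
                   seed = 22)))
  pooled <- sqrt(eqa$sem^2 + eqb$sem^2)
  expect_lt(abs(eqa$gamma_eq - eqb$gamma_eq), 3 * pooled)
})

test_that("rate constants convert to tabulated 1e-3/s units", {
  expect_equal(rate_in_table_units(0.004551), 4.551)
  expect_equal(rate_in_table_units(0.001), 1)
  expect_equal(rate_in_table_units(0.005878), 5.878)
})

test_that("tension CSV and fit JSON round-trip", {
  tr <- make_tension_trace(tension_params(noise_sd = 0, t_end = 400))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = tr$times, tension_mN_m = tr$tension,
                       replicate = 1), path, row.names = FALSE)
  back <- read_tension_csv(path, label = "x")[[1]]
  expect_equal(back$tension, tr$tension)
  fit <- fit_exponential_decay(back)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_surface_fit_json(fit, jpath)
  rec <- jsonlite::read_json(jpath)
  expect_equal(rec$k_1e3_per_s, 4.551)
  expect_true(rec$converged)
  bad <- withr::local_tempfile(lines = "t,y\n0,1")
  expect_error(read_tension_csv(bad), "missing column")
})
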