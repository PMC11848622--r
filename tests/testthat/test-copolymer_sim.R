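# Chain-length sampling and terminal-model Monte-Carlo growth.

test_that("fixed-length model is degenerate at round(mean_dp)", {
  expect_equal(
    sample_chain_lengths(chain_length_model(100, family = "fixed"), 5),
    rep(100L, 5))
  # dispersity 1 under schulz_zimm family degenerates the same way
  expect_equal(
    sample_chain_lengths(chain_length_model(100, 1), 3, seed = 1),
    rep(100L, 3))
  expect_error(chain_length_model(100, 0.9), "dispersity")
})

test_that("Schulz-Zimm sampling hits the target moments", {
  # Gamma-moment oracle: shape z = 1/(D-1) gives Mw/Mn = D for the
  # continuous law; integer rounding perturbs this only slightly.
  lens <- sample_chain_lengths(chain_length_model(157, 1.20), 5e4,
                               seed = 42)
  realized_d <- (sum(as.numeric(lens)^2) / sum(lens)) / mean(lens)
  expect_gt(realized_d, 1.17)
  expect_lt(realized_d, 1.23)

  lens2 <- sample_chain_lengths(chain_length_model(63, 1.11), 5e4,
                                seed = 43)
  expect_gt(mean(lens2), 61.7)
  expect_lt(mean(lens2), 64.3)
  expect_true(all(lens2 >= 1))
})

test_that("grow_chain honors single-monomer feeds and counts sum to length", {
  g <- grow_chain(10, c(1, 0), reactivity_ratios(5, 0.1), seed = 1)
  expect_equal(g$counts, c(10, 0))
  g2 <- grow_chain(10, c(0, 1), reactivity_ratios(), seed = 1)
  expect_equal(g2$counts, c(0, 10))
  g3 <- grow_chain(500, c(0.3, 0.7), reactivity_ratios(2, 0.5), seed = 2)
  expect_equal(sum(g3$counts), 500)
  expect_error(grow_chain(10, c(0, 0)), "feed")
})

test_that("long-chain composition matches the Mayo-Lewis closed form", {
  # One chain of 1e6 units: the incorporated fraction converges to the
  # instantaneous copolymer equation F1 = (r1 f1^2 + f1 f2) /
  # (r1 f1^2 + 2 f1 f2 + r2 f2^2) (no drift at fixed feed).
  cases <- expand.grid(r1 = c(0.5, 1, 2), r2 = c(0.5, 1, 2))
  for (i in seq_len(nrow(cases))) {
    r1 <- cases$r1[i]; r2 <- cases$r2[i]
    g <- grow_chain(1e6, c(0.5, 0.5), reactivity_ratios(r1, r2),
                    seed = 100 + i)
    f1_hat <- g$counts[1] / 1e6
    expect_lt(abs(f1_hat - mayo_lewis_f1(0.5, r1, r2)), 0.005,
              label = sprintf("r1=%g r2=%g |F1hat-F1|", r1, r2))
  }
  # ideal-random at the 77/23 feed reduces to Bernoulli
  g <- grow_chain(1e6, c(0.77, 0.23), reactivity_ratios(), seed = 7)
  expect_lt(abs(g$counts[1] / 1e6 - 0.77), 0.005)
})

test_that("ideal-random per-chain counts are Binomial(length, f1)", {
  # chi-square goodness of fit on 1e4 chains at fixed length 40
  n <- 1e4; L <- 40L; f1 <- 0.77
  cfg <- sim_config(monomers = moni_monomers(),
                    length_model = chain_length_model(L, family = "fixed"),
                    n_chains = n, seed = 5)
  ens <- simulate_ensemble(cfg)
  x <- ens$chains$count_Morph
  # clamp the tails (<= 24 and >= 37) so every bin has expectation >= 5
  obs <- table(factor(pmin(pmax(x, 24L), 37L), levels = 24:37))
  expd <- n * c(pbinom(24, L, f1), dbinom(25:36, L, f1),
                pbinom(36, L, f1, lower.tail = FALSE))
  expect_true(all(expd >= 5))
  chi2 <- sum((as.numeric(obs) - expd)^2 / expd)
  pval <- pchisq(chi2, df = length(expd) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("infinite-feed ensemble is symmetric at a 50/50 ideal feed", {
  cfg <- sim_config(
    monomers = list(monomer_spec("A", 100, 0.5), monomer_spec("B", 100, 0.5)),
    length_model = chain_length_model(100, family = "fixed"),
    n_chains = 1e4, seed = 9)
  s <- simulate_ensemble(cfg)$summary
  expect_lt(abs(s$mean_fractions[["A"]] - 0.5), 0.005)
  expect_lt(abs(s$mean_fractions[["B"]] - 0.5), 0.005)
})

test_that("identical config and seed give identical ensembles", {
  cfg <- moni_config(63, 1.11, n_chains = 2000, seed = 77)
  e1 <- simulate_ensemble(cfg)
  e2 <- simulate_ensemble(cfg)
  expect_identical(e1$chains, e2$chains)
  # and a different seed does not
  cfg2 <- moni_config(63, 1.11, n_chains = 2000, seed = 78)
  expect_false(identical(simulate_ensemble(cfg2)$chains, e1$chains))
  # finite-pool mode is deterministic too
  cfgp <- moni_config(63, 1.11, n_chains = 500, seed = 12,
                      pool_mode = "finite_pool")
  expect_identical(simulate_ensemble(cfgp)$chains,
                   simulate_ensemble(cfgp)$chains)
})

test_that("finite-pool mode conserves monomer exactly", {
  for (seed in 1:3) {
    cfg <- moni_config(63, 1.11, n_chains = 400, seed = seed,
                       pool_mode = "finite_pool",
                       ratios = reactivity_ratios(2, 0.5))
    ens <- simulate_ensemble(cfg)
    consumed <- colSums(as.matrix(ens$chains[, 2:3]))
    expect_identical(as.integer(consumed + ens$pool$residual),
                     as.integer(ens$pool$initial))
    # growth stops at the target conversion
    expect_lte(ens$pool$consumed,
               floor(0.98 * sum(ens$pool$initial)))
  }
})

test_that("simulate_ensemble does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_ensemble(moni_config(30, 1.1,
                                                         n_chains = 100)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("ensemble CSV round-trips", {
  ens <- simulate_ensemble(moni_config(30, 1.1, n_chains = 50, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ensemble_csv(ens, path)
  back <- read_ensemble_csv(path)
  expect_equal(back$count_Morph, ens$chains$count_Morph)
  expect_equal(back$length, ens$chains$length)
  expect_error(read_ensemble_csv(withr::local_tempfile(lines = "a,b\n1,2")),
               "ensemble CSV")
})

test_that("config files round-trip through the flat key-value format", {
  cfg <- moni_config(94, 1.14, n_chains = 1234, seed = 55)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back, cfg)
  expect_error(read_sim_config(withr::local_tempfile(lines = "nonsense")),
               "malformed|missing")
})
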