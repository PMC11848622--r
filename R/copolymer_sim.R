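# Monte-Carlo simulation of per-chain copolymer compositions under the
# terminal (Mayo-Lewis) model, with Schulz-Zimm chain-length dispersity and
# optional finite-pool monomer depletion.
#
# The chain-growth inner loop lives in src/chain_growth.cpp and uses R's
# RNG, so a single set.seed() (applied locally by simulate_ensemble)
# determines the whole ensemble.

#' Monomer specification
#'
#' @param name Short label (e.g. `"Morph"`).
#' @param molar_mass Molar mass in g/mol (positive).
#' @param feed_fraction Mole fraction of this monomer in the feed, in
#'   `[0, 1]`. Fractions over a system must sum to 1.
#' @return A `monomer_spec` list.
#' @export
monomer_spec <- function(name, molar_mass, feed_fraction) {
  stopifnot(is.character(name), length(name) == 1L)
  check_number(molar_mass, "molar_mass", positive = TRUE)
  check_number(feed_fraction, "feed_fraction")
  if (feed_fraction < 0 || feed_fraction > 1) {
    stopf("feed_fraction must lie in [0, 1]")
  }
  structure(list(name = name, molar_mass = molar_mass,
                 feed_fraction = feed_fraction),
            class = "monomer_spec")
}

#' Terminal-model reactivity ratios
#'
#' r1 and r2 are the classical Mayo-Lewis ratios for a two-monomer system:
#' the preference of a chain ending in monomer i for adding its own monomer
#' over the comonomer. `r1 = r2 = 1` is the ideal-random default, under
#' which every added unit is an independent draw from the feed.
#'
#' @param r1,r2 Non-negative dimensionless ratios.
#' @return A `reactivity_ratios` list.
#' @export
reactivity_ratios <- function(r1 = 1, r2 = 1) {
  check_number(r1, "r1"); check_number(r2, "r2")
  if (r1 < 0 || r2 < 0) stopf("reactivity ratios must be non-negative")
  structure(list(r1 = r1, r2 = r2), class = "reactivity_ratios")
}

#' Chain-length distribution model
#'
#' `schulz_zimm` draws lengths from a Gamma distribution with shape
#' z = 1/(D - 1) and scale mean_dp/z (so the continuous distribution has
#' number-average mean_dp and dispersity D = Mw/Mn), rounded to the nearest
#' integer with floor 1. `fixed` makes every chain exactly
#' `round(mean_dp)` units long and forces dispersity 1.
#'
#' @param mean_dp Number-average degree of polymerization (positive).
#' @param dispersity Target Mw/Mn of lengths, `>= 1`.
#' @param family `"schulz_zimm"` or `"fixed"`.
#' @return A `chain_length_model` list.
#' @export
chain_length_model <- function(mean_dp, dispersity = 1,
                               family = c("schulz_zimm", "fixed")) {
  family <- match.arg(family)
  check_number(mean_dp, "mean_dp", positive = TRUE)
  check_number(dispersity, "dispersity")
  if (dispersity < 1) stopf("dispersity must be >= 1")
  if (family == "fixed") dispersity <- 1
  structure(list(mean_dp = mean_dp, dispersity = dispersity,
                 family = family),
            class = "chain_length_model")
}

#' Simulation configuration
#'
#' @param monomers List of two [monomer_spec] objects; feed fractions must
#'   sum to 1 (tolerance 1e-9).
#' @param ratios A [reactivity_ratios] object.
#' @param length_model A [chain_length_model] object.
#' @param n_chains Number of chains to simulate (`>= 1`).
#' @param target_conversion Fraction of the monomer pool converted before
#'   growth stops, in `(0, 1]`; used only in `finite_pool` mode. Default
#'   0.98, typical of a RAFT polymerization run to high conversion.
#' @param pool_mode `"infinite_feed"` (each chain sees the initial feed; no
#'   compositional drift) or `"finite_pool"` (a shared pool sized
#'   `n_chains * mean_dp / target_conversion` is depleted as chains grow in
#'   randomized round-robin order).
#' @param seed Integer seed; fixes the ensemble exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(monomers, ratios = reactivity_ratios(),
                       length_model, n_chains,
                       target_conversion = 0.98,
                       pool_mode = c("infinite_feed", "finite_pool"),
                       seed = 1L) {
  pool_mode <- match.arg(pool_mode)
  if (!is.list(monomers) || length(monomers) != 2L ||
      !all(vapply(monomers, inherits, logical(1), "monomer_spec"))) {
    stopf("`monomers` must be a list of exactly two monomer_spec objects")
  }
  feeds <- vapply(monomers, `[[`, numeric(1), "feed_fraction")
  if (abs(sum(feeds) - 1) > 1e-9) stopf("feed fractions must sum to 1")
  if (sum(feeds) == 0) stopf("all-zero feed")
  stopifnot(inherits(ratios, "reactivity_ratios"),
            inherits(length_model, "chain_length_model"))
  check_number(n_chains, "n_chains", positive = TRUE)
  if (n_chains != round(n_chains)) stopf("n_chains must be an integer")
  check_number(target_conversion, "target_conversion")
  if (target_conversion <= 0 || target_conversion > 1) {
    stopf("target_conversion must lie in (0, 1]")
  }
  check_number(seed, "seed")
  structure(list(monomers = monomers, ratios = ratios,
                 length_model = length_model,
                 n_chains = as.integer(n_chains),
                 target_conversion = target_conversion,
                 pool_mode = pool_mode, seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample chain lengths from a length model
#'
#' @param model A [chain_length_model].
#' @param n Number of lengths to draw (`>= 1`).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [simulate_ensemble]).
#' @return Integer vector of `n` degrees of polymerization, each `>= 1`.
#' @export
#' @examples
#' sample_chain_lengths(chain_length_model(100, family = "fixed"), 5)
sample_chain_lengths <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "chain_length_model"))
  check_number(n, "n", positive = TRUE)
  draw <- function() {
    if (model$family == "fixed" || model$dispersity == 1) {
      rep(max(1L, as.integer(round(model$mean_dp))), n)
    } else {
      z <- 1 / (model$dispersity - 1)
      raw <- stats::rgamma(n, shape = z, scale = model$mean_dp / z)
      pmax(1L, as.integer(round(raw)))
    }
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Grow a single chain under the terminal model
#'
#' The first unit is drawn with probability equal to the feed fraction;
#' each subsequent unit follows the terminal-model conditionals, e.g. after
#' a terminal unit of monomer 1, P(add 1) = r1 f1 / (r1 f1 + f2). With
#' r1 = r2 = 1 this reduces to independent Bernoulli draws from the feed.
#'
#' @param length Chain length (degree of polymerization, `>= 1`).
#' @param feed Numeric vector of two feed mole fractions summing to 1.
#' @param ratios A [reactivity_ratios] object.
#' @param seed Optional integer seed.
#' @return Named list: `counts` (two per-monomer integers) and `length`.
#' @export
#' @examples
#' grow_chain(10, c(1, 0), reactivity_ratios(), seed = 1)
grow_chain <- function(length, feed, ratios = reactivity_ratios(),
                       seed = NULL) {
  check_number(length, "length", positive = TRUE)
  if (base::length(feed) != 2L) stopf("`feed` must have two fractions")
  if (sum(feed) <= 0) stopf("all-zero feed")
  if (abs(sum(feed) - 1) > 1e-9) stopf("feed fractions must sum to 1")
  stopifnot(inherits(ratios, "reactivity_ratios"))
  run <- function() {
    counts <- cpp_grow_infinite(as.integer(length), feed[1],
                                ratios$r1, ratios$r2)
    list(counts = c(counts[1, 1], counts[1, 2]), length = as.integer(length))
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Simulate an ensemble of copolymer chains
#'
#' Samples `n_chains` lengths from the configured length model, then grows
#' each chain under the terminal model. In `infinite_feed` mode every chain
#' sees the initial feed fractions; in `finite_pool` mode a shared integer
#' monomer pool of `ceiling(n_chains * mean_dp / target_conversion)` units
#' (split by feed fraction) is depleted as chains are extended one unit at
#' a time in randomized round-robin order, stopping at the target
#' conversion. The output is a pure function of the config (seed included).
#'
#' @param config A [sim_config].
#' @return A `chain_ensemble` list with elements `chains` (data frame:
#'   `chain_id`, `count_<name1>`, `count_<name2>`, `length`), `summary`
#'   (an `ensemble_summary`), `config`, and in finite-pool mode
#'   `pool` (initial/residual/consumed unit bookkeeping).
#' @export
#' @examples
#' cfg <- sim_config(
#'   monomers = list(monomer_spec("Morph", 141.17, 0.77),
#'                   monomer_spec("Nipam", 113.16, 0.23)),
#'   length_model = chain_length_model(63, 1.11),
#'   n_chains = 1000, seed = 7)
#' ens <- simulate_ensemble(cfg)
#' ens$summary
simulate_ensemble <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    lengths <- sample_chain_lengths(config$length_model, config$n_chains)
    f1 <- config$monomers[[1]]$feed_fraction
    r1 <- config$ratios$r1
    r2 <- config$ratios$r2
    pool <- NULL
    if (config$pool_mode == "infinite_feed") {
      counts <- cpp_grow_infinite(lengths, f1, r1, r2)
    } else {
      total <- ceiling(config$n_chains * config$length_model$mean_dp /
                         config$target_conversion)
      pool1 <- as.integer(round(f1 * total))
      pool2 <- as.integer(total - pool1)
      if (total < 1) stopf("monomer pool is empty before any chain can grow")
      max_consume <- as.integer(floor(config$target_conversion * total))
      ord <- sample.int(config$n_chains) - 1L
      res <- cpp_grow_finite(lengths, ord, pool1, pool2, max_consume, r1, r2)
      counts <- res$counts
      if (res$consumed == 0) {
        stopf("monomer pool exhausted before any chain reached length 1")
      }
      pool <- list(initial = c(pool1, pool2), residual = res$residual,
                   consumed = res$consumed)
      lengths <- as.integer(rowSums(counts))
      if (all(lengths == 0)) {
        stopf("monomer pool exhausted before any chain reached length 1")
      }
      keep <- lengths >= 1L
      counts <- counts[keep, , drop = FALSE]
      lengths <- lengths[keep]
    }
    nms <- vapply(config$monomers, `[[`, character(1), "name")
    chains <- data.frame(chain_id = seq_len(nrow(counts)),
                         c1 = counts[, 1], c2 = counts[, 2],
                         length = lengths)
    names(chains)[2:3] <- paste0("count_", nms)
    structure(list(chains = chains,
                   summary = ensemble_summary(counts, lengths, nms),
                   config = config, pool = pool),
              class = "chain_ensemble")
  })
}

# Aggregate statistics of a sampled chain population.
ensemble_summary <- function(counts, lengths, names) {
  total <- colSums(counts)
  mn <- mean(lengths)
  mw <- sum(as.numeric(lengths)^2) / sum(lengths)
  structure(list(n_chains = length(lengths),
                 mean_fractions = stats::setNames(total / sum(total), names),
                 mn_dp = mn, mw_dp = mw,
                 dispersity_realized = mw / mn),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Chain ensemble:", x$n_chains, "chains\n")
  cat("  mean composition:",
      paste(sprintf("%s = %.4f", names(x$mean_fractions), x$mean_fractions),
            collapse = ", "), "\n")
  cat(sprintf("  Mn(DP) = %.2f, Mw(DP) = %.2f, realized dispersity = %.3f\n",
              x$mn_dp, x$mw_dp, x$dispersity_realized))
  invisible(x)
}

#' @export
print.chain_ensemble <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Write / read a chain ensemble as CSV
#'
#' The CSV has header `chain_id,count_<monomer1>,count_<monomer2>,length`,
#' the exchange format consumed by the CDI module.
#'
#' @param ensemble A `chain_ensemble` (or its `chains` data frame).
#' @param path File path.
#' @return `write_ensemble_csv` returns `path` invisibly;
#'   `read_ensemble_csv` returns the chains data frame.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  chains <- if (inherits(ensemble, "chain_ensemble")) ensemble$chains else ensemble
  utils::write.csv(chains, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  chains <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain_id", "length")
  if (!all(need %in% names(chains)) ||
      sum(startsWith(names(chains), "count_")) != 2L) {
    stopf("ensemble CSV must have columns chain_id, count_<m1>, count_<m2>, length")
  }
  chains
}
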