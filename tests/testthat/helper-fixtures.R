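# Shared fixture builders. Everything is generated in code at test time.

moni_monomers <- function(f1 = 0.77) {
  list(monomer_spec("Morph", 141.17, f1),
       monomer_spec("Nipam", 113.16, 1 - f1))
}

moni_config <- function(mean_dp, dispersity, n_chains = 20000, seed = 101,
                        ...) {
  sim_config(monomers = moni_monomers(),
             length_model = chain_length_model(mean_dp, dispersity),
             n_chains = n_chains, seed = seed, ...)
}

# The library's (mean DP, dispersity) grid: count sums and SEC dispersities
# of the 2-20 kDa rows of the characterization table.
dp_grid <- data.frame(
  kda = c(2, 4, 8, 12, 16, 20),
  mean_dp = c(15, 31, 63, 94, 126, 157),
  dispersity = c(1.08, 1.11, 1.11, 1.14, 1.19, 1.20))

# Mayo-Lewis instantaneous copolymer composition (closed form): fraction of
# monomer 1 incorporated at feed f1 and ratios (r1, r2).
mayo_lewis_f1 <- function(f1, r1, r2) {
  f2 <- 1 - f1
  (r1 * f1^2 + f1 * f2) / (r1 * f1^2 + 2 * f1 * f2 + r2 * f2^2)
}
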