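# copolex

Quantitative tools for designing amphiphilic copolymer **excipients** —
the inactive surfactants added to biopharmaceutical formulations (here,
monomeric insulin) to stop the protein from aggregating at the air–water
interface. For a library of polyacrylamide copolymers
(poly(acryloylmorpholine-*co*-N-isopropylacrylamide), "MoNi", and the
dodecylacrylamide analog "MoDD"), three measurable properties jointly
explain and predict stabilizing performance:

1. **Compositional dispersity index (CDI).** A copolymerization with feed
   mole fractions (f₁, f₂) should, ideally, put every chain on the line
   y = (f₂/f₁)·x in (major-monomer count, minor-monomer count) space —
   slope 0.23/0.77 ≈ **0.299** for the 77/23 feed. Monte-Carlo simulation
   of individual chains under the terminal (Mayo–Lewis) model, with
   Schulz–Zimm chain-length dispersity matched to SEC, yields a per-chain
   composition scatter; the index is

   CDI = |1 / R²|,  R² = 1 − Σ(yᵢ − s·xᵢ)² / Σ(yᵢ − ȳ)²

   about the *fixed* ideal line (no fitting). CDI = 1 means perfectly
   homogeneous composition; short chains give large CDI, which is why
   low-molecular-weight excipients underperform despite excellent surface
   activity.
2. **Equilibrium surface tension** γ_eq (mN/m), read from the tail of a
   5000-s Wilhelmy-plate trace.
3. **Surface equilibration kinetics**: the rate constant k (s⁻¹) of a
   one-phase exponential decay γ(t) = γ_eq + (γ₀ − γ_eq)e^(−kt) fitted to
   the first 300 s of the tension transient.

Protein stability itself is read out as the **T10 aggregation time**: the
time for a shaken, heated insulin formulation's 540-nm turbidity to reach
10% of its maximum rise above baseline.

The package implements the full pipeline: chain simulation (`Rcpp` core),
CDI, T10 extraction, exponential-decay fitting, the three
molecular-weight regime regressions (CDI at ≤ 8 kDa, tension at ≥ 12 kDa,
kinetics for the intermediate near-identical set), the a-priori design
screen (CDI < 3 **and** k ≥ 4.3 × 10⁻³ s⁻¹), polymer bookkeeping
(Mn from counts, weight↔mole conversion, blend moments), seeded synthetic
data generators for every input, and a CLI.

## Worked example

```r
library(copolex)

# 8 kDa MoNi condition: mean DP 63, SEC dispersity 1.11, 77/23 feed
cfg <- sim_config(
  monomers = list(monomer_spec("Morph", 141.17, 0.77),
                  monomer_spec("Nipam", 113.16, 0.23)),
  length_model = chain_length_model(mean_dp = 63, dispersity = 1.11),
  n_chains = 20000, seed = 42)
ens <- simulate_ensemble(cfg)
ens
#> Chain ensemble: 20000 chains
#>   mean composition: Morph = 0.7698, Nipam = 0.2302
#>   Mn(DP) = 63.22, Mw(DP) = 70.40, realized dispersity = 1.113
cdi_of_ensemble(ens)
#> CDI = 2.15  (R^2 = 0.4648 about line y = 0.299 x, n = 20000 chains)
```

The simulated CDI (2.15) reproduces the tabulated 2.10 for the 8 kDa
polymer. Screening that CDI with the measured rate constant of the
V-70-capped 8 kDa polymer (4.551 × 10⁻³ s⁻¹):

```r
screen_candidate(2.15, 4.551)
#> Design screen: PASS (quadrant low-CDI/fast)
#>   CDI < 3: TRUE | k >= 4.3 x 1e-3/s: TRUE
```

Regime regressions on the bundled excipient characterization table
recover the headline explained-variance figures (99%, 99%, 96%), and the
end-group fold change:

```r
tab <- make_table4_fixture()
fit_regime(tab, "low_mw_cdi")
#> Regime low_mw_cdi: T10 = 28.834 + -2.274 * cdi  (R^2 = 99.0%, n = 3)
fit_regime(tab, "high_mw_tension")
#> Regime high_mw_tension: T10 = 133.489 + -2.351 * gamma_eq  (R^2 = 98.7%, n = 3)
fit_regime(tab, "mid_mw_kinetics")
#> Regime mid_mw_kinetics: T10 = -33.940 + 12.765 * k_1e3_per_s  (R^2 = 95.5%, n = 4)
fold_change(24.37, 12.08)   # 8 kDa, V-70 vs AIBN end group
#> [1] 2.017384
```

Surface kinetics on a synthetic 5000-s trace (parameters of the 8 kDa
V-70 polymer):

```r
tr <- make_tension_trace(tension_params(seed = 42))
fit_exponential_decay(tr)      # first 300 s
#> Surface fit [synthetic]: gamma0 = 71.968, gamma_eq = 49.920 mN/m, k = 0.004568 1/s (4.568 x 1e-3/s)
#>   window [0, 300] s, SSE = 0.7257, converged: TRUE
equilibrium_tension(tr)$gamma_eq
#> [1] 49.87827
```

## Command line

```sh
Rscript inst/exec/copolex simulate --config sim.cfg --out runs/
Rscript inst/exec/copolex cdi --in runs/ensemble.csv --out runs/ --slope 0.299
Rscript inst/exec/copolex regress --out runs/          # bundled table
Rscript inst/exec/copolex screen --cdi 1.64 --k 4.6
```

(After installation the script is at `system.file("exec", "copolex",
package = "copolex")`.) Each artifact gets a `.config.json` sidecar with
the producing configuration, its md5, and the seed; outputs are never
overwritten without `--force`.

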