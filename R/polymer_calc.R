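# Deterministic polymer bookkeeping: number-average molecular weight from
# monomer counts, weight <-> mole composition conversion, blend moments,
# and mean-DP targeting for simulation configs.

#' Built-in monomer and end-group molar masses
#'
#' Returns the molar-mass lookup table shipped with the package:
#' the acrylamide monomers used by the MoNi / MoDD excipient families
#' (acryloylmorpholine `Morph` 141.17 g/mol, N-isopropylacrylamide `Nipam`
#' 113.16 g/mol, N-dodecylacrylamide `Dodecyl` 239.40 g/mol) and the chain
#' end groups (the RAFT chain-transfer agent `CPDT`, 345.6 g/mol, plus the
#' radical fragments left by common end-group removal initiators).
#'
#' @param kind `"monomer"`, `"end_group"`, or `"all"` (default).
#' @return A data frame with columns `name`, `kind`, `molar_mass` (g/mol).
#' @export
#' @examples
#' monomer_masses("monomer")
monomer_masses <- function(kind = c("all", "monomer", "end_group")) {
  kind <- match.arg(kind)
  path <- system.file("extdata", "monomer_masses.csv", package = "copolex",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (kind != "all") tab <- tab[tab$kind == kind, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# Look up one molar mass by name from the built-in table.
lookup_mass <- function(name, kind) {
  tab <- monomer_masses(kind)
  hit <- match(name, tab$name)
  if (is.na(hit)) {
    stopf("unknown %s '%s'; known: %s", kind, name,
          paste(tab$name, collapse = ", "))
  }
  tab$molar_mass[hit]
}

#' Number-average molecular weight from monomer counts
#'
#' Computes Mn = sum(count_i * molar_mass_i) + end-group mass, the
#' NMR-style bookkeeping value for a chain-transfer-agent-capped chain.
#' A secondary value rounded to the nearest 100 g/mol is returned for
#' reporting; rounding never feeds back into computation.
#'
#' @param counts Non-negative numeric vector of per-monomer counts.
#' @param masses Positive numeric vector of monomer molar masses (g/mol),
#'   same length as `counts`.
#' @param end_group_mass End-group molar mass in g/mol (default the CPDT
#'   chain-transfer agent, 345.6 g/mol), or a name from
#'   [monomer_masses]`("end_group")`.
#' @return List with `mn` (g/mol) and `mn_rounded` (nearest 100 g/mol).
#' @export
#' @examples
#' mn_from_counts(c(23, 8), c(141.17, 113.16))        # ~4500 g/mol polymer
mn_from_counts <- function(counts, masses, end_group_mass = 345.6) {
  if (is.character(end_group_mass)) {
    end_group_mass <- lookup_mass(end_group_mass, "end_group")
  }
  if (length(counts) != length(masses)) {
    stopf("`counts` and `masses` must have equal length")
  }
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(masses <= 0)) stopf("molar masses must be positive")
  check_number(end_group_mass, "end_group_mass")
  if (sum(counts) == 0 && end_group_mass <= 0) {
    stopf("composition needs at least one positive count or an end group")
  }
  mn <- sum(counts * masses) + end_group_mass
  list(mn = mn, mn_rounded = round(mn / 100) * 100)
}

#' Convert weight fractions to mole fractions
#'
#' x_i = (w_i / m_i) / sum_j (w_j / m_j). The inverse operation is
#' [mol_to_wt]; the two round-trip to machine precision.
#'
#' @param weight_fractions Numeric vector summing to 1.
#' @param molar_masses Positive numeric vector of the same length (g/mol).
#' @return Mole fractions summing to 1.
#' @export
#' @examples
#' wt_to_mol(c(0.77, 0.23), c(141.17, 113.16))
wt_to_mol <- function(weight_fractions, molar_masses) {
  if (length(weight_fractions) != length(molar_masses)) {
    stopf("fraction and mass vectors must have equal length")
  }
  if (any(molar_masses <= 0)) stopf("molar masses must be positive")
  if (abs(sum(weight_fractions) - 1) > 1e-9) {
    stopf("weight fractions must sum to 1")
  }
  moles <- weight_fractions / molar_masses
  moles / sum(moles)
}

#' Convert mole fractions to weight fractions
#'
#' @inheritParams wt_to_mol
#' @param mole_fractions Numeric vector summing to 1.
#' @return Weight fractions summing to 1.
#' @export
mol_to_wt <- function(mole_fractions, molar_masses) {
  if (length(mole_fractions) != length(molar_masses)) {
    stopf("fraction and mass vectors must have equal length")
  }
  if (any(molar_masses <= 0)) stopf("molar masses must be positive")
  if (abs(sum(mole_fractions) - 1) > 1e-9) {
    stopf("mole fractions must sum to 1")
  }
  mass <- mole_fractions * molar_masses
  mass / sum(mass)
}

#' Molecular-weight moments of a polymer blend
#'
#' For components mixed by mass fraction w_i with number- and weight-average
#' molecular weights (Mn_i, Mw_i):
#' Mw_blend = sum w_i Mw_i; Mn_blend = 1 / sum(w_i / Mn_i); dispersity =
#' Mw/Mn. These are the exact moment identities for mixing molecular-weight
#' distributions by mass.
#'
#' @param mn Numeric vector of component Mn (g/mol).
#' @param mw Numeric vector of component Mw (g/mol), `mw >= mn` elementwise.
#' @param mass_fraction Numeric vector of mass fractions summing to 1.
#' @return List with `mn`, `mw`, `dispersity`.
#' @export
#' @examples
#' blend_moments(c(5000, 10000), c(5500, 12000), c(0.5, 0.5))
blend_moments <- function(mn, mw, mass_fraction) {
  n <- length(mn)
  if (length(mw) != n || length(mass_fraction) != n) {
    stopf("component vectors must have equal length")
  }
  if (any(mn <= 0) || any(mw <= 0)) stopf("moments must be positive")
  if (any(mw < mn)) stopf("each component must satisfy mw >= mn")
  if (abs(sum(mass_fraction) - 1) > 1e-9) {
    stopf("mass fractions must sum to 1")
  }
  mw_b <- sum(mass_fraction * mw)
  mn_b <- 1 / sum(mass_fraction / mn)
  list(mn = mn_b, mw = mw_b, dispersity = mw_b / mn_b)
}

#' Mean monomer counts for a target number-average molecular weight
#'
#' Builds the per-monomer mean degrees of polymerization needed to hit a
#' target Mn: the end group (and any monomers with fixed counts) is
#' subtracted first, the remaining mass is allocated across the free
#' monomers by weight fraction and divided by their molar masses. Used to
#' size simulation configs for de novo designs (e.g. a 10 kDa Morph/Dodecyl
#' copolymer with exactly 5 dodecyl units).
#'
#' @param target_mn Target Mn in g/mol; must exceed the end-group mass plus
#'   any fixed-count mass.
#' @param weight_fractions Weight fractions over the free monomers (summing
#'   to 1); monomers with a fixed count get weight fraction 0.
#' @param molar_masses Molar masses (g/mol) for all monomers.
#' @param end_group_mass End-group mass in g/mol (default CPDT 345.6).
#' @param fixed_counts Optional numeric vector (same length, NA = free)
#'   pinning some monomer counts.
#' @return Real-valued mean counts per monomer.
#' @export
#' @examples
#' # 10 kDa Morph/Dodecyl design, dodecyl pinned at 5 units:
#' dp_from_target_mn(10000, c(1, 0), c(141.17, 239.4), fixed_counts = c(NA, 5))
dp_from_target_mn <- function(target_mn, weight_fractions, molar_masses,
                              end_group_mass = 345.6, fixed_counts = NULL) {
  if (is.character(end_group_mass)) {
    end_group_mass <- lookup_mass(end_group_mass, "end_group")
  }
  n <- length(molar_masses)
  if (length(weight_fractions) != n) {
    stopf("fraction and mass vectors must have equal length")
  }
  if (any(molar_masses <= 0)) stopf("molar masses must be positive")
  if (is.null(fixed_counts)) fixed_counts <- rep(NA_real_, n)
  fixed <- !is.na(fixed_counts)
  fixed_mass <- sum(fixed_counts[fixed] * molar_masses[fixed])
  budget <- target_mn - end_group_mass - fixed_mass
  if (budget < -1e-9) {
    stopf("target_mn infeasible: end group plus fixed counts exceed it")
  }
  budget <- max(budget, 0)
  free_w <- weight_fractions[!fixed]
  if (any(free_w < 0)) stopf("weight fractions must be non-negative")
  if (length(free_w) > 0 && budget > 0) {
    if (abs(sum(free_w) - 1) > 1e-9) {
      stopf("weight fractions over free monomers must sum to 1")
    }
  }
  counts <- fixed_counts
  counts[!fixed] <- budget * free_w / molar_masses[!fixed]
  counts
}
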