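#include <Rcpp.h>
using namespace Rcpp;

// Terminal-model (Mayo-Lewis) conditional probability of adding monomer 1
// given the terminal unit and the current unreacted mole fractions.
static inline double p_add1(int terminal, double f1, double f2,
                            double r1, double r2) {
  if (terminal == 1) {
    double d = r1 * f1 + f2;
    return d > 0.0 ? r1 * f1 / d : 0.0;
  }
  double d = r2 * f2 + f1;
  return d > 0.0 ? f1 / d : 1.0;
}

// Grow chains against an infinite (non-depleting) monomer feed.
// Every chain sees the same feed mole fractions throughout.
// Uses R's RNG so set.seed() in R gives full determinism.
// [[Rcpp::export]]
IntegerMatrix cpp_grow_infinite(IntegerVector lengths, double f1,
                                double r1, double r2) {
  int n = lengths.size();
  double f2 = 1.0 - f1;
  IntegerMatrix counts(n, 2);
  for (int i = 0; i < n; ++i) {
    int L = lengths[i];
    int c1 = 0;
    // first unit: probability equal to feed fraction
    int terminal = (unif_rand() < f1) ? 1 : 2;
    if (terminal == 1) ++c1;
    for (int j = 1; j < L; ++j) {
      double p1 = p_add1(terminal, f1, f2, r1, r2);
      terminal = (unif_rand() < p1) ? 1 : 2;
      if (terminal == 1) ++c1;
    }
    counts(i, 0) = c1;
    counts(i, 1) = L - c1;
  }
  return counts;
}

// Grow chains from a shared finite monomer pool, depleted as chains grow.
// Chains are extended one unit at a time in the (pre-randomized) order
// given by `order` (0-based), cycling until either every chain reaches its
// target length or `max_consume` total units have been consumed.
// Returns counts plus the residual pool so conservation can be checked.
// [[Rcpp::export]]
List cpp_grow_finite(IntegerVector lengths, IntegerVector order,
                     int pool1, int pool2, int max_consume,
                     double r1, double r2) {
  int n = lengths.size();
  IntegerMatrix counts(n, 2);
  IntegerVector grown(n);      // current length of each chain
  IntegerVector terminal(n);   // 0 = not started, 1, 2
  long consumed = 0;
  long p1 = pool1, p2 = pool2;
  bool active = true;
  while (active && consumed < max_consume && (p1 + p2) > 0) {
    active = false;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      if (grown[i] >= lengths[i]) continue;
      if (consumed >= max_consume || (p1 + p2) == 0) { active = true; break; }
      double tot = (double)(p1 + p2);
      double f1 = p1 / tot, f2 = p2 / tot;
      int add;
      if (terminal[i] == 0) {
        add = (unif_rand() < f1) ? 1 : 2;
      } else {
        add = (unif_rand() < p_add1(terminal[i], f1, f2, r1, r2)) ? 1 : 2;
      }
      // a monomer with an exhausted pool cannot be added
      if (add == 1 && p1 == 0) add = 2;
      if (add == 2 && p2 == 0) add = 1;
      if (add == 1) { ++counts(i, 0); --p1; } else { ++counts(i, 1); --p2; }
      terminal[i] = add;
      ++grown[i];
      ++consumed;
      active = true;
    }
  }
  return List::create(_["counts"] = counts,
                      _["residual"] = IntegerVector::create(p1, p2),
                      _["consumed"] = (double)consumed);
}
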