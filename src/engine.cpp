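#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Uniform index in {0, ..., n-1} from one unif_rand() draw. The R-level
// single-event code uses the identical construction so both consume the RNG
// stream the same way (trajectory equality is tested).
static inline int draw_index(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// mode: 0 = standard, 1 = threshold
// rule: 0 = within_threshold, 1 = literal_two_stage (threshold mode only)

static inline bool pair_active(const IntegerMatrix &tr, int i, int j,
                               int F, int mode, int a) {
  if (mode == 0) {
    int shared = 0;
    for (int k = 0; k < F; ++k)
      if (tr(i, k) == tr(j, k)) ++shared;
    return shared > 0 && shared < F;
  }
  for (int k = 0; k < F; ++k) {
    int d = std::abs(tr(i, k) - tr(j, k));
    if (d > 0 && d <= a) return true;
  }
  return false;
}

static bool all_edges_inactive(const IntegerMatrix &tr,
                               const IntegerMatrix &edges,
                               int F, int mode, int a) {
  int E = edges.nrow();
  for (int e = 0; e < E; ++e)
    if (pair_active(tr, edges(e, 0), edges(e, 1), F, mode, a)) return false;
  return true;
}

// [[Rcpp::export]]
bool cpp_is_absorbing(IntegerMatrix traits, IntegerMatrix edges0,
                      int mode, int a) {
  return all_edges_inactive(traits, edges0, traits.ncol(), mode, a);
}

// One elementary event. RNG protocol (shared with the R implementation):
//   u1 -> agent i; u2 -> neighbour j; u3 -> interaction Bernoulli;
//   u4 -> candidate feature, drawn only if the pair interacts and the
//         eligible set is nonempty.
// Returns 1 if a trait was copied, 0 otherwise. Mutates `tr` in place.
static inline int one_event(IntegerMatrix &tr,
                            const IntegerVector &nbr_flat,
                            const IntegerVector &nbr_start,
                            int N, int F, int q, int a,
                            int mode, int rule,
                            std::vector<int> &buf) {
  int i = draw_index(N);
  int deg = nbr_start[i + 1] - nbr_start[i];
  int j = nbr_flat[nbr_start[i] + draw_index(deg)];

  int cnt = 0;
  if (mode == 0) {
    for (int k = 0; k < F; ++k)
      if (tr(i, k) == tr(j, k)) ++cnt;
  } else {
    for (int k = 0; k < F; ++k)
      if (std::abs(tr(i, k) - tr(j, k)) <= a) ++cnt;
  }
  double u3 = unif_rand();
  if (u3 >= (double)cnt / F) return 0;

  // eligible candidate features
  buf.clear();
  for (int k = 0; k < F; ++k) {
    int d = std::abs(tr(i, k) - tr(j, k));
    if (mode == 1 && rule == 0) {
      if (d > 0 && d <= a) buf.push_back(k);
    } else {
      if (d > 0) buf.push_back(k);
    }
  }
  if (buf.empty()) return 0;
  int k = buf[draw_index((int)buf.size())];
  if (mode == 1 && rule == 1 &&
      std::abs(tr(i, k) - tr(j, k)) > a) return 0;
  tr(i, k) = tr(j, k);
  return 1;
}

// [[Rcpp::export]]
List cpp_run_engine(IntegerMatrix traits,
                    IntegerVector nbr_flat, IntegerVector nbr_start,
                    IntegerMatrix edges0,
                    int q, int a, int mode, int rule,
                    double max_steps, double check_every) {
  IntegerMatrix tr = clone(traits);
  int N = tr.nrow(), F = tr.ncol();
  std::vector<int> buf;
  buf.reserve(F);

  double steps = 0, copies = 0;
  bool absorbed = all_edges_inactive(tr, edges0, F, mode, a);
  while (!absorbed && steps < max_steps) {
    double chunk = std::min(check_every, max_steps - steps);
    for (double s = 0; s < chunk; ++s) {
      copies += one_event(tr, nbr_flat, nbr_start, N, F, q, a, mode, rule, buf);
      steps += 1;
    }
    absorbed = all_edges_inactive(tr, edges0, F, mode, a);
  }
  return List::create(_["traits"] = tr,
                      _["steps"] = steps,
                      _["copies"] = copies,
                      _["absorbed"] = absorbed);
}
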