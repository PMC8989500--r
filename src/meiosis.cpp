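#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Crossover positions are sampled from a piecewise-constant intensity given by
// the per-window landscape: cum_cM holds the cumulative genetic position (cM)
// at the window boundaries win_bounds (bp). Inverse-CDF sampling maps a
// uniform draw on [0, total cM] back to a physical position.
static double invert_cum(const NumericVector &win_bounds,
                         const NumericVector &cum_cM, double target) {
  int nb = cum_cM.size();
  // first index with cum_cM[idx] >= target
  int lo = 0, hi = nb - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum_cM[mid] < target) lo = mid + 1; else hi = mid;
  }
  if (lo == 0) return win_bounds[0];
  double c0 = cum_cM[lo - 1], c1 = cum_cM[lo];
  double b0 = win_bounds[lo - 1], b1 = win_bounds[lo];
  if (c1 <= c0) return b0;
  return b0 + (b1 - b0) * (target - c0) / (c1 - c0);
}

// One meiosis: recombine haplotypes h1/h2 (founder-origin codes per marker)
// into a gamete. CO count ~ Poisson(genetic length in Morgans), Haldane model
// (no interference); start chromatid chosen at random.
static void meiosis(const std::vector<int> &h1, const std::vector<int> &h2,
                    const NumericVector &pos, const NumericVector &win_bounds,
                    const NumericVector &cum_cM, double tot_morgans,
                    bool obligate, std::vector<int> &gamete,
                    std::vector<double> &co_buf) {
  int m = pos.size();
  int k = (tot_morgans > 0.0) ? (int)R::rpois(tot_morgans) : 0;
  if (obligate && k < 1) k = 1;
  double total_cM = cum_cM[cum_cM.size() - 1];
  co_buf.clear();
  for (int i = 0; i < k; ++i)
    co_buf.push_back(invert_cum(win_bounds, cum_cM, unif_rand() * total_cM));
  std::sort(co_buf.begin(), co_buf.end());
  int phase = (unif_rand() < 0.5) ? 0 : 1;
  size_t j = 0;
  for (int i = 0; i < m; ++i) {
    while (j < co_buf.size() && co_buf[j] <= pos[i]) { ++j; phase ^= 1; }
    gamete[i] = phase ? h2[i] : h1[i];
  }
}

// Crossover count observable in a genotype sequence: scan codes in physical
// order, skip heterozygous (1), count transitions between opposite homozygous
// states. Used on true founder-origin sums, at marker resolution.
static int count_transitions(const std::vector<int> &s) {
  int last = -1, n = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int v = s[i];
    if (v == 1) continue;
    if (last >= 0 && v != last) ++n;
    last = v;
  }
  return n;
}

//' @keywords internal
// [[Rcpp::export(name = ".sim_ril_chromosome")]]
List sim_ril_chromosome(int n_ril, int n_gen, NumericVector pos,
                        NumericVector win_bounds, NumericVector cum_cM,
                        bool obligate) {
  int m = pos.size();
  double tot_morgans = cum_cM[cum_cM.size() - 1] / 100.0;
  IntegerMatrix O1(n_ril, m), O2(n_ril, m);
  IntegerVector true_co(n_ril);
  std::vector<int> h1(m), h2(m), g1(m), g2(m), s(m);
  std::vector<double> co_buf;
  for (int r = 0; r < n_ril; ++r) {
    // F1 of the cross: one chromosome from each parent
    std::fill(h1.begin(), h1.end(), 0);
    std::fill(h2.begin(), h2.end(), 1);
    // single-seed descent: each generation draws two gametes from one plant
    for (int g = 0; g < n_gen; ++g) {
      meiosis(h1, h2, pos, win_bounds, cum_cM, tot_morgans, obligate, g1, co_buf);
      meiosis(h1, h2, pos, win_bounds, cum_cM, tot_morgans, obligate, g2, co_buf);
      h1 = g1; h2 = g2;
    }
    for (int i = 0; i < m; ++i) {
      O1(r, i) = h1[i];
      O2(r, i) = h2[i];
      s[i] = h1[i] + h2[i];
    }
    true_co[r] = count_transitions(s);
  }
  return List::create(_["origin1"] = O1, _["origin2"] = O2,
                      _["true_co"] = true_co);
}
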