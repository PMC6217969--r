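#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted Kolmogorov-Smirnov running-sum enrichment score evaluated only at
// hit positions.  The running sum increments by w_i / sum(w) at each hit and
// decrements by 1/(N - s) at each miss, so its extrema occur at a hit (for the
// positive deviation) or immediately before a hit (for the negative one).
// `pos` must be sorted ascending, 1-based ranks of the set members; `w` the
// hit weights |metric|^alpha in the same order.  When all weights are zero
// (possible for alpha > 0 on a degenerate metric) hits fall back to uniform
// weight, which reproduces the classic unweighted statistic.
//
// peak convention: positive ES peaks AT a hit rank; the negative extreme is
// attained just before a hit, and the reported peak rank is that hit's rank so
// that members at ranks >= peak form the (trailing) leading edge.
static double es_from_hits(const int* pos, const double* w, int s, int n,
                           int* peak_out) {
  double W = 0.0;
  for (int i = 0; i < s; ++i) W += w[i];
  const double d = 1.0 / (double)(n - s);
  double cum = 0.0, es_pos = 0.0, es_neg = 0.0;
  int peak_pos = 0, peak_neg = 0;
  for (int i = 0; i < s; ++i) {
    double frac_before = (W > 0.0) ? cum / W : (double)i / (double)s;
    double before = frac_before - d * (double)(pos[i] - 1 - i);
    if (before < es_neg) { es_neg = before; peak_neg = pos[i]; }
    cum += w[i];
    double frac_at = (W > 0.0) ? cum / W : (double)(i + 1) / (double)s;
    double at = frac_at - d * (double)(pos[i] - (i + 1));
    if (at > es_pos) { es_pos = at; peak_pos = pos[i]; }
  }
  // tie at equal |deviation| of opposite signs -> take the positive ES;
  // the comparison carries a small tolerance so rounding in the two
  // running-sum branches cannot flip a mathematically exact tie
  if (es_pos >= -es_neg - 1e-12) {
    if (peak_out) *peak_out = (es_pos > 0.0) ? peak_pos : 0;
    return es_pos;
  }
  if (peak_out) *peak_out = peak_neg;
  return es_neg;
}

// [[Rcpp::export]]
NumericVector es_stat_cpp(IntegerVector pos, NumericVector w, int n) {
  int s = pos.size();
  if (s == 0) stop("empty hit set");
  if (s >= n) stop("set spans the whole ranked list");
  int peak = 0;
  double es = es_from_hits(INTEGER(pos), REAL(w), s, n, &peak);
  return NumericVector::create(es, (double)peak);
}

// ES for many sets against one ranked list.  `rankpos[g]` is the 1-based rank
// of gene g; `absw[r]` is |metric|^alpha at rank r (1-based); `sets` holds
// 1-based gene indices per set.
// [[Rcpp::export]]
NumericVector es_many_cpp(IntegerVector rankpos, NumericVector absw, List sets) {
  int nsets = sets.size();
  int n = rankpos.size();
  NumericVector out(nsets);
  std::vector<int> pos;
  std::vector<double> w;
  for (int j = 0; j < nsets; ++j) {
    IntegerVector idx = sets[j];
    int s = idx.size();
    pos.resize(s);
    w.resize(s);
    for (int i = 0; i < s; ++i) pos[i] = rankpos[idx[i] - 1];
    std::sort(pos.begin(), pos.end());
    for (int i = 0; i < s; ++i) w[i] = absw[pos[i] - 1];
    out[j] = es_from_hits(pos.data(), w.data(), s, n, (int*)0);
  }
  return out;
}

// draw `s` distinct indices from 0..n-1 with R's RNG (partial Fisher-Yates on
// a persistent identity array, swaps undone after each draw)
static void draw_subset(std::vector<int>& idx, int n, int s, int* out) {
  for (int j = 0; j < s; ++j) {
    int k = j + (int)(unif_rand() * (double)(n - j));
    if (k >= n) k = n - 1;
    std::swap(idx[j], idx[k]);
    out[j] = idx[j];
  }
  // restore identity: a tail position touched by a swap always sends its
  // original value into the drawn prefix, so `out` names every dirty slot
  for (int j = 0; j < s; ++j) idx[j] = j;
  for (int j = 0; j < s; ++j) {
    int v = out[j];
    if (v >= s) idx[v] = v;
  }
}

// null ES distribution under gene-set permutation: `nperm` random member sets
// of size `s` scored against the observed ranked list
// [[Rcpp::export]]
NumericVector es_null_sets_cpp(NumericVector absw, int s, int nperm) {
  int n = absw.size();
  if (s >= n) stop("set spans the whole ranked list");
  NumericVector out(nperm);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<int> pick(s), pos(s);
  std::vector<double> w(s);
  for (int p = 0; p < nperm; ++p) {
    draw_subset(idx, n, s, pick.data());
    for (int i = 0; i < s; ++i) pos[i] = pick[i] + 1;  // ranks directly
    std::sort(pos.begin(), pos.end());
    for (int i = 0; i < s; ++i) w[i] = absw[pos[i] - 1];
    out[p] = es_from_hits(pos.data(), w.data(), s, n, (int*)0);
  }
  return out;
}

// MAGENTA sampling null: counts of above-cutoff members among `nnull` random
// gene sets of size `s` drawn without replacement from the scored genes
// [[Rcpp::export]]
IntegerVector count_null_sets_cpp(LogicalVector above, int s, int nnull) {
  int n = above.size();
  if (s > n) stop("set larger than scored-gene universe");
  IntegerVector out(nnull);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<int> pick(s);
  for (int p = 0; p < nnull; ++p) {
    draw_subset(idx, n, s, pick.data());
    int c = 0;
    for (int i = 0; i < s; ++i) if (above[pick[i]]) ++c;
    out[p] = c;
  }
  return out;
}
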