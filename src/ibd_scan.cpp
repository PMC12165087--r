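// Pairwise seed-and-extend IBD matcher (GERMLINE-style): for every
// cross-group haplotype pair, maximal runs of allele identity with a small
// mismatch budget, every tolerated mismatch at least `clearance` usable
// sites from either run end. Coordinates snap to the midpoint between the
// bounding discordant sites, or to the chromosome edges.
//
// This is the compiled twin of the quadratic R reference scanner used as
// the oracle in the test-suite; both must produce identical tracts.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Tract {
  int ia, ib;
  double start, end;
  int n_sites;
};

// enumerate maximal merged runs for one pair; usable/mism are 0-based
void pair_runs(const std::vector<int> &usable, const std::vector<int> &mism,
               const NumericVector &pos, double L, double min_length,
               int min_sites, int max_mismatch, int clearance, int ia,
               int ib, std::vector<Tract> &out) {
  const int n_use = (int)usable.size();
  const int K = (int)mism.size();
  // candidate merged runs (a..b over pure runs 0..K, mismatches between)
  std::vector<int> cand_a, cand_b;
  if (K == 0) {
    cand_a.push_back(0);
    cand_b.push_back(0);
  } else {
    // pure-run lengths; bounds[t] = index (into usable) of mismatch t
    std::vector<int> run_len(K + 1);
    run_len[0] = mism[0];
    for (int t = 1; t < K; ++t) run_len[t] = mism[t] - mism[t - 1] - 1;
    run_len[K] = n_use - mism[K - 1] - 1;

    // a qualifying merge must contain a clean stretch of at least
    // ceil((min_sites - m) / (m + 1)) sites
    int p = min_sites - max_mismatch;
    int anchor = p > 0 ? (p + max_mismatch) / (max_mismatch + 1) : 0;
    int max_run = 0;
    for (int t = 0; t <= K; ++t) max_run = std::max(max_run, run_len[t]);
    if (max_run < anchor) return;

    std::vector<std::pair<int, int> > valid;
    for (int a = 0; a <= K; ++a) {
      int b_max = std::min(K, a + max_mismatch);
      for (int b = a; b <= b_max; ++b) {
        bool ok = true;
        for (int t = a + 1; t <= b && ok; ++t) {
          int left = 0, right = 0;
          for (int u = a; u <= t - 1; ++u) left += run_len[u];
          left += (t - 1 - a);
          for (int u = t; u <= b; ++u) right += run_len[u];
          right += (b - t);
          if (left < clearance || right < clearance) ok = false;
        }
        if (!ok) continue;
        // first/last usable index of the merge (may be empty)
        int first = (a == 0) ? 0 : mism[a - 1] + 1;
        int last = (b == K) ? n_use - 1 : mism[b] - 1;
        if (first > last) continue;
        valid.push_back(std::make_pair(a, b));
      }
    }
    for (size_t i = 0; i < valid.size(); ++i) {
      bool maximal = true;
      for (size_t j = 0; j < valid.size() && maximal; ++j) {
        if (i == j) continue;
        if (valid[j].first <= valid[i].first &&
            valid[j].second >= valid[i].second)
          maximal = false;
      }
      if (maximal) {
        cand_a.push_back(valid[i].first);
        cand_b.push_back(valid[i].second);
      }
    }
  }
  for (size_t c = 0; c < cand_a.size(); ++c) {
    int a = cand_a[c], b = cand_b[c];
    int first = (a == 0) ? 0 : mism[a - 1] + 1;
    int last = (b == K) ? n_use - 1 : mism[b] - 1;
    int n_sites_run = last - first + 1;
    if (n_sites_run < min_sites) continue;
    double p_first = pos[usable[first]];
    double p_last = pos[usable[last]];
    double start = (a == 0)
                       ? 0.0
                       : std::floor((pos[usable[mism[a - 1]]] + p_first) / 2);
    double end = (b == K)
                     ? L
                     : std::floor((p_last + pos[usable[mism[b]]]) / 2);
    if (end - start < min_length) continue;
    Tract t;
    t.ia = ia;
    t.ib = ib;
    t.start = start;
    t.end = end;
    t.n_sites = n_sites_run;
    out.push_back(t);
  }
}

}  // namespace

// `alleles_t` is site-major (sites x haplotypes) so each haplotype is a
// contiguous column.
// [[Rcpp::export(name = ".cpp_detect_ibd")]]
NumericMatrix cpp_detect_ibd(IntegerMatrix alleles_t, IntegerVector rows_a,
                             IntegerVector rows_b, NumericVector pos,
                             double L, double min_length, int min_sites,
                             int max_mismatch, int clearance) {
  const int n_sites_all = alleles_t.nrow();
  std::vector<Tract> tracts;
  std::vector<int> usable, mism;
  usable.reserve(n_sites_all);
  mism.reserve(n_sites_all);
  for (int x = 0; x < rows_a.size(); ++x) {
    const int ia = rows_a[x] - 1;
    const int *col_a = &alleles_t(0, ia);
    for (int y = 0; y < rows_b.size(); ++y) {
      const int ib = rows_b[y] - 1;
      const int *col_b = &alleles_t(0, ib);
      usable.clear();
      mism.clear();
      for (int s = 0; s < n_sites_all; ++s) {
        const int va = col_a[s], vb = col_b[s];
        if (va == NA_INTEGER || vb == NA_INTEGER) continue;
        if (va != vb) mism.push_back((int)usable.size());
        usable.push_back(s);
      }
      if ((int)usable.size() < min_sites) continue;
      pair_runs(usable, mism, pos, L, min_length, min_sites, max_mismatch,
                clearance, ia + 1, ib + 1, tracts);
    }
  }
  NumericMatrix out((int)tracts.size(), 5);
  for (size_t i = 0; i < tracts.size(); ++i) {
    out(i, 0) = tracts[i].ia;
    out(i, 1) = tracts[i].ib;
    out(i, 2) = tracts[i].start;
    out(i, 3) = tracts[i].end;
    out(i, 4) = tracts[i].n_sites;
  }
  return out;
}
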