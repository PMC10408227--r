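// Structured-coalescent engine. Time is in units of 4N generations with
// pairwise coalescence rate 1/x in a deme of relative size x; mutations
// are an infinite-sites Poisson process of rate theta/2 per unit branch
// length, dropped interval-by-interval on the active lineages (an exact
// equivalent of per-branch Poisson placement).
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// deme: 1-based starting deme per sampled lineage; sizes: relative deme
// sizes; demes merge into one deme of size anc_size at merge_time.
// group: 1-based output column per lineage (individual or sample).
// Returns an integer matrix of derived-allele dosages, one row per
// segregating site.
// [[Rcpp::export]]
IntegerMatrix coal_locus_engine(IntegerVector deme, NumericVector sizes,
                                double merge_time, double theta,
                                double anc_size, IntegerVector group,
                                int n_groups) {
  int n = deme.size();
  std::vector< std::vector<int> > desc(n);
  std::vector<int> dm(n);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) {
    desc[i].push_back(i);
    dm[i] = deme[i] - 1;
    active[i] = i;
  }
  int ndeme = sizes.size();
  std::vector<double> sz(sizes.begin(), sizes.end());
  bool allsame = true;
  for (int i = 1; i < n; ++i) if (dm[i] != dm[0]) allsame = false;
  bool merged = allsame || merge_time <= 0;
  if (merged) {
    for (int i = 0; i < n; ++i) dm[i] = 0;
    ndeme = 1;
    sz.assign(1, anc_size);
  }
  double t = 0.0;
  std::vector< std::vector<int> > site_rows;
  std::vector<double> rates(ndeme);
  std::vector<int> k(ndeme);

  while ((int)active.size() > 1) {
    std::fill(k.begin(), k.end(), 0);
    for (size_t i = 0; i < active.size(); ++i) k[dm[active[i]]]++;
    double R = 0.0;
    for (int d = 0; d < ndeme; ++d) {
      rates[d] = k[d] * (k[d] - 1) / (2.0 * sz[d]);
      R += rates[d];
    }
    double delta;
    bool do_merge;
    if (R <= 0.0) {              // isolated singletons await the merge
      delta = merge_time - t;
      do_merge = true;
    } else {
      double dt = R::exp_rand() / R;
      if (!merged && t + dt >= merge_time) {
        delta = merge_time - t;
        do_merge = true;
      } else {
        delta = dt;
        do_merge = false;
      }
    }
    // mutations during this interval on every active lineage
    if (theta > 0 && delta > 0) {
      for (size_t i = 0; i < active.size(); ++i) {
        int nm = (int)R::rpois(theta / 2.0 * delta);
        for (int m = 0; m < nm; ++m) site_rows.push_back(desc[active[i]]);
      }
    }
    t += delta;
    if (do_merge) {
      merged = true;
      for (int i = 0; i < n; ++i) dm[i] = 0;
      ndeme = 1;
      sz.assign(1, anc_size);
      continue;
    }
    // choose deme, then a uniform pair within it
    double u = R::unif_rand() * R, acc = 0.0;
    int d = 0;
    for (; d < ndeme; ++d) { acc += rates[d]; if (u <= acc) break; }
    if (d == ndeme) d = ndeme - 1;
    std::vector<int> in_deme;
    for (size_t i = 0; i < active.size(); ++i)
      if (dm[active[i]] == d) in_deme.push_back((int)i);
    int kd = in_deme.size();
    int pi = (int)(R::unif_rand() * kd); if (pi >= kd) pi = kd - 1;
    int pj = (int)(R::unif_rand() * (kd - 1)); if (pj >= kd - 1) pj = kd - 2;
    if (pj >= pi) pj++;
    int ai = in_deme[pi], aj = in_deme[pj];
    int li = active[ai], lj = active[aj];
    desc[li].insert(desc[li].end(), desc[lj].begin(), desc[lj].end());
    active.erase(active.begin() + aj);
  }

  int ns = site_rows.size();
  IntegerMatrix out(ns, n_groups);
  for (int s = 0; s < ns; ++s)
    for (size_t j = 0; j < site_rows[s].size(); ++j)
      out(s, group[site_rows[s][j]] - 1)++;
  return out;
}
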