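#include <Rcpp.h>
using namespace Rcpp;

// Structured-coalescent event loop with infinite-sites mutation.
//
// Demes are indexed globally: 0 = diploid, 1 = tet (tetrasomic) or
// subgenome A (disomic), 2 = subgenome B (disomic), 3 = extinct lineage,
// 4 = ancestral. `sizes` is a 3 x 5 matrix of deme sizes (gene copies) per
// epoch; a deme unavailable in an epoch carries NA. Epoch 1 ends at the
// whole-genome duplication (g_wgd generations), epoch 2 at the progenitor
// split (g_split), epoch 3 is unbounded. Migration flows apply in epoch 1
// only. Formation codes: 0 tetraploid lineages -> extinct deme;
// 1 -> diploid deme; 2 allopolyploid (tetrasomic: fair coin between
// diploid and extinct per lineage; disomic: A -> diploid, B -> extinct).
//
// Uses R's RNG throughout so results are reproducible under set.seed().
// [[Rcpp::export(name = ".cpp_simulate_locus")]]
List cpp_simulate_locus(IntegerVector deme0, NumericMatrix sizes,
                        IntegerVector flow_from, IntegerVector flow_to,
                        NumericVector flow_rate, double g_wgd,
                        double g_split, double mu, int formation,
                        bool tetrasomic) {
  const int n = deme0.size();
  const int ndeme = 5;
  std::vector< std::vector<int> > lin(n);
  std::vector<double> blen(n, 0.0);
  std::vector<int> deme(n);
  std::vector< std::vector<int> > carriers;
  for (int i = 0; i < n; ++i) {
    lin[i].push_back(i);
    deme[i] = deme0[i];
  }
  int nactive = n;
  double t = 0.0;
  int epoch = 0;  // 0-based
  double bounds[3] = {g_wgd, g_split, R_PosInf};

  auto finalize = [&](int i) {
    int k = (int) R::rpois(mu * blen[i]);
    for (int z = 0; z < k; ++z) carriers.push_back(lin[i]);
  };
  auto restructure = [&](int ep_done) {
    if (ep_done == 0) {
      for (int i = 0; i < nactive; ++i) {
        if (deme[i] == 1 || deme[i] == 2) {
          if (formation == 0) deme[i] = 3;
          else if (formation == 1) deme[i] = 0;
          else {
            if (tetrasomic) deme[i] = (unif_rand() < 0.5) ? 0 : 3;
            else deme[i] = (deme[i] == 1) ? 0 : 3;
          }
        }
      }
    } else {
      for (int i = 0; i < nactive; ++i) deme[i] = 4;
    }
  };
  while (epoch < 2 && t >= bounds[epoch]) { restructure(epoch); ++epoch; }

  int cnt[5];
  while (nactive > 1) {
    for (int d = 0; d < ndeme; ++d) cnt[d] = 0;
    for (int i = 0; i < nactive; ++i) ++cnt[deme[i]];
    double coal[5], tot = 0.0;
    for (int d = 0; d < ndeme; ++d) {
      double N = sizes(epoch, d);
      coal[d] = (cnt[d] >= 2 && R_finite(N) && N > 0)
        ? cnt[d] * (cnt[d] - 1.0) / 2.0 / N : 0.0;
      tot += coal[d];
    }
    int nflow = (epoch == 0) ? flow_rate.size() : 0;
    double frate_total = 0.0;
    std::vector<double> frate(nflow);
    for (int f = 0; f < nflow; ++f) {
      frate[f] = cnt[flow_from[f]] * flow_rate[f];
      frate_total += frate[f];
    }
    tot += frate_total;
    double dt = (tot > 0) ? R::rexp(1.0 / tot) : R_PosInf;
    if (t + dt >= bounds[epoch]) {
      double step = bounds[epoch] - t;
      for (int i = 0; i < nactive; ++i) blen[i] += step;
      t = bounds[epoch];
      restructure(epoch);
      ++epoch;
      continue;
    }
    for (int i = 0; i < nactive; ++i) blen[i] += dt;
    t += dt;
    double pick = unif_rand() * tot, acc = 0.0;
    bool done = false;
    for (int d = 0; d < ndeme && !done; ++d) {
      acc += coal[d];
      if (pick <= acc && coal[d] > 0) {
        // choose two distinct lineages in deme d
        int a = (int) (unif_rand() * cnt[d]);
        int b = (int) (unif_rand() * (cnt[d] - 1));
        if (b >= a) ++b;
        int ia = -1, ib = -1, seen = 0;
        for (int i = 0; i < nactive; ++i) {
          if (deme[i] == d) {
            if (seen == a) ia = i;
            if (seen == b) ib = i;
            ++seen;
          }
        }
        if (ia > ib) std::swap(ia, ib);
        finalize(ia); finalize(ib);
        std::vector<int> merged;
        merged.reserve(lin[ia].size() + lin[ib].size());
        std::merge(lin[ia].begin(), lin[ia].end(),
                   lin[ib].begin(), lin[ib].end(),
                   std::back_inserter(merged));
        lin[ia] = merged;
        blen[ia] = 0.0;
        lin[ib] = lin[nactive - 1];
        blen[ib] = blen[nactive - 1];
        deme[ib] = deme[nactive - 1];
        --nactive;
        done = true;
      }
    }
    if (!done) {
      for (int f = 0; f < nflow; ++f) {
        acc += frate[f];
        if (pick <= acc && frate[f] > 0) {
          int a = (int) (unif_rand() * cnt[flow_from[f]]);
          int seen = 0;
          for (int i = 0; i < nactive; ++i) {
            if (deme[i] == flow_from[f]) {
              if (seen == a) { deme[i] = flow_to[f]; break; }
              ++seen;
            }
          }
          break;
        }
      }
    }
  }

  const int S = carriers.size();
  IntegerMatrix mat(n, S);
  for (int j = 0; j < S; ++j)
    for (size_t z = 0; z < carriers[j].size(); ++z)
      mat(carriers[j][z], j) = 1;
  return List::create(_["mat"] = mat);
}
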