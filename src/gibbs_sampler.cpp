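// Gibbs sampler for diploid haplotype phase over ambiguity-coded genotypes.
//
// One sweep updates every multi-site heterozygote conditional on all other
// current haplotypes H_{-i}: a candidate pair (x, y) is drawn with
// probability proportional to pi(x | H_{-i}) * pi(y | H_{-i} + x), where
// pi(. | H) is an approximate coalescent conditional: a mixture over the
// haplotypes in H with a geometric-in-theta mutation kernel g(d) =
// (1-q) q^d over mutational distance d, truncated at `trunc` steps.
// Individuals with few heterozygous sites are updated by enumerating all
// 2^(h-1) unordered decompositions; larger individuals are updated
// site-by-site (Gibbs on one phase bit at a time), which leaves the target
// unchanged.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

struct Indiv {
  std::vector<int> het;    // 0-based variable-column indices that are het
  std::vector<int> baseA;  // first base per variable column
  std::vector<int> baseB;  // second base per variable column
};

inline double gkern(int d, const std::vector<double>& gcoef) {
  return (d >= 0 && d < (int)gcoef.size()) ? gcoef[d] : 0.0;
}

} // namespace

// [[Rcpp::export(name = ".gibbs_phase_cpp")]]
List gibbs_phase_cpp(IntegerMatrix baseA, IntegerMatrix baseB, List hetSites,
                     int nBurn, int nMain, int thin,
                     double q, int trunc, int capPair) {
  const int N = baseA.nrow();
  const int V = baseA.ncol();
  const int n2 = 2 * N;
  if (nMain <= 0 || thin <= 0) stop("iteration counts must be positive");

  std::vector<Indiv> ind(N);
  std::vector<int> ambig;
  for (int i = 0; i < N; ++i) {
    IntegerVector hs = hetSites[i];
    ind[i].het.assign(hs.begin(), hs.end());
    ind[i].baseA.resize(V);
    ind[i].baseB.resize(V);
    for (int v = 0; v < V; ++v) {
      ind[i].baseA[v] = baseA(i, v);
      ind[i].baseB[v] = baseB(i, v);
    }
    if ((int)ind[i].het.size() >= 2) ambig.push_back(i);
  }

  // current haplotypes: rows 2i, 2i+1 as strings over V (chars '0'..'3')
  std::vector<std::string> hap(n2, std::string(V, '0'));
  // assignment bit per het site: 0 -> hap 2i carries baseA at that site
  std::vector<std::vector<unsigned char>> assign(N);
  for (int i = 0; i < N; ++i) {
    assign[i].assign(ind[i].het.size(), 0);
    for (size_t s = 0; s < ind[i].het.size(); ++s)
      if (unif_rand() < 0.5) assign[i][s] = 1;
    for (int v = 0; v < V; ++v) {
      hap[2 * i][v] = (char)('0' + ind[i].baseA[v]);
      hap[2 * i + 1][v] = (char)('0' + ind[i].baseB[v]);
    }
    for (size_t s = 0; s < ind[i].het.size(); ++s) {
      int v = ind[i].het[s];
      int a = assign[i][s] ? ind[i].baseB[v] : ind[i].baseA[v];
      int b = assign[i][s] ? ind[i].baseA[v] : ind[i].baseB[v];
      hap[2 * i][v] = (char)('0' + a);
      hap[2 * i + 1][v] = (char)('0' + b);
    }
  }

  std::vector<double> gcoef(trunc + 1);
  for (int d = 0; d <= trunc; ++d)
    gcoef[d] = (1.0 - q) * std::pow(q, d);
  const double g_self = 0.0; // distance x->y is h >= 2; kept explicit below

  // per-ambiguous-individual sample tallies: canonical "x|y" -> count
  std::vector<std::unordered_map<std::string, int>> tally(ambig.size());

  // pool of current haplotypes, maintained incrementally across updates
  std::unordered_map<std::string, int> pool;
  for (int r = 0; r < n2; ++r) pool[hap[r]] += 1;
  auto pool_remove = [&pool](const std::string& s) {
    auto it = pool.find(s);
    if (it != pool.end() && --(it->second) == 0) pool.erase(it);
  };

  std::vector<std::string> distinct;
  std::vector<int> dcount;
  std::vector<int> dbase;
  std::vector<unsigned char> mA, mB; // flattened [s*K + k] mismatch flags
  std::vector<double> wts;
  std::vector<int> dx, dy;

  const int nIter = nBurn + nMain;
  for (int iter = 0; iter < nIter; ++iter) {
    for (size_t ai = 0; ai < ambig.size(); ++ai) {
      const int i = ambig[ai];
      const Indiv& I = ind[i];
      const int h = (int)I.het.size();

      // distinct haplotypes among the other individuals
      pool_remove(hap[2 * i]);
      pool_remove(hap[2 * i + 1]);
      distinct.clear(); dcount.clear();
      distinct.reserve(pool.size()); dcount.reserve(pool.size());
      for (auto& kv : pool) {
        distinct.push_back(kv.first);
        dcount.push_back(kv.second);
      }
      const int K = (int)distinct.size();
      const double nOther = (double)(n2 - 2);

      // distance over the individual's homozygous variable columns
      std::vector<bool> isHet(V, false);
      for (int s = 0; s < h; ++s) isHet[I.het[s]] = true;
      dbase.assign(K, 0);
      for (int k = 0; k < K; ++k) {
        const std::string& hk = distinct[k];
        int d = 0;
        for (int v = 0; v < V; ++v)
          if (!isHet[v] && hk[v] != (char)('0' + I.baseA[v])) ++d;
        dbase[k] = d;
      }
      // per het site, mismatch of each base option against each distinct hap
      mA.assign((size_t)h * K, 0);
      mB.assign((size_t)h * K, 0);
      for (int s = 0; s < h; ++s) {
        int v = I.het[s];
        char ca = (char)('0' + I.baseA[v]);
        char cb = (char)('0' + I.baseB[v]);
        for (int k = 0; k < K; ++k) {
          mA[(size_t)s * K + k] = distinct[k][v] != ca;
          mB[(size_t)s * K + k] = distinct[k][v] != cb;
        }
      }
      double g_xy = (h <= trunc) ? gcoef[h] : g_self; // kernel x -> complement

      if (h - 1 <= capPair) {
        // enumerate all 2^(h-1) unordered decompositions
        const long nc = 1L << (h - 1);
        wts.assign(nc, 0.0);
        double total = 0.0;
        for (long mask = 0; mask < nc; ++mask) {
          double wx = 0.0, wy = 0.0;
          for (int k = 0; k < K; ++k) {
            if (dbase[k] > trunc) continue; // distances only grow
            int ddx = dbase[k], ddy = dbase[k];
            for (int s = 0; s < h; ++s) {
              int bit = (s == 0) ? 0 : (int)((mask >> (s - 1)) & 1L);
              ddx += bit ? mB[(size_t)s * K + k] : mA[(size_t)s * K + k];
              ddy += bit ? mA[(size_t)s * K + k] : mB[(size_t)s * K + k];
              if (ddx > trunc && ddy > trunc) { ddx = trunc + 1; ddy = trunc + 1; break; }
            }
            wx += dcount[k] * gkern(ddx, gcoef);
            wy += dcount[k] * gkern(ddy, gcoef);
          }
          double px = wx / nOther;
          double py = (wy + g_xy) / (nOther + 1.0);
          wts[mask] = px * py;
          total += wts[mask];
        }
        long pick;
        if (total <= 0.0) {
          pick = (long)(unif_rand() * nc);
          if (pick >= nc) pick = nc - 1;
        } else {
          double u = unif_rand() * total, acc = 0.0;
          pick = nc - 1;
          for (long mask = 0; mask < nc; ++mask) {
            acc += wts[mask];
            if (u <= acc) { pick = mask; break; }
          }
        }
        for (int s = 0; s < h; ++s)
          assign[i][s] = (s == 0) ? 0 : (unsigned char)((pick >> (s - 1)) & 1L);
      } else {
        // site-wise Gibbs: flip one phase bit at a time
        dx.assign(K, 0); dy.assign(K, 0);
        for (int k = 0; k < K; ++k) {
          int ddx = dbase[k], ddy = dbase[k];
          for (int s = 0; s < h; ++s) {
            ddx += assign[i][s] ? mB[(size_t)s * K + k] : mA[(size_t)s * K + k];
            ddy += assign[i][s] ? mA[(size_t)s * K + k] : mB[(size_t)s * K + k];
          }
          dx[k] = ddx; dy[k] = ddy;
        }
        for (int s = 0; s < h; ++s) {
          double wx_cur = 0.0, wy_cur = 0.0, wx_flip = 0.0, wy_flip = 0.0;
          for (int k = 0; k < K; ++k) {
            int del = assign[i][s] ? ((int)mA[(size_t)s * K + k] - (int)mB[(size_t)s * K + k])
                                   : ((int)mB[(size_t)s * K + k] - (int)mA[(size_t)s * K + k]);
            wx_cur += dcount[k] * gkern(dx[k], gcoef);
            wy_cur += dcount[k] * gkern(dy[k], gcoef);
            wx_flip += dcount[k] * gkern(dx[k] + del, gcoef);
            wy_flip += dcount[k] * gkern(dy[k] - del, gcoef);
          }
          double w_cur = (wx_cur / nOther) * ((wy_cur + g_xy) / (nOther + 1.0));
          double w_flip = (wx_flip / nOther) * ((wy_flip + g_xy) / (nOther + 1.0));
          double tot = w_cur + w_flip;
          bool flip = (tot <= 0.0) ? (unif_rand() < 0.5)
                                   : (unif_rand() * tot > w_cur);
          if (flip) {
            for (int k = 0; k < K; ++k) {
              int del = assign[i][s] ? ((int)mA[(size_t)s * K + k] - (int)mB[(size_t)s * K + k])
                                     : ((int)mB[(size_t)s * K + k] - (int)mA[(size_t)s * K + k]);
              dx[k] += del; dy[k] -= del;
            }
            assign[i][s] ^= 1;
          }
        }
      }

      // write the chosen pair back into the haplotype pool
      for (int s = 0; s < h; ++s) {
        int v = I.het[s];
        int a = assign[i][s] ? I.baseB[v] : I.baseA[v];
        int b = assign[i][s] ? I.baseA[v] : I.baseB[v];
        hap[2 * i][v] = (char)('0' + a);
        hap[2 * i + 1][v] = (char)('0' + b);
      }
      pool[hap[2 * i]] += 1;
      pool[hap[2 * i + 1]] += 1;
    }

    if (iter >= nBurn && (iter - nBurn) % thin == 0) {
      for (size_t ai = 0; ai < ambig.size(); ++ai) {
        int i = ambig[ai];
        const std::string& x = hap[2 * i];
        const std::string& y = hap[2 * i + 1];
        std::string key = (x <= y) ? x + "|" + y : y + "|" + x;
        tally[ai][key] += 1;
      }
    }
  }

  List out(ambig.size());
  for (size_t ai = 0; ai < ambig.size(); ++ai) {
    std::vector<std::string> keys;
    std::vector<int> counts;
    keys.reserve(tally[ai].size());
    for (auto& kv : tally[ai]) { keys.push_back(kv.first); counts.push_back(kv.second); }
    out[ai] = List::create(Named("keys") = wrap(keys),
                           Named("counts") = wrap(counts));
  }
  return List::create(Named("ambiguous") = wrap(ambig),
                      Named("samples") = out);
}
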