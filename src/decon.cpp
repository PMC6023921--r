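#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Random-swap search resolving one bulk profile into n reference cells.
//
// Objective: Pearson correlation between transform(sum of member columns)
// and transform(bulk), where transform is log2(1 + counts-per-10k) or the
// identity.  Greedy acceptance keeps a swap iff the objective strictly
// increases; Metropolis accepts worse moves with probability exp(dr/T).
//
// When the reference has integer entries and uniform column totals (the
// post-downsampling case) the log transform of the member sum is evaluated
// through an exact lookup table over integer gene sums, since the scale
// factor 1e4/total is then invariant under swaps.

static inline double objective(const std::vector<double>& s, double S,
                               const std::vector<double>& zc, double zden,
                               const std::vector<double>& lut, bool use_lut,
                               bool log_space, int G) {
  double sy = 0.0, syy = 0.0, syz = 0.0;
  if (use_lut) {
    for (int g = 0; g < G; ++g) {
      double y = lut[(int)(s[g] + 0.5)];
      sy += y; syy += y * y; syz += y * zc[g];
    }
  } else if (log_space) {
    const double c0 = 1e4 / S, inv_ln2 = 1.0 / M_LN2;
    for (int g = 0; g < G; ++g) {
      double y = std::log1p(s[g] * c0) * inv_ln2;
      sy += y; syy += y * y; syz += y * zc[g];
    }
  } else {
    for (int g = 0; g < G; ++g) {
      double y = s[g];
      sy += y; syy += y * y; syz += y * zc[g];
    }
  }
  double vary = syy - sy * sy / G;
  if (vary <= 0.0 || zden <= 0.0) return -2.0;  // below any correlation
  return syz / (std::sqrt(vary) * zden);
}

// [[Rcpp::export]]
List decon_search_cpp(NumericMatrix ref, NumericVector bulk, int n,
                      int n_swaps, int n_restarts, bool greedy,
                      double temperature, bool log_space) {
  const int G = ref.nrow(), C = ref.ncol();
  if (n > C) stop("n exceeds the number of reference cells");

  // transformed, centred bulk
  std::vector<double> z(G);
  double bsum = 0.0;
  for (int g = 0; g < G; ++g) bsum += bulk[g];
  if (log_space) {
    const double c0 = 1e4 / bsum, inv_ln2 = 1.0 / M_LN2;
    for (int g = 0; g < G; ++g) z[g] = std::log1p(bulk[g] * c0) * inv_ln2;
  } else {
    for (int g = 0; g < G; ++g) z[g] = bulk[g];
  }
  double zm = 0.0;
  for (int g = 0; g < G; ++g) zm += z[g];
  zm /= G;
  std::vector<double> zc(G);
  double zss = 0.0;
  for (int g = 0; g < G; ++g) { zc[g] = z[g] - zm; zss += zc[g] * zc[g]; }
  double zden = std::sqrt(zss);
  if (zden == 0.0) stop("transformed bulk profile has zero variance");

  // column totals, sparse columns, lookup-table eligibility
  std::vector<double> tot(C, 0.0);
  std::vector< std::vector<int> > cidx(C);
  std::vector< std::vector<double> > cval(C);
  bool all_int = true;
  double maxval = 0.0;
  for (int c = 0; c < C; ++c) {
    for (int g = 0; g < G; ++g) {
      double v = ref(g, c);
      if (v != 0.0) {
        cidx[c].push_back(g);
        cval[c].push_back(v);
        tot[c] += v;
        if (v != std::floor(v) || v < 0.0) all_int = false;
        if (v > maxval) maxval = v;
      }
    }
  }
  bool all_eq = true;
  for (int c = 1; c < C; ++c) if (tot[c] != tot[0]) { all_eq = false; break; }
  bool use_lut = log_space && all_int && all_eq &&
                 (double)n * maxval < 5e7;
  std::vector<double> lut;
  if (use_lut) {
    const double S0 = (double)n * tot[0];
    const double c0 = 1e4 / S0, inv_ln2 = 1.0 / M_LN2;
    int lmax = (int)((double)n * maxval) + 1;
    lut.resize(lmax + 1);
    for (int v = 0; v <= lmax; ++v) lut[v] = std::log1p(v * c0) * inv_ln2;
  }

  IntegerMatrix members_out(n_restarts, n);
  NumericVector corr_out(n_restarts);
  IntegerVector accepted_out(n_restarts);
  List traces(n_restarts);

  std::vector<int> perm(C);
  std::vector<bool> member(C);
  std::vector<double> s(G);
  std::vector<int> mem(n), best_mem(n);

  for (int r = 0; r < n_restarts; ++r) {
    // initial members: partial Fisher-Yates
    for (int c = 0; c < C; ++c) perm[c] = c;
    for (int i = 0; i < n; ++i) {
      int j = i + (int)(unif_rand() * (C - i));
      if (j >= C) j = C - 1;
      std::swap(perm[i], perm[j]);
      mem[i] = perm[i];
    }
    std::fill(member.begin(), member.end(), false);
    std::fill(s.begin(), s.end(), 0.0);
    double S = 0.0;
    for (int i = 0; i < n; ++i) {
      member[mem[i]] = true;
      S += tot[mem[i]];
      const std::vector<int>& ix = cidx[mem[i]];
      const std::vector<double>& vx = cval[mem[i]];
      for (size_t k = 0; k < ix.size(); ++k) s[ix[k]] += vx[k];
    }
    double cur = objective(s, S, zc, zden, lut, use_lut, log_space, G);
    std::vector<double> trace;
    trace.push_back(cur);
    int acc = 0;
    double best = cur;
    best_mem = mem;

    if (n < C) {
      for (int sw = 0; sw < n_swaps; ++sw) {
        int pos = (int)(unif_rand() * n);
        if (pos >= n) pos = n - 1;
        int out = mem[pos];
        int in;
        do {
          in = (int)(unif_rand() * C);
          if (in >= C) in = C - 1;
        } while (member[in]);
        // apply candidate
        for (size_t k = 0; k < cidx[out].size(); ++k)
          s[cidx[out][k]] -= cval[out][k];
        for (size_t k = 0; k < cidx[in].size(); ++k)
          s[cidx[in][k]] += cval[in][k];
        double Snew = S - tot[out] + tot[in];
        double cand = objective(s, Snew, zc, zden, lut, use_lut, log_space, G);
        bool ok = greedy ? (cand > cur)
                         : (cand > cur ||
                            unif_rand() < std::exp((cand - cur) / temperature));
        if (ok) {
          mem[pos] = in;
          member[out] = false;
          member[in] = true;
          S = Snew;
          cur = cand;
          ++acc;
          trace.push_back(cur);
          if (cur > best) { best = cur; best_mem = mem; }
        } else {
          for (size_t k = 0; k < cidx[in].size(); ++k)
            s[cidx[in][k]] -= cval[in][k];
          for (size_t k = 0; k < cidx[out].size(); ++k)
            s[cidx[out][k]] += cval[out][k];
        }
      }
    }
    for (int i = 0; i < n; ++i) members_out(r, i) = best_mem[i] + 1;
    corr_out[r] = best;
    accepted_out[r] = acc;
    traces[r] = NumericVector(trace.begin(), trace.end());
  }
  return List::create(_["members"] = members_out,
                      _["correlation"] = corr_out,
                      _["accepted"] = accepted_out,
                      _["traces"] = traces,
                      _["used_lookup"] = use_lut);
}
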