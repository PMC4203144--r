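// Minimum-free-energy folding of a single RNA strand, no pseudoknots.
// Simplified Zuker recursion over a nearest-neighbor model: stacking
// energies for WC and G:U pairs, loop-length initiation tables for
// hairpin/bulge/internal loops (linear extrapolation past the table),
// affine multiloop energy a + b*branches + c*unpaired, optional flat
// per-pair bonus (pair_bonus = -1 with zero loop terms reproduces the
// Nussinov pair-maximization objective). Minimum hairpin loop = 3 nt.
//
// Bases are encoded 1..4 = A,C,G,U; pair types 1..6 = CG,GC,GU,UG,AU,UA
// (same order as the R-side stack table).

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = 1e18;
static const double EPS = 1e-9;

static inline int pair_type(int a, int b) {
  if (a == 2 && b == 3) return 1;  // C-G
  if (a == 3 && b == 2) return 2;  // G-C
  if (a == 3 && b == 4) return 3;  // G-U
  if (a == 4 && b == 3) return 4;  // U-G
  if (a == 1 && b == 4) return 5;  // A-U
  if (a == 4 && b == 1) return 6;  // U-A
  return 0;
}

struct Model {
  std::vector<double> hairpin, bulge, internal;  // index 1..30
  double stack[7][7];
  double slope, a, b, c, pair_bonus;
  int max_loop;
  double loop(const std::vector<double>& tab, int len) const {
    int n = (int)tab.size() - 1;
    if (len <= 0) return INF;
    if (len <= n) {
      double v = tab[len];
      return R_finite(v) ? v : INF;
    }
    return tab[n] + slope * (len - n);
  }
  double hp(int len) const { return loop(hairpin, len); }
  double bl(int len) const { return loop(bulge, len); }
  double il(int len) const { return loop(internal, len); }
};

class Folder {
public:
  Folder(const IntegerVector& seq, const Model& m) : s(seq.size()), mod(m) {
    n = seq.size();
    for (int i = 0; i < n; ++i) s[i] = seq[i];
    pt.assign((size_t)n * n, 0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        pt[(size_t)i * n + j] = pair_type(s[i], s[j]);
    V.assign((size_t)n * n, INF);
    WM.assign((size_t)n * n, INF);
    W.assign(n + 1, 0.0);
    fill();
  }

  double mfe() const { return n ? W[n] : 0.0; }

  List pairs() {
    pi.clear(); pj.clear();
    if (n) trace_W(n - 1);
    return List::create(Named("i") = wrap(pi), Named("j") = wrap(pj));
  }

private:
  int n;
  std::vector<int> s, pt;
  std::vector<double> V, WM, W;
  std::vector<int> pi, pj;
  const Model& mod;

  inline int P(int i, int j) const { return pt[(size_t)i * n + j]; }
  inline double& v(int i, int j) { return V[(size_t)i * n + j]; }
  inline double& wm(int i, int j) { return WM[(size_t)i * n + j]; }

  double interior_cost(int i, int j, int k, int l) const {
    int l1 = k - i - 1, l2 = j - l - 1;
    if (l1 == 0 && l2 == 0) return mod.stack[P(i, j)][P(k, l)];
    if (l1 == 0 || l2 == 0) return mod.bl(l1 + l2);
    return mod.il(l1 + l2);
  }

  void fill() {
    for (int span = 4; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // --- V(i,j) ---
        if (P(i, j)) {
          double best = mod.hp(j - i - 1);
          int kmax = std::min(j - 2, i + 1 + mod.max_loop);
          for (int k = i + 1; k <= kmax; ++k) {
            int l1 = k - i - 1;
            int lmin = std::max(k + 1, j - 1 - (mod.max_loop - l1));
            for (int l = j - 1; l >= lmin; --l) {
              if (!P(k, l) || V[(size_t)k * n + l] >= INF / 2) continue;
              double e = interior_cost(i, j, k, l) + V[(size_t)k * n + l];
              if (e < best) best = e;
            }
          }
          // multiloop: >= 2 internal branches
          for (int k = i + 2; k <= j - 2; ++k) {
            double left = WM[(size_t)(i + 1) * n + k];
            double right = WM[(size_t)(k + 1) * n + (j - 1)];
            if (left >= INF / 2 || right >= INF / 2) continue;
            double e = mod.a + mod.b + left + right;
            if (e < best) best = e;
          }
          v(i, j) = best + mod.pair_bonus;
        }
        // --- WM(i,j) ---
        double best = INF;
        if (v(i, j) < INF / 2) best = v(i, j) + mod.b;
        if (wm(i + 1, j) < INF / 2) best = std::min(best, wm(i + 1, j) + mod.c);
        if (wm(i, j - 1) < INF / 2) best = std::min(best, wm(i, j - 1) + mod.c);
        for (int k = i + 1; k < j; ++k) {
          double le = wm(i, k - 1), re = wm(k, j);
          if (le < INF / 2 && re < INF / 2)
            best = std::min(best, le + re);
        }
        wm(i, j) = best;
      }
    }
    // external loop, W[j+1] = best energy of prefix s[0..j]
    for (int j = 0; j < n; ++j) {
      double best = W[j];  // j unpaired
      for (int i = 0; i + 4 <= j; ++i) {
        double e = v(i, j);
        if (e >= INF / 2) continue;
        e += (i > 0 ? W[i] : 0.0);
        if (e < best) best = e;
      }
      W[j + 1] = best;
    }
  }

  // --- deterministic traceback: 5'-most explanations first ---
  void trace_W(int j) {
    while (j >= 0) {
      if (j < 4 || std::abs(W[j + 1] - W[j]) < EPS) { --j; continue; }
      bool found = false;
      for (int i = 0; i + 4 <= j; ++i) {
        double e = v(i, j);
        if (e >= INF / 2) continue;
        if (std::abs(W[j + 1] - (e + (i > 0 ? W[i] : 0.0))) < EPS) {
          trace_V(i, j);
          j = i - 1;
          found = true;
          break;
        }
      }
      if (!found) --j;  // defensive; should not happen
    }
  }

  void trace_V(int i, int j) {
    pi.push_back(i + 1); pj.push_back(j + 1);
    double target = v(i, j) - mod.pair_bonus;
    if (std::abs(target - mod.hp(j - i - 1)) < EPS) return;
    int kmax = std::min(j - 2, i + 1 + mod.max_loop);
    for (int k = i + 1; k <= kmax; ++k) {
      int l1 = k - i - 1;
      int lmin = std::max(k + 1, j - 1 - (mod.max_loop - l1));
      for (int l = j - 1; l >= lmin; --l) {
        if (!P(k, l) || v(k, l) >= INF / 2) continue;
        if (std::abs(target - (interior_cost(i, j, k, l) + v(k, l))) < EPS) {
          trace_V(k, l);
          return;
        }
      }
    }
    for (int k = i + 2; k <= j - 2; ++k) {
      double left = wm(i + 1, k), right = wm(k + 1, j - 1);
      if (left >= INF / 2 || right >= INF / 2) continue;
      if (std::abs(target - (mod.a + mod.b + left + right)) < EPS) {
        trace_WM(i + 1, k);
        trace_WM(k + 1, j - 1);
        return;
      }
    }
    Rcpp::stop("traceback failed in V");
  }

  void trace_WM(int i, int j) {
    for (;;) {
      if (j - i < 4) Rcpp::stop("traceback failed in WM");
      double t = wm(i, j);
      if (v(i, j) < INF / 2 && std::abs(t - (v(i, j) + mod.b)) < EPS) {
        trace_V(i, j);
        return;
      }
      if (wm(i + 1, j) < INF / 2 && std::abs(t - (wm(i + 1, j) + mod.c)) < EPS) {
        ++i; continue;
      }
      if (wm(i, j - 1) < INF / 2 && std::abs(t - (wm(i, j - 1) + mod.c)) < EPS) {
        --j; continue;
      }
      bool found = false;
      for (int k = i + 1; k < j; ++k) {
        double le = wm(i, k - 1), re = wm(k, j);
        if (le < INF / 2 && re < INF / 2 && std::abs(t - (le + re)) < EPS) {
          trace_WM(i, k - 1);
          i = k;
          found = true;
          break;
        }
      }
      if (!found) Rcpp::stop("traceback failed in WM split");
    }
  }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq, NumericMatrix stack,
                  NumericVector hairpin, NumericVector bulge,
                  NumericVector internal, double slope, int max_loop,
                  double ml_close, double ml_branch, double ml_unpaired,
                  double pair_bonus) {
  Model m;
  m.hairpin.assign(hairpin.size() + 1, INF);
  for (int k = 0; k < hairpin.size(); ++k)
    m.hairpin[k + 1] = R_finite(hairpin[k]) ? hairpin[k] : INF;
  m.bulge.assign(bulge.size() + 1, INF);
  for (int k = 0; k < bulge.size(); ++k)
    m.bulge[k + 1] = R_finite(bulge[k]) ? bulge[k] : INF;
  m.internal.assign(internal.size() + 1, INF);
  for (int k = 0; k < internal.size(); ++k)
    m.internal[k + 1] = R_finite(internal[k]) ? internal[k] : INF;
  for (int p = 0; p < 7; ++p)
    for (int q = 0; q < 7; ++q) m.stack[p][q] = 0.0;
  for (int p = 1; p <= 6; ++p)
    for (int q = 1; q <= 6; ++q) m.stack[p][q] = stack(p - 1, q - 1);
  m.slope = slope; m.max_loop = max_loop;
  m.a = ml_close; m.b = ml_branch; m.c = ml_unpaired;
  m.pair_bonus = pair_bonus;
  Folder f(seq, m);
  List pr = f.pairs();
  return List::create(Named("mfe") = f.mfe(),
                      Named("i") = pr["i"], Named("j") = pr["j"]);
}
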