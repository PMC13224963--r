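// Hot loop of the strain-frequency search: greedy stochastic descent of the
// hexamodal score S over the 3-strain frequency simplex. Randomness comes
// from R's RNG so seeds set with set.seed() control the whole search.
#include <Rcpp.h>
using namespace Rcpp;

static const int COMP[6] = {5, 4, 3, 2, 1, 0};

static inline void peaks6(const double *f, double *p) {
  p[0] = f[0]; p[1] = f[1]; p[2] = f[2];
  p[3] = f[0] + f[1]; p[4] = f[0] + f[2]; p[5] = f[1] + f[2];
}

// nearest peak; ties resolved to the lowest index (smallest subset first,
// lexicographic within size — the canonical peak order)
static inline int nearest_peak(double x, const double *p, double *dist) {
  int best = 0;
  double bd = std::fabs(x - p[0]);
  for (int k = 1; k < 6; ++k) {
    double d = std::fabs(x - p[k]);
    if (d < bd) { bd = d; best = k; }
  }
  *dist = bd;
  return best;
}

// When peaks coincide (degenerate distributions, e.g. f3 = 0) several
// peaks tie for nearest; the pair/complement assignment is compatible if
// ANY tied choice for the pair has its complementary subset tied for the
// complement — ties are resolved in favour of compatibility.
static const double TIE_EPS = 1e-9;

static double score_at(const double *freq, const double *w, int n,
                       const double *f) {
  double p[6];
  peaks6(f, p);
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double d1, d2;
    nearest_peak(freq[i], p, &d1);
    nearest_peak(1.0 - freq[i], p, &d2);
    bool compat = false;
    for (int k = 0; k < 6 && !compat; ++k) {
      if (std::fabs(std::fabs(freq[i] - p[k]) - d1) <= TIE_EPS &&
          std::fabs(std::fabs(1.0 - freq[i] - p[COMP[k]]) - d2) <= TIE_EPS) {
        compat = true;
      }
    }
    s += w[i] * (compat ? (d1 + d2) : 1.0);
  }
  return s;
}

static inline void clip_renorm(double *f) {
  double s = 0.0;
  for (int i = 0; i < 3; ++i) {
    if (f[i] < 0.0) f[i] = 0.0;
    if (f[i] > 1.0) f[i] = 1.0;
    s += f[i];
  }
  if (s <= 0.0) { f[0] = f[1] = f[2] = 1.0 / 3.0; return; }
  for (int i = 0; i < 3; ++i) f[i] /= s;
}

// shift two random coordinates by signed N(0.002, 0.002) * scale draws,
// set the third to the complement, then clip to [0,1] and renormalize
static void propose(const double *f, double *out, double scale) {
  int i = (int)std::floor(unif_rand() * 3.0); if (i > 2) i = 2;
  int j = (int)std::floor(unif_rand() * 2.0); if (j > 1) j = 1;
  if (j >= i) ++j;               // j is a different coordinate than i
  int k = 3 - i - j;
  double di = R::rnorm(0.002 * scale, 0.002 * scale);
  double dj = R::rnorm(0.002 * scale, 0.002 * scale);
  if (unif_rand() < 0.5) di = -di;
  if (unif_rand() < 0.5) dj = -dj;
  out[i] = f[i] + di;
  out[j] = f[j] + dj;
  out[k] = 1.0 - out[i] - out[j];
  clip_renorm(out);
}

// uniform draw from the simplex (normalized exponentials)
static void fresh_draw(double *out) {
  double s = 0.0;
  for (int i = 0; i < 3; ++i) { out[i] = R::exp_rand(); s += out[i]; }
  for (int i = 0; i < 3; ++i) out[i] /= s;
}

// one of four equiprobable options: proposal scale x5, x10, x100, or a
// fresh uniform distribution
static void big_jump(const double *f, double *out) {
  double u = unif_rand();
  if (u < 0.25) propose(f, out, 5.0);
  else if (u < 0.5) propose(f, out, 10.0);
  else if (u < 0.75) propose(f, out, 100.0);
  else fresh_draw(out);
}

// [[Rcpp::export]]
double cpp_pair_score(NumericVector freq, NumericVector weights,
                      NumericVector dist) {
  return score_at(freq.begin(), weights.begin(), freq.size(), dist.begin());
}

// [[Rcpp::export]]
NumericVector cpp_propose(NumericVector dist, double scale) {
  NumericVector out(3);
  propose(dist.begin(), out.begin(), scale);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_big_jump(NumericVector dist) {
  NumericVector out(3);
  big_jump(dist.begin(), out.begin());
  return out;
}

// Best two-strain configuration (a, 1-a, 0): coarse grid then local
// refinement. Used to simplify degenerate three-strain solutions.
// [[Rcpp::export]]
List cpp_refit2(NumericVector freq, NumericVector weights) {
  const double *fr = freq.begin();
  const double *w = weights.begin();
  const int n = freq.size();
  double best_a = 0.5, best_s = R_PosInf;
  double f[3];
  f[2] = 0.0;
  for (double a = 0.5; a <= 1.0 + 1e-12; a += 0.002) {
    f[0] = a; f[1] = 1.0 - a;
    double s = score_at(fr, w, n, f);
    if (s < best_s) { best_s = s; best_a = a; }
  }
  for (double a = best_a - 0.002; a <= best_a + 0.002 + 1e-12; a += 1e-4) {
    if (a < 0.5 || a > 1.0) continue;
    f[0] = a; f[1] = 1.0 - a;
    double s = score_at(fr, w, n, f);
    if (s < best_s) { best_s = s; best_a = a; }
  }
  return List::create(_["a"] = best_a, _["score"] = best_s);
}

// [[Rcpp::export]]
List cpp_run_search(NumericVector freq, NumericVector weights,
                    int n_walkers, int converge, int stall_jump,
                    int jump_every, double init_sd, int max_iter) {
  const double *fr = freq.begin();
  const double *w = weights.begin();
  const int n = freq.size();

  NumericMatrix trace(n_walkers, 6);
  double gbest[3] = {1.0 / 3.0, 1.0 / 3.0, 1.0 / 3.0};
  double gbest_s = R_PosInf;

  for (int wk = 0; wk < n_walkers; ++wk) {
    double f[3];
    if (wk == 0) {
      f[0] = f[1] = f[2] = 1.0 / 3.0;   // the equal-frequency start
    } else {
      for (int i = 0; i < 3; ++i) f[i] = 1.0 / 3.0 + R::rnorm(0.0, init_sd);
      clip_renorm(f);
    }
    double s = score_at(fr, w, n, f);
    int noimp = 0, stall = 0, iter = 0;
    double cand[3];
    while (noimp < converge && iter < max_iter) {
      ++iter;
      bool jump = (iter % jump_every == 0) || (stall >= stall_jump);
      if (jump) big_jump(f, cand); else propose(f, cand, 1.0);
      double cs = score_at(fr, w, n, cand);
      if (cs < s) {
        f[0] = cand[0]; f[1] = cand[1]; f[2] = cand[2];
        s = cs; noimp = 0; stall = 0;
      } else {
        ++noimp; ++stall;
      }
    }
    trace(wk, 0) = wk + 1; trace(wk, 1) = iter; trace(wk, 2) = s;
    trace(wk, 3) = f[0]; trace(wk, 4) = f[1]; trace(wk, 5) = f[2];
    if (s < gbest_s) {
      gbest_s = s; gbest[0] = f[0]; gbest[1] = f[1]; gbest[2] = f[2];
    }
  }
  return List::create(_["freqs"] = NumericVector::create(
                          gbest[0], gbest[1], gbest[2]),
                      _["score"] = gbest_s, _["trace"] = trace);
}
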