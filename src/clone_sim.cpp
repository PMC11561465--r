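#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Time-inhomogeneous birth-death simulation of one KC clone by thinning.
//
// State: K = TAPs, D = prNBs, P = pmNBs (absorbing). Events:
//   K -> 2K            rate lamK * K
//   TAP differentiation rate gK0 * t^aK * K, effect by modeK:
//     0 independent of division:  K-1, D+1
//     1 symmetric division:       K-1, D+2
//     2 asymmetric division:      K  , D+1
//   D -> 2D            rate lamD * D
//   D -> P (cycle exit) rate gD0 * t^aD * D   (division-independent)
//
// Power-law propensities are nondecreasing in t (alpha >= 0 enforced on
// the R side), so a piecewise-constant majorant evaluated at the end of a
// bounded window dominates the true rate over the window.

struct CloneP {
  double lamK, lamD, gK0, aK, gD0, aD;
  int modeK;
};

static inline double gam(double g0, double a, double t) {
  if (g0 <= 0.0) return 0.0;
  if (t <= 0.0) return a > 0.0 ? 0.0 : g0;
  return g0 * std::pow(t, a);
}

// Advance one clone from time t0 to t_max. Optionally record events.
// Returns true if the clone is "frozen": K + D > 0 but every applicable
// rate is identically zero, so no event can ever occur.
static bool run_clone(const CloneP &p, double t0, double t_max,
                      int &K, int &D, int &P,
                      std::vector<double> *ev_t = nullptr,
                      std::vector<int> *ev_type = nullptr,
                      std::vector<int> *ev_K = nullptr,
                      std::vector<int> *ev_D = nullptr,
                      std::vector<int> *ev_P = nullptr) {
  const double win = 0.25;
  double t = t0;
  while (t < t_max && (K + D) > 0) {
    double t_end = std::min(t + win, t_max);
    double maj = K * (p.lamK + gam(p.gK0, p.aK, t_end)) +
                 D * (p.lamD + gam(p.gD0, p.aD, t_end));
    if (maj <= 0.0) {
      // power-law rates only grow with t: zero majorant at t_end > 0
      // means the active populations have all-zero rate parameters
      bool k_dead = (K == 0) || (p.lamK == 0.0 && p.gK0 == 0.0);
      bool d_dead = (D == 0) || (p.lamD == 0.0 && p.gD0 == 0.0);
      if (k_dead && d_dead) return (K + D) > 0;
      t = t_end;
      continue;
    }
    double dt = R::exp_rand() / maj;
    if (t + dt > t_end) { t = t_end; continue; }
    t += dt;
    double rKb = p.lamK * K;
    double rKd = gam(p.gK0, p.aK, t) * K;
    double rDb = p.lamD * D;
    double rDd = gam(p.gD0, p.aD, t) * D;
    double u = unif_rand() * maj;
    int type;
    if (u < rKb) { K += 1; type = 0; }
    else if (u < rKb + rKd) {
      if (p.modeK == 0) { K -= 1; D += 1; }
      else if (p.modeK == 1) { K -= 1; D += 2; }
      else { D += 1; }
      type = 1;
    }
    else if (u < rKb + rKd + rDb) { D += 1; type = 2; }
    else if (u < rKb + rKd + rDb + rDd) { D -= 1; P += 1; type = 3; }
    else continue;  // thinning rejection
    if (ev_t) {
      ev_t->push_back(t); ev_type->push_back(type);
      ev_K->push_back(K); ev_D->push_back(D); ev_P->push_back(P);
    }
  }
  return false;
}

// [[Rcpp::export]]
List clone_trajectory_cpp(double lamK, double lamD, double gK0, double aK,
                          double gD0, double aD, int modeK, double t_max,
                          int K0, int D0, int P0) {
  CloneP p{lamK, lamD, gK0, aK, gD0, aD, modeK};
  int K = K0, D = D0, P = P0;
  std::vector<double> ev_t;
  std::vector<int> ev_type, ev_K, ev_D, ev_P;
  bool frozen = run_clone(p, 0.0, t_max, K, D, P,
                          &ev_t, &ev_type, &ev_K, &ev_D, &ev_P);
  return List::create(
      _["time"] = wrap(ev_t), _["type"] = wrap(ev_type),
      _["K"] = wrap(ev_K), _["D"] = wrap(ev_D), _["P"] = wrap(ev_P),
      _["final"] = IntegerVector::create(K, D, P),
      _["frozen"] = frozen);
}

// [[Rcpp::export]]
IntegerMatrix clone_snapshots_cpp(double lamK, double lamD, double gK0,
                                  double aK, double gD0, double aD,
                                  int modeK, NumericVector ages,
                                  int K0, int D0, int P0) {
  CloneP p{lamK, lamD, gK0, aK, gD0, aD, modeK};
  int n = ages.size();
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    int K = K0, D = D0, P = P0;
    run_clone(p, 0.0, ages[i], K, D, P);
    out(i, 0) = K; out(i, 1) = D; out(i, 2) = P;
  }
  colnames(out) = CharacterVector::create("k", "d", "p");
  return out;
}
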