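// Compiled cores: damped Newton for the reduced mean-field system and the
// event-driven Gillespie simulator on the nucleosome lattice.
//
// State codes are 0-based here: 0=S, 1=U, 2=A, 3=M, 4=E (R side is 1-based).
// All random draws go through R's RNG (unif_rand) so that set.seed() in R
// makes every trajectory bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Mean-field Newton
// ---------------------------------------------------------------------------

// Reduced RHS in x = (s, a, m, e); u = 1 - sum(x). Rates: al and de are
// already scaled by the titration factor.
static inline void mf_F(const double* x, const double* r, double* f) {
  const double al = r[0], de = r[1], ga = r[2], b0 = r[3], be = r[4],
               et = r[5], la = r[6];
  const double s = x[0], a = x[1], m = x[2], e = x[3];
  const double u = 1.0 - s - a - m - e;
  const double bb = b0 + be * e;
  f[0] = al * u + de * s * u - la * s;
  f[1] = ga * u - (bb + et * s + la) * a;
  f[2] = bb * u + et * s * e - (ga + la) * m;
  f[3] = ga * m + bb * a - (et * s + la) * e;
}

static inline void mf_J(const double* x, const double* r, double J[4][4]) {
  const double al = r[0], de = r[1], ga = r[2], b0 = r[3], be = r[4],
               et = r[5], la = r[6];
  const double s = x[0], a = x[1], m = x[2], e = x[3];
  const double u = 1.0 - s - a - m - e;
  const double bb = b0 + be * e;
  J[0][0] = -al + de * (u - s) - la; J[0][1] = -al - de * s;
  J[0][2] = -al - de * s;            J[0][3] = -al - de * s;
  J[1][0] = -ga - et * a; J[1][1] = -ga - (bb + et * s + la);
  J[1][2] = -ga;          J[1][3] = -ga - be * a;
  J[2][0] = -bb + et * e; J[2][1] = -bb;
  J[2][2] = -bb - ga - la; J[2][3] = be * u - bb + et * s;
  J[3][0] = -et * e; J[3][1] = bb;
  J[3][2] = ga;      J[3][3] = be * a - et * s - la;
}

// solve 4x4 linear system by Gaussian elimination with partial pivoting;
// returns false when singular
static bool solve4(double A[4][4], double* b, double* out) {
  int piv[4] = {0, 1, 2, 3};
  for (int c = 0; c < 4; ++c) {
    int best = c;
    double amax = std::fabs(A[piv[c]][c]);
    for (int rI = c + 1; rI < 4; ++rI) {
      double v = std::fabs(A[piv[rI]][c]);
      if (v > amax) { amax = v; best = rI; }
    }
    if (amax < 1e-300) return false;
    std::swap(piv[c], piv[best]);
    const double d = A[piv[c]][c];
    for (int rI = c + 1; rI < 4; ++rI) {
      const double fmult = A[piv[rI]][c] / d;
      if (fmult == 0.0) continue;
      for (int k = c; k < 4; ++k) A[piv[rI]][k] -= fmult * A[piv[c]][k];
      b[piv[rI]] -= fmult * b[piv[c]];
    }
  }
  for (int c = 3; c >= 0; --c) {
    double s = b[piv[c]];
    for (int k = c + 1; k < 4; ++k) s -= A[piv[c]][k] * out[k];
    out[c] = s / A[piv[c]][c];
  }
  return true;
}

static inline double maxabs4(const double* v) {
  double m = std::fabs(v[0]);
  for (int i = 1; i < 4; ++i) m = std::max(m, std::fabs(v[i]));
  return m;
}

// [[Rcpp::export]]
NumericMatrix mf_newton_multi(NumericVector rates, NumericMatrix starts,
                              double tol, int maxit) {
  const int ns = starts.nrow();
  std::vector<double> found;  // flattened roots, 4 per entry
  const double* r = rates.begin();
  for (int sI = 0; sI < ns; ++sI) {
    double x[4], f[4];
    for (int i = 0; i < 4; ++i) x[i] = starts(sI, i);
    mf_F(x, r, f);
    bool ok = true;
    for (int it = 0; it < maxit; ++it) {
      double fn0 = maxabs4(f);
      if (fn0 < tol) break;
      double J[4][4], b[4], step[4];
      mf_J(x, r, J);
      for (int i = 0; i < 4; ++i) b[i] = f[i];
      if (!solve4(J, b, step)) { ok = false; break; }
      double lam = 1.0, xn[4], fn[4];
      for (int h = 0; h < 25; ++h) {
        bool fin = true;
        for (int i = 0; i < 4; ++i) {
          xn[i] = x[i] - lam * step[i];
          if (!std::isfinite(xn[i])) fin = false;
        }
        if (fin) {
          mf_F(xn, r, fn);
          for (int i = 0; i < 4; ++i) if (!std::isfinite(fn[i])) fin = false;
          if (fin && (maxabs4(fn) < fn0 || h == 24)) break;
        }
        lam *= 0.5;
      }
      for (int i = 0; i < 4; ++i) { x[i] = xn[i]; f[i] = fn[i]; }
    }
    if (!ok || maxabs4(f) >= 1e-10) continue;
    double u = 1.0 - x[0] - x[1] - x[2] - x[3];
    bool inbox = (u > -1e-9 && u < 1.0 + 1e-9);
    for (int i = 0; i < 4; ++i)
      if (x[i] < -1e-9 || x[i] > 1.0 + 1e-9) inbox = false;
    if (!inbox) continue;
    for (int i = 0; i < 4; ++i) found.push_back(std::min(std::max(x[i], 0.0), 1.0));
  }
  const int nr = (int)found.size() / 4;
  NumericMatrix out(nr, 4);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = found[4 * i + j];
  return out;
}

// ---------------------------------------------------------------------------
// Gillespie lattice simulator
// ---------------------------------------------------------------------------

struct Channels {
  std::vector<int> src, tgt, cm;      // cm = -1 when purely basal
  std::vector<double> basal, coop;
  std::vector<int> tit;               // titrated flag
  // channel indices grouped by source state
  std::vector<std::vector<int> > by_src;
  void build_index() {
    by_src.assign(5, std::vector<int>());
    for (size_t k = 0; k < src.size(); ++k) by_src[src[k]].push_back((int)k);
  }
};

class LatticeSim {
public:
  int L, hw, pinL, pinR;
  bool include_self, titrate;
  double n_total, v_nuc, rho_ref, fixed_fac;
  std::vector<int> state;
  std::vector<double> wts;            // length 2*hw+1, centered
  Channels ch;

  std::vector<double> dens;           // L x 5 raw weighted counts
  std::vector<double> norm;           // per-site weight normalization
  std::vector<double> pfix, ptit;     // per-site propensity parts
  double Sfix, Stit;
  double n_bound, rho_free;

  LatticeSim(IntegerVector st, int pin_left, int pin_right,
             NumericVector weights, int half_width, bool incl_self,
             List channels, double nt, double v, double rr,
             bool tit, double ffac)
      : L(st.size()), hw(half_width), pinL(pin_left), pinR(pin_right),
        include_self(incl_self), titrate(tit), n_total(nt), v_nuc(v),
        rho_ref(rr), fixed_fac(ffac) {
    state.assign(st.begin(), st.end());
    wts.assign(weights.begin(), weights.end());
    IntegerVector s = channels["src"], t = channels["tgt"], c = channels["cm"];
    NumericVector b = channels["basal"], co = channels["coop"];
    IntegerVector ti = channels["tit"];
    ch.src.assign(s.begin(), s.end());
    ch.tgt.assign(t.begin(), t.end());
    ch.cm.assign(c.begin(), c.end());
    ch.basal.assign(b.begin(), b.end());
    ch.coop.assign(co.begin(), co.end());
    ch.tit.assign(ti.begin(), ti.end());
    ch.build_index();
    refresh_all();
  }

  bool pinned(int i) const { return i < pinL || i >= L - pinR; }

  void recount_bound() {
    n_bound = 0;
    for (int i = 0; i < L; ++i) if (state[i] == 0) n_bound += 1;
    rho_free = (n_total - n_bound) / v_nuc;
    if (rho_free < 0) stop("Sir pool overdrawn: n_bound > n_total");
  }

  void recompute_densities() {
    dens.assign((size_t)L * 5, 0.0);
    norm.assign(L, 0.0);
    for (int i = 0; i < L; ++i) {
      for (int d = -hw; d <= hw; ++d) {
        if (d == 0 && !include_self) continue;
        int j = i + d;
        if (j < 0 || j >= L) continue;
        double w = wts[d + hw];
        norm[i] += w;
        dens[(size_t)i * 5 + state[j]] += w;
      }
    }
  }

  double site_prop(int i, bool tit_part) const {
    if (pinned(i)) return 0.0;
    const int s = state[i];
    double tot = 0.0;
    const std::vector<int>& idx = ch.by_src[s];
    for (size_t k = 0; k < idx.size(); ++k) {
      const int c = idx[k];
      if ((ch.tit[c] != 0) != tit_part) continue;
      double rate = ch.basal[c];
      if (ch.cm[c] >= 0 && norm[i] > 0)  // a 1-site lattice has no neighbors
        rate += ch.coop[c] * dens[(size_t)i * 5 + ch.cm[c]] / norm[i];
      tot += rate;
    }
    return tot;
  }

  void recompute_propensities() {
    pfix.assign(L, 0.0);
    ptit.assign(L, 0.0);
    Sfix = Stit = 0.0;
    for (int i = 0; i < L; ++i) {
      pfix[i] = site_prop(i, false);
      ptit[i] = site_prop(i, true);
      Sfix += pfix[i];
      Stit += ptit[i];
    }
  }

  void refresh_all() {
    recount_bound();
    recompute_densities();
    recompute_propensities();
  }

  double fac() const {
    if (!titrate) return fixed_fac;
    double f = rho_free / rho_ref;
    return f > 0 ? f : 0.0;
  }

  // execute state change at site i
  void execute(int i, int s_new) {
    const int s_old = state[i];
    state[i] = s_new;
    if (s_old == 0) { n_bound -= 1; }
    if (s_new == 0) {
      n_bound += 1;
      if (n_bound > n_total + 1e-9) stop("Sir pool overdrawn (propensity bug)");
    }
    rho_free = (n_total - n_bound) / v_nuc;
    // density updates at neighbors
    for (int d = -hw; d <= hw; ++d) {
      if (d == 0 && !include_self) continue;
      int j = i + d;
      if (j < 0 || j >= L) continue;
      double w = wts[hw - d];  // weight of site i as neighbor of j (symmetric)
      dens[(size_t)j * 5 + s_old] -= w;
      dens[(size_t)j * 5 + s_new] += w;
    }
    // propensity updates at i and neighbors
    int lo = std::max(0, i - hw), hi = std::min(L - 1, i + hw);
    for (int j = lo; j <= hi; ++j) {
      Sfix -= pfix[j]; Stit -= ptit[j];
      pfix[j] = site_prop(j, false);
      ptit[j] = site_prop(j, true);
      Sfix += pfix[j]; Stit += ptit[j];
    }
  }
};

// [[Rcpp::export]]
List gillespie_lattice(IntegerVector init_state, int pin_left, int pin_right,
                       NumericVector weights, int half_width,
                       bool include_self, List channels,
                       double n_total, double v_nucleus, double rho_ref,
                       bool titrate, double fixed_fac,
                       double n_events, double burn_in, double sample_every) {
  LatticeSim sim(init_state, pin_left, pin_right, weights, half_width,
                 include_self, channels, n_total, v_nucleus, rho_ref,
                 titrate, fixed_fac);
  const long long NE = (long long)n_events;
  const long long BI = (long long)burn_in;
  const long long SE = (long long)sample_every;
  const long long n_samp = (NE - BI) / SE;
  IntegerMatrix samples((int)n_samp, sim.L);
  NumericVector s_event(n_samp), s_time(n_samp), s_nb(n_samp), s_rho(n_samp);
  bool frozen = false;
  double t = 0.0;
  long long ev = 0, rec = 0, executed = 0;

  RNGScope rng;
  while (ev < NE) {
    ++ev;
    if (ev % 100000 == 0) sim.refresh_all();  // kill float drift
    double f = sim.fac();
    double tot = sim.Sfix + f * sim.Stit;
    if (!frozen && tot > 1e-12) {
      t += -std::log(unif_rand()) / tot;
      double u = unif_rand() * tot;
      int isite = -1;
      double acc = 0.0;
      for (int i = 0; i < sim.L; ++i) {
        double sp = sim.pfix[i] + f * sim.ptit[i];
        acc += sp;
        if (u <= acc && sp > 0) { isite = i; break; }
      }
      if (isite < 0) {  // float slack: take last site with positive propensity
        for (int i = sim.L - 1; i >= 0; --i)
          if (sim.pfix[i] + f * sim.ptit[i] > 0) { isite = i; break; }
      }
      if (isite >= 0) {
        // channel within site
        const std::vector<int>& idx = sim.ch.by_src[sim.state[isite]];
        double ctot = 0.0;
        std::vector<double> cp(idx.size());
        for (size_t k = 0; k < idx.size(); ++k) {
          const int c = idx[k];
          double rate = sim.ch.basal[c];
          if (sim.ch.cm[c] >= 0 && sim.norm[isite] > 0)
            rate += sim.ch.coop[c] *
                    sim.dens[(size_t)isite * 5 + sim.ch.cm[c]] / sim.norm[isite];
          if (sim.ch.tit[c]) rate *= f;
          cp[k] = rate;
          ctot += rate;
        }
        double uc = unif_rand() * ctot, ca = 0.0;
        int cpick = (int)idx.size() - 1;
        for (size_t k = 0; k < idx.size(); ++k) {
          ca += cp[k];
          if (uc <= ca) { cpick = (int)k; break; }
        }
        sim.execute(isite, sim.ch.tgt[idx[cpick]]);
        ++executed;
      }
    } else if (!frozen) {
      frozen = true;  // no reaction possible; remaining samples repeat state
    }
    if (ev > BI && (ev - BI) % SE == 0 && rec < n_samp) {
      for (int i = 0; i < sim.L; ++i) samples((int)rec, i) = sim.state[i] + 1;
      s_event[rec] = (double)ev;
      s_time[rec] = t;
      s_nb[rec] = sim.n_bound;
      s_rho[rec] = sim.rho_free;
      ++rec;
    }
  }
  return List::create(_["samples"] = samples, _["event"] = s_event,
                      _["time"] = s_time, _["n_bound"] = s_nb,
                      _["rho_free"] = s_rho,
                      _["event_count"] = (double)executed,
                      _["frozen"] = frozen);
}

// ---------------------------------------------------------------------------
// Well-mixed reference simulator: uniform interaction over the whole
// lattice (local density = global fraction), no pinning. Test oracle for
// mean-field agreement.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gillespie_wellmixed(IntegerVector init_state, List channels,
                         double n_total, double v_nucleus, double rho_ref,
                         bool titrate, double fixed_fac,
                         double n_events, double burn_in,
                         double sample_every) {
  const int L = init_state.size();
  std::vector<int> state(init_state.begin(), init_state.end());
  Channels ch;
  {
    IntegerVector s = channels["src"], t = channels["tgt"], c = channels["cm"];
    NumericVector b = channels["basal"], co = channels["coop"];
    IntegerVector ti = channels["tit"];
    ch.src.assign(s.begin(), s.end());
    ch.tgt.assign(t.begin(), t.end());
    ch.cm.assign(c.begin(), c.end());
    ch.basal.assign(b.begin(), b.end());
    ch.coop.assign(co.begin(), co.end());
    ch.tit.assign(ti.begin(), ti.end());
    ch.build_index();
  }
  double cnt[5] = {0, 0, 0, 0, 0};
  for (int i = 0; i < L; ++i) cnt[state[i]] += 1;
  double n_bound = cnt[0];
  double rho_free = (n_total - n_bound) / v_nucleus;
  const long long NE = (long long)n_events;
  const long long BI = (long long)burn_in;
  const long long SEv = (long long)sample_every;
  const long long n_samp = (NE - BI) / SEv;
  NumericMatrix frac(n_samp, 5);
  bool frozen = false;
  long long ev = 0, rec = 0, executed = 0;
  const int K = (int)ch.src.size();
  std::vector<double> cprop(K);

  RNGScope rng;
  while (ev < NE) {
    ++ev;
    double f;
    if (titrate) {
      f = rho_free / rho_ref;
      if (f < 0) f = 0;
    } else f = fixed_fac;
    double tot = 0.0;
    for (int c = 0; c < K; ++c) {
      double rate = ch.basal[c];
      if (ch.cm[c] >= 0) {
        // uniform weights over all OTHER sites (self excluded, as on the
        // lattice): every source site sees the same density
        double d = cnt[ch.cm[c]] - (ch.cm[c] == ch.src[c] ? 1.0 : 0.0);
        rate += ch.coop[c] * d / (L - 1);
      }
      if (ch.tit[c]) rate *= f;
      cprop[c] = rate * cnt[ch.src[c]];
      tot += cprop[c];
    }
    if (!frozen && tot > 1e-12) {
      double u = unif_rand() * tot, acc = 0.0;
      int cpick = K - 1;
      for (int c = 0; c < K; ++c) {
        acc += cprop[c];
        if (u <= acc && cprop[c] > 0) { cpick = c; break; }
      }
      // uniformly random site among those in the source state
      const int s_old = ch.src[cpick], s_new = ch.tgt[cpick];
      int k = (int)std::floor(unif_rand() * cnt[s_old]);
      if (k >= (int)cnt[s_old]) k = (int)cnt[s_old] - 1;
      int isite = -1, seen = 0;
      for (int i = 0; i < L; ++i) {
        if (state[i] == s_old && seen++ == k) { isite = i; break; }
      }
      state[isite] = s_new;
      cnt[s_old] -= 1;
      cnt[s_new] += 1;
      if (s_old == 0 || s_new == 0) {
        n_bound = cnt[0];
        rho_free = (n_total - n_bound) / v_nucleus;
        if (rho_free < -1e-9) stop("Sir pool overdrawn (wellmixed)");
      }
      ++executed;
    } else if (!frozen) frozen = true;
    if (ev > BI && (ev - BI) % SEv == 0 && rec < n_samp) {
      for (int j = 0; j < 5; ++j) frac(rec, j) = cnt[j] / L;
      ++rec;
    }
  }
  return List::create(_["frac"] = frac, _["event_count"] = (double)executed,
                      _["frozen"] = frozen);
}
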