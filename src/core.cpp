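// Fixed-step RK4 integration core for 1-D fields of cell-autonomous GRN ODEs.
//
// Families: 0 = FF, 1 = FFTG (timer is the last state), 2 = SR2M, 3 = SRDM.
// Cells are indexed 0..n-1 anterior -> posterior; the posterior pole sits
// behind the last cell, so cell c's distance from the pole at a time with
// nAlive cells is (nAlive - c) - 0.5 (cell-centers convention).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sigm(double u, double k) {
  return 1.0 / (1.0 + std::exp(-k * u));
}

struct Net {
  int family, n, nstate;
  std::vector<double> Wd, Ws, rho, hd, hs, R, lam0, lam1;
  double ksig, Mmax, kappa, lamT, Tref;
  bool hasWs;
};

static Net unpackNet(const List& nl) {
  Net net;
  net.family = as<int>(nl["family_code"]);
  net.n      = as<int>(nl["n_genes"]);
  net.nstate = net.family == 1 ? net.n + 1 : net.n;
  NumericMatrix Wd = nl["W_dyn"];
  net.Wd.assign(Wd.begin(), Wd.end());
  RObject wsObj = nl["W_stat"];
  net.hasWs = !wsObj.isNULL();
  if (net.hasWs) {
    NumericMatrix Ws = nl["W_stat"];
    net.Ws.assign(Ws.begin(), Ws.end());
  }
  NumericVector rho = nl["rho"], hd = nl["h_dyn"], hs = nl["h_stat"],
                R = nl["R"], l0 = nl["lam0"], l1 = nl["lam1"];
  net.rho.assign(rho.begin(), rho.end());
  net.hd.assign(hd.begin(), hd.end());
  net.hs.assign(hs.begin(), hs.end());
  net.R.assign(R.begin(), R.end());
  net.lam0.assign(l0.begin(), l0.end());
  net.lam1.assign(l1.begin(), l1.end());
  net.ksig = as<double>(nl["k_sig"]);
  net.Mmax = as<double>(nl["M_max"]);
  net.kappa = as<double>(nl["kappa"]);
  net.lamT  = as<double>(nl["lam_T"]);
  net.Tref  = as<double>(nl["T_ref"]);
  return net;
}

// family-specific right-hand side for one cell; Rs = effective production
// ceilings (after RNAi scaling), add = additive exogenous production term.
static void rhs(const Net& net, const double* g, double M,
                const double* Rs, const double* add, double* dg) {
  const int n = net.n;
  if (net.family == 0) {            // FF: thresholds of M itself
    for (int i = 0; i < n; ++i) {
      double u = net.rho[i] * M + net.hd[i];
      for (int j = 0; j < n; ++j) u += net.Wd[i + n * j] * g[j];
      dg[i] = Rs[i] * sigm(u, net.ksig) - net.lam0[i] * g[i] + add[i];
    }
  } else if (net.family == 1) {     // FFTG: thresholds of the timer
    double Tn = g[n] / net.Tref;
    for (int i = 0; i < n; ++i) {
      double u = net.rho[i] * Tn + net.hd[i];
      for (int j = 0; j < n; ++j) u += net.Wd[i + n * j] * g[j];
      dg[i] = Rs[i] * sigm(u, net.ksig) - net.lam0[i] * g[i] + add[i];
    }
    dg[n] = net.kappa * M - net.lamT * g[n];
  } else if (net.family == 2) {     // SR2M: convex dynamic/static mixing
    double m = M / net.Mmax;
    if (m < 0) m = 0; else if (m > 1) m = 1;
    for (int i = 0; i < n; ++i) {
      double ud = net.hd[i], us = net.hs[i];
      for (int j = 0; j < n; ++j) {
        ud += net.Wd[i + n * j] * g[j];
        us += net.Ws[i + n * j] * g[j];
      }
      double u = m * ud + (1.0 - m) * us;
      dg[i] = Rs[i] * sigm(u, net.ksig) - net.lam0[i] * g[i] + add[i];
    }
  } else {                          // SRDM: m scales production and decay
    double m = M / net.Mmax;
    if (m < 0) m = 0; else if (m > 1) m = 1;
    for (int i = 0; i < n; ++i) {
      double u = net.hd[i];
      for (int j = 0; j < n; ++j) u += net.Wd[i + n * j] * g[j];
      dg[i] = m * Rs[i] * sigm(u, net.ksig)
              - (net.lam0[i] + net.lam1[i] * m) * g[i] + add[i];
    }
  }
}

struct Prog {
  int regime;   // 0 static 1 buildup 2 decaying 3 buildup_decay 4 composite 5 axn
  double amp, xi, tau_build, t_decay_start, tau_decay, xi_axn;
};

static Prog unpackProg(const List& pl) {
  Prog p;
  p.regime = as<int>(pl["regime_code"]);
  p.amp = as<double>(pl["M_amp"]);
  p.xi = as<double>(pl["xi"]);
  p.tau_build = as<double>(pl["tau_build"]);
  p.t_decay_start = as<double>(pl["t_decay_start"]);
  p.tau_decay = as<double>(pl["tau_decay"]);
  p.xi_axn = as<double>(pl["xi_axn"]);
  return p;
}

static inline double evalM(const Prog& p, double d, double t) {
  double len = (p.regime == 5) ? p.xi_axn : p.xi;
  double M = p.amp * std::exp(-d / len);
  if (p.regime == 1 || p.regime == 3)
    M *= 1.0 - std::exp(-t / p.tau_build);
  if (p.regime == 2 || p.regime == 3) {
    double dt_ = t - p.t_decay_start;
    if (dt_ > 0) M *= std::exp(-dt_ / p.tau_decay);
  }
  return M;
}

// one RK4 step for a single cell; M supplied at t, t+dt/2, t+dt
static void rk4step(const Net& net, double* g, double M0, double Mh, double M1,
                    const double* Rs, const double* add0, const double* addh,
                    const double* add1, double dt) {
  const int ns = net.nstate;
  double k1[32], k2[32], k3[32], k4[32], tmp[32];
  rhs(net, g, M0, Rs, add0, k1);
  for (int i = 0; i < ns; ++i) tmp[i] = g[i] + 0.5 * dt * k1[i];
  rhs(net, tmp, Mh, Rs, addh, k2);
  for (int i = 0; i < ns; ++i) tmp[i] = g[i] + 0.5 * dt * k2[i];
  rhs(net, tmp, Mh, Rs, addh, k3);
  for (int i = 0; i < ns; ++i) tmp[i] = g[i] + dt * k3[i];
  rhs(net, tmp, M1, Rs, add1, k4);
  for (int i = 0; i < ns; ++i)
    g[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// events: reinduce (gene1based, t_on, t_off, amp, mode 0=additive 1=clamp),
// rnai (gene1based, scale, from)
// [[Rcpp::export(name = ".simulateCore")]]
List simulateCore(List netList, List progList, Nullable<List> progList2,
                  double tOverride,
                  int n0, int nFinal, double tStartGrowth, double rate,
                  NumericMatrix reinduce, NumericMatrix rnai,
                  double tEnd, double dt, double dtOut,
                  NumericMatrix init) {
  Net net = unpackNet(netList);
  if (net.nstate > 32) stop("state dimension limited to 32");
  Prog prog = unpackProg(progList);
  Prog prog2 = prog;
  bool hasOverride = progList2.isNotNull();
  if (hasOverride) prog2 = unpackProg(progList2.get());

  const int ns = net.nstate;
  const int nSteps = (int)std::lround(tEnd / dt);
  const int keep = (int)std::lround(dtOut / dt);
  const int nFrames = nSteps / keep + 1;

  // birth step for each cell added by growth (first step boundary >= due time)
  std::vector<int> birthStep(nFinal, 0);
  for (int c = n0; c < nFinal; ++c) {
    double due = tStartGrowth + (c - n0 + 1) / rate;
    birthStep[c] = (int)std::ceil(due / dt - 1e-9);
  }

  NumericVector conc(nFrames * nFinal * ns, NA_REAL);
  NumericMatrix morph(nFrames, nFinal);
  std::fill(morph.begin(), morph.end(), NA_REAL);
  NumericVector birthTime(nFinal, 0.0);
  for (int c = n0; c < nFinal; ++c) birthTime[c] = birthStep[c] * dt;
  NumericVector times(nFrames);

  std::vector<double> g(nFinal * ns, 0.0);
  for (int c = 0; c < n0; ++c)
    for (int k = 0; k < ns; ++k) g[c * ns + k] = init(c, k);
  int nAlive = n0;

  const int nRe = reinduce.nrow(), nRn = rnai.nrow();
  std::vector<double> Rs(net.n), add0(ns, 0.0), addh(ns, 0.0), add1(ns, 0.0);

  for (int s = 0; s <= nSteps; ++s) {
    double B = s * dt;  // current step-boundary time
    while (nAlive < nFinal && birthStep[nAlive] <= s) {
      for (int k = 0; k < ns; ++k) g[nAlive * ns + k] = 0.0;  // naive cell
      ++nAlive;
    }
    const Prog& pr = (hasOverride && B >= tOverride - 1e-12) ? prog2 : prog;
    if (s % keep == 0) {
      int f = s / keep;
      times[f] = B;
      for (int c = 0; c < nAlive; ++c) {
        double d = (nAlive - c) - 0.5;
        morph(f, c) = evalM(pr, d, B);
        for (int k = 0; k < ns; ++k)
          conc[f + nFrames * (c + nFinal * k)] = g[c * ns + k];
      }
    }
    if (s == nSteps) break;

    // effective production ceilings under RNAi at time B
    for (int i = 0; i < net.n; ++i) Rs[i] = net.R[i];
    for (int e = 0; e < nRn; ++e)
      if (B >= rnai(e, 2) - 1e-12) Rs[(int)rnai(e, 0) - 1] *= rnai(e, 1);

    // additive re-induction terms at the three RK stage times
    std::fill(add0.begin(), add0.end(), 0.0);
    std::fill(addh.begin(), addh.end(), 0.0);
    std::fill(add1.begin(), add1.end(), 0.0);
    for (int e = 0; e < nRe; ++e) {
      if ((int)reinduce(e, 4) != 0) continue;  // clamp handled after the step
      int gi = (int)reinduce(e, 0) - 1;
      double on = reinduce(e, 1), off = reinduce(e, 2), A = reinduce(e, 3);
      double t0 = B, th = B + 0.5 * dt, t1 = B + dt;
      // forcing acts on [t_on, t_off): a step ending exactly at t_on is
      // untouched, a step ending exactly at t_off still sees it
      if (t0 >= on - 1e-12 && t0 < off - 1e-12) add0[gi] += A;
      if (th >  on + 1e-12 && th < off - 1e-12) addh[gi] += A;
      if (t1 >  on + 1e-12 && t1 <= off + 1e-12) add1[gi] += A;
    }

    for (int c = 0; c < nAlive; ++c) {
      double d = (nAlive - c) - 0.5;
      double M0 = evalM(pr, d, B), Mh = evalM(pr, d, B + 0.5 * dt),
             M1 = evalM(pr, d, B + dt);
      rk4step(net, &g[c * ns], M0, Mh, M1, Rs.data(),
              add0.data(), addh.data(), add1.data(), dt);
    }

    // clamp events pin the target gene's concentration during the window
    for (int e = 0; e < nRe; ++e) {
      if ((int)reinduce(e, 4) != 1) continue;
      double on = reinduce(e, 1), off = reinduce(e, 2);
      double t1 = B + dt;
      if (t1 > on + 1e-12 && t1 < off + 1e-12) {
        int gi = (int)reinduce(e, 0) - 1;
        for (int c = 0; c < nAlive; ++c) g[c * ns + gi] = reinduce(e, 3);
      }
    }

    for (int c = 0; c < nAlive; ++c)
      for (int k = 0; k < ns; ++k)
        if (!std::isfinite(g[c * ns + k]) || std::fabs(g[c * ns + k]) > 1e6)
          stop("numerical instability at t = %f (cell %d, state %d)",
               B + dt, c + 1, k + 1);
  }

  conc.attr("dim") = IntegerVector::create(nFrames, nFinal, ns);
  return List::create(_["conc"] = conc, _["morphogen"] = morph,
                      _["times"] = times, _["birth"] = birthTime);
}

// Single-cell integration against a caller-supplied morphogen series
// sampled on the half-step grid t = 0, dt/2, dt, ... (length 2*nSteps+1).
// [[Rcpp::export(name = ".integrateCellCore")]]
NumericMatrix integrateCellCore(List netList, NumericVector Mgrid,
                                NumericVector g0, double tEnd, double dt,
                                double dtOut) {
  Net net = unpackNet(netList);
  const int ns = net.nstate;
  const int nSteps = (int)std::lround(tEnd / dt);
  const int keep = (int)std::lround(dtOut / dt);
  // either a half-step grid (2 nSteps + 1 values) or explicit per-step
  // stage triples (3 nSteps values)
  bool triples = Mgrid.size() == 3 * nSteps;
  if (!triples && Mgrid.size() < 2 * nSteps + 1)
    stop("morphogen grid too short");
  NumericMatrix out(nSteps / keep + 1, ns);
  std::vector<double> g(g0.begin(), g0.end());
  std::vector<double> Rs(net.R.begin(), net.R.end());
  std::vector<double> zero(ns, 0.0);
  for (int k = 0; k < ns; ++k) out(0, k) = g[k];
  for (int s = 0; s < nSteps; ++s) {
    double M0 = triples ? Mgrid[3 * s]     : Mgrid[2 * s];
    double Mh = triples ? Mgrid[3 * s + 1] : Mgrid[2 * s + 1];
    double M1 = triples ? Mgrid[3 * s + 2] : Mgrid[2 * s + 2];
    rk4step(net, g.data(), M0, Mh, M1,
            Rs.data(), zero.data(), zero.data(), zero.data(), dt);
    for (int k = 0; k < ns; ++k)
      if (!std::isfinite(g[k]) || std::fabs(g[k]) > 1e6)
        stop("numerical instability at t = %f (state %d)", (s + 1) * dt, k + 1);
    if ((s + 1) % keep == 0)
      for (int k = 0; k < ns; ++k) out((s + 1) / keep, k) = g[k];
  }
  return out;
}
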