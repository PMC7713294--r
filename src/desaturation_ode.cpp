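// Mass-action ODE core for sequential phytoene desaturation with explicit
// enzyme-substrate/product binding, plus a stiff SDIRK3(2) integrator.
//
// State layout (length 2*(n+1) + 1 + n_branch):
//   [0 .. n]            free chain species S_0 .. S_n (µM)
//   [n+1]               free enzyme E (µM)
//   [n+2 .. 2n+2]       complexes ES_0 .. ES_n (µM)
//   [2n+3 .. ]          cyclised branch species (µM), enzyme-free
//
// Reactions: E + S_i <=> ES_i (k_f[i], k_r[i]); ES_i -> E + S_{i+1}
// (k_cat[i], i < n; the terminal complex ES_n is a dead end). Optional
// irreversible Michaelis-Menten cyclisation branches act on free species
// only, and an optional zeroth-order influx feeds S_0 (synthase surrogate).
// Units are µM and seconds throughout.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct NetworkDef {
  int n;                         // number of catalytic steps
  int nstate;                    // full state length
  std::vector<double> kf, kr, kcat;
  std::vector<int> bsrc, bdst;   // branch source/dest indices into state
  std::vector<double> bvmax, bkm;
  double influx;                 // µM/s into S_0

  int idxE() const { return n + 1; }
  int idxES(int i) const { return n + 2 + i; }
};

void rhs(const NetworkDef& net, const double* y, double* dy) {
  const int n = net.n;
  for (int i = 0; i < net.nstate; ++i) dy[i] = 0.0;
  const double E = y[net.idxE()];
  for (int i = 0; i <= n; ++i) {
    const double bind = net.kf[i] * E * y[i];
    const double unbind = net.kr[i] * y[net.idxES(i)];
    const double cat = (i < n) ? net.kcat[i] * y[net.idxES(i)] : 0.0;
    dy[i] += -bind + unbind;
    dy[net.idxES(i)] = bind - unbind - cat;
    dy[net.idxE()] += -bind + unbind + cat;
    if (i < n) dy[i + 1] += cat;
  }
  dy[0] += net.influx;
  for (size_t b = 0; b < net.bsrc.size(); ++b) {
    const double s = y[net.bsrc[b]];
    const double v = net.bvmax[b] * s / (net.bkm[b] + s);
    dy[net.bsrc[b]] -= v;
    dy[net.bdst[b]] += v;
  }
}

// Dense analytic Jacobian, row-major J[r*nstate + c] = d(dy_r)/d(y_c).
void jacobian(const NetworkDef& net, const double* y, double* J) {
  const int n = net.n, ns = net.nstate, iE = net.idxE();
  std::fill(J, J + ns * ns, 0.0);
  const double E = y[iE];
  for (int i = 0; i <= n; ++i) {
    const int iC = net.idxES(i);
    const double kf = net.kf[i], kr = net.kr[i];
    const double kc = (i < n) ? net.kcat[i] : 0.0;
    // d/dS_i, d/dE, d/dES_i of the three lumped fluxes
    J[i * ns + i] += -kf * E;
    J[i * ns + iE] += -kf * y[i];
    J[i * ns + iC] += kr;
    J[iC * ns + i] = kf * E;
    J[iC * ns + iE] = kf * y[i];
    J[iC * ns + iC] = -(kr + kc);
    J[iE * ns + i] += -kf * E;
    J[iE * ns + iE] += -kf * y[i];
    J[iE * ns + iC] += kr + kc;
    if (i < n) J[(i + 1) * ns + iC] += kc;
  }
  for (size_t b = 0; b < net.bsrc.size(); ++b) {
    const int s = net.bsrc[b], d = net.bdst[b];
    const double km = net.bkm[b];
    const double dv = net.bvmax[b] * km / ((km + y[s]) * (km + y[s]));
    J[s * ns + s] -= dv;
    J[d * ns + s] += dv;
  }
}

// Partial-pivot LU of an ns x ns row-major matrix, in place.
bool lu_factor(std::vector<double>& A, std::vector<int>& piv, int ns) {
  for (int k = 0; k < ns; ++k) {
    int p = k;
    double amax = std::fabs(A[k * ns + k]);
    for (int r = k + 1; r < ns; ++r) {
      const double v = std::fabs(A[r * ns + k]);
      if (v > amax) { amax = v; p = r; }
    }
    if (amax == 0.0) return false;
    piv[k] = p;
    if (p != k)
      for (int c = 0; c < ns; ++c) std::swap(A[k * ns + c], A[p * ns + c]);
    const double inv = 1.0 / A[k * ns + k];
    for (int r = k + 1; r < ns; ++r) {
      const double m = A[r * ns + k] * inv;
      A[r * ns + k] = m;
      if (m != 0.0)
        for (int c = k + 1; c < ns; ++c) A[r * ns + c] -= m * A[k * ns + c];
    }
  }
  return true;
}

void lu_solve(const std::vector<double>& A, const std::vector<int>& piv,
              double* b, int ns) {
  for (int k = 0; k < ns; ++k) {
    if (piv[k] != k) std::swap(b[k], b[piv[k]]);
    for (int r = k + 1; r < ns; ++r) b[r] -= A[r * ns + k] * b[k];
  }
  for (int k = ns - 1; k >= 0; --k) {
    for (int c = k + 1; c < ns; ++c) b[k] -= A[k * ns + c] * b[c];
    b[k] /= A[k * ns + k];
  }
}

NetworkDef make_net(int n_steps, NumericVector kf, NumericVector kr,
                    NumericVector kcat, IntegerVector bsrc, IntegerVector bdst,
                    NumericVector bvmax, NumericVector bkm, double influx,
                    int n_branch_species) {
  NetworkDef net;
  net.n = n_steps;
  net.nstate = 2 * (n_steps + 1) + 1 + n_branch_species;
  net.kf.assign(kf.begin(), kf.end());
  net.kr.assign(kr.begin(), kr.end());
  net.kcat.assign(kcat.begin(), kcat.end());
  net.bsrc.assign(bsrc.begin(), bsrc.end());
  net.bdst.assign(bdst.begin(), bdst.end());
  net.bvmax.assign(bvmax.begin(), bvmax.end());
  net.bkm.assign(bkm.begin(), bkm.end());
  net.influx = influx;
  return net;
}

}  // namespace

// [[Rcpp::export]]
NumericVector crti_rhs_cpp(NumericVector y, int n_steps, NumericVector kf,
                           NumericVector kr, NumericVector kcat,
                           IntegerVector bsrc, IntegerVector bdst,
                           NumericVector bvmax, NumericVector bkm,
                           double influx, int n_branch_species) {
  NetworkDef net = make_net(n_steps, kf, kr, kcat, bsrc, bdst, bvmax, bkm,
                            influx, n_branch_species);
  if ((int)y.size() != net.nstate) stop("state length does not match network");
  NumericVector dy(net.nstate);
  rhs(net, y.begin(), dy.begin());
  return dy;
}

// [[Rcpp::export]]
NumericMatrix crti_jacobian_cpp(NumericVector y, int n_steps, NumericVector kf,
                                NumericVector kr, NumericVector kcat,
                                IntegerVector bsrc, IntegerVector bdst,
                                NumericVector bvmax, NumericVector bkm,
                                double influx, int n_branch_species) {
  NetworkDef net = make_net(n_steps, kf, kr, kcat, bsrc, bdst, bvmax, bkm,
                            influx, n_branch_species);
  if ((int)y.size() != net.nstate) stop("state length does not match network");
  std::vector<double> J(net.nstate * net.nstate);
  jacobian(net, y.begin(), J.data());
  NumericMatrix out(net.nstate, net.nstate);
  for (int r = 0; r < net.nstate; ++r)
    for (int c = 0; c < net.nstate; ++c) out(r, c) = J[r * net.nstate + c];
  return out;
}

// SDIRK3(2): three-stage, stiffly accurate, L-stable singly diagonally
// implicit Runge-Kutta method of order 3 (gamma is the root of
// x^3 - 3x^2 + 3x/2 - 1/6 in (1/6, 1/2)), with an embedded second-order
// solution for error control. The error estimate is premultiplied by
// (I - h*gamma*J)^-1 to avoid rejection storms on stiff components.
// Linear first integrals (carotene backbone, total enzyme) are conserved
// to Newton tolerance because every accepted state is a stage solution.

namespace {

struct Sdirk {
  // method coefficients
  double gam, a21, b1, b2, d1, d2, d3;
  // workspace, sized once per problem
  int ns;
  std::vector<double> J, LU, F1, F2, Y, res, known, err, y;
  std::vector<int> piv;
  long steps = 0, nfev = 0, nreject = 0;
  int status = 0;
  int iout_done = 0;
  const char* msg = "ok";

  explicit Sdirk(int ns_) : ns(ns_) {
    gam = 0.43586652150845899941601945119356;
    const double g2 = gam * gam;
    a21 = (1.0 - gam) / 2.0;
    b1 = -(6.0 * g2 - 16.0 * gam + 1.0) / 4.0;
    b2 = (6.0 * g2 - 20.0 * gam + 5.0) / 4.0;
    const double bh2 = (1.0 - 2.0 * gam) / (1.0 - gam);  // embedded order 2
    d1 = b1 - (1.0 - bh2);
    d2 = b2 - bh2;
    d3 = gam;
    J.resize(ns * ns); LU.resize(ns * ns);
    F1.resize(ns); F2.resize(ns); Y.resize(ns); res.resize(ns);
    known.resize(ns); err.resize(ns); y.resize(ns); piv.resize(ns);
  }

  // Integrate from times[0] to times[nt-1]; store rows of `out` at every
  // output time (row 0 = initial condition). Returns false on failure.
  bool run(const NetworkDef& net, const double* y0, const double* times,
           int nt, double rtol, double atol, double max_steps, double* out) {
    for (int c = 0; c < ns; ++c) { y[c] = y0[c]; out[c] = y0[c]; }
    int iout = 1;
    iout_done = 1;
    double t = times[0];
    if (nt < 2) return true;
    const double tend = times[nt - 1];
    double h = std::min(1e-3, (tend - t) / 100.0);
    if (h <= 0) { status = 4; msg = "output times must be strictly increasing"; return false; }

    while (t < tend) {
      if (steps++ > max_steps) { status = 1; msg = "max step count exceeded"; return false; }
      bool hit_output = false;
      double h_use = h;
      if (t + h_use >= times[iout] - 1e-12 * std::max(1.0, std::fabs(times[iout]))) {
        h_use = times[iout] - t;
        hit_output = true;
      }

      jacobian(net, y.data(), J.data());
      for (int r = 0; r < ns; ++r) {
        double* Wr = &LU[r * ns];
        const double* Jr = &J[r * ns];
        for (int c = 0; c < ns; ++c) Wr[c] = -h_use * gam * Jr[c];
        Wr[r] += 1.0;
      }
      if (!lu_factor(LU, piv, ns)) { status = 2; msg = "singular iteration matrix"; return false; }

      // Newton solve of the three stages; the step ends at stage 3
      // (stiffly accurate). Stage derivatives F1/F2 are exact rhs values
      // so the linear conservation laws hold to rounding; the error
      // estimate uses the algebraic identity for stage 3.
      bool ok = true;
      for (int stage = 1; stage <= 3 && ok; ++stage) {
        if (stage == 1) {
          for (int i = 0; i < ns; ++i) known[i] = y[i];
        } else if (stage == 2) {
          for (int i = 0; i < ns; ++i) known[i] = y[i] + h_use * a21 * F1[i];
        } else {
          for (int i = 0; i < ns; ++i)
            known[i] = y[i] + h_use * (b1 * F1[i] + b2 * F2[i]);
        }
        // predictor: known + h*gamma*F(previous stage) once one exists
        if (stage == 1) {
          for (int i = 0; i < ns; ++i) Y[i] = y[i];
        } else {
          const double* Fp = (stage == 2) ? F1.data() : F2.data();
          for (int i = 0; i < ns; ++i) Y[i] = known[i] + h_use * gam * Fp[i];
        }
        double* F = (stage == 1) ? F1.data() : (stage == 2 ? F2.data() : res.data());
        bool conv = false;
        for (int it = 0; it < 10; ++it) {
          rhs(net, Y.data(), F);
          ++nfev;
          double dmax = 0.0;
          // for stage 3, F aliases res: each element is read before being
          // overwritten, which is exactly the in-place update wanted
          for (int i = 0; i < ns; ++i)
            res[i] = known[i] + h_use * gam * F[i] - Y[i];
          lu_solve(LU, piv, res.data(), ns);
          for (int i = 0; i < ns; ++i) {
            Y[i] += res[i];
            const double sc = atol + rtol * std::fabs(Y[i]);
            dmax = std::max(dmax, std::fabs(res[i]) / sc);
          }
          if (dmax < 1e-3) {
            if (stage < 3) { rhs(net, Y.data(), F); ++nfev; }
            conv = true;
            break;
          }
        }
        if (!conv) ok = false;
      }

      if (!ok) {
        h *= 0.25;
        ++nreject;
        if (h < 1e-14 * std::max(1.0, std::fabs(t))) {
          status = 3; msg = "step size underflow (Newton failure)"; return false;
        }
        continue;
      }

      // error estimate, filtered through W^-1; F3 from the stage identity
      // F3 = (Y - known)/(h*gamma)
      double errnorm = 0.0;
      {
        const double ihg = 1.0 / (h_use * gam);
        for (int i = 0; i < ns; ++i) {
          const double f3 = (Y[i] - known[i]) * ihg;
          err[i] = h_use * (d1 * F1[i] + d2 * F2[i] + d3 * f3);
        }
        lu_solve(LU, piv, err.data(), ns);
        for (int i = 0; i < ns; ++i) {
          const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(Y[i]));
          const double e = err[i] / sc;
          errnorm += e * e;
        }
        errnorm = std::sqrt(errnorm / ns);
      }

      if (errnorm <= 1.0) {
        t += h_use;
        for (int i = 0; i < ns; ++i) y[i] = Y[i];
        if (hit_output) {
          double* row = out + (size_t)iout * ns;
          for (int c = 0; c < ns; ++c) row[c] = y[c];
          ++iout;
          iout_done = iout;
          if (iout >= nt) break;
        }
        const double fac = std::min(5.0, std::max(0.2, 0.9 * std::pow(std::max(errnorm, 1e-10), -1.0 / 3.0)));
        h = std::min(h_use * fac, tend - t + 1e-30);
        if (h <= 0) h = 1e-12;
      } else {
        ++nreject;
        const double fac = std::max(0.1, 0.9 * std::pow(errnorm, -1.0 / 3.0));
        h = h_use * fac;
        if (h < 1e-14 * std::max(1.0, std::fabs(t))) {
          status = 3; msg = "step size underflow (error control)"; return false;
        }
      }
    }
    return true;
  }
};

}  // namespace

// [[Rcpp::export]]
List crti_integrate_cpp(NumericVector y0, NumericVector times, int n_steps,
                        NumericVector kf, NumericVector kr, NumericVector kcat,
                        IntegerVector bsrc, IntegerVector bdst,
                        NumericVector bvmax, NumericVector bkm, double influx,
                        int n_branch_species, double rtol, double atol,
                        double max_steps) {
  NetworkDef net = make_net(n_steps, kf, kr, kcat, bsrc, bdst, bvmax, bkm,
                            influx, n_branch_species);
  const int ns = net.nstate;
  if ((int)y0.size() != ns) stop("state length does not match network");
  const int nt = times.size();

  std::vector<double> buf((size_t)nt * ns);
  Sdirk solver(ns);
  bool ok = solver.run(net, y0.begin(), times.begin(), nt, rtol, atol,
                       max_steps, buf.data());
  NumericMatrix out(nt, ns);
  const int n_out = ok ? nt : solver.iout_done;
  for (int r = 0; r < nt; ++r)
    for (int c = 0; c < ns; ++c) out(r, c) = buf[(size_t)r * ns + c];

  return List::create(_["states"] = out, _["status"] = solver.status,
                      _["message"] = std::string(solver.msg),
                      _["steps"] = (double)solver.steps,
                      _["nfev"] = (double)solver.nfev,
                      _["nreject"] = (double)solver.nreject,
                      _["n_out"] = n_out);
}

// Batched weighted-least-squares objective for the particle swarm: one
// integration per parameter row, totals (free + bound) compared against
// the observed matrix. Rows whose integration fails get +Inf.
//
// obs_idx: 0-based indices of the observed species among the observable
// totals (chain species first, then branch species).
// [[Rcpp::export]]
NumericVector objective_batch_cpp(NumericMatrix par, int n_steps,
                                  IntegerVector bsrc, IntegerVector bdst,
                                  NumericVector bvmax, NumericVector bkm,
                                  double influx, int n_branch_species,
                                  NumericVector y0, NumericVector times,
                                  NumericMatrix obs, IntegerVector obs_idx,
                                  NumericVector weights, double rtol,
                                  double atol, double max_steps) {
  const int n = n_steps;
  const int npar = 3 * n + 2;
  if (par.ncol() != npar) stop("parameter matrix has wrong width");
  const int nt = times.size();
  if (obs.nrow() != nt) stop("observation rows must match output times");
  const int nobs = obs_idx.size();
  const int ns = 2 * (n + 1) + 1 + n_branch_species;
  if ((int)y0.size() != ns) stop("state length does not match network");

  NumericVector out(par.nrow());
  std::vector<double> buf((size_t)nt * ns);
  NumericVector kf(n + 1), kr(n + 1), kcat(n);

  for (int pr = 0; pr < par.nrow(); ++pr) {
    for (int i = 0; i <= n; ++i) { kf[i] = par(pr, i); kr[i] = par(pr, n + 1 + i); }
    for (int i = 0; i < n; ++i) kcat[i] = par(pr, 2 * (n + 1) + i);
    NetworkDef net = make_net(n, kf, kr, kcat, bsrc, bdst, bvmax, bkm, influx,
                              n_branch_species);
    Sdirk solver(ns);
    if (!solver.run(net, y0.begin(), times.begin(), nt, rtol, atol, max_steps,
                    buf.data())) {
      out[pr] = R_PosInf;
      continue;
    }
    double sse = 0.0;
    for (int j = 0; j < nobs; ++j) {
      const int sp = obs_idx[j];
      const double w = weights[j];
      if (!R_finite(w)) continue;
      for (int r = 0; r < nt; ++r) {
        const double* row = &buf[(size_t)r * ns];
        double tot;
        if (sp <= n) {
          tot = row[sp] + row[n + 2 + sp];  // free + complexed
        } else {
          tot = row[sp + n + 2];  // branch species (after E and complexes)
        }
        const double d = tot - obs(r, j);
        sse += w * d * d;
      }
    }
    out[pr] = sse;
  }
  return out;
}
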