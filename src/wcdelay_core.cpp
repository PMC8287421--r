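// Core fixed-step integrators for delay-coupled Wilson-Cowan networks.
//
// All delayed lookups are served by a ring-buffer history holding states and
// derivatives at grid points, interpolated with cubic Hermite polynomials
// (locally O(h^4), matching the RK4 step order). The step size must not
// exceed the smallest positive lag, so every stage lookup lands in already
// completed history.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double phi_s(double x, double a) {
  return 1.0 / (1.0 + std::exp(-a * x));
}
static inline double phi_prime_s(double x, double a) {
  double f = phi_s(x, a);
  return a * f * (1.0 - f);
}

// Ring-buffer history for nv variables on a fixed grid t_i = i*h.
// Before t = 0 the history is constant (y0); derivative there is zero.
struct Hist {
  int nv;
  long cap, next; // next absolute grid index to write
  double h;
  std::vector<double> y, f, y0;

  Hist(int nv_, long cap_, double h_, const std::vector<double>& y0_)
      : nv(nv_), cap(cap_), next(0), h(h_), y(cap_ * nv_), f(cap_ * nv_),
        y0(y0_) {}

  void push(const double* yv, const double* fv) {
    long s = (next % cap) * nv;
    for (int v = 0; v < nv; ++v) { y[s + v] = yv[v]; f[s + v] = fv[v]; }
    ++next;
  }

  double eval(double t, int v) const {
    if (t <= 1e-14) return y0[v];
    double u = t / h;
    long i0 = (long)std::floor(u + 1e-9);
    if (i0 >= next - 1) i0 = next - 2; // stage at the right end of the last interval
    if (i0 < 0) return y0[v];
    double th = u - (double)i0;
    if (th < 0) th = 0; if (th > 1) th = 1;
    long s0 = (i0 % cap) * nv, s1 = ((i0 + 1) % cap) * nv;
    double y0i = y[s0 + v], y1i = y[s1 + v];
    double f0i = f[s0 + v], f1i = f[s1 + v];
    double th2 = th * th, th3 = th2 * th;
    return (2 * th3 - 3 * th2 + 1) * y0i + (th3 - 2 * th2 + th) * h * f0i +
           (-2 * th3 + 3 * th2) * y1i + (th3 - th2) * h * f1i;
  }

  void scale_all(double c) { // rescale buffered values (linear systems only)
    for (size_t i = 0; i < y.size(); ++i) { y[i] *= c; f[i] *= c; }
    for (int v = 0; v < nv; ++v) y0[v] *= c;
  }
};

// ---------------------------------------------------------------------------
// Full network: tau1 E_k' = -E_k + phi(sum_j W_kj E_j(t - eps_kj) - Wei_k I_k)
//               I_k'      = -I_k + phi(W_IE E_k)
//               tau2 Wei_k' = I_k (E_k - p)
// ---------------------------------------------------------------------------

struct NetSys {
  int N;
  const double *W, *epsm; // N x N, column-major from R
  double p, a, tau1, tau2, W_IE;
  Hist* hist; // E history, nv = N

  void deriv(double t, const double* y, double* dy, bool any_delay) const {
    const double* E = y; const double* I = y + N; const double* Wei = y + 2 * N;
    for (int k = 0; k < N; ++k) {
      double s = 0.0;
      for (int j = 0; j < N; ++j) {
        double w = W[k + (long)j * N];
        if (w == 0.0) continue;
        double lag = epsm[k + (long)j * N];
        double Ej = (!any_delay || lag == 0.0) ? E[j] : hist->eval(t - lag, j);
        s += w * Ej;
      }
      dy[k] = (-E[k] + phi_s(s - Wei[k] * I[k], a)) / tau1;
      dy[N + k] = -I[k] + phi_s(W_IE * E[k], a);
      dy[2 * N + k] = I[k] * (E[k] - p) / tau2;
    }
  }
};

// One RK4 step from t with history pushes handled by the caller.
template <class Sys>
static void rk4_step(const Sys& sys, double t, double h, std::vector<double>& y,
                     const std::vector<double>& k1, std::vector<double>& k2,
                     std::vector<double>& k3, std::vector<double>& k4,
                     std::vector<double>& tmp, bool any_delay) {
  size_t n = y.size();
  for (size_t i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  sys.deriv(t + 0.5 * h, tmp.data(), k2.data(), any_delay);
  for (size_t i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  sys.deriv(t + 0.5 * h, tmp.data(), k3.data(), any_delay);
  for (size_t i = 0; i < n; ++i) tmp[i] = y[i] + h * k3[i];
  sys.deriv(t + h, tmp.data(), k4.data(), any_delay);
  for (size_t i = 0; i < n; ++i)
    y[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
}

// [[Rcpp::export]]
List sim_wc_network_cpp(NumericMatrix W, NumericMatrix epsm, double p, double a,
                        double tau1, double tau2, double W_IE,
                        NumericVector E0, NumericVector I0, NumericVector Wei0,
                        double t_end, double h, double record_start,
                        int stride) {
  int N = W.nrow();
  double max_lag = 0.0, min_pos = R_PosInf;
  bool any_delay = false;
  for (int i = 0; i < N * N; ++i) {
    double l = epsm[i];
    if (l > max_lag) max_lag = l;
    if (l > 0 && l < min_pos) { min_pos = l; any_delay = true; }
  }
  if (any_delay && h > min_pos + 1e-12)
    stop("step size %g exceeds the smallest positive lag %g", h, min_pos);

  long nsteps = (long)std::llround(t_end / h);
  long cap = any_delay ? (long)std::ceil(max_lag / h) + 4 : 4;

  std::vector<double> Ehist0(E0.begin(), E0.end());
  Hist hist(N, cap, h, Ehist0);

  NetSys sys{N, REAL(W), REAL(epsm), p, a, tau1, tau2, W_IE, &hist};

  std::vector<double> y(3 * N);
  for (int k = 0; k < N; ++k) {
    y[k] = E0[k]; y[N + k] = I0[k]; y[2 * N + k] = Wei0[k];
  }
  std::vector<double> k1(3 * N), k2(3 * N), k3(3 * N), k4(3 * N), tmp(3 * N);

  long first_rec = (long)std::ceil(record_start / h - 1e-9);
  long nrec = 0;
  for (long i = first_rec; i <= nsteps; i += stride) ++nrec;
  NumericVector tout(nrec);
  NumericMatrix Eout(nrec, N), Iout(nrec, N), Weiout(nrec, N), dEout(nrec, N);
  long irec = 0;

  for (long step = 0; step <= nsteps; ++step) {
    double t = step * h;
    sys.deriv(t, y.data(), k1.data(), any_delay);
    hist.push(y.data(), k1.data()); // derivative slots beyond E unused: push E only
    // (Hist stores nv = N values: pass E part and its derivative)
    // -- the push above used full y/k1 pointers; Hist only reads first N
    if (step >= first_rec && (step - first_rec) % stride == 0) {
      tout[irec] = t;
      for (int k = 0; k < N; ++k) {
        Eout(irec, k) = y[k]; Iout(irec, k) = y[N + k];
        Weiout(irec, k) = y[2 * N + k]; dEout(irec, k) = k1[k];
      }
      ++irec;
    }
    if (step == nsteps) break;
    rk4_step(sys, t, h, y, k1, k2, k3, k4, tmp, any_delay);
    for (size_t i = 0; i < y.size(); ++i)
      if (!std::isfinite(y[i]))
        stop("state became non-finite at t = %g", t + h);
  }

  return List::create(_["t"] = tout, _["E"] = Eout, _["I"] = Iout,
                      _["W_EI"] = Weiout, _["dE"] = dEout);
}

// ---------------------------------------------------------------------------
// Synchronous node co-integrated with the chain-discretized variational
// system at a single connectivity eigenvalue r_hat (complex).
//
// Variational state (complex): eta_x (= chain head x_1), eta_y, eta_z,
// x_2..x_m. The chain advects eta_x down m cells so that x_m approximates
// eta_x(t - eps). With eps = 0 the chain is dropped and the delayed value is
// the live eta_x.
// ---------------------------------------------------------------------------

struct LyapSys {
  double r_re, r_im, W_E, eps;
  double p, a, tau1, tau2, W_IE;
  int m;          // chain cells (>= 2) when eps > 0
  bool with_var;  // variational block active
  Hist* hist;     // node E history (nv = 1)

  // layout: y[0..2] = node (E, I, Wei); then complex pairs:
  // eta_x, eta_y, eta_z, x_2..x_m  -> 3 + (eps>0 ? m-1 : 0) pairs
  int npairs() const { return 3 + (eps > 0 ? m - 1 : 0); }
  int dim() const { return 3 + 2 * npairs(); }

  void deriv(double t, const double* y, double* dy, bool any_delay) const {
    double E = y[0], I = y[1], Wei = y[2];
    double Elag = (eps > 0) ? hist->eval(t - eps, 0) : E;
    double u = W_E * Elag - Wei * I;
    dy[0] = (-E + phi_s(u, a)) / tau1;
    dy[1] = -I + phi_s(W_IE * E, a);
    dy[2] = I * (E - p) / tau2;
    if (!with_var) {
      for (int i = 3; i < dim(); ++i) dy[i] = 0.0;
      return;
    }
    double M1 = phi_prime_s(u, a);
    double M2 = W_IE * phi_prime_s(W_IE * E, a);
    const double* v = y + 3; double* dv = dy + 3;
    double xr = v[0], xi = v[1];       // eta_x
    double yr = v[2], yi = v[3];       // eta_y
    double zr = v[4], zi = v[5];       // eta_z
    double xdr, xdi;                   // delayed eta_x
    if (eps > 0) { xdr = v[6 + 2 * (m - 2)]; xdi = v[7 + 2 * (m - 2)]; }
    else { xdr = xr; xdi = xi; }
    double rxr = r_re * xdr - r_im * xdi;
    double rxi = r_re * xdi + r_im * xdr;
    dv[0] = (-xr + M1 * (rxr - I * zr - Wei * yr)) / tau1;
    dv[1] = (-xi + M1 * (rxi - I * zi - Wei * yi)) / tau1;
    dv[2] = -yr + M2 * xr;
    dv[3] = -yi + M2 * xi;
    dv[4] = ((E - p) * yr + I * xr) / tau2;
    dv[5] = ((E - p) * yi + I * xi) / tau2;
    if (eps > 0) {
      double c2 = m / (2.0 * eps), c1 = m / eps;
      // cells x_2..x_m live at v[6..], x_1 = eta_x
      // interior cells advect the live signal toward the delayed end:
      // x_n' = (x_{n-1} - x_{n+1}) * m / (2 eps)
      for (int n = 2; n <= m - 1; ++n) {
        int i = 6 + 2 * (n - 2);
        double prr = (n == 2) ? xr : v[i - 2];
        double pri = (n == 2) ? xi : v[i - 1];
        dv[i] = (prr - v[i + 2]) * c2;
        dv[i + 1] = (pri - v[i + 3]) * c2;
      }
      int im_ = 6 + 2 * (m - 2);
      double prr = (m == 2) ? xr : v[im_ - 2];
      double pri = (m == 2) ? xi : v[im_ - 1];
      dv[im_] = (prr - v[im_]) * c1;
      dv[im_ + 1] = (pri - v[im_ + 1]) * c1;
    }
  }
};

// [[Rcpp::export]]
List lyap_chain_cpp(double r_re, double r_im, double W_E, double eps, double p,
                    double a, double tau1, double tau2, double W_IE, int m,
                    double h, double t_transient, double t_var_skip,
                    double t_avg, double renorm_dt, NumericVector node0,
                    double conv_tol) {
  if (eps > 0 && h > eps + 1e-12)
    stop("step size %g exceeds the lag %g", h, eps);
  LyapSys sys{r_re, r_im, W_E, eps, p, a, tau1, tau2, W_IE, m, false, nullptr};
  int dim = sys.dim(), np = sys.npairs();

  long cap = (eps > 0) ? (long)std::ceil(eps / h) + 4 : 4;
  std::vector<double> h0(1, node0[0]);
  Hist hist(1, cap, h, h0);
  sys.hist = &hist;

  std::vector<double> y(dim, 0.0), k1(dim), k2(dim), k3(dim), k4(dim), tmp(dim);
  y[0] = node0[0]; y[1] = node0[1]; y[2] = node0[2];

  long n_tr = (long)std::llround(t_transient / h);
  long n_rn = (long)std::llround(renorm_dt / h);
  long n_tot = n_tr + (long)std::llround((t_var_skip + t_avg) / h);
  double t_skip_end = t_transient + t_var_skip;

  double logsum = 0.0, t_accum = 0.0;
  std::vector<double> running;

  for (long step = 0; step <= n_tot; ++step) {
    double t = step * h;
    if (step == n_tr) { // switch on the variational block, unit init
      sys.with_var = true;
      double c = 1.0 / std::sqrt((double)(2 * np));
      for (int i = 0; i < 2 * np; ++i) y[3 + i] = c;
    }
    sys.deriv(t, y.data(), k1.data(), eps > 0);
    hist.push(y.data(), k1.data()); // nv = 1: node E and dE
    if (sys.with_var && step > n_tr && (step - n_tr) % n_rn == 0) {
      double s2 = 0.0;
      for (int i = 0; i < 2 * np; ++i) s2 += y[3 + i] * y[3 + i];
      double nrm = std::sqrt(s2);
      if (nrm <= 0 || !std::isfinite(nrm))
        stop("variational norm degenerate at t = %g", t);
      if (t > t_skip_end + 1e-9) {
        logsum += std::log(nrm);
        t_accum += renorm_dt;
        running.push_back(logsum / t_accum);
      }
      for (int i = 0; i < 2 * np; ++i) y[3 + i] /= nrm;
      sys.deriv(t, y.data(), k1.data(), eps > 0); // refresh derivative after rescale
    }
    if (step == n_tot) break;
    rk4_step(sys, t, h, y, k1, k2, k3, k4, tmp, eps > 0);
    for (int i = 0; i < 3; ++i)
      if (!std::isfinite(y[i])) stop("node state non-finite at t = %g", t + h);
  }

  double lambda = (t_accum > 0) ? logsum / t_accum : NA_REAL;
  bool converged = false;
  size_t nr = running.size();
  if (nr >= 8) {
    double mid = running[nr / 2 - 1], fin = running[nr - 1];
    converged = std::fabs(fin - mid) < conv_tol;
  }
  return List::create(_["lambda"] = lambda, _["converged"] = converged,
                      _["running"] = NumericVector(running.begin(), running.end()));
}

// ---------------------------------------------------------------------------
// Direct integration of the linear delayed variational system (no chain):
// eta_x(t - eps) is read from a dense history of eta_x itself. Benettin-style
// renormalization keeps the linear solution in range; the whole eta_x history
// buffer is rescaled along with the state, which is exact for linear systems.
// ---------------------------------------------------------------------------

struct DirectSys {
  double r_re, r_im, W_E, eps;
  double p, a, tau1, tau2, W_IE;
  bool with_var;
  Hist* hist; // nv = 3: node E, eta_x re, eta_x im

  int dim() const { return 9; }

  void deriv(double t, const double* y, double* dy, bool any_delay) const {
    double E = y[0], I = y[1], Wei = y[2];
    double Elag = (eps > 0) ? hist->eval(t - eps, 0) : E;
    double u = W_E * Elag - Wei * I;
    dy[0] = (-E + phi_s(u, a)) / tau1;
    dy[1] = -I + phi_s(W_IE * E, a);
    dy[2] = I * (E - p) / tau2;
    if (!with_var) { for (int i = 3; i < 9; ++i) dy[i] = 0.0; return; }
    double M1 = phi_prime_s(u, a);
    double M2 = W_IE * phi_prime_s(W_IE * E, a);
    double xr = y[3], xi = y[4], yr = y[5], yi = y[6], zr = y[7], zi = y[8];
    double xdr = (eps > 0) ? hist->eval(t - eps, 1) : xr;
    double xdi = (eps > 0) ? hist->eval(t - eps, 2) : xi;
    double rxr = r_re * xdr - r_im * xdi;
    double rxi = r_re * xdi + r_im * xdr;
    dy[3] = (-xr + M1 * (rxr - I * zr - Wei * yr)) / tau1;
    dy[4] = (-xi + M1 * (rxi - I * zi - Wei * yi)) / tau1;
    dy[5] = -yr + M2 * xr;
    dy[6] = -yi + M2 * xi;
    dy[7] = ((E - p) * yr + I * xr) / tau2;
    dy[8] = ((E - p) * yi + I * xi) / tau2;
  }
};

// [[Rcpp::export]]
List direct_dde_growth_cpp(double r_re, double r_im, double W_E, double eps,
                           double p, double a, double tau1, double tau2,
                           double W_IE, double h, double t_transient,
                           double t_var_skip, double t_avg, double renorm_dt,
                           NumericVector node0, double conv_tol) {
  if (eps > 0 && h > eps + 1e-12)
    stop("step size %g exceeds the lag %g", h, eps);
  DirectSys sys{r_re, r_im, W_E, eps, p, a, tau1, tau2, W_IE, false, nullptr};
  long cap = (eps > 0) ? (long)std::ceil(eps / h) + 4 : 4;
  std::vector<double> h0 = {node0[0], 0.0, 0.0};
  Hist hist(3, cap, h, h0);
  sys.hist = &hist;

  std::vector<double> y(9, 0.0), k1(9), k2(9), k3(9), k4(9), tmp(9), hv(3), hf(3);
  y[0] = node0[0]; y[1] = node0[1]; y[2] = node0[2];

  long n_tr = (long)std::llround(t_transient / h);
  long n_rn = (long)std::llround(renorm_dt / h);
  long n_tot = n_tr + (long)std::llround((t_var_skip + t_avg) / h);
  double t_skip_end = t_transient + t_var_skip;

  double logsum = 0.0, t_accum = 0.0;
  std::vector<double> running;

  for (long step = 0; step <= n_tot; ++step) {
    double t = step * h;
    if (step == n_tr) {
      sys.with_var = true;
      double c = 1.0 / std::sqrt(6.0);
      for (int i = 3; i < 9; ++i) y[i] = c;
      // pre-history of the perturbation: constant at the initial value
      hist.y0[1] = c; hist.y0[2] = c;
      for (long s = 0; s < std::min(hist.next, hist.cap); ++s) {
        hist.y[s * 3 + 1] = c; hist.y[s * 3 + 2] = c;
        hist.f[s * 3 + 1] = 0.0; hist.f[s * 3 + 2] = 0.0;
      }
    }
    sys.deriv(t, y.data(), k1.data(), eps > 0);
    hv[0] = y[0]; hv[1] = y[3]; hv[2] = y[4];
    hf[0] = k1[0]; hf[1] = k1[3]; hf[2] = k1[4];
    hist.push(hv.data(), hf.data());
    if (sys.with_var && step > n_tr && (step - n_tr) % n_rn == 0) {
      double s2 = 0.0;
      for (int i = 3; i < 9; ++i) s2 += y[i] * y[i];
      double nrm = std::sqrt(s2);
      if (nrm <= 0 || !std::isfinite(nrm))
        stop("variational norm degenerate at t = %g", t);
      if (t > t_skip_end + 1e-9) {
        logsum += std::log(nrm);
        t_accum += renorm_dt;
        running.push_back(logsum / t_accum);
      }
      for (int i = 3; i < 9; ++i) y[i] /= nrm;
      // rescale the perturbation part of the history (vars 1, 2)
      double c = 1.0 / nrm;
      long nslots = std::min(hist.next, hist.cap);
      for (long s = 0; s < nslots; ++s) {
        hist.y[s * 3 + 1] *= c; hist.y[s * 3 + 2] *= c;
        hist.f[s * 3 + 1] *= c; hist.f[s * 3 + 2] *= c;
      }
      hist.y0[1] *= c; hist.y0[2] *= c;
      sys.deriv(t, y.data(), k1.data(), eps > 0);
      hv[1] = y[3]; hv[2] = y[4]; hf[1] = k1[3]; hf[2] = k1[4];
      long slast = ((hist.next - 1) % hist.cap) * 3;
      hist.y[slast + 1] = y[3]; hist.y[slast + 2] = y[4];
      hist.f[slast + 1] = k1[3]; hist.f[slast + 2] = k1[4];
    }
    if (step == n_tot) break;
    rk4_step(sys, t, h, y, k1, k2, k3, k4, tmp, eps > 0);
    for (int i = 0; i < 3; ++i)
      if (!std::isfinite(y[i])) stop("node state non-finite at t = %g", t + h);
  }

  double rate = (t_accum > 0) ? logsum / t_accum : NA_REAL;
  bool converged = false;
  size_t nr = running.size();
  if (nr >= 8) {
    double mid = running[nr / 2 - 1], fin = running[nr - 1];
    converged = std::fabs(fin - mid) < conv_tol;
  }
  return List::create(_["rate"] = rate, _["converged"] = converged,
                      _["running"] = NumericVector(running.begin(), running.end()));
}
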