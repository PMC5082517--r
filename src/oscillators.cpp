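#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::complex<double> cplx;

// Edge list of the nonzero entries of a complex weight matrix.
struct EdgeList {
  std::vector<int> to, from;
  std::vector<cplx> w;
};

static EdgeList edges_of(const ComplexMatrix &W) {
  EdgeList E;
  int n = W.nrow();
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      cplx w(W(i, j).r, W(i, j).i);
      if (std::abs(w) > 0.0) {
        E.to.push_back(i);
        E.from.push_back(j);
        E.w.push_back(w);
      }
    }
  return E;
}

// Coupled phase-oscillator sources for the surrogate-EEG generator:
//   dtheta_c = omega_c + sum_j |W(c,j)| sin(theta_j - theta_c + arg W(c,j))
// integrated with Euler-Maruyama (phase diffusion sigma_w, rad/sqrt(s)).
// Returns channels x n_steps phases; column t is the state before step t's update,
// so column 0 is theta0. Uses R's RNG (seed via set.seed()).
// [[Rcpp::export]]
NumericMatrix kuramoto_phases(NumericVector omega, ComplexMatrix W,
                              NumericVector theta0, double sigma_w,
                              double dt, int n_steps) {
  int n = omega.size();
  if (W.nrow() != n || W.ncol() != n)
    stop("coupling matrix dimension does not match omega");
  NumericMatrix out(n, n_steps);
  std::vector<double> th(n);
  for (int c = 0; c < n; ++c) th[c] = theta0[c];
  EdgeList E = edges_of(W);
  bool coupled = !E.w.empty();
  double sq = sigma_w * std::sqrt(dt);
  std::vector<cplx> e(n);
  std::vector<double> drift(n);
  for (int t = 0; t < n_steps; ++t) {
    for (int c = 0; c < n; ++c) out(c, t) = th[c];
    for (int c = 0; c < n; ++c) drift[c] = omega[c];
    if (coupled) {
      for (int c = 0; c < n; ++c) e[c] = std::polar(1.0, th[c]);
      for (size_t k = 0; k < E.w.size(); ++k) {
        cplx z = std::conj(e[E.to[k]]) * E.w[k] * e[E.from[k]];
        drift[E.to[k]] += z.imag();
      }
    }
    for (int c = 0; c < n; ++c) {
      th[c] += drift[c] * dt;
      if (sq > 0.0) th[c] += sq * R::norm_rand();
    }
  }
  return out;
}

// One evaluation of the mean-field node vector field
//   f_i = (i*omega0 - delta) z_i + (H_i - conj(H_i) z_i^2) / 2,
//   H_i = k_i z_i + sum_j W(i,j) z_j
// where W(i,j) is the complex input weight from node j into node i.
static inline void field(const std::vector<cplx> &z, const std::vector<double> &k,
                         const EdgeList &E, double delta, double omega0,
                         std::vector<cplx> &H, std::vector<cplx> &f) {
  int n = z.size();
  cplx iw(0.0, omega0);
  for (int i = 0; i < n; ++i) H[i] = k[i] * z[i];
  for (size_t e = 0; e < E.w.size(); ++e) H[E.to[e]] += E.w[e] * z[E.from[e]];
  for (int i = 0; i < n; ++i)
    f[i] = (iw - delta) * z[i] + 0.5 * (H[i] - std::conj(H[i]) * z[i] * z[i]);
}

static inline void clamp_unit(std::vector<cplx> &z) {
  for (size_t i = 0; i < z.size(); ++i) {
    double n2 = std::norm(z[i]);  // squared magnitude: no sqrt unless needed
    if (n2 > 1.0) z[i] /= std::sqrt(n2);
  }
}

// Heun integration of the node model. Fills frac_above[j] = fraction of sampled
// post-burn-in times with |z_j| > theta_sync; optionally records sampled |z|
// into traj (n x n_samples). Throws on non-finite state.
static void heun_run(const EdgeList &E, const std::vector<double> &k, int n,
                     double delta, double omega0, double dt, int burn_steps,
                     int sim_steps, int stride, double theta_sync,
                     double noise_amp, double z0,
                     std::vector<double> &frac_above, NumericMatrix *traj) {
  std::vector<cplx> z(n, cplx(z0, 0.0)), z1(n), f1(n), f2(n), H(n);
  std::vector<int> cnt(n, 0);
  int nsamp = 0, total = burn_steps + sim_steps;
  double na = noise_amp * std::sqrt(dt);
  for (int t = 0; t < total; ++t) {
    field(z, k, E, delta, omega0, H, f1);
    for (int i = 0; i < n; ++i) z1[i] = z[i] + dt * f1[i];
    clamp_unit(z1);
    field(z1, k, E, delta, omega0, H, f2);
    for (int i = 0; i < n; ++i) z[i] += 0.5 * dt * (f1[i] + f2[i]);
    if (na > 0.0)
      for (int i = 0; i < n; ++i)
        z[i] += cplx(na * R::norm_rand(), na * R::norm_rand());
    clamp_unit(z);
    if ((t & 255) == 0)
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(z[i].real()) || !std::isfinite(z[i].imag()))
          stop("non-finite state at integration step %d", t);
    if (t >= burn_steps && (t - burn_steps) % stride == 0) {
      ++nsamp;
      for (int i = 0; i < n; ++i) {
        double m = std::abs(z[i]);
        if (m > theta_sync) cnt[i]++;
        if (traj) (*traj)(i, nsamp - 1) = m;
      }
    }
  }
  for (int i = 0; i < n; ++i)
    frac_above[i] = nsamp > 0 ? (double)cnt[i] / nsamp : 0.0;
}

static int n_samples_of(double t_sim, double dt, int stride) {
  int sim_steps = (int)std::lround(t_sim / dt);
  return (sim_steps + stride - 1) / stride;
}

// Seizure-likelihood profile: for each requested driven node m (1-based),
// clamp k_m = k_drive, integrate, and return S_m = mean over the other nodes
// (or all nodes if exclude_driven = FALSE) of the time fraction above theta_sync.
// [[Rcpp::export]]
NumericVector dnm_profile_cpp(ComplexMatrix W, NumericVector k_local,
                              IntegerVector driven_nodes, double k_drive,
                              double delta, double omega0, double dt,
                              double t_burn, double t_sim, double theta_sync,
                              double noise_amp, double sample_every, double z0,
                              bool exclude_driven) {
  int n = k_local.size();
  EdgeList E = edges_of(W);
  int burn_steps = (int)std::lround(t_burn / dt);
  int sim_steps = (int)std::lround(t_sim / dt);
  int stride = std::max(1, (int)std::lround(sample_every / dt));
  NumericVector S(driven_nodes.size());
  std::vector<double> k(n), frac(n);
  for (int d = 0; d < driven_nodes.size(); ++d) {
    int m = driven_nodes[d] - 1;
    if (m < 0 || m >= n) stop("driven node index out of range");
    for (int i = 0; i < n; ++i) k[i] = k_local[i];
    k[m] = k_drive;
    heun_run(E, k, n, delta, omega0, dt, burn_steps, sim_steps, stride,
             theta_sync, noise_amp, z0, frac, NULL);
    double s = 0.0;
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      if (exclude_driven && i == m) continue;
      s += frac[i];
      ++cnt;
    }
    S[d] = cnt > 0 ? s / cnt : 0.0;
  }
  return S;
}

// Full (K, driven node) grid for one subject: k_local = K * sigma2 for each K
// in Kgrid, S computed for every driven node. Returns length(Kgrid) x n matrix.
// [[Rcpp::export]]
NumericMatrix dnm_grid_cpp(ComplexMatrix W, NumericVector sigma2,
                           NumericVector Kgrid, double k_drive, double delta,
                           double omega0, double dt, double t_burn,
                           double t_sim, double theta_sync, double noise_amp,
                           double sample_every, double z0,
                           bool exclude_driven) {
  int n = sigma2.size(), nK = Kgrid.size();
  EdgeList E = edges_of(W);
  int burn_steps = (int)std::lround(t_burn / dt);
  int sim_steps = (int)std::lround(t_sim / dt);
  int stride = std::max(1, (int)std::lround(sample_every / dt));
  NumericMatrix S(nK, n);
  std::vector<double> k(n), frac(n);
  for (int ik = 0; ik < nK; ++ik) {
    for (int m = 0; m < n; ++m) {
      for (int i = 0; i < n; ++i) k[i] = Kgrid[ik] * sigma2[i];
      k[m] = k_drive;
      heun_run(E, k, n, delta, omega0, dt, burn_steps, sim_steps, stride,
               theta_sync, noise_amp, z0, frac, NULL);
      double s = 0.0;
      int cnt = 0;
      for (int i = 0; i < n; ++i) {
        if (exclude_driven && i == m) continue;
        s += frac[i];
        ++cnt;
      }
      S(ik, m) = cnt > 0 ? s / cnt : 0.0;
    }
    Rcpp::checkUserInterrupt();
  }
  return S;
}

// Sampled |z| trajectories (n x n_samples). driven = 0 means no node is clamped.
// [[Rcpp::export]]
NumericMatrix dnm_traj_cpp(ComplexMatrix W, NumericVector k_local, int driven,
                           double k_drive, double delta, double omega0,
                           double dt, double t_burn, double t_sim,
                           double theta_sync, double noise_amp,
                           double sample_every, double z0) {
  int n = k_local.size();
  EdgeList E = edges_of(W);
  int burn_steps = (int)std::lround(t_burn / dt);
  int sim_steps = (int)std::lround(t_sim / dt);
  int stride = std::max(1, (int)std::lround(sample_every / dt));
  NumericMatrix traj(n, n_samples_of(t_sim, dt, stride));
  std::vector<double> k(n), frac(n);
  for (int i = 0; i < n; ++i) k[i] = k_local[i];
  if (driven > 0) {
    if (driven > n) stop("driven node index out of range");
    k[driven - 1] = k_drive;
  }
  heun_run(E, k, n, delta, omega0, dt, burn_steps, sim_steps, stride,
           theta_sync, noise_amp, z0, frac, &traj);
  return traj;
}

// Direct-form-II-transposed IIR filter with initial state zi (length
// max(len(a),len(b)) - 1); a and b must be same length with a[0] = 1.
// [[Rcpp::export]]
NumericVector df2t_filter(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int n = x.size(), m = b.size();
  if (a.size() != m) stop("a and b must have equal length");
  std::vector<double> z(m - 1, 0.0);
  for (int j = 0; j < zi.size() && j < m - 1; ++j) z[j] = zi[j];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 0; j < m - 2; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[m - 2] = b[m - 1] * xi - a[m - 1] * yi;
    y[i] = yi;
  }
  return y;
}
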