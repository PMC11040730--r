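// Forward lineshape evaluation and the Hamiltonian Monte Carlo engine.
//
// The sampled posterior is over
//   theta_w  : log component weights (one per candidate compound)
//   delta    : chemical-shift offsets, ppm (one per resonance)
//   log sigma: i.i.d. Gaussian residual scale of the density match
// with Half-Cauchy priors on weights and noise scale and Normal priors on
// the shift offsets.  The model spectrum is a weighted sum of pseudo-Voigt
// lines (Lorentzian natural linewidth convolved with the Gaussian
// apodization kernel), normalized to unit trapezoid area so that both
// sides of the likelihood are probability densities.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SQRT_2PI = 2.5066282746310002;

// Sum of lines on a uniform ppm grid.  Each line is a unit-area
// pseudo-Voigt: eta * Lorentzian(gamma) + (1 - eta) * Gaussian(sd),
// scaled by amp.  window_ppm limits evaluation to |x| <= window
// (Inf evaluates everywhere).
// [[Rcpp::export]]
NumericVector pv_mixture_cpp(NumericVector grid, NumericVector centers,
                             NumericVector amps, NumericVector gamma_ppm,
                             NumericVector gsd_ppm, NumericVector eta,
                             double window_ppm) {
  const int ng = grid.size(), nl = centers.size();
  const double g0 = grid[0];
  const double h = ng > 1 ? grid[1] - grid[0] : 1.0;
  NumericVector out(ng);
  for (int l = 0; l < nl; ++l) {
    const double c = centers[l], A = amps[l];
    const double gam = gamma_ppm[l], s = gsd_ppm[l], et = eta[l];
    int lo = 0, hi = ng - 1;
    if (R_finite(window_ppm)) {
      lo = (int)std::ceil((c - window_ppm - g0) / h);
      hi = (int)std::floor((c + window_ppm - g0) / h);
      if (lo < 0) lo = 0;
      if (hi > ng - 1) hi = ng - 1;
      if (lo > hi) continue;
    }
    const double gam_pi = gam / M_PI, gnorm = 1.0 / (s * SQRT_2PI);
    for (int g = lo; g <= hi; ++g) {
      const double x = g0 + g * h - c;
      out[g] += A * et * gam_pi / (x * x + gam * gam);
    }
    // Gaussian component only where it is numerically nonzero
    int glo = (int)std::ceil((c - 8.5 * s - g0) / h);
    int ghi = (int)std::floor((c + 8.5 * s - g0) / h);
    if (glo < lo) glo = lo;
    if (ghi > hi) ghi = hi;
    const double u = -0.5 / (s * s);
    for (int g = glo; g <= ghi; ++g) {
      const double x = g0 + g * h - c;
      out[g] += A * (1.0 - et) * gnorm * std::exp(u * x * x);
    }
  }
  return out;
}

namespace {

struct Model {
  // grid
  int ng;
  double g0, h;
  std::vector<double> y, tw;  // observed density, trapezoid weights
  // lines
  int nl;
  std::vector<double> cen0, amp, gam, gsd, eta;
  std::vector<int> comp, res;  // 0-based
  // resonances
  int nr;
  std::vector<double> rsd;  // shift prior sd, ppm
  // compounds
  int nc;
  double wscale, nscale, window;
  bool truncate;
  bool normalize;  // unit-area model (global fit) vs absolute (interval fit)
  int dim;

  // scratch
  std::vector<double> m, d, rres, V, Vp;
  std::vector<int> wlo, wlen;
  int wmax;

  void init_scratch() {
    m.resize(ng);
    d.resize(ng);
    rres.resize(ng);
    wmax = (int)(2.0 * window / h) + 4;
    V.resize((size_t)nl * wmax);
    Vp.resize((size_t)nl * wmax);
    wlo.resize(nl);
    wlen.resize(nl);
  }

  // negative log posterior (up to a constant) and its gradient
  double potential(const std::vector<double>& q, std::vector<double>* grad) {
    const double* theta = q.data();
    const double* delta = q.data() + nc;
    const double lsig = q[dim - 1];
    const double sigma = std::exp(lsig);
    if (!R_finite(sigma)) return R_PosInf;

    std::vector<double> w(nc);
    for (int c = 0; c < nc; ++c) {
      w[c] = std::exp(theta[c]);
      if (!R_finite(w[c])) return R_PosInf;
    }

    std::fill(m.begin(), m.end(), 0.0);
    // pass 1: lineshapes and mixture
    for (int l = 0; l < nl; ++l) {
      const double c = cen0[l] + delta[res[l]];
      int lo = (int)std::ceil((c - window - g0) / h);
      int hi = (int)std::floor((c + window - g0) / h);
      if (lo < 0) lo = 0;
      if (hi > ng - 1) hi = ng - 1;
      wlo[l] = lo;
      wlen[l] = hi >= lo ? hi - lo + 1 : 0;
      if (wlen[l] == 0) continue;
      const double B = w[comp[l]] * amp[l];
      const double gm = gam[l], s = gsd[l], et = eta[l];
      const double gam_pi = et * gm / M_PI, gnorm = (1.0 - et) / (s * SQRT_2PI);
      const double u = -0.5 / (s * s), inv_s2 = 1.0 / (s * s);
      double* Vl = V.data() + (size_t)l * wmax;
      double* Vpl = Vp.data() + (size_t)l * wmax;
      double x = grid_at(lo) - c;
      for (int k = 0; k < wlen[l]; ++k, x += h) {
        const double den = 1.0 / (x * x + gm * gm);
        const double L = gam_pi * den;
        Vl[k] = L;
        Vpl[k] = -2.0 * x * L * den;
      }
      // Gaussian component on the subwindow where it is nonzero; the
      // incremental recurrence stays in range there (|x| <= 8.5 sd)
      int glo = (int)std::ceil((c - 8.5 * s - g0) / h);
      int ghi = (int)std::floor((c + 8.5 * s - g0) / h);
      if (glo < lo) glo = lo;
      if (ghi > lo + wlen[l] - 1) ghi = lo + wlen[l] - 1;
      if (glo <= ghi) {
        double xg = grid_at(glo) - c;
        double a = std::exp(u * xg * xg);
        double m1 = std::exp(u * (2.0 * xg * h + h * h));
        const double r2 = std::exp(2.0 * u * h * h);
        for (int g = glo; g <= ghi; ++g, xg += h) {
          const double G = gnorm * a;
          Vl[g - lo] += G;
          Vpl[g - lo] += -xg * inv_s2 * G;
          a *= m1;
          m1 *= r2;
        }
      }
      for (int k = 0; k < wlen[l]; ++k) m[lo + k] += B * Vl[k];
    }

    double I = 1.0;
    if (normalize) {
      I = 0.0;
      for (int g = 0; g < ng; ++g) I += tw[g] * m[g];
      if (!(I > 0.0) || !R_finite(I)) return R_PosInf;
    }

    double SSR = 0.0, C2 = 0.0;
    for (int g = 0; g < ng; ++g) {
      d[g] = m[g] / I;
      rres[g] = d[g] - y[g];
      SSR += rres[g] * rres[g];
      C2 += rres[g] * d[g];
    }
    if (!normalize) C2 = 0.0;  // no normalization chain in the gradient
    const double sig2 = sigma * sigma;
    double U = ng * lsig + 0.5 * SSR / sig2;

    if (grad) {
      std::fill(grad->begin(), grad->end(), 0.0);
      double* gq = grad->data();
      const double inv = 1.0 / (sig2 * I);
      // pass 2: per-line reductions
      for (int l = 0; l < nl; ++l) {
        if (wlen[l] == 0) continue;
        const int lo = wlo[l];
        const double B = w[comp[l]] * amp[l];
        const double* Vl = V.data() + (size_t)l * wmax;
        const double* Vpl = Vp.data() + (size_t)l * wmax;
        double S1 = 0.0, TV = 0.0, S1d = 0.0, TVd = 0.0;
        for (int k = 0; k < wlen[l]; ++k) {
          const int g = lo + k;
          S1 += rres[g] * Vl[k];
          TV += tw[g] * Vl[k];
          S1d += rres[g] * Vpl[k];
          TVd += tw[g] * Vpl[k];
        }
        gq[comp[l]] += B * (S1 - C2 * TV) * inv;
        gq[nc + res[l]] += B * (C2 * TVd - S1d) * inv;
      }
      gq[dim - 1] = ng - SSR / sig2;
    }

    // priors
    for (int c = 0; c < nc; ++c) {
      const double t = w[c] / wscale, t2 = t * t;
      U += std::log1p(t2) - theta[c];
      if (grad) (*grad)[c] += -1.0 + 2.0 * t2 / (1.0 + t2);
    }
    for (int r = 0; r < nr; ++r) {
      const double z = delta[r] / rsd[r];
      U += 0.5 * z * z;
      if (grad) (*grad)[nc + r] += z / rsd[r];
      if (truncate) {
        // soft wall approximating truncation at +/- 4 prior sd
        const double zz = delta[r] / (4.0 * rsd[r]);
        const double z6 = zz * zz * zz * zz * zz * zz;
        U += z6 * zz * zz;
        if (grad) (*grad)[nc + r] += 8.0 * z6 * zz / (4.0 * rsd[r]);
      }
    }
    {
      const double t = sigma / nscale, t2 = t * t;
      U += std::log1p(t2) - lsig;
      if (grad) (*grad)[dim - 1] += -1.0 + 2.0 * t2 / (1.0 + t2);
    }
    return U;
  }

  double grid_at(int g) const { return g0 + g * h; }
};

double kinetic(const std::vector<double>& p, const std::vector<double>& var) {
  double k = 0.0;
  for (size_t i = 0; i < p.size(); ++i) k += 0.5 * p[i] * p[i] * var[i];
  return k;
}

// one leapfrog trajectory; returns false if it blew up
bool leapfrog(Model& mod, std::vector<double>& q, std::vector<double>& p,
              std::vector<double>& grad, const std::vector<double>& var,
              double eps, int L, double* U_out) {
  const int dim = mod.dim;
  for (int step = 0; step < L; ++step) {
    for (int i = 0; i < dim; ++i) p[i] -= 0.5 * eps * grad[i];
    for (int i = 0; i < dim; ++i) q[i] += eps * p[i] * var[i];
    double U = mod.potential(q, &grad);
    if (!R_finite(U)) return false;
    for (int i = 0; i < dim; ++i) p[i] -= 0.5 * eps * grad[i];
    *U_out = U;
  }
  return true;
}

}  // namespace

static Model build_model(NumericVector grid, NumericVector y,
                         NumericVector line_center, NumericVector line_amp,
                         IntegerVector line_comp, IntegerVector line_res,
                         NumericVector line_gamma, NumericVector line_gsd,
                         NumericVector line_eta, NumericVector res_sd,
                         int n_comp, double weight_scale, double noise_scale,
                         double window_ppm, bool truncate_shifts,
                         bool normalize) {
  Model mod;
  mod.ng = grid.size();
  mod.g0 = grid[0];
  mod.h = grid[1] - grid[0];
  mod.y.assign(y.begin(), y.end());
  mod.tw.assign(mod.ng, mod.h);
  mod.tw[0] = mod.tw[mod.ng - 1] = 0.5 * mod.h;
  mod.nl = line_center.size();
  mod.cen0.assign(line_center.begin(), line_center.end());
  mod.amp.assign(line_amp.begin(), line_amp.end());
  mod.gam.assign(line_gamma.begin(), line_gamma.end());
  mod.gsd.assign(line_gsd.begin(), line_gsd.end());
  mod.eta.assign(line_eta.begin(), line_eta.end());
  mod.comp.assign(line_comp.begin(), line_comp.end());
  mod.res.assign(line_res.begin(), line_res.end());
  mod.nr = res_sd.size();
  mod.rsd.assign(res_sd.begin(), res_sd.end());
  mod.nc = n_comp;
  mod.wscale = weight_scale;
  mod.nscale = noise_scale;
  mod.window = window_ppm;
  mod.truncate = truncate_shifts;
  mod.normalize = normalize;
  mod.dim = mod.nc + mod.nr + 1;
  mod.init_scratch();
  return mod;
}

// Negative log posterior and gradient at one point; exposed for testing
// the analytic gradient against finite differences.
// [[Rcpp::export]]
List nmr_potential_cpp(NumericVector grid, NumericVector y,
                       NumericVector line_center, NumericVector line_amp,
                       IntegerVector line_comp, IntegerVector line_res,
                       NumericVector line_gamma, NumericVector line_gsd,
                       NumericVector line_eta, NumericVector res_sd,
                       int n_comp, double weight_scale, double noise_scale,
                       double window_ppm, NumericVector q,
                       bool truncate_shifts, bool normalize) {
  Model mod = build_model(grid, y, line_center, line_amp, line_comp, line_res,
                          line_gamma, line_gsd, line_eta, res_sd, n_comp,
                          weight_scale, noise_scale, window_ppm,
                          truncate_shifts, normalize);
  std::vector<double> qq(q.begin(), q.end()), grad(mod.dim);
  double U = mod.potential(qq, &grad);
  return List::create(Named("U") = U,
                      Named("grad") = NumericVector(grad.begin(), grad.end()));
}

// [[Rcpp::export]]
List nmr_hmc_cpp(NumericVector grid, NumericVector y,
                 NumericVector line_center, NumericVector line_amp,
                 IntegerVector line_comp, IntegerVector line_res,
                 NumericVector line_gamma, NumericVector line_gsd,
                 NumericVector line_eta, NumericVector res_sd,
                 int n_comp, double weight_scale, double noise_scale,
                 double window_ppm, int warmup, int samples, int l_max,
                 double target_accept, NumericVector q_init,
                 bool truncate_shifts, bool normalize) {
  Model mod = build_model(grid, y, line_center, line_amp, line_comp, line_res,
                          line_gamma, line_gsd, line_eta, res_sd, n_comp,
                          weight_scale, noise_scale, window_ppm,
                          truncate_shifts, normalize);
  const int dim = mod.dim;
  std::vector<double> q(q_init.begin(), q_init.end());
  std::vector<double> grad(dim), var(dim, 1.0);
  // shift coordinates live on the ppm scale: start their mass from the
  // prior variance so the first warmup phase is well conditioned
  for (int r = 0; r < mod.nr; ++r)
    var[mod.nc + r] = mod.rsd[r] * mod.rsd[r];
  double U = mod.potential(q, &grad);
  if (!R_finite(U)) stop("invalid initial state for the sampler");

  RNGScope scope;

  // find a reasonable initial step size (one-step acceptance near 0.5)
  double eps = 0.1;
  {
    std::vector<double> p(dim), q1 = q, g1 = grad;
    for (int i = 0; i < dim; ++i) p[i] = norm_rand() / std::sqrt(var[i]);
    double H0 = U + kinetic(p, var), U1 = U;
    std::vector<double> p1 = p;
    bool ok = leapfrog(mod, q1, p1, g1, var, eps, 1, &U1);
    double logr = ok ? H0 - (U1 + kinetic(p1, var)) : R_NegInf;
    const double dir = (logr > std::log(0.5)) ? 1.0 : -1.0;
    for (int it = 0; it < 50; ++it) {
      eps *= (dir > 0 ? 2.0 : 0.5);
      q1 = q;
      p1 = p;
      g1 = grad;
      ok = leapfrog(mod, q1, p1, g1, var, eps, 1, &U1);
      logr = ok ? H0 - (U1 + kinetic(p1, var)) : R_NegInf;
      if (dir > 0 ? (logr < std::log(0.5)) : (logr > std::log(0.5))) break;
    }
  }

  // dual averaging state
  double mu = std::log(10.0 * eps), log_eps = std::log(eps);
  double log_eps_bar = 0.0, Hbar = 0.0;
  const double gamma_da = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  // expanding variance-adaptation windows (Stan-style): an initial
  // step-size-only buffer, then doubling windows each ending in a mass
  // update and step-size reset, then a final step-size-only buffer
  int init_buf = std::max(20, (int)(0.15 * warmup));
  int term_buf = std::max(25, (int)(0.10 * warmup));
  if (init_buf + term_buf > warmup / 2) {
    init_buf = warmup / 4;
    term_buf = warmup / 4;
  }
  std::vector<int> win_end;
  {
    int pos = init_buf, wsize = std::max(15, warmup / 20);
    while (pos + wsize < warmup - term_buf) {
      pos += wsize;
      // make the last window swallow the remainder
      if (pos + 2 * wsize >= warmup - term_buf) pos = warmup - term_buf;
      win_end.push_back(pos);
      wsize *= 2;
    }
    if (win_end.empty()) win_end.push_back(warmup - term_buf);
  }
  size_t win_idx = 0;
  std::vector<double> sum(dim, 0.0), sum2(dim, 0.0);
  int n_adapt = 0;

  NumericMatrix draws(samples, dim);
  int n_div = 0, n_acc = 0, n_tot = 0;
  std::vector<double> p(dim), q_prop(dim), g_prop(dim);

  for (int iter = 0; iter < warmup + samples; ++iter) {
    const bool in_warm = iter < warmup;
    for (int i = 0; i < dim; ++i) p[i] = norm_rand() / std::sqrt(var[i]);
    const double H0 = U + kinetic(p, var);
    const int L = 1 + (int)std::floor(unif_rand() * l_max);
    q_prop = q;
    g_prop = grad;
    std::vector<double> p_prop = p;
    double U_prop = U;
    const double step = std::exp(in_warm ? log_eps : log_eps_bar);
    bool ok = leapfrog(mod, q_prop, p_prop, g_prop, var, step, L, &U_prop);
    double accept_prob = 0.0;
    if (ok) {
      const double dH = H0 - (U_prop + kinetic(p_prop, var));
      if (R_finite(dH)) {
        accept_prob = dH > 0 ? 1.0 : std::exp(dH);
        if (dH < -1000.0) {
          if (!in_warm) ++n_div;
          accept_prob = 0.0;
        }
      } else if (!in_warm) {
        ++n_div;
      }
    } else if (!in_warm) {
      ++n_div;
    }
    if (unif_rand() < accept_prob) {
      q = q_prop;
      grad = g_prop;
      U = U_prop;
      if (!in_warm) ++n_acc;
    }
    if (!in_warm) ++n_tot;

    if (in_warm) {
      // dual averaging toward the target acceptance
      ++da_count;
      const double eta_da = 1.0 / (da_count + t0);
      Hbar = (1.0 - eta_da) * Hbar + eta_da * (target_accept - accept_prob);
      log_eps = mu - std::sqrt((double)da_count) / gamma_da * Hbar;
      const double xi = std::pow((double)da_count, -kappa);
      log_eps_bar = xi * log_eps + (1.0 - xi) * log_eps_bar;

      if (iter >= init_buf && win_idx < win_end.size()) {
        for (int i = 0; i < dim; ++i) {
          sum[i] += q[i];
          sum2[i] += q[i] * q[i];
        }
        ++n_adapt;
        if (iter + 1 == win_end[win_idx]) {
          if (n_adapt > 10) {
            const double shrink = 5.0 / (n_adapt + 5.0);
            for (int i = 0; i < dim; ++i) {
              double v =
                  (sum2[i] - sum[i] * sum[i] / n_adapt) / (n_adapt - 1);
              v = (1.0 - shrink) * v + shrink * 1e-3;
              var[i] = std::max(v, 1e-12);
            }
            mu = std::log(10.0 * std::exp(log_eps));
            Hbar = 0.0;
            log_eps_bar = 0.0;
            da_count = 0;
          }
          std::fill(sum.begin(), sum.end(), 0.0);
          std::fill(sum2.begin(), sum2.end(), 0.0);
          n_adapt = 0;
          ++win_idx;
        }
      }
    } else {
      for (int i = 0; i < dim; ++i) draws(iter - warmup, i) = q[i];
    }
  }

  return List::create(
      Named("draws") = draws, Named("accept_rate") = (double)n_acc / n_tot,
      Named("divergences") = n_div,
      Named("step_size") = std::exp(log_eps_bar),
      Named("mass_var") = NumericVector(var.begin(), var.end()));
}
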