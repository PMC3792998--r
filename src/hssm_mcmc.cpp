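// Metropolis-within-Gibbs sampler for the hierarchical two-state switching
// first-difference correlated random walk with class-specific t observation
// errors. Movement parameters (theta, gamma, alpha, Sigma) are shared across
// animals; location states x and behaviour states b are per-animal.
//
// Indexing (0-based here): animal has n states x[0..n-1]; displacements
// d[t] = x[t+1] - x[t] for t = 0..n-2; behaviour b[t] belongs to
// displacement t; the process density applies for t >= 1:
//   d[t] ~ N2(gamma[b] * T(theta[b]) * d[t-1], Sigma).
// Observations carry a left-bracket state index L and weight j in [0,1):
// predicted position (1-j)*x[L] + j*x[L+1], independent scaled-t errors.
#include <Rcpp.h>
using namespace Rcpp;

struct Obs {
  double lon, lat, j;
  int L;                      // left bracket state (0-based)
  double nu, tau_lon, tau_lat, c_lon, c_lat; // per-obs t-density constants
};

struct Animal {
  int n;                      // number of grid states
  std::vector<double> xlon, xlat;
  std::vector<int> b;         // length n-1, values 1/2
  std::vector<Obs> obs;
  std::vector<std::vector<int> > obs_by_state;
  std::vector<double> step;   // per-state RW proposal sd
  std::vector<int> acc, try_; // per-state acceptance tallies
};

struct Params {
  double theta[2], gamma[2], alpha[2];
  double slon, slat, rho;
  // derived covariance terms
  double det, i11, i12, i22;  // inverse of Sigma and its determinant
  void refresh() {
    double v1 = slon * slon, v2 = slat * slat, c = rho * slon * slat;
    det = v1 * v2 - c * c;
    i11 = v2 / det; i22 = v1 / det; i12 = -c / det;
  }
};

static inline double mvn2_ll(double r1, double r2, const Params &p) {
  return -M_LN2 - std::log(M_PI) - 0.5 * std::log(p.det)
    - 0.5 * (r1 * r1 * p.i11 + 2.0 * r1 * r2 * p.i12 + r2 * r2 * p.i22);
}

// process log density of displacement t (requires t >= 1)
static inline double proc_ll(const Animal &a, int t, int b, const Params &p) {
  double ct = std::cos(p.theta[b - 1]), st = std::sin(p.theta[b - 1]);
  double g = p.gamma[b - 1];
  double dpl = a.xlon[t] - a.xlon[t - 1], dpa = a.xlat[t] - a.xlat[t - 1];
  double dcl = a.xlon[t + 1] - a.xlon[t], dca = a.xlat[t + 1] - a.xlat[t];
  double m1 = g * (ct * dpl - st * dpa);
  double m2 = g * (st * dpl + ct * dpa);
  return mvn2_ll(dcl - m1, dca - m2, p);
}

static inline double obs_ll(const Animal &a, const Obs &o) {
  double pl = (1.0 - o.j) * a.xlon[o.L] + o.j * a.xlon[o.L + 1];
  double pa = (1.0 - o.j) * a.xlat[o.L] + o.j * a.xlat[o.L + 1];
  double zl = (o.lon - pl) / o.tau_lon, za = (o.lat - pa) / o.tau_lat;
  return o.c_lon - 0.5 * (o.nu + 1.0) * std::log1p(zl * zl / o.nu)
       + o.c_lat - 0.5 * (o.nu + 1.0) * std::log1p(za * za / o.nu);
}

// total process log likelihood, optionally restricted to one behaviour state
static double total_proc_ll(const std::vector<Animal> &animals, const Params &p,
                            int only_b = 0) {
  double ll = 0.0;
  for (size_t k = 0; k < animals.size(); ++k) {
    const Animal &a = animals[k];
    for (int t = 1; t <= a.n - 2; ++t) {
      if (only_b == 0 || a.b[t] == only_b) ll += proc_ll(a, t, a.b[t], p);
    }
  }
  return ll;
}

static inline double trans_lp(int from, int to, const Params &p) {
  double a1 = p.alpha[from - 1];           // P(next = 1 | from)
  return std::log(to == 1 ? a1 : 1.0 - a1);
}

// [[Rcpp::export]]
List hssm_mcmc(List animals_in, List init, int n_iter, int burn_in, int thin) {
  int n_anim = animals_in.size();
  std::vector<Animal> animals(n_anim);
  for (int k = 0; k < n_anim; ++k) {
    List ak = animals_in[k];
    NumericMatrix x0 = ak["x0"], y = ak["y"];
    IntegerVector ot = ak["obs_t"];
    NumericVector oj = ak["obs_j"], nu = ak["nu"],
      tl = ak["tau_lon"], ta = ak["tau_lat"];
    Animal &a = animals[k];
    a.n = x0.nrow();
    a.xlon.assign(a.n, 0.0); a.xlat.assign(a.n, 0.0);
    for (int i = 0; i < a.n; ++i) { a.xlon[i] = x0(i, 0); a.xlat[i] = x0(i, 1); }
    a.b.assign(a.n - 1, 1);
    a.obs.resize(y.nrow());
    a.obs_by_state.assign(a.n, std::vector<int>());
    for (int i = 0; i < y.nrow(); ++i) {
      Obs &o = a.obs[i];
      o.lon = y(i, 0); o.lat = y(i, 1);
      o.L = ot[i] - 1; o.j = oj[i];
      o.nu = nu[i]; o.tau_lon = tl[i]; o.tau_lat = ta[i];
      double cst = R::lgammafn((o.nu + 1.0) / 2.0) - R::lgammafn(o.nu / 2.0)
        - 0.5 * std::log(o.nu * M_PI);
      o.c_lon = cst - std::log(o.tau_lon);
      o.c_lat = cst - std::log(o.tau_lat);
      a.obs_by_state[o.L].push_back(i);
      if (o.L + 1 < a.n) a.obs_by_state[o.L + 1].push_back(i);
    }
    a.step.assign(a.n, 0.02);
    a.acc.assign(a.n, 0);
    a.try_.assign(a.n, 0);
  }

  Params p;
  {
    NumericVector th = init["theta"], g = init["gamma"], al = init["alpha"],
      sg = init["sigma"];
    p.theta[0] = th[0]; p.theta[1] = th[1];
    p.gamma[0] = g[0];  p.gamma[1] = g[1];
    p.alpha[0] = al[0]; p.alpha[1] = al[1];
    p.slon = sg[0]; p.slat = sg[1];
    p.rho = as<double>(init["rho"]);
    p.refresh();
  }

  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix out_params(n_keep, 9);
  List out_x(n_anim), out_b(n_anim);
  std::vector<NumericMatrix> xs(n_anim);
  std::vector<IntegerMatrix> bs(n_anim);
  for (int k = 0; k < n_anim; ++k) {
    xs[k] = NumericMatrix(n_keep, 2 * animals[k].n);
    bs[k] = IntegerMatrix(n_keep, animals[k].n);
  }

  // scalar-parameter RW steps and acceptance trackers: theta1, theta2,
  // gamma1, gamma2, slon, slat, rho
  double pstep[7] = {0.05, 0.15, 0.03, 0.03, 0.01, 0.01, 0.05};
  int pacc[7] = {0};
  int ptry = 0;
  const double half_normal_scale = 0.1;
  // several update sweeps per recorded iteration speed up mixing of the
  // sticky (state path, gamma) pair without changing the chain contract
  const int n_sweeps = 2, n_param_rounds = 5;

  RNGScope scope;
  int keep_row = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
   for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    // --- behaviour states: exact Gibbs sweep ---
    for (int k = 0; k < n_anim; ++k) {
      Animal &a = animals[k];
      int nd = a.n - 1;
      for (int t = 0; t < nd; ++t) {
        double lp[2];
        for (int s = 1; s <= 2; ++s) {
          double v = (t > 0) ? trans_lp(a.b[t - 1], s, p) : -M_LN2;
          if (t < nd - 1) v += trans_lp(s, a.b[t + 1], p);
          if (t >= 1) v += proc_ll(a, t, s, p);
          lp[s - 1] = v;
        }
        double pr1 = 1.0 / (1.0 + std::exp(lp[1] - lp[0]));
        a.b[t] = (unif_rand() < pr1) ? 1 : 2;
      }
    }

    // --- location states: single-site random-walk Metropolis ---
    for (int k = 0; k < n_anim; ++k) {
      Animal &a = animals[k];
      for (int i = 0; i < a.n; ++i) {
        double cur_ll = 0.0;
        int tlo = std::max(1, i - 1), thi = std::min(a.n - 2, i + 1);
        for (int t = tlo; t <= thi; ++t) cur_ll += proc_ll(a, t, a.b[t], p);
        const std::vector<int> &oi = a.obs_by_state[i];
        for (size_t q = 0; q < oi.size(); ++q) cur_ll += obs_ll(a, a.obs[oi[q]]);

        double old_lon = a.xlon[i], old_lat = a.xlat[i];
        if (i > 0 && i < a.n - 1 && unif_rand() < 0.3) {
          // reflect through the neighbour midpoint (symmetric involution,
          // unit Jacobian): flips local zigzag parity, the slow mode that
          // couples the latent path with the ARS persistence parameter
          a.xlon[i] = a.xlon[i - 1] + a.xlon[i + 1] - a.xlon[i]
            + norm_rand() * a.step[i];
          a.xlat[i] = a.xlat[i - 1] + a.xlat[i + 1] - a.xlat[i]
            + norm_rand() * a.step[i];
        } else {
          a.xlon[i] += norm_rand() * a.step[i];
          a.xlat[i] += norm_rand() * a.step[i];
        }
        double new_ll = 0.0;
        for (int t = tlo; t <= thi; ++t) new_ll += proc_ll(a, t, a.b[t], p);
        for (size_t q = 0; q < oi.size(); ++q) new_ll += obs_ll(a, a.obs[oi[q]]);
        ++a.try_[i];
        if (std::log(unif_rand()) < new_ll - cur_ll) {
          ++a.acc[i];
        } else {
          a.xlon[i] = old_lon; a.xlat[i] = old_lat;
        }
      }
    }
   } // sweeps

    // --- switching probabilities: conjugate Beta given transition counts ---
    {
      int n11 = 0, n12 = 0, n21 = 0, n22 = 0;
      for (int k = 0; k < n_anim; ++k) {
        const Animal &a = animals[k];
        for (size_t t = 1; t < a.b.size(); ++t) {
          if (a.b[t - 1] == 1) { (a.b[t] == 1 ? n11 : n12)++; }
          else                 { (a.b[t] == 1 ? n21 : n22)++; }
        }
      }
      p.alpha[0] = R::rbeta(1.0 + n11, 1.0 + n12);
      p.alpha[1] = R::rbeta(1.0 + n21, 1.0 + n22);
    }

    // --- movement parameters: random-walk Metropolis, one at a time ---
    for (int round = 0; round < n_param_rounds; ++round) {
    ++ptry;
    for (int w = 0; w < 7; ++w) {
      Params prop = p;
      double lp_prior_cur = 0.0, lp_prior_new = 0.0;
      bool ok = true;
      int only_b = 0;
      switch (w) {
      case 0: // theta1 ~ U(-pi/4, pi/4)
        prop.theta[0] = p.theta[0] + norm_rand() * pstep[0];
        ok = std::fabs(prop.theta[0]) < M_PI / 4.0;
        only_b = 1; break;
      case 1: { // theta2 ~ U(-pi, pi], proposal wrapped on the circle
        double th = p.theta[1] + norm_rand() * pstep[1];
        th -= 2.0 * M_PI * std::floor((th + M_PI) / (2.0 * M_PI));
        prop.theta[1] = th;
        only_b = 2; break;
      }
      case 2: // gamma1 ~ Beta(2,1), ordered above gamma2
        prop.gamma[0] = p.gamma[0] + norm_rand() * pstep[2];
        ok = prop.gamma[0] < 1.0 && prop.gamma[0] > prop.gamma[1];
        if (ok) {
          lp_prior_cur = std::log(2.0 * p.gamma[0]);
          lp_prior_new = std::log(2.0 * prop.gamma[0]);
        }
        only_b = 1; break;
      case 3: // gamma2 ~ Beta(1,2), ordered below gamma1
        prop.gamma[1] = p.gamma[1] + norm_rand() * pstep[3];
        ok = prop.gamma[1] > 0.0 && prop.gamma[1] < prop.gamma[0];
        if (ok) {
          lp_prior_cur = std::log(2.0 * (1.0 - p.gamma[1]));
          lp_prior_new = std::log(2.0 * (1.0 - prop.gamma[1]));
        }
        only_b = 2; break;
      case 4: // sigma_lon ~ half-normal(0.1)
        prop.slon = p.slon + norm_rand() * pstep[4];
        ok = prop.slon > 1e-6;
        if (ok) {
          lp_prior_cur = -0.5 * std::pow(p.slon / half_normal_scale, 2);
          lp_prior_new = -0.5 * std::pow(prop.slon / half_normal_scale, 2);
        }
        break;
      case 5: // sigma_lat ~ half-normal(0.1)
        prop.slat = p.slat + norm_rand() * pstep[5];
        ok = prop.slat > 1e-6;
        if (ok) {
          lp_prior_cur = -0.5 * std::pow(p.slat / half_normal_scale, 2);
          lp_prior_new = -0.5 * std::pow(prop.slat / half_normal_scale, 2);
        }
        break;
      case 6: // rho ~ U(-1, 1)
        prop.rho = p.rho + norm_rand() * pstep[6];
        ok = std::fabs(prop.rho) < 0.999;
        break;
      }
      if (!ok) continue;
      prop.refresh();
      double ll_cur = total_proc_ll(animals, p, only_b);
      double ll_new = total_proc_ll(animals, prop, only_b);
      if (std::log(unif_rand()) < (ll_new + lp_prior_new) - (ll_cur + lp_prior_cur)) {
        p = prop;
        ++pacc[w];
      }
    }
    } // parameter rounds

    // --- proposal adaptation during burn-in ---
    if (iter < burn_in && (iter + 1) % 100 == 0) {
      for (int k = 0; k < n_anim; ++k) {
        Animal &a = animals[k];
        for (int i = 0; i < a.n; ++i) {
          double rate = a.try_[i] ? (double)a.acc[i] / a.try_[i] : 0.0;
          a.step[i] *= std::exp(rate - 0.3);
          a.step[i] = std::min(std::max(a.step[i], 1e-5), 1.0);
          a.acc[i] = 0; a.try_[i] = 0;
        }
      }
      for (int w = 0; w < 7; ++w) {
        double rate = (double)pacc[w] / ptry;
        pstep[w] *= std::exp(rate - 0.44);
        pstep[w] = std::min(std::max(pstep[w], 1e-5), 2.0);
        pacc[w] = 0;
      }
      ptry = 0;
    }

    // --- retain thinned post-burn-in samples ---
    if (iter >= burn_in && (iter - burn_in) % thin == 0 && keep_row < n_keep) {
      out_params(keep_row, 0) = p.theta[0];
      out_params(keep_row, 1) = p.theta[1];
      out_params(keep_row, 2) = p.gamma[0];
      out_params(keep_row, 3) = p.gamma[1];
      out_params(keep_row, 4) = p.alpha[0];
      out_params(keep_row, 5) = p.alpha[1];
      out_params(keep_row, 6) = p.slon;
      out_params(keep_row, 7) = p.slat;
      out_params(keep_row, 8) = p.rho;
      for (int k = 0; k < n_anim; ++k) {
        const Animal &a = animals[k];
        for (int i = 0; i < a.n; ++i) {
          xs[k](keep_row, i) = a.xlon[i];
          xs[k](keep_row, a.n + i) = a.xlat[i];
          // behaviour of the displacement ending at state i (state 0 takes
          // the first displacement's behaviour)
          bs[k](keep_row, i) = a.b[i == 0 ? 0 : i - 1];
        }
      }
      ++keep_row;
    }
  }

  for (int k = 0; k < n_anim; ++k) { out_x[k] = xs[k]; out_b[k] = bs[k]; }
  colnames(out_params) = CharacterVector::create(
    "theta1", "theta2", "gamma1", "gamma2", "alpha1", "alpha2",
    "sigma_lon", "sigma_lat", "rho");
  return List::create(_["params"] = out_params, _["x"] = out_x, _["b"] = out_b);
}
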