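#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Shared arithmetic for one trial of the assembled circuit: per-phase
// settling (net excitation -> kWTA inhibition -> Euler membrane step ->
// activation), phase snapshots, and the end-of-plus-phase weight update.
// Mirrors the exported R primitives in R/netcore.R and R/plasticity.R;
// equivalence is asserted by the test suite.

struct Layer {
  int n, k;
  double gl, gebar, El, Ee, Ei, gamma, theta, q, tau, Vrest;
  NumericVector gibar;       // per-cell maximal inhibitory conductance
  bool clamped;              // externally imposed activity for whole trial
  bool reset_each_phase;     // CA1: Vm back to Vrest at each phase start
  std::vector<double> vm, y;
};

struct Proj {
  int from, to, minus_phase;
  double r, a, khebb, eps, sig_gain, sig_off;
  NumericMatrix W;           // linear weights (plasticity operates here)
  NumericMatrix Weff;        // contrast-enhanced weights (forward pass)
  NumericMatrix mask;
  NumericVector denom;       // max(n_conn_i, 1) * alpha_sender
};

// sigmoidal contrast enhancement of a linear weight
static inline double wt_sig_c(double w, double gain, double off) {
  if (w <= 0.0) return 0.0;
  if (w >= 1.0) return 1.0;
  return 1.0 / (1.0 + std::pow(off * (1.0 - w) / w, gain));
}

static inline double act_fn(double vm, double gamma, double theta) {
  double chi = vm > theta ? gamma * (vm - theta) : 0.0;
  return chi / (1.0 + chi);
}

// gi = s(k+1) + q*(s(k) - s(k+1)) on supports s_i = g_theta(ge_i)/gibar_i,
// floored at zero.
static double kwta_gi(const std::vector<double>& support, int k, double q) {
  std::vector<double> buf(support);
  std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end(),
                   std::greater<double>());
  double sk = buf[k - 1];
  std::nth_element(buf.begin() + k, buf.begin() + k, buf.end(),
                   std::greater<double>());
  double sk1 = buf[k];
  double gi = sk1 + q * (sk - sk1);
  return gi > 0.0 ? gi : 0.0;
}

// [[Rcpp::export]]
List trial_kernel_cpp(List layers_in, List projs_in, NumericVector r_sum,
                      List incoming, IntegerVector phase_steps,
                      NumericMatrix gates, NumericVector ecin_clamp,
                      Nullable<NumericVector> ecin_plus_,
                      Nullable<NumericVector> ecout_clamp_, bool learn,
                      int ecin_idx, int ecout_idx) {
  const int L = layers_in.size();
  const int P = projs_in.size();
  const int n_phase = phase_steps.size();

  std::vector<Layer> lay(L);
  for (int l = 0; l < L; ++l) {
    List li = layers_in[l];
    Layer& a = lay[l];
    a.n = as<int>(li["n"]); a.k = as<int>(li["k"]);
    a.gl = as<double>(li["gl_bar"]); a.gebar = as<double>(li["ge_bar"]);
    a.El = as<double>(li["El"]); a.Ee = as<double>(li["Ee"]);
    a.Ei = as<double>(li["Ei"]); a.gamma = as<double>(li["gamma"]);
    a.theta = as<double>(li["theta"]); a.q = as<double>(li["q"]);
    a.tau = as<double>(li["tau"]); a.Vrest = as<double>(li["Vrest"]);
    a.gibar = as<NumericVector>(li["gi_bar"]);
    a.clamped = as<bool>(li["clamped"]);
    a.reset_each_phase = as<bool>(li["reset_each_phase"]);
    a.vm.assign(a.n, a.Vrest);
    a.y.assign(a.n, 0.0);
  }

  std::vector<Proj> prj(P);
  for (int p = 0; p < P; ++p) {
    List pi = projs_in[p];
    Proj& a = prj[p];
    a.from = as<int>(pi["from"]) - 1; a.to = as<int>(pi["to"]) - 1;
    a.r = as<double>(pi["r"]); a.a = as<double>(pi["a"]);
    a.khebb = as<double>(pi["k_hebb"]); a.eps = as<double>(pi["epsilon"]);
    a.minus_phase = as<int>(pi["minus_phase"]);
    a.sig_gain = as<double>(pi["sig_gain"]);
    a.sig_off = as<double>(pi["sig_off"]);
    a.W = as<NumericMatrix>(pi["w"]);
    a.Weff = as<NumericMatrix>(pi["w_eff"]);
    a.mask = as<NumericMatrix>(pi["mask"]);
    a.denom = as<NumericVector>(pi["denom"]);
  }

  // ECin carries the upstream cortical pattern: the cue fields throughout,
  // plus the reward field only once the plus phase reveals the outcome.
  {
    Layer& e = lay[ecin_idx - 1];
    for (int i = 0; i < e.n; ++i) e.y[i] = ecin_clamp[i];
  }
  NumericVector ecin_plus;
  bool have_ecin_plus = false;
  if (ecin_plus_.isNotNull()) {
    ecin_plus = NumericVector(ecin_plus_);
    have_ecin_plus = true;
  }
  NumericVector ecout_clamp;
  bool have_plus_clamp = false;
  if (ecout_clamp_.isNotNull()) {
    ecout_clamp = NumericVector(ecout_clamp_);
    have_plus_clamp = true;
  }

  List snaps(n_phase);
  std::vector<std::vector<double>> y_old(L);
  std::vector<double> ge, support;

  for (int ph = 0; ph < n_phase; ++ph) {
    bool plus_phase = (ph == 2);
    for (int l = 0; l < L; ++l) {
      if (lay[l].reset_each_phase && !lay[l].clamped) {
        lay[l].vm.assign(lay[l].n, lay[l].Vrest);
        lay[l].y.assign(lay[l].n, 0.0);
      }
    }
    if (plus_phase && have_ecin_plus) {
      Layer& e = lay[ecin_idx - 1];
      for (int i = 0; i < e.n; ++i) e.y[i] = ecin_plus[i];
    }
    bool ecout_is_clamped = plus_phase && have_plus_clamp;
    if (ecout_is_clamped) {
      Layer& e = lay[ecout_idx - 1];
      for (int i = 0; i < e.n; ++i) e.y[i] = ecout_clamp[i];
    }

    for (int step = 0; step < phase_steps[ph]; ++step) {
      for (int l = 0; l < L; ++l) y_old[l] = lay[l].y;
      for (int l = 0; l < L; ++l) {
        Layer& a = lay[l];
        if (a.clamped) continue;
        if (l == ecout_idx - 1 && ecout_is_clamped) continue;
        ge.assign(a.n, 0.0);
        IntegerVector inc = incoming[l];
        for (int ii = 0; ii < inc.size(); ++ii) {
          int p = inc[ii] - 1;
          double gate = gates(p, ph);
          if (gate == 0.0) continue;
          const Proj& pr = prj[p];
          const std::vector<double>& x = y_old[pr.from];
          double scale = (pr.r / r_sum[l]) * pr.a * gate;
          const double* Wp = REAL(pr.Weff);
          int n_to = a.n;
          std::vector<double> raw(a.n, 0.0);
          for (size_t h = 0; h < x.size(); ++h) {
            double xv = x[h];
            if (xv <= 0.0) continue;
            const double* col = Wp + (size_t)h * n_to;
            for (int i = 0; i < n_to; ++i) raw[i] += xv * col[i];
          }
          for (int i = 0; i < a.n; ++i)
            ge[i] += scale * raw[i] / pr.denom[i];
        }
        support.assign(a.n, 0.0);
        for (int i = 0; i < a.n; ++i) {
          double gth = (ge[i] * a.gebar * (a.Ee - a.theta) +
                        a.gl * (a.El - a.theta)) / (a.theta - a.Ei);
          support[i] = gth / a.gibar[i];
        }
        double gi = kwta_gi(support, a.k, a.q);
        // semi-implicit Euler: same fixed point as the forward step, stable
        // for the large shunting conductances contextual suppression makes
        for (int i = 0; i < a.n; ++i) {
          double num = a.gl * a.El + ge[i] * a.gebar * a.Ee +
                       gi * a.gibar[i] * a.Ei;
          double den = a.gl + ge[i] * a.gebar + gi * a.gibar[i];
          a.vm[i] = (a.vm[i] + a.tau * num) / (1.0 + a.tau * den);
          a.y[i] = act_fn(a.vm[i], a.gamma, a.theta);
        }
      }
    }

    List sl(L);
    for (int l = 0; l < L; ++l) sl[l] = NumericVector(lay[l].y.begin(), lay[l].y.end());
    snaps[ph] = sl;
  }

  if (learn && n_phase == 3) {
    for (int p = 0; p < P; ++p) {
      Proj& pr = prj[p];
      NumericVector xp = as<List>(snaps[2])[pr.from];
      NumericVector yp = as<List>(snaps[2])[pr.to];
      NumericVector xm = as<List>(snaps[pr.minus_phase - 1])[pr.from];
      NumericVector ym = as<List>(snaps[pr.minus_phase - 1])[pr.to];
      int n_to = pr.W.nrow(), n_from = pr.W.ncol();
      double kh = pr.khebb, eps = pr.eps;
      for (int i = 0; i < n_to; ++i) {
        double ypi = yp[i], ymi = ym[i];
        if (ypi <= 0.0 && (kh >= 1.0 || ymi <= 0.0)) continue;
        for (int h = 0; h < n_from; ++h) {
          if (pr.mask(i, h) == 0.0) continue;
          double w = pr.W(i, h);
          double dh = ypi > 0.0 ? ypi * (xp[h] - w) : 0.0;
          double d;
          if (kh < 1.0) {
            double de = xp[h] * ypi - xm[h] * ymi;
            de = de > 0.0 ? de * (1.0 - w) : de * w;
            d = kh * dh + (1.0 - kh) * de;
          } else {
            d = dh;
          }
          double wn = w + eps * d;
          if (wn < 0.0) wn = 0.0; else if (wn > 1.0) wn = 1.0;
          pr.W(i, h) = wn;
          if (pr.sig_gain != 1.0 || pr.sig_off != 1.0)
            pr.Weff(i, h) = wt_sig_c(wn, pr.sig_gain, pr.sig_off);
        }
      }
    }
  }

  return List::create(_["snapshots"] = snaps);
}
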