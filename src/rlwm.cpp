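// Session-level RLWM-LBA computations: likelihood replay and generative
// simulation. These mirror the reference R operations in R/core-updates.R
// and R/lba.R exactly; the R unit tests cross-check the two routes.

#include <Rcpp.h>
using namespace Rcpp;

static const int NA_ACT = 3;

// softmax with max-subtraction, beta*q can reach ~50
static inline void softmax3(const double *q, double beta, double *p) {
  double z0 = beta * q[0], z1 = beta * q[1], z2 = beta * q[2];
  double m = std::max(z0, std::max(z1, z2));
  double e0 = std::exp(z0 - m), e1 = std::exp(z1 - m), e2 = std::exp(z2 - m);
  double s = e0 + e1 + e2;
  p[0] = e0 / s; p[1] = e1 / s; p[2] = e2 / s;
}

// For A/(t*s) below ~1e-6 the standard closed form cancels
// catastrophically (bracket of order A times 1/A); switch to the exact
// A -> 0 limit: finishing time b/v with v ~ N(V, s).
static inline double lba_pdf1(double t, double v, double A, double b, double s) {
  double ts = t * s;
  double z1 = (b - t * v) / ts;
  if (A / ts < 1e-6)
    return b / (t * t * s) * R::dnorm(z1, 0, 1, 0);
  double z2 = (b - A - t * v) / ts;
  double f = (1.0 / A) * (-v * R::pnorm(z2, 0, 1, 1, 0) + s * R::dnorm(z2, 0, 1, 0)
                          + v * R::pnorm(z1, 0, 1, 1, 0) - s * R::dnorm(z1, 0, 1, 0));
  return f > 0 ? f : 0.0;
}

static inline double lba_cdf1(double t, double v, double A, double b, double s) {
  double ts = t * s;
  double z1 = (b - t * v) / ts;
  if (A / ts < 1e-6)
    return R::pnorm(-z1, 0, 1, 1, 0);
  double z2 = (b - A - t * v) / ts;
  double F = 1.0 + (b - A - t * v) / A * R::pnorm(z2, 0, 1, 1, 0)
                 - (b - t * v) / A * R::pnorm(z1, 0, 1, 1, 0)
                 + ts / A * R::dnorm(z2, 0, 1, 0)
                 - ts / A * R::dnorm(z1, 0, 1, 0);
  if (F < 0) F = 0; if (F > 1) F = 1;
  return F;
}

// Shared per-trial machinery: given the pre-trial Q tables, produce the
// mixed policy of the presented stimulus and the drift rates.
struct TrialPolicy {
  double pol[3];  // mixed policy of presented stimulus
  double V[3];    // drift rates
};

static void trial_policy(const std::vector<double> &qrl,
                         const std::vector<double> &qwm,
                         int ns, int st, double beta, double w,
                         double eta, double h_floor, TrialPolicy &out) {
  double avg[3] = {0, 0, 0};
  double mix_st[3] = {0, 0, 0};
  double prl[3], pwm[3], mix[3];
  for (int j = 0; j < ns; ++j) {
    softmax3(&qrl[3 * j], beta, prl);
    softmax3(&qwm[3 * j], beta, pwm);
    for (int a = 0; a < 3; ++a) {
      mix[a] = w * pwm[a] + (1 - w) * prl[a];
      avg[a] += mix[a] / ns;
    }
    if (j == st) { mix_st[0] = mix[0]; mix_st[1] = mix[1]; mix_st[2] = mix[2]; }
  }
  double H = 0;
  for (int a = 0; a < 3; ++a)
    if (avg[a] > 0) H -= avg[a] * std::log2(avg[a]);
  double Hd = std::max(H, h_floor);
  for (int a = 0; a < 3; ++a) {
    out.pol[a] = mix_st[a];
    out.V[a] = eta * mix_st[a] / Hd;
  }
}

static inline void apply_updates(std::vector<double> &qrl,
                                 std::vector<double> &qwm,
                                 int ns, int st, int act, double r,
                                 double alpha, double bias, double phi) {
  // RL delta rule with positive learning bias
  double q = qrl[3 * st + act];
  double delta = r - q;
  double rate = delta < 0 ? (1 - bias) * alpha : alpha;
  qrl[3 * st + act] = q + rate * delta;
  // WM: learning rate 1, same bias
  q = qwm[3 * st + act];
  delta = r - q;
  rate = delta < 0 ? (1 - bias) : 1.0;
  qwm[3 * st + act] = q + rate * delta;
  // decay of ALL WM entries toward 1/3, applied after updating
  for (int i = 0; i < 3 * ns; ++i)
    qwm[i] += phi * (1.0 / 3.0 - qwm[i]);
}

// Trials must be ordered by block then trial index; `stim` is the 0-based
// stimulus index within its block; `choice` is 0..2 or -1 for a
// non-response (excluded from the likelihood; decay still applies).
// [[Rcpp::export]]
double cpp_session_loglik(IntegerVector block, IntegerVector stim,
                          IntegerVector set_size, IntegerVector correct,
                          IntegerVector choice, NumericVector rt,
                          NumericVector pars, double beta, double tau,
                          double s, double h_floor, double lp_floor) {
  const double alpha = pars[0], bias = pars[1], phi = pars[2], rho = pars[3];
  const double C = pars[4], eta = pars[5], A = pars[6], kk = pars[7];
  const double b = A + kk;
  int n = block.size();
  double ll = 0;
  std::vector<double> qrl, qwm;
  int cur_block = INT_MIN;
  TrialPolicy tp;
  for (int t = 0; t < n; ++t) {
    int ns = set_size[t];
    if (block[t] != cur_block) {
      cur_block = block[t];
      qrl.assign(3 * ns, 1.0 / 3.0);
      qwm.assign(3 * ns, 1.0 / 3.0);
    }
    int st = stim[t];
    if (st < 0 || st >= ns) stop("stimulus index out of range");
    double w = rho * std::min(1.0, C / ns);
    int act = choice[t];
    if (act >= 0) {
      trial_policy(qrl, qwm, ns, st, beta, w, eta, h_floor, tp);
      double rtt = rt[t];
      double lp = lp_floor;
      if (R_finite(rtt) && rtt > tau) {
        double tt = rtt - tau;
        double dens = lba_pdf1(tt, tp.V[act], A, b, s);
        for (int j = 0; j < 3; ++j)
          if (j != act) dens *= (1.0 - lba_cdf1(tt, tp.V[j], A, b, s));
        if (dens > 1e-10) lp = std::log(dens);
      }
      ll += lp;
      double r = (act == correct[t]) ? 1.0 : 0.0;
      apply_updates(qrl, qwm, ns, st, act, r, alpha, bias, phi);
    } else {
      // non-response: no evidence, no update, time still passes
      for (int i = 0; i < 3 * ns; ++i)
        qwm[i] += phi * (1.0 / 3.0 - qwm[i]);
    }
  }
  return ll;
}

// Generative direction: play the model through a session design, sampling
// choice and RT from the LBA race with R's RNG (deterministic under
// set.seed). RTs beyond rt_max become non-responses (NA action/rt/reward).
// [[Rcpp::export]]
DataFrame cpp_simulate_session(IntegerVector block, IntegerVector stim,
                               IntegerVector set_size, IntegerVector correct,
                               NumericVector pars, double beta, double tau,
                               double s, double h_floor, double rt_max) {
  const double alpha = pars[0], bias = pars[1], phi = pars[2], rho = pars[3];
  const double C = pars[4], eta = pars[5], A = pars[6], kk = pars[7];
  const double b = A + kk;
  int n = block.size();
  IntegerVector out_choice(n);
  NumericVector out_rt(n);
  IntegerVector out_reward(n);
  std::vector<double> qrl, qwm;
  int cur_block = INT_MIN;
  TrialPolicy tp;
  RNGScope scope;
  for (int t = 0; t < n; ++t) {
    int ns = set_size[t];
    if (block[t] != cur_block) {
      cur_block = block[t];
      qrl.assign(3 * ns, 1.0 / 3.0);
      qwm.assign(3 * ns, 1.0 / 3.0);
    }
    int st = stim[t];
    double w = rho * std::min(1.0, C / ns);
    trial_policy(qrl, qwm, ns, st, beta, w, eta, h_floor, tp);
    // race: start ~ U(0,A), drift ~ N(V, s)
    double drift[3], start[3];
    bool any_pos = false;
    for (int tries = 0; tries < 1000 && !any_pos; ++tries) {
      for (int a = 0; a < 3; ++a) drift[a] = tp.V[a] + s * norm_rand();
      any_pos = drift[0] > 0 || drift[1] > 0 || drift[2] > 0;
    }
    if (!any_pos) {
      int best = 0;
      for (int a = 1; a < 3; ++a) if (tp.V[a] > tp.V[best]) best = a;
      drift[best] = 1e-6;
    }
    for (int a = 0; a < 3; ++a) start[a] = A * unif_rand();
    int winner = -1;
    double tmin = R_PosInf;
    for (int a = 0; a < 3; ++a) {
      if (drift[a] > 0) {
        double ta = (b - start[a]) / drift[a];
        if (ta < tmin) { tmin = ta; winner = a; }
      }
    }
    double rtt = tau + tmin;
    if (rtt > rt_max) {
      out_choice[t] = NA_INTEGER;
      out_rt[t] = NA_REAL;
      out_reward[t] = NA_INTEGER;
      for (int i = 0; i < 3 * ns; ++i)
        qwm[i] += phi * (1.0 / 3.0 - qwm[i]);
    } else {
      double r = (winner == correct[t]) ? 1.0 : 0.0;
      out_choice[t] = winner;
      out_rt[t] = rtt;
      out_reward[t] = (int) r;
      apply_updates(qrl, qwm, ns, st, winner, r, alpha, bias, phi);
    }
  }
  return DataFrame::create(_["action"] = out_choice, _["rt"] = out_rt,
                           _["reward"] = out_reward);
}
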