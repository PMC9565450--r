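// Event-driven exact simulators.
//
// Stage transitions have the time-inhomogeneous hazard (a V(t))^alpha with
// V(t) = V0 e^{g t}; the waiting time is sampled by exact inverse
// transform: with E ~ Exp(1),
//   tau = log(1 + alpha g E / (a V0)^alpha) / (alpha g),
// so the generalized added size V0^alpha (e^{alpha g tau} - 1) is
// exponential with mean alpha g / a^alpha.  No thinning is used anywhere.
// Burst and degradation channels have state-constant rates, so candidate
// event times can be raced against the pre-sampled stage time exactly.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double inhom_wait(double rate0, double ag) {
  // hazard rate0 * e^{ag t}; exact inversion (ag > 0 assumed)
  double E = R::exp_rand();
  return std::log1p(ag * E / rate0) / ag;
}

static inline long rgeom_mean(double meanB) {
  // geometric on {0,1,2,...} with mean meanB
  if (meanB <= 0) return 0;
  return (long) R::rgeom(1.0 / (meanB + 1.0));
}

// [[Rcpp::export]]
List sim_full_cpp(double g, double rho, double kappa, double B, double beta,
                  double d, int N, int N0, double alpha0, double alpha1,
                  double a, double t_max, double sample_dt, double V0,
                  int n_init) {
  double t = 0.0, V = V0;
  int k = 1;
  long n = n_init;
  int gen = 0;

  const int nsamp = (int) std::floor(t_max / sample_dt) + 1;
  NumericVector s_time(nsamp), s_vol(nsamp);
  IntegerVector s_stage(nsamp), s_num(nsamp), s_gen(nsamp);
  int si = 0;
  double next_s = 0.0;

  std::vector<double> gVb, gVr, gVd, g_tb, gTrep, gTdiv;
  std::vector<int> g_nb, g_nd;
  double cur_Vb = V, cur_tb = 0.0, cur_Vr = NA_REAL, cur_tr = NA_REAL;
  int cur_nb = n_init;

  // emit samples up to time tu with current state (volume extrapolated)
  auto emit = [&](double tu) {
    while (si < nsamp && next_s <= tu * (1 + 1e-15) + 1e-300) {
      s_time[si] = next_s;
      s_stage[si] = k;
      s_num[si] = (int) n;
      s_gen[si] = gen;
      s_vol[si] = V * std::exp(g * (next_s - t));
      ++si;
      next_s += sample_dt;
    }
  };

  bool running = true;
  while (running) {
    double alpha = (k <= N0) ? alpha0 : alpha1;
    double rk = (k <= N0) ? rho : kappa * rho;
    double rate0 = std::pow(a * V, alpha);
    double t_stage = t + inhom_wait(rate0, alpha * g);

    // chemistry race until the stage transition
    for (;;) {
      double lam = rk + (double) n * d;
      double t_chem = (lam > 0) ? t + R::exp_rand() / lam : R_PosInf;
      double t_ev = std::min(t_chem, t_stage);
      if (t_ev >= t_max) {
        emit(t_max);
        running = false;
        break;
      }
      if (t_chem < t_stage) {
        emit(t_chem);
        V *= std::exp(g * (t_chem - t));
        t = t_chem;
        if (R::unif_rand() * lam < rk) {
          n += rgeom_mean(B * std::pow(V, beta));
        } else {
          n -= 1;
        }
      } else {
        emit(t_stage);
        V *= std::exp(g * (t_stage - t));
        t = t_stage;
        break;
      }
    }
    if (!running) break;

    // stage transition
    k += 1;
    if (k == N0 + 1) { cur_Vr = V; cur_tr = t; }
    if (k > N) {
      gVb.push_back(cur_Vb);
      gVr.push_back(cur_Vr);
      gVd.push_back(V);
      g_tb.push_back(cur_tb);
      gTrep.push_back(cur_tr - cur_tb);
      gTdiv.push_back(t - cur_tb);
      g_nb.push_back(cur_nb);
      g_nd.push_back((int) n);
      V *= 0.5;
      n = (long) R::rbinom((double) n, 0.5);
      k = 1;
      gen += 1;
      cur_Vb = V; cur_tb = t; cur_Vr = NA_REAL; cur_tr = NA_REAL;
      cur_nb = (int) n;
    }
    if (!std::isfinite(V) || n < 0)
      stop("nonfinite simulator state at t = %f", t);
  }

  return List::create(
    _["time"] = s_time, _["stage"] = s_stage, _["volume"] = s_vol,
    _["number"] = s_num, _["generation"] = s_gen, _["n_samples"] = si,
    _["gen_Vb"] = wrap(gVb), _["gen_Vr"] = wrap(gVr), _["gen_Vd"] = wrap(gVd),
    _["gen_tb"] = wrap(g_tb), _["gen_Trep"] = wrap(gTrep),
    _["gen_Tdiv"] = wrap(gTdiv), _["gen_nb"] = wrap(g_nb),
    _["gen_nd"] = wrap(g_nd));
}

// [[Rcpp::export]]
List sim_reduced_cpp(NumericVector v, NumericVector q, NumericVector Bk,
                     NumericVector rhok, double d, double t_max,
                     double sample_dt, int n_init) {
  const int N = v.size();
  double t = 0.0;
  int k = 1;
  long n = n_init;
  int gen = 0;

  const int nsamp = (int) std::floor(t_max / sample_dt) + 1;
  NumericVector s_time(nsamp), s_vol(nsamp);
  IntegerVector s_stage(nsamp), s_num(nsamp), s_gen(nsamp);
  int si = 0;
  double next_s = 0.0;

  auto emit = [&](double tu) {
    while (si < nsamp && next_s <= tu * (1 + 1e-15) + 1e-300) {
      s_time[si] = next_s;
      s_stage[si] = k;
      s_num[si] = (int) n;
      s_gen[si] = gen;
      s_vol[si] = v[k - 1];
      ++si;
      next_s += sample_dt;
    }
  };

  while (true) {
    double lam = q[k - 1] + rhok[k - 1] + (double) n * d;
    double t_ev = t + R::exp_rand() / lam;
    if (t_ev >= t_max) { emit(t_max); break; }
    emit(t_ev);
    t = t_ev;
    double u = R::unif_rand() * lam;
    if (u < rhok[k - 1]) {
      n += rgeom_mean(Bk[k - 1]);
    } else if (u < rhok[k - 1] + (double) n * d) {
      n -= 1;
    } else {
      k += 1;
      if (k > N) {
        n = (long) R::rbinom((double) n, 0.5);
        k = 1;
        gen += 1;
      }
    }
  }

  return List::create(
    _["time"] = s_time, _["stage"] = s_stage, _["volume"] = s_vol,
    _["number"] = s_num, _["generation"] = s_gen, _["n_samples"] = si);
}

// Three-stage model: gene switching between inactive and active states,
// transcription with rate s V(t)^beta per active copy, translation, and
// first-order mRNA/protein decay, on top of the same cell-size machinery.
// All candidate times are resampled after every event; the stage and
// transcription candidates use the exact inversion above.
// [[Rcpp::export]]
List sim3_cpp(double g, double rho_act, double r, double s, double u,
              double vdeg, double d, double kappa, double beta,
              int N, int N0, double alpha0, double alpha1, double a,
              double t_max, double sample_dt, double V0) {
  double t = 0.0, V = V0;
  int k = 1, copies = 1, ga = 0, gen = 0;
  long m = 0, P = 0;

  const int nsamp = (int) std::floor(t_max / sample_dt) + 1;
  NumericVector s_time(nsamp), s_vol(nsamp);
  IntegerVector s_stage(nsamp), s_mrna(nsamp), s_prot(nsamp), s_gen(nsamp);
  int si = 0;
  double next_s = 0.0;

  auto emit = [&](double tu) {
    while (si < nsamp && next_s <= tu * (1 + 1e-15) + 1e-300) {
      s_time[si] = next_s;
      s_stage[si] = k;
      s_mrna[si] = (int) m;
      s_prot[si] = (int) P;
      s_gen[si] = gen;
      s_vol[si] = V * std::exp(g * (next_s - t));
      ++si;
      next_s += sample_dt;
    }
  };

  while (true) {
    double alpha = (k <= N0) ? alpha0 : alpha1;
    double act = (k <= N0) ? rho_act : kappa * rho_act / 2.0;

    double t_stage = t + inhom_wait(std::pow(a * V, alpha), alpha * g);

    double t_tx = R_PosInf;
    if (ga > 0 && s > 0) {
      double c0 = ga * s * std::pow(V, beta);
      t_tx = (beta > 0) ? t + inhom_wait(c0, beta * g)
                        : t + R::exp_rand() / c0;
    }

    double r_act = (copies - ga) * act;
    double r_inact = ga * r;
    double r_tl = u * (double) m;
    double r_mdeg = vdeg * (double) m;
    double r_pdeg = d * (double) P;
    double lam = r_act + r_inact + r_tl + r_mdeg + r_pdeg;
    double t_const = (lam > 0) ? t + R::exp_rand() / lam : R_PosInf;

    double t_ev = std::min(t_stage, std::min(t_tx, t_const));
    if (t_ev >= t_max) { emit(t_max); break; }
    emit(t_ev);
    V *= std::exp(g * (t_ev - t));
    t = t_ev;

    if (t_ev == t_stage) {
      k += 1;
      if (k == N0 + 1) copies = 2;  // replication: new copy inactive
      if (k > N) {
        m = (long) R::rbinom((double) m, 0.5);
        P = (long) R::rbinom((double) P, 0.5);
        // follow one daughter: it inherits one of the two copies
        ga = (R::unif_rand() < ga / 2.0) ? 1 : 0;
        copies = 1;
        V *= 0.5;
        k = 1;
        gen += 1;
      }
    } else if (t_ev == t_tx) {
      m += 1;
    } else {
      double z = R::unif_rand() * lam;
      if (z < r_act) ga += 1;
      else if (z < r_act + r_inact) ga -= 1;
      else if (z < r_act + r_inact + r_tl) P += 1;
      else if (z < r_act + r_inact + r_tl + r_mdeg) m -= 1;
      else P -= 1;
    }
  }

  return List::create(
    _["time"] = s_time, _["stage"] = s_stage, _["volume"] = s_vol,
    _["mrna"] = s_mrna, _["protein"] = s_prot, _["generation"] = s_gen,
    _["n_samples"] = si);
}
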