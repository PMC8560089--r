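#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shared Gaussian suppression envelope. `tc` holds the (absolute) times of
// the envelope peaks, one per light pulse; pulses are assumed non-overlapping
// but the shape is summed and clamped to 1 for safety.
struct Envelope {
  std::vector<double> tc;
  double depth, width, depth_d;
  int side; // 0 = both, 1 = ventral only (Ma > 0), 2 = dorsal only (Ma < 0)

  bool active() const { return !tc.empty() && depth > 0.0 && width > 0.0; }

  double shape(double t) const {
    double s = 0.0;
    for (size_t i = 0; i < tc.size(); ++i) {
      double u = t - tc[i];
      if (std::fabs(u) <= 5.0 * width)
        s += std::exp(-0.5 * u * u / (width * width));
    }
    return s > 1.0 ? 1.0 : s;
  }

  // suppression factor applied to the active moment, gated by its sign
  double eps(double t, double ma) const {
    if (!active()) return 0.0;
    double d;
    if (side == 0) d = depth;
    else if (side == 1) d = (ma > 0.0) ? depth : 0.0;
    else d = (ma < 0.0) ? depth_d : 0.0;
    if (d <= 0.0) return 0.0;
    return d * shape(t);
  }
};

static Envelope make_env(List env) {
  Envelope e;
  NumericVector tc = env["tc"];
  e.tc = std::vector<double>(tc.begin(), tc.end());
  e.depth = as<double>(env["depth"]);
  e.width = as<double>(env["width"]);
  e.depth_d = as<double>(env["depth_dorsal"]);
  e.side = as<int>(env["side"]);
  return e;
}

// Threshold-switch oscillator:
//   tau_u dK/dt = Ma_eff - K,   Ma_eff = Ma (1 - eps(t, Ma))
//   tau_m dMa/dt = Mt - Ma,     Mt = mt * M0, mt in {+1,-1}
//   P = K + b dK/dt; mt flips +->- when P crosses +Pth upward and
//   -->+ when P crosses -Pth downward (hysteretic, no chattering).
// Ma is integrated exactly between switches (its ODE is linear and
// independent of K), so the scheme remains stable as tau_m -> 0; K is
// advanced with classical RK4 against the analytic Ma(t).
// [[Rcpp::export]]
List sim_threshold_cpp(double tau_u, double tau_m, double M0, double b,
                       double Pth, double duration, double dt,
                       double K0, double Ma0, int mt0,
                       List env, int thin) {
  Envelope E = make_env(env);
  const long nstep = (long)std::ceil(duration / dt);
  const long nout = nstep / thin + 1;

  NumericVector out_t(nout), out_K(nout), out_Kdot(nout), out_Ma(nout),
      out_Mt(nout);
  std::vector<double> ev_t;
  std::vector<int> ev_sign;

  double K = K0, Ma_a = Ma0; // Ma anchor value at t_a
  double t_a = 0.0;          // anchor time (last switch or t=0)
  int mt = (mt0 >= 0) ? 1 : -1;
  bool finite_ok = true;

  // analytic Ma(t) on current branch
  const bool inst = (tau_m <= 0.0);
  #define MA_AT(tt) (inst ? (double)mt * M0 \
    : (double)mt * M0 + (Ma_a - (double)mt * M0) * std::exp(-((tt) - t_a) / tau_m))

  #define KDOT(tt, KK, MAA) ((MAA * (1.0 - E.eps((tt), (MAA))) - (KK)) / tau_u)

  // one RK4 substep for K over [t0, t0+h], Ma analytic
  #define RK4K(t0, h, KK) do {                               \
    double m1 = MA_AT(t0), m2 = MA_AT((t0) + 0.5 * (h)), m4 = MA_AT((t0) + (h)); \
    double k1 = KDOT((t0), (KK), m1);                        \
    double k2 = KDOT((t0) + 0.5 * (h), (KK) + 0.5 * (h) * k1, m2); \
    double k3 = KDOT((t0) + 0.5 * (h), (KK) + 0.5 * (h) * k2, m2); \
    double k4 = KDOT((t0) + (h), (KK) + (h) * k3, m4);       \
    (KK) += (h) / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);     \
  } while (0)

  double t = 0.0;
  double Ma_now = MA_AT(0.0);
  double P_prev = K + b * KDOT(0.0, K, Ma_now);
  long iout = 0;
  out_t[0] = 0.0; out_K[0] = K; out_Ma[0] = Ma_now;
  out_Kdot[0] = KDOT(0.0, K, Ma_now); out_Mt[0] = mt * M0;
  ++iout;

  for (long i = 1; i <= nstep; ++i) {
    double t_prev = t;
    double K_prev = K;
    t = i * dt;

    RK4K(t_prev, dt, K);
    Ma_now = MA_AT(t);
    double P_new = K + b * KDOT(t, K, Ma_now);

    bool crossed = false;
    double thr = 0.0;
    if (mt == 1 && P_prev < Pth && P_new >= Pth) { crossed = true; thr = Pth; }
    else if (mt == -1 && P_prev > -Pth && P_new <= -Pth) { crossed = true; thr = -Pth; }

    if (crossed && P_new != P_prev) {
      double theta = (thr - P_prev) / (P_new - P_prev);
      if (theta < 0.0) theta = 0.0;
      if (theta > 1.0) theta = 1.0;
      double t_ev = t_prev + theta * dt;
      // redo the step: old branch up to the event, then flip
      K = K_prev;
      if (theta > 0.0) RK4K(t_prev, theta * dt, K);
      double Ma_ev = MA_AT(t_ev);
      mt = -mt;
      t_a = t_ev;
      Ma_a = Ma_ev;
      if (theta < 1.0) RK4K(t_ev, (1.0 - theta) * dt, K);
      Ma_now = MA_AT(t);
      P_new = K + b * KDOT(t, K, Ma_now);
      ev_t.push_back(t_ev);
      ev_sign.push_back(mt);
    }
    P_prev = P_new;

    if (!std::isfinite(K) || !std::isfinite(Ma_now)) { finite_ok = false; break; }

    if (i % thin == 0 && iout < nout) {
      out_t[iout] = t; out_K[iout] = K; out_Ma[iout] = Ma_now;
      out_Kdot[iout] = KDOT(t, K, Ma_now); out_Mt[iout] = mt * M0;
      ++iout;
    }
  }
  #undef MA_AT
  #undef KDOT
  #undef RK4K

  if (iout < nout) {
    out_t = head(out_t, iout); out_K = head(out_K, iout);
    out_Kdot = head(out_Kdot, iout); out_Ma = head(out_Ma, iout);
    out_Mt = head(out_Mt, iout);
  }
  return List::create(_["t"] = out_t, _["K"] = out_K, _["Kdot"] = out_Kdot,
                      _["Ma"] = out_Ma, _["Mt"] = out_Mt,
                      _["ev_t"] = wrap(ev_t), _["ev_sign"] = wrap(ev_sign),
                      _["ok"] = finite_ok);
}

// Alternative oscillators under the shared perturbation interface.
// kind: 0 van der Pol, 1 Rayleigh, 2 Stuart-Landau.
// Perturbation: extra contraction toward the origin, -gain*eps(t)*state,
// applied to both state components (radial contraction for Stuart-Landau).
// Events recorded: upward (+1) and downward (-1) zero crossings of x.
// [[Rcpp::export]]
List sim_alt_cpp(int kind, double mu, double lambda, double omega,
                 double duration, double dt, double x0, double y0,
                 double gain, List env, int thin) {
  Envelope E = make_env(env);
  const long nstep = (long)std::ceil(duration / dt);
  const long nout = nstep / thin + 1;

  NumericVector out_t(nout), out_x(nout), out_y(nout);
  std::vector<double> ev_t;
  std::vector<int> ev_sign;

  double x = x0, y = y0;
  bool finite_ok = true;

  struct Deriv {
    int kind; double mu, lambda, omega, gain;
    const Envelope* E;
    void operator()(double t, double x, double y, double& dx, double& dy) const {
      // side gating keys on x (the bending-like variable) for one-sided pulses
      double e = E->eps(t, x);
      if (kind == 0) {            // van der Pol: suppress the active
        dx = y;                   // (velocity-dependent) drive
        dy = mu * (1.0 - x * x) * y * (1.0 - e) - x;
      } else if (kind == 1) {     // Rayleigh: suppress the active drive
        dx = y;
        dy = mu * (1.0 - y * y) * y * (1.0 - e) - x;
      } else {                    // Stuart-Landau: radial contraction
        double r2 = x * x + y * y;
        dx = (lambda - r2) * x - omega * y - gain * e * x;
        dy = omega * x + (lambda - r2) * y - gain * e * y;
      }
    }
  } f = {kind, mu, lambda, omega, gain, &E};

  double t = 0.0;
  long iout = 0;
  out_t[0] = 0.0; out_x[0] = x; out_y[0] = y; ++iout;

  for (long i = 1; i <= nstep; ++i) {
    double t_prev = t, x_prev = x;
    t = i * dt;
    double k1x, k1y, k2x, k2y, k3x, k3y, k4x, k4y;
    f(t_prev, x, y, k1x, k1y);
    f(t_prev + 0.5 * dt, x + 0.5 * dt * k1x, y + 0.5 * dt * k1y, k2x, k2y);
    f(t_prev + 0.5 * dt, x + 0.5 * dt * k2x, y + 0.5 * dt * k2y, k3x, k3y);
    f(t_prev + dt, x + dt * k3x, y + dt * k3y, k4x, k4y);
    x += dt / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
    y += dt / 6.0 * (k1y + 2.0 * k2y + 2.0 * k3y + k4y);

    if (!std::isfinite(x) || !std::isfinite(y)) { finite_ok = false; break; }

    if (x_prev < 0.0 && x >= 0.0) {
      ev_t.push_back(t_prev + dt * (-x_prev) / (x - x_prev));
      ev_sign.push_back(1);
    } else if (x_prev > 0.0 && x <= 0.0) {
      ev_t.push_back(t_prev + dt * (x_prev) / (x_prev - x));
      ev_sign.push_back(-1);
    }

    if (i % thin == 0 && iout < nout) {
      out_t[iout] = t; out_x[iout] = x; out_y[iout] = y; ++iout;
    }
  }

  if (iout < nout) {
    out_t = head(out_t, iout); out_x = head(out_x, iout); out_y = head(out_y, iout);
  }
  return List::create(_["t"] = out_t, _["x"] = out_x, _["y"] = out_y,
                      _["ev_t"] = wrap(ev_t), _["ev_sign"] = wrap(ev_sign),
                      _["ok"] = finite_ok);
}
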