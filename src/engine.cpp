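// Fixed-step engine for small spiking networks: Izhikevich neurons,
// Tsodyks-Markram synapses, delay-aware trace-based multiplicative STDP —
// plus the closed-loop animat (differential-drive robot in a 2D arena).
// All event times live on the dt grid; axonal delays are integer step counts.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double clip01(double w) {
  if (w < 0.0) return 0.0;
  if (w > 1.0) return 1.0;
  return w;
}

struct StimChannel {
  int neuron;              // 0-based
  double amp;
  long long period, width, phase, on, off; // in steps, global clock
};

// Per-step order (one step advances t by dt):
//   1. exponential decay of STDP traces and TM variables
//   2. deliver queued spike arrivals: facilitation + transmitter release
//   3. currents (stimulus pulses, Gaussian noise, bias, synaptic g*w*y)
//   4. Euler update of v,u; threshold/reset detection
//   5. potentiation (post spike consumes delayed presynaptic trace)
//   6. depression (pre arrival consumes postsynaptic trace)
//   7. trace increments (after the updates that consume them, so a spike
//      never pairs with itself) and enqueue of outgoing arrivals
// Potentiation strictly before depression on same-step coincidences.
class Engine {
public:
  int n_neu, n_syn, Q;
  double dt;
  // neuron state + parameters
  std::vector<double> v, u, s_post, a, b, cr, d, bias, Dv;
  // synapse state + topology
  std::vector<double> w, x, y, uf, s_pre, gsyn;
  std::vector<int> pre, post, delay, plastic;
  std::vector<std::vector<int> > in_syn, out_syn, ring;
  // shared parameters
  double tau_S, lambda, alpha, U, noise_scale;
  double fS, fI, frec1, ffac;
  bool plastic_on, record_spikes;
  // logs
  std::vector<int> spike_id, spike_count;
  std::vector<double> spike_t;
  std::vector<int> fired, arrived;
  std::vector<double> Iext, Isyn;
  std::vector<StimChannel> stim;

  void init(List state, List topo, List pars, double dt_) {
    dt = dt_;
    v = as<std::vector<double> >(state["v"]);
    u = as<std::vector<double> >(state["u"]);
    s_post = as<std::vector<double> >(state["s_post"]);
    n_neu = (int)v.size();
    w = as<std::vector<double> >(state["w"]);
    x = as<std::vector<double> >(state["x"]);
    y = as<std::vector<double> >(state["y"]);
    uf = as<std::vector<double> >(state["uf"]);
    s_pre = as<std::vector<double> >(state["s_pre"]);
    pre = as<std::vector<int> >(topo["pre"]);
    post = as<std::vector<int> >(topo["post"]);
    gsyn = as<std::vector<double> >(topo["g"]);
    delay = as<std::vector<int> >(topo["delay_steps"]);
    plastic = as<std::vector<int> >(topo["plastic"]);
    n_syn = (int)pre.size();
    a = as<std::vector<double> >(pars["a"]);
    b = as<std::vector<double> >(pars["b"]);
    cr = as<std::vector<double> >(pars["c"]);
    d = as<std::vector<double> >(pars["d"]);
    bias = as<std::vector<double> >(pars["bias"]);
    Dv = as<std::vector<double> >(pars["D"]);
    double tau_I = as<double>(pars["tau_I"]);
    double tau_rec = as<double>(pars["tau_rec"]);
    double tau_facil = as<double>(pars["tau_facil"]);
    tau_S = as<double>(pars["tau_S"]);
    lambda = as<double>(pars["lambda"]);
    alpha = as<double>(pars["alpha"]);
    U = as<double>(pars["U"]);
    noise_scale = as<double>(pars["noise_scale"]);
    fS = std::exp(-dt / tau_S);
    fI = std::exp(-dt / tau_I);
    frec1 = 1.0 - std::exp(-dt / tau_rec);
    ffac = std::exp(-dt / tau_facil);
    in_syn.assign(n_neu, std::vector<int>());
    out_syn.assign(n_neu, std::vector<int>());
    int max_delay = 1;
    for (int s = 0; s < n_syn; ++s) {
      if (pre[s] < 0 || pre[s] >= n_neu || post[s] < 0 || post[s] >= n_neu)
        stop("synapse %d references a non-existent neuron", s + 1);
      if (delay[s] < 1) stop("synapse %d: delay must be at least one step", s + 1);
      if (delay[s] > max_delay) max_delay = delay[s];
      in_syn[post[s]].push_back(s);
      out_syn[pre[s]].push_back(s);
    }
    Q = max_delay + 1;
    ring.assign(Q, std::vector<int>(n_syn, 0));
    NumericMatrix pending = as<NumericMatrix>(state["pending"]);
    for (int r = 0; r < pending.nrow(); ++r) {
      int rel = (int)pending(r, 0), s = (int)pending(r, 1) - 1,
          cnt = (int)pending(r, 2);
      if (rel < 0 || rel >= Q) stop("pending arrival outside the delay horizon");
      ring[rel % Q][s] += cnt;
    }
    spike_count.assign(n_neu, 0);
    fired.assign(n_neu, 0);
    arrived.assign(n_syn, 0);
    Iext.assign(n_neu, 0.0);
    Isyn.assign(n_neu, 0.0);
  }

  void set_stim(NumericMatrix m) {
    stim.clear();
    for (int ch = 0; ch < m.nrow(); ++ch) {
      StimChannel c;
      c.neuron = (int)m(ch, 0);
      c.amp = m(ch, 1);
      c.period = (long long)m(ch, 2);
      c.width = (long long)m(ch, 3);
      c.phase = (long long)m(ch, 4);
      c.on = (long long)m(ch, 5);
      c.off = (long long)m(ch, 6);
      if (c.period <= 0) stop("stimulus channel: period must be positive");
      if (c.neuron < 0 || c.neuron >= n_neu)
        stop("stimulus channel targets a non-existent neuron");
      stim.push_back(c);
    }
  }

  // one step at global step index kg (ring slot derived from kg)
  void step(long long kg) {
    for (int i = 0; i < n_neu; ++i) s_post[i] *= fS;
    for (int s = 0; s < n_syn; ++s) {
      s_pre[s] *= fS;
      double yn = y[s] * fI;
      double z = 1.0 - x[s] - yn;        // inactive pool after y decay
      x[s] += z * frec1;                 // recovery from depression
      y[s] = yn;
      uf[s] = U + (uf[s] - U) * ffac;    // facilitation decays to baseline
    }
    const int slot = (int)(kg % (long long)Q);
    for (int s = 0; s < n_syn; ++s) {
      int m = ring[slot][s];
      arrived[s] = m;
      if (m > 0) {
        ring[slot][s] = 0;
        for (int q = 0; q < m; ++q) {
          uf[s] += U * (1.0 - uf[s]);
          double rel = uf[s] * x[s];
          y[s] += rel;
          x[s] -= rel;
        }
      }
    }
    for (int i = 0; i < n_neu; ++i) {
      double In = 0.0;
      if (Dv[i] > 0.0) In = norm_rand() * std::sqrt(Dv[i] * noise_scale);
      Iext[i] = In + bias[i];
      Isyn[i] = 0.0;
    }
    for (size_t ch = 0; ch < stim.size(); ++ch) {
      const StimChannel& c = stim[ch];
      if (kg < c.on || kg >= c.off || kg < c.phase) continue;
      if ((kg - c.phase) % c.period < c.width) Iext[c.neuron] += c.amp;
    }
    for (int s = 0; s < n_syn; ++s)
      Isyn[post[s]] += gsyn[s] * w[s] * y[s];
    for (int i = 0; i < n_neu; ++i) {
      double I = Iext[i] + Isyn[i];
      double vn = v[i] + dt * (0.04 * v[i] * v[i] + 5.0 * v[i] + 140.0 - u[i] + I);
      double un = u[i] + dt * a[i] * (b[i] * vn - u[i]);
      if (!std::isfinite(vn) || !std::isfinite(un))
        stop("non-finite state in neuron %d at t = %.4f ms", i + 1,
             (double)(kg + 1) * dt);
      if (vn >= 30.0) {
        fired[i] = 1;
        v[i] = cr[i];
        u[i] = un + d[i];
        spike_count[i]++;
        if (record_spikes) {
          spike_id.push_back(i + 1);
          spike_t.push_back((double)(kg + 1) * dt);
        }
      } else {
        fired[i] = 0;
        v[i] = vn;
        u[i] = un;
      }
    }
    if (plastic_on) {
      for (int i = 0; i < n_neu; ++i) {
        if (!fired[i]) continue;
        const std::vector<int>& in = in_syn[i];
        for (size_t q = 0; q < in.size(); ++q) {
          int s = in[q];
          if (plastic[s]) w[s] = clip01(w[s] + lambda * (1.0 - w[s]) * s_pre[s]);
        }
      }
      for (int s = 0; s < n_syn; ++s) {
        if (!arrived[s] || !plastic[s]) continue;
        for (int q = 0; q < arrived[s]; ++q)
          w[s] = clip01(w[s] - lambda * alpha * w[s] * s_post[post[s]]);
      }
    }
    for (int s = 0; s < n_syn; ++s)
      if (arrived[s]) s_pre[s] += (double)arrived[s];
    for (int i = 0; i < n_neu; ++i) {
      if (!fired[i]) continue;
      s_post[i] += 1.0;
      const std::vector<int>& out = out_syn[i];
      for (size_t q = 0; q < out.size(); ++q) {
        int s = out[q];
        ring[(int)((kg + (long long)delay[s]) % (long long)Q)][s] += 1;
      }
    }
  }

  // export pending arrivals relative to step `now`
  NumericMatrix export_pending(long long now) {
    std::vector<int> p_rel, p_syn, p_cnt;
    for (int rel = 0; rel < Q; ++rel) {
      int slot2 = (int)((now + (long long)rel) % (long long)Q);
      for (int s = 0; s < n_syn; ++s)
        if (ring[slot2][s] > 0) {
          p_rel.push_back(rel);
          p_syn.push_back(s + 1);
          p_cnt.push_back(ring[slot2][s]);
        }
    }
    NumericMatrix out((int)p_rel.size(), 3);
    for (size_t r = 0; r < p_rel.size(); ++r) {
      out(r, 0) = p_rel[r];
      out(r, 1) = p_syn[r];
      out(r, 2) = p_cnt[r];
    }
    return out;
  }

  List export_state(long long now) {
    return List::create(
      _["v"] = v, _["u"] = u, _["s_post"] = s_post,
      _["w"] = w, _["x"] = x, _["y"] = y, _["uf"] = uf, _["s_pre"] = s_pre,
      _["pending"] = export_pending(now));
  }
};

// [[Rcpp::export]]
List engine_run_cpp(List state, List topo, List pars, NumericMatrix stim,
                    int n_steps, double dt, double t0_step_d,
                    bool plastic_on, int sample_every, bool record_spikes) {
  Engine e;
  e.init(state, topo, pars, dt);
  e.plastic_on = plastic_on;
  e.record_spikes = record_spikes;
  e.set_stim(stim);
  const long long t0_step = (long long)std::llround(t0_step_d);
  std::vector<double> wlog_t, wlog_w;
  for (int k = 0; k < n_steps; ++k) {
    const long long kg = t0_step + k;
    e.step(kg);
    if (sample_every > 0 && ((k + 1) % sample_every) == 0) {
      wlog_t.push_back((double)(kg + 1) * dt);
      for (int s = 0; s < e.n_syn; ++s) wlog_w.push_back(e.w[s]);
    }
  }
  int n_samp = (int)wlog_t.size();
  NumericMatrix wmat(n_samp, e.n_syn);
  for (int r = 0; r < n_samp; ++r)
    for (int s = 0; s < e.n_syn; ++s) wmat(r, s) = wlog_w[(size_t)r * e.n_syn + s];
  List out = e.export_state(t0_step + n_steps);
  out["spike_id"] = e.spike_id;
  out["spike_t"] = e.spike_t;
  out["spike_count"] = e.spike_count;
  out["wlog_t"] = wlog_t;
  out["wlog_w"] = wmat;
  out["t0_step_new"] = (double)(t0_step + n_steps);
  return out;
}

// Replays a single plastic synapse through the same per-step trace logic the
// engine uses, from explicit presynaptic *arrival* steps and postsynaptic
// spike steps. Used to test the trace formulation against the closed-form
// all-pairs rule.
// [[Rcpp::export]]
double stdp_replay_cpp(IntegerVector arrival_steps, IntegerVector post_steps,
                       double w0, double dt, double tau_S, double lambda,
                       double alpha) {
  const double fS = std::exp(-dt / tau_S);
  int n_steps = 0;
  for (int i = 0; i < arrival_steps.size(); ++i)
    if (arrival_steps[i] + 1 > n_steps) n_steps = arrival_steps[i] + 1;
  for (int i = 0; i < post_steps.size(); ++i)
    if (post_steps[i] + 1 > n_steps) n_steps = post_steps[i] + 1;
  std::vector<int> arr(n_steps, 0), po(n_steps, 0);
  for (int i = 0; i < arrival_steps.size(); ++i) arr[arrival_steps[i]]++;
  for (int i = 0; i < post_steps.size(); ++i) po[post_steps[i]]++;
  double s_pre = 0.0, s_post = 0.0, w = w0;
  for (int k = 0; k < n_steps; ++k) {
    s_pre *= fS;
    s_post *= fS;
    for (int q = 0; q < po[k]; ++q) w = clip01(w + lambda * (1.0 - w) * s_pre);
    for (int q = 0; q < arr[k]; ++q) w = clip01(w - lambda * alpha * w * s_post);
    s_pre += arr[k];
    s_post += po[k];
  }
  return w;
}

// ---------------------------------------------------------------------------
// 2D geometry for the animat

static inline double wrap_pi(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a <= -M_PI) a += 2.0 * M_PI;
  return a;
}

// distance from p along direction (dx,dy) to segment (x1,y1)-(x2,y2); Inf if missed
static double ray_seg(double px, double py, double dx, double dy,
                      double x1, double y1, double x2, double y2) {
  double ex = x2 - x1, ey = y2 - y1;
  double den = dx * ey - dy * ex;
  if (std::fabs(den) < 1e-12) return R_PosInf;
  double t = ((x1 - px) * ey - (y1 - py) * ex) / den; // along ray
  double s = ((x1 - px) * dy - (y1 - py) * dx) / den; // along segment
  if (t >= 0.0 && s >= 0.0 && s <= 1.0) return t;
  return R_PosInf;
}

static void closest_on_seg(double px, double py, double x1, double y1,
                           double x2, double y2, double* cx, double* cy) {
  double ex = x2 - x1, ey = y2 - y1;
  double L2 = ex * ex + ey * ey;
  double t = L2 > 0 ? ((px - x1) * ex + (py - y1) * ey) / L2 : 0.0;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  *cx = x1 + t * ex;
  *cy = y1 + t * ey;
}

struct SenseOut { bool sonarL, sonarR, touchL, touchR; double dmin; };

static SenseOut do_sense(double x, double y, double th, double radius,
                         const NumericMatrix& segs, double sonar_range,
                         double mount, double half_angle, int n_rays,
                         double touch_tol) {
  SenseOut o;
  o.sonarL = o.sonarR = o.touchL = o.touchR = false;
  o.dmin = R_PosInf;
  for (int side = 0; side < 2; ++side) {
    double centre = th + (side == 0 ? mount : -mount);
    bool hit = false;
    for (int r = 0; r < n_rays && !hit; ++r) {
      double ang = centre + (n_rays > 1
                     ? -half_angle + 2.0 * half_angle * r / (n_rays - 1) : 0.0);
      double dx = std::cos(ang), dy = std::sin(ang);
      for (int sgi = 0; sgi < segs.nrow(); ++sgi) {
        double dd = ray_seg(x, y, dx, dy, segs(sgi, 0), segs(sgi, 1),
                            segs(sgi, 2), segs(sgi, 3));
        if (R_finite(dd) && dd - radius <= sonar_range) { hit = true; break; }
      }
    }
    if (side == 0) o.sonarL = hit; else o.sonarR = hit;
  }
  for (int sgi = 0; sgi < segs.nrow(); ++sgi) {
    double cx, cy;
    closest_on_seg(x, y, segs(sgi, 0), segs(sgi, 1), segs(sgi, 2), segs(sgi, 3),
                   &cx, &cy);
    double dd = std::hypot(cx - x, cy - y);
    if (dd < o.dmin) o.dmin = dd;
    if (dd <= radius + touch_tol) {
      // front-mounted bumper: only contacts in the front half register
      double rel = wrap_pi(std::atan2(cy - y, cx - x) - th);
      if (rel >= 0.0 && rel <= M_PI_2) o.touchL = true;
      else if (rel < 0.0 && rel >= -M_PI_2) o.touchR = true;
    }
  }
  return o;
}

static int do_resolve(double* x, double* y, double radius,
                      const NumericMatrix& segs) {
  int contact = 0;
  for (int it = 0; it < 4; ++it) {
    double best = R_PosInf, bx = 0, by = 0;
    for (int sgi = 0; sgi < segs.nrow(); ++sgi) {
      double cx, cy;
      closest_on_seg(*x, *y, segs(sgi, 0), segs(sgi, 1), segs(sgi, 2),
                     segs(sgi, 3), &cx, &cy);
      double dd = std::hypot(cx - *x, cy - *y);
      if (dd < best) { best = dd; bx = cx; by = cy; }
    }
    if (best >= radius || !R_finite(best)) break;
    contact = 1;
    if (best < 1e-9) break; // degenerate: centre on the edge
    double nx = (*x - bx) / best, ny = (*y - by) / best;
    *x = bx + nx * radius;
    *y = by + ny * radius;
  }
  return contact;
}

// Sonar cones (ray-cast fans) and bumper contact for a circular robot.
// segs: rows (x1,y1,x2,y2) of obstacle + wall edges.
// [[Rcpp::export]]
List animat_sense_cpp(double x, double y, double th, double radius,
                      NumericMatrix segs, double sonar_range, double mount,
                      double half_angle, int n_rays, double touch_tol) {
  SenseOut o = do_sense(x, y, th, radius, segs, sonar_range, mount,
                        half_angle, n_rays, touch_tol);
  return List::create(_["sonarL"] = o.sonarL, _["sonarR"] = o.sonarR,
                      _["touchL"] = o.touchL, _["touchR"] = o.touchR,
                      _["min_dist"] = o.dmin);
}

// Pushes a penetrating circular robot back to contact distance (the robot
// stops at the obstacle; no physics engine).
// [[Rcpp::export]]
NumericVector animat_resolve_cpp(double x, double y, double radius,
                                 NumericMatrix segs) {
  int contact = do_resolve(&x, &y, radius, segs);
  return NumericVector::create(x, y, (double)contact);
}

// Full closed-loop operant run: per control period, sense -> stimulate ->
// advance the network -> map motoneurons to wheels -> kinematic Euler step
// -> contact resolution. Mirrors the R-level sensors_to_stimuli() /
// motors_from_snn() semantics.
// [[Rcpp::export]]
List operant_loop_cpp(List state, List topo, List pars, double dt,
                      double t0_step_d, NumericMatrix segs,
                      NumericVector robot_pars, NumericVector ctrl_pars,
                      IntegerVector neuron_idx, int n_slices,
                      int swap_at_slice, int wiring_pa,
                      double arena_w, double arena_h) {
  Engine e;
  e.init(state, topo, pars, dt);
  e.plastic_on = true;
  e.record_spikes = false;

  double rx = robot_pars[0], ry = robot_pars[1], rth = robot_pars[2];
  const double radius = robot_pars[3], v_max = robot_pars[4],
               sonar_range = robot_pars[5], mount = robot_pars[6],
               half_angle = robot_pars[7];
  const int n_rays = (int)robot_pars[8];
  const double touch_tol = robot_pars[9];

  const double cp_ms = ctrl_pars[0], amplitude = ctrl_pars[1],
               lag_ms = ctrl_pars[2], period_ms = ctrl_pars[3],
               width_ms = ctrl_pars[4], k_f = ctrl_pars[5],
               k_m = ctrl_pars[6], tau_motor = ctrl_pars[7],
               tau_rate = ctrl_pars[8];
  double rate_f = ctrl_pars[9];
  const int traj_every = (int)ctrl_pars[10];
  const int wsample_every = (int)ctrl_pars[11];

  // neuron indices (0-based): N1, N2, N3, N4, N5, N6, N7
  const int i_n1 = neuron_idx[0], i_n2 = neuron_idx[1], i_n3 = neuron_idx[2],
            i_n4 = neuron_idx[3], i_n5 = neuron_idx[4], i_n6 = neuron_idx[5],
            i_n7 = neuron_idx[6];
  // plastic synapse indices for the weight log: w31, w42, w41, w32
  IntegerVector wsyn = as<IntegerVector>(topo["wlog_syn"]);

  const int cp_steps = (int)std::llround(cp_ms / dt);
  const long long period_steps = (long long)std::llround(period_ms / dt);
  const long long width_steps = (long long)std::llround(width_ms / dt);
  const long long lag_steps = (long long)std::llround(lag_ms / dt);
  long long kg = (long long)std::llround(t0_step_d);

  const double dec_m = std::exp(-cp_ms / tau_motor);
  const double track = 2.0 * radius;
  double drive5 = 0.0, drive6 = 0.0;
  bool prev_touch = false;
  int pa = wiring_pa; // 1 = PA (left sonar -> N1), 0 = DA (left -> N2)

  std::vector<double> traj;    // t,x,y,th,touchL,touchR
  std::vector<double> coll;    // t,x,y,side(1=left,2=right)
  std::vector<int> sonar_on(n_slices, 0);
  std::vector<double> wlog;    // t,w31,w42,w41,w32

  for (int sl = 0; sl < n_slices; ++sl) {
    double t_s = sl * cp_ms / 1000.0;
    if (swap_at_slice >= 0 && sl >= swap_at_slice) { pa = 1 - pa; swap_at_slice = -1; }
    SenseOut o = do_sense(rx, ry, rth, radius, segs, sonar_range, mount,
                          half_angle, n_rays, touch_tol);
    sonar_on[sl] = (o.sonarL || o.sonarR) ? 1 : 0;
    bool touching = o.touchL || o.touchR;
    if (touching && !prev_touch) {
      coll.push_back(t_s); coll.push_back(rx); coll.push_back(ry);
      coll.push_back(o.touchL ? 1.0 : 2.0);
    }
    prev_touch = touching;

    e.stim.clear();
    long long on = kg, off = kg + cp_steps;
    StimChannel c;
    c.amp = amplitude; c.period = period_steps; c.width = width_steps;
    c.on = on; c.off = off;
    if (o.sonarL) { c.neuron = pa ? i_n1 : i_n2; c.phase = 0; e.stim.push_back(c); }
    if (o.sonarR) { c.neuron = pa ? i_n2 : i_n1; c.phase = 0; e.stim.push_back(c); }
    if (o.touchL) { c.neuron = i_n3; c.phase = lag_steps; e.stim.push_back(c); }
    if (o.touchR) { c.neuron = i_n4; c.phase = lag_steps; e.stim.push_back(c); }

    int c5 = e.spike_count[i_n5], c6 = e.spike_count[i_n6],
        c7 = e.spike_count[i_n7];
    for (int k = 0; k < cp_steps; ++k) { e.step(kg); ++kg; }
    c5 = e.spike_count[i_n5] - c5;
    c6 = e.spike_count[i_n6] - c6;
    c7 = e.spike_count[i_n7] - c7;

    drive5 = drive5 * dec_m + c5;
    drive6 = drive6 * dec_m + c6;
    rate_f += (c7 / (cp_ms / 1000.0) - rate_f) * (cp_ms / tau_rate);
    double vfwd = k_f * rate_f;
    double wl = vfwd - k_m * drive6, wr = vfwd - k_m * drive5;
    if (wl > v_max) wl = v_max; if (wl < -v_max) wl = -v_max;
    if (wr > v_max) wr = v_max; if (wr < -v_max) wr = -v_max;
    double vv = 0.5 * (wl + wr), omega = (wr - wl) / track;
    rth = rth + omega * cp_ms / 1000.0;
    rx += vv * std::cos(rth) * cp_ms / 1000.0;
    ry += vv * std::sin(rth) * cp_ms / 1000.0;
    do_resolve(&rx, &ry, radius, segs);
    if (rx < -1e-6 || rx > arena_w + 1e-6 || ry < -1e-6 || ry > arena_h + 1e-6)
      stop("robot escaped the arena at t = %.2f s (x = %.3f, y = %.3f)",
           t_s, rx, ry);
    if ((sl + 1) % traj_every == 0) {
      traj.push_back(t_s); traj.push_back(rx); traj.push_back(ry);
      traj.push_back(rth);
      traj.push_back(o.touchL ? 1.0 : 0.0); traj.push_back(o.touchR ? 1.0 : 0.0);
    }
    if ((sl + 1) % wsample_every == 0) {
      wlog.push_back(t_s + cp_ms / 1000.0);
      for (int q = 0; q < wsyn.size(); ++q) wlog.push_back(e.w[wsyn[q]]);
    }
  }

  int n_traj = (int)traj.size() / 6;
  NumericMatrix tm(n_traj, 6);
  for (int r = 0; r < n_traj; ++r)
    for (int cc = 0; cc < 6; ++cc) tm(r, cc) = traj[(size_t)r * 6 + cc];
  int n_coll = (int)coll.size() / 4;
  NumericMatrix cm(n_coll, 4);
  for (int r = 0; r < n_coll; ++r)
    for (int cc = 0; cc < 4; ++cc) cm(r, cc) = coll[(size_t)r * 4 + cc];
  int n_wl = wsyn.size() > 0 ? (int)wlog.size() / (1 + wsyn.size()) : 0;
  NumericMatrix wm(n_wl, 1 + wsyn.size());
  for (int r = 0; r < n_wl; ++r)
    for (int cc = 0; cc < 1 + wsyn.size(); ++cc)
      wm(r, cc) = wlog[(size_t)r * (1 + wsyn.size()) + cc];

  List out = e.export_state(kg);
  out["spike_count"] = e.spike_count;
  out["t0_step_new"] = (double)kg;
  out["trajectory"] = tm;
  out["collisions"] = cm;
  out["wlog"] = wm;
  out["sonar_on"] = sonar_on;
  out["pose"] = NumericVector::create(rx, ry, rth);
  out["rate_f"] = rate_f;
  out["wiring_pa"] = pa;
  return out;
}
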