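// Simulation core: toroidal arena physics, sensing, neural control, and the
// stuck/release helping dynamics.  All randomness is drawn from R's RNG so
// that set.seed() at the R level makes every run reproducible.
//
// Draw order per evaluation (fixed contract, relied upon by tests):
//   1. robot 0 placement: x, y, heading (3 uniforms)
//   2. robot 1 placement: x, y, heading, redrawn until the minimum initial
//      separation holds (3 uniforms per attempt)
//   3. each food source in index order: x, y, redrawn while within eating
//      distance of a robot (2 uniforms per attempt)
//   4. per step: eating respawns in (robot, food) order as they occur, then
//      one uniform per robot (index order) for the stuck/release event.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

struct Config {
  double side;        // arena side (m), toroidal
  double robot_r;     // robot radius (m)
  double food_r;      // food radius (m)
  int    n_food;
  double dt;          // step duration (s)
  double vmax;        // max wheel speed (m/s)
  double p_stuck;     // per-step stuck-onset probability
  double p_release;   // per-step self-release probability
  double help_mult;   // hazard multiplier while partner close
  double help_gap;    // edge-to-edge helping distance (m)
  double prox_range;  // proximity sensor range beyond the body (m)
};

static Config parse_config(List cfg) {
  Config c;
  c.side       = as<double>(cfg["arena_side"]);
  c.robot_r    = as<double>(cfg["robot_diameter"]) / 2.0;
  c.food_r     = as<double>(cfg["food_diameter"]) / 2.0;
  c.n_food     = as<int>(cfg["n_food"]);
  c.dt         = as<double>(cfg["dt"]);
  c.vmax       = as<double>(cfg["wheel_vmax"]) / 100.0; // cm/s -> m/s
  c.p_stuck    = as<double>(cfg["p_stuck"]);
  c.p_release  = as<double>(cfg["p_self_release"]);
  c.help_mult  = as<double>(cfg["help_multiplier"]);
  c.help_gap   = as<double>(cfg["help_gap"]);
  c.prox_range = as<double>(cfg["prox_range"]);
  return c;
}

// shortest-wrap displacement component on the torus, in [-side/2, side/2)
static inline double wrap_delta(double d, double side) {
  d -= side * std::floor(d / side + 0.5);
  return d;
}

static inline double wrap_pos(double x, double side) {
  x -= side * std::floor(x / side);
  return x;
}

static inline double wrap_angle(double a) { // to (-pi, pi]
  a -= TWO_PI * std::floor(a / TWO_PI + 0.5);
  return a;
}

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Feed-forward controller.  Weight layout (genome decode order):
//   [0 .. 18*9-1]    input->hidden, hidden-major: w[j*18 + i], i = 0 bias,
//                    1..8 proximity, 9..17 camera
//   [162 .. 170]     (memory topology only) memory-input weight of hidden j
//   [off .. off+19]  hidden->output, output-major: w[off + o*10 + k],
//                    k = 0..8 hidden, k = 9 output bias
struct Net {
  const double* w;
  bool has_memory;
  int off; // start of hidden->output block
  Net(const double* w_, bool mem) : w(w_), has_memory(mem) {
    off = mem ? 171 : 162;
  }
  // sensors: 17 values; mem: memory activation (ignored unless has_memory)
  // out: two wheel velocities in m/s
  void activate(const double* sensors, double mem, double vmax,
                double* out) const {
    double h[9];
    for (int j = 0; j < 9; ++j) {
      const double* wj = w + j * 18;
      double s = wj[0]; // bias input = 1
      for (int i = 0; i < 17; ++i) s += wj[1 + i] * sensors[i];
      if (has_memory) s += w[162 + j] * mem;
      h[j] = sigmoid(s);
    }
    for (int o = 0; o < 2; ++o) {
      const double* wo = w + off + o * 10;
      double s = wo[9]; // hidden-layer bias
      for (int k = 0; k < 9; ++k) s += wo[k] * h[k];
      out[o] = -vmax + sigmoid(s) * 2.0 * vmax;
    }
  }
};

struct World {
  Config c;
  double x[2], y[2], th[2];
  bool stuck[2];
  std::vector<double> fx, fy;
  int food_count[2];
  long mem_opp[2], mem_help[2]; // completed stuck episodes / helped ones
  int helping_given[2];
  int episode_start[2];
  // episode logs: start, end, helped per robot
  std::vector<int> ep_start[2], ep_end[2], ep_helped[2];

  World(const Config& cfg) : c(cfg), fx(cfg.n_food), fy(cfg.n_food) {
    for (int i = 0; i < 2; ++i) {
      stuck[i] = false; food_count[i] = 0;
      mem_opp[i] = 0; mem_help[i] = 0; helping_given[i] = 0;
      episode_start[i] = -1;
    }
  }

  double memory_activation(int i) const {
    return mem_opp[i] == 0 ? 1.0 : (double)mem_help[i] / (double)mem_opp[i];
  }

  bool food_clear(double px, double py) const {
    double eat = c.robot_r + c.food_r;
    for (int i = 0; i < 2; ++i) {
      double dx = wrap_delta(px - x[i], c.side);
      double dy = wrap_delta(py - y[i], c.side);
      if (dx * dx + dy * dy < eat * eat) return false;
    }
    return true;
  }

  void respawn_food(int k) {
    for (int tries = 0; tries < 10000; ++tries) {
      double px = unif_rand() * c.side, py = unif_rand() * c.side;
      if (food_clear(px, py)) { fx[k] = px; fy[k] = py; return; }
    }
    stop("food placement failed");
  }

  void place(double min_center_sep) {
    x[0] = unif_rand() * c.side; y[0] = unif_rand() * c.side;
    th[0] = unif_rand() * TWO_PI;
    int tries = 0;
    for (;;) {
      x[1] = unif_rand() * c.side; y[1] = unif_rand() * c.side;
      th[1] = unif_rand() * TWO_PI;
      double dx = wrap_delta(x[1] - x[0], c.side);
      double dy = wrap_delta(y[1] - y[0], c.side);
      if (std::sqrt(dx * dx + dy * dy) >= min_center_sep) break;
      if (++tries > 1000) stop("robot placement failed");
    }
    for (int k = 0; k < c.n_food; ++k) respawn_food(k);
  }

  // partner geometry relative to robot i
  void partner_delta(int i, double& dx, double& dy, double& dist) const {
    int j = 1 - i;
    dx = wrap_delta(x[j] - x[i], c.side);
    dy = wrap_delta(y[j] - y[i], c.side);
    dist = std::sqrt(dx * dx + dy * dy);
  }

  bool partner_close(int i) const {
    double dx, dy, d; partner_delta(i, dx, dy, d);
    return d < 2.0 * c.robot_r + c.help_gap;
  }

  // 8 proximity activations: sensor k faces heading + k*45deg; the sensor
  // whose facing is nearest the partner's bearing responds linearly in the
  // edge-to-edge gap, saturating at contact.  Only the partner is solid.
  void sense_proximity(int i, bool partner_vis, double* out) const {
    for (int k = 0; k < 8; ++k) out[k] = 0.0;
    if (!partner_vis) return;
    double dx, dy, d; partner_delta(i, dx, dy, d);
    double gap = d - 2.0 * c.robot_r;
    if (gap >= c.prox_range) return;
    double bearing = wrap_angle(std::atan2(dy, dx) - th[i]);
    int k = (int)std::floor(bearing / (TWO_PI / 8.0) + 0.5);
    k = ((k % 8) + 8) % 8;
    double g = gap > 0.0 ? gap : 0.0;
    out[k] = 1.0 - g / c.prox_range;
  }

  // 9 camera activations for a 60 degree forward cone split into three 20
  // degree sectors; order: color-major (red, green, blue) x sector
  // (from -30deg to +30deg).  Food renders red; the partner renders green
  // when mobile, blue when stuck.  Nearest object occludes; activation is
  // the fraction of the sector's angular width covered by the color.
  void sense_camera(int i, bool partner_vis, double* out) const {
    const double cone = M_PI / 6.0;       // half-width, 30 deg
    const double sec_w = M_PI / 9.0;      // 20 deg
    for (int k = 0; k < 9; ++k) out[k] = 0.0;

    // objects: up to partner + foods; color 0=red 1=green 2=blue
    const int MAXOBJ = 15;
    if (c.n_food + 1 > MAXOBJ) stop("too many food sources for the camera");
    double olo[MAXOBJ], ohi[MAXOBJ], odist[MAXOBJ];
    int ocol[MAXOBJ], nobj = 0;
    if (partner_vis) {
      double dx, dy, d; partner_delta(i, dx, dy, d);
      double a = d <= c.robot_r ? M_PI / 2.0 : std::asin(c.robot_r / d);
      double b = wrap_angle(std::atan2(dy, dx) - th[i]);
      olo[nobj] = b - a; ohi[nobj] = b + a; odist[nobj] = d;
      ocol[nobj] = stuck[1 - i] ? 2 : 1; ++nobj;
    }
    for (int k = 0; k < c.n_food; ++k) {
      double dx = wrap_delta(fx[k] - x[i], c.side);
      double dy = wrap_delta(fy[k] - y[i], c.side);
      double d = std::sqrt(dx * dx + dy * dy);
      double a = d <= c.food_r ? M_PI / 2.0 : std::asin(c.food_r / d);
      double b = wrap_angle(std::atan2(dy, dx) - th[i]);
      olo[nobj] = b - a; ohi[nobj] = b + a; odist[nobj] = d;
      ocol[nobj] = 0; ++nobj;
    }
    // sort near -> far (tiny n: insertion sort)
    for (int a = 1; a < nobj; ++a)
      for (int b = a; b > 0 && odist[b] < odist[b - 1]; --b) {
        std::swap(olo[b], olo[b - 1]); std::swap(ohi[b], ohi[b - 1]);
        std::swap(odist[b], odist[b - 1]); std::swap(ocol[b], ocol[b - 1]);
      }

    // disjoint occupied intervals claimed by nearer objects
    double qlo[MAXOBJ], qhi[MAXOBJ];
    int nocc = 0;
    for (int ob = 0; ob < nobj; ++ob) {
      double lo = olo[ob] > -cone ? olo[ob] : -cone;
      double hi = ohi[ob] <  cone ? ohi[ob] :  cone;
      if (hi <= lo) continue;
      for (int s = 0; s < 3; ++s) {
        double slo = -cone + s * sec_w, shi = slo + sec_w;
        double a = lo > slo ? lo : slo, b = hi < shi ? hi : shi;
        if (b <= a) continue;
        double vis = b - a;
        for (int q = 0; q < nocc; ++q) {
          double qa = a > qlo[q] ? a : qlo[q];
          double qb = b < qhi[q] ? b : qhi[q];
          if (qb > qa) vis -= qb - qa;
        }
        if (vis > 0.0) {
          int idx = ocol[ob] * 3 + s;
          out[idx] += vis / sec_w;
          if (out[idx] > 1.0) out[idx] = 1.0;
        }
      }
      // merge [lo,hi] into the occupied set, keeping entries disjoint
      double mlo = lo, mhi = hi;
      int w = 0;
      for (int q = 0; q < nocc; ++q) {
        if (qhi[q] < mlo || qlo[q] > mhi) {
          qlo[w] = qlo[q]; qhi[w] = qhi[q]; ++w;
        } else {
          if (qlo[q] < mlo) mlo = qlo[q];
          if (qhi[q] > mhi) mhi = qhi[q];
        }
      }
      qlo[w] = mlo; qhi[w] = mhi; nocc = w + 1;
    }
  }

  void sense(int i, bool partner_vis, double* sensors) const {
    sense_proximity(i, partner_vis, sensors);
    sense_camera(i, partner_vis, sensors + 8);
  }

  // differential-drive Euler step; heading updates first, translation uses
  // the new heading.  Stuck robots do not move.
  void move(int i, double vl, double vr) {
    if (stuck[i]) return;
    double v = 0.5 * (vl + vr);
    double w = (vr - vl) / (2.0 * c.robot_r); // axle = robot diameter
    th[i] = wrap_angle(th[i] + w * c.dt);
    x[i] = wrap_pos(x[i] + v * std::cos(th[i]) * c.dt, c.side);
    y[i] = wrap_pos(y[i] + v * std::sin(th[i]) * c.dt, c.side);
  }

  // push overlapping discs apart along the center line; stuck robots anchor.
  void resolve_collision() {
    double dx = wrap_delta(x[1] - x[0], c.side);
    double dy = wrap_delta(y[1] - y[0], c.side);
    double d = std::sqrt(dx * dx + dy * dy);
    double min_d = 2.0 * c.robot_r;
    if (d >= min_d) return;
    double ux, uy;
    if (d > 1e-12) { ux = dx / d; uy = dy / d; }
    else { ux = std::cos(th[0]); uy = std::sin(th[0]); }
    double over = min_d - d;
    if (stuck[0] && stuck[1]) return;
    if (stuck[0]) {
      x[1] = wrap_pos(x[1] + over * ux, c.side);
      y[1] = wrap_pos(y[1] + over * uy, c.side);
    } else if (stuck[1]) {
      x[0] = wrap_pos(x[0] - over * ux, c.side);
      y[0] = wrap_pos(y[0] - over * uy, c.side);
    } else {
      x[0] = wrap_pos(x[0] - 0.5 * over * ux, c.side);
      y[0] = wrap_pos(y[0] - 0.5 * over * uy, c.side);
      x[1] = wrap_pos(x[1] + 0.5 * over * ux, c.side);
      y[1] = wrap_pos(y[1] + 0.5 * over * uy, c.side);
    }
  }

  void eat() {
    double eat_d = c.robot_r + c.food_r;
    for (int i = 0; i < 2; ++i)
      for (int k = 0; k < c.n_food; ++k) {
        double dx = wrap_delta(fx[k] - x[i], c.side);
        double dy = wrap_delta(fy[k] - y[i], c.side);
        if (dx * dx + dy * dy < eat_d * eat_d) {
          ++food_count[i];
          respawn_food(k);
        }
      }
  }

  void end_episode(int i, int step, bool helped) {
    ep_start[i].push_back(episode_start[i]);
    ep_end[i].push_back(step);
    ep_helped[i].push_back(helped ? 1 : 0);
    ++mem_opp[i];
    if (helped) { ++mem_help[i]; ++helping_given[1 - i]; }
    episode_start[i] = -1;
    stuck[i] = false;
  }
};

// mode 0: full evaluation (both robots controlled, stuck dynamics on)
// mode 1: helping assay (robot 1 permanently stuck; released only by help;
//         robot 0 never becomes stuck; run ends at release)
//
// clamp0/clamp1: memory-input clamps (NA = dynamic); used only with memory
// topologies.  partner_invisible: robot 1 contributes nothing to robot 0's
// sensors (chance-level assay).
// [[Rcpp::export]]
List sim_run(NumericVector weights0, NumericVector weights1, bool has_memory,
             List cfg, int steps, int mode, double clamp0, double clamp1,
             bool partner_invisible, bool log_trajectory,
             Nullable<NumericVector> init_state = R_NilValue) {
  Config c = parse_config(cfg);
  int expected = has_memory ? 191 : 182;
  if (weights0.size() != expected || weights1.size() != expected)
    stop("weight vector length does not match topology");

  Net net0(REAL(weights0), has_memory), net1(REAL(weights1), has_memory);
  World w(c);
  RNGScope rng;

  if (init_state.isNotNull()) {
    // c(x0,y0,th0, x1,y1,th1, food x/y pairs...) — fixed layout for tests
    NumericVector st(init_state);
    if ((int)st.size() != 6 + 2 * c.n_food) stop("bad init_state length");
    for (int i = 0; i < 2; ++i) {
      w.x[i] = st[3 * i]; w.y[i] = st[3 * i + 1]; w.th[i] = st[3 * i + 2];
    }
    for (int k = 0; k < c.n_food; ++k) {
      w.fx[k] = st[6 + 2 * k]; w.fy[k] = st[7 + 2 * k];
    }
  } else {
    // assays use a one-diameter edge gap so trials never start pre-docked
    double min_sep = mode == 1 ? 4.0 * c.robot_r : 2.0 * c.robot_r;
    w.place(min_sep);
  }

  if (mode == 1) { w.stuck[1] = true; w.episode_start[1] = 0; }

  int release_step = NA_INTEGER;
  int traj_cols = 13;
  NumericMatrix traj(log_trajectory ? steps : 0, traj_cols);

  double sensors[17], vel0[2] = {0, 0}, vel1[2] = {0, 0};

  int step = 0;
  for (; step < steps; ++step) {
    // 1. sense + think (stuck robots produce no movement; skip their nets)
    if (!w.stuck[0]) {
      w.sense(0, !partner_invisible, sensors);
      double m = ISNAN(clamp0) ? w.memory_activation(0) : clamp0;
      net0.activate(sensors, m, c.vmax, vel0);
    }
    if (!w.stuck[1]) {
      w.sense(1, true, sensors);
      double m = ISNAN(clamp1) ? w.memory_activation(1) : clamp1;
      net1.activate(sensors, m, c.vmax, vel1);
    }
    // 2. move
    if (!w.stuck[0]) w.move(0, vel0[0], vel0[1]);
    if (!w.stuck[1]) w.move(1, vel1[0], vel1[1]);
    // 3. collisions, 4. eating
    w.resolve_collision();
    w.eat();
    // 5. stuck / release events: one uniform per robot per step
    for (int i = 0; i < 2; ++i) {
      double u = unif_rand();
      if (mode == 1) {
        if (i == 0) continue; // focal never sticks in an assay
        bool close = w.partner_close(1);
        if (close && u < c.p_release * c.help_mult) {
          w.end_episode(1, step + 1, true);
          release_step = step + 1;
        }
      } else {
        if (!w.stuck[i]) {
          if (u < c.p_stuck) { w.stuck[i] = true; w.episode_start[i] = step + 1; }
        } else {
          bool close = w.partner_close(i);
          double hz = c.p_release * (close ? c.help_mult : 1.0);
          if (u < hz) w.end_episode(i, step + 1, close);
        }
      }
    }
    if (log_trajectory) {
      traj(step, 0) = step + 1;
      traj(step, 1) = w.x[0]; traj(step, 2) = w.y[0]; traj(step, 3) = w.th[0];
      traj(step, 4) = w.stuck[0] ? 1 : 0;
      traj(step, 5) = w.x[1]; traj(step, 6) = w.y[1]; traj(step, 7) = w.th[1];
      traj(step, 8) = w.stuck[1] ? 1 : 0;
      traj(step, 9) = w.memory_activation(0);
      traj(step, 10) = w.memory_activation(1);
      traj(step, 11) = w.food_count[0];
      traj(step, 12) = w.food_count[1];
    }
    if (mode == 1 && release_step != NA_INTEGER) { ++step; break; }
  }

  List episodes(2);
  for (int i = 0; i < 2; ++i) {
    int n = w.ep_start[i].size();
    bool open = w.episode_start[i] >= 0;
    int m = n + (open ? 1 : 0);
    IntegerVector s(m), e(m), h(m);
    for (int k = 0; k < n; ++k) {
      s[k] = w.ep_start[i][k]; e[k] = w.ep_end[i][k]; h[k] = w.ep_helped[i][k];
    }
    if (open) { s[n] = w.episode_start[i]; e[n] = NA_INTEGER; h[n] = NA_INTEGER; }
    episodes[i] = DataFrame::create(_["start"] = s, _["end"] = e,
                                    _["helped"] = h);
  }

  List out = List::create(
    _["food_counts"] = IntegerVector::create(w.food_count[0], w.food_count[1]),
    _["stuck_episodes"] = episodes,
    _["helping_given"] = IntegerVector::create(w.helping_given[0],
                                               w.helping_given[1]),
    _["memory"] = List::create(
      List::create(_["opportunities"] = (double)w.mem_opp[0],
                   _["helps"] = (double)w.mem_help[0]),
      List::create(_["opportunities"] = (double)w.mem_opp[1],
                   _["helps"] = (double)w.mem_help[1])),
    _["release_step"] = release_step,
    _["steps_run"] = step,
    _["final_state"] = NumericVector::create(w.x[0], w.y[0], w.th[0],
                                             w.x[1], w.y[1], w.th[1]));
  if (log_trajectory) out["trajectory"] = traj;
  return out;
}

// Sensor computation on a frozen world state, for unit tests.
// state layout as init_state above; returns 17 activations for robot_index
// (R-side 1-based converted before the call).
// [[Rcpp::export]]
NumericVector sim_sense(List cfg, NumericVector state, LogicalVector stuck,
                        int robot_index, bool partner_invisible) {
  Config c = parse_config(cfg);
  World w(c);
  if ((int)state.size() != 6 + 2 * c.n_food) stop("bad state length");
  for (int i = 0; i < 2; ++i) {
    w.x[i] = state[3 * i]; w.y[i] = state[3 * i + 1]; w.th[i] = state[3 * i + 2];
    w.stuck[i] = stuck[i];
  }
  for (int k = 0; k < c.n_food; ++k) {
    w.fx[k] = state[6 + 2 * k]; w.fy[k] = state[7 + 2 * k];
  }
  NumericVector out(17);
  double s[17];
  w.sense(robot_index, !partner_invisible, s);
  for (int i = 0; i < 17; ++i) out[i] = s[i];
  return out;
}

// Monte-Carlo stuck-episode durations using the same per-step Bernoulli
// hazard as the world step: hazard = p_release (unhelped) or
// p_release * help_mult (partner continuously within helping range).
// [[Rcpp::export]]
IntegerVector sim_stuck_durations(int n, double p_release, double help_mult,
                                  bool helped, int max_steps) {
  if (p_release <= 0 || p_release > 1) stop("p_release must be in (0, 1]");
  double hz = p_release * (helped ? help_mult : 1.0);
  if (hz > 1) stop("hazard exceeds 1");
  RNGScope rng;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int t = 1;
    while (unif_rand() >= hz && t < max_steps) ++t;
    out[i] = t;
  }
  return out;
}

// Fast forward pass for cross-checking the R reference implementation.
// [[Rcpp::export]]
NumericVector sim_activate(NumericVector weights, bool has_memory,
                           NumericVector sensors, double memory, double vmax) {
  int expected = has_memory ? 191 : 182;
  if (weights.size() != expected) stop("weight length mismatch");
  if (sensors.size() != 17) stop("17 sensor values required");
  Net net(REAL(weights), has_memory);
  double out[2];
  net.activate(REAL(sensors), memory, vmax, out);
  return NumericVector::create(out[0], out[1]);
}
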