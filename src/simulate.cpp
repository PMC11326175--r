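// Compiled inner loops: the per-step agent simulation (VR mode: one focal
// agent plus projected dot stimuli; group mode: N interacting agents) and
// the internal-state integrator. All randomness comes from R's RNG so runs
// are reproducible from set.seed().
//
// Conventions match the R level: cm, degrees CCW (0 = +x axis), angles in
// (-180, 180], positive bearings to the left of heading, turning right =
// clockwise = negative heading change.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double DEG = 57.29577951308232;

// configuration vector layout (see R/simulator.R, cfg_vector())
enum CfgIdx {
  C_DT = 0, C_ARENA_R, C_FISH_LEN, C_BOUT_RATE, C_BOUT_SIZE, C_BOUT_STEPS,
  C_A_BASE, C_TAU_S, C_R_SCALE, C_S_REST, C_S_START, C_D, C_LOOM_MODE,
  C_HALF_FIELD, C_WALL_BL, C_WALL_K, C_P_TURN_BOUT, C_TURN_MEAN, C_TURN_SD,
  C_FORWARD_SD, C_PER_SECOND, C_FISH_HEIGHT
};

static inline double wrap_deg(double x) {
  // identical to R's ((x + 180) %% 360) - 180 with the -180 -> 180 fixup
  double w = x + 180.0 - 360.0 * std::floor((x + 180.0) / 360.0) - 180.0;
  if (w == -180.0) w = 180.0;
  return w;
}

static inline double clamp01(double p) {
  return p < 0.0 ? 0.0 : (p > 1.0 ? 1.0 : p);
}

// move (x, y) by (dx, dy); if the move would exit the arena disc, advance
// only to the boundary and report truncation
static inline bool move_truncated(double &x, double &y, double dx, double dy,
                                  double arena_r) {
  double nx = x + dx, ny = y + dy;
  double rlim = arena_r * (1.0 - 1e-9);
  if (std::hypot(nx, ny) < rlim) {
    x = nx; y = ny;
    return false;
  }
  // largest t in [0, 1] with |p + t*d| = rlim
  double aa = dx * dx + dy * dy;
  double bb = 2.0 * (x * dx + y * dy);
  double cc = x * x + y * y - rlim * rlim;
  double disc = bb * bb - 4.0 * aa * cc;
  if (aa > 0 && disc >= 0) {
    double t = (-bb + std::sqrt(disc)) / (2.0 * aa);
    if (t > 0 && t < 1) { x += t * dx; y += t * dy; }
  }
  return true;
}

struct BoutRow {
  double time, turn, wall, drive, p_right, dist_wall_bl;
  int agent;
};

// plan a bout: pick the turn direction (wall rule, then social policy),
// sample the magnitude, and rotate the heading. Returns the logged row.
static BoutRow plan_bout(double &heading, double x, double y,
                         const std::vector<double> &v, // per-object occupancy
                         const std::vector<double> &bearing,
                         const NumericVector &cfg, double a_eff,
                         double time, int agent) {
  double rr = std::hypot(x, y);
  double dist_wall_bl = (cfg[C_ARENA_R] - rr) / cfg[C_FISH_LEN];
  double p_wall = 1.0 / (1.0 + std::exp(cfg[C_WALL_K] *
                                        (dist_wall_bl - cfg[C_WALL_BL])));
  double sv = 0, sl = 0, sr = 0;
  for (size_t j = 0; j < v.size(); ++j) {
    if (v[j] <= 0) continue;
    sv += v[j];
    if (bearing[j] > 0) sl += v[j] * v[j]; else sr += v[j] * v[j];
  }
  double drive = sv > 0 ? (sl - sr) / sv : 0.0;
  double sign, p_right = 0.5;
  double wall = 0.0;
  if (unif_rand() < p_wall) {
    wall = 1.0;
    double beta = rr > 0 ? wrap_deg(std::atan2(y, x) * DEG - heading) : 0.0;
    sign = beta > 0 ? -1.0 : 1.0; // wall to the left -> turn right
  } else if (dist_wall_bl < cfg[C_WALL_BL]) {
    sign = unif_rand() < 0.5 ? -1.0 : 1.0; // neighbors ignored near the wall
  } else {
    p_right = clamp01(0.5 + a_eff * drive);
    sign = unif_rand() < p_right ? -1.0 : 1.0; // right = clockwise
  }
  double mag = unif_rand() < cfg[C_P_TURN_BOUT]
    ? std::fabs(::Rf_rnorm(cfg[C_TURN_MEAN], cfg[C_TURN_SD]))
    : std::fabs(::Rf_rnorm(0.0, cfg[C_FORWARD_SD]));
  heading = wrap_deg(heading + sign * mag);
  BoutRow row = { time, sign * mag, wall, drive, p_right, dist_wall_bl, agent };
  return row;
}

static NumericMatrix bouts_matrix(const std::vector<BoutRow> &log,
                                  double bout_dur_ms) {
  NumericMatrix m(log.size(), 8);
  for (size_t i = 0; i < log.size(); ++i) {
    m(i, 0) = log[i].agent;
    m(i, 1) = log[i].time;
    m(i, 2) = log[i].turn;
    m(i, 3) = log[i].wall;
    m(i, 4) = log[i].drive;
    m(i, 5) = log[i].p_right;
    m(i, 6) = log[i].dist_wall_bl;
    m(i, 7) = bout_dur_ms;
  }
  colnames(m) = CharacterVector::create("agent_id", "onset_s", "turn_deg",
                                        "wall_turn", "drive_deg", "p_right",
                                        "dist_wall_bl", "duration_ms");
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_integrate(double s0, NumericVector inputs, double dt,
                            double tau_s, double s_rest, double r,
                            double lo, double hi) {
  int n = inputs.size();
  NumericVector out(n);
  double s = s0, k = dt / tau_s;
  for (int i = 0; i < n; ++i) {
    s += k * (s_rest - s + r * inputs[i]);
    if (s < lo) s = lo;
    if (s > hi) s = hi;
    out[i] = s;
  }
  return out;
}

// Single focal agent interacting with a dot stimulus stream.
// state0: x, y, heading, s, bout_left, step_dx, step_dy, pending, truncated
// stim*: n_frames x n_dots matrices (NaN marks an absent dot); the stream
// starts at the beginning of this call and loops.
// [[Rcpp::export]]
List cpp_simulate_vr(NumericVector state0, NumericVector cfg,
                     NumericMatrix stimX, NumericMatrix stimY,
                     NumericMatrix stimR, int focal_frame, double period,
                     int n_steps, double t0, int emit_every) {
  RNGScope rng;
  const double dt = cfg[C_DT];
  const int n_frames = stimX.nrow();
  const int n_dots = stimX.ncol();
  const int bout_steps = (int)cfg[C_BOUT_STEPS];
  const bool loom_raw = cfg[C_LOOM_MODE] > 0.5;
  const double half_field = cfg[C_HALF_FIELD];

  double x = state0[0], y = state0[1], heading = state0[2], s = state0[3];
  int bout_left = (int)state0[4];
  double step_dx = state0[5], step_dy = state0[6];
  int pending = (int)state0[7];
  bool truncated = state0[8] > 0.5;

  int m = n_steps / emit_every;
  NumericMatrix traj(m, 5), state(m, 5);
  std::vector<BoutRow> blog;

  // per-dot scratch and previous-step scene
  std::vector<double> v_now(n_dots), bear_now(n_dots), d_now(n_dots);
  std::vector<double> wx(n_dots), wy(n_dots);
  std::vector<double> p_wx(n_dots), p_wy(n_dots), p_rd(n_dots), p_rad(n_dots),
    p_bear(n_dots), p_v(n_dots);
  std::vector<char> present(n_dots), p_present(n_dots, 0);

  for (int k = 0; k < n_steps; ++k) {
    int fi = 0;
    if (n_frames > 0) {
      fi = (int)(((long long)std::floor(k * dt / period + 1e-9)) % n_frames);
    }
    double hr = heading / DEG, ch = std::cos(hr), sh = std::sin(hr);

    // perception: bearings, distances, vertical occupancy
    double input = 0.0, nn = NA_REAL;
    for (int j = 0; j < n_dots; ++j) {
      double sx = stimX(fi, j), sy = stimY(fi, j), rad = stimR(fi, j);
      present[j] = !ISNAN(sx);
      if (!present[j]) { v_now[j] = 0; continue; }
      double rd, br;
      if (focal_frame) { // coordinates in the heading frame of the focal
        rd = std::hypot(sx, sy);
        br = wrap_deg(std::atan2(sy, sx) * DEG);
        wx[j] = x + ch * sx - sh * sy;
        wy[j] = y + sh * sx + ch * sy;
      } else {
        wx[j] = sx; wy[j] = sy;
        double dx = sx - x, dy = sy - y;
        rd = std::hypot(dx, dy);
        br = wrap_deg(std::atan2(dy, dx) * DEG - heading);
      }
      d_now[j] = rd; bear_now[j] = br;
      bool vis = rd > 0 && std::fabs(br) <= half_field;
      v_now[j] = vis ? 2.0 * std::atan(rad / rd) * DEG : 0.0;
      if (ISNAN(nn) || rd < nn) nn = rd;
    }

    // looming input: max per-object occupancy increase, floored at 0
    if (k > 0) {
      for (int j = 0; j < n_dots; ++j) {
        if (!present[j] || v_now[j] <= 0) continue;
        double v_prev = 0.0;
        if (p_present[j]) {
          if (loom_raw) {
            v_prev = p_v[j]; // as experienced at the previous step
          } else if (focal_frame) {
            // re-anchored stream: previous relative geometry
            bool vis = p_rd[j] > 0 && std::fabs(p_bear[j]) <= half_field;
            v_prev = vis ? 2.0 * std::atan(p_rad[j] / p_rd[j]) * DEG : 0.0;
          } else {
            // previous scene viewed from the *current* pose: self-motion
            // through a static scene contributes nothing
            double dx = p_wx[j] - x, dy = p_wy[j] - y;
            double rd = std::hypot(dx, dy);
            double br = wrap_deg(std::atan2(dy, dx) * DEG - heading);
            bool vis = rd > 0 && std::fabs(br) <= half_field;
            v_prev = vis ? 2.0 * std::atan(p_rad[j] / rd) * DEG : 0.0;
          }
          // an object that was in the scene but invisible (blind zone)
          // emerges without looming; only objects newly added to the
          // scene count with their full occupancy
          if (v_prev <= 0) continue;
        }
        double inc = v_now[j] - v_prev;
        if (inc > input) input = inc;
      }
      if (input < 1e-9) input = 0.0; // numerical dead-band
    }
    for (int j = 0; j < n_dots; ++j) {
      p_present[j] = present[j];
      if (present[j]) {
        p_wx[j] = wx[j]; p_wy[j] = wy[j]; p_rd[j] = d_now[j];
        p_rad[j] = stimR(fi, j); p_bear[j] = bear_now[j]; p_v[j] = v_now[j];
      }
    }

    // internal state and effective slope
    double in_scaled = cfg[C_PER_SECOND] > 0.5 ? input / dt : input;
    s += (dt / cfg[C_TAU_S]) * (cfg[C_S_REST] - s + cfg[C_R_SCALE] * in_scaled);
    double lo = cfg[C_S_REST], hi = cfg[C_S_START] + cfg[C_D];
    if (s < lo) s = lo;
    if (s > hi) s = hi;
    double a_eff = cfg[C_A_BASE] * (1.0 - (s - cfg[C_S_START]) / cfg[C_D]);
    if (a_eff < 0) a_eff = 0;

    // bout decision clock runs every step; bouts execute serially
    if (unif_rand() < cfg[C_BOUT_RATE] * dt) pending++;
    if (bout_left <= 0 && pending > 0) {
      pending--;
      blog.push_back(plan_bout(heading, x, y, v_now, bear_now, cfg, a_eff,
                               t0 + k * dt, 1));
      bout_left = bout_steps;
      double hr2 = heading / DEG;
      step_dx = cfg[C_BOUT_SIZE] / bout_steps * std::cos(hr2);
      step_dy = cfg[C_BOUT_SIZE] / bout_steps * std::sin(hr2);
      truncated = false;
    }
    int bouting = 0;
    if (bout_left > 0) {
      if (!truncated) {
        truncated = move_truncated(x, y, step_dx, step_dy, cfg[C_ARENA_R]);
      }
      bout_left--;
      bouting = 1;
    }

    if ((k + 1) % emit_every == 0) {
      int i = (k + 1) / emit_every - 1;
      double tt = t0 + (k + 1) * dt;
      traj(i, 0) = tt; traj(i, 1) = x; traj(i, 2) = y; traj(i, 3) = heading;
      traj(i, 4) = bouting;
      state(i, 0) = tt; state(i, 1) = s; state(i, 2) = input;
      state(i, 3) = a_eff; state(i, 4) = nn;
    }
  }

  NumericVector fin = NumericVector::create(x, y, heading, s,
                                            (double)bout_left, step_dx,
                                            step_dy, (double)pending,
                                            truncated ? 1.0 : 0.0);
  colnames(traj) = CharacterVector::create("time_s", "x_cm", "y_cm",
                                           "heading_deg", "bouting");
  colnames(state) = CharacterVector::create("time_s", "s", "input_deg",
                                            "a_eff", "nn_cm");
  double bdur = bout_steps * dt * 1000.0;
  return List::create(_["traj"] = traj, _["state"] = state,
                      _["bouts"] = bouts_matrix(blog, bdur),
                      _["final"] = fin);
}

// N interacting agents; perception uses previous-step poses for all agents
// (synchronous update), per-object occupancy without occlusion correction.
// agents0: n x 9 matrix, rows as in cpp_simulate_vr's state0.
// [[Rcpp::export]]
List cpp_simulate_group(NumericMatrix agents0, NumericVector cfg,
                        int n_steps, double t0, int emit_every) {
  RNGScope rng;
  const double dt = cfg[C_DT];
  const int n = agents0.nrow();
  const int bout_steps = (int)cfg[C_BOUT_STEPS];
  const bool loom_raw = cfg[C_LOOM_MODE] > 0.5;
  const double half_field = cfg[C_HALF_FIELD];
  const double H = cfg[C_FISH_HEIGHT];

  std::vector<double> x(n), y(n), heading(n), s(n), step_dx(n), step_dy(n);
  std::vector<int> bout_left(n), pending(n);
  std::vector<char> truncated(n);
  for (int i = 0; i < n; ++i) {
    x[i] = agents0(i, 0); y[i] = agents0(i, 1); heading[i] = agents0(i, 2);
    s[i] = agents0(i, 3); bout_left[i] = (int)agents0(i, 4);
    step_dx[i] = agents0(i, 5); step_dy[i] = agents0(i, 6);
    pending[i] = (int)agents0(i, 7); truncated[i] = agents0(i, 8) > 0.5;
  }
  std::vector<double> px = x, py = y, ph = heading;   // poses at step k-1
  std::vector<double> p2x = x, p2y = y, p2h = heading; // poses at step k-2

  int m = n_steps / emit_every;
  NumericVector times(m);
  NumericMatrix X(m, n), Y(m, n), Hd(m, n), Bt(m, n), Sm(m, n), In(m, n),
    Ae(m, n), Nn(m, n);
  std::vector<BoutRow> blog;
  std::vector<double> v_now(n), bear_now(n);

  for (int k = 0; k < n_steps; ++k) {
    for (int i = 0; i < n; ++i) {
      // perception of neighbors from previous-step poses
      double input = 0.0, nn = NA_REAL;
      for (int j = 0; j < n; ++j) {
        if (j == i) { v_now[j] = 0; continue; }
        double dx = px[j] - px[i], dy = py[j] - py[i];
        double rd = std::hypot(dx, dy);
        double br = wrap_deg(std::atan2(dy, dx) * DEG - ph[i]);
        bear_now[j] = br;
        bool vis = rd > 0 && std::fabs(br) <= half_field;
        v_now[j] = vis ? 2.0 * std::atan(H / rd) * DEG : 0.0;
        if (ISNAN(nn) || rd < nn) nn = rd;
        if (k > 0 && v_now[j] > 0) {
          double ox = p2x[j] - px[i], oy = p2y[j] - py[i];
          double ord = std::hypot(ox, oy);
          double obr, v_prev = 0.0;
          double href = ph[i];
          if (loom_raw) {
            // as experienced last step (from the agent's k-2 pose)
            ox = p2x[j] - p2x[i]; oy = p2y[j] - p2y[i];
            ord = std::hypot(ox, oy);
            href = p2h[i];
          }
          obr = wrap_deg(std::atan2(oy, ox) * DEG - href);
          bool ovis = ord > 0 && std::fabs(obr) <= half_field;
          if (!ovis) continue; // emerging from the blind zone: no loom
          v_prev = 2.0 * std::atan(H / ord) * DEG;
          double inc = v_now[j] - v_prev;
          if (inc > input) input = inc;
        }
      }
      if (input < 1e-9) input = 0.0; // numerical dead-band
      double in_scaled = cfg[C_PER_SECOND] > 0.5 ? input / dt : input;
      s[i] += (dt / cfg[C_TAU_S]) *
        (cfg[C_S_REST] - s[i] + cfg[C_R_SCALE] * in_scaled);
      double lo = cfg[C_S_REST], hi = cfg[C_S_START] + cfg[C_D];
      if (s[i] < lo) s[i] = lo;
      if (s[i] > hi) s[i] = hi;
      double a_eff = cfg[C_A_BASE] * (1.0 - (s[i] - cfg[C_S_START]) / cfg[C_D]);
      if (a_eff < 0) a_eff = 0;

      if (unif_rand() < cfg[C_BOUT_RATE] * dt) pending[i]++;
      if (bout_left[i] <= 0 && pending[i] > 0) {
        pending[i]--;
        blog.push_back(plan_bout(heading[i], x[i], y[i], v_now, bear_now,
                                 cfg, a_eff, t0 + k * dt, i + 1));
        bout_left[i] = bout_steps;
        double hr2 = heading[i] / DEG;
        step_dx[i] = cfg[C_BOUT_SIZE] / bout_steps * std::cos(hr2);
        step_dy[i] = cfg[C_BOUT_SIZE] / bout_steps * std::sin(hr2);
        truncated[i] = false;
      }
      int bouting = 0;
      if (bout_left[i] > 0) {
        if (!truncated[i]) {
          truncated[i] = move_truncated(x[i], y[i], step_dx[i], step_dy[i],
                                        cfg[C_ARENA_R]);
        }
        bout_left[i]--;
        bouting = 1;
      }

      if ((k + 1) % emit_every == 0) {
        int row = (k + 1) / emit_every - 1;
        X(row, i) = x[i]; Y(row, i) = y[i]; Hd(row, i) = heading[i];
        Bt(row, i) = bouting; Sm(row, i) = s[i]; In(row, i) = input;
        Ae(row, i) = a_eff; Nn(row, i) = nn;
      }
    }
    if ((k + 1) % emit_every == 0) times[(k + 1) / emit_every - 1] =
      t0 + (k + 1) * dt;
    p2x = px; p2y = py; p2h = ph;
    px = x; py = y; ph = heading;
  }

  NumericMatrix fin(n, 9);
  for (int i = 0; i < n; ++i) {
    fin(i, 0) = x[i]; fin(i, 1) = y[i]; fin(i, 2) = heading[i];
    fin(i, 3) = s[i]; fin(i, 4) = bout_left[i]; fin(i, 5) = step_dx[i];
    fin(i, 6) = step_dy[i]; fin(i, 7) = pending[i];
    fin(i, 8) = truncated[i] ? 1.0 : 0.0;
  }
  double bdur = bout_steps * dt * 1000.0;
  return List::create(_["time_s"] = times, _["x"] = X, _["y"] = Y,
                      _["heading"] = Hd, _["bouting"] = Bt, _["s"] = Sm,
                      _["input"] = In, _["a_eff"] = Ae, _["nn"] = Nn,
                      _["bouts"] = bouts_matrix(blog, bdur),
                      _["final"] = fin);
}
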