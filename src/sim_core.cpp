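#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Ring-buffer rolling mean / population SD with capped capacity.
// Accumulators are re-summed exactly at regular intervals so drift stays
// far below the 1e-9 equivalence tolerance against from-scratch
// recomputation.
struct RollingStats {
  std::vector<double> buf;
  int cap, head, count;
  long long n_seen;
  long double sum, sumsq;
  static const int RESYNC = 8192;

  explicit RollingStats(int capacity)
      : buf(capacity, 0.0), cap(capacity), head(0), count(0), n_seen(0),
        sum(0.0L), sumsq(0.0L) {}

  void push(double x) {
    if (count == cap) {
      double old = buf[head];
      sum -= old;
      sumsq -= (long double)old * old;
    } else {
      ++count;
    }
    buf[head] = x;
    head = (head + 1 == cap) ? 0 : head + 1;
    sum += x;
    sumsq += (long double)x * x;
    ++n_seen;
    if (n_seen % RESYNC == 0) {
      long double s = 0.0L, s2 = 0.0L;
      for (int i = 0; i < count; ++i) {
        double v = buf[i];
        s += v;
        s2 += (long double)v * v;
      }
      sum = s;
      sumsq = s2;
    }
  }

  double mean() const { return (double)(sum / count); }

  double psd() const {
    long double m = sum / count;
    long double v = sumsq / count - m * m;
    return v > 0.0L ? (double)std::sqrt((double)v) : 0.0;
  }
};

// Streaming moving z-score over a whole force vector; NA until warm_n
// samples of prior history exist.
// [[Rcpp::export]]
NumericVector stream_stress_cpp(NumericVector force, int cap, int warm_n,
                                double sd_floor) {
  int n = force.size();
  NumericVector out(n, NA_REAL);
  RollingStats rs(cap);
  for (int i = 0; i < n; ++i) {
    bool warmed = rs.count >= warm_n;
    rs.push(force[i]);
    if (warmed) {
      double sd = rs.psd();
      if (sd < sd_floor) sd = sd_floor;
      out[i] = (force[i] - rs.mean()) / sd;
    }
  }
  return out;
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Closed-loop trainee simulation over a rest/task segment schedule.
//
// trainee: s_opt u_width h_max loss_base speed_ref tau_learn theta sigma
//          kappa g0 g1 gnoise
// pol:     code(0 constant,1 time_ramp,2 stress_adaptive) initial_speed
//          initial_phase constant_speed ramp_step ramp_interval stress_high
//          stress_low adapt_step adapt_tick min_speed max_speed
// est:     rate_hz cap warm_n sd_floor
//
// Latent stress follows mean-reverting (OU) dynamics whose equilibrium is
// kappa*(speed - speed_ref) during task segments and 0 at rest.  Grip force
// is a noisy linear readout of latent stress, fed to the same streaming
// estimator as recorded data.  Hit and life-loss streams are inhomogeneous
// Poisson processes realised by thinning a dominating homogeneous process,
// with the hit rate inverted-U in latent stress times a saturating learning
// factor in cumulative task time.  The adaptive controller ticks every
// adapt_tick seconds using the most recent stress score strictly before the
// tick; per task segment the speed restarts at the initial phase.
// [[Rcpp::export]]
List sim_core_cpp(NumericVector seg_dur, IntegerVector seg_task,
                  NumericVector trainee, NumericVector pol,
                  NumericVector est, bool reset_at_rest) {
  const double s_opt = trainee[0], u_width = trainee[1], h_max = trainee[2],
               loss_base = trainee[3], speed_ref = trainee[4],
               tau_learn = trainee[5], theta = trainee[6],
               sigma = trainee[7], kappa = trainee[8], g0 = trainee[9],
               g1 = trainee[10], gnoise = trainee[11];
  const int pol_code = (int)pol[0];
  const double init_speed = pol[1], phase = pol[2], const_speed = pol[3],
               ramp_step = pol[4], ramp_int = pol[5], s_hi = pol[6],
               s_lo = pol[7], a_step = pol[8], a_tick = pol[9],
               min_speed = pol[10], max_speed = pol[11];
  const double rate = est[0];
  const int cap = (int)est[1], warm_n = (int)est[2];
  const double sd_floor = est[3];

  const double dt = 1.0 / rate;
  const double sqrt_dt = std::sqrt(dt);
  int tick_steps = (int)std::lround(a_tick * rate);
  if (tick_steps < 1) tick_steps = 1;

  int total_steps = 0;
  for (int k = 0; k < seg_dur.size(); ++k)
    total_steps += (int)std::lround(seg_dur[k] * rate);

  NumericVector t_out(total_steps), force_out(total_steps),
      latent_out(total_steps), s_out(total_steps);
  std::vector<double> tick_t, tick_speed, hit_t, loss_t;
  tick_t.reserve(total_steps / tick_steps + 8);
  tick_speed.reserve(total_steps / tick_steps + 8);

  RollingStats rs(cap);
  double x = 0.0;               // latent stress
  double cur_speed = init_speed; // adaptive controller state
  double last_s = NA_REAL;
  bool have_s = false;
  double task_time = 0.0;       // cumulative seconds on task
  double t_global = 0.0;
  const double lam_hit_max = h_max;
  const double lam_loss_max = loss_base * (max_speed / speed_ref) * 2.0;
  long double abs_dev_sum = 0.0L;
  long long task_steps = 0;
  int idx = 0;

  for (int k = 0; k < seg_dur.size(); ++k) {
    const bool task = seg_task[k] != 0;
    const int m = (int)std::lround(seg_dur[k] * rate);
    if (task) cur_speed = init_speed; // each game starts at the initial phase
    if (!task && reset_at_rest) rs = RollingStats(cap);
    for (int j = 0; j < m; ++j, ++idx) {
      const double t_seg = j * dt;
      double speed_now = 0.0;
      if (task) {
        if (pol_code == 2 && j % tick_steps == 0 &&
            t_seg >= phase - 1e-9 && have_s) {
          double ns = cur_speed;
          if (last_s > s_hi) ns = cur_speed - a_step;
          else if (last_s < s_lo) ns = cur_speed + a_step;
          cur_speed = clampd(ns, min_speed, max_speed);
        }
        if (pol_code == 0)
          speed_now = (t_seg < phase) ? init_speed : const_speed;
        else if (pol_code == 1)
          speed_now = (t_seg < phase)
                          ? init_speed
                          : init_speed +
                                ramp_step * std::floor((t_seg - phase) / ramp_int);
        else
          speed_now = cur_speed;
        speed_now = clampd(speed_now, min_speed, max_speed);
        if (j % tick_steps == 0) {
          tick_t.push_back(t_global);
          tick_speed.push_back(speed_now);
        }
      }

      // latent stress: OU step toward the task-load equilibrium
      const double mu = task ? kappa * (speed_now - speed_ref) : 0.0;
      x += theta * (mu - x) * dt + sigma * sqrt_dt * norm_rand();

      double force = g0 + g1 * x + gnoise * norm_rand();
      if (force < 0.0) force = 0.0;

      const bool warmed = rs.count >= warm_n;
      rs.push(force);
      double s = NA_REAL;
      if (warmed) {
        double sd = rs.psd();
        if (sd < sd_floor) sd = sd_floor;
        s = (force - rs.mean()) / sd;
        last_s = s;
        have_s = true;
      }

      t_out[idx] = t_global;
      force_out[idx] = force;
      latent_out[idx] = x;
      s_out[idx] = s;

      if (task) {
        abs_dev_sum += std::fabs(x - s_opt);
        ++task_steps;
        const double dev = (x - s_opt) / u_width;
        const double bell = std::exp(-0.5 * dev * dev);
        // hits: thin a dominating Poisson(h_max) stream
        int kh = (int)R::rpois(lam_hit_max * dt);
        for (int e = 0; e < kh; ++e) {
          double frac = unif_rand();
          double tt = task_time + frac * dt;
          double learn =
              tau_learn > 0.0 ? 1.0 - std::exp(-tt / tau_learn) : 1.0;
          double lam = h_max * bell * learn;
          if (unif_rand() * lam_hit_max < lam)
            hit_t.push_back(t_global + frac * dt);
        }
        // life losses: rate scales with speed, eases with learning
        int kl = (int)R::rpois(lam_loss_max * dt);
        for (int e = 0; e < kl; ++e) {
          double frac = unif_rand();
          double tt = task_time + frac * dt;
          double learn =
              tau_learn > 0.0 ? 1.0 - std::exp(-tt / tau_learn) : 1.0;
          double lam = loss_base * (speed_now / speed_ref) * (2.0 - learn);
          if (unif_rand() * lam_loss_max < lam)
            loss_t.push_back(t_global + frac * dt);
        }
        task_time += dt;
      }
      t_global += dt;
    }
  }

  return List::create(
      _["t"] = t_out, _["force"] = force_out, _["latent"] = latent_out,
      _["s"] = s_out, _["speed_t"] = NumericVector(tick_t.begin(), tick_t.end()),
      _["speed"] = NumericVector(tick_speed.begin(), tick_speed.end()),
      _["hit_t"] = NumericVector(hit_t.begin(), hit_t.end()),
      _["loss_t"] = NumericVector(loss_t.begin(), loss_t.end()),
      _["mean_abs_dev"] =
          task_steps > 0 ? (double)(abs_dev_sum / task_steps) : NA_REAL);
}
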