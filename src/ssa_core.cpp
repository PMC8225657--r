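#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Direct-method Gillespie simulation of the per-gene reaction system.
//
// Species layout: x_1..x_G, y_1..y_G, z_1..z_G.
// Reaction layout per gene g (6 reactions, 0-based block g*6):
//   0 transcription  (+x)
//   1 splicing       (-x, +y)
//   2 translation    (+z, catalytic on y)
//   3 degrade pre-mRNA (-x)
//   4 degrade mRNA     (-y)
//   5 degrade protein  (-z)
//
// Transcription propensity: thermodynamic promoter-occupancy model,
//   f = xpr * (ba - sy^{|R+|} + prod_{act}(nu_i + sy)) / prod_{all}(nu_i + 1)
// with nu_i = (state[reg_sp]/k_i)^{n_i}, clamped at zero, multiplied by
// the per-gene transcription mask (used for the warm-up phase).
//
// Uses R's RNG so set.seed() on the R side makes runs reproducible.

static inline void compute_propensities(
    const std::vector<double>& state, int G,
    const NumericVector& xpr, const NumericVector& ba, const NumericVector& sy,
    const NumericVector& splice, const NumericVector& transl,
    const NumericVector& deg_x, const NumericVector& deg_y, const NumericVector& deg_z,
    const IntegerVector& reg_ptr, const IntegerVector& reg_sp,
    const NumericVector& reg_k, const NumericVector& reg_n, const NumericVector& reg_eff,
    const LogicalVector& transcription_on,
    std::vector<double>& props) {
  for (int g = 0; g < G; ++g) {
    double f = 0.0;
    if (transcription_on[g]) {
      double denom = 1.0, actprod = 1.0;
      int nact = 0;
      for (int i = reg_ptr[g]; i < reg_ptr[g + 1]; ++i) {
        double nu = std::pow(state[reg_sp[i]] / reg_k[i], reg_n[i]);
        denom *= nu + 1.0;
        if (reg_eff[i] > 0) {
          actprod *= nu + sy[g];
          ++nact;
        }
      }
      f = xpr[g] * (ba[g] - std::pow(sy[g], nact) + actprod) / denom;
      if (f < 0.0) f = 0.0;
    }
    double x = state[g], y = state[G + g], z = state[2 * G + g];
    props[g * 6 + 0] = f;
    props[g * 6 + 1] = splice[g] * x;
    props[g * 6 + 2] = transl[g] * y;
    props[g * 6 + 3] = deg_x[g] * x;
    props[g * 6 + 4] = deg_y[g] * y;
    props[g * 6 + 5] = deg_z[g] * z;
  }
}

static inline void apply_reaction(std::vector<double>& state, int G, int r) {
  int g = r / 6, kind = r % 6;
  switch (kind) {
    case 0: state[g] += 1; break;
    case 1: state[g] -= 1; state[G + g] += 1; break;
    case 2: state[2 * G + g] += 1; break;
    case 3: state[g] -= 1; break;
    case 4: state[G + g] -= 1; break;
    case 5: state[2 * G + g] -= 1; break;
  }
}

// [[Rcpp::export]]
List ssa_run_core(
    NumericVector state0, double t0, double t_end, double census_interval,
    NumericVector xpr, NumericVector ba, NumericVector sy,
    NumericVector splice, NumericVector transl,
    NumericVector deg_x, NumericVector deg_y, NumericVector deg_z,
    IntegerVector reg_ptr, IntegerVector reg_sp,
    NumericVector reg_k, NumericVector reg_n, NumericVector reg_eff,
    LogicalVector transcription_on,
    double max_events) {
  int G = xpr.size();
  int M = 6 * G;
  std::vector<double> state(state0.begin(), state0.end());
  std::vector<double> props(M, 0.0);
  std::vector<double> firings(M, 0.0);

  std::vector<double> rec_time;
  std::vector<double> rec_state;
  std::vector<double> rec_props;
  std::vector<double> rec_fire;

  RNGScope rngscope;

  double t = t0;
  compute_propensities(state, G, xpr, ba, sy, splice, transl, deg_x, deg_y, deg_z,
                       reg_ptr, reg_sp, reg_k, reg_n, reg_eff, transcription_on, props);

  bool event_census = census_interval <= 0.0;
  double next_census = event_census ? t0 : t0 + census_interval;

  // record a row for the current (constant) state at time `at`
  auto record = [&](double at) {
    rec_time.push_back(at);
    rec_state.insert(rec_state.end(), state.begin(), state.end());
    rec_props.insert(rec_props.end(), props.begin(), props.end());
    rec_fire.insert(rec_fire.end(), firings.begin(), firings.end());
    std::fill(firings.begin(), firings.end(), 0.0);
  };

  record(t0);  // initial census row

  double n_events = 0;
  while (true) {
    double total = 0.0;
    for (int j = 0; j < M; ++j) total += props[j];

    double t_next;
    if (total <= 0.0) {
      t_next = R_PosInf;  // absorbing state: coast to the end
    } else {
      t_next = t + (1.0 / total) * std::log(1.0 / unif_rand());
    }

    if (!event_census) {
      while (next_census <= t_next && next_census <= t_end + 1e-12) {
        record(next_census);
        next_census += census_interval;
      }
    }

    if (t_next > t_end) break;
    t = t_next;

    // choose the reaction proportionally to its propensity
    double u = unif_rand() * total, acc = 0.0;
    int chosen = M - 1;
    for (int j = 0; j < M; ++j) {
      acc += props[j];
      if (u <= acc) { chosen = j; break; }
    }
    apply_reaction(state, G, chosen);
    firings[chosen] += 1.0;

    compute_propensities(state, G, xpr, ba, sy, splice, transl, deg_x, deg_y, deg_z,
                         reg_ptr, reg_sp, reg_k, reg_n, reg_eff, transcription_on, props);

    if (event_census) record(t);

    if (++n_events >= max_events) {
      Rcpp::warning("SSA stopped after reaching max_events");
      break;
    }
  }

  int n_rows = rec_time.size();
  NumericMatrix counts(n_rows, 3 * G), pmat(n_rows, M), fmat(n_rows, M);
  for (int r = 0; r < n_rows; ++r) {
    for (int s = 0; s < 3 * G; ++s) counts(r, s) = rec_state[(size_t)r * 3 * G + s];
    for (int j = 0; j < M; ++j) {
      pmat(r, j) = rec_props[(size_t)r * M + j];
      fmat(r, j) = rec_fire[(size_t)r * M + j];
    }
  }
  return List::create(
    _["times"] = NumericVector(rec_time.begin(), rec_time.end()),
    _["counts"] = counts,
    _["propensities"] = pmat,
    _["firings"] = fmat,
    _["final_state"] = NumericVector(state.begin(), state.end()),
    _["final_time"] = t_end
  );
}
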