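#include <Rcpp.h>
using namespace Rcpp;

// Direct-method SSA for a one-species network.
//
// Propensity kinds: 0 constant, 1 linear (c*x), 2 pure quadratic (c*x^2),
// 3 mass-action second order (c*x*(x-1)). guard[j] is the smallest state at
// which reaction j is active (0 = unguarded).
//
// Draw-count convention: every exponential waiting-time draw counts,
// including the final draw that would cross t_end without being committed.
// Hence draw_count = events + 1 for an uncapped trajectory that is still
// active at t_end, and draw_count = cap when the reaction cap is hit.
// Uses R's RNG, so results are reproducible via set.seed() on the R side.

static inline double prop(int kind, double rate, int guard, double x) {
  if (x < guard) return 0.0;
  switch (kind) {
    case 0: return rate;
    case 1: return rate * x;
    case 2: return rate * x * x;
    default: return rate * x * (x - 1.0);
  }
}

// [[Rcpp::export]]
List ssa_simulate_cpp(IntegerVector nu, IntegerVector kind,
                      NumericVector rate, IntegerVector guard,
                      int x0, double t_end, int cap) {
  const int J = nu.size();
  std::vector<double> ev_times;
  std::vector<int> ev_states;
  ev_times.reserve(256);
  ev_states.reserve(256);

  double t = 0.0;
  double x = x0;
  int draws = 0, events = 0;
  bool capped = false;
  std::vector<double> a(J);

  for (;;) {
    double lambda = 0.0;
    for (int j = 0; j < J; ++j) {
      a[j] = prop(kind[j], rate[j], guard[j], x);
      if (!R_finite(a[j]) || a[j] < 0.0)
        stop("non-finite or negative propensity at state %g", x);
      lambda += a[j];
    }
    if (lambda <= 0.0) break;  // absorbing: rest until t_end, no draw

    double tau = exp_rand() / lambda;
    ++draws;
    if (t + tau > t_end) break;  // crossing draw recorded, not committed
    t += tau;

    double u = unif_rand() * lambda;
    int j = 0;
    double acc = a[0];
    while (u > acc && j < J - 1) acc += a[++j];

    x += nu[j];
    ++events;
    ev_times.push_back(t);
    ev_states.push_back((int)x);
    if (events >= cap) { capped = true; break; }
  }

  return List::create(
    _["times"] = wrap(ev_times),
    _["states"] = wrap(ev_states),
    _["draw_count"] = draws,
    _["capped"] = capped);
}
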