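#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a Wiener diffusion between absorbing
// boundaries, evaluated with the standard small-time / large-time series
// expansions, each truncated adaptively so the absolute error of the
// normalised density stays below `eps`.
//
// Normalised problem: unit boundary separation, zero drift, relative start
// point w in (0,1); density of absorption at the LOWER boundary at scaled
// time u > 0.

static double fpt_density_scaled(double u, double w, double eps) {
  if (u <= 0.0) return 0.0;

  // Series lengths needed for absolute error eps (small- vs large-time form).
  double ks = 2.0;
  if (2.0 * eps * std::sqrt(2.0 * M_PI * u) < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  }
  double kl = 1.0 / (M_PI * std::sqrt(u));
  if (M_PI * u * eps < 1.0) {
    kl = std::max(std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u)), kl);
  }

  double f;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    f = 0.0;
    for (int k = -((K - 1) / 2); k <= K / 2; k++) {
      double z = w + 2.0 * k;
      f += z * std::exp(-z * z / (2.0 * u));
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    f = 0.0;
    for (int k = 1; k <= K; k++) {
      f += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return std::max(f, 0.0);
}

// Density of hitting the LOWER boundary at time rt, for drift v, boundary
// separation a, relative start w, non-decision time t0, diffusion scale 1.
static double wiener_lower(double rt, double v, double a, double w,
                           double t0, double eps) {
  double t = rt - t0;
  if (t <= 0.0) return 0.0;
  double u = t / (a * a);
  double f = fpt_density_scaled(u, w, eps);
  return f * std::exp(-v * a * w - v * v * t / 2.0) / (a * a);
}

//' @keywords internal
// [[Rcpp::export(name = ".wiener_density_cpp")]]
NumericVector wiener_density_cpp(NumericVector rt, LogicalVector upper,
                                 double v, double a, double t0,
                                 double w = 0.5, double eps = 1e-7) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    if (upper[i]) {
      // upper-boundary hit: reflect (v -> -v, w -> 1 - w)
      out[i] = wiener_lower(rt[i], -v, a, 1.0 - w, t0, eps);
    } else {
      out[i] = wiener_lower(rt[i], v, a, w, t0, eps);
    }
  }
  return out;
}

// Summed log-likelihood under accuracy coding (upper = correct), w = 0.5.
// Returns -Inf when any trial has non-positive decision time.
// [[Rcpp::export(name = ".wiener_loglik_cpp")]]
double wiener_loglik_cpp(NumericVector rt, LogicalVector correct,
                         double v, double a, double t0,
                         double eps = 1e-7) {
  if (a <= 0.0 || t0 < 0.0) return R_NegInf;
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; i++) {
    double d;
    if (correct[i]) {
      d = wiener_lower(rt[i], -v, a, 0.5, t0, eps);
    } else {
      d = wiener_lower(rt[i], v, a, 0.5, t0, eps);
    }
    if (d <= 0.0 || !R_finite(d)) return R_NegInf;
    ll += std::log(d);
  }
  return ll;
}

// Euler-Maruyama simulation of the diffusion from z = a/2 with drift v and
// unit diffusion scale; uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".simulate_ddm_cpp")]]
List simulate_ddm_cpp(int n, double v, double a, double t0, double dt) {
  NumericVector rts(n);
  LogicalVector upper(n);
  double sdt = std::sqrt(dt);
  // 120 s of decision time; truncation beyond this is resolved by position
  int max_steps = (int)(120.0 / dt);
  for (int i = 0; i < n; i++) {
    double x = a / 2.0;
    int step = 0;
    bool hit_upper = false, hit = false;
    while (!hit && step < max_steps) {
      double x1 = x + v * dt + sdt * norm_rand();
      step++;
      if (x1 <= 0.0) {
        hit = true; hit_upper = false;
      } else if (x1 >= a) {
        hit = true; hit_upper = true;
      } else {
        // Brownian-bridge correction: the path may have crossed a boundary
        // between the endpoints of the step even though both lie inside
        double p_low = std::exp(-2.0 * x * x1 / dt);
        double p_up = std::exp(-2.0 * (a - x) * (a - x1) / dt);
        double u = unif_rand();
        if (u < p_low) {
          hit = true; hit_upper = false;
        } else if (u > 1.0 - p_up) {
          hit = true; hit_upper = true;
        }
      }
      x = x1;
    }
    if (!hit) hit_upper = (x >= a / 2.0);
    upper[i] = hit_upper;
    rts[i] = t0 + step * dt;
  }
  return List::create(_["rt"] = rts, _["upper"] = upper);
}

// Expected posterior Shannon entropy for each candidate stimulus.
// L: n_candidates x n_nodes matrix of P(correct | node, candidate);
// post: current posterior mass over nodes (sums to 1).
// [[Rcpp::export(name = ".psi_expected_entropy_cpp")]]
NumericVector psi_expected_entropy_cpp(NumericMatrix L, NumericVector post) {
  int nc = L.nrow(), nn = L.ncol();
  NumericVector eh(nc);
  for (int c = 0; c < nc; c++) {
    double pc = 0.0, s1 = 0.0, s0 = 0.0;
    for (int j = 0; j < nn; j++) {
      double m1 = post[j] * L(c, j);
      double m0 = post[j] - m1;
      pc += m1;
      if (m1 > 0.0) s1 += m1 * std::log(m1);
      if (m0 > 0.0) s0 += m0 * std::log(m0);
    }
    double h = -(s1 + s0);
    if (pc > 0.0) h += pc * std::log(pc);
    if (pc < 1.0) h += (1.0 - pc) * std::log(1.0 - pc);
    eh[c] = h;
  }
  return eh;
}
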