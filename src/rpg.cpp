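#include <Rcpp.h>
using namespace Rcpp;

// Exact sampler for the Polya-Gamma distribution PG(1, z), following the
// alternating-series rejection scheme of Devroye (2009) as adapted for
// logistic models by Polson, Scott & Windle (2013).  A draw J* from the
// tilted Jacobi distribution is returned as J*/4, which is PG(1, z).
// Uses R's RNG so that set.seed() governs reproducibility.

static const double TRUNC = 0.64;          // series switch point t
static const double PISQ8 = M_PI * M_PI / 8.0;

// coefficients a_n(x) of the alternating series for the Jacobi density
static double a_coef(int n, double x) {
  double np = n + 0.5;
  if (x > TRUNC)
    return M_PI * np * std::exp(-np * np * M_PI * M_PI * x / 2.0);
  return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np * np / x);
}

// CDF of inverse-Gaussian(mu = 1/z, lambda = 1) at t, z >= 0
static double pigauss(double t, double z) {
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  return R::pnorm(b, 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(a, 0.0, 1.0, 1, 0);
}

// Inverse-Gaussian(1/z, 1) truncated to (0, t]
static double rtigauss(double z, double t) {
  double x = t + 1.0;
  if (1.0 / z > t) {              // mu > t: rejection from scaled inv-chi^2
    double alpha = 0.0;
    while (R::runif(0.0, 1.0) > alpha) {
      double e1 = R::exp_rand(), e2 = R::exp_rand();
      while (e1 * e1 > 2.0 * e2 / t) {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      }
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = R::norm_rand();
      y = y * y;
      double half = 0.5 * mu;
      x = mu + half * mu * y -
          half * std::sqrt(4.0 * mu * y + (mu * y) * (mu * y));
      if (R::runif(0.0, 1.0) > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// one draw from PG(1, z)
static double rpg_one(double z) {
  z = std::fabs(z) * 0.5;
  double k = PISQ8 + z * z / 2.0;
  double p = (M_PI / (2.0 * k)) * std::exp(-k * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);

  for (;;) {
    double x;
    if (R::runif(0.0, 1.0) < p / (p + q))
      x = TRUNC + R::exp_rand() / k;       // truncated exponential tail
    else
      x = rtigauss(z, TRUNC);              // truncated inverse-Gaussian body
    double s = a_coef(0, x);
    double y = R::runif(0.0, 1.0) * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x);
        if (y > s) break;                  // reject, redraw proposal
      }
    }
  }
}

//' Draw Polya-Gamma PG(1, z) variates
//'
//' @param z numeric vector of tilting parameters (the linear predictors).
//' @return numeric vector of the same length with one PG(1, z_i) draw each.
//' @keywords internal
// [[Rcpp::export(name = ".rpg_vec")]]
NumericVector rpg_vec(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg_one(z[i]);
  return out;
}
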