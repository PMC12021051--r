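#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Training-loop kernel: mean ZINB negative log-likelihood plus its gradient
// with respect to the head pre-activations (logit pi, log mu, log theta),
// with the numerical-safety clamps applied inside (clamped entries carry
// zero gradient). One pass, no intermediate allocations; the reference R
// implementation in R/losses.R is the oracle this kernel is tested against.
//
// Pre-activation clamp ranges match R/model.R:
//   pi    in [1e-6, 1 - 1e-6]  (on the logit scale)
//   mu,th in [1e-5, 1e6]       (on the log scale)

// [[Rcpp::export]]
List zinb_loss_grad_cpp(NumericVector x, NumericVector ppi,
                        NumericVector pmu, NumericVector pth) {
  const R_xlen_t n = x.size();
  if (ppi.size() != n || pmu.size() != n || pth.size() != n)
    stop("shape mismatch in ZINB kernel");
  const double pi_lo = std::log(1e-6) - std::log1p(-1e-6);   // qlogis(1e-6)
  const double pi_hi = -pi_lo;
  const double log_lo = std::log(1e-5), log_hi = std::log(1e6);
  NumericVector gpi(n), gmu(n), gth(n);
  double nll = 0.0;
  // log-factorial table (counts are small integers; values beyond the table
  // fall back to lgamma)
  int maxx = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] > maxx && x[i] == std::floor(x[i]) && x[i] < 4096) {
      maxx = (int)x[i];
    }
  }
  std::vector<double> lfact(maxx + 1, 0.0);
  for (int v = 2; v <= maxx; ++v) lfact[v] = lfact[v - 1] + std::log((double)v);
  for (R_xlen_t i = 0; i < n; ++i) {
    double zpi = ppi[i], zmu = pmu[i], zth = pth[i];
    bool open_pi = zpi > pi_lo && zpi < pi_hi;
    bool open_mu = zmu > log_lo && zmu < log_hi;
    bool open_th = zth > log_lo && zth < log_hi;
    if (!open_pi) zpi = (zpi <= pi_lo) ? pi_lo : pi_hi;
    if (!open_mu) zmu = (zmu <= log_lo) ? log_lo : log_hi;
    if (!open_th) zth = (zth <= log_lo) ? log_lo : log_hi;
    const double p = 1.0 / (1.0 + std::exp(-zpi));
    const double m = std::exp(zmu);
    const double t = std::exp(zth);
    const double tm = t + m;
    const double log_r = std::log(t) - std::log(tm);
    const double xi = x[i];
    if (xi == 0.0) {
      const double a = std::log(p);
      const double b = std::log1p(-p) + t * log_r;
      const double mx = a > b ? a : b;
      nll -= mx + std::log(std::exp(a - mx) + std::exp(b - mx));
      const double rt = std::exp(t * log_r);
      const double p0 = p + (1.0 - p) * rt;
      if (open_pi) gpi[i] = -p * (1.0 - p) * (1.0 - rt) / p0;
      if (open_mu) gmu[i] = m * (1.0 - p) * t * rt / (tm * p0);
      if (open_th) gth[i] = -t * (1.0 - p) * rt * (log_r + m / tm) / p0;
    } else {
      // lgamma(x+t)-lgamma(t) = sum_{j<x} log(t+j);
      // digamma(x+t)-digamma(t) = sum_{j<x} 1/(t+j)  (x integer)
      double lgam_diff, digam_diff, lfx;
      const bool small_int = xi == std::floor(xi) && xi <= 64.0;
      if (small_int) {
        lgam_diff = 0.0; digam_diff = 0.0;
        for (int j = 0; j < (int)xi; ++j) {
          const double tj = t + (double)j;
          lgam_diff += std::log(tj);
          digam_diff += 1.0 / tj;
        }
        lfx = ((int)xi <= maxx) ? lfact[(int)xi] : std::lgamma(xi + 1.0);
      } else {
        lgam_diff = std::lgamma(xi + t) - std::lgamma(t);
        digam_diff = R::digamma(xi + t) - R::digamma(t);
        lfx = std::lgamma(xi + 1.0);
      }
      nll -= std::log1p(-p) + lgam_diff - lfx + t * log_r
             + xi * (std::log(m) - std::log(tm));
      if (open_pi) gpi[i] = p;
      if (open_mu) gmu[i] = -(xi - m * (xi + t) / tm);
      if (open_th) gth[i] = -t * (digam_diff + log_r + 1.0 - t / tm
                                  - xi / tm);
    }
  }
  SEXP dm = x.attr("dim");
  if (!Rf_isNull(dm)) {
    gpi.attr("dim") = dm; gmu.attr("dim") = dm; gth.attr("dim") = dm;
  }
  return List::create(_["nll"] = nll / (double)n, _["d_ppi"] = gpi,
                      _["d_pmu"] = gmu, _["d_pth"] = gth);
}
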