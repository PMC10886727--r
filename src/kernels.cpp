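// Inner kernels for windowed pairwise phase-connectivity metrics.
// Layout convention: `analytic` is samples x channels x trials; `pairs` is
// P x 2 with 0-based channel indices; `windows` is W x 2 half-open 0-based
// sample ranges. Returns pairs x windows x trials arrays.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// [[Rcpp::export]]
Rcpp::List pair_metrics_cpp(const arma::cx_cube& analytic,
                            const arma::umat& pairs,
                            const arma::umat& windows,
                            const bool do_plv,
                            const bool do_wpli) {
  const uword n_samples = analytic.n_rows;
  const uword n_trials = analytic.n_slices;
  const uword P = pairs.n_rows;
  const uword W = windows.n_rows;

  for (uword w = 0; w < W; ++w)
    if (windows(w, 1) > n_samples || windows(w, 0) >= windows(w, 1))
      Rcpp::stop("window out of range");

  cube plv_out, wpli_out, degen_out;
  if (do_plv) plv_out.zeros(P, W, n_trials);
  if (do_wpli) { wpli_out.zeros(P, W, n_trials); degen_out.zeros(P, W, n_trials); }

  cx_mat unit;
  for (uword t = 0; t < n_trials; ++t) {
    const cx_mat& slice = analytic.slice(t);
    if (do_plv) {
      // unit phasors per channel, computed once per trial
      unit = slice;
      for (uword c = 0; c < unit.n_cols; ++c)
        for (uword s = 0; s < n_samples; ++s) {
          double m = std::abs(unit(s, c));
          unit(s, c) = (m > 0.0) ? unit(s, c) / m : cx_double(0.0, 0.0);
        }
    }
    for (uword p = 0; p < P; ++p) {
      const uword i = pairs(p, 0), j = pairs(p, 1);
      for (uword w = 0; w < W; ++w) {
        const uword a = windows(w, 0), b = windows(w, 1);
        if (do_plv) {
          cx_double acc(0.0, 0.0);
          uword n_ok = 0;
          const cx_double* xi = unit.colptr(i);
          const cx_double* xj = unit.colptr(j);
          for (uword s = a; s < b; ++s) {
            if (xi[s] != cx_double(0.0, 0.0) && xj[s] != cx_double(0.0, 0.0)) {
              acc += xi[s] * std::conj(xj[s]);
              ++n_ok;
            }
          }
          double v = (n_ok > 0) ? std::abs(acc) / double(n_ok) : 0.0;
          plv_out(p, w, t) = std::min(v, 1.0);
        }
        if (do_wpli) {
          double num = 0.0, den = 0.0;
          const cx_double* xi = slice.colptr(i);
          const cx_double* xj = slice.colptr(j);
          for (uword s = a; s < b; ++s) {
            double im = std::imag(xi[s] * std::conj(xj[s]));
            num += im;
            den += std::fabs(im);
          }
          if (den == 0.0) {
            wpli_out(p, w, t) = 0.0;
            degen_out(p, w, t) = 1.0;
          } else {
            wpli_out(p, w, t) = std::min(std::fabs(num) / den, 1.0);
          }
        }
      }
    }
  }

  Rcpp::List out;
  if (do_plv) out["plv"] = plv_out;
  if (do_wpli) {
    out["wpli"] = wpli_out;
    Rcpp::LogicalVector flag(degen_out.begin(), degen_out.end());
    flag.attr("dim") = Rcpp::IntegerVector::create(P, W, n_trials);
    out["degenerate"] = flag;
  }
  return out;
}
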