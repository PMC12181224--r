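#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// First-order relaxation with per-step target and rate:
//   w[n] = w[n-1] + eta[n] * (fp[n] - w[n-1])
// Covers the 1D FPLR rule and the SBC decay rules once fp/eta are expressed
// per time step.
// [[Rcpp::export]]
NumericVector relax_integrate_cpp(NumericVector fp, NumericVector eta, double w0) {
  R_xlen_t n = fp.size();
  NumericVector w(n);
  double cur = w0;
  for (R_xlen_t i = 0; i < n; ++i) {
    cur += eta[i] * (fp[i] - cur);
    w[i] = cur;
  }
  return w;
}

// Original Graupner-Brunel update, noise term omitted.
// region codes per step: 0 = pre-depressive, 1 = depressive, 2 = potentiative.
// tau * dw = -w(1-w)(w* - w) [- eta_d * w] [+ eta_p * (1-w)]
// [[Rcpp::export]]
NumericVector gb_integrate_cpp(IntegerVector region, double w0, double w_star,
                               double eta_d, double eta_p, double tau) {
  R_xlen_t n = region.size();
  NumericVector w(n);
  double cur = w0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double d = -cur * (1.0 - cur) * (w_star - cur);
    int reg = region[i];
    if (reg >= 1) d -= eta_d * cur;
    if (reg >= 2) d += eta_p * (1.0 - cur);
    cur += d / tau;
    w[i] = cur;
  }
  return w;
}

// Simplified Graupner-Brunel update: exactly one branch active per step.
// [[Rcpp::export]]
NumericVector gb_simplified_integrate_cpp(IntegerVector region, double w0,
                                          double w_star, double eta_drift,
                                          double eta_d, double eta_p) {
  R_xlen_t n = region.size();
  NumericVector w(n);
  double cur = w0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int reg = region[i];
    if (reg == 2) {
      cur += eta_p * (1.0 - cur);
    } else if (reg == 1) {
      cur += -eta_d * cur;
    } else {
      if (cur < w_star) cur += -eta_drift * cur;
      else if (cur > w_star) cur += eta_drift * (1.0 - cur);
      // cur == w_star: unstable fixed point, no change
    }
    w[i] = cur;
  }
  return w;
}

namespace {

struct RegionSpec {
  bool basin;
  double F;
  double eta;
  std::vector<double> bounds;
  std::vector<double> fps;
  std::vector<double> rates;
  std::vector<int> bmode; // 0 unstable, 1 joins left basin, 2 joins right basin
};

std::vector<RegionSpec> parse_regions(List regions) {
  std::vector<RegionSpec> out;
  for (R_xlen_t k = 0; k < regions.size(); ++k) {
    List rk = regions[k];
    RegionSpec rs;
    rs.basin = as<bool>(rk["basin"]);
    if (rs.basin) {
      rs.bounds = as<std::vector<double> >(rk["boundaries"]);
      rs.fps = as<std::vector<double> >(rk["fixed_points"]);
      rs.rates = as<std::vector<double> >(rk["learning_rates"]);
      rs.bmode = as<std::vector<int> >(rk["boundary_mode"]);
      rs.F = 0.0; rs.eta = 0.0;
    } else {
      rs.F = as<double>(rk["F"]);
      rs.eta = as<double>(rk["eta"]);
    }
    out.push_back(rs);
  }
  return out;
}

// One weight update under a possibly basin-structured region.
inline double step_region(const RegionSpec &rs, double w, double tol) {
  if (!rs.basin) return w + rs.eta * (rs.F - w);
  const std::vector<double> &b = rs.bounds;
  size_t nb = b.size();
  if (w < b[0] - tol || w > b[nb - 1] + tol)
    stop("weight %f outside basin range [%f, %f]", w, b[0], b[nb - 1]);
  // boundary handling
  for (size_t j = 0; j < nb; ++j) {
    if (std::fabs(w - b[j]) <= tol) {
      int mode = rs.bmode[j];
      if (mode == 0) return w;                       // unstable fixed point
      size_t k = (mode == 1) ? (j == 0 ? 0 : j - 1)  // half-stable: left basin
                             : (j >= nb - 1 ? nb - 2 : j); // right basin
      return w + rs.rates[k] * (rs.fps[k] - w);
    }
  }
  size_t k = 0;
  while (k + 2 < nb && w > b[k + 1]) ++k;
  return w + rs.rates[k] * (rs.fps[k] - w);
}

} // namespace

// 2D FPLR rule: per-step calcium region index (0-based) selects either a
// scalar (F, eta) pair or a basin specification evaluated at the current w.
// [[Rcpp::export]]
NumericVector fplr2d_integrate_cpp(IntegerVector region, double w0,
                                   List regions, double tol) {
  std::vector<RegionSpec> rs = parse_regions(regions);
  R_xlen_t n = region.size();
  NumericVector w(n);
  double cur = w0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int k = region[i];
    if (k < 0 || k >= (int)rs.size()) stop("region index out of range");
    cur = step_region(rs[k], cur, tol);
    w[i] = cur;
  }
  return w;
}

// Protein-gated rule: protein[i] == 0 dispatches to the 1D rule whose
// per-step fixed points / rates are precomputed in fp1/eta1; protein[i] == 1
// dispatches to the 2D rule given by `regions` and the per-step region index.
// [[Rcpp::export]]
NumericVector protein_integrate_cpp(IntegerVector region, IntegerVector protein,
                                    NumericVector fp1, NumericVector eta1,
                                    List regions, double w0, double tol) {
  std::vector<RegionSpec> rs = parse_regions(regions);
  R_xlen_t n = region.size();
  NumericVector w(n);
  double cur = w0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (protein[i] == 0) {
      cur += eta1[i] * (fp1[i] - cur);
    } else {
      int k = region[i];
      if (k < 0 || k >= (int)rs.size()) stop("region index out of range");
      cur = step_region(rs[k], cur, tol);
    }
    w[i] = cur;
  }
  return w;
}
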