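#include <Rcpp.h>
using namespace Rcpp;

// Term-table right-hand side for a candidate growth structure.
// Each row of `terms`: form, sign, target, x, y, offset
//   form: 0 const, 1 linear, 2 quadratic, 3 product, 4 mm_act, 5 mm_rep
//   sign: +1 production, -1 consumption
//   target/x/y: state indices 0..3 (G,P,Q,N); -1 if unused
//   offset: 0-based index of the term's first parameter
static inline void rhs(const IntegerMatrix& terms, const double* p,
                       const double* y, double* d) {
  d[0] = d[1] = d[2] = d[3] = 0.0;
  double yc[4];
  for (int s = 0; s < 4; ++s) yc[s] = y[s] > 0.0 ? y[s] : 0.0;
  const int nt = terms.nrow();
  for (int t = 0; t < nt; ++t) {
    const int form = terms(t, 0), sign = terms(t, 1), tg = terms(t, 2);
    const int xi = terms(t, 3), yi = terms(t, 4), off = terms(t, 5);
    double r = 0.0;
    const double xv = xi >= 0 ? yc[xi] : 0.0;
    switch (form) {
    case 0: r = p[off]; break;
    case 1: r = p[off] * xv; break;
    case 2: r = p[off] * xv * xv; break;
    case 3: r = p[off] * xv * (yi >= 0 ? yc[yi] : 0.0); break;
    case 4: r = p[off] * xv / (p[off + 1] + xv); break;
    case 5: r = p[off] * p[off + 1] / (p[off + 1] + xv); break;
    }
    d[tg] += sign * r;
  }
}

//' Fixed-step RK4 integration of a term-table structure (internal).
//'
//' Returns the G (growth-rate modulator) trajectory on the output grid
//' `0, dt, ..., (n_out-1)*dt`, or NA-filled from the first non-finite or
//' exploding state onward.
//'
//' @param terms integer term table (see candidate_structure).
//' @param params parameter vector.
//' @param init initial state (G, P, Q, N).
//' @param dt output step (hours).
//' @param n_out number of output points.
//' @param substeps RK4 substeps per output step.
//' @keywords internal
// [[Rcpp::export]]
NumericVector structure_mu_rk4(IntegerMatrix terms, NumericVector params,
                               NumericVector init, double dt, int n_out,
                               int substeps = 2) {
  NumericVector out(n_out, NA_REAL);
  double y[4], k1[4], k2[4], k3[4], k4[4], tmp[4];
  for (int s = 0; s < 4; ++s) y[s] = init[s];
  const double* p = params.begin();
  const double h = dt / substeps;
  out[0] = y[0];
  for (int i = 1; i < n_out; ++i) {
    for (int sub = 0; sub < substeps; ++sub) {
      rhs(terms, p, y, k1);
      for (int s = 0; s < 4; ++s) tmp[s] = y[s] + 0.5 * h * k1[s];
      rhs(terms, p, tmp, k2);
      for (int s = 0; s < 4; ++s) tmp[s] = y[s] + 0.5 * h * k2[s];
      rhs(terms, p, tmp, k3);
      for (int s = 0; s < 4; ++s) tmp[s] = y[s] + h * k3[s];
      rhs(terms, p, tmp, k4);
      for (int s = 0; s < 4; ++s)
        y[s] += h / 6.0 * (k1[s] + 2.0 * k2[s] + 2.0 * k3[s] + k4[s]);
    }
    bool bad = false;
    for (int s = 0; s < 4; ++s)
      if (!R_finite(y[s]) || std::abs(y[s]) > 1e8) bad = true;
    if (bad) return out;            // NA from here on signals failure
    out[i] = y[0];
  }
  return out;
}
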