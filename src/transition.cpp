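#include <Rcpp.h>
using namespace Rcpp;

// Dense multinomial transition matrix between genotypic states.
//
// logf:    S x 3 log category probabilities per source state (log(0) as
//          -Inf is fine: a zero-probability category only contributes
//          when the target count is positive, and then n * -Inf = -Inf,
//          exp -> 0).
// counts:  S x 3 integer target-state counts (n_aa, n_aA, n_AA).
// logcoef: length-S multinomial log coefficients
//          lgamma(N+1) - sum_k lgamma(counts_k + 1) per target state.
//
// Rows are renormalised to sum exactly 1; the maximum pre-normalisation
// deviation |rowsum - 1| is returned as attribute "max_row_drift" so the
// caller can assert it is pure rounding (~1e-15), not a model error.
// [[Rcpp::export]]
NumericMatrix build_transition_cpp(NumericMatrix logf, IntegerMatrix counts,
                                   NumericVector logcoef) {
  const int S = counts.nrow();
  if (logf.nrow() != S || logcoef.size() != S)
    stop("dimension mismatch between states and frequencies");
  NumericMatrix P(S, S);
  const int *n0 = &counts(0, 0), *n1 = &counts(0, 1), *n2 = &counts(0, 2);
  const double *lc = &logcoef[0];
  double max_drift = 0.0;
  for (int i = 0; i < S; ++i) {
    const double l0 = logf(i, 0), l1 = logf(i, 1), l2 = logf(i, 2);
    double *row = &P(0, 0) + (R_xlen_t)i; // column-major: stride S
    double s = 0.0, comp = 0.0;           // Kahan-compensated row sum
    for (int j = 0; j < S; ++j) {
      double lp = lc[j];
      if (n0[j]) lp += n0[j] * l0;
      if (n1[j]) lp += n1[j] * l1;
      if (n2[j]) lp += n2[j] * l2;
      double p = std::exp(lp);
      row[(R_xlen_t)j * S] = p;
      double y = p - comp;
      double t = s + y;
      comp = (t - s) - y;
      s = t;
    }
    double drift = std::fabs(s - 1.0);
    if (drift > max_drift) max_drift = drift;
    const double inv = 1.0 / s;
    for (int j = 0; j < S; ++j) row[(R_xlen_t)j * S] *= inv;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  P.attr("max_row_drift") = max_drift;
  return P;
}

// One multinomial transition row (same convention), renormalised.
// [[Rcpp::export]]
NumericVector transition_row_cpp(NumericVector logf, IntegerMatrix counts,
                                 NumericVector logcoef) {
  const int S = counts.nrow();
  NumericVector row(S);
  double s = 0.0, comp = 0.0;             // Kahan-compensated sum
  for (int j = 0; j < S; ++j) {
    double lp = logcoef[j];
    if (counts(j, 0)) lp += counts(j, 0) * logf[0];
    if (counts(j, 1)) lp += counts(j, 1) * logf[1];
    if (counts(j, 2)) lp += counts(j, 2) * logf[2];
    row[j] = std::exp(lp);
    double y = row[j] - comp;
    double t = s + y;
    comp = (t - s) - y;
    s = t;
  }
  row.attr("max_row_drift") = std::fabs(s - 1.0);
  for (int j = 0; j < S; ++j) row[j] /= s;
  return row;
}
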