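#include <Rcpp.h>
using namespace Rcpp;

// Draw one gene row of zero-inflated negative binomial counts.
//
// Cells are laid out individual-by-individual (nCell cells each).  Per cell:
// a log-mean is drawn Normal(mu_j, sigma_j^2), shifted by the cell's log
// size factor and clipped to [lo, hi]; with probability pzero_j the count is
// an inflated zero, otherwise NB with mean exp(log-mean) and size phi_j
// (variance m + m^2/phi).  Exactly one normal and one uniform deviate are
// consumed per cell ahead of the NB draw, so streams for different parameter
// values stay aligned up to the first cell whose parameters differ.
// [[Rcpp::export(name = ".zinb_emit_row")]]
IntegerVector zinb_emit_row(NumericVector mu, NumericVector sigma,
                            NumericVector phi, NumericVector pzero,
                            int nCell, NumericVector cellLogSf,
                            double lo, double hi) {
  const int N = mu.size();
  IntegerVector out(N * nCell);
  int clipped = 0;
  int col = 0;
  for (int j = 0; j < N; ++j) {
    const double mj = mu[j], sj = sigma[j], pj = pzero[j], fj = phi[j];
    for (int c = 0; c < nCell; ++c, ++col) {
      double lm = mj + sj * norm_rand() + cellLogSf[col];
      if (lm < lo) { lm = lo; ++clipped; }
      else if (lm > hi) { lm = hi; ++clipped; }
      const double u = unif_rand();
      if (u < pj) {
        out[col] = 0;
      } else {
        const double m = std::exp(lm);
        out[col] = (int) R::rnbinom(fj, fj / (fj + m));
      }
    }
  }
  out.attr("clipped") = clipped;
  return out;
}

// Per-(gene, individual) non-zero summaries of a dense genes x cells matrix:
// number of non-zero cells, sum and sum of squares of the non-zero values.
// `group` holds the 1-based individual index of each cell.
// [[Rcpp::export(name = ".group_stats_dense")]]
List group_stats_dense(NumericMatrix X, IntegerVector group, int nGroups) {
  const int M = X.nrow(), C = X.ncol();
  NumericMatrix nnz(M, nGroups), s1(M, nGroups), s2(M, nGroups);
  for (int c = 0; c < C; ++c) {
    const int g = group[c] - 1;
    const double* xc = &X(0, c);
    double* nz = &nnz(0, g);
    double* a = &s1(0, g);
    double* b = &s2(0, g);
    for (int i = 0; i < M; ++i) {
      const double v = xc[i];
      if (v != 0) { nz[i] += 1.0; a[i] += v; b[i] += v * v; }
    }
  }
  return List::create(_["nnz"] = nnz, _["sum"] = s1, _["sumsq"] = s2);
}

// Same summaries for a column-compressed sparse matrix given by its slots.
// Explicitly stored zeros (legal in dgCMatrix) are skipped.
// [[Rcpp::export(name = ".group_stats_sparse")]]
List group_stats_sparse(IntegerVector p, IntegerVector i, NumericVector x,
                        int M, IntegerVector group, int nGroups) {
  const int C = p.size() - 1;
  NumericMatrix nnz(M, nGroups), s1(M, nGroups), s2(M, nGroups);
  for (int c = 0; c < C; ++c) {
    const int g = group[c] - 1;
    for (int k = p[c]; k < p[c + 1]; ++k) {
      const double v = x[k];
      if (v != 0) {
        const int row = i[k];
        nnz(row, g) += 1.0;
        s1(row, g) += v;
        s2(row, g) += v * v;
      }
    }
  }
  return List::create(_["nnz"] = nnz, _["sum"] = s1, _["sumsq"] = s2);
}
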