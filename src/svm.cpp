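// Linear L1 soft-margin C-SVC via SMO (maximal violating pair working-set
// selection on the dual), plus batched cross-validated decoding loops used
// by the time-resolved and searchlight analyses. Small-n regime: the full
// kernel matrix is precomputed (pseudo-trial counts are tens, not thousands).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct SvmFit {
  vec alpha;
  vec w;
  double b;
  int iter;
  bool converged;
};

// X: n x d, y in {-1,+1}. Solves the dual of
//   min 1/2 ||w||^2 + C sum xi   s.t.  y_i (w.x_i + b) >= 1 - xi
// and returns multipliers plus the primal w = sum alpha_i y_i x_i.
SvmFit smo_linear(const mat& X, const vec& y, double C, double tol,
                  int max_iter) {
  const int n = X.n_rows;
  const double TAU = 1e-12;
  mat K = X * X.t();
  mat Q(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) Q(i, j) = y(i) * y(j) * K(i, j);
  vec alpha(n, fill::zeros);
  vec G(n, fill::value(-1.0));   // gradient of 1/2 a'Qa - e'a

  int it = 0;
  bool conv = false;
  for (; it < max_iter; ++it) {
    int i = -1, j = -1;
    double gmax = -datum::inf, gmin = datum::inf;
    for (int t = 0; t < n; ++t) {
      bool up = (y(t) > 0) ? (alpha(t) < C) : (alpha(t) > 0);
      bool lo = (y(t) > 0) ? (alpha(t) > 0) : (alpha(t) < C);
      double v = -y(t) * G(t);
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) { conv = true; break; }

    double ai_old = alpha(i), aj_old = alpha(j);
    if (y(i) != y(j)) {
      double quad = Q(i, i) + Q(j, j) + 2.0 * Q(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-G(i) - G(j)) / quad;
      double diff = alpha(i) - alpha(j);
      alpha(i) += delta;
      alpha(j) += delta;
      if (diff > 0) { if (alpha(j) < 0) { alpha(j) = 0; alpha(i) = diff; } }
      else          { if (alpha(i) < 0) { alpha(i) = 0; alpha(j) = -diff; } }
      if (diff > 0) { if (alpha(i) > C) { alpha(i) = C; alpha(j) = C - diff; } }
      else          { if (alpha(j) > C) { alpha(j) = C; alpha(i) = C + diff; } }
    } else {
      double quad = Q(i, i) + Q(j, j) - 2.0 * Q(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G(i) - G(j)) / quad;
      double sum = alpha(i) + alpha(j);
      alpha(i) -= delta;
      alpha(j) += delta;
      if (sum > C) { if (alpha(i) > C) { alpha(i) = C; alpha(j) = sum - C; } }
      else         { if (alpha(j) < 0) { alpha(j) = 0; alpha(i) = sum; } }
      if (sum > C) { if (alpha(j) > C) { alpha(j) = C; alpha(i) = sum - C; } }
      else         { if (alpha(i) < 0) { alpha(i) = 0; alpha(j) = sum; } }
    }
    double dai = alpha(i) - ai_old, daj = alpha(j) - aj_old;
    for (int t = 0; t < n; ++t) G(t) += Q(t, i) * dai + Q(t, j) * daj;
  }

  SvmFit f;
  f.alpha = alpha;
  f.w = X.t() * (alpha % y);
  // bias: KKT on free SVs (y_t (w.x_t + b) = 1); else midpoint of the
  // feasible interval implied by the bound SVs
  vec wx = X * f.w;
  double s = 0; int nf = 0;
  double hi = datum::inf, lo = -datum::inf;
  for (int t = 0; t < n; ++t) {
    double bt = y(t) - wx(t);
    if (alpha(t) > TAU && alpha(t) < C - TAU) { s += bt; ++nf; }
    else if (alpha(t) <= TAU) {
      // y_t (wx + b) >= 1
      if (y(t) > 0) lo = std::max(lo, bt); else hi = std::min(hi, bt);
    } else {
      // alpha = C: y_t (wx + b) <= 1
      if (y(t) > 0) hi = std::min(hi, bt); else lo = std::max(lo, bt);
    }
  }
  if (nf > 0) f.b = s / nf;
  else if (std::isfinite(hi) && std::isfinite(lo)) f.b = (hi + lo) / 2.0;
  else if (std::isfinite(hi)) f.b = hi;
  else if (std::isfinite(lo)) f.b = lo;
  else f.b = 0.0;
  f.iter = it;
  f.converged = conv;
  return f;
}

// z-score columns using train stats; zero-variance features left centered
void standardize_cols(mat& tr, mat& te) {
  rowvec mu = mean(tr, 0);
  rowvec sd = stddev(tr, 0, 0);
  sd.elem(find(sd < 1e-300)).ones();
  tr.each_row() -= mu; tr.each_row() /= sd;
  te.each_row() -= mu; te.each_row() /= sd;
}

} // namespace

// [[Rcpp::export(name = ".cpp_svm_fit")]]
Rcpp::List cpp_svm_fit(const arma::mat& X, const arma::vec& y, double C,
                       double tol, int max_iter) {
  SvmFit f = smo_linear(X, y, C, tol, max_iter);
  return Rcpp::List::create(
      Rcpp::Named("alpha") = f.alpha, Rcpp::Named("w") = f.w,
      Rcpp::Named("b") = f.b, Rcpp::Named("iter") = f.iter,
      Rcpp::Named("converged") = f.converged);
}

// Cross-validated decoding at every slice of a trials x features x slices
// cube. folds: 1-based fold id per observation. Returns pooled confusion
// counts per slice (tp, fn, fp, tn) with class +1 as "positive".
// standardize: 0 none, 1 train-fold stats (the shipped path), 2 pooled
// train+test stats (the deliberately leaky variant kept for the
// no-leakage control experiment).
// [[Rcpp::export(name = ".cpp_cv_cube")]]
arma::mat cpp_cv_cube(const arma::cube& X, const arma::vec& y,
                      const arma::ivec& folds, double C, int standardize,
                      double tol, int max_iter) {
  const int nslice = X.n_slices;
  const int nfold = folds.max();
  mat out(nslice, 4, fill::zeros); // tp fn fp tn
  for (int s = 0; s < nslice; ++s) {
    const mat& Xs = X.slice(s);
    for (int f = 1; f <= nfold; ++f) {
      uvec te = find(folds == f);
      uvec tr = find(folds != f);
      if (te.n_elem == 0) continue;
      mat Xtr = Xs.rows(tr), Xte = Xs.rows(te);
      if (standardize == 1) {
        standardize_cols(Xtr, Xte);
      } else if (standardize == 2) {
        rowvec mu = mean(Xs, 0);
        rowvec sd = stddev(Xs, 0, 0);
        sd.elem(find(sd < 1e-300)).ones();
        Xtr.each_row() -= mu; Xtr.each_row() /= sd;
        Xte.each_row() -= mu; Xte.each_row() /= sd;
      }
      SvmFit fit = smo_linear(Xtr, y.elem(tr), C, tol, max_iter);
      vec dec = Xte * fit.w + fit.b;
      for (unsigned k = 0; k < te.n_elem; ++k) {
        bool pos = dec(k) >= 0;
        bool truth = y(te(k)) > 0;
        if (truth && pos)       out(s, 0) += 1;
        else if (truth)         out(s, 1) += 1;
        else if (pos)           out(s, 2) += 1;
        else                    out(s, 3) += 1;
      }
    }
  }
  return out;
}

// Label-permutation null for the cross-validated timecourse: each column of
// ymat is one permuted {-1,+1} labeling with its own stratified fold
// assignment (column of foldmat). Returns n_perm x n_slices accuracies.
// [[Rcpp::export(name = ".cpp_null_cube")]]
arma::mat cpp_null_cube(const arma::cube& X, const arma::mat& ymat,
                        const arma::imat& foldmat, double C, int standardize,
                        double tol, int max_iter) {
  const int nperm = ymat.n_cols;
  const int nslice = X.n_slices;
  mat out(nperm, nslice);
  for (int p = 0; p < nperm; ++p) {
    mat conf = cpp_cv_cube(X, ymat.col(p), foldmat.col(p), C, standardize,
                           tol, max_iter);
    for (int s = 0; s < nslice; ++s) {
      double tot = accu(conf.row(s));
      out(p, s) = (conf(s, 0) + conf(s, 3)) / tot;
    }
  }
  return out;
}
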