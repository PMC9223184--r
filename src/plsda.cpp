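// Cross-validated PLS-DA misclassification rate via SIMPLS.
//
// This is the fitness evaluator behind the stochastic wavelength selectors,
// which score on the order of 10^4-10^5 candidate subsets per run; the SIMPLS
// fit and the fold loop therefore live in compiled code, and a batch entry
// point amortizes call overhead across many subsets. Classification is by
// nearest class centroid in score space, accumulated component by component,
// so one fit scores every component count; the reported fitness is the
// minimum over component counts (CV choice of the component number). The
// centroid rule, unlike indicator-argmax, handles middle classes of ordered
// grades lying along one latent direction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct FoldSplit {
  uvec tr, te;
};

// CV error of one column subset. y coded 1..g, fold 1..k.
double cv_error_subset(const mat& X, const ivec& y,
                       const std::vector<FoldSplit>& folds,
                       const uvec& cols, int g, int max_comp) {
  const uword n = X.n_rows;
  const uword p = cols.n_elem;
  vec errs(static_cast<uword>(max_comp), fill::zeros);
  uword a_max_global = 0;

  for (const FoldSplit& fs : folds) {
    const uword ntr = fs.tr.n_elem, nte = fs.te.n_elem;
    if (nte == 0) continue;
    mat Xtr = X.submat(fs.tr, cols);
    mat Xte = X.submat(fs.te, cols);
    rowvec xm = mean(Xtr, 0);
    Xtr.each_row() -= xm;
    Xte.each_row() -= xm;

    mat Y(ntr, static_cast<uword>(g), fill::zeros);
    vec clcount(static_cast<uword>(g), fill::zeros);
    for (uword i = 0; i < ntr; ++i) {
      Y(i, y(fs.tr(i)) - 1) = 1.0;
      clcount(y(fs.tr(i)) - 1) += 1.0;
    }
    rowvec ym = mean(Y, 0);
    mat Yc = Y;
    Yc.each_row() -= ym;

    uword A = std::min<uword>(static_cast<uword>(max_comp),
                              std::min<uword>(p, ntr - 1));
    mat S = Xtr.t() * Yc;                 // p x g
    mat V(p, A, fill::zeros);
    mat dist2(nte, static_cast<uword>(g), fill::zeros);
    ivec last_pred(nte, fill::ones);

    uword a_done = 0;
    for (uword a = 0; a < A; ++a) {
      mat StS = S.t() * S;
      vec eval;
      mat evec;
      if (!eig_sym(eval, evec, StS)) break;
      vec q = evec.col(evec.n_cols - 1);
      vec r = S * q;
      vec t = Xtr * r;
      double nt = norm(t);
      if (nt < 1e-10) break;
      t /= nt;
      r /= nt;
      vec pl = Xtr.t() * t;
      vec v = pl;
      if (a > 0) {
        vec proj = V.cols(0, a - 1).t() * pl;
        v -= V.cols(0, a - 1) * proj;
      }
      double nv = norm(v);
      if (nv < 1e-10) break;
      v /= nv;
      V.col(a) = v;
      S -= v * (v.t() * S);

      // class centroids of the training scores on this component
      vec cen(static_cast<uword>(g), fill::zeros);
      for (uword i = 0; i < ntr; ++i) cen(y(fs.tr(i)) - 1) += t(i);
      for (int c = 0; c < g; ++c)
        cen(c) = clcount(c) > 0 ? cen(c) / clcount(c) : datum::inf;

      vec tte = Xte * r;
      uword nerr = 0;
      for (uword i = 0; i < nte; ++i) {
        uword best = 0;
        double dbest = datum::inf;
        for (int c = 0; c < g; ++c) {
          double d = tte(i) - cen(c);
          dist2(i, c) += d * d;
          if (dist2(i, c) < dbest) { dbest = dist2(i, c); best = c; }
        }
        last_pred(i) = static_cast<int>(best) + 1;
        if (last_pred(i) != y(fs.te(i))) ++nerr;
      }
      errs(a) += static_cast<double>(nerr);
      a_done = a + 1;
    }
    if (a_done == 0) {
      // degenerate fold: majority-class prediction
      uword best;
      clcount.max(best);
      uword nerr = 0;
      for (uword i = 0; i < nte; ++i)
        if (static_cast<int>(best) + 1 != y(fs.te(i))) ++nerr;
      errs += static_cast<double>(nerr);
      a_max_global = std::max<uword>(a_max_global, 1);
      continue;
    }
    uword nerr_last = 0;
    for (uword i = 0; i < nte; ++i)
      if (last_pred(i) != y(fs.te(i))) ++nerr_last;
    for (uword a = a_done; a < static_cast<uword>(max_comp); ++a)
      errs(a) += static_cast<double>(nerr_last);
    a_max_global = std::max(a_max_global, a_done);
  }
  if (a_max_global == 0) return 1.0;
  return errs.min() / static_cast<double>(n);
}

std::vector<FoldSplit> make_splits(const ivec& fold) {
  int k = fold.max();
  std::vector<FoldSplit> out;
  out.reserve(k);
  for (int f = 1; f <= k; ++f) {
    FoldSplit fs;
    fs.te = find(fold == f);
    fs.tr = find(fold != f);
    out.push_back(fs);
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
double cpp_cv_plsda(const arma::mat& X, const arma::ivec& y,
                    const arma::ivec& fold, int max_comp) {
  if (max_comp < 1) max_comp = 1;
  std::vector<FoldSplit> folds = make_splits(fold);
  uvec cols = regspace<uvec>(0, X.n_cols - 1);
  return cv_error_subset(X, y, folds, cols, y.max(), max_comp);
}

// Batch evaluation: `subsets` is a list of 1-based integer column index
// vectors; component cap min(max_comp, subset size, n_train - 1) applies
// per subset.
// [[Rcpp::export]]
arma::vec cpp_cv_plsda_batch(const arma::mat& X, const arma::ivec& y,
                             const arma::ivec& fold, int max_comp,
                             Rcpp::List subsets) {
  if (max_comp < 1) max_comp = 1;
  std::vector<FoldSplit> folds = make_splits(fold);
  const int g = y.max();
  const int m = subsets.size();
  vec out(static_cast<uword>(m));
  for (int i = 0; i < m; ++i) {
    Rcpp::IntegerVector s = subsets[i];
    uvec cols(static_cast<uword>(s.size()));
    for (int j = 0; j < s.size(); ++j)
      cols(static_cast<uword>(j)) = static_cast<uword>(s[j] - 1);
    out(static_cast<uword>(i)) = cv_error_subset(X, y, folds, cols, g,
                                                 max_comp);
  }
  return out;
}
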