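// Hot numerical loops: batch Procrustes superimposition and KNN pre-imputation.
// Poses are stored as cubes (N_bp x d x n); observation masks as umat (N_bp x n),
// 1 = observed. Row-vector convention throughout: aligned = s * X * R + t.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <algorithm>

using namespace arma;

// Orthogonal Procrustes on the common rows of src/tgt (k x d, k >= min_common).
// Reflections are excluded: det(R) = +1 by sign-flipping the smallest singular
// direction. Returns false when the SVD fails (degenerate input).
static bool procrustes_core(const mat& src, const mat& tgt, bool est_scale,
                            mat& R, rowvec& t, double& s, double& resid) {
  const uword d = src.n_cols;
  rowvec cs = mean(src, 0), ct = mean(tgt, 0);
  mat S = src.each_row() - cs;
  mat T = tgt.each_row() - ct;
  mat A = S.t() * T;                     // d x d cross-covariance
  mat U, V; vec D;
  if (!svd(U, D, V, A)) return false;
  vec sgn = ones<vec>(d);
  if (det(U * V.t()) < 0.0) sgn(d - 1) = -1.0;
  R = U * diagmat(sgn) * V.t();
  if (est_scale) {
    double denom = accu(square(S));
    s = denom > 0.0 ? dot(D, sgn) / denom : 1.0;
    if (s <= 0.0) s = 1.0;               // pathological; fall back to rigid
  } else {
    s = 1.0;
  }
  t = ct - s * cs * R;
  mat res = (s * src * R);
  res.each_row() += t;
  res -= tgt;
  resid = std::sqrt(accu(square(res)) / double(src.n_rows));
  return true;
}

// Align every pose in X to a reference pose. Transform is estimated on the
// points observed in both, applied to all observed points of the source.
// [[Rcpp::export]]
Rcpp::List cpp_align_batch(const arma::cube& X, const arma::umat& obs,
                           const arma::mat& ref, const arma::uvec& ref_obs,
                           int min_common, bool est_scale) {
  const uword n = X.n_slices, nbp = X.n_rows, d = X.n_cols;
  cube aligned(nbp, d, n); aligned.fill(datum::nan);
  cube rots(d, d, n, fill::zeros);
  mat trans(n, d, fill::zeros);
  vec scales(n, fill::ones), resid(n, fill::value(datum::nan));
  ivec ncommon(n, fill::zeros);
  uvec ok(n, fill::zeros);

  for (uword i = 0; i < n; ++i) {
    uvec common = find((obs.col(i) % ref_obs) == 1);
    ncommon(i) = (sword)common.n_elem;
    if ((int)common.n_elem < min_common) continue;
    mat src = X.slice(i).rows(common);
    mat tgt = ref.rows(common);
    mat R; rowvec t; double s, r2;
    if (!procrustes_core(src, tgt, est_scale, R, t, s, r2)) continue;
    uvec oi = find(obs.col(i) == 1);
    mat out = s * X.slice(i).rows(oi) * R;
    out.each_row() += t;
    aligned.slice(i).rows(oi) = out;
    rots.slice(i) = R;
    trans.row(i) = t;
    scales(i) = s;
    resid(i) = r2;
    ok(i) = 1;
  }
  return Rcpp::List::create(
      Rcpp::Named("aligned") = aligned, Rcpp::Named("rotation") = rots,
      Rcpp::Named("translation") = trans, Rcpp::Named("scale") = scales,
      Rcpp::Named("residual") = resid, Rcpp::Named("n_common") = ncommon,
      Rcpp::Named("ok") = ok);
}

// KNN fill-up of missing landmarks. For each target pose with missing points,
// candidate recovering poses (observed at every missing position of the
// target) are rigidly aligned to the target on commonly observed points,
// ranked by RMS distance over those points, and the nearest k are averaged at
// the missing positions. Ties broken by dataset order (stable sort).
// [[Rcpp::export]]
Rcpp::List cpp_knn_impute(const arma::cube& X, const arma::umat& obs,
                          int k, int min_common) {
  const uword n = X.n_slices, nbp = X.n_rows;
  cube out = X;
  std::vector<int> fail_pose, fail_point;

  for (uword i = 0; i < n; ++i) {
    uvec miss = find(obs.col(i) == 0);
    if (miss.n_elem == 0) continue;
    uvec oi = find(obs.col(i) == 1);
    mat tgt = X.slice(i).rows(oi);
    std::vector<std::pair<double, uword>> cand;
    cand.reserve(n);
    for (uword j = 0; j < n; ++j) {
      if (j == i) continue;
      bool covers = true;                          // must cover missing pos.
      for (uword m = 0; m < miss.n_elem; ++m)
        if (obs(miss(m), j) == 0) { covers = false; break; }
      if (!covers) continue;
      uvec common = find((obs.col(i) % obs.col(j)) == 1);
      if ((int)common.n_elem < min_common) continue;
      // align candidate to target on common points (rigid)
      mat src = X.slice(j).rows(common);
      mat R; rowvec t; double s, r2;
      if (!procrustes_core(src, X.slice(i).rows(common), false, R, t, s, r2))
        continue;
      cand.push_back({r2, j});
    }
    if (cand.empty()) {
      fail_pose.push_back((int)i + 1);
      fail_point.push_back((int)miss(0) + 1);
      continue;
    }
    std::stable_sort(cand.begin(), cand.end(),
                     [](const std::pair<double, uword>& a,
                        const std::pair<double, uword>& b) {
                       return a.first < b.first;
                     });
    uword kk = std::min<uword>((uword)k, (uword)cand.size());
    mat acc(miss.n_elem, X.n_cols, fill::zeros);
    for (uword m = 0; m < kk; ++m) {
      uword j = cand[m].second;
      uvec common = find((obs.col(i) % obs.col(j)) == 1);
      mat R; rowvec t; double s, r2;
      procrustes_core(X.slice(j).rows(common), X.slice(i).rows(common), false,
                      R, t, s, r2);
      mat al = X.slice(j).rows(miss) * R;
      al.each_row() += t;
      acc += al;
    }
    out.slice(i).rows(miss) = acc / double(kk);
  }
  return Rcpp::List::create(
      Rcpp::Named("coords") = out,
      Rcpp::Named("fail_pose") = Rcpp::IntegerVector(fail_pose.begin(), fail_pose.end()),
      Rcpp::Named("fail_point") = Rcpp::IntegerVector(fail_point.begin(), fail_point.end()));
}
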