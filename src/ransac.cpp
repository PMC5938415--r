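// Normalized-DLT homography fitting and seeded RANSAC consensus search.
// The RNG is a private mt19937 so results are bit-reproducible for a given
// seed regardless of R's RNG state.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Hartley-normalized direct linear transform; points are n x 2 (x, y)
bool dlt(const arma::mat &p, const arma::mat &q, arma::mat33 &H) {
  const arma::uword n = p.n_rows;
  if (n < 4) return false;
  arma::rowvec cp = arma::mean(p, 0), cq = arma::mean(q, 0);
  double sp = arma::mean(arma::sqrt(arma::sum(arma::square(p.each_row() - cp), 1)));
  double sq = arma::mean(arma::sqrt(arma::sum(arma::square(q.each_row() - cq), 1)));
  if (sp < 1e-12 || sq < 1e-12) return false;
  double fp = std::sqrt(2.0) / sp, fq = std::sqrt(2.0) / sq;
  arma::mat33 Tp = {{fp, 0, -fp * cp[0]}, {0, fp, -fp * cp[1]}, {0, 0, 1}};
  arma::mat33 Tq = {{fq, 0, -fq * cq[0]}, {0, fq, -fq * cq[1]}, {0, 0, 1}};
  arma::mat A(2 * n, 9, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    double x = fp * (p(i, 0) - cp[0]), y = fp * (p(i, 1) - cp[1]);
    double u = fq * (q(i, 0) - cq[0]), v = fq * (q(i, 1) - cq[1]);
    A(2 * i, 0) = -x; A(2 * i, 1) = -y; A(2 * i, 2) = -1;
    A(2 * i, 6) = u * x; A(2 * i, 7) = u * y; A(2 * i, 8) = u;
    A(2 * i + 1, 3) = -x; A(2 * i + 1, 4) = -y; A(2 * i + 1, 5) = -1;
    A(2 * i + 1, 6) = v * x; A(2 * i + 1, 7) = v * y; A(2 * i + 1, 8) = v;
  }
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, A, "std")) return false;
  arma::vec h = V.col(8);
  arma::mat33 Hn;
  Hn(0, 0) = h[0]; Hn(0, 1) = h[1]; Hn(0, 2) = h[2];
  Hn(1, 0) = h[3]; Hn(1, 1) = h[4]; Hn(1, 2) = h[5];
  Hn(2, 0) = h[6]; Hn(2, 1) = h[7]; Hn(2, 2) = h[8];
  H = arma::solve(Tq, Hn * Tp);
  if (!H.is_finite()) return false;
  double d = arma::det(H);
  if (!std::isfinite(d) || std::fabs(d) < 1e-12) return false;
  if (std::fabs(H(2, 2)) > 1e-12) H /= H(2, 2);
  return true;
}

inline bool collinear3(double ax, double ay, double bx, double by,
                       double cx, double cy, double tol) {
  double cr = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
  return std::fabs(cr) <= tol;
}

// any 3 of the 4 sample points collinear, or repeated points
bool degenerate4(const arma::mat &p, double tol) {
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j)
      if (std::fabs(p(i, 0) - p(j, 0)) < tol && std::fabs(p(i, 1) - p(j, 1)) < tol)
        return true;
  static const int tri[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
  for (auto &t : tri)
    if (collinear3(p(t[0], 0), p(t[0], 1), p(t[1], 0), p(t[1], 1),
                   p(t[2], 0), p(t[2], 1), tol))
      return true;
  return false;
}

arma::vec reproj_errors(const arma::mat33 &H, const arma::mat &p, const arma::mat &q) {
  arma::vec e(p.n_rows);
  for (arma::uword i = 0; i < p.n_rows; ++i) {
    double w = H(2, 0) * p(i, 0) + H(2, 1) * p(i, 1) + H(2, 2);
    if (std::fabs(w) < 1e-300) { e[i] = R_PosInf; continue; }
    double x = (H(0, 0) * p(i, 0) + H(0, 1) * p(i, 1) + H(0, 2)) / w;
    double y = (H(1, 0) * p(i, 0) + H(1, 1) * p(i, 1) + H(1, 2)) / w;
    e[i] = std::sqrt((x - q(i, 0)) * (x - q(i, 0)) + (y - q(i, 1)) * (y - q(i, 1)));
  }
  return e;
}

}  // namespace

// [[Rcpp::export(name = ".fit_homography_cpp")]]
NumericMatrix fit_homography_cpp(NumericMatrix p_, NumericMatrix q_) {
  arma::mat p(p_.begin(), p_.nrow(), 2), q(q_.begin(), q_.nrow(), 2);
  if (p.n_rows == 4 && degenerate4(p, 1e-9)) {
    stop("degenerate correspondence set: repeated or collinear sample points");
  }
  arma::mat33 H;
  if (!dlt(p, q, H)) stop("homography fit failed (degenerate configuration)");
  return wrap(arma::mat(H));
}

// [[Rcpp::export(name = ".ransac_cpp")]]
List ransac_cpp(NumericMatrix p_, NumericMatrix q_, int iterations,
                double inlier_threshold, int seed, bool refit) {
  const int n = p_.nrow();
  arma::mat p(p_.begin(), n, 2), q(q_.begin(), n, 2);
  std::mt19937 rng((unsigned)seed);
  arma::mat33 bestH;
  int best_count = -1;
  LogicalVector best_flags(n, false);
  const long max_attempts = (long)iterations * 100L;
  long attempts = 0;
  int done = 0;
  int idx[4];
  while (done < iterations && attempts < max_attempts) {
    ++attempts;
    // partial Fisher-Yates over 0..n-1
    int pool[4];
    for (int i = 0; i < 4; ++i) {
      int j = (int)(rng() % (unsigned)(n - i));
      // map j through the already-chosen prefix
      for (int k0 = 0; k0 < i; ++k0)
        if (j >= pool[k0]) ++j;
      // keep pool sorted for the remap above
      int ins = i;
      while (ins > 0 && pool[ins - 1] > j) { pool[ins] = pool[ins - 1]; --ins; }
      pool[ins] = j;
      idx[i] = j;
    }
    arma::mat ps(4, 2), qs(4, 2);
    for (int i = 0; i < 4; ++i) { ps.row(i) = p.row(idx[i]); qs.row(i) = q.row(idx[i]); }
    if (degenerate4(ps, 1e-9)) continue;  // resample without consuming an iteration
    arma::mat33 H;
    if (!dlt(ps, qs, H)) continue;
    ++done;
    arma::vec e = reproj_errors(H, p, q);
    int count = (int)arma::sum(e < inlier_threshold);
    if (count > best_count) {  // strict: earlier iteration wins ties
      best_count = count;
      bestH = H;
      for (int i = 0; i < n; ++i) best_flags[i] = e[i] < inlier_threshold;
    }
  }
  if (best_count < 0) {
    return List::create(_["homography"] = R_NilValue,
                        _["inlier_flags"] = LogicalVector(n, false),
                        _["inlier_count"] = 0, _["iterations_run"] = done);
  }
  if (refit && best_count >= 4) {
    std::vector<arma::uword> ins;
    for (int i = 0; i < n; ++i)
      if (best_flags[i]) ins.push_back((arma::uword)i);
    arma::uvec in(ins);
    arma::mat33 H2;
    if (in.n_elem >= 4 && dlt(p.rows(in), q.rows(in), H2)) {
      arma::vec e = reproj_errors(H2, p, q);
      int count = (int)arma::sum(e < inlier_threshold);
      if (count >= best_count) {
        best_count = count;
        bestH = H2;
        for (int i = 0; i < n; ++i) best_flags[i] = e[i] < inlier_threshold;
      }
    }
  }
  return List::create(_["homography"] = wrap(arma::mat(bestH)),
                      _["inlier_flags"] = best_flags,
                      _["inlier_count"] = best_count,
                      _["iterations_run"] = done);
}
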