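// Frequency-domain diffusion physics: semi-infinite Green's function with
// extrapolated boundary, Born scattered field, and sensitivity assembly.
// All lengths in cm, mua/musp in 1/cm, omega in rad/s, c_tissue in cm/s.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <complex>

using namespace arma;

static const double MIN_SEP = 0.1; // cm; below this the 1/r kernel blows up

// complex diffusion wavenumber, principal root has Im(k) > 0 so exp(ikr) decays
static std::complex<double> diff_k(double mua, double musp, double omega,
                                   double c_tissue) {
  double D = 1.0 / (3.0 * (mua + musp));
  std::complex<double> k2(-mua / D, omega / (c_tissue * D));
  return std::sqrt(k2);
}

// extrapolated-boundary offset z_b = 2 D (1 + Reff) / (1 - Reff)
static double zb_offset(double mua, double musp, double reff) {
  double D = 1.0 / (3.0 * (mua + musp));
  return 2.0 * D * (1.0 + reff) / (1.0 - reff);
}

static std::complex<double> green_pair(double ax, double ay, double az,
                                       double bx, double by, double bz,
                                       std::complex<double> k, double D,
                                       double zb, bool check_sep) {
  double dx = ax - bx, dy = ay - by, dz = az - bz;
  double r1 = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (check_sep && r1 < MIN_SEP)
    Rcpp::stop("point separation %.4f cm below %.2f cm: Green's function singularity",
               r1, MIN_SEP);
  double zi = az + bz + 2.0 * zb; // image-source axial distance
  double r2 = std::sqrt(dx * dx + dy * dy + zi * zi);
  std::complex<double> i1(0.0, 1.0);
  std::complex<double> g = std::exp(i1 * k * r1) / r1 - std::exp(i1 * k * r2) / r2;
  return g / (4.0 * arma::datum::pi * D);
}

// [[Rcpp::export]]
arma::cx_mat cpp_green_matrix(const arma::mat& a, const arma::mat& b,
                              double mua, double musp, double omega,
                              double c_tissue, double reff,
                              bool check_sep = true) {
  if (mua <= 0 || musp <= 0) Rcpp::stop("optical properties must be positive");
  double D = 1.0 / (3.0 * (mua + musp));
  std::complex<double> k = diff_k(mua, musp, omega, c_tissue);
  double zb = zb_offset(mua, musp, reff);
  cx_mat g(a.n_rows, b.n_rows);
  for (uword i = 0; i < a.n_rows; ++i)
    for (uword j = 0; j < b.n_rows; ++j)
      g(i, j) = green_pair(a(i, 0), a(i, 1), a(i, 2), b(j, 0), b(j, 1),
                           b(j, 2), k, D, zb, check_sep);
  return g;
}

// Born scattered field over a voxelised absorber:
//   U_sc(s,d) = -(1/D) sum_j G(s,j) G(j,d) dmua_j V_j
// The minus sign makes increased absorption reduce the detected field.
// [[Rcpp::export]]
arma::cx_mat cpp_born_scatter(const arma::mat& src, const arma::mat& det,
                              const arma::mat& vox, const arma::vec& vol,
                              const arma::vec& dmua, double mua0, double musp0,
                              double omega, double c_tissue, double reff) {
  double D = 1.0 / (3.0 * (mua0 + musp0));
  cx_mat gs = cpp_green_matrix(src, vox, mua0, musp0, omega, c_tissue, reff);
  cx_mat gd = cpp_green_matrix(vox, det, mua0, musp0, omega, c_tissue, reff);
  cx_vec w = conv_to<cx_vec>::from(dmua % vol);
  return -(gs * diagmat(w) * gd) / D;
}

// Unnormalised Born sensitivity, rows ordered source-fastest:
//   W[(d-1)*S + s, j] = -G(s,j) G(j,d) V_j / D
// Division by the homogeneous field is done by the caller.
// [[Rcpp::export]]
arma::cx_mat cpp_sensitivity(const arma::mat& src, const arma::mat& det,
                             const arma::mat& vox, const arma::vec& vol,
                             double mua0, double musp0, double omega,
                             double c_tissue, double reff) {
  double D = 1.0 / (3.0 * (mua0 + musp0));
  cx_mat gs = cpp_green_matrix(src, vox, mua0, musp0, omega, c_tissue, reff);
  cx_mat gd = cpp_green_matrix(vox, det, mua0, musp0, omega, c_tissue, reff);
  uword S = src.n_rows, Dn = det.n_rows, N = vox.n_rows;
  cx_mat w(S * Dn, N);
  for (uword j = 0; j < N; ++j) {
    for (uword d = 0; d < Dn; ++d) {
      std::complex<double> gdv = gd(j, d) * vol(j) / D;
      for (uword s = 0; s < S; ++s) w(d * S + s, j) = -gs(s, j) * gdv;
    }
  }
  return w;
}

// index (1-based) of the nearest voxel centre for each query point
// [[Rcpp::export]]
arma::uvec cpp_nearest_voxel(const arma::mat& pts, const arma::mat& centers) {
  const uword n = centers.n_rows;
  const double* cx = centers.colptr(0);
  const double* cy = centers.colptr(1);
  const double* cz = centers.colptr(2);
  uvec idx(pts.n_rows);
  for (uword i = 0; i < pts.n_rows; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double best = datum::inf; uword bj = 0;
    for (uword j = 0; j < n; ++j) {
      double dx = px - cx[j], dy = py - cy[j], dz = pz - cz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx(i) = bj + 1;
  }
  return idx;
}

// Tikhonov CG on the normal equations of the stacked real system.
// Templated so the pipeline can run in single precision while the
// reference double path keeps full accuracy.
template <typename MT, typename VT>
static Rcpp::List cg_core(const MT& a, const VT& b, double lambda,
                          int power_iters, int max_iterations, double tol,
                          bool track_objective) {
  if (lambda < 0) { // sentinel: estimate 0.1 * sigma_max by power iteration
    VT v(a.n_cols, fill::ones);
    v /= std::sqrt((double)a.n_cols);
    for (int i = 0; i < power_iters; ++i) {
      v = a.t() * (a * v);
      v /= norm(v);
    }
    VT bv = a.t() * (a * v);
    lambda = 0.1 * std::sqrt(norm(bv));
  }
  double l2 = lambda * lambda;
  VT x(a.n_cols, fill::zeros);
  VT r = a.t() * b;
  VT p = r;
  double rs = dot(r, r), rs0 = rs;
  std::vector<double> obj;
  int iters = 0; bool converged = false;
  for (int i = 0; i < max_iterations; ++i) {
    VT q = a.t() * (a * p) + l2 * p;
    double alpha = rs / dot(p, q);
    x += alpha * p;
    r -= alpha * q;
    if (track_objective) {
      VT res = a * x - b;
      obj.push_back(dot(res, res) + l2 * dot(x, x));
    }
    iters = i + 1;
    double rs_new = dot(r, r);
    if (std::sqrt(rs_new / rs0) < tol) { converged = true; break; }
    p = r + (rs_new / rs) * p;
    rs = rs_new;
  }
  return Rcpp::List::create(
      Rcpp::Named("x") = Rcpp::wrap(conv_to<vec>::from(x)),
      Rcpp::Named("lambda") = lambda,
      Rcpp::Named("iterations") = iters,
      Rcpp::Named("objective") = Rcpp::wrap(obj),
      Rcpp::Named("converged") = converged);
}

// [[Rcpp::export]]
Rcpp::List cpp_cg(const arma::mat& a, const arma::vec& b, double lambda,
                  int power_iters, int max_iterations, double tol,
                  bool track_objective, bool single_precision) {
  if (single_precision) {
    fmat af = conv_to<fmat>::from(a);
    fvec bf = conv_to<fvec>::from(b);
    return cg_core<fmat, fvec>(af, bf, lambda, power_iters, max_iterations,
                               tol, track_objective);
  }
  return cg_core<mat, vec>(a, b, lambda, power_iters, max_iterations, tol,
                           track_objective);
}
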