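// Batched per-voxel SVD of coil x image matrices.
//
// Each voxel's signal matrix S (coil x image) is decomposed independently;
// the first left singular vector estimates the relative coil sensitivities,
// the first right singular vector the magnetization series, and the phase
// convention assigns the first image's magnetization phase to the
// sensitivities (first right entry becomes real and non-negative).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// data: complex array flattened as (voxel, coil, image), column-major.
// Returns per-voxel quantities; all-zero voxels yield zeroed outputs.
// [[Rcpp::export(name = ".voxelwise_svd_cpp")]]
List voxelwise_svd_cpp(const ComplexVector& data, int n_voxel, int n_coil,
                       int n_image) {
  const std::complex<double>* d =
      reinterpret_cast<const std::complex<double>*>(&data[0]);

  arma::cx_mat c_prime(n_voxel, n_coil, arma::fill::zeros);
  arma::cx_mat m_series(n_voxel, n_image, arma::fill::zeros);
  arma::vec lambda1(n_voxel, arma::fill::zeros);
  arma::vec lambda2(n_voxel, arma::fill::zeros);

  arma::cx_mat S(n_coil, n_image);
  arma::cx_mat U, V;
  arma::vec s;

  const long long nv = n_voxel;
  for (int v = 0; v < n_voxel; ++v) {
    bool all_zero = true;
    for (int j = 0; j < n_image; ++j)
      for (int i = 0; i < n_coil; ++i) {
        std::complex<double> z = d[v + nv * (i + (long long)n_coil * j)];
        S(i, j) = z;
        if (z != std::complex<double>(0.0, 0.0)) all_zero = false;
      }
    if (all_zero) continue;

    if (!arma::svd_econ(U, s, V, S, "both"))
      stop("SVD failed to converge at voxel %d", v + 1);

    lambda1(v) = s(0);
    lambda2(v) = (s.n_elem > 1) ? s(1) : 0.0;

    // S ~ lambda1 * u1 * v1^H, so m_j is proportional to conj(V(j,0)).
    std::complex<double> m1 = std::conj(V(0, 0));
    double am1 = std::abs(m1);
    std::complex<double> ph =
        (am1 > 0.0) ? m1 / am1 : std::complex<double>(1.0, 0.0);
    for (int i = 0; i < n_coil; ++i) c_prime(v, i) = U(i, 0) * ph;
    for (int j = 0; j < n_image; ++j)
      m_series(v, j) = s(0) * std::conj(V(j, 0)) * std::conj(ph);
  }

  return List::create(_["c_prime"] = wrap(c_prime),
                      _["m_series"] = wrap(m_series),
                      _["lambda1"] = wrap(lambda1),
                      _["lambda2"] = wrap(lambda2));
}
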