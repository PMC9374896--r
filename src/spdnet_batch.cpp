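// Batched SPD-network forward/backward over a whole trajectory.
// The per-window matrices are small (tens of rows), so the cost is dominated
// by loop overhead in interpreted code; batching the eigendecompositions and
// Daleckii-Krein gradients here makes training throughput practical.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using namespace Rcpp;

static mat symm(const mat& A) { return 0.5 * (A + A.t()); }

// Daleckii-Krein pullback: given eigenpairs (U, lam) of the layer input,
// scalar map values flam = f(lam) and derivative fp evaluated on ties,
// pull the upstream gradient G back through S -> U f(Lam) U'.
static mat loewner_apply(const mat& U, const vec& lam, const vec& flam,
                         const vec& fplam, const mat& G) {
  const uword n = lam.n_elem;
  mat M = U.t() * symm(G) * U;
  mat F(n, n);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < n; ++j) {
      double dl = lam(i) - lam(j);
      F(i, j) = (std::abs(dl) < 1e-12)
        ? 0.5 * (fplam(i) + fplam(j))
        : (flam(i) - flam(j)) / dl;
    }
  }
  return symm(U * (F % M) * U.t());
}

// [[Rcpp::export(name = ".spdnet_batch_forward_cpp")]]
List spdnet_batch_forward_cpp(const arma::cube& X, const List& Wlist,
                              const arma::vec& eps) {
  const int K = Wlist.size();
  const uword T = X.n_slices;
  List Xin(K), Uc(K), Lamc(K);
  cube cur = X;
  for (int k = 0; k < K; ++k) {
    mat W = as<mat>(Wlist[k]);
    const uword nk = W.n_rows;
    Xin[k] = cur;
    cube Uk(nk, nk, T), nxt(nk, nk, T);
    mat lamk(nk, T);
    for (uword t = 0; t < T; ++t) {
      vec lam;
      mat U;
      eig_sym(lam, U, symm(W * cur.slice(t) * W.t()));
      lamk.col(t) = lam;
      Uk.slice(t) = U;
      vec lc = lam;
      lc.elem(find(lc < eps(k))).fill(eps(k));
      nxt.slice(t) = symm(U * diagmat(lc) * U.t());
    }
    Uc[k] = Uk;
    Lamc[k] = lamk;
    cur = nxt;
  }
  // log-chart rows of the output, reusing the last layer's eigenvectors
  const uword P = cur.n_rows;
  mat L0(T, P * P);
  cube UK = as<cube>(Uc[K - 1]);
  mat lamK = as<mat>(Lamc[K - 1]);
  for (uword t = 0; t < T; ++t) {
    vec lc = lamK.col(t);
    lc.elem(find(lc < eps(K - 1))).fill(eps(K - 1));
    mat Lg = symm(UK.slice(t) * diagmat(log(lc)) * UK.slice(t).t());
    L0.row(t) = vectorise(Lg).t();
  }
  return List::create(_["L0"] = L0, _["out"] = cur, _["Xin"] = Xin,
                      _["U"] = Uc, _["lam"] = Lamc);
}

// [[Rcpp::export(name = ".spdnet_batch_backward_cpp")]]
List spdnet_batch_backward_cpp(const List& cache, const List& Wlist,
                               const arma::vec& eps, const arma::mat& gL) {
  const int K = Wlist.size();
  List Xin = cache["Xin"], Uc = cache["U"], Lamc = cache["lam"];
  cube UK = as<cube>(Uc[K - 1]);
  mat lamK = as<mat>(Lamc[K - 1]);
  const uword T = UK.n_slices;
  const uword P = UK.n_rows;

  std::vector<mat> gW(K);
  std::vector<mat> Wm(K);
  for (int k = 0; k < K; ++k) {
    Wm[k] = as<mat>(Wlist[k]);
    gW[k] = zeros<mat>(Wm[k].n_rows, Wm[k].n_cols);
  }

  for (uword t = 0; t < T; ++t) {
    mat G = symm(reshape(gL.row(t).t(), P, P));
    // backward through the log map at the clipped spectrum
    vec lc = lamK.col(t);
    lc.elem(find(lc < eps(K - 1))).fill(eps(K - 1));
    G = loewner_apply(UK.slice(t), lc, log(lc), 1.0 / lc, G);
    for (int k = K - 1; k >= 0; --k) {
      // backward through the eigenvalue rectification
      cube Uk = as<cube>(Uc[k]);
      mat lamk = as<mat>(Lamc[k]);
      vec lam = lamk.col(t);
      vec flam = lam;
      flam.elem(find(flam < eps(k))).fill(eps(k));
      vec fp = conv_to<vec>::from(lam > eps(k));
      G = loewner_apply(Uk.slice(t), lam, flam, fp, G);
      // backward through the bilinear map
      cube Xk = as<cube>(Xin[k]);
      gW[k] += 2.0 * G * Wm[k] * Xk.slice(t);
      G = Wm[k].t() * G * Wm[k];
    }
  }
  List out(K);
  for (int k = 0; k < K; ++k) out[k] = gW[k];
  return out;
}
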