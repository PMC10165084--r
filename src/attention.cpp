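// Batched multi-head attention kernels.
//
// Sequences arrive stacked: Q is a (B*Lq) x D matrix where sample b
// occupies rows [b*Lq, (b+1)*Lq) and head h occupies columns
// [h*dh, (h+1)*dh), dh = D/H. The ProbSparse variant scores each query by
// M(q, K) = logsumexp_j(q.k_j / sqrt(dh)) - mean_j(q.k_j / sqrt(dh)) and
// computes full softmax attention only for the top-u queries; the
// remaining rows receive the column mean of V ("average distribution"
// fill). Softmax probabilities and the selection mask are returned so the
// backward pass can be exact for the selected rows and the mean-fill rule.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;
using arma::cube;

static void softmax_rows(mat& S) {
  vec mx = arma::max(S, 1);
  S = arma::exp(S.each_col() - mx);
  vec rs = arma::sum(S, 1);
  S.each_col() /= rs;
}

// [[Rcpp::export(name = ".mha_forward_cpp")]]
List mha_forward_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                     int B, int Lq, int Lk, int H,
                     bool causal, int u) {
  const int D = Q.n_cols;
  const int dh = D / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat O(B * Lq, D, arma::fill::zeros);
  cube P(Lq, Lk, B * H, arma::fill::zeros);
  arma::imat sel(Lq, B * H, arma::fill::ones);

  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      const int s = b * H + h;
      mat Qb = Q.submat(b * Lq, h * dh, (b + 1) * Lq - 1, (h + 1) * dh - 1);
      mat Kb = K.submat(b * Lk, h * dh, (b + 1) * Lk - 1, (h + 1) * dh - 1);
      mat Vb = V.submat(b * Lk, h * dh, (b + 1) * Lk - 1, (h + 1) * dh - 1);
      mat S = Qb * Kb.t() * scale;

      bool sparse = (u > 0 && u < Lq && !causal);
      if (sparse) {
        vec mx = arma::max(S, 1);
        vec lse = mx + arma::log(arma::sum(arma::exp(S.each_col() - mx), 1));
        vec M = lse - arma::mean(S, 1);
        uvec ord = arma::sort_index(M, "descend");
        uvec active = arma::sort(ord.head(u));
        sel.col(s).zeros();
        for (arma::uword k = 0; k < active.n_elem; ++k)
          sel(active(k), s) = 1;
        mat Ssel = S.rows(active);
        softmax_rows(Ssel);
        mat Ob(Lq, dh);
        arma::rowvec vbar = arma::mean(Vb, 0);
        Ob.each_row() = vbar;
        Ob.rows(active) = Ssel * Vb;
        for (arma::uword k = 0; k < active.n_elem; ++k)
          P.slice(s).row(active(k)) = Ssel.row(k);
        O.submat(b * Lq, h * dh, (b + 1) * Lq - 1, (h + 1) * dh - 1) = Ob;
      } else {
        if (causal) {
          for (int i = 0; i < Lq; ++i)
            for (int j = i + 1; j < Lk; ++j)
              S(i, j) = -arma::datum::inf;
        }
        softmax_rows(S);
        P.slice(s) = S;
        O.submat(b * Lq, h * dh, (b + 1) * Lq - 1, (h + 1) * dh - 1) =
          S * Vb;
      }
    }
  }
  return List::create(_["O"] = O, _["P"] = P, _["sel"] = sel);
}

// [[Rcpp::export(name = ".mha_backward_cpp")]]
List mha_backward_cpp(const arma::mat& dO, const arma::mat& Q, const arma::mat& K,
                      const arma::mat& V, const arma::cube& P,
                      const arma::imat& sel,
                      int B, int Lq, int Lk, int H) {
  const int D = Q.n_cols;
  const int dh = D / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat dQ(arma::size(Q), arma::fill::zeros);
  mat dK(arma::size(K), arma::fill::zeros);
  mat dV(arma::size(V), arma::fill::zeros);

  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      const int s = b * H + h;
      mat Qb = Q.submat(b * Lq, h * dh, (b + 1) * Lq - 1, (h + 1) * dh - 1);
      mat Kb = K.submat(b * Lk, h * dh, (b + 1) * Lk - 1, (h + 1) * dh - 1);
      mat Vb = V.submat(b * Lk, h * dh, (b + 1) * Lk - 1, (h + 1) * dh - 1);
      mat dOb = dO.submat(b * Lq, h * dh, (b + 1) * Lq - 1,
                          (h + 1) * dh - 1);
      const mat& Pb = P.slice(s);

      // selected rows: standard softmax-attention backward (unselected
      // rows of Pb are all-zero, so they contribute nothing here)
      mat dVb = Pb.t() * dOb;
      mat dP = dOb * Vb.t();
      vec rs = arma::sum(dP % Pb, 1);
      mat dS = Pb % (dP.each_col() - rs);
      mat dQb = dS * Kb * scale;
      mat dKb = dS.t() * Qb * scale;

      // mean-of-V fill for unselected rows: dV gets dO/Lk, no dQ/dK
      arma::rowvec acc(dh, arma::fill::zeros);
      bool any_unsel = false;
      for (int i = 0; i < Lq; ++i) {
        if (sel(i, s) == 0) { acc += dOb.row(i); any_unsel = true; }
      }
      if (any_unsel) dVb.each_row() += acc / (double)Lk;

      dQ.submat(b * Lq, h * dh, (b + 1) * Lq - 1, (h + 1) * dh - 1) = dQb;
      dK.submat(b * Lk, h * dh, (b + 1) * Lk - 1, (h + 1) * dh - 1) += dKb;
      dV.submat(b * Lk, h * dh, (b + 1) * Lk - 1, (h + 1) * dh - 1) += dVb;
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
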