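// Compute kernels of the tiny CNN backbone. The whole forward/backward
// pass of one mini-batch runs inside a single call so that the large
// intermediate activations never cross the R/C++ boundary.
//
// Batch layout: a batch of B images of H x W x C is a (B*H*W) x C matrix,
// each image flattened column-major (row p = y + x*H within its block);
// channels are columns, which makes per-channel batch-norm statistics
// plain column operations. Convolution weights are (9*Cin) x Cout
// matrices; row c*9 + k holds input channel c at kernel offset
// k = (dy+1) + 3*(dx+1), dy/dx in {-1,0,1}.
//
// Architecture: four 3x3 same-padded conv layers (channels 3-8-16-32-32)
// each followed by batch normalization and ReLU, 2x2 max pooling after
// the first three, global average pooling, linear head. Batch norm uses
// batch statistics during training and running statistics at inference.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double BN_EPS = 1e-5;

static arma::mat im2col3(const arma::mat& X, int H, int W, int B) {
  const int Cin = X.n_cols, HW = H * W;
  arma::mat out(static_cast<arma::uword>(B) * HW, 9 * Cin);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = X.colptr(c);
    for (int k = 0; k < 9; ++k) {
      const int dy = k % 3 - 1, dx = k / 3 - 1;
      double* oc = out.colptr(c * 9 + k);
      for (int b = 0; b < B; ++b) {
        const double* xb = xc + static_cast<size_t>(b) * HW;
        double* ob = oc + static_cast<size_t>(b) * HW;
        for (int x = 0; x < W; ++x) {
          double* dst = ob + static_cast<size_t>(x) * H;
          const int xs = x + dx;
          if (xs < 0 || xs >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xb + static_cast<size_t>(xs) * H;
          const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
          for (int y = 0; y < y0; ++y) dst[y] = 0.0;
          for (int y = y0; y < y1; ++y) dst[y] = src[y + dy];
          for (int y = y1; y < H; ++y) dst[y] = 0.0;
        }
      }
    }
  }
  return out;
}

// scatter-add transpose of im2col3
static arma::mat col2im3(const arma::mat& dcols, int H, int W, int B,
                         int Cin) {
  const int HW = H * W;
  arma::mat dX(static_cast<arma::uword>(B) * HW, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    double* xc = dX.colptr(c);
    for (int k = 0; k < 9; ++k) {
      const int dy = k % 3 - 1, dx = k / 3 - 1;
      const double* oc = dcols.colptr(c * 9 + k);
      for (int b = 0; b < B; ++b) {
        double* xb = xc + static_cast<size_t>(b) * HW;
        const double* ob = oc + static_cast<size_t>(b) * HW;
        for (int x = 0; x < W; ++x) {
          const int xs = x + dx;
          if (xs < 0 || xs >= W) continue;
          const double* src = ob + static_cast<size_t>(x) * H;
          double* dst = xb + static_cast<size_t>(xs) * H;
          const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
          for (int y = y0; y < y1; ++y) dst[y + dy] += src[y];
        }
      }
    }
  }
  return dX;
}

static arma::mat pool2(const arma::mat& A, int H, int W, int B) {
  const int C = A.n_cols, H2 = H / 2, W2 = W / 2, HW = H * W;
  arma::mat M(static_cast<arma::uword>(B) * H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    const double* ac = A.colptr(c);
    double* mc = M.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* ab = ac + static_cast<size_t>(b) * HW;
      double* mb = mc + static_cast<size_t>(b) * H2 * W2;
      for (int x = 0; x < W2; ++x)
        for (int y = 0; y < H2; ++y) {
          const double* p = ab + static_cast<size_t>(2 * x) * H + 2 * y;
          mb[static_cast<size_t>(x) * H2 + y] =
            std::max(std::max(p[0], p[1]), std::max(p[H], p[H + 1]));
        }
    }
  }
  return M;
}

// gradient routed to the first (column-major) slot attaining the max
static arma::mat pool2_bwd(const arma::mat& A, const arma::mat& dM, int H,
                           int W, int B) {
  const int C = A.n_cols, H2 = H / 2, W2 = W / 2, HW = H * W;
  arma::mat dA(A.n_rows, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* ac = A.colptr(c);
    const double* gc = dM.colptr(c);
    double* dc = dA.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* ab = ac + static_cast<size_t>(b) * HW;
      const double* gb = gc + static_cast<size_t>(b) * H2 * W2;
      double* db = dc + static_cast<size_t>(b) * HW;
      for (int x = 0; x < W2; ++x)
        for (int y = 0; y < H2; ++y) {
          const size_t base = static_cast<size_t>(2 * x) * H + 2 * y;
          const size_t off[4] = {base, base + 1, base + H, base + H + 1};
          int best = 0;
          for (int j = 1; j < 4; ++j)
            if (ab[off[j]] > ab[off[best]]) best = j;
          db[off[best]] += gb[static_cast<size_t>(x) * H2 + y];
        }
    }
  }
  return dA;
}

// zero dY wherever the post-ReLU activation is zero
static void relu_mask(arma::mat& dY, const arma::mat& A) {
  const double* a = A.memptr();
  double* d = dY.memptr();
  const size_t n = A.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (a[i] <= 0) d[i] = 0;
}

struct Params {
  std::vector<arma::mat> W;                 // conv weights
  std::vector<arma::rowvec> gamma, beta;    // batch-norm affine
  std::vector<arma::rowvec> rmean, rvar;    // running statistics
  arma::mat fcW;
  arma::rowvec fcb;
};

static void unpack(const List& convW, const List& gamma, const List& beta,
                   const List& rmean, const List& rvar, const arma::mat& fcW,
                   const arma::rowvec& fcb, Params& P) {
  const int L = convW.size();
  P.W.resize(L); P.gamma.resize(L); P.beta.resize(L);
  P.rmean.resize(L); P.rvar.resize(L);
  for (int l = 0; l < L; ++l) {
    P.W[l] = as<arma::mat>(convW[l]);
    P.gamma[l] = as<arma::rowvec>(gamma[l]);
    P.beta[l] = as<arma::rowvec>(beta[l]);
    P.rmean[l] = as<arma::rowvec>(rmean[l]);
    P.rvar[l] = as<arma::rowvec>(rvar[l]);
  }
  P.fcW = fcW;
  P.fcb = fcb;
}

struct FwdCache {
  std::vector<arma::mat> cols, Yhat, A, Pm;
  std::vector<arma::rowvec> inv_std, bmean, bvar;
  arma::mat G, logits;
  std::vector<std::pair<int, int> > hw;
};

static void forward(const Params& P, const arma::mat& X, int H, int W,
                    int B, bool training, bool keep, FwdCache& C) {
  const int L = P.W.size();
  C.cols.resize(L); C.Yhat.resize(L); C.A.resize(L); C.Pm.resize(L - 1);
  C.inv_std.resize(L); C.bmean.resize(L); C.bvar.resize(L);
  C.hw.resize(L);
  arma::mat Z = X;
  int h = H, w = W;
  for (int l = 0; l < L; ++l) {
    C.hw[l] = std::make_pair(h, w);
    arma::mat cols = im2col3(Z, h, w, B);
    arma::mat Y = cols * P.W[l];
    if (keep) C.cols[l] = std::move(cols);
    arma::rowvec mu, va;
    if (training) {
      mu = arma::mean(Y, 0);
      va = arma::var(Y, 1, 0);              // biased (1/N) batch variance
      C.bmean[l] = mu; C.bvar[l] = va;
    } else {
      mu = P.rmean[l]; va = P.rvar[l];
    }
    arma::rowvec inv_std = 1.0 / arma::sqrt(va + BN_EPS);
    C.inv_std[l] = inv_std;
    Y.each_row() -= mu;
    Y.each_row() %= inv_std;                // Y is now Yhat
    if (keep) C.Yhat[l] = Y;
    Y.each_row() %= P.gamma[l];
    Y.each_row() += P.beta[l];
    // ReLU
    Y.for_each([](arma::mat::elem_type& v) { if (v < 0) v = 0; });
    C.A[l] = std::move(Y);
    if (l < L - 1) {
      Z = pool2(C.A[l], h, w, B);
      if (keep) C.Pm[l] = Z;
      h /= 2; w /= 2;
    } else {
      Z = C.A[l];
    }
  }
  const int Flast = C.hw[L - 1].first * C.hw[L - 1].second;
  const arma::mat& Alast = C.A[L - 1];
  C.G.set_size(B, Alast.n_cols);
  for (int b = 0; b < B; ++b)
    C.G.row(b) = arma::mean(
      Alast.rows(static_cast<arma::uword>(b) * Flast,
                 static_cast<arma::uword>(b + 1) * Flast - 1), 0);
  C.logits = C.G * P.fcW;
  C.logits.each_row() += P.fcb;
}

// expand the GAP gradient back to spatial rows
static arma::mat gap_bwd(const arma::mat& dG, int F, int B) {
  arma::mat dA(static_cast<arma::uword>(B) * F, dG.n_cols);
  for (int b = 0; b < B; ++b)
    dA.rows(static_cast<arma::uword>(b) * F,
            static_cast<arma::uword>(b + 1) * F - 1) =
      arma::repmat(dG.row(b) / F, F, 1);
  return dA;
}

// [[Rcpp::export(name = ".tiny_logits")]]
arma::mat tiny_logits(const List& convW, const List& gamma, const List& beta,
                      const List& rmean, const List& rvar,
                      const arma::mat& fcW, const arma::rowvec& fcb,
                      const arma::mat& X, int H, int W, int B) {
  Params P;
  unpack(convW, gamma, beta, rmean, rvar, fcW, fcb, P);
  FwdCache C;
  forward(P, X, H, W, B, false, false, C);
  return C.logits;
}

// One SGD step's worth of gradients: forward pass with batch statistics,
// softmax cross-entropy gradient with per-sample weight
// (1 + alpha * wrong_i) / B (the adaptive loss; alpha = 0 recovers plain
// cross-entropy; the misclassification indicator is a constant of the
// forward pass), full backward pass through batch norm. y is 1-based.
// Returns logits, parameter gradients and the batch statistics used.
// [[Rcpp::export(name = ".tiny_step")]]
List tiny_step(const List& convW, const List& gamma, const List& beta,
               const List& rmean, const List& rvar, const arma::mat& fcW,
               const arma::rowvec& fcb, const arma::mat& X, int H, int W,
               int B, const IntegerVector& y, double alpha) {
  Params P;
  unpack(convW, gamma, beta, rmean, rvar, fcW, fcb, P);
  const int L = P.W.size();
  FwdCache C;
  forward(P, X, H, W, B, true, true, C);
  // softmax + weighted CE gradient on the logits
  arma::mat Pr = C.logits;
  for (int b = 0; b < B; ++b) {
    arma::rowvec r = Pr.row(b) - Pr.row(b).max();
    r = arma::exp(r);
    Pr.row(b) = r / arma::accu(r);
  }
  arma::mat dlogits = Pr;
  for (int b = 0; b < B; ++b) {
    arma::uword pred;
    Pr.row(b).max(pred);
    const bool wrong = (static_cast<int>(pred) + 1) != y[b];
    const double wgt = (1.0 + alpha * (wrong ? 1.0 : 0.0)) / B;
    dlogits(b, y[b] - 1) -= 1.0;
    dlogits.row(b) *= wgt;
  }
  // backward
  arma::mat gfcW = C.G.t() * dlogits;
  arma::rowvec gfcb = arma::sum(dlogits, 0);
  arma::mat dG = dlogits * P.fcW.t();
  const int Flast = C.hw[L - 1].first * C.hw[L - 1].second;
  arma::mat dA = gap_bwd(dG, Flast, B);
  List gW(L), ggamma(L), gbeta(L), bmean(L), bvar(L);
  for (int l = L - 1; l >= 0; --l) {
    const int h = C.hw[l].first, w = C.hw[l].second;
    arma::mat dOut = dA;
    relu_mask(dOut, C.A[l]);
    // batch-norm backward (batch statistics)
    const arma::mat& Yhat = C.Yhat[l];
    const double N = static_cast<double>(Yhat.n_rows);
    arma::rowvec dbeta = arma::sum(dOut, 0);
    arma::rowvec dgamma = arma::sum(dOut % Yhat, 0);
    arma::mat dY = dOut;
    dY.each_row() %= P.gamma[l];            // dYhat
    arma::rowvec s1 = arma::sum(dY, 0);
    arma::rowvec s2 = arma::sum(dY % Yhat, 0);
    for (arma::uword c = 0; c < dY.n_cols; ++c)
      dY.col(c) = (dY.col(c) - Yhat.col(c) * (s2[c] / N) - s1[c] / N) *
        C.inv_std[l][c];
    gW[l] = C.cols[l].t() * dY;
    ggamma[l] = dgamma;
    gbeta[l] = dbeta;
    bmean[l] = C.bmean[l];
    bvar[l] = C.bvar[l];
    if (l > 0) {
      arma::mat dcols = dY * P.W[l].t();
      arma::mat dZ = col2im3(dcols, h, w, B, P.W[l].n_rows / 9);
      dA = pool2_bwd(C.A[l - 1], dZ, C.hw[l - 1].first, C.hw[l - 1].second,
                     B);
    }
  }
  return List::create(_["logits"] = C.logits, _["gW"] = gW,
                      _["ggamma"] = ggamma, _["gbeta"] = gbeta,
                      _["gfcW"] = gfcW, _["gfcb"] = gfcb,
                      _["bmean"] = bmean, _["bvar"] = bvar);
}

// Activations of conv layer `layer` (1-based, post-ReLU) and the gradient
// of the class-v logit with respect to them (Grad-CAM inputs). Inference
// mode: batch norm uses running statistics, so its backward is the fixed
// per-channel affine scale gamma / sqrt(rvar + eps).
// [[Rcpp::export(name = ".tiny_actgrad")]]
List tiny_actgrad(const List& convW, const List& gamma, const List& beta,
                  const List& rmean, const List& rvar, const arma::mat& fcW,
                  const arma::rowvec& fcb, const arma::mat& X, int H, int W,
                  int B, int v, int layer) {
  Params P;
  unpack(convW, gamma, beta, rmean, rvar, fcW, fcb, P);
  const int L = P.W.size();
  FwdCache C;
  forward(P, X, H, W, B, false, true, C);
  arma::mat dlogits(B, P.fcW.n_cols, arma::fill::zeros);
  dlogits.col(v - 1).fill(1.0);
  arma::mat dG = dlogits * P.fcW.t();
  const int Flast = C.hw[L - 1].first * C.hw[L - 1].second;
  arma::mat dA = gap_bwd(dG, Flast, B);
  for (int l = L - 1; l > layer - 1; --l) {
    arma::mat dOut = dA;
    relu_mask(dOut, C.A[l]);
    dOut.each_row() %= P.gamma[l] % C.inv_std[l];
    arma::mat dcols = dOut * P.W[l].t();
    arma::mat dZ = col2im3(dcols, C.hw[l].first, C.hw[l].second, B,
                           P.W[l].n_rows / 9);
    dA = pool2_bwd(C.A[l - 1], dZ, C.hw[l - 1].first, C.hw[l - 1].second, B);
  }
  return List::create(_["A"] = C.A[layer - 1], _["dA"] = dA,
                      _["logits"] = C.logits);
}
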