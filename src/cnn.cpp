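// Small 2-D convolutional network on 16x16 inputs, used for all four
// localization tasks. Fixed topology: conv 3x3 (valid) -> ReLU -> maxpool
// 2x2 -> conv 3x3 -> ReLU -> maxpool 2x2 -> FC -> ReLU -> linear head.
// Spatial sizes: 16 -> 14 -> 7 -> 5 -> 2. Convolutions run as im2col + GEMM
// stacked over the whole mini-batch. Plain SGD; seeded mt19937 drives weight
// init and epoch shuffling, so training is deterministic per seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Idx {
  umat conv1;  // 196 x 9 patch indices into the 16x16 input
  umat pool1;  // 49 x 4 window indices into the 14x14 map
  umat conv2;  // 25 x 9 patch indices into the 7x7 map
  umat pool2;  // 4 x 4 window indices into the 5x5 map
  Idx() {
    conv1.set_size(196, 9);
    for (int c = 0; c < 14; ++c)
      for (int r = 0; r < 14; ++r)
        for (int dc = 0; dc < 3; ++dc)
          for (int dr = 0; dr < 3; ++dr)
            conv1(r + 14 * c, dr + 3 * dc) = (r + dr) + 16 * (c + dc);
    pool1.set_size(49, 4);
    for (int c = 0; c < 7; ++c)
      for (int r = 0; r < 7; ++r)
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr)
            pool1(r + 7 * c, dr + 2 * dc) = (2 * r + dr) + 14 * (2 * c + dc);
    conv2.set_size(25, 9);
    for (int c = 0; c < 5; ++c)
      for (int r = 0; r < 5; ++r)
        for (int dc = 0; dc < 3; ++dc)
          for (int dr = 0; dr < 3; ++dr)
            conv2(r + 5 * c, dr + 3 * dc) = (r + dr) + 7 * (c + dc);
    pool2.set_size(4, 4);
    for (int c = 0; c < 2; ++c)
      for (int r = 0; r < 2; ++r)
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr)
            pool2(r + 2 * c, dr + 2 * dc) = (2 * r + dr) + 5 * (2 * c + dc);
  }
};

const Idx IDX;

struct Net {
  mat W1, W2, W3, W4;
  rowvec b1, b2, b3, b4;
  int F1, F2, H, K;
};

Net unpack(const Rcpp::List& w) {
  Net n;
  n.W1 = Rcpp::as<mat>(w["W1"]); n.b1 = Rcpp::as<rowvec>(w["b1"]);
  n.W2 = Rcpp::as<mat>(w["W2"]); n.b2 = Rcpp::as<rowvec>(w["b2"]);
  n.W3 = Rcpp::as<mat>(w["W3"]); n.b3 = Rcpp::as<rowvec>(w["b3"]);
  n.W4 = Rcpp::as<mat>(w["W4"]); n.b4 = Rcpp::as<rowvec>(w["b4"]);
  n.F1 = n.W1.n_cols; n.F2 = n.W2.n_cols; n.H = n.W3.n_cols; n.K = n.W4.n_cols;
  return n;
}

Rcpp::List pack(const Net& n) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = n.W1, Rcpp::Named("b1") = n.b1,
      Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
      Rcpp::Named("W3") = n.W3, Rcpp::Named("b3") = n.b3,
      Rcpp::Named("W4") = n.W4, Rcpp::Named("b4") = n.b4);
}

// Activations of one mini-batch, stacked sample-major along rows.
struct Batch {
  uword B = 0;
  mat X1;   // (B*196) x 9
  mat A1;   // (B*196) x F1, post-ReLU
  mat P1;   // (B*49) x F1
  umat M1;  // argmax window offsets
  mat X2;   // (B*25) x 9*F1
  mat A2;   // (B*25) x F2, post-ReLU
  mat P2;   // (B*4) x F2
  umat M2;
  mat F;    // B x 4*F2
  mat H;    // B x fc, post-ReLU
  mat O;    // B x K
};

void batch_pool(const mat& in, const umat& idx, uword B, uword stride_in,
                mat& out, umat& amax) {
  const uword P = idx.n_rows, Wn = idx.n_cols, Fn = in.n_cols;
  out.set_size(B * P, Fn); amax.set_size(B * P, Fn);
  for (uword f = 0; f < Fn; ++f) {
    const double* col = in.colptr(f);
    double* oc = out.colptr(f);
    uword* ac = amax.colptr(f);
    for (uword s = 0; s < B; ++s) {
      const double* base = col + s * stride_in;
      for (uword p = 0; p < P; ++p) {
        double best = base[idx(p, 0)]; uword bi = 0;
        for (uword o = 1; o < Wn; ++o) {
          double v = base[idx(p, o)];
          if (v > best) { best = v; bi = o; }
        }
        oc[s * P + p] = best; ac[s * P + p] = bi;
      }
    }
  }
}

void batch_forward(const Net& n, const mat& X, const uvec& rows, Batch& s) {
  const uword B = rows.n_elem;
  const int F1 = n.F1, F2 = n.F2;
  s.B = B;
  s.X1.set_size(B * 196, 9);
  for (uword o = 0; o < 9; ++o) {
    double* dst = s.X1.colptr(o);
    for (uword q = 0; q < B; ++q) {
      const uword i = rows(q);
      for (uword p = 0; p < 196; ++p)
        dst[q * 196 + p] = X(i, IDX.conv1(p, o));
    }
  }
  s.A1 = s.X1 * n.W1;
  s.A1.each_row() += n.b1;
  s.A1.clamp(0.0, datum::inf);
  batch_pool(s.A1, IDX.pool1, B, 196, s.P1, s.M1);

  s.X2.set_size(B * 25, 9 * F1);
  for (uword o = 0; o < 9; ++o)
    for (int f = 0; f < F1; ++f) {
      const double* src = s.P1.colptr(f);
      double* dst = s.X2.colptr(o * F1 + f);
      for (uword q = 0; q < B; ++q)
        for (uword p = 0; p < 25; ++p)
          dst[q * 25 + p] = src[q * 49 + IDX.conv2(p, o)];
    }
  s.A2 = s.X2 * n.W2;
  s.A2.each_row() += n.b2;
  s.A2.clamp(0.0, datum::inf);
  batch_pool(s.A2, IDX.pool2, B, 25, s.P2, s.M2);

  s.F.set_size(B, 4 * F2);
  for (int f = 0; f < F2; ++f) {
    const double* src = s.P2.colptr(f);
    for (uword q = 0; q < B; ++q)
      for (uword p = 0; p < 4; ++p)
        s.F(q, p + 4 * f) = src[q * 4 + p];
  }
  s.H = s.F * n.W3;
  s.H.each_row() += n.b3;
  s.H.clamp(0.0, datum::inf);
  s.O = s.H * n.W4;
  s.O.each_row() += n.b4;
}

void softmax_rows(mat& o) {
  for (uword i = 0; i < o.n_rows; ++i) {
    rowvec r = o.row(i);
    r -= r.max();
    r = exp(r);
    o.row(i) = r / accu(r);
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnn_init(int f1, int f2, int fc, int nout, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::normal_distribution<double> N(0.0, 1.0);
  auto he = [&](int rows, int cols, int fan_in) {
    mat m(rows, cols);
    double s = std::sqrt(2.0 / fan_in);
    for (uword j = 0; j < m.n_cols; ++j)
      for (uword i = 0; i < m.n_rows; ++i) m(i, j) = s * N(rng);
    return m;
  };
  Net n;
  n.W1 = he(9, f1, 9);
  n.W2 = he(9 * f1, f2, 9 * f1);
  n.W3 = he(4 * f2, fc, 4 * f2);
  n.W4 = he(fc, nout, fc);
  n.b1 = zeros<rowvec>(f1); n.b2 = zeros<rowvec>(f2);
  n.b3 = zeros<rowvec>(fc); n.b4 = zeros<rowvec>(nout);
  return pack(n);
}

// [[Rcpp::export]]
Rcpp::List cnn_fit(Rcpp::List weights, const arma::mat& X, const arma::mat& Y,
                   bool classify, double lr, int batch, int epochs, int seed) {
  Net n = unpack(weights);
  const uword N = X.n_rows;
  if (Y.n_rows != N) Rcpp::stop("X and Y row mismatch");
  std::mt19937 rng(static_cast<unsigned>(seed) + 1000003u);
  std::vector<uword> perm(N);
  for (uword i = 0; i < N; ++i) perm[i] = i;

  vec epoch_loss(epochs, fill::zeros);
  Batch s;
  const int F1 = n.F1, F2 = n.F2;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double loss_sum = 0.0; uword loss_n = 0;
    for (uword start = 0; start < N; start += batch) {
      const uword end = std::min<uword>(start + batch, N);
      const uword B = end - start;
      uvec rows(B);
      for (uword q = 0; q < B; ++q) rows(q) = perm[start + q];
      batch_forward(n, X, rows, s);

      mat d_out(B, n.K);
      if (classify) {
        mat P = s.O;
        softmax_rows(P);
        for (uword q = 0; q < B; ++q) {
          int cls = static_cast<int>(Y(rows(q), 0)) - 1;
          loss_sum += -std::log(std::max(P(q, cls), 1e-12));
          d_out.row(q) = P.row(q) / double(B);
          d_out(q, cls) -= 1.0 / B;
        }
      } else {
        for (uword q = 0; q < B; ++q) {
          rowvec diff = s.O.row(q) - Y.row(rows(q));
          loss_sum += accu(abs(diff)) / n.K;
          d_out.row(q) = sign(diff) / (double(B) * n.K);
        }
      }
      loss_n += B;

      // head and FC
      mat dW4 = s.H.t() * d_out;
      rowvec db4 = sum(d_out, 0);
      mat dH = d_out * n.W4.t();
      dH.elem(find(s.H <= 0)).zeros();
      mat dW3 = s.F.t() * dH;
      rowvec db3 = sum(dH, 0);
      mat dF = dH * n.W3.t();

      // unpool 2 + ReLU mask
      mat dP2(B * 4, F2, fill::none);
      for (int f = 0; f < F2; ++f)
        for (uword q = 0; q < B; ++q)
          for (uword p = 0; p < 4; ++p)
            dP2(q * 4 + p, f) = dF(q, p + 4 * f);
      mat dA2(B * 25, F2, fill::zeros);
      for (int f = 0; f < F2; ++f) {
        double* dc = dA2.colptr(f);
        const double* pc = dP2.colptr(f);
        const uword* mc = s.M2.colptr(f);
        for (uword q = 0; q < B; ++q)
          for (uword p = 0; p < 4; ++p)
            dc[q * 25 + IDX.pool2(p, mc[q * 4 + p])] += pc[q * 4 + p];
      }
      dA2.elem(find(s.A2 <= 0)).zeros();
      mat dW2 = s.X2.t() * dA2;
      rowvec db2 = sum(dA2, 0);
      mat dX2 = dA2 * n.W2.t();

      // scatter back through im2col 2, unpool 1, ReLU mask
      mat dP1(B * 49, F1, fill::zeros);
      for (uword o = 0; o < 9; ++o)
        for (int f = 0; f < F1; ++f) {
          const double* src = dX2.colptr(o * F1 + f);
          double* dst = dP1.colptr(f);
          for (uword q = 0; q < B; ++q)
            for (uword p = 0; p < 25; ++p)
              dst[q * 49 + IDX.conv2(p, o)] += src[q * 25 + p];
        }
      mat dA1(B * 196, F1, fill::zeros);
      for (int f = 0; f < F1; ++f) {
        double* dc = dA1.colptr(f);
        const double* pc = dP1.colptr(f);
        const uword* mc = s.M1.colptr(f);
        for (uword q = 0; q < B; ++q)
          for (uword p = 0; p < 49; ++p)
            dc[q * 196 + IDX.pool1(p, mc[q * 49 + p])] += pc[q * 49 + p];
      }
      dA1.elem(find(s.A1 <= 0)).zeros();
      mat dW1 = s.X1.t() * dA1;
      rowvec db1 = sum(dA1, 0);

      n.W1 -= lr * dW1; n.b1 -= lr * db1;
      n.W2 -= lr * dW2; n.b2 -= lr * db2;
      n.W3 -= lr * dW3; n.b3 -= lr * db3;
      n.W4 -= lr * dW4; n.b4 -= lr * db4;
    }
    epoch_loss(ep) = loss_sum / loss_n;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("weights") = pack(n),
                            Rcpp::Named("loss") = epoch_loss);
}

// [[Rcpp::export]]
arma::mat cnn_forward(Rcpp::List weights, const arma::mat& X, bool classify) {
  Net n = unpack(weights);
  const uword N = X.n_rows;
  mat out(N, n.K);
  Batch s;
  const uword chunk = 256;
  for (uword start = 0; start < N; start += chunk) {
    const uword end = std::min(start + chunk, N);
    uvec rows = regspace<uvec>(start, end - 1);
    batch_forward(n, X, rows, s);
    if (classify) softmax_rows(s.O);
    out.rows(start, end - 1) = s.O;
  }
  return out;
}
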