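// 1D convolutional network engine for multichannel gait windows.
//
// Single-precision, GEMM-based (im2col) implementation so that full training
// runs of the posture/fatigue classifier stay tractable on one CPU core.
// Layout convention: an activation tensor of C channels x L samples x B
// windows is stored as an arma::fmat with C rows and L*B columns, columns
// grouped window-major (column b*L + l holds window b, position l).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Zero-padded im2col for "same" convolutions: rows ordered offset-major
// (row j*C + c holds channel c at kernel offset j).
void im2col(const fmat& Z, int C, int L, int B, int k, fmat& col) {
  const int pad = (k - 1) / 2;
  col.set_size(C * k, (uword)L * B);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < k; ++j) {
      // output position l reads input position l + j - pad
      int lo = std::max(0, pad - j);            // first valid output position
      int hi = std::min(L - 1, L - 1 + pad - j); // last valid output position
      if (lo > 0)
        col.submat(j * C, (uword)b * L, j * C + C - 1, (uword)b * L + lo - 1).zeros();
      if (hi < L - 1)
        col.submat(j * C, (uword)b * L + hi + 1, j * C + C - 1, (uword)b * L + L - 1).zeros();
      if (lo > hi) continue;
      col.submat(j * C, (uword)b * L + lo, j * C + C - 1, (uword)b * L + hi) =
        Z.cols((uword)b * L + lo + j - pad, (uword)b * L + hi + j - pad);
    }
  }
}

// Adjoint of im2col: scatter-add column gradients back onto the input grid.
void col2im(const fmat& dcol, int C, int L, int B, int k, fmat& dZ) {
  const int pad = (k - 1) / 2;
  dZ.set_size(C, (uword)L * B);
  for (int b = 0; b < B; ++b) {
    // centre offset covers every column: assign first, accumulate the rest
    dZ.cols((uword)b * L, (uword)b * L + L - 1) =
      dcol.submat(pad * C, (uword)b * L, pad * C + C - 1, (uword)b * L + L - 1);
    for (int j = 0; j < k; ++j) {
      if (j == pad) continue;
      int lo = std::max(0, pad - j);
      int hi = std::min(L - 1, L - 1 + pad - j);
      if (lo > hi) continue;
      dZ.cols((uword)b * L + lo + j - pad, (uword)b * L + hi + j - pad) +=
        dcol.submat(j * C, (uword)b * L + lo, j * C + C - 1, (uword)b * L + hi);
    }
  }
}

// Max pooling with stride 2 along the sample axis; mask records whether the
// even (1) or odd position won, for gradient routing.
void maxpool2(const fmat& Z, int L, int B, fmat& P, Mat<unsigned char>& mask) {
  const int Lh = L / 2;
  const uword R = Z.n_rows;
  P.set_size(R, (uword)Lh * B);
  mask.set_size(R, (uword)Lh * B);
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < Lh; ++l) {
      const float* e = Z.colptr((uword)b * L + 2 * l);
      const float* o = e + R;
      float* p = P.colptr((uword)b * Lh + l);
      unsigned char* m = mask.colptr((uword)b * Lh + l);
      for (uword r = 0; r < R; ++r) {
        const bool take_even = e[r] >= o[r];
        p[r] = take_even ? e[r] : o[r];
        m[r] = take_even ? 1 : 0;
      }
    }
  }
}

void maxpool2_backward(const fmat& dP, const Mat<unsigned char>& mask, int L, int B, fmat& dZ) {
  const int Lh = L / 2;
  const uword R = dP.n_rows;
  dZ.zeros(R, (uword)L * B);
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < Lh; ++l) {
      const float* p = dP.colptr((uword)b * Lh + l);
      const unsigned char* m = mask.colptr((uword)b * Lh + l);
      float* e = dZ.colptr((uword)b * L + 2 * l);
      float* o = e + R;
      for (uword r = 0; r < R; ++r) {
        if (m[r]) e[r] = p[r]; else o[r] = p[r];
      }
    }
  }
}

inline void relu_inplace(fmat& A) {
  float* a = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i) if (a[i] < 0) a[i] = 0;
}

// zero gradient entries where the forward activation was clipped
inline void relu_backward(fmat& dA, const fmat& A) {
  float* d = dA.memptr();
  const float* a = A.memptr();
  const uword n = dA.n_elem;
  for (uword i = 0; i < n; ++i) if (a[i] <= 0) d[i] = 0;
}

struct AdamParam {
  fmat W, mW, vW;
  fvec b, mb, vb;
  void init(int rows, int cols, float sd, std::mt19937& rng) {
    std::normal_distribution<float> g(0.0f, sd);
    W.set_size(rows, cols);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = g(rng);
    b.zeros(rows);
    mW.zeros(rows, cols); vW.zeros(rows, cols);
    mb.zeros(rows); vb.zeros(rows);
  }
  void step(const fmat& dW, const fvec& db, float lr, float t) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    const float c1 = 1.0f - std::pow(b1, t), c2 = 1.0f - std::pow(b2, t);
    mW = b1 * mW + (1 - b1) * dW;  vW = b2 * vW + (1 - b2) * square(dW);
    W -= lr * (mW / c1) / (sqrt(vW / c2) + eps);
    mb = b1 * mb + (1 - b1) * db;  vb = b2 * vb + (1 - b2) * square(db);
    b -= lr * (mb / c1) / (sqrt(vb / c2) + eps);
  }
};

struct Net {
  int C, L, k, ncls;
  ivec filters;       // length 4
  AdamParam conv[4], dense;

  int flat_dim() const { return filters(3) * (L / 4); }

  void init(int C_, int L_, const ivec& filters_, int k_, int ncls_, std::mt19937& rng) {
    C = C_; L = L_; k = k_; ncls = ncls_; filters = filters_;
    int cin = C;
    for (int i = 0; i < 4; ++i) {
      conv[i].init(filters(i), cin * k, std::sqrt(2.0f / (cin * k)), rng);
      cin = filters(i);
    }
    dense.init(ncls, flat_dim(), std::sqrt(2.0f / flat_dim()), rng);
  }

  // Forward pass; caches are only filled when training.
  struct Cache {
    fmat col1, col2, col3, col4;     // im2col inputs per conv layer
    fmat a1, a2, a3, a4;             // post-ReLU activations
    fmat p1, p2;                     // pooled activations
    Mat<unsigned char> m1, m2;       // pooling masks
  };

  fmat forward(const fmat& X, int B, Cache* cc) const {
    Cache local;
    Cache& c = cc ? *cc : local;
    const int L2 = L / 2, L4 = L / 4;
    im2col(X, C, L, B, k, c.col1);
    c.a1 = conv[0].W * c.col1; c.a1.each_col() += conv[0].b;
    relu_inplace(c.a1);
    im2col(c.a1, filters(0), L, B, k, c.col2);
    c.a2 = conv[1].W * c.col2; c.a2.each_col() += conv[1].b;
    relu_inplace(c.a2);
    maxpool2(c.a2, L, B, c.p1, c.m1);
    im2col(c.p1, filters(1), L2, B, k, c.col3);
    c.a3 = conv[2].W * c.col3; c.a3.each_col() += conv[2].b;
    relu_inplace(c.a3);
    im2col(c.a3, filters(2), L2, B, k, c.col4);
    c.a4 = conv[3].W * c.col4; c.a4.each_col() += conv[3].b;
    relu_inplace(c.a4);
    maxpool2(c.a4, L2, B, c.p2, c.m2);
    // flatten: contiguous block per window
    const fmat Zf(const_cast<float*>(c.p2.memptr()), (uword)filters(3) * L4, B, false, true);
    fmat logits = dense.W * Zf; logits.each_col() += dense.b;
    return logits;
  }
};

fmat softmax_cols(const fmat& logits) {
  fmat P = logits;
  P.each_row() -= max(P, 0);
  P = exp(P);
  P.each_row() /= sum(P, 0);
  return P;
}

fmat gather_windows(const fcube& X, const uvec& idx) {
  const int C = X.n_rows, L = X.n_cols;
  fmat out(C, (uword)L * idx.n_elem);
  for (uword b = 0; b < idx.n_elem; ++b)
    out.cols((uword)b * L, (uword)b * L + L - 1) = X.slice(idx(b));
  return out;
}

fcube as_fcube(const Rcpp::NumericVector& xr) {
  Rcpp::IntegerVector d = xr.attr("dim");
  fcube X(d[0], d[1], d[2]);
  const double* p = xr.begin();
  for (uword i = 0; i < X.n_elem; ++i) X(i) = (float)p[i];
  return X;
}

Rcpp::NumericMatrix to_r(const fmat& M) {
  Rcpp::NumericMatrix out(M.n_rows, M.n_cols);
  for (uword i = 0; i < M.n_elem; ++i) out[i] = M(i);
  return out;
}

fmat from_r(const Rcpp::NumericMatrix& M) {
  fmat out(M.nrow(), M.ncol());
  for (uword i = 0; i < out.n_elem; ++i) out(i) = (float)M[i];
  return out;
}

void load_weights(Net& net, const Rcpp::List& weights, int C, int L, int k, int ncls) {
  Rcpp::List cw = weights["conv"];
  ivec filters(4);
  for (int i = 0; i < 4; ++i) {
    Rcpp::List layer = cw[i];
    net.conv[i].W = from_r(layer["W"]);
    net.conv[i].b = conv_to<fvec>::from(from_r(layer["b"]));
    filters(i) = net.conv[i].W.n_rows;
  }
  Rcpp::List dl = weights["dense"];
  net.dense.W = from_r(dl["W"]);
  net.dense.b = conv_to<fvec>::from(from_r(dl["b"]));
  net.C = C; net.L = L; net.k = k; net.ncls = ncls; net.filters = filters;
}

Rcpp::List dump_weights(const Net& net) {
  Rcpp::List cw(4);
  for (int i = 0; i < 4; ++i)
    cw[i] = Rcpp::List::create(Rcpp::Named("W") = to_r(net.conv[i].W),
                               Rcpp::Named("b") = to_r(fmat(net.conv[i].b)));
  return Rcpp::List::create(
    Rcpp::Named("conv") = cw,
    Rcpp::Named("dense") = Rcpp::List::create(Rcpp::Named("W") = to_r(net.dense.W),
                                              Rcpp::Named("b") = to_r(fmat(net.dense.b))));
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(Rcpp::NumericVector x, Rcpp::IntegerVector y,
                         Rcpp::IntegerVector filters, int kernel, int n_classes,
                         int epochs, int batch_size, double lr0, int seed) {
  fcube X = as_fcube(x);
  const int C = X.n_rows, L = X.n_cols, N = X.n_slices;
  if (L % 4 != 0) Rcpp::stop("window length must be divisible by 4 (two pooling stages)");
  if (kernel > L) Rcpp::stop("kernel larger than input length");
  ivec f = conv_to<ivec>::from(Rcpp::as<std::vector<int>>(filters));

  std::mt19937 rng((unsigned)seed);
  Net net;
  net.init(C, L, f, kernel, n_classes, rng);

  std::vector<uword> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  Rcpp::NumericVector h_loss(epochs), h_acc(epochs), h_lr(epochs);
  const int L2 = L / 2, L4 = L / 4;
  float t_adam = 0;

  for (int e = 0; e < epochs; ++e) {
    const float lr = (float)(lr0 * 0.5 * (1.0 + std::cos(M_PI * e / epochs)));
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; int ep_correct = 0;

    for (int start = 0; start < N; start += batch_size) {
      const int B = std::min(batch_size, N - start);
      uvec idx(B);
      for (int i = 0; i < B; ++i) idx(i) = order[start + i];
      fmat Xb = gather_windows(X, idx);

      Net::Cache c;
      fmat logits = net.forward(Xb, B, &c);
      fmat P = softmax_cols(logits);

      fmat dlogits = P;
      for (int i = 0; i < B; ++i) {
        const int yi = y[idx(i)];
        ep_loss += -std::log(std::max(P(yi, i), 1e-12f));
        uword pred; P.col(i).max(pred);
        if ((int)pred == yi) ++ep_correct;
        dlogits(yi, i) -= 1.0f;
      }
      dlogits /= (float)B;

      // dense backward
      const fmat Zf(c.p2.memptr(), (uword)f(3) * L4, B, false, true);
      fmat dWd = dlogits * Zf.t();
      fvec dbd = sum(dlogits, 1);
      fmat dZf = net.dense.W.t() * dlogits;
      fmat dP2((uword)f(3), (uword)L4 * B);
      std::memcpy(dP2.memptr(), dZf.memptr(), sizeof(float) * dZf.n_elem);

      // pool2 backward -> conv4
      fmat dA4; maxpool2_backward(dP2, c.m2, L2, B, dA4);
      relu_backward(dA4, c.a4);
      fmat dW4 = dA4 * c.col4.t(); fvec db4 = sum(dA4, 1);
      fmat dcol4 = net.conv[3].W.t() * dA4;
      fmat dA3; col2im(dcol4, f(2), L2, B, kernel, dA3);
      relu_backward(dA3, c.a3);
      fmat dW3 = dA3 * c.col3.t(); fvec db3 = sum(dA3, 1);
      fmat dcol3 = net.conv[2].W.t() * dA3;
      fmat dP1; col2im(dcol3, f(1), L2, B, kernel, dP1);

      // pool1 backward -> conv2
      fmat dA2; maxpool2_backward(dP1, c.m1, L, B, dA2);
      relu_backward(dA2, c.a2);
      fmat dW2 = dA2 * c.col2.t(); fvec db2 = sum(dA2, 1);
      fmat dcol2 = net.conv[1].W.t() * dA2;
      fmat dA1; col2im(dcol2, f(0), L, B, kernel, dA1);
      relu_backward(dA1, c.a1);
      fmat dW1 = dA1 * c.col1.t(); fvec db1 = sum(dA1, 1);
      // (gradient w.r.t. the raw input is not needed)

      t_adam += 1;
      net.conv[0].step(dW1, db1, lr, t_adam);
      net.conv[1].step(dW2, db2, lr, t_adam);
      net.conv[2].step(dW3, db3, lr, t_adam);
      net.conv[3].step(dW4, db4, lr, t_adam);
      net.dense.step(dWd, dbd, lr, t_adam);
    }
    h_loss[e] = ep_loss / N;
    h_acc[e] = (double)ep_correct / N;
    h_lr[e] = lr;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = dump_weights(net),
    Rcpp::Named("loss") = h_loss,
    Rcpp::Named("accuracy") = h_acc,
    Rcpp::Named("learning_rate") = h_lr);
}

//' @noRd
// [[Rcpp::export(name = ".cnn_predict_cpp")]]
Rcpp::NumericMatrix cnn_predict_cpp(Rcpp::List weights, Rcpp::NumericVector x,
                                    int kernel, int n_classes, int batch_size) {
  fcube X = as_fcube(x);
  const int C = X.n_rows, L = X.n_cols, N = X.n_slices;
  Net net;
  load_weights(net, weights, C, L, kernel, n_classes);
  fmat probs(n_classes, N);
  for (int start = 0; start < N; start += batch_size) {
    const int B = std::min(batch_size, N - start);
    uvec idx(B);
    for (int i = 0; i < B; ++i) idx(i) = start + i;
    fmat Xb = gather_windows(X, idx);
    fmat logits = net.forward(Xb, B, nullptr);
    probs.cols(start, start + B - 1) = softmax_cols(logits);
  }
  return to_r(probs);
}
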