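// Compute kernels for the six-layer tile classifier:
// conv(3x3,8)+ReLU -> maxpool(2) -> conv(3x3,16)+ReLU -> maxpool(2)
// -> dense(32)+ReLU -> dense(1)+sigmoid.
// The full forward/backward pass runs here in single precision with the
// ReLU fused into the pooling stages, so that no large activation array
// ever crosses the R boundary; R keeps the Adam optimizer and batching.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

typedef arma::fmat fm;
typedef arma::fvec fv;

// im2col for a valid 3x3 convolution. Input laid out as (H, W, B) per
// channel, channels as columns of `X` (H*W*B x Cin). Output:
// (Ho*Wo*B) x (9*Cin), column q = ci*9 + dj*3 + di.
fm im2col3(const fm& X, int H, int W, int B) {
  const int Cin = X.n_cols;
  const int Ho = H - 2, Wo = W - 2;
  fm P(static_cast<arma::uword>(Ho) * Wo * B, 9 * Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    const float* xc = X.colptr(ci);
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        float* pc = P.colptr(ci * 9 + dj * 3 + di);
        arma::uword k = 0;
        for (int b = 0; b < B; ++b) {
          const float* xb = xc + static_cast<size_t>(b) * H * W;
          for (int j = 0; j < Wo; ++j) {
            const float* col = xb + static_cast<size_t>(j + dj) * H + di;
            for (int i = 0; i < Ho; ++i) pc[k++] = col[i];
          }
        }
      }
    }
  }
  return P;
}

// Adjoint scatter-add of im2col3.
fm col2im3(const fm& dP, int H, int W, int B, int Cin) {
  const int Ho = H - 2, Wo = W - 2;
  fm dX(static_cast<arma::uword>(H) * W * B, Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    float* xc = dX.colptr(ci);
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const float* pc = dP.colptr(ci * 9 + dj * 3 + di);
        arma::uword k = 0;
        for (int b = 0; b < B; ++b) {
          float* xb = xc + static_cast<size_t>(b) * H * W;
          for (int j = 0; j < Wo; ++j) {
            float* col = xb + static_cast<size_t>(j + dj) * H + di;
            for (int i = 0; i < Ho; ++i) col[i] += pc[k++];
          }
        }
      }
    }
  }
  return dX;
}

// Fused ReLU + 2x2 stride-2 max pool on pre-activations Z:
// out = max(0, max of the 2x2 window). `which` records the argmax (0..3),
// or 4 when the window max is <= 0 (no gradient flows). Odd trailing
// rows/columns are cropped.
void relu_maxpool2(const fm& Z, int H, int W, int B,
                   fm& out, arma::Mat<unsigned char>& which) {
  const int Hp = H / 2, Wp = W / 2;
  const int C = Z.n_cols;
  out.set_size(static_cast<arma::uword>(Hp) * Wp * B, C);
  which.set_size(static_cast<arma::uword>(Hp) * Wp * B, C);
  for (int c = 0; c < C; ++c) {
    const float* xc = Z.colptr(c);
    float* oc = out.colptr(c);
    unsigned char* wc = which.colptr(c);
    arma::uword k = 0;
    for (int b = 0; b < B; ++b) {
      const float* xb = xc + static_cast<size_t>(b) * H * W;
      for (int j = 0; j < Wp; ++j) {
        const float* c0 = xb + static_cast<size_t>(2 * j) * H;
        const float* c1 = xb + static_cast<size_t>(2 * j + 1) * H;
        for (int i = 0; i < Hp; ++i) {
          const float v[4] = {c0[2 * i], c0[2 * i + 1], c1[2 * i],
                              c1[2 * i + 1]};
          int a = 0;
          for (int t = 1; t < 4; ++t) if (v[t] > v[a]) a = t;
          if (v[a] > 0.0f) {
            oc[k] = v[a];
            wc[k] = static_cast<unsigned char>(a);
          } else {
            oc[k] = 0.0f;
            wc[k] = 4;
          }
          ++k;
        }
      }
    }
  }
}

void relu_maxpool2_back(const fm& dOut, const arma::Mat<unsigned char>& which,
                        int H, int W, int B, fm& dZ) {
  const int Hp = H / 2, Wp = W / 2;
  const int C = dOut.n_cols;
  dZ.zeros(static_cast<arma::uword>(H) * W * B, C);
  for (int c = 0; c < C; ++c) {
    const float* dc = dOut.colptr(c);
    const unsigned char* wc = which.colptr(c);
    float* xc = dZ.colptr(c);
    arma::uword k = 0;
    for (int b = 0; b < B; ++b) {
      float* xb = xc + static_cast<size_t>(b) * H * W;
      for (int j = 0; j < Wp; ++j) {
        float* c0 = xb + static_cast<size_t>(2 * j) * H;
        float* c1 = xb + static_cast<size_t>(2 * j + 1) * H;
        for (int i = 0; i < Hp; ++i) {
          const int a = wc[k];
          const float g = dc[k];
          ++k;
          switch (a) {
            case 0: c0[2 * i] += g; break;
            case 1: c0[2 * i + 1] += g; break;
            case 2: c1[2 * i] += g; break;
            case 3: c1[2 * i + 1] += g; break;
            default: break;  // window max was non-positive
          }
        }
      }
    }
  }
}

struct Dims {
  int w, c1, p1, c2, p2, ch1, ch2, flat, dense;
};

Dims read_dims(const List& dims) {
  Dims d;
  d.w = as<int>(dims["w"]);
  d.c1 = as<int>(dims["c1"]);
  d.p1 = as<int>(dims["p1"]);
  d.c2 = as<int>(dims["c2"]);
  d.p2 = as<int>(dims["p2"]);
  IntegerVector ch = dims["ch"];
  d.ch1 = ch[0];
  d.ch2 = ch[1];
  d.flat = as<int>(dims["flat"]);
  d.dense = as<int>(dims["dense"]);
  return d;
}

struct Params {
  fm W1, W2, W3, W4;
  fv b1, b2, b3;
  float b4;
};

Params read_params(const List& params) {
  Params p;
  p.W1 = arma::conv_to<fm>::from(as<arma::mat>(params["W1"]));
  p.W2 = arma::conv_to<fm>::from(as<arma::mat>(params["W2"]));
  p.W3 = arma::conv_to<fm>::from(as<arma::mat>(params["W3"]));
  p.W4 = arma::conv_to<fm>::from(as<arma::mat>(params["W4"]));
  p.b1 = arma::conv_to<fv>::from(as<arma::vec>(params["b1"]));
  p.b2 = arma::conv_to<fv>::from(as<arma::vec>(params["b2"]));
  p.b3 = arma::conv_to<fv>::from(as<arma::vec>(params["b3"]));
  p.b4 = static_cast<float>(as<double>(params["b4"]));
  return p;
}

struct Forward {
  fm P1, Z1, pool1, P2, Z2, pool2, Fl, Z3, A3;
  arma::Mat<unsigned char> which1, which2;
  arma::vec prob;
};

void forward_pass(const Params& p, const Dims& d, const fm& X0, int B,
                  Forward& f, bool keep) {
  f.P1 = im2col3(X0, d.w, d.w, B);                 // (c1^2 B) x 9
  f.Z1 = f.P1 * p.W1.t();
  f.Z1.each_row() += p.b1.t();
  relu_maxpool2(f.Z1, d.c1, d.c1, B, f.pool1, f.which1);   // (p1^2 B) x 8
  f.P2 = im2col3(f.pool1, d.p1, d.p1, B);          // (c2^2 B) x 72
  f.Z2 = f.P2 * p.W2.t();
  f.Z2.each_row() += p.b2.t();
  relu_maxpool2(f.Z2, d.c2, d.c2, B, f.pool2, f.which2);   // (p2^2 B) x 16
  // flatten (p2,p2,B) x 16 -> (p2*p2*16) x B
  f.Fl.set_size(d.flat, B);
  const int sp = d.p2 * d.p2;
  for (int c = 0; c < d.ch2; ++c) {
    const float* pc = f.pool2.colptr(c);
    for (int b = 0; b < B; ++b) {
      std::copy(pc + static_cast<size_t>(b) * sp,
                pc + static_cast<size_t>(b + 1) * sp,
                f.Fl.colptr(b) + static_cast<size_t>(c) * sp);
    }
  }
  f.Z3 = p.W3 * f.Fl;
  f.Z3.each_col() += p.b3;
  f.A3 = arma::clamp(f.Z3, 0.0f, arma::datum::inf);
  arma::frowvec z4 = p.W4 * f.A3 + p.b4;
  f.prob = arma::conv_to<arma::vec>::from(1.0f / (1.0f + arma::exp(-z4.t())));
  if (!keep) {
    f.P1.reset(); f.Z1.reset(); f.P2.reset(); f.Z2.reset();
  }
}

// elementwise in-place: dZ <- dZ where Z > 0 else 0 (single fused pass)
void relu_mask_inplace(fm& dZ, const fm& Z) {
  const arma::uword n = dZ.n_elem;
  float* d = dZ.memptr();
  const float* z = Z.memptr();
  for (arma::uword i = 0; i < n; ++i) if (z[i] <= 0.0f) d[i] = 0.0f;
}

}  // namespace

// [[Rcpp::export(name = "cnn_forward_cpp")]]
arma::vec cnn_forward_cpp(List params, List dims, arma::mat tiles) {
  Dims d = read_dims(dims);
  Params p = read_params(params);
  fm X0 = arma::conv_to<fm>::from(tiles);
  const int B = tiles.n_cols;
  X0.reshape(static_cast<arma::uword>(d.w) * d.w * B, 1);
  Forward f;
  forward_pass(p, d, X0, B, f, false);
  return f.prob;
}

// [[Rcpp::export(name = "cnn_train_step_cpp")]]
List cnn_train_step_cpp(List params, List dims, arma::mat tiles,
                        arma::vec y, arma::vec w) {
  Dims d = read_dims(dims);
  Params p = read_params(params);
  const int B = tiles.n_cols;
  fm X0 = arma::conv_to<fm>::from(tiles);
  X0.reshape(static_cast<arma::uword>(d.w) * d.w * B, 1);
  Forward f;
  forward_pass(p, d, X0, B, f, true);

  const double sw = arma::accu(w);
  const double eps = 1e-12;
  const arma::vec pr = f.prob;
  const double loss = arma::accu(w % (-y % arma::log(pr + eps) -
                                 (1.0 - y) % arma::log(1.0 - pr + eps))) / sw;

  arma::frowvec dZ4 = arma::conv_to<arma::frowvec>::from(
      ((w % (pr - y)) / sw).t());                       // 1 x B
  fm gW4 = dZ4 * f.A3.t();
  float gb4 = arma::accu(dZ4);
  fm dA3 = p.W4.t() * dZ4;
  relu_mask_inplace(dA3, f.Z3);                         // now dZ3
  fm gW3 = dA3 * f.Fl.t();
  fv gb3 = arma::sum(dA3, 1);
  fm dFl = p.W3.t() * dA3;                              // flat x B
  // un-flatten to (p2^2 B) x 16
  fm dPool2(static_cast<arma::uword>(d.p2) * d.p2 * B, d.ch2);
  const int sp = d.p2 * d.p2;
  for (int c = 0; c < d.ch2; ++c) {
    float* pc = dPool2.colptr(c);
    for (int b = 0; b < B; ++b) {
      std::copy(dFl.colptr(b) + static_cast<size_t>(c) * sp,
                dFl.colptr(b) + static_cast<size_t>(c + 1) * sp,
                pc + static_cast<size_t>(b) * sp);
    }
  }
  fm dZ2;
  relu_maxpool2_back(dPool2, f.which2, d.c2, d.c2, B, dZ2);
  fm gW2 = dZ2.t() * f.P2;
  fv gb2 = arma::sum(dZ2, 0).t();
  fm dP2 = dZ2 * p.W2;                                  // (c2^2 B) x 72
  fm dPool1 = col2im3(dP2, d.p1, d.p1, B, d.ch1);
  fm dZ1;
  relu_maxpool2_back(dPool1, f.which1, d.c1, d.c1, B, dZ1);
  fm gW1 = dZ1.t() * f.P1;
  fv gb1 = arma::sum(dZ1, 0).t();

  return List::create(
    _["loss"] = loss, _["prob"] = f.prob,
    _["grads"] = List::create(
      _["W1"] = arma::conv_to<arma::mat>::from(gW1),
      _["b1"] = arma::conv_to<arma::vec>::from(gb1),
      _["W2"] = arma::conv_to<arma::mat>::from(gW2),
      _["b2"] = arma::conv_to<arma::vec>::from(gb2),
      _["W3"] = arma::conv_to<arma::mat>::from(gW3),
      _["b3"] = arma::conv_to<arma::vec>::from(gb3),
      _["W4"] = arma::conv_to<arma::mat>::from(gW4),
      _["b4"] = static_cast<double>(gb4)));
}
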