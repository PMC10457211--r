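// Minimal CNN engine (single precision, CPU) used by the three
// feature-extraction branches and the fusion head.  Supports the layer
// vocabulary those architectures need: 3x3 same-padding convolution,
// batch normalisation, ReLU, 2x2 max pooling, zero padding, flatten and
// fully connected layers, trained by softmax cross-entropy with SGD
// (momentum) or Adam and an optional per-phase cosine learning-rate
// schedule.  Activations are stored as (H*W*C) x N column-major float
// matrices, matching the memory layout of an R array dim c(H, W, C, N).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;

struct Layer {
  std::string type;
  // conv / linear parameters
  fmat W; fvec b; bool trainable = false;
  // batch norm
  fvec gamma, beta, rmean, rvar;
  float eps = 1e-5f, momentum = 0.1f;
  // zeropad: top, bottom, left, right
  int pt = 0, pb = 0, pl = 0, pr = 0;
  // gradients
  fmat dW; fvec db, dgamma, dbeta;
  // optimizer state
  fmat mW, vW; fvec mb, vb, mg, vg, mbe, vbe;
  // per-batch caches
  fmat xhat;        // bn normalised input
  fvec bmean, bstd; // bn batch stats
  umat argmax;      // pool winners
};

struct Shape { int H = 0, W = 0, C = 0; bool flat = false;
  int size() const { return flat ? C : H * W * C; } };

static std::vector<Layer> parse_layers(const Rcpp::List& ls) {
  std::vector<Layer> out;
  for (int i = 0; i < ls.size(); ++i) {
    Rcpp::List l = ls[i];
    Layer L;
    L.type = Rcpp::as<std::string>(l["type"]);
    if (L.type == "conv" || L.type == "linear") {
      L.W = Rcpp::as<fmat>(l["W"]);
      L.b = Rcpp::as<fvec>(l["b"]);
      L.trainable = Rcpp::as<bool>(l["trainable"]);
    } else if (L.type == "bn") {
      L.gamma = Rcpp::as<fvec>(l["gamma"]);
      L.beta = Rcpp::as<fvec>(l["beta"]);
      L.rmean = Rcpp::as<fvec>(l["rmean"]);
      L.rvar = Rcpp::as<fvec>(l["rvar"]);
      L.trainable = Rcpp::as<bool>(l["trainable"]);
    } else if (L.type == "zeropad") {
      Rcpp::IntegerVector p = l["pad"];
      L.pt = p[0]; L.pb = p[1]; L.pl = p[2]; L.pr = p[3];
    }
    out.push_back(std::move(L));
  }
  return out;
}

static Rcpp::List layers_to_r(const Rcpp::List& ls_in,
                              const std::vector<Layer>& layers) {
  Rcpp::List out = Rcpp::clone(ls_in);
  for (size_t i = 0; i < layers.size(); ++i) {
    const Layer& L = layers[i];
    Rcpp::List l = out[i];
    // frozen parameters are not written back: the caller's original
    // (double precision) values stay bit-identical
    if ((L.type == "conv" || L.type == "linear") && L.trainable) {
      l["W"] = Rcpp::wrap(L.W); l["b"] = Rcpp::wrap(L.b);
    } else if (L.type == "bn") {
      if (L.trainable) {
        l["gamma"] = Rcpp::wrap(L.gamma); l["beta"] = Rcpp::wrap(L.beta);
      }
      l["rmean"] = Rcpp::wrap(L.rmean); l["rvar"] = Rcpp::wrap(L.rvar);
    }
    out[i] = l;
  }
  return out;
}

// im2col for 3x3 stride-1 pad-1 convolution, laid out (H*W) x (C*9) so
// both the fill and the GEMM read/write contiguously; `row0` places the
// sample inside a multi-sample column matrix so one GEMM covers a
// whole sub-batch
static void im2col(const float* x, int H, int W, int C, fmat& col,
                   size_t row0 = 0) {
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)c * H * W;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        int cc = c * 9 + (dw + 1) * 3 + (dh + 1);
        float* dst0 = col.colptr(cc) + row0;
        for (int wo = 0; wo < W; ++wo) {
          int wi = wo + dw;
          float* dst = dst0 + (size_t)wo * H;
          if (wi < 0 || wi >= W) {
            std::memset(dst, 0, sizeof(float) * H);
            continue;
          }
          const float* srcc = xc + (size_t)wi * H;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          if (h0 > 0) dst[0] = 0.0f;
          if (h1 < H) dst[H - 1] = 0.0f;
          std::memcpy(dst + h0, srcc + h0 + dh, sizeof(float) * (h1 - h0));
        }
      }
    }
  }
}

static void col2im_add(const fmat& col, int H, int W, int C, float* x,
                       size_t row0 = 0) {
  for (int c = 0; c < C; ++c) {
    float* xc = x + (size_t)c * H * W;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        int cc = c * 9 + (dw + 1) * 3 + (dh + 1);
        const float* src0 = col.colptr(cc) + row0;
        for (int wo = 0; wo < W; ++wo) {
          int wi = wo + dw;
          if (wi < 0 || wi >= W) continue;
          const float* src = src0 + (size_t)wo * H;
          float* xcc = xc + (size_t)wi * H;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int ho = h0; ho < h1; ++ho) xcc[ho + dh] += src[ho];
        }
      }
    }
  }
}

// forward one layer; x is (H*W*C) x N (or flat dim x N)
static fmat layer_forward(Layer& L, const fmat& x, Shape& s, bool training) {
  if (L.type == "conv") {
    int C = s.C, H = s.H, W = s.W;
    if ((int)L.W.n_cols != C * 9)
      Rcpp::stop("conv expects %d input channels, got %d", (int)L.W.n_cols / 9, C);
    int Co = L.W.n_rows;
    size_t HW = (size_t)H * W;
    fmat y(HW * Co, x.n_cols);
    fmat wt = L.W.t();             // (C*9) x Co
    frowvec bt = L.b.t();
    // sub-batch so one GEMM covers several samples while the column
    // matrix stays within ~64 MB
    int sub = std::max<int>(1, (int)(16000000 / (HW * C * 9)));
    fmat col;
    for (uword n0 = 0; n0 < x.n_cols; n0 += sub) {
      int nb = std::min<int>(sub, x.n_cols - n0);
      col.set_size(HW * nb, C * 9);
      for (int i = 0; i < nb; ++i)
        im2col(x.colptr(n0 + i), H, W, C, col, (size_t)i * HW);
      fmat o = col * wt;           // (HW*nb) x Co
      o.each_row() += bt;
      for (int i = 0; i < nb; ++i)
        for (int c = 0; c < Co; ++c)
          std::memcpy(y.colptr(n0 + i) + (size_t)c * HW,
                      o.colptr(c) + (size_t)i * HW, sizeof(float) * HW);
    }
    s.C = Co;
    return y;
  }
  if (L.type == "relu") return clamp(x, 0.0f, datum::inf);
  if (L.type == "pool") {
    int C = s.C, H = s.H, W = s.W, Ho = H / 2, Wo = W / 2;
    fmat y(Ho * Wo * C, x.n_cols);
    L.argmax.set_size(Ho * Wo * C, x.n_cols);
    for (uword n = 0; n < x.n_cols; ++n) {
      const float* xn = x.colptr(n);
      float* yn = y.colptr(n);
      for (int c = 0; c < C; ++c)
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho) {
            size_t base = (size_t)c * H * W;
            float best = -datum::inf; size_t barg = 0;
            for (int dw = 0; dw < 2; ++dw)
              for (int dh = 0; dh < 2; ++dh) {
                size_t idx = base + (size_t)(2 * wo + dw) * H + (2 * ho + dh);
                if (xn[idx] > best) { best = xn[idx]; barg = idx; }
              }
            size_t oi = (size_t)c * Ho * Wo + (size_t)wo * Ho + ho;
            yn[oi] = best;
            L.argmax(oi, n) = barg;
          }
    }
    s.H = Ho; s.W = Wo;
    return y;
  }
  if (L.type == "bn") {
    int C = s.C, HW = s.H * s.W;
    if ((int)L.gamma.n_elem != C) Rcpp::stop("bn channel mismatch");
    fmat y(x.n_rows, x.n_cols);
    if (training) {
      L.xhat.set_size(x.n_rows, x.n_cols);
      L.bmean.set_size(C); L.bstd.set_size(C);
    }
    for (int c = 0; c < C; ++c) {
      uword r0 = (uword)c * HW, r1 = r0 + HW - 1;
      fmat xc = x.rows(r0, r1);
      float m, sd;
      if (training) {
        m = accu(xc) / xc.n_elem;
        float v = accu(square(xc - m)) / xc.n_elem;
        sd = std::sqrt(v + L.eps);
        L.bmean(c) = m; L.bstd(c) = sd;
        L.rmean(c) = (1.0f - L.momentum) * L.rmean(c) + L.momentum * m;
        L.rvar(c) = (1.0f - L.momentum) * L.rvar(c) + L.momentum * v;
      } else {
        m = L.rmean(c);
        sd = std::sqrt(L.rvar(c) + L.eps);
      }
      fmat xh = (xc - m) / sd;
      if (training) L.xhat.rows(r0, r1) = xh;
      y.rows(r0, r1) = L.gamma(c) * xh + L.beta(c);
    }
    return y;
  }
  if (L.type == "zeropad") {
    int C = s.C, H = s.H, W = s.W;
    int Ho = H + L.pt + L.pb, Wo = W + L.pl + L.pr;
    fmat y(Ho * Wo * C, x.n_cols, fill::zeros);
    for (uword n = 0; n < x.n_cols; ++n)
      for (int c = 0; c < C; ++c)
        for (int w = 0; w < W; ++w) {
          const float* src = x.colptr(n) + (size_t)c * H * W + (size_t)w * H;
          float* dst = y.colptr(n) + (size_t)c * Ho * Wo +
                       (size_t)(w + L.pl) * Ho + L.pt;
          std::memcpy(dst, src, sizeof(float) * H);
        }
    s.H = Ho; s.W = Wo;
    return y;
  }
  if (L.type == "flatten") {
    s.flat = true; s.C = s.H * s.W * s.C;
    return x;
  }
  if (L.type == "linear") {
    if (!s.flat) Rcpp::stop("linear layer requires flattened input");
    if ((int)L.W.n_cols != s.C)
      Rcpp::stop("linear expects input of size %d, got %d", (int)L.W.n_cols, s.C);
    fmat y = L.W * x;
    y.each_col() += L.b;
    s.C = L.W.n_rows;
    return y;
  }
  Rcpp::stop("unknown layer type '%s'", L.type.c_str());
}

// backward one layer; returns dX (empty if need_dx is false)
static fmat layer_backward(Layer& L, const fmat& x, const fmat& y,
                           const fmat& dy, const Shape& sin, bool need_dx) {
  if (L.type == "conv") {
    int C = sin.C, H = sin.H, W = sin.W;
    int Co = L.W.n_rows;
    if (L.trainable && L.dW.n_elem == 0) {
      L.dW.zeros(L.W.n_rows, L.W.n_cols); L.db.zeros(L.b.n_elem);
    }
    fmat dx;
    if (need_dx) dx.zeros(x.n_rows, x.n_cols);
    size_t HW = (size_t)H * W;
    int sub = std::max<int>(1, (int)(16000000 / (HW * C * 9)));
    fmat col, dyn;
    for (uword n0 = 0; n0 < x.n_cols; n0 += sub) {
      int nb = std::min<int>(sub, x.n_cols - n0);
      dyn.set_size(HW * nb, Co);
      for (int i = 0; i < nb; ++i)
        for (int c = 0; c < Co; ++c)
          std::memcpy(dyn.colptr(c) + (size_t)i * HW,
                      dy.colptr(n0 + i) + (size_t)c * HW,
                      sizeof(float) * HW);
      if (L.trainable) {
        col.set_size(HW * nb, C * 9);
        for (int i = 0; i < nb; ++i)
          im2col(x.colptr(n0 + i), H, W, C, col, (size_t)i * HW);
        L.dW += dyn.t() * col;          // Co x (C*9)
        L.db += sum(dyn, 0).t();
      }
      if (need_dx) {
        fmat dcol = dyn * L.W;          // (HW*nb) x (C*9)
        for (int i = 0; i < nb; ++i)
          col2im_add(dcol, H, W, C, dx.colptr(n0 + i), (size_t)i * HW);
      }
    }
    return dx;
  }
  if (L.type == "relu") {
    fmat dx = dy;
    dx.elem(find(y <= 0.0f)).zeros();
    return dx;
  }
  if (L.type == "pool") {
    fmat dx(x.n_rows, x.n_cols, fill::zeros);
    for (uword n = 0; n < dy.n_cols; ++n) {
      const float* dyn = dy.colptr(n);
      float* dxn = dx.colptr(n);
      for (uword i = 0; i < dy.n_rows; ++i) dxn[L.argmax(i, n)] += dyn[i];
    }
    return dx;
  }
  if (L.type == "bn") {
    int C = sin.C, HW = sin.H * sin.W;
    if (L.trainable && L.dgamma.n_elem == 0) {
      L.dgamma.zeros(C); L.dbeta.zeros(C);
    }
    fmat dx(x.n_rows, x.n_cols);
    for (int c = 0; c < C; ++c) {
      uword r0 = (uword)c * HW, r1 = r0 + HW - 1;
      fmat dyc = dy.rows(r0, r1);
      fmat xh = L.xhat.rows(r0, r1);
      float sg = accu(dyc % xh), sb = accu(dyc);
      if (L.trainable) { L.dgamma(c) += sg; L.dbeta(c) += sb; }
      float m = (float)dyc.n_elem;
      dx.rows(r0, r1) =
          (L.gamma(c) / (m * L.bstd(c))) * (m * dyc - sb - xh * sg);
    }
    return dx;
  }
  if (L.type == "zeropad") {
    int C = sin.C, H = sin.H, W = sin.W;
    int Ho = H + L.pt + L.pb, Wo = W + L.pl + L.pr;
    fmat dx(x.n_rows, x.n_cols);
    for (uword n = 0; n < dy.n_cols; ++n)
      for (int c = 0; c < C; ++c)
        for (int w = 0; w < W; ++w) {
          const float* src = dy.colptr(n) + (size_t)c * Ho * Wo +
                             (size_t)(w + L.pl) * Ho + L.pt;
          float* dst = dx.colptr(n) + (size_t)c * H * W + (size_t)w * H;
          std::memcpy(dst, src, sizeof(float) * H);
        }
    return dx;
  }
  if (L.type == "flatten") return dy;
  if (L.type == "linear") {
    if (L.trainable && L.dW.n_elem == 0) {
      L.dW.zeros(L.W.n_rows, L.W.n_cols); L.db.zeros(L.b.n_elem);
    }
    if (L.trainable) { L.dW += dy * x.t(); L.db += sum(dy, 1); }
    if (need_dx) return L.W.t() * dy;
    return fmat();
  }
  Rcpp::stop("unknown layer type in backward");
}

static void softmax_rows(fmat& logits) { // logits: K x N, in place
  for (uword n = 0; n < logits.n_cols; ++n) {
    fvec z = logits.col(n);
    z -= z.max();
    fvec e = exp(z);
    logits.col(n) = e / accu(e);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_nn_forward(Rcpp::List layers_r, Rcpp::NumericVector x_r,
                          Rcpp::IntegerVector dims, int tap = 0) {
  std::vector<Layer> layers = parse_layers(layers_r);
  Shape s; s.H = dims[0]; s.W = dims[1]; s.C = dims[2];
  int N = dims[3];
  fmat x(s.H * s.W * s.C, N);
  std::copy(x_r.begin(), x_r.end(), x.begin());
  fmat tap_act;
  Shape tap_shape;
  for (size_t i = 0; i < layers.size(); ++i) {
    x = layer_forward(layers[i], x, s, false);
    if ((int)i + 1 == tap) { tap_act = x; tap_shape = s; }
  }
  if (s.flat == false || s.C < 1) Rcpp::stop("network did not end in a linear head");
  softmax_rows(x);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("prob") = Rcpp::wrap(conv_to<mat>::from(x.t())));
  if (tap > 0) {
    Rcpp::NumericVector arr(tap_act.n_elem);
    std::copy(tap_act.begin(), tap_act.end(), arr.begin());
    arr.attr("dim") = Rcpp::IntegerVector::create(tap_shape.H, tap_shape.W,
                                                  tap_shape.C, N);
    out["tap"] = arr;
  }
  return out;
}

struct Optim {
  std::string type; float momentum; long t = 0;
  void step(Layer& L, float lr) {
    if (!L.trainable) return;
    auto upd = [&](fmat& p, fmat& g, fmat& m, fmat& v) {
      if (g.n_elem == 0) return;
      if (m.n_elem == 0) m.zeros(p.n_rows, p.n_cols);
      if (type == "sgd") {
        m = momentum * m + g;
        p -= lr * m;
      } else {
        if (v.n_elem == 0) v.zeros(p.n_rows, p.n_cols);
        m = 0.9f * m + 0.1f * g;
        v = 0.999f * v + 0.001f * (g % g);
        float bc1 = 1.0f - std::pow(0.9f, (float)t);
        float bc2 = 1.0f - std::pow(0.999f, (float)t);
        p -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8f);
      }
      g.zeros();
    };
    if (L.type == "conv" || L.type == "linear") {
      upd(L.W, L.dW, L.mW, L.vW);
      if (L.db.n_elem) {
        if (L.mb.n_elem == 0) L.mb.zeros(L.b.n_elem);
        if (type == "sgd") {
          L.mb = momentum * L.mb + L.db; L.b -= lr * L.mb;
        } else {
          if (L.vb.n_elem == 0) L.vb.zeros(L.b.n_elem);
          L.mb = 0.9f * L.mb + 0.1f * L.db;
          L.vb = 0.999f * L.vb + 0.001f * (L.db % L.db);
          float bc1 = 1.0f - std::pow(0.9f, (float)t);
          float bc2 = 1.0f - std::pow(0.999f, (float)t);
          L.b -= lr * (L.mb / bc1) / (sqrt(L.vb / bc2) + 1e-8f);
        }
        L.db.zeros();
      }
    } else if (L.type == "bn" && L.dgamma.n_elem) {
      if (L.mg.n_elem == 0) { L.mg.zeros(L.gamma.n_elem); L.mbe.zeros(L.beta.n_elem); }
      if (type == "sgd") {
        L.mg = momentum * L.mg + L.dgamma; L.gamma -= lr * L.mg;
        L.mbe = momentum * L.mbe + L.dbeta; L.beta -= lr * L.mbe;
      } else {
        if (L.vg.n_elem == 0) { L.vg.zeros(L.gamma.n_elem); L.vbe.zeros(L.beta.n_elem); }
        float bc1 = 1.0f - std::pow(0.9f, (float)t);
        float bc2 = 1.0f - std::pow(0.999f, (float)t);
        L.mg = 0.9f * L.mg + 0.1f * L.dgamma;
        L.vg = 0.999f * L.vg + 0.001f * (L.dgamma % L.dgamma);
        L.gamma -= lr * (L.mg / bc1) / (sqrt(L.vg / bc2) + 1e-8f);
        L.mbe = 0.9f * L.mbe + 0.1f * L.dbeta;
        L.vbe = 0.999f * L.vbe + 0.001f * (L.dbeta % L.dbeta);
        L.beta -= lr * (L.mbe / bc1) / (sqrt(L.vbe / bc2) + 1e-8f);
      }
      L.dgamma.zeros(); L.dbeta.zeros();
    }
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_nn_train(Rcpp::List layers_r, Rcpp::NumericVector x_r,
                        Rcpp::IntegerVector dims, Rcpp::IntegerVector y_r,
                        Rcpp::List phases, int batch_size, int seed) {
  std::vector<Layer> layers = parse_layers(layers_r);
  Shape s0; s0.H = dims[0]; s0.W = dims[1]; s0.C = dims[2];
  int N = dims[3];
  if ((int)y_r.size() != N) Rcpp::stop("label length does not match batch");
  fmat X(s0.H * s0.W * s0.C, N);
  std::copy(x_r.begin(), x_r.end(), X.begin());
  ivec y(N);
  for (int i = 0; i < N; ++i) y(i) = y_r[i];

  // lowest layer that needs gradients: backprop stops below it
  int first_train = (int)layers.size();
  for (int i = 0; i < (int)layers.size(); ++i)
    if (layers[i].trainable) { first_train = i; break; }

  std::mt19937 rng((unsigned)seed);
  std::vector<double> loss_hist, lr_hist;

  for (int ph = 0; ph < phases.size(); ++ph) {
    Rcpp::List phase = phases[ph];
    int epochs = Rcpp::as<int>(phase["epochs"]);
    double lr0 = Rcpp::as<double>(phase["lr"]);
    std::string opt_type = Rcpp::as<std::string>(phase["optimizer"]);
    double mom = phase.containsElementNamed("momentum")
                     ? Rcpp::as<double>(phase["momentum"]) : 0.9;
    bool cosine = phase.containsElementNamed("cosine")
                      ? Rcpp::as<bool>(phase["cosine"]) : false;
    Optim opt; opt.type = opt_type; opt.momentum = (float)mom;

    for (int e = 0; e < epochs; ++e) {
      double lr = cosine
          ? lr0 * 0.5 * (1.0 + std::cos(datum::pi * (double)e / (double)epochs))
          : lr0;
      lr_hist.push_back(lr);
      std::vector<int> idx(N);
      for (int i = 0; i < N; ++i) idx[i] = i;
      std::shuffle(idx.begin(), idx.end(), rng);
      double epoch_loss = 0.0; int n_seen = 0;
      for (int start = 0; start < N; start += batch_size) {
        int nb = std::min(batch_size, N - start);
        fmat xb(X.n_rows, nb);
        ivec yb(nb);
        for (int i = 0; i < nb; ++i) {
          xb.col(i) = X.col(idx[start + i]);
          yb(i) = y(idx[start + i]);
        }
        // forward with cached inputs
        std::vector<fmat> acts(layers.size() + 1);
        std::vector<Shape> shapes(layers.size() + 1);
        acts[0] = xb; shapes[0] = s0;
        Shape s = s0;
        for (size_t li = 0; li < layers.size(); ++li) {
          acts[li + 1] = layer_forward(layers[li], acts[li], s, true);
          shapes[li + 1] = s;
        }
        fmat probs = acts.back();
        softmax_rows(probs);
        double loss = 0.0;
        for (int i = 0; i < nb; ++i)
          loss -= std::log(std::max(probs(yb(i), i), 1e-12f));
        epoch_loss += loss; n_seen += nb;
        // backward
        fmat dy = probs;
        for (int i = 0; i < nb; ++i) dy(yb(i), i) -= 1.0f;
        dy /= (float)nb;
        for (int li = (int)layers.size() - 1; li >= first_train; --li) {
          bool need_dx = li > first_train;
          dy = layer_backward(layers[li], acts[li], acts[li + 1], dy,
                              shapes[li], need_dx);
        }
        opt.t += 1;
        for (auto& L : layers) opt.step(L, (float)lr);
      }
      loss_hist.push_back(epoch_loss / n_seen);
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("layers") = layers_to_r(layers_r, layers),
      Rcpp::Named("loss") = Rcpp::wrap(loss_hist),
      Rcpp::Named("lr") = Rcpp::wrap(lr_hist));
}
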