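// Compact CNN engine: stacks of (same-padded conv + ReLU -> 2x2 max pool ->
// dropout) followed by a linear dense head, trained with Adam on MSE (or a
// periodic "mixed" loss for 3-output models). Single precision, im2col + GEMM.
// Also hosts the anisotropic Voronoi labeller used by the tissue generator.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PI_D = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// layer plumbing
// ---------------------------------------------------------------------------

// Feature maps are arma::fmat of shape (channels) x (H*W); pixel p = y*W + x.

static void im2col(const arma::fmat& A, int H, int W, int k, arma::fmat& K) {
  const int c = A.n_rows;
  const int h = k / 2;
  K.zeros();
  for (int kr = 0; kr < k; ++kr) {
    const int dr = kr - h;
    for (int kc = 0; kc < k; ++kc) {
      const int dc = kc - h;
      const int rb = (kr * k + kc) * c;  // row block for this kernel offset
      for (int y = 0; y < H; ++y) {
        const int sy = y + dr;
        if (sy < 0 || sy >= H) continue;
        const int x0 = std::max(0, -dc), x1 = std::min(W, W - dc);
        if (x1 <= x0) continue;
        const float* src = A.colptr((size_t)sy * W + x0 + dc);
        float* dst = K.colptr((size_t)y * W + x0) + rb;
        const size_t sK = K.n_rows, sA = A.n_rows;
        for (int j = 0; j < x1 - x0; ++j)
          std::memcpy(dst + (size_t)j * sK, src + (size_t)j * sA,
                      c * sizeof(float));
      }
    }
  }
}

static void col2im_acc(const arma::fmat& K, int H, int W, int k,
                       arma::fmat& dA) {
  const int c = dA.n_rows;
  const int h = k / 2;
  dA.zeros();
  for (int kr = 0; kr < k; ++kr) {
    const int dr = kr - h;
    for (int kc = 0; kc < k; ++kc) {
      const int dc = kc - h;
      const int rb = (kr * k + kc) * c;
      for (int y = 0; y < H; ++y) {
        const int sy = y + dr;
        if (sy < 0 || sy >= H) continue;
        const int x0 = std::max(0, -dc), x1 = std::min(W, W - dc);
        for (int x = x0; x < x1; ++x) {
          const float* src = K.colptr((size_t)y * W + x) + rb;
          float* dst = dA.colptr((size_t)sy * W + x + dc);
          for (int ch = 0; ch < c; ++ch) dst[ch] += src[ch];
        }
      }
    }
  }
}

static void maxpool2(const arma::fmat& A, int H, int W, arma::fmat& out,
                     arma::umat& arg) {
  const int c = A.n_rows, Ho = H / 2, Wo = W / 2;
  for (int y = 0; y < Ho; ++y) {
    for (int x = 0; x < Wo; ++x) {
      const size_t p = (size_t)y * Wo + x;
      const size_t q[4] = {(size_t)(2 * y) * W + 2 * x,
                           (size_t)(2 * y) * W + 2 * x + 1,
                           (size_t)(2 * y + 1) * W + 2 * x,
                           (size_t)(2 * y + 1) * W + 2 * x + 1};
      const float* a0 = A.colptr(q[0]);
      const float* a1 = A.colptr(q[1]);
      const float* a2 = A.colptr(q[2]);
      const float* a3 = A.colptr(q[3]);
      float* o = out.colptr(p);
      arma::uword* g = arg.colptr(p);
      for (int ch = 0; ch < c; ++ch) {
        float best = a0[ch];
        size_t bi = q[0];
        if (a1[ch] > best) { best = a1[ch]; bi = q[1]; }
        if (a2[ch] > best) { best = a2[ch]; bi = q[2]; }
        if (a3[ch] > best) { best = a3[ch]; bi = q[3]; }
        o[ch] = best;
        g[ch] = bi;
      }
    }
  }
}

struct ConvLayer {
  int k = 0, c_in = 0, c_out = 0, H_in = 0, W_in = 0;  // pool halves H_in,W_in
  arma::fmat W, dW, mW, vW;
  arma::fvec b, db, mb, vb;
  // per-image buffers
  arma::fmat K;       // im2col of the layer input
  arma::fmat act;     // post-ReLU conv activation, c_out x (H_in*W_in)
  arma::fmat pooled;  // c_out x (H_in*W_in/4), after dropout during training
  arma::umat arg;     // argmax of the pool
  arma::fmat drop;    // inverted-dropout mask (already scaled)
};

struct Net {
  std::vector<ConvLayer> L;
  int input_size = 0, n_out = 0, flat = 0;
  float dropout = 0.2f;
  arma::fmat Wd, dWd, mWd, vWd;
  arma::fvec bd, dbd, mbd, vbd;
  arma::fmat A0;  // input as 1 x P
  long t_adam = 0;

  void configure(const IntegerMatrix& blocks, int input, int nout,
                 double drop_rate) {
    input_size = input;
    n_out = nout;
    dropout = (float)drop_rate;
    int H = input, c = 1;
    L.resize(blocks.nrow());
    for (int i = 0; i < blocks.nrow(); ++i) {
      ConvLayer& cl = L[i];
      cl.c_out = blocks(i, 0);
      cl.k = blocks(i, 1);
      cl.c_in = c;
      cl.H_in = H;
      cl.W_in = H;
      const size_t P = (size_t)H * H;
      cl.K.set_size((size_t)cl.k * cl.k * cl.c_in, P);
      cl.act.set_size(cl.c_out, P);
      cl.pooled.set_size(cl.c_out, P / 4);
      cl.arg.set_size(cl.c_out, P / 4);
      cl.drop.set_size(cl.c_out, P / 4);
      cl.dW.set_size(cl.c_out, (size_t)cl.k * cl.k * cl.c_in);
      cl.db.set_size(cl.c_out);
      c = cl.c_out;
      H /= 2;
    }
    flat = c * H * H;
    A0.set_size(1, (size_t)input * input);
    dWd.set_size(n_out, flat);
    dbd.set_size(n_out);
  }

  void zero_adam() {
    for (auto& cl : L) {
      cl.mW.zeros(arma::size(cl.dW)); cl.vW.zeros(arma::size(cl.dW));
      cl.mb.zeros(cl.c_out); cl.vb.zeros(cl.c_out);
    }
    mWd.zeros(arma::size(dWd)); vWd.zeros(arma::size(dWd));
    mbd.zeros(n_out); vbd.zeros(n_out);
    t_adam = 0;
  }

  void zero_grads() {
    for (auto& cl : L) { cl.dW.zeros(); cl.db.zeros(); }
    dWd.zeros();
    dbd.zeros();
  }

  // forward one image; x points at input_size^2 floats
  arma::fvec forward(const float* x, bool training, std::mt19937* rng) {
    std::memcpy(A0.memptr(), x, A0.n_elem * sizeof(float));
    const arma::fmat* in = &A0;
    std::uniform_real_distribution<float> unif(0.f, 1.f);
    for (size_t i = 0; i < L.size(); ++i) {
      ConvLayer& cl = L[i];
      im2col(*in, cl.H_in, cl.W_in, cl.k, cl.K);
      cl.act = cl.W * cl.K;
      cl.act.each_col() += cl.b;
      cl.act.transform([](float v) { return v > 0.f ? v : 0.f; });
      maxpool2(cl.act, cl.H_in, cl.W_in, cl.pooled, cl.arg);
      if (training && dropout > 0.f) {
        const float keep = 1.f - dropout;
        float* m = cl.drop.memptr();
        for (size_t j = 0; j < cl.drop.n_elem; ++j)
          m[j] = (unif(*rng) < keep) ? 1.f / keep : 0.f;
        cl.pooled %= cl.drop;
      }
      in = &cl.pooled;
    }
    const arma::fvec f(const_cast<float*>(in->memptr()), flat, false, true);
    return Wd * f + bd;
  }

  // backward one image (buffers hold the forward state); accumulates grads
  void backward(const arma::fvec& dy, bool used_dropout) {
    const ConvLayer& last = L.back();
    const arma::fvec f(const_cast<float*>(last.pooled.memptr()), flat, false,
                       true);
    dWd += dy * f.t();
    dbd += dy;
    arma::fvec dfv = Wd.t() * dy;
    arma::fmat da(dfv.memptr(), last.c_out, flat / last.c_out, false, true);
    arma::fmat cur = da;  // gradient wrt pooled output of the last layer
    for (int i = (int)L.size() - 1; i >= 0; --i) {
      ConvLayer& cl = L[i];
      if (used_dropout && dropout > 0.f) cur %= cl.drop;
      // unpool + ReLU mask
      arma::fmat dz(cl.c_out, (size_t)cl.H_in * cl.W_in, arma::fill::zeros);
      for (size_t p = 0; p < cur.n_cols; ++p) {
        const float* s = cur.colptr(p);
        const arma::uword* g = cl.arg.colptr(p);
        for (int ch = 0; ch < cl.c_out; ++ch)
          if (cl.act(ch, g[ch]) > 0.f) dz(ch, g[ch]) += s[ch];
      }
      cl.dW += dz * cl.K.t();
      cl.db += arma::sum(dz, 1);
      if (i > 0) {
        arma::fmat dK = cl.W.t() * dz;
        arma::fmat dA(cl.c_in, (size_t)cl.H_in * cl.W_in);
        col2im_acc(dK, cl.H_in, cl.W_in, cl.k, dA);
        cur = dA;
      }
    }
  }
};

static void adam_step(arma::fmat& W, const arma::fmat& g, arma::fmat& m,
                      arma::fmat& v, double lr, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * (g % g);
  const double c1 = 1.0 - std::pow(b1, (double)t);
  const double c2 = 1.0 - std::pow(b2, (double)t);
  const float a = (float)(lr / c1);
  const float sc = (float)std::sqrt(c2);
  W -= a * (m / (arma::sqrt(v) / sc + (float)eps));
}

static void adam_step(arma::fvec& W, const arma::fvec& g, arma::fvec& m,
                      arma::fvec& v, double lr, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * (g % g);
  const double c1 = 1.0 - std::pow(b1, (double)t);
  const double c2 = 1.0 - std::pow(b2, (double)t);
  const float a = (float)(lr / c1);
  const float sc = (float)std::sqrt(c2);
  W -= a * (m / (arma::sqrt(v) / sc + (float)eps));
}

// ---------------------------------------------------------------------------
// weights <-> R lists
// ---------------------------------------------------------------------------

static void load_weights(Net& net, const List& weights) {
  int idx = 0;
  for (size_t i = 0; i < net.L.size(); ++i) {
    ConvLayer& cl = net.L[i];
    NumericVector w = weights[idx++];
    NumericVector b = weights[idx++];
    cl.W.set_size(cl.c_out, (size_t)cl.k * cl.k * cl.c_in);
    if ((size_t)w.size() != cl.W.n_elem)
      stop("conv weight length mismatch at block %d", (int)i + 1);
    std::copy(w.begin(), w.end(), cl.W.memptr());
    cl.b.set_size(cl.c_out);
    if (b.size() != cl.c_out) stop("conv bias length mismatch");
    std::copy(b.begin(), b.end(), cl.b.memptr());
  }
  NumericVector wd = weights[idx++];
  NumericVector bd = weights[idx++];
  net.Wd.set_size(net.n_out, net.flat);
  if ((size_t)wd.size() != net.Wd.n_elem) stop("dense weight length mismatch");
  std::copy(wd.begin(), wd.end(), net.Wd.memptr());
  net.bd.set_size(net.n_out);
  std::copy(bd.begin(), bd.end(), net.bd.memptr());
}

static List dump_weights(const Net& net) {
  List out;
  CharacterVector nm;
  for (size_t i = 0; i < net.L.size(); ++i) {
    const ConvLayer& cl = net.L[i];
    out.push_back(NumericVector(cl.W.begin(), cl.W.end()));
    out.push_back(NumericVector(cl.b.begin(), cl.b.end()));
    nm.push_back("conv" + std::to_string(i + 1) + "_w");
    nm.push_back("conv" + std::to_string(i + 1) + "_b");
  }
  out.push_back(NumericVector(net.Wd.begin(), net.Wd.end()));
  out.push_back(NumericVector(net.bd.begin(), net.bd.end()));
  nm.push_back("dense_w");
  nm.push_back("dense_b");
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
List cpp_cnn_init(IntegerMatrix blocks, int input_size, int n_outputs,
                  double dropout_rate, int seed) {
  Net net;
  net.configure(blocks, input_size, n_outputs, dropout_rate);
  std::mt19937 rng((unsigned)seed);
  for (auto& cl : net.L) {
    const double fan_in = (double)cl.k * cl.k * cl.c_in;
    const double fan_out = (double)cl.k * cl.k * cl.c_out;
    const double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> u(-lim, lim);
    cl.W.set_size(cl.c_out, (size_t)cl.k * cl.k * cl.c_in);
    for (size_t j = 0; j < cl.W.n_elem; ++j) cl.W.memptr()[j] = (float)u(rng);
    cl.b.zeros(cl.c_out);
  }
  const double lim = std::sqrt(6.0 / (net.flat + net.n_out));
  std::uniform_real_distribution<double> u(-lim, lim);
  net.Wd.set_size(net.n_out, net.flat);
  for (size_t j = 0; j < net.Wd.n_elem; ++j) net.Wd.memptr()[j] = (float)u(rng);
  net.bd.zeros(net.n_out);
  return dump_weights(net);
}

// X: n x (input^2), rows = samples. Returns n x n_outputs predictions.
// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(IntegerMatrix blocks, int input_size,
                              int n_outputs, double dropout_rate, List weights,
                              NumericMatrix X) {
  Net net;
  net.configure(blocks, input_size, n_outputs, dropout_rate);
  load_weights(net, weights);
  const int n = X.nrow();
  const size_t P = (size_t)input_size * input_size;
  if ((size_t)X.ncol() != P) stop("input pixel count mismatch");
  NumericMatrix out(n, n_outputs);
  arma::fvec xbuf(P);
  for (int i = 0; i < n; ++i) {
    for (size_t j = 0; j < P; ++j) xbuf[j] = (float)X(i, j);
    arma::fvec y = net.forward(xbuf.memptr(), false, nullptr);
    for (int k = 0; k < n_outputs; ++k) out(i, k) = y[k];
  }
  return out;
}

// loss_type 0: MSE averaged over outputs. loss_type 1 ("mixed", 3 outputs):
// squared errors on the first two outputs plus the squared orientation error
// folded modulo pi, summed.
static double sample_loss_grad(const arma::fvec& pred, const float* y,
                               int n_out, int loss_type, arma::fvec& dy) {
  double loss = 0.0;
  if (loss_type == 0) {
    for (int k = 0; k < n_out; ++k) {
      const double d = pred[k] - y[k];
      loss += d * d;
      dy[k] = (float)(2.0 * d / n_out);
    }
    return loss / n_out;
  }
  for (int k = 0; k < n_out - 1; ++k) {
    const double d = pred[k] - y[k];
    loss += d * d;
    dy[k] = (float)(2.0 * d);
  }
  double d = (double)pred[n_out - 1] - y[n_out - 1] + PI_D / 2;
  d -= std::floor(d / PI_D) * PI_D;  // reduce into [0, pi)
  d -= PI_D / 2;
  loss += d * d;
  dy[n_out - 1] = (float)(2.0 * d);
  return loss;
}

// [[Rcpp::export]]
List cpp_cnn_train(IntegerMatrix blocks, int input_size, int n_outputs,
                   double dropout_rate, List weights, NumericMatrix X,
                   NumericMatrix Y, NumericMatrix Xval, NumericMatrix Yval,
                   int epochs, int batch_size, double lr, int patience,
                   int seed, int loss_type) {
  Net net;
  net.configure(blocks, input_size, n_outputs, dropout_rate);
  load_weights(net, weights);
  net.zero_adam();

  const int n = X.nrow(), nval = Xval.nrow();
  const size_t P = (size_t)input_size * input_size;
  if ((size_t)X.ncol() != P) stop("input pixel count mismatch");

  // column-major single-precision copies, one column per sample
  arma::fmat Xf(P, n), Yf(n_outputs, n), Xvf(P, std::max(nval, 1)),
      Yvf(n_outputs, std::max(nval, 1));
  for (int i = 0; i < n; ++i)
    for (size_t j = 0; j < P; ++j) Xf(j, i) = (float)X(i, j);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n_outputs; ++k) Yf(k, i) = (float)Y(i, k);
  for (int i = 0; i < nval; ++i)
    for (size_t j = 0; j < P; ++j) Xvf(j, i) = (float)Xval(i, j);
  for (int i = 0; i < nval; ++i)
    for (int k = 0; k < n_outputs; ++k) Yvf(k, i) = (float)Yval(i, k);

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> train_hist, val_hist;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0, wait = 0;
  List best_weights = dump_weights(net);
  arma::fvec dy(n_outputs);

  for (int ep = 1; ep <= epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double tr_loss = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int bend = std::min(start + batch_size, n);
      const int bs = bend - start;
      net.zero_grads();
      for (int ii = start; ii < bend; ++ii) {
        const int s = order[ii];
        arma::fvec pred = net.forward(Xf.colptr(s), true, &rng);
        tr_loss += sample_loss_grad(pred, Yf.colptr(s), n_outputs, loss_type,
                                    dy);
        net.backward(dy, true);
      }
      const float inv = 1.f / bs;
      for (auto& cl : net.L) { cl.dW *= inv; cl.db *= inv; }
      net.dWd *= inv;
      net.dbd *= inv;
      ++net.t_adam;
      for (auto& cl : net.L) {
        adam_step(cl.W, cl.dW, cl.mW, cl.vW, lr, net.t_adam);
        adam_step(cl.b, cl.db, cl.mb, cl.vb, lr, net.t_adam);
      }
      adam_step(net.Wd, net.dWd, net.mWd, net.vWd, lr, net.t_adam);
      adam_step(net.bd, net.dbd, net.mbd, net.vbd, lr, net.t_adam);
      ++nb;
    }
    train_hist.push_back(tr_loss / n);

    double vl = 0.0;
    for (int i = 0; i < nval; ++i) {
      arma::fvec pred = net.forward(Xvf.colptr(i), false, nullptr);
      vl += sample_loss_grad(pred, Yvf.colptr(i), n_outputs, loss_type, dy);
    }
    vl = nval > 0 ? vl / nval : train_hist.back();
    val_hist.push_back(vl);

    if (vl < best_val) {
      best_val = vl;
      best_epoch = ep;
      best_weights = dump_weights(net);
      wait = 0;
    } else {
      ++wait;
      if (wait > patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["weights"] = best_weights,
                      _["train_loss"] = NumericVector(train_hist.begin(),
                                                      train_hist.end()),
                      _["val_loss"] = NumericVector(val_hist.begin(),
                                                    val_hist.end()),
                      _["best_epoch"] = best_epoch,
                      _["best_val_loss"] = best_val,
                      _["epochs_run"] = (int)val_hist.size());
}

// ---------------------------------------------------------------------------
// anisotropic Voronoi labelling for the synthetic tissue generator
// ---------------------------------------------------------------------------

// Pixel (row r, col c) is assigned to the seed minimizing an anisotropic
// metric: the displacement component along the seed's orientation is divided
// by its stretch, so cells extend ~stretch times further along it.
// seeds: n x 2 matrix of (x = col, y = row), 0-based.
// [[Rcpp::export]]
IntegerMatrix cpp_anisotropic_voronoi(int H, int W, NumericMatrix seeds,
                                      NumericVector angle,
                                      NumericVector stretch) {
  const int n = seeds.nrow();
  std::vector<double> sx(n), sy(n), ca(n), sa(n), inv_s2(n);
  double max_s2 = 1.0;
  for (int i = 0; i < n; ++i) {
    sx[i] = seeds(i, 0);
    sy[i] = seeds(i, 1);
    ca[i] = std::cos(angle[i]);
    sa[i] = std::sin(angle[i]);
    inv_s2[i] = 1.0 / (stretch[i] * stretch[i]);
    max_s2 = std::max(max_s2, stretch[i] * stretch[i]);
  }
  IntegerMatrix lab(H, W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double best = std::numeric_limits<double>::infinity();
      int bi = 0;
      for (int i = 0; i < n; ++i) {
        const double dx = c - sx[i], dy = r - sy[i];
        const double de = dx * dx + dy * dy;
        if (de / max_s2 >= best) continue;
        const double u = dx * ca[i] + dy * sa[i];
        const double v = -dx * sa[i] + dy * ca[i];
        const double d = u * u * inv_s2[i] + v * v;
        if (d < best) { best = d; bi = i; }
      }
      lab(r, c) = bi + 1;
    }
  }
  return lab;
}

// Membrane mask: pixel whose right or down neighbour carries another label.
// [[Rcpp::export]]
LogicalMatrix cpp_boundary_mask(IntegerMatrix labels) {
  const int H = labels.nrow(), W = labels.ncol();
  LogicalMatrix m(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      bool b = false;
      if (c + 1 < W && labels(r, c + 1) != labels(r, c)) b = true;
      if (!b && r + 1 < H && labels(r + 1, c) != labels(r, c)) b = true;
      m(r, c) = b;
    }
  return m;
}
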