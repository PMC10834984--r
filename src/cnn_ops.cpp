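// Training and inference kernels for the compact 3-block convolutional
// network: [conv 3x3 valid + ReLU + maxpool 2x2/2] x 3 -> flatten -> dropout
// -> dense ReLU -> dense softmax, optimized with Adam on categorical
// cross-entropy. The only randomness is the dropout mask, driven by an
// explicit integer seed so runs are reproducible bit-for-bit.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

// im2col for valid 3x3 (or k x k) convolution. Row index r = di + dj*k + c*k*k,
// column index p = i + j*Ho (column-major over output pixels).
static mat im2col(const cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H - k + 1, Wo = W - k + 1;
  mat col(k * k * C, Ho * Wo);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const int r = di + dj * k + c * k * k;
        for (int j = 0; j < Wo; ++j)
          for (int i = 0; i < Ho; ++i)
            col(r, i + j * Ho) = x(i + di, j + dj, c);
      }
  return col;
}

static void col2im_add(cube& dx, const mat& dcol, int k) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  const int Ho = H - k + 1, Wo = W - k + 1;
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const int r = di + dj * k + c * k * k;
        for (int j = 0; j < Wo; ++j)
          for (int i = 0; i < Ho; ++i)
            dx(i + di, j + dj, c) += dcol(r, i + j * Ho);
      }
}

// 2x2 stride-2 max pooling with floor division; argmax (first occurrence in
// column-major scan order) recorded as a linear index into the input slice.
static void maxpool(const cube& x, cube& out, arma::umat& arg) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  out.set_size(Ho, Wo, C);
  arg.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        arma::uword bi = 2 * i + 2 * j * H;
        const int ii[4] = {2 * i, 2 * i + 1, 2 * i, 2 * i + 1};
        const int jj[4] = {2 * j, 2 * j, 2 * j + 1, 2 * j + 1};
        for (int t = 1; t < 4; ++t) {
          const double v = x(ii[t], jj[t], c);
          if (v > best) { best = v; bi = ii[t] + (arma::uword)jj[t] * H; }
        }
        out(i, j, c) = best;
        arg(i + j * Ho, c) = bi;
      }
}

struct BlockCache {
  mat col;        // im2col of the block input
  arma::umat relu;  // ReLU mask on pre-activation (F x P)
  arma::umat arg;   // pooling argmax
  int Hin, Win, Cin, Hc, Wc; // conv-output spatial dims
};

struct Net {
  std::vector<mat> Wc; std::vector<vec> bc;
  mat Wd; vec bd; mat Wo; vec bo;
  int k; // kernel size
};

static Net unpack(const List& w) {
  Net net;
  List Wc = w["Wc"], bc = w["bc"];
  for (int i = 0; i < Wc.size(); ++i) {
    net.Wc.push_back(as<mat>(Wc[i]));
    net.bc.push_back(as<vec>(bc[i]));
  }
  net.Wd = as<mat>(w["Wd"]); net.bd = as<vec>(w["bd"]);
  net.Wo = as<mat>(w["Wo"]); net.bo = as<vec>(w["bo"]);
  net.k = as<int>(w["kernel"]);
  return net;
}

static List pack(const Net& net) {
  List Wc(net.Wc.size()), bc(net.bc.size());
  for (size_t i = 0; i < net.Wc.size(); ++i) { Wc[i] = net.Wc[i]; bc[i] = net.bc[i]; }
  return List::create(_["Wc"] = Wc, _["bc"] = bc, _["Wd"] = net.Wd,
                      _["bd"] = net.bd, _["Wo"] = net.Wo, _["bo"] = net.bo,
                      _["kernel"] = net.k);
}

// Forward through the conv blocks; caches filled only when `train` is true.
static cube forward_blocks(const Net& net, cube x, std::vector<BlockCache>* caches) {
  for (size_t b = 0; b < net.Wc.size(); ++b) {
    mat col = im2col(x, net.k);
    mat z = net.Wc[b] * col;
    z.each_col() += net.bc[b];
    arma::umat rmask = (z > 0);
    z %= arma::conv_to<mat>::from(rmask);
    const int Hc = x.n_rows - net.k + 1, Wcc = x.n_cols - net.k + 1;
    const int F = net.Wc[b].n_rows;
    cube conv(Hc, Wcc, F);
    for (int f = 0; f < F; ++f)
      conv.slice(f) = arma::reshape(z.row(f), Hc, Wcc);
    cube pooled; arma::umat arg;
    maxpool(conv, pooled, arg);
    if (caches) {
      BlockCache cc;
      cc.col = std::move(col); cc.relu = std::move(rmask); cc.arg = std::move(arg);
      cc.Hin = x.n_rows; cc.Win = x.n_cols; cc.Cin = x.n_slices;
      cc.Hc = Hc; cc.Wc = Wcc;
      (*caches)[b] = std::move(cc);
    }
    x = std::move(pooled);
  }
  return x;
}

static vec softmax(vec o) {
  o -= o.max();
  vec e = arma::exp(o);
  return e / arma::accu(e);
}

// One full epoch of minibatch Adam. x: (H, W, C, N) array; y: 0-based labels;
// order: 0-based visiting order. Returns updated weights, Adam state, step
// counter and the epoch's mean loss / accuracy.
// [[Rcpp::export(name = ".cnn_epoch_cpp")]]
List cnn_epoch_cpp(NumericVector x, IntegerVector y, List weights, List adam,
                   double lr, double beta1, double beta2, double eps,
                   int batch_size, IntegerVector order, double dropout,
                   int dropout_seed, int t0) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const double* base = REAL(x);
  Net net = unpack(weights);
  const int nb = net.Wc.size();

  // Adam state (zero-initialized on first call)
  Net m = net, v = net;
  bool fresh = adam.size() == 0;
  if (fresh) {
    for (int i = 0; i < nb; ++i) { m.Wc[i].zeros(); m.bc[i].zeros(); v.Wc[i].zeros(); v.bc[i].zeros(); }
    m.Wd.zeros(); m.bd.zeros(); m.Wo.zeros(); m.bo.zeros();
    v.Wd.zeros(); v.bd.zeros(); v.Wo.zeros(); v.bo.zeros();
  } else {
    m = unpack(as<List>(adam["m"]));
    v = unpack(as<List>(adam["v"]));
  }

  std::mt19937 rng(dropout_seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  int t = t0;
  double loss_sum = 0.0; int correct = 0;
  Net g = net; // gradient accumulators (shapes only)

  for (int start = 0; start < N; start += batch_size) {
    const int bsz = std::min(batch_size, N - start);
    for (int i = 0; i < nb; ++i) { g.Wc[i].zeros(); g.bc[i].zeros(); }
    g.Wd.zeros(); g.bd.zeros(); g.Wo.zeros(); g.bo.zeros();

    for (int s = 0; s < bsz; ++s) {
      const int idx = order[start + s];
      cube xi(const_cast<double*>(base + (size_t)idx * H * W * C), H, W, C, false, true);
      std::vector<BlockCache> caches(nb);
      cube feat = forward_blocks(net, xi, &caches);
      vec flat = arma::vectorise(feat);

      // inverted dropout
      vec mask(flat.n_elem, arma::fill::ones);
      if (dropout > 0) {
        for (arma::uword i = 0; i < mask.n_elem; ++i)
          mask(i) = unif(rng) >= dropout ? 1.0 / (1.0 - dropout) : 0.0;
      }
      vec fd = flat % mask;
      vec hpre = net.Wd * fd + net.bd;
      vec h = arma::clamp(hpre, 0.0, arma::datum::inf);
      vec p = softmax(net.Wo * h + net.bo);

      const int yi = y[idx];
      loss_sum += -std::log(std::max(p(yi), 1e-300));
      if ((int)p.index_max() == yi) ++correct;

      vec dout = p; dout(yi) -= 1.0;
      g.Wo += dout * h.t(); g.bo += dout;
      vec dh = (net.Wo.t() * dout) % (hpre > 0);
      g.Wd += dh * fd.t(); g.bd += dh;
      vec dflat = (net.Wd.t() * dh) % mask;

      // back through blocks
      cube dpool(dflat.memptr(), feat.n_rows, feat.n_cols, feat.n_slices);
      for (int b = nb - 1; b >= 0; --b) {
        const BlockCache& cc = caches[b];
        // unpool
        cube dconv(cc.Hc, cc.Wc, net.Wc[b].n_rows, arma::fill::zeros);
        const int Ho = cc.Hc / 2, Wo2 = cc.Wc / 2;
        for (arma::uword c = 0; c < dconv.n_slices; ++c) {
          double* sl = dconv.slice_memptr(c);
          for (int pcol = 0; pcol < Ho * Wo2; ++pcol)
            sl[cc.arg(pcol, c)] += dpool(pcol % Ho, pcol / Ho, c);
        }
        // relu + conv backward; slice c of dconv is filter c's spatial grad
        mat dzm(net.Wc[b].n_rows, cc.Hc * cc.Wc);
        for (arma::uword c = 0; c < dconv.n_slices; ++c)
          dzm.row(c) = arma::vectorise(dconv.slice(c)).t();
        dzm %= arma::conv_to<mat>::from(cc.relu);
        g.Wc[b] += dzm * cc.col.t();
        g.bc[b] += arma::sum(dzm, 1);
        if (b > 0) {
          mat dcol = net.Wc[b].t() * dzm;
          cube dx(cc.Hin, cc.Win, cc.Cin, arma::fill::zeros);
          col2im_add(dx, dcol, net.k);
          dpool = std::move(dx);
        }
      }
    }

    // Adam step on batch-mean gradients
    ++t;
    const double bc1 = 1.0 - std::pow(beta1, t), bc2 = 1.0 - std::pow(beta2, t);
    auto upd = [&](mat& w, mat& mm, mat& vv, const mat& gr) {
      mat gb = gr / (double)bsz;
      mm = beta1 * mm + (1 - beta1) * gb;
      vv = beta2 * vv + (1 - beta2) * (gb % gb);
      w -= lr * (mm / bc1) / (arma::sqrt(vv / bc2) + eps);
    };
    auto updv = [&](vec& w, vec& mm, vec& vv, const vec& gr) {
      vec gb = gr / (double)bsz;
      mm = beta1 * mm + (1 - beta1) * gb;
      vv = beta2 * vv + (1 - beta2) * (gb % gb);
      w -= lr * (mm / bc1) / (arma::sqrt(vv / bc2) + eps);
    };
    for (int i = 0; i < nb; ++i) { upd(net.Wc[i], m.Wc[i], v.Wc[i], g.Wc[i]); updv(net.bc[i], m.bc[i], v.bc[i], g.bc[i]); }
    upd(net.Wd, m.Wd, v.Wd, g.Wd); updv(net.bd, m.bd, v.bd, g.bd);
    upd(net.Wo, m.Wo, v.Wo, g.Wo); updv(net.bo, m.bo, v.bo, g.bo);
  }

  return List::create(
    _["weights"] = pack(net),
    _["adam"] = List::create(_["m"] = pack(m), _["v"] = pack(v)),
    _["t"] = t,
    _["loss"] = loss_sum / N,
    _["acc"] = (double)correct / N);
}

// Forward pass for inference (no dropout). Returns an N x K probability matrix.
// [[Rcpp::export(name = ".cnn_predict_cpp")]]
NumericMatrix cnn_predict_cpp(NumericVector x, List weights) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const double* base = REAL(x);
  Net net = unpack(weights);
  const int K = net.Wo.n_rows;
  NumericMatrix out(N, K);
  for (int idx = 0; idx < N; ++idx) {
    cube xi(const_cast<double*>(base + (size_t)idx * H * W * C), H, W, C, false, true);
    cube feat = forward_blocks(net, xi, nullptr);
    vec flat = arma::vectorise(feat);
    vec h = arma::clamp(net.Wd * flat + net.bd, 0.0, arma::datum::inf);
    vec p = softmax(net.Wo * h + net.bo);
    for (int k2 = 0; k2 < K; ++k2) out(idx, k2) = p(k2);
  }
  return out;
}
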