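// Low-level numerical kernels: U-Net forward/backward passes, 8-connected
// component labeling, and exact small-set point matching.
//
// Feature maps are stored as arma::mat of shape (channels x H*W) with pixel
// index p = y + x*H, i.e. R's column-major layout for an H x W matrix, so an
// image matrix passed from R can be used without reordering.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

// ---------------------------------------------------------------------------
// im2col / col2im for 3x3 kernels with zero padding 1 ("same" output size)
// ---------------------------------------------------------------------------

static mat im2col3(const mat& F, int H, int W) {
  const int C = F.n_rows;
  mat out(9 * C, H * W, arma::fill::zeros);
  for (int kx = -1; kx <= 1; ++kx) {
    for (int ky = -1; ky <= 1; ++ky) {
      const int k = (ky + 1) + 3 * (kx + 1);
      for (int x = 0; x < W; ++x) {
        const int xs = x + kx;
        if (xs < 0 || xs >= W) continue;
        const int y0 = std::max(0, -ky), y1 = std::min(H, H - ky);
        if (y1 <= y0) continue;
        out.submat(k * C, x * H + y0, (k + 1) * C - 1, x * H + y1 - 1) =
            F.cols(xs * H + y0 + ky, xs * H + y1 - 1 + ky);
      }
    }
  }
  return out;
}

static mat col2im3(const mat& cols, int C, int H, int W) {
  mat out(C, H * W, arma::fill::zeros);
  for (int kx = -1; kx <= 1; ++kx) {
    for (int ky = -1; ky <= 1; ++ky) {
      const int k = (ky + 1) + 3 * (kx + 1);
      for (int x = 0; x < W; ++x) {
        const int xs = x + kx;
        if (xs < 0 || xs >= W) continue;
        const int y0 = std::max(0, -ky), y1 = std::min(H, H - ky);
        if (y1 <= y0) continue;
        out.cols(xs * H + y0 + ky, xs * H + y1 - 1 + ky) +=
            cols.submat(k * C, x * H + y0, (k + 1) * C - 1, x * H + y1 - 1);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 2x2 max-pool (stride 2) and 2x2 nearest-neighbour upsampling
// ---------------------------------------------------------------------------

static mat maxpool2(const mat& F, int H, int W, arma::umat& idx) {
  const int C = F.n_rows, Ho = H / 2, Wo = W / 2;
  mat out(C, Ho * Wo);
  idx.set_size(C, Ho * Wo);
  for (int xo = 0; xo < Wo; ++xo) {
    for (int yo = 0; yo < Ho; ++yo) {
      const int po = yo + xo * Ho;
      const int p00 = 2 * yo + (2 * xo) * H;
      const int cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
      for (int c = 0; c < C; ++c) {
        double v = F(c, cand[0]);
        int b = cand[0];
        for (int j = 1; j < 4; ++j)
          if (F(c, cand[j]) > v) { v = F(c, cand[j]); b = cand[j]; }
        out(c, po) = v;
        idx(c, po) = b;
      }
    }
  }
  return out;
}

static mat maxpool2_back(const mat& dY, const arma::umat& idx, int C, int H, int W) {
  mat out(C, H * W, arma::fill::zeros);
  for (arma::uword p = 0; p < dY.n_cols; ++p)
    for (int c = 0; c < C; ++c)
      out(c, idx(c, p)) += dY(c, p);
  return out;
}

static mat upsample2(const mat& F, int H, int W) {  // H, W of the *input*
  const int C = F.n_rows, Ho = 2 * H, Wo = 2 * W;
  mat out(C, Ho * Wo);
  for (int x = 0; x < Wo; ++x)
    for (int y = 0; y < Ho; ++y)
      out.col(y + x * Ho) = F.col((y >> 1) + (x >> 1) * H);
  return out;
}

static mat upsample2_back(const mat& dY, int H, int W) {  // H, W of the input map
  const int C = dY.n_rows, Ho = 2 * H;
  mat out(C, H * W, arma::fill::zeros);
  for (int x = 0; x < 2 * W; ++x)
    for (int y = 0; y < Ho; ++y)
      out.col((y >> 1) + (x >> 1) * H) += dY.col(y + x * Ho);
  return out;
}

// ---------------------------------------------------------------------------
// Deterministic dropout RNG (xorshift64*), independent of R's RNG stream
// ---------------------------------------------------------------------------

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  double unif() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return (double)(s >> 11) * (1.0 / 9007199254740992.0);
  }
};

// ---------------------------------------------------------------------------
// Convolution layer with ReLU and (optional) inverted dropout
// ---------------------------------------------------------------------------

struct ConvCache {
  mat cols;      // im2col of the layer input
  mat relu_out;  // activation after ReLU, before dropout
  mat drop_mask; // empty when dropout is off
  int C_in = 0, H = 0, W = 0;
};

static mat conv_fwd(const mat& Wm, const vec& b, const mat& in, int H, int W,
                    bool train, double drop, XorShift& rng, ConvCache& cc) {
  cc.C_in = in.n_rows; cc.H = H; cc.W = W;
  cc.cols = im2col3(in, H, W);
  mat z = Wm * cc.cols;
  z.each_col() += b;
  z.transform([](double v) { return v > 0.0 ? v : 0.0; });
  cc.relu_out = z;
  if (train && drop > 0.0) {
    const double keep = 1.0 - drop, inv = 1.0 / keep;
    cc.drop_mask.set_size(z.n_rows, z.n_cols);
    for (arma::uword i = 0; i < z.n_elem; ++i)
      cc.drop_mask(i) = (rng.unif() < keep) ? inv : 0.0;
    return z % cc.drop_mask;
  }
  cc.drop_mask.reset();
  return z;
}

// dOut is the gradient w.r.t. the layer output (post-dropout); returns dIn.
static mat conv_bwd(const mat& Wm, const ConvCache& cc, mat dOut,
                    mat& dW, vec& db) {
  if (cc.drop_mask.n_elem) dOut %= cc.drop_mask;
  dOut.elem(arma::find(cc.relu_out <= 0.0)).zeros();
  dW = dOut * cc.cols.t();
  db = arma::sum(dOut, 1);
  mat dcols = Wm.t() * dOut;
  return col2im3(dcols, cc.C_in, cc.H, cc.W);
}

// ---------------------------------------------------------------------------
// Full U-Net: encoder (depth levels, two 3x3 convs each, 2x2 pools between),
// decoder (2x2 nearest upsample + skip concatenation + two 3x3 convs),
// final 1x1 convolution to n_classes with per-pixel softmax.
//
// Parameter list order (matching R/unet.R):
//   enc level 1..depth:        W1, b1, W2, b2
//   dec level depth-1 .. 1:    W1, b1, W2, b2
//   output head:               W,  b
// ---------------------------------------------------------------------------

struct NetShape {
  int depth, base, n_classes, H, W, in_ch;
  int filters(int level) const { return base << (level - 1); }
};

static NetShape read_cfg(const IntegerVector& cfg) {
  NetShape s;
  s.depth = cfg[0]; s.base = cfg[1]; s.n_classes = cfg[2];
  s.H = cfg[3]; s.W = cfg[4]; s.in_ch = cfg[5];
  return s;
}

struct Caches {
  std::vector<ConvCache> enc1, enc2, dec1, dec2;
  std::vector<arma::umat> pool_idx;
  std::vector<mat> enc_out;   // skip tensors e_l (post conv2, pre pool)
  std::vector<mat> dec_out;   // decoder outputs per level (level-indexed)
  mat head_in;                // input of the 1x1 output conv
};

static mat unet_forward_impl(const List& params, const NetShape& s, const mat& x,
                             bool train, double drop, uint64_t seed, Caches* C) {
  XorShift rng(seed);
  const int D = s.depth;
  Caches local;
  Caches& cc = C ? *C : local;
  cc.enc1.resize(D + 1); cc.enc2.resize(D + 1);
  cc.dec1.resize(D); cc.dec2.resize(D);
  cc.pool_idx.resize(D); cc.enc_out.resize(D + 1); cc.dec_out.resize(D);

  int pi = 0;
  mat cur = x;
  int H = s.H, W = s.W;
  for (int l = 1; l <= D; ++l) {
    mat W1 = params[pi++]; vec b1 = as<vec>(params[pi++]);
    mat W2 = params[pi++]; vec b2 = as<vec>(params[pi++]);
    cur = conv_fwd(W1, b1, cur, H, W, train, drop, rng, cc.enc1[l]);
    cur = conv_fwd(W2, b2, cur, H, W, train, drop, rng, cc.enc2[l]);
    cc.enc_out[l] = cur;
    if (l < D) {
      cur = maxpool2(cur, H, W, cc.pool_idx[l]);
      H /= 2; W /= 2;
    }
  }
  for (int l = D - 1; l >= 1; --l) {
    mat W1 = params[pi++]; vec b1 = as<vec>(params[pi++]);
    mat W2 = params[pi++]; vec b2 = as<vec>(params[pi++]);
    mat up = upsample2(cur, H, W);
    H *= 2; W *= 2;
    mat cat = arma::join_cols(up, cc.enc_out[l]);
    cur = conv_fwd(W1, b1, cat, H, W, train, drop, rng, cc.dec1[l]);
    cur = conv_fwd(W2, b2, cur, H, W, train, drop, rng, cc.dec2[l]);
    cc.dec_out[l] = cur;
  }
  mat Wo = params[pi++]; vec bo = as<vec>(params[pi++]);
  cc.head_in = cur;
  mat logits = Wo * cur;
  logits.each_col() += bo;
  // per-pixel softmax
  arma::rowvec mx = arma::max(logits, 0);
  logits.each_row() -= mx;
  logits = arma::exp(logits);
  arma::rowvec zs = arma::sum(logits, 0);
  logits.each_row() /= zs;
  return logits;  // probabilities, n_classes x HW
}

// [[Rcpp::export]]
arma::mat cpp_unet_forward(List params, IntegerVector cfg, arma::mat x) {
  NetShape s = read_cfg(cfg);
  return unet_forward_impl(params, s, x, false, 0.0, 0, nullptr);
}

// [[Rcpp::export]]
double cpp_unet_loss(List params, IntegerVector cfg, arma::mat x,
                     arma::ivec y, arma::vec class_weights) {
  NetShape s = read_cfg(cfg);
  mat P = unet_forward_impl(params, s, x, false, 0.0, 0, nullptr);
  const int HW = P.n_cols;
  double loss = 0.0, wsum = 0.0;
  for (int p = 0; p < HW; ++p) {
    const double w = class_weights[y[p]];
    loss -= w * std::log(std::max(P(y[p], p), 1e-12));
    wsum += w;
  }
  return loss / wsum;
}

// [[Rcpp::export]]
List cpp_unet_grad(List params, IntegerVector cfg, arma::mat x, arma::ivec y,
                   double dropout, double seed, arma::vec class_weights) {
  NetShape s = read_cfg(cfg);
  Caches cc;
  mat P = unet_forward_impl(params, s, x, true, dropout, (uint64_t)seed, &cc);

  const int D = s.depth, HW = s.H * s.W;
  double wsum = 0.0, loss = 0.0;
  for (int p = 0; p < HW; ++p) {
    const double w = class_weights[y[p]];
    loss -= w * std::log(std::max(P(y[p], p), 1e-12));
    wsum += w;
  }
  loss /= wsum;

  // d logits of the softmax + weighted CE: w_y * (p - onehot) / wsum
  mat dlog = P;
  for (int p = 0; p < HW; ++p) {
    dlog(y[p], p) -= 1.0;
    dlog.col(p) *= class_weights[y[p]];
  }
  dlog /= wsum;

  const int n_par = params.size();
  List grads(n_par);
  int pi = n_par - 2;
  mat Wo = params[pi];
  grads[pi] = wrap(mat(dlog * cc.head_in.t()));
  grads[pi + 1] = wrap(vec(arma::sum(dlog, 1)));
  mat dcur = Wo.t() * dlog;

  // decoder backward: forward order was l = D-1 .. 1, so reverse is l = 1 .. D-1
  int H = s.H, W = s.W;
  std::vector<mat> dskip(D + 1);
  for (int l = 1; l <= D - 1; ++l) {
    const int base_i = 4 * D + 4 * (D - 1 - l);
    mat W1 = params[base_i]; mat W2 = params[base_i + 2];
    mat dW1, dW2; vec db1, db2;
    mat d_mid = conv_bwd(W2, cc.dec2[l], dcur, dW2, db2);
    mat d_cat = conv_bwd(W1, cc.dec1[l], d_mid, dW1, db1);
    grads[base_i] = wrap(dW1); grads[base_i + 1] = wrap(db1);
    grads[base_i + 2] = wrap(dW2); grads[base_i + 3] = wrap(db2);
    const int ch_up = s.filters(l + 1);
    mat d_up = d_cat.rows(0, ch_up - 1);
    dskip[l] = d_cat.rows(ch_up, d_cat.n_rows - 1);
    dcur = upsample2_back(d_up, H / 2, W / 2);
    H /= 2; W /= 2;
  }
  // here dcur is the gradient w.r.t. enc_out[D] (bottleneck)

  // encoder backward: l = D .. 1; each level's output gradient combines the
  // decoder skip gradient with what flows back through the next level's pool
  std::vector<mat> denc(D + 1);
  denc[D] = dcur;
  int Hl = s.H >> (D - 1), Wl = s.W >> (D - 1);
  for (int l = D; l >= 1; --l) {
    const int base_i = 4 * (l - 1);
    mat W1 = params[base_i]; mat W2 = params[base_i + 2];
    mat dW1, dW2; vec db1, db2;
    mat d_mid = conv_bwd(W2, cc.enc2[l], denc[l], dW2, db2);
    mat d_in = conv_bwd(W1, cc.enc1[l], d_mid, dW1, db1);
    grads[base_i] = wrap(dW1); grads[base_i + 1] = wrap(db1);
    grads[base_i + 2] = wrap(dW2); grads[base_i + 3] = wrap(db2);
    if (l > 1) {
      // d_in is w.r.t. the pooled map of level l-1
      Hl *= 2; Wl *= 2;
      denc[l - 1] = dskip[l - 1] +
          maxpool2_back(d_in, cc.pool_idx[l - 1], d_in.n_rows, Hl, Wl);
    }
  }

  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// ---------------------------------------------------------------------------
// 8-connected component labeling (BFS) of a binary matrix
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix bin) {
  const int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> qy(H * W), qx(H * W);
  for (int x0 = 0; x0 < W; ++x0) {
    for (int y0 = 0; y0 < H; ++y0) {
      if (bin(y0, x0) == 0 || lab(y0, x0) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      qy[tail] = y0; qx[tail] = x0; ++tail;
      lab(y0, x0) = next;
      while (head < tail) {
        const int y = qy[head], x = qx[head]; ++head;
        for (int dx = -1; dx <= 1; ++dx) {
          for (int dy = -1; dy <= 1; ++dy) {
            if (dx == 0 && dy == 0) continue;
            const int ny = y + dy, nx = x + dx;
            if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
            if (bin(ny, nx) != 0 && lab(ny, nx) == 0) {
              lab(ny, nx) = next;
              qy[tail] = ny; qx[tail] = nx; ++tail;
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Maximum-cardinality matching within a distance threshold (exact, bitmask DP
// over the smaller point set; ties broken by minimum total distance)
// ---------------------------------------------------------------------------

// dmat: n_small x n_big pairwise distances. Returns the number of matched
// pairs and the minimal total distance among maximum matchings.
// [[Rcpp::export]]
List cpp_max_matching(arma::mat dmat, double tol) {
  const int k = dmat.n_rows, nb = dmat.n_cols;
  const size_t M = (size_t)1 << k;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> best_n(M, -1);
  std::vector<double> best_d(M, INF);
  best_n[0] = 0; best_d[0] = 0.0;
  for (int b = 0; b < nb; ++b) {
    std::vector<int> nn(best_n);
    std::vector<double> nd(best_d);
    for (size_t m = 0; m < M; ++m) {
      if (best_n[m] < 0) continue;
      for (int a = 0; a < k; ++a) {
        if (m & ((size_t)1 << a)) continue;
        const double d = dmat(a, b);
        if (d > tol) continue;
        const size_t m2 = m | ((size_t)1 << a);
        const int cand_n = best_n[m] + 1;
        const double cand_d = best_d[m] + d;
        if (cand_n > nn[m2] || (cand_n == nn[m2] && cand_d < nd[m2])) {
          nn[m2] = cand_n; nd[m2] = cand_d;
        }
      }
    }
    best_n.swap(nn); best_d.swap(nd);
  }
  int bn = 0; double bd = 0.0;
  for (size_t m = 0; m < M; ++m)
    if (best_n[m] > bn || (best_n[m] == bn && best_n[m] >= 0 && best_d[m] < bd)) {
      bn = best_n[m]; bd = best_d[m];
    }
  return List::create(_["n_matched"] = bn, _["total_distance"] = bd);
}
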