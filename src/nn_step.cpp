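// Fused training / inference steps for the multi-branch 1D-CNN.
//
// Mirrors the reference R implementation (nn-core.R / cnn.R) exactly:
// flat (B*L, C) activation layout, same-padding stride-1 convolution via
// im2col + GEMM, batch normalization, ReLU, inverted dropout, global
// average pooling, dense fusion head with sigmoid outputs, and weighted
// BCE / focal loss gradients. The R path stays the correctness oracle;
// this path is the fast route used by the training loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Deterministic uniform in [0,1) from a seeded mt19937 (fixed mapping so
// results do not depend on the standard library's distribution).
struct URand {
  std::mt19937 gen;
  explicit URand(uint32_t seed) : gen(seed) {}
  double operator()() { return gen() * (1.0 / 4294967296.0); }
};

arma::mat im2col_flat(const arma::mat& x, int B, int L, int K) {
  const int n = B * L;
  const int C = x.n_cols;
  const int half = (K - 1) / 2;
  arma::mat M(n, K * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    for (int k = 0; k < K; ++k) {
      const int o = (k - half) * B;
      double* dst = M.colptr(c * K + k);
      if (o >= 0)
        std::copy(src + o, src + n, dst);
      else
        std::copy(src, src + n + o, dst - o);
    }
  }
  return M;
}

arma::mat col2im_flat(const arma::mat& dM, int B, int L, int C, int K) {
  const int n = B * L;
  const int half = (K - 1) / 2;
  arma::mat dx(n, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = dx.colptr(c);
    for (int k = 0; k < K; ++k) {
      const int o = (k - half) * B;
      const double* src = dM.colptr(c * K + k);
      if (o >= 0)
        for (int i = o; i < n; ++i) dst[i] += src[i - o];
      else
        for (int i = 0; i < n + o; ++i) dst[i] += src[i - o];
    }
  }
  return dx;
}

struct LayerCache {
  arma::mat M;         // im2col patches
  arma::mat xhat;      // batch-norm normalized activations
  arma::rowvec inv;    // 1/sqrt(var+eps)
  arma::umat relu;     // relu mask
  arma::mat drop;      // dropout mask (empty if none)
  int C;               // input channels
  int L_in;            // time length at this layer's input/output
};

// average-pool the time axis of a flat (B*L, C) activation by factor p
arma::mat avg_pool_flat(const arma::mat& x, int B, int L, int p) {
  const int Lp = L / p;
  arma::mat out((size_t)B * Lp, x.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < x.n_cols; ++c) {
    const double* src = x.colptr(c);
    double* dst = out.colptr(c);
    for (int tp = 0; tp < Lp; ++tp)
      for (int j = 0; j < p; ++j) {
        const double* s = src + (size_t)(tp * p + j) * B;
        double* d = dst + (size_t)tp * B;
        for (int b = 0; b < B; ++b) d[b] += s[b];
      }
  }
  return out / (double)p;
}

arma::mat avg_unpool_flat(const arma::mat& d, int B, int Lp, int p, int L) {
  arma::mat out((size_t)B * L, d.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < d.n_cols; ++c) {
    const double* src = d.colptr(c);
    double* dst = out.colptr(c);
    for (int tp = 0; tp < Lp; ++tp)
      for (int j = 0; j < p; ++j) {
        const double* s = src + (size_t)tp * B;
        double* dd = dst + (size_t)(tp * p + j) * B;
        for (int b = 0; b < B; ++b) dd[b] = s[b] / p;
      }
  }
  return out;
}

struct BranchCache {
  std::vector<LayerCache> layers;
  int B, L;
};

void bn_stats_update(arma::rowvec& run_mean, arma::rowvec& run_var,
                     const arma::rowvec& mu, const arma::rowvec& v,
                     double momentum) {
  run_mean = momentum * run_mean + (1.0 - momentum) * mu;
  run_var = momentum * run_var + (1.0 - momentum) * v;
}

}  // namespace

// One fused forward+backward step (or forward-only when `training` is
// false and `y` is empty). Parameter naming matches the R flat list.
// [[Rcpp::export(name = ".cpp_nn_step")]]
List cpp_nn_step(List xs,                // named: branch -> (B x L) matrix
                 Nullable<NumericMatrix> clin_,
                 List params, List bn_stats,
                 IntegerVector filters_, int K, int pool,
                 bool batchnorm, double dropout,
                 NumericMatrix y_, NumericVector w_,
                 std::string loss_mode, double gamma_,
                 bool training, int mask_seed) {
  const double eps = 1e-5, momentum = 0.9;
  CharacterVector br_names = xs.names();
  const int n_br = br_names.size();
  const arma::ivec filters = as<arma::ivec>(filters_);
  const int n_layers = filters.n_elem;
  URand rng((uint32_t)mask_seed);

  std::vector<BranchCache> caches(n_br);
  // bn_new is rebuilt from scratch (never modified in place) so the
  // caller's bn_stats object keeps R value semantics
  List bn_new(n_br);
  bn_new.names() = br_names;
  arma::mat feat;
  int B = 0;

  // ---- branch forwards ----
  for (int bi = 0; bi < n_br; ++bi) {
    std::string br = as<std::string>(br_names[bi]);
    arma::mat xin = as<arma::mat>(xs[br]);
    B = xin.n_rows;
    int L = xin.n_cols;
    arma::mat x(xin.memptr(), (size_t)B * L, 1);  // flat copy
    BranchCache& bc = caches[bi];
    bc.B = B; bc.L = L;
    bc.layers.resize(n_layers);
    List bn_in = batchnorm ? as<List>(bn_stats[br]) : List();
    List bn_br(n_layers);
    for (int li = 0; li < n_layers; ++li) {
      LayerCache& lc = bc.layers[li];
      lc.C = x.n_cols;
      lc.L_in = L;
      lc.M = im2col_flat(x, B, L, K);
      std::string pre = br + ".conv_";
      arma::mat W = as<arma::mat>(params[pre + "W_" + std::to_string(li + 1)]);
      arma::rowvec b = as<arma::rowvec>(params[pre + "b_" + std::to_string(li + 1)]);
      arma::mat z = lc.M * W;
      z.each_row() += b;
      arma::mat a_pre;
      if (batchnorm) {
        List st = as<List>(bn_in[li]);
        arma::rowvec run_mean = as<arma::rowvec>(st["run_mean"]);
        arma::rowvec run_var = as<arma::rowvec>(st["run_var"]);
        arma::rowvec mu, v;
        if (training) {
          mu = arma::mean(z, 0);
          v = arma::mean(arma::square(z), 0) - arma::square(mu);
          bn_stats_update(run_mean, run_var, mu, v, momentum);
        } else {
          mu = run_mean;
          v = run_var;
        }
        bn_br[li] = List::create(
            _["run_mean"] = NumericVector(run_mean.begin(), run_mean.end()),
            _["run_var"] = NumericVector(run_var.begin(), run_var.end()));
        lc.inv = 1.0 / arma::sqrt(v + eps);
        z.each_row() -= mu;
        z.each_row() %= lc.inv;
        lc.xhat = z;
        arma::rowvec g = as<arma::rowvec>(params[br + ".bn_gamma_" + std::to_string(li + 1)]);
        arma::rowvec be = as<arma::rowvec>(params[br + ".bn_beta_" + std::to_string(li + 1)]);
        a_pre = z;
        a_pre.each_row() %= g;
        a_pre.each_row() += be;
      } else {
        a_pre = z;
      }
      lc.relu = a_pre > 0;
      arma::mat a = a_pre % arma::conv_to<arma::mat>::from(lc.relu);
      if (training && dropout > 0) {
        lc.drop.set_size(a.n_rows, a.n_cols);
        const double inv_keep = 1.0 / (1.0 - dropout);
        for (arma::uword j = 0; j < lc.drop.n_elem; ++j)
          lc.drop(j) = (rng() >= dropout) ? inv_keep : 0.0;
        a %= lc.drop;
      }
      if (pool > 1 && li < n_layers - 1) {
        a = avg_pool_flat(a, B, L, pool);
        L = L / pool;
      }
      x = a;
    }
    if (batchnorm) bn_new[br] = bn_br;
    bc.L = L;  // final (possibly pooled) length feeding the GAP
    // GAP over time: each feature column is a (B, L) block
    const int Fo = x.n_cols;
    arma::mat gap(B, Fo);
    for (int f = 0; f < Fo; ++f) {
      arma::mat blk(x.colptr(f), B, bc.L, false);
      gap.col(f) = arma::mean(blk, 1);
    }
    feat = (bi == 0) ? gap : arma::join_rows(feat, gap);
  }

  // ---- clinical branch ----
  bool use_clin = clin_.isNotNull();
  arma::mat clin, hc;
  arma::umat mc;
  if (use_clin) {
    clin = as<arma::mat>(clin_.get());
    arma::mat zc = clin * as<arma::mat>(params["clin.W"]);
    zc.each_row() += as<arma::rowvec>(params["clin.b"]);
    mc = zc > 0;
    hc = zc % arma::conv_to<arma::mat>::from(mc);
    feat = arma::join_rows(feat, hc);
  }

  // ---- fusion head ----
  arma::mat zf = feat * as<arma::mat>(params["fuse.W"]);
  zf.each_row() += as<arma::rowvec>(params["fuse.b"]);
  arma::umat mf = zf > 0;
  arma::mat hf = zf % arma::conv_to<arma::mat>::from(mf);
  arma::mat fdrop;
  if (training && dropout > 0) {
    fdrop.set_size(hf.n_rows, hf.n_cols);
    const double inv_keep = 1.0 / (1.0 - dropout);
    for (arma::uword j = 0; j < fdrop.n_elem; ++j)
      fdrop(j) = (rng() >= dropout) ? inv_keep : 0.0;
    hf %= fdrop;
  }
  arma::mat logits = hf * as<arma::mat>(params["out.W"]);
  logits.each_row() += as<arma::rowvec>(params["out.b"]);
  arma::mat prob = 1.0 / (1.0 + arma::exp(-logits));

  if (y_.nrow() == 0) {
    return List::create(_["prob"] = prob, _["bn"] = bn_new);
  }

  // ---- loss and gradient w.r.t. logits ----
  arma::mat y = as<arma::mat>(y_);
  arma::rowvec w = as<arma::rowvec>(w_);
  arma::mat p = arma::clamp(prob, 1e-7, 1.0 - 1e-7);
  arma::mat W_(p.n_rows, p.n_cols);
  W_.each_row() = w;
  double loss;
  arma::mat dlog;
  if (loss_mode == "weighted_bce") {
    loss = arma::accu(-(W_ % y % arma::log(p) +
                        (1.0 - y) % arma::log(1.0 - p))) / p.n_elem;
    dlog = (-W_ % y % (1.0 - p) + (1.0 - y) % p) / p.n_elem;
  } else {
    arma::mat lp = arma::log(p), l1p = arma::log(1.0 - p);
    arma::mat om = arma::pow(1.0 - p, gamma_), pm = arma::pow(p, gamma_);
    loss = arma::accu(-(W_ % y % om % lp +
                        (1.0 - y) % pm % l1p)) / p.n_elem;
    dlog = (y % W_ % (gamma_ * p % om % lp - om % (1.0 - p)) +
            (1.0 - y) % (pm % p - gamma_ * pm % (1.0 - p) % l1p)) / p.n_elem;
  }

  // ---- backward ----
  List grads;
  grads["out.W"] = wrap(arma::mat(hf.t() * dlog));
  {
    arma::rowvec gb = arma::sum(dlog, 0);
    grads["out.b"] = NumericVector(gb.begin(), gb.end());
  }
  arma::mat dhf = dlog * as<arma::mat>(params["out.W"]).t();
  if (training && dropout > 0) dhf %= fdrop;
  arma::mat dzf = dhf % arma::conv_to<arma::mat>::from(mf);
  grads["fuse.W"] = wrap(arma::mat(feat.t() * dzf));
  {
    arma::rowvec gb = arma::sum(dzf, 0);
    grads["fuse.b"] = NumericVector(gb.begin(), gb.end());
  }
  arma::mat dfeat = dzf * as<arma::mat>(params["fuse.W"]).t();

  int off = 0;
  const int gap_w = filters(n_layers - 1);
  for (int bi = 0; bi < n_br; ++bi) {
    std::string br = as<std::string>(br_names[bi]);
    BranchCache& bc = caches[bi];
    arma::mat dgap = dfeat.cols(off, off + gap_w - 1);
    off += gap_w;
    // GAP backward
    int Lcur = bc.L;
    arma::mat da((size_t)bc.B * Lcur, gap_w);
    for (int f = 0; f < gap_w; ++f) {
      arma::mat blk(da.colptr(f), bc.B, Lcur, false, true);
      blk.each_col() = arma::vec(dgap.colptr(f), bc.B) / (double)Lcur;
    }
    for (int li = n_layers - 1; li >= 0; --li) {
      LayerCache& lc = bc.layers[li];
      if (pool > 1 && li < n_layers - 1) {
        da = avg_unpool_flat(da, bc.B, Lcur, pool, lc.L_in);
        Lcur = lc.L_in;
      }
      if (lc.drop.n_elem) da %= lc.drop;
      da %= arma::conv_to<arma::mat>::from(lc.relu);
      arma::mat dz;
      std::string sfx = std::to_string(li + 1);
      if (batchnorm) {
        arma::rowvec g = as<arma::rowvec>(params[br + ".bn_gamma_" + sfx]);
        arma::rowvec dgamma = arma::sum(da % lc.xhat, 0);
        arma::rowvec dbeta = arma::sum(da, 0);
        arma::mat dxhat = da;
        dxhat.each_row() %= g;
        arma::rowvec m1 = arma::mean(dxhat, 0);
        arma::rowvec m2 = arma::mean(dxhat % lc.xhat, 0);
        arma::mat xm = lc.xhat;
        xm.each_row() %= m2;
        dz = dxhat - xm;
        dz.each_row() -= m1;
        dz.each_row() %= lc.inv;
        grads[br + ".bn_gamma_" + sfx] = NumericVector(dgamma.begin(), dgamma.end());
        grads[br + ".bn_beta_" + sfx] = NumericVector(dbeta.begin(), dbeta.end());
      } else {
        dz = da;
      }
      grads[br + ".conv_W_" + sfx] = wrap(arma::mat(lc.M.t() * dz));
      {
        arma::rowvec gb = arma::sum(dz, 0);
        grads[br + ".conv_b_" + sfx] = NumericVector(gb.begin(), gb.end());
      }
      if (li > 0) {
        arma::mat W = as<arma::mat>(params[br + ".conv_W_" + sfx]);
        arma::mat dM = dz * W.t();
        da = col2im_flat(dM, bc.B, lc.L_in, lc.C, K);
      }
    }
  }
  if (use_clin) {
    arma::mat dh = dfeat.cols(off, off + hc.n_cols - 1);
    arma::mat dzc = dh % arma::conv_to<arma::mat>::from(mc);
    grads["clin.W"] = wrap(arma::mat(clin.t() * dzc));
    arma::rowvec gb = arma::sum(dzc, 0);
    grads["clin.b"] = NumericVector(gb.begin(), gb.end());
  }

  return List::create(_["prob"] = prob, _["loss"] = loss,
                      _["grads"] = grads, _["bn"] = bn_new);
}
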