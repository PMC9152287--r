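// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "rng.h"
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;
using namespace arma;

// Mini-batch training allocates MB-sized temporaries thousands of times;
// keep them on the heap free list instead of per-allocation mmap/munmap.
static void keep_large_allocs_on_heap() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 64 * 1024 * 1024);
    done = true;
  }
#endif
}

// CNN feature encoder: conv (C kernels 1xk, same padding) -> ReLU FC hidden
// of the same CxW size -> max-pool 1x2 stride 2 -> linear FC to the code ->
// dropout -> linear FC to 2 -> softmax. Single threaded; all randomness
// from one splitmix64 stream. The core is templated on precision: training
// runs in single precision (the usual deep-learning convention), while the
// exported loss/gradient entry point instantiates double so analytic
// gradients can be verified against central differences. Ablation variants
// drop exactly one named layer; the FC hidden layer is a position-shared
// channel mix by default or a fully dense map when fc_dense is set (forced
// dense when the conv layer is ablated, where channels collapse to 1).
//
// Parameters live in one flat vector; layout (column-major within blocks):
//   K (C x k), bc (C), M (din x din), bm (din), Wc (F x code), bcode (code),
//   Wh (code x 2), bh (2)   -- absent layers contribute nothing.

struct Cfg {
  int W, C, k, code_dim;
  bool has_conv, has_fc, has_pool, fc_dense;
  double dropout;
  int Ceff() const { return has_conv ? C : 1; }
  int D() const { return Ceff() * W; }            // dense-FC width
  int fcin() const { return fc_dense ? D() : C; } // FC hidden square dim
  int L() const { return has_pool ? W / 2 : W; }  // pooled length
  int F() const { return Ceff() * L(); }          // code-FC input width
  int oK() const { return 0; }
  int obc() const { return has_conv ? C * k : 0; }
  int oM() const { return has_conv ? C * k + C : 0; }
  int obm() const { return oM() + (has_fc ? fcin() * fcin() : 0); }
  int oWc() const { return obm() + (has_fc ? fcin() : 0); }
  int obcode() const { return oWc() + F() * code_dim; }
  int oWh() const { return obcode() + code_dim; }
  int obh() const { return oWh() + code_dim * 2; }
  int n_par() const { return obh() + 2; }
};

static Cfg parse_cfg(const List& L) {
  Cfg c;
  c.W = as<int>(L["W"]);
  c.C = as<int>(L["channels"]);
  c.k = as<int>(L["kernel"]);
  c.code_dim = as<int>(L["code_dim"]);
  c.has_conv = as<bool>(L["has_conv"]);
  c.has_fc = as<bool>(L["has_fc"]);
  c.has_pool = as<bool>(L["has_pool"]);
  c.fc_dense = as<bool>(L["fc_dense"]) || !c.has_conv;
  c.dropout = as<double>(L["dropout"]);
  return c;
}

#define VIEW_M(name, base, off, r, cc) \
  Mat<eT> name((base) + (off), (r), (cc), false, true)
#define VIEW_V(name, base, off, r) Col<eT> name((base) + (off), (r), false, true)

// forward (+ optional backward). y empty => no loss/grad. dropmask NULL =>
// identity (evaluation mode). Returns mean cross-entropy when y is given.
template <typename eT>
static double fwd_bwd(Col<eT>& theta, const Mat<eT>& X, const ivec& y,
                      const Cfg& c, Col<eT>* grad, const Mat<eT>* dropmask,
                      Mat<eT>* probs_out, Mat<eT>* code_out) {
  const int n = X.n_rows, W = c.W, Ce = c.Ceff(), L = c.L(), din = c.fcin();
  eT* tp = theta.memptr();
  VIEW_M(vK, tp, c.oK(), c.has_conv ? c.C : 0, c.has_conv ? c.k : 0);
  VIEW_V(vbc, tp, c.obc(), c.has_conv ? c.C : 0);
  VIEW_M(vM, tp, c.oM(), c.has_fc ? din : 0, c.has_fc ? din : 0);
  VIEW_V(vbm, tp, c.obm(), c.has_fc ? din : 0);
  VIEW_M(vWc, tp, c.oWc(), c.F(), c.code_dim);
  VIEW_V(vbcode, tp, c.obcode(), c.code_dim);
  VIEW_M(vWh, tp, c.oWh(), c.code_dim, 2);
  VIEW_V(vbh, tp, c.obh(), 2);

  // conv: channel blocks side by side, column index = ch*W + j
  Mat<eT> Acat;
  if (c.has_conv) {
    Acat.set_size(n, Ce * W);
    for (int ch = 0; ch < Ce; ++ch) {
      Mat<eT> blk(n, W);
      blk.fill(vbc(ch));
      for (int t = 0; t < c.k; ++t) {
        int off = t - c.k / 2;
        int j0 = std::max(0, -off), j1 = W - 1 - std::max(0, off);
        if (j0 > j1) continue;
        blk.cols(j0, j1) += vK(ch, t) * X.cols(j0 + off, j1 + off);
      }
      Acat.cols(ch * W, ch * W + W - 1) = blk;
    }
  } else {
    Acat = X;
  }

  // ReLU FC hidden: same output size as its input map
  Mat<eT> Zcat;
  if (c.has_fc) {
    if (c.fc_dense) {
      Zcat = Acat * vM.t();
      Zcat.each_row() += vbm.t();
    } else {
      // channel mix shared across positions: reshape to (n*W) x C
      Mat<eT> U(Acat.memptr(), (size_t)n * W, Ce, false, true);
      Mat<eT> Hu = U * vM.t();
      Hu.each_row() += vbm.t();
      Zcat = Mat<eT>(Hu.memptr(), n, Ce * W);
    }
    Zcat.transform([](eT x) { return x > eT(0) ? x : eT(0); });
  } else {
    Zcat = Acat;
  }

  // max-pool 1x2 stride 2 along the length axis, per channel
  Mat<eT> Pcat, amax;
  if (c.has_pool) {
    Pcat.set_size(n, Ce * L);
    amax.set_size(n, Ce * L);
    for (int ch = 0; ch < Ce; ++ch) {
      for (int t = 0; t < L; ++t) {
        const eT* __restrict__ pa = Zcat.colptr(ch * W + 2 * t);
        const eT* __restrict__ pb = Zcat.colptr(ch * W + 2 * t + 1);
        eT* __restrict__ po = Pcat.colptr(ch * L + t);
        eT* __restrict__ ao = amax.colptr(ch * L + t);
        for (int i = 0; i < n; ++i) {
          bool sel = pb[i] > pa[i];
          po[i] = sel ? pb[i] : pa[i];
          ao[i] = sel ? eT(1) : eT(0);
        }
      }
    }
  } else {
    Pcat = Zcat;
  }

  Mat<eT> code = Pcat * vWc;
  code.each_row() += vbcode.t();
  if (code_out) *code_out = code;

  Mat<eT> coded = dropmask ? Mat<eT>(code % (*dropmask)) : code;
  Mat<eT> logits = coded * vWh;
  logits.each_row() += vbh.t();
  Col<eT> mx = arma::max(logits, 1);
  logits.each_col() -= mx;
  Mat<eT> P = arma::exp(logits);
  Col<eT> rs = arma::sum(P, 1);
  P.each_col() /= rs;
  if (probs_out) *probs_out = P;

  double loss = NA_REAL;
  if (y.n_elem > 0) {
    loss = 0.0;
    for (int i = 0; i < n; ++i)
      loss -= std::log(std::max((double)P(i, y(i)), 1e-12));
    loss /= n;
  }
  if (!grad) return loss;

  grad->zeros(c.n_par());
  eT* gp = grad->memptr();
  VIEW_M(gK, gp, c.oK(), c.has_conv ? c.C : 0, c.has_conv ? c.k : 0);
  VIEW_V(gbc, gp, c.obc(), c.has_conv ? c.C : 0);
  VIEW_M(gM, gp, c.oM(), c.has_fc ? din : 0, c.has_fc ? din : 0);
  VIEW_V(gbm, gp, c.obm(), c.has_fc ? din : 0);
  VIEW_M(gWc, gp, c.oWc(), c.F(), c.code_dim);
  VIEW_V(gbcode, gp, c.obcode(), c.code_dim);
  VIEW_M(gWh, gp, c.oWh(), c.code_dim, 2);
  VIEW_V(gbh, gp, c.obh(), 2);

  Mat<eT> dlog = P;
  for (int i = 0; i < n; ++i) dlog(i, y(i)) -= eT(1);
  dlog /= eT(n);

  gWh = coded.t() * dlog;
  gbh = sum(dlog, 0).t();
  Mat<eT> dcoded = dlog * vWh.t();
  Mat<eT> dcode = dropmask ? Mat<eT>(dcoded % (*dropmask)) : dcoded;

  gWc = Pcat.t() * dcode;
  gbcode = sum(dcode, 0).t();
  Mat<eT> dP = dcode * vWc.t();

  Mat<eT> dZcat;
  if (c.has_pool) {
    dZcat.zeros(n, Ce * W);
    for (int ch = 0; ch < Ce; ++ch) {
      for (int t = 0; t < L; ++t) {
        eT* __restrict__ da = dZcat.colptr(ch * W + 2 * t);
        eT* __restrict__ db = dZcat.colptr(ch * W + 2 * t + 1);
        const eT* __restrict__ dp = dP.colptr(ch * L + t);
        const eT* __restrict__ ao = amax.colptr(ch * L + t);
        for (int i = 0; i < n; ++i) {
          da[i] = dp[i] * (eT(1) - ao[i]);
          db[i] = dp[i] * ao[i];
        }
      }
    }
  } else {
    dZcat = dP;
  }

  Mat<eT> dAcat;
  if (c.has_fc) {
    Mat<eT> dH(n, Ce * W);
    {
      const eT* __restrict__ z = Zcat.memptr();
      const eT* __restrict__ d = dZcat.memptr();
      eT* __restrict__ o = dH.memptr();
      const size_t ne = dH.n_elem;
      for (size_t i = 0; i < ne; ++i) o[i] = z[i] > eT(0) ? d[i] : eT(0);
    }
    if (c.fc_dense) {
      gM = dH.t() * Acat;
      gbm = sum(dH, 0).t();
      dAcat = dH * vM;
    } else {
      Mat<eT> U(Acat.memptr(), (size_t)n * W, Ce, false, true);
      Mat<eT> dHu(dH.memptr(), (size_t)n * W, Ce, false, true);
      gM = dHu.t() * U;
      gbm = sum(dHu, 0).t();
      Mat<eT> dU = dHu * vM;
      dAcat = Mat<eT>(dU.memptr(), n, Ce * W);
    }
  } else {
    dAcat = dZcat;
  }

  if (c.has_conv) {
    for (int ch = 0; ch < Ce; ++ch) {
      Mat<eT> dblk = dAcat.cols(ch * W, ch * W + W - 1);
      gbc(ch) = accu(dblk);
      for (int t = 0; t < c.k; ++t) {
        int off = t - c.k / 2;
        int j0 = std::max(0, -off), j1 = W - 1 - std::max(0, off);
        if (j0 > j1) continue;
        gK(ch, t) = accu(dblk.cols(j0, j1) % X.cols(j0 + off, j1 + off));
      }
    }
  }
  return loss;
}

// Glorot-uniform weights, zero biases. Drawn in float regardless of the
// working precision so the same seed yields the same starting point.
static fvec init_theta_f(const Cfg& c, Splitmix& rng) {
  fvec th(c.n_par(), fill::zeros);
  auto glorot = [&](int off, int nelem, int fin, int fout) {
    double a = std::sqrt(6.0 / (fin + fout));
    for (int i = 0; i < nelem; ++i)
      th(off + i) = (float)((rng.unif() * 2.0 - 1.0) * a);
  };
  if (c.has_conv) glorot(c.oK(), c.C * c.k, c.k, c.k * c.C);
  if (c.has_fc) glorot(c.oM(), c.fcin() * c.fcin(), c.fcin(), c.fcin());
  glorot(c.oWc(), c.F() * c.code_dim, c.F(), c.code_dim);
  glorot(c.oWh(), c.code_dim * 2, c.code_dim, 2);
  return th;
}

// [[Rcpp::export]]
int cpp_enc_nparams(List cfgL) { return parse_cfg(cfgL).n_par(); }

// [[Rcpp::export]]
NumericVector cpp_enc_init(List cfgL, int seed) {
  Cfg c = parse_cfg(cfgL);
  Splitmix rng((uint64_t)seed * 1099511628211ULL + 3ULL);
  fvec th = init_theta_f(c, rng);
  return NumericVector(th.begin(), th.end());
}

// evaluation-grade forward pass in double precision
// [[Rcpp::export]]
List cpp_enc_forward(NumericVector theta, List cfgL, NumericMatrix Xr,
                     bool train_mode, int seed) {
  Cfg c = parse_cfg(cfgL);
  vec th(theta.begin(), theta.size());
  if ((int)th.n_elem != c.n_par()) stop("parameter vector has wrong length");
  mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  mat probs, code;
  ivec y;
  if (train_mode && c.dropout > 0) {
    Splitmix rng((uint64_t)seed * 2862933555777941757ULL + 11ULL);
    double keep = 1.0 - c.dropout;
    mat mask(X.n_rows, c.code_dim);
    for (uword i = 0; i < mask.n_elem; ++i)
      mask(i) = rng.unif() < keep ? 1.0 / keep : 0.0;
    fwd_bwd<double>(th, X, y, c, nullptr, &mask, &probs, &code);
  } else {
    fwd_bwd<double>(th, X, y, c, nullptr, nullptr, &probs, &code);
  }
  return List::create(
      _["probs"] = NumericMatrix(probs.n_rows, probs.n_cols, probs.begin()),
      _["code"] = NumericMatrix(code.n_rows, code.n_cols, code.begin()));
}

// loss and analytic gradient, double precision, dropout disabled (the
// deterministic path the finite-difference checks exercise)
// [[Rcpp::export]]
List cpp_enc_loss_grad(NumericVector theta, List cfgL, NumericMatrix Xr,
                       IntegerVector yr) {
  Cfg c = parse_cfg(cfgL);
  vec th(theta.begin(), theta.size());
  if ((int)th.n_elem != c.n_par()) stop("parameter vector has wrong length");
  mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  ivec y(yr.size());
  for (int i = 0; i < yr.size(); ++i) y(i) = yr[i];
  vec gr;
  double loss = fwd_bwd<double>(th, X, y, c, &gr, nullptr, nullptr, nullptr);
  return List::create(_["loss"] = loss,
                      _["grad"] = NumericVector(gr.begin(), gr.end()));
}

// [[Rcpp::export]]
List cpp_enc_train(List cfgL, NumericMatrix Xr, IntegerVector yr, int epochs,
                   int batch_size, double lr, int patience, double min_improve,
                   int seed) {
  keep_large_allocs_on_heap();
  Cfg c = parse_cfg(cfgL);
  fmat X = conv_to<fmat>::from(mat(Xr.begin(), Xr.nrow(), Xr.ncol(), false));
  ivec yall(yr.size());
  for (int i = 0; i < yr.size(); ++i) yall(i) = yr[i];
  const int n = X.n_rows;

  Splitmix rng((uint64_t)seed * 1099511628211ULL + 3ULL);
  fvec theta = init_theta_f(c, rng);
  fvec m(c.n_par(), fill::zeros), vv(c.n_par(), fill::zeros), gr;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long tstep = 0;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> trace;
  double best = datum::inf;
  int wait = 0, ep_run = 0;
  double keep = 1.0 - c.dropout;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i) {
      int j = rng.randint(i + 1);
      std::swap(idx[i], idx[j]);
    }
    double ep_loss = 0.0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(n, s + batch_size), bn = e - s;
      uvec rows(bn);
      for (int i = 0; i < bn; ++i) rows(i) = idx[s + i];
      fmat Xb = X.rows(rows);
      ivec yb(bn);
      for (int i = 0; i < bn; ++i) yb(i) = yall(rows(i));
      fmat mask;
      const fmat* mptr = nullptr;
      if (c.dropout > 0) {
        mask.set_size(bn, c.code_dim);
        for (uword i = 0; i < mask.n_elem; ++i)
          mask(i) = rng.unif() < keep ? (float)(1.0 / keep) : 0.0f;
        mptr = &mask;
      }
      double loss = fwd_bwd<float>(theta, Xb, yb, c, &gr, mptr, nullptr, nullptr);
      ep_loss += loss * bn;
      ++tstep;
      const float bc1 = (float)(1.0 - std::pow(b1, (double)tstep));
      const float bc2 = (float)(1.0 - std::pow(b2, (double)tstep));
      const float fb1 = (float)b1, fb2 = (float)b2, flr = (float)lr,
                  fe = (float)eps;
      float* __restrict__ mp = m.memptr();
      float* __restrict__ vp = vv.memptr();
      float* __restrict__ gp2 = gr.memptr();
      float* __restrict__ thp = theta.memptr();
      const int np = c.n_par();
      for (int i = 0; i < np; ++i) {
        float g = gp2[i];
        mp[i] = fb1 * mp[i] + (1.0f - fb1) * g;
        vp[i] = fb2 * vp[i] + (1.0f - fb2) * g * g;
        thp[i] -= flr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + fe);
      }
    }
    ep_loss /= n;
    trace.push_back(ep_loss);
    ++ep_run;
    if (ep_loss < 1e-3) break; // training CE effectively zero: converged
    if (ep_loss < best * (1.0 - min_improve)) {
      best = ep_loss;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }
  return List::create(
      _["theta"] = NumericVector(theta.begin(), theta.end()),
      _["loss_trace"] = NumericVector(trace.begin(), trace.end()),
      _["epochs_run"] = ep_run);
}
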