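// Fast forward and analytic backward pass for the multi-order graph
// attention network. Mirrors the reference R implementation in R/model.R
// (tests pin the two together); used by the training loop where an R-level
// per-molecule pass would dominate the run time.
//
// Layout conventions: hidden states are d x n matrices (one column per
// atom); neighbour lists arrive in CSR form (0-based); dropout masks are
// generated R-side and passed in, so the pass itself is deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat lrelu(const arma::mat& x) {
  return arma::max(x, 0.01 * x);
}
static inline arma::mat lrelu_grad(const arma::mat& x) {
  arma::mat g(arma::size(x));
  g.fill(0.01);
  g.elem(arma::find(x >= 0)).fill(1.0);
  return g;
}
static inline arma::mat sigm(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}
static inline arma::vec softmax_vec(const arma::vec& z) {
  arma::vec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}
static inline arma::mat elu_mat(const arma::mat& x) {
  arma::mat y = x;
  arma::uvec neg = arma::find(x <= 0);
  y.elem(neg) = arma::exp(x.elem(neg)) - 1.0;
  return y;
}

struct LayerP {
  arma::vec w;
  arma::mat V, Wr, Wz, Wh;
};

struct ModelP {
  arma::mat proj;
  std::vector<LayerP> layers, super;
  arma::vec fc_w;
  double fc_b;
};

static LayerP unpack_layer(const List& lst) {
  LayerP p;
  p.w = as<arma::vec>(lst["w"]);
  p.V = as<arma::mat>(lst["V"]);
  p.Wr = as<arma::mat>(lst["W_r"]);
  p.Wz = as<arma::mat>(lst["W_z"]);
  p.Wh = as<arma::mat>(lst["W_h"]);
  return p;
}

static ModelP unpack_model(const List& params) {
  ModelP mp;
  List lay = as<List>(params["layers"]);
  List sup = as<List>(params["super"]);
  for (int k = 0; k < lay.size(); ++k) mp.layers.push_back(unpack_layer(lay[k]));
  for (int k = 0; k < sup.size(); ++k) mp.super.push_back(unpack_layer(sup[k]));
  mp.proj = as<arma::mat>(params["proj"]);
  mp.fc_w = as<arma::vec>(params["fc_w"]);
  mp.fc_b = as<double>(params["fc_b"]);
  return mp;
}

// gradient accumulators, same structure as the parameters
struct GradAcc {
  arma::mat proj;
  std::vector<arma::vec> lw, sw;
  std::vector<arma::mat> lV, lWr, lWz, lWh, sV, sWr, sWz, sWh;
  arma::vec fc_w;
  double fc_b;
  double loss;
  void init(const ModelP& mp) {
    int kappa = (int)mp.layers.size();
    int d = mp.proj.n_rows;
    proj.zeros(d, mp.proj.n_cols);
    fc_w.zeros(d);
    fc_b = 0.0;
    loss = 0.0;
    lw.resize(kappa); sw.resize(kappa);
    lV.resize(kappa); lWr.resize(kappa); lWz.resize(kappa); lWh.resize(kappa);
    sV.resize(kappa); sWr.resize(kappa); sWz.resize(kappa); sWh.resize(kappa);
    for (int k = 0; k < kappa; ++k) {
      lw[k].zeros(mp.layers[k].w.n_elem);
      sw[k].zeros(mp.super[k].w.n_elem);
      lV[k].zeros(d, d); sV[k].zeros(d, d);
      lWr[k].zeros(d, 2 * d); lWz[k].zeros(d, 2 * d); lWh[k].zeros(d, 2 * d);
      sWr[k].zeros(d, 2 * d); sWz[k].zeros(d, 2 * d); sWh[k].zeros(d, 2 * d);
    }
  }
  List pack() const {
    int kappa = (int)lw.size();
    List glay(kappa), gsup(kappa);
    for (int k = 0; k < kappa; ++k) {
      glay[k] = List::create(_["w"] = lw[k], _["V"] = lV[k],
                             _["W_r"] = lWr[k], _["W_z"] = lWz[k],
                             _["W_h"] = lWh[k]);
      gsup[k] = List::create(_["w"] = sw[k], _["V"] = sV[k],
                             _["W_r"] = sWr[k], _["W_z"] = sWz[k],
                             _["W_h"] = sWh[k]);
    }
    return List::create(_["proj"] = proj, _["layers"] = glay,
                        _["super"] = gsup, _["fc_w"] = fc_w,
                        _["fc_b"] = fc_b);
  }
};

// per-layer forward records kept for the backward pass
struct LayerTraceC {
  arma::mat Hin;            // d x n states entering the layer
  arma::vec raw;            // pre-activation logits per neighbour pair
  arma::vec s;              // softmax weights per pair
  arma::mat M;              // d x n weighted neighbour sums
  arma::mat PreC;           // d x n pre-ELU context
  arma::mat Ctx;            // d x n context after ELU and dropout
  arma::mat R, Z, HC, Hout; // GRU internals
  // super-node readout (tau steps)
  std::vector<arma::vec> g_prev, sraw, sa, sm, spre, sctx, sr, sz, shc;
  arma::vec g_final;
};

struct ForwardTrace {
  std::vector<LayerTraceC> layers;
  arma::mat H0raw;     // pre-activation of the initial projection
  arma::mat G;         // kappa x d graph embeddings
  arma::mat A;         // kappa x kappa fusion weights
  arma::vec fused;     // final embedding after dropout
  arma::vec fused_pre; // before final dropout
  double pred;
};

static void run_forward(const arma::mat& X, const arma::ivec& nbr_off,
                        const arma::ivec& nbr_idx, const arma::mat& pairB,
                        const ModelP& mp, int tau, const List& masks,
                        bool use_masks, ForwardTrace& tr) {
  const int n = X.n_rows;
  const int d = mp.proj.n_rows;
  const int kappa = (int)mp.layers.size();
  const int npairs = nbr_idx.n_elem;

  tr.H0raw = mp.proj * X.t();           // d x n
  arma::mat H = lrelu(tr.H0raw);
  tr.G.set_size(kappa, d);
  tr.layers.resize(kappa);

  List mlayer, msuper;
  if (use_masks) {
    mlayer = as<List>(masks["layer_ctx"]);
    msuper = as<List>(masks["super_ctx"]);
  }

  for (int k = 0; k < kappa; ++k) {
    LayerTraceC& lt = tr.layers[k];
    lt.Hin = H;
    const LayerP& lp = mp.layers[k];
    arma::vec w1 = lp.w.subvec(0, d - 1);
    arma::vec w2 = lp.w.subvec(d, 2 * d - 1);
    arma::vec w3;
    if (k == 0 && (int)lp.w.n_elem > 2 * d) {
      w3 = lp.w.subvec(2 * d, lp.w.n_elem - 1);
    }
    arma::rowvec dv = w1.t() * H;  // per-atom "query" dots
    arma::rowvec dn = w2.t() * H;  // per-atom "key" dots
    lt.raw.set_size(npairs);
    lt.s.set_size(npairs);
    lt.M.zeros(d, n);
    for (int v = 0; v < n; ++v) {
      int a = nbr_off[v], b = nbr_off[v + 1];
      arma::vec logits(b - a);
      for (int p = a; p < b; ++p) {
        double raw = dv[v] + dn[nbr_idx[p]];
        if (k == 0 && w3.n_elem > 0) raw += arma::dot(w3, pairB.col(p));
        lt.raw[p] = raw;
        logits[p - a] = raw >= 0 ? raw : 0.01 * raw;
      }
      arma::vec s = softmax_vec(logits);
      for (int p = a; p < b; ++p) {
        lt.s[p] = s[p - a];
        lt.M.col(v) += s[p - a] * H.col(nbr_idx[p]);
      }
    }
    lt.PreC = lp.V * lt.M;
    lt.Ctx = elu_mat(lt.PreC);
    if (use_masks) {
      arma::mat mk = as<arma::mat>(mlayer[k]);  // n x d
      lt.Ctx %= mk.t();
    }
    arma::mat A1 = arma::join_cols(H, lt.Ctx);
    lt.R = sigm(lp.Wr * A1);
    lt.Z = sigm(lp.Wz * A1);
    arma::mat A2 = arma::join_cols(lt.R % H, lt.Ctx);
    lt.HC = arma::tanh(lp.Wh * A2);
    lt.Hout = (1.0 - lt.Z) % lt.HC + lt.Z % H;
    H = lt.Hout;

    // super-node readout
    const LayerP& sp = mp.super[k];
    arma::vec u1 = sp.w.subvec(0, d - 1);
    arma::vec u2 = sp.w.subvec(d, 2 * d - 1);
    arma::rowvec hdots = u2.t() * H;
    arma::vec g = arma::sum(H, 1);
    List msup_k;
    if (use_masks) msup_k = as<List>(msuper[k]);
    for (int t = 0; t < tau; ++t) {
      lt.g_prev.push_back(g);
      double gq = arma::dot(u1, g);
      arma::vec raw = gq + hdots.t();
      lt.sraw.push_back(raw);
      arma::vec logits = raw;
      for (int v = 0; v < n; ++v) if (logits[v] < 0) logits[v] *= 0.01;
      arma::vec a = softmax_vec(logits);
      lt.sa.push_back(a);
      arma::vec m = H * a;
      lt.sm.push_back(m);
      arma::vec pre = sp.V * m;
      lt.spre.push_back(pre);
      arma::vec ctx = elu_mat(pre);
      if (use_masks) ctx %= as<arma::vec>(msup_k[t]);
      lt.sctx.push_back(ctx);
      arma::vec a1 = arma::join_cols(g, ctx);
      arma::vec r = sigm(sp.Wr * a1);
      arma::vec z = sigm(sp.Wz * a1);
      arma::vec a2 = arma::join_cols(r % g, ctx);
      arma::vec hc = arma::tanh(sp.Wh * a2);
      lt.sr.push_back(r);
      lt.sz.push_back(z);
      lt.shc.push_back(hc);
      g = (1.0 - z) % hc + z % g;
    }
    lt.g_final = g;
    tr.G.row(k) = g.t();
  }

  arma::mat S = (tr.G * tr.G.t()) / std::sqrt((double)d);
  tr.A.set_size(kappa, kappa);
  for (int i = 0; i < kappa; ++i) {
    tr.A.row(i) = softmax_vec(S.row(i).t()).t();
  }
  arma::mat AG = tr.A * tr.G;
  tr.fused_pre = arma::mean(AG, 0).t();
  tr.fused = tr.fused_pre;
  if (use_masks) tr.fused %= as<arma::vec>(masks["final"]);
  tr.pred = arma::dot(mp.fc_w, tr.fused) + mp.fc_b;
}

// backward of one GRU cell (matrix form, all atoms at once)
static void gru_backward(const arma::mat& Hin, const arma::mat& Ctx,
                         const arma::mat& R, const arma::mat& Z,
                         const arma::mat& HC, const arma::mat& dHout,
                         const LayerP& p, arma::mat& dWr, arma::mat& dWz,
                         arma::mat& dWh, arma::mat& dHin, arma::mat& dCtx) {
  arma::mat dZ = dHout % (Hin - HC);
  arma::mat dHC = dHout % (1.0 - Z);
  dHin = dHout % Z;

  arma::mat dPreH = dHC % (1.0 - HC % HC);
  arma::mat A2 = arma::join_cols(R % Hin, Ctx);
  dWh += dPreH * A2.t();
  arma::mat dA2 = p.Wh.t() * dPreH;
  const int d = Hin.n_rows;
  arma::mat dRH = dA2.rows(0, d - 1);
  dCtx = dA2.rows(d, 2 * d - 1);
  arma::mat dR = dRH % Hin;
  dHin += dRH % R;

  arma::mat A1 = arma::join_cols(Hin, Ctx);
  arma::mat dPreZ = dZ % Z % (1.0 - Z);
  arma::mat dPreR = dR % R % (1.0 - R);
  dWz += dPreZ * A1.t();
  dWr += dPreR * A1.t();
  arma::mat dA1 = p.Wz.t() * dPreZ + p.Wr.t() * dPreR;
  dHin += dA1.rows(0, d - 1);
  dCtx += dA1.rows(d, 2 * d - 1);
}

// forward + backward for one molecule; accumulates into `acc`
static double backward_accumulate(const arma::mat& X,
                                  const arma::ivec& nbr_off,
                                  const arma::ivec& nbr_idx,
                                  const arma::mat& pairB, const ModelP& mp,
                                  int tau, double y, const List& mk,
                                  bool use_masks, GradAcc& acc) {
  ForwardTrace tr;
  run_forward(X, nbr_off, nbr_idx, pairB, mp, tau, mk, use_masks, tr);

  const int n = X.n_rows;
  const int d = mp.proj.n_rows;
  const int kappa = (int)mp.layers.size();
  double resid = tr.pred - y;
  acc.loss += resid * resid;
  double dpred = 2.0 * resid;

  acc.fc_w += dpred * tr.fused;
  acc.fc_b += dpred;

  arma::vec dfused = dpred * mp.fc_w;
  if (use_masks) dfused %= as<arma::vec>(mk["final"]);
  arma::mat dAG = arma::repmat(dfused.t() / (double)kappa, kappa, 1);
  arma::mat dA = dAG * tr.G.t();
  arma::mat dG = tr.A.t() * dAG;
  arma::mat dS(kappa, kappa);
  for (int i = 0; i < kappa; ++i) {
    arma::rowvec a = tr.A.row(i);
    double dot = arma::dot(dA.row(i), a);
    dS.row(i) = (dA.row(i) - dot) % a;
  }
  dG += ((dS + dS.t()) * tr.G) / std::sqrt((double)d);

  List mlayer, msuper;
  if (use_masks) {
    mlayer = as<List>(mk["layer_ctx"]);
    msuper = as<List>(mk["super_ctx"]);
  }

  arma::mat carry(d, n, arma::fill::zeros);  // dH flowing from layer k+1
  for (int k = kappa - 1; k >= 0; --k) {
    LayerTraceC& lt = tr.layers[k];
    const LayerP& sp = mp.super[k];
    const LayerP& lp = mp.layers[k];
    arma::vec u1 = sp.w.subvec(0, d - 1);
    arma::vec u2 = sp.w.subvec(d, 2 * d - 1);
    const arma::mat& H = lt.Hout;

    arma::mat dH = carry;            // contributions to states after layer k
    arma::vec dg = dG.row(k).t();

    // ---- super readout backward (tau steps, reversed)
    for (int t = tau - 1; t >= 0; --t) {
      const arma::vec& g_prev = lt.g_prev[t];
      const arma::vec& a = lt.sa[t];
      const arma::vec& ctx = lt.sctx[t];
      const arma::vec& r = lt.sr[t];
      const arma::vec& z = lt.sz[t];
      const arma::vec& hc = lt.shc[t];

      arma::vec dz = dg % (g_prev - hc);
      arma::vec dhc = dg % (1.0 - z);
      arma::vec dg_new = dg % z;

      arma::vec dpreh = dhc % (1.0 - hc % hc);
      arma::vec a2 = arma::join_cols(r % g_prev, ctx);
      acc.sWh[k] += dpreh * a2.t();
      arma::vec da2 = sp.Wh.t() * dpreh;
      arma::vec drh = da2.subvec(0, d - 1);
      arma::vec dctx = da2.subvec(d, 2 * d - 1);
      arma::vec dr = drh % g_prev;
      dg_new += drh % r;

      arma::vec a1 = arma::join_cols(g_prev, ctx);
      arma::vec dprez = dz % z % (1.0 - z);
      arma::vec dprer = dr % r % (1.0 - r);
      acc.sWz[k] += dprez * a1.t();
      acc.sWr[k] += dprer * a1.t();
      arma::vec da1 = sp.Wz.t() * dprez + sp.Wr.t() * dprer;
      dg_new += da1.subvec(0, d - 1);
      dctx += da1.subvec(d, 2 * d - 1);

      if (use_masks) {
        List msup_k = as<List>(msuper[k]);
        dctx %= as<arma::vec>(msup_k[t]);
      }
      const arma::vec& pre = lt.spre[t];
      arma::vec dpre = dctx;
      for (int i = 0; i < d; ++i) if (pre[i] <= 0) dpre[i] *= std::exp(pre[i]);
      acc.sV[k] += dpre * lt.sm[t].t();
      arma::vec dm = sp.V.t() * dpre;
      arma::vec dsa = H.t() * dm;     // m = H a
      dH += dm * a.t();
      double dota = arma::dot(dsa, a);
      arma::vec de = (dsa - dota) % a;
      const arma::vec& raw = lt.sraw[t];
      double coef_sum = 0.0;
      for (int v = 0; v < n; ++v) {
        double lg = raw[v] >= 0 ? 1.0 : 0.01;
        double coef = de[v] * lg;
        coef_sum += coef;
        acc.sw[k].subvec(d, 2 * d - 1) += coef * H.col(v);
        dH.col(v) += coef * u2;
      }
      acc.sw[k].subvec(0, d - 1) += coef_sum * g_prev;
      dg_new += coef_sum * u1;   // query side of every logit
      dg = dg_new;
    }
    // super init: g0 = sum of columns of H
    dH.each_col() += dg;

    // ---- node embedding layer backward
    arma::mat dHin(d, n, arma::fill::zeros);
    arma::mat dCtx(d, n, arma::fill::zeros);
    gru_backward(lt.Hin, lt.Ctx, lt.R, lt.Z, lt.HC, dH, lp,
                 acc.lWr[k], acc.lWz[k], acc.lWh[k], dHin, dCtx);
    if (use_masks) {
      arma::mat mkk = as<arma::mat>(mlayer[k]);  // n x d
      dCtx %= mkk.t();
    }
    arma::mat dPre = dCtx;
    for (int v = 0; v < n; ++v) {
      for (int i = 0; i < d; ++i) {
        if (lt.PreC(i, v) <= 0) dPre(i, v) *= std::exp(lt.PreC(i, v));
      }
    }
    acc.lV[k] += dPre * lt.M.t();
    arma::mat dM = lp.V.t() * dPre;  // d x n

    arma::vec w1 = lp.w.subvec(0, d - 1);
    arma::vec w2 = lp.w.subvec(d, 2 * d - 1);
    bool has_b = (k == 0) && ((int)lp.w.n_elem > 2 * d);
    for (int v = 0; v < n; ++v) {
      int a = nbr_off[v], b = nbr_off[v + 1];
      int len = b - a;
      arma::vec s(len), ds(len);
      for (int p = a; p < b; ++p) {
        s[p - a] = lt.s[p];
        ds[p - a] = arma::dot(dM.col(v), lt.Hin.col(nbr_idx[p]));
        dHin.col(nbr_idx[p]) += s[p - a] * dM.col(v);
      }
      double dots = arma::dot(ds, s);
      for (int p = a; p < b; ++p) {
        double de = (ds[p - a] - dots) * s[p - a];
        double lg = lt.raw[p] >= 0 ? 1.0 : 0.01;
        double coef = de * lg;
        acc.lw[k].subvec(0, d - 1) += coef * lt.Hin.col(v);
        acc.lw[k].subvec(d, 2 * d - 1) += coef * lt.Hin.col(nbr_idx[p]);
        if (has_b) {
          acc.lw[k].subvec(2 * d, lp.w.n_elem - 1) += coef * pairB.col(p);
        }
        dHin.col(v) += coef * w1;
        dHin.col(nbr_idx[p]) += coef * w2;
      }
    }
    carry = dHin;
  }

  arma::mat dH0 = carry % lrelu_grad(tr.H0raw);
  acc.proj += dH0 * X;
  return tr.pred;
}

// [[Rcpp::export(name = ".mogat_forward_cpp")]]
List mogat_forward_cpp(const arma::mat& X, const arma::ivec& nbr_off,
                       const arma::ivec& nbr_idx, const arma::mat& pairB,
                       const List& params, int tau,
                       Nullable<List> masks = R_NilValue) {
  ModelP mp = unpack_model(params);
  ForwardTrace tr;
  bool use_masks = masks.isNotNull();
  List mk = use_masks ? List(masks) : List();
  run_forward(X, nbr_off, nbr_idx, pairB, mp, tau, mk, use_masks, tr);

  int kappa = (int)mp.layers.size();
  int n = X.n_rows;
  arma::mat atom_att(kappa, n);
  for (int k = 0; k < kappa; ++k) {
    atom_att.row(k) = tr.layers[k].sa.back().t();
  }
  return List::create(_["prediction"] = tr.pred, _["G"] = tr.G,
                      _["A"] = tr.A, _["final"] = tr.fused,
                      _["atom_attention"] = atom_att);
}

// [[Rcpp::export(name = ".mogat_grad_cpp")]]
List mogat_grad_cpp(const arma::mat& X, const arma::ivec& nbr_off,
                    const arma::ivec& nbr_idx, const arma::mat& pairB,
                    const List& params, int tau, double y,
                    Nullable<List> masks = R_NilValue) {
  ModelP mp = unpack_model(params);
  GradAcc acc;
  acc.init(mp);
  bool use_masks = masks.isNotNull();
  List mk = use_masks ? List(masks) : List();
  double pred = backward_accumulate(X, nbr_off, nbr_idx, pairB, mp, tau, y,
                                    mk, use_masks, acc);
  return List::create(_["loss"] = acc.loss, _["prediction"] = pred,
                      _["grads"] = acc.pack());
}

// batched version: sums losses and gradients over a list of molecules
// [[Rcpp::export(name = ".mogat_grad_batch_cpp")]]
List mogat_grad_batch_cpp(const List& Xs, const List& offs, const List& idxs,
                          const List& pairBs, const List& params, int tau,
                          const NumericVector& ys,
                          Nullable<List> mask_list = R_NilValue) {
  ModelP mp = unpack_model(params);
  GradAcc acc;
  acc.init(mp);
  bool use_masks = mask_list.isNotNull();
  List ml = use_masks ? List(mask_list) : List();
  for (int i = 0; i < Xs.size(); ++i) {
    arma::mat X = as<arma::mat>(Xs[i]);
    arma::ivec off = as<arma::ivec>(offs[i]);
    arma::ivec idx = as<arma::ivec>(idxs[i]);
    arma::mat pairB = as<arma::mat>(pairBs[i]);
    List mk = use_masks ? as<List>(ml[i]) : List();
    backward_accumulate(X, off, idx, pairB, mp, tau, ys[i], mk, use_masks,
                        acc);
  }
  return List::create(_["loss"] = acc.loss, _["grads"] = acc.pack());
}

// batched prediction (no trace)
// [[Rcpp::export(name = ".mogat_predict_batch_cpp")]]
NumericVector mogat_predict_batch_cpp(const List& Xs, const List& offs,
                                      const List& idxs, const List& pairBs,
                                      const List& params, int tau) {
  ModelP mp = unpack_model(params);
  NumericVector out(Xs.size());
  List empty;
  for (int i = 0; i < Xs.size(); ++i) {
    arma::mat X = as<arma::mat>(Xs[i]);
    arma::ivec off = as<arma::ivec>(offs[i]);
    arma::ivec idx = as<arma::ivec>(idxs[i]);
    arma::mat pairB = as<arma::mat>(pairBs[i]);
    ForwardTrace tr;
    run_forward(X, off, idx, pairB, mp, tau, empty, false, tr);
    out[i] = tr.pred;
  }
  return out;
}
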