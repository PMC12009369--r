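// Core forward/backward pass for the continuous-time sequence classifiers.
//
// One function handles the ODE-RNN and the plain RNN/LSTM/GRU baselines: the
// hidden state is (optionally) evolved between observations by integrating a
// small MLP vector field with a fixed-step solver (euler or rk4), updated at
// each observation by the chosen recurrent cell on the input
// [values; mask; delta_t], and finally fused with the processed statics into
// the latent phenotype from which an MLP classifier emits class logits.
// Gradients are exact backpropagation through the full computation graph,
// including the solver steps; they are validated against finite differences
// in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct MLP2 {              // two-layer perceptron y = W2 * tanh(W1 x + b1) + b2
  mat W1, W2; vec b1, b2;
  void load(const List& p, const std::string& pre) {
    W1 = as<mat>(p[pre + "_W1"]); b1 = as<vec>(p[pre + "_b1"]);
    W2 = as<mat>(p[pre + "_W2"]); b2 = as<vec>(p[pre + "_b2"]);
  }
  vec fwd(const vec& x, vec& hidden) const {
    hidden = arma::tanh(W1 * x + b1);
    return W2 * hidden + b2;
  }
};

struct MLP2Grad {
  mat W1, W2; vec b1, b2;
  void init(const MLP2& m) {
    W1.zeros(m.W1.n_rows, m.W1.n_cols); b1.zeros(m.b1.n_elem);
    W2.zeros(m.W2.n_rows, m.W2.n_cols); b2.zeros(m.b2.n_elem);
  }
  // back-propagate dL/dy; returns dL/dx
  vec bwd(const MLP2& m, const vec& x, const vec& hidden, const vec& dy) {
    W2 += dy * hidden.t(); b2 += dy;
    vec dh = m.W2.t() * dy;
    vec dpre = dh % (1.0 - hidden % hidden);
    W1 += dpre * x.t(); b1 += dpre;
    return m.W1.t() * dpre;
  }
  void store(List& g, const std::string& pre) const {
    g[pre + "_W1"] = W1; g[pre + "_b1"] = b1;
    g[pre + "_W2"] = W2; g[pre + "_b2"] = b2;
  }
};

// caches for one euler sub-step / one rk4 stage evaluation
struct OdeCache {
  std::vector<vec> h_in;      // state fed to f_ODE
  std::vector<vec> act;       // hidden activation of f_ODE
};

// f_ODE evaluation with cache push
static inline vec ode_f(const MLP2& f, const vec& h, OdeCache& cc) {
  vec a;
  vec out = f.fwd(h, a);
  cc.h_in.push_back(h);
  cc.act.push_back(a);
  return out;
}

// [[Rcpp::export(name = ".ttd_core_batch")]]
List ttd_core_batch(List params, List patients, List cfg,
                    bool want_grad, bool want_latent) {
  const std::string cell = as<std::string>(cfg["cell"]);
  const bool use_ode = as<bool>(cfg["use_ode"]);
  const std::string solver = as<std::string>(cfg["solver"]);
  const double max_step = as<double>(cfg["max_step_h"]);
  const vec cw = as<vec>(cfg["class_weights"]);
  const int C = cw.n_elem;

  // --- load parameters ------------------------------------------------------
  vec h0 = as<vec>(params["h0"]);
  const int H = h0.n_elem;
  mat Wz, Wr, Wh, Wi, Wf, Wo, Wg, Wx;
  vec bz, br, bh, bi, bf, bo, bg, bx, c0;
  if (cell == "gru") {
    Wz = as<mat>(params["Wz"]); bz = as<vec>(params["bz"]);
    Wr = as<mat>(params["Wr"]); br = as<vec>(params["br"]);
    Wh = as<mat>(params["Wh"]); bh = as<vec>(params["bh"]);
  } else if (cell == "lstm") {
    Wi = as<mat>(params["Wi"]); bi = as<vec>(params["bi"]);
    Wf = as<mat>(params["Wf"]); bf = as<vec>(params["bf"]);
    Wo = as<mat>(params["Wo"]); bo = as<vec>(params["bo"]);
    Wg = as<mat>(params["Wg"]); bg = as<vec>(params["bg"]);
    c0 = as<vec>(params["c0"]);
  } else if (cell == "rnn") {
    Wx = as<mat>(params["Wx"]); bx = as<vec>(params["bx"]);
  } else stop("unknown cell type: %s", cell.c_str());

  MLP2 f_ode, f_static, f_long, f_fusion, f_cls;
  if (use_ode) f_ode.load(params, "ode");
  f_static.load(params, "static");
  f_long.load(params, "long");
  f_fusion.load(params, "fusion");
  f_cls.load(params, "cls");

  const int P = f_fusion.W2.n_rows;   // phenotype dim
  const int nPat = patients.size();

  // --- gradient accumulators ------------------------------------------------
  vec g_h0(H, arma::fill::zeros), g_c0;
  mat gWz, gWr, gWh, gWi, gWf, gWo, gWg, gWx;
  vec gbz, gbr, gbh, gbi, gbf, gbo, gbg, gbx;
  if (want_grad) {
    if (cell == "gru") {
      gWz.zeros(Wz.n_rows, Wz.n_cols); gbz.zeros(bz.n_elem);
      gWr.zeros(Wr.n_rows, Wr.n_cols); gbr.zeros(br.n_elem);
      gWh.zeros(Wh.n_rows, Wh.n_cols); gbh.zeros(bh.n_elem);
    } else if (cell == "lstm") {
      gWi.zeros(Wi.n_rows, Wi.n_cols); gbi.zeros(bi.n_elem);
      gWf.zeros(Wf.n_rows, Wf.n_cols); gbf.zeros(bf.n_elem);
      gWo.zeros(Wo.n_rows, Wo.n_cols); gbo.zeros(bo.n_elem);
      gWg.zeros(Wg.n_rows, Wg.n_cols); gbg.zeros(bg.n_elem);
      g_c0.zeros(H);
    } else {
      gWx.zeros(Wx.n_rows, Wx.n_cols); gbx.zeros(bx.n_elem);
    }
  }
  MLP2Grad g_ode, g_static, g_long, g_fusion, g_cls;
  if (want_grad) {
    if (use_ode) g_ode.init(f_ode);
    g_static.init(f_static); g_long.init(f_long);
    g_fusion.init(f_fusion); g_cls.init(f_cls);
  }

  mat probs(nPat, C, arma::fill::zeros);
  mat phenos;
  if (want_latent) phenos.zeros(nPat, P);
  double loss = 0.0, wsum = 0.0;
  int n_used = 0;

  for (int pidx = 0; pidx < nPat; ++pidx) {
    List pat = patients[pidx];
    mat X = as<mat>(pat["X"]);     // n x k
    mat M = as<mat>(pat["M"]);
    vec dts = as<vec>(pat["dt"]);  // hours since previous obs (integration time)
    // optional separate time feature for the cell input (defaults to the gap)
    vec tfs = pat.containsElementNamed("tf") ? as<vec>(pat["tf"]) : dts;
    vec s = as<vec>(pat["s"]);
    int y = as<int>(pat["y"]);     // 0-based label, -1 = unlabeled
    const int n = X.n_rows, k = X.n_cols;
    const int D = 2 * k + 1;

    // ---- forward with caches ----------------------------------------------
    std::vector<vec> H_prev(n), Zg(n), Rg(n), Gg(n), U(n);
    std::vector<vec> Ig(n), Fg(n), Og(n), GGg(n), Cprev(n), Cnew(n), Hnew(n);
    std::vector<OdeCache> ode_caches(n);
    std::vector<int> nsubs(n, 0);
    std::vector<double> deltas(n, 0.0);
    std::vector<std::vector<vec> > rk_k(n), rk_y(n);

    vec h = h0, cst;
    if (cell == "lstm") cst = c0;
    for (int i = 0; i < n; ++i) {
      double dt = dts[i];
      if (use_ode && i > 0 && dt > 0) {
        int ns = (int)std::ceil(dt / max_step);
        double delta = dt / ns;
        nsubs[i] = ns; deltas[i] = delta;
        if (solver == "euler") {
          for (int jsub = 0; jsub < ns; ++jsub)
            h = h + delta * ode_f(f_ode, h, ode_caches[i]);
        } else {  // rk4
          for (int jsub = 0; jsub < ns; ++jsub) {
            vec k1 = ode_f(f_ode, h, ode_caches[i]);
            vec k2 = ode_f(f_ode, h + 0.5 * delta * k1, ode_caches[i]);
            vec k3 = ode_f(f_ode, h + 0.5 * delta * k2, ode_caches[i]);
            vec k4 = ode_f(f_ode, h + delta * k3, ode_caches[i]);
            rk_k[i].push_back(k1); rk_k[i].push_back(k2);
            rk_k[i].push_back(k3); rk_k[i].push_back(k4);
            h = h + (delta / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
          }
        }
        if (!h.is_finite())
          stop("non-finite hidden state during ODE integration; try a smaller max_step or learning rate");
      }
      vec u(D);
      u.subvec(0, k - 1) = X.row(i).t();
      u.subvec(k, 2 * k - 1) = M.row(i).t();
      u[D - 1] = tfs[i];
      U[i] = u; H_prev[i] = h;
      if (cell == "gru") {
        vec cat = arma::join_cols(u, h);
        vec z = sigmoid(Wz * cat + bz);
        vec r = sigmoid(Wr * cat + br);
        vec cat2 = arma::join_cols(u, r % h);
        vec g = arma::tanh(Wh * cat2 + bh);
        h = z % h + (1.0 - z) % g;
        Zg[i] = z; Rg[i] = r; Gg[i] = g;
      } else if (cell == "lstm") {
        vec cat = arma::join_cols(u, h);
        vec ig = sigmoid(Wi * cat + bi);
        vec fg = sigmoid(Wf * cat + bf);
        vec og = sigmoid(Wo * cat + bo);
        vec gg = arma::tanh(Wg * cat + bg);
        Cprev[i] = cst;
        cst = fg % cst + ig % gg;
        h = og % arma::tanh(cst);
        Ig[i] = ig; Fg[i] = fg; Og[i] = og; GGg[i] = gg; Cnew[i] = cst;
      } else {
        vec cat = arma::join_cols(u, h);
        h = arma::tanh(Wx * cat + bx);
      }
      Hnew[i] = h;
      if (!h.is_finite())
        stop("non-finite hidden state at observation %d; try a smaller learning rate", i + 1);
    }

    // ---- head --------------------------------------------------------------
    vec a_s, a_l, a_f, a_c;
    vec zs = f_static.fwd(s, a_s);
    vec zl = f_long.fwd(h, a_l);
    vec fin = arma::join_cols(zs, zl);
    vec z = f_fusion.fwd(fin, a_f);
    vec logits = f_cls.fwd(z, a_c);
    vec lmax = logits - logits.max();
    vec ex = arma::exp(lmax);
    vec p = ex / arma::accu(ex);
    probs.row(pidx) = p.t();
    if (want_latent) phenos.row(pidx) = z.t();

    if (y < 0) continue;  // unlabeled: prediction only
    double w = cw[y];
    loss += -w * std::log(std::max(p[y], 1e-300));
    wsum += w; ++n_used;

    if (!want_grad) continue;

    // ---- backward ----------------------------------------------------------
    vec dlog = w * p; dlog[y] -= w;
    vec dz = g_cls.bwd(f_cls, z, a_c, dlog);
    vec dfin = g_fusion.bwd(f_fusion, fin, a_f, dz);
    int ds = zs.n_elem;
    vec dzs = dfin.subvec(0, ds - 1);
    vec dzl = dfin.subvec(ds, dfin.n_elem - 1);
    g_static.bwd(f_static, s, a_s, dzs);
    vec dh = g_long.bwd(f_long, h, a_l, dzl);
    vec dc(H, arma::fill::zeros);

    for (int i = n - 1; i >= 0; --i) {
      const vec& hp = H_prev[i];
      const vec& u = U[i];
      const int k2 = u.n_elem;
      if (cell == "gru") {
        const vec &z_ = Zg[i], &r_ = Rg[i], &g_ = Gg[i];
        vec cat = arma::join_cols(u, hp);
        vec cat2 = arma::join_cols(u, r_ % hp);
        vec dzg = dh % (hp - g_);
        vec dg = dh % (1.0 - z_);
        vec dhp = dh % z_;
        vec dgpre = dg % (1.0 - g_ % g_);
        gWh += dgpre * cat2.t(); gbh += dgpre;
        vec dcat2 = Wh.t() * dgpre;
        vec drh = dcat2.subvec(k2, k2 + H - 1);
        vec dr = drh % hp;
        dhp += drh % r_;
        vec drpre = dr % r_ % (1.0 - r_);
        gWr += drpre * cat.t(); gbr += drpre;
        dhp += vec(Wr.t() * drpre).subvec(k2, k2 + H - 1);
        vec dzpre = dzg % z_ % (1.0 - z_);
        gWz += dzpre * cat.t(); gbz += dzpre;
        dhp += vec(Wz.t() * dzpre).subvec(k2, k2 + H - 1);
        dh = dhp;
      } else if (cell == "lstm") {
        const vec &ig = Ig[i], &fg = Fg[i], &og = Og[i], &gg = GGg[i];
        const vec &cp = Cprev[i], &cn = Cnew[i];
        vec cat = arma::join_cols(u, hp);
        vec tc = arma::tanh(cn);
        vec dog = dh % tc;
        dc += dh % og % (1.0 - tc % tc);
        vec dig = dc % gg;
        vec dfg = dc % cp;
        vec dgg = dc % ig;
        vec dc_prev = dc % fg;
        vec dipre = dig % ig % (1.0 - ig);
        vec dfpre = dfg % fg % (1.0 - fg);
        vec dopre = dog % og % (1.0 - og);
        vec dgpre = dgg % (1.0 - gg % gg);
        gWi += dipre * cat.t(); gbi += dipre;
        gWf += dfpre * cat.t(); gbf += dfpre;
        gWo += dopre * cat.t(); gbo += dopre;
        gWg += dgpre * cat.t(); gbg += dgpre;
        vec dcat = Wi.t() * dipre + Wf.t() * dfpre + Wo.t() * dopre + Wg.t() * dgpre;
        dh = dcat.subvec(k2, k2 + H - 1);
        dc = dc_prev;
      } else {
        const vec& hn = Hnew[i];
        vec cat = arma::join_cols(u, hp);
        vec dpre = dh % (1.0 - hn % hn);
        gWx += dpre * cat.t(); gbx += dpre;
        dh = vec(Wx.t() * dpre).subvec(k2, k2 + H - 1);
      }
      // back through the ODE segment preceding observation i
      if (use_ode && nsubs[i] > 0) {
        double delta = deltas[i];
        if (solver == "euler") {
          for (int jsub = nsubs[i] - 1; jsub >= 0; --jsub) {
            const vec& hin = ode_caches[i].h_in[jsub];
            const vec& a = ode_caches[i].act[jsub];
            vec df = delta * dh;
            g_ode.W2 += df * a.t(); g_ode.b2 += df;
            vec da = f_ode.W2.t() * df;
            vec dapre = da % (1.0 - a % a);
            g_ode.W1 += dapre * hin.t(); g_ode.b1 += dapre;
            dh += f_ode.W1.t() * dapre;
          }
        } else {  // rk4: reverse through the stages of each sub-step
          for (int jsub = nsubs[i] - 1; jsub >= 0; --jsub) {
            // stage caches for this sub-step
            const vec* hin = &ode_caches[i].h_in[4 * jsub];
            const vec* act = &ode_caches[i].act[4 * jsub];
            vec dk1 = (delta / 6.0) * dh;
            vec dk2 = (delta / 3.0) * dh;
            vec dk3 = (delta / 3.0) * dh;
            vec dk4 = (delta / 6.0) * dh;
            // k4 = f(y4), y4 = h + delta k3
            vec dy4 = g_ode.bwd(f_ode, hin[3], act[3], dk4);
            dh += dy4; dk3 += delta * dy4;
            // k3 = f(y3), y3 = h + delta/2 k2
            vec dy3 = g_ode.bwd(f_ode, hin[2], act[2], dk3);
            dh += dy3; dk2 += 0.5 * delta * dy3;
            // k2 = f(y2), y2 = h + delta/2 k1
            vec dy2 = g_ode.bwd(f_ode, hin[1], act[1], dk2);
            dh += dy2; dk1 += 0.5 * delta * dy2;
            // k1 = f(h)
            vec dy1 = g_ode.bwd(f_ode, hin[0], act[0], dk1);
            dh += dy1;
          }
        }
      }
    }
    g_h0 += dh;
    if (cell == "lstm") g_c0 += dc;
  }

  List out = List::create(
    _["loss"] = loss, _["wsum"] = wsum, _["n"] = n_used,
    _["probs"] = probs);
  if (want_latent) out["phenotypes"] = phenos;
  if (want_grad) {
    List g;
    g["h0"] = g_h0;
    if (cell == "gru") {
      g["Wz"] = gWz; g["bz"] = gbz; g["Wr"] = gWr; g["br"] = gbr;
      g["Wh"] = gWh; g["bh"] = gbh;
    } else if (cell == "lstm") {
      g["Wi"] = gWi; g["bi"] = gbi; g["Wf"] = gWf; g["bf"] = gbf;
      g["Wo"] = gWo; g["bo"] = gbo; g["Wg"] = gWg; g["bg"] = gbg;
      g["c0"] = g_c0;
    } else {
      g["Wx"] = gWx; g["bx"] = gbx;
    }
    if (use_ode) g_ode.store(g, "ode");
    g_static.store(g, "static"); g_long.store(g, "long");
    g_fusion.store(g, "fusion"); g_cls.store(g, "cls");
    out["grads"] = g;
  }
  out;
  return out;
}
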