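// Compiled engine for the enclosing-subgraph classifier: sparse-adjacency
// forward pass, hand-derived backward pass and Adam updates. The pure-R
// functions in R/model.R are the dense reference implementation; tests hold
// the two paths to within 1e-6.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

enum Prop { P_A = 0, P_A2 = 1, P_RW = 2, P_SYM = 3 };

struct Cfg {
  int L;
  std::vector<int> props;    // subset of {P_A, P_A2, P_RW, P_SYM}, ordered
  std::vector<int> dims;     // conv layer output widths, last == 1
  int k, c1, c2, k2, dense, pool, stride;
  bool tanh_act;
  int F() const { int s = 0; for (int d : dims) s += d; return s; }
  int Q() const { return (k - pool) / stride + 1; }
  int O2() const { return Q() - k2 + 1; }
};

struct Sub {
  int n;
  arma::sp_mat A;            // symmetric 0/1, target edge already removed
  arma::vec dinv, dhalf;     // 1/deg~ and 1/sqrt(deg~) with deg~ = deg + 1
  arma::mat X;               // one-hot features n x L
  int y;
};

static Cfg parse_cfg(const List& config) {
  Cfg c;
  c.L = as<int>(config["L"]);
  for (int p : as<std::vector<int>>(config["props"])) c.props.push_back(p);
  c.dims = as<std::vector<int>>(config["conv_dims"]);
  c.k = as<int>(config["k"]);
  c.c1 = as<int>(config["conv1_channels"]);
  c.c2 = as<int>(config["conv2_channels"]);
  c.k2 = as<int>(config["conv2_kernel"]);
  c.dense = as<int>(config["dense_units"]);
  c.pool = as<int>(config["pool_size"]);
  c.stride = as<int>(config["pool_stride"]);
  c.tanh_act = as<std::string>(config["activation"]) == "tanh";
  if (c.Q() < c.k2) stop("pooling k too small for the read-out head");
  return c;
}

static std::vector<Sub> parse_subs(const List& subgraphs, const Cfg& cfg) {
  std::vector<Sub> subs;
  subs.reserve(subgraphs.size());
  for (int s = 0; s < subgraphs.size(); ++s) {
    List sg = subgraphs[s];
    Sub sub;
    sub.n = as<int>(sg["n"]);
    arma::uvec ei = as<arma::uvec>(sg["ei"]);  // 0-based, each edge once
    arma::uvec ej = as<arma::uvec>(sg["ej"]);
    arma::umat loc(2, 2 * ei.n_elem);
    for (arma::uword e = 0; e < ei.n_elem; ++e) {
      loc(0, 2 * e) = ei(e); loc(1, 2 * e) = ej(e);
      loc(0, 2 * e + 1) = ej(e); loc(1, 2 * e + 1) = ei(e);
    }
    arma::vec vals(2 * ei.n_elem, arma::fill::ones);
    sub.A = arma::sp_mat(loc, vals, sub.n, sub.n);
    arma::vec deg = arma::vec(arma::sum(sub.A, 1)) + 1.0;
    sub.dinv = 1.0 / deg;
    sub.dhalf = 1.0 / arma::sqrt(deg);
    arma::uvec slots = as<arma::uvec>(sg["slots"]);  // 0-based
    sub.X.zeros(sub.n, cfg.L);
    for (int i = 0; i < sub.n; ++i) sub.X(i, slots(i)) = 1.0;
    sub.y = as<int>(sg["y"]);
    subs.push_back(std::move(sub));
  }
  return subs;
}

// Apply one propagator (or its transpose) to a node matrix.
static arma::mat apply_prop(const Sub& s, int p, const arma::mat& M,
                            bool transpose) {
  switch (p) {
    case P_A: return s.A * M;                 // symmetric
    case P_A2: return s.A * (s.A * M);        // symmetric
    case P_RW: {
      if (!transpose) {                       // D~^-1 A~ M
        arma::mat AM = s.A * M + M;
        AM.each_col() %= s.dinv;
        return AM;
      }
      arma::mat G = M;                        // (D~^-1 A~)^T G = A~ D~^-1 G
      G.each_col() %= s.dinv;
      return s.A * G + G;
    }
    case P_SYM: {                             // symmetric
      arma::mat G = M;
      G.each_col() %= s.dhalf;
      arma::mat R = s.A * G + G;
      R.each_col() %= s.dhalf;
      return R;
    }
  }
  stop("unknown propagator");
}

struct Params {
  std::vector<arma::mat> W;   // graph conv weights
  arma::mat K1, K2, Wd1, Wd2;
  arma::vec b1, b2, bd1, bd2;
};

static Params parse_params(const List& params) {
  Params p;
  List W = params["W"];
  for (int t = 0; t < W.size(); ++t) p.W.push_back(as<arma::mat>(W[t]));
  p.K1 = as<arma::mat>(params["K1"]);
  p.b1 = as<arma::vec>(params["b1"]);
  p.K2 = as<arma::mat>(params["K2"]);
  p.b2 = as<arma::vec>(params["b2"]);
  p.Wd1 = as<arma::mat>(params["Wd1"]);
  p.bd1 = as<arma::vec>(params["bd1"]);
  p.Wd2 = as<arma::mat>(params["Wd2"]);
  p.bd2 = as<arma::vec>(params["bd2"]);
  return p;
}

static List params_to_list(const Params& p) {
  List W(p.W.size());
  for (size_t t = 0; t < p.W.size(); ++t) W[t] = wrap(p.W[t]);
  return List::create(_["W"] = W, _["K1"] = p.K1, _["b1"] = p.b1,
                      _["K2"] = p.K2, _["b2"] = p.b2,
                      _["Wd1"] = p.Wd1, _["bd1"] = p.bd1,
                      _["Wd2"] = p.Wd2, _["bd2"] = p.bd2);
}

struct Cache {
  std::vector<arma::mat> Z;   // Z[0] = X, Z[t] conv outputs
  std::vector<arma::mat> H;   // spliced pre-weight inputs per layer
  arma::mat Zcat, pooled, a1, r1, m1, Mwin, a2, r2;
  arma::umat amax;            // max-pool argmax row per (Q, c1)
  arma::uvec ord;
  int take;
  arma::vec flat, hid, logits, logp;
};

// Stable descending lexicographic order, last column first.
static arma::uvec sortpool_order(const arma::mat& Z) {
  const int n = Z.n_rows, f = Z.n_cols;
  std::vector<arma::uword> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](arma::uword a, arma::uword b) {
                     for (int c = f - 1; c >= 0; --c) {
                       if (Z(a, c) > Z(b, c)) return true;
                       if (Z(a, c) < Z(b, c)) return false;
                     }
                     return false;
                   });
  return arma::uvec(idx);
}

static void forward_one(const Sub& s, const Params& p, const Cfg& cfg,
                        Cache& ca) {
  const int T = cfg.dims.size(), m = cfg.props.size();
  ca.Z.assign(T + 1, arma::mat());
  ca.H.assign(T, arma::mat());
  ca.Z[0] = s.X;
  for (int t = 0; t < T; ++t) {
    const arma::mat& Zin = ca.Z[t];
    arma::mat H(s.n, m * Zin.n_cols);
    for (int j = 0; j < m; ++j) {
      H.cols(j * Zin.n_cols, (j + 1) * Zin.n_cols - 1) =
        apply_prop(s, cfg.props[j], Zin, false);
    }
    ca.H[t] = H;
    arma::mat U = H * p.W[t];
    ca.Z[t + 1] = cfg.tanh_act ? arma::mat(arma::tanh(U))
                               : arma::mat(arma::clamp(U, 0.0, arma::datum::inf));
  }
  const int F = cfg.F();
  ca.Zcat.set_size(s.n, F);
  int off = 0;
  for (int t = 0; t < T; ++t) {
    ca.Zcat.cols(off, off + cfg.dims[t] - 1) = ca.Z[t + 1];
    off += cfg.dims[t];
  }
  ca.ord = sortpool_order(ca.Zcat);
  ca.take = std::min(s.n, cfg.k);
  ca.pooled.zeros(cfg.k, F);
  for (int r = 0; r < ca.take; ++r) ca.pooled.row(r) = ca.Zcat.row(ca.ord(r));
  // head
  ca.a1 = ca.pooled * p.K1.t();
  ca.a1.each_row() += p.b1.t();
  ca.r1 = arma::clamp(ca.a1, 0.0, arma::datum::inf);
  const int Q = cfg.Q();
  ca.m1.set_size(Q, cfg.c1);
  ca.amax.set_size(Q, cfg.c1);
  for (int q = 0; q < Q; ++q) {
    for (int c = 0; c < cfg.c1; ++c) {
      int base = q * cfg.stride;
      double best = ca.r1(base, c);
      int bi = base;
      for (int u = 1; u < cfg.pool; ++u) {
        if (ca.r1(base + u, c) > best) { best = ca.r1(base + u, c); bi = base + u; }
      }
      ca.m1(q, c) = best;
      ca.amax(q, c) = bi;
    }
  }
  const int O2 = cfg.O2();
  ca.Mwin.set_size(O2, cfg.k2 * cfg.c1);
  for (int q = 0; q < O2; ++q) {
    for (int u = 0; u < cfg.k2; ++u) {
      ca.Mwin(q, arma::span(u * cfg.c1, (u + 1) * cfg.c1 - 1)) =
        ca.m1.row(q + u);
    }
  }
  ca.a2 = ca.Mwin * p.K2.t();
  ca.a2.each_row() += p.b2.t();
  ca.r2 = arma::clamp(ca.a2, 0.0, arma::datum::inf);
  ca.flat.set_size(O2 * cfg.c2);   // row-major: position q, then channel
  for (int q = 0; q < O2; ++q)
    for (int c = 0; c < cfg.c2; ++c) ca.flat(q * cfg.c2 + c) = ca.r2(q, c);
  arma::vec hpre = p.Wd1 * ca.flat + p.bd1;
  ca.hid = arma::clamp(hpre, 0.0, arma::datum::inf);
  ca.logits = p.Wd2 * ca.hid + p.bd2;
  double mx = ca.logits.max();
  ca.logp = ca.logits - (mx + std::log(arma::sum(arma::exp(ca.logits - mx))));
}

static void zero_like(const Params& p, Params& g) {
  g.W.clear();
  for (const auto& w : p.W) g.W.push_back(arma::zeros<arma::mat>(w.n_rows, w.n_cols));
  g.K1.zeros(p.K1.n_rows, p.K1.n_cols);
  g.b1.zeros(p.b1.n_elem);
  g.K2.zeros(p.K2.n_rows, p.K2.n_cols);
  g.b2.zeros(p.b2.n_elem);
  g.Wd1.zeros(p.Wd1.n_rows, p.Wd1.n_cols);
  g.bd1.zeros(p.bd1.n_elem);
  g.Wd2.zeros(p.Wd2.n_rows, p.Wd2.n_cols);
  g.bd2.zeros(p.bd2.n_elem);
}

// Accumulate gradients of -logp[y] into g. Returns the sample loss.
static double backward_one(const Sub& s, const Params& p, const Cfg& cfg,
                           const Cache& ca, Params& g) {
  const int T = cfg.dims.size(), m = cfg.props.size();
  const int Q = cfg.Q(), O2 = cfg.O2(), F = cfg.F();
  double loss = -ca.logp(s.y);
  arma::vec dlogits = arma::exp(ca.logp);
  dlogits(s.y) -= 1.0;
  g.Wd2 += dlogits * ca.hid.t();
  g.bd2 += dlogits;
  arma::vec dhid = p.Wd2.t() * dlogits;
  dhid.elem(arma::find(ca.hid <= 0)).zeros();
  g.Wd1 += dhid * ca.flat.t();
  g.bd1 += dhid;
  arma::vec dflat = p.Wd1.t() * dhid;
  arma::mat dr2(O2, cfg.c2);
  for (int q = 0; q < O2; ++q)
    for (int c = 0; c < cfg.c2; ++c) dr2(q, c) = dflat(q * cfg.c2 + c);
  arma::mat da2 = dr2;
  da2.elem(arma::find(ca.a2 <= 0)).zeros();
  g.K2 += da2.t() * ca.Mwin;
  g.b2 += arma::sum(da2, 0).t();
  arma::mat dMwin = da2 * p.K2;
  arma::mat dm1(Q, cfg.c1, arma::fill::zeros);
  for (int q = 0; q < O2; ++q)
    for (int u = 0; u < cfg.k2; ++u)
      dm1.row(q + u) += dMwin(q, arma::span(u * cfg.c1, (u + 1) * cfg.c1 - 1));
  arma::mat dr1(cfg.k, cfg.c1, arma::fill::zeros);
  for (int q = 0; q < Q; ++q)
    for (int c = 0; c < cfg.c1; ++c) dr1(ca.amax(q, c), c) += dm1(q, c);
  arma::mat da1 = dr1;
  da1.elem(arma::find(ca.a1 <= 0)).zeros();
  g.K1 += da1.t() * ca.pooled;
  g.b1 += arma::sum(da1, 0).t();
  arma::mat dpooled = da1 * p.K1;
  arma::mat dZcat(s.n, F, arma::fill::zeros);
  for (int r = 0; r < ca.take; ++r) dZcat.row(ca.ord(r)) += dpooled.row(r);
  // back through the conv stack
  std::vector<int> offs(T);
  {
    int off = 0;
    for (int t = 0; t < T; ++t) { offs[t] = off; off += cfg.dims[t]; }
  }
  arma::mat carry;   // gradient flowing into Z[t] from layer t+1
  for (int t = T - 1; t >= 0; --t) {
    arma::mat dZ = dZcat.cols(offs[t], offs[t] + cfg.dims[t] - 1);
    if (t < T - 1 && carry.n_elem) dZ += carry;
    const arma::mat& Zt = ca.Z[t + 1];
    arma::mat dU;
    if (cfg.tanh_act) dU = dZ % (1.0 - arma::square(Zt));
    else { dU = dZ; dU.elem(arma::find(Zt <= 0)).zeros(); }
    g.W[t] += ca.H[t].t() * dU;
    arma::mat dH = dU * p.W[t].t();
    const int din = ca.Z[t].n_cols;
    carry.zeros(s.n, din);
    for (int j = 0; j < m; ++j) {
      carry += apply_prop(s, cfg.props[j],
                          dH.cols(j * din, (j + 1) * din - 1), true);
    }
  }
  return loss;
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_batch(List subgraphs, List params, List config) {
  Cfg cfg = parse_cfg(config);
  Params p = parse_params(params);
  std::vector<Sub> subs = parse_subs(subgraphs, cfg);
  NumericMatrix out(subs.size(), 2);
  Cache ca;
  for (size_t i = 0; i < subs.size(); ++i) {
    forward_one(subs[i], p, cfg, ca);
    out(i, 0) = ca.logp(0);
    out(i, 1) = ca.logp(1);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_loss_grad(List subgraphs, List params, List config) {
  Cfg cfg = parse_cfg(config);
  Params p = parse_params(params);
  std::vector<Sub> subs = parse_subs(subgraphs, cfg);
  Params g;
  zero_like(p, g);
  double total = 0.0;
  Cache ca;
  for (size_t i = 0; i < subs.size(); ++i) {
    forward_one(subs[i], p, cfg, ca);
    total += backward_one(subs[i], p, cfg, ca, g);
  }
  const double inv = 1.0 / subs.size();
  for (auto& w : g.W) w *= inv;
  g.K1 *= inv; g.b1 *= inv; g.K2 *= inv; g.b2 *= inv;
  g.Wd1 *= inv; g.bd1 *= inv; g.Wd2 *= inv; g.bd2 *= inv;
  return List::create(_["loss"] = total * inv,
                      _["grads"] = params_to_list(g));
}

struct Adam {
  Params m, v;
  long step = 0;
  double lr, b1, b2, eps;
  void init(const Params& p, double lr_, double b1_, double b2_, double eps_) {
    zero_like(p, m); zero_like(p, v);
    lr = lr_; b1 = b1_; b2 = b2_; eps = eps_;
  }
  void upd(arma::mat& w, arma::mat& mw, arma::mat& vw, const arma::mat& gw,
           double c1, double c2) {
    mw = b1 * mw + (1 - b1) * gw;
    vw = b2 * vw + (1 - b2) * arma::square(gw);
    w -= lr * (mw / c1) / (arma::sqrt(vw / c2) + eps);
  }
  void upd(arma::vec& w, arma::vec& mw, arma::vec& vw, const arma::vec& gw,
           double c1, double c2) {
    mw = b1 * mw + (1 - b1) * gw;
    vw = b2 * vw + (1 - b2) * arma::square(gw);
    w -= lr * (mw / c1) / (arma::sqrt(vw / c2) + eps);
  }
  void apply(Params& p, const Params& g) {
    ++step;
    double c1 = 1.0 - std::pow(b1, (double)step);
    double c2 = 1.0 - std::pow(b2, (double)step);
    for (size_t t = 0; t < p.W.size(); ++t) upd(p.W[t], m.W[t], v.W[t], g.W[t], c1, c2);
    upd(p.K1, m.K1, v.K1, g.K1, c1, c2);
    upd(p.b1, m.b1, v.b1, g.b1, c1, c2);
    upd(p.K2, m.K2, v.K2, g.K2, c1, c2);
    upd(p.b2, m.b2, v.b2, g.b2, c1, c2);
    upd(p.Wd1, m.Wd1, v.Wd1, g.Wd1, c1, c2);
    upd(p.bd1, m.bd1, v.bd1, g.bd1, c1, c2);
    upd(p.Wd2, m.Wd2, v.Wd2, g.Wd2, c1, c2);
    upd(p.bd2, m.bd2, v.bd2, g.bd2, c1, c2);
  }
};

// perms: epochs x N matrix of 0-based sample indices fixing the shuffle
// order, generated on the R side so all randomness flows from one seed.
// [[Rcpp::export]]
List cpp_train(List subgraphs, List params, List config, double lr,
               int batch_size, IntegerMatrix perms,
               double beta1 = 0.9, double beta2 = 0.999, double eps = 1e-8) {
  Cfg cfg = parse_cfg(config);
  Params p = parse_params(params);
  std::vector<Sub> subs = parse_subs(subgraphs, cfg);
  const int N = subs.size(), epochs = perms.nrow();
  if (perms.ncol() != N) stop("permutation matrix does not match sample count");
  Adam opt;
  opt.init(p, lr, beta1, beta2, eps);
  NumericVector epoch_loss(epochs);
  Params g;
  Cache ca;
  for (int e = 0; e < epochs; ++e) {
    double tot = 0.0;
    for (int start = 0; start < N; start += batch_size) {
      int end = std::min(start + batch_size, N);
      zero_like(p, g);
      double bloss = 0.0;
      for (int i = start; i < end; ++i) {
        const Sub& s = subs[perms(e, i)];
        forward_one(s, p, cfg, ca);
        bloss += backward_one(s, p, cfg, ca, g);
      }
      const double inv = 1.0 / (end - start);
      for (auto& w : g.W) w *= inv;
      g.K1 *= inv; g.b1 *= inv; g.K2 *= inv; g.b2 *= inv;
      g.Wd1 *= inv; g.bd1 *= inv; g.Wd2 *= inv; g.bd2 *= inv;
      opt.apply(p, g);
      tot += bloss;
    }
    epoch_loss[e] = tot / N;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = params_to_list(p),
                      _["epoch_loss"] = epoch_loss);
}
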