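// Fast forward/backward pass and training loop for the hierarchical
// multiple-instance attention network. Mirrors the R reference path in
// R/model.R exactly (same gate equations, same attention formulas); the
// test suite asserts agreement between the two routes.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct GRUP { mat W, U; vec b; };      // W: 3H x In, U: 3H x H (r,z,n stacked)
struct AttnP { mat W; vec b, u; };
struct ClfP { mat W; vec b; };

struct Params {
  mat We;
  GRUP wf, wb, uf, ub;
  AttnP wa, ta;
  ClfP tc, uc;
};

static GRUP gru_from_list(const Rcpp::List& l) {
  GRUP g;
  g.W = Rcpp::as<mat>(l["W"]);
  g.U = Rcpp::as<mat>(l["U"]);
  g.b = Rcpp::as<vec>(l["b"]);
  return g;
}
static AttnP attn_from_list(const Rcpp::List& l) {
  AttnP a;
  a.W = Rcpp::as<mat>(l["W"]);
  a.b = Rcpp::as<vec>(l["b"]);
  a.u = Rcpp::as<vec>(l["u"]);
  return a;
}
static ClfP clf_from_list(const Rcpp::List& l) {
  ClfP c;
  c.W = Rcpp::as<mat>(l["W"]);
  c.b = Rcpp::as<vec>(l["b"]);
  return c;
}

static Params params_from_list(const Rcpp::List& l) {
  Params p;
  p.We = Rcpp::as<mat>(l["We"]);
  p.wf = gru_from_list(l["wgru_f"]);
  p.wb = gru_from_list(l["wgru_b"]);
  p.uf = gru_from_list(l["ugru_f"]);
  p.ub = gru_from_list(l["ugru_b"]);
  p.wa = attn_from_list(l["wattn"]);
  p.ta = attn_from_list(l["tattn"]);
  p.tc = clf_from_list(l["tclf"]);
  p.uc = clf_from_list(l["uclf"]);
  return p;
}

static Rcpp::NumericVector as_rvec(const vec& v) {
  return Rcpp::NumericVector(v.begin(), v.end());
}

static Rcpp::List params_to_list(const Params& p) {
  using Rcpp::List;
  using Rcpp::Named;
  auto gl = [](const GRUP& g) {
    return List::create(Named("W") = g.W, Named("U") = g.U,
                        Named("b") = as_rvec(g.b));
  };
  auto al = [](const AttnP& a) {
    return List::create(Named("W") = a.W, Named("b") = as_rvec(a.b),
                        Named("u") = as_rvec(a.u));
  };
  auto cl = [](const ClfP& c) {
    return List::create(Named("W") = c.W, Named("b") = as_rvec(c.b));
  };
  List out = List::create(
      Named("We") = p.We,
      Named("wgru_f") = gl(p.wf), Named("wgru_b") = gl(p.wb),
      Named("wattn") = al(p.wa), Named("tclf") = cl(p.tc),
      Named("ugru_f") = gl(p.uf), Named("ugru_b") = gl(p.ub),
      Named("tattn") = al(p.ta), Named("uclf") = cl(p.uc));
  out.attr("class") = "mil_params";
  return out;
}

// Collect pointers to every tensor so the optimizer can iterate them.
struct ParamRefs {
  std::vector<mat*> ms;
  std::vector<vec*> vs;
  explicit ParamRefs(Params& p) {
    ms = {&p.We,
          &p.wf.W, &p.wf.U, &p.wb.W, &p.wb.U,
          &p.uf.W, &p.uf.U, &p.ub.W, &p.ub.U,
          &p.wa.W, &p.ta.W, &p.tc.W, &p.uc.W};
    vs = {&p.wf.b, &p.wb.b, &p.uf.b, &p.ub.b,
          &p.wa.b, &p.wa.u, &p.ta.b, &p.ta.u,
          &p.tc.b, &p.uc.b};
  }
};

static Params zeros_like(const Params& p) {
  Params g = p;
  ParamRefs r(g);
  for (mat* m : r.ms) m->zeros();
  for (vec* v : r.vs) v->zeros();
  return g;
}

struct Bag {
  imat ids;    // n_posts x max_tokens, 0-based vocab ids, 0 = pad
  ivec counts; // valid tokens per post
  mat S;       // n_posts x ds pronoun features (0 columns for MIL)
  int y;
};

static std::vector<Bag> bags_from_list(const Rcpp::List& l) {
  std::vector<Bag> out(l.size());
  for (int i = 0; i < l.size(); ++i) {
    Rcpp::List b = l[i];
    out[i].ids = Rcpp::as<imat>(b["ids"]);
    out[i].counts = Rcpp::as<ivec>(b["counts"]);
    out[i].S = Rcpp::as<mat>(b["S"]);
    out[i].y = Rcpp::as<int>(b["y"]);
  }
  return out;
}

// ---------------------------------------------------------------- GRU

struct GruCache {
  mat R, Z, N, Unh, Hprev, H;
};

static void gru_forward(const GRUP& g, const mat& X, GruCache& c) {
  const uword H = g.U.n_cols, L = X.n_cols;
  c.R.set_size(H, L); c.Z.set_size(H, L); c.N.set_size(H, L);
  c.Unh.set_size(H, L); c.Hprev.set_size(H, L); c.H.set_size(H, L);
  vec h(H, fill::zeros);
  for (uword t = 0; t < L; ++t) {
    vec Wx = g.W * X.col(t) + g.b;
    vec Uh = g.U * h;
    vec r = 1.0 / (1.0 + exp(-(Wx.subvec(0, H - 1) + Uh.subvec(0, H - 1))));
    vec z = 1.0 / (1.0 + exp(-(Wx.subvec(H, 2 * H - 1) + Uh.subvec(H, 2 * H - 1))));
    vec unh = Uh.subvec(2 * H, 3 * H - 1);
    vec n = tanh(Wx.subvec(2 * H, 3 * H - 1) + r % unh);
    c.Hprev.col(t) = h;
    h = (1.0 - z) % n + z % h;
    c.R.col(t) = r; c.Z.col(t) = z; c.N.col(t) = n; c.Unh.col(t) = unh;
    c.H.col(t) = h;
  }
}

static void gru_backward(const GRUP& g, const mat& X, const GruCache& c,
                         const mat& dH, GRUP& grad, mat& dX) {
  const uword H = g.U.n_cols, L = X.n_cols;
  dX.zeros(X.n_rows, L);
  vec dh(H, fill::zeros);
  for (uword tt = L; tt-- > 0;) {
    vec dht = dH.col(tt) + dh;
    vec r = c.R.col(tt), z = c.Z.col(tt), n = c.N.col(tt);
    vec hprev = c.Hprev.col(tt), unh = c.Unh.col(tt);
    vec dz = dht % (hprev - n);
    vec dn = dht % (1.0 - z);
    dh = dht % z;
    vec dn_pre = dn % (1.0 - n % n);
    vec dunh = dn_pre % r;
    vec dr = dn_pre % unh;
    vec dr_pre = dr % r % (1.0 - r);
    vec dz_pre = dz % z % (1.0 - z);
    vec d3 = join_cols(dr_pre, join_cols(dz_pre, dn_pre));
    vec du3 = join_cols(dr_pre, join_cols(dz_pre, dunh));
    grad.W += d3 * X.col(tt).t();
    grad.b += d3;
    grad.U += du3 * hprev.t();
    dh += g.U.rows(0, H - 1).t() * dr_pre
        + g.U.rows(H, 2 * H - 1).t() * dz_pre
        + g.U.rows(2 * H, 3 * H - 1).t() * dunh;
    dX.col(tt) = g.W.rows(0, H - 1).t() * dr_pre
               + g.W.rows(H, 2 * H - 1).t() * dz_pre
               + g.W.rows(2 * H, 3 * H - 1).t() * dn_pre;
  }
}

// -------------------------------------------------------- attention

struct AttnCache {
  mat Ua;      // A x L
  vec a;       // L
};

static vec attn_forward(const AttnP& p, const mat& H, AttnCache& c) {
  c.Ua = tanh(p.W * H + repmat(p.b, 1, H.n_cols));
  vec scores = c.Ua.t() * p.u;
  scores -= scores.max();
  vec e = exp(scores);
  c.a = e / accu(e);
  return H * c.a;
}

static void attn_backward(const AttnP& p, const mat& H, const AttnCache& c,
                          const vec& dsum, AttnP& grad, mat& dH) {
  dH = dsum * c.a.t();
  vec da = H.t() * dsum;
  vec dscore = c.a % (da - dot(c.a, da));
  grad.u += c.Ua * dscore;
  mat dUa = p.u * dscore.t();
  mat dUa_pre = dUa % (1.0 - c.Ua % c.Ua);
  grad.W += dUa_pre * H.t();
  grad.b += sum(dUa_pre, 1);
  dH += p.W.t() * dUa_pre;
}

static vec softmax2(const vec& logits) {
  vec s = logits - logits.max();
  vec e = exp(s);
  return e / accu(e);
}

// ------------------------------------------------- forward (+ cache)

struct PostCache {
  mat X;                 // E x L embedded tokens
  GruCache gf, gb;
  mat Hcat;              // 2H x L (after dropout in training)
  mat dropmask;          // same shape, empty in eval
  AttnCache wa;
  vec t;                 // 2H
  vec p;                 // 2
};

struct BagCache {
  std::vector<PostCache> posts;
  mat Rep;               // D x n
  GruCache uf, ub;
  mat Hu;                // 2G x n (after dropout)
  mat udropmask;
  AttnCache ta;
  vec v;                 // 2G
  vec yhat;              // 2
};

// Forward one bag. If rng != nullptr, dropout is active (training mode).
static double bag_forward(const Params& P, const Bag& bag, int prob_dim,
                          BagCache& C, double dropout, std::mt19937_64* rng) {
  const uword H2 = 2 * P.wf.U.n_cols;
  const uword n = bag.ids.n_rows;
  const uword ds = bag.S.n_cols;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double keep = 1.0 - dropout;
  C.posts.resize(n);
  C.Rep.set_size(ds + prob_dim, n);
  for (uword j = 0; j < n; ++j) {
    PostCache& pc = C.posts[j];
    const uword L = (uword)bag.counts(j);
    if (L > 0) {
      pc.X.set_size(P.We.n_cols, L);
      for (uword k = 0; k < L; ++k)
        pc.X.col(k) = P.We.row((uword)bag.ids(j, k)).t();
      gru_forward(P.wf, pc.X, pc.gf);
      mat Xr = fliplr(pc.X);
      gru_forward(P.wb, Xr, pc.gb);
      pc.Hcat = join_cols(pc.gf.H, fliplr(pc.gb.H));
      if (rng && dropout > 0) {
        pc.dropmask.set_size(pc.Hcat.n_rows, pc.Hcat.n_cols);
        for (uword i = 0; i < pc.dropmask.n_elem; ++i)
          pc.dropmask(i) = unif(*rng) < keep ? 1.0 / keep : 0.0;
        pc.Hcat %= pc.dropmask;
      }
      pc.t = attn_forward(P.wa, pc.Hcat, pc.wa);
    } else {
      pc.t = vec(H2, fill::zeros);
    }
    pc.p = softmax2(P.tc.W * pc.t + P.tc.b);
    if (ds > 0) C.Rep.col(j).subvec(0, ds - 1) = bag.S.row(j).t();
    if (prob_dim == 2) C.Rep.col(j).subvec(ds, ds + 1) = pc.p;
    else C.Rep(ds, j) = pc.p(1);
  }
  gru_forward(P.uf, C.Rep, C.uf);
  mat RepR = fliplr(C.Rep);
  gru_forward(P.ub, RepR, C.ub);
  C.Hu = join_cols(C.uf.H, fliplr(C.ub.H));
  if (rng && dropout > 0) {
    C.udropmask.set_size(C.Hu.n_rows, C.Hu.n_cols);
    for (uword i = 0; i < C.udropmask.n_elem; ++i)
      C.udropmask(i) = unif(*rng) < keep ? 1.0 / keep : 0.0;
    C.Hu %= C.udropmask;
  }
  C.v = attn_forward(P.ta, C.Hu, C.ta);
  C.yhat = softmax2(P.uc.W * C.v + P.uc.b);
  double py = std::max(C.yhat(bag.y), 1e-12);
  return -std::log(py);
}

static void bag_backward(const Params& P, const Bag& bag, int prob_dim,
                         BagCache& C, Params& G, bool freeze_emb) {
  const uword G2 = 2 * P.uf.U.n_cols;
  const uword Gh = P.uf.U.n_cols;
  const uword n = bag.ids.n_rows;
  const uword ds = bag.S.n_cols;
  // user classifier
  vec dlog = C.yhat;
  dlog(bag.y) -= 1.0;
  G.uc.W += dlog * C.v.t();
  G.uc.b += dlog;
  vec dv = P.uc.W.t() * dlog;
  // post attention
  mat dHu;
  attn_backward(P.ta, C.Hu, C.ta, dv, G.ta, dHu);
  if (C.udropmask.n_elem) dHu %= C.udropmask;
  // user BiGRU
  mat dRep_f, dRep_b;
  gru_backward(P.uf, C.Rep, C.uf, dHu.rows(0, Gh - 1), G.uf, dRep_f);
  mat RepR = fliplr(C.Rep);
  mat dHb_rev = fliplr(dHu.rows(Gh, G2 - 1));
  gru_backward(P.ub, RepR, C.ub, dHb_rev, G.ub, dRep_b);
  mat dRep = dRep_f + fliplr(dRep_b);
  // per post: classifier -> word attention -> word BiGRU -> embeddings
  const uword Hh = P.wf.U.n_cols;
  for (uword j = 0; j < n; ++j) {
    PostCache& pc = C.posts[j];
    vec dp(2, fill::zeros);
    if (prob_dim == 2) dp = dRep.col(j).subvec(ds, ds + 1);
    else dp(1) = dRep(ds, j);
    vec dc = pc.p % dp - pc.p * dot(pc.p, dp);
    G.tc.W += dc * pc.t.t();
    G.tc.b += dc;
    const uword L = (uword)bag.counts(j);
    if (L == 0) continue;
    vec dt = P.tc.W.t() * dc;
    mat dHcat;
    attn_backward(P.wa, pc.Hcat, pc.wa, dt, G.wa, dHcat);
    if (pc.dropmask.n_elem) dHcat %= pc.dropmask;
    mat dXf, dXb;
    gru_backward(P.wf, pc.X, pc.gf, dHcat.rows(0, Hh - 1), G.wf, dXf);
    mat Xr = fliplr(pc.X);
    mat dHb = fliplr(dHcat.rows(Hh, 2 * Hh - 1));
    gru_backward(P.wb, Xr, pc.gb, dHb, G.wb, dXb);
    mat dX = dXf + fliplr(dXb);
    if (!freeze_emb)
      for (uword k = 0; k < L; ++k)
        G.We.row((uword)bag.ids(j, k)) += dX.col(k).t();
  }
}

// --------------------------------------------------------- optimizer

struct OptState {
  std::vector<mat> m_m, v_m, s_m;
  std::vector<vec> m_v, v_v, s_v;
  long step = 0;
  void init(ParamRefs& r, bool adamod) {
    for (mat* p : r.ms) {
      m_m.emplace_back(p->n_rows, p->n_cols, fill::zeros);
      v_m.emplace_back(p->n_rows, p->n_cols, fill::zeros);
      if (adamod) s_m.emplace_back(p->n_rows, p->n_cols, fill::zeros);
    }
    for (vec* p : r.vs) {
      m_v.emplace_back(p->n_elem, fill::zeros);
      v_v.emplace_back(p->n_elem, fill::zeros);
      if (adamod) s_v.emplace_back(p->n_elem, fill::zeros);
    }
  }
};

template <typename T>
static void adam_update_one(T& param, const T& grad, T& m, T& v, T* s,
                            double lr, double b1, double b2, double b3,
                            double eps, long step) {
  m = b1 * m + (1.0 - b1) * grad;
  v = b2 * v + (1.0 - b2) * (grad % grad);
  double c1 = 1.0 - std::pow(b1, (double)step);
  double c2 = 1.0 - std::pow(b2, (double)step);
  T mhat = m / c1;
  T vhat = v / c2;
  T eta = lr / (sqrt(vhat) + eps);
  if (s) {  // AdaMod: bound the step size by its own exponential average
    *s = b3 * (*s) + (1.0 - b3) * eta;
    eta = arma::min(eta, *s);
  }
  param -= eta % mhat;
}

// ------------------------------------------------------- entry points

struct TrainCfg {
  double lr, dropout, b1, b2, b3, eps;
  int batch, max_epochs, patience, prob_dim;
  bool adamod, freeze_emb;
  unsigned seed;
};

static TrainCfg tcfg_from_list(const Rcpp::List& l) {
  TrainCfg t;
  t.lr = Rcpp::as<double>(l["lr"]);
  t.dropout = Rcpp::as<double>(l["dropout"]);
  t.b1 = Rcpp::as<double>(l["beta1"]);
  t.b2 = Rcpp::as<double>(l["beta2"]);
  t.b3 = Rcpp::as<double>(l["beta3"]);
  t.eps = 1e-8;
  t.batch = Rcpp::as<int>(l["batch_size"]);
  t.max_epochs = Rcpp::as<int>(l["max_epochs"]);
  t.patience = Rcpp::as<int>(l["patience"]);
  t.prob_dim = Rcpp::as<int>(l["prob_dim"]);
  t.adamod = Rcpp::as<std::string>(l["optimizer"]) == "adamod";
  t.freeze_emb = Rcpp::as<bool>(l["freeze_embeddings"]);
  t.seed = (unsigned)Rcpp::as<int>(l["seed"]);
  return t;
}

static double mean_eval_loss(const Params& P, const std::vector<Bag>& bags,
                             int prob_dim) {
  double tot = 0.0;
  BagCache C;
  for (const Bag& b : bags) tot += bag_forward(P, b, prob_dim, C, 0.0, nullptr);
  return tot / (double)bags.size();
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List train_bags, Rcpp::List val_bags,
                     Rcpp::List params, Rcpp::List tcfg) {
  std::vector<Bag> train = bags_from_list(train_bags);
  std::vector<Bag> val = bags_from_list(val_bags);
  Params P = params_from_list(params);
  TrainCfg cfg = tcfg_from_list(tcfg);
  ParamRefs refs(P);
  OptState opt;
  opt.init(refs, cfg.adamod);
  std::mt19937_64 rng(cfg.seed);

  Params best = P;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0;
  std::vector<double> hist_train, hist_val;
  std::vector<size_t> order(train.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = i;

  for (int epoch = 1; epoch <= cfg.max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0;
    size_t done = 0;
    while (done < order.size()) {
      size_t bs = std::min((size_t)cfg.batch, order.size() - done);
      Params G = zeros_like(P);
      ParamRefs grefs(G);
      double batch_loss = 0.0;
      for (size_t i = 0; i < bs; ++i) {
        const Bag& bag = train[order[done + i]];
        BagCache C;
        batch_loss += bag_forward(P, bag, cfg.prob_dim, C, cfg.dropout, &rng);
        bag_backward(P, bag, cfg.prob_dim, C, G, cfg.freeze_emb);
      }
      if (!std::isfinite(batch_loss))
        Rcpp::stop("training diverged: non-finite loss at epoch %d", epoch);
      epoch_loss += batch_loss;
      double inv = 1.0 / (double)bs;
      for (mat* g : grefs.ms) *g *= inv;
      for (vec* g : grefs.vs) *g *= inv;
      opt.step += 1;
      for (size_t i = 0; i < refs.ms.size(); ++i)
        adam_update_one(*refs.ms[i], *grefs.ms[i], opt.m_m[i], opt.v_m[i],
                        cfg.adamod ? &opt.s_m[i] : nullptr,
                        cfg.lr, cfg.b1, cfg.b2, cfg.b3, cfg.eps, opt.step);
      for (size_t i = 0; i < refs.vs.size(); ++i)
        adam_update_one(*refs.vs[i], *grefs.vs[i], opt.m_v[i], opt.v_v[i],
                        cfg.adamod ? &opt.s_v[i] : nullptr,
                        cfg.lr, cfg.b1, cfg.b2, cfg.b3, cfg.eps, opt.step);
      P.We.row(0).zeros();  // padding embedding stays zero
      done += bs;
    }
    double train_loss = epoch_loss / (double)train.size();
    double val_loss = val.empty() ? train_loss
                                  : mean_eval_loss(P, val, cfg.prob_dim);
    hist_train.push_back(train_loss);
    hist_val.push_back(val_loss);
    if (val_loss < best_val - 1e-5) {
      best_val = val_loss;
      best = P;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= cfg.patience) break;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_list(best),
      Rcpp::Named("train_loss") = hist_train,
      Rcpp::Named("val_loss") = hist_val,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_loss") = best_val);
}

// Loss and exact gradients for one bag (no dropout); used by the test
// suite to validate the analytic backward pass against finite
// differences of the forward loss.
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List bag_list, Rcpp::List params,
                         int prob_dim) {
  std::vector<Bag> bags = bags_from_list(bag_list);
  Params P = params_from_list(params);
  Params G = zeros_like(P);
  double loss = 0.0;
  for (const Bag& b : bags) {
    BagCache C;
    loss += bag_forward(P, b, prob_dim, C, 0.0, nullptr);
    bag_backward(P, b, prob_dim, C, G, false);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(G));
}

// Batch eval-mode forward. Returns user probabilities and, optionally,
// per-post probabilities and both attention maps.
// [[Rcpp::export]]
Rcpp::List cpp_predict(Rcpp::List bags_list, Rcpp::List params, int prob_dim,
                       bool details) {
  std::vector<Bag> bags = bags_from_list(bags_list);
  Params P = params_from_list(params);
  const size_t n = bags.size();
  mat probs(n, 2);
  Rcpp::List p_list(details ? (int)n : 0);
  Rcpp::List alpha_list(details ? (int)n : 0);
  Rcpp::List wattn_list(details ? (int)n : 0);
  BagCache C;
  for (size_t i = 0; i < n; ++i) {
    bag_forward(P, bags[i], prob_dim, C, 0.0, nullptr);
    probs.row(i) = C.yhat.t();
    if (details) {
      const uword np = bags[i].ids.n_rows;
      mat pm(np, 2);
      for (uword j = 0; j < np; ++j) pm.row(j) = C.posts[j].p.t();
      p_list[(int)i] = pm;
      alpha_list[(int)i] = as_rvec(C.ta.a);
      mat am(np, bags[i].ids.n_cols, fill::zeros);
      for (uword j = 0; j < np; ++j) {
        const uword L = (uword)bags[i].counts(j);
        if (L > 0) am.row(j).subvec(0, L - 1) = C.posts[j].wa.a.t();
      }
      wattn_list[(int)i] = am;
    }
  }
  if (details)
    return Rcpp::List::create(Rcpp::Named("probs") = probs,
                              Rcpp::Named("p") = p_list,
                              Rcpp::Named("alpha") = alpha_list,
                              Rcpp::Named("word_attention") = wattn_list);
  return Rcpp::List::create(Rcpp::Named("probs") = probs);
}
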