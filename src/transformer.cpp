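// Transformer encoder with masked-language-model and center-residue
// classification heads, forward and analytic backward passes.
//
// Layout (pre-layer-norm residual blocks, learned positional embeddings):
//   x0 = tok_emb[token] + pos_emb[position]
//   per layer: x += Attn(LN1(x));  x += FFN(LN2(x))
//   y = LNf(x)
// MLM head: logits = y * Wm + bm over the vocabulary, loss = mean negative
// log-likelihood at masked positions. Classification head: the row of y at
// the peptide-center index -> dense(embed_dim, gelu) -> dense(2) -> softmax,
// trained with focal loss -(1-p_t)^gamma * log(p_t).
//
// All randomness lives on the R side; these kernels are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double INV_SQRT2 = 0.7071067811865475244;
static const double INV_SQRT2PI = 0.3989422804014326779;

struct Config {
  int n_layers, n_heads, d, f, V;
  explicit Config(const List& cfg) {
    n_layers = as<int>(cfg["n_layers"]);
    n_heads = as<int>(cfg["n_heads"]);
    d = as<int>(cfg["embed_dim"]);
    f = as<int>(cfg["ffn_dim"]);
    V = as<int>(cfg["vocab_size"]);
    if (d % n_heads != 0) stop("embed_dim must be divisible by n_heads");
  }
};

static mat P(const List& params, const std::string& name) {
  return as<mat>(params[name]);
}
static rowvec Pv(const List& params, const std::string& name) {
  return as<rowvec>(params[name]);
}
static std::string lname(int l, const char* what) {
  return "l" + std::to_string(l + 1) + "." + what;
}

// ---- primitives -----------------------------------------------------------

static mat gelu(const mat& x) {
  // exact gelu: x * Phi(x)
  mat out(x.n_rows, x.n_cols);
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    double v = x(i);
    out(i) = v * 0.5 * (1.0 + std::erf(v * INV_SQRT2));
  }
  return out;
}

static mat gelu_grad(const mat& x) {
  mat out(x.n_rows, x.n_cols);
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    double v = x(i);
    double phi = INV_SQRT2PI * std::exp(-0.5 * v * v);
    out(i) = 0.5 * (1.0 + std::erf(v * INV_SQRT2)) + v * phi;
  }
  return out;
}

struct LNCache {
  mat xhat;     // normalized input
  vec invstd;   // per-row 1/sd
};

static mat layer_norm(const mat& x, const rowvec& g, const rowvec& b,
                      LNCache& cache) {
  const double eps = 1e-5;
  vec mu = arma::mean(x, 1);
  vec va = arma::var(x, 1 /* population */, 1);
  cache.invstd = 1.0 / arma::sqrt(va + eps);
  cache.xhat = x;
  cache.xhat.each_col() -= mu;
  cache.xhat.each_col() %= cache.invstd;
  mat out = cache.xhat;
  out.each_row() %= g;
  out.each_row() += b;
  return out;
}

static mat layer_norm_back(const mat& dy, const rowvec& g,
                           const LNCache& cache, rowvec& gg, rowvec& gb) {
  gg += arma::sum(dy % cache.xhat, 0);
  gb += arma::sum(dy, 0);
  mat dxhat = dy.each_row() % g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % cache.xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  mat corr = cache.xhat;
  corr.each_col() %= m2;
  dx -= corr;
  dx.each_col() %= cache.invstd;
  return dx;
}

static void softmax_rows_inplace(mat& s) {
  for (arma::uword i = 0; i < s.n_rows; ++i) {
    rowvec r = s.row(i);
    r -= r.max();
    r = arma::exp(r);
    s.row(i) = r / arma::accu(r);
  }
}

// ---- forward with caches --------------------------------------------------

struct LayerCache {
  mat x_in;                 // T x d
  LNCache ln1, ln2;
  mat a;                    // post-LN1
  mat Q, K, V;              // T x d (heads concatenated)
  std::vector<mat> A;       // per-head T x T attention
  mat ctx;                  // concatenated head contexts, T x d
  mat x_mid;                // after attention residual
  mat bnorm;                // post-LN2
  mat h1;                   // pre-gelu, T x f
  mat g1;                   // post-gelu
};

struct SeqCache {
  std::vector<LayerCache> layers;
  LNCache lnf;
  mat y;                    // final normalized output, T x d
};

static mat forward_seq(const List& params, const Config& cfg,
                       const IntegerVector& tok, SeqCache& sc,
                       bool want_attn) {
  const int T = tok.size();
  const int dh = cfg.d / cfg.n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat tok_emb = P(params, "tok"), pos_emb = P(params, "pos");
  if (T > (int)pos_emb.n_rows)
    stop("sequence length %d exceeds max length %d", T, (int)pos_emb.n_rows);
  mat x(T, cfg.d);
  for (int t = 0; t < T; ++t)
    x.row(t) = tok_emb.row(tok[t]) + pos_emb.row(t);

  sc.layers.resize(cfg.n_layers);
  for (int l = 0; l < cfg.n_layers; ++l) {
    LayerCache& c = sc.layers[l];
    c.x_in = x;
    c.a = layer_norm(x, Pv(params, lname(l, "ln1.g")),
                     Pv(params, lname(l, "ln1.b")), c.ln1);
    c.Q = c.a * P(params, lname(l, "Wq"));
    c.Q.each_row() += Pv(params, lname(l, "bq"));
    c.K = c.a * P(params, lname(l, "Wk"));
    c.K.each_row() += Pv(params, lname(l, "bk"));
    c.V = c.a * P(params, lname(l, "Wv"));
    c.V.each_row() += Pv(params, lname(l, "bv"));
    c.A.resize(cfg.n_heads);
    c.ctx.set_size(T, cfg.d);
    for (int h = 0; h < cfg.n_heads; ++h) {
      mat Qh = c.Q.cols(h * dh, (h + 1) * dh - 1);
      mat Kh = c.K.cols(h * dh, (h + 1) * dh - 1);
      mat Vh = c.V.cols(h * dh, (h + 1) * dh - 1);
      mat S = (Qh * Kh.t()) * scale;
      softmax_rows_inplace(S);
      c.A[h] = S;
      c.ctx.cols(h * dh, (h + 1) * dh - 1) = S * Vh;
    }
    mat attn_out = c.ctx * P(params, lname(l, "Wo"));
    attn_out.each_row() += Pv(params, lname(l, "bo"));
    c.x_mid = c.x_in + attn_out;
    c.bnorm = layer_norm(c.x_mid, Pv(params, lname(l, "ln2.g")),
                         Pv(params, lname(l, "ln2.b")), c.ln2);
    c.h1 = c.bnorm * P(params, lname(l, "W1"));
    c.h1.each_row() += Pv(params, lname(l, "b1"));
    c.g1 = gelu(c.h1);
    mat ffn = c.g1 * P(params, lname(l, "W2"));
    ffn.each_row() += Pv(params, lname(l, "b2"));
    x = c.x_mid + ffn;
  }
  sc.y = layer_norm(x, Pv(params, "lnf.g"), Pv(params, "lnf.b"), sc.lnf);
  return sc.y;
}

// ---- backward -------------------------------------------------------------

struct Grads {
  std::map<std::string, mat> m;
  std::map<std::string, rowvec> v;
  mat& M(const std::string& k, int r, int c) {
    auto it = m.find(k);
    if (it == m.end())
      it = m.emplace(k, mat(r, c, arma::fill::zeros)).first;
    return it->second;
  }
  rowvec& R(const std::string& k, int n) {
    auto it = v.find(k);
    if (it == v.end())
      it = v.emplace(k, rowvec(n, arma::fill::zeros)).first;
    return it->second;
  }
};

static void backward_seq(const List& params, const Config& cfg,
                         const IntegerVector& tok, const SeqCache& sc,
                         mat dy, Grads& g) {
  const int T = tok.size();
  const int dh = cfg.d / cfg.n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);

  mat dx = layer_norm_back(dy, Pv(params, "lnf.g"), sc.lnf,
                           g.R("lnf.g", cfg.d), g.R("lnf.b", cfg.d));
  for (int l = cfg.n_layers - 1; l >= 0; --l) {
    const LayerCache& c = sc.layers[l];
    // FFN block
    mat dffn = dx;                         // into W2 branch
    g.M(lname(l, "W2"), cfg.f, cfg.d) += c.g1.t() * dffn;
    g.R(lname(l, "b2"), cfg.d) += arma::sum(dffn, 0);
    mat dg1 = dffn * P(params, lname(l, "W2")).t();
    mat dh1 = dg1 % gelu_grad(c.h1);
    g.M(lname(l, "W1"), cfg.d, cfg.f) += c.bnorm.t() * dh1;
    g.R(lname(l, "b1"), cfg.f) += arma::sum(dh1, 0);
    mat dbnorm = dh1 * P(params, lname(l, "W1")).t();
    mat dx_mid = dx + layer_norm_back(dbnorm, Pv(params, lname(l, "ln2.g")),
                                      c.ln2, g.R(lname(l, "ln2.g"), cfg.d),
                                      g.R(lname(l, "ln2.b"), cfg.d));
    // attention block
    mat dattn_out = dx_mid;
    g.M(lname(l, "Wo"), cfg.d, cfg.d) += c.ctx.t() * dattn_out;
    g.R(lname(l, "bo"), cfg.d) += arma::sum(dattn_out, 0);
    mat dctx = dattn_out * P(params, lname(l, "Wo")).t();
    mat dQ(T, cfg.d), dK(T, cfg.d), dV(T, cfg.d);
    for (int h = 0; h < cfg.n_heads; ++h) {
      mat Qh = c.Q.cols(h * dh, (h + 1) * dh - 1);
      mat Kh = c.K.cols(h * dh, (h + 1) * dh - 1);
      mat Vh = c.V.cols(h * dh, (h + 1) * dh - 1);
      mat dctxh = dctx.cols(h * dh, (h + 1) * dh - 1);
      const mat& A = c.A[h];
      mat dA = dctxh * Vh.t();
      dV.cols(h * dh, (h + 1) * dh - 1) = A.t() * dctxh;
      // softmax rows backward
      vec rs = arma::sum(dA % A, 1);
      mat dS = dA;
      dS.each_col() -= rs;
      dS %= A;
      dS *= scale;
      dQ.cols(h * dh, (h + 1) * dh - 1) = dS * Kh;
      dK.cols(h * dh, (h + 1) * dh - 1) = dS.t() * Qh;
    }
    g.M(lname(l, "Wq"), cfg.d, cfg.d) += c.a.t() * dQ;
    g.R(lname(l, "bq"), cfg.d) += arma::sum(dQ, 0);
    g.M(lname(l, "Wk"), cfg.d, cfg.d) += c.a.t() * dK;
    g.R(lname(l, "bk"), cfg.d) += arma::sum(dK, 0);
    g.M(lname(l, "Wv"), cfg.d, cfg.d) += c.a.t() * dV;
    g.R(lname(l, "bv"), cfg.d) += arma::sum(dV, 0);
    mat da = dQ * P(params, lname(l, "Wq")).t() +
             dK * P(params, lname(l, "Wk")).t() +
             dV * P(params, lname(l, "Wv")).t();
    dx = dx_mid + layer_norm_back(da, Pv(params, lname(l, "ln1.g")), c.ln1,
                                  g.R(lname(l, "ln1.g"), cfg.d),
                                  g.R(lname(l, "ln1.b"), cfg.d));
  }
  // embeddings
  mat& gtok = g.M("tok", cfg.V, cfg.d);
  mat& gpos = g.M("pos", P(params, "pos").n_rows, cfg.d);
  for (int t = 0; t < T; ++t) {
    gtok.row(tok[t]) += dx.row(t);
    gpos.row(t) += dx.row(t);
  }
}

static List grads_to_list(Grads& g) {
  List out;
  for (auto& kv : g.m) out[kv.first] = wrap(kv.second);
  for (auto& kv : g.v) out[kv.first] = wrap(kv.second);
  return out;
}

// ---- exported entry points ------------------------------------------------

// Encoder forward: returns final-layer embeddings (and optionally the
// final-layer per-head attention matrices) for each sequence.
// [[Rcpp::export]]
List cpp_encode(List params, List cfg_, List tokens, bool want_attention) {
  Config cfg(cfg_);
  int n = tokens.size();
  List emb(n), attn(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector tok = tokens[i];
    SeqCache sc;
    mat y = forward_seq(params, cfg, tok, sc, want_attention);
    emb[i] = wrap(y);
    if (want_attention) {
      const std::vector<mat>& A = sc.layers[cfg.n_layers - 1].A;
      arma::cube cube(tok.size(), tok.size(), cfg.n_heads);
      for (int h = 0; h < cfg.n_heads; ++h) cube.slice(h) = A[h];
      attn[i] = wrap(cube);
    }
  }
  return want_attention ? List::create(_["embeddings"] = emb,
                                       _["attention"] = attn)
                        : List::create(_["embeddings"] = emb);
}

// MLM loss (mean negative log-likelihood over masked positions across the
// batch) and, optionally, parameter gradients.
// labels[i]: per-position original token id at masked positions, -1 elsewhere.
// [[Rcpp::export]]
List cpp_mlm(List params, List cfg_, List tokens, List labels,
             bool want_grads) {
  Config cfg(cfg_);
  int n = tokens.size();
  long K = 0;
  for (int i = 0; i < n; ++i) {
    IntegerVector lab = labels[i];
    for (int t = 0; t < lab.size(); ++t) if (lab[t] >= 0) ++K;
  }
  if (K == 0) stop("MLM batch contains no masked positions");
  mat Wm = P(params, "mlm.W");
  rowvec bm = Pv(params, "mlm.b");
  Grads g;
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    IntegerVector tok = tokens[i], lab = labels[i];
    SeqCache sc;
    mat y = forward_seq(params, cfg, tok, sc, false);
    mat dy(y.n_rows, cfg.d, arma::fill::zeros);
    bool any = false;
    for (int t = 0; t < tok.size(); ++t) {
      if (lab[t] < 0) continue;
      any = true;
      rowvec logits = y.row(t) * Wm + bm;
      logits -= logits.max();
      rowvec p = arma::exp(logits);
      p /= arma::accu(p);
      double pt = std::max(p[lab[t]], 1e-300);
      loss += -std::log(pt) / (double)K;
      if (want_grads) {
        rowvec dlogit = p / (double)K;
        dlogit[lab[t]] -= 1.0 / (double)K;
        g.M("mlm.W", cfg.d, cfg.V) += y.row(t).t() * dlogit;
        g.R("mlm.b", cfg.V) += dlogit;
        dy.row(t) += dlogit * Wm.t();
      }
    }
    if (want_grads && any) backward_seq(params, cfg, tok, sc, dy, g);
  }
  List out = List::create(_["loss"] = loss, _["K"] = (double)K);
  if (want_grads) out["grads"] = grads_to_list(g);
  return out;
}

// Focal-loss classification over the center-residue embedding. Returns the
// mean loss, positive-class probabilities and optionally gradients.
// centers are 1-based row indices into each sequence; y_true in {0, 1}.
// [[Rcpp::export]]
List cpp_classify(List params, List cfg_, List tokens, IntegerVector centers,
                  IntegerVector y_true, double gamma, bool want_grads) {
  Config cfg(cfg_);
  int n = tokens.size();
  mat Wh = P(params, "cls.Wh"), Wc = P(params, "cls.Wc");
  rowvec bh = Pv(params, "cls.bh"), bc = Pv(params, "cls.bc");
  Grads g;
  NumericVector prob(n);
  double loss = 0.0;
  const double invn = 1.0 / (double)n;
  for (int i = 0; i < n; ++i) {
    IntegerVector tok = tokens[i];
    int cidx = centers[i] - 1;
    if (cidx < 0 || cidx >= tok.size()) stop("center index out of range");
    SeqCache sc;
    mat y = forward_seq(params, cfg, tok, sc, false);
    rowvec h = y.row(cidx);
    rowvec z1 = h * Wh + bh;
    mat z1m(1, cfg.d); z1m.row(0) = z1;
    rowvec gl = gelu(z1m).row(0);
    rowvec logits = gl * Wc + bc;
    logits -= logits.max();
    rowvec p = arma::exp(logits);
    p /= arma::accu(p);
    prob[i] = p[1];
    int lab = y_true[i];
    double pt = std::min(std::max(p[lab], 1e-12), 1.0 - 1e-12);
    double om = 1.0 - pt;
    loss += invn * (-std::pow(om, gamma) * std::log(pt));
    if (want_grads) {
      // dL/dp_t for focal loss
      double dpt = (gamma > 0.0)
        ? gamma * std::pow(om, gamma - 1.0) * std::log(pt)
            - std::pow(om, gamma) / pt
        : -1.0 / pt;
      rowvec dlogits(2);
      for (int j = 0; j < 2; ++j) {
        double ind = (j == lab) ? 1.0 : 0.0;
        dlogits[j] = invn * dpt * pt * (ind - p[j]);
      }
      g.M("cls.Wc", cfg.d, 2) += gl.t() * dlogits;
      g.R("cls.bc", 2) += dlogits;
      rowvec dgl = dlogits * Wc.t();
      rowvec dz1 = dgl % gelu_grad(z1m).row(0);
      g.M("cls.Wh", cfg.d, cfg.d) += h.t() * dz1;
      g.R("cls.bh", cfg.d) += dz1;
      mat dy(y.n_rows, cfg.d, arma::fill::zeros);
      dy.row(cidx) = dz1 * Wh.t();
      backward_seq(params, cfg, tok, sc, dy, g);
    }
  }
  List out = List::create(_["loss"] = loss, _["prob"] = prob);
  if (want_grads) out["grads"] = grads_to_list(g);
  return out;
}
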