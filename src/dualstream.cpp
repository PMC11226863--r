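// Dual-stream encoder: amino-acid stream supplies attention queries, codon
// stream supplies keys and values. Forward, backward and the masked
// cross-entropy objective are implemented here; batching, masking and the
// optimizer live in R. All operations are deterministic given inputs (the
// only RNG is the dropout stream, seeded per call).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double LN_EPS = 1e-5;

struct LNCache {
  mat xhat;
  vec invstd;
};

// row-wise layer normalization with learned gain/bias (stored as 1 x d mats)
static mat ln_fwd(const mat& X, const mat& g, const mat& b, LNCache& c) {
  const double d = (double)X.n_cols;
  vec mu = arma::mean(X, 1);
  mat xc = X;
  xc.each_col() -= mu;
  vec v = arma::sum(xc % xc, 1) / d;
  c.invstd = 1.0 / arma::sqrt(v + LN_EPS);
  c.xhat = xc;
  c.xhat.each_col() %= c.invstd;
  mat Y = c.xhat;
  Y.each_row() %= g.row(0);
  Y.each_row() += b.row(0);
  return Y;
}

static mat ln_bwd(const mat& dY, const mat& g, const LNCache& c,
                  mat& dg, mat& db) {
  dg += arma::sum(dY % c.xhat, 0);
  db += arma::sum(dY, 0);
  mat dxh = dY;
  dxh.each_row() %= g.row(0);
  vec m1 = arma::mean(dxh, 1);
  vec m2 = arma::mean(dxh % c.xhat, 1);
  mat dX = dxh;
  dX.each_col() -= m1;
  mat t = c.xhat;
  t.each_col() %= m2;
  dX -= t;
  dX.each_col() %= c.invstd;
  return dX;
}

struct AttnCache {
  mat Aq, Akv, Q, K, V, O;
  std::vector<mat> P;  // per-head attention weights
};

// multi-head scaled dot-product attention on pre-normalized inputs.
// Aq: Lq x d (queries), Akv: Lk x d (keys and values).
static mat attn_fwd(const mat& Aq, const mat& Akv,
                    const mat& Wq, const mat& Wk, const mat& Wv, const mat& Wo,
                    int h, AttnCache& c) {
  const int d = Wq.n_cols;
  const int dh = d / h;
  const double s = 1.0 / std::sqrt((double)dh);
  c.Aq = Aq;
  c.Akv = Akv;
  c.Q = Aq * Wq;
  c.K = Akv * Wk;
  c.V = Akv * Wv;
  c.O.set_size(Aq.n_rows, d);
  c.P.assign(h, mat());
  for (int i = 0; i < h; ++i) {
    arma::span cs(i * dh, (i + 1) * dh - 1);
    mat S = c.Q.cols(cs) * c.K.cols(cs).t() * s;
    S.each_col() -= arma::max(S, 1);
    mat P = arma::exp(S);
    P.each_col() /= arma::sum(P, 1);
    c.P[i] = P;
    c.O.cols(cs) = P * c.V.cols(cs);
  }
  return c.O * Wo;
}

static void attn_bwd(const mat& dOut,
                     const mat& Wq, const mat& Wk, const mat& Wv, const mat& Wo,
                     int h, const AttnCache& c,
                     mat& dWq, mat& dWk, mat& dWv, mat& dWo,
                     mat& dAq, mat& dAkv) {
  const int d = Wq.n_cols;
  const int dh = d / h;
  const double s = 1.0 / std::sqrt((double)dh);
  dWo += c.O.t() * dOut;
  mat dO = dOut * Wo.t();
  mat dQ(arma::size(c.Q), arma::fill::zeros);
  mat dK(arma::size(c.K), arma::fill::zeros);
  mat dV(arma::size(c.V), arma::fill::zeros);
  for (int i = 0; i < h; ++i) {
    arma::span cs(i * dh, (i + 1) * dh - 1);
    mat dOh = dO.cols(cs);
    mat dP = dOh * c.V.cols(cs).t();
    dV.cols(cs) = c.P[i].t() * dOh;
    mat dS = c.P[i] % dP;
    vec rs = arma::sum(dS, 1);
    mat t = c.P[i];
    t.each_col() %= rs;
    dS -= t;
    dS *= s;
    dQ.cols(cs) = dS * c.K.cols(cs);
    dK.cols(cs) = dS.t() * c.Q.cols(cs);
  }
  dWq += c.Aq.t() * dQ;
  dAq += dQ * Wq.t();
  dWk += c.Akv.t() * dK;
  dAkv += dK * Wk.t();
  dWv += c.Akv.t() * dV;
  dAkv += dV * Wv.t();
}

struct FFCache {
  mat A, H1, H;
};

static mat ff_fwd(const mat& A, const mat& W1, const mat& b1,
                  const mat& W2, const mat& b2, FFCache& c) {
  c.A = A;
  c.H1 = A * W1;
  c.H1.each_row() += b1.row(0);
  c.H = c.H1 % arma::conv_to<mat>::from(c.H1 > 0.0);
  mat out = c.H * W2;
  out.each_row() += b2.row(0);
  return out;
}

static mat ff_bwd(const mat& dOut, const mat& W1, const mat& W2,
                  const FFCache& c,
                  mat& dW1, mat& db1, mat& dW2, mat& db2) {
  dW2 += c.H.t() * dOut;
  db2 += arma::sum(dOut, 0);
  mat dH = dOut * W2.t();
  mat dH1 = dH % arma::conv_to<mat>::from(c.H1 > 0.0);
  dW1 += c.A.t() * dH1;
  db1 += arma::sum(dH1, 0);
  return dH1 * W1.t();
}

struct DropCache {
  bool on = false;
  mat mask;
};

static mat drop_fwd(const mat& X, double p, bool train,
                    std::mt19937_64& rng, DropCache& c) {
  if (!train || p <= 0.0) {
    c.on = false;
    return X;
  }
  c.on = true;
  std::bernoulli_distribution keep(1.0 - p);
  c.mask.set_size(arma::size(X));
  const double scale = 1.0 / (1.0 - p);
  for (arma::uword j = 0; j < X.n_cols; ++j)
    for (arma::uword i = 0; i < X.n_rows; ++i)
      c.mask(i, j) = keep(rng) ? scale : 0.0;
  return X % c.mask;
}

static mat drop_bwd(const mat& dY, const DropCache& c) {
  if (!c.on) return dY;
  return dY % c.mask;
}

struct BlockCache {
  LNCache ln_sa_a, ln_sa_c, ln_xq, ln_xkv, ln_ff_a, ln_ff_c;
  AttnCache sa_a, sa_c, x;
  FFCache ff_a, ff_c;
  DropCache d1, d2, d3, d4, d5;
};

typedef std::map<std::string, mat> ParamMap;

static const mat& P(const ParamMap& p, const std::string& n) {
  ParamMap::const_iterator it = p.find(n);
  if (it == p.end()) Rcpp::stop("missing parameter: " + n);
  return it->second;
}

static mat& G(ParamMap& g, const std::string& n) { return g[n]; }

// Runs the full network over a batch, optionally accumulating parameter
// gradients of the masked cross-entropy loss and/or collecting logits.
// All integer ids are 1-based (R convention); label 0 means "ignore".
// [[Rcpp::export]]
List cpp_dualstream_run(List params, List batch, List cfg,
                        bool want_grads, bool want_logits) {
  const int d  = as<int>(cfg["embed_dim"]);
  const int h  = as<int>(cfg["n_heads"]);
  const int nb = as<int>(cfg["n_blocks"]);
  const double pdrop = as<double>(cfg["dropout"]);
  const bool train = as<bool>(cfg["train"]);
  const unsigned long long dseed = (unsigned long long)as<double>(cfg["dropout_seed"]);

  IntegerMatrix aa = batch["aa_ids"];
  IntegerMatrix cd = batch["codon_ids"];
  IntegerVector lens = batch["lens"];
  LogicalVector zeroed = batch["seq_zeroed"];
  IntegerMatrix aa_lab = batch["aa_labels"];
  IntegerMatrix cd_lab = batch["codon_labels"];
  const int B = aa.nrow();

  CharacterVector pn = params.names();
  ParamMap pm;
  for (int i = 0; i < params.size(); ++i)
    pm[std::string(pn[i])] = as<mat>(params[i]);
  ParamMap gm;
  if (want_grads)
    for (ParamMap::iterator it = pm.begin(); it != pm.end(); ++it)
      gm[it->first] = mat(arma::size(it->second), arma::fill::zeros);

  // label counts over the whole batch fix the loss normalization
  long n_lab_c = 0, n_lab_a = 0;
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < lens[b]; ++t) {
      if (cd_lab(b, t) > 0) ++n_lab_c;
      if (aa_lab(b, t) > 0) ++n_lab_a;
    }
  if (n_lab_c == 0 && n_lab_a == 0 && want_grads)
    Rcpp::stop("no labeled positions in batch");

  std::mt19937_64 rng(dseed);
  double loss_c = 0.0, loss_a = 0.0;
  long acc_c = 0;
  List logits_c_out(B), logits_a_out(B);

  const mat& tok_aa = P(pm, "tok_aa");
  const mat& tok_c  = P(pm, "tok_c");
  const mat& pos    = P(pm, "pos");
  if (arma::uword(*std::max_element(lens.begin(), lens.end())) > pos.n_rows)
    Rcpp::stop("sequence longer than max_len");

  for (int b = 0; b < B; ++b) {
    const int L = lens[b];
    mat Xa(L, d), Xc(L, d, arma::fill::zeros);
    for (int t = 0; t < L; ++t) {
      Xa.row(t) = tok_aa.row(aa(b, t) - 1) + pos.row(t);
      if (!zeroed[b])
        Xc.row(t) = tok_c.row(cd(b, t) - 1) + pos.row(t);
    }

    std::vector<BlockCache> C(nb);
    std::vector<mat> Xa_hist, Xc_hist;  // inputs seen by each sublayer LN
    char nm[64];
    for (int i = 0; i < nb; ++i) {
      BlockCache& c = C[i];
      std::string pre = "b" + std::to_string(i + 1) + "_";
      // self-attention, amino-acid stream
      {
        mat A = ln_fwd(Xa, P(pm, pre + "sa_a_ln_g"), P(pm, pre + "sa_a_ln_b"), c.ln_sa_a);
        mat out = attn_fwd(A, A, P(pm, pre + "sa_a_Wq"), P(pm, pre + "sa_a_Wk"),
                           P(pm, pre + "sa_a_Wv"), P(pm, pre + "sa_a_Wo"), h, c.sa_a);
        Xa += drop_fwd(out, pdrop, train, rng, c.d1);
      }
      // self-attention, codon stream
      {
        mat A = ln_fwd(Xc, P(pm, pre + "sa_c_ln_g"), P(pm, pre + "sa_c_ln_b"), c.ln_sa_c);
        mat out = attn_fwd(A, A, P(pm, pre + "sa_c_Wq"), P(pm, pre + "sa_c_Wk"),
                           P(pm, pre + "sa_c_Wv"), P(pm, pre + "sa_c_Wo"), h, c.sa_c);
        Xc += drop_fwd(out, pdrop, train, rng, c.d2);
      }
      // cross-attention: queries from amino acids, keys/values from codons
      {
        mat Aq = ln_fwd(Xa, P(pm, pre + "x_lnq_g"), P(pm, pre + "x_lnq_b"), c.ln_xq);
        mat Kv = ln_fwd(Xc, P(pm, pre + "x_lnkv_g"), P(pm, pre + "x_lnkv_b"), c.ln_xkv);
        mat out = attn_fwd(Aq, Kv, P(pm, pre + "x_Wq"), P(pm, pre + "x_Wk"),
                           P(pm, pre + "x_Wv"), P(pm, pre + "x_Wo"), h, c.x);
        Xa += drop_fwd(out, pdrop, train, rng, c.d3);
      }
      // position-wise feed-forward, each stream
      {
        mat A = ln_fwd(Xa, P(pm, pre + "ff_a_ln_g"), P(pm, pre + "ff_a_ln_b"), c.ln_ff_a);
        mat out = ff_fwd(A, P(pm, pre + "ff_a_W1"), P(pm, pre + "ff_a_b1"),
                         P(pm, pre + "ff_a_W2"), P(pm, pre + "ff_a_b2"), c.ff_a);
        Xa += drop_fwd(out, pdrop, train, rng, c.d4);
      }
      {
        mat A = ln_fwd(Xc, P(pm, pre + "ff_c_ln_g"), P(pm, pre + "ff_c_ln_b"), c.ln_ff_c);
        mat out = ff_fwd(A, P(pm, pre + "ff_c_W1"), P(pm, pre + "ff_c_b1"),
                         P(pm, pre + "ff_c_W2"), P(pm, pre + "ff_c_b2"), c.ff_c);
        Xc += drop_fwd(out, pdrop, train, rng, c.d5);
      }
    }
    (void)nm;

    // heads: the codon head reads the query (amino-acid) stream, the
    // amino-acid head reads the codon stream
    LNCache lnfa, lnfc;
    mat Ha = ln_fwd(Xa, P(pm, "lnf_a_g"), P(pm, "lnf_a_b"), lnfa);
    mat Hc = ln_fwd(Xc, P(pm, "lnf_c_g"), P(pm, "lnf_c_b"), lnfc);
    mat logit_c = Ha * P(pm, "head_c_W");
    logit_c.each_row() += P(pm, "head_c_b").row(0);
    mat logit_a = Hc * P(pm, "head_a_W");
    logit_a.each_row() += P(pm, "head_a_b").row(0);

    if (want_logits) {
      logits_c_out[b] = wrap(logit_c);
      logits_a_out[b] = wrap(logit_a);
    }

    // softmax cross-entropy over labeled positions
    mat dlc(arma::size(logit_c), arma::fill::zeros);
    mat dla(arma::size(logit_a), arma::fill::zeros);
    {
      mat Z = logit_c;
      Z.each_col() -= arma::max(Z, 1);
      mat E = arma::exp(Z);
      vec s = arma::sum(E, 1);
      for (int t = 0; t < L; ++t) {
        int lab = cd_lab(b, t);
        if (lab > 0) {
          loss_c += -(Z(t, lab - 1) - std::log(s(t)));
          if ((int)arma::index_max(Z.row(t)) == lab - 1) ++acc_c;
          if (want_grads && n_lab_c > 0) {
            dlc.row(t) = E.row(t) / s(t) / (double)n_lab_c;
            dlc(t, lab - 1) -= 1.0 / (double)n_lab_c;
          }
        }
      }
      Z = logit_a;
      Z.each_col() -= arma::max(Z, 1);
      E = arma::exp(Z);
      s = arma::sum(E, 1);
      for (int t = 0; t < L; ++t) {
        int lab = aa_lab(b, t);
        if (lab > 0) {
          loss_a += -(Z(t, lab - 1) - std::log(s(t)));
          if (want_grads && n_lab_a > 0) {
            dla.row(t) = E.row(t) / s(t) / (double)n_lab_a;
            dla(t, lab - 1) -= 1.0 / (double)n_lab_a;
          }
        }
      }
    }

    if (!want_grads) continue;

    // ---- backward ----
    G(gm, "head_c_W") += Ha.t() * dlc;
    G(gm, "head_c_b") += arma::sum(dlc, 0);
    G(gm, "head_a_W") += Hc.t() * dla;
    G(gm, "head_a_b") += arma::sum(dla, 0);
    mat dXa = ln_bwd(dlc * P(pm, "head_c_W").t(), P(pm, "lnf_a_g"), lnfa,
                     G(gm, "lnf_a_g"), G(gm, "lnf_a_b"));
    mat dXc = ln_bwd(dla * P(pm, "head_a_W").t(), P(pm, "lnf_c_g"), lnfc,
                     G(gm, "lnf_c_g"), G(gm, "lnf_c_b"));

    for (int i = nb - 1; i >= 0; --i) {
      BlockCache& c = C[i];
      std::string pre = "b" + std::to_string(i + 1) + "_";
      // ff_c
      {
        mat dsub = drop_bwd(dXc, c.d5);
        mat dA = ff_bwd(dsub, P(pm, pre + "ff_c_W1"), P(pm, pre + "ff_c_W2"), c.ff_c,
                        G(gm, pre + "ff_c_W1"), G(gm, pre + "ff_c_b1"),
                        G(gm, pre + "ff_c_W2"), G(gm, pre + "ff_c_b2"));
        dXc += ln_bwd(dA, P(pm, pre + "ff_c_ln_g"), c.ln_ff_c,
                      G(gm, pre + "ff_c_ln_g"), G(gm, pre + "ff_c_ln_b"));
      }
      // ff_a
      {
        mat dsub = drop_bwd(dXa, c.d4);
        mat dA = ff_bwd(dsub, P(pm, pre + "ff_a_W1"), P(pm, pre + "ff_a_W2"), c.ff_a,
                        G(gm, pre + "ff_a_W1"), G(gm, pre + "ff_a_b1"),
                        G(gm, pre + "ff_a_W2"), G(gm, pre + "ff_a_b2"));
        dXa += ln_bwd(dA, P(pm, pre + "ff_a_ln_g"), c.ln_ff_a,
                      G(gm, pre + "ff_a_ln_g"), G(gm, pre + "ff_a_ln_b"));
      }
      // cross-attention
      {
        mat dsub = drop_bwd(dXa, c.d3);
        mat dAq(L, d, arma::fill::zeros), dAkv(L, d, arma::fill::zeros);
        attn_bwd(dsub, P(pm, pre + "x_Wq"), P(pm, pre + "x_Wk"),
                 P(pm, pre + "x_Wv"), P(pm, pre + "x_Wo"), h, c.x,
                 G(gm, pre + "x_Wq"), G(gm, pre + "x_Wk"),
                 G(gm, pre + "x_Wv"), G(gm, pre + "x_Wo"), dAq, dAkv);
        dXa += ln_bwd(dAq, P(pm, pre + "x_lnq_g"), c.ln_xq,
                      G(gm, pre + "x_lnq_g"), G(gm, pre + "x_lnq_b"));
        dXc += ln_bwd(dAkv, P(pm, pre + "x_lnkv_g"), c.ln_xkv,
                      G(gm, pre + "x_lnkv_g"), G(gm, pre + "x_lnkv_b"));
      }
      // sa_c
      {
        mat dsub = drop_bwd(dXc, c.d2);
        mat dA1(L, d, arma::fill::zeros), dA2(L, d, arma::fill::zeros);
        attn_bwd(dsub, P(pm, pre + "sa_c_Wq"), P(pm, pre + "sa_c_Wk"),
                 P(pm, pre + "sa_c_Wv"), P(pm, pre + "sa_c_Wo"), h, c.sa_c,
                 G(gm, pre + "sa_c_Wq"), G(gm, pre + "sa_c_Wk"),
                 G(gm, pre + "sa_c_Wv"), G(gm, pre + "sa_c_Wo"), dA1, dA2);
        dXc += ln_bwd(dA1 + dA2, P(pm, pre + "sa_c_ln_g"), c.ln_sa_c,
                      G(gm, pre + "sa_c_ln_g"), G(gm, pre + "sa_c_ln_b"));
      }
      // sa_a
      {
        mat dsub = drop_bwd(dXa, c.d1);
        mat dA1(L, d, arma::fill::zeros), dA2(L, d, arma::fill::zeros);
        attn_bwd(dsub, P(pm, pre + "sa_a_Wq"), P(pm, pre + "sa_a_Wk"),
                 P(pm, pre + "sa_a_Wv"), P(pm, pre + "sa_a_Wo"), h, c.sa_a,
                 G(gm, pre + "sa_a_Wq"), G(gm, pre + "sa_a_Wk"),
                 G(gm, pre + "sa_a_Wv"), G(gm, pre + "sa_a_Wo"), dA1, dA2);
        dXa += ln_bwd(dA1 + dA2, P(pm, pre + "sa_a_ln_g"), c.ln_sa_a,
                      G(gm, pre + "sa_a_ln_g"), G(gm, pre + "sa_a_ln_b"));
      }
    }

    // embeddings
    for (int t = 0; t < L; ++t) {
      G(gm, "tok_aa").row(aa(b, t) - 1) += dXa.row(t);
      G(gm, "pos").row(t) += dXa.row(t);
      if (!zeroed[b]) {
        G(gm, "tok_c").row(cd(b, t) - 1) += dXc.row(t);
        G(gm, "pos").row(t) += dXc.row(t);
      }
    }
  }

  double loss = 0.0;
  if (n_lab_c > 0) loss += loss_c / (double)n_lab_c;
  if (n_lab_a > 0) loss += loss_a / (double)n_lab_a;

  List out = List::create(
    _["loss"] = loss,
    _["n_labeled_codon"] = (double)n_lab_c,
    _["n_labeled_aa"] = (double)n_lab_a,
    _["n_correct_codon"] = (double)acc_c);
  if (want_grads) {
    List gl(params.size());
    CharacterVector gn(params.size());
    for (int i = 0; i < params.size(); ++i) {
      std::string n = std::string(pn[i]);
      gl[i] = wrap(gm[n]);
      gn[i] = n;
    }
    gl.names() = gn;
    out["grads"] = gl;
  }
  if (want_logits) {
    out["codon_logits"] = logits_c_out;
    out["aa_logits"] = logits_a_out;
  }
  return out;
}
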