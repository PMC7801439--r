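// Encoder-decoder transformer: batched forward, backprop and Adam training.
//
// The R level owns tokenization, batching and the weight layout; this file
// consumes a flat list of parameters in the fixed order produced by
// flatten_weights() (see R/train.R) and implements
//   - cpp_train:           the optimizer loop (teacher forcing, label
//                          smoothing, inverse-sqrt warmup schedule, Adam),
//                          running in single precision for speed
//   - cpp_loss/_grads:     double-precision loss/gradient evaluation
//                          (finite-difference tests)
//   - cpp_encode:          encoder forward for a single source sequence
//   - cpp_decode_logprobs: batched decoder forward returning log-probs of
//                          the last prefix position (beam search inner loop)
//
// Parameter layout, offsets into the flat vector (biases are 1-row mats):
//   0 src_emb (V x d)   1 tgt_emb (V x d)   2 out_W (d x V)   3 out_b (1 x V)
//   encoder layer l at 4 + 12*l:
//     Wq Wk Wv Wo | ln1.g ln1.b | W1 b1 W2 b2 | ln2.g ln2.b
//   decoder layer l at 4 + 12*L + 18*l:
//     self.Wq..Wo | ln1.g ln1.b | cross.Wq..Wo | ln2.g ln2.b |
//     W1 b1 W2 b2 | ln3.g ln3.b

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::uword;

namespace {

constexpr int PAD = 0;
constexpr double LN_EPS = 1e-6;

struct Cfg {
  int L, d, h, dff, V, dh;
  double dropout, pe_base, ls, warmup;
  bool pre_ln;  // normalize-then-sublayer composition with a final LN
};

Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.L = as<int>(cfg["n_layers"]);
  c.d = as<int>(cfg["d_model"]);
  c.h = as<int>(cfg["n_heads"]);
  c.dff = as<int>(cfg["d_ff"]);
  c.V = as<int>(cfg["vocab_size"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.pe_base = as<double>(cfg["pe_base"]);
  c.ls = as<double>(cfg["label_smoothing"]);
  c.warmup = as<double>(cfg["warmup_steps"]);
  c.pre_ln = as<std::string>(cfg["norm_position"]) == "pre";
  c.dh = c.d / c.h;
  return c;
}

inline int ENC(const Cfg& c, int l, int k) { return 4 + 12 * l + k; }
inline int DEC(const Cfg& c, int l, int k) { return 4 + 12 * c.L + 18 * l + k; }
// final layer-norm params (used in pre-LN mode): 0 enc.g 1 enc.b 2 dec.g 3 dec.b
inline int FLN(const Cfg& c, int k) { return 4 + 30 * c.L + k; }

template <class MT>
std::vector<MT> params_from_list(const List& p) {
  std::vector<MT> out;
  out.reserve(p.size());
  for (int i = 0; i < p.size(); ++i)
    out.push_back(arma::conv_to<MT>::from(as<arma::mat>(p[i])));
  return out;
}

template <class MT>
List params_to_list(const std::vector<MT>& p, const CharacterVector& names) {
  List out(p.size());
  for (size_t i = 0; i < p.size(); ++i)
    out[i] = wrap(arma::conv_to<arma::mat>::from(p[i]));
  out.attr("names") = names;
  return out;
}

template <class MT>
MT pe_table(int len, const Cfg& c) {
  MT pe(len, c.d);
  for (int pos = 0; pos < len; ++pos) {
    for (int i = 0; i < c.d / 2; ++i) {
      double angle = pos / std::pow(c.pe_base, 2.0 * i / c.d);
      pe(pos, 2 * i) = std::sin(angle);
      pe(pos, 2 * i + 1) = std::cos(angle);
    }
  }
  return pe;
}

// -- layer norm ---------------------------------------------------------------

template <class MT>
struct LNCache {
  MT xhat;
  arma::Col<typename MT::elem_type> istd;
};

template <class MT>
MT ln_fwd(const MT& x, const MT& g, const MT& b, LNCache<MT>& cc) {
  using eT = typename MT::elem_type;
  arma::Col<eT> mu = arma::mean(x, 1);
  MT cen = x.each_col() - mu;
  arma::Col<eT> var = arma::mean(arma::square(cen), 1);
  cc.istd = eT(1) / arma::sqrt(var + eT(LN_EPS));
  cc.xhat = cen.each_col() % cc.istd;
  MT y = cc.xhat.each_row() % g.row(0);
  y.each_row() += b.row(0);
  return y;
}

template <class MT>
MT ln_bwd(const MT& dy, const LNCache<MT>& cc, const MT& g, MT& dg, MT& db) {
  using eT = typename MT::elem_type;
  dg.row(0) += arma::sum(dy % cc.xhat, 0);
  db.row(0) += arma::sum(dy, 0);
  MT dxhat = dy.each_row() % g.row(0);
  arma::Col<eT> m1 = arma::mean(dxhat, 1);
  arma::Col<eT> m2 = arma::mean(dxhat % cc.xhat, 1);
  MT dx = dxhat;
  dx.each_col() -= m1;
  dx -= cc.xhat.each_col() % m2;
  dx.each_col() %= cc.istd;
  return dx;
}

// -- dropout ------------------------------------------------------------------

struct Rng {
  std::mt19937_64 gen;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  explicit Rng(uint64_t seed) : gen(seed) {}
};

template <class MT>
void dropout_fwd(MT& x, double p, Rng* rng, MT& mask) {
  using eT = typename MT::elem_type;
  if (p <= 0.0 || rng == nullptr) { mask.reset(); return; }
  mask.set_size(x.n_rows, x.n_cols);
  eT scale = eT(1.0 / (1.0 - p));
  for (uword i = 0; i < mask.n_elem; ++i)
    mask(i) = rng->unif(rng->gen) < p ? eT(0) : scale;
  x %= mask;
}

template <class MT>
inline void dropout_bwd(MT& dx, const MT& mask) {
  if (mask.n_elem > 0) dx %= mask;
}

// -- multi-head attention -----------------------------------------------------

template <class MT>
struct AttnCache {
  MT Qp, Kp, Vp;            // (B*Tq|Tk) x d projections
  std::vector<MT> A;        // per (b, head) attention weights, Tq x Tk
  MT H;                     // concatenated head outputs, B*Tq x d
};

// key_alive: per sequence, 0/1 over attendable key positions (empty = all).
template <class MT>
MT mha_fwd(const MT& Xq, const MT& Xkv, int B, int Tq, int Tk, const Cfg& c,
           const MT& Wq, const MT& Wk, const MT& Wv, const MT& Wo, bool causal,
           const std::vector<arma::Col<typename MT::elem_type>>& key_alive,
           AttnCache<MT>& cc) {
  using eT = typename MT::elem_type;
  cc.Qp = Xq * Wq;
  cc.Kp = Xkv * Wk;
  cc.Vp = Xkv * Wv;
  cc.A.assign(static_cast<size_t>(B) * c.h, MT());
  cc.H.set_size(Xq.n_rows, c.d);
  eT scale = eT(1.0 / std::sqrt(static_cast<double>(c.dh)));
  for (int b = 0; b < B; ++b) {
    uword q0 = static_cast<uword>(b) * Tq, k0 = static_cast<uword>(b) * Tk;
    for (int hh = 0; hh < c.h; ++hh) {
      uword c0 = static_cast<uword>(hh) * c.dh;
      MT S = cc.Qp.submat(q0, c0, q0 + Tq - 1, c0 + c.dh - 1) *
             cc.Kp.submat(k0, c0, k0 + Tk - 1, c0 + c.dh - 1).t() * scale;
      if (!key_alive.empty()) {
        const auto& alive = key_alive[b];
        for (int j = 0; j < Tk; ++j)
          if (alive(j) == eT(0)) S.col(j).fill(eT(-1e30));
      }
      if (causal) {
        for (int i = 0; i < Tq; ++i)
          for (int j = i + 1; j < Tk; ++j) S(i, j) = eT(-1e30);
      }
      for (int i = 0; i < Tq; ++i) {  // row-wise softmax in place
        eT mx = S.row(i).max();
        S.row(i) = arma::exp(S.row(i) - mx);
        S.row(i) /= arma::accu(S.row(i));
      }
      cc.H.submat(q0, c0, q0 + Tq - 1, c0 + c.dh - 1) =
          S * cc.Vp.submat(k0, c0, k0 + Tk - 1, c0 + c.dh - 1);
      cc.A[static_cast<size_t>(b) * c.h + hh] = std::move(S);
    }
  }
  return cc.H * Wo;
}

template <class MT>
void mha_bwd(const MT& dout, const MT& Xq, const MT& Xkv, int B, int Tq,
             int Tk, const Cfg& c, const MT& Wq, const MT& Wk, const MT& Wv,
             const MT& Wo, const AttnCache<MT>& cc, MT& dXq, MT& dXkv,
             MT& dWq, MT& dWk, MT& dWv, MT& dWo) {
  using eT = typename MT::elem_type;
  dWo += cc.H.t() * dout;
  MT dH = dout * Wo.t();
  MT dQp(arma::size(cc.Qp), arma::fill::zeros);
  MT dKp(arma::size(cc.Kp), arma::fill::zeros);
  MT dVp(arma::size(cc.Vp), arma::fill::zeros);
  eT scale = eT(1.0 / std::sqrt(static_cast<double>(c.dh)));
  for (int b = 0; b < B; ++b) {
    uword q0 = static_cast<uword>(b) * Tq, k0 = static_cast<uword>(b) * Tk;
    for (int hh = 0; hh < c.h; ++hh) {
      uword c0 = static_cast<uword>(hh) * c.dh;
      const MT& A = cc.A[static_cast<size_t>(b) * c.h + hh];
      MT dO = dH.submat(q0, c0, q0 + Tq - 1, c0 + c.dh - 1);
      MT dA = dO * cc.Vp.submat(k0, c0, k0 + Tk - 1, c0 + c.dh - 1).t();
      MT dS = A % (dA.each_col() - arma::sum(dA % A, 1));
      dQp.submat(q0, c0, q0 + Tq - 1, c0 + c.dh - 1) =
          dS * cc.Kp.submat(k0, c0, k0 + Tk - 1, c0 + c.dh - 1) * scale;
      dKp.submat(k0, c0, k0 + Tk - 1, c0 + c.dh - 1) =
          dS.t() * cc.Qp.submat(q0, c0, q0 + Tq - 1, c0 + c.dh - 1) * scale;
      dVp.submat(k0, c0, k0 + Tk - 1, c0 + c.dh - 1) = A.t() * dO;
    }
  }
  dWq += Xq.t() * dQp;
  dWk += Xkv.t() * dKp;
  dWv += Xkv.t() * dVp;
  dXq += dQp * Wq.t();
  dXkv += dKp * Wk.t() + dVp * Wv.t();
}

// -- feed-forward -------------------------------------------------------------

template <class MT>
struct FFNCache { MT in, hid; };

template <class MT>
MT ffn_fwd(const MT& x, const MT& W1, const MT& b1, const MT& W2, const MT& b2,
           FFNCache<MT>& cc) {
  using eT = typename MT::elem_type;
  cc.in = x;
  cc.hid = x * W1;
  cc.hid.each_row() += b1.row(0);
  cc.hid.transform([](eT v) { return v > eT(0) ? v : eT(0); });
  MT out = cc.hid * W2;
  out.each_row() += b2.row(0);
  return out;
}

template <class MT>
MT ffn_bwd(const MT& dy, const MT& W1, const MT& W2, const FFNCache<MT>& cc,
           MT& dW1, MT& db1, MT& dW2, MT& db2) {
  using eT = typename MT::elem_type;
  dW2 += cc.hid.t() * dy;
  db2.row(0) += arma::sum(dy, 0);
  MT dhid = dy * W2.t();
  dhid.elem(arma::find(cc.hid == eT(0))).zeros();
  dW1 += cc.in.t() * dhid;
  db1.row(0) += arma::sum(dhid, 0);
  return dhid * W1.t();
}

// -- full forward/backward over one batch ------------------------------------

struct Batch {
  arma::imat src, tgt_in, tgt_out;  // B x Ls, B x Lt, B x Lt (PAD-filled)
};

template <class MT>
struct Caches {
  MT X0drop;
  std::vector<AttnCache<MT>> enc_attn;
  std::vector<FFNCache<MT>> enc_ffn;
  std::vector<LNCache<MT>> enc_ln1, enc_ln2;
  std::vector<MT> enc_in, enc_mid, enc_drop1, enc_drop2;
  MT memory;
  MT Y0drop;
  std::vector<AttnCache<MT>> dec_self, dec_cross;
  std::vector<FFNCache<MT>> dec_ffn;
  std::vector<LNCache<MT>> dec_ln1, dec_ln2, dec_ln3;
  std::vector<MT> dec_in, dec_mid1, dec_mid2;
  std::vector<MT> dec_drop1, dec_drop2, dec_drop3;
  LNCache<MT> enc_lnf, dec_lnf;
  MT Yfin;
};

template <class MT>
MT embed(const arma::imat& ids, const MT& emb, const MT& pe, int d) {
  using eT = typename MT::elem_type;
  int B = ids.n_rows, T = ids.n_cols;
  MT X(static_cast<uword>(B) * T, d);
  eT s = eT(std::sqrt(static_cast<double>(d)));
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t)
      X.row(static_cast<uword>(b) * T + t) = emb.row(ids(b, t)) * s + pe.row(t);
  return X;
}

template <class MT>
std::vector<arma::Col<typename MT::elem_type>> alive_from_ids(
    const arma::imat& ids) {
  using eT = typename MT::elem_type;
  std::vector<arma::Col<eT>> out(ids.n_rows);
  for (uword b = 0; b < ids.n_rows; ++b) {
    arma::Col<eT> a(ids.n_cols);
    for (uword t = 0; t < ids.n_cols; ++t)
      a(t) = ids(b, t) == PAD ? eT(0) : eT(1);
    out[b] = a;
  }
  return out;
}

// Forward pass; fills caches; returns mean label-smoothed cross entropy over
// non-PAD target positions and (optionally) its gradient w.r.t. the logits.
template <class MT>
double forward(const std::vector<MT>& P, const Cfg& c, const Batch& bt,
               Rng* rng, Caches<MT>& cs, MT& dlogits, bool want_grad) {
  using eT = typename MT::elem_type;
  int B = bt.src.n_rows, Ls = bt.src.n_cols, Lt = bt.tgt_in.n_cols;
  MT pe = pe_table<MT>(std::max(Ls, Lt), c);
  auto src_alive = alive_from_ids<MT>(bt.src);

  // encoder
  MT X = embed(bt.src, P[0], pe, c.d);
  dropout_fwd(X, c.dropout, rng, cs.X0drop);
  cs.enc_attn.resize(c.L); cs.enc_ffn.resize(c.L);
  cs.enc_ln1.resize(c.L); cs.enc_ln2.resize(c.L);
  cs.enc_in.resize(c.L); cs.enc_mid.resize(c.L);
  cs.enc_drop1.resize(c.L); cs.enc_drop2.resize(c.L);
  for (int l = 0; l < c.L; ++l) {
    if (c.pre_ln) {
      // x += Attn(LN(x)); x += FFN(LN(x)); enc_in/enc_mid hold the LN outputs
      cs.enc_in[l] = ln_fwd(X, P[ENC(c, l, 4)], P[ENC(c, l, 5)],
                            cs.enc_ln1[l]);
      MT a = mha_fwd(cs.enc_in[l], cs.enc_in[l], B, Ls, Ls, c,
                     P[ENC(c, l, 0)], P[ENC(c, l, 1)], P[ENC(c, l, 2)],
                     P[ENC(c, l, 3)], false, src_alive, cs.enc_attn[l]);
      dropout_fwd(a, c.dropout, rng, cs.enc_drop1[l]);
      X += a;
      cs.enc_mid[l] = ln_fwd(X, P[ENC(c, l, 10)], P[ENC(c, l, 11)],
                             cs.enc_ln2[l]);
      MT f = ffn_fwd(cs.enc_mid[l], P[ENC(c, l, 6)], P[ENC(c, l, 7)],
                     P[ENC(c, l, 8)], P[ENC(c, l, 9)], cs.enc_ffn[l]);
      dropout_fwd(f, c.dropout, rng, cs.enc_drop2[l]);
      X += f;
    } else {
      cs.enc_in[l] = X;
      MT a = mha_fwd(X, X, B, Ls, Ls, c, P[ENC(c, l, 0)], P[ENC(c, l, 1)],
                     P[ENC(c, l, 2)], P[ENC(c, l, 3)], false, src_alive,
                     cs.enc_attn[l]);
      dropout_fwd(a, c.dropout, rng, cs.enc_drop1[l]);
      MT X2 = ln_fwd(MT(X + a), P[ENC(c, l, 4)], P[ENC(c, l, 5)],
                     cs.enc_ln1[l]);
      cs.enc_mid[l] = X2;
      MT f = ffn_fwd(X2, P[ENC(c, l, 6)], P[ENC(c, l, 7)], P[ENC(c, l, 8)],
                     P[ENC(c, l, 9)], cs.enc_ffn[l]);
      dropout_fwd(f, c.dropout, rng, cs.enc_drop2[l]);
      X = ln_fwd(MT(X2 + f), P[ENC(c, l, 10)], P[ENC(c, l, 11)],
                 cs.enc_ln2[l]);
    }
  }
  cs.memory = c.pre_ln ? ln_fwd(X, P[FLN(c, 0)], P[FLN(c, 1)], cs.enc_lnf)
                       : X;

  // decoder
  MT Y = embed(bt.tgt_in, P[1], pe, c.d);
  dropout_fwd(Y, c.dropout, rng, cs.Y0drop);
  cs.dec_self.resize(c.L); cs.dec_cross.resize(c.L); cs.dec_ffn.resize(c.L);
  cs.dec_ln1.resize(c.L); cs.dec_ln2.resize(c.L); cs.dec_ln3.resize(c.L);
  cs.dec_in.resize(c.L); cs.dec_mid1.resize(c.L); cs.dec_mid2.resize(c.L);
  cs.dec_drop1.resize(c.L); cs.dec_drop2.resize(c.L); cs.dec_drop3.resize(c.L);
  std::vector<arma::Col<eT>> none;
  for (int l = 0; l < c.L; ++l) {
    if (c.pre_ln) {
      cs.dec_in[l] = ln_fwd(Y, P[DEC(c, l, 4)], P[DEC(c, l, 5)],
                            cs.dec_ln1[l]);
      MT a = mha_fwd(cs.dec_in[l], cs.dec_in[l], B, Lt, Lt, c,
                     P[DEC(c, l, 0)], P[DEC(c, l, 1)], P[DEC(c, l, 2)],
                     P[DEC(c, l, 3)], true, none, cs.dec_self[l]);
      dropout_fwd(a, c.dropout, rng, cs.dec_drop1[l]);
      Y += a;
      cs.dec_mid1[l] = ln_fwd(Y, P[DEC(c, l, 10)], P[DEC(c, l, 11)],
                              cs.dec_ln2[l]);
      MT cr = mha_fwd(cs.dec_mid1[l], cs.memory, B, Lt, Ls, c,
                      P[DEC(c, l, 6)], P[DEC(c, l, 7)], P[DEC(c, l, 8)],
                      P[DEC(c, l, 9)], false, src_alive, cs.dec_cross[l]);
      dropout_fwd(cr, c.dropout, rng, cs.dec_drop2[l]);
      Y += cr;
      cs.dec_mid2[l] = ln_fwd(Y, P[DEC(c, l, 16)], P[DEC(c, l, 17)],
                              cs.dec_ln3[l]);
      MT f = ffn_fwd(cs.dec_mid2[l], P[DEC(c, l, 12)], P[DEC(c, l, 13)],
                     P[DEC(c, l, 14)], P[DEC(c, l, 15)], cs.dec_ffn[l]);
      dropout_fwd(f, c.dropout, rng, cs.dec_drop3[l]);
      Y += f;
    } else {
      cs.dec_in[l] = Y;
      MT a = mha_fwd(Y, Y, B, Lt, Lt, c, P[DEC(c, l, 0)], P[DEC(c, l, 1)],
                     P[DEC(c, l, 2)], P[DEC(c, l, 3)], true, none,
                     cs.dec_self[l]);
      dropout_fwd(a, c.dropout, rng, cs.dec_drop1[l]);
      MT Y1 = ln_fwd(MT(Y + a), P[DEC(c, l, 4)], P[DEC(c, l, 5)],
                     cs.dec_ln1[l]);
      cs.dec_mid1[l] = Y1;
      MT cr = mha_fwd(Y1, cs.memory, B, Lt, Ls, c, P[DEC(c, l, 6)],
                      P[DEC(c, l, 7)], P[DEC(c, l, 8)], P[DEC(c, l, 9)],
                      false, src_alive, cs.dec_cross[l]);
      dropout_fwd(cr, c.dropout, rng, cs.dec_drop2[l]);
      MT Y2 = ln_fwd(MT(Y1 + cr), P[DEC(c, l, 10)], P[DEC(c, l, 11)],
                     cs.dec_ln2[l]);
      cs.dec_mid2[l] = Y2;
      MT f = ffn_fwd(Y2, P[DEC(c, l, 12)], P[DEC(c, l, 13)], P[DEC(c, l, 14)],
                     P[DEC(c, l, 15)], cs.dec_ffn[l]);
      dropout_fwd(f, c.dropout, rng, cs.dec_drop3[l]);
      Y = ln_fwd(MT(Y2 + f), P[DEC(c, l, 16)], P[DEC(c, l, 17)],
                 cs.dec_ln3[l]);
    }
  }
  cs.Yfin = c.pre_ln ? ln_fwd(Y, P[FLN(c, 2)], P[FLN(c, 3)], cs.dec_lnf) : Y;

  MT logits = cs.Yfin * P[2];
  logits.each_row() += P[3].row(0);
  int ntok = 0;
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Lt; ++t)
      if (bt.tgt_out(b, t) != PAD) ++ntok;
  if (ntok == 0) stop("training batch contains no target tokens");
  double loss = 0.0;
  double off = c.ls / (c.V - 1), on = 1.0 - c.ls;
  if (want_grad) dlogits.zeros(logits.n_rows, logits.n_cols);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < Lt; ++t) {
      if (bt.tgt_out(b, t) == PAD) continue;
      uword r = static_cast<uword>(b) * Lt + t;
      arma::Row<eT> lg = logits.row(r);
      eT mx = lg.max();
      arma::Row<eT> e = arma::exp(lg - mx);
      double Z = arma::accu(e);
      arma::Row<eT> logp = lg - mx - eT(std::log(Z));
      int y = bt.tgt_out(b, t);
      loss += -(on * logp(y) + off * (arma::accu(logp) - logp(y)));
      if (want_grad) {
        arma::Row<eT> p = e / eT(Z);
        p -= eT(off);
        p(y) -= eT(on - off);
        dlogits.row(r) = p / eT(ntok);
      }
    }
  }
  return loss / ntok;
}

template <class MT>
void backward(const std::vector<MT>& P, const Cfg& c, const Batch& bt,
              const Caches<MT>& cs, const MT& dlogits, std::vector<MT>& G) {
  using eT = typename MT::elem_type;
  int B = bt.src.n_rows, Ls = bt.src.n_cols, Lt = bt.tgt_in.n_cols;

  G[2] += cs.Yfin.t() * dlogits;
  G[3].row(0) += arma::sum(dlogits, 0);
  MT dY = dlogits * P[2].t();
  MT dMem(arma::size(cs.memory), arma::fill::zeros);
  if (c.pre_ln) dY = ln_bwd(dY, cs.dec_lnf, P[FLN(c, 2)], G[FLN(c, 2)],
                            G[FLN(c, 3)]);

  for (int l = c.L - 1; l >= 0; --l) {
    if (c.pre_ln) {
      MT df = dY;
      dropout_bwd(df, cs.dec_drop3[l]);
      MT dyn3 = ffn_bwd(df, P[DEC(c, l, 12)], P[DEC(c, l, 14)],
                        cs.dec_ffn[l], G[DEC(c, l, 12)], G[DEC(c, l, 13)],
                        G[DEC(c, l, 14)], G[DEC(c, l, 15)]);
      dY += ln_bwd(dyn3, cs.dec_ln3[l], P[DEC(c, l, 16)], G[DEC(c, l, 16)],
                   G[DEC(c, l, 17)]);
      MT dcr = dY;
      dropout_bwd(dcr, cs.dec_drop2[l]);
      MT dyn2(arma::size(dY), arma::fill::zeros);
      mha_bwd(dcr, cs.dec_mid1[l], cs.memory, B, Lt, Ls, c, P[DEC(c, l, 6)],
              P[DEC(c, l, 7)], P[DEC(c, l, 8)], P[DEC(c, l, 9)],
              cs.dec_cross[l], dyn2, dMem, G[DEC(c, l, 6)], G[DEC(c, l, 7)],
              G[DEC(c, l, 8)], G[DEC(c, l, 9)]);
      dY += ln_bwd(dyn2, cs.dec_ln2[l], P[DEC(c, l, 10)], G[DEC(c, l, 10)],
                   G[DEC(c, l, 11)]);
      MT da = dY;
      dropout_bwd(da, cs.dec_drop1[l]);
      MT dyn1(arma::size(dY), arma::fill::zeros);
      mha_bwd(da, cs.dec_in[l], cs.dec_in[l], B, Lt, Lt, c, P[DEC(c, l, 0)],
              P[DEC(c, l, 1)], P[DEC(c, l, 2)], P[DEC(c, l, 3)],
              cs.dec_self[l], dyn1, dyn1, G[DEC(c, l, 0)], G[DEC(c, l, 1)],
              G[DEC(c, l, 2)], G[DEC(c, l, 3)]);
      dY += ln_bwd(dyn1, cs.dec_ln1[l], P[DEC(c, l, 4)], G[DEC(c, l, 4)],
                   G[DEC(c, l, 5)]);
    } else {
      MT dY2pf = ln_bwd(dY, cs.dec_ln3[l], P[DEC(c, l, 16)], G[DEC(c, l, 16)],
                        G[DEC(c, l, 17)]);
      MT df = dY2pf;
      dropout_bwd(df, cs.dec_drop3[l]);
      MT dY2 = dY2pf + ffn_bwd(df, P[DEC(c, l, 12)], P[DEC(c, l, 14)],
                               cs.dec_ffn[l], G[DEC(c, l, 12)],
                               G[DEC(c, l, 13)], G[DEC(c, l, 14)],
                               G[DEC(c, l, 15)]);
      MT dY1pc = ln_bwd(dY2, cs.dec_ln2[l], P[DEC(c, l, 10)], G[DEC(c, l, 10)],
                        G[DEC(c, l, 11)]);
      MT dcr = dY1pc;
      dropout_bwd(dcr, cs.dec_drop2[l]);
      MT dY1 = dY1pc;
      mha_bwd(dcr, cs.dec_mid1[l], cs.memory, B, Lt, Ls, c, P[DEC(c, l, 6)],
              P[DEC(c, l, 7)], P[DEC(c, l, 8)], P[DEC(c, l, 9)],
              cs.dec_cross[l], dY1, dMem, G[DEC(c, l, 6)], G[DEC(c, l, 7)],
              G[DEC(c, l, 8)], G[DEC(c, l, 9)]);
      MT dYpa = ln_bwd(dY1, cs.dec_ln1[l], P[DEC(c, l, 4)], G[DEC(c, l, 4)],
                       G[DEC(c, l, 5)]);
      MT da = dYpa;
      dropout_bwd(da, cs.dec_drop1[l]);
      dY = dYpa;
      mha_bwd(da, cs.dec_in[l], cs.dec_in[l], B, Lt, Lt, c, P[DEC(c, l, 0)],
              P[DEC(c, l, 1)], P[DEC(c, l, 2)], P[DEC(c, l, 3)],
              cs.dec_self[l], dY, dY, G[DEC(c, l, 0)], G[DEC(c, l, 1)],
              G[DEC(c, l, 2)], G[DEC(c, l, 3)]);
    }
  }
  dropout_bwd(dY, cs.Y0drop);
  eT s = eT(std::sqrt(static_cast<double>(c.d)));
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Lt; ++t)
      G[1].row(bt.tgt_in(b, t)) += dY.row(static_cast<uword>(b) * Lt + t) * s;

  MT dX = dMem;
  if (c.pre_ln) dX = ln_bwd(dX, cs.enc_lnf, P[FLN(c, 0)], G[FLN(c, 0)],
                            G[FLN(c, 1)]);
  for (int l = c.L - 1; l >= 0; --l) {
    if (c.pre_ln) {
      MT df = dX;
      dropout_bwd(df, cs.enc_drop2[l]);
      MT dxn2 = ffn_bwd(df, P[ENC(c, l, 6)], P[ENC(c, l, 8)],
                        cs.enc_ffn[l], G[ENC(c, l, 6)], G[ENC(c, l, 7)],
                        G[ENC(c, l, 8)], G[ENC(c, l, 9)]);
      dX += ln_bwd(dxn2, cs.enc_ln2[l], P[ENC(c, l, 10)], G[ENC(c, l, 10)],
                   G[ENC(c, l, 11)]);
      MT da = dX;
      dropout_bwd(da, cs.enc_drop1[l]);
      MT dxn1(arma::size(dX), arma::fill::zeros);
      mha_bwd(da, cs.enc_in[l], cs.enc_in[l], B, Ls, Ls, c, P[ENC(c, l, 0)],
              P[ENC(c, l, 1)], P[ENC(c, l, 2)], P[ENC(c, l, 3)],
              cs.enc_attn[l], dxn1, dxn1, G[ENC(c, l, 0)], G[ENC(c, l, 1)],
              G[ENC(c, l, 2)], G[ENC(c, l, 3)]);
      dX += ln_bwd(dxn1, cs.enc_ln1[l], P[ENC(c, l, 4)], G[ENC(c, l, 4)],
                   G[ENC(c, l, 5)]);
    } else {
      MT dX2pf = ln_bwd(dX, cs.enc_ln2[l], P[ENC(c, l, 10)], G[ENC(c, l, 10)],
                        G[ENC(c, l, 11)]);
      MT df = dX2pf;
      dropout_bwd(df, cs.enc_drop2[l]);
      MT dX2 = dX2pf + ffn_bwd(df, P[ENC(c, l, 6)], P[ENC(c, l, 8)],
                               cs.enc_ffn[l], G[ENC(c, l, 6)], G[ENC(c, l, 7)],
                               G[ENC(c, l, 8)], G[ENC(c, l, 9)]);
      MT dXpa = ln_bwd(dX2, cs.enc_ln1[l], P[ENC(c, l, 4)], G[ENC(c, l, 4)],
                       G[ENC(c, l, 5)]);
      MT da = dXpa;
      dropout_bwd(da, cs.enc_drop1[l]);
      dX = dXpa;
      mha_bwd(da, cs.enc_in[l], cs.enc_in[l], B, Ls, Ls, c, P[ENC(c, l, 0)],
              P[ENC(c, l, 1)], P[ENC(c, l, 2)], P[ENC(c, l, 3)],
              cs.enc_attn[l], dX, dX, G[ENC(c, l, 0)], G[ENC(c, l, 1)],
              G[ENC(c, l, 2)], G[ENC(c, l, 3)]);
    }
  }
  dropout_bwd(dX, cs.X0drop);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Ls; ++t)
      G[0].row(bt.src(b, t)) += dX.row(static_cast<uword>(b) * Ls + t) * s;
}

Batch batch_from_list(const List& b) {
  Batch bt;
  bt.src = as<arma::imat>(b["src"]);
  bt.tgt_in = as<arma::imat>(b["tgt_in"]);
  bt.tgt_out = as<arma::imat>(b["tgt_out"]);
  return bt;
}

}  // namespace

template <class MT>
List train_impl(List params, List cfg, List batches, IntegerVector schedule,
                int step_start, Nullable<List> adam_m, Nullable<List> adam_v,
                int seed, int log_every) {
  Cfg c = read_cfg(cfg);
  std::vector<MT> P = params_from_list<MT>(params);
  CharacterVector pnames = params.attr("names");
  std::vector<MT> M, Vv;
  if (adam_m.isNotNull()) {
    M = params_from_list<MT>(adam_m.get());
    Vv = params_from_list<MT>(adam_v.get());
  } else {
    for (auto& p : P) M.emplace_back(arma::size(p), arma::fill::zeros);
    for (auto& p : P) Vv.emplace_back(arma::size(p), arma::fill::zeros);
  }
  std::vector<Batch> bts;
  bts.reserve(batches.size());
  for (int i = 0; i < batches.size(); ++i)
    bts.push_back(batch_from_list(batches[i]));

  using eT = typename MT::elem_type;
  const eT b1 = eT(0.9), b2 = eT(0.98), adam_eps = eT(1e-9);
  int n_steps = schedule.size();
  std::vector<double> log_step, log_lr, log_loss;
  std::vector<MT> G;
  for (auto& p : P) G.emplace_back(arma::size(p), arma::fill::zeros);
  Caches<MT> cs;
  MT dlogits;

  for (int k = 0; k < n_steps; ++k) {
    int step = step_start + k;
    const Batch& bt = bts[schedule[k] - 1];
    Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL +
            static_cast<uint64_t>(step));
    Rng* rp = c.dropout > 0.0 ? &rng : nullptr;
    double loss = forward(P, c, bt, rp, cs, dlogits, true);
    if (!std::isfinite(loss)) stop("NaN/Inf training loss at step %d", step);
    for (auto& g : G) g.zeros();
    backward(P, c, bt, cs, dlogits, G);

    double lr = std::pow(static_cast<double>(c.d), -0.5) *
                std::min(std::pow(static_cast<double>(step), -0.5),
                         step * std::pow(c.warmup, -1.5));
    eT bc1 = eT(1) - std::pow(b1, eT(step));
    eT bc2 = eT(1) - std::pow(b2, eT(step));
    eT lrf = eT(lr);
    for (size_t i = 0; i < P.size(); ++i) {
      M[i] = b1 * M[i] + (eT(1) - b1) * G[i];
      Vv[i] = b2 * Vv[i] + (eT(1) - b2) * arma::square(G[i]);
      P[i] -= lrf * (M[i] / bc1) / (arma::sqrt(Vv[i] / bc2) + adam_eps);
    }
    if (log_every > 0 && (step % log_every == 0 || k == 0 || k == n_steps - 1)) {
      log_step.push_back(step);
      log_lr.push_back(lr);
      log_loss.push_back(loss);
    }
    if (k % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["params"] = params_to_list(P, pnames),
      _["m"] = params_to_list(M, pnames),
      _["v"] = params_to_list(Vv, pnames),
      _["log"] = DataFrame::create(_["step"] = log_step, _["lr"] = log_lr,
                                   _["loss"] = log_loss));
}

// [[Rcpp::export]]
List cpp_train(List params, List cfg, List batches, IntegerVector schedule,
               int step_start, Nullable<List> adam_m, Nullable<List> adam_v,
               int seed, int log_every, bool single_precision) {
  if (single_precision) {
    return train_impl<arma::fmat>(params, cfg, batches, schedule, step_start,
                                  adam_m, adam_v, seed, log_every);
  }
  return train_impl<arma::mat>(params, cfg, batches, schedule, step_start,
                               adam_m, adam_v, seed, log_every);
}

// [[Rcpp::export]]
List cpp_loss_grads(List params, List cfg, List batch) {
  using MT = arma::mat;
  Cfg c = read_cfg(cfg);
  std::vector<MT> P = params_from_list<MT>(params);
  CharacterVector pnames = params.attr("names");
  Batch bt = batch_from_list(batch);
  Caches<MT> cs;
  MT dlogits;
  double loss = forward(P, c, bt, nullptr, cs, dlogits, true);
  std::vector<MT> G;
  for (auto& p : P) G.emplace_back(arma::size(p), arma::fill::zeros);
  backward(P, c, bt, cs, dlogits, G);
  return List::create(_["loss"] = loss, _["grads"] = params_to_list(G, pnames));
}

// [[Rcpp::export]]
double cpp_loss(List params, List cfg, List batch) {
  using MT = arma::mat;
  Cfg c = read_cfg(cfg);
  std::vector<MT> P = params_from_list<MT>(params);
  Batch bt = batch_from_list(batch);
  Caches<MT> cs;
  MT dlogits;
  return forward(P, c, bt, nullptr, cs, dlogits, false);
}

// [[Rcpp::export]]
arma::mat cpp_encode(List params, List cfg, IntegerVector src) {
  using MT = arma::mat;
  Cfg c = read_cfg(cfg);
  std::vector<MT> P = params_from_list<MT>(params);
  Batch bt;
  bt.src = arma::imat(1, src.size());
  for (int t = 0; t < src.size(); ++t) bt.src(0, t) = src[t];
  bt.tgt_in = arma::imat(1, 1, arma::fill::ones);   // dummy BOS
  bt.tgt_out = arma::imat(1, 1, arma::fill::ones);  // dummy (non-PAD)
  Caches<MT> cs;
  MT dlogits;
  forward(P, c, bt, nullptr, cs, dlogits, false);
  return cs.memory;
}

// Decoder-only forward over a batch of equal-length prefixes sharing one
// encoder memory; returns log-probabilities at the final position.
// [[Rcpp::export]]
arma::mat cpp_decode_logprobs(List params, List cfg, arma::mat memory,
                              IntegerMatrix prefixes, IntegerVector src_ids) {
  using MT = arma::mat;
  Cfg c = read_cfg(cfg);
  std::vector<MT> P = params_from_list<MT>(params);
  int B = prefixes.nrow(), Lt = prefixes.ncol(), Ls = memory.n_rows;
  MT pe = pe_table<MT>(std::max(Ls, Lt), c);
  std::vector<arma::Col<double>> src_alive(B);
  arma::Col<double> alive(Ls);
  for (int t = 0; t < Ls; ++t) alive(t) = src_ids[t] == PAD ? 0.0 : 1.0;
  for (int b = 0; b < B; ++b) src_alive[b] = alive;

  arma::imat tgt(B, Lt);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Lt; ++t) tgt(b, t) = prefixes(b, t);
  MT Y = embed(tgt, P[1], pe, c.d);
  // replicate memory per sequence for the batched cross-attention layout
  MT Mem(static_cast<uword>(B) * Ls, c.d);
  for (int b = 0; b < B; ++b)
    Mem.rows(static_cast<uword>(b) * Ls, static_cast<uword>(b) * Ls + Ls - 1) =
        memory;
  std::vector<arma::Col<double>> none;
  for (int l = 0; l < c.L; ++l) {
    AttnCache<MT> a1, a2;
    LNCache<MT> n1, n2, n3;
    FFNCache<MT> ff;
    if (c.pre_ln) {
      MT Yn = ln_fwd(Y, P[DEC(c, l, 4)], P[DEC(c, l, 5)], n1);
      Y += mha_fwd(Yn, Yn, B, Lt, Lt, c, P[DEC(c, l, 0)], P[DEC(c, l, 1)],
                   P[DEC(c, l, 2)], P[DEC(c, l, 3)], true, none, a1);
      Yn = ln_fwd(Y, P[DEC(c, l, 10)], P[DEC(c, l, 11)], n2);
      Y += mha_fwd(Yn, Mem, B, Lt, Ls, c, P[DEC(c, l, 6)], P[DEC(c, l, 7)],
                   P[DEC(c, l, 8)], P[DEC(c, l, 9)], false, src_alive, a2);
      Yn = ln_fwd(Y, P[DEC(c, l, 16)], P[DEC(c, l, 17)], n3);
      Y += ffn_fwd(Yn, P[DEC(c, l, 12)], P[DEC(c, l, 13)], P[DEC(c, l, 14)],
                   P[DEC(c, l, 15)], ff);
    } else {
      MT a = mha_fwd(Y, Y, B, Lt, Lt, c, P[DEC(c, l, 0)], P[DEC(c, l, 1)],
                     P[DEC(c, l, 2)], P[DEC(c, l, 3)], true, none, a1);
      MT Y1 = ln_fwd(MT(Y + a), P[DEC(c, l, 4)], P[DEC(c, l, 5)], n1);
      MT cr = mha_fwd(Y1, Mem, B, Lt, Ls, c, P[DEC(c, l, 6)], P[DEC(c, l, 7)],
                      P[DEC(c, l, 8)], P[DEC(c, l, 9)], false, src_alive, a2);
      MT Y2 = ln_fwd(MT(Y1 + cr), P[DEC(c, l, 10)], P[DEC(c, l, 11)], n2);
      MT f = ffn_fwd(Y2, P[DEC(c, l, 12)], P[DEC(c, l, 13)], P[DEC(c, l, 14)],
                     P[DEC(c, l, 15)], ff);
      Y = ln_fwd(MT(Y2 + f), P[DEC(c, l, 16)], P[DEC(c, l, 17)], n3);
    }
  }
  if (c.pre_ln) {
    LNCache<MT> nf;
    Y = ln_fwd(Y, P[FLN(c, 2)], P[FLN(c, 3)], nf);
  }
  MT out(B, c.V);
  for (int b = 0; b < B; ++b) {
    arma::rowvec lg =
        Y.row(static_cast<uword>(b) * Lt + (Lt - 1)) * P[2] + P[3].row(0);
    double mx = lg.max();
    arma::rowvec e = arma::exp(lg - mx);
    out.row(b) = lg - mx - std::log(arma::accu(e));
  }
  return out;
}
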