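// Recurrent cell kernels on the stacked sequence representation.
//
// A sequence batch is a (Tn*B) x d matrix whose t-th row block is the
// batch at timestep t. Cells run in forward or reversed time order;
// caches stay on the C++ side (external pointers) so nothing large
// crosses the R boundary between the forward and backward passes. The
// pure-R cell implementations remain the reference oracle in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::span;
using arma::uword;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct LstmCache {
  mat Xstack, Hstack, Cstack, G;  // G = [i | f | g | o]
  int Tn, B;
  bool reverse;
};

struct GruCache {
  mat Xstack, Hstack, G, RH;      // G = [z | r | hbar]
  int Tn, B;
  bool reverse;
};

// no-copy views over R matrices
static inline mat view(const NumericMatrix& m) {
  return mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(), false, true);
}

static inline mat view_vec(const NumericVector& v) {
  return mat(const_cast<double*>(v.begin()), v.size(), 1, false, true);
}

// [[Rcpp::export]]
List lstm_forward_cpp(const NumericMatrix& Wx_, const NumericMatrix& Wh_,
                      const NumericVector& b_, const NumericMatrix& Xstack_,
                      int Tn, int B, bool reverse, bool keep_cache) {
  const mat Wx = view(Wx_), Wh = view(Wh_);
  const mat bcol = view_vec(b_);
  const uword h = Wh.n_rows;
  LstmCache* ca = new LstmCache();
  ca->Tn = Tn; ca->B = B; ca->reverse = reverse;
  ca->Xstack = view(Xstack_);  // copy; needed for dWx in backward
  mat XW = ca->Xstack * Wx;
  XW.each_row() += bcol.t();
  mat H(B, h, arma::fill::zeros), C(B, h, arma::fill::zeros);
  ca->Hstack.set_size(Tn * B, h);
  ca->Cstack.set_size(Tn * B, h);
  ca->G.set_size(Tn * B, 4 * h);
  for (int t = 0; t < Tn; ++t) {
    int src = reverse ? (Tn - 1 - t) : t;
    span rows(t * B, (t + 1) * B - 1);
    mat Z = XW.rows(span(src * B, (src + 1) * B - 1)) + H * Wh;
    mat i = sigm(Z.cols(0, h - 1));
    mat f = sigm(Z.cols(h, 2 * h - 1));
    mat g = arma::tanh(Z.cols(2 * h, 3 * h - 1));
    mat o = sigm(Z.cols(3 * h, 4 * h - 1));
    C = f % C + i % g;
    H = o % arma::tanh(C);
    ca->G(rows, span(0, h - 1)) = i;
    ca->G(rows, span(h, 2 * h - 1)) = f;
    ca->G(rows, span(2 * h, 3 * h - 1)) = g;
    ca->G(rows, span(3 * h, 4 * h - 1)) = o;
    ca->Hstack.rows(rows) = H;
    ca->Cstack.rows(rows) = C;
  }
  List out = List::create(_["Hstack"] = wrap(ca->Hstack),
                          _["final"] = wrap(H));
  if (keep_cache) {
    out["cache"] = XPtr<LstmCache>(ca, true);
  } else {
    delete ca;
  }
  return out;
}

// [[Rcpp::export]]
List lstm_backward_cpp(SEXP cache_, const NumericMatrix& Wx_,
                       const NumericMatrix& Wh_, const NumericMatrix& dHstack_,
                       const NumericMatrix& dHfinal_) {
  XPtr<LstmCache> ca(cache_);
  const mat Wx = view(Wx_), Wh = view(Wh_);
  const int Tn = ca->Tn, B = ca->B;
  const uword h = Wh.n_rows;
  const bool has_seq = dHstack_.nrow() > 0;
  const bool has_final = dHfinal_.nrow() > 0;
  const mat dHstack = has_seq ? view(dHstack_) : mat();
  const mat dHfinal = has_final ? view(dHfinal_) : mat();
  mat dWh(h, 4 * h, arma::fill::zeros);
  mat dZstack(Tn * B, 4 * h);
  mat dHnext(B, h, arma::fill::zeros), dCnext(B, h, arma::fill::zeros);
  mat zeros(B, h, arma::fill::zeros);
  for (int t = Tn - 1; t >= 0; --t) {
    span rows(t * B, (t + 1) * B - 1);
    mat dH = dHnext;
    if (has_seq) dH += dHstack.rows(rows);
    if (has_final && t == Tn - 1) dH += dHfinal;
    const mat i = ca->G(rows, span(0, h - 1));
    const mat f = ca->G(rows, span(h, 2 * h - 1));
    const mat g = ca->G(rows, span(2 * h, 3 * h - 1));
    const mat o = ca->G(rows, span(3 * h, 4 * h - 1));
    const mat tc = arma::tanh(ca->Cstack.rows(rows));
    mat hprev = (t == 0) ? zeros : mat(ca->Hstack.rows(span((t - 1) * B, t * B - 1)));
    mat cprev = (t == 0) ? zeros : mat(ca->Cstack.rows(span((t - 1) * B, t * B - 1)));
    mat dC = dH % o % (1.0 - tc % tc) + dCnext;
    mat dZ(B, 4 * h);
    dZ.cols(0, h - 1) = dC % g % i % (1.0 - i);
    dZ.cols(h, 2 * h - 1) = dC % cprev % f % (1.0 - f);
    dZ.cols(2 * h, 3 * h - 1) = dC % i % (1.0 - g % g);
    dZ.cols(3 * h, 4 * h - 1) = dH % tc % o % (1.0 - o);
    dZstack.rows(rows) = dZ;
    dWh += hprev.t() * dZ;
    dHnext = dZ * Wh.t();
    dCnext = dC % f;
  }
  if (ca->reverse) {
    mat tmp(Tn * B, 4 * h);
    for (int t = 0; t < Tn; ++t) {
      tmp.rows(span(t * B, (t + 1) * B - 1)) =
        dZstack.rows(span((Tn - 1 - t) * B, (Tn - t) * B - 1));
    }
    dZstack = std::move(tmp);
  }
  mat dWx = ca->Xstack.t() * dZstack;
  arma::rowvec db = arma::sum(dZstack, 0);
  mat dXstack = dZstack * Wx.t();
  return List::create(_["dWx"] = dWx, _["dWh"] = dWh, _["db"] = db.t(),
                      _["dXstack"] = dXstack);
}

// [[Rcpp::export]]
List gru_forward_cpp(const NumericMatrix& Wx_, const NumericMatrix& Wh_,
                     const NumericVector& b_, const NumericMatrix& Xstack_,
                     int Tn, int B, bool reverse, bool keep_cache) {
  const mat Wx = view(Wx_), Wh = view(Wh_);
  const mat bcol = view_vec(b_);
  const uword h = Wh.n_rows;
  GruCache* ca = new GruCache();
  ca->Tn = Tn; ca->B = B; ca->reverse = reverse;
  ca->Xstack = view(Xstack_);
  mat XW = ca->Xstack * Wx;
  XW.each_row() += bcol.t();
  mat H(B, h, arma::fill::zeros);
  ca->Hstack.set_size(Tn * B, h);
  ca->G.set_size(Tn * B, 3 * h);
  ca->RH.set_size(Tn * B, h);
  const mat Wh_zr = Wh.cols(0, 2 * h - 1);
  const mat Wh_h = Wh.cols(2 * h, 3 * h - 1);
  for (int t = 0; t < Tn; ++t) {
    int src = reverse ? (Tn - 1 - t) : t;
    span rows(t * B, (t + 1) * B - 1);
    mat Zx = XW.rows(span(src * B, (src + 1) * B - 1));
    mat Zh = H * Wh_zr;
    mat z = sigm(Zx.cols(0, h - 1) + Zh.cols(0, h - 1));
    mat r = sigm(Zx.cols(h, 2 * h - 1) + Zh.cols(h, 2 * h - 1));
    mat rh = r % H;
    mat hb = arma::tanh(Zx.cols(2 * h, 3 * h - 1) + rh * Wh_h);
    H = z % H + (1.0 - z) % hb;
    ca->G(rows, span(0, h - 1)) = z;
    ca->G(rows, span(h, 2 * h - 1)) = r;
    ca->G(rows, span(2 * h, 3 * h - 1)) = hb;
    ca->RH.rows(rows) = rh;
    ca->Hstack.rows(rows) = H;
  }
  List out = List::create(_["Hstack"] = wrap(ca->Hstack),
                          _["final"] = wrap(H));
  if (keep_cache) {
    out["cache"] = XPtr<GruCache>(ca, true);
  } else {
    delete ca;
  }
  return out;
}

// [[Rcpp::export]]
List gru_backward_cpp(SEXP cache_, const NumericMatrix& Wx_,
                      const NumericMatrix& Wh_, const NumericMatrix& dHstack_,
                      const NumericMatrix& dHfinal_) {
  XPtr<GruCache> ca(cache_);
  const mat Wx = view(Wx_), Wh = view(Wh_);
  const int Tn = ca->Tn, B = ca->B;
  const uword h = Wh.n_rows;
  const bool has_seq = dHstack_.nrow() > 0;
  const bool has_final = dHfinal_.nrow() > 0;
  const mat dHstack = has_seq ? view(dHstack_) : mat();
  const mat dHfinal = has_final ? view(dHfinal_) : mat();
  mat dWh(h, 3 * h, arma::fill::zeros);
  mat dZstack(Tn * B, 3 * h);
  mat dHnext(B, h, arma::fill::zeros);
  mat zeros(B, h, arma::fill::zeros);
  const mat Wh_zr = Wh.cols(0, 2 * h - 1);
  const mat Wh_h = Wh.cols(2 * h, 3 * h - 1);
  for (int t = Tn - 1; t >= 0; --t) {
    span rows(t * B, (t + 1) * B - 1);
    mat dH = dHnext;
    if (has_seq) dH += dHstack.rows(rows);
    if (has_final && t == Tn - 1) dH += dHfinal;
    const mat z = ca->G(rows, span(0, h - 1));
    const mat r = ca->G(rows, span(h, 2 * h - 1));
    const mat hb = ca->G(rows, span(2 * h, 3 * h - 1));
    const mat rh = ca->RH.rows(rows);
    mat hprev = (t == 0) ? zeros : mat(ca->Hstack.rows(span((t - 1) * B, t * B - 1)));
    mat dz = dH % (hprev - hb) % z % (1.0 - z);
    mat dhb_pre = dH % (1.0 - z) % (1.0 - hb % hb);
    mat drh = dhb_pre * Wh_h.t();
    mat dr = drh % hprev % r % (1.0 - r);
    mat dZx = arma::join_rows(dz, dr, dhb_pre);
    dZstack.rows(rows) = dZx;
    dWh.cols(0, 2 * h - 1) += hprev.t() * arma::join_rows(dz, dr);
    dWh.cols(2 * h, 3 * h - 1) += rh.t() * dhb_pre;
    dHnext = dH % z + arma::join_rows(dz, dr) * Wh_zr.t() + drh % r;
  }
  if (ca->reverse) {
    mat tmp(Tn * B, 3 * h);
    for (int t = 0; t < Tn; ++t) {
      tmp.rows(span(t * B, (t + 1) * B - 1)) =
        dZstack.rows(span((Tn - 1 - t) * B, (Tn - t) * B - 1));
    }
    dZstack = std::move(tmp);
  }
  mat dWx = ca->Xstack.t() * dZstack;
  arma::rowvec db = arma::sum(dZstack, 0);
  mat dXstack = dZstack * Wx.t();
  return List::create(_["dWx"] = dWx, _["dWh"] = dWh, _["db"] = db.t(),
                      _["dXstack"] = dXstack);
}

// ---- one-hot-aware embedding-layer variants -----------------------------
//
// The first layer's input is a one-hot character window, so its input
// projection is a row gather of Wx and the input-side weight gradient is
// a row scatter-add; no dense one-hot matrix, no GEMM, and no dX is ever
// needed (nothing sits below the embedding layer).

struct LstmIdxCache {
  arma::imat ctx;  // B x Tn, 0-based symbol indices
  mat Hstack, Cstack, G;
  int Tn, B;
  bool reverse;
};

// [[Rcpp::export]]
List lstm_forward_idx_cpp(const NumericMatrix& Wx_, const NumericMatrix& Wh_,
                          const NumericVector& b_, const IntegerMatrix& ctx_,
                          bool reverse, bool keep_cache) {
  const mat Wx = view(Wx_), Wh = view(Wh_);
  const mat bcol = view_vec(b_);
  const uword h = Wh.n_rows;
  const int B = ctx_.nrow(), Tn = ctx_.ncol();
  LstmIdxCache* ca = new LstmIdxCache();
  ca->Tn = Tn; ca->B = B; ca->reverse = reverse;
  ca->ctx.set_size(B, Tn);
  for (int t = 0; t < Tn; ++t)
    for (int i = 0; i < B; ++i) ca->ctx(i, t) = ctx_(i, t);
  mat H(B, h, arma::fill::zeros), C(B, h, arma::fill::zeros);
  ca->Hstack.set_size(Tn * B, h);
  ca->Cstack.set_size(Tn * B, h);
  ca->G.set_size(Tn * B, 4 * h);
  mat Z(B, 4 * h);
  for (int t = 0; t < Tn; ++t) {
    int src = reverse ? (Tn - 1 - t) : t;
    Z = H * Wh;
    Z.each_row() += bcol.t();
    for (int i = 0; i < B; ++i) Z.row(i) += Wx.row(ca->ctx(i, src));
    span rows(t * B, (t + 1) * B - 1);
    // fused gate math, single pass over the row block
    double* zp = Z.memptr();
    double* gp = ca->G.colptr(0) + t * B;     // column-major: handle per column
    // operate column-wise: columns j of Z map to gates
    for (uword j = 0; j < h; ++j) {
      const double* zi = Z.colptr(j);
      const double* zf = Z.colptr(h + j);
      const double* zg = Z.colptr(2 * h + j);
      const double* zo = Z.colptr(3 * h + j);
      double* Gi = ca->G.colptr(j) + t * B;
      double* Gf = ca->G.colptr(h + j) + t * B;
      double* Gg = ca->G.colptr(2 * h + j) + t * B;
      double* Go = ca->G.colptr(3 * h + j) + t * B;
      double* Cc = C.colptr(j);
      double* Hc = H.colptr(j);
      double* Hs = ca->Hstack.colptr(j) + t * B;
      double* Cs = ca->Cstack.colptr(j) + t * B;
      for (int i = 0; i < B; ++i) {
        double gi = 1.0 / (1.0 + std::exp(-zi[i]));
        double gf = 1.0 / (1.0 + std::exp(-zf[i]));
        double gg = std::tanh(zg[i]);
        double go = 1.0 / (1.0 + std::exp(-zo[i]));
        double c = gf * Cc[i] + gi * gg;
        double hh = go * std::tanh(c);
        Gi[i] = gi; Gf[i] = gf; Gg[i] = gg; Go[i] = go;
        Cc[i] = c; Hc[i] = hh;
        Hs[i] = hh; Cs[i] = c;
      }
    }
    (void)zp; (void)gp;
  }
  List out = List::create(_["Hstack"] = wrap(ca->Hstack), _["final"] = wrap(H));
  if (keep_cache) out["cache"] = XPtr<LstmIdxCache>(ca, true);
  else delete ca;
  return out;
}

// [[Rcpp::export]]
List lstm_backward_idx_cpp(SEXP cache_, const NumericMatrix& Wx_,
                           const NumericMatrix& Wh_,
                           const NumericMatrix& dHstack_,
                           const NumericMatrix& dHfinal_) {
  XPtr<LstmIdxCache> ca(cache_);
  const mat Wx = view(Wx_), Wh = view(Wh_);
  const int Tn = ca->Tn, B = ca->B;
  const uword h = Wh.n_rows;
  const bool has_seq = dHstack_.nrow() > 0;
  const bool has_final = dHfinal_.nrow() > 0;
  const mat dHstack = has_seq ? view(dHstack_) : mat();
  const mat dHfinal = has_final ? view(dHfinal_) : mat();
  mat dWx(Wx.n_rows, 4 * h, arma::fill::zeros);
  mat dWh(h, 4 * h, arma::fill::zeros);
  arma::rowvec db(4 * h, arma::fill::zeros);
  mat dHnext(B, h, arma::fill::zeros), dCnext(B, h, arma::fill::zeros);
  mat zeros(B, h, arma::fill::zeros);
  mat dZ(B, 4 * h);
  for (int t = Tn - 1; t >= 0; --t) {
    span rows(t * B, (t + 1) * B - 1);
    mat dH = dHnext;
    if (has_seq) dH += dHstack.rows(rows);
    if (has_final && t == Tn - 1) dH += dHfinal;
    const mat hprev = (t == 0) ? zeros
      : mat(ca->Hstack.rows(span((t - 1) * B, t * B - 1)));
    const mat cprev = (t == 0) ? zeros
      : mat(ca->Cstack.rows(span((t - 1) * B, t * B - 1)));
    for (uword j = 0; j < h; ++j) {
      const double* Gi = ca->G.colptr(j) + t * B;
      const double* Gf = ca->G.colptr(h + j) + t * B;
      const double* Gg = ca->G.colptr(2 * h + j) + t * B;
      const double* Go = ca->G.colptr(3 * h + j) + t * B;
      const double* Cs = ca->Cstack.colptr(j) + t * B;
      const double* cp = cprev.colptr(j);
      const double* dh = dH.colptr(j);
      double* dcn = dCnext.colptr(j);
      double* dzi = dZ.colptr(j);
      double* dzf = dZ.colptr(h + j);
      double* dzg = dZ.colptr(2 * h + j);
      double* dzo = dZ.colptr(3 * h + j);
      for (int i = 0; i < B; ++i) {
        double tc = std::tanh(Cs[i]);
        double dC = dh[i] * Go[i] * (1.0 - tc * tc) + dcn[i];
        dzi[i] = dC * Gg[i] * Gi[i] * (1.0 - Gi[i]);
        dzf[i] = dC * cp[i] * Gf[i] * (1.0 - Gf[i]);
        dzg[i] = dC * Gi[i] * (1.0 - Gg[i] * Gg[i]);
        dzo[i] = dh[i] * tc * Go[i] * (1.0 - Go[i]);
        dcn[i] = dC * Gf[i];
      }
    }
    dWh += hprev.t() * dZ;
    db += arma::sum(dZ, 0);
    int src = ca->reverse ? (Tn - 1 - t) : t;
    for (int i = 0; i < B; ++i) dWx.row(ca->ctx(i, src)) += dZ.row(i);
    dHnext = dZ * Wh.t();
  }
  return List::create(_["dWx"] = dWx, _["dWh"] = dWh, _["db"] = db.t());
}
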