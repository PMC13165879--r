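// Batched forward/backward pass of the FC + double-LSTM stack.
// Mirrors the layer equations exactly: per-step affine FC layers with tanh
// (or identity), LSTM gates T(x, h) = x*Wx + h*Wh + b split into the four
// blocks [i, f, o, m], state update c = f%c_prev + i%m, h = o%tanh(c),
// final readout -> softmax, per-unit binary cross-entropy summed over units
// and averaged over the batch.
//
// Rows of every stacked matrix are (trial, step) pairs with row index
// t*B + b, so the input-side transforms of both the FC stack and the LSTM
// gates run as single GEMMs over all steps; only the recurrent term stays
// inside the time loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct LayerState {
  mat gi, gf, go, gm, c, tanh_c, h;  // (B*T) x H stacks
};

// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(const Rcpp::List& fc_W, const Rcpp::List& fc_b,
                         const Rcpp::List& lstm_Wx, const Rcpp::List& lstm_Wh,
                         const Rcpp::List& lstm_b,
                         const arma::mat& out_W, const arma::rowvec& out_b,
                         const arma::mat& Xstack, int B, int T,
                         const arma::ivec& y, int activation, int readout,
                         bool want_grad) {
  const int n_fc = fc_W.size();
  const int n_lstm = lstm_Wx.size();
  const double eps = 1e-12;

  // time-distributed FC stack over all (trial, step) rows at once
  std::vector<mat> fc_acts(n_fc + 1);
  fc_acts[0] = Xstack;
  for (int l = 0; l < n_fc; ++l) {
    const mat& W = fc_W[l];
    rowvec b = Rcpp::as<rowvec>(fc_b[l]);
    mat a = fc_acts[l] * W;
    a.each_row() += b;
    fc_acts[l + 1] = (activation == 0) ? mat(tanh(a)) : a;
  }

  std::vector<LayerState> st(n_lstm);
  std::vector<mat> layer_in(n_lstm);  // (B*T) x in, input stack per layer
  {
    mat x = fc_acts[n_fc];
    for (int l = 0; l < n_lstm; ++l) {
      const mat& Wx = lstm_Wx[l];
      const mat& Wh = lstm_Wh[l];
      rowvec b = Rcpp::as<rowvec>(lstm_b[l]);
      const int H = Wh.n_cols / 4;
      layer_in[l] = x;
      mat gpre = x * Wx;           // input side of all four gates, all steps
      gpre.each_row() += b;
      LayerState& s = st[l];
      s.gi.set_size(B * T, H); s.gf.set_size(B * T, H);
      s.go.set_size(B * T, H); s.gm.set_size(B * T, H);
      s.c.set_size(B * T, H);  s.tanh_c.set_size(B * T, H);
      s.h.set_size(B * T, H);
      mat h_prev = zeros<mat>(B, H), c_prev = zeros<mat>(B, H);
      for (int t = 0; t < T; ++t) {
        const span rows(t * B, (t + 1) * B - 1);
        mat g = gpre.rows(rows) + h_prev * Wh;  // add the recurrent term
        mat gi = 1.0 / (1.0 + exp(-g.cols(0, H - 1)));
        mat gf = 1.0 / (1.0 + exp(-g.cols(H, 2 * H - 1)));
        mat go = 1.0 / (1.0 + exp(-g.cols(2 * H, 3 * H - 1)));
        mat gm = tanh(g.cols(3 * H, 4 * H - 1));
        mat c_t = gf % c_prev + gi % gm;
        mat tc = tanh(c_t);
        mat h_t = go % tc;
        s.gi.rows(rows) = gi; s.gf.rows(rows) = gf;
        s.go.rows(rows) = go; s.gm.rows(rows) = gm;
        s.c.rows(rows) = c_t; s.tanh_c.rows(rows) = tc;
        s.h.rows(rows) = h_t;
        h_prev = h_t; c_prev = c_t;
      }
      x = s.h;
    }
  }
  const mat& top_h = st[n_lstm - 1].h;
  mat h_read;
  if (readout == 0) {
    h_read = top_h.rows((T - 1) * B, T * B - 1);
  } else {
    h_read = zeros<mat>(B, top_h.n_cols);
    for (int t = 0; t < T; ++t) h_read += top_h.rows(t * B, (t + 1) * B - 1);
    h_read /= T;
  }
  mat logits = h_read * out_W;
  logits.each_row() += out_b;
  logits.each_col() -= max(logits, 1);
  mat probs = exp(logits);
  probs.each_col() /= sum(probs, 1);

  const int K = probs.n_cols;
  mat Y = zeros<mat>(B, K);
  for (int i = 0; i < B; ++i) Y(i, y[i] - 1) = 1.0;
  mat a = clamp(probs, eps, 1.0 - eps);
  double loss = accu(-(Y % log(a) + (1.0 - Y) % log(1.0 - a))) / B;

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loss") = loss,
                                      Rcpp::Named("probs") = probs);
  if (!want_grad) return out;

  // d loss / d probs through the softmax jacobian
  mat u = (-(Y / a) + (1.0 - Y) / (1.0 - a)) / B;
  mat dz = probs % (u.each_col() - sum(u % probs, 1));
  mat g_outW = h_read.t() * dz;
  rowvec g_outb = sum(dz, 0);
  mat dh_read = dz * out_W.t();

  // external gradient on the top LSTM output, stacked over steps
  mat dh_ext(B * T, dh_read.n_cols, fill::zeros);
  if (readout == 0) {
    dh_ext.rows((T - 1) * B, T * B - 1) = dh_read;
  } else {
    for (int t = 0; t < T; ++t)
      dh_ext.rows(t * B, (t + 1) * B - 1) = dh_read / T;
  }

  Rcpp::List gWx(n_lstm), gWh(n_lstm), glb(n_lstm);
  for (int l = n_lstm - 1; l >= 0; --l) {
    const mat& Wx = lstm_Wx[l];
    const mat& Wh = lstm_Wh[l];
    const int H = Wh.n_cols / 4;
    const LayerState& s = st[l];
    mat dG(B * T, 4 * H);            // gate pre-activation grads, all steps
    mat g_Wh = zeros<mat>(H, 4 * H);
    mat dh_next = zeros<mat>(B, H), dc_next = zeros<mat>(B, H);
    for (int t = T - 1; t >= 0; --t) {
      const span rows(t * B, (t + 1) * B - 1);
      mat gi = s.gi.rows(rows), gf = s.gf.rows(rows);
      mat go = s.go.rows(rows), gm = s.gm.rows(rows);
      mat tc = s.tanh_c.rows(rows);
      mat c_prev = (t == 0) ? zeros<mat>(B, H) : mat(s.c.rows(rows.a - B, rows.b - B));
      mat dh = dh_ext.rows(rows) + dh_next;
      mat do_ = dh % tc;
      mat dc = dh % go % (1.0 - square(tc)) + dc_next;
      dc_next = dc % gf;
      mat dg(B, 4 * H);
      dg.cols(0, H - 1) = (dc % gm) % gi % (1.0 - gi);
      dg.cols(H, 2 * H - 1) = (dc % c_prev) % gf % (1.0 - gf);
      dg.cols(2 * H, 3 * H - 1) = do_ % go % (1.0 - go);
      dg.cols(3 * H, 4 * H - 1) = (dc % gi) % (1.0 - square(gm));
      mat h_prev = (t == 0) ? zeros<mat>(B, H) : mat(s.h.rows(rows.a - B, rows.b - B));
      g_Wh += h_prev.t() * dg;
      dh_next = dg * Wh.t();
      dG.rows(rows) = dg;
    }
    gWx[l] = layer_in[l].t() * dG;   // input-side grads as one GEMM
    gWh[l] = g_Wh;
    glb[l] = rowvec(sum(dG, 0));
    dh_ext = dG * Wx.t();            // gradient into the layer below / FC
  }

  mat da = dh_ext;
  Rcpp::List g_fcW(n_fc), g_fcb(n_fc);
  for (int l = n_fc - 1; l >= 0; --l) {
    const mat& W = fc_W[l];
    mat dpre = (activation == 0) ? mat(da % (1.0 - square(fc_acts[l + 1])))
                                 : da;
    g_fcW[l] = fc_acts[l].t() * dpre;
    g_fcb[l] = rowvec(sum(dpre, 0));
    da = dpre * W.t();
  }
  out["grads"] = Rcpp::List::create(
      Rcpp::Named("fc_W") = g_fcW, Rcpp::Named("fc_b") = g_fcb,
      Rcpp::Named("lstm_Wx") = gWx, Rcpp::Named("lstm_Wh") = gWh,
      Rcpp::Named("lstm_b") = glb,
      Rcpp::Named("out_W") = g_outW, Rcpp::Named("out_b") = g_outb);
  return out;
}
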