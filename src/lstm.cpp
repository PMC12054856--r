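// Stacked uni/bi-directional LSTM sequence labeller: forward pass,
// backpropagation through time, and a fused Adam step. Parameters live in a
// single flat numeric vector owned by R; this file maps views onto it.
//
// Gate row order within each 4H block: input (i), forget (f), candidate (g),
// output (o). Per direction and layer: W (4H x D), U (4H x H), b (4H).
// Layer input D is 3 for layer 1, H * ndir above. A final linear readout
// (w_out, b_out) maps the top hidden state to a per-minute logit.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

struct Params {
  std::vector<mat> W, U;
  std::vector<vec> b;
  std::vector<vec> wout;  // single element
  double *bout;
  int L, H, ndir;
};

static size_t layer_in_dim(int l, int H, int ndir) {
  return l == 0 ? 3 : (size_t)H * ndir;
}

static size_t n_theta(int L, int H, int ndir) {
  size_t s = 0;
  for (int l = 0; l < L; ++l) {
    size_t D = layer_in_dim(l, H, ndir);
    s += (size_t)ndir * (4 * H * D + 4 * (size_t)H * H + 4 * H);
  }
  return s + (size_t)H * ndir + 1;
}

static void map_params(double *p, int L, int H, int ndir, Params &pv) {
  pv.L = L; pv.H = H; pv.ndir = ndir;
  // reserve so the vectors never reallocate: reallocation would copy the
  // aliased views into owning matrices and detach them from the flat buffer
  pv.W.reserve((size_t)L * ndir); pv.U.reserve((size_t)L * ndir);
  pv.b.reserve((size_t)L * ndir); pv.wout.reserve(1);
  size_t off = 0;
  for (int l = 0; l < L; ++l) {
    size_t D = layer_in_dim(l, H, ndir);
    for (int d = 0; d < ndir; ++d) {
      pv.W.emplace_back(p + off, 4 * H, D, false, true); off += 4 * H * D;
      pv.U.emplace_back(p + off, 4 * H, H, false, true); off += 4 * (size_t)H * H;
      pv.b.emplace_back(p + off, 4 * H, false, true);    off += 4 * H;
    }
  }
  pv.wout.emplace_back(p + off, (size_t)H * ndir, false, true);
  off += (size_t)H * ndir;
  pv.bout = p + off;
}

struct Cache {
  std::vector<mat> I;                       // layer inputs, I[L] = top output
  std::vector<mat> gi, gf, gg, go, C, tC, Hh;  // per (layer, dir)
  vec logits, probs;
};

static void forward_pass(const Params &pv, const mat &X3T, Cache &ca) {
  const int L = pv.L, H = pv.H, ndir = pv.ndir;
  const int T = X3T.n_cols;
  mat input = X3T;
  for (int l = 0; l < L; ++l) {
    ca.I.push_back(input);
    mat out((size_t)H * ndir, T);
    for (int d = 0; d < ndir; ++d) {
      const int idx = l * ndir + d;
      mat G = pv.W[idx] * input;
      G.each_col() += pv.b[idx];
      mat gi(H, T), gf(H, T), gg(H, T), go(H, T), C(H, T), tC(H, T), Hh(H, T);
      vec h(H, fill::zeros), c(H, fill::zeros);
      for (int s = 0; s < T; ++s) {
        const int t = (d == 0) ? s : T - 1 - s;
        vec a = G.col(t) + pv.U[idx] * h;
        vec i_ = 1.0 / (1.0 + exp(-a.subvec(0, H - 1)));
        vec f_ = 1.0 / (1.0 + exp(-a.subvec(H, 2 * H - 1)));
        vec g_ = tanh(a.subvec(2 * H, 3 * H - 1));
        vec o_ = 1.0 / (1.0 + exp(-a.subvec(3 * H, 4 * H - 1)));
        c = f_ % c + i_ % g_;
        vec tc = tanh(c);
        h = o_ % tc;
        gi.col(t) = i_; gf.col(t) = f_; gg.col(t) = g_; go.col(t) = o_;
        C.col(t) = c; tC.col(t) = tc; Hh.col(t) = h;
      }
      out.rows(d * H, (d + 1) * H - 1) = Hh;
      ca.gi.push_back(gi); ca.gf.push_back(gf); ca.gg.push_back(gg);
      ca.go.push_back(go); ca.C.push_back(C); ca.tC.push_back(tC);
      ca.Hh.push_back(Hh);
    }
    input = out;
  }
  ca.I.push_back(input);
  rowvec lg = pv.wout[0].t() * input;
  ca.logits = lg.t() + *pv.bout;
  ca.probs = 1.0 / (1.0 + exp(-ca.logits));
}

// Mean binary cross-entropy from logits (numerically stable).
static double bce_loss(const vec &logits, const vec &y) {
  vec z = logits;
  vec l = arma::max(z, zeros<vec>(z.n_elem)) - z % y + log1p(exp(-abs(z)));
  return mean(l);
}

static void backward_pass(const Params &pv, Params &gv, const Cache &ca,
                          const vec &y) {
  const int L = pv.L, H = pv.H, ndir = pv.ndir;
  const int T = ca.probs.n_elem;
  vec dlogit = (ca.probs - y) / (double)T;
  const mat &top = ca.I[L];
  gv.wout[0] += top * dlogit;
  *gv.bout += accu(dlogit);
  mat dO = pv.wout[0] * dlogit.t();  // (H*ndir) x T
  for (int l = L - 1; l >= 0; --l) {
    mat dI(layer_in_dim(l, H, ndir), T, fill::zeros);
    for (int d = 0; d < ndir; ++d) {
      const int idx = l * ndir + d;
      const mat &gi = ca.gi[idx], &gf = ca.gf[idx], &gg = ca.gg[idx],
                &go = ca.go[idx], &C = ca.C[idx], &tC = ca.tC[idx],
                &Hh = ca.Hh[idx];
      mat Delta(4 * H, T);
      vec dh(H, fill::zeros), dc(H, fill::zeros);
      for (int s = 0; s < T; ++s) {
        const int t = (d == 0) ? T - 1 - s : s;   // reverse of forward order
        vec dht = dO.rows(d * H, (d + 1) * H - 1).col(t) + dh;
        vec o_ = go.col(t), tc = tC.col(t);
        vec do_ = dht % tc;
        dc += dht % o_ % (1.0 - tc % tc);
        vec i_ = gi.col(t), f_ = gf.col(t), g_ = gg.col(t);
        vec cprev(H, fill::zeros);
        if (d == 0) { if (t > 0) cprev = C.col(t - 1); }
        else        { if (t < T - 1) cprev = C.col(t + 1); }
        vec da(4 * H);
        da.subvec(0, H - 1)         = (dc % g_) % (i_ % (1.0 - i_));
        da.subvec(H, 2 * H - 1)     = (dc % cprev) % (f_ % (1.0 - f_));
        da.subvec(2 * H, 3 * H - 1) = (dc % i_) % (1.0 - g_ % g_);
        da.subvec(3 * H, 4 * H - 1) = do_ % (o_ % (1.0 - o_));
        Delta.col(t) = da;
        dh = pv.U[idx].t() * da;
        dc = dc % f_;
      }
      mat Hprev(H, T, fill::zeros);
      if (T > 1) {
        if (d == 0) Hprev.cols(1, T - 1) = Hh.cols(0, T - 2);
        else        Hprev.cols(0, T - 2) = Hh.cols(1, T - 1);
      }
      gv.W[idx] += Delta * ca.I[l].t();
      gv.U[idx] += Delta * Hprev.t();
      gv.b[idx] += sum(Delta, 1);
      dI += pv.W[idx].t() * Delta;
    }
    if (l > 0) dO = dI;
  }
}

// [[Rcpp::export]]
int cpp_lstm_n_params(int n_layers, int hidden, int bidirectional) {
  return (int)n_theta(n_layers, hidden, bidirectional ? 2 : 1);
}

// [[Rcpp::export]]
NumericVector cpp_lstm_forward(NumericVector theta, NumericMatrix X,
                               int n_layers, int hidden, int bidirectional) {
  const int ndir = bidirectional ? 2 : 1;
  if ((size_t)theta.size() != n_theta(n_layers, hidden, ndir))
    stop("theta has wrong length for this architecture");
  Params pv;
  map_params(theta.begin(), n_layers, hidden, ndir, pv);
  mat Xa(X.begin(), X.nrow(), X.ncol(), false);
  mat X3T = Xa.t();
  Cache ca;
  forward_pass(pv, X3T, ca);
  return NumericVector(ca.probs.begin(), ca.probs.end());
}

// One BPTT + Adam step on a single (sequence, labels) pair. theta, m and v
// are updated in place; returns the pre-update mean BCE loss.
// [[Rcpp::export]]
double cpp_lstm_step(NumericVector theta, NumericVector m, NumericVector v,
                     int step, NumericMatrix X, IntegerVector y,
                     int n_layers, int hidden, int bidirectional,
                     double lr, double clip,
                     double beta1 = 0.9, double beta2 = 0.999,
                     double eps = 1e-8) {
  const int ndir = bidirectional ? 2 : 1;
  const size_t P = n_theta(n_layers, hidden, ndir);
  if ((size_t)theta.size() != P || (size_t)m.size() != P || (size_t)v.size() != P)
    stop("parameter vectors have wrong length");
  if (X.nrow() != y.size()) stop("labels must match sequence length");
  Params pv;
  map_params(theta.begin(), n_layers, hidden, ndir, pv);
  mat Xa(X.begin(), X.nrow(), X.ncol(), false);
  mat X3T = Xa.t();
  Cache ca;
  forward_pass(pv, X3T, ca);
  vec yv = conv_to<vec>::from(as<std::vector<int>>(y));
  double loss = bce_loss(ca.logits, yv);

  std::vector<double> gbuf(P, 0.0);
  Params gv;
  map_params(gbuf.data(), n_layers, hidden, ndir, gv);
  backward_pass(pv, gv, ca, yv);

  double sq = 0.0;
  for (size_t i = 0; i < P; ++i) sq += gbuf[i] * gbuf[i];
  double gnorm = std::sqrt(sq);
  double scale = (clip > 0 && gnorm > clip) ? clip / gnorm : 1.0;

  const double bc1 = 1.0 - std::pow(beta1, (double)step);
  const double bc2 = 1.0 - std::pow(beta2, (double)step);
  double *th = theta.begin(), *mm = m.begin(), *vv = v.begin();
  for (size_t i = 0; i < P; ++i) {
    const double g = gbuf[i] * scale;
    mm[i] = beta1 * mm[i] + (1.0 - beta1) * g;
    vv[i] = beta2 * vv[i] + (1.0 - beta2) * g * g;
    th[i] -= lr * (mm[i] / bc1) / (std::sqrt(vv[i] / bc2) + eps);
  }
  return loss;
}
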