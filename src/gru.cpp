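// Core numerics for the GRU SMILES language model: batched forward pass,
// backpropagation through time, and autoregressive multinomial sampling.
//
// Parameter layout (see R/model.R):
//   params$E              V x e embedding matrix (one row per vocabulary id)
//   params$layers[[l]]$Wx 3H x in   input weights,  rows [r | z | n]
//   params$layers[[l]]$Wh 3H x H    recurrent weights, same gate order
//   params$layers[[l]]$b  3H        bias
//   params$Wo             V x H     output projection
//   params$bo             V
//
// Gate equations (update-gate convention: z gates the candidate in):
//   r_t = sigmoid(Wx_r x_t + Wh_r h_{t-1} + b_r)
//   z_t = sigmoid(Wx_z x_t + Wh_z h_{t-1} + b_z)
//   n_t = tanh  (Wx_n x_t + Wh_n (r_t % h_{t-1}) + b_n)
//   h_t = (1 - z_t) % h_{t-1} + z_t % n_t
//
// Sequences arrive as a T x B integer matrix of 1-based vocabulary ids with
// 0 as padding. Position t predicts position t+1; padded targets are masked
// out of the loss.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Layer {
  mat Wx, Wh;
  vec b;
};

struct Net {
  mat E;
  std::vector<Layer> layers;
  mat Wo;
  vec bo;
  int V, H, e, L;
};

Net unpack(const Rcpp::List& params) {
  Net net;
  net.E = Rcpp::as<mat>(params["E"]);
  Rcpp::List lys = params["layers"];
  for (int l = 0; l < lys.size(); ++l) {
    Rcpp::List ly = lys[l];
    Layer layer;
    layer.Wx = Rcpp::as<mat>(ly["Wx"]);
    layer.Wh = Rcpp::as<mat>(ly["Wh"]);
    layer.b = Rcpp::as<vec>(ly["b"]);
    net.layers.push_back(layer);
  }
  net.Wo = Rcpp::as<mat>(params["Wo"]);
  net.bo = Rcpp::as<vec>(params["bo"]);
  net.V = net.E.n_rows;
  net.e = net.E.n_cols;
  net.L = net.layers.size();
  net.H = net.layers[0].Wh.n_cols;
  return net;
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Softmax over columns (classes in rows).
inline mat softmax_cols(const mat& logits) {
  mat shifted = logits.each_row() - max(logits, 0);
  mat e = exp(shifted);
  e.each_row() /= sum(e, 0);
  return e;
}

// One GRU step for a batch: x (in x B), h (H x B). Writes gate activations.
void gru_cell(const Layer& ly, const mat& x, const mat& h, int H,
              mat& r, mat& z, mat& n, mat& hnew) {
  mat pre_x = ly.Wx * x;
  pre_x.each_col() += ly.b;
  mat pre_h = ly.Wh.rows(0, 2 * H - 1) * h;
  r = sigmoid(pre_x.rows(0, H - 1) + pre_h.rows(0, H - 1));
  z = sigmoid(pre_x.rows(H, 2 * H - 1) + pre_h.rows(H, 2 * H - 1));
  n = tanh(pre_x.rows(2 * H, 3 * H - 1) + ly.Wh.rows(2 * H, 3 * H - 1) * (r % h));
  hnew = (1.0 - z) % h + z % n;
}

} // namespace

// Forward pass returning total NLL (natural log), number of scored tokens,
// and optionally the per-step class probabilities for a single sequence.
// [[Rcpp::export(name = ".cpp_gru_forward")]]
Rcpp::List cpp_gru_forward(Rcpp::List params, Rcpp::IntegerMatrix Xr,
                           bool return_probs = false) {
  Net net = unpack(params);
  imat X(Xr.begin(), Xr.nrow(), Xr.ncol(), true);
  int T = X.n_rows, B = X.n_cols, H = net.H;

  std::vector<mat> h(net.L, zeros<mat>(H, B));
  mat r, z, n, hnew;
  double nll = 0.0;
  long ntok = 0;
  mat probs_out;
  if (return_probs) probs_out.zeros(net.V, (T - 1) * B);

  for (int t = 0; t < T - 1; ++t) {
    // gather embeddings; padded inputs (id 0) contribute nothing scored
    mat x(net.e, B);
    for (int b = 0; b < B; ++b) {
      int id = X(t, b);
      if (id > 0) x.col(b) = net.E.row(id - 1).t();
      else x.col(b).zeros();
    }
    mat inp = x;
    for (int l = 0; l < net.L; ++l) {
      gru_cell(net.layers[l], inp, h[l], H, r, z, n, hnew);
      h[l] = hnew;
      inp = h[l];
    }
    mat logits = net.Wo * h[net.L - 1];
    logits.each_col() += net.bo;
    mat p = softmax_cols(logits);
    if (return_probs) probs_out.cols(t * B, t * B + B - 1) = p;
    for (int b = 0; b < B; ++b) {
      int tgt = X(t + 1, b);
      if (tgt > 0 && X(t, b) > 0) {
        nll -= std::log(std::max(p(tgt - 1, b), 1e-300));
        ++ntok;
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("nll") = nll, Rcpp::Named("ntok") = (double)ntok);
  if (return_probs) out["probs"] = probs_out;
  return out;
}

// Forward + BPTT. Returns total NLL, scored-token count, and gradients in
// the same layout as params.
// [[Rcpp::export(name = ".cpp_gru_grad")]]
Rcpp::List cpp_gru_grad(Rcpp::List params, Rcpp::IntegerMatrix Xr) {
  Net net = unpack(params);
  imat X(Xr.begin(), Xr.nrow(), Xr.ncol(), true);
  int T = X.n_rows, B = X.n_cols, H = net.H, L = net.L, V = net.V, e = net.e;
  int S = T - 1;  // number of steps

  // caches per step per layer
  std::vector<std::vector<mat>> R(L), Z(L), N(L), Hprev(L);
  std::vector<mat> Xemb(S);
  std::vector<mat> P(S);  // softmax probs minus one-hot (dlogits), built later
  std::vector<mat> h(L, zeros<mat>(H, B));

  double nll = 0.0;
  long ntok = 0;
  mat r, z, n, hnew;

  for (int t = 0; t < S; ++t) {
    mat x(e, B);
    for (int b = 0; b < B; ++b) {
      int id = X(t, b);
      if (id > 0) x.col(b) = net.E.row(id - 1).t();
      else x.col(b).zeros();
    }
    Xemb[t] = x;
    mat inp = x;
    for (int l = 0; l < L; ++l) {
      Hprev[l].push_back(h[l]);
      gru_cell(net.layers[l], inp, h[l], H, r, z, n, hnew);
      R[l].push_back(r);
      Z[l].push_back(z);
      N[l].push_back(n);
      h[l] = hnew;
      inp = h[l];
    }
    mat logits = net.Wo * h[L - 1];
    logits.each_col() += net.bo;
    mat p = softmax_cols(logits);
    for (int b = 0; b < B; ++b) {
      int tgt = X(t + 1, b);
      if (tgt > 0 && X(t, b) > 0) {
        nll -= std::log(std::max(p(tgt - 1, b), 1e-300));
        p(tgt - 1, b) -= 1.0;
        ++ntok;
      } else {
        p.col(b).zeros();  // masked position: no gradient
      }
    }
    P[t] = p;
  }

  // gradient accumulators
  mat gE = zeros<mat>(V, e);
  mat gWo = zeros<mat>(V, H);
  vec gbo = zeros<vec>(V);
  std::vector<mat> gWx(L), gWh(L);
  std::vector<vec> gb(L);
  for (int l = 0; l < L; ++l) {
    gWx[l] = zeros<mat>(size(net.layers[l].Wx));
    gWh[l] = zeros<mat>(size(net.layers[l].Wh));
    gb[l] = zeros<vec>(3 * H);
  }

  std::vector<mat> dh(L, zeros<mat>(H, B));  // dL/dh_t carried backwards

  for (int t = S - 1; t >= 0; --t) {
    // output layer (recompute h_t of the top layer from cached gates)
    mat htop = (Z[L-1][t] % N[L-1][t]) + (1.0 - Z[L-1][t]) % Hprev[L-1][t];
    gWo += P[t] * htop.t();
    gbo += sum(P[t], 1);
    dh[L - 1] += net.Wo.t() * P[t];

    mat dx_lower;  // gradient flowing to the layer below's h_t (or embedding)
    for (int l = L - 1; l >= 0; --l) {
      const mat& hp = Hprev[l][t];
      const mat& rr = R[l][t];
      const mat& zz = Z[l][t];
      const mat& nn = N[l][t];
      const Layer& ly = net.layers[l];

      mat dhv = dh[l];
      mat dz = dhv % (nn - hp);
      mat dn = dhv % zz;
      mat dpre_n = dn % (1.0 - nn % nn);
      mat dpre_z = dz % zz % (1.0 - zz);
      // candidate uses Wh_n * (r % hp)
      mat Whn = ly.Wh.rows(2 * H, 3 * H - 1);
      mat d_rh = Whn.t() * dpre_n;
      mat dr = d_rh % hp;
      mat dpre_r = dr % rr % (1.0 - rr);

      const mat& xin = (l == 0) ? Xemb[t]
                                : ((Z[l-1][t] % N[l-1][t]) + (1.0 - Z[l-1][t]) % Hprev[l-1][t]);

      mat dpre_rz = join_cols(dpre_r, dpre_z);
      gWx[l].rows(0, 2 * H - 1) += dpre_rz * xin.t();
      gWx[l].rows(2 * H, 3 * H - 1) += dpre_n * xin.t();
      gWh[l].rows(0, 2 * H - 1) += dpre_rz * hp.t();
      gWh[l].rows(2 * H, 3 * H - 1) += dpre_n * (rr % hp).t();
      gb[l].subvec(0, 2 * H - 1) += sum(dpre_rz, 1);
      gb[l].subvec(2 * H, 3 * H - 1) += sum(dpre_n, 1);

      // into h_{t-1} of this layer
      mat dhp = dhv % (1.0 - zz) + d_rh % rr +
                ly.Wh.rows(0, 2 * H - 1).t() * dpre_rz;
      // into the input of this layer
      mat dxin = ly.Wx.t() * join_cols(dpre_rz, dpre_n);

      dh[l] = dhp;            // carried to step t-1
      if (l > 0) {
        dh[l - 1] += dxin;    // layer below's h_t also feeds this layer
      } else {
        dx_lower = dxin;      // embedding gradient
      }
    }
    for (int b = 0; b < B; ++b) {
      int id = X(t, b);
      if (id > 0) gE.row(id - 1) += dx_lower.col(b).t();
    }
  }

  Rcpp::List glayers(L);
  for (int l = 0; l < L; ++l) {
    glayers[l] = Rcpp::List::create(Rcpp::Named("Wx") = gWx[l],
                                    Rcpp::Named("Wh") = gWh[l],
                                    Rcpp::Named("b") = gb[l]);
  }
  return Rcpp::List::create(
      Rcpp::Named("nll") = nll, Rcpp::Named("ntok") = (double)ntok,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("E") = gE, Rcpp::Named("layers") = glayers,
          Rcpp::Named("Wo") = gWo, Rcpp::Named("bo") = gbo));
}

// Autoregressive sampling. Returns a maxlen x n integer matrix of sampled
// ids (excluding the start token); 0 marks positions after the end token.
// Deterministic for a given seed (own Mersenne Twister stream).
// [[Rcpp::export(name = ".cpp_gru_sample")]]
Rcpp::IntegerMatrix cpp_gru_sample(Rcpp::List params, int n, int maxlen,
                                   int start_id, int end_id,
                                   unsigned int seed) {
  Net net = unpack(params);
  int H = net.H, L = net.L, V = net.V;
  std::mt19937 rng(seed);
  auto runif01 = [&rng]() {
    return (rng() + 0.5) / 4294967296.0;  // in (0,1)
  };

  Rcpp::IntegerMatrix out(maxlen, n);
  std::fill(out.begin(), out.end(), 0);

  // process in batches of up to 256 sequences
  int bs = std::min(n, 256);
  for (int off = 0; off < n; off += bs) {
    int B = std::min(bs, n - off);
    std::vector<mat> h(L, zeros<mat>(H, B));
    ivec cur(B);
    cur.fill(start_id);
    uvec alive = ones<uvec>(B);
    mat r, z, nn, hnew;
    for (int t = 0; t < maxlen; ++t) {
      mat x(net.e, B);
      for (int b = 0; b < B; ++b) x.col(b) = net.E.row(cur(b) - 1).t();
      mat inp = x;
      for (int l = 0; l < L; ++l) {
        gru_cell(net.layers[l], inp, h[l], H, r, z, nn, hnew);
        h[l] = hnew;
        inp = h[l];
      }
      mat logits = net.Wo * h[L - 1];
      logits.each_col() += net.bo;
      mat p = softmax_cols(logits);
      bool any_alive = false;
      for (int b = 0; b < B; ++b) {
        if (!alive(b)) continue;
        double u = runif01();
        double acc = 0.0;
        int pick = V;
        for (int k = 0; k < V; ++k) {
          acc += p(k, b);
          if (u <= acc) { pick = k + 1; break; }
        }
        cur(b) = pick;
        if (pick == end_id) {
          alive(b) = 0;
        } else {
          out(t, off + b) = pick;
          any_alive = true;
        }
      }
      if (!any_alive) break;
    }
  }
  return out;
}
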