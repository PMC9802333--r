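// Edge-network numerics: MLP forward/backward, forward-mode position
// tangents (potential-mode node operator), and fused per-batch loss +
// parameter-gradient routines for the physics-operator model and the
// learned-node baselines. All matrices are row-per-sample; weight W[l]
// is (in x out) so Z = H * W + b.
//
// The transcendental primitive of each hidden layer (sigmoid for SiLU,
// tanh for tanh) is computed once in the forward pass and cached; the
// activation and its first/second derivatives are cheap algebraic
// functions of it, which matters because exp dominates the elementwise
// cost at training time.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

// activation codes: 0 = silu, 1 = tanh, 2 = relu, 3 = leaky relu (0.01)

// primitive S: sigmoid(z) for silu, tanh(z) for tanh, empty otherwise
static void act_fwd(const mat& z, int act, mat& h, mat& s) {
  switch (act) {
  case 0: s = 1.0 / (1.0 + arma::exp(-z)); h = z % s; return;
  case 1: s = arma::tanh(z); h = s; return;
  case 2: h = arma::clamp(z, 0.0, arma::datum::inf); return;
  case 3: h = arma::max(z, 0.01 * z); return;
  }
  stop("unknown activation code");
}

// first derivative from z and the cached primitive
static mat act_d(const mat& z, const mat& s, int act) {
  switch (act) {
  case 0: return s + (z % s) % (1.0 - s);
  case 1: return 1.0 - s % s;
  case 2: return arma::conv_to<mat>::from(z > 0.0);
  case 3: { mat d(z.n_rows, z.n_cols, arma::fill::value(0.01));
            d.elem(arma::find(z > 0.0)).fill(1.0); return d; }
  }
  stop("unknown activation code");
}

// second derivative; needed when backpropagating through the tangent pass
static mat act_dd(const mat& z, const mat& s, int act) {
  switch (act) {
  case 0: return (s % (1.0 - s)) % (2.0 + z % (1.0 - 2.0 * s));
  case 1: return -2.0 * s % (1.0 - s % s);
  case 2:
  case 3: return mat(z.n_rows, z.n_cols, arma::fill::zeros);
  }
  stop("unknown activation code");
}

static void get_params(const List& Wl, const List& bl,
                       std::vector<mat>& W, std::vector<vec>& b) {
  int L = Wl.size();
  if ((int)bl.size() != L) stop("W and b length mismatch");
  W.resize(L); b.resize(L);
  for (int l = 0; l < L; l++) {
    W[l] = as<mat>(Wl[l]);
    b[l] = as<vec>(bl[l]);
  }
}

static List wrap_mats(const std::vector<mat>& v) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); i++) out[i] = v[i];
  return out;
}
static List wrap_vecs(const std::vector<vec>& v) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); i++) out[i] = v[i];
  return out;
}

// H[l] is the input of layer l, Z[l] its pre-activation, S[l] the cached
// activation primitive of layer l (hidden layers only)
struct Cache { std::vector<mat> H, Z, S; };

// plain forward; output layer is linear
static mat mlp_fwd(const std::vector<mat>& W, const std::vector<vec>& b,
                   const mat& X, int act, Cache* c) {
  int L = W.size();
  mat h = X;
  if (c) { c->H.resize(L); c->Z.resize(L); c->S.resize(L); }
  for (int l = 0; l < L; l++) {
    if ((int)h.n_cols != (int)W[l].n_rows) stop("feature layout mismatch in MLP");
    if (c) c->H[l] = h;
    mat z = h * W[l];
    z.each_row() += b[l].t();
    if (l == L - 1) {
      if (c) c->Z[l] = z;
      h = z;
    } else {
      mat s;
      act_fwd(z, act, h, s);
      if (c) { c->Z[l] = std::move(z); c->S[l] = std::move(s); }
    }
  }
  return h;
}

// reverse pass; outbar is dLoss/dOutput
static void mlp_bwd(const std::vector<mat>& W, const Cache& c, const mat& outbar,
                    int act, std::vector<mat>& gW, std::vector<vec>& gb,
                    mat* inbar) {
  int L = W.size();
  gW.resize(L); gb.resize(L);
  mat zbar = outbar;
  for (int l = L - 1; l >= 0; l--) {
    gW[l] = c.H[l].t() * zbar;
    gb[l] = arma::sum(zbar, 0).t();
    if (l > 0) {
      zbar = (zbar * W[l].t()) % act_d(c.Z[l - 1], c.S[l - 1], act);
    } else if (inbar) {
      *inbar = zbar * W[0].t();
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_mlp_forward(List Wl, List bl, const arma::mat& X, int act) {
  std::vector<mat> W; std::vector<vec> b;
  get_params(Wl, bl, W, b);
  return mlp_fwd(W, b, X, act, nullptr);
}

// ---------------------------------------------------------------------------
// Force-mode batch: accel_i = scale_i * sum of incoming messages.
// scale is 1/m (physics operator) or 10^-w (GN+). Optional symmetry
// regularizer alpha * mean over directed edges of l1(M_e + M_rev(e)).
// recv and rev are 0-based. Loss = sum |A - target| / n_nodes (+ reg).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_force_batch(List Wl, List bl, const arma::mat& X, const arma::uvec& recv,
                     const arma::vec& scale, const arma::mat& target, int act,
                     double alpha, const arma::uvec& rev, bool want_grad) {
  std::vector<mat> W; std::vector<vec> b;
  get_params(Wl, bl, W, b);
  Cache c;
  mat M = mlp_fwd(W, b, X, act, want_grad ? &c : nullptr);
  arma::uword nnodes = target.n_rows;
  mat S(nnodes, M.n_cols, arma::fill::zeros);
  for (arma::uword e = 0; e < recv.n_elem; e++) S.row(recv[e]) += M.row(e);
  mat A = S;
  A.each_col() %= scale;
  mat diff = A - target;
  double loss = arma::accu(arma::abs(diff)) / nnodes;
  mat Msym;
  if (alpha > 0.0) {
    Msym = M + M.rows(rev);
    loss += alpha * arma::accu(arma::abs(Msym)) / M.n_rows;
  }
  List out = List::create(_["loss"] = loss, _["accel"] = A, _["msg_sum"] = S);
  if (want_grad) {
    mat abar = arma::sign(diff) / (double)nnodes;
    vec gscale = arma::sum(abar % S, 1);
    mat sbar = abar;
    sbar.each_col() %= scale;
    mat Mbar = sbar.rows(recv);
    if (alpha > 0.0)
      Mbar += (2.0 * alpha / M.n_rows) * arma::sign(Msym);
    std::vector<mat> gW; std::vector<vec> gb;
    mlp_bwd(W, c, Mbar, act, gW, gb, nullptr);
    out["gW"] = wrap_mats(gW);
    out["gb"] = wrap_vecs(gb);
    out["gscale"] = gscale;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Potential mode. The edge net outputs a scalar message per edge; the node
// operator needs g_e = dM_e/dr_i, the derivative through the receiver-position
// input slots (+1 seed) and, for periodic layouts, the displacement slots
// (-1 seed, since the stored displacement points from receiver to sender).
// Computed with forward-mode tangents, one per spatial direction; parameter
// gradients reverse through the combined primal+tangent computation, which
// requires the activation's second derivative.
// ---------------------------------------------------------------------------

struct TangentCache {
  std::vector<mat> H, Z, S, D;           // primal + act_d per hidden layer
  std::vector<std::vector<mat>> Zd;      // Zd[k][l], tangent pre-activations
};

// pos_cols/disp_cols 0-based; disp_cols may be empty
static void tangent_fwd(const std::vector<mat>& W, const std::vector<vec>& b,
                        const mat& X, int act, const uvec& pos_cols,
                        const uvec& disp_cols, mat& M, mat& G, TangentCache* tc) {
  int L = W.size();
  int d = pos_cols.n_elem;
  bool has_disp = disp_cols.n_elem > 0;
  if (W[L - 1].n_cols != 1) stop("potential-mode edge net must have scalar output");
  mat h = X;
  std::vector<mat> hd(d);  // current-layer activation tangents (l >= 1)
  std::vector<mat> zd(d);
  if (tc) {
    tc->H.resize(L); tc->Z.resize(L); tc->S.resize(L); tc->D.resize(L);
    tc->Zd.assign(d, std::vector<mat>(L));
  }
  for (int l = 0; l < L; l++) {
    if (tc) tc->H[l] = h;
    mat z = h * W[l];
    z.each_row() += b[l].t();
    for (int k = 0; k < d; k++) {
      if (l == 0) {
        arma::rowvec wrow = W[0].row(pos_cols[k]);
        if (has_disp) wrow -= W[0].row(disp_cols[k]);
        zd[k].set_size(X.n_rows, W[0].n_cols);
        zd[k].each_row() = wrow;
      } else {
        zd[k] = hd[k] * W[l];
      }
      if (tc) tc->Zd[k][l] = zd[k];
    }
    if (l < L - 1) {
      mat s;
      act_fwd(z, act, h, s);
      mat dz = act_d(z, s, act);
      for (int k = 0; k < d; k++) hd[k] = dz % zd[k];
      if (tc) {
        tc->Z[l] = std::move(z); tc->S[l] = std::move(s);
        tc->D[l] = std::move(dz);
      }
    } else {
      M = z;
      G.set_size(X.n_rows, d);
      for (int k = 0; k < d; k++) G.col(k) = zd[k];
      if (tc) tc->Z[l] = std::move(z);
    }
  }
}

// [[Rcpp::export]]
List cpp_edge_tangent(List Wl, List bl, const arma::mat& X, int act,
                      const arma::uvec& pos_cols, const arma::uvec& disp_cols) {
  std::vector<mat> W; std::vector<vec> b;
  get_params(Wl, bl, W, b);
  mat M, G;
  tangent_fwd(W, b, X, act, pos_cols, disp_cols, M, G, nullptr);
  return List::create(_["M"] = M, _["G"] = G);
}

// [[Rcpp::export]]
List cpp_potential_batch(List Wl, List bl, const arma::mat& X, const arma::uvec& recv,
                         const arma::vec& scale, const arma::mat& target, int act,
                         const arma::uvec& pos_cols, const arma::uvec& disp_cols,
                         bool want_grad) {
  std::vector<mat> W; std::vector<vec> b;
  get_params(Wl, bl, W, b);
  int L = W.size();
  int d = pos_cols.n_elem;
  bool has_disp = disp_cols.n_elem > 0;
  TangentCache tc;
  mat M, G;
  tangent_fwd(W, b, X, act, pos_cols, disp_cols, M, G, want_grad ? &tc : nullptr);
  arma::uword nnodes = target.n_rows;
  mat S(nnodes, d, arma::fill::zeros);
  for (arma::uword e = 0; e < recv.n_elem; e++) S.row(recv[e]) += G.row(e);
  mat A = -S;
  A.each_col() %= scale;
  mat diff = A - target;
  double loss = arma::accu(arma::abs(diff)) / nnodes;
  List out = List::create(_["loss"] = loss, _["accel"] = A, _["M"] = M, _["G"] = G);
  if (!want_grad) return out;

  mat abar = arma::sign(diff) / (double)nnodes;
  vec gscale = -arma::sum(abar % S, 1);
  mat sbar = abar;
  sbar.each_col() %= -scale;     // dL/dS
  mat Gbar = sbar.rows(recv);    // dL/dg_e per direction

  std::vector<mat> gW(L); std::vector<vec> gb(L);
  mat zbar(X.n_rows, 1, arma::fill::zeros);  // primal output not in the loss
  std::vector<mat> zdbar(d);
  for (int k = 0; k < d; k++) zdbar[k] = Gbar.col(k);
  for (int l = L - 1; l >= 0; l--) {
    gW[l] = tc.H[l].t() * zbar;
    gb[l] = arma::sum(zbar, 0).t();
    if (l > 0) {
      const mat& dz = tc.D[l - 1];
      for (int k = 0; k < d; k++) {
        mat hd = dz % tc.Zd[k][l - 1];       // tangent activations feeding layer l
        gW[l] += hd.t() * zdbar[k];
      }
      mat hbar = zbar * W[l].t();
      mat zbar_new = hbar % dz;
      mat ddz = act_dd(tc.Z[l - 1], tc.S[l - 1], act);
      for (int k = 0; k < d; k++) {
        mat hdbar = zdbar[k] * W[l].t();
        zbar_new += hdbar % tc.Zd[k][l - 1] % ddz;
        zdbar[k] = hdbar % dz;
      }
      zbar = std::move(zbar_new);
    } else {
      // layer-0 tangent inputs are constant one-hot seeds
      for (int k = 0; k < d; k++) {
        arma::rowvec cs = arma::sum(zdbar[k], 0);
        gW[0].row(pos_cols[k]) += cs;
        if (has_disp) gW[0].row(disp_cols[k]) -= cs;
      }
    }
  }
  out["gW"] = wrap_mats(gW);
  out["gb"] = wrap_vecs(gb);
  out["gscale"] = gscale;
  return out;
}

// ---------------------------------------------------------------------------
// Learned-node baseline: edge MLP -> aggregate -> node MLP on
// concat(node features, message sum). Optional symmetry regularizer on the
// edge messages (alpha > 0 gives the symmetry-regularized variant).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_baseline_batch(List eWl, List ebl, List nWl, List nbl,
                        const arma::mat& Xe, const arma::uvec& recv,
                        const arma::mat& Xn, const arma::mat& target, int act,
                        double alpha, const arma::uvec& rev, bool want_grad) {
  std::vector<mat> eW, nW; std::vector<vec> eb, nb;
  get_params(eWl, ebl, eW, eb);
  get_params(nWl, nbl, nW, nb);
  Cache ec, nc;
  mat M = mlp_fwd(eW, eb, Xe, act, want_grad ? &ec : nullptr);
  arma::uword nnodes = target.n_rows;
  mat S(nnodes, M.n_cols, arma::fill::zeros);
  for (arma::uword e = 0; e < recv.n_elem; e++) S.row(recv[e]) += M.row(e);
  mat Xin = arma::join_rows(Xn, S);
  mat A = mlp_fwd(nW, nb, Xin, act, want_grad ? &nc : nullptr);
  mat diff = A - target;
  double loss = arma::accu(arma::abs(diff)) / nnodes;
  mat Msym;
  if (alpha > 0.0) {
    Msym = M + M.rows(rev);
    loss += alpha * arma::accu(arma::abs(Msym)) / M.n_rows;
  }
  List out = List::create(_["loss"] = loss, _["accel"] = A,
                          _["M"] = M, _["msg_sum"] = S);
  if (!want_grad) return out;
  mat abar = arma::sign(diff) / (double)nnodes;
  std::vector<mat> gnW; std::vector<vec> gnb;
  mat xinbar;
  mlp_bwd(nW, nc, abar, act, gnW, gnb, &xinbar);
  mat Sbar = xinbar.cols(Xn.n_cols, Xin.n_cols - 1);
  mat Mbar = Sbar.rows(recv);
  if (alpha > 0.0)
    Mbar += (2.0 * alpha / M.n_rows) * arma::sign(Msym);
  std::vector<mat> geW; std::vector<vec> geb;
  mlp_bwd(eW, ec, Mbar, act, geW, geb, nullptr);
  out["geW"] = wrap_mats(geW);
  out["geb"] = wrap_vecs(geb);
  out["gnW"] = wrap_mats(gnW);
  out["gnb"] = wrap_vecs(gnb);
  return out;
}
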