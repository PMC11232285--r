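// Residual-MLP cycle-consistent GAN engine.
//
// Data layout is features x samples (column-major batches) so that dense
// layers are single dgemm calls. All randomness (weight init, shuffling)
// comes from a std::mt19937_64 seeded from R, never from R's RNG, so a
// training run is reproducible from its integer seed alone.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::stop;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;
static const double ADAM_EPS = 1e-8;

struct AdamCfg {
  double lr, beta1, beta2;
};

// ---------------------------------------------------------------- dense ----

struct Dense {
  mat W; vec b;
  mat gW; vec gb;
  mat mW, vW; vec mb, vb;
  mat Xc;  // cached input of the last forward (consumed by bwd)

  void init(int in, int out, std::mt19937_64& rng, double gain) {
    std::normal_distribution<double> nd(0.0, std::sqrt(gain / (double)in));
    W.set_size(out, in);
    for (uword i = 0; i < W.n_elem; ++i) W[i] = nd(rng);
    b.zeros(out);
    zero_grad();
    mW.zeros(out, in); vW.zeros(out, in); mb.zeros(out); vb.zeros(out);
  }
  void zero_grad() { gW.zeros(W.n_rows, W.n_cols); gb.zeros(b.n_elem); }
  mat fwd(const mat& X) {
    Xc = X;
    mat Y = W * X;
    Y.each_col() += b;
    return Y;
  }
  // forward without caching (no backward planned)
  mat fwd_nograd(const mat& X) const {
    mat Y = W * X;
    Y.each_col() += b;
    return Y;
  }
  mat bwd(const mat& dY, bool accum = true, bool need_dx = true) {
    if (accum) { gW += dY * Xc.t(); gb += sum(dY, 1); }
    if (!need_dx) return mat();
    return W.t() * dY;
  }
  void step(const AdamCfg& a, double corr) {
    mW = a.beta1 * mW + (1 - a.beta1) * gW;
    vW = a.beta2 * vW + (1 - a.beta2) * square(gW);
    W -= corr * mW / (sqrt(vW) + ADAM_EPS);
    mb = a.beta1 * mb + (1 - a.beta1) * gb;
    vb = a.beta2 * vb + (1 - a.beta2) * square(gb);
    b -= corr * mb / (sqrt(vb) + ADAM_EPS);
  }
};

// ----------------------------------------------------------- batch norm ----

struct BNorm {
  vec g, be, rm, rv;
  vec gg, gbe;
  vec mg, vg, mbe, vbe;
  mat Xhat; vec inv_sd;  // caches

  void init(int d) {
    g.ones(d); be.zeros(d); rm.zeros(d); rv.ones(d);
    zero_grad();
    mg.zeros(d); vg.zeros(d); mbe.zeros(d); vbe.zeros(d);
  }
  void zero_grad() { gg.zeros(g.n_elem); gbe.zeros(g.n_elem); }
  mat fwd(const mat& X, bool train, bool update_running) {
    if (train) {
      double N = (double)X.n_cols;
      vec mu = mean(X, 1);
      mat Xc = X.each_col() - mu;
      vec va = mean(square(Xc), 1);  // population variance of the batch
      inv_sd = 1.0 / sqrt(va + BN_EPS);
      Xhat = Xc.each_col() % inv_sd;
      if (update_running) {
        double ub = (N > 1.0) ? N / (N - 1.0) : 1.0;
        rm = (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu;
        rv = (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * (ub * va);
      }
      mat Y = Xhat.each_col() % g;
      Y.each_col() += be;
      return Y;
    }
    vec is = 1.0 / sqrt(rv + BN_EPS);
    mat Y = X.each_col() - rm;
    Y.each_col() %= (is % g);
    Y.each_col() += be;
    return Y;
  }
  mat bwd(const mat& dY, bool accum = true) {
    if (accum) { gbe += sum(dY, 1); gg += sum(dY % Xhat, 1); }
    double N = (double)dY.n_cols;
    mat dXh = dY.each_col() % g;
    vec s1 = sum(dXh, 1);
    vec s2 = sum(dXh % Xhat, 1);
    mat dX = N * dXh;
    dX.each_col() -= s1;
    dX -= Xhat.each_col() % s2;
    dX.each_col() %= (inv_sd / N);
    return dX;
  }
  void step(const AdamCfg& a, double corr) {
    mg = a.beta1 * mg + (1 - a.beta1) * gg;
    vg = a.beta2 * vg + (1 - a.beta2) * square(gg);
    g -= corr * mg / (sqrt(vg) + ADAM_EPS);
    mbe = a.beta1 * mbe + (1 - a.beta1) * gbe;
    vbe = a.beta2 * vbe + (1 - a.beta2) * square(gbe);
    be -= corr * mbe / (sqrt(vbe) + ADAM_EPS);
  }
};

static inline mat relu(mat X) {
  X.transform([](double v) { return v > 0 ? v : 0.0; });
  return X;
}
// zero the entries of dx where the (post-ReLU) activation was clipped
static inline void mask_relu(mat& dx, const mat& act) {
  for (uword i = 0; i < dx.n_elem; ++i)
    if (act[i] <= 0) dx[i] = 0.0;
}

// ------------------------------------------------------------ generator ----
//
// dense+BN+ReLU x2 -> residual block x3 -> dense+BN+ReLU x2 -> dense(linear)
// residual block: y = x + BN(dense(ReLU(BN(dense(x))))), no post-skip
// activation. All hidden layers share one width.

struct Generator {
  int d = 0, h = 0, nres = 3;
  Dense d0, d1, d2, d3, dout;
  std::vector<Dense> ra, rb;
  BNorm b0, b1, b2, b3;
  std::vector<BNorm> bra, brb;
  long t = 0;  // adam step counter
  // activation caches (post-ReLU), consumed by backward
  mat m0, m1, m2, m3;
  std::vector<mat> mr;

  void init(int d_, int h_, int nres_, std::uint64_t seed) {
    d = d_; h = h_; nres = nres_;
    std::mt19937_64 rng(seed);
    d0.init(d, h, rng, 2.0);
    d1.init(h, h, rng, 2.0);
    ra.assign(nres, Dense()); rb.assign(nres, Dense());
    bra.assign(nres, BNorm()); brb.assign(nres, BNorm());
    for (int r = 0; r < nres; ++r) {
      ra[r].init(h, h, rng, 2.0);
      rb[r].init(h, h, rng, 2.0);
      bra[r].init(h); brb[r].init(h);
    }
    d2.init(h, h, rng, 2.0);
    d3.init(h, h, rng, 2.0);
    dout.init(h, d, rng, 1.0);
    b0.init(h); b1.init(h); b2.init(h); b3.init(h);
    mr.assign(nres, mat());
    t = 0;
  }

  mat forward(const mat& X, bool train, bool upd) {
    m0 = relu(b0.fwd(d0.fwd(X), train, upd));
    m1 = relu(b1.fwd(d1.fwd(m0), train, upd));
    mat x = m1;
    for (int r = 0; r < nres; ++r) {
      mr[r] = relu(bra[r].fwd(ra[r].fwd(x), train, upd));
      x += brb[r].fwd(rb[r].fwd(mr[r]), train, upd);
    }
    m2 = relu(b2.fwd(d2.fwd(x), train, upd));
    m3 = relu(b3.fwd(d3.fwd(m2), train, upd));
    return dout.fwd(m3);
  }

  // mirrors forward exactly: through dout, then (ReLU, BN, dense) of layer
  // 3 and 2, the residual blocks in reverse, then layers 1 and 0
  mat backward(const mat& dOut, bool need_dx = true) {
    mat dx = dout.bwd(dOut);           // grad wrt m3
    mask_relu(dx, m3);
    dx = d3.bwd(b3.bwd(dx));           // grad wrt m2
    mask_relu(dx, m2);
    dx = d2.bwd(b2.bwd(dx));           // grad wrt last block output
    for (int r = nres - 1; r >= 0; --r) {
      mat dt = rb[r].bwd(brb[r].bwd(dx));  // grad wrt branch activation t
      mask_relu(dt, mr[r]);
      dx += ra[r].bwd(bra[r].bwd(dt));     // skip path + branch path
    }
    mask_relu(dx, m1);                 // dx is grad wrt m1
    dx = d1.bwd(b1.bwd(dx));           // grad wrt m0
    mask_relu(dx, m0);
    return d0.bwd(b0.bwd(dx), true, need_dx);
  }

  void zero_grad() {
    d0.zero_grad(); d1.zero_grad(); d2.zero_grad(); d3.zero_grad();
    dout.zero_grad();
    b0.zero_grad(); b1.zero_grad(); b2.zero_grad(); b3.zero_grad();
    for (int r = 0; r < nres; ++r) {
      ra[r].zero_grad(); rb[r].zero_grad();
      bra[r].zero_grad(); brb[r].zero_grad();
    }
  }
  void step(const AdamCfg& a) {
    ++t;
    double corr = a.lr * std::sqrt(1.0 - std::pow(a.beta2, (double)t)) /
                  (1.0 - std::pow(a.beta1, (double)t));
    d0.step(a, corr); d1.step(a, corr); d2.step(a, corr); d3.step(a, corr);
    dout.step(a, corr);
    b0.step(a, corr); b1.step(a, corr); b2.step(a, corr); b3.step(a, corr);
    for (int r = 0; r < nres; ++r) {
      ra[r].step(a, corr); rb[r].step(a, corr);
      bra[r].step(a, corr); brb[r].step(a, corr);
    }
  }
};

// -------------------------------------------------------- discriminator ----
//
// dense+leakyReLU x3 -> dense(1, linear); unbounded scalar output (LSGAN).

struct Discrim {
  int d = 0; ivec widths;
  double slope = 0.2;
  Dense l1, l2, l3, l4;
  long t = 0;
  mat a1, a2, a3;  // post-activation caches

  void init(int d_, int w1, int w2, int w3, double slope_, std::uint64_t seed) {
    d = d_; slope = slope_;
    std::mt19937_64 rng(seed);
    l1.init(d, w1, rng, 2.0);
    l2.init(w1, w2, rng, 2.0);
    l3.init(w2, w3, rng, 2.0);
    l4.init(w3, 1, rng, 1.0);
    t = 0;
  }
  mat lrelu(const mat& X) const {
    return clamp(X, 0.0, datum::inf) + slope * clamp(X, -datum::inf, 0.0);
  }
  rowvec forward(const mat& X) {
    a1 = lrelu(l1.fwd(X));
    a2 = lrelu(l2.fwd(a1));
    a3 = lrelu(l3.fwd(a2));
    return conv_to<rowvec>::from(l4.fwd(a3));
  }
  mat lrelu_grad(const mat& act) const {
    // slope > 0 preserves sign, so the post-activation sign recovers the
    // pre-activation region; at slope == 0 the zero region has gradient 0.
    mat g(act.n_rows, act.n_cols);
    for (uword i = 0; i < act.n_elem; ++i) g[i] = act[i] > 0 ? 1.0 : slope;
    return g;
  }
  mat backward(const rowvec& dY, bool accum) {
    mat d4 = l4.bwd(conv_to<mat>::from(dY), accum);
    mat d3_ = l3.bwd(d4 % lrelu_grad(a3), accum);
    mat d2_ = l2.bwd(d3_ % lrelu_grad(a2), accum);
    return l1.bwd(d2_ % lrelu_grad(a1), accum);
  }
  void zero_grad() { l1.zero_grad(); l2.zero_grad(); l3.zero_grad(); l4.zero_grad(); }
  void step(const AdamCfg& a) {
    ++t;
    double corr = a.lr * std::sqrt(1.0 - std::pow(a.beta2, (double)t)) /
                  (1.0 - std::pow(a.beta1, (double)t));
    l1.step(a, corr); l2.step(a, corr); l3.step(a, corr); l4.step(a, corr);
  }
};

// -------------------------------------------------------- serialization ----

static List dense_to_list(const Dense& L) {
  return List::create(Named("W") = L.W, Named("b") = L.b);
}
static void dense_from_list(Dense& L, const List& x) {
  L.W = Rcpp::as<mat>(x["W"]);
  L.b = Rcpp::as<vec>(x["b"]);
  L.zero_grad();
  L.mW.zeros(L.W.n_rows, L.W.n_cols); L.vW.zeros(L.W.n_rows, L.W.n_cols);
  L.mb.zeros(L.b.n_elem); L.vb.zeros(L.b.n_elem);
}
static List bn_to_list(const BNorm& B) {
  return List::create(Named("gamma") = B.g, Named("beta") = B.be,
                      Named("run_mean") = B.rm, Named("run_var") = B.rv);
}
static void bn_from_list(BNorm& B, const List& x) {
  B.g = Rcpp::as<vec>(x["gamma"]);
  B.be = Rcpp::as<vec>(x["beta"]);
  B.rm = Rcpp::as<vec>(x["run_mean"]);
  B.rv = Rcpp::as<vec>(x["run_var"]);
  B.zero_grad();
  int d = B.g.n_elem;
  B.mg.zeros(d); B.vg.zeros(d); B.mbe.zeros(d); B.vbe.zeros(d);
}

static List gen_to_list(const Generator& G) {
  List dense = List::create(
      Named("d0") = dense_to_list(G.d0), Named("d1") = dense_to_list(G.d1),
      Named("d2") = dense_to_list(G.d2), Named("d3") = dense_to_list(G.d3),
      Named("dout") = dense_to_list(G.dout));
  List res(G.nres);
  for (int r = 0; r < G.nres; ++r)
    res[r] = List::create(Named("da") = dense_to_list(G.ra[r]),
                          Named("bna") = bn_to_list(G.bra[r]),
                          Named("db") = dense_to_list(G.rb[r]),
                          Named("bnb") = bn_to_list(G.brb[r]));
  List bn = List::create(Named("b0") = bn_to_list(G.b0), Named("b1") = bn_to_list(G.b1),
                         Named("b2") = bn_to_list(G.b2), Named("b3") = bn_to_list(G.b3));
  return List::create(Named("input_dim") = G.d, Named("hidden_width") = G.h,
                      Named("n_residual_blocks") = G.nres,
                      Named("dense") = dense, Named("bn") = bn,
                      Named("residual") = res);
}

static void gen_from_list(Generator& G, const List& x) {
  G.d = Rcpp::as<int>(x["input_dim"]);
  G.h = Rcpp::as<int>(x["hidden_width"]);
  G.nres = Rcpp::as<int>(x["n_residual_blocks"]);
  List dense = x["dense"], bn = x["bn"], res = x["residual"];
  dense_from_list(G.d0, dense["d0"]); dense_from_list(G.d1, dense["d1"]);
  dense_from_list(G.d2, dense["d2"]); dense_from_list(G.d3, dense["d3"]);
  dense_from_list(G.dout, dense["dout"]);
  bn_from_list(G.b0, bn["b0"]); bn_from_list(G.b1, bn["b1"]);
  bn_from_list(G.b2, bn["b2"]); bn_from_list(G.b3, bn["b3"]);
  G.ra.assign(G.nres, Dense()); G.rb.assign(G.nres, Dense());
  G.bra.assign(G.nres, BNorm()); G.brb.assign(G.nres, BNorm());
  G.mr.assign(G.nres, mat());
  for (int r = 0; r < G.nres; ++r) {
    List blk = res[r];
    dense_from_list(G.ra[r], blk["da"]); bn_from_list(G.bra[r], blk["bna"]);
    dense_from_list(G.rb[r], blk["db"]); bn_from_list(G.brb[r], blk["bnb"]);
  }
  G.t = 0;
}

static List disc_to_list(const Discrim& D) {
  return List::create(Named("input_dim") = D.d, Named("leaky_slope") = D.slope,
                      Named("l1") = dense_to_list(D.l1), Named("l2") = dense_to_list(D.l2),
                      Named("l3") = dense_to_list(D.l3), Named("l4") = dense_to_list(D.l4));
}
static void disc_from_list(Discrim& D, const List& x) {
  D.d = Rcpp::as<int>(x["input_dim"]);
  D.slope = Rcpp::as<double>(x["leaky_slope"]);
  dense_from_list(D.l1, x["l1"]); dense_from_list(D.l2, x["l2"]);
  dense_from_list(D.l3, x["l3"]); dense_from_list(D.l4, x["l4"]);
  D.t = 0;
}

// ------------------------------------------------------------- exports -----

// [[Rcpp::export]]
List cpp_init_generator(int input_dim, int hidden_width, int n_residual_blocks,
                        double seed) {
  if (input_dim < 1 || hidden_width < 1 || n_residual_blocks < 0)
    stop("invalid generator dimensions");
  Generator G;
  G.init(input_dim, hidden_width, n_residual_blocks, (std::uint64_t)seed);
  return gen_to_list(G);
}

// [[Rcpp::export]]
List cpp_init_discriminator(int input_dim, int w1, int w2, int w3,
                            double leaky_slope, double seed) {
  if (input_dim < 1 || w1 < 1 || w2 < 1 || w3 < 1)
    stop("invalid discriminator dimensions");
  Discrim D;
  D.init(input_dim, w1, w2, w3, leaky_slope, (std::uint64_t)seed);
  return disc_to_list(D);
}

// X: features x samples. training = TRUE uses batch statistics (no running
// update), FALSE uses the stored running statistics (inference mode).
// [[Rcpp::export]]
arma::mat cpp_generator_forward(List params, const arma::mat& X, bool training) {
  Generator G;
  gen_from_list(G, params);
  if ((int)X.n_rows != G.d) stop("input dimension mismatch: expected %d rows", G.d);
  return G.forward(X, training, false);
}

// [[Rcpp::export]]
arma::rowvec cpp_discriminator_forward(List params, const arma::mat& X) {
  Discrim D;
  disc_from_list(D, params);
  if ((int)X.n_rows != D.d) stop("input dimension mismatch: expected %d rows", D.d);
  return D.forward(X);
}

// Finite-difference verification of the analytic gradients (used by the
// test suite). Loss: L = accu(G(X) % R) with fixed random R, batch
// statistics active. Checks dL/dX plus every parameter tensor at a few
// sampled coordinates; returns the maximum relative error.
// [[Rcpp::export]]
double cpp_generator_grad_check(int d, int h, int nres, double seed,
                                int n_batch, int n_coords) {
  Generator G;
  G.init(d, h, nres, (std::uint64_t)seed);
  std::mt19937_64 rng((std::uint64_t)seed + 99);
  std::normal_distribution<double> nd(0.0, 1.0);
  mat X(d, n_batch), R(d, n_batch);
  for (auto& v : X) v = std::abs(nd(rng));
  for (auto& v : R) v = nd(rng);

  auto loss = [&]() { return accu(G.forward(X, true, false) % R); };
  double L0 = loss();
  G.zero_grad();
  G.forward(X, true, false);
  mat dX = G.backward(R, true);

  const double eps = 1e-6;
  double max_rel = 0.0;
  auto rel = [&](double analytic, double numeric) {
    double denom = std::max(1.0, std::max(std::fabs(analytic), std::fabs(numeric)));
    return std::fabs(analytic - numeric) / denom;
  };
  std::uniform_int_distribution<int> pick_x(0, d * n_batch - 1);
  for (int k = 0; k < n_coords; ++k) {
    int i = pick_x(rng);
    double old = X[i];
    X[i] = old + eps;
    double Lp = loss();
    X[i] = old;
    max_rel = std::max(max_rel, rel(dX[i], (Lp - L0) / eps));
  }
  std::vector<std::pair<double*, double*>> tensors = {
      {G.d0.W.memptr(), G.d0.gW.memptr()}, {G.d1.W.memptr(), G.d1.gW.memptr()},
      {G.d2.W.memptr(), G.d2.gW.memptr()}, {G.d3.W.memptr(), G.d3.gW.memptr()},
      {G.dout.W.memptr(), G.dout.gW.memptr()},
      {G.b0.g.memptr(), G.b0.gg.memptr()}, {G.b3.be.memptr(), G.b3.gbe.memptr()},
      {G.ra[0].W.memptr(), G.ra[0].gW.memptr()},
      {G.rb[0].W.memptr(), G.rb[0].gW.memptr()},
      {G.bra[0].g.memptr(), G.bra[0].gg.memptr()},
      {G.brb[0].be.memptr(), G.brb[0].gbe.memptr()},
      {G.d0.b.memptr(), G.d0.gb.memptr()}};
  for (auto& tp : tensors) {
    for (int k = 0; k < 3; ++k) {
      int i = k * 7 % h;  // deterministic spread of coordinates
      double old = tp.first[i];
      tp.first[i] = old + eps;
      double Lp = loss();
      tp.first[i] = old;
      max_rel = std::max(max_rel, rel(tp.second[i], (Lp - L0) / eps));
    }
  }
  return max_rel;
}

// Same check for the discriminator: L = accu(D(X) % r).
// [[Rcpp::export]]
double cpp_discriminator_grad_check(int d, double seed, int n_batch,
                                    int n_coords) {
  Discrim D;
  D.init(d, 8, 6, 4, 0.2, (std::uint64_t)seed);
  std::mt19937_64 rng((std::uint64_t)seed + 7);
  std::normal_distribution<double> nd(0.0, 1.0);
  mat X(d, n_batch);
  rowvec r(n_batch);
  for (auto& v : X) v = nd(rng);
  for (auto& v : r) v = nd(rng);
  auto loss = [&]() { return accu(D.forward(X) % r); };
  double L0 = loss();
  D.zero_grad();
  D.forward(X);
  mat dX = D.backward(r, true);
  const double eps = 1e-6;
  double max_rel = 0.0;
  auto rel = [&](double analytic, double numeric) {
    double denom = std::max(1.0, std::max(std::fabs(analytic), std::fabs(numeric)));
    return std::fabs(analytic - numeric) / denom;
  };
  std::uniform_int_distribution<int> pick_x(0, d * n_batch - 1);
  for (int k = 0; k < n_coords; ++k) {
    int i = pick_x(rng);
    double old = X[i];
    X[i] = old + eps;
    max_rel = std::max(max_rel, rel(dX[i], (loss() - L0) / eps));
    X[i] = old;
  }
  for (int k = 0; k < 4; ++k) {
    double old = D.l2.W[k];
    D.l2.W[k] = old + eps;
    max_rel = std::max(max_rel, rel(D.l2.gW[k], (loss() - L0) / eps));
    D.l2.W[k] = old;
  }
  return max_rel;
}

static inline void check_finite(double v, const char* what, int pass, int batch) {
  if (!std::isfinite(v))
    stop("non-finite %s loss (%.4g) at pass %d, batch %d: training diverged",
         what, v, pass + 1, batch + 1);
}

// Full adversarial training loop.
//
// cfg fields: epochs, batch_size, g_steps_per_d_step, n_repeats,
// lambda_cycle, lambda_identity, learning_rate, beta1, beta2, seed,
// freeze_generators, restart_each_repeat.
//
// Returns updated network parameter lists, a per-pass (epoch x repeat) loss
// history and the per-update discriminator loss trace.
// [[Rcpp::export]]
List cpp_train(List gab, List gba, List da, List db,
               const arma::mat& A, const arma::mat& B, List cfg) {
  Generator GAB, GBA;
  Discrim DA, DB;
  gen_from_list(GAB, gab); gen_from_list(GBA, gba);
  disc_from_list(DA, da); disc_from_list(DB, db);
  if (A.n_rows != B.n_rows) stop("domain feature dimensions differ");
  if ((int)A.n_rows != GAB.d) stop("domain dimension does not match model");

  const int epochs = Rcpp::as<int>(cfg["epochs"]);
  const int bs = Rcpp::as<int>(cfg["batch_size"]);
  const int g_steps = Rcpp::as<int>(cfg["g_steps_per_d_step"]);
  const int n_rep = Rcpp::as<int>(cfg["n_repeats"]);
  const double lc = Rcpp::as<double>(cfg["lambda_cycle"]);
  const double li = Rcpp::as<double>(cfg["lambda_identity"]);
  const bool freeze_g = Rcpp::as<bool>(cfg["freeze_generators"]);
  const bool restart = Rcpp::as<bool>(cfg["restart_each_repeat"]);
  AdamCfg adam{Rcpp::as<double>(cfg["learning_rate"]),
               Rcpp::as<double>(cfg["beta1"]), Rcpp::as<double>(cfg["beta2"])};
  AdamCfg adam_d{Rcpp::as<double>(cfg["d_learning_rate"]),
                 Rcpp::as<double>(cfg["beta1"]), Rcpp::as<double>(cfg["beta2"])};
  const std::uint64_t seed = (std::uint64_t)Rcpp::as<double>(cfg["seed"]);

  const int nA = A.n_cols, nB = B.n_cols;
  const int nL = std::max(nA, nB);
  const int n_batches = (nL + bs - 1) / bs;
  const int n_pass = epochs * n_rep;

  mat history(n_pass, 6, fill::zeros);
  std::vector<double> d_trace;
  d_trace.reserve((size_t)n_pass * n_batches);

  std::mt19937_64 rng(seed + 0x9e3779b9ULL);

  // cyclic sampler over the smaller domain
  const bool a_large = nA >= nB;
  std::vector<uword> permL(nL), permS(std::min(nA, nB));
  for (int i = 0; i < nL; ++i) permL[i] = i;
  for (size_t i = 0; i < permS.size(); ++i) permS[i] = i;
  size_t posS = 0;

  int pass = 0;
  for (int rep = 0; rep < n_rep; ++rep) {
    if (restart && rep > 0) {
      std::uint64_t s2 = seed + 7919ULL * (std::uint64_t)rep;
      GAB.init(GAB.d, GAB.h, GAB.nres, s2 + 1);
      GBA.init(GBA.d, GBA.h, GBA.nres, s2 + 2);
      DA.init(DA.d, DA.l1.W.n_rows, DA.l2.W.n_rows, DA.l3.W.n_rows, DA.slope, s2 + 3);
      DB.init(DB.d, DB.l1.W.n_rows, DB.l2.W.n_rows, DB.l3.W.n_rows, DB.slope, s2 + 4);
    }
    for (int ep = 0; ep < epochs; ++ep, ++pass) {
      std::shuffle(permL.begin(), permL.end(), rng);
      double acc_gab = 0, acc_gba = 0, acc_cyc = 0, acc_id = 0, acc_d = 0;
      for (int bi = 0; bi < n_batches; ++bi) {
        const int lo = bi * bs;
        const int m = std::min(bs, nL - lo);
        uvec idxL(m), idxS(m);
        for (int j = 0; j < m; ++j) {
          idxL[j] = permL[lo + j];
          if (posS >= permS.size()) {
            std::shuffle(permS.begin(), permS.end(), rng);
            posS = 0;
          }
          idxS[j] = permS[posS++];
        }
        mat a = A.cols(a_large ? idxL : idxS);
        mat b = B.cols(a_large ? idxS : idxL);
        double dm = (double)m;

        double cyc = datum::nan, idl = datum::nan;
        if (!freeze_g) {
          for (int s = 0; s < g_steps; ++s) {
            GAB.zero_grad(); GBA.zero_grad();
            // A -> B -> A path
            mat fakeB = GAB.forward(a, true, true);
            rowvec vB = DB.forward(fakeB);
            mat dfakeB = DB.backward((2.0 / dm) * (vB - 1.0), false);
            mat recA = GBA.forward(fakeB, true, true);
            double cyc_a = accu(abs(recA - a)) / dm;
            dfakeB += GBA.backward((lc / dm) * sign(recA - a));
            GAB.backward(dfakeB);
            // B -> A -> B path
            mat fakeA = GBA.forward(b, true, true);
            rowvec vA = DA.forward(fakeA);
            mat dfakeA = DA.backward((2.0 / dm) * (vA - 1.0), false);
            mat recB = GAB.forward(fakeA, true, true);
            double cyc_b = accu(abs(recB - b)) / dm;
            dfakeA += GAB.backward((lc / dm) * sign(recB - b));
            GBA.backward(dfakeA);
            cyc = cyc_a + cyc_b;
            // identity terms
            idl = 0.0;
            if (li > 0) {
              mat idB = GAB.forward(b, true, true);
              GAB.backward((li / dm) * sign(idB - b));
              mat idA = GBA.forward(a, true, true);
              GBA.backward((li / dm) * sign(idA - a));
              idl = (accu(abs(idB - b)) + accu(abs(idA - a))) / dm;
            }
            GAB.step(adam); GBA.step(adam);
          }
          check_finite(cyc, "cycle", pass, bi);
        } else {
          // report-only forward passes so the history stays interpretable
          mat fakeB = GAB.forward(a, true, false);
          mat recA = GBA.forward(fakeB, true, false);
          mat fakeA = GBA.forward(b, true, false);
          mat recB = GAB.forward(fakeA, true, false);
          cyc = (accu(abs(recA - a)) + accu(abs(recB - b))) / dm;
          idl = (accu(abs(GAB.forward(b, true, false) - b)) +
                 accu(abs(GBA.forward(a, true, false) - a))) / dm;
        }

        // discriminator update (one per batch)
        mat fakeB = GAB.forward(a, true, false);
        mat fakeA = GBA.forward(b, true, false);
        DB.zero_grad();
        rowvec vRb = DB.forward(b);
        double db_real = accu(square(vRb - 1.0)) / dm;
        DB.backward((2.0 / dm) * (vRb - 1.0), true);
        rowvec vFb = DB.forward(fakeB);
        double db_fake = accu(square(vFb)) / dm;
        DB.backward((2.0 / dm) * vFb, true);
        DB.step(adam_d);
        DA.zero_grad();
        rowvec vRa = DA.forward(a);
        double da_real = accu(square(vRa - 1.0)) / dm;
        DA.backward((2.0 / dm) * (vRa - 1.0), true);
        rowvec vFa = DA.forward(fakeA);
        double da_fake = accu(square(vFa)) / dm;
        DA.backward((2.0 / dm) * vFa, true);
        DA.step(adam_d);

        double gan_ab = db_real + db_fake;  // adversarial objective vs D_B
        double gan_ba = da_real + da_fake;
        check_finite(gan_ab + gan_ba, "adversarial", pass, bi);
        d_trace.push_back(gan_ab + gan_ba);
        acc_gab += gan_ab; acc_gba += gan_ba;
        acc_cyc += cyc; acc_id += idl;
        acc_d += gan_ab + gan_ba;
      }
      history(pass, 0) = acc_gab / n_batches;
      history(pass, 1) = acc_gba / n_batches;
      history(pass, 2) = acc_cyc / n_batches;
      history(pass, 3) = acc_id / n_batches;
      history(pass, 4) = history(pass, 0) + history(pass, 1) +
                         lc * history(pass, 2) + li * history(pass, 3);
      history(pass, 5) = acc_d / n_batches;
    }
  }

  return List::create(
      Named("gen_ab") = gen_to_list(GAB), Named("gen_ba") = gen_to_list(GBA),
      Named("disc_a") = disc_to_list(DA), Named("disc_b") = disc_to_list(DB),
      Named("history") = history,
      Named("d_update_trace") = d_trace,
      Named("batches_per_epoch") = n_batches);
}
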