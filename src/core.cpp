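// Compiled core: interception environment stepping, the two-headed joint
// network (shared ReLU trunk, linear G head + linear transition head),
// Adam updates, replay buffer, and the per-step training loop.
//
// All randomness is drawn from R's RNG (unif_rand / norm_rand) so that
// set.seed() at the R level makes every trajectory reproducible.
//
// Network arithmetic is single precision: a trial is ~7.5e5 minibatch
// updates of a 128-unit trunk and sgemm roughly halves the wall time
// relative to double. R-level oracles in the test suite check the float
// path against double-precision reference implementations.

#include <RcppArmadillo.h>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static const int OUT_ONGOING = 0, OUT_SUCCESS = 1, OUT_MISS = 2;

// ---------------------------------------------------------------- environment

struct EnvC {
  double dt, K, capture_radius, max_dur, target_init_distance;
  double agent_lo, agent_hi, onset_lo, onset_hi, fmean, fsd, ramp;
  std::vector<double> pedal, init_speeds;
};

static EnvC env_from_list(List cfg) {
  EnvC e;
  e.dt = as<double>(cfg["dt"]);
  double kbase = as<double>(cfg["lag_base"]);
  double kmul  = as<double>(cfg["lag_multiplier"]);
  e.K = kbase * kmul;
  e.pedal = as<std::vector<double>>(cfg["pedal_speeds"]);
  NumericVector ar = cfg["agent_init_distance_range"];
  e.agent_lo = ar[0]; e.agent_hi = ar[1];
  e.init_speeds = as<std::vector<double>>(cfg["target_init_speeds"]);
  e.target_init_distance = as<double>(cfg["target_init_distance"]);
  NumericVector orng = cfg["change_onset_range"];
  e.onset_lo = orng[0]; e.onset_hi = orng[1];
  e.fmean = as<double>(cfg["final_speed_mean"]);
  e.fsd   = as<double>(cfg["final_speed_sd"]);
  e.ramp  = as<double>(cfg["ramp_duration"]);
  e.capture_radius = as<double>(cfg["capture_radius"]);
  e.max_dur = as<double>(cfg["max_episode_duration"]);
  return e;
}

struct SetupC { double x_s0, v0, v1, onset, ramp, x_t0; };

static SetupC sample_setup(const EnvC& e) {
  SetupC s;
  s.x_s0 = e.agent_lo + unif_rand() * (e.agent_hi - e.agent_lo);
  int k = (int)(unif_rand() * e.init_speeds.size());
  if (k >= (int)e.init_speeds.size()) k = e.init_speeds.size() - 1;
  s.v0 = e.init_speeds[k];
  s.onset = e.onset_lo + unif_rand() * (e.onset_hi - e.onset_lo);
  // final speed: normal truncated at mean +/- 1 sd, by rejection
  double v1;
  do { v1 = e.fmean + e.fsd * norm_rand(); }
  while (v1 < e.fmean - e.fsd || v1 > e.fmean + e.fsd);
  s.v1 = v1;
  s.ramp = e.ramp;
  s.x_t0 = e.target_init_distance;
  return s;
}

static double speed_at(const SetupC& s, double t) {
  if (t < s.onset) return s.v0;
  if (t < s.onset + s.ramp) return s.v0 + (s.v1 - s.v0) * (t - s.onset) / s.ramp;
  return s.v1;
}

struct StateC {
  double t, x_t, v_t, x_s, v_s;
  int phase;       // 0 pre_change, 1 ramping, 2 post_change
  bool terminal;
  int outcome;     // 0 ongoing, 1 success, 2 miss
};

static StateC init_state(const SetupC& s) {
  StateC st;
  st.t = 0.0; st.x_t = s.x_t0; st.v_t = s.v0; st.x_s = s.x_s0; st.v_s = 0.0;
  st.phase = 0; st.terminal = false; st.outcome = OUT_ONGOING;
  return st;
}

// one 60 Hz step; semi-implicit Euler (updated speeds move the distances)
static void step_env(StateC& st, int action, const SetupC& su, const EnvC& e) {
  double vp = e.pedal[action];
  st.v_s += e.K * (vp - st.v_s);
  if (st.v_s < 0) st.v_s = 0;
  st.x_s -= st.v_s * e.dt;
  st.t += e.dt;
  st.v_t = speed_at(su, st.t);
  st.x_t -= st.v_t * e.dt;
  st.phase = (st.t < su.onset) ? 0 : (st.t < su.onset + su.ramp ? 1 : 2);
  double r = e.capture_radius;
  if (std::abs(st.x_s) <= r && std::abs(st.x_t) <= r) {
    st.terminal = true; st.outcome = OUT_SUCCESS;
  } else if (st.x_t < -r || st.t > e.max_dur) {
    st.terminal = true; st.outcome = OUT_MISS;
  }
}

static List state_to_list(const StateC& st) {
  return List::create(
    _["t"] = st.t, _["x_t"] = st.x_t, _["v_t"] = st.v_t,
    _["x_s"] = st.x_s, _["v_s"] = st.v_s, _["phase"] = st.phase,
    _["terminal"] = st.terminal, _["outcome"] = st.outcome);
}

static StateC state_from_list(List s) {
  StateC st;
  st.t = as<double>(s["t"]); st.x_t = as<double>(s["x_t"]);
  st.v_t = as<double>(s["v_t"]); st.x_s = as<double>(s["x_s"]);
  st.v_s = as<double>(s["v_s"]); st.phase = as<int>(s["phase"]);
  st.terminal = as<bool>(s["terminal"]); st.outcome = as<int>(s["outcome"]);
  return st;
}

static SetupC setup_from_list(List s) {
  SetupC su;
  su.x_s0 = as<double>(s["agent_init_distance"]);
  su.v0 = as<double>(s["target_init_speed"]);
  su.v1 = as<double>(s["target_final_speed"]);
  su.onset = as<double>(s["change_onset"]);
  su.ramp = as<double>(s["ramp_duration"]);
  su.x_t0 = as<double>(s["target_init_distance"]);
  return su;
}

static List setup_to_list(const SetupC& su) {
  return List::create(
    _["agent_init_distance"] = su.x_s0, _["target_init_speed"] = su.v0,
    _["target_final_speed"] = su.v1, _["change_onset"] = su.onset,
    _["ramp_duration"] = su.ramp, _["target_init_distance"] = su.x_t0);
}

// [[Rcpp::export]]
List cpp_sample_setup(List cfg) {
  EnvC e = env_from_list(cfg);
  return setup_to_list(sample_setup(e));
}

// [[Rcpp::export]]
List cpp_env_reset(List cfg) {
  EnvC e = env_from_list(cfg);
  SetupC su = sample_setup(e);
  StateC st = init_state(su);
  NumericVector obs = NumericVector::create(st.x_t, st.v_t, st.x_s, st.v_s);
  obs.names() = CharacterVector::create("x_t", "v_t", "x_s", "v_s");
  return List::create(_["state"] = state_to_list(st), _["observation"] = obs,
                      _["setup"] = setup_to_list(su));
}

// [[Rcpp::export]]
List cpp_env_step(List state, int action, List setup, List cfg) {
  EnvC e = env_from_list(cfg);
  SetupC su = setup_from_list(setup);
  StateC st = state_from_list(state);
  if (st.terminal) stop("cannot step a terminal state");
  if (action < 0 || action >= (int)e.pedal.size())
    stop("action index out of range");
  step_env(st, action, su, e);
  NumericVector obs = NumericVector::create(st.x_t, st.v_t, st.x_s, st.v_s);
  obs.names() = CharacterVector::create("x_t", "v_t", "x_s", "v_s");
  return List::create(_["state"] = state_to_list(st), _["observation"] = obs,
                      _["terminal"] = st.terminal, _["outcome"] = st.outcome);
}

// ---------------------------------------------------------------- joint model

struct Net {
  fmat W1, W2, Wa, Wo;
  fvec b1, b2, ba, bo;
  bool bias;
};

static Net net_from_list(List p, bool bias) {
  Net n;
  n.W1 = arma::conv_to<fmat>::from(as<arma::mat>(p["W1"]));
  n.W2 = arma::conv_to<fmat>::from(as<arma::mat>(p["W2"]));
  n.Wa = arma::conv_to<fmat>::from(as<arma::mat>(p["Wa"]));
  n.Wo = arma::conv_to<fmat>::from(as<arma::mat>(p["Wo"]));
  n.bias = bias;
  if (bias) {
    n.b1 = arma::conv_to<fvec>::from(as<arma::vec>(p["b1"]));
    n.b2 = arma::conv_to<fvec>::from(as<arma::vec>(p["b2"]));
    n.ba = arma::conv_to<fvec>::from(as<arma::vec>(p["ba"]));
    n.bo = arma::conv_to<fvec>::from(as<arma::vec>(p["bo"]));
  } else {
    n.b1.zeros(n.W1.n_rows); n.b2.zeros(n.W2.n_rows);
    n.ba.zeros(n.Wa.n_rows); n.bo.zeros(n.Wo.n_rows);
  }
  return n;
}

static List net_to_list(const Net& n) {
  List p = List::create(
    _["W1"] = arma::conv_to<arma::mat>::from(n.W1),
    _["W2"] = arma::conv_to<arma::mat>::from(n.W2),
    _["Wa"] = arma::conv_to<arma::mat>::from(n.Wa),
    _["Wo"] = arma::conv_to<arma::mat>::from(n.Wo),
    _["b1"] = arma::conv_to<arma::vec>::from(n.b1),
    _["b2"] = arma::conv_to<arma::vec>::from(n.b2),
    _["ba"] = arma::conv_to<arma::vec>::from(n.ba),
    _["bo"] = arma::conv_to<arma::vec>::from(n.bo));
  return p;
}

static inline void relu_inplace(fmat& z) {
  float* p = z.memptr();
  for (arma::uword i = 0; i < z.n_elem; ++i)
    if (p[i] < 0.0f) p[i] = 0.0f;
}

// zero entries of d where the corresponding activation was clipped
static inline void relu_mask(fmat& d, const fmat& z) {
  float* p = d.memptr();
  const float* q = z.memptr();
  for (arma::uword i = 0; i < d.n_elem; ++i)
    if (q[i] <= 0.0f) p[i] = 0.0f;
}

// forward pass on already-normalized inputs (columns = samples); outputs
// are written in place, so preallocated workspaces avoid reallocation
static void net_forward(const Net& n, const fmat& X,
                        fmat& Z1, fmat& Z2, fmat& Ga, fmat& Oo) {
  Z1 = n.W1 * X;
  if (n.bias) Z1.each_col() += n.b1;
  relu_inplace(Z1);
  Z2 = n.W2 * Z1;
  if (n.bias) Z2.each_col() += n.b2;
  relu_inplace(Z2);
  Ga = n.Wa * Z2;
  if (n.bias) Ga.each_col() += n.ba;
  Oo = n.Wo * Z2;
  if (n.bias) Oo.each_col() += n.bo;
}

// gradient of the batch-averaged two-headed quadratic loss given the
// already-computed activations; the target matrix T is a constant (the
// bootstrap is stop-gradient)
static void net_grad_core(const Net& n, const fmat& X, const fmat& Z1,
                          const fmat& Z2, const fmat& Ga, const fmat& Oo,
                          const fmat& T, const fmat& O2, double sigma_a,
                          double sigma_o, double obs_head_w, Net& g,
                          fmat& dGa, fmat& dOo, fmat& dZ1, fmat& dZ2) {
  const float B = (float)X.n_cols;
  const float ka = 1.0f / ((float)(sigma_a * sigma_a) * B);
  const float ko = (float)obs_head_w / ((float)(sigma_o * sigma_o) * B);
  dGa = (Ga - T) * ka;
  dOo = (Oo - O2) * ko;
  dZ2 = n.Wa.t() * dGa;
  dZ2 += n.Wo.t() * dOo;
  relu_mask(dZ2, Z2);
  dZ1 = n.W2.t() * dZ2;
  relu_mask(dZ1, Z1);
  g.Wa = dGa * Z2.t(); g.Wo = dOo * Z2.t();
  g.W2 = dZ2 * Z1.t(); g.W1 = dZ1 * X.t();
  if (n.bias) {
    g.ba = arma::sum(dGa, 1); g.bo = arma::sum(dOo, 1);
    g.b2 = arma::sum(dZ2, 1); g.b1 = arma::sum(dZ1, 1);
  }
}

static void net_grad(const Net& n, const fmat& X, const fmat& T,
                     const fmat& O2, double sigma_a, double sigma_o,
                     double obs_head_w, Net& g) {
  fmat Z1, Z2, Ga, Oo, dGa, dOo, dZ1, dZ2;
  net_forward(n, X, Z1, Z2, Ga, Oo);
  net_grad_core(n, X, Z1, Z2, Ga, Oo, T, O2, sigma_a, sigma_o, obs_head_w,
                g, dGa, dOo, dZ1, dZ2);
}

// G-values only (used for the frozen bootstrap; skips the obs head)
static void net_g_values(const Net& n, const fmat& X, fmat& Z1, fmat& Z2,
                         fmat& Ga) {
  Z1 = n.W1 * X;
  if (n.bias) Z1.each_col() += n.b1;
  relu_inplace(Z1);
  Z2 = n.W2 * Z1;
  if (n.bias) Z2.each_col() += n.b2;
  relu_inplace(Z2);
  Ga = n.Wa * Z2;
  if (n.bias) Ga.each_col() += n.ba;
}

// bootstrap targets: taken action gets r + gamma * (1-terminal) * max_a
// frozen-G(o'), all other actions keep the online network's own estimate
static fmat build_targets(const Net& online, const Net& frozen,
                          const fmat& X, const arma::ivec& a,
                          const fvec& r, const fmat& X2,
                          const arma::ivec& term, double gamma) {
  fmat Z1, Z2, Ga, Oo, FZ1, FZ2, FGa, FOo;
  net_forward(online, X, Z1, Z2, Ga, Oo);
  net_forward(frozen, X2, FZ1, FZ2, FGa, FOo);
  fmat T = Ga;
  for (arma::uword j = 0; j < X.n_cols; ++j) {
    float boot = term(j) ? 0.0f : (float)gamma * FGa.col(j).max();
    T(a(j), j) = r(j) + boot;
  }
  return T;
}

// [[Rcpp::export]]
List cpp_forward(List params, arma::mat x_norm, bool bias) {
  Net n = net_from_list(params, bias);
  fmat X = arma::conv_to<fmat>::from(x_norm);
  fmat Z1, Z2, Ga, Oo;
  net_forward(n, X, Z1, Z2, Ga, Oo);
  return List::create(_["g"] = arma::conv_to<arma::mat>::from(Ga),
                      _["pred"] = arma::conv_to<arma::mat>::from(Oo));
}

// [[Rcpp::export]]
List cpp_efe_targets(List online, List frozen, arma::mat x_norm,
                     IntegerVector a, NumericVector r, arma::mat x2_norm,
                     IntegerVector term, double gamma, bool bias) {
  Net on = net_from_list(online, bias), fr = net_from_list(frozen, bias);
  fmat X = arma::conv_to<fmat>::from(x_norm);
  fmat X2 = arma::conv_to<fmat>::from(x2_norm);
  arma::ivec aa(a.size()), tt(term.size());
  fvec rr(r.size());
  for (int j = 0; j < a.size(); ++j) { aa(j) = a[j]; tt(j) = term[j]; rr(j) = r[j]; }
  fmat T = build_targets(on, fr, X, aa, rr, X2, tt, gamma);
  return List::create(_["targets"] = arma::conv_to<arma::mat>::from(T));
}

// [[Rcpp::export]]
List cpp_loss_grad(List params, arma::mat x_norm, arma::mat targets,
                   arma::mat x2_norm, double sigma_a, double sigma_o,
                   double obs_head_weight, bool bias) {
  Net n = net_from_list(params, bias);
  Net g; g.bias = bias;
  if (bias) { g.b1.zeros(n.b1.n_elem); g.b2.zeros(n.b2.n_elem);
              g.ba.zeros(n.ba.n_elem); g.bo.zeros(n.bo.n_elem); }
  net_grad(n, arma::conv_to<fmat>::from(x_norm),
           arma::conv_to<fmat>::from(targets),
           arma::conv_to<fmat>::from(x2_norm),
           sigma_a, sigma_o, obs_head_weight, g);
  return net_to_list(g);
}

// ---------------------------------------------------------------- agent state

struct AdamState {
  fmat mW1, vW1, mW2, vW2, mWa, vWa, mWo, vWo;
  fvec mb1, vb1, mb2, vb2, mba, vba, mbo, vbo;
  void init(const Net& n) {
    mW1.zeros(arma::size(n.W1)); vW1.zeros(arma::size(n.W1));
    mW2.zeros(arma::size(n.W2)); vW2.zeros(arma::size(n.W2));
    mWa.zeros(arma::size(n.Wa)); vWa.zeros(arma::size(n.Wa));
    mWo.zeros(arma::size(n.Wo)); vWo.zeros(arma::size(n.Wo));
    mb1.zeros(n.b1.n_elem); vb1.zeros(n.b1.n_elem);
    mb2.zeros(n.b2.n_elem); vb2.zeros(n.b2.n_elem);
    mba.zeros(n.ba.n_elem); vba.zeros(n.ba.n_elem);
    mbo.zeros(n.bo.n_elem); vbo.zeros(n.bo.n_elem);
  }
};

// fused elementwise Adam step (no temporaries)
static inline void adam_update_mem(float* w, const float* g, float* m,
                                   float* v, arma::uword n, float lr,
                                   float b1, float b2, float eps,
                                   float c1, float c2) {
  const float sc2 = std::sqrt(c2);
  const float tiny = 1e-30f;  // flush decaying moments before they go
                              // subnormal (subnormal arithmetic is slow)
  for (arma::uword i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0f - b1) * g[i];
    if (m[i] < tiny && m[i] > -tiny) m[i] = 0.0f;
    v[i] = b2 * v[i] + (1.0f - b2) * g[i] * g[i];
    if (v[i] < tiny) v[i] = 0.0f;
    w[i] -= lr * (m[i] / c1) / (std::sqrt(v[i]) / sc2 + eps);
  }
}

static inline void adam_update(fmat& w, const fmat& g, fmat& m, fmat& v,
                               float lr, float b1, float b2, float eps,
                               float c1, float c2) {
  adam_update_mem(w.memptr(), g.memptr(), m.memptr(), v.memptr(),
                  w.n_elem, lr, b1, b2, eps, c1, c2);
}

static inline void adam_update_v(fvec& w, const fvec& g, fvec& m, fvec& v,
                                 float lr, float b1, float b2, float eps,
                                 float c1, float c2) {
  adam_update_mem(w.memptr(), g.memptr(), m.memptr(), v.memptr(),
                  w.n_elem, lr, b1, b2, eps, c1, c2);
}

class GAgent {
public:
  int D, A, batch_size, capacity, sync_interval;
  bool bias;
  double gamma, lr, lr_final, sigma_a, sigma_o, obs_head_w;
  long lr_decay_updates;
  fvec obs_norm;
  Net net, frozen;
  AdamState adam;
  long n_updates = 0;
  // replay buffer (raw observation units), FIFO ring
  fmat BO, BO2;
  arma::ivec BA, BT;
  fvec BR;
  int bsize = 0, bnext = 0;
  // preallocated minibatch workspaces (sized on first use)
  fmat WX, WX2, WZ1, WZ2, WGa, WOo, WFZ1, WFZ2, WFGa, WT,
       WdGa, WdOo, WdZ1, WdZ2;
  Net gw;
  // single-observation workspaces for the acting forward pass
  fmat SX, SZ1, SZ2, SGa, SOo;

  GAgent(List cfg, List params) {
    D = as<int>(cfg["obs_dim"]); A = as<int>(cfg["n_actions"]);
    bias = as<bool>(cfg["bias"]);
    gamma = as<double>(cfg["gamma"]); lr = as<double>(cfg["learning_rate"]);
    lr_final = as<double>(cfg["learning_rate_final"]);
    lr_decay_updates = (long)as<double>(cfg["lr_decay_updates"]);
    sigma_a = as<double>(cfg["sigma_a"]); sigma_o = as<double>(cfg["sigma_o"]);
    obs_head_w = as<double>(cfg["obs_head_weight"]);
    batch_size = as<int>(cfg["batch_size"]);
    capacity = as<int>(cfg["buffer_capacity"]);
    sync_interval = as<int>(cfg["target_sync_interval"]);
    obs_norm = arma::conv_to<fvec>::from(as<arma::vec>(cfg["obs_norm"]));
    net = net_from_list(params, bias);
    frozen = net;
    adam.init(net);
    BO.zeros(D, capacity); BO2.zeros(D, capacity);
    BA.zeros(capacity); BT.zeros(capacity); BR.zeros(capacity);
  }

  fvec normalize(const fvec& o) const { return o / obs_norm; }

  void store(const fvec& o, int a, double r, const fvec& o2, bool term) {
    BO.col(bnext) = o; BO2.col(bnext) = o2;
    BA(bnext) = a; BR(bnext) = (float)r; BT(bnext) = term ? 1 : 0;
    bnext = (bnext + 1) % capacity;
    if (bsize < capacity) bsize++;
  }

  arma::uvec sample_idx(int n) const {
    arma::uvec idx(n);
    for (int j = 0; j < n; ++j) {
      int k = (int)(unif_rand() * bsize);
      if (k >= bsize) k = bsize - 1;
      idx(j) = k;
    }
    return idx;
  }

  void train_batch() {
    arma::uvec idx = sample_idx(batch_size);
    WX.set_size(D, batch_size);
    WX2.set_size(D, batch_size);
    for (int j = 0; j < batch_size; ++j) {
      WX.col(j) = BO.col(idx(j));
      WX2.col(j) = BO2.col(idx(j));
    }
    WX.each_col() /= obs_norm;
    WX2.each_col() /= obs_norm;
    net_forward(net, WX, WZ1, WZ2, WGa, WOo);
    net_g_values(frozen, WX2, WFZ1, WFZ2, WFGa);
    WT = WGa;
    for (int j = 0; j < batch_size; ++j) {
      int k = idx(j);
      float boot = BT(k) ? 0.0f : (float)gamma * WFGa.col(j).max();
      WT(BA(k), j) = BR(k) + boot;
    }
    gw.bias = bias;
    net_grad_core(net, WX, WZ1, WZ2, WGa, WOo, WT, WX2,
                  sigma_a, sigma_o, obs_head_w, gw, WdGa, WdOo, WdZ1, WdZ2);
    n_updates++;
    float lr = (float)this->lr;
    if (lr_decay_updates > 0) {
      double f = std::min((double)n_updates / (double)lr_decay_updates, 1.0);
      lr = (float)(this->lr + (lr_final - this->lr) * f);
    }
    float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    float c1 = 1.0f - std::pow(b1, (float)n_updates);
    float c2 = 1.0f - std::pow(b2, (float)n_updates);
    adam_update(net.W1, gw.W1, adam.mW1, adam.vW1, lr, b1, b2, eps, c1, c2);
    adam_update(net.W2, gw.W2, adam.mW2, adam.vW2, lr, b1, b2, eps, c1, c2);
    adam_update(net.Wa, gw.Wa, adam.mWa, adam.vWa, lr, b1, b2, eps, c1, c2);
    adam_update(net.Wo, gw.Wo, adam.mWo, adam.vWo, lr, b1, b2, eps, c1, c2);
    if (bias) {
      adam_update_v(net.b1, gw.b1, adam.mb1, adam.vb1, lr, b1, b2, eps, c1, c2);
      adam_update_v(net.b2, gw.b2, adam.mb2, adam.vb2, lr, b1, b2, eps, c1, c2);
      adam_update_v(net.ba, gw.ba, adam.mba, adam.vba, lr, b1, b2, eps, c1, c2);
      adam_update_v(net.bo, gw.bo, adam.mbo, adam.vbo, lr, b1, b2, eps, c1, c2);
    }
    if (sync_interval > 0 && n_updates % sync_interval == 0) frozen = net;
  }

  // forward pass for acting; results live in SGa / SOo
  void act_forward(const fvec& xn) {
    SX = xn;
    net_forward(net, SX, SZ1, SZ2, SGa, SOo);
  }

  int act_greedy(const fvec& xn) {
    act_forward(xn);
    fvec g = SGa.col(0);
    return (int)g.index_max();  // first maximum: lowest index on ties
  }
};

static GAgent* agent_ptr(SEXP p) {
  Rcpp::XPtr<GAgent> xp(p);
  return xp.get();
}

// [[Rcpp::export]]
SEXP cpp_agent_new(List cfg, List params) {
  GAgent* ag = new GAgent(cfg, params);
  Rcpp::XPtr<GAgent> xp(ag, true);
  return xp;
}

// [[Rcpp::export]]
List cpp_agent_params(SEXP p) {
  GAgent* ag = agent_ptr(p);
  return List::create(_["online"] = net_to_list(ag->net),
                      _["frozen"] = net_to_list(ag->frozen),
                      _["n_updates"] = (double)ag->n_updates,
                      _["buffer_size"] = ag->bsize);
}

// [[Rcpp::export]]
void cpp_agent_set_params(SEXP p, List params, bool also_frozen) {
  GAgent* ag = agent_ptr(p);
  ag->net = net_from_list(params, ag->bias);
  if (also_frozen) ag->frozen = ag->net;
}

// [[Rcpp::export]]
List cpp_agent_forward(SEXP p, NumericVector obs) {
  GAgent* ag = agent_ptr(p);
  fvec o = arma::conv_to<fvec>::from(as<arma::vec>(obs));
  fvec xn = ag->normalize(o);
  fmat Z1, Z2, Ga, Oo;
  net_forward(ag->net, xn, Z1, Z2, Ga, Oo);
  return List::create(_["g"] = arma::conv_to<arma::vec>::from(Ga.col(0)),
                      _["pred"] = arma::conv_to<arma::vec>::from(Oo.col(0)));
}

// [[Rcpp::export]]
int cpp_agent_act(SEXP p, NumericVector obs, double epsilon) {
  GAgent* ag = agent_ptr(p);
  if (epsilon > 0 && unif_rand() < epsilon) {
    int k = (int)(unif_rand() * ag->A);
    return k >= ag->A ? ag->A - 1 : k;
  }
  fvec o = arma::conv_to<fvec>::from(as<arma::vec>(obs));
  return ag->act_greedy(ag->normalize(o));
}

// [[Rcpp::export]]
void cpp_agent_store(SEXP p, NumericVector o, int a, double r,
                     NumericVector o2, bool terminal) {
  GAgent* ag = agent_ptr(p);
  if (a < 0 || a >= ag->A) stop("action index out of range");
  ag->store(arma::conv_to<fvec>::from(as<arma::vec>(o)), a, r,
            arma::conv_to<fvec>::from(as<arma::vec>(o2)), terminal);
}

// [[Rcpp::export]]
int cpp_agent_buffer_size(SEXP p) { return agent_ptr(p)->bsize; }

// [[Rcpp::export]]
List cpp_agent_sample(SEXP p, int n) {
  GAgent* ag = agent_ptr(p);
  if (ag->bsize == 0) stop("cannot sample from an empty replay buffer");
  arma::uvec idx = ag->sample_idx(n);
  arma::mat o(ag->D, n), o2(ag->D, n);
  IntegerVector a(n), tt(n);
  NumericVector r(n);
  for (int j = 0; j < n; ++j) {
    o.col(j) = arma::conv_to<arma::vec>::from(ag->BO.col(idx(j)));
    o2.col(j) = arma::conv_to<arma::vec>::from(ag->BO2.col(idx(j)));
    a[j] = ag->BA(idx(j)); r[j] = ag->BR(idx(j)); tt[j] = ag->BT(idx(j));
  }
  return List::create(_["o"] = o, _["a"] = a, _["r"] = r, _["o2"] = o2,
                      _["terminal"] = tt);
}

// [[Rcpp::export]]
double cpp_agent_train_step(SEXP p) {
  GAgent* ag = agent_ptr(p);
  if (ag->bsize < ag->batch_size)
    stop("replay buffer holds fewer transitions than one batch");
  ag->train_batch();
  return (double)ag->n_updates;
}

// [[Rcpp::export]]
void cpp_agent_sync(SEXP p) { agent_ptr(p)->frozen = agent_ptr(p)->net; }

// ---------------------------------------------------------------- trial loop

// instrumental reward (drop-constant Gaussian log-density over the speed
// difference); `speed` is the pedal speed of the taken action or the
// realized agent speed depending on the prior's speed_source; the speed
// difference is clamped so the required-speed construction stays bounded
// as x_t -> 0
static double instrumental_c(double x_t, double v_t, double x_s, double speed,
                             double sd, double scale, double dmax) {
  double xt = (x_t >= 0 && x_t < 1e-9) ? 1e-9 : x_t;
  double d = speed - x_s * v_t / xt;
  if (d > dmax) d = dmax;
  if (d < -dmax) d = -dmax;
  return -scale * d * d / (2.0 * sd * sd);
}

// [[Rcpp::export]]
List cpp_run_trial(SEXP p, List env_cfg, int n_episodes, List run) {
  GAgent* ag = agent_ptr(p);
  EnvC env = env_from_list(env_cfg);
  if (ag->D != 4) stop("the interception task needs a 4-dimensional agent");

  const int reward_mode = as<int>(run["reward_mode"]);   // 0 aif, 1 dqn_sparse
  const double w_e = as<double>(run["epistemic_weight"]);
  const double prior_sd = as<double>(run["prior_sd"]);
  const double prior_scale = as<double>(run["instrumental_scale"]);
  const double prior_dmax = as<double>(run["max_abs_diff"]);
  const bool prior_pedal = as<bool>(run["speed_source_pedal"]);
  const double sp_s = as<double>(run["sparse_reward_success"]);
  const double sp_m = as<double>(run["sparse_reward_miss"]);
  const double eps_start = as<double>(run["epsilon_start"]);
  const double eps_end = as<double>(run["epsilon_end"]);
  const int eps_decay = as<int>(run["epsilon_decay_episodes"]);
  const bool train = as<bool>(run["train"]);
  const int warmup = as<int>(run["warmup"]);
  const int update_every = as<int>(run["update_every"]);
  long env_steps = 0;
  const int record_eps = as<int>(run["record_transitions"]);

  NumericVector ep_success(n_episodes), ep_outcome(n_episodes),
    ep_steps(n_episodes), ep_return(n_episodes), ep_inst(n_episodes),
    ep_epist(n_episodes), ep_eps(n_episodes), su_xs(n_episodes),
    su_v0(n_episodes), su_v1(n_episodes), su_onset(n_episodes),
    on_xt(n_episodes), on_vt(n_episodes), on_xs(n_episodes), on_vs(n_episodes);

  std::vector<double> tr_o, tr_o2, tr_r, tr_ri, tr_re;
  std::vector<int> tr_a, tr_term, tr_ep;

  for (int e = 0; e < n_episodes; ++e) {
    if (e % 64 == 0) Rcpp::checkUserInterrupt();
    SetupC su = sample_setup(env);
    StateC st = init_state(su);
    double eps;
    if (eps_decay <= 0 || e >= eps_decay) eps = eps_end;
    else eps = eps_start + (eps_end - eps_start) * (double)e / (double)eps_decay;
    double ret = 0, sum_i = 0, sum_e = 0;
    int nst = 0;
    bool onset_rec = false;
    on_xt[e] = NA_REAL; on_vt[e] = NA_REAL; on_xs[e] = NA_REAL; on_vs[e] = NA_REAL;

    while (!st.terminal) {
      fvec o = {(float)st.x_t, (float)st.v_t, (float)st.x_s, (float)st.v_s};
      if (!onset_rec && st.t >= su.onset) {
        on_xt[e] = st.x_t; on_vt[e] = st.v_t; on_xs[e] = st.x_s; on_vs[e] = st.v_s;
        onset_rec = true;
      }
      fvec xn = ag->normalize(o);
      ag->act_forward(xn);
      int a;
      if (eps > 0 && unif_rand() < eps) {
        a = (int)(unif_rand() * ag->A);
        if (a >= ag->A) a = ag->A - 1;
      } else {
        fvec gv = ag->SGa.col(0);
        a = (int)gv.index_max();
      }
      step_env(st, a, su, env);
      fvec o2 = {(float)st.x_t, (float)st.v_t, (float)st.x_s, (float)st.v_s};
      double ri = 0, re = 0, r;
      if (reward_mode == 0) {
        if (st.terminal && st.outcome == OUT_SUCCESS) {
          ri = 0.0;  // the preferred outcome: speed difference treated as 0
        } else {
          double sp = prior_pedal ? env.pedal[a] : st.v_s;
          ri = instrumental_c(st.x_t, st.v_t, st.x_s, sp,
                              prior_sd, prior_scale, prior_dmax);
        }
        if (w_e != 0) {
          fvec err = ag->SOo.col(0) - ag->normalize(o2);
          re = w_e * (double)arma::dot(err, err);
        }
        r = ri + re;
      } else {
        r = st.terminal ? (st.outcome == OUT_SUCCESS ? sp_s : sp_m) : 0.0;
      }
      if (train) {
        ag->store(o, a, r, o2, st.terminal);
        env_steps++;
        if (ag->bsize >= warmup && ag->bsize >= ag->batch_size &&
            env_steps % update_every == 0)
          ag->train_batch();
      }
      if (e < record_eps) {
        for (int k = 0; k < 4; ++k) tr_o.push_back(o(k));
        for (int k = 0; k < 4; ++k) tr_o2.push_back(o2(k));
        tr_a.push_back(a); tr_r.push_back(r); tr_ri.push_back(ri);
        tr_re.push_back(re); tr_term.push_back(st.terminal ? 1 : 0);
        tr_ep.push_back(e);
      }
      ret += r; sum_i += ri; sum_e += re; nst++;
    }
    ep_success[e] = (st.outcome == OUT_SUCCESS) ? 1 : 0;
    ep_outcome[e] = st.outcome;
    ep_steps[e] = nst;
    ep_return[e] = ret;
    ep_inst[e] = nst > 0 ? sum_i / nst : NA_REAL;
    ep_epist[e] = nst > 0 ? sum_e / nst : NA_REAL;
    ep_eps[e] = eps;
    su_xs[e] = su.x_s0; su_v0[e] = su.v0; su_v1[e] = su.v1; su_onset[e] = su.onset;
  }

  List out = List::create(
    _["success"] = ep_success, _["outcome"] = ep_outcome,
    _["steps"] = ep_steps, _["episode_return"] = ep_return,
    _["mean_instrumental"] = ep_inst, _["mean_epistemic"] = ep_epist,
    _["epsilon"] = ep_eps, _["agent_init_distance"] = su_xs,
    _["target_init_speed"] = su_v0, _["target_final_speed"] = su_v1,
    _["change_onset"] = su_onset, _["onset_x_t"] = on_xt,
    _["onset_v_t"] = on_vt, _["onset_x_s"] = on_xs, _["onset_v_s"] = on_vs);

  if (record_eps > 0) {
    int n = tr_a.size();
    arma::mat O(4, n), O2(4, n);
    for (int j = 0; j < n; ++j)
      for (int k = 0; k < 4; ++k) {
        O(k, j) = tr_o[4 * j + k];
        O2(k, j) = tr_o2[4 * j + k];
      }
    out["transitions"] = List::create(
      _["o"] = O, _["a"] = IntegerVector(tr_a.begin(), tr_a.end()),
      _["r"] = NumericVector(tr_r.begin(), tr_r.end()),
      _["r_instrumental"] = NumericVector(tr_ri.begin(), tr_ri.end()),
      _["r_epistemic"] = NumericVector(tr_re.begin(), tr_re.end()),
      _["o2"] = O2,
      _["terminal"] = IntegerVector(tr_term.begin(), tr_term.end()),
      _["episode"] = IntegerVector(tr_ep.begin(), tr_ep.end()));
  }
  return out;
}
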