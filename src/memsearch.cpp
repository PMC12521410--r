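// Compiled hot paths: batch CMR recall simulation and the GRU
// encoder-decoder with dot-product attention (forward, sampling, and exact
// analytic gradients for cross-entropy and PPO objectives). Pure-R reference
// implementations of the forward operations live in R/ and are parity-tested
// against these.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline vec softmax_vec(const vec& s) {
  vec z = s - s.max();
  vec e = exp(z);
  return e / accu(e);
}

// sample an index from probabilities with a single uniform draw (cumulative
// scan; mirrors the R-side sampling exactly so seeded runs agree)
static inline int sample_cum(const vec& p) {
  double u = unif_rand();
  double cum = 0.0;
  for (uword i = 0; i < p.n_elem; ++i) {
    cum += p[i];
    if (u <= cum + 1e-15) return (int)i;
  }
  return (int)p.n_elem - 1;
}

// ---------------------------------------------------------------------------
// CMR batch simulation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cmr_simulate_cpp(IntegerMatrix lists, int N, double beta_enc,
                               double beta_rec, double gamma_fc, double k,
                               int max_att) {
  const int n = lists.nrow(), L = lists.ncol();
  IntegerMatrix out(n, std::max(max_att, 1));
  for (int t = 0; t < n; ++t) {
    std::vector<int> study(L);
    std::vector<bool> inlist(N + 1, false);
    for (int i = 0; i < L; ++i) { study[i] = lists(t, i); inlist[study[i]] = true; }
    vec c(N, fill::zeros);
    int slot = 0;
    for (int j = 1; j <= N; ++j) if (!inlist[j]) { slot = j; break; }
    if (slot) c[slot - 1] = 1.0; else c.fill(1.0 / std::sqrt((double)N));
    mat stored(L, N);
    for (int i = 0; i < L; ++i) {
      stored.row(i) = c.t();
      const int it = study[i] - 1;
      const double cx = c[it];
      const double rho = std::sqrt(1.0 + beta_enc * beta_enc * (cx * cx - 1.0))
                         - beta_enc * cx;
      c *= rho;
      c[it] += beta_enc;
    }
    int prev = -1;
    for (int step = 0; step < max_att; ++step) {
      vec p = softmax_vec(k * (stored * c));
      const int pick = sample_cum(p);
      const int item = study[pick];
      out(t, step) = item;
      if (step >= 1 && item == prev) break;
      prev = item;
      vec input = gamma_fc * stored.row(pick).t();
      input[item - 1] += (1.0 - gamma_fc);
      input /= norm(input);
      const double cx = dot(c, input);
      const double rho = std::sqrt(1.0 + beta_rec * beta_rec * (cx * cx - 1.0))
                         - beta_rec * cx;
      c = rho * c + beta_rec * input;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// GRU seq2seq with attention
// ---------------------------------------------------------------------------

struct S2S {
  mat emb, encW, encU, decW, decU, Wc, out_emb;
  vec encb, decb, eos_w, val_w;
  double eos_b, val_b, temp;
  int d, demb, N, mode; // mode: 1 full-vocab, 0 in-list
  bool attention;
};

static S2S load_model(const List& params, const List& cfg) {
  S2S m;
  m.emb = as<mat>(params["emb"]);
  m.encW = as<mat>(params["encW"]); m.encU = as<mat>(params["encU"]);
  m.encb = as<vec>(params["encb"]);
  m.decW = as<mat>(params["decW"]); m.decU = as<mat>(params["decU"]);
  m.decb = as<vec>(params["decb"]);
  m.Wc = as<mat>(params["Wc"]);
  m.out_emb = as<mat>(params["out_emb"]);
  m.eos_w = as<vec>(params["eos_w"]); m.eos_b = as<double>(params["eos_b"]);
  m.val_w = as<vec>(params["val_w"]); m.val_b = as<double>(params["val_b"]);
  m.d = as<int>(cfg["hidden_dim"]); m.demb = as<int>(cfg["embed_dim"]);
  m.N = as<int>(cfg["vocab_size"]);
  m.attention = as<bool>(cfg["attention"]);
  m.mode = as<std::string>(cfg["output_mode"]) == "full_vocab" ? 1 : 0;
  m.temp = as<double>(cfg["score_temperature"]);
  return m;
}

struct GruCache { vec x, hprev, z, r, n, Uhn, h; };

static vec gru_step(const mat& W, const mat& U, const vec& b, const vec& x,
                    const vec& hprev, int d, GruCache* cache) {
  vec a = W * x + b;
  vec au = U * hprev;
  vec z = 1.0 / (1.0 + exp(-(a.subvec(0, d - 1) + au.subvec(0, d - 1))));
  vec r = 1.0 / (1.0 + exp(-(a.subvec(d, 2 * d - 1) + au.subvec(d, 2 * d - 1))));
  vec Uhn = au.subvec(2 * d, 3 * d - 1);
  vec n = tanh(a.subvec(2 * d, 3 * d - 1) + r % Uhn);
  vec h = (1.0 - z) % n + z % hprev;
  if (cache) { cache->x = x; cache->hprev = hprev; cache->z = z; cache->r = r;
               cache->n = n; cache->Uhn = Uhn; cache->h = h; }
  return h;
}

// backward through one GRU step; accumulates dW/dU/db, returns dhprev and dx
static void gru_back(const mat& W, const mat& U, const GruCache& c, int d,
                     const vec& dh, mat& dW, mat& dU, vec& db,
                     vec& dhprev, vec& dx) {
  vec dz = dh % (c.hprev - c.n);
  vec dn = dh % (1.0 - c.z);
  vec dan = dn % (1.0 - c.n % c.n);
  vec dr = dan % c.Uhn;
  vec daz = dz % c.z % (1.0 - c.z);
  vec dar = dr % c.r % (1.0 - c.r);
  vec da(3 * d), dau(3 * d);
  da.subvec(0, d - 1) = daz; da.subvec(d, 2 * d - 1) = dar;
  da.subvec(2 * d, 3 * d - 1) = dan;
  dau.subvec(0, d - 1) = daz; dau.subvec(d, 2 * d - 1) = dar;
  dau.subvec(2 * d, 3 * d - 1) = dan % c.r;
  dW += da * c.x.t();
  dU += dau * c.hprev.t();
  db += da;
  dhprev = c.z % dh + U.t() * dau;
  dx = W.t() * da;
}

struct StepCache {
  GruCache gru;
  int input_row;      // 0-based row of emb fed to the decoder at this step
  vec w, alpha, cat, hhat, p, scores;
  double value;
  int action;         // 0-based action index
};

struct EpisodeFwd {
  std::vector<GruCache> enc;
  mat H;                       // L x d encoder states
  std::vector<StepCache> steps;
  std::vector<int> pos_of_item; // 0-based study position per item, -1 if absent
  std::vector<int> study;       // 1-based items
};

// action space size: full-vocab = N items + EOS; in-list = L positions + EOS
static int n_actions(const S2S& m, int L) {
  return (m.mode == 1 ? m.N : L) + 1;
}

static void forward_encoder(const S2S& m, const std::vector<int>& study,
                            EpisodeFwd& ep) {
  const int L = (int)study.size();
  ep.H.set_size(L, m.d);
  ep.enc.resize(L);
  ep.pos_of_item.assign(m.N, -1);
  vec h(m.d, fill::zeros);
  for (int i = 0; i < L; ++i) {
    ep.pos_of_item[study[i] - 1] = i;
    vec x = m.emb.row(study[i] - 1).t();
    h = gru_step(m.encW, m.encU, m.encb, x, h, m.d, &ep.enc[i]);
    ep.H.row(i) = h.t();
  }
  ep.study = study;
}

// one decoder step; prev_action < 0 means start-of-sequence
static void forward_step(const S2S& m, EpisodeFwd& ep, int prev_action,
                         const vec& hprev, StepCache& sc) {
  const int L = ep.H.n_rows;
  sc.input_row = prev_action < 0 ? m.N : prev_action; // emb row N = SOS
  vec x = m.emb.row(sc.input_row).t();
  vec h = gru_step(m.decW, m.decU, m.decb, x, hprev, m.d, &sc.gru);
  if (m.attention) {
    vec s = ep.H * h;
    sc.w = softmax_vec(s);
    sc.alpha = ep.H.t() * sc.w;
    sc.cat = join_cols(h, sc.alpha);
  } else {
    sc.cat = h;
  }
  sc.hhat = tanh(m.Wc * sc.cat);
  const int A = n_actions(m, L);
  vec sco(A);
  if (m.mode == 1) {
    // full-vocab: studied items are scored by the match to their stored
    // encoder state; without attention the model has no episodic access
    // and every item is scored from the recurrent state via its output
    // embedding
    for (int it = 0; it < m.N; ++it) {
      const int p = ep.pos_of_item[it];
      sco[it] = (m.attention && p >= 0) ? dot(sc.hhat, ep.H.row(p).t())
                                        : dot(sc.hhat, m.out_emb.row(it).t());
    }
  } else {
    for (int l = 0; l < L; ++l) sco[l] = dot(sc.hhat, ep.H.row(l).t());
  }
  sco[A - 1] = dot(m.eos_w, sc.hhat) + m.eos_b;
  sco *= m.temp;
  sc.scores = sco;
  sc.p = softmax_vec(sco);
  sc.value = dot(m.val_w, sc.hhat) + m.val_b;
}

// roll the decoder; actions_in nonempty = teacher forcing, else greedy/sample
static void forward_episode(const S2S& m, const std::vector<int>& study,
                            const std::vector<int>& actions_in, int sample_mode,
                            int max_steps, EpisodeFwd& ep) {
  forward_encoder(m, study, ep);
  const int L = (int)study.size();
  const int A = n_actions(m, L);
  vec h = ep.H.row(L - 1).t(); // decoder initialized with final encoder state
  int prev = -1;
  const int T = actions_in.empty() ? max_steps : (int)actions_in.size();
  for (int t = 0; t < T; ++t) {
    StepCache sc;
    forward_step(m, ep, prev, h, sc);
    int a;
    if (!actions_in.empty()) a = actions_in[t];
    else if (sample_mode == 1) a = sample_cum(sc.p);
    else a = (int)sc.p.index_max();
    sc.action = a;
    ep.steps.push_back(std::move(sc));
    if (a == A - 1) break;     // end-of-sequence
    // feed the emitted item back in: map in-list positions to item rows
    prev = (m.mode == 1) ? a : study[a] - 1;
    h = ep.steps.back().gru.h;
  }
}

struct Grads {
  mat demb, dencW, dencU, ddecW, ddecU, dWc, dout_emb;
  vec dencb, ddecb, deos_w, dval_w;
  double deos_b = 0, dval_b = 0;
  void init(const S2S& m) {
    demb.zeros(m.emb.n_rows, m.emb.n_cols);
    dencW.zeros(size(m.encW)); dencU.zeros(size(m.encU)); dencb.zeros(m.encb.n_elem);
    ddecW.zeros(size(m.decW)); ddecU.zeros(size(m.decU)); ddecb.zeros(m.decb.n_elem);
    dWc.zeros(size(m.Wc)); dout_emb.zeros(size(m.out_emb));
    deos_w.zeros(m.eos_w.n_elem); dval_w.zeros(m.val_w.n_elem);
  }
};

// backward through a decoded episode given per-step dlogits and dvalue
static void backward_episode(const S2S& m, EpisodeFwd& ep,
                             const std::vector<vec>& dlogits,
                             const std::vector<double>& dvalue, Grads& g) {
  const int L = ep.H.n_rows;
  const int T = (int)ep.steps.size();
  mat dH(L, m.d, fill::zeros);
  vec dh_carry(m.d, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    StepCache& sc = ep.steps[t];
    vec dhhat(m.d, fill::zeros);
    // value head
    if (dvalue[t] != 0.0) {
      g.dval_w += dvalue[t] * sc.hhat;
      g.dval_b += dvalue[t];
      dhhat += dvalue[t] * m.val_w;
    }
    // retrieval scores
    vec ds = m.temp * dlogits[t];
    const int A = n_actions(m, L);
    if (m.mode == 1) {
      for (int it = 0; it < m.N; ++it) {
        if (ds[it] == 0.0) continue;
        const int p = ep.pos_of_item[it];
        if (m.attention && p >= 0) {
          dH.row(p) += ds[it] * sc.hhat.t();
          dhhat += ds[it] * ep.H.row(p).t();
        } else {
          g.dout_emb.row(it) += ds[it] * sc.hhat.t();
          dhhat += ds[it] * m.out_emb.row(it).t();
        }
      }
    } else {
      for (int l = 0; l < L; ++l) {
        dH.row(l) += ds[l] * sc.hhat.t();
        dhhat += ds[l] * ep.H.row(l).t();
      }
    }
    g.deos_w += ds[A - 1] * sc.hhat;
    g.deos_b += ds[A - 1];
    dhhat += ds[A - 1] * m.eos_w;
    // mixing layer
    vec da = dhhat % (1.0 - sc.hhat % sc.hhat);
    g.dWc += da * sc.cat.t();
    vec dcat = m.Wc.t() * da;
    vec dh = dcat.subvec(0, m.d - 1);
    if (m.attention) {
      vec dalpha = dcat.subvec(m.d, 2 * m.d - 1);
      vec dw = ep.H * dalpha;
      vec dsA = sc.w % (dw - dot(sc.w, dw));
      dh += ep.H.t() * dsA;
      dH += sc.w * dalpha.t() + dsA * sc.gru.h.t();
    }
    dh += dh_carry;
    vec dhprev, dx;
    gru_back(m.decW, m.decU, sc.gru, m.d, dh, g.ddecW, g.ddecU, g.ddecb,
             dhprev, dx);
    g.demb.row(sc.input_row) += dx.t();
    dh_carry = dhprev;
  }
  dH.row(L - 1) += dh_carry.t(); // decoder h0 = encoder final state
  vec carry(m.d, fill::zeros);
  for (int i = L - 1; i >= 0; --i) {
    vec dh = dH.row(i).t() + carry;
    vec dhprev, dx;
    gru_back(m.encW, m.encU, ep.enc[i], m.d, dh, g.dencW, g.dencU, g.dencb,
             dhprev, dx);
    g.demb.row(ep.study[i] - 1) += dx.t();
    carry = dhprev;
  }
}

static std::vector<int> ivec_to_std(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

// [[Rcpp::export]]
List s2s_rollout_cpp(List params, List cfg, IntegerVector study,
                     int sample_mode, int max_steps, IntegerVector forced,
                     bool record_attention) {
  S2S m = load_model(params, cfg);
  if (study.size() == 0) stop("empty study list");
  EpisodeFwd ep;
  forward_episode(m, ivec_to_std(study), ivec_to_std(forced), sample_mode,
                  max_steps, ep);
  const int T = (int)ep.steps.size();
  const int L = study.size();
  IntegerVector actions(T);
  NumericVector logp(T), value(T), entropy(T);
  NumericMatrix attn(record_attention && m.attention ? T : 0, L);
  for (int t = 0; t < T; ++t) {
    const StepCache& sc = ep.steps[t];
    actions[t] = sc.action + 1; // 1-based for R
    logp[t] = std::log(std::max(sc.p[sc.action], 1e-300));
    value[t] = sc.value;
    double H = 0;
    for (uword i = 0; i < sc.p.n_elem; ++i)
      if (sc.p[i] > 0) H -= sc.p[i] * std::log(sc.p[i]);
    entropy[t] = H;
    if (record_attention && m.attention)
      for (int l = 0; l < L; ++l) attn(t, l) = sc.w[l];
  }
  return List::create(_["actions"] = actions, _["logp"] = logp,
                      _["value"] = value, _["entropy"] = entropy,
                      _["attention"] = attn);
}

// [[Rcpp::export]]
List s2s_generate_many_cpp(List params, List cfg, IntegerMatrix lists,
                           int sample_mode, int max_steps) {
  S2S m = load_model(params, cfg);
  const int n = lists.nrow(), L = lists.ncol();
  IntegerMatrix out(n, max_steps);
  for (int i = 0; i < n; ++i) {
    std::vector<int> study(L);
    for (int j = 0; j < L; ++j) study[j] = lists(i, j);
    EpisodeFwd ep;
    forward_episode(m, study, std::vector<int>(), sample_mode, max_steps, ep);
    for (int t = 0; t < (int)ep.steps.size(); ++t)
      out(i, t) = ep.steps[t].action + 1;
  }
  return List::create(_["actions"] = out);
}

static List grads_to_list(const Grads& g) {
  return List::create(
    _["emb"] = g.demb, _["encW"] = g.dencW, _["encU"] = g.dencU,
    _["encb"] = g.dencb, _["decW"] = g.ddecW, _["decU"] = g.ddecU,
    _["decb"] = g.ddecb, _["Wc"] = g.dWc, _["out_emb"] = g.dout_emb,
    _["eos_w"] = g.deos_w, _["eos_b"] = g.deos_b,
    _["val_w"] = g.dval_w, _["val_b"] = g.dval_b);
}

// PPO clipped-surrogate + entropy bonus + value regression over a batch of
// episodes (fields: study, actions, adv, ret, oldlogp). Losses are means
// over all steps in the batch.
// [[Rcpp::export]]
List s2s_ppo_grad_cpp(List params, List cfg, List episodes, double clip,
                      double ent_coef, double vf_coef) {
  S2S m = load_model(params, cfg);
  Grads g; g.init(m);
  int total_steps = 0;
  for (int e = 0; e < episodes.size(); ++e) {
    List epi = episodes[e];
    total_steps += (int)as<IntegerVector>(epi["actions"]).size();
  }
  if (total_steps == 0) stop("empty batch");
  const double inv = 1.0 / total_steps;
  double actor_loss = 0, critic_loss = 0, ent_sum = 0;
  for (int e = 0; e < episodes.size(); ++e) {
    List epi = episodes[e];
    std::vector<int> study = ivec_to_std(epi["study"]);
    IntegerVector actsR = epi["actions"];
    std::vector<int> actions(actsR.size());
    for (int t = 0; t < actsR.size(); ++t) actions[t] = actsR[t] - 1;
    NumericVector adv = epi["adv"], ret = epi["ret"], oldlp = epi["oldlogp"];
    EpisodeFwd ep;
    forward_episode(m, study, actions, 0, (int)actions.size(), ep);
    const int T = (int)ep.steps.size();
    std::vector<vec> dlogits(T);
    std::vector<double> dvalue(T);
    for (int t = 0; t < T; ++t) {
      const StepCache& sc = ep.steps[t];
      const int a = sc.action;
      const double lp = std::log(std::max(sc.p[a], 1e-300));
      const double ratio = std::exp(lp - oldlp[t]);
      const double A = adv[t];
      const double unclipped = ratio * A;
      const double clipped = std::min(std::max(ratio, 1.0 - clip), 1.0 + clip) * A;
      actor_loss -= inv * std::min(unclipped, clipped);
      // d(min)/d logp: active when unclipped selected or ratio inside the clip
      double gcoef = 0.0;
      if (unclipped <= clipped + 1e-12 ||
          (ratio > 1.0 - clip && ratio < 1.0 + clip)) gcoef = ratio * A;
      double H = 0;
      vec plogp(sc.p.n_elem, fill::zeros);
      for (uword i = 0; i < sc.p.n_elem; ++i)
        if (sc.p[i] > 0) { plogp[i] = std::log(sc.p[i]); H -= sc.p[i] * plogp[i]; }
      ent_sum += inv * H;
      vec dl = ent_coef * inv * (sc.p % (plogp + H)); // from -ent_coef * mean(H)
      dl[a] -= inv * gcoef;                            // actor: -mean(min(...))
      dl += inv * gcoef * sc.p;
      dlogits[t] = dl;
      const double verr = sc.value - ret[t];
      critic_loss += inv * verr * verr;
      dvalue[t] = vf_coef * 2.0 * verr * inv;
    }
    backward_episode(m, ep, dlogits, dvalue, g);
  }
  const double loss = actor_loss + vf_coef * critic_loss - ent_coef * ent_sum;
  return List::create(_["grads"] = grads_to_list(g), _["actor_loss"] = actor_loss,
                      _["critic_loss"] = critic_loss, _["entropy"] = ent_sum,
                      _["loss"] = loss);
}

// Teacher-forced cross-entropy over a batch (fields: study, actions); the
// loss is the mean negative log-probability of the target actions.
// [[Rcpp::export]]
List s2s_ce_grad_cpp(List params, List cfg, List batch, bool compute_grads) {
  S2S m = load_model(params, cfg);
  Grads g; g.init(m);
  int total_steps = 0;
  for (int e = 0; e < batch.size(); ++e) {
    List epi = batch[e];
    total_steps += (int)as<IntegerVector>(epi["actions"]).size();
  }
  if (total_steps == 0) stop("empty batch");
  const double inv = 1.0 / total_steps;
  double loss = 0;
  for (int e = 0; e < batch.size(); ++e) {
    List epi = batch[e];
    std::vector<int> study = ivec_to_std(epi["study"]);
    IntegerVector actsR = epi["actions"];
    std::vector<int> actions(actsR.size());
    for (int t = 0; t < actsR.size(); ++t) actions[t] = actsR[t] - 1;
    EpisodeFwd ep;
    forward_episode(m, study, actions, 0, (int)actions.size(), ep);
    const int T = (int)ep.steps.size();
    std::vector<vec> dlogits(T);
    std::vector<double> dvalue(T, 0.0);
    for (int t = 0; t < T; ++t) {
      const StepCache& sc = ep.steps[t];
      const int a = sc.action;
      loss -= inv * std::log(std::max(sc.p[a], 1e-300));
      vec dl = inv * sc.p;
      dl[a] -= inv;
      dlogits[t] = dl;
    }
    if (compute_grads) backward_episode(m, ep, dlogits, dvalue, g);
  }
  List out = List::create(_["loss"] = loss);
  if (compute_grads) out["grads"] = grads_to_list(g);
  return out;
}
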