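// Fixed-step simulation engine for the cell-cytokine network.
//
// The network is compiled on the R side into flat index/rate arrays
// (see compile_model()).  One step = (1) refresh noisy rates, (2) one
// classical RK4 advance with rates frozen, (3) apply Poisson jump events,
// (4) clip negatives to zero.  With all noise intensities zero and no
// jump processes the scheme reduces exactly to deterministic RK4, which
// the deterministic-limit tests rely on.
//
// All randomness goes through R's RNG so that set.seed() on the R side
// gives full, portable reproducibility.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double hillf(double c, double Kpow, double n, double K) {
  if (c <= 0.0) return 0.0;
  double cp;
  if (n == 1.0)      cp = c;
  else if (n == 2.0) cp = c * c;
  else               cp = std::pow(c, n);
  return cp / (Kpow + cp);
}

static inline double kpow(double K, double n) {
  if (n == 1.0) return K;
  if (n == 2.0) return K * K;
  return std::pow(K, n);
}

struct FlatModel {
  int n_sp, n_cell, n_cyt, n_conv, n_prod, n_edge, n_jump;
  // cells
  std::vector<double> prolif, decay, cbar;
  std::vector<int> angio_dep;
  // conversions (into dst from src)
  std::vector<int> conv_src, conv_dst;
  std::vector<double> conv_rate;
  // cytokine production pairs and decay
  std::vector<int> prod_cell, prod_cyt;
  std::vector<double> prod_rate, cyt_decay;
  // edges
  std::vector<int> edge_src, edge_dir, edge_ttype, edge_tidx;
  std::vector<double> edge_K, edge_n, edge_a, edge_Kpow;
  // angiogenesis
  int angio_driver;
  double angio_min, angio_K, angio_n, angio_Kpow;
  // jumps
  std::vector<int> jump_target, jump_src, jump_sign;
  std::vector<double> jump_rate, jump_mag;
  // noise
  double sigma_prod, sigma_rate, tau_n, trunc_lo, trunc_hi;
};

static FlatModel unpack(const List& model) {
  FlatModel m;
  NumericVector init = model["init"];
  m.n_sp   = init.size();
  m.n_cell = as<int>(model["n_cell"]);
  m.n_cyt  = m.n_sp - m.n_cell;
  NumericVector prolif = model["prolif"], decay = model["decay"], cbar = model["cbar"];
  IntegerVector adep = model["angio_dep"];
  m.prolif = as<std::vector<double>>(prolif);
  m.decay  = as<std::vector<double>>(decay);
  m.cbar   = as<std::vector<double>>(cbar);
  m.angio_dep = as<std::vector<int>>(adep);
  IntegerVector cs = model["conv_src"], cd = model["conv_dst"];
  NumericVector cr = model["conv_rate"];
  m.conv_src = as<std::vector<int>>(cs);
  m.conv_dst = as<std::vector<int>>(cd);
  m.conv_rate = as<std::vector<double>>(cr);
  m.n_conv = m.conv_src.size();
  IntegerVector pc = model["prod_cell"], py = model["prod_cyt"];
  NumericVector pr = model["prod_rate"], cyd = model["cyt_decay"];
  m.prod_cell = as<std::vector<int>>(pc);
  m.prod_cyt  = as<std::vector<int>>(py);
  m.prod_rate = as<std::vector<double>>(pr);
  m.cyt_decay = as<std::vector<double>>(cyd);
  m.n_prod = m.prod_cell.size();
  IntegerVector es = model["edge_src"], ed = model["edge_dir"],
                et = model["edge_ttype"], ei = model["edge_tidx"];
  NumericVector eK = model["edge_K"], en = model["edge_n"], ea = model["edge_a"];
  m.edge_src = as<std::vector<int>>(es);
  m.edge_dir = as<std::vector<int>>(ed);
  m.edge_ttype = as<std::vector<int>>(et);
  m.edge_tidx = as<std::vector<int>>(ei);
  m.edge_K = as<std::vector<double>>(eK);
  m.edge_n = as<std::vector<double>>(en);
  m.edge_a = as<std::vector<double>>(ea);
  m.n_edge = m.edge_src.size();
  m.edge_Kpow.resize(m.n_edge);
  for (int e = 0; e < m.n_edge; ++e) m.edge_Kpow[e] = kpow(m.edge_K[e], m.edge_n[e]);
  m.angio_driver = as<int>(model["angio_driver"]);
  m.angio_min = as<double>(model["angio_min"]);
  m.angio_K = as<double>(model["angio_K"]);
  m.angio_n = as<double>(model["angio_n"]);
  m.angio_Kpow = kpow(m.angio_K, m.angio_n);
  IntegerVector jt = model["jump_target"], js = model["jump_src"], jg = model["jump_sign"];
  NumericVector jr = model["jump_rate"], jm = model["jump_mag"];
  m.jump_target = as<std::vector<int>>(jt);
  m.jump_src = as<std::vector<int>>(js);
  m.jump_sign = as<std::vector<int>>(jg);
  m.jump_rate = as<std::vector<double>>(jr);
  m.jump_mag = as<std::vector<double>>(jm);
  m.n_jump = m.jump_target.size();
  m.sigma_prod = as<double>(model["sigma_prod"]);
  m.sigma_rate = as<double>(model["sigma_rate"]);
  m.tau_n = as<double>(model["tau_n"]);
  m.trunc_lo = as<double>(model["trunc_lo"]);
  m.trunc_hi = as<double>(model["trunc_hi"]);
  return m;
}

// Derivative of the deterministic skeleton at state c with the supplied
// (possibly noise-perturbed) rate arrays.
static void deriv(const FlatModel& m,
                  const double* c,
                  const double* r_prolif, const double* r_decay,
                  const double* r_conv, const double* r_prod,
                  double* dc,
                  double* mp, double* mdc, double* mdy,
                  double* mpr, double* mcv) {
  for (int i = 0; i < m.n_cell; ++i) { mp[i] = 1.0; mdc[i] = 1.0; }
  for (int j = 0; j < m.n_cyt; ++j) mdy[j] = 1.0;
  for (int p = 0; p < m.n_prod; ++p) mpr[p] = 1.0;
  for (int k = 0; k < m.n_conv; ++k) mcv[k] = 1.0;

  for (int e = 0; e < m.n_edge; ++e) {
    double h = hillf(c[m.edge_src[e]], m.edge_Kpow[e], m.edge_n[e], m.edge_K[e]);
    double a = m.edge_a[e];
    double mod = (m.edge_dir[e] > 0) ? 1.0 + (a - 1.0) * h : 1.0 - (1.0 - a) * h;
    int ti = m.edge_tidx[e];
    switch (m.edge_ttype[e]) {
      case 0: mp[ti] *= mod; break;                       // proliferation
      case 1:                                             // decay (cell or cytokine)
        if (ti < m.n_cell) mdc[ti] *= mod; else mdy[ti - m.n_cell] *= mod;
        break;
      case 2: mpr[ti] *= mod; break;                      // secretion pair
      case 3: mcv[ti] *= mod; break;                      // conversion
      case 4: break;                                      // recruitment (jump), handled per step
    }
  }

  double total = 0.0;
  for (int i = 0; i < m.n_cell; ++i) total += c[i];
  double A = m.angio_min + (1.0 - m.angio_min) *
             hillf(c[m.angio_driver], m.angio_Kpow, m.angio_n, m.angio_K);

  for (int i = 0; i < m.n_cell; ++i) {
    double L = 1.0 - total / m.cbar[i];
    if (L < 0.0) L = 0.0;
    double ang = m.angio_dep[i] ? A : 1.0;
    dc[i] = r_prolif[i] * mp[i] * L * ang * c[i] - r_decay[i] * mdc[i] * c[i];
  }
  for (int k = 0; k < m.n_conv; ++k) {
    double flux = r_conv[k] * mcv[k] * c[m.conv_src[k]];
    dc[m.conv_dst[k]] += flux;
    dc[m.conv_src[k]] -= flux;
  }
  for (int j = 0; j < m.n_cyt; ++j)
    dc[m.n_cell + j] = -m.cyt_decay[j] * mdy[j] * c[m.n_cell + j];
  for (int p = 0; p < m.n_prod; ++p)
    dc[m.n_cell + m.prod_cyt[p]] += r_prod[p] * mpr[p] * c[m.prod_cell[p]];
}

struct Trigger {
  int kind;           // 0 = fixed time, 1 = species threshold (upward)
  int species;
  double value;       // time (days) or threshold concentration
  double duration;    // days; R_PosInf = permanent
  bool fired, reverted;
  double fire_time;
  std::vector<double> m_prolif, m_decay, m_prod, m_conv, m_K;
};

static void apply_mults(FlatModel& m, const Trigger& tr,
                        std::vector<double>& b_prolif, std::vector<double>& b_decay,
                        std::vector<double>& b_prod, std::vector<double>& b_conv,
                        bool invert) {
  for (int i = 0; i < m.n_cell; ++i) {
    double f = tr.m_prolif[i]; if (invert) f = 1.0 / f;
    b_prolif[i] *= f;
    double g = tr.m_decay[i]; if (invert) g = 1.0 / g;
    b_decay[i] *= g;
  }
  for (int p = 0; p < m.n_prod; ++p) {
    double f = tr.m_prod[p]; if (invert) f = 1.0 / f;
    b_prod[p] *= f;
  }
  for (int k = 0; k < m.n_conv; ++k) {
    double f = tr.m_conv[k]; if (invert) f = 1.0 / f;
    b_conv[k] *= f;
  }
  for (int e = 0; e < m.n_edge; ++e) {
    double f = tr.m_K[e]; if (invert) f = 1.0 / f;
    m.edge_K[e] *= f;
    m.edge_Kpow[e] = kpow(m.edge_K[e], m.edge_n[e]);
  }
}

// [[Rcpp::export]]
List engine_run(List model, double t_end, double dt, int record_every,
                bool stochastic, List therapy) {
  FlatModel m = unpack(model);
  NumericVector init = model["init"];
  int n_steps = (int)std::ceil(t_end / dt - 1e-9);
  int n_rec = n_steps / record_every + 1;

  std::vector<Trigger> trig;
  for (int t = 0; t < therapy.size(); ++t) {
    List tl = therapy[t];
    Trigger tr;
    tr.kind = as<int>(tl["kind"]);
    tr.species = as<int>(tl["species"]);
    tr.value = as<double>(tl["value"]);
    tr.duration = as<double>(tl["duration"]);
    tr.fired = false; tr.reverted = false; tr.fire_time = NA_REAL;
    tr.m_prolif = as<std::vector<double>>(tl["m_prolif"]);
    tr.m_decay  = as<std::vector<double>>(tl["m_decay"]);
    tr.m_prod   = as<std::vector<double>>(tl["m_prod"]);
    tr.m_conv   = as<std::vector<double>>(tl["m_conv"]);
    tr.m_K      = as<std::vector<double>>(tl["m_K"]);
    trig.push_back(tr);
  }

  // working copies of basal rates (therapy multiplies these)
  std::vector<double> b_prolif = m.prolif, b_decay = m.decay,
                      b_conv = m.conv_rate, b_prod = m.prod_rate;
  // per-step noisy rates
  std::vector<double> r_prolif = b_prolif, r_decay = b_decay,
                      r_conv = b_conv, r_prod = b_prod;
  // sine-Wiener phases (one per cell proliferation + one per conversion)
  std::vector<double> th_prolif(m.n_cell, 0.0), th_conv(m.n_conv, 0.0);

  std::vector<double> c(init.begin(), init.end());
  std::vector<double> dc(m.n_sp), k1(m.n_sp), k2(m.n_sp), k3(m.n_sp), k4(m.n_sp),
                      tmp(m.n_sp);
  std::vector<double> mp(m.n_cell), mdc(m.n_cell), mdy(m.n_cyt),
                      mpr(m.n_prod), mcv(m.n_conv);

  NumericMatrix out(n_rec, m.n_sp);
  NumericVector out_t(n_rec);
  for (int i = 0; i < m.n_sp; ++i) out(0, i) = c[i];
  out_t[0] = 0.0;
  int rec = 1;

  long clip_count = 0;
  std::vector<double> jump_added(m.n_jump, 0.0);
  std::vector<double> jump_events(m.n_jump, 0.0);
  std::vector<int> rec_edges;
  for (int e = 0; e < m.n_edge; ++e)
    if (m.edge_ttype[e] == 4) rec_edges.push_back(e);

  double sw = (m.tau_n > 0) ? std::sqrt(2.0 / m.tau_n) : 0.0;

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;

    // --- therapy triggers (evaluated on the current state) ---
    for (size_t q = 0; q < trig.size(); ++q) {
      Trigger& tr = trig[q];
      if (!tr.fired) {
        bool fire = (tr.kind == 0) ? (t >= tr.value)
                                   : (c[tr.species] >= tr.value);
        if (fire) {
          tr.fired = true; tr.fire_time = t;
          apply_mults(m, tr, b_prolif, b_decay, b_prod, b_conv, false);
        }
      } else if (!tr.reverted && R_finite(tr.duration) &&
                 t >= tr.fire_time + tr.duration) {
        tr.reverted = true;
        apply_mults(m, tr, b_prolif, b_decay, b_prod, b_conv, true);
      }
    }

    // --- refresh noisy rates (frozen for this step) ---
    if (stochastic) {
      for (int p = 0; p < m.n_prod; ++p) {
        double f = 1.0 + m.sigma_prod * norm_rand();
        if (f < m.trunc_lo) f = m.trunc_lo;
        if (f > m.trunc_hi) f = m.trunc_hi;
        r_prod[p] = b_prod[p] * f;
      }
      for (int i = 0; i < m.n_cell; ++i) {
        th_prolif[i] += sw * std::sqrt(dt) * norm_rand();
        r_prolif[i] = b_prolif[i] * (1.0 + m.sigma_rate * std::sin(th_prolif[i]));
        r_decay[i] = b_decay[i];
      }
      for (int k = 0; k < m.n_conv; ++k) {
        th_conv[k] += sw * std::sqrt(dt) * norm_rand();
        r_conv[k] = b_conv[k] * (1.0 + m.sigma_rate * std::sin(th_conv[k]));
      }
    } else {
      r_prod = b_prod; r_prolif = b_prolif; r_decay = b_decay; r_conv = b_conv;
    }

    // --- RK4 advance with frozen rates ---
    const double* rp = r_prolif.data(); const double* rd = r_decay.data();
    const double* rc = r_conv.data();  const double* rq = r_prod.data();
    deriv(m, c.data(), rp, rd, rc, rq, k1.data(), mp.data(), mdc.data(), mdy.data(), mpr.data(), mcv.data());
    for (int i = 0; i < m.n_sp; ++i) tmp[i] = c[i] + 0.5 * dt * k1[i];
    deriv(m, tmp.data(), rp, rd, rc, rq, k2.data(), mp.data(), mdc.data(), mdy.data(), mpr.data(), mcv.data());
    for (int i = 0; i < m.n_sp; ++i) tmp[i] = c[i] + 0.5 * dt * k2[i];
    deriv(m, tmp.data(), rp, rd, rc, rq, k3.data(), mp.data(), mdc.data(), mdy.data(), mpr.data(), mcv.data());
    for (int i = 0; i < m.n_sp; ++i) tmp[i] = c[i] + dt * k3[i];
    deriv(m, tmp.data(), rp, rd, rc, rq, k4.data(), mp.data(), mdc.data(), mdy.data(), mpr.data(), mcv.data());
    for (int i = 0; i < m.n_sp; ++i)
      c[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    // --- jump events (volume 1 ml: counts are concentration increments) ---
    if (stochastic && m.n_jump > 0) {
      for (int j = 0; j < m.n_jump; ++j) {
        double lam = m.jump_rate[j];
        // recruitment edges modulate the arrival rate
        for (size_t q = 0; q < rec_edges.size(); ++q) {
          int e = rec_edges[q];
          if (m.edge_tidx[e] != j) continue;
          double h = hillf(c[m.edge_src[e]], m.edge_Kpow[e], m.edge_n[e], m.edge_K[e]);
          double a = m.edge_a[e];
          lam *= (m.edge_dir[e] > 0) ? 1.0 + (a - 1.0) * h : 1.0 - (1.0 - a) * h;
        }
        int n_ev = (int)R::rpois(lam * dt);
        if (n_ev <= 0) continue;
        double tot = 0.0;
        for (int ev = 0; ev < n_ev; ++ev)
          tot += 1.0 + R::rpois(m.jump_mag[j] - 1.0);
        int src = m.jump_src[j];
        if (src >= 0) {                       // conversion-type event: conserve cells
          double avail = c[src];
          if (tot > avail) tot = avail;
          c[src] -= tot;
        }
        c[m.jump_target[j]] += m.jump_sign[j] * tot;
        jump_added[j] += m.jump_sign[j] * tot;
        jump_events[j] += n_ev;
      }
    }

    for (int i = 0; i < m.n_sp; ++i)
      if (c[i] < 0.0) { c[i] = 0.0; ++clip_count; }

    if ((s + 1) % record_every == 0 && rec < n_rec) {
      for (int i = 0; i < m.n_sp; ++i) out(rec, i) = c[i];
      out_t[rec] = (s + 1) * dt;
      ++rec;
    }
  }

  NumericVector fire_times(trig.size());
  for (size_t q = 0; q < trig.size(); ++q)
    fire_times[q] = trig[q].fired ? trig[q].fire_time : NA_REAL;

  return List::create(_["time"] = out_t, _["states"] = out,
                      _["clip_count"] = (double)clip_count,
                      _["trigger_times"] = fire_times,
                      _["jump_added"] = NumericVector(jump_added.begin(), jump_added.end()),
                      _["jump_events"] = NumericVector(jump_events.begin(), jump_events.end()));
}

// Derivative of the compiled model at one state; used for cross-checking
// the R-side RHS assembly against the engine.
// [[Rcpp::export]]
NumericVector engine_deriv(List model, NumericVector state) {
  FlatModel m = unpack(model);
  std::vector<double> c(state.begin(), state.end());
  std::vector<double> dc(m.n_sp);
  std::vector<double> mp(m.n_cell), mdc(m.n_cell), mdy(m.n_cyt),
                      mpr(m.n_prod), mcv(m.n_conv);
  deriv(m, c.data(), m.prolif.data(), m.decay.data(), m.conv_rate.data(),
        m.prod_rate.data(), dc.data(), mp.data(), mdc.data(), mdy.data(),
        mpr.data(), mcv.data());
  return NumericVector(dc.begin(), dc.end());
}
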