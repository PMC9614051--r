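// Time-stepped simulation core for the clustered-network clock model.
//
// Update order within one step (double-buffered: every read of V, u, v, x, y
// during a step uses the values holding at the step start):
//   1. deliver recurrent spikes due at t (per-class delay): conductance
//      jumps, spike-triggered plasticity terms (LTD on EE/RE, presynaptic
//      term of the inhibitory rule) at trace left limits, then delayed
//      presynaptic trace increments
//   2. sample external Poisson input and add its conductance jumps
//   3. advance conductance channels (exact exponential decay + jumps)
//   4. accumulate the continuous potentiation term (closed-form within-step
//      integral, pre-step V/v and post-arrival x)
//   5. integrate membranes (exponential Euler, explicit capped exponential
//      spike-initiation term, ceiling V_peak); postsynaptic spike terms of
//      the inhibitory rule; push spikes to the delay ring
//   6. advance u, v (toward pre-step V), x, y traces
//   7. synaptic normalization at tau_norm boundaries
//
// All indices are 0-based internally; spike records are returned with
// 1-based neuron ids within each population.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <climits>
using namespace Rcpp;

namespace {

struct EdgeClass {
  std::string name;
  int src_pop = 0, tgt_pop = 0;
  std::vector<int> src, tgt;      // local population indices
  std::vector<double> w;
  std::vector<int> src_ptr;       // outgoing view: edge ids sorted by source
  std::vector<int> out_perm;
  std::vector<int> in_perm;       // incoming view: edge ids sorted by target
  std::vector<int> tgt_ptr;
  int delay = 1;
  bool plastic = false;
  bool exc = true;                // excitatory source population
  double wmin = 0.0, wmax = 0.0;
  long clipped = 0;
};

inline double clipw(EdgeClass &ec, double w) {
  if (w < ec.wmin) { ec.clipped++; return ec.wmin; }
  if (w > ec.wmax) { ec.clipped++; return ec.wmax; }
  return w;
}

// closed-form within-step potentiation integral: see ltp_window_integral()
inline double ltp_integral(double v0, double V, double dt,
                           double tau_x, double tau_v, double tau_h,
                           double thp, double thd) {
  double gate = V - thp;
  if (gate <= 0.0) return 0.0;
  double A = V - thd, B = v0 - V;
  double h0 = A + B;
  double h1 = A + B * std::exp(-dt / tau_v);
  double out;
  if (h0 >= 0.0 && h1 >= 0.0) {
    out = A * tau_x * (1.0 - std::exp(-dt / tau_x)) +
          B * tau_h * (1.0 - std::exp(-dt / tau_h));
  } else if (h0 <= 0.0 && h1 <= 0.0) {
    return 0.0;
  } else {
    double ts = tau_v * std::log(B / (-A));
    if (ts < 0.0) ts = 0.0;
    if (ts > dt) ts = dt;
    double a, b;
    if (h0 > 0.0) { a = 0.0; b = ts; } else { a = ts; b = dt; }
    out = A * tau_x * (std::exp(-a / tau_x) - std::exp(-b / tau_x)) +
          B * tau_h * (std::exp(-a / tau_h) - std::exp(-b / tau_h));
  }
  if (out < 0.0) out = 0.0;
  return gate * out;
}

// Poisson sampler: cached-inversion for small lambda, R's rpois otherwise
inline int rpois_fast(double lam, double elam) {
  if (lam <= 0.0) return 0;
  if (lam > 12.0) return (int)R::rpois(lam);
  double u = unif_rand();
  double p = elam, cum = p;
  int k = 0;
  while (u > cum && k < 160) {
    ++k;
    p *= lam / k;
    cum += p;
  }
  return k;
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List ec) {
  const int nE = as<int>(ec["n_E"]);
  const int nI = as<int>(ec["n_I"]);
  const int nR = as<int>(ec["n_R"]);
  const double dt = as<double>(ec["dt"]);
  const int n_steps = as<int>(ec["n_steps"]);

  // population layout: E, I, R, S, H
  const int n_pop[5] = {nE, nI, nR, nR, nR};
  int off[5];
  off[0] = 0;
  for (int p = 1; p < 5; ++p) off[p] = off[p - 1] + n_pop[p - 1];
  const int N = off[4] + n_pop[4];

  NumericVector nE_par = ec["neuronE"];
  const double e_tau = nE_par["tau_m"], e_EL = nE_par["E_L"],
               e_DT = nE_par["Delta_T"], e_VT0 = nE_par["V_T0"],
               e_AT = nE_par["A_T"], e_tauT = nE_par["tau_T"],
               e_Vpk = nE_par["V_peak"], e_Vre = nE_par["V_reset"],
               e_taua = nE_par["tau_a"], e_ba = nE_par["b_a"];
  const int e_ref = (int)nE_par["t_ref_steps"];
  NumericVector nI_par = ec["neuronI"];
  const double i_tau = nI_par["tau_m"], i_EL = nI_par["E_L"],
               i_Vth = nI_par["V_th"], i_Vre = nI_par["V_reset"];
  const int i_ref = (int)nI_par["t_ref_steps"];

  NumericVector syn = ec["syn"];
  const double Eex = syn["E_rev_exc"], Ein = syn["E_rev_inh"],
               tre = syn["tau_r_exc"], tde = syn["tau_d_exc"],
               tri = syn["tau_r_inh"], tdi = syn["tau_d_inh"],
               cK = syn["c_K"], cq = syn["c_q"];
  const double dec_de = std::exp(-dt / tde), dec_re = std::exp(-dt / tre);
  const double dec_di = std::exp(-dt / tdi), dec_ri = std::exp(-dt / tri);
  const double gsc_e = cK / (tde - tre), gsc_i = cK / (tdi - tri);

  NumericVector pl = ec["plast"];
  const double A_LTD = pl["A_LTD"], A_LTP = pl["A_LTP"],
               thLTD = pl["theta_LTD"], thLTP = pl["theta_LTP"],
               tau_u = pl["tau_u"], tau_v = pl["tau_v"],
               tau_xEE = pl["tau_x_EE"], tau_xRE = pl["tau_x_RE"],
               alpha = pl["alpha"], A_inh = pl["A_inh"],
               tau_y = pl["tau_y"];
  const double inh_offset = 2.0 * alpha * as<double>(pl["r_0"]) * tau_y;
  const double tau_hEE = 1.0 / (1.0 / tau_xEE + 1.0 / tau_v);
  const double tau_hRE = 1.0 / (1.0 / tau_xRE + 1.0 / tau_v);
  const double dec_T = std::exp(-dt / e_tauT), dec_a = std::exp(-dt / e_taua);
  const double dec_u = std::exp(-dt / tau_u), dec_v = std::exp(-dt / tau_v);
  const double dec_xEE = std::exp(-dt / tau_xEE),
               dec_xRE = std::exp(-dt / tau_xRE),
               dec_y = std::exp(-dt / tau_y);

  const bool frozen = as<bool>(ec["frozen"]);
  const bool norm_on = as<bool>(ec["norm_on"]) && !frozen;
  const int norm_steps = as<int>(ec["norm_steps"]);
  NumericVector K = ec["K"];

  // connection classes
  List cls_in = ec["classes"];
  std::vector<EdgeClass> cls(cls_in.size());
  int iEE = -1, iEI = -1, iRE = -1;
  int max_delay = 1;
  for (int c = 0; c < cls_in.size(); ++c) {
    List L = cls_in[c];
    EdgeClass &e = cls[c];
    e.name = as<std::string>(L["name"]);
    e.src_pop = as<int>(L["src_pop"]);
    e.tgt_pop = as<int>(L["tgt_pop"]);
    e.src = as<std::vector<int>>(L["src"]);
    e.tgt = as<std::vector<int>>(L["tgt"]);
    e.w = as<std::vector<double>>(L["w"]);
    e.delay = as<int>(L["delay_steps"]);
    e.plastic = as<bool>(L["plastic"]) && !frozen;
    e.exc = as<bool>(L["exc"]);
    e.wmin = as<double>(L["wmin"]);
    e.wmax = as<double>(L["wmax"]);
    if (e.delay > max_delay) max_delay = e.delay;
    const int ns = n_pop[e.src_pop];
    e.src_ptr.assign(ns + 1, 0);
    for (size_t k = 0; k < e.src.size(); ++k) e.src_ptr[e.src[k] + 1]++;
    for (int s = 0; s < ns; ++s) e.src_ptr[s + 1] += e.src_ptr[s];
    {
      std::vector<int> fill_s(e.src_ptr.begin(), e.src_ptr.end() - 1);
      e.out_perm.assign(e.src.size(), 0);
      for (size_t k = 0; k < e.src.size(); ++k)
        e.out_perm[fill_s[e.src[k]]++] = (int)k;
    }
    // incoming view
    const int nt = n_pop[e.tgt_pop];
    e.tgt_ptr.assign(nt + 1, 0);
    for (size_t k = 0; k < e.tgt.size(); ++k) e.tgt_ptr[e.tgt[k] + 1]++;
    for (int t = 0; t < nt; ++t) e.tgt_ptr[t + 1] += e.tgt_ptr[t];
    std::vector<int> fill(e.tgt_ptr.begin(), e.tgt_ptr.end() - 1);
    e.in_perm.assign(e.tgt.size(), 0);
    for (size_t k = 0; k < e.tgt.size(); ++k) e.in_perm[fill[e.tgt[k]]++] = (int)k;
    if (e.name == "EE") iEE = c;
    if (e.name == "EI") iEI = c;
    if (e.name == "RE") iRE = c;
  }

  // state arrays
  std::vector<double> V(N), VT(N, e_VT0), a_ad(N, 0.0);
  std::vector<int> refrac(N, 0);
  std::vector<double> zde(N, 0.0), zre(N, 0.0), zdi(N, 0.0), zri(N, 0.0);
  std::vector<double> u_tr(N), v_tr(N), xEE(nE, 0.0), xRE(nE, 0.0);
  std::vector<double> yE(nE, 0.0), yI(nI, 0.0);
  for (int i = 0; i < N; ++i) {
    bool inh_role = (i >= off[1] && i < off[2]) || i >= off[4];
    V[i] = inh_role ? i_EL : e_EL;
    u_tr[i] = v_tr[i] = V[i];
  }
  SEXP st0 = ec["state"];
  if (!Rf_isNull(st0)) {
    List st(st0);
    V = as<std::vector<double>>(st["V"]);
    VT = as<std::vector<double>>(st["V_T"]);
    a_ad = as<std::vector<double>>(st["a"]);
    refrac = as<std::vector<int>>(st["refrac"]);
    zde = as<std::vector<double>>(st["zd_exc"]);
    zre = as<std::vector<double>>(st["zr_exc"]);
    zdi = as<std::vector<double>>(st["zd_inh"]);
    zri = as<std::vector<double>>(st["zr_inh"]);
    u_tr = as<std::vector<double>>(st["u"]);
    v_tr = as<std::vector<double>>(st["v"]);
    xEE = as<std::vector<double>>(st["x_EE"]);
    xRE = as<std::vector<double>>(st["x_RE"]);
    yE = as<std::vector<double>>(st["y_E"]);
    yI = as<std::vector<double>>(st["y_I"]);
  }

  // stimulation program (periodic, piecewise constant, optional trigger lock)
  List prog = ec["program"];
  const int period_steps = as<int>(prog["period_steps"]);
  IntegerVector break_steps = prog["break_steps"];
  List blocks = prog["blocks"];
  std::vector<double> lam_e(N, 0.0), lam_i(N, 0.0),
                      elam_e(N, 1.0), elam_i(N, 1.0),
                      wx_e(N, 0.0), wx_i(N, 0.0);
  int cur_break = -1;
  auto apply_break = [&](int b) {
    std::fill(lam_e.begin(), lam_e.end(), 0.0);
    std::fill(lam_i.begin(), lam_i.end(), 0.0);
    NumericMatrix M = blocks[b];
    for (int r = 0; r < M.nrow(); ++r) {
      int lo = (int)M(r, 0), hi = (int)M(r, 1);
      int ch = (int)M(r, 2);
      double lam = M(r, 3), wx = M(r, 4);
      for (int i = lo; i <= hi; ++i) {
        if (ch == 0) { lam_e[i] += lam; wx_e[i] = wx; }
        else { lam_i[i] += lam; wx_i[i] = wx; }
      }
    }
    for (int i = 0; i < N; ++i) {
      elam_e[i] = std::exp(-lam_e[i]);
      elam_i[i] = std::exp(-lam_i[i]);
    }
    cur_break = b;
  };
  const int n_breaks = break_steps.size();
  // trigger-locked mode: program position resets when the reference
  // cluster activates; otherwise the position wraps periodically
  List trig = ec["trigger"];
  const bool trig_on = as<bool>(trig["on"]);
  IntegerVector trig_ids = trig["ids"];
  const int trig_win = as<int>(trig["window_steps"]);
  const int trig_cnt = as<int>(trig["count_min"]);
  const int trig_refr = as<int>(trig["refractory_steps"]);
  std::vector<int> trig_buf(std::max(trig_win, 1), 0);
  std::vector<char> is_trig(N, 0);
  for (int k = 0; k < trig_ids.size(); ++k) is_trig[trig_ids[k]] = 1;
  int trig_sum = 0, since_trig = 1 << 30;
  long pos = 0;                     // program position (steps)

  // delay ring
  const int ring_len = max_delay + 1;
  std::vector<std::vector<int>> ring(ring_len);

  // recording
  const bool rec_spk = as<bool>(ec["record_spikes"]);
  const int rec_from = as<int>(ec["rec_from_step"]);
  std::vector<int> sp_pop, sp_id;
  std::vector<double> sp_t;
  List recV = ec["record_V"];
  IntegerVector recV_ids = recV["ids"];
  const int recV_every = as<int>(recV["every"]);
  const int n_recV = recV_ids.size();
  std::vector<double> V_rec;
  int n_samples = 0;

  std::vector<double> jump_e(N, 0.0), jump_i(N, 0.0);
  double norm_resid_max = 0.0;
  long norm_events = 0;

  for (int step = 0; step < n_steps; ++step) {
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
    // program position and interval
    if (trig_on) {
      if (pos < period_steps) ++pos; // hold at end until next trigger
    } else {
      pos = step % period_steps;
    }
    int b = 0;
    for (int k = n_breaks - 1; k >= 0; --k) {
      if (break_steps[k] <= pos) { b = k; break; }
    }
    if (b != cur_break) apply_break(b);

    std::fill(jump_e.begin(), jump_e.end(), 0.0);
    std::fill(jump_i.begin(), jump_i.end(), 0.0);

    // 1. delayed recurrent deliveries
    for (auto &e : cls) {
      int slot = ((step - e.delay) % ring_len + ring_len) % ring_len;
      if (step - e.delay < 0) continue;
      const int o_src = off[e.src_pop], o_tgt = off[e.tgt_pop];
      const int lo = o_src, hi = o_src + n_pop[e.src_pop];
      const bool isEE = (e.name == "EE"), isRE = (e.name == "RE"),
                 isEI = (e.name == "EI");
      for (int g : ring[slot]) {
        if (g < lo || g >= hi) continue;
        const int j = g - o_src;
        for (int kk = e.src_ptr[j]; kk < e.src_ptr[j + 1]; ++kk) {
          const int eid = e.out_perm[kk];
          const int tg = o_tgt + e.tgt[eid];
          if (e.exc) jump_e[tg] += e.w[eid]; else jump_i[tg] += e.w[eid];
          if (e.plastic) {
            if (isEE || isRE) {
              double du = u_tr[tg] - thLTD;
              if (du > 0.0) e.w[eid] = clipw(e, e.w[eid] - A_LTD * du);
            } else if (isEI) {
              e.w[eid] = clipw(e, e.w[eid] + A_inh * (yE[tg - off[0]] - inh_offset));
            }
          }
        }
        // delayed presynaptic traces (per spike, not per edge)
        if (isEE) xEE[j] += alpha;
        else if (isRE) xRE[j] += alpha;
      }
    }

    // 2. external Poisson input
    for (int i = 0; i < N; ++i) {
      if (lam_e[i] > 0.0) {
        int k = rpois_fast(lam_e[i], elam_e[i]);
        if (k) jump_e[i] += k * wx_e[i];
      }
      if (lam_i[i] > 0.0) {
        int k = rpois_fast(lam_i[i], elam_i[i]);
        if (k) jump_i[i] += k * wx_i[i];
      }
    }

    // 3. conductances: exact decay + this step's jumps
    for (int i = 0; i < N; ++i) {
      zde[i] = zde[i] * dec_de + jump_e[i];
      zre[i] = zre[i] * dec_re + jump_e[i];
      zdi[i] = zdi[i] * dec_di + jump_i[i];
      zri[i] = zri[i] * dec_ri + jump_i[i];
    }

    // 4. continuous potentiation (EE, RE), pre-step V and v
    if (iEE >= 0 && cls[iEE].plastic) {
      EdgeClass &e = cls[iEE];
      for (int i = 0; i < nE; ++i) {
        const int gi = off[0] + i;
        double J = ltp_integral(v_tr[gi], V[gi], dt, tau_xEE, tau_v, tau_hEE,
                                thLTP, thLTD);
        if (J <= 0.0) continue;
        const double coef = A_LTP * J;
        for (int kk = e.tgt_ptr[i]; kk < e.tgt_ptr[i + 1]; ++kk) {
          const int eid = e.in_perm[kk];
          e.w[eid] = clipw(e, e.w[eid] + coef * xEE[e.src[eid]]);
        }
      }
    }
    if (iRE >= 0 && cls[iRE].plastic) {
      EdgeClass &e = cls[iRE];
      for (int i = 0; i < nR; ++i) {
        const int gi = off[2] + i;
        double J = ltp_integral(v_tr[gi], V[gi], dt, tau_xRE, tau_v, tau_hRE,
                                thLTP, thLTD);
        if (J <= 0.0) continue;
        const double coef = A_LTP * J;
        for (int kk = e.tgt_ptr[i]; kk < e.tgt_ptr[i + 1]; ++kk) {
          const int eid = e.in_perm[kk];
          e.w[eid] = clipw(e, e.w[eid] + coef * xRE[e.src[eid]]);
        }
      }
    }

    // 5. membrane integration; the slot for this step's spikes is reused
    // from ring_len steps ago (fully delivered by now) and must be cleared
    ring[step % ring_len].clear();
    int trig_step_count = 0;
    const double t_now = step * dt;
    for (int i = 0; i < N; ++i) {
      const bool inh_role = (i >= off[1] && i < off[2]) || i >= off[4];
      bool spiked = false;
      if (refrac[i] > 0) {
        refrac[i]--;
        V[i] = inh_role ? i_Vre : e_Vre;
      } else {
        const double ge = gsc_e * (zde[i] - zre[i]);
        const double gi = gsc_i * (zdi[i] - zri[i]);
        const double Vp = V[i];
        double Vn;
        if (!inh_role) {
          const double gamma = (i < off[1]) ? 1.0 : 0.0; // adaptation: E only
          double arg = (Vp - VT[i]) / e_DT;
          if (arg > 16.0) arg = 16.0;
          const double Bc = 1.0 / e_tau + (ge + gi) / cq;
          const double Ac = e_EL / e_tau + e_DT / e_tau * std::exp(arg) -
                            gamma * a_ad[i] + (ge * Eex + gi * Ein) / cq;
          const double Vinf = Ac / Bc;
          Vn = Vinf + (Vp - Vinf) * std::exp(-Bc * dt);
          if (!std::isfinite(Vn)) {
            stop("non-finite membrane potential: neuron %d at t = %.2f ms",
                 i + 1, t_now);
          }
          if (Vn >= e_Vpk) {
            spiked = true;
            Vn = e_Vre;
            // adaptation (threshold and current) is an E-only mechanism
            if (gamma > 0.0) {
              VT[i] += e_AT;
              a_ad[i] += e_ba;
            }
            refrac[i] = e_ref;
          }
        } else {
          const double Bc = 1.0 / i_tau + (ge + gi) / cq;
          const double Ac = i_EL / i_tau + (ge * Eex + gi * Ein) / cq;
          const double Vinf = Ac / Bc;
          Vn = Vinf + (Vp - Vinf) * std::exp(-Bc * dt);
          if (!std::isfinite(Vn)) {
            stop("non-finite membrane potential: neuron %d at t = %.2f ms",
                 i + 1, t_now);
          }
          if (Vn >= i_Vth) {
            spiked = true;
            Vn = i_Vre;
            refrac[i] = i_ref;
          }
        }
        V[i] = Vn;
      }
      if (spiked) {
        ring[step % ring_len].push_back(i);
        if (rec_spk && step >= rec_from) {
          int p = 4;
          for (int q = 0; q < 4; ++q) {
            if (i < off[q + 1]) { p = q; break; }
          }
          sp_pop.push_back(p);
          sp_id.push_back(i - off[p] + 1);
          sp_t.push_back(t_now);
        }
        // inhibitory-rule postsynaptic term: E spike, incoming EI edges
        if (i < off[1] && iEI >= 0 && cls[iEI].plastic) {
          EdgeClass &e = cls[iEI];
          for (int kk = e.tgt_ptr[i]; kk < e.tgt_ptr[i + 1]; ++kk) {
            const int eid = e.in_perm[kk];
            e.w[eid] = clipw(e, e.w[eid] + A_inh * yI[e.src[eid]]);
          }
        }
        // trigger detection on the reference cluster
        if (trig_on && is_trig[i]) trig_step_count++;
      }
    }

    // trigger bookkeeping: sliding-window spike count over the reference
    // cluster; a crossing resets the program position (start of a cycle)
    if (trig_on) {
      const int sl = step % trig_win;
      trig_sum += trig_step_count - trig_buf[sl];
      trig_buf[sl] = trig_step_count;
      since_trig++;
      if (trig_sum >= trig_cnt && since_trig >= trig_refr) {
        pos = 0;
        since_trig = 0;
      }
    }

    // 6. traces (toward pre-step V is not needed here because u/v are read
    // before this point next step; V already updated, so relax toward the
    // updated potential of this step's end)
    for (int i = 0; i < N; ++i) {
      u_tr[i] = V[i] + (u_tr[i] - V[i]) * dec_u;
      v_tr[i] = V[i] + (v_tr[i] - V[i]) * dec_v;
      VT[i] = e_VT0 + (VT[i] - e_VT0) * dec_T;
      a_ad[i] *= dec_a;
    }
    for (int j = 0; j < nE; ++j) { xEE[j] *= dec_xEE; xRE[j] *= dec_xRE; }
    // undelayed spike-rate traces: jump at the spike instant, then decay
    for (int g : ring[step % ring_len]) {
      if (g < off[1]) yE[g] += alpha;
      else if (g < off[2]) yI[g - off[1]] += alpha;
    }
    for (int j = 0; j < nE; ++j) yE[j] *= dec_y;
    for (int j = 0; j < nI; ++j) yI[j] *= dec_y;

    // 7. synaptic normalization
    if (norm_on && iEE >= 0 && cls[iEE].plastic && norm_steps > 0 &&
        (step + 1) % norm_steps == 0) {
      EdgeClass &e = cls[iEE];
      for (int i = 0; i < nE; ++i) {
        const int l = e.tgt_ptr[i + 1] - e.tgt_ptr[i];
        if (l == 0) continue;
        double s = 0.0;
        for (int kk = e.tgt_ptr[i]; kk < e.tgt_ptr[i + 1]; ++kk)
          s += e.w[e.in_perm[kk]];
        const double corr = (s - K[i]) / l;
        double s2 = 0.0;
        for (int kk = e.tgt_ptr[i]; kk < e.tgt_ptr[i + 1]; ++kk) {
          const int eid = e.in_perm[kk];
          e.w[eid] = clipw(e, e.w[eid] - corr);
          s2 += e.w[eid];
        }
        const double resid = std::fabs(s2 - K[i]);
        if (resid > norm_resid_max) norm_resid_max = resid;
      }
      norm_events++;
    }

    // V recording
    if (n_recV > 0 && recV_every > 0 && step % recV_every == 0) {
      for (int q = 0; q < n_recV; ++q) V_rec.push_back(V[recV_ids[q]]);
      n_samples++;
    }
  }

  // outputs
  List w_out(cls.size());
  CharacterVector w_names(cls.size());
  IntegerVector clip_out(cls.size());
  for (size_t c = 0; c < cls.size(); ++c) {
    w_out[c] = NumericVector(cls[c].w.begin(), cls[c].w.end());
    w_names[c] = cls[c].name;
    clip_out[c] = (int)std::min<long>(cls[c].clipped, INT_MAX);
  }
  w_out.attr("names") = w_names;
  clip_out.attr("names") = w_names;

  List state_out = List::create(
    _["V"] = V, _["V_T"] = VT, _["a"] = a_ad, _["refrac"] = refrac,
    _["zd_exc"] = zde, _["zr_exc"] = zre, _["zd_inh"] = zdi,
    _["zr_inh"] = zri, _["u"] = u_tr, _["v"] = v_tr,
    _["x_EE"] = xEE, _["x_RE"] = xRE, _["y_E"] = yE, _["y_I"] = yI);

  NumericMatrix Vrec_out(n_recV > 0 ? n_recV : 0, n_samples);
  if (n_recV > 0 && n_samples > 0) {
    for (int s = 0; s < n_samples; ++s)
      for (int q = 0; q < n_recV; ++q)
        Vrec_out(q, s) = V_rec[(size_t)s * n_recV + q];
  }

  return List::create(
    _["spike_pop"] = IntegerVector(sp_pop.begin(), sp_pop.end()),
    _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["weights"] = w_out,
    _["clipped"] = clip_out,
    _["norm_residual_max"] = norm_resid_max,
    _["norm_events"] = (double)norm_events,
    _["state"] = state_out,
    _["V_rec"] = Vrec_out);
}
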