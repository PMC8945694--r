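#include <Rcpp.h>
using namespace Rcpp;

// Monte Carlo core of the two-zone accumulation process.
//
// A population of floc elements is split between a maintenance volume Vm
// (low substrate, uptake active) and a stimulation zone Vs (high substrate,
// uptake negligible under assumed DO limitation). Each element remembers
// the highest substrate concentration it has recently experienced (c_ref)
// and relaxes its uptake rate towards the hysteretic target with a first-
// order response. Elements move between zones by random selection in
// proportion to flow and suspended-solids concentration; an ideal separator
// keeps every element in the system.
//
// Units: time in seconds internally; specific rates carried in
// mgCOD/gVSS/min; flows in L/s; volumes in L; concentrations mgCOD/L;
// element mass in gVSS; f_pha in gPHA/gVSS.
//
// All randomness comes from R's RNG (seed with set.seed before calling).

// pick k distinct members of the given zone by rejection sampling
static void pick_members(const std::vector<int>& in_s, int zone_flag, int k,
                         int n, std::vector<int>& out) {
  out.clear();
  int guard = 0;
  while ((int)out.size() < k && guard < 100000) {
    int id = (int)(unif_rand() * n);
    if (id >= n) id = n - 1;
    if (in_s[id] == zone_flag) {
      bool dup = false;
      for (int j : out) if (j == id) { dup = true; break; }
      if (!dup) out.push_back(id);
    }
    ++guard;
  }
}

// [[Rcpp::export]]
List process_core(int n_elements, double vm, double vs, double qm_ls,
                  double csf, double f_l, double xa_elem, double f_pha_max,
                  double beta_phb, double alpha, double yos, double qsr,
                  double qsu, double ku, double ks, double tau_resp,
                  double dt, double t_end_s, int macro_every,
                  double record_every_s, bool recirculate,
                  double cref_decay, IntegerVector init_in_s,
                  NumericVector init_f_pha) {
  const int n = n_elements;
  std::vector<int> in_s(init_in_s.begin(), init_in_s.end());
  std::vector<double> c_ref(n, 0.0), q_cur(n, 0.0),
      f_pha(init_f_pha.begin(), init_f_pha.end()), phi(n, 1.0);

  double css = 0.0, csm = 0.0, qf_ls = 0.0;
  const double relax = 1.0 - std::exp(-dt / tau_resp);
  const double qs_sat = qsr + qsu;
  const double pha_per_uptake =
      (1.0 - yos) * dt / (60.0 * beta_phb * 1000.0);  // f_pha per (q * dt)

  double cum_feed = 0.0, cum_eff = 0.0, cum_uptake = 0.0;

  const int n_steps = (int)std::ceil(t_end_s / dt);
  const int rec_every = std::max(1, (int)std::round(record_every_s / dt));
  const int n_rec = n_steps / rec_every + 2;
  NumericVector r_t(n_rec), r_css(n_rec), r_csm(n_rec), r_qf(n_rec),
      r_uptake(n_rec), r_frac(n_rec), r_fpha(n_rec), r_feed(n_rec),
      r_eff(n_rec), r_ns(n_rec);
  int ir = 0;

  std::vector<int> movers;
  double uptake_mg_min = 0.0, cap_mg_min = 1e-12;

  for (int step = 0; step <= n_steps; ++step) {
    // controller + PHA inhibition refresh (macro step)
    if (step % macro_every == 0) {
      double cap = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = f_pha[i] / f_pha_max;
        if (r > 1.0) r = 1.0;
        phi[i] = 1.0 - std::pow(r, alpha);
        if (phi[i] < 0.0) phi[i] = 0.0;
        if (in_s[i] == 0) cap += xa_elem * qs_sat * phi[i];
      }
      cap_mg_min = std::max(cap, 1e-12);           // mgCOD/min
      qf_ls = f_l * cap_mg_min / csf / 60.0;       // L/s
    }

    // element targets, relaxation, uptake sum
    double uptake = 0.0;  // mgCOD/min
    for (int i = 0; i < n; ++i) {
      double target;
      if (in_s[i] == 1) {
        if (css > c_ref[i]) c_ref[i] = css;
        target = 0.0;  // DO-limited stimulation zone
      } else {
        if (csm > c_ref[i]) c_ref[i] = csm;
        double qsm_i = qsr + qsu * c_ref[i] / (ku + c_ref[i]);
        target = qsm_i * csm / (ks + csm) * phi[i];
      }
      if (cref_decay > 0.0) c_ref[i] -= cref_decay * dt * c_ref[i];
      q_cur[i] += (target - q_cur[i]) * relax;
      if (in_s[i] == 0) uptake += xa_elem * q_cur[i];
    }

    // transport between zones (stochastic rounding of expected movers)
    if (recirculate && qm_ls > 0.0) {
      int n_s_now = 0;
      for (int i = 0; i < n; ++i) n_s_now += in_s[i];
      int n_m_now = n - n_s_now;
      double exp_ms = qm_ls * dt * n_m_now / vm;
      double exp_sm = (qm_ls + qf_ls) * dt * n_s_now / vs;
      int k_ms = (int)std::floor(exp_ms) +
                 (unif_rand() < (exp_ms - std::floor(exp_ms)) ? 1 : 0);
      int k_sm = (int)std::floor(exp_sm) +
                 (unif_rand() < (exp_sm - std::floor(exp_sm)) ? 1 : 0);
      if (k_ms > n_m_now) k_ms = n_m_now;
      if (k_sm > n_s_now) k_sm = n_s_now;
      if (k_ms > 0) {
        pick_members(in_s, 0, k_ms, n, movers);
        for (int id : movers) { in_s[id] = 1; if (css > c_ref[id]) c_ref[id] = css; }
      }
      if (k_sm > 0) {
        pick_members(in_s, 1, k_sm, n, movers);
        for (int id : movers) in_s[id] = 0;
      }
    }

    // concentration mass balances (uptake constant over dt)
    double uptake_mg_s = uptake / 60.0;
    double dcsm;
    if (recirculate) {
      double dcss = (qf_ls * csf + qm_ls * csm - (qm_ls + qf_ls) * css) / vs;
      dcsm = ((qm_ls + qf_ls) * css - qm_ls * csm - qf_ls * csm -
              uptake_mg_s) / vm;
      css += dcss * dt;
      if (css < 0.0) css = 0.0;
    } else {
      // feed directly into Vm (no stimulation recirculation)
      dcsm = (qf_ls * csf - qf_ls * csm - uptake_mg_s) / vm;
      css = csm;
    }
    double csm_new = csm + dcsm * dt;
    double scale = 1.0;
    if (csm_new < 0.0) {  // curtail uptake: substrate cannot go negative
      double avail = csm + (dcsm + uptake_mg_s / vm) * dt;  // without uptake
      double need = uptake_mg_s * dt / vm;
      scale = need > 0.0 ? std::max(avail, 0.0) / need : 0.0;
      if (scale > 1.0) scale = 1.0;
      csm_new = std::max(avail - scale * need, 0.0);
    }
    csm = csm_new;

    // polymer accrual and ledgers
    for (int i = 0; i < n; ++i) {
      if (in_s[i] == 0 && q_cur[i] > 0.0) {
        f_pha[i] += q_cur[i] * scale * pha_per_uptake;
        if (f_pha[i] > f_pha_max) f_pha[i] = f_pha_max;
      }
    }
    uptake_mg_min = uptake * scale;
    cum_feed += qf_ls * csf * dt;
    cum_eff += qf_ls * csm * dt;
    cum_uptake += uptake_mg_min / 60.0 * dt;

    if (step % rec_every == 0 && ir < n_rec) {
      int n_s_now = 0;
      double fsum = 0.0;
      for (int i = 0; i < n; ++i) { n_s_now += in_s[i]; fsum += f_pha[i]; }
      r_t[ir] = step * dt / 60.0;
      r_css[ir] = css;
      r_csm[ir] = csm;
      r_qf[ir] = qf_ls * 60.0;
      r_uptake[ir] = uptake_mg_min;
      r_frac[ir] = uptake_mg_min / cap_mg_min;
      r_fpha[ir] = fsum / n;
      r_feed[ir] = cum_feed;
      r_eff[ir] = cum_eff;
      r_ns[ir] = n_s_now;
      ++ir;
    }

    if (!std::isfinite(csm) || !std::isfinite(css) || csm > 10.0 * csf) {
      stop("process simulation diverged at t = %f min (csm = %f, css = %f)",
           step * dt / 60.0, csm, css);
    }
  }

  IntegerVector zone_out(n);
  NumericVector cref_out(n), q_out(n), fpha_out(n);
  for (int i = 0; i < n; ++i) {
    zone_out[i] = in_s[i];
    cref_out[i] = c_ref[i];
    q_out[i] = q_cur[i];
    fpha_out[i] = f_pha[i];
  }

  return List::create(
      _["trajectory"] = List::create(
          _["t_min"] = r_t[Range(0, ir - 1)],
          _["css"] = r_css[Range(0, ir - 1)],
          _["csm"] = r_csm[Range(0, ir - 1)],
          _["qf_l_min"] = r_qf[Range(0, ir - 1)],
          _["uptake_mg_min"] = r_uptake[Range(0, ir - 1)],
          _["uptake_frac"] = r_frac[Range(0, ir - 1)],
          _["mean_fpha"] = r_fpha[Range(0, ir - 1)],
          _["cum_feed_mg"] = r_feed[Range(0, ir - 1)],
          _["cum_effluent_mg"] = r_eff[Range(0, ir - 1)],
          _["n_in_vs"] = r_ns[Range(0, ir - 1)]),
      _["elements"] = List::create(
          _["zone"] = zone_out, _["c_ref"] = cref_out, _["q_cur"] = q_out,
          _["f_pha"] = fpha_out),
      _["ledger"] = List::create(
          _["cum_feed_mg"] = cum_feed, _["cum_effluent_mg"] = cum_eff,
          _["cum_uptake_mg"] = cum_uptake,
          _["dissolved_mg"] = vm * csm + (recirculate ? vs * css : 0.0)));
}
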