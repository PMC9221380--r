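#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step integrator for a small network of two-compartment LC neurons.
// Gating and calcium use exponential-Euler updates (exact for frozen voltage),
// voltages an explicit Euler update. GIRK drive from release events is kept in
// per-edge exponential accumulators so the cost per step is O(edges), not
// O(events): a double-exponential kernel B*(exp(-t/tau_s) - exp(-t/tau_f))
// summed over events is the difference of two decaying sums.

namespace {

struct NeuronPar {
  double cm, g_na, g_k, g_p, g_ahp, g_l, g_ld, g_ca;
  double v_na, v_k, v_ca, v_l, v_ld;
  double g_sd, g_ds, noise_amp;
  double f_ca, k_ca, tau_ca, ahp_kd;
  double v_girk, ca_high, k_rel, girk_scale, rect_slope;
  double theta_m, sigma_m, theta_h, sigma_h;
  double tau_h0, tau_h1, tau_h_v, tau_h_s;
  double theta_n, sigma_n, tau_n0, tau_n1, tau_n_v, tau_n_s;
  double theta_p, sigma_p;
  double spike_thresh, refractory;
};

inline double getp(const NumericVector& v, const char* nm) {
  if (!v.containsElementNamed(nm))
    stop("neuron parameter vector is missing element '%s'", nm);
  return v[nm];
}

NeuronPar parse_params(const NumericVector& p) {
  NeuronPar q;
  q.cm = getp(p, "cm");
  q.g_na = getp(p, "g_na"); q.g_k = getp(p, "g_k"); q.g_p = getp(p, "g_p");
  q.g_ahp = getp(p, "g_ahp"); q.g_l = getp(p, "g_l"); q.g_ld = getp(p, "g_ld");
  q.g_ca = getp(p, "g_ca");
  q.v_na = getp(p, "v_na"); q.v_k = getp(p, "v_k"); q.v_ca = getp(p, "v_ca");
  q.v_l = getp(p, "v_l"); q.v_ld = getp(p, "v_ld");
  q.g_sd = getp(p, "g_sd"); q.g_ds = getp(p, "g_ds");
  q.noise_amp = getp(p, "noise_amp");
  q.f_ca = getp(p, "f_ca"); q.k_ca = getp(p, "k_ca");
  q.tau_ca = getp(p, "tau_ca"); q.ahp_kd = getp(p, "ahp_kd");
  q.v_girk = getp(p, "v_girk"); q.ca_high = getp(p, "ca_high");
  q.k_rel = getp(p, "k_rel"); q.girk_scale = getp(p, "girk_scale");
  q.rect_slope = getp(p, "rect_slope");
  q.theta_m = getp(p, "theta_m"); q.sigma_m = getp(p, "sigma_m");
  q.theta_h = getp(p, "theta_h"); q.sigma_h = getp(p, "sigma_h");
  q.tau_h0 = getp(p, "tau_h0"); q.tau_h1 = getp(p, "tau_h1");
  q.tau_h_v = getp(p, "tau_h_v"); q.tau_h_s = getp(p, "tau_h_s");
  q.theta_n = getp(p, "theta_n"); q.sigma_n = getp(p, "sigma_n");
  q.tau_n0 = getp(p, "tau_n0"); q.tau_n1 = getp(p, "tau_n1");
  q.tau_n_v = getp(p, "tau_n_v"); q.tau_n_s = getp(p, "tau_n_s");
  q.theta_p = getp(p, "theta_p"); q.sigma_p = getp(p, "sigma_p");
  q.spike_thresh = getp(p, "spike_thresh");
  q.refractory = getp(p, "refractory");
  return q;
}

inline double logi(double v, double theta, double sigma) {
  return 1.0 / (1.0 + std::exp(-(v - theta) / sigma));
}

inline double ca_drive(double v) {
  return 1.0 / (1.0 + std::exp(-(v + 25.0) / 2.5));
}

inline double rel_frac(double ca, double ca_high, double k) {
  double cak = std::pow(ca, k);
  return 2.0 * cak / (std::pow(ca_high, k) + cak);
}

} // namespace

// [[Rcpp::export]]
List simulate_network_cpp(List neuron_params, NumericMatrix state0,
                          DataFrame edges, DataFrame gaps, List protocols,
                          double duration, double dt, double record_dt,
                          bool noise_on) {
  const int n = neuron_params.size();
  if (state0.nrow() != n || state0.ncol() != 5)
    stop("state0 must be an n x 5 matrix (v_s, v_d, h, n, ca)");
  std::vector<NeuronPar> par(n);
  for (int i = 0; i < n; ++i)
    par[i] = parse_params(as<NumericVector>(neuron_params[i]));

  // state
  std::vector<double> vs(n), vd(n), hh(n), nn(n), ca(n);
  for (int i = 0; i < n; ++i) {
    vs[i] = state0(i, 0); vd[i] = state0(i, 1);
    hh[i] = state0(i, 2); nn[i] = state0(i, 3); ca[i] = state0(i, 4);
  }

  // edges: src, dst (1-based), weight (S_ij), tau_f, tau_s, amp
  const int ne = edges.nrows();
  IntegerVector e_src, e_dst; NumericVector e_w, e_tf, e_ts, e_amp;
  if (ne > 0) {
    e_src = edges["src"]; e_dst = edges["dst"]; e_w = edges["weight"];
    e_tf = edges["tau_f"]; e_ts = edges["tau_s"]; e_amp = edges["amp"];
  }
  std::vector<double> accS(ne, 0.0), accF(ne, 0.0), decS(ne), decF(ne), Bn(ne);
  for (int e = 0; e < ne; ++e) {
    double tf = e_tf[e], ts = e_ts[e];
    if (!(ts > tf) || tf <= 0) stop("edge %d: requires tau_s > tau_f > 0", e + 1);
    double tp = tf * ts / (ts - tf) * std::log(ts / tf);
    Bn[e] = 1.0 / (std::exp(-tp / ts) - std::exp(-tp / tf));
    decS[e] = std::exp(-dt / ts);
    decF[e] = std::exp(-dt / tf);
  }

  const int ng = gaps.nrows();
  IntegerVector g_a, g_b; NumericVector g_g;
  if (ng > 0) { g_a = gaps["a"]; g_b = gaps["b"]; g_g = gaps["g"]; }

  // protocols: per neuron matrix (onset, dur, amp)
  std::vector<NumericMatrix> prot(n);
  for (int i = 0; i < n; ++i) prot[i] = as<NumericMatrix>(protocols[i]);

  const long nsteps = (long)std::llround(duration / dt);
  const int rec_every = std::max(1, (int)std::llround(record_dt / dt));
  const int nrec = (int)(nsteps / rec_every) + 1;

  NumericVector rt(nrec);
  NumericMatrix r_vs(nrec, n), r_vd(nrec, n), r_ca(nrec, n), r_gg(nrec, n);
  std::vector<std::vector<double>> spikes(n);
  std::vector<double> rel_t, rel_ca, rel_rr; std::vector<int> rel_id;
  std::vector<double> last_spike(n, -1e18);

  const double sqdt = std::sqrt(dt);
  int irec = 0;

  // record initial state
  {
    rt[0] = 0.0;
    for (int i = 0; i < n; ++i) {
      r_vs(0, i) = vs[i]; r_vd(0, i) = vd[i]; r_ca(0, i) = ca[i];
      r_gg(0, i) = 0.0;
    }
    irec = 1;
  }

  std::vector<double> girk_p(n), ggirk(n), igj(n), ielec(n);

  for (long s = 0; s < nsteps; ++s) {
    double t = s * dt;

    // decay release-event accumulators, collect per-neuron open-kernel sum
    std::fill(girk_p.begin(), girk_p.end(), 0.0);
    for (int e = 0; e < ne; ++e) {
      accS[e] *= decS[e]; accF[e] *= decF[e];
      girk_p[e_dst[e] - 1] += accS[e] - accF[e];
    }

    // gap-junction currents on dendrites
    std::fill(igj.begin(), igj.end(), 0.0);
    for (int g = 0; g < ng; ++g) {
      double cur = g_g[g] * (vd[g_a[g] - 1] - vd[g_b[g] - 1]);
      igj[g_a[g] - 1] += cur;
      igj[g_b[g] - 1] -= cur;
    }

    // electrode currents
    for (int i = 0; i < n; ++i) {
      double cur = 0.0;
      const NumericMatrix& pm = prot[i];
      for (int k = 0; k < pm.nrow(); ++k)
        if (t >= pm(k, 0) && t < pm(k, 0) + pm(k, 1)) cur += pm(k, 2);
      ielec[i] = cur;
    }

    for (int i = 0; i < n; ++i) {
      const NeuronPar& q = par[i];
      double v = vs[i];

      double minf = logi(v, q.theta_m, q.sigma_m);
      double pinf = logi(v, q.theta_p, q.sigma_p);
      double i_na = q.g_na * minf * minf * minf * hh[i] * (v - q.v_na);
      double i_k = q.g_k * std::pow(nn[i], 4) * (v - q.v_k);
      double i_p = q.g_p * pinf * (v - q.v_na);
      double r_gate = ca[i] / (ca[i] + q.ahp_kd);
      double i_ahp = q.g_ahp * r_gate * (v - q.v_k);
      double i_ca = q.g_ca * (v - q.v_ca);
      ggirk[i] = q.girk_scale * girk_p[i] /
                 (1.0 + std::exp(q.rect_slope * (v - q.v_girk)));
      double i_girk = ggirk[i] * (v - q.v_girk);
      double i_dend = q.g_sd * (v - vd[i]);
      double i_l = q.g_l * (v - q.v_l);
      double eta = 0.0;
      if (noise_on && q.noise_amp > 0) eta = q.noise_amp * norm_rand() / sqdt;

      double dvs = (ielec[i] - i_na - i_k - i_p - i_ahp - i_ca - i_girk -
                    i_dend - i_l + eta) / q.cm;
      double i_soma = q.g_ds * (vd[i] - v);
      double i_ld = q.g_ld * (vd[i] - q.v_ld);
      double dvd = (-i_soma - igj[i] - i_ld) / q.cm;

      // gating: exponential Euler
      double hinf = logi(v, q.theta_h, q.sigma_h);
      double tauh = q.tau_h0 + q.tau_h1 /
                    (1.0 + std::exp((v - q.tau_h_v) / q.tau_h_s));
      double ninf = logi(v, q.theta_n, q.sigma_n);
      double taun = q.tau_n0 + q.tau_n1 /
                    (1.0 + std::exp((v - q.tau_n_v) / q.tau_n_s));
      hh[i] = hinf + (hh[i] - hinf) * std::exp(-dt / tauh);
      nn[i] = ninf + (nn[i] - ninf) * std::exp(-dt / taun);

      // calcium: exact relaxation toward voltage-dependent steady state
      double cainf = q.f_ca * q.k_ca * q.tau_ca * (q.v_ca - v) * ca_drive(v);
      ca[i] = cainf + (ca[i] - cainf) * std::exp(-dt / q.tau_ca);

      double vs_new = v + dt * dvs;
      double vd_new = vd[i] + dt * dvd;
      if (!std::isfinite(vs_new) || !std::isfinite(vd_new) ||
          !std::isfinite(ca[i]))
        stop("numerical blow-up in neuron %d at t = %.3f ms (try smaller dt)",
             i + 1, t);

      // spike: upward crossing with refractory lockout
      if (v < q.spike_thresh && vs_new >= q.spike_thresh &&
          (t + dt - last_spike[i]) >= q.refractory) {
        double tsp = t + dt;
        last_spike[i] = tsp;
        spikes[i].push_back(tsp);
        double rr = rel_frac(ca[i], q.ca_high, q.k_rel);
        bool released = false;
        for (int e = 0; e < ne; ++e) {
          if (e_src[e] - 1 == i && e_w[e] > 0) {
            double w = Bn[e] * e_amp[e] * e_w[e] * rr;
            accS[e] += w; accF[e] += w;
            released = true;
          }
        }
        if (released) {
          rel_id.push_back(i + 1); rel_t.push_back(tsp);
          rel_ca.push_back(ca[i]); rel_rr.push_back(rr);
        }
      }
      vs[i] = vs_new; vd[i] = vd_new;
    }

    if ((s + 1) % rec_every == 0 && irec < nrec) {
      rt[irec] = (s + 1) * dt;
      for (int i = 0; i < n; ++i) {
        r_vs(irec, i) = vs[i]; r_vd(irec, i) = vd[i];
        r_ca(irec, i) = ca[i]; r_gg(irec, i) = ggirk[i];
      }
      ++irec;
    }
  }

  List sp(n);
  for (int i = 0; i < n; ++i) sp[i] = wrap(spikes[i]);
  NumericMatrix fin(n, 5);
  for (int i = 0; i < n; ++i) {
    fin(i, 0) = vs[i]; fin(i, 1) = vd[i]; fin(i, 2) = hh[i];
    fin(i, 3) = nn[i]; fin(i, 4) = ca[i];
  }
  return List::create(
      _["time_ms"] = rt, _["v_s"] = r_vs, _["v_d"] = r_vd, _["ca"] = r_ca,
      _["g_girk"] = r_gg, _["spikes"] = sp,
      _["releases"] = DataFrame::create(_["neuron"] = wrap(rel_id),
                                        _["t_ap_ms"] = wrap(rel_t),
                                        _["ca_ap_uM"] = wrap(rel_ca),
                                        _["r_rel"] = wrap(rel_rr)),
      _["final_state"] = fin);
}
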