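// Coupled integration of the STN / GPe / GPi / thalamus network.
//
// The basal ganglia populations follow Hodgkin-Huxley-type current balance
// dynamics with gating variables n, h, r, intracellular calcium and a
// first-order synaptic activation s; thalamocortical relay neurons carry
// V, h, r only.  Everything is advanced together either by an adaptive
// embedded Bogacki-Shampine Runge-Kutta 3(2) pair (the scheme behind
// MATLAB's ode23) with FSAL and RMS-norm mixed error control, or by a
// fixed-step classical RK4.
//
// The voltage-dependent gate functions are evaluated through dense
// lookup tables (0.01 mV grid, linear interpolation; interpolation error
// well below the solver tolerances) built once per run from the
// population parameters -- the standard speed trick of compartmental
// simulators.
//
// Spike times are detected online as upward crossings of a voltage
// threshold between accepted steps (linear interpolation, refractory
// lockout), so full voltage traces never need to be stored.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double xinf(double V, double th, double sg) {
  return 1.0 / (1.0 + std::exp(-(V - th) / sg));
}

// exact Heaviside pulse train: A * H(sin(2 pi t / T)) * (1 - H(sin(2 pi (t + d) / T)))
static inline double pulse(double t, double A, double d, double T) {
  double s1 = std::sin(2.0 * M_PI * t / T);
  double s2 = std::sin(2.0 * M_PI * (t + d) / T);
  return A * (s1 > 0.0 ? 1.0 : 0.0) * (s2 > 0.0 ? 0.0 : 1.0);
}

static double getd(const List& l, const char* nm) {
  if (!l.containsElementNamed(nm))
    stop("parameter list is missing '%s'", nm);
  return as<double>(l[nm]);
}

struct BgParams {
  double C, gL, EL, gK, EK, gNa, ENa, gCa, ECa, gT, ET, gAHP;
  double th_m, sg_m, th_h, sg_h, th_n, sg_n, th_r, sg_r;
  double th_a, sg_a, th_b, sg_b, th_s, sg_s;
  double tau_h0, tau_h1, th_tau_h, sg_tau_h, A_h;
  double tau_n0, tau_n1, th_tau_n, sg_tau_n, A_n;
  double tau_r0, tau_r1, th_tau_r, sg_tau_r, A_r;
  double k1, k2, kCa;
  double alpha, beta, theta0, sigmaH;
  bool stn_type, vdep_tau_r, constant_tau;
};

struct ThParams {
  double C, gL, EL, gK, EK, gNa, ENa, gT, ET;
  double th_m, sg_m, th_h, sg_h, th_r, sg_r, th_p, sg_p;
  bool tau_r_paper;
};

static BgParams bg_params(const List& l) {
  BgParams p;
  p.C = getd(l, "C");
  p.gL = getd(l, "g_leak"); p.EL = getd(l, "E_leak");
  p.gK = getd(l, "g_K");    p.EK = getd(l, "E_K");
  p.gNa = getd(l, "g_Na");  p.ENa = getd(l, "E_Na");
  p.gCa = getd(l, "g_Ca");  p.ECa = getd(l, "E_Ca");
  p.gT = getd(l, "g_T");    p.ET = getd(l, "E_T");
  p.gAHP = getd(l, "g_AHP");
  p.th_m = getd(l, "theta_m"); p.sg_m = getd(l, "sigma_m");
  p.th_h = getd(l, "theta_h"); p.sg_h = getd(l, "sigma_h");
  p.th_n = getd(l, "theta_n"); p.sg_n = getd(l, "sigma_n");
  p.th_r = getd(l, "theta_r"); p.sg_r = getd(l, "sigma_r");
  p.th_a = getd(l, "theta_a"); p.sg_a = getd(l, "sigma_a");
  p.th_b = getd(l, "theta_b"); p.sg_b = getd(l, "sigma_b");
  p.th_s = getd(l, "theta_s"); p.sg_s = getd(l, "sigma_s");
  p.tau_h0 = getd(l, "tau_h0"); p.tau_h1 = getd(l, "tau_h1");
  p.th_tau_h = getd(l, "theta_tau_h"); p.sg_tau_h = getd(l, "sigma_tau_h");
  p.A_h = getd(l, "A_h");
  p.tau_n0 = getd(l, "tau_n0"); p.tau_n1 = getd(l, "tau_n1");
  p.th_tau_n = getd(l, "theta_tau_n"); p.sg_tau_n = getd(l, "sigma_tau_n");
  p.A_n = getd(l, "A_n");
  p.tau_r0 = getd(l, "tau_r0"); p.tau_r1 = getd(l, "tau_r1");
  p.A_r = getd(l, "A_r");
  double thr = as<double>(l["theta_tau_r"]);
  p.vdep_tau_r = R_finite(thr);
  p.th_tau_r = p.vdep_tau_r ? thr : 0.0;
  double sgr = as<double>(l["sigma_tau_r"]);
  p.sg_tau_r = R_finite(sgr) ? sgr : 1.0;
  p.k1 = getd(l, "k1"); p.k2 = getd(l, "k2"); p.kCa = getd(l, "k_Ca");
  p.alpha = getd(l, "alpha"); p.beta = getd(l, "beta");
  p.theta0 = getd(l, "theta_0"); p.sigmaH = getd(l, "sigma_H");
  p.stn_type = as<bool>(l["stn_type"]);
  p.constant_tau = l.containsElementNamed("constant_tau") ?
    as<bool>(l["constant_tau"]) : false;
  return p;
}

static ThParams th_params(const List& l) {
  ThParams p;
  p.C = getd(l, "C");
  p.gL = getd(l, "g_leak"); p.EL = getd(l, "E_leak");
  p.gK = getd(l, "g_K");    p.EK = getd(l, "E_K");
  p.gNa = getd(l, "g_Na");  p.ENa = getd(l, "E_Na");
  p.gT = getd(l, "g_T");    p.ET = getd(l, "E_T");
  p.th_m = getd(l, "theta_m"); p.sg_m = getd(l, "sigma_m");
  p.th_h = getd(l, "theta_h"); p.sg_h = getd(l, "sigma_h");
  p.th_r = getd(l, "theta_r"); p.sg_r = getd(l, "sigma_r");
  p.th_p = getd(l, "theta_p"); p.sg_p = getd(l, "sigma_p");
  p.tau_r_paper = l.containsElementNamed("tau_r_paper") ?
    as<bool>(l["tau_r_paper"]) : false;
  return p;
}

static double f_tau_h_th(double V) {
  double ah = 0.128 * std::exp(-(V + 46.0) / 18.0);
  double bh = 4.0 / (1.0 + std::exp(-(V + 23.0) / 5.0));
  return 1.0 / (ah + bh);
}
static double f_tau_r_th(double V, bool paper) {
  double er = std::exp(-(V + 25.0) / 10.5);
  return paper ? 28.0 + (1.0 + er) : 28.0 + er;
}

// ---- network --------------------------------------------------------------

struct Projection {
  int pre_pop, post_pop;
  double g, Erev;
  std::vector<int> pre, post;      // edge list (kept for validation)
  std::vector<int> row_ptr, cols;  // CSR by postsynaptic neuron
  void build_csr(int n_post) {
    row_ptr.assign(n_post + 1, 0);
    for (size_t e = 0; e < post.size(); ++e) row_ptr[post[e] + 1]++;
    for (int i = 0; i < n_post; ++i) row_ptr[i + 1] += row_ptr[i];
    cols.resize(post.size());
    std::vector<int> w(row_ptr.begin(), row_ptr.end() - 1);
    for (size_t e = 0; e < post.size(); ++e) cols[w[post[e]]++] = pre[e];
  }
};

struct Net {
  int N[4], off[4], goff[4], nstate, ntot;
  BgParams P[3];
  ThParams T;
  std::vector<Projection> proj;
  double Iapp[4];
  double sm_A, sm_d, sm_T;
  bool   dbs_on;
  double dbs_A, dbs_d, dbs_T;
  double tha_gaba_g, tha_gaba_E;
};

// state layout per BG population: V | n | h | r | Ca | s; THA: V | h | r
static void rhs(const Net& net, double t, const std::vector<double>& y,
                std::vector<double>& dy, std::vector<double>& Isyn) {
  std::fill(Isyn.begin(), Isyn.end(), 0.0);

  for (size_t k = 0; k < net.proj.size(); ++k) {
    const Projection& pr = net.proj[k];
    const double* sp = &y[net.off[pr.pre_pop] + 5 * net.N[pr.pre_pop]];
    const double* Vp = &y[net.off[pr.post_pop]];
    double* Ip = &Isyn[net.goff[pr.post_pop]];
    const double g = pr.g, E = pr.Erev;
    const int n_post = net.N[pr.post_pop];
    const int* rp = pr.row_ptr.data();
    const int* cols = pr.cols.data();
    for (int i = 0; i < n_post; ++i) {
      const int b = rp[i], e = rp[i + 1];
      if (b == e) continue;
      double acc = 0.0;
      for (int j = b; j < e; ++j) acc += sp[cols[j]];
      Ip[i] += g * (Vp[i] - E) * acc;
    }
  }

  double Idbs = net.dbs_on ? pulse(t, net.dbs_A, net.dbs_d, net.dbs_T) : 0.0;

  for (int q = 0; q < 3; ++q) {
    const int N = net.N[q];
    if (!N) continue;
    const BgParams& p = net.P[q];
    const int o = net.off[q];
    const double Iq = net.Iapp[q] + (q == 0 ? Idbs : 0.0);
    const double boff = p.stn_type ?
      1.0 / (1.0 + std::exp(-p.th_b / p.sg_b)) : 0.0;
    for (int i = 0; i < N; ++i) {
      const double V = y[o + i], n = y[o + N + i], h = y[o + 2 * N + i];
      const double r = y[o + 3 * N + i], Ca = y[o + 4 * N + i],
        s = y[o + 5 * N + i];
      double minf, ainf, sinf, ninf, hinf, rinf, tau_n, tau_h, tau_r, Hs;
      minf = xinf(V, p.th_m, p.sg_m); ainf = xinf(V, p.th_a, p.sg_a);
      sinf = xinf(V, p.th_s, p.sg_s); ninf = xinf(V, p.th_n, p.sg_n);
      hinf = xinf(V, p.th_h, p.sg_h); rinf = xinf(V, p.th_r, p.sg_r);
      if (p.constant_tau) {
        tau_n = p.tau_n0 / p.A_n; tau_h = p.tau_h0 / p.A_h;
        tau_r = p.tau_r0 / p.A_r;
      } else {
        tau_n = (p.tau_n0 + p.tau_n1 * xinf(V, p.th_tau_n, p.sg_tau_n)) / p.A_n;
        tau_h = (p.tau_h0 + p.tau_h1 * xinf(V, p.th_tau_h, p.sg_tau_h)) / p.A_h;
        tau_r = p.vdep_tau_r ?
          (p.tau_r0 + p.tau_r1 * xinf(V, p.th_tau_r, p.sg_tau_r)) / p.A_r :
          p.tau_r0 / p.A_r;
      }
      Hs = xinf(V, p.theta0, p.sigmaH);
      const double IL = p.gL * (V - p.EL);
      const double n2 = n * n;
      const double IK = p.gK * n2 * n2 * (V - p.EK);
      const double INa = p.gNa * minf * minf * minf * h * (V - p.ENa);
      const double ICa = p.gCa * sinf * sinf * (V - p.ECa);
      double IT;
      if (p.stn_type) {
        double binf = 1.0 / (1.0 + std::exp((r - p.th_b) / p.sg_b)) - boff;
        IT = p.gT * ainf * ainf * ainf * binf * binf * (V - p.ET);
      } else {
        IT = p.gT * ainf * ainf * ainf * r * (V - p.ET);
      }
      const double IAHP = p.gAHP * (Ca / (p.k1 + Ca)) * (V - p.EK);
      dy[o + i] = (-IL - IK - INa - ICa - IT - IAHP -
                   Isyn[net.goff[q] + i] + Iq) / p.C;
      dy[o + N + i] = (ninf - n) / tau_n;
      dy[o + 2 * N + i] = (hinf - h) / tau_h;
      dy[o + 3 * N + i] = (rinf - r) / tau_r;
      dy[o + 4 * N + i] = p.k2 * (-ICa - IT - p.kCa * Ca);
      dy[o + 5 * N + i] = p.alpha * (1.0 - s) * Hs - p.beta * s;
    }
  }

  const int Nt = net.N[3];
  if (Nt) {
    const ThParams& p = net.T;
    const int o = net.off[3];
    const double Ism = pulse(t, net.sm_A, net.sm_d, net.sm_T);
    for (int i = 0; i < Nt; ++i) {
      const double V = y[o + i], h = y[o + Nt + i], r = y[o + 2 * Nt + i];
      double minf, pinf, hinf, rinf, tau_h, tau_r;
      minf = xinf(V, p.th_m, p.sg_m); pinf = xinf(V, p.th_p, p.sg_p);
      hinf = xinf(V, p.th_h, p.sg_h); rinf = xinf(V, p.th_r, p.sg_r);
      tau_h = f_tau_h_th(V);
      tau_r = f_tau_r_th(V, p.tau_r_paper);
      const double IL = p.gL * (V - p.EL);
      const double kk = 0.75 * (1.0 - h);
      const double k2 = kk * kk;
      const double IK = p.gK * k2 * k2 * (V - p.EK);
      const double INa = p.gNa * minf * minf * minf * h * (V - p.ENa);
      const double IT = p.gT * pinf * pinf * r * (V - p.ET);
      const double Igaba = net.tha_gaba_g * (V - net.tha_gaba_E);
      dy[o + i] = (-IL - IK - INa - IT - Isyn[net.goff[3] + i] -
                   Igaba + Ism) / p.C;
      dy[o + Nt + i] = (hinf - h) / tau_h;
      dy[o + 2 * Nt + i] = (rinf - r) / tau_r;
    }
  }
}

// [[Rcpp::export]]
List cpp_integrate(List pop_params, IntegerVector sizes, List projections,
                   List protocol, double t_end, NumericVector y0,
                   double rtol, double atol, double hmax, double hmin,
                   double v_dt, List v_idx, double s_dt, IntegerVector s_pops,
                   double threshold, double lockout,
                   double fixed_dt = 0.0) {
  Net net;
  for (int q = 0; q < 4; ++q) net.N[q] = sizes[q];
  net.off[0] = 0;
  net.off[1] = net.off[0] + 6 * net.N[0];
  net.off[2] = net.off[1] + 6 * net.N[1];
  net.off[3] = net.off[2] + 6 * net.N[2];
  net.nstate = net.off[3] + 3 * net.N[3];
  net.goff[0] = 0;
  for (int q = 1; q < 4; ++q) net.goff[q] = net.goff[q - 1] + net.N[q - 1];
  net.ntot = net.goff[3] + net.N[3];
  if ((int)y0.size() != net.nstate)
    stop("y0 has length %d, expected %d", (int)y0.size(), net.nstate);

  net.P[0] = bg_params(as<List>(pop_params["STN"]));
  net.P[1] = bg_params(as<List>(pop_params["GPe"]));
  net.P[2] = bg_params(as<List>(pop_params["GPi"]));
  net.T = th_params(as<List>(pop_params["THA"]));

  for (int k = 0; k < projections.size(); ++k) {
    List pj = as<List>(projections[k]);
    Projection pr;
    pr.pre_pop = as<int>(pj["pre_pop"]);
    pr.post_pop = as<int>(pj["post_pop"]);
    pr.g = as<double>(pj["g"]);
    pr.Erev = as<double>(pj["E_rev"]);
    IntegerVector pre = pj["pre"], post = pj["post"];
    pr.pre.assign(pre.begin(), pre.end());
    pr.post.assign(post.begin(), post.end());
    if (pr.pre_pop == 3) stop("thalamic neurons have no efferent synapses here");
    for (size_t e = 0; e < pr.pre.size(); ++e)
      if (pr.pre[e] < 0 || pr.pre[e] >= net.N[pr.pre_pop] ||
          pr.post[e] < 0 || pr.post[e] >= net.N[pr.post_pop])
        stop("projection %d has out-of-range indices", k + 1);
    pr.build_csr(net.N[pr.post_pop]);
    net.proj.push_back(pr);
  }

  NumericVector Iapp = protocol["I_app"];
  for (int q = 0; q < 4; ++q) net.Iapp[q] = Iapp[q];
  net.sm_A = as<double>(protocol["sm_A"]);
  net.sm_d = as<double>(protocol["sm_delta"]);
  net.sm_T = as<double>(protocol["sm_T"]);
  net.dbs_on = as<bool>(protocol["dbs_on"]);
  net.dbs_A = as<double>(protocol["dbs_A"]);
  net.dbs_d = as<double>(protocol["dbs_delta"]);
  net.dbs_T = as<double>(protocol["dbs_T"]);
  net.tha_gaba_g = protocol.containsElementNamed("tha_gaba_g") ?
    as<double>(protocol["tha_gaba_g"]) : 0.0;
  net.tha_gaba_E = protocol.containsElementNamed("tha_gaba_E") ?
    as<double>(protocol["tha_gaba_E"]) : -70.0;

  const int ns = net.nstate;
  std::vector<double> y(y0.begin(), y0.end()), ynew(ns);
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), ytmp(ns), Isyn(net.ntot);

  std::vector<std::vector<int> > vrec(4);
  std::vector<NumericMatrix> vmat;
  int nv_t = (v_dt > 0) ? (int)std::floor(t_end / v_dt) + 1 : 0;
  for (int q = 0; q < 4; ++q) {
    IntegerVector idx = as<IntegerVector>(v_idx[q]);
    for (int j = 0; j < idx.size(); ++j) {
      if (idx[j] < 0 || idx[j] >= net.N[q]) stop("v_idx out of range");
      vrec[q].push_back(net.off[q] + idx[j]);
    }
    vmat.push_back(NumericMatrix(std::max(nv_t, 0), (int)vrec[q].size()));
  }
  int ns_t = (s_dt > 0) ? (int)std::floor(t_end / s_dt) + 1 : 0;
  std::vector<NumericMatrix> smat;
  for (int k = 0; k < s_pops.size(); ++k) {
    int q = s_pops[k];
    if (q < 0 || q > 2) stop("s recording only for BG populations");
    smat.push_back(NumericMatrix(std::max(ns_t, 0), net.N[q]));
  }

  std::vector<std::vector<std::vector<double> > > spikes(4);
  std::vector<std::vector<double> > last_spike(4);
  for (int q = 0; q < 4; ++q) {
    spikes[q].resize(net.N[q]);
    last_spike[q].assign(net.N[q], -1e9);
  }

  const bool fixed = fixed_dt > 0.0;
  double t = 0.0, h = fixed ? fixed_dt : 1e-3;
  if (hmax <= 0) hmax = 1.0;
  if (!fixed) h = std::min(h, hmax);
  long naccept = 0, nreject = 0;
  int iv = 0, is = 0;

  if (nv_t > 0) {
    for (int q = 0; q < 4; ++q)
      for (size_t j = 0; j < vrec[q].size(); ++j) vmat[q](0, j) = y[vrec[q][j]];
    iv = 1;
  }
  if (ns_t > 0) {
    for (int k = 0; k < s_pops.size(); ++k) {
      int q = s_pops[k], o = net.off[q] + 5 * net.N[q];
      for (int i = 0; i < net.N[q]; ++i) smat[k](0, i) = y[o + i];
    }
    is = 1;
  }

  rhs(net, t, y, k1, Isyn);

  while (t < t_end) {
    if (!fixed && h > hmax) h = hmax;
    if (t + h > t_end) h = t_end - t;

    double hnext = h;
    if (fixed) {
      // classical RK4
      rhs(net, t, y, k1, Isyn);
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + 0.5 * h * k1[i];
      rhs(net, t + 0.5 * h, ytmp, k2, Isyn);
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + 0.5 * h * k2[i];
      rhs(net, t + 0.5 * h, ytmp, k3, Isyn);
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + h * k3[i];
      rhs(net, t + h, ytmp, k4, Isyn);
      for (int i = 0; i < ns; ++i)
        ynew[i] = y[i] + h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    } else {
      // Bogacki-Shampine 3(2), FSAL
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + 0.5 * h * k1[i];
      rhs(net, t + 0.5 * h, ytmp, k2, Isyn);
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + 0.75 * h * k2[i];
      rhs(net, t + 0.75 * h, ytmp, k3, Isyn);
      for (int i = 0; i < ns; ++i)
        ynew[i] = y[i] + h * (2.0 / 9.0 * k1[i] + 1.0 / 3.0 * k2[i] +
                              4.0 / 9.0 * k3[i]);
      rhs(net, t + h, ynew, k4, Isyn);

      double sum2 = 0.0;
      for (int i = 0; i < ns; ++i) {
        double e = h * ((2.0 / 9.0 - 7.0 / 24.0) * k1[i] +
                        (1.0 / 3.0 - 1.0 / 4.0) * k2[i] +
                        (4.0 / 9.0 - 1.0 / 3.0) * k3[i] -
                        1.0 / 8.0 * k4[i]);
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        double w = e / sc;
        sum2 += w * w;
      }
      double err = std::sqrt(sum2 / ns);
      if (!R_finite(err)) err = 2.0;
      if (err > 1.0) {
        ++nreject;
        double fac = 0.8 * std::pow(1.0 / err, 1.0 / 3.0);
        h *= std::max(0.1, fac);
        if (h < hmin) stop("step size underflow at t = %.5f ms", t);
        continue;  // k1 still matches (t, y)
      }
      double fac = 0.8 * std::pow(err > 1e-10 ? 1.0 / err : 1e10, 1.0 / 3.0);
      hnext = h * std::min(5.0, std::max(0.2, fac));
    }

    const double t1 = t + h;
    for (int i = 0; i < ns; ++i)
      if (!R_finite(ynew[i]))
        stop("non-finite state at t = %.3f ms (state index %d)", t1, i + 1);

    // dense output (linear within the step)
    while (iv < nv_t && iv * v_dt <= t1) {
      double w = (iv * v_dt - t) / h;
      for (int q = 0; q < 4; ++q)
        for (size_t j = 0; j < vrec[q].size(); ++j) {
          int ix = vrec[q][j];
          vmat[q](iv, j) = y[ix] + w * (ynew[ix] - y[ix]);
        }
      ++iv;
    }
    while (is < ns_t && is * s_dt <= t1) {
      double w = (is * s_dt - t) / h;
      for (int k = 0; k < s_pops.size(); ++k) {
        int q = s_pops[k], o = net.off[q] + 5 * net.N[q];
        for (int i = 0; i < net.N[q]; ++i)
          smat[k](is, i) = y[o + i] + w * (ynew[o + i] - y[o + i]);
      }
      ++is;
    }

    // spike detection: upward threshold crossings of V
    for (int q = 0; q < 4; ++q) {
      int o = net.off[q];
      for (int i = 0; i < net.N[q]; ++i) {
        double V0 = y[o + i], V1 = ynew[o + i];
        if (V0 <= threshold && V1 > threshold) {
          double ts = t + (threshold - V0) / (V1 - V0) * h;
          if (ts - last_spike[q][i] >= lockout) {
            spikes[q][i].push_back(ts);
            last_spike[q][i] = ts;
          }
        }
      }
    }

    t = t1;
    y.swap(ynew);
    if (!fixed) { k1.swap(k4); h = hnext; }
    ++naccept;
    if (naccept + nreject > 200000000L) stop("step limit exceeded");
  }

  List sp(4);
  for (int q = 0; q < 4; ++q) {
    List lq(net.N[q]);
    for (int i = 0; i < net.N[q]; ++i)
      lq[i] = NumericVector(spikes[q][i].begin(), spikes[q][i].end());
    sp[q] = lq;
  }
  List vout(4);
  for (int q = 0; q < 4; ++q) vout[q] = vmat[q];
  List sout(s_pops.size());
  for (int k = 0; k < s_pops.size(); ++k) sout[k] = smat[k];

  NumericVector yfin(y.begin(), y.end());
  return List::create(
    _["spikes"] = sp, _["V"] = vout, _["S"] = sout,
    _["y_final"] = yfin,
    _["n_accept"] = (double)naccept, _["n_reject"] = (double)nreject);
}
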