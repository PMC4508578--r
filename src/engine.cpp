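// Time-stepped simulation engine for twisted-torus E-I attractor networks.
//
// Exponential integrate-and-fire membranes, single-exponential conductance
// synapses with per-projection delays, per-cell Gaussian current noise,
// theta/velocity/place-cell drive.  Forward Euler at a fixed dt (0.1 ms by
// default); the exponential spike term is clipped to avoid overflow and a
// threshold crossing of V_peak triggers reset + refractory clamp.
//
// All randomness comes from an internal xoshiro128+ stream seeded from R so
// that runs are bit-reproducible for a given seed on any platform.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// splitmix64 used only to expand the user seed into generator state
inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s0, s1;
  bool has_spare;
  double spare;

  explicit Rng(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t x = seed;
    s0 = splitmix64(x);
    s1 = splitmix64(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }

  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }

  // uniform in (0, 1)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // standard normal, Box-Muller with caching
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586476925286766559 * v;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// minimum distance on the twisted torus (vertical wrap shifts x by n_x/2)
inline double torus_dist2(double dx, double dy, double nx, double ny) {
  double best = 1e300;
  for (int k = -1; k <= 1; ++k) {
    double ddy = dy + k * ny;
    double base = dx + k * 0.5 * nx;
    for (int m = -1; m <= 1; ++m) {
      double ddx = base + m * nx;
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 < best) best = d2;
    }
  }
  return best;
}

struct Population {
  int n;
  double C, gL, EL, VT, DT, Vpeak, Vreset;
  int tref_steps;
  std::vector<double> V;
  std::vector<double> ge, gi;   // conductances (nS)
  std::vector<int> refr;        // remaining refractory steps
  Population(List p, NumericVector V0)
      : n(as<int>(p["n"])), C(as<double>(p["C"])), gL(as<double>(p["gL"])),
        EL(as<double>(p["EL"])), VT(as<double>(p["VT"])), DT(as<double>(p["DT"])),
        Vpeak(as<double>(p["Vpeak"])), Vreset(as<double>(p["Vreset"])),
        tref_steps(as<int>(p["tref_steps"])),
        V(V0.begin(), V0.end()), ge(n, 0.0), gi(n, 0.0), refr(n, 0) {}
};

// ring buffer of scheduled conductance increments
struct DelayBuf {
  int size, n;
  std::vector<double> buf; // size x n, row-major
  DelayBuf(int size_, int n_) : size(size_), n(n_), buf((size_t)size_ * n_, 0.0) {}
  inline double *row(int slot) { return &buf[(size_t)slot * n]; }
};

} // namespace

// [[Rcpp::export(name = ".gt_engine")]]
List gt_engine(List args) {
  const double dt = as<double>(args["dt"]);           // ms
  const int n_steps = as<int>(args["n_steps"]);

  Population E(args["E"], args["V0_E"]);
  Population I(args["I"], args["V0_I"]);

  // synapse constants
  List syn = args["syn"];
  const double E_exc = as<double>(syn["E_exc"]);
  const double E_inh = as<double>(syn["E_inh"]);
  const double dec_e = std::exp(-dt / as<double>(syn["tau_exc"]));
  const double dec_i = std::exp(-dt / as<double>(syn["tau_inh"]));
  const double dec_n = std::exp(-dt / as<double>(syn["tau_nmda"]));
  const double nmda_frac = as<double>(syn["nmda_frac"]);
  const bool has_nmda = nmda_frac > 0.0;
  const int d_EI = as<int>(syn["delay_steps_EI"]);
  const int d_IE = as<int>(syn["delay_steps_IE"]);
  const int d_II = as<int>(syn["delay_steps_II"]);
  const int d_EE = as<int>(syn["delay_steps_EE"]);

  // weights, stored transposed: column j = outgoing weights of presynaptic j
  NumericMatrix tW_EI = args["tW_EI"]; // n_I x n_E
  NumericMatrix tW_IE = args["tW_IE"]; // n_E x n_I
  NumericMatrix tW_II = args["tW_II"]; // n_I x n_I or 0 x 0
  NumericMatrix tW_EE = args["tW_EE"]; // n_E x n_E or 0 x 0
  const bool has_II = tW_II.nrow() > 0;
  const bool has_EE = tW_EE.nrow() > 0;

  int max_d = std::max(std::max(d_EI, d_IE), std::max(d_II, d_EE));
  const int ring = max_d + 1;
  DelayBuf buf_ge_E(ring, E.n), buf_gi_E(ring, E.n);
  DelayBuf buf_ge_I(ring, I.n), buf_gi_I(ring, I.n);
  std::vector<double> gn_E(E.n, 0.0), gn_I(I.n, 0.0); // slow (NMDA-like) exc

  // theta drive
  List theta = args["theta"];
  const bool theta_on = as<bool>(theta["enabled"]);
  const double f_theta = as<double>(theta["f_theta"]);   // Hz
  const double Ac_E = as<double>(theta["A_const_E"]);
  const double At_E = as<double>(theta["A_theta_E"]);
  const double Ac_I = as<double>(theta["A_const_I"]);
  const double At_I = as<double>(theta["A_theta_I"]);
  const double phase = as<double>(theta["phase"]);
  const int theta_onset = as<int>(theta["onset_step"]);
  const double two_pi_f = 2.0 * M_PI * f_theta * 1e-3;   // per ms

  // noise: piecewise-constant samples with SD sigma, refreshed every
  // noise_steps engine steps (the original simulator's generator convention)
  const double sigma = as<double>(args["sigma"]);
  const int noise_steps = as<int>(args["noise_steps"]);
  std::vector<double> noise_E(E.n, 0.0), noise_I(I.n, 0.0);

  Rng rng(static_cast<uint64_t>(as<double>(args["seed"])));

  // velocity drive (E cells only, rectified projection on preferred dirs)
  const bool has_vel = as<bool>(args["has_vel"]);
  NumericMatrix dirs_E;           // n_E x 2
  NumericVector vx, vy;           // per trajectory sample
  double vel_gain = 0.0, vel_offset = 0.0;
  int traj_steps = 1;
  bool vel_rect = true;
  if (has_vel) {
    dirs_E = as<NumericMatrix>(args["dirs_E"]);
    vx = as<NumericVector>(args["vx"]);
    vy = as<NumericVector>(args["vy"]);
    vel_gain = as<double>(args["vel_gain"]);
    vel_offset = as<double>(args["vel_offset"]);
    vel_rect = as<bool>(args["vel_rect"]);
    traj_steps = as<int>(args["traj_steps"]);
  }
  std::vector<double> Ivel(E.n, 0.0);

  // place-cell resetting input: Poisson spikes onto E cells whose rate is a
  // Gaussian (in torus metric) of the distance between each cell's position
  // and the trajectory-implied torus position
  const bool has_place = as<bool>(args["has_place"]);
  NumericMatrix coords_E;   // n_E x 2 (torus units)
  NumericVector imp_u, imp_v;
  double pc_rmax = 0.0, pc_sigma = 1.0, pc_w = 0.0, nx_t = 1.0, ny_t = 1.0;
  int place_rate_steps = 1, place_spk_steps = 1;
  std::vector<double> pc_prob; // per-cell spike prob per spike substep
  if (has_place) {
    coords_E = as<NumericMatrix>(args["coords_E"]);
    imp_u = as<NumericVector>(args["imp_u"]);
    imp_v = as<NumericVector>(args["imp_v"]);
    pc_rmax = as<double>(args["pc_rmax"]);       // Hz
    pc_sigma = as<double>(args["pc_sigma"]);     // torus units
    pc_w = as<double>(args["pc_w"]);             // nS per spike
    nx_t = as<double>(args["n_x"]);
    ny_t = as<double>(args["n_y"]);
    place_rate_steps = as<int>(args["place_rate_steps"]);
    place_spk_steps = as<int>(args["place_spk_steps"]);
    pc_prob.assign(E.n, 0.0);
  }

  // recording of inhibitory synaptic currents onto selected E cells
  IntegerVector rec_idx = args["rec_idx"];       // 0-based
  const int rec_every = as<int>(args["rec_every"]);
  const int n_rec = rec_idx.size();
  const int n_rec_samples = n_rec > 0 ? (n_steps / rec_every) : 0;
  NumericMatrix rec_Iinh(n_rec_samples > 0 ? n_rec_samples : 0, n_rec);
  int rec_row = 0;

  std::vector<double> spk_t_E, spk_t_I;
  std::vector<int> spk_i_E, spk_i_I;
  spk_t_E.reserve(1 << 16); spk_t_I.reserve(1 << 16);

  const double fac_E = dt / E.C, fac_I = dt / I.C;
  const double clip_E = 3.0 * (E.Vpeak - E.VT), clip_I = 3.0 * (I.Vpeak - I.VT);

  for (int t = 0; t < n_steps; ++t) {
    const int slot = t % ring;
    const double t_ms = t * dt;

    // deliver delayed conductance increments
    { double *r = buf_ge_E.row(slot); for (int j = 0; j < E.n; ++j) { E.ge[j] += r[j]; if (has_nmda) gn_E[j] += nmda_frac * r[j]; r[j] = 0.0; } }
    { double *r = buf_gi_E.row(slot); for (int j = 0; j < E.n; ++j) { E.gi[j] += r[j]; r[j] = 0.0; } }
    { double *r = buf_ge_I.row(slot); for (int j = 0; j < I.n; ++j) { I.ge[j] += r[j]; if (has_nmda) gn_I[j] += nmda_frac * r[j]; r[j] = 0.0; } }
    { double *r = buf_gi_I.row(slot); for (int j = 0; j < I.n; ++j) { I.gi[j] += r[j]; r[j] = 0.0; } }

    // refresh held noise samples
    if (sigma > 0.0 && t % noise_steps == 0) {
      for (int j = 0; j < E.n; ++j) noise_E[j] = sigma * rng.norm();
      for (int j = 0; j < I.n; ++j) noise_I[j] = sigma * rng.norm();
    }

    // theta drive (raised sinusoid, or its mean before onset / when disabled)
    double th_E, th_I;
    if (theta_on && t >= theta_onset) {
      double s = 0.5 * (1.0 + std::sin(two_pi_f * t_ms + phase));
      th_E = Ac_E + At_E * s;
      th_I = Ac_I + At_I * s;
    } else {
      th_E = Ac_E + 0.5 * At_E;
      th_I = Ac_I + 0.5 * At_I;
    }

    // velocity input
    if (has_vel && t % traj_steps == 0) {
      int k = t / traj_steps;
      if (k >= vx.size()) k = vx.size() - 1;
      const double vxk = vx[k], vyk = vy[k];
      // affine current map: the bump-speed response to the velocity
      // current is concave, so the calibrated map I = gain * v + offset
      // (clamped at zero) linearizes tracking across the walking-speed band
      for (int j = 0; j < E.n; ++j) {
        double p = vxk * dirs_E(j, 0) + vyk * dirs_E(j, 1);
        double I = 0.0;
        if (p > 1e-9) I = std::max(0.0, vel_gain * p + vel_offset);
        else if (!vel_rect) I = -std::max(0.0, -vel_gain * p + vel_offset);
        Ivel[j] = I;
      }
    }

    // place-cell input rates and spikes
    if (has_place) {
      if (t % place_rate_steps == 0) {
        int k = t / place_rate_steps;
        if (k >= imp_u.size()) k = imp_u.size() - 1;
        const double uu = imp_u[k], vv = imp_v[k];
        const double inv2s2 = 1.0 / (2.0 * pc_sigma * pc_sigma);
        const double pfac = pc_rmax * 1e-3 * dt * place_spk_steps; // Hz -> prob/substep
        for (int j = 0; j < E.n; ++j) {
          double d2 = torus_dist2(coords_E(j, 0) - uu, coords_E(j, 1) - vv, nx_t, ny_t);
          pc_prob[j] = pfac * std::exp(-d2 * inv2s2);
        }
      }
      if (t % place_spk_steps == 0) {
        for (int j = 0; j < E.n; ++j) {
          if (pc_prob[j] > 0.0 && rng.unif() < pc_prob[j]) E.ge[j] += pc_w;
        }
      }
    }

    // membrane update, E population
    for (int j = 0; j < E.n; ++j) {
      if (E.refr[j] > 0) { --E.refr[j]; E.V[j] = E.Vreset; continue; }
      double V = E.V[j];
      double arg = V - E.VT; if (arg > clip_E) arg = clip_E;
      double Iion = -E.gL * (V - E.EL) + E.gL * E.DT * std::exp(arg / E.DT);
      double Isyn = -(E.ge[j] + gn_E[j]) * (V - E_exc) - E.gi[j] * (V - E_inh);
      V += fac_E * (Iion + Isyn + th_E + noise_E[j] + Ivel[j]);
      E.V[j] = V;
    }
    // membrane update, I population
    for (int j = 0; j < I.n; ++j) {
      if (I.refr[j] > 0) { --I.refr[j]; I.V[j] = I.Vreset; continue; }
      double V = I.V[j];
      double arg = V - I.VT; if (arg > clip_I) arg = clip_I;
      double Iion = -I.gL * (V - I.EL) + I.gL * I.DT * std::exp(arg / I.DT);
      double Isyn = -(I.ge[j] + gn_I[j]) * (V - E_exc) - I.gi[j] * (V - E_inh);
      V += fac_I * (Iion + Isyn + th_I + noise_I[j]);
      I.V[j] = V;
    }

    // spike detection and scheduling
    for (int j = 0; j < E.n; ++j) {
      if (E.refr[j] == 0 && E.V[j] >= E.Vpeak) {
        E.V[j] = E.Vreset; E.refr[j] = E.tref_steps;
        spk_t_E.push_back(t_ms); spk_i_E.push_back(j + 1);
        {
          double *dst = buf_ge_I.row((t + d_EI) % ring);
          const double *w = &tW_EI(0, j);
          for (int p = 0; p < I.n; ++p) dst[p] += w[p];
        }
        if (has_EE) {
          double *dst = buf_ge_E.row((t + d_EE) % ring);
          const double *w = &tW_EE(0, j);
          for (int p = 0; p < E.n; ++p) dst[p] += w[p];
        }
      }
    }
    for (int j = 0; j < I.n; ++j) {
      if (I.refr[j] == 0 && I.V[j] >= I.Vpeak) {
        I.V[j] = I.Vreset; I.refr[j] = I.tref_steps;
        spk_t_I.push_back(t_ms); spk_i_I.push_back(j + 1);
        {
          double *dst = buf_gi_E.row((t + d_IE) % ring);
          const double *w = &tW_IE(0, j);
          for (int p = 0; p < E.n; ++p) dst[p] += w[p];
        }
        if (has_II) {
          double *dst = buf_gi_I.row((t + d_II) % ring);
          const double *w = &tW_II(0, j);
          for (int p = 0; p < I.n; ++p) dst[p] += w[p];
        }
      }
    }

    // record inhibitory synaptic current onto selected E cells (pA)
    if (n_rec > 0 && t % rec_every == 0 && rec_row < n_rec_samples) {
      for (int r = 0; r < n_rec; ++r) {
        int j = rec_idx[r];
        rec_Iinh(rec_row, r) = E.gi[j] * (E.V[j] - E_inh);
      }
      ++rec_row;
    }

    // conductance decay
    for (int j = 0; j < E.n; ++j) { E.ge[j] *= dec_e; E.gi[j] *= dec_i; }
    for (int j = 0; j < I.n; ++j) { I.ge[j] *= dec_e; I.gi[j] *= dec_i; }
    if (has_nmda) {
      for (int j = 0; j < E.n; ++j) gn_E[j] *= dec_n;
      for (int j = 0; j < I.n; ++j) gn_I[j] *= dec_n;
    }

    if ((t & 0x3fff) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["spike_t_E"] = NumericVector(spk_t_E.begin(), spk_t_E.end()),
      _["spike_i_E"] = IntegerVector(spk_i_E.begin(), spk_i_E.end()),
      _["spike_t_I"] = NumericVector(spk_t_I.begin(), spk_t_I.end()),
      _["spike_i_I"] = IntegerVector(spk_i_I.begin(), spk_i_I.end()),
      _["I_inh_rec"] = rec_Iinh,
      _["V_E"] = NumericVector(E.V.begin(), E.V.end()),
      _["V_I"] = NumericVector(I.V.begin(), I.V.end()));
}

// single-neuron EIF integration used by the membrane-step contract tests
// [[Rcpp::export(name = ".gt_eif_single")]]
List gt_eif_single(List prm, double V0, NumericVector I_in, double dt) {
  const double C = as<double>(prm["C"]), gL = as<double>(prm["gL"]),
               EL = as<double>(prm["EL"]), VT = as<double>(prm["VT"]),
               DT = as<double>(prm["DT"]), Vpeak = as<double>(prm["Vpeak"]),
               Vreset = as<double>(prm["Vreset"]);
  const int tref_steps = as<int>(prm["tref_steps"]);
  const int n = I_in.size();
  NumericVector V(n + 1);
  std::vector<double> spikes;
  V[0] = V0;
  double v = V0; int refr = 0;
  const double clip = 3.0 * (Vpeak - VT);
  for (int t = 0; t < n; ++t) {
    if (refr > 0) { --refr; v = Vreset; V[t + 1] = v; continue; }
    double arg = v - VT; if (arg > clip) arg = clip;
    v += dt / C * (-gL * (v - EL) + gL * DT * std::exp(arg / DT) + I_in[t]);
    if (v >= Vpeak) { v = Vreset; refr = tref_steps; spikes.push_back(t * dt); }
    V[t + 1] = v;
  }
  return List::create(_["V"] = V,
                      _["spikes"] = NumericVector(spikes.begin(), spikes.end()));
}
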