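// Trajectory engine for two-state surface hopping (MASH / FSSH) on the
// Brownian-oscillator spin-boson model.
//
// Reduced units: beta = hbar = mass = 1 by default (kept symbolic below).
// Nuclear dynamics: BAOAB Langevin splitting on the active adiabat
// (gamma = 0 limit is velocity Verlet).  Electronic dynamics: exact
// rotation of the Bloch vector about the field (0, 2*Qdot*d, gap/hbar)
// held piecewise constant over each nuclear step, so the norm |S| = 1 is
// preserved to machine precision.
//
// Per-trajectory RNG substreams (xoshiro256++ seeded via splitmix64 from
// the master seed and the trajectory index) make ensembles independent of
// batch size and execution order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

namespace {

// ---------------------------------------------------------------- RNG ----

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t master, uint64_t stream) {
    // decorrelate streams: mix the stream index into the splitmix state
    uint64_t x = master ^ (0xD1B54A32D192ED03ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0,1]
  double unif() {
    return ((next() >> 11) + 1) * 0x1.0p-53;
  }

  double norm();
};

// Marsaglia-Tsang ziggurat for standard normals (128 layers); the common
// path costs one 64-bit draw, one compare and one multiply.
struct ZigTables {
  double x[130];
  double f[130];
  ZigTables() {
    const double r = 3.442619855899;
    const double v = 9.91256303526217e-3;
    x[0] = v * std::exp(0.5 * r * r);   // pseudo-layer for the tail
    x[1] = r;
    f[0] = std::exp(-0.5 * r * r);
    f[1] = f[0];
    for (int i = 2; i <= 128; ++i) {
      double prev = x[i - 1];
      double fi = v / prev + std::exp(-0.5 * prev * prev);
      x[i] = (i < 128) ? std::sqrt(-2.0 * std::log(fi)) : 0.0;
      f[i] = (i < 128) ? std::exp(-0.5 * x[i] * x[i]) : 1.0;
    }
  }
};

static const ZigTables zig;

double Xoshiro::norm() {
  for (;;) {
    uint64_t u = next();
    int i = (int)(u & 127);
    double sign = (u & 128) ? -1.0 : 1.0;
    double mag = (double)(u >> 11) * 0x1.0p-53;   // [0,1)
    double xx = mag * zig.x[i];
    if (xx < zig.x[i + 1]) return sign * xx;
    if (i == 0) {             // tail beyond r
      const double r = 3.442619855899;
      double x1, y;
      do {
        x1 = -std::log(unif()) / r;
        y = -std::log(unif());
      } while (2.0 * y < x1 * x1);
      return sign * (r + x1);
    }
    // wedge: f increases with i (x decreases); accept under the density
    if (zig.f[i] + unif() * (zig.f[i + 1] - zig.f[i]) <
        std::exp(-0.5 * xx * xx))
      return sign * xx;
  }
}

// -------------------------------------------------------------- model ----

struct Model {
  double lam, eps, delta, omega, gamma, beta, hbar;
  // derived
  double Q0, c1, Qx, om2, fourD2;

  void init() {
    Q0 = std::sqrt(2.0 * lam) / omega;
    om2 = omega * omega;
    c1 = om2 * Q0;                 // d(V_r - V_p)/dQ, constant
    Qx = (lam - eps) / c1;         // diabatic crossing
    fourD2 = 4.0 * delta * delta;
  }

  double vr(double Q) const { return 0.5 * om2 * Q * Q; }
  double vp(double Q) const { double x = Q - Q0; return 0.5 * om2 * x * x - eps; }
  double dV(double Q) const { return c1 * (Q - Qx); }          // V_r - V_p
  double root(double Q) const {                                 // V_+ - V_-
    double g = dV(Q);
    return std::sqrt(g * g + fourD2);
  }
  double vadb(double Q, int n) const {                          // V_n
    double m = 0.5 * (vr(Q) + vp(Q));
    return m + 0.5 * n * root(Q);
  }
  // F = -dV_n/dQ (Hellmann-Feynman on the 2x2 diabatic matrix)
  double force(double Q, int n) const {
    double g = dV(Q);
    double r = std::sqrt(g * g + fourD2);
    double msl = 0.5 * om2 * (2.0 * Q - Q0);   // d(mean)/dQ
    return -(msl + 0.5 * n * g * c1 / r);
  }
  double coupling(double Q) const {                             // d(Q)
    double g = dV(Q);
    return delta * c1 / (g * g + fourD2);
  }
  bool product(double Q, int n) const {
    // boundary Q = Qx assigned to reactant
    return (n == -1 && Q > Qx) || (n == +1 && Q < Qx);
  }
};

Model make_model(const Rcpp::NumericVector &p) {
  Model m;
  m.lam = p["lam"]; m.eps = p["eps"]; m.delta = p["delta"];
  m.omega = p["omega"]; m.gamma = p["gamma"];
  m.beta = p["beta"]; m.hbar = p["hbar"];
  m.init();
  return m;
}

// ----------------------------------------------------- initial sampling ----

// Joint classical Boltzmann sample of (Q, n) over the two adiabats,
// restricted to a region of the (Q, n) product/reactant partition.
// Within a region there is one allowed branch per position, and the branch
// potential tracks that region's diabat to within Delta (the reactant
// branch is V_- left of the crossing and V_+ right of it, both within
// Delta of V_r; mirrored for products).  So rejection uses that diabat's
// Gaussian as proposal:  exp(-beta*V_n) <= exp(beta*Delta) exp(-beta*V_dia),
// giving near-unit acceptance for every driving force.  The unconstrained
// case proposes from the Boltzmann-weighted mixture of both diabats.
// region: 0 = reactant, 1 = product, 2 = unconstrained
struct InitSample { double Q, P; int n; };

InitSample sample_nuclear(const Model &m, int region, Xoshiro &rng) {
  const double sigQ = 1.0 / (std::sqrt(m.beta) * m.omega);
  const double pr_r = (region == 0) ? 1.0
                    : (region == 1) ? 0.0
                    : 1.0 / (1.0 + std::exp(m.beta * m.eps));
  InitSample out;
  for (long attempt = 0; ; ++attempt) {
    if (attempt > 100000000L)
      Rcpp::stop("initial-condition rejection sampling acceptance < 1e-6; check region/model");
    double Q = (rng.unif() < pr_r ? 0.0 : m.Q0) + sigQ * rng.norm();
    int n;
    if (region == 0)      n = (Q > m.Qx) ? +1 : -1;   // reactant branch at this Q
    else if (region == 1) n = (Q >= m.Qx) ? -1 : +1;  // product branch
    else                  n = (rng.unif() < 0.5) ? -1 : +1;
    double vn = m.vadb(Q, n);
    double acc;
    if (region == 0) {
      acc = std::exp(-m.beta * (vn - m.vr(Q) + m.delta));
    } else if (region == 1) {
      acc = std::exp(-m.beta * (vn - m.vp(Q) + m.delta));
    } else {
      double shift = std::min(0.0, -m.eps);
      acc = std::exp(-m.beta * (vn - shift)) /
        (std::exp(m.beta * m.delta) *
         (std::exp(-m.beta * (m.vr(Q) - shift)) +
          std::exp(-m.beta * (m.vp(Q) - shift))));
    }
    if (rng.unif() < acc) { out.Q = Q; out.n = n; break; }
  }
  out.P = rng.norm() / std::sqrt(m.beta);
  return out;
}

struct Bloch { double x, y, z; };

// MASH hemisphere sampling: |S_z| density proportional to |S_z| on the
// hemisphere of the active state; FSSH: pure state (pole).
Bloch sample_electronic(int n, bool mash, Xoshiro &rng) {
  Bloch S;
  if (!mash) { S.x = 0.0; S.y = 0.0; S.z = (double)n; return S; }
  double sz = n * std::sqrt(rng.unif());
  double phi = 6.283185307179586476925286766559 * rng.unif();
  double st = std::sqrt(std::max(0.0, 1.0 - sz * sz));
  S.x = st * std::cos(phi); S.y = st * std::sin(phi); S.z = sz;
  return S;
}

// ------------------------------------------------------------ dynamics ----

struct StepCounters {
  long hops = 0, frustrated = 0, deco = 0, deco_skipped = 0, prob_gt1 = 0;
};

struct Settings {
  int method;            // 0 = MASH, 1 = FSSH
  double dt;
  long nsteps;
  int stride;            // sampling stride (steps)
  bool deco_on;
  double deco_threshold; // energy gap trigger (k_B T units)
  int deco_stride;       // steps between decoherence checks
  bool reflect_frustrated;
};

struct TrajState {
  double Q, P;
  Bloch S;
  int n;
  long hops;
  double F;              // cached force at (Q, n)
};

// One full step: BAOAB nuclear + exact Bloch rotation + hop logic.
inline void do_step(const Model &m, const Settings &st, TrajState &tr,
                    Xoshiro &rng, double cO, double sO, StepCounters &cnt,
                    long step) {
  const double h2 = 0.5 * st.dt;
  double Qold = tr.Q;

  // B A O A B
  tr.P += h2 * tr.F;
  tr.Q += h2 * tr.P;
  if (sO > 0.0) tr.P = cO * tr.P + sO * rng.norm();
  tr.Q += h2 * tr.P;
  tr.F = m.force(tr.Q, tr.n);
  tr.P += h2 * tr.F;

  // electronic rotation with mid-step field
  double Qmid = 0.5 * (Qold + tr.Q);
  double Qdot = (tr.Q - Qold) / st.dt;
  double g = m.dV(Qmid);
  double den = g * g + m.fourD2;
  double gap = std::sqrt(den);
  double d = m.delta * m.c1 / den;
  double by = 2.0 * d * Qdot;
  double bz = gap / m.hbar;
  double w = std::sqrt(by * by + bz * bz);
  if (w > 0.0) {
    double ang = w * st.dt;
    double cw, sw;
#if defined(__GNUC__) && defined(__linux__)
    ::sincos(ang, &sw, &cw);
#else
    cw = std::cos(ang); sw = std::sin(ang);
#endif
    double uy = by / w, uz = bz / w;
    double udotS = uy * tr.S.y + uz * tr.S.z;
    double cxy = uy * tr.S.z - uz * tr.S.y;   // (u x S)_x
    double cxz = -uy * tr.S.x;                // (u x S)_z
    double cyy = uz * tr.S.x;                 // (u x S)_y
    double omc = 1.0 - cw;
    double Sx = tr.S.x * cw + cxy * sw;
    double Sy = tr.S.y * cw + cyy * sw + uy * udotS * omc;
    double Sz = tr.S.z * cw + cxz * sw + uz * udotS * omc;
    tr.S.x = Sx; tr.S.y = Sy; tr.S.z = Sz;
  }

  // hop decision
  bool attempt = false;
  int target = -tr.n;
  if (st.method == 0) {
    attempt = (tr.S.z * tr.n < 0.0);          // Sz = 0 tie keeps current n
  } else {
    double pop = (tr.n == 1) ? 0.5 * (1.0 + tr.S.z) : 0.5 * (1.0 - tr.S.z);
    double raw = tr.n * Qdot * d * tr.S.x * st.dt;
    double prob;
    if (raw <= 0.0) {
      prob = 0.0;
    } else if (pop < 1e-300) {
      prob = 1.0;
    } else {
      prob = raw / pop;
      if (prob > 1.0) { ++cnt.prob_gt1; prob = 1.0; }
    }
    if (prob > 0.0 && rng.unif() < prob) attempt = true;
  }
  if (attempt) {
    double dE = m.vadb(tr.Q, target) - m.vadb(tr.Q, tr.n);
    double P2 = tr.P * tr.P - 2.0 * dE;
    if (P2 >= 0.0) {
      tr.P = (tr.P >= 0.0 ? 1.0 : -1.0) * std::sqrt(P2);
      tr.n = target;
      tr.hops += 1;
      ++cnt.hops;
      tr.F = m.force(tr.Q, tr.n);
    } else {
      if (st.reflect_frustrated) tr.P = -tr.P;
      ++cnt.frustrated;
    }
  }

  // energy-gap-triggered decoherence, checked every deco_stride steps
  if (st.deco_on && (step % st.deco_stride == 0)) {
    if (m.root(tr.Q) > st.deco_threshold) {
      if (st.method == 0) {
        if (tr.S.z * tr.n > 0.0) {
          tr.S = sample_electronic(tr.n, true, rng);
          ++cnt.deco;
        } else {
          ++cnt.deco_skipped;  // inconsistent transient: resampling would flip n
        }
      } else {
        tr.S.x = 0.0; tr.S.y = 0.0; tr.S.z = (double)tr.n;
        ++cnt.deco;
      }
    }
  }
}

}  // namespace

// ------------------------------------------------------------- exports ----

// [[Rcpp::export]]
Rcpp::List cpp_sample_initial(Rcpp::NumericVector params, int n_traj,
                              int region, bool mash, double seed) {
  Model m = make_model(params);
  uint64_t master = (uint64_t)seed;
  Rcpp::NumericVector Q(n_traj), P(n_traj), Sx(n_traj), Sy(n_traj), Sz(n_traj);
  Rcpp::IntegerVector n(n_traj);
  for (int i = 0; i < n_traj; ++i) {
    Xoshiro rng; rng.seed(master, (uint64_t)i);
    InitSample s = sample_nuclear(m, region, rng);
    Bloch S = sample_electronic(s.n, mash, rng);
    Q[i] = s.Q; P[i] = s.P; n[i] = s.n;
    Sx[i] = S.x; Sy[i] = S.y; Sz[i] = S.z;
  }
  return Rcpp::List::create(Rcpp::Named("Q") = Q, Rcpp::Named("P") = P,
                            Rcpp::Named("n") = n, Rcpp::Named("Sx") = Sx,
                            Rcpp::Named("Sy") = Sy, Rcpp::Named("Sz") = Sz);
}

// [[Rcpp::export]]
Rcpp::List cpp_run_ensemble(Rcpp::NumericVector params, int method,
                            int region, int n_traj, double dt, double nsteps_d,
                            int stride, double seed, bool deco_on,
                            double deco_threshold, int deco_stride,
                            bool reflect_frustrated, int max_strata,
                            bool return_final, int n_batches) {
  Model m = make_model(params);
  Settings st{method, dt, (long)nsteps_d, stride, deco_on, deco_threshold,
              deco_stride, reflect_frustrated};
  const long nsteps = st.nsteps;
  const int nsamp = (int)(nsteps / stride) + 1;
  const int nbuck = max_strata + 2;       // 0..max_strata hops, plus remainder

  const double cO = std::exp(-m.gamma * dt);
  const double sO = (m.gamma > 0.0)
      ? std::sqrt((1.0 - cO * cO) / m.beta) : 0.0;

  if (n_batches < 1) n_batches = 1;
  if (n_batches > n_traj) n_batches = n_traj;
  std::vector<double> sum_pp(nsamp, 0.0);
  std::vector<double> batch_pp(static_cast<size_t>(nsamp) * n_batches, 0.0);
  std::vector<double> strata(static_cast<size_t>(nsamp) * nbuck, 0.0);
  std::vector<long> hop_hist(nbuck, 0);
  StepCounters cnt;

  Rcpp::NumericVector fQ, fP, fSz;
  Rcpp::IntegerVector fn;
  if (return_final) {
    fQ = Rcpp::NumericVector(n_traj); fP = Rcpp::NumericVector(n_traj);
    fSz = Rcpp::NumericVector(n_traj); fn = Rcpp::IntegerVector(n_traj);
  }

  uint64_t master = (uint64_t)seed;
  for (int i = 0; i < n_traj; ++i) {
    Xoshiro rng; rng.seed(master, (uint64_t)i);
    InitSample s0 = sample_nuclear(m, region, rng);
    TrajState tr;
    tr.Q = s0.Q; tr.P = s0.P; tr.n = s0.n; tr.hops = 0;
    tr.S = sample_electronic(tr.n, method == 0, rng);
    tr.F = m.force(tr.Q, tr.n);

    const int batch = i % n_batches;
    {  // sample at t = 0
      double pp = m.product(tr.Q, tr.n) ? 1.0 : 0.0;
      sum_pp[0] += pp;
      batch_pp[(size_t)0 * n_batches + batch] += pp;
      strata[0 * nbuck + 0] += pp;
    }
    int isamp = 1;
    for (long step = 1; step <= nsteps; ++step) {
      do_step(m, st, tr, rng, cO, sO, cnt, step);
      if (step % stride == 0) {
        double pp = m.product(tr.Q, tr.n) ? 1.0 : 0.0;
        sum_pp[isamp] += pp;
        batch_pp[(size_t)isamp * n_batches + batch] += pp;
        int b = (tr.hops <= max_strata) ? (int)tr.hops : max_strata + 1;
        strata[(size_t)isamp * nbuck + b] += pp;
        ++isamp;
      }
    }
    int b = (tr.hops <= max_strata) ? (int)tr.hops : max_strata + 1;
    hop_hist[b] += 1;
    if (return_final) {
      fQ[i] = tr.Q; fP[i] = tr.P; fSz[i] = tr.S.z; fn[i] = tr.n;
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::NumericMatrix batch_out(nsamp, n_batches);
  for (int t = 0; t < nsamp; ++t)
    for (int b = 0; b < n_batches; ++b)
      batch_out(t, b) = batch_pp[(size_t)t * n_batches + b];
  Rcpp::NumericMatrix strata_out(nsamp, nbuck);
  for (int t = 0; t < nsamp; ++t)
    for (int b = 0; b < nbuck; ++b)
      strata_out(t, b) = strata[(size_t)t * nbuck + b];

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("sum_pp") = Rcpp::NumericVector(sum_pp.begin(), sum_pp.end()),
      Rcpp::Named("strata") = strata_out,
      Rcpp::Named("batch_pp") = batch_out,
      Rcpp::Named("hop_hist") = Rcpp::IntegerVector(hop_hist.begin(), hop_hist.end()),
      Rcpp::Named("hops_total") = (double)cnt.hops,
      Rcpp::Named("frustrated_total") = (double)cnt.frustrated,
      Rcpp::Named("deco_total") = (double)cnt.deco,
      Rcpp::Named("deco_skipped") = (double)cnt.deco_skipped,
      Rcpp::Named("prob_gt1") = (double)cnt.prob_gt1);
  if (return_final) {
    out["final_Q"] = fQ; out["final_P"] = fP;
    out["final_Sz"] = fSz; out["final_n"] = fn;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_run_trajectory(Rcpp::NumericVector params, int method,
                              double Q, double P, int n,
                              double Sx, double Sy, double Sz,
                              double dt, double nsteps_d, int stride,
                              double seed, double traj_index,
                              bool deco_on, double deco_threshold,
                              int deco_stride, bool reflect_frustrated) {
  Model m = make_model(params);
  Settings st{method, dt, (long)nsteps_d, stride, deco_on, deco_threshold,
              deco_stride, reflect_frustrated};
  const long nsteps = st.nsteps;
  const int nsamp = (int)(nsteps / stride) + 1;

  const double cO = std::exp(-m.gamma * dt);
  const double sO = (m.gamma > 0.0)
      ? std::sqrt((1.0 - cO * cO) / m.beta) : 0.0;

  Xoshiro rng; rng.seed((uint64_t)seed, (uint64_t)traj_index);

  TrajState tr;
  tr.Q = Q; tr.P = P; tr.n = n; tr.hops = 0;
  tr.S.x = Sx; tr.S.y = Sy; tr.S.z = Sz;
  tr.F = m.force(tr.Q, tr.n);

  Rcpp::NumericVector ot(nsamp), oQ(nsamp), oP(nsamp),
      oSx(nsamp), oSy(nsamp), oSz(nsamp);
  Rcpp::IntegerVector on(nsamp), ohops(nsamp), ofrust(nsamp);
  StepCounters cnt;

  auto record = [&](int k, long step) {
    ot[k] = step * dt; oQ[k] = tr.Q; oP[k] = tr.P;
    oSx[k] = tr.S.x; oSy[k] = tr.S.y; oSz[k] = tr.S.z;
    on[k] = tr.n; ohops[k] = (int)tr.hops; ofrust[k] = (int)cnt.frustrated;
  };
  record(0, 0);
  int isamp = 1;
  for (long step = 1; step <= nsteps; ++step) {
    do_step(m, st, tr, rng, cO, sO, cnt, step);
    if (step % stride == 0) record(isamp++, step);
  }

  return Rcpp::List::create(
      Rcpp::Named("t") = ot, Rcpp::Named("Q") = oQ, Rcpp::Named("P") = oP,
      Rcpp::Named("Sx") = oSx, Rcpp::Named("Sy") = oSy, Rcpp::Named("Sz") = oSz,
      Rcpp::Named("n") = on, Rcpp::Named("hops") = ohops,
      Rcpp::Named("frustrated") = ofrust,
      Rcpp::Named("hops_total") = (double)cnt.hops,
      Rcpp::Named("frustrated_total") = (double)cnt.frustrated,
      Rcpp::Named("deco_total") = (double)cnt.deco,
      Rcpp::Named("prob_gt1") = (double)cnt.prob_gt1);
}
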