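#include <Rcpp.h>
using namespace Rcpp;

// One-dimensional random walk through a layered domain with semi-permeable
// membranes. Walkers are independent; each step draws a sign (one uniform),
// moves by sqrt(2 D_i dt), and resolves at most one membrane interaction:
// the step is split at the barrier into dx_i + dx_j, a transit draw (second
// uniform, only when an interaction occurs) is compared against the model's
// transit probability, and the walker either transmits with the remaining
// sub-step rescaled by sqrt(D_j / D_i) or reflects elastically. Domain ends
// are impermeable and always reflect.
//
// model: 0 = reference (p = 2 k dx_i / (D_i + 2 k dx_i)),
//        1 = hybrid    (p = p_ref * min(1, sqrt(D_j / D_i))).
//
// Returns per-step directional crossing counts per internal interface, and
// per-step compartment occupancy counts (both optional), plus position
// snapshots at requested steps.
//
// The per-run uniform stream comes from an inline xoshiro256+ generator
// whose state is seeded from R's RNG, so runs remain bit-reproducible from
// set.seed() while avoiding the R API call overhead in the hot loop.

namespace {

struct Xoshiro256p {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256p(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform double in [0, 1)
  double runif() { return (next() >> 11) * 0x1.0p-53; }
};

}  // namespace

// [[Rcpp::export(name = ".rw_simulate")]]
List rw_simulate(NumericVector barriers, NumericVector D, NumericVector kappa,
                 NumericVector x0, IntegerVector comp0, double dt, int nsteps,
                 int model, bool record_flux, bool record_counts,
                 IntegerVector snapshot_steps) {
  const int m = D.size();
  const int np = x0.size();
  const int nifc = m - 1;

  NumericVector x = clone(x0);
  IntegerVector comp = clone(comp0);  // 0-based compartment index

  // precomputed per-compartment step lengths and per-interface quantities
  std::vector<double> stepl(m);
  for (int i = 0; i < m; ++i) stepl[i] = std::sqrt(2.0 * D[i] * dt);
  // rescale[i][dir], pd[i][dir]: dir 0 = crossing interface i+1 L->R
  // (from comp i to i+1), dir 1 = crossing R->L (from comp i+1 to i)
  std::vector<double> resc_lr(std::max(nifc, 1)), resc_rl(std::max(nifc, 1)),
      pd_lr(std::max(nifc, 1)), pd_rl(std::max(nifc, 1));
  for (int i = 0; i < nifc; ++i) {
    resc_lr[i] = std::sqrt(D[i + 1] / D[i]);
    resc_rl[i] = std::sqrt(D[i] / D[i + 1]);
    pd_lr[i] = std::min(1.0, resc_lr[i]);
    pd_rl[i] = std::min(1.0, resc_rl[i]);
  }

  IntegerMatrix cross_lr(record_flux ? nsteps : 0,
                         record_flux ? nifc : 0);
  IntegerMatrix cross_rl(record_flux ? nsteps : 0,
                         record_flux ? nifc : 0);
  IntegerMatrix counts(record_counts ? nsteps : 0,
                       record_counts ? m : 0);

  // snapshots: snapshot_steps are 1-based step indices, ascending
  List snaps(snapshot_steps.size());
  int next_snap = 0;

  uint64_t seed;
  {
    RNGScope scope;  // derive the stream seed from R's RNG (set.seed-driven)
    seed = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
           (uint64_t)(unif_rand() * 4294967296.0);
  }
  Xoshiro256p rng(seed);

  for (int k = 0; k < nsteps; ++k) {
    for (int p = 0; p < np; ++p) {
      int ci = comp[p];
      double s = (rng.runif() < 0.5) ? -1.0 : 1.0;
      double dx = s * stepl[ci];
      double xn = x[p] + dx;
      double bl = barriers[ci], br = barriers[ci + 1];
      if (xn >= bl && xn <= br) {  // free step inside the compartment
        x[p] = xn;
        continue;
      }
      // membrane interaction
      double xb = (s > 0) ? br : bl;
      int ifc = (s > 0) ? ci + 1 : ci;      // barrier index in 0..m
      double dxi = std::fabs(xb - x[p]);
      double dxj = stepl[ci] - dxi;
      bool is_end = (ifc == 0 || ifc == m);
      double kap = kappa[ifc];
      bool transmit = false;
      if (!is_end && kap > 0.0) {
        double p_t;
        if (model == 1) {
          // hybrid: membrane transit is resolved in the low-diffusivity
          // medium (the membrane sits on the low-D side of the infinitesimal
          // gap), so the walker's distance to the barrier is mapped into
          // that medium by the step rescaling; the diffusivity-step
          // acceptance min(1, sqrt(D_j / D_i)) multiplies it.
          double pd = (s > 0) ? pd_lr[ci] : pd_rl[ci - 1];
          double dxe = dxi * pd;             // pd = min(1, sqrt(Dj/Di))
          int cj = (s > 0) ? ci + 1 : ci - 1;
          double Dlow = std::min(D[ci], D[cj]);
          p_t = pd * 2.0 * kap * dxe / (Dlow + 2.0 * kap * dxe);
        } else {
          p_t = 2.0 * kap * dxi / (D[ci] + 2.0 * kap * dxi);
        }
        double u = rng.runif();
        transmit = (u < p_t);
      } else if (!is_end) {
        // kappa == 0 internal: reflection certain, but keep the draw order
        // identical across models (no transit draw when p_t would be 0 is
        // model-independent, so skipping it preserves reproducibility)
        transmit = false;
      }
      if (transmit) {
        int cj = (s > 0) ? ci + 1 : ci - 1;
        double resc = (s > 0) ? resc_lr[ci] : resc_rl[ci - 1];
        double xt = xb + s * dxj * resc;
        // guarded by dt <= dt_max: the rescaled sub-step fits in compartment j
        if (xt < barriers[cj] || xt > barriers[cj + 1])
          stop("walker overshot its new compartment; time step exceeds the domain limit");
        x[p] = xt;
        comp[p] = cj;
        if (record_flux) {
          if (s > 0) cross_lr(k, ci) += 1; else cross_rl(k, ci - 1) += 1;
        }
      } else {
        double xr = xb - s * dxj;
        if (xr < bl || xr > br)
          stop("reflected walker left its compartment; time step exceeds the domain limit");
        x[p] = xr;
      }
    }
    if (record_counts) {
      for (int p = 0; p < np; ++p) counts(k, comp[p]) += 1;
    }
    if (next_snap < snapshot_steps.size() && snapshot_steps[next_snap] == k + 1) {
      snaps[next_snap] = clone(x);
      ++next_snap;
    }
    if ((k & 1023) == 0) checkUserInterrupt();
  }
  return List::create(_["x"] = x, _["comp"] = comp,
                      _["cross_lr"] = cross_lr, _["cross_rl"] = cross_rl,
                      _["counts"] = counts, _["snapshots"] = snaps);
}
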