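#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG: splitmix64. Replicate r of a run seeded with s draws
// from an independent stream derived from (s, r), so replicates are
// reproducible and order-independent. All stochastic code in the package
// uses this stream, never R's global RNG.
// ---------------------------------------------------------------------------

static inline uint64_t fmix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t sm64_next(uint64_t &state) {
  state += 0x9E3779B97F4A7C15ULL;
  return fmix64(state);
}

// Initial state for replicate `rep` of a run seeded with `master`. Both
// inputs pass through the full avalanche mix so that distinct (seed, rep)
// pairs land in unrelated regions of the splitmix64 counter sequence; a
// plain additive or XOR offset by the internal increment would make
// replicate streams shifted copies of one another.
static inline uint64_t stream_seed(double master, uint64_t rep) {
  uint64_t s = (uint64_t)((int64_t)master);
  return fmix64(fmix64(s + 0x9E3779B97F4A7C15ULL) ^
                fmix64(rep + 0x632BE59BD9B4E019ULL));
}

static inline double runif01(uint64_t &state) {
  return ((sm64_next(state) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export]]
NumericVector runif_stream_cpp(int n, double seed) {
  uint64_t st = stream_seed(seed, 0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = runif01(st);
  return out;
}

// ---------------------------------------------------------------------------
// Within-group Gillespie birth-death-mutation simulation.
//
// Cell trait map, rows g1..g8: (z_u, z_v, z_p).
// Birth rate of genotype i:   b_i = (1 - s_c z_u,i) / (1 - s_c zbar_u)
//   (control variant:         b_i = (1 - s_c + s_c z_w,i) /
//                                   (1 - s_c + s_c zbar_w), z_w in u slot)
// Death rate of genotype i:   d_i = (1 - s_c z_v,i) / (1 - s_c zbar_v)
//                                   * (N - 1) / K
// Propensities n_i b_i, n_i d_i over 16 channels, recomputed after every
// event (rates are frequency dependent). On birth the offspring genotype is
// drawn from row i of the mutation matrix H by inverse CDF.
// ---------------------------------------------------------------------------

static const int ZU[8] = {0,0,0,0,1,1,1,1};
static const int ZV[8] = {0,0,1,1,0,0,1,1};
static const int ZP[8] = {0,1,0,1,0,1,0,1};

struct GroupState {
  long n[8];
  long N, su, sv, sp;
  void init(const IntegerVector &founders) {
    N = su = sv = sp = 0;
    for (int i = 0; i < 8; ++i) {
      n[i] = founders[i];
      N  += n[i];
      su += n[i] * ZU[i];
      sv += n[i] * ZV[i];
      sp += n[i] * ZP[i];
    }
  }
  void add(int i, int delta) {
    n[i] += delta; N += delta;
    su += delta * ZU[i]; sv += delta * ZV[i]; sp += delta * ZP[i];
  }
};

static inline void cell_rates(const GroupState &st, double s_c, int K,
                              bool control, double *b, double *d) {
  double zu = (double)st.su / st.N;
  double zv = (double)st.sv / st.N;
  double denom_b = control ? (1.0 - s_c + s_c * zu) : (1.0 - s_c * zu);
  double denom_d = 1.0 - s_c * zv;
  double crowd = (double)(st.N - 1) / K;
  for (int i = 0; i < 8; ++i) {
    b[i] = control ? (1.0 - s_c + s_c * ZU[i]) / denom_b
                   : (1.0 - s_c * ZU[i]) / denom_b;
    d[i] = (1.0 - s_c * ZV[i]) / denom_d * crowd;
  }
}

// [[Rcpp::export]]
List sim_group_cpp(IntegerVector founders, NumericMatrix H, double s_c,
                   int K, bool control, NumericVector age_grid,
                   int n_replicates, double seed, bool record_dfe) {
  const int NA_ = age_grid.size();
  NumericMatrix mean_counts(8, NA_), mean_freq(8, NA_);
  NumericMatrix mean_trait(3, NA_);
  NumericVector mean_N(NA_);
  std::vector<double> dfe;  // rows of (rep, age, anc, desc, effect)

  // per-row mutation CDFs
  double cdf[8][8];
  for (int i = 0; i < 8; ++i) {
    double c = 0.0;
    for (int j = 0; j < 8; ++j) { c += H(i, j); cdf[i][j] = c; }
    cdf[i][7] = 1.0 + 1e-12;
  }

  const double horizon = age_grid[NA_ - 1];
  double b[8], d[8], ab[8], ad[8];

  for (int rep = 0; rep < n_replicates; ++rep) {
    uint64_t rng = stream_seed(seed, (uint64_t)rep);
    GroupState st; st.init(founders);
    double t = 0.0;
    int gp = 0;

    auto record_upto = [&](double tnew) {
      while (gp < NA_ && age_grid[gp] <= tnew) {
        double invN = 1.0 / st.N;
        for (int i = 0; i < 8; ++i) {
          mean_counts(i, gp) += st.n[i];
          mean_freq(i, gp)   += st.n[i] * invN;
        }
        mean_trait(0, gp) += st.su * invN;
        mean_trait(1, gp) += st.sv * invN;
        mean_trait(2, gp) += st.N > 0 ? st.sp * invN : 0.0;
        mean_N[gp] += st.N;
        ++gp;
      }
    };

    record_upto(0.0);
    while (gp < NA_) {
      cell_rates(st, s_c, K, control, b, d);
      double A = 0.0;
      for (int i = 0; i < 8; ++i) {
        ab[i] = st.n[i] * b[i];
        ad[i] = st.n[i] * d[i];
        A += ab[i] + ad[i];
      }
      if (!(A > 0.0) || !std::isfinite(A))
        stop("non-finite or non-positive total propensity");
      double tau = -std::log(runif01(rng)) / A;
      double tnew = t + tau;
      record_upto(tnew);
      if (gp >= NA_ || tnew > horizon) break;
      t = tnew;
      double r = runif01(rng) * A;
      int ch = -1; bool birth = true;
      for (int i = 0; i < 8; ++i) { if (r < ab[i]) { ch = i; break; } r -= ab[i]; }
      if (ch < 0) {
        birth = false;
        for (int i = 0; i < 8; ++i) { if (r < ad[i]) { ch = i; break; } r -= ad[i]; }
        if (ch < 0) ch = 7;  // numerical edge
      }
      if (birth) {
        double u = runif01(rng);
        int j = 0;
        while (u > cdf[ch][j]) ++j;
        if (record_dfe && j != ch && st.N >= 2) {
          double eff = std::log(b[j] / b[ch]) - std::log(d[j] / d[ch]);
          dfe.push_back(rep + 1); dfe.push_back(t);
          dfe.push_back(ch + 1);  dfe.push_back(j + 1);
          dfe.push_back(eff);
        }
        st.add(j, +1);
      } else {
        st.add(ch, -1);
      }
    }
  }

  double inv = 1.0 / n_replicates;
  for (int g = 0; g < NA_; ++g) {
    for (int i = 0; i < 8; ++i) { mean_counts(i, g) *= inv; mean_freq(i, g) *= inv; }
    for (int k = 0; k < 3; ++k) mean_trait(k, g) *= inv;
    mean_N[g] *= inv;
  }

  NumericMatrix dfe_mat((int)(dfe.size() / 5), 5);
  for (size_t r = 0; r < dfe.size() / 5; ++r)
    for (int c = 0; c < 5; ++c) dfe_mat(r, c) = dfe[5 * r + c];

  return List::create(_["mean_counts"] = mean_counts,
                      _["mean_freq"] = mean_freq,
                      _["mean_trait"] = mean_trait,
                      _["mean_N"] = mean_N,
                      _["dfe"] = dfe_mat);
}

// ---------------------------------------------------------------------------
// Finite-volume advection in age with superbee flux limiter.
// Solves dn/dt + dn/dy = 0 (ageing speed 1) on a uniform grid, conservative
// form, zero inflow at y = 0 and first-order outflow at y_max.
// dens is (n_age x n_types), age down the columns.
// ---------------------------------------------------------------------------

static inline double superbee(double r) {
  double a = std::min(2.0 * r, 1.0);
  double b = std::min(r, 2.0);
  return std::max(0.0, std::max(a, b));
}

// Advance one column in place. `inflow` is the flux density entering at
// the y = 0 boundary (group births; ageing speed is 1 so flux = density).
// Returns the outflow in density units (mass = return value * dy).
static double advect_col(double *n, int N, double c, double inflow) {
  std::vector<double> F(N + 1);
  F[0] = inflow;
  for (int i = 1; i < N; ++i) {
    double up = n[i - 1];
    double dn = n[i] - n[i - 1];
    double corr = 0.0;
    if (dn != 0.0) {
      double dup = (i >= 2) ? (n[i - 1] - n[i - 2]) : (n[i - 1] - inflow);
      double r = dup / dn;
      corr = 0.5 * superbee(r) * (1.0 - c) * dn;
    }
    F[i] = up + corr;
  }
  F[N] = n[N - 1];  // upwind outflow
  for (int i = 0; i < N; ++i) n[i] -= c * (F[i + 1] - F[i]);
  return F[N] * c;
}

// [[Rcpp::export]]
List advect_step_cpp(NumericMatrix dens, double dy, double dt) {
  if (dt > dy * (1.0 + 1e-12)) stop("CFL violation: dt must be <= dy");
  int N = dens.nrow(), T = dens.ncol();
  NumericMatrix out(clone(dens));
  double c = dt / dy, outflow = 0.0;
  for (int k = 0; k < T; ++k)
    outflow += advect_col(&out(0, k), N, c, 0.0) * dy;
  return List::create(_["density"] = out, _["outflow"] = outflow);
}

// ---------------------------------------------------------------------------
// Full PDE step chunk: advection + group-level deaths and births.
//
// Group birth rate:  b_k(y) = rho (1 - s_g + s_g z_r,k(y)) /
//                              (1 - s_g + s_g zbar_r(t))
// Group death rate:  d_k(y) = rho (1 - s_g z_f,k(y)) / (1 - s_g zbar_f(t))
// zbar_r, zbar_f are group-density-weighted population means. All births
// enter the age-0 cell of the descendant type, distributed by the ancestral
// type's age-dependent offspring-type kernel Hg[y, k, l].
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List pde_advance_cpp(NumericMatrix dens, double dy, double dt, int nsteps,
                     NumericMatrix zr, NumericMatrix zf, NumericVector Hg,
                     double rho, double s_g, bool renormalize) {
  if (dt > dy * (1.0 + 1e-12)) stop("CFL violation: dt must be <= dy");
  int N = dens.nrow(), T = dens.ncol();
  if (zr.nrow() != N || zf.nrow() != N || zr.ncol() != T || zf.ncol() != T ||
      (int)Hg.size() != N * T * T)
    stop("profile arrays do not match the density grid");
  NumericMatrix n(clone(dens));
  double c = dt / dy;
  double total_outflow = 0.0, max_mass_dev = 0.0;
  std::vector<double> B(T), D(N * T);
  const double *hg = Hg.begin();

  // Birth influx B_l and death rates for the current state. Because zbar_r
  // and zbar_f are computed from the same state with the same weights, the
  // population totals of births and deaths both equal rho * mass exactly.
  auto rates_from_state = [&](void) {
    double mass = 0.0, wr = 0.0, wf = 0.0;
    for (int k = 0; k < T; ++k)
      for (int y = 0; y < N; ++y) {
        double v = n(y, k);
        mass += v; wr += v * zr(y, k); wf += v * zf(y, k);
      }
    if (mass <= 0.0) stop("population mass vanished");
    double zbar_r = wr / mass, zbar_f = wf / mass;
    double db = 1.0 - s_g + s_g * zbar_r;
    double dd = 1.0 - s_g * zbar_f;
    std::fill(B.begin(), B.end(), 0.0);
    for (int k = 0; k < T; ++k)
      for (int y = 0; y < N; ++y) {
        double v = n(y, k);
        D[y + N * k] = rho * (1.0 - s_g * zf(y, k)) / dd;
        if (v <= 0.0) continue;
        double w = v * rho * (1.0 - s_g + s_g * zr(y, k)) / db * dy;
        const double *row = hg + y;  // Hg[y + N*(k + T*l)]
        for (int l = 0; l < T; ++l) B[l] += w * row[N * (k + T * l)];
      }
  };

  for (int s = 0; s < nsteps; ++s) {
    for (int k = 0; k < T; ++k)
      total_outflow += advect_col(&n(0, k), N, c, 0.0) * dy;

    double mass_pre = 0.0;
    for (int k = 0; k < T; ++k)
      for (int y = 0; y < N; ++y) mass_pre += n(y, k);

    // deaths (multiplicative, stays >= 0) and births (age-0 injection),
    // both evaluated from the same post-advection state: their population
    // totals are each exactly rho * mass * dt, so the step conserves mass
    rates_from_state();
    for (int k = 0; k < T; ++k)
      for (int y = 0; y < N; ++y)
        n(y, k) *= 1.0 - D[y + N * k] * dt;
    for (int l = 0; l < T; ++l) n(0, l) += B[l] * dt / dy;

    double mass_post = 0.0;
    for (int k = 0; k < T; ++k)
      for (int y = 0; y < N; ++y) mass_post += n(y, k);
    double dev = std::fabs(mass_post - mass_pre) * dy;
    if (dev > max_mass_dev) max_mass_dev = dev;

    if (renormalize) {
      double f = 1.0 / (mass_post * dy);
      for (int k = 0; k < T; ++k)
        for (int y = 0; y < N; ++y) n(y, k) *= f;
    }
  }
  return List::create(_["density"] = n,
                      _["outflow"] = total_outflow,
                      _["max_mass_step_dev"] = max_mass_dev);
}
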