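#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Pure-death chain machinery for the Kingman coalescent with piecewise-constant
// population size.  States are k = 2..n ancestral lineages; state k exits at
// rate choose(k,2)/nu(t).  All computations are done in rescaled time
// tau = integral dt/nu(t), where the chain is time-homogeneous with rates
// choose(k,2); occupancy times are mapped back by weighting each rescaled
// interval with its nu.

// One multiplication v <- P v with the uniformized transition kernel
// P = I + Q/Lambda of the death chain (rates lam[k]), in place.
static inline void death_kernel_mult(std::vector<double> &v,
                                     const std::vector<double> &lam,
                                     double Lambda, int nstate) {
  // state index s corresponds to k = s + 2; transition k+1 -> k
  for (int s = 0; s < nstate; ++s) {
    double stay = (1.0 - lam[s] / Lambda) * v[s];
    double in = (s + 1 < nstate) ? (lam[s + 1] / Lambda) * v[s + 1] : 0.0;
    v[s] = stay + in;
  }
}

// Expected occupancy time W_k (natural time units of 2*N_ref generations) for
// k = 2..n lineages, under epochs listed from the present backwards.
// nu: relative sizes, length E; dur: durations, length E-1 (the final epoch is
// the ancestral one and extends to infinity).
// [[Rcpp::export(name = ".cppOccupancy")]]
NumericVector cpp_occupancy(int n, NumericVector nu, NumericVector dur) {
  if (n < 2) stop("need at least 2 lineages");
  int E = nu.size();
  if (dur.size() != E - 1) stop("dur must have length(nu) - 1");
  int nstate = n - 1;
  std::vector<double> lam(nstate);
  for (int s = 0; s < nstate; ++s) {
    double k = s + 2.0;
    lam[s] = k * (k - 1.0) / 2.0;
  }
  double Lambda = lam[nstate - 1];
  std::vector<double> p(nstate, 0.0), v(nstate), pnew(nstate);
  p[nstate - 1] = 1.0; // start with n lineages
  NumericVector W(nstate);

  for (int e = 0; e < E - 1; ++e) {
    if (nu[e] <= 0.0) stop("population sizes must be positive");
    if (dur[e] < 0.0) stop("durations must be non-negative");
    double remaining = dur[e] / nu[e]; // rescaled
    while (remaining > 0.0) {
      double delta = remaining;
      if (Lambda * delta > 4096.0) delta = 4096.0 / Lambda;
      remaining -= delta;
      double rate = Lambda * delta;
      int M = (int)std::ceil(rate + 10.0 * std::sqrt(rate + 1.0) + 30.0);
      v = p;
      std::fill(pnew.begin(), pnew.end(), 0.0);
      for (int m = 0; m <= M; ++m) {
        double tail = R::ppois((double)m, rate, 0, 0); // P(Pois > m)
        double dens = R::dpois((double)m, rate, 0);
        for (int s = 0; s < nstate; ++s) {
          W[s] += nu[e] * (tail / Lambda) * v[s];
          pnew[s] += dens * v[s];
        }
        if (m > rate && tail < 1e-16) break;
        death_kernel_mult(v, lam, Lambda, nstate);
      }
      p = pnew;
      double surv = 0.0;
      for (int s = 0; s < nstate; ++s) surv += p[s];
      if (surv < 1e-14) return W; // genealogy effectively absorbed
    }
  }

  // ancestral epoch: exponential occupancy of every state still reachable
  double nuA = nu[E - 1];
  if (nuA <= 0.0) stop("population sizes must be positive");
  double cum = 0.0;
  for (int s = nstate - 1; s >= 0; --s) {
    cum += p[s];                   // P(current #lineages >= k)
    W[s] += nuA * cum / lam[s];    // E[Exp(lam_k/nuA)] = nuA/lam_k
  }
  return W;
}

// draw an exponential waiting time across piecewise-constant epochs, advancing
// the epoch pointer; helper for the single-population simulator
// (inlined in the loops below).

// Hudson-style single-locus coalescent simulator under piecewise-constant
// relative size.  Epochs from the present backwards; final epoch infinite.
// Returns per-replicate sums and sums of squares of the unfolded SFS
// contribution (Poisson-sprinkled mutation counts if poisson, else expected
// counts theta/2 * branch length per frequency class).
// [[Rcpp::export(name = ".cppSimSfs1d")]]
List cpp_sim_sfs1d(int n, NumericVector nu, NumericVector dur, double theta,
                   int reps, bool poisson) {
  if (n < 2) stop("need n >= 2");
  int E = nu.size();
  if (dur.size() != E - 1) stop("dur must have length(nu) - 1");
  for (int e = 0; e < E; ++e)
    if (nu[e] <= 0.0) stop("population sizes must be positive");
  NumericVector sum(n - 1), sumsq(n - 1), totlen(1);
  std::vector<double> bound(E - 1); // epoch end times, natural units
  double acc = 0.0;
  for (int e = 0; e < E - 1; ++e) { acc += dur[e]; bound[e] = acc; }
  std::vector<int> desc(n);
  std::vector<double> len(n - 1);
  RNGScope scope;
  for (int r = 0; r < reps; ++r) {
    int k = n;
    for (int i = 0; i < n; ++i) desc[i] = 1;
    std::fill(len.begin(), len.end(), 0.0);
    double t = 0.0;
    int e = 0;
    while (k > 1) {
      double rate = (k * (k - 1.0) / 2.0) / nu[e];
      double wait = exp_rand() / rate;
      if (e < E - 1 && t + wait > bound[e]) {
        double dt = bound[e] - t;
        for (int i = 0; i < k; ++i) len[desc[i] - 1] += dt;
        t = bound[e];
        ++e;
        continue;
      }
      for (int i = 0; i < k; ++i) len[desc[i] - 1] += wait;
      t += wait;
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      desc[i] += desc[j];
      desc[j] = desc[k - 1];
      --k;
    }
    for (int c = 0; c < n - 1; ++c) {
      double x = poisson ? R::rpois(0.5 * theta * len[c])
                         : 0.5 * theta * len[c];
      sum[c] += x;
      sumsq[c] += x * x;
      totlen[0] += len[c];
    }
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq,
                      _["total_length"] = totlen[0]);
}

// Structured-coalescent simulator for two demes that merge into a single
// ancestral deme at scaled time Tsplit in the past.  Backward in time a
// lineage in deme 1 migrates to deme 2 at rate m12 (and vice versa), matching
// the forward convention in which m12 is the scaled rate of migration into
// population 1 from population 2.  Returns sums/sums of squares of joint SFS
// contributions over replicates.
// [[Rcpp::export(name = ".cppSimSfs2d")]]
List cpp_sim_sfs2d(int n1, int n2, double nu1, double nu2, double Tsplit,
                   double m12, double m21, double nuAnc, double theta,
                   int reps, bool poisson, double maxEventsPerRep = 0.0) {
  if (n1 < 1 || n2 < 1 || n1 + n2 < 2) stop("need at least 2 sampled lineages");
  if (nu1 <= 0 || nu2 <= 0 || nuAnc <= 0) stop("population sizes must be positive");
  if (Tsplit < 0 || m12 < 0 || m21 < 0) stop("Tsplit and migration rates must be >= 0");
  int ntot = n1 + n2;
  NumericMatrix sum(n1 + 1, n2 + 1), sumsq(n1 + 1, n2 + 1);
  std::vector<int> deme(ntot), d1(ntot), d2(ntot);
  std::vector<double> len((n1 + 1) * (n2 + 1));
  // optional guard against pathological parameter corners during
  // optimization: bail out once the whole batch exceeds its event budget
  double eventBudget = (maxEventsPerRep > 0.0)
    ? maxEventsPerRep * (double)reps : R_PosInf;
  double eventCount = 0.0;
  RNGScope scope;
  for (int r = 0; r < reps; ++r) {
    int k = ntot, k1 = n1, k2 = n2;
    for (int i = 0; i < ntot; ++i) {
      deme[i] = (i < n1) ? 1 : 2;
      d1[i] = (i < n1) ? 1 : 0;
      d2[i] = (i < n1) ? 0 : 1;
    }
    std::fill(len.begin(), len.end(), 0.0);
    double t = 0.0;
    bool merged = (Tsplit <= 0.0);
    if (merged) for (int i = 0; i < ntot; ++i) deme[i] = 0;
    while (k > 1) {
      if (++eventCount > eventBudget)
        stop("event budget exceeded (parameters imply an extremely deep or migration-heavy genealogy)");
      double rate, u;
      if (!merged) {
        double rc1 = (k1 * (k1 - 1.0) / 2.0) / nu1;
        double rc2 = (k2 * (k2 - 1.0) / 2.0) / nu2;
        double rm1 = k1 * m12, rm2 = k2 * m21;
        rate = rc1 + rc2 + rm1 + rm2;
        double wait = (rate > 0.0) ? exp_rand() / rate : R_PosInf;
        if (t + wait > Tsplit) {
          double dt = Tsplit - t;
          for (int i = 0; i < k; ++i) len[d1[i] * (n2 + 1) + d2[i]] += dt;
          t = Tsplit;
          merged = true;
          continue;
        }
        for (int i = 0; i < k; ++i) len[d1[i] * (n2 + 1) + d2[i]] += wait;
        t += wait;
        u = unif_rand() * rate;
        if (u < rc1 || u < rc1 + rc2) {
          int dm = (u < rc1) ? 1 : 2;
          int kk = (dm == 1) ? k1 : k2;
          int a = (int)(unif_rand() * kk); if (a >= kk) a = kk - 1;
          int b = (int)(unif_rand() * (kk - 1)); if (b >= kk - 1) b = kk - 2;
          if (b >= a) ++b;
          // locate the a-th and b-th lineages of deme dm
          int ia = -1, ib = -1, seen = 0;
          for (int i = 0; i < k; ++i) {
            if (deme[i] == dm) {
              if (seen == a) ia = i;
              if (seen == b) ib = i;
              ++seen;
            }
          }
          d1[ia] += d1[ib];
          d2[ia] += d2[ib];
          d1[ib] = d1[k - 1]; d2[ib] = d2[k - 1]; deme[ib] = deme[k - 1];
          --k;
          if (dm == 1) --k1; else --k2;
        } else {
          int dm = (u < rc1 + rc2 + k1 * m12) ? 1 : 2;
          int kk = (dm == 1) ? k1 : k2;
          int a = (int)(unif_rand() * kk); if (a >= kk) a = kk - 1;
          int seen = 0;
          for (int i = 0; i < k; ++i) {
            if (deme[i] == dm && seen++ == a) {
              deme[i] = (dm == 1) ? 2 : 1;
              break;
            }
          }
          if (dm == 1) { --k1; ++k2; } else { --k2; ++k1; }
        }
      } else {
        rate = (k * (k - 1.0) / 2.0) / nuAnc;
        double wait = exp_rand() / rate;
        for (int i = 0; i < k; ++i) len[d1[i] * (n2 + 1) + d2[i]] += wait;
        t += wait;
        int a = (int)(unif_rand() * k); if (a >= k) a = k - 1;
        int b = (int)(unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
        if (b >= a) ++b;
        d1[a] += d1[b];
        d2[a] += d2[b];
        d1[b] = d1[k - 1]; d2[b] = d2[k - 1]; deme[b] = deme[k - 1];
        --k;
      }
    }
    for (int i = 0; i <= n1; ++i) {
      for (int j = 0; j <= n2; ++j) {
        if (i + j == 0 || i + j == ntot) continue;
        double L = len[i * (n2 + 1) + j];
        if (L == 0.0 && poisson) continue;
        double x = poisson ? R::rpois(0.5 * theta * L) : 0.5 * theta * L;
        sum(i, j) += x;
        sumsq(i, j) += x * x;
      }
    }
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq);
}
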