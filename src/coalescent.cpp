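// Structured-coalescent engine: multi-deme genealogies under piecewise
// constant / exponential / logistic deme sizes, continuous migration,
// deme-founding (backward joins) and admixture pulses.
//
// Conventions (dadi-style scaling): time is measured backward from the
// present in units of 2*N_ref generations; deme sizes nu are relative to
// N_ref; the coalescence rate for k lineages in a deme of size nu is
// choose(k,2)/nu and the backward migration rate per lineage is the scaled
// rate M = 2*N_ref*m. Time-varying rates are handled by exact thinning:
// candidate events are proposed at the maximal rate over a window within
// which no deme size can fall below half its current value, and accepted
// with probability actual/bound.
//
// All randomness comes from R's RNG, so set.seed() in R gives full
// determinism.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// phase size spec: per deme a row (type, a, b, c)
//   type 0 (constant):   nu(t) = a
//   type 1 (exponential):nu(t) = a * exp(-b * (t - t0))
//   type 2 (logistic):   nu(t) = a / (1 + b * exp(c * (t - t0)))
static inline double nu_at(const double* row, double x) {
  int type = (int)row[0];
  if (type == 0) return row[1];
  if (type == 1) return row[1] * std::exp(-row[2] * x);
  return row[1] / (1.0 + row[2] * std::exp(row[3] * x));
}

// time offset (from phase start) at which nu drops to half of nu(x);
// R_PosInf if nu is non-decreasing backward in time.
static inline double half_offset(const double* row, double x) {
  int type = (int)row[0];
  if (type == 0) return R_PosInf;
  if (type == 1) {
    double b = row[2];
    if (b <= 0.0) return R_PosInf;
    return x + M_LN2 / b;
  }
  double b = row[2], c = row[3];
  if (c <= 0.0 || b <= 0.0) return R_PosInf;
  double nu_x = nu_at(row, x);
  double arg = (2.0 * row[1] / nu_x - 1.0) / b;
  if (arg <= 0.0) return R_PosInf;
  return std::log(arg) / c;
}

struct Phases {
  std::vector<double> breaks;                   // phase start times, breaks[0] = 0
  std::vector<std::vector<double> > mig;        // per-phase row-major n x n rates
  std::vector<std::vector<double> > sizes;      // per-phase n x 4 size rows
  std::vector<std::vector<double> > outm;       // per-phase per-deme out-rate
  NumericMatrix events;                         // time, type(0 join,1 pulse), from, to, frac
  int n_demes;
};

static Phases unpack(List phases_r, NumericMatrix events, int n_demes) {
  Phases ph;
  ph.n_demes = n_demes;
  ph.events = events;
  NumericVector br = phases_r["breaks"];
  ph.breaks = std::vector<double>(br.begin(), br.end());
  List mig = phases_r["mig"], sizes = phases_r["sizes"];
  int P = mig.size();
  for (int p = 0; p < P; ++p) {
    NumericMatrix M = mig[p];
    NumericMatrix S = as<NumericMatrix>(sizes[p]);
    std::vector<double> mv(n_demes * n_demes), sv(n_demes * 4);
    for (int d = 0; d < n_demes; ++d) {
      for (int j = 0; j < n_demes; ++j) mv[d * n_demes + j] = M(d, j);
      for (int c = 0; c < 4; ++c) sv[d * 4 + c] = S(d, c);
    }
    ph.mig.push_back(mv);
    ph.sizes.push_back(sv);
    std::vector<double> om(n_demes, 0.0);
    for (int d = 0; d < n_demes; ++d)
      for (int j = 0; j < n_demes; ++j)
        if (j != d) om[d] += M(d, j);
    ph.outm.push_back(om);
  }
  return ph;
}

// One genealogy. Lineage state lives in parallel arrays; the caller supplies
// callbacks through the template-free structure below (two modes compiled
// separately for speed/simplicity).

struct SfsAcc {
  int n1, n2;
  std::vector<double> acc; // (n1+1) x (n2+1), column-major on n1+1
  void reset() { std::fill(acc.begin(), acc.end(), 0.0); }
  inline void branch(int c1, int c2, double len) { acc[c1 + (n1 + 1) * c2] += len; }
};

struct MutRec {
  std::vector<std::vector<int> > derived; // per mutation: sample copy indices
};

static const long MAX_ITER = 20000000L;

// mode 0: accumulate branch lengths by joint descendant counts (SFS)
// mode 1: record mutations on completed branches (dataset simulation)
static void simulate_genealogy(const Phases& ph,
                               const IntegerVector& deme_of_copy,
                               const IntegerVector& pop_of_copy,
                               int mode, double theta,
                               SfsAcc* sfs, MutRec* muts) {
  int n = deme_of_copy.size();
  int nd = ph.n_demes;
  int P = ph.breaks.size();

  std::vector<int> deme(n), c1(n), c2(n);
  std::vector<double> birth(n, 0.0);
  std::vector<std::vector<int> > desc;
  if (mode == 1) desc.resize(n);
  for (int i = 0; i < n; ++i) {
    deme[i] = deme_of_copy[i];
    if (mode == 0) {
      c1[i] = (pop_of_copy[i] == 0) ? 1 : 0;
      c2[i] = (pop_of_copy[i] == 1) ? 1 : 0;
    } else {
      desc[i].assign(1, i);
    }
  }
  std::vector<int> alive(n);
  for (int i = 0; i < n; ++i) alive[i] = i;
  int k = n;
  std::vector<int> kd(nd, 0);
  for (int i = 0; i < n; ++i) kd[deme[i]]++;

  double t = 0.0;
  int p = 0;
  int ei = 0; // next event row
  long iter = 0;
  std::vector<double> numin(nd), bound(nd);

  while (k > 1) {
    if (++iter > MAX_ITER)
      stop("coalescent did not complete: non-coalescing parameterization?");
    double t0 = ph.breaks[p];
    double t1 = (p + 1 < P) ? ph.breaks[p + 1] : R_PosInf;
    const double* S = ph.sizes[p].data();
    const double* M = ph.mig[p].data();
    const std::vector<double>& om = ph.outm[p];

    // window end: phase end, capped so no coalescing deme halves in size
    double x = t - t0;
    double tw = t1;
    for (int d = 0; d < nd; ++d) {
      if (kd[d] >= 2 && (int)S[4 * d] != 0) {
        double hx = half_offset(S + 4 * d, x);
        if (t0 + hx < tw) tw = t0 + hx;
      }
    }
    if (tw <= t) tw = std::min(t1, t + 1e-9); // numeric guard: always progress
    double xw = tw - t0;

    double mig_rate = 0.0;
    for (int d = 0; d < nd; ++d) mig_rate += kd[d] * om[d];
    double coal_bound = 0.0;
    for (int d = 0; d < nd; ++d) {
      bound[d] = 0.0;
      if (kd[d] >= 2) {
        const double* row = S + 4 * d;
        double nu_now = nu_at(row, x);
        double nu_end = std::isfinite(xw) ? nu_at(row, xw) : nu_now;
        numin[d] = std::min(nu_now, nu_end);
        if (numin[d] <= 0.0) stop("non-positive deme size encountered");
        bound[d] = 0.5 * kd[d] * (kd[d] - 1.0) / numin[d];
        coal_bound += bound[d];
      }
    }
    double R = coal_bound + mig_rate;

    // draw candidate events inside the window; the bound and the migration
    // rates stay valid until the state changes or the window ends, so
    // thinning rejections do not force a recomputation
    bool advance_to_window = false;
    bool state_changed = false;
    if (R <= 0.0) {
      if (!std::isfinite(tw))
        stop("lineages cannot coalesce: zero rates in terminal phase");
      advance_to_window = true;
    } else {
      while (!state_changed) {
        if (++iter > MAX_ITER)
          stop("coalescent did not complete: non-coalescing parameterization?");
        double dt = exp_rand() / R;
        if (t + dt >= tw) { advance_to_window = true; break; }
        t += dt;
        double u = unif_rand() * R;
        if (u < mig_rate) {
          // migration: pick deme, lineage, destination
          double acc = 0.0;
          int d = nd - 1;
          for (int dd = 0; dd < nd; ++dd) {
            acc += kd[dd] * om[dd];
            if (u < acc) { d = dd; break; }
          }
          int pick = (int)(unif_rand() * kd[d]);
          int li = -1;
          for (int a = 0; a < k; ++a) {
            if (deme[alive[a]] == d && pick-- == 0) { li = alive[a]; break; }
          }
          double v = unif_rand() * om[d], accj = 0.0;
          int dest = -1;
          for (int j = 0; j < nd; ++j) {
            if (j == d) continue;
            accj += M[d * nd + j];
            if (v < accj) { dest = j; break; }
          }
          if (dest < 0) dest = (d == nd - 1) ? 0 : nd - 1;
          deme[li] = dest; kd[d]--; kd[dest]++;
          state_changed = true;
        } else {
          u -= mig_rate;
          double acc = 0.0;
          int d = -1;
          for (int dd = 0; dd < nd; ++dd) {
            acc += bound[dd];
            if (u < acc) { d = dd; break; }
          }
          if (d < 0) continue;
          const double* row = S + 4 * d;
          double nu_now = nu_at(row, t - t0);
          if (unif_rand() >= numin[d] / nu_now) continue; // thinning rejection
          // coalesce a uniform pair within deme d
          int i1 = (int)(unif_rand() * kd[d]);
          int i2 = (int)(unif_rand() * (kd[d] - 1));
          if (i2 >= i1) i2++;
          int la = -1, lb = -1, seen = 0;
          for (int a = 0; a < k; ++a) {
            int li = alive[a];
            if (deme[li] == d) {
              if (seen == i1) la = a;
              if (seen == i2) lb = a;
              seen++;
            }
          }
          int A = alive[la], B = alive[lb];
          if (mode == 0) {
            sfs->branch(c1[A], c2[A], t - birth[A]);
            sfs->branch(c1[B], c2[B], t - birth[B]);
            c1[A] += c1[B]; c2[A] += c2[B];
          } else {
            double lenA = t - birth[A], lenB = t - birth[B];
            int nmA = (int)R::rpois(0.5 * theta * lenA);
            for (int mi = 0; mi < nmA; ++mi) muts->derived.push_back(desc[A]);
            int nmB = (int)R::rpois(0.5 * theta * lenB);
            for (int mi = 0; mi < nmB; ++mi) muts->derived.push_back(desc[B]);
            desc[A].insert(desc[A].end(), desc[B].begin(), desc[B].end());
            std::vector<int>().swap(desc[B]);
          }
          birth[A] = t;
          kd[d]--;
          alive[lb] = alive[k - 1];
          k--;
          state_changed = true;
        }
      }
    }

    if (advance_to_window) {
      t = tw;
      if (tw >= t1) {
        // crossing a phase boundary: apply events scheduled at t1
        int E = ph.events.nrow();
        while (ei < E && ph.events(ei, 0) <= t1 + 1e-12) {
          int type = (int)ph.events(ei, 1);
          int from = (int)ph.events(ei, 2);
          int to = (int)ph.events(ei, 3);
          double frac = ph.events(ei, 4);
          for (int a = 0; a < k; ++a) {
            int li = alive[a];
            if (deme[li] == from) {
              if (type == 0 || unif_rand() < frac) {
                deme[li] = to; kd[from]--; kd[to]++;
              }
            }
          }
          ei++;
        }
        p++;
        if (p >= P) stop("internal error: ran past terminal phase");
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_branch_sfs(List phases_r, NumericMatrix events, int n_demes,
                    IntegerVector deme_of_copy, IntegerVector pop_of_copy,
                    int n1, int n2, int n_reps) {
  Phases ph = unpack(phases_r, events, n_demes);
  SfsAcc sfs;
  sfs.n1 = n1; sfs.n2 = n2;
  sfs.acc.assign((n1 + 1) * (n2 + 1), 0.0);
  int ncell = (n1 + 1) * (n2 + 1);
  std::vector<double> sum(ncell, 0.0), sumsq(ncell, 0.0);
  for (int r = 0; r < n_reps; ++r) {
    if (r % 256 == 0) checkUserInterrupt();
    sfs.reset();
    simulate_genealogy(ph, deme_of_copy, pop_of_copy, 0, 0.0, &sfs, NULL);
    for (int i = 0; i < ncell; ++i) {
      sum[i] += sfs.acc[i];
      sumsq[i] += sfs.acc[i] * sfs.acc[i];
    }
  }
  NumericMatrix mean(n1 + 1, n2 + 1), se(n1 + 1, n2 + 1);
  for (int j = 0; j <= n2; ++j)
    for (int i = 0; i <= n1; ++i) {
      int idx = i + (n1 + 1) * j;
      double m = sum[idx] / n_reps;
      mean(i, j) = m;
      double v = (sumsq[idx] / n_reps - m * m) / std::max(1, n_reps - 1);
      se(i, j) = std::sqrt(std::max(0.0, v));
    }
  return List::create(_["mean"] = mean, _["se"] = se, _["n_reps"] = n_reps);
}

// [[Rcpp::export]]
List cpp_sim_loci(List phases_r, NumericMatrix events, int n_demes,
                  IntegerVector deme_of_copy, double theta, int n_loci,
                  bool one_snp) {
  Phases ph = unpack(phases_r, events, n_demes);
  IntegerVector dummy(deme_of_copy.size());
  int n = deme_of_copy.size();
  List out(n_loci);
  MutRec muts;
  for (int l = 0; l < n_loci; ++l) {
    if (l % 16 == 0) checkUserInterrupt();
    muts.derived.clear();
    simulate_genealogy(ph, deme_of_copy, dummy, 1, theta, NULL, &muts);
    int nm = muts.derived.size();
    if (nm == 0) { out[l] = IntegerMatrix(0, n); continue; }
    if (one_snp && nm > 1) {
      int keep = (int)(unif_rand() * nm);
      std::vector<int> kept = muts.derived[keep];
      muts.derived.clear();
      muts.derived.push_back(kept);
      nm = 1;
    }
    IntegerMatrix snp(nm, n);
    for (int mi = 0; mi < nm; ++mi)
      for (size_t j = 0; j < muts.derived[mi].size(); ++j)
        snp(mi, muts.derived[mi][j]) = 1;
    out[l] = snp;
  }
  return out;
}
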