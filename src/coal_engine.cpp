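// Structured two-deme coalescent engine.
//
// Time flows backward from the present in units of 2*N_ref generations.
// Deme sizes are relative to N_ref and may change exponentially within an
// epoch; migration rates are the scaled backward per-lineage rates
// (m_ij = 2*N_ref * fraction of deme i replaced by migrants from deme j per
// generation, so a lineage in deme i jumps to deme j at rate m_ij).
// After the last two-deme epoch all lineages merge into a single ancestral
// deme of constant size nuA.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <unordered_set>

using namespace Rcpp;

namespace {

struct Lineage {
  int c1, c2;          // sample descendants in deme-1 / deme-2 samples
  double birth;        // global time this lineage arose (backward)
  std::vector<int> members;  // sample indices (only tracked when needed)
};

struct Epoch {
  double len;          // duration (backward)
  double s1, r1;       // deme 0 size at epoch start (recent end) and rate:
                       // nu0(t) = s1 * exp(r1 * t), t = time into epoch
  double s2, r2;       // deme 1 likewise
  double m12, m21;     // backward per-lineage migration rates
};

class Rng {
 public:
  explicit Rng(double seed) : eng_(static_cast<uint64_t>(seed)) {}
  double unif() {
    double u;
    do { u = dist_(eng_); } while (u <= 0.0 || u >= 1.0);
    return u;
  }
  double rexp() { return -std::log(unif()); }
  int rint(int n) { return static_cast<int>(unif() * n) % n; }
  int rpois(double lambda) {
    std::poisson_distribution<int> d(lambda);
    return d(eng_);
  }
 private:
  std::mt19937_64 eng_;
  std::uniform_real_distribution<double> dist_{0.0, 1.0};
};

// Waiting time to the next coalescence among k lineages in a deme whose size
// is a * exp(r * t) looking backward from now; E is a unit exponential draw.
double coal_wait(int k, double a, double r, double E) {
  if (k < 2) return R_PosInf;
  double c = k * (k - 1) / 2.0;
  if (a <= 0.0) stop("non-positive population size in coalescent engine");
  if (r == 0.0) return E * a / c;
  double arg = 1.0 - E * r * a / c;
  if (arg <= 0.0) return R_PosInf;  // rate decays too fast: no event
  return -std::log(arg) / r;
}

// Flush callback: a lineage died at time t; its branch subtends (c1, c2).
typedef void (*unused_t)();

struct Completed {
  std::vector<int> c1, c2;
  std::vector<double> blen;
  std::vector<std::vector<int> > members;
};

struct SimOut {
  double tmrca;
  double total_len;
};

SimOut simulate_genealogy(int n1, int n2, const std::vector<Epoch>& epochs,
                          double nuA, bool track_members, Rng& rng,
                          Completed* done, double* cells, int ncell_rows) {
  std::vector<Lineage> lin;
  lin.reserve(2 * (n1 + n2));
  std::vector<int> deme_idx[2];
  deme_idx[0].reserve(n1 + n2);
  deme_idx[1].reserve(n1 + n2);
  for (int i = 0; i < n1; ++i) {
    Lineage l; l.c1 = 1; l.c2 = 0; l.birth = 0.0;
    if (track_members) l.members.assign(1, i);
    deme_idx[0].push_back(static_cast<int>(lin.size()));
    lin.push_back(l);
  }
  for (int j = 0; j < n2; ++j) {
    Lineage l; l.c1 = 0; l.c2 = 1; l.birth = 0.0;
    if (track_members) l.members.assign(1, n1 + j);
    deme_idx[1].push_back(static_cast<int>(lin.size()));
    lin.push_back(l);
  }

  SimOut out;
  out.total_len = 0.0;

  double t = 0.0;           // global backward time
  size_t ie = 0;            // epoch index; epochs.size() => ancestral
  double t_off = 0.0;       // time elapsed within current epoch
  int n_active = n1 + n2;

  auto flush = [&](int idx, double death) {
    const Lineage& L = lin[idx];
    double b = death - L.birth;
    out.total_len += b;
    if (cells) cells[L.c1 + ncell_rows * L.c2] += b;
    if (done) {
      done->c1.push_back(L.c1);
      done->c2.push_back(L.c2);
      done->blen.push_back(b);
      if (track_members) done->members.push_back(L.members);
    }
  };

  while (n_active > 1) {
    int k0 = static_cast<int>(deme_idx[0].size());
    int k1 = static_cast<int>(deme_idx[1].size());

    double a0, r0, a1, r1m, m12, m21, remaining;
    if (ie < epochs.size()) {
      const Epoch& e = epochs[ie];
      a0 = e.s1 * std::exp(e.r1 * t_off); r0 = e.r1;
      a1 = e.s2 * std::exp(e.r2 * t_off); r1m = e.r2;
      m12 = e.m12; m21 = e.m21;
      remaining = e.len - t_off;
    } else {
      a0 = nuA; r0 = 0.0; a1 = 1.0; r1m = 0.0; m12 = 0.0; m21 = 0.0;
      remaining = R_PosInf;
    }

    double tc0 = coal_wait(k0, a0, r0, rng.rexp());
    double tc1 = coal_wait(k1, a1, r1m, rng.rexp());
    double tm0 = (k0 > 0 && m12 > 0.0) ? rng.rexp() / (k0 * m12) : R_PosInf;
    double tm1 = (k1 > 0 && m21 > 0.0) ? rng.rexp() / (k1 * m21) : R_PosInf;

    double tmin = std::min(std::min(tc0, tc1), std::min(tm0, tm1));

    if (tmin >= remaining) {
      if (!std::isfinite(remaining))
        stop("coalescent engine failed to reach the MRCA");
      t += remaining;
      t_off = 0.0;
      ++ie;
      if (ie == epochs.size() && !deme_idx[1].empty()) {
        // merge: move everything into the ancestral deme
        deme_idx[0].insert(deme_idx[0].end(), deme_idx[1].begin(),
                           deme_idx[1].end());
        deme_idx[1].clear();
      }
      continue;
    }

    t += tmin;
    t_off += tmin;

    if (tmin == tc0 || tmin == tc1) {
      int d = (tmin == tc0) ? 0 : 1;
      std::vector<int>& idx = deme_idx[d];
      int kd = static_cast<int>(idx.size());
      int a = rng.rint(kd);
      int b = rng.rint(kd - 1);
      if (b >= a) ++b;
      int ia = idx[a], ib = idx[b];
      flush(ia, t);
      flush(ib, t);
      Lineage merged;
      merged.c1 = lin[ia].c1 + lin[ib].c1;
      merged.c2 = lin[ia].c2 + lin[ib].c2;
      merged.birth = t;
      if (track_members) {
        merged.members = lin[ia].members;
        merged.members.insert(merged.members.end(), lin[ib].members.begin(),
                              lin[ib].members.end());
      }
      // swap-remove the two children (larger position first)
      int pa = std::max(a, b), pb = std::min(a, b);
      idx[pa] = idx.back(); idx.pop_back();
      idx[pb] = idx.back(); idx.pop_back();
      idx.push_back(static_cast<int>(lin.size()));
      lin.push_back(merged);
      --n_active;
    } else {
      int from = (tmin == tm0) ? 0 : 1;
      std::vector<int>& idx = deme_idx[from];
      int a = rng.rint(static_cast<int>(idx.size()));
      deme_idx[1 - from].push_back(idx[a]);
      idx[a] = idx.back(); idx.pop_back();
    }
  }
  out.tmrca = t;
  return out;
}

std::vector<Epoch> build_epochs(NumericVector len, NumericVector s1,
                                NumericVector r1, NumericVector s2,
                                NumericVector r2, NumericVector m12,
                                NumericVector m21) {
  int K = len.size();
  if (s1.size() != K || r1.size() != K || s2.size() != K || r2.size() != K ||
      m12.size() != K || m21.size() != K)
    stop("epoch vectors must have equal length");
  std::vector<Epoch> ep(K);
  for (int k = 0; k < K; ++k) {
    ep[k].len = len[k];
    ep[k].s1 = s1[k]; ep[k].r1 = r1[k];
    ep[k].s2 = s2[k]; ep[k].r2 = r2[k];
    ep[k].m12 = m12[k]; ep[k].m21 = m21[k];
    if (!(ep[k].len >= 0)) stop("epoch durations must be non-negative");
    if (ep[k].m12 < 0 || ep[k].m21 < 0) stop("migration rates must be >= 0");
  }
  return ep;
}

}  // namespace

// Mean branch length subtending (i, j) sample descendants, averaged over
// `reps` independent genealogies: the Monte-Carlo estimate of the expected
// (unfolded, theta/2-free) joint SFS.
// [[Rcpp::export]]
NumericMatrix cpp_branch_jsfs(int n1, int n2, NumericVector len,
                              NumericVector s1, NumericVector r1,
                              NumericVector s2, NumericVector r2,
                              NumericVector m12, NumericVector m21,
                              double nuA, int reps, double seed) {
  if (n1 < 0 || n2 < 0 || n1 + n2 < 2) stop("need at least two sampled lineages");
  if (reps < 1) stop("reps must be >= 1");
  if (nuA <= 0) stop("ancestral size must be positive");
  std::vector<Epoch> ep = build_epochs(len, s1, r1, s2, r2, m12, m21);
  Rng rng(seed);
  NumericMatrix out(n1 + 1, n2 + 1);
  for (int r = 0; r < reps; ++r)
    simulate_genealogy(n1, n2, ep, nuA, false, rng, nullptr,
                       REAL(out), n1 + 1);
  for (int i = 0; i <= n1; ++i)
    for (int j = 0; j <= n2; ++j) out(i, j) /= reps;
  return out;
}

// Per-replicate TMRCA and total tree length (oracle hooks).
// [[Rcpp::export]]
NumericMatrix cpp_coal_summaries(int n1, int n2, NumericVector len,
                                 NumericVector s1, NumericVector r1,
                                 NumericVector s2, NumericVector r2,
                                 NumericVector m12, NumericVector m21,
                                 double nuA, int reps, double seed) {
  if (n1 + n2 < 2) stop("need at least two sampled lineages");
  std::vector<Epoch> ep = build_epochs(len, s1, r1, s2, r2, m12, m21);
  Rng rng(seed);
  NumericMatrix out(reps, 2);
  colnames(out) = CharacterVector::create("tmrca", "total_length");
  for (int r = 0; r < reps; ++r) {
    SimOut sim = simulate_genealogy(n1, n2, ep, nuA, false, rng, nullptr,
                                    nullptr, 0);
    out(r, 0) = sim.tmrca;
    out(r, 1) = sim.total_len;
  }
  return out;
}

// Simulate haplotypes at independent loci under the infinite-sites model.
// theta_locus = 4*N_ref*mu per locus; mutations fall on branches with
// probability proportional to branch length; each segregating site is
// biallelic with a distinct position in 1..locus_length (multi-hit positions
// are redrawn).  Returns, per locus, an S x (n1+n2) 0/1 haplotype matrix and
// the site positions.
// [[Rcpp::export]]
List cpp_sim_loci(int n1, int n2, NumericVector len, NumericVector s1,
                  NumericVector r1, NumericVector s2, NumericVector r2,
                  NumericVector m12, NumericVector m21, double nuA,
                  int n_loci, double theta_locus, int locus_length,
                  double seed) {
  if (n1 + n2 < 2) stop("need at least two sampled lineages");
  if (n_loci < 1) stop("n_loci must be >= 1");
  if (theta_locus < 0) stop("theta must be >= 0");
  if (locus_length < 1) stop("locus_length must be >= 1");
  std::vector<Epoch> ep = build_epochs(len, s1, r1, s2, r2, m12, m21);
  Rng rng(seed);
  int n = n1 + n2;
  List out(n_loci);
  for (int loc = 0; loc < n_loci; ++loc) {
    Completed done;
    simulate_genealogy(n1, n2, ep, nuA, true, rng, &done, nullptr, 0);
    double acc = 0.0;
    std::vector<double> cum(done.blen.size());
    for (size_t k = 0; k < done.blen.size(); ++k) {
      acc += done.blen[k];
      cum[k] = acc;
    }
    int S = rng.rpois(theta_locus / 2.0 * acc);
    if (S > locus_length)
      stop("more mutations than sites at a locus; increase locus_length or lower theta");
    IntegerMatrix hap(S, n);
    IntegerVector pos(S);
    std::unordered_set<int> used;
    for (int s = 0; s < S; ++s) {
      double u = rng.unif() * acc;
      size_t k = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
      if (k >= done.members.size()) k = done.members.size() - 1;
      for (size_t m = 0; m < done.members[k].size(); ++m)
        hap(s, done.members[k][m]) = 1;
      int p;
      do { p = 1 + rng.rint(locus_length); } while (used.count(p));
      used.insert(p);
      pos[s] = p;
    }
    out[loc] = List::create(_["hap"] = hap, _["pos"] = pos);
  }
  return out;
}
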