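// Serial-sampling structured coalescent core and sequence statistics.
//
// Time is measured in generations before present (backward). Demes have
// constant haploid sizes: a pair of lineages in a deme of size Ne coalesces
// at rate 1/Ne per generation. Serial samples enter the process at their
// sampling time. Demographic events (backward view): a merge moves all of a
// child deme's lineages to its parent deme and retires the child; a pulse
// moves each lineage of the sink deme to the source deme with probability p.
// A lineage sampled in a deme that has already been retired enters the
// deme's current ancestor (deme-remap rule), so every prior draw yields a
// proper genealogy.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <set>
#include <vector>
using namespace Rcpp;

static int resolve(std::vector<int>& remap, int d) {
  while (remap[d] != d) d = remap[d];
  return d;
}

struct SimEvent {
  double t;
  int type;  // 0 sample, 1 pulse, 2 merge
  int a, b;  // sample: a=deme; pulse: a=sink,b=source; merge: a=child,b=parent
  double p;
  int n;
};

// Simulate genealogy + mutations, return leaf state matrix (rows in the
// order leaves were sampled, i.e. sampling events in time order, each block
// of n consecutive rows). scheme 0 = two-state transition toggling,
// scheme 1 = equal-rates four-state (JC-like).
// [[Rcpp::export]]
IntegerMatrix cpp_sim_serial(NumericVector ne,
                             IntegerVector samp_deme,
                             NumericVector samp_time,
                             IntegerVector samp_n,
                             NumericVector ev_time,
                             IntegerVector ev_type,
                             IntegerVector ev_a,
                             IntegerVector ev_b,
                             NumericVector ev_p,
                             double mu_seq_gen,
                             int L,
                             int scheme) {
  const int ndeme = ne.size();
  std::vector<SimEvent> events;
  int ntot = 0;
  for (int i = 0; i < samp_deme.size(); ++i) {
    events.push_back({samp_time[i], 0, samp_deme[i], -1, 0.0, samp_n[i]});
    ntot += samp_n[i];
  }
  for (int i = 0; i < ev_time.size(); ++i)
    events.push_back({ev_time[i], ev_type[i], ev_a[i], ev_b[i], ev_p[i], 0});
  std::stable_sort(events.begin(), events.end(),
                   [](const SimEvent& x, const SimEvent& y) {
                     if (x.t != y.t) return x.t < y.t;
                     return x.type < y.type;
                   });

  std::vector<int> remap(ndeme);
  for (int d = 0; d < ndeme; ++d) remap[d] = d;

  // tree arrays; leaves 0..ntot-1 created in sampling order
  int maxNodes = 2 * ntot;
  std::vector<int> parent(maxNodes, -1);
  std::vector<double> ntime(maxNodes, 0.0);
  std::vector<int> lin;       // active node ids
  std::vector<int> lindeme;   // deme of each active lineage
  int nextInternal = ntot;    // internal nodes start after the leaves
  int leavesMade = 0;

  double t = 0.0;
  size_t ei = 0;
  const double INF = R_PosInf;
  while (ei < events.size() || (int)lin.size() > 1) {
    double te = ei < events.size() ? events[ei].t : INF;
    // per-deme lineage counts
    std::vector<int> k(ndeme, 0);
    for (size_t i = 0; i < lin.size(); ++i) ++k[lindeme[i]];
    double R = 0.0;
    std::vector<double> rate(ndeme, 0.0);
    for (int d = 0; d < ndeme; ++d) {
      if (k[d] > 1) rate[d] = k[d] * (k[d] - 1.0) / 2.0 / ne[d];
      R += rate[d];
    }
    double dt = R > 0 ? exp_rand() / R : INF;
    if (t + dt < te) {
      t += dt;
      double u = unif_rand() * R;
      int d = 0;
      for (; d < ndeme - 1; ++d) { u -= rate[d]; if (u <= 0) break; }
      // pick a random pair in deme d
      std::vector<int> idx;
      for (size_t i = 0; i < lin.size(); ++i)
        if (lindeme[i] == d) idx.push_back((int)i);
      int i1 = (int)(unif_rand() * idx.size()); if (i1 == (int)idx.size()) --i1;
      int i2 = (int)(unif_rand() * (idx.size() - 1)); if (i2 >= i1) ++i2;
      int a = idx[i1], b = idx[i2];
      int node = nextInternal++;
      if (node >= maxNodes) stop("node overflow");
      parent[lin[a]] = node;
      parent[lin[b]] = node;
      ntime[node] = t;
      // replace lineage a by parent node, drop b
      lin[a] = node;
      int last = (int)lin.size() - 1;
      lin[b] = lin[last]; lindeme[b] = lindeme[last];
      lin.pop_back(); lindeme.pop_back();
    } else {
      if (te == INF)
        stop("lineages stranded in disconnected demes (model invalid)");
      t = te;
      const SimEvent& e = events[ei++];
      if (e.type == 0) {
        int d = resolve(remap, e.a);
        for (int j = 0; j < e.n; ++j) {
          int node = leavesMade++;
          ntime[node] = t;
          lin.push_back(node);
          lindeme.push_back(d);
        }
      } else if (e.type == 1) {
        int sink = resolve(remap, e.a), src = resolve(remap, e.b);
        if (sink != src)
          for (size_t i = 0; i < lin.size(); ++i)
            if (lindeme[i] == sink && unif_rand() < e.p) lindeme[i] = src;
      } else {
        int child = resolve(remap, e.a), par = resolve(remap, e.b);
        if (child != par) {
          remap[child] = par;
          for (size_t i = 0; i < lin.size(); ++i)
            if (lindeme[i] == child) lindeme[i] = par;
        }
      }
    }
  }
  int totalNodes = nextInternal;
  int root = lin[0];

  // mutations per branch: Poisson(branch_length * mu_seq_gen)
  std::vector<std::vector<int>> msite(totalNodes);
  std::vector<std::vector<int>> mdelta(totalNodes);
  for (int v = 0; v < totalNodes; ++v) {
    if (parent[v] < 0) continue;
    double bl = ntime[parent[v]] - ntime[v];
    int nm = (int)R::rpois(bl * mu_seq_gen);
    for (int j = 0; j < nm; ++j) {
      int s = (int)(unif_rand() * L); if (s == L) --s;
      msite[v].push_back(s);
      int delta = 1;
      if (scheme == 1) { delta = 1 + (int)(unif_rand() * 3); if (delta == 4) delta = 3; }
      mdelta[v].push_back(delta);
    }
  }

  // children lists
  std::vector<std::vector<int>> child(totalNodes);
  for (int v = 0; v < totalNodes; ++v)
    if (parent[v] >= 0) child[parent[v]].push_back(v);

  IntegerMatrix out(ntot, L);
  std::vector<uint8_t> state(L, 0);
  int nstates = scheme == 1 ? 4 : 2;
  // iterative DFS with apply/undo
  std::vector<std::pair<int, int>> stk;  // (node, phase 0=enter 1=exit)
  stk.push_back({root, 0});
  while (!stk.empty()) {
    auto [v, phase] = stk.back(); stk.pop_back();
    if (phase == 0) {
      for (size_t j = 0; j < msite[v].size(); ++j)
        state[msite[v][j]] =
          (uint8_t)((state[msite[v][j]] + mdelta[v][j]) % nstates);
      if (v < ntot)
        for (int s = 0; s < L; ++s) out(v, s) = state[s];
      stk.push_back({v, 1});
      for (int c : child[v]) stk.push_back({c, 0});
    } else {
      for (size_t j = 0; j < msite[v].size(); ++j)
        state[msite[v][j]] =
          (uint8_t)((state[msite[v][j]] + nstates - mdelta[v][j]) % nstates);
    }
  }
  return out;
}

// ---- pairwise differences on state matrices ------------------------------

static std::vector<std::vector<uint64_t>> packBinary(const IntegerMatrix& X) {
  int n = X.nrow(), L = X.ncol(), W = (L + 63) / 64;
  std::vector<std::vector<uint64_t>> P(n, std::vector<uint64_t>(W, 0));
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < L; ++s)
      if (X(i, s)) P[i][s / 64] |= (uint64_t)1 << (s % 64);
  return P;
}

static inline int popdiff(const std::vector<uint64_t>& a,
                          const std::vector<uint64_t>& b) {
  int d = 0;
  for (size_t w = 0; w < a.size(); ++w) {
#if defined(__GNUC__) || defined(__clang__)
    d += __builtin_popcountll(a[w] ^ b[w]);
#else
    uint64_t x = a[w] ^ b[w];
    while (x) { x &= x - 1; ++d; }
#endif
  }
  return d;
}

// Pairwise difference matrix for state matrices (any alphabet size).
// [[Rcpp::export]]
NumericMatrix cpp_state_diff(IntegerMatrix X) {
  int n = X.nrow(), L = X.ncol();
  NumericMatrix D(n, n);
  bool binary = true;
  for (int i = 0; i < n && binary; ++i)
    for (int s = 0; s < L; ++s)
      if (X(i, s) > 1) { binary = false; break; }
  if (binary) {
    auto P = packBinary(X);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        D(i, j) = D(j, i) = popdiff(P[i], P[j]);
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        int d = 0;
        for (int s = 0; s < L; ++s) d += X(i, s) != X(j, s);
        D(i, j) = D(j, i) = d;
      }
  }
  return D;
}

// Pairwise difference matrix for aligned character sequences.
// 'N' matches anything; a one-sided gap run of any length counts as a
// single event; double gaps are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_seq_diff(std::vector<std::string> seqs) {
  int n = seqs.size();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const std::string &a = seqs[i], &b = seqs[j];
      if (a.size() != b.size()) stop("sequences of unequal length");
      int d = 0;
      int run = 0;  // 0 none, 1 gap in a, 2 gap in b
      for (size_t s = 0; s < a.size(); ++s) {
        char ca = a[s], cb = b[s];
        bool ga = ca == '-', gb = cb == '-';
        if (ga && gb) { run = 0; continue; }
        if (ga != gb) {
          int cur = ga ? 1 : 2;
          if (run != cur) ++d;
          run = cur;
          continue;
        }
        run = 0;
        if (ca == 'N' || cb == 'N') continue;
        if (ca != cb) ++d;
      }
      D(i, j) = D(j, i) = d;
    }
  return D;
}

// ---- AMOVA / PhiST --------------------------------------------------------

// One-level AMOVA PhiST from a (squared-)distance matrix and population
// labels (0-based). Returns the raw estimate (can be negative).
static double phistFromD(const NumericMatrix& D, const std::vector<int>& pop,
                         int npop) {
  int N = D.nrow();
  std::vector<double> nper(npop, 0.0), ssdw(npop, 0.0);
  double ssdt = 0.0;
  for (int i = 0; i < N; ++i) ++nper[pop[i]];
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      ssdt += D(i, j);
      if (pop[i] == pop[j]) ssdw[pop[i]] += D(i, j);
    }
  ssdt /= N;
  double ssdW = 0.0, sumn2 = 0.0;
  int P = 0;
  for (int p = 0; p < npop; ++p) {
    if (nper[p] > 0) { ++P; ssdW += ssdw[p] / nper[p]; sumn2 += nper[p] * nper[p]; }
  }
  if (P < 2 || N - P <= 0) return 0.0;
  double ssdA = ssdt - ssdW;
  double sc = ssdW / (N - P);
  double nprime = (N - sumn2 / N) / (P - 1);
  double sa = (ssdA / (P - 1) - sc) / nprime;
  double tot = sa + sc;
  if (tot <= 0) return 0.0;
  return sa / tot;
}

// [[Rcpp::export]]
double cpp_phist(NumericMatrix D, IntegerVector pop, int npop) {
  std::vector<int> p(pop.begin(), pop.end());
  return phistFromD(D, p, npop);
}

// PhiST with a label-permutation test. Returns [phist, count of
// permutations with phist >= observed].
// [[Rcpp::export]]
NumericVector cpp_phist_perm(NumericMatrix D, IntegerVector pop, int npop,
                             int nperm) {
  std::vector<int> p(pop.begin(), pop.end());
  double obs = phistFromD(D, p, npop);
  int ge = 0;
  for (int r = 0; r < nperm; ++r) {
    for (int i = (int)p.size() - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1)); if (j > i) j = i;
      std::swap(p[i], p[j]);
    }
    if (phistFromD(D, p, npop) >= obs - 1e-12) ++ge;
  }
  return NumericVector::create(obs, (double)ge);
}

// ---- summary statistics ---------------------------------------------------

// Fixed-order summary vector for a state matrix with population labels:
// per population {n_haplotypes, haplotype diversity, segregating sites,
// mean pairwise differences, Tajima's D}; per population pair
// {PhiST, shared haplotype count}. Populations of size < 2 yield NaN-masked
// diversity entries encoded as 0 (mask handled downstream).
// [[Rcpp::export]]
NumericVector cpp_stats_state(IntegerMatrix X, IntegerVector pop, int npop) {
  int N = X.nrow(), L = X.ncol();
  NumericMatrix D = cpp_state_diff(X);
  // haplotype keys per individual
  std::map<std::vector<int>, int> hapid;
  std::vector<int> hap(N);
  for (int i = 0; i < N; ++i) {
    std::vector<int> key(L);
    for (int s = 0; s < L; ++s) key[s] = X(i, s);
    auto it = hapid.find(key);
    if (it == hapid.end()) { int id = hapid.size(); hapid[key] = id; hap[i] = id; }
    else hap[i] = it->second;
  }
  int nstats = 5 * npop + npop * (npop - 1);
  NumericVector out(nstats);
  int k = 0;
  std::vector<std::vector<int>> members(npop);
  for (int i = 0; i < N; ++i) members[pop[i]].push_back(i);
  for (int p = 0; p < npop; ++p) {
    const std::vector<int>& m = members[p];
    int n = m.size();
    // distinct haplotypes and diversity
    std::map<int, int> cnt;
    for (int i : m) ++cnt[hap[i]];
    double K = cnt.size();
    double h = 0.0;
    if (n > 1) {
      double sump2 = 0.0;
      for (auto& kv : cnt) { double f = kv.second / (double)n; sump2 += f * f; }
      h = (double)n / (n - 1.0) * (1.0 - sump2);
    }
    // segregating sites within population
    int S = 0;
    for (int s = 0; s < L; ++s) {
      int first = n ? X(m[0], s) : 0;
      for (int i = 1; i < n; ++i)
        if (X(m[i], s) != first) { ++S; break; }
    }
    // mean pairwise differences
    double pi = 0.0;
    if (n > 1) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) pi += D(m[i], m[j]);
      pi /= n * (n - 1.0) / 2.0;
    }
    // Tajima's D
    double Dt = 0.0;
    if (n > 2 && S > 0) {
      double a1 = 0, a2 = 0;
      for (int i = 1; i < n; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
      double b1 = (n + 1.0) / (3.0 * (n - 1.0));
      double b2 = 2.0 * (n * n + n + 3.0) / (9.0 * n * (n - 1.0));
      double c1 = b1 - 1.0 / a1;
      double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
      double e1 = c1 / a1;
      double e2 = c2 / (a1 * a1 + a2);
      double varD = e1 * S + e2 * S * (S - 1.0);
      if (varD > 0) Dt = (pi - S / a1) / std::sqrt(varD);
    }
    out[k++] = K; out[k++] = h; out[k++] = S; out[k++] = pi; out[k++] = Dt;
  }
  for (int p = 0; p < npop; ++p)
    for (int q = p + 1; q < npop; ++q) {
      const std::vector<int>&mp = members[p], &mq = members[q];
      std::vector<int> sub;
      sub.insert(sub.end(), mp.begin(), mp.end());
      sub.insert(sub.end(), mq.begin(), mq.end());
      int n = sub.size();
      NumericMatrix Dsub(n, n);
      std::vector<int> lab(n);
      for (int i = 0; i < n; ++i) {
        lab[i] = i < (int)mp.size() ? 0 : 1;
        for (int j = 0; j < n; ++j) Dsub(i, j) = D(sub[i], sub[j]);
      }
      double ph = (mp.size() > 0 && mq.size() > 0)
                      ? phistFromD(Dsub, lab, 2) : 0.0;
      std::set<int> hp, hq;
      for (int i : mp) hp.insert(hap[i]);
      for (int i : mq) hq.insert(hap[i]);
      int shared = 0;
      for (int hh : hp) if (hq.count(hh)) ++shared;
      out[k++] = ph; out[k++] = shared;
    }
  return out;
}

// Simulate and summarize in one call (avoids returning the matrix to R in
// the ABC reference-table loop).
// [[Rcpp::export]]
NumericVector cpp_sim_stats(NumericVector ne, IntegerVector samp_deme,
                            NumericVector samp_time, IntegerVector samp_n,
                            NumericVector ev_time, IntegerVector ev_type,
                            IntegerVector ev_a, IntegerVector ev_b,
                            NumericVector ev_p, double mu_seq_gen, int L,
                            int scheme) {
  IntegerMatrix X = cpp_sim_serial(ne, samp_deme, samp_time, samp_n, ev_time,
                                   ev_type, ev_a, ev_b, ev_p, mu_seq_gen, L,
                                   scheme);
  int npop = samp_deme.size();
  IntegerVector pop(X.nrow());
  int k = 0;
  for (int e = 0; e < samp_n.size(); ++e)
    for (int j = 0; j < samp_n[e]; ++j) pop[k++] = e;
  return cpp_stats_state(X, pop, npop);
}
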