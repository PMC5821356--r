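// Forward stochastic-logistic demography on a deme lattice and the
// backward Wright-Fisher coalescent conditioned on its recorded history.
// Uses R's RNG throughout (RNGScope), so set.seed() in R governs all draws.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Deterministic largest-remainder split of `total` into `parts` shares.
static void split_deterministic(int total, int parts, int *out) {
  int base = total / parts, rem = total - base * parts;
  for (int k = 0; k < parts; ++k) out[k] = base + (k < rem ? 1 : 0);
}

// Multinomial split (equal probabilities) via sequential binomials.
static void split_multinomial(int total, int parts, int *out) {
  int left = total;
  for (int k = 0; k < parts - 1; ++k) {
    out[k] = (left > 0) ? (int) R::rbinom(left, 1.0 / (parts - k)) : 0;
    left -= out[k];
  }
  out[parts - 1] = left;
}

// [[Rcpp::export]]
List cpp_forward(IntegerMatrix nbr, int origin, int Tgen, int Ni, int N,
                 double r, double m, bool deterministic, bool sea_absorb) {
  const int D = nbr.nrow();
  IntegerMatrix sizes(D, Tgen + 1);   // post-migration census, col g = gen g
  IntegerMatrix premig(D, Tgen);      // post-growth / pre-migration
  IntegerVector mig(Dimension(4, D, Tgen)); // migrants[dir, deme, gen]
  int *migp = INTEGER(mig);
  sizes(origin, Tgen) = Ni;

  std::vector<int> cur(D, 0), nxt(D);
  cur[origin] = Ni;
  const double cap = 10.0 * (double) N;
  bool warned = false;

  for (int g = Tgen - 1; g >= 0; --g) {
    // growth / regulation: Poisson around the logistic expectation
    for (int d = 0; d < D; ++d) {
      int n = cur[d];
      if (n == 0) { premig(d, g) = 0; continue; }
      double mean = n + r * (double) n * (1.0 - (double) n / N);
      if (mean < 0) mean = 0;
      if (mean > cap) {
        mean = cap;
        if (!warned) { warned = true; Rf_warning("expected deme size capped at 10*N"); }
      }
      premig(d, g) = deterministic ? (int) (mean + 0.5) : (int) R::rpois(mean);
    }
    // migration: each individual emigrates w.p. m, split over neighbours
    for (int d = 0; d < D; ++d) nxt[d] = premig(d, g);
    R_xlen_t off = (R_xlen_t) g * D * 4;
    for (int d = 0; d < D; ++d) {
      int n = premig(d, g);
      if (n == 0 || m <= 0) continue;
      int landk[4], nl = 0;
      for (int k = 0; k < 4; ++k) if (nbr(d, k) >= 0) landk[nl++] = k;
      if (nl == 0) continue;
      int e = deterministic ? (int) (n * m + 0.5) : (int) R::rbinom(n, m);
      if (e == 0) continue;
      if (sea_absorb && nl < 4) {
        // emigrants pick among all 4 directions; water-bound ones are lost
        int e4[4];
        if (deterministic) split_deterministic(e, 4, e4);
        else split_multinomial(e, 4, e4);
        nxt[d] -= e;
        for (int k = 0; k < 4; ++k) {
          if (nbr(d, k) >= 0 && e4[k] > 0) {
            nxt[nbr(d, k)] += e4[k];
            migp[off + (R_xlen_t) d * 4 + k] = e4[k];
          }
        }
      } else {
        int el[4];
        if (deterministic) split_deterministic(e, nl, el);
        else split_multinomial(e, nl, el);
        nxt[d] -= e;
        for (int k = 0; k < nl; ++k) {
          if (el[k] > 0) {
            int dir = landk[k];
            nxt[nbr(d, dir)] += el[k];
            migp[off + (R_xlen_t) d * 4 + dir] = el[k];
          }
        }
      }
    }
    for (int d = 0; d < D; ++d) { sizes(d, g) = nxt[d]; cur[d] = nxt[d]; }
  }
  return List::create(_["sizes"] = sizes, _["premig"] = premig,
                      _["migrants"] = mig);
}

// Single-stepwise-mutation walk along a branch: Poisson(mu*len) steps of
// +-1, reflected so the repeat count never drops below 1.
static int smm_walk(int start, double len, double mu) {
  if (len <= 0 || mu <= 0) return start;
  int k = (int) R::rpois(mu * len);
  if (k == 0) return start;
  if (start - k >= 1) {            // boundary unreachable: net displacement
    int up = (int) R::rbinom(k, 0.5);
    return start + 2 * up - k;
  }
  int s = start;
  for (int i = 0; i < k; ++i) {
    s += (unif_rand() < 0.5) ? -1 : 1;
    if (s < 1) s = 1;
  }
  return s;
}

// [[Rcpp::export]]
int cpp_smm_mutate(int start, double len, double mu) {
  return smm_walk(start, len, mu);
}

// Backward coalescent for n_loci independent loci conditioned on a recorded
// demography. tip_deme gives the land-deme index (0-based) of each sampled
// gene copy. Returns an n_tips x n_loci matrix of allele repeat lengths.
// [[Rcpp::export]]
IntegerMatrix cpp_coalescent(IntegerMatrix nbr, IntegerMatrix recip,
                             IntegerMatrix sizes, IntegerMatrix premig,
                             IntegerVector migrants, int Tgen, int origin,
                             int Ni, IntegerVector tip_deme, int n_loci,
                             double mu, int ancestral) {
  const int D = nbr.nrow();
  const int n_tips = tip_deme.size();
  const int *migp = INTEGER(migrants);
  IntegerMatrix out(n_tips, n_loci);

  std::vector<int> node_parent, lin_node, lin_deme;
  std::vector<double> node_time;
  std::unordered_map<long long, int> hits;

  for (int locus = 0; locus < n_loci; ++locus) {
    node_parent.assign(n_tips, -1);
    node_time.assign(n_tips, 0.0);
    lin_node.resize(n_tips); lin_deme.resize(n_tips);
    for (int i = 0; i < n_tips; ++i) { lin_node[i] = i; lin_deme[i] = tip_deme[i]; }
    int k = n_tips;

    for (int g = 0; g < Tgen && k > 1; ++g) {
      R_xlen_t off = (R_xlen_t) g * D * 4;
      // (i) migration inversion: source proportional to realized counts
      for (int l = 0; l < k; ++l) {
        int j = lin_deme[l];
        int postm = sizes(j, g);
        if (postm <= 0) stop("lineage in an empty deme (inconsistent history)");
        int emig = 0;
        for (int kk = 0; kk < 4; ++kk) emig += migp[off + (R_xlen_t) j * 4 + kk];
        int stay = premig(j, g) - emig;
        double u = unif_rand() * postm;
        if (u >= stay) {
          u -= stay;
          for (int kk = 0; kk < 4; ++kk) {
            int i = nbr(j, kk);
            if (i < 0) continue;
            int cnt = migp[off + (R_xlen_t) i * 4 + recip(j, kk)];
            if (u < cnt) { lin_deme[l] = i; break; }
            u -= cnt;
          }
        }
      }
      // (ii) coalescence: uniform parent pick among 2n gene copies of the
      // deme's pre-migration size; equal picks merge (multiple mergers ok)
      hits.clear();
      int w = 0;
      for (int l = 0; l < k; ++l) {
        int i = lin_deme[l];
        int pool = 2 * premig(i, g);
        if (pool <= 0) stop("empty parent pool (inconsistent history)");
        int parent = (int) (unif_rand() * pool);
        if (parent >= pool) parent = pool - 1;
        long long key = ((long long) i << 32) + parent;
        auto it = hits.find(key);
        if (it == hits.end()) {
          hits.emplace(key, w);
          lin_node[w] = lin_node[l]; lin_deme[w] = i; ++w;
        } else {
          int slot = it->second;
          int tn = lin_node[slot];
          if (tn >= n_tips && node_time[tn] == g + 1.0) {
            node_parent[lin_node[l]] = tn;       // join this gen's merger
          } else {
            int nn = (int) node_time.size();
            node_parent.push_back(-1);
            node_time.push_back(g + 1.0);
            node_parent[tn] = nn;
            node_parent[lin_node[l]] = nn;
            lin_node[slot] = nn;
          }
        }
      }
      k = w;
    }

    if (k > 1) {
      // panmictic origin deme of constant size Ni before the onset
      for (int l = 0; l < k; ++l)
        if (lin_deme[l] != origin) stop("lineage outside origin at expansion onset");
      double t = Tgen;
      const int pool = 2 * Ni;
      while (k > 1) {
        t += 1.0;
        if (t > 5e8) stop("coalescent did not complete (runaway origin phase)");
        hits.clear();
        int w = 0;
        for (int l = 0; l < k; ++l) {
          int parent = (int) (unif_rand() * pool);
          if (parent >= pool) parent = pool - 1;
          auto it = hits.find((long long) parent);
          if (it == hits.end()) {
            hits.emplace((long long) parent, w);
            lin_node[w] = lin_node[l]; ++w;
          } else {
            int slot = it->second;
            int tn = lin_node[slot];
            if (tn >= n_tips && node_time[tn] == t) {
              node_parent[lin_node[l]] = tn;
            } else {
              int nn = (int) node_time.size();
              node_parent.push_back(-1);
              node_time.push_back(t);
              node_parent[tn] = nn;
              node_parent[lin_node[l]] = nn;
              lin_node[slot] = nn;
            }
          }
        }
        k = w;
      }
    }

    // mutations top-down: every parent was created after its children, so a
    // reverse index sweep sees each parent's state before its children's
    int n_nodes = (int) node_time.size();
    std::vector<int> state(n_nodes);
    state[n_nodes - 1] = ancestral;
    for (int v = n_nodes - 2; v >= 0; --v) {
      int p = node_parent[v];
      state[v] = (p < 0) ? ancestral
                         : smm_walk(state[p], node_time[p] - node_time[v], mu);
    }
    for (int i = 0; i < n_tips; ++i) out(i, locus) = state[i];
  }
  return out;
}
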