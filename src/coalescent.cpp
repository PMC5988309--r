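// Structured coalescent with piecewise-constant demography.
//
// Demography is a sequence of epochs looking backward in time from the
// present (t = 0).  Each epoch e has a start time, per-population diploid
// sizes, a backward migration-rate matrix (m[i][j] = per-generation rate at
// which a lineage currently in population i jumps to population j), and a
// remap vector applied on entry to the epoch (lineages in population p are
// moved to remap[p]; used for population splits, read backward as mergers).
//
// Mutations are dropped on the realised genealogy under an infinite-sites
// model at rate mu per site per generation; alleles are coded 0 = ancestral,
// 1 = derived.  Loci are independent, with no intra-locus recombination.
//
// Uses R's RNG throughout so results are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <set>
#include <cmath>
using namespace Rcpp;

namespace {

struct Genealogy {
  int n_tips;
  std::vector<int> parent;     // -1 for root
  std::vector<double> time;    // node ages in generations
  std::vector<int> left, right; // children (-1 for tips)
};

// Simulate one genealogy under the epoch demography.
Genealogy sim_tree(const std::vector<int> &nsam,
                   const NumericVector &epoch_start,
                   const NumericMatrix &sizes,
                   const NumericVector &mig,      // E * P * P, m(e,i,j) = mig[(e*P+i)*P+j]
                   const IntegerMatrix &remap) {
  const int P = sizes.ncol();
  const int E = sizes.nrow();
  int n_total = 0;
  for (int p = 0; p < P; ++p) n_total += nsam[p];

  Genealogy g;
  g.n_tips = n_total;
  int n_nodes = 2 * n_total - 1;
  g.parent.assign(n_nodes, -1);
  g.time.assign(n_nodes, 0.0);
  g.left.assign(n_nodes, -1);
  g.right.assign(n_nodes, -1);

  // active lineages per population
  std::vector<std::vector<int> > act(P);
  int tip = 0;
  for (int p = 0; p < P; ++p)
    for (int i = 0; i < nsam[p]; ++i) act[p].push_back(tip++);

  int next_node = n_total;
  double t = 0.0;
  int e = 0;
  int n_active = n_total;
  long guard = 0;

  // per-epoch outgoing migration-rate row sums
  std::vector<double> mig_out((size_t)E * P, 0.0);
  for (int ee = 0; ee < E; ++ee)
    for (int p = 0; p < P; ++p) {
      double mo = 0.0;
      for (int j = 0; j < P; ++j)
        if (j != p) mo += mig[((size_t)ee * P + p) * P + j];
      mig_out[(size_t)ee * P + p] = mo;
    }
  std::vector<double> r_coal(P), r_mig(P);

  while (n_active > 1) {
    if (++guard > 100000000L)
      stop("coalescent simulation exceeded event limit; check demography");
    // rates in current epoch
    double r_tot = 0.0;
    for (int p = 0; p < P; ++p) {
      double k = (double)act[p].size();
      r_coal[p] = k >= 2.0 ? k * (k - 1.0) / 2.0 / (2.0 * sizes(e, p)) : 0.0;
      r_mig[p] = k >= 1.0 ? k * mig_out[(size_t)e * P + p] : 0.0;
      r_tot += r_coal[p] + r_mig[p];
    }
    bool advance = false;
    double dt = 0.0;
    if (r_tot <= 0.0) {
      advance = true;
    } else {
      dt = R::exp_rand() / r_tot;
      if (e + 1 < E && t + dt > epoch_start[e + 1]) advance = true;
    }
    if (advance) {
      if (e + 1 >= E) {
        if (r_tot <= 0.0)
          stop("lineages cannot coalesce: populations never merge and no migration in final epoch");
        t += dt; // final epoch: fall through to event
      } else {
        t = epoch_start[e + 1];
        ++e;
        // apply remap on epoch entry
        std::vector<std::vector<int> > nact(P);
        for (int p = 0; p < P; ++p) {
          int q = remap(e, p);
          for (size_t i = 0; i < act[p].size(); ++i) nact[q].push_back(act[p][i]);
        }
        act.swap(nact);
        continue;
      }
    } else {
      t += dt;
    }
    // choose event
    double u = unif_rand() * r_tot;
    int p = 0;
    bool coal = false;
    for (p = 0; p < P; ++p) {
      if (u < r_coal[p]) { coal = true; break; }
      u -= r_coal[p];
      if (u < r_mig[p]) { coal = false; break; }
      u -= r_mig[p];
    }
    if (p >= P) p = P - 1; // numerical edge
    if (coal) {
      int k = (int)act[p].size();
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int a = act[p][i], b = act[p][j];
      int anc = next_node++;
      g.parent[a] = anc; g.parent[b] = anc;
      g.left[anc] = a; g.right[anc] = b;
      g.time[anc] = t;
      // remove i and j, add anc
      if (i < j) std::swap(i, j);
      act[p].erase(act[p].begin() + i);
      act[p].erase(act[p].begin() + j);
      act[p].push_back(anc);
      --n_active;
    } else {
      // migration out of p: choose destination
      double mo = 0.0;
      for (int j2 = 0; j2 < P; ++j2) if (j2 != p) mo += mig[((size_t)e * P + p) * P + j2];
      double v = unif_rand() * mo;
      int dest = -1;
      for (int j2 = 0; j2 < P; ++j2) {
        if (j2 == p) continue;
        v -= mig[((size_t)e * P + p) * P + j2];
        if (v <= 0.0) { dest = j2; break; }
      }
      if (dest < 0) { for (int j2 = P - 1; j2 >= 0; --j2) if (j2 != p) { dest = j2; break; } }
      int k = (int)act[p].size();
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int lin = act[p][i];
      act[p].erase(act[p].begin() + i);
      act[dest].push_back(lin);
    }
  }
  return g;
}

// collect tip indices below a node
void collect_tips(const Genealogy &g, int node, std::vector<int> &out) {
  std::vector<int> stack;
  stack.push_back(node);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    if (v < g.n_tips) out.push_back(v);
    else { stack.push_back(g.left[v]); stack.push_back(g.right[v]); }
  }
}

// draw mutations: returns (positions, carrier tip sets)
void drop_mutations(const Genealogy &g, double mu, int L,
                    std::vector<int> &pos, std::vector<std::vector<int> > &carriers) {
  int n_nodes = (int)g.parent.size();
  std::vector<double> bl(n_nodes, 0.0);
  double total = 0.0;
  for (int v = 0; v < n_nodes; ++v)
    if (g.parent[v] >= 0) { bl[v] = g.time[g.parent[v]] - g.time[v]; total += bl[v]; }
  int S = (int)R::rpois(mu * (double)L * total);
  if (S <= 0) return;
  // cumulative branch lengths
  std::vector<double> cum(n_nodes, 0.0);
  double c = 0.0;
  for (int v = 0; v < n_nodes; ++v) { c += bl[v]; cum[v] = c; }
  std::set<int> used;
  for (int s = 0; s < S; ++s) {
    // unique integer position (infinite-sites approximation on L sites)
    if ((int)used.size() >= L) break;
    int p;
    do { p = (int)(unif_rand() * L) + 1; if (p > L) p = L; } while (used.count(p));
    used.insert(p);
    double u = unif_rand() * total;
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (v >= n_nodes) v = n_nodes - 1;
    pos.push_back(p);
    std::vector<int> tips;
    collect_tips(g, v, tips);
    carriers.push_back(tips);
  }
  // sort by position
  std::vector<int> ord(pos.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return pos[a] < pos[b]; });
  std::vector<int> pos2(pos.size());
  std::vector<std::vector<int> > car2(pos.size());
  for (size_t i = 0; i < ord.size(); ++i) { pos2[i] = pos[ord[i]]; car2[i] = carriers[ord[i]]; }
  pos.swap(pos2); carriers.swap(car2);
}

double harmonic(int n, int pw) {
  double s = 0.0;
  for (int i = 1; i < n; ++i) s += 1.0 / std::pow((double)i, pw);
  return s;
}

// Tajima's D from haplotype count n, segregating sites S, total pairwise diversity pi
double tajimas_d_const(int n, int S, double pi) {
  if (S <= 0 || n < 4) return NA_REAL;
  double a1 = harmonic(n, 1), a2 = harmonic(n, 2);
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  double denom = std::sqrt(e1 * S + e2 * (double)S * (S - 1.0));
  if (denom <= 0.0) return NA_REAL;
  return (pi - S / a1) / denom;
}

} // namespace

// [[Rcpp::export]]
List coal_simulate_cpp(IntegerVector nsam, NumericVector epoch_start,
                       NumericMatrix sizes, NumericVector mig, IntegerMatrix remap,
                       int n_loci, int locus_length, double mu) {
  std::vector<int> ns(nsam.begin(), nsam.end());
  int n_total = 0;
  for (size_t i = 0; i < ns.size(); ++i) n_total += ns[i];
  List out(n_loci);
  for (int l = 0; l < n_loci; ++l) {
    Genealogy g = sim_tree(ns, epoch_start, sizes, mig, remap);
    std::vector<int> pos;
    std::vector<std::vector<int> > car;
    drop_mutations(g, mu, locus_length, pos, car);
    int S = (int)pos.size();
    IntegerMatrix G(S, n_total);
    for (int s = 0; s < S; ++s)
      for (size_t i = 0; i < car[s].size(); ++i) G(s, car[s][i]) = 1;
    out[l] = List::create(_["pos"] = wrap(pos), _["G"] = G);
  }
  return out;
}

namespace {
// accumulate the 10 per-locus summaries from per-site derived counts
void pair_stats_accumulate(int d1, int d2, int n1, int n2,
                           double &pi1, double &pi2, int &S1, int &S2,
                           int &shared, int &priv1, int &priv2,
                           double &fst_num, double &fst_den) {
  bool poly1 = d1 > 0 && d1 < n1, poly2 = d2 > 0 && d2 < n2;
  if (poly1) { ++S1; pi1 += 2.0 * d1 * (n1 - d1) / ((double)n1 * (n1 - 1.0)); }
  if (poly2) { ++S2; pi2 += 2.0 * d2 * (n2 - d2) / ((double)n2 * (n2 - 1.0)); }
  if (poly1 && poly2) ++shared;
  else if (poly1) ++priv1;
  else if (poly2) ++priv2;
  int dtot = d1 + d2;
  if (dtot > 0 && dtot < n1 + n2) {
    double p1 = (double)d1 / n1, p2 = (double)d2 / n2;
    double nbar = (n1 + n2) / 2.0;
    double nc = (n1 + n2) - ((double)n1 * n1 + (double)n2 * n2) / (n1 + n2);
    double pbar = (n1 * p1 + n2 * p2) / (n1 + n2);
    double s2 = (n1 * (p1 - pbar) * (p1 - pbar) +
                 n2 * (p2 - pbar) * (p2 - pbar)) / nbar;
    double a = (nbar / nc) * (s2 - (pbar * (1.0 - pbar) - s2 / 2.0) / (nbar - 1.0));
    double b = (nbar / (nbar - 1.0)) * (pbar * (1.0 - pbar) - s2 / 2.0);
    fst_num += a;
    fst_den += a + b;
  }
}
} // namespace

// 10 per-locus summaries from an explicit 0/1 site x haplotype matrix
// (first n1 columns = population 1); cross-check entry point for the
// simulation fast path.
// [[Rcpp::export]]
NumericVector locus_stats_matrix_cpp(IntegerMatrix G, int n1, int n2) {
  double pi1 = 0, pi2 = 0, fst_num = 0, fst_den = 0;
  int S1 = 0, S2 = 0, shared = 0, priv1 = 0, priv2 = 0;
  for (int s = 0; s < G.nrow(); ++s) {
    int d1 = 0, d2 = 0;
    for (int j = 0; j < n1; ++j) d1 += G(s, j);
    for (int j = n1; j < n1 + n2; ++j) d2 += G(s, j);
    pair_stats_accumulate(d1, d2, n1, n2, pi1, pi2, S1, S2, shared,
                          priv1, priv2, fst_num, fst_den);
  }
  NumericVector out(10);
  out[0] = pi1; out[1] = pi2;
  out[2] = n1 > 1 ? S1 / harmonic(n1, 1) : NA_REAL;
  out[3] = n2 > 1 ? S2 / harmonic(n2, 1) : NA_REAL;
  out[4] = tajimas_d_const(n1, S1, pi1);
  out[5] = tajimas_d_const(n2, S2, pi2);
  out[6] = fst_den > 0 ? fst_num / fst_den : NA_REAL;
  out[7] = shared; out[8] = priv1; out[9] = priv2;
  return out;
}

// Per-locus two-population summaries computed in one pass, for ABC reference
// tables.  Populations 0 and 1 of the demography are summarised (any further
// populations are simulated but ignored).  Columns:
// pi1, pi2, thetaW1, thetaW2, tajd1, tajd2, fst, n_shared, n_private1, n_private2
// pi / thetaW are per-locus totals (not per site).
// [[Rcpp::export]]
NumericMatrix coal_pair_summaries_cpp(IntegerVector nsam, NumericVector epoch_start,
                                      NumericMatrix sizes, NumericVector mig,
                                      IntegerMatrix remap, int n_loci,
                                      int locus_length, double mu) {
  std::vector<int> ns(nsam.begin(), nsam.end());
  int n1 = ns[0], n2 = ns.size() > 1 ? ns[1] : 0;
  NumericMatrix out(n_loci, 10);
  for (int l = 0; l < n_loci; ++l) {
    Genealogy g = sim_tree(ns, epoch_start, sizes, mig, remap);
    // per-node descendant-tip counts per population (children are always
    // created before their parent, so one forward pass suffices)
    int n_nodes = (int)g.parent.size();
    std::vector<int> c1(n_nodes, 0), c2(n_nodes, 0);
    for (int v = 0; v < n_nodes; ++v) {
      if (v < g.n_tips) {
        if (v < n1) c1[v] = 1; else if (v < n1 + n2) c2[v] = 1;
      } else {
        c1[v] = c1[g.left[v]] + c1[g.right[v]];
        c2[v] = c2[g.left[v]] + c2[g.right[v]];
      }
    }
    // branch lengths and mutation placement (positions are irrelevant for
    // the summaries; only derived counts per site matter)
    std::vector<double> cum(n_nodes, 0.0);
    double total = 0.0;
    for (int v = 0; v < n_nodes; ++v) {
      if (g.parent[v] >= 0) total += g.time[g.parent[v]] - g.time[v];
      cum[v] = total;
    }
    int S = (int)R::rpois(mu * (double)locus_length * total);
    double pi1 = 0.0, pi2 = 0.0, fst_num = 0.0, fst_den = 0.0;
    int S1 = 0, S2 = 0, shared = 0, priv1 = 0, priv2 = 0;
    for (int s = 0; s < S; ++s) {
      double u = unif_rand() * total;
      int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (v >= n_nodes) v = n_nodes - 1;
      pair_stats_accumulate(c1[v], c2[v], n1, n2, pi1, pi2, S1, S2,
                            shared, priv1, priv2, fst_num, fst_den);
    }
    out(l, 0) = pi1;
    out(l, 1) = pi2;
    out(l, 2) = n1 > 1 ? S1 / harmonic(n1, 1) : NA_REAL;
    out(l, 3) = n2 > 1 ? S2 / harmonic(n2, 1) : NA_REAL;
    out(l, 4) = tajimas_d_const(n1, S1, pi1);
    out(l, 5) = tajimas_d_const(n2, S2, pi2);
    out(l, 6) = fst_den > 0.0 ? fst_num / fst_den : NA_REAL;
    out(l, 7) = shared;
    out(l, 8) = priv1;
    out(l, 9) = priv2;
  }
  return out;
}
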