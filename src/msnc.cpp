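#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

// Structured-coalescent gene-tree simulator with instantaneous introgression
// pulses, plus an optional Poisson binary-trait overlay.  One haploid sample
// per species; time in coalescent units (2N generations), tips at time 0.
//
// Populations are labelled by the smallest tip index they contain.  Events
// (species-tree merges and pulses) arrive sorted by time; between events,
// lineages coalesce within populations at rate k(k-1)/2.  A pulse moves each
// lineage currently in the recipient-side population into the donor-side
// population independently with probability `prob` (backward-time semantics
// of a forward-time donor -> recipient pulse).

namespace {

struct NodeBuf {
  std::vector<int> parent, child1, child2;
  std::vector<double> time;
  void reset(int n_nodes) {
    parent.assign(n_nodes, -1);
    child1.assign(n_nodes, -1);
    child2.assign(n_nodes, -1);
    time.assign(n_nodes, 0.0);
  }
};

void canon_str(int v, const NodeBuf& nb, int n_tips, std::string& out) {
  if (v < n_tips) {
    out += 't';
    out += std::to_string(v + 1);
    return;
  }
  std::string a, b;
  canon_str(nb.child1[v], nb, n_tips, a);
  canon_str(nb.child2[v], nb, n_tips, b);
  if (b < a) std::swap(a, b);
  out += '(';
  out += a;
  out += ',';
  out += b;
  out += ')';
}

void newick_str(int v, const NodeBuf& nb, const CharacterVector& labels,
                int n_tips, double parent_time, std::string& out) {
  if (v < n_tips) {
    out += std::string(labels[v]);
  } else {
    out += '(';
    newick_str(nb.child1[v], nb, labels, n_tips, nb.time[v], out);
    out += ',';
    newick_str(nb.child2[v], nb, labels, n_tips, nb.time[v], out);
    out += ')';
  }
  if (parent_time >= 0) {
    char buf[40];
    snprintf(buf, sizeof(buf), ":%.10g", parent_time - nb.time[v]);
    out += buf;
  }
}

} // namespace

// [[Rcpp::export]]
List msnc_sim_cpp(int n_tips, CharacterVector tip_labels,
                  NumericVector ev_time, IntegerVector ev_type,
                  IntegerVector ev_a, IntegerVector ev_b,
                  NumericVector ev_prob, IntegerVector ev_id,
                  int n_loci, double mut_rate, double stem_height,
                  LogicalVector derived, bool want_trees,
                  bool want_topologies, bool want_focal) {
  const int n_ev = ev_time.size();
  const int n_nodes = 2 * n_tips - 1;
  const int root_id = n_nodes - 1;

  NodeBuf nb;
  std::vector<int> lin_node(n_tips), lin_pop(n_tips);
  std::vector<int> pop_count(n_tips);
  std::vector<int> kmut(n_nodes);
  std::vector<int> state(n_nodes);
  std::vector<bool> pure(n_nodes);

  std::map<std::string, long> topo_counts;
  std::vector<std::string> trees;
  std::vector<int> tree_origin;
  if (want_trees) {
    trees.reserve(n_loci);
    tree_origin.reserve(n_loci);
  }

  // focal-locus records
  std::vector<int> f_locus, f_muts, f_tipmut, f_intmut, f_fwd, f_rev,
      f_clades, f_origin;
  std::vector<std::string> f_topo;

  long n_focal = 0, n_introgressed = 0;
  int max_pulse = 0;
  for (int e = 0; e < n_ev; ++e)
    if (ev_type[e] == 1 && ev_id[e] > max_pulse) max_pulse = ev_id[e];
  std::vector<long> pulse_taken(max_pulse + 1, 0);

  for (int locus = 0; locus < n_loci; ++locus) {
    nb.reset(n_nodes);
    int n_lin = n_tips;
    for (int i = 0; i < n_tips; ++i) {
      lin_node[i] = i;
      lin_pop[i] = i;
    }
    int next_node = n_tips;
    int origin_mask = 0;
    double t = 0.0;

    for (int e = 0; e <= n_ev && n_lin > 1; ++e) {
      double t_end = (e < n_ev) ? ev_time[e] : R_PosInf;
      // coalesce within [t, t_end)
      while (n_lin > 1) {
        std::fill(pop_count.begin(), pop_count.end(), 0);
        for (int i = 0; i < n_lin; ++i) pop_count[lin_pop[i]]++;
        double rate = 0.0;
        for (int p = 0; p < n_tips; ++p)
          rate += 0.5 * pop_count[p] * (pop_count[p] - 1);
        if (rate <= 0.0) { t = t_end; break; }
        double dt = exp_rand() / rate;
        if (t + dt >= t_end) { t = t_end; break; }
        t += dt;
        // choose population proportional to its pair rate
        double u = unif_rand() * rate, acc = 0.0;
        int pop = -1;
        for (int p = 0; p < n_tips; ++p) {
          acc += 0.5 * pop_count[p] * (pop_count[p] - 1);
          if (u <= acc) { pop = p; break; }
        }
        if (pop < 0) pop = n_tips - 1;
        // choose an unordered pair uniformly within pop
        int k = pop_count[pop];
        int i1 = (int)(unif_rand() * k), i2 = (int)(unif_rand() * (k - 1));
        if (i2 >= i1) i2++;
        int a = -1, b = -1, seen = 0;
        for (int i = 0; i < n_lin; ++i) {
          if (lin_pop[i] != pop) continue;
          if (seen == i1) a = i;
          if (seen == i2) b = i;
          seen++;
        }
        int v = next_node++;
        nb.time[v] = t;
        nb.child1[v] = lin_node[a];
        nb.child2[v] = lin_node[b];
        nb.parent[lin_node[a]] = v;
        nb.parent[lin_node[b]] = v;
        lin_node[a] = v;
        // drop lineage b
        lin_node[b] = lin_node[n_lin - 1];
        lin_pop[b] = lin_pop[n_lin - 1];
        n_lin--;
      }
      if (e == n_ev || n_lin == 1) break;
      if (ev_type[e] == 0) { // merge: absorb ev_b into ev_a
        for (int i = 0; i < n_lin; ++i)
          if (lin_pop[i] == ev_b[e]) lin_pop[i] = ev_a[e];
      } else {
        // Pulses sharing one time form an exclusive group: at most one of
        // them fires per locus (a locus follows at most one introgressed
        // history at an instant).  The firing pulse moves every lineage
        // currently in its recipient population into the donor population.
        int g_end = e;
        while (g_end + 1 < n_ev && ev_type[g_end + 1] == 1 &&
               ev_time[g_end + 1] == ev_time[e])
          g_end++;
        double u = unif_rand(), acc = 0.0;
        for (int j = e; j <= g_end; ++j) {
          acc += ev_prob[j];
          if (u < acc) {
            for (int i = 0; i < n_lin; ++i)
              if (lin_pop[i] == ev_a[j]) {
                lin_pop[i] = ev_b[j];
                origin_mask |= (1 << ev_id[j]);
              }
            break;
          }
        }
        e = g_end;
      }
    }

    if (origin_mask) {
      n_introgressed++;
      for (int pid = 0; pid <= max_pulse; ++pid)
        if (origin_mask & (1 << pid)) pulse_taken[pid]++;
    }
    // re-root bookkeeping: last created node is the root
    // (next_node - 1 == root_id always, since all lineages coalesce)
    if (want_trees) {
      std::string s;
      newick_str(root_id, nb, tip_labels, n_tips, -1.0, s);
      s += ';';
      trees.push_back(s);
      tree_origin.push_back(origin_mask);
    }
    if (want_topologies) {
      std::string s;
      canon_str(root_id, nb, n_tips, s);
      topo_counts[s]++;
    }

    if (mut_rate > 0.0) {
      int total = 0;
      for (int v = 0; v < root_id; ++v) {
        double len = nb.time[nb.parent[v]] - nb.time[v];
        kmut[v] = (int)R::rpois(mut_rate * len);
        total += kmut[v];
      }
      double stem_len =
          (stem_height > 0.0 && stem_height > nb.time[root_id])
              ? stem_height - nb.time[root_id]
              : 0.0;
      int k_stem = (stem_len > 0.0) ? (int)R::rpois(mut_rate * stem_len) : 0;
      total += k_stem;
      if (total == 0) continue;
      // states by parity, preorder (nodes were created tips-first so a
      // parent always has a larger index than its children)
      state[root_id] = k_stem % 2;
      for (int v = root_id - 1; v >= 0; --v)
        state[v] = (state[nb.parent[v]] + kmut[v]) % 2;
      bool match = true;
      for (int i = 0; i < n_tips && match; ++i)
        if ((state[i] == 1) != (derived[i] == TRUE)) match = false;
      if (!match || !want_focal) continue;
      n_focal++;
      int tipmut = 0, intmut = k_stem, fwd = 0, rev = 0;
      // stem events: start in state 0
      fwd += (k_stem + 1) / 2;
      rev += k_stem / 2;
      for (int v = 0; v < root_id; ++v) {
        if (kmut[v] == 0) continue;
        if (v < n_tips) tipmut += kmut[v]; else intmut += kmut[v];
        int s0 = state[nb.parent[v]];
        if (s0 == 0) { fwd += (kmut[v] + 1) / 2; rev += kmut[v] / 2; }
        else         { rev += (kmut[v] + 1) / 2; fwd += kmut[v] / 2; }
      }
      // derived-clade count on the gene tree (maximal clades of derived tips)
      for (int v = 0; v < n_tips; ++v) pure[v] = (derived[v] == TRUE);
      for (int v = n_tips; v < n_nodes; ++v)
        pure[v] = pure[nb.child1[v]] && pure[nb.child2[v]];
      int clades = 0;
      for (int v = 0; v < n_nodes; ++v)
        if (pure[v] && (v == root_id || !pure[nb.parent[v]])) clades++;
      std::string topo;
      canon_str(root_id, nb, n_tips, topo);
      f_locus.push_back(locus + 1);
      f_muts.push_back(total);
      f_tipmut.push_back(tipmut);
      f_intmut.push_back(intmut);
      f_fwd.push_back(fwd);
      f_rev.push_back(rev);
      f_clades.push_back(clades);
      f_origin.push_back(origin_mask);
      f_topo.push_back(topo);
    }
  }

  List out = List::create(
      _["n_loci"] = (double)n_loci, _["n_focal"] = (double)n_focal,
      _["n_introgressed"] = (double)n_introgressed,
      _["pulse_taken"] = wrap(pulse_taken),
      _["focal"] = List::create(
          _["locus"] = wrap(f_locus), _["n_mutations"] = wrap(f_muts),
          _["tip_mutations"] = wrap(f_tipmut),
          _["internal_mutations"] = wrap(f_intmut),
          _["forward"] = wrap(f_fwd), _["reversal"] = wrap(f_rev),
          _["derived_clades"] = wrap(f_clades),
          _["origin_mask"] = wrap(f_origin), _["topology"] = wrap(f_topo)));
  if (want_trees) {
    out["trees"] = wrap(trees);
    out["tree_origin"] = wrap(tree_origin);
  }
  if (want_topologies) {
    CharacterVector nm(topo_counts.size());
    NumericVector ct(topo_counts.size());
    int i = 0;
    for (auto& kv : topo_counts) {
      nm[i] = kv.first;
      ct[i] = (double)kv.second;
      i++;
    }
    ct.names() = nm;
    out["topology_counts"] = ct;
  }
  return out;
}
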