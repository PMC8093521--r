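#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Brute-force dense-time membrane lattice.
//
// Each neurite is a 1-D chain of membrane points with spacing
// velocity * dt; a point fires at step s when its upstream neighbour
// fired at step s - 1 and the point itself has not fired within the
// last L_steps steps.  Network nodes are shared lattice points: a node
// fires when any incoming neurite's last point fired one step earlier
// (or a source input is scheduled), subject to the same refractory
// rule, and a node firing feeds the first point of every outgoing
// neurite.  A blocked (refractory) firing is dropped entirely and does
// not propagate.
//
// edge_steps[e] is the neurite latency in dt steps (node-to-node), so
// the chain holds edge_steps[e] - 1 interior points.
//
// [[Rcpp::export]]
List oracle_lattice_cpp(IntegerVector edge_from, IntegerVector edge_to,
                        IntegerVector edge_steps, int n_nodes,
                        List input_steps, int n_steps, int L_steps) {
  const int ne = edge_from.size();
  const int NEG = INT_MIN / 4;
  std::vector< std::vector<int> > pt_last(ne);
  std::vector< std::vector<char> > pt_prev(ne);
  std::vector<int> npts(ne);
  for (int e = 0; e < ne; ++e) {
    npts[e] = edge_steps[e] - 1;
    if (npts[e] < 1)
      stop("neurite latency must be at least 2 dt steps");
    pt_last[e].assign(npts[e], NEG);
    pt_prev[e].assign(npts[e], 0);
  }
  std::vector<int> node_last(n_nodes, NEG);
  std::vector<char> node_prev(n_nodes, 0), node_now(n_nodes, 0);
  std::vector< std::vector<int> > inputs(n_nodes), fires(n_nodes);
  std::vector<size_t> ip(n_nodes, 0);
  for (int n = 0; n < n_nodes; ++n) {
    IntegerVector v = input_steps[n];
    inputs[n] = as< std::vector<int> >(v);
  }

  for (int s = 0; s <= n_steps; ++s) {
    // node firings, from incoming edges (state at s - 1) and inputs
    for (int n = 0; n < n_nodes; ++n) {
      node_now[n] = 0;
      if (ip[n] < inputs[n].size() && inputs[n][ip[n]] == s) {
        node_now[n] = 1;
        ++ip[n];
      }
    }
    for (int e = 0; e < ne; ++e)
      if (pt_prev[e][npts[e] - 1]) node_now[edge_to[e]] = 1;
    for (int n = 0; n < n_nodes; ++n) {
      if (node_now[n]) {
        if (s - node_last[n] >= L_steps) {
          node_last[n] = s;
          fires[n].push_back(s);
        } else {
          node_now[n] = 0;  // refractory: dropped, does not propagate
        }
      }
    }
    // neurite points, descending so position j reads j-1's s-1 state
    for (int e = 0; e < ne; ++e) {
      std::vector<char>& pp = pt_prev[e];
      std::vector<int>& pl = pt_last[e];
      for (int j = npts[e] - 1; j >= 1; --j) {
        char f = pp[j - 1] && (s - pl[j] >= L_steps);
        pp[j] = f;
        if (f) pl[j] = s;
      }
      char f0 = node_prev[edge_from[e]] && (s - pl[0] >= L_steps);
      pp[0] = f0;
      if (f0) pl[0] = s;
    }
    std::swap(node_prev, node_now);
  }

  List out(n_nodes);
  for (int n = 0; n < n_nodes; ++n) out[n] = wrap(fires[n]);
  return out;
}
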