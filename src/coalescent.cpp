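#include <Rcpp.h>
using namespace Rcpp;

// Serial-sample coalescent at one microsatellite locus under a two-epoch
// piecewise-constant demography, with generalized stepwise mutation.
//
// Tips 0..(2*n_cont - 1) enter at time 0 (contemporary sample); tips
// 2*n_cont..(tips-1) enter at t_hist generations before present
// (historical sample). Pairs coalesce at rate C(k,2)/(2N), with N
// switching from N_cur to N_anc at t_bot. Mutations are Poisson along
// branches with per-locus rate mu; each mutation moves the repeat count by
// a +/- geometric(1 - gsm_p) step, reflected into [1, n_states]. The root
// state is the centre of the allowed range.
//
// Returns tip states; with return_tree also the parent pointers and node
// times (tips first, internal nodes in order of creation, root last).
// [[Rcpp::export]]
List sim_msat_locus_cpp(int n_cont, int n_hist, double t_hist,
                        double N_cur, double N_anc, double t_bot,
                        double mu, double gsm_p, int n_states,
                        bool return_tree = false) {
  const int tips = 2 * (n_cont + n_hist);
  if (tips < 2) stop("need at least one diploid individual in total");
  const int n_nodes = 2 * tips - 1;
  std::vector<int> parent(n_nodes, -1);
  std::vector<double> tnode(n_nodes, 0.0);
  std::vector<int> active;
  active.reserve(tips);
  for (int i = 0; i < 2 * n_cont; ++i) { active.push_back(i); tnode[i] = 0.0; }
  for (int i = 2 * n_cont; i < tips; ++i) tnode[i] = t_hist;
  bool hist_pending = (n_hist > 0);

  double t = 0.0;
  int next_node = tips;
  while ((int)active.size() + (hist_pending ? 2 * n_hist : 0) > 1) {
    int k = (int)active.size();
    if (k < 2) {            // cannot coalesce until historical tips enter
      t = t_hist;
      for (int i = 2 * n_cont; i < tips; ++i) active.push_back(i);
      hist_pending = false;
      continue;
    }
    double bnd = R_PosInf;
    if (hist_pending) bnd = std::min(bnd, t_hist);
    if (t < t_bot) bnd = std::min(bnd, t_bot);
    double N = (t < t_bot) ? N_cur : N_anc;
    double rate = (double)k * (k - 1) / 2.0 / (2.0 * N);
    double tn = t + R::exp_rand() / rate;
    if (tn >= bnd) {
      t = bnd;
      if (hist_pending && bnd == t_hist) {
        for (int i = 2 * n_cont; i < tips; ++i) active.push_back(i);
        hist_pending = false;
      }
      continue;             // epoch switch handled by the (t < t_bot) test
    }
    t = tn;
    int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    int p = next_node++;
    parent[a] = p; parent[b] = p; tnode[p] = t;
    if (i < j) std::swap(i, j);       // remove the larger index first
    active[i] = active.back(); active.pop_back();
    active[j] = active.back(); active.pop_back();
    active.push_back(p);
  }

  // drop mutations root -> tips (parents always have larger index)
  std::vector<int> st(n_nodes);
  const int root = n_nodes - 1;
  st[root] = (n_states + 1) / 2;
  for (int v = root - 1; v >= 0; --v) {
    double len = tnode[parent[v]] - tnode[v];
    int s = st[parent[v]];
    if (mu > 0.0 && len > 0.0) {
      int nm = (int)R::rpois(mu * len);
      for (int m = 0; m < nm; ++m) {
        int step = 1;
        if (gsm_p > 0.0) step += (int)R::rgeom(1.0 - gsm_p);
        if (unif_rand() < 0.5) step = -step;
        s += step;
        while (s < 1 || s > n_states) {
          if (s < 1) s = 2 - s; else s = 2 * n_states - s;
        }
      }
    }
    st[v] = s;
  }
  IntegerVector states(tips);
  for (int i = 0; i < tips; ++i) states[i] = st[i];
  if (!return_tree) return List::create(_["states"] = states);
  return List::create(_["states"] = states,
                      _["parent"] = IntegerVector(parent.begin(), parent.end()),
                      _["time"] = NumericVector(tnode.begin(), tnode.end()));
}
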