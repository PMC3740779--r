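#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Node-limited betweenness centrality, restricted Brandes accumulation.
//
// The graph is passed in CSR form: ptr has length V+1, adj holds the
// 0-based neighbour indices of node i in adj[ptr[i] .. ptr[i+1]-1].
// All graphs are simple, undirected and unweighted; shortest paths are
// hop counts found by BFS, and sigma path counts are exact in double
// precision (integers below 2^53).
//
// For one source s in U the backward sweep carries two dependencies:
//   d1[v] = sum over targets t in U\{s} of sigma_st(v)/sigma_st
//   dw[v] = the same sum with each term multiplied by w(t)
// so the ordered-pair accumulation for s is w(s)*d1[v] + dw[v].
// Summed over all s in U this double-counts each unordered pair exactly
// once in both the numerator and the normalizer 2*(|U|-1)*sum(w), so the
// quotient equals the unordered-pair definition.

namespace {

struct Workspace {
    std::vector<int> dist;
    std::vector<double> sigma;
    std::vector<int> order;   // BFS visit order
    std::vector<double> d1;
    std::vector<double> dw;
    explicit Workspace(int V)
        : dist(V), sigma(V), d1(V), dw(V) {
        order.reserve(V);
    }
};

// Accumulate ordered-pair dependencies for all sources into acc.
// isU / wOf describe the current input set (wOf is 0 off-U).
void accumulate_all_sources(const std::vector<int>& ptr,
                            const std::vector<int>& adj,
                            int V,
                            const std::vector<int>& sources,
                            const std::vector<char>& isU,
                            const std::vector<double>& wOf,
                            std::vector<double>& acc,
                            Workspace& ws) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (size_t si = 0; si < sources.size(); ++si) {
        const int s = sources[si];
        const double w_s = wOf[s];

        std::fill(ws.dist.begin(), ws.dist.end(), -1);
        std::fill(ws.sigma.begin(), ws.sigma.end(), 0.0);
        ws.order.clear();

        ws.dist[s] = 0;
        ws.sigma[s] = 1.0;
        ws.order.push_back(s);
        for (size_t head = 0; head < ws.order.size(); ++head) {
            const int u = ws.order[head];
            const int du = ws.dist[u];
            for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
                const int v = adj[k];
                if (ws.dist[v] < 0) {
                    ws.dist[v] = du + 1;
                    ws.order.push_back(v);
                }
                if (ws.dist[v] == du + 1) ws.sigma[v] += ws.sigma[u];
            }
        }

        for (size_t i = 0; i < ws.order.size(); ++i) {
            ws.d1[ws.order[i]] = 0.0;
            ws.dw[ws.order[i]] = 0.0;
        }
        // Reverse BFS order: every node precedes its predecessors.
        for (size_t i = ws.order.size(); i-- > 0;) {
            const int u = ws.order[i];
            double c1 = ws.d1[u];
            double cw = ws.dw[u];
            if (u != s && isU[u]) {  // u is a target: seed its endpoint credit
                c1 += 1.0;
                cw += wOf[u];
            }
            if (c1 == 0.0 && cw == 0.0) continue;
            const int du = ws.dist[u];
            for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
                const int p = adj[k];
                if (ws.dist[p] == du - 1) {  // p is a shortest-path predecessor
                    const double ratio = ws.sigma[p] / ws.sigma[u];
                    ws.d1[p] += ratio * c1;
                    ws.dw[p] += ratio * cw;
                }
            }
        }

        // Interior-only: the source never scores from its own sweep, and
        // targets only pick up credit routed through them to farther targets.
        for (size_t i = 0; i < ws.order.size(); ++i) {
            const int v = ws.order[i];
            if (v == s) continue;
            acc[v] += w_s * ws.d1[v] + ws.dw[v];
        }
    }
}

}  // namespace

// [[Rcpp::export(name = ".nlbc_brandes_csr")]]
NumericVector nlbc_brandes_csr(IntegerVector ptr_r, IntegerVector adj_r,
                               IntegerVector sources_r, NumericVector weights_r,
                               int V) {
    const std::vector<int> ptr(ptr_r.begin(), ptr_r.end());
    const std::vector<int> adj(adj_r.begin(), adj_r.end());
    const int m = sources_r.size();
    if (m < 2) stop("need at least two input nodes");

    std::vector<int> sources(sources_r.begin(), sources_r.end());
    std::vector<char> isU(V, 0);
    std::vector<double> wOf(V, 0.0);
    double wsum = 0.0;
    for (int i = 0; i < m; ++i) {
        isU[sources[i]] = 1;
        wOf[sources[i]] = weights_r[i];
        wsum += weights_r[i];
    }

    Workspace ws(V);
    std::vector<double> acc(V);
    accumulate_all_sources(ptr, adj, V, sources, isU, wOf, acc, ws);

    const double norm = 2.0 * (m - 1) * wsum;  // ordered-pair normalizer
    NumericVector out(V);
    for (int v = 0; v < V; ++v) out[v] = acc[v] / norm;
    return out;
}

// Monte-Carlo null: column j of samples holds the 0-based node indices of
// replicate j's input set; column j of wmat holds the weights mapped onto
// those nodes. r counts replicates whose nlBC at a tracked node meets or
// exceeds the observed value.
// [[Rcpp::export(name = ".nlbc_null_counts_csr")]]
List nlbc_null_counts_csr(IntegerVector ptr_r, IntegerVector adj_r, int V,
                          IntegerMatrix samples, NumericMatrix wmat,
                          NumericVector original, IntegerVector tracked_r,
                          bool keep_samples) {
    const std::vector<int> ptr(ptr_r.begin(), ptr_r.end());
    const std::vector<int> adj(adj_r.begin(), adj_r.end());
    const int m = samples.nrow();
    const int nrep = samples.ncol();
    if (m < 2) stop("need at least two input nodes");
    const int ntr = tracked_r.size();

    std::vector<int> tracked(tracked_r.begin(), tracked_r.end());
    std::vector<double> orig(ntr);
    for (int i = 0; i < ntr; ++i) orig[i] = original[tracked[i]];

    Workspace ws(V);
    std::vector<double> acc(V);
    std::vector<char> isU(V, 0);
    std::vector<double> wOf(V, 0.0);
    std::vector<int> sources(m);

    IntegerVector r(ntr);
    NumericMatrix kept =
        keep_samples ? NumericMatrix(nrep, ntr) : NumericMatrix(0, 0);

    for (int j = 0; j < nrep; ++j) {
        double wsum = 0.0;
        for (int i = 0; i < m; ++i) {
            const int v = samples(i, j);
            sources[i] = v;
            isU[v] = 1;
            wOf[v] = wmat(i, j);
            wsum += wmat(i, j);
        }
        accumulate_all_sources(ptr, adj, V, sources, isU, wOf, acc, ws);
        const double norm = 2.0 * (m - 1) * wsum;
        for (int i = 0; i < ntr; ++i) {
            const double val = acc[tracked[i]] / norm;
            if (val >= orig[i]) ++r[i];
            if (keep_samples) kept(j, i) = val;
        }
        for (int i = 0; i < m; ++i) {  // reset only the touched slots
            isU[sources[i]] = 0;
            wOf[sources[i]] = 0.0;
        }
        if (j % 256 == 0) Rcpp::checkUserInterrupt();
    }

    if (keep_samples) return List::create(_["r"] = r, _["samples"] = kept);
    return List::create(_["r"] = r, _["samples"] = R_NilValue);
}
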