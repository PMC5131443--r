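#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

// Brandes' accumulation for betweenness centrality on an unweighted,
// undirected simple graph. The graph is passed in CSR form: adj holds the
// 0-based neighbour indices of node 0, then node 1, ...; ptr (length n+1,
// 0-based offsets) delimits each node's slice. Pairs in different components
// contribute nothing; endpoints are excluded. Each unordered pair is counted
// once (the directed double-count is halved at the end).
// [[Rcpp::export]]
NumericVector brandes_betweenness(int n, IntegerVector adj, IntegerVector ptr) {
    NumericVector bc_out(n, 0.0);
    if (n == 0) return bc_out;

    std::vector<int> adj_v(adj.begin(), adj.end());
    std::vector<int> ptr_v(ptr.begin(), ptr.end());
    const int *adj_p = adj_v.data();
    const int *ptr_p = ptr_v.data();
    std::vector<double> bc(n, 0.0);

    std::vector<int> dist(n), order_stack(n);
    std::vector<double> sigma(n), delta(n);
    std::vector<int> queue_buf(n);

    for (int s = 0; s < n; ++s) {
        std::fill(dist.begin(), dist.end(), -1);
        std::fill(sigma.begin(), sigma.end(), 0.0);
        std::fill(delta.begin(), delta.end(), 0.0);

        int qhead = 0, qtail = 0, stop = 0;
        dist[s] = 0;
        sigma[s] = 1.0;
        queue_buf[qtail++] = s;
        while (qhead < qtail) {
            int v = queue_buf[qhead++];
            order_stack[stop++] = v;
            for (int j = ptr_p[v]; j < ptr_p[v + 1]; ++j) {
                int w = adj_p[j];
                if (dist[w] < 0) {
                    dist[w] = dist[v] + 1;
                    queue_buf[qtail++] = w;
                }
                if (dist[w] == dist[v] + 1) sigma[w] += sigma[v];
            }
        }
        // dependency accumulation in reverse BFS order
        for (int i = stop - 1; i > 0; --i) {
            int w = order_stack[i];
            for (int j = ptr_p[w]; j < ptr_p[w + 1]; ++j) {
                int v = adj_p[j];
                if (dist[v] == dist[w] - 1)
                    delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
            }
            bc[w] += delta[w];
        }
    }
    for (int v = 0; v < n; ++v) bc_out[v] = bc[v] / 2.0;
    return bc_out;
}
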