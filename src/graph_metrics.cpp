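#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Unweighted single-source BFS over a CSR adjacency; fills dist with
// -1 for unreachable nodes.
static void bfs(const int n, const IntegerVector& indptr,
                const IntegerVector& indices, const int src,
                std::vector<int>& dist, std::vector<int>& queue_buf) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[src] = 0;
    queue_buf[tail++] = src;
    while (head < tail) {
        int u = queue_buf[head++];
        int d = dist[u] + 1;
        for (int p = indptr[u]; p < indptr[u + 1]; ++p) {
            int v = indices[p];
            if (dist[v] < 0) {
                dist[v] = d;
                queue_buf[tail++] = v;
            }
        }
    }
}

// Per-node sums over all other nodes of 1/d (unreachable -> 0), of
// finite d, and the count of reachable other nodes. Columns:
// inv_dist_sum, fin_dist_sum, fin_count.
// [[Rcpp::export(name = ".cpp_path_sums")]]
NumericMatrix cpp_path_sums(const IntegerVector indptr,
                            const IntegerVector indices) {
    const int n = indptr.size() - 1;
    NumericMatrix out(n, 3);
    std::vector<int> dist(n), qb(n);
    for (int s = 0; s < n; ++s) {
        bfs(n, indptr, indices, s, dist, qb);
        double inv = 0.0, fin = 0.0; int cnt = 0;
        for (int v = 0; v < n; ++v) {
            if (v == s || dist[v] < 0) continue;
            inv += 1.0 / dist[v];
            fin += dist[v];
            ++cnt;
        }
        out(s, 0) = inv;
        out(s, 1) = fin;
        out(s, 2) = cnt;
    }
    return out;
}

// Global efficiency of the subgraph induced on each node's neighbors
// (the node itself excluded); nodes with < 2 neighbors get 0.
// [[Rcpp::export(name = ".cpp_local_efficiency")]]
NumericVector cpp_local_efficiency(const IntegerVector indptr,
                                   const IntegerVector indices) {
    const int n = indptr.size() - 1;
    NumericVector out(n);
    std::vector<int> local_id(n, -1);
    std::vector<int> nb, dist, qb;
    std::vector<std::vector<int>> ladj;
    for (int s = 0; s < n; ++s) {
        const int k = indptr[s + 1] - indptr[s];
        if (k < 2) { out[s] = 0.0; continue; }
        nb.assign(indices.begin() + indptr[s], indices.begin() + indptr[s + 1]);
        for (int a = 0; a < k; ++a) local_id[nb[a]] = a;
        ladj.assign(k, std::vector<int>());
        for (int a = 0; a < k; ++a) {
            int u = nb[a];
            for (int p = indptr[u]; p < indptr[u + 1]; ++p) {
                int lv = local_id[indices[p]];
                if (lv >= 0) ladj[a].push_back(lv);
            }
        }
        // BFS within the induced subgraph from every neighbor
        dist.assign(k, -1);
        qb.assign(k, 0);
        double total = 0.0;
        for (int a = 0; a < k; ++a) {
            std::fill(dist.begin(), dist.end(), -1);
            int head = 0, tail = 0;
            dist[a] = 0;
            qb[tail++] = a;
            while (head < tail) {
                int u = qb[head++];
                int d = dist[u] + 1;
                for (int v : ladj[u])
                    if (dist[v] < 0) { dist[v] = d; qb[tail++] = v; }
            }
            for (int v = 0; v < k; ++v)
                if (v != a && dist[v] > 0) total += 1.0 / dist[v];
        }
        out[s] = total / (static_cast<double>(k) * (k - 1));
        for (int a = 0; a < k; ++a) local_id[nb[a]] = -1;
    }
    return out;
}

// Triangle count through each node (each triangle counted once per
// incident node), for the binary clustering coefficient.
// [[Rcpp::export(name = ".cpp_triangles")]]
NumericVector cpp_triangles(const IntegerVector indptr,
                            const IntegerVector indices) {
    const int n = indptr.size() - 1;
    NumericVector out(n);
    std::vector<char> is_nb(n, 0);
    for (int s = 0; s < n; ++s) {
        for (int p = indptr[s]; p < indptr[s + 1]; ++p) is_nb[indices[p]] = 1;
        double t = 0.0;
        for (int p = indptr[s]; p < indptr[s + 1]; ++p) {
            int u = indices[p];
            for (int q = indptr[u]; q < indptr[u + 1]; ++q)
                if (is_nb[indices[q]]) t += 1.0;
        }
        out[s] = t / 2.0;  // each neighbor pair seen twice
        for (int p = indptr[s]; p < indptr[s + 1]; ++p) is_nb[indices[p]] = 0;
    }
    return out;
}
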