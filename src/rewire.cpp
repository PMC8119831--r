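#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Small self-contained PRNG (xorshift64*) so rewiring is reproducible from
// an integer seed independently of R's RNG state.
static inline uint64_t next_u64(uint64_t &s) {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s * 0x2545F4914F6CDD1DULL;
}

// Maslov-Sneppen degree-preserving rewiring by repeated double-edge swaps
// (a-b, c-d -> a-d, c-b).  `edges` is an m x 2 matrix of 0-based endpoints
// of an undirected simple graph.  `n_attempts` swap attempts are made; for
// each, up to `max_tries` random edge pairs are tried before the attempt is
// counted as skipped.  Swaps creating self-loops or multi-edges (or drawing
// two edges sharing an endpoint) are rejected.  Endpoints are modified in
// place per edge row, so per-edge weights tracked by row order travel with
// the rewired edges.
// [[Rcpp::export]]
List rewire_edges_cpp(IntegerMatrix edges, int n_nodes, int n_attempts,
                      int max_tries, double seed) {
    int m = edges.nrow();
    IntegerMatrix out(clone(edges));
    std::vector<char> adj((size_t)n_nodes * n_nodes, 0);
    for (int e = 0; e < m; ++e) {
        int a = out(e, 0), b = out(e, 1);
        adj[(size_t)a * n_nodes + b] = 1;
        adj[(size_t)b * n_nodes + a] = 1;
    }
    uint64_t state = (uint64_t)seed * 2654435761ULL + 88172645463325252ULL;
    int skipped = 0;
    for (int att = 0; att < n_attempts; ++att) {
        bool done = false;
        for (int t = 0; t < max_tries && !done; ++t) {
            int e1 = (int)(next_u64(state) % (uint64_t)m);
            int e2 = (int)(next_u64(state) % (uint64_t)m);
            if (e1 == e2) continue;
            int a = out(e1, 0), b = out(e1, 1);
            int c = out(e2, 0), d = out(e2, 1);
            if (next_u64(state) & 1ULL) std::swap(c, d); // both pairings reachable
            if (a == c || a == d || b == c || b == d) continue;
            if (adj[(size_t)a * n_nodes + d] || adj[(size_t)c * n_nodes + b])
                continue;
            adj[(size_t)a * n_nodes + b] = adj[(size_t)b * n_nodes + a] = 0;
            adj[(size_t)c * n_nodes + d] = adj[(size_t)d * n_nodes + c] = 0;
            adj[(size_t)a * n_nodes + d] = adj[(size_t)d * n_nodes + a] = 1;
            adj[(size_t)c * n_nodes + b] = adj[(size_t)b * n_nodes + c] = 1;
            out(e1, 1) = d;
            out(e2, 0) = c;
            out(e2, 1) = b;
            done = true;
        }
        if (!done) ++skipped;
    }
    return List::create(_["edges"] = out, _["skipped"] = skipped);
}
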