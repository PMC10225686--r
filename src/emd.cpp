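#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact earth mover's distance between two discrete distributions via
// successive-shortest-path min-cost flow on the dense bipartite transport
// graph. Arcs are uncapacitated, so each augmentation saturates at least one
// supply or demand node and at most m + n - 1 augmentations occur. Node
// potentials keep reduced costs nonnegative so Dijkstra applies.
//
// supply: length-m positive masses, demand: length-n positive masses
// (equal totals up to rounding); cost: m x n ground-distance matrix.
// [[Rcpp::export(name = ".emdTransport")]]
double emdTransport(Rcpp::NumericVector supply,
                    Rcpp::NumericVector demand,
                    Rcpp::NumericMatrix cost) {
    const int m = supply.size(), n = demand.size();
    const int V = m + n; // nodes: 0..m-1 sources, m..m+n-1 sinks
    std::vector<double> rs(supply.begin(), supply.end());
    std::vector<double> rd(demand.begin(), demand.end());
    std::vector<std::vector<double>> flow(m, std::vector<double>(n, 0.0));
    std::vector<double> pot(V, 0.0);

    double total = 0.0;
    for (int i = 0; i < m; ++i) total += rs[i];
    double shipped = 0.0;
    const double eps = 1e-12 * std::max(1.0, total);
    const double INF = std::numeric_limits<double>::infinity();

    std::vector<double> dist(V);
    std::vector<int> parent(V);
    std::vector<bool> done(V);

    long iter = 0, maxIter = 1000L * (m + n) + 1000L;
    while (total - shipped > eps && ++iter <= maxIter) {
        std::fill(dist.begin(), dist.end(), INF);
        std::fill(parent.begin(), parent.end(), -1);
        std::fill(done.begin(), done.end(), false);
        // implicit super-source with zero-cost arcs to each remaining
        // supply node: initial label is that arc's reduced cost
        for (int i = 0; i < m; ++i)
            if (rs[i] > eps) dist[i] = std::max(-pot[i], 0.0);

        // dense Dijkstra
        for (int it = 0; it < V; ++it) {
            int u = -1;
            double best = INF;
            for (int v = 0; v < V; ++v)
                if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
            if (u < 0) break;
            done[u] = true;
            if (u < m) {
                // forward arcs source u -> every sink
                for (int j = 0; j < n; ++j) {
                    if (done[m + j]) continue;
                    // reduced costs are >= 0 up to rounding; clamp so
                    // finalized labels can never be undercut (no parent
                    // cycles)
                    double rc = cost(u, j) + pot[u] - pot[m + j];
                    if (rc < 0) rc = 0;
                    if (dist[u] + rc < dist[m + j]) {
                        dist[m + j] = dist[u] + rc;
                        parent[m + j] = u;
                    }
                }
            } else {
                // backward arcs sink -> source where flow exists
                int j = u - m;
                for (int i = 0; i < m; ++i) {
                    if (done[i]) continue;
                    if (flow[i][j] > eps) {
                        double rc = -cost(i, j) + pot[u] - pot[i];
                        if (rc < 0) rc = 0;
                        if (dist[u] + rc < dist[i]) {
                            dist[i] = dist[u] + rc;
                            parent[i] = u;
                        }
                    }
                }
            }
        }

        // closest sink with remaining demand
        int target = -1;
        double bestD = INF;
        for (int j = 0; j < n; ++j)
            if (rd[j] > eps && dist[m + j] < bestD) {
                bestD = dist[m + j];
                target = j;
            }
        if (target < 0) break; // numerically exhausted

        for (int v = 0; v < V; ++v)
            if (dist[v] < INF) pot[v] += dist[v];

        // trace path back, find bottleneck
        double delta = rd[target];
        int v = m + target;
        while (parent[v] >= 0) {
            int u = parent[v];
            if (u >= m) {            // backward arc u(sink) <- v(source)
                delta = std::min(delta, flow[v][u - m]);
            }
            v = u;
        }
        delta = std::min(delta, rs[v]); // v is the originating source

        // apply augmentation
        int w = m + target;
        while (parent[w] >= 0) {
            int u = parent[w];
            if (u < m) flow[u][w - m] += delta;      // forward source->sink
            else       flow[w][u - m] -= delta;      // backward
            w = u;
        }
        rs[w] -= delta;
        rd[target] -= delta;
        shipped += delta;
        if (delta <= eps) break; // no numerical progress possible
    }

    // ship any residual mass greedily (only reachable when the main loop
    // exits on a numerical guard; keeps the result a valid transport cost)
    for (int i = 0; i < m; ++i) {
        if (rs[i] <= 0) continue;
        for (int j = 0; j < n && rs[i] > 0; ++j) {
            if (rd[j] <= 0) continue;
            double d = std::min(rs[i], rd[j]);
            flow[i][j] += d;
            rs[i] -= d;
            rd[j] -= d;
        }
    }

    double c = 0.0;
    for (int i = 0; i < m; ++i)
        for (int j = 0; j < n; ++j)
            if (flow[i][j] > 0) c += flow[i][j] * cost(i, j);
    return c;
}
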