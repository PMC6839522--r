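#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Trees arrive as undirected edge matrices over node ids 1..N, where ids
// 1..ntip are tips (rows of tip_state) and the rest are internal. State sets
// are bitmasks over the 0-9 alphabet (bit k = state k). Cells coded missing
// or inapplicable must already have been replaced by the per-character
// observed-state set on the R side.

static const int NSTATES = 10;

struct Oriented {
    std::vector<int> parent;          // 0 = none (root), 1..N otherwise
    std::vector<int> order;           // children-before-parents
    std::vector<std::vector<int>> kids;
};

static Oriented orient_tree(const IntegerMatrix& edge, int N, int root) {
    std::vector<std::vector<int>> adj(N + 1);
    for (int i = 0; i < edge.nrow(); ++i) {
        int a = edge(i, 0), b = edge(i, 1);
        adj[a].push_back(b);
        adj[b].push_back(a);
    }
    Oriented o;
    o.parent.assign(N + 1, 0);
    o.kids.assign(N + 1, std::vector<int>());
    o.order.reserve(N);
    std::vector<int> stack;
    stack.push_back(root);
    std::vector<char> seen(N + 1, 0);
    seen[root] = 1;
    // preorder; reversed it gives a valid children-first order
    std::vector<int> pre;
    pre.reserve(N);
    while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        pre.push_back(v);
        for (int w : adj[v]) {
            if (!seen[w]) {
                seen[w] = 1;
                o.parent[w] = v;
                o.kids[v].push_back(w);
                stack.push_back(w);
            }
        }
    }
    o.order.assign(pre.rbegin(), pre.rend());
    return o;
}

// Hartigan downpass for one tree; fills `down` (N x nchar bitmasks) and
// returns per-character added steps.
static void hartigan_down(const Oriented& o, int ntip,
                          const IntegerMatrix& tip_state,
                          std::vector<int>& down, IntegerVector& steps,
                          int nchar, int N) {
    for (int v : o.order) {
        if (v <= ntip) {
            for (int c = 0; c < nchar; ++c)
                down[(size_t)(v - 1) * nchar + c] = tip_state(v - 1, c);
            continue;
        }
        const std::vector<int>& kk = o.kids[v];
        int d = (int)kk.size();
        for (int c = 0; c < nchar; ++c) {
            int cnt[NSTATES] = {0};
            for (int w : kk) {
                int s = down[(size_t)(w - 1) * nchar + c];
                for (int k = 0; k < NSTATES; ++k)
                    if (s & (1 << k)) cnt[k]++;
            }
            int m = 0;
            for (int k = 0; k < NSTATES; ++k)
                if (cnt[k] > m) m = cnt[k];
            int set = 0;
            for (int k = 0; k < NSTATES; ++k)
                if (cnt[k] == m) set |= (1 << k);
            down[(size_t)(v - 1) * nchar + c] = set;
            steps[c] += d - m;
        }
    }
}

// Full single-tree analysis: downpass steps plus directional ("up") and MPR
// ("final") state sets needed for synapomorphy mapping and zero-length-branch
// detection. Rooted internally at node ntip+1.
// [[Rcpp::export]]
List fitch_analyze_cpp(IntegerMatrix edge, int ntip, IntegerMatrix tip_state) {
    int nchar = tip_state.ncol();
    int N = 0;
    for (int i = 0; i < edge.nrow(); ++i)
        N = std::max(N, std::max(edge(i, 0), edge(i, 1)));
    int root = ntip + 1;
    if (N < root) stop("tree has no internal node");
    Oriented o = orient_tree(edge, N, root);

    std::vector<int> down((size_t)N * nchar, 0);
    IntegerVector steps(nchar);
    hartigan_down(o, ntip, tip_state, down, steps, nchar, N);

    // counts over children only, per node (needed to exclude one child)
    std::vector<short> cdown((size_t)N * nchar * NSTATES, 0);
    for (int v = ntip + 1; v <= N; ++v) {
        for (int c = 0; c < nchar; ++c) {
            short* cc = &cdown[((size_t)(v - 1) * nchar + c) * NSTATES];
            for (int w : o.kids[v]) {
                int s = down[(size_t)(w - 1) * nchar + c];
                for (int k = 0; k < NSTATES; ++k)
                    if (s & (1 << k)) cc[k]++;
            }
        }
    }

    // up(v): Hartigan set of the component on the parent side of edge
    // (parent(v), v); preorder so parents are done first.
    std::vector<int> up((size_t)N * nchar, 0);
    for (auto it = o.order.rbegin(); it != o.order.rend(); ++it) {
        int v = *it;
        int u = o.parent[v];
        if (u == 0) continue;  // root: no parent side
        bool uroot = (u == root);
        for (int c = 0; c < nchar; ++c) {
            const short* cc = &cdown[((size_t)(u - 1) * nchar + c) * NSTATES];
            int sv = down[(size_t)(v - 1) * nchar + c];
            int su = uroot ? 0 : up[(size_t)(u - 1) * nchar + c];
            int m = 0, set = 0;
            int cnt[NSTATES];
            for (int k = 0; k < NSTATES; ++k) {
                cnt[k] = cc[k] - ((sv >> k) & 1) + ((su >> k) & 1);
                if (cnt[k] > m) m = cnt[k];
            }
            for (int k = 0; k < NSTATES; ++k)
                if (cnt[k] == m) set |= (1 << k);
            up[(size_t)(v - 1) * nchar + c] = set;
        }
    }

    // final/MPR set: argmax over children counts + parent-side set
    IntegerMatrix fin(N, nchar), dn(N, nchar), upm(N, nchar);
    for (int v = 1; v <= N; ++v) {
        for (int c = 0; c < nchar; ++c) {
            dn(v - 1, c) = down[(size_t)(v - 1) * nchar + c];
            upm(v - 1, c) = up[(size_t)(v - 1) * nchar + c];
            int f;
            if (v <= ntip) {
                // tip MPR set: compatible subset of its observed set if any
                int s = down[(size_t)(v - 1) * nchar + c];
                int pu = up[(size_t)(v - 1) * nchar + c];
                int inter = s & pu;
                f = inter ? inter : s;
            } else if (v == root) {
                f = down[(size_t)(v - 1) * nchar + c];
            } else {
                const short* cc =
                    &cdown[((size_t)(v - 1) * nchar + c) * NSTATES];
                int pu = up[(size_t)(v - 1) * nchar + c];
                int m = 0, set = 0;
                int cnt[NSTATES];
                for (int k = 0; k < NSTATES; ++k) {
                    cnt[k] = cc[k] + ((pu >> k) & 1);
                    if (cnt[k] > m) m = cnt[k];
                }
                for (int k = 0; k < NSTATES; ++k)
                    if (cnt[k] == m) set |= (1 << k);
                f = set;
            }
            fin(v - 1, c) = f;
        }
    }

    IntegerVector parent(N);
    for (int v = 1; v <= N; ++v) parent[v - 1] = o.parent[v];
    return List::create(_["steps"] = steps, _["down"] = dn, _["up"] = upm,
                        _["final"] = fin, _["parent"] = parent);
}

// Weighted total parsimony length for a list of trees over a common tip set.
// [[Rcpp::export]]
NumericVector fitch_batch_cpp(List edges, int ntip, IntegerMatrix tip_state,
                              NumericVector weights) {
    int nchar = tip_state.ncol();
    int nt = edges.size();
    NumericVector out(nt);
    for (int t = 0; t < nt; ++t) {
        IntegerMatrix edge = edges[t];
        int N = 0;
        for (int i = 0; i < edge.nrow(); ++i)
            N = std::max(N, std::max(edge(i, 0), edge(i, 1)));
        Oriented o = orient_tree(edge, N, ntip + 1);
        std::vector<int> down((size_t)N * nchar, 0);
        IntegerVector steps(nchar);
        hartigan_down(o, ntip, tip_state, down, steps, nchar, N);
        double tot = 0;
        for (int c = 0; c < nchar; ++c) tot += weights[c] * steps[c];
        out[t] = tot;
    }
    return out;
}

// Per-character steps for a list of trees (used by per-character fit tables
// and tests); rows = trees, cols = characters.
// [[Rcpp::export]]
IntegerMatrix fitch_batch_steps_cpp(List edges, int ntip,
                                    IntegerMatrix tip_state) {
    int nchar = tip_state.ncol();
    int nt = edges.size();
    IntegerMatrix out(nt, nchar);
    for (int t = 0; t < nt; ++t) {
        IntegerMatrix edge = edges[t];
        int N = 0;
        for (int i = 0; i < edge.nrow(); ++i)
            N = std::max(N, std::max(edge(i, 0), edge(i, 1)));
        Oriented o = orient_tree(edge, N, ntip + 1);
        std::vector<int> down((size_t)N * nchar, 0);
        IntegerVector steps(nchar);
        hartigan_down(o, ntip, tip_state, down, steps, nchar, N);
        for (int c = 0; c < nchar; ++c) out(t, c) = steps[c];
    }
    return out;
}
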