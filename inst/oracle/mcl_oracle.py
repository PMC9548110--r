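#!/usr/bin/env python
"""Independent Markov-clustering oracle used by the test suite.

Reads a whitespace-delimited edge list (node_a node_b weight) on stdin,
runs dense MCL with the same numeric policy as the R implementation
(self-loop = max incident weight, column-stochastic, expansion power 2,
inflation + renormalise, prune < 1e-6, stop when max change < 1e-8 or 200
iterations, per connected component) and prints one cluster per line as
tab-separated node names. Written against numpy only, independently of the
R code path it checks.
"""
import sys

import numpy as np


def mcl(adj, inflation, prune=1e-6, tol=1e-8, max_iter=200):
    n = adj.shape[0]
    m = adj.astype(float).copy()
    loops = m.max(axis=1)
    loops[loops == 0] = 1.0
    np.fill_diagonal(m, loops)
    m = m / m.sum(axis=0, keepdims=True)
    for _ in range(max_iter):
        m2 = m @ m
        m2 = m2 ** inflation
        m2[m2 < prune] = 0.0
        cs = m2.sum(axis=0, keepdims=True)
        cs[cs == 0] = 1.0
        m2 = m2 / cs
        delta = np.abs(m2 - m).max()
        m = m2
        if delta < tol:
            break
    # attractor read-off with union-find
    eps = 1e-9
    parent = list(range(n))

    def find(i):
        while parent[i] != i:
            parent[i] = parent[parent[i]]
            i = parent[i]
        return i

    def union(i, j):
        ri, rj = find(i), find(j)
        if ri != rj:
            parent[max(ri, rj)] = min(ri, rj)

    attractors = [i for i in range(n) if m[i, i] > eps]
    if not attractors:
        attractors = [int(np.argmax(np.diag(m)))]
    for a in attractors:
        for j in np.nonzero(m[a] > eps)[0]:
            union(a, int(j))
    for j in range(n):
        col = m[:, j]
        if col.max() > eps:
            union(j, int(np.argmax(col)))
    roots = [find(i) for i in range(n)]
    clusters = {}
    for i, r in enumerate(roots):
        clusters.setdefault(r, []).append(i)
    return list(clusters.values())


def components(adj):
    n = adj.shape[0]
    seen = [False] * n
    for s in range(n):
        if seen[s]:
            continue
        stack, comp = [s], []
        seen[s] = True
        while stack:
            v = stack.pop()
            comp.append(v)
            for w in np.nonzero(adj[v] > 0)[0]:
                if not seen[w]:
                    seen[w] = True
                    stack.append(int(w))
        yield comp


def main():
    inflation = float(sys.argv[1]) if len(sys.argv) > 1 else 2.0
    edges = []
    nodes = {}
    for line in sys.stdin:
        parts = line.split()
        if len(parts) < 3:
            continue
        a, b, w = parts[0], parts[1], float(parts[2])
        for x in (a, b):
            if x not in nodes:
                nodes[x] = len(nodes)
        edges.append((nodes[a], nodes[b], w))
    names = [None] * len(nodes)
    for k, v in nodes.items():
        names[v] = k
    n = len(nodes)
    adj = np.zeros((n, n))
    for a, b, w in edges:
        adj[a, b] = adj[b, a] = w
    out = []
    for comp in components(adj):
        sub = adj[np.ix_(comp, comp)]
        for cl in mcl(sub, inflation):
            out.append(sorted(names[comp[i]] for i in cl))
    out.sort()
    for cl in out:
        print("\t".join(cl))


if __name__ == "__main__":
    main()
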