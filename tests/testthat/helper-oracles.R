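# Independent oracles and shared fixtures. The oracles deliberately use
# different algorithms than the package (plain-matrix BFS, per-column loops,
# spanning-tree LP enumeration) so they can arbitrate its results.

# graph neighborhood by BFS on a dense 0/1 matrix
bfsNeighborhood <- function(Adense, center, radius) {
    reached <- logical(nrow(Adense))
    reached[center] <- TRUE
    frontier <- center
    d <- 0L
    while (d < radius && length(frontier)) {
        nb <- unique(unlist(lapply(frontier, function(v)
            which(Adense[v, ] != 0))))
        nb <- nb[!reached[nb]]
        reached[nb] <- TRUE
        frontier <- nb
        d <- d + 1L
    }
    sort(which(reached))
}

# localizer by explicit per-column loop
localizerLoop <- function(P, Q, L) {
    vapply(seq_len(ncol(L)), function(j) {
        v <- Q %*% L[, j]
        sum((P %*% v)^2) / sum(v^2)
    }, numeric(1))
}

# exact transportation optimum by enumerating spanning trees of K_{m,n}:
# every basic feasible solution of the transportation polytope is supported
# on a spanning tree; the tree flow is unique and linear, so the optimum is
# the cheapest feasible tree flow.
emdOracle <- function(a, b, cost) {
    m <- length(a); n <- length(b)
    edges <- expand.grid(i = seq_len(m), j = seq_len(n))
    nE <- nrow(edges)
    nNodes <- m + n
    best <- Inf
    for (sel in utils::combn(nE, nNodes - 1L, simplify = FALSE)) {
        ## check the selected edges form a spanning tree of the bipartite graph
        inc <- matrix(0, nNodes, length(sel))
        for (e in seq_along(sel)) {
            inc[edges$i[sel[e]], e] <- 1
            inc[m + edges$j[sel[e]], e] <- 1
        }
        if (qr(inc)$rank != nNodes - 1L) next
        ## unique flow on the tree: solve the balance equations
        rhs <- c(a, b)
        fl <- tryCatch(qr.solve(inc[-1L, , drop = FALSE], rhs[-1L]),
                       error = function(e) NULL)
        if (is.null(fl)) next
        if (any(fl < -1e-9)) next
        cc <- sum(fl * cost[cbind(edges$i[sel], edges$j[sel])])
        if (cc < best) best <- cc
    }
    best
}

# small path-graph source space embedded on a line (spacing in mm)
pathSpace <- function(n, spacing = 10) {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) A[i, i + 1L] <- A[i + 1L, i] <- 1
    sourceSpace(cbind(seq_len(n) * spacing, 0, 0), A,
                checkConnected = FALSE)
}

# star graph: center 1, leaves 2..(k+1)
starSpace <- function(nLeaves, spacing = 10) {
    n <- nLeaves + 1L
    A <- matrix(0, n, n)
    A[1, 2:n] <- A[2:n, 1] <- 1
    pos <- rbind(c(0, 0, 0),
                 cbind(spacing * cos(2 * pi * seq_len(nLeaves) / nLeaves),
                       spacing * sin(2 * pi * seq_len(nLeaves) / nLeaves), 0))
    sourceSpace(pos, A, checkConnected = FALSE)
}

# cached synthetic forwards (built once per test run)
.fixtureCache <- new.env()

smallForward <- function() {
    if (is.null(.fixtureCache$small)) {
        syn <- synthesizeSourceSpace(2, 70, seed = 5)   # 64 x 162
        .fixtureCache$small <- forwardModel(syn$space, syn$lead, maxOrder = 8)
    }
    .fixtureCache$small
}

benchForward <- function() {
    if (is.null(.fixtureCache$bench)) {
        syn <- synthesizeSourceSpace(3, 70, seed = 11)  # 64 x 642
        .fixtureCache$bench <- forwardModel(syn$space, syn$lead, maxOrder = 8)
    }
    .fixtureCache$bench
}

# coherent noiseless data from given topographies with independent smooth
# time courses
noiselessData <- function(topos, nT = 20, seed = 1) {
    set.seed(seed)
    tcs <- replicate(ncol(topos), coloredTimeCourse(nT, 1))
    topos %*% t(tcs)
}
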