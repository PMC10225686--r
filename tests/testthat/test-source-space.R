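test_that("buildAdjacency encodes triangle co-membership", {
    A <- buildAdjacency(list(c(0, 1, 2)), 3)
    expect_equal(as.matrix(A), matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3),
                 ignore_attr = TRUE)

    expect_equal(sum(buildAdjacency(list(), 4)), 0)
    expect_equal(dim(buildAdjacency(list(), 4)), c(4L, 4L))

    A2 <- buildAdjacency(list(c(0, 1, 2), c(1, 2, 3)), 4)
    ## edges {01, 02, 12, 13, 23}; degree sequence (2, 3, 3, 2)
    expect_equal(as.numeric(Matrix::rowSums(A2)), c(2, 3, 3, 2))
    expect_equal(sum(A2) / 2, 5)
    expect_true(Matrix::isSymmetric(A2))
    expect_equal(sum(Matrix::diag(A2)), 0)

    expect_error(buildAdjacency(list(c(0, 1, 4)), 4), "out of range")
    expect_error(buildAdjacency(list(c(0, 1)), 4), "exactly 3")
})

test_that("adjacency matches pairwise co-membership enumeration on random meshes", {
    set.seed(42)
    for (rep in 1:3) {
        nV <- 30L
        tri <- lapply(1:40, function(i) sample.int(nV, 3L) - 1L)
        A <- as.matrix(buildAdjacency(tri, nV))
        oracle <- matrix(0, nV, nV)
        for (tr in tri)
            for (pair in list(tr[1:2], tr[2:3], tr[c(1, 3)])) {
                oracle[pair[1] + 1, pair[2] + 1] <- 1
                oracle[pair[2] + 1, pair[1] + 1] <- 1
            }
        diag(oracle) <- 0
        expect_equal(A, oracle, ignore_attr = TRUE)
    }
})

test_that("icosphere meshes have the expected vertex counts and degrees", {
    s0 <- synthesizeSourceSpace(0, 70, seed = 1)
    expect_equal(nDipoles(s0$space), 12L)
    expect_true(all(Matrix::rowSums(adjacency(s0$space)) == 5))
    expect_equal(nDipoles(synthesizeSourceSpace(1, 70, seed = 1)$space), 42L)
    s2 <- synthesizeSourceSpace(2, 70, seed = 1)
    expect_equal(nDipoles(s2$space), 162L)
    expect_equal(dim(gain(s2$lead)), c(64L, 162L))
    ## all dipoles on the requested sphere
    expect_equal(sqrt(rowSums(positions(s2$space)^2)),
                 rep(70, 162), tolerance = 1e-10, ignore_attr = TRUE)
    ## deterministic given seed
    s2b <- synthesizeSourceSpace(2, 70, seed = 1)
    expect_identical(gain(s2$lead), gain(s2b$lead))
    expect_false(identical(gain(s2$lead),
                           gain(synthesizeSourceSpace(2, 70, seed = 2)$lead)))
})

test_that("smoothness dictionary: identity first order, L unchanged", {
    fwd <- smallForward()
    d1 <- buildSmoothnessDictionary(fwd@lead, fwd@space, maxOrder = 1)
    expect_equal(maxOrder(d1), 1L)
    expect_equal(as.matrix(operators(d1)[[1]]), diag(nDipoles(fwd@space)),
                 ignore_attr = TRUE)
    expect_equal(smoothedGains(d1)[[1]], gain(fwd@lead), ignore_attr = TRUE)
})

test_that("patch supports equal graph neighborhoods of radius k-1", {
    ## path graph 1-2-3, order 2: middle column covers all 3, ends cover 2
    sp <- pathSpace(3)
    lead <- leadField(matrix(rnorm(2 * 3), 2, 3))
    dict <- buildSmoothnessDictionary(lead, sp, maxOrder = 2)
    G2 <- as.matrix(operators(dict)[[2]])
    expect_equal(sum(G2[, 2] > 0), 3)
    expect_equal(sum(G2[, 1] > 0), 2)
    expect_equal(sum(G2[, 3] > 0), 2)

    ## star graph, 5 leaves: center column of order 2 has 6 positive
    ## entries summing to one
    st <- starSpace(5)
    leadS <- leadField(matrix(rnorm(2 * 6), 2, 6))
    dictS <- buildSmoothnessDictionary(leadS, st, maxOrder = 2)
    colC <- as.numeric(operators(dictS)[[2]][, 1])
    expect_equal(sum(colC > 0), 6)
    expect_equal(sum(colC), 1)

    ## BFS oracle on an icosphere for every order
    fwd <- smallForward()
    Adense <- as.matrix(adjacency(fwd@space))
    dict <- fwd@dictionary
    set.seed(3)
    for (center in sample.int(nDipoles(fwd@space), 5)) {
        for (k in c(2, 4, 8)) {
            support <- which(as.numeric(operators(dict)[[k]][, center]) > 0)
            expect_equal(support, bfsNeighborhood(Adense, center, k - 1))
        }
    }
})

test_that("operator columns are stochastic and supports grow monotonically", {
    fwd <- smallForward()
    dict <- fwd@dictionary
    p <- nDipoles(fwd@space)
    for (k in seq_len(maxOrder(dict))) {
        G <- operators(dict)[[k]]
        expect_true(all(G@x >= 0))
        expect_equal(as.numeric(Matrix::colSums(G)), rep(1, p),
                     tolerance = 1e-12)
        ## L_k = L G_k
        expect_equal(smoothedGains(dict)[[k]],
                     as.matrix(gain(fwd@lead) %*% G), ignore_attr = TRUE,
                     tolerance = 1e-12)
        if (k > 1) {
            Gprev <- operators(dict)[[k - 1]]
            for (j in c(1L, 50L, 101L))
                expect_true(all(which(Gprev[, j] > 0) %in%
                                which(G[, j] > 0)))
        }
    }
})

test_that("orders beyond the graph diameter cover the whole graph", {
    sp <- pathSpace(4)   # diameter 3
    lead <- leadField(matrix(rnorm(2 * 4), 2, 4))
    dict <- buildSmoothnessDictionary(lead, sp, maxOrder = 5)
    expect_true(all(as.matrix(operators(dict)[[4]]) > 0))  # radius 3
    expect_true(all(as.matrix(operators(dict)[[5]]) > 0))
})

test_that("literal operator variant uses the graph Laplacian", {
    sp <- pathSpace(4)
    lead <- leadField(matrix(rnorm(3 * 4), 3, 4))
    dict <- buildSmoothnessDictionary(lead, sp, maxOrder = 3,
                                      operatorType = "literal")
    A <- as.matrix(adjacency(sp))
    Lap <- diag(rowSums(A)) - A
    expect_equal(as.matrix(operators(dict)[[2]]), Lap, ignore_attr = TRUE)
    expect_equal(as.matrix(operators(dict)[[3]]), Lap %*% A,
                 ignore_attr = TRUE)
})

test_that("dimension mismatches and bad inputs are rejected", {
    sp <- pathSpace(3)
    lead <- leadField(matrix(rnorm(2 * 4), 2, 4))  # 4 dipoles vs 3
    expect_error(buildSmoothnessDictionary(lead, sp, 2), "dipole counts")
    expect_error(buildSmoothnessDictionary(leadField(matrix(rnorm(6), 2, 3)),
                                           sp, 0), "maxOrder")
    expect_error(leadField(matrix(0, 2, 3)), "all-zero")
    expect_warning(sourceSpace(matrix(rnorm(12), 4, 3),
                               rbind(cbind(matrix(c(0, 1, 1, 0), 2), 0, 0),
                                     cbind(0, 0, matrix(c(0, 1, 1, 0), 2)))),
                   "not connected")
})

test_that("source spaces, leadfields and forwards round-trip through disk", {
    fwd <- smallForward()
    tmp <- withr::local_tempdir()
    prefix <- file.path(tmp, "space")
    writeSourceSpace(fwd@space, prefix)
    sp2 <- readSourceSpace(prefix)
    expect_equal(positions(sp2), positions(fwd@space), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(as.matrix(adjacency(sp2)), as.matrix(adjacency(fwd@space)),
                 ignore_attr = TRUE)

    lf <- file.path(tmp, "lead.tsv")
    writeLeadField(fwd@lead, lf)
    l2 <- readLeadField(lf)
    expect_equal(gain(l2), gain(fwd@lead), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(channelNames(l2), channelNames(fwd@lead))

    fdir <- file.path(tmp, "fwd")
    writeForward(fwd, fdir)
    f2 <- readForward(fdir, maxOrder = 2)
    expect_equal(gain(f2@lead), gain(fwd@lead), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(nDipoles(f2@space), nDipoles(fwd@space))
})
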