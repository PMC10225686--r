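test_that("out-projector annihilates its topographies and is idempotent", {
    expect_equal(outProjector(matrix(0, 4, 0)), diag(4))
    expect_equal(outProjector(cbind(c(1, 0, 0))), diag(c(0, 1, 1)))

    set.seed(5)
    B <- matrix(rnorm(10), 5, 2)
    Q <- outProjector(B)
    expect_lt(max(abs(Q %*% B)), 1e-10)
    expect_lt(max(abs(Q %*% Q - Q)), 1e-10)
    expect_equal(Q, t(Q), tolerance = 1e-12)
    ## least-squares oracle for the pseudo-inverse: B B^+ = B (B'B)^-1 B'
    oracle <- diag(5) - B %*% solve(crossprod(B), t(B))
    expect_equal(Q, oracle, tolerance = 1e-10)
    ## rank-deficient B handled via SVD
    Bd <- cbind(B, B[, 1])
    Qd <- outProjector(Bd)
    expect_lt(max(abs(Qd %*% Bd)), 1e-9)
    expect_equal(sum(diag(Qd)), 3, tolerance = 1e-8)
})

test_that("TRAP recovers a noiseless single dipole exactly", {
    fwd <- smallForward()
    L <- gain(fwd@lead)
    j <- 42L
    M <- noiselessData(L[, j, drop = FALSE], seed = 2)
    cs <- trapMusic(M, fwd@lead)
    expect_equal(nrow(candidates(cs)), 1L)
    expect_equal(candidates(cs)$center_index, j)
    expect_equal(candidates(cs)$order, 1L)
    expect_gt(candidates(cs)$peak_score, 1 - 1e-8)
    ## exhaustive check: j is the unique localizer maximizer
    mod <- subspaceModel(M)
    mu <- localizer(mod@projector, NULL, L)
    expect_equal(which.max(mu), j)
    expect_lt(max(mu[-j]), mu[j])
})

test_that("TRAP recovers two noiseless dipoles and leaves no residual", {
    fwd <- smallForward()
    L <- gain(fwd@lead)
    idx <- c(30L, 140L)
    M <- noiselessData(L[, idx], seed = 3)
    cs <- trapMusic(M, fwd@lead)
    expect_setequal(candidates(cs)$center_index, idx)
    ## residual subspace explains no further dipole
    Q <- outProjector(cs)
    Cq <- Q %*% dataCovariance(M) %*% Q
    e <- eigen((Cq + t(Cq)) / 2, symmetric = TRUE)
    if (max(e$values) > 1e-10 * max(abs(Cq))) {
        P <- signalProjector(e$vectors, selectSignalRank(pmax(e$values, 0)))
        expect_lt(max(localizer(P, Q, L)), 0.975)
    }
    ## out-projection invariant
    expect_lt(max(abs(outProjector(cs) %*% topographies(cs))),
              1e-8 * max(abs(topographies(cs))))
})

test_that("pure-noise data yields no candidates at the default threshold", {
    fwd <- smallForward()
    set.seed(99)
    counts <- replicate(20, {
        M <- matrix(rnorm(64 * 20), 64, 20)
        length(trapMusic(M, fwd@lead))
    })
    expect_equal(median(counts), 0)
})

test_that("FLEX recovers a noiseless single dipole with order 1", {
    fwd <- smallForward()
    L <- gain(fwd@lead)
    j <- 77L
    M <- noiselessData(L[, j, drop = FALSE], seed = 4)
    cs <- flexMusic(M, fwd@dictionary)
    expect_equal(nrow(candidates(cs)), 1L)
    expect_equal(candidates(cs)$center_index, j)
    expect_equal(candidates(cs)$order, 1L)
})

test_that("FLEX recovers a noiseless order-2 patch with correct center and order", {
    fwd <- smallForward()
    dict <- fwd@dictionary
    cIdx <- 100L
    topo <- smoothedGains(dict)[[2]][, cIdx, drop = FALSE]
    M <- noiselessData(topo, seed = 5)
    cs <- flexMusic(M, dict)
    expect_equal(nrow(candidates(cs)), 1L)
    expect_equal(candidates(cs)$center_index, cIdx)
    expect_equal(candidates(cs)$order, 2L)
    expect_gt(candidates(cs)$peak_score, 1 - 1e-8)
    ## exhaustive (k, p) oracle: the patch topography attains the global
    ## maximum and no single-dipole column does
    mod <- subspaceModel(M)
    best <- vapply(smoothedGains(dict), function(G)
        max(localizer(mod@projector, NULL, G)), numeric(1))
    mu2 <- localizer(mod@projector, NULL, smoothedGains(dict)[[2]])
    expect_equal(mu2[cIdx], max(best), tolerance = 1e-10)
    expect_lt(best[1], mu2[cIdx] - 1e-8)
})

test_that("FLEX separates a single dipole from an order-3 patch", {
    fwd <- smallForward()
    dict <- fwd@dictionary
    L <- gain(fwd@lead)
    jSingle <- 15L
    cPatch <- 130L
    topos <- cbind(L[, jSingle], smoothedGains(dict)[[3]][, cPatch])
    M <- noiselessData(topos, seed = 6)
    cs <- flexMusic(M, dict)
    df <- candidates(cs)
    expect_equal(nrow(df), 2L)
    expect_setequal(df$center_index, c(jSingle, cPatch))
    expect_equal(df$order[df$center_index == jSingle], 1L)
    expect_equal(df$order[df$center_index == cPatch], 3L)
})

test_that("FLEX with a depth-1 dictionary reproduces RAP-MUSIC exactly", {
    fwd <- smallForward()
    dict1 <- buildSmoothnessDictionary(fwd@lead, fwd@space, maxOrder = 1)
    set.seed(7)
    L <- gain(fwd@lead)
    clean <- noiselessData(L[, c(25, 90, 155)], seed = 7)
    M <- addNoise(clean, 20)$noisy
    c1 <- flexMusic(M, dict1)
    c2 <- rapMusic(M, fwd@lead)
    expect_identical(candidates(c1), candidates(c2))
    expect_identical(stopReason(c1), stopReason(c2))
})

test_that("FLEX does not inflate single dipoles into patches at high SNR", {
    fwd <- smallForward()
    L <- gain(fwd@lead)
    set.seed(7)
    inflated <- 0L
    for (r in 1:50) {
        j <- sample.int(ncol(L), 1)
        clean <- L[, j, drop = FALSE] %*% t(coloredTimeCourse(20, 1))
        M <- addNoise(clean, 100)$noisy
        cs <- flexMusic(M, fwd@dictionary)
        if (any(candidates(cs)$order > 1)) inflated <- inflated + 1L
    }
    expect_gte(50 - inflated, 48)   # >= 95% of runs stay at order 1
})

test_that("wMNE reconstruction satisfies its limiting cases", {
    ## orthonormal-row leadfield, S = I, vanishing ridge: J -> L' M
    set.seed(8)
    L <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:4]
    lead <- leadField(t(L))            # 4 x 6, orthonormal rows
    M <- matrix(rnorm(4 * 5), 4, 5)
    est <- wmneReconstruct(Matrix::Diagonal(6), lead, M, ridge = 1e-14)
    expect_equal(currents(est), t(gain(lead)) %*% M, tolerance = 1e-6)

    ## zero data gives a zero estimate
    est0 <- wmneReconstruct(Matrix::Diagonal(6), lead, matrix(0, 4, 5))
    expect_equal(currents(est0), matrix(0, 6, 5))

    ## all-zero source covariance warns and returns zeros
    expect_warning(estZ <- wmneReconstruct(Matrix::Diagonal(6, 0), lead, M),
                   "all-zero")
    expect_equal(currents(estZ), matrix(0, 6, 5))
})

test_that("wMNE fits noiseless data supported on the source covariance", {
    fwd <- smallForward()
    L <- gain(fwd@lead)
    support <- c(40L, 41L, 90L)
    J <- matrix(0, ncol(L), 20)
    set.seed(9)
    for (s in support) J[s, ] <- coloredTimeCourse(20, 1)
    M <- L %*% J
    S <- numeric(ncol(L)); S[support] <- 1
    est <- wmneReconstruct(Matrix::Diagonal(ncol(L), S), fwd@lead, M,
                           ridge = 1e-12)
    fit <- L %*% currents(est)
    expect_lt(sqrt(sum((fit - M)^2)) / sqrt(sum(M^2)), 1e-6)
    ## rows outside the support are exactly zero
    expect_true(all(currents(est)[-support, ] == 0))
})

test_that("solveInverse returns a zero estimate when nothing is found", {
    fwd <- smallForward()
    set.seed(10)
    M <- matrix(rnorm(64 * 20), 64, 20)   # pure noise
    est <- solveInverse(M, fwd, method = "flex")
    expect_equal(dim(currents(est)), c(162L, 20L))
    expect_equal(sum(abs(currents(est))), 0)
    expect_equal(stopReason(est@candidateSet), "below_threshold")
})

test_that("one-shot MUSIC flags the true dipole and respects the criterion", {
    fwd <- smallForward()
    L <- gain(fwd@lead)
    j <- 60L
    M <- noiselessData(L[, j, drop = FALSE], seed = 11)
    res <- musicOneshot(M, fwd@lead, criterion = 0.95)
    expect_true(res$active[j])
    expect_equal(res$score[j], 1, tolerance = 1e-10)
    ## data equal to a gain column scores exactly one
    res2 <- musicOneshot(L[, j, drop = FALSE], fwd@lead)
    expect_equal(res2$score[j], 1, tolerance = 1e-10)
    ## unattainable criterion on noisy data gives an empty mask
    set.seed(11)
    noisy <- addNoise(M, 5)$noisy
    res3 <- musicOneshot(noisy, fwd@lead, criterion = 1 + 1e-9)
    expect_false(any(res3$active))
})

test_that("estimates serialize with a JSON candidate sidecar", {
    fwd <- smallForward()
    L <- gain(fwd@lead)
    M <- noiselessData(L[, 5, drop = FALSE], seed = 12)
    est <- solveInverse(M, fwd, method = "trap")
    tmp <- withr::local_tempdir()
    paths <- writeEstimate(est, file.path(tmp, "est"))
    expect_true(all(file.exists(paths)))
    side <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
    expect_equal(side$candidates$center_index, 5L)
    expect_equal(readRDS(paths[1]), currents(est))
})
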