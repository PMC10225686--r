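test_that("local maxima respect the graph, the floor and the plateau rule", {
    sp <- pathSpace(7)
    v <- c(0, 0, 0, 5, 0, 0, 0)
    expect_equal(localMaxima(v, sp), 4L)

    ## two equal peaks separated by a valley: both reported
    v2 <- c(0, 5, 1, 1, 5, 0, 0)
    expect_equal(localMaxima(v2, sp), c(2L, 5L))

    ## uniform plateau on a connected graph: single representative
    expect_equal(localMaxima(rep(3, 7), sp), 1L)

    ## floor removes low secondary peaks
    v3 <- c(0, 0.4, 0, 0, 10, 0, 0)
    expect_equal(localMaxima(v3, sp, floorFrac = 0.1), 5L)
    expect_equal(localMaxima(v3, sp, floorFrac = 0.01), c(2L, 5L))

    expect_equal(localMaxima(rep(0, 7), sp), integer(0))
    expect_error(localMaxima(c(-1, rep(0, 6)), sp), "nonnegative")
})

test_that("mean localization error reproduces hand-computed distances", {
    sp <- pathSpace(4)   # positions (10,0,0) ... (40,0,0)
    J <- matrix(0, 4, 2); J[2, ] <- 1
    expect_equal(meanLocalizationError(J, J, sp), 0)

    ## 3-4-5 triangle: true at origin, estimate at (3, 4, 0)
    pos <- rbind(c(0, 0, 0), c(3, 4, 0))
    sp2 <- sourceSpace(pos, matrix(c(0, 1, 1, 0), 2),
                       checkConnected = FALSE)
    truth <- matrix(c(1, 0), 2, 1)
    est <- matrix(c(0, 1), 2, 1)
    expect_equal(meanLocalizationError(truth, est, sp2), 5)

    ## two true maxima vs three estimated: brute-force mean of row minima
    sp7 <- pathSpace(7)
    truth2 <- matrix(0, 7, 1); truth2[c(2, 6), ] <- c(2, 3)
    est2 <- matrix(0, 7, 1); est2[c(1, 4, 7), ] <- c(1, 2, 1.5)
    tMax <- c(2, 6); eMax <- c(1, 4, 7)
    pos7 <- positions(sp7)
    tab <- outer(tMax, eMax, function(a, b) abs(pos7[a, 1] - pos7[b, 1]))
    expect_equal(meanLocalizationError(truth2, est2, sp7),
                 mean(apply(tab, 1, min)))

    ## empty estimate: penalized with the space diameter
    expect_equal(meanLocalizationError(truth2, matrix(0, 7, 1), sp7),
                 max(dist(pos7)))
})

test_that("EMD matches the spanning-tree LP oracle on small instances", {
    sp <- pathSpace(4)
    J <- matrix(0, 4, 1); J[1, ] <- 1
    expect_equal(earthMoversDistance(J, J, sp), 0)

    ## unit mass moved across 10 mm
    J2 <- matrix(0, 4, 1); J2[2, ] <- 3        # scale must not matter
    expect_equal(earthMoversDistance(J, J2, sp), 10)

    set.seed(11)
    pos <- matrix(runif(12, 0, 50), 4, 3)
    spR <- sourceSpace(pos, matrix(1, 4, 4) - diag(4),
                       checkConnected = FALSE)
    D <- as.matrix(dist(pos))
    for (rep in 1:5) {
        a <- runif(4); a <- a / sum(a)
        b <- runif(4); b <- b / sum(b)
        got <- flexMUSIC:::.emdTransport(a, b, D)
        expect_equal(got, emdOracle(a, b, D), tolerance = 1e-8)
    }
})

test_that("EMD behaves as a metric on random instances", {
    set.seed(12)
    pos <- matrix(runif(24, 0, 100), 8, 3)
    sp <- sourceSpace(pos, matrix(1, 8, 8) - diag(8),
                      checkConnected = FALSE)
    mkJ <- function() {
        J <- matrix(runif(8), 8, 1)
        J[sample.int(8, 3)] <- 0
        J
    }
    for (rep in 1:5) {
        A <- mkJ(); B <- mkJ(); C <- mkJ()
        dab <- earthMoversDistance(A, B, sp)
        dba <- earthMoversDistance(B, A, sp)
        dac <- earthMoversDistance(A, C, sp)
        dcb <- earthMoversDistance(C, B, sp)
        expect_gte(dab, 0)
        expect_equal(dab, dba, tolerance = 1e-8)
        expect_lte(dab, dac + dcb + 1e-8)
    }
    ## unit-mass normalization makes the metric scale-free
    A <- mkJ(); B <- mkJ()
    expect_equal(earthMoversDistance(A, B * 12, sp),
                 earthMoversDistance(A, B, sp), tolerance = 1e-8)
    expect_error(earthMoversDistance(matrix(0, 8, 1), mkJ(), sp),
                 "all-zero")
})

test_that("mean squared error averages entrywise differences", {
    J <- matrix(0, 5, 4)
    expect_equal(meanSquaredError(J, J), 0)
    expect_equal(meanSquaredError(J, J + 1), 1)
    set.seed(13)
    A <- matrix(rnorm(20), 5, 4); B <- matrix(rnorm(20), 5, 4)
    acc <- 0
    for (i in 1:5) for (j in 1:4) acc <- acc + (A[i, j] - B[i, j])^2
    expect_equal(meanSquaredError(A, B), acc / 20, tolerance = 1e-12)
    expect_equal(meanSquaredError(A, B, type = "norm"), acc,
                 tolerance = 1e-12)
})

test_that("sparsity equals the L1 norm of L2-normalized columns", {
    oneHot <- diag(4)[, 1:3]
    expect_equal(sparsityL1(oneHot), 1)
    expect_equal(sparsityL1(matrix(1, 16, 2)), 4)   # sqrt(16)
    set.seed(14)
    X <- matrix(rnorm(18), 6, 3)
    oracle <- mean(vapply(1:3, function(j)
        sum(abs(X[, j])) / sqrt(sum(X[, j]^2)), numeric(1)))
    expect_equal(sparsityL1(X), oracle, tolerance = 1e-12)
    ## invariant to global rescaling; zero columns skipped
    expect_equal(sparsityL1(X * 37.5), sparsityL1(X), tolerance = 1e-12)
    expect_equal(sparsityL1(cbind(X, 0)), sparsityL1(X), tolerance = 1e-12)
    expect_error(sparsityL1(matrix(0, 4, 2)), "all columns")
})

test_that("benchmark aggregates behave for oracle and failing solvers", {
    fwd <- smallForward()
    cfg <- simulationConfig(nSamples = 6, nSourcesRange = c(1, 3),
                            extentOrders = 0:2, seed = 51)
    ds <- generateDataset(fwd@space, fwd@lead, fwd@dictionary, cfg)

    oracleSolver <- function(data, forward) currents(attr(data, "sample"))
    ## attach ground truth so the oracle can return it
    dsO <- lapply(ds, function(s) {
        M <- sensorData(s)
        attr(M, "sample") <- s
        s@sensorData <- M
        s
    })
    attr(dsO, "config") <- attr(ds, "config")

    rep1 <- runBenchmark(dsO, fwd, list(oracle = oracleSolver))
    expect_equal(rep1@medians$mle_mm, 0)
    expect_lt(rep1@medians$emd, 1e-6)
    expect_equal(rep1@medians$mse, 0, tolerance = 1e-12)
    expect_equal(rep1@sparsityCor$r, 1, tolerance = 1e-12)

    ## single sample, single solver: medians equal that sample's metrics
    rep2 <- suppressWarnings(runBenchmark(ds[1], fwd, "flex"))
    expect_equal(nrow(rep2@records), 1L)
    expect_equal(rep2@medians$mle_mm, rep2@records$mle_mm)

    ## an oracle dominates a real solver on every aggregate metric
    noisySolver <- function(data, forward) {
        J <- currents(attr(data, "sample"))
        J + matrix(rnorm(length(J), sd = 0.5 * max(abs(J))), nrow(J))
    }
    rep3 <- runBenchmark(dsO, fwd,
                         list(oracle = oracleSolver, noisy = noisySolver))
    m <- rep3@medians
    expect_lte(m$mle_mm[m$solver == "oracle"], m$mle_mm[m$solver == "noisy"])
    expect_lte(m$emd[m$solver == "oracle"], m$emd[m$solver == "noisy"])
    expect_lte(m$mse[m$solver == "oracle"], m$mse[m$solver == "noisy"])

    ## a failing solver is recorded as missing, with a warning per sample
    bad <- function(data, forward) stop("boom")
    w <- capture_warnings(rep4 <- runBenchmark(ds[1:2], fwd,
                                               list(bad = bad)))
    expect_true(any(grepl("failed on sample", w)))
    expect_true(all(is.na(rep4@records$mle_mm)))

    ## unknown solver names are rejected by name
    expect_error(runBenchmark(ds, fwd, "eloreta"), "eloreta")
})
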