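#' @include AllGenerics.R
#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix Matrix Diagonal t isSymmetric diag colSums rowSums crossprod tcrossprod drop0 sparseMatrix
NULL

setClassUnion("MatrixOrNULL", c("matrix", "NULL"))

#' SourceSpace: discretized cortical source model
#'
#' Holds the dipole positions (mm) and the neighborhood structure of the
#' source mesh: a binary symmetric adjacency matrix in which entry (i, j) is 1
#' iff dipoles i and j share a mesh edge. All graph-based notions of source
#' extent (patch radius, local maxima) are defined on this graph.
#'
#' @slot positions numeric p x 3 matrix of dipole coordinates in mm.
#' @slot adjacency sparse p x p binary symmetric matrix with zero diagonal.
#'
#' @seealso [sourceSpace()], [buildAdjacency()], [synthesizeSourceSpace()]
#' @export
setClass("SourceSpace",
    slots = c(positions = "matrix", adjacency = "Matrix"))

setValidity("SourceSpace", function(object) {
    p <- nrow(object@positions)
    A <- object@adjacency
    msg <- character()
    if (ncol(object@positions) != 3L)
        msg <- c(msg, "positions must have 3 columns (x, y, z in mm)")
    if (!all(is.finite(object@positions)))
        msg <- c(msg, "positions must be finite")
    if (nrow(A) != p || ncol(A) != p)
        msg <- c(msg, "adjacency dimensions must match number of positions")
    else {
        if (!Matrix::isSymmetric(A, tol = 0))
            msg <- c(msg, "adjacency must be symmetric")
        if (any(Matrix::diag(A) != 0))
            msg <- c(msg, "adjacency must have zero diagonal")
        x <- A@x
        if (length(x) && !all(x %in% c(0, 1)))
            msg <- c(msg, "adjacency entries must be 0 or 1")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SourceSpace
#'
#' @param positions numeric p x 3 matrix of dipole positions in mm.
#' @param adjacency p x p binary symmetric neighbor indicator (dense or
#'   sparse); coerced to a sparse matrix.
#' @param checkConnected if TRUE (default), warn when the adjacency graph is
#'   not connected. Disconnected spaces are allowed but patch growing cannot
#'   cross components.
#' @return a \linkS4class{SourceSpace}.
#' @examples
#' A <- buildAdjacency(list(c(0, 1, 2)), 3)
#' ss <- sourceSpace(diag(3), A)
#' nDipoles(ss)
#' @export
sourceSpace <- function(positions, adjacency, checkConnected = TRUE) {
    positions <- as.matrix(positions)
    storage.mode(positions) <- "double"
    A <- as(as(as(adjacency, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    A <- Matrix::drop0(A)
    obj <- new("SourceSpace", positions = positions, adjacency = A)
    if (checkConnected && nrow(positions) > 1L &&
        !.graphConnected(A))
        warning("source space graph is not connected")
    obj
}

## BFS-style connectivity check on a sparse adjacency
.graphConnected <- function(A) {
    p <- nrow(A)
    reached <- logical(p)
    frontier <- 1L
    reached[1L] <- TRUE
    while (length(frontier)) {
        nb <- unique(.neighborList(A, frontier))
        nb <- nb[!reached[nb]]
        reached[nb] <- TRUE
        frontier <- nb
    }
    all(reached)
}

## indices of all neighbors of a set of vertices (with duplicates removed)
.neighborList <- function(A, idx) {
    ## column slices of a CsparseMatrix: rows with nonzero entries
    out <- integer(0)
    for (j in idx) {
        r <- (A@p[j] + 1L):A@p[j + 1L]
        if (A@p[j + 1L] > A@p[j]) out <- c(out, A@i[r] + 1L)
    }
    unique(out)
}

#' @describeIn SourceSpace number of dipoles p.
#' @param x a SourceSpace.
#' @export
setMethod("nDipoles", "SourceSpace", function(x) nrow(x@positions))

#' @describeIn SourceSpace dipole positions (p x 3, mm).
#' @export
setMethod("positions", "SourceSpace", function(x) x@positions)

#' @describeIn SourceSpace sparse binary adjacency matrix.
#' @export
setMethod("adjacency", "SourceSpace", function(x) x@adjacency)

setMethod("show", "SourceSpace", function(object) {
    p <- nDipoles(object)
    nEdges <- sum(object@adjacency != 0) / 2
    cat("SourceSpace with", p, "dipoles and", nEdges, "edges\n")
})

#' LeadField: gain matrix of the forward model
#'
#' Linear map from dipole current amplitudes (nAm) to sensor measurements
#' (microvolts): a q x p matrix whose column j is the sensor topography of a
#' unit current at dipole j. Dipole orientations are fixed (perpendicular to
#' the cortical surface), so each dipole contributes a single column.
#'
#' @slot gain numeric q x p matrix.
#' @slot channelNames character vector of q sensor labels.
#'
#' @seealso [leadField()], [synthesizeSourceSpace()]
#' @export
setClass("LeadField",
    slots = c(gain = "matrix", channelNames = "character"))

setValidity("LeadField", function(object) {
    msg <- character()
    L <- object@gain
    if (!all(is.finite(L)))
        msg <- c(msg, "gain entries must be finite")
    if (nrow(L) < 2L)
        msg <- c(msg, "need at least 2 channels")
    if (any(colSums(L^2) == 0))
        msg <- c(msg, "gain must not contain all-zero columns")
    if (length(object@channelNames) != nrow(L))
        msg <- c(msg, "channelNames length must equal number of rows")
    if (length(msg)) msg else TRUE
})

#' Construct a LeadField
#'
#' @param gain numeric q x p gain matrix (sensors x dipoles).
#' @param channelNames optional character vector of q channel labels; defaults
#'   to \code{"CH001"}, ...
#' @return a \linkS4class{LeadField}.
#' @export
leadField <- function(gain, channelNames = NULL) {
    gain <- as.matrix(gain)
    storage.mode(gain) <- "double"
    if (is.null(channelNames))
        channelNames <- sprintf("CH%03d", seq_len(nrow(gain)))
    new("LeadField", gain = gain, channelNames = channelNames)
}

#' @describeIn LeadField the q x p gain matrix.
#' @param x a LeadField.
#' @export
setMethod("gain", "LeadField", function(x) x@gain)

#' @describeIn LeadField sensor labels.
#' @export
setMethod("channelNames", "LeadField", function(x) x@channelNames)

#' @describeIn LeadField number of sensors q.
#' @export
setMethod("nChannels", "LeadField", function(x) nrow(x@gain))

#' @describeIn LeadField number of dipoles p.
#' @export
setMethod("nDipoles", "LeadField", function(x) ncol(x@gain))

setMethod("show", "LeadField", function(object) {
    cat("LeadField:", nrow(object@gain), "channels x",
        ncol(object@gain), "dipoles\n")
})

#' SmoothnessDictionary: graph-smoothed leadfield family
#'
#' A family of smoothing operators G_1, ..., G_K on the source graph together
#' with the corresponding smoothed leadfields L_k = L G_k. Column j of G_k is
#' a nonnegative patch profile of graph radius k - 1 centered at dipole j and
#' summing to one, so L_k's column j is the sensor topography of a coherent
#' patch source of that extent. G_1 is the identity: single dipoles remain in
#' the candidate set.
#'
#' @slot operators list of K sparse p x p patch-profile matrices.
#' @slot smoothedGains list of K dense q x p smoothed gain matrices.
#' @slot maxOrder integer K.
#'
#' @seealso [buildSmoothnessDictionary()]
#' @export
setClass("SmoothnessDictionary",
    slots = c(operators = "list", smoothedGains = "list",
              maxOrder = "integer"))

setValidity("SmoothnessDictionary", function(object) {
    msg <- character()
    K <- object@maxOrder
    if (K < 1L) msg <- c(msg, "maxOrder must be >= 1")
    if (length(object@operators) != K || length(object@smoothedGains) != K)
        msg <- c(msg, "operator and gain lists must have length maxOrder")
    if (length(msg)) msg else TRUE
})

#' @describeIn SmoothnessDictionary list of patch-profile operators G_k.
#' @param x a SmoothnessDictionary.
#' @export
setMethod("operators", "SmoothnessDictionary", function(x) x@operators)

#' @describeIn SmoothnessDictionary list of smoothed gain matrices L_k.
#' @export
setMethod("smoothedGains", "SmoothnessDictionary", function(x) x@smoothedGains)

#' @describeIn SmoothnessDictionary largest smoothness order K.
#' @export
setMethod("maxOrder", "SmoothnessDictionary", function(x) x@maxOrder)

#' @describeIn SmoothnessDictionary number of dipoles p.
#' @export
setMethod("nDipoles", "SmoothnessDictionary",
    function(x) ncol(x@smoothedGains[[1L]]))

setMethod("show", "SmoothnessDictionary", function(object) {
    cat("SmoothnessDictionary: orders 1 ..", object@maxOrder,
        "over", ncol(object@smoothedGains[[1L]]), "dipoles\n")
})

#' SubspaceModel: eigendecomposition and signal-subspace selection
#'
#' Result of decomposing a sensor covariance matrix and selecting the number
#' of leading eigenvectors attributed to signal rather than noise. The signal
#' subspace projector is P_s = U_s U_s' with U_s the leading eigenvectors.
#'
#' @slot covariance q x q symmetric covariance.
#' @slot eigvecs q x q orthonormal eigenvector matrix (columns, decreasing
#'   eigenvalue order).
#' @slot eigvals length-q nonincreasing eigenvalues (negatives clipped at 0).
#' @slot signalRank selected signal-subspace dimension.
#' @slot epsilon relative eigenvalue-drop criterion used for the selection.
#' @slot projector q x q signal-subspace projector.
#'
#' @seealso [subspaceModel()], [selectSignalRank()], [signalProjector()]
#' @export
setClass("SubspaceModel",
    slots = c(covariance = "matrix", eigvecs = "matrix", eigvals = "numeric",
              signalRank = "integer", epsilon = "numeric",
              projector = "matrix"))

setValidity("SubspaceModel", function(object) {
    msg <- character()
    q <- nrow(object@covariance)
    tol <- 1e-8 * max(1, abs(object@eigvals[1L]))
    if (is.unsorted(-object@eigvals))
        msg <- c(msg, "eigvals must be nonincreasing")
    if (any(object@eigvals < -tol))
        msg <- c(msg, "eigvals must be nonnegative")
    if (object@signalRank < 1L || object@signalRank > q)
        msg <- c(msg, "signalRank must be in [1, q]")
    P <- object@projector
    if (max(abs(P %*% P - P)) > 1e-6)
        msg <- c(msg, "projector must be idempotent")
    if (abs(sum(diag(P)) - object@signalRank) > 1e-6)
        msg <- c(msg, "projector trace must equal signalRank")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SubspaceModel", function(object) {
    cat("SubspaceModel: q =", nrow(object@covariance),
        ", signal rank =", object@signalRank,
        ", epsilon =", object@epsilon, "\n")
})

#' CandidateSet: sources selected by a recursive MUSIC scan
#'
#' The ordered set of candidate sources selected across the recursions of
#' RAP-, TRAP- or FLEX-MUSIC, together with the algebraic state of the
#' recursion: the matrix B of selected topographies, the out-projector
#' Q = I - B B^+, and the accumulated diagonal source covariance S used by
#' the weighted minimum-norm reconstruction.
#'
#' @slot candidates data.frame with one row per selected source: columns
#'   \code{center_index} (1-based dipole index), \code{order} (smoothness
#'   order, 1 = single dipole), \code{peak_score} (localizer value at
#'   selection).
#' @slot topographies q x i matrix B of candidate topographies.
#' @slot patchWeights sparse p x i matrix; column i is the patch profile
#'   (the G_k column) of candidate i.
#' @slot outProjector q x q out-projection matrix Q.
#' @slot sourceCov sparse p x p diagonal source covariance S.
#' @slot stopReason one of \code{"below_threshold"}, \code{"max_iter"},
#'   \code{"rank_exhausted"}.
#'
#' @seealso [flexMusic()], [trapMusic()], [wmneReconstruct()]
#' @export
setClass("CandidateSet",
    slots = c(candidates = "data.frame", topographies = "matrix",
              patchWeights = "Matrix", outProjector = "matrix",
              sourceCov = "Matrix", stopReason = "character"))

setValidity("CandidateSet", function(object) {
    msg <- character()
    if (!all(c("center_index", "order", "peak_score") %in%
             colnames(object@candidates)))
        msg <- c(msg, "candidates must have center_index, order, peak_score")
    if (nrow(object@candidates) != ncol(object@topographies))
        msg <- c(msg, "one topography column per candidate required")
    if (nrow(object@candidates) &&
        (any(object@candidates$order < 1L) ||
         any(object@candidates$peak_score < 0) ||
         any(object@candidates$peak_score > 1 + 1e-8)))
        msg <- c(msg, "orders must be >= 1 and peak scores in [0, 1]")
    if (!object@stopReason %in%
        c("below_threshold", "max_iter", "rank_exhausted"))
        msg <- c(msg, "invalid stopReason")
    B <- object@topographies
    Q <- object@outProjector
    if (ncol(B) && max(abs(Q %*% B)) > 1e-6 * max(1, max(abs(B))))
        msg <- c(msg, "out-projector must annihilate selected topographies")
    if (length(msg)) msg else TRUE
})

#' @describeIn CandidateSet data.frame of selected candidates.
#' @param x a CandidateSet.
#' @export
setMethod("candidates", "CandidateSet", function(x) x@candidates)

#' @describeIn CandidateSet q x i matrix of candidate topographies B.
#' @export
setMethod("topographies", "CandidateSet", function(x) x@topographies)

#' @describeIn CandidateSet accumulated out-projector Q.
#' @export
setMethod("outProjector", "CandidateSet", function(x) x@outProjector)

#' @describeIn CandidateSet diagonal source covariance S.
#' @export
setMethod("sourceCov", "CandidateSet", function(x) x@sourceCov)

#' @describeIn CandidateSet why the recursion stopped.
#' @export
setMethod("stopReason", "CandidateSet", function(x) x@stopReason)

#' @describeIn CandidateSet number of selected candidates.
#' @param object a CandidateSet.
#' @export
setMethod("length", "CandidateSet", function(x) nrow(x@candidates))

setMethod("show", "CandidateSet", function(object) {
    n <- nrow(object@candidates)
    cat("CandidateSet with", n, "candidate(s); stop reason:",
        object@stopReason, "\n")
    if (n) {
        df <- object@candidates
        df$peak_score <- signif(df$peak_score, 4)
        print(utils::head(df, 10), row.names = FALSE)
        if (n > 10) cat("... and", n - 10, "more\n")
    }
})

#' SourceEstimate: reconstructed source current time courses
#'
#' @slot currents p x t matrix of estimated dipole currents (nAm).
#' @slot candidateSet the \linkS4class{CandidateSet} the reconstruction is
#'   based on.
#'
#' @seealso [wmneReconstruct()], [solveInverse()]
#' @export
setClass("SourceEstimate",
    slots = c(currents = "matrix", candidateSet = "CandidateSet"))

#' @describeIn SourceEstimate estimated p x t current matrix.
#' @param x a SourceEstimate.
#' @export
setMethod("currents", "SourceEstimate", function(x) x@currents)

#' @describeIn SourceEstimate provenance candidate set.
#' @export
setMethod("candidates", "SourceEstimate",
    function(x) x@candidateSet@candidates)

setMethod("show", "SourceEstimate", function(object) {
    cat("SourceEstimate:", nrow(object@currents), "dipoles x",
        ncol(object@currents), "time points;",
        sum(rowSums(abs(object@currents)) > 0), "active dipole(s)\n")
})

#' SimulationConfig: parameters of the synthetic ground-truth generator
#'
#' Encodes the simulation protocol: number of samples, per-sample source
#' count range, source extents (graph radius; 0 = single dipole), time-series
#' length, SNR range (amplitude ratio, sampled log-uniformly), temporal
#' smoothness exponent range for the 1/f^beta source spectra, per-source
#' amplitude range in nAm, and the RNG seed.
#'
#' @slot nSamples number of samples to simulate.
#' @slot nSourcesRange integer range (lo, hi) of simultaneous sources.
#' @slot extentOrders integer set of source extents as graph radii; 0 denotes
#'   a single dipole, r > 0 a patch covering all dipoles within graph
#'   distance r of the center.
#' @slot nTimepoints samples per time course.
#' @slot snrRange amplitude-SNR range; drawn log-uniformly.
#' @slot betaRange range of the spectral exponent beta.
#' @slot amplitudeRange per-source amplitude range (nAm).
#' @slot patchProfile "dictionary" (patch weights follow the smoothing
#'   operator column) or "uniform" (equal weights; model mismatch mode).
#' @slot seed integer RNG seed.
#'
#' @seealso [simulationConfig()], [generateDataset()]
#' @export
setClass("SimulationConfig",
    slots = c(nSamples = "integer", nSourcesRange = "integer",
              extentOrders = "integer", nTimepoints = "integer",
              snrRange = "numeric", betaRange = "numeric",
              amplitudeRange = "numeric", patchProfile = "character",
              seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
    if (length(object@nSourcesRange) != 2L ||
        any(object@nSourcesRange < 1L) ||
        object@nSourcesRange[1L] > object@nSourcesRange[2L])
        msg <- c(msg, "nSourcesRange must be a nonempty positive range")
    if (!length(object@extentOrders) || any(object@extentOrders < 0L))
        msg <- c(msg, "extentOrders must be nonnegative")
    if (object@nTimepoints < 2L) msg <- c(msg, "nTimepoints must be >= 2")
    if (length(object@snrRange) != 2L || any(object@snrRange <= 0) ||
        object@snrRange[1L] > object@snrRange[2L])
        msg <- c(msg, "snrRange must be a positive nonempty range")
    if (!object@patchProfile %in% c("dictionary", "uniform"))
        msg <- c(msg, "patchProfile must be 'dictionary' or 'uniform'")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults mirror the benchmark protocol: 1 to 10 simultaneous sources,
#' single dipoles (radius 0) and patches of radius 1 to 3, t = 20 time
#' points, amplitude SNR log-uniform in [0.1, 100].
#'
#' @param nSamples number of samples.
#' @param nSourcesRange integer range of simultaneous sources per sample.
#' @param extentOrders graph radii of sources; 0 = single dipole. When both 0
#'   and positive radii are present, half of the dataset is simulated with
#'   single dipoles and half with extended patches.
#' @param nTimepoints time points per sample.
#' @param snrRange amplitude-SNR range, sampled log-uniformly.
#' @param betaRange range of the 1/f^beta spectral exponent (uniform draw).
#' @param amplitudeRange per-source amplitude range in nAm (uniform draw).
#' @param patchProfile "dictionary" or "uniform" patch weighting.
#' @param seed RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nSamples = 1000L,
                             nSourcesRange = c(1L, 10L),
                             extentOrders = 0:3,
                             nTimepoints = 20L,
                             snrRange = c(0.1, 100),
                             betaRange = c(0, 2),
                             amplitudeRange = c(1, 10),
                             patchProfile = c("dictionary", "uniform"),
                             seed = 1L) {
    new("SimulationConfig",
        nSamples = as.integer(nSamples),
        nSourcesRange = as.integer(nSourcesRange),
        extentOrders = as.integer(sort(unique(extentOrders))),
        nTimepoints = as.integer(nTimepoints),
        snrRange = as.numeric(snrRange),
        betaRange = as.numeric(betaRange),
        amplitudeRange = as.numeric(amplitudeRange),
        patchProfile = match.arg(patchProfile),
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nSamples, "samples,",
        paste(object@nSourcesRange, collapse = "-"), "sources, extents {",
        paste(object@extentOrders, collapse = ", "), "}, t =",
        object@nTimepoints, ", SNR", paste(object@snrRange, collapse = "-"),
        ", seed", object@seed, "\n")
})

#' SimulatedSample: one ground-truth / sensor-data pair
#'
#' @slot currents p x t ground-truth current matrix J (nAm).
#' @slot sensorData q x t sensor matrix M = L J + noise.
#' @slot noise q x t additive noise matrix.
#' @slot trueCenters dipole indices of the simulated source centers.
#' @slot trueOrders graph radii of the simulated sources (0 = single dipole).
#' @slot snr realized amplitude SNR.
#' @slot beta spectral exponent of the source time courses.
#'
#' @export
setClass("SimulatedSample",
    slots = c(currents = "matrix", sensorData = "matrix", noise = "matrix",
              trueCenters = "integer", trueOrders = "integer",
              snr = "numeric", beta = "numeric"))

#' @describeIn SimulatedSample ground-truth currents J.
#' @param x a SimulatedSample.
#' @export
setMethod("currents", "SimulatedSample", function(x) x@currents)

#' @describeIn SimulatedSample sensor data M.
#' @export
setMethod("sensorData", "SimulatedSample", function(x) x@sensorData)

setMethod("show", "SimulatedSample", function(object) {
    cat("SimulatedSample:", length(object@trueCenters), "source(s), radii {",
        paste(object@trueOrders, collapse = ", "), "}, SNR",
        signif(object@snr, 3), ", beta", signif(object@beta, 3), "\n")
})

#' ForwardModel: source space, leadfield and smoothness dictionary
#'
#' Bundles the three ingredients every solver needs. The dictionary may be
#' built lazily with [buildSmoothnessDictionary()].
#'
#' @slot space a \linkS4class{SourceSpace}.
#' @slot lead a \linkS4class{LeadField}.
#' @slot dictionary a \linkS4class{SmoothnessDictionary}.
#'
#' @seealso [forwardModel()]
#' @export
setClass("ForwardModel",
    slots = c(space = "SourceSpace", lead = "LeadField",
              dictionary = "SmoothnessDictionary"))

setValidity("ForwardModel", function(object) {
    p1 <- nDipoles(object@space)
    p2 <- ncol(object@lead@gain)
    if (p1 != p2)
        return("source space and leadfield dipole counts differ")
    if (ncol(object@dictionary@smoothedGains[[1L]]) != p1)
        return("dictionary dipole count differs from source space")
    TRUE
})

#' Construct a ForwardModel
#'
#' @param space a \linkS4class{SourceSpace}.
#' @param lead a \linkS4class{LeadField} over the same dipoles.
#' @param dictionary optional \linkS4class{SmoothnessDictionary}; built with
#'   \code{maxOrder} smoothness orders when missing.
#' @param maxOrder dictionary depth used when \code{dictionary} is missing.
#' @return a \linkS4class{ForwardModel}.
#' @export
forwardModel <- function(space, lead, dictionary = NULL, maxOrder = 8L) {
    if (is.null(dictionary))
        dictionary <- buildSmoothnessDictionary(lead, space, maxOrder)
    new("ForwardModel", space = space, lead = lead, dictionary = dictionary)
}

setMethod("show", "ForwardModel", function(object) {
    cat("ForwardModel:", nChannels(object@lead), "channels,",
        nDipoles(object@space), "dipoles, dictionary depth",
        maxOrder(object@dictionary), "\n")
})

#' BenchmarkReport: aggregated solver evaluation
#'
#' @slot records per-sample, per-solver metric records.
#' @slot medians per-solver medians of each metric.
#' @slot sparsityCor per-solver Pearson correlation between true and
#'   estimated sparsity.
#' @slot strata list of stratified summaries (by SNR bin, by source count,
#'   by single/extended).
#'
#' @seealso [runBenchmark()]
#' @export
setClass("BenchmarkReport",
    slots = c(records = "data.frame", medians = "data.frame",
              sparsityCor = "data.frame", strata = "list"))

setMethod("show", "BenchmarkReport", function(object) {
    cat("BenchmarkReport over", nrow(object@records), "records\n")
    cat("Medians:\n")
    print(object@medians, row.names = FALSE)
    cat("Sparsity correlation (true vs estimated):\n")
    print(object@sparsityCor, row.names = FALSE)
})
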