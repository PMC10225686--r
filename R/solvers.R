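## Moore-Penrose pseudoinverse via SVD (rank-revealing)
.pinv <- function(B, tol = NULL) {
    s <- svd(B)
    if (is.null(tol)) tol <- max(dim(B)) * max(s$d, 0) * .Machine$double.eps
    keep <- s$d > tol
    if (!any(keep)) return(matrix(0, ncol(B), nrow(B)))
    s$v[, keep, drop = FALSE] %*%
        (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' @describeIn outProjector build Q = I - B B^+ from a topography matrix.
#' @export
setMethod("outProjector", "matrix", function(x) {
    q <- nrow(x)
    if (ncol(x) == 0L) return(diag(q))
    Q <- diag(q) - x %*% .pinv(x)
    (Q + t(Q)) / 2
})

## Shared recursion engine behind RAP-, TRAP- and FLEX-MUSIC.
##
## gains:   list over smoothness orders of q x p candidate-topography matrices
## patches: list over orders of sparse p x p patch-profile matrices
## truncate: TRAP convention — at recursion i retain (selected rank - number
##           of sources already found) leading subspace components
.recursiveScan <- function(data, gains, patches, threshold = 0.975,
                           epsilon = 0.01, truncate = FALSE,
                           maxIter = NULL, rankRule = "value") {
    data <- as.matrix(data)
    if (!length(data) || max(abs(data)) == 0)
        stop("data must be nonzero")
    q <- nrow(data)
    p <- ncol(gains[[1L]])
    K <- length(gains)
    C <- dataCovariance(data)
    debug <- isTRUE(getOption("flexMUSIC.debug", FALSE))

    B <- matrix(0, q, 0L)
    Q <- diag(q)
    sDiag <- numeric(p)
    cand <- data.frame(center_index = integer(0), order = integer(0),
                       peak_score = numeric(0))
    pw <- Matrix::Matrix(0, p, 0L, sparse = TRUE)
    stopReason <- "max_iter"
    if (is.null(maxIter)) maxIter <- q - 1L
    rank0 <- NA_integer_   # signal rank of the first decomposition

    i <- 0L
    repeat {
        Cq <- Q %*% C %*% Q
        e <- eigen((Cq + t(Cq)) / 2, symmetric = TRUE)
        vals <- pmax(e$values, 0)
        if (max(vals) <= 1e-12 * max(abs(C))) {
            stopReason <- "rank_exhausted"
            break
        }
        rank <- selectSignalRank(vals, epsilon, rule = rankRule)
        if (i == 0L) rank0 <- rank
        ## TRAP truncation: the retained dimension shrinks by one per found
        ## source, measured against the initial signal-space estimate
        if (truncate) rank <- min(rank, rank0 - i)
        if (rank < 1L) {
            stopReason <- "rank_exhausted"
            break
        }
        rank <- min(rank, q - i)
        P <- signalProjector(e$vectors, rank)

        best <- -Inf; bestK <- 0L; bestP <- 0L
        for (k in seq_len(K)) {
            mu <- localizer(P, Q, gains[[k]])
            mx <- max(mu)
            if (mx > best + 1e-12) {   # lower order wins ties
                best <- mx
                bestK <- k
                bestP <- which.max(mu) # which.max: lowest index on ties
            }
        }
        if (debug)
            message(sprintf("recursion %d: rank %d, max localizer %.6f at (k=%d, p=%d)",
                            i + 1L, rank, best, bestK, bestP))
        if (best < threshold) {
            stopReason <- "below_threshold"
            break
        }

        topo <- gains[[bestK]][, bestP]
        B <- cbind(B, topo)
        wcol <- patches[[bestK]][, bestP]
        sDiag <- sDiag + as.numeric(wcol)
        pw <- cbind(pw, Matrix::Matrix(as.numeric(wcol), p, 1L, sparse = TRUE))
        cand <- rbind(cand, data.frame(center_index = bestP,
                                       order = bestK,
                                       peak_score = best))
        Q <- outProjector(B)
        i <- i + 1L
        if (i >= maxIter) {
            stopReason <- "max_iter"
            break
        }
        if (i >= q - 1L) {
            stopReason <- "rank_exhausted"
            break
        }
    }
    colnames(B) <- NULL
    new("CandidateSet", candidates = cand, topographies = B,
        patchWeights = pw, outProjector = Q,
        sourceCov = Matrix::Diagonal(p, sDiag), stopReason = stopReason)
}

#' TRAP-MUSIC / RAP-MUSIC recursive dipole scan
#'
#' Recursively selects single-dipole candidates: at each recursion the sensor
#' covariance is out-projected by the topographies selected so far, its
#' eigendecomposition re-taken, the signal rank re-selected, and the MUSIC
#' localizer evaluated for every dipole; the best-scoring dipole is appended.
#' With \code{truncate = TRUE} (TRAP convention) the retained subspace
#' dimension is additionally reduced by one per source already found, which
#' suppresses the residual-variance interference that biases plain RAP
#' recursions. The scan stops when the best localizer value falls below
#' \code{threshold}, when \code{maxIter} sources were found, or when the
#' out-projected subspace is exhausted.
#'
#' @param data q x t sensor matrix.
#' @param lead a \linkS4class{LeadField}.
#' @param threshold localizer stopping threshold (default 0.975).
#' @param truncate apply TRAP subspace truncation (default TRUE).
#' @param epsilon signal-rank selection criterion (default 0.01).
#' @param maxIter maximum number of candidates; defaults to the signal rank
#'   of the first decomposition.
#' @param rankRule signal-rank rule, see [selectSignalRank()].
#' @return a \linkS4class{CandidateSet} with all orders equal to 1.
#' @seealso [flexMusic()], [wmneReconstruct()]
#' @export
trapMusic <- function(data, lead, threshold = 0.975, truncate = TRUE,
                      epsilon = 0.01, maxIter = NULL,
                      rankRule = c("value", "drop")) {
    L <- gain(lead)
    p <- ncol(L)
    .recursiveScan(data, gains = list(L),
                   patches = list(Matrix::Diagonal(p)),
                   threshold = threshold, epsilon = epsilon,
                   truncate = truncate, maxIter = maxIter,
                   rankRule = match.arg(rankRule))
}

#' @rdname trapMusic
#' @export
rapMusic <- function(data, lead, threshold = 0.975, epsilon = 0.01,
                     maxIter = NULL, rankRule = c("value", "drop")) {
    trapMusic(data, lead, threshold = threshold, truncate = FALSE,
              epsilon = epsilon, maxIter = maxIter,
              rankRule = match.arg(rankRule))
}

#' FLEX-MUSIC: recursive scan over dipoles and patches of growing extent
#'
#' Extends the recursive MUSIC scan by evaluating the localizer not only for
#' single-dipole topographies but for every smoothed topography in the
#' dictionary: at each recursion all (order k, center p) pairs are scored and
#' the global best is appended, so a coherent cortical patch can be explained
#' by a single candidate of matching extent instead of several single
#' dipoles. The selected patch profile (column of G_k) is accumulated into
#' the diagonal source covariance used by [wmneReconstruct()]. No subspace
#' truncation is applied. Single dipoles remain in the candidate set via the
#' identity operator at order 1; ties are broken toward the lowest order and
#' then the lowest dipole index, preferring the sparsest explanation.
#'
#' @param data q x t sensor matrix.
#' @param dictionary a \linkS4class{SmoothnessDictionary} built over the
#'   leadfield that models \code{data}.
#' @param threshold localizer stopping threshold (default 0.975).
#' @param epsilon signal-rank selection criterion (default 0.01).
#' @param maxIter maximum number of candidates; defaults to the signal rank
#'   of the first decomposition.
#' @param rankRule signal-rank rule, see [selectSignalRank()].
#' @return a \linkS4class{CandidateSet}; each candidate records its center
#'   dipole, smoothness order (1 = single dipole) and localizer peak.
#' @seealso [trapMusic()], [buildSmoothnessDictionary()], [wmneReconstruct()]
#' @export
flexMusic <- function(data, dictionary, threshold = 0.975, epsilon = 0.01,
                      maxIter = NULL, rankRule = c("value", "drop")) {
    .recursiveScan(data, gains = smoothedGains(dictionary),
                   patches = operators(dictionary),
                   threshold = threshold, epsilon = epsilon,
                   truncate = FALSE, maxIter = maxIter,
                   rankRule = match.arg(rankRule))
}

#' One-shot MUSIC scan
#'
#' Evaluates the plain MUSIC localizer once (no recursion, no
#' out-projection) over all single-dipole topographies and thresholds it.
#'
#' @param data q x t sensor matrix.
#' @param lead a \linkS4class{LeadField}.
#' @param criterion activity criterion in (0, 1); dipoles with localizer
#'   scores at or above it are flagged active (typical values 0.9-0.99).
#' @param epsilon signal-rank selection criterion.
#' @param rankRule signal-rank rule, see [selectSignalRank()].
#' @return list with \code{score} (length-p localizer values) and
#'   \code{active} (logical mask \code{score >= criterion}).
#' @export
musicOneshot <- function(data, lead, criterion = 0.95, epsilon = 0.01,
                         rankRule = c("value", "drop")) {
    model <- subspaceModel(data, epsilon = epsilon, rankRule = rankRule)
    mu <- localizer(model@projector, NULL, gain(lead))
    list(score = mu, active = mu >= criterion)
}

#' Weighted minimum-norm reconstruction of source currents
#'
#' Computes J = S L' (L S L' + lambda I)^-1 M: the minimum-norm current
#' estimate weighted by the diagonal source covariance S accumulated during
#' candidate selection. Dipoles outside the support of S have exactly zero
#' rows. The ridge term regularizes the q x q system; it is scaled relative
#' to the problem, lambda = ridge * trace(L S L') / q, so the default
#' \code{ridge = 1e-6} is a dimensionless relative regularizer. A
#' pseudo-inverse is used if the regularized system is still singular.
#'
#' @param sourceCov p x p positive semidefinite source covariance (diagonal
#'   matrices are handled efficiently), or a \linkS4class{CandidateSet}.
#' @param lead a \linkS4class{LeadField}.
#' @param data q x t sensor matrix M.
#' @param ridge relative Tikhonov regularization (default 1e-6).
#' @return a \linkS4class{SourceEstimate}.
#' @export
wmneReconstruct <- function(sourceCov, lead, data, ridge = 1e-6) {
    cs <- NULL
    if (is(sourceCov, "CandidateSet")) {
        cs <- sourceCov
        sourceCov <- cs@sourceCov
    }
    L <- gain(lead)
    data <- as.matrix(data)
    q <- nrow(L)
    p <- ncol(L)
    sDiag <- if (is(sourceCov, "Matrix") || is.matrix(sourceCov))
        Matrix::diag(sourceCov) else as.numeric(sourceCov)
    J <- matrix(0, p, ncol(data))
    if (is.null(cs))
        cs <- new("CandidateSet",
                  candidates = data.frame(center_index = integer(0),
                                          order = integer(0),
                                          peak_score = numeric(0)),
                  topographies = matrix(0, q, 0L),
                  patchWeights = Matrix::Matrix(0, p, 0L, sparse = TRUE),
                  outProjector = diag(q),
                  sourceCov = Matrix::Diagonal(p, sDiag),
                  stopReason = "below_threshold")
    if (all(sDiag == 0)) {
        warning("source covariance is all-zero; returning an all-zero estimate")
        return(new("SourceEstimate", currents = J, candidateSet = cs))
    }
    support <- which(sDiag != 0)
    Ls <- L[, support, drop = FALSE]
    SLt <- t(Ls) * sDiag[support]          # S L' restricted to the support
    Gram <- Ls %*% SLt                     # L S L'
    lambda <- ridge * sum(diag(Gram)) / q
    Greg <- Gram + diag(lambda, q)
    W <- tryCatch(solve(Greg, data),
                  error = function(e) .pinv(Greg) %*% data)
    J[support, ] <- SLt %*% W
    new("SourceEstimate", currents = J, candidateSet = cs)
}

#' Solve an inverse problem end-to-end
#'
#' Runs a recursive scan followed by the weighted minimum-norm
#' reconstruction.
#'
#' @param data q x t sensor matrix.
#' @param forward a \linkS4class{ForwardModel}.
#' @param method one of \code{"flex"}, \code{"trap"}, \code{"rap"}.
#' @param threshold,epsilon,maxIter,ridge,rankRule solver parameters, see
#'   [flexMusic()], [trapMusic()], [wmneReconstruct()].
#' @return a \linkS4class{SourceEstimate} (candidate set in
#'   \code{candidates()}).
#' @examples
#' syn <- synthesizeSourceSpace(2, 70, seed = 7)
#' fwd <- forwardModel(syn$space, syn$lead, maxOrder = 3)
#' tc <- sin(seq(0, 2 * pi, length.out = 20))
#' M <- gain(syn$lead)[, 42] %*% t(tc)   # noiseless single dipole
#' est <- solveInverse(M, fwd, method = "flex")
#' candidates(est)
#' @export
solveInverse <- function(data, forward,
                         method = c("flex", "trap", "rap"),
                         threshold = 0.975, epsilon = 0.01,
                         maxIter = NULL, ridge = 1e-6,
                         rankRule = c("value", "drop")) {
    method <- match.arg(method)
    rankRule <- match.arg(rankRule)
    cs <- switch(method,
        flex = flexMusic(data, forward@dictionary, threshold = threshold,
                         epsilon = epsilon, maxIter = maxIter,
                         rankRule = rankRule),
        trap = trapMusic(data, forward@lead, threshold = threshold,
                         truncate = TRUE, epsilon = epsilon,
                         maxIter = maxIter, rankRule = rankRule),
        rap = rapMusic(data, forward@lead, threshold = threshold,
                       epsilon = epsilon, maxIter = maxIter,
                       rankRule = rankRule))
    if (length(cs) == 0L) {
        p <- nDipoles(forward@space)
        return(new("SourceEstimate",
                   currents = matrix(0, p, ncol(as.matrix(data))),
                   candidateSet = cs))
    }
    wmneReconstruct(cs, forward@lead, data, ridge = ridge)
}

#' Serialize a solver result
#'
#' Writes the current estimate as an \code{.rds} array container and the
#' candidate metadata (centers, orders, scores, stop reason) as a JSON
#' sidecar.
#'
#' @param estimate a \linkS4class{SourceEstimate}.
#' @param prefix output path prefix; \code{<prefix>.rds} and
#'   \code{<prefix>.json} are written.
#' @return the two paths, invisibly.
#' @export
writeEstimate <- function(estimate, prefix) {
    rds <- paste0(prefix, ".rds")
    js <- paste0(prefix, ".json")
    saveRDS(currents(estimate), rds)
    cs <- estimate@candidateSet
    jsonlite::write_json(
        list(candidates = cs@candidates, stop_reason = cs@stopReason),
        js, auto_unbox = TRUE, digits = NA)
    invisible(c(rds, js))
}
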