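#' Sensor covariance of an M/EEG data matrix
#'
#' Computes the raw outer-product covariance C = M M' used by the subspace
#' scan. Because both the signal-rank rule and the localizer are invariant to
#' a global scale, neither 1/t scaling nor mean removal changes any result;
#' both are available behind flags for comparison with other conventions.
#'
#' @param data numeric q x t sensor matrix (channels x time).
#' @param center subtract the row (channel) means first.
#' @param scale divide by the number of time points.
#' @return symmetric positive semidefinite q x q matrix.
#' @examples
#' dataCovariance(diag(2))         # identity
#' dataCovariance(matrix(c(1, 2))) # outer product [[1,2],[2,4]]
#' @export
dataCovariance <- function(data, center = FALSE, scale = FALSE) {
    data <- as.matrix(data)
    if (!length(data) || ncol(data) < 1L)
        stop("data must have at least one time point")
    if (center) data <- data - rowMeans(data)
    C <- tcrossprod(data)
    if (scale) C <- C / ncol(data)
    C
}

#' Select the signal-subspace rank from an eigenvalue spectrum
#'
#' Normalizes the eigenvalues to a maximum of one and selects how many
#' leading eigenvectors belong to the signal subspace, under one of two
#' readings of the relative criterion \code{epsilon}:
#' \describe{
#'   \item{\code{"value"} (default)}{the signal subspace consists of all
#'     eigenvalues within a fraction \code{epsilon} of the largest: rank =
#'     number of normalized eigenvalues >= \code{epsilon}. Components
#'     carrying at least 1\% of the peak variance are kept; this errs toward
#'     overestimating the rank, which is the safer direction for subspace
#'     scans (losing part of the signal subspace is worse than carrying a
#'     noise direction).}
#'   \item{\code{"drop"}}{scan the consecutive drops of the normalized
#'     spectrum; the rank is the index after which the drop first falls
#'     below \code{epsilon} (the flat tail is attributed to noise). If every
#'     drop is already below \code{epsilon} the rank is 1; if no drop ever
#'     falls below \code{epsilon} it is q - 1. This variant keys on the
#'     spectrum's elbow rather than its magnitude.}
#' }
#' Both rules agree on clearly gapped spectra (e.g. eigenvalues
#' 4, 2, 1, 0.004, 0.003, 0.002 give rank 3 either way); they differ on
#' slowly decaying spectra, where the value rule retains more components.
#'
#' @param eigvals nonincreasing nonnegative eigenvalues.
#' @param epsilon relative criterion (default 0.01).
#' @param rule \code{"value"} (default) or \code{"drop"}, see above.
#' @return integer signal rank in [1, q].
#' @examples
#' selectSignalRank(c(4, 2, 1, 0.004, 0.003, 0.002))  # 3
#' @export
selectSignalRank <- function(eigvals, epsilon = 0.01,
                             rule = c("value", "drop")) {
    rule <- match.arg(rule)
    d <- as.numeric(eigvals)
    q <- length(d)
    if (!q || max(d) <= 0)
        stop("eigenvalue spectrum carries no signal (all zero)")
    tol <- 1e-10 * max(d)
    if (any(diff(d) > tol))
        stop("eigvals must be nonincreasing")
    if (q == 1L) return(1L)
    dn <- d / max(d)
    if (rule == "value")
        return(max(1L, sum(dn >= epsilon)))
    drops <- dn[-q] - dn[-1L]
    below <- which(drops < epsilon)
    if (!length(below)) return(q - 1L)
    max(below[1L] - 1L, 1L)
}

#' Signal-subspace projector
#'
#' @param eigvecs q x q orthonormal eigenvector matrix (columns sorted by
#'   decreasing eigenvalue).
#' @param signalRank number of leading eigenvectors spanning the signal
#'   subspace.
#' @return symmetric idempotent q x q projector of rank \code{signalRank}.
#' @export
signalProjector <- function(eigvecs, signalRank) {
    eigvecs <- as.matrix(eigvecs)
    q <- ncol(eigvecs)
    signalRank <- as.integer(signalRank)
    if (signalRank < 1L || signalRank > q)
        stop("signalRank must be in [1, q]")
    Us <- eigvecs[, seq_len(signalRank), drop = FALSE]
    tcrossprod(Us)
}

#' Fit a SubspaceModel to sensor data
#'
#' Convenience wrapper: covariance, eigendecomposition, automatic signal-rank
#' selection, and the signal-subspace projector.
#'
#' @param data q x t sensor matrix, or a precomputed q x q covariance passed
#'   via \code{covariance}.
#' @param epsilon relative eigenvalue criterion of [selectSignalRank()].
#' @param covariance optional q x q covariance (overrides \code{data}).
#' @param rankRule signal-rank rule, see [selectSignalRank()].
#' @return a \linkS4class{SubspaceModel}.
#' @export
subspaceModel <- function(data = NULL, epsilon = 0.01, covariance = NULL,
                          rankRule = c("value", "drop")) {
    C <- if (is.null(covariance)) dataCovariance(data) else as.matrix(covariance)
    e <- eigen(C, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    rank <- selectSignalRank(vals, epsilon, rule = rankRule)
    new("SubspaceModel", covariance = C, eigvecs = e$vectors, eigvals = vals,
        signalRank = as.integer(rank), epsilon = epsilon,
        projector = signalProjector(e$vectors, rank))
}

#' MUSIC localizer scores
#'
#' For each candidate topography (column of \code{gainColumns}) computes the
#' fraction of its out-projected energy lying inside the current signal
#' subspace: mu_j = ||P Q l_j||^2 / ||Q l_j||^2. Scores live in [0, 1]; a
#' score of 1 means the (out-projected) topography is fully contained in the
#' signal subspace. Columns annihilated by the out-projector — i.e., fully
#' explained by already-selected topographies — receive a score of 0 so they
#' cannot be re-selected.
#'
#' @param projector q x q signal-subspace projector P.
#' @param outProjector q x q out-projection matrix Q, or NULL for plain
#'   MUSIC (Q = I).
#' @param gainColumns q x m matrix of candidate topographies.
#' @param tol relative tolerance below which an out-projected column is
#'   treated as annihilated.
#' @return numeric vector of m scores in [0, 1].
#' @export
localizer <- function(projector, outProjector, gainColumns, tol = 1e-8) {
    L <- as.matrix(gainColumns)
    if (nrow(L) != nrow(projector))
        stop("gain columns and projector dimensions differ")
    QL <- if (is.null(outProjector)) L else {
        if (!all(dim(outProjector) == dim(projector)))
            stop("out-projector and projector dimensions differ")
        outProjector %*% L
    }
    den <- colSums(QL^2)
    num <- colSums((projector %*% QL)^2)
    mu <- numeric(ncol(L))
    keep <- den > (tol^2) * colSums(L^2)
    mu[keep] <- num[keep] / den[keep]
    pmin(pmax(mu, 0), 1)
}
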