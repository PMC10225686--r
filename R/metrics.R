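#' Local maxima of a source activity map on the mesh graph
#'
#' A dipole is a local maximum when its value is at least as large as every
#' graph neighbor's value and at least \code{floorFrac} times the global
#' maximum (the floor suppresses numerical ripple from minimum-norm-like
#' reconstructions). Plateaus — connected sets of equal-valued maxima —
#' contribute a single representative, the lowest index.
#'
#' @param values length-p nonnegative activity values (typically the
#'   absolute mean over time of a current matrix).
#' @param space a \linkS4class{SourceSpace}.
#' @param floorFrac fraction of the global maximum below which maxima are
#'   discarded (default 0.1).
#' @return integer vector of dipole indices (possibly empty).
#' @export
localMaxima <- function(values, space, floorFrac = 0.1) {
    v <- as.numeric(values)
    if (any(v < 0)) stop("values must be nonnegative")
    if (max(v) == 0) return(integer(0))
    A <- adjacency(space)
    p <- length(v)
    floorVal <- floorFrac * max(v)
    isMax <- logical(p)
    for (i in seq_len(p)) {
        if (v[i] < floorVal) next
        nb <- .neighborList(A, i)
        isMax[i] <- !length(nb) || all(v[i] >= v[nb])
    }
    sel <- which(isMax)
    if (length(sel) <= 1L) return(sel)
    ## collapse plateaus: connected equal-valued maxima -> lowest index
    comp <- seq_along(sel)
    names(comp) <- sel
    lookup <- integer(p)
    lookup[sel] <- seq_along(sel)
    find <- function(x) {
        while (comp[x] != x) x <- comp[x]
        x
    }
    for (a in seq_along(sel)) {
        i <- sel[a]
        nb <- .neighborList(A, i)
        for (j in nb) {
            if (lookup[j] && v[j] == v[i]) {
                ra <- find(a); rb <- find(lookup[j])
                if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
            }
        }
    }
    roots <- vapply(seq_along(sel), find, integer(1))
    unname(sort(vapply(split(sel, roots), min, integer(1))))
}

#' Mean localization error in mm
#'
#' Identifies the local maxima of the ground truth and of the estimate
#' (absolute mean over time) and averages, over the true maxima, the
#' Euclidean distance to the nearest estimated maximum. An estimate with no
#' maxima (e.g., an all-zero reconstruction) is penalized with the maximum
#' pairwise distance of the source space — a bounded worst-case penalty.
#'
#' @param truth p x t ground-truth current matrix.
#' @param estimate p x t estimated current matrix.
#' @param space a \linkS4class{SourceSpace}.
#' @param floorFrac local-maxima floor, see [localMaxima()].
#' @return nonnegative scalar in mm (NA when the truth has no maxima).
#' @export
meanLocalizationError <- function(truth, estimate, space, floorFrac = 0.1) {
    tMax <- localMaxima(rowMeans(abs(as.matrix(truth))), space, floorFrac)
    eMax <- localMaxima(rowMeans(abs(as.matrix(estimate))), space, floorFrac)
    if (!length(tMax)) return(NA_real_)
    pos <- positions(space)
    if (!length(eMax)) return(max(stats::dist(pos)))
    dd <- vapply(tMax, function(i) {
        d2 <- colSums((t(pos[eMax, , drop = FALSE]) - pos[i, ])^2)
        sqrt(min(d2))
    }, numeric(1))
    mean(dd)
}

#' Earth mover's distance between two source distributions
#'
#' Reduces both current matrices to their absolute mean over time,
#' normalizes each to unit mass, and solves the optimal-transport problem
#' between the two distributions over the dipole positions with Euclidean
#' ground distance in mm. The result is the minimal cost (mass x mm) of
#' morphing the estimated distribution into the true one.
#'
#' @param truth,estimate p x t current matrices (each nonzero).
#' @param space a \linkS4class{SourceSpace}.
#' @return nonnegative scalar.
#' @export
earthMoversDistance <- function(truth, estimate, space) {
    wt <- rowMeans(abs(as.matrix(truth)))
    we <- rowMeans(abs(as.matrix(estimate)))
    if (sum(wt) == 0 || sum(we) == 0)
        stop("cannot compute EMD for an all-zero distribution")
    wt <- wt / sum(wt)
    we <- we / sum(we)
    si <- which(wt > 0)
    di <- which(we > 0)
    pos <- positions(space)
    ## coordinate-difference form: exact zeros for coincident dipoles
    cost <- sqrt(outer(pos[si, 1], pos[di, 1], "-")^2 +
                 outer(pos[si, 2], pos[di, 2], "-")^2 +
                 outer(pos[si, 3], pos[di, 3], "-")^2)
    .emdTransport(wt[si], we[di], cost)
}

#' Mean squared error between current matrices
#'
#' @param truth,estimate p x t current matrices.
#' @param type \code{"mean"} (default): mean of squared entrywise
#'   differences; \code{"norm"}: squared Frobenius norm.
#' @return nonnegative scalar.
#' @export
meanSquaredError <- function(truth, estimate, type = c("mean", "norm")) {
    type <- match.arg(type)
    d2 <- (as.matrix(truth) - as.matrix(estimate))^2
    if (type == "mean") mean(d2) else sum(d2)
}

#' Sparsity of a source estimate (L1 norm of L2-normalized columns)
#'
#' Each nonzero column of the estimate is scaled to unit L2 norm and its L1
#' norm taken; the mean over columns is returned. The value is 1 for a
#' single active dipole per column and sqrt(p) for spatially uniform
#' activity, so it measures "non-sparsity"; it is invariant to global
#' rescaling. All-zero columns are skipped.
#'
#' @param estimate p x t current matrix with at least one nonzero column.
#' @return scalar in [1, sqrt(p)].
#' @export
sparsityL1 <- function(estimate) {
    X <- as.matrix(estimate)
    l2 <- sqrt(colSums(X^2))
    keep <- l2 > 0
    if (!any(keep)) stop("sparsity undefined: all columns are zero")
    mean(colSums(abs(X[, keep, drop = FALSE])) / l2[keep])
}
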