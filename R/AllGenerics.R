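#' @export
setGeneric("nDipoles", function(x) standardGeneric("nDipoles"))

#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @export
setGeneric("gain", function(x) standardGeneric("gain"))

#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @export
setGeneric("operators", function(x) standardGeneric("operators"))

#' @export
setGeneric("smoothedGains", function(x) standardGeneric("smoothedGains"))

#' @export
setGeneric("maxOrder", function(x) standardGeneric("maxOrder"))

#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @export
setGeneric("topographies", function(x) standardGeneric("topographies"))

#' Out-projector: build from topographies or extract from a candidate set
#'
#' For a numeric matrix \code{B} (channels x selected topographies) returns the
#' orthogonal projector \eqn{Q = I - B B^+} onto the complement of the column
#' space of \code{B}; applied to sensor data it removes the contribution of the
#' already-selected source topographies. For a \linkS4class{CandidateSet} it
#' returns the out-projector accumulated during the recursion.
#'
#' @param x a numeric matrix of topographies (possibly with zero columns), or a
#'   \linkS4class{CandidateSet}.
#' @return a symmetric idempotent q x q matrix annihilating the columns of
#'   \code{x} (\code{Q \%*\% x} is numerically zero).
#' @examples
#' B <- cbind(c(1, 0, 0))
#' Q <- outProjector(B)         # diag(0, 1, 1)
#' max(abs(Q %*% B))            # ~ 0
#' @export
setGeneric("outProjector", function(x) standardGeneric("outProjector"))

#' @export
setGeneric("sourceCov", function(x) standardGeneric("sourceCov"))

#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))

#' @export
setGeneric("currents", function(x) standardGeneric("currents"))

#' @export
setGeneric("sensorData", function(x) standardGeneric("sensorData"))
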