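#' Colored (1/f^beta) random time course
#'
#' Draws Gaussian white noise, shapes its amplitude spectrum proportional to
#' f^(-beta/2) (so the power spectrum follows 1/f^beta), inverse-transforms,
#' and standardizes the result to zero mean and unit sample variance. The DC
#' component is removed, which makes the output exactly zero-mean. beta = 0
#' yields (approximately) white noise; larger beta yields temporally smoother
#' traces.
#'
#' @param nTimepoints length t of the time course (>= 2).
#' @param beta spectral exponent (>= 0).
#' @return numeric vector of length t with mean 0 and sample variance 1.
#' @export
coloredTimeCourse <- function(nTimepoints, beta) {
    t <- as.integer(nTimepoints)
    if (t < 2L) stop("nTimepoints must be >= 2")
    w <- stats::rnorm(t)
    W <- stats::fft(w)
    k <- 0:(t - 1L)
    f <- pmin(k, t - k)              # folded frequency index
    amp <- numeric(t)
    pos <- f > 0
    amp[pos] <- f[pos]^(-beta / 2)   # DC removed (amp[1] = 0)
    x <- Re(stats::fft(W * amp, inverse = TRUE)) / t
    x <- x - mean(x)
    sdx <- stats::sd(x)
    if (sdx == 0) stop("degenerate time course (zero variance)")
    x / sdx
}

#' Draw ground-truth sources into a current matrix
#'
#' Draws the number of sources uniformly from the configured range; for each
#' source a center dipole (uniform, resampled on collision), an extent (graph
#' radius from the requested set), a per-source amplitude (uniform in nAm)
#' and one time course shared coherently by the whole patch. A source of
#' radius r places its spatial profile on all dipoles within graph distance r
#' of the center: by default the corresponding smoothing-operator column (the
#' same patch model the FLEX scan searches over), optionally a uniform patch
#' for model-mismatch experiments. Sources sum into the p x t current
#' matrix J.
#'
#' @param space a \linkS4class{SourceSpace}.
#' @param dictionary a \linkS4class{SmoothnessDictionary} covering the
#'   requested extents (order k covers radius k - 1).
#' @param config a \linkS4class{SimulationConfig}; \code{extentOrders} here
#'   are the radii to draw from.
#' @param extentOrders optional override of the radii set (used internally
#'   to split single/extended samples).
#' @return list with \code{currents} (p x t), \code{centers}, \code{orders}
#'   (radii), \code{amplitudes}, \code{beta}.
#' @export
sampleSources <- function(space, dictionary, config, extentOrders = NULL) {
    radii <- if (is.null(extentOrders)) config@extentOrders else
        as.integer(extentOrders)
    if (max(radii) + 1L > maxOrder(dictionary))
        stop("requested extent exceeds dictionary depth")
    p <- nDipoles(space)
    nt <- config@nTimepoints
    lo <- config@nSourcesRange[1L]; hi <- config@nSourcesRange[2L]
    nSources <- if (lo == hi) lo else sample(lo:hi, 1L)
    beta <- stats::runif(1L, config@betaRange[1L], config@betaRange[2L])

    centers <- integer(0)
    while (length(centers) < nSources) {      # collision rule: resample
        cand <- sample.int(p, 1L)
        if (!cand %in% centers) centers <- c(centers, cand)
    }
    orders <- radii[sample.int(length(radii), nSources, replace = TRUE)]
    amps <- stats::runif(nSources, config@amplitudeRange[1L],
                         config@amplitudeRange[2L])
    J <- matrix(0, p, nt)
    for (s in seq_len(nSources)) {
        tc <- coloredTimeCourse(nt, beta)
        k <- orders[s] + 1L
        profile <- as.numeric(operators(dictionary)[[k]][, centers[s]])
        if (config@patchProfile == "uniform" && orders[s] > 0L) {
            supp <- profile > 0
            profile <- as.numeric(supp) / sum(supp)
        }
        J <- J + tcrossprod(amps[s] * profile, tc)
    }
    list(currents = J, centers = centers, orders = orders,
         amplitudes = amps, beta = beta)
}

#' Add channel-correlated white noise at a controlled SNR
#'
#' Noise is generated as a random square mixing matrix applied to
#' spatio-temporal white noise, which induces pairwise inter-channel
#' correlations spanning the full range, and rescaled so that the amplitude
#' SNR — RMS(clean) / RMS(noise) over all channels and time points — equals
#' the requested value exactly.
#'
#' @param clean q x t noiseless sensor matrix (nonzero).
#' @param snr target amplitude SNR (> 0).
#' @return list with \code{noisy} and \code{noise}, both q x t.
#' @export
addNoise <- function(clean, snr) {
    clean <- as.matrix(clean)
    if (snr <= 0) stop("snr must be positive")
    rmsClean <- sqrt(mean(clean^2))
    if (rmsClean == 0) stop("clean data is all-zero; SNR undefined")
    q <- nrow(clean); t <- ncol(clean)
    mixing <- matrix(stats::rnorm(q * q), q, q) / sqrt(q)
    noise <- mixing %*% matrix(stats::rnorm(q * t), q, t)
    noise <- noise * (rmsClean / (snr * sqrt(mean(noise^2))))
    list(noisy = clean + noise, noise = noise)
}

#' Generate a simulated benchmark dataset
#'
#' Deterministically (given \code{config@seed}) simulates
#' \code{config@nSamples} ground-truth / sensor-data pairs. When the
#' configured extents contain both radius 0 and positive radii, the first
#' half of the dataset contains single-dipole samples (radius 0) and the
#' second half extended patch samples (positive radii), mirroring a
#' half/half single/extended protocol. The SNR of each sample is drawn
#' log-uniformly over the configured range.
#'
#' @param space a \linkS4class{SourceSpace}.
#' @param lead the matching \linkS4class{LeadField}.
#' @param dictionary a \linkS4class{SmoothnessDictionary} covering the
#'   configured extents.
#' @param config a \linkS4class{SimulationConfig}.
#' @return list of \linkS4class{SimulatedSample} objects, with the config
#'   attached as attribute \code{"config"}.
#' @export
generateDataset <- function(space, lead, dictionary, config) {
    stopifnot(is(config, "SimulationConfig"))
    L <- gain(lead)
    if (ncol(L) != nDipoles(space))
        stop("leadfield and source space dimensions differ")
    n <- config@nSamples
    radii <- config@extentOrders
    singles <- radii[radii == 0L]
    extended <- radii[radii > 0L]
    both <- length(singles) && length(extended)
    nSingle <- if (both) ceiling(n / 2) else if (length(extended)) 0L else n

    old <- .seedSwap(config@seed)
    on.exit(.seedRestore(old))
    out <- vector("list", n)
    lo <- log10(config@snrRange[1L]); hi <- log10(config@snrRange[2L])
    for (s in seq_len(n)) {
        radSet <- if (s <= nSingle) 0L else extended
        src <- sampleSources(space, dictionary, config, extentOrders = radSet)
        snr <- 10^stats::runif(1L, lo, hi)
        clean <- L %*% src$currents
        nz <- addNoise(clean, snr)
        out[[s]] <- new("SimulatedSample",
                        currents = src$currents,
                        sensorData = as.matrix(clean + nz$noise),
                        noise = nz$noise,
                        trueCenters = as.integer(src$centers),
                        trueOrders = as.integer(src$orders),
                        snr = snr, beta = src$beta)
    }
    attr(out, "config") <- config
    out
}

#' Serialize / load a simulated dataset
#'
#' The samples are stored in an \code{.rds} array container; the
#' configuration and per-sample metadata go to a JSON manifest, and the
#' metadata additionally to CSV.
#'
#' @param dataset list of \linkS4class{SimulatedSample} (from
#'   [generateDataset()]).
#' @param prefix output path prefix.
#' @return \code{readDataset} returns the dataset list.
#' @export
writeDataset <- function(dataset, prefix) {
    saveRDS(dataset, paste0(prefix, ".rds"))
    meta <- datasetMetadata(dataset)
    cfg <- attr(dataset, "config")
    jsonlite::write_json(
        list(config = list(nSamples = cfg@nSamples,
                           nSourcesRange = cfg@nSourcesRange,
                           extentOrders = cfg@extentOrders,
                           nTimepoints = cfg@nTimepoints,
                           snrRange = cfg@snrRange,
                           betaRange = cfg@betaRange,
                           amplitudeRange = cfg@amplitudeRange,
                           patchProfile = cfg@patchProfile,
                           seed = cfg@seed),
             samples = meta),
        paste0(prefix, "-manifest.json"), digits = NA)
    utils::write.csv(meta, paste0(prefix, "-metadata.csv"),
                     row.names = FALSE)
    invisible(prefix)
}

#' @rdname writeDataset
#' @export
readDataset <- function(prefix) readRDS(paste0(prefix, ".rds"))

#' Per-sample metadata table of a dataset
#'
#' @param dataset list of \linkS4class{SimulatedSample}.
#' @return data.frame with one row per sample.
#' @export
datasetMetadata <- function(dataset) {
    do.call(rbind, lapply(seq_along(dataset), function(s) {
        smp <- dataset[[s]]
        data.frame(sample_id = s,
                   n_sources = length(smp@trueCenters),
                   max_order = max(smp@trueOrders),
                   extended = any(smp@trueOrders > 0L),
                   snr = smp@snr,
                   beta = smp@beta)
    }))
}
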