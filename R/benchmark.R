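## Resolve a solver specification into a function(data, forward) -> p x t
## matrix. Built-in names: "flex", "trap", "rap". A list element may carry
## parameters (threshold, epsilon, maxIter, ridge); a function is used as-is.
.resolveSolver <- function(name, spec) {
    if (is.function(spec)) return(spec)
    params <- if (is.list(spec)) spec else list()
    method <- if (!is.null(params$method)) params$method else name
    if (!method %in% c("flex", "trap", "rap"))
        stop("unknown solver: '", method, "'")
    args <- params[names(params) %in%
                   c("threshold", "epsilon", "maxIter", "ridge")]
    function(data, forward) {
        est <- do.call(solveInverse,
                       c(list(data = data, forward = forward,
                              method = method), args))
        currents(est)
    }
}

.normalizeSolvers <- function(solvers) {
    if (is.character(solvers)) {
        out <- stats::setNames(vector("list", length(solvers)), solvers)
        return(out)
    }
    if (is.list(solvers)) {
        if (is.null(names(solvers)) || any(names(solvers) == ""))
            stop("solver list must be named")
        return(solvers)
    }
    stop("solvers must be a character vector or a named list")
}

#' Run the simulation benchmark
#'
#' Applies every solver to every simulated sample, computes the four
#' evaluation metrics per sample (mean localization error, earth mover's
#' distance, mean squared error, sparsity) plus the ground-truth sparsity,
#' and aggregates: per-solver medians, the per-solver Pearson correlation
#' between true and estimated sparsity (the extent-recovery statistic), and
#' stratified medians by SNR bin, by source count, and by single/extended
#' samples. A solver failure on a sample is recorded as missing with a
#' warning and excluded from the aggregates.
#'
#' @param dataset list of \linkS4class{SimulatedSample} (from
#'   [generateDataset()]).
#' @param forward the \linkS4class{ForwardModel} the data were simulated
#'   with.
#' @param solvers character vector of built-in solver names ("flex",
#'   "trap", "rap"), or a named list whose elements are parameter lists
#'   (fields \code{method}, \code{threshold}, \code{epsilon},
#'   \code{maxIter}, \code{ridge}) or functions \code{(data, forward)}
#'   returning a p x t current matrix.
#' @param reportPath optional path prefix; per-sample records are written to
#'   \code{<reportPath>-records.csv} and aggregates to
#'   \code{<reportPath>-aggregates.json}.
#' @param snrBreaks breakpoints (in SNR units) of the SNR stratification.
#' @param floorFrac local-maxima floor for the localization error.
#' @return a \linkS4class{BenchmarkReport}.
#' @export
runBenchmark <- function(dataset, forward, solvers = c("flex", "trap"),
                         reportPath = NULL,
                         snrBreaks = c(0.1, 1, 10, 100),
                         floorFrac = 0.1) {
    if (!length(dataset)) stop("dataset must contain at least one sample")
    solvers <- .normalizeSolvers(solvers)
    if (!length(solvers)) stop("at least one solver is required")
    fns <- lapply(names(solvers),
                  function(nm) .resolveSolver(nm, solvers[[nm]]))
    names(fns) <- names(solvers)
    space <- forward@space
    maxDist <- max(stats::dist(positions(space)))

    rows <- list()
    for (s in seq_along(dataset)) {
        smp <- dataset[[s]]
        J <- currents(smp)
        trueSp <- sparsityL1(J)
        for (nm in names(fns)) {
            rec <- data.frame(sample_id = s, solver = nm,
                              mle_mm = NA_real_, emd = NA_real_,
                              mse = NA_real_, sparsity_l1 = NA_real_,
                              true_sparsity_l1 = trueSp,
                              n_candidates = NA_integer_,
                              snr = smp@snr,
                              n_sources = length(smp@trueCenters),
                              extended = any(smp@trueOrders > 0L))
            Jh <- tryCatch(fns[[nm]](sensorData(smp), forward),
                           error = function(e) {
                               warning("solver '", nm, "' failed on sample ",
                                       s, ": ", conditionMessage(e))
                               NULL
                           })
            if (!is.null(Jh)) {
                rec$mle_mm <- meanLocalizationError(J, Jh, space, floorFrac)
                rec$emd <- if (sum(abs(Jh)) > 0)
                    earthMoversDistance(J, Jh, space) else maxDist
                rec$mse <- meanSquaredError(J, Jh)
                rec$sparsity_l1 <- if (sum(abs(Jh)) > 0)
                    sparsityL1(Jh) else NA_real_
                rec$n_candidates <- sum(rowSums(abs(Jh)) > 0)
            }
            rows[[length(rows) + 1L]] <- rec
        }
    }
    records <- do.call(rbind, rows)

    medOf <- function(df) data.frame(
        n = nrow(df),
        mle_mm = stats::median(df$mle_mm, na.rm = TRUE),
        emd = stats::median(df$emd, na.rm = TRUE),
        mse = stats::median(df$mse, na.rm = TRUE),
        sparsity_l1 = stats::median(df$sparsity_l1, na.rm = TRUE))

    bySolver <- split(records, records$solver)
    medians <- do.call(rbind, lapply(names(bySolver), function(nm)
        cbind(data.frame(solver = nm), medOf(bySolver[[nm]]))))

    sparsityCor <- do.call(rbind, lapply(names(bySolver), function(nm) {
        df <- bySolver[[nm]]
        ok <- stats::complete.cases(df$sparsity_l1, df$true_sparsity_l1)
        r <- if (sum(ok) > 2 && stats::sd(df$sparsity_l1[ok]) > 0)
            stats::cor(df$true_sparsity_l1[ok], df$sparsity_l1[ok]) else
            NA_real_
        data.frame(solver = nm, r = r, n = sum(ok))
    }))

    strat <- function(fac) {
        grp <- split(records, list(records$solver, fac), drop = TRUE)
        do.call(rbind, lapply(names(grp), function(g)
            cbind(data.frame(group = g), medOf(grp[[g]]))))
    }
    snrBin <- cut(records$snr, breaks = snrBreaks, include.lowest = TRUE)
    strata <- list(by_snr = strat(snrBin),
                   by_n_sources = strat(records$n_sources),
                   by_extent = strat(ifelse(records$extended,
                                            "extended", "single")))

    report <- new("BenchmarkReport", records = records, medians = medians,
                  sparsityCor = sparsityCor, strata = strata)
    if (!is.null(reportPath)) {
        utils::write.csv(records, paste0(reportPath, "-records.csv"),
                         row.names = FALSE)
        jsonlite::write_json(list(medians = medians,
                                  sparsity_correlation = sparsityCor,
                                  strata = strata),
                             paste0(reportPath, "-aggregates.json"),
                             digits = NA)
    }
    report
}
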