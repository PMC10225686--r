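#' Write / read a source space as delimited text
#'
#' Positions are stored as a 3-column TSV (x, y, z in mm) and the adjacency
#' as a two-column TSV edge list of 1-based vertex indices (each undirected
#' edge once, i < j).
#'
#' @param space a \linkS4class{SourceSpace}.
#' @param prefix file path prefix; \code{<prefix>-positions.tsv} and
#'   \code{<prefix>-edges.tsv} are written/read.
#' @return \code{writeSourceSpace} returns the two file paths invisibly;
#'   \code{readSourceSpace} returns a \linkS4class{SourceSpace}.
#' @export
writeSourceSpace <- function(space, prefix) {
    posFile <- paste0(prefix, "-positions.tsv")
    edgeFile <- paste0(prefix, "-edges.tsv")
    utils::write.table(positions(space), posFile, sep = "\t",
                       row.names = FALSE, col.names = c("x", "y", "z"))
    A <- adjacency(space)
    idx <- Matrix::which(A != 0, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    utils::write.table(data.frame(i = idx[, 1L], j = idx[, 2L]), edgeFile,
                       sep = "\t", row.names = FALSE)
    invisible(c(posFile, edgeFile))
}

#' @rdname writeSourceSpace
#' @export
readSourceSpace <- function(prefix) {
    pos <- as.matrix(utils::read.table(paste0(prefix, "-positions.tsv"),
                                       header = TRUE, sep = "\t"))
    edges <- utils::read.table(paste0(prefix, "-edges.tsv"),
                               header = TRUE, sep = "\t")
    p <- nrow(pos)
    A <- Matrix::sparseMatrix(i = c(edges$i, edges$j),
                              j = c(edges$j, edges$i),
                              x = 1, dims = c(p, p))
    sourceSpace(pos, A)
}

#' Write / read a leadfield as delimited text
#'
#' The gain matrix is stored as TSV with channel names as row names.
#'
#' @param lead a \linkS4class{LeadField}.
#' @param file path of the TSV file.
#' @return \code{readLeadField} returns a \linkS4class{LeadField}.
#' @export
writeLeadField <- function(lead, file) {
    G <- gain(lead)
    rownames(G) <- channelNames(lead)
    utils::write.table(G, file, sep = "\t", col.names = FALSE)
    invisible(file)
}

#' @rdname writeLeadField
#' @export
readLeadField <- function(file) {
    tab <- utils::read.table(file, sep = "\t", row.names = 1L)
    leadField(as.matrix(tab), channelNames = rownames(tab))
}

#' Load a forward model from disk
#'
#' Accepts either (a) a directory containing \code{leadfield.tsv},
#' \code{space-positions.tsv} and \code{space-edges.tsv} in the formats of
#' [writeLeadField()] / [writeSourceSpace()] — the interchange layout any
#' M/EEG ecosystem can export its forward solution to (fixed-orientation
#' gain; for free-orientation forwards export the surface-normal component)
#' — or (b) an \code{.rds} file holding a list with elements \code{space}
#' and \code{lead} (or \code{gain} + \code{positions} + \code{adjacency}).
#'
#' @param path directory or \code{.rds} file.
#' @param maxOrder smoothness-dictionary depth to build (default 8).
#' @return a \linkS4class{ForwardModel}.
#' @export
readForward <- function(path, maxOrder = 8L) {
    if (dir.exists(path)) {
        lead <- readLeadField(file.path(path, "leadfield.tsv"))
        space <- readSourceSpace(file.path(path, "space"))
    } else if (grepl("\\.rds$", path, ignore.case = TRUE)) {
        obj <- readRDS(path)
        if (!is.null(obj$space) && !is.null(obj$lead)) {
            space <- obj$space
            lead <- obj$lead
        } else if (!is.null(obj$gain)) {
            space <- sourceSpace(obj$positions, obj$adjacency)
            lead <- leadField(obj$gain, obj$channel_names)
        } else stop("unrecognized forward .rds layout")
    } else stop("forward path must be a directory or an .rds file: ", path)
    forwardModel(space, lead, maxOrder = maxOrder)
}

#' Write a forward model to a directory
#'
#' @param forward a \linkS4class{ForwardModel}.
#' @param path output directory (created if needed).
#' @export
writeForward <- function(forward, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    writeLeadField(forward@lead, file.path(path, "leadfield.tsv"))
    writeSourceSpace(forward@space, file.path(path, "space"))
    invisible(path)
}
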