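#' Build a mesh adjacency matrix from triangles
#'
#' Two vertices are adjacent iff they co-occur in at least one triangle. This
#' is the neighbor structure used for patch growing and local-maxima
#' detection on triangulated cortical meshes.
#'
#' @param triangles list of integer triples of 0-based vertex indices (each
#'   a length-3 vector), or an n x 3 matrix of 0-based indices.
#' @param nVertices number of mesh vertices.
#' @return sparse binary symmetric \code{nVertices} x \code{nVertices}
#'   adjacency matrix with zero diagonal.
#' @examples
#' A <- buildAdjacency(list(c(0, 1, 2), c(1, 2, 3)), 4)
#' Matrix::rowSums(A)  # degree sequence 2, 3, 3, 2
#' @export
buildAdjacency <- function(triangles, nVertices) {
    if (is.matrix(triangles))
        triangles <- split(triangles, seq_len(nrow(triangles)))
    nVertices <- as.integer(nVertices)
    if (length(triangles)) {
        tri <- do.call(rbind, lapply(triangles, function(x) {
            x <- as.integer(x)
            if (length(x) != 3L)
                stop("each triangle must have exactly 3 vertex indices")
            x
        }))
        if (any(tri < 0L) || any(tri >= nVertices))
            stop("triangle vertex index out of range [0, nVertices)")
        ## all three undirected edges of each triangle, 1-based
        i <- c(tri[, 1L], tri[, 1L], tri[, 2L]) + 1L
        j <- c(tri[, 2L], tri[, 3L], tri[, 3L]) + 1L
        A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                                  dims = c(nVertices, nVertices))
        A@x[] <- 1  # collapse duplicate edge contributions to binary
        A <- Matrix::drop0(A)
    } else {
        A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(nVertices, nVertices))
    }
    A
}

#' Graph-distance neighborhoods by breadth-first search
#'
#' @param A sparse adjacency matrix.
#' @param center 1-based vertex index.
#' @param radius maximum graph distance.
#' @return integer vector of vertices within \code{radius} of \code{center}
#'   (including the center), in increasing index order.
#' @keywords internal
.graphNeighborhood <- function(A, center, radius) {
    reached <- logical(nrow(A))
    reached[center] <- TRUE
    frontier <- center
    d <- 0L
    while (d < radius && length(frontier)) {
        nb <- .neighborList(A, frontier)
        nb <- nb[!reached[nb]]
        reached[nb] <- TRUE
        frontier <- nb
        d <- d + 1L
    }
    which(reached)
}

#' Build the smoothness-operator dictionary
#'
#' Constructs patch-profile operators G_1, ..., G_K and the smoothed
#' leadfields L_k = L G_k. G_1 is the identity, so order 1 represents single
#' dipoles. For k >= 2 the default operator is the column-normalized
#' (k-1)-th power of (A + I): column j is then a nonnegative profile summing
#' to one and supported exactly on the dipoles within graph distance k - 1 of
#' j, with weight decaying from the center — a smooth patch of radius k - 1.
#'
#' The \code{operatorType = "literal"} variant instead uses the combinatorial
#' graph Laplacian for G_2 and G_k = G_{k-1} A for k > 2. Its columns are
#' neither nonnegative nor normalized and it is provided only for comparison
#' with that formulation; the localizer itself is scale-invariant per column.
#'
#' @param lead a \linkS4class{LeadField}.
#' @param space a \linkS4class{SourceSpace} with matching dipole count.
#' @param maxOrder largest smoothness order K (default 8).
#' @param operatorType \code{"normalized"} (default) or \code{"literal"}.
#' @return a \linkS4class{SmoothnessDictionary}.
#' @examples
#' syn <- synthesizeSourceSpace(1, 70, seed = 1)
#' dict <- buildSmoothnessDictionary(syn$lead, syn$space, maxOrder = 3)
#' maxOrder(dict)
#' @export
buildSmoothnessDictionary <- function(lead, space, maxOrder = 8L,
                                      operatorType = c("normalized",
                                                       "literal")) {
    operatorType <- match.arg(operatorType)
    maxOrder <- as.integer(maxOrder)
    if (maxOrder < 1L) stop("maxOrder must be >= 1")
    p <- nDipoles(space)
    if (ncol(gain(lead)) != p)
        stop("leadfield and source space have different dipole counts")
    A <- adjacency(space)
    I <- Matrix::Diagonal(p)
    ops <- vector("list", maxOrder)
    ops[[1L]] <- I
    if (maxOrder > 1L) {
        if (operatorType == "normalized") {
            W <- A + I
            Gk <- I
            for (k in 2:maxOrder) {
                Gk <- W %*% Gk            # support radius grows by 1 per order
                cs <- Matrix::colSums(Gk)
                ops[[k]] <- Gk %*% Matrix::Diagonal(p, 1 / cs)
            }
        } else {
            ## literal formulation: G2 = Laplacian(A), Gk = G_{k-1} A
            deg <- Matrix::rowSums(A)
            G <- Matrix::Diagonal(p, deg) - A
            ops[[2L]] <- G
            if (maxOrder > 2L)
                for (k in 3:maxOrder) {
                    G <- G %*% A
                    ops[[k]] <- G
                }
        }
    }
    L <- gain(lead)
    gains <- lapply(ops, function(G) as.matrix(L %*% G))
    new("SmoothnessDictionary", operators = ops, smoothedGains = gains,
        maxOrder = maxOrder)
}

## vertices and faces (0-based) of a unit icosahedron
.icosahedron <- function() {
    phi <- (1 + sqrt(5)) / 2
    v <- rbind(
        c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
        c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
        c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
    v <- v / sqrt(rowSums(v^2))
    f <- rbind(
        c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
        c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
        c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
        c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
    list(vertices = v, faces = f)
}

## one 4-to-1 triangle subdivision step with midpoint deduplication
.subdivide <- function(vertices, faces) {
    midCache <- new.env(hash = TRUE)
    verts <- vertices
    midpoint <- function(a, b) {
        key <- paste(min(a, b), max(a, b))
        idx <- midCache[[key]]
        if (!is.null(idx)) return(idx)
        m <- (verts[a + 1L, ] + verts[b + 1L, ]) / 2
        m <- m / sqrt(sum(m^2))
        verts <<- rbind(verts, m)
        idx <- nrow(verts) - 1L
        midCache[[key]] <- idx
        idx
    }
    newFaces <- matrix(0L, nrow = 4L * nrow(faces), ncol = 3L)
    r <- 1L
    for (t in seq_len(nrow(faces))) {
        a <- faces[t, 1L]; b <- faces[t, 2L]; c <- faces[t, 3L]
        ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
        newFaces[r, ] <- c(a, ab, ca)
        newFaces[r + 1L, ] <- c(b, bc, ab)
        newFaces[r + 2L, ] <- c(c, ca, bc)
        newFaces[r + 3L, ] <- c(ab, bc, ca)
        r <- r + 4L
    }
    list(vertices = verts, faces = newFaces)
}

## roughly uniform points on a sphere (Fibonacci lattice)
.fibonacciSphere <- function(n, radius) {
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    theta <- pi * (1 + sqrt(5)) * i
    radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Synthesize a spherical source space with a plausible leadfield
#'
#' Builds an icosphere source mesh (recursively subdivided icosahedron,
#' yielding 10 * 4^s + 2 dipoles at subdivision s) scaled to the requested
#' radius, and a synthetic EEG-like leadfield: 64 virtual sensors on a
#' concentric sphere at 1.35 x the source radius, each dipole radially
#' oriented (perpendicular to the spherical surface) with a smooth
#' distance-decaying sensitivity profile and small seeded gain perturbations
#' emulating instrumental heterogeneity. The result is a geometrically
#' plausible stand-in for a BEM forward model, suitable for simulation
#' benchmarks; it is synthetic and not tied to any head anatomy.
#'
#' @param subdivisions number of icosahedral subdivision steps (>= 0).
#' @param radiusMm source sphere radius in mm.
#' @param seed integer seed for the gain perturbations.
#' @param nSensors number of virtual sensors (default 64).
#' @return list with elements \code{space} (\linkS4class{SourceSpace}),
#'   \code{lead} (\linkS4class{LeadField}) and \code{faces} (0-based
#'   triangle matrix).
#' @examples
#' syn <- synthesizeSourceSpace(0, 70, seed = 1)
#' nDipoles(syn$space)  # 12 (icosahedron)
#' @export
synthesizeSourceSpace <- function(subdivisions, radiusMm = 70, seed = 1L,
                                  nSensors = 64L) {
    if (subdivisions < 0L) stop("subdivisions must be >= 0")
    mesh <- .icosahedron()
    s <- 0L
    while (s < subdivisions) {
        mesh <- .subdivide(mesh$vertices, mesh$faces)
        s <- s + 1L
    }
    pos <- mesh$vertices * radiusMm
    A <- buildAdjacency(mesh$faces, nrow(pos))
    space <- sourceSpace(pos, A, checkConnected = FALSE)

    sensors <- .fibonacciSphere(nSensors, 1.35 * radiusMm)
    p <- nrow(pos)
    q <- nrow(sensors)
    ## radial dipole orientation; sensitivity falls off with squared distance
    ## and scales with the cosine between dipole axis and sensor direction
    G <- matrix(0, q, p)
    r0 <- 0.35 * radiusMm
    for (j in seq_len(p)) {
        dvec <- sweep(sensors, 2L, pos[j, ])
        d2 <- rowSums(dvec^2)
        nrm <- pos[j, ] / sqrt(sum(pos[j, ]^2))
        cosang <- as.numeric(dvec %*% nrm) / sqrt(d2)
        G[, j] <- (1 + cosang) / (d2 + r0^2)
    }
    G <- G * radiusMm^2          # keep entries O(1)
    old <- .seedSwap(seed)
    on.exit(.seedRestore(old))
    G <- G * (1 + 0.02 * matrix(stats::rnorm(q * p), q, p))
    list(space = space,
         lead = leadField(G),
         faces = mesh$faces)
}

## save/restore the global RNG state around seeded helpers
.seedSwap <- function(seed) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    old
}

.seedRestore <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
    } else {
        assign(".Random.seed", old, envir = globalenv())
    }
}
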