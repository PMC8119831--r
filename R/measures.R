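## Graph-measure layer.  Degree, strength and Onnela clustering are computed
## directly on the weight matrix; shortest-path distances and betweenness
## centrality run through igraph (Dijkstra / weighted Brandes) on edge
## lengths d_ij = 1 / w_ij, the conventional mapping for FA-weighted
## connectomes (stronger connection = shorter distance).

.asIgraph <- function(w) {
    ## edge-list construction: much cheaper than graph_from_adjacency_matrix,
    ## which re-checks symmetry on every call
    el <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    g <- igraph::make_empty_graph(nrow(w), directed = FALSE)
    g <- igraph::add_edges(g, as.vector(t(el)))
    igraph::E(g)$weight <- w[el]
    g
}

.getW <- function(net) if (is(net, "WeightedNetwork")) net@weights else net

#' Nodal degree
#'
#' Number of edges incident to each node, computed on the binarized
#' network.
#'
#' @param net a [WeightedNetwork-class] or weight matrix.
#' @return named numeric vector, one value per node.
#' @rdname nodeDegree
#' @export
setMethod("nodeDegree", "WeightedNetwork", function(net) nodeDegree(net@weights))

#' @rdname nodeDegree
#' @export
setMethod("nodeDegree", "matrix", function(net) rowSums(net > 0))

#' Nodal strength
#'
#' Sum of the weights of the edges incident to each node.
#'
#' @param net a [WeightedNetwork-class] or weight matrix.
#' @return named numeric vector, one value per node.
#' @rdname nodeStrength
#' @export
setMethod("nodeStrength", "WeightedNetwork", function(net) nodeStrength(net@weights))

#' @rdname nodeStrength
#' @export
setMethod("nodeStrength", "matrix", function(net) rowSums(net))

#' Weighted local clustering coefficient (Onnela)
#'
#' With weights rescaled by the network maximum, \eqn{\hat w = w / \max(w)},
#' \deqn{C_i = \frac{1}{k_i (k_i - 1)} \sum_{j,h}
#'       (\hat w_{ij} \hat w_{ih} \hat w_{jh})^{1/3},}
#' the geometric-mean form of the weighted clustering coefficient (the
#' Brain Connectivity Toolbox default).  `C_i = 0` for nodes of degree
#' below 2.
#'
#' @param net a [WeightedNetwork-class] or weight matrix.
#' @return named numeric vector in `[0, 1]`.
#' @rdname localClustering
#' @export
setMethod("localClustering", "WeightedNetwork",
          function(net) localClustering(net@weights))

#' @rdname localClustering
#' @export
setMethod("localClustering", "matrix", function(net) {
    k <- rowSums(net > 0)
    mx <- max(net)
    if (mx == 0) return(setNames(numeric(nrow(net)), rownames(net)))
    w3 <- (net / mx)^(1 / 3)
    cyc <- diag(w3 %*% w3 %*% w3)   # sum over closed weighted triples at i
    ci <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
    setNames(ci, rownames(net))
})

#' Shortest-path distance matrix
#'
#' Dijkstra shortest paths over edge lengths \eqn{d_{ij} = 1 / w_{ij}}.
#' Unreachable pairs are `Inf`; the diagonal is 0.
#'
#' @param net a [WeightedNetwork-class] or weight matrix.
#' @return symmetric distance matrix.
#' @rdname shortestPathDistances
#' @export
setMethod("shortestPathDistances", "WeightedNetwork",
          function(net) shortestPathDistances(net@weights))

#' @rdname shortestPathDistances
#' @export
setMethod("shortestPathDistances", "matrix", function(net) {
    g <- .asIgraph(net)
    wts <- igraph::E(g)$weight
    d <- igraph::distances(g, weights = if (length(wts)) 1 / wts else NULL)
    dimnames(d) <- dimnames(net)
    d
})

#' Nodal shortest path length
#'
#' Mean shortest-path distance from each node to the nodes it can reach.
#' A node reaching no other node gets 0 with a warning.
#'
#' @param distances a distance matrix from [shortestPathDistances()].
#' @return named numeric vector.
#' @export
nodalPathLength <- function(distances) {
    n <- nrow(distances)
    out <- vapply(seq_len(n), function(i) {
        d <- distances[i, -i]
        d <- d[is.finite(d)]
        if (!length(d)) NA_real_ else mean(d)
    }, numeric(1))
    if (anyNA(out)) {
        warning(sum(is.na(out)), " node(s) reach no other node; ",
                "nodal path length set to 0")
        out[is.na(out)] <- 0
    }
    setNames(out, rownames(distances))
}

#' Betweenness centrality
#'
#' Brandes betweenness on edge lengths \eqn{1 / w}: the number of weighted
#' shortest paths passing through each node, with equal-length path
#' multiplicities shared fractionally.  Unnormalized; on an undirected
#' network each unordered source-target pair is counted once, so the star
#' center of an n-node star scores \eqn{(n-1)(n-2)/2}.
#'
#' @param net a [WeightedNetwork-class] or weight matrix.
#' @return named numeric vector.
#' @rdname betweennessCentrality
#' @export
setMethod("betweennessCentrality", "WeightedNetwork",
          function(net) betweennessCentrality(net@weights))

#' @rdname betweennessCentrality
#' @export
setMethod("betweennessCentrality", "matrix", function(net) {
    g <- .asIgraph(net)
    wts <- igraph::E(g)$weight
    bc <- igraph::betweenness(g, directed = FALSE,
                              weights = if (length(wts)) 1 / wts else NULL)
    setNames(as.numeric(bc), rownames(net))
})

#' Global network measures (raw fields)
#'
#' Aggregates the local measures into the raw global measures: mean degree,
#' mean strength, clustering coefficient (mean local clustering),
#' characteristic path length `L` (mean of the finite off-diagonal
#' distances) and global efficiency `E_glob` (mean over ordered node pairs
#' of `1 / d`, with unreachable pairs contributing 0).  The normalized
#' fields (`gamma`, `lambda`, `normEglob`, `sigma`) are `NA` until
#' [normalizeGlobals()] fills them.
#'
#' @param net a [WeightedNetwork-class] or weight matrix.
#' @param distances optional precomputed distance matrix.
#' @param locals optional precomputed list with elements `degree`,
#'   `strength`, `clustering`.
#' @return named numeric vector with elements `meanDegree`, `meanStrength`,
#'   `clustering`, `pathLength`, `globalEfficiency`, `gamma`, `lambda`,
#'   `normEglob`, `sigma`.
#' @examples
#' w <- matrix(1, 3, 3); diag(w) <- 0
#' globalMeasures(w)[c("pathLength", "globalEfficiency")]  # both 1
#' @export
globalMeasures <- function(net, distances = NULL, locals = NULL) {
    w <- .getW(net)
    if (is.null(distances)) distances <- shortestPathDistances(w)
    if (is.null(locals))
        locals <- list(degree = nodeDegree(w), strength = nodeStrength(w),
                       clustering = localClustering(w))
    off <- distances[row(distances) != col(distances)]
    finite <- off[is.finite(off)]
    if (!length(finite)) {
        warning("network has no connected node pair; ",
                "characteristic path length undefined (NA)")
        L <- NA_real_
    } else L <- mean(finite)
    eglob <- if (length(off)) mean(ifelse(is.finite(off), 1 / off, 0)) else 0
    c(meanDegree = mean(locals$degree), meanStrength = mean(locals$strength),
      clustering = mean(locals$clustering), pathLength = L,
      globalEfficiency = eglob, gamma = NA_real_, lambda = NA_real_,
      normEglob = NA_real_, sigma = NA_real_)
}

## One raw global measure straight from the weight matrix, skipping whatever
## the caller does not need (the cohort generator calls this per subject).
.globalValue <- function(w, name) {
    switch(name,
        meanDegree = mean(rowSums(w > 0)),
        meanStrength = mean(rowSums(w)),
        clustering = mean(localClustering(w)),
        globalEfficiency = ,
        pathLength = {
            d <- shortestPathDistances(w)
            off <- d[row(d) != col(d)]
            if (name == "globalEfficiency")
                mean(ifelse(is.finite(off), 1 / off, 0))
            else {
                fin <- off[is.finite(off)]
                if (length(fin)) mean(fin) else NA_real_
            }
        },
        stop("unknown raw global measure: ", name))
}

#' All local and global measures for one network
#'
#' @param net a [WeightedNetwork-class].
#' @return list with `local` (data.frame: label, degree, strength,
#'   clustering, pathLength, betweenness) and `global` (see
#'   [globalMeasures()]).
#' @export
computeMeasures <- function(net) {
    w <- .getW(net)
    d <- shortestPathDistances(w)
    loc <- list(degree = nodeDegree(w), strength = nodeStrength(w),
                clustering = localClustering(w))
    localDf <- data.frame(
        label = rownames(w), degree = as.numeric(loc$degree),
        strength = as.numeric(loc$strength),
        clustering = as.numeric(loc$clustering),
        pathLength = as.numeric(suppressWarnings(nodalPathLength(d))),
        betweenness = as.numeric(betweennessCentrality(w)),
        row.names = NULL)
    list(local = localDf, global = globalMeasures(w, distances = d, locals = loc))
}
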