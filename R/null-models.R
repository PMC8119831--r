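#' Specify a random-graph ensemble
#'
#' @param nGraphs number of degree-preserving random graphs averaged over;
#'   default 100.
#' @param swapsPerEdge double-edge-swap attempts per edge; default 10, the
#'   standard mixing heuristic.
#' @param seed integer seed making the ensemble reproducible.
#' @return a [NullEnsembleSpec-class].
#' @export
nullEnsembleSpec <- function(nGraphs = 100L, swapsPerEdge = 10L, seed = 1L) {
    new("NullEnsembleSpec", nGraphs = as.integer(nGraphs),
        swapsPerEdge = as.integer(swapsPerEdge), seed = as.integer(seed))
}

setMethod("show", "NullEnsembleSpec", function(object) {
    cat(sprintf("NullEnsembleSpec: %d graphs, %d swaps/edge, seed %d\n",
                object@nGraphs, object@swapsPerEdge, object@seed))
})

.edgeList <- function(w) {
    ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    list(edges = ut, weights = w[ut])
}

#' Degree-preserving rewiring (Maslov-Sneppen)
#'
#' Randomizes the topology of a network by repeated double-edge swaps
#' (a-b, c-d becomes a-d, c-b), rejecting swaps that would create
#' self-loops or multi-edges.  `swapsPerEdge * m` swap attempts are made
#' (m = edge count); an attempt that finds no legal swap within 100 random
#' tries is skipped and counted.  Edge weights travel with the rewired
#' edges, so the number of nodes, the number of edges, the degree sequence
#' and the multiset of edge weights are all preserved exactly.
#'
#' @param net a [WeightedNetwork-class] (or weight matrix).
#' @param swapsPerEdge swap attempts per edge; default 10.
#' @param seed integer seed; when `NULL` one is drawn from R's RNG.
#' @return a rewired network of the same class, with attribute
#'   `"skippedSwaps"` on its weight matrix giving the skip count.
#' @rdname rewireDegreePreserving
#' @export
setMethod("rewireDegreePreserving", "WeightedNetwork",
    function(net, swapsPerEdge = 10L, seed = NULL) {
        w <- rewireDegreePreserving(net@weights, swapsPerEdge, seed)
        out <- weightedNetwork(w, labels = rownames(net@weights))
        attr(out@weights, "skippedSwaps") <- attr(w, "skippedSwaps")
        out
    })

#' @rdname rewireDegreePreserving
#' @export
setMethod("rewireDegreePreserving", "matrix",
    function(net, swapsPerEdge = 10L, seed = NULL) {
        el <- .edgeList(net)
        m <- nrow(el$edges)
        if (m < 2L) {
            warning("network has fewer than 2 edges; returned unchanged")
            attr(net, "skippedSwaps") <- 0L
            return(net)
        }
        if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
        res <- rewire_edges_cpp(el$edges - 1L, nrow(net),
                                as.integer(swapsPerEdge) * m, 100L,
                                as.double(seed))
        e <- res$edges + 1L
        out <- matrix(0, nrow(net), ncol(net), dimnames = dimnames(net))
        out[e] <- el$weights
        out[e[, 2:1, drop = FALSE]] <- el$weights
        attr(out, "skippedSwaps") <- res$skipped
        out
    })

## clustering mean / characteristic path length / global efficiency of one
## weight matrix -- the three quantities the null ensemble averages.
.cleStats <- function(w) {
    d <- shortestPathDistances(w)
    off <- d[row(d) != col(d)]
    fin <- off[is.finite(off)]
    c(C = mean(localClustering(w)),
      L = if (length(fin)) mean(fin) else NA_real_,
      E = if (length(off)) mean(ifelse(is.finite(off), 1 / off, 0)) else 0)
}

#' Normalize global measures against a random-graph ensemble
#'
#' Scales the raw clustering coefficient, characteristic path length and
#' global efficiency of a network against their mean values over
#' `spec@nGraphs` matched random graphs that preserve the number of nodes,
#' the number of edges and the degree sequence (degree-preserving
#' rewiring; weights travel with the edges so the weight multiset is also
#' matched):
#' \deqn{\gamma = C / \langle C_{rand}\rangle,\quad
#'       \lambda = L / \langle L_{rand}\rangle,\quad
#'       E_{glob}^{norm} = E_{glob} / \langle E_{glob,rand}\rangle,\quad
#'       \sigma = \gamma / \lambda.}
#'
#' @param net a [WeightedNetwork-class] or weight matrix.
#' @param raw optional raw [globalMeasures()] vector for `net` (computed if
#'   missing).
#' @param spec a [NullEnsembleSpec-class]; per-graph seeds are derived from
#'   `spec@seed` so the ensemble is reproducible.
#' @param verbose emit a summary message per call.
#' @return the [globalMeasures()] vector with `gamma`, `lambda`,
#'   `normEglob` and `sigma` filled; attribute `"ensembleStats"` holds the
#'   ensemble means/SDs and total skipped swaps.  If an ensemble mean is 0
#'   the corresponding normalized value is `NA` with a warning.
#' @export
normalizeGlobals <- function(net, raw = NULL, spec = nullEnsembleSpec(),
                             verbose = FALSE) {
    w <- .getW(net)
    if (is.null(raw)) raw <- globalMeasures(w)
    seeds <- .withSeed(spec@seed,
                       sample.int(.Machine$integer.max - 1L, spec@nGraphs))
    stats <- matrix(NA_real_, spec@nGraphs, 3,
                    dimnames = list(NULL, c("C", "L", "E")))
    skipped <- 0L
    for (i in seq_len(spec@nGraphs)) {
        r <- rewireDegreePreserving(w, spec@swapsPerEdge, seed = seeds[i])
        skipped <- skipped + attr(r, "skippedSwaps")
        stats[i, ] <- .cleStats(r)
    }
    mns <- colMeans(stats)
    sds <- apply(stats, 2, sd)
    normOne <- function(val, mn, what) {
        if (!is.finite(mn) || mn == 0) {
            warning("ensemble mean of ", what,
                    " is 0 or undefined; normalized value set to NA")
            return(NA_real_)
        }
        val / mn
    }
    raw["gamma"] <- normOne(raw[["clustering"]], mns[["C"]], "clustering")
    raw["lambda"] <- normOne(raw[["pathLength"]], mns[["L"]], "path length")
    raw["normEglob"] <- normOne(raw[["globalEfficiency"]], mns[["E"]],
                                "global efficiency")
    raw["sigma"] <- raw[["gamma"]] / raw[["lambda"]]
    attr(raw, "ensembleStats") <- data.frame(
        measure = c("clustering", "pathLength", "globalEfficiency"),
        mean = as.numeric(mns), sd = as.numeric(sds), n = spec@nGraphs,
        skippedSwaps = skipped)
    if (verbose)
        message(sprintf(
            "null ensemble (%d graphs): <C>=%.4g <L>=%.4g <E>=%.4g, %d skipped swaps",
            spec@nGraphs, mns[["C"]], mns[["L"]], mns[["E"]], skipped))
    raw
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's state afterwards.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else on.exit(rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}
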