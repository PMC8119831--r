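#' Construct a SubjectRaw object
#'
#' @param id subject identifier.
#' @param counts symmetric non-negative integer streamline-count matrix.
#' @param meanFA symmetric mean-FA matrix in `[0, 1]`, zero where `counts`
#'   is zero.
#' @param volumes positive per-node volumes (mm^3).
#' @param icv intracranial volume (mm^3).
#' @param labels optional node labels used for dimnames (defaults to
#'   existing dimnames or `V1..Vn`).
#' @return a [SubjectRaw-class] object.
#' @export
subjectRaw <- function(id, counts, meanFA, volumes, icv, labels = NULL) {
    if (is.null(labels))
        labels <- if (!is.null(rownames(counts))) rownames(counts)
                  else paste0("V", seq_len(nrow(counts)))
    dimnames(counts) <- dimnames(meanFA) <- list(labels, labels)
    names(volumes) <- labels
    new("SubjectRaw", id = as.character(id), counts = counts,
        meanFA = meanFA, volumes = volumes, icv = icv)
}

#' Construct a WeightedNetwork from a weight matrix
#'
#' @param weights symmetric non-negative matrix with zero diagonal.
#' @param labels optional node labels.
#' @return a [WeightedNetwork-class] object.
#' @export
weightedNetwork <- function(weights, labels = NULL) {
    if (!is.null(labels)) dimnames(weights) <- list(labels, labels)
    else if (is.null(rownames(weights))) {
        labels <- paste0("V", seq_len(nrow(weights)))
        dimnames(weights) <- list(labels, labels)
    }
    new("WeightedNetwork", weights = weights)
}

#' @rdname edgeWeights
#' @param x a [WeightedNetwork-class].
#' @return the symmetric weight matrix.
#' @export
setMethod("edgeWeights", "WeightedNetwork", function(x) x@weights)

#' @rdname nNodes
#' @export
setMethod("nNodes", "WeightedNetwork", function(x) nrow(x@weights))

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "WeightedNetwork", function(x) rownames(x@weights))

setMethod("show", "WeightedNetwork", function(object) {
    w <- object@weights
    m <- sum(w[upper.tri(w)] > 0)
    cat(sprintf("WeightedNetwork: %d nodes, %d edges (density %.3f)\n",
                nrow(w), m, m / choose(nrow(w), 2)))
})

setMethod("show", "SubjectRaw", function(object) {
    cat(sprintf("SubjectRaw '%s': %d nodes, %d node pairs with >=1 streamline, ICV %.3g mm^3\n",
                object@id, nrow(object@counts),
                sum(object@counts[upper.tri(object@counts)] > 0), object@icv))
})

#' Build a subject's weighted structural network
#'
#' A node pair is treated as structurally connected when at least
#' `minStreamlines` streamlines connect it end-to-end (default 3, a
#' threshold guarding against false-positive connections of deterministic
#' tractography).  Retained edges are weighted by the mean FA along the
#' connecting streamlines multiplied by the streamline count, divided by
#' the average volume of the two regions to account for node size:
#' \deqn{w_{ij} = \mathrm{count}_{ij} \times \mathrm{FA}_{ij} /
#'       \big((v_i + v_j)/2\big).}
#'
#' @param raw a [SubjectRaw-class] object.
#' @param minStreamlines minimum streamline count (inclusive) for an edge
#'   to be retained; default 3.
#' @param weighting `"countTimesFA"` (default) multiplies mean FA by the
#'   streamline count; `"faOnly"` uses mean FA alone.  Both are divided by
#'   the average regional volume.
#' @return a [WeightedNetwork-class] over the same nodes.
#' @examples
#' counts <- matrix(0, 3, 3); counts[1, 2] <- counts[2, 1] <- 4
#' fa <- matrix(0, 3, 3); fa[1, 2] <- fa[2, 1] <- 0.5
#' raw <- subjectRaw("s1", counts, fa, volumes = c(2, 2, 2), icv = 1.4e6)
#' edgeWeights(buildNetwork(raw))[1, 2]  # 4 * 0.5 / 2 = 1
#' @export
buildNetwork <- function(raw, minStreamlines = 3L,
                         weighting = c("countTimesFA", "faOnly")) {
    stopifnot(is(raw, "SubjectRaw"))
    weighting <- match.arg(weighting)
    if (minStreamlines < 1L) stop("minStreamlines must be >= 1")
    counts <- raw@counts   # validity enforced at construction
    keep <- counts >= minStreamlines
    base <- if (weighting == "countTimesFA") counts * raw@meanFA else raw@meanFA
    avgVol <- outer(raw@volumes, raw@volumes, "+") / 2
    w <- ifelse(keep, base / avgVol, 0)
    diag(w) <- 0
    weightedNetwork(w, labels = rownames(counts))
}

#' Binarize a weighted network
#'
#' @param net a [WeightedNetwork-class].
#' @return 0/1 adjacency matrix (symmetric, zero diagonal).
#' @rdname binarizeNetwork
#' @export
setMethod("binarizeNetwork", "WeightedNetwork",
          function(net) binarizeNetwork(net@weights))

#' @rdname binarizeNetwork
#' @export
setMethod("binarizeNetwork", "matrix", function(net) {
    a <- (net > 0) * 1
    diag(a) <- 0
    a
})
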