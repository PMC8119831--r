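#' @rdname nNodes
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nodeLabels
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname edgeWeights
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname nodeDegree
#' @export
setGeneric("nodeDegree", function(net) standardGeneric("nodeDegree"))

#' @rdname nodeStrength
#' @export
setGeneric("nodeStrength", function(net) standardGeneric("nodeStrength"))

#' @rdname localClustering
#' @export
setGeneric("localClustering", function(net) standardGeneric("localClustering"))

#' @rdname shortestPathDistances
#' @export
setGeneric("shortestPathDistances",
           function(net) standardGeneric("shortestPathDistances"))

#' @rdname betweennessCentrality
#' @export
setGeneric("betweennessCentrality",
           function(net) standardGeneric("betweennessCentrality"))

#' @rdname binarizeNetwork
#' @export
setGeneric("binarizeNetwork", function(net) standardGeneric("binarizeNetwork"))

#' @rdname rewireDegreePreserving
#' @export
setGeneric("rewireDegreePreserving",
           function(net, swapsPerEdge = 10L, seed = NULL)
               standardGeneric("rewireDegreePreserving"))
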