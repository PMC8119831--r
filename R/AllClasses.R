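## Central S4 data containers.  Validity methods enforce the structural
## contracts every downstream computation assumes (symmetry, zero diagonals,
## FA range, matching dimensions), so errors surface at construction rather
## than deep inside a measure or model fit.

.checkSquareSymmetric <- function(m, what, tol = 1e-8) {
    msgs <- character()
    if (!is.matrix(m) || !is.numeric(m))
        return(sprintf("'%s' must be a numeric matrix", what))
    if (nrow(m) != ncol(m))
        msgs <- c(msgs, sprintf("'%s' must be square", what))
    else {
        if (max(abs(m - t(m))) > tol)
            msgs <- c(msgs, sprintf("'%s' must be symmetric (tol %g)", what, tol))
        if (any(abs(diag(m)) > tol))
            msgs <- c(msgs, sprintf("'%s' must have a zero diagonal", what))
    }
    if (anyNA(m))
        msgs <- c(msgs, sprintf("'%s' contains missing values", what))
    msgs
}

#' Parcellation: the node scheme of the connectome
#'
#' An ordered set of brain parcels (nodes).  The default scheme
#' ([aalParcellation()]) has 92 nodes: the 45 AAL regions of each hemisphere
#' (including six subcortical regions) plus the bilateral substantia
#' innominata.
#'
#' @slot nodes a `data.frame` with columns `index` (1-based), `label`
#'   (unique region name, e.g. `"Caudate_L"`) and `hemisphere`
#'   (`"L"` or `"R"`).
#' @seealso [aalParcellation()], [nNodes()], [nodeLabels()]
#' @export
setClass("Parcellation", representation(nodes = "data.frame"))

setValidity("Parcellation", function(object) {
    nd <- object@nodes
    msgs <- character()
    need <- c("index", "label", "hemisphere")
    if (!all(need %in% names(nd)))
        return(paste("nodes must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(nd$label))
        msgs <- c(msgs, "node labels must be unique")
    if (!all(nd$hemisphere %in% c("L", "R")))
        msgs <- c(msgs, "hemisphere must be 'L' or 'R'")
    if (!identical(as.integer(nd$index), seq_len(nrow(nd))))
        msgs <- c(msgs, "index must be 1..n in order")
    if (length(msgs)) msgs else TRUE
})

#' SubjectRaw: one subject's raw connectome inputs
#'
#' Holds the tractography tallies a subject's network is built from: a
#' symmetric streamline-count matrix, the matrix of mean fractional
#' anisotropy (FA) along the streamlines of each connection, per-node gray
#' matter volumes, and intracranial volume (ICV).
#'
#' @slot id subject identifier.
#' @slot counts symmetric non-negative integer matrix of streamline counts,
#'   zero diagonal.
#' @slot meanFA symmetric matrix of mean FA in `[0, 1]`; zero wherever the
#'   corresponding count is zero.
#' @slot volumes positive per-node volumes (mm^3), named by node label.
#' @slot icv intracranial volume (mm^3).
#' @seealso [buildNetwork()], [generateCohort()]
#' @export
setClass("SubjectRaw", representation(
    id = "character", counts = "matrix", meanFA = "matrix",
    volumes = "numeric", icv = "numeric"))

setValidity("SubjectRaw", function(object) {
    msgs <- c(.checkSquareSymmetric(object@counts, "counts"),
              .checkSquareSymmetric(object@meanFA, "meanFA"))
    if (length(msgs)) return(msgs)
    n <- nrow(object@counts)
    if (!identical(dim(object@meanFA), dim(object@counts)))
        msgs <- c(msgs, "counts and meanFA dimensions differ")
    if (any(object@counts < 0) || max(abs(object@counts - round(object@counts))) > 1e-8)
        msgs <- c(msgs, "counts must be non-negative integers")
    if (any(object@meanFA < 0) || any(object@meanFA > 1))
        msgs <- c(msgs, "meanFA must lie in [0, 1]")
    if (any(object@meanFA[object@counts == 0] != 0))
        msgs <- c(msgs, "meanFA must be 0 wherever counts are 0")
    if (length(object@volumes) != n || any(!is.finite(object@volumes)) ||
        any(object@volumes <= 0))
        msgs <- c(msgs, "volumes must be positive, one per node")
    if (length(object@icv) != 1L || !is.finite(object@icv) || object@icv <= 0)
        msgs <- c(msgs, "icv must be a positive scalar")
    if (length(msgs)) msgs else TRUE
})

#' WeightedNetwork: a subject's weighted structural network
#'
#' A symmetric non-negative edge-weight matrix over the parcellation nodes
#' with zero diagonal, as produced by [buildNetwork()].  Node labels are
#' carried in the dimnames.
#'
#' @slot weights symmetric non-negative numeric matrix, zero diagonal.
#' @seealso [buildNetwork()], [nodeDegree()], [globalMeasures()]
#' @export
setClass("WeightedNetwork", representation(weights = "matrix"))

setValidity("WeightedNetwork", function(object) {
    msgs <- .checkSquareSymmetric(object@weights, "weights")
    if (!length(msgs) && any(object@weights < 0))
        msgs <- c(msgs, "weights must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' CohortConfig: parameters of the synthetic cohort generator
#'
#' Created by [cohortConfig()]; see that constructor for the meaning and
#' defaults of every component.
#'
#' @slot groupSizes named integer vector with components `control`,
#'   `pure_ADCI`, `pure_LBCI`, `mixed`.
#' @slot covariateParams per-group covariate distributions.
#' @slot effectParams list of planted multiplicative disease effects.
#' @slot cognitionParams linear model generating the 14 cognitive scores.
#' @slot templateParams parameters of the population base connectome.
#' @slot seed integer seed making the cohort fully reproducible.
#' @export
setClass("CohortConfig", representation(
    groupSizes = "integer", covariateParams = "list", effectParams = "list",
    cognitionParams = "list", templateParams = "list", seed = "integer"))

setValidity("CohortConfig", function(object) {
    msgs <- character()
    gs <- object@groupSizes
    if (!identical(names(gs), c("control", "pure_ADCI", "pure_LBCI", "mixed")))
        msgs <- c(msgs, "groupSizes must be named control, pure_ADCI, pure_LBCI, mixed")
    if (any(gs < 0)) msgs <- c(msgs, "group sizes must be non-negative")
    for (eff in object@effectParams) {
        sc <- c(eff$countScale, eff$faScale)
        if (any(sc <= 0 | sc > 1.5))
            msgs <- c(msgs, "effect scalings must lie in (0, 1.5]")
        if (!eff$flag %in% c("adci", "lbci", "interaction"))
            msgs <- c(msgs, "effect flag must be 'adci', 'lbci' or 'interaction'")
    }
    if (!is.null(object@cognitionParams$noiseSD) &&
        any(object@cognitionParams$noiseSD <= 0))
        msgs <- c(msgs, "cognition noise SD must be > 0")
    for (g in names(object@covariateParams)) {
        cp <- object@covariateParams[[g]]
        for (w in c("dwmh", "pwmh")) {
            pr <- cp[[w]]
            if (length(pr) != 3L || any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
                msgs <- c(msgs, sprintf(
                    "%s/%s must be a probability vector over ordinal levels 1..3", g, w))
        }
    }
    if (length(object@seed) != 1L || is.na(object@seed))
        msgs <- c(msgs, "seed must be a single integer")
    if (length(msgs)) msgs else TRUE
})

#' NullEnsembleSpec: how to build the random-graph ensemble
#'
#' @slot nGraphs number of degree-preserving random graphs the normalization
#'   averages over (default 100).
#' @slot swapsPerEdge double-edge-swap attempts per edge when randomizing
#'   (default 10).
#' @slot seed integer seed for the ensemble.
#' @seealso [nullEnsembleSpec()], [normalizeGlobals()]
#' @export
setClass("NullEnsembleSpec", representation(
    nGraphs = "integer", swapsPerEdge = "integer", seed = "integer"))

setValidity("NullEnsembleSpec", function(object) {
    msgs <- character()
    if (object@nGraphs < 1L) msgs <- c(msgs, "nGraphs must be >= 1")
    if (object@swapsPerEdge < 1L) msgs <- c(msgs, "swapsPerEdge must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' GlmFit: a fitted ordinary-least-squares general linear model
#'
#' Returned by [fitGlm()] and the disease-effect wrappers.  Coefficient
#' vectors are aligned with `predictors` (intercept first).
#'
#' @slot outcome name of the modeled outcome.
#' @slot predictors predictor names, `"(Intercept)"` first.
#' @slot coefficients,se,tstat,pvalue per-predictor estimates, standard
#'   errors, t statistics and two-sided p-values.
#' @slot n number of rows used after listwise deletion.
#' @slot df residual degrees of freedom.
#' @slot rss residual sum of squares.
#' @slot aic Gaussian OLS Akaike information criterion,
#'   `n * log(rss / n) + 2 * k` with `k` the number of coefficients.
#' @slot nDropped rows removed by listwise deletion.
#' @export
setClass("GlmFit", representation(
    outcome = "character", predictors = "character", coefficients = "numeric",
    se = "numeric", tstat = "numeric", pvalue = "numeric", n = "integer",
    df = "integer", rss = "numeric", aic = "numeric", nDropped = "integer"))

setValidity("GlmFit", function(object) {
    k <- length(object@predictors)
    if (length(object@coefficients) != k || length(object@se) != k ||
        length(object@pvalue) != k)
        return("coefficient vectors must align with predictors")
    TRUE
})

#' ConnectomeExperiment: cohort-level measures plus metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay per local
#' network measure (`degree`, `strength`, `clustering`, `pathLength`,
#' `betweenness`; nodes as rows, subjects as columns), the parcellation as
#' `rowData`, and the cohort table — covariates, disease flags, the nine
#' global network measures and the 14 cognitive scores — as `colData`.
#' Built by [measureCohort()].
#'
#' @export
setClass("ConnectomeExperiment", contains = "SummarizedExperiment")
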