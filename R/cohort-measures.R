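#' Measure a cohort of networks into a ConnectomeExperiment
#'
#' Computes the five local measures (degree, strength, clustering, nodal
#' path length, betweenness) and the nine global measures for every
#' subject and assembles them into a [ConnectomeExperiment-class]: one
#' assay per local measure (nodes x subjects), the parcellation as row
#' metadata, and the cohort table, global measures and cognition as column
#' metadata.  When `nullSpec` is supplied the normalized global measures
#' (gamma, lambda, normalized E_glob, sigma) are computed per subject
#' against a degree-preserving random-graph ensemble, with the per-subject
#' ensemble seed derived deterministically from `nullSpec@seed` and the
#' subject index so cohorts are reproducible.
#'
#' @param networks named list of [WeightedNetwork-class], one per subject.
#' @param cohort cohort data.frame (one row per subject, in the same
#'   order); must contain `subject_id`.
#' @param parc a [Parcellation-class]; default [aalParcellation()].
#' @param nullSpec optional [NullEnsembleSpec-class]; when `NULL` the
#'   normalized global fields are left `NA`.
#' @param verbose log a line per subject during normalization.
#' @return a [ConnectomeExperiment-class].
#' @export
measureCohort <- function(networks, cohort, parc = aalParcellation(),
                          nullSpec = NULL, verbose = FALSE) {
    stopifnot(length(networks) == nrow(cohort), "subject_id" %in% names(cohort))
    N <- length(networks)
    n <- nNodes(parc)
    localNames <- c("degree", "strength", "clustering", "pathLength",
                    "betweenness")
    assaysL <- lapply(localNames, function(x)
        matrix(NA_real_, n, N, dimnames = list(nodeLabels(parc),
                                               cohort$subject_id)))
    names(assaysL) <- localNames
    globals <- matrix(NA_real_, N, 9)
    subjectSeeds <- if (!is.null(nullSpec))
        .withSeed(nullSpec@seed, sample.int(.Machine$integer.max - 1L, N))
    for (i in seq_len(N)) {
        ms <- computeMeasures(networks[[i]])
        for (x in localNames) assaysL[[x]][, i] <- ms$local[[x]]
        g <- ms$global
        if (!is.null(nullSpec)) {
            subSpec <- nullEnsembleSpec(nullSpec@nGraphs, nullSpec@swapsPerEdge,
                                        subjectSeeds[i])
            g <- normalizeGlobals(networks[[i]], raw = g, spec = subSpec,
                                  verbose = verbose)
        }
        if (i == 1L) colnames(globals) <- names(g)
        globals[i, ] <- as.numeric(g)
    }
    cd <- DataFrame(cohort, check.names = FALSE)
    for (j in colnames(globals)) cd[[j]] <- globals[, j]
    se <- SummarizedExperiment(
        assays = assaysL, colData = cd,
        rowData = DataFrame(parc@nodes))
    new("ConnectomeExperiment", se)
}

setMethod("show", "ConnectomeExperiment", function(object) {
    cat("ConnectomeExperiment:", nrow(object), "nodes x", ncol(object),
        "subjects\n")
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
    if ("group" %in% names(colData(object))) {
        tb <- table(colData(object)$group)
        cat("  groups:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
    }
    cat("  normalized globals:",
        if (all(is.na(colData(object)$lambda))) "absent" else "present", "\n")
})

#' Simulate, build and measure a whole cohort in one call
#'
#' Convenience wrapper: [generateCohort()], [buildNetwork()] per subject,
#' then [measureCohort()].
#'
#' @param config a [CohortConfig-class].
#' @param parc a [Parcellation-class].
#' @param minStreamlines edge-retention threshold; default 3.
#' @param nullSpec optional [NullEnsembleSpec-class] for normalized
#'   globals.
#' @param verbose passed to [measureCohort()].
#' @return a [ConnectomeExperiment-class].
#' @export
simulateExperiment <- function(config, parc = aalParcellation(),
                               minStreamlines = 3L, nullSpec = NULL,
                               verbose = FALSE) {
    coh <- generateCohort(config, parc, minStreamlines = minStreamlines)
    nets <- lapply(coh$subjects, buildNetwork, minStreamlines = minStreamlines)
    measureCohort(nets, coh$cohort, parc, nullSpec = nullSpec,
                  verbose = verbose)
}
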