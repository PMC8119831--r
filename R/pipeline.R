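## End-to-end orchestration: simulate (or load) -> construct -> measure ->
## normalize -> infer, with stable file outputs and a machine-readable run
## manifest.  No timestamps are written, so reruns with an identical config
## are byte-identical.

#' Wide per-subject measure table
#'
#' One row per subject: `subject_id`, the 5 x nNodes local measures as
#' columns `<measure>_<node-label>`, then the nine global measures.
#'
#' @param ce a [ConnectomeExperiment-class].
#' @return data.frame with `1 + 5 * nNodes + 9` columns.
#' @export
measureTable <- function(ce) {
    out <- data.frame(subject_id = colnames(ce))
    for (m in assayNames(ce)) {
        a <- t(assay(ce, m))
        colnames(a) <- paste(m, colnames(a), sep = "_")
        out <- cbind(out, a)
    }
    glob <- c("meanDegree", "meanStrength", "clustering", "pathLength",
              "globalEfficiency", "gamma", "lambda", "normEglob", "sigma")
    cd <- cohortTable(ce)
    out <- cbind(out, cd[, glob])
    rownames(out) <- NULL
    out
}

.asCohortConfig <- function(block) {
    if (is(block, "CohortConfig")) return(block)
    if (!is.null(block$groupSizes))
        block$groupSizes <- unlist(block$groupSizes)
    do.call(cohortConfig, block)
}

#' Run the full analysis pipeline
#'
#' Composes the whole analysis: obtain raw subject data (from the
#' simulate block *or* from input files — exactly one must be present),
#' build each subject's weighted network, compute local/global measures,
#' normalize the globals against degree-preserving random graphs, and fit
#' the disease-effect and cognition GLMs.  Writes into `outDir`:
#' `cohort.csv`, `measures.csv` (wide per-subject table),
#' `global_effects.csv`, `local_effects_<measure>.csv` for the five local
#' measures, `cognition_<predictor>.csv` (Model 1 and Model 2 rows), and
#' `manifest.json` recording seeds, versions, and model-selection
#' rationale.
#'
#' @param config named list (or path to a YAML/JSON file readable by
#'   [readRunConfig()]) with components:
#'   \describe{
#'     \item{simulate}{[cohortConfig()] arguments for a synthetic cohort.}
#'     \item{inputs}{`list(dir =, cohort =)` pointing at per-subject TSVs
#'       ([readSubjectRaw()]) and a cohort CSV.}
#'     \item{minStreamlines}{edge-retention threshold; default 3.}
#'     \item{nullEnsemble}{[nullEnsembleSpec()] arguments, or `FALSE` to
#'       skip normalization.}
#'     \item{stats}{`list(interaction = "screen"|"always"|"never",
#'       cognitionPredictors =, model2Flag =)`.}
#'   }
#' @param outDir output directory (created if needed).
#' @param parc a [Parcellation-class].
#' @param verbose log per-stage progress.
#' @return (invisibly) list with the [ConnectomeExperiment-class], the
#'   effect tables and the manifest.
#' @export
runPipeline <- function(config, outDir, parc = aalParcellation(),
                        verbose = FALSE) {
    if (is.character(config)) config <- readRunConfig(config)
    if (!is.null(config$simulate) && !is.null(config$inputs))
        stop("config must contain exactly one of 'simulate' or 'inputs'")
    if (is.null(config$simulate) && is.null(config$inputs))
        stop("config must contain a 'simulate' block or an 'inputs' block")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    minStreamlines <- config$minStreamlines %||% 3L
    say <- function(...) if (verbose) message(...)

    if (!is.null(config$simulate)) {
        cfg <- .asCohortConfig(config$simulate)
        say("simulating cohort of ", sum(cfg@groupSizes), " subjects")
        coh <- generateCohort(cfg, parc, minStreamlines = minStreamlines)
        cohort <- coh$cohort; subjects <- coh$subjects
        seedUsed <- cfg@seed
    } else {
        say("loading cohort from ", config$inputs$cohort)
        viol <- validateInputs(config$inputs$dir, config$inputs$cohort, parc)
        if (nrow(viol))
            stop("input validation failed:\n",
                 paste(sprintf("  %s: %s", viol$file, viol$violation),
                       collapse = "\n"))
        cohort <- read.csv(config$inputs$cohort)
        subjects <- lapply(seq_len(nrow(cohort)), function(i)
            readSubjectRaw(cohort$subject_id[i], config$inputs$dir,
                           cohort$icv[i]))
        names(subjects) <- cohort$subject_id
        seedUsed <- NA_integer_
    }

    say("building networks (minStreamlines = ", minStreamlines, ")")
    nets <- lapply(subjects, buildNetwork, minStreamlines = minStreamlines)

    nullSpec <- NULL
    if (!isFALSE(config$nullEnsemble)) {
        ns <- config$nullEnsemble %||% list()
        nullSpec <- nullEnsembleSpec(
            nGraphs = ns$nGraphs %||% 100L,
            swapsPerEdge = ns$swapsPerEdge %||% 10L,
            seed = ns$seed %||% 1L)
    }
    say("measuring cohort", if (!is.null(nullSpec))
        paste0(" (null ensemble: ", nullSpec@nGraphs, " graphs)"))
    ce <- measureCohort(nets, cohort, parc, nullSpec = nullSpec)

    statsCfg <- config$stats %||% list()
    cogPreds <- statsCfg$cognitionPredictors %||%
        (if (!is.null(nullSpec)) c("lambda", "normEglob")
         else "globalEfficiency")
    model2Flag <- statsCfg$model2Flag %||% "lbci"

    say("fitting disease-effect models")
    ge <- globalEffects(ce)
    localTabs <- lapply(setNames(nm = assayNames(ce)), function(m)
        localEffects(ce, m))
    cogTabs <- lapply(setNames(nm = cogPreds), function(pr)
        cognitionModels(ce, pr, model2Flag = model2Flag))

    writeOne <- function(df, name)
        write.csv(df, file.path(outDir, name), row.names = FALSE)
    writeOne(cohort, "cohort.csv")
    writeOne(measureTable(ce), "measures.csv")
    writeOne(ge, "global_effects.csv")
    for (m in names(localTabs))
        writeOne(localTabs[[m]], paste0("local_effects_", m, ".csv"))
    for (pr in names(cogTabs))
        writeOne(cogTabs[[pr]], paste0("cognition_", pr, ".csv"))

    manifest <- list(
        package = "ConnectomeStats",
        version = as.character(utils::packageVersion("ConnectomeStats")),
        nSubjects = nrow(cohort), nNodes = nNodes(parc),
        minStreamlines = minStreamlines,
        simulateSeed = seedUsed,
        nullEnsemble = if (is.null(nullSpec)) NULL else
            list(nGraphs = nullSpec@nGraphs,
                 swapsPerEdge = nullSpec@swapsPerEdge, seed = nullSpec@seed),
        modelSelection = as.list(attr(ge, "modelSelection")),
        cognitionPredictors = cogPreds, model2Flag = model2Flag)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("wrote outputs to ", outDir)
    invisible(list(experiment = ce, globalEffects = ge,
                   localEffects = localTabs, cognition = cogTabs,
                   manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
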