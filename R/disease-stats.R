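## Disease-effect inference: covariate-adjusted GLMs for the independent
## and interaction effects of ADCI and LBCI on network measures, group
## contrasts, cognition models, and BH-FDR control.

.COVARIATES <- c("age", "sex", "education", "dwmh", "pwmh", "icv")

#' Cohort table of a ConnectomeExperiment
#' @param ce a [ConnectomeExperiment-class].
#' @return colData as a plain data.frame.
#' @export
cohortTable <- function(ce) as.data.frame(colData(ce))

.checkCohort <- function(cohort, needGroups = 2L) {
    miss <- setdiff(c("adci", "lbci", .COVARIATES), names(cohort))
    if (length(miss))
        stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
    if ("group" %in% names(cohort) &&
        length(unique(cohort$group)) < needGroups)
        stop("cohort must contain at least ", needGroups, " groups")
    invisible(cohort)
}

.diseaseDesign <- function(cohort, interaction = FALSE) {
    d <- cohort[, c("adci", "lbci", .COVARIATES)]
    if (interaction) d[["adci:lbci"]] <- d$adci * d$lbci
    d
}

.resolveValues <- function(x, values) {
    if (is.character(values) && length(values) == 1L) {
        tab <- if (is(x, "ConnectomeExperiment")) cohortTable(x) else x
        if (!values %in% names(tab)) stop("no measure column '", values, "'")
        return(tab[[values]])
    }
    values
}

#' Independent (and interaction) effects of ADCI and LBCI on a measure
#'
#' Fits `measure ~ ADCI + LBCI + age + sex + education + DWMH + PWMH +
#' ICV`, optionally adding the ADCI x LBCI interaction (coded 1 for the
#' mixed disease group only, 0 for pure ADCI, pure LBCI and controls).
#' The ADCI/LBCI flags are binary: a subject has ADCI whether pure or
#' mixed, and likewise for LBCI.
#'
#' @param values numeric outcome vector, or the name of a column of
#'   `cohort` / `colData` of a [ConnectomeExperiment-class].
#' @param cohort cohort data.frame (or a [ConnectomeExperiment-class]).
#' @param interaction include the ADCI x LBCI term.
#' @param outcome outcome name recorded on the fit.
#' @return a [GlmFit-class].
#' @export
diseaseEffectModel <- function(values, cohort, interaction = FALSE,
                               outcome = if (is.character(values)) values
                                         else "measure") {
    force(outcome)
    values <- .resolveValues(cohort, values)
    if (is(cohort, "ConnectomeExperiment")) cohort <- cohortTable(cohort)
    .checkCohort(cohort)
    fitGlm(values, .diseaseDesign(cohort, interaction), outcome = outcome)
}

#' Group-wise contrast of a measure, covariate-adjusted
#'
#' GLM on the two-group subset with a group indicator (1 = `groupA`,
#' 0 = `groupB`) plus the six covariates; the `group` beta is the adjusted
#' `groupA - groupB` difference.
#'
#' @inheritParams diseaseEffectModel
#' @param groupA,groupB group labels present in `cohort$group`.
#' @return a [GlmFit-class].
#' @export
groupwiseContrast <- function(values, cohort, groupA, groupB,
                              outcome = if (is.character(values)) values
                                        else "measure") {
    force(outcome)
    values <- .resolveValues(cohort, values)
    if (is(cohort, "ConnectomeExperiment")) cohort <- cohortTable(cohort)
    if (identical(groupA, groupB))
        stop("cannot contrast a group with itself")
    sel <- cohort$group %in% c(groupA, groupB)
    if (!any(cohort$group == groupA) || !any(cohort$group == groupB))
        stop("both groups must be present in the cohort")
    sub <- cohort[sel, , drop = FALSE]
    design <- cbind(group = as.integer(sub$group == groupA),
                    sub[, .COVARIATES])
    fitGlm(values[sel], design, outcome = outcome)
}

#' Effects of ADCI and LBCI on the nine global network measures
#'
#' For each global measure, models with and without the ADCI x LBCI
#' interaction are fitted; if the interaction is not significant the
#' better-fitted (lower-AIC) model is kept ([selectModelByAic()]).  No
#' multiplicity correction is applied across the nine global measures (an
#' explicit analysis choice; `p_fdr` is `NA` with scope `"none"`).
#'
#' @param ce a [ConnectomeExperiment-class] (normalized globals needed for
#'   gamma/lambda/normEglob/sigma rows).
#' @param measures which global measures to model.
#' @return an effect table: one row per measure x disease predictor with
#'   `beta`, `se`, `t`, `p`, `p_fdr`, plus the model-selection choice and
#'   rationale; scope tag in `attr(, "scope")`, per-measure rationale in
#'   `attr(, "modelSelection")`.
#' @export
globalEffects <- function(ce, measures = c("meanDegree", "meanStrength",
                                           "clustering", "pathLength",
                                           "globalEfficiency", "gamma",
                                           "lambda", "normEglob", "sigma")) {
    cohort <- cohortTable(ce)
    .checkCohort(cohort)
    rows <- list(); rationale <- character()
    for (m in measures) {
        if (!m %in% names(cohort) || all(is.na(cohort[[m]]))) next
        fitW <- diseaseEffectModel(m, cohort, interaction = TRUE, outcome = m)
        fitO <- diseaseEffectModel(m, cohort, interaction = FALSE, outcome = m)
        selRes <- selectModelByAic(fitW, fitO)
        fit <- selRes$fit
        rationale[m] <- selRes$rationale
        preds <- intersect(c("adci", "lbci", "adci:lbci"), fit@predictors)
        rows[[m]] <- data.frame(
            measure = m, predictor = preds,
            beta = as.numeric(fit@coefficients[preds]),
            se = as.numeric(fit@se[preds]), t = as.numeric(fit@tstat[preds]),
            p = as.numeric(fit@pvalue[preds]), p_fdr = NA_real_,
            model = selRes$choice, row.names = NULL)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "scope") <- "none"
    attr(out, "modelSelection") <- rationale
    out
}

#' Per-node effects of ADCI and LBCI on a local measure
#'
#' Fits the covariate-adjusted disease model at every node of one local
#' measure and applies Benjamini-Hochberg FDR correction across the nodes
#' (separately per disease predictor).
#'
#' @param ce a [ConnectomeExperiment-class].
#' @param measure assay name: `"degree"`, `"strength"`, `"clustering"`,
#'   `"pathLength"` or `"betweenness"`.
#' @param interaction include the ADCI x LBCI term.
#' @return effect table with one row per node x disease predictor
#'   (`node`, `predictor`, `beta`, `se`, `t`, `p`, `p_fdr`); FDR scope in
#'   `attr(, "scope")`.
#' @export
localEffects <- function(ce, measure = "degree", interaction = FALSE) {
    if (!measure %in% assayNames(ce)) stop("no assay '", measure, "'")
    cohort <- cohortTable(ce)
    .checkCohort(cohort)
    Y <- t(assay(ce, measure))                 # subjects x nodes
    f <- fitGlmMulti(Y, .diseaseDesign(cohort, interaction))
    preds <- c("adci", "lbci", if (interaction) "adci:lbci")
    out <- do.call(rbind, lapply(preds, function(pr) {
        pv <- f$pvalue[pr, ]
        pv[!is.finite(pv)] <- 1   # zero-variance outcome: no evidence
        data.frame(
            node = colnames(Y), predictor = pr,
            beta = f$coefficients[pr, ], se = f$se[pr, ], t = f$tstat[pr, ],
            p = pv, p_fdr = fdrCorrect(pv), row.names = NULL)
    }))
    attr(out, "scope") <- paste(ncol(Y), "nodes")
    out
}

#' GLMs of the 14 cognitive scores on a network measure
#'
#' Model 1 regresses each standardized neuropsychological score on the
#' network predictor plus the six covariates; Model 2 (when
#' `model2Flag` is given) additionally controls for the disease flag, to
#' guard against spurious association driven by disease presence.  FDR
#' correction is applied across the 14 tests within each model.
#'
#' @param cohort cohort data.frame (or [ConnectomeExperiment-class]) with
#'   the 14 score columns of [cognitionScores()].
#' @param networkPredictor numeric vector or measure column name (e.g.
#'   `"lambda"`).
#' @param model2Flag optional disease flag column (`"adci"` or `"lbci"`)
#'   for Model 2.
#' @param predictorName name recorded for the network predictor.
#' @return effect table with one row per score per model (`model`,
#'   `score`, `beta`, `se`, `t`, `p`, `p_fdr` for the network-predictor
#'   coefficient); FDR scope `"14 tests"`.
#' @export
cognitionModels <- function(cohort, networkPredictor,
                            model2Flag = NULL,
                            predictorName = if (is.character(networkPredictor))
                                networkPredictor else "networkMeasure") {
    force(predictorName)
    values <- .resolveValues(cohort, networkPredictor)
    if (is(cohort, "ConnectomeExperiment")) cohort <- cohortTable(cohort)
    miss <- setdiff(cognitionScores(), names(cohort))
    if (length(miss))
        stop("missing cognition score column(s): ", paste(miss, collapse = ", "))
    oneModel <- function(design, label) {
        res <- do.call(rbind, lapply(cognitionScores(), function(sc) {
            fit <- fitGlm(cohort[[sc]], design, outcome = sc)
            data.frame(model = label, score = sc, predictor = predictorName,
                       beta = unname(fit@coefficients["netPredictor"]),
                       se = unname(fit@se["netPredictor"]),
                       t = unname(fit@tstat["netPredictor"]),
                       p = unname(fit@pvalue["netPredictor"]),
                       row.names = NULL)
        }))
        res$p_fdr <- fdrCorrect(res$p)
        res
    }
    d1 <- cbind(netPredictor = values, cohort[, .COVARIATES])
    out <- oneModel(d1, "model1")
    if (!is.null(model2Flag)) {
        if (!model2Flag %in% names(cohort))
            stop("no disease flag column '", model2Flag, "'")
        d2 <- cbind(d1, flag = cohort[[model2Flag]])
        names(d2)[ncol(d2)] <- model2Flag
        out <- rbind(out, oneModel(d2, "model2"))
    }
    attr(out, "scope") <- "14 tests"
    out
}
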