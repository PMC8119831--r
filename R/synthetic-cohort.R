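#' Names of the 14 standardized cognitive scores
#'
#' The neuropsychological battery the cohort carries: digit span backward,
#' Korean Boston naming test (K-BNT), Rey complex figure copy/immediate/
#' delayed/recognition (RCFT), Seoul verbal learning test immediate/delayed/
#' recognition (SVLT), semantic (animal, supermarket) and phonemic verbal
#' fluency (COWAT), Stroop color reading, and the Korean mini-mental state
#' examination (K-MMSE).  All scores are standardized (z) scores.
#'
#' @return character vector of length 14, in canonical order.
#' @export
cognitionScores <- function() c(
    "digitSpanBackward", "kBnt", "rcftCopy", "svltImmediate", "svltDelayed",
    "svltRecognition", "rcftImmediate", "rcftDelayed", "rcftRecognition",
    "cowatAnimal", "cowatSupermarket", "cowatPhonemic", "stroopColorReading",
    "kMmse")

.defaultCovariateParams <- function() list(
    control   = list(ageMean = 70.2, ageSD = 5.6, femaleP = 0.676,
                     eduMean = 11.6, eduSD = 4.7,
                     dwmh = c(0.90, 0.10, 0.00), pwmh = c(0.90, 0.10, 0.00),
                     icvMean = 1.45e6, icvSD = 1.2e5),
    pure_ADCI = list(ageMean = 69.8, ageSD = 9.1, femaleP = 0.636,
                     eduMean = 10.9, eduSD = 3.7,
                     dwmh = c(0.45, 0.50, 0.05), pwmh = c(0.55, 0.40, 0.05),
                     icvMean = 1.45e6, icvSD = 1.2e5),
    pure_LBCI = list(ageMean = 75.4, ageSD = 8.8, femaleP = 0.632,
                     eduMean = 9.4, eduSD = 4.6,
                     dwmh = c(0.55, 0.40, 0.05), pwmh = c(0.35, 0.50, 0.15),
                     icvMean = 1.45e6, icvSD = 1.2e5),
    mixed     = list(ageMean = 74.5, ageSD = 7.3, femaleP = 0.472,
                     eduMean = 10.9, eduSD = 5.1,
                     dwmh = c(0.55, 0.40, 0.05), pwmh = c(0.35, 0.50, 0.15),
                     icvMean = 1.45e6, icvSD = 1.2e5))

.defaultEffectParams <- function() list(
    list(flag = "lbci", target = "node:Caudate_L", countScale = 0.55, faScale = 1),
    list(flag = "lbci", target = "between_module", countScale = 0.60, faScale = 1),
    list(flag = "adci", target = "all", countScale = 1, faScale = 0.93))

.defaultCognitionParams <- function() {
    sc <- cognitionScores()
    list(degreeNode = "Caudate_L",
         globalMeasure = "globalEfficiency",
         bDegree = setNames(rep(0.35, 14), sc),
         bGlobal = setNames(rep(0.30, 14), sc),
         bAge = -0.03, bEducation = 0.04, noiseSD = 0.8)
}

.defaultTemplateParams <- function() list(
    nModules = 4L, pWithin = 0.45, pBetween = 0.12,
    countMu = 10, countSize = 0.7, faMin = 0.15, faRange = 0.55,
    faShape = 9, volMeanLog = log(8000), volSDLog = 0.45,
    subjectCountSD = 0.20, subjectFASD = 0.025, subjectVolSD = 0.05)

#' Configure the synthetic cohort generator
#'
#' Defaults emulate the case-control study design the statistics assume:
#' group sizes 37/22/19/36 (control / pure ADCI / pure LBCI / mixed),
#' per-group age, sex, education and white-matter-hyperintensity
#' distributions loosely matched to the study's demographic table, and
#' planted multiplicative disease effects — LBCI scales streamline counts
#' of left-caudate-incident edges by 0.55 and of between-module edges by
#' 0.6 (a global-integration deficit: enough low-count between-module
#' shortcuts fall below the 3-streamline threshold that characteristic
#' path length rises relative to degree-matched random graphs); ADCI
#' scales FA diffusely by 0.93, touching strength but not degree.  ICV
#' distributions are invented (no per-group values are reported).
#'
#' @param groupSizes named counts for `control`, `pure_ADCI`, `pure_LBCI`,
#'   `mixed`.
#' @param covariateParams per-group list of `ageMean`, `ageSD`, `femaleP`,
#'   `eduMean`, `eduSD`, `dwmh`/`pwmh` (probability vectors over ordinal
#'   levels 1-3) and `icvMean`/`icvSD` (mm^3).
#' @param effectParams list of planted effects, each
#'   `list(flag, target, countScale, faScale)` with `flag` one of
#'   `"adci"`, `"lbci"`, `"interaction"` (mixed group only) and `target`
#'   `"all"`, `"between_module"` or `"node:<label>"`.  Scalings multiply
#'   counts/FA before integer rounding and must lie in (0, 1.5].
#' @param cognitionParams linear model generating the 14 scores from the
#'   subject's network measures (left-caudate degree and one raw global
#'   measure, cohort-standardized) and covariates, plus Gaussian noise.
#' @param templateParams parameters of the population base connectome; see
#'   [generateTemplate()].
#' @param seed integer seed; the cohort is bitwise-reproducible from it.
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(groupSizes = c(control = 37L, pure_ADCI = 22L,
                                        pure_LBCI = 19L, mixed = 36L),
                         covariateParams = list(), effectParams = NULL,
                         cognitionParams = list(), templateParams = list(),
                         seed = 20260101L) {
    gs <- as.integer(groupSizes)
    names(gs) <- names(groupSizes)
    cov <- .defaultCovariateParams()
    for (g in names(covariateParams))
        cov[[g]] <- modifyList(cov[[g]], covariateParams[[g]])
    if (is.null(effectParams)) effectParams <- .defaultEffectParams()
    effectParams <- lapply(effectParams, function(e)
        modifyList(list(countScale = 1, faScale = 1), e))
    cog <- modifyList(.defaultCognitionParams(), cognitionParams)
    tpl <- modifyList(.defaultTemplateParams(), templateParams)
    new("CohortConfig", groupSizes = gs, covariateParams = cov,
        effectParams = effectParams, cognitionParams = cog,
        templateParams = tpl, seed = as.integer(seed))
}

setMethod("show", "CohortConfig", function(object) {
    gs <- object@groupSizes
    cat(sprintf("CohortConfig: %d subjects (%s), %d planted effect(s), seed %d\n",
                sum(gs), paste(gs, collapse = "/"),
                length(object@effectParams), object@seed))
})

#' Generate the population base connectome template
#'
#' A distance-free modular random template: nodes are assigned to
#' `nModules` modules (cycling over node order, which segregates the
#' interleaved hemispheres of the default parcellation) and node pairs are
#' connected with probability `pWithin` within and `pBetween` between
#' modules.  Present edges get heavy-tailed streamline counts
#' (`1 + NegBinomial(mu = countMu - 1, size = countSize)`), mean FA drawn
#' from a scaled Beta on `[faMin, faMin + faRange]`, and nodes get
#' log-normal volumes.  This is a simulation device, not a claim about
#' brains.
#'
#' @param nNodes number of nodes (>= 3).
#' @param seed integer seed; identical seeds give bitwise-identical
#'   templates.
#' @param params template parameters (see [cohortConfig()] defaults);
#'   `pWithin = pBetween = 0` gives an empty template.
#' @return list with `counts`, `fa` (symmetric matrices), `volumes` and
#'   `modules` (module index per node).
#' @export
generateTemplate <- function(nNodes = 92L, seed = 1L,
                             params = .defaultTemplateParams()) {
    if (nNodes < 3L) stop("nNodes must be >= 3")
    params <- modifyList(.defaultTemplateParams(), params)
    .withSeed(seed, {
        modules <- (seq_len(nNodes) - 1L) %% params$nModules + 1L
        sameMod <- outer(modules, modules, "==")
        ut <- upper.tri(sameMod)
        pEdge <- ifelse(sameMod[ut], params$pWithin, params$pBetween)
        present <- runif(length(pEdge)) < pEdge
        m <- sum(present)
        counts <- matrix(0, nNodes, nNodes)
        fa <- matrix(0, nNodes, nNodes)
        cVals <- numeric(length(pEdge)); fVals <- numeric(length(pEdge))
        if (m > 0) {
            cVals[present] <- 1 + rnbinom(m, size = params$countSize,
                                          mu = params$countMu - 1)
            fVals[present] <- params$faMin + params$faRange *
                rbeta(m, params$faShape, params$faShape)
        }
        counts[ut] <- cVals; fa[ut] <- fVals
        counts <- counts + t(counts); fa <- fa + t(fa)
        volumes <- rlnorm(nNodes, params$volMeanLog, params$volSDLog)
        list(counts = counts, fa = fa, volumes = volumes, modules = modules)
    })
}

## Logical edge mask (n x n) for one planted-effect target.
.effectMask <- function(target, parc, modules) {
    n <- nNodes(parc)
    if (identical(target, "all")) {
        mask <- matrix(TRUE, n, n)
    } else if (identical(target, "between_module")) {
        mask <- outer(modules, modules, "!=")
    } else if (startsWith(target, "node:")) {
        idx <- matchNodes(parc, sub("^node:", "", target))
        mask <- matrix(FALSE, n, n)
        mask[idx, ] <- TRUE; mask[, idx] <- TRUE
    } else stop("unknown effect target: ", target)
    diag(mask) <- FALSE
    mask
}

.sampleOrdinal <- function(n, probs) sample(1:3, n, replace = TRUE, prob = probs)

#' Generate a synthetic cohort
#'
#' Draws per-group covariates, derives each subject's raw connectome from
#' the population template (log-normal multiplicative count noise, additive
#' FA noise, ICV-coupled volumes), applies the configured disease effects
#' multiplicatively to the designated edge sets *before* integer rounding
#' (scaled counts rounding below 1 remove the edge), and generates the 14
#' cognitive scores from the subject's network measures and covariates via
#' the configured linear model plus Gaussian noise.  Fully reproducible
#' from `config@seed`.
#'
#' @param config a [CohortConfig-class].
#' @param parc a [Parcellation-class]; default [aalParcellation()].
#' @param minStreamlines edge threshold used when computing the network
#'   measures that drive cognition; default 3.
#' @return list with `cohort` (data.frame: subject_id, group, adci, lbci,
#'   age, sex, education, dwmh, pwmh, icv and the 14 score columns),
#'   `subjects` (named list of [SubjectRaw-class]) and `template`.
#' @examples
#' cfg <- cohortConfig(groupSizes = c(control = 3L, pure_ADCI = 2L,
#'                                    pure_LBCI = 2L, mixed = 3L), seed = 7L)
#' coh <- generateCohort(cfg)
#' table(coh$cohort$group)
#' @export
generateCohort <- function(config, parc = aalParcellation(),
                           minStreamlines = 3L) {
    validObject(config)
    n <- nNodes(parc)
    labels <- nodeLabels(parc)
    for (eff in config@effectParams)           # fail fast on bad labels
        .effectMask(eff$target, parc, rep(1L, n))
    tpl <- generateTemplate(n, seed = config@seed, params = config@templateParams)
    masks <- lapply(config@effectParams, function(eff)
        .effectMask(eff$target, parc, tpl$modules))

    groups <- rep(names(config@groupSizes), config@groupSizes)
    N <- length(groups)
    if (N == 0L) stop("empty cohort")
    tp <- config@templateParams
    ut <- upper.tri(tpl$counts)

    .withSeed(config@seed + 1L, {
        cohort <- do.call(rbind, lapply(names(config@groupSizes), function(g) {
            ng <- config@groupSizes[[g]]
            cp <- config@covariateParams[[g]]
            data.frame(
                group = rep(g, ng),
                adci = as.integer(g %in% c("pure_ADCI", "mixed")),
                lbci = as.integer(g %in% c("pure_LBCI", "mixed")),
                age = rnorm(ng, cp$ageMean, cp$ageSD),
                sex = as.integer(runif(ng) >= cp$femaleP),  # 1 = male
                education = pmax(0, rnorm(ng, cp$eduMean, cp$eduSD)),
                dwmh = .sampleOrdinal(ng, cp$dwmh),
                pwmh = .sampleOrdinal(ng, cp$pwmh),
                icv = rnorm(ng, cp$icvMean, cp$icvSD))
        }))
        cohort <- cbind(subject_id = sprintf("S%03d", seq_len(N)), cohort)
        rownames(cohort) <- cohort$subject_id

        icvRef <- mean(vapply(config@covariateParams, `[[`, 0, "icvMean"))
        subjects <- vector("list", N)
        degNode <- numeric(N); globVal <- numeric(N)
        degIdx <- matchNodes(parc, config@cognitionParams$degreeNode)
        gmName <- config@cognitionParams$globalMeasure

        for (i in seq_len(N)) {
            counts <- tpl$counts
            counts[ut] <- counts[ut] * exp(rnorm(sum(ut), 0, tp$subjectCountSD))
            fa <- tpl$fa
            fa[ut] <- ifelse(tpl$counts[ut] > 0,
                             pmin(0.99, pmax(0.01,
                                  fa[ut] + rnorm(sum(ut), 0, tp$subjectFASD))),
                             0)
            for (k in seq_along(config@effectParams)) {
                eff <- config@effectParams[[k]]
                on <- switch(eff$flag,
                             adci = cohort$adci[i] == 1L,
                             lbci = cohort$lbci[i] == 1L,
                             interaction = cohort$adci[i] == 1L &&
                                           cohort$lbci[i] == 1L)
                if (on) {
                    counts[masks[[k]]] <- counts[masks[[k]]] * eff$countScale
                    fa[masks[[k]]] <- fa[masks[[k]]] * eff$faScale
                }
            }
            fa <- pmin(fa, 0.99)        # faScale > 1 must not leave [0, 1]
            counts <- round(counts)
            counts[counts < 1] <- 0
            fa[counts == 0] <- 0
            counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
            fa[lower.tri(fa)] <- t(fa)[lower.tri(fa)]
            vols <- tpl$volumes * (cohort$icv[i] / icvRef) *
                exp(rnorm(n, 0, tp$subjectVolSD))
            subjects[[i]] <- subjectRaw(cohort$subject_id[i], counts, fa,
                                        vols, cohort$icv[i], labels = labels)
            net <- buildNetwork(subjects[[i]], minStreamlines = minStreamlines)
            degNode[i] <- nodeDegree(net)[degIdx]
            globVal[i] <- .globalValue(edgeWeights(net), gmName)
        }
        names(subjects) <- cohort$subject_id

        zscore <- function(x) {
            s <- sd(x)
            if (!is.finite(s) || s == 0) s <- 1
            (x - mean(x)) / s
        }
        cg <- config@cognitionParams
        zd <- zscore(degNode); zg <- zscore(globVal)
        for (sc in cognitionScores())
            cohort[[sc]] <- cg$bDegree[[sc]] * zd + cg$bGlobal[[sc]] * zg +
                cg$bAge * (cohort$age - 73) +
                cg$bEducation * (cohort$education - 10.5) +
                rnorm(N, 0, cg$noiseSD)

        list(cohort = cohort, subjects = subjects, template = tpl)
    })
}
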