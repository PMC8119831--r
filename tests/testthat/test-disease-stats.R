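# A moderately sized measured cohort shared across the blocks in this file.
localCE <- local({
    cfg <- smallConfig(groupSizes = c(control = 12L, pure_ADCI = 8L,
                                      pure_LBCI = 8L, mixed = 12L),
                       seed = 321L)
    suppressWarnings(simulateExperiment(cfg, parc = smallParcellation(30)))
})

test_that("disease models code predictors exactly as specified", {
    fit <- diseaseEffectModel("meanDegree", localCE)
    expect_identical(fit@predictors,
                     c("(Intercept)", "adci", "lbci", "age", "sex",
                       "education", "dwmh", "pwmh", "icv"))
    fitI <- diseaseEffectModel("meanDegree", localCE, interaction = TRUE)
    expect_true("adci:lbci" %in% fitI@predictors)
    # the interaction column is 1 for the mixed group only
    cd <- cohortTable(localCE)
    expect_identical(cd$adci * cd$lbci,
                     as.integer(cd$group == "mixed"))
    # single-group cohorts are rejected
    sub <- cd[cd$group == "control", ]
    expect_error(diseaseEffectModel(sub$meanDegree, sub), "at least 2")
})

test_that("planted LBCI-only effects load on the LBCI beta, not the ADCI beta", {
    deg <- assay(localCE, "degree")["Caudate_L", ]
    fit <- diseaseEffectModel(deg, localCE, outcome = "caudateDegree")
    expect_lt(coef(fit)[["lbci"]], 0)
    expect_lt(fit@pvalue[["lbci"]], 0.05)
    expect_gt(fit@pvalue[["adci"]], 0.05)
})

test_that("a mixed-only (pure interaction) planted effect loads on the interaction term", {
    cfg <- smallConfig(
        groupSizes = c(control = 14L, pure_ADCI = 12L, pure_LBCI = 12L,
                       mixed = 14L),
        effectParams = list(list(flag = "interaction",
                                 target = "node:Caudate_L",
                                 countScale = 0.45)),
        seed = 654L)
    coh <- generateCohort(cfg, smallParcellation(30))
    deg <- vapply(coh$subjects, function(s)
        unname(nodeDegree(buildNetwork(s))["Caudate_L"]), numeric(1))
    fit <- diseaseEffectModel(deg, coh$cohort, interaction = TRUE)
    expect_lt(coef(fit)[["adci:lbci"]], 0)
    expect_lt(fit@pvalue[["adci:lbci"]], 0.05)
    expect_gt(abs(fit@tstat[["adci:lbci"]]), abs(fit@tstat[["adci"]]))
    expect_gt(abs(fit@tstat[["adci:lbci"]]), abs(fit@tstat[["lbci"]]))
})

test_that("group-wise contrasts recover planted differences and reject degenerate calls", {
    deg <- assay(localCE, "degree")["Caudate_L", ]
    fit <- groupwiseContrast(deg, localCE, "mixed", "control")
    expect_lt(coef(fit)[["group"]], 0)
    expect_error(groupwiseContrast(deg, localCE, "mixed", "mixed"), "itself")
    expect_error(groupwiseContrast(deg, localCE, "mixed", "dlb"),
                 "must be present")
})

test_that("label permutation under the null rejects at about the nominal rate", {
    cd <- cohortTable(localCE)
    sel <- cd$group %in% c("control", "pure_ADCI")
    sub <- cd[sel, , drop = FALSE]
    y <- rnorm(nrow(sub))                # outcome unrelated to any label
    set.seed(99)
    pvals <- vapply(seq_len(400), function(i) {
        sub$group <- sample(sub$group)
        fit <- groupwiseContrast(y, sub, "control", "pure_ADCI")
        fit@pvalue[["group"]]
    }, numeric(1))
    rate <- mean(pvals < 0.05)
    expect_gt(rate, 0.02); expect_lt(rate, 0.10)
})

test_that("local sweeps return one row per node and predictor with in-scope FDR", {
    le <- localEffects(localCE, "degree")
    expect_identical(nrow(le), 2L * 30L)
    expect_setequal(unique(le$predictor), c("adci", "lbci"))
    expect_true(all(le$p_fdr >= le$p - 1e-15))
    expect_identical(attr(le, "scope"), "30 nodes")
    lbci <- le[le$predictor == "lbci", ]
    caud <- lbci[lbci$node == "Caudate_L", ]
    expect_lt(caud$beta, 0)
    expect_lt(caud$p_fdr, 0.05)
    expect_error(localEffects(localCE, "volume"), "no assay")
})

test_that("global effect tables carry model choice and no cross-measure correction", {
    ge <- suppressMessages(globalEffects(localCE))
    expect_true(all(is.na(ge$p_fdr)))
    expect_identical(attr(ge, "scope"), "none")
    expect_true(all(ge$model %in% c("with", "without")))
    expect_true(length(attr(ge, "modelSelection")) >= 1)
    # normalized measures were not computed for this experiment
    expect_false(any(ge$measure %in% c("gamma", "lambda", "normEglob",
                                       "sigma")))
})

test_that("cognition models produce 14 rows per model and recover planted loadings", {
    cm <- cognitionModels(localCE, "globalEfficiency", model2Flag = "lbci")
    expect_identical(as.integer(table(cm$model)), c(14L, 14L))
    expect_identical(attr(cm, "scope"), "14 tests")
    expect_true(all(cm$p_fdr >= cm$p - 1e-15))
    bad <- cohortTable(localCE)
    bad$kMmse <- NULL
    expect_error(cognitionModels(bad, "globalEfficiency"), "kMmse")
})

test_that("cognition generated from path length yields negative Model 1 betas", {
    cfg <- smallConfig(
        groupSizes = c(control = 15L, pure_ADCI = 10L, pure_LBCI = 10L,
                       mixed = 15L),
        effectParams = list(),
        cognitionParams = list(
            globalMeasure = "pathLength",
            bGlobal = setNames(rep(-0.8, 14), cognitionScores()),
            bDegree = setNames(rep(0, 14), cognitionScores()),
            noiseSD = 0.5),
        seed = 987L)
    ce <- suppressWarnings(simulateExperiment(cfg, smallParcellation(30)))
    cm <- cognitionModels(ce, "pathLength")
    expect_true(all(cm$beta < 0))
    expect_true(mean(cm$p_fdr < 0.05) > 0.5)
})

test_that("controlling for a driving disease flag attenuates network betas", {
    # cognition driven entirely by the disease flag; the network predictor is
    # merely correlated with the flag
    set.seed(55)
    n <- 160
    coh <- data.frame(
        group = sample(c("control", "pure_LBCI"), n, replace = TRUE),
        age = rnorm(n, 73, 7), sex = rbinom(n, 1, 0.5),
        education = rnorm(n, 10, 4), dwmh = sample(1:3, n, TRUE),
        pwmh = sample(1:3, n, TRUE), icv = rnorm(n, 1.45e6, 1.2e5))
    coh$adci <- 0L
    coh$lbci <- as.integer(coh$group == "pure_LBCI")
    netPred <- coh$lbci * 1.2 + rnorm(n, sd = 0.8)
    for (sc in cognitionScores()) coh[[sc]] <- -coh$lbci + rnorm(n, sd = 0.6)
    m1 <- cognitionModels(coh, netPred)
    m12 <- cognitionModels(coh, netPred, model2Flag = "lbci")
    m2 <- m12[m12$model == "model2", ]
    expect_lt(mean(abs(m2$beta)), mean(abs(m1$beta)))
})
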