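test_that("template generation is deterministic, symmetric and density-controlled", {
    t1 <- generateTemplate(92, seed = 1)
    t2 <- generateTemplate(92, seed = 1)
    expect_identical(t1, t2)                       # bitwise under fixed seed
    expect_false(identical(t1, generateTemplate(92, seed = 2)))
    expect_equal(t1$counts, t(t1$counts))
    expect_true(all(diag(t1$counts) == 0))
    expect_true(all(t1$counts == round(t1$counts) & t1$counts >= 0))
    expect_true(all(t1$fa >= 0 & t1$fa <= 1))
    expect_true(all(t1$fa[t1$counts == 0] == 0))
    expect_true(all(t1$fa[t1$counts > 0] > 0))
    expect_true(all(t1$volumes > 0))
    # degenerate density: no edges at all
    t0 <- generateTemplate(92, seed = 1,
                           params = list(pWithin = 0, pBetween = 0))
    expect_true(all(t0$counts == 0))
    expect_error(generateTemplate(2, seed = 1), ">= 3")
})

test_that("default configuration reproduces the study group structure", {
    cfg <- cohortConfig(seed = 5L)
    expect_identical(unname(cfg@groupSizes), c(37L, 22L, 19L, 36L))
    coh <- generateCohort(cfg)
    tab <- table(coh$cohort$group)
    expect_identical(as.integer(tab[c("control", "pure_ADCI", "pure_LBCI",
                                      "mixed")]), c(37L, 22L, 19L, 36L))
    expect_identical(nrow(coh$cohort), 114L)
    expect_length(coh$subjects, 114L)
    # disease flags are implied by group membership
    with(coh$cohort, {
        expect_identical(adci, as.integer(group %in% c("pure_ADCI", "mixed")))
        expect_identical(lbci, as.integer(group %in% c("pure_LBCI", "mixed")))
    })
    expect_true(all(cognitionScores() %in% names(coh$cohort)))
    expect_length(cognitionScores(), 14L)
    expect_true(all(coh$cohort$dwmh %in% 1:3 & coh$cohort$pwmh %in% 1:3))
    expect_true(all(coh$cohort$sex %in% 0:1))
})

test_that("cohorts are bitwise-reproducible from the config seed", {
    cfg <- smallConfig(groupSizes = c(control = 4L, pure_ADCI = 3L,
                                      pure_LBCI = 3L, mixed = 4L), seed = 77L)
    p <- smallParcellation(20)
    expect_identical(generateCohort(cfg, p), generateCohort(cfg, p))
})

test_that("invalid configurations are rejected", {
    expect_error(cohortConfig(effectParams = list(
        list(flag = "lbci", target = "all", countScale = 1.7))),
        "\\(0, 1.5\\]")
    expect_error(cohortConfig(effectParams = list(
        list(flag = "dementia", target = "all", countScale = 0.9))), "flag")
    expect_error(cohortConfig(cognitionParams = list(noiseSD = 0)),
                 "noise SD")
    expect_error(cohortConfig(covariateParams = list(
        control = list(dwmh = c(0.5, 0.6, 0.2)))), "probability")
    # effect referencing an unknown node label fails at generation
    cfg <- smallConfig(effectParams = list(
        list(flag = "lbci", target = "node:Nucleus_Basalis_L",
             countScale = 0.5)))
    expect_error(generateCohort(cfg, smallParcellation(20)),
                 "unknown node label")
})

test_that("a planted left-caudate count scaling lowers caudate degree in LBCI subjects", {
    # 200-subject cohort, caudate-only effect; direction forced by construction
    cfg <- cohortConfig(
        groupSizes = c(control = 50L, pure_ADCI = 50L, pure_LBCI = 50L,
                       mixed = 50L),
        effectParams = list(list(flag = "lbci", target = "node:Caudate_L",
                                 countScale = 0.5)),
        seed = 404L)
    coh <- generateCohort(cfg)
    deg <- vapply(coh$subjects, function(s)
        unname(nodeDegree(buildNetwork(s))["Caudate_L"]), numeric(1))
    expect_lt(mean(deg[coh$cohort$lbci == 1]), mean(deg[coh$cohort$lbci == 0]))
})

test_that("null configurations leave downstream disease betas centered at zero", {
    # 500 replicate null cohorts (no planted effects); ADCI and LBCI betas on
    # mean degree must average to 0 within 3 Monte-Carlo standard errors
    p <- smallParcellation(30)
    gs <- c(control = 10L, pure_ADCI = 10L, pure_LBCI = 10L, mixed = 10L)
    B <- 500
    betas <- matrix(NA_real_, B, 2, dimnames = list(NULL, c("adci", "lbci")))
    for (b in seq_len(B)) {
        cfg <- cohortConfig(groupSizes = gs, effectParams = list(),
                            seed = 9000L + b)
        coh <- generateCohort(cfg, p)
        md <- vapply(coh$subjects, function(s)
            mean(nodeDegree(buildNetwork(s))), numeric(1))
        fit <- diseaseEffectModel(md, coh$cohort)
        betas[b, ] <- coef(fit)[c("adci", "lbci")]
    }
    for (fl in c("adci", "lbci")) {
        se <- sd(betas[, fl]) / sqrt(B)
        expect_lt(abs(mean(betas[, fl])), 3 * se)
    }
})
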