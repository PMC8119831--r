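test_that("noise-free linear data are recovered exactly", {
    set.seed(1)
    x <- rnorm(40)
    fit <- fitGlm(2 * x, data.frame(x = x))
    expect_equal(unname(coef(fit)["x"]), 2, tolerance = 1e-10)
    expect_lt(fit@rss, 1e-20)
})

test_that("estimates match lm and a normal-equations oracle on random designs", {
    set.seed(2)
    for (rep in seq_len(50)) {
        n <- sample(30:80, 1); k <- sample(2:6, 1)
        X <- matrix(rnorm(n * k), n, k,
                    dimnames = list(NULL, paste0("x", seq_len(k))))
        y <- rnorm(n)
        fit <- fitGlm(y, as.data.frame(X))
        ref <- oracleOLS(y, cbind(1, X))
        expect_equal(unname(coef(fit)), unname(ref$beta), tolerance = 1e-8)
        expect_equal(unname(fit@se), unname(ref$se), tolerance = 1e-8)
        expect_equal(unname(fit@pvalue), unname(ref$p), tolerance = 1e-8)
        lmfit <- summary(lm(y ~ X))
        expect_equal(unname(coef(fit)), unname(lmfit$coefficients[, 1]),
                     tolerance = 1e-8)
        expect_equal(unname(fit@se), unname(lmfit$coefficients[, 2]),
                     tolerance = 1e-8)
        # AIC: Gaussian-OLS form, and model ranking consistent with stats::AIC
        expect_equal(fit@aic, n * log(ref$rss / n) + 2 * (k + 1),
                     tolerance = 1e-8)
    }
})

test_that("multi-outcome fitting equals column-by-column fitting", {
    set.seed(3)
    X <- data.frame(a = rnorm(60), b = rnorm(60))
    Y <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("y", 1:5)))
    multi <- fitGlmMulti(Y, X)
    for (j in 1:5) {
        single <- fitGlm(Y[, j], X)
        expect_equal(unname(multi$coefficients[, j]), unname(coef(single)),
                     tolerance = 1e-12)
        expect_equal(unname(multi$se[, j]), unname(single@se),
                     tolerance = 1e-12)
        expect_equal(unname(multi$pvalue[, j]), unname(single@pvalue),
                     tolerance = 1e-12)
        expect_equal(multi$aic[[j]], single@aic, tolerance = 1e-12)
    }
})

test_that("a planted coefficient is recovered without bias", {
    set.seed(4)
    n <- 114; B <- 500
    x <- rnorm(n)
    covar <- rnorm(n)
    Y <- 0.5 * x + 0.3 * covar +
        matrix(rnorm(n * B), n, B)          # 500 replicate outcomes
    f <- fitGlmMulti(Y, data.frame(x = x, covar = covar))
    est <- f$coefficients["x", ]
    mcse <- sd(est) / sqrt(B)
    expect_lt(abs(mean(est) - 0.5), 3 * mcse)
})

test_that("rank-deficient designs fail loudly naming the collinear column", {
    set.seed(5)
    x <- rnorm(30)
    expect_error(fitGlm(rnorm(30), data.frame(x = x, xcopy = x)),
                 "collinear.*xcopy")
})

test_that("rows with missing values are dropped listwise with a count", {
    set.seed(6)
    x <- rnorm(40); y <- rnorm(40)
    x[c(3, 7)] <- NA; y[11] <- NA
    expect_message(fit <- fitGlm(y, data.frame(x = x)), "3 row")
    expect_identical(fit@n, 37L)
    expect_identical(fit@nDropped, 3L)
})

test_that("BH adjustment matches the hand-computed step-up and its properties", {
    expect_equal(fdrCorrect(0.01), 0.01)                 # m = 1 identity
    expect_equal(fdrCorrect(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    set.seed(7)
    p <- runif(50)^2
    adj <- fdrCorrect(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))      # monotone in rank
    expect_error(fdrCorrect(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(fdrCorrect(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("interaction-model selection applies the significance-then-AIC rule", {
    set.seed(8)
    n <- 60
    d <- data.frame(adci = rbinom(n, 1, 0.5), lbci = rbinom(n, 1, 0.5),
                    z = rnorm(n))
    y <- d$adci + d$z + rnorm(n)
    dW <- cbind(d, `adci:lbci` = d$adci * d$lbci)
    fitW <- fitGlm(y, dW); fitO <- fitGlm(y, d)
    # non-significant interaction, lower AIC without -> without
    sel <- selectModelByAic(fitW, fitO, interactionP = 0.60)
    if (fitO@aic <= fitW@aic) expect_identical(sel$choice, "without")
    # significant interaction wins regardless of AIC
    expect_identical(selectModelByAic(fitW, fitO, interactionP = 0.01)$choice,
                     "with")
    # exact AIC tie with n.s. interaction -> parsimony
    fitTie <- fitO; fitTie@aic <- fitW@aic
    expect_identical(
        selectModelByAic(fitW, fitTie, interactionP = 0.30)$choice, "without")
    # default interaction p is read off the interaction term itself
    selDef <- selectModelByAic(fitW, fitO)
    expect_match(selDef$rationale, "interaction")
    fitBad <- fitGlm(y[-1], d[-1, ])
    expect_error(selectModelByAic(fitW, fitBad, interactionP = 0.5),
                 "different rows")
})
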