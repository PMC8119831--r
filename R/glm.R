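## Ordinary-least-squares engine shared by all inference wrappers.  A single
## QR decomposition of the design serves any number of outcome columns,
## which keeps 92-node local sweeps and simulation loops cheap.

.olsEngine <- function(X, Y) {
    n <- nrow(X); k <- ncol(X)
    qrX <- qr(X)
    if (qrX$rank < k) {
        bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, k)]]
        stop("rank-deficient design; collinear column(s): ",
             paste(bad, collapse = ", "))
    }
    coef <- qr.coef(qrX, Y)
    res <- qr.resid(qrX, Y)
    rss <- colSums(res^2)
    df <- n - k
    sigma2 <- rss / df
    R <- qr.R(qrX)
    xtxinvDiag <- diag(chol2inv(R))[order(qrX$pivot)]
    se <- sqrt(outer(xtxinvDiag, sigma2))
    dimnames(coef) <- list(colnames(X), colnames(Y))
    dimnames(se) <- dimnames(coef)
    tstat <- coef / se
    pval <- 2 * pt(-abs(tstat), df)
    aic <- ifelse(rss > 0, n * log(rss / n) + 2 * k, -Inf)
    list(coefficients = coef, se = se, tstat = tstat, pvalue = pval,
         rss = rss, df = df, n = n, k = k, aic = aic)
}

.designMatrix <- function(design) {
    X <- as.matrix(design)
    storage.mode(X) <- "double"
    cbind(`(Intercept)` = 1, X)
}

#' Fit an ordinary-least-squares general linear model
#'
#' OLS fit of `y` on an intercept plus the columns of `design`; standard
#' errors from the residual variance, two-sided p-values from the t
#' distribution on the residual degrees of freedom.  Rows with any missing
#' value are dropped listwise (the number dropped is recorded).  The AIC
#' stored is the Gaussian-OLS form `n * log(rss/n) + 2k` (k = coefficients
#' including the intercept); additive constants common to same-`n` models
#' are dropped, so model rankings are unaffected.
#'
#' @param y numeric outcome vector.
#' @param design data.frame or matrix of predictors (no intercept column).
#' @param outcome name recorded for the outcome.
#' @return a [GlmFit-class].
#' @examples
#' x <- rnorm(50); fit <- fitGlm(2 * x, data.frame(x = x))
#' coef(fit)[["x"]]  # 2
#' @export
fitGlm <- function(y, design, outcome = "y") {
    design <- as.data.frame(design)
    keep <- complete.cases(design) & !is.na(y)
    nDropped <- sum(!keep)
    if (nDropped > 0)
        message(nDropped, " row(s) with missing values dropped")
    y <- y[keep]
    X <- .designMatrix(design[keep, , drop = FALSE])
    if (length(y) <= ncol(X))
        stop("need more observations than predictors (n = ", length(y),
             ", coefficients = ", ncol(X), ")")
    f <- .olsEngine(X, matrix(y, ncol = 1))
    new("GlmFit", outcome = outcome, predictors = colnames(X),
        coefficients = setNames(f$coefficients[, 1], colnames(X)),
        se = setNames(f$se[, 1], colnames(X)),
        tstat = setNames(f$tstat[, 1], colnames(X)),
        pvalue = setNames(f$pvalue[, 1], colnames(X)),
        n = as.integer(f$n), df = as.integer(f$df), rss = f$rss[[1]],
        aic = f$aic[[1]], nDropped = as.integer(nDropped))
}

#' Fit one design against many outcomes at once
#'
#' Shares a single QR decomposition across outcome columns; used for
#' per-node sweeps and calibration simulations.
#'
#' @param Y numeric matrix, one outcome per column.
#' @param design data.frame or matrix of predictors (no intercept column).
#' @return list of matrices `coefficients`, `se`, `tstat`, `pvalue`
#'   (coefficients x outcomes), vectors `rss` and `aic`, scalars `df`, `n`.
#' @export
fitGlmMulti <- function(Y, design) {
    Y <- as.matrix(Y)
    X <- .designMatrix(design)
    if (anyNA(X) || anyNA(Y))
        stop("fitGlmMulti requires complete data")
    if (nrow(Y) != nrow(X)) stop("Y and design row counts differ")
    .olsEngine(X, Y)
}

#' @describeIn fitGlm coefficients of a fitted model.
#' @param object,... a [GlmFit-class] (further arguments ignored).
#' @export
setMethod("coef", "GlmFit", function(object, ...) object@coefficients)

#' Coefficient table of a GlmFit
#' @param fit a [GlmFit-class].
#' @return data.frame with predictor, beta, se, t, p.
#' @export
coefTable <- function(fit) {
    data.frame(predictor = fit@predictors, beta = as.numeric(fit@coefficients),
               se = as.numeric(fit@se), t = as.numeric(fit@tstat),
               p = as.numeric(fit@pvalue), row.names = NULL)
}

setMethod("show", "GlmFit", function(object) {
    cat(sprintf("GlmFit for '%s' (n = %d, df = %d, AIC = %.2f)\n",
                object@outcome, object@n, object@df, object@aic))
    tab <- coefTable(object)
    tab$beta <- signif(tab$beta, 4); tab$se <- signif(tab$se, 4)
    tab$t <- signif(tab$t, 3); tab$p <- signif(tab$p, 3)
    print(tab, row.names = FALSE)
})

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, clipped to 1 and monotone in the input
#' ranking.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @examples
#' fdrCorrect(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdrCorrect <- function(pvals) {
    if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvals, method = "BH")
}

#' Choose between models with and without the interaction term
#'
#' Keeps the interaction model when the interaction term is significant
#' (p < 0.05); otherwise keeps whichever model has the lower AIC, with the
#' model without the interaction preferred on an exact tie (parsimony).
#'
#' @param fitWith [GlmFit-class] including the interaction term.
#' @param fitWithout [GlmFit-class] without it.
#' @param interactionP p-value of the interaction term; defaults to the
#'   `adci:lbci` p-value found in `fitWith`.
#' @param alpha significance level for the interaction; default 0.05.
#' @return list with `fit` (the chosen [GlmFit-class]), `choice`
#'   (`"with"`/`"without"`) and `rationale` (human-readable record).
#' @export
selectModelByAic <- function(fitWith, fitWithout, interactionP = NULL,
                             alpha = 0.05) {
    if (fitWith@n != fitWithout@n)
        stop("models were fitted on different rows (n = ", fitWith@n,
             " vs ", fitWithout@n, ")")
    if (is.null(interactionP)) {
        ip <- grep(":", fitWith@predictors)
        if (!length(ip)) stop("fitWith has no interaction term")
        interactionP <- unname(fitWith@pvalue[ip[1]])
    }
    if (interactionP < alpha) {
        choice <- "with"
        rationale <- sprintf(
            "interaction significant (p = %.4g < %.2g); interaction model kept",
            interactionP, alpha)
    } else if (fitWith@aic < fitWithout@aic) {
        choice <- "with"
        rationale <- sprintf(
            "interaction n.s. (p = %.4g); AIC favors interaction model (%.2f < %.2f)",
            interactionP, fitWith@aic, fitWithout@aic)
    } else {
        choice <- "without"
        rationale <- sprintf(
            "interaction n.s. (p = %.4g); AIC favors model without interaction (%.2f <= %.2f)",
            interactionP, fitWithout@aic, fitWith@aic)
    }
    list(fit = if (choice == "with") fitWith else fitWithout,
         choice = choice, rationale = rationale)
}
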