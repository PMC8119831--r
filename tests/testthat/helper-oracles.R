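# Brute-force reference implementations, deliberately independent of the
# package's code paths: Floyd-Warshall instead of Dijkstra, explicit triple
# loops instead of matrix products, a distance-matrix path-count DP instead
# of Brandes accumulation, normal equations instead of QR.

randomWeightedGraph <- function(n, density = 0.5) {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    on <- ut[runif(length(ut)) < density]
    w[on] <- runif(length(on), 0.2, 2)
    w <- w + t(w)
    dimnames(w) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
    w
}

oracleDistances <- function(w) {
    n <- nrow(w)
    d <- ifelse(w > 0, 1 / w, Inf)
    diag(d) <- 0
    for (k in seq_len(n))
        d <- pmin(d, outer(d[, k], d[k, ], `+`))
    d
}

oracleDegree <- function(w)
    vapply(seq_len(nrow(w)), function(i) sum(w[i, ] > 0), numeric(1))

oracleStrength <- function(w)
    vapply(seq_len(nrow(w)), function(i) sum(w[i, ]), numeric(1))

oracleClustering <- function(w) {
    n <- nrow(w)
    out <- numeric(n)
    mx <- max(w)
    if (mx == 0) return(out)
    wh <- w / mx
    for (i in seq_len(n)) {
        k <- sum(w[i, ] > 0)
        if (k < 2) next
        s <- 0
        for (j in seq_len(n)) for (h in seq_len(n))
            if (j != i && h != i && j != h)
                s <- s + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
        out[i] <- s / (k * (k - 1))
    }
    out
}

# Shortest-path counts sigma[s, v] by DP over the Floyd-Warshall distance
# matrix (predecessors of v on s-shortest paths are strictly closer to s,
# so processing nodes by distance is well-defined); betweenness by the
# pair-dependency formula.
oracleBetweenness <- function(w, tol = 1e-10) {
    n <- nrow(w)
    d <- oracleDistances(w)
    len <- ifelse(w > 0, 1 / w, Inf)
    sigma <- matrix(0, n, n)
    for (s in seq_len(n)) {
        sigma[s, s] <- 1
        for (v in order(d[s, ])) {
            if (v == s || !is.finite(d[s, v])) next
            pred <- which(is.finite(len[, v]) &
                          abs(d[s, ] + len[, v] - d[s, v]) < tol)
            sigma[s, v] <- sum(sigma[s, pred])
        }
    }
    bc <- numeric(n)
    for (v in seq_len(n))
        for (s in seq_len(n - 1)) for (t2 in seq(s + 1, n)) {
            if (s == v || t2 == v || !is.finite(d[s, t2])) next
            if (abs(d[s, v] + d[v, t2] - d[s, t2]) < tol)
                bc[v] <- bc[v] + sigma[s, v] * sigma[t2, v] / sigma[s, t2]
        }
    bc
}

oracleGlobals <- function(w) {
    d <- oracleDistances(w)
    off <- d[row(d) != col(d)]
    fin <- off[is.finite(off)]
    c(meanDegree = mean(oracleDegree(w)),
      meanStrength = mean(oracleStrength(w)),
      clustering = mean(oracleClustering(w)),
      pathLength = if (length(fin)) mean(fin) else NA_real_,
      globalEfficiency = mean(ifelse(is.finite(off), 1 / off, 0)))
}

# Textbook normal-equations OLS (X includes the intercept column).
oracleOLS <- function(y, X) {
    xtxInv <- solve(t(X) %*% X)
    beta <- xtxInv %*% t(X) %*% y
    res <- y - X %*% beta
    df <- nrow(X) - ncol(X)
    rss <- sum(res^2)
    se <- sqrt(diag(xtxInv) * rss / df)
    tt <- drop(beta) / se
    list(beta = drop(beta), se = se, t = tt,
         p = 2 * pt(-abs(tt), df), rss = rss, df = df)
}
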