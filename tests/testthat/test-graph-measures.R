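test_that("degree and strength match closed forms on canonical graphs", {
    expect_equal(unname(nodeDegree(triangleNet())), c(2, 2, 2))
    st <- starNet(5)
    expect_equal(unname(nodeDegree(st)), c(4, 1, 1, 1, 1))
    expect_equal(unname(nodeStrength(triangleNet(1, 2, 0.5))),
                 c(3, 1.5, 2.5))
    # handshake identity
    set.seed(1)
    w <- randomWeightedGraph(8)
    expect_equal(sum(nodeStrength(w)), 2 * sum(w[upper.tri(w)]))
})

test_that("Onnela clustering matches hand-evaluated cases", {
    expect_equal(unname(localClustering(triangleNet(1, 1, 1))), c(1, 1, 1))
    # path graph has no triangles
    path <- matrix(0, 4, 4)
    path[cbind(1:3, 2:4)] <- 1; path <- path + t(path)
    expect_equal(unname(localClustering(path)), rep(0, 4))
    # w_ab = w_ac = 1, w_bc = 0.125: C_a = (1 * 1 * 0.125)^(1/3) = 0.5
    expect_equal(unname(localClustering(triangleNet(1, 1, 0.125))[1]), 0.5)
})

test_that("shortest-path distances invert weights and flag disconnection", {
    chain <- matrix(0, 3, 3)
    chain[1, 2] <- chain[2, 1] <- chain[2, 3] <- chain[3, 2] <- 1
    d <- shortestPathDistances(chain)
    expect_equal(d[1, 3], 2)
    # a single edge of weight 2 is 0.5 away
    e <- matrix(0, 2, 2); e[1, 2] <- e[2, 1] <- 2
    expect_equal(shortestPathDistances(e)[1, 2], 0.5)
    # disconnected components are infinitely far apart
    two <- matrix(0, 4, 4)
    two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 1
    expect_identical(shortestPathDistances(two)[1, 3], Inf)
})

test_that("nodal path length averages finite distances, isolated nodes warn", {
    d <- shortestPathDistances(edgeWeights(starNet(5)))
    L <- nodalPathLength(d)
    expect_equal(unname(L), c(1, rep((1 + 3 * 2) / 4, 4)))
    cmplt <- matrix(1, 4, 4); diag(cmplt) <- 0
    expect_equal(unname(nodalPathLength(shortestPathDistances(cmplt))),
                 rep(1, 4))
    iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
    expect_warning(Liso <- nodalPathLength(shortestPathDistances(iso)),
                   "reach no other node")
    expect_equal(unname(Liso[3]), 0)
})

test_that("betweenness matches the star closed form and vanishes on complete graphs", {
    bc <- betweennessCentrality(starNet(5))
    expect_equal(unname(bc), c(6, 0, 0, 0, 0))  # (n-1)(n-2)/2 = 6
    cmplt <- matrix(1, 5, 5); diag(cmplt) <- 0
    expect_equal(unname(betweennessCentrality(cmplt)), rep(0, 5))
})

test_that("raw global measures match hand enumeration on a 3-chain", {
    chain <- matrix(0, 3, 3)
    chain[1, 2] <- chain[2, 1] <- chain[2, 3] <- chain[3, 2] <- 1
    g <- globalMeasures(chain)
    expect_equal(g[["pathLength"]], 4 / 3)
    expect_equal(g[["globalEfficiency"]], 5 / 6)
    cmplt <- matrix(1, 4, 4); diag(cmplt) <- 0
    gc <- globalMeasures(cmplt)
    expect_equal(gc[["pathLength"]], 1)
    expect_equal(gc[["globalEfficiency"]], 1)
    # no connected pair: efficiency 0, L undefined
    expect_warning(ge <- globalMeasures(matrix(0, 2, 2)), "no connected")
    expect_equal(ge[["globalEfficiency"]], 0)
    expect_true(is.na(ge[["pathLength"]]))
    # normalized fields unset before normalization
    expect_true(all(is.na(g[c("gamma", "lambda", "normEglob", "sigma")])))
})

test_that("all measures agree with brute-force oracles on random small networks", {
    set.seed(20260915)
    for (rep in seq_len(60)) {
        n <- sample(4:8, 1)
        w <- randomWeightedGraph(n, density = runif(1, 0.3, 0.9))
        expect_equal(unname(nodeDegree(w)), oracleDegree(w), tolerance = 1e-9)
        expect_equal(unname(nodeStrength(w)), oracleStrength(w),
                     tolerance = 1e-9)
        expect_equal(unname(localClustering(w)), oracleClustering(w),
                     tolerance = 1e-9)
        expect_equal(unname(shortestPathDistances(w)), unname(oracleDistances(w)),
                     tolerance = 1e-9)
        expect_equal(unname(betweennessCentrality(w)), oracleBetweenness(w),
                     tolerance = 1e-9)
        og <- oracleGlobals(w)
        pg <- suppressWarnings(globalMeasures(w))[names(og)]
        expect_equal(unname(pg), unname(og), tolerance = 1e-9)
    }
})

test_that("node relabeling permutes local measures and fixes global ones", {
    set.seed(5)
    w <- randomWeightedGraph(9, 0.5)
    perm <- sample(9)
    wp <- w[perm, perm]
    expect_equal(unname(nodeDegree(wp)), unname(nodeDegree(w))[perm])
    expect_equal(unname(betweennessCentrality(wp)),
                 unname(betweennessCentrality(w))[perm], tolerance = 1e-12)
    expect_equal(suppressWarnings(globalMeasures(wp))[1:5],
                 suppressWarnings(globalMeasures(w))[1:5], tolerance = 1e-12)
})

test_that("weight rescaling acts as expected on each measure", {
    set.seed(6)
    w <- randomWeightedGraph(8, 0.6)
    c0 <- 3.7
    ws <- w * c0
    expect_equal(nodeDegree(ws), nodeDegree(w))
    expect_equal(nodeStrength(ws), nodeStrength(w) * c0)
    expect_equal(localClustering(ws), localClustering(w))  # scale-free
    expect_equal(shortestPathDistances(ws), shortestPathDistances(w) / c0)
    expect_equal(order(betweennessCentrality(ws)),
                 order(betweennessCentrality(w)))
})
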