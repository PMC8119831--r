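# Shared fixture builders.  Everything is generated in code; tests set
# their own seeds before calling these.

# Compact parcellation for fast cohort-level tests; keeps the node labels
# the default planted effects and cognition model refer to.
smallParcellation <- function(n = 30) {
    stopifnot(n >= 4, n %% 2 == 0)
    base <- c("Caudate", "Calcarine", "Occipital_Inf")
    if (n / 2 > 3) base <- c(base, paste0("Region", seq_len(n / 2 - 3)))
    labels <- as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
    parcellation(labels, rep(c("L", "R"), n / 2))
}

smallConfig <- function(groupSizes = c(control = 10L, pure_ADCI = 10L,
                                       pure_LBCI = 10L, mixed = 10L),
                        seed = 1L, ...) {
    cohortConfig(groupSizes = groupSizes, seed = seed, ...)
}

# Weighted triangle a-b-c.
triangleNet <- function(wab = 1, wac = 1, wbc = 1) {
    w <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    w["a", "b"] <- w["b", "a"] <- wab
    w["a", "c"] <- w["c", "a"] <- wac
    w["b", "c"] <- w["c", "b"] <- wbc
    weightedNetwork(w)
}

# n-node star, node 1 at the center.
starNet <- function(n = 5, weight = 1) {
    w <- matrix(0, n, n)
    w[1, 2:n] <- w[2:n, 1] <- weight
    weightedNetwork(w)
}

# Toy SubjectRaw over 3 nodes with a single a-b connection.
toyRaw <- function(count, fa = 0.5, volumes = c(2, 2, 2)) {
    counts <- matrix(0, 3, 3)
    counts[1, 2] <- counts[2, 1] <- count
    fam <- matrix(0, 3, 3)
    if (count > 0) fam[1, 2] <- fam[2, 1] <- fa
    subjectRaw("toy", counts, fam, volumes, icv = 1.4e6,
               labels = letters[1:3])
}

# Ring lattice: each node tied to its k nearest neighbours per side.
ringLatticeNet <- function(n = 92, k = 2, weight = 1) {
    w <- matrix(0, n, n)
    for (s in seq_len(k)) {
        idx <- cbind(seq_len(n), (seq_len(n) + s - 1) %% n + 1)
        w[idx] <- weight
        w[idx[, 2:1]] <- weight
    }
    weightedNetwork(w)
}
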