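## Independent oracles and small fixtures used across the suite.

## Patristic distance by brute force: depth(i) + depth(j) - 2 * depth(mrca).
oraclePatristic <- function(tree) {
    n <- length(tree$tip.label)
    depths <- ape::node.depth.edgelength(tree)
    out <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        mrca <- ape::getMRCA(tree, c(i, j))
        out[i, j] <- out[j, i] <- depths[i] + depths[j] - 2 * depths[mrca]
    }
    out
}

## Exhaustive k-medoids: minimum assignment cost over all medoid subsets.
oraclePamCost <- function(d, k) {
    n <- nrow(d)
    best <- Inf
    for (med in utils::combn(n, k, simplify = FALSE)) {
        cost <- sum(apply(d[, med, drop = FALSE], 1, min))
        if (cost < best) best <- cost
    }
    best
}

pamAssignmentCost <- function(d, fa) {
    med <- match(foldMedoids(fa), rownames(d))
    sum(apply(d[, med, drop = FALSE], 1, min))
}

## TRUE when no single (medoid, non-medoid) exchange lowers the cost.
pamIsLocalOptimum <- function(d, fa) {
    med <- match(foldMedoids(fa), rownames(d))
    cost <- pamAssignmentCost(d, fa)
    for (m in med) for (cand in setdiff(seq_len(nrow(d)), med)) {
        trial <- c(setdiff(med, m), cand)
        if (sum(apply(d[, trial, drop = FALSE], 1, min)) < cost - 1e-12)
            return(FALSE)
    }
    TRUE
}

## Pearson chi-square by direct summation of (O - E)^2 / E.
oracleChiSquare <- function(counts) {
    E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    sum((counts - E)^2 / E)
}

## Logistic log-likelihood for a design with leading intercept column.
logisticNegLogLik <- function(beta, Z, y) {
    eta <- drop(Z %*% beta)
    -sum(y * eta - log1p(exp(eta)))
}

## A small balanced four-clade tree: long stems, short within-clade branches.
fourCladeTree <- function() {
    clade <- function(a, b) sprintf("(%s:0.1,%s:0.1):5", a, b)
    parseNewick(sprintf("((%s,%s):1,(%s,%s):1);",
                        clade("a1", "a2"), clade("b1", "b2"),
                        clade("c1", "c2"), clade("d1", "d2")))
}

## 2x2 confidence table whose scores are [[1, 0], [0.74, 0.5]].
toyConfidenceTable <- function() {
    cp <- matrix(c(1, 0, 0.8, 0.5), 2, 2, byrow = TRUE,
                 dimnames = list(c("sp1", "sp2"), c("tA", "tB")))
    cm <- matrix(c(0, 1, 0.2, 0.5), 2, 2, byrow = TRUE,
                 dimnames = dimnames(cp))
    ConfidenceTable(cp, cm)
}
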