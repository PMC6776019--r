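test_that("parseNewick validates structure and round-trips", {
    tr <- parseNewick("((A:1,B:2):3,C:4);")
    expect_equal(length(tr$tip.label), 3L)
    expect_equal(tr$Nnode, 2L)

    sim <- simulateTree(50, seed = 9)
    rt <- parseNewick(ape::write.tree(sim, digits = 12))
    expect_setequal(rt$tip.label, sim$tip.label)
    expect_equal(sort(rt$edge.length), sort(sim$edge.length),
                 tolerance = 1e-9)
    expect_equal(patristicMatrix(rt)[sim$tip.label, sim$tip.label],
                 patristicMatrix(sim), tolerance = 1e-9)

    expect_error(parseNewick("((A:1,B:2):3,C:4;"), "unbalanced")
    expect_error(parseNewick("((A:1,B):3,C:4);"), "branch length")
})

test_that("patristic distances equal hand path sums and the MRCA oracle", {
    tr <- parseNewick("((A:1,B:2):3,C:4);")
    d <- patristicMatrix(tr)
    expect_equal(d["A", "B"], 3)
    expect_equal(d["A", "C"], 8)
    expect_equal(d["B", "C"], 9)
    expect_true(all(diag(d) == 0))
    expect_equal(d, t(d))

    sim <- simulateTree(25, seed = 10)
    expect_equal(patristicMatrix(sim), oraclePatristic(sim), tolerance = 1e-9)
})

test_that("patristic distances satisfy the four-point condition", {
    tr <- simulateTree(40, seed = 11)
    d <- patristicMatrix(tr)
    set.seed(11)
    for (rep in 1:50) {
        q <- sample(40, 4)
        s <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                    d[q[1], q[3]] + d[q[2], q[4]],
                    d[q[1], q[4]] + d[q[2], q[3]]))
        expect_lt(s[3] - s[2], 1e-9)  # two largest sums equal
    }
})

test_that("pamCluster separates obvious blocks and is exhaustively optimal", {
    ## two tight pairs far apart
    d <- matrix(10, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    d[1, 2] <- d[2, 1] <- 1; d[3, 4] <- d[4, 3] <- 1; diag(d) <- 0
    fa <- pamCluster(d, 2)
    f <- foldIds(fa)
    expect_identical(unname(f["a"]), unname(f["b"]))
    expect_identical(unname(f["c"]), unname(f["d"]))
    expect_false(f["a"] == f["c"])

    ## k = n: every point its own medoid, zero cost
    fa4 <- pamCluster(d, 4)
    expect_setequal(foldMedoids(fa4), letters[1:4])
    expect_equal(pamAssignmentCost(d, fa4), 0)

    ## random instances with n <= 8: BUILD+SWAP reaches the exhaustive
    ## optimum or a verified swap-local optimum; the swap trace never rises
    set.seed(12)
    nOptimal <- 0
    for (rep in 1:20) {
        n <- sample(4:8, 1); k <- sample(2:3, 1)
        p <- matrix(rnorm(2 * n), n)
        d <- as.matrix(dist(p))
        dimnames(d) <- list(paste0("x", 1:n), paste0("x", 1:n))
        fa <- pamCluster(d, k)
        cost <- pamAssignmentCost(d, fa)
        opt <- oraclePamCost(d, k)
        expect_gte(cost, opt - 1e-9)
        if (abs(cost - opt) < 1e-9) nOptimal <- nOptimal + 1
        else expect_true(pamIsLocalOptimum(d, fa))
        expect_true(all(diff(attr(fa, "costTrace")) < 0))
        expect_equal(cost, utils::tail(attr(fa, "costTrace"), 1),
                     tolerance = 1e-9)
    }
    expect_gte(nOptimal, 15)  # the local-optimum escape hatch stays rare

    expect_error(pamCluster(d, 99), "1..n")
})

test_that("pamCluster agrees with the reference PAM cost on larger instances", {
    skip_if_not_installed("cluster")
    set.seed(13)
    for (rep in 1:5) {
        p <- matrix(rnorm(60), 30)
        d <- as.matrix(dist(p))
        dimnames(d) <- list(paste0("x", 1:30), paste0("x", 1:30))
        fa <- pamCluster(d, 4)
        ref <- cluster::pam(as.dist(d), 4)
        refCost <- sum(apply(d[, ref$id.med, drop = FALSE], 1, min))
        ## both are swap-local optima of the same objective; they may differ
        ## in which optimum they land in, but not substantially in quality
        expect_lt(abs(pamAssignmentCost(d, fa) - refCost), 0.1 * refCost)
        expect_true(pamIsLocalOptimum(d, fa))
    }
})

test_that("blocked folds recover clades and are deterministic", {
    tr <- fourCladeTree()
    fa <- makeBlockedFolds(tr, k = 4)
    f <- foldIds(fa)
    for (cl in c("a", "b", "c", "d")) {
        pair <- paste0(cl, 1:2)
        expect_identical(unname(f[pair[1]]), unname(f[pair[2]]))
    }
    expect_equal(length(unique(f)), 4L)
    expect_identical(foldIds(makeBlockedFolds(tr, k = 4)), f)

    expect_error(makeBlockedFolds(tr, k = 1), "k >= 2")
    expect_error(makeBlockedFolds(tr, k = 4, species = c("a1", "zz")), "zz")
})

test_that("blocked folds on a star tree still give a usable partition", {
    star <- ape::stree(12, type = "star")
    star$edge.length <- rep(1, nrow(star$edge))
    fa <- makeBlockedFolds(star, k = 4)
    expect_equal(sort(unique(foldIds(fa))), 1:4)
    expect_true(all(tabulate(foldIds(fa), 4) > 0))
})

test_that("random folds are balanced, seeded and marginally uniform", {
    sp <- paste0("s", 1:10)
    fa <- makeRandomFolds(sp, k = 5, seed = 1)
    expect_equal(unname(tabulate(foldIds(fa), 5)), rep(2L, 5))
    expect_identical(foldIds(makeRandomFolds(sp, 5, seed = 1)), foldIds(fa))
    expect_false(identical(foldIds(makeRandomFolds(sp, 5, seed = 2)),
                           foldIds(fa)))

    ## fold frequency of one species over many seeds ~ uniform
    n <- 1000
    firstFold <- vapply(seq_len(n), function(s)
        foldIds(makeRandomFolds(sp, 5, seed = s))[["s1"]], integer(1))
    freq <- tabulate(firstFold, 5) / n
    se <- sqrt(0.2 * 0.8 / n)
    expect_true(all(abs(freq - 0.2) < 3 * se))
})

test_that("holdoutSplit is disjoint, exhaustive and guards its edges", {
    sp <- paste0("s", 1:20)
    fa <- makeRandomFolds(sp, k = 5, seed = 3)
    out <- holdoutSplit(sp, 3, fa)
    expect_setequal(c(out$train, out$test), sp)
    expect_length(intersect(out$train, out$test), 0)
    expect_setequal(out$test, names(foldIds(fa))[foldIds(fa) == 3])

    out2 <- holdoutSplit(sp, c("s1", "s5"))
    expect_setequal(out2$test, c("s1", "s5"))

    expect_error(holdoutSplit(sp, sp), "empty side")
    expect_error(holdoutSplit(sp, 3), "FoldAssignment")
    expect_error(holdoutSplit(sp, c("s1", "nope")), "nope")
})
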