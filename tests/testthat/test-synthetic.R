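test_that("simulated Yule trees are unit-depth, ultrametric and deterministic", {
    expect_error(simulateTree(1), "nSpecies")

    tr2 <- simulateTree(2, seed = 1)
    depths2 <- ape::node.depth.edgelength(tr2)[1:2]
    expect_equal(depths2, c(1, 1))
    expect_equal(length(tr2$tip.label), 2L)

    tr <- simulateTree(50, seed = 1)
    expect_identical(ape::write.tree(tr),
                     ape::write.tree(simulateTree(50, seed = 1)))
    expect_equal(tr$Nnode, 49L)  # strictly bifurcating rooted tree
    expect_true(all(tr$edge.length > 0))
    tipDepths <- ape::node.depth.edgelength(tr)[1:50]
    expect_equal(tipDepths, rep(1, 50), tolerance = 1e-9)
})

test_that("Mk trait simulation matches the 2-state CTMC closed form", {
    ## two tips joined at the root, each branch length 1:
    ## P(tips differ) = p(1-q) + q(1-p) with p = q = (1 - exp(-2r))/2
    tree <- parseNewick("(A:1,B:1);")
    r <- 0.7
    x <- simulateTraits(tree, nTraits = 10000, signalFraction = 1,
                        mkRate = r, seed = 42)
    p <- (1 - exp(-2 * r)) / 2
    pDiff <- 2 * p * (1 - p)
    obs <- mean(x["A", ] != x["B", ])
    se <- sqrt(pDiff * (1 - pDiff) / 10000)
    expect_lt(abs(obs - pDiff), 3 * se)
})

test_that("mkRate = 0 freezes every signal trait at its root state", {
    tree <- simulateTree(30, seed = 2)
    x <- simulateTraits(tree, nTraits = 20, signalFraction = 1, mkRate = 0,
                        seed = 2)
    expect_true(all(apply(x, 2, function(col) length(unique(col)) == 1L)))
    expect_error(simulateTraits(tree, 5, mkRate = -1), "nonnegative")
})

test_that("signalFraction = 0 gives phylogenetically unstructured traits", {
    tree <- simulateTree(100, seed = 3)
    x <- simulateTraits(tree, nTraits = 200, signalFraction = 0, seed = 3)
    ## correlation between the two tips of each cherry, across traits
    sisters <-which(tabulate(tree$edge[, 1])[tree$edge[, 1]] == 2 &
                     tree$edge[, 2] <= 100)
    parents <- tree$edge[sisters, 1]
    cherries <- split(tree$edge[sisters, 2], parents)
    cherries <- Filter(function(p) length(p) == 2, cherries)
    rs <- vapply(cherries, function(p) {
        a <- x[p[1], ]; b <- x[p[2], ]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
        stats::cor(a, b)
    }, numeric(1))
    expect_lt(abs(mean(rs)), 0.1)
})

test_that("confidence simulation respects missingness and informativeness", {
    tree <- simulateTree(300, seed = 4)
    x <- simulateTraits(tree, 100, seed = 4)

    ctAll <- simulateConfidences(x, missingFraction = 1, seed = 4)
    expect_true(all(is.na(ctAll@cplus)))

    ct <- simulateConfidences(x, missingFraction = 0.18, seed = 4)
    expect_lt(abs(mean(is.na(ct@cplus)) - 0.18), 0.02)
    expect_identical(is.na(ct@cplus), is.na(ct@cminus))

    ## strength 8: derived scores separate true 1s from true 0s
    ct8 <- simulateConfidences(x, confidenceStrength = 8, missingFraction = 0,
                               seed = 4)
    p <- traitScores(scoreTable(ct8))
    expect_gt(mean(p[x == 1]), 0.5)
    expect_lt(mean(p[x == 0]), 0.5)

    expect_error(simulateConfidences(x, missingFraction = 1.5), "missingFraction")
    expect_error(simulateConfidences(x, confidenceStrength = 0.5), ">= 1")
})

test_that("liability outcome hits target prevalence and responds to drivers", {
    tree <- simulateTree(300, seed = 5)
    x <- simulateTraits(tree, 10, seed = 5)

    y <- simulateOutcome(x, tree, phyloLiabilitySd = 0,
                         targetPrevalence = 0.5, seed = 5)
    expect_lte(abs(mean(y) - 0.5), 1 / 300)
    expect_named(y)

    y2 <- simulateOutcome(x, tree, targetPrevalence = 0.45, seed = 5)
    expect_lte(abs(mean(y2) - 0.45), 1 / 300)

    ## a strong single driver leaves a clear phi correlation
    hits <- vapply(1:20, function(s) {
        tr <- simulateTree(300, seed = s)
        xx <- simulateTraits(tr, 10, seed = s)
        yy <- simulateOutcome(xx, tr, driverIndices = 1L, driverEffects = 3,
                              phyloLiabilitySd = 1, targetPrevalence = 0.5,
                              seed = s)
        phiCorrelation(xx[, 1], yy[names(yy)]) > 0.3
    }, logical(1))
    expect_gte(sum(hits), 18)

    expect_error(simulateOutcome(x, tree, driverIndices = 99L,
                                 driverEffects = 1), "out of range")
})

test_that("phylogenetic liability makes sister tips agree more than random pairs", {
    agreeSis <- agreeRand <- numeric(10)
    for (s in 1:10) {
        tree <- simulateTree(200, seed = s)
        x <- simulateTraits(tree, 2, seed = s)
        y <- simulateOutcome(x, tree, phyloLiabilitySd = 2,
                             targetPrevalence = 0.5, seed = s)
        sisters <- which(tabulate(tree$edge[, 1])[tree$edge[, 1]] == 2 &
                         tree$edge[, 2] <= 200)
        cherries <- Filter(function(p) length(p) == 2,
                           split(tree$edge[sisters, 2], tree$edge[sisters, 1]))
        agreeSis[s] <- mean(vapply(cherries, function(p)
            y[p[1]] == y[p[2]], logical(1)))
        set.seed(s)
        i <- sample(200, 500, TRUE); j <- sample(200, 500, TRUE)
        ok <- i != j
        agreeRand[s] <- mean(y[i[ok]] == y[j[ok]])
    }
    expect_gt(mean(agreeSis), mean(agreeRand))
})

test_that("generateDataset is deterministic, shaped by config, byte-stable", {
    cfg <- SimulationConfig(nSpecies = 300, nTraits = 30, seed = 11)
    b <- generateDataset(cfg)
    expect_equal(dim(b$traits), c(300L, 30L))
    expect_length(b$labels, 300L)

    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeBundle(b, d1)
    writeBundle(generateDataset(cfg), d2)
    for (f in list.files(d1)) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), label = f)
    }

    b0 <- generateDataset(SimulationConfig(nSpecies = 50, nTraits = 10,
                                           missingFraction = 0, seed = 1))
    expect_false(anyNA(b0$confidences@cplus))

    ## round trip through the bundle readers
    rb <- readBundle(d1)
    expect_equal(rb$traits, b$traits * 1)
    expect_equal(rb$labels, b$labels)
    expect_equal(rb$confidences@cplus, b$confidences@cplus, tolerance = 1e-9)
    expect_equal(ape::write.tree(rb$tree), ape::write.tree(b$tree))
})

test_that("invalid simulation configs are rejected", {
    expect_error(SimulationConfig(nSpecies = 1), "nSpecies")
    expect_error(SimulationConfig(missingFraction = 2), "missingFraction")
    expect_error(SimulationConfig(driverIndices = 1:2, driverEffects = 1),
                 "equal length")
    expect_error(SimulationConfig(driverIndices = 40L, driverEffects = 1,
                                  nTraits = 30), "1..nTraits")
})
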