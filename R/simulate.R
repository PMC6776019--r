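#' Simulate a unit-depth Yule tree
#'
#' Pure-birth tree with \code{nSpecies} tips, rescaled so every root-to-tip
#' path has length one. Tips are labelled \code{sp1..spN}.
#'
#' @param nSpecies number of tips (>= 2).
#' @param seed integer seed; the same seed always yields the same tree.
#' @return An ultrametric rooted \code{ape::phylo} with positive branch
#'   lengths and unit depth.
#' @examples
#' tr <- simulateTree(20, seed = 1)
#' max(ape::node.depth.edgelength(tr))  # 1
#' @export
simulateTree <- function(nSpecies, seed = 1L) {
    if (length(nSpecies) != 1L || nSpecies < 2)
        stop("nSpecies must be >= 2", call. = FALSE)
    nSpecies <- as.integer(nSpecies)
    set.seed(deriveSubSeed(seed, "tree"))
    tr <- ape::rphylo(nSpecies, birth = 1, death = 0)
    tr$tip.label <- paste0("sp", seq_len(nSpecies))
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr
}

## Simulate one binary character down the tree under a symmetric 2-state Mk
## model: root ~ Bernoulli(0.5), per-edge flip probability
## (1 - exp(-2 * rate * t)) / 2 (the exact CTMC endpoint distribution).
.simulateMkTrait <- function(tree, rate) {
    ntip <- length(tree$tip.label)
    state <- integer(ntip + tree$Nnode)
    root <- ntip + 1L
    state[root] <- stats::rbinom(1L, 1L, 0.5)
    ord <- ape::reorder.phylo(tree, "cladewise")
    pflip <- (1 - exp(-2 * rate * ord$edge.length)) / 2
    flips <- stats::rbinom(nrow(ord$edge), 1L, pflip)
    for (e in seq_len(nrow(ord$edge))) {
        child <- ord$edge[e, 2L]
        state[child] <- if (flips[e] == 1L) 1L - state[ord$edge[e, 1L]]
                        else state[ord$edge[e, 1L]]
    }
    state[seq_len(ntip)]
}

#' Simulate binary traits with (partial) phylogenetic signal
#'
#' The first \code{floor(signalFraction * nTraits)} traits evolve down the
#' tree under a symmetric two-state Mk model from a Bernoulli(0.5) root state;
#' the remaining traits are i.i.d. Bernoulli(0.5) across species.
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @param nTraits number of trait columns.
#' @param signalFraction fraction of traits evolved on the tree.
#' @param mkRate nonnegative transition rate per unit branch length.
#' @param seed integer seed.
#' @return Binary matrix (tips x traits) with rownames = tip labels and
#'   colnames \code{trait01..}; signal traits occupy the leading columns.
#' @export
simulateTraits <- function(tree, nTraits, signalFraction = 0.8, mkRate = 1,
                           seed = 1L) {
    if (mkRate < 0) stop("mkRate must be nonnegative", call. = FALSE)
    .assertProb(signalFraction, "signalFraction")
    nTraits <- as.integer(nTraits)
    ntip <- length(tree$tip.label)
    nSignal <- as.integer(floor(signalFraction * nTraits))
    set.seed(deriveSubSeed(seed, "traits"))
    out <- matrix(0L, ntip, nTraits,
                  dimnames = list(tree$tip.label,
                                  sprintf("trait%02d", seq_len(nTraits))))
    for (j in seq_len(nSignal)) out[, j] <- .simulateMkTrait(tree, mkRate)
    if (nSignal < nTraits)
        out[, (nSignal + 1L):nTraits] <-
            stats::rbinom(ntip * (nTraits - nSignal), 1L, 0.5)
    out
}

#' Simulate paired confidence observations of binary traits
#'
#' Emulates text-mined trait confidences: for a true-1 cell, \code{c+} is
#' drawn Beta(\code{confidenceStrength}, 1) and \code{c-} Beta(1,
#' \code{confidenceStrength}); the pair is reversed for a true-0 cell. Cells
#' are then masked missing independently with probability
#' \code{missingFraction}.
#'
#' @param trueTraits binary species x trait matrix.
#' @param confidenceStrength Beta shape parameter >= 1 (1 = uninformative).
#' @param missingFraction per-cell missingness probability in \code{[0, 1]}.
#' @param seed integer seed.
#' @return A \linkS4class{ConfidenceTable}.
#' @export
simulateConfidences <- function(trueTraits, confidenceStrength = 8,
                                missingFraction = 0.18, seed = 1L) {
    if (confidenceStrength < 1)
        stop("confidenceStrength must be >= 1", call. = FALSE)
    if (length(missingFraction) != 1L || is.na(missingFraction) ||
        missingFraction < 0 || missingFraction > 1)
        stop("missingFraction must lie in [0, 1]", call. = FALSE)
    x <- as.matrix(trueTraits)
    set.seed(deriveSubSeed(seed, "confidences"))
    n <- length(x)
    hi <- stats::rbeta(n, confidenceStrength, 1)
    lo <- stats::rbeta(n, 1, confidenceStrength)
    cp <- ifelse(x == 1, hi, lo)
    cm <- ifelse(x == 1, lo, hi)
    miss <- stats::runif(n) < missingFraction
    cp[miss] <- NA_real_
    cm[miss] <- NA_real_
    dim(cp) <- dim(cm) <- dim(x)
    dimnames(cp) <- dimnames(cm) <- dimnames(x)
    ConfidenceTable(cp, cm)
}

#' Simulate a liability-threshold binary outcome on a tree
#'
#' Liability \eqn{L_i = \sum_j \beta_j x_{ij} + B_i + \epsilon_i}, where
#' \eqn{B} is a Brownian motion realised on the tree (variance
#' \code{phyloLiabilitySd^2} at unit depth) and \eqn{\epsilon} is i.i.d.
#' standard normal. Labels are 1 where the liability exceeds the empirical
#' quantile that brings prevalence closest to \code{targetPrevalence}.
#'
#' @param trueTraits binary species x trait matrix (rows match tree tips).
#' @param tree the phylogeny the species evolved on.
#' @param driverIndices,driverEffects causal trait columns and their effects.
#' @param phyloLiabilitySd Brownian standard deviation at unit depth.
#' @param targetPrevalence target fraction of 1 labels.
#' @param seed integer seed.
#' @return Named integer 0/1 vector over species.
#' @export
simulateOutcome <- function(trueTraits, tree, driverIndices = integer(0),
                            driverEffects = numeric(0), phyloLiabilitySd = 1,
                            targetPrevalence = 0.45, seed = 1L) {
    x <- as.matrix(trueTraits)
    if (length(driverIndices) != length(driverEffects))
        stop("driverIndices and driverEffects must match in length", call. = FALSE)
    if (length(driverIndices) &&
        (any(driverIndices < 1) || any(driverIndices > ncol(x))))
        stop("driverIndices out of range", call. = FALSE)
    .assertProb(targetPrevalence, "targetPrevalence")
    x <- x[tree$tip.label, , drop = FALSE]
    n <- nrow(x)
    set.seed(deriveSubSeed(seed, "outcome"))
    L <- as.numeric(x[, driverIndices, drop = FALSE] %*% driverEffects)
    if (phyloLiabilitySd > 0)
        L <- L + ape::rTraitCont(tree, model = "BM",
                                 sigma = phyloLiabilitySd)[tree$tip.label]
    L <- L + stats::rnorm(n)
    m <- round(targetPrevalence * n)
    labels <- integer(n)
    if (m > 0) labels[order(L, decreasing = TRUE)[seq_len(m)]] <- 1L
    names(labels) <- tree$tip.label
    labels
}

#' Generate a complete synthetic study bundle
#'
#' Composes [simulateTree()], [simulateTraits()], [simulateConfidences()] and
#' [simulateOutcome()] with stage sub-seeds derived deterministically from
#' \code{config@seed}, so the same config always produces a bit-identical
#' bundle.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A list with elements \code{tree} (\code{phylo}), \code{traits}
#'   (binary matrix), \code{confidences} (\linkS4class{ConfidenceTable}),
#'   \code{labels} (named 0/1 vector) and \code{config}.
#' @examples
#' b <- generateDataset(SimulationConfig(nSpecies = 40, nTraits = 8, seed = 7))
#' dim(b$traits)
#' @export
generateDataset <- function(config = SimulationConfig()) {
    validObject(config)
    s <- config@seed
    tree <- simulateTree(config@nSpecies, seed = s)
    traits <- simulateTraits(tree, config@nTraits, config@signalFraction,
                             config@mkRate, seed = s)
    conf <- simulateConfidences(traits, config@confidenceStrength,
                                config@missingFraction, seed = s)
    labels <- simulateOutcome(traits, tree, config@driverIndices,
                              config@driverEffects, config@phyloLiabilitySd,
                              config@targetPrevalence, seed = s)
    list(tree = tree, traits = traits, confidences = conf, labels = labels,
         config = config)
}
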