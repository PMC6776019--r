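#' Parse a newick string into a phylogeny
#'
#' Thin validated wrapper around \code{ape::read.tree}: requires balanced
#' parentheses, branch lengths on every edge, and unique tip labels.
#' Write/parse round trips preserve topology and branch lengths.
#'
#' @param text a newick string (or path via [ape::read.tree] semantics is not
#'   supported here; pass the string itself).
#' @return An \code{ape::phylo}.
#' @examples
#' parseNewick("((A:1,B:2):3,C:4);")
#' @export
parseNewick <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    depth <- 0L
    for (i in seq_len(nchar(text))) {
        ch <- substr(text, i, i)
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") depth <- depth - 1L
        if (depth < 0L)
            stop(sprintf("newick parse error at position %d: unbalanced ')'", i),
                 call. = FALSE)
    }
    if (depth != 0L)
        stop("newick parse error: unbalanced '(' (", depth, " unclosed)",
             call. = FALSE)
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
    if (is.null(tr)) stop("newick parse error: unreadable string", call. = FALSE)
    if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
        anyNA(tr$edge.length))
        stop("newick parse error: every edge needs a branch length", call. = FALSE)
    if (any(tr$edge.length < 0))
        stop("branch lengths must be nonnegative", call. = FALSE)
    if (anyDuplicated(tr$tip.label))
        stop("tip labels must be unique", call. = FALSE)
    tr
}

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' tips i and j.
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @return Symmetric numeric matrix with zero diagonal, rows/cols ordered as
#'   \code{tree$tip.label}.
#' @export
patristicMatrix <- function(tree) {
    d <- ape::cophenetic.phylo(tree)
    d[tree$tip.label, tree$tip.label]
}

## Total cost of assigning every point to its nearest medoid.
.pamCost <- function(d, medoids) sum(apply(d[, medoids, drop = FALSE], 1, min))

#' Deterministic partitioning around medoids (PAM)
#'
#' Classic BUILD + SWAP k-medoids on a precomputed distance matrix. BUILD
#' greedily adds the medoid giving the largest cost reduction; SWAP repeatedly
#' applies the single best (medoid, non-medoid) exchange while it lowers the
#' total distance of points to their nearest medoid. All ties are broken by
#' smallest index, so the result is deterministic.
#'
#' @param d symmetric nonnegative distance matrix with labelled rows.
#' @param k number of clusters (2 <= k <= n; k = n allowed and trivial).
#' @param maxSwaps cap on SWAP iterations (default 200).
#' @return A \linkS4class{FoldAssignment} of kind \code{"blocked"} whose folds
#'   are the clusters (fold i = cluster of the i-th medoid in index order).
#'   The objective value after BUILD and after each accepted swap is attached
#'   as \code{attr(, "costTrace")} (non-increasing by construction).
#' @export
pamCluster <- function(d, k, maxSwaps = 200L) {
    d <- as.matrix(d)
    n <- nrow(d)
    if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("s", seq_len(n))
    if (k < 1 || k > n) stop("k must lie in 1..n", call. = FALSE)
    if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0) || any(d < 0))
        stop("d must be a symmetric nonnegative matrix with zero diagonal",
             call. = FALSE)
    k <- as.integer(k)
    ## BUILD
    medoids <- which.min(colSums(d))[1L]
    while (length(medoids) < k) {
        best <- NA_integer_; bestCost <- Inf
        cur <- apply(d[, medoids, drop = FALSE], 1, min)
        for (cand in setdiff(seq_len(n), medoids)) {
            cost <- sum(pmin(cur, d[, cand]))
            if (cost < bestCost - 1e-12) { bestCost <- cost; best <- cand }
        }
        medoids <- c(medoids, best)
    }
    ## SWAP
    cost <- .pamCost(d, medoids)
    costTrace <- cost
    for (iter in seq_len(maxSwaps)) {
        bestCost <- cost; bestSwap <- NULL
        for (mi in seq_along(sort(medoids))) {
            m <- sort(medoids)[mi]
            for (cand in setdiff(seq_len(n), medoids)) {
                trial <- c(setdiff(medoids, m), cand)
                tc <- .pamCost(d, trial)
                if (tc < bestCost - 1e-12) { bestCost <- tc; bestSwap <- c(m, cand) }
            }
        }
        if (is.null(bestSwap)) break
        medoids <- c(setdiff(medoids, bestSwap[1L]), bestSwap[2L])
        cost <- bestCost
        costTrace <- c(costTrace, cost)
    }
    medoids <- sort(medoids)
    ## nearest-medoid assignment, ties to the smallest medoid index
    dm <- d[, medoids, drop = FALSE]
    assign <- apply(dm, 1, which.min)
    out <- new("FoldAssignment",
               folds = stats::setNames(as.integer(assign), rownames(d)),
               k = k, kind = "blocked", medoids = rownames(d)[medoids])
    attr(out, "costTrace") <- costTrace
    out
}

#' Phylogenetically blocked cross-validation folds
#'
#' Clusters the tips of a tree into \code{k} folds by running deterministic
#' PAM ([pamCluster()]) on the patristic distance matrix, so each fold is a
#' phylogenetically coherent block.
#'
#' @param tree an \code{ape::phylo}.
#' @param k number of folds (>= 2; default 5).
#' @param species optional subset of tip labels to assign (default all tips);
#'   species missing from the tree are a hard error.
#' @return A \linkS4class{FoldAssignment} of kind \code{"blocked"}.
#' @export
makeBlockedFolds <- function(tree, k = 5L, species = NULL) {
    if (k < 2) stop("cross-validation needs k >= 2 folds", call. = FALSE)
    if (is.null(species)) species <- tree$tip.label
    missing <- setdiff(species, tree$tip.label)
    if (length(missing))
        stop("species absent from the tree: ",
             paste(missing, collapse = ", "), call. = FALSE)
    d <- patristicMatrix(tree)[species, species]
    pamCluster(d, k)
}

#' Random cross-validation folds
#'
#' Uniform random partition into \code{k} folds whose sizes differ by at most
#' one.
#'
#' @param species character vector of species identifiers.
#' @param k number of folds.
#' @param seed integer seed.
#' @return A \linkS4class{FoldAssignment} of kind \code{"random"}.
#' @export
makeRandomFolds <- function(species, k = 5L, seed = 1L) {
    n <- length(species)
    if (k < 2 || k > n) stop("k must lie in 2..length(species)", call. = FALSE)
    set.seed(deriveSubSeed(seed, "randomfolds"))
    f <- rep(seq_len(k), length.out = n)[sample.int(n)]
    new("FoldAssignment", folds = stats::setNames(as.integer(f), species),
        k = as.integer(k), kind = "random", medoids = character(0))
}

#' Split species into a training set and a held-out test set
#'
#' The test group may be named as a fold index of an existing (typically
#' blocked) \linkS4class{FoldAssignment}, or as an explicit species list. The
#' split is disjoint and exhaustive; downstream fitting must only ever see the
#' training side.
#'
#' @param species all species identifiers.
#' @param testGroup either a single fold index (requires \code{folds}) or a
#'   character vector of test species.
#' @param folds a \linkS4class{FoldAssignment} when \code{testGroup} is a fold
#'   index.
#' @return \code{list(train =, test =)} of species vectors.
#' @export
holdoutSplit <- function(species, testGroup, folds = NULL) {
    if (is.numeric(testGroup) && length(testGroup) == 1L) {
        if (is.null(folds) || !is(folds, "FoldAssignment"))
            stop("a FoldAssignment is required when testGroup is a fold index",
                 call. = FALSE)
        if (testGroup < 1 || testGroup > folds@k)
            stop("fold index out of range", call. = FALSE)
        test <- intersect(species, names(folds@folds)[folds@folds == testGroup])
    } else {
        test <- as.character(testGroup)
        unknown <- setdiff(test, species)
        if (length(unknown))
            stop("test species not in the species universe: ",
                 paste(unknown, collapse = ", "), call. = FALSE)
    }
    train <- setdiff(species, test)
    if (!length(test) || !length(train))
        stop("holdout split leaves an empty side", call. = FALSE)
    list(train = train, test = test)
}
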