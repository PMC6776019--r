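#' Construct a ConfidenceTable
#'
#' @param cplus,cminus numeric species x trait matrices of positive and
#'   negative confidences in \code{[0, 1]}; \code{NA} marks a missing cell and
#'   must appear in both matrices at the same positions.
#' @return A \linkS4class{ConfidenceTable}.
#' @examples
#' cp <- matrix(c(1, 0.8, 0, 0.5), 2, 2,
#'              dimnames = list(c("sp1", "sp2"), c("tA", "tB")))
#' cm <- matrix(c(0, 0.2, 1, 0.5), 2, 2, dimnames = dimnames(cp))
#' ConfidenceTable(cp, cm)
#' @export
ConfidenceTable <- function(cplus, cminus) {
    new("ConfidenceTable", cplus = as.matrix(cplus), cminus = as.matrix(cminus))
}

#' Construct a TraitMatrix
#'
#' @param scores numeric species x trait matrix of scores in \code{[0, 1]},
#'   \code{NA} allowed.
#' @return A \linkS4class{TraitMatrix}; \code{complete} is set from the data.
#' @export
TraitMatrix <- function(scores) {
    scores <- as.matrix(scores)
    new("TraitMatrix", scores = scores, complete = !anyNA(scores))
}

#' Construct a SimulationConfig
#'
#' Default values define the package's reference synthetic study: 300 species
#' on a unit-depth Yule tree, 30 binary traits of which 80\% carry
#' phylogenetic signal (symmetric Mk rate 1), three driver traits with
#' log-odds effects of 2, a Brownian liability residual of unit standard
#' deviation, 45\% outcome prevalence, informative but noisy Beta(8, 1)
#' confidences, and 18\% missing cells.
#'
#' @param nSpecies,nTraits problem size.
#' @param signalFraction fraction of traits evolved on the tree.
#' @param mkRate symmetric Mk transition rate per unit branch length.
#' @param driverIndices,driverEffects outcome drivers and their log-odds
#'   effects.
#' @param phyloLiabilitySd Brownian liability standard deviation at unit depth.
#' @param targetPrevalence target fraction of outcome = 1.
#' @param confidenceStrength Beta shape parameter (>= 1) of confidence noise.
#' @param missingFraction per-cell missingness probability.
#' @param seed master seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @seealso [generateDataset()]
#' @export
SimulationConfig <- function(nSpecies = 300L, nTraits = 30L,
                             signalFraction = 0.8, mkRate = 1,
                             driverIndices = 1:3,
                             driverEffects = rep(2, length(driverIndices)),
                             phyloLiabilitySd = 1, targetPrevalence = 0.45,
                             confidenceStrength = 8, missingFraction = 0.18,
                             seed = 1L) {
    new("SimulationConfig",
        nSpecies = as.integer(nSpecies), nTraits = as.integer(nTraits),
        signalFraction = signalFraction, mkRate = mkRate,
        driverIndices = as.integer(driverIndices),
        driverEffects = as.numeric(driverEffects),
        phyloLiabilitySd = phyloLiabilitySd,
        targetPrevalence = targetPrevalence,
        confidenceStrength = confidenceStrength,
        missingFraction = missingFraction, seed = as.integer(seed))
}

#' @describeIn ConfidenceTable species identifiers
#' @param x a ConfidenceTable or TraitMatrix
#' @export
speciesNames <- function(x) {
    if (is(x, "ConfidenceTable")) return(rownames(x@cplus))
    if (is(x, "TraitMatrix")) return(rownames(x@scores))
    stop("no species names for this object")
}

#' @describeIn ConfidenceTable trait names
#' @export
traitNames <- function(x) {
    if (is(x, "ConfidenceTable")) return(colnames(x@cplus))
    if (is(x, "TraitMatrix")) return(colnames(x@scores))
    stop("no trait names for this object")
}

#' Extract the score matrix of a TraitMatrix
#' @param x a \linkS4class{TraitMatrix}
#' @return numeric matrix of scores.
#' @export
traitScores <- function(x) {
    stopifnot(is(x, "TraitMatrix"))
    x@scores
}

#' Fold indices of a FoldAssignment
#' @param x a \linkS4class{FoldAssignment}
#' @return named integer vector, species -> fold.
#' @export
foldIds <- function(x) {
    stopifnot(is(x, "FoldAssignment"))
    x@folds
}

#' Medoid species of a blocked FoldAssignment
#' @param x a \linkS4class{FoldAssignment}
#' @return character vector of medoids (empty for random folds).
#' @export
foldMedoids <- function(x) {
    stopifnot(is(x, "FoldAssignment"))
    x@medoids
}

#' Per-forest weights of an ensemble
#' @param x an \linkS4class{EnsembleModel}
#' @return numeric weights summing to one.
#' @export
ensembleWeights <- function(x) {
    stopifnot(is(x, "EnsembleModel"))
    x@weights
}

#' Per-forest raw Cohen's kappa of an ensemble
#' @param x an \linkS4class{EnsembleModel}
#' @return numeric kappas measured on each excluded fold.
#' @export
ensembleKappas <- function(x) {
    stopifnot(is(x, "EnsembleModel"))
    x@kappas
}

#' Variance-explained fractions of an ordination
#' @param x an \linkS4class{OrdinationResult}
#' @return numeric vector of fractions.
#' @export
varianceExplained <- function(x) {
    stopifnot(is(x, "OrdinationResult"))
    x@varExplained
}

#' Component scores of an ordination
#' @param x an \linkS4class{OrdinationResult}
#' @return numeric species x component matrix.
#' @export
ordinationScores <- function(x) {
    stopifnot(is(x, "OrdinationResult"))
    x@scores
}

#' Confusion metrics of an EvaluationReport as a named vector
#' @param x an \linkS4class{EvaluationReport}
#' @return named numeric vector with tp, fp, tn, fn, accuracy, kappa, tpr.
#' @export
reportMetrics <- function(x) {
    stopifnot(is(x, "EvaluationReport"))
    c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn,
      accuracy = x@accuracy, kappa = x@kappa, tpr = x@tpr)
}

setMethod("show", "ConfidenceTable", function(object) {
    cat(sprintf("ConfidenceTable: %d species x %d traits (%.1f%% missing)\n",
                nrow(object@cplus), ncol(object@cplus),
                100 * mean(is.na(object@cplus))))
})

setMethod("show", "TraitMatrix", function(object) {
    cat(sprintf("TraitMatrix: %d species x %d traits, %s\n",
                nrow(object@scores), ncol(object@scores),
                if (object@complete) "complete"
                else sprintf("%.1f%% missing", 100 * mean(is.na(object@scores)))))
})

setMethod("show", "FoldAssignment", function(object) {
    cat(sprintf("FoldAssignment (%s): %d species in %d folds (sizes %s)\n",
                object@kind, length(object@folds), object@k,
                paste(tabulate(object@folds, object@k), collapse = "/")))
})

setMethod("show", "EnsembleModel", function(object) {
    cat(sprintf("EnsembleModel: %d forests x %d trees%s\n",
                length(object@forests), object@nTrees,
                if (object@stratified) " (stratified)" else ""))
    cat("  kappa:", paste(sprintf("%.3f", object@kappas), collapse = " "), "\n")
    cat("  weight:", paste(sprintf("%.3f", object@weights), collapse = " "), "\n")
})

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf(
        "EvaluationReport: n = %d | accuracy %.3f | kappa %.3f | TPR %.3f\n",
        object@tp + object@fp + object@tn + object@fn,
        object@accuracy, object@kappa, object@tpr))
    cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
                object@tp, object@fp, object@tn, object@fn))
})

setMethod("show", "OrdinationResult", function(object) {
    cat(sprintf("OrdinationResult: %d species, %d components (%s%% variance)\n",
                nrow(object@scores), ncol(object@scores),
                paste(round(100 * object@varExplained, 1), collapse = "/")))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d species x %d traits, %d drivers, seed %d\n",
        object@nSpecies, object@nTraits, length(object@driverIndices),
        object@seed))
})
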