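#' @import methods
NULL

#' Paired trait-confidence table
#'
#' Holds, for every species x trait cell, the pair of text-mining confidences
#' that the species does (\code{c+}) and does not (\code{c-}) have the trait.
#' Both matrices share dimensions and dimnames; a cell is either fully present
#' (both confidences in \code{[0, 1]}) or fully missing (\code{NA} in both).
#'
#' @slot cplus numeric matrix of positive confidences (species x traits).
#' @slot cminus numeric matrix of negative confidences, same shape.
#'
#' @seealso [ConfidenceTable()] for the constructor, [scoreTable()] to derive
#'   single scores.
#' @export
setClass("ConfidenceTable", representation(cplus = "matrix", cminus = "matrix"))

setValidity("ConfidenceTable", function(object) {
    cp <- object@cplus; cm <- object@cminus
    if (!identical(dim(cp), dim(cm)))
        return("cplus and cminus must have identical dimensions")
    if (is.null(rownames(cp)) || is.null(colnames(cp)))
        return("cplus must have species rownames and trait colnames")
    if (!identical(dimnames(cp), dimnames(cm)))
        return("cplus and cminus must have identical dimnames")
    if (anyDuplicated(rownames(cp))) return("species identifiers must be unique")
    if (anyDuplicated(colnames(cp))) return("trait names must be unique")
    if (!identical(is.na(cp), is.na(cm)))
        return("a cell must be fully present or fully missing in both confidences")
    vals <- c(cp[!is.na(cp)], cm[!is.na(cm)])
    if (length(vals) && (min(vals) < 0 || max(vals) > 1))
        return("all confidences must lie in [0, 1]")
    TRUE
})

#' Species x trait score matrix
#'
#' A matrix of derived trait scores \eqn{p \in [0, 1]}, possibly with missing
#' cells before imputation. The \code{complete} flag records whether the
#' matrix has been through (or never needed) imputation.
#'
#' @slot scores numeric matrix (species x traits), values in \code{[0, 1]} or
#'   \code{NA}.
#' @slot complete logical; \code{TRUE} when no cell is missing.
#'
#' @seealso [TraitMatrix()], [imputeMissing()], [dropTraits()]
#' @export
setClass("TraitMatrix", representation(scores = "matrix", complete = "logical"))

setValidity("TraitMatrix", function(object) {
    x <- object@scores
    if (is.null(rownames(x)) || is.null(colnames(x)))
        return("scores must carry species rownames and trait colnames")
    if (anyDuplicated(rownames(x))) return("species identifiers must be unique")
    if (anyDuplicated(colnames(x))) return("trait names must be unique")
    vals <- x[!is.na(x)]
    if (length(vals) && (min(vals) < 0 || max(vals) > 1))
        return("scores must lie in [0, 1]")
    if (object@complete && anyNA(x))
        return("complete = TRUE but missing cells present")
    TRUE
})

#' Cross-validation fold assignment
#'
#' Maps each species to a fold in \code{1..k}. Blocked assignments come from
#' k-medoids clustering of patristic distances and record the medoid species;
#' random assignments are near-equal-size uniform partitions.
#'
#' @slot folds named integer vector, species -> fold index.
#' @slot k integer number of folds.
#' @slot kind \code{"blocked"} or \code{"random"}.
#' @slot medoids character vector of medoid species (blocked only; one per
#'   fold, empty for random assignments).
#'
#' @seealso [makeBlockedFolds()], [makeRandomFolds()], [pamCluster()]
#' @export
setClass("FoldAssignment",
    representation(folds = "integer", k = "integer", kind = "character",
                   medoids = "character"))

setValidity("FoldAssignment", function(object) {
    f <- object@folds
    if (is.null(names(f)) || anyDuplicated(names(f)))
        return("folds must be named by unique species")
    if (!object@kind %in% c("blocked", "random"))
        return("kind must be 'blocked' or 'random'")
    k <- object@k
    if (length(k) != 1L || k < 1L) return("k must be a positive integer")
    if (anyNA(f) || any(f < 1L) || any(f > k))
        return("every species must be assigned a fold in 1..k")
    if (!all(seq_len(k) %in% f)) return("every fold must be non-empty")
    if (object@kind == "blocked" && length(object@medoids) != k)
        return("blocked assignments need one medoid per fold")
    TRUE
})

#' Kappa-weighted blocked random-forest ensemble
#'
#' One base forest per blocked fold, each trained with that fold left out and
#' weighted by its Cohen's kappa on the excluded fold (negative kappas floored
#' at zero, weights renormalised; uniform fallback when all kappas are <= 0).
#'
#' @slot forests list of \code{randomForest} objects, one per fold.
#' @slot kappas numeric raw kappa of each forest on its excluded fold.
#' @slot weights numeric nonnegative weights summing to one.
#' @slot folds the \linkS4class{FoldAssignment} used for training.
#' @slot classLevels character levels of the outcome (as factor levels).
#' @slot majorityClass character; training-set majority class, used to break
#'   exact vote ties.
#' @slot nTrees integer trees per forest.
#' @slot stratified logical; whether per-tree balanced class sampling was used.
#' @slot seed integer seed the ensemble was fitted under.
#'
#' @seealso [fitBlockedEnsemble()], [predictEnsemble()], [ensembleImportance()]
#' @export
setClass("EnsembleModel",
    representation(forests = "list", kappas = "numeric", weights = "numeric",
                   folds = "FoldAssignment", classLevels = "character",
                   majorityClass = "character", nTrees = "integer",
                   stratified = "logical", seed = "integer"))

setValidity("EnsembleModel", function(object) {
    k <- length(object@forests)
    if (k != object@folds@k) return("number of forests must equal number of folds")
    if (length(object@weights) != k || length(object@kappas) != k)
        return("one kappa and one weight per forest required")
    if (any(object@weights < 0)) return("weights must be nonnegative")
    if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
    TRUE
})

#' Binary classification evaluation report
#'
#' Confusion counts plus the three headline metrics used throughout:
#' accuracy, Cohen's kappa, and the true positive rate.
#'
#' @slot tp,fp,tn,fn integer confusion counts.
#' @slot accuracy numeric, (TP+TN)/n.
#' @slot kappa numeric, Cohen's kappa.
#' @slot tpr numeric, TP/(TP+FN) (NaN when no positives in truth).
#'
#' @seealso [evaluatePredictions()]
#' @export
setClass("EvaluationReport",
    representation(tp = "integer", fp = "integer", tn = "integer",
                   fn = "integer", accuracy = "numeric", kappa = "numeric",
                   tpr = "numeric"))

#' Trait-space ordination result
#'
#' Principal component scores, orthonormal loadings and per-component
#' variance-explained fractions for a complete trait matrix.
#'
#' @slot scores numeric matrix, species x components.
#' @slot loadings numeric matrix, traits x components (orthonormal columns).
#' @slot varExplained numeric fractions of total variance, non-increasing.
#' @slot scaled logical; whether columns were scaled to unit variance.
#'
#' @seealso [runPCA()], [topLoadings()]
#' @export
setClass("OrdinationResult",
    representation(scores = "matrix", loadings = "matrix",
                   varExplained = "numeric", scaled = "logical"))

setValidity("OrdinationResult", function(object) {
    v <- object@varExplained
    if (any(v < -1e-12) || any(v > 1 + 1e-12))
        return("variance fractions must lie in [0, 1]")
    if (is.unsorted(rev(v), strictly = FALSE) && any(diff(v) > 1e-9))
        return("variance fractions must be non-increasing")
    if (sum(v) > 1 + 1e-8) return("variance fractions must sum to <= 1")
    TRUE
})

#' Configuration of the synthetic study generator
#'
#' Describes the simulated study conditions: a unit-depth Yule tree, binary
#' traits with phylogenetic signal evolved under a symmetric Mk model, paired
#' Beta-distributed confidence observations with missingness, and a
#' liability-threshold outcome driven by a few traits plus a Brownian
#' (phylogenetically correlated) residual.
#'
#' @slot nSpecies,nTraits positive integers.
#' @slot signalFraction fraction of traits evolved on the tree (rest i.i.d.).
#' @slot mkRate per-unit-branch-length 0<->1 transition rate.
#' @slot driverIndices integer indices of traits that causally affect the
#'   outcome.
#' @slot driverEffects per-driver log-odds effect sizes.
#' @slot phyloLiabilitySd standard deviation of the Brownian liability
#'   component at unit depth.
#' @slot targetPrevalence target fraction of outcome = 1 species.
#' @slot confidenceStrength Beta shape parameter >= 1; larger means more
#'   informative confidence pairs.
#' @slot missingFraction probability a confidence cell is missing.
#' @slot seed integer master seed; stage sub-seeds are derived from it.
#'
#' @seealso [SimulationConfig()], [generateDataset()]
#' @export
setClass("SimulationConfig",
    representation(nSpecies = "integer", nTraits = "integer",
                   signalFraction = "numeric", mkRate = "numeric",
                   driverIndices = "integer", driverEffects = "numeric",
                   phyloLiabilitySd = "numeric", targetPrevalence = "numeric",
                   confidenceStrength = "numeric", missingFraction = "numeric",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    if (object@nSpecies < 2L) return("nSpecies must be >= 2")
    if (object@nTraits < 1L) return("nTraits must be >= 1")
    for (nm in c("signalFraction", "missingFraction", "targetPrevalence")) {
        v <- slot(object, nm)
        if (v < 0 || v > 1) return(sprintf("%s must lie in [0, 1]", nm))
    }
    if (object@mkRate < 0) return("mkRate must be nonnegative")
    if (object@phyloLiabilitySd < 0) return("phyloLiabilitySd must be nonnegative")
    if (object@confidenceStrength < 1) return("confidenceStrength must be >= 1")
    if (length(object@driverEffects) != length(object@driverIndices))
        return("driverEffects and driverIndices must have equal length")
    if (length(object@driverIndices) &&
        (any(object@driverIndices < 1L) || any(object@driverIndices > object@nTraits)))
        return("driverIndices must lie in 1..nTraits")
    TRUE
})
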