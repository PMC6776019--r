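#' Cohen's kappa for binary agreement
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement \eqn{p_o}
#' and chance agreement \eqn{p_e = \sum_c m_t(c) m_p(c)} from the marginal
#' class frequencies of truth and prediction. When \eqn{p_e = 1} (both vectors
#' constant and equal) kappa is 0 by convention.
#'
#' @param truth,pred equal-length binary 0/1 vectors.
#' @return Kappa in \code{[-1, 1]}.
#' @examples
#' cohensKappa(c(1, 1, 1, 0, 0, 0), c(1, 1, 0, 0, 0, 1))  # 1/3
#' @export
cohensKappa <- function(truth, pred) {
    truth <- .assertBinary(truth, "truth")
    pred <- .assertBinary(pred, "pred")
    if (length(truth) != length(pred))
        stop("truth and pred must have equal length", call. = FALSE)
    po <- mean(truth == pred)
    pt1 <- mean(truth); pp1 <- mean(pred)
    pe <- pt1 * pp1 + (1 - pt1) * (1 - pp1)
    if (abs(1 - pe) < .Machine$double.eps) return(0)
    (po - pe) / (1 - pe)
}

#' Fit a single random-forest classifier
#'
#' Bagged classification forest with \code{floor(sqrt(p))} candidate variables
#' per split and permutation + impurity importances. With
#' \code{stratified = TRUE}, every tree's bootstrap draws an equal number of
#' observations from each class (the minority-class count, with replacement) —
#' the balanced-sampling device for rare outcomes.
#'
#' @param X complete numeric matrix (species x traits).
#' @param y binary 0/1 outcome with both classes present.
#' @param nTrees number of trees (default 500).
#' @param seed integer seed; fixed seed gives identical forests.
#' @param stratified use per-tree balanced class bootstraps.
#' @return A \code{randomForest} object (factor levels \code{"0"}, \code{"1"}).
#' @export
fitForest <- function(X, y, nTrees = 500L, seed = 1L, stratified = FALSE) {
    X <- .asScoreMatrix(X)
    y <- .assertBinary(y, "y")
    if (length(unique(y)) < 2L)
        stop("degenerate outcome: y has a single class", call. = FALSE)
    yf <- factor(y, levels = c(0, 1))
    set.seed(deriveSubSeed(seed, "forest"))
    args <- list(x = X, y = yf, ntree = as.integer(nTrees),
                 mtry = max(1L, floor(sqrt(ncol(X)))),
                 importance = TRUE, keep.inbag = TRUE)
    if (stratified) {
        m <- min(table(yf))
        args$strata <- yf
        args$sampsize <- c(m, m)
        args$replace <- TRUE
    }
    do.call(randomForest::randomForest, args)
}

#' Fit a kappa-weighted ensemble of blocked random forests
#'
#' One forest per blocked fold, trained with that fold excluded; each forest's
#' Cohen's kappa on its excluded fold becomes its raw weight. Negative kappas
#' are floored at zero and the weights renormalised to sum to one (uniform
#' fallback when every raw kappa is <= 0), so no forest can anti-vote.
#'
#' @param X complete numeric matrix with species rownames.
#' @param y named binary outcome (aligned by rownames of \code{X}).
#' @param folds a blocked \linkS4class{FoldAssignment} with k >= 2 covering
#'   all rows.
#' @param nTrees trees per forest (default 500).
#' @param seed integer seed; each forest uses a sub-seed.
#' @param stratified balanced per-tree class sampling (see [fitForest()]).
#' @return An \linkS4class{EnsembleModel}.
#' @export
fitBlockedEnsemble <- function(X, y, folds, nTrees = 500L, seed = 1L,
                               stratified = FALSE) {
    X <- .asScoreMatrix(X)
    y <- .assertBinary(y, "y")
    if (folds@k < 2) stop("ensemble needs k >= 2 folds", call. = FALSE)
    f <- folds@folds[rownames(X)]
    if (anyNA(f)) stop("folds must cover every row of X", call. = FALSE)
    forests <- vector("list", folds@k)
    kappas <- numeric(folds@k)
    for (i in seq_len(folds@k)) {
        hold <- f == i
        forests[[i]] <- fitForest(X[!hold, , drop = FALSE], y[!hold], nTrees,
                                  seed = deriveSubSeed(seed, paste0("fold", i)),
                                  stratified = stratified)
        predHold <- as.integer(as.character(
            stats::predict(forests[[i]], X[hold, , drop = FALSE])))
        kappas[i] <- cohensKappa(y[hold], predHold)
    }
    w <- pmax(kappas, 0)
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / folds@k, folds@k)
    maj <- names(which.max(table(factor(y, levels = c(0, 1)))))
    new("EnsembleModel", forests = forests, kappas = kappas, weights = w,
        folds = folds, classLevels = c("0", "1"), majorityClass = maj,
        nTrees = as.integer(nTrees), stratified = stratified,
        seed = as.integer(seed))
}

## Weighted hard-label vote: per class, sum the weights of forests voting it;
## exact ties go to the training majority class.
.weightedVote <- function(votes, weights, majorityClass,
                          classLevels = c("0", "1")) {
    votes <- as.character(votes)
    tot <- vapply(classLevels,
                  function(cl) sum(weights[votes == cl]), numeric(1))
    if (abs(tot[1L] - tot[2L]) < 1e-12) return(majorityClass)
    classLevels[which.max(tot)]
}

#' Predict labels with a kappa-weighted ensemble
#'
#' Each forest casts its majority-vote hard label per observation; per class,
#' the weights of the forests voting for it are summed and the heaviest class
#' wins. An exact tie returns the training-set majority class.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param X numeric matrix whose columns match the training columns (order
#'   free; names must agree).
#' @return Integer 0/1 vector named by \code{rownames(X)}.
#' @export
predictEnsemble <- function(model, X) {
    stopifnot(is(model, "EnsembleModel"))
    X <- .asScoreMatrix(X)
    trainCols <- rownames(model@forests[[1L]]$importance)
    missing <- setdiff(trainCols, colnames(X))
    extra <- setdiff(colnames(X), trainCols)
    if (length(missing) || length(extra))
        stop("column mismatch with training data",
             if (length(missing)) paste0("; missing: ",
                                         paste(missing, collapse = ", ")),
             if (length(extra)) paste0("; extra: ",
                                       paste(extra, collapse = ", ")),
             call. = FALSE)
    X <- X[, trainCols, drop = FALSE]
    votes <- vapply(model@forests,
                    function(fr) as.character(stats::predict(fr, X)),
                    character(nrow(X)))
    votes <- matrix(votes, nrow = nrow(X))
    out <- vapply(seq_len(nrow(X)), function(i)
        .weightedVote(votes[i, ], model@weights, model@majorityClass,
                      model@classLevels), character(1))
    stats::setNames(as.integer(out), rownames(X))
}

#' Aggregate variable importances across an ensemble
#'
#' Weighted mean (by the ensemble's kappa weights) of each forest's mean
#' decrease in accuracy (out-of-bag permutation) and mean decrease in Gini
#' impurity, sorted by mean decrease in accuracy, descending.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @return data.frame with columns \code{trait}, \code{meanDecreaseAccuracy},
#'   \code{meanDecreaseGini}.
#' @export
ensembleImportance <- function(model) {
    stopifnot(is(model, "EnsembleModel"))
    imp <- lapply(model@forests, randomForest::importance)
    traits <- rownames(imp[[1L]])
    mda <- rowSums(vapply(seq_along(imp), function(i)
        model@weights[i] * imp[[i]][traits, "MeanDecreaseAccuracy"],
        numeric(length(traits))))
    mdg <- rowSums(vapply(seq_along(imp), function(i)
        model@weights[i] * imp[[i]][traits, "MeanDecreaseGini"],
        numeric(length(traits))))
    out <- data.frame(trait = traits, meanDecreaseAccuracy = mda,
                      meanDecreaseGini = mdg, row.names = NULL,
                      stringsAsFactors = FALSE)
    out[order(out$meanDecreaseAccuracy, decreasing = TRUE), , drop = FALSE]
}

#' Confusion counts and headline metrics of binary predictions
#'
#' @param truth,pred equal-length binary 0/1 vectors.
#' @return An \linkS4class{EvaluationReport} with TP/FP/TN/FN, accuracy,
#'   Cohen's kappa and the true positive rate TP/(TP+FN).
#' @export
evaluatePredictions <- function(truth, pred) {
    truth <- .assertBinary(truth, "truth")
    pred <- .assertBinary(pred, "pred")
    if (length(truth) != length(pred))
        stop("truth and pred must have equal length", call. = FALSE)
    tp <- sum(truth == 1 & pred == 1); fp <- sum(truth == 0 & pred == 1)
    tn <- sum(truth == 0 & pred == 0); fn <- sum(truth == 1 & pred == 0)
    new("EvaluationReport", tp = as.integer(tp), fp = as.integer(fp),
        tn = as.integer(tn), fn = as.integer(fn),
        accuracy = (tp + tn) / length(truth),
        kappa = cohensKappa(truth, pred),
        tpr = tp / (tp + fn))
}
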