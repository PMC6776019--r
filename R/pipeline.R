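#' Configuration of an end-to-end pipeline run
#'
#' Collects inputs and hyperparameters for [runPipeline()]. Inputs may be
#' in-memory objects (\linkS4class{ConfidenceTable}, \code{phylo}, named label
#' vector, data.frame of per-species categorical metadata) or file paths
#' readable by the package's readers.
#'
#' @param confidences a \linkS4class{ConfidenceTable}, or
#'   \code{c(cplusPath, cminusPath)}.
#' @param tree an \code{ape::phylo} or a newick file path.
#' @param labels named 0/1 vector or a labels file path.
#' @param metadata optional data.frame (species rownames, categorical columns)
#'   or a tab-delimited file path with species in the first column.
#' @param k number of blocked folds (default 5).
#' @param testGroup held-out test set: a fold index of the all-species blocked
#'   assignment, or an explicit species vector.
#' @param dropPatterns literal substrings of trait names to remove
#'   post-imputation.
#' @param models which models to fit: any of \code{"forwardLogistic"},
#'   \code{"blockedEnsemble"}, \code{"plainForest"}.
#' @param nTrees trees per forest (default 500).
#' @param maxSize forward-selection size cap (default 30).
#' @param criterion CV error criterion, \code{"brier"} or \code{"zeroone"}.
#' @param stratified balanced per-tree class sampling in forests.
#' @param imputeIter maximum imputation sweeps.
#' @param seed master seed.
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(confidences, tree, labels, metadata = NULL, k = 5L,
                      testGroup = 1L, dropPatterns = character(0),
                      models = c("forwardLogistic", "blockedEnsemble",
                                 "plainForest"),
                      nTrees = 500L, maxSize = 30L,
                      criterion = c("brier", "zeroone"), stratified = FALSE,
                      imputeIter = 10L, seed = 1L) {
    structure(list(confidences = confidences, tree = tree, labels = labels,
                   metadata = metadata, k = as.integer(k),
                   testGroup = testGroup, dropPatterns = dropPatterns,
                   models = match.arg(models, several.ok = TRUE),
                   nTrees = as.integer(nTrees), maxSize = as.integer(maxSize),
                   criterion = match.arg(criterion),
                   stratified = isTRUE(stratified),
                   imputeIter = as.integer(imputeIter),
                   seed = as.integer(seed)),
              class = "RunConfig")
}

.loadInputs <- function(config) {
    ct <- config$confidences
    if (is.character(ct)) ct <- readConfidenceTable(ct[1L], ct[2L])
    tree <- config$tree
    if (is.character(tree)) tree <- parseNewick(readLines(tree)[1L])
    labels <- config$labels
    if (is.character(labels) && length(labels) == 1L && file.exists(labels))
        labels <- readLabels(labels)
    md <- config$metadata
    if (is.character(md) && length(md) == 1L) {
        df <- utils::read.table(md, sep = "\t", header = TRUE,
                                check.names = FALSE, stringsAsFactors = FALSE)
        rownames(df) <- df[[1L]]
        md <- df[, -1L, drop = FALSE]
    }
    list(confidences = ct, tree = tree, labels = labels, metadata = md)
}

.writeReportDcf <- function(report, path) {
    write.dcf(as.data.frame(t(reportMetrics(report))), path)
}

#' Run the full phylogenetically blocked prediction study
#'
#' Fixed stage order: load and reconcile inputs, score confidences, impute
#' missing scores, drop trait columns by name, build blocked folds over all
#' species, hold out a phylogenetically coherent test group, rebuild blocked
#' folds on the training species only, fit the enabled models exclusively on
#' the training side, evaluate each model once on the held-out test species,
#' and produce ordination and association reports. Every artifact is written
#' into \code{outDir} and every stochastic stage derives its seed from
#' \code{config$seed}, so a rerun with the same config reproduces the same
#' reports. Test labels are read only at the evaluation stage.
#'
#' @param config a \code{"RunConfig"} from [runConfig()].
#' @param outDir run directory (created; default a fresh temporary directory).
#' @return Invisibly, a list: \code{outDir}, \code{traitMatrix} (imputed,
#'   filtered), \code{folds} (all-species blocked), \code{trainFolds},
#'   \code{split}, \code{models} (fitted objects), \code{evaluations}
#'   (named \linkS4class{EvaluationReport}s), \code{selectionPath},
#'   \code{ordination}, \code{associations}.
#' @export
runPipeline <- function(config, outDir = tempfile("ptmlrun")) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logFile <- file.path(outDir, "log.txt")
    logStage <- function(stage, msg) {
        cat(sprintf("%s | %s | %s\n",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg),
            file = logFile, append = TRUE)
    }

    inp <- .loadInputs(config)
    ct <- inp$confidences; tree <- inp$tree; labels <- inp$labels
    species <- speciesNames(ct)
    offenders <- setdiff(species, tree$tip.label)
    if (length(offenders))
        stop("species absent from the tree: ",
             paste(offenders, collapse = ", "), call. = FALSE)
    offenders <- setdiff(species, names(labels))
    if (length(offenders))
        stop("species without outcome labels: ",
             paste(offenders, collapse = ", "), call. = FALSE)
    labels <- labels[species]

    ## copy inputs into the run directory and log their hashes
    inDir <- file.path(outDir, "inputs")
    dir.create(inDir, showWarnings = FALSE)
    writeConfidenceTable(ct, file.path(inDir, "cplus.tsv"),
                         file.path(inDir, "cminus.tsv"))
    ape::write.tree(tree, file.path(inDir, "tree.nwk"))
    writeLabels(labels, file.path(inDir, "labels.tsv"))
    for (f in list.files(inDir, full.names = TRUE))
        logStage("inputs", sprintf("%s md5=%s", basename(f),
                                   unname(tools::md5sum(f))))
    cfgOut <- config
    cfgOut$confidences <- cfgOut$tree <- cfgOut$labels <- cfgOut$metadata <- NULL
    cfgOut$models <- paste(cfgOut$models, collapse = ",")
    cfgOut$dropPatterns <- paste(cfgOut$dropPatterns, collapse = ",")
    cfgOut$testGroup <- paste(cfgOut$testGroup, collapse = ",")
    write.dcf(as.data.frame(unclass(cfgOut)), file.path(outDir, "config.dcf"))

    logStage("score", sprintf("%d x %d cells, %.1f%% missing",
                              nrow(ct@cplus), ncol(ct@cplus),
                              100 * mean(is.na(ct@cplus))))
    tm <- scoreTable(ct)
    tm <- imputeMissing(tm, maxIter = config$imputeIter, seed = config$seed)
    logStage("impute", "scores complete")
    tm <- dropTraits(tm, config$dropPatterns)
    if (length(attr(tm, "removed")))
        logStage("filter", paste("removed:",
                                 paste(attr(tm, "removed"), collapse = ", ")))
    writeTraitTable(tm, file.path(outDir, "trait_scores.tsv"))

    folds <- makeBlockedFolds(tree, k = config$k, species = species)
    writeFolds(folds, file.path(outDir, "folds_all.tsv"))
    split <- holdoutSplit(species, config$testGroup, folds)
    logStage("holdout", sprintf("train n=%d test n=%d", length(split$train),
                                length(split$test)))
    logStage("holdout", sprintf(
        "outcome prevalence: train %.3f vs test %.3f (mismatch logged, not corrected)",
        mean(labels[split$train]), mean(labels[split$test])))
    trainFolds <- makeBlockedFolds(tree, k = config$k, species = split$train)
    writeFolds(trainFolds, file.path(outDir, "folds_train.tsv"))

    X <- traitScores(tm)
    Xtr <- X[split$train, , drop = FALSE]
    Xte <- X[split$test, , drop = FALSE]
    ytr <- labels[split$train]

    modelsOut <- list(); evals <- list(); selPath <- NULL
    if ("forwardLogistic" %in% config$models) {
        logStage("forwardLogistic", "selection started")
        selPath <- forwardPath(Xtr, ytr, trainFolds, maxSize = config$maxSize,
                               criterion = config$criterion)
        chosen <- selectByBIC(selPath)
        utils::write.table(selPath$table,
                           file.path(outDir, "selection_path.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        fit <- fitLogistic(Xtr[, chosen, drop = FALSE], ytr)
        modelsOut$forwardLogistic <- fit
        pred <- as.integer(predict(fit, Xte) >= 0.5)
        evals$forwardLogistic <- evaluatePredictions(labels[split$test], pred)
        logStage("forwardLogistic", sprintf("chosen size %d", length(chosen)))
    }
    if ("blockedEnsemble" %in% config$models) {
        logStage("blockedEnsemble", "fitting started")
        ens <- fitBlockedEnsemble(Xtr, ytr, trainFolds, nTrees = config$nTrees,
                                  seed = config$seed,
                                  stratified = config$stratified)
        modelsOut$blockedEnsemble <- ens
        write.dcf(data.frame(fold = seq_len(ens@folds@k), kappa = ens@kappas,
                             weight = ens@weights),
                  file.path(outDir, "ensemble_weights.dcf"))
        utils::write.table(ensembleImportance(ens),
                           file.path(outDir, "ensemble_importance.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        evals$blockedEnsemble <-
            evaluatePredictions(labels[split$test], predictEnsemble(ens, Xte))
    }
    if ("plainForest" %in% config$models) {
        logStage("plainForest", "fitting started")
        rf <- fitForest(Xtr, ytr, nTrees = config$nTrees, seed = config$seed,
                        stratified = config$stratified)
        modelsOut$plainForest <- rf
        pred <- as.integer(as.character(stats::predict(rf, Xte)))
        evals$plainForest <- evaluatePredictions(labels[split$test], pred)
    }
    for (nm in names(evals))
        .writeReportDcf(evals[[nm]],
                        file.path(outDir, sprintf("evaluation_%s.dcf", nm)))

    ord <- runPCA(tm, nComponents = min(3L, nrow(X) - 1L, ncol(X)))
    utils::write.table(
        data.frame(species = rownames(ordinationScores(ord)),
                   ordinationScores(ord)),
        file.path(outDir, "pca_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(trait = rownames(ord@loadings), ord@loadings),
        file.path(outDir, "pca_loadings.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    nc <- ncol(ordinationScores(ord))
    if (nc >= 2L) {
        idx <- if (nc >= 3L) c(2L, 3L) else c(1L, 2L)
        emb <- exportEmbedding(ordinationScores(ord)[, idx, drop = FALSE],
                               labels)
        utils::write.table(emb, file.path(outDir, "embedding.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    logStage("ordination", sprintf("variance fractions %s",
                                   paste(round(varianceExplained(ord), 3),
                                         collapse = "/")))

    associations <- list()
    md <- inp$metadata
    if (!is.null(md)) {
        md <- md[species, , drop = FALSE]
        for (col in colnames(md)) {
            inc <- incidenceByCategory(labels, md[[col]])
            tab <- table(md[[col]], labels)
            chi <- chiSquare(unclass(tab))
            associations[[col]] <- list(incidence = inc, chiSquare = chi)
            utils::write.table(inc,
                               file.path(outDir,
                                         sprintf("incidence_%s.tsv", col)),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            logStage("association",
                     sprintf("%s: chi2=%.3f df=%d p=%.3g", col, chi$statistic,
                             chi$df, chi$p.value))
        }
    }
    logStage("done", "all stages complete")
    invisible(list(outDir = outDir, traitMatrix = tm, folds = folds,
                   trainFolds = trainFolds, split = split, models = modelsOut,
                   evaluations = evals, selectionPath = selPath,
                   ordination = ord, associations = associations))
}
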