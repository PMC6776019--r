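## Tab-delimited text I/O. All tables carry a header row and species
## identifiers in the first column; missing cells use the literal token NA.

#' Write a species x trait table as tab-delimited text
#' @param x matrix or \linkS4class{TraitMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTraitTable <- function(x, path) {
    x <- .asScoreMatrix(x)
    df <- data.frame(species = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    invisible(path)
}

#' Read a species x trait score table
#' @param path tab-delimited file written by [writeTraitTable()].
#' @return A \linkS4class{TraitMatrix}.
#' @export
readTraitTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    TraitMatrix(m)
}

#' Write a ConfidenceTable as two tab-delimited files
#' @param ct a \linkS4class{ConfidenceTable}.
#' @param cplusPath,cminusPath output files for the positive and negative
#'   confidence matrices.
#' @return Invisibly, the two paths.
#' @export
writeConfidenceTable <- function(ct, cplusPath, cminusPath) {
    stopifnot(is(ct, "ConfidenceTable"))
    for (p in list(list(ct@cplus, cplusPath), list(ct@cminus, cminusPath))) {
        df <- data.frame(species = rownames(p[[1L]]), p[[1L]],
                         check.names = FALSE, stringsAsFactors = FALSE)
        utils::write.table(df, p[[2L]], sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA")
    }
    invisible(c(cplusPath, cminusPath))
}

#' Read a ConfidenceTable from two tab-delimited files
#' @param cplusPath,cminusPath files written by [writeConfidenceTable()].
#' @return A \linkS4class{ConfidenceTable}.
#' @export
readConfidenceTable <- function(cplusPath, cminusPath) {
    rd <- function(path) {
        df <- utils::read.table(path, sep = "\t", header = TRUE,
                                check.names = FALSE, stringsAsFactors = FALSE)
        m <- as.matrix(df[, -1L, drop = FALSE])
        rownames(m) <- df[[1L]]
        m
    }
    ConfidenceTable(rd(cplusPath), rd(cminusPath))
}

#' Write a fold assignment as two-column tab-delimited text
#' @param fa a \linkS4class{FoldAssignment}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFolds <- function(fa, path) {
    stopifnot(is(fa, "FoldAssignment"))
    utils::write.table(
        data.frame(species = names(fa@folds), fold = unname(fa@folds)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write binary labels as two-column tab-delimited text
#' @param labels named 0/1 vector.
#' @param path output file.
#' @param name column name for the outcome (default "label").
#' @return \code{path}, invisibly.
#' @export
writeLabels <- function(labels, path, name = "label") {
    df <- data.frame(species = names(labels), unname(labels))
    names(df)[2L] <- name
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read binary labels written by [writeLabels()]
#' @param path tab-delimited file (species, label).
#' @return Named integer vector.
#' @export
readLabels <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    stats::setNames(as.integer(df[[2L]]), df[[1L]])
}

#' Write a synthetic study bundle to a directory
#'
#' Files written: \code{tree.nwk} (newick), \code{traits.tsv} (true binary
#' traits), \code{cplus.tsv} / \code{cminus.tsv} (confidences),
#' \code{labels.tsv}, and \code{manifest.dcf} recording the generating
#' configuration.
#'
#' @param bundle a list from [generateDataset()].
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
    writeTraitTable(bundle$traits, file.path(dir, "traits.tsv"))
    writeConfidenceTable(bundle$confidences, file.path(dir, "cplus.tsv"),
                         file.path(dir, "cminus.tsv"))
    writeLabels(bundle$labels, file.path(dir, "labels.tsv"))
    cfg <- bundle$config
    manifest <- data.frame(
        nSpecies = cfg@nSpecies, nTraits = cfg@nTraits,
        signalFraction = cfg@signalFraction, mkRate = cfg@mkRate,
        driverIndices = paste(cfg@driverIndices, collapse = ","),
        driverEffects = paste(cfg@driverEffects, collapse = ","),
        phyloLiabilitySd = cfg@phyloLiabilitySd,
        targetPrevalence = cfg@targetPrevalence,
        confidenceStrength = cfg@confidenceStrength,
        missingFraction = cfg@missingFraction, seed = cfg@seed)
    write.dcf(manifest, file.path(dir, "manifest.dcf"))
    invisible(dir)
}

#' Read a synthetic study bundle written by [writeBundle()]
#' @param dir bundle directory.
#' @return A list with tree, traits, confidences, labels, config.
#' @export
readBundle <- function(dir) {
    m <- as.data.frame(read.dcf(file.path(dir, "manifest.dcf")),
                       stringsAsFactors = FALSE)
    num <- function(s) as.numeric(strsplit(s, ",")[[1L]])
    cfg <- SimulationConfig(
        nSpecies = as.integer(m$nSpecies), nTraits = as.integer(m$nTraits),
        signalFraction = as.numeric(m$signalFraction),
        mkRate = as.numeric(m$mkRate),
        driverIndices = as.integer(num(m$driverIndices)),
        driverEffects = num(m$driverEffects),
        phyloLiabilitySd = as.numeric(m$phyloLiabilitySd),
        targetPrevalence = as.numeric(m$targetPrevalence),
        confidenceStrength = as.numeric(m$confidenceStrength),
        missingFraction = as.numeric(m$missingFraction),
        seed = as.integer(m$seed))
    tm <- readTraitTable(file.path(dir, "traits.tsv"))
    list(tree = parseNewick(readLines(file.path(dir, "tree.nwk"))[1L]),
         traits = traitScores(tm),
         confidences = readConfidenceTable(file.path(dir, "cplus.tsv"),
                                           file.path(dir, "cminus.tsv")),
         labels = readLabels(file.path(dir, "labels.tsv")),
         config = cfg)
}
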