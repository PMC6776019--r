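#' Combine a confidence pair into a single trait score
#'
#' Maps paired confidences that a species does (\code{cplus}) and does not
#' (\code{cminus}) have a trait to a single score
#' \deqn{p = 1/2 + (c_+/(c_+ + c_-) - 1/2) \times \max(c_+, c_-),}
#' which is 1 under full confidence the trait is present, 0 under full
#' confidence it is absent, and shrinks toward 0.5 as overall confidence
#' drops. The indeterminate pair (0, 0) maps to 0.5 by convention.
#'
#' @param cplus,cminus numeric vectors in \code{[0, 1]} (recycled to a common
#'   length).
#' @return Numeric vector of scores in \code{[0, 1]}.
#' @examples
#' deriveScore(1, 0)      # 1
#' deriveScore(0.7, 0.7)  # 0.5
#' deriveScore(0.8, 0.2)  # 0.74
#' @export
deriveScore <- function(cplus, cminus) {
    .assertProb(cplus, "cplus")
    .assertProb(cminus, "cminus")
    tot <- cplus + cminus
    rel <- ifelse(tot == 0, 0.5, cplus / tot)
    0.5 + (rel - 0.5) * pmax(cplus, cminus)
}

#' Score every cell of a ConfidenceTable
#'
#' Applies [deriveScore()] elementwise; missing cells stay missing and shape
#' and labels are preserved.
#'
#' @param ct a \linkS4class{ConfidenceTable}.
#' @return A \linkS4class{TraitMatrix} (incomplete if any cell was missing).
#' @export
scoreTable <- function(ct) {
    stopifnot(is(ct, "ConfidenceTable"))
    validObject(ct)
    cp <- ct@cplus
    p <- cp
    ok <- !is.na(cp)
    p[ok] <- deriveScore(cp[ok], ct@cminus[ok])
    TraitMatrix(p)
}

#' Impute missing trait scores with iterative regression forests
#'
#' missForest-style scheme: missing cells are initialised with column means;
#' then, sweeping columns in order of increasing missingness, each incomplete
#' column is regressed on all other (current) columns with a random forest
#' fitted to its observed rows, and its missing cells are overwritten with
#' forest predictions. Sweeps repeat until the normalised squared change of
#' the imputed cells increases, or \code{maxIter} is reached; the matrix from
#' the sweep before the increase is returned. Observed cells are never
#' altered; output is clipped to \code{[0, 1]}.
#'
#' @param tm a \linkS4class{TraitMatrix} (missing cells allowed).
#' @param maxIter maximum number of sweeps (default 10).
#' @param seed integer seed making the forests deterministic.
#' @param nTrees trees per regression forest (default 100).
#' @return A complete \linkS4class{TraitMatrix}.
#' @export
imputeMissing <- function(tm, maxIter = 10L, seed = 1L, nTrees = 100L) {
    stopifnot(is(tm, "TraitMatrix"))
    x <- tm@scores
    miss <- is.na(x)
    if (!any(miss)) return(tm)
    allMissing <- colnames(x)[colSums(!miss) == 0]
    if (length(allMissing))
        stop("column(s) entirely missing, cannot impute: ",
             paste(allMissing, collapse = ", "), call. = FALSE)
    colMu <- colMeans(x, na.rm = TRUE)
    for (j in which(colSums(miss) > 0)) x[miss[, j], j] <- colMu[j]
    if (ncol(x) < 2L) {  # single column: mean fill is all we can do
        return(TraitMatrix(pmin(pmax(x, 0), 1)))
    }
    ord <- order(colSums(miss))
    ord <- ord[colSums(miss)[ord] > 0]
    set.seed(deriveSubSeed(seed, "impute"))
    prevDelta <- Inf
    for (iter in seq_len(max(1L, as.integer(maxIter)))) {
        old <- x
        for (j in ord) {
            obs <- !miss[, j]
            ## constant / near-constant columns are legitimate here, so the
            ## forest's "few unique response values" warning is noise
            fit <- suppressWarnings(randomForest::randomForest(
                x = x[obs, -j, drop = FALSE], y = x[obs, j],
                ntree = nTrees))
            x[!obs, j] <- stats::predict(fit, x[!obs, -j, drop = FALSE])
        }
        delta <- sum((x[miss] - old[miss])^2) / max(sum(x[miss]^2), .Machine$double.eps)
        if (delta >= prevDelta) { x <- old; break }
        prevDelta <- delta
    }
    x <- pmin(pmax(x, 0), 1)
    x[!miss] <- tm@scores[!miss]
    TraitMatrix(x)
}

#' Drop trait columns whose names match any pattern
#'
#' Patterns are literal substrings (fixed matching, no regular expressions),
#' mirroring removal of e.g. summary and substrate trait families by name.
#'
#' @param tm a \linkS4class{TraitMatrix}.
#' @param namePatterns character vector of literal substrings; empty vector
#'   leaves the matrix unchanged.
#' @return The filtered \linkS4class{TraitMatrix}, with the removed trait
#'   names attached as \code{attr(, "removed")}.
#' @export
dropTraits <- function(tm, namePatterns = character(0)) {
    stopifnot(is(tm, "TraitMatrix"))
    nm <- colnames(tm@scores)
    hit <- rep(FALSE, length(nm))
    for (p in namePatterns) hit <- hit | grepl(p, nm, fixed = TRUE)
    if (all(hit))
        stop("name patterns would remove every trait column", call. = FALSE)
    out <- TraitMatrix(tm@scores[, !hit, drop = FALSE])
    attr(out, "removed") <- nm[hit]
    out
}
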