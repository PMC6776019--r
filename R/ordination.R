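#' Principal component analysis of a trait matrix
#'
#' Column-centred (optionally unit-variance scaled) PCA by singular value
#' decomposition. Outcome labels are never part of the input: ordination is
#' strictly unsupervised.
#'
#' @param tm a complete \linkS4class{TraitMatrix} or numeric matrix.
#' @param nComponents number of components to keep (default all available,
#'   i.e. \code{min(n - 1, p)}).
#' @param scale scale columns to unit variance (default FALSE, matching the
#'   centring-only default of \code{prcomp}).
#' @return An \linkS4class{OrdinationResult}; variance fractions are relative
#'   to the total variance of all components.
#' @export
runPCA <- function(tm, nComponents = NULL, scale = FALSE) {
    x <- .asScoreMatrix(tm)
    if (anyNA(x))
        stop("incomplete input: impute missing scores first (imputeMissing)",
             call. = FALSE)
    maxComp <- min(nrow(x) - 1L, ncol(x))
    if (is.null(nComponents)) nComponents <- maxComp
    if (nComponents < 1 || nComponents > maxComp)
        stop("nComponents must lie in 1..min(nrow - 1, ncol)", call. = FALSE)
    if (scale && any(apply(x, 2, stats::sd) == 0))
        stop("cannot scale: constant trait column present", call. = FALSE)
    pc <- stats::prcomp(x, center = TRUE, scale. = scale)
    frac <- pc$sdev^2 / sum(pc$sdev^2)
    idx <- seq_len(nComponents)
    new("OrdinationResult",
        scores = pc$x[, idx, drop = FALSE],
        loadings = pc$rotation[, idx, drop = FALSE],
        varExplained = frac[idx], scaled = scale)
}

#' Traits loading most heavily on a component
#'
#' @param ord an \linkS4class{OrdinationResult}.
#' @param component component index.
#' @param n how many traits to report (default 10; capped at the trait count).
#' @return data.frame (trait, weight) sorted by absolute weight, descending.
#' @export
topLoadings <- function(ord, component = 1L, n = 10L) {
    stopifnot(is(ord, "OrdinationResult"))
    if (component < 1 || component > ncol(ord@loadings))
        stop("component out of range", call. = FALSE)
    w <- ord@loadings[, component]
    ordIdx <- order(abs(w), decreasing = TRUE)[seq_len(min(n, length(w)))]
    data.frame(trait = rownames(ord@loadings)[ordIdx], weight = w[ordIdx],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Plot-ready embedding table with outcome overlay
#'
#' Joins any two-dimensional per-species embedding (PCA scores or an external
#' nonlinear embedding) with per-species labels for plotting. Labels enter
#' only here, after the unsupervised step, preserving the separation between
#' ordination inputs and the outcome.
#'
#' @param coords numeric matrix or data.frame with two columns and species
#'   rownames.
#' @param labels named vector of labels over the same species.
#' @return data.frame (species, x, y, label).
#' @export
exportEmbedding <- function(coords, labels) {
    coords <- as.matrix(coords)
    if (ncol(coords) != 2L) stop("coords must have exactly 2 columns",
                                 call. = FALSE)
    sp <- rownames(coords)
    if (is.null(sp) || is.null(names(labels)) ||
        !setequal(sp, names(labels)) || length(labels) != nrow(coords))
        stop("species mismatch between coords and labels", call. = FALSE)
    data.frame(species = sp, x = coords[, 1L], y = coords[, 2L],
               label = unname(labels[sp]), row.names = NULL,
               stringsAsFactors = FALSE)
}
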