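#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact interval: lower bound
#' \code{qbeta(alpha/2, s, n - s + 1)} (0 when \code{s = 0}), upper bound
#' \code{qbeta(1 - alpha/2, s + 1, n - s)} (1 when \code{s = n}).
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.99).
#' @return Numeric \code{c(lower, upper)} within \code{[0, 1]}.
#' @export
binomialCI <- function(successes, n, level = 0.99) {
    if (length(n) != 1L || n < 1 || successes < 0 || successes > n ||
        successes != round(successes))
        stop("need integer 0 <= successes <= n with n >= 1", call. = FALSE)
    alpha <- 1 - level
    lower <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes,
                                                     n - successes + 1)
    upper <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2,
                                                     successes + 1,
                                                     n - successes)
    c(lower = lower, upper = upper)
}

#' Outcome incidence per category with exact confidence intervals
#'
#' Per category: group size, incidence fraction and a Clopper-Pearson interval
#' at \code{level}. Categories with fewer than \code{minCount} species are
#' omitted from the summary and listed in the \code{"omitted"} attribute.
#'
#' @param labels binary 0/1 outcome per species.
#' @param categories one category label per species.
#' @param level confidence level (default 0.99).
#' @param minCount smallest category size retained (default 10).
#' @return data.frame (category, n, positives, incidence, lower, upper) with
#'   an \code{"omitted"} attribute (data.frame of category, n).
#' @export
incidenceByCategory <- function(labels, categories, level = 0.99,
                                minCount = 10L) {
    labels <- .assertBinary(labels, "labels")
    if (length(labels) != length(categories))
        stop("labels and categories must have equal length", call. = FALSE)
    categories <- as.character(categories)
    sizes <- table(categories)
    keep <- names(sizes)[sizes >= minCount]
    if (!length(keep))
        stop("every category falls below minCount; empty result", call. = FALSE)
    rows <- lapply(keep, function(cat) {
        idx <- categories == cat
        s <- sum(labels[idx]); n <- sum(idx)
        ci <- binomialCI(s, n, level)
        data.frame(category = cat, n = n, positives = s, incidence = s / n,
                   lower = ci[["lower"]], upper = ci[["upper"]],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    omitted <- names(sizes)[sizes < minCount]
    attr(out, "omitted") <- data.frame(category = omitted,
                                       n = as.integer(sizes[omitted]),
                                       stringsAsFactors = FALSE)
    out
}

#' Pearson chi-square test with small-category exclusion
#'
#' Rows (categories) whose total count falls below \code{minCount} are removed
#' before a plain Pearson chi-square test (no continuity correction unless
#' requested) of independence between category and outcome.
#'
#' @param counts nonnegative integer contingency matrix (categories x outcome
#'   classes).
#' @param minCount smallest retained row total (default 10).
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return List with \code{statistic}, \code{df}, \code{p.value},
#'   \code{excluded} (dropped row labels).
#' @export
chiSquare <- function(counts, minCount = 10L, correct = FALSE) {
    counts <- as.matrix(counts)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be nonnegative integers", call. = FALSE)
    keep <- rowSums(counts) >= minCount
    excluded <- rownames(counts)[!keep]
    counts <- counts[keep, , drop = FALSE]
    if (nrow(counts) < 2L)
        stop("degenerate table: fewer than 2 categories after exclusion",
             call. = FALSE)
    ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = unname(ht$p.value), excluded = excluded)
}

#' Phi coefficient (Pearson correlation of two binary vectors)
#'
#' @param a,b equal-length binary 0/1 vectors, each with both values present.
#' @return Correlation in \code{[-1, 1]}.
#' @export
phiCorrelation <- function(a, b) {
    a <- .assertBinary(a, "a"); b <- .assertBinary(b, "b")
    if (length(a) != length(b)) stop("a and b must have equal length",
                                     call. = FALSE)
    if (stats::var(a) == 0 || stats::var(b) == 0)
        stop("undefined correlation: zero-variance vector", call. = FALSE)
    stats::cor(a, b)
}

#' Binary association between outcome and factor, stratified
#'
#' Within each stratum with at least \code{minCount} species (and pooled over
#' all species), computes the phi correlation and a 2x2 Pearson chi-square
#' test between \code{outcome} and \code{factor}. Strata where either vector
#' is constant report \code{NA} correlation.
#'
#' @param outcome,factor binary 0/1 vectors per species.
#' @param stratum stratum label per species.
#' @param minCount smallest stratum analysed (default 10).
#' @return data.frame (stratum, n, rho, chisq, df, p) with the pooled row
#'   labelled \code{"pooled"} first.
#' @export
stratifiedAssociation <- function(outcome, factor, stratum, minCount = 10L) {
    outcome <- .assertBinary(outcome, "outcome")
    factor <- .assertBinary(factor, "factor")
    stratum <- as.character(stratum)
    stopifnot(length(outcome) == length(factor),
              length(outcome) == length(stratum))
    oneRow <- function(name, idx) {
        o <- outcome[idx]; f <- factor[idx]
        rho <- if (stats::var(o) == 0 || stats::var(f) == 0) NA_real_
               else stats::cor(o, f)
        tab <- table(factor(f, levels = 0:1), factor(o, levels = 0:1))
        ht <- if (is.na(rho)) list(statistic = NA_real_, parameter = NA_real_,
                                   p.value = NA_real_)
              else suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        data.frame(stratum = name, n = sum(idx), rho = rho,
                   chisq = unname(ht$statistic), df = unname(ht$parameter),
                   p = unname(ht$p.value), stringsAsFactors = FALSE)
    }
    out <- oneRow("pooled", rep(TRUE, length(outcome)))
    for (s in sort(unique(stratum))) {
        idx <- stratum == s
        if (sum(idx) >= minCount) out <- rbind(out, oneRow(s, idx))
    }
    out
}
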