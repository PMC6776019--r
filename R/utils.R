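## Internal helpers shared across modules.

## Deterministic sub-seed for a named pipeline stage: a small string hash
## folded into the master seed, kept below 2^31 so set.seed() accepts it.
## Doubles represent all intermediates exactly (< 2^53).
deriveSubSeed <- function(seed, stage) {
    stopifnot(length(seed) == 1L, is.finite(seed))
    h <- 0
    for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
    as.integer((h + abs(as.numeric(seed))) %% 2147483647)
}

.assertProb <- function(x, what) {
    if (anyNA(x) || any(x < 0) || any(x > 1))
        stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
    invisible(x)
}

.assertBinary <- function(x, what) {
    x <- as.numeric(x)
    if (anyNA(x) || !all(x %in% c(0, 1)))
        stop(sprintf("%s must be a binary (0/1) vector without NAs", what),
             call. = FALSE)
    x
}

## A species x trait numeric matrix from either a TraitMatrix or a bare matrix.
.asScoreMatrix <- function(x) {
    if (is(x, "TraitMatrix")) x <- x@scores
    if (!is.matrix(x) || !is.numeric(x))
        stop("expected a TraitMatrix or a numeric matrix", call. = FALSE)
    x
}
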