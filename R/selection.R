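#' Fit a logistic regression by IRLS with ridge stabilisation
#'
#' Maximum-likelihood logistic fit via iteratively reweighted least squares,
#' with a tiny ridge penalty (1e-6 on all coefficients) that keeps estimates
#' finite under complete separation; separated fits are flagged rather than
#' rejected. Convergence is declared when the penalised score norm drops below
#' 1e-6.
#'
#' @param X numeric design matrix (no intercept column; one is added).
#' @param y binary 0/1 response with both classes present.
#' @param ridge ridge penalty (default 1e-6).
#' @param maxIter IRLS iteration cap (default 100).
#' @return A list of class \code{"logisticFit"}: \code{coef} (named, first
#'   element \code{(Intercept)}), \code{logLik} (unpenalised training
#'   log-likelihood), \code{converged}, \code{separated}, \code{n}.
#' @export
fitLogistic <- function(X, y, ridge = 1e-6, maxIter = 100L) {
    y <- .assertBinary(y, "y")
    if (length(unique(y)) < 2L)
        stop("degenerate outcome: y has a single class", call. = FALSE)
    X <- if (is.null(X) || ncol(as.matrix(X)) == 0)
        matrix(numeric(0), nrow = length(y), ncol = 0)
    else as.matrix(X)
    if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
    Z <- cbind(`(Intercept)` = 1, X)
    p <- ncol(Z)
    beta <- numeric(p)
    converged <- FALSE
    for (i in seq_len(maxIter)) {
        eta <- pmin(pmax(drop(Z %*% beta), -30), 30)
        mu <- stats::plogis(eta)
        w <- pmax(mu * (1 - mu), 1e-10)
        score <- drop(crossprod(Z, y - mu)) - ridge * beta
        if (sqrt(sum(score^2)) < 1e-6) { converged <- TRUE; break }
        H <- crossprod(Z * w, Z) + diag(ridge, p)
        beta <- beta + solve(H, score)
    }
    eta <- pmin(pmax(drop(Z %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
    ## under the tiny ridge, separation shows as a perfectly classifying fit
    ## whose linear predictor has drifted to implausible magnitude
    separated <- all((mu >= 0.5) == (y == 1)) && max(abs(eta)) > 8
    structure(list(coef = stats::setNames(beta, colnames(Z)), logLik = ll,
                   converged = converged, separated = separated,
                   n = length(y)),
              class = "logisticFit")
}

#' Predict probabilities from a logisticFit
#' @param object a \code{"logisticFit"}.
#' @param newdata numeric matrix with the predictor columns the model was
#'   fitted on.
#' @param ... unused.
#' @return Numeric vector of probabilities.
#' @export
predict.logisticFit <- function(object, newdata, ...) {
    newdata <- as.matrix(newdata)
    vars <- names(object$coef)[-1L]
    if (length(vars)) newdata <- newdata[, vars, drop = FALSE]
    eta <- object$coef[1L] +
        if (length(vars)) drop(newdata %*% object$coef[-1L]) else 0
    stats::plogis(pmin(pmax(eta, -30), 30))
}

#' Cross-validated prediction error of a logistic predictor set
#'
#' For each fold, fits the logistic model on the complement and predicts the
#' held-out rows; returns the mean squared error over all held-out
#' observations. With \code{criterion = "brier"} (default) the error is
#' \eqn{(\hat p - y)^2} on predicted probabilities (the Brier score); with
#' \code{"zeroone"} it is the misclassification indicator at threshold 0.5.
#' A training complement containing a single class contributes a constant
#' class-frequency forecast, with a warning.
#'
#' @param X complete numeric trait matrix (species x traits, named columns).
#' @param y binary outcome aligned with \code{rownames(X)}.
#' @param predictorSet character vector of column names (may be empty:
#'   intercept-only model).
#' @param folds a \linkS4class{FoldAssignment} covering all rows.
#' @param criterion \code{"brier"} or \code{"zeroone"}.
#' @return Mean held-out error (a single number).
#' @export
cvError <- function(X, y, predictorSet = character(0), folds,
                    criterion = c("brier", "zeroone")) {
    criterion <- match.arg(criterion)
    X <- .asScoreMatrix(X)
    y <- .assertBinary(y, "y")
    f <- folds@folds[rownames(X)]
    if (anyNA(f)) stop("folds must cover every row of X", call. = FALSE)
    err <- 0
    for (i in seq_len(folds@k)) {
        hold <- f == i
        if (!any(hold)) next
        ytr <- y[!hold]
        if (length(unique(ytr)) < 2L) {
            warning("training complement of fold ", i,
                    " has a single class; using its class frequency")
            phat <- rep(mean(ytr), sum(hold))
        } else {
            fit <- fitLogistic(X[!hold, predictorSet, drop = FALSE], ytr)
            phat <- predict(fit, X[hold, predictorSet, drop = FALSE])
        }
        err <- err + if (criterion == "brier") sum((phat - y[hold])^2)
                     else sum((phat >= 0.5) != y[hold])
    }
    err / length(y)
}

## BIC of the full-data refit on a predictor set; d counts the intercept.
.refitBIC <- function(X, y, predictorSet) {
    fit <- fitLogistic(X[, predictorSet, drop = FALSE], y)
    -2 * fit$logLik + (length(predictorSet) + 1) * log(length(y))
}

#' Forward selection path under cross-validated error
#'
#' Greedy forward subset selection: starting from the intercept-only model, at
#' each step adds the predictor whose inclusion minimises [cvError()]; exact
#' ties go to the alphabetically first trait name. For every model size the
#' chosen (nested) set, its CV error, and the BIC of a full-data refit are
#' recorded.
#'
#' @inheritParams cvError
#' @param maxSize largest model size to grow to (default 30, capped at the
#'   number of predictors).
#' @return A list of class \code{"selectionPath"}: \code{table} (data.frame
#'   with size, added trait, cvError, bic — size 0 row included), \code{sets}
#'   (list of predictor sets by size, starting at size 0), \code{n}.
#' @export
forwardPath <- function(X, y, folds, maxSize = 30L,
                        criterion = c("brier", "zeroone")) {
    criterion <- match.arg(criterion)
    X <- .asScoreMatrix(X)
    y <- .assertBinary(y, "y")
    maxSize <- min(as.integer(maxSize), ncol(X))
    chosen <- character(0)
    sets <- list(character(0))
    tab <- data.frame(size = 0L, added = NA_character_,
                      cvError = cvError(X, y, character(0), folds, criterion),
                      bic = .refitBIC(X, y, character(0)),
                      stringsAsFactors = FALSE)
    remaining <- sort(colnames(X))
    for (s in seq_len(maxSize)) {
        errs <- vapply(remaining, function(v)
            cvError(X, y, c(chosen, v), folds, criterion), numeric(1))
        best <- remaining[which.min(errs)]  # remaining is name-sorted: ties
        chosen <- c(chosen, best)           # resolve to the first name
        remaining <- setdiff(remaining, best)
        sets[[s + 1L]] <- chosen
        tab <- rbind(tab, data.frame(size = s, added = best,
                                     cvError = min(errs),
                                     bic = .refitBIC(X, y, chosen),
                                     stringsAsFactors = FALSE))
    }
    structure(list(table = tab, sets = sets, n = length(y)),
              class = "selectionPath")
}

#' Choose the model size minimising BIC along a selection path
#'
#' @param path a \code{"selectionPath"} from [forwardPath()].
#' @return Character vector of the chosen predictors (possibly empty); ties in
#'   BIC go to the smaller model.
#' @export
selectByBIC <- function(path) {
    stopifnot(inherits(path, "selectionPath"))
    bic <- path$table$bic
    path$sets[[which.min(bic)]]  # which.min returns the first (smallest) size
}
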