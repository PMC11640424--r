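## L1-penalized logistic scoring of pair indicators.
##
## The model minimizes the standard Lasso-logistic objective
##   (1/n) * sum_s log(1 + exp(-y_s * (b0 + x_s' b))) + lambda * ||b||_1
## (labels coded +/-1), fitted by glmnet's coordinate descent on the
## unstandardized binary indicators. lambda is chosen by seeded, stratified
## k-fold cross-validated deviance on a path of 100 log-spaced values from
## lambda_max down to 1e-3 * lambda_max. Coefficients are the penalized
## solution itself -- no post-selection refit -- and pairs whose coefficient
## is shrunk to exactly zero are dropped from the returned model.

.lambdaPathArgs <- function() list(nlambda = 100L, lambda.min.ratio = 1e-3)

# glmnet emits advisory warnings at the class sizes typical of biofluid
# cohorts (< 8 per class, single-observation folds), and truncates the
# lambda path when separable data make the unpenalized tail diverge (the
# returned knots are still valid, and lambda is chosen among them). Both
# restate the study design rather than flag a defect, so they are muffled.
.quietGlmnet <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
        if (grepl(paste0("dangerous ground|fewer than 8|grouped=FALSE|",
                         "Convergence for .* lambda value not reached"),
                  conditionMessage(w)))
            invokeRestart("muffleWarning")
    })
}

# glmnet needs >= 2 predictor columns; a zero column is inert under the
# penalty and is stripped from the solution afterwards.
.padForGlmnet <- function(X) {
    if (ncol(X) >= 2L) return(list(X = X, padded = FALSE))
    list(X = cbind(X, .pad. = 0), padded = TRUE)
}

#' Fit the penalized logistic pair model
#'
#' @param x a [PairIndicators-class] (or plain 0/1 matrix with one column
#'   per pair when `pairs` is supplied).
#' @param labels class labels, one per sample (row).
#' @param cvFolds number of cross-validation folds; default
#'   `min(10, smallest class size)` (never below 3). `"loo"` or the sample
#'   size requests leave-one-out.
#' @param seed RNG seed controlling the stratified fold assignment.
#' @param lambda optional fixed penalty; skips cross-validation.
#' @param lambdaRule `"min"` (minimum cross-validated deviance, default) or
#'   `"1se"`.
#' @param positive,negative class label mapping; positive scores map to
#'   `positive`.
#' @param pairs pairs data.frame when `x` is a bare matrix.
#' @param gridHash optional feature-grid key stored in the model.
#' @return A [TSPModel-class].
#' @export
fitTSPModel <- function(x, labels, cvFolds = NULL, seed = 1L,
                        lambda = NULL, lambdaRule = c("min", "1se"),
                        positive = "positive", negative = "negative",
                        pairs = NULL, gridHash = "") {
    lambdaRule <- match.arg(lambdaRule)
    if (is(x, "PairIndicators")) {
        ind <- x@indicators
        pairs <- x@pairs
    } else {
        ind <- x
        if (is.null(pairs))
            stop("pairs data.frame required with a bare indicator matrix")
    }
    if (!all(ind %in% c(0, 1)))
        stop("indicators must be binary", call. = FALSE)
    y <- .binaryY(labels, positive, negative)
    if (sum(y) < 2L || sum(!y) < 2L)
        stop("model fitting requires at least 2 samples per class",
             call. = FALSE)

    keep <- apply(ind, 2L, function(col) length(unique(col)) > 1L)
    if (!all(keep))
        warning(sprintf("dropping constant indicator column(s): %s",
            paste(colnames(ind)[!keep], collapse = ", ")), call. = FALSE)
    ind <- ind[, keep, drop = FALSE]
    pairs <- pairs[keep, , drop = FALSE]

    if (ncol(ind) == 0L) {
        # nothing left to penalize: intercept-only model at the class odds
        return(new("TSPModel", pairs = pairs[0, , drop = FALSE],
            intercept = stats::qlogis(mean(y)), coefficients = numeric(),
            lambda = 0, positiveLabel = positive, negativeLabel = negative,
            cvFolds = 0L, seed = as.integer(seed), gridHash = gridHash))
    }

    yf <- factor(ifelse(y, positive, negative),
                 levels = c(negative, positive))
    pad <- .padForGlmnet(ind)
    pathArgs <- .lambdaPathArgs()

    if (!is.null(lambda)) {
        fit <- .quietGlmnet(glmnet::glmnet(pad$X, yf, family = "binomial",
            standardize = FALSE, thresh = 1e-12,
            nlambda = pathArgs$nlambda,
            lambda.min.ratio = pathArgs$lambda.min.ratio))
        lamGrid <- sort(unique(c(fit$lambda, lambda * c(4, 2, 1))),
                        decreasing = TRUE)
        lamGrid <- lamGrid[lamGrid >= lambda - 1e-15]
        fit <- .quietGlmnet(glmnet::glmnet(pad$X, yf, family = "binomial",
            standardize = FALSE, thresh = 1e-12, lambda = lamGrid))
        cf <- as.numeric(stats::coef(fit, s = lambda))
        chosen <- lambda
        usedFolds <- 0L
    } else {
        k <- if (is.null(cvFolds))
            max(3L, min(10L, min(sum(y), sum(!y))))
        else if (identical(cvFolds, "loo")) length(y)
        else as.integer(cvFolds)
        foldid <- if (k >= length(y)) seq_along(y)
                  else stratifiedFolds(y, k, seed)
        k <- max(foldid)
        # grouped = FALSE: per-observation deviance, stable for the small
        # (down to single-observation) folds used at these cohort sizes
        cv <- .quietGlmnet(glmnet::cv.glmnet(pad$X, yf,
            family = "binomial",
            type.measure = "deviance", foldid = foldid, grouped = FALSE,
            standardize = FALSE, thresh = 1e-9,
            nlambda = pathArgs$nlambda,
            lambda.min.ratio = pathArgs$lambda.min.ratio))
        chosen <- if (lambdaRule == "min") cv$lambda.min else cv$lambda.1se
        cf <- as.numeric(stats::coef(cv, s = chosen))
        usedFolds <- k
    }

    intercept <- cf[1L]
    beta <- cf[-1L]
    if (pad$padded) beta <- beta[seq_len(ncol(ind))]
    # coordinate descent leaves numerical dust of order thresh on inactive
    # coordinates; anything below 1e-8 is a zero
    nz <- abs(beta) > 1e-8
    out <- new("TSPModel",
        pairs = local({p <- pairs[nz, , drop = FALSE]; rownames(p) <- NULL; p}),
        intercept = intercept, coefficients = beta[nz],
        lambda = chosen, positiveLabel = positive, negativeLabel = negative,
        cvFolds = as.integer(usedFolds), seed = as.integer(seed),
        gridHash = gridHash)
    validObject(out)
    out
}

.featureValuesFor <- function(fx) {
    if (is(fx, "ThermogramFeatures")) {
        list(X = featureMatrix(fx),
             temps = SummarizedExperiment::rowData(fx)$temperature,
             hash = S4Vectors::metadata(fx)$gridHash)
    } else if (is.numeric(fx) && !is.null(names(fx))) {
        list(X = matrix(fx, nrow = 1,
                        dimnames = list("sample", names(fx))),
             temps = as.numeric(names(fx)), hash = NULL)
    } else stop("expected ThermogramFeatures or a named feature vector")
}

.checkModelGrid <- function(model, hash) {
    if (nzchar(model@gridHash) && !is.null(hash) &&
        !identical(model@gridHash, hash))
        stop(sprintf(
            "grid mismatch: model expects %s but features were prepared with %s",
            model@gridHash, hash), call. = FALSE)
}

#' Score samples with a fitted pair model
#'
#' `score = intercept + sum_k coefficient_k * I(cp(Ti_k) > cp(Tj_k))`; an
#' unbounded real number per sample.
#'
#' @param model a [TSPModel-class].
#' @param fx a [ThermogramFeatures-class], or a single named feature vector
#'   (names = temperatures).
#' @return named numeric vector of scores.
#' @export
tspScore <- function(model, fx) {
    stopifnot(is(model, "TSPModel"))
    fv <- .featureValuesFor(fx)
    .checkModelGrid(model, fv$hash)
    s <- rep(model@intercept, nrow(fv$X))
    for (k in seq_len(nrow(model@pairs))) {
        ij <- matchTemperature(c(model@pairs$ti[k], model@pairs$tj[k]),
                               fv$temps)
        if (anyNA(ij))
            stop(sprintf(
                "grid mismatch: temperature %g required by the model is absent",
                c(model@pairs$ti[k], model@pairs$tj[k])[is.na(ij)][1L]),
                call. = FALSE)
        s <- s + model@coefficients[k] *
            as.numeric(fv$X[, ij[1L]] > fv$X[, ij[2L]])
    }
    setNames(s, rownames(fv$X))
}

#' Classify samples by the sign of the model score
#'
#' Strictly positive scores map to the positive class; zero or negative
#' scores map to the negative class (ties broken toward the lower-risk
#' class).
#'
#' @inheritParams tspScore
#' @return named character vector of predicted labels.
#' @export
tspClassify <- function(model, fx) {
    s <- tspScore(model, fx)
    setNames(ifelse(s > 0, model@positiveLabel, model@negativeLabel),
             names(s))
}

#' Per-sample score table
#'
#' @inheritParams tspScore
#' @param truth optional named true labels.
#' @return data.frame with columns sample_id, score, predicted, truth.
#' @export
scoreTable <- function(model, fx, truth = NULL) {
    s <- tspScore(model, fx)
    pred <- ifelse(s > 0, model@positiveLabel, model@negativeLabel)
    tr <- if (is.null(truth)) rep(NA_character_, length(s))
          else unname(truth[names(s)])
    data.frame(sample_id = names(s), score = unname(s),
               predicted = unname(pred), truth = tr,
               stringsAsFactors = FALSE)
}

#' Split a cohort into training and validation sets
#'
#' Training samples are those with a confirmed diagnosis; the remaining
#' (high-probability) samples form the validation set. The partition is
#' exhaustive and disjoint.
#'
#' @param cohort a [ThermogramCohort-class] with confirmed flags.
#' @return list with elements `training` and `validation`, both
#'   [ThermogramCohort-class].
#' @export
trainValidateSplit <- function(cohort) {
    stopifnot(is(cohort, "ThermogramCohort"))
    conf <- confirmedFlags(cohort)
    if (all(is.na(conf)))
        stop("confirmed flags absent: cannot split", call. = FALSE)
    isConf <- !is.na(conf) & conf
    if (!any(isConf))
        stop("no confirmed samples: cannot form a training set",
             call. = FALSE)
    if (all(isConf))
        warning("all samples confirmed: validation set is empty",
                call. = FALSE)
    list(training = cohort[which(isConf)],
         validation = cohort[which(!isConf)])
}

#' Serialize a fitted model to JSON
#'
#' @param model a [TSPModel-class].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
writeTSPModel <- function(model, path) {
    stopifnot(is(model, "TSPModel"))
    obj <- list(
        package = "thermoTLB",
        version = as.character(packageVersion("thermoTLB")),
        pairs = model@pairs,
        intercept = model@intercept,
        coefficients = model@coefficients,
        lambda = model@lambda,
        positiveLabel = model@positiveLabel,
        negativeLabel = model@negativeLabel,
        cvFolds = model@cvFolds,
        seed = model@seed,
        gridHash = model@gridHash)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path JSON file written by [writeTSPModel()].
#' @return A [TSPModel-class].
#' @export
readTSPModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pairs <- as.data.frame(obj$pairs)
    if (!nrow(pairs))
        pairs <- data.frame(ti = numeric(), tj = numeric(),
                            scorePrimary = numeric(),
                            scoreSecondary = numeric())
    new("TSPModel", pairs = pairs,
        intercept = as.numeric(obj$intercept),
        coefficients = as.numeric(obj$coefficients),
        lambda = as.numeric(obj$lambda),
        positiveLabel = obj$positiveLabel,
        negativeLabel = obj$negativeLabel,
        cvFolds = as.integer(obj$cvFolds),
        seed = as.integer(obj$seed),
        gridHash = obj$gridHash)
}
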