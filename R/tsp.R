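## Temperature-pair ordering features (top-scoring-pairs statistic).
##
## For a pair of feature temperatures (Ti, Tj) the indicator
## I(cp(Ti) > cp(Tj)) captures local curve shape independently of amplitude.
## The primary pair score is the absolute difference between the two
## within-class frequencies of that event; a rank-based secondary score
## orders ties. Being rank-based, both are invariant to any positive
## rescaling of a sample's curve.

.resolveFeatures <- function(x) {
    if (is(x, "ThermogramFeatures")) {
        list(X = featureMatrix(x),
             temps = SummarizedExperiment::rowData(x)$temperature,
             labels = classLabels(x))
    } else if (is.matrix(x)) {
        list(X = x, temps = as.numeric(colnames(x)), labels = NULL)
    } else stop("expected ThermogramFeatures or a samples-by-temperatures matrix")
}

.binaryY <- function(labels, positive, negative) {
    if (anyNA(labels))
        stop("all samples must be labeled for pair scoring", call. = FALSE)
    if (!all(labels %in% c(positive, negative)))
        stop(sprintf("labels must be '%s' or '%s'", negative, positive),
             call. = FALSE)
    y <- labels == positive
    if (!any(y) || all(y))
        stop("both classes must be non-empty", call. = FALSE)
    y
}

# Per-sample ranks across the feature grid (basis of the secondary score).
.sampleRanks <- function(X) t(apply(X, 1L, rank))

#' Score one temperature pair
#'
#' Primary score: `| P(cp(Ti) > cp(Tj) | positive) - P(cp(Ti) > cp(Tj) |
#' negative) |` with within-class empirical frequencies and strict
#' inequality (ties do not count). Secondary score: absolute between-class
#' difference of the mean within-sample rank difference `rank(Ti) -
#' rank(Tj)`; used only to order ties in the primary score.
#'
#' @param x a [ThermogramFeatures-class] or samples-by-temperatures matrix
#'   with temperature colnames.
#' @param ti,tj distinct feature-grid temperatures (degC).
#' @param labels class labels; defaults to `classLabels(x)`.
#' @param positive,negative label values.
#' @return named numeric `c(primary = , secondary = )`.
#' @export
pairScore <- function(x, ti, tj, labels = NULL,
                      positive = "positive", negative = "negative") {
    fr <- .resolveFeatures(x)
    if (is.null(labels)) labels <- fr$labels
    y <- .binaryY(labels, positive, negative)
    if (isTRUE(all.equal(ti, tj)))
        stop("ti and tj must differ", call. = FALSE)
    ij <- matchTemperature(c(ti, tj), fr$temps)
    if (anyNA(ij))
        stop("pair temperature not on the feature grid", call. = FALSE)
    X <- fr$X
    R <- .sampleRanks(X)
    gt <- X[, ij[1L]] > X[, ij[2L]]
    d <- R[, ij[1L]] - R[, ij[2L]]
    c(primary = abs(mean(gt[y]) - mean(gt[!y])),
      secondary = abs(mean(d[y]) - mean(d[!y])))
}

# Score every unordered pair; returns one row per pair in canonical
# direction (the one with P(positive) >= P(negative) for the strict
# ordering event).
.allPairScores <- function(X, temps, y) {
    R <- .sampleRanks(X)
    m <- length(temps)
    rows <- vector("list", m * (m - 1L) / 2L)
    k <- 0L
    for (i in seq_len(m - 1L)) {
        for (j in seq.int(i + 1L, m)) {
            k <- k + 1L
            gt <- X[, i] > X[, j]
            delta <- mean(gt[y]) - mean(gt[!y])
            dR <- R[, i] - R[, j]
            sec <- abs(mean(dR[y]) - mean(dR[!y]))
            if (delta >= 0) {
                rows[[k]] <- c(temps[i], temps[j], delta, sec)
            } else {
                lt <- X[, j] > X[, i]
                rows[[k]] <- c(temps[j], temps[i],
                               mean(lt[y]) - mean(lt[!y]), sec)
            }
        }
    }
    out <- as.data.frame(do.call(rbind, rows))
    names(out) <- c("ti", "tj", "scorePrimary", "scoreSecondary")
    out
}

#' Select top-scoring temperature pairs
#'
#' Scores every unordered pair on the feature grid, stores each in the
#' canonical direction (positive class more likely to satisfy
#' `cp(Ti) > cp(Tj)`), sorts by primary score (descending), then secondary
#' score (descending), then `(ti, tj)` ascending, and returns the top
#' `kMax` pairs. With `disjoint = TRUE` (standard kTSP semantics) each
#' temperature is used by at most one selected pair, filtered greedily down
#' the sorted list.
#'
#' @inheritParams pairScore
#' @param kMax maximum number of pairs to return.
#' @param disjoint require temperature-disjoint pairs.
#' @return data.frame with columns ti, tj, scorePrimary, scoreSecondary.
#' @examples
#' cohort <- generateCohort(defaultRecipes()[["shifted-peak"]])
#' fx <- prepareFeatures(cohort)
#' ktspSelect(fx, kMax = 3)
#' @export
ktspSelect <- function(x, kMax = 10, disjoint = TRUE, labels = NULL,
                       positive = "positive", negative = "negative") {
    stopifnot(kMax >= 1)
    fr <- .resolveFeatures(x)
    if (is.null(labels)) labels <- fr$labels
    y <- .binaryY(labels, positive, negative)
    if (length(fr$temps) < 2L)
        stop("need at least two feature temperatures to form pairs",
             call. = FALSE)
    sc <- .allPairScores(fr$X, fr$temps, y)
    sc <- sc[order(-sc$scorePrimary, -sc$scoreSecondary, sc$ti, sc$tj), ]
    if (disjoint) {
        used <- numeric(0)
        keep <- logical(nrow(sc))
        for (r in seq_len(nrow(sc))) {
            if (!(sc$ti[r] %in% used) && !(sc$tj[r] %in% used)) {
                keep[r] <- TRUE
                used <- c(used, sc$ti[r], sc$tj[r])
            }
        }
        sc <- sc[keep, ]
    }
    out <- utils::head(sc, kMax)
    rownames(out) <- NULL
    out
}

#' Binary ordering-indicator matrix for selected pairs
#'
#' Entry (s, k) is 1 when sample s has `cp(Ti_k) > cp(Tj_k)`, else 0; exact
#' ties count as 0 (strictly-greater semantics, so tied floating-point
#' values never score).
#'
#' @inheritParams pairScore
#' @param pairs data.frame with columns ti, tj (e.g. from [ktspSelect()]).
#' @return A [PairIndicators-class].
#' @export
indicatorMatrix <- function(x, pairs) {
    fr <- .resolveFeatures(x)
    X <- fr$X
    ind <- matrix(0, nrow = nrow(X), ncol = nrow(pairs),
                  dimnames = list(rownames(X),
                      if (nrow(pairs)) paste0("T", pairs$ti, ">T", pairs$tj)
                      else character()))
    for (k in seq_len(nrow(pairs))) {
        ij <- matchTemperature(c(pairs$ti[k], pairs$tj[k]), fr$temps)
        if (anyNA(ij))
            stop(sprintf("pair (%g, %g) not on the feature grid",
                         pairs$ti[k], pairs$tj[k]), call. = FALSE)
        ind[, k] <- as.numeric(X[, ij[1L]] > X[, ij[2L]])
    }
    new("PairIndicators", indicators = ind, pairs = pairs)
}
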