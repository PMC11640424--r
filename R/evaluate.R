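## Diagnostic performance evaluation: 2x2 confusion metrics, ROC/AUC with
## stratified bootstrap confidence intervals, and the Wilcoxon rank-sum
## comparison of score distributions.

.ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Build a ConfusionSummary from 2x2 counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return A [ConfusionSummary-class]; ratios with zero denominator are NA.
#' @examples
#' cs <- ConfusionSummary(tp = 11, fp = 4, tn = 6, fn = 1)
#' percentMetrics(cs)
#' @export
ConfusionSummary <- function(tp, fp, tn, fn) {
    stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
    total <- tp + fp + tn + fn
    metrics <- c(
        sensitivity = .ratio(tp, tp + fn),
        specificity = .ratio(tn, tn + fp),
        ppv = .ratio(tp, tp + fp),
        npv = .ratio(tn, tn + fn),
        accuracy = .ratio(tp + tn, total))
    new("ConfusionSummary", tp = as.integer(tp), fp = as.integer(fp),
        tn = as.integer(tn), fn = as.integer(fn), metrics = metrics)
}

#' Confusion metrics from predictions
#'
#' Cross-tabulates predicted against true labels and derives sensitivity,
#' specificity, PPV, NPV and accuracy. Sample order is irrelevant.
#'
#' @param x a score table (data.frame with `predicted` and `truth`
#'   columns, e.g. from [scoreTable()]).
#' @param positive,negative class label values.
#' @return A [ConfusionSummary-class].
#' @export
confusionMetrics <- function(x, positive = "positive",
                             negative = "negative") {
    stopifnot(is.data.frame(x),
              all(c("predicted", "truth") %in% names(x)))
    if (anyNA(x$truth))
        stop("every scored sample needs a true label", call. = FALSE)
    if (!all(x$truth %in% c(positive, negative)) ||
        !all(x$predicted %in% c(positive, negative)))
        stop("labels outside the positive/negative pair", call. = FALSE)
    ConfusionSummary(
        tp = sum(x$predicted == positive & x$truth == positive),
        fp = sum(x$predicted == positive & x$truth == negative),
        tn = sum(x$predicted == negative & x$truth == negative),
        fn = sum(x$predicted == negative & x$truth == positive))
}

# Mann-Whitney AUC; ties contribute 1/2 via midranks.
.aucMW <- function(pos, neg) {
    n1 <- length(pos); n0 <- length(neg)
    r <- rank(c(pos, neg))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' The AUC is the Mann-Whitney normalization (probability that a random
#' positive scores above a random negative, ties counted one half). The 95
#' percent confidence interval is obtained from a seeded class-stratified
#' bootstrap (percentiles 2.5 / 97.5). Perfectly separated scores give
#' AUC 1 with interval (1, 1).
#'
#' @param x a score table (data.frame with `score` and `truth` columns) or
#'   a numeric score vector.
#' @param truth true labels when `x` is a numeric vector.
#' @param positive,negative label values.
#' @param nBoot bootstrap replicates (default 2000).
#' @param seed bootstrap RNG seed.
#' @return A [ROCResult-class].
#' @export
rocAUC <- function(x, truth = NULL, positive = "positive",
                   negative = "negative", nBoot = 2000L, seed = 1L) {
    if (is.data.frame(x)) {
        truth <- x$truth
        s <- x$score
    } else s <- x
    stopifnot(nBoot >= 1L, length(s) == length(truth))
    if (anyNA(truth))
        stop("every scored sample needs a true label", call. = FALSE)
    pos <- s[truth == positive]
    neg <- s[truth == negative]
    if (!length(pos) || !length(neg))
        stop("both classes must be present to compute a ROC curve",
             call. = FALSE)

    aucHat <- .aucMW(pos, neg)
    boots <- withSeed(seed, vapply(seq_len(nBoot), function(b)
        .aucMW(sample(pos, replace = TRUE), sample(neg, replace = TRUE)),
        numeric(1)))
    ci <- unname(quantile(boots, c(0.025, 0.975), names = FALSE))
    # degenerate separation: every resample is also separated
    ciLo <- min(ci[1L], aucHat)
    ciHi <- max(ci[2L], aucHat)

    th <- c(Inf, sort(unique(s), decreasing = TRUE))
    curve <- data.frame(
        threshold = th,
        fpr = vapply(th, function(t) mean(neg >= t), numeric(1)),
        tpr = vapply(th, function(t) mean(pos >= t), numeric(1)))

    new("ROCResult", auc = aucHat, ciLo = ciLo, ciHi = ciHi,
        curve = curve, nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Wilcoxon rank-sum comparison of two score groups
#'
#' Two-sided test of a location difference between independent groups.
#' Exact enumeration when the smaller group has at most 12 observations and
#' there are no ties; otherwise the normal approximation with tie-corrected
#' variance (no continuity correction). The conventional significance
#' threshold is a two-sided p below 0.05.
#'
#' @param a,b numeric score vectors, both non-empty.
#' @return list with `statistic` (rank-sum W of the first group), `pValue`,
#'   `exact` (logical) and `method`.
#' @export
wilcoxonRankSum <- function(a, b) {
    if (!length(a) || !length(b))
        stop("both groups must be non-empty", call. = FALSE)
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- min(length(a), length(b)) <= 12L && !ties
    ht <- suppressWarnings(
        wilcox.test(a, b, alternative = "two.sided", exact = exact,
                    correct = FALSE))
    list(statistic = unname(ht$statistic), pValue = ht$p.value,
         exact = exact,
         method = if (exact) "exact enumeration"
                  else "normal approximation, tie-corrected variance")
}
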