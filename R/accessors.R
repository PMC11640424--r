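#' @describeIn Thermogram-class sample identifier.
#' @param object,x a package object.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @export
setMethod("sampleId", "Thermogram", function(object) object@sampleId)

#' @describeIn Thermogram-class temperature vector (degC).
#' @export
setGeneric("temperatures", function(object) standardGeneric("temperatures"))

#' @export
setMethod("temperatures", "Thermogram", function(object) object@temperature)

#' @describeIn Thermogram-class excess heat capacity vector.
#' @export
setGeneric("heatCapacity", function(object) standardGeneric("heatCapacity"))

#' @export
setMethod("heatCapacity", "Thermogram", function(object) object@cp)

#' @describeIn ThermogramCohort-class sample identifiers in cohort order.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @export
setMethod("sampleIds", "ThermogramCohort", function(object)
    .cohortIds(object))

#' Class labels of a cohort or feature set
#'
#' Returns the per-sample class label vector (`"negative"`/`"positive"`,
#' `NA` for unlabeled samples), named by sample id.
#'
#' @param object a [ThermogramCohort-class] or [ThermogramFeatures-class].
#' @return named character vector.
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @export
setMethod("classLabels", "ThermogramCohort", function(object) {
    ids <- sampleIds(object)
    out <- setNames(rep(NA_character_, length(ids)), ids)
    out[names(object@classLabel)] <- object@classLabel
    out
})

#' @export
setMethod("classLabels", "ThermogramFeatures", function(object)
    setNames(object$classLabel, colnames(object)))

#' Diagnosis-confidence flags
#'
#' @param object a [ThermogramCohort-class] or [ThermogramFeatures-class].
#' @return named logical vector (`NA` when the flag was never supplied).
#' @export
setGeneric("confirmedFlags", function(object)
    standardGeneric("confirmedFlags"))

#' @export
setMethod("confirmedFlags", "ThermogramCohort", function(object) {
    ids <- sampleIds(object)
    out <- setNames(rep(NA, length(ids)), ids)
    out[names(object@confirmed)] <- object@confirmed
    out
})

#' @export
setMethod("confirmedFlags", "ThermogramFeatures", function(object)
    setNames(object$confirmed, colnames(object)))

#' @export
setMethod("length", "ThermogramCohort", function(x) length(x@thermograms))

#' @export
setMethod("[[", "ThermogramCohort", function(x, i, ...) {
    if (is.character(i)) {
        i <- match(i, sampleIds(x))
        if (is.na(i)) stop("unknown sample id")
    }
    x@thermograms[[i]]
})

#' @export
setMethod("[", "ThermogramCohort", function(x, i, ...) {
    ids <- sampleIds(x)
    if (is.character(i)) i <- match(i, ids)
    keep <- ids[i]
    ThermogramCohort(x@thermograms[i],
        classLabel = x@classLabel[intersect(names(x@classLabel), keep)],
        confirmed = x@confirmed[intersect(names(x@confirmed), keep)])
})

#' @describeIn GridSpec-class the uniform interpolation grid
#'   (tMin, tMin + dt, ..., tMax), generated by index arithmetic.
#' @export
setGeneric("uniformGrid", function(object) standardGeneric("uniformGrid"))

#' @export
setMethod("uniformGrid", "GridSpec", function(object)
    object@tMin + object@dt * seq.int(0L,
        round((object@tMax - object@tMin) / object@dt)))

#' @describeIn GridSpec-class the feature temperatures
#'   (featureLo, ..., featureHi).
#' @export
setGeneric("featureGrid", function(object) standardGeneric("featureGrid"))

#' @export
setMethod("featureGrid", "GridSpec", function(object)
    object@featureLo + object@featureStep * seq.int(0L,
        round((object@featureHi - object@featureLo) / object@featureStep)))

#' @describeIn TSPModel-class selected temperature pairs.
#' @export
setGeneric("modelPairs", function(object) standardGeneric("modelPairs"))

#' @export
setMethod("modelPairs", "TSPModel", function(object) object@pairs)

#' @export
setMethod("coef", "TSPModel", function(object, ...)
    c(`(Intercept)` = object@intercept,
      setNames(object@coefficients,
               if (nrow(object@pairs))
                   paste0("T", object@pairs$ti, ">T", object@pairs$tj)
               else character())))

#' @describeIn ConfusionSummary-class the five metrics as proportions.
#' @export
setGeneric("metricValues", function(object) standardGeneric("metricValues"))

#' @export
setMethod("metricValues", "ConfusionSummary", function(object) object@metrics)

#' Whole-percent display metrics
#'
#' Diagnostic metrics rounded to the nearest whole percent, the convention
#' used for reporting; internal values keep full precision.
#'
#' @param object a [ConfusionSummary-class].
#' @return named numeric vector of percentages (NA preserved).
#' @export
setGeneric("percentMetrics", function(object)
    standardGeneric("percentMetrics"))

#' @export
setMethod("percentMetrics", "ConfusionSummary", function(object)
    round(100 * object@metrics))

#' @describeIn ROCResult-class the AUC value.
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))

#' @export
setMethod("auc", "ROCResult", function(object) object@auc)

#' @describeIn ROCResult-class 95 percent bootstrap CI as c(lo, hi).
#' @export
setGeneric("aucCI", function(object) standardGeneric("aucCI"))

#' @export
setMethod("aucCI", "ROCResult", function(object)
    c(lower = object@ciLo, upper = object@ciHi))

setMethod("show", "Thermogram", function(object) {
    cat(sprintf("Thermogram '%s': %d points, %.2f--%.2f degC\n",
        object@sampleId, length(object@temperature),
        min(object@temperature), max(object@temperature)))
})

setMethod("show", "ThermogramCohort", function(object) {
    lab <- classLabels(object)
    cat(sprintf(
        "ThermogramCohort: %d samples (%d negative, %d positive, %d unlabeled)\n",
        length(object), sum(lab == "negative", na.rm = TRUE),
        sum(lab == "positive", na.rm = TRUE), sum(is.na(lab))))
    conf <- confirmedFlags(object)
    cat(sprintf("  confirmed diagnoses: %d\n", sum(conf, na.rm = TRUE)))
})

setMethod("show", "GridSpec", function(object) {
    cat(sprintf(
        "GridSpec: %.2f--%.2f degC (dt = %.2f); features %.0f--%.0f step %.2f (%d values)\n",
        object@tMin, object@tMax, object@dt, object@featureLo,
        object@featureHi, object@featureStep, length(featureGrid(object))))
})

setMethod("show", "TSPModel", function(object) {
    cat(sprintf(
        "TSPModel: %d temperature pair(s), lambda = %.4g, positive class = '%s'\n",
        nrow(object@pairs), object@lambda, object@positiveLabel))
    if (nrow(object@pairs)) {
        df <- data.frame(pair = paste0("Cp(", object@pairs$ti, ") > Cp(",
                                       object@pairs$tj, ")"),
                         coefficient = object@coefficients)
        print(df, row.names = FALSE)
    }
    cat(sprintf("  intercept = %.4f; score > 0 -> %s, score <= 0 -> %s\n",
        object@intercept, object@positiveLabel, object@negativeLabel))
})

setMethod("show", "ConfusionSummary", function(object) {
    cat(sprintf("ConfusionSummary: tp=%d fp=%d tn=%d fn=%d\n",
        object@tp, object@fp, object@tn, object@fn))
    pm <- percentMetrics(object)
    cat("  ", paste(sprintf("%s=%s%%", names(pm),
        ifelse(is.na(pm), "NA", pm)), collapse = " "), "\n", sep = "")
})

setMethod("show", "ROCResult", function(object) {
    cat(sprintf("ROCResult: AUC = %.3f (95%% CI %.3f--%.3f, %d bootstrap)\n",
        object@auc, object@ciLo, object@ciHi, object@nBoot))
})

setMethod("show", "CohortRecipe", function(object) {
    cat(sprintf(
        "CohortRecipe: %d/class, %d vs %d peaks, jitter sd %.2f degC, noise sd %.3g, seed %d\n",
        object@nPerClass, nrow(object@peaksClass0), nrow(object@peaksClass1),
        object@tmJitterSd, object@noiseSd, object@seed))
})
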