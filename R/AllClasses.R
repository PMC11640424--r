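#' @import methods
#' @importFrom stats approx rnorm rbinom runif quantile wilcox.test predict
#'   setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

## Central S4 containers for thermal liquid biopsy (TLB) analysis.
## A Thermogram is one sample's excess heat capacity curve Cp(T); a
## ThermogramCohort bundles curves with class labels and diagnosis-confidence
## flags; ThermogramFeatures holds the preprocessed per-degree feature matrix
## as a SummarizedExperiment (rows = grid temperatures, columns = samples).

#' Thermogram: a single DSC excess heat capacity curve
#'
#' Stores one sample's differential scanning calorimetry trace: temperatures
#' in degrees Celsius, excess heat capacity (arbitrary units, negative values
#' allowed before normalization) and free-form string metadata such as lesion
#' subtype.
#'
#' @slot sampleId single opaque sample identifier.
#' @slot temperature numeric, strictly increasing, length >= 2.
#' @slot cp numeric, same length as `temperature`.
#' @slot meta named list of character scalars.
#' @exportClass Thermogram
setClass("Thermogram",
    slots = c(
        sampleId = "character",
        temperature = "numeric",
        cp = "numeric",
        meta = "list"
    )
)

setValidity("Thermogram", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
        !nzchar(object@sampleId))
        msg <- c(msg, "sampleId must be a single non-empty string")
    nT <- length(object@temperature)
    if (nT < 2L)
        msg <- c(msg, "at least 2 temperature points required")
    if (length(object@cp) != nT)
        msg <- c(msg, "temperature and cp must have equal length")
    if (nT >= 1L && any(!is.finite(object@temperature)))
        msg <- c(msg, "temperatures must all be finite")
    if (length(object@cp) >= 1L && any(!is.finite(object@cp)))
        msg <- c(msg, "cp values must all be finite")
    if (nT >= 2L && any(diff(object@temperature) <= 0))
        msg <- c(msg, sprintf(
            "temperatures must be strictly increasing (sample '%s')",
            object@sampleId))
    if (length(msg)) msg else TRUE
})

#' Construct a Thermogram
#'
#' @param sampleId single sample identifier.
#' @param temperature strictly increasing numeric vector of temperatures (degC).
#' @param cp excess heat capacity values, same length as `temperature`.
#' @param meta named list of character metadata.
#' @return A [Thermogram-class] object.
#' @examples
#' tg <- Thermogram("s1", seq(40, 95, by = 0.5), rnorm(111))
#' @export
Thermogram <- function(sampleId, temperature, cp, meta = list()) {
    new("Thermogram", sampleId = as.character(sampleId),
        temperature = as.numeric(temperature), cp = as.numeric(cp),
        meta = meta)
}

#' ThermogramCohort: labeled thermogram collection
#'
#' A list of [Thermogram-class] objects plus per-sample binary class labels
#' (`"negative"` / `"positive"`) and a logical flag marking samples whose
#' diagnosis is confirmed (used for train/validation splitting).
#'
#' @slot thermograms list of Thermogram, unique sample ids.
#' @slot classLabel named character, values in negative/positive; names must
#'   be sample ids present in the cohort. Unlabeled samples are permitted.
#' @slot confirmed named logical, same naming rule.
#' @exportClass ThermogramCohort
setClass("ThermogramCohort",
    slots = c(
        thermograms = "list",
        classLabel = "character",
        confirmed = "logical"
    )
)

.cohortIds <- function(object)
    vapply(object@thermograms, function(t) t@sampleId, character(1))

setValidity("ThermogramCohort", function(object) {
    msg <- character()
    ok <- vapply(object@thermograms, is, logical(1), "Thermogram")
    if (!all(ok))
        msg <- c(msg, "thermograms must all be Thermogram objects")
    ids <- if (all(ok)) .cohortIds(object) else character()
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate sample ids: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    badLab <- setdiff(names(object@classLabel), ids)
    if (length(badLab))
        msg <- c(msg, sprintf("label given for unknown sample(s): %s",
            paste(badLab, collapse = ", ")))
    if (length(object@classLabel) &&
        !all(object@classLabel %in% c("negative", "positive")))
        msg <- c(msg, "class labels must be 'negative' or 'positive'")
    badConf <- setdiff(names(object@confirmed), ids)
    if (length(badConf))
        msg <- c(msg, sprintf("confirmed flag for unknown sample(s): %s",
            paste(badConf, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a ThermogramCohort
#'
#' @param thermograms list of [Thermogram-class] objects.
#' @param classLabel named character vector (`"negative"`/`"positive"`),
#'   names are sample ids.
#' @param confirmed named logical vector of diagnosis-confidence flags.
#' @return A [ThermogramCohort-class].
#' @export
ThermogramCohort <- function(thermograms, classLabel = character(),
                             confirmed = logical()) {
    new("ThermogramCohort", thermograms = unname(thermograms),
        classLabel = classLabel, confirmed = confirmed)
}

#' GridSpec: uniform temperature grid and feature window
#'
#' Defines the preprocessing grid: thermograms are interpolated to a uniform
#' grid from `tMin` to `tMax` in steps of `dt`, then features are the
#' normalized heat-capacity values sampled every `featureStep` degrees from
#' `featureLo` to `featureHi`. Defaults give a 0.25 degC grid on 40--95 degC
#' and 31 per-degree features on 55--85 degC, the window where biofluid
#' denaturation profiles change most between diagnostic groups.
#'
#' @slot tMin,tMax retained temperature span (degC).
#' @slot dt uniform grid step (degC).
#' @slot featureLo,featureHi feature window (degC).
#' @slot featureStep feature sampling step (degC), integer multiple of `dt`.
#' @exportClass GridSpec
setClass("GridSpec",
    slots = c(
        tMin = "numeric", tMax = "numeric", dt = "numeric",
        featureLo = "numeric", featureHi = "numeric", featureStep = "numeric"
    )
)

setValidity("GridSpec", function(object) {
    msg <- character()
    g <- object
    if (!(g@tMin < g@featureLo && g@featureLo < g@featureHi &&
          g@featureHi <= g@tMax))
        msg <- c(msg, "need tMin < featureLo < featureHi <= tMax")
    if (g@dt <= 0)
        msg <- c(msg, "dt must be positive")
    if (g@dt > 0) {
        r <- g@featureStep / g@dt
        if (abs(r - round(r)) > 1e-9)
            msg <- c(msg, "featureStep must be an integer multiple of dt")
        n <- (g@tMax - g@tMin) / g@dt
        if (abs(n - round(n)) > 1e-9)
            msg <- c(msg, "(tMax - tMin)/dt must be integral")
        m <- (g@featureHi - g@featureLo) / g@featureStep
        if (abs(m - round(m)) > 1e-9)
            msg <- c(msg, "(featureHi - featureLo)/featureStep must be integral")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname GridSpec-class
#' @param tMin,tMax,dt,featureLo,featureHi,featureStep see slots.
#' @return `GridSpec()` returns a [GridSpec-class] object.
#' @examples
#' g <- GridSpec()
#' length(featureGrid(g))  # 31
#' @export
GridSpec <- function(tMin = 40, tMax = 95, dt = 0.25,
                     featureLo = 55, featureHi = 85, featureStep = 1) {
    new("GridSpec", tMin = tMin, tMax = tMax, dt = dt,
        featureLo = featureLo, featureHi = featureHi,
        featureStep = featureStep)
}

#' ThermogramFeatures: preprocessed per-degree feature matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose single assay
#' `"cp"` holds area-normalized heat capacity values on the feature grid
#' (rows = grid temperatures, columns = samples); `colData` carries
#' `classLabel` and `confirmed`; `metadata(x)$gridSpec` records the grid.
#'
#' @exportClass ThermogramFeatures
setClass("ThermogramFeatures", contains = "SummarizedExperiment")

#' TSPModel: penalized logistic model over temperature-pair indicators
#'
#' The fitted classifier: a set of temperature pairs (Ti, Tj), a logistic
#' intercept and one coefficient per pair applied to the binary ordering
#' indicator I(cp(Ti) > cp(Tj)). The decision rule is by sign of the score:
#' strictly positive scores map to `positiveLabel`, zero or negative scores
#' to `negativeLabel`.
#'
#' @slot pairs data.frame with columns ti, tj, scorePrimary, scoreSecondary.
#' @slot intercept,coefficients penalized logistic solution (no refit).
#' @slot lambda selected L1 penalty.
#' @slot positiveLabel,negativeLabel class label mapping.
#' @slot cvFolds,seed cross-validation settings used at fit time.
#' @slot gridHash character key of the feature grid the model expects.
#' @exportClass TSPModel
setClass("TSPModel",
    slots = c(
        pairs = "data.frame",
        intercept = "numeric",
        coefficients = "numeric",
        lambda = "numeric",
        positiveLabel = "character",
        negativeLabel = "character",
        cvFolds = "integer",
        seed = "integer",
        gridHash = "character"
    )
)

setValidity("TSPModel", function(object) {
    msg <- character()
    if (nrow(object@pairs) != length(object@coefficients))
        msg <- c(msg, "one coefficient per pair required")
    if (length(object@lambda) != 1L || object@lambda < 0)
        msg <- c(msg, "lambda must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' PairIndicators: binary ordering-indicator matrix
#'
#' @slot indicators numeric 0/1 matrix, rows = samples, one column per pair.
#' @slot pairs data.frame of the pairs (columns ti, tj, ...).
#' @exportClass PairIndicators
setClass("PairIndicators",
    slots = c(indicators = "matrix", pairs = "data.frame"))

setValidity("PairIndicators", function(object) {
    msg <- character()
    if (ncol(object@indicators) != nrow(object@pairs))
        msg <- c(msg, "column count must equal number of pairs")
    v <- object@indicators
    if (length(v) && !all(v %in% c(0, 1)))
        msg <- c(msg, "indicator entries must be 0 or 1")
    if (length(msg)) msg else TRUE
})

#' ConfusionSummary: 2x2 diagnostic counts and derived metrics
#'
#' Undefined ratios (zero denominator) are reported as `NA`, never as 0.
#'
#' @slot tp,fp,tn,fn integer counts.
#' @slot metrics named numeric: sensitivity, specificity, ppv, npv, accuracy
#'   as proportions in \[0, 1\] (or NA).
#' @exportClass ConfusionSummary
setClass("ConfusionSummary",
    slots = c(tp = "integer", fp = "integer", tn = "integer", fn = "integer",
              metrics = "numeric"))

#' ROCResult: AUC with bootstrap confidence interval and curve points
#'
#' @slot auc area under the ROC curve (Mann-Whitney normalization, ties 1/2).
#' @slot ciLo,ciHi stratified bootstrap percentile 95 percent interval.
#' @slot curve data.frame with threshold, fpr, tpr (from (0,0) to (1,1)).
#' @slot nBoot,seed bootstrap settings.
#' @exportClass ROCResult
setClass("ROCResult",
    slots = c(auc = "numeric", ciLo = "numeric", ciHi = "numeric",
              curve = "data.frame", nBoot = "integer", seed = "integer"))

setValidity("ROCResult", function(object) {
    msg <- character()
    if (!(object@ciLo <= object@auc + 1e-12 &&
          object@auc <= object@ciHi + 1e-12))
        msg <- c(msg, "need ciLo <= auc <= ciHi")
    if (length(msg)) msg else TRUE
})

#' CohortRecipe: parameters for the synthetic thermogram generator
#'
#' Each simulated curve is a sum of Gaussian denaturation transitions plus a
#' linear baseline drift and white measurement noise; the two classes differ
#' through their peak sets. See [generateCohort()].
#'
#' @slot nPerClass samples per class.
#' @slot peaksClass0,peaksClass1 data.frames with columns tm (degC),
#'   width (Gaussian sigma, degC), amplitude (a.u., > 0).
#' @slot tmJitterSd per-sample peak-position jitter SD (degC).
#' @slot ampJitterCv per-sample multiplicative amplitude jitter CV.
#' @slot baselineSlope linear drift (a.u./degC).
#' @slot noiseSd additive Gaussian noise SD (a.u.).
#' @slot rawGridStep raw sampling step (degC); deliberately not equal to the
#'   0.25 degC analysis grid so interpolation is always exercised.
#' @slot confirmedFraction fraction of each class flagged as confirmed
#'   diagnoses (training split); remainder acts as a held-out validation set.
#' @slot seed RNG seed for the cohort.
#' @exportClass CohortRecipe
setClass("CohortRecipe",
    slots = c(
        nPerClass = "integer",
        peaksClass0 = "data.frame",
        peaksClass1 = "data.frame",
        tmJitterSd = "numeric",
        ampJitterCv = "numeric",
        baselineSlope = "numeric",
        noiseSd = "numeric",
        rawGridStep = "numeric",
        confirmedFraction = "numeric",
        seed = "integer"
    )
)

.validPeaks <- function(p) {
    all(c("tm", "width", "amplitude") %in% names(p)) &&
        all(p$width > 0) && all(p$amplitude > 0) &&
        all(p$tm > 40 & p$tm < 95)
}

setValidity("CohortRecipe", function(object) {
    msg <- character()
    if (object@nPerClass < 1L)
        msg <- c(msg, "nPerClass must be >= 1")
    if (!.validPeaks(object@peaksClass0) || !.validPeaks(object@peaksClass1))
        msg <- c(msg,
            "peaks need columns tm/width/amplitude with width > 0, amplitude > 0, 40 < tm < 95")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be >= 0")
    if (object@rawGridStep <= 0)
        msg <- c(msg, "rawGridStep must be > 0")
    if (object@confirmedFraction <= 0 || object@confirmedFraction > 1)
        msg <- c(msg, "confirmedFraction must be in (0, 1]")
    if (length(msg)) msg else TRUE
})
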