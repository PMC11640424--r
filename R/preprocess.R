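## Preprocessing of raw DSC traces into model features.
##
## Pipeline per sample: linear baseline correction through pre/post
## transition windows -> piecewise-linear interpolation onto the uniform
## 0.25 degC grid over 40--95 degC -> area normalization (unit trapezoidal
## integral over the retained span) -> per-degree sub-sampling on the
## 55--85 degC feature window. Area normalization removes the amplitude
## scale, so downstream features are dimensionless shape descriptors.

.windowIdx <- function(tg, window, what) {
    if (length(window) != 2L || window[2L] <= window[1L])
        stop(sprintf("%s window must be an increasing (lo, hi) pair", what),
             call. = FALSE)
    t <- tg@temperature
    if (window[1L] < min(t) - 1e-9 || window[2L] > max(t) + 1e-9)
        stop(sprintf(
            "%s window (%g, %g) outside data span (%g, %g) of sample '%s'",
            what, window[1L], window[2L], min(t), max(t), tg@sampleId),
            call. = FALSE)
    idx <- which(t >= window[1L] - 1e-9 & t <= window[2L] + 1e-9)
    if (length(idx) < 2L)
        stop(sprintf("%s window contains fewer than 2 points", what),
             call. = FALSE)
    idx
}

#' Linear baseline correction
#'
#' Fits a straight line through the mean (temperature, cp) point of a
#' pre-transition window and of a post-transition window, and subtracts it
#' pointwise. On a signal that is exactly linear, the corrected curve is
#' identically zero.
#'
#' @param tg a [Thermogram-class].
#' @param preWindow,postWindow `(lo, hi)` temperature windows (degC) inside
#'   the data span, each containing at least two points. Defaults
#'   `(40, 45)` and `(90, 95)`.
#' @return The corrected [Thermogram-class] on the same temperature grid.
#' @export
baselineCorrect <- function(tg, preWindow = c(40, 45),
                            postWindow = c(90, 95)) {
    stopifnot(is(tg, "Thermogram"))
    i1 <- .windowIdx(tg, preWindow, "pre-transition")
    i2 <- .windowIdx(tg, postWindow, "post-transition")
    x1 <- mean(tg@temperature[i1]); y1 <- mean(tg@cp[i1])
    x2 <- mean(tg@temperature[i2]); y2 <- mean(tg@cp[i2])
    slope <- (y2 - y1) / (x2 - x1)
    baseline <- y1 + slope * (tg@temperature - x1)
    Thermogram(tg@sampleId, tg@temperature, tg@cp - baseline, tg@meta)
}

#' Interpolate a thermogram onto the uniform analysis grid
#'
#' Piecewise-linear interpolation onto `uniformGrid(grid)`. The thermogram
#' must cover the grid span (endpoints within one raw step); at input knots
#' the interpolant reproduces the input exactly.
#'
#' @param tg a [Thermogram-class].
#' @param grid a [GridSpec-class].
#' @return A [Thermogram-class] on the uniform grid.
#' @export
interpolateGrid <- function(tg, grid = GridSpec()) {
    stopifnot(is(tg, "Thermogram"), is(grid, "GridSpec"))
    t <- tg@temperature
    rawStep <- max(diff(t))
    if (min(t) > grid@tMin + rawStep + 1e-9 ||
        max(t) < grid@tMax - rawStep - 1e-9)
        stop(sprintf(
            "sample '%s' spans %.2f--%.2f degC and does not cover the grid %g--%g degC",
            tg@sampleId, min(t), max(t), grid@tMin, grid@tMax),
            call. = FALSE)
    xout <- uniformGrid(grid)
    # rule = 2 tolerates sub-raw-step shortfall at the extremes
    yout <- approx(t, tg@cp, xout = xout, method = "linear", rule = 2,
                   ties = "ordered")$y
    Thermogram(tg@sampleId, xout, yout, tg@meta)
}

#' Area-normalize a thermogram
#'
#' Divides the curve by its trapezoidal integral over the full retained
#' span, so that the integral of the result is exactly 1. Performed before
#' truncation to the feature window, hence over 40--95 degC by default.
#'
#' @param tg a [Thermogram-class].
#' @return The normalized [Thermogram-class].
#' @export
areaNormalize <- function(tg) {
    stopifnot(is(tg, "Thermogram"))
    a <- trapezoidArea(tg@temperature, tg@cp)
    if (!is.finite(a) || a <= 0)
        stop(sprintf(
            "sample '%s': non-positive area (%.4g); thermogram unusable for normalization",
            tg@sampleId, a), call. = FALSE)
    Thermogram(tg@sampleId, tg@temperature, tg@cp / a, tg@meta)
}

#' Extract the per-degree feature values
#'
#' Samples the (already gridded) thermogram at the feature temperatures
#' `featureGrid(grid)` (default 55, 56, ..., 85 degC; 31 values).
#'
#' @param tg a [Thermogram-class] on the uniform grid of `grid`.
#' @param grid a [GridSpec-class].
#' @return named numeric vector, names are the feature temperatures.
#' @export
extractFeatures <- function(tg, grid = GridSpec()) {
    stopifnot(is(tg, "Thermogram"), is(grid, "GridSpec"))
    ft <- featureGrid(grid)
    idx <- matchTemperature(ft, tg@temperature)
    if (anyNA(idx))
        stop(sprintf(
            "sample '%s': feature temperature(s) %s absent from grid",
            tg@sampleId, paste(ft[is.na(idx)], collapse = ", ")),
            call. = FALSE)
    setNames(tg@cp[idx], format(ft))
}

.prepareOne <- function(tg, grid, preWindow, postWindow) {
    tg <- baselineCorrect(tg, preWindow, postWindow)
    tg <- interpolateGrid(tg, grid)
    tg <- areaNormalize(tg)
    extractFeatures(tg, grid)
}

#' Prepare model features from raw thermograms
#'
#' Runs the full preprocessing composition (baseline correction,
#' interpolation, restriction to the retained span, area normalization,
#' per-degree extraction). Deterministic; invariant to positive rescaling
#' of the input curve.
#'
#' @param x a [Thermogram-class] or [ThermogramCohort-class].
#' @param grid a [GridSpec-class].
#' @param preWindow,postWindow baseline windows, see [baselineCorrect()].
#' @return For a single thermogram, a named numeric feature vector; for a
#'   cohort, a [ThermogramFeatures-class] with one column per sample and
#'   the cohort's labels and confirmed flags in `colData`.
#' @examples
#' cohort <- generateCohort(defaultRecipes()[["shifted-peak"]])
#' fx <- prepareFeatures(cohort)
#' dim(fx)  # 31 x 40
#' @export
setGeneric("prepareFeatures", function(x, grid = GridSpec(),
                                       preWindow = c(40, 45),
                                       postWindow = c(90, 95))
    standardGeneric("prepareFeatures"))

#' @export
setMethod("prepareFeatures", "Thermogram",
    function(x, grid, preWindow, postWindow)
        .prepareOne(x, grid, preWindow, postWindow))

#' @export
setMethod("prepareFeatures", "ThermogramCohort",
    function(x, grid, preWindow, postWindow) {
        ids <- sampleIds(x)
        vals <- vapply(x@thermograms,
            function(tg) .prepareOne(tg, grid, preWindow, postWindow),
            numeric(length(featureGrid(grid))))
        mat <- matrix(vals, nrow = length(featureGrid(grid)),
                      dimnames = list(format(featureGrid(grid)), ids))
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(cp = mat),
            rowData = S4Vectors::DataFrame(temperature = featureGrid(grid)),
            colData = S4Vectors::DataFrame(
                classLabel = unname(classLabels(x)[ids]),
                confirmed = unname(confirmedFlags(x)[ids]),
                row.names = ids),
            metadata = list(gridSpec = grid, gridHash = gridHash(grid)))
        new("ThermogramFeatures", se)
    })

#' Feature matrix in samples-by-temperatures orientation
#'
#' @param fx a [ThermogramFeatures-class].
#' @return numeric matrix, rows = samples, columns = feature temperatures.
#' @export
featureMatrix <- function(fx) {
    stopifnot(is(fx, "ThermogramFeatures"))
    t(SummarizedExperiment::assay(fx, "cp"))
}
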