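## Synthetic thermogram cohorts.
##
## Real biofluid thermograms are envelopes of several overlapping
## denaturation transitions riding on an instrument baseline. The generator
## emulates that structure with sums of Gaussian peaks (analytically
## tractable means and areas), linear baseline drift, per-sample jitter of
## peak positions and amplitudes, and white measurement noise. Class
## structure enters only through the two peak sets, so a recipe controls
## exactly how (and whether) the classes differ.

#' Describe a set of denaturation transitions
#'
#' @param tm transition midpoints (degC, inside (40, 95)).
#' @param width Gaussian sigma per peak (degC).
#' @param amplitude peak heights (a.u., positive).
#' @return data.frame with columns tm, width, amplitude.
#' @export
peakSet <- function(tm, width, amplitude)
    data.frame(tm = tm, width = width, amplitude = amplitude)

#' Construct a synthetic-cohort recipe
#'
#' @param peaksClass0,peaksClass1 peak sets (see [peakSet()]) for the
#'   negative and positive class.
#' @param nPerClass samples per class (default 20).
#' @param tmJitterSd per-sample SD of peak-position jitter (degC).
#' @param ampJitterCv CV of the multiplicative per-sample amplitude jitter
#'   (truncated positive normal).
#' @param baselineSlope linear baseline drift (a.u./degC).
#' @param noiseSd additive Gaussian noise SD (a.u.).
#' @param rawGridStep raw sampling step (degC); the default 0.1 differs
#'   from the 0.25 analysis grid on purpose so interpolation is exercised.
#' @param confirmedFraction fraction of each class flagged confirmed
#'   (default 0.63, the typical share of pathologically confirmed diagnoses
#'   in pancreatic-cyst cohorts).
#' @param seed cohort RNG seed.
#' @return A [CohortRecipe-class].
#' @export
cohortRecipe <- function(peaksClass0, peaksClass1 = peaksClass0,
                         nPerClass = 20L, tmJitterSd = 0.5,
                         ampJitterCv = 0.1, baselineSlope = 0.002,
                         noiseSd = 0.02, rawGridStep = 0.1,
                         confirmedFraction = 0.63, seed = 1L) {
    new("CohortRecipe", nPerClass = as.integer(nPerClass),
        peaksClass0 = peaksClass0, peaksClass1 = peaksClass1,
        tmJitterSd = tmJitterSd, ampJitterCv = ampJitterCv,
        baselineSlope = baselineSlope, noiseSd = noiseSd,
        rawGridStep = rawGridStep, confirmedFraction = confirmedFraction,
        seed = as.integer(seed))
}

# Noiseless class-mean curve (no jitter): sum of the recipe's Gaussians
# plus baseline drift, evaluated at t.
.meanCurve <- function(peaks, t, baselineSlope = 0) {
    y <- rep(0, length(t))
    for (m in seq_len(nrow(peaks)))
        y <- y + peaks$amplitude[m] *
            exp(-(t - peaks$tm[m])^2 / (2 * peaks$width[m]^2))
    y + baselineSlope * (t - 40)
}

.truncatedPositive <- function(meanv, sdv) {
    if (sdv == 0) return(meanv)
    for (i in 1:100) {
        v <- rnorm(1, meanv, sdv)
        if (v > 0) return(v)
    }
    stop("amplitude jitter failed to draw a positive value")
}

#' Generate a labeled synthetic cohort
#'
#' Each sample's curve is
#' `cp(T) = sum_m A_m * f_m * exp(-(T - (Tm_m + e_m))^2 / (2 sigma_m^2)) +
#' slope * (T - 40) + noise`, with per-sample, per-peak position jitter
#' `e_m ~ N(0, tmJitterSd^2)`, amplitude factor `f_m ~ N(1, ampJitterCv^2)`
#' truncated positive, and white noise. Class 0 samples (ids `N...`) are
#' labeled `"negative"`, class 1 (`P...`) `"positive"`. A seeded random
#' subset of each class (size `round(confirmedFraction * n)`, at least 2)
#' is flagged confirmed. Deterministic given the recipe seed.
#'
#' @param recipe a [CohortRecipe-class].
#' @return A [ThermogramCohort-class] spanning 40--95 degC.
#' @examples
#' cohort <- generateCohort(defaultRecipes()[["null"]])
#' length(cohort)  # 40
#' @export
generateCohort <- function(recipe) {
    stopifnot(is(recipe, "CohortRecipe"))
    validObject(recipe)
    t <- 40 + recipe@rawGridStep *
        seq.int(0L, round(55 / recipe@rawGridStep))
    n <- recipe@nPerClass

    withSeed(recipe@seed, {
        tgs <- list()
        labs <- character()
        conf <- logical()
        for (cls in 0:1) {
            peaks <- if (cls == 0) recipe@peaksClass0 else recipe@peaksClass1
            prefix <- if (cls == 0) "N" else "P"
            label <- if (cls == 0) "negative" else "positive"
            nConf <- if (recipe@confirmedFraction >= 1) n else
                min(n, max(2L, round(recipe@confirmedFraction * n)))
            confIdx <- if (nConf >= n) seq_len(n) else
                sort(sample(n, nConf))
            for (i in seq_len(n)) {
                cp <- recipe@baselineSlope * (t - 40)
                for (m in seq_len(nrow(peaks))) {
                    tm <- peaks$tm[m] + rnorm(1, 0, recipe@tmJitterSd)
                    amp <- peaks$amplitude[m] *
                        .truncatedPositive(1, recipe@ampJitterCv)
                    cp <- cp + amp * exp(-(t - tm)^2 /
                                         (2 * peaks$width[m]^2))
                }
                if (recipe@noiseSd > 0)
                    cp <- cp + rnorm(length(t), 0, recipe@noiseSd)
                id <- sprintf("%s%03d", prefix, i)
                tgs[[length(tgs) + 1L]] <- Thermogram(id, t, cp,
                    meta = list(class = label,
                                seed = as.character(recipe@seed)))
                labs[id] <- label
                conf[id] <- i %in% confIdx
            }
        }
        ThermogramCohort(tgs, classLabel = labs, confirmed = conf)
    })
}

#' Reference synthetic recipes
#'
#' Three named study conditions:
#' \describe{
#'   \item{null}{identical single-peak classes; no signal by construction,
#'     used to check that the pipeline does not invent separation.}
#'   \item{shifted-peak}{the positive class's single transition midpoint is
#'     shifted +4 degC (68 vs 72 degC); the pair-recovery benchmark.}
#'   \item{envelope}{three transitions near 62/70/77 degC with the
#'     amplitude redistributed toward the high-temperature transition in
#'     the positive class, loosely mimicking multi-transition biofluid
#'     envelopes.}
#' }
#'
#' @param seed seed stored in each recipe.
#' @return named list of [CohortRecipe-class] objects.
#' @export
defaultRecipes <- function(seed = 1L) {
    list(
        "null" = cohortRecipe(
            peakSet(70, 4, 1), nPerClass = 20L, seed = seed),
        "shifted-peak" = cohortRecipe(
            peaksClass0 = peakSet(68, 4, 1),
            peaksClass1 = peakSet(72, 4, 1),
            nPerClass = 20L, seed = seed),
        "envelope" = cohortRecipe(
            peaksClass0 = peakSet(c(62, 70, 77), c(3, 3.5, 3),
                                  c(0.9, 1.0, 0.55)),
            peaksClass1 = peakSet(c(62, 70, 77), c(3, 3.5, 3),
                                  c(0.5, 0.9, 1.0)),
            nPerClass = 20L, tmJitterSd = 0.3, ampJitterCv = 0.15,
            seed = seed))
}
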