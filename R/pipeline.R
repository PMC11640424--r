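## End-to-end orchestration: split -> preprocess -> pair selection ->
## penalized fit -> scoring -> evaluation, with reproducible artifacts.

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Assemble a run configuration
#'
#' All tunables of the pipeline in one plain list; round-trips losslessly
#' through YAML via [writeRunConfig()] / [readRunConfig()].
#'
#' Two presets select the training split: `"itlb1"` trains on confirmed
#' diagnoses and keeps the high-probability remainder as a validation set;
#' `"itlb2"` trains on all labeled samples (no held-out validation),
#' the appropriate choice when the cohort is too small to split.
#'
#' @param preset `"itlb1"` or `"itlb2"`.
#' @param tMin,tMax,dt,featureLo,featureHi,featureStep see
#'   [GridSpec-class].
#' @param preWindow,postWindow baseline windows (degC).
#' @param kMax,disjoint pair-selection settings, see [ktspSelect()].
#' @param cvFolds,lambdaRule penalized-fit settings, see [fitTSPModel()].
#'   The pipeline default is leave-one-out (`"loo"`): at cohorts of a few
#'   dozen samples, k-fold deviance estimates are dominated by fold noise,
#'   and leave-one-out is in addition deterministic.
#' @param nBoot bootstrap replicates for the AUC interval.
#' @param seed seed for fold assignment and the bootstrap.
#' @return named list of class `tlbRunConfig`.
#' @export
runConfig <- function(preset = c("itlb1", "itlb2"),
                      tMin = 40, tMax = 95, dt = 0.25,
                      featureLo = 55, featureHi = 85, featureStep = 1,
                      preWindow = c(40, 45), postWindow = c(90, 95),
                      kMax = 10L, disjoint = TRUE, cvFolds = "loo",
                      lambdaRule = "min", nBoot = 2000L, seed = 1L) {
    preset <- match.arg(preset)
    structure(list(preset = preset, tMin = tMin, tMax = tMax, dt = dt,
        featureLo = featureLo, featureHi = featureHi,
        featureStep = featureStep, preWindow = preWindow,
        postWindow = postWindow, kMax = kMax, disjoint = disjoint,
        cvFolds = cvFolds, lambdaRule = lambdaRule, nBoot = nBoot,
        seed = seed), class = "tlbRunConfig")
}

#' @rdname runConfig
#' @param config a `tlbRunConfig`.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    base <- runConfig()
    known <- intersect(names(raw), names(base))
    base[known] <- raw[known]
    base$preset <- match.arg(base$preset, c("itlb1", "itlb2"))
    base
}

.configGrid <- function(config)
    GridSpec(config$tMin, config$tMax, config$dt,
             config$featureLo, config$featureHi, config$featureStep)

.configKey <- function(config)
    paste(vapply(unclass(config), function(v)
        paste(format(v), collapse = ","), character(1)),
        collapse = "|")

.labeledOnly <- function(cohort) {
    lab <- classLabels(cohort)
    cohort[which(!is.na(lab))]
}

#' Train a thermogram classifier end to end
#'
#' Splits the cohort according to the preset, preprocesses every sample,
#' selects top-scoring temperature pairs on the training set, fits the
#' penalized logistic model, scores training and validation samples, and
#' evaluates training performance (confusion metrics, ROC/AUC with
#' bootstrap CI, Wilcoxon rank-sum comparison of the two classes' scores).
#'
#' @param cohort a labeled [ThermogramCohort-class].
#' @param config a [runConfig()] list.
#' @param outDir optional directory; when given, writes `model.json`,
#'   `scores.csv`, `metrics.json` and `run.log`.
#' @return list with elements `model` ([TSPModel-class]), `training` and
#'   `validation` score tables, `confusion` ([ConfusionSummary-class]),
#'   `roc` ([ROCResult-class]), `wilcoxon` (list), and `configKey`.
#' @examples
#' cohort <- generateCohort(defaultRecipes()[["shifted-peak"]])
#' res <- runTrain(cohort, runConfig(nBoot = 200))
#' res$model
#' auc(res$roc)
#' @export
runTrain <- function(cohort, config = runConfig(), outDir = NULL) {
    stopifnot(is(cohort, "ThermogramCohort"))
    grid <- .configGrid(config)

    split <- .stage("split", {
        if (config$preset == "itlb1") {
            s <- trainValidateSplit(.labeledOnly(cohort))
        } else {
            s <- list(training = .labeledOnly(cohort),
                      validation = ThermogramCohort(list()))
        }
        if (length(s$training) < 4L)
            stop("training split too small to fit a model")
        s
    })

    fxTrain <- .stage("prepare", prepareFeatures(split$training, grid,
        config$preWindow, config$postWindow))
    fxVal <- .stage("prepare", prepareFeatures(split$validation, grid,
        config$preWindow, config$postWindow))

    pairs <- .stage("ktsp", ktspSelect(fxTrain, kMax = config$kMax,
        disjoint = config$disjoint))
    model <- .stage("fit", {
        pm <- indicatorMatrix(fxTrain, pairs)
        fitTSPModel(pm, classLabels(fxTrain), cvFolds = config$cvFolds,
            seed = config$seed, lambdaRule = config$lambdaRule,
            gridHash = gridHash(grid))
    })

    trainTab <- .stage("score",
        scoreTable(model, fxTrain, classLabels(fxTrain)))
    valTab <- .stage("score", if (length(split$validation))
        scoreTable(model, fxVal, classLabels(fxVal))
        else trainTab[0, ])

    confusion <- .stage("evaluate", confusionMetrics(trainTab))
    roc <- .stage("evaluate", rocAUC(trainTab, nBoot = config$nBoot,
        seed = config$seed))
    wrs <- .stage("evaluate", wilcoxonRankSum(
        trainTab$score[trainTab$truth == "negative"],
        trainTab$score[trainTab$truth == "positive"]))

    out <- list(model = model, training = trainTab, validation = valTab,
                confusion = confusion, roc = roc, wilcoxon = wrs,
                configKey = .configKey(config))
    if (!is.null(outDir)) .writeRunArtifacts(out, config, outDir)
    out
}

.writeRunArtifacts <- function(res, config, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeTSPModel(res$model, file.path(outDir, "model.json"))
    scores <- rbind(
        cbind(res$training, split = "training"),
        if (nrow(res$validation))
            cbind(res$validation, split = "validation"))
    write.csv(scores, file.path(outDir, "scores.csv"), row.names = FALSE)
    cs <- res$confusion
    metrics <- list(
        configKey = res$configKey,
        version = as.character(packageVersion("thermoTLB")),
        counts = list(tp = cs@tp, fp = cs@fp, tn = cs@tn, fn = cs@fn),
        metrics = as.list(metricValues(cs)),
        percent = as.list(percentMetrics(cs)),
        auc = auc(res$roc),
        auc_ci = as.list(aucCI(res$roc)),
        wilcoxon_p = res$wilcoxon$pValue)
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
        auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(c(
        sprintf("thermoTLB %s", packageVersion("thermoTLB")),
        sprintf("configKey: %s", res$configKey),
        sprintf("seed: %s", config$seed),
        sprintf("model pairs: %d", nrow(modelPairs(res$model)))),
        file.path(outDir, "run.log"))
    invisible(NULL)
}

#' Score a cohort with a previously fitted model
#'
#' Applies a fitted model to new thermograms without refitting. The model's
#' stored grid key must match the configured preprocessing grid; scoring on
#' a different feature grid is refused.
#'
#' @param model a [TSPModel-class] or path to a model JSON file.
#' @param cohort a [ThermogramCohort-class].
#' @param config a [runConfig()] list (grid and baseline windows are used).
#' @return score table data.frame (empty for an empty cohort).
#' @export
runPredict <- function(model, cohort, config = runConfig()) {
    if (is.character(model)) model <- readTSPModel(model)
    stopifnot(is(model, "TSPModel"), is(cohort, "ThermogramCohort"))
    grid <- .configGrid(config)
    if (nzchar(model@gridHash) &&
        !identical(model@gridHash, gridHash(grid)))
        stop(sprintf(
            "grid mismatch: model expects %s, config gives %s",
            model@gridHash, gridHash(grid)), call. = FALSE)
    if (!length(cohort))
        return(data.frame(sample_id = character(), score = numeric(),
                          predicted = character(), truth = character(),
                          stringsAsFactors = FALSE))
    fx <- .stage("prepare", prepareFeatures(cohort, grid,
        config$preWindow, config$postWindow))
    scoreTable(model, fx, classLabels(cohort))
}
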