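# Penalized logistic fitting, scoring, the sign decision rule, and the
# confirmed/high-probability split.

makePairs <- function(k) data.frame(ti = 70 + seq_len(k), tj = 55 + seq_len(k),
                                    scorePrimary = 1, scoreSecondary = 0)

test_that("a separating indicator is kept with a positive coefficient", {
    ind <- matrix(rep(c(0, 1), each = 6), ncol = 1,
                  dimnames = list(sprintf("s%d", 1:12), "T71>T56"))
    y <- rep(c("negative", "positive"), each = 6)
    model <- fitTSPModel(ind, y, pairs = makePairs(1), seed = 4)
    expect_equal(nrow(modelPairs(model)), 1L)
    expect_gt(model@coefficients[1], 0)
    fx <- asFeatures(matrix(c(rep(0, 6), rep(1, 6), rep(0.5, 12)),
        ncol = 2, dimnames = list(sprintf("s%d", 1:12), c("71", "56"))), y)
    expect_identical(unname(tspClassify(model, fx)), y)
})

test_that("full shrinkage leaves the class-prevalence intercept", {
    set.seed(8)
    ind <- matrix(rbinom(24, 1, 0.5), ncol = 2)
    colnames(ind) <- c("T71>T56", "T72>T57")
    y <- rep(c("negative", "positive"), times = c(4, 8))
    model <- fitTSPModel(ind, y, pairs = makePairs(2), lambda = 5)
    expect_equal(nrow(modelPairs(model)), 0L)
    expect_equal(model@intercept, qlogis(8 / 12), tolerance = 1e-6)
})

test_that("fixed-penalty coefficients match the grid-search oracle", {
    ind <- matrix(c(0, 0, 0, 1, 1, 1,
                    0, 1, 0, 1, 1, 0), ncol = 2,
                  dimnames = list(sprintf("s%d", 1:6),
                                  c("T71>T56", "T72>T57")))
    y <- c("negative", "negative", "negative",
           "positive", "positive", "positive")
    model <- fitTSPModel(ind, y, pairs = makePairs(2), lambda = 0.1)
    oracle <- lassoGridOracle(ind, as.numeric(y == "positive"), 0.1)
    beta <- setNames(rep(0, 2), colnames(ind))
    kept <- paste0("T", modelPairs(model)$ti, ">T", modelPairs(model)$tj)
    if (length(kept)) beta[kept] <- model@coefficients
    expect_equal(unname(beta), oracle$beta, tolerance = 5e-3)
    expect_equal(model@intercept, oracle$intercept, tolerance = 5e-3)
    expect_gt(model@coefficients[1], 0)  # the separating pair survives
})

test_that("scores are the penalized linear predictor of the indicators", {
    model <- new("TSPModel",
        pairs = data.frame(ti = 70, tj = 60, scorePrimary = 1,
                           scoreSecondary = 0),
        intercept = 0, coefficients = 2, lambda = 0.05,
        positiveLabel = "positive", negativeLabel = "negative",
        cvFolds = 5L, seed = 1L, gridHash = "")
    fv <- setNames(c(2, 1), c("70", "60"))   # indicator 1
    expect_equal(unname(tspScore(model, fv)), 2)
    fv0 <- setNames(c(1, 2), c("70", "60"))  # indicator 0
    expect_equal(unname(tspScore(model, fv0)), 0)

    # two independent accumulations agree: matrix product vs scalar loop
    set.seed(31)
    X <- makeFeatureMatrix(8, seed = 31)
    pairs <- data.frame(ti = c(70, 57, 84), tj = c(60, 82, 55))
    model3 <- new("TSPModel",
        pairs = cbind(pairs, scorePrimary = 1, scoreSecondary = 0),
        intercept = -0.7, coefficients = c(1.5, -2.2, 0.4), lambda = 0.01,
        positiveLabel = "positive", negativeLabel = "negative",
        cvFolds = 5L, seed = 1L, gridHash = "")
    fx <- asFeatures(X, randomLabels(8))
    got <- tspScore(model3, fx)
    ind <- indicatorMatrix(fx, pairs)@indicators
    byMatrix <- drop(-0.7 + ind %*% c(1.5, -2.2, 0.4))
    expect_equal(unname(got), unname(byMatrix), tolerance = 1e-12)

    expect_error(tspScore(model3, setNames(1, "70")), "grid mismatch")
})

test_that("the sign rule maps scores to classes with 0 as negative", {
    mkModel <- function(b0) new("TSPModel",
        pairs = data.frame(ti = numeric(), tj = numeric(),
                           scorePrimary = numeric(),
                           scoreSecondary = numeric()),
        intercept = b0, coefficients = numeric(), lambda = 0,
        positiveLabel = "positive", negativeLabel = "negative",
        cvFolds = 0L, seed = 1L, gridHash = "")
    fv <- setNames(c(1, 2), c("60", "70"))
    # the reported group-median scores: -1.31 (non-mucinous side) and 1.54
    expect_identical(unname(tspClassify(mkModel(-1.31), fv)), "negative")
    expect_identical(unname(tspClassify(mkModel(1.54), fv)), "positive")
    expect_identical(unname(tspClassify(mkModel(0), fv)), "negative")
})

test_that("confirmed diagnoses form the training split", {
    t <- seq(40, 95, by = 0.5)
    tgs <- lapply(1:35, function(i)
        Thermogram(sprintf("s%02d", i), t, rnorm(length(t)) + 1))
    ids <- vapply(tgs, sampleId, character(1))
    conf <- setNames(c(rep(TRUE, 22), rep(FALSE, 13)), ids)
    cohort <- ThermogramCohort(tgs, confirmed = conf)
    split <- trainValidateSplit(cohort)
    expect_length(split$training, 22L)
    expect_length(split$validation, 13L)
    expect_length(intersect(sampleIds(split$training),
                            sampleIds(split$validation)), 0L)

    allConf <- ThermogramCohort(tgs, confirmed = setNames(rep(TRUE, 35), ids))
    expect_warning(split2 <- trainValidateSplit(allConf), "empty")
    expect_length(split2$validation, 0L)

    expect_error(trainValidateSplit(ThermogramCohort(tgs)), "absent")
})

test_that("fitting is deterministic and sparser under stronger penalty", {
    cohort <- generateCohort(defaultRecipes()[["envelope"]])
    fx <- prepareFeatures(cohort)
    pairs <- ktspSelect(fx, kMax = 8)
    pm <- indicatorMatrix(fx, pairs)
    y <- classLabels(fx)

    m1 <- fitTSPModel(pm, y, seed = 11)
    m2 <- fitTSPModel(pm, y, seed = 11)
    expect_identical(m1, m2)

    # active-set size is non-increasing along increasing penalties
    lams <- c(0.001, 0.01, 0.05, 0.1, 0.3)
    sizes <- vapply(lams, function(l)
        nrow(modelPairs(suppressWarnings(
            fitTSPModel(pm, y, lambda = l)))), integer(1))
    expect_true(all(diff(sizes) <= 0L))
})

test_that("degenerate fitting inputs are refused or repaired", {
    ind <- matrix(c(0, 1, 0, 1, 1, 1, 1, 1), ncol = 2,
                  dimnames = list(NULL, c("T71>T56", "T72>T57")))
    y <- rep(c("negative", "positive"), each = 2)
    # constant second column is dropped with a warning
    expect_warning(
        m <- fitTSPModel(ind, y, pairs = makePairs(2), lambda = 0.01),
        "constant indicator")
    expect_true(all(modelPairs(m)$ti != 72))
    expect_error(
        fitTSPModel(ind, rep("positive", 4), pairs = makePairs(2),
                    lambda = 0.1),
        "non-empty")
    expect_error(
        fitTSPModel(ind, c("negative", rep("positive", 3)),
                    pairs = makePairs(2), lambda = 0.1),
        "at least 2 samples per class")
})

test_that("models round-trip through JSON", {
    cohort <- generateCohort(defaultRecipes()[["shifted-peak"]])
    fx <- prepareFeatures(cohort)
    pairs <- ktspSelect(fx, kMax = 5)
    model <- fitTSPModel(indicatorMatrix(fx, pairs), classLabels(fx),
                         seed = 3, gridHash = gridHash(GridSpec()))
    f <- withr::local_tempfile(fileext = ".json")
    writeTSPModel(model, f)
    back <- readTSPModel(f)
    expect_equal(back@intercept, model@intercept)
    expect_equal(back@coefficients, model@coefficients)
    expect_equal(back@pairs$ti, model@pairs$ti)
    expect_identical(back@gridHash, model@gridHash)
    expect_equal(unname(tspScore(back, fx)), unname(tspScore(model, fx)))
})
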