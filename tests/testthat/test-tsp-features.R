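# Temperature-pair scoring, top-scoring-pair selection and the binary
# ordering indicators.

test_that("pair score is 1 under perfect separation and 0 under symmetry", {
    X <- makeFeatureMatrix(8, temps = c(55, 70))
    # class structure: negatives have X55 < X70, positives the reverse
    X[, 1] <- c(0, 0, 0, 0, 2, 2, 2, 2)
    X[, 2] <- 1
    y <- rep(c("negative", "positive"), each = 4)
    s <- pairScore(asFeatures(X, y), 55, 70)
    expect_equal(unname(s["primary"]), 1)

    # equal within-class frequencies cancel exactly
    X[, 1] <- c(0, 2, 0, 2, 0, 2, 0, 2)
    s <- pairScore(asFeatures(X, y), 55, 70)
    expect_equal(unname(s["primary"]), 0)
})

test_that("pair scores match exhaustive counting on all 465 pairs", {
    X <- makeFeatureMatrix(8, seed = 3)
    y <- rep(c("negative", "positive"), each = 4)
    fx <- asFeatures(X, y)
    yb <- y == "positive"
    temps <- as.numeric(colnames(X))
    for (i in seq_len(30)) {
        for (j in seq.int(i + 1, 31)) {
            s <- pairScore(fx, temps[i], temps[j])
            expect_equal(unname(s["primary"]), brutePairScore(X, yb, i, j),
                         tolerance = 1e-12)
            expect_equal(unname(s["secondary"]), bruteSecondary(X, yb, i, j),
                         tolerance = 1e-12)
        }
    }
})

test_that("selection puts a perfectly separating pair first", {
    X <- makeFeatureMatrix(20, seed = 9)
    y <- rep(c("negative", "positive"), each = 10)
    # plant the only perfectly ordering pair: 60 vs 61 flips with the class
    X[, "60"] <- X[, "61"] + ifelse(y == "positive", 0.5, -0.5)
    sel <- ktspSelect(asFeatures(X, y), kMax = 3)
    expect_equal(sort(c(sel$ti[1], sel$tj[1])), c(60, 61))
    expect_equal(sel$scorePrimary[1], 1)
    expect_equal(sel$ti[1], 60)  # canonical direction: positives higher
})

test_that("disjoint selection skips pairs reusing a temperature", {
    # temp 70 separates the classes perfectly, so every pair containing it
    # scores 1; the other temperatures are distinct constants (score 0)
    X <- matrix(rep(c(1, 2, 0, 3), each = 10), nrow = 10,
                dimnames = list(sprintf("s%d", 1:10),
                                c("55", "60", "70", "80")))
    y <- rep(c("negative", "positive"), each = 5)
    X[, "70"] <- ifelse(y == "positive", 10, -10)

    selAll <- ktspSelect(asFeatures(X, y), kMax = 4, disjoint = FALSE)
    expect_true(all(selAll$ti[1:3] == 70))
    expect_equal(selAll$scorePrimary[1:3], rep(1, 3))

    # with equal primary and secondary scores, (ti, tj) ascending breaks
    # the tie, and the later 70-pairs are skipped as non-disjoint
    selDis <- ktspSelect(asFeatures(X, y), kMax = 4, disjoint = TRUE)
    expect_identical(anyDuplicated(c(selDis$ti, selDis$tj)), 0L)
    expect_equal(selDis$ti[1], 70)
    expect_equal(selDis$tj[1], 55)
    expect_equal(nrow(selDis), 2L)
})

test_that("selection equals brute-force enumeration with the same rule", {
    for (seed in c(2, 7)) {
        X <- makeFeatureMatrix(10, temps = seq(55, 85, by = 3), seed = seed)
        y <- randomLabels(10, seed = seed)
        fx <- asFeatures(X, y)
        yb <- y == "positive"
        temps <- as.numeric(colnames(X))
        for (disjoint in c(TRUE, FALSE)) {
            got <- ktspSelect(fx, kMax = 3, disjoint = disjoint)
            want <- bruteKtsp(X, temps, yb, 3, disjoint)
            rownames(want) <- NULL
            expect_equal(got, want, tolerance = 1e-12)
        }
    }
})

test_that("indicators apply strictly-greater semantics with ties as 0", {
    X <- matrix(c(3, 1,
                  1, 3,
                  2, 2), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), c("60", "70")))
    pm <- indicatorMatrix(asFeatures(X, rep(c("negative", "positive"),
                                            length.out = 3)),
                          data.frame(ti = 60, tj = 70))
    expect_equal(unname(pm@indicators[, 1]), c(1, 0, 0))

    # element-wise recomputation over a 5 x 2 pair layout
    X5 <- makeFeatureMatrix(5, seed = 21)
    pairs <- data.frame(ti = c(57, 84), tj = c(83, 56))
    pm5 <- indicatorMatrix(asFeatures(X5, randomLabels(5)), pairs)
    for (s in 1:5)
        for (k in 1:2)
            expect_identical(pm5@indicators[s, k],
                as.numeric(X5[s, format(pairs$ti[k])] >
                           X5[s, format(pairs$tj[k])]))
    expect_error(
        indicatorMatrix(asFeatures(X5, randomLabels(5)),
                        data.frame(ti = 54, tj = 70)),
        "not on the feature grid")
})

test_that("scores are invariant to label swap and per-sample rescaling", {
    X <- makeFeatureMatrix(10, seed = 13)
    y <- randomLabels(10, seed = 13)
    ySwap <- ifelse(y == "positive", "negative", "positive")
    fx <- asFeatures(X, y)
    fxSwap <- asFeatures(X, ySwap)
    for (pair in list(c(55, 70), c(60, 85), c(71, 72))) {
        a <- pairScore(fx, pair[1], pair[2])
        b <- pairScore(fxSwap, pair[1], pair[2])
        expect_equal(a, b, tolerance = 1e-12)
        # reversal: same primary score for (tj, ti)
        r <- pairScore(fx, pair[2], pair[1])
        expect_equal(unname(a["primary"]), unname(r["primary"]),
                     tolerance = 1e-12)
    }

    # positive per-sample rescaling changes no indicator
    scale <- runif(10, 0.1, 10)
    pairs <- ktspSelect(fx, kMax = 5)
    ind1 <- indicatorMatrix(fx, pairs)
    ind2 <- indicatorMatrix(asFeatures(X * scale, y), pairs)
    expect_identical(ind1@indicators, ind2@indicators)
})

test_that("degenerate scoring inputs are rejected", {
    X <- makeFeatureMatrix(6)
    expect_error(pairScore(asFeatures(X, rep("positive", 6)), 55, 70),
                 "non-empty")
    expect_error(pairScore(asFeatures(X, randomLabels(6)), 70, 70),
                 "must differ")
    expect_error(pairScore(asFeatures(X, randomLabels(6)), 54.5, 70),
                 "not on the feature grid")
})
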