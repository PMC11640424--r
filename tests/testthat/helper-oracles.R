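# Independent brute-force oracles and small fixture builders. Each oracle
# re-derives the quantity from first principles, sharing no code with the
# implementation it checks.

# Two-point linear interpolation by explicit bracket search.
bruteInterp <- function(x, y, x0) {
    vapply(x0, function(v) {
        if (v <= x[1]) return(y[1])
        if (v >= x[length(x)]) return(y[length(y)])
        i <- max(which(x <= v))
        if (x[i] == v) return(y[i])
        y[i] + (y[i + 1] - y[i]) * (v - x[i]) / (x[i + 1] - x[i])
    }, numeric(1))
}

# Pair score by explicit per-sample counting.
brutePairScore <- function(X, y, i, j) {
    n1 <- 0; c1 <- 0; n0 <- 0; c0 <- 0
    for (s in seq_len(nrow(X))) {
        hit <- X[s, i] > X[s, j]
        if (y[s]) { n1 <- n1 + 1; c1 <- c1 + hit }
        else { n0 <- n0 + 1; c0 <- c0 + hit }
    }
    abs(c1 / n1 - c0 / n0)
}

# Rank-difference secondary score by explicit loops.
bruteSecondary <- function(X, y, i, j) {
    d <- numeric(nrow(X))
    for (s in seq_len(nrow(X))) {
        r <- rank(X[s, ])
        d[s] <- r[i] - r[j]
    }
    abs(mean(d[y]) - mean(d[!y]))
}

# Full kTSP selection re-derived: score every unordered pair by counting,
# canonicalize direction, apply the same ordering rule, greedy disjoint.
bruteKtsp <- function(X, temps, y, kMax, disjoint) {
    rows <- list()
    for (i in seq_len(length(temps) - 1)) {
        for (j in seq.int(i + 1, length(temps))) {
            p1 <- mean(X[y, i] > X[y, j]); p0 <- mean(X[!y, i] > X[!y, j])
            sec <- bruteSecondary(X, y, i, j)
            if (p1 - p0 >= 0) {
                rows[[length(rows) + 1]] <-
                    data.frame(ti = temps[i], tj = temps[j],
                               scorePrimary = p1 - p0, scoreSecondary = sec)
            } else {
                q1 <- mean(X[y, j] > X[y, i]); q0 <- mean(X[!y, j] > X[!y, i])
                rows[[length(rows) + 1]] <-
                    data.frame(ti = temps[j], tj = temps[i],
                               scorePrimary = q1 - q0, scoreSecondary = sec)
            }
        }
    }
    sc <- do.call(rbind, rows)
    sc <- sc[order(-sc$scorePrimary, -sc$scoreSecondary, sc$ti, sc$tj), ]
    if (disjoint) {
        used <- numeric(0); keep <- logical(nrow(sc))
        for (r in seq_len(nrow(sc)))
            if (!(sc$ti[r] %in% used || sc$tj[r] %in% used)) {
                keep[r] <- TRUE; used <- c(used, sc$ti[r], sc$tj[r])
            }
        sc <- sc[keep, ]
    }
    head(sc, kMax)
}

# AUC as the fraction of concordant positive/negative score pairs
# (ties counted one half).
bruteAUC <- function(pos, neg) {
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments.
bruteWilcoxonP <- function(a, b) {
    n <- length(a) + length(b)
    vals <- c(a, b)
    r <- rank(vals)
    wObs <- sum(r[seq_along(a)])
    mu <- length(a) * (n + 1) / 2
    sets <- combn(n, length(a))
    ws <- apply(sets, 2, function(idx) sum(r[idx]))
    mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}

# Coarse-to-fine grid minimization of the penalized logistic objective
# (mean negative log-likelihood + lambda * L1), intercept profiled by 1-D
# golden-section search at every grid point. Final lattice step 1e-3.
lassoGridOracle <- function(X, y01, lambda, span = 3) {
    obj <- function(b0, b1, b2) {
        eta <- b0 + X[, 1] * b1 + X[, 2] * b2
        mean(log1p(exp(eta)) - y01 * eta) + lambda * (abs(b1) + abs(b2))
    }
    prof <- function(b1, b2)
        optimize(function(b0) obj(b0, b1, b2), c(-20, 20), tol = 1e-12)
    best <- c(0, 0); bestVal <- prof(0, 0)$objective
    for (step in c(0.1, 0.01, 0.001)) {
        lo1 <- best[1] - if (step == 0.1) span else step * 15
        hi1 <- best[1] + if (step == 0.1) span else step * 15
        lo2 <- best[2] - if (step == 0.1) span else step * 15
        hi2 <- best[2] + if (step == 0.1) span else step * 15
        for (b1 in seq(lo1, hi1, by = step))
            for (b2 in seq(lo2, hi2, by = step)) {
                v <- prof(b1, b2)$objective
                if (v < bestVal) { bestVal <- v; best <- c(b1, b2) }
            }
    }
    p <- prof(best[1], best[2])
    list(intercept = optimize(function(b0) obj(b0, best[1], best[2]),
                              c(-20, 20), tol = 1e-12)$minimum,
         beta = best, value = bestVal)
}

# --- fixture builders -------------------------------------------------

# A raw thermogram: Gaussian peak + linear baseline on an irregular-ish grid.
makeRawThermogram <- function(id = "s1", tm = 70, sigma = 4, amp = 1,
                              intercept = 0.2, slope = 0.01,
                              tstep = 0.1, noise = 0, seed = NULL) {
    t <- seq(40, 95, by = tstep)
    cp <- amp * exp(-(t - tm)^2 / (2 * sigma^2)) + intercept + slope * t
    if (noise > 0) {
        if (!is.null(seed)) set.seed(seed)
        cp <- cp + rnorm(length(t), 0, noise)
    }
    Thermogram(id, t, cp)
}

# Random feature matrix (samples x temperatures) on the default grid.
makeFeatureMatrix <- function(n, temps = 55:85, seed = 1) {
    set.seed(seed)
    matrix(rnorm(n * length(temps)), nrow = n,
           dimnames = list(sprintf("s%02d", seq_len(n)), format(temps)))
}

randomLabels <- function(n, seed = 1) {
    set.seed(seed)
    sample(rep(c("negative", "positive"), length.out = n))
}

# ThermogramFeatures wrapper around a plain matrix, for tests that start
# from features rather than raw curves.
asFeatures <- function(X, labels, temps = as.numeric(colnames(X))) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(cp = t(X)),
        rowData = S4Vectors::DataFrame(temperature = temps),
        colData = S4Vectors::DataFrame(classLabel = unname(labels),
                                       confirmed = TRUE,
                                       row.names = rownames(X)),
        metadata = list(gridSpec = NULL, gridHash = "test"))
    new("ThermogramFeatures", se)
}

# Held-out AUC of the default pipeline on a recipe's validation split.
heldoutAUC <- function(recipe, nBoot = 1) {
    res <- runTrain(generateCohort(recipe), runConfig(nBoot = nBoot))
    auc(rocAUC(res$validation, nBoot = nBoot))
}
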