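## Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random stream.
withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}

# Match temperatures against a grid with a float tolerance; NA where absent.
matchTemperature <- function(x, grid, tol = 1e-6) {
    vapply(x, function(v) {
        i <- which(abs(grid - v) <= tol)
        if (length(i)) i[1L] else NA_integer_
    }, integer(1))
}

trapezoidArea <- function(t, y) pracma::trapz(t, y)

#' Grid identity key
#'
#' Canonical string encoding of a [GridSpec-class]; models store it so that
#' scoring on a differently gridded feature set is rejected.
#'
#' @param grid a [GridSpec-class].
#' @return single character string.
#' @export
gridHash <- function(grid) {
    stopifnot(is(grid, "GridSpec"))
    sprintf("grid[%g:%g:%g]feat[%g:%g:%g]",
        grid@tMin, grid@tMax, grid@dt,
        grid@featureLo, grid@featureHi, grid@featureStep)
}

# Stratified k-fold assignment, seeded; returns integer fold id per sample.
stratifiedFolds <- function(y, k, seed) {
    fold <- integer(length(y))
    withSeed(seed, for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    })
    fold
}
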