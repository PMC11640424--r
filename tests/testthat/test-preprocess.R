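# Baseline correction, interpolation, area normalization, feature
# extraction, and the invariants of their composition.

test_that("baseline correction removes a pure linear signal", {
    t <- seq(40, 95, by = 0.5)
    tg <- Thermogram("lin", t, 2 + 0.1 * t)
    corrected <- baselineCorrect(tg)
    expect_lt(max(abs(heatCapacity(corrected))), 1e-9)
    expect_equal(temperatures(corrected), t)
})

test_that("baseline correction recovers a peak riding on a linear drift", {
    t <- seq(40, 95, by = 0.1)
    peak <- exp(-(t - 70)^2 / (2 * 3^2))   # < 1e-12 inside both windows
    tg <- Thermogram("pk", t, peak + 0.5 - 0.004 * t)
    corrected <- baselineCorrect(tg)
    expect_lt(max(abs(heatCapacity(corrected) - peak)), 1e-6)
})

test_that("baseline windows outside the data span are rejected", {
    tg <- makeRawThermogram()
    expect_error(baselineCorrect(tg, preWindow = c(30, 35)),
                 "outside data span")
    expect_error(baselineCorrect(tg, preWindow = c(45, 40)), "increasing")
    tgShort <- Thermogram("s", seq(40, 95, by = 4), rep(1, 14))
    expect_error(baselineCorrect(tgShort, preWindow = c(43, 43.5)),
                 "fewer than 2")
})

test_that("grid interpolation is piecewise linear and exact at knots", {
    tg <- Thermogram("two", c(40, 95), c(0, 11))
    gridded <- interpolateGrid(tg)
    i <- match(67.5, temperatures(gridded))
    expect_equal(heatCapacity(gridded)[i], 5.5)

    # input already on the grid passes through unchanged
    g <- GridSpec()
    onGrid <- Thermogram("og", uniformGrid(g),
                         sin(uniformGrid(g) / 7))
    expect_equal(heatCapacity(interpolateGrid(onGrid, g)),
                 heatCapacity(onGrid), tolerance = 1e-12)
})

test_that("interpolation matches a brute-force two-point oracle", {
    set.seed(11)
    knots <- sort(c(40, 95, runif(25, 40.2, 94.8)))
    vals <- rnorm(length(knots))
    tg <- Thermogram("pl", knots, vals)
    gridded <- interpolateGrid(tg)
    probes <- sample(temperatures(gridded), 50)
    got <- heatCapacity(gridded)[match(probes, temperatures(gridded))]
    expect_equal(got, bruteInterp(knots, vals, probes), tolerance = 1e-10)
})

test_that("a thermogram that does not cover the grid span is refused", {
    tg <- Thermogram("short", seq(50, 90, by = 0.1),
                     rnorm(length(seq(50, 90, by = 0.1))))
    expect_error(interpolateGrid(tg), "does not cover the grid")
    # the composed preparation fails at its first step on the same curve
    expect_error(prepareFeatures(tg), "outside data span")
})

test_that("area normalization gives unit integral and a known constant", {
    t <- seq(40, 95, by = 0.25)
    const <- Thermogram("const", t, rep(7, length(t)))
    normed <- areaNormalize(const)
    expect_equal(heatCapacity(normed), rep(1 / 55, length(t)),
                 tolerance = 1e-9)

    tg <- makeRawThermogram(tstep = 0.25)
    normed <- areaNormalize(tg)
    expect_equal(pracma::trapz(temperatures(normed), heatCapacity(normed)),
                 1, tolerance = 1e-9)

    # idempotence
    twice <- areaNormalize(normed)
    expect_equal(heatCapacity(twice), heatCapacity(normed),
                 tolerance = 1e-9)

    # a discretized Gaussian pre-scaled to unit area is left unchanged
    gauss <- exp(-(t - 70)^2 / (2 * 4^2))
    gauss <- gauss / pracma::trapz(t, gauss)
    unit <- Thermogram("unit", t, gauss)
    expect_equal(heatCapacity(areaNormalize(unit)), gauss,
                 tolerance = 1e-9)

    flat0 <- Thermogram("zero", t, rep(0, length(t)))
    expect_error(areaNormalize(flat0), "non-positive area")
})

test_that("feature extraction samples the per-degree window", {
    g <- GridSpec()
    expect_equal(featureGrid(g), 55:85)
    tg <- Thermogram("idn", uniformGrid(g), uniformGrid(g))
    fv <- extractFeatures(tg, g)
    expect_length(fv, 31L)
    expect_equal(unname(fv), as.numeric(55:85))

    gHalf <- GridSpec(featureStep = 0.5)
    expect_length(extractFeatures(tg, gHalf), 61L)

    offGrid <- Thermogram("og", seq(41, 95, by = 0.25),
                          rep(1, length(seq(41, 95, by = 0.25))))
    gOdd <- GridSpec(tMin = 41, featureLo = 55.1, featureHi = 85.1)
    expect_error(extractFeatures(offGrid, gOdd), "absent from grid")
})

test_that("the prepared features are deterministic and scale invariant", {
    tg <- makeRawThermogram(noise = 0.02, seed = 5)
    fv1 <- prepareFeatures(tg)
    fv2 <- prepareFeatures(tg)
    expect_identical(fv1, fv2)

    scaled <- Thermogram(sampleId(tg), temperatures(tg),
                         37.5 * heatCapacity(tg))
    expect_equal(prepareFeatures(scaled), fv1, tolerance = 1e-9)
})

test_that("grids are generated by index arithmetic without drift", {
    g <- GridSpec()
    ug <- uniformGrid(g)
    expect_identical(ug[length(ug)], 95)
    expect_identical(ug[1], 40)
    expect_length(ug, 221L)
    g3 <- GridSpec(dt = 0.1)
    expect_identical(max(uniformGrid(g3)), 95)
})

test_that("grid specifications are validated", {
    expect_error(GridSpec(featureLo = 30), "tMin < featureLo")
    expect_error(GridSpec(dt = 0.3), "integer multiple|integral")
    expect_error(GridSpec(featureStep = 0.3), "integer multiple")
})

test_that("cohort preparation yields a labeled 31 x n feature set", {
    cohort <- generateCohort(defaultRecipes()[["envelope"]])
    fx <- prepareFeatures(cohort)
    expect_s4_class(fx, "ThermogramFeatures")
    expect_identical(dim(fx), c(31L, 40L))
    expect_identical(unname(classLabels(fx)),
                     unname(classLabels(cohort)))
    # every prepared column is a unit-area curve restricted to 55-85 degC,
    # so values are positive around the transitions and finite everywhere
    expect_true(all(is.finite(featureMatrix(fx))))
})
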