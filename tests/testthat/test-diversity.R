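test_that("expectedUnique matches enumeration and closed forms", {
    ## single clonotype: any draw sees exactly it
    expect_equal(expectedUnique(5, 1), 1)
    ## all singletons: every draw is new
    expect_equal(expectedUnique(rep(1, 30), 7), 7)
    ## abundances (2,1), n=2: enumeration over C(3,2)=3 subsets gives 5/3
    expect_equal(expectedUnique(c(2, 1), 2), 5 / 3)
    ## n = 0 and n = N extremes
    expect_equal(expectedUnique(c(4, 3, 2), 0), 0)
    expect_equal(expectedUnique(c(4, 3, 2), 9), 3)
    expect_error(expectedUnique(c(2, 1), 4), "out of range")
})

test_that("rarefaction handles degenerate key sets", {
    ## all identical keys: one clonotype in every non-empty subsample
    c1 <- rarefyClonotypes(rep("K", 50), c(0, 1, 10, 50), seed = 2)
    expect_equal(divCalc(c1), c(0, 1, 1, 1))
    expect_true(all(c1@replicateCounts[-1, ] == 1L))
    ## all distinct keys, n = N: every clonotype seen
    c2 <- rarefyClonotypes(as.character(1:40), c(0, 40), seed = 2)
    expect_equal(divCalc(c2), c(0, 40))
    ## n beyond N is a value error naming both
    expect_error(rarefyClonotypes(letters, 30, seed = 1), "N = 26")
})

test_that("rarefaction means track the hypergeometric expectation", {
    set.seed(77)
    abund <- as.integer(table(sample(50, 2000, replace = TRUE,
                                     prob = 0.93^(1:50))))
    keys <- rep(sprintf("c%02d", seq_along(abund)), times = abund)
    curve <- rarefyClonotypes(keys, c(100, 500, 1000), replicates = 200,
                              seed = 19)
    for (i in 1:3) {
        expected <- expectedUnique(abund, nGrid(curve)[i])
        expect_lt(abs(divCalc(curve)[i] - expected) / expected, 0.02)
    }
})

test_that("rarefaction is reproducible from its seed", {
    keys <- rep(letters, times = 1:26)
    a <- rarefyClonotypes(keys, c(0, 50, 200), seed = 123)
    b <- rarefyClonotypes(keys, c(0, 50, 200), seed = 123)
    expect_identical(a@replicateCounts, b@replicateCounts)
})

test_that("the diversity model evaluates its closed form", {
    expect_equal(divModel(0, 123, 0.1, 0.5), 0)
    expect_equal(divModel(100, 100, 0.01, 0.001), 63.3121,
                 tolerance = 1e-6)
    ## k = 0: approaches a for large n
    expect_equal(divModel(1e7, 80, 0.01, 0), 80)
    ## increasing in n when a*b + k > 0; bounded by a + k*n
    n <- seq(0, 5000, by = 100)
    y <- divModel(n, 50, 2e-3, 0.01)
    expect_true(all(diff(y) > 0))
    expect_true(all(y <= 50 + 0.01 * n + 1e-9))
    expect_error(divModel(10, -1, 0.1, 0.1), "non-negative")
})

test_that("the ES recovers parameters from a noiseless model curve", {
    n <- seq(0, 50000, by = 1000)
    y <- divModel(n, a = 5000, b = 5e-4, k = 0.002)
    fit <- fitDiversityModel(makeCurve(n, y),
                             ESConfig(generations = 300, seed = 11))
    p <- fittedParams(fit)
    expect_lt(abs(p["a"] - 5000) / 5000, 0.01)
    ## objective no worse than the initial guess (curve value at N, etc.)
    init <- sum((divModel(n, max(y), 3 / max(n), 0.002) - y)^2)
    expect_lte(p["objective"], init)
})

test_that("a flat zero curve fits to a = k = 0", {
    n <- seq(0, 10000, by = 500)
    fit <- fitDiversityModel(makeCurve(n, rep(0, length(n))),
                             ESConfig(generations = 100, seed = 4))
    expect_lt(fit@a * (1 - exp(-fit@b * max(n))) + fit@k * max(n), 1e-6)
    expect_lt(fit@objective, 1e-10)
})

test_that("fits are deterministic given the seed and need 4+ points", {
    n <- seq(0, 8000, by = 400)
    y <- divModel(n, 300, 1e-3, 0.005)
    cfg <- ESConfig(generations = 60, seed = 99)
    f1 <- fitDiversityModel(makeCurve(n, y), cfg)
    f2 <- fitDiversityModel(makeCurve(n, y), cfg)
    expect_identical(fittedParams(f1), fittedParams(f2))
    expect_identical(esTrace(f1), esTrace(f2))
    expect_error(fitDiversityModel(makeCurve(c(0, 10, 20), c(0, 5, 8)),
                                   cfg), "4 grid points")
})

test_that("the elitist ES trace is monotonically non-increasing", {
    n <- seq(0, 20000, by = 1000)
    for (seed in c(3, 17, 42)) {
        y <- divModel(n, 800, 3e-4, 0.004) *
            (1 + 0.02 * withSeedNoise(seed, length(n)))
        fit <- fitDiversityModel(makeCurve(n, pmax(y, 0)),
                                 ESConfig(generations = 150, seed = seed))
        expect_true(all(diff(esTrace(fit)) <= 0))
    }
})

test_that("read-error slope vanishes when an error-free curve saturates", {
    ## uniform abundances: the error-free curve truly plateaus, so the
    ## linear term has nothing to absorb and k fits to ~0
    sim <- simulateRepertoire(SimulationConfig(
        nClonotypes = 200, nReads = 20000, abundanceModel = "uniform",
        errorRate = 0, seed = 71))
    res <- estimateRepertoireDiversity(sim$records, nStep = 500,
                                       config = ESConfig(seed = 72))
    p <- fittedParams(res$fit)
    expect_lt(p["k"], 1e-4)
    expect_lt(abs(p["a"] - 200) / 200, 0.05)
})

test_that("end-to-end estimate orders sample richness correctly", {
    ## two samples at equal depth: one from 200 clonotypes, one from 20
    rich <- simulateRepertoire(SimulationConfig(
        nClonotypes = 200, nReads = 4000, abundanceModel = "uniform",
        errorRate = 0, seed = 21))
    poor <- simulateRepertoire(SimulationConfig(
        nClonotypes = 20, nReads = 4000, abundanceModel = "uniform",
        errorRate = 0, seed = 22))
    cfg <- ESConfig(generations = 200, seed = 5)
    aRich <- fittedParams(estimateRepertoireDiversity(
        rich$records, nStep = 200, config = cfg)$fit)["a"]
    aPoor <- fittedParams(estimateRepertoireDiversity(
        poor$records, nStep = 200, config = cfg)$fit)["a"]
    expect_gt(aRich, aPoor)
    expect_lt(abs(aPoor - 20) / 20, 0.05)
})
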