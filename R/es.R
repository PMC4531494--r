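#' @include AllClasses.R diversity.R
NULL

## Sum of squared residuals between the model and the empirical means.
.diversitySSE <- function(par, n, y) {
    sum((par[1] * (1 - exp(-par[2] * n)) + par[3] * n - y)^2)
}

## Floor for the log-scale parameters b and k: keeps them strictly
## positive so multiplicative mutation remains defined, while being far
## below any biologically meaningful rate.
.LOG_FLOOR <- 1e-12

#' Fit the diversity model by evolution strategy
#'
#' Fits the parameters `a`, `b`, `k` of the saturation-plus-read-error
#' model to an empirical rarefaction curve by minimising the unweighted
#' sum of squared residuals over the grid means with an elitist
#' (mu+lambda) evolution strategy. Mutation is Gaussian per parameter
#' with self-adaptive log-normal step-size control (learning rate
#' `1/sqrt(2 d)` for `d = 3` parameters); `a` is mutated on the linear
#' scale, `b` and `k` — which span orders of magnitude — on the log
#' scale. Negative `a` proposals are reflected at zero. Because
#' selection is elitist over parents and offspring, the best objective
#' is non-increasing across generations.
#'
#' Initialisation places the start in the basin of attraction of
#' typical saturating curves: `a0` is the curve value at the largest
#' grid point, `b0 = 3/max(n)`, and `k0` the slope between the last two
#' grid points (floored at a tiny positive value).
#'
#' @param curve A [DiversityCurve] with at least 4 grid points (the
#'   model has 3 free parameters).
#' @param config An [ESConfig].
#' @return A [DiversityModelFit]; `esTrace()` exposes the
#'   per-generation best objective.
#' @examples
#' n <- seq(0, 20000, by = 1000)
#' y <- divModel(n, a = 500, b = 5e-4, k = 0.01)
#' curve <- new("DiversityCurve", N = 20000L, nGrid = as.integer(n),
#'              replicateCounts = matrix(as.integer(round(y)), ncol = 1),
#'              divCalc = y, replicates = 1L, seed = 1L)
#' fit <- fitDiversityModel(curve, ESConfig(generations = 120, seed = 1))
#' fittedParams(fit)
#' @export
fitDiversityModel <- function(curve, config = ESConfig()) {
    stopifnot(is(curve, "DiversityCurve"), is(config, "ESConfig"))
    n <- as.numeric(curve@nGrid)
    y <- curve@divCalc
    if (length(n) < 4L)
        stop("need at least 4 grid points to fit 3 parameters")
    nMax <- max(n)
    ord <- order(n)
    last <- ord[length(ord)]; prev <- ord[length(ord) - 1L]
    slope <- (y[last] - y[prev]) / (n[last] - n[prev])
    init <- c(a = max(y[last], .LOG_FLOOR),
              b = 3 / max(nMax, 1),
              k = max(slope, .LOG_FLOOR))
    tau <- 1 / sqrt(2 * 3)
    mu <- config@mu; lambda <- config@lambda
    sse <- function(p) .diversitySSE(p, n, y)

    withSeed(config@seed, {
        ## parent population: parameters, per-parameter step sizes, fitness
        pars <- matrix(rep(init, each = mu), nrow = mu,
                       dimnames = list(NULL, c("a", "b", "k")))
        sigmaA <- rep(config@stepSizes[1] * max(init["a"], 1), mu)
        sigmaB <- rep(config@stepSizes[2], mu)
        sigmaK <- rep(config@stepSizes[3], mu)
        fitness <- apply(pars, 1L, sse)
        trace <- numeric(config@generations)
        for (gen in seq_len(config@generations)) {
            parent <- sample.int(mu, lambda, replace = TRUE)
            sA <- sigmaA[parent] * exp(tau * rnorm(lambda))
            sB <- sigmaB[parent] * exp(tau * rnorm(lambda))
            sK <- sigmaK[parent] * exp(tau * rnorm(lambda))
            a <- abs(pars[parent, 1L] + sA * rnorm(lambda))
            b <- pmax(pars[parent, 2L] * exp(sB * rnorm(lambda)), .LOG_FLOOR)
            k <- pmax(pars[parent, 3L] * exp(sK * rnorm(lambda)), .LOG_FLOOR)
            off <- cbind(a = a, b = b, k = k)
            offFit <- vapply(seq_len(lambda),
                             function(i) sse(off[i, ]), 0)
            allPars <- rbind(pars, off)
            allFit <- c(fitness, offFit)
            allSA <- c(sigmaA, sA); allSB <- c(sigmaB, sB)
            allSK <- c(sigmaK, sK)
            keep <- order(allFit)[seq_len(mu)]
            pars <- allPars[keep, , drop = FALSE]
            fitness <- allFit[keep]
            sigmaA <- allSA[keep]; sigmaB <- allSB[keep]; sigmaK <- allSK[keep]
            trace[gen] <- fitness[1L]
        }
        best <- pars[1L, ]
        new("DiversityModelFit", a = unname(best["a"]),
            b = unname(best["b"]),
            k = unname(best["k"]),
            objective = fitness[1L], esTrace = trace)
    })
}
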