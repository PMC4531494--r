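#' @include AllClasses.R repertoire.R
NULL

#' Rarefy clonotype keys
#'
#' Builds the empirical diversity curve of a sample: for each subsample
#' size `n`, draws `replicates` independent subsamples of size `n`
#' without replacement from the `N` clonotype keys and counts the
#' distinct keys in each; the per-`n` mean is the calculated diversity
#' `div_calc(n)`. Fully reproducible from `seed`.
#'
#' @param keys Character (or integer) vector of clonotype keys, one per
#'   read.
#' @param nGrid Integer vector of subsample sizes, each in `[0, N]`.
#' @param replicates Subsamples per grid point (default 5).
#' @param seed RNG seed.
#' @return A [DiversityCurve].
#' @examples
#' keys <- sample(letters[1:5], 100, replace = TRUE)
#' curve <- rarefyClonotypes(keys, nGrid = c(0, 10, 50, 100), seed = 1)
#' divCalc(curve)
#' @export
rarefyClonotypes <- function(keys, nGrid, replicates = 5L, seed = 1L) {
    N <- length(keys)
    nGrid <- sort(unique(as.integer(nGrid)))
    replicates <- as.integer(replicates)
    if (replicates < 1L) stop("need at least one replicate")
    if (any(nGrid < 0L) || any(nGrid > N))
        stop("subsample size out of range: n = ", nGrid[nGrid > N][1],
             " exceeds N = ", N, call. = FALSE)
    codes <- as.integer(factor(keys))
    counts <- withSeed(seed, {
        vapply(nGrid, function(n) {
            vapply(seq_len(replicates), function(r) {
                if (n == 0L) 0L
                else length(unique.default(
                    codes[sample.int(N, n, replace = FALSE)]))
            }, 0L)
        }, integer(replicates))
    })
    counts <- matrix(counts, nrow = length(nGrid), ncol = replicates,
                     byrow = TRUE,
                     dimnames = list(n = nGrid, replicate = NULL))
    new("DiversityCurve", N = N, nGrid = nGrid, replicateCounts = counts,
        divCalc = unname(rowMeans(counts)), replicates = replicates,
        seed = as.integer(seed))
}

#' Expected number of distinct clonotypes in a subsample
#'
#' Closed-form expectation of the number of distinct clonotypes seen in
#' a size-`n` subsample drawn without replacement from a sample with the
#' given clonotype abundances:
#' \deqn{E[c_{unique}] = \sum_i \left(1 - \binom{N-N_i}{n} / \binom{N}{n}\right)}
#' computed in log-space via `lchoose` to avoid overflow. This is the
#' analytic oracle against which [rarefyClonotypes()] means converge.
#'
#' @param abundances Positive integer vector of reads per clonotype.
#' @param n Subsample size, `0 <= n <= sum(abundances)`.
#' @return Expected distinct-clonotype count (numeric scalar).
#' @examples
#' expectedUnique(c(2, 1), 2)  # = 5/3
#' @export
expectedUnique <- function(abundances, n) {
    abundances <- as.numeric(abundances)
    if (any(abundances <= 0)) stop("abundances must be positive")
    N <- sum(abundances)
    if (n < 0 || n > N)
        stop("subsample size out of range: n = ", n, ", N = ", N,
             call. = FALSE)
    if (n == 0) return(0)
    sum(1 - exp(lchoose(N - abundances, n) - lchoose(N, n)))
}

#' Saturation-plus-read-error diversity model
#'
#' Evaluates the diversity model
#' \deqn{div_{mod}(n) = a (1 - e^{-b n}) + k n}
#' in which `a` is the true number of unique clonotypes (the saturation
#' level approached as sequencing depth grows), `b` the per-read
#' saturation rate, and `k` the linear rate at which read errors keep
#' producing spuriously novel clonotypes.
#'
#' @param n Non-negative numeric vector of read counts.
#' @param a,b,k Non-negative model parameters.
#' @return `div_mod(n)`, same length as `n`.
#' @examples
#' divModel(100, a = 100, b = 0.01, k = 0.001)  # 63.3121
#' @export
divModel <- function(n, a, b, k) {
    if (a < 0 || b < 0 || k < 0)
        stop("model parameters a, b, k must be non-negative")
    a * (1 - exp(-b * n)) + k * n
}

#' Estimate repertoire diversity
#'
#' End-to-end diversity analysis of an annotated repertoire: derives
#' clonotype keys under `def`, rarefies on the grid `{0, nStep, 2 nStep,
#' ..., N}` (the sample size `N` is always included as the final point),
#' and fits the saturation-plus-read-error model by evolution strategy.
#' The fitted `a` is the estimated true number of unique clonotypes in
#' the sample.
#'
#' @param x A [RepertoireSet].
#' @param def A [ClonotypeDefinition] (default CDR3 amino acid).
#' @param nStep Grid spacing (default 1000 reads).
#' @param replicates Rarefaction replicates per grid point (default 5).
#' @param config An [ESConfig]; its seed also seeds the rarefaction.
#' @return List with elements `curve` ([DiversityCurve]) and `fit`
#'   ([DiversityModelFit]).
#' @seealso [rarefyClonotypes()], [fitDiversityModel()]
#' @export
estimateRepertoireDiversity <- function(x, def = ClonotypeDefinition(),
                                        nStep = 1000L, replicates = 5L,
                                        config = ESConfig()) {
    keys <- clonotypeKey(x, def)
    keys <- keys[!is.na(keys)]
    if (!length(keys))
        stop("no reads yield a clonotype key under this definition")
    N <- length(keys)
    grid <- unique(c(seq(0L, N, by = as.integer(nStep)), N))
    curve <- rarefyClonotypes(keys, grid, replicates = replicates,
                              seed = config@seed)
    fit <- fitDiversityModel(curve, config)
    list(curve = curve, fit = fit)
}

#' Export a diversity curve and fit as TSV
#'
#' @param curve A [DiversityCurve].
#' @param fit Optional [DiversityModelFit]; adds a `div_mod` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
exportDiversity <- function(curve, fit = NULL, path) {
    df <- data.frame(n = curve@nGrid, curve@replicateCounts,
                     div_calc = curve@divCalc)
    colnames(df) <- c("n", paste0("replicate_", seq_len(curve@replicates)),
                      "div_calc")
    if (!is.null(fit))
        df$div_mod <- divModel(curve@nGrid, fit@a, fit@b, fit@k)
    exportTable(df, path)
}
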