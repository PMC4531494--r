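#' @importFrom methods new is validObject initialize setValidity show
#' @importFrom stats rnorm runif setNames median
#' @importFrom utils head read.delim write.table
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
NULL

## gzip magic bytes: 0x1f 0x8b
isGzip <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", n = 2L)
    length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

## Open a read connection, transparently decompressing gzip input.
openInput <- function(path) {
    if (!file.exists(path))
        stop("cannot read '", path, "': no such file", call. = FALSE)
    if (isGzip(path)) gzfile(path, "rt") else file(path, "rt")
}

openOutput <- function(path, gzip = FALSE) {
    if (gzip) gzfile(path, "wt") else file(path, "wt")
}

readAllLines <- function(path) {
    con <- openInput(path)
    on.exit(close(con))
    readLines(con, warn = FALSE)
}

#' Run code with a temporarily seeded RNG
#'
#' Evaluates `expr` with the random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so that seeded package
#' internals never perturb user scripts.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Natural-order sort key for IMGT-style gene names: sorts by locus+segment,
## then numerically by family and member (TRBV2 < TRBV6-4 < TRBV12-3).
naturalGeneOrder <- function(names) {
    stripped <- sub("\\*.*$", "", names)
    prefix <- sub("([0-9].*)?$", "", stripped)
    rest <- substring(stripped, nchar(prefix) + 1L)
    nums <- regmatches(rest, gregexpr("[0-9]+", rest))
    n1 <- vapply(nums, function(x) if (length(x) >= 1L) as.numeric(x[1]) else NA_real_, 0)
    n2 <- vapply(nums, function(x) if (length(x) >= 2L) as.numeric(x[2]) else -1, 0)
    n3 <- vapply(nums, function(x) if (length(x) >= 3L) as.numeric(x[3]) else -1, 0)
    allele <- sub("^[^*]*\\*?", "", names)
    alleleNum <- suppressWarnings(as.numeric(allele))
    alleleNum[is.na(alleleNum)] <- -1
    order(prefix, n1, n2, n3, alleleNum, names)
}

naturalSortGenes <- function(names) names[naturalGeneOrder(names)]

## Deterministic tie-break used by every ranked table in the package:
## descending count, then ascending lexicographic key (C collation so that
## ordering is locale-independent).
orderByCountThenKey <- function(count, key) {
    order(-count, key, method = "radix")
}
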