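#' @include AllClasses.R repertoire.R
NULL

## Stable palette index for a clonotype key: a deterministic hash of the
## key so that the same clonotype is coloured identically in every
## report, replacing ad-hoc random colour assignment.
.PALETTE_SIZE <- 64L

keyColorIndex <- function(keys, paletteSize = .PALETTE_SIZE) {
    vapply(keys, function(k) {
        bytes <- as.integer(charToRaw(k))
        h <- 0
        for (b in bytes) h <- (h * 31 + b) %% 2147483647
        as.integer(h %% paletteSize) + 1L
    }, 1L, USE.NAMES = FALSE)
}

.checkSameDefinition <- function(tables) {
    defs <- lapply(tables, definition)
    ref <- defs[[1]]
    same <- vapply(defs, function(d)
        identical(d@mode, ref@mode) && identical(d@level, ref@level) &&
        setequal(d@include, ref@include), TRUE)
    if (!all(same))
        stop("all samples must share the same clonotype definition",
             call. = FALSE)
    ref
}

#' Top clonotypes of a sample
#'
#' The `c` most abundant clonotypes under the table's deterministic
#' ordering (descending count, ties by ascending key).
#'
#' @param table A [ClonotypeTable].
#' @param c Number of clonotypes to keep (default 20, the conventional
#'   panel size for clonality comparisons).
#' @param sampleId Label for the sample.
#' @return A [RankedClonotypes].
#' @export
topClonotypes <- function(table, c = 20L, sampleId = "sample") {
    stopifnot(is(table, "ClonotypeTable"), c >= 1L)
    n <- min(as.integer(c), nrow(table@table))
    new("RankedClonotypes", sampleId = sampleId,
        definition = table@definition,
        entries = table@table[seq_len(n), , drop = FALSE])
}

## Shared core: union of per-sample top-c keys + frequency matrix.
.compareCore <- function(tables, c, sampleIds) {
    def <- .checkSameDefinition(tables)
    tops <- lapply(seq_along(tables), function(i)
        topClonotypes(tables[[i]], c, sampleIds[i]))
    topKeys <- lapply(tops, function(t) t@entries$key)
    keys <- sort(unique(unlist(topKeys)), method = "radix")
    freq <- vapply(tables, function(tab) {
        m <- match(keys, tab@table$key)
        ifelse(is.na(m), 0, tab@table$frequency[m])
    }, numeric(length(keys)))
    freq <- matrix(freq, nrow = length(keys),
                   dimnames = list(keys, sampleIds))
    provenance <- lapply(keys, function(k)
        sampleIds[vapply(topKeys, function(tk) k %in% tk, TRUE)])
    names(provenance) <- keys
    ## rows by descending frequency in the first sample, ties by key
    ord <- order(-freq[, 1L], keys, method = "radix")
    new("ComparisonReport", keys = keys[ord],
        frequencies = freq[ord, , drop = FALSE],
        provenance = provenance[ord],
        colorIndex = keyColorIndex(keys[ord]), definition = def)
}

#' Pairwise clonotype comparison
#'
#' Compares two samples by searching each sample's top-`c` clonotypes in
#' the other: the report covers the union of both top lists, with each
#' key's frequency (percent) in both samples, zero where absent. A
#' stable colour index per key allows matched clonotypes to be rendered
#' identically across reports.
#'
#' @param a,b [ClonotypeTable]s sharing the same definition.
#' @param c Top-list size (default 20).
#' @param sampleIds Length-2 character vector of labels.
#' @return A [ComparisonReport].
#' @examples
#' rsA <- RepertoireSet(sequence_id = as.character(1:4),
#'                      functionality = "productive",
#'                      cdr3_aa = c("AAA", "AAA", "BBB", "CCC"))
#' rsB <- RepertoireSet(sequence_id = as.character(1:2),
#'                      functionality = "productive",
#'                      cdr3_aa = c("BBB", "DDD"))
#' def <- ClonotypeDefinition("CDR3_AA")
#' rep <- pairwiseCompare(buildClonotypeTable(rsA, def),
#'                        buildClonotypeTable(rsB, def), c = 2)
#' comparisonFrequencies(rep)
#' @export
pairwiseCompare <- function(a, b, c = 20L, sampleIds = c("a", "b")) {
    .compareCore(list(a, b), c, sampleIds)
}

#' Multiple-sample clonotype comparison
#'
#' Generates the top-`c` clonotypes of every sample and searches the
#' collected union in all samples, yielding a keys-by-samples frequency
#' matrix. Works identically for CDR3-based and V-(D)-J-based
#' definitions.
#'
#' @param tables List of two or more [ClonotypeTable]s sharing one
#'   definition.
#' @param c Top-list size (default 20).
#' @param sampleIds Sample labels (default `names(tables)` or
#'   `sample1..k`).
#' @return A [ComparisonReport].
#' @export
multiCompare <- function(tables, c = 20L, sampleIds = NULL) {
    if (length(tables) < 2L) stop("need at least two samples")
    if (is.null(sampleIds))
        sampleIds <- if (!is.null(names(tables)) && all(nzchar(names(tables))))
            names(tables) else paste0("sample", seq_along(tables))
    .compareCore(tables, c, sampleIds)
}

#' Comparison report frequency matrix
#'
#' @param x A [ComparisonReport].
#' @return Numeric matrix (keys x samples) of frequencies in percent.
#' @export
comparisonFrequencies <- function(x) {
    stopifnot(is(x, "ComparisonReport"))
    x@frequencies
}

#' Track clonotypes across timepoints
#'
#' Follows clonotype frequencies over a time-ordered series of samples.
#' By default the tracked keys are the union of each timepoint's top-`c`
#' clonotypes; an explicit `keys` vector tracks exactly those (keys
#' absent everywhere yield all-zero trajectories).
#'
#' @param tables Time-ordered list of two or more [ClonotypeTable]s.
#' @param keys Optional character vector of keys to track.
#' @param c Top-list size when `keys` is `NULL` (default 20).
#' @param timepoints Labels (default `T1..Tk` or `names(tables)`).
#' @return Long-format `data.frame` with columns `key`, `timepoint`,
#'   `frequency` (percent), one row per key and timepoint, ready for
#'   line plots.
#' @export
trackClonotypes <- function(tables, keys = NULL, c = 20L,
                            timepoints = NULL) {
    if (length(tables) < 2L) stop("need at least two timepoints")
    if (is.null(timepoints))
        timepoints <- if (!is.null(names(tables)) &&
                          all(nzchar(names(tables))))
            names(tables) else paste0("T", seq_along(tables))
    .checkSameDefinition(tables)
    if (is.null(keys)) {
        tops <- lapply(tables, function(t) topClonotypes(t, c)@entries$key)
        keys <- sort(unique(unlist(tops)), method = "radix")
    }
    freq <- vapply(tables, function(tab) {
        m <- match(keys, tab@table$key)
        ifelse(is.na(m), 0, tab@table$frequency[m])
    }, numeric(length(keys)))
    freq <- matrix(freq, nrow = length(keys))
    data.frame(
        key = rep(keys, times = length(tables)),
        timepoint = factor(rep(timepoints, each = length(keys)),
                           levels = timepoints),
        frequency = as.vector(freq),
        stringsAsFactors = FALSE)
}

#' Export a comparison report as wide TSV
#'
#' One row per clonotype key, one frequency column per sample, plus the
#' stable colour index and the samples whose top list contributed the
#' key.
#'
#' @param x A [ComparisonReport].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
exportComparison <- function(x, path) {
    stopifnot(is(x, "ComparisonReport"))
    df <- data.frame(key = x@keys, x@frequencies,
                     color_index = x@colorIndex,
                     in_top_of = vapply(x@provenance, paste, "",
                                        collapse = ","),
                     check.names = FALSE, stringsAsFactors = FALSE)
    exportTable(df, path)
}
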