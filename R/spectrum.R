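#' @include AllClasses.R genecall.R
NULL

#' Load a germline gene/allele reference
#'
#' Reads a germline reference table (columns `locus`, `segment`, `gene`,
#' `allele`, `functionality`; `#` lines are comments). With no `path`,
#' loads the reference bundled with the package: a constructed,
#' versioned stand-in covering the human TRB and IGH loci, adequate for
#' spectrum mapping and simulation without any network access.
#'
#' @param path Optional path to a user-supplied reference TSV.
#' @param version Version string recorded in the object (default: taken
#'   from the bundled file's name or `"user"`).
#' @return A [GermlineReference].
#' @examples
#' ref <- germlineReference()
#' referenceVersion(ref)
#' @export
germlineReference <- function(path = NULL, version = NULL) {
    if (is.null(path)) {
        path <- system.file("extdata", "germline_reference_synthetic.tsv",
                            package = "ClonoScope", mustWork = TRUE)
        if (is.null(version)) version <- "synthetic-1.0"
    }
    if (is.null(version)) version <- "user"
    df <- read.delim(path, sep = "\t", comment.char = "#",
                     colClasses = "character", stringsAsFactors = FALSE)
    new("GermlineReference", genes = S4Vectors::DataFrame(df),
        version = version)
}

## Known gene (or allele) names for one locus/segment, natural-sorted.
referenceNames <- function(reference, locus, segment,
                           level = c("gene", "allele")) {
    level <- match.arg(level)
    g <- reference@genes
    sel <- g[g$locus == locus & g$segment == segment, , drop = FALSE]
    names <- if (level == "allele")
        paste0(sel$gene, "*", sel$allele) else unique(sel$gene)
    naturalSortGenes(unique(names))
}

#' Tabulate V-(D)-J combinations
#'
#' Counts gene (or allele) combinations over an ordered tuple of
#' segments — `(V, J)`, `(V, D)`, `(D, J)` or `(V, D, J)` — among reads
#' that carry a call for every axis segment. The total is the number of
#' such reads, so cell counts always sum to the total.
#'
#' @param x A [RepertoireSet].
#' @param axes Character vector of segments, one of the four tuples
#'   above (default `c("V", "D", "J")`).
#' @param level `"gene"` or `"allele"`.
#' @return A [CombinationMatrix].
#' @examples
#' rs <- RepertoireSet(sequence_id = as.character(1:3),
#'                     functionality = "productive",
#'                     v_call = c("TRBV6-4", "TRBV6-4", "TRBV12-3"),
#'                     d_call = c("TRBD2", "TRBD2", "TRBD1"),
#'                     j_call = c("TRBJ2-1", "TRBJ2-1", "TRBJ2-1"))
#' cells(combinationMatrix(rs))
#' @export
combinationMatrix <- function(x, axes = c("V", "D", "J"),
                              level = c("gene", "allele")) {
    stopifnot(is(x, "RepertoireSet"))
    level <- match.arg(level)
    allowed <- list(c("V", "J"), c("V", "D"), c("D", "J"), c("V", "D", "J"))
    if (!any(vapply(allowed, identical, TRUE, y = axes)))
        stop("axes must be one of (V,J), (V,D), (D,J), (V,D,J)")
    cols <- c(V = "v_call", D = "d_call", J = "j_call")
    calls <- lapply(axes, function(s) geneNames(x@records[[cols[[s]]]],
                                                level = level))
    names(calls) <- axes
    complete <- Reduce(`&`, lapply(calls, function(v) !is.na(v)))
    tab <- S4Vectors::DataFrame(lapply(calls, function(v) v[complete]))
    if (nrow(tab)) {
        keyStr <- do.call(paste, c(as.list(tab), sep = "\r"))
        agg <- table(keyStr)
        parts <- strsplit(names(agg), "\r", fixed = TRUE)
        cellTable <- S4Vectors::DataFrame(
            lapply(seq_along(axes), function(i)
                vapply(parts, `[[`, "", i)))
        colnames(cellTable) <- axes
        cellTable$count <- as.integer(agg)
        ord <- orderByCountThenKey(cellTable$count, names(agg))
        cellTable <- cellTable[ord, , drop = FALSE]
    } else {
        cellTable <- S4Vectors::DataFrame(
            setNames(rep(list(character()), length(axes)), axes))
        cellTable$count <- integer()
    }
    new("CombinationMatrix", axes = axes, level = level,
        cellTable = cellTable, total = sum(complete),
        axisLevels = list(), referenceVersion = "")
}

#' Map a combination matrix onto the full germline spectrum
#'
#' Re-expresses a combination matrix over the complete, natural-sorted
#' spectrum of known genes (or alleles) of a germline reference:
#' observed combinations keep their counts, every unobserved
#' combination becomes an explicit zero cell, and the axis orderings
#' are fixed by the reference — so any two samples mapped to the same
#' reference have identical axes and are directly comparable. Observed
#' names absent from the reference are not dropped: they are kept under
#' an appended "unknown" section of the axis, with a warning.
#'
#' @param x A [CombinationMatrix].
#' @param reference A [GermlineReference].
#' @param locus Locus whose spectrum to use (default: inferred from the
#'   first observed gene name).
#' @return A [CombinationMatrix] with dense cells and fixed
#'   `axisLevels`.
#' @export
mapToSpectrum <- function(x, reference, locus = NULL) {
    stopifnot(is(x, "CombinationMatrix"), is(reference, "GermlineReference"))
    tab <- x@cellTable
    if (is.null(locus)) {
        if (!nrow(tab))
            stop("cannot infer locus from an empty matrix; pass `locus`")
        locus <- substr(tab[[x@axes[1]]][1], 1L, 3L)
    }
    if (!locus %in% reference@genes$locus)
        stop("locus '", locus, "' not present in the reference")
    axisLevels <- lapply(x@axes, function(s) {
        known <- referenceNames(reference, locus, s, x@level)
        observed <- unique(tab[[s]])
        unknown <- setdiff(observed, known)
        if (length(unknown))
            warning(length(unknown), " observed ", s,
                    " name(s) absent from reference ", reference@version,
                    ": ", paste(head(unknown, 5L), collapse = ", "),
                    call. = FALSE)
        c(known, naturalSortGenes(unknown))
    })
    names(axisLevels) <- x@axes
    dense <- expand.grid(rev(axisLevels), stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)[, rev(seq_along(x@axes)),
                                                 drop = FALSE]
    colnames(dense) <- x@axes
    denseKey <- do.call(paste, c(as.list(dense), sep = "\r"))
    obsKey <- if (nrow(tab))
        do.call(paste, c(as.list(as.data.frame(tab[, x@axes, drop = FALSE])),
                         sep = "\r")) else character()
    count <- integer(length(denseKey))
    count[match(obsKey, denseKey)] <- tab$count
    cellTable <- S4Vectors::DataFrame(dense)
    cellTable$count <- count
    new("CombinationMatrix", axes = x@axes, level = x@level,
        cellTable = cellTable, total = x@total, axisLevels = axisLevels,
        referenceVersion = reference@version)
}

#' Filter combination cells by frequency threshold
#'
#' Retains cells whose relative frequency (`count/total`) is at least
#' `minFrequency`. The total is deliberately not recomputed, so the
#' surviving frequencies remain interpretable against the original
#' sample.
#'
#' @param x A [CombinationMatrix].
#' @param minFrequency Threshold in `[0, 1]`.
#' @return A filtered [CombinationMatrix].
#' @export
filterByThreshold <- function(x, minFrequency) {
    stopifnot(is(x, "CombinationMatrix"),
              minFrequency >= 0, minFrequency <= 1)
    if (x@total == 0L) return(x)
    keep <- x@cellTable$count / x@total >= minFrequency
    initialize(x, cellTable = x@cellTable[keep, , drop = FALSE])
}

#' Marginalize a combination matrix over a segment
#'
#' Sums counts over one axis, e.g. collapsing a `(V, D, J)` matrix over
#' `D` to recover the `(V, J)` matrix.
#'
#' @param x A [CombinationMatrix].
#' @param drop Segment to marginalize out.
#' @return A [CombinationMatrix] over the remaining axes.
#' @export
marginalizeMatrix <- function(x, drop) {
    stopifnot(is(x, "CombinationMatrix"), drop %in% x@axes,
              length(x@axes) > 1L)
    keepAxes <- setdiff(x@axes, drop)
    tab <- as.data.frame(x@cellTable)
    agg <- stats::aggregate(tab$count,
                            by = tab[, keepAxes, drop = FALSE], FUN = sum)
    colnames(agg) <- c(keepAxes, "count")
    key <- do.call(paste, c(as.list(agg[, keepAxes, drop = FALSE]),
                            sep = "\r"))
    agg <- agg[orderByCountThenKey(agg$count, key), , drop = FALSE]
    cellTable <- S4Vectors::DataFrame(agg[, keepAxes, drop = FALSE])
    cellTable$count <- as.integer(agg$count)
    new("CombinationMatrix", axes = keepAxes, level = x@level,
        cellTable = cellTable, total = x@total,
        axisLevels = if (length(x@axisLevels)) x@axisLevels[keepAxes]
                     else list(),
        referenceVersion = x@referenceVersion)
}
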