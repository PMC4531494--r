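#' @include AllClasses.R genecall.R
NULL

#' Summarize read functionality
#'
#' Counts reads per functionality class (productive, unproductive,
#' unknown, no result) with relative frequencies — the standard first
#' look at an annotated repertoire.
#'
#' @param x A [RepertoireSet].
#' @return A list with `counts` (named integer vector over the four
#'   classes), `total`, and `frequencies` (fractions; all zero for empty
#'   input).
#' @examples
#' rs <- RepertoireSet(sequence_id = c("a", "b", "c"),
#'                     functionality = c("productive", "productive",
#'                                       "no_result"))
#' summarizeFunctionality(rs)
#' @export
summarizeFunctionality <- function(x) {
    stopifnot(is(x, "RepertoireSet"))
    counts <- table(functionality(x))
    counts <- setNames(as.integer(counts), names(counts))
    total <- length(x)
    freqs <- if (total > 0L) counts / total else setNames(
        numeric(length(counts)), names(counts))
    list(counts = counts, total = total, frequencies = freqs)
}

#' Tabulate V, D or J gene usage
#'
#' One row per distinct gene (or allele) among reads carrying a call for
#' the chosen segment; reads without a call are excluded from the
#' denominator. Rows are sorted by descending count, ties broken by
#' ascending name.
#'
#' @param x A [RepertoireSet].
#' @param segment `"V"`, `"D"` or `"J"`.
#' @param level `"gene"` (collapses alleles) or `"allele"`.
#' @return A `data.frame` with columns `name`, `count`, `frequency`
#'   (fractions summing to 1 when any row exists).
#' @examples
#' rs <- RepertoireSet(sequence_id = as.character(1:4),
#'                     functionality = "productive",
#'                     v_call = c("TRBV6-4*01", "TRBV6-4*02",
#'                                "TRBV12-3*01", "TRBV12-3*01"))
#' geneUsage(rs, "V", level = "gene")
#' @export
geneUsage <- function(x, segment = c("V", "D", "J"),
                      level = c("gene", "allele")) {
    stopifnot(is(x, "RepertoireSet"))
    segment <- match.arg(segment)
    level <- match.arg(level)
    col <- c(V = "v_call", D = "d_call", J = "j_call")[[segment]]
    names <- geneNames(x@records[[col]], level = level)
    names <- names[!is.na(names)]
    if (!length(names))
        return(data.frame(name = character(), count = integer(),
                          frequency = numeric()))
    tab <- table(names)
    out <- data.frame(name = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[orderByCountThenKey(out$count, out$name), , drop = FALSE]
    out$frequency <- out$count / sum(out$count)
    rownames(out) <- NULL
    out
}

#' Compute per-read clonotype keys
#'
#' Derives the grouping key for each read under a
#' [ClonotypeDefinition]: the chosen CDR sequence, the whole-read
#' nucleotide sequence, or the V-(D)-J gene combination joined with
#' `"|"` (absent D rendered `"-"`, as for loci without D segments).
#' Keys are upper-cased and whitespace-stripped; a read whose needed
#' field is absent, or whose functionality class is not in the
#' definition's include set, yields `NA`.
#'
#' @param x A [RepertoireSet].
#' @param def A [ClonotypeDefinition].
#' @return Character vector of keys, `NA` where no key applies.
#' @examples
#' rs <- RepertoireSet(sequence_id = "r1", functionality = "productive",
#'                     v_call = "TRBV6-4*01", d_call = "TRBD2*01",
#'                     j_call = "TRBJ2-1*01", cdr3_aa = "ASSMGQNNEQF")
#' clonotypeKey(rs, ClonotypeDefinition("CDR3_AA"))
#' clonotypeKey(rs, ClonotypeDefinition("VDJ_GENES"))
#' @export
clonotypeKey <- function(x, def = ClonotypeDefinition()) {
    stopifnot(is(x, "RepertoireSet"), is(def, "ClonotypeDefinition"))
    rec <- x@records
    keys <- switch(def@mode,
        CDR1_AA = rec$cdr1_aa,
        CDR2_AA = rec$cdr2_aa,
        CDR3_AA = rec$cdr3_aa,
        CDR3_NT = rec$cdr3_nt,
        WHOLE_READ_NT = rec$sequence_nt,
        VDJ_GENES = {
            v <- geneNames(rec$v_call, def@level)
            d <- geneNames(rec$d_call, def@level)
            j <- geneNames(rec$j_call, def@level)
            out <- paste(v, ifelse(is.na(d), "-", d), j, sep = "|")
            out[is.na(v) | is.na(j)] <- NA_character_
            out
        })
    keys <- toupper(gsub("\\s+", "", keys))
    keys[!as.character(functionality(x)) %in% def@include] <- NA_character_
    keys[!is.na(keys) & !nzchar(keys)] <- NA_character_
    keys
}

#' Build a clonotype table
#'
#' Tallies identical clonotype keys over all reads yielding a key under
#' the definition; relative frequencies are percentages of the reads
#' used. Rows sorted by descending count, ties by ascending key.
#'
#' @param x A [RepertoireSet].
#' @param def A [ClonotypeDefinition].
#' @return A [ClonotypeTable].
#' @examples
#' rs <- RepertoireSet(sequence_id = as.character(1:4),
#'                     functionality = "productive",
#'                     cdr3_aa = c("ASSA", "ASSA", "ASSA", "ASSB"))
#' tab <- buildClonotypeTable(rs, ClonotypeDefinition("CDR3_AA"))
#' clonotypes(tab)
#' @export
buildClonotypeTable <- function(x, def = ClonotypeDefinition()) {
    keys <- clonotypeKey(x, def)
    keys <- keys[!is.na(keys)]
    n <- length(keys)
    if (n == 0L)
        return(new("ClonotypeTable", definition = def,
                   table = S4Vectors::DataFrame(key = character(),
                                                count = integer(),
                                                frequency = numeric()),
                   nRecordsUsed = 0L))
    tab <- table(keys)
    key <- names(tab)
    count <- as.integer(tab)
    ord <- orderByCountThenKey(count, key)
    new("ClonotypeTable", definition = def,
        table = S4Vectors::DataFrame(key = key[ord], count = count[ord],
                                     frequency = 100 * count[ord] / n),
        nRecordsUsed = n)
}

#' Export a table as TSV
#'
#' Writes any of the package's tabular results (clonotype tables, gene
#' usage, functionality summaries, comparison reports) as a
#' tab-separated UTF-8 text file with a header row.
#'
#' @param x A `ClonotypeTable`, `data.frame` or `DataFrame`.
#' @param path Output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
exportTable <- function(x, path) {
    if (is(x, "ClonotypeTable")) x <- as.data.frame(clonotypes(x))
    if (is(x, "DataFrame")) x <- as.data.frame(x)
    con <- openOutput(path, gzip = endsWith(path, ".gz"))
    on.exit(close(con))
    write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "", fileEncoding = "UTF-8")
    invisible(path)
}
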