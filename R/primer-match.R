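#' @include AllClasses.R
NULL

#' Reverse-complement a nucleotide sequence
#'
#' IUPAC-aware reverse complement (degenerate codes map to their
#' complements: R/Y, K/M, B/V, D/H; S, W and N are self-complementary).
#'
#' @param sequence Character vector of IUPAC nucleotide sequences.
#' @return Reverse-complemented sequences.
#' @examples
#' reverseComplementSeq("AAGR")  # "YCTT"
#' @export
reverseComplementSeq <- function(sequence) {
    bad <- grepl(sprintf("[^%s]", .IUPAC_CHARS), toupper(sequence))
    if (any(bad))
        stop("invalid nucleotide character in: ", sequence[bad][1],
             call. = FALSE)
    as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(toupper(sequence))))
}

#' Match PCR primers against reads
#'
#' Exact-substring primer search over the reads of a repertoire, for
#' multiplex-PCR efficiency analysis. A primer hits a read if its
#' sequence occurs anywhere in the read; reverse primers are searched as
#' their reverse complements by default, because annotated reads are
#' reported in V-to-J orientation (`literal = TRUE` searches the
#' sequence as given instead). IUPAC degenerate codes in a primer match
#' any compatible read base; ambiguity codes on the read side are
#' treated literally. Each read contributes at most one hit per primer,
#' so a primer's relative frequency is the fraction of searched reads
#' carrying it.
#'
#' @param x A [RepertoireSet] whose reads carry nucleotide sequences.
#' @param primerSet A [PrimerSet].
#' @param field `"whole_read"` (the `sequence_nt` column) or
#'   `"cdr3"` (`cdr3_nt`).
#' @param literal If `TRUE`, search reverse primers as written.
#' @return A [PrimerMatchReport].
#' @examples
#' rs <- RepertoireSet(sequence_id = c("r1", "r2"),
#'                     functionality = "productive",
#'                     sequence_nt = c("CCAAGGTTAACC", "GGTTCCAAGGTT"))
#' ps <- new("PrimerSet", setName = "demo",
#'           primerTable = S4Vectors::DataFrame(
#'               name = "p1", sequence = "CCAAGG",
#'               orientation = "forward"))
#' primers(matchPrimers(rs, ps))
#' @export
matchPrimers <- function(x, primerSet, field = c("whole_read", "cdr3"),
                         literal = FALSE) {
    stopifnot(is(x, "RepertoireSet"), is(primerSet, "PrimerSet"))
    field <- match.arg(field)
    col <- c(whole_read = "sequence_nt", cdr3 = "cdr3_nt")[[field]]
    seqs <- x@records[[col]]
    seqs <- seqs[!is.na(seqs) & nzchar(seqs)]
    if (!length(seqs))
        stop("no reads carry a nucleotide sequence in field '", field, "'")
    subject <- Biostrings::DNAStringSet(toupper(seqs))
    tab <- primerSet@primerTable
    nReads <- length(subject)
    hitMatrix <- vapply(seq_len(nrow(tab)), function(i) {
        pattern <- tab$sequence[i]
        if (tab$orientation[i] == "reverse" && !literal)
            pattern <- reverseComplementSeq(pattern)
        Biostrings::vcountPattern(pattern, subject, fixed = "subject") > 0L
    }, logical(nReads))
    hitMatrix <- matrix(hitMatrix, nrow = nReads)
    counts <- colSums(hitMatrix)
    fwd <- tab$orientation == "forward"
    noFwd <- if (any(fwd)) sum(rowSums(hitMatrix[, fwd, drop = FALSE]) == 0L)
             else nReads
    noRev <- if (any(!fwd)) sum(rowSums(hitMatrix[, !fwd, drop = FALSE]) == 0L)
             else nReads
    new("PrimerMatchReport",
        report = S4Vectors::DataFrame(name = tab$name,
                                      orientation = tab$orientation,
                                      count = as.integer(counts),
                                      frequency = counts / nReads),
        readsSearched = nReads,
        noForwardHit = as.integer(noFwd), noReverseHit = as.integer(noRev))
}
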