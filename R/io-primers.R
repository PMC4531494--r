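#' @include AllClasses.R
NULL

#' Read a multiplex-PCR primer set
#'
#' Reads a primer panel from either a TSV with columns
#' `name`/`sequence`/`orientation`, or a FASTA whose headers end in
#' `_fwd` or `_rev` to encode orientation. Sequences are upper-cased and
#' validated against the IUPAC nucleotide alphabet (degenerate codes are
#' legal).
#'
#' @param path Primer list (TSV or FASTA, optionally gzip).
#' @param setName Panel name (default: file stem).
#' @return A [PrimerSet].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("name\tsequence\torientation",
#'              "VH1-FR1\tCCTCAGTGAAGGTCTCCTGCAAGG\tforward"), tf)
#' readPrimerSet(tf)
#' @export
readPrimerSet <- function(path, setName = sub("\\.[^.]*$", "",
                                              basename(path))) {
    lines <- readAllLines(path)
    if (length(lines) && startsWith(lines[[1]], ">")) {
        starts <- fastaRecordStarts(lines)
        headers <- sub("^>", "", trimws(lines[starts]))
        ends <- c(starts[-1] - 1L, length(lines))
        seqs <- vapply(seq_along(starts), function(i) {
            paste(trimws(lines[(starts[i] + 1L):ends[i]]), collapse = "")
        }, "")
        orientation <- ifelse(grepl("_rev$", headers), "reverse",
                       ifelse(grepl("_fwd$", headers), "forward",
                              NA_character_))
        if (anyNA(orientation))
            stop("FASTA primer header(s) without _fwd/_rev suffix: ",
                 paste(headers[is.na(orientation)], collapse = ", "),
                 call. = FALSE)
        name <- sub("_(fwd|rev)$", "", headers)
    } else {
        con <- openInput(path)
        on.exit(close(con))
        df <- read.delim(con, sep = "\t", header = TRUE,
                         colClasses = "character", quote = "",
                         stringsAsFactors = FALSE)
        need <- c("name", "sequence", "orientation")
        if (!all(need %in% colnames(df)))
            stop("primer TSV needs columns name/sequence/orientation",
                 call. = FALSE)
        name <- trimws(df$name)
        seqs <- trimws(df$sequence)
        orientation <- match.arg(trimws(tolower(df$orientation)),
                                 c("forward", "reverse"),
                                 several.ok = TRUE)
    }
    seqs <- toupper(seqs)
    bad <- grepl(sprintf("[^%s]", .IUPAC_CHARS), seqs)
    if (any(bad))
        stop("primer '", name[bad][1],
             "' contains a non-IUPAC character", call. = FALSE)
    new("PrimerSet", setName = setName,
        primerTable = S4Vectors::DataFrame(name = name, sequence = seqs,
                                           orientation = orientation))
}
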