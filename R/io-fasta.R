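#' @include AllClasses.R
NULL

## Line indices at which FASTA records start; errors (with the line
## number) if sequence data precedes the first header.
fastaRecordStarts <- function(lines) {
    headers <- which(startsWith(lines, ">"))
    nonEmpty <- which(nzchar(trimws(lines)))
    if (length(nonEmpty) && (!length(headers) || nonEmpty[1] < headers[1]))
        stop("malformed FASTA: sequence data before first header at line ",
             nonEmpty[1], call. = FALSE)
    headers
}

#' Split a FASTA file into record-bounded chunks
#'
#' Splits a FASTA file into chunks of at most `maxRecords` records each,
#' preserving record order and copying header and sequence lines
#' byte-identically, so that merging the chunks reproduces the source.
#' The default threshold of 500,000 records matches the per-submission
#' limit of the high-throughput annotation portal the outputs are
#' intended for.
#'
#' @param path Input FASTA (plain or gzip).
#' @param maxRecords Maximum records per chunk (default 500,000).
#' @param outDir Directory for chunk files (default: directory of
#'   `path`). Chunks are named `<stem>_part<i>.fasta`.
#' @return A list with elements `source_path`, `max_records_per_chunk`,
#'   `chunk_paths` and `records_per_chunk`.
#' @seealso [mergeOutputs()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGT", ">r2", "GGCC", ">r3", "TTAA"), fa)
#' plan <- splitFasta(fa, maxRecords = 2)
#' plan$records_per_chunk
#' @export
splitFasta <- function(path, maxRecords = 500000L, outDir = dirname(path)) {
    maxRecords <- as.integer(maxRecords)
    if (maxRecords < 1L) stop("maxRecords must be at least 1")
    lines <- readAllLines(path)
    starts <- fastaRecordStarts(lines)
    n <- length(starts)
    stem <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path),
                ignore.case = TRUE)
    if (n == 0L)
        return(list(source_path = path, max_records_per_chunk = maxRecords,
                    chunk_paths = character(), records_per_chunk = integer()))
    nChunks <- ceiling(n / maxRecords)
    bounds <- c(starts[seq(1L, n, by = maxRecords)], length(lines) + 1L)
    chunkPaths <- file.path(outDir, sprintf("%s_part%d.fasta", stem,
                                            seq_len(nChunks)))
    for (i in seq_len(nChunks)) {
        con <- file(chunkPaths[i], "wt")
        writeLines(lines[bounds[i]:(bounds[i + 1L] - 1L)], con)
        close(con)
    }
    perChunk <- pmin(maxRecords, n - maxRecords * (seq_len(nChunks) - 1L))
    list(source_path = path, max_records_per_chunk = maxRecords,
         chunk_paths = chunkPaths, records_per_chunk = as.integer(perChunk))
}

#' Count FASTA records
#'
#' @param path FASTA path (plain or gzip).
#' @return Integer number of records.
#' @export
countFastaRecords <- function(path) {
    length(fastaRecordStarts(readAllLines(path)))
}

#' Write sequences as wrapped FASTA
#'
#' @param sequences Named character vector (names become headers) or a
#'   [Biostrings::DNAStringSet].
#' @param path Output path; `.gz` suffix triggers compression.
#' @param width Sequence line width (default 80).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(sequences, path, width = 80L) {
    if (is(sequences, "XStringSet"))
        sequences <- setNames(as.character(sequences), names(sequences))
    con <- openOutput(path, gzip = endsWith(path, ".gz"))
    on.exit(close(con))
    for (i in seq_along(sequences)) {
        writeLines(paste0(">", names(sequences)[i]), con)
        seq <- sequences[[i]]
        starts <- seq(1L, nchar(seq), by = width)
        writeLines(substring(seq, starts, pmin(starts + width - 1L,
                                               nchar(seq))), con)
    }
    invisible(path)
}
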