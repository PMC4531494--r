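#' @include AllClasses.R
NULL

#' Normalize functionality tokens to the four-class scheme
#'
#' Annotation portals decorate functionality tokens with parenthetical
#' comments ("unproductive (see comment)"), so classification is a
#' case-insensitive prefix match: `unproductive*` before `productive*`,
#' then `unknown*`; "no result(s)" and empty/missing tokens map to
#' `no_result`; anything else maps to `unknown` with a warning.
#'
#' @param tokens Character vector of raw functionality tokens.
#' @return Factor with levels [FUNCTIONALITY_CLASSES].
#' @examples
#' normalizeFunctionality(c("productive", "unproductive (see comment)",
#'                          "No results", ""))
#' @export
normalizeFunctionality <- function(tokens) {
    tok <- tolower(trimws(as.character(tokens)))
    tok[is.na(tok)] <- ""
    out <- rep(NA_character_, length(tok))
    out[startsWith(tok, "unproductive")] <- "unproductive"
    noRes <- is.na(out) & (startsWith(tok, "no result") |
                           startsWith(tok, "no_result") |
                           startsWith(tok, "no-result") | !nzchar(tok))
    out[noRes] <- "no_result"
    out[is.na(out) & startsWith(tok, "productive")] <- "productive"
    out[is.na(out) & startsWith(tok, "unknown")] <- "unknown"
    odd <- is.na(out)
    if (any(odd)) {
        warning("unrecognized functionality token(s) mapped to 'unknown': ",
                paste(unique(tokens[odd]), collapse = ", "), call. = FALSE)
        out[odd] <- "unknown"
    }
    factor(out, levels = FUNCTIONALITY_CLASSES)
}

#' Read a per-read annotation summary table
#'
#' Reads a tab-separated (optionally gzip-compressed) per-read V(D)J
#' annotation table into a [RepertoireSet], using a [SummaryDialect] to
#' map physical column names onto the package's logical fields.
#' Functionality tokens are normalized with [normalizeFunctionality()];
#' optional columns missing from the file are filled with `NA`.
#'
#' @param path Path to the table (plain or gzip).
#' @param dialect A [SummaryDialect]; default is the canonical dialect.
#' @return A [RepertoireSet].
#' @seealso [writeSummary()] for the inverse.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sequence_id\tfunctionality\tv_call\tj_call\tcdr3_aa",
#'              "r1\tproductive\tTRBV6-4*01\tTRBJ2-1*01\tASSMGQNNEQF"), tf)
#' readSummary(tf)
#' @export
readSummary <- function(path, dialect = SummaryDialect()) {
    stopifnot(is(dialect, "SummaryDialect"))
    con <- openInput(path)
    on.exit(close(con))
    df <- read.delim(con, sep = dialect@delimiter, header = TRUE,
                     colClasses = "character", check.names = FALSE,
                     na.strings = character(), quote = "",
                     stringsAsFactors = FALSE)
    cols <- dialect@columns
    present <- cols[cols %in% colnames(df)]
    missingMandatory <- setdiff(.MANDATORY_FIELDS,
                                names(cols)[cols %in% colnames(df)])
    if (length(missingMandatory))
        stop("summary table '", path, "' is missing mandatory column(s): ",
             paste(cols[missingMandatory], collapse = ", "), call. = FALSE)
    getField <- function(field) {
        col <- cols[[field]]
        if (!col %in% colnames(df)) return(rep(NA_character_, nrow(df)))
        x <- df[[col]]
        x[x %in% dialect@missingTokens] <- NA_character_
        x
    }
    RepertoireSet(
        sequence_id = getField("sequence_id"),
        functionality = normalizeFunctionality(df[[cols[["functionality"]]]]),
        v_call = getField("v_call"), d_call = getField("d_call"),
        j_call = getField("j_call"),
        cdr1_aa = getField("cdr1_aa"), cdr2_aa = getField("cdr2_aa"),
        cdr3_aa = getField("cdr3_aa"), cdr3_nt = getField("cdr3_nt"),
        sequence_nt = getField("sequence_nt"),
        metadata = list(source = path, dialect = dialect))
}

#' Write a RepertoireSet as a summary table
#'
#' Writes the annotation table back out in a dialect's column naming,
#' tab-separated with a header row, optionally gzip-compressed (chosen
#' by a `.gz` suffix). `readSummary(writeSummary(x))` reproduces the
#' records field for field.
#'
#' @param x A [RepertoireSet].
#' @param path Output path; a `.gz` suffix triggers compression.
#' @param dialect A [SummaryDialect] providing the header names.
#' @return `path`, invisibly.
#' @export
writeSummary <- function(x, path, dialect = SummaryDialect()) {
    stopifnot(is(x, "RepertoireSet"))
    df <- as.data.frame(x@records)
    df$functionality <- as.character(df$functionality)
    colnames(df) <- dialect@columns[colnames(df)]
    con <- openOutput(path, gzip = endsWith(path, ".gz"))
    on.exit(close(con))
    write.table(df, con, sep = dialect@delimiter, quote = FALSE,
                row.names = FALSE, na = "")
    invisible(path)
}

#' Merge analysis outputs
#'
#' Concatenates split analysis outputs back into one file. Tables (any
#' file whose first line is not a FASTA header) must share an identical
#' header row, which is emitted once; FASTA inputs are concatenated
#' record-wise. Gzip inputs are decompressed transparently; the output
#' is compressed when `out` ends in `.gz`.
#'
#' @param paths Character vector of input paths (at least one), in order.
#' @param out Output path.
#' @return `out`, invisibly.
#' @seealso [splitFasta()]
#' @export
mergeOutputs <- function(paths, out) {
    if (length(paths) < 1L) stop("need at least one input file")
    first <- readAllLines(paths[[1]])
    isFasta <- length(first) > 0L && startsWith(first[[1]], ">")
    con <- openOutput(out, gzip = endsWith(out, ".gz"))
    on.exit(close(con))
    if (isFasta) {
        writeLines(first, con)
        for (p in paths[-1]) writeLines(readAllLines(p), con)
    } else {
        header <- first[[1]]
        writeLines(first, con)
        for (p in paths[-1]) {
            lines <- readAllLines(p)
            if (!length(lines) || !identical(lines[[1]], header))
                stop("header mismatch between '", paths[[1]], "' and '",
                     p, "'", call. = FALSE)
            if (length(lines) > 1L) writeLines(lines[-1], con)
        }
    }
    invisible(out)
}
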