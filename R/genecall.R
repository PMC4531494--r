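#' @include AllClasses.R
NULL

## Regex for one IMGT-nomenclature call: optional species word, gene name
## (locus + segment letter + designation), optional *allele, optional
## functionality flag, e.g. "Homsap TRBV6-4*01 F".
.GENE_CALL_RE <- paste0(
    "^\\s*(?:([A-Za-z]+)\\s+)?",                     # species prefix
    "((IGH|IGK|IGL|TRA|TRB|TRG|TRD)([VDJ])[-A-Za-z0-9/.]*)", # gene name
    "(?:\\*([0-9]+))?",                              # allele
    "(?:\\s+\\(?(F|ORF|P)\\)?)?\\s*$")               # functionality flag

#' Parse an IMGT-style gene call
#'
#' Parses nomenclature strings such as `"Homsap TRBV6-4*01 F"` into
#' their components. When a read carries several comma-separated
#' alternative calls (the annotation portal lists ambiguous hits in
#' decreasing score order, joined by `", or "`), the first — highest
#' scoring — call is taken.
#'
#' @param raw Character vector of raw call tokens.
#' @return A `data.frame` with columns `raw`, `species`, `locus`,
#'   `segment`, `gene`, `allele`, `flag`; one row per input. `NA` input
#'   yields an all-`NA` row.
#' @examples
#' parseGeneCall("Homsap TRBV6-4*01 F")
#' parseGeneCall("Homsap IGHV1-69*06 F, or Homsap IGHV1-69D*01 F")$gene
#' @export
parseGeneCall <- function(raw) {
    raw <- as.character(raw)
    first <- sub("\\s*,.*$", "", raw)
    first <- sub("^\\s*or\\s+", "", first, ignore.case = TRUE)
    m <- regmatches(first, regexec(.GENE_CALL_RE, first))
    bad <- !is.na(raw) & nzchar(trimws(raw)) &
        vapply(m, length, 0L) == 0L
    if (any(bad))
        stop("cannot parse gene call token(s): ",
             paste(unique(raw[bad]), collapse = "; "), call. = FALSE)
    pick <- function(i) vapply(m, function(x) {
        if (length(x) < i || !nzchar(x[i])) NA_character_ else x[i]
    }, "")
    data.frame(raw = raw, species = pick(2L), locus = pick(4L),
               segment = pick(5L), gene = pick(3L), allele = pick(6L),
               flag = pick(7L), stringsAsFactors = FALSE)
}

## Vectorized gene-name extraction at gene or allele level; NA for
## missing or unparseable calls (a warning is raised once per segment).
geneNames <- function(calls, level = c("gene", "allele")) {
    level <- match.arg(level)
    out <- rep(NA_character_, length(calls))
    ok <- !is.na(calls) & nzchar(trimws(calls))
    if (!any(ok)) return(out)
    parsed <- tryCatch(parseGeneCall(calls[ok]), error = function(e) NULL)
    if (is.null(parsed)) {
        ## fall back to per-token parsing so one bad token does not lose all
        parsed <- parseGeneCall(rep(NA_character_, sum(ok)))
        tokens <- calls[ok]
        for (i in seq_along(tokens)) {
            row <- tryCatch(parseGeneCall(tokens[i]), error = function(e) NULL)
            if (!is.null(row)) parsed[i, ] <- row
        }
        nbad <- sum(is.na(parsed$gene))
        if (nbad) warning(nbad, " unparseable gene call(s) treated as missing",
                          call. = FALSE)
    }
    name <- parsed$gene
    if (level == "allele")
        name <- ifelse(is.na(parsed$allele), name,
                       paste0(name, "*", parsed$allele))
    out[ok] <- name
    out
}
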