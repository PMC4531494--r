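#' @include AllGenerics.R
NULL

#' Functionality classes
#'
#' The four functionality classes a rearranged read can carry after
#' annotation: `productive` (in-frame, stop-free), `unproductive`
#' (frame-shifted or containing stop codons), `unknown` (alignment found
#' but functionality undecidable) and `no_result` (no alignment at all;
#' such reads are reported but excluded from clonality and diversity
#' calculations).
#'
#' @format Character vector of length 4.
#' @export
FUNCTIONALITY_CLASSES <- c("productive", "unproductive", "unknown", "no_result")

CLONOTYPE_MODES <- c("CDR1_AA", "CDR2_AA", "CDR3_AA", "CDR3_NT",
                     "WHOLE_READ_NT", "VDJ_GENES")

KNOWN_LOCI <- c("IGH", "IGK", "IGL", "TRA", "TRB", "TRG", "TRD")

## ---------------------------------------------------------------------------
## SummaryDialect
## ---------------------------------------------------------------------------

#' SummaryDialect: column mapping for annotation summary tables
#'
#' Describes how to read a tab-separated per-read annotation table: which
#' physical column holds each logical field, the delimiter, and which
#' tokens denote a missing value. The defaults define this package's
#' canonical dialect; remap the column names to consume tables whose
#' headers differ (e.g. the `1_Summary` table of an online V(D)J
#' annotation portal).
#'
#' Mandatory logical fields are `sequence_id`, `functionality`, `v_call`,
#' `j_call` and `cdr3_aa`. `d_call` and the CDR1/CDR2/nucleotide columns
#' are optional because D segments do not exist for light-chain-like loci
#' (IGK, IGL, TRA).
#'
#' @param columns Named character vector mapping logical field names to
#'   physical column names. Unspecified fields keep their defaults.
#' @param delimiter Single field-delimiter character (default tab).
#' @param missingTokens Character vector of tokens read as missing.
#' @return A `SummaryDialect` object.
#' @examples
#' SummaryDialect(columns = c(functionality = "V-DOMAIN Functionality"))
#' @export SummaryDialect
#' @exportClass SummaryDialect
setClass("SummaryDialect",
    representation(columns = "character", delimiter = "character",
                   missingTokens = "character"))

.DIALECT_FIELDS <- c(sequence_id = "sequence_id",
                     functionality = "functionality",
                     v_call = "v_call", d_call = "d_call", j_call = "j_call",
                     cdr1_aa = "cdr1_aa", cdr2_aa = "cdr2_aa",
                     cdr3_aa = "cdr3_aa", cdr3_nt = "cdr3_nt",
                     sequence_nt = "sequence_nt")

.MANDATORY_FIELDS <- c("sequence_id", "functionality", "v_call", "j_call",
                       "cdr3_aa")

SummaryDialect <- function(columns = character(), delimiter = "\t",
                           missingTokens = c("", "NA", "null")) {
    cols <- .DIALECT_FIELDS
    if (length(columns)) {
        bad <- setdiff(names(columns), names(.DIALECT_FIELDS))
        if (length(bad))
            stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
        cols[names(columns)] <- columns
    }
    new("SummaryDialect", columns = cols, delimiter = delimiter,
        missingTokens = missingTokens)
}

setValidity("SummaryDialect", function(object) {
    if (!all(names(.DIALECT_FIELDS) %in% names(object@columns)))
        return("dialect must map every logical field name")
    if (length(object@delimiter) != 1L || nchar(object@delimiter) != 1L)
        return("delimiter must be a single character")
    TRUE
})

## ---------------------------------------------------------------------------
## RepertoireSet
## ---------------------------------------------------------------------------

#' RepertoireSet: a set of annotated repertoire reads
#'
#' Container for per-read V(D)J annotations: one row per read with its
#' functionality class, raw V/D/J gene calls, CDR1/2/3 amino-acid
#' sequences and optional nucleotide sequences. Build one with
#' [RepertoireSet()], [readSummary()] or [simulateRepertoire()].
#'
#' @slot records A [S4Vectors::DataFrame] with columns `sequence_id`,
#'   `functionality` (factor over the four classes), `v_call`, `d_call`,
#'   `j_call`, `cdr1_aa`, `cdr2_aa`, `cdr3_aa`, `cdr3_nt`, `sequence_nt`.
#' @slot metadata List of free-form provenance (source path, dialect).
#' @export
setClass("RepertoireSet",
    representation(records = "DataFrame", metadata = "list"))

.RECORD_COLUMNS <- names(.DIALECT_FIELDS)

#' Construct a RepertoireSet
#'
#' @param sequence_id,functionality,v_call,d_call,j_call Character
#'   vectors (recycled scalars allowed); `functionality` must contain
#'   only the four class labels of [FUNCTIONALITY_CLASSES].
#' @param cdr1_aa,cdr2_aa,cdr3_aa,cdr3_nt,sequence_nt Optional sequence
#'   columns; `NA` marks an absent value.
#' @param metadata Optional list of provenance.
#' @return A `RepertoireSet`.
#' @examples
#' rs <- RepertoireSet(
#'     sequence_id = c("r1", "r2"),
#'     functionality = c("productive", "no_result"),
#'     v_call = c("Homsap TRBV6-4*01 F", NA),
#'     j_call = c("Homsap TRBJ2-1*01 F", NA),
#'     cdr3_aa = c("ASSMGQNNEQF", NA))
#' functionality(rs)
#' @export
RepertoireSet <- function(sequence_id, functionality,
                          v_call = NA_character_, d_call = NA_character_,
                          j_call = NA_character_,
                          cdr1_aa = NA_character_, cdr2_aa = NA_character_,
                          cdr3_aa = NA_character_, cdr3_nt = NA_character_,
                          sequence_nt = NA_character_, metadata = list()) {
    n <- length(sequence_id)
    rec <- function(x) {
        x <- as.character(x)
        if (length(x) == 1L) rep(x, n) else x
    }
    df <- S4Vectors::DataFrame(
        sequence_id = as.character(sequence_id),
        functionality = factor(rec(functionality),
                               levels = FUNCTIONALITY_CLASSES),
        v_call = rec(v_call), d_call = rec(d_call), j_call = rec(j_call),
        cdr1_aa = rec(cdr1_aa), cdr2_aa = rec(cdr2_aa), cdr3_aa = rec(cdr3_aa),
        cdr3_nt = rec(cdr3_nt), sequence_nt = rec(sequence_nt))
    new("RepertoireSet", records = df, metadata = metadata)
}

setValidity("RepertoireSet", function(object) {
    df <- object@records
    missing <- setdiff(.RECORD_COLUMNS, colnames(df))
    if (length(missing))
        return(paste("missing record column(s):",
                     paste(missing, collapse = ", ")))
    if (anyNA(df$functionality))
        return("functionality must be one of the four classes")
    cdr3 <- df$cdr3_aa
    if (any(!is.na(cdr3) & !nzchar(cdr3)))
        return("cdr3_aa, when present, must be non-empty")
    TRUE
})

#' @describeIn RepertoireSet-class Number of reads.
#' @param x A `RepertoireSet`.
#' @export
setMethod("length", "RepertoireSet", function(x) nrow(x@records))

#' @describeIn RepertoireSet-class The per-read annotation `DataFrame`.
#' @export
setMethod("records", "RepertoireSet", function(x) x@records)

#' @describeIn RepertoireSet-class Factor of per-read functionality classes.
#' @export
setMethod("functionality", "RepertoireSet", function(x) x@records$functionality)

#' @describeIn RepertoireSet-class Subset reads.
#' @param i Index vector.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "RepertoireSet", function(x, i, j, ..., drop = FALSE) {
    initialize(x, records = x@records[i, , drop = FALSE])
})

setMethod("show", "RepertoireSet", function(object) {
    counts <- table(functionality(object))
    cat("RepertoireSet with", length(object), "reads\n")
    cat("  functionality:",
        paste(names(counts), counts, sep = "=", collapse = " "), "\n")
    if (!is.null(object@metadata$source))
        cat("  source:", object@metadata$source, "\n")
})

## ---------------------------------------------------------------------------
## ClonotypeDefinition / ClonotypeTable
## ---------------------------------------------------------------------------

#' ClonotypeDefinition: what counts as "the same clone"
#'
#' A clonotype definition selects the per-read key on which reads are
#' grouped into clonotypes, and which functionality classes enter the
#' tally. Reads of class `no_result` never enter any calculation.
#'
#' @param mode One of `"CDR1_AA"`, `"CDR2_AA"`, `"CDR3_AA"` (default),
#'   `"CDR3_NT"`, `"WHOLE_READ_NT"`, `"VDJ_GENES"`.
#' @param level For `VDJ_GENES` keys: `"gene"` (default) or `"allele"`.
#' @param include Functionality classes counted; defaults to all classes
#'   except `no_result`. Use `"productive"` to restrict to productive
#'   rearrangements only.
#' @return A `ClonotypeDefinition`.
#' @examples
#' ClonotypeDefinition("CDR3_AA")
#' ClonotypeDefinition("VDJ_GENES", level = "allele", include = "productive")
#' @export ClonotypeDefinition
#' @exportClass ClonotypeDefinition
setClass("ClonotypeDefinition",
    representation(mode = "character", level = "character",
                   include = "character"))

ClonotypeDefinition <- function(mode = "CDR3_AA", level = "gene",
                                include = c("productive", "unproductive",
                                            "unknown")) {
    mode <- match.arg(mode, CLONOTYPE_MODES)
    level <- match.arg(level, c("gene", "allele"))
    new("ClonotypeDefinition", mode = mode, level = level,
        include = include)
}

setValidity("ClonotypeDefinition", function(object) {
    if (!object@mode %in% CLONOTYPE_MODES)
        return("unknown clonotype mode")
    if ("no_result" %in% object@include)
        return("no_result reads are never included in clonality calculations")
    if (!all(object@include %in% FUNCTIONALITY_CLASSES))
        return("include must be a subset of the functionality classes")
    if (!length(object@include))
        return("include must name at least one functionality class")
    TRUE
})

setMethod("show", "ClonotypeDefinition", function(object) {
    cat("ClonotypeDefinition:", object@mode,
        if (object@mode == "VDJ_GENES") paste0("(", object@level, " level)"),
        "\n  include:", paste(object@include, collapse = ", "), "\n")
})

#' ClonotypeTable: clonotype counts under a definition
#'
#' One row per distinct clonotype key with its read count and relative
#' frequency in percent (0-100, matching the tabular convention of
#' repertoire clonality reports). Rows are sorted by descending count,
#' ties broken by ascending key, so outputs are deterministic.
#'
#' @slot definition The [ClonotypeDefinition] used.
#' @slot table `DataFrame` with columns `key`, `count`, `frequency`.
#' @slot nRecordsUsed Number of reads that yielded a key.
#' @seealso [buildClonotypeTable()]
#' @export
setClass("ClonotypeTable",
    representation(definition = "ClonotypeDefinition", table = "DataFrame",
                   nRecordsUsed = "integer"))

setValidity("ClonotypeTable", function(object) {
    tab <- object@table
    if (!all(c("key", "count", "frequency") %in% colnames(tab)))
        return("table needs key/count/frequency columns")
    if (anyDuplicated(tab$key))
        return("clonotype keys must be unique")
    if (nrow(tab)) {
        if (sum(tab$count) != object@nRecordsUsed)
            return("counts must sum to nRecordsUsed")
        if (abs(sum(tab$frequency) - 100) > 1e-6)
            return("frequencies must sum to 100")
        if (any(tab$count <= 0))
            return("counts must be positive")
    } else if (object@nRecordsUsed != 0L) {
        return("empty table implies nRecordsUsed == 0")
    }
    TRUE
})

#' @describeIn ClonotypeTable-class The clonotype `DataFrame`
#'   (`key`, `count`, `frequency` in percent).
#' @param x A `ClonotypeTable`.
#' @export
setMethod("clonotypes", "ClonotypeTable", function(x) x@table)

#' @describeIn ClonotypeTable-class The definition used.
#' @export
setMethod("definition", "ClonotypeTable", function(x) x@definition)

#' @describeIn ClonotypeTable-class Number of reads contributing a key.
#' @export
setMethod("nRecordsUsed", "ClonotypeTable", function(x) x@nRecordsUsed)

#' @describeIn ClonotypeTable-class Number of distinct clonotypes.
#' @export
setMethod("length", "ClonotypeTable", function(x) nrow(x@table))

setMethod("show", "ClonotypeTable", function(object) {
    cat("ClonotypeTable (", object@definition@mode, "): ",
        nrow(object@table), " clonotypes from ", object@nRecordsUsed,
        " reads\n", sep = "")
    if (nrow(object@table)) {
        top <- head(as.data.frame(object@table), 5L)
        top$frequency <- sprintf("%.3f%%", top$frequency)
        print(top, row.names = FALSE)
        if (nrow(object@table) > 5L) cat("  ...\n")
    }
})

## ---------------------------------------------------------------------------
## Diversity classes
## ---------------------------------------------------------------------------

#' DiversityCurve: empirical rarefaction curve
#'
#' For each subsample size `n` in `nGrid`, the number of distinct
#' clonotypes observed in each of several random subsamples of size `n`
#' drawn without replacement from the sample's clonotype keys, and their
#' mean `divCalc(n)`.
#'
#' @slot N Total number of clonotype-bearing reads.
#' @slot nGrid Increasing integer vector of subsample sizes.
#' @slot replicateCounts Integer matrix, one row per grid point, one
#'   column per replicate.
#' @slot divCalc Numeric vector of per-`n` replicate means.
#' @slot replicates Number of replicates per grid point.
#' @slot seed Seed that reproduces the curve.
#' @seealso [rarefyClonotypes()], [fitDiversityModel()]
#' @export
setClass("DiversityCurve",
    representation(N = "integer", nGrid = "integer",
                   replicateCounts = "matrix", divCalc = "numeric",
                   replicates = "integer", seed = "integer"))

setValidity("DiversityCurve", function(object) {
    if (is.unsorted(object@nGrid, strictly = TRUE))
        return("nGrid must be strictly increasing")
    if (any(object@nGrid < 0L) || any(object@nGrid > object@N))
        return("grid points must satisfy 0 <= n <= N")
    if (nrow(object@replicateCounts) != length(object@nGrid))
        return("one row of replicate counts per grid point")
    if (any(object@divCalc < 0))
        return("divCalc cannot be negative")
    TRUE
})

#' @describeIn DiversityCurve-class Mean distinct-clonotype counts.
#' @param x A `DiversityCurve`.
#' @export
setMethod("divCalc", "DiversityCurve", function(x) x@divCalc)

#' @describeIn DiversityCurve-class The subsample-size grid.
#' @export
setMethod("nGrid", "DiversityCurve", function(x) x@nGrid)

setMethod("show", "DiversityCurve", function(object) {
    cat("DiversityCurve: N =", object@N, "reads,",
        length(object@nGrid), "grid points,",
        object@replicates, "replicates\n")
    cat("  div_calc(N) =", object@divCalc[length(object@divCalc)], "\n")
})

#' ESConfig: evolution-strategy settings for the diversity fit
#'
#' Configuration of the elitist (mu+lambda) evolution strategy used to
#' fit the saturation-plus-read-error diversity model. Mutation is
#' Gaussian per parameter with self-adaptive log-normal step-size
#' control; the saturation level is mutated on the linear scale while
#' the rate and error-slope parameters, which span orders of magnitude,
#' are mutated on the log scale.
#'
#' @param mu Number of parents (default 10).
#' @param lambda Number of offspring per generation (default 50).
#' @param generations Number of generations (default 500).
#' @param stepSizes Initial step sizes `c(a, b, k)`; `a` in clonotype
#'   units relative to the curve plateau, `b` and `k` in natural-log
#'   units.
#' @param seed RNG seed for the fit.
#' @return An `ESConfig`.
#' @examples
#' ESConfig(generations = 200, seed = 7)
#' @export ESConfig
#' @exportClass ESConfig
setClass("ESConfig",
    representation(mu = "integer", lambda = "integer", generations = "integer",
                   stepSizes = "numeric", seed = "integer"))

ESConfig <- function(mu = 10L, lambda = 50L, generations = 500L,
                     stepSizes = c(a = 0.1, b = 0.5, k = 0.5), seed = 1L) {
    new("ESConfig", mu = as.integer(mu), lambda = as.integer(lambda),
        generations = as.integer(generations),
        stepSizes = as.numeric(stepSizes), seed = as.integer(seed))
}

setValidity("ESConfig", function(object) {
    if (object@mu < 1L || object@lambda < object@mu)
        return("need lambda >= mu >= 1")
    if (object@generations < 1L)
        return("need at least one generation")
    if (length(object@stepSizes) != 3L || any(object@stepSizes <= 0))
        return("stepSizes must be three positive numbers")
    TRUE
})

#' DiversityModelFit: fitted saturation-plus-read-error model
#'
#' Parameters of the diversity model
#' \deqn{div_{mod}(n) = a (1 - e^{-b n}) + k n}
#' fitted to an empirical rarefaction curve: `a` is the estimated true
#' number of unique clonotypes in the sample, `b` the per-read
#' saturation rate, and `k` the fraction of reads whose apparent novelty
#' is caused by read errors (the linear tail of the curve).
#'
#' @slot a,b,k Non-negative model parameters.
#' @slot objective Sum of squared residuals at the optimum.
#' @slot esTrace Best objective after each generation.
#' @seealso [fitDiversityModel()], [divModel()]
#' @export
setClass("DiversityModelFit",
    representation(a = "numeric", b = "numeric", k = "numeric",
                   objective = "numeric", esTrace = "numeric"))

setValidity("DiversityModelFit", function(object) {
    if (object@a < 0 || object@b < 0 || object@k < 0)
        return("model parameters must be non-negative")
    if (object@objective < 0)
        return("objective is a sum of squares and cannot be negative")
    TRUE
})

#' @describeIn DiversityModelFit-class Named vector `c(a, b, k, objective)`.
#' @param x A `DiversityModelFit`.
#' @export
setMethod("fittedParams", "DiversityModelFit", function(x)
    c(a = x@a, b = x@b, k = x@k, objective = x@objective))

#' @describeIn DiversityModelFit-class Per-generation best objective.
#' @export
setMethod("esTrace", "DiversityModelFit", function(x) x@esTrace)

setMethod("show", "DiversityModelFit", function(object) {
    cat("DiversityModelFit: div_mod(n) = a*(1-exp(-b*n)) + k*n\n")
    cat(sprintf("  a = %.6g (true unique clonotypes)\n", object@a))
    cat(sprintf("  b = %.6g (saturation rate per read)\n", object@b))
    cat(sprintf("  k = %.6g (read-error slope)\n", object@k))
    cat(sprintf("  objective (SSE) = %.6g\n", object@objective))
})

## ---------------------------------------------------------------------------
## Germline reference / combination matrices
## ---------------------------------------------------------------------------

#' GermlineReference: known germline genes and alleles per locus
#'
#' The full spectrum of known V/D/J gene and allele names for one or
#' more loci, used to map observed combination matrices onto a common,
#' comparable axis system. The package bundles a constructed reference
#' (see `germlineReference()`); it is versioned so reports can state
#' which spectrum they were mapped against.
#'
#' @slot genes `DataFrame` with columns `locus`, `segment`, `gene`,
#'   `allele`, `functionality`.
#' @slot version Version string of the reference.
#' @export
setClass("GermlineReference",
    representation(genes = "DataFrame", version = "character"))

setValidity("GermlineReference", function(object) {
    g <- object@genes
    need <- c("locus", "segment", "gene", "allele", "functionality")
    if (!all(need %in% colnames(g)))
        return("reference needs locus/segment/gene/allele/functionality")
    if (anyDuplicated(paste(g$locus, g$segment, g$gene, g$allele)))
        return("duplicate gene/allele entries in reference")
    TRUE
})

#' @describeIn GermlineReference-class Reference version string.
#' @param x A `GermlineReference`.
#' @export
setMethod("referenceVersion", "GermlineReference", function(x) x@version)

setMethod("show", "GermlineReference", function(object) {
    cat("GermlineReference", object@version, "\n")
    print(table(object@genes$locus, object@genes$segment))
})

#' CombinationMatrix: V-(D)-J combination counts
#'
#' Counts of observed gene (or allele) combinations over an ordered
#' tuple of segments, e.g. `(V, J)` or `(V, D, J)`. Stored sparsely as a
#' cell table; [mapToSpectrum()] expands it onto the full germline
#' spectrum so that different samples share identical axes.
#'
#' @slot axes Ordered character vector of segments, subset of V/D/J.
#' @slot level `"gene"` or `"allele"`.
#' @slot cellTable `DataFrame` with one column per axis plus `count`.
#' @slot total Number of reads carrying calls for every axis segment.
#' @slot axisLevels Named list; after spectrum mapping, the full ordered
#'   name vector per axis (empty before mapping).
#' @slot referenceVersion Version of the reference mapped against, or "".
#' @seealso [combinationMatrix()], [mapToSpectrum()],
#'   [filterByThreshold()]
#' @export
setClass("CombinationMatrix",
    representation(axes = "character", level = "character",
                   cellTable = "DataFrame", total = "integer",
                   axisLevels = "list", referenceVersion = "character"))

setValidity("CombinationMatrix", function(object) {
    if (!all(object@axes %in% c("V", "D", "J")))
        return("axes must be segments V, D or J")
    if (!all(object@axes %in% colnames(object@cellTable)))
        return("cell table must have one column per axis")
    if (!"count" %in% colnames(object@cellTable))
        return("cell table needs a count column")
    TRUE
})

#' @describeIn CombinationMatrix-class Cell table with per-combination
#'   `count` and `frequency` columns.
#' @param x A `CombinationMatrix`.
#' @export
setMethod("cells", "CombinationMatrix", function(x) {
    tab <- x@cellTable
    tab$frequency <- if (x@total > 0L) tab$count / x@total else numeric(nrow(tab))
    tab
})

#' @describeIn CombinationMatrix-class Number of reads with complete calls.
#' @export
setMethod("matrixTotal", "CombinationMatrix", function(x) x@total)

setMethod("show", "CombinationMatrix", function(object) {
    cat("CombinationMatrix (", paste(object@axes, collapse = "-"), ", ",
        object@level, " level): ", nrow(object@cellTable),
        " cells, total ", object@total, " reads\n", sep = "")
    if (nzchar(object@referenceVersion))
        cat("  mapped to reference", object@referenceVersion, "\n")
})

## ---------------------------------------------------------------------------
## Primers
## ---------------------------------------------------------------------------

#' PrimerSet: a multiplex-PCR primer panel
#'
#' Named primer sequences with orientation, as used in multiplex
#' amplification of rearranged V-(D)-J regions (e.g. BIOMED-2-style
#' panels). Sequences use the IUPAC nucleotide alphabet; degenerate
#' codes are legal and match any compatible base during matching.
#'
#' @slot setName Name of the panel.
#' @slot primerTable `DataFrame` with columns `name`, `sequence`,
#'   `orientation` (`"forward"`/`"reverse"`).
#' @seealso [readPrimerSet()], [matchPrimers()]
#' @export
setClass("PrimerSet",
    representation(setName = "character", primerTable = "DataFrame"))

setValidity("PrimerSet", function(object) {
    tab <- object@primerTable
    if (!all(c("name", "sequence", "orientation") %in% colnames(tab)))
        return("primer table needs name/sequence/orientation")
    if (anyDuplicated(tab$name))
        return("primer names must be unique within a set")
    if (any(!nzchar(tab$sequence)))
        return("primer sequences must be non-empty")
    if (!all(tab$orientation %in% c("forward", "reverse")))
        return("orientation must be 'forward' or 'reverse'")
    bad <- grepl(sprintf("[^%s]", .IUPAC_CHARS), tab$sequence)
    if (any(bad))
        return(paste("non-IUPAC character in primer", tab$name[bad][1]))
    TRUE
})

.IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

#' @describeIn PrimerSet-class Primer table.
#' @param x A `PrimerSet`.
#' @export
setMethod("primers", "PrimerSet", function(x) x@primerTable)

#' @describeIn PrimerSet-class Number of primers.
#' @export
setMethod("length", "PrimerSet", function(x) nrow(x@primerTable))

setMethod("show", "PrimerSet", function(object) {
    tab <- object@primerTable
    cat("PrimerSet '", object@setName, "': ", nrow(tab), " primers (",
        sum(tab$orientation == "forward"), " forward, ",
        sum(tab$orientation == "reverse"), " reverse)\n", sep = "")
})

#' PrimerMatchReport: per-primer hit statistics
#'
#' For each primer, the number of reads containing an exact (IUPAC-aware)
#' occurrence of the primer sequence and the corresponding fraction of
#' all searched reads. Reads lacking any forward (or reverse) hit are
#' counted separately, so the denominator is always the full set of
#' searched reads.
#'
#' @slot report `DataFrame` with columns `name`, `orientation`, `count`,
#'   `frequency`.
#' @slot readsSearched Number of reads searched.
#' @slot noForwardHit,noReverseHit Reads without any hit of that
#'   orientation.
#' @seealso [matchPrimers()]
#' @export
setClass("PrimerMatchReport",
    representation(report = "DataFrame", readsSearched = "integer",
                   noForwardHit = "integer", noReverseHit = "integer"))

setValidity("PrimerMatchReport", function(object) {
    if (any(object@report$count > object@readsSearched))
        return("a primer cannot hit more reads than were searched")
    TRUE
})

#' @describeIn PrimerMatchReport-class The per-primer report table.
#' @param x A `PrimerMatchReport`.
#' @export
setMethod("primers", "PrimerMatchReport", function(x) x@report)

setMethod("show", "PrimerMatchReport", function(object) {
    cat("PrimerMatchReport:", nrow(object@report), "primers over",
        object@readsSearched, "reads\n")
    cat("  reads with no forward hit:", object@noForwardHit,
        "| no reverse hit:", object@noReverseHit, "\n")
})

## ---------------------------------------------------------------------------
## Comparison classes
## ---------------------------------------------------------------------------

#' RankedClonotypes: the top clonotypes of one sample
#'
#' The `c` most abundant clonotypes of a sample under its definition's
#' deterministic ordering (descending count, ties by ascending key).
#'
#' @slot sampleId Sample label.
#' @slot definition The [ClonotypeDefinition] used.
#' @slot entries `DataFrame` with `key`, `count`, `frequency` (percent).
#' @seealso [topClonotypes()]
#' @export
setClass("RankedClonotypes",
    representation(sampleId = "character",
                   definition = "ClonotypeDefinition",
                   entries = "DataFrame"))

#' @describeIn RankedClonotypes-class The ranked entries.
#' @param x A `RankedClonotypes`.
#' @export
setMethod("clonotypes", "RankedClonotypes", function(x) x@entries)

setMethod("show", "RankedClonotypes", function(object) {
    cat("RankedClonotypes '", object@sampleId, "': top ",
        nrow(object@entries), " (", object@definition@mode, ")\n", sep = "")
})

#' ComparisonReport: clonotype frequencies across samples
#'
#' Union of the per-sample top-`c` clonotype keys with each key's
#' frequency (percent) in every sample, zero where absent. `provenance`
#' records which samples contributed each key to the union, and
#' `colorIndex` assigns each key a stable palette index (deterministic
#' in the key, so the same clonotype is rendered identically across
#' reports).
#'
#' @slot keys Ordered clonotype keys.
#' @slot frequencies Numeric matrix, keys x samples, in percent.
#' @slot provenance List (per key) of contributing sample ids.
#' @slot colorIndex Integer palette index per key.
#' @slot definition Shared [ClonotypeDefinition].
#' @seealso [pairwiseCompare()], [multiCompare()], [trackClonotypes()]
#' @export
setClass("ComparisonReport",
    representation(keys = "character", frequencies = "matrix",
                   provenance = "list", colorIndex = "integer",
                   definition = "ClonotypeDefinition"))

setValidity("ComparisonReport", function(object) {
    if (nrow(object@frequencies) != length(object@keys))
        return("one frequency row per key")
    if (any(object@frequencies < 0))
        return("frequencies cannot be negative")
    TRUE
})

setMethod("show", "ComparisonReport", function(object) {
    cat("ComparisonReport:", length(object@keys), "clonotypes x",
        ncol(object@frequencies), "samples\n")
})

## ---------------------------------------------------------------------------
## Simulation classes
## ---------------------------------------------------------------------------

#' SimulationConfig: synthetic-repertoire study conditions
#'
#' Parameters of the synthetic multiplex-PCR repertoire generator: a
#' fixed set of true clonotypes with an abundance distribution, random
#' V-(D)-J assignments from a germline reference, a functionality mix,
#' and a per-read substitution error process on the CDR3 that creates
#' spurious unique clonotypes (the phenomenon the diversity model's
#' linear `k`-term describes).
#'
#' @param nClonotypes Number of true clonotypes.
#' @param nReads Number of reads to emit.
#' @param abundanceModel `"uniform"`, `"geometric"` or `"lognormal"`.
#' @param abundanceParam Model parameter: ratio for geometric (default
#'   0.995, giving the saturating-then-linear curves typical of deeply
#'   sequenced blood repertoires), `sdlog` for lognormal; ignored for
#'   uniform.
#' @param errorRate Per-read probability that the CDR3 acquires one
#'   substitution.
#' @param functionalityMix Named fractions over the four classes,
#'   summing to 1.
#' @param locus Locus whose germline genes are assigned (default TRB).
#' @param cdr3LengthRange Integer pair of CDR3 amino-acid lengths.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return A `SimulationConfig`.
#' @examples
#' SimulationConfig(nClonotypes = 50, nReads = 2000, seed = 42)
#' @export SimulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(nClonotypes = "integer", nReads = "integer",
                   abundanceModel = "character", abundanceParam = "numeric",
                   errorRate = "numeric", functionalityMix = "numeric",
                   locus = "character", cdr3LengthRange = "integer",
                   seed = "integer"))

SimulationConfig <- function(nClonotypes, nReads,
                             abundanceModel = "geometric",
                             abundanceParam = 0.995,
                             errorRate = 0,
                             functionalityMix = c(productive = 0.82,
                                                  unproductive = 0.11,
                                                  unknown = 0.01,
                                                  no_result = 0.06),
                             locus = "TRB",
                             cdr3LengthRange = c(8L, 20L),
                             seed = 1L) {
    abundanceModel <- match.arg(abundanceModel,
                                c("uniform", "geometric", "lognormal"))
    new("SimulationConfig", nClonotypes = as.integer(nClonotypes),
        nReads = as.integer(nReads), abundanceModel = abundanceModel,
        abundanceParam = abundanceParam, errorRate = errorRate,
        functionalityMix = functionalityMix, locus = locus,
        cdr3LengthRange = as.integer(cdr3LengthRange),
        seed = as.integer(seed))
}

setValidity("SimulationConfig", function(object) {
    if (object@nClonotypes < 1L || object@nReads < 1L)
        return("need at least one clonotype and one read")
    if (object@errorRate < 0 || object@errorRate > 1)
        return("errorRate must lie in [0, 1]")
    mix <- object@functionalityMix
    if (!all(FUNCTIONALITY_CLASSES %in% names(mix)))
        return("functionalityMix must cover all four classes")
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
        return("functionalityMix fractions must be non-negative and sum to 1")
    if (length(object@cdr3LengthRange) != 2L ||
        object@cdr3LengthRange[1] < 1L ||
        object@cdr3LengthRange[1] > object@cdr3LengthRange[2])
        return("cdr3LengthRange must be an increasing positive pair")
    if (object@nClonotypes > 20^min(object@cdr3LengthRange))
        return("key space exhausted: nClonotypes exceeds 20^min length")
    TRUE
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nClonotypes, "clonotypes,",
        object@nReads, "reads,", object@abundanceModel, "abundances,",
        sprintf("error rate %.4g", object@errorRate), "\n")
})

#' GroundTruth: provenance of a simulated repertoire
#'
#' Complete ground truth of a [simulateRepertoire()] run: the true
#' clonotype keys with their realised read counts and gene assignments,
#' and per-read provenance (source clonotype, whether a read error was
#' applied).
#'
#' @slot clonotypeTable `DataFrame`: `key`, `abundance` (realised reads),
#'   `v_gene`, `d_gene`, `j_gene`.
#' @slot readProvenance `DataFrame`: `sequence_id`, `sourceClonotype`,
#'   `errorApplied`.
#' @export
setClass("GroundTruth",
    representation(clonotypeTable = "DataFrame", readProvenance = "DataFrame"))

setValidity("GroundTruth", function(object) {
    if (sum(object@clonotypeTable$abundance) !=
        nrow(object@readProvenance))
        return("clonotype abundances must sum to the number of reads")
    TRUE
})

#' @describeIn GroundTruth-class True clonotype table.
#' @param x A `GroundTruth`.
#' @export
setMethod("clonotypes", "GroundTruth", function(x) x@clonotypeTable)

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", nrow(object@clonotypeTable), "true clonotypes,",
        nrow(object@readProvenance), "reads (",
        sum(object@readProvenance$errorApplied), "with read errors )\n")
})
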