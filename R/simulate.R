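#' @include AllClasses.R spectrum.R io-fasta.R io-summary.R
NULL

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.NT4 <- c("A", "C", "G", "T")

randomStrings <- function(n, lengths, alphabet) {
    vapply(seq_len(n), function(i)
        paste(sample(alphabet, lengths[i], replace = TRUE), collapse = ""),
        "")
}

#' Simulate an annotated repertoire with known ground truth
#'
#' Emulates the outcome of multiplex-PCR amplification plus annotation
#' of a blood repertoire: a fixed set of true clonotypes (distinct CDR3
#' amino-acid keys with V-(D)-J gene assignments drawn from a germline
#' reference) with a chosen abundance distribution, a functionality
#' mix, and a per-read substitution-error process on the CDR3 that
#' creates spurious unique clonotypes — the phenomenon the diversity
#' model's linear error term describes. Reads of class `no_result`
#' carry no gene calls and no CDR3, as in real annotation output.
#' Deterministic given the config seed.
#'
#' @param config A [SimulationConfig].
#' @param reference A [GermlineReference] for gene assignment (default:
#'   the bundled reference).
#' @return List with `records` (a [RepertoireSet]) and `truth` (a
#'   [GroundTruth]).
#' @examples
#' sim <- simulateRepertoire(SimulationConfig(nClonotypes = 20,
#'                                            nReads = 500, seed = 7))
#' sim$records
#' clonotypes(sim$truth)[1:3, ]
#' @export
simulateRepertoire <- function(config, reference = germlineReference()) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    nC <- config@nClonotypes
    nR <- config@nReads
    locus <- config@locus
    withSeed(config@seed, {
        ## distinct CDR3 amino-acid keys
        lens <- sample(config@cdr3LengthRange[1]:config@cdr3LengthRange[2],
                       nC, replace = TRUE)
        keys <- randomStrings(nC, lens, .AA20)
        tries <- 0L
        while (anyDuplicated(keys)) {
            dup <- which(duplicated(keys))
            keys[dup] <- randomStrings(length(dup), lens[dup], .AA20)
            tries <- tries + 1L
            if (tries > 100L) stop("key space exhausted")
        }
        cdr3nt <- randomStrings(nC, 3L * lens, .NT4)
        vFlank <- randomStrings(nC, rep(25L, nC), .NT4)
        jFlank <- randomStrings(nC, rep(20L, nC), .NT4)

        ## V/D/J assignment from the reference (allele-level call strings)
        pickCalls <- function(segment) {
            pool <- referenceNames(reference, locus, segment,
                                   level = "allele")
            if (!length(pool)) return(rep(NA_character_, nC))
            paste("Homsap", sample(pool, nC, replace = TRUE), "F")
        }
        vCall <- pickCalls("V"); dCall <- pickCalls("D")
        jCall <- pickCalls("J")

        ## abundance weights
        weights <- switch(config@abundanceModel,
            uniform = rep(1, nC),
            geometric = config@abundanceParam^(seq_len(nC) - 1L),
            lognormal = stats::rlnorm(nC, meanlog = 0,
                                      sdlog = config@abundanceParam))
        src <- sample.int(nC, nR, replace = TRUE, prob = weights)

        ## functionality assignment
        fun <- sample(FUNCTIONALITY_CLASSES, nR, replace = TRUE,
                      prob = config@functionalityMix[FUNCTIONALITY_CLASSES])

        ## per-read substitution errors on the CDR3
        erred <- stats::runif(nR) < config@errorRate
        cdr3aaRead <- keys[src]
        cdr3ntRead <- cdr3nt[src]
        if (any(erred)) {
            idx <- which(erred)
            for (i in idx) {
                s <- cdr3aaRead[i]
                pos <- sample.int(nchar(s), 1L)
                old <- substr(s, pos, pos)
                substr(cdr3aaRead[i], pos, pos) <-
                    sample(setdiff(.AA20, old), 1L)
                ntPos <- 3L * (pos - 1L) + sample.int(3L, 1L)
                oldNt <- substr(cdr3ntRead[i], ntPos, ntPos)
                substr(cdr3ntRead[i], ntPos, ntPos) <-
                    sample(setdiff(.NT4, oldNt), 1L)
            }
        }
        seqNt <- paste0(vFlank[src], cdr3ntRead, jFlank[src])

        noRes <- fun == "no_result"
        toNA <- function(x) { x[noRes] <- NA_character_; x }
        records <- RepertoireSet(
            sequence_id = sprintf("read%06d", seq_len(nR)),
            functionality = fun,
            v_call = toNA(vCall[src]), d_call = toNA(dCall[src]),
            j_call = toNA(jCall[src]),
            cdr3_aa = toNA(cdr3aaRead), cdr3_nt = toNA(cdr3ntRead),
            sequence_nt = toNA(seqNt),
            metadata = list(simulated = TRUE, seed = config@seed))

        abundance <- tabulate(src, nbins = nC)
        truth <- new("GroundTruth",
            clonotypeTable = S4Vectors::DataFrame(
                key = keys, abundance = as.integer(abundance),
                v_call = vCall, d_call = dCall, j_call = jCall),
            readProvenance = S4Vectors::DataFrame(
                sequence_id = sprintf("read%06d", seq_len(nR)),
                sourceClonotype = keys[src],
                functionality = fun,
                errorApplied = erred))
        list(records = records, truth = truth)
    })
}

#' Write a simulated repertoire as plain-text fixtures
#'
#' Writes the annotation summary table (canonical dialect TSV), a FASTA
#' of the reads' nucleotide sequences, and the ground-truth clonotype
#' table into a directory. Contents are deterministic given the
#' simulation seed.
#'
#' @param sim The list returned by [simulateRepertoire()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
writeFixture <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(summary = file.path(dir, "summary.tsv"),
               fasta = file.path(dir, "reads.fasta"),
               truth = file.path(dir, "ground_truth.tsv"))
    writeSummary(sim$records, paths[["summary"]])
    rec <- records(sim$records)
    keep <- !is.na(rec$sequence_nt)
    writeFasta(setNames(rec$sequence_nt[keep], rec$sequence_id[keep]),
               paths[["fasta"]])
    exportTable(as.data.frame(sim$truth@clonotypeTable), paths[["truth"]])
    paths
}
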