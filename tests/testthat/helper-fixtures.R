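## Shared fixture builders. Everything is generated in code; nothing is
## read from disk except files the helpers themselves write to tempdirs.

## A RepertoireSet with the given CDR3 amino-acid keys, all productive
## unless a functionality vector is supplied.
cdr3Set <- function(keys, functionality = "productive") {
    RepertoireSet(sequence_id = sprintf("r%04d", seq_along(keys)),
                  functionality = functionality,
                  cdr3_aa = keys)
}

## A RepertoireSet with full V/D/J calls (raw IMGT-style tokens).
vdjSet <- function(v, d, j, functionality = "productive") {
    RepertoireSet(sequence_id = sprintf("r%04d", seq_along(v)),
                  functionality = functionality,
                  v_call = v, d_call = d, j_call = j,
                  cdr3_aa = "ASSX")
}

## Write a random FASTA of `n` records with variable line wrapping and
## return its path.
writeRandomFasta <- function(n, dir = NULL, seed = 1, lineWidth = 20L) {
    if (is.null(dir)) {
        dir <- tempfile("fasta")
        dir.create(dir)
    }
    set.seed(seed)
    path <- file.path(dir, sprintf("random_%d.fasta", n))
    con <- file(path, "wt")
    on.exit(close(con))
    for (i in seq_len(n)) {
        len <- sample(10:60, 1)
        seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        writeLines(paste0(">seq", i, " desc", i), con)
        starts <- seq(1L, len, by = lineWidth)
        writeLines(substring(seq, starts,
                             pmin(starts + lineWidth - 1L, len)), con)
    }
    path
}

## Independent one-pass dictionary tally of keys (the clonotype-count
## oracle: no table()/factor machinery shared with the implementation).
dictTally <- function(keys) {
    env <- new.env(hash = TRUE, parent = emptyenv())
    for (k in keys) {
        prev <- if (exists(k, envir = env, inherits = FALSE))
            get(k, envir = env) else 0L
        assign(k, prev + 1L, envir = env)
    }
    counts <- vapply(ls(env, sorted = FALSE), get, 0L, envir = env)
    counts[order(names(counts), method = "radix")]
}

## Build a DiversityCurve directly from (n, y) values, bypassing
## rarefaction, for model-fitting tests.
makeCurve <- function(n, y) {
    new("DiversityCurve", N = as.integer(max(n)), nGrid = as.integer(n),
        replicateCounts = matrix(y, ncol = 1),
        divCalc = as.numeric(y), replicates = 1L, seed = 0L)
}

## Seeded standard-normal noise vector without touching the global RNG
## stream of the surrounding test.
withSeedNoise <- function(seed, n) {
    state <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv())
    set.seed(seed)
    x <- rnorm(n)
    if (!is.null(state)) assign(".Random.seed", state, globalenv())
    x
}

## Primer set from name/sequence/orientation vectors.
makePrimerSet <- function(name, sequence, orientation) {
    new("PrimerSet", setName = "test",
        primerTable = S4Vectors::DataFrame(name = name, sequence = sequence,
                                           orientation = orientation))
}
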