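test_that("functionality summary counts partition the input", {
    rs <- cdr3Set(rep("ASSX", 10),
                  functionality = c(rep("productive", 6),
                                    rep("unproductive", 2),
                                    "unknown", "no_result"))
    s <- summarizeFunctionality(rs)
    expect_equal(s$total, 10L)
    expect_equal(sum(s$counts), s$total)
    expect_equal(unname(s$counts),  c(6L, 2L, 1L, 1L))
    expect_equal(sum(s$frequencies), 1)

    ## empty input: zero counts, zero frequencies
    s0 <- summarizeFunctionality(cdr3Set(character()))
    expect_equal(s0$total, 0L)
    expect_true(all(s0$counts == 0L) && all(s0$frequencies == 0))

    ## single class
    s1 <- summarizeFunctionality(cdr3Set(rep("A", 10)))
    expect_equal(unname(s1$frequencies["productive"]), 1)
})

test_that("gene usage tallies calls, excluding missing from denominator", {
    rs <- vdjSet(v = c("TRBV6-4*01", "TRBV6-4*01", "TRBV12-3*01",
                       "TRBV12-3*01"),
                 d = NA, j = "TRBJ2-1*01")
    u <- geneUsage(rs, "V")
    expect_equal(u$name, c("TRBV12-3", "TRBV6-4"))  # tie broken by name
    expect_equal(u$count, c(2L, 2L))
    expect_equal(u$frequency, c(0.5, 0.5))

    ## no D calls -> empty table (light-chain-like case)
    expect_equal(nrow(geneUsage(rs, "D")), 0L)
})

test_that("allele level distinguishes what gene level merges", {
    rs <- vdjSet(v = c("TRBV6-4*01", "TRBV6-4*02", "TRBV6-4*01"),
                 d = "TRBD1*01", j = "TRBJ1-1*01")
    gene <- geneUsage(rs, "V", level = "gene")
    allele <- geneUsage(rs, "V", level = "allele")
    expect_equal(nrow(gene), 1L)
    expect_equal(gene$count, 3L)
    expect_equal(allele$name, c("TRBV6-4*01", "TRBV6-4*02"))
    expect_equal(allele$count, c(2L, 1L))
    expect_gte(nrow(allele), nrow(gene))
})

test_that("clonotype keys follow the chosen mode and include-set", {
    rs <- RepertoireSet(
        sequence_id = c("r1", "r2", "r3"),
        functionality = c("productive", "productive", "no_result"),
        v_call = c("Homsap TRBV6-4*01 F", "TRBV12-3*01", NA),
        d_call = c("Homsap TRBD2*01 F", NA, NA),
        j_call = c("Homsap TRBJ2-1*01 F", "TRBJ2-7*01", NA),
        cdr3_aa = c("ASSMGQNNEQF", "assff ", NA),
        cdr3_nt = c("GCTAGC", "TTTAAA", NA),
        sequence_nt = c("ACGTACGT", "GGGTTT", NA))
    expect_equal(clonotypeKey(rs, ClonotypeDefinition("CDR3_AA")),
                 c("ASSMGQNNEQF", "ASSFF", NA))
    expect_equal(clonotypeKey(rs, ClonotypeDefinition("VDJ_GENES")),
                 c("TRBV6-4|TRBD2|TRBJ2-1", "TRBV12-3|-|TRBJ2-7", NA))
    expect_equal(
        clonotypeKey(rs, ClonotypeDefinition("VDJ_GENES",
                                             level = "allele"))[1],
        "TRBV6-4*01|TRBD2*01|TRBJ2-1*01")
    expect_equal(clonotypeKey(rs, ClonotypeDefinition("WHOLE_READ_NT"))[2],
                 "GGGTTT")
    ## productive-only excludes nothing here but a restricted include does
    onlyUnprod <- ClonotypeDefinition("CDR3_AA", include = "unproductive")
    expect_true(all(is.na(clonotypeKey(rs, onlyUnprod))))
})

test_that("clonotype tables match an independent dictionary tally", {
    keys <- c("A", "A", "A", "B")
    tab <- buildClonotypeTable(cdr3Set(keys))
    expect_equal(clonotypes(tab)$key, c("A", "B"))
    expect_equal(clonotypes(tab)$count, c(3L, 1L))
    expect_equal(clonotypes(tab)$frequency, c(75, 25))
    expect_equal(nRecordsUsed(tab), 4L)

    ## simulated repertoire vs oracle
    sim <- simulateRepertoire(SimulationConfig(nClonotypes = 50,
                                               nReads = 1000, seed = 9))
    tab <- buildClonotypeTable(sim$records)
    keys <- clonotypeKey(sim$records, definition(tab))
    oracle <- dictTally(keys[!is.na(keys)])
    got <- setNames(clonotypes(tab)$count, clonotypes(tab)$key)
    expect_equal(got[order(names(got), method = "radix")], oracle)
    expect_equal(sum(clonotypes(tab)$count), nRecordsUsed(tab))
    expect_equal(sum(clonotypes(tab)$frequency), 100, tolerance = 1e-9)

    ## all records excluded -> empty table
    none <- buildClonotypeTable(cdr3Set(rep("K", 5), "no_result"))
    expect_equal(length(none), 0L)
    expect_equal(nRecordsUsed(none), 0L)
})

test_that("no_result can never enter a clonotype definition", {
    expect_error(ClonotypeDefinition("CDR3_AA",
                                     include = c("productive", "no_result")),
                 "no_result")
})

test_that("tables export as TSV with header", {
    tab <- buildClonotypeTable(cdr3Set(c("A", "A", "B")))
    path <- file.path(withr::local_tempdir(), "clono.tsv")
    exportTable(tab, path)
    back <- read.delim(path)
    expect_equal(back$key, c("A", "B"))
    expect_equal(back$count, c(2L, 1L))
})
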