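makeTable <- function(keys, def = ClonotypeDefinition()) {
    buildClonotypeTable(cdr3Set(keys), def)
}

test_that("top clonotypes follow the deterministic tie-break", {
    tab <- makeTable(c(rep("A", 5), rep("B", 5), "C"))
    top2 <- topClonotypes(tab, 2)
    expect_equal(clonotypes(top2)$key, c("A", "B"))
    ## c larger than the table returns the whole table
    expect_equal(nrow(clonotypes(topClonotypes(tab, 50))), 3L)
    expect_equal(clonotypes(topClonotypes(makeTable(
        c(rep("X", 10), rep("Y", 3))), 1))$key, "X")
})

test_that("pairwise comparison unions top lists with per-sample frequencies", {
    a <- makeTable(c(rep("P", 5), rep("Q", 3), rep("R", 2)))
    b <- makeTable(c(rep("Q", 3), rep("S", 2)))
    rep <- pairwiseCompare(a, b, c = 2)
    freq <- comparisonFrequencies(rep)
    expect_setequal(rownames(freq), c("P", "Q", "S"))
    expect_equal(freq["Q", ], c(a = 30, b = 60))
    expect_equal(freq["P", ], c(a = 50, b = 0))
    expect_equal(freq["S", ], c(a = 0, b = 40))
    ## every nonzero frequency equals the source table's exactly
    expect_equal(freq["Q", "a"],
                 clonotypes(a)$frequency[clonotypes(a)$key == "Q"])
})

test_that("self-comparison yields identical columns", {
    a <- makeTable(sample(LETTERS[1:8], 100, replace = TRUE))
    rep <- pairwiseCompare(a, a, c = 5)
    freq <- comparisonFrequencies(rep)
    expect_equal(freq[, 1], freq[, 2])
    expect_true(all(freq[, 1] > 0))
})

test_that("disjoint samples overlap nowhere", {
    a <- makeTable(rep(c("AA", "AB"), 3))
    b <- makeTable(rep(c("BA", "BB"), 3))
    freq <- comparisonFrequencies(pairwiseCompare(a, b, c = 5))
    expect_true(all(rowSums(freq == 0) == 1))
})

test_that("comparison requires a shared definition", {
    a <- makeTable(c("A", "B"))
    b <- buildClonotypeTable(cdr3Set(c("A", "B")),
                             ClonotypeDefinition("CDR3_AA",
                                                 include = "productive"))
    expect_error(pairwiseCompare(a, b, c = 2), "same clonotype definition")
})

test_that("multi-sample key sets are order-invariant; colors are stable", {
    set.seed(51)
    tabs <- lapply(1:3, function(i)
        makeTable(sample(paste0("K", 1:15), 200, replace = TRUE)))
    r1 <- multiCompare(tabs, c = 4)
    r2 <- multiCompare(rev(tabs), c = 4)
    expect_setequal(r1@keys, r2@keys)
    ## stable deterministic colour per key across reports
    m <- match(r1@keys, r2@keys)
    expect_equal(r1@colorIndex, r2@colorIndex[m])
    ## three identical tables give identical columns
    same <- multiCompare(list(tabs[[1]], tabs[[1]], tabs[[1]]), c = 4)
    freq <- comparisonFrequencies(same)
    expect_equal(freq[, 1], freq[, 2])
    expect_equal(freq[, 2], freq[, 3])
})

test_that("persistent simulated clonotypes stay nonzero in all samples", {
    persistent <- c(rep("CORE1", 40), rep("CORE2", 30))
    tabs <- lapply(1:3, function(i)
        makeTable(c(persistent, paste0("S", i, "_", 1:30))))
    freq <- comparisonFrequencies(multiCompare(tabs, c = 2))
    expect_true(all(freq["CORE1", ] > 0))
    expect_true(all(freq["CORE2", ] > 0))
    others <- setdiff(rownames(freq), c("CORE1", "CORE2"))
    expect_true(all(apply(freq[others, , drop = FALSE], 1,
                          function(r) any(r == 0))))
})

test_that("trajectories come out in long format over timepoints", {
    tabs <- list(T1 = makeTable(c(rep("A", 6), rep("B", 4))),
                 T2 = makeTable(c(rep("A", 6), rep("B", 4))),
                 T3 = makeTable(c(rep("A", 6), rep("B", 4))))
    tr <- trackClonotypes(tabs, keys = c("A", "B"))
    expect_equal(nrow(tr), 6L)  # 2 keys x 3 timepoints
    expect_equal(tr$frequency[tr$key == "A"], rep(60, 3))
    ## a key absent everywhere yields an all-zero trajectory
    tr0 <- trackClonotypes(tabs, keys = "ZZZ")
    expect_equal(tr0$frequency, rep(0, 3))
    expect_error(trackClonotypes(tabs[1]), "two timepoints")
})

test_that("comparison reports export as wide TSV", {
    a <- makeTable(c(rep("P", 5), rep("Q", 5)))
    b <- makeTable(c(rep("Q", 5), rep("R", 5)))
    path <- file.path(withr::local_tempdir(), "cmp.tsv")
    exportComparison(pairwiseCompare(a, b, c = 2,
                                     sampleIds = c("s1", "s2")), path)
    back <- read.delim(path)
    expect_setequal(back$key, c("P", "Q", "R"))
    expect_true(all(c("s1", "s2", "color_index", "in_top_of") %in%
                    colnames(back)))
})
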