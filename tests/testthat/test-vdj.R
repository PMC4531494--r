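test_that("gene calls parse species, allele, flag and multi-hits", {
    p <- parseGeneCall("Homsap TRBV6-4*01 F")
    expect_equal(p$locus, "TRB")
    expect_equal(p$segment, "V")
    expect_equal(p$gene, "TRBV6-4")
    expect_equal(p$allele, "01")
    ## minimal form
    p2 <- parseGeneCall("TRBJ2-1")
    expect_equal(p2$gene, "TRBJ2-1")
    expect_true(is.na(p2$allele))
    ## ambiguous multi-hit: first (highest-scoring) call wins
    p3 <- parseGeneCall("Homsap IGHV1-69*06 F, or Homsap IGHV1-69D*01 F")
    expect_equal(p3$gene, "IGHV1-69")
    expect_equal(p3$allele, "06")
    ## unrecognizable token carries the raw text
    expect_error(parseGeneCall("not-a-gene"), "not-a-gene")
})

test_that("combination matrices tally complete-call reads only", {
    rs <- vdjSet(v = c("TRBV6-4*01", "TRBV6-4*01", "TRBV12-3*01"),
                 d = c("TRBD2*01", "TRBD2*01", "TRBD1*01"),
                 j = "TRBJ2-1*01")
    m <- combinationMatrix(rs, c("V", "D", "J"))
    tab <- cells(m)
    expect_equal(nrow(tab), 2L)
    expect_equal(tab$count, c(2L, 1L))
    expect_equal(tab$V, c("TRBV6-4", "TRBV12-3"))
    expect_equal(matrixTotal(m), 3L)
    expect_equal(sum(tab$count), matrixTotal(m))

    ## missing D calls with a D axis: empty matrix, total zero
    noD <- vdjSet(v = "TRBV9*01", d = NA, j = "TRBJ1-1*01")
    m0 <- combinationMatrix(noD, c("V", "D"))
    expect_equal(nrow(cells(m0)), 0L)
    expect_equal(matrixTotal(m0), 0L)
})

test_that("combination counts equal a brute-force nested tally", {
    sim <- simulateRepertoire(SimulationConfig(nClonotypes = 40,
                                               nReads = 500, seed = 31))
    m <- combinationMatrix(sim$records, c("V", "J"), level = "allele")
    rec <- records(sim$records)
    ok <- !is.na(rec$v_call) & !is.na(rec$j_call)
    brute <- list()
    for (i in which(ok)) {
        v <- sub(" F$", "", sub("^Homsap ", "", rec$v_call[i]))
        j <- sub(" F$", "", sub("^Homsap ", "", rec$j_call[i]))
        key <- paste(v, j, sep = "|")
        brute[[key]] <- (if (is.null(brute[[key]])) 0L else brute[[key]]) + 1L
    }
    tab <- cells(m)
    got <- setNames(tab$count, paste(tab$V, tab$J, sep = "|"))
    expect_equal(sort(names(got)), sort(names(brute)))
    expect_equal(got[names(brute)],
                 setNames(unlist(brute), names(brute)))
})

test_that("marginalizing V-D-J over D reproduces the V-J matrix", {
    sim <- simulateRepertoire(SimulationConfig(
        nClonotypes = 30, nReads = 400, seed = 8,
        functionalityMix = c(productive = 1, unproductive = 0,
                             unknown = 0, no_result = 0)))
    vdj <- combinationMatrix(sim$records, c("V", "D", "J"))
    vj <- combinationMatrix(sim$records, c("V", "J"))
    marg <- marginalizeMatrix(vdj, "D")
    key <- function(m) {
        tab <- cells(m)
        setNames(tab$count, paste(tab$V, tab$J, sep = "|"))
    }
    a <- key(marg); b <- key(vj)
    expect_equal(a[order(names(a))], b[order(names(b))])
    expect_equal(matrixTotal(marg), matrixTotal(vj))
})

test_that("allele-level matrices refine gene-level matrices", {
    rs <- vdjSet(v = c("TRBV6-4*01", "TRBV6-4*02", "TRBV6-4*01",
                       "TRBV28*01"),
                 d = "TRBD1*01", j = "TRBJ1-1*01")
    gene <- cells(combinationMatrix(rs, c("V", "J"), "gene"))
    allele <- cells(combinationMatrix(rs, c("V", "J"), "allele"))
    for (i in seq_len(nrow(gene))) {
        within <- startsWith(allele$V, gene$V[i])
        expect_equal(sum(allele$count[within]), gene$count[i])
    }
})

test_that("spectrum mapping zero-pads, aligns samples and keeps unknowns", {
    ref <- germlineReference()
    rs1 <- vdjSet(v = c("TRBV6-4*01", "TRBV9*01"), d = "TRBD1*01",
                  j = "TRBJ1-1*01")
    rs2 <- vdjSet(v = c("TRBV28*01", "TRBV28*01"), d = "TRBD2*01",
                  j = "TRBJ2-7*01")
    m1 <- mapToSpectrum(combinationMatrix(rs1, c("V", "J")), ref)
    m2 <- mapToSpectrum(combinationMatrix(rs2, c("V", "J")), ref)
    ## identical axes for disjoint samples mapped to the same reference
    expect_identical(m1@axisLevels, m2@axisLevels)
    expect_identical(cells(m1)$V, cells(m2)$V)
    ## counts conserved, all other cells explicit zeros
    expect_equal(sum(cells(m1)$count), matrixTotal(m1))
    expect_equal(sum(cells(m1)$count > 0), 2L)
    ## natural order: TRBV2 before TRBV6-4 before TRBV12-3
    v <- m1@axisLevels$V
    expect_lt(match("TRBV2", v), match("TRBV6-4", v))
    expect_lt(match("TRBV6-4", v), match("TRBV12-3", v))

    ## observed gene absent from the reference is warned about, kept
    odd <- vdjSet(v = "TRBV99*01", d = "TRBD1*01", j = "TRBJ1-1*01")
    expect_warning(mOdd <- mapToSpectrum(combinationMatrix(odd,
                                                           c("V", "J")),
                                         ref, locus = "TRB"),
                   "absent from reference")
    expect_true("TRBV99" %in% mOdd@axisLevels$V)
    expect_equal(sum(cells(mOdd)$count), matrixTotal(mOdd))
})

test_that("frequency thresholds filter cells without rescaling", {
    rs <- vdjSet(v = c(rep("TRBV6-4*01", 6), rep("TRBV9*01", 3),
                       "TRBV28*01"),
                 d = "TRBD1*01", j = "TRBJ1-1*01")
    m <- combinationMatrix(rs, c("V", "J"))
    ## threshold 0 is the identity
    expect_equal(nrow(cells(filterByThreshold(m, 0))), nrow(cells(m)))
    ## 0.25 keeps the 60% and 30% cells only
    kept <- cells(filterByThreshold(m, 0.25))
    expect_equal(nrow(kept), 2L)
    expect_equal(sort(kept$frequency), c(0.3, 0.6))
    expect_equal(matrixTotal(filterByThreshold(m, 0.25)), 10L)
    ## threshold 1 keeps nothing in a multi-cell matrix
    expect_equal(nrow(cells(filterByThreshold(m, 1))), 0L)
})
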