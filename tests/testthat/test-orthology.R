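mkGenes <- function(scaffold, starts, symbols, width = 1000) {
    GenomicRanges::GRanges(scaffold,
                           IRanges::IRanges(starts, starts + width - 1L),
                           symbol = symbols)
}

mkUnitSet <- function(scaffold, starts, ends, mt_list, species = "T") {
    n <- length(starts)
    gr <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(starts, ends))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        numt_id = sprintf("%s_numt_%d", species, seq_len(n)),
        identity = rep(90, n),
        mt_intervals = IRanges::IRangesList(mt_list),
        n_hsps = rep(1L, n))
    NumtSet(gr, species = species)
}

test_that("reciprocal mitogenome overlap handles wrap and boundaries", {
    a <- IRanges::IRanges(1, 200)
    expect_equal(mtOverlapFraction(a, a), 1)
    b <- IRanges::IRanges(101, 300)
    expect_equal(mtOverlapFraction(a, b), 0.5)
    # wrapped footprints: [16501..16600 + 1..100] vs [16551..16600 + 1..150]
    w1 <- IRanges::IRanges(c(16501, 1), c(16600, 100))
    w2 <- IRanges::IRanges(c(16551, 1), c(16600, 150))
    expect_equal(mtOverlapFraction(w1, w2), 0.75)
    expect_error(mtOverlapFraction(IRanges::IRanges(), a), "empty")
})

test_that("synteny contexts pick the k nearest genes per side, nearest first", {
    genes <- mkGenes("s", c(1000, 3000, 5000, 9000, 11000, 13000, 15000),
                     c("A", "B", "C", "D", "E", "F", "G"))
    units <- mkUnitSet("s", 7000, 7200, list(IRanges::IRanges(1, 200)))
    ctx <- buildSyntenyContext(units, genes)
    expect_equal(ctx$up_anchors[[1]], c("C", "B", "A"))
    expect_equal(ctx$down_anchors[[1]], c("D", "E", "F"))
    # near the scaffold start only one upstream gene exists
    units2 <- mkUnitSet("s", 2200, 2400, list(IRanges::IRanges(1, 200)))
    ctx2 <- buildSyntenyContext(units2, genes)
    expect_equal(ctx2$up_anchors[[1]], "A")
    expect_equal(length(ctx2$down_anchors[[1]]), 3L)
    # an intronic unit records its host separately, anchors unchanged
    units3 <- mkUnitSet("s", 9100, 9300, list(IRanges::IRanges(1, 200)))
    ctx3 <- buildSyntenyContext(units3, genes)
    expect_equal(ctx3$host[[1]], "D")
    expect_false("D" %in% c(ctx3$up_anchors[[1]], ctx3$down_anchors[[1]]))
    # duplicated symbols are ambiguous and excluded
    genes_dup <- mkGenes("s", c(1000, 3000, 5000), c("A", "B", "A"))
    expect_warning(buildSyntenyContext(units, genes_dup), "ambiguous")
})

test_that("ortholog assignment requires shared anchors and 50% overlap", {
    genes <- mkGenes("s", c(1000, 3000, 9000, 11000), c("A", "B", "C", "D"))
    uA <- mkUnitSet("s", 5000, 5200, list(IRanges::IRanges(100, 299)), "Aaa")
    ctxA <- buildSyntenyContext(uA, genes)
    uB <- mkUnitSet("s", 5100, 5300, list(IRanges::IRanges(100, 299)), "Bbb")
    ctxB <- buildSyntenyContext(uB, genes)
    p <- assignOrthologs(ctxA, ctxB)
    expect_equal(nrow(p), 1L)
    expect_equal(p$overlap, 1)
    # overlap 0.49: rejected at the boundary
    uB2 <- mkUnitSet("s", 5100, 5300, list(IRanges::IRanges(202, 401)), "Bbb")
    expect_equal(nrow(assignOrthologs(ctxA, buildSyntenyContext(uB2, genes))),
                 0L)
    # overlap exactly 0.50 passes
    uB3 <- mkUnitSet("s", 5100, 5300, list(IRanges::IRanges(200, 399)), "Bbb")
    expect_equal(nrow(assignOrthologs(ctxA, buildSyntenyContext(uB3, genes))),
                 1L)
})

test_that("greedy resolution is one-to-one by descending overlap", {
    genes <- mkGenes("s", c(1000, 3000, 9000, 11000), c("A", "B", "C", "D"))
    uA <- mkUnitSet("s", 5000, 5200, list(IRanges::IRanges(1, 1000)), "Aaa")
    ctxA <- buildSyntenyContext(uA, genes)
    uB <- mkUnitSet("s", c(5000, 7500), c(5200, 7700),
                    list(IRanges::IRanges(1, 900),      # overlap 0.9
                         IRanges::IRanges(1, 600)),     # overlap 0.6
                    "Bbb")
    ctxB <- buildSyntenyContext(uB, genes)
    p <- assignOrthologs(ctxA, ctxB)
    expect_equal(nrow(p), 1L)
    expect_equal(p$unit_b, "Bbb_numt_1")
    expect_equal(p$overlap, 0.9)
})

test_that("assignment is symmetric and one-to-one on random fixtures", {
    set.seed(21)
    genes <- mkGenes("s", seq(1000, by = 4000, length.out = 30),
                     sprintf("G%02d", 1:30))
    for (rep in 1:10) {
        mk <- function(sp) {
            n <- sample(4:10, 1)
            st <- sort(sample(seq(2500, 118000, by = 100), n))
            mt <- lapply(seq_len(n), function(i) {
                s <- sample.int(16000, 1)
                IRanges::IRanges(s, s + sample(100:400, 1))
            })
            buildSyntenyContext(mkUnitSet("s", st, st + 150, mt, sp), genes)
        }
        ca <- mk("Aaa"); cb <- mk("Bbb")
        ab <- assignOrthologs(ca, cb)
        ba <- assignOrthologs(cb, ca)
        expect_setequal(paste(ab$unit_a, ab$unit_b),
                        paste(ba$unit_b, ba$unit_a))
        expect_false(anyDuplicated(ab$unit_a) > 0)
        expect_false(anyDuplicated(ab$unit_b) > 0)
    }
})

test_that("the analytic error rate reproduces its stated value", {
    expect_equal(signif(errorRate(), 3), 3.03e-6)
    # exact-coincidence variant: (5/20000) * (1/16600)
    expect_equal(errorRate(f = 1), (5 / 20000) * (1 / 16600))
    expect_error(errorRate(G = 4, k = 3), "2k")
    expect_error(errorRate(f = 0), "f must")
    expect_error(errorRate(L = 30000), "exceed")
})

test_that("Monte-Carlo placement agrees with the analytic rate", {
    # scaled-down genome: G = 200 gene slots, M = 1,660 bp circle
    set.seed(31)
    G <- 200; M <- 1660; L <- 200; k <- 3; f <- 0.5
    n <- 1e6
    slotA <- sample.int(G, n, replace = TRUE)
    slotB <- sample.int(G, n, replace = TRUE)
    dslot <- pmin(abs(slotA - slotB), G - abs(slotA - slotB))
    same_window <- dslot <= k - 1
    sA <- sample.int(M, n, replace = TRUE)
    sB <- sample.int(M, n, replace = TRUE)
    dmt <- pmin(abs(sA - sB), M - abs(sA - sB))
    overlap_ok <- (L - dmt) >= ceiling(f * L)
    emp <- mean(same_window & overlap_ok)
    rate <- errorRate(G = G, L = L, M = M, k = k, f = f)
    se <- sqrt(rate * (1 - rate) / n)
    expect_lt(abs(emp - rate), 3 * se)
})

test_that("error expectation scales with unit counts and flags E >= 1", {
    expect_equal(errorExpectation(3.03e-6, 0, 500), 0)
    expect_equal(errorExpectation(3.03e-6, 100, 100), 0.0303)
    expect_warning(errorExpectation(3.03e-6, 4000, 90000), "unreliable")
    expect_error(errorExpectation(1e-6, -1, 5), ">= 0")
})
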