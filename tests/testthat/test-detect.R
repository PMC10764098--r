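test_that("HSP filtering applies the e-value and length thresholds", {
    h <- hspTable(
        hspRow("s", 1, 50, 100, 149, e_value = 1e-4),
        hspRow("s", 100, 599, 200, 699, e_value = 1e-2),
        hspRow("s", 700, 728, 300, 328, e_value = 1e-10)
    )
    kept <- filterHsps(h)
    expect_equal(nrow(kept), 1L)
    expect_equal(kept$n_start, 1L)
    # boundary: e-value equal to the threshold is kept, length 30 is kept
    h2 <- hspTable(hspRow("s", 1, 30, 1, 30, e_value = 1e-3))
    expect_equal(nrow(filterHsps(h2)), 1L)
})

test_that("continuing HSPs merge across nuclear and mitogenome gaps", {
    h <- hspTable(
        hspRow("scaf1", 1001, 1200, 301, 500, identity = 90),
        hspRow("scaf1", 1206, 1400, 502, 696, identity = 100)
    )
    ns <- mergeHsps(h, mt_length = 16600, species = "Hsap")
    expect_equal(length(ns), 1L)
    df <- as.data.frame(ns)
    expect_equal(df$start, 1001L)
    expect_equal(df$end, 1400L)
    expect_equal(df$numt_id, "Hsap_numt_1")
    fp <- mtFootprint(ns)[[1]]
    expect_equal(IRanges::start(fp), 301L)
    expect_equal(IRanges::end(fp), 696L)
    # alignment-length-weighted identity: (90*200 + 100*195)/395
    expect_equal(df$identity, (90 * 200 + 100 * 195) / 395)
})

test_that("a D-loop-spanning insertion merges across the circular boundary", {
    h <- hspTable(
        hspRow("scaf1", 1001, 1100, 16501, 16600),
        hspRow("scaf1", 1104, 1300, 1, 197)
    )
    ns <- mergeHsps(h, mt_length = 16600)
    expect_equal(length(ns), 1L)
    fp <- mtFootprint(ns)[[1]]
    expect_equal(IRanges::start(fp), c(1L, 16501L))
    expect_equal(IRanges::end(fp), c(197L, 16600L))
    # and on the minus strand (tail piece first along the nucleus)
    hm <- hspTable(
        hspRow("scaf1", 1001, 1197, 1, 197, orientation = "-"),
        hspRow("scaf1", 1201, 1300, 16501, 16600, orientation = "-")
    )
    nsm <- mergeHsps(hm, mt_length = 16600)
    expect_equal(length(nsm), 1L)
    expect_equal(as.character(BiocGenerics::strand(granges(nsm))), "-")
})

test_that("large nuclear gaps and orientation switches block merging", {
    h <- hspTable(
        hspRow("scaf1", 1001, 1200, 301, 500),
        hspRow("scaf1", 1251, 1400, 501, 650)   # gap = 50 bp
    )
    expect_equal(length(mergeHsps(h, 16600)), 2L)
    # boundary: gap of exactly nuclear_gap_max does not merge
    h2 <- hspTable(
        hspRow("scaf1", 1001, 1200, 301, 500),
        hspRow("scaf1", 1211, 1400, 501, 690)   # gap = 10 bp
    )
    expect_equal(length(mergeHsps(h2, 16600)), 2L)
    h3 <- hspTable(
        hspRow("scaf1", 1001, 1200, 301, 500),
        hspRow("scaf1", 1205, 1400, 501, 696, orientation = "-")
    )
    expect_equal(length(mergeHsps(h3, 16600)), 2L)
})

test_that("merging matches the brute-force oracle on random instances and is idempotent", {
    set.seed(101)
    for (rep in 1:60) {
        h <- randomHspInstance(sample(2:50, 1))
        ns <- suppressWarnings(mergeHsps(h, mt_length = 16600, species = "T"))
        orc <- oracleMergeHsps(h, mt_length = 16600)
        df <- as.data.frame(ns)
        df <- df[order(df$start), ]
        expect_equal(df$start, orc$n_start)
        expect_equal(df$end, orc$n_end)
        expect_equal(df$n_hsps, orc$n_hsps)
        expect_equal(df$identity, orc$identity, tolerance = 1e-10)
    }
})

test_that("merging already-merged records is the identity", {
    # records separated by the rule (nuclear gap >= 10 or discontinuous
    # mitogenome coordinates) stay untouched on a second pass
    h <- hspTable(
        hspRow("s", 1, 200, 1000, 1199),
        hspRow("s", 215, 400, 1200, 1385),     # nuclear gap 14: separate
        hspRow("s", 405, 600, 5000, 5195),     # mt jump: separate
        hspRow("s", 603, 800, 5196, 5393)      # continues: merges with prev
    )
    once <- mergeHsps(h, 16600)
    expect_equal(length(once), 3L)
    twice <- mergeHsps(as.data.frame(once) |>
        (\(df) hspTable(
            hspRow("s", df$start[1], df$end[1], 1000, 1199),
            hspRow("s", df$start[2], df$end[2], 1200, 1385),
            hspRow("s", df$start[3], df$end[3], 5000, 5393)))(), 16600)
    expect_equal(as.data.frame(twice)[, c("start", "end")],
                 as.data.frame(once)[, c("start", "end")])
})

test_that("the short-contig filter is strict and renumbers densely", {
    h <- hspTable(
        hspRow("small", 100, 200, 1, 101),
        hspRow("edge", 100, 200, 1, 101),
        hspRow("big", 100, 200, 1, 101),
        hspRow("big", 5000, 5100, 300, 400)
    )
    gi <- GenomeInfoDb::Seqinfo(c("small", "edge", "big"),
                                c(15000L, 20000L, 1000000L))
    ns <- mergeHsps(h, 16600, species = "Hsap", genome_index = gi)
    out <- filterByContigLength(ns, gi)
    df <- as.data.frame(out)
    expect_equal(df$scaffold, c("edge", "big", "big"))
    # 20,000 bp contig kept: the filter is strictly < 20 kb
    expect_equal(df$numt_id, c("Hsap_numt_1", "Hsap_numt_2", "Hsap_numt_3"))
    gi2 <- GenomeInfoDb::Seqinfo("other", 1000L)
    expect_error(filterByContigLength(ns, gi2), "not in genome index")
})

test_that("block assembly chains by strict 2 kb gaps and flags complexity", {
    mk <- function(coords) {
        h <- do.call(hspTable, lapply(seq_len(nrow(coords)), function(i)
            hspRow("s", coords[i, 1], coords[i, 2],
                   (i - 1) * 500 + 1, (i - 1) * 500 + coords[i, 2] - coords[i, 1] + 1)))
        mergeHsps(h, 16600, species = "T")
    }
    # gaps of 1000 and 1500 bp chain into one complex block
    ns <- mk(rbind(c(1, 100), c(1101, 1200), c(2701, 2800)))
    bs <- assembleBlocks(ns)
    expect_equal(length(bs), 1L)
    expect_true(unname(isComplex(bs)[1]))
    expect_equal(unname(lengths(blockMembers(bs))), 3L)
    # gap of exactly 2000 bp splits
    ns2 <- mk(rbind(c(1, 100), c(2101, 2200)))
    bs2 <- assembleBlocks(ns2)
    expect_equal(length(bs2), 2L)
    expect_false(any(isComplex(bs2)))
    # isolated NUMT: singleton block
    ns3 <- mk(rbind(c(1, 100)))
    expect_equal(length(assembleBlocks(ns3)), 1L)
})

test_that("block assembly equals the quadratic connected-components oracle", {
    set.seed(77)
    for (rep in 1:40) {
        n <- sample(2:40, 1)
        scaf <- sample(c("a", "b"), n, replace = TRUE)
        st <- sample.int(50000, n)
        en <- st + sample(30:3000, n, replace = TRUE)
        gr <- GenomicRanges::GRanges(scaf, IRanges::IRanges(st, en))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            numt_id = sprintf("T_numt_%d", seq_len(n)),
            identity = rep(90, n),
            mt_intervals = IRanges::IRangesList(
                lapply(seq_len(n), function(i) IRanges::IRanges(1, 100))),
            n_hsps = rep(1L, n))
        ns <- NumtSet(gr, species = "T")
        bs <- assembleBlocks(ns)
        truth <- oracleBlocks(st, en, scaf)
        # same partition: members of each block = one oracle component
        got <- blockMembers(bs)
        ids <- numtIds(ns)
        expected_sets <- lapply(split(ids, truth), sort)
        got_sets <- lapply(as.list(got), sort)
        expect_setequal(unname(vapply(got_sets, paste, "", collapse = ",")),
                        unname(vapply(expected_sets, paste, "", collapse = ",")))
        # blocks partition the NUMTs
        expect_equal(sum(lengths(got)), length(ns))
        expect_equal(sort(unlist(got, use.names = FALSE)), sort(ids))
    }
})

test_that("tandem duplicate detection applies all three rules", {
    mkNumt <- function(starts_ends_mt) {
        n <- nrow(starts_ends_mt)
        gr <- GenomicRanges::GRanges("s",
            IRanges::IRanges(starts_ends_mt[, 1], starts_ends_mt[, 2]))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            numt_id = sprintf("T_numt_%d", seq_len(n)),
            identity = rep(90, n),
            mt_intervals = IRanges::IRangesList(lapply(seq_len(n), function(i)
                IRanges::IRanges(starts_ends_mt[i, 3], starts_ends_mt[i, 4]))),
            n_hsps = rep(1L, n))
        NumtSet(gr, species = "T")
    }
    # 4 kb apart, similar mt starts, heavy overlap: duplicate pair
    dup <- findTandemDuplicates(mkNumt(rbind(c(1000, 1200, 100, 300),
                                             c(5200, 5405, 105, 310))))
    expect_equal(nrow(dup), 1L)
    # same mt coordinates but 50 kb apart: not reported
    far <- findTandemDuplicates(mkNumt(rbind(c(1000, 1200, 100, 300),
                                             c(51300, 51500, 100, 300))))
    expect_equal(nrow(far), 0L)
    # nearby but disjoint mt footprints: not reported
    disj <- findTandemDuplicates(mkNumt(rbind(c(1000, 1200, 100, 300),
                                              c(5200, 5400, 500, 700))))
    expect_equal(nrow(disj), 0L)
})

test_that("summary statistics follow their definitions", {
    h <- hspTable(hspRow("s", 1, 100, 1, 100, identity = 97),
                  hspRow("s", 5000, 5099, 300, 399, identity = 99))
    gi <- GenomeInfoDb::Seqinfo("s", 1000000L)
    ns <- mergeHsps(h, 16600, species = "T", genome_index = gi)
    sm <- numtSummary(ns, assembleBlocks(ns), gi)
    expect_equal(sm$cumulative_bp, 200L)
    expect_equal(sm$genome_fraction, 2e-4)
    expect_equal(sm$frac_identity_above_cut, 0.5)
    # boundary: identity exactly 98 does not count as "above 98%"
    h2 <- hspTable(hspRow("s", 1, 100, 1, 100, identity = 98))
    sm2 <- numtSummary(mergeHsps(h2, 16600), genome_index = gi)
    expect_equal(sm2$frac_identity_above_cut, 0)
    # empty set: zero counts, undefined identity statistics
    sm0 <- numtSummary(NumtSet(species = "T"), genome_index = gi)
    expect_equal(sm0$n_numts, 0L)
    expect_true(is.na(sm0$mean_identity))
})

test_that("length-distribution comparison separates within- from across-order pairs", {
    # identical length lists: KS p = 1
    ls <- list(a = c(100, 200, 300), b = c(100, 200, 300))
    r <- compareLengthDistributions(ls, c(a = "O1", b = "O1"))
    expect_equal(r$p_matrix["a", "b"], 1, tolerance = 1e-9)
    # fully disjoint ranges at n = 50: exact KS statistic D = 1, p < 1e-6
    set.seed(1)
    ls2 <- list(a = runif(50, 90, 110), b = runif(50, 9000, 11000))
    r2 <- compareLengthDistributions(ls2, c(a = "O1", b = "O2"))
    expect_lt(r2$p_matrix["a", "b"], 1e-6)
    # two orders, identical within, shifted across: within-order p larger
    set.seed(2)
    base1 <- rlnorm(60, log(200), 0.5)
    base2 <- base1 * 8
    ls3 <- list(a1 = base1, a2 = base1 + 0.01, a3 = base1 + 0.02,
                b1 = base2, b2 = base2 + 0.01, b3 = base2 + 0.02)
    r3 <- compareLengthDistributions(
        ls3, c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B"))
    expect_gt(mean(r3$within_log10p), mean(r3$across_log10p))
    expect_lt(r3$contrast_p, 0.05)
    # species with < 2 NUMTs are excluded with a warning
    expect_warning(
        compareLengthDistributions(c(ls, list(tiny = 5)),
                                   c(a = "O1", b = "O1", tiny = "O2")),
        "excluding")
})
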