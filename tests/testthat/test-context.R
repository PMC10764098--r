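mkRepeats <- function(scaffold, starts, ends) {
    if (!length(starts))
        return(GenomicRanges::GRanges(repeat_class = character(),
                                      repeat_label = character()))
    GenomicRanges::GRanges(scaffold, IRanges::IRanges(starts, ends),
                           repeat_class = "LINE", repeat_label = "sim")
}

mkNumts <- function(scaffold, starts, ends, species = "T",
                    identity = rep(90, length(starts)),
                    mt_list = NULL) {
    n <- length(starts)
    if (is.null(mt_list))
        mt_list <- lapply(seq_len(n), function(i) IRanges::IRanges(1, 200))
    gr <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(starts, ends))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        numt_id = sprintf("%s_numt_%d", species, seq_len(n)),
        identity = identity,
        mt_intervals = IRanges::IRangesList(mt_list),
        n_hsps = rep(1L, n))
    NumtSet(gr, species = species)
}

test_that("flank TE fractions are per-window coverage ordered outward", {
    gi <- GenomeInfoDb::Seqinfo("s", 100000L)
    u <- mkNumts("s", 50001, 50200)
    # the whole upstream flank is one TE: all 10 windows = 1
    r <- flankTeProfile(u, mkRepeats("s", 45001, 50000), gi)
    up <- r[r$side == "up", ]
    expect_equal(up$te_fraction, rep(1, 10))
    expect_equal(r$te_fraction[r$side == "down"], rep(0, 10))
    # a TE covering the first 250 bp of downstream window 1: fraction 0.5
    r2 <- flankTeProfile(u, mkRepeats("s", 50201, 50450), gi)
    dn <- r2[r2$side == "down", ]
    expect_equal(dn$te_fraction[dn$window == 1], 0.5)
    expect_equal(dn$te_fraction[dn$window > 1], rep(0, 9))
    # no repeats at all: all zeros
    r3 <- flankTeProfile(u, mkRepeats("s", integer(0), integer(0)), gi)
    expect_true(all(r3$te_fraction == 0))
})

test_that("flank fractions are invariant to splitting TE intervals", {
    gi <- GenomeInfoDb::Seqinfo("s", 100000L)
    u <- mkNumts("s", 50001, 50200)
    whole <- flankTeProfile(u, mkRepeats("s", 46001, 48000), gi)
    split <- flankTeProfile(u, mkRepeats("s", c(46001, 47001), c(47000, 48000)),
                            gi)
    expect_equal(whole$te_fraction, split$te_fraction)
})

test_that("windows truncated at scaffold ends are flagged", {
    gi <- GenomeInfoDb::Seqinfo("s", 10000L)
    u <- mkNumts("s", 1201, 1400)   # only 1200 bp upstream available
    r <- flankTeProfile(u, mkRepeats("s", 1, 1200), gi)
    up <- r[r$side == "up", ]
    expect_equal(up$truncated, c(FALSE, FALSE, TRUE, rep(TRUE, 7)))
    expect_equal(up$te_fraction[1:3], c(1, 1, 1))
    expect_true(all(is.na(up$te_fraction[4:10])))
})

test_that("random placement respects the edge exclusion (property)", {
    set.seed(12)
    slen <- c(a = 30000L, b = 60000L)
    for (i in 1:500) {
        p <- numtkit:::.randomPlacement(500L, slen, 5000L)
        expect_gte(p$start, 5001L)
        expect_lte(p$end, slen[[p$scaffold]] - 5000L)
    }
    expect_warning(numtkit:::.randomPlacement(500L, c(a = 8000L), 5000L),
                   "no valid placement")
})

test_that("background placement recovers TE-free insertion-site signal", {
    # every species: TE everywhere except a clear zone around each NUMT,
    # reproducing the observed dip in the window adjoining the insertion
    set.seed(13)
    species <- sprintf("sp%d", 1:8)
    units_list <- list(); repeats_list <- list(); gi_list <- list()
    for (sp in species) {
        gi_list[[sp]] <- GenomeInfoDb::Seqinfo("s", 200000L)
        starts <- seq(30000, 170000, by = 20000)
        units_list[[sp]] <- mkNumts("s", starts, starts + 199, species = sp)
        clear <- IRanges::IRanges(starts - 500, starts + 699)
        tes <- IRanges::setdiff(IRanges::IRanges(1, 200000), clear)
        repeats_list[[sp]] <- GenomicRanges::GRanges("s", tes)
    }
    r <- backgroundTeProfile(units_list, repeats_list, gi_list,
                             n_iter = 10, seed = 14)
    # window 1 on both sides: observed 0, background near genome average
    expect_true(all(r$observed[, "up1"] == 0))
    expect_true(all(r$observed[, "down1"] == 0))
    expect_true(all(r$background[, "up1"] > 0.8))
    expect_lt(r$tests$p_value[r$tests$window == "up1"], 0.05)
    expect_lt(r$tests$p_value[r$tests$window == "down1"], 0.05)
    # full-TE genome degenerate case: background = 1 everywhere
    full <- backgroundTeProfile(
        list(a = units_list$sp1), list(a = mkRepeats("s", 1, 200000)),
        list(a = gi_list$sp1), n_iter = 3, seed = 1)
    expect_true(all(full$background == 1))
    expect_true(all(full$observed == 1))
})

test_that("identity-TE-distance correlation behaves at its limits", {
    gi <- GenomeInfoDb::Seqinfo("s", 1000000L)
    # identity strictly decreasing with distance: rho = -1
    starts <- seq(10000, 100000, by = 10000)
    te <- mkRepeats("s", 1, 5000)
    u <- mkNumts("s", starts, starts + 99, identity = 100 - seq_along(starts))
    r <- teDistanceIdentityCorrelation(u, te)
    expect_equal(r$rho, -1)
    # a NUMT inside a TE has distance 0 and all-equal distances are undefined
    u2 <- mkNumts("s", c(100, 200, 300, 400, 500), c(150, 250, 350, 450, 550))
    expect_warning(r2 <- teDistanceIdentityCorrelation(
        u2, mkRepeats("s", 1, 600)), "identical")
    expect_true(is.na(r2$rho))
    # random permutation: negligible correlation
    set.seed(15)
    starts3 <- sample(seq(10000, 900000, by = 100), 300)
    u3 <- mkNumts("s", starts3, starts3 + 99,
                  identity = runif(300, 70, 100))
    r3 <- teDistanceIdentityCorrelation(u3, te)
    expect_lt(abs(r3$rho), 0.15)
    expect_gt(r3$p_value, 0.05)
})

test_that("genic context classification partitions units", {
    genes <- GenomicRanges::GRanges("s", IRanges::IRanges(c(50, 5000),
                                                          c(500, 6000)),
                                    symbol = c("G1", "G2"))
    u <- mkNumts("s", c(100, 1000, 450), c(200, 1100, 600))
    r <- classifyGenicContext(u, genes)
    expect_equal(unname(r$classification),
                 c("intronic", "intergenic", "intronic"))  # straddling counts
    expect_equal(r$n_intronic + r$n_intergenic, 3L)
    expect_equal(r$intergenic_intronic_ratio, 0.5)
})

test_that("expression calls apply both junction and coverage criteria", {
    ev <- data.frame(unit_id = c("u1", "u2", "u3"),
                     junc5 = c(2L, 2L, 3L), junc3 = c(2L, 1L, 3L),
                     cov_fraction = c(0.71, 0.99, 0.70))
    r <- callExpressed(ev)
    expect_equal(r$expressed, c(TRUE, FALSE, FALSE))
    # enrichment: expressed concentrated in introns
    set.seed(16)
    expressed <- c(rep(TRUE, 20), rep(FALSE, 80))
    context <- c(rep("intronic", 18), rep("intergenic", 2),
                 rep("intronic", 20), rep("intergenic", 60))
    r2 <- expressionEnrichmentTest(expressed, context)
    expect_lt(r2$p_value, 0.01)
    expect_warning(expressionEnrichmentTest(c(TRUE, FALSE, FALSE, FALSE),
                                            c("intronic", "intergenic",
                                              "intronic", "intergenic")),
                   "below 5")
})

test_that("the two genetic codes differ at exactly four codons", {
    expect_setequal(geneticCodeDifferences(), c("TGA", "AGA", "AGG", "ATA"))
})

test_that("ORF classification distinguishes intact, stop-carrying and partial genes", {
    # toy mitogenome region: one 30-codon gene at 101..190
    gene <- data.frame(gene = "TOY", start = 101L, end = 190L)
    clean <- paste0("ATG", paste(rep("GCT", 28), collapse = ""))  # 29 codons
    clean <- paste0(clean, "TAA")                                  # 90 bp
    # footprint fully covering the gene
    fp <- IRanges::IRanges(51, 250)
    seq_around <- function(core) {
        paste0(paste(rep("A", 50), collapse = ""), core,
               paste(rep("A", 60), collapse = ""))
    }
    r <- classifyOrf(seq_around(clean), fp, "+", gene)
    expect_equal(r$class, "intact_orf")
    expect_equal(r$n_stops_nuclear, 0L)
    # internal TGA: stop under the nuclear code, Trp under the mitochondrial
    tga <- paste0("ATG", paste(rep("GCT", 13), collapse = ""), "TGA",
                  paste(rep("GCT", 14), collapse = ""), "TAA")
    r2 <- classifyOrf(seq_around(tga), fp, "+", gene)
    expect_equal(r2$class, "full_with_stops")
    expect_equal(r2$n_stops_nuclear, 1L)
    expect_equal(r2$n_stops_mito, 0L)
    # minus orientation: reverse-complemented input classifies identically
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq_around(clean))))
    r3 <- classifyOrf(rc, fp, "-", gene)
    expect_equal(r3$class, "intact_orf")
    # footprint covering half the gene: incomplete
    r4 <- classifyOrf(paste(rep("A", 95), collapse = ""),
                      IRanges::IRanges(51, 145), "+", gene)
    expect_equal(r4$class, "incomplete")
})
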