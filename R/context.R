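# Per-scaffold cumulative TE coverage: c[i+1] = TE-covered bases in 1..i.
# Used for O(1) window fractions in the flank and background profiles.
.teCumsum <- function(repeats, genome_index) {
    len <- GenomeInfoDb::seqlengths(genome_index)
    by_scaf <- split(GenomicRanges::ranges(repeats),
                     as.character(GenomicRanges::seqnames(repeats)))
    out <- lapply(names(len), function(sc) {
        L <- len[[sc]]
        cov <- integer(L)
        if (sc %in% names(by_scaf)) {
            ir <- IRanges::restrict(IRanges::reduce(by_scaf[[sc]]), 1L, L)
            for (i in seq_along(ir)) {
                cov[IRanges::start(ir)[i]:IRanges::end(ir)[i]] <- 1L
            }
        }
        c(0, cumsum(cov))
    })
    names(out) <- names(len)
    out
}

.teWindowFraction <- function(cum, start, end) {
    L <- length(cum) - 1L
    s <- max(1L, start); e <- min(L, end)
    if (e < s) return(c(frac = NA_real_, avail = 0))
    c(frac = (cum[e + 1L] - cum[s]) / (e - s + 1L), avail = e - s + 1L)
}

#' Transposable-element content of NUMT/block flanks
#'
#' For each unit, the 5 kb upstream and downstream flanks are scanned in
#' 500 bp windows (10 per side), ordered outward from the unit boundary
#' (window 1 adjoins the unit). Each window's value is the fraction of its
#' bases covered by at least one TE interval. Windows truncated by a
#' scaffold end are flagged and their fractions computed on the available
#' bases (fully off-scaffold windows give `NA`).
#'
#' @param units A [NumtSet-class], [NumtBlockSet-class] or `GRanges`.
#' @param repeats TE annotation `GRanges` from [readRepeatAnnotation()].
#' @param genome_index [GenomeInfoDb::Seqinfo] with scaffold lengths.
#' @param flank Flank length per side in bp.
#' @param window Window width in bp; must divide `flank`.
#' @return `data.frame`: `unit_id`, `side` (`"up"`/`"down"`), `window`
#'   (1 = nearest the unit), `te_fraction`, `truncated`.
#' @export
flankTeProfile <- function(units, repeats, genome_index, flank = 5000,
                           window = 500) {
    if (flank %% window != 0L) stop("flank must be a multiple of window")
    W <- flank %/% window
    gr <- if (is(units, "GRanges")) units else units@ranges
    ids <- .unitIds(units, gr)
    cums <- .teCumsum(repeats, genome_index)
    rows <- vector("list", length(gr) * 2L * W)
    rr <- 0L
    scafs <- as.character(GenomicRanges::seqnames(gr))
    for (i in seq_along(gr)) {
        cum <- cums[[scafs[i]]]
        if (is.null(cum)) stop("scaffold not in genome index: ", scafs[i])
        s <- BiocGenerics::start(gr)[i]; e <- BiocGenerics::end(gr)[i]
        for (w in seq_len(W)) {
            up <- .teWindowFraction(cum, s - w * window, s - (w - 1L) * window - 1L)
            dn <- .teWindowFraction(cum, e + (w - 1L) * window + 1L, e + w * window)
            rows[[rr + 1L]] <- list(ids[i], "up", w, up[["frac"]],
                                    up[["avail"]] < window)
            rows[[rr + 2L]] <- list(ids[i], "down", w, dn[["frac"]],
                                    dn[["avail"]] < window)
            rr <- rr + 2L
        }
    }
    df <- do.call(rbind, lapply(rows, function(r)
        data.frame(unit_id = r[[1]], side = r[[2]], window = r[[3]],
                   te_fraction = r[[4]], truncated = r[[5]],
                   stringsAsFactors = FALSE)))
    df
}

.unitIds <- function(units, gr) {
    if (is(units, "NumtSet")) mcols(gr)$numt_id
    else if (is(units, "NumtBlockSet")) mcols(gr)$block_id
    else if (!is.null(names(gr))) names(gr)
    else sprintf("unit_%d", seq_along(gr))
}

# mean TE fraction per (side, window) over all units of one species
.meanFlankProfile <- function(df) {
    agg <- stats::aggregate(te_fraction ~ side + window, data = df,
                            FUN = mean, na.rm = TRUE, na.action = NULL)
    agg[order(agg$side, agg$window), ]
}

#' Background TE profile from random pseudo-NUMT placement
#'
#' The comparative baseline for [flankTeProfile()]: per iteration, every
#' unit is re-placed uniformly at random (scaffold chosen with probability
#' proportional to its eligible length), keeping its length and excluding
#' scaffold terminal regions so that both 5 kb flanks lie fully on-scaffold.
#' The per-window mean TE fraction is averaged over iterations. When
#' profiles for several species are supplied, each window's observed vs
#' background species means are compared with a paired two-sided Wilcoxon
#' signed-rank test.
#'
#' @param units_list Named list, species -> [NumtSet-class] or
#'   [NumtBlockSet-class] (a single set is also accepted).
#' @param repeats_list Matching list of TE `GRanges` (or a single one).
#' @param genome_index_list Matching list of [GenomeInfoDb::Seqinfo].
#' @param n_iter Placement iterations (>= 1).
#' @param edge_exclusion Terminal scaffold region excluded from placement,
#'   in bp.
#' @param flank,window As in [flankTeProfile()].
#' @param seed Optional integer seed.
#' @return List with `observed` and `background` (matrices species x 2W,
#'   columns `up10..up1, down1..down10` ordered along the genome outward),
#'   and `tests` (`data.frame` per window with the paired test p-value;
#'   `NA` p-values with fewer than 2 species).
#' @export
backgroundTeProfile <- function(units_list, repeats_list, genome_index_list,
                                n_iter = 1000, edge_exclusion = 5000,
                                flank = 5000, window = 500, seed = NULL) {
    if (n_iter < 1L) stop("n_iter must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    if (!is.list(units_list) || is(units_list, "NumtSet") ||
        is(units_list, "NumtBlockSet")) {
        units_list <- list(sp = units_list)
        repeats_list <- list(sp = repeats_list)
        genome_index_list <- list(sp = genome_index_list)
    }
    W <- flank %/% window
    colkey <- c(paste0("up", W:1), paste0("down", seq_len(W)))
    obs <- matrix(NA_real_, length(units_list), 2L * W,
                  dimnames = list(names(units_list), colkey))
    bg <- obs
    for (sp in names(units_list)) {
        units <- units_list[[sp]]
        gidx <- genome_index_list[[sp]]
        cums <- .teCumsum(repeats_list[[sp]], gidx)
        odf <- flankTeProfile(units, repeats_list[[sp]], gidx,
                              flank = flank, window = window)
        om <- .meanFlankProfile(odf)
        obs[sp, ] <- .profileRow(om, W)
        gr <- if (is(units, "GRanges")) units else units@ranges
        lens <- BiocGenerics::width(gr)
        slen <- GenomeInfoDb::seqlengths(gidx)
        acc <- matrix(0, n_iter, 2L * W)
        for (it in seq_len(n_iter)) {
            prof <- matrix(NA_real_, length(lens), 2L * W)
            for (u in seq_along(lens)) {
                pl <- .randomPlacement(lens[u], slen, edge_exclusion)
                if (is.null(pl)) next
                cum <- cums[[pl$scaffold]]
                for (w in seq_len(W)) {
                    upf <- .teWindowFraction(cum, pl$start - w * window,
                                             pl$start - (w - 1L) * window - 1L)
                    dnf <- .teWindowFraction(cum, pl$end + (w - 1L) * window + 1L,
                                             pl$end + w * window)
                    prof[u, W - w + 1L] <- upf[["frac"]]
                    prof[u, W + w] <- dnf[["frac"]]
                }
            }
            acc[it, ] <- colMeans(prof, na.rm = TRUE)
        }
        bg[sp, ] <- colMeans(acc)
    }
    tests <- data.frame(window = colkey, p_value = NA_real_,
                        stringsAsFactors = FALSE)
    if (nrow(obs) >= 2L) {
        for (j in seq_len(ncol(obs))) {
            d <- obs[, j] - bg[, j]
            if (all(is.na(d)) || all(d[!is.na(d)] == 0)) next
            tests$p_value[j] <- suppressWarnings(
                stats::wilcox.test(obs[, j], bg[, j], paired = TRUE)$p.value)
        }
    }
    list(observed = obs, background = bg, tests = tests)
}

# uniform placement over scaffolds proportional to eligible length, both
# flanks (edge_exclusion bp) fully on-scaffold; NULL if nowhere fits
.randomPlacement <- function(len, scaffold_lengths, edge_exclusion) {
    lo <- edge_exclusion + 1
    hi <- scaffold_lengths - edge_exclusion - len + 1
    elig <- pmax(hi - lo + 1, 0)
    if (sum(elig) == 0) {
        warning("unit of length ", len, " has no valid placement; skipped")
        return(NULL)
    }
    sc <- sample(names(scaffold_lengths), 1L, prob = elig)
    st <- lo + sample.int(elig[[sc]], 1L) - 1L
    list(scaffold = sc, start = st, end = st + len - 1L)
}

.profileRow <- function(mean_df, W) {
    up <- mean_df$te_fraction[mean_df$side == "up"][W:1]
    dn <- mean_df$te_fraction[mean_df$side == "down"][seq_len(W)]
    c(up, dn)
}

#' Correlation of NUMT identity with distance to the nearest TE
#'
#' Newly inserted NUMTs (high identity to the mitogenome) tend to lie closer
#' to transposable elements than older ones. Per NUMT the distance is the
#' mean of the nearest-TE distances from its 5' and 3' ends (0 when
#' overlapping a TE); identity vs distance is tested with Spearman's
#' correlation. NUMT blocks should not be passed here (their member
#' identities are heterogeneous).
#'
#' @param numts A [NumtSet-class].
#' @param repeats TE `GRanges`.
#' @param min_n Minimum NUMTs with finite distances.
#' @return List: `rho`, `p_value`, `n`. `rho` is `NA` when all distances are
#'   identical.
#' @export
teDistanceIdentityCorrelation <- function(numts, repeats, min_n = 5) {
    gr <- numts@ranges
    ends5 <- GRanges(GenomicRanges::seqnames(gr),
                     IRanges(BiocGenerics::start(gr), BiocGenerics::start(gr)))
    ends3 <- GRanges(GenomicRanges::seqnames(gr),
                     IRanges(BiocGenerics::end(gr), BiocGenerics::end(gr)))
    d5 <- .nearestDistance(ends5, repeats)
    d3 <- .nearestDistance(ends3, repeats)
    d <- (d5 + d3) / 2
    ok <- is.finite(d)
    if (sum(ok) < min_n)
        stop("need >= ", min_n, " NUMTs with finite TE distances")
    idn <- mcols(gr)$identity[ok]
    d <- d[ok]
    if (length(unique(d)) == 1L) {
        warning("all TE distances identical; correlation undefined")
        return(list(rho = NA_real_, p_value = NA_real_, n = sum(ok)))
    }
    ct <- suppressWarnings(stats::cor.test(idn, d, method = "spearman"))
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

.nearestDistance <- function(points, subject) {
    hits <- GenomicRanges::distanceToNearest(points, subject,
                                             ignore.strand = TRUE)
    out <- rep(Inf, length(points))
    out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    out
}

#' Classify NUMTs/blocks as intronic or intergenic
#'
#' A unit overlapping any protein-coding gene span by at least 1 bp is
#' intronic (gene spans are used whole; exon-level subtraction is not
#' attempted, and near-gene UTR insertions count as intergenic when the UTR
#' is unannotated); otherwise intergenic.
#'
#' @param units A [NumtSet-class], [NumtBlockSet-class] or `GRanges`.
#' @param genes Protein-coding gene `GRanges`.
#' @return List: `classification` (named character, unit -> `"intronic"` /
#'   `"intergenic"`), `n_intronic`, `n_intergenic`,
#'   `intergenic_intronic_ratio`.
#' @export
classifyGenicContext <- function(units, genes) {
    gr <- if (is(units, "GRanges")) units else units@ranges
    ids <- .unitIds(units, gr)
    hit <- GenomicRanges::countOverlaps(gr, genes, ignore.strand = TRUE) > 0
    cls <- ifelse(hit, "intronic", "intergenic")
    list(classification = stats::setNames(cls, ids),
         n_intronic = sum(hit), n_intergenic = sum(!hit),
         intergenic_intronic_ratio = if (sum(hit)) sum(!hit) / sum(hit)
                                     else NA_real_)
}

#' Call NUMT expression from junction and coverage evidence
#'
#' A unit is expressed in a tissue when RNA-seq junction reads (already
#' filtered upstream to a minimum overhang, by default 5 bp) support both
#' the 5' and the 3' NUMT/nucleus boundary with at least `min_junction`
#' reads each, and the read coverage of the unit exceeds `min_cov` (strict;
#' coverage of exactly 70% does not qualify).
#'
#' @param evidence `data.frame` with columns `unit_id`, `junc5`, `junc3`,
#'   `cov_fraction` (and optionally `tissue`).
#' @param min_junction Minimum junction reads per side.
#' @param min_overhang Documented minimum read overhang in bp (evidence is
#'   expected to be pre-filtered to this; recorded in the result).
#' @param min_cov Coverage fraction that must be strictly exceeded.
#' @return The evidence `data.frame` with a logical `expressed` column and
#'   attribute `min_overhang`.
#' @export
callExpressed <- function(evidence, min_junction = 2, min_overhang = 5,
                          min_cov = 0.7) {
    evidence$expressed <- evidence$junc5 >= min_junction &
        evidence$junc3 >= min_junction &
        evidence$cov_fraction > min_cov
    attr(evidence, "min_overhang") <- min_overhang
    evidence
}

#' Chi-square enrichment of expression in genic context
#'
#' 2x2 chi-square test of expressed/not expressed against
#' intronic/intergenic (expressed NUMTs tend to be enriched in introns,
#' where they can be co-expressed with the host gene).
#'
#' @param expressed Logical vector per unit.
#' @param context Character vector per unit (`"intronic"`/`"intergenic"`).
#' @return List: `p_value`, `table`. Warns when an expected cell count is
#'   below 5 (the p-value is still returned).
#' @export
expressionEnrichmentTest <- function(expressed, context) {
    tab <- table(factor(expressed, levels = c(FALSE, TRUE)),
                 factor(context, levels = c("intergenic", "intronic")))
    res <- suppressWarnings(stats::chisq.test(tab))
    if (any(res$expected < 5))
        warning("expected cell count below 5; chi-square approximation is rough")
    list(p_value = res$p.value, table = tab)
}
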