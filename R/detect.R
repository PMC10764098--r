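#' Filter raw HSPs by e-value and alignment length
#'
#' Raw alignment hits are screened with an e-value ceiling of 1e-3 and a
#' minimum HSP length of 30 bp to suppress false positives from assembly
#' errors or non-mitochondrial sequence. Order is preserved.
#'
#' @param hsps HSP table from [readHspTable()].
#' @param max_e Maximum e-value (inclusive).
#' @param min_len Minimum alignment length in bp (inclusive).
#' @return The filtered HSP table.
#' @export
filterHsps <- function(hsps, max_e = 1e-3, min_len = 30) {
    hsps[hsps$e_value <= max_e & hsps$aln_length >= min_len, , drop = FALSE]
}

# Is hsp `b` (next along the nucleus) a continuation of `a` on the
# mitogenome, in the orientation-consistent direction?  Returns TRUE also for
# the circular case where the footprint crosses the linearization boundary;
# attr "wrap" marks that case.
.mtContinuous <- function(a_mt_start, a_mt_end, b_mt_start, b_mt_end,
                          orientation, mt_length, mt_gap_max) {
    if (orientation == "+") {
        lin <- abs(b_mt_start - (a_mt_end + 1)) <= mt_gap_max
        wrap <- (mt_length - a_mt_end) + (b_mt_start - 1) <= mt_gap_max
    } else {
        lin <- abs((a_mt_start - 1) - b_mt_end) <= mt_gap_max
        wrap <- (a_mt_start - 1) + (mt_length - b_mt_end) <= mt_gap_max
    }
    structure(lin || wrap, wrap = !lin && wrap)
}

#' Merge adjacent HSPs into NUMTs
#'
#' Adjacent HSPs on the same scaffold and orientation are merged when the
#' nuclear gap between them is below `nuclear_gap_max` and their mitogenome
#' coordinates continue in the orientation-consistent direction (gap or
#' overlap at most `mt_gap_max` bp). A single insertion that traverses the
#' D-loop end of the linearized mitogenome arrives as two HSPs (one ending at
#' `mt_length`, the next starting at base 1); these are merged across the
#' circular boundary and the resulting NUMT carries two mitogenome intervals.
#' Merged identity is the alignment-length-weighted mean over member HSPs.
#' NUMTs are named `"{species}_numt_{k}"` in (scaffold order, nuclear start)
#' order.
#'
#' @param hsps Filtered HSP table.
#' @param mt_length Length of the linearized mitogenome in bp.
#' @param species Species code used in NUMT names.
#' @param nuclear_gap_max Merge only when the nuclear gap is strictly below
#'   this many bp.
#' @param mt_gap_max Maximum mitogenome gap/overlap between continuing HSPs.
#' @param genome_index Optional [GenomeInfoDb::Seqinfo]; its scaffold order
#'   drives NUMT numbering (otherwise order of first appearance).
#' @return A [NumtSet-class].
#' @export
mergeHsps <- function(hsps, mt_length, species = "Sp",
                      nuclear_gap_max = 10, mt_gap_max = 10,
                      genome_index = NULL) {
    if (!nrow(hsps))
        return(NumtSet(species = species, mtLength = mt_length))
    scaf_order <- unique(hsps$scaffold)
    rows <- list()
    warned_overlap <- FALSE
    for (scaf in scaf_order) {
        h <- hsps[hsps$scaffold == scaf, , drop = FALSE]
        h <- h[order(h$n_start, h$n_end), , drop = FALSE]
        # chain state
        cur <- NULL
        flush <- function(chain) rows[[length(rows) + 1L]] <<- chain
        for (i in seq_len(nrow(h))) {
            r <- h[i, ]
            if (is.null(cur)) {
                cur <- list(n_start = r$n_start, n_end = r$n_end,
                            orientation = r$orientation,
                            mt = IRanges(r$mt_start, r$mt_end),
                            last_mt_start = r$mt_start, last_mt_end = r$mt_end,
                            w_identity = r$identity * r$aln_length,
                            w = r$aln_length, n_hsps = 1L, wrapped = FALSE,
                            scaffold = scaf)
                next
            }
            gap <- r$n_start - cur$n_end - 1L
            ok <- FALSE
            if (r$orientation == cur$orientation && gap < nuclear_gap_max) {
                cont <- .mtContinuous(cur$last_mt_start, cur$last_mt_end,
                                      r$mt_start, r$mt_end,
                                      cur$orientation, mt_length, mt_gap_max)
                is_wrap <- isTRUE(attr(cont, "wrap"))
                if (cont && (!is_wrap || !cur$wrapped)) {
                    ok <- TRUE
                    cur$n_end <- max(cur$n_end, r$n_end)
                    cur$mt <- c(cur$mt, IRanges(r$mt_start, r$mt_end))
                    cur$last_mt_start <- r$mt_start
                    cur$last_mt_end <- r$mt_end
                    cur$w_identity <- cur$w_identity + r$identity * r$aln_length
                    cur$w <- cur$w + r$aln_length
                    cur$n_hsps <- cur$n_hsps + 1L
                    cur$wrapped <- cur$wrapped || is_wrap
                }
            }
            if (!ok) {
                if (gap < 0L && !warned_overlap) {
                    warning("overlapping nuclear intervals from distinct ",
                            "mitogenome regions kept as separate NUMTs")
                    warned_overlap <- TRUE
                }
                flush(cur)
                cur <- list(n_start = r$n_start, n_end = r$n_end,
                            orientation = r$orientation,
                            mt = IRanges(r$mt_start, r$mt_end),
                            last_mt_start = r$mt_start, last_mt_end = r$mt_end,
                            w_identity = r$identity * r$aln_length,
                            w = r$aln_length, n_hsps = 1L, wrapped = FALSE,
                            scaffold = scaf)
            }
        }
        if (!is.null(cur)) flush(cur)
    }
    gr <- GRanges(
        vapply(rows, `[[`, character(1), "scaffold"),
        IRanges(vapply(rows, `[[`, numeric(1), "n_start"),
                vapply(rows, `[[`, numeric(1), "n_end")),
        strand = vapply(rows, `[[`, character(1), "orientation")
    )
    mt_gap_merge <- max(1L, as.integer(mt_gap_max) + 1L)
    mcols(gr) <- DataFrame(
        numt_id = sprintf("unnamed_%d", seq_along(gr)),
        identity = vapply(rows, function(x) x$w_identity / x$w, numeric(1)),
        mt_intervals = IRangesList(lapply(rows, function(x)
            IRanges::reduce(x$mt, min.gapwidth = mt_gap_merge))),
        n_hsps = vapply(rows, `[[`, integer(1), "n_hsps")
    )
    renameNumts(NumtSet(gr, species = species, mtLength = mt_length),
                genome_index = genome_index)
}

#' Renumber NUMTs densely in genome order
#'
#' Ids become `"{species}_numt_{k}"`, `k = 1..n` with no gaps, ordered by
#' scaffold order (from the genome index if given, otherwise current
#' scaffold level order) then nuclear start. Applied automatically after
#' merging and after every filter.
#'
#' @param numts A [NumtSet-class].
#' @param genome_index Optional [GenomeInfoDb::Seqinfo] fixing scaffold order.
#' @return The renumbered [NumtSet-class].
#' @export
renameNumts <- function(numts, genome_index = NULL) {
    gr <- numts@ranges
    if (!length(gr)) return(numts)
    scafs <- as.character(GenomicRanges::seqnames(gr))
    lev <- if (!is.null(genome_index)) GenomeInfoDb::seqnames(genome_index)
           else unique(scafs)
    if (!all(scafs %in% lev))
        stop("scaffold(s) absent from genome index: ",
             paste(setdiff(scafs, lev), collapse = ", "))
    o <- order(match(scafs, lev), BiocGenerics::start(gr))
    gr <- gr[o]
    mcols(gr)$numt_id <- sprintf("%s_numt_%d", numts@species,
                                 seq_along(gr))
    initialize(numts, ranges = gr)
}

#' Drop NUMTs on short contigs
#'
#' NUMTs located on contigs shorter than `min_contig` (default 20 kb,
#' strictly less-than) are removed, as such hits are likely mtDNA
#' contamination or assembly errors. Remaining NUMTs are renumbered.
#'
#' @param numts A [NumtSet-class].
#' @param genome_index [GenomeInfoDb::Seqinfo] covering every scaffold in
#'   `numts` (unknown scaffold is an error).
#' @param min_contig Minimum contig length in bp to keep.
#' @return The filtered, renumbered [NumtSet-class].
#' @export
filterByContigLength <- function(numts, genome_index, min_contig = 20000) {
    gr <- numts@ranges
    if (!length(gr)) return(numts)
    scafs <- as.character(GenomicRanges::seqnames(gr))
    len <- GenomeInfoDb::seqlengths(genome_index)
    unknown <- setdiff(scafs, names(len))
    if (length(unknown))
        stop("scaffold(s) not in genome index: ",
             paste(unknown, collapse = ", "))
    keep <- len[scafs] >= min_contig
    renameNumts(initialize(numts, ranges = gr[keep]),
                genome_index = genome_index)
}

#' Assemble NUMTs into blocks
#'
#' Single-linkage chaining: NUMTs whose nuclear gap to the previous chain
#' member is strictly below `max_gap` bp (default 2 kb) join one block,
#' regardless of orientation. Every NUMT belongs to exactly one block
#' (possibly a singleton); blocks with >= 3 members are flagged complex.
#'
#' @param numts A [NumtSet-class].
#' @param max_gap Chain gap in bp (strict upper bound).
#' @return A [NumtBlockSet-class] with blocks named
#'   `"{species}_block_{k}"`.
#' @export
assembleBlocks <- function(numts, max_gap = 2000) {
    gr <- numts@ranges
    empty <- GRanges()
    mcols(empty) <- DataFrame(block_id = character(),
                              members = IRanges::CharacterList(),
                              n_members = integer(), is_complex = logical(),
                              mt_intervals = IRangesList())
    if (!length(gr))
        return(new("NumtBlockSet", ranges = empty, species = numts@species,
                   mtLength = numts@mtLength))
    scafs <- as.character(GenomicRanges::seqnames(gr))
    o <- order(match(scafs, unique(scafs)), BiocGenerics::start(gr))
    gr <- gr[o]
    scafs <- scafs[o]
    st <- BiocGenerics::start(gr); en <- BiocGenerics::end(gr)
    block <- integer(length(gr))
    b <- 0L
    run_end <- -Inf
    prev_scaf <- ""
    for (i in seq_along(gr)) {
        gap <- st[i] - run_end - 1L
        if (scafs[i] != prev_scaf || gap >= max_gap) {
            b <- b + 1L
            run_end <- en[i]
        } else {
            run_end <- max(run_end, en[i])
        }
        block[i] <- b
        prev_scaf <- scafs[i]
    }
    idx <- split(seq_along(gr), block)
    bscaf <- vapply(idx, function(ii) scafs[ii[1]], character(1))
    bstart <- vapply(idx, function(ii) min(st[ii]), numeric(1))
    bend <- vapply(idx, function(ii) max(en[ii]), numeric(1))
    members <- IRanges::CharacterList(lapply(idx, function(ii)
        mcols(gr)$numt_id[ii]))
    fp <- IRangesList(lapply(idx, function(ii)
        IRanges::reduce(unlist(mcols(gr)$mt_intervals[ii]))))
    bgr <- GRanges(bscaf, IRanges(bstart, bend))
    n_members <- lengths(idx)
    mcols(bgr) <- DataFrame(
        block_id = sprintf("%s_block_%d", numts@species, seq_along(bgr)),
        members = members,
        n_members = as.integer(n_members),
        is_complex = n_members >= 3L,
        mt_intervals = fp
    )
    new("NumtBlockSet", ranges = bgr, species = numts@species,
        mtLength = numts@mtLength)
}

#' Find tandem-duplicated NUMT pairs
#'
#' Candidate post-insertion tandem duplicates: two NUMTs on the same
#' scaffold within a `window` bp nuclear distance whose mitogenome
#' footprints have similar start or end coordinates (within `coord_tol` bp)
#' and overlap reciprocally by at least `min_overlap`.
#'
#' @param numts A [NumtSet-class].
#' @param window Maximum nuclear distance (gap between the two intervals) in
#'   bp.
#' @param coord_tol Tolerance on mitogenome start/end similarity in bp.
#' @param min_overlap Minimum reciprocal footprint overlap fraction.
#' @return `data.frame` with columns `numt_a`, `numt_b`, `distance_bp`,
#'   `overlap_fraction`.
#' @export
findTandemDuplicates <- function(numts, window = 10000, coord_tol = 10,
                                 min_overlap = 0.5) {
    gr <- numts@ranges
    out <- data.frame(numt_a = character(), numt_b = character(),
                      distance_bp = integer(), overlap_fraction = numeric())
    if (length(gr) < 2L) return(out)
    fp <- mcols(gr)$mt_intervals
    mt_s <- vapply(as.list(fp), function(x) min(IRanges::start(x)), numeric(1))
    mt_e <- vapply(as.list(fp), function(x) max(IRanges::end(x)), numeric(1))
    scafs <- as.character(GenomicRanges::seqnames(gr))
    for (i in seq_len(length(gr) - 1L)) {
        for (j in (i + 1L):length(gr)) {
            if (scafs[i] != scafs[j]) next
            d <- max(0L, max(BiocGenerics::start(gr)[c(i, j)]) -
                         min(BiocGenerics::end(gr)[c(i, j)]) - 1L)
            if (d > window) next
            if (abs(mt_s[i] - mt_s[j]) > coord_tol &&
                abs(mt_e[i] - mt_e[j]) > coord_tol) next
            ov <- mtOverlapFraction(fp[[i]], fp[[j]])
            if (ov >= min_overlap)
                out[nrow(out) + 1L, ] <- list(mcols(gr)$numt_id[i],
                                              mcols(gr)$numt_id[j],
                                              as.integer(d), ov)
        }
    }
    out
}

#' Per-species NUMT summary statistics
#'
#' @param numts A [NumtSet-class].
#' @param blocks Optional [NumtBlockSet-class] for the block count.
#' @param genome_index [GenomeInfoDb::Seqinfo]; total scaffold length is the
#'   denominator of the genome fraction.
#' @param identity_cut Percent identity above which (strictly) a NUMT counts
#'   as recent; reported as a fraction of NUMTs.
#' @return One-row `data.frame`: `n_numts`, `n_blocks`, `cumulative_bp`,
#'   `genome_fraction`, `mean_identity`, `median_identity`,
#'   `frac_identity_above_cut`. Identity statistics are `NA` for an empty
#'   set.
#' @export
numtSummary <- function(numts, blocks = NULL, genome_index = NULL,
                        identity_cut = 98) {
    gr <- numts@ranges
    n <- length(gr)
    cum <- if (n) sum(BiocGenerics::width(gr)) else 0L
    gsize <- if (!is.null(genome_index))
        sum(as.numeric(GenomeInfoDb::seqlengths(genome_index))) else NA_real_
    idn <- mcols(gr)$identity
    data.frame(
        species = numts@species,
        n_numts = n,
        n_blocks = if (!is.null(blocks)) length(blocks) else NA_integer_,
        cumulative_bp = as.integer(cum),
        genome_fraction = if (is.na(gsize)) NA_real_ else cum / gsize,
        mean_identity = if (n) mean(idn) else NA_real_,
        median_identity = if (n) stats::median(idn) else NA_real_,
        frac_identity_above_cut = if (n) mean(idn > identity_cut) else NA_real_,
        stringsAsFactors = FALSE
    )
}

#' Compare NUMT length distributions across species
#'
#' Pairwise two-sample Kolmogorov-Smirnov tests of per-species NUMT length
#' lists, followed by a rank-sum contrast of log10 p-values between
#' within-order and across-order species pairs (closely related species tend
#' to share length distributions, so within-order p-values sit higher).
#'
#' @param length_sets Named list, species -> numeric vector of NUMT lengths.
#' @param order_labels Named character, species -> taxonomic order.
#' @return List with `p_matrix` (symmetric KS p-values), `within_log10p`,
#'   `across_log10p`, and `contrast_p` (two-sided rank-sum p for the
#'   within/across contrast; `NA` when either set is empty).
#' @export
compareLengthDistributions <- function(length_sets, order_labels) {
    small <- lengths(length_sets) < 2L
    if (any(small)) {
        warning("excluding species with < 2 NUMTs: ",
                paste(names(length_sets)[small], collapse = ", "))
        length_sets <- length_sets[!small]
    }
    sp <- names(length_sets)
    if (length(sp) < 2L) stop("need >= 2 species with >= 2 NUMTs")
    n <- length(sp)
    p <- matrix(NA_real_, n, n, dimnames = list(sp, sp))
    within <- logical(0); pv <- numeric(0)
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            pij <- suppressWarnings(
                stats::ks.test(length_sets[[i]], length_sets[[j]])$p.value)
            p[i, j] <- p[j, i] <- pij
            pv <- c(pv, pij)
            within <- c(within,
                        identical(unname(order_labels[sp[i]]),
                                  unname(order_labels[sp[j]])))
        }
    }
    lp <- log10(pmax(pv, .Machine$double.xmin))
    contrast <- if (any(within) && any(!within))
        suppressWarnings(stats::wilcox.test(lp[within], lp[!within])$p.value)
    else NA_real_
    list(p_matrix = p, within_log10p = lp[within],
         across_log10p = lp[!within], contrast_p = contrast)
}
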