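#' Reciprocal mitogenome overlap fraction of two footprints
#'
#' Footprints are unions of intervals on the linearized mitogenome; a
#' footprint that wraps the linearization boundary is simply represented by
#' two intervals, so overlap on the circular molecule falls out of ordinary
#' interval intersection. The overlap length is divided by each footprint's
#' total length and the minimum of the two fractions returned (reciprocal
#' criterion).
#'
#' @param a,b `IRanges` footprints (>= 1 interval each; the intervals within
#'   one footprint must be disjoint, as all footprints produced by this
#'   package are).
#' @return Overlap fraction in `[0, 1]`.
#' @export
mtOverlapFraction <- function(a, b) {
    if (!length(a) || !length(b)) stop("empty mitogenome footprint")
    as_ <- IRanges::start(a); ae <- IRanges::end(a)
    bs <- IRanges::start(b); be <- IRanges::end(b)
    ov <- 0
    for (i in seq_along(as_))
        ov <- ov + sum(pmax(0L, pmin(ae[i], be) - pmax(as_[i], bs) + 1L))
    min(ov / sum(ae - as_ + 1), ov / sum(be - bs + 1))
}

#' Build microsynteny contexts for NUMTs/blocks
#'
#' For each unit, the `k` nearest protein-coding genes on each side (by
#' midpoint distance; nearest first) are recorded as anchors. A gene whose
#' span overlaps the unit is its host (intronic insertion) and is kept
#' separate from the anchor lists. Gene symbols occurring at more than one
#' locus in the annotation are ambiguous and excluded from anchoring with a
#' warning. Units on gene-free scaffolds get empty contexts and are excluded
#' from orthology assignment with a warning.
#'
#' @param units A [NumtSet-class] or [NumtBlockSet-class].
#' @param genes `GRanges` with metadata column `symbol`, sorted or not.
#' @param k Anchor genes per side.
#' @return `data.frame` with columns `unit_id`, `up_anchors`, `down_anchors`,
#'   `host` (list columns of symbols) and `footprint` (list of `IRanges`),
#'   plus attribute `mt_length`.
#' @export
buildSyntenyContext <- function(units, genes, k = 3) {
    dup <- unique(genes$symbol[duplicated(genes$symbol)])
    if (length(dup)) {
        warning("excluding ", length(dup),
                " ambiguous gene symbol(s) present at multiple loci")
        genes <- genes[!(genes$symbol %in% dup)]
    }
    gr <- units@ranges
    ids <- if (is(units, "NumtSet")) mcols(gr)$numt_id else mcols(gr)$block_id
    fp <- mcols(gr)$mt_intervals
    gmid <- (BiocGenerics::start(genes) + BiocGenerics::end(genes)) / 2
    gscaf <- as.character(GenomicRanges::seqnames(genes))
    uscaf <- as.character(GenomicRanges::seqnames(gr))
    up <- vector("list", length(gr))
    down <- vector("list", length(gr))
    host <- vector("list", length(gr))
    no_genes <- character(0)
    ov <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
    for (i in seq_along(gr)) {
        onscaf <- which(gscaf == uscaf[i])
        hosts_i <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
        host[[i]] <- genes$symbol[hosts_i]
        cand <- setdiff(onscaf, hosts_i)
        if (!length(onscaf)) {
            no_genes <- c(no_genes, ids[i])
            up[[i]] <- character(0); down[[i]] <- character(0)
            next
        }
        umid <- (BiocGenerics::start(gr)[i] + BiocGenerics::end(gr)[i]) / 2
        d <- gmid[cand] - umid
        upc <- cand[d < 0]
        dnc <- cand[d >= 0]
        up[[i]] <- genes$symbol[upc[order(-gmid[upc])]][seq_len(min(k, length(upc)))]
        down[[i]] <- genes$symbol[dnc[order(gmid[dnc])]][seq_len(min(k, length(dnc)))]
    }
    if (length(no_genes))
        warning("unit(s) on gene-free scaffolds excluded from orthology: ",
                paste(no_genes, collapse = ", "))
    out <- data.frame(unit_id = ids, stringsAsFactors = FALSE)
    out$up_anchors <- up
    out$down_anchors <- down
    out$host <- host
    out$footprint <- as.list(fp)
    attr(out, "mt_length") <- mtLength(units)
    attr(out, "species") <- speciesCode(units)
    out
}

#' Assign NUMT/block orthologs between two species
#'
#' Two units are candidate orthologs when they share at least one anchor
#' gene symbol (union of upstream, downstream and host symbols; i.e. they
#' sit in the same microsynteny block within a 2k-gene neighborhood) and
#' their mitogenome footprints overlap reciprocally by at least
#' `min_overlap`. Candidates are resolved to a one-to-one matching greedily
#' by descending overlap fraction, ties broken by larger shared-anchor count
#' then by unit id.
#'
#' @param context_a,context_b Contexts from [buildSyntenyContext()].
#' @param min_overlap Minimum reciprocal mitogenome overlap fraction.
#' @return `data.frame`: `unit_a`, `unit_b`, `shared_anchors`
#'   (comma-collapsed), `n_shared`, `overlap`.
#' @export
assignOrthologs <- function(context_a, context_b, min_overlap = 0.5) {
    anchors <- function(ctx, i)
        unique(c(ctx$up_anchors[[i]], ctx$down_anchors[[i]], ctx$host[[i]]))
    empty <- data.frame(unit_a = character(), unit_b = character(),
                        shared_anchors = character(), n_shared = integer(),
                        overlap = numeric(), stringsAsFactors = FALSE)
    if (!nrow(context_a) || !nrow(context_b)) return(empty)
    # inverted index: symbol -> units of B
    idx_b <- list()
    for (j in seq_len(nrow(context_b))) {
        for (s in anchors(context_b, j)) idx_b[[s]] <- c(idx_b[[s]], j)
    }
    cand <- list()
    for (i in seq_len(nrow(context_a))) {
        sa <- anchors(context_a, i)
        if (!length(sa)) next
        js <- unique(unlist(idx_b[sa], use.names = FALSE))
        for (j in js) {
            shared <- intersect(sa, anchors(context_b, j))
            ovf <- mtOverlapFraction(context_a$footprint[[i]],
                                     context_b$footprint[[j]])
            if (ovf >= min_overlap)
                cand[[length(cand) + 1L]] <- list(
                    i = i, j = j, shared = sort(shared),
                    n_shared = length(shared), overlap = ovf)
        }
    }
    if (!length(cand)) return(empty)
    ovl <- vapply(cand, `[[`, numeric(1), "overlap")
    nsh <- vapply(cand, `[[`, integer(1), "n_shared")
    ia <- vapply(cand, function(x) context_a$unit_id[x$i], character(1))
    ib <- vapply(cand, function(x) context_b$unit_id[x$j], character(1))
    o <- order(-ovl, -nsh, ia, ib)
    used_a <- logical(nrow(context_a))
    used_b <- logical(nrow(context_b))
    keep <- integer(0)
    for (kk in o) {
        i <- cand[[kk]]$i; j <- cand[[kk]]$j
        if (used_a[i] || used_b[j]) next
        used_a[i] <- TRUE; used_b[j] <- TRUE
        keep <- c(keep, kk)
    }
    data.frame(
        unit_a = ia[keep], unit_b = ib[keep],
        shared_anchors = vapply(cand[keep], function(x)
            paste(x$shared, collapse = ","), character(1)),
        n_shared = nsh[keep], overlap = ovl[keep],
        stringsAsFactors = FALSE
    )
}

#' Analytic per-pair false-assignment rate of synteny orthology
#'
#' Probability that two randomly placed units from two species are assigned
#' as orthologs by chance under the synteny criteria: the chance that both
#' fall into the same 2k-gene microsynteny window, `(2k - 1)/G` (a window of
#' 2k genes spans 2k - 1 shared inter-gene intervals among G genes), times
#' the chance that two random L-bp segments on a circular M-bp mitogenome
#' overlap by at least `ceiling(f * L)` bp,
#' `(2 * (L - ceiling(f * L)) + 1)/M`.
#'
#' With the defaults (G = 20,000 protein-coding genes, mean NUMT length
#' L = 200 bp, mitogenome M = 16,600 bp, k = 3 anchors per side, overlap
#' fraction f = 0.5) the rate is 3.03e-6.
#'
#' @param G Protein-coding genes per genome.
#' @param L Mean NUMT length in bp.
#' @param M Mitogenome length in bp.
#' @param k Anchor genes per side of the synteny window.
#' @param f Required overlap fraction.
#' @return Per-pair probability of false orthology assignment.
#' @export
errorRate <- function(G = 20000, L = 200, M = 16600, k = 3, f = 0.5) {
    if (G < 2 * k) stop("G must be >= 2k")
    if (f <= 0 || f > 1) stop("f must lie in (0, 1]")
    if (L > M) stop("L must not exceed M")
    p_window <- (2 * k - 1) / G
    p_overlap <- (2 * (L - ceiling(f * L)) + 1) / M
    rate <- p_window * p_overlap
    if (rate < 0 || rate > 1) stop("degenerate parameters")
    rate
}

#' Expected number of false ortholog pairs between two species
#'
#' `E = rate * N_a * N_b` over all possible unit pairs. An expectation at or
#' above 1 flags the species comparison as unreliable (warning), as for
#' species pairs where both carry very many NUMTs.
#'
#' @param rate Per-pair false-assignment probability from [errorRate()].
#' @param n_a,n_b Unit counts in species A and B.
#' @return The expectation `E`.
#' @export
errorExpectation <- function(rate, n_a, n_b) {
    if (n_a < 0 || n_b < 0) stop("counts must be >= 0")
    E <- rate * n_a * n_b
    if (E >= 1)
        warning(sprintf(
            "error expectation E = %.3g >= 1; orthologs from this species pair are unreliable", E))
    E
}
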