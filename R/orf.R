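#' Codons where the vertebrate mitochondrial code differs from the standard
#' code
#'
#' @return Character vector of codons (should be TGA, AGA, AGG, ATA) at
#'   which the two translation tables disagree.
#' @export
geneticCodeDifferences <- function() {
    std <- Biostrings::GENETIC_CODE
    mito <- Biostrings::getGeneticCode("SGC1")  # vertebrate mitochondrial
    names(std)[std != mito[names(std)]]
}

#' Classify the ORF status of mitochondrial genes contained in a NUMT
#'
#' For every mitochondrial protein-coding gene whose span is entirely inside
#' the NUMT's mitogenome footprint, the NUMT-resident copy is extracted and
#' translated under the standard nuclear code and the vertebrate
#' mitochondrial code. A gene copy is `intact_orf` when an uninterrupted
#' reading frame spans the gene under the nuclear code (no internal stop;
#' the criterion for protein-coding potential in the nucleus), otherwise
#' `full_with_stops`. Genes only partially covered by the footprint are
#' `incomplete`. Minus-orientation NUMTs are reverse-complemented before
#' translation. Extraction assumes the NUMT sequence is colinear with its
#' footprint (substitutions only, no indels).
#'
#' @param numt_seq `DNAString` (or character) of the NUMT's nuclear sequence.
#' @param mt_intervals `IRanges` footprint on the linearized mitogenome, in
#'   the order the intervals occur along the nuclear plus strand for a
#'   plus-orientation NUMT.
#' @param orientation `"+"` or `"-"` relative to the mitogenome.
#' @param mt_genes `data.frame` with columns `gene`, `start`, `end`
#'   (1-based inclusive on the linearized mitogenome) of protein-coding
#'   genes, or a `GRanges` with a `gene` metadata column.
#' @return `data.frame`: `gene`, `class`
#'   (`intact_orf`/`full_with_stops`/`incomplete`), `n_stops_nuclear`,
#'   `n_stops_mito` (internal stops under each code; `NA` for incomplete).
#' @export
classifyOrf <- function(numt_seq, mt_intervals, orientation = "+", mt_genes) {
    if (is(mt_genes, "GRanges"))
        mt_genes <- data.frame(gene = mt_genes$gene,
                               start = BiocGenerics::start(mt_genes),
                               end = BiocGenerics::end(mt_genes))
    seq <- Biostrings::DNAString(as.character(numt_seq))
    if (orientation == "-") seq <- Biostrings::reverseComplement(seq)
    if (length(seq) != sum(IRanges::width(mt_intervals)))
        stop("NUMT sequence length does not match its mitogenome footprint")
    # mitogenome base -> offset in the footprint-ordered sequence
    offs <- cumsum(c(0L, IRanges::width(mt_intervals)))
    mapPos <- function(pos) {
        for (i in seq_along(mt_intervals)) {
            s <- IRanges::start(mt_intervals)[i]
            e <- IRanges::end(mt_intervals)[i]
            if (pos >= s && pos <= e) return(offs[i] + pos - s + 1L)
        }
        NA_integer_
    }
    nuc <- Biostrings::GENETIC_CODE
    mito <- Biostrings::getGeneticCode("SGC1")
    res <- lapply(seq_len(nrow(mt_genes)), function(g) {
        gs <- mt_genes$start[g]; ge <- mt_genes$end[g]
        covered <- sum(IRanges::width(IRanges::intersect(
            IRanges::reduce(mt_intervals), IRanges(gs, ge))))
        if (covered < ge - gs + 1L)
            return(data.frame(gene = mt_genes$gene[g], class = "incomplete",
                              n_stops_nuclear = NA_integer_,
                              n_stops_mito = NA_integer_))
        p1 <- mapPos(gs)
        glen <- ge - gs + 1L
        glen <- glen - glen %% 3L
        gseq <- Biostrings::subseq(seq, p1, p1 + glen - 1L)
        codons <- substring(as.character(gseq),
                            seq(1L, glen - 2L, by = 3L),
                            seq(3L, glen, by = 3L))
        internal <- codons[-length(codons)]
        n_nuc <- sum(nuc[internal] == "*", na.rm = TRUE)
        n_mit <- sum(mito[internal] == "*", na.rm = TRUE)
        cls <- if (n_nuc == 0L) "intact_orf" else "full_with_stops"
        data.frame(gene = mt_genes$gene[g], class = cls,
                   n_stops_nuclear = n_nuc, n_stops_mito = n_mit)
    })
    do.call(rbind, res)
}
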