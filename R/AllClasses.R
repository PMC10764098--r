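#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges IRangesList
#' @importFrom GenomicRanges GRanges granges
NULL

#' NumtSet: called NUMTs of one species
#'
#' A `NumtSet` holds the NUMTs (nuclear mitochondrial DNA segments) called in
#' one nuclear genome. The nuclear intervals live in a [GenomicRanges::GRanges]
#' (strand encodes orientation relative to the mitogenome); per-NUMT metadata
#' columns carry the NUMT identifier, the alignment-length-weighted percent
#' identity to the mitogenome, the mitogenome footprint (an
#' [IRanges::IRangesList]; two intervals when the footprint wraps the
#' linearization boundary of the circular mitogenome) and the number of
#' merged HSPs.
#'
#' @slot ranges `GRanges` of nuclear intervals with metadata columns
#'   `numt_id`, `identity`, `mt_intervals`, `n_hsps`.
#' @slot species Single character, the species code (e.g. `"Hsap"`).
#' @slot mtLength Length in bp of the linearized mitogenome.
#'
#' @seealso [mergeHsps()], [assembleBlocks()], [numtSummary()]
#' @export
setClass("NumtSet",
    slots = c(
        ranges = "GRanges",
        species = "character",
        mtLength = "numeric"
    )
)

setValidity("NumtSet", function(object) {
    msg <- character()
    gr <- object@ranges
    mc <- mcols(gr)
    need <- c("numt_id", "identity", "mt_intervals", "n_hsps")
    if (!all(need %in% colnames(mc)))
        return(paste("metadata columns required:", paste(need, collapse = ", ")))
    if (length(object@species) != 1L || is.na(object@species) ||
        !nzchar(object@species))
        msg <- c(msg, "'species' must be one non-empty string")
    if (length(object@mtLength) != 1L || object@mtLength < 1)
        msg <- c(msg, "'mtLength' must be a single length >= 1")
    if (anyDuplicated(mc$numt_id))
        msg <- c(msg, "NUMT ids must be unique")
    if (length(gr)) {
        idn <- mc$identity
        if (any(idn < 0 | idn > 100, na.rm = TRUE))
            msg <- c(msg, "identity must lie in [0, 100]")
        fp <- mc$mt_intervals
        if (any(lengths(fp) < 1L))
            msg <- c(msg, "every NUMT needs >= 1 mitogenome interval")
        tot <- sum(IRanges::width(fp))
        if (any(tot > object@mtLength))
            msg <- c(msg, "mitogenome footprint exceeds mitogenome length")
        if (any(max(IRanges::end(fp)) > object@mtLength) ||
            any(min(IRanges::start(fp)) < 1L))
            msg <- c(msg, "mitogenome intervals outside [1, mtLength]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a NumtSet
#'
#' @param ranges `GRanges` of nuclear intervals with metadata columns
#'   `numt_id`, `identity`, `mt_intervals` (`IRangesList`), `n_hsps`.
#' @param species Species code, e.g. `"Hsap"`.
#' @param mtLength Linearized mitogenome length in bp.
#' @return A [NumtSet-class] object.
#' @export
NumtSet <- function(ranges = GRanges(), species = "Sp", mtLength = 16600) {
    if (is.null(mcols(ranges)$numt_id)) {
        mcols(ranges)$numt_id <- character(length(ranges))
        mcols(ranges)$identity <- numeric(length(ranges))
        mcols(ranges)$mt_intervals <- IRangesList(rep(list(IRanges()), length(ranges)))
        mcols(ranges)$n_hsps <- integer(length(ranges))
    }
    new("NumtSet", ranges = ranges, species = species,
        mtLength = as.numeric(mtLength))
}

#' NumtBlockSet: assembled NUMT blocks of one species
#'
#' NUMTs within a short nuclear distance of each other (by default < 2 kb)
#' are chained into blocks, the unit of downstream context and orthology
#' analysis. Blocks with three or more member NUMTs are flagged complex.
#'
#' @slot ranges `GRanges` of block spans with metadata columns `block_id`,
#'   `members` (`CharacterList` of member NUMT ids), `n_members`,
#'   `is_complex`, `mt_intervals` (union of member footprints).
#' @slot species Species code.
#' @slot mtLength Linearized mitogenome length in bp.
#' @seealso [assembleBlocks()]
#' @export
setClass("NumtBlockSet",
    slots = c(
        ranges = "GRanges",
        species = "character",
        mtLength = "numeric"
    )
)

setValidity("NumtBlockSet", function(object) {
    msg <- character()
    mc <- mcols(object@ranges)
    need <- c("block_id", "members", "n_members", "is_complex", "mt_intervals")
    if (!all(need %in% colnames(mc)))
        return(paste("metadata columns required:", paste(need, collapse = ", ")))
    if (length(object@ranges)) {
        if (!identical(unname(lengths(mc$members)), as.integer(mc$n_members)))
            msg <- c(msg, "n_members must equal length(members)")
        if (!identical(unname(mc$is_complex), unname(mc$n_members >= 3L)))
            msg <- c(msg, "is_complex must be TRUE exactly when n_members >= 3")
    }
    if (length(msg)) msg else TRUE
})
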