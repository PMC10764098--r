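#' Accessors for NumtSet
#'
#' `numtIds()` returns the NUMT identifiers (`"{Species}_numt_{k}"`);
#' `numtIdentity()` the percent identity to the mitogenome; `mtFootprint()`
#' the mitogenome footprints as an [IRanges::IRangesList] named by NUMT id;
#' `speciesCode()` and `mtLength()` the species code and linearized
#' mitogenome length; `granges()` the nuclear intervals.
#'
#' @param x A [NumtSet-class] or [NumtBlockSet-class].
#' @name NumtSet-accessors
NULL

#' @rdname NumtSet-accessors
#' @export
setMethod("numtIds", "NumtSet", function(x) mcols(x@ranges)$numt_id)

#' @rdname NumtSet-accessors
#' @export
setMethod("numtIdentity", "NumtSet", function(x) {
    stats::setNames(mcols(x@ranges)$identity, mcols(x@ranges)$numt_id)
})

#' @rdname NumtSet-accessors
#' @export
setMethod("mtFootprint", "NumtSet", function(x) {
    stats::setNames(mcols(x@ranges)$mt_intervals, mcols(x@ranges)$numt_id)
})

#' @rdname NumtSet-accessors
#' @export
setMethod("mtFootprint", "NumtBlockSet", function(x) {
    stats::setNames(mcols(x@ranges)$mt_intervals, mcols(x@ranges)$block_id)
})

#' @rdname NumtSet-accessors
#' @export
setMethod("speciesCode", "NumtSet", function(x) x@species)

#' @rdname NumtSet-accessors
#' @export
setMethod("speciesCode", "NumtBlockSet", function(x) x@species)

#' @rdname NumtSet-accessors
#' @export
setMethod("mtLength", "NumtSet", function(x) x@mtLength)

#' @rdname NumtSet-accessors
#' @export
setMethod("mtLength", "NumtBlockSet", function(x) x@mtLength)

#' @rdname NumtSet-accessors
#' @param use.names,use.mcols Passed through from the `granges` generic.
#' @param ... Ignored.
#' @export
setMethod("granges", "NumtSet", function(x, use.names = TRUE,
                                         use.mcols = FALSE, ...) {
    if (use.mcols) x@ranges else granges(x@ranges)
})

#' @rdname NumtSet-accessors
#' @export
setMethod("granges", "NumtBlockSet", function(x, use.names = TRUE,
                                              use.mcols = FALSE, ...) {
    if (use.mcols) x@ranges else granges(x@ranges)
})

#' @rdname NumtSet-accessors
#' @export
setMethod("length", "NumtSet", function(x) length(x@ranges))

#' @rdname NumtBlockSet-accessors
#' @param x A [NumtBlockSet-class].
#' @export
setMethod("length", "NumtBlockSet", function(x) length(x@ranges))

#' Accessors for NumtBlockSet
#'
#' `blockIds()` returns block identifiers, `blockMembers()` the member NUMT
#' ids per block as a `CharacterList`, `isComplex()` the complexity flag
#' (block has >= 3 member NUMTs).
#'
#' @name NumtBlockSet-accessors
NULL

#' @rdname NumtBlockSet-accessors
#' @export
setMethod("blockIds", "NumtBlockSet", function(x) mcols(x@ranges)$block_id)

#' @rdname NumtBlockSet-accessors
#' @export
setMethod("blockMembers", "NumtBlockSet", function(x) {
    stats::setNames(mcols(x@ranges)$members, mcols(x@ranges)$block_id)
})

#' @rdname NumtBlockSet-accessors
#' @export
setMethod("isComplex", "NumtBlockSet", function(x) {
    stats::setNames(mcols(x@ranges)$is_complex, mcols(x@ranges)$block_id)
})

#' @rdname NumtSet-accessors
#' @param i Index for subsetting.
#' @param j,drop Ignored.
#' @export
setMethod("[", "NumtSet", function(x, i, j, ..., drop = TRUE) {
    initialize(x, ranges = x@ranges[i])
})

#' @rdname NumtBlockSet-accessors
#' @param i Index for subsetting.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "NumtBlockSet", function(x, i, j, ..., drop = TRUE) {
    initialize(x, ranges = x@ranges[i])
})

setMethod("show", "NumtSet", function(object) {
    cat("NumtSet for species", object@species,
        "with", length(object), "NUMTs",
        sprintf("(mitogenome %d bp)\n", as.integer(object@mtLength)))
    if (length(object)) {
        idn <- mcols(object@ranges)$identity
        cat(sprintf("  identity: mean %.1f%%, range %.1f-%.1f%%\n",
                    mean(idn), min(idn), max(idn)))
        cat(sprintf("  cumulative length: %d bp on %d scaffold(s)\n",
                    sum(BiocGenerics::width(object@ranges)),
                    length(unique(as.character(
                        GenomicRanges::seqnames(object@ranges))))))
    }
    invisible(object)
})

setMethod("show", "NumtBlockSet", function(object) {
    cat("NumtBlockSet for species", object@species, "with",
        length(object), "blocks")
    if (length(object))
        cat(sprintf(" (%d complex)", sum(mcols(object@ranges)$is_complex)))
    cat("\n")
    invisible(object)
})

#' Coerce a NumtSet to a data.frame
#'
#' One row per NUMT with nuclear coordinates (1-based inclusive), orientation,
#' identity and the mitogenome footprint rendered as `"start-end[,start-end]"`.
#'
#' @param x A [NumtSet-class].
#' @param row.names,optional,... Passed on conventionally; ignored.
#' @return A `data.frame`.
#' @method as.data.frame NumtSet
#' @export
as.data.frame.NumtSet <- function(x, row.names = NULL, optional = FALSE, ...) {
    gr <- x@ranges
    data.frame(
        numt_id = mcols(gr)$numt_id,
        scaffold = as.character(GenomicRanges::seqnames(gr)),
        start = BiocGenerics::start(gr),
        end = BiocGenerics::end(gr),
        orientation = as.character(BiocGenerics::strand(gr)),
        identity = mcols(gr)$identity,
        n_hsps = mcols(gr)$n_hsps,
        mt_footprint = .footprintString(mcols(gr)$mt_intervals),
        stringsAsFactors = FALSE
    )
}

#' @rdname as.data.frame.NumtSet
#' @export
setMethod("as.data.frame", "NumtSet", function(x, row.names = NULL,
                                               optional = FALSE, ...) {
    as.data.frame.NumtSet(x, row.names = row.names, optional = optional, ...)
})

.footprintString <- function(fl) {
    vapply(as.list(fl), function(ir) {
        paste(sprintf("%d-%d", IRanges::start(ir), IRanges::end(ir)),
              collapse = ",")
    }, character(1))
}

.parseFootprintString <- function(s) {
    IRangesList(lapply(strsplit(s, ","), function(parts) {
        se <- do.call(rbind, strsplit(parts, "-"))
        IRanges(as.integer(se[, 1]), as.integer(se[, 2]))
    }))
}
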