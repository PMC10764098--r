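#' Read a 12-column tabular alignment (outfmt-6 dialect) of mitogenome HSPs
#'
#' Parses BLAST-style tabular hits of a linearized mitogenome (query) against
#' nuclear scaffolds (subject). Subject coordinates are normalized to
#' ascending order; hits reported with `sstart > send` are flagged as minus
#' orientation. All coordinates are 1-based inclusive, as printed by the
#' aligner.
#'
#' @param path Path to a tab-separated file with columns query, subject,
#'   percent identity, alignment length, mismatches, gap opens, qstart, qend,
#'   sstart, send, e-value, bit score. No header.
#' @return A `data.frame` with one row per HSP and columns `query`,
#'   `scaffold`, `identity`, `aln_length`, `mismatches`, `gap_opens`,
#'   `mt_start`, `mt_end`, `n_start`, `n_end`, `orientation` (`"+"`/`"-"`),
#'   `e_value`, `bit_score`. Empty file gives zero rows.
#' @examples
#' tf <- tempfile()
#' writeLines("mt\tscaf1\t95.0\t200\t10\t0\t300\t499\t1199\t1000\t1e-50\t250", tf)
#' readHspTable(tf)
#' @export
readHspTable <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(.emptyHspTable())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 12L)
    if (length(bad))
        stop("malformed HSP row at line ", bad[1], ": expected 12 fields, got ",
             lengths(fields)[bad[1]])
    m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
    numcols <- c(3:10, 11, 12)
    suppressWarnings(vals <- apply(m[, numcols, drop = FALSE], 2, as.numeric))
    vals <- matrix(vals, ncol = length(numcols))
    if (anyNA(vals)) {
        bad <- which(apply(is.na(vals), 1, any))[1]
        stop("non-numeric coordinate or score at line ", bad)
    }
    sstart <- vals[, 7]; send <- vals[, 8]
    minus <- sstart > send
    df <- data.frame(
        query = m[, 1], scaffold = m[, 2],
        identity = vals[, 1], aln_length = as.integer(vals[, 2]),
        mismatches = as.integer(vals[, 3]), gap_opens = as.integer(vals[, 4]),
        mt_start = as.integer(pmin(vals[, 5], vals[, 6])),
        mt_end = as.integer(pmax(vals[, 5], vals[, 6])),
        n_start = as.integer(pmin(sstart, send)),
        n_end = as.integer(pmax(sstart, send)),
        orientation = ifelse(minus, "-", "+"),
        e_value = vals[, 9], bit_score = vals[, 10],
        stringsAsFactors = FALSE
    )
    if (any(df$e_value < 0)) stop("negative e-value in HSP table")
    df
}

.emptyHspTable <- function() {
    data.frame(query = character(), scaffold = character(),
               identity = numeric(), aln_length = integer(),
               mismatches = integer(), gap_opens = integer(),
               mt_start = integer(), mt_end = integer(),
               n_start = integer(), n_end = integer(),
               orientation = character(), e_value = numeric(),
               bit_score = numeric(), stringsAsFactors = FALSE)
}

#' Read scaffold lengths from a genome FASTA or a two-column TSV
#'
#' The genome index drives the short-contig filter and the scaffold order
#' used when numbering NUMTs. Scaffold order is preserved from the source
#' file.
#'
#' @param path Genome FASTA, or a headerless TSV with columns scaffold id and
#'   length in bp.
#' @return A [GenomeInfoDb::Seqinfo] with one entry per scaffold.
#' @export
readGenomeIndex <- function(path) {
    first <- readLines(path, n = 1L)
    if (length(first) && startsWith(first, ">")) {
        len <- Biostrings::fasta.seqlengths(path)
        names(len) <- sub("\\s.*$", "", names(len))
    } else {
        df <- utils::read.table(path, sep = "\t", header = FALSE,
                                col.names = c("scaffold", "length"),
                                colClasses = c("character", "integer"))
        len <- stats::setNames(df$length, df$scaffold)
    }
    if (anyDuplicated(names(len))) stop("duplicate scaffold ids in ", path)
    if (any(len < 1)) stop("scaffold lengths must be >= 1")
    GenomeInfoDb::Seqinfo(seqnames = names(len), seqlengths = unname(len))
}

#' Read protein-coding gene models from GFF3 or BED6
#'
#' Noncoding features are dropped, and gene features without a recognizable
#' gene symbol (attributes `gene_name`, `Name` or `gene`) are skipped with a
#' warning. Genes are returned sorted by scaffold then start.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or 6-column BED file (name column is the
#'   gene symbol).
#' @return A sorted `GRanges` with metadata column `symbol`.
#' @export
readGeneAnnotation <- function(path) {
    is_gff <- grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)
    if (!is_gff) {
        first <- readLines(path, n = 1L)
        is_gff <- length(first) && grepl("^##gff", first)
    }
    if (is_gff) {
        gr <- rtracklayer::import(path, format = "gff3")
        noncoding <- c("lncRNA", "ncRNA", "tRNA", "rRNA", "snoRNA", "snRNA",
                       "miRNA", "pseudogene", "ncRNA_gene")
        gr <- gr[!(as.character(gr$type) %in% noncoding)]
        gr <- gr[as.character(gr$type) == "gene"]
        bt <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else gr$biotype
        if (!is.null(bt)) gr <- gr[is.na(bt) | bt == "protein_coding"]
        sym <- rep(NA_character_, length(gr))
        for (field in c("gene_name", "Name", "gene")) {
            v <- mcols(gr)[[field]]
            if (!is.null(v)) sym[is.na(sym) & !is.na(v)] <- v[is.na(sym) & !is.na(v)]
        }
        drop <- is.na(sym) | !nzchar(sym)
        if (any(drop))
            warning(sum(drop), " gene feature(s) without a gene symbol skipped")
        gr <- gr[!drop]
        sym <- sym[!drop]
        mcols(gr) <- DataFrame(symbol = sym)
    } else {
        gr <- rtracklayer::import(path, format = "bed")
        sym <- gr$name
        drop <- is.na(sym) | !nzchar(sym)
        if (any(drop))
            warning(sum(drop), " BED record(s) without a gene symbol skipped")
        gr <- gr[!drop]
        mcols(gr) <- DataFrame(symbol = sym[!drop])
    }
    BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Read repeat (transposable element) annotation
#'
#' Accepts RepeatMasker `.out` files (three header lines, then
#' whitespace-separated records) or BED files. Overlapping intervals are
#' retained as given.
#'
#' @param path RepeatMasker `.out` or BED file.
#' @return A `GRanges` with metadata columns `repeat_class` (the part of the
#'   class/family label before `/`) and `repeat_label` (full label; for BED
#'   input, the name column).
#' @export
readRepeatAnnotation <- function(path) {
    lines <- readLines(path)
    first_data <- if (length(lines) >= 4L) lines[4L] else ""
    looks_rm <- length(lines) >= 1L &&
        (grepl("^\\s*SW", lines[1]) || grepl("score", lines[1], fixed = TRUE))
    if (looks_rm) {
        body <- lines[-seq_len(min(3L, length(lines)))]
        body <- body[nzchar(trimws(body))]
        if (!length(body))
            return(GRanges(repeat_class = character(),
                           repeat_label = character()))
        fields <- strsplit(trimws(body), "\\s+")
        bad <- which(lengths(fields) < 11L)
        if (length(bad))
            stop("unparseable RepeatMasker record at line ", bad[1] + 3L)
        scaf <- vapply(fields, `[`, character(1), 5L)
        beg <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 6L)))
        end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 7L)))
        if (anyNA(beg) || anyNA(end)) {
            bad <- which(is.na(beg) | is.na(end))[1]
            stop("unparseable coordinates at line ", bad + 3L)
        }
        lab <- vapply(fields, `[`, character(1), 11L)
        GRanges(scaf, IRanges(beg, end),
                repeat_class = sub("/.*$", "", lab), repeat_label = lab)
    } else {
        gr <- rtracklayer::import(path, format = "bed")
        lab <- if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr))
        mcols(gr) <- DataFrame(repeat_class = sub("/.*$", "", lab),
                               repeat_label = lab)
        gr
    }
}

#' Read a rooted, time-calibrated species tree
#'
#' The tree must be rooted, strictly bifurcating (the both-clades ancestral
#' rule needs binary nodes), have branch lengths in Myr on every edge, unique
#' tip labels, and be ultrametric within a relative tolerance of 1e-6. Node
#' ages (Myr before present) are attached as element `node_age`, indexed by
#' ape node number.
#'
#' @param path Newick file.
#' @return An [ape::read.tree] `phylo` object with an extra `node_age`
#'   element (numeric of length `Ntip + Nnode`).
#' @export
readTree <- function(path) {
    tr <- ape::read.tree(path)
    if (is.null(tr)) stop("could not parse newick tree from ", path)
    checkPhylogeny(tr)
}

#' Validate a phylogeny and compute node ages
#'
#' @param tr A `phylo` object.
#' @param tol Relative ultrametricity tolerance.
#' @return The tree with `node_age` attached.
#' @export
checkPhylogeny <- function(tr, tol = 1e-6) {
    if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in tree")
    if (is.null(tr$edge.length) || anyNA(tr$edge.length))
        stop("tree must carry branch lengths on every edge")
    if (!ape::is.rooted(tr)) stop("tree must be rooted")
    if (!ape::is.binary(tr))
        stop("tree must be strictly bifurcating (no polytomies)")
    depth <- ape::node.depth.edgelength(tr)
    tip_depth <- depth[seq_len(ape::Ntip(tr))]
    if (diff(range(tip_depth)) > tol * max(tip_depth))
        stop("tree is not ultrametric within tolerance")
    tr$node_age <- max(tip_depth) - depth
    tr$node_age[abs(tr$node_age) < tol * max(tip_depth)] <- 0
    tr
}

#' Ages of tree nodes in Myr before present
#'
#' @param tr A tree from [readTree()] or [checkPhylogeny()].
#' @return Named numeric: tips (age 0) followed by internal nodes, names are
#'   tip labels and node numbers.
#' @export
nodeAges <- function(tr) {
    if (is.null(tr$node_age)) tr <- checkPhylogeny(tr)
    nm <- c(tr$tip.label, as.character(ape::Ntip(tr) + seq_len(tr$Nnode)))
    stats::setNames(tr$node_age, nm)
}

#' Write / read NUMT and block tables as BED
#'
#' Emitted BED is 0-based half-open with columns chrom, start, end, name,
#' score (percent identity for NUMTs, member count for blocks), strand, and
#' an extra column holding the mitogenome footprint as
#' `"start-end[,start-end]"` (1-based inclusive on the linearized
#' mitogenome). `readNumtBed()` inverts `writeNumtBed()` exactly.
#'
#' @param x A [NumtSet-class] or [NumtBlockSet-class].
#' @param path Output file.
#' @return `writeNumtBed` returns `path` invisibly; `readNumtBed` a
#'   [NumtSet-class].
#' @export
writeNumtBed <- function(x, path) {
    gr <- x@ranges
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = BiocGenerics::start(gr) - 1L,
        end = BiocGenerics::end(gr),
        name = mcols(gr)$numt_id,
        score = mcols(gr)$identity,
        strand = as.character(BiocGenerics::strand(gr)),
        mt_footprint = .footprintString(mcols(gr)$mt_intervals),
        n_hsps = mcols(gr)$n_hsps
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeNumtBed
#' @param species,mt_length Species code and mitogenome length to attach on
#'   reading.
#' @export
readNumtBed <- function(path, species = "Sp", mt_length = 16600) {
    if (!length(readLines(path, n = 1L)))
        return(NumtSet(species = species, mtLength = mt_length))
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand", "mt_footprint",
                                          "n_hsps"),
                            colClasses = c("character", "integer", "integer",
                                           "character", "numeric", "character",
                                           "character", "integer"))
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = df$strand)
    mcols(gr) <- DataFrame(numt_id = df$name, identity = df$score,
                           mt_intervals = .parseFootprintString(df$mt_footprint),
                           n_hsps = df$n_hsps)
    NumtSet(gr, species = species, mtLength = mt_length)
}

#' @rdname writeNumtBed
#' @export
writeBlockBed <- function(x, path) {
    gr <- x@ranges
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = BiocGenerics::start(gr) - 1L,
        end = BiocGenerics::end(gr),
        name = mcols(gr)$block_id,
        score = mcols(gr)$n_members,
        strand = ".",
        members = vapply(as.list(mcols(gr)$members), paste,
                         character(1), collapse = ",")
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
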