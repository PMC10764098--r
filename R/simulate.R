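#' Configuration for the NUMT forward simulator
#'
#' Defines the study conditions the simulator emulates: a time-calibrated
#' species tree, a linearized mitogenome with a 13-gene protein-coding map,
#' nuclear scaffolds carrying conserved gene synteny, transposable-element
#' annotation, and NUMT gain/loss/decay along the tree. All randomness flows
#' from `seed`.
#'
#' @param seed Integer seed (mandatory).
#' @param tree Newick string or `phylo`; rooted, binary, ultrametric, branch
#'   lengths in Myr. Default: six taxa spanning 60 Myr.
#' @param mt_length Linearized mitogenome length in bp.
#' @param n_scaffolds Nuclear scaffolds per species.
#' @param genes_per_scaffold Protein-coding genes per scaffold (shared
#'   symbols across species; the microsynteny anchor system).
#' @param gene_length Gene span in bp.
#' @param intergenic_gap Gap between consecutive elements in bp; must exceed
#'   the block-assembly threshold so independent insertions stay distinct.
#' @param numt_gap Gap between NUMT copies inserted at the same position, in
#'   bp; below the block threshold so co-inserted copies assemble into
#'   blocks.
#' @param scaffold_pad Scaffold padding at each end in bp (also keeps units
#'   clear of the background-placement edge exclusion).
#' @param te_density Target fraction of each scaffold covered by TE
#'   intervals (mammal-like, ~0.35).
#' @param te_len_meanlog,te_len_sdlog Log-normal TE length parameters.
#' @param gain_rate NUMT gains per Myr per lineage (Poisson process on
#'   branches).
#' @param numt_len_meanlog,numt_len_sdlog Log-normal NUMT length parameters
#'   (mean ~200 bp, matching the error-model default).
#' @param numt_len_min Minimum NUMT length in bp (the detection limit).
#' @param loss_rate Loss rate per copy per Myr (exponential waiting).
#' @param subst_rate Substitutions per site per Myr for inserted copies.
#' @param origin_bias `NULL` for uniform mtDNA origin, or
#'   `list(weight =, start =, end =)`: with probability `weight` a gain
#'   start is drawn uniformly from `[start, end]` instead of the whole
#'   mitogenome.
#' @param rearrangement_rate Gene-order inversion events per Myr per
#'   lineage.
#' @return A validated config (classed list `numt_sim_config`).
#' @export
simConfig <- function(seed,
                      tree = "(((SppA:10,SppB:10):25,(SppC:20,SppD:20):15):15,(SppE:30,SppF:30):20);",
                      mt_length = 16600,
                      n_scaffolds = 3,
                      genes_per_scaffold = 40,
                      gene_length = 1500,
                      intergenic_gap = 3000,
                      numt_gap = 800,
                      scaffold_pad = 25000,
                      te_density = 0.35,
                      te_len_meanlog = log(500),
                      te_len_sdlog = 0.7,
                      gain_rate = 0.9,
                      numt_len_meanlog = log(200),
                      numt_len_sdlog = 0.8,
                      numt_len_min = 30,
                      loss_rate = 0.01,
                      subst_rate = 0.002,
                      origin_bias = NULL,
                      rearrangement_rate = 0) {
    if (missing(seed) || is.null(seed)) stop("seed is mandatory")
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    tree <- checkPhylogeny(tree)
    cfg <- list(seed = as.integer(seed), tree = tree,
                mt_length = as.integer(mt_length),
                n_scaffolds = as.integer(n_scaffolds),
                genes_per_scaffold = as.integer(genes_per_scaffold),
                gene_length = as.integer(gene_length),
                intergenic_gap = as.integer(intergenic_gap),
                numt_gap = as.integer(numt_gap),
                scaffold_pad = as.integer(scaffold_pad),
                te_density = te_density,
                te_len_meanlog = te_len_meanlog, te_len_sdlog = te_len_sdlog,
                gain_rate = gain_rate,
                numt_len_meanlog = numt_len_meanlog,
                numt_len_sdlog = numt_len_sdlog,
                numt_len_min = as.integer(numt_len_min),
                loss_rate = loss_rate, subst_rate = subst_rate,
                origin_bias = origin_bias,
                rearrangement_rate = rearrangement_rate)
    rates <- c(cfg$te_density, cfg$gain_rate, cfg$loss_rate, cfg$subst_rate,
               cfg$rearrangement_rate)
    if (any(rates < 0)) stop("all rates must be >= 0")
    if (!is.null(origin_bias) &&
        !all(c("weight", "start", "end") %in% names(origin_bias)))
        stop("origin_bias needs weight, start, end")
    structure(cfg, class = "numt_sim_config")
}

# Toy mitogenome: 13 protein-coding genes with human-like proportional
# lengths (rounded to codons), laid head-to-tail with tRNA-sized gaps.
.mtGeneMap <- function(mt_length) {
    lens <- c(ND1 = 957, ND2 = 1044, COX1 = 1545, COX2 = 684, ATP8 = 207,
              ATP6 = 681, COX3 = 784, ND3 = 346, ND4L = 297, ND4 = 1378,
              ND5 = 1812, ND6 = 528, CYTB = 1141)
    lens <- lens - lens %% 3
    gap <- 70
    start <- 650  # 12S/16S-like leader compressed
    df <- data.frame(gene = names(lens), start = NA_integer_,
                     end = NA_integer_)
    pos <- start
    for (i in seq_along(lens)) {
        df$start[i] <- pos
        df$end[i] <- pos + lens[[i]] - 1L
        pos <- df$end[i] + gap
    }
    if (max(df$end) > mt_length - 500)
        stop("mt_length too short for the 13-gene map")
    df
}

.randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random ORF: ATG + codons that are not stops under either code + TAA
.randomOrf <- function(len) {
    stopifnot(len %% 3 == 0, len >= 9)
    bases <- c("A", "C", "G", "T")
    all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    stops <- union(names(which(Biostrings::GENETIC_CODE == "*")),
                   names(which(Biostrings::getGeneticCode("SGC1") == "*")))
    ok <- setdiff(all_codons, stops)
    n_mid <- len / 3 - 2L
    paste0("ATG", paste(sample(ok, n_mid, replace = TRUE), collapse = ""), "TAA")
}

.sampleNumtLength <- function(cfg) {
    repeat {
        l <- as.integer(round(stats::rlnorm(1, cfg$numt_len_meanlog,
                                            cfg$numt_len_sdlog)))
        if (l >= cfg$numt_len_min && l <= cfg$mt_length) return(l)
    }
}

.sampleMtStart <- function(cfg, len) {
    repeat {
        if (!is.null(cfg$origin_bias) &&
            stats::runif(1) < cfg$origin_bias$weight) {
            s <- sample(seq(cfg$origin_bias$start, cfg$origin_bias$end), 1L)
        } else {
            s <- sample.int(cfg$mt_length, 1L)
        }
        e <- s + len - 1L
        # reject wrap placements whose pieces would fall under the
        # detection length limit
        if (e <= cfg$mt_length) return(s)
        head_len <- cfg$mt_length - s + 1L
        tail_len <- e - cfg$mt_length
        if (head_len >= cfg$numt_len_min && tail_len >= cfg$numt_len_min)
            return(s)
    }
}

#' Simulate a truth-annotated multi-species NUMT dataset
#'
#' Forward simulation along the config's species tree: NUMT gains arrive as
#' a Poisson process on branches, each picking a mitogenome start (from the
#' origin-bias profile), a length, an orientation, and a nuclear insertion
#' position between elements of the ancestral scaffold; copies are inherited
#' by descendant lineages, lost with the stated rate, and accumulate
#' substitutions with time since insertion. Gene order is conserved across
#' species except for lineage-specific inversion events. HSP tables are
#' emitted directly from the truth (identity = 100 * (1 - substitutions /
#' length); a footprint crossing the linearization boundary is split into
#' two HSPs), so the whole pipeline is testable without running an aligner.
#'
#' @param config A [simConfig()].
#' @param out_dir Optional directory; when given, per-species genome FASTA
#'   (`{sp}_genome.fa`), gene GFF3 (`{sp}_genes.gff3`), TE BED
#'   (`{sp}_te.bed`), HSP table (`{sp}_hsps.tsv`), plus `mitogenome.fa`,
#'   `mt_genes.tsv`, `tree.nwk` and `truth_copies.tsv` are written.
#' @param emit_sequences Generate nucleotide sequences (needed for FASTA
#'   output and ORF analysis); coordinate-only simulation is faster.
#' @return List: `species`, per-species `data` (genome_index, genes,
#'   repeats, hsps, numt truth, genome sequences if emitted), `mt`
#'   (sequence, gene map, length), `truth` (events, copies, groups,
#'   ancestral node counts), `config`.
#' @export
simulateDataset <- function(config, out_dir = NULL, emit_sequences = TRUE) {
    cfg <- config
    set.seed(cfg$seed)
    tr <- cfg$tree
    ntip <- ape::Ntip(tr)
    root <- ntip + 1L
    mt_genes <- .mtGeneMap(cfg$mt_length)
    mt_seq <- NULL
    if (emit_sequences) {
        mt_chars <- strsplit(.randomDna(cfg$mt_length), "")[[1]]
        for (i in seq_len(nrow(mt_genes))) {
            orf <- strsplit(.randomOrf(mt_genes$end[i] - mt_genes$start[i] + 1L),
                            "")[[1]]
            mt_chars[mt_genes$start[i]:mt_genes$end[i]] <- orf
        }
        mt_seq <- Biostrings::DNAString(paste(mt_chars, collapse = ""))
    }

    # ancestral scaffold element lists: genes g{scaffold}_{i}
    anc <- lapply(seq_len(cfg$n_scaffolds), function(s) {
        data.frame(type = "gene",
                   id = sprintf("g%d_%03d", s, seq_len(cfg$genes_per_scaffold)),
                   orient = "+", event = NA_integer_,
                   stringsAsFactors = FALSE)
    })
    names(anc) <- sprintf("scaf%d", seq_len(cfg$n_scaffolds))

    events <- list()      # per gain: id, edge, node below, time of origin (age)
    state <- vector("list", ntip + tr$Nnode)   # element lists per node
    state[[root]] <- anc
    node_order <- .preorderEdges(tr)
    copies_alive <- vector("list", ntip + tr$Nnode)  # event ids alive per node
    copies_alive[[root]] <- integer(0)

    for (ei in node_order) {
        parent <- tr$edge[ei, 1]; child <- tr$edge[ei, 2]
        blen <- tr$edge.length[ei]
        st <- state[[parent]]
        alive <- copies_alive[[parent]]
        # losses of inherited copies
        if (length(alive) && cfg$loss_rate > 0) {
            p_loss <- 1 - exp(-cfg$loss_rate * blen)
            lost <- alive[stats::runif(length(alive)) < p_loss]
            if (length(lost)) {
                alive <- setdiff(alive, lost)
                st <- lapply(st, function(df)
                    df[!(df$type == "numt" & df$event %in% lost), ,
                       drop = FALSE])
            }
        }
        # rearrangements: invert a contiguous element run on one scaffold
        n_rear <- stats::rpois(1, cfg$rearrangement_rate * blen)
        for (r in seq_len(n_rear)) {
            sc <- sample(names(st), 1L)
            df <- st[[sc]]
            if (nrow(df) < 2L) next
            a <- sample.int(nrow(df), 1L)
            b <- min(nrow(df), a + sample.int(max(1L, nrow(df) %/% 3L), 1L))
            seg <- df[a:b, , drop = FALSE]
            seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
            seg$orient <- ifelse(seg$orient == "+", "-", "+")
            st[[sc]] <- rbind(if (a > 1) df[1:(a - 1), ], seg,
                              if (b < nrow(df)) df[(b + 1):nrow(df), ])
        }
        # gains
        n_gain <- stats::rpois(1, cfg$gain_rate * blen)
        parent_age <- tr$node_age[parent]
        child_age <- tr$node_age[child]
        for (gn in seq_len(n_gain)) {
            len <- .sampleNumtLength(cfg)
            mt_start <- .sampleMtStart(cfg, len)
            ev_id <- length(events) + 1L
            t_origin <- stats::runif(1, child_age, parent_age)
            events[[ev_id]] <- list(id = ev_id, edge = ei, child = child,
                                    mt_start = mt_start, length = len,
                                    orientation = sample(c("+", "-"), 1L),
                                    t_origin = t_origin)
            sc <- sample(names(st), 1L)
            df <- st[[sc]]
            pos <- sample.int(nrow(df) + 1L, 1L)
            newrow <- data.frame(type = "numt", id = sprintf("ev%d", ev_id),
                                 orient = events[[ev_id]]$orientation,
                                 event = ev_id, stringsAsFactors = FALSE)
            st[[sc]] <- rbind(if (pos > 1) df[1:(pos - 1), ], newrow,
                              if (pos <= nrow(df)) df[pos:nrow(df), ])
            alive <- c(alive, ev_id)
        }
        state[[child]] <- st
        copies_alive[[child]] <- alive
    }

    events_df <- do.call(rbind, lapply(events, function(e)
        data.frame(event = e$id, edge = e$edge, child_node = e$child,
                   mt_start = e$mt_start, length = e$length,
                   orientation = e$orientation, t_origin_myr = e$t_origin)))
    if (is.null(events_df))
        events_df <- data.frame(event = integer(), edge = integer(),
                                child_node = integer(), mt_start = integer(),
                                length = integer(), orientation = character(),
                                t_origin_myr = numeric())

    species <- tr$tip.label
    per_species <- stats::setNames(vector("list", length(species)), species)
    copies_rows <- list()
    for (sp_i in seq_along(species)) {
        sp <- species[sp_i]
        st <- state[[sp_i]]
        build <- .assembleSpecies(sp, st, events, cfg, mt_seq, mt_genes)
        per_species[[sp]] <- build
        if (nrow(build$numt_truth))
            copies_rows[[sp]] <- cbind(species = sp, build$numt_truth)
    }
    copies_df <- if (length(copies_rows)) do.call(rbind, copies_rows)
                 else data.frame()
    rownames(copies_df) <- NULL

    # true ortholog groups: surviving copies of one event
    groups <- if (nrow(copies_df))
        lapply(split(copies_df$species, copies_df$event), unique)
    else list()
    # true ancestral counts under the both-child-clades rule
    anc_nodes <- ntip + seq_len(tr$Nnode)
    anc_counts <- vapply(anc_nodes, function(nd) {
        ct <- .childTips(tr, nd)
        sum(vapply(groups, function(pr)
            any(pr %in% ct[[1]]) && any(pr %in% ct[[2]]), logical(1)))
    }, integer(1))

    truth <- list(events = events_df, copies = copies_df,
                  groups = groups,
                  ancestral = data.frame(node = anc_nodes,
                                         age_myr = tr$node_age[anc_nodes],
                                         count = anc_counts))
    out <- list(species = species, data = per_species,
                mt = list(sequence = mt_seq, genes = mt_genes,
                          length = cfg$mt_length),
                truth = truth, config = cfg)
    if (!is.null(out_dir)) .writeSimDataset(out, out_dir)
    invisible(out)
}

# depth-first preorder of edge indices from the root
.preorderEdges <- function(tr) {
    root <- ape::Ntip(tr) + 1L
    out <- integer(0)
    stack <- root
    while (length(stack)) {
        n <- stack[length(stack)]; stack <- stack[-length(stack)]
        eis <- which(tr$edge[, 1] == n)
        out <- c(out, eis)
        stack <- c(stack, tr$edge[eis, 2])
    }
    out
}

# lay out one species' scaffolds from element lists; returns coordinates,
# annotations, HSPs and (optionally) sequences
.assembleSpecies <- function(sp, st, events, cfg, mt_seq, mt_genes) {
    tip_age <- 0
    gene_rows <- list(); numt_rows <- list(); hsp_rows <- list()
    seqs <- character(length(st))
    scaffold_len <- integer(length(st))
    names(scaffold_len) <- names(st)
    for (si in seq_along(st)) {
        df <- st[[si]]
        pos <- cfg$scaffold_pad + 1L
        pieces <- if (!is.null(mt_seq)) list(.randomDna(cfg$scaffold_pad))
                  else list()
        prev_type <- NA_character_
        for (i in seq_len(nrow(df))) {
            gap <- if (is.na(prev_type)) 0L
                   else if (prev_type == "numt" && df$type[i] == "numt")
                       cfg$numt_gap
                   else cfg$intergenic_gap
            if (gap > 0L) {
                if (!is.null(mt_seq))
                    pieces[[length(pieces) + 1L]] <- .randomDna(gap)
                pos <- pos + gap
            }
            if (df$type[i] == "gene") {
                gene_rows[[length(gene_rows) + 1L]] <- data.frame(
                    scaffold = names(st)[si], symbol = df$id[i],
                    start = pos, end = pos + cfg$gene_length - 1L,
                    strand = df$orient[i], stringsAsFactors = FALSE)
                if (!is.null(mt_seq))
                    pieces[[length(pieces) + 1L]] <- .randomDna(cfg$gene_length)
                pos <- pos + cfg$gene_length
            } else {
                ev <- events[[df$event[i]]]
                res <- .emitCopy(sp, ev, df$orient[i], names(st)[si], pos,
                                 cfg, mt_seq)
                numt_rows[[length(numt_rows) + 1L]] <- res$truth
                hsp_rows <- c(hsp_rows, res$hsps)
                if (!is.null(mt_seq))
                    pieces[[length(pieces) + 1L]] <- res$seq
                pos <- pos + ev$length
            }
            prev_type <- df$type[i]
        }
        if (!is.null(mt_seq)) {
            pieces[[length(pieces) + 1L]] <- .randomDna(cfg$scaffold_pad)
            seqs[si] <- paste(unlist(pieces), collapse = "")
            scaffold_len[si] <- nchar(seqs[si])
        } else {
            scaffold_len[si] <- pos - 1L + cfg$scaffold_pad
        }
    }
    gidx <- GenomeInfoDb::Seqinfo(seqnames = names(st),
                                  seqlengths = unname(scaffold_len))
    genes_df <- do.call(rbind, gene_rows)
    genes <- GRanges(genes_df$scaffold, IRanges(genes_df$start, genes_df$end),
                     strand = genes_df$strand, symbol = genes_df$symbol,
                     seqinfo = gidx)
    repeats <- .simulateTe(gidx, cfg)
    numt_truth <- if (length(numt_rows)) do.call(rbind, numt_rows)
                  else data.frame(event = integer(), scaffold = character(),
                                  start = integer(), end = integer(),
                                  orientation = character(),
                                  mt_start = integer(), length = integer(),
                                  substitutions = integer(),
                                  identity = numeric())
    hsps <- if (length(hsp_rows)) do.call(rbind, hsp_rows) else .emptyHspTable()
    genome <- NULL
    if (!is.null(mt_seq)) {
        genome <- Biostrings::DNAStringSet(seqs)
        names(genome) <- names(st)
    }
    list(genome_index = gidx, genes = genes, repeats = repeats, hsps = hsps,
         numt_truth = numt_truth, genome = genome)
}

# one surviving copy at a tip: mutate, build sequence and HSP rows
.emitCopy <- function(sp, ev, orient_now, scaffold, pos, cfg, mt_seq) {
    len <- ev$length
    age <- ev$t_origin  # tip age is 0, so time since insertion = t_origin
    p_sub <- min(0.75, cfg$subst_rate * age)
    n_sub <- stats::rbinom(1, len, p_sub)
    identity <- round(100 * (1 - n_sub / len), 2)
    mt_s <- ev$mt_start
    mt_e_raw <- mt_s + len - 1L
    wraps <- mt_e_raw > cfg$mt_length
    seq_str <- NULL
    if (!is.null(mt_seq)) {
        if (wraps) {
            s1 <- as.character(Biostrings::subseq(mt_seq, mt_s, cfg$mt_length))
            s2 <- as.character(Biostrings::subseq(mt_seq, 1L,
                                                  mt_e_raw - cfg$mt_length))
            base <- paste0(s1, s2)
        } else {
            base <- as.character(Biostrings::subseq(mt_seq, mt_s, mt_e_raw))
        }
        if (n_sub > 0) {
            chars <- strsplit(base, "")[[1]]
            sites <- sample.int(len, n_sub)
            for (k in sites) {
                chars[k] <- sample(setdiff(c("A", "C", "G", "T"), chars[k]), 1L)
            }
            base <- paste(chars, collapse = "")
        }
        seq_str <- if (orient_now == "-")
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(base)))
        else base
    } else if (n_sub > 0) {
        # no sequence emitted; substitutions only lower identity
    }
    n_start <- pos; n_end <- pos + len - 1L
    mkhsp <- function(mt_a, mt_b, na, nb) {
        plen <- mt_b - mt_a + 1L
        pid <- identity
        mism <- round(plen * (1 - pid / 100))
        ev_val <- 10^-pmin(180, pmax(5, plen * pid / 200))
        if (orient_now == "+") {
            ss <- na; se <- nb
        } else {
            ss <- nb; se <- na
        }
        data.frame(query = "mt", scaffold = scaffold, identity = pid,
                   aln_length = plen, mismatches = as.integer(mism),
                   gap_opens = 0L, mt_start = mt_a, mt_end = mt_b,
                   n_start = min(ss, se), n_end = max(ss, se),
                   orientation = orient_now, e_value = ev_val,
                   bit_score = round(1.8 * plen * pid / 100, 1),
                   stringsAsFactors = FALSE)
    }
    hsps <- list()
    if (!wraps) {
        hsps[[1]] <- mkhsp(mt_s, mt_e_raw, n_start, n_end)
    } else {
        head_len <- cfg$mt_length - mt_s + 1L
        tail_len <- len - head_len
        if (orient_now == "+") {
            hsps[[1]] <- mkhsp(mt_s, cfg$mt_length, n_start,
                               n_start + head_len - 1L)
            hsps[[2]] <- mkhsp(1L, tail_len, n_start + head_len, n_end)
        } else {
            # minus strand: the mt tail piece comes first along the nucleus
            hsps[[1]] <- mkhsp(1L, tail_len, n_start, n_start + tail_len - 1L)
            hsps[[2]] <- mkhsp(mt_s, cfg$mt_length, n_start + tail_len, n_end)
        }
    }
    truth <- data.frame(event = ev$id, scaffold = scaffold,
                        start = n_start, end = n_end,
                        orientation = orient_now, mt_start = mt_s,
                        length = len, substitutions = n_sub,
                        identity = identity, stringsAsFactors = FALSE)
    list(truth = truth, hsps = hsps, seq = seq_str)
}

.simulateTe <- function(gidx, cfg) {
    len <- GenomeInfoDb::seqlengths(gidx)
    grl <- lapply(names(len), function(sc) {
        L <- len[[sc]]
        target <- cfg$te_density * L
        mean_len <- exp(cfg$te_len_meanlog + cfg$te_len_sdlog^2 / 2)
        n <- max(0L, stats::rpois(1, target / mean_len))
        if (!n) return(GRanges())
        w <- pmax(50L, pmin(L, as.integer(round(
            stats::rlnorm(n, cfg$te_len_meanlog, cfg$te_len_sdlog)))))
        s <- vapply(w, function(wi) sample.int(L - wi + 1L, 1L), integer(1))
        GRanges(sc, IRanges(s, s + w - 1L),
                repeat_class = sample(c("LINE", "SINE", "LTR", "DNA"), n,
                                      replace = TRUE, prob = c(.4, .3, .2, .1)),
                repeat_label = "sim")
    })
    gr <- suppressWarnings(do.call(c, grl))
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(gidx)
    GenomeInfoDb::seqinfo(gr) <- gidx
    gr
}

.writeSimDataset <- function(sim, out_dir) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(sim$mt$sequence)) {
        mt <- Biostrings::DNAStringSet(sim$mt$sequence)
        names(mt) <- "mt"
        Biostrings::writeXStringSet(mt, file.path(out_dir, "mitogenome.fa"))
    }
    utils::write.table(sim$mt$genes, file.path(out_dir, "mt_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ape::write.tree(sim$config$tree, file.path(out_dir, "tree.nwk"))
    for (sp in sim$species) {
        d <- sim$data[[sp]]
        if (!is.null(d$genome))
            Biostrings::writeXStringSet(
                d$genome, file.path(out_dir, sprintf("%s_genome.fa", sp)))
        len <- GenomeInfoDb::seqlengths(d$genome_index)
        utils::write.table(
            data.frame(names(len), unname(len)),
            file.path(out_dir, sprintf("%s_scaffolds.tsv", sp)),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
        .writeGff3(d$genes, file.path(out_dir, sprintf("%s_genes.gff3", sp)))
        .writeBed(d$repeats, file.path(out_dir, sprintf("%s_te.bed", sp)))
        h <- d$hsps
        hsp_out <- data.frame(h$query, h$scaffold, h$identity, h$aln_length,
                              h$mismatches, h$gap_opens, h$mt_start, h$mt_end,
                              ifelse(h$orientation == "+", h$n_start, h$n_end),
                              ifelse(h$orientation == "+", h$n_end, h$n_start),
                              format(h$e_value, scientific = TRUE),
                              h$bit_score)
        utils::write.table(hsp_out,
                           file.path(out_dir, sprintf("%s_hsps.tsv", sp)),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
    }
    utils::write.table(sim$truth$copies,
                       file.path(out_dir, "truth_copies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(out_dir)
}

.writeGff3 <- function(genes, path) {
    lines <- c("##gff-version 3",
               sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_name=%s;gene_biotype=protein_coding",
                       as.character(GenomicRanges::seqnames(genes)),
                       BiocGenerics::start(genes), BiocGenerics::end(genes),
                       as.character(BiocGenerics::strand(genes)),
                       genes$symbol, genes$symbol))
    writeLines(lines, path)
}

.writeBed <- function(gr, path) {
    df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                     BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                     if (!is.null(gr$repeat_class)) gr$repeat_class else ".",
                     0L, ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

#' Emit synthetic per-unit expression evidence
#'
#' A designated fraction of units receives evidence passing the expression
#' criteria (junction reads >= 2 on both sides, coverage > 0.7); all others
#' receive sub-threshold evidence.
#'
#' @param unit_ids Character vector of unit ids.
#' @param expressed_fraction Fraction of units designated expressed.
#' @param seed Optional integer seed for choosing the designated units.
#' @return `data.frame`: `unit_id`, `junc5`, `junc3`, `cov_fraction`,
#'   `designated` (the truth flag).
#' @export
emitExpressionEvidence <- function(unit_ids, expressed_fraction, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(unit_ids)
    n_exp <- round(expressed_fraction * n)
    chosen <- if (n_exp) sample(unit_ids, n_exp) else character(0)
    is_exp <- unit_ids %in% chosen
    data.frame(
        unit_id = unit_ids,
        junc5 = ifelse(is_exp, 3L, 1L),
        junc3 = ifelse(is_exp, 3L, 0L),
        cov_fraction = ifelse(is_exp, 0.9, 0.3),
        designated = is_exp,
        stringsAsFactors = FALSE
    )
}
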