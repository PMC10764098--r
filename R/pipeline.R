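#' Assemble a run configuration for the full pipeline
#'
#' Collects per-species input paths and analysis thresholds (all defaulting
#' to the values used throughout the package) into one validated object.
#' Overridden thresholds are recorded in the run manifest.
#'
#' @param species_inputs Named list, species code -> list of paths with
#'   elements `hsps` (required), `genome` (FASTA or scaffold-length TSV,
#'   required), and optionally `genes` (GFF3/BED with gene symbols),
#'   `repeats` (RepeatMasker .out or BED).
#' @param tree Optional newick path for the ancestry stage.
#' @param mt_length Linearized mitogenome length in bp.
#' @param out_dir Output directory.
#' @param seed Integer seed for the resampling stages.
#' @param max_e,min_len,min_contig,block_gap,origin_span,origin_window,
#'   alpha,null_iters,synteny_k,min_overlap Analysis thresholds.
#' @return Classed list `numt_run_config`.
#' @export
runConfig <- function(species_inputs, tree = NULL, mt_length = 16600,
                      out_dir = "numt_results", seed = 1,
                      max_e = 1e-3, min_len = 30, min_contig = 20000,
                      block_gap = 2000, origin_span = 16000,
                      origin_window = 50, alpha = 0.01, null_iters = 0,
                      synteny_k = 3, min_overlap = 0.5) {
    stopifnot(is.list(species_inputs), length(species_inputs) >= 1,
              !is.null(names(species_inputs)))
    for (sp in names(species_inputs)) {
        si <- species_inputs[[sp]]
        if (is.null(si$hsps) || is.null(si$genome))
            stop("species ", sp, " needs 'hsps' and 'genome' inputs")
    }
    structure(list(species_inputs = species_inputs, tree = tree,
                   mt_length = mt_length, out_dir = out_dir,
                   seed = as.integer(seed), max_e = max_e, min_len = min_len,
                   min_contig = min_contig, block_gap = block_gap,
                   origin_span = origin_span, origin_window = origin_window,
                   alpha = alpha, null_iters = null_iters,
                   synteny_k = synteny_k, min_overlap = min_overlap),
              class = "numt_run_config")
}

#' Run the full NUMT pipeline
#'
#' Executes detection, block assembly, origin analysis, context
#' classification, orthology and ancestry in order, writing per-stage TSV/BED
#' outputs and a JSON manifest (seed, thresholds, per-stage record counts)
#' under the configured output directory. Species without symbol-level gene
#' annotation participate in detection and origin analysis but are excluded
#' from orthology and ancestry, with the reason logged in the manifest.
#'
#' @param config A [runConfig()].
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
runPipeline <- function(config) {
    cfg <- config
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(cfg$seed)
    manifest <- list(package = "numtkit",
                     version = as.character(utils::packageVersion("numtkit")),
                     seed = cfg$seed,
                     thresholds = cfg[setdiff(names(cfg),
                                              c("species_inputs", "tree",
                                                "out_dir"))],
                     stages = list(), excluded = list())
    numts <- list(); blocks <- list(); gidx <- list()
    genes <- list(); repeats <- list()
    for (sp in names(cfg$species_inputs)) {
        si <- cfg$species_inputs[[sp]]
        gi <- readGenomeIndex(si$genome)
        h <- filterHsps(readHspTable(si$hsps), max_e = cfg$max_e,
                        min_len = cfg$min_len)
        ns <- mergeHsps(h, mt_length = cfg$mt_length, species = sp,
                        genome_index = gi)
        ns <- filterByContigLength(ns, gi, min_contig = cfg$min_contig)
        bs <- assembleBlocks(ns, max_gap = cfg$block_gap)
        writeNumtBed(ns, file.path(cfg$out_dir, sprintf("%s_numts.bed", sp)))
        writeBlockBed(bs, file.path(cfg$out_dir, sprintf("%s_blocks.bed", sp)))
        numts[[sp]] <- ns; blocks[[sp]] <- bs; gidx[[sp]] <- gi
        if (!is.null(si$genes)) genes[[sp]] <- readGeneAnnotation(si$genes)
        if (!is.null(si$repeats))
            repeats[[sp]] <- readRepeatAnnotation(si$repeats)
    }
    manifest$stages$detect <- lapply(numts, length)
    summary_df <- do.call(rbind, lapply(names(numts), function(sp)
        numtSummary(numts[[sp]], blocks[[sp]], gidx[[sp]])))
    utils::write.table(summary_df, file.path(cfg$out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    origin <- NULL
    if (length(numts) >= 2L) {
        profiles <- lapply(numts, coverageProfile, span = cfg$origin_span)
        wm <- windowMedians(profiles, window = cfg$origin_window)
        tests <- pairwiseWindowTests(wm, alpha = cfg$alpha)
        utils::write.table(wm, file.path(cfg$out_dir, "window_medians.tsv"),
                           sep = "\t", quote = FALSE)
        origin <- list(window_medians = wm, tests = tests)
        if (cfg$null_iters > 0) {
            origin$null <- reshuffleNull(numts, n_iter = cfg$null_iters,
                                         span = cfg$origin_span,
                                         window = cfg$origin_window,
                                         alpha = cfg$alpha, seed = cfg$seed)
            utils::write.table(
                data.frame(n_significant = origin$null$null_n_significant),
                file.path(cfg$out_dir, "null_distribution.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }
        manifest$stages$origin <- list(n_tests = tests$n_tests,
                                       n_significant = tests$n_significant)
        over <- lapply(profiles, overrepresentedRegions)
        for (sp in names(over)) {
            if (nrow(over[[sp]]))
                utils::write.table(cbind(species = sp, over[[sp]]),
                    file.path(cfg$out_dir, sprintf("%s_overrep.tsv", sp)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }

    context <- list()
    for (sp in names(numts)) {
        if (is.null(genes[[sp]])) next
        cls <- classifyGenicContext(blocks[[sp]], genes[[sp]])
        context[[sp]] <- cls
        utils::write.table(
            data.frame(unit_id = names(cls$classification),
                       context = unname(cls$classification)),
            file.path(cfg$out_dir, sprintf("%s_context.tsv", sp)),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$context <- lapply(context, function(x)
        list(intronic = x$n_intronic, intergenic = x$n_intergenic))

    orth_species <- names(genes)
    manifest$excluded$orthology <- lapply(
        setdiff(names(numts), orth_species),
        function(sp) "no symbol-level gene annotation")
    names(manifest$excluded$orthology) <-
        setdiff(names(numts), orth_species)
    pairs_all <- NULL; groups <- NULL; anc <- NULL; rates <- NULL
    if (length(orth_species) >= 2L) {
        rate <- errorRate()
        contexts <- lapply(orth_species, function(sp)
            buildSyntenyContext(blocks[[sp]], genes[[sp]], k = cfg$synteny_k))
        names(contexts) <- orth_species
        pr <- list()
        for (i in seq_len(length(orth_species) - 1L)) {
            for (j in (i + 1L):length(orth_species)) {
                a <- orth_species[i]; b <- orth_species[j]
                pairs <- assignOrthologs(contexts[[a]], contexts[[b]],
                                         min_overlap = cfg$min_overlap)
                E <- suppressWarnings(errorExpectation(
                    rate, length(blocks[[a]]), length(blocks[[b]])))
                if (nrow(pairs))
                    pr[[length(pr) + 1L]] <- data.frame(
                        species_a = a, unit_a = pairs$unit_a,
                        species_b = b, unit_b = pairs$unit_b,
                        shared_anchors = pairs$shared_anchors,
                        overlap = pairs$overlap, E = E,
                        stringsAsFactors = FALSE)
            }
        }
        pairs_all <- if (length(pr)) do.call(rbind, pr)
                     else data.frame(species_a = character(),
                                     unit_a = character(),
                                     species_b = character(),
                                     unit_b = character(), E = numeric())
        utils::write.table(pairs_all, file.path(cfg$out_dir, "orthologs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$stages$orthology <- list(n_pairs = nrow(pairs_all),
                                          n_comparisons =
                                              choose(length(orth_species), 2))
        all_units <- lapply(blocks[orth_species], blockIds)
        groups <- buildOrthologGroups(pairs_all, all_units = all_units)
        utils::write.table(groups$groups,
                           file.path(cfg$out_dir, "ortholog_groups.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(cfg$tree)) {
            tr <- if (is.character(cfg$tree)) readTree(cfg$tree) else cfg$tree
            keep <- intersect(tr$tip.label, orth_species)
            if (length(keep) >= 2L) {
                tr2 <- checkPhylogeny(ape::keep.tip(tr, keep))
                anc <- ancestralCounts(groups, tr2)
                utils::write.table(anc$counts,
                                   file.path(cfg$out_dir,
                                             "ancestral_counts.tsv"),
                                   sep = "\t", quote = FALSE,
                                   row.names = FALSE)
                # rates use individual NUMTs mapped into block-level groups
                sp_units <- lapply(numts[keep], numtIds)
                block_groups <- .numtLevelGroups(groups, blocks[keep])
                rates <- insertionRate(block_groups, tr2, sp_units)
                utils::write.table(rates,
                                   file.path(cfg$out_dir, "insertion_rates.tsv"),
                                   sep = "\t", quote = FALSE,
                                   row.names = FALSE)
                manifest$stages$ancestry <-
                    list(n_groups = length(groups$presence))
            }
        }
    }
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    invisible(list(numts = numts, blocks = blocks, summary = summary_df,
                   origin = origin, context = context, pairs = pairs_all,
                   groups = groups, ancestral = anc, rates = rates,
                   manifest = manifest))
}

# expand block-level ortholog groups to member NUMT ids so that individual
# NUMTs can be looked up in them
.numtLevelGroups <- function(groups, blocks_list) {
    g <- groups$groups
    rows <- lapply(seq_len(nrow(g)), function(i) {
        sp <- g$species[i]
        mem <- blockMembers(blocks_list[[sp]])[[g$unit_id[i]]]
        if (is.null(mem)) mem <- g$unit_id[i]
        data.frame(group_id = g$group_id[i], species = sp, unit_id = mem,
                   stringsAsFactors = FALSE)
    })
    gg <- do.call(rbind, rows)
    structure(list(groups = gg,
                   presence = lapply(split(gg$species, gg$group_id), unique)),
              class = "numt_ortholog_groups")
}
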