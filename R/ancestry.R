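#' Build ortholog groups from pairwise ortholog tables
#'
#' Units are nodes (`"Species|unit_id"`), accepted ortholog pairs are edges;
#' groups are the connected components of this graph. Comparisons whose
#' false-assignment expectation `E` is 1 or more can be excluded (default),
#' since their pairs are likely chance assignments.
#'
#' @param pairs `data.frame` with columns `species_a`, `unit_a`,
#'   `species_b`, `unit_b`, and optionally `E` (per species-pair
#'   expectation).
#' @param all_units Optional named list, species -> character vector of all
#'   unit ids; units in no pair then form singleton groups.
#' @param drop_unreliable Drop pairs from comparisons with `E >= 1`.
#' @return Object of class `numt_ortholog_groups`: list with `groups` (a
#'   `data.frame` of `group_id`, `species`, `unit_id`) and `presence`
#'   (list, group id -> character vector of species).
#' @export
buildOrthologGroups <- function(pairs, all_units = NULL,
                                drop_unreliable = TRUE) {
    if (nrow(pairs) && drop_unreliable && !is.null(pairs$E)) {
        drop <- pairs$E >= 1
        if (any(drop))
            message("dropping ", sum(drop),
                    " pair(s) from comparisons with E >= 1")
        pairs <- pairs[!drop, , drop = FALSE]
    }
    va <- paste(pairs$species_a, pairs$unit_a, sep = "|")
    vb <- paste(pairs$species_b, pairs$unit_b, sep = "|")
    singletons <- character(0)
    if (!is.null(all_units))
        singletons <- unlist(lapply(names(all_units), function(sp)
            paste(sp, all_units[[sp]], sep = "|")), use.names = FALSE)
    verts <- unique(c(va, vb, singletons))
    if (!length(verts))
        return(structure(list(groups = data.frame(group_id = character(),
                                                  species = character(),
                                                  unit_id = character()),
                              presence = list()),
                         class = "numt_ortholog_groups"))
    g <- igraph::graph_from_data_frame(
        data.frame(from = va, to = vb, stringsAsFactors = FALSE),
        directed = FALSE, vertices = data.frame(name = verts))
    comp <- igraph::components(g)$membership
    sp <- sub("\\|.*$", "", names(comp))
    un <- sub("^[^|]*\\|", "", names(comp))
    gid <- sprintf("og_%d", comp)
    o <- order(comp, sp, un)
    groups <- data.frame(group_id = gid[o], species = sp[o], unit_id = un[o],
                         stringsAsFactors = FALSE)
    presence <- lapply(split(groups$species, groups$group_id), unique)
    structure(list(groups = groups, presence = presence),
              class = "numt_ortholog_groups")
}

#' @export
print.numt_ortholog_groups <- function(x, ...) {
    cat("NUMT ortholog groups:", length(x$presence), "groups over",
        length(unique(x$groups$species)), "species;",
        sum(lengths(x$presence) > 1), "span >= 2 species\n")
    invisible(x)
}

# tip labels descending from each child of `node` in an ape phylo
.childTips <- function(tr, node) {
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    lapply(kids, function(k) {
        if (k <= ape::Ntip(tr)) return(tr$tip.label[k])
        todo <- k
        tips <- character(0)
        while (length(todo)) {
            n <- todo[1]; todo <- todo[-1]
            ch <- tr$edge[tr$edge[, 1] == n, 2]
            tips <- c(tips, tr$tip.label[ch[ch <= ape::Ntip(tr)]])
            todo <- c(todo, ch[ch > ape::Ntip(tr)])
        }
        tips
    })
}

#' Count ancestral NUMTs per tree node
#'
#' A group is ancestral on an internal node when at least one of its member
#' species lies in each of the node's two child clades (the insertion must
#' predate the split). The rule is applied to every node independently, so a
#' widespread group is counted at several nested nodes.
#'
#' @param groups Output of [buildOrthologGroups()].
#' @param tree Tree from [readTree()]/[checkPhylogeny()]; every species with
#'   presence must be a tip.
#' @return List with `counts` (`data.frame`: `node`, `age_myr`, `count`) and
#'   `supporting` (list, node -> character vector of group ids).
#' @export
ancestralCounts <- function(groups, tree) {
    tree <- if (is.null(tree$node_age)) checkPhylogeny(tree) else tree
    sp_all <- unique(unlist(groups$presence))
    missing <- setdiff(sp_all, tree$tip.label)
    if (length(missing))
        stop("species missing from tree: ", paste(missing, collapse = ", "))
    nodes <- ape::Ntip(tree) + seq_len(tree$Nnode)
    supporting <- stats::setNames(vector("list", length(nodes)),
                                  as.character(nodes))
    counts <- integer(length(nodes))
    for (ni in seq_along(nodes)) {
        ct <- .childTips(tree, nodes[ni])
        hit <- vapply(groups$presence, function(pr)
            any(pr %in% ct[[1]]) && any(pr %in% ct[[2]]), logical(1))
        counts[ni] <- sum(hit)
        supporting[[ni]] <- names(groups$presence)[hit]
    }
    list(
        counts = data.frame(node = nodes,
                            age_myr = tree$node_age[nodes],
                            count = counts),
        supporting = supporting
    )
}

#' Per-species NUMT insertion rate
#'
#' The rate (insertions per Myr) is the number of the species' individual
#' NUMTs that have no ortholog in its sister clade (the most closely related
#' species or monophyletic group in the tree), divided by the divergence
#' time from that sister clade (the age of the species' parent node).
#' Post-insertion duplicates are not subtracted.
#'
#' @param groups Output of [buildOrthologGroups()]; unit ids must be in the
#'   same namespace as `species_units`.
#' @param tree Time-calibrated tree containing the species.
#' @param species_units Named list, species -> character vector of that
#'   species' individual NUMT ids.
#' @return `data.frame`: `species`, `n_units`, `n_nonorthologous`,
#'   `divergence_myr`, `rate_per_myr`.
#' @export
insertionRate <- function(groups, tree, species_units) {
    tree <- if (is.null(tree$node_age)) checkPhylogeny(tree) else tree
    res <- lapply(names(species_units), function(sp) {
        tip <- match(sp, tree$tip.label)
        if (is.na(tip)) stop("species not in tree: ", sp)
        parent <- tree$edge[tree$edge[, 2] == tip, 1]
        ct <- .childTips(tree, parent)
        sister <- unlist(ct[!vapply(ct, function(x) sp %in% x, logical(1))])
        t_div <- tree$node_age[parent]
        if (t_div <= 0) stop("zero divergence time for ", sp)
        units <- species_units[[sp]]
        # unit ids of this species that sit in a group also containing a
        # sister-clade species
        gdf <- groups$groups
        shared_groups <- names(groups$presence)[vapply(groups$presence,
            function(pr) any(pr %in% sister), logical(1))]
        orth_units <- gdf$unit_id[gdf$species == sp &
                                  gdf$group_id %in% shared_groups]
        n_non <- sum(!(units %in% orth_units))
        data.frame(species = sp, n_units = length(units),
                   n_nonorthologous = n_non, divergence_myr = t_div,
                   rate_per_myr = n_non / t_div, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}
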