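# Shared fixtures and independent oracles for the test suite.

# one HSP row in the internal (parsed) layout
hspRow <- function(scaffold, n_start, n_end, mt_start, mt_end,
                   orientation = "+", identity = 95,
                   e_value = 1e-50, aln_length = NULL) {
    if (is.null(aln_length)) aln_length <- n_end - n_start + 1L
    data.frame(query = "mt", scaffold = scaffold, identity = identity,
               aln_length = as.integer(aln_length), mismatches = 0L,
               gap_opens = 0L, mt_start = as.integer(mt_start),
               mt_end = as.integer(mt_end), n_start = as.integer(n_start),
               n_end = as.integer(n_end), orientation = orientation,
               e_value = e_value, bit_score = 100,
               stringsAsFactors = FALSE)
}

hspTable <- function(...) do.call(rbind, list(...))

# write an outfmt-6 line (BLAST coordinate conventions: subject reversed on
# the minus strand)
outfmt6Line <- function(scaffold, n_start, n_end, mt_start, mt_end,
                        orientation = "+", identity = 95, e_value = 1e-50) {
    len <- mt_end - mt_start + 1L
    ss <- if (orientation == "+") n_start else n_end
    se <- if (orientation == "+") n_end else n_start
    sprintf("mt\t%s\t%.1f\t%d\t0\t0\t%d\t%d\t%d\t%d\t%g\t100",
            scaffold, identity, len, mt_start, mt_end, ss, se, e_value)
}

# ---- independent brute-force oracle for HSP merging -------------------
# Transitive closure of the adjacent-pair merge predicate along each
# scaffold; deliberately a different algorithm from the package's
# incremental chaining.
oracleMergeHsps <- function(hsps, mt_length, nuclear_gap_max = 10,
                            mt_gap_max = 10) {
    res <- list()
    for (scaf in unique(hsps$scaffold)) {
        h <- hsps[hsps$scaffold == scaf, , drop = FALSE]
        h <- h[order(h$n_start, h$n_end), , drop = FALSE]
        n <- nrow(h)
        comp <- seq_len(n)
        wrapped <- rep(FALSE, n)   # has the growing component wrapped yet
        find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
        for (i in seq_len(max(0, n - 1))) {
            a <- h[i, ]; b <- h[i + 1, ]
            if (a$orientation != b$orientation) next
            if (b$n_start - a$n_end - 1 >= nuclear_gap_max) next
            if (a$orientation == "+") {
                lin <- abs(b$mt_start - (a$mt_end + 1)) <= mt_gap_max
                wrap <- (mt_length - a$mt_end) + (b$mt_start - 1) <= mt_gap_max
            } else {
                lin <- abs((a$mt_start - 1) - b$mt_end) <= mt_gap_max
                wrap <- (a$mt_start - 1) + (mt_length - b$mt_end) <= mt_gap_max
            }
            is_wrap <- !lin && wrap
            root <- find(i)
            if (lin || (wrap && !wrapped[root])) {
                comp[find(i + 1)] <- root
                wrapped[root] <- wrapped[root] || is_wrap
            }
        }
        roots <- vapply(seq_len(n), find, integer(1))
        for (r in unique(roots)) {
            members <- h[roots == r, , drop = FALSE]
            res[[length(res) + 1L]] <- data.frame(
                scaffold = scaf,
                n_start = min(members$n_start), n_end = max(members$n_end),
                orientation = members$orientation[1],
                n_hsps = nrow(members),
                identity = sum(members$identity * members$aln_length) /
                    sum(members$aln_length))
        }
    }
    out <- do.call(rbind, res)
    out[order(out$scaffold, out$n_start), , drop = FALSE]
}

# ---- independent quadratic oracle for block assembly ------------------
oracleBlocks <- function(starts, ends, scaffolds, max_gap = 2000) {
    n <- length(starts)
    comp <- seq_len(n)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (i in seq_len(max(0, n - 1))) {
        for (j in (i + 1):n) {
            if (scaffolds[i] != scaffolds[j]) next
            gap <- max(0, max(starts[i], starts[j]) -
                          min(ends[i], ends[j]) - 1)
            if (gap < max_gap) comp[find(j)] <- find(i)
        }
    }
    vapply(seq_len(n), find, integer(1))
}

# random HSP instance on one scaffold with a mixture of independent hits
# and deliberate chain continuations (boundary gaps included)
randomHspInstance <- function(n, mt_length = 16600) {
    ns_v <- integer(n); ne_v <- integer(n)
    ms_v <- integer(n); me_v <- integer(n)
    ori_v <- character(n)
    pos <- 1L
    for (i in seq_len(n)) {
        continue <- i > 1L && stats::runif(1) < 0.45
        len <- sample(30:300, 1)
        if (continue) {
            gap_n <- sample(-5:15, 1)
            gap_m <- sample(-5:15, 1)
            ns <- ne_v[i - 1L] + gap_n + 1L
            if (ori_v[i - 1L] == "+") {
                ms <- me_v[i - 1L] + gap_m + 1L
                if (ms < 1L || ms + len - 1L > mt_length) continue <- FALSE
            } else {
                me <- ms_v[i - 1L] - gap_m - 1L
                ms <- me - len + 1L
                if (ms < 1L || me > mt_length) continue <- FALSE
            }
        }
        if (!continue) {
            ns <- pos + sample(0:2000, 1)
            ms <- sample.int(mt_length - len, 1)
            ori_v[i] <- sample(c("+", "-"), 1)
        } else {
            ori_v[i] <- ori_v[i - 1L]
        }
        ns_v[i] <- ns; ne_v[i] <- ns + len - 1L
        ms_v[i] <- ms; me_v[i] <- ms + len - 1L
        pos <- max(pos, ne_v[i])
    }
    data.frame(query = "mt", scaffold = "scafX",
               identity = round(stats::runif(n, 70, 100), 1),
               aln_length = ne_v - ns_v + 1L, mismatches = 0L,
               gap_opens = 0L, mt_start = ms_v, mt_end = me_v,
               n_start = ns_v, n_end = ne_v, orientation = ori_v,
               e_value = 1e-50, bit_score = 100,
               stringsAsFactors = FALSE)
}

# detect chain used across tests
detectSpecies <- function(sim, sp, mt_length = 16600) {
    d <- sim$data[[sp]]
    ns <- mergeHsps(filterHsps(d$hsps), mt_length = mt_length, species = sp,
                    genome_index = d$genome_index)
    filterByContigLength(ns, d$genome_index)
}

# map called NUMT ids to true event ids by exact coordinates
eventMap <- function(sim, numts, sp) {
    df <- as.data.frame(numts)
    tru <- sim$truth$copies[sim$truth$copies$species == sp, , drop = FALSE]
    m <- merge(df, tru, by.x = c("scaffold", "start", "end"),
               by.y = c("scaffold", "start", "end"))
    stats::setNames(m$event, m$numt_id)
}

# near-star tree: internal branches of 0.01 Myr, so gains are effectively
# independent across species (uniform-origin calibration fixture)
starLikeTree <- function(n = 10, depth = 30) {
    nwk <- sprintf("S%02d:%.2f", 1, depth)
    d <- depth
    for (i in 2:n) {
        d <- d + 0.01
        nwk <- sprintf("(%s,S%02d:%.2f):0.01", nwk, i, d - 0.01)
    }
    # wrap: last paren carries root edge; strip trailing root length
    nwk <- sub(":0\\.01$", "", nwk)
    ape::read.tree(text = paste0(nwk, ";"))
}
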