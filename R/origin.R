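#' Per-base mitogenome coverage by NUMT footprints
#'
#' Depth of NUMT mitogenome footprints over the first `span` bp of the
#' linearized mitogenome (footprint bases beyond `span` are clipped off for
#' this analysis; the D-loop tail varies in length across species and is
#' excluded by the default span).
#'
#' @param numts A [NumtSet-class], or an `IRangesList` of mitogenome
#'   footprints.
#' @param span Analysis span in bp.
#' @return Integer vector of length `span`; element i is the number of
#'   footprints covering base i.
#' @export
coverageProfile <- function(numts, span = 16000) {
    fp <- if (is(numts, "NumtSet")) mcols(numts@ranges)$mt_intervals
          else numts
    ir <- unlist(IRangesList(fp), use.names = FALSE)
    ir <- IRanges::restrict(ir, start = 1L, end = as.integer(span))
    ir <- ir[IRanges::width(ir) > 0L]
    as.integer(IRanges::coverage(ir, width = as.integer(span)))
}

#' Median coverage per sliding window
#'
#' Scans each species' coverage profile with non-overlapping windows
#' (default 50 bp; 16,000 bp / 50 bp = 320 windows) and records the median
#' per-base coverage per window.
#'
#' @param profiles Named list, species -> integer coverage vector (all the
#'   same span).
#' @param window Window width in bp; must divide the span.
#' @return Numeric matrix, species x windows.
#' @export
windowMedians <- function(profiles, window = 50) {
    spans <- unique(lengths(profiles))
    if (length(spans) != 1L) stop("all profiles must share one span")
    span <- spans[[1]]
    if (span %% window != 0L)
        stop("span (", span, ") is not divisible by window (", window, ")")
    W <- span %/% window
    med <- t(vapply(profiles, function(p)
        .cpp_col_medians(matrix(as.numeric(p), nrow = window)),
        numeric(W)))
    dimnames(med) <- list(names(profiles), paste0("w", seq_len(W)))
    med
}

#' Pairwise rank-sum tests between all window pairs
#'
#' For each unordered pair of windows, the across-species vectors of window
#' medians are compared with a two-sided Mann-Whitney U test (normal
#' approximation with tie and continuity correction; exact when both
#' samples have fewer than 8 observations and no ties). P-values are
#' Benjamini-Hochberg adjusted over all W(W-1)/2 tests.
#'
#' @param table Species x window matrix from [windowMedians()].
#' @param alpha Significance threshold on the adjusted p-values.
#' @return List: `q_matrix` (symmetric window x window adjusted p-values,
#'   `NA` diagonal), `p_matrix`, `n_tests`, `n_significant`, `alpha`.
#' @export
pairwiseWindowTests <- function(table, alpha = 0.01) {
    if (nrow(table) < 2L) stop("need >= 2 species rows")
    W <- ncol(table)
    S <- nrow(table)
    if (S < 8L) {
        p <- matrix(NA_real_, W, W)
        for (i in seq_len(W - 1L)) for (j in (i + 1L):W) {
            p[i, j] <- p[j, i] <- ranksumTest(table[, i], table[, j])
        }
    } else {
        p <- .cpp_pairwise_ranksum_p(table)
    }
    ut <- upper.tri(p)
    q <- matrix(NA_real_, W, W, dimnames = dimnames(p))
    qv <- stats::p.adjust(p[ut], method = "BH")
    q[ut] <- qv
    q <- pmin(q, t(q), na.rm = TRUE)
    diag(q) <- NA_real_
    list(q_matrix = q, p_matrix = p, n_tests = sum(ut & !is.na(p)),
         n_significant = sum(qv < alpha, na.rm = TRUE), alpha = alpha)
}

#' Two-sided rank-sum (Mann-Whitney U) test p-value
#'
#' Normal approximation with tie and continuity correction; exact null
#' distribution when both samples have fewer than 8 observations and no
#' ties are present.
#'
#' @param x,y Numeric samples.
#' @return Two-sided p-value. Identical constant samples give p = 1.
#' @export
ranksumTest <- function(x, y) {
    if (length(x) < 8L && length(y) < 8L &&
        !anyDuplicated(c(x, y))) {
        return(stats::wilcox.test(x, y, exact = TRUE)$p.value)
    }
    .cpp_ranksum_p(as.numeric(x), as.numeric(y))
}

#' Reshuffling null for the window-pair test count
#'
#' Simulates the null of homogeneous mitogenome coverage: per iteration and
#' species, each NUMT keeps its footprint length and draws a new start
#' uniformly from 1..span; footprints running past the span wrap around by
#' subtracting the span (circular mitogenome). The full window/test pipeline
#' is re-run per iteration and the number of significant window-pair tests
#' recorded.
#'
#' @param numts_list Named list of [NumtSet-class] (or of numeric vectors of
#'   footprint lengths), one per species.
#' @param n_iter Number of reshuffling iterations (>= 1).
#' @param span,window,alpha As in the observed pipeline.
#' @param seed Integer seed; same seed reproduces the null exactly.
#' @return List: `observed_n_significant`, `null_n_significant` (length
#'   `n_iter`), `null_median`, `null_q95`, and `observed_exceeds_null_q95`.
#' @export
reshuffleNull <- function(numts_list, n_iter = 1000, span = 16000,
                          window = 50, alpha = 0.01, seed = NULL) {
    if (n_iter < 1L) stop("n_iter must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    span <- as.integer(span)
    lens <- lapply(numts_list, function(x) {
        if (is(x, "NumtSet"))
            as.integer(sum(IRanges::width(mcols(x@ranges)$mt_intervals)))
        else as.integer(x)
    })
    lens <- lapply(lens, function(l) pmin(l, span))
    obs_profiles <- lapply(numts_list, function(x) {
        if (is(x, "NumtSet")) coverageProfile(x, span = span)
        else stop("observed profiles need NumtSet inputs")
    })
    obs <- pairwiseWindowTests(windowMedians(obs_profiles, window = window),
                               alpha = alpha)$n_significant
    null_n <- integer(n_iter)
    for (it in seq_len(n_iter)) {
        profs <- lapply(lens, function(l) .reshuffledProfile(l, span))
        names(profs) <- names(lens)
        null_n[it] <- pairwiseWindowTests(
            windowMedians(profs, window = window), alpha = alpha)$n_significant
    }
    q95 <- stats::quantile(null_n, 0.95, names = FALSE, type = 1)
    list(observed_n_significant = obs, null_n_significant = null_n,
         null_median = stats::median(null_n), null_q95 = q95,
         observed_exceeds_null_q95 = obs > q95)
}

# Coverage profile of n segments of the given lengths with uniform random
# starts on the circular span; linear difference-array accumulation.
.reshuffledProfile <- function(lens, span) {
    n <- length(lens)
    if (!n) return(integer(span))
    s <- sample.int(span, n, replace = TRUE)
    e <- s + lens - 1L
    over <- e > span
    e1 <- pmin(e, span)
    # wrapped tails occupy bases 1 .. (e - span)
    adds <- c(s, rep(1L, sum(over)))
    subs <- c(e1 + 1L, e[over] - span + 1L)
    delta <- tabulate(adds, nbins = span + 1L) -
             tabulate(subs, nbins = span + 1L)
    cumsum(delta[seq_len(span)])
}

#' Mitogenome regions over-represented by NUMTs
#'
#' Converts a per-base coverage profile to z-scores (mean and SD over the
#' full profile, zeros included) and reports maximal runs of bases whose
#' z-score exceeds `z_cut`.
#'
#' @param profile Integer coverage vector.
#' @param z_cut z-score threshold (strict).
#' @return `data.frame` with 1-based inclusive `start`, `end`, and the
#'   `max_coverage` within each run; zero rows if no base qualifies. A
#'   zero-variance profile yields zero rows with a warning.
#' @export
overrepresentedRegions <- function(profile, z_cut = 3) {
    mu <- mean(profile)
    sd <- stats::sd(profile)
    empty <- data.frame(start = integer(), end = integer(),
                        max_coverage = integer())
    if (is.na(sd) || sd == 0) {
        warning("zero-variance coverage profile; no regions callable")
        return(empty)
    }
    hit <- (profile - mu) / sd > z_cut
    if (!any(hit)) return(empty)
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(
        start = starts[keep], end = ends[keep],
        max_coverage = vapply(keep, function(k)
            max(profile[starts[k]:ends[k]]), numeric(1))
    )
}
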