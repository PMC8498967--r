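## Divergence landscapes: per-superfamily histograms of read-to-consensus
## divergence and a deterministic classifier of amplification-history
## shape and current activity.

#' Closest-consensus divergence per query
#'
#' For each query (read) keeps the hit with the minimum percent
#' divergence — the closest, i.e. least divergent, consensus — taking the
#' superfamily label from that hit. Ties are broken by higher score, then
#' input order. Queries whose only hits are unclassified are emitted with
#' the `"unclassified"` label.
#'
#' @param x a [RepeatHits-class].
#' @return data.frame with `query_id`, `superfamily`, `pct_div`,
#'   `masked_bp` (bp of the winning hit, for bp-weighted landscapes).
#' @export
bestHitDivergence <- function(x) {
    h <- hitTable(x)
    if (nrow(h) == 0L)
        return(data.frame(query_id = character(0), superfamily = character(0),
                          pct_div = numeric(0), masked_bp = integer(0)))
    ord <- order(h$pct_div, -h$score, seq_len(nrow(h)))
    first <- ord[!duplicated(h$query_id[ord])]
    first <- first[order(match(h$query_id[first], unique(h$query_id)))]
    data.frame(query_id = h$query_id[first],
               superfamily = taxonAtLevel(h[first, , drop = FALSE],
                                          "superfamily"),
               pct_div = h$pct_div[first],
               masked_bp = h$q_end[first] - h$q_start[first],
               stringsAsFactors = FALSE)
}

#' Build per-superfamily divergence landscapes
#'
#' Bins best-hit divergences into half-open bins `[k*w, (k+1)*w)` (1%
#' bins by default), one [DivergenceLandscape-class] per superfamily.
#'
#' @param divs data.frame as from [bestHitDivergence()] (columns
#'   `superfamily`, `pct_div`, and `masked_bp` when `weight = "bp"`).
#' @param weight `"reads"` (count each read once) or `"bp"` (sum the
#'   masked bp of each read's best hit).
#' @param binWidth bin width in percent, default 1.
#' @return named list of [DivergenceLandscape-class] objects.
#' @export
buildLandscape <- function(divs, weight = c("reads", "bp"), binWidth = 1) {
    weight <- match.arg(weight)
    if (!is.numeric(binWidth) || binWidth <= 0)
        .stopf("binWidth must be positive")
    if (nrow(divs) == 0L) return(list())
    if (any(divs$pct_div < 0 | divs$pct_div > 100))
        .stopf("pct_div out of [0, 100]")
    out <- lapply(split(divs, divs$superfamily), function(d) {
        idx <- floor(d$pct_div / binWidth)
        nbin <- max(idx) + 1L
        w <- if (weight == "bp") d$masked_bp else rep(1, nrow(d))
        bins <- vapply(seq_len(nbin) - 1L,
                       function(k) sum(w[idx == k]), numeric(1))
        divergenceLandscape(d$superfamily[1L], bins, binWidth, weight)
    })
    out[order(names(out))]
}

.ACTIVE_SHAPES <- c("monotonic_decreasing", "unimodal_right_skewed",
                    "unimodal_right_skewed_recent_spike", "j_shaped_left",
                    "bimodal_recent")

#' Classify amplification-history shape and activity of a landscape
#'
#' Deterministic decision procedure over the divergence histogram:
#' \enumerate{
#'   \item normalize the bins and smooth with a centered moving average
#'     (`smoothWindow` bins, edges reflected);
#'   \item `recent_fraction` = raw mass at divergence `[0, 1)`;
#'   \item modes = local maxima of the smoothed profile exceeding 10\% of
#'     its global maximum (plateaus collapsed);
#'   \item shape rules, in order: *monotonic_decreasing* if no smoothed
#'     bin exceeds its predecessor by more than a factor `1 + monoTol`
#'     and the (first) mode sits in bin 0; with exactly one mode,
#'     *unimodal_inactive* if `recent_fraction <= recentThreshold`, else
#'     *j_shaped_left* if the mode lies in the top decile of occupied
#'     bins with mass concentrated to its left, else
#'     *unimodal_right_skewed* if smoothed mass right of the mode exceeds
#'     the mass left of it (with suffix *_recent_spike* when the raw
#'     first bin is more than twice its smoothed value), else
#'     *unimodal_inactive*; with two or more modes, *bimodal_recent* if
#'     one mode lies within the first two bins, else *other_inactive*;
#'   \item `active` iff `recent_fraction > recentThreshold` and the shape
#'     is one of the active set (monotonic decreasing, unimodal
#'     right-skewed with or without a recent spike, J-shaped, bimodal
#'     with a recent mode).
#' }
#' The procedure is invariant to uniform rescaling of the bin counts.
#'
#' @param x a [DivergenceLandscape-class] with positive total mass.
#' @param smoothWindow moving-average width in bins (default 3).
#' @param recentThreshold minimum fraction of mass below 1\% divergence
#'   for a superfamily to count as currently active (default 0.005,
#'   robust to a handful of spurious low-divergence hits).
#' @param monoTol tolerated relative increase between consecutive
#'   smoothed bins in the monotonicity test (default 0.05).
#' @return data.frame row with `superfamily`, `shape`, `active`,
#'   `recent_fraction`.
#' @export
classifyActivity <- function(x, smoothWindow = 3, recentThreshold = 0.005,
                             monoTol = 0.05) {
    stopifnot(is(x, "DivergenceLandscape"))
    bins <- landscapeBins(x)
    total <- sum(bins)
    if (total <= 0) .stopf("landscape '%s' has zero mass", x@superfamily)
    p <- bins / total
    s <- .smoothReflect(p, smoothWindow)
    nRecent <- max(1L, ceiling(1 / x@binWidth))
    recent <- sum(p[seq_len(min(nRecent, length(p)))])
    modes <- .findModes(s)
    shape <- .shapeRule(p, s, modes, recent, recentThreshold, monoTol)
    data.frame(superfamily = x@superfamily, shape = shape,
               active = recent > recentThreshold && shape %in% .ACTIVE_SHAPES,
               recent_fraction = recent, stringsAsFactors = FALSE)
}

## local maxima of the smoothed profile, plateaus collapsed to their
## first bin, filtered at 10% of the global max
.findModes <- function(s) {
    n <- length(s)
    if (n == 1L) return(1L)
    isMax <- logical(n)
    for (i in seq_len(n)) {
        left <- if (i == 1L) -Inf else s[i - 1L]
        right <- if (i == n) -Inf else s[i + 1L]
        isMax[i] <- s[i] >= left && s[i] >= right
    }
    cand <- which(isMax & s > 0.1 * max(s))
    if (length(cand) == 0L) return(integer(0))
    ## adjacent candidates are plateau members: collapse each run to its
    ## first bin
    cand[c(TRUE, diff(cand) > 1L)]
}

.shapeRule <- function(p, s, modes, recent, recentThreshold, monoTol) {
    n <- length(s)
    monotone <- all(s[-1L] <= s[-n] * (1 + monoTol)) &&
        length(modes) > 0L && modes[1L] == 1L
    if (monotone) return("monotonic_decreasing")
    if (length(modes) == 1L) {
        if (recent <= recentThreshold) return("unimodal_inactive")
        m <- modes[1L]
        occupied <- which(p > 0)
        topDecile <- length(occupied) > 0L &&
            m >= stats::quantile(occupied, 0.9, type = 1L)
        leftMass <- if (m > 1L) sum(s[seq_len(m - 1L)]) else 0
        rightMass <- if (m < n) sum(s[(m + 1L):n]) else 0
        if (topDecile && leftMass > rightMass) return("j_shaped_left")
        if (rightMass > leftMass) {
            spike <- p[1L] > 2 * s[1L]
            return(if (spike) "unimodal_right_skewed_recent_spike"
                   else "unimodal_right_skewed")
        }
        return("unimodal_inactive")
    }
    if (length(modes) >= 2L && any(modes <= 2L)) return("bimodal_recent")
    "other_inactive"
}

#' Activity summary across superfamilies
#'
#' Applies [classifyActivity()] to every landscape whose superfamily
#' reaches a minimum genome fraction (so that shape calls are only made
#' where the histogram has meaningful support), and counts active calls.
#'
#' @param landscapes list of [DivergenceLandscape-class] objects.
#' @param abundance optional [AbundanceTable-class] at superfamily level
#'   used to apply the genome-fraction floor; landscapes for absent
#'   superfamilies are excluded from assessment.
#' @param minGenomeFraction assessment floor as a fraction of the genome
#'   (default 5e-5, i.e. 0.005\%).
#' @param ... passed to [classifyActivity()].
#' @return list with `calls` (one row per assessed superfamily),
#'   `n_assessed`, `n_active`, `excluded` (superfamilies below the floor).
#' @export
activitySummary <- function(landscapes, abundance = NULL,
                            minGenomeFraction = 5e-5, ...) {
    if (length(landscapes) == 0L)
        return(list(calls = data.frame(), n_assessed = 0L, n_active = 0L,
                    excluded = character(0)))
    sf <- vapply(landscapes, function(l) l@superfamily, character(1))
    excluded <- character(0)
    if (!is.null(abundance)) {
        t <- taxonTable(abundance)
        frac <- t$pct_genome[match(sf, t$taxon)] / 100
        frac[is.na(frac)] <- 0
        excluded <- sf[frac < minGenomeFraction]
        landscapes <- landscapes[frac >= minGenomeFraction]
        sf <- sf[frac >= minGenomeFraction]
    }
    calls <- do.call(rbind, lapply(landscapes, classifyActivity, ...))
    if (is.null(calls)) calls <- data.frame()
    list(calls = calls, n_assessed = nrow(calls),
         n_active = if (nrow(calls)) sum(calls$active) else 0L,
         excluded = excluded)
}
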