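## Element architecture and ectopic recombination-mediated deletion.
##
## Ectopic (non-allelic homologous) recombination between the terminal
## repeats of a retroelement deletes the internal sequence and one
## terminal, leaving a solo terminal. The footprint in shotgun data is an
## excess of read depth over terminal sequence relative to internal
## sequence; the length-normalized total terminal-to-internal depth ratio
## (TT:I) is therefore 1:1 in the absence of deletion and rises with the
## solo-terminal fraction.

#' Find terminal repeats by self-comparison of a contig
#'
#' Seed-and-extend comparison of the first `endWindow` bp of a contig
#' against its last `endWindow` bp (against the reverse complement of the
#' tail for `mode = "inverted"`): exact k-mer seeds (k = 11) are extended
#' without gaps under +1 match / -2 mismatch scoring with an X-drop of
#' 20. Pairs reaching `minLen` and `minIdentity` are returned best score
#' first. Windows are clipped to the sequence; pairs whose two footprints
#' overlap on the contig (possible only for short contigs) are dropped.
#'
#' @param seq a nucleotide string or [Biostrings::DNAString].
#' @param mode `"direct"` (LTR-like) or `"inverted"` (TIR/DIRS-like).
#' @param minLen minimum alignment length, bp (default 50).
#' @param minIdentity minimum identity fraction (default 0.8).
#' @param endWindow bp examined at each end (default 1000).
#' @return data.frame with 0-based half-open coordinates of both copies
#'   (`start1`, `end1`, `start2`, `end2`), `length`, `identity`, `score`;
#'   zero rows when no repeat is found.
#' @export
findTerminalRepeats <- function(seq, mode = c("direct", "inverted"),
                                minLen = 50, minIdentity = 0.8,
                                endWindow = 1000) {
    mode <- match.arg(mode)
    seq <- toupper(as.character(seq))
    if (grepl("[^ACGTRYSWKMBDHVN]", seq))
        .stopf("sequence contains non-IUPAC characters")
    n <- nchar(seq)
    w <- min(endWindow, n)
    head <- substr(seq, 1L, w)
    tailStart <- n - w + 1L
    tail <- substr(seq, tailStart, n)
    tailCmp <- if (mode == "inverted")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(tail)))
    else tail
    alns <- .seedExtend(head, tailCmp, k = 11L, xdrop = 20,
                        minLen = minLen, minIdentity = minIdentity)
    if (nrow(alns) == 0L) return(alns)
    ## map window-local coordinates (0-based half-open) to the contig
    alns$start1 <- alns$a_start
    alns$end1 <- alns$a_end
    if (mode == "inverted") {
        ## position i (0-based) in revcomp(tail) is tail position
        ## (w - 1 - i), global (tailStart - 1) + that
        alns$start2 <- (tailStart - 1L) + (w - alns$b_end)
        alns$end2 <- (tailStart - 1L) + (w - alns$b_start)
    } else {
        alns$start2 <- (tailStart - 1L) + alns$b_start
        alns$end2 <- (tailStart - 1L) + alns$b_end
    }
    ## drop self-overlapping pairs and identity/length failures
    keep <- alns$end1 <= alns$start2
    alns <- alns[keep, c("start1", "end1", "start2", "end2",
                         "length", "identity", "score")]
    alns[order(-alns$score), , drop = FALSE]
}

## ungapped seed-and-extend between two strings; coordinates 0-based
## half-open within each string
.seedExtend <- function(a, b, k, xdrop, minLen, minIdentity) {
    empty <- data.frame(a_start = integer(0), a_end = integer(0),
                        b_start = integer(0), b_end = integer(0),
                        length = integer(0), identity = numeric(0),
                        score = numeric(0))
    na <- nchar(a); nb <- nchar(b)
    if (na < k || nb < k) return(empty)
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    bk <- substring(b, seq_len(nb - k + 1L), seq_len(nb - k + 1L) + k - 1L)
    bIndex <- split(seq_len(nb - k + 1L), bk)
    ak <- substring(a, seq_len(na - k + 1L), seq_len(na - k + 1L) + k - 1L)
    seen <- new.env(parent = emptyenv())   # diag -> covered a-intervals
    out <- list()
    for (i in seq_len(na - k + 1L)) {
        js <- bIndex[[ak[i]]]
        if (is.null(js)) next
        for (j in js) {
            diag <- i - j
            key <- as.character(diag)
            covered <- get0(key, envir = seen, ifnotfound = NULL)
            if (!is.null(covered) &&
                any(i >= covered[, 1L] & i <= covered[, 2L])) next
            ext <- .ungappedExtend(av, bv, i, j, k, xdrop)
            assign(key, rbind(covered, c(ext$aFrom, ext$aTo)), envir = seen)
            len <- ext$aTo - ext$aFrom + 1L
            ident <- ext$matches / len
            if (len >= minLen && ident >= minIdentity)
                out[[length(out) + 1L]] <- data.frame(
                    a_start = ext$aFrom - 1L, a_end = ext$aTo,
                    b_start = ext$bFrom - 1L, b_end = ext$bTo,
                    length = len, identity = ident, score = ext$score)
        }
    }
    if (length(out) == 0L) return(empty)
    res <- do.call(rbind, out)
    res[!duplicated(res[, c("a_start", "a_end", "b_start")]), , drop = FALSE]
}

## X-drop ungapped extension of a seed at a[i..i+k-1] ~ b[j..j+k-1]
## (1-based); match +1, mismatch -2
.ungappedExtend <- function(av, bv, i, j, k, xdrop) {
    na <- length(av); nb <- length(bv)
    score <- k; matches <- k
    ## right
    best <- score; aTo <- i + k - 1L; bTo <- j + k - 1L
    p <- aTo; q <- bTo
    while (p < na && q < nb) {
        p <- p + 1L; q <- q + 1L
        score <- score + if (av[p] == bv[q]) 1 else -2
        if (av[p] == bv[q]) matches <- matches + 1L
        if (score > best) { best <- score; aTo <- p; bTo <- q }
        else if (best - score > xdrop) break
    }
    ## trim bookkeeping back to the best right endpoint
    matches <- matches - sum(av[seq2(aTo + 1L, p)] == bv[seq2(bTo + 1L, q)])
    score <- best
    ## left
    aFrom <- i; bFrom <- j
    p <- i; q <- j
    while (p > 1L && q > 1L) {
        p <- p - 1L; q <- q - 1L
        score <- score + if (av[p] == bv[q]) 1 else -2
        if (av[p] == bv[q]) matches <- matches + 1L
        if (score > best) { best <- score; aFrom <- p; bFrom <- q }
        else if (best - score > xdrop) break
    }
    matches <- matches - sum(av[seq2(p, aFrom - 1L)] == bv[seq2(q, bFrom - 1L)])
    list(aFrom = aFrom, aTo = aTo, bFrom = bFrom, bTo = bTo,
         matches = matches, score = best)
}

## like seq(from, to) but empty when from > to
seq2 <- function(from, to) if (from > to) integer(0) else from:to

#' Build an element architecture model
#'
#' The internal interval is conservatively bounded by the first and last
#' recognizable TE protein domains; terminal intervals are clipped to
#' exclude any overlap with the internal interval.
#'
#' @param contigID contig identifier.
#' @param contigLen contig length, bp.
#' @param terminalPairs data.frame as from [findTerminalRepeats()] (its
#'   best row is used) or a list of 0-based half-open intervals.
#' @param domainHits list (or 2-column matrix) of 0-based half-open
#'   protein-domain intervals on the contig.
#' @param mode `"direct"` or `"inverted"`.
#' @param superfamily superfamily label.
#' @return an [ElementModel-class].
#' @export
buildElementModel <- function(contigID, contigLen, terminalPairs, domainHits,
                              mode = c("direct", "inverted"),
                              superfamily = NA_character_) {
    mode <- match.arg(mode)
    if (is.data.frame(terminalPairs)) {
        if (nrow(terminalPairs) == 0L)
            .stopf("no terminal pair supplied for contig '%s'", contigID)
        best <- terminalPairs[1L, ]
        terminals <- list(c(best$start1, best$end1), c(best$start2, best$end2))
    } else {
        if (length(terminalPairs) == 0L)
            .stopf("no terminal pair supplied for contig '%s'", contigID)
        terminals <- terminalPairs
    }
    dm <- .asIntervalMatrix(domainHits)
    if (nrow(dm) == 0L)
        .stopf("no domain hits for contig '%s'", contigID)
    internal <- c(min(dm[, 1L]), max(dm[, 2L]))
    clipped <- lapply(terminals, function(t) {
        if (t[1] >= internal[1] && t[2] <= internal[2]) return(NULL)
        if (t[2] > internal[1] && t[1] < internal[1]) t[2] <- internal[1]
        if (t[1] < internal[2] && t[2] > internal[2]) t[1] <- internal[2]
        if (t[2] <= t[1]) NULL else t
    })
    clipped <- clipped[!vapply(clipped, is.null, logical(1))]
    if (length(clipped) == 0L)
        .stopf("internal interval engulfs all terminals on contig '%s'",
               contigID)
    elementModel(contigID, contigLen, clipped, internal, mode = mode,
                 superfamily = superfamily)
}

.checkAlignments <- function(alignments) {
    need <- c("read_id", "contig_id", "start", "end", "aligned_len")
    missing <- setdiff(need, names(alignments))
    if (length(missing) > 0L)
        .stopf("alignment table missing column(s): %s",
               paste(missing, collapse = ", "))
    if (nrow(alignments) > 0L) {
        if (any(alignments$start >= alignments$end))
            .stopf("alignments must satisfy start < end")
        if (any(alignments$aligned_len !=
                alignments$end - alignments$start))
            .stopf("aligned_len must equal end - start")
    }
    alignments
}

#' Terminal-to-internal depth ratio of one contig
#'
#' Depth over each region is the summed overlap bp of retained alignments
#' with the region divided by the region length, so a read contributes
#' fractionally to regions it partially covers, and a uniform-coverage
#' intact element yields a ratio of 1. All terminal intervals are pooled
#' into one "total terminal" class. Alignments shorter than
#' `minAlignedLen` are discarded first (the stringency knob of the
#' mapper-score sweep, expressed as the observable it manipulates).
#'
#' @param alignments data.frame of read alignments with columns
#'   `read_id`, `contig_id`, `start`, `end` (0-based half-open),
#'   `aligned_len`.
#' @param model an [ElementModel-class].
#' @param minAlignedLen minimum alignment length retained, bp (default
#'   20).
#' @return data.frame row: `contig_id`, `superfamily`, `depth_terminal`,
#'   `depth_internal`, `tti`, `min_aligned_len`, `n_alignments`.
#' @examples
#' m <- elementModel("c", 600L, list(c(0, 100), c(500, 600)), c(100, 500))
#' a <- data.frame(read_id = "r", contig_id = "c", start = 0L, end = 600L,
#'                 aligned_len = 600L)
#' ttiRatio(a, m)  # uniform depth: tti = 1
#' @export
ttiRatio <- function(alignments, model, minAlignedLen = 20) {
    stopifnot(is(model, "ElementModel"))
    alignments <- .checkAlignments(alignments)
    a <- alignments[alignments$contig_id == model@contigID &
                    alignments$aligned_len >= minAlignedLen, , drop = FALSE]
    depth <- function(region) {
        if (nrow(a) == 0L) return(0)
        q <- IRanges::IRanges(start = a$start + 1L, end = a$end)
        ov <- IRanges::findOverlaps(q, region)
        inter <- IRanges::pintersect(q[S4Vectors::queryHits(ov)],
                                     region[S4Vectors::subjectHits(ov)])
        sum(IRanges::width(inter)) / sum(IRanges::width(region))
    }
    dT <- depth(model@terminals)
    dI <- depth(model@internal)
    if (dI == 0)
        .stopf("undefined TT:I on contig '%s': internal depth is zero",
               model@contigID)
    data.frame(contig_id = model@contigID, superfamily = model@superfamily,
               depth_terminal = dT, depth_internal = dI, tti = dT / dI,
               min_aligned_len = minAlignedLen, n_alignments = nrow(a),
               stringsAsFactors = FALSE)
}

#' TT:I stringency sweep across contigs and alignment-length thresholds
#'
#' Recomputes per-contig TT:I ratios at each minimum-alignment-length
#' threshold and averages within superfamilies (unweighted mean over
#' contigs). Contigs whose internal depth drops to zero at a threshold
#' are excluded from that mean and counted.
#'
#' @param alignments alignment data.frame, see [ttiRatio()].
#' @param models list of [ElementModel-class] objects.
#' @param thresholds minimum alignment lengths to sweep, bp (default
#'   `c(20, 30, 40, 50)`).
#' @return list with `summary` (superfamily, threshold, mean_tti,
#'   n_contigs, n_undefined) and `perContig` (all per-contig rows).
#' @export
ttiSweep <- function(alignments, models, thresholds = c(20, 30, 40, 50)) {
    if (length(thresholds) == 0L) .stopf("no thresholds supplied")
    if (length(models) == 0L) .stopf("no element models supplied")
    rows <- list(); undef <- list()
    for (th in thresholds) {
        for (m in models) {
            r <- tryCatch(ttiRatio(alignments, m, minAlignedLen = th),
                          error = function(e) NULL)
            if (is.null(r))
                undef[[length(undef) + 1L]] <- data.frame(
                    superfamily = m@superfamily, threshold = th)
            else rows[[length(rows) + 1L]] <- r
        }
    }
    perContig <- if (length(rows)) do.call(rbind, rows) else data.frame()
    undefDf <- if (length(undef)) do.call(rbind, undef) else
        data.frame(superfamily = character(0), threshold = numeric(0))
    summary <- if (nrow(perContig)) {
        agg <- stats::aggregate(
            list(mean_tti = perContig$tti),
            by = list(superfamily = perContig$superfamily,
                      threshold = perContig$min_aligned_len),
            FUN = mean)
        agg$n_contigs <- stats::aggregate(
            list(n = perContig$tti),
            by = list(superfamily = perContig$superfamily,
                      threshold = perContig$min_aligned_len),
            FUN = length)$n
        agg$n_undefined <- vapply(seq_len(nrow(agg)), function(i)
            sum(undefDf$superfamily == agg$superfamily[i] &
                undefDf$threshold == agg$threshold[i]), numeric(1))
        agg[order(agg$superfamily, agg$threshold), , drop = FALSE]
    } else data.frame()
    list(summary = summary, perContig = perContig)
}

#' Solo-terminal fraction implied by a TT:I ratio
#'
#' Inverts the uniform-sampling expectation for a two-terminal element
#' population: with `s` solo terminals per intact element, pooled
#' terminal depth is proportional to `(2 + s) / 2` of internal depth, so
#' `TT:I = 1 + s/2` and `s = 2 (TT:I - 1)`. Ratios below 1 (excess
#' internal depth) return 0 with a warning.
#'
#' @param tti TT:I ratio(s).
#' @return estimated solo terminals per intact element.
#' @examples
#' soloFractionEstimate(1.5)  # 1 solo per intact element
#' @export
soloFractionEstimate <- function(tti) {
    out <- 2 * (tti - 1)
    if (any(tti < 1)) {
        warning("TT:I below 1 (excess internal depth); returning 0")
        out[tti < 1] <- 0
    }
    out
}
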