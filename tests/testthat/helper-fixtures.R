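## Fixture builders and independent oracles used across test files.
## Everything is generated in code; no binary fixtures.

randomSeq <- function(n, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

substituteBases <- function(s, positions) {
    v <- strsplit(s, "")[[1]]
    for (p in positions) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
}

## minimal hit-table row builder (0-based half-open coordinates)
makeHits <- function(query_id, query_len, q_start, q_end, superfamily,
                     te_order = "LINE", te_class = "I", pct_div = 5,
                     score = 100, strand = "+", overlap_flag = FALSE,
                     consensus_id = "cons") {
    n <- max(length(query_id), length(q_start))
    if (length(query_id) == 0L && length(q_start) == 0L) n <- 0L
    repeatHits(data.frame(
        query_id = rep_len(query_id, n),
        query_len = as.integer(rep_len(query_len, n)),
        q_start = as.integer(rep_len(q_start, n)),
        q_end = as.integer(rep_len(q_end, n)),
        consensus_id = rep_len(consensus_id, n),
        te_class = rep_len(te_class, n),
        te_order = rep_len(te_order, n),
        superfamily = rep_len(superfamily, n),
        nonautonomous_kind = rep_len("none", n),
        pct_div = rep_len(pct_div, n),
        score = rep_len(score, n),
        strand = rep_len(strand, n),
        overlap_flag = rep_len(overlap_flag, n),
        stringsAsFactors = FALSE))
}

## Per-base bitmask oracle for masked_fraction: assigns every base of
## every query to the winning hit (score desc, then input order) and sums
## bp per taxon. Brute force, independent of the package's resolution.
bitmaskOracle <- function(hits, totalBp, level = "superfamily") {
    h <- hitTable(hits)
    taxon <- taxonAtLevel(h, level)
    won <- numeric(nrow(h))
    for (q in unique(h$query_id)) {
        idx <- which(h$query_id == q)
        owner <- integer(h$query_len[idx[1]])
        for (i in idx[order(-h$score[idx], idx)]) {
            for (b in (h$q_start[i] + 1L):h$q_end[i])
                if (owner[b] == 0L) owner[b] <- i
        }
        for (i in idx) won[i] <- sum(owner == i)
    }
    agg <- aggregate(list(masked_bp = won), by = list(taxon = taxon),
                     FUN = sum)
    agg <- agg[agg$masked_bp > 0, , drop = FALSE]
    agg[order(agg$taxon), , drop = FALSE]
}

## Brute-force per-base depth oracle for the TT:I ratio.
depthOracle <- function(alignments, model, minAlignedLen = 20) {
    a <- alignments[alignments$contig_id == model@contigID &
                    alignments$aligned_len >= minAlignedLen, , drop = FALSE]
    depthAt <- function(pos) {
        sum(a$start < pos & a$end >= pos)   # pos is 1-based
    }
    regionDepth <- function(intervals) {
        pos <- unlist(lapply(seq_len(nrow(intervals)), function(i)
            (intervals[i, 1] + 1L):intervals[i, 2]))
        mean(vapply(pos, depthAt, numeric(1)))
    }
    tm <- terminalIntervals(model)
    im <- matrix(internalInterval(model), ncol = 2)
    dT <- regionDepth(tm)
    dI <- regionDepth(im)
    list(depth_terminal = dT, depth_internal = dI, tti = dT / dI)
}

## Affine-gap global alignment score oracle (Gotoh), same scoring as
## pairwiseIdentity: match +1, mismatch -1, gap open -5, gap extend -1
## (opening a gap of length 1 costs 5 + 1).
gotohScore <- function(a, b, match = 1, mismatch = -1,
                       gapOpen = 5, gapExt = 1) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    n <- length(av); m <- length(bv)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
    M[1, 1] <- 0
    for (i in 2:(n + 1)) X[i, 1] <- -gapOpen - gapExt * (i - 1)
    for (j in 2:(m + 1)) Y[1, j] <- -gapOpen - gapExt * (j - 1)
    for (i in 2:(n + 1)) {
        for (j in 2:(m + 1)) {
            s <- if (av[i - 1] == bv[j - 1]) match else mismatch
            M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                           Y[i - 1, j - 1]) + s
            X[i, j] <- max(M[i - 1, j] - gapOpen - gapExt,
                           X[i - 1, j] - gapExt)
            Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExt,
                           Y[i, j - 1] - gapExt)
        }
    }
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## exhaustive shared-kmer oracle: is there any shared k-mer between the
## two end windows of a sequence?
sharedKmer <- function(seq, k, endWindow) {
    n <- nchar(seq)
    w <- min(endWindow, n)
    head <- substr(seq, 1, w)
    tail <- substr(seq, n - w + 1, n)
    km <- function(s) unique(substring(s, 1:(nchar(s) - k + 1),
                                       k:nchar(s)))
    length(intersect(km(head), km(tail))) > 0
}

## abundance table straight from a named percentage vector
abundanceFromPct <- function(pct, totalBp = 1e6, level = "superfamily") {
    new("AbundanceTable",
        table = data.frame(taxon = names(pct),
                           masked_bp = pct / 100 * totalBp,
                           pct_genome = unname(pct)),
        level = level, totalBp = totalBp)
}
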