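## Greedy identity clustering at the family threshold. TE families are
## operationally delimited at 80% sequence identity; the cluster count
## per superfamily is a richness proxy for within-superfamily diversity
## when evenness cannot be measured.

#' Global pairwise identity of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open
#' -5, gap extend -1); identity is matches divided by the alignment
#' columns in which the shorter sequence is aligned (i.e. columns that
#' are not gaps in the shorter sequence), approximating the convention of
#' short-vs-long comparisons in greedy clustering tools. Documented as a
#' dialect choice.
#'
#' @param a,b non-empty nucleotide strings (or `DNAString`s).
#' @return identity fraction in `[0, 1]`.
#' @examples
#' pairwiseIdentity("ACGTACGT", "ACGTACGT")  # 1
#' @export
pairwiseIdentity <- function(a, b) {
    a <- toupper(as.character(a)); b <- toupper(as.character(b))
    if (!nzchar(a) || !nzchar(b)) .stopf("sequences must be non-empty")
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(b),
        type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -1, baseOnly = FALSE),
        gapOpening = 5, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    shorterIsA <- nchar(a) <= nchar(b)
    anchor <- if (shorterIsA) pa else pb
    cols <- anchor != "-"
    if (!any(cols)) return(0)
    sum(pa[cols] == pb[cols] & pa[cols] != "-") / sum(cols)
}

#' Greedy identity clustering of sequences
#'
#' Deterministic longest-first greedy clustering with representative-only
#' comparison: sequences are sorted by decreasing length (ties by id);
#' each sequence joins the first existing cluster whose representative it
#' matches at `>= threshold` identity, otherwise it founds a new cluster.
#' The representative of a cluster is its (longest) founding sequence.
#'
#' @param seqs named character vector, named list of sequences, or a
#'   [Biostrings::DNAStringSet]; names are the (unique) sequence ids.
#' @param threshold identity threshold (default 0.80, the family
#'   definition).
#' @return data.frame with `representative_id`, `member_id`, `identity`
#'   (identity of the member to its representative; 1 for
#'   representatives), `threshold`.
#' @export
greedyCluster <- function(seqs, threshold = 0.80) {
    if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
    seqs <- unlist(as.list(seqs))
    if (length(seqs) == 0L)
        return(data.frame(representative_id = character(0),
                          member_id = character(0), identity = numeric(0),
                          threshold = numeric(0)))
    ids <- names(seqs)
    if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
        .stopf("sequences must carry unique non-empty names")
    ord <- order(-nchar(seqs), ids)
    reps <- integer(0)
    rows <- vector("list", length(seqs))
    for (i in ord) {
        assigned <- FALSE
        for (r in reps) {
            ident <- pairwiseIdentity(seqs[[i]], seqs[[r]])
            if (ident >= threshold) {
                rows[[i]] <- data.frame(representative_id = ids[r],
                                        member_id = ids[i],
                                        identity = ident,
                                        threshold = threshold)
                assigned <- TRUE
                break
            }
        }
        if (!assigned) {
            reps <- c(reps, i)
            rows[[i]] <- data.frame(representative_id = ids[i],
                                    member_id = ids[i], identity = 1,
                                    threshold = threshold)
        }
    }
    out <- do.call(rbind, rows[ord])
    rownames(out) <- NULL
    out
}

#' Number of clusters (family richness proxy)
#'
#' @param clusters data.frame as returned by [greedyCluster()].
#' @return number of distinct clusters.
#' @export
clusterCount <- function(clusters) {
    length(unique(clusters$representative_id))
}
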