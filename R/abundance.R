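## Per-taxon genome-fraction tables from hit records, with deterministic
## per-base resolution of overlapping hits, plus the small summary
## arithmetic of a genome-skimming repeat survey.

#' Genome-fraction table from repeat hits
#'
#' Rolls hit records up to a taxonomic level and reports masked bp and
#' percent of surveyed bp per taxon. Overlapping hits on the same query
#' are resolved per base: the highest-scoring hit wins each base, ties
#' broken by earlier input order, so every surveyed base is counted in at
#' most one row. Mass from labels not reaching the requested level is
#' reported under `"unclassified"`.
#'
#' @param x a [RepeatHits-class].
#' @param totalBp total surveyed bp (sum of read lengths). Supplied by the
#'   caller because the survey unit is the read set, not an assembly.
#' @param level `"class"`, `"order"` or `"superfamily"`.
#' @param weighting `"bp"` (percent of surveyed bp; the default and the
#'   reporting convention of genome-skimming repeat surveys) or
#'   `"records"` (hit counts; `pct_genome` then reports percent of hits).
#' @param dropOverlapFlagged drop hits flagged as overlapped in the source
#'   file before resolution (default FALSE; the parser retains them and
#'   this stage decides).
#' @return an [AbundanceTable-class].
#' @examples
#' h <- repeatHits(data.frame(
#'   query_id = "r1", query_len = 200L, q_start = c(0L, 99L),
#'   q_end = c(150L, 200L), consensus_id = c("G", "L"),
#'   te_class = "I", te_order = c("LTR", "LINE"),
#'   superfamily = c("Gypsy", "L1"), nonautonomous_kind = "none",
#'   pct_div = c(3.2, 10), score = c(500, 300), strand = "+",
#'   overlap_flag = FALSE))
#' maskedFractionTable(h, totalBp = 1000, level = "superfamily")
#' @export
maskedFractionTable <- function(x, totalBp,
                                level = c("superfamily", "order", "class"),
                                weighting = c("bp", "records"),
                                dropOverlapFlagged = FALSE) {
    level <- match.arg(level)
    weighting <- match.arg(weighting)
    .assertSingleNumber(totalBp, "totalBp", positive = TRUE)
    h <- hitTable(x)
    if (dropOverlapFlagged) h <- h[!h$overlap_flag, , drop = FALSE]
    if (nrow(h) == 0L)
        return(new("AbundanceTable",
                   table = data.frame(taxon = character(0),
                                      masked_bp = numeric(0),
                                      pct_genome = numeric(0)),
                   level = level, totalBp = totalBp))
    taxon <- taxonAtLevel(h, level)
    if (weighting == "records") {
        agg <- stats::aggregate(list(masked_bp = rep(1, nrow(h))),
                                by = list(taxon = taxon), FUN = sum)
        denom <- nrow(h)
    } else {
        won <- .resolvePerBase(h)
        agg <- stats::aggregate(list(masked_bp = won),
                                by = list(taxon = taxon), FUN = sum)
        agg <- agg[agg$masked_bp > 0, , drop = FALSE]
        denom <- totalBp
    }
    agg <- agg[order(-agg$masked_bp, agg$taxon), , drop = FALSE]
    rownames(agg) <- NULL
    agg$pct_genome <- 100 * agg$masked_bp / denom
    ## record weighting reports shares of hit records; the stored total is
    ## then the record count, not surveyed bp
    new("AbundanceTable", table = agg, level = level, totalBp = denom)
}

## bp won by each hit after highest-score-wins / earlier-order-ties
## per-base resolution within each query; single-hit queries (the vast
## majority in read data) bypass the per-base mask
.resolvePerBase <- function(h) {
    won <- numeric(nrow(h))
    nPerQuery <- table(h$query_id)
    single <- nPerQuery[h$query_id] == 1L
    won[single] <- h$q_end[single] - h$q_start[single]
    multi <- which(!single)
    if (length(multi) > 0L) {
        pri <- order(-h$score[multi], multi)   # score desc, then file order
        rank <- integer(nrow(h))
        rank[multi[pri]] <- seq_along(multi)
        for (idx in split(multi, h$query_id[multi])) {
            taken <- logical(h$query_len[idx[1L]])
            for (i in idx[order(rank[idx])]) {
                span <- (h$q_start[i] + 1L):h$q_end[i]
                free <- !taken[span]
                won[i] <- sum(free)
                taken[span] <- TRUE
            }
        }
    }
    won
}

#' Genome share of unknown repeats from two masking runs
#'
#' The masked percentage obtained with the full repeat library minus the
#' percentage obtained when unknown (unclassified) repeats are excluded
#' from the library: a rough approximation of the genome share of
#' repetitive sequence not classifiable as known TEs.
#'
#' @param pctWithUnknown percent masked with the full library.
#' @param pctWithoutUnknown percent masked with unknowns excluded.
#' @return the differential, in percent.
#' @examples
#' unknownDifferential(77.62, 68.20)  # 9.42
#' @export
unknownDifferential <- function(pctWithUnknown, pctWithoutUnknown) {
    .assertSingleNumber(pctWithUnknown, "pctWithUnknown")
    .assertSingleNumber(pctWithoutUnknown, "pctWithoutUnknown")
    if (pctWithoutUnknown < 0 || pctWithUnknown > 100 ||
        pctWithoutUnknown > pctWithUnknown)
        .stopf(paste("expected 0 <= pctWithoutUnknown <= pctWithUnknown",
                     "<= 100; are the runs mislabeled?"))
    pctWithUnknown - pctWithoutUnknown
}

#' Sequencing coverage of a shotgun survey
#'
#' @param totalReadBp summed length of retained reads, bp.
#' @param genomeSizeBp haploid genome size, bp.
#' @return fold coverage (dimensionless).
#' @examples
#' coverageEstimate(1635569256, 12.2e9)  # ~0.134x genome skim
#' @export
coverageEstimate <- function(totalReadBp, genomeSizeBp) {
    .assertSingleNumber(totalReadBp, "totalReadBp", positive = TRUE)
    .assertSingleNumber(genomeSizeBp, "genomeSizeBp", positive = TRUE)
    totalReadBp / genomeSizeBp
}

#' Fold ratio between two classes of an abundance table
#'
#' @param x an [AbundanceTable-class] at class level (or any level whose
#'   taxa include the two names).
#' @param numerator,denominator taxon names, e.g. `"ClassI"`, `"ClassII"`.
#' @return ratio of their `pct_genome` values.
#' @export
classRatio <- function(x, numerator = "ClassI", denominator = "ClassII") {
    t <- taxonTable(x)
    iN <- match(numerator, t$taxon)
    iD <- match(denominator, t$taxon)
    if (is.na(iN)) .stopf("taxon '%s' not present", numerator)
    if (is.na(iD) || t$pct_genome[iD] <= 0)
        .stopf("denominator taxon '%s' absent or zero", denominator)
    t$pct_genome[iN] / t$pct_genome[iD]
}
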