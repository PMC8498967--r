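## Transcriptome TE annotation rules, expression summaries and the
## abundance--expression relationship.

#' The 80/80/80 rule for non-autonomous TE hits
#'
#' A transcriptome/genome nucleotide hit supports a non-autonomous TE
#' annotation only when the overlap is longer than 80 bp, more than 80\%
#' identical, and covers more than 80\% of the genomic (library) contig.
#' All three comparisons are strict.
#'
#' @param alnLen alignment length, bp.
#' @param identity identity fraction in `[0, 1]`.
#' @param libraryCoverage fraction of the genomic contig covered, `[0, 1]`.
#' @return logical vector.
#' @examples
#' eightyRuleFilter(100, 0.85, 0.90)  # TRUE
#' eightyRuleFilter(80, 0.95, 0.95)   # FALSE: 80 bp is not > 80 bp
#' @export
eightyRuleFilter <- function(alnLen, identity, libraryCoverage) {
    if (any(identity < 0 | identity > 1) ||
        any(libraryCoverage < 0 | libraryCoverage > 1))
        .stopf("identity and libraryCoverage must lie in [0, 1]")
    alnLen > 80 & identity > 0.80 & libraryCoverage > 0.80
}

.checkTranscripts <- function(records) {
    need <- c("contig_id", "tpm")
    missing <- setdiff(need, names(records))
    if (length(missing) > 0L)
        .stopf("transcript table missing column(s): %s",
               paste(missing, collapse = ", "))
    if (any(records$tpm < 0)) .stopf("tpm must be >= 0")
    for (col in c("protein_te_hits", "nucl_te_hits", "gene_annotations"))
        if (is.null(records[[col]])) records[[col]] <- vector("list",
                                                              nrow(records))
    records
}

#' Categorize transcriptome contigs
#'
#' Drops contigs below the TPM floor, then assigns exactly one category
#' per retained contig in fixed decision order: a contig carrying both a
#' TE-protein hit and a passing (80/80/80) non-autonomous nucleotide hit
#' is a conflicting annotation and is filtered; a TE hit of either kind
#' combined with a gene annotation is a TE/gene co-transcript; otherwise
#' protein TE hits mean autonomous TE, passing nucleotide hits mean
#' non-autonomous TE, gene annotations mean gene, and anything else is
#' unknown.
#'
#' @param records data.frame with columns `contig_id`, `tpm` and
#'   list-columns `protein_te_hits` (each element a data.frame with at
#'   least `superfamily`, `e_value`), `nucl_te_hits` (data.frames with
#'   `aln_len`, `identity`, `library_coverage`), `gene_annotations`
#'   (data.frames with `gene_id`).
#' @param minTpm expression floor; contigs with `tpm < minTpm` are
#'   dropped before categorization (default 0.01).
#' @param overrides optional data.frame (`contig_id`, `category`) of
#'   manual curation decisions applied after rule-based assignment.
#' @return list with `assignments` (contig_id, category), `summary`
#'   (category counts) and `n_dropped` (contigs below the floor).
#' @export
categorizeTranscripts <- function(records, minTpm = 0.01, overrides = NULL) {
    records <- .checkTranscripts(records)
    kept <- records[records$tpm >= minTpm, , drop = FALSE]
    nDropped <- nrow(records) - nrow(kept)
    category <- vapply(seq_len(nrow(kept)), function(i) {
        hasProt <- .nhits(kept$protein_te_hits[[i]]) > 0L
        nucl <- kept$nucl_te_hits[[i]]
        hasNucl <- .nhits(nucl) > 0L &&
            any(eightyRuleFilter(nucl$aln_len, nucl$identity,
                                 nucl$library_coverage))
        hasGene <- .nhits(kept$gene_annotations[[i]]) > 0L
        if (hasProt && hasNucl) "filtered_conflict"
        else if (hasProt && hasGene) "te_gene"
        else if (hasNucl && hasGene) "te_gene"
        else if (hasProt) "autonomous_te"
        else if (hasNucl) "non_autonomous_te"
        else if (hasGene) "gene"
        else "unknown"
    }, character(1))
    assignments <- data.frame(contig_id = kept$contig_id,
                              category = category,
                              stringsAsFactors = FALSE)
    if (!is.null(overrides) && nrow(overrides) > 0L) {
        hit <- match(assignments$contig_id, overrides$contig_id)
        assignments$category[!is.na(hit)] <-
            overrides$category[hit[!is.na(hit)]]
    }
    list(assignments = assignments,
         summary = as.data.frame(table(category = assignments$category),
                                 stringsAsFactors = FALSE),
         n_dropped = nDropped)
}

.nhits <- function(x) {
    if (is.null(x)) return(0L)
    if (is.data.frame(x)) return(nrow(x))
    length(x)
}

#' Summed expression per category and per superfamily
#'
#' TPM values are summed across all contigs assigned to each category,
#' and across all TE contigs annotated to the same superfamily (taken
#' from each contig's best protein hit: lowest e-value, ties by input
#' order). Transcriptome fractions divide by the TPM normalization
#' constant 10^6 by default; `denominator = "observed"` divides by the
#' summed TPM of retained contigs instead.
#'
#' @param assignments data.frame (`contig_id`, `category`) as from
#'   [categorizeTranscripts()].
#' @param records the transcript table passed to
#'   [categorizeTranscripts()].
#' @param denominator `"million"` or `"observed"`.
#' @return list with `byCategory` (category, summed_tpm,
#'   fraction_transcriptome) and `bySuperfamily` (superfamily, summed_tpm,
#'   fraction_transcriptome, n_contigs), superfamily rows restricted to
#'   autonomous/non-autonomous TE contigs.
#' @export
expressionSummary <- function(assignments, records,
                              denominator = c("million", "observed")) {
    denominator <- match.arg(denominator)
    records <- .checkTranscripts(records)
    idx <- match(assignments$contig_id, records$contig_id)
    if (anyNA(idx)) .stopf("assignments reference unknown contigs")
    tpm <- records$tpm[idx]
    denom <- if (denominator == "million") 1e6 else sum(tpm)
    byCat <- stats::aggregate(list(summed_tpm = tpm),
                              by = list(category = assignments$category),
                              FUN = sum)
    byCat$fraction_transcriptome <- byCat$summed_tpm / denom
    teRows <- which(assignments$category %in%
                    c("autonomous_te", "non_autonomous_te"))
    sfRows <- lapply(teRows, function(r) {
        rec <- records[idx[r], ]
        sf <- .bestHitSuperfamily(rec)
        if (is.na(sf)) return(NULL)
        data.frame(superfamily = sf, tpm = rec$tpm)
    })
    sfRows <- do.call(rbind, sfRows)
    bySf <- if (is.null(sfRows) || nrow(sfRows) == 0L)
        data.frame(superfamily = character(0), summed_tpm = numeric(0),
                   fraction_transcriptome = numeric(0),
                   n_contigs = integer(0))
    else {
        agg <- stats::aggregate(list(summed_tpm = sfRows$tpm),
                                by = list(superfamily = sfRows$superfamily),
                                FUN = sum)
        agg$fraction_transcriptome <- agg$summed_tpm / denom
        agg$n_contigs <- as.integer(table(sfRows$superfamily)[agg$superfamily])
        agg[order(-agg$summed_tpm), , drop = FALSE]
    }
    list(byCategory = byCat, bySuperfamily = bySf)
}

## superfamily of the best (lowest e-value, ties by order) protein hit,
## falling back to the first passing nucleotide hit's library superfamily
## when no protein hit exists
.bestHitSuperfamily <- function(rec) {
    prot <- rec$protein_te_hits[[1]]
    if (.nhits(prot) > 0L) {
        best <- which.min(prot$e_value)
        return(prot$superfamily[best])
    }
    nucl <- rec$nucl_te_hits[[1]]
    if (.nhits(nucl) > 0L && "superfamily" %in% names(nucl)) {
        pass <- which(eightyRuleFilter(nucl$aln_len, nucl$identity,
                                       nucl$library_coverage))
        if (length(pass) > 0L) return(nucl$superfamily[pass[1L]])
    }
    NA_character_
}

#' Correlation of genomic abundance with expression across superfamilies
#'
#' Pearson correlation of log-transformed genome percentage against
#' log-transformed summed TPM per superfamily, with a two-sided p-value
#' from the t transform. Superfamilies absent or zero in either table are
#' excluded (and counted); logs are base 10 (r is invariant to the log
#' base).
#'
#' @param abundance an [AbundanceTable-class] at superfamily level.
#' @param exprSums data.frame (`superfamily`, `summed_tpm`), e.g. the
#'   `bySuperfamily` table of [expressionSummary()].
#' @return list with `r`, `p_value`, `n`, and `data` (the paired
#'   log-transformed values used).
#' @export
abundanceExpressionCorrelation <- function(abundance, exprSums) {
    t <- taxonTable(abundance)
    t <- t[t$taxon != "unclassified" & t$pct_genome > 0, , drop = FALSE]
    e <- exprSums[exprSums$summed_tpm > 0, , drop = FALSE]
    common <- intersect(t$taxon, e$superfamily)
    if (length(common) < 3L)
        .stopf("need >= 3 superfamilies with positive values in both tables")
    x <- log10(t$pct_genome[match(common, t$taxon)])
    y <- log10(e$summed_tpm[match(common, e$superfamily)])
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    list(r = unname(ct$estimate), p_value = ct$p.value, n = length(common),
         data = data.frame(superfamily = common, log10_pct_genome = x,
                           log10_summed_tpm = y))
}

#' Geometry of a TE/gene co-transcript
#'
#' For a contig carrying one TE and one gene annotation: the TE is
#' upstream if it ends at or before the gene start, downstream if it
#' starts at or after the gene end, else overlapping; strands are
#' compared directly; the TE is "in frame" when on the same strand and
#' the start offset between gene and TE is divisible by 3 (frame is not
#' applicable for opposite strands or overlaps).
#'
#' @param teCoords numeric `(start, end)` of the TE on the contig,
#'   0-based half-open.
#' @param teStrand `"+"` or `"-"`.
#' @param geneCoords numeric `(start, end)` of the gene.
#' @param geneStrand `"+"` or `"-"`.
#' @return data.frame row with `position` (`upstream`/`downstream`/
#'   `overlapping`), `strand` (`same`/`opposite`), `frame`
#'   (`in`/`out`/`n/a`).
#' @examples
#' teGeneGeometry(c(100, 400), "+", c(500, 900), "+")
#' @export
teGeneGeometry <- function(teCoords, teStrand, geneCoords, geneStrand) {
    if (length(teCoords) < 2L || length(geneCoords) < 2L ||
        anyNA(c(teCoords[1:2], geneCoords[1:2])))
        .stopf("both annotations must carry coordinates")
    position <- if (teCoords[2] <= geneCoords[1]) "upstream"
                else if (teCoords[1] >= geneCoords[2]) "downstream"
                else "overlapping"
    strand <- if (teStrand == geneStrand) "same" else "opposite"
    frame <- if (strand == "same" && position != "overlapping") {
        if ((geneCoords[1] - teCoords[1]) %% 3 == 0) "in" else "out"
    } else "n/a"
    data.frame(position = position, strand = strand, frame = frame,
               stringsAsFactors = FALSE)
}
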