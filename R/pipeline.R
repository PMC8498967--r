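## End-to-end orchestration: run the available stages on a configuration
## of inputs and write a consolidated plain-text report bundle. The
## pipeline has no hidden state: each section equals the output of the
## corresponding stage function on the same inputs.

#' Read element models from a BED-like TSV
#'
#' Expected columns: `contig`, `start`, `end` (0-based half-open),
#' `part` (`"terminal"` or `"internal"`), `superfamily`, `mode`
#' (`"direct"`/`"inverted"`), `contig_len`.
#'
#' @param path TSV path.
#' @return named list of [ElementModel-class] objects.
#' @export
readElementModels <- function(path) {
    df <- .readTsv(path)
    need <- c("contig", "start", "end", "part", "superfamily", "mode",
              "contig_len")
    missing <- setdiff(need, names(df))
    if (length(missing) > 0L)
        .stopf("element model table missing column(s): %s",
               paste(missing, collapse = ", "))
    out <- lapply(split(df, df$contig), function(d) {
        term <- d[d$part == "terminal", , drop = FALSE]
        int <- d[d$part == "internal", , drop = FALSE]
        if (nrow(int) != 1L)
            .stopf("contig '%s' needs exactly one internal interval",
                   d$contig[1])
        elementModel(d$contig[1], d$contig_len[1],
                     terminals = lapply(seq_len(nrow(term)), function(i)
                         c(term$start[i], term$end[i])),
                     internal = c(int$start[1], int$end[1]),
                     mode = d$mode[1], superfamily = d$superfamily[1])
    })
    out
}

#' Write element models to a BED-like TSV
#'
#' @param models list of [ElementModel-class] objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeElementModels <- function(models, path) {
    rows <- lapply(models, function(m) {
        tm <- terminalIntervals(m)
        im <- internalInterval(m)
        data.frame(
            contig = m@contigID,
            start = c(tm[, "start"], im[["start"]]),
            end = c(tm[, "end"], im[["end"]]),
            part = c(rep("terminal", nrow(tm)), "internal"),
            superfamily = m@superfamily, mode = m@mode,
            contig_len = m@contigLen, stringsAsFactors = FALSE)
    })
    .writeTsv(do.call(rbind, rows), path)
}

#' Run the end-to-end TE landscape characterization
#'
#' Executes whichever stages the configuration provides inputs for —
#' abundance, diversity, divergence landscapes with activity calls, the
#' TT:I sweep, abundance--expression correlation, family clustering —
#' writing one TSV per stage plus a consolidated `summary.txt` embedding
#' the configuration for provenance. Stages with absent inputs are
#' skipped with a notice.
#'
#' @param config a list with any of: `hits` (path to a hit table or a
#'   [RepeatHits-class]), `hits_dialect` (`"out"`/`"tsv"`), `total_bp`
#'   (required with `hits`), `level` (default `"superfamily"`),
#'   `include_unclassified`, `min_genome_fraction`, `models` (path to an
#'   element-model TSV or a list of models), `alignments` (path or
#'   data.frame), `tti_thresholds`, `transcripts` (transcript table for
#'   [categorizeTranscripts()]) with `min_tpm` and `overrides`,
#'   `expr_sums` (path or data.frame with
#'   `superfamily`, `summed_tpm`), `cluster_fasta` (path),
#'   `cluster_threshold`, `seed`.
#' @param outDir output directory, created if needed; `NULL` suppresses
#'   file output.
#' @return list of stage results (`abundance`, `diversity`, `landscape`,
#'   `activity`, `tti`, `expression_correlation`, `clusters`), with
#'   `config` attached.
#' @export
runCharacterization <- function(config, outDir = NULL) {
    if (!is.list(config)) .stopf("config must be a list")
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    note <- function(...) message("[pipeline] ", sprintf(...))
    report <- list(config = config)

    hits <- config$hits
    if (!is.null(hits)) {
        if (is.character(hits))
            hits <- readRepeatMaskerOut(hits,
                dialect = if (is.null(config$hits_dialect)) "out"
                          else config$hits_dialect)
        if (is.null(config$total_bp))
            .stopf("abundance requested (hits given) but total_bp missing")
        level <- if (is.null(config$level)) "superfamily" else config$level
        ab <- maskedFractionTable(hits, totalBp = config$total_bp,
                                  level = level)
        report$abundance <- ab
        comm <- communityProportions(ab,
            includeUnclassified = isTRUE(config$include_unclassified))
        report$diversity <- diversitySummary(comm)
        divs <- bestHitDivergence(hits)
        lands <- buildLandscape(divs)
        report$landscape <- lands
        mgf <- if (is.null(config$min_genome_fraction)) 5e-5
               else config$min_genome_fraction
        report$activity <- activitySummary(lands, ab,
                                           minGenomeFraction = mgf)
        if (!is.null(outDir)) {
            .writeTsv(taxonTable(ab), file.path(outDir, "abundance.tsv"))
            .writeTsv(report$diversity, file.path(outDir, "diversity.tsv"))
            .writeTsv(do.call(rbind, lapply(lands, function(l)
                data.frame(superfamily = l@superfamily,
                           bin_start = (seq_along(l@bins) - 1L) * l@binWidth,
                           mass = l@bins))),
                file.path(outDir, "landscape.tsv"))
            .writeTsv(report$activity$calls,
                      file.path(outDir, "activity.tsv"))
        }
    } else note("no hits supplied; skipping abundance/diversity/landscape")

    models <- config$models
    if (!is.null(models) && !is.null(config$alignments)) {
        if (is.character(models)) models <- readElementModels(models)
        aln <- config$alignments
        if (is.character(aln)) aln <- .readTsv(aln)
        th <- if (is.null(config$tti_thresholds)) c(20, 30, 40, 50)
              else config$tti_thresholds
        report$tti <- ttiSweep(aln, models, thresholds = th)
        if (!is.null(outDir))
            .writeTsv(report$tti$summary, file.path(outDir, "tti.tsv"))
    } else note("no element models/alignments; skipping TT:I stage")

    if (!is.null(config$transcripts)) {
        minTpm <- if (is.null(config$min_tpm)) 0.01 else config$min_tpm
        cat0 <- categorizeTranscripts(config$transcripts, minTpm = minTpm,
                                      overrides = config$overrides)
        report$expression <- list(
            categories = cat0,
            summary = expressionSummary(cat0$assignments,
                                        config$transcripts))
        if (!is.null(outDir)) {
            .writeTsv(report$expression$summary$byCategory,
                      file.path(outDir, "expression_categories.tsv"))
            .writeTsv(report$expression$summary$bySuperfamily,
                      file.path(outDir, "expression_superfamilies.tsv"))
        }
    }

    exprSums <- config$expr_sums
    if (!is.null(exprSums) && !is.null(report$abundance)) {
        if (is.character(exprSums)) exprSums <- .readTsv(exprSums)
        report$expression_correlation <-
            abundanceExpressionCorrelation(report$abundance, exprSums)
        if (!is.null(outDir))
            .writeTsv(report$expression_correlation$data,
                      file.path(outDir, "expression_correlation.tsv"))
    } else note("no expression sums (or no abundance); skipping correlation")

    if (!is.null(config$cluster_fasta)) {
        seqs <- readRepeatLibrary(config$cluster_fasta)
        thr <- if (is.null(config$cluster_threshold)) 0.80
               else config$cluster_threshold
        report$clusters <- greedyCluster(seqs, threshold = thr)
        if (!is.null(outDir))
            .writeTsv(report$clusters, file.path(outDir, "clusters.tsv"))
    }

    if (!is.null(outDir)) {
        summaryLines <- c(
            "TE landscape characterization report",
            sprintf("seed: %s", if (is.null(config$seed)) "none"
                    else config$seed),
            sprintf("stages run: %s",
                    paste(setdiff(names(report), "config"),
                          collapse = ", ")),
            "", "config:",
            utils::capture.output(utils::str(
                config[!vapply(config, is.object, logical(1))])))
        writeLines(summaryLines, file.path(outDir, "summary.txt"))
    }
    report
}
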