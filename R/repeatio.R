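## Reading and writing the tabular / sequence formats consumed by the
## pipeline: RepeatMasker-style .out hit tables (and an equivalent named
## TSV dialect) and classified repeat-library FASTA.

#' Read a RepeatMasker-style hit table
#'
#' Parses the `.out` dialect (3 header lines followed by
#' whitespace-delimited hit rows) or the package's equivalent named-header
#' TSV into a [RepeatHits-class] container. The `.out` strand token `"C"`
#' maps to `"-"`; a trailing `"*"` marks a hit overlapped by a
#' higher-scoring hit (`overlap_flag = TRUE`). Such hits are retained:
#' exclusion is downstream policy, not a parsing decision. File
#' coordinates are 1-based inclusive and converted to 0-based half-open.
#'
#' @param path path to the file (or a character vector of lines via
#'   `text`).
#' @param dialect `"out"` or `"tsv"`.
#' @param text optional character vector of raw lines, used instead of
#'   `path`.
#' @param map classification dialect table, see [classificationMap()].
#' @return a [RepeatHits-class].
#' @examples
#' lines <- c("   SW  perc perc perc  query     position in query",
#'            "score  div. del. ins.  sequence  begin end (left)",
#'            "",
#'            "500 3.2 0.0 0.0 read1 1 150 (100) + Gypsy-7 LTR/Gypsy 1 150 (0) 1")
#' readRepeatMaskerOut(text = lines)
#' @export
readRepeatMaskerOut <- function(path, dialect = c("out", "tsv"),
                                text = NULL, map = classificationMap()) {
    dialect <- match.arg(dialect)
    if (dialect == "tsv") {
        df <- if (is.null(text)) .readTsv(path)
              else utils::read.delim(text = text, comment.char = "#",
                                     stringsAsFactors = FALSE)
        return(.hitsFromTsv(df, map))
    }
    lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
    if (length(lines) > 0L)
        lines <- lines[-seq_len(min(3L, length(lines)))]  # header block
    keep <- nzchar(trimws(lines))
    lineNo <- which(keep) + 3L
    lines <- lines[keep]
    rows <- lapply(seq_along(lines), function(i)
        .parseOutRow(lines[i], lineNo[i]))
    .hitsFromParsedRows(rows, map)
}

.parseOutRow <- function(line, lineNo) {
    tok <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(tok) < 14L || length(tok) > 16L)
        .stopf("malformed .out row at line %d: expected 14-16 fields, got %d",
               lineNo, length(tok))
    num <- function(x, what) {
        v <- suppressWarnings(as.numeric(gsub("[()]", "", x)))
        if (is.na(v))
            .stopf("malformed .out row at line %d: non-numeric %s '%s'",
                   lineNo, what, x)
        v
    }
    score <- num(tok[1], "score")
    div <- num(tok[2], "divergence")
    qbegin <- num(tok[6], "query begin")
    qend <- num(tok[7], "query end")
    qleft <- num(tok[8], "query left")
    if (qbegin < 1 || qend < qbegin)
        .stopf("malformed .out row at line %d: coordinates %d-%d",
               lineNo, qbegin, qend)
    strandTok <- tok[9]
    if (!strandTok %in% c("+", "C", "-"))
        .stopf("malformed .out row at line %d: strand token '%s'",
               lineNo, strandTok)
    repname <- tok[10]
    classfam <- if (length(tok) >= 11L) tok[11] else "Unknown"
    overlap <- identical(tok[length(tok)], "*")
    if (grepl("#", repname, fixed = TRUE)) {
        parts <- strsplit(repname, "#", fixed = TRUE)[[1]]
        repname <- parts[1]
        classfam <- parts[2]
    }
    list(query_id = tok[5], query_len = as.integer(qend + qleft),
         q_start = as.integer(qbegin), q_end = as.integer(qend),
         consensus_id = repname, label = classfam, pct_div = div,
         score = score,
         strand = if (strandTok == "+") "+" else "-",
         overlap_flag = overlap)
}

.hitsFromParsedRows <- function(rows, map) {
    if (length(rows) == 0L) {
        h <- data.frame(query_id = character(0), query_len = integer(0),
                        q_start = integer(0), q_end = integer(0),
                        consensus_id = character(0), te_class = character(0),
                        te_order = character(0), superfamily = character(0),
                        nonautonomous_kind = character(0),
                        pct_div = numeric(0), score = numeric(0),
                        strand = character(0), overlap_flag = logical(0))
        return(repeatHits(h))
    }
    df <- do.call(rbind, lapply(rows, function(r)
        data.frame(r, stringsAsFactors = FALSE)))
    cls <- parseClassification(df$label, map)
    h <- data.frame(query_id = df$query_id, query_len = df$query_len,
                    q_start = df$q_start - 1L,      # to 0-based half-open
                    q_end = df$q_end,
                    consensus_id = df$consensus_id, cls,
                    pct_div = df$pct_div, score = df$score,
                    strand = df$strand, overlap_flag = df$overlap_flag,
                    stringsAsFactors = FALSE)
    repeatHits(h)
}

.hitsFromTsv <- function(df, map) {
    need <- c("query_id", "query_len", "q_start", "q_end", "consensus_id",
              "classification", "pct_div", "score", "strand", "overlap_flag")
    missing <- setdiff(need, names(df))
    if (length(missing) > 0L)
        .stopf("TSV hit table missing column(s): %s",
               paste(missing, collapse = ", "))
    cls <- parseClassification(df$classification, map)
    h <- data.frame(query_id = as.character(df$query_id),
                    query_len = as.integer(df$query_len),
                    q_start = as.integer(df$q_start) - 1L,
                    q_end = as.integer(df$q_end),
                    consensus_id = as.character(df$consensus_id), cls,
                    pct_div = as.numeric(df$pct_div),
                    score = as.numeric(df$score),
                    strand = as.character(df$strand),
                    overlap_flag = as.logical(df$overlap_flag),
                    stringsAsFactors = FALSE)
    repeatHits(h)
}

#' Write a RepeatHits container back to file
#'
#' Inverse of [readRepeatMaskerOut()]; all parsed fields round-trip.
#' Coordinates are converted back to the 1-based inclusive file
#' convention. Fields of the `.out` format not modeled here (deletion /
#' insertion percentages, consensus coordinates) are written as zeros /
#' full-length placeholders.
#'
#' @param x a [RepeatHits-class].
#' @param path output path; with `path = NULL` the lines are returned
#'   invisibly instead of written.
#' @param dialect `"out"` or `"tsv"`.
#' @return the path (or lines, for `path = NULL`), invisibly.
#' @export
writeRepeatMaskerOut <- function(x, path, dialect = c("out", "tsv")) {
    dialect <- match.arg(dialect)
    h <- hitTable(x)
    if (dialect == "tsv") {
        cls <- h[, c("te_class", "te_order", "superfamily",
                     "nonautonomous_kind")]
        out <- data.frame(query_id = h$query_id, query_len = h$query_len,
                          q_start = h$q_start + 1L, q_end = h$q_end,
                          consensus_id = h$consensus_id,
                          classification = classificationString(cls),
                          pct_div = h$pct_div, score = h$score,
                          strand = h$strand, overlap_flag = h$overlap_flag)
        if (is.null(path)) return(invisible(out))
        return(.writeTsv(out, path))
    }
    header <- c(
        "   SW   perc perc perc  query      position in query     matching  repeat               position in repeat",
        "score   div. del. ins.  sequence   begin end      (left) repeat    class/family      begin  end    (left)  ID",
        "")
    cls <- h[, c("te_class", "te_order", "superfamily", "nonautonomous_kind")]
    classfam <- .maskerClassFam(cls)
    rows <- vapply(seq_len(nrow(h)), function(i) {
        width <- h$q_end[i] - h$q_start[i]
        paste(format(h$score[i], trim = TRUE, digits = 15),
              format(h$pct_div[i], trim = TRUE, digits = 15), "0.0", "0.0",
              h$query_id[i], h$q_start[i] + 1L, h$q_end[i],
              sprintf("(%d)", h$query_len[i] - h$q_end[i]),
              if (h$strand[i] == "+") "+" else "C",
              h$consensus_id[i], classfam[i],
              1L, width, "(0)", i,
              if (h$overlap_flag[i]) "*" else "",
              sep = " ")
    }, character(1))
    lines <- c(header, trimws(rows, which = "right"))
    if (is.null(path)) return(invisible(lines))
    writeLines(lines, path)
    invisible(path)
}

## RepeatMasker-style class/family strings ("LTR/Gypsy", "Unknown")
.maskerClassFam <- function(cls) {
    vapply(seq_len(nrow(cls)), function(i) {
        r <- cls[i, ]
        if (r$te_class == "unclassified") return("Unknown")
        if (r$nonautonomous_kind %in% c("TRIM", "LARD", "MITE") &&
            r$superfamily == "none")
            return(r$nonautonomous_kind)
        if (r$te_order == "none") return(paste0("Class", r$te_class))
        if (r$superfamily == "none") return(r$te_order)
        paste(r$te_order, r$superfamily, sep = "/")
    }, character(1))
}

#' Read a classified repeat library FASTA
#'
#' Sequence names of the form `name#classification` (the RepeatMasker
#' library convention, e.g. `DIRS-3#DIRS/DIRS`) are split into identifier
#' and classification; names without a `#` are treated as unclassified.
#'
#' @param path FASTA path.
#' @param map classification dialect table.
#' @return a [Biostrings::DNAStringSet] whose `mcols()` carry the parsed
#'   classification columns; names are the bare identifiers.
#' @export
readRepeatLibrary <- function(path, map = classificationMap()) {
    seqs <- Biostrings::readDNAStringSet(path)
    full <- sub("[ \t].*$", "", names(seqs))
    hasTag <- grepl("#", full, fixed = TRUE)
    id <- ifelse(hasTag, sub("#.*$", "", full), full)
    label <- ifelse(hasTag, sub("^[^#]*#", "", full), "Unknown")
    cls <- parseClassification(label, map)
    names(seqs) <- id
    S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(cls)
    seqs
}

#' Write a classified repeat library FASTA
#'
#' @param seqs a [Biostrings::DNAStringSet] with classification columns in
#'   `mcols()` (as produced by [readRepeatLibrary()]).
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
writeRepeatLibrary <- function(seqs, path) {
    cls <- as.data.frame(S4Vectors::mcols(seqs))
    out <- seqs
    names(out) <- paste(names(seqs), classificationString(cls), sep = "#")
    Biostrings::writeXStringSet(out, path)
    invisible(path)
}
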