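## Internal helpers shared across modules.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assertSingleNumber <- function(x, name, positive = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        .stopf("'%s' must be a single finite number", name)
    if (positive && x <= 0)
        .stopf("'%s' must be > 0", name)
    invisible(x)
}

## Centered moving average of odd width with reflected edges, so that a
## histogram mode sitting in the first or last bin is not washed out by
## implicit zero padding.
.smoothReflect <- function(x, window) {
    if (window <= 1L) return(x)
    if (window %% 2L == 0L) window <- window + 1L
    half <- (window - 1L) %/% 2L
    n <- length(x)
    if (n == 1L) return(x)
    pad <- c(x[(half + 1L):2L][seq_len(min(half, n - 1L))], x,
             x[(n - 1L):max(1L, n - half)][seq_len(min(half, n - 1L))])
    ## reflection shorter than half (tiny vectors): fall back to clamping
    while (length(pad) < n + 2L * half)
        pad <- c(pad[1L], pad, pad[length(pad)])
    vapply(seq_len(n), function(i) mean(pad[i:(i + 2L * half)]), numeric(1))
}

#' Percentage share of a count within a total
#'
#' Small summary arithmetic used throughout reporting: `100 * part / whole`.
#' Used, e.g., to express how many repeat contigs a single mining tool
#' contributed, or the fraction of contigs classifiable as known TEs.
#'
#' @param part numeric, the subset count (or bp).
#' @param whole numeric, the total count (or bp), must be > 0.
#' @return `100 * part / whole`.
#' @examples
#' percentShare(50471, 59825)  # fraction of repeat contigs that are known TEs
#' @export
percentShare <- function(part, whole) {
    .assertSingleNumber(part, "part")
    .assertSingleNumber(whole, "whole", positive = TRUE)
    if (part < 0) .stopf("'part' must be >= 0")
    100 * part / whole
}

## Read/write helpers for the package's TSV dialect: UTF-8, tab-delimited,
## '#'-prefixed comment lines permitted.
.readTsv <- function(path) {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
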