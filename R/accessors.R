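#' Construct a RepeatHits container
#'
#' @param hits data.frame with the columns documented in
#'   [RepeatHits-class]; coordinates 0-based half-open.
#' @return a [RepeatHits-class] object.
#' @export
repeatHits <- function(hits) {
    rownames(hits) <- NULL
    new("RepeatHits", hits = hits)
}

#' @describeIn repeatHits extract the hit table (data.frame, 0-based
#'   half-open coordinates).
#' @param x a `RepeatHits` object.
#' @export
hitTable <- function(x) {
    stopifnot(is(x, "RepeatHits"))
    x@hits
}

setMethod("length", "RepeatHits", function(x) nrow(x@hits))

#' @export
setMethod("[", "RepeatHits", function(x, i, j, ..., drop = FALSE) {
    repeatHits(x@hits[i, , drop = FALSE])
})

#' Construct a TECommunity
#'
#' @param taxa character vector of taxon names.
#' @param p positive proportions (any positive weights; normalized to sum
#'   to 1).
#' @param level taxonomic level label.
#' @return a [TECommunity-class].
#' @examples
#' teCommunity(c("DIRS", "Jockey"), c(30.20, 20.59))
#' @export
teCommunity <- function(taxa, p, level = "superfamily") {
    p <- as.numeric(p)
    if (any(p < 0)) .stopf("proportions must be non-negative")
    keep <- p > 0
    taxa <- as.character(taxa)[keep]
    p <- p[keep]
    if (length(p) == 0L) .stopf("community has no positive mass")
    new("TECommunity", level = level, taxa = taxa, p = p / sum(p))
}

#' @describeIn teCommunity proportions, named by taxon.
#' @param x a `TECommunity`.
#' @export
taxonProportions <- function(x) {
    stopifnot(is(x, "TECommunity"))
    stats::setNames(x@p, x@taxa)
}

#' @describeIn teCommunity number of taxa.
#' @export
richness <- function(x) {
    stopifnot(is(x, "TECommunity"))
    length(x@p)
}

#' @describeIn abundanceAccessors the per-taxon table.
#' @export
taxonTable <- function(x) {
    stopifnot(is(x, "AbundanceTable"))
    x@table
}

#' Accessors for AbundanceTable
#'
#' @param x an [AbundanceTable-class].
#' @return `taxonTable()`: data.frame (taxon, masked_bp, pct_genome);
#'   `totalBp()`: surveyed bp; `abundanceLevel()`: taxonomic level.
#' @name abundanceAccessors
#' @export
totalBp <- function(x) {
    stopifnot(is(x, "AbundanceTable"))
    x@totalBp
}

#' @describeIn abundanceAccessors the taxonomic level.
#' @export
abundanceLevel <- function(x) {
    stopifnot(is(x, "AbundanceTable"))
    x@level
}

#' Construct a DivergenceLandscape
#'
#' @param superfamily superfamily label.
#' @param bins non-negative per-bin mass; first bin covers `[0, binWidth)`.
#' @param binWidth bin width in percent divergence.
#' @param weight `"reads"` or `"bp"`.
#' @return a [DivergenceLandscape-class].
#' @export
divergenceLandscape <- function(superfamily, bins, binWidth = 1,
                                weight = "reads") {
    new("DivergenceLandscape", superfamily = superfamily,
        bins = as.numeric(bins), binWidth = binWidth, weight = weight)
}

#' @describeIn divergenceLandscape bin masses (first bin = `[0, binWidth)`).
#' @param x a `DivergenceLandscape`.
#' @export
landscapeBins <- function(x) {
    stopifnot(is(x, "DivergenceLandscape"))
    x@bins
}

#' Construct an ElementModel from 0-based half-open intervals
#'
#' @param contigID contig identifier.
#' @param contigLen contig length in bp.
#' @param terminals list (or 2-column matrix) of 0-based half-open
#'   `(start, end)` terminal intervals.
#' @param internal 0-based half-open `(start, end)` internal interval.
#' @param mode `"direct"` or `"inverted"`.
#' @param superfamily superfamily label.
#' @return an [ElementModel-class].
#' @seealso [buildElementModel()] which derives the internal interval from
#'   protein-domain hits and clips overlapping terminals.
#' @export
elementModel <- function(contigID, contigLen, terminals, internal,
                         mode = "direct", superfamily = NA_character_) {
    tm <- .asIntervalMatrix(terminals)
    im <- .asIntervalMatrix(list(internal))
    new("ElementModel", contigID = as.character(contigID),
        contigLen = as.integer(contigLen), mode = mode,
        terminals = IRanges::IRanges(start = tm[, 1L] + 1L, end = tm[, 2L]),
        internal = IRanges::IRanges(start = im[, 1L] + 1L, end = im[, 2L]),
        superfamily = as.character(superfamily))
}

.asIntervalMatrix <- function(x) {
    if (is.matrix(x)) m <- x
    else m <- do.call(rbind, lapply(x, function(iv) as.integer(iv[1:2])))
    if (any(m[, 2L] <= m[, 1L]))
        .stopf("intervals must satisfy start < end (0-based half-open)")
    m
}

#' @describeIn elementModel terminal intervals as a 0-based half-open
#'   2-column matrix.
#' @param x an `ElementModel`.
#' @export
terminalIntervals <- function(x) {
    stopifnot(is(x, "ElementModel"))
    cbind(start = start(x@terminals) - 1L, end = end(x@terminals))
}

#' @describeIn elementModel internal interval, 0-based half-open.
#' @export
internalInterval <- function(x) {
    stopifnot(is(x, "ElementModel"))
    c(start = start(x@internal) - 1L, end = end(x@internal))
}
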