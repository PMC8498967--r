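#' @import methods
#' @importFrom S4Vectors isSingleString isSingleNumber
NULL

## Column layout shared by the hit-table container and its parser/writer.
.REPEAT_HIT_COLS <- c(
    "query_id", "query_len", "q_start", "q_end", "consensus_id",
    "te_class", "te_order", "superfamily", "nonautonomous_kind",
    "pct_div", "score", "strand", "overlap_flag"
)

#' RepeatHits: a table of per-hit repeat annotations
#'
#' One row per masked hit of a repeat-library consensus on a query sequence
#' (typically an unassembled shotgun read), the atom of all abundance and
#' divergence-landscape computations. Coordinates are stored 0-based
#' half-open internally; file readers/writers convert from/to the 1-based
#' inclusive convention of RepeatMasker `.out` tables.
#'
#' @slot hits data.frame with columns `query_id`, `query_len`, `q_start`,
#'   `q_end` (0-based half-open), `consensus_id`, `te_class` (`"I"`, `"II"`
#'   or `"unclassified"`), `te_order`, `superfamily`, `nonautonomous_kind`
#'   (`"TRIM"`, `"LARD"`, `"MITE"`, `"SINE"` or `"none"`), `pct_div`
#'   (percent divergence from the consensus, 0-100), `score`, `strand`
#'   (`"+"`/`"-"`) and `overlap_flag` (TRUE for lower-scoring hits flagged
#'   as overlapped in the source file).
#'
#' @seealso [readRepeatMaskerOut()], [maskedFractionTable()],
#'   [bestHitDivergence()]
#' @export
setClass("RepeatHits", representation(hits = "data.frame"))

setValidity("RepeatHits", function(object) {
    h <- object@hits
    missing <- setdiff(.REPEAT_HIT_COLS, names(h))
    if (length(missing) > 0L)
        return(paste("missing hit columns:", paste(missing, collapse = ", ")))
    if (nrow(h) == 0L)
        return(TRUE)
    if (any(h$q_start < 0L) || any(h$q_end <= h$q_start))
        return("coordinates must satisfy 0 <= q_start < q_end")
    if (any(h$q_end > h$query_len))
        return("q_end exceeds query_len")
    if (any(h$pct_div < 0) || any(h$pct_div > 100))
        return("pct_div must lie in [0, 100]")
    if (!all(h$strand %in% c("+", "-")))
        return("strand must be '+' or '-'")
    if (!all(h$te_class %in% c("I", "II", "unclassified")))
        return("te_class must be 'I', 'II' or 'unclassified'")
    TRUE
})

#' AbundanceTable: per-taxon genome-fraction summary
#'
#' Masked base pairs and percent of surveyed bp per TE taxon at one
#' taxonomic level, after per-base overlap resolution. Every surveyed base
#' is counted in at most one row, so `sum(maskedBp) <= totalBp`.
#'
#' @slot table data.frame with columns `taxon`, `masked_bp`, `pct_genome`.
#' @slot level one of `"class"`, `"order"`, `"superfamily"`.
#' @slot totalBp total surveyed bp (denominator of `pct_genome`).
#'
#' @seealso [maskedFractionTable()], [communityProportions()]
#' @export
setClass("AbundanceTable",
    representation(table = "data.frame", level = "character",
                   totalBp = "numeric"))

setValidity("AbundanceTable", function(object) {
    t <- object@table
    if (!all(c("taxon", "masked_bp", "pct_genome") %in% names(t)))
        return("table needs columns taxon, masked_bp, pct_genome")
    if (!isSingleNumber(object@totalBp) || object@totalBp <= 0)
        return("totalBp must be a single positive number")
    if (!object@level %in% c("class", "order", "superfamily"))
        return("level must be class, order or superfamily")
    if (nrow(t) > 0L) {
        if (sum(t$masked_bp) > object@totalBp + 1e-6)
            return("sum of masked_bp exceeds totalBp")
        if (max(abs(t$pct_genome - 100 * t$masked_bp / object@totalBp)) > 1e-6)
            return("pct_genome inconsistent with masked_bp / totalBp")
        if (anyDuplicated(t$taxon))
            return("duplicate taxa")
    }
    TRUE
})

#' TECommunity: a normalized TE-taxon proportion vector
#'
#' Proportions of a genome's TE complement belonging to each taxon at one
#' taxonomic level; the input of the diversity indices. Proportions are
#' strictly positive and sum to 1.
#'
#' @slot level taxonomic level the proportions refer to.
#' @slot taxa character vector of unique taxon names.
#' @slot p numeric proportions, parallel to `taxa`.
#'
#' @seealso [communityProportions()], [shannonIndex()], [giniSimpsonIndex()]
#' @export
setClass("TECommunity",
    representation(level = "character", taxa = "character", p = "numeric"))

setValidity("TECommunity", function(object) {
    if (length(object@taxa) != length(object@p))
        return("taxa and p differ in length")
    if (length(object@p) == 0L)
        return("community must contain at least one taxon")
    if (anyDuplicated(object@taxa))
        return("taxa must be unique")
    if (any(object@p <= 0))
        return("all proportions must be > 0")
    if (abs(sum(object@p) - 1) > 1e-9)
        return("proportions must sum to 1 (within 1e-9)")
    TRUE
})

#' DivergenceLandscape: binned read-to-consensus divergence histogram
#'
#' Histogram of percent divergence between reads and their closest
#' (least-divergent) consensus, for one superfamily, with half-open bins
#' `[k*w, (k+1)*w)` starting at 0. Mass may be read counts or masked bp.
#'
#' @slot superfamily superfamily label.
#' @slot binWidth bin width in percent divergence (default 1).
#' @slot bins non-negative per-bin mass, first bin covering `[0, binWidth)`.
#' @slot weight `"reads"` or `"bp"`.
#'
#' @seealso [buildLandscape()], [classifyActivity()]
#' @export
setClass("DivergenceLandscape",
    representation(superfamily = "character", binWidth = "numeric",
                   bins = "numeric", weight = "character"))

setValidity("DivergenceLandscape", function(object) {
    if (!isSingleNumber(object@binWidth) || object@binWidth <= 0)
        return("binWidth must be a single positive number")
    if (length(object@bins) == 0L || any(object@bins < 0))
        return("bins must be non-empty and non-negative")
    if (!object@weight %in% c("reads", "bp"))
        return("weight must be 'reads' or 'bp'")
    TRUE
})

#' ElementModel: terminal/internal architecture of a TE contig
#'
#' A contig's terminal-repeat intervals and internal interval (bounded by
#' the first and last recognizable TE protein domains), plus whether the
#' terminal repeats are direct (LTR-like) or inverted (DIRS/TIR-like). The
#' geometry against which mapped reads are scored in the TT:I estimator.
#'
#' @slot contigID contig identifier.
#' @slot contigLen contig length in bp.
#' @slot mode `"direct"` or `"inverted"` terminal repeats.
#' @slot terminals [IRanges::IRanges] of terminal intervals (0-based
#'   half-open encoded as start = 0-based start + 1 is *not* used: ranges
#'   are stored as IRanges over 1-based positions, see Details).
#' @slot internal [IRanges::IRanges] of length 1, the internal interval.
#' @slot superfamily superfamily label.
#'
#' @details Intervals are held as `IRanges` over 1-based inclusive
#' positions (the native IRanges convention); constructors accept 0-based
#' half-open `(start, end)` pairs and convert.
#'
#' @seealso [buildElementModel()], [ttiRatio()]
#' @export
setClass("ElementModel",
    representation(contigID = "character", contigLen = "integer",
                   mode = "character", terminals = "IRanges",
                   internal = "IRanges", superfamily = "character"))

setValidity("ElementModel", function(object) {
    if (!object@mode %in% c("direct", "inverted"))
        return("mode must be 'direct' or 'inverted'")
    if (length(object@internal) != 1L)
        return("exactly one internal interval required")
    if (length(object@terminals) < 1L)
        return("at least one terminal interval required")
    if (!isDisjoint(object@terminals))
        return("terminal intervals overlap each other")
    if (sum(width(IRanges::intersect(object@terminals, object@internal))) > 0L)
        return("terminals overlap the internal interval")
    upper <- max(end(object@terminals), end(object@internal))
    if (upper > object@contigLen)
        return("intervals extend past contigLen")
    if (min(start(object@terminals), start(object@internal)) < 1L)
        return("intervals start before position 1")
    TRUE
})

#' CommunitySpec: parameters of a synthetic TE genome
#'
#' Declarative description of the community a synthetic genome should
#' contain: one row per superfamily with its classification, target genome
#' fraction, divergence-landscape scenario, number of families and
#' consensus length, plus genome length, background GC and the seed.
#'
#' @slot superfamilies data.frame with columns `name`, `classification`
#'   (Wicker-style path, e.g. `"ClassI/LTR/Gypsy"`),
#'   `target_genome_fraction`, `landscape_scenario` (one of
#'   `"recent_burst"`, `"past_peak"`, `"inactive_old"`, `"bimodal"`,
#'   `"monotonic"`), `n_families`, `consensus_len`.
#' @slot genomeLen genome length in bp.
#' @slot backgroundGC background GC fraction.
#' @slot seed integer seed; every generator derived from the spec is fully
#'   reproducible given this seed.
#'
#' @seealso [communitySpec()], [simulateGenomeAndReads()]
#' @export
setClass("CommunitySpec",
    representation(superfamilies = "data.frame", genomeLen = "integer",
                   backgroundGC = "numeric", seed = "integer"))

setValidity("CommunitySpec", function(object) {
    sf <- object@superfamilies
    need <- c("name", "classification", "target_genome_fraction",
              "landscape_scenario", "n_families", "consensus_len")
    if (!all(need %in% names(sf)))
        return(paste("superfamilies needs columns:",
                     paste(need, collapse = ", ")))
    if (nrow(sf) > 0L) {
        if (anyDuplicated(sf$name))
            return("duplicate superfamily names")
        if (any(sf$target_genome_fraction < 0) ||
            sum(sf$target_genome_fraction) > 1)
            return("target fractions must be >= 0 and sum to <= 1")
        ok <- c("recent_burst", "past_peak", "inactive_old", "bimodal",
                "monotonic")
        if (!all(sf$landscape_scenario %in% ok))
            return("unknown landscape_scenario")
        if (any(sf$consensus_len < 1) || any(sf$n_families < 1))
            return("consensus_len and n_families must be positive")
    }
    if (object@genomeLen < 1L)
        return("genomeLen must be positive")
    if (object@backgroundGC < 0 || object@backgroundGC > 1)
        return("backgroundGC must lie in [0, 1]")
    TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "RepeatHits", function(object) {
    h <- object@hits
    cat(sprintf("RepeatHits with %d hits on %d queries\n",
                nrow(h), length(unique(h$query_id))))
    if (nrow(h) > 0L) {
        tab <- sort(table(h$superfamily), decreasing = TRUE)
        top <- utils::head(tab, 5L)
        cat("  top superfamilies:",
            paste(sprintf("%s (%d)", names(top), top), collapse = ", "), "\n")
    }
})

setMethod("show", "AbundanceTable", function(object) {
    cat(sprintf("AbundanceTable at %s level: %d taxa, %.2f%% of %.0f bp masked\n",
                object@level, nrow(object@table),
                sum(object@table$pct_genome), object@totalBp))
})

setMethod("show", "TECommunity", function(object) {
    cat(sprintf("TECommunity (%s level): %d taxa, max p = %.3f (%s)\n",
                object@level, length(object@p), max(object@p),
                object@taxa[which.max(object@p)]))
})

setMethod("show", "DivergenceLandscape", function(object) {
    cat(sprintf(
        "DivergenceLandscape '%s': %d bins of %.2g%%, total mass %.0f (%s)\n",
        object@superfamily, length(object@bins), object@binWidth,
        sum(object@bins), object@weight))
})

setMethod("show", "ElementModel", function(object) {
    cat(sprintf(
        "ElementModel '%s' (%s, %s): %d bp, %d terminal(s) totalling %d bp, internal %d bp\n",
        object@contigID, object@superfamily, object@mode, object@contigLen,
        length(object@terminals), sum(width(object@terminals)),
        width(object@internal)))
})

setMethod("show", "CommunitySpec", function(object) {
    cat(sprintf(
        "CommunitySpec: %d superfamilies, genome %d bp, GC %.2f, seed %d\n",
        nrow(object@superfamilies), object@genomeLen, object@backgroundGC,
        object@seed))
})
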