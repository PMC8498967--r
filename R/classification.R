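## Wicker-style hierarchical TE classification labels.
##
## Labels arrive in several dialects: full paths ("ClassI/LTR/Gypsy"),
## RepeatMasker-style order/superfamily suffixes ("LTR/Gypsy"), bare
## orders ("LINE"), non-autonomous tags ("MITE", "TRIM", "LARD", "SINE"),
## or "Unknown". Unparseable text degrades to unclassified rather than
## erroring, because masker outputs routinely contain tool-specific names.

.RETRO_ORDERS <- c("LTR", "DIRS", "PLE", "LINE", "SINE")
.DNA_ORDERS <- c("TIR", "Helitron", "Maverick", "Crypton")
.NONAUT_TAGS <- c("TRIM", "LARD", "MITE", "SINE")

## order implied by each non-autonomous tag (MITEs are TIR derivatives,
## TRIM/LARD are LTR derivatives, SINEs are their own order)
.NONAUT_ORDER <- c(TRIM = "LTR", LARD = "LTR", MITE = "TIR", SINE = "SINE")

.classificationMapCache <- new.env(parent = emptyenv())

#' The superfamily dialect table
#'
#' Maps superfamily names as emitted by annotation tools to their Wicker
#' order and class. Shipped as an editable TSV
#' (`inst/extdata/classification_map.tsv`) seeded with the superfamilies
#' recognized in amphibian repeat libraries; tool-name drift can be
#' accommodated by passing a custom table.
#'
#' @param path optional path to an alternative map TSV with columns
#'   `superfamily`, `order`, `class`.
#' @return data.frame with columns `superfamily`, `order`, `class`.
#' @export
classificationMap <- function(path = NULL) {
    if (is.null(path)) {
        if (!is.null(.classificationMapCache$default))
            return(.classificationMapCache$default)
        path <- system.file("extdata", "classification_map.tsv",
                            package = "TElandscape", mustWork = TRUE)
        map <- .readTsv(path)
        .classificationMapCache$default <- map
        return(map)
    }
    .readTsv(path)
}

#' Parse Wicker-style TE classification labels
#'
#' Fills the classification hierarchy (class, order, superfamily,
#' non-autonomous kind) to the deepest level present in each label.
#' Retrotransposon orders (LTR, DIRS, PLE, LINE, SINE) imply Class I; DNA
#' transposon orders (TIR, Helitron, Maverick, Crypton) imply Class II.
#' Unknown or unparseable tokens degrade to `"unclassified"` with a
#' message.
#'
#' @param label character vector of labels, e.g. `"ClassI/LTR/Gypsy"`,
#'   `"LTR/Gypsy"`, `"LINE"`, `"MITE"`, `"Unknown"`.
#' @param map superfamily dialect table, see [classificationMap()].
#' @return data.frame with character columns `te_class` (`"I"`, `"II"`,
#'   `"unclassified"`), `te_order`, `superfamily` (both `"none"` when
#'   absent) and `nonautonomous_kind` (`"TRIM"`, `"LARD"`, `"MITE"`,
#'   `"SINE"` or `"none"`), one row per input label.
#' @examples
#' parseClassification(c("LINE/Jockey", "ClassII/TIR/hAT", "Unknown"))
#' @export
parseClassification <- function(label, map = classificationMap()) {
    label <- as.character(label)
    out <- data.frame(
        te_class = rep("unclassified", length(label)),
        te_order = rep("none", length(label)),
        superfamily = rep("none", length(label)),
        nonautonomous_kind = rep("none", length(label)),
        stringsAsFactors = FALSE)
    bad <- character(0)
    for (i in seq_along(label)) {
        f <- .parseOneLabel(label[i], map)
        if (is.null(f)) bad <- c(bad, label[i]) else out[i, ] <- f
    }
    if (length(bad) > 0L)
        message("unrecognized classification label(s) kept as unclassified: ",
                paste(unique(bad), collapse = ", "))
    out
}

.orderToClass <- function(ord) {
    if (ord %in% .RETRO_ORDERS) "I"
    else if (ord %in% .DNA_ORDERS) "II"
    else NA_character_
}

## returns a 4-element character vector, NULL if nothing recognized
.parseOneLabel <- function(label, map) {
    if (is.na(label) || !nzchar(label) ||
        tolower(label) %in% c("unknown", "unclassified", "unspecified"))
        return(c("unclassified", "none", "none", "none"))
    toks <- strsplit(label, "/", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L)
        return(c("unclassified", "none", "none", "none"))
    ## strip an explicit leading class token
    cls <- NA_character_
    t1 <- gsub("[ _-]", "", tolower(toks[1]))
    if (t1 %in% c("classi", "i", "retrotransposon")) {
        cls <- "I"; toks <- toks[-1]
    } else if (t1 %in% c("classii", "ii", "dnatransposon", "dna")) {
        cls <- "II"; toks <- toks[-1]
    }
    if (length(toks) == 0L)
        return(c(ifelse(is.na(cls), "unclassified", cls),
                 "none", "none", "none"))
    ## non-autonomous tag as the whole (remaining) label
    if (length(toks) == 1L && toupper(toks[1]) %in% .NONAUT_TAGS) {
        tag <- toupper(toks[1])
        ord <- .NONAUT_ORDER[[tag]]
        return(c(.orderToClass(ord), ord, "none", tag))
    }
    ord <- .matchOrder(toks[1])
    if (!is.na(ord)) {
        if (length(toks) == 1L)
            return(c(.orderToClass(ord), ord, "none",
                     if (ord == "SINE") "SINE" else "none"))
        sf <- .matchSuperfamily(toks[2], map, order = ord)
        if (is.na(sf)) {
            ## order recognized, superfamily token not in the dialect
            ## table: keep the token verbatim at superfamily rank
            sf <- toks[2]
            if (tolower(sf) %in% c("unknown", "unclassified"))
                return(c(.orderToClass(ord), ord, "none",
                         if (ord == "SINE") "SINE" else "none"))
        }
        return(c(.orderToClass(ord), ord, sf,
                 if (ord == "SINE") "SINE" else "none"))
    }
    ## bare superfamily name
    sfRow <- .matchSuperfamily(toks[1], map)
    if (!is.na(sfRow)) {
        ord <- map$order[match(tolower(sfRow), tolower(map$superfamily))]
        return(c(.orderToClass(ord), ord, sfRow,
                 if (ord == "SINE") "SINE" else "none"))
    }
    NULL
}

.matchOrder <- function(tok) {
    known <- c(.RETRO_ORDERS, .DNA_ORDERS)
    hit <- match(tolower(tok), tolower(known))
    if (!is.na(hit)) return(known[hit])
    ## common synonyms
    syn <- c(rc = "Helitron", helitron2 = "Helitron", penelope = "PLE",
             nonltr = "LINE")
    s <- syn[gsub("[ _-]", "", tolower(tok))]
    if (!is.na(s)) unname(s) else NA_character_
}

.matchSuperfamily <- function(tok, map, order = NULL) {
    rows <- map
    if (!is.null(order)) rows <- map[tolower(map$order) == tolower(order), ]
    norm <- function(x) gsub("[ _–-]", "", tolower(x))
    hit <- match(norm(tok), norm(rows$superfamily))
    if (is.na(hit) && !is.null(order)) {
        rows <- map
        hit <- match(norm(tok), norm(rows$superfamily))
    }
    if (is.na(hit)) NA_character_ else rows$superfamily[hit]
}

#' Canonical rendering of a parsed classification
#'
#' Renders parsed classification columns back to the package's canonical
#' label dialect (`"ClassI/LTR/Gypsy"`, `"ClassI/LINE"`, `"MITE"`,
#' `"Unknown"`). `parseClassification()` is idempotent on this rendering.
#'
#' @param cls data.frame as returned by [parseClassification()].
#' @return character vector of canonical labels.
#' @export
classificationString <- function(cls) {
    vapply(seq_len(nrow(cls)), function(i) {
        r <- cls[i, ]
        if (r$te_class == "unclassified") return("Unknown")
        if (r$nonautonomous_kind %in% c("TRIM", "LARD", "MITE") &&
            r$superfamily == "none")
            return(r$nonautonomous_kind)
        base <- paste0("Class", r$te_class)
        if (r$te_order == "none") return(base)
        if (r$superfamily == "none") return(paste(base, r$te_order, sep = "/"))
        paste(base, r$te_order, r$superfamily, sep = "/")
    }, character(1))
}

#' Render a classification at a chosen taxonomic level
#'
#' @param cls data.frame as from [parseClassification()] (or the
#'   corresponding columns of a hit table).
#' @param level `"class"`, `"order"` or `"superfamily"`.
#' @return character vector of taxon names at that level;
#'   `"unclassified"` where the label does not reach the requested level.
#' @export
taxonAtLevel <- function(cls, level = c("superfamily", "order", "class")) {
    level <- match.arg(level)
    switch(level,
        class = ifelse(cls$te_class == "unclassified", "unclassified",
                       paste0("Class", cls$te_class)),
        order = ifelse(cls$te_order == "none", "unclassified", cls$te_order),
        superfamily = ifelse(cls$superfamily == "none", "unclassified",
                             cls$superfamily))
}
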