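outLines <- function(rows) c("   SW  perc ...", "score  div. ...", "", rows)

test_that("hit rows parse with strand, overlap flag and library tags", {
    lines <- outLines(c(
        "500 3.2 0.0 0.0 read1 1 150 (100) + Gypsy-7#LTR/Gypsy 1 150 (0) 1",
        "300 10.0 0.0 0.0 read1 100 200 (50) C L1-2 LINE/L1 1 100 (0) 2 *"))
    h <- hitTable(readRepeatMaskerOut(text = lines))
    expect_equal(nrow(h), 2L)
    expect_equal(h$pct_div, c(3.2, 10.0))
    expect_equal(h$q_start, c(0L, 99L))     # 0-based half-open internally
    expect_equal(h$q_end, c(150L, 200L))
    expect_equal(h$query_len, c(250L, 250L))
    expect_equal(h$superfamily, c("Gypsy", "L1"))
    expect_equal(h$te_class, c("I", "I"))
    expect_equal(h$strand, c("+", "-"))     # "C" maps to minus
    expect_equal(h$overlap_flag, c(FALSE, TRUE))
    expect_equal(h$consensus_id, c("Gypsy-7", "L1-2"))
})

test_that("empty stream after headers yields an empty container", {
    h <- readRepeatMaskerOut(text = outLines(character(0)))
    expect_s4_class(h, "RepeatHits")
    expect_equal(length(h), 0L)
})

test_that("malformed rows raise an error naming the line number", {
    bad <- outLines("500 3.2 0.0 0.0 read1 1 150")
    expect_error(readRepeatMaskerOut(text = bad), "line 4")
    nonnum <- outLines(
        "500 xx 0.0 0.0 read1 1 150 (100) + A LTR/Gypsy 1 150 (0) 1")
    expect_error(readRepeatMaskerOut(text = nonnum), "line 4")
})

test_that("write/parse round-trips every modeled field in both dialects", {
    lines <- outLines(c(
        "500 3.2 0.0 0.0 read1 1 150 (100) + Gypsy-7 LTR/Gypsy 1 150 (0) 1",
        "300 10.0 0.0 0.0 read1 100 200 (50) C L1-2 LINE/L1 1 100 (0) 2 *",
        "250 25.5 0.0 0.0 read2 5 90 (10) + unkrep Unknown 1 85 (0) 3",
        "100 1.0 0.0 0.0 read3 1 80 (0) + mite1 MITE 1 80 (0) 4"))
    h <- readRepeatMaskerOut(text = lines)
    for (dialect in c("out", "tsv")) {
        tmp <- tempfile(fileext = paste0(".", dialect))
        writeRepeatMaskerOut(h, tmp, dialect = dialect)
        h2 <- readRepeatMaskerOut(tmp, dialect = dialect)
        expect_equal(hitTable(h2), hitTable(h), info = dialect)
        unlink(tmp)
    }
})

test_that("classification labels parse to the deepest level present", {
    cls <- parseClassification(c("LINE/Jockey", "ClassII/TIR/hAT",
                                 "Unknown", "LINE", "TRIM", "DIRS/DIRS"))
    expect_equal(cls$te_class,
                 c("I", "II", "unclassified", "I", "I", "I"))
    expect_equal(cls$te_order, c("LINE", "TIR", "none", "LINE", "LTR", "DIRS"))
    expect_equal(cls$superfamily,
                 c("Jockey", "hAT", "none", "none", "none", "DIRS"))
    expect_equal(cls$nonautonomous_kind,
                 c("none", "none", "none", "none", "TRIM", "none"))
})

test_that("DNA vs retro orders imply the TE class", {
    cls <- parseClassification(c("TIR/Tc1-Mariner", "Helitron/Helitron",
                                 "Maverick/Maverick", "LTR/Copia",
                                 "PLE/Penelope", "SINE/5S"))
    expect_equal(cls$te_class, c("II", "II", "II", "I", "I", "I"))
})

test_that("parsing is idempotent on the canonical rendering", {
    labels <- c("LINE/Jockey", "ClassI/DIRS/DIRS", "Unknown", "MITE",
                "LTR/Gypsy", "LINE", "SINE/7SL", "ClassII/TIR/CACTA")
    cls1 <- parseClassification(labels)
    cls2 <- parseClassification(classificationString(cls1))
    expect_equal(cls2, cls1)
})

test_that("unparseable tokens degrade to unclassified with a message", {
    expect_message(cls <- parseClassification("totally/bogus/thing"))
    expect_equal(cls$te_class, "unclassified")
})

test_that("repeat library FASTA round-trips ids and classifications", {
    set.seed(1)
    seqs <- Biostrings::DNAStringSet(c(
        "DIRS-3#DIRS/DIRS" = randomSeq(80),
        "gypsy_cons#LTR/Gypsy" = randomSeq(120),
        "mystery" = randomSeq(60)))
    tmp <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(seqs, tmp)
    lib <- readRepeatLibrary(tmp)
    expect_equal(names(lib), c("DIRS-3", "gypsy_cons", "mystery"))
    cls <- as.data.frame(S4Vectors::mcols(lib))
    expect_equal(cls$superfamily, c("DIRS", "Gypsy", "none"))
    expect_equal(cls$te_class, c("I", "I", "unclassified"))
    tmp2 <- tempfile(fileext = ".fa")
    writeRepeatLibrary(lib, tmp2)
    lib2 <- readRepeatLibrary(tmp2)
    expect_equal(as.character(lib2), as.character(lib))
    expect_equal(S4Vectors::mcols(lib2), S4Vectors::mcols(lib))
    unlink(c(tmp, tmp2))
})
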