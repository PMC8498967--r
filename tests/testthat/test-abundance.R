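test_that("overlapping hits are resolved per base by score then order", {
    h <- makeHits("r1", 200L, q_start = c(0L, 99L), q_end = c(150L, 200L),
                  superfamily = c("Gypsy", "L1"),
                  te_order = c("LTR", "LINE"), score = c(500, 300))
    t <- taxonTable(maskedFractionTable(h, totalBp = 1000))
    expect_equal(t$masked_bp[t$taxon == "Gypsy"], 150)
    expect_equal(t$masked_bp[t$taxon == "L1"], 50)
    expect_equal(t$pct_genome[t$taxon == "Gypsy"], 15.0)
    expect_equal(t$pct_genome[t$taxon == "L1"], 5.0)
})

test_that("score ties are broken by input order", {
    h <- makeHits("r1", 100L, q_start = c(0L, 0L), q_end = c(100L, 100L),
                  superfamily = c("A", "B"), score = c(100, 100))
    t <- taxonTable(maskedFractionTable(h, totalBp = 100))
    expect_equal(t$taxon, "A")
    expect_equal(t$masked_bp, 100)
})

test_that("no records gives an empty table and 0% masked", {
    h <- makeHits(character(0), integer(0), integer(0), integer(0),
                  character(0))
    ab <- maskedFractionTable(h, totalBp = 1000)
    expect_equal(nrow(taxonTable(ab)), 0L)
})

test_that("non-overlapping same-superfamily hits add up", {
    h <- makeHits("r1", 300L, q_start = c(0L, 200L), q_end = c(100L, 300L),
                  superfamily = "Gypsy", te_order = "LTR")
    t <- taxonTable(maskedFractionTable(h, totalBp = 1000))
    expect_equal(t$masked_bp, 200)
})

test_that("rollup conserves mass across levels and record counts", {
    set.seed(31)
    h <- makeHits(rep(sprintf("r%d", 1:12), each = 2), 150L,
                  q_start = sample(0:60, 24, TRUE),
                  q_end = sample(80:150, 24, TRUE),
                  superfamily = sample(c("Gypsy", "DIRS", "hAT"), 24, TRUE),
                  te_order = "LTR", te_class = sample(c("I", "II"), 24, TRUE),
                  score = sample(100:900, 24))
    byS <- maskedFractionTable(h, totalBp = 5000, level = "superfamily")
    byC <- maskedFractionTable(h, totalBp = 5000, level = "class")
    expect_equal(sum(taxonTable(byS)$masked_bp),
                 sum(taxonTable(byC)$masked_bp))
    byRec <- maskedFractionTable(h, totalBp = 5000, weighting = "records")
    expect_equal(sum(taxonTable(byRec)$masked_bp), 24)
    expect_equal(sum(taxonTable(byRec)$pct_genome), 100)
})

test_that("per-base resolution matches the bitmask oracle on random fixtures", {
    set.seed(7)
    for (rep in 1:20) {
        n <- sample(2:10, 1)
        qlen <- sample(60:120, 1)
        starts <- sample(0:(qlen - 20), n, replace = TRUE)
        ends <- pmin(qlen, starts + sample(10:60, n, replace = TRUE))
        h <- makeHits(sample(c("q1", "q2"), n, TRUE), qlen,
                      q_start = starts, q_end = ends,
                      superfamily = sample(c("A", "B", "C"), n, TRUE),
                      score = sample(1:5, n, TRUE) * 100)
        got <- taxonTable(maskedFractionTable(h, totalBp = 10 * qlen))
        got <- got[order(got$taxon), c("taxon", "masked_bp")]
        rownames(got) <- NULL
        want <- bitmaskOracle(h, totalBp = 10 * qlen)
        rownames(want) <- NULL
        expect_equal(got, want)
    }
})

test_that("adding a record never decreases total masked bp", {
    set.seed(13)
    h <- makeHits(rep("q", 5), 200L, q_start = sample(0:100, 5),
                  q_end = sample(120:200, 5),
                  superfamily = c("A", "B", "A", "C", "B"),
                  score = sample(1:500, 5))
    total <- function(x) sum(taxonTable(
        maskedFractionTable(x, totalBp = 1000))$masked_bp)
    for (k in 2:5)
        expect_gte(total(h[seq_len(k)]), total(h[seq_len(k - 1)]))
})

test_that("overlap-flagged hits can be excluded as downstream policy", {
    h <- makeHits("r1", 100L, q_start = c(0L, 50L), q_end = c(50L, 100L),
                  superfamily = c("A", "B"), overlap_flag = c(FALSE, TRUE))
    all <- maskedFractionTable(h, totalBp = 100)
    expect_equal(nrow(taxonTable(all)), 2L)
    kept <- maskedFractionTable(h, totalBp = 100, dropOverlapFlagged = TRUE)
    expect_equal(taxonTable(kept)$taxon, "A")
})

test_that("unknown-repeat differential is a guarded subtraction", {
    expect_equal(unknownDifferential(77.62, 68.20), 9.42)
    expect_equal(unknownDifferential(50, 50), 0)
    expect_equal(unknownDifferential(50.0, 40.0), 10.0)
    expect_error(unknownDifferential(40, 50), "mislabeled")
})

test_that("coverage estimate is total read bp over genome size", {
    expect_equal(round(coverageEstimate(1635569256, 12.2e9), 3), 0.134)
    expect_equal(coverageEstimate(5e9, 5e9), 1.0)
    expect_equal(coverageEstimate(2.5e9, 5e9), 0.5)
    expect_error(coverageEstimate(0, 5e9))
})

test_that("class ratio divides percent-genome values", {
    ab <- abundanceFromPct(c(ClassI = 52.09, ClassII = 2.63),
                           level = "class")
    expect_equal(round(classRatio(ab), 1), 19.8)
    ab2 <- abundanceFromPct(c(ClassI = 30, ClassII = 10), level = "class")
    expect_equal(classRatio(ab2), 3.0)
    expect_equal(classRatio(ab2, "ClassII", "ClassII"), 1.0)
    expect_error(classRatio(ab2, "ClassI", "ClassIII"), "absent")
})
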