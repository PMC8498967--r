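twoSfSpec <- function(genomeLen = 1e6, seed = 1L) {
    communitySpec(data.frame(
        name = c("DIRS", "hAT"),
        classification = c("ClassI/DIRS/DIRS", "ClassII/TIR/hAT"),
        target_genome_fraction = c(0.30, 0.20),
        landscape_scenario = c("past_peak", "recent_burst"),
        n_families = c(3L, 2L), consensus_len = c(2000L, 1500L)),
        genomeLen = genomeLen, seed = seed)
}

test_that("generation is deterministic under a fixed seed", {
    g1 <- simulateGenomeAndReads(twoSfSpec(2e5), coverage = 3)
    g2 <- simulateGenomeAndReads(twoSfSpec(2e5), coverage = 3)
    expect_identical(g1$genome, g2$genome)
    expect_identical(g1$reads, g2$reads)
    expect_identical(g1$truth$copies, g2$truth$copies)
    g3 <- simulateGenomeAndReads(twoSfSpec(2e5, seed = 2L), coverage = 3)
    expect_false(identical(g1$genome, g3$genome))
    e1 <- simulateExpression(c(A = 1, B = 0.1), seed = 5)
    e2 <- simulateExpression(c(A = 1, B = 0.1), seed = 5)
    expect_identical(e1, e2)
    p1 <- simulateElementPopulation(10, 5, coverage = 5, seed = 9)
    p2 <- simulateElementPopulation(10, 5, coverage = 5, seed = 9)
    expect_identical(p1$alignments, p2$alignments)
})

test_that("realized TE composition tracks the spec", {
    g <- simulateGenomeAndReads(twoSfSpec(), coverage = 1,
                                emitSequences = FALSE)
    comp <- g$truth$composition
    ## 60/40 split of TE bp within 5% relative
    ratio <- comp[["DIRS"]] / (comp[["DIRS"]] + comp[["hAT"]])
    expect_lt(abs(ratio - 0.6) / 0.6, 0.05)
    expect_lt(abs(comp[["DIRS"]] - 0.30) / 0.30, 0.05)
    ## zero-TE spec: background only, truth empty
    empty <- communitySpec(twoSfSpec()@superfamilies[0, ], genomeLen = 1e4)
    g0 <- simulateGenomeAndReads(empty, coverage = 1)
    expect_equal(nchar(g0$genome), 1e4)
    expect_equal(length(g0$truth$composition), 0L)
    expect_equal(nrow(emitMaskRecords(g0$truth, g0$reads)@hits), 0L)
})

test_that("infeasible target fractions are rejected", {
    bad <- communitySpec(data.frame(
        name = "X", classification = "ClassI/LINE/L1",
        target_genome_fraction = 0.999, landscape_scenario = "monotonic",
        n_families = 1L, consensus_len = 5000L), genomeLen = 1e4)
    expect_error(simulateGenomeAndReads(bad, coverage = 1), "infeasible")
})

test_that("mask records reflect the truth and parse cleanly", {
    g <- simulateGenomeAndReads(twoSfSpec(2e5), coverage = 5,
                                emitSequences = FALSE)
    hits <- emitMaskRecords(g$truth, g$reads)
    h <- hitTable(hits)
    ## a read fully inside a copy carries that copy's true divergence
    copies <- g$truth$copies
    inside <- which(vapply(seq_len(nrow(g$reads)), function(i)
        any(copies$start <= g$reads$start[i] &
            copies$end >= g$reads$end[i]), logical(1)))
    expect_gt(length(inside), 0L)
    i <- inside[1]
    row <- h[h$query_id == g$reads$read_id[i], ]
    expect_equal(nrow(row), 1L)
    cp <- copies[copies$start <= g$reads$start[i] &
                 copies$end >= g$reads$end[i], ]
    expect_equal(row$pct_div, cp$divergence[1])
    expect_equal(row$q_start, 0L)
    expect_equal(row$q_end, 150L)
    ## background reads emit nothing
    bg <- which(vapply(seq_len(nrow(g$reads)), function(i)
        all(g$reads$end[i] <= copies$start | g$reads$start[i] >= copies$end),
        logical(1)))
    expect_false(any(g$reads$read_id[bg] %in% h$query_id))
    ## round-trip through the .out writer with zero warnings
    expect_no_warning({
        tmp <- tempfile()
        writeRepeatMaskerOut(hits[seq_len(200)], tmp)
        back <- readRepeatMaskerOut(tmp)
        unlink(tmp)
    })
    expect_equal(hitTable(back)$pct_div, h$pct_div[1:200])
})

test_that("emitted landscapes match the truth divergence histogram", {
    g <- simulateGenomeAndReads(twoSfSpec(5e5), coverage = 10,
                                emitSequences = FALSE)
    hits <- emitMaskRecords(g$truth, g$reads)
    lands <- buildLandscape(bestHitDivergence(hits), weight = "bp")
    copies <- g$truth$copies
    for (sf in c("DIRS", "hAT")) {
        est <- landscapeBins(lands[[sf]])
        cp <- copies[copies$superfamily == sf, ]
        nb <- max(length(est), floor(max(cp$divergence)) + 1L)
        est <- c(est, rep(0, nb - length(est)))
        est <- est / sum(est)
        ## bp-weighted truth histogram over the same bins
        truthBins <- vapply(seq_len(nb) - 1L, function(k)
            sum((cp$end - cp$start)[floor(cp$divergence) == k]), numeric(1))
        truthBins <- truthBins / sum(truthBins)
        overlap <- sum(pmin(est, truthBins))
        expect_gte(overlap, 0.95)
    }
})

test_that("element population geometry and coverage behave as configured", {
    sim <- simulateElementPopulation(20, 10, terminalLen = 150,
                                     internalLen = 2000, coverage = 15,
                                     seed = 3)
    expect_s4_class(sim$model, "ElementModel")
    tm <- terminalIntervals(sim$model)
    expect_equal(unname(tm[, "end"] - tm[, "start"]), c(150, 150))
    expect_equal(unname(diff(internalInterval(sim$model))), 2000)
    a <- sim$alignments
    expect_true(all(a$aligned_len == a$end - a$start))
    expect_true(all(a$start >= 0 & a$end <= 2300))
    ## internal depth close to the requested coverage per copy
    r <- ttiRatio(a, sim$model, minAlignedLen = 1)
    expect_lt(abs(r$depth_internal / 20 - 15) / 15, 0.1)
    expect_error(simulateElementPopulation(0, 0), "nFull")
})
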