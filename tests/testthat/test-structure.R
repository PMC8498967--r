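test_that("direct and inverted terminal repeats are found by construction", {
    set.seed(41)
    T <- randomSeq(120)
    filler <- randomSeq(800)
    direct <- paste0(T, filler, T)
    tr <- findTerminalRepeats(direct, "direct", minLen = 50, endWindow = 300)
    expect_equal(nrow(tr), 1L)
    expect_equal(unname(unlist(tr[1, 1:4])), c(0, 120, 920, 1040))
    expect_equal(tr$identity[1], 1.0)
    inv <- paste0(T, filler, revcomp(T))
    tr2 <- findTerminalRepeats(inv, "inverted", minLen = 50, endWindow = 300)
    expect_equal(nrow(tr2), 1L)
    expect_equal(unname(unlist(tr2[1, 1:4])), c(0, 120, 920, 1040))
    ## the direct-mode search must not find the inverted repeat
    expect_equal(nrow(findTerminalRepeats(inv, "direct", minLen = 50,
                                          endWindow = 300)), 0L)
})

test_that("diverged terminal copies are still recovered above the identity floor", {
    set.seed(43)
    T <- randomSeq(200)
    T2 <- substituteBases(T, sample(200, 10))   # 95% identity
    seq <- paste0(T, randomSeq(1000), T2)
    tr <- findTerminalRepeats(seq, "direct", minLen = 100, endWindow = 400)
    expect_gte(nrow(tr), 1L)
    expect_gte(tr$identity[1], 0.9)
    expect_gte(tr$length[1], 150)
})

test_that("random sequence yields no 50 bp terminal repeat (k-mer oracle)", {
    set.seed(47)
    for (rep in 1:3) {
        s <- randomSeq(5000)
        tr <- findTerminalRepeats(s, "direct", minLen = 50, endWindow = 1000)
        expect_equal(nrow(tr), 0L)
        ## oracle: a 50 bp ungapped repeat at >= 80% identity must share
        ## an 11-mer between the windows; absence of hits is consistent
        ## only if shared 11-mers are absent or sparse
        if (!sharedKmer(s, 11, 1000)) succeed()
    }
    expect_error(findTerminalRepeats("ACGTQQ", "direct"), "IUPAC")
})

test_that("element models bound the internal by domain hits and clip terminals", {
    m <- buildElementModel("c1", 6000L,
                           terminalPairs = list(c(0, 150), c(5850, 6000)),
                           domainHits = list(c(200, 3000), c(2500, 5800)),
                           mode = "direct", superfamily = "Gypsy")
    expect_equal(unname(internalInterval(m)), c(200, 5800))
    expect_equal(unname(terminalIntervals(m)[, "end"]), c(150, 6000))
    ## terminal overlapping internal by 10 bp gets clipped by 10 bp
    m2 <- buildElementModel("c2", 6000L,
                            terminalPairs = list(c(0, 210), c(5850, 6000)),
                            domainHits = list(c(200, 5800)),
                            mode = "direct")
    expect_equal(unname(terminalIntervals(m2)[1, ]), c(0, 200))
    expect_error(buildElementModel("c3", 6000L, terminalPairs = list(),
                                   domainHits = list(c(200, 5800))),
                 "no terminal pair")
    expect_error(buildElementModel("c4", 6000L,
                                   terminalPairs = list(c(100, 200)),
                                   domainHits = list(c(0, 6000))),
                 "engulfs")
})

test_that("TT:I is exact on hand-built depth configurations", {
    m <- elementModel("c", 600L, list(c(0, 100), c(500, 600)), c(100, 500),
                      superfamily = "X")
    uniform <- data.frame(read_id = sprintf("r%d", 1:10), contig_id = "c",
                          start = 0L, end = 600L, aligned_len = 600L)
    expect_equal(ttiRatio(uniform, m)$tti, 1.0)
    ## terminal depth 15, internal depth 10
    extra <- data.frame(read_id = sprintf("t%d", 1:5), contig_id = "c",
                        start = c(0L, 0L, 0L, 500L, 500L),
                        end = c(100L, 100L, 100L, 600L, 600L),
                        aligned_len = 100L)
    both <- rbind(uniform, extra)
    r <- ttiRatio(both, m)
    expect_equal(r$depth_terminal, 12.5)
    expect_equal(r$depth_internal, 10)
    expect_equal(r$tti, 1.25)
    ## short alignments are discarded by the stringency threshold
    short <- data.frame(read_id = "s", contig_id = "c", start = 0L,
                        end = 10L, aligned_len = 10L)
    expect_equal(ttiRatio(rbind(uniform, short), m, minAlignedLen = 20)$tti,
                 1.0)
    expect_error(ttiRatio(uniform[0, ], m), "internal depth is zero")
})

test_that("TT:I equals the brute-force per-base depth oracle", {
    set.seed(53)
    m <- elementModel("c", 400L, list(c(0, 60), c(340, 400)), c(60, 340),
                      superfamily = "X")
    for (rep in 1:5) {
        n <- sample(30:100, 1)
        starts <- sample(0:360, n, replace = TRUE)
        lens <- sample(15:80, n, replace = TRUE)
        ends <- pmin(400L, starts + lens)
        a <- data.frame(read_id = sprintf("r%d", 1:n), contig_id = "c",
                        start = starts, end = ends,
                        aligned_len = ends - starts)
        got <- ttiRatio(a, m, minAlignedLen = 20)
        want <- depthOracle(a, m, minAlignedLen = 20)
        expect_equal(got$depth_terminal, want$depth_terminal,
                     tolerance = 1e-12)
        expect_equal(got$depth_internal, want$depth_internal,
                     tolerance = 1e-12)
        expect_equal(got$tti, want$tti, tolerance = 1e-12)
    }
})

test_that("sweep rows are identical when thresholds discard nothing", {
    m <- elementModel("c", 600L, list(c(0, 100), c(500, 600)), c(100, 500),
                      superfamily = "X")
    a <- data.frame(read_id = sprintf("r%d", 1:10), contig_id = "c",
                    start = 0L, end = 600L, aligned_len = 600L)
    sw <- ttiSweep(a, list(m), thresholds = c(20, 50))
    expect_equal(nrow(sw$summary), 2L)
    expect_equal(sw$summary$mean_tti[1], sw$summary$mean_tti[2])
    expect_equal(sw$summary$mean_tti[1], 1.0)
    expect_error(ttiSweep(a, list(m), thresholds = numeric(0)),
                 "no thresholds")
})

test_that("shorter terminals are more sensitive to the stringency sweep", {
    simFor <- function(tl, seeds) {
        rows <- lapply(seeds, function(s) {
            sim <- simulateElementPopulation(40, 40, terminalLen = tl,
                                             internalLen = 3000,
                                             coverage = 30, seed = s)
            sw <- ttiSweep(sim$alignments, list(sim$model),
                           thresholds = c(20, 50))
            sw$summary$mean_tti
        })
        colMeans(do.call(rbind, rows))
    }
    shortT <- simFor(150, 1:3)
    longT <- simFor(744, 1:3)
    dShort <- abs(shortT[1] - shortT[2])
    dLong <- abs(longT[1] - longT[2])
    expect_gt(dShort, dLong)
})

test_that("solo fraction inverts the TT:I expectation", {
    expect_equal(soloFractionEstimate(1.0), 0.0)
    expect_equal(soloFractionEstimate(1.5), 1.0)
    expect_equal(soloFractionEstimate(1.2), 0.4, tolerance = 1e-12)
    expect_warning(z <- soloFractionEstimate(0.8), "below 1")
    expect_equal(z, 0)
})
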