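mkTranscript <- function(contig_id, tpm, prot = NULL, nucl = NULL,
                         gene = NULL) {
    data.frame(contig_id = contig_id, tpm = tpm,
               protein_te_hits = I(list(prot)),
               nucl_te_hits = I(list(nucl)),
               gene_annotations = I(list(gene)),
               stringsAsFactors = FALSE)
}

protHit <- function(superfamily = "DIRS", e = 1e-20)
    data.frame(superfamily = superfamily, e_value = e)
nuclHit <- function(len = 100, id = 0.9, cov = 0.9, superfamily = "MITE")
    data.frame(aln_len = len, identity = id, library_coverage = cov,
               superfamily = superfamily)
geneAnn <- function(id = "g1") data.frame(gene_id = id)

test_that("the 80/80/80 rule is strict on all three margins", {
    expect_true(eightyRuleFilter(100, 0.85, 0.90))
    expect_false(eightyRuleFilter(80, 0.95, 0.95))
    expect_false(eightyRuleFilter(300, 0.95, 0.60))
    expect_false(eightyRuleFilter(300, 0.80, 0.95))
    expect_error(eightyRuleFilter(100, 1.2, 0.5), "\\[0, 1\\]")
})

test_that("transcript categorization follows the decision order", {
    recs <- rbind(
        mkTranscript("auto", 10, prot = protHit()),
        mkTranscript("nonauto", 10, nucl = nuclHit()),
        mkTranscript("conflict", 10, prot = protHit(), nucl = nuclHit()),
        mkTranscript("tegene", 10, prot = protHit(), gene = geneAnn()),
        mkTranscript("tegene2", 10, nucl = nuclHit(), gene = geneAnn()),
        mkTranscript("gene", 10, gene = geneAnn()),
        mkTranscript("unk", 10),
        mkTranscript("low", 0.005, prot = protHit()),
        mkTranscript("failnucl", 10, nucl = nuclHit(len = 50)))
    res <- categorizeTranscripts(recs)
    got <- setNames(res$assignments$category, res$assignments$contig_id)
    expect_equal(unname(got[c("auto", "nonauto", "conflict", "tegene",
                              "tegene2", "gene", "unk", "failnucl")]),
                 c("autonomous_te", "non_autonomous_te", "filtered_conflict",
                   "te_gene", "te_gene", "gene", "unknown", "unknown"))
    expect_false("low" %in% res$assignments$contig_id)  # TPM floor
    expect_equal(res$n_dropped, 1L)
    ## categories partition the retained contigs
    expect_equal(sum(res$summary$Freq) + res$n_dropped, nrow(recs))
    ## curation override hook
    res2 <- categorizeTranscripts(recs, overrides = data.frame(
        contig_id = "auto", category = "gene"))
    expect_equal(res2$assignments$category[
        res2$assignments$contig_id == "auto"], "gene")
})

test_that("expression sums aggregate by category and best-hit superfamily", {
    recs <- rbind(
        mkTranscript("c1", 10, prot = protHit("DIRS")),
        mkTranscript("c2", 5, prot = rbind(protHit("DIRS", 1e-30),
                                           protHit("hAT", 1e-5))),
        mkTranscript("c3", 2, prot = protHit("hAT")),
        mkTranscript("c4", 100, gene = geneAnn()))
    res <- categorizeTranscripts(recs)
    s <- expressionSummary(res$assignments, recs)
    bySf <- setNames(s$bySuperfamily$summed_tpm, s$bySuperfamily$superfamily)
    expect_equal(unname(bySf["DIRS"]), 15)
    expect_equal(unname(bySf["hAT"]), 2)
    byCat <- setNames(s$byCategory$summed_tpm, s$byCategory$category)
    expect_equal(unname(byCat["autonomous_te"]), 17)
    expect_equal(unname(byCat["gene"]), 100)
    ## fractions divide by the TPM constant
    expect_equal(sum(s$byCategory$fraction_transcriptome),
                 117 / 1e6, tolerance = 1e-12)
    obs <- expressionSummary(res$assignments, recs,
                             denominator = "observed")
    expect_equal(sum(obs$byCategory$fraction_transcriptome), 1,
                 tolerance = 1e-12)
    ## printed-scale check: summed TPM 131793 is 13.2% of the
    ## transcriptome at 1 decimal place
    one <- mkTranscript("all", 131793, prot = protHit())
    r1 <- categorizeTranscripts(one)
    s1 <- expressionSummary(r1$assignments, one)
    expect_equal(round(100 * s1$byCategory$fraction_transcriptome, 1), 13.2)
})

test_that("abundance-expression correlation is exact on log-linear data", {
    ab <- abundanceFromPct(c(A = 10, B = 1, C = 0.1))
    perfect <- data.frame(superfamily = c("A", "B", "C"),
                          summed_tpm = c(1000, 100, 10))
    res <- abundanceExpressionCorrelation(ab, perfect)
    expect_equal(res$r, 1.0, tolerance = 1e-12)
    expect_equal(res$n, 3L)
    inverse <- data.frame(superfamily = c("A", "B", "C"),
                          summed_tpm = c(10, 100, 1000))
    expect_equal(abundanceExpressionCorrelation(ab, inverse)$r, -1.0,
                 tolerance = 1e-12)
    ## r is invariant to the log base: natural-log transform by hand
    set.seed(61)
    pct <- setNames(10^runif(8, -2, 1), letters[1:8])
    tpm <- data.frame(superfamily = letters[1:8],
                      summed_tpm = 10^(log10(pct) + rnorm(8, 0, 0.3)))
    r10 <- abundanceExpressionCorrelation(abundanceFromPct(pct), tpm)$r
    rln <- cor(log(pct), log(tpm$summed_tpm))
    expect_equal(r10, unname(rln), tolerance = 1e-12)
    ## absent-in-one superfamilies are excluded and n reported
    part <- data.frame(superfamily = letters[1:4],
                       summed_tpm = c(1, 2, 3, 4))
    expect_equal(abundanceExpressionCorrelation(abundanceFromPct(pct),
                                                part)$n, 4L)
    expect_error(abundanceExpressionCorrelation(
        abundanceFromPct(c(A = 1, B = 2)), part), ">= 3")
})

test_that("synthetic expression recovers the configured coupling strength", {
    comp <- syntheticComposition(25)
    ab <- abundanceFromPct(comp)
    r <- vapply(1:100, function(s) {
        e <- simulateExpression(comp, targetR = 0.88, seed = s)
        abundanceExpressionCorrelation(ab, e)$r
    }, numeric(1))
    ## mean estimate within the 95% CI of the configured r*
    expect_lt(abs(mean(r) - 0.88), 2 * sd(r) / sqrt(length(r)) + 0.01)
    ## noiseless coupling gives r = 1 exactly
    e0 <- simulateExpression(comp, noiseSd = 0, seed = 1)
    expect_equal(abundanceExpressionCorrelation(ab, e0)$r, 1.0,
                 tolerance = 1e-12)
})

test_that("TE/gene geometry classifies position, strand and frame", {
    ## start offset 502 - 100 = 402, divisible by 3: in frame
    expect_equal(
        unlist(teGeneGeometry(c(100, 400), "+", c(502, 900), "+")),
        c(position = "upstream", strand = "same", frame = "in"))
    expect_equal(
        unlist(teGeneGeometry(c(600, 900), "-", c(100, 500), "+")),
        c(position = "downstream", strand = "opposite", frame = "n/a"))
    expect_equal(
        teGeneGeometry(c(100, 600), "+", c(400, 900), "+")$position,
        "overlapping")
    expect_equal(teGeneGeometry(c(100, 400), "+", c(501, 900), "+")$frame,
                 "out")
    expect_error(teGeneGeometry(c(NA, 400), "+", c(500, 900), "+"),
                 "coordinates")
})
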