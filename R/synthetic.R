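## Fully seeded synthetic TE genomes, reads, hit records, element-
## population alignments and expression tables with known ground truth,
## so that every pipeline stage can be tested at desk scale without
## external data. Mutation is substitution-only by default so that truth
## divergence and reported divergence coincide, and reads are error-free;
## sequencing error would blur the divergence landscape and is orthogonal
## to the statistics computed here.

.SCENARIOS <- c("recent_burst", "past_peak", "inactive_old", "bimodal",
                "monotonic")

#' Construct a CommunitySpec
#'
#' @param superfamilies data.frame with columns `name`, `classification`,
#'   `target_genome_fraction`, `landscape_scenario`, `n_families`,
#'   `consensus_len`; see [CommunitySpec-class].
#' @param genomeLen genome length, bp.
#' @param backgroundGC background GC fraction.
#' @param seed integer seed.
#' @return a [CommunitySpec-class].
#' @export
communitySpec <- function(superfamilies, genomeLen = 1e6,
                          backgroundGC = 0.41, seed = 1L) {
    new("CommunitySpec", superfamilies = superfamilies,
        genomeLen = as.integer(genomeLen), backgroundGC = backgroundGC,
        seed = as.integer(seed))
}

#' Default synthetic community
#'
#' A desk-scale community whose composition mirrors a giant-genome TE
#' landscape: two dominant retrotransposon superfamilies (DIRS and
#' Jockey at roughly 30\% and 21\% of the genome) over a tail of minor
#' superfamilies, with amplification-history scenarios assigned to cover
#' every landscape shape the classifier recognizes. Fractions for the
#' nine most abundant superfamilies follow the excluding-unknown genome
#' percentages typical of a giant amphibian genome; the two
#' low-abundance entries (a bimodal SINE and an inactive endogenous
#' retrovirus) are set to small representative values.
#'
#' @param genomeLen genome length, bp (default 1e6; desk scale).
#' @param seed integer seed.
#' @return a [CommunitySpec-class] with 11 superfamilies totalling ~60\%
#'   of the genome.
#' @export
defaultCommunitySpec <- function(genomeLen = 1e6, seed = 1L) {
    sf <- data.frame(
        name = c("DIRS", "Jockey", "L1", "ERV", "RTE", "Gypsy",
                 "hAT", "Tc1-Mariner", "CACTA", "5S", "Retrovirus"),
        classification = c("ClassI/DIRS/DIRS", "ClassI/LINE/Jockey",
                           "ClassI/LINE/L1", "ClassI/LTR/ERV",
                           "ClassI/LINE/RTE", "ClassI/LTR/Gypsy",
                           "ClassII/TIR/hAT", "ClassII/TIR/Tc1-Mariner",
                           "ClassII/TIR/CACTA", "ClassI/SINE/5S",
                           "ClassI/LTR/Retrovirus"),
        target_genome_fraction = c(0.3020, 0.2059, 0.0323, 0.0182, 0.0160,
                                   0.0135, 0.0115, 0.0059, 0.0056, 0.0010,
                                   0.0005),
        landscape_scenario = c("past_peak", "past_peak", "monotonic",
                               "past_peak", "past_peak", "monotonic",
                               "recent_burst", "recent_burst", "monotonic",
                               "bimodal", "inactive_old"),
        n_families = c(8L, 6L, 4L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L),
        consensus_len = c(2000L, 2500L, 3000L, 2000L, 2000L, 2500L,
                          1500L, 1300L, 1500L, 300L, 2000L),
        stringsAsFactors = FALSE)
    communitySpec(sf, genomeLen = genomeLen, seed = seed)
}

#' Draw per-copy divergences for a landscape scenario
#'
#' Scenario shapes: `recent_burst` exponential with mean 2\%;
#' `past_peak` normal(8\%, 2\%) truncated at 0; `inactive_old`
#' normal(15\%, 2\%) truncated at 0 (essentially no mass below 1\%);
#' `bimodal` an equal mixture of the first two; `monotonic` exponential
#' with mean 5\%. Values are capped at 45\% (beyond recognizable
#' homology).
#'
#' @param scenario one of the five scenario names.
#' @param n number of draws.
#' @return numeric vector of percent divergences.
#' @export
scenarioDivergences <- function(scenario, n) {
    scenario <- match.arg(scenario, .SCENARIOS)
    truncNorm <- function(n, mean, sd) {
        x <- stats::rnorm(n, mean, sd)
        while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), mean, sd)
        x
    }
    d <- switch(scenario,
        recent_burst = stats::rexp(n, rate = 1 / 2),
        past_peak = truncNorm(n, 8, 2),
        inactive_old = truncNorm(n, 15, 2),
        bimodal = {
            pick <- stats::runif(n) < 0.5
            out <- numeric(n)
            out[pick] <- stats::rexp(sum(pick), rate = 1 / 2)
            out[!pick] <- truncNorm(sum(!pick), 8, 2)
            out
        },
        monotonic = stats::rexp(n, rate = 1 / 5))
    pmin(d, 45)
}

#' Expected activity of a scenario
#'
#' The activity dichotomy each scenario is constructed to show:
#' `recent_burst`, `monotonic` and `bimodal` populations retain copies
#' below 1\% divergence and active shapes; `past_peak` and
#' `inactive_old` have essentially no mass below 1\% divergence.
#'
#' @param scenario scenario name(s).
#' @return logical vector.
#' @export
scenarioExpectedActivity <- function(scenario) {
    scenario %in% c("recent_burst", "monotonic", "bimodal")
}

.BASES <- c("A", "C", "G", "T")

.randomSeqVec <- function(n, gc = 0.5) {
    sample(.BASES, n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## substitution-only mutation; returns list(seq, realizedDivergence)
.mutateVec <- function(x, rate) {
    n <- length(x)
    nMut <- stats::rbinom(1L, n, min(rate, 1))
    if (nMut > 0L) {
        pos <- sample.int(n, nMut)
        for (p in pos) x[p] <- sample(setdiff(.BASES, x[p]), 1L)
    }
    list(seq = x, divergence = 100 * nMut / n)
}

#' Simulate a genome of known TE composition plus shotgun reads
#'
#' Builds a background sequence of i.i.d. bases at the requested GC,
#' generates per-superfamily family consensus sequences, mutates copies
#' at per-copy substitution rates drawn from the superfamily's landscape
#' scenario, inserts the copies at uniform non-overlapping positions, and
#' samples error-free fixed-length reads uniformly. Fully reproducible
#' from the spec's seed.
#'
#' @param spec a [CommunitySpec-class].
#' @param coverage fold sequencing coverage (default 10).
#' @param readLen read length, bp (default 150).
#' @param emitSequences keep genome/read sequences (default TRUE; set
#'   FALSE when only coordinates and truth are needed).
#' @return list with `genome` (character or NULL), `reads` (data.frame
#'   `read_id`, `start`, `end`; plus `sequence` when emitted) and `truth`
#'   (list: `copies` data.frame with `superfamily`, `classification`,
#'   `family`, `start`, `end`, `divergence`; `composition` realized
#'   per-superfamily bp fractions; `spec`).
#' @export
simulateGenomeAndReads <- function(spec, coverage = 10, readLen = 150,
                                   emitSequences = TRUE) {
    stopifnot(is(spec, "CommunitySpec"))
    if (coverage <= 0) .stopf("coverage must be > 0")
    if (readLen >= spec@genomeLen) .stopf("readLen must be < genomeLen")
    set.seed(spec@seed)
    sf <- spec@superfamilies
    G <- spec@genomeLen
    ## plan copies per superfamily
    copies <- list()
    for (i in seq_len(nrow(sf))) {
        targetBp <- sf$target_genome_fraction[i] * G
        if (targetBp <= 0) next
        len <- sf$consensus_len[i]
        nCopies <- max(1L, round(targetBp / len))
        fams <- lapply(seq_len(sf$n_families[i]), function(f) {
            ## families within a superfamily share a superfamily ancestor
            ## but are themselves well diverged
            .randomSeqVec(len, spec@backgroundGC)
        })
        famIdx <- sample.int(length(fams), nCopies, replace = TRUE)
        divs <- scenarioDivergences(sf$landscape_scenario[i], nCopies)
        copies[[i]] <- list(
            sf = sf$name[i], cls = sf$classification[i],
            fams = fams, famIdx = famIdx, divs = divs, len = len)
    }
    copies <- copies[!vapply(copies, is.null, logical(1))]
    teBp <- sum(vapply(copies, function(c) length(c$famIdx) * c$len,
                       numeric(1)))
    if (teBp >= G)
        .stopf("target fractions infeasible for genomeLen %d", G)
    if (length(copies) == 0L) {
        genome <- if (emitSequences)
            paste(.randomSeqVec(G, spec@backgroundGC), collapse = "")
        else NULL
        nReads <- max(1L, round(coverage * G / readLen))
        starts <- sample.int(G - readLen + 1L, nReads, replace = TRUE) - 1L
        reads <- data.frame(read_id = sprintf("read%06d", seq_len(nReads)),
                            start = starts, end = starts + readLen,
                            stringsAsFactors = FALSE)
        if (emitSequences)
            reads$sequence <- substring(genome, starts + 1L, starts + readLen)
        truth <- list(copies = data.frame(superfamily = character(0),
                                          classification = character(0),
                                          family = integer(0),
                                          start = integer(0),
                                          end = integer(0),
                                          divergence = numeric(0)),
                      composition = numeric(0), spec = spec)
        return(list(genome = genome, reads = reads, truth = truth))
    }
    ## flatten copies, shuffle insertion order
    copyTab <- do.call(rbind, lapply(copies, function(c)
        data.frame(superfamily = c$sf, classification = c$cls,
                   family = c$famIdx, len = c$len,
                   divergence = c$divs, stringsAsFactors = FALSE)))
    copySeqs <- unlist(lapply(copies, function(c)
        lapply(seq_along(c$famIdx), function(k) {
            m <- .mutateVec(c$fams[[c$famIdx[k]]], c$divs[k] / 100)
            m
        })), recursive = FALSE)
    copyTab$divergence <- vapply(copySeqs, function(m) m$divergence,
                                 numeric(1))
    nCopy <- nrow(copyTab)
    ord <- sample.int(nCopy)
    copyTab <- copyTab[ord, , drop = FALSE]
    copySeqs <- copySeqs[ord]
    ## insertion offsets within the background, uniform without overlap
    bgLen <- G - teBp
    offsets <- sort(sample.int(bgLen + 1L, nCopy, replace = TRUE) - 1L)
    cum <- cumsum(c(0, copyTab$len))[seq_len(nCopy)]
    copyTab$start <- offsets + cum
    copyTab$end <- copyTab$start + copyTab$len
    genome <- NULL
    if (emitSequences) {
        bg <- .randomSeqVec(bgLen, spec@backgroundGC)
        pieces <- character(2L * nCopy + 1L)
        prev <- 0L
        for (k in seq_len(nCopy)) {
            pieces[2L * k - 1L] <- paste(bg[seq2(prev + 1L, offsets[k])],
                                         collapse = "")
            pieces[2L * k] <- paste(copySeqs[[k]]$seq, collapse = "")
            prev <- offsets[k]
        }
        pieces[2L * nCopy + 1L] <- paste(bg[seq2(prev + 1L, bgLen)],
                                         collapse = "")
        genome <- paste(pieces, collapse = "")
        stopifnot(nchar(genome) == G)
    }
    ## reads
    nReads <- max(1L, round(coverage * G / readLen))
    starts <- sample.int(G - readLen + 1L, nReads, replace = TRUE) - 1L
    reads <- data.frame(read_id = sprintf("read%06d", seq_len(nReads)),
                        start = starts, end = starts + readLen,
                        stringsAsFactors = FALSE)
    if (emitSequences)
        reads$sequence <- substring(genome, starts + 1L, starts + readLen)
    realized <- tapply(copyTab$len, copyTab$superfamily, sum) / G
    truth <- list(copies = copyTab[, c("superfamily", "classification",
                                       "family", "start", "end",
                                       "divergence")],
                  composition = realized[!is.na(realized)],
                  spec = spec)
    list(genome = genome, reads = reads, truth = truth)
}

#' Emit oracle hit records for simulated reads
#'
#' Stand-in for an external masker that uses the generator's ground
#' truth: every read overlapping a TE copy by at least `minOverlap` bp
#' yields one hit whose divergence is the copy's true substitution
#' divergence and whose classification comes from the truth table. Reads
#' entirely in background yield nothing.
#'
#' @param truth the `truth` element of [simulateGenomeAndReads()].
#' @param reads the `reads` element of the same call.
#' @param minOverlap minimum read/copy overlap, bp (default 20).
#' @return a [RepeatHits-class].
#' @export
emitMaskRecords <- function(truth, reads, minOverlap = 20) {
    copies <- truth$copies
    readLen <- reads$end - reads$start
    rr <- IRanges::IRanges(start = reads$start + 1L, end = reads$end)
    cr <- IRanges::IRanges(start = copies$start + 1L, end = copies$end)
    ov <- IRanges::findOverlaps(rr, cr, minoverlap = as.integer(minOverlap))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (length(qh) == 0L) return(.hitsFromParsedRows(list(),
                                                     classificationMap()))
    inter <- IRanges::pintersect(rr[qh], cr[sh])
    cls <- parseClassification(copies$classification)
    h <- data.frame(
        query_id = reads$read_id[qh],
        query_len = readLen[qh],
        q_start = IRanges::start(inter) - 1L - reads$start[qh],
        q_end = IRanges::end(inter) - reads$start[qh],
        consensus_id = sprintf("%s-fam%d", copies$superfamily[sh],
                               copies$family[sh]),
        cls[sh, , drop = FALSE],
        pct_div = copies$divergence[sh],
        score = round(IRanges::width(inter) *
                      (1 - copies$divergence[sh] / 100), 1),
        strand = "+",
        overlap_flag = FALSE,
        stringsAsFactors = FALSE)
    rownames(h) <- NULL
    repeatHits(h)
}

#' Simulate reads over a population of intact and solo-terminal elements
#'
#' Builds a two-terminal consensus element model (terminal, internal,
#' terminal) and draws error-free reads from a virtual population of
#' `nFull` intact copies and `nSolo` solo terminals, each copy embedded
#' in ample flanking DNA: read start positions fall uniformly over every
#' position overlapping the copy, and each read is converted to a
#' consensus-coordinate alignment covering its overlap with the element
#' (reads from solo terminals land on a uniformly chosen terminal of the
#' consensus). Read counts per copy are Poisson at the requested
#' coverage.
#'
#' @param nFull number of intact two-terminal copies.
#' @param nSolo number of solo terminals.
#' @param terminalLen terminal repeat length, bp (default 150).
#' @param internalLen internal sequence length, bp (default 5586).
#' @param coverage fold coverage of the population (default 20).
#' @param readLen read length, bp (default 150).
#' @param seed integer seed.
#' @param mode `"direct"` or `"inverted"` (geometry only; depth handling
#'   is identical).
#' @param superfamily label for the model.
#' @return list with `model` (an [ElementModel-class]), `alignments`
#'   (data.frame `read_id`, `contig_id`, `start`, `end`, `aligned_len`)
#'   and `truth` (list with the population parameters).
#' @export
simulateElementPopulation <- function(nFull, nSolo, terminalLen = 150,
                                      internalLen = 5586, coverage = 20,
                                      readLen = 150, seed = 1L,
                                      mode = "direct",
                                      superfamily = "synthetic") {
    if (nFull < 1L || nSolo < 0L)
        .stopf("need nFull >= 1 and nSolo >= 0")
    if (readLen >= internalLen)
        .stopf("readLen must be < internalLen")
    set.seed(seed)
    tl <- as.integer(terminalLen); il <- as.integer(internalLen)
    L <- 2L * tl + il
    contig <- sprintf("%s-consensus", superfamily)
    model <- elementModel(contig, L,
                          terminals = list(c(0L, tl), c(tl + il, L)),
                          internal = c(tl, tl + il),
                          mode = mode, superfamily = superfamily)
    lambda <- coverage / readLen     # read starts per bp
    sampleCopy <- function(copyLen, offsetChooser) {
        nStartPos <- copyLen + readLen - 1L
        n <- stats::rpois(1L, lambda * nStartPos)
        if (n == 0L) return(NULL)
        s <- sample.int(nStartPos, n, replace = TRUE) - readLen  # in
        ## copy coordinates, alignment = [s, s+readLen) clipped to copy
        aStart <- pmax(s, 0L)
        aEnd <- pmin(s + readLen, copyLen)
        off <- offsetChooser(n)
        data.frame(start = aStart + off, end = aEnd + off)
    }
    alns <- list()
    for (i in seq_len(nFull)) {
        a <- sampleCopy(L, function(n) rep(0L, n))
        if (!is.null(a)) alns[[length(alns) + 1L]] <- a
    }
    for (i in seq_len(nSolo)) {
        a <- sampleCopy(tl, function(n)
            sample(c(0L, tl + il), n, replace = TRUE))
        if (!is.null(a)) alns[[length(alns) + 1L]] <- a
    }
    alnDf <- do.call(rbind, alns)
    alignments <- data.frame(
        read_id = sprintf("read%06d", seq_len(nrow(alnDf))),
        contig_id = contig,
        start = alnDf$start, end = alnDf$end,
        aligned_len = alnDf$end - alnDf$start,
        stringsAsFactors = FALSE)
    list(model = model, alignments = alignments,
         truth = list(n_full = nFull, n_solo = nSolo,
                      solo_per_full = nSolo / nFull,
                      terminal_len = tl, internal_len = il,
                      coverage = coverage, read_len = readLen, seed = seed))
}

#' Simulate expression coupled to genomic abundance
#'
#' Generates per-superfamily summed TPM log-linearly coupled to genome
#' fraction: `log10 TPM = slope * log10 fraction + intercept + noise`,
#' then rescales so the total over superfamilies equals the TPM
#' normalization constant 10^6 times `transcriptomeShare`. With
#' `noiseSd = NULL` the noise is calibrated so the expected Pearson
#' correlation on log scales equals `targetR` (default 0.879, the
#' coupling strength this generator emulates).
#'
#' @param genomeFractions named numeric vector of positive genome
#'   fractions (or percentages; only ratios matter).
#' @param slope log-log slope (default 1).
#' @param noiseSd standard deviation of the log10 noise; `NULL` to
#'   calibrate from `targetR`.
#' @param targetR target Pearson correlation used when `noiseSd` is
#'   `NULL`.
#' @param transcriptomeShare fraction of the 10^6 TPM total assigned to
#'   these superfamilies (default 0.132).
#' @param seed integer seed.
#' @return data.frame (`superfamily`, `summed_tpm`).
#' @export
simulateExpression <- function(genomeFractions, slope = 1, noiseSd = NULL,
                               targetR = 0.879, transcriptomeShare = 0.132,
                               seed = 1L) {
    if (any(genomeFractions <= 0)) .stopf("fractions must be positive")
    if (is.null(names(genomeFractions)))
        .stopf("genomeFractions must be named by superfamily")
    set.seed(seed)
    lx <- log10(genomeFractions)
    if (is.null(noiseSd)) {
        if (targetR <= 0 || targetR > 1) .stopf("targetR must be in (0, 1]")
        noiseSd <- abs(slope) * stats::sd(lx) * sqrt(1 / targetR^2 - 1)
    }
    ly <- slope * lx + stats::rnorm(length(lx), 0, noiseSd)
    tpm <- 10^ly
    tpm <- tpm / sum(tpm) * 1e6 * transcriptomeShare
    data.frame(superfamily = names(genomeFractions), summed_tpm = tpm,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' A synthetic 25-superfamily composition
#'
#' Deterministic stand-in for a full per-superfamily genome-percentage
#' column: 25 superfamily names from the classification dialect table
#' with percentages log-uniformly spaced from 30.2\% down to 0.005\%,
#' mimicking the strongly uneven abundance distribution of a giant
#' genome. Used as the abundance side of expression-coupling
#' simulations; it is synthetic and carries no empirical cell values
#' beyond the dominant-superfamily scale.
#'
#' @param n number of superfamilies (default 25).
#' @return named numeric vector of genome percentages.
#' @export
syntheticComposition <- function(n = 25) {
    map <- classificationMap()
    names <- utils::head(map$superfamily, n)
    pct <- 10^seq(log10(30.2), log10(0.005), length.out = n)
    stats::setNames(pct, names)
}
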