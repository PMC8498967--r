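---
title: "Methods: TE landscape characterization from genome skims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE landscape characterization from genome skims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TElandscape)
```

This vignette is the package's own account of its methods: the models
and decision procedures, the parameters that matter and their defaults,
what the synthetic generator does and does not emulate, and the
numerical and design choices made where more than one convention was
defensible.

## The setting

For organisms with multi-gigabase genomes, assembly-based TE annotation
is often infeasible, but low-coverage shotgun reads masked against a
classified repeat library still estimate the *overall* repeat landscape:
which TE superfamilies are present, what fraction of the genome each
occupies, how diverged extant copies are from their consensus (a record
of amplification history), how much terminal-repeat sequence exists
relative to internal sequence (a record of deletion by ectopic
recombination), and how much of the transcriptome TEs consume. The
package implements each of these estimators over plain tabular inputs,
plus a seeded generator that manufactures inputs with known truth.

Coordinates are 1-based inclusive in files (the RepeatMasker `.out`
convention) and 0-based half-open internally; all writers convert back.
This removes ambiguity from interval arithmetic, which is pervasive
here (overlap resolution, region depth, element architecture).

## Abundance: per-base overlap resolution

A hit table may assign overlapping intervals of the same read to
different consensus sequences. `maskedFractionTable()` resolves
ownership per base — highest alignment score wins, ties broken by
earlier input order — so each surveyed base is counted at most once and
rollups conserve mass exactly across taxonomic levels. The tests hold
this against a brute-force per-base bitmask oracle. Weighting is
bp-based ("percent of surveyed bp") because that is the unit in which
genome occupancy is conventionally reported; a record-count weighting
exists as an option but is never the default. The surveyed-bp
denominator `totalBp` is supplied by the caller (the summed length of
the read set): the survey unit is reads, not an assembly, and the
package does not second-guess it. Reads masked only by simple repeats
are not removed from the denominator; keeping the full surveyed bp
makes percentages comparable across masking runs.

Hits flagged as overlapped in the source file (`*`) are retained by the
parser and excluded only on request: parsing is kept free of policy.

## Diversity: the TE community as an ecological community

With proportions $P_i$ of TE mass per taxon, the package computes the
Shannon index $H' = -\sum_i P_i \ln P_i$ (natural log, reported in
nats, exactly as the formula is written) and the Gini-Simpson index
$D = 1 - \sum_i P_i^2$, the probability that two random draws are
different taxa. Both are label-invariant, and merging taxa can only
decrease them; the tests check the closed forms ($\ln k$ and $1 - 1/k$
for uniform communities), brute-force summation, a Monte-Carlo
interpretation of $D$, and agreement with `vegan::diversity()` as an
independent implementation.

Default proportions are bp-weighted and exclude mass not classified to
the requested level before renormalizing — the convention under which
cross-genome comparisons are parsed from masking summaries —
with `includeUnclassified = TRUE` available for sensitivity analysis.
A reported Gini-Simpson of exactly 1 in comparative tables is treated
as rounding: the index is bounded by $1 - 1/k$ and the package never
produces 1 for finite richness. For family-level diversity, where
short-read data cannot support evenness estimates, the 80%-identity
cluster count (`greedyCluster()`, below) serves as a richness-only
proxy.

## Divergence landscapes and the activity call

Each read is assigned the divergence of its *closest* (least divergent)
consensus hit, ties broken by higher score then input order, and the
per-superfamily divergences are binned into half-open 1% bins.
`classifyActivity()` then applies a deterministic decision procedure:

1. normalize the bins; smooth with a centered moving average of width
   `smoothWindow` (default 3 bins). Edges are reflected rather than
   zero-padded, so a genuine mode in the first bin — the signature of a
   monotonically decreasing, currently-amplifying superfamily — is not
   manufactured away (zero padding at the left edge systematically
   demotes bin 0);
2. `recent_fraction` is the raw mass below 1% divergence;
3. modes are local maxima of the smoothed profile exceeding 10% of its
   global maximum (plateaus collapse to their first bin);
4. shapes, in order: *monotonic decreasing* (no smoothed bin exceeds
   its predecessor by more than `1 + monoTol`, mode in bin 0);
   *unimodal* variants for a single mode — right-skewed if smoothed
   mass right of the mode exceeds the mass to its left, with a
   *recent-spike* suffix when the raw first bin is more than twice its
   smoothed value; J-shaped when the mode sits in the top decile of
   occupied bins with left-concentrated mass; otherwise inactive —
   and *bimodal recent* for two or more modes with one in the first
   two bins;
5. a superfamily is *active* iff `recent_fraction > recentThreshold`
   and its shape is in the active set. A single-mode profile without
   recent mass is always *unimodal inactive*.

`recentThreshold = 0.005` (0.5% of mass below 1% divergence)
operationalizes "presence of copies < 1% diverged" while remaining
robust to a handful of spurious low-divergence hits; no published
numeric floor exists, so the package fixes one and exposes it. The
smoothing window and the 10%-of-max mode prominence are likewise fixed,
exposed defaults standing in for by-eye shape classification. The
procedure is invariant to uniform rescaling of counts (tested), and
divergences are used exactly as reported by the masker — no
Kimura/CpG correction is applied or inferred; the parser stores the
per-hit column as-is and labels it raw.

`activitySummary()` assesses only superfamilies above a genome-fraction
floor (default 0.005% of the genome): below that, a 1%-binned histogram
has too little support for a shape call.

Exact per-superfamily shape labels on sparse data are *not* a promise
of this package: at desk scale a minor superfamily may be represented
by a dozen copies, each contributing a point mass to one bin, and the
shape call becomes an artifact of which copies were drawn. What is
promised — and tested on 200 seeded scenario-labeled landscapes with
hundreds of copies each — is the activity dichotomy at ≥ 95% accuracy.

## TT:I: deletion by ectopic recombination

An element model is a contig with terminal-repeat intervals and an
internal interval conservatively bounded by the first and last
recognizable TE protein domains; terminals overlapping the internal
interval are clipped. Terminal repeats are found by self-comparison of
the contig's two ends: exact 11-mer seeds, ungapped extension at
+1/−2 with an X-drop of 20, against the reverse complement of the tail
for inverted-repeat (DIRS/TIR-like) elements. Ungapped extension is
sufficient because terminal-repeat copies within one element are young
and nearly indel-free at the identity floor used (80%).

Depth over a region is summed alignment-overlap bp divided by region
length, so a read contributes fractionally to regions it partially
covers. This is the only depth convention under which an intact,
uniformly covered element gives TT:I exactly 1 — hit *counts* scaled by
region length would overweight regions shorter than a read — and reads
spanning a terminal/internal boundary contribute to both sides, which
is unbiased under uniform coverage. Both terminals pool into a single
"total terminal" class. Under uniform sampling from a population with
$s$ solo terminals per intact element, pooled terminal depth is
$(2+s)/2$ times internal depth, so $\mathrm{TT:I} = 1 + s/2$ and
`soloFractionEstimate()` inverts this as $\hat s = 2(\mathrm{TT:I}-1)$.

Alignment stringency is expressed as a minimum aligned length in bp
(default sweep 20, 30, 40, 50 bp): mapper score scales are
tool-specific, but the observable a score threshold manipulates is
alignment length. Discarding short alignments trims depth near region
edges, so TT:I drifts slightly below 1 at high stringency even without
deletion, and the effect is stronger for shorter terminals — the
mechanism behind stringency sensitivity differing between superfamilies
with 150 bp versus 744 bp terminals, which the tests reproduce on
synthetic populations. Inverted-repeat elements are handled identically
to direct-repeat elements at the depth stage (their structural
difference lives only in terminal finding); no correction is attempted
for partial internal deletion via internal complementary regions, and
every alignment record is treated independently (no paired-end
handling).

## Expression

Transcript categorization applies a TPM ≥ 0.01 floor, then a fixed
decision order: protein-TE hit **and** passing nucleotide hit →
conflict, filtered; TE hit of either kind + gene annotation → TE/gene
co-transcript; protein hit → autonomous TE; passing nucleotide hit
(strict 80 bp / 80% / 80% on overlap length, identity, and library-
contig coverage) → non-autonomous TE; gene annotation → gene; else
unknown. Transcriptome fractions divide by the TPM constant $10^6$ by
default (an observed-sum mode exists); per-superfamily sums take each
contig's best protein hit (lowest e-value, ties by input order).
Manual curation of spurious annotations is out of scope, but a
curation-override table can be applied after rule-based assignment.

The abundance–expression relationship is Pearson's $r$ between
log genome percentage and log summed TPM per superfamily, two-sided $p$
from the t transform, superfamilies absent or zero in either table
excluded and counted. Logs are base 10; $r$ is invariant to the base
(tested). The genome-percentage side defaults to the
excluding-unknown column. "In frame" for TE/gene co-transcripts is
defined operationally as same strand with a start offset divisible by
3, since no published operational definition exists.

## Family clustering

`greedyCluster()` sorts sequences longest-first (ties by id) and
assigns each to the first cluster whose representative it matches at
the threshold, else it founds a cluster — a deterministic, desk-scale
analogue of greedy identity clustering tools whose internal heuristics
are undocumented. Matching a specific external tool contig-for-contig
is a non-goal; recovering planted family structure is tested instead.
Identity comes from global alignment (match +1, mismatch −1, gap open
−5, gap extend −1) with the denominator restricted to columns where
the shorter sequence is aligned — a dialect choice approximating
short-vs-long comparisons in such tools; the alignment engine's scoring
is cross-checked against an affine-gap dynamic-programming oracle in
the tests.

## The synthetic generator

`simulateGenomeAndReads()` emulates a genome skim over a genome of
known TE content: i.i.d. background at a configurable GC, family
consensus sequences per superfamily, copies mutated by i.i.d.
substitutions at per-copy rates drawn from one of five scenario shapes
(recent burst: exponential mean 2%; past peak: normal(8%, 2%)
truncated at 0; inactive old: normal(15%, 2%); bimodal: an equal
mixture of the first two; monotonic: exponential mean 5%), inserted at
uniform non-overlapping positions, and sampled by error-free
fixed-length reads. `emitMaskRecords()` stands in for the masker using
the generator's own truth — deliberately, so stage logic is tested in
isolation from alignment heuristics. The default community
(`defaultCommunitySpec()`) mirrors a giant-genome landscape: two
dominant superfamilies near 30% and 21% of the genome over a tail of
minor ones, scenarios spread across all five shapes; the dominant
fractions follow the excluding-unknown percentages characteristic of
such genomes, and the two smallest entries are set to representative
values.

What the generator does *not* emulate: indels (substitution-only by
default, so truth divergence and reported divergence coincide; an
indel-free world also keeps copy lengths exact), sequencing error,
nested or fragmented insertions, target-site preference, and assembly.
Passing tests therefore demonstrate the correctness of the estimators
under clean sampling, not robustness to annotation noise in real data.

`simulateElementPopulation()` draws reads uniformly over intact copies
and solo terminals, each embedded in ample flanking sequence: read
starts fall on every position overlapping the copy and the alignment
records the overlap, as a local aligner would produce. This makes
coverage uniform across each copy before stringency filtering; the
minimum-alignment-length filter then induces the small edge-trimming
deficit discussed above (order $t^2/(2\,r\,\ell_T)$ for threshold $t$,
read length $r$, terminal length $\ell_T$ — about 0.8% per exposed
terminal edge at the defaults), which is part of the phenomenon being
modeled, not an artifact to remove.

`simulateExpression()` draws log TPM as a linear function of log genome
fraction plus Gaussian noise, rescaled to a configurable share of the
$10^6$ TPM total. With `noiseSd = NULL` the noise is calibrated from
the target correlation $r^\*$ via
$\sigma = |b|\,\mathrm{sd}(\log_{10} f)\sqrt{1/r^{*2} - 1}$; the default
$r^\* = 0.879$ is the coupling strength the generator is built to
emulate. `syntheticComposition()` supplies a deterministic 25-
superfamily abundance vector, log-uniformly spaced from 30.2% down to
0.005%, as the abundance side of these simulations; it is synthetic
and carries no empirical per-cell values beyond the dominant-
superfamily scale.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by choice: 1 Mb
genomes at 10× for end-to-end recovery (Shannon within 0.05 nats of
truth), 200 landscapes of 500–600 copies for classifier accuracy,
element populations of 30–40 copies at 20–30× over 20 seeds for TT:I
(mean within 3 SE of 1 under the null; solo load recovered within 15%),
100 seeded replicates for the expression coupling. All brute-force
oracle comparisons (per-base masking, per-base depth) are exact at
tolerance 1e-12 on fixtures of ≤ 10 kb. Every generator takes an
explicit integer seed and is byte-reproducible under it.

Degenerate inputs are defined errors, not silent results: zero-mass
landscapes, zero internal depth (undefined TT:I; the contig is skipped
and counted in sweeps), empty communities after unclassified-mass
removal, inverted percentage pairs in the unknown-repeat differential,
fewer than three paired superfamilies in the correlation.

## Known limitations

Shape labels on sparse landscapes are noisy (see above); TT:I carries a
stringency-dependent edge bias of order 1% at the default threshold and
is reported as-is; the greedy clustering is quadratic in the number of
sequences and intended for thousands, not millions; non-autonomous
superfamily attribution in expression summaries requires the
nucleotide-hit table to carry a superfamily column; and the pipeline
treats its inputs as already quality-controlled — it does not validate
that a hit table and a read set describe the same survey.
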