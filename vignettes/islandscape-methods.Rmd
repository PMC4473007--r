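---
title: "Methods: island calling and promoter signal analysis in islandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: island calling and promoter signal analysis in islandscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

islandscape analyzes a promoter-associated broad histone mark (the motivating
case is H3K4me3 in skeletal muscle) from aligned single-end ChIP-Seq reads in
two conditions. This vignette describes the statistical model behind each
stage, the parameters that matter, the design decisions taken where the
method leaves room, and what the synthetic benchmark does and does not show.

## Coordinates and data model

All coordinates are 0-based, half-open `[start, end)` intervals — the BED
convention — in every structure the package reads, writes or returns. The
TSS of a minus-strand gene is taken as its last covered base (`end - 1`).
Reads are `(chrom, start, strand)` records with a fixed length (default
25 bp); fragment extension is a downstream operation, not a property of the
read.

## Read filtering and window summarization

Reads flagged as multi-mapping are discarded; PCR duplicates are removed by
keeping one read per `(chrom, start, strand)` key (5'-position duplicates).
Surviving reads are extended to the estimated fragment length (default
190 bp): `[start, start + L)` on the plus strand, `[end - L, end)` on the
minus strand, clipped at chromosome bounds. Each extended fragment is then
counted once, into the non-overlapping 200 bp window containing its
*midpoint*. Midpoint assignment keeps the window counts an exact partition
of the fragments (each fragment contributes exactly 1 to exactly 1 window),
which the per-bp-coverage alternative would not; it is also what the
island-calling null model assumes. Tracks are normalized to reads per
million mapped reads, where the denominator is the post-filter unique read
count of the sample; normalizing twice is an error rather than a silent
re-scaling. We extend reads before both browser-track summarization and
island calling; `reads_to_track(extend = FALSE)` disables extension.

## Island calling

Window counts under pure background are modeled as iid Poisson with the
genome-average rate

$$\lambda = \frac{N \cdot W}{f \cdot G},$$

with $N$ summarized fragments, $W$ the window size, $G$ the genome length
and $f$ the effective (mappable) genome fraction (default 0.74, a common
mammalian value; set $f = 1$ for fully mappable synthetic genomes). A window
is *eligible* when its count reaches the smallest integer $c$ with
$P(\mathrm{Pois}(\lambda) \ge c) < p$ (default $p = 0.20$). Eligible windows
separated by at most `gap_size` bp of ineligible windows (default 400 bp =
2 windows) merge into one island; the reported span is trimmed to the first
and last eligible window. An island's read count sums *all* windows in its
span; its score sums, over eligible windows only,

$$s(k) = -\ln P(\mathrm{Pois}(\lambda) \ge k).$$

Significance is controlled by an E-value: the threshold $s^\*$ is the
smallest score such that the expected number of background islands scoring
$\ge s^\*$ over the whole genome is at most $E$ (default 100). The null
island-score distribution is computed exactly (up to discretization) by a
dynamic program: with $q = P(\text{window ineligible})$, single-eligible-window
score distribution $W(s)$, and gap factor
$\gamma = \sum_{j=0}^{g} q^j$ ($g$ = gap in windows), island score mass
solves $G = W + \gamma (W \ast G)$ and the expected count at score $s$ is
$L\, q^{2(g+1)} G(s)$ — an island must be flanked by more than $g$
ineligible windows on each side. Scores are discretized in steps of 0.1
score units (configurable); the convolution is truncated once the
expectation carried by longer islands is provably below both $10^{-9}$ and
$10^{-6} E$, and the truncation remainder is added back as an upper bound
before the threshold search, so ties and borderline bins resolve toward the
more conservative (higher) threshold. If the gap factor makes the recursion
non-convergent ($\gamma (1-q) \ge 1$) the caller stops with an explicit
error naming the cause. The model was validated against Monte-Carlo
simulation: on $10^5$ windows at $\lambda = 0.2$ the predicted total island
count matches simulation to within sampling error, and the number of
background islands passing $s^\*$ at $E = 100$ averages about 100, as the
definition requires.

Two-condition comparison declares an island "shared" when it overlaps any
island of the other condition by at least 1 bp; because one large island can
overlap several small ones, the shared counts of the two sides legitimately
differ. `shared + unique = total` holds on each side by construction.

## Annotation

Two gene-model sources are merged with RefSeq precedence: every RefSeq gene
is kept and an Ensembl gene is kept only if its gene body overlaps no RefSeq
gene on the same chromosome and strand ("annotated region" is operationalized
as any-overlap; the strand requirement is configurable). A gene is called
*enriched* when at least one island overlaps its promoter, defined as
TSS ± 2 kb — the definition attached to the gene lists that are interpreted
downstream; TSS ± 1 kb and the txStart − 5 kb … txEnd + 5 kb extended region
are available through `region_kind` because broad-mark studies use all
three for different purposes and no single choice serves them all.

Each island is classified by its *midpoint* into one of seven categories —
5' UTR, 3' UTR, exon, first intron, last intron, other intron, intergenic —
with precedence in that order when the midpoint touches several features or
genes. Midpoint classification makes the categories a partition (fractions
sum to exactly 1), which a span-based multi-count would break. A single
intron counts as "first". UTRs are the exonic portions outside the thick
(CDS) span; the synthetic annotation plants them as the terminal 10% of
each terminal exon. Distances from island midpoints to the nearest TSS are
signed in the gene's own orientation (negative = upstream); ties break
lexicographically by gene id.

## Expression

Probe-level values are averaged per gene on the provided log2 scale (not
after delogging, matching how log2 microarray values are treated in box
plots). Categories depend only on ranks: deciles split the ranked genes
into 10 groups whose sizes differ by at most one (ties broken by gene id,
so assignment is deterministic); the four-class scheme marks genes at or
below a silent floor as "silent" and splits the rest into equal tertiles.
The silent floor is never defined by the upstream literature; the default
for real tables is the 25th percentile, and synthetic runs use the
generator's known background floor. Both schemes are invariant under any
strictly monotone transform of the values.

## Profiles

Two layouts, both strand-oriented so column 1 is always the most-5' bin:

* `tss_fine`: 5 bp bins across TSS ± 2 kb (800 columns);
* `metagene`: five 1 kb upstream bins, twenty bins of 5% of the gene length
  each, five 1 kb downstream bins (30 columns). Genes with bodies shorter
  than 20 bp are excluded (degenerate bins); all others use fractional 5%
  bins directly.

Fragments are binned by midpoint, consistently with the window tracks.
Category curves divide the per-category column sums by (number of genes in
the category × total reads / 10^6), i.e. they are normalized to category
size and sequencing depth; the identity
`sum(curve) * n_genes * reads/1e6 = raw count` is tested. The clustering
matrix uses TSS ± 2 kb in 50 bp bins (80 columns) by default rather than
5 bp: 80 columns condition k-means far better at a few hundred genes, and a
flag restores the 5 bp layout. Genes shorter than 2 kb are excluded from
the promoter matrix. One wording conflict upstream (an "intergenic region
from 3000 to TTS" alongside a 5 kb flank) is resolved in favour of the 5 kb
flank; the flank bins of the metagene layout serve that role.

## Clustering

k-means with Euclidean distance on the normalized promoter matrix, *without*
per-row standardization: standardizing would erase the enrichment-magnitude
signal that separates the "no enrichment" cluster from the peaked ones,
which is exactly the biology the clustering is meant to expose. We run our
own Lloyd iterations because the contract requires k-means++ seeding, a
deterministic best-of-10-restarts under one seed, and empty-cluster repair
by reseeding from the farthest point (`stats::kmeans`'s Lloyd variant
errors on empty clusters); `stats::kmeans` is used as an independent
cross-check in the tests and recovers the same partitions on separated
data. k = 3 is the headline configuration, with k in 2…5 sweepable. Rows
are rendered sorted by cluster then by descending expression, with
five-number expression summaries per cluster.

## The synthetic generator

The generator emulates the statistical structure of a two-condition
promoter-mark study: non-overlapping gene loci with exon/intron structure
and planted UTRs on a small multi-chromosome genome; two annotation sources
sharing a configurable fraction of loci (same coordinates, different
identifiers) so the merging rule is exercised; a probe table with 1–3
probes per gene whose stored gene-level truth is the exact probe mean; and
reads composed of uniform background plus, for each active gene, a Poisson
number of reads (mean = `enrichment_reads_per_active_gene` × intensity)
whose midpoints follow a normal distribution truncated at ±`halfwidth`
(sd = halfwidth/2) around the TSS. With `expression_coupling = 1` the
intensity is a strictly increasing function of expression rank; at 0 it is
independent. PCR duplicates are exact copies of primary reads and primaries
are kept unique on the dedup key, so deduplication has exact ground truth.
Adjacent loci are separated by more than the enrichment halfwidth so each
planted interval contains exactly one active TSS. Planted read 5' starts
are placed so the read midpoint sits at the drawn offset; downstream
fragment extension shifts plus- and minus-strand fragment midpoints
symmetrically by ±(fragment − read)/2, preserving TSS-centred symmetry.

What the generator does *not* emulate: sequence content and mappability
structure, GC and amplification biases beyond uniform duplication,
overdispersed (non-Poisson) background, overlapping or isoform-rich gene
models, and array normalization artifacts. Benchmarks passing on this
generator therefore demonstrate the correctness of the algorithms under
their own model assumptions, not performance on real tissue ChIP-Seq.

Benchmark problem sizes were chosen at desk scale: the demo study uses two
2.5 Mb chromosomes, 300 genes and roughly 10^5 background reads per
condition; the null-calibration runs use 10^5 windows at lambda 0.2; the
recovery benchmark plants 50 sites at 20× background on 10 Mb; the coupling
benchmark uses 500 genes; the archetype benchmark 300 rows. Read depths per
sample are not published for the motivating study (only a combined unique
read total), so depths were set for realistic per-window background rates
rather than fidelity to an unknown.

## Numerical and degenerate-input policy

Normalizing an already-normalized track, a zero read total, a fragment
length below the read length, an unknown chromosome, probes mapped to
unknown genes, duplicate gene ids within one source, and k larger than the
row count are all explicit errors. An all-multimapping read set and an
empty expression category warn and return empty/zero results. bedGraph
export rounds to 4 decimals; in-memory values keep full precision. The
pipeline driver validates all input paths before any stage runs, caches
each stage's outputs, recomputes a stage when its outputs are missing or
any upstream stage was recomputed, and records md5 checksums in a JSON
manifest so reruns are verifiably identical.
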