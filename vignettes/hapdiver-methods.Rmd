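---
title: "Methods: amplicon haplotype diversity with hapdiver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon haplotype diversity with hapdiver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapdiver)
```

`hapdiver` analyses nucleotide diversity of one resequenced amplicon across
a panel of inbred accessions, with the barley *HvCKX2.1* gene (a 1321-nt
amplicon, nine biallelic SNPs, 444 wild and landrace accessions) as its
worked system. This vignette records the models the package implements, the
parameters that matter, the numerical conventions, and what the synthetic
data do and do not establish.

## Variant calling

The data are one consensus sequence per accession, not reads, so "coverage"
at an alignment column is the number of accessions carrying an unambiguous
A/C/G/T there; `N`, every IUPAC ambiguity code and gaps count as no-calls.
This matches a selfing species panel, where Sanger heterozygote or quality
ambiguity is best collapsed to "no call" rather than phased.

The error model is a symmetric per-base miscall probability `errorRate`
(default 0.01, dimensionless). For a biallelic column with coverage $c$ and
minor-allele count $k$, the variant p-value is the one-sided binomial tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Bin}(c, e),$$

the probability that error alone produces at least $k$ minor calls. Columns
are tiered by the most stringent thresholds passed:

* high: $p \le 10^{-9}$ and coverage $\ge 393/444 \approx 88.5\%$ of the
  panel (the study's settings for its six high-confidence SNPs);
* medium (defaults, exposed as configuration): $p \le 10^{-4}$ and coverage
  $\ge 75\%$. Commercial callers do not publish their variant p-value
  formula, so the binomial tail is used as the standard conservative
  surrogate; only the threshold *semantics* are fixed, the values are
  arguments of `callThresholds()`. Coverage thresholds below 1 are read as
  panel fractions, which keeps settings meaningful across panel sizes.

Columns with more than two segregating bases are reported `rejected` with a
`multiallelic` flag and are never promoted to the SNP panel, which is
strictly biallelic by construction. Ties between allele counts are broken
alphabetically, making calls invariant under accession permutation.

## Haplotypes and partial-data resolution

A haplotype is the ordered allele vector over the panel positions
(coordinates are 1-based and inclusive on the amplicon). Only accessions
with a call at *every* panel position enter the haplotype table; counts are
stratified wild/landrace. Partial accessions are never counted, imputed or
networked — they are reported separately by `extendPartial()`, which labels
an accession `partial-resolvable` when at least one catalogued haplotype
agrees with it at all observed positions and `partial-novel` otherwise
(novel completions are not enumerated). Labels are assigned in descending
total count with lexicographic allele-vector tie-breaks; because singleton
ordering is otherwise arbitrary, `buildHaplotypeTable()` accepts a
reference table whose labels are adopted for matching vectors, so rebuilt
tables can be compared label-for-label against the shipped catalogue.

## Gene model and protein effects

The gene model is a single-intron coordinate system: `cdsStart` (the A of
the initiation ATG), an intron interval, and candidate alternative starts.
`fitGeneModel()` recovers it by exhaustive search from codon-level SNP
annotations: an exon-1 row (position, codon $c$, position-in-codon $q$)
requires $\mathrm{pos} = s + 3(c-1) + (q-1)$; exon-2 rows add the intron
length $I$. The search demands a unique $(s, I)$ — for the shipped
annotations $s = 127$ and $I = 98$ nt. Only $I$ is identifiable from
annotations, not the splice coordinates; the intron is therefore placed
immediately after the last annotated exon-1 codon (position 709), a choice
that cannot affect any annotated SNP's codon assignment. Codon variants are
built by substituting each allele into the reference codon and translated
under the standard genetic code (nuclear gene); a SNP is synonymous iff
both codons translate identically.

Initiation-codon arbitration (`resolveStart()`) follows orthologue
conservation: an upstream in-frame ATG is accepted only if the orthologue's
aligned upstream region carries an ATG at exactly those columns; otherwise
the downstream start is kept. The rejected candidate is returned as an
alternative `GeneModel` so its would-be effects can be tabulated — under
the upstream start of the shipped system the protein gains
$(127-52)/3 = 25$ N-terminal residues and the two promoter-proximal SNPs
become second-position coding changes (leu/pro, lys/arg).

Protein variants are equivalence classes of haplotypes sharing residues at
the non-synonymous positions, ordered by ascending protein position;
variant letters run A, B, C, … in descending total count.

## Median-joining networks

`minimumSpanningNetwork()` computes the $\varepsilon$-relaxed MSN: edge
$(u,v)$ is kept iff $d(u,v) \le \lambda(u,v) + \varepsilon$, where $d$ is
Hamming distance (all positions weighted equally; no weighting is needed
for a small panel of point substitutions) and $\lambda$ is the
single-linkage merge level, computed as the maximum edge on the MST path.
$\varepsilon = 0$ (the default, matching the classical program default)
gives the union of all MSTs. Construction is deterministic: Kruskal with
edges ordered by (weight, lexicographic endpoint vectors).

`medianJoining()` augments the node set: for each pair of edges sharing a
node, the positionwise majority (median) vector of the three endpoints is a
candidate Steiner point (ties — three distinct bases at a position — fall
back to the pivot node's base; with biallelic panels ties cannot occur).
Candidates are added greedily, one per round, whenever they *strictly*
reduce the total minimum-spanning cost of the node set, until a fixpoint;
a cap (`maxIter`, default 50) turns pathological non-convergence into a
diagnostic error. Median nodes of degree below three lying on no shortest
path between observed nodes are pruned; under strict-improvement addition
such nodes essentially never arise, so the network's inferred nodes are
genuine branch points. Median nodes carry count 0 and a `median` flag in
GML/CSV exports.

On panels of up to 4 haplotypes and 5 binary sites the test suite compares
the final spanning cost against an exhaustive Steiner oracle (all candidate
vector subsets of size ≤ 2, which is sufficient because a Steiner minimal
tree on $k$ terminals needs at most $k-2$ degree-3 Steiner points and
degree-2 points never reduce cost in a metric space).

## Inferential statistics

The sampling-bias null treats landrace sampling as binomial with
replacement at the wild frequency $f$: $P(\text{absent}) = (1-f)^n$,
evaluated as $\exp(n \log(1-f))$ so that values near $10^{-31}$ do not
underflow; the log-space and direct products agree to 12 significant digits
wherever the direct product is representable. The general tail
$P(X \le k)$ is exposed through the same function. For the shipped
catalogue, $f = 51/172 = 29.65\%$ and $n = 200$ give $2.84\times10^{-31}$
when the frequency enters at its quoted 2-decimal-percentage precision
($2.83\times10^{-31}$ at full precision — identical at the two significant
figures that matter).

The haplotype-by-phenotype test is the plain Pearson $\chi^2$ with
$(r-1)(c-1)$ degrees of freedom and no continuity correction by default
(the correction applies only to 2×2 tables and is non-default in the
field's software; a flag enables it), with an optional seeded Monte-Carlo
p-value. Under a simulated independence null (10⁴ multinomial 2×2 tables,
all expected cells ≥ 100) the empirical type-I error at $\alpha = 0.05$
falls within [0.04, 0.06] in the test suite.

## Climate envelopes

`monthlySummary()` reports per-haplotype monthly precipitation means with
$\mathrm{se} = \mathrm{sd}/\sqrt{n}$; an $n=1$ group gets se 0 with an
explicit flag rather than disappearing from plots. `bimonthlyAggregate()`
sums the six two-month windows Oct/Nov … Aug/Sep, pairing validated as an
exact partition of the year.

PCA is an eigendecomposition of the covariance matrix of column-centred
data — covariance, not correlation, because all twelve variables share
units (mm); `scale. = TRUE` switches to correlation. Component signs are
fixed so each component's largest-magnitude loading is positive, making
score orientations reproducible. The 95% ellipse of a group's 2-D scores
uses the sample mean and covariance with Mahalanobis radius²
$= \chi^2_{0.95}(2)$; its Monte-Carlo coverage on 10⁵ Gaussian points is
0.95 ± 0.01 in the test suite. WorldClim raster extraction is deliberately
not implemented — the module consumes a pre-joined CSV of (accession, 12
monthly values), keeping the package free of downloads; published variance
fractions for the real collection sites (67.8%/25.3%) are therefore not
reproducible here and are documented as non-targets.

## The synthetic generator: what it emulates, and what it does not

`simulationConfig()` defaults encode the study conditions: 444 accessions;
the fourteen catalogued haplotypes at their observed frequencies
(232, 54, 51, …)/372; each haplotype's observed wild/landrace split; a
1321-nt amplicon with the consensus allele at every panel position; miscall
rate 0.001 per base (an optimistic Sanger consensus error rate, applied to
panel and off-panel columns alike so the caller's error model is exercised
everywhere); missing rate 0.02 per SNP site per accession, calibrated so
that about one accession in six has at least one no-call over nine sites,
the proportion of incomplete haplotypes in the study (72/444); a
winter-wet, summer-dry monthly precipitation base (62, 55, 48, 30, 12, 3,
1, 1, 4, 22, 44, 60 mm, sd 10 mm) typical of the Fertile Crescent; and a
+30 mm November–February shift linked to haplotype 3, the seasonal pattern
reported for that haplotype's collection sites. Growth habit is drawn
independently of haplotype (a true null), and coordinates are uniform in a
Fertile-Crescent bounding box.

The generated reference plants a deterministic gene context (both candidate
ATGs, the coding-SNP codon contexts, GT..AG intron ends, no spurious
in-frame upstream ATG or in-frame stop between the starts) so codon
annotation on synthetic panels reproduces the real amino-acid effects; the
rest of the sequence is uniform random and makes no claim to realism.

Not simulated: chromatogram traces, indels and alignment gaps,
recombination, heterozygosity, read redundancy (one consensus per
accession is assumed), spatial autocorrelation of climate, and any
haplotype–phenotype association. Passing tests therefore show that the
pipeline recovers planted truth under binomial noise on a gap-free
alignment — not that it is robust to misalignment or structural variation.

All stochastic functions take an explicit integer seed and restore the
caller's RNG state; no hidden global state is used.

## Problem sizes and determinism

The test suite works at the study's own scale where that is cheap (444
accessions × 1321 nt panels; 5000 accessions for frequency convergence)
and at reduced scale where an exhaustive oracle is the point (Steiner
comparisons on ≤ 4 haplotypes × ≤ 5 sites; binomial-sum p-value checks at
coverage ≤ 50; 10⁴ null tables for the χ² size; 10⁵ points for ellipse
coverage; 200 random panels for network structure). All seeds are fixed in
the tests; every generator call is bit-reproducible for a given seed.

## Known limitations

* The variant p-value is a surrogate for the unpublished formula of the
  commercial caller the field uses; tier membership near the thresholds
  may differ from that program's output.
* Median-joining uses greedy strict-improvement Steiner augmentation; on
  large panels it inherits the usual heuristic character of the algorithm
  family and is validated exhaustively only at small scale.
* The intron's internal coordinates (beyond its length and its placement
  after the last annotated exon-1 codon) are not identifiable from codon
  annotations; supply exact splice coordinates to `GeneModel()` if known.
* Partial haplotypes are classified, not imputed; no LD or phasing
  machinery is included.
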