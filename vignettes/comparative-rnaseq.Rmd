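---
title: "Reference-free comparative RNA-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free comparative RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoexpress)
```

## The problem

Many species of biological interest — the axolotl and its regenerating limb
blastema being the motivating example — have no sequenced genome. RNA-seq in
such a species starts from a de novo transcriptome assembly: a large set of
contigs that are fragmentary, redundant, and unannotated. xenoexpress
implements a comparative strategy: reads are quantified against the contigs
upstream (by an EM-based quantifier such as RSEM, consumed here as an
expected-count matrix), contigs are assigned to the gene set of a
well-annotated *anchor* species (human, in the motivating study) by best
BLAST hit, and all downstream analysis — normalization, differential
expression, enrichment, clustering — is performed on anchor-gene-level
counts. In effect, the contigs are treated as fragmentary "isoforms" of the
anchor genes.

## Homology mapping

Contigs are aligned upstream against anchor transcripts (nucleotide search)
and anchor proteins (protein search); the package consumes standard
12-column tabular output. Per contig and search, the best hit is the
minimum e-value below a threshold (default `1e-5`); exact e-value ties go to
the hit listed first in the file. When the two searches qualify a contig to
different genes, the lower e-value wins and an exact cross-search tie goes
to the nucleotide search — nucleotide-level identity is the stronger
orthology claim for transcript quantification. This arbitration is a design
choice of this package (the two searches could be combined in other ways);
affected contigs are reported. Contigs whose best target is on a
user-supplied rRNA accession list are flagged and excluded, and abundances
are renormalized without them.

The mapped entries, the rRNA-flagged set and the unmapped set always
partition the contig universe (all ids in the assembly FASTA); ids present
in the counts but not in the universe are a hard error, guarding against
mismatched inputs.

## Quantification

Gene counts are plain sums of the expected counts of the gene's mapped,
non-rRNA contigs. Counts stay fractional here; rounding happens only at the
test boundary. TPM uses gene-level effective lengths: the sum over member
contigs of (contig length − read length), the number of distinct read start
positions. Contigs shorter than the read would get a non-positive effective
length, so the per-contig value is floored at 1 (real assemblies contain
such contigs; each is logged). Per sample, count/length rates are rescaled
to sum to one million; an all-zero sample stays all-zero rather than
producing NaN. The read length is an explicit argument (default 76 nt in the
pipeline configuration) — it cannot be inferred from a count matrix.

A parallel contig-level path (no aggregation, per-contig effective lengths)
exists for the method comparison below.

## Differential expression without replicates

The time course has one library per time point, so biological variation is
estimated from consecutive time-point pairs: transcription changes between
neighboring samples are small relative to biological noise, so treating a
consecutive pair as pseudo-replicates yields a conservative dispersion
estimate. Counts follow a negative binomial with variance
$\mu + \phi\mu^2$; a single common dispersion $\phi$ is shared by all genes.

For each consecutive pair, columns are scaled to the geometric mean of their
library sizes and rounded half-to-even (exact conditional enumeration needs
integers; the upstream expected counts are fractional, and rounding at this
boundary is a documented choice). The pair's $\phi$ maximizes the summed
per-gene log conditional likelihood of the observed split $(y_1, y_2)$ given
the total $t = y_1 + y_2$, where both counts are NB with mean $t/2$ and
dispersion $\phi$. The conditional normalizer uses the NB convolution
identity $\sum_k f(k;r) f(t-k;r) = f(t;2r)$, so no numerical summation is
involved; the maximization runs over $\delta = \phi/(1+\phi) \in [0,1)$ with
an explicit check of the Poisson boundary $\phi = 0$. The common dispersion
is the median of the per-pair values; for an even number of pairs the lower
median is taken (deterministic, no interpolation). Pairs with fewer than 10
informative genes flag the estimate as unstable.

Each non-control time point is then tested against the control: conditional
on $t$, the null probability of a split is
$P(k) \propto f(k)\,f(t-k)$, and the two-sided p-value sums $P(k)$ over all
$k$ with $P(k) \le P(y_1)$. At $\phi = 0$ this reduces to a binomial
$(t, 1/2)$ split; $t = 0$ gives $p = 1$ by convention. This is the classic
conditional exact NB test implemented directly rather than through edgeR:
edgeR's quantile-adjusted pseudo-counts differ in detail, and the package
asserts correctness against its own brute-force enumeration oracle, not
against edgeR. Benjamini–Hochberg adjustment is applied within each time
point separately (matching per-time-point DE lists), genes with FDR < 0.05
are called DE, and the union over time points forms the whole-time-course
set. Log2 fold changes use a 0.5 offset on equalized counts to avoid
infinities; the offset choice is visible in the API documentation.

Two open choices were resolved as follows: library sizes are equalized by
column sums only (no TMM-style factor), and expected counts are rounded at
the test boundary. Both are stated in the function documentation.

### Why gene-level aggregation gains power

When a gene's expected count $\mu$ is split over $m$ contigs with weights
$w_i$, each contig count is NB$(w_i\mu, \phi)$ and their sum has variance
$\mu + \phi\mu^2\sum_i w_i^2 < \mu + \phi\mu^2$: aggregated counts are
relatively less overdispersed, so the gene-level path estimates a smaller
common dispersion and detects at least as many true effects. The acceptance
suite reproduces exactly this ordering on fragmented synthetic data, and the
`compare_de_levels()` report exposes the shared/unique DE sets and the
2×2 reference-gene comparison table for the corresponding Fisher test.

## Assembly completeness

For a read, let AL/UN denote aligned/unaligned against the assembly, A that
it is truly from the organism, B that it has a protein-search hit, and HQ a
mean phred score ≥ 38. Under three assumptions — aligned reads are all from
the organism, non-organism reads never have hits, and hit probability given
A and HQ is independent of alignment — the organism fraction among unaligned
reads is the hit-rate ratio
$P(A \mid UN) = P(B \mid UN, HQ)\,/\,P(B \mid AL, HQ)$, and the overall
unalignable-organism fraction is $P(UN) \cdot P(A \mid UN)$. Only the
highest-quality reads enter the hit rates so that alignability is not
confounded with read quality, while $P(UN)$ is computed over all reads.
False-positive hits among artifact reads inflate the numerator, so the
estimate is conservative (an over-estimate of what is missing); the test
suite asserts this direction by deliberately violating the assumption in
simulation. Ratios above 1 (possible under sampling noise) are clipped with
a warning. Proteome representation is $|AL|/|AL \cup UN|$ over the sets of
distinct proteins hit. Whole-percent reporting truncates toward zero,
matching the presentation convention of the estimator's published inputs
(4/17 reports as 23, not 24).

## Gene-set enrichment

All enrichment runs through one exact 2×2 Fisher computation (hypergeometric
point-probability rule for the two-sided test, upper tail for one-sided).
Per-time-point set enrichment tests the upregulated DE genes at each time
point against a background of anchor genes with a qualifying best hit and at
least one mapped read; these tests default to one-sided (greater), since the
question is enrichment. The grouped early-vs-late test compares in-set
fractions between the unions of upregulated genes over the two label groups
and defaults to two-sided (identical group queries then give exactly
$p = 1$). Degenerate tables — an empty margin, where no association is
possible — return $p = 1$ and odds ratio 1 rather than NaN. The
term-enrichment matrix applies, per time point, a one-sided Fisher test per
term with a minimum-overlap filter (default 2) and an optional EASE variant
(one gene removed from the overlap cell — uniformly conservative), adjusts
BH across terms, keeps terms reaching FDR < 0.01 at any time point, and
returns $-\log_{10}(\mathrm{FDR})$ for heat-map clustering.

## Clustering with bootstrap support

Samples are clustered by UPGMA (average linkage, via `stats::hclust`) on the
uncentered Pearson distance
$1 - \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$ — appropriate for log
fold-change profiles, which are centered at zero by construction; the
centered Pearson variant serves all-non-negative matrices such as the
term-enrichment heat-map input.

Edge support resamples features (genes) and re-clusters the samples.
BP is the ordinary bootstrap proportion at scale 1. The approximately
unbiased (AU) value comes from multiscale resampling: ten relative sizes
equally spaced in $[0.6, 1.4]$ of the feature count (the spacing within the
stated range, and the equal allocation of the bootstrap budget across
scales, are this package's documented defaults), probit-transformed
per-scale proportions $z_r = \Phi^{-1}(1 - \mathrm{bp}_r)$, a weighted
least-squares fit $z_r \approx v\sqrt{r} + c/\sqrt{r}$ with weights from the
binomial variance of $\mathrm{bp}_r$ propagated through the probit, and
$\mathrm{AU} = 1 - \Phi(v - c)$. Proportions are clipped to
$[1/(B{+}1),\, 1 - 1/(B{+}1)]$ before the transform; an edge present (or
absent) in every resample at every scale gets AU 1 (or 0) directly and is
flagged as unfitted. AU ≥ BP is not a theorem and is not asserted anywhere.
The Newick export labels internal nodes `au-bp` (dash separator, since the
colon is reserved Newick syntax).

## ORF analysis

The coding-potential analysis scans all six frames. An ORF is ATG-initiated
and terminated by the first in-frame stop (stop included in the length); an
ATG-initiated run reaching the sequence end also qualifies. ATG initiation
is the default because stop-to-stop runs inflate the null; a `stop2stop`
mode is provided. N never completes a start or stop codon. Coordinates are
0-based half-open on the forward strand. The null model shuffles each
sequence by uniform mononucleotide permutation — composition is preserved
exactly while coding structure is destroyed. The implementation is verified
against an independent brute-force per-codon state machine on seeded random
sequences, and reverse-complement symmetry of the ORF length is asserted as
a property.

## qPCR concordance

RNA-seq ratios are $\log_2((\mathrm{TPM}_x + 1)/(\mathrm{TPM}_0 + 1))$; the
+1 guards zeros and deflates ratios of two tiny values. For qPCR, two
conventions are implemented because they are both in circulation and differ
numerically: the ratio of raw ΔCT values
($\log_2(\Delta CT_x/\Delta CT_0)$, zeros replaced by 0.1 before division)
and the standard comparative-CT exponent $-\Delta\Delta CT$. The ratio
convention is the default; the flag switches. Replicate CTs are averaged
per gene and sample before ΔCT (aggregation order is a documented choice).
Undetected control samples carry CT = 40 by convention. The shift-left
alignment drops the day-3 qPCR point and pairs RNA-seq days 3–21 with qPCR
days 5–28 (qPCR animals were larger and regenerate more slowly), yielding
exactly 10 pairs from 11 non-control points; it is optional and off for
synthetic data, which has no lag. Concordance reports both Pearson r and
r², per gene and averaged.

## The synthetic-data generator

Every input format has a seeded generator, so the whole pipeline is testable
without external data:

* **Anchor + contigs** — transcripts carry planted ORFs (5' UTR, ATG +
  non-stop codons + stop, 3' UTR) so contig ORF statistics behave like real
  coding sequence; contigs are substrings, optionally fragmented (2–3
  pieces) and point-mutated; orphan contigs are mononucleotide-shuffled real
  sequence, so their ORF statistics match the shuffled null by construction
  and they have no anchor homolog.
* **Counts** — gene mean × $2^{\mathrm{logFC}}$ × library factor,
  partitioned over member contigs by per-gene Dirichlet(1, …, 1) weights
  drawn once and stored in the truth, each contig drawn NB$(\cdot, \phi)$.
  Defaults: 12 canonical time points with the control first, 5% early-burst
  genes (up at 3 h–1 d), 5% late-peak genes (up at 7–14 d), amplitude 3
  log2 units, $\phi = 0.05$, log-normal baselines around 100 counts. These
  defaults are the study conditions the tests run under.
* **BLAST rows** — true hits with e-values log-uniform in
  $[10^{-50}, 10^{-6}]$, decoys log-uniform in $[10^{-4}, 1]$; only the
  $10^{-5}$ threshold matters downstream.
* **Read provenance** — satisfies the three completeness assumptions by
  construction, with a switchable violation used to test conservativeness.
* **qPCR CTs** — ΔCT encodes the true fold change under the comparative-CT
  convention plus Gaussian noise.

What the generator does *not* emulate: read-level sequencing error,
multi-mapping ambiguity in the upstream quantifier (expected counts are
drawn directly), amplification bias, and correlated gene programs beyond
the two planted ones. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to every
artifact of real libraries.

## Problem sizes and numerical choices

The test suite runs the statistical guarantees at reduced, stated sizes
chosen to keep Monte-Carlo error well inside the asserted bands: dispersion
recovery on 20 runs of 2000 genes × 12 samples; null FDR control on 20 runs
of 1000 genes; the power comparison on 20 runs of 300 fully fragmented
genes; AU calibration on 20 planted two-cluster matrices (60 features × 10
samples) at 1000 bootstrap draws; ORF oracle equivalence on 1000 random
sequences of 30–3000 nt. The exact-test oracle equivalence covers every
total up to 50 at $\phi \in \{0, 0.05, 0.5\}$ to $10^{-12}$. The
end-to-end pipeline default uses 300 genes and completes in seconds.

Numerical conventions collected in one place: half-to-even rounding at the
test boundary; p-value tie comparison with a $1 + 10^{-10}$ relative guard
(and $1 + 10^{-7}$ in the Fisher test, matching common practice); the
conditional pmf renormalized by its numeric sum so a perfectly balanced
split returns exactly 1; effective-length floor 1; logFC offset 0.5; lower
median for even pair counts; whole-percent truncation; AU proportion
clipping at $1/(B+1)$.

## Known limitations

* Best-hit assignment is winner-takes-all; reciprocal-best-hit orthology and
  multi-gene ambiguity splitting are out of scope.
* The common dispersion is a single global value — no tagwise or trended
  estimation; consecutive-pair estimates absorb real between-time-point
  signal and are therefore biased upward for strongly changing genes, which
  the median across pairs only partially suppresses.
* Completeness estimates inherit the three stated independence assumptions;
  the package quantifies the direction but not the size of their violation.
* AU values are asymptotic approximations; at small feature counts they are
  noisy, and the per-edge fit is skipped (with a flag) whenever a
  proportion saturates.
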