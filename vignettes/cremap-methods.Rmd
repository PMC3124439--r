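---
title: "Mapping a carbon catabolite regulator's targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a carbon catabolite regulator's targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cremap)
```

# The problem

Carbon catabolite repression (CCR) lets a fungus assimilate preferred carbon
sources first: when glucose is available, the C2H2 zinc-finger repressor
CreA/CRE1 shuts down genes for the catabolism of alternative substrates,
binding promoters at the degenerate consensus 5'-SYGGRG-3' (S = G/C,
Y = C/T, R = A/G), with functional repression thought to require two closely
spaced sites. `cremap` implements a complete, testable pipeline for mapping
such a regulator's target range from two-channel expression microarrays of
chemostat cultures: wild-type versus regulator-knockout strains grown at a
repressing (D = 0.07 h^-1^) and a derepressing (D = 0.025 h^-1^) dilution
rate, compared pairwise in four hybridized contrasts, each as two dye-swap
biological replicates on a multi-probe-per-transcript array.

Every stage consumes and produces plain TSV/FASTA files, and a synthetic-data
generator with planted ground truth makes the full cascade verifiable
without any external download.

# Array pretreatment

Per hybridization (`preprocess_array()`):

1. **Background threshold.** Spots the gridding software could not locate
   ("not found") carry only background signal. The detectability threshold
   is their mean intensity plus two sample standard deviations (n−1
   denominator; the SD of a single value is defined as 0). Per-channel
   means of flagged spots are pooled across both channels. An input with no
   "not found" spots is an error, not a silent zero threshold.
2. **Filtering.** Flagged spots and saturating spots (either channel at or
   above the scanner ceiling, default 2^16^−1; the ceiling is configurable
   because "saturating" has no universal definition) are discarded before
   normalization.
3. **Normalization.** Global intensity-dependent (lowess) normalization of
   M = log2(ch1/ch2) on A = ½·log2(ch1·ch2), with *no background
   subtraction* at any point. We use a locally weighted linear fit with
   span 0.3 and the symmetric (Tukey biweight) robustness family; residuals
   M − trend(A) are the normalized log-ratios. Residual bias after removing
   a synthetic intensity-dependent trend is below 0.05 per intensity decile
   (tested).
4. **Detectability and aggregation.** A spot is "detectable" when its raw
   intensities exceed the background threshold. By default **both**
   channels must exceed it — a ratio needs signal in both; the
   more permissive either-channel rule is available via
   `detect_channels = "either"`. The transcript log2 ratio is the
   unweighted mean of normalized M over detectable probes lying inside the
   coding sequence on the matching strand; transcripts with fewer than two
   qualifying probes are discarded.

Dye-swap replicates exchange fluorophore assignments, so the raw ratio sign
flips between orientations; orientation signs (+1/−1) are carried alongside
the replicate tables and applied during model fitting. At zero noise this
correction is exact (tested to 1e−12).

# Moderated differential expression

For each of the four comparisons independently, `fit_moderated()` fits a
one-sample model per transcript across the orientation-corrected replicate
ratios and shrinks the residual variances by empirical Bayes. The prior
(d~0~, s~0~²) of the scaled inverse chi-square variance distribution is
estimated by matching the mean and variance of log s² — the excess of the
observed spread over the sampling value trigamma(d/2) identifies d~0~ via
Newton inversion of the trigamma function, and the scale follows from the
mean. When the observed spread does not exceed the sampling component the
prior degenerates to a point mass (d~0~ = ∞) with scale equal to the mean
variance. The moderated statistic mean/(s̃/√n) with
s̃² = (d~0~s~0~² + d·s²)/(d~0~ + d) is referred to a t distribution on
d~0~ + d degrees of freedom. The implementation is checked in its limits
(d~0~ = 0 recovers the ordinary t-test; d~0~ = ∞ the pooled-variance
statistic), against an independent reference empirical-Bayes
implementation, and for type-I error control on 2,000 null transcripts.

`select_regulated()` applies the two published cutoffs jointly: BH-adjusted
p < 0.05 **and** |log2 ratio| > 2 in at least one comparison, with an
exclusion list (the deleted regulator gene itself is a trivial hit in such
designs). The output is the regulated-gene set and its gene × 4 profile
matrix; a transcript discarded by the detectability rules in one comparison
contributes a 0 there, keeping profiles finite.

# The cluster-assignment cascade

Regulated genes are assigned to behaviour clusters A–H plus a heterogeneous
remainder X in three stages (`assign_clusters()`):

1. **Template matching.** Each seed group (a user-supplied, biologically
   curated set of genes exemplifying one behaviour) defines a template
   profile (its mean). The correlation threshold R\* is fixed
   automatically at the largest value that still retrieves *every* seed
   gene; all genes at or above R\* join the group. A gene retrieved by
   several templates goes to the best-correlated one. Because the published
   description ("absolute R threshold") is ambiguous, both absolute-|r| and
   signed-r retrieval are implemented; absolute is the default.
2. **CAST.** Genes left unassigned are clustered by the Clustering
   Affinity Search Technique with Pearson-correlation affinity and
   threshold 0.8: grow a cluster by adding the highest-affinity gene while
   its mean affinity to the members is ≥ 0.8, remove members whose
   affinity drops below, iterate to stability, close, repeat. Tie-breaks
   (highest affinity, then lexicographic gene id) make the partition
   independent of input order (tested by permutation).
3. **Merge and pool.** A CAST cluster whose mean profile correlates with a
   template at or above that group's R\* is absorbed; remaining clusters
   pool into X. Finally each group is split in two by average-linkage
   hierarchical clustering on Euclidean distance, cut at the root's two
   children; the sub-split is recorded as a sublabel (`E.1`/`E.2`) rather
   than as new top-level labels.

Two design points deserve emphasis:

* **Correlation identifiability.** With four comparisons (within-strain
  growth-rate contrasts and within-growth-rate strain contrasts), a purely
  growth-rate-regulated profile (m, m, 0, 0) and a purely
  knockout-regulated profile (0, 0, m, m) are *collinear after centering*:
  Pearson correlation cannot distinguish them, and mirrored behaviour pairs
  are anticorrelated, which the absolute-|r| rule also conflates. The
  synthetic generator therefore plants its nine behaviour classes on an
  orthogonal contrast basis (pairwise |r| ≤ 0.58), and the demonstration
  pipeline uses signed-r matching. Real analyses with behaviour classes of
  both signs should do the same.
* **Seed-group size.** R\* is the minimum seed correlation, so tiny seed
  groups drawn from the densest part of a class set R\* too high and
  exclude legitimate members. The demonstration pipeline takes 8 seed
  genes per class, emulating the sizeable curated behaviour groups a
  scientist would assemble; the seed file is an explicit input
  (`read_seed_file()`) because seed choice is a scientific judgement, not
  an algorithmic one.

`report_accounting()` turns an assignment into the derived sums used when
summarizing such a regulon: regulator-repressed (C+E+G+H),
regulator-induced (D+F), growth-rate-only (A+B), the X remainder, and the
total attributed to the regulator (total − growth-rate-only), each as a
percentage rounded to one decimal. On the published cluster sizes
(`published_cluster_sizes()`: 250 genes over A–H with X by subtraction)
this reproduces the printed identities 118 repressed, 207
regulator-dependent, 43 (17.2%) growth-rate-only.

# Promoter motif analysis

* **Retrieval** (`retrieve_promoters()`): the 1,000 bases (coordinates
  −1000..−1) immediately 5' of the coding start, strand-aware, truncated
  with a warning at contig edges. Upstream ORFs are *not* clipped — our
  reading of running the retrieval with ORF-clipping off; clipping, if
  wanted, can be emulated by editing the coordinate table.
* **Scanning** (`scan_pattern()`): left-to-right greedy non-overlapping
  IUPAC matching — a match consumes its bases and the scan resumes after
  them. `N` in a sequence matches nothing. Only the given strand is
  scanned; reverse-strand sites are counted by scanning the explicit
  reverse-complement pattern (CYCCRS for SYGGRG), which keeps the two
  strands' counts separately reportable. The scanner is property-tested
  against a brute-force window oracle on 1,000 random 200-mers.
* **Dyads** (`scan_dyad()`): ordered pairs of component matches with a gap
  (end of first to start of second, inclusive of 0 — the anchor is
  configurable to start-to-start) of at most 20 or 50 bp; every qualifying
  ordered pair counts once, verified against exhaustive pair enumeration.
  Overlapping first/second components never pair (gap ≥ 0).
* **Enrichment** (`cluster_enrichment()`): the cluster's mean sites/gene is
  normalized to the whole-genome mean and reported as a percent deviation,
  (cluster/genome − 1)·100 — the only reading consistent with
  "normalized to the genome average" that reproduces entries like +23%.
  Significance is a two-sided Welch t-test of per-gene counts, cluster
  versus the whole genome (including the cluster, as the normalization
  implies; excluding it is a switch), starred at p < 0.1 and p < 0.05. The
  test's null calibration is verified at 5% ± 1% over 10,000 random draws.
* **De novo discovery** (`discover_motifs()`, `discover_dyads()`): every
  exact word of lengths 5–8 (or spaced trinucleotide pair, spacer 0–20) is
  scored as −log10 of the binomial upper tail of its per-promoter presence
  count in the cluster, with per-promoter occurrence probability estimated
  from the genome promoter set using a (k+0.5)/(n+1) pseudocount so
  unseen words keep finite scores. Three random same-size gene groups are
  scored identically, and only words beating the highest control score
  + 0.5 are accepted — the published control-set rule.

The genome-wide density of the consensus in real promoters (about 4 sites
per kb in the organism that motivated this pipeline) is *not* a number the
generator aims for: on i.i.d. promoters at GC fraction g the expected
density is (L−5)·g⁴/32 ≈ 2/kb at g = 0.5, and real genomes sit above that
floor because their sites cluster. The test suite checks the machinery
against the i.i.d. closed form; genome values require the genome.

# Category enrichment

`hypergeom_enrich()` computes the exact hypergeometric upper tail
P(X ≥ k) for every category present in a cluster, with the ratio
(k/n)/(K/N) as effect size. The universe defaults to annotated genes only
(matching analyses that report "171 annotated genes among 250" against a
4,977-of-9,129 annotated genome); the whole-genome universe is a switch.
GO mode adds BH adjustment across tested categories; categories absent from
the cluster are not tested. The implementation is verified against direct
combinatorial summation and, for the large-margin case, against the exact
product form of the point probability.

# The synthetic-data generator

`simulation_config()` + `simulate_experiment()` emulate the study design:
4 comparisons × 2 dye-swap replicates, 7 probes per transcript (the real
array's probes-per-transcript count is not published; 7 is a free
parameter). Channel intensities are log-normal with a common per-spot
abundance effect a ~ N(10, 1.5) and spot ratio M = s·(true + e),
e ~ N(0, noise_sd), s the orientation sign; this Gaussian-in-log2 noise
model is chosen for analytic tractability, not taken from any publication.
"Not found" spots (rate `flag_rate`) draw both channels from a low
2^N(6, 0.5)^ background; saturating spots are clipped at 65,535 so the
pretreatment can identify them. Promoters are i.i.d. bases at a configured
GC fraction with motif instances planted at uniform non-overlapping
positions in target-cluster genes — planted counts are recorded exactly, so
tests can compare scanner output with ≥ (background can add hits) or
exactly (GC = 0 excludes a GC-containing consensus from the background).
Annotations assign categories uniformly except one category planted at an
elevated rate in one cluster; the annotated fraction defaults to
4,977/9,129.

`demo_config()` assembles the full demonstration: 1,000 genes (500 in the
bundled tests and acceptance runs, keeping the suite fast at one CPU),
125–250 regulated genes in the proportions of the published clusters,
centroid magnitude 3 with per-gene amplitude uniform on 0.85–1.3 and
per-condition jitter SD 0.25 — within-class dispersion that makes
within-class template correlations span 0.95–0.999, as in real expression
clusters; with *identical* planted profiles the min-seed-correlation rule
degenerates (R\* → 1) and stops being informative. Everything is
deterministic given `rng_seed` (tested byte-identically), and the
generator restores the caller's RNG state.

What the generator does **not** emulate: print-tip/block spatial
artifacts, scanner optics, sequence-specific dye bias, correlated probe
effects, promoter sequence composition beyond i.i.d. bases, and GO-graph
structure. Passing tests therefore demonstrate the pipeline's correctness
and statistical calibration under a clean generative model — not robustness
to every artifact of real slides.

# Numerical choices and degenerate inputs

* Lowess: span 0.3, degree 1, symmetric family, 3 robustness iterations,
  exact ("direct") surface; fewer than 10 spots is an error; a
  zero-variance M vector short-circuits to constant removal.
* Variance prior: zero sample variances are excluded from prior fitting;
  a transcript with zero mean gets t = 0, p = 1 regardless of variance.
* BH: `stats::p.adjust`, with the step-up definition enforced by an
  enumeration oracle in the tests; ties share the common adjusted value.
* CAST/hierarchical ties: resolved lexicographically / by `hclust`'s
  deterministic merge order; input-order invariance is the tested contract.
* Hypergeometric: `stats::phyper` upper tails; margins are validated
  (k ≤ K, n ≤ N) before testing.
* Discovery scores: binomial tails in log space; words seen in fewer than
  2 cluster promoters are never scored (suppresses singleton noise).

# Problem sizes

The bundled tests and the acceptance script use 500–1,000 genes, 7 probes
per transcript, 1-kb promoters, 600-promoter genome backgrounds, 10,000
null draws for the Welch calibration and 2,000 transcripts for the
moderated-t calibration. These sizes were chosen so the entire suite runs
in a couple of minutes on one CPU while keeping every statistical check's
Monte-Carlo error well inside its asserted band.

# Known limitations

* Four-condition profiles give Pearson correlation little room: behaviour
  classes that are collinear after centering are indistinguishable by the
  template stage no matter the threshold (see above).
* The min-seed-correlation rule is sensitive to seed-group composition;
  across random seeds the demonstration's cluster recovery (adjusted Rand
  index against the planted partition) ranges roughly 0.8–0.96, with
  leakage into X as the failure mode.
* Genome-scale dyad discovery (64 × 64 trinucleotide pairs × 21 spacers)
  is implemented straightforwardly and is practical for cluster-sized
  inputs, not for scanning thousands of promoters repeatedly.
* The enrichment t-test treats per-gene counts as approximately normal;
  for rare motifs in small clusters its p-values are conservative at best.
  The published analysis made the same choice.
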