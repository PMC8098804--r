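---
title: "Methods: non-coding RNA analysis of peach bud dormancy release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-coding RNA analysis of peach bud dormancy release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dormantnc)
```

# Scope and design

`dormantnc` analyses regulatory non-coding RNAs — small RNAs (microRNAs,
siRNAs) and long non-coding RNAs — across five peach floral bud stages
spanning dormancy release: T1, T2 and T3 at 0, 500 and 1000 accumulated
chill hours (endodormancy through ecodormancy), and D3, D7 at days 3 and 7
after transfer to warm conditions (bud break). The default replicate
structure is 3 per stage except T3 with 2, reflecting the removal of one
outlier library in the experiment the package models.

The package starts from post-alignment artifacts: a small RNA locus table
with each locus's *major RNA* (its most abundant small RNA sequence),
per-locus read alignments, count matrices, gene/repeat/QTL annotations,
and reference sequence sets. Read trimming, alignment, locus discovery and
transcript assembly are out of scope.

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive)
is converted on read and write, BED passes through unchanged. Interval
overlap always means ≥ 1 bp and is strand-agnostic unless stated.

# Small RNA classification

The classification cascade assigns exactly one label per locus:

1. the major RNA is matched against reference sets in the fixed precedence
   order rRNA > tRNA > snRNA > miRNA > ta-siRNA (first hit wins);
2. unmatched loci with a 20–24 nt major RNA are `siRNA`;
3. everything else is `other`.

The reference matcher is a deliberately deterministic contract rather than
an external aligner: a hit is an ungapped local match of the major RNA with
at most 2 mismatches over at least 90% of the query length, where the
matching sub-window must lie entirely inside one reference sequence.
At 18–30 nt query lengths this is strict enough that random sequences
essentially never hit, which the planted-signal tests rely on. The
precedence order resolves multi-class hits conservatively in decreasing
typical abundance; the choice matters only for ambiguous references.

Genomic origin uses the precedence repeat > gene > intergenic so each
locus gets exactly one origin; this ordering is what the heterochromatic
siRNA definition keys on. hc-siRNAs are then the conjunction of three
criteria: repeat origin, class `siRNA` (no known-class match), and a
23–24 nt major RNA. Loci on chromosomes absent from the annotation are
labelled intergenic with a warning rather than erroring, so partial
annotations degrade gracefully.

The novel-microRNA post-filter retains candidates that match no known
microRNA, are 21–22 nt, fall outside coding regions, and carry a secondary
structure randomization p-value below 0.05 together with a hairpin
prediction score strictly above 3 (boundaries are strict; a score of
exactly 3 is rejected). Hairpin discovery itself is upstream of the
package.

# lncRNA identification and taxonomy

Candidate transcripts become putative lncRNAs when they are strictly
longer than 200 nt, their longest open reading frame is strictly shorter
than 100 codons, and they do not overlap an annotated exon on their own
strand. The ORF rule is a transparent stand-in for a trained
coding-potential classifier; it scans the three frames of the transcript
strand only, since strand-specific assembly fixes the orientation of each
candidate. ORF length counts codons from ATG up to (not including) the
stop; an unterminated ORF runs to the last complete codon. The
sense-exonic exclusion treats such transcripts as unannotated mRNA
isoforms — which is also why the sense/genic/exonic cell of the taxonomy
is structurally empty.

Each retained lncRNA receives one (direction, zone, position) triple
relative to its closest gene: `genic` on ≥ 1 bp gene-body overlap
(`exonic` if an exon is touched, else `intronic`), otherwise `intergenic`
(`upstream` when 5′ of the closest gene's transcription start relative to
that gene's strand, else `downstream`). The closest gene is the one with
minimum gap distance; at equal gaps a true overlap beats a merely touching
interval, and remaining ties go to the lexicographically smallest gene id
— a determinism rule, since biology provides no natural tie-break.
Partner genes are all overlapping genes for genic lncRNAs and all genes
within a 100 kb gap for intergenic ones; distance is measured edge to
edge, matching the "within 100 kb" convention, not TSS-to-TSS.

Manually curated intronic ncRNAs (such as the DAM-intron D1–D6 ncRNAs of
dormancy biology) are supplied as pre-labelled records by the user, not
re-derived.

# Expression analysis

Size factors use the median-of-ratios estimator: per sample, the median
over features of the ratio of its count to the feature's geometric mean,
computed over features with nonzero counts in every sample. When no such
feature exists, total-count factors are used with a warning. The test
suite cross-checks this estimator against an independent reference
implementation.

Differential expression between two stages is tested per feature on
`log2(normalized count + 1)`. The default test is the empirical-Bayes
moderated t-test with a mean–variance trend. This is a deliberate design
choice: with 2–3 replicates per stage, a per-feature variance estimate has
so few degrees of freedom that a plain two-sample t-test cannot produce
p-values small enough to survive multiple-testing correction even for
clear 4-fold effects, and the recovery the pipeline is designed for is
unreachable; pooling variance information across the ~thousands of
features restores power while leaving the null calibrated (the test suite
asserts a raw-p type-I rate within [0.03, 0.07] under the null
generator). A plain Welch t-test remains available via `method = "welch"`
for users who want strictly per-feature inference. p-values are corrected
by Benjamini–Hochberg within each pairwise contrast separately (10
contrasts for 5 stages). Fold changes are computed on stage means of
normalized counts with a pseudocount of 1, and the significance contract
is strict in both parts: |fold change| > 2 AND FDR < 0.05, so a fold
change of exactly 2 is never significant. Zero-variance features get
p = 1. Swapping the contrast direction negates fold changes and leaves
p-values unchanged.

Sample PCA operates on the same log2 matrix with samples as observations
and features as mean-centered variables; variance fractions are
non-increasing and sum to 1 over all components. Relative expression
fractions divide each feature's normalized stage total by the stage sum;
all-zero stages are flagged as `NA` rather than silently dropped.
Pathway enrichment compares member features' p-values against non-members
with a one-sided Wilcoxon rank-sum test (members shifted toward smaller
p); the exact null distribution is used when the product of group sizes is
at most 20,000 and there are no ties, otherwise the continuity-corrected
normal approximation.

# Co-expression modules

Modules are detected by average-linkage hierarchical clustering on the
signed correlation distance 1 − r with a static tree cut at height 0.25
(i.e. clusters merge while average within-cluster correlation exceeds
0.75). Clusters smaller than the kind-specific minimum — 300 loci for
hc-siRNA, 10 for microRNA, 30 for lncRNA — are pooled into module 0, and
surviving modules are renumbered by size, largest first. Constant features
go to module 0 with a warning. The procedure is fully deterministic; no
soft-thresholding or topological overlap is used, as only module
membership, eigengenes and module–trait correlations are consumed
downstream.

A module eigengene is the first right singular vector of the
feature-standardized module submatrix: a unit-norm per-sample score whose
sign is fixed so it correlates non-negatively with the module's mean
standardized profile (principal components have arbitrary sign; the
convention makes "high eigengene" mean "high module expression").
Standardization makes the eigengene invariant to per-feature scaling. The
variance share is the top squared singular value over their total.
Module–trait correlation is the Pearson correlation of each eigengene
with each stage's one-hot sample indicator.

# microRNA target scoring, degradome support and quadrants

Target sites are scored exhaustively at every ungapped antiparallel offset
of the transcript. Per miRNA position (counted from the miRNA 5′ end):
Watson–Crick pair 0, G:U wobble 0.5, mismatch 1.0, with penalties doubled
at positions 2–13 (the seed-proximal region that dominates plant target
recognition). The expectation is the penalty sum and a site is retained
when it is strictly below 2. T/U equivalence is enforced on input. The
predicted cleavage position is the transcript base paired to miRNA
position 10, the canonical slicing register. This fully specified scheme
is oracle-checkable by construction; it does not attempt to reproduce any
external server's internals.

Degradome (PARE) peak categories are computed over each transcript's
position profile: 0 = the cleavage count exceeds 1 read and is the unique
transcript maximum; 1 = tied maximum; 2 = above the median of nonzero
positions but below the maximum; 3 = at or below the median; 4 = exactly
1 read; positions with no reads get no category. Categories 0–2 count as
degradome support.

Quadrant analysis groups miRNA/target pairs in which both members are
differentially expressed in the same contrast by the signs of their fold
changes (labels read target-direction `_vs_` miRNA-direction); the
`opposite` quadrants mark candidate miRNA-driven repression. Pairs with a
non-differential member are excluded and counted, so the quadrants
partition the doubly-DE pairs exactly.

# 24-nt phasing and PHAS calling

phasiRNA biogenesis lays successive 24-nt small RNAs down in a fixed
register after a trigger microRNA (miR2275-type) cleaves the precursor.
The phase score of a locus is computed from read 5′ starts: minus-strand
starts are shifted +2 nt (the 2-nt 3′ overhang of phased duplexes), reads
whose raw 5′ start falls outside the locus are excluded, and all 24
registers are searched for the one maximizing phased abundance P. With U
the remaining abundance and k the number of 24-nt cycles containing at
least one phased read,

score = (k − 2) · ln(1 + 10 · P / (1 + U))   for k ≥ 3, else 0.

This widely used functional form is adopted as the package's definition
(the decision threshold and trigger logic, not a formula, are what the
analysis it models published). It is translation-invariant by multiples
of the phase length, never decreases when a phased read is added, and
never increases when an unphased read is added at fixed k. Register ties
break toward the smallest register. Candidate loci are restricted to
24-nt major RNAs, and a PHAS call requires both a phase score strictly
above 30 and a retained trigger-miRNA target site on the locus sequence;
high-scoring loci without a trigger site are reported but not called.

# Networks and QTL co-localization

Typed edge lists build igraph graphs: `ppi`/`interacts` undirected,
`targets` directed; self-loops and edges touching unknown nodes are
rejected and reported, duplicates collapse. The hub score is the
principal eigenvector of the adjacency matrix (for directed target
graphs, of A·Aᵀ, the Kleinberg hub formulation), computed by power
iteration with an identity shift — the shift keeps the dominant eigenvalue
strictly largest in magnitude, which bipartite graphs otherwise violate —
to a tolerance of 1e-10 and normalized so the maximum is 1. On a
disconnected graph the principal eigenvector concentrates on the
spectrally dominant component and other components score ~0; this is the
well-defined behaviour of the full-graph eigenvector, chosen over
per-component normalization because the relative scale of per-component
eigenvectors is mathematically arbitrary. QTL co-localization flags
feature × region pairs with ≥ 1 bp overlap under half-open semantics, so
a feature ending exactly at a region start does not overlap.

# The synthetic data generator

The generator is first-class, tested code. Each operation draws from its
own stream seeded as configuration seed + a fixed per-operation offset, so
partial re-runs reproduce byte-identical files. Defaults define the
emulated study: 2 chromosomes × 1 Mb, 60 genes (1–3 exons,
non-overlapping), 80 repeats, 2 QTL, 500 small RNA loci, 60 lncRNAs, 30
microRNAs, the five-stage design with 3/3/2/3/3 replicates,
negative-binomial (gamma–Poisson) counts with dispersion 0.05, planted
4-fold effects in 10% of features, 24-nt phasing with 5% off-register
reads. These sizes run the full pipeline in seconds.

Planted structure: loci whose major RNA is an exact substring of a class
reference; repeat-resident 23–24 nt siRNA loci satisfying all three
hc-siRNA criteria; one 10-cycle PHAS locus whose read stack places a
binomial (1 − noise) fraction of 5′ starts in one register (minus-strand
phased reads are planted at register − 2 so the +2 correction restores
them) and whose sequence carries an exact reverse complement of the
trigger microRNA; count matrices with per-sample depth factors, planted
fold changes in a designated stage, and co-expression blocks sharing a
latent stage profile; degradome profiles with sparse background and a
unique maximal peak at each planted cleavage site; and lncRNA candidates
placed into introns, across exons antisense, and up/downstream of genes,
with truth recorded by an independent definitional scan of the realized
placement. Baseline feature means are log-normal (meanlog log 200,
sdlog 1) — an engineering choice of a realistic expression spread, as the
modelled study reports no effect-size distributions.

By design the generator omits much of real data's texture: no sequencing
error or multi-mapping ambiguity, no GC or length biases, independent
features outside the planted blocks, a single dispersion for all
features, and exact reference substrings for planted classes. Passing the
planted-recovery tests therefore demonstrates that the implementations
compute their declared definitions correctly and recover clean signal —
not that the pipeline is robust to the full messiness of real libraries.

# Verification strategy and problem sizes

Every non-trivial operation is checked against an independent oracle
written as naive nested loops: quadratic overlap scans for origin,
partner-gene and QTL assignment; an exhaustive subquery/offset scan for
the reference matcher; a step-up construction for Benjamini–Hochberg;
dense eigendecompositions for PCA fractions, eigengene variance shares
and hub scores; all-offset rescoring for target sites; definitional
re-derivation for degradome categories; and a plain-loop phase score with
the closed-form spot check (P = 100, U = 0, k = 10 giving 8·ln 1001).
Property-style suites assert determinism of the generator, the partition
invariants of classification and module assignment, fold-change/p-value
symmetry, translation invariance and monotonicity of the phase score, and
null calibration (raw-p type-I rate in [0.03, 0.07]; ≥ 99% of
uniform-position read stacks score ≤ 30).

The recovery battery runs the generator at its default sizes across 100
seeds in the test suite and 30 seeds in `scripts/acceptance.R` (with 50
null-calibration runs and 1000 uniform-position phasing loci), asserting
full hc-siRNA recovery, PHAS detection with the trigger conjunction, DE
recall ≥ 0.9 with false-discovery proportion ≤ 0.1 at planted 4-fold
effects (m = 2000 features, 3 vs 3 replicates), module-recovery adjusted
Rand index > 0.9 on two planted 60-feature blocks among 220 features, and
module-trait peaks at the planted stage for ≥ 90% of recovered modules.
These sizes were chosen so the whole suite runs in a few minutes on one
CPU while keeping the statistical assertions stable across seeds.

# Known limitations

* The DE stand-in operates on log-transformed normalized counts; it does
  not replicate any specific count-model tool's dispersion shrinkage or
  independent filtering, and concordance with such tools on real data is
  not claimed.
* The target-scoring scheme and degradome categories are fully specified
  conventions, not reproductions of any server's internals; published
  target counts from such tools are not reproduction targets.
* Module counts on real data depend on correlation structure and the cut
  height; only the planted-recovery behaviour is asserted.
* Locus-level collapsing of lncRNA transcripts follows the `locus_id`
  provided in the input; the package does not invent a clustering rule.
* The phase-score formula is this package's declared definition; only the
  "> 30 plus trigger site" decision rule is taken from the analysis the
  package models.
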