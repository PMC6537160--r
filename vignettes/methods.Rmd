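---
title: "Methods: syntenic homology, variant effects, RIL breakpoints, and expression backgrounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: syntenic homology, variant effects, RIL breakpoints, and expression backgrounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`syntril` re-implements, as one tested toolkit, the comparative analyses
used to contrast two closely related, largely collinear plant genomes (a
sweet and a grain sorghum in the motivating study) together with a
recombinant inbred line (RIL) derived from the two parents.  This
vignette is the package's account of the underlying methods: the models
and rules each stage applies, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
design choices made where the procedure was genuinely open.

## 1. Syntenic homolog assignment

The central object is a pairing of gene models across two genomes.
Within each whole-genome alignment block (a `show-coords`-style table of
collinear segments), the ordered gene lists of the two genomes are
aligned by a global Needleman–Wunsch dynamic program over *gene order*:
the "substitution score" of pairing gene $i$ with gene $j$ is a
transcript similarity score $s_{ij} \in [0,1]$, and every unpaired gene
costs a gap penalty $g$ (end gaps included).  The DP maximises

$$\sum_{(i,j) \in P} s_{ij} \;-\; g\,\bigl[(n - |P|) + (m - |P|)\bigr]$$

over monotone pairings $P$ (no crossing pairs), which the test suite
verifies against exhaustive enumeration of all monotone pairings for
lists up to length 6.

Two remarks on fidelity to the source procedure:

* The source describes the step as "locally aligned using a
  Needleman–Wunsch algorithm".  Needleman–Wunsch is a *global*
  algorithm; we implement the global form with end gaps penalised and
  flag the wording as self-contradictory rather than guessing that a
  Smith–Waterman variant was intended.
* The similarity score stands in for a BLAT alignment score whose exact
  normalisation is unpublished.  We use a single ends-free global
  alignment of the two transcripts (via `Biostrings::pairwiseAlignment`)
  and define identity = matches / aligned columns (end gaps excluded),
  coverage = aligned span of the *shorter* transcript / its length, and
  score = identity × coverage.  The product is bounded in $[0,1]$, is
  monotone in both components, and gives the 0.5 match threshold the
  semantics of "at least half of a clean match".  The shorter-sequence
  coverage convention means an exact prefix scores 1, which is the
  behaviour wanted when a truncated gene model faces its full-length
  counterpart.

Genes inside a block that the DP leaves unpaired (or whose pair scores
below `min_pair_similarity`) are *unresolved in block*: following the
source procedure they are never counted as presence/absence variants,
because within-block singletons are most plausibly annotation artefacts.

Genes outside every block are classified against the entire other
genome: no candidate at score ≥ 0.5 ⇒ **PAV**; best candidate already
paired ⇒ **paralogous copy**; best candidate unpaired ⇒ a rescued
homolog pair.  The source states that multi-candidate choices were
"weighted to take into account which pairings were also the most
syntenic" without giving the form of the weighting; we use a
multiplicative 10% bonus for candidates lying within 10 genes of the
paired partner of either chromosomal neighbour of the query, with
residual ties broken by gene-rank proximity and then gene id.  The
bonus size and neighbourhood are package choices, exposed in code and
covered by a hand-computed test (0.60 × 1.1 = 0.66 beats 0.62).

The same list alignment is applied inside externally supplied
expansion/contraction intervals (`classify_sv_region_genes`), with pairs
labelled `sv_region`.  Annotation completeness uses the separate rule
*identity ≥ 0.90 and coverage ≥ 0.85*, both inclusive.

Defaults: `gap_penalty = 0.2`, `min_pair_similarity = 0.3`,
`unblocked_threshold = 0.5`.  The first two are not stated in the
source and are therefore configuration keys logged by the pipeline; the
0.5 threshold and the 0.90/0.85 completeness margins are the published
values.

## 2. Variant-effect annotation

A deliberately compact, snpEff-like classifier over the canonical
(first) transcript of each gene:

* CDS SNP: translate the affected codon before and after, strand-aware.
  Same residue ⇒ `synonymous` (LOW); new stop ⇒ `stop_gained` (HIGH);
  lost stop ⇒ `stop_lost` (HIGH); a changed first codon ⇒ `start_lost`
  (HIGH); otherwise `missense` (MODERATE).
* CDS indel: `frameshift` (HIGH) iff the length difference is not a
  multiple of 3, else `inframe_insertion`/`inframe_deletion` (MODERATE).
  VCF anchored representation: inserted bases sit between POS and
  POS+1; deleted bases span POS+1..POS+len.
* Inside a gene but outside the CDS: `utr` if in an exon, else
  `intron` (MODIFIER).  Within 5 kb of a gene: `upstream`/`downstream`
  by the gene's orientation (5 kb is the common annotator default; the
  source does not state one).  Everything else: `intergenic`.

The test suite checks every possible single-base substitution in
several simulated genes on both strands against an independent oracle
that re-translates the whole mutated CDS and compares proteins (with
initiator-codon special-casing disabled, so that ATG→CTG is a start
loss, not a silent initiator exchange).

"Silent" is counted as synonymous SNPs only; missense:silent ratios are
reported per gene (ratio > 1 flagged, including the infinite-ratio case
of missense with zero silent) and genome-wide as the ratio of sums.
SNP densities use 1 Mb sliding windows reported as SNPs per 200 kb; the
window step is not stated in the source figure, so the default step is
200 kb, which makes the density "per 200 kb" natively.  Trailing
truncated windows are rescaled by their actual width.

## 3. RIL haplotype painting and breakpoints

Sites from the 3-sample VCF (reference parent, other parent, RIL)
survive the filters iff all three genotypes are called, the reference
parent is homozygous-reference (a polymorphism between the
reference-parent reads and its own assembly disqualifies the site), the
other parent is homozygous, and the parents differ.  Surviving sites
are grouped into consecutive non-overlapping windows of 15 sites
(trailing remainder dropped).  The published rule gives the window call
from the ratio of RIL alleles matching each parent: ratio > 2 ⇒ R,
ratio < 0.25 ⇒ B.  Decisions the source leaves open, resolved here:

* The "proportion" counts *alleles* (2 per homozygous call, 1 each for
  a heterozygous call), so het RIL calls contribute symmetrically.
* Both thresholds are strict; ratios in [0.25, 2] give an undetermined
  (U) window.
* Pure windows use the zero-denominator convention (b = 0 with r > 0 is
  R; r = 0 is B), so clean windows are always callable.

Breakpoints are emitted between adjacent *determined* windows with
different calls, as the interval from the last site of the left window
to the first site of the right window; U windows are skipped, so an
interleaved U window is absorbed into the interval.  Runs of same-call
determined windows merge into haplotype blocks (written as BED,
0-based half-open — the package's only coordinate conversion, since
internally everything is 1-based inclusive as in GFF3/VCF and the
Bioconductor ranges stack).

A breakpoint is therefore an *interval*, not a point: its resolution is
bounded by the informative-site spacing and the window size.  The
synthetic RIL generator places crossovers in the gap following a whole
number of 15-site groups (`breakpoint_quantum = 15`, settable to 1 for
free placement).  With free placement a crossover interior to a window
that still calls R or B (e.g. 12R/3B) is localised only to within one
window, and exact interval containment of the truth is impossible by
construction; quantised placement makes window-resolution recovery
exactly assessable, which is what the recovery tests measure.  The
robustness test (2% genotyping error, recovery within one window span)
does not depend on this alignment.

## 4. Genotype-by-time differential expression

The published analysis used a count-based NB GLM (DESeq2) for the
genotype × time interaction and an HMM clusterer (EBSeqHMM) for
temporal patterns.  Both are replaced here by declared stand-ins that
preserve the decision structure while keeping the toolkit light:

* **Normalisation**: median-of-ratios size factors (median across
  genes of count / geometric-mean count, zero-containing genes excluded
  from the median; total-count fallback with a warning when every gene
  contains a zero), then the transform $\log_2(\text{count}/s_j + 1)$.
* **Interaction test**: per gene, a two-way fixed-effects linear model
  on transformed counts with genotype, stage, and genotype × stage
  terms; the reported p-value is the F-test of the interaction against
  the additive model.  One QR decomposition per design is shared by all
  genes, so the test is a matrix operation; the suite verifies equality
  with per-gene `anova(lm(...))` and calibration of the type-I rate at
  the published raw threshold p < 0.001 (no FDR step, matching the
  source).  Genes with constant counts (or no residual variation) are
  excluded and flagged.
* **Patterns**: per genotype, stage means of transformed counts are
  discretised between consecutive stages at a threshold of 1.0
  transformed unit (configurable; the source's HMM settings are
  unpublished) into up/down/flat path strings such as
  `flat-up-down-flat`, with a `peak_at(stage)` predicate so
  "peak-at-FL in the RIL vs peak-at-ANT in the reference genotype"
  cohorts are countable.

Backgrounds come from the haplotype blocks only: a gene fully inside an
R block is RIO, fully inside a B block is BTX, anything overlapping a
breakpoint interval, U gap, or uncovered chromosome is SPANNING.  The
background filter retains DEGs whose alleles differ between the lines
(background BTX); SPANNING genes are excluded from numerator and
denominator, since the source does not mention them.

**Percentage arithmetic.**  The retained percentage is the integer
count ratio truncated to one decimal.  Truncation (rather than half-up
rounding) is the only rule that reproduces *both* printed study values
from their printed counts — 820/1686 → 48.6 and 119/156 → 76.2
(half-up would give 76.3) — so it is adopted package-wide, and the
report also carries the unrounded fraction.  Recomputing the third
tissue from its printed counts gives 533/1220 → 43.6 against a printed
"47%"; the discrepancy is in the source and both numbers are surfaced
by the tool rather than adjudicated.

## 5. The synthetic-data generator

The generator exists so that every stage can be tested against recorded
truth without external data.  It emulates:

* a pair of largely collinear genomes separated by SNPs
  (2.6 × 10⁻³/bp) and small 1–6 bp indels (5.4 × 10⁻⁴/bp), the rates
  implied by the study's genome-wide variant counts over a 729.4 Mb
  assembly;
* single-gene tandem duplications and deletions.  The study's per-gene
  event frequencies (≈0.0015 and ≈0.008) give fewer than one expected
  event on a desk-scale genome, so the defaults (0.015 and 0.03) are
  scaled up once so that a default genome carries a handful of events;
  event *structure* (single-gene, tandem) follows the study's
  observation that most events encompass one gene;
* coding-SNP placement rejection-sampled within codons so the
  genome-wide missense:silent ratio matches a target (default 1.1, the
  published genome-wide value) in expectation — the acceptance-sampling
  probability for missense proposals is estimated by Monte Carlo from
  the actual codon composition;
* a fully homozygous RIL mosaic (matching an inbred line; the published
  heterozygosity filter applies to the parent only) with configurable
  breakpoints, genotyping errors (flips to the other homozygote), and
  missing calls, plus deliberately non-informative sites that exercise
  every filter;
* negative-binomial counts, NB(μ, size = 1/dispersion), under the
  study design of 2 genotypes × 3 tissues × 5 stages × 3 replicates
  (the source's methods mention six stages while its design figure
  shows five; the stage count is a parameter, defaulting to five), with
  genotype × stage log2 fold-change patterns planted in a configurable
  fraction of genes and DE genes placed *independently* of parental
  background.

Gene models are random-codon ORFs (ATG … stop, 60–150 codons by
default, 1–3 exons, short UTRs), which makes codon-level effect classes
exactly decidable — the reason this construction was chosen.  What the
generator does **not** emulate: real codon usage and GC content, repeat
content and transposons, segmental duplications larger than one gene,
inversions (the parser handles inverted blocks; the generator does not
produce them), read-level noise (no FASTQ), linked selection on the RIL
mosaic, and realistic expression covariance between genes.  Passing
tests therefore demonstrate algorithmic correctness under the stated
models, not performance on real sequencing data.

Everything is a pure function of `(config, seed)`: one master seed is
fanned out to fixed per-stage child seeds, and byte-identical outputs
across runs are part of the test suite.

## 6. Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen
once as the package's own evaluation conditions: default genomes of
2 chromosomes × 60 genes (120 genes, ≈0.5 Mb) for homolog-map recovery;
5 × 100-codon genes for the exhaustive effect oracle; 3,000 informative
sites and 6 breakpoints per RIL replicate (20 clean seeds, 10 noisy
seeds); 10,000 null genes for type-I calibration and 200 planted
interaction genes for power; 3,000 pseudo-genes for the
background-independence property.

Numerical details worth knowing: DP traceback prefers diagonal moves on
ties (so equal-scoring candidates pair by position, as in the
tandem-duplication test); similarity uses match +1 / mismatch −1 / gap
open 4 / extend 1 in the underlying nucleotide alignment; the
completeness margins are inclusive; window calls use strict
inequalities; percentages truncate to one decimal; and all
probabilities reported by the interaction test are raw, never adjusted.

## 7. Limitations

The homology stage is quadratic in block gene count through the
similarity matrix and is intended for desk-scale or per-block use, not
for whole plant genomes at once.  The variant annotator handles one
canonical transcript per gene and omits splice-site classes.  The
breakpoint caller assumes a biparental, essentially homozygous RIL; it
is not a general population-haplotyping method.  The expression stand-in
uses a Gaussian F-test on transformed counts: calibrated and powerful at
the simulated depths, but not a substitute for count-based inference at
very low counts.
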