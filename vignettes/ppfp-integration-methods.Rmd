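---
title: "Methods: integrating a fusion-protein cistrome with its expression program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating a fusion-protein cistrome with its expression program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppfptools)
```

# The analysis problem

The PAX8–PPARG fusion protein (PPFP) carries the DNA-binding domains of
two unrelated transcription factors. Understanding what it does in a
thyroid cell therefore requires joining two genome-scale measurements:
a ChIP-seq binding map (where does it sit?) and RNA-seq differential
expression under several perturbations (what does it change, and does a
PPARG agonist rewire it?). `ppfptools` implements that joining layer:
peak annotation against random backgrounds, dual-motif analysis of the
bound sequence, contingency-based comparisons across perturbations and
species, and gene-set enrichment of both data types. Peak calling and
differential-expression model fitting are upstream of this package;
their outputs (BED intervals, per-gene log2FC/p/FDR tables) are its
inputs.

All coordinates are 0-based, half-open. BED input is native; 1-based
gene tables are converted on read (`one_based = TRUE`).

# Peak representation and annotation

A peak is an interval with a *mode*, the base of maximal signal.
Boundaries are standardized to ±150 bp around the mode
(`redefine_boundaries()`), so peaks are 300 bp unless clipped at a
chromosome end; all distance computations use the mode rather than the
midpoint, consistent with that convention.

`annotate_peaks()` assigns each peak exactly one category by a fixed
priority: TSS ±1 kb, 1–5 kb upstream, 5–10 kb upstream, exon, UTR,
intron, intergenic. Overlap of a single base pair suffices; the
annotation convention this follows states no overlap fraction, and one
shared base is the least arbitrary choice. Three decisions deserve explanation:

* **Strand-aware upstream windows.** "Upstream" means 5′ of the TSS in
  transcription direction. Promoter-proximal elements are defined
  relative to the direction of transcription, so a minus-strand gene's
  1–5 kb window lies at higher coordinates than its TSS.
* **Exon vs UTR.** The priority list distinguishes exon from UTR, which
  is only meaningful if "exon" means *coding* exon portions; UTR
  regions are the untranslated portions of terminal exons. Without this
  split the UTR category would be unreachable.
* **Intergenic.** A peak is intergenic if and only if it overlaps no
  region between 10 kb upstream of a TSS and that gene's 3′ end. This
  is deliberately not "outside any annotation window": the intergenic
  definition and the locus-length covariate of the binding-enrichment
  model (below) use the same span.

Intronic peaks carry the index of the intron they overlap, numbered in
transcription direction; when several transcripts' introns overlap the
peak, the transcript whose TSS is nearest the peak mode decides, then
the smallest index. Ties between genes for the *same* category need no
tie-break, because the category is identical.

Fold enrichment (`annotation_enrichment()`) compares observed category
counts to the mean over `n_replicates = 10` random peak sets, each
size-matched and width-matched per peak, with starts uniform over valid
positions genome-wide (chromosomes weighted by length). Width-matching
per peak is the default because enrichment should be judged against
backgrounds with the same interval geometry; a fixed-width option
exists. Random intervals do not exclude gene bodies — no such exclusion
is part of the method being reproduced — and a category whose random
mean is zero reports an undefined ratio rather than infinity. The mean
(not median) random count is the denominator.

# Motif scanning with exact null p-values

A PWM is a positions × 4 probability matrix; scores are log2 odds
against a 0-order background, which defaults to the mononucleotide
composition of the scanned FASTA (uniform as fallback). Count matrices
become probabilities with a background-weighted pseudocount (default
0.1 per position) so no letter scores −∞; windows containing non-ACGT
letters score −∞ and can never be occurrences.

An *occurrence* is a window (either strand) whose null exceedance
probability P(score ≥ s) is below 1e-4, the FIMO default. That null
distribution is computed exactly by dynamic programming over PWM
positions under the background model, on scores quantized to 0.001-bit
bins. Quantization matters for correctness, not just speed: the scanner
scores windows with the *same* quantized matrix the null table was
built from, so a score-to-p lookup is exact and the hit set is
identical to brute-force enumeration (this equivalence is asserted in
the test suite against an independent oracle). The discretization error
(≤ half a bin per position, ~0.007 bits for a 14-mer) is orders of
magnitude below the threshold granularity. Minus-strand scanning uses
the reverse-complemented PWM on the forward sequence, which is
mathematically identical to scanning the reverse strand.

Overlapping hits are all reported; per-peak presence/absence collapses
them, so co-occurrence statistics are invariant to hit multiplicity.
Hit offsets are reported relative to the peak center.

# Co-occurrence, spatial centering, and overlap tests

`motif_cooccurrence()` partitions a peak set into both/only-A/only-B/
neither and reports the fraction with either motif and P(B | A). The
spatial profile (`spatial_profile()`) bins hit-start offsets in 10 bp
bins over ±150 bp — matching the standardized peak half-width — and
compares them with a null built by scanning random 300 bp regions; both
are pooled counts divided by the number of regions (per-peak
normalization was the open alternative; pooled counts keep observed and
null on the same scale and are what a density-over-regions null
estimates). A real binding motif concentrates at peak centers; false
positive matches are flat, which is the diagnostic use of this plot.

`motif_conditioned_overlap_test()` reproduces the "does factor X bind
the motif-bearing subset" design: peaks pre-filtered for motif 1 are
cross-classified by overlap (≥1 bp) with a second peak set and by
motif-2 content, then tested by two-sided Fisher's exact test with the
standard point-probability two-sided rule. The sample odds ratio ad/bc
is flagged undefined when bc = 0.

# Expression classification and concordance

`classify_de()` calls a gene UP when FDR < cut, 2^|log2FC| > cut, and
log2FC > 0 (DOWN symmetrically). The fold-change cut is interpreted on
the linear scale and two-sided, matching the symmetric up/down usage of
such cuts in practice.

`concordance_analysis()` tabulates genes changed by perturbation A
against their UP/DOWN/NC status under perturbation B (a 2×3 table with
row percentages) and reports Fisher's exact test on the *full 2×3
table* as the headline p-value, alongside the 2×2 of doubly-changed
genes with its own exact test and the discordant fraction. The 2×3
exact test (Freeman–Halton) is the one that reproduces the worked
example this package ships; the 2×2 view answers the narrower question
of direction association among genes changed in both.

`reversal_analysis()` counts same- versus opposite-direction genes among
those DE in two comparisons; `opposite_direction_genesets()` lifts the
same idea to enrichment results, returning sets significant in both
runs with opposite direction flags.

# Homolog-mapped binding overlap

To compare binding across species (e.g. mouse adipocyte/macrophage
PPARG peaks versus rat PPFP peaks), species-B bound gene sets are
mapped through a homolog table and the fraction of mapped homologs
bound in species A is compared between the two sets. Many-to-many maps
collapse to "any homolog bound"; a strict 1:1 mode is available. The
two proportions are tested on the 2×2 of set-exclusive homologs by
two-sided Fisher's exact test — the source analysis names no test for
this comparison, so the choice is documented here as an assumption;
exclusivity avoids counting shared homologs in both margins.

# Gene-set enrichment

Two logistic-regression engines share BH FDR across tested sets, a
minimum set size of 5 (the source states only a maximum) and a ≤500
gene maximum.

**Directional expression enrichment** fits, per gene set, membership
(0/1) against the signed evidence statistic sign(log2FC)·(−log p)
across all genes. The sign construction is the standard way to make a
directional test from "−log p-values": a positive slope means members
concentrate among significantly induced genes. Wald p-values on the
slope are the default, with a likelihood-ratio option (`test = "lrt"`).
Under strong planted signal the Wald statistic can collapse
(Hauck–Donner effect via quasi-separation), so separation is detected
and the fit falls back to Firth-penalized logistic regression,
implemented in-package as adjusted-score IRLS under the Jeffreys prior.
The engine is exactly antisymmetric: negating every log2FC flips every
direction and preserves p-values.

**Locus-length-adjusted binding enrichment** fits
`has_peak ~ membership + ns(log10 locus_length, df = 10)`. Locus length
(10 kb upstream of the TSS to the transcript 3′ end) confounds naive
peak-presence tests because long loci catch more peaks by chance; gene
sets of long genes (developmental regulators, neuronal genes) would
otherwise be spuriously enriched. The natural cubic spline on log10
length with knots at quantiles is a deliberately flexible,
monotone-friendly adjustment; df = 10 follows common practice for this
correction and is reduced automatically for tiny universes. The test
suite demonstrates the key property: a planted length-dependent peak
probability inflates a naive Fisher test far above its nominal level
while the adjusted test stays near 5%. Mappability, the other covariate
sometimes used in this adjustment, is out of scope; locus length alone
is modeled. Complete separation falls back to the same Firth fit,
flagged in the output.

**Stratification.** Peaks are classified by motif content and by TSS
distance: *near* = within 10 kb of the nearest TSS (two-sided), *far* =
more than 10 kb from it and upstream in transcription direction. The
asymmetry (two-sided near, upstream-only far) follows the analysis this
reproduces as written; both windows are configurable. Each stratum gets
its own binding-enrichment run, optionally joined with a directional
expression run to mark sets both bound and regulated. The point of
stratification is that regulatory mode can differ by geometry — e.g.
near-TSS binding associated with induced sets and distal upstream
binding with repressed ones — and pooling blurs exactly that signal.

# The synthetic-study generator

`simulate_study()` produces every input with planted ground truth, at
desk-scale defaults chosen once as the package's study conditions: a
2 Mb genome over four chromosomes, 300 genes, 2,000 peaks of 300 bp,
500 gene sets, four DE comparisons, a 1,500-gene species-B homolog map.
Specific emulation choices:

* **Genes** pack the head of each chromosome with random gaps
  (transcripts never overlap) and the tail remains a gene desert, so
  intergenic space exists at desk scale the way gene deserts provide it
  in real genomes. Each gene has 2–4 exons, UTR portions on terminal
  exons, and a random strand.
* **Motif plant rates** default to 0.30 (PAX8-like) and 0.50
  (PPARG-like), independent per peak: independence at these rates gives
  65% of peaks with at least one motif and P(PPARG | PAX8) = 50%, the
  fractions the real study measured — so downstream analyses see
  realistic motif structure. Planted sites are sampled from the PWM by
  default (consensus optional) so recovery tests exercise sub-consensus
  sites; offsets are N(0, 20 bp) around the center by default. The
  shipped PWMs are synthetic stand-ins with the qualitative character
  of the real motifs (a DR1 direct repeat for PPARG); real matrices can
  be supplied in MEME format.
* **DE tables** mirror the two-factor design (construct × ligand): three
  comparisons carry planted directional set effects (two induced, two
  repressed each, chosen gene-disjoint within a comparison; a gene in
  several planted sets keeps its first effect) and the vehicle-control
  comparison is pure null, matching the study's observation that the
  ligand alone changes nothing in control cells.
* **Homologs** map species-B genes 1:1 onto species-A ids (5% get a
  second homolog, making the map many-to-many), with bound-in-A
  fractions planted at 0.34 vs 0.25 for the two species-B sets — the
  study's reported overlap difference.

Determinism: every simulation function derives its RNG stream from the
config seed and restores the caller's RNG state, so one seed yields
byte-identical outputs.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: read-level noise (no FASTQ; DE summary
statistics are drawn directly), correlated gene expression within
pathways beyond the planted shifts, realistic motif clustering and GC
structure, overlapping transcript isoforms, and genome-scale sparsity.
At desk scale peaks are ~1000× denser per megabase than a real
cistrome, so peaks overlap each other and can share planted sites; this
raises measured co-occurrence above the planted rates and is expected
behavior, not leakage.

# Numerical choices and degenerate inputs

* Score quantization 0.001 bits; p-value lookups are exact on that grid.
* Fisher tests use the point-probability two-sided rule; odds ratios
  with a zero denominator are flagged, not returned as Inf.
* BH q-values come from the standard step-up procedure
  (`stats::p.adjust`); empty input returns empty output.
* Degenerate enrichment fits (sets covering all or none of the
  universe) are skipped with a notice; constant statistics report slope
  0 and p = 1; separation triggers the Firth fallback and a flag.
* Random-interval sampling with `n ≤ 0` returns an empty frame; widths
  exceeding the shortest chromosome are rejected.
* Nearest-TSS ties break to the lexicographically smallest gene id, so
  assignments are deterministic; peaks on gene-free chromosomes get an
  NA sentinel and are excluded from gene-level summaries.

# Problem sizes

The test suite and the acceptance script run the generator at 0.9–2 Mb
genomes with 100–400 peaks for sequence-heavy stages and 2,000 peaks
for counting stages; calibration suites use 400–500 replicate null
fits. These sizes were chosen so the full suite completes in a few
minutes while every statistical property under test (oracle
equivalence, null uniformity, confounder removal, planted-parameter
recovery) is evaluated at adequate power.

# Known limitations

* The annotation priority and window constants are fixed to one
  published convention; other annotation schemes (e.g. nearest-feature
  annotation) are not provided.
* The scanner's background is 0-order; dinucleotide backgrounds and
  per-hit q-values are out of scope.
* The binding-enrichment model adjusts for locus length only, not
  mappability.
* Homolog maps are inputs; no ortholog inference is attempted.
* No figure rendering: all outputs are tables (TSV/JSON), by design.
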