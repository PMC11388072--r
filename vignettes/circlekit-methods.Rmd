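---
title: "circlekit: models and methods for circular-DNA analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circlekit: models and methods for circular-DNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(circlekit)
```

circlekit analyzes extrachromosomal circular DNA (eccDNA) from Circle-Seq
short reads and rolling-circle-amplified (RCA) long reads. This vignette
is the package's own account of its models: what each method computes,
the assumptions behind it, the tunable parameters, and the design
decisions taken where the underlying approach left the choice open.

## Coordinate conventions

Every interval in the package is 0-based, half-open (`start` inclusive,
`end` exclusive), the BED convention. VCF and GTF are 1-based and are
converted at the I/O boundary (`pos_internal = pos_vcf - 1`), never
inside analysis code; a single internal convention removes the usual
off-by-one failure mode. Chromosome names are compared as exact strings —
no silent `chr` aliasing, because aliasing produces wrong overlaps
without any error; the CLI offers `--strip-chr` for data that genuinely
needs normalizing. Strand is recorded on circle intervals but ignored in
overlap arithmetic, since Circle-Seq junctions are unstranded.

## The junction caller

A circular DNA molecule sequenced as a linear library betrays itself in
two ways. A read crossing the circle's junction aligns with a terminal
soft clip whose clipped bases come from the other side of the junction;
and a read pair whose *insert* (but neither read) crosses the junction
maps in outward-facing orientation — the reverse-strand read upstream of
its forward-strand mate. The caller uses both signals:

1. **Candidates** (`extract_candidates()`). Primary, non-duplicate
   alignments with MAPQ ≥ `mapq_min` (default 20) contribute: terminal
   soft clips of at least `min_softclip_len` (10 bp) as split candidates,
   and same-chromosome outward-facing pairs with span ≤ `max_circle_span`
   as discordant candidates.
2. **Realignment** (`realign_softclip()`). Each clip is scanned gaplessly
   over a window of `realign_search_window` (10 kb) on the
   junction-consistent side of its anchor. Per offset the log-likelihood
   is `log(1 - eps)` per matching base and `log(eps/3)` per mismatch,
   with `eps` decoded from the base quality. The *posterior* of the best
   offset is its likelihood over the sum across all offsets, so a clip
   that fits two near-identical repeat copies is split to ≈ 0.5 per copy
   rather than asserted at either. The scan is implemented in C++; the
   denominator ignores offsets more than 34.5 nats (likelihood ratio
   1e-15) below the running best, a truncation far below float noise.
3. **Clustering and scoring** (`score_and_merge()`). Junctions agreeing
   within `junction_merge_tolerance` (10 bp) at both breakpoints merge;
   the representative breakpoint is the posterior-weighted mode, which is
   exact on clean data and robust to the occasional misplaced
   realignment. The published score threshold (≥ 200) is given a concrete
   construction here: `circle_score = sum(100 * posterior)` over
   supporting split reads, making the threshold read naturally as "at
   least two confident junction reads" and keeping it dimensionally
   consistent with the split-read filter. The score of the original
   implementation is not reconstructible from its published description,
   so numerical identity with it is not claimed — the threshold's meaning
   is preserved instead.
4. **Filters** (`coverage_filters()`, `apply_circle_filters()`): split
   reads ≥ 2; circle score ≥ 200; relative coverage increase ≥ 0.33 at
   both boundaries; coverage continuity (zero-coverage fraction inside)
   ≤ 0.1; coverage SD below the mean; and circles of ≥ 2 kb must have at
   least one supporting discordant pair — long calls supported only by
   split reads are a known false-positive mode when one read supplies
   both signal types. The boundary coverage increase is
   `max(0, (m_in - m_out)/m_in)` over 100 bp windows (`boundary_window`);
   the inside mean as denominator keeps the statistic in [0, 1], windows
   shrink for calls shorter than the window, and an inside mean of zero
   fails the boundary filters by definition.

Overlapping passed calls keep the higher score, then the shorter
interval. Raising any threshold can only shrink the passed set — a
monotonicity property the tests sweep explicitly.

**Evaluation** (`evaluate_calls()`) matches calls to truth one-to-one,
greedily by reciprocal overlap; a pair is matchable when both breakpoints
agree within ±10 bp or the reciprocal overlap is at least 0.95. Capture
rate is matched truth over truth; precision is matched calls over calls.

## The simulator

The simulator is first-class code: it defines the study conditions under
which every downstream claim is tested.

* **Genome** — `n_chroms` i.i.d. sequences at `gc_target`; interspersed
  repeats from a handful of seeded units, each planted copy 2% diverged
  (divergence is what makes most real repeat copies distinguishable to a
  quality-aware realigner); multi-exon gene models tiling ≈ 40% of the
  genome with CDS/UTR structure, so the element partition is non-trivial.
* **Circles** — sizes log-normal (`meanlog` 6.7, `sdlog` 0.6 in log-bp, a
  median near 800 bp with a tail past 2 kb, matching the "mostly < 2 kb"
  regime of Circle-Seq libraries); a `chimera_prob` fraction (default
  10%) built from 2-9 fragments of ≥ 50 bp, possibly inverted, possibly
  cross-chromosomal. Planted fragments do not overlap one another
  (200 bp margin) — a desk-scale simplification; real eccDNA hotspots can
  overlap, and overlapping circles are a harder calling problem than
  these tests exercise.
* **Short reads** — pairs drawn uniformly from the circularized
  coordinate system, so junction-spanning reads acquire soft clips
  (encoded as one clipped primary alignment, anchored on the longer
  segment, no SA tags — the caller must not rely on supplementary
  records) and inserts wrapping the junction produce outward-facing
  (reverse-forward) pairs. Defaults: 150 bp reads, insert 450 ± 50 bp —
  an insert comfortably longer than two read lengths, so the inner gap
  exists and discordant pairs occur at a realistic rate — 0.5%
  substitution errors with matching constant base qualities, and a
  junction-coverage target (`depth`) of 30×. A "perfect SAM" is emitted
  with every read at its true position and CIGAR, making the caller
  testable with no aligner in the loop; FASTQ is emitted for use with a
  real aligner.
* **RCA long reads** — k concatenated copies of the circle (k uniform in
  `passes_range`) from a uniform rotation, substitution errors only; the
  matching PAF lists every fragment traversal in query order and stays
  error-free by construction, keeping the reconstruction test surface
  exact. Indels are deliberately not modeled: the reconstruction operates
  on PAF intervals, not bases.
* **Clustered SNVs** — a Poisson background at a stated mean
  inter-mutation distance plus planted clusters of 6-15 SNVs with
  100-600 bp gaps (thus always satisfying the detection rule), a set
  fraction placed inside supplied ecDNA intervals; truth labels are
  derived from final placements.
* **Determinism** — every operation draws from its own stream seeded by a
  fixed offset from `sim_config()$seed`, so outputs are byte-reproducible
  and adding an operation does not reshuffle the others.

What the simulator does **not** model: PCR duplicates, GC bias, phi29
chimera artifacts, quality-score miscalibration, indel errors in short
reads, overlapping circles, and mappability structure beyond the planted
repeats. Passing the benchmark therefore demonstrates correctness of the
junction logic, filters and reconstruction arithmetic under controlled
conditions — not performance on any particular real library.

## Quantification

* **EPM** — circles per million mapped reads, the depth-normalized
  eccDNA load.
* **Per-gene abundance** — `J_g` counts *distinct circle start
  coordinates* inside the gene span (duplicate starts collapse: unique
  junction counting, with the start site standing in for the junction; a
  start inside two overlapping genes counts in both). The normalized
  abundance is the length- and total-normalized closed form
  `A_g = (J_g / L_g) / sum_i (J_i / L_i) * 1e6`, so a sample's
  abundances sum to one million — the transcript-per-million family,
  chosen for interpretability; only rank/ratio structure is identifiable
  from the underlying description, and the 1e6 scale is this package's
  convention.
* **Element profile** — the genome is partitioned per-base with priority
  CDS > UTR > intron > up/downstream 2 kb > intergenic; a circle counts
  toward every class it overlaps by ≥ 1 bp (multi-hit). Two enrichment
  measures are reported. `relative_enrichment` divides the circle
  fraction by the class's share of the genome — simple, but biased
  upward for long circles over fragmented classes, because a circle of
  length L overlaps a class segment whenever its *start* falls within
  L - 1 bp of it. `enrichment` divides instead by the exact probability
  that a uniformly placed circle of the observed lengths overlaps the
  class (computed per distinct length by extending each class segment by
  L - 1, clipping to valid placements, and reducing); this calibrated
  measure equals 1 in expectation for shuffled circles of any length and
  is the one the package's own baseline checks use.
* **Shuffled baseline** (`shuffle_intervals()`) — same interval count and
  identical length multiset, placed uniformly over valid positions
  (chromosome chosen proportionally to the positions that can hold the
  interval), seeded and deterministic.
* **GC and size classes** — GC from the reference sequence of each
  called region, ambiguous bases excluded from the denominator; size
  classes `< 2 kb`, `2-10 kb` (both boundaries inclusive), `> 10 kb`.

## Differential abundance

Per gene, a two-sided Wilcoxon rank-sum test on per-sample abundances:
the exact null distribution when the smaller group has ≤ 12 samples and
no ties occur, otherwise the normal approximation with continuity
correction. Fold change is `log2((mean_t + c)/(mean_c + c))` with
pseudocount `c` = 1e-3 of the global mean positive abundance (tunable);
genes all-zero in both groups get `p = 1`, `log2FC = 0`. Significance is
`|log2FC| > 0.5` and `P < 0.01` with **no multiple-testing correction by
default** — matching the analysis this package reproduces; `fdr = "BH"`
adds an adjusted column without changing the flag. The cohorts are
treated as unpaired by the rank-sum test even when samples are matched
pairs; that is the published choice, kept as the default. Note the
compositional caveat: because abundances are normalized per sample,
strong planted effects depress all other genes' abundances slightly, so
the null false-positive rate is evaluated on fully null simulations.

The mRNA coupling uses Spearman correlation per gene across matched
samples, restricted to genes with TPM > 5 in *every* sample (< 4 samples
is an error: a rank correlation on 3 points is meaningless).

## Kataegis and kyklonas

Kataegis is detected per chromosome by sliding a 6-SNV window: a window
qualifies when the mean of its 5 gaps is ≤ 1000 bp (inclusive);
qualifying windows sharing an SNV merge into one maximal event — the
standard convention of rainfall-style callers; the merging rule is this
package's choice, and a merged event's mean IMD, reported over the
merged span as `(last - first)/(n - 1)`, may exceed the window
threshold. Multi-allelic sites collapse to one position. The detector is
property-tested against an independent brute-force enumeration.

Kyklonas labelling against ecDNA intervals: `on_ecdna` when any member
SNV lies inside an interval, else `near_ecdna_10kb` when the minimum
member-SNV-to-endpoint distance is ≤ 10 kb (inclusive), else `none`.
Whether "within 10 kb" should be measured from event boundaries or
member SNVs is ambiguous; the member-SNV minimum is used (it is the more
inclusive reading and is documented here once). Distances to breakpoints
are computed per mutation against all interval endpoints on the same
chromosome, `NA` when the chromosome has none. VAF stratification of
events is provided as a grouping utility (`vaf_stratify()`) without an
attached statistical claim.

The 96-context spectrum uses the pyrimidine-centered convention: purine
references are complemented together with their flanks, leaving 6
substitutions × 16 contexts. Counts are conserved and strand-invariant
by construction — both are asserted in tests.

## Long-read reconstruction

An RCA read is k concatenated traversals of its circle. Reconstruction
proceeds per read: PAF fragments are collapsed into units (merging
alignment breaks that continue on the reference within a 20 bp
tolerance), units get locus keys by coordinate matching (first matching
earlier unit within 20 bp at both ends — matching, not binning, so
near-boundary coordinates cannot split a key), and the smallest tandem
period of the key sequence is found. The first and last unit of a read
are usually truncated traversals; they are folded onto a matching
complete unit by one-sided matching and excluded from consensus
coordinates. The pass count is total aligned query length over the
period length — the number of times the read covers the entire
circularized region — and reads with fewer than 2 passes are rejected.

Compositions identical up to rotation and orientation merge across
reads (a circle read from the complementary strand appears as the
reversed, strand-flipped period; canonicalization compares both
orientations and all rotations, keeping the lexicographically smallest
signature). Consensus fragment endpoints are medians over supporting
reads; the reported pass count is the maximum over supporting reads
(reads of the same circle legitimately differ in k; the maximum records
the best available evidence). A circle from exactly one read is a
single-event circle; a period with ≥ 2 distinct loci is chimeric.

## Study conditions and problem sizes

The package's standard scene — the default `sim_config()` — is a 2 Mb
genome on two chromosomes, 200 circles, 10% chimeric, junction depth
30×, 0.5% errors. The property checks use: the full scene for the caller
benchmark (with an error-free variant for breakpoint exactness); 1000
random SNV configurations (n ≤ 200) plus a 10 Mb Poisson background for
the kataegis oracle; 20 + 20 samples × 2000 genes for null calibration
and 10 + 10 × 2000 with 50 planted 4× genes for sensitivity; 10,000
shuffled circles for the enrichment baseline; 500 RCA reads (k ∈ 1..5)
over 100 circles for reconstruction; 10,000 random SNVs for the spectrum
invariants. These sizes were chosen as the smallest at which the
binomial noise of the measured rates is well inside the asserted margins.

## Known limitations

* The caller is single-sample and does not assemble circle sequence from
  short reads; nested or overlapping circles are resolved only by the
  overlap tie-break.
* The circle score is this package's construction; absolute score values
  are not comparable to other callers, only the ≥ 200 threshold's intent
  is preserved.
* The abundance formula's absolute scale (1e6) is a convention; only
  ratios and ranks are meaningful across pipelines.
* Enrichment via `relative_enrichment` is kept for comparability but is
  length-biased (see above); prefer `enrichment`.
* The RCA module consumes PAF; it does not generate consensus sequence
  or polish bases, and with error-containing alignments the 20 bp
  tolerances, not the defaults here, become the binding parameters.
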