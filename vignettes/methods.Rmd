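---
title: "Methods: SV calling, optical cross-validation, and cross-line concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SV calling, optical cross-validation, and cross-line concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms, parameter choices and known
limitations behind `svconcord`. The package reconstructs, end to end, the
kind of analysis used to survey structural variants (SVs) among several
*de novo* assemblies of lines of one species against a common reference:
call SVs from whole-genome alignment, call large SVs independently from
optical (nick-label) maps, keep the sequence calls the maps confirm, and
use cross-line coincidence of SV breakpoints to quantify sharing and infer
a relationship tree.

# The simulated study

Real inputs for such a study are ~120 Mb assemblies; the package instead
ships a simulator whose output is a complete miniature study with known
truth. The default configuration (`default_config()`) builds:

* an **ancestor** of 5 Mb random uniform ACGT sequence over two
  chromosomes, with 150 tandem arrays (unit 15–30 bp, 6–15 copies) and 20
  copies of one dispersed 500 bp repeat family spliced in at recorded
  positions. The ancestor doubles as the reference genome.
* a **line tree** with five leaves,
  `(((L1:1,L2:1):0.6,(L3:1,L4:1):0.6):0.6,L5:2.2);` in abstract time
  units — four lines in two sister pairs and one diverged outgroup, with
  equal root-to-leaf path lengths (2.2). A **stem branch** of length 0.3
  above the root carries events present in *every* line; these model
  divergence specific to the reference genome, the source of loci shared
  by all lines in a real survey.
* **SV events** drawn per branch as Poisson(rate × branch length) with
  rate 45 per unit length, so each line carries roughly 100 events —
  about 22 SVs per Mb of genome, matching the per-Mb SV density of a
  multi-line fly comparison (~2,900 SVs per ~120 Mb line). Sizes are
  log-uniform on 50 bp–10 kb (the floor is the standard ≥ 50 bp SV
  definition; the shape is a choice, surfaced in the configuration, since
  real SV size spectra are heavy-tailed). Class weights default to 34%
  insertions, 34% deletions, 7% for each of the four copy-number classes,
  and 4% inversions (drawn uniform 10–30 kb), echoing the predominance of
  plain indels in alignment-based call sets.
* an **exon annotation** (300 genes, 2–6 exons of 100–400 bp, disjoint
  footprints) and per-line **label maps**: motif occurrences of the
  nicking site `CACGAG` on both strands, each label dropped with
  probability 0.1, false labels added at 1 per 100 kb, and inter-label
  distances perturbed multiplicatively by Normal(1, 0.005) before
  re-accumulation. One consensus map per chromosome is simulated directly;
  molecule-level assembly is out of scope.

## Placement rules that make truth unambiguous

Planted loci are pairwise disjoint on the reference and kept at least
5 kb apart (`min_spacing`), at least 25 kb from chromosome ends
(`end_margin`), and indel/inversion junctions are re-drawn until free of
flanking micro-homology. These rules exist to make the truth↔call
correspondence exact:

* *Spacing.* The mean label spacing for a 6-bp motif counted on both
  strands is 4⁶/2 ≈ 2 kb. Two events inside one inter-label interval are
  physically confounded on a map — only their net size is measurable — so
  loci are separated by more than a typical label interval. (A real survey
  needs no such rule because it measures genomes as they are.)
* *End margin.* Detecting an event from a map requires aligned labels on
  both sides; a chromosome end provides none, so events are kept away from
  ends.
* *Micro-homology.* If the first deleted base equals the base that follows
  the deletion, maximal exact alignment extends one base into the deleted
  sequence and the observed breakpoint shifts. Re-drawing junctions until
  all four junction bases differ makes planted breakpoints exactly
  recoverable, so indel calls can be held to ±1 bp.

## Where the copy-number classes are planted

The six-class gap decision table (below) is this package's normative
definition of the classes, and the simulator plants events whose alignment
signature *provably* matches their intended class. For a tandem array of
span `s` and unit `u`, exact-match anchors extend into the array from both
sides; a gain of `m·u` bp is classified *tandem* expansion when
`m·u ≥ s` (the anchors overlap on the reference only) and *repeat*
expansion when `m·u < s` (they overlap on both genomes); losses mirror
this relative to the remaining span. The simulator therefore plants all
four copy-number classes as copy-number changes of recorded tandem arrays,
choosing `m` with a ≥ 50 bp margin on the deciding inequality; dispersed
repeat copies remain in the genome as alignment-opaque background (no
unique seeds inside them). Planting "repeat" events at dispersed copies
instead would produce tandem-class signatures under exact-match anchoring
and make exact class recovery impossible.

## What the simulation does *not* emulate

No substitutions or small indels (assemblies are exact copies apart from
SVs), no sequencing or assembly errors, no heterozygosity, no
translocations, no nested or overlapping SVs, uniform base composition,
a single dispersed-repeat family. Perfect recovery on these genomes
therefore demonstrates the correctness of the gap classification, the
coincidence matching and the tree machinery — not robustness to assembly
noise, which in real use is delegated to an external aligner via PAF
input.

# Sequence SV calling

**Anchoring.** Seeds are canonical k-mers (k = 21) occurring exactly once
in each genome, extended to maximal exact matches in both orientations
(compiled code; per-diagonal bookkeeping makes extension near-linear).
Exact matching suffices because the simulated genomes differ only
structurally; substitution-tolerant alignment is delegated to external
aligners, whose PAF (+`cg:Z` CIGAR) can be read directly, with I/D runs
≥ 50 bp inside an alignment extracted as insertions/deletions.

**Chaining and filtering.** Greedy chaining joins co-linear same-strand
anchors when reference and query gaps are ≤ 50 kb (above the size of the
large majority of SVs); anchors overlapping a chain tail by more than half
their length are dropped. Match filters retain blocks ≥ 500 bp always and
blocks in [100, 500) bp only within a chain that keeps ≥ 2 blocks.

**Gap classification.** For consecutive blocks, with reference gap `r`,
query gap `q` (signed; negative = overlap) and size `s = q − r`,
`50 ≤ |s| ≤ 50000`:

| `s > 0` | `s < 0` | condition |
|---|---|---|
| insertion | deletion | `r ≥ 0` and `q ≥ 0` |
| tandem_expansion | tandem_contraction | overlap on one genome only |
| repeat_expansion | repeat_contraction | `r < 0` and `q < 0` |

Ties with `s = 0` are never called. The reported interval is
`[min(ref_end₁, ref_start₂), max(ref_end₁, ref_start₂))`; insertions get a
zero-length anchor point.

**Inversions.** A maximal run of minus-strand blocks whose reference span
is flanked by plus-strand blocks of the same query chromosome, with the
run's query coordinates falling between the flanks, is an inversion over
the run's span (default floor 10 kb). A whole-chromosome reverse-complement
alignment has no plus flank and is deliberately not called.

# Optical-map SV detection

**Digestion.** The reference digest is the sorted, deduplicated set of
motif occurrence positions on both strands.

**Alignment.** A banded dynamic program over label pairs maximizes

```
Σ match_bonus − sizing_cost(Δq, Δr) − miss_penalty·(skipped ref labels)
                                     − false_penalty·(skipped query labels)
```

with at most `band = 5` consecutive skips per step and free leading and
trailing skips. The sizing cost is `w·|Δq − Δr| / max(Δr, 1000)` with
`w = 150`, **capped at 12 when `|Δq − Δr| ≥ 800`**; a capped
("SV-opening") step also waives its per-label skip charges. The default
economics were derived from explicit failure analyses on planted truth:

* a positive `match_bonus` (6) is required at all — under the raw penalty
  sum the empty matching would be optimal — and must exceed the expected
  per-pair noise cost by enough that an alignment crossing many SVs stays
  profitable end to end rather than restarting after each event;
* the weight is high so that pairing a label a few hundred bp off register
  (absorbing part of an SV into a neighbouring interval, or "bridging" a
  nearby deletion/insertion pair through phantom matches to deleted and
  inserted labels) costs more than skipping it: at 2 kb spacing a 300 bp
  discrepancy costs 150·300/2000 ≈ 22, far above a skip;
* the cap makes spanning a true SV affordable (a bounded event-opening
  cost, like an affine gap-open), and waiving skip charges inside an
  opening step reflects that the labels inserted or deleted *by* the event
  are part of the event, not independent errors.

`miss_penalty = false_penalty = 3` — one skip costs as much as a
several-hundred-bp discrepancy on a typical interval, so the program
prefers skipping a missed or false label to distorting the register.

**Detection.** Per consecutive matched pair, `d = Δq − Δr` is the local
net size change. Because an inserted segment carries its own labels, a
single event may spread across adjacent intervals, so consecutive
intervals with `|d| ≥ 500` are aggregated and their *net* is the event
size (the distance change between the nearest well-aligned flanking
labels); nets ≥ 1 kb are reported — the 1 kb floor mirrors the resolution
of optical-map SV detection, and the 500 bp aggregation floor sits far
above the sizing noise (3σ ≈ 30 bp on a 2 kb interval at cv = 0.005)
while below any reportable event.

**Cross-validation.** A sequence SV is validated when an optical SV of the
same sign (gain classes vs optical insertions, loss classes vs optical
deletions) overlaps its interval padded outward to one flanking reference
label on each side — optical breakpoint uncertainty is bounded by label
spacing, so requiring direct interval overlap would be too strict and a
fixed pad would be arbitrary. One optical call may validate several
sequence SVs. Inversions are balanced (no net length change) and carry no
inter-label distance signal, so they cannot be optically validated by this
mechanism; they are reported by the sequence path only.

**Known limitation.** At the default event density (~22 carried SVs per
Mb, i.e. one event per ~45 kb with local Poisson clustering), a minority
of large events are confounded: when the only labels separating two
nearby events are lost to the 10% miss process, any aligner sees a single
interval whose net combines both events, and when several events crowd a
20–40 kb window the register between them can be mis-assigned. In this
regime the detector recovers most but not all (just under nine in ten)
planted size-changing events ≥ 2 kb, with recovery rising well above that
level when events are sparser; detection below 500 bp never occurs, by
construction of the floors. A noise-model-weighted (χ²) scorer with
iterative refinement, as production optical-map aligners use, would be
needed to close the remaining gap; it is out of scope here.

# Cross-line concordance

**Coincidence matching.** Records coincide when chromosome and class match
and both breakpoints agree within 3 bp. Loci are connected components of
the coincidence graph (single linkage via union–find): the pairwise rule
is silent about chains of near-matches (A–B and B–C within tolerance but
A–C outside it), and single linkage resolves them deterministically; the
consensus key is the component-wise minimum start / maximum end. Two
same-line records in one component keep a single presence cell and are
logged. Class identity is part of coincidence, reading "the identity of
each SV" as type identity.

**Sharing.** `pairwise_percent[i, j]` is row-normalized — the percentage of
line *i*'s loci that line *j* also carries — hence asymmetric;
`shared_in_all` counts all-ones rows.

**Distance and tree.** The Jaccard distance
`1 − |i ∩ j| / |i ∪ j|` on presence columns suits a binary matrix better
than a correlation distance (documented as the `method` argument for
extension). UPGMA (average linkage) via `stats::hclust` with leaves
pre-sorted lexicographically, so merge ties resolve toward the smallest
leaf. Two all-zero columns are defined to be at distance 0.

**BP and AU supports.** For each scale `r` in {0.5, …, 1.4}, `B = 1000`
resamples of `⌈r·n⌉` loci rows (with replacement, implemented as row
weights) are reclustered and each full-data clade's recovery frequency
`BP_r` recorded; `BP = 100·BP₁`. AU comes from the standard two-term
multiscale model: `z(r) = Φ⁻¹(1 − BP_r)` is fit as `z = v√r + c/√r` by
weighted least squares over scales with `0 < BP_r < 1` (weights are the
inverse delta-method variances `B·φ(Φ⁻¹(BP_r))²/(BP_r(1−BP_r))`), and
`AU = 100·(1 − Φ(v − c))`. Degenerate clades (every `BP_r` ∈ {0, 1}, or
fewer than two usable scales) fall back to `AU = 100·BP₁`. Sanity anchors:
`BP_r ≡ 0.5` gives `v = c = 0` and AU = 50; clades formed by identical
column groups are unbreakable and get BP = AU = 100.

# Exonic impact and rate

Intersection uses a sorted sweep with a pruned active-exon pool,
O((n+m) log(n+m)), equivalent to brute force. Half-open interval overlap
is positive-length for reference-consuming classes; a zero-length
insertion overlaps an exon iff its point lies strictly inside the exon.
Affected base pairs sum the overlap for reference-consuming classes;
an insertion at an exonic point contributes its full inserted length —
an insertion consumes no reference span yet adds that many bases into the
exon, so some such convention is forced; it is stated prominently because
it inflates insertion bp totals relative to overlap-based ones. The
pipeline (not the module) restricts impact input to cross-validated SVs.

The rate estimate is `sv_count / (2 · divergence_my · genome_mb)` — the
factor 2 counts both lineages separating a line from the reference since
their split. It is a transparent arithmetic normalization: with the
simulation's abstract branch lengths read as MY it makes no claim to
reproduce any particular empirical rate, whose inputs (calibrated
divergence times, mutation spectra) the simulation does not model.

# Numerical and engineering notes

* All internal coordinates are 0-based half-open; GFF3 (1-based closed) is
  converted on read/write via `rtracklayer`. PAF minus-strand query
  coordinates stay on the forward strand as PAF defines.
* Determinism: every stage seeds the RNG from the configuration seed;
  identical configurations give byte-identical outputs, and the presence
  matrix is invariant to the order lines are supplied (lines are sorted).
* Degenerate inputs: rate 0 yields empty truth, zero calls and a
  gracefully empty report; maps need ≥ 2 labels to align; empty SV files
  round-trip to empty tables.
* Problem sizes: the shipped study runs at a 5 Mb / 5-line scale
  (~400 events, ~2,500 labels per chromosome), where the full pipeline
  including a B = 1000 multiscale bootstrap completes in about a minute on
  one core; the test suite uses the same generator at 0.2–5 Mb scales.
* The anchor finder and the label-map DP are implemented in C++ (Rcpp);
  everything else is plain R over data frames.
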