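---
title: "Detecting horizontal transposon transfer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal transposon transfer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httscan)
```

# The inference problem

Horizontal transposon transfer (HTT) is the movement of a transposable
element between host species outside of descent.  Because any one signal
can be mimicked by other processes (rate variation, lineage sorting,
assembly gaps), HTT is argued from converging evidence.  `httscan`
operationalizes four streams for hAT-like DNA transposons and combines
them per species pair:

* **identity** — the cross-species TE divergence is far below the neutral
  expectation for the host split;
* **patchiness** — species more closely related to one member of the pair
  lack the element;
* **discordance** — the TE tree conflicts with the species tree;
* **independence** — no orthologous insertions are shared (empty sites at
  the homologous loci).

An `HTT` verdict requires the identity criterion plus at least one
corroborating criterion; a `vertical` verdict requires divergence
commensurate with the split *and* at least one shared orthologous
insertion; anything else is `inconclusive`.  This conjunction rule is one
defensible reading of how multi-evidence HTT cases are argued in the
literature; it is deliberate that no single criterion suffices.

# Sequence search

TE copies are found by seed-and-extend local alignment with the sensitive
scoring used for low-identity repeat searches: exact 7-mer seeds on both
strands, match +4, mismatch −5, affine gaps (open −8, extend −2; a gap of
length $L$ scores $-8 - 2L$).  Seeds are triaged by ungapped X-drop
extension (X = 20) and promoted to a banded gapped extension (half-width
16 diagonals, full traceback) only when the ungapped score already
reaches the reporting floor.  This trigger choice trades a little
sensitivity to heavily indel-ridden alignments for a large constant
factor; it is safe here because diverged-but-contiguous alignments are
dense in exact 7-mers, so every reportable region promotes some seed.

Noise is controlled by a raw-score floor (`min_score`, default 100)
rather than e-values, whose database-size statistics add nothing at this
scale.  For these scoring parameters and desk-scale search spaces, a raw
score of ~170 corresponds to a stringent e-value regime; 100 is therefore
*more* sensitive than a classic strict cutoff, and everything below it is
discarded anyway by the downstream 100 bp length and 75 % identity
filters.  Candidate full-length copies additionally require 90 % query
coverage.  Overlapping same-strand hits (≥ 50 % of the shorter span) are
merged, best score wins.  Identity is matches over aligned columns,
excluding gap columns; `N` never seeds and always counts as a mismatch.

# Structural hallmarks

hAT elements are bounded by ~15 bp terminal inverted repeats (TIRs) and
flanked by an ~8 bp target site duplication (TSD) created at integration.
`find_tirs()` returns the longest arm length in 10–30 bp whose prefix
matches the reverse complement of the suffix with at most 20 % mismatches
(a tolerant window centred on the canonical 15 bp); `find_tsd()` requires
an exact duplicated k-mer of 4–12 bp, longest wins — the conservative
reading of the hallmark, since no mismatch tolerance is part of its usual
definition.  Both bounds are configurable.  A copy is *full-length* when
both hallmarks are present and it covers ≥ 90 % of the family consensus;
coverage is counted as consensus positions paired with a copy base in a
global alignment, which unlike an end-to-end span is stable when several
gap placements tie.  The ORF screen reports the longest
ATG-to-stop reading frame over all six frames; ≥ 600 aa flags a copy as
transposase-coding-capable.

Hallmarks erode with age: a TSD survives unmutated with probability
$(1-d)^{16}$, under half at $d = 0.05$ per site.  Detection rates quoted
for the hallmark detectors therefore refer to divergence on the copy
itself with intact flanks; on old insertions the hallmarks are expected
to be partially lost, exactly as in real genomes.

# Divergence

The Kimura 2-parameter distance separates transition proportion $P$ from
transversion proportion $Q$ over comparable sites (gap and `N` columns
excluded):

$$K = -\tfrac12 \ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right].$$

When the log argument is non-positive the estimate is saturated: it is
flagged, and in landscapes the copy's bp are routed to the top bin rather
than dropped, so the binned total always equals the aligned input total.
No CpG adjustment is applied.

Divergence landscapes weight each copy's bin (default 1 % wide) by its
aligned bp.  Copies that are mostly short tandem repeats are excluded
(period ≤ 6 autocorrelation identity ≥ 0.8 — an explicit, testable
surrogate for the usual "simple repeat" exclusion).  Peaks are local
maxima filtered by topographic prominence.

**Alignment for distances.**  Copy-to-consensus and copy-to-copy
alignments use a plain global aligner (match +4, mismatch −5) with a
*linear gap of −16*.  The −6 gap used for the coverage alignment is too
cheap for distance work: at true $d = 0.30$ the optimizing DP converts
mismatch runs into indel pairs and deflates $K$ to ~0.22, while −16
recovers the simulated distance (coverage itself is insensitive to the
choice).  Cross-species TE divergence in the pipeline is the *minimum*
copy-pair $K$ over the top 3 copies per species, computed through
consensus-coordinate projections.  The minimum is the right statistic for
HTT screens — it captures the most recently shared copies — and it is
also necessary here: independent copies of one insertion burst coalesce
at the burst, not along the species tree, so one arbitrary representative
per species does not carry the species-tree signal, whereas taking 3 of
≤ 5 copies per species guarantees (by pigeonhole) that orthologous pairs
enter the minimum.  Pairs with fewer than 300 comparable sites are
excluded from the minimum as too noisy.

# Trees and discordance

TE trees are neighbor-joining trees on the K2P matrix.  Distance trees
suffice because the discordance argument needs topology only; this keeps
the inference fully specified inside the package instead of delegating to
an external maximum-likelihood engine.  Both trees are pruned to their
shared leaves and compared unrooted; the Robinson–Foulds distance is
normalized by $2(n-3)$ and any positive value flags discordance (at least
4 shared leaves are required, otherwise discordance is undefined and the
criterion is simply unavailable to the caller).  Nodes are not collapsed
by bootstrap support before comparison.

# The presence/absence test

For each insertion, 1500 bp flanks are taken on each side (clipped at
contig edges, clip recorded) and searched in the target genome; flank
hits under 100 bp or 75 % identity are discarded.  The decision is made
on the geometry of a co-linear flank pair (same contig and strand,
correct order), using junctions *projected* from the hit endpoints —
extrapolating across any unaligned flank tail so that trimmed alignments
still point at the insertion point:

* **shared** — inter-flank gap within 0.5–1.5 × the TE length;
* **absent (empty site)** — gap ≤ 50 bp; small negative gaps down to
  −100 bp are allowed because the target site duplication makes the two
  flank images overlap by up to ~TSD length;
* **unresolved** — anything else, including missing or rearranged flanks.

Among candidate pairs the classifier prefers *junction-anchored* hits —
minimal unaligned proximal overhang — over best-scoring ones: a flank hit
interrupted by a target-specific insertion near the junction would
otherwise overshoot the projected junction and misread the gap.  These
explicit rules replace a by-eye dot-plot judgment with something
computable and testable; all thresholds sit in the `presence` section of
`default_run_config()`.

# The caller

With a species tree in substitutions/site, the neutral expectation for a
pair is its patristic distance; with a divergence-time tree in MY it is
$2rT$ and the substitution rate $r$ must be supplied explicitly — there
is deliberately no default rate, and without one the identity criterion
is skipped rather than fabricated, leaving calls to rest on the remaining
criteria (flagged by the reported criteria set).  The identity bar is
`te_k2p ≤ 0.5 · expected_K`; the ratio is always reported so users can
apply their own bar.  A vertical call requires `ratio ≥ 0.6`: the
minimum-pair statistic is biased downward by one to two standard errors
and fragment pairs add variance, so demanding ~1 would misroute genuinely
vertical elements, while 0.6 still clears the 0.5 HTT bar.  Direction of
transfer is never inferred; calls are symmetric in the pair.

# The simulator

`simulate_scenario()` generates an ancestral background genome (default
50 kb, GC 0.42) and evolves it down a clock-like species tree under the
exact K2P transition process (default transition/transversion rate ratio
$\kappa = \alpha/2\beta = 2$, a typical nuclear value; $\kappa = 0.5$ is
the Jukes–Cantor limit).  Sites are independent and there are no indels
outside TE insertion and truncation, which keeps every truth value
analytically checkable and makes the simulator the exact generative twin
of the estimator.

Insertion events place pristine consensus copies (default 3 kb, 15 bp
TIRs, 8 bp TSD, 5 copies per burst) at uniform positions.  Vertical
events sit on internal branches (or above the root, pre-aging the element
by the excess) and their copies are inherited as orthologous insertions
by all descendants; horizontal events insert into one recipient's
terminal branch, so copy divergence reflects only the time since
transfer.  A fraction of copies (default 0.2) is truncated on one side
(retained fraction uniform in 0.3–0.9) and inserted without a TSD,
defeating hallmark detection as real fragments do.  Positions are
rejected inside existing copies, within 150 bp of them, within 1600 bp of
contig ends, and within 150 bp of any previous insertion's
background-homologous position across all species.  The last rule
excludes cross-lineage homoplasy — two independent insertions at (nearly)
the same orthologous spot — which no flank-geometry test can resolve and
which at realistic genome sizes is vanishingly rare; at the 50 kb
simulation scale it would otherwise occur in a noticeable fraction of
runs purely as a small-genome artifact.

The default study conditions are a six-species ultrametric tree of depth
0.10 substitutions/site (sister splits at 0.04–0.06): `vertical_scenario()`
puts one burst above the root at 0.15; `htt_scenario()` adds a recent
transfer (0.005 — under 1 % divergence, the young-copy signature) into
each of two random non-sister recipients on top of that old vertical
background, the realistic case of genomes that already carry ancient
relatives of the family.  A pure-transfer variant
(`background_time = NULL`) and a two-species ancestral-plus-independent
layout for presence/absence work are also provided.

What the simulator does *not* emulate: insertion-site preferences,
nesting, segregating polymorphism, selection, GC/CpG rate heterogeneity,
genome rearrangement, and assembly artifacts (gaps, collapsed repeats).
Passing tests on this generator demonstrate that the inference machinery
recovers truth under its own model assumptions — substitution-only
divergence and clean assemblies — not that it is robust to everything
real genomes do.

# Numerical and reproducibility choices

* Coordinates are 0-based half-open everywhere, including BED output;
  1-based appears only in human-readable text.
* Ambiguity codes collapse to `N` on input; `N` is excluded from
  comparable sites and TSD calls, counts as a TIR/search mismatch, and
  scores 0 in global alignments.
* All randomized operations take explicit seeds; identical (inputs,
  config, seed) give byte-identical outputs, and `write_run_manifest()`
  records the config MD5 and seed.
* Ties: TIR/TSD detection returns the longest qualifying length; hit
  merging keeps the best score; flank-pair choice breaks overhang ties by
  score; NJ and RF are deterministic in their inputs.
* Saturated K2P values are flagged, never silently dropped: top bin in
  landscapes, max-defined-distance in matrices.

Problem sizes in the shipped tests were chosen to make each check sharp
but quick on a single CPU: 10 kb × 200 replicates for estimator recovery,
≤ 500 bp instances against the exhaustive Smith–Waterman oracle, 50 kb
genomes with 5–20 copies for scenario work, and 20 seeded scenarios for
the end-to-end verdict check.

# Known limitations

* Copy boundaries come from local alignment and can be trimmed by a few
  terminal mismatches on diverged copies, which then hides the TSD; no
  boundary-refinement pass is implemented, so hallmark statistics are
  most meaningful for young copies (where they matter for HTT).
* The empty-site rule cannot distinguish a truly absent insertion from a
  precise excision, and a coincidental independent insertion at the same
  site would look shared; both are intrinsic to the flank-geometry
  approach.
* The minimum-K2P statistic is conservative by construction; its
  downward bias is absorbed by the `vertical_min` margin but makes the
  reported ratio a lower bound, not an unbiased age estimate.
* Attribution of secondary landscape peaks (e.g. to unrelated degraded
  relatives of the family) is left to the user; the package reports the
  peaks, not their identity.
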