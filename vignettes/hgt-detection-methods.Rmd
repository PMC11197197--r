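---
title: "Detecting horizontal gene transfer in plant mitochondrial genomes with hgtscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal gene transfer in plant mitochondrial genomes with hgtscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Plant mitochondrial genomes are promiscuous: besides their native gene
repertoire they accumulate plastid-derived DNA moved within the same cell
(native MTPTs) and, more strikingly, DNA acquired horizontally from other
species — both mitochondrion-derived and plastid-derived (foreign MTPTs).
In lianescent gymnosperms such as Asian *Gnetum*, foreign angiosperm DNA can
amount to several percent of a megabase-scale mitogenome. Detecting that
foreign DNA, naming its donor lineages, and deciding whether it arrived as
genomic DNA or as a reverse-transcribed mRNA copy requires a chain of
analyses that are usually run ad hoc. hgtscan packages that chain as tested,
composable functions: every stage takes a tibble and returns a tibble, so a
whole analysis is a pipe.

The package also ships the generative counterpart of the analysis: a
chimeric-genome simulator with a complete truth table, so each stage — and
the pipeline end to end — is validated by recovery of known ground truth
rather than by eyeballing.

## Windowed homology classification

The genome is clipped into non-overlapping 1-kb windows
(`extract_windows()`), each searched against a taxonomically labeled
reference panel (`search_windows()`), and each classified by which taxon
groups it matches (`classify_windows()`).

The search is a desk-scale analogue of megablast: exact 28-mer seeds located
through a hash index over both strands of the panel, seed clusters extended
by full affine-gap local alignment, hits filtered at E ≤ 1e-10 and capped at
100 targets per window. Scoring is match +1, mismatch −2, gap open −5, gap
extend −2 (the megablast-like defaults); the E-value uses the Karlin–Altschul
form E = K·m·n·e^(−λS) with the ungapped DNA constants K = 0.41, λ = 0.625
applied to the gapped score. This is a documented approximation — exact
gapped statistics are out of scope — and it is deterministic, which matters
more here: the E-value only thresholds hits, all downstream decisions use
taxon identity of the hits. Alignments shorter than 50 bp are suppressed as
micro-hits. The local-alignment kernel is verified in the test suite against
an independent Smith–Waterman implementation.

Classification is a pure rule cascade over the hit groups:

1. a hit to the recipient genus' own plastome at identity ≥ 0.95 →
   **native MTPT** ("matched well" operationalized as near-identity, the only
   printed guidance being that native MTPTs are nearly identical to their
   plastid counterparts);
2. plastid-type hits exclusively from non-gymnosperm plastomes →
   **foreign MTPT**;
3. mitochondrial-type hits that include angiosperm mitogenomes and exclude
   non-congeneric gymnosperm mitogenomes → **foreign mitochondrion-derived**;
4. any remaining hit to a gymnosperm or congeneric mitogenome → **native**;
5. no qualifying hits → **unclassified**, treated downstream as native of
   unknown affinity and never counted as foreign (the burden of evidence is
   on the HGT call).

When a window carries both kinds of foreign evidence, the best E-value wins,
ties resolve by identity and then by the priority foreign-mito >
foreign-MTPT; the choice is arbitrary but deterministic.

### Segment boundaries

Windows are a search unit, not a biological one. Merging runs of foreign
windows into segments (`merge_segments()`) would leave boundary errors of up
to a window on each side: the window containing an insertion boundary is
usually classified native, because its native half hits the gymnosperm
panel. hgtscan therefore refines segment edges with the homology evidence
itself: terminal windows are trimmed to the span covered by the segment's
donor-group hits, and a flanking window whose donor-group hits abut the
segment boundary extends the segment to the extent of those hits. Since
donor homology ends where the insert ends, this recovers boundaries to
within a few bases and is what lifts per-base precision and recall of
foreign calls above 0.95 in the recovery tests.

`summarize_genome()` then reports per-category totals and the foreign
fraction, rounded to one decimal place, reproducing the published
worked-example arithmetic exactly when fed the printed per-category totals.

## Donor inference

Each foreign gene is aligned with homologs (`align_homologs()`: progressive
alignment over an average-linkage guide tree of shared 6-mer distances,
profile–profile merges under match +1, mismatch −1, gap open −4, gap extend
−1), distances are Jukes–Cantor (`jc_distance()`; p ≥ 0.75 is capped at
d = 5 with a saturation flag; pairs sharing fewer than 50 ungapped columns
are an error), trees are neighbor joining (`build_nj_tree()`), and supports
come from the standard nonparametric bootstrap (`bootstrap_support()`).

The reference analysis used MAFFT, IQ-TREE maximum likelihood with automatic
model selection, and 5000 ultrafast bootstraps. hgtscan deliberately
replaces that stack with NJ + JC + 1000 standard bootstrap replicates. This
is a fidelity reduction, chosen because the package's donor question is a
*label-recovery* problem on alignments where the foreign gene sits a few
percent divergence from its donor: at that depth NJ recovers the same sister
relationships ML would, in seconds rather than hours, with no external
binaries. NJ tie-breaking is deterministic (smallest Q, then the
lexicographically smallest taxon pair), negative branch lengths are clamped
to zero, and the implementation provably recovers every additive topology
(tested exhaustively against random additive matrices up to 7 taxa). Trees
are evaluated unrooted; outgroup taxa marked in the taxonomy map are used
only to keep the outgroup side from being picked as a sister, mirroring
display rooting with a fern outgroup.

`call_donor()` applies the sister-clade rule: the sister is the minimal leaf
set across the foreign leaf's attachment, the support is the bootstrap
percentage of the bipartition grouping the foreign leaf with that sister,
and the donor is assigned only when that support strictly exceeds 50% *and*
the sister taxa are exclusively angiosperm. An all-invariant alignment
carries no signal; rather than report the 100% support a degenerate
resampling would produce, supports are reported as 0 with a `no_signal`
flag.

## RNA editing and the retroprocessing test

C-to-U editing sites are called from pileup evidence
(`call_editing_sites()`): coding-strand C, depth ≥ 10, T fraction among
mapped bases ≥ 0.1. The source method's exact thresholds are not reprinted
in the text this design follows, so both are exposed as arguments; the
defaults are ordinary RNA-seq practice (10 reads is where a 10% minor
fraction becomes distinguishable from sequencing error at ~1%). The reported
editing fraction is T/(C+T). Site effects compare the standard-code
translation before and after C→T; stop gains count as nonsynonymous in
summaries.

The retroprocessing test asks: at alignment columns where editing is
conserved among native homologs (≥ 2 annotated natives by default — the
figure legend this mirrors says only "conserved", so the quorum is a
parameter), does the foreign gene carry C (DNA-mediated transfer) or T
(integrated cDNA)? `retroprocessing_verdict()` requires ≥ 3 informative
sites and an 80% majority; anything between is `ambiguous`. Columns where
the foreign gene and exactly one native share a T are flagged as shared
substitutions at editing sites — evidence strengthening a donor link (the
donor lost the editing site by a genomic C→T), never a verdict changer.

## Expression

`compute_tpm()` normalizes counts by effective (annotated exonic) length and
rescales to a million; genes with zero mapped reads are kept at TPM 0, since
dropping them would bias the foreign-vs-native test toward significance.
`mann_whitney_u()` is self-contained: the exact two-tailed p-value by full
enumeration of the U distribution when n1·n2 ≤ 400 and there are no ties,
otherwise a normal approximation with tie correction and a 0.5 continuity
correction. The exact path is tested against complete enumeration of rank
assignments and against the reference implementation in `stats`.

## Shared foreign sequence across species

`find_exact_anchors()` enumerates maximal exact matches (≥ 50 bp, both
strands) between two genomes — the anchoring step a MUMmer run would
provide, validated against a brute-force all-diagonals oracle.
`shared_foreign_venn()` counts a foreign base as shared between two species
when an anchor intersecting foreign segments in both species covers it, and
builds the 7-region base-count Venn. The 50-bp floor sits just under the
smallest shared residue reported in the motivating analysis (61 bp).
Anchor coverage is counted in each species' own coordinate frame, so
pairwise regions are reported from both frames rather than collapsed —
published pairwise counts are themselves direction-dependent ranges.
Overlapping anchors are union-merged before counting to avoid double
counting.

## The simulator: what it emulates, and what it does not

`build_chimeric_genome()` emits a recipient mitogenome assembled from known
parts, with a complete truth table:

* a random backbone at GC 0.47 (the observed mitogenome regime) carrying 25
  native genes of 0.6–1.5 kb;
* C-to-U editing sites planted at ~10 sites/kb of native CDS, biased toward
  first and second codon positions (30/45/25%) so that roughly 80% of sites
  are nonsynonymous, as observed in these mitogenomes; editing fractions are
  Beta(8.5, 1.5) (mean 0.85);
* native MTPTs copied from a simulated recipient plastome at 99–100%
  identity;
* foreign segments totaling 14% of the genome (the upper end of the observed
  6.4–14.2% range), 2–12 kb each, cut from angiosperm donor mitogenomes that
  evolved from a common ancestor along a four-donor tree, then diverged a
  further 0.05–0.12 substitutions/site after transfer — so inserts sit at
  88–95% identity to their best panel match;
* one pseudogenized gene per foreign mitochondrial segment: at least one
  premature stop (codon overwritten with TAA) or 1-bp frameshift indel, at
  an expected 2 events/kb;
* a reference panel holding the recipient plastome, an unrelated angiosperm
  plastome, a gymnosperm mitochondrial relative at 0.08 substitutions/site
  from the backbone, and the donor mitogenomes — but never the recipient's
  own mitogenome, matching the realism of searching a database that does not
  contain the genome being analyzed.

Two deliberate simplifications: plastome-vs-plastome divergence between the
recipient genus and angiosperms is emulated by independent random sequences
(300 My of divergence is far beyond 28-mer seed detection anyway), and
simulated genes are intronless with uniform random composition — no codon
structure, no real editing context, no repeat families, no structural
rearrangement. Recovery results on this simulator therefore demonstrate that
the *pipeline logic* is correct under the stated divergence regime; they do
not measure robustness to compositional bias, repeats, or alignment over
introns, which real data would add.

Sequence evolution is exact Jukes–Cantor per branch (`evolve_sequences()`),
matching the analysis-side distance model, so generation and inference are
model-consistent; a transition bias is deliberately not defaulted on.
`simulate_editing_and_expression()` emits pileups (native editing sites
T-major at Beta-distributed fractions; foreign DNA-mode genes unedited) and
log-normal read counts with native meanlog 9 versus foreign meanlog 4 —
TPM regimes matching the published foreign range (single digits to
hundreds) against native thousands to hundreds of thousands. All simulator
output is byte-identical for a fixed seed and configuration.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package; GFF3 and
  the tabular output dialects convert at the boundary. Window math and
  interval algebra stay off-by-one-free that way.
* The trailing window of each chromosome keeps its remainder, whatever its
  length; windows under 100 bp are flagged `short` but still classified.
  Dropping genome ends silently would be worse than classifying a short
  window. Circular chromosomes are linearized at position 0 with no
  wrap-around window, matching circular-mapping chromosomes displayed as
  linear molecules.
* Gap cost is open + ext·length, the same convention as
  `Biostrings::pairwiseAlignment`, which is what makes oracle comparisons
  exact.
* The exact Mann–Whitney p at the distribution center (U = n1·n2/2) is 1 by
  construction; the continuity correction is clamped so p never exceeds 1.
* `jc_distance()` refuses incomplete matrices instead of imputing: a missing
  pair means the alignment cannot support the tree.

## Problem sizes

The shipped tests and the acceptance script exercise: a 500-kb chimeric
genome against a ~700-kb panel for classification recovery (about 90 s);
100 simulated foreign genes, each aligned over 9 taxa and bootstrapped 1000
times, for donor recovery (a few minutes); 200 retroprocessing cases; and
exact-vs-oracle sweeps for the alignment, anchoring, tree and rank-test
kernels. These sizes were chosen as the smallest at which the recovery
statistics are stable; all scale linearly if raised.

## Known limitations

* NJ + JC in place of ML: adequate for sister-label recovery at ≤ 0.15
  substitutions/site, not for deep or rate-heterogeneous phylogenies.
* Karlin–Altschul constants are ungapped approximations; E-values are
  comparable within a run, not calibrated against BLAST.
* Repeat annotation is out of scope; repeats are neither masked nor
  reported, and windows dominated by repeats will classify by whatever
  homology they show.
* The Venn quantification assumes single-sequence genomes per species (the
  simulator's shape); multi-chromosome genomes need per-sequence segment
  tables concatenated on a shared coordinate space first.
* The editing caller trusts the pileup's strand-aware orientation; it does
  not re-orient reads.
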