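# hgtscan

Detection of horizontal gene transfer (HGT) in plant mitochondrial genomes.

Plant mitogenomes — megabase-scale in some lineages — accumulate DNA from
three sources: their own native repertoire, plastid DNA moved within the
cell (native MTPTs), and DNA acquired horizontally from other species,
either mitochondrion-derived or plastid-derived (foreign MTPTs). hgtscan is
for researchers who have an assembled mitogenome plus a labeled reference
panel and want to answer, reproducibly: *how much of this genome is foreign,
where, from which donor lineages, by what mechanism, and is it expressed?*

Every stage takes a tibble and returns a tibble, so an analysis composes
with the pipe; a synthetic-data module generates chimeric genomes with known
truth so the whole pipeline is testable without any database access.

## What it computes

**Windowed homology classification.** The genome is clipped into 1-kb
non-overlapping windows, searched against the panel by seed-and-extend local
alignment (exact 28-mer seeds, affine-gap extension with match +1, mismatch
−2, gap open −5, gap extend −2; Karlin–Altschul E-value
E = K·m·n·e^(−λS), hits kept at E ≤ 10⁻¹⁰, ≤ 100 targets per window), and
classified by a taxon-match rule cascade: near-identical hits to the
recipient's own plastome are native MTPTs; plastid hits exclusively from
non-gymnosperm plastomes are foreign MTPTs; mitochondrial hits including
angiosperms but no other gymnosperm are foreign; anything hitting gymnosperm
or congeneric mitogenomes is native. Foreign windows merge into segments
whose boundaries are refined to the span of the donor-group homology
evidence, and the genome summary reports per-category totals and the
foreign fraction.

**Donor inference.** Each foreign gene is aligned with its homologs
(progressive alignment), distanced under Jukes–Cantor
(d = −¾ ln(1 − 4p/3)), built into a neighbor-joining tree, and
bootstrapped (1000 standard replicates). A donor is assigned when the
foreign gene is sister to an exclusively angiosperm clade with bootstrap
support > 50%.

**Retroprocessing test.** C-to-U RNA editing sites are called from pileups
(coding-strand C, depth ≥ 10, T fraction ≥ 0.1). At editing sites conserved
among native homologs, a DNA-mediated transfer leaves unedited **C** in the
foreign copy while an integrated reverse-transcribed mRNA leaves **T**; an
80% majority over ≥ 3 informative sites decides the verdict.

**Expression.** TPM per gene (count/length rates rescaled to 10⁶) and a
self-implemented two-tailed Mann–Whitney U test (exact by full enumeration
for small tie-free samples) of foreign versus native expression.

**Shared foreign sequence.** Maximal exact matches (≥ 50 bp, both strands)
anchor cross-species comparison; foreign bases covered by anchors landing in
foreign segments of both species fill a 7-region base-count Venn over three
species.

## Worked example

Simulate a 100-kb chimeric mitogenome with known truth, generate RNA
evidence, and run the full pipeline:

```r
library(hgtscan)

cfg <- simulation_config(seed = 42, recipient_genome_size = 100000,
                         n_native_genes = 8)
sim <- build_chimeric_genome(cfg)
evidence <- simulate_editing_and_expression(sim)
report <- run_pipeline(sim$genome, sim$annotations, sim$panel,
                       pileup = evidence$pileup, counts = evidence$counts,
                       n_boot = 1000, seed = 1)
report
```

```
<hgt_report>
# A tibble: 4 × 3
  stage      status note
  <chr>      <chr>  <chr>
1 classify   ok     ""
2 donors     ok     ""
3 editing    ok     ""
4 expression ok     ""

Genome summary:
# A tibble: 1 × 7
  genome_size gc_percent native_mtpt_bp foreign_mtpt_bp foreign_mito_bp
        <int>      <dbl>          <int>           <int>           <int>
1      100000         46           8000            4001            9334
# ℹ 2 more variables: foreign_total_bp <int>, foreign_fraction_percent <dbl>

Donor calls:
# A tibble: 2 × 5
  foreign_gene status       sister_label support_percent verdict
  <chr>        <chr>        <chr>                  <dbl> <chr>
1 fgene_02     foreign only MitoDonor_C             99.7 donor_assigned
2 fgene_04     foreign only MitoDonor_D             99.9 donor_assigned

C-to-U editing:
# A tibble: 1 × 4
  n_total n_nonsyn n_syn nonsyn_percent
    <int>    <int> <int>          <dbl>
1      87       56    31           64.4
Mann-Whitney U test (exact): U = 0, n = 2/8, two-tailed p = 0.04444
```

Reading this: of 100 kb, 13,335 bp (13.3%) was called foreign — 9,334 bp
mitochondrion-derived and 4,001 bp of foreign MTPT — alongside 8,000 bp of
native MTPT. Both simulated foreign genes were assigned to their true donor
taxa with ~100% bootstrap support. All 87 editing sites called are in native
genes (foreign genes show none, as expected for DNA-mediated transfer), and
the two foreign genes rank below all eight native genes in TPM (U = 0).
Comparing against the simulator's truth table:

```r
score_classification(report$segments, sim$truth$segments)
#> # A tibble: 1 × 5
#>   true_bp called_bp tp_bp precision recall
#>     <int>     <int> <int>     <dbl>  <dbl>
#> 1   13337     13335 13332     1.000  1.000
```

Per result type there are `autoplot()`/`plot_*()` views
(`plot_genome_map()`, `plot_expression()`, editing-state and Venn
autoplots) and broom-style `tidy()`/`glance()` methods.

A thin command-line wrapper (`inst/cli/hgtscan.R`) exposes `simulate`,
`classify` and `run` subcommands over the same functions.

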