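# one plus-strand and one minus-strand gene on a toy contig
toy_editing_fixture <- function() {
  withr::local_seed(61, .local_envir = parent.frame())
  seq <- rand_dna(600)
  substring(seq, 101, 103) <- "CCA"    # gene A codon 1 (0-based CDS 0..2)
  substring(seq, 301, 303) <- "TGG"    # gene B (minus strand): coding CCA
  genome <- tibble::tibble(id = "c", seq = seq, length = 600L)
  feats <- tibble::tibble(seq_id = "c", start = c(100L, 250L),
                          end = c(220L, 310L), strand = c("+", "-"),
                          kind = "gene", name = c("gA", "gB"),
                          parent = NA_character_, origin = "native",
                          pseudogene = FALSE)
  list(genome = genome, feats = feats)
}

test_that("editing sites are called only above depth and fraction thresholds", {
  fx <- toy_editing_fixture()
  pos <- 101L  # second base of CCA codon in gA: genomic C at 0-based 101
  pile <- function(depth, tcount)
    tibble::tibble(seq_id = "c", pos = pos, ref = "C", depth = depth,
                   A = 0L, C = depth - tcount, G = 0L, T = tcount)
  called <- call_editing_sites(pile(20L, 18L), fx$feats, fx$genome)
  expect_equal(nrow(called), 1)
  expect_equal(called$editing_fraction, 0.9)
  expect_equal(called$codon_pos, 1L)
  expect_equal(called$effect, "nonsynonymous")   # CCA Pro -> CTA Leu

  expect_equal(nrow(call_editing_sites(pile(20L, 1L), fx$feats, fx$genome)), 0)
  expect_equal(nrow(call_editing_sites(pile(5L, 5L), fx$feats, fx$genome)), 0)
})

test_that("minus-strand genes are called in transcript orientation", {
  fx <- toy_editing_fixture()
  # gB spans [250,310) on '-': CDS position of genomic pos p is 309 - p.
  # Genomic TGG at [300,303) reads CCA on the coding strand; its middle C is
  # genomic pos 301 (CDS pos 8, codon_pos 2).
  pileup <- tibble::tibble(seq_id = "c", pos = 301L, ref = "G", depth = 30L,
                           A = 0L, C = 6L, G = 0L, T = 24L)
  called <- call_editing_sites(pileup, fx$feats, fx$genome)
  expect_equal(nrow(called), 1)
  expect_equal(called$gene, "gB")
  expect_equal(called$editing_fraction, 0.8)
  expect_equal(called$codon_pos, 2L)
})

test_that("pileup positions outside any CDS are ignored with a warning", {
  fx <- toy_editing_fixture()
  pileup <- tibble::tibble(seq_id = "c", pos = 590L, ref = "C", depth = 30L,
                           A = 0L, C = 10L, G = 0L, T = 20L)
  expect_warning(out <- call_editing_sites(pileup, fx$feats, fx$genome),
                 "outside annotated CDS")
  expect_equal(nrow(out), 0)
})

test_that("codon effects follow the standard genetic code", {
  expect_equal(classify_site_effect("CCA", 1), "nonsynonymous")  # Pro -> Leu
  expect_equal(classify_site_effect("CTC", 2), "synonymous")     # Leu -> Leu
  expect_equal(classify_site_effect("CGA", 0), "stop_gain")      # Arg -> *
  expect_error(classify_site_effect("CNA", 0), "ambiguity")
  expect_error(classify_site_effect("ATG", 0), "must hold a C")
})

test_that("editing summaries recompute the published percentages exactly", {
  gp <- summarize_editing(n_nonsyn = 269, n_syn = 75)
  expect_equal(gp$n_total, 344)
  expect_equal(gp$nonsyn_percent, 78.2)
  gu <- summarize_editing(n_nonsyn = 267, n_syn = 71)
  expect_equal(gu$n_total, 338)
  expect_equal(gu$nonsyn_percent, 79.0)
  expect_equal(summarize_editing(n_nonsyn = 0, n_syn = 10)$nonsyn_percent, 0)
  expect_true(is.na(summarize_editing(n_nonsyn = 0, n_syn = 0)$nonsyn_percent))
  # stop gains count as nonsynonymous
  sites <- tibble::tibble(effect = c("stop_gain", "nonsynonymous", "synonymous"))
  expect_equal(summarize_editing(sites)$n_nonsyn, 2)
})

test_that("conserved-site detection requires the configured native quorum", {
  s <- rand_dna(60)
  al <- align_homologs(tibble::tibble(taxon = c("n1", "n2", "n3", "f"),
                                      seq = rep(s, 4)))
  ann3 <- tibble::tibble(taxon = c("n1", "n2", "n3"), pos = 10L)
  expect_equal(predict_conserved_sites(al, ann3, min_taxa = 2), 11L)
  ann1 <- tibble::tibble(taxon = "n1", pos = 10L)
  expect_equal(length(predict_conserved_sites(al, ann1, min_taxa = 2)), 0)
  bad <- tibble::tibble(taxon = "n1", pos = 400L)
  expect_error(predict_conserved_sites(al, bad), "beyond sequence length")
})

test_that("state matrix records gaps and flags donor-shared substitutions", {
  al <- aln_from_rows(n1 = "ACGTCA", n2 = "ACGTCA", donor = "ATGTCA",
                      f = "AT-TCA")
  m <- editing_state_matrix(al, conserved_cols = c(2L, 3L, 5L),
                            foreign_taxon = "f")
  expect_equal(unname(m["f", ]), c("T", "gap", "C"))
  expect_equal(unname(m["n1", ]), c("C", "other", "C"))
  # foreign and exactly one native (donor) share T at column 2
  expect_equal(attr(m, "shared_T_columns"), 2L)
})

test_that("retroprocessing verdicts follow the editing-state majority", {
  al <- aln_from_rows(n1 = strrep("C", 10), n2 = strrep("C", 10),
                      fC = strrep("C", 10), fT = strrep("T", 10),
                      fMix = paste0(strrep("C", 5), strrep("T", 5)))
  m <- editing_state_matrix(al, 1:10)
  expect_equal(retroprocessing_verdict(m, "fC")$verdict, "dna_mediated")
  expect_equal(retroprocessing_verdict(m, "fT")$verdict, "retroprocessed")
  expect_equal(retroprocessing_verdict(m, "fMix")$verdict, "ambiguous")

  m2 <- editing_state_matrix(al, 1:2)
  v2 <- retroprocessing_verdict(m2, "fC", min_sites = 3)
  expect_equal(v2$verdict, "ambiguous")
  expect_true(v2$insufficient_data)
  expect_error(retroprocessing_verdict(m, "nope"), "not in state matrix")
})
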