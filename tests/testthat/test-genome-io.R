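test_that("FASTA records load with correct lengths, case folding and taxonomy", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "ACGTACGT", ">chr2", "ggccggccgg"), fa)
  g <- read_genome(fa)
  expect_equal(g$id, c("chr1", "chr2"))
  expect_equal(g$length, c(8L, 10L))
  expect_equal(g$seq[2], "GGCCGGCCGG")
  expect_equal(g$taxon, c("unknown", "unknown"))

  tax <- tibble::tibble(id = "chr1", taxon = "Gnetum_sp",
                        compartment = "mitochondrial", group = "other")
  g2 <- read_genome(fa, taxonomy = tax)
  expect_equal(g2$taxon, c("Gnetum_sp", "unknown"))
  expect_equal(g2$compartment, c("mitochondrial", "unknown"))
})

test_that("invalid FASTA content is rejected", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT123ACGT"), fa)
  expect_error(read_genome(fa), "non-IUPAC")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), fa)
  expect_error(read_genome(fa), "duplicate")
  expect_error(read_genome(file.path(tempdir(), "no_such.fa")), "not found")
})

test_that("write then read round-trips id and sequence", {
  g <- tibble::tibble(id = c("s1", "s2"),
                      seq = c(rand_dna(137), rand_dna(2049)))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, fa)
  back <- read_genome(fa)
  expect_equal(back$id, g$id)
  expect_equal(back$seq, g$seq)
})

test_that("windows tile each sequence completely and keep the remainder", {
  g <- tibble::tibble(id = "x", seq = rand_dna(3000), length = 3000L)
  w <- extract_windows(g, 1000)
  expect_equal(nrow(w), 3)
  expect_equal(w$start, c(0L, 1000L, 2000L))
  expect_equal(w$end, c(1000L, 2000L, 3000L))

  g2 <- tibble::tibble(id = "x", seq = rand_dna(2500), length = 2500L)
  w2 <- extract_windows(g2, 1000)
  expect_equal(nrow(w2), 3)
  expect_equal(c(w2$start[3], w2$end[3]), c(2000L, 2500L))

  g3 <- tibble::tibble(id = "x", seq = rand_dna(999), length = 999L)
  w3 <- extract_windows(g3, 1000)
  expect_equal(nrow(w3), 1)
  expect_equal(w3$end, 999L)

  expect_error(extract_windows(g, size = 50), "at least 100")
})

test_that("window tiling reconstructs the genome for arbitrary lengths", {
  withr::local_seed(41)
  for (len in sample(100:5000, 8)) {
    g <- tibble::tibble(id = "r", seq = rand_dna(len), length = len)
    w <- extract_windows(g, 1000)
    expect_equal(sum(w$width), len)
    expect_false(is.unsorted(w$start))
    expect_equal(paste(w$seq, collapse = ""), g$seq)
  }
})

test_that("GFF3 coordinates convert between 1-based and 0-based half-open", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=gA;origin=foreign;pseudo=true",
               "chr1\tsrc\texon\t1\t40\t.\t+\t.\tID=gA.e1;Parent=gA",
               "chr1\tsrc\texon\t51\t80\t.\t+\t.\tID=gA.e2;Parent=gA",
               "chr1\tsrc\texon\t91\t100\t.\t+\t.\tID=gA.e3;Parent=gA"), gff)
  feats <- read_annotations(gff)
  gene <- feats[feats$kind == "gene", ]
  expect_equal(c(gene$start, gene$end), c(0L, 100L))
  expect_true(gene$pseudogene)
  expect_equal(gene$origin, "foreign")
  expect_equal(sum(feats$kind == "exon" & feats$parent == "gA", na.rm = TRUE), 3)
})

test_that("GFF3 round trip preserves coordinates and attributes", {
  feats <- tibble::tibble(seq_id = "c", start = c(0L, 249L), end = c(100L, 1000L),
                          strand = c("+", "-"), kind = "gene",
                          name = c("a", "b"), parent = NA_character_,
                          origin = c("native", "foreign"),
                          pseudogene = c(FALSE, TRUE))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotations(feats, gff)
  back <- read_annotations(gff)
  expect_equal(back[names(feats)], feats)
})

test_that("malformed annotations are rejected", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines("chr1\tsrc\tgene\t100\t50\t.\t+\t.\tID=g", gff)
  expect_error(read_annotations(gff), "end < start")
  writeLines("chr1\tsrc\tgene\t1\t50\t.\t?\t.\tID=g", gff)
  expect_error(read_annotations(gff), "strand")
  writeLines("chr1\tsrc\tgene\t1\t500\t.\t+\t.\tID=g", gff)
  genome <- tibble::tibble(id = "chr1", seq = rand_dna(100), length = 100L)
  expect_error(read_annotations(gff, genome), "extends past")
})
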