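wtab <- windows_of("native_mito")[, 1:7]   # one bare window for classify tests

classify_with <- function(hits, ...) {
  classify_windows(wtab, hits, ...)$category
}

test_that("the taxon-match rule cascade reproduces the published rules", {
  # near-identical hit to the recipient genus' plastome -> native MTPT
  expect_equal(classify_with(make_hit("gnetum_plastid", identity = 0.99)),
               "native_MTPT")
  # plastid hits exclusively from non-gymnosperm plastomes -> foreign MTPT
  expect_equal(classify_with(make_hit("non_gymnosperm_plastid")), "foreign_MTPT")
  # angiosperm mito hits without other-gymnosperm mito hits -> foreign mito,
  # even when congeneric mito hits coexist
  expect_equal(classify_with(dplyr::bind_rows(make_hit("angiosperm_mito"),
                                              make_hit("gnetum_mito"))),
               "foreign_mito")
  # a gymnosperm mitochondrial hit vetoes the foreign call
  expect_equal(classify_with(dplyr::bind_rows(
    make_hit("angiosperm_mito"), make_hit("non_gnetum_gymnosperm_mito"))),
    "native_mito")
  # a weak plastome hit does not qualify as native MTPT
  expect_equal(classify_with(make_hit("gnetum_plastid", identity = 0.80)),
               "unclassified")
  # no hits at all
  expect_equal(classify_with(make_hit("other")[0, ]), "unclassified")
})

test_that("classification is a pure function of the hit set, not its order", {
  hits <- dplyr::bind_rows(make_hit("angiosperm_mito", evalue = 1e-40),
                           make_hit("gnetum_mito", evalue = 1e-20),
                           make_hit("non_gymnosperm_plastid", evalue = 1e-60))
  cats <- vapply(list(1:3, 3:1, c(2, 3, 1)), function(ord)
    classify_with(hits[ord, ]), character(1))
  expect_equal(length(unique(cats)), 1)
  # dual foreign evidence resolves by best E-value (plastid hit is strongest)
  expect_equal(cats[1], "foreign_MTPT")
})

test_that("runs of foreign windows merge with bounded gap absorption", {
  f3 <- windows_of(c("foreign_mito", "foreign_mito", "foreign_mito"))
  seg <- merge_segments(f3)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length, 3000L)

  fnf <- windows_of(c("foreign_mito", "native_mito", "foreign_mito"))
  expect_equal(nrow(merge_segments(fnf)), 2)

  fuf <- windows_of(c("foreign_mito", "unclassified", "foreign_mito"))
  expect_equal(nrow(merge_segments(fuf, max_gap_windows = 0)), 2)
  seg1 <- merge_segments(fuf, max_gap_windows = 1)
  expect_equal(nrow(seg1), 1)
  expect_equal(c(seg1$start, seg1$end), c(0L, 3000L))

  shuffled <- windows_of(c("foreign_mito", "foreign_mito"))[2:1, ]
  expect_error(merge_segments(shuffled), "sorted")
})

test_that("segment boundaries are refined by donor-group hit evidence", {
  # three windows; the middle one is fully foreign, flanks are mixed, and the
  # donor-group hits delimit the true insert [700, 2300)
  w <- windows_of(c("native_mito", "foreign_mito", "native_mito"))
  hits <- dplyr::bind_rows(
    dplyr::mutate(make_hit("angiosperm_mito", window_index = 1L),
                  g_start = 700L, g_end = 1000L),
    dplyr::mutate(make_hit("angiosperm_mito", window_index = 2L),
                  g_start = 1000L, g_end = 2000L),
    dplyr::mutate(make_hit("angiosperm_mito", window_index = 3L),
                  g_start = 2000L, g_end = 2300L))
  seg <- merge_segments(w, hits)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(700L, 2300L))
})

test_that("genome summary arithmetic matches the published worked examples", {
  gg <- summarize_genome(foreign_mtpt_bp = 1664, foreign_mito_bp = 34971,
                         genome_size = 575501)
  expect_equal(gg$foreign_total_bp, 36635)
  expect_equal(gg$foreign_fraction_percent, 6.4)

  gu <- summarize_genome(foreign_mtpt_bp = 6227, foreign_mito_bp = 188386,
                         genome_size = 1372030)
  expect_equal(gu$foreign_total_bp, 194613)
  expect_equal(gu$foreign_fraction_percent, 14.2)

  none <- summarize_genome(segments = merge_segments(windows_of("native_mito")),
                           genome_size = 10000)
  expect_equal(none$foreign_total_bp, 0)
  expect_equal(none$foreign_fraction_percent, 0)

  expect_error(summarize_genome(foreign_mtpt_bp = 0, foreign_mito_bp = 0,
                                genome_size = 0), "positive")
})

test_that("every window of a classified genome carries exactly one category", {
  withr::local_seed(21)
  g <- tibble::tibble(id = "mini", seq = rand_dna(6500), length = 6500L)
  w <- extract_windows(g)
  wc <- classify_windows(w, make_hit("other")[0, ])
  expect_equal(sum(wc$width), 6500L)
  expect_true(all(wc$category == "unclassified"))
})
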