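test_that("maximal exact matches behave on canonical small cases", {
  withr::local_seed(81)
  s <- rand_dna(200)
  one <- find_exact_anchors(s, s, min_len = 50)
  fw <- one[one$strand == "+", ]
  expect_equal(nrow(fw), 1)
  expect_equal(fw$length, 200L)

  # single substitution splits the match into [0,100) and [101,200)
  s2 <- s
  old <- substring(s, 101, 101)
  substring(s2, 101, 101) <- setdiff(c("A", "C", "G", "T"), old)[1]
  two <- find_exact_anchors(s, s2, min_len = 50)
  fw2 <- dplyr::filter(two, strand == "+")
  expect_equal(nrow(fw2), 2)
  expect_equal(sort(fw2$length), c(99L, 100L))

  none <- find_exact_anchors(rand_dna(1000), rand_dna(1000), min_len = 50)
  expect_equal(nrow(none), 0)

  expect_error(find_exact_anchors(s, s, min_len = 10), "spurious")
  expect_error(find_exact_anchors("", s), "non-empty")
})

test_that("minus-strand anchors are reported in forward coordinates", {
  withr::local_seed(82)
  a <- rand_dna(300)
  b <- paste0(rand_dna(50), rc(substring(a, 101, 200)), rand_dna(40))
  res <- find_exact_anchors(a, b, min_len = 60)
  rv <- dplyr::filter(res, strand == "-")
  expect_equal(nrow(rv), 1)
  # covers the planted region; maximal extension may add a few chance-matched
  # flanking bases
  expect_lte(rv$a_start, 100L); expect_gte(rv$a_end, 200L)
  expect_lte(rv$b_start, 50L); expect_gte(rv$b_end, 150L)
  # substring equality holds up to reverse complement
  expect_equal(substring(a, rv$a_start + 1, rv$a_end),
               rc(substring(b, rv$b_start + 1, rv$b_end)))
})

test_that("anchors equal the brute-force MEM set on sequences up to 2 kb", {
  withr::local_seed(83)
  for (case in 1:4) {
    base <- rand_dna(600)
    a <- paste0(rand_dna(300), base, rand_dna(200))
    b <- paste0(rand_dna(150), mutseq(base, 0.01), rand_dna(100),
                rc(substring(base, 50, 250)))
    mine <- find_exact_anchors(a, b, min_len = 40)[
      , c("a_start", "a_end", "b_start", "b_end", "strand")]
    ora <- mem_oracle(a, b, 40)
    expect_equal(as.data.frame(dplyr::arrange(mine, a_start, b_start, strand)),
                 as.data.frame(dplyr::arrange(ora, a_start, b_start, strand)),
                 ignore_attr = TRUE)
  }
})

test_that("Venn base counts recover the simulated sharing pattern", {
  trio <- simulate_shared_trio(seed = 17)
  sp <- names(trio$genomes)
  anchors <- list()
  for (i in 1:2) for (j in (i + 1):3)
    anchors[[paste(sp[i], sp[j], sep = "|")]] <-
      find_exact_anchors(trio$genomes[[sp[i]]], trio$genomes[[sp[j]]])
  vn <- shared_foreign_venn(trio$segments, anchors)

  k_of <- dplyr::count(trio$membership, segment)
  lens <- dplyr::distinct(dplyr::bind_rows(trio$segments), segment, length)
  expected_triple <- sum(lens$length[lens$segment %in% k_of$segment[k_of$n == 3]])
  triple <- dplyr::filter(vn, region == paste(sort(sp), collapse = "&"))
  expect_equal(unique(triple$bp), expected_triple)

  # additivity: each species' foreign total is conserved across its 4 regions
  for (s in sp) {
    tot <- sum(trio$segments[[s]]$length)
    expect_equal(sum(vn$bp[vn$frame == s]), tot)
  }

  # unique segments land in the species' unique region only
  uniq_segs <- k_of$segment[k_of$n == 1]
  for (s in sp) {
    mine <- trio$membership$segment[trio$membership$species == s]
    expected_unique <- sum(lens$length[lens$segment %in% intersect(uniq_segs, mine)])
    expect_equal(vn$bp[vn$region == paste(s, "only")], expected_unique)
  }
})

test_that("Venn counts are symmetric under species relabeling", {
  trio <- simulate_shared_trio(seed = 18, n_segments = 8)
  sp <- names(trio$genomes)
  anchors <- list()
  for (i in 1:2) for (j in (i + 1):3)
    anchors[[paste(sp[i], sp[j], sep = "|")]] <-
      find_exact_anchors(trio$genomes[[sp[i]]], trio$genomes[[sp[j]]])
  v1 <- shared_foreign_venn(trio$segments, anchors)
  # relabel: rotate species names
  rot <- c(sp_A = "sp_B", sp_B = "sp_C", sp_C = "sp_A")
  seg2 <- stats::setNames(trio$segments, unname(rot[names(trio$segments)]))
  an2 <- stats::setNames(anchors, vapply(names(anchors), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    paste(rot[p], collapse = "|")
  }, ""))
  v2 <- shared_foreign_venn(seg2[sp], an2)
  relabel <- function(region) {
    parts <- strsplit(region, "&| only")[[1]]
    paste(sort(unname(rot[parts])), collapse = "&")
  }
  for (r in unique(v1$region[grepl("&", v1$region)])) {
    expect_equal(sort(v2$bp[v2$region == relabel(r)]),
                 sort(v1$bp[v1$region == r]))
  }
})
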