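test_that("Jukes-Cantor transform matches the closed form and saturation cap", {
  # identical rows
  al0 <- aln_from_rows(a = strrep("ACGT", 30), b = strrep("ACGT", 30))
  expect_equal(unname(jc_distance(al0)["a", "b"]), 0)

  # p = 0.1 over 200 columns -> d = -(3/4) ln(1 - 4*0.1/3)
  base <- rand_dna(200)
  mism <- base
  substring(mism, 1, 20) <- chartr("ACGT", "CGTA", substring(base, 1, 20))
  al1 <- aln_from_rows(a = base, b = mism)
  expect_equal(unname(jc_distance(al1)["a", "b"]),
               -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-12)
  expect_equal(round(-0.75 * log(1 - 4 * 0.1 / 3), 4), 0.1073)

  # p = 0.8 -> capped at 5 with a saturation flag
  sat <- base
  substring(sat, 1, 160) <- chartr("ACGT", "CGTA", substring(base, 1, 160))
  al2 <- aln_from_rows(a = base, b = sat)
  d2 <- jc_distance(al2)
  expect_equal(unname(d2["a", "b"]), 5.0)
  expect_true(attr(d2, "saturated")["a", "b"])

  # insufficient overlap is an error
  short <- aln_from_rows(a = paste0(rand_dna(30), strrep("-", 170)),
                         b = paste0(strrep("-", 170), rand_dna(30)))
  expect_error(jc_distance(short), "fewer than")
})

test_that("neighbor joining recovers additive topologies", {
  # additive matrix from ((A:1,B:2):2,(C:2,D:4)) with internal edge 4
  D <- matrix(c(0, 3, 7, 9,
                3, 0, 8, 10,
                7, 8, 0, 6,
                9, 10, 6, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- build_nj_tree(D)
  ph <- tree_phylo(tr)
  truth <- ape::read.tree(text = "((A:1,B:2):4,(C:2,D:4));")
  expect_equal(ape::dist.topo(ape::unroot(ph), ape::unroot(truth)), 0,
               ignore_attr = TRUE)

  # recovered branch lengths reproduce the generating matrix
  expect_equal(ape::cophenetic.phylo(ph)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-9)

  expect_error(build_nj_tree(D[1:3, 1:3]), "at least 4")
  Db <- D; Db[1, 2] <- 99
  expect_error(build_nj_tree(Db), "symmetric")
})

test_that("neighbor joining is consistent on random additive matrices up to 7 taxa", {
  withr::local_seed(51)
  for (n in 4:7) {
    for (rep in 1:5) {
      true_tree <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
      D <- ape::cophenetic.phylo(true_tree)
      D <- D[sort(rownames(D)), sort(colnames(D))]
      ph <- tree_phylo(build_nj_tree(D))
      expect_equal(ape::dist.topo(ape::unroot(ph), ape::unroot(true_tree)), 0,
                   ignore_attr = TRUE)
    }
  }
})

test_that("equidistant taxa give a tree with zero internal length", {
  D <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(D) <- 0
  ph <- tree_phylo(build_nj_tree(D))
  internal <- ph$edge.length[ph$edge[, 2] > ape::Ntip(ph)]
  expect_true(all(abs(internal) < 1e-9))
})

test_that("bootstrap supports are reproducible and reflect signal", {
  withr::local_seed(52)
  # two clean clades: every variable column supports AB|CD
  s <- rand_dna(300)
  sAB <- mutseq(s, 0.02)
  sCD <- mutseq(s, 0.25)
  al <- align_homologs(tibble::tibble(
    taxon = c("A", "B", "C", "D"),
    seq = c(mutseq(sAB, 0.01), mutseq(sAB, 0.01),
            mutseq(sCD, 0.01), mutseq(sCD, 0.01))))
  t1 <- bootstrap_support(al, n_reps = 200, seed = 5)
  t2 <- bootstrap_support(al, n_reps = 200, seed = 5)
  expect_equal(t1$supports, t2$supports)
  expect_true(all(t1$supports >= 0 & t1$supports <= 100))
  expect_gt(max(t1$supports), 95)     # the AB|CD split dominates

  # all-invariant alignment: no signal
  flat <- align_homologs(tibble::tibble(taxon = LETTERS[1:4],
                                        seq = rep(strrep("ACGT", 25), 4)))
  t3 <- bootstrap_support(flat, n_reps = 100, seed = 1)
  expect_true(t3$no_signal)
  expect_true(all(t3$supports == 0))

  expect_error(bootstrap_support(al[1:3, ], n_reps = 100), "at least 4")
  expect_error(bootstrap_support(al, n_reps = 10), "at least 100")
})

test_that("the sister-clade rule assigns donors only above the support threshold", {
  withr::local_seed(53)
  sim <- simulate_donor_genes(n_genes = 1, seed = 99)
  truth <- attr(sim, "truth")
  al <- align_homologs(sim[, c("taxon", "seq")])
  tr <- bootstrap_support(al, n_reps = 200, seed = 2)
  dc <- call_donor(tr, "foreign_gene", default_donor_taxonomy())
  expect_equal(dc$verdict, "donor_assigned")
  expect_true(truth$donor %in% dc$sister_taxa[[1]])
  expect_true(all(startsWith(default_donor_taxonomy()[dc$sister_taxa[[1]]],
                             "angiosperm")))

  # the same tree with weak support stays unresolved (>50 is strict)
  tr_weak <- tr
  tr_weak$supports <- rep(45, length(tr$supports))
  expect_equal(call_donor(tr_weak, "foreign_gene",
                          default_donor_taxonomy())$verdict, "unresolved")
  tr50 <- tr
  tr50$supports <- rep(50, length(tr$supports))
  expect_equal(call_donor(tr50, "foreign_gene",
                          default_donor_taxonomy())$verdict, "unresolved")

  expect_error(call_donor(tr, "no_such_leaf", default_donor_taxonomy()),
               "not in tree")
})

test_that("a gymnosperm sister is never reported as a donor", {
  withr::local_seed(54)
  # foreign copy derived from a gymnosperm: sister set is non-angiosperm
  root <- rand_dna(600)
  tips <- evolve_sequences(c(g = root), default_donor_tree())
  fseq <- mutseq(tips$seq[tips$taxon == "Gymno_A"], 0.03)
  al <- align_homologs(dplyr::bind_rows(
    tips[, c("taxon", "seq")],
    tibble::tibble(taxon = "foreign_gene", seq = fseq)))
  tr <- bootstrap_support(al, n_reps = 200, seed = 3)
  dc <- call_donor(tr, "foreign_gene", default_donor_taxonomy())
  expect_equal(dc$verdict, "unresolved")
  expect_true("Gymno_A" %in% dc$sister_taxa[[1]])
})
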