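test_that("sequence evolution follows the Jukes-Cantor expectation", {
  s <- rand_dna(500)
  same <- evolve_sequences(c(g = s), "(a:0,b:0);", seed = 1)
  expect_equal(same$seq, c(s, s))

  # two tips at path length 0.2: expected p = (3/4)(1 - exp(-4*0.2/3))
  tips <- evolve_sequences(c(g = rand_dna(10000)), "(a:0.1,b:0.1);", seed = 2)
  p_obs <- mean(strsplit(tips$seq[1], "")[[1]] != strsplit(tips$seq[2], "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 * 0.2 / 3))
  sigma <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * sigma)

  r1 <- evolve_sequences(c(g = s), "(a:0.1,b:0.2);", seed = 3)
  r2 <- evolve_sequences(c(g = s), "(a:0.1,b:0.2);", seed = 3)
  expect_identical(r1, r2)

  expect_error(evolve_sequences(c(g = s), "(a:-0.1,b:0.2);", seed = 1),
               "negative branch length")
})

test_that("chimeric genomes hit the configured foreign fraction and GC", {
  cfg <- simulation_config(seed = 5, recipient_genome_size = 120000,
                           n_native_genes = 8, foreign_fraction_target = 0.14)
  sim <- build_chimeric_genome(cfg)
  fg <- sim$truth$segments[startsWith(sim$truth$segments$category, "foreign"), ]
  frac <- sum(fg$length) / sim$genome$length
  expect_gte(frac, 0.12)
  expect_lte(frac, 0.16)
  expect_lt(abs(hgtscan:::gc_content(sim$genome$seq) - cfg$gc_target), 0.02)
  # truth coordinates address the emitted genome and carry the donor copy
  expect_true(all(fg$end <= sim$genome$length))
  # the panel never contains the recipient's own mitogenome
  expect_false(any(sim$panel$id == sim$genome$id))
  expect_setequal(unique(sim$panel$group),
                  c("gnetum_plastid", "non_gymnosperm_plastid",
                    "non_gnetum_gymnosperm_mito", "angiosperm_mito"))
})

test_that("truth segment sequences really descend from their recorded donors", {
  cfg <- simulation_config(seed = 6, recipient_genome_size = 100000,
                           n_native_genes = 6)
  sim <- build_chimeric_genome(cfg)
  seg <- dplyr::filter(sim$truth$segments, category == "foreign_mito")[1, ]
  insert <- substring(sim$genome$seq, seg$start + 1, seg$end)
  donor_seq <- sim$panel$seq[sim$panel$taxon == seg$donor]
  anch <- find_exact_anchors(insert, donor_seq, min_len = 30)
  expect_gt(sum(anch$length), 0.2 * seg$length)
})

test_that("a zero-foreign configuration yields an empty truth table", {
  cfg <- simulation_config(seed = 7, recipient_genome_size = 60000,
                           n_native_genes = 5, foreign_fraction_target = 0)
  sim <- build_chimeric_genome(cfg)
  expect_equal(sum(startsWith(sim$truth$segments$category, "foreign")), 0)
  expect_equal(sum(sim$truth$genes$origin == "foreign"), 0)
})

test_that("unattainable foreign fractions are rejected", {
  cfg <- simulation_config(seed = 8, recipient_genome_size = 8000,
                           n_native_genes = 2, foreign_fraction_target = 0.1)
  expect_error(build_chimeric_genome(cfg), "unattainable")
})

test_that("retroprocessed inserts carry T at their recorded editing sites", {
  cfg <- simulation_config(seed = 9, recipient_genome_size = 100000,
                           n_native_genes = 6, retro_fraction = 1)
  sim <- build_chimeric_genome(cfg)
  retro <- dplyr::filter(sim$truth$segments, transfer_mode == "retroprocessed")
  expect_gt(nrow(retro), 0)
  rs <- dplyr::filter(sim$truth$editing_sites, origin == "foreign_retro")
  expect_gt(nrow(rs), 0)
  bases <- substring(sim$genome$seq, rs$pos + 1, rs$pos + 1)
  expect_true(all(bases == "T"))
})

test_that("simulation output is byte-identical across runs with one seed", {
  cfg <- simulation_config(seed = 10, recipient_genome_size = 60000,
                           n_native_genes = 5)
  s1 <- build_chimeric_genome(cfg)
  s2 <- build_chimeric_genome(cfg)
  expect_identical(s1$genome$seq, s2$genome$seq)
  expect_identical(s1$truth, s2$truth)
  e1 <- simulate_editing_and_expression(s1)
  e2 <- simulate_editing_and_expression(s2)
  expect_identical(e1, e2)
})

test_that("simulated pileups drive the expected editing calls", {
  cfg <- simulation_config(seed = 12, recipient_genome_size = 80000,
                           n_native_genes = 6)
  sim <- build_chimeric_genome(cfg)
  ev <- simulate_editing_and_expression(sim)
  sites <- call_editing_sites(ev$pileup, sim$annotations, sim$genome)
  # native genes recover at least 4 of every 5 planted sites
  truth_n <- nrow(sim$truth$editing_sites)
  called_native <- sum(sites$origin == "native")
  expect_gte(called_native, ceiling(0.8 * truth_n))
  # foreign DNA-mediated genes show no editing at all
  expect_equal(sum(sites$origin == "foreign"), 0)
  # expression contrast mirrors the native >> foreign regime
  ec <- expression_contrast(ev$counts)
  expect_lt(ec$test$p_two_tailed, 0.05)
})
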