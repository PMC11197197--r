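# Synthetic chimeric mitogenomes with known HGT truth: sequence evolution
# under Jukes-Cantor along a phylogeny, chimeric genome assembly, and
# editing/expression evidence generation.

#' Default donor phylogeny for simulated gene trees
#'
#' Eight taxa: five angiosperm mitochondrial donors, two gymnosperm
#' relatives, one fern outgroup. Branch lengths in substitutions/site give
#' moderate pairwise divergences (roughly 0.05-0.25).
#'
#' @return A Newick string.
#' @export
default_donor_tree <- function() {
  paste0("(((Angio_A:0.05,(Angio_B:0.04,Angio_C:0.04):0.02):0.03,",
         "(Angio_D:0.05,Angio_E:0.06):0.02):0.06,",
         "((Gymno_A:0.04,Gymno_B:0.05):0.05,Fern_out:0.18):0.06);")
}

#' Taxonomy map for the default donor phylogeny
#'
#' @return Named character vector taxon -> group.
#' @export
default_donor_taxonomy <- function() {
  c(Angio_A = "angiosperm_mito", Angio_B = "angiosperm_mito",
    Angio_C = "angiosperm_mito", Angio_D = "angiosperm_mito",
    Angio_E = "angiosperm_mito",
    Gymno_A = "non_gnetum_gymnosperm_mito",
    Gymno_B = "non_gnetum_gymnosperm_mito",
    Fern_out = "outgroup")
}

# exact Jukes-Cantor transition applied site-wise: substitution probability
# p = 3/4 (1 - exp(-4 b / 3)); a substituted site takes one of the other
# three bases uniformly. Composes correctly along a path.
mutate_seq <- function(seq, branch_length) {
  if (branch_length < 0) abort("negative branch length")
  if (branch_length == 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * branch_length / 3))
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < p)
  if (length(hit) > 0) {
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                  nrow = 3, dimnames = list(NULL, c("A", "C", "G", "T")))
    pick <- sample.int(3, length(hit), replace = TRUE)
    chars[hit] <- alt[cbind(pick, match(chars[hit], c("A", "C", "G", "T")))]
  }
  paste(chars, collapse = "")
}

#' Evolve sequences along a phylogeny under Jukes-Cantor
#'
#' Independent-site substitution along each branch with the exact JC
#' transition kernel, so the expected p-distance between two tips matches
#' their path length under the model.
#'
#' @param root_seqs Named character vector of root sequences (one per gene).
#' @param tree Newick string or `ape::phylo` with branch lengths in
#'   substitutions/site.
#' @param seed Integer seed (optional; omit to use the current RNG state).
#' @return A tibble with columns `taxon`, `gene`, `seq` (tip sequences).
#' @export
evolve_sequences <- function(root_seqs, tree, seed = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (any(tree$edge.length < 0)) abort("negative branch length in tree")
  run <- function() {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    node_seqs <- vector("list", max(tree$edge))
    node_seqs[[root]] <- root_seqs
    # preorder: ape edges are already usable parent-before-child after reorder
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; b <- tr$edge.length[e]
      node_seqs[[ch]] <- vapply(node_seqs[[par]], mutate_seq, character(1),
                                branch_length = b)
    }
    purrr::map_dfr(seq_len(n_tip), function(i) {
      tibble(taxon = tree$tip.label[i],
             gene = names(root_seqs) %||% paste0("g", seq_along(root_seqs)),
             seq = unname(node_seqs[[i]]))
    })
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Configuration for the chimeric-genome simulator
#'
#' Defaults emulate the observed regime of Asian *Gnetum*-like mitogenomes:
#' a ~500-kb recipient at 47% GC carrying native genes with active C-to-U
#' editing, near-identical native MTPTs, and angiosperm-derived foreign
#' segments amounting to ~14% of the genome at 5-15% divergence from their
#' donors, with pseudogenized foreign genes and foreign expression far below
#' native expression.
#'
#' @param seed Integer seed driving all randomness.
#' @param recipient_genome_size Target genome size in bp.
#' @param gc_target Backbone GC fraction.
#' @param n_native_genes,native_gene_length Native gene count and length
#'   range (bp).
#' @param plastome_size Size of the recipient plastome (and of the
#'   angiosperm plastome) in bp.
#' @param n_native_mtpt,native_mtpt_length,native_mtpt_divergence Native
#'   MTPT count, length range, and divergence range from the plastome
#'   (near-identity by default).
#' @param angio_mito_tree Newick tree of the angiosperm mitochondrial donor
#'   taxa; donor genomes evolve from a common ancestor along it.
#' @param angio_mito_genome_size Donor mitogenome size in bp.
#' @param gymnosperm_divergence Divergence of the gymnosperm mitochondrial
#'   relative from the recipient backbone (substitutions/site).
#' @param foreign_fraction_target Foreign fraction of the final genome.
#' @param segment_length_range Foreign segment length range (bp).
#' @param prob_mtpt_segment Probability a foreign segment is plastid-derived
#'   (foreign MTPT) rather than mitochondrion-derived.
#' @param insert_divergence Divergence range between an inserted segment and
#'   its donor copy (substitutions/site).
#' @param foreign_gene_length Length range of the gene carried by each
#'   foreign mitochondrial segment (bp, rounded to codons).
#' @param pseudogenization_rate Expected premature stops + frameshifts per kb
#'   of foreign gene (at least one event per gene is enforced).
#' @param retro_fraction Probability a foreign gene-bearing segment is
#'   retroprocessed (T at its former editing sites) instead of DNA-mediated.
#' @param editing_site_density C-to-U editing sites per kb of native CDS.
#' @param editing_codon_pos_probs Probabilities of a site landing on codon
#'   positions 1/2/3; the default concentrates sites at the first two
#'   positions so most are nonsynonymous, as observed in plant mitochondria.
#' @param editing_beta Shape parameters of the Beta distribution of editing
#'   fractions at native sites (mean ~0.85 by default).
#' @param depth_native,depth_foreign Mean pileup read depths.
#' @param expr_meanlog_native,expr_meanlog_foreign,expr_sdlog Log-normal
#'   read-count parameters by origin class.
#' @return A list of class `hgt_sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              recipient_genome_size = 500000,
                              gc_target = 0.47,
                              n_native_genes = 25,
                              native_gene_length = c(600, 1500),
                              plastome_size = 30000,
                              n_native_mtpt = 3,
                              native_mtpt_length = c(500, 3000),
                              native_mtpt_divergence = c(0, 0.01),
                              angio_mito_tree = paste0(
                                "((MitoDonor_A:0.03,MitoDonor_B:0.03):0.03,",
                                "(MitoDonor_C:0.04,MitoDonor_D:0.02):0.02);"),
                              angio_mito_genome_size = 60000,
                              gymnosperm_divergence = 0.08,
                              foreign_fraction_target = 0.14,
                              segment_length_range = c(2000, 12000),
                              prob_mtpt_segment = 0.15,
                              insert_divergence = c(0.05, 0.12),
                              foreign_gene_length = c(300, 900),
                              pseudogenization_rate = 2,
                              retro_fraction = 0,
                              editing_site_density = 10,
                              editing_codon_pos_probs = c(0.30, 0.45, 0.25),
                              editing_beta = c(8.5, 1.5),
                              depth_native = 60,
                              depth_foreign = 20,
                              expr_meanlog_native = 9,
                              expr_meanlog_foreign = 4,
                              expr_sdlog = 1) {
  cfg <- as.list(environment())
  if (cfg$foreign_fraction_target < 0 || cfg$foreign_fraction_target >= 0.5)
    abort("foreign_fraction_target must be in [0, 0.5)")
  structure(cfg, class = "hgt_sim_config")
}

place_nonoverlapping <- function(space, lengths, occupied, pad = 50L) {
  # sample start positions for intervals of given lengths inside [0, space),
  # avoiding `occupied` intervals and each other
  out <- integer(0)
  occ <- occupied
  for (len in lengths) {
    ok <- FALSE
    for (try in 1:2000) {
      s <- sample.int(space - len, 1L)
      cand <- tibble(start = s - pad, end = s + len + pad)
      if (ivl_width(ivl_intersect(cand, occ)) == 0) {
        out <- c(out, s)
        occ <- bind_rows(occ, tibble(start = s, end = s + len))
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("could not place intervals without overlap; genome too small")
  }
  out
}

#' Build a chimeric recipient mitogenome with known truth
#'
#' Assembles a recipient genome of approximately the configured size: a
#' random backbone at the target GC carrying native genes (with C-to-U
#' editing sites planted at native CDS positions), near-identical native
#' MTPTs copied from the recipient plastome, and foreign segments sampled
#' from angiosperm donor mitogenomes (or the angiosperm plastome for foreign
#' MTPTs), diverged by the configured amount and inserted intergenically.
#' Each foreign mitochondrial segment carries one pseudogenized gene. The
#' labeled reference panel contains the recipient plastome, the angiosperm
#' plastome, a gymnosperm mitochondrial relative of the backbone, and the
#' donor mitogenomes -- but never the recipient's own mitogenome.
#'
#' @param config An `hgt_sim_config` from [simulation_config()].
#' @return A list of class `hgt_simulation`: `genome`, `annotations`,
#'   `panel` (tibble ready for [build_panel_index()]), `truth` (list of
#'   `segments`, `genes`, `editing_sites` tibbles), `config`.
#' @export
build_chimeric_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "hgt_sim_config"))
  with_seed(config$seed, build_chimeric_genome_impl(config))
}

build_chimeric_genome_impl <- function(cfg) {
  F_target <- round(cfg$foreign_fraction_target * cfg$recipient_genome_size)
  if (F_target > 0 && F_target < cfg$segment_length_range[1])
    abort("requested foreign fraction is unattainable at this genome size")
  # component sequences
  plastome <- random_dna(cfg$plastome_size, 0.38)
  angio_plastome <- random_dna(cfg$plastome_size, 0.38)
  angio_ancestor <- random_dna(cfg$angio_mito_genome_size, 0.45)
  donors <- evolve_sequences(c(genome = angio_ancestor), cfg$angio_mito_tree)
  # foreign segment plan
  seg_len <- integer(0)
  while (sum(seg_len) < F_target)
    seg_len <- c(seg_len, as.integer(round(runif(1, cfg$segment_length_range[1],
                                                 cfg$segment_length_range[2]))))
  over <- sum(seg_len) - F_target
  if (over > 0 && seg_len[length(seg_len)] - over >= 500)
    seg_len[length(seg_len)] <- seg_len[length(seg_len)] - over
  n_seg <- length(seg_len)
  seg_cat <- ifelse(runif(n_seg) < cfg$prob_mtpt_segment, "foreign_MTPT", "foreign_mito")
  seg_len[seg_cat == "foreign_MTPT"] <-
    pmin(seg_len[seg_cat == "foreign_MTPT"], 4000L)
  # native MTPT plan
  mtpt_len <- as.integer(round(runif(cfg$n_native_mtpt, cfg$native_mtpt_length[1],
                                     cfg$native_mtpt_length[2])))
  backbone_size <- cfg$recipient_genome_size - sum(seg_len) - sum(mtpt_len)
  if (backbone_size < cfg$recipient_genome_size / 3)
    abort("requested foreign fraction is unattainable at this genome size")
  backbone <- random_dna(backbone_size, cfg$gc_target)
  # native genes on the backbone
  gene_len <- as.integer(3 * round(runif(cfg$n_native_genes,
                                         cfg$native_gene_length[1],
                                         cfg$native_gene_length[2]) / 3))
  gene_start <- place_nonoverlapping(backbone_size, gene_len,
                                     tibble(start = integer(), end = integer()))
  gene_strand <- sample(c("+", "-"), cfg$n_native_genes, replace = TRUE)
  genes <- tibble(name = sprintf("ngene_%02d", seq_len(cfg$n_native_genes)),
                  origin = "native", start = gene_start,
                  end = gene_start + gene_len, strand = gene_strand,
                  pseudogene = FALSE, n_stop = 0L, n_frameshift = 0L)
  # plant editing sites: genomic C (+) or G (-) at sampled CDS positions
  bb <- strsplit(backbone, "")[[1]]
  edit_rows <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    n_sites <- max(1L, rpois(1, cfg$editing_site_density * (g$end - g$start) / 1000))
    n_sites <- min(n_sites, (g$end - g$start) %/% 6)
    # editing concentrates at first and second codon positions, which is what
    # makes most real sites nonsynonymous
    codon <- sample.int((g$end - g$start) %/% 3, n_sites)
    within <- sample(0:2, n_sites, replace = TRUE,
                     prob = cfg$editing_codon_pos_probs)
    cds_pos <- sort(3L * (codon - 1L) + within)
    pos <- if (g$strand == "+") g$start + cds_pos else g$end - 1L - cds_pos
    tibble(gene = g$name, pos = sort(pos), strand = g$strand,
           fraction = rbeta(n_sites, cfg$editing_beta[1], cfg$editing_beta[2]))
  })
  bb[edit_rows$pos + 1L] <- ifelse(edit_rows$strand == "+", "C", "G")
  backbone <- paste(bb, collapse = "")
  # gymnosperm relative diverges from the pre-insert backbone
  gymno <- mutate_seq(backbone, cfg$gymnosperm_divergence)
  # native MTPT sequences
  mtpt_src <- vapply(mtpt_len, function(l) {
    s <- sample.int(cfg$plastome_size - l, 1L)
    substring(plastome, s + 1L, s + l)
  }, character(1))
  mtpt_seq <- vapply(mtpt_src, function(s)
    mutate_seq(s, runif(1, cfg$native_mtpt_divergence[1],
                        cfg$native_mtpt_divergence[2])), character(1),
    USE.NAMES = FALSE)
  # foreign segments
  donor_names <- donors$taxon
  fseg <- purrr::map(seq_len(n_seg), function(i) {
    len <- seg_len[i]
    if (seg_cat[i] == "foreign_MTPT") {
      donor <- "Angiosperm_plastome"
      s <- sample.int(cfg$plastome_size - len, 1L)
      seq <- substring(angio_plastome, s + 1L, s + len)
      gene_off <- NA_integer_; gene_len_i <- NA_integer_
    } else {
      donor <- sample(donor_names, 1L)
      dseq <- donors$seq[donors$taxon == donor]
      s <- sample.int(nchar(dseq) - len, 1L)
      seq <- substring(dseq, s + 1L, s + len)
      gene_len_i <- as.integer(3 * round(runif(1, cfg$foreign_gene_length[1],
                                               cfg$foreign_gene_length[2]) / 3))
      gene_len_i <- min(gene_len_i, len - 60L)
      gene_off <- sample.int(len - gene_len_i, 1L)
    }
    mode <- if (!is.na(gene_off) && runif(1) < cfg$retro_fraction)
      "retroprocessed" else "dna"
    list(seq = mutate_seq(seq, runif(1, cfg$insert_divergence[1],
                                     cfg$insert_divergence[2])),
         category = seg_cat[i], donor = donor, mode = mode,
         gene_off = gene_off, gene_len = gene_len_i)
  })
  # pseudogenize foreign genes; retro genes carry T at former editing sites
  for (i in seq_along(fseg)) {
    fs <- fseg[[i]]
    if (is.na(fs$gene_off)) next
    chars <- strsplit(fs$seq, "")[[1]]
    g0 <- fs$gene_off; g1 <- g0 + fs$gene_len   # 0-based half-open within segment
    n_ev <- max(1L, rpois(1, cfg$pseudogenization_rate * fs$gene_len / 1000))
    n_stop <- 0L; n_fs <- 0L
    for (ev in seq_len(n_ev)) {
      if (runif(1) < 0.5) {
        codon <- sample.int(fs$gene_len %/% 3 - 2L, 1L)  # avoid terminal codon
        at <- g0 + 3L * codon
        chars[(at + 1L):(at + 3L)] <- c("T", "A", "A")
        n_stop <- n_stop + 1L
      } else {
        at <- g0 + sample.int(fs$gene_len - 2L, 1L)
        if (runif(1) < 0.5) {
          chars <- append(chars, chars[at + 1L], after = at)
          g1 <- g1 + 1L
        } else {
          chars <- chars[-(at + 1L)]
          g1 <- g1 - 1L
        }
        n_fs <- n_fs + 1L
      }
    }
    if (fs$mode == "retroprocessed") {
      n_sites <- max(3L, rpois(1, cfg$editing_site_density * fs$gene_len / 1000))
      spos <- sort(sample(seq.int(g0, g1 - 1L), min(n_sites, g1 - g0)))
      chars[spos + 1L] <- "T"
      fs$retro_pos <- spos
    }
    fs$seq <- paste(chars, collapse = "")
    fs$gene_off <- g0; fs$gene_len <- g1 - g0
    fs$n_stop <- n_stop; fs$n_frameshift <- n_fs
    fseg[[i]] <- fs
  }
  # choose insertion points in the backbone, away from native genes
  inserts <- c(
    purrr::map(seq_along(mtpt_seq), function(i)
      list(seq = mtpt_seq[i], category = "native_MTPT",
           donor = "Gnetum_plastome", mode = NA_character_,
           gene_off = NA_integer_, gene_len = NA_integer_)),
    fseg)
  ins_len <- vapply(inserts, function(x) nchar(x$seq), integer(1))
  occupied <- tibble(start = genes$start, end = genes$end)
  ins_pos <- place_nonoverlapping(backbone_size, rep(1L, length(inserts)), occupied)
  ord <- order(ins_pos)
  inserts <- inserts[ord]; ins_pos <- ins_pos[ord]; ins_len <- ins_len[ord]
  # splice inserts into the backbone and track coordinate shifts
  pieces <- character(0); cur <- 0L
  shift_at <- ins_pos; shift_by <- cumsum(ins_len)
  final_pos <- ins_pos + c(0L, shift_by[-length(shift_by)])
  for (i in seq_along(inserts)) {
    pieces <- c(pieces, substring(backbone, cur + 1L, ins_pos[i]), inserts[[i]]$seq)
    cur <- ins_pos[i]
  }
  pieces <- c(pieces, substring(backbone, cur + 1L, backbone_size))
  genome_seq <- paste(pieces, collapse = "")
  offset_of <- function(pos) {
    # final coordinate of a backbone position
    pos + vapply(pos, function(p) sum(ins_len[ins_pos <= p]), numeric(1))
  }
  truth_segments <- purrr::map_dfr(seq_along(inserts), function(i) {
    x <- inserts[[i]]
    tibble(seq_id = "recipient_mt1", start = as.integer(final_pos[i]),
           end = as.integer(final_pos[i] + ins_len[i]),
           category = x$category, donor = x$donor,
           transfer_mode = x$mode, length = ins_len[i])
  })
  fgene_rows <- purrr::map_dfr(seq_along(inserts), function(i) {
    x <- inserts[[i]]
    if (is.na(x$gene_off)) return(NULL)
    tibble(name = sprintf("fgene_%02d", i), origin = "foreign",
           start = as.integer(final_pos[i] + x$gene_off),
           end = as.integer(final_pos[i] + x$gene_off + x$gene_len),
           strand = "+", pseudogene = TRUE,
           n_stop = x$n_stop, n_frameshift = x$n_frameshift)
  })
  genes_final <- genes |>
    mutate(start = as.integer(offset_of(.data$start)),
           end = as.integer(.data$start + gene_len))
  all_genes <- bind_rows(genes_final, fgene_rows)
  annotations <- bind_rows(
    tibble(seq_id = "recipient_mt1", start = all_genes$start, end = all_genes$end,
           strand = all_genes$strand, kind = "gene", name = all_genes$name,
           parent = NA_character_, origin = all_genes$origin,
           pseudogene = all_genes$pseudogene),
    truth_segments |>
      filter(.data$category == "native_MTPT") |>
      mutate(kind = "MTPT", name = sprintf("mtpt_%02d", row_number()),
             parent = NA_character_, origin = "native", pseudogene = FALSE) |>
      select("seq_id", "start", "end", kind = "kind", name = "name",
             parent = "parent", origin = "origin", pseudogene = "pseudogene") |>
      mutate(strand = "+", .after = "end"))
  retro_truth <- purrr::map_dfr(seq_along(inserts), function(i) {
    x <- inserts[[i]]
    if (is.null(x$retro_pos)) return(NULL)
    tibble(gene = sprintf("fgene_%02d", i),
           pos = as.integer(final_pos[i] + x$retro_pos),
           strand = "+", fraction = 0, origin = "foreign_retro")
  })
  editing_truth <- bind_rows(
    mutate(edit_rows, pos = as.integer(offset_of(.data$pos)), origin = "native"),
    retro_truth)
  genome <- tibble(id = "recipient_mt1", taxon = "Gnetum_recipient",
                   compartment = "mitochondrial", group = "unknown",
                   seq = genome_seq, length = nchar(genome_seq))
  panel <- bind_rows(
    tibble(id = "Gnetum_plastome", taxon = "Gnetum_recipient",
           compartment = "plastid", group = "gnetum_plastid", seq = plastome),
    tibble(id = "Angiosperm_plastome", taxon = "Angiosperm_sp",
           compartment = "plastid", group = "non_gymnosperm_plastid",
           seq = angio_plastome),
    tibble(id = "Gymnosperm_relative_mt", taxon = "Gymnosperm_relative",
           compartment = "mitochondrial", group = "non_gnetum_gymnosperm_mito",
           seq = gymno),
    tibble(id = paste0(donors$taxon, "_mt"), taxon = donors$taxon,
           compartment = "mitochondrial", group = "angiosperm_mito",
           seq = donors$seq)) |>
    mutate(length = nchar(.data$seq))
  structure(list(genome = genome, annotations = annotations, panel = panel,
                 truth = list(segments = truth_segments, genes = all_genes,
                              editing_sites = editing_truth),
                 config = cfg),
            class = "hgt_simulation")
}

#' @export
print.hgt_simulation <- function(x, ...) {
  fg <- x$truth$segments |> filter(startsWith(.data$category, "foreign"))
  cat(sprintf("<hgt_simulation> genome %s bp, %d foreign segments (%s bp, %.1f%%), %d genes\n",
              format(x$genome$length, big.mark = ","), nrow(fg),
              format(sum(fg$length), big.mark = ","),
              100 * sum(fg$length) / x$genome$length, nrow(x$truth$genes)))
  invisible(x)
}

#' Simulate RNA evidence: per-site pileups and per-gene read counts
#'
#' Native editing sites emit T-majority pileups with Beta-distributed edited
#' fractions; foreign (DNA-mediated) genes emit unedited C. Per-gene read
#' counts are log-normal with native mean far above foreign mean. An optional
#' per-base noise rate scatters a fraction of reads to random other bases.
#'
#' @param sim An `hgt_simulation` from [build_chimeric_genome()].
#' @param seed Integer seed (defaults to the simulation seed + 1).
#' @param noise Per-read base error rate (default 0).
#' @return A list with `pileup` and `counts` tibbles matching the input
#'   contracts of [call_editing_sites()] and [compute_tpm()].
#' @export
simulate_editing_and_expression <- function(sim, seed = NULL, noise = 0) {
  stopifnot(inherits(sim, "hgt_simulation"))
  cfg <- sim$config
  seed <- seed %||% (cfg$seed + 1)
  with_seed(seed, {
    genes <- filter(sim$annotations, .data$kind == "gene")
    gseq <- sim$genome$seq
    edit_by_pos <- setNames(sim$truth$editing_sites$fraction,
                            sim$truth$editing_sites$pos)
    pileup <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      cmap <- gene_cds_map(g, genes[0, ], sim$genome)
      depth <- rpois(nrow(cmap), if (g$origin == "native") cfg$depth_native
                                 else cfg$depth_foreign)
      frac <- unname(edit_by_pos[as.character(cmap$genomic_pos)])
      frac[is.na(frac)] <- 0
      edited <- rbinom(nrow(cmap), depth, frac)
      out <- tibble(seq_id = g$seq_id, pos = cmap$genomic_pos,
                    ref = substring(gseq, cmap$genomic_pos + 1L,
                                    cmap$genomic_pos + 1L),
                    depth = depth, A = 0L, C = 0L, G = 0L, T = 0L)
      base_main <- cmap$coding_base
      tcol <- match("T", c("A", "C", "G", "T"))
      counts <- matrix(0L, nrow(cmap), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
      counts[cbind(seq_len(nrow(cmap)), match(base_main, colnames(counts)))] <-
        depth - edited
      counts[, "T"] <- counts[, "T"] + edited
      if (noise > 0) {
        for (r in seq_len(nrow(counts))) {
          for (b in 1:4) {
            nb <- counts[r, b]
            if (nb == 0) next
            err <- rbinom(1, nb, noise)
            if (err == 0) next
            counts[r, b] <- counts[r, b] - err
            dest <- sample(setdiff(1:4, b), err, replace = TRUE)
            for (d2 in dest) counts[r, d2] <- counts[r, d2] + 1L
          }
        }
      }
      out$A <- counts[, "A"]; out$C <- counts[, "C"]
      out$G <- counts[, "G"]; out$T <- counts[, "T"]
      out
    })
    counts_tbl <- genes |>
      mutate(gene = .data$name,
             count = as.integer(round(rlnorm(
               n(), ifelse(.data$origin == "native", cfg$expr_meanlog_native,
                           cfg$expr_meanlog_foreign), cfg$expr_sdlog))),
             length = .data$end - .data$start) |>
      select("gene", "origin", "count", "length")
    list(pileup = pileup, counts = counts_tbl)
  })
}

#' Simulate foreign genes with known donors for sister-clade recovery
#'
#' Each gene evolves along the donor phylogeny from a random root sequence;
#' one angiosperm tip is chosen as the donor, and the foreign copy diverges
#' from that tip by an extra branch. The true donor should be recovered as
#' the foreign leaf's sister.
#'
#' @param n_genes Number of genes to simulate.
#' @param tree Newick donor phylogeny (default [default_donor_tree()]).
#' @param taxonomy Taxon -> group map (default [default_donor_taxonomy()]).
#' @param gene_length Gene length range (bp).
#' @param extra_divergence Range of the foreign branch length.
#' @param seed Integer seed.
#' @return A tibble with one row per gene x taxon (`gene`, `taxon`, `seq`,
#'   `role`), plus the foreign row (`taxon = "foreign_gene"`); true donors
#'   are in attribute `truth` (tibble `gene`, `donor`).
#' @export
simulate_donor_genes <- function(n_genes = 100, tree = default_donor_tree(),
                                 taxonomy = default_donor_taxonomy(),
                                 gene_length = c(500, 1200),
                                 extra_divergence = c(0.02, 0.08), seed = 1) {
  angio <- names(taxonomy)[startsWith(taxonomy, "angiosperm")]
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_genes), function(i) {
      L <- round(runif(1, gene_length[1], gene_length[2]))
      root <- random_dna(L, 0.45)
      tips <- evolve_sequences(c(gene = root), tree)
      donor <- sample(angio, 1)
      fseq <- mutate_seq(tips$seq[tips$taxon == donor],
                         runif(1, extra_divergence[1], extra_divergence[2]))
      bind_rows(mutate(tips, gene = sprintf("sim_gene_%03d", i), role = "homolog"),
                tibble(taxon = "foreign_gene", gene = sprintf("sim_gene_%03d", i),
                       seq = fseq, role = "foreign")) |>
        mutate(donor = donor)
    }) -> out
    truth <- distinct(out, .data$gene, .data$donor)
    structure(select(out, -"donor"), truth = truth)
  })
}

#' Simulate a foreign gene family for the retroprocessing test
#'
#' Builds native homologs sharing conserved C-to-U editing sites and a
#' foreign copy whose states at those sites reflect the transfer mode:
#' unedited C for DNA-mediated integration, T for a retroprocessed (cDNA)
#' copy. Optional base noise substitutes bases uniformly at the given rate.
#'
#' @param mode `"dna"` or `"retroprocessed"`.
#' @param n_natives Number of native homolog rows.
#' @param n_sites Number of conserved editing sites.
#' @param gene_length Gene length (bp).
#' @param divergence Divergence of each homolog from the family root.
#' @param noise Per-base substitution noise applied to all rows.
#' @param seed Integer seed.
#' @return A list: `seqs` (tibble `taxon`, `seq`), `annotations` (tibble
#'   `taxon`, `pos` of editing sites), `foreign_taxon`, `mode`.
#' @export
simulate_retro_gene <- function(mode = c("dna", "retroprocessed"),
                                n_natives = 3, n_sites = 8, gene_length = 600,
                                divergence = 0.02, noise = 0, seed = 1) {
  mode <- match.arg(mode)
  with_seed(seed, {
    root <- random_dna(gene_length, 0.45)
    sites <- sort(sample.int(gene_length, n_sites)) - 1L
    set_base <- function(seq, pos0, base) {
      ch <- strsplit(seq, "")[[1]]
      ch[pos0 + 1L] <- base
      paste(ch, collapse = "")
    }
    noisy <- function(seq) if (noise > 0) mutate_seq(seq, -0.75 * log(1 - 4 * noise / 3)) else seq
    natives <- vapply(seq_len(n_natives), function(i)
      noisy(set_base(mutate_seq(root, divergence), sites, "C")), character(1))
    fstate <- if (mode == "dna") "C" else "T"
    foreign <- noisy(set_base(mutate_seq(root, divergence), sites, fstate))
    taxa <- c(paste0("native_", seq_len(n_natives)), "foreign_copy")
    list(seqs = tibble(taxon = taxa, seq = c(natives, foreign)),
         annotations = tibble(taxon = rep(paste0("native_", seq_len(n_natives)),
                                          each = n_sites),
                              pos = rep(sites, n_natives)),
         foreign_taxon = "foreign_copy", mode = mode)
  })
}

#' Simulate three species sharing foreign inserts
#'
#' Generates three recipient genomes carrying foreign segments with a known
#' sharing pattern (each segment is present, as an identical copy, in a
#' random non-empty subset of the species), for exercising cross-species
#' shared-foreign quantification against truth.
#'
#' @param n_segments Number of distinct foreign segments.
#' @param genome_size Per-species backbone size (bp).
#' @param segment_length_range Foreign segment length range (bp).
#' @param p_triple,p_pair Probabilities that a segment is shared by all
#'   three / by a given pair (remaining mass is species-unique).
#' @param seed Integer seed.
#' @return A list: `genomes` (named list of genome tibbles), `segments`
#'   (named list of per-species foreign segment tibbles), `membership`
#'   (tibble `segment`, `species`).
#' @export
simulate_shared_trio <- function(n_segments = 12, genome_size = 60000,
                                 segment_length_range = c(500, 3000),
                                 p_triple = 0.3, p_pair = 0.1, seed = 1) {
  species <- c("sp_A", "sp_B", "sp_C")
  with_seed(seed, {
    pairs <- utils::combn(species, 2, simplify = FALSE)
    seglen <- as.integer(round(runif(n_segments, segment_length_range[1],
                                     segment_length_range[2])))
    segseq <- vapply(seglen, random_dna, character(1), gc = 0.45)
    member <- purrr::map(seq_len(n_segments), function(i) {
      u <- runif(1)
      if (u < p_triple) species
      else if (u < p_triple + 3 * p_pair) pairs[[ceiling((u - p_triple) / p_pair)]]
      else sample(species, 1)
    })
    genomes <- list(); segments <- list()
    for (sp in species) {
      keep <- which(purrr::map_lgl(member, ~ sp %in% .x))
      backbone <- random_dna(genome_size, 0.47)
      pos <- place_nonoverlapping(genome_size, seglen[keep],
                                  tibble(start = integer(), end = integer()))
      ord <- order(pos)
      pos <- pos[ord]; keep <- keep[ord]
      cur <- 0L; pieces <- character(0); starts <- integer(0); off <- 0L
      for (j in seq_along(keep)) {
        pieces <- c(pieces, substring(backbone, cur + 1L, pos[j]))
        starts <- c(starts, pos[j] + off)
        pieces <- c(pieces, segseq[keep[j]])
        off <- off + seglen[keep[j]]
        cur <- pos[j]
      }
      pieces <- c(pieces, substring(backbone, cur + 1L, genome_size))
      genomes[[sp]] <- tibble(id = sp, taxon = sp, compartment = "mitochondrial",
                              group = "unknown",
                              seq = paste(pieces, collapse = ""),
                              length = genome_size + off)
      segments[[sp]] <- tibble(segment = keep, start = starts,
                               end = starts + seglen[keep],
                               category = "foreign_mito",
                               length = seglen[keep])
    }
    membership <- purrr::map_dfr(seq_len(n_segments), function(i)
      tibble(segment = i, species = member[[i]]))
    list(genomes = genomes, segments = segments, membership = membership)
  })
}
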