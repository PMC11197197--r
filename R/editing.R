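# C-to-U RNA editing: site calling from pileup evidence, codon-effect
# classification, and the retroprocessing test on foreign genes.

#' Classify the codon effect of a C-to-U editing site
#'
#' Compares the standard-genetic-code translation of a codon against the same
#' codon with C replaced by T at the edited position.
#'
#' @param codon Character vector of 3-mers over A/C/G/T.
#' @param codon_pos Position of the edited C within the codon (0, 1 or 2).
#' @return Character vector: `"synonymous"`, `"nonsynonymous"` or
#'   `"stop_gain"`.
#' @export
#' @examples
#' classify_site_effect("CCA", 1)  # Pro -> Leu
#' classify_site_effect("CGA", 0)  # Arg -> stop
classify_site_effect <- function(codon, codon_pos) {
  if (length(codon) == 0) return(character(0))
  codon <- toupper(codon)
  if (any(stringr::str_detect(codon, "[^ACGT]")))
    abort("codon contains ambiguity codes")
  if (any(substring(codon, codon_pos + 1, codon_pos + 1) != "C"))
    abort("codon position to classify must hold a C")
  edited <- codon
  substring(edited, codon_pos + 1, codon_pos + 1) <- "T"
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon])
  aa_ed <- unname(code[edited])
  dplyr::case_when(aa_ed == "*" & aa_ref != "*" ~ "stop_gain",
                   aa_ref == aa_ed ~ "synonymous",
                   TRUE ~ "nonsynonymous")
}

# transcript-coordinate map of a gene: tibble of genomic pos (0-based) in
# transcript order, with the coding-strand base
gene_cds_map <- function(gene_row, exons, genome) {
  seq <- genome$seq[genome$id == gene_row$seq_id]
  if (length(seq) != 1) abort(sprintf("sequence '%s' not in genome", gene_row$seq_id))
  iv <- if (nrow(exons) > 0) arrange(exons, .data$start) else gene_row
  pos <- unlist(purrr::map2(iv$start, iv$end, function(s, e) seq.int(s, e - 1L)))
  base <- strsplit(paste(substring(seq, iv$start + 1L, iv$end), collapse = ""), "")[[1]]
  if (gene_row$strand == "-") {
    pos <- rev(pos)
    base <- rev(chartr("ACGT", "TGCA", base))
  }
  tibble(genomic_pos = pos, cds_pos = seq_along(pos) - 1L, coding_base = base)
}

#' Call C-to-U RNA editing sites from pileup evidence
#'
#' A site is called where the coding-strand genomic base is C, read depth is
#' at least `min_depth`, and the T fraction among mapped bases is at least
#' `min_fraction`. Base counts in the pileup are expected in strand-aware
#' transcript orientation. The reported `editing_fraction` is T/(C+T).
#'
#' @param pileup Tibble with columns `seq_id`, `pos` (0-based genomic), `ref`,
#'   `depth`, `A`, `C`, `G`, `T`.
#' @param features Annotation tibble ([read_annotations()]); rows with
#'   `kind == "gene"` define CDS intervals, optionally with exon children
#'   (rows with `kind == "exon"` and matching `parent`).
#' @param genome Genome tibble containing the annotated sequences.
#' @param min_depth Minimum read depth (default 10).
#' @param min_fraction Minimum T fraction among mapped bases (default 0.1).
#' @return A tibble of editing sites: `gene`, `origin`, `seq_id`, `pos`,
#'   `cds_pos`, `codon_index`, `codon_pos`, `codon`, `effect`,
#'   `editing_fraction`, `depth`.
#' @export
call_editing_sites <- function(pileup, features, genome,
                               min_depth = 10, min_fraction = 0.1) {
  genes <- filter(features, .data$kind == "gene")
  out <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    exons <- filter(features, .data$kind == "exon",
                    !is.na(.data$parent), .data$parent == g$name)
    cmap <- gene_cds_map(g, exons, genome)
    rows <- pileup |>
      filter(.data$seq_id == g$seq_id) |>
      dplyr::inner_join(cmap, by = c(pos = "genomic_pos"))
    if (nrow(rows) == 0) return(NULL)
    cds_seq <- paste(cmap$coding_base, collapse = "")
    rows <- rows |>
      filter(.data$coding_base == "C",
             .data$depth >= min_depth,
             (.data$T / pmax(.data$A + .data$C + .data$G + .data$T, 1)) >= min_fraction,
             .data$T > 0)
    if (nrow(rows) == 0) return(NULL)
    rows |>
      mutate(gene = g$name, origin = g$origin,
             codon_index = .data$cds_pos %/% 3L,
             codon_pos = .data$cds_pos %% 3L,
             codon = substring(cds_seq, .data$codon_index * 3L + 1L,
                               .data$codon_index * 3L + 3L),
             editing_fraction = .data$T / (.data$C + .data$T)) |>
      filter(nchar(.data$codon) == 3) |>
      mutate(effect = classify_site_effect(.data$codon, .data$codon_pos)) |>
      select("gene", "origin", "seq_id", "pos", "cds_pos", "codon_index",
             "codon_pos", "codon", "effect", "editing_fraction", "depth")
  })
  dropped <- anti_positions_outside_cds(pileup, features)
  if (dropped > 0)
    warn(sprintf("%d pileup positions fall outside annotated CDS and were ignored", dropped))
  out
}

anti_positions_outside_cds <- function(pileup, features) {
  genes <- filter(features, .data$kind %in% c("gene", "exon"))
  if (nrow(genes) == 0) return(nrow(pileup))
  inside <- rep(FALSE, nrow(pileup))
  for (i in seq_len(nrow(genes)))
    inside <- inside | (pileup$seq_id == genes$seq_id[i] &
                          pileup$pos >= genes$start[i] & pileup$pos < genes$end[i])
  sum(!inside)
}

#' Summarize editing-site counts
#'
#' Computes the total number of C-to-U editing sites and the percentage that
#' are nonsynonymous (stop-gain sites count as nonsynonymous), rounded to one
#' decimal place.
#'
#' @param sites Editing-site tibble from [call_editing_sites()], or `NULL`
#'   when explicit counts are given.
#' @param n_nonsyn,n_syn Explicit counts, overriding `sites`.
#' @return A one-row tibble: `n_total`, `n_nonsyn`, `n_syn`,
#'   `nonsyn_percent` (`NA` when there are no sites).
#' @export
#' @examples
#' summarize_editing(n_nonsyn = 269, n_syn = 75)  # 344 sites, 78.2%
summarize_editing <- function(sites = NULL, n_nonsyn = NULL, n_syn = NULL) {
  if (is.null(n_nonsyn) || is.null(n_syn)) {
    if (is.null(sites)) abort("supply 'sites' or explicit counts")
    n_nonsyn <- sum(sites$effect %in% c("nonsynonymous", "stop_gain"))
    n_syn <- sum(sites$effect == "synonymous")
  }
  total <- n_nonsyn + n_syn
  tibble(n_total = total, n_nonsyn = n_nonsyn, n_syn = n_syn,
         nonsyn_percent = if (total == 0) NA_real_
                          else round(100 * n_nonsyn / total, 1))
}

#' Find conserved editing-site columns on a gene alignment
#'
#' A column qualifies as a conserved editing site when it maps to an
#' annotated editing site in at least `min_taxa` native homolog rows.
#'
#' @param alignment An `hgt_alignment` of the foreign gene with its native
#'   homologs.
#' @param annotations Tibble (`taxon`, `pos`) of predicted editing-site
#'   positions in ungapped 0-based coordinates of each row.
#' @param min_taxa Minimum native rows annotated at a column (default 2).
#' @param native_taxa Taxa counted as native homologs (default: all annotated
#'   taxa).
#' @return Integer vector of 1-based alignment columns.
#' @export
predict_conserved_sites <- function(alignment, annotations, min_taxa = 2,
                                    native_taxa = NULL) {
  native_taxa <- native_taxa %||% unique(annotations$taxon)
  cols <- purrr::map_dfr(intersect(native_taxa, alignment$taxon), function(tx) {
    cmap <- alignment_column_map(alignment, tx)
    pos <- annotations$pos[annotations$taxon == tx]
    if (any(pos >= length(cmap)))
      abort(sprintf("editing annotation beyond sequence length for taxon '%s'", tx))
    tibble(taxon = tx, column = cmap[pos + 1L])
  })
  if (nrow(cols) == 0) return(integer(0))
  keep <- cols |>
    distinct(.data$taxon, .data$column) |>
    dplyr::count(.data$column) |>
    filter(.data$n >= min_taxa)
  sort(keep$column)
}

#' Nucleotide states at conserved editing sites
#'
#' Builds the taxa x conserved-columns state matrix (`C`, `T`, `other`,
#' `gap`) used by the retroprocessing test, and flags columns where the
#' foreign row and exactly one native taxon share a T (a shared substitution
#' at an editing site -- evidence of donor identity, not a verdict changer).
#'
#' @param alignment An `hgt_alignment`.
#' @param conserved_cols Columns from [predict_conserved_sites()].
#' @param foreign_taxon Row treated as the foreign gene (for the shared-T
#'   flag); optional.
#' @return An object of class `hgt_editing_matrix`: a character matrix with
#'   attribute `shared_T_columns`.
#' @export
editing_state_matrix <- function(alignment, conserved_cols, foreign_taxon = NULL) {
  m <- alignment_matrix(alignment)
  states <- m[, conserved_cols, drop = FALSE]
  states[!(states %in% c("C", "T", "-"))] <- "other"
  states[states == "-"] <- "gap"
  colnames(states) <- as.character(conserved_cols)
  shared <- integer(0)
  if (!is.null(foreign_taxon) && foreign_taxon %in% rownames(states)) {
    f <- states[foreign_taxon, , drop = TRUE]
    natives <- states[setdiff(rownames(states), foreign_taxon), , drop = FALSE]
    shared <- conserved_cols[f == "T" & colSums(natives == "T") == 1]
  }
  structure(states, shared_T_columns = shared, class = "hgt_editing_matrix")
}

#' @export
print.hgt_editing_matrix <- function(x, ...) {
  cat(sprintf("<hgt_editing_matrix> %d taxa x %d conserved editing sites\n",
              nrow(x), ncol(x)))
  print(unclass(x))
  sh <- attr(x, "shared_T_columns")
  if (length(sh) > 0)
    cat("shared substitution at editing site (foreign + one native share T):",
        paste(sh, collapse = ", "), "\n")
  invisible(x)
}

#' Retroprocessing verdict for a foreign gene
#'
#' DNA-mediated transfer leaves unedited cytidines at conserved editing
#' sites; integration of a reverse-transcribed mRNA (retroprocessing) leaves
#' thymidines. The verdict is `dna_mediated` when the C fraction among
#' informative (C/T) cells of the foreign row reaches `majority`,
#' `retroprocessed` when the T fraction does, otherwise `ambiguous`.
#'
#' @param matrix An `hgt_editing_matrix` from [editing_state_matrix()].
#' @param foreign_row Row name of the foreign gene.
#' @param min_sites Minimum informative cells needed (default 3); fewer gives
#'   an `ambiguous` verdict flagged `insufficient_data`.
#' @param majority Majority fraction for a verdict (default 0.8).
#' @return A one-row tibble: `gene`, `n_sites`, `n_C`, `n_T`, `verdict`,
#'   `insufficient_data`.
#' @export
retroprocessing_verdict <- function(matrix, foreign_row, min_sites = 3,
                                    majority = 0.8) {
  if (!foreign_row %in% rownames(matrix))
    abort(sprintf("foreign row '%s' not in state matrix", foreign_row))
  f <- matrix[foreign_row, , drop = TRUE]
  n_C <- sum(f == "C"); n_T <- sum(f == "T")
  informative <- n_C + n_T
  insufficient <- informative < min_sites
  verdict <- if (insufficient) "ambiguous"
  else if (n_C / informative >= majority) "dna_mediated"
  else if (n_T / informative >= majority) "retroprocessed"
  else "ambiguous"
  tibble(gene = foreign_row, n_sites = ncol(matrix), n_C = n_C, n_T = n_T,
         verdict = verdict, insufficient_data = insufficient)
}
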