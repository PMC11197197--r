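# Pipeline orchestration: classify -> donors -> editing -> expression
# (-> shared), with per-stage failure isolation and a regenerable report.

#' Score foreign-sequence calls against simulator truth
#'
#' Per-base precision and recall of foreign calls, counting every base inside
#' a truth foreign segment as positive.
#'
#' @param segments Called segment tibble from [merge_segments()].
#' @param truth_segments Truth tibble (`start`, `end`, `category`) from an
#'   `hgt_simulation`; only foreign categories are scored.
#' @return A one-row tibble: `true_bp`, `called_bp`, `tp_bp`, `precision`,
#'   `recall`.
#' @export
score_classification <- function(segments, truth_segments) {
  tr <- truth_segments |>
    filter(.data$category %in% FOREIGN_CATEGORIES) |>
    select("start", "end") |> ivl_merge()
  ca <- segments |>
    filter(.data$category %in% FOREIGN_CATEGORIES) |>
    select("start", "end") |> ivl_merge()
  tp <- ivl_width(ivl_intersect(tr, ca))
  tibble(true_bp = ivl_width(tr), called_bp = ivl_width(ca), tp_bp = tp,
         precision = if (ivl_width(ca) > 0) tp / ivl_width(ca) else NA_real_,
         recall = if (ivl_width(tr) > 0) tp / ivl_width(tr) else NA_real_)
}

# Fig-2-style gene status: does a native copy of the same gene coexist?
gene_status <- function(gene_name, annotations) {
  native <- filter(annotations, .data$kind == "gene", .data$origin == "native",
                   .data$name == gene_name)
  if (nrow(native) == 0) return("foreign only")
  if (any(native$pseudogene)) return("native pseudogene + foreign")
  "native + foreign coexist"
}

# donor inference for one foreign gene: harvest homolog regions from the
# panel via homology search, align, bootstrap, sister-clade call
infer_gene_donor <- function(gene_row, genome, panel, taxonomy,
                             n_boot = 1000, seed = 1, threshold = 50,
                             pad = 50) {
  gseq <- substring(genome$seq[genome$id == gene_row$seq_id],
                    gene_row$start + 1L, gene_row$end)
  if (gene_row$strand == "-") gseq <- revcomp(gseq)
  qw <- tibble(seq_id = gene_row$seq_id, index = 1L, start = 0L, seq = gseq)
  hits <- search_windows(qw, panel)
  homs <- hits |>
    filter(.data$subject_group %in%
             c("angiosperm_mito", "non_gnetum_gymnosperm_mito")) |>
    group_by(.data$subject_taxon) |>
    slice_head(n = 1) |>
    ungroup()
  if (nrow(homs) < 3)
    return(tibble(foreign_gene = gene_row$name, sister_taxa = list(character(0)),
                  sister_label = "", support_percent = NA_real_,
                  verdict = "unresolved"))
  seqs <- purrr::map_dfr(seq_len(nrow(homs)), function(i) {
    h <- homs[i, ]
    subj <- panel$records$seq[panel$records$id == h$subject_id]
    s <- substring(subj, max(0L, h$s_start - pad) + 1L,
                   min(nchar(subj), h$s_end + pad))
    if (h$strand == "-") s <- revcomp(s)
    tibble(taxon = h$subject_taxon, seq = s)
  })
  seqs <- bind_rows(tibble(taxon = gene_row$name, seq = gseq), seqs)
  aln <- align_homologs(seqs)
  tree <- bootstrap_support(aln, n_reps = n_boot, seed = seed)
  call_donor(tree, gene_row$name, taxonomy, threshold = threshold) |>
    mutate(support_percent = round(.data$support_percent, 1))
}

#' Donor calls for all annotated foreign genes
#'
#' For each foreign gene, homologous regions are harvested from the panel by
#' homology search, aligned, bootstrapped, and run through the sister-clade
#' rule. Gene status follows the coexistence semantics of the donor-call
#' table: native + foreign coexist, foreign only, or native pseudogene +
#' foreign.
#'
#' @param genome,annotations,panel Pipeline inputs (`panel` indexed via
#'   [build_panel_index()]).
#' @param taxonomy Taxon -> group map for [call_donor()].
#' @param n_boot Bootstrap replicates per gene (default 1000).
#' @param seed Integer seed.
#' @param threshold Support threshold in percent.
#' @param harvest_k Word size for the homolog-harvest search (default 16 --
#'   more sensitive than the window scan, as gene-level searches need to see
#'   past donor-to-donor divergence).
#' @return A tibble: one row per foreign gene with `status`, `sister_label`,
#'   `support_percent`, `verdict`.
#' @export
call_all_donors <- function(genome, annotations, panel, taxonomy,
                            n_boot = 1000, seed = 1, threshold = 50,
                            harvest_k = 16) {
  fgenes <- filter(annotations, .data$kind == "gene", .data$origin == "foreign")
  if (nrow(fgenes) == 0)
    return(tibble(foreign_gene = character(), status = character(),
                  sister_taxa = list(), sister_label = character(),
                  support_percent = double(), verdict = character()))
  records <- if (inherits(panel, "hgt_panel")) panel$records else panel
  harvest_panel <- build_panel_index(records, k = harvest_k)
  purrr::map_dfr(seq_len(nrow(fgenes)), function(i) {
    infer_gene_donor(fgenes[i, ], genome, harvest_panel, taxonomy,
                     n_boot = n_boot, seed = seed + i, threshold = threshold) |>
      mutate(status = gene_status(fgenes$name[i], annotations), .after = 1)
  })
}

#' Run the full HGT-detection pipeline
#'
#' Executes the stages in order -- window classification, donor inference,
#' editing, expression -- on in-memory inputs, isolating failures per stage:
#' a failed stage is recorded and downstream stages that depend on it are
#' skipped, independent stages still run.
#'
#' @param genome Genome tibble ([read_genome()]).
#' @param annotations Annotation tibble ([read_annotations()]).
#' @param panel Reference panel tibble (with `group`), or an `hgt_panel`.
#' @param pileup,counts Optional RNA-evidence tibbles; their stages are
#'   skipped when absent.
#' @param taxonomy Optional taxon -> group map for donor calls (defaults to
#'   the panel's taxon/group pairs).
#' @param window_size Window size in bp (default 1000).
#' @param max_evalue,max_targets Homology search thresholds.
#' @param min_identity_native_mtpt Native-MTPT identity threshold.
#' @param n_boot Bootstrap replicates per foreign gene.
#' @param seed Integer seed.
#' @return An object of class `hgt_report`: a list with per-stage results
#'   (`summary`, `segments`, `windows`, `donor_calls`, `editing_sites`,
#'   `editing_summary`, `expression`, `stages`, `provenance`).
#' @export
run_pipeline <- function(genome, annotations, panel, pileup = NULL,
                         counts = NULL, taxonomy = NULL, window_size = 1000,
                         max_evalue = 1e-10, max_targets = 100,
                         min_identity_native_mtpt = 0.95, n_boot = 1000,
                         seed = 1) {
  if (!inherits(panel, "hgt_panel")) panel <- build_panel_index(panel)
  taxonomy <- taxonomy %||%
    setNames(ifelse(panel$records$group == "angiosperm_mito",
                    "angiosperm_mito", panel$records$group),
             panel$records$taxon)
  report <- list(stages = tibble(stage = character(), status = character(),
                                 note = character()))
  note_stage <- function(stage, status, note = "") {
    report$stages <<- bind_rows(report$stages,
                                tibble(stage = stage, status = status, note = note))
  }
  run_stage <- function(stage, code) {
    tryCatch({ v <- force(code); note_stage(stage, "ok"); v },
             error = function(e) { note_stage(stage, "failed", conditionMessage(e)); NULL })
  }
  # stage 1: classification
  cls <- run_stage("classify", {
    windows <- extract_windows(genome, size = window_size)
    hits <- search_windows(windows, panel, max_targets = max_targets,
                           max_evalue = max_evalue)
    wcls <- classify_windows(windows, hits,
                             min_identity_native_mtpt = min_identity_native_mtpt)
    segments <- merge_segments(wcls, hits)
    native_mtpt_bp <- sum(wcls$width[wcls$category == "native_MTPT"])
    list(windows = wcls, hits = hits, segments = segments,
         summary = summarize_genome(segments, genome,
                                    native_mtpt_bp = native_mtpt_bp))
  })
  report$windows <- cls$windows
  report$segments <- cls$segments
  report$summary <- cls$summary
  # stage 2: donors (needs classification only for reporting; runs off
  # annotations, so independent of stage 1 success)
  donors <- run_stage("donors",
    call_all_donors(genome, annotations, panel, taxonomy,
                    n_boot = n_boot, seed = seed))
  report$donor_calls <- donors
  # stage 3: editing
  if (!is.null(pileup)) {
    ed <- run_stage("editing", {
      sites <- call_editing_sites(pileup, annotations, genome)
      list(sites = sites, summary = summarize_editing(sites))
    })
    report$editing_sites <- ed$sites
    report$editing_summary <- ed$summary
  } else note_stage("editing", "skipped", "no pileup supplied")
  # stage 4: expression
  if (!is.null(counts)) {
    ex <- run_stage("expression", expression_contrast(counts))
    report$expression <- ex
  } else note_stage("expression", "skipped", "no counts supplied")
  report$provenance <- list(
    seed = seed,
    window_size = window_size,
    max_evalue = max_evalue,
    config_hash = rlang::hash(list(window_size, max_evalue, max_targets,
                                   min_identity_native_mtpt, n_boot, seed)),
    package_version = as.character(utils::packageVersion("hgtscan")))
  structure(report, class = "hgt_report")
}

#' @export
print.hgt_report <- function(x, ...) {
  cat("<hgt_report>\n")
  print(x$stages)
  if (!is.null(x$summary)) {
    cat("\nGenome summary:\n")
    print(x$summary)
  }
  if (!is.null(x$donor_calls) && nrow(x$donor_calls) > 0) {
    cat("\nDonor calls:\n")
    print(select(x$donor_calls, "foreign_gene", "status", "sister_label",
                 "support_percent", "verdict"))
  }
  if (!is.null(x$editing_summary)) {
    cat("\nC-to-U editing:\n")
    print(x$editing_summary)
  }
  if (!is.null(x$expression)) print(x$expression$test)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `hgt_report`.
#' @param ... Unused.
#' @export
glance.hgt_report <- function(x, ...) {
  s <- x$summary %||% tibble(foreign_total_bp = NA_integer_,
                             foreign_fraction_percent = NA_real_)
  tibble(genome_size = s$genome_size %||% NA_integer_,
         foreign_total_bp = s$foreign_total_bp,
         foreign_fraction_percent = s$foreign_fraction_percent,
         n_foreign_genes = if (is.null(x$donor_calls)) NA_integer_
                           else nrow(x$donor_calls),
         n_donor_assigned = if (is.null(x$donor_calls)) NA_integer_
                            else sum(x$donor_calls$verdict == "donor_assigned"),
         n_editing_sites = if (is.null(x$editing_summary)) NA_integer_
                           else x$editing_summary$n_total,
         expression_p = if (is.null(x$expression)) NA_real_
                        else x$expression$test$p_two_tailed)
}

#' @rdname run_pipeline
#' @export
tidy.hgt_report <- function(x, ...) {
  if (is.null(x$segments)) return(tibble())
  select(x$segments, -"top_taxa")
}

#' Write a report's tables to a directory
#'
#' Emits the segment BED, summary TSV, donor-call TSV, editing TSV,
#' expression TSV and a JSON digest into `dir`.
#'
#' @param report An `hgt_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$segments))
    write_segments_bed(report$segments, file.path(dir, "foreign_segments.bed"))
  if (!is.null(report$summary))
    readr::write_tsv(report$summary, file.path(dir, "genome_summary.tsv"))
  if (!is.null(report$donor_calls))
    readr::write_tsv(select(report$donor_calls, -"sister_taxa"),
                     file.path(dir, "donor_calls.tsv"))
  if (!is.null(report$editing_sites))
    readr::write_tsv(report$editing_sites, file.path(dir, "editing_sites.tsv"))
  if (!is.null(report$expression))
    readr::write_tsv(report$expression$expression, file.path(dir, "expression.tsv"))
  jsonlite::write_json(c(as.list(glance(report)),
                         provenance = list(report$provenance)),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
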