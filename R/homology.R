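# Seed-and-extend local similarity search against a labeled reference panel.
# A desk-scale analogue of megablast: exact k-mer seeds (word size 28 by
# default) are located through a hash index over both strands, seed clusters
# are extended by full affine-gap local alignment, and hits are filtered by a
# Karlin-Altschul E-value.

PANEL_GROUPS <- c("gnetum_plastid", "gnetum_mito", "non_gnetum_gymnosperm_mito",
                  "non_gymnosperm_plastid", "angiosperm_mito", "other")

# Karlin-Altschul parameters for ungapped DNA scoring, applied to the gapped
# score as a documented approximation.
KA_LAMBDA <- 0.625
KA_K <- 0.41

kmerize <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1), k:L)
}

#' Build a k-mer index over a labeled reference panel
#'
#' Every exact k-mer occurrence in the panel, on both strands, becomes a
#' posting retrievable by [search_windows()]. Panel records must carry a
#' `group` column with one of the recognized taxon-compartment groups:
#' `r paste(PANEL_GROUPS, collapse = ", ")`.
#'
#' @param panel Tibble of panel records with columns `id`, `taxon`, `group`,
#'   `seq` (e.g. from [read_genome()] with a taxonomy table).
#' @param k Seed word size in bp (default 28, minimum 8).
#' @return An object of class `hgt_panel` wrapping the records and the index.
#' @export
build_panel_index <- function(panel, k = 28) {
  if (k < 8) abort("seed word size below 8 is too unspecific")
  panel <- as_tibble(panel)
  if (!"group" %in% names(panel)) abort("panel must have a 'group' column")
  if (!"taxon" %in% names(panel)) panel$taxon <- panel$id
  bad <- !panel$group %in% PANEL_GROUPS
  if (any(bad))
    abort(sprintf("unknown panel group '%s' (expected one of: %s)",
                  panel$group[bad][1], paste(PANEL_GROUPS, collapse = ", ")))
  if (any(nchar(panel$seq) < k))
    abort("all panel sequences must be at least as long as the word size")
  panel$rc <- revcomp(panel$seq)
  postings <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    fw <- kmerize(panel$seq[i], k)
    rv <- kmerize(panel$rc[i], k)
    tibble(kmer = c(fw, rv),
           rec = i,
           pos = c(seq_along(fw), seq_along(rv)) - 1L,
           strand = rep(c("+", "-"), c(length(fw), length(rv))))
  })
  idx <- data.table::as.data.table(postings)
  data.table::setkey(idx, kmer)
  structure(list(records = panel, index = idx, k = k,
                 total_bp = sum(nchar(panel$seq))),
            class = "hgt_panel")
}

#' @export
print.hgt_panel <- function(x, ...) {
  cat(sprintf("<hgt_panel> %d records, %s bp, word size %d\n",
              nrow(x$records), format(x$total_bp, big.mark = ","), x$k))
  print(dplyr::count(x$records, .data$group))
  invisible(x)
}

evalue_from_score <- function(score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

bitscore_from_score <- function(score) {
  (KA_LAMBDA * score - log(KA_K)) / log(2)
}

# Run one query sequence against the panel. Returns window-local 0-based
# half-open query coordinates and forward-strand subject coordinates.
search_one <- function(qseq, panel, max_targets, max_evalue, min_aln_len,
                       match, mismatch, gap_open, gap_ext) {
  k <- panel$k
  qk <- kmerize(qseq, k)
  if (length(qk) == 0) return(NULL)
  qdt <- data.table::data.table(kmer = qk, qpos = seq_along(qk) - 1L)
  seeds <- panel$index[qdt, on = "kmer", nomatch = NULL]
  if (nrow(seeds) == 0) return(NULL)
  qlen <- nchar(qseq)
  seeds[, diag := pos - qpos]
  hits <- list()
  for (key in split(seq_len(nrow(seeds)),
                    paste(seeds$rec, seeds$strand, sep = "."))) {
    s <- seeds[key]
    rec <- s$rec[1]; strand <- s$strand[1]
    subj <- if (strand == "+") panel$records$seq[rec] else panel$records$rc[rec]
    slen <- nchar(subj)
    # cluster seeds into candidate regions by subject-position gaps
    s <- s[order(s$pos)]
    brk <- cumsum(c(1L, as.integer(diff(s$pos) > qlen)))
    for (g in split(seq_len(nrow(s)), brk)) {
      cl <- s[g]
      lo <- max(0L, min(cl$diag) - 100L)
      hi <- min(slen, max(cl$diag) + qlen + 100L)
      aln <- .sw_local(qseq, substring(subj, lo + 1L, hi),
                       match, mismatch, gap_open, gap_ext)
      if (aln$aln_len < min_aln_len) next
      s_start <- lo + aln$b_start; s_end <- lo + aln$b_end
      if (strand == "-") { tmp <- s_start; s_start <- slen - s_end; s_end <- slen - tmp }
      hits[[length(hits) + 1]] <- tibble(
        subject_id = panel$records$id[rec],
        subject_taxon = panel$records$taxon[rec],
        subject_group = panel$records$group[rec],
        strand = strand,
        q_start = aln$a_start, q_end = aln$a_end,
        s_start = s_start, s_end = s_end,
        score = aln$score,
        identity = aln$n_ident / aln$aln_len,
        mismatches = aln$n_mismatch, gapopens = aln$n_gapopen,
        aln_len = aln$aln_len)
    }
  }
  if (length(hits) == 0) return(NULL)
  out <- bind_rows(hits) |>
    mutate(evalue = evalue_from_score(.data$score, qlen, panel$total_bp),
           bitscore = bitscore_from_score(.data$score)) |>
    filter(.data$evalue <= max_evalue)
  if (nrow(out) == 0) return(NULL)
  # merge overlapping hits to the same subject: keep the best-scoring one
  out <- out |>
    arrange(desc(.data$score)) |>
    group_by(.data$subject_id) |>
    filter(!overlaps_better(.data$q_start, .data$q_end, .data$score)) |>
    ungroup() |>
    arrange(.data$evalue, desc(.data$score)) |>
    slice_head(n = max_targets)
  out
}

# within one subject, drop hits whose query interval overlaps a higher-scoring
# hit (rows arrive sorted by descending score)
overlaps_better <- function(qs, qe, score) {
  n <- length(qs)
  drop <- logical(n)
  if (n > 1) {
    for (i in 2:n) {
      for (j in seq_len(i - 1)) {
        if (!drop[j] && qs[i] < qe[j] && qs[j] < qe[i]) { drop[i] <- TRUE; break }
      }
    }
  }
  drop
}

#' Search windows against an indexed reference panel
#'
#' For each window, exact seed matches are clustered into candidate subject
#' regions and extended by affine-gap local alignment (match +1, mismatch -2,
#' gap open -5, gap extend -2, megablast-like defaults). Hits shorter than
#' `min_aln_len` or with E-value above `max_evalue` are discarded; remaining
#' hits are sorted by ascending E-value and truncated to `max_targets` per
#' window. Overlapping hits to the same subject are merged to the
#' best-scoring one.
#'
#' @param windows Window tibble from [extract_windows()] (or any tibble with
#'   `seq_id`, `index`, `start`, `seq`).
#' @param panel An `hgt_panel` from [build_panel_index()].
#' @param max_targets Maximum hits reported per window (default 100).
#' @param max_evalue E-value ceiling (default 1e-10).
#' @param min_aln_len Minimum reported alignment length in bp (default 50).
#' @param match,mismatch,gap_open,gap_ext Alignment scoring parameters.
#' @return A tibble of hits, one row per window x subject region, with query
#'   coordinates both window-local (`q_start`, `q_end`) and genomic
#'   (`g_start`, `g_end`), all 0-based half-open.
#' @export
search_windows <- function(windows, panel, max_targets = 100, max_evalue = 1e-10,
                           min_aln_len = 50, match = 1, mismatch = -2,
                           gap_open = -5, gap_ext = -2) {
  stopifnot(inherits(panel, "hgt_panel"))
  res <- purrr::map(seq_len(nrow(windows)), function(i) {
    h <- search_one(windows$seq[i], panel, max_targets, max_evalue, min_aln_len,
                    match, mismatch, gap_open, gap_ext)
    if (is.null(h)) return(NULL)
    mutate(h, seq_id = windows$seq_id[i], window_index = windows$index[i],
           g_start = windows$start[i] + .data$q_start,
           g_end = windows$start[i] + .data$q_end, .before = 1)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0)
    return(tibble(seq_id = character(), window_index = integer(),
                  g_start = integer(), g_end = integer(),
                  subject_id = character(), subject_taxon = character(),
                  subject_group = character(), strand = character(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(), score = double(),
                  identity = double(), mismatches = integer(),
                  gapopens = integer(), aln_len = integer(),
                  evalue = double(), bitscore = double()))
  out
}

#' Write hits in 12-column tab-separated pairwise format
#'
#' The classic BLAST `outfmt 6` dialect (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), with 1-based inclusive
#' coordinates on output.
#'
#' @param hits Hit tibble from [search_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- tibble(
    qseqid = paste0(hits$seq_id, ":w", hits$window_index),
    sseqid = hits$subject_id,
    pident = round(100 * hits$identity, 3),
    length = hits$aln_len,
    mismatch = hits$mismatches,
    gapopen = hits$gapopens,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = ifelse(hits$strand == "+", hits$s_start + 1L, hits$s_end),
    send = ifelse(hits$strand == "+", hits$s_end, hits$s_start + 1L),
    evalue = signif(hits$evalue, 3),
    bitscore = round(hits$bitscore, 1))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
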