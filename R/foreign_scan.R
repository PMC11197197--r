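# Native/foreign classification of windows, segment merging with
# homology-refined boundaries, and Table-1-style genome summaries.

PLASTID_GROUPS <- c("gnetum_plastid", "non_gymnosperm_plastid")
MITO_GROUPS <- c("gnetum_mito", "non_gnetum_gymnosperm_mito", "angiosperm_mito")
FOREIGN_CATEGORIES <- c("foreign_MTPT", "foreign_mito")

classify_one <- function(groups, identities, evalues,
                         min_identity_native_mtpt) {
  if (length(groups) == 0) return("unclassified")
  # rule 1: a good hit to the recipient genus' own plastome -> native MTPT
  if (any(groups == "gnetum_plastid" & identities >= min_identity_native_mtpt))
    return("native_MTPT")
  plastid <- groups[groups %in% PLASTID_GROUPS]
  mito <- groups[groups %in% MITO_GROUPS]
  # rule 2: plastid-type hits exclusively from non-gymnosperm plastomes
  fmtpt <- length(plastid) > 0 && all(plastid == "non_gymnosperm_plastid")
  # rule 3: mito-type hits include angiosperms and exclude other gymnosperms
  fmito <- any(mito == "angiosperm_mito") &&
    !any(mito == "non_gnetum_gymnosperm_mito")
  if (fmtpt && fmito) {
    # both foreign routes qualify: best E-value wins, ties by identity,
    # then category priority foreign_mito > foreign_MTPT
    bp <- which(groups == "non_gymnosperm_plastid")
    bm <- which(groups == "angiosperm_mito")
    ep <- min(evalues[bp]); em <- min(evalues[bm])
    if (em < ep) return("foreign_mito")
    if (ep < em) return("foreign_MTPT")
    ip <- max(identities[bp]); im <- max(identities[bm])
    if (im >= ip) return("foreign_mito") else return("foreign_MTPT")
  }
  if (fmtpt) return("foreign_MTPT")
  if (fmito) return("foreign_mito")
  # rule 4: any hit to gymnosperm or congeneric mitochondrial sequence
  if (any(mito %in% c("non_gnetum_gymnosperm_mito", "gnetum_mito")))
    return("native_mito")
  "unclassified"
}

#' Classify windows as native or foreign from their homology hits
#'
#' Applies a taxon-match rule cascade per window: (1) a hit to the recipient
#' genus' own plastome at identity >= `min_identity_native_mtpt` makes the
#' window a native MTPT; (2) plastid-type hits exclusively from non-gymnosperm
#' plastomes make it a foreign MTPT; (3) mitochondrial-type hits that include
#' angiosperm mitogenomes but no non-congeneric gymnosperm mitogenome make it
#' foreign mitochondrion-derived; (4) any remaining hit to a gymnosperm or
#' congeneric mitogenome makes it native; (5) windows with no qualifying hits
#' are unclassified and treated downstream as native of unknown affinity.
#' The classification is a pure function of the hit groups and thresholds and
#' does not depend on hit order.
#'
#' @param windows Window tibble from [extract_windows()].
#' @param hits Hit tibble from [search_windows()] (already E-value filtered).
#' @param min_identity_native_mtpt Identity needed for the native-MTPT rule
#'   (default 0.95, operationalizing "nearly identical" plastid copies).
#' @return The window tibble with columns `category`, `supporting_groups`
#'   (list), `n_hits`, `best_subject`, `best_identity`, `best_evalue` added.
#' @export
classify_windows <- function(windows, hits, min_identity_native_mtpt = 0.95) {
  key <- paste(windows$seq_id, windows$index)
  hkey <- paste(hits$seq_id, hits$window_index)
  split_idx <- split(seq_len(nrow(hits)), factor(hkey, levels = key))
  res <- purrr::map(split_idx, function(ix) {
    h <- hits[ix, , drop = FALSE]
    if (nrow(h) == 0)
      return(list(category = "unclassified", groups = list(character(0)),
                  n = 0L, subj = NA_character_, ident = NA_real_, ev = NA_real_))
    best <- which.min(h$evalue)
    list(category = classify_one(h$subject_group, h$identity, h$evalue,
                                 min_identity_native_mtpt),
         groups = list(sort(unique(h$subject_group))),
         n = nrow(h), subj = h$subject_id[best],
         ident = h$identity[best], ev = h$evalue[best])
  })
  res <- unname(res)
  windows |>
    mutate(category = purrr::map_chr(res, "category"),
           supporting_groups = purrr::map(res, ~ .x$groups[[1]]),
           n_hits = purrr::map_int(res, "n"),
           best_subject = purrr::map_chr(res, "subj"),
           best_identity = purrr::map_dbl(res, "ident"),
           best_evalue = purrr::map_dbl(res, "ev"))
}

segment_group_for <- function(category) {
  switch(category,
         foreign_mito = "angiosperm_mito",
         foreign_MTPT = "non_gymnosperm_plastid",
         abort(sprintf("not a foreign category: %s", category)))
}

# homology-evidence boundary refinement: trim the terminal windows of a
# segment to the extent covered by hits of the segment's donor group, and
# extend into flanking mixed windows whose donor-group hits abut the segment
# boundary.
refine_edges <- function(seg_start, seg_end, seq_id, w_first, w_last,
                         windows, hits, group, slack = 20L) {
  wh <- hits[hits$seq_id == seq_id & hits$subject_group == group, , drop = FALSE]
  if (nrow(wh) == 0) return(c(seg_start, seg_end))
  win <- windows[windows$seq_id == seq_id, , drop = FALSE]
  # trim within terminal windows
  h1 <- wh[wh$window_index == w_first, , drop = FALSE]
  if (nrow(h1) > 0) seg_start <- min(h1$g_start)
  h2 <- wh[wh$window_index == w_last, , drop = FALSE]
  if (nrow(h2) > 0) seg_end <- max(h2$g_end)
  # extend into the left flanking window if its donor hits touch the boundary
  if (w_first > 1) {
    wl <- win[win$index == w_first - 1L, , drop = FALSE]
    hl <- wh[wh$window_index == w_first - 1L, , drop = FALSE]
    if (nrow(wl) == 1 && nrow(hl) > 0) {
      touch <- hl$g_end >= wl$end - slack
      if (any(touch)) seg_start <- min(hl$g_start[touch])
    }
  }
  # right flank
  wr <- win[win$index == w_last + 1L, , drop = FALSE]
  hr <- wh[wh$window_index == w_last + 1L, , drop = FALSE]
  if (nrow(wr) == 1 && nrow(hr) > 0) {
    touch <- hr$g_start <= wr$start + slack
    if (any(touch)) seg_end <- max(hr$g_end[touch])
  }
  c(seg_start, seg_end)
}

#' Merge classified foreign windows into segments
#'
#' Runs of consecutive windows with the same foreign category are merged into
#' segments; gaps of up to `max_gap_windows` unclassified windows inside a run
#' are absorbed. When `hits` are supplied (the default pipeline path), segment
#' boundaries are refined with the homology evidence: terminal windows are
#' trimmed to the extent of the segment's donor-group hits and flanking
#' windows whose donor-group hits abut the segment boundary extend it, giving
#' sub-window boundary resolution.
#'
#' @param classifications Window classification tibble from
#'   [classify_windows()], sorted by position within each sequence.
#' @param hits Optional hit tibble for boundary refinement.
#' @param max_gap_windows Number of intervening unclassified windows absorbed
#'   into a run (default 0).
#' @return A tibble of segments: `seq_id`, `start`, `end`, `category`,
#'   `length`, `n_windows`, `top_taxa` (list of taxon/identity tibbles).
#' @export
merge_segments <- function(classifications, hits = NULL, max_gap_windows = 0) {
  cl <- classifications
  if (is.unsorted(order(cl$seq_id, cl$index)) ||
      any(unlist(tapply(cl$index, cl$seq_id, function(ix) diff(ix) <= 0))))
    abort("window classifications must be sorted by position within each sequence")
  segs <- list()
  for (sid in unique(cl$seq_id)) {
    w <- cl[cl$seq_id == sid, , drop = FALSE]
    for (cat in FOREIGN_CATEGORIES) {
      is_f <- w$category == cat
      absorb <- w$category == "unclassified"
      # run detection with gap absorption
      i <- 1L; n <- nrow(w)
      while (i <= n) {
        if (!is_f[i]) { i <- i + 1L; next }
        j <- i; last_f <- i
        while (j < n) {
          nxt <- j + 1L
          if (is_f[nxt]) { j <- nxt; last_f <- nxt; next }
          # try to absorb a bounded run of unclassified windows
          g <- 0L; k2 <- nxt
          while (k2 <= n && absorb[k2] && g < max_gap_windows) { g <- g + 1L; k2 <- k2 + 1L }
          if (k2 <= n && g <= max_gap_windows && g > 0L && is_f[k2]) {
            j <- k2; last_f <- k2
          } else break
        }
        seg_start <- w$start[i]; seg_end <- w$end[last_f]
        if (!is.null(hits)) {
          se <- refine_edges(seg_start, seg_end, sid, w$index[i], w$index[last_f],
                             classifications, hits, segment_group_for(cat))
          seg_start <- se[1]; seg_end <- se[2]
        }
        top <- if (!is.null(hits)) {
          hits |>
            filter(.data$seq_id == sid,
                   .data$window_index %in% w$index[i:last_f],
                   .data$subject_group == segment_group_for(cat)) |>
            group_by(taxon = .data$subject_taxon) |>
            summarise(best_identity = max(.data$identity), .groups = "drop") |>
            arrange(desc(.data$best_identity))
        } else tibble(taxon = character(), best_identity = double())
        segs[[length(segs) + 1]] <- tibble(
          seq_id = sid, start = as.integer(seg_start), end = as.integer(seg_end),
          category = cat, length = as.integer(seg_end - seg_start),
          n_windows = last_f - i + 1L, top_taxa = list(top))
        i <- last_f + 1L
      }
    }
  }
  out <- bind_rows(segs)
  if (nrow(out) == 0)
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  category = character(), length = integer(),
                  n_windows = integer(), top_taxa = list()))
  arrange(out, .data$seq_id, .data$start)
}

#' Summarize foreign content of a genome
#'
#' Computes the foreign-sequence summary of a genome from its merged foreign
#' segments (or from explicit per-category totals): total foreign bp and the
#' foreign fraction of the genome, rounded to one decimal place.
#'
#' @param segments Segment tibble from [merge_segments()], or `NULL` when
#'   explicit totals are given.
#' @param genome One-row genome tibble, or `NULL` when `genome_size` is given.
#' @param native_mtpt_bp Native MTPT total in bp (reported, not counted as
#'   foreign).
#' @param foreign_mtpt_bp,foreign_mito_bp Explicit per-category totals,
#'   overriding `segments`.
#' @param genome_size Explicit genome size in bp, overriding `genome`.
#' @return A one-row tibble: `genome_size`, `gc_percent`, `native_mtpt_bp`,
#'   `foreign_mtpt_bp`, `foreign_mito_bp`, `foreign_total_bp`,
#'   `foreign_fraction_percent`.
#' @export
#' @examples
#' summarize_genome(foreign_mtpt_bp = 1664, foreign_mito_bp = 34971,
#'                  genome_size = 575501)
summarize_genome <- function(segments = NULL, genome = NULL, native_mtpt_bp = 0,
                             foreign_mtpt_bp = NULL, foreign_mito_bp = NULL,
                             genome_size = NULL) {
  if (is.null(genome_size)) {
    if (is.null(genome)) abort("supply either 'genome' or 'genome_size'")
    genome_size <- sum(genome$length)
  }
  if (genome_size <= 0) abort("genome size must be positive")
  gc_percent <- if (!is.null(genome)) round(100 * sum(gc_content(genome$seq) * genome$length) /
                                              sum(genome$length), 1) else NA_real_
  if (is.null(foreign_mtpt_bp) || is.null(foreign_mito_bp)) {
    if (is.null(segments)) abort("supply 'segments' or explicit per-category totals")
    ov <- segments |>
      group_by(.data$seq_id, .data$category) |>
      summarise(overlap = any(.data$start < dplyr::lag(.data$end, default = -1L)),
                .groups = "drop")
    if (any(ov$overlap)) abort("segments of one category must be non-overlapping")
    foreign_mtpt_bp <- sum(segments$length[segments$category == "foreign_MTPT"])
    foreign_mito_bp <- sum(segments$length[segments$category == "foreign_mito"])
  }
  total <- foreign_mtpt_bp + foreign_mito_bp
  tibble(genome_size = genome_size,
         gc_percent = gc_percent,
         native_mtpt_bp = native_mtpt_bp,
         foreign_mtpt_bp = foreign_mtpt_bp,
         foreign_mito_bp = foreign_mito_bp,
         foreign_total_bp = total,
         foreign_fraction_percent = round(100 * total / genome_size, 1))
}

#' Write foreign segments as BED
#'
#' Standard 0-based half-open BED with the segment category in the name
#' column.
#'
#' @param segments Segment tibble from [merge_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  readr::write_tsv(tibble(chrom = segments$seq_id, start = segments$start,
                          end = segments$end, name = segments$category),
                   path, col_names = FALSE)
  invisible(path)
}
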