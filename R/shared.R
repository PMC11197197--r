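# Cross-species shared foreign sequence: maximal-exact-match anchoring and
# 3-set Venn quantification of foreign bases in bp.

#' Find maximal exact matches between two sequences
#'
#' All maximal exact matches (MEMs) of length at least `min_len`, on both
#' strands: exact substring matches that cannot be extended on either side.
#' Coordinates are 0-based half-open on the forward strand of each sequence.
#'
#' @param a,b Sequences: DNA strings or one-row genome tibbles with `seq`.
#' @param min_len Minimum anchor length in bp (default 50; below 20 is
#'   rejected as a spurious-match floor).
#' @return A tibble: `a_start`, `a_end`, `b_start`, `b_end`, `length`,
#'   `strand`.
#' @export
find_exact_anchors <- function(a, b, min_len = 50) {
  if (min_len < 20) abort("anchors shorter than 20 bp are spurious; raise min_len")
  if (is.data.frame(a)) a <- a$seq[1]
  if (is.data.frame(b)) b <- b$seq[1]
  if (nchar(a) == 0 || nchar(b) == 0) abort("both sequences must be non-empty")
  fw <- .mems_fwd(a, b, min_len)
  rcb <- revcomp(b)
  rv <- .mems_fwd(a, rcb, min_len)
  out <- tibble(a_start = integer(), a_end = integer(), b_start = integer(),
                b_end = integer(), strand = character())
  if (nrow(fw) > 0)
    out <- bind_rows(out, tibble(a_start = unname(fw[, 1]), a_end = unname(fw[, 2]),
                                 b_start = unname(fw[, 3]), b_end = unname(fw[, 4]),
                                 strand = "+"))
  if (nrow(rv) > 0) {
    m <- nchar(b)
    out <- bind_rows(out, tibble(a_start = unname(rv[, 1]), a_end = unname(rv[, 2]),
                                 b_start = m - unname(rv[, 4]),
                                 b_end = m - unname(rv[, 3]),
                                 strand = "-"))
  }
  out |>
    mutate(length = .data$a_end - .data$a_start) |>
    arrange(.data$a_start, .data$b_start) |>
    select("a_start", "a_end", "b_start", "b_end", "length", "strand")
}

#' Write anchors in a MUMmer-style coordinate table
#'
#' Tab-separated with 1-based inclusive coordinates, one row per anchor.
#'
#' @param anchors Tibble from [find_exact_anchors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchors_tsv <- function(anchors, path) {
  readr::write_tsv(tibble(s1 = anchors$a_start + 1L, e1 = anchors$a_end,
                          s2 = anchors$b_start + 1L, e2 = anchors$b_end,
                          len = anchors$length, strand = anchors$strand),
                   path)
  invisible(path)
}

# bases of species X (interval set, X coordinates) shared with species Y:
# anchors must intersect foreign segments on both sides
shared_bases_one_way <- function(fx, fy, anchors, min_shared) {
  anchors <- filter(anchors, .data$length >= min_shared)
  if (nrow(anchors) == 0) return(tibble(start = integer(), end = integer()))
  qual <- purrr::map_lgl(seq_len(nrow(anchors)), function(i) {
    ivl_width(ivl_intersect(tibble(start = anchors$a_start[i], end = anchors$a_end[i]), fx)) > 0 &&
      ivl_width(ivl_intersect(tibble(start = anchors$b_start[i], end = anchors$b_end[i]), fy)) > 0
  })
  if (!any(qual)) return(tibble(start = integer(), end = integer()))
  cov <- ivl_merge(tibble(start = anchors$a_start[qual], end = anchors$a_end[qual]))
  ivl_intersect(cov, fx)
}

#' Quantify foreign sequence shared across three species
#'
#' Builds the 7-region base-count Venn of foreign segments across three
#' species. A foreign base of species X is shared with species Y when it is
#' covered by an anchor (of length >= `min_shared`) that intersects foreign
#' segments in both species; the triple region holds bases shared pairwise
#' with both other species. Because anchor coverage is counted in each
#' species' own coordinates, pairwise regions are reported from both species'
#' frames (they can differ slightly, e.g. through indels), rather than
#' collapsed.
#'
#' @param segments Named list (one element per species) of foreign-segment
#'   tibbles with `start`, `end` (single-sequence genomes; coordinates on the
#'   species' genome).
#' @param anchors Named list of anchor tibbles for the three species pairs,
#'   with names `"X|Y"` meaning a = species X, b = species Y (one orientation
#'   per pair suffices).
#' @param min_shared Minimum anchor length counted as shared (default 50).
#' @return An object of class `hgt_venn`: a tibble with columns `region`
#'   (e.g. `"A&B"`, `"A&B&C"`, `"A only"`), `frame` (the species whose
#'   coordinates the bases are counted in) and `bp`; the per-species
#'   membership tables are in attribute `membership`.
#' @export
shared_foreign_venn <- function(segments, anchors, min_shared = 50) {
  sp <- names(segments)
  if (length(sp) != 3) abort("shared_foreign_venn expects exactly 3 species")
  fg <- lapply(segments, function(s) ivl_merge(tibble(start = s$start, end = s$end)))
  get_anchors <- function(x, y) {
    key <- paste(x, y, sep = "|"); rkey <- paste(y, x, sep = "|")
    if (!is.null(anchors[[key]])) return(anchors[[key]])
    if (!is.null(anchors[[rkey]])) {
      a <- anchors[[rkey]]
      return(tibble(a_start = a$b_start, a_end = a$b_end,
                    b_start = a$a_start, b_end = a$a_end,
                    length = a$length, strand = a$strand))
    }
    abort(sprintf("no anchors supplied for species pair %s / %s", x, y))
  }
  shared <- list()
  for (x in sp) for (y in setdiff(sp, x))
    shared[[paste(x, y, sep = "|")]] <-
      shared_bases_one_way(fg[[x]], fg[[y]], get_anchors(x, y), min_shared)
  rows <- list(); membership <- list()
  for (x in sp) {
    others <- setdiff(sp, x)
    s1 <- shared[[paste(x, others[1], sep = "|")]]
    s2 <- shared[[paste(x, others[2], sep = "|")]]
    triple <- ivl_intersect(s1, s2)
    p1 <- ivl_setdiff(s1, triple)
    p2 <- ivl_setdiff(s2, triple)
    uniq <- ivl_setdiff(ivl_setdiff(fg[[x]], s1), s2)
    rows[[x]] <- tibble(
      region = c(paste(x, "only"),
                 paste(sort(c(x, others[1])), collapse = "&"),
                 paste(sort(c(x, others[2])), collapse = "&"),
                 paste(sort(sp), collapse = "&")),
      frame = x,
      bp = c(ivl_width(uniq), ivl_width(p1), ivl_width(p2), ivl_width(triple)))
    membership[[x]] <- list(unique = uniq,
                            pair = setNames(list(p1, p2), others),
                            triple = triple)
  }
  out <- bind_rows(rows) |> arrange(.data$region, .data$frame)
  structure(out, membership = membership,
            class = c("hgt_venn", class(out)))
}
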