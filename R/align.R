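# Progressive multiple alignment over a k-mer-distance guide tree, with
# affine-gap profile-profile alignment (match +1, mismatch -1, open -4,
# extend -1). Deterministic for fixed input order and tie rules.

BASES <- c("A", "C", "G", "T")

seq_to_profile <- function(rows) {
  # rows: character matrix (sequences x columns) incl. "-"
  L <- ncol(rows)
  prof <- matrix(0, 4, L, dimnames = list(BASES, NULL))
  for (b in seq_along(BASES))
    prof[b, ] <- colMeans(rows == BASES[b])
  prof
}

kmer_set_distance <- function(seqs, k = 6) {
  sets <- lapply(seqs, function(s) unique(kmerize(s, k)))
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / min(length(sets[[i]]), length(sets[[j]]))
  }
  d
}

apply_ops <- function(rows_a, rows_b, ops) {
  # ops: 1 both, 2 column from A (gap in B), 3 column from B (gap in A)
  la <- ops != 3; lb <- ops != 2
  ia <- cumsum(la); ib <- cumsum(lb)
  L <- length(ops)
  out_a <- matrix("-", nrow(rows_a), L)
  out_b <- matrix("-", nrow(rows_b), L)
  out_a[, la] <- rows_a[, ia[la], drop = FALSE]
  out_b[, lb] <- rows_b[, ib[lb], drop = FALSE]
  rbind(out_a, out_b)
}

#' Progressive multiple alignment of homologous sequences
#'
#' Sequences are aligned progressively along a guide tree built by
#' average-linkage clustering of shared k-mer distances; groups are merged by
#' affine-gap global profile-profile alignment. The procedure is
#' deterministic for a fixed input order.
#'
#' @param seqs A tibble with columns `taxon` and `seq` (>= 2 rows, each
#'   sequence >= 30 bp), or a named character vector.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring (defaults +1, -1,
#'   -4, -1).
#' @param guide_k k-mer size for the guide-tree distance (default 6).
#' @return An object of class `hgt_alignment`: a tibble with columns `taxon`
#'   and `aligned` (equal-length gapped sequences), with attribute
#'   `n_columns`. Ungapping any row reproduces its input sequence.
#' @export
align_homologs <- function(seqs, match = 1, mismatch = -1,
                           gap_open = -4, gap_ext = -1, guide_k = 6) {
  if (is.character(seqs)) seqs <- tibble(taxon = names(seqs), seq = unname(seqs))
  seqs <- as_tibble(seqs)
  if (nrow(seqs) < 2) abort("alignment needs at least 2 sequences")
  if (any(nchar(seqs$seq) < 30)) abort("all sequences must be at least 30 bp")
  seqs$seq <- toupper(seqs$seq)
  amb <- stringr::str_count(seqs$seq, "[^ACGT]") / nchar(seqs$seq)
  if (any(amb > 0.5))
    abort(sprintf("sequence '%s' has more than 50%% ambiguity codes",
                  seqs$taxon[amb > 0.5][1]))
  n <- nrow(seqs)
  groups <- lapply(seq_len(n), function(i) {
    matrix(strsplit(seqs$seq[i], "")[[1]], nrow = 1)
  })
  members <- lapply(seq_len(n), identity)
  if (n == 2) {
    merge_order <- matrix(c(-1L, -2L), 1)
  } else {
    d <- kmer_set_distance(seqs$seq, guide_k)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    merge_order <- hc$merge
  }
  merged <- vector("list", nrow(merge_order))
  memb <- vector("list", nrow(merge_order))
  for (s in seq_len(nrow(merge_order))) {
    pick <- function(x) if (x < 0) list(groups[[-x]], members[[-x]])
                        else list(merged[[x]], memb[[x]])
    a <- pick(merge_order[s, 1]); b <- pick(merge_order[s, 2])
    ops <- .nw_profile(seq_to_profile(a[[1]]), seq_to_profile(b[[1]]),
                       match, mismatch, gap_open, gap_ext)
    merged[[s]] <- apply_ops(a[[1]], b[[1]], ops)
    memb[[s]] <- c(a[[2]], b[[2]])
  }
  final <- merged[[length(merged)]]
  ord <- unlist(memb[[length(memb)]])
  rows <- final[order(ord), , drop = FALSE]
  out <- tibble(taxon = seqs$taxon,
                aligned = apply(rows, 1, paste, collapse = ""))
  structure(out, n_columns = ncol(final), class = c("hgt_alignment", class(out)))
}

#' Alignment as a character matrix
#'
#' @param alignment An `hgt_alignment` (or tibble with `taxon`, `aligned`).
#' @return Character matrix, taxa x columns.
#' @export
alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$aligned, ""))
  rownames(m) <- alignment$taxon
  m
}

#' Map ungapped sequence positions to alignment columns
#'
#' @param alignment An `hgt_alignment`.
#' @param taxon Row to map.
#' @return Integer vector: for each ungapped position (0-based) of the row's
#'   input sequence, its 1-based alignment column.
#' @export
alignment_column_map <- function(alignment, taxon) {
  row <- alignment$aligned[alignment$taxon == taxon]
  if (length(row) != 1) abort(sprintf("taxon '%s' not in alignment", taxon))
  which(strsplit(row, "")[[1]] != "-")
}
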