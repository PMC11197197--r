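# Jukes-Cantor distances, neighbor joining with deterministic tie-breaking,
# nonparametric bootstrap supports, and the sister-clade donor rule.

JC_CAP <- 5.0

jc_transform <- function(p) {
  ifelse(p >= 0.75, JC_CAP, -0.75 * log(1 - 4 * p / 3))
}

#' Jukes-Cantor distance matrix from an alignment
#'
#' Pairwise p-distances are computed over ungapped shared columns and
#' transformed as d = -(3/4) ln(1 - (4/3) p). Saturated pairs (p >= 0.75) are
#' capped at `r JC_CAP` and flagged via the `saturated` attribute.
#'
#' @param alignment An `hgt_alignment` from [align_homologs()].
#' @param min_overlap Minimum number of shared ungapped columns per pair
#'   (default 50); pairs below it are missing, and any missing entry makes
#'   the matrix incomplete, which is an error.
#' @return A symmetric numeric matrix with taxa as dimnames; attributes
#'   `saturated` (logical matrix) record capped pairs.
#' @export
jc_distance <- function(alignment, min_overlap = 50) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2) abort("distance matrix needs at least 2 taxa")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  ok <- m %in% BASES
  dim(ok) <- dim(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- ok[i, ] & ok[j, ]
    no <- sum(shared)
    if (no < min_overlap) {
      d[i, j] <- d[j, i] <- NA_real_
      next
    }
    p <- sum(m[i, shared] != m[j, shared]) / no
    d[i, j] <- d[j, i] <- jc_transform(p)
    sat[i, j] <- sat[j, i] <- p >= 0.75
  }
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, ]
    abort(sprintf("incomplete distance matrix: %s vs %s share fewer than %d ungapped columns",
                  rownames(d)[bad[1]], colnames(d)[bad[2]], min_overlap))
  }
  attr(d, "saturated") <- sat
  d
}

# ---- internal tree structure -------------------------------------------
# An hgt_tree wraps the neighbor-joining join history: node ids 0..n-1 are
# leaves (in taxa order), internal nodes follow in join order, and the tree
# ends in a trifurcation. Bipartitions of internal edges are stored as leaf
# bitmasks canonicalized to the side not containing leaf 1.

nj_from_matrix <- function(D, taxa) {
  core <- .nj_core(D)
  structure(list(taxa = taxa, core = core, supports = NULL,
                 no_signal = FALSE),
            class = "hgt_tree")
}

tree_children <- function(tree) {
  n <- length(tree$taxa)
  co <- tree$core
  kids <- list()
  if (length(co$join_a) > 0)
    for (i in seq_along(co$join_a)) {
      u <- n + i - 1L
      kids[[as.character(u)]] <- list(
        nodes = c(co$join_a[i], co$join_b[i]),
        lens = c(co$len_a[i], co$len_b[i]))
    }
  root <- n + length(co$join_a)
  kids[[as.character(root)]] <- list(nodes = co$final_nodes, lens = co$final_lens)
  kids
}

tree_newick <- function(tree, digits = 6) {
  n <- length(tree$taxa)
  kids <- tree_children(tree)
  root <- n + length(tree$core$join_a)
  supports <- tree$supports
  masks <- tree$core$masks
  lab <- function(node) {
    if (node < n) return(tree$taxa[node + 1])
    k <- kids[[as.character(node)]]
    inner <- paste(purrr::map2_chr(k$nodes, k$lens, function(ch, ln)
      sprintf("%s:%s", lab(ch), as.character(signif(ln, digits)))),
      collapse = ",")
    sup <- ""
    if (!is.null(supports) && node != root) {
      i <- node - n + 1L
      sup <- as.character(signif(supports[i], 4))
    }
    sprintf("(%s)%s", inner, sup)
  }
  paste0(lab(root), ";")
}

#' Build a neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining with deterministic tie-breaking (smallest Q
#' wins; residual ties go to the lexicographically smallest pair of taxon
#' indices). Negative branch lengths are clamped to zero. On a tree-additive
#' matrix the generating topology is recovered.
#'
#' @param D Symmetric distance matrix with zero diagonal and taxon dimnames,
#'   at least 4 taxa.
#' @return An object of class `hgt_tree`. Use [tree_phylo()] for an
#'   `ape::phylo` view and [call_donor()] for sister-clade queries.
#' @export
build_nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("D must be a square matrix")
  if (nrow(D) < 4) abort("neighbor joining needs at least 4 taxa")
  if (max(abs(D - t(D))) > 1e-8) abort("D must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) abort("D must have a zero diagonal")
  taxa <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  nj_from_matrix(D, taxa)
}

#' Convert an `hgt_tree` to `ape::phylo`
#'
#' Supports, when present, become internal node labels in the Newick string.
#'
#' @param tree An `hgt_tree`.
#' @return An `ape::phylo` object (unrooted, trifurcating root).
#' @export
tree_phylo <- function(tree) {
  ape::read.tree(text = tree_newick(tree))
}

#' Write an `hgt_tree` as Newick
#'
#' @param tree An `hgt_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  readr::write_lines(tree_newick(tree), path)
  invisible(path)
}

#' @export
print.hgt_tree <- function(x, ...) {
  cat(sprintf("<hgt_tree> %d taxa%s\n", length(x$taxa),
              if (!is.null(x$supports)) " with bootstrap supports" else ""))
  cat(tree_newick(x), "\n")
  invisible(x)
}

pair_signature_matrices <- function(m) {
  # per taxon pair: valid-column (both ungapped) and mismatch indicators
  n <- nrow(m); L <- ncol(m)
  ok <- m %in% BASES; dim(ok) <- dim(m)
  pairs <- utils::combn(n, 2)
  P <- ncol(pairs)
  V <- matrix(FALSE, P, L); M <- matrix(FALSE, P, L)
  for (p in seq_len(P)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    V[p, ] <- ok[i, ] & ok[j, ]
    M[p, ] <- V[p, ] & (m[i, ] != m[j, ])
  }
  list(pairs = pairs, valid = V, mismatch = M)
}

#' Nonparametric bootstrap supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate is run through Jukes-Cantor distances and neighbor joining, and
#' the support of each internal bipartition of the full-data tree is the
#' percentage of replicates containing it. Reproducible for a fixed seed.
#' Alignments without any variable column carry no signal: supports are
#' reported as 0 and the tree is flagged `no_signal`.
#'
#' @param alignment An `hgt_alignment` with at least 4 taxa.
#' @param n_reps Number of bootstrap replicates (default 1000, minimum 100).
#' @param seed Integer seed.
#' @param min_overlap Passed to the replicate distance computation.
#' @return An `hgt_tree` with `supports` (percent per internal edge, in join
#'   order) and `no_signal` set.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000, seed = 1,
                              min_overlap = 50) {
  if (nrow(alignment) < 4) abort("bootstrap needs an alignment of at least 4 taxa")
  if (n_reps < 100) abort("use at least 100 bootstrap replicates")
  m <- alignment_matrix(alignment)
  D <- jc_distance(alignment, min_overlap = min_overlap)
  tree <- build_nj_tree(D)
  masks <- tree$core$masks
  n <- nrow(m); L <- ncol(m)
  variable <- apply(m, 2, function(col) {
    b <- col[col %in% BASES]
    length(unique(b)) > 1
  })
  if (!any(variable)) {
    tree$supports <- rep(0, length(masks))
    tree$no_signal <- TRUE
    return(tree)
  }
  sig <- pair_signature_matrices(m)
  counts <- setNames(rep(0L, length(masks)), as.character(masks))
  with_seed(seed, {
    idx <- matrix(sample.int(L, L * n_reps, replace = TRUE), nrow = L)
    ind <- matrix(0, L, n_reps)
    for (r in seq_len(n_reps)) {
      tb <- tabulate(idx[, r], nbins = L)
      ind[, r] <- tb
    }
    nvalid <- sig$valid %*% ind
    nmis <- sig$mismatch %*% ind
    for (r in seq_len(n_reps)) {
      p <- ifelse(nvalid[, r] > 0, nmis[, r] / nvalid[, r], 0)
      d <- jc_transform(p)
      Dr <- matrix(0, n, n)
      Dr[t(sig$pairs)] <- d
      Dr <- Dr + t(Dr)
      rep_masks <- .nj_core(Dr)$masks
      hit <- as.character(masks) %in% as.character(rep_masks)
      counts[hit] <- counts[hit] + 1L
    }
  })
  tree$supports <- 100 * as.numeric(counts) / n_reps
  tree
}

# leaf set (1-based taxa indices) below each node, and the full adjacency
tree_leafsets <- function(tree) {
  n <- length(tree$taxa)
  kids <- tree_children(tree)
  sets <- as.list(seq_len(n) - 1L)
  names(sets) <- as.character(seq_len(n) - 1L)
  internal <- sort(as.integer(names(kids)))
  for (u in internal) {
    k <- kids[[as.character(u)]]
    sets[[as.character(u)]] <- sort(unlist(sets[as.character(k$nodes)]))
  }
  sets
}

#' Call the donor lineage of a foreign gene from its gene tree
#'
#' The sister clade of the foreign leaf is the leaf set across its adjacent
#' internal edge, taking the minimal side; when the taxonomy map marks
#' outgroup taxa, a candidate side containing an outgroup taxon is never
#' chosen as sister. The donor is assigned if and only if the bipartition
#' grouping the foreign leaf with its sister clade has bootstrap support
#' strictly greater than `threshold` and the sister taxa are exclusively
#' angiosperm.
#'
#' @param tree An `hgt_tree` with bootstrap supports (see
#'   [bootstrap_support()]).
#' @param foreign_leaf Taxon label of the foreign gene in the tree.
#' @param taxonomy Named character vector or tibble (`taxon`, `group`)
#'   mapping taxa to groups; groups starting with `"angiosperm"` count as
#'   angiosperm, groups `"outgroup"` or `"fern"` mark display-rooting taxa.
#' @param threshold Support threshold in percent (default 50, strict
#'   inequality).
#' @return A one-row tibble: `foreign_gene`, `sister_taxa` (list column),
#'   `sister_label`, `support_percent`, `verdict`
#'   (`donor_assigned`/`unresolved`).
#' @export
call_donor <- function(tree, foreign_leaf, taxonomy, threshold = 50) {
  if (is.data.frame(taxonomy)) taxonomy <- setNames(taxonomy$group, taxonomy$taxon)
  n <- length(tree$taxa)
  leaf <- match(foreign_leaf, tree$taxa) - 1L
  if (is.na(leaf)) abort(sprintf("foreign leaf '%s' not in tree", foreign_leaf))
  kids <- tree_children(tree)
  sets <- tree_leafsets(tree)
  # parent of each node
  parent <- integer()
  for (u in names(kids)) for (ch in kids[[u]]$nodes)
    parent[as.character(ch)] <- as.integer(u)
  v <- parent[[as.character(leaf)]]
  # neighbor subtrees of v other than the foreign leaf: its other children
  # plus (unless v is the root trifurcation) the "up" side
  root <- n + length(tree$core$join_a)
  cand <- list()
  for (ch in setdiff(kids[[as.character(v)]]$nodes, leaf))
    cand[[length(cand) + 1]] <- sets[[as.character(ch)]]
  if (v != root) {
    below <- c(sets[[as.character(v)]])
    cand[[length(cand) + 1]] <- sort(setdiff(seq_len(n) - 1L, below))
  }
  grp <- function(taxa) unname(taxonomy[taxa])
  is_og <- function(idx) any(grp(tree$taxa[idx + 1L]) %in% c("outgroup", "fern"),
                             na.rm = TRUE)
  # outgroup side is never the sister when an alternative exists; among the
  # remaining candidates take the minimal side (ties: first in join order)
  og <- vapply(cand, is_og, logical(1))
  pool <- if (any(!og)) which(!og) else seq_along(cand)
  pick <- pool[which.min(lengths(cand)[pool])]
  sister_idx <- cand[[pick]]
  sister <- tree$taxa[sister_idx + 1L]
  # support of the bipartition {foreign} U sister
  mask <- sum(2^c(leaf, sister_idx))
  full <- sum(2^(seq_len(n) - 1L))
  canon <- if (mask %% 2 == 1) full - mask else mask
  supports <- tree$supports %||% rep(NA_real_, length(tree$core$masks))
  hit <- match(canon, tree$core$masks)
  support <- if (is.na(hit)) 0 else supports[hit]
  groups <- grp(sister)
  all_angio <- length(sister) > 0 && all(startsWith(groups %||% "", "angiosperm"))
  verdict <- if (!is.na(support) && support > threshold && all_angio)
    "donor_assigned" else "unresolved"
  tibble(foreign_gene = foreign_leaf,
         sister_taxa = list(sister),
         sister_label = paste(sister, collapse = ","),
         support_percent = support,
         verdict = verdict)
}
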