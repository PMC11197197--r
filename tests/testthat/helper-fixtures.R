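# shared fixtures and independent oracles, all built in code

rand_dna <- function(n, gc = 0.5) hgtscan:::random_dna(n, gc)
mutseq <- function(seq, b) hgtscan:::mutate_seq(seq, b)
rc <- function(seq) hgtscan:::revcomp(seq)

aln_from_rows <- function(...) {
  rows <- c(...)
  structure(tibble::tibble(taxon = names(rows), aligned = unname(rows)),
            n_columns = nchar(rows[1]),
            class = c("hgt_alignment", "tbl_df", "tbl", "data.frame"))
}

# a hit-tibble row with sensible defaults, for classification tests
make_hit <- function(group, identity = 0.9, evalue = 1e-30, seq_id = "g",
                     window_index = 1L, taxon = group) {
  tibble::tibble(seq_id = seq_id, window_index = window_index,
                 g_start = 0L, g_end = 1000L,
                 subject_id = paste0(group, "_rec"), subject_taxon = taxon,
                 subject_group = group, strand = "+",
                 q_start = 0L, q_end = 1000L, s_start = 0L, s_end = 1000L,
                 score = 500, identity = identity, mismatches = 10L,
                 gapopens = 0L, aln_len = 1000L, evalue = evalue,
                 bitscore = 100)
}

windows_of <- function(categories, seq_id = "g", size = 1000L) {
  n <- length(categories)
  tibble::tibble(seq_id = seq_id, index = seq_len(n),
                 start = (seq_len(n) - 1L) * size, end = seq_len(n) * size,
                 seq = NA_character_, width = size, short = FALSE,
                 category = categories,
                 supporting_groups = rep(list(character(0)), n),
                 n_hits = 0L, best_subject = NA_character_,
                 best_identity = NA_real_, best_evalue = NA_real_)
}

# brute-force maximal-exact-match oracle: scan every diagonal of the
# comparison matrix with run-length encoding (forward strand)
mem_oracle_fwd <- function(a, b, min_len) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  out <- list()
  for (d in (-(m - 1)):(n - 1)) {
    i0 <- max(0, d); j0 <- max(0, -d)
    len <- min(n - i0, m - j0)
    if (len < min_len) next
    eq <- av[i0 + seq_len(len)] == bv[j0 + seq_len(len)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values & r$lengths >= min_len)
    for (k in keep)
      out[[length(out) + 1]] <- c(a_start = i0 + starts[k] - 1,
                                  a_end = i0 + ends[k],
                                  b_start = j0 + starts[k] - 1,
                                  b_end = j0 + ends[k])
  }
  if (length(out) == 0)
    return(tibble::tibble(a_start = integer(), a_end = integer(),
                          b_start = integer(), b_end = integer()))
  dplyr::arrange(tibble::as_tibble(do.call(rbind, out)), a_start, b_start)
}

mem_oracle <- function(a, b, min_len) {
  fw <- dplyr::mutate(mem_oracle_fwd(a, b, min_len), strand = "+")
  m <- nchar(b)
  rv <- mem_oracle_fwd(a, rc(b), min_len)
  rv <- tibble::tibble(a_start = rv$a_start, a_end = rv$a_end,
                       b_start = m - rv$b_end, b_end = m - rv$b_start,
                       strand = "-")
  dplyr::arrange(dplyr::bind_rows(fw, rv), a_start, b_start)
}

# full-enumeration Mann-Whitney oracle for tiny tie-free samples
mwu_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 * n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- utils::combn(n1 + n2, n1)
  us <- apply(picks, 2, function(ix) sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2)
  # two-tailed: configurations at least as extreme (distance from N/2)
  mean(abs(us - N / 2) >= abs(u_obs - N / 2) - 1e-9)
}

# Smith-Waterman oracle through Biostrings (local, same scoring convention)
sw_oracle <- function(a, b, match = 1, mismatch = -2, gap_open = 5, gap_ext = 2) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE),
    gapOpening = gap_open, gapExtension = gap_ext)
}
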