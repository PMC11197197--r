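# Internal helpers: sequence utilities and interval algebra on 0-based
# half-open coordinates.

.datatable.aware <- TRUE

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

check_dna <- function(seq, id = "<sequence>") {
  bad <- stringr::str_detect(seq, paste0("[^", paste(IUPAC_DNA, collapse = ""), "]"))
  if (any(bad)) {
    chars <- unique(unlist(stringr::str_extract_all(
      seq[bad], paste0("[^", paste(IUPAC_DNA, collapse = ""), "]"))))
    abort(sprintf("sequence '%s' contains non-IUPAC characters: %s",
                  id[bad][1], paste(chars, collapse = " ")))
  }
  invisible(TRUE)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

gc_content <- function(seq) {
  n_gc <- stringr::str_count(seq, "[GCgcSs]")
  n_gc / nchar(seq)
}

#' Generate random DNA at a target GC content
#'
#' @param n Sequence length in bp.
#' @param gc Target GC fraction.
#' @return A single DNA string.
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# interval tibbles: columns start, end (0-based half-open)
ivl_merge <- function(iv) {
  if (nrow(iv) == 0) return(tibble(start = integer(), end = integer()))
  iv <- dplyr::arrange(iv, .data$start, .data$end)
  out_s <- iv$start[1]; out_e <- iv$end[1]
  ss <- integer(); ee <- integer()
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv$start[i] <= out_e) {
        out_e <- max(out_e, iv$end[i])
      } else {
        ss <- c(ss, out_s); ee <- c(ee, out_e)
        out_s <- iv$start[i]; out_e <- iv$end[i]
      }
    }
  }
  tibble(start = c(ss, out_s), end = c(ee, out_e))
}

ivl_intersect <- function(a, b) {
  a <- ivl_merge(a); b <- ivl_merge(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(tibble(start = integer(), end = integer()))
  out <- purrr::map_dfr(seq_len(nrow(a)), function(i) {
    s <- pmax(a$start[i], b$start); e <- pmin(a$end[i], b$end)
    keep <- s < e
    tibble(start = s[keep], end = e[keep])
  })
  ivl_merge(out)
}

ivl_setdiff <- function(a, b) {
  a <- ivl_merge(a); b <- ivl_merge(b)
  if (nrow(a) == 0) return(a)
  if (nrow(b) == 0) return(a)
  pieces <- purrr::map_dfr(seq_len(nrow(a)), function(i) {
    s <- a$start[i]; e <- a$end[i]
    cuts <- b[b$end > s & b$start < e, , drop = FALSE]
    if (nrow(cuts) == 0) return(tibble(start = s, end = e))
    keep_s <- integer(); keep_e <- integer()
    cur <- s
    for (j in seq_len(nrow(cuts))) {
      if (cuts$start[j] > cur) { keep_s <- c(keep_s, cur); keep_e <- c(keep_e, cuts$start[j]) }
      cur <- max(cur, cuts$end[j])
    }
    if (cur < e) { keep_s <- c(keep_s, cur); keep_e <- c(keep_e, e) }
    tibble(start = keep_s, end = keep_e)
  })
  ivl_merge(pieces)
}

ivl_width <- function(iv) sum(iv$end - iv$start)

# deterministic local RNG scope
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
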