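#' Read genome sequences from FASTA
#'
#' Loads one sequence record per FASTA entry into a tibble. Sequences are
#' uppercased and validated against the IUPAC DNA alphabet. If a taxonomy
#' table is supplied, taxon, compartment and group labels are joined by
#' sequence id; otherwise they default to `"unknown"`.
#'
#' @param path Path to a FASTA file.
#' @param taxonomy Optional path to a TSV with columns `id`, `taxon`,
#'   `compartment`, `group`, or a data frame with those columns.
#' @return A tibble with columns `id`, `taxon`, `compartment`, `group`,
#'   `seq`, `length`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT", ">chr2", "ggccggcc"), fa)
#' read_genome(fa)
read_genome <- function(path, taxonomy = NULL) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    abort(sprintf("duplicate sequence ids in '%s': %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) check_dna(seqs[i], ids[i])
  out <- tibble(id = ids, taxon = "unknown", compartment = "unknown",
                group = "unknown", seq = unname(seqs),
                length = unname(nchar(seqs)))
  if (!is.null(taxonomy)) {
    tax <- if (is.data.frame(taxonomy)) as_tibble(taxonomy)
           else readr::read_tsv(taxonomy, show_col_types = FALSE)
    need <- intersect(c("taxon", "compartment", "group"), names(tax))
    out <- out |>
      select(-dplyr::any_of(need)) |>
      left_join(select(tax, dplyr::all_of(c("id", need))), by = "id") |>
      mutate(across(dplyr::all_of(need), ~ tidyr::replace_na(.x, "unknown"))) |>
      select("id", "taxon", "compartment", "group", "seq", "length")
  }
  out
}

#' Write genome sequences to FASTA
#'
#' @param genome A tibble with columns `id` and `seq`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(setNames(genome$seq, genome$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Coordinates are converted from GFF3's 1-based inclusive convention to the
#' 0-based half-open convention used throughout the package. The attribute
#' keys `origin` (native/foreign) and `pseudo` (true/false) are read when
#' present; `Parent` links exons to genes.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional genome tibble; when given, features extending past
#'   the end of their sequence raise an error.
#' @return A tibble with columns `seq_id`, `start`, `end`, `strand`, `kind`,
#'   `name`, `parent`, `origin`, `pseudogene`.
#' @export
read_annotations <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(sprintf("GFF3 file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0)
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  strand = character(), kind = character(), name = character(),
                  parent = character(), origin = character(), pseudogene = logical()))
  fields <- stringr::str_split(lines, "\t")
  bad <- lengths(fields) != 9
  if (any(bad))
    abort(sprintf("GFF3 line %d does not have 9 tab-separated columns", which(bad)[1]))
  m <- do.call(rbind, fields)
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) abort("non-numeric coordinates in GFF3")
  if (any(end1 < start1))
    abort(sprintf("GFF3 feature with end < start at line %d", which(end1 < start1)[1]))
  strand <- m[, 7]
  if (!all(strand %in% c("+", "-")))
    abort(sprintf("unknown strand symbol '%s' in GFF3", setdiff(strand, c("+", "-"))[1]))
  attr_get <- function(attrs, key) {
    v <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    v
  }
  out <- tibble(
    seq_id = m[, 1],
    start = start1 - 1L,
    end = end1,
    strand = strand,
    kind = m[, 3],
    name = dplyr::coalesce(attr_get(m[, 9], "Name"), attr_get(m[, 9], "ID")),
    parent = attr_get(m[, 9], "Parent"),
    origin = dplyr::coalesce(attr_get(m[, 9], "origin"), "unknown"),
    pseudogene = tolower(dplyr::coalesce(attr_get(m[, 9], "pseudo"), "false")) %in%
      c("true", "1", "yes"))
  if (!is.null(genome)) {
    lens <- setNames(genome$length, genome$id)
    over <- !is.na(lens[out$seq_id]) & out$end > lens[out$seq_id]
    if (any(over))
      abort(sprintf("feature '%s' extends past the end of sequence '%s'",
                    out$name[over][1], out$seq_id[over][1]))
  }
  out
}

#' Write annotations to GFF3
#'
#' The inverse of [read_annotations()]: 0-based half-open coordinates are
#' converted back to GFF3's 1-based inclusive convention, and `origin` and
#' `pseudo` are written as attributes.
#'
#' @param features Annotation tibble as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(features, path) {
  attrs <- purrr::pmap_chr(features, function(name, parent, origin, pseudogene, ...) {
    parts <- c(sprintf("ID=%s", name))
    if (!is.na(parent) && nzchar(parent %||% "")) parts <- c(parts, sprintf("Parent=%s", parent))
    parts <- c(parts, sprintf("origin=%s", origin))
    if (isTRUE(pseudogene)) parts <- c(parts, "pseudo=true")
    paste(parts, collapse = ";")
  })
  lines <- sprintf("%s\thgtscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   features$seq_id, features$kind, features$start + 1L,
                   features$end, features$strand, attrs)
  readr::write_lines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Cut genome sequences into non-overlapping analysis windows
#'
#' Each sequence is tiled left to right with windows of `size` bp; the final
#' window keeps whatever remainder is left, however short, so that the
#' concatenation of window sequences reproduces the input exactly. Windows
#' shorter than 100 bp are flagged via the `short` column but are still
#' classified downstream. Circular chromosomes are treated as linearized at
#' position 0 (no wrap-around window).
#'
#' @param genome Genome tibble from [read_genome()].
#' @param size Window size in bp (default 1000, minimum 100).
#' @return A tibble with columns `seq_id`, `index` (1-based), `start`, `end`
#'   (0-based half-open), `seq`, `width`, `short`.
#' @export
extract_windows <- function(genome, size = 1000) {
  if (size < 100) abort("window size must be at least 100 bp")
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    if (len == 0) return(NULL)
    starts <- seq.int(0L, len - 1L, by = size)
    ends <- pmin(starts + size, len)
    tibble(seq_id = genome$id[i],
           index = seq_along(starts),
           start = as.integer(starts), end = as.integer(ends),
           seq = substring(genome$seq[i], starts + 1L, ends),
           width = as.integer(ends - starts),
           short = (ends - starts) < 100L)
  })
}
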