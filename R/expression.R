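# TPM normalization and a self-contained Mann-Whitney U test (exact by
# enumeration of the U distribution for small tie-free samples, otherwise a
# tie- and continuity-corrected normal approximation).

#' Compute transcripts-per-million (TPM) from read counts
#'
#' Per-gene read counts are divided by effective length (annotated exonic
#' length) to give rates, which are rescaled so the TPM of one sample sums to
#' one million. Genes with zero mapped reads are retained at TPM 0.
#'
#' @param counts Tibble with columns `gene`, `count` and `length` (effective
#'   length in bp); other columns (e.g. `origin`) pass through.
#' @return The input tibble with a `tpm` column added.
#' @export
#' @examples
#' compute_tpm(tibble::tibble(gene = c("a", "b"), count = c(10, 20),
#'                            length = c(1000, 2000)))
compute_tpm <- function(counts) {
  counts <- as_tibble(counts)
  if (any(counts$length <= 0)) abort("all effective lengths must be positive")
  if (any(counts$count < 0)) abort("counts must be non-negative")
  if (sum(counts$count) == 0) abort("all counts are zero; TPM is undefined")
  rate <- counts$count / counts$length
  mutate(counts, tpm = 1e6 * rate / sum(rate))
}

# exact null distribution of U for sample sizes (n1, n2): counts of rank
# configurations per U value, via the standard two-index recursion
mwu_exact_dist <- function(n1, n2) {
  N <- n1 * n2
  # cnt[[m+1]][u+1] = number of configurations with statistic u for (m, n2)
  prev <- matrix(0, n1 + 1, N + 1)
  prev[, 1] <- 1  # n = 0: the only configuration has U = 0 for any m
  for (n in seq_len(n2)) {
    cur <- matrix(0, n1 + 1, N + 1)
    cur[1, 1] <- 1
    for (m in seq_len(n1)) {
      for (u in 0:(m * n)) {
        a <- if (u - n >= 0) cur[m, u - n + 1] else 0    # f(u - n; m-1, n)
        b <- prev[m + 1, u + 1]                           # f(u; m, n-1)
        cur[m + 1, u + 1] <- a + b
      }
    }
    prev <- cur
  }
  counts <- prev[n1 + 1, ]
  counts / sum(counts)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test of identical distributions. The exact two-tailed
#' p-value is computed by full enumeration of the U distribution when
#' `n1 * n2 <= 400` and the pooled sample has no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return An object of class `hgt_mwu` with fields `U` (statistic for `x`),
#'   `z`, `p_two_tailed`, `method`, `n1`, `n2`. `tidy()` and `glance()`
#'   methods are provided.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 * n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (mode == "exact" && has_ties)
    abort("exact p-value is not defined in the presence of ties")
  use_exact <- mode == "exact" || (mode == "auto" && !has_ties && N <= 400)
  if (use_exact) {
    probs <- mwu_exact_dist(n1, n2)
    lo <- min(U, N - U)
    p <- sum(probs[(0:N) <= lo]) + sum(probs[(0:N) >= N - lo])
    if (2 * lo == N) p <- p - sum(probs[(0:N) == lo])  # center counted twice
    p <- min(1, p)
    res <- list(U = U, z = NA_real_, p_two_tailed = p, method = "exact",
                n1 = n1, n2 = n2)
  } else {
    mu <- N / 2
    tie_tab <- table(pooled)
    Nn <- n1 + n2
    tie_term <- sum(tie_tab^3 - tie_tab) / (Nn * (Nn - 1))
    sigma2 <- N / 12 * ((Nn + 1) - tie_term)
    if (sigma2 <= 0) {
      res <- list(U = U, z = 0, p_two_tailed = 1, method = "normal_approx",
                  n1 = n1, n2 = n2)
    } else {
      z <- sign(U - mu) * max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
      res <- list(U = U, z = z, p_two_tailed = p, method = "normal_approx",
                  n1 = n1, n2 = n2)
    }
  }
  structure(res, class = "hgt_mwu")
}

#' @export
print.hgt_mwu <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g, n = %d/%d, two-tailed p = %.4g\n",
              x$method, x$U, x$n1, x$n2, x$p_two_tailed))
  invisible(x)
}

#' @rdname mann_whitney_u
#' @param x An `hgt_mwu` object (for `tidy`/`glance`).
#' @param ... Unused.
#' @export
tidy.hgt_mwu <- function(x, ...) {
  tibble(statistic = x$U, z = x$z, p.value = x$p_two_tailed,
         method = x$method, n1 = x$n1, n2 = x$n2)
}

#' @rdname mann_whitney_u
#' @export
glance.hgt_mwu <- function(x, ...) tidy.hgt_mwu(x)

#' Compare foreign versus native expression
#'
#' Computes TPM and tests the foreign-vs-native TPM difference with a
#' two-tailed Mann-Whitney U test.
#'
#' @param counts Tibble with `gene`, `origin` (`"native"`/`"foreign"`),
#'   `count`, `length`.
#' @return A list with `expression` (tibble incl. `tpm`) and `test`
#'   (`hgt_mwu`).
#' @export
expression_contrast <- function(counts) {
  expr <- compute_tpm(counts)
  fo <- expr$tpm[expr$origin == "foreign"]
  na_ <- expr$tpm[expr$origin == "native"]
  if (length(fo) == 0 || length(na_) == 0)
    abort("need both foreign and native genes for the expression contrast")
  list(expression = expr, test = mann_whitney_u(fo, na_))
}
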