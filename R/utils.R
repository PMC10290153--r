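#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over plain character sequences. `U` is
#' accepted and treated as `T`; the result is always in DNA alphabet.
#'
#' @param x Character vector of sequences (A/C/G/T/U/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGGA"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  x <- chartr("uU", "tT", x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fast vectorised random DNA: one long draw, then substring extraction.
random_dna <- function(lengths) {
  if (length(lengths) == 0) return(character(0))
  total <- sum(lengths)
  s <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE), collapse = "")
  ends <- cumsum(lengths)
  substring(s, ends - lengths + 1, ends)
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, chartr("uU", "tT", toupper(x)))
  if (any(bad)) {
    abort(sprintf("%s contains characters outside the %s alphabet (first offender: %s)",
                  what, if (allow_n) "A/C/G/T/N" else "A/C/G/T",
                  x[which(bad)[1]]))
  }
  invisible(chartr("uU", "tT", toupper(x)))
}

# Welch (or pooled-variance) two-sample t-test, vectorised over the rows of
# a matrix. Degenerate rows (both groups zero-variance) get p = 1 when the
# means agree and p = 0 otherwise, so constant equal spectra never fire.
welch_rows <- function(x, g, var_equal = FALSE) {
  stopifnot(is.matrix(x), length(g) == ncol(x))
  g <- as.factor(g)
  lev <- levels(g)
  if (length(lev) != 2) abort("exactly two groups are required")
  xa <- x[, g == lev[1], drop = FALSE]
  xb <- x[, g == lev[2], drop = FALSE]
  n1 <- ncol(xa); n2 <- ncol(xb)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 samples")
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  v1 <- apply(xa, 1, var); v2 <- apply(xb, 1, var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  t_stat <- (m1 - m2) / se
  p <- 2 * pt(-abs(t_stat), df)
  degen <- se == 0 | !is.finite(se)
  if (any(degen)) {
    eq <- degen & (m1 == m2)
    t_stat[eq] <- 0; p[eq] <- 1; df[eq] <- NA_real_
    ne <- degen & (m1 != m2)
    t_stat[ne] <- sign(m1[ne] - m2[ne]) * Inf; p[ne] <- 0; df[ne] <- NA_real_
  }
  tibble(mean_a = m1, mean_b = m2, t_stat = t_stat, df = df, p_value = p)
}

# Two group labels in reporting order: first label is the numerator of
# every fold. Order of first appearance unless `group_order` is given.
group_levels <- function(g, group_order = NULL) {
  u <- unique(as.character(g))
  u <- u[u != "QC"]
  if (!is.null(group_order)) {
    if (!setequal(group_order, u)) {
      abort("`group_order` must be a permutation of the observed group labels")
    }
    u <- group_order
  }
  if (length(u) != 2) abort("exactly two (non-QC) groups are required")
  u
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
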