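# Independent oracles used across tests. These re-derive results by brute
# force or closed form and must stay independent of the package internals.

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# naive sliding-window exact matcher (both strands, forward coordinates)
naive_match <- function(query, genome) {
  w <- nchar(query)
  rc <- trfscan::revcomp(query)
  out <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    L <- nchar(s)
    if (L < w) next
    starts <- seq_len(L - w + 1)
    subs <- substring(s, starts, starts + w - 1)
    for (st in starts[subs == query]) {
      out[[length(out) + 1]] <- data.frame(chrom = chrom, start = st,
                                           end = st + w - 1, strand = "+")
    }
    for (st in starts[subs == rc]) {
      out[[length(out) + 1]] <- data.frame(chrom = chrom, start = st,
                                           end = st + w - 1, strand = "-")
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

# brute-force local duplex alignment score: every alignment is substitution
# columns separated by explicit gap runs, so the best score ending in a
# substitution at (i, j) is a max over all previous substitution cells with
# the affine run costs charged directly (no Gotoh state machine).
oracle_duplex_score <- function(q, tgt, params = trfscan::duplex_params()) {
  sub_score <- function(a, b) {
    wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
    gu <- (a == "G" & b == "T") | (a == "T" & b == "G")
    ifelse(wc, params$match, ifelse(gu, params$gu_wobble, params$mismatch))
  }
  qc <- strsplit(q, "")[[1]]
  tc <- rev(strsplit(tgt, "")[[1]])
  n <- length(qc); m <- length(tc)
  scale_i <- ifelse(seq_len(n) >= params$seed_range[1] &
                      seq_len(n) <= params$seed_range[2], params$seed_scale, 1)
  pen <- function(g) ifelse(g > 0, params$gap_open + (g - 1) * params$gap_extend, 0)
  B <- matrix(-Inf, n, m)
  best <- 0
  for (i in seq_len(n)) {
    s_i <- sub_score(qc[i], tc) * scale_i[i]
    for (j in seq_len(m)) {
      prev <- 0
      if (i > 1 && j > 1) {
        sub <- B[seq_len(i - 1), seq_len(j - 1), drop = FALSE]
        penq <- pen(i - seq_len(i - 1) - 1)
        pent <- pen(j - seq_len(j - 1) - 1)
        prev <- max(0, sub + outer(penq, pent, `+`))
      }
      B[i, j] <- s_i[j] + prev
      if (B[i, j] > best) best <- B[i, j]
    }
  }
  best
}

# exact hypergeometric upper tail by combinatorial enumeration
oracle_hyper_tail <- function(k, N, K, n) {
  j <- max(0, k):min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# small two-group tibble builders
make_counts <- function(values_a, values_b, totals = NULL) {
  n_a <- length(values_a); n_b <- length(values_b)
  totals <- totals %||% rep(1e6, n_a + n_b)
  tibble::tibble(
    sequence = "S",
    sample_id = c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b))),
    group = rep(c("ga", "gb"), c(n_a, n_b)),
    count = c(values_a, values_b),
    total_retained = totals
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
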