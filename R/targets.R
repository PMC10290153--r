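#' Scoring parameters for the duplex aligner
#'
#' Score units follow published miRNA-target-scan conventions: +5 for a
#' Watson-Crick pair, +2 for a G:U wobble, -3 for a mismatch, affine gaps at
#' -9 open / -4 extend, and a 4-fold multiplier on substitution scores at
#' small-RNA seed positions 2-8 (1-based from the 5' end). Candidate sites
#' must reach `score_threshold` and a paired-fraction stability proxy of at
#' least `stability_threshold` (GC pairs weighted 1, A:U 0.65, G:U 0.35,
#' averaged over the small-RNA length).
#'
#' @param match,gu_wobble,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (non-positive;
#'   `gap_open <= gap_extend`).
#' @param seed_scale Multiplier on substitution scores in the seed.
#' @param seed_range 1-based closed range of seed positions on the query.
#' @param score_threshold Minimum alignment score for a reported hit.
#' @param stability_threshold Minimum stability proxy for a reported hit.
#' @return A list of class `duplex_params`.
#' @export
duplex_params <- function(match = 5, gu_wobble = 2, mismatch = -3,
                          gap_open = -9, gap_extend = -4,
                          seed_scale = 4.0, seed_range = c(2L, 8L),
                          score_threshold = 140,
                          stability_threshold = 0.7) {
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    abort("gap penalties must satisfy gap_open <= gap_extend <= 0")
  }
  if (seed_scale < 1) abort("seed_scale must be >= 1")
  structure(list(match = match, gu_wobble = gu_wobble, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed_scale = seed_scale, seed_range = as.integer(seed_range),
                 score_threshold = score_threshold,
                 stability_threshold = stability_threshold),
            class = "duplex_params")
}

# Substitution score lookup (4x4; A,C,G,T) for query base vs target base.
# "Match" means the bases hybridise: A-T/T-A/C-G/G-C Watson-Crick, G-T/T-G
# wobble (the DNA representation of G:U).
sub_matrix <- function(params) {
  s <- matrix(params$mismatch, 4, 4)
  s[1, 4] <- s[4, 1] <- s[2, 3] <- s[3, 2] <- params$match
  s[3, 4] <- s[4, 3] <- params$gu_wobble
  s
}

seq_to_int <- function(x) match(strsplit(x, "")[[1]], c("A", "C", "G", "T"))

#' Align a small RNA against a UTR window as an RNA duplex
#'
#' Smith-Waterman-style local alignment of the small RNA (5'->3') against
#' the reverse of the UTR window, so that antiparallel hybridisation is
#' colinear: a "match" scores complementary base pairs (A:U, G:C), G:U
#' wobbles score lower, and gaps are affine (Gotoh recursion). Substitution
#' scores at small-RNA seed positions 2-8 are multiplied by `seed_scale`.
#' Ties prefer alignments with fewer gaps, then smaller UTR start.
#'
#' @param small_rna Small-RNA sequence, 5'->3' (16-40 nt; U accepted).
#' @param utr_window Target window, 5'->3' (at most 80 nt).
#' @param params A [duplex_params()].
#' @return A list: `score`; `query_start`/`query_end` (positions on the
#'   small RNA); `target_start`/`target_end` (forward coordinates on the
#'   window); `query_aln`, `pair`, `target_aln` (alignment rows, query on
#'   top 5'->3', window bottom 3'->5'; `|` Watson-Crick, `:` wobble);
#'   `n_gaps`; `stability` (paired-fraction proxy in [0, 1]).
#' @export
align_duplex <- function(small_rna, utr_window, params = duplex_params()) {
  q <- assert_dna(small_rna, "small_rna", allow_n = FALSE)
  tgt <- assert_dna(utr_window, "utr_window", allow_n = FALSE)
  if (nchar(q) < 16 || nchar(q) > 40) abort("small_rna must be 16-40 nt")
  if (nchar(tgt) > 80) abort("utr_window longer than 80 nt")
  qi <- seq_to_int(q)
  tj <- rev(seq_to_int(tgt))          # reversed window: colinear pairing
  n <- length(qi); m <- length(tj)
  S <- sub_matrix(params)
  scale_i <- ifelse(seq_len(n) >= params$seed_range[1] &
                      seq_len(n) <= params$seed_range[2],
                    params$seed_scale, 1)
  go <- params$gap_open; ge <- params$gap_extend

  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)     # gap in query (consumes target)
  F_ <- matrix(-Inf, n + 1, m + 1)    # gap in target (consumes query)
  ptrH <- matrix(0L, n + 1, m + 1)    # 0 stop, 1 diag, 2 E, 3 F
  ptrE <- matrix(0L, n + 1, m + 1)    # 1 open from H, 2 extend
  ptrF <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    si <- S[qi[i], ] * scale_i[i]
    Hrow <- H[i + 1, ]
    for (j in seq_len(m)) {
      eo <- Hrow[j] + go; ee <- E[i + 1, j] + ge
      if (eo >= ee) { E[i + 1, j + 1] <- eo; ptrE[i + 1, j + 1] <- 1L }
      else { E[i + 1, j + 1] <- ee; ptrE[i + 1, j + 1] <- 2L }
      fo <- H[i, j + 1] + go; fe <- F_[i, j + 1] + ge
      if (fo >= fe) { F_[i + 1, j + 1] <- fo; ptrF[i + 1, j + 1] <- 1L }
      else { F_[i + 1, j + 1] <- fe; ptrF[i + 1, j + 1] <- 2L }
      diag <- H[i, j] + si[tj[j]]
      h <- 0; p <- 0L
      if (diag > h) { h <- diag; p <- 1L }
      if (E[i + 1, j + 1] > h) { h <- E[i + 1, j + 1]; p <- 2L }
      if (F_[i + 1, j + 1] > h) { h <- F_[i + 1, j + 1]; p <- 3L }
      H[i + 1, j + 1] <- h; ptrH[i + 1, j + 1] <- p
      Hrow[j + 1] <- h
      # tie-break: larger j in reversed coordinates = smaller UTR start
      if (h > best || (h == best && h > 0 && j > bj)) {
        best <- h; bi <- i; bj <- j
      }
    }
    H[i + 1, ] <- Hrow
  }

  if (best <= 0) {
    return(list(score = 0, query_start = NA_integer_, query_end = NA_integer_,
                target_start = NA_integer_, target_end = NA_integer_,
                query_aln = "", pair = "", target_aln = "",
                n_gaps = 0L, stability = 0))
  }

  # traceback
  bases <- c("A", "C", "G", "T")
  qa <- character(0); ta <- character(0); pr <- character(0)
  i <- bi; j <- bj; state <- "H"; n_gaps <- 0L
  repeat {
    if (state == "H") {
      p <- ptrH[i + 1, j + 1]
      if (p == 0L) break
      if (p == 1L) {
        qb <- bases[qi[i]]; tb <- bases[tj[j]]
        sc <- S[qi[i], tj[j]]
        pr <- c(if (sc == params$match) "|" else if (sc == params$gu_wobble) ":" else " ", pr)
        qa <- c(qb, qa); ta <- c(tb, ta)
        i <- i - 1L; j <- j - 1L
      } else state <- if (p == 2L) "E" else "F"
    } else if (state == "E") {
      qa <- c("-", qa); ta <- c(bases[tj[j]], ta); pr <- c(" ", pr)
      n_gaps <- n_gaps + 1L
      p <- ptrE[i + 1, j + 1]
      j <- j - 1L
      if (p == 1L) state <- "H"
    } else {
      qa <- c(bases[qi[i]], qa); ta <- c("-", ta); pr <- c(" ", pr)
      n_gaps <- n_gaps + 1L
      p <- ptrF[i + 1, j + 1]
      i <- i - 1L
      if (p == 1L) state <- "H"
    }
    if (i == 0L && j == 0L) break
  }
  q_start <- i + 1L; q_end <- bi
  # reversed-window positions j..bj map back to forward window coordinates
  t_start <- m - bj + 1L; t_end <- m - (j + 1L) + 1L

  qa_chr <- paste(qa, collapse = ""); ta_chr <- paste(ta, collapse = "")
  pr_chr <- paste(pr, collapse = "")
  pairs_q <- strsplit(qa_chr, "")[[1]]
  pairs_t <- strsplit(ta_chr, "")[[1]]
  pairs_p <- strsplit(pr_chr, "")[[1]]
  gc_pair <- pairs_p == "|" & (pairs_q %in% c("G", "C"))
  au_pair <- pairs_p == "|" & (pairs_q %in% c("A", "T"))
  gu_pair <- pairs_p == ":"
  stability <- (sum(gc_pair) + 0.65 * sum(au_pair) + 0.35 * sum(gu_pair)) / n

  list(score = best, query_start = q_start, query_end = q_end,
       target_start = t_start, target_end = t_end,
       query_aln = qa_chr, pair = pr_chr, target_aln = ta_chr,
       n_gaps = n_gaps, stability = stability)
}

#' Scan 3'UTR sequences for small-RNA target sites
#'
#' Slides a window (width = fragment length + 15, step 5) over each UTR,
#' scores every window with [align_duplex()], keeps hits passing both the
#' score and stability thresholds, and merges overlapping hits keeping the
#' best score. A gene is called a target when it retains at least one hit.
#'
#' @param fragment Small-RNA sequence (5'->3').
#' @param utrs Named character vector of 3'UTR sequences.
#' @param params A [duplex_params()].
#' @param step Window step in nt.
#' @return Tibble with `utr_id`, `start`, `end` (site coordinates on the
#'   UTR, 1-based closed), `score`, `stability`, `query_aln`, `pair`,
#'   `target_aln`, sorted by `utr_id` then `start`.
#' @export
scan_targets <- function(fragment, utrs, params = duplex_params(), step = 5L) {
  if (length(utrs) == 0) abort("UTR set is empty")
  if (is.null(names(utrs)) || any(names(utrs) == "")) {
    abort("UTRs must be named")
  }
  width <- nchar(fragment) + 15L
  hits <- purrr::imap(utrs, function(u, id) {
    L <- nchar(u)
    starts <- unique(pmin(seq(1L, max(1L, L), by = step), max(1L, L - width + 1L)))
    rows <- purrr::map(starts, function(s) {
      w <- substr(u, s, min(L, s + width - 1L))
      a <- align_duplex(fragment, w, params)
      if (a$score < params$score_threshold ||
            a$stability < params$stability_threshold) return(NULL)
      tibble(utr_id = id, start = s + a$target_start - 1L,
             end = s + a$target_end - 1L, score = a$score,
             stability = a$stability, query_aln = a$query_aln,
             pair = a$pair, target_aln = a$target_aln)
    })
    bind_rows(rows)
  }) %>% bind_rows()
  if (nrow(hits) == 0) {
    return(tibble(utr_id = character(0), start = integer(0), end = integer(0),
                  score = numeric(0), stability = numeric(0),
                  query_aln = character(0), pair = character(0),
                  target_aln = character(0)))
  }
  # merge overlapping hits per UTR, keeping the maximum score
  hits %>%
    group_by(.data$utr_id) %>%
    arrange(.data$start, .data$end, .by_group = TRUE) %>%
    mutate(cluster = cumsum(.data$start > dplyr::lag(cummax(as.numeric(.data$end)),
                                                     default = -Inf))) %>%
    group_by(.data$utr_id, .data$cluster) %>%
    arrange(desc(.data$score), .data$start, .by_group = TRUE) %>%
    slice_head(n = 1) %>%
    ungroup() %>%
    select(-"cluster") %>%
    arrange(.data$utr_id, .data$start)
}

#' Gene-level target calls from a site scan
#'
#' @param hits Tibble from [scan_targets()].
#' @return Character vector of target gene ids.
#' @export
target_genes <- function(hits) sort(unique(hits$utr_id))
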