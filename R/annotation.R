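#' Find all exact genomic matches of a small-RNA sequence
#'
#' Scans both strands of a genome for exact occurrences of the query.
#' Minus-strand matches are reported in forward-reference coordinates
#' (1-based fully closed) with `strand = "-"`. An optional Hamming-distance
#' mode tolerates a small number of base polymorphisms.
#'
#' @param query Query sequence (A/C/G/T; no N; length >= 16).
#' @param genome Named character vector of chromosome sequences.
#' @param max_mismatch Maximum number of mismatches (default 0, exact).
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `matched`
#'   (the forward-reference sequence), sorted by `chrom` then `start`.
#' @export
#' @examples
#' g <- c(chr1 = "AAAACGTACGTACGTACGTACGTTTT")
#' match_genome("ACGTACGTACGTACGTACGT", g)
match_genome <- function(query, genome, max_mismatch = 0L) {
  query <- assert_dna(query, "query", allow_n = TRUE)
  if (grepl("N", query, fixed = TRUE)) {
    abort("query rejected: contains N (ambiguous bases cannot be matched exactly)")
  }
  if (nchar(query) < 16) {
    abort("query rejected: shorter than 16 nt (too ambiguous to place)")
  }
  subject <- Biostrings::DNAStringSet(genome)
  hits_for <- function(q, strand) {
    m <- Biostrings::vmatchPattern(q, subject, max.mismatch = max_mismatch)
    purrr::imap(as.list(m), function(ir, chrom) {
      if (length(ir) == 0) return(NULL)
      tibble(chrom = chrom, start = BiocGenerics::start(ir),
             end = BiocGenerics::end(ir), strand = strand)
    }) %>% bind_rows()
  }
  out <- bind_rows(hits_for(query, "+"), hits_for(revcomp(query), "-"))
  if (nrow(out) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  strand = character(0), matched = character(0)))
  }
  out %>%
    mutate(matched = substr(genome[.data$chrom], .data$start, .data$end)) %>%
    arrange(.data$chrom, .data$start, .data$strand)
}

#' Intersect genomic hits with tRNA gene loci
#'
#' Pairs each hit with a tRNA locus when the hit interval lies fully within
#' the locus or within `trailer` nt downstream of its 3' end (strand-aware:
#' downstream of a minus-strand gene extends to lower coordinates). The
#' 5' offset is computed strand-aware — offset 0 means the hit starts at the
#' first base of the gene, which for a minus-strand gene is its higher
#' genomic coordinate. Unmatched hits are classed `unannotated`. Each
#' matched hit also gets a fragment class from [classify_fragment()].
#'
#' @param hits Tibble from [match_genome()].
#' @param loci Locus tibble (`chrom`, `start`, `end`, `strand`, `gene_name`;
#'   1-based closed).
#' @param trailer Trailer-zone width in nt downstream of the gene 3' end.
#' @return Tibble: hit columns plus `gene_name`, `locus_start`, `locus_end`,
#'   `locus_strand`, `offset5` (NA when unannotated), `fragment_class`,
#'   `reported_label`.
#' @export
intersect_trna <- function(hits, loci, trailer = 50L) {
  if (any(loci$end < loci$start)) {
    abort("locus input error: end < start (inconsistent coordinate dialect)")
  }
  if (nrow(hits) == 0) {
    return(hits %>% mutate(gene_name = character(0), locus_start = integer(0),
                           locus_end = integer(0), locus_strand = character(0),
                           offset5 = integer(0), fragment_class = character(0),
                           reported_label = character(0)))
  }
  ext <- loci %>% mutate(
    ext_start = ifelse(.data$strand == "+", .data$start, .data$start - trailer),
    ext_end = ifelse(.data$strand == "+", .data$end + trailer, .data$end)
  )
  rows <- purrr::pmap(hits, function(chrom, start, end, strand, matched, ...) {
    cand <- ext %>%
      filter(.data$chrom == !!chrom, !!start >= .data$ext_start,
             !!end <= .data$ext_end)
    base <- tibble(chrom = chrom, start = start, end = end,
                   strand = strand, matched = matched)
    if (nrow(cand) == 0) {
      return(base %>% mutate(gene_name = NA_character_,
                             locus_start = NA_integer_, locus_end = NA_integer_,
                             locus_strand = NA_character_, offset5 = NA_integer_,
                             fragment_class = "unannotated",
                             reported_label = "unannotated"))
    }
    cand <- cand %>% mutate(
      offset5 = ifelse(.data$strand == "+", !!start - .data$start,
                       .data$end - !!end)
    ) %>% arrange(.data$offset5, .data$start) %>% slice_head(n = 1)
    frag_len <- end - start + 1L
    cls <- classify_fragment(cand$offset5, frag_len,
                             cand$end - cand$start + 1L)
    base %>% mutate(gene_name = cand$gene_name,
                    locus_start = cand$start, locus_end = cand$end,
                    locus_strand = cand$strand,
                    offset5 = as.integer(cand$offset5),
                    fragment_class = cls,
                    reported_label = reported_label(cls))
  })
  bind_rows(rows)
}

#' Assign a tRNA-fragment class from anchor geometry
#'
#' Classes follow the standard tRF taxonomy, parameterised by the fragment's
#' strand-aware 5' offset on the gene, the fragment length and the gene
#' length. Rules, applied in order:
#' * `offset5 <= 1` and length < 30 -> `tRF-5`;
#' * `offset5 <= 1` and 30 <= length <= 40 -> `half-5`;
#' * 3' end within 1 nt of the gene 3' end and length < 30 -> `tRF-3`;
#' * same anchor with 30-40 nt -> `half-3`;
#' * start beyond the gene 3' end (in the trailer) -> `tRF-1`;
#' * length equal to the gene length -> `full-length`;
#' * anything else -> `internal`.
#'
#' A 32 nt 5'-anchored fragment of a 71 nt gene is therefore a `half-5`;
#' such tRNA-derived fragments are commonly reported simply as "tRF", which
#' [reported_label()] emits alongside the precise class.
#'
#' @param offset5 Strand-aware 5' offset (0 = first base of the gene).
#' @param frag_len Fragment length in nt.
#' @param locus_len Gene length in nt.
#' @return Character vector of fragment classes (vectorised).
#' @export
#' @examples
#' classify_fragment(0, 32, 71)   # half-5 (reported as tRF)
#' classify_fragment(0, 71, 71)   # full-length
classify_fragment <- function(offset5, frag_len, locus_len) {
  end_off <- offset5 + frag_len - locus_len   # 3'-end offset from gene 3' end
  case_when(
    offset5 <= 1 & frag_len < 30 ~ "tRF-5",
    offset5 <= 1 & frag_len >= 30 & frag_len <= 40 ~ "half-5",
    abs(end_off) <= 1 & frag_len < 30 ~ "tRF-3",
    abs(end_off) <= 1 & frag_len >= 30 & frag_len <= 40 ~ "half-3",
    offset5 >= locus_len ~ "tRF-1",
    frag_len == locus_len ~ "full-length",
    TRUE ~ "internal"
  )
}

#' @rdname classify_fragment
#' @param fragment_class Character vector of fragment classes.
#' @export
reported_label <- function(fragment_class) {
  ifelse(fragment_class %in% c("unannotated", "full-length"),
         fragment_class, "tRF")
}

#' Annotate a candidate fragment sequence against genome and loci
#'
#' Convenience wrapper: [match_genome()] then [intersect_trna()].
#'
#' @inheritParams match_genome
#' @inheritParams intersect_trna
#' @return Annotated hit tibble (see [intersect_trna()]).
#' @export
annotate_fragment <- function(query, genome, loci, trailer = 50L,
                              max_mismatch = 0L) {
  intersect_trna(match_genome(query, genome, max_mismatch = max_mismatch),
                 loci, trailer = trailer)
}
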