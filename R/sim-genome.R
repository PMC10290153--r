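#' Simulate a toy genome with multi-copy tRNA genes
#'
#' Builds a small genome in which one glycine tRNA gene sequence is planted
#' in `trna_copies` copies spread over several chromosomes and both strands,
#' separated by random flanking sequence. All copies share the same gene
#' sequence, so the 5'-anchored fragment aligns to every copy — the
#' multi-locus situation a real tRF presents. Flanks are rejection-checked
#' so the fragment has no accidental exact occurrence outside the planted
#' loci (on either strand).
#'
#' @param config A [sim_config()].
#' @return A list with components:
#'   * `genome`: named character vector of chromosome sequences;
#'   * `loci`: tibble of tRNA gene intervals (`chrom`, `start`, `end`,
#'     `strand`, `gene_name`; 1-based fully-closed coordinates, so
#'     `end - start + 1` equals the gene length);
#'   * `trna_seq`: the tRNA gene sequence (5'->3');
#'   * `trf_seq`: its 5'-anchored fragment of `fragment_length` nt.
#' @export
#' @examples
#' toy <- simulate_genome(sim_config(seed = 1, trna_copies = 3))
#' toy$loci
simulate_genome <- function(config) {
  validate_sim_config(config)
  if (config$trna_copies < 1) abort("invalid config: trna_copies must be >= 1")
  withr::with_seed(sim_seed(config, "genome"), {
    gene <- random_dna(config$trna_gene_length)
    frag <- substr(gene, 1L, config$fragment_length)
    n_chrom <- min(5L, config$trna_copies)
    chroms <- paste0("chr", seq_len(n_chrom))
    copy_chrom <- chroms[((seq_len(config$trna_copies) - 1L) %% n_chrom) + 1L]
    strands <- sample(c("+", "-"), config$trna_copies, replace = TRUE)
    if (config$trna_copies >= 2) strands[1:2] <- c("+", "-")
    gene_names <- rep(c("TRNAG-CCC", "TRNAG-GCC"),
                      length.out = config$trna_copies)

    for (attempt in 1:20) {
      genome <- setNames(character(n_chrom), chroms)
      loci <- vector("list", config$trna_copies)
      pos <- setNames(integer(n_chrom), chroms)
      ord <- seq_len(config$trna_copies)
      for (i in ord) {
        chr <- copy_chrom[i]
        flank <- random_dna(sample(300:800, 1L))
        start <- nchar(genome[[chr]]) + nchar(flank) + 1L
        body <- if (strands[i] == "+") gene else revcomp(gene)
        genome[[chr]] <- paste0(genome[[chr]], flank, body)
        loci[[i]] <- tibble(
          chrom = chr, start = start,
          end = start + config$trna_gene_length - 1L,
          strand = strands[i], gene_name = gene_names[i]
        )
      }
      genome <- vapply(chroms, function(chr)
        paste0(genome[[chr]], random_dna(sample(300:800, 1L))),
        character(1))
      loci <- bind_rows(loci) %>% arrange(.data$chrom, .data$start)
      # No stray exact copy of the fragment outside the planted loci.
      n_fwd <- sum(stringr::str_count(genome, stringr::fixed(frag)))
      n_rev <- sum(stringr::str_count(genome, stringr::fixed(revcomp(frag))))
      expected <- config$trna_copies
      if (n_fwd + n_rev == expected) break
      if (attempt == 20) abort("could not place tRNA copies without collisions")
    }
    list(genome = genome, loci = loci, trna_seq = gene, trf_seq = frag)
  })
}

#' Draw decoy fragment-length sequences from non-tRNA genome regions
#'
#' Extracts `n` sequences of the configured fragment length from regions of
#' the toy genome that do not overlap any tRNA locus, so a downstream
#' annotator classifies them as unannotated.
#'
#' @param toy Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @param n Number of decoys.
#' @return Character vector of `n` distinct sequences.
#' @keywords internal
decoy_sequences <- function(toy, config, n = 3L) {
  len <- config$fragment_length
  out <- character(0)
  chrs <- names(toy$genome)
  for (tries in 1:500) {
    chr <- sample(chrs, 1L)
    L <- nchar(toy$genome[[chr]])
    if (L < len) next
    s <- sample.int(L - len + 1L, 1L)
    e <- s + len - 1L
    loc <- toy$loci %>% filter(.data$chrom == chr)
    if (nrow(loc) > 0 && any(s <= loc$end & e >= loc$start)) next
    cand <- substr(toy$genome[[chr]], s, e)
    if (cand %in% c(out, toy$trf_seq)) next
    out <- c(out, cand)
    if (length(out) == n) return(out)
  }
  abort("could not draw decoy sequences from non-tRNA regions")
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a genome (or any sequence set) from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read or write tRNA locus tables
#'
#' The locus table dialect is 5 columns (`chrom`, `start`, `end`, `strand`,
#' `gene_name`) with 1-based fully-closed coordinates, i.e. a 71 nt gene has
#' `end - start + 1 = 71`. This matches printed tRNA gene tables, NOT the
#' UCSC BED convention; set `bed_zero_based = TRUE` to convert from 0-based
#' half-open input (start incremented on read, decremented on write).
#'
#' @param path TSV path.
#' @param bed_zero_based Logical; treat the file as 0-based half-open.
#' @return `read_loci()`: a tibble of loci in the 1-based closed dialect.
#' @export
read_loci <- function(path, bed_zero_based = FALSE) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), strand = readr::col_character(),
    gene_name = readr::col_character()
  ))
  if (bed_zero_based) x$start <- x$start + 1
  if (any(x$end < x$start)) {
    abort("locus input error: end < start (wrong coordinate dialect?)")
  }
  if (!all(x$strand %in% c("+", "-"))) abort("locus strand must be '+' or '-'")
  as_tibble(x)
}

#' @rdname read_loci
#' @param loci Tibble of loci (1-based closed).
#' @export
write_loci <- function(loci, path, bed_zero_based = FALSE) {
  if (bed_zero_based) loci$start <- loci$start - 1
  readr::write_tsv(loci, path)
  invisible(path)
}
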