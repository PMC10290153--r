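test_that("exact matching recovers planted coordinates on both strands", {
  set.seed(101)
  core <- rand_seq(32)
  g <- c(chr1 = paste0(rand_seq(100), core, rand_seq(100)))
  h <- match_genome(core, g)
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end, h$strand), c("101", "132", "+"))

  g2 <- c(chr1 = paste0(rand_seq(200), revcomp(core), rand_seq(50)))
  h2 <- match_genome(core, g2)
  expect_equal(nrow(h2), 1)
  expect_equal(c(h2$start, h2$end, h2$strand), c("201", "232", "-"))
})

test_that("matching agrees with a naive sliding-window scan", {
  set.seed(7)
  for (rep in 1:5) {
    g <- c(chrA = rand_seq(1500), chrB = rand_seq(900))
    q <- rand_seq(18)
    # plant occurrences on both strands and chromosomes
    g[["chrA"]] <- paste0(g[["chrA"]], q, rand_seq(40), revcomp(q))
    g[["chrB"]] <- paste0(q, g[["chrB"]])
    got <- match_genome(q, g)
    ora <- naive_match(q, g)
    expect_equal(nrow(got), nrow(ora))
    expect_equal(got$start, ora$start)
    expect_equal(got$end, ora$end)
    expect_equal(got$strand, ora$strand)
    expect_equal(got$chrom, ora$chrom)
  }
})

test_that("reverse-complement involution swaps strands", {
  set.seed(15)
  g <- c(chr1 = paste0(rand_seq(80), rand_seq(20), rand_seq(80)))
  q <- rand_seq(20)
  g[["chr1"]] <- paste0(g[["chr1"]], q, rand_seq(30))
  a <- match_genome(q, g)
  b <- match_genome(revcomp(q), g)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(a$strand, chartr("+-", "-+", b$strand))
})

test_that("ambiguous or short queries are rejected with a reason", {
  g <- c(chr1 = strrep("ACGT", 50))
  expect_error(match_genome("ACGTNACGTACGTACGT", g), "contains N")
  expect_error(match_genome("ACGTACGTACGT", g), "shorter than 16")
})

test_that("offset5 is strand-aware with 0 at the gene 5prime end", {
  loci <- tibble::tibble(chrom = "chr1", start = 101L, end = 171L,
                         strand = "+", gene_name = "TRNAG-CCC")
  hit <- tibble::tibble(chrom = "chr1", start = 101L, end = 132L,
                        strand = "+", matched = strrep("A", 32))
  ann <- intersect_trna(hit, loci)
  expect_equal(ann$offset5, 0L)
  expect_equal(ann$fragment_class, "half-5")

  loci_m <- dplyr::mutate(loci, strand = "-")
  hit_m <- dplyr::mutate(hit, start = 140L, end = 171L, strand = "-")
  ann_m <- intersect_trna(hit_m, loci_m)
  expect_equal(ann_m$offset5, 0L)
  expect_equal(ann_m$fragment_class, "half-5")
})

test_that("minus-strand offsets agree with reverse-complement reconstruction", {
  # plant a minus-strand gene, match its 5'-anchored fragment, and verify
  # the fragment really is the gene prefix by reconstructing from the genome
  cfg <- sim_config(seed = 33, trna_copies = 6)
  toy <- simulate_genome(cfg)
  ann <- annotate_fragment(toy$trf_seq, toy$genome, toy$loci)
  expect_true(all(ann$offset5 == 0))
  minus <- dplyr::filter(ann, locus_strand == "-")
  expect_gt(nrow(minus), 0)
  for (i in seq_len(nrow(minus))) {
    gene_fwd <- substr(toy$genome[[minus$chrom[i]]],
                       minus$locus_start[i], minus$locus_end[i])
    expect_equal(substr(revcomp(gene_fwd), 1, 32), toy$trf_seq)
  }
})

test_that("hits outside loci and trailer are unannotated; trailer gives tRF-1", {
  loci <- tibble::tibble(chrom = "chr1", start = 101L, end = 171L,
                         strand = "+", gene_name = "TRNAG-CCC")
  far <- tibble::tibble(chrom = "chr1", start = 400L, end = 431L,
                        strand = "+", matched = strrep("A", 32))
  expect_equal(intersect_trna(far, loci)$fragment_class, "unannotated")

  trailer_hit <- tibble::tibble(chrom = "chr1", start = 176L, end = 195L,
                                strand = "+", matched = strrep("A", 20))
  ann <- intersect_trna(trailer_hit, loci)
  expect_equal(ann$fragment_class, "tRF-1")
  expect_equal(ann$offset5, 75L)

  beyond <- tibble::tibble(chrom = "chr1", start = 230L, end = 249L,
                           strand = "+", matched = strrep("A", 20))
  expect_equal(intersect_trna(beyond, loci)$fragment_class, "unannotated")
})

test_that("coordinate dialect errors are caught", {
  bad <- tibble::tibble(chrom = "chr1", start = 171L, end = 101L,
                        strand = "+", gene_name = "x")
  hit <- tibble::tibble(chrom = "chr1", start = 110L, end = 130L,
                        strand = "+", matched = strrep("A", 21))
  expect_error(intersect_trna(hit, bad), "coordinate dialect")
})

test_that("fragment class rules cover the anchor/length table", {
  expect_equal(classify_fragment(0, 32, 71), "half-5")
  expect_equal(classify_fragment(1, 38, 71), "half-5")
  expect_equal(classify_fragment(0, 20, 71), "tRF-5")
  expect_equal(classify_fragment(71 - 20, 20, 71), "tRF-3")   # 3' anchored, short
  expect_equal(classify_fragment(71 - 35, 35, 71), "half-3")
  expect_equal(classify_fragment(76, 20, 71), "tRF-1")        # 5 nt past gene end
  expect_equal(classify_fragment(0, 71, 71), "full-length")
  expect_equal(classify_fragment(10, 20, 71), "internal")
  expect_equal(reported_label(c("half-5", "tRF-3", "unannotated", "full-length")),
               c("tRF", "tRF", "unannotated", "full-length"))
})

test_that("classification is exhaustive and single-valued over random anchors", {
  set.seed(3)
  classes <- c("tRF-5", "tRF-3", "tRF-1", "half-5", "half-3",
               "internal", "full-length")
  off <- sample(0:130, 300, replace = TRUE)
  len <- sample(16:45, 300, replace = TRUE)
  got <- classify_fragment(off, len, 71)
  expect_true(all(got %in% classes))
  expect_equal(length(got), 300)
})

test_that("the multi-copy fragment annotates as a 5prime half at all loci", {
  cfg <- sim_config(seed = 41, trna_copies = 15)
  toy <- simulate_genome(cfg)
  ann <- annotate_fragment(toy$trf_seq, toy$genome, toy$loci)
  expect_equal(nrow(ann), 15)
  expect_true(all(ann$fragment_class == "half-5"))
  expect_true(all(ann$reported_label == "tRF"))
  # decoys drawn from non-tRNA regions take the negative path
  decoy <- decoy_seq <- trfscan::simulate_reads(toy, sim_config(seed = 41,
    trna_copies = 15, read_depth = 100))$truth$decoys[1]
  ann_d <- annotate_fragment(decoy, toy$genome, toy$loci)
  expect_true(all(ann_d$fragment_class == "unannotated"))
})

test_that("locus IO honours both coordinate dialects", {
  loci <- tibble::tibble(chrom = "chr1", start = 101L, end = 171L,
                         strand = "+", gene_name = "TRNAG-CCC")
  f <- tempfile(fileext = ".tsv")
  write_loci(loci, f)
  expect_equal(read_loci(f)$start, 101)
  write_loci(loci, f, bed_zero_based = TRUE)
  raw <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(raw$start, 100)               # 0-based half-open on disk
  expect_equal(read_loci(f, bed_zero_based = TRUE)$start, 101)
})
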