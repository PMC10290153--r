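write_fastq_lines <- function(reads, path) {
  lines <- unlist(lapply(seq_along(reads), function(i) {
    c(sprintf("@r%d", i), reads[i], "+", strrep("I", nchar(reads[i])))
  }))
  writeLines(lines, path)
  path
}

test_that("FASTQ loading returns one row per record and flags malformed files", {
  f <- write_fastq_lines(strrep("A", 22), tempfile(fileext = ".fastq"))
  rs <- load_reads(f, "s1", "coarse")
  expect_equal(nrow(rs), 1)
  expect_equal(nchar(rs$read), 22)

  empty <- tempfile(fileext = ".fastq"); file.create(empty)
  expect_equal(nrow(load_reads(empty, "s1", "coarse")), 0)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+"), bad)   # truncated record
  expect_error(load_reads(bad, "s1", "coarse"), "malformed FASTQ")
})

test_that("length filter keeps the closed 18-41 window", {
  rs <- tibble::tibble(sample_id = "s", group = "g",
                       read = vapply(c(17, 18, 32, 41, 42), function(n)
                         strrep("A", n), character(1)))
  kept <- filter_by_length(rs)
  expect_setequal(nchar(kept$read), c(18, 32, 41))
  only32 <- filter_by_length(rs, 32, 32)
  expect_equal(nchar(only32$read), 32)
  expect_equal(nrow(filter_by_length(rs[0, ])), 0)
  expect_error(filter_by_length(rs, 30, 20), "min_len")
})

test_that("length spectrum counts and RPM match direct arithmetic", {
  rs <- tibble::tibble(sample_id = "s", group = "g",
                       read = c(strrep("A", 22), strrep("C", 22), strrep("G", 32)))
  sp <- length_spectrum(rs)
  expect_equal(sp$count[sp$length == 22], 2)
  expect_equal(sp$count[sp$length == 32], 1)
  expect_equal(sum(sp$count), sp$total_retained[1])
  expect_equal(sp$rpm[sp$length == 22], 2 / 3 * 1e6)
  expect_equal(sp$rpm[sp$length == 32], 1 / 3 * 1e6)
  expect_equal(sum(sp$rpm), 1e6)
})

test_that("empty read sets give all-zero spectra flagged by total_retained", {
  rs <- tibble::tibble(sample_id = character(0), group = character(0),
                       read = character(0))
  sp <- length_spectrum(rs)
  expect_equal(nrow(sp), 0)
  rs1 <- tibble::tibble(sample_id = "s", group = "g", read = strrep("A", 50))
  sp1 <- length_spectrum(rs1)   # read outside window
  expect_true(all(sp1$count == 0))
  expect_true(all(sp1$total_retained == 0))
  expect_true(all(sp1$rpm == 0))
})

test_that("spectrum equals an independent tally on simulated reads", {
  cfg <- sim_config(seed = 13, read_depth = 3000, n_per_group = 1,
                    trna_copies = 2)
  toy <- simulate_genome(cfg)
  rs <- simulate_reads(toy, cfg)
  sp <- length_spectrum(rs$reads)
  for (sid in unique(rs$reads$sample_id)) {
    lens <- nchar(rs$reads$read[rs$reads$sample_id == sid])
    tal <- table(factor(lens[lens >= 18 & lens <= 41], levels = 18:41))
    got <- sp$count[sp$sample_id == sid][match(18:41, sp$length[sp$sample_id == sid])]
    expect_equal(unname(got), as.vector(tal))
  }
})

test_that("relabelled identical spectra produce no peak calls", {
  cfg <- sim_config(seed = 19, read_depth = 20000, n_per_group = 2)
  sp <- simulate_length_spectra(cfg)
  coarse <- dplyr::filter(sp, group == "coarse")
  # copy the coarse samples verbatim into a fake second group
  fake <- dplyr::mutate(coarse, group = "fake",
                        sample_id = paste0("fake_", sample_id))
  both <- dplyr::bind_rows(coarse, fake)
  calls <- detect_anomalous_peaks(both, group_order = c("coarse", "fake"))
  expect_equal(nrow(calls), 0)
  # and the degenerate-variance rule sets p = 1, not NA
  tests <- spectrum_length_tests(both, group_order = c("coarse", "fake"))
  expect_true(all(tests$p_value == 1))
})

test_that("a planted fragment component yields exactly one call at 32 nt", {
  cfg <- sim_config(seed = 23, read_depth = 30000, n_per_group = 3)
  sp <- simulate_length_spectra(cfg)
  calls <- detect_anomalous_peaks(sp, group_order = c("coarse", "fine"))
  expect_equal(calls$length, 32)
  expect_gt(calls$group_fold, 2)
})

test_that("insufficient replication is an explicit error", {
  cfg <- sim_config(seed = 2, read_depth = 1000, n_per_group = 1)
  sp <- simulate_length_spectra(cfg)
  expect_error(detect_anomalous_peaks(sp), "insufficient replication")
})

test_that("peak decomposition reports sorted fractions that sum to one", {
  rs <- tibble::tibble(
    sample_id = "s", group = "g",
    read = c(rep(strrep("ACGT", 8), 3), paste0(strrep("ACGT", 7), "AAAA"))
  )
  comp <- decompose_peak(rs, 32)
  pooled <- dplyr::filter(comp, scope == "pooled")
  expect_equal(pooled$fraction, c(0.75, 0.25))
  expect_equal(pooled$rank, 1:2)
  expect_equal(sum(pooled$fraction), 1)
  expect_equal(pooled$sequence[1], strrep("ACGT", 8))
})

test_that("N-containing reads are excluded and absent lengths give empty output", {
  rs <- tibble::tibble(sample_id = "s", group = "g",
                       read = c(strrep("ACGT", 8),
                                paste0(strrep("ACGT", 7), "ANNA")))
  comp <- decompose_peak(rs, 32)
  expect_equal(nrow(dplyr::filter(comp, scope == "pooled")), 1)
  expect_equal(nrow(decompose_peak(rs, 30)), 0)
})

test_that("four planted sequences dominate the simulated 32nt composition", {
  cfg <- sim_config(seed = 29, read_depth = 50000, n_per_group = 2)
  toy <- simulate_genome(cfg)
  rs <- simulate_reads(toy, cfg)
  comp <- decompose_peak(rs$reads, 32)
  pooled <- dplyr::filter(comp, scope == "pooled")
  planted <- c(rs$truth$trf_seq, rs$truth$decoys)
  expect_setequal(pooled$sequence[1:4], planted)
  expect_equal(pooled$sequence[1], rs$truth$trf_seq)
  # everything beyond the planted four is background singleton noise
  expect_lt(sum(pooled$fraction[-(1:4)]), 0.1)
  for (sc in unique(comp$scope)) {
    expect_equal(sum(comp$fraction[comp$scope == sc]), 1)
  }
})
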