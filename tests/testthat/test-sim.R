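test_that("toy genome places tRNA copies with closed-interval coordinates", {
  cfg <- sim_config(seed = 5, trna_copies = 1)
  toy <- simulate_genome(cfg)
  expect_equal(nrow(toy$loci), 1)
  expect_equal(toy$loci$end - toy$loci$start + 1, 71)

  cfg15 <- sim_config(seed = 5, trna_copies = 15)
  toy15 <- simulate_genome(cfg15)
  expect_equal(nrow(toy15$loci), 15)
  expect_true(all(toy15$loci$gene_name %in% c("TRNAG-CCC", "TRNAG-GCC")))
  expect_true(all(c("+", "-") %in% toy15$loci$strand))
  expect_true(all(toy15$loci$end - toy15$loci$start + 1 == 71))
})

test_that("minus-strand locus sequence is the reverse complement of the gene", {
  toy <- simulate_genome(sim_config(seed = 9, trna_copies = 4))
  minus <- dplyr::filter(toy$loci, strand == "-")
  for (i in seq_len(nrow(minus))) {
    fwd <- substr(toy$genome[[minus$chrom[i]]], minus$start[i], minus$end[i])
    expect_equal(revcomp(fwd), toy$trna_seq)
  }
})

test_that("flanks carry no accidental copy of the fragment", {
  toy <- simulate_genome(sim_config(seed = 21, trna_copies = 15))
  n_occ <- sum(stringr::str_count(toy$genome, stringr::fixed(toy$trf_seq))) +
    sum(stringr::str_count(toy$genome, stringr::fixed(revcomp(toy$trf_seq))))
  expect_equal(n_occ, 15)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 42, read_depth = 2000, trna_copies = 3)
  toy1 <- simulate_genome(cfg); toy2 <- simulate_genome(cfg)
  expect_identical(toy1, toy2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(toy1$genome, f1); write_genome_fasta(toy2$genome, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  expect_identical(simulate_reads(toy1, cfg), simulate_reads(toy1, cfg))
  expect_identical(simulate_proteome(cfg), simulate_proteome(cfg))
  expect_identical(simulate_metabolome(cfg), simulate_metabolome(cfg))
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(fragment_length = 80, trna_gene_length = 71),
               "fragment_length")
  expect_error(sim_config(trf_fold = -1), "folds")
  expect_error(sim_config(dominant_fraction_coarse = 1.2), "\\[0, 1\\]")
  expect_error(simulate_proteome(sim_config(n_per_group = 1)), "t-test")
  expect_error(simulate_proteome(sim_config(protein_count = 5)), "protein_count")
  expect_error(simulate_metabolome(sim_config(n_qc = 1)), "n_qc")
  toy <- simulate_genome(sim_config(seed = 1, trna_copies = 2))
  toy$loci <- toy$loci[0, ]
  expect_error(simulate_reads(toy, sim_config(seed = 1, read_depth = 100)),
               "locus list is empty")
})

test_that("dominant sequence frequency follows the configured binomial draw", {
  cfg <- sim_config(seed = 31, read_depth = 1e5, n_per_group = 1)
  toy <- simulate_genome(cfg)
  rs <- simulate_reads(toy, cfg)
  coarse <- rs$reads$read[rs$reads$group == "coarse"]
  n_dom <- sum(coarse == rs$truth$trf_seq)
  n_decoy <- sum(coarse %in% rs$truth$decoys)
  n_comp <- n_dom + n_decoy
  p_hat <- n_dom / n_comp
  se <- sqrt(0.9 * 0.1 / n_comp)
  expect_lt(abs(p_hat - 0.90), 3 * se)
})

test_that("fragment-component weights differ between groups by the configured fold", {
  cfg <- sim_config(seed = 8, read_depth = 1e5, n_per_group = 2)
  toy <- simulate_genome(cfg)
  rs <- simulate_reads(toy, cfg)
  expect_equal(rs$truth$trf_weight$coarse / rs$truth$trf_weight$fine,
               cfg$trf_fold)
  frag_set <- c(rs$truth$trf_seq, rs$truth$decoys)
  comp <- rs$reads %>%
    dplyr::group_by(group) %>%
    dplyr::summarise(n = sum(read %in% frag_set) / dplyr::n_distinct(sample_id))
  ratio <- comp$n[comp$group == "coarse"] / comp$n[comp$group == "fine"]
  # 3 SE of the count ratio at this depth
  expect_lt(abs(ratio - cfg$trf_fold), 0.35)
})

test_that("removing the fragment component leaves no 32nt excess", {
  cfg <- sim_config(seed = 3, read_depth = 5e4, trf_weight = 0)
  sp <- simulate_length_spectra(cfg)
  by_len <- sp %>% dplyr::group_by(length) %>%
    dplyr::summarise(m = mean(rpm))
  at32 <- by_len$m[by_len$length == 32]
  bg <- by_len$m[!by_len$length %in% c(22, 32)]
  expect_lt(at32, mean(bg) + 4 * sd(bg))
})

test_that("null proteome p-values reject at the nominal rate", {
  cfg <- sim_config(seed = 77, protein_count = 1000, n_protein_up = 0,
                    n_protein_down = 0, n_per_group = 4)
  pr <- simulate_proteome(cfg)
  deps <- call_deps(pr$proteins, group_order = c("coarse", "fine"))
  rate <- mean(deps$p_value < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.08)
})

test_that("planted down-shifted proteins pass the 0.83 fold cutoff", {
  cfg <- sim_config(seed = 12, protein_count = 50, n_protein_up = 0,
                    n_protein_down = 10, protein_log2fc = 1, protein_sd = 0.05,
                    n_per_group = 3)
  pr <- simulate_proteome(cfg)
  deps <- call_deps(pr$proteins, group_order = c("coarse", "fine"))
  planted <- pr$truth$protein[pr$truth$planted_down]
  called <- deps$protein[deps$direction == "down"]
  expect_true(all(planted %in% called))
  expect_true(all(deps$fold[deps$protein %in% planted] < 0.83))
})

test_that("QC profiles collapse to the pooled mean when technical noise is zero", {
  cfg <- sim_config(seed = 6, metabolite_count = 20, qc_sd = 0)
  mb <- simulate_metabolome(cfg)
  qc <- mb$metabolites %>%
    dplyr::filter(group == "QC") %>%
    tidyr::pivot_wider(id_cols = "metabolite", names_from = "sample_id",
                       values_from = "intensity")
  m <- as.matrix(qc[, -1])
  expect_equal(apply(m, 1, sd), rep(0, nrow(m)))
})

test_that("qPCR generator encodes the fold in delta-Ct exactly at zero noise", {
  cfg <- sim_config(seed = 4, trf_fold = 1)
  q1 <- simulate_qpcr(cfg, "trf", noise_sd = 0)
  dct <- q1$qpcr$ct_target - q1$qpcr$ct_reference
  expect_equal(max(dct) - min(dct), 0)

  cfg2 <- sim_config(seed = 4, trf_fold = 2)
  q2 <- simulate_qpcr(cfg2, "trf", noise_sd = 0)
  rq <- ddct(q2$qpcr, "fine")
  expect_equal(rq$ddct[rq$group == "coarse"], -1)
  expect_equal(rq$rq[rq$group == "coarse"], 2)
})
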