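#' Configuration for the synthetic study generator
#'
#' Bundles every tunable of the synthetic coarse-vs-fine wool study:
#' the toy genome and its multi-copy glycine tRNA gene, the small-RNA read
#' mixture, and the proteome / metabolome / qPCR layers. Defaults encode
#' the study conditions the generators emulate: a 71 nt tRNA gene present
#' in 15 genomic copies, a 32 nt 5'-anchored fragment whose abundance is
#' 5.77-fold higher in the coarse group, an intact tRNA 6.28-fold higher in
#' the fine group, and a dominant sequence making up 90% of the 32 nt peak
#' in coarse samples.
#'
#' @param seed Integer seed; fixing it makes every generator byte-identical.
#' @param n_per_group Samples per group (coarse / fine).
#' @param trna_copies Number of genomic copies of the tRNA gene.
#' @param trna_gene_length tRNA gene length in nt.
#' @param fragment_length Length of the tRNA-derived fragment in nt.
#' @param trf_fold True coarse/fine fold of the fragment component.
#' @param trna_fold True fine/coarse fold of the intact tRNA (qPCR layer).
#' @param dominant_fraction_coarse,dominant_fraction_fine Probability that a
#'   32 nt read is the dominant fragment sequence, per group; the remainder
#'   is split evenly among three decoy sequences.
#' @param mirna_peak_length Length of the canonical miRNA peak (nt).
#' @param mirna_weight Mixture weight of the miRNA component.
#' @param trf_weight Mixture weight of the fragment component in the coarse
#'   group; the fine group gets `trf_weight / trf_fold`, the remainder of
#'   each group's mass is uniform background over the length window.
#' @param length_window Closed read-length window (nt) retained downstream.
#' @param read_depth Reads per sample.
#' @param protein_count,n_protein_up,n_protein_down Proteome size and number
#'   of planted up-/down-shifted proteins (coarse relative to fine).
#' @param protein_log2fc Absolute log2 fold change of planted proteins.
#' @param protein_sd Residual sd of log2 protein abundance.
#' @param target_fraction_down,target_fraction_null Fraction of down-shifted
#'   (resp. unshifted) proteins flagged as planted fragment targets.
#' @param metabolite_count,n_metab_disc Metabolome size and number of planted
#'   discriminating metabolites.
#' @param metab_log_shift Log-scale group shift of planted discriminators.
#' @param metab_sd Log-scale biological sd of metabolite intensities.
#' @param qc_sd Log-scale technical sd of pooled QC injections.
#' @param n_qc Number of QC samples.
#' @param qpcr_sd Sd of Ct noise.
#' @param utr_length Length of each synthetic 3'UTR (nt).
#' @param utr_count Number of synthetic 3'UTRs emitted for the target scan.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, read_depth = 1000)
#' cfg$trf_fold
sim_config <- function(seed = 1L,
                       n_per_group = 3L,
                       trna_copies = 15L,
                       trna_gene_length = 71L,
                       fragment_length = 32L,
                       trf_fold = 5.77,
                       trna_fold = 6.28,
                       dominant_fraction_coarse = 0.90,
                       dominant_fraction_fine = 0.55,
                       mirna_peak_length = 22L,
                       mirna_weight = 0.28,
                       trf_weight = 0.35,
                       length_window = c(18L, 41L),
                       read_depth = 100000L,
                       protein_count = 500L,
                       n_protein_up = 40L,
                       n_protein_down = 120L,
                       protein_log2fc = 1.0,
                       protein_sd = 0.25,
                       target_fraction_down = 0.5,
                       target_fraction_null = 0.1,
                       metabolite_count = 120L,
                       n_metab_disc = 18L,
                       metab_log_shift = 2.0,
                       metab_sd = 0.30,
                       qc_sd = 0.02,
                       n_qc = 3L,
                       qpcr_sd = 0.1,
                       utr_length = 300L,
                       utr_count = 40L) {
  cfg <- list(
    seed = as.integer(seed),
    n_per_group = as.integer(n_per_group),
    trna_copies = as.integer(trna_copies),
    trna_gene_length = as.integer(trna_gene_length),
    fragment_length = as.integer(fragment_length),
    trf_fold = trf_fold,
    trna_fold = trna_fold,
    dominant_fraction_coarse = dominant_fraction_coarse,
    dominant_fraction_fine = dominant_fraction_fine,
    mirna_peak_length = as.integer(mirna_peak_length),
    mirna_weight = mirna_weight,
    trf_weight = trf_weight,
    length_window = as.integer(length_window),
    read_depth = as.integer(read_depth),
    protein_count = as.integer(protein_count),
    n_protein_up = as.integer(n_protein_up),
    n_protein_down = as.integer(n_protein_down),
    protein_log2fc = protein_log2fc,
    protein_sd = protein_sd,
    target_fraction_down = target_fraction_down,
    target_fraction_null = target_fraction_null,
    metabolite_count = as.integer(metabolite_count),
    n_metab_disc = as.integer(n_metab_disc),
    metab_log_shift = metab_log_shift,
    metab_sd = metab_sd,
    qc_sd = qc_sd,
    n_qc = as.integer(n_qc),
    qpcr_sd = qpcr_sd,
    utr_length = as.integer(utr_length),
    utr_count = as.integer(utr_count)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste0("invalid config: ", msg))
  counts <- c("n_per_group", "trna_copies", "trna_gene_length", "fragment_length",
              "read_depth", "protein_count", "metabolite_count", "n_qc",
              "n_protein_up", "n_protein_down", "n_metab_disc", "utr_length",
              "utr_count")
  for (f in counts) chk(cfg[[f]] >= 0, sprintf("%s must be >= 0", f))
  chk(cfg$trf_fold > 0 && cfg$trna_fold > 0, "folds must be > 0")
  for (f in c("dominant_fraction_coarse", "dominant_fraction_fine",
              "mirna_weight", "trf_weight",
              "target_fraction_down", "target_fraction_null")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, sprintf("%s must be in [0, 1]", f))
  }
  chk(cfg$mirna_weight + cfg$trf_weight <= 1, "mixture weights exceed 1")
  chk(cfg$fragment_length <= cfg$trna_gene_length,
      "fragment_length must not exceed trna_gene_length")
  chk(length(cfg$length_window) == 2 && cfg$length_window[1] <= cfg$length_window[2],
      "length_window must be an ordered pair")
  chk(cfg$mirna_peak_length >= cfg$length_window[1] &&
        cfg$mirna_peak_length <= cfg$length_window[2],
      "mirna_peak_length outside length_window")
  invisible(cfg)
}

# Per-generator seed streams: deterministic offsets keep generators
# independent of call order while staying tied to the one config seed.
sim_seed <- function(cfg, stream) {
  offsets <- c(genome = 101L, reads = 211L, proteome = 307L,
               metabolome = 401L, qpcr = 503L, utrs = 601L, spectra = 701L)
  (cfg$seed + offsets[[stream]]) %% .Machine$integer.max
}
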