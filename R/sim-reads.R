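# Per-group mixture over the read-length window: a uniform background, a
# canonical miRNA peak, and the fragment component whose weight differs
# between groups by trf_fold. Weights are NOT renormalised across groups:
# the fine group's missing fragment mass goes to background, so the
# expected coarse/fine ratio of fragment-component reads is exactly trf_fold.
group_mixture <- function(config, group) {
  trf_w <- switch(group,
    coarse = config$trf_weight,
    fine = config$trf_weight / config$trf_fold,
    abort(sprintf("unknown group '%s'", group))
  )
  bg <- 1 - config$mirna_weight - trf_w
  c(background = bg, mirna = config$mirna_weight, trf = trf_w)
}

dominant_fraction <- function(config, group) {
  switch(group,
    coarse = config$dominant_fraction_coarse,
    fine = config$dominant_fraction_fine
  )
}

#' Simulate small-RNA reads for a two-group study
#'
#' Draws `read_depth` reads per sample from a three-component mixture:
#' a uniform background over the read-length window, a canonical miRNA peak
#' at `mirna_peak_length` (a fixed pool of decoy miRNA sequences with
#' Zipf-like abundances), and the tRNA-fragment component at
#' `fragment_length`, whose mixture weight is `trf_fold`-times higher in the
#' coarse group. Within the fragment component the designated 5'-anchored
#' tRNA fragment is emitted with the group's dominant fraction; the rest is
#' split evenly among three decoy sequences of the same length drawn from
#' non-tRNA genome regions.
#'
#' @param toy Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @return A list:
#'   * `reads`: tibble with `sample_id`, `group`, `read` (one row per read);
#'   * `truth`: list with the true fragment sequence, the decoys, the
#'     per-group fragment weights and dominant fractions. Truth is emitted
#'     alongside the data and must never feed the pipeline.
#' @export
simulate_reads <- function(toy, config) {
  validate_sim_config(config)
  if (config$read_depth < 1) abort("invalid config: read_depth must be > 0")
  if (config$trf_weight > 0 && (is.null(toy$loci) || nrow(toy$loci) == 0)) {
    abort("invalid config: fragment component requested but locus list is empty")
  }
  win <- seq(config$length_window[1], config$length_window[2])
  withr::with_seed(sim_seed(config, "reads"), {
    mirna_pool <- unique(random_dna(rep(config$mirna_peak_length, 40)))[1:25]
    mirna_prob <- (1 / seq_along(mirna_pool)) / sum(1 / seq_along(mirna_pool))
    decoys <- if (config$trf_weight > 0) decoy_sequences(toy, config, 3L) else character(0)

    samples <- tibble(
      sample_id = c(paste0("coarse_", seq_len(config$n_per_group)),
                    paste0("fine_", seq_len(config$n_per_group))),
      group = rep(c("coarse", "fine"), each = config$n_per_group)
    )
    reads <- purrr::pmap(samples, function(sample_id, group) {
      w <- group_mixture(config, group)
      n_comp <- as.vector(rmultinom(1, config$read_depth, w))
      bg_lens <- sample(win, n_comp[1], replace = TRUE)
      bg <- random_dna(bg_lens)
      mir <- sample(mirna_pool, n_comp[2], replace = TRUE, prob = mirna_prob)
      n_dom <- rbinom(1, n_comp[3], dominant_fraction(config, group))
      trf <- c(rep(toy$trf_seq, n_dom),
               if (n_comp[3] > n_dom)
                 sample(decoys, n_comp[3] - n_dom, replace = TRUE))
      tibble(sample_id = sample_id, group = group,
             read = sample(c(bg, mir, trf)))
    }) %>% bind_rows()

    truth <- list(
      trf_seq = toy$trf_seq,
      decoys = decoys,
      trf_weight = list(coarse = group_mixture(config, "coarse")[["trf"]],
                        fine = group_mixture(config, "fine")[["trf"]]),
      dominant_fraction = list(coarse = config$dominant_fraction_coarse,
                               fine = config$dominant_fraction_fine),
      trf_fold = config$trf_fold
    )
    list(reads = reads, truth = truth)
  })
}

#' Simulate per-sample read-length spectra directly
#'
#' Draws the marginal length distribution of [simulate_reads()] — a
#' multinomial over the length window with the same per-group mixture
#' weights — without materialising read sequences. Useful for calibration
#' studies that only consume spectra.
#'
#' @param config A [sim_config()].
#' @param trf_weight_override Optional; set the coarse-group fragment weight
#'   (e.g. 0 for a null study where both groups share the background +
#'   miRNA mixture).
#' @return A length-spectrum tibble (`sample_id`, `group`, `length`,
#'   `count`, `total_retained`, `rpm`) of class `trf_spectrum`.
#' @export
simulate_length_spectra <- function(config, trf_weight_override = NULL) {
  validate_sim_config(config)
  cfg <- config
  if (!is.null(trf_weight_override)) cfg$trf_weight <- trf_weight_override
  win <- seq(cfg$length_window[1], cfg$length_window[2])
  withr::with_seed(sim_seed(cfg, "spectra"), {
    samples <- tibble(
      sample_id = c(paste0("coarse_", seq_len(cfg$n_per_group)),
                    paste0("fine_", seq_len(cfg$n_per_group))),
      group = rep(c("coarse", "fine"), each = cfg$n_per_group)
    )
    out <- purrr::pmap(samples, function(sample_id, group) {
      w <- group_mixture(cfg, group)
      p <- rep(w[["background"]] / length(win), length(win))
      p[win == cfg$mirna_peak_length] <- p[win == cfg$mirna_peak_length] + w[["mirna"]]
      p[win == cfg$fragment_length] <- p[win == cfg$fragment_length] + w[["trf"]]
      cnt <- as.vector(rmultinom(1, cfg$read_depth, p))
      tibble(sample_id = sample_id, group = group, length = win, count = cnt)
    }) %>% bind_rows() %>%
      group_by(.data$sample_id) %>%
      mutate(total_retained = sum(.data$count),
             rpm = ifelse(.data$total_retained > 0,
                          .data$count / .data$total_retained * 1e6, 0)) %>%
      ungroup()
    class(out) <- c("trf_spectrum", class(out))
    out
  })
}

#' Write simulated reads as one FASTQ file per sample
#'
#' Qualities are fixed at 'I' (Phred 40); the generator has no error model.
#'
#' @param reads Tibble with `sample_id`, `group`, `read`.
#' @param dir Output directory (created if missing).
#' @return Tibble manifest (`sample_id`, `group`, `path`).
#' @export
write_reads_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- reads %>% distinct(.data$sample_id, .data$group)
  manifest$path <- file.path(dir, paste0(manifest$sample_id, ".fastq"))
  for (i in seq_len(nrow(manifest))) {
    r <- reads$read[reads$sample_id == manifest$sample_id[i]]
    x <- Biostrings::DNAStringSet(r)
    names(x) <- sprintf("%s_read%06d", manifest$sample_id[i], seq_along(r))
    q <- Biostrings::BStringSet(strrep("I", nchar(r)))
    Biostrings::writeXStringSet(x, manifest$path[i], format = "fastq", qualities = q)
  }
  manifest
}
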