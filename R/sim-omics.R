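#' Simulate a TMT-style protein abundance table
#'
#' Log2 abundances are Gaussian and homoscedastic around protein-specific
#' baselines; a planted subset is shifted up and another down in the coarse
#' group. A configured fraction of the down-shifted proteins (and a smaller
#' background fraction of all other proteins) is flagged in the ground truth
#' as planted fragment targets, to exercise the target/DEP overlap stage.
#'
#' @param config A [sim_config()].
#' @return A list:
#'   * `proteins`: tibble with `protein`, `sample_id`, `group`, `abundance`
#'     (linear scale, positive);
#'   * `truth`: tibble with `protein`, `true_log2fc` (coarse minus fine),
#'     `planted_up`, `planted_down`, `planted_target`.
#' @export
simulate_proteome <- function(config) {
  validate_sim_config(config)
  if (config$protein_count < 10) abort("invalid config: protein_count must be >= 10")
  if (config$n_per_group < 2) abort("invalid config: n_per_group must be >= 2 (t-test undefined)")
  if (config$n_protein_up + config$n_protein_down > config$protein_count) {
    abort("invalid config: planted proteins exceed protein_count")
  }
  withr::with_seed(sim_seed(config, "proteome"), {
    prot <- sprintf("G%04d", seq_len(config$protein_count))
    lfc <- rep(0, config$protein_count)
    up_idx <- seq_len(config$n_protein_up)
    down_idx <- config$n_protein_up + seq_len(config$n_protein_down)
    lfc[up_idx] <- config$protein_log2fc
    lfc[down_idx] <- -config$protein_log2fc
    base <- rnorm(config$protein_count, mean = 8, sd = 1)

    is_target <- logical(config$protein_count)
    is_target[down_idx] <- runif(length(down_idx)) < config$target_fraction_down
    rest <- setdiff(seq_len(config$protein_count), down_idx)
    is_target[rest] <- runif(length(rest)) < config$target_fraction_null

    samples <- tibble(
      sample_id = c(paste0("coarse_", seq_len(config$n_per_group)),
                    paste0("fine_", seq_len(config$n_per_group))),
      group = rep(c("coarse", "fine"), each = config$n_per_group)
    )
    tab <- tidyr::crossing(tibble(protein = prot, base = base, lfc = lfc), samples) %>%
      mutate(
        log2_abund = .data$base +
          ifelse(.data$group == "coarse", .data$lfc / 2, -.data$lfc / 2) +
          rnorm(n(), sd = config$protein_sd),
        abundance = 2^.data$log2_abund
      ) %>%
      select("protein", "sample_id", "group", "abundance") %>%
      arrange(.data$protein, .data$sample_id)

    truth <- tibble(
      protein = prot, true_log2fc = lfc,
      planted_up = seq_along(prot) %in% up_idx,
      planted_down = seq_along(prot) %in% down_idx,
      planted_target = is_target
    )
    list(proteins = tab, truth = truth)
  })
}

#' Simulate a metabolite intensity table with pooled QC samples
#'
#' Intensities are log-normal around metabolite baselines; a planted subset
#' of discriminators is shifted between groups (half up, half down in
#' coarse). Planted discriminators sit in the upper part of the abundance
#' range: Pareto scaling retains a square-root-of-sd magnitude weight, so a
#' discriminator far below average abundance is structurally invisible to a
#' VIP screen no matter how large its fold change — the screen's named
#' hits in real studies are correspondingly well-detected compounds. QC
#' samples emulate repeated injections of a pooled aliquot: each QC column
#' is the across-sample mean profile perturbed by small log-normal
#' technical noise.
#'
#' @param config A [sim_config()].
#' @return A list:
#'   * `metabolites`: tibble with `metabolite`, `sample_id`, `group`
#'     (`"QC"` for pooled QC injections), `intensity`;
#'   * `truth`: tibble with `metabolite`, `planted`, `true_log_shift`.
#' @export
simulate_metabolome <- function(config) {
  validate_sim_config(config)
  if (config$metabolite_count < 5) abort("invalid config: metabolite_count must be >= 5")
  if (config$n_qc < 2) abort("invalid config: n_qc must be >= 2")
  if (config$n_metab_disc > config$metabolite_count) {
    abort("invalid config: n_metab_disc exceeds metabolite_count")
  }
  withr::with_seed(sim_seed(config, "metabolome"), {
    met <- sprintf("M%04d", seq_len(config$metabolite_count))
    shift <- rep(0, config$metabolite_count)
    disc <- seq_len(config$n_metab_disc)
    shift[disc] <- config$metab_log_shift *
      rep_len(c(1, -1), config$n_metab_disc)
    base <- rnorm(config$metabolite_count, mean = 12, sd = 1)
    # discriminators come from the detectable (above-average) abundance range
    base[disc] <- rnorm(config$n_metab_disc, mean = 12.8, sd = 0.5)

    samples <- tibble(
      sample_id = c(paste0("coarse_", seq_len(config$n_per_group)),
                    paste0("fine_", seq_len(config$n_per_group))),
      group = rep(c("coarse", "fine"), each = config$n_per_group)
    )
    tab <- tidyr::crossing(tibble(metabolite = met, base = base, shift = shift),
                           samples) %>%
      mutate(intensity = exp(
        .data$base +
          ifelse(.data$group == "coarse", .data$shift / 2, -.data$shift / 2) +
          rnorm(n(), sd = config$metab_sd)
      )) %>%
      select("metabolite", "sample_id", "group", "intensity")

    pooled <- tab %>%
      group_by(.data$metabolite) %>%
      summarise(pool = mean(.data$intensity), .groups = "drop")
    qc <- tidyr::crossing(pooled,
                          tibble(sample_id = paste0("QC_", seq_len(config$n_qc)))) %>%
      mutate(group = "QC",
             intensity = .data$pool * exp(rnorm(n(), sd = config$qc_sd))) %>%
      select("metabolite", "sample_id", "group", "intensity")

    truth <- tibble(metabolite = met,
                    planted = seq_along(met) %in% disc,
                    true_log_shift = shift)
    list(metabolites = bind_rows(tab, qc) %>% arrange(.data$metabolite, .data$sample_id),
         truth = truth)
  })
}

#' Simulate a qPCR Ct table
#'
#' Reference-gene Ct values are stable across groups; target Ct values are
#' offset so that the group difference in delta-Ct encodes minus log2 of the
#' true fold, plus Gaussian noise. Two assays are available: `"trf"` (the
#' fragment, `trf_fold`-times higher in coarse) and `"trna"` (the intact
#' tRNA, `trna_fold`-times higher in fine).
#'
#' @param config A [sim_config()].
#' @param assay `"trf"` or `"trna"`.
#' @param noise_sd Ct noise sd; defaults to `config$qpcr_sd`.
#' @return A list:
#'   * `qpcr`: tibble with `sample_id`, `group`, `ct_target`, `ct_reference`;
#'   * `truth`: list with the assay's true coarse/fine expression fold.
#' @export
simulate_qpcr <- function(config, assay = c("trf", "trna"), noise_sd = NULL) {
  validate_sim_config(config)
  assay <- match.arg(assay)
  noise_sd <- noise_sd %||% config$qpcr_sd
  # coarse/fine expression fold; trna is higher in fine, hence the inverse
  fold <- switch(assay, trf = config$trf_fold, trna = 1 / config$trna_fold)
  if (fold <= 0) abort("invalid config: true fold must be > 0")
  withr::with_seed(sim_seed(config, "qpcr") + match(assay, c("trf", "trna")), {
    samples <- tibble(
      sample_id = c(paste0("coarse_", seq_len(config$n_per_group)),
                    paste0("fine_", seq_len(config$n_per_group))),
      group = rep(c("coarse", "fine"), each = config$n_per_group)
    )
    base_dct <- 5
    q <- samples %>% mutate(
      ct_reference = rnorm(n(), mean = 20, sd = noise_sd),
      dct = base_dct -
        ifelse(.data$group == "coarse", log2(fold), 0) +
        rnorm(n(), sd = noise_sd),
      ct_target = .data$ct_reference + .data$dct
    ) %>% select("sample_id", "group", "ct_target", "ct_reference")
    list(qpcr = q, truth = list(assay = assay, fold_coarse_over_fine = fold))
  })
}

#' Simulate 3'UTR sequences with planted fragment target sites
#'
#' Generates one synthetic 3'UTR per selected protein gene. UTRs of proteins
#' flagged as planted fragment targets carry an embedded perfect
#' complementary site (the reverse complement of the fragment); other UTRs
#' are random background.
#'
#' @param toy Output of [simulate_genome()] (source of the fragment).
#' @param proteome_truth `truth` tibble from [simulate_proteome()].
#' @param config A [sim_config()].
#' @return A list:
#'   * `utrs`: named character vector (names are protein/gene ids);
#'   * `truth`: tibble with `gene`, `has_site`.
#' @export
simulate_utrs <- function(toy, proteome_truth, config) {
  validate_sim_config(config)
  withr::with_seed(sim_seed(config, "utrs"), {
    n <- min(config$utr_count, nrow(proteome_truth))
    targets <- proteome_truth$protein[proteome_truth$planted_target]
    others <- setdiff(proteome_truth$protein, targets)
    n_t <- min(length(targets), ceiling(n / 2))
    genes <- c(sample(targets, n_t), sample(others, n - n_t))
    site <- revcomp(toy$trf_seq)
    utrs <- setNames(vapply(genes, function(g) {
      u <- random_dna(config$utr_length)
      if (g %in% targets) {
        pos <- sample.int(config$utr_length - nchar(site) + 1L, 1L)
        substr(u, pos, pos + nchar(site) - 1L) <- site
      }
      u
    }, character(1)), genes)
    list(utrs = utrs,
         truth = tibble(gene = genes, has_site = genes %in% targets))
  })
}
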