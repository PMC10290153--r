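#' Assemble a validated pipeline configuration
#'
#' One configuration object drives every stage of the workflow. Unknown
#' keys are rejected so that typos cannot silently fall back to defaults.
#'
#' @param seed Integer seed forwarded to the synthetic generators.
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param window Read-length retention window (closed).
#' @param canonical_window,min_ratio,alpha,min_fold Peak-detection
#'   parameters (see [detect_anomalous_peaks()]).
#' @param duplex A [duplex_params()].
#' @param dep A [dep_cutoffs()].
#' @param vip_cutoff,metab_alpha Metabolite screen gates.
#' @param group_order Group labels, fold numerator first.
#' @param control_group Calibrator group for the 2^-ddCt computation.
#' @param ... Unknown keys: always an error.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            window = c(18L, 41L),
                            canonical_window = c(20L, 24L),
                            min_ratio = 0.25,
                            alpha = 0.05,
                            min_fold = 2,
                            duplex = duplex_params(),
                            dep = dep_cutoffs(),
                            vip_cutoff = 1,
                            metab_alpha = 0.05,
                            group_order = c("coarse", "fine"),
                            control_group = "fine",
                            ...) {
  extra <- list(...)
  if (length(extra)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(names(extra), collapse = ", ")))
  }
  sim$seed <- as.integer(seed)
  validate_sim_config(sim)
  structure(list(seed = as.integer(seed), sim = sim, window = window,
                 canonical_window = canonical_window, min_ratio = min_ratio,
                 alpha = alpha, min_fold = min_fold, duplex = duplex,
                 dep = dep, vip_cutoff = vip_cutoff,
                 metab_alpha = metab_alpha, group_order = group_order,
                 control_group = control_group),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys map to [pipeline_config()] arguments; `sim` is a
#' nested mapping of [sim_config()] arguments, `duplex` of
#' [duplex_params()], `dep` of [dep_cutoffs()]. Unknown keys error.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$duplex)) y$duplex <- do.call(duplex_params, y$duplex)
  if (!is.null(y$dep)) y$dep <- do.call(dep_cutoffs, y$dep)
  do.call(pipeline_config, y)
}

pipeline_stages <- function() {
  c("simulate", "spectrum", "decompose", "annotate", "diff", "targets",
    "proteome", "integrate", "metabolome", "report")
}

stage_requires <- function(stage) {
  switch(stage,
    simulate = character(0),
    spectrum = "samples.tsv",
    decompose = c("samples.tsv", "peaks.tsv"),
    annotate = c("genome.fasta", "loci.tsv", "composition.tsv"),
    diff = c("samples.tsv", "composition.tsv", "qpcr_trf.tsv", "qpcr_trna.tsv"),
    targets = c("composition.tsv", "utrs.fasta"),
    proteome = "proteome.tsv",
    integrate = c("target_genes.txt", "deps.tsv", "utrs.fasta"),
    metabolome = "metabolome.tsv",
    report = c("peaks.tsv", "composition.tsv", "fragments.tsv", "diff.tsv",
               "qpcr_rq.tsv", "overlap.json", "metabolite_screen.tsv"),
    abort(sprintf("unknown stage '%s'", stage))
  )
}

load_sample_reads <- function(outdir, window) {
  manifest <- readr::read_tsv(file.path(outdir, "samples.tsv"),
                              col_types = "ccc")
  reads <- purrr::pmap(manifest, function(sample_id, group, path) {
    load_reads(file.path(outdir, path), sample_id, group)
  }) %>% bind_rows()
  filter_by_length(reads, window[1], window[2])
}

dominant_sequence <- function(outdir) {
  comp <- readr::read_tsv(file.path(outdir, "composition.tsv"),
                          col_types = "ccini")
  comp$sequence[comp$scope == "pooled" & comp$rank == 1][1]
}

stage_run <- function(stage, config, outdir) {
  switch(stage,
    simulate = {
      toy <- simulate_genome(config$sim)
      write_genome_fasta(toy$genome, file.path(outdir, "genome.fasta"))
      write_loci(toy$loci, file.path(outdir, "loci.tsv"))
      rs <- simulate_reads(toy, config$sim)
      manifest <- write_reads_fastq(rs$reads, file.path(outdir, "reads"))
      manifest$path <- file.path("reads", basename(manifest$path))
      readr::write_tsv(manifest, file.path(outdir, "samples.tsv"))
      pr <- simulate_proteome(config$sim)
      readr::write_tsv(pr$proteins, file.path(outdir, "proteome.tsv"))
      mb <- simulate_metabolome(config$sim)
      readr::write_tsv(mb$metabolites, file.path(outdir, "metabolome.tsv"))
      for (assay in c("trf", "trna")) {
        q <- simulate_qpcr(config$sim, assay = assay)
        readr::write_tsv(q$qpcr, file.path(outdir, sprintf("qpcr_%s.tsv", assay)))
      }
      ut <- simulate_utrs(toy, pr$truth, config$sim)
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(ut$utrs),
                                  file.path(outdir, "utrs.fasta"))
      # ground truth: emitted for evaluation only, never read by any stage
      truth <- list(reads = rs$truth, utrs = ut$truth,
                    proteome = pr$truth, metabolome = mb$truth)
      jsonlite::write_json(truth, file.path(outdir, "truth_simulation.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      c("genome.fasta", "loci.tsv", "samples.tsv", "proteome.tsv",
        "metabolome.tsv", "qpcr_trf.tsv", "qpcr_trna.tsv", "utrs.fasta")
    },
    spectrum = {
      reads <- load_sample_reads(outdir, config$window)
      sp <- length_spectrum(reads, config$window)
      readr::write_tsv(sp, file.path(outdir, "spectra.tsv"))
      peaks <- detect_anomalous_peaks(sp,
        canonical_window = config$canonical_window,
        min_ratio = config$min_ratio, alpha = config$alpha,
        min_fold = config$min_fold, group_order = config$group_order)
      readr::write_tsv(peaks, file.path(outdir, "peaks.tsv"))
      c("spectra.tsv", "peaks.tsv")
    },
    decompose = {
      peaks <- readr::read_tsv(file.path(outdir, "peaks.tsv"),
                               col_types = readr::cols())
      if (nrow(peaks) == 0) abort("no anomalous peak to decompose")
      reads <- load_sample_reads(outdir, config$window)
      comp <- decompose_peak(reads, peaks$length[1])
      readr::write_tsv(comp, file.path(outdir, "composition.tsv"))
      "composition.tsv"
    },
    annotate = {
      genome <- read_fasta_seqs(file.path(outdir, "genome.fasta"))
      loci <- read_loci(file.path(outdir, "loci.tsv"))
      frag <- dominant_sequence(outdir)
      ann <- annotate_fragment(frag, genome, loci)
      readr::write_tsv(ann, file.path(outdir, "fragments.tsv"))
      "fragments.tsv"
    },
    diff = {
      reads <- load_sample_reads(outdir, config$window)
      comp <- readr::read_tsv(file.path(outdir, "composition.tsv"),
                              col_types = "ccini")
      targets <- comp %>% filter(.data$scope == "pooled") %>%
        slice_head(n = 4) %>% pull(.data$sequence)
      cm <- build_count_matrix(reads, targets)
      readr::write_tsv(cm, file.path(outdir, "counts.tsv"))
      dr <- group_ttest(cm, group_order = config$group_order)
      readr::write_tsv(dr, file.path(outdir, "diff.tsv"))
      rq <- purrr::map(c("trf", "trna"), function(assay) {
        q <- readr::read_tsv(file.path(outdir, sprintf("qpcr_%s.tsv", assay)),
                             col_types = "ccnn")
        ddct(q, config$control_group) %>% mutate(assay = assay)
      }) %>% bind_rows()
      readr::write_tsv(rq, file.path(outdir, "qpcr_rq.tsv"))
      c("counts.tsv", "diff.tsv", "qpcr_rq.tsv")
    },
    targets = {
      frag <- dominant_sequence(outdir)
      utrs <- read_fasta_seqs(file.path(outdir, "utrs.fasta"))
      sites <- scan_targets(frag, utrs, config$duplex)
      readr::write_tsv(sites, file.path(outdir, "target_sites.tsv"))
      writeLines(target_genes(sites), file.path(outdir, "target_genes.txt"))
      c("target_sites.tsv", "target_genes.txt")
    },
    proteome = {
      pt <- readr::read_tsv(file.path(outdir, "proteome.tsv"),
                            col_types = "cccn")
      deps <- call_deps(pt, config$dep, group_order = config$group_order)
      readr::write_tsv(deps, file.path(outdir, "deps.tsv"))
      "deps.tsv"
    },
    integrate = {
      targ <- readLines(file.path(outdir, "target_genes.txt"))
      deps <- readr::read_tsv(file.path(outdir, "deps.tsv"),
                              col_types = readr::cols())
      universe <- names(read_fasta_seqs(file.path(outdir, "utrs.fasta")))
      down <- intersect(deps$protein[deps$direction == "down"], universe)
      ov <- overlap_targets_deps(targ, down, universe)
      jsonlite::write_json(as.list(ov), file.path(outdir, "overlap.json"),
                           auto_unbox = TRUE, digits = NA)
      "overlap.json"
    },
    metabolome = {
      mt <- readr::read_tsv(file.path(outdir, "metabolome.tsv"),
                            col_types = "cccn")
      mt <- prevalence_filter(mt) %>% normalize_total_intensity()
      sc <- pareto_scale(mt)
      pca <- pca_scores(sc, k = 2)
      readr::write_tsv(
        tibble(sample_id = rownames(pca$scores), group = pca$groups,
               pc1 = pca$scores[, 1], pc2 = pca$scores[, 2]),
        file.path(outdir, "pca_scores.tsv"))
      fit <- plsda_vip(sc, n_components = 2)
      readr::write_tsv(fit$vip, file.path(outdir, "vip.tsv"))
      scr <- screen_metabolites(mt, fit$vip, vip_cutoff = config$vip_cutoff,
                                alpha = config$metab_alpha,
                                group_order = config$group_order)
      readr::write_tsv(scr, file.path(outdir, "metabolite_screen.tsv"))
      c("pca_scores.tsv", "vip.tsv", "metabolite_screen.tsv")
    },
    report = {
      rd <- function(f) readr::read_tsv(file.path(outdir, f),
                                        col_types = readr::cols())
      comp <- rd("composition.tsv")
      frag <- rd("fragments.tsv")
      scr <- rd("metabolite_screen.tsv")
      rep <- list(
        peak_calls = rd("peaks.tsv"),
        dominant_sequence = dominant_sequence(outdir),
        dominant_fraction = comp %>% filter(.data$rank == 1) %>%
          select("scope", "fraction"),
        fragment_classes = frag %>%
          count(.data$fragment_class, .data$reported_label),
        n_genomic_hits = nrow(frag),
        fold_changes = rd("diff.tsv") %>%
          select("sequence", "fold", "p_value"),
        qpcr = rd("qpcr_rq.tsv"),
        overlap = jsonlite::read_json(file.path(outdir, "overlap.json")),
        significant_metabolites = scr %>% filter(.data$significant)
      )
      jsonlite::write_json(rep, file.path(outdir, "report.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE,
                           dataframe = "rows")
      "report.json"
    }
  )
}

#' Run one pipeline stage with manifest-based caching
#'
#' Executes a stage against `outdir`, then records a manifest with the
#' configuration hash and the MD5 of every input and output file. A rerun
#' with identical hashes is a no-op unless `force = TRUE`. Truth files
#' written by the simulate stage (named `truth_*`) are never read by any
#' stage.
#'
#' @param stage One of `simulate`, `spectrum`, `decompose`, `annotate`,
#'   `diff`, `targets`, `proteome`, `integrate`, `metabolome`, `report`.
#' @param config A [pipeline_config()].
#' @param outdir Working directory for stage inputs/outputs.
#' @param force Recompute even when the manifest is up to date.
#' @return Invisibly, the manifest list; `manifest$skipped` says whether
#'   the cached result was reused.
#' @export
run_stage <- function(stage, config, outdir, force = FALSE) {
  stage <- match.arg(stage, pipeline_stages())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  req <- stage_requires(stage)
  missing <- req[!file.exists(file.path(outdir, req))]
  if (length(missing)) {
    upstream <- pipeline_stages()[
      vapply(pipeline_stages(),
             function(s) any(tryCatch(stage_run_outputs(s), error = function(e) "") %in% missing),
             logical(1))]
    abort(sprintf(
      "stage '%s' is missing input(s) %s; run stage '%s' first",
      stage, paste(missing, collapse = ", "),
      if (length(upstream)) upstream[1] else "simulate"))
  }
  cfg_hash <- md5_of(unclass(config))
  in_hash <- as.list(tools::md5sum(file.path(outdir, req)))
  names(in_hash) <- req
  man_path <- file.path(outdir, sprintf("manifest_%s.json", stage))
  if (!force && file.exists(man_path)) {
    prev <- jsonlite::read_json(man_path)
    if (identical(prev$config_hash, cfg_hash) &&
          identical(lapply(prev$input_md5, as.character),
                    lapply(in_hash, as.character)) &&
          all(file.exists(file.path(outdir, unlist(prev$outputs))))) {
      prev$skipped <- TRUE
      return(invisible(prev))
    }
  }
  outputs <- stage_run(stage, config, outdir)
  manifest <- list(stage = stage, config_hash = cfg_hash,
                   input_md5 = in_hash,
                   outputs = as.list(outputs),
                   output_md5 = as.list(tools::md5sum(file.path(outdir, outputs))),
                   skipped = FALSE)
  names(manifest$output_md5) <- outputs
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# static declaration of each stage's outputs, for upstream diagnostics
stage_run_outputs <- function(stage) {
  switch(stage,
    simulate = c("genome.fasta", "loci.tsv", "samples.tsv", "proteome.tsv",
                 "metabolome.tsv", "qpcr_trf.tsv", "qpcr_trna.tsv", "utrs.fasta"),
    spectrum = c("spectra.tsv", "peaks.tsv"),
    decompose = "composition.tsv",
    annotate = "fragments.tsv",
    diff = c("counts.tsv", "diff.tsv", "qpcr_rq.tsv"),
    targets = c("target_sites.tsv", "target_genes.txt"),
    proteome = "deps.tsv",
    integrate = "overlap.json",
    metabolome = c("pca_scores.tsv", "vip.tsv", "metabolite_screen.tsv"),
    report = "report.json"
  )
}

#' Run the full pipeline end to end
#'
#' @inheritParams run_stage
#' @param stages Stages to run, in order; defaults to all.
#' @return Invisibly, a named list of stage manifests.
#' @export
run_pipeline <- function(config, outdir, stages = pipeline_stages(),
                         force = FALSE) {
  out <- lapply(stages, run_stage, config = config, outdir = outdir,
                force = force)
  invisible(setNames(out, stages))
}
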