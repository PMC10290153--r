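#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns per-variable results as a tibble; `glance()` returns a
#' one-row model summary, following the broom convention.
#'
#' @param x A `plsda_vip` or `trf_pca` object.
#' @param ... Unused.
#' @return A tibble.
#' @name trfscan-tidiers
NULL

#' @rdname trfscan-tidiers
#' @export
tidy.plsda_vip <- function(x, ...) {
  x$vip %>% arrange(desc(.data$vip))
}

#' @rdname trfscan-tidiers
#' @export
glance.plsda_vip <- function(x, ...) {
  tibble(n_components = x$n_components,
         r2y = x$r2y,
         n_samples = nrow(x$scores),
         n_variables = nrow(x$vip),
         max_vip = max(x$vip$vip),
         n_vip_gt_1 = sum(x$vip$vip > 1))
}

#' @rdname trfscan-tidiers
#' @export
tidy.trf_pca <- function(x, ...) {
  scores <- as_tibble(x$scores, .name_repair = ~ paste0("pc", seq_along(.x)))
  scores$sample_id <- rownames(x$scores)
  scores$group <- x$groups %||% NA_character_
  scores %>% select("sample_id", "group", dplyr::starts_with("pc"))
}

#' @rdname trfscan-tidiers
#' @export
glance.trf_pca <- function(x, ...) {
  tibble(n_components = ncol(x$scores),
         variance_explained = sum(x$variance_fraction),
         pc1_fraction = x$variance_fraction[1])
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d/group | depth %d reads\n",
              x$seed, x$n_per_group, x$read_depth))
  cat(sprintf("  tRNA gene: %d nt x %d copies; fragment %d nt, fold %.2f (coarse/fine)\n",
              x$trna_gene_length, x$trna_copies, x$fragment_length, x$trf_fold))
  cat(sprintf("  proteome: %d proteins | metabolome: %d metabolites (+%d QC)\n",
              x$protein_count, x$metabolite_count, x$n_qc))
  invisible(x)
}

#' @export
print.plsda_vip <- function(x, ...) {
  cat(sprintf("PLS-DA VIP fit: %d component(s), %d variables, R2Y = %.3f\n",
              x$n_components, nrow(x$vip), x$r2y))
  cat(sprintf("  %d variable(s) with VIP > 1; max VIP = %.2f\n",
              sum(x$vip$vip > 1), max(x$vip$vip)))
  invisible(x)
}
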