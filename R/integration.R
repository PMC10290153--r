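#' Cutoffs for differentially expressed proteins
#'
#' The conventional TMT screen: fold change above `up_fold` or below
#' `down_fold` (nearly symmetric on the log scale: log2 1.20 is about
#' -log2 0.83) together with a t-test p-value below `alpha`.
#'
#' @param up_fold,down_fold Linear fold-change gates.
#' @param alpha Significance gate.
#' @return A list of class `dep_cutoffs`.
#' @export
dep_cutoffs <- function(up_fold = 1.20, down_fold = 0.83, alpha = 0.05) {
  if (!(down_fold < 1 && 1 < up_fold)) abort("need down_fold < 1 < up_fold")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  structure(list(up_fold = up_fold, down_fold = down_fold, alpha = alpha),
            class = "dep_cutoffs")
}

#' Call differentially expressed proteins
#'
#' Computes the linear-scale fold (first group's mean over the second's),
#' tests on log2 abundances with a two-sided t-test, and gates on both fold
#' and p-value.
#'
#' @param proteins Tibble with `protein`, `sample_id`, `group`, `abundance`
#'   (positive, linear scale).
#' @param cutoffs A [dep_cutoffs()].
#' @param group_order Optional group label order (fold numerator first).
#' @param var_equal Pooled-variance (Student) test instead of Welch.
#' @return Tibble with `protein`, group means, `fold`, `t_stat`, `p_value`,
#'   `direction` (`"up"`, `"down"`, `"ns"`).
#' @export
call_deps <- function(proteins, cutoffs = dep_cutoffs(), group_order = NULL,
                      var_equal = FALSE) {
  if (any(proteins$abundance <= 0)) {
    abort("non-positive abundance: cannot log-transform")
  }
  lev <- group_levels(proteins$group, group_order)
  wide <- proteins %>%
    tidyr::pivot_wider(id_cols = "protein", names_from = "sample_id",
                       values_from = "abundance")
  sample_groups <- proteins %>% distinct(.data$sample_id, .data$group)
  m <- as.matrix(wide[, -1])
  g <- factor(sample_groups$group[match(colnames(m), sample_groups$sample_id)],
              levels = lev)
  res <- welch_rows(log2(m), g, var_equal = var_equal)
  lin_a <- rowMeans(m[, g == lev[1], drop = FALSE])
  lin_b <- rowMeans(m[, g == lev[2], drop = FALSE])
  tibble(protein = wide$protein,
         group_a = lev[1], group_b = lev[2],
         mean_a = lin_a, mean_b = lin_b,
         fold = lin_a / lin_b,
         t_stat = res$t_stat, p_value = res$p_value) %>%
    mutate(direction = case_when(
      .data$fold > cutoffs$up_fold & .data$p_value < cutoffs$alpha ~ "up",
      .data$fold < cutoffs$down_fold & .data$p_value < cutoffs$alpha ~ "down",
      TRUE ~ "ns"
    ))
}

#' Overlap predicted targets with down-regulated proteins
#'
#' Intersects the predicted target-gene set with the down-regulated DEP
#' set, reports the overlap as a percentage of the down-regulated DEPs, and
#' attaches the hypergeometric upper-tail enrichment p-value: the
#' probability of drawing at least `n_overlap` targets when sampling
#' `n_down_deps` genes without replacement from a universe containing
#' `n_targets` targets.
#'
#' @param target_genes Character vector of predicted target genes.
#' @param down_deps Character vector of down-regulated proteins.
#' @param universe Character vector: all quantified genes/proteins.
#' @return One-row tibble: `n_targets`, `n_down_deps`, `n_overlap`,
#'   `pct_of_down`, `hypergeom_p`, `universe_size`.
#' @export
#' @examples
#' u <- paste0("g", 1:4757)
#' down <- u[1:1157]
#' targ <- c(u[1:606], u[2000:3000])
#' overlap_targets_deps(targ, down, u)
overlap_targets_deps <- function(target_genes, down_deps, universe) {
  target_genes <- unique(target_genes)
  down_deps <- unique(down_deps)
  universe <- unique(universe)
  out_t <- setdiff(target_genes, universe)
  out_d <- setdiff(down_deps, universe)
  if (length(out_t) || length(out_d)) {
    abort(sprintf("elements outside the universe: %s",
                  paste(head(c(out_t, out_d), 5), collapse = ", ")))
  }
  k <- length(intersect(target_genes, down_deps))
  K <- length(target_genes); n <- length(down_deps); N <- length(universe)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(n_targets = K, n_down_deps = n, n_overlap = k,
         pct_of_down = if (n > 0) 100 * k / n else NA_real_,
         hypergeom_p = p, universe_size = N)
}

#' Over-representation analysis against gene-set collections
#'
#' One-sided hypergeometric test per gene set (equivalent to the one-tailed
#' Fisher exact test), Benjamini-Hochberg adjusted across sets. Sets with
#' no query hit get `p = 1` under the upper-tail convention P(X >= 0) = 1.
#'
#' @param query_genes Character vector of genes of interest.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of all eligible genes.
#' @return Tibble with `set_id`, `k` (hits), `K` (set size within the
#'   universe), `n` (query size), `N` (universe size), `p_value`, `q_value`,
#'   sorted by p then set id.
#' @export
ora <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  query <- intersect(unique(query_genes), universe)
  N <- length(universe); n <- length(query)
  rows <- purrr::imap(gene_sets, function(s, id) {
    s <- intersect(unique(s), universe)
    k <- length(intersect(query, s)); K <- length(s)
    tibble(set_id = id, k = k, K = K, n = n, N = N,
           p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  }) %>% bind_rows()
  rows %>%
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) %>%
    arrange(.data$p_value, .data$set_id)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `id`, `description`,
#' then member genes.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, character(1), 1))
}
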