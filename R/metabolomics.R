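#' Prevalence-filter a metabolite table
#'
#' Keeps a metabolite iff strictly more than half of its measurements are
#' nonzero in at least one biological group. QC samples do not participate
#' in the test but are retained in the output. Missing values are treated
#' as zeros before the filter.
#'
#' @param metabolites Tibble with `metabolite`, `sample_id`, `group`
#'   (`"QC"` marks pooled QC injections), `intensity`.
#' @return Filtered tibble of the same shape.
#' @export
prevalence_filter <- function(metabolites) {
  metabolites <- metabolites %>%
    mutate(intensity = tidyr::replace_na(.data$intensity, 0))
  keep <- metabolites %>%
    filter(.data$group != "QC") %>%
    group_by(.data$metabolite, .data$group) %>%
    summarise(frac = mean(.data$intensity > 0), .groups = "drop") %>%
    group_by(.data$metabolite) %>%
    summarise(keep = any(.data$frac > 0.5), .groups = "drop") %>%
    filter(.data$keep) %>%
    pull(.data$metabolite)
  metabolites %>% filter(.data$metabolite %in% keep)
}

#' Normalise to total peak intensity
#'
#' Divides each sample column by its total intensity and rescales by the
#' median column total, so a uniformly doubled sample is mapped back onto
#' its neighbours exactly.
#'
#' @inheritParams prevalence_filter
#' @return Normalised tibble of the same shape.
#' @export
normalize_total_intensity <- function(metabolites) {
  totals <- metabolites %>%
    group_by(.data$sample_id) %>%
    summarise(total = sum(.data$intensity), .groups = "drop")
  if (any(totals$total == 0)) {
    abort(sprintf("zero total intensity in sample(s): %s",
                  paste(totals$sample_id[totals$total == 0], collapse = ", ")))
  }
  med <- median(totals$total)
  metabolites %>%
    left_join(totals, by = "sample_id") %>%
    mutate(intensity = .data$intensity / .data$total * med) %>%
    select(-"total")
}

#' Pareto-scale a metabolite table into a samples-by-metabolites matrix
#'
#' Per metabolite: subtract the across-sample mean and divide by the square
#' root of the (sample) standard deviation — the scaling conventional in
#' chemometrics, down-weighting high-abundance metabolites less aggressively
#' than unit-variance scaling. Constant metabolites scale to all zeros, with
#' a warning. All samples (including QC) enter the scaling.
#'
#' @inheritParams prevalence_filter
#' @return A numeric matrix (samples x metabolites) with the sample group
#'   labels in `attr(, "groups")`.
#' @export
pareto_scale <- function(metabolites) {
  wide <- metabolites %>%
    tidyr::pivot_wider(id_cols = c("sample_id", "group"),
                       names_from = "metabolite", values_from = "intensity")
  m <- as.matrix(wide[, -(1:2)])
  rownames(m) <- wide$sample_id
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  if (any(s == 0)) {
    warn(sprintf("%d constant metabolite(s) scaled to zero", sum(s == 0)))
  }
  sc <- sweep(m, 2, mu)
  sc <- sweep(sc, 2, ifelse(s > 0, sqrt(s), 1), "/")
  sc[, s == 0] <- 0
  attr(sc, "groups") <- wide$group
  sc
}

#' PCA scores for a scaled metabolite matrix
#'
#' Singular value decomposition of the (already column-centred) matrix,
#' i.e. the eigendecomposition of the sample covariance. The sign of each
#' component is fixed so its largest-magnitude loading is positive.
#'
#' @param scaled Samples-by-metabolites matrix from [pareto_scale()].
#' @param k Number of components.
#' @return A list of class `trf_pca`: `scores` (samples x k), `loadings`
#'   (metabolites x k), `variance_fraction` (length k), `groups`.
#' @export
pca_scores <- function(scaled, k = 2L) {
  # columns are centred, so the rows sum to zero: rank <= n_samples - 1
  r <- max(1L, min(nrow(scaled) - 1L, ncol(scaled)))
  if (k > r) {
    warn(sprintf("k = %d exceeds the rank bound %d; reduced", k, r))
    k <- r
  }
  sv <- svd(scaled)
  d2 <- sv$d^2
  flip <- vapply(seq_len(k), function(a) {
    v <- sv$v[, a]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k, k), 2, flip, "*")
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  rownames(scores) <- rownames(scaled)
  rownames(loadings) <- colnames(scaled)
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = d2[seq_len(k)] / sum(d2),
                 groups = attr(scaled, "groups")),
            class = "trf_pca")
}

#' PLS-DA with variable importance in projection (VIP)
#'
#' Fits a NIPALS partial least squares model with a single centred binary
#' response encoding the two groups (QC samples are dropped), then scores
#' each metabolite with
#' `VIP_j = sqrt(p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a)`,
#' where `SSY_a` is the response variance explained by component `a`.
#' The invariant `mean(VIP^2) = 1` is enforced exactly.
#'
#' @param scaled Samples-by-metabolites matrix from [pareto_scale()].
#' @param groups Group label per row; defaults to `attr(scaled, "groups")`.
#' @param n_components Number of PLS components.
#' @return An object of class `plsda_vip`: tibble `vip` (`metabolite`,
#'   `vip`), `n_components`, `r2y` (cumulative response variance
#'   explained), `weights`, `scores`, `groups`.
#' @export
plsda_vip <- function(scaled, groups = NULL, n_components = 2L) {
  groups <- groups %||% attr(scaled, "groups")
  if (is.null(groups)) abort("group labels are required")
  keep <- groups != "QC"
  X <- scaled[keep, , drop = FALSE]
  g <- groups[keep]
  lev <- unique(g)
  if (length(lev) != 2) abort("exactly two groups are required")
  if (min(table(g)) < 2) abort("each group needs at least 2 samples")
  if (n_components < 1) abort("n_components must be >= 1")
  y <- ifelse(g == lev[1], 1, -1)
  y <- y - mean(y)
  p <- ncol(X)
  A <- min(n_components, nrow(X) - 1L, p)
  W <- matrix(0, p, A); TT <- matrix(0, nrow(X), A)
  ssy <- numeric(A)
  Xa <- X; ya <- y
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) { A <- a - 1L; break }
    w <- w / nw
    t_ <- drop(Xa %*% w)
    tt <- sum(t_^2)
    p_load <- drop(crossprod(Xa, t_)) / tt
    q <- sum(ya * t_) / tt
    ssy[a] <- q^2 * tt
    W[, a] <- w; TT[, a] <- t_
    Xa <- Xa - tcrossprod(t_, p_load)
    ya <- ya - t_ * q
  }
  if (A < 1) abort("no usable PLS component (degenerate predictors)")
  W <- W[, seq_len(A), drop = FALSE]
  ssy <- ssy[seq_len(A)]
  vip2 <- p * drop(W^2 %*% ssy) / sum(ssy)
  vip <- sqrt(vip2 / mean(vip2))          # enforce mean(VIP^2) = 1 exactly
  structure(list(
    vip = tibble(metabolite = colnames(scaled), vip = vip),
    n_components = A,
    r2y = sum(ssy) / sum(y^2),
    weights = W,
    scores = TT[, seq_len(A), drop = FALSE],
    groups = g
  ), class = "plsda_vip")
}

#' Null distribution of the maximum VIP under label permutation
#'
#' Refits the PLS-DA on permuted group labels and records the largest VIP,
#' giving a calibration reference for the VIP > 1 gate.
#'
#' @inheritParams plsda_vip
#' @param n_perm Number of permutations.
#' @return Numeric vector of length `n_perm` (max VIP per permutation).
#' @export
plsda_vip_permute <- function(scaled, groups = NULL, n_components = 2L,
                              n_perm = 100L) {
  groups <- groups %||% attr(scaled, "groups")
  keep <- groups != "QC"
  g <- groups[keep]
  X <- scaled[keep, , drop = FALSE]
  vapply(seq_len(n_perm), function(i) {
    max(plsda_vip(X, sample(g), n_components)$vip$vip)
  }, numeric(1))
}

#' Screen metabolites by VIP then univariate t-test
#'
#' Sequential gate: metabolites with VIP > `vip_cutoff` are carried to a
#' two-sided Student t-test on their (normalised) intensities; those with
#' `p < alpha` are called significant.
#'
#' @param metabolites Normalised metabolite tibble (QC rows ignored).
#' @param vip Tibble with `metabolite`, `vip` (from [plsda_vip()], or its
#'   `tidy()` output).
#' @param vip_cutoff VIP gate (default 1).
#' @param alpha Significance gate.
#' @param group_order Optional group label order (fold numerator first).
#' @return Tibble of VIP-passing metabolites with group means, `fold`,
#'   `vip`, `p_value` and `significant`, sorted by p.
#' @export
screen_metabolites <- function(metabolites, vip, vip_cutoff = 1,
                               alpha = 0.05, group_order = NULL) {
  pass <- vip %>% filter(.data$vip > vip_cutoff)
  bio <- metabolites %>%
    filter(.data$group != "QC", .data$metabolite %in% pass$metabolite)
  if (nrow(bio) == 0) {
    return(tibble(metabolite = character(0), mean_a = numeric(0),
                  mean_b = numeric(0), fold = numeric(0), vip = numeric(0),
                  p_value = numeric(0), significant = logical(0)))
  }
  lev <- group_levels(bio$group, group_order)
  wide <- bio %>%
    tidyr::pivot_wider(id_cols = "metabolite", names_from = "sample_id",
                       values_from = "intensity")
  sample_groups <- bio %>% distinct(.data$sample_id, .data$group)
  m <- as.matrix(wide[, -1])
  g <- factor(sample_groups$group[match(colnames(m), sample_groups$sample_id)],
              levels = lev)
  res <- welch_rows(m, g, var_equal = TRUE)   # Student's t at this stage
  tibble(metabolite = wide$metabolite,
         mean_a = res$mean_a, mean_b = res$mean_b,
         fold = ifelse(res$mean_b > 0, res$mean_a / res$mean_b, NA_real_),
         p_value = res$p_value) %>%
    left_join(pass, by = "metabolite") %>%
    mutate(significant = .data$p_value < alpha) %>%
    select("metabolite", "mean_a", "mean_b", "fold", "vip",
           "p_value", "significant") %>%
    arrange(.data$p_value)
}
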