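make_metab <- function(mat, groups, ids = sprintf("M%02d", seq_len(nrow(mat)))) {
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  tibble::as_tibble(mat, .name_repair = "minimal") %>%
    dplyr::mutate(metabolite = ids) %>%
    tidyr::pivot_longer(-metabolite, names_to = "sample_id",
                        values_to = "intensity") %>%
    dplyr::left_join(tibble::tibble(sample_id = paste0("s", seq_along(groups)),
                                    group = groups), by = "sample_id")
}

test_that("prevalence filter keeps strictly-majority-nonzero metabolites", {
  m <- rbind(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),   # 3/5 in A, 0/5 in B -> kept
             c(1, 1, 0, 0, 0, 1, 1, 0, 0, 0),   # exactly 50% in both -> dropped
             c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0),   # all zero -> dropped
             c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  mt <- make_metab(m, rep(c("A", "B"), each = 5))
  kept <- unique(prevalence_filter(mt)$metabolite)
  expect_setequal(kept, c("M01", "M04"))
})

test_that("QC samples do not influence the prevalence test", {
  m <- rbind(c(1, 1, 0, 0, 1, 1))   # 50% in each group, nonzero QC
  mt <- make_metab(m, c("A", "A", "A", "A", "QC", "QC"))
  expect_equal(nrow(prevalence_filter(mt)), 0)
})

test_that("total-intensity normalisation removes column scale factors exactly", {
  set.seed(1)
  base <- matrix(runif(40, 1, 10), nrow = 10)
  doubled <- cbind(base, base[, 1] * 2)
  mt <- make_metab(doubled, rep("A", 5))
  norm <- normalize_total_intensity(mt)
  wide <- tidyr::pivot_wider(norm, id_cols = "metabolite",
                             names_from = "sample_id",
                             values_from = "intensity")
  expect_equal(wide$s5, wide$s1)
  sums <- norm %>% dplyr::group_by(sample_id) %>%
    dplyr::summarise(s = sum(intensity))
  expect_equal(diff(range(sums$s)), 0)
  mt0 <- make_metab(matrix(0, 2, 2), rep("A", 2))
  expect_error(normalize_total_intensity(mt0), "zero total")
})

test_that("Pareto scaling matches the closed form and guards constants", {
  mt <- make_metab(rbind(c(1, 3), c(5, 5)), c("A", "B"))
  expect_warning(sc <- pareto_scale(mt), "constant")
  expect_equal(unname(sc[, "M01"]), c(-1, 1) / 2^(1 / 4))
  expect_equal(unname(sc[, "M02"]), c(0, 0))
  expect_equal(unname(colMeans(sc)), c(0, 0))
})

test_that("PCA reproduces rank structure and matches prcomp", {
  set.seed(2)
  # rank-1: one direction carries all variance
  v <- rnorm(6); u <- rnorm(4)
  m1 <- outer(u, v)
  m1 <- sweep(m1, 2, colMeans(m1))
  attr(m1, "groups") <- rep("A", 4)
  colnames(m1) <- paste0("m", 1:6); rownames(m1) <- paste0("s", 1:4)
  p1 <- pca_scores(m1, k = 1)
  expect_equal(p1$variance_fraction, 1)

  m <- matrix(rnorm(60), 6, 10)
  m <- sweep(m, 2, colMeans(m))
  colnames(m) <- paste0("m", 1:10); rownames(m) <- paste0("s", 1:6)
  attr(m, "groups") <- rep(c("A", "B"), 3)
  k <- 5   # full rank for 6 centred samples
  p <- pca_scores(m, k = k)
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - m)), 1e-8)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_equal(crossprod(p$loadings), diag(k), tolerance = 1e-10)
  ref <- prcomp(m, center = FALSE)
  expect_equal(abs(p$scores), abs(ref$x[, 1:k]), ignore_attr = TRUE)
  expect_warning(pca_scores(m, k = 6), "rank")
})

test_that("VIP satisfies its normalisation identity on random matrices", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(6:12, 1); p <- sample(5:30, 1)
    m <- matrix(rnorm(n * p), n, p)
    m <- sweep(m, 2, colMeans(m))
    colnames(m) <- paste0("m", seq_len(p)); rownames(m) <- paste0("s", seq_len(n))
    fit <- plsda_vip(m, groups = rep_len(c("A", "B"), n),
                     n_components = sample(1:3, 1))
    expect_equal(mean(fit$vip$vip^2), 1)
    expect_true(all(fit$vip$vip >= 0))
  }
})

test_that("a single noiseless informative variable takes all the VIP mass", {
  p <- 25; n <- 10
  g <- rep(c("A", "B"), each = n / 2)
  m <- matrix(0, n, p)
  m[, 1] <- ifelse(g == "A", 1, -1)
  m[, 2:p] <- matrix(rnorm(n * (p - 1), sd = 1e-8), n)
  m <- sweep(m, 2, colMeans(m))
  colnames(m) <- paste0("m", 1:p); rownames(m) <- paste0("s", 1:n)
  fit <- plsda_vip(m, groups = g, n_components = 1)
  expect_equal(fit$vip$vip[1], sqrt(p), tolerance = 1e-6)
  expect_lt(max(fit$vip$vip[-1]), 1e-4)
})

test_that("one-component VIP equals the closed-form weight expression", {
  set.seed(4)
  n <- 8; p <- 12
  g <- rep(c("A", "B"), each = 4)
  m <- matrix(rnorm(n * p), n, p)
  m <- sweep(m, 2, colMeans(m))
  colnames(m) <- paste0("m", 1:p); rownames(m) <- paste0("s", 1:n)
  fit <- plsda_vip(m, groups = g, n_components = 1)
  y <- ifelse(g == "A", 1, -1); y <- y - mean(y)
  w <- drop(crossprod(m, y)); w <- w / sqrt(sum(w^2))
  expect_equal(fit$vip$vip, unname(sqrt(p) * abs(w)), tolerance = 1e-10)
})

test_that("degenerate group sizes are rejected", {
  m <- matrix(rnorm(30), 5, 6)
  colnames(m) <- paste0("m", 1:6); rownames(m) <- paste0("s", 1:5)
  expect_error(plsda_vip(m, groups = c("A", "B", "B", "B", "B")), "at least 2")
  expect_error(plsda_vip(m, groups = rep("A", 5)), "two groups")
})

test_that("planted group structure separates in score space while QC cluster", {
  cfg <- sim_config(seed = 17, n_per_group = 5, metabolite_count = 60,
                    n_metab_disc = 6)
  mb <- simulate_metabolome(cfg)
  mt <- normalize_total_intensity(prevalence_filter(mb$metabolites))
  sc <- pareto_scale(mt)
  pca <- pca_scores(sc, k = 2)
  d <- as.matrix(dist(pca$scores))
  grp <- pca$groups
  qc_d <- d[grp == "QC", grp == "QC"]
  between <- d[grp == "coarse", grp == "fine"]
  expect_lt(mean(qc_d[upper.tri(qc_d)]), mean(between))
})

test_that("the screen gates on VIP before testing and sorts by p", {
  vip <- tibble::tibble(metabolite = c("M1", "M2", "M3"),
                        vip = c(1.5, 0.9, 1.2))
  set.seed(6)
  m <- rbind(c(10, 11, 10, 5, 5.5, 5),       # strong shift, VIP pass
             c(10, 10, 10, 2, 2, 2),         # stronger shift but VIP fail
             c(7, 7.2, 7.1, 7.0, 7.2, 7.1))  # VIP pass, null
  mt <- make_metab(m, rep(c("A", "B"), each = 3), ids = c("M1", "M2", "M3"))
  scr <- screen_metabolites(mt, vip, group_order = c("A", "B"))
  expect_setequal(scr$metabolite, c("M1", "M3"))   # M2 excluded by VIP gate
  expect_equal(scr$metabolite[1], "M1")
  expect_true(scr$significant[scr$metabolite == "M1"])
  expect_false(scr$significant[scr$metabolite == "M3"])
  expect_true(!is.unsorted(scr$p_value))
})

test_that("permutation nulls keep the max VIP near its reference range", {
  set.seed(9)
  n <- 12; p <- 20
  m <- matrix(rnorm(n * p), n, p)
  m <- sweep(m, 2, colMeans(m))
  colnames(m) <- paste0("m", 1:p); rownames(m) <- paste0("s", 1:n)
  attr(m, "groups") <- rep_len(c("A", "B"), n)
  null_max <- plsda_vip_permute(m, n_perm = 20)
  expect_length(null_max, 20)
  expect_true(all(null_max >= 1))   # the max of scores with mean square 1
})
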