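#' Build a fragment count matrix by exact sequence assignment
#'
#' Counts, per sample, the reads exactly equal to each target sequence —
#' a desk-scale replacement for aligner + featureCounts quantification of
#' short fragments. Library sizes (total retained reads per sample) are
#' carried along for RPM normalisation.
#'
#' @param reads Read tibble (`sample_id`, `group`, `read`), already
#'   length-filtered.
#' @param target_sequences Character vector of unique target sequences.
#' @return Tibble of class `trf_counts` with `sequence`, `sample_id`,
#'   `group`, `count`, `total_retained`.
#' @export
build_count_matrix <- function(reads, target_sequences) {
  if (anyDuplicated(target_sequences)) {
    abort("input error: duplicate target sequences")
  }
  samples <- reads %>%
    count(.data$sample_id, .data$group, name = "total_retained")
  tallied <- reads %>%
    filter(.data$read %in% target_sequences) %>%
    count(.data$sample_id, .data$read, name = "count") %>%
    rename(sequence = "read")
  out <- tidyr::crossing(samples, sequence = target_sequences) %>%
    left_join(tallied, by = c("sample_id", "sequence")) %>%
    mutate(count = tidyr::replace_na(.data$count, 0L)) %>%
    select("sequence", "sample_id", "group", "count", "total_retained") %>%
    arrange(.data$sequence, .data$sample_id)
  class(out) <- c("trf_counts", class(out))
  out
}

#' Test fragment count differences between two groups
#'
#' Normalises counts to RPM (per-sample library size) and applies a
#' two-sided Welch t-test per fragment. The fold is the first group's mean
#' over the second group's mean; when the denominator mean is zero the fold
#' is `Inf` (flagged via `fold_defined = FALSE`). Rows with zero variance
#' and equal means get `p = 1`.
#'
#' @param counts A `trf_counts` tibble from [build_count_matrix()] (or any
#'   tibble with `sequence`, `sample_id`, `group`, `count`,
#'   `total_retained`).
#' @param normalize `"rpm"` (default) or `"none"` (raw counts).
#' @param group_order Optional group label order (fold numerator first).
#' @param var_equal Pooled-variance (Student) test instead of Welch.
#' @return Tibble with `sequence`, group means, `fold`, `fold_defined`,
#'   `t_stat`, `p_value`, sorted by p.
#' @export
group_ttest <- function(counts, normalize = c("rpm", "none"),
                        group_order = NULL, var_equal = FALSE) {
  normalize <- match.arg(normalize)
  lev <- group_levels(counts$group, group_order)
  counts <- counts %>% mutate(
    value = if (normalize == "rpm") {
      ifelse(.data$total_retained > 0,
             .data$count / .data$total_retained * 1e6, 0)
    } else as.numeric(.data$count)
  )
  wide <- counts %>%
    tidyr::pivot_wider(id_cols = "sequence", names_from = "sample_id",
                       values_from = "value")
  sample_groups <- counts %>% distinct(.data$sample_id, .data$group)
  m <- as.matrix(wide[, -1])
  g <- factor(sample_groups$group[match(colnames(m), sample_groups$sample_id)],
              levels = lev)
  res <- welch_rows(m, g, var_equal = var_equal)
  tibble(sequence = wide$sequence,
         group_a = lev[1], group_b = lev[2],
         mean_a = res$mean_a, mean_b = res$mean_b,
         fold = ifelse(res$mean_b > 0, res$mean_a / res$mean_b,
                       ifelse(res$mean_a > 0, Inf, NA_real_)),
         fold_defined = res$mean_b > 0,
         t_stat = res$t_stat, p_value = res$p_value) %>%
    arrange(.data$p_value)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per case group,
#' `ddCt = mean(dCt_case) - mean(dCt_control)` and relative expression
#' `RQ = 2^-ddCt`. The control group's RQ is 1 by construction.
#'
#' @param qpcr Tibble with `sample_id`, `group`, `ct_target`,
#'   `ct_reference`.
#' @param control_group Name of the control (calibrator) group.
#' @return Tibble with `group`, `n`, `mean_dct`, `ddct`, `rq`.
#' @export
#' @examples
#' q <- tibble::tibble(sample_id = paste0("s", 1:4),
#'                     group = c("a", "a", "b", "b"),
#'                     ct_target = c(24, 24, 25, 25),
#'                     ct_reference = c(20, 20, 20, 20))
#' ddct(q, control_group = "b")   # group a: ddCt = -1, RQ = 2
ddct <- function(qpcr, control_group) {
  if (!control_group %in% qpcr$group) {
    abort(sprintf("control group '%s' not present", control_group))
  }
  if (any(!is.finite(qpcr$ct_reference)) || any(!is.finite(qpcr$ct_target))) {
    abort("missing or non-finite Ct values")
  }
  if (any(qpcr$ct_target < 10 | qpcr$ct_target > 40 |
            qpcr$ct_reference < 10 | qpcr$ct_reference > 40)) {
    warn("Ct values outside the typical 10-40 range")
  }
  per_group <- qpcr %>%
    mutate(dct = .data$ct_target - .data$ct_reference) %>%
    group_by(.data$group) %>%
    summarise(n = n(), mean_dct = mean(.data$dct), .groups = "drop")
  ctrl <- per_group$mean_dct[per_group$group == control_group]
  per_group %>%
    mutate(ddct = .data$mean_dct - ctrl, rq = 2^(-.data$ddct)) %>%
    arrange(.data$group != control_group, .data$group)
}
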