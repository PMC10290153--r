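#' Load small-RNA reads from a FASTQ file
#'
#' Reads every record of a (plain or gzip-compressed) FASTQ file into a tidy
#' read table. Reads containing `N` are retained here; filtering happens
#' later and only by length.
#'
#' @param path FASTQ path.
#' @param sample_id Sample identifier attached to every read.
#' @param group Group label attached to every read.
#' @return Tibble with `sample_id`, `group`, `read`.
#' @export
load_reads <- function(path, sample_id, group) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  validate_fastq_structure(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      abort(sprintf("malformed FASTQ in %s: %s", path, conditionMessage(e)))
    }
  )
  tibble(sample_id = sample_id, group = group, read = unname(as.character(x)))
}

# Structural pre-check with a record index: Biostrings' parser tolerates
# some truncations, but the loading contract requires a hard error.
validate_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n == 0) return(invisible(TRUE))
  bad <- function(rec, why) {
    abort(sprintf("malformed FASTQ in %s at record %d: %s", path, rec, why))
  }
  if (n %% 4 != 0) bad(n %/% 4L + 1L, "truncated record")
  rec <- seq_len(n %/% 4L)
  hdr <- lines[(rec - 1L) * 4L + 1L]
  sq <- lines[(rec - 1L) * 4L + 2L]
  sep <- lines[(rec - 1L) * 4L + 3L]
  qual <- lines[(rec - 1L) * 4L + 4L]
  if (any(!startsWith(hdr, "@"))) {
    bad(which(!startsWith(hdr, "@"))[1], "header does not start with '@'")
  }
  if (any(!startsWith(sep, "+"))) {
    bad(which(!startsWith(sep, "+"))[1], "separator does not start with '+'")
  }
  if (any(nchar(sq) != nchar(qual))) {
    bad(which(nchar(sq) != nchar(qual))[1],
        "sequence and quality lengths differ")
  }
  invisible(TRUE)
}

#' Filter reads by length
#'
#' Retains reads whose length lies in the closed window
#' `[min_len, max_len]`. The default window of 18–41 nt is the span over
#' which small-RNA length spectra are analysed.
#'
#' @param reads Read tibble (`sample_id`, `group`, `read`).
#' @param min_len,max_len Closed window bounds in nt.
#' @return Filtered read tibble.
#' @export
filter_by_length <- function(reads, min_len = 18, max_len = 41) {
  if (min_len > max_len) abort("min_len must not exceed max_len")
  reads %>% filter(nchar(.data$read) >= min_len, nchar(.data$read) <= max_len)
}

#' Per-sample read-length spectrum
#'
#' Tallies retained reads by length over every length in the window
#' (including zero counts) and normalises to reads per million retained
#' reads (RPM). Samples with no retained reads get all-zero RPM and are
#' identifiable by `total_retained == 0`.
#'
#' @param reads Read tibble (`sample_id`, `group`, `read`).
#' @param window Closed length window, default `c(18, 41)`.
#' @return Tibble of class `trf_spectrum` with `sample_id`, `group`,
#'   `length`, `count`, `total_retained`, `rpm`.
#' @export
#' @examples
#' rs <- tibble::tibble(sample_id = "s1", group = "a",
#'                      read = c(strrep("A", 22), strrep("C", 22), strrep("G", 32)))
#' length_spectrum(rs, window = c(18, 41))
length_spectrum <- function(reads, window = c(18, 41)) {
  win <- seq(window[1], window[2])
  samples <- reads %>% distinct(.data$sample_id, .data$group)
  grid <- tidyr::crossing(samples, length = win)
  tallied <- reads %>%
    mutate(length = nchar(.data$read)) %>%
    filter(.data$length %in% win) %>%
    count(.data$sample_id, .data$group, .data$length, name = "count")
  out <- grid %>%
    left_join(tallied, by = c("sample_id", "group", "length")) %>%
    mutate(count = tidyr::replace_na(.data$count, 0L)) %>%
    group_by(.data$sample_id) %>%
    mutate(total_retained = sum(.data$count),
           rpm = ifelse(.data$total_retained > 0,
                        .data$count / .data$total_retained * 1e6, 0)) %>%
    ungroup() %>%
    arrange(.data$sample_id, .data$length)
  class(out) <- c("trf_spectrum", class(out))
  out
}

#' Per-length two-sample tests on a set of spectra
#'
#' Welch two-sided t-test of per-sample RPM at every length of the spectrum,
#' with the group fold (first group over second). This is the testing core
#' of [detect_anomalous_peaks()], exposed for calibration studies.
#'
#' @param spectra A `trf_spectrum` tibble covering two groups.
#' @param group_order Optional; the two group labels in reporting order
#'   (first label is the fold numerator). Defaults to order of appearance.
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @return Tibble with `length`, per-group mean RPM, `group_fold`, `t_stat`,
#'   `p_value`.
#' @export
spectrum_length_tests <- function(spectra, group_order = NULL, var_equal = FALSE) {
  lev <- group_levels(spectra$group, group_order)
  wide <- spectra %>%
    select("sample_id", "group", "length", "rpm") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "rpm",
                       id_cols = "length")
  sample_groups <- spectra %>% distinct(.data$sample_id, .data$group)
  m <- as.matrix(wide[, -1])
  g <- sample_groups$group[match(colnames(m), sample_groups$sample_id)]
  g <- factor(g, levels = lev)
  res <- welch_rows(m, g, var_equal = var_equal)
  tibble(length = wide$length,
         mean_rpm_a = res$mean_a, mean_rpm_b = res$mean_b,
         group_a = lev[1], group_b = lev[2],
         group_fold = ifelse(res$mean_b > 0, res$mean_a / res$mean_b,
                             ifelse(res$mean_a > 0, Inf, NA_real_)),
         t_stat = res$t_stat, p_value = res$p_value)
}

#' Detect anomalous read-length peaks between two groups
#'
#' Flags lengths outside the canonical miRNA window that behave like a
#' group-specific sub-peak: the length must be a local maximum of a group's
#' mean RPM spectrum, reach at least `min_ratio` of that group's canonical
#' peak height, and show a significant (two-sided Welch t-test on
#' per-sample RPM, `p < alpha`) group difference of at least `min_fold`
#' in either direction. Rows where both groups have zero variance and
#' equal means are assigned `p = 1` and never called.
#'
#' @param spectra A `trf_spectrum` tibble covering two groups with at least
#'   two samples each.
#' @param canonical_window Closed window of canonical miRNA lengths whose
#'   maximum mean RPM defines the reference peak height; candidates inside
#'   it are skipped.
#' @param min_ratio Minimum candidate height as a fraction of the canonical
#'   peak height (in the same group).
#' @param alpha Per-length significance level.
#' @param min_fold Minimum group fold (either direction).
#' @param p_adjust Multiple-testing adjustment across candidate lengths
#'   (`"none"`, the default, or any [stats::p.adjust()] method).
#' @param group_order Optional group label order (fold numerator first).
#' @return Tibble of peak calls sorted by p-value: `length`, group means,
#'   `group_fold`, `p_value`, `ratio_to_canonical`.
#' @export
detect_anomalous_peaks <- function(spectra,
                                   canonical_window = c(20, 24),
                                   min_ratio = 0.25,
                                   alpha = 0.05,
                                   min_fold = 2,
                                   p_adjust = "none",
                                   group_order = NULL) {
  lev <- group_levels(spectra$group, group_order)
  n_per <- spectra %>% distinct(.data$sample_id, .data$group) %>%
    count(.data$group)
  if (any(n_per$n < 2)) {
    abort("insufficient replication: each group needs >= 2 samples")
  }
  means <- spectra %>%
    group_by(.data$group, .data$length) %>%
    summarise(mean_rpm = mean(.data$rpm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "mean_rpm")
  lens <- means$length
  canon <- vapply(lev, function(g) {
    max(means[[g]][lens >= canonical_window[1] & lens <= canonical_window[2]])
  }, numeric(1))

  is_local_max <- function(y) {
    n <- length(y)
    left <- c(-Inf, y[-n]); right <- c(y[-1], -Inf)
    y >= left & y >= right & (y > left | y > right)
  }
  cand <- rep(FALSE, length(lens))
  for (g in lev) {
    y <- means[[g]]
    ok <- is_local_max(y) & (canon[[g]] > 0) & (y >= min_ratio * canon[[g]])
    cand <- cand | ok
  }
  cand <- cand & (lens < canonical_window[1] | lens > canonical_window[2])
  if (!any(cand)) {
    return(tibble(length = integer(0), group_a = character(0),
                  group_b = character(0), mean_rpm_a = numeric(0),
                  mean_rpm_b = numeric(0), group_fold = numeric(0),
                  p_value = numeric(0), ratio_to_canonical = numeric(0)))
  }
  tests <- spectrum_length_tests(spectra, group_order = lev) %>%
    filter(.data$length %in% lens[cand]) %>%
    mutate(p_value = p.adjust(.data$p_value, method = p_adjust),
           ratio_to_canonical = pmax(.data$mean_rpm_a / max(canon[[lev[1]]], .Machine$double.eps),
                                     .data$mean_rpm_b / max(canon[[lev[2]]], .Machine$double.eps)))
  tests %>%
    filter(.data$p_value < alpha,
           !is.na(.data$group_fold),
           .data$group_fold >= min_fold | .data$group_fold <= 1 / min_fold) %>%
    arrange(.data$p_value) %>%
    select("length", "group_a", "group_b", "mean_rpm_a", "mean_rpm_b",
           "group_fold", "p_value", "ratio_to_canonical")
}

#' Decompose a read-length peak into its constituent sequences
#'
#' Collapses all reads of exactly the given length to unique sequences and
#' reports counts and fractions, per group and pooled. Reads containing `N`
#' are excluded (they cannot be matched to a genome exactly and would
#' inflate the unique-sequence set). Entries are sorted by count
#' descending, ties broken lexicographically; the rank-1 entry is the
#' dominant sequence.
#'
#' @param reads Read tibble (`sample_id`, `group`, `read`).
#' @param length Peak length in nt.
#' @return Tibble with `scope` (group label or `"pooled"`), `sequence`,
#'   `count`, `fraction`, `rank`. Empty (zero rows) if no reads have that
#'   length.
#' @export
decompose_peak <- function(reads, length) {
  at <- reads %>%
    filter(nchar(.data$read) == !!length, !grepl("N", .data$read, fixed = TRUE))
  if (nrow(at) == 0) {
    return(tibble(scope = character(0), sequence = character(0),
                  count = integer(0), fraction = numeric(0), rank = integer(0)))
  }
  one_scope <- function(df, scope) {
    df %>%
      count(.data$read, name = "count") %>%
      rename(sequence = "read") %>%
      arrange(desc(.data$count), .data$sequence) %>%
      mutate(scope = scope, fraction = .data$count / sum(.data$count),
             rank = row_number()) %>%
      select("scope", "sequence", "count", "fraction", "rank")
  }
  per_group <- at %>%
    group_by(.data$group) %>%
    dplyr::group_map(~ one_scope(.x, .y$group)) %>%
    bind_rows()
  bind_rows(per_group, one_scope(at, "pooled"))
}
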