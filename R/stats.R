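#' Significance star label
#'
#' Maps a p-value to the star convention used throughout the figures:
#' `ns` (p > 0.05), `*` (p <= 0.05), `**` (p <= 0.01), `***` (p <= 0.001),
#' `****` (p <= 0.0001). Boundary values take the stronger label, matching
#' the "<=" convention.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of labels.
#' @export
star_label <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = TRUE) |>
    as.character()
}

#' Normality-gated two-group comparison
#'
#' Implements the comparison procedure used for all two-group readouts:
#' normality is assessed with the Shapiro-Wilk test (on the paired
#' differences for paired data, per group otherwise); normal data are
#' compared with a two-tailed t test (paired or unpaired), non-normal data
#' with the Wilcoxon matched-pairs signed-rank test (paired) or the
#' Mann-Whitney test (unpaired). A sample with zero variance is treated as
#' non-normal (the Shapiro-Wilk statistic is undefined for constant data).
#' Rank tests use the exact distribution for n <= 25 without ties and the
#' continuity-corrected normal approximation otherwise.
#'
#' @param a,b numeric samples (n >= 3 each; equal length and aligned
#'   ordering when `paired`).
#' @param paired logical: are the samples paired?
#' @param alpha_normality significance level of the normality gate.
#' @return a `comparison_result`: list with `test_name` (one of
#'   `paired_t`, `wilcoxon_signed_rank`, `unpaired_t`, `mann_whitney`),
#'   `statistic`, `p_value`, `stars`, `n_a`, `n_b`, `paired`,
#'   `normality_p`.
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha_normality = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 observations per group", call. = FALSE)
  if (paired && length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  sw_p <- function(x) {
    if (sd(x) == 0) return(0)  # constant: cannot be treated as Gaussian
    shapiro.test(x)$p.value
  }
  if (paired) {
    d <- a - b
    if (all(d == 0))
      stop("all paired differences are zero: the signed-rank test is ",
           "undefined and no comparison is meaningful", call. = FALSE)
    normal <- sw_p(d) > alpha_normality
    norm_p <- sw_p(d)
  } else {
    pa <- sw_p(a); pb <- sw_p(b)
    normal <- pa > alpha_normality && pb > alpha_normality
    norm_p <- min(pa, pb)
  }
  if (normal) {
    ht <- t.test(a, b, paired = paired, var.equal = FALSE)
    test_name <- if (paired) "paired_t" else "unpaired_t"
  } else {
    n <- max(length(a), length(b))
    use_exact <- n <= 25 && !any(duplicated(c(a, b))) &&
      (!paired || !any(a - b == 0))
    ht <- suppressWarnings(
      wilcox.test(a, b, paired = paired, exact = use_exact, correct = TRUE))
    test_name <- if (paired) "wilcoxon_signed_rank" else "mann_whitney"
  }
  structure(list(test_name = test_name, statistic = unname(ht$statistic),
                 p_value = ht$p.value, stars = star_label(ht$p.value),
                 n_a = length(a), n_b = length(b), paired = paired,
                 normality_p = norm_p),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: stat = %.4g, p = %.4g %s (n = %d/%d%s)\n",
              x$test_name, x$statistic, x$p_value, x$stars, x$n_a, x$n_b,
              if (x$paired) ", paired" else ""))
  invisible(x)
}

#' Compare metrics in a tidy table
#'
#' Convenience wrapper applying [compare_groups()] to a long-format data
#' frame: for every metric, the two levels of `group_col` are compared.
#'
#' @param df data frame.
#' @param value_col column holding the measured value.
#' @param group_col column with exactly two levels to compare.
#' @param metric_col optional column splitting rows into separate
#'   comparisons (one row of output each).
#' @param id_col pairing key; when given, rows are matched on it and the
#'   comparison is paired.
#' @param alpha_normality passed to [compare_groups()].
#' @return data frame with one row per metric: test name, statistic,
#'   p-value and stars.
#' @export
compare_table <- function(df, value_col, group_col, metric_col = NULL,
                          id_col = NULL, alpha_normality = 0.05) {
  pieces <- if (is.null(metric_col)) list(all = df)
            else split(df, df[[metric_col]])
  rows <- lapply(names(pieces), function(nm) {
    d <- pieces[[nm]]
    lv <- unique(d[[group_col]])
    if (length(lv) != 2L)
      stop("`", group_col, "` must have exactly 2 levels, got ",
           length(lv), call. = FALSE)
    d1 <- d[d[[group_col]] == lv[1], ]; d2 <- d[d[[group_col]] == lv[2], ]
    paired <- !is.null(id_col)
    if (paired) {
      ids <- intersect(d1[[id_col]], d2[[id_col]])
      d1 <- d1[match(ids, d1[[id_col]]), ]
      d2 <- d2[match(ids, d2[[id_col]]), ]
    }
    r <- compare_groups(d1[[value_col]], d2[[value_col]], paired = paired,
                        alpha_normality = alpha_normality)
    data.frame(metric = nm, group_a = as.character(lv[1]),
               group_b = as.character(lv[2]),
               mean_a = mean(d1[[value_col]]), mean_b = mean(d2[[value_col]]),
               test = r$test_name, statistic = r$statistic,
               p_value = r$p_value, stars = r$stars,
               n_a = r$n_a, n_b = r$n_b)
  })
  do.call(rbind, rows)
}
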