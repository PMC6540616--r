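#' Per-group mean, SEM and n
#'
#' @param df Data frame of per-cell or per-well measures.
#' @param value,group Column names (strings) of the measure and the
#'   grouping label.
#' @return Tibble with one row per group: `group`, `n`, `mean`, `sem`
#'   (sample SD / sqrt(n); `NA` for a single observation).
#' @examples
#' summarize_groups(data.frame(g = "a", v = 1:3), "v", "g")
#' @export
summarize_groups <- function(df, value, group) {
  stopifnot(value %in% names(df), group %in% names(df))
  df |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sem = if (dplyr::n() > 1) sd(.data[[value]]) / sqrt(dplyr::n())
            else NA_real_,
      .groups = "drop")
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z-tests on mean ranks following a Kruskal-Wallis omnibus test,
#' with the standard tie correction: for groups i, j,
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/ni + 1/nj))` where
#' `Ri` are mean ranks of the pooled sample and `T = sum(t^3 - t)` over
#' tie groups. Two-sided normal p-values; multiplicity adjustment across
#' the pairs via [stats::p.adjust()] (default `"none"`, i.e. Dunn's own
#' z-tests only).
#'
#' @param values Numeric vector of pooled observations.
#' @param groups Group label for each observation.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return Tibble with one row per pair: `group1`, `group2`, `z`, `p`,
#'   `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust = "none") {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups), length(unique(groups)) >= 2)
  n_tot <- length(values)
  r <- rank(values)
  labs <- unique(groups)
  rm <- vapply(labs, function(g) mean(r[groups == g]), numeric(1))
  ns <- vapply(labs, function(g) sum(groups == g), numeric(1))
  ties <- table(r)
  tie_sum <- sum(ties^3 - ties)
  base_var <- n_tot * (n_tot + 1) / 12 - tie_sum / (12 * (n_tot - 1))
  pairs <- utils::combn(labs, 2)
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    (rm[i] - rm[j]) / sqrt(base_var * (1 / ns[i] + 1 / ns[j]))
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
         p_adj = p.adjust(p, method = p_adjust))
}

#' Rank-based group comparison
#'
#' The comparisons used for image and growth measures: two groups are
#' compared with the Mann-Whitney (Wilcoxon rank-sum) test; three or more
#' with the Kruskal-Wallis omnibus test followed by Dunn's pairwise post
#' hoc comparisons ([dunn_test()]). Omnibus and pairwise routines are the
#' standard ones, not re-derived.
#'
#' @param df Data frame of observations.
#' @param value,group Column names (strings).
#' @param design `"auto"` (default; chosen by the number of groups),
#'   `"two_group"` or `"multi_group"`.
#' @param p_adjust Adjustment method for Dunn's pairwise p-values.
#' @return A `group_comparison` list: `test_name`, `omnibus_stat`,
#'   `omnibus_p`, `pairwise` (tibble, or `NULL` for two groups), `groups`
#'   (per-group summary from [summarize_groups()]).
#' @export
compare_groups <- function(df, value, group,
                           design = c("auto", "two_group", "multi_group"),
                           p_adjust = "none") {
  design <- match.arg(design)
  v <- df[[value]]
  g <- as.character(df[[group]])
  counts <- table(g)
  if (any(counts == 0) || length(v) == 0) {
    abort("Empty group.", class = "synquant_bad_group")
  }
  k <- length(counts)
  if (design == "auto") design <- if (k == 2) "two_group" else "multi_group"
  if (design == "two_group") {
    if (k != 2) abort("`two_group` design requires exactly 2 groups.",
                      class = "synquant_bad_group")
    wt <- wilcox.test(v[g == names(counts)[1]], v[g == names(counts)[2]],
                      exact = FALSE)
    out <- list(test_name = "Mann-Whitney",
                omnibus_stat = unname(wt$statistic),
                omnibus_p = wt$p.value, pairwise = NULL)
  } else {
    if (k < 3) abort("`multi_group` design requires at least 3 groups.",
                     class = "synquant_bad_group")
    kw <- kruskal.test(v, factor(g))
    out <- list(test_name = "Kruskal-Wallis + Dunn",
                omnibus_stat = unname(kw$statistic),
                omnibus_p = kw$p.value,
                pairwise = dunn_test(v, g, p_adjust))
  }
  out$groups <- summarize_groups(df, value, group)
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g\n", x$test_name,
              x$omnibus_stat, x$omnibus_p))
  if (!is.null(x$pairwise)) {
    cat("Pairwise (Dunn):\n")
    print(as.data.frame(x$pairwise), digits = 3)
  }
  invisible(x)
}

#' Normality pre-check
#'
#' Shapiro-Wilk test per group; groups that fail (p < alpha) indicate the
#' rank-based tests of [compare_groups()] should be used rather than
#' parametric ones.
#'
#' @inheritParams compare_groups
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `group`, `n`, `p`, `normal`.
#' @export
check_normality <- function(df, value, group, alpha = 0.05) {
  df |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(n = dplyr::n(),
                     p = shapiro.test(.data[[value]])$p.value,
                     .groups = "drop") |>
    dplyr::mutate(normal = .data$p >= alpha)
}
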