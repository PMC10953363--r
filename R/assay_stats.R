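#' Trapezoidal area under a time-course curve
#'
#' Integrates a chemiluminescence (or any) time series by the trapezoidal
#' rule over the recorded interval — the summary used for respiratory-burst
#' readouts recorded at fixed intervals. Thin wrapper around
#' [pracma::trapz()].
#'
#' @param time Numeric vector of time points in minutes, strictly
#'   increasing.
#' @param value Signal values (same length as `time`).
#' @return The area in signal·min.
#' @examples
#' auc_trapezoid(c(0, 50, 100), c(1, 1, 1))  # 100
#' @export
auc_trapezoid <- function(time, value) {
  if (length(time) != length(value) || length(time) < 2) {
    abort("`time` and `value` must have equal length >= 2.",
          class = "polarscope_bad_argument")
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    abort("`time` must be finite and strictly increasing.",
          class = "polarscope_unordered_times")
  }
  pracma::trapz(time, value)
}

#' Per-sample AUC from a tidy time-series table
#'
#' @param data Data frame with time, value and grouping columns.
#' @param time,value,sample_id Column names (defaults `time_min`, `value`,
#'   `sample_id`).
#' @return Tibble (`sample_id`, ..., `auc`), one row per sample (grouping
#'   columns beyond `sample_id`, e.g. `group`, are carried through).
#' @export
auc_by_sample <- function(data, time = "time_min", value = "value",
                          sample_id = "sample_id") {
  miss <- setdiff(c(time, value, sample_id), names(data))
  if (length(miss) > 0) {
    abort(paste0("`data` is missing column(s): ", toString(miss), "."),
          class = "polarscope_bad_argument")
  }
  extra <- intersect("group", names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(sample_id, extra)))) |>
    dplyr::arrange(.data[[time]], .by_group = TRUE) |>
    dplyr::summarise(auc = auc_trapezoid(.data[[time]], .data[[value]]),
                     .groups = "drop")
}

#' Nonparametric group comparison (Kruskal-Wallis + Dunn post hoc)
#'
#' The group-comparison contract used for per-field motility and AUC
#' readouts: an omnibus Kruskal-Wallis rank test (delegated to
#' [stats::kruskal.test()]) followed by Dunn's pairwise z tests on mean
#' ranks with multiplicity adjustment. The Dunn statistics use the standard
#' tie-corrected formula.
#'
#' @param data Data frame with a numeric value column and a group column.
#' @param value,group Column names (defaults `"value"`, `"group"`).
#' @param p_adjust_method Adjustment for the pairwise p-values
#'   (default "holm"; any [stats::p.adjust()] method).
#' @return List of class `group_comparison`: `omnibus` (one-row tibble:
#'   `statistic`, `df`, `p_value`, `method`), `posthoc` (tibble
#'   `group1`, `group2`, `z`, `p_value`, `p_adjusted`, `method`).
#'   `glance()` returns the omnibus row, `tidy()` the post hoc table.
#' @examples
#' d <- data.frame(value = c(1, 2, 3, 8, 9, 10), group = rep(c("a", "b"), each = 3))
#' compare_groups(d)
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           p_adjust_method = "holm") {
  miss <- setdiff(c(value, group), names(data))
  if (length(miss) > 0) {
    abort(paste0("`data` is missing column(s): ", toString(miss), "."),
          class = "polarscope_bad_argument")
  }
  v <- data[[value]]
  g <- factor(data[[group]])
  counts <- table(g)
  if (length(counts) < 2) {
    abort("Need >= 2 groups.", class = "polarscope_bad_argument")
  }
  small <- names(counts)[counts < 3]
  if (length(small) > 0) {
    abort(paste0("Group(s) with < 3 values: ", toString(small), "."),
          class = "polarscope_small_group")
  }
  kw <- stats::kruskal.test(v, g)
  # Dunn's test: z on mean ranks with tie correction
  n <- length(v)
  r <- rank(v)
  mean_ranks <- tapply(r, g, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  levels_g <- levels(g)
  pairs <- utils::combn(levels_g, 2)
  posthoc <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / counts[[a]] + 1 / counts[[b]]))
    z <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    tibble(group1 = a, group2 = b, z = z,
           p_value = 2 * stats::pnorm(-abs(z)))
  })
  posthoc$p_adjusted <- stats::p.adjust(posthoc$p_value, method = p_adjust_method)
  posthoc$method <- "Dunn"
  structure(list(
    omnibus = tibble(statistic = unname(kw$statistic), df = unname(kw$parameter),
                     p_value = kw$p.value, method = "Kruskal-Wallis"),
    posthoc = posthoc
  ), class = "group_comparison")
}

#' @export
glance.group_comparison <- function(x, ...) x$omnibus

#' @export
tidy.group_comparison <- function(x, ...) x$posthoc

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.3g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  print(x$posthoc)
  invisible(x)
}
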