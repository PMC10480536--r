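#' Collapse per-sample screen results to per-target scores
#'
#' QC-failing and failed samples are dropped; the remaining replicate
#' ratios of each target are collapsed to one score (mean by default).
#' Targets left with no passing replicate are excluded with a warning.
#'
#' @param results Screen results as returned by [screen_cohort()]
#'   (columns `sample_id`, `target`, `ratio`, `qc_pass`, `status`; an
#'   optional `class` column is carried through).
#' @param aggregate `"mean"`, `"median"` or `"max"`.
#' @return A tibble with one row per target: `target`, `n_samples`,
#'   `score` (and `class` if present), unranked.
#' @export
aggregate_targets <- function(results, aggregate = c("mean", "median", "max")) {
  aggregate <- match.arg(aggregate)
  check_columns(results, c("target", "ratio", "qc_pass", "status"),
                "screen results")
  passing <- dplyr::filter(results, .data$status == "ok", .data$qc_pass,
                           !is.na(.data$ratio))
  if (nrow(passing) == 0) {
    abort("no QC-passing samples in the cohort; nothing to aggregate.")
  }
  dropped <- setdiff(unique(results$target), unique(passing$target))
  if (length(dropped) > 0) {
    warn(sprintf("target(s) with no passing samples excluded: %s.",
                 paste(dropped, collapse = ", ")))
  }
  fun <- switch(aggregate, mean = mean, median = stats::median, max = max)
  grouping <- if ("class" %in% names(passing)) c("target", "class") else "target"
  out <- dplyr::summarise(
    dplyr::group_by(passing, dplyr::across(dplyr::all_of(grouping))),
    n_samples = dplyr::n(),
    score = fun(.data$ratio),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$target)
}

#' Five-number summary and Tukey fences of a score distribution
#'
#' Quartiles use the linear-interpolation convention
#' (`stats::quantile(type = 7)`); the fences are `q1 - 1.5 * IQR` and
#' `q3 + 1.5 * IQR`, the conventional box-plot whisker/outlier bounds.
#'
#' @param scores Numeric vector (or a data frame with a `score` column).
#' @return A one-row tibble: `n`, `min`, `q1`, `median`, `q3`, `max`,
#'   `iqr`, `lower_fence`, `upper_fence`.
#' @export
summarize_distribution <- function(scores) {
  if (is.data.frame(scores)) {
    check_columns(scores, "score", "score table")
    scores <- scores$score
  }
  scores <- as.numeric(scores)
  if (length(scores) == 0 || any(!is.finite(scores))) {
    abort("`scores` must be a non-empty vector of finite numbers.")
  }
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  tibble(n = length(scores), min = min(scores), q1 = q[1], median = q[2],
         q3 = q[3], max = max(scores), iqr = iqr,
         lower_fence = q[1] - 1.5 * iqr, upper_fence = q[3] + 1.5 * iqr)
}

#' Rank targets by score and call outlier candidates
#'
#' Targets are sorted by descending score, ties broken lexicographically
#' by target name so ranking is deterministic. A target is called an
#' outlier candidate when its score exceeds the upper Tukey fence of the
#' score distribution (or `mean + 3 sd` under the `"zscore"` rule).
#' When a `class` column is present, non-`"protein"` entries (e.g.
#' histone markers) contribute to the fence distribution but are
#' excluded from ranking and candidate calls.
#'
#' @param scores Score table from [aggregate_targets()].
#' @param outlier_rule `"tukey"` (default) or `"zscore"`.
#' @return A tibble of class `telo_ranking`, ranked rows only:
#'   `target`, `n_samples`, `score`, `rank`, `is_outlier`; the
#'   distribution summary (over all scores supplied) is attached as
#'   attribute `"distribution"`.
#' @export
rank_and_call <- function(scores, outlier_rule = c("tukey", "zscore")) {
  outlier_rule <- match.arg(outlier_rule)
  check_columns(scores, c("target", "score"), "score table")
  dist <- summarize_distribution(scores$score)
  ranked <- scores
  if ("class" %in% names(ranked)) {
    ranked <- dplyr::filter(ranked, .data$class == "protein")
  }
  if (nrow(ranked) < 2) {
    abort("ranking requires at least 2 (protein-class) targets.")
  }
  cutoff <- switch(outlier_rule,
    tukey = dist$upper_fence,
    zscore = mean(scores$score) + 3 * stats::sd(scores$score))
  ranked <- dplyr::arrange(ranked, dplyr::desc(.data$score), .data$target)
  ranked$rank <- seq_len(nrow(ranked))
  ranked$is_outlier <- ranked$score > cutoff
  out <- dplyr::relocate(
    ranked, dplyr::any_of(c("target", "n_samples", "score", "rank",
                            "is_outlier")))
  attr(out, "distribution") <- dist
  class(out) <- c("telo_ranking", class(out))
  out
}
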