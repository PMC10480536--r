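# Mutual-nearest-neighbor pairing between two coordinate sets.
# Foci are stably ordered by (x, y, original index) first so that
# nearest-neighbor ties resolve to the lowest index deterministically.
mutual_nn_pairs <- function(ax, ay, bx, by, threshold) {
  if (length(ax) == 0 || length(bx) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  oa <- order(ax, ay)
  ob <- order(bx, by)
  ax <- ax[oa]; ay <- ay[oa]
  bx <- bx[ob]; by <- by[ob]
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  nn_of_a <- apply(d, 1, which.min)  # which.min: first minimum = lowest index
  nn_of_b <- apply(d, 2, which.min)
  i <- seq_along(ax)
  mutual <- nn_of_b[nn_of_a[i]] == i &
    d[cbind(i, nn_of_a[i])] <= threshold
  pairs <- cbind(a = oa[i[mutual]], b = ob[nn_of_a[i[mutual]]])
  pairs
}

match_foci_nucleus <- function(coords, channels, threshold) {
  ch <- purrr::map(channels, function(c) {
    rows <- coords[coords$channel == c, , drop = FALSE]
    list(x = rows$x, y = rows$y, n = nrow(rows))
  })
  counts <- vapply(ch, function(z) z$n, 1L)
  pairs <- mutual_nn_pairs(ch[[1]]$x, ch[[1]]$y, ch[[2]]$x, ch[[2]]$y,
                           threshold)
  if (length(channels) == 2) {
    n_coloc <- nrow(pairs)
  } else {
    # a matched A-B pair extends to a triple iff an unclaimed C focus
    # lies within threshold of the pair midpoint; nearest such focus is
    # claimed, each C focus at most once
    claimed <- rep(FALSE, ch[[3]]$n)
    n_coloc <- 0L
    if (nrow(pairs) > 0 && ch[[3]]$n > 0) {
      mx <- (ch[[1]]$x[pairs[, 1]] + ch[[2]]$x[pairs[, 2]]) / 2
      my <- (ch[[1]]$y[pairs[, 1]] + ch[[2]]$y[pairs[, 2]]) / 2
      for (p in seq_len(nrow(pairs))) {
        dc <- sqrt((ch[[3]]$x - mx[p])^2 + (ch[[3]]$y - my[p])^2)
        dc[claimed] <- Inf
        j <- which.min(dc)
        if (length(j) == 1 && dc[j] <= threshold) {
          claimed[j] <- TRUE
          n_coloc <- n_coloc + 1L
        }
      }
    }
  }
  list(counts = counts, n_coloc = as.integer(n_coloc))
}

#' Match foci across channels per nucleus and count colocalization
#'
#' Pairwise matching is one-to-one mutual nearest neighbor: a focus pair
#' (a, b) is colocalized iff each is the other's nearest cross-channel
#' focus and their distance is at most `threshold` (same units as the
#' coordinates; microscopy images never come with a universal criterion,
#' so the threshold is required explicitly). With three channels, a
#' matched pair extends to a triple iff an unclaimed third-channel focus
#' lies within `threshold` of the pair midpoint. Each focus is used at
#' most once.
#'
#' @param foci Foci table: `nucleus_id`, `channel`, `x`, `y` (one or
#'   many nuclei).
#' @param channels 2 or 3 channel names to query, all present in the
#'   declared channel set of the table.
#' @param threshold Positive matching distance.
#' @param reference Channel whose per-nucleus focus count is the ratio
#'   denominator; defaults to the last queried channel (for TIF-style
#'   ratios, the telomere channel).
#' @return A tibble with one row per nucleus: `nucleus_id`, one
#'   `n_<channel>` count column per queried channel, `n_coloc`,
#'   `ratio` (`n_coloc` / reference count; `NA` when the reference
#'   count is 0), `threshold`.
#' @export
match_foci <- function(foci, channels, threshold,
                       reference = channels[length(channels)]) {
  check_columns(foci, c("nucleus_id", "channel", "x", "y"), "foci table")
  if (length(channels) < 2 || length(channels) > 3) {
    abort("`channels` must name 2 or 3 channels.")
  }
  check_scalar_number(threshold, "threshold",
                      lower = .Machine$double.xmin)
  unknown <- setdiff(channels, unique(foci$channel))
  if (length(unknown) > 0) {
    abort(sprintf("channel(s) absent from the foci table: %s.",
                  paste(unknown, collapse = ", ")))
  }
  if (!reference %in% channels) {
    abort("`reference` must be one of the queried channels.")
  }
  if (any(!is.finite(foci$x)) || any(!is.finite(foci$y))) {
    abort("all coordinates must be finite.")
  }
  nuclei <- unique(foci$nucleus_id)
  rows <- purrr::map(nuclei, function(nid) {
    sub <- foci[foci$nucleus_id == nid, , drop = FALSE]
    m <- match_foci_nucleus(sub, channels, threshold)
    counts <- as.list(m$counts)
    names(counts) <- paste0("n_", channels)
    ref_n <- m$counts[match(reference, channels)]
    dplyr::bind_cols(
      tibble(nucleus_id = nid),
      as_tibble(counts),
      tibble(n_coloc = m$n_coloc,
             ratio = if (ref_n > 0) m$n_coloc / ref_n else NA_real_,
             threshold = threshold)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("telo_coloc", class(out))
  out
}

default_cofoci_bins <- function() {
  tibble(lo = c(0L, 1L, 5L, 9L, 11L), hi = c(0L, 4L, 8L, 10L, Inf),
         label = c("0", "1-4", "5-8", "9-10", ">10"))
}

#' Bin per-nucleus cofoci counts into nucleus fractions
#'
#' Tabulates the fraction of nuclei whose colocalized-focus count falls
#' in each bin; the default bins `0`, `1-4`, `5-8`, `9-10`, `>10` mirror
#' the conventional reporting of per-nucleus cofoci histograms.
#'
#' @param coloc Colocalization results from [match_foci()] (or any data
#'   frame with an `n_coloc` column).
#' @param bins Optional custom bins: a data frame with integer columns
#'   `lo`, `hi` (inclusive, `hi` may be `Inf`) and optional `label`.
#'   Bins must not overlap.
#' @return A tibble of class `telo_cofoci_hist`: `bin`, `lo`, `hi`,
#'   `n_nuclei`, `fraction` (fractions over binned nuclei sum to 1).
#' @export
cofoci_histogram <- function(coloc, bins = NULL) {
  check_columns(coloc, "n_coloc", "colocalization results")
  if (nrow(coloc) == 0) abort("need at least one nucleus.")
  if (is.null(bins)) bins <- default_cofoci_bins()
  check_columns(bins, c("lo", "hi"), "bins")
  if (any(bins$hi < bins$lo)) abort("each bin needs lo <= hi.")
  o <- order(bins$lo)
  bins <- bins[o, , drop = FALSE]
  if (nrow(bins) > 1 && any(bins$lo[-1] <= bins$hi[-nrow(bins)])) {
    abort("custom bins overlap.")
  }
  if (!"label" %in% names(bins)) {
    bins$label <- ifelse(is.infinite(bins$hi), paste0(">", bins$lo - 1),
                         ifelse(bins$lo == bins$hi, as.character(bins$lo),
                                paste0(bins$lo, "-", bins$hi)))
  }
  counts <- vapply(seq_len(nrow(bins)), function(i) {
    sum(coloc$n_coloc >= bins$lo[i] & coloc$n_coloc <= bins$hi[i])
  }, 1L)
  out <- tibble(bin = bins$label, lo = bins$lo, hi = bins$hi,
                n_nuclei = counts, fraction = counts / sum(counts))
  class(out) <- c("telo_cofoci_hist", class(out))
  out
}

#' Chi-squared test for two positive-cell fractions
#'
#' Standard 2x2 chi-squared comparison of positive counts between two
#' conditions (e.g. fraction of nuclei with telomere cofoci in ALT vs
#' non-ALT cells); no continuity correction by default, Yates correction
#' available.
#'
#' @param n_positive_a,n_a Positives and total in condition A.
#' @param n_positive_b,n_b Positives and total in condition B.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A `telo_test` with the chi-squared statistic, df = 1 and
#'   p-value.
#' @examples
#' positive_fraction_test(90, 100, 40, 100)   # chi2 = 54.95, p < 0.001
#' @export
positive_fraction_test <- function(n_positive_a, n_a, n_positive_b, n_b,
                                   correct = FALSE) {
  for (v in list(n_positive_a, n_a, n_positive_b, n_b)) {
    check_scalar_number(v, "counts", lower = 0, integerish = TRUE)
  }
  if (n_positive_a > n_a || n_positive_b > n_b) {
    abort("positives cannot exceed totals.")
  }
  tab <- matrix(c(n_positive_a, n_a - n_positive_a,
                  n_positive_b, n_b - n_positive_b),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("a margin of the 2x2 table is zero; the test is undefined.")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  new_telo_test("2x2 chi-squared test", statistic = ht$statistic,
                p_value = ht$p.value, df = 1,
                prop_a = n_positive_a / n_a, prop_b = n_positive_b / n_b)
}

#' Summarize per-nucleus colocalization ratios by group and compare
#'
#' Pools per-nucleus ratios (e.g. TIF per telomere, APB per telomere)
#' within each group, reports the group means, and compares groups with
#' a Welch t test (2 groups) or one-way ANOVA (3 or more).
#'
#' @param coloc_by_group Data frame with columns `group` and `ratio`
#'   (one row per nucleus), e.g. [match_foci()] output with a `group`
#'   column appended.
#' @param reference_col Optional name of the reference-channel count
#'   column (e.g. `"n_TEL"`); when given, a pooled per-group ratio
#'   `sum(n_coloc) / sum(reference)` is reported alongside the
#'   per-nucleus-then-average default.
#' @return A list with `summary` (per-group tibble: `group`, `n_nuclei`,
#'   `mean_ratio`, `sd_ratio`, and `pooled_ratio` when requested) and
#'   `comparison` (a `telo_test`).
#' @export
group_ratio_summary <- function(coloc_by_group, reference_col = NULL) {
  check_columns(coloc_by_group, c("group", "ratio"), "grouped results")
  data <- dplyr::filter(coloc_by_group, !is.na(.data$ratio))
  groups <- split(data$ratio, data$group)
  if (length(groups) < 2) {
    abort("need at least 2 groups to compare.")
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    abort("each group needs at least 2 nuclei.")
  }
  summary <- dplyr::summarise(
    dplyr::group_by(data, .data$group),
    n_nuclei = dplyr::n(),
    mean_ratio = mean(.data$ratio),
    sd_ratio = stats::sd(.data$ratio),
    .groups = "drop"
  )
  if (!is.null(reference_col)) {
    check_columns(data, c("n_coloc", reference_col), "grouped results")
    pooled <- dplyr::summarise(
      dplyr::group_by(data, .data$group),
      pooled_ratio = sum(.data$n_coloc) / sum(.data[[reference_col]]),
      .groups = "drop"
    )
    summary <- dplyr::left_join(summary, pooled, by = "group")
  }
  comparison <- if (length(groups) == 2) {
    compare_means(groups[[1]], groups[[2]])
  } else {
    anova_groups(groups)
  }
  list(summary = summary, comparison = comparison)
}
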