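#' qPCR relative telomere length (T/S) from Ct records
#'
#' Implements the standard relative-quantity transform of monochrome
#' multiplex qPCR telomere assays: for each sample,
#' `dCt = Ct(telomere) - Ct(albumin)` and `T/S = 2^-dCt`, a
#' dimensionless relative telomere length (albumin is the single-copy
#' internal control). `T/S` is 1 when the two Ct values coincide,
#' doubles for each cycle the telomere product comes up earlier, and is
#' invariant under shifting both Ct values by a constant.
#'
#' @param ct_table Data frame with columns `sample_id`, `group`,
#'   `ct_tel`, `ct_alb` (cycles).
#' @return The input as a tibble with appended columns `delta_ct` and
#'   `t_s`. Ct values outside the typical (0, 45) cycle range are
#'   flagged in a logical `ct_out_of_range` column, not rejected.
#' @examples
#' compute_ts(data.frame(sample_id = "s1", group = "WT",
#'                       ct_tel = 18, ct_alb = 20))   # T/S = 4
#' @export
compute_ts <- function(ct_table) {
  check_columns(ct_table, c("sample_id", "group", "ct_tel", "ct_alb"),
                "Ct table")
  if (any(!is.finite(ct_table$ct_tel)) || any(!is.finite(ct_table$ct_alb))) {
    abort("all Ct values must be finite.")
  }
  out <- as_tibble(ct_table)
  out$delta_ct <- out$ct_tel - out$ct_alb
  out$t_s <- 2^(-out$delta_ct)
  out$ct_out_of_range <- out$ct_tel <= 0 | out$ct_tel >= 45 |
    out$ct_alb <= 0 | out$ct_alb >= 45
  out
}

map_alternative <- function(alternative) {
  switch(alternative,
         a_greater = "greater", a_less = "less", two_sided = "two.sided")
}

new_telo_test <- function(method, statistic, p_value, alternative = NA_character_,
                          ...) {
  structure(
    list(method = method, statistic = unname(statistic),
         p_value = unname(p_value), alternative = alternative, ...),
    class = "telo_test"
  )
}

#' @export
print.telo_test <- function(x, ...) {
  cat(sprintf("<telo_test> %s\n", x$method))
  cat(sprintf("  statistic = %g, p = %g", x$statistic, x$p_value))
  if (!is.na(x$alternative)) cat(sprintf(" (%s)", x$alternative))
  cat("\n")
  invisible(x)
}

# Exact Wilcoxon rank-sum p by enumeration over all C(n, n_a) rank splits,
# midranks for ties. Statistic reported is Mann-Whitney U of group a.
wilcoxon_exact <- function(values_a, values_b, alternative) {
  n_a <- length(values_a)
  n <- n_a + length(values_b)
  r <- rank(c(values_a, values_b))
  w_obs <- sum(r[seq_len(n_a)])
  splits <- utils::combn(n, n_a)
  w_all <- colSums(matrix(r[splits], nrow = n_a))
  eps <- 1e-9
  p <- switch(alternative,
    a_greater = mean(w_all >= w_obs - eps),
    a_less = mean(w_all <= w_obs + eps),
    two_sided = {
      mu <- n_a * (n + 1) / 2
      mean(abs(w_all - mu) >= abs(w_obs - mu) - eps)
    })
  list(u = w_obs - n_a * (n_a + 1) / 2, p = p)
}

# Normal approximation with midrank tie correction and continuity
# correction, as conventional for large samples.
wilcoxon_approx <- function(values_a, values_b, alternative) {
  n_a <- length(values_a)
  n_b <- length(values_b)
  n <- n_a + n_b
  r <- rank(c(values_a, values_b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  ties <- table(r)
  sigma2 <- (n_a * n_b / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- u - mu
  correction <- switch(alternative,
                       a_greater = 0.5, a_less = -0.5,
                       two_sided = sign(z) * 0.5)
  z <- (z - correction) / sqrt(sigma2)
  p <- switch(alternative,
    a_greater = stats::pnorm(z, lower.tail = FALSE),
    a_less = stats::pnorm(z),
    two_sided = 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE), 0.5))
  list(u = u, p = p)
}

#' Compare two relative-length distributions (Wilcoxon rank-sum)
#'
#' The Wilcoxon rank-sum (Mann-Whitney) test used to compare relative
#' telomere-length distributions between groups. For combined sample
#' size up to `exact_threshold` the p-value is computed by exact
#' enumeration over all assignments of the (mid)ranks to group A;
#' beyond that, the normal approximation with tie and continuity
#' correction is used.
#'
#' @param values_a,values_b Numeric vectors, each non-empty; ties
#'   allowed.
#' @param alternative `"two_sided"`, `"a_greater"` (A stochastically
#'   larger) or `"a_less"`.
#' @param exact_threshold Combined sample size at or below which exact
#'   enumeration is used (default 10).
#' @return A `telo_test` object with `statistic` (Mann-Whitney U of
#'   group A), `p_value`, `method`, `alternative`, `n_a`, `n_b`; see
#'   [tidy.telo_test()].
#' @examples
#' compare_length_distributions(c(4, 5, 6), c(1, 2, 3), "a_greater")  # p = 0.05
#' @export
compare_length_distributions <- function(values_a, values_b,
                                         alternative = c("two_sided",
                                                         "a_greater",
                                                         "a_less"),
                                         exact_threshold = 10L) {
  alternative <- match.arg(alternative)
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both groups must contain at least one value.")
  }
  if (any(!is.finite(c(values_a, values_b)))) {
    abort("all values must be finite.")
  }
  n <- length(values_a) + length(values_b)
  if (n <= exact_threshold) {
    res <- wilcoxon_exact(values_a, values_b, alternative)
    method <- "Wilcoxon rank-sum, exact enumeration"
  } else {
    res <- wilcoxon_approx(values_a, values_b, alternative)
    method <- "Wilcoxon rank-sum, normal approximation"
  }
  new_telo_test(method, statistic = res$u, p_value = res$p,
                alternative = alternative,
                n_a = length(values_a), n_b = length(values_b))
}

#' Welch two-sample t test on group values
#'
#' @param values_a,values_b Numeric vectors with at least 2 values each.
#' @return A `telo_test` with the t statistic, two-sided p-value and
#'   Welch degrees of freedom.
#' @export
compare_means <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values for a t test.")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    # degenerate limits of the Welch statistic for constant groups:
    # equal means -> t = 0, p = 1; unequal -> |t| -> Inf, p -> 0
    diff <- mean(values_a) - mean(values_b)
    return(new_telo_test("Welch two-sample t test",
                         statistic = if (diff == 0) 0 else sign(diff) * Inf,
                         p_value = if (diff == 0) 1 else 0,
                         alternative = "two_sided",
                         df = length(values_a) + length(values_b) - 2,
                         mean_a = mean(values_a), mean_b = mean(values_b)))
  }
  ht <- stats::t.test(values_a, values_b)
  new_telo_test("Welch two-sample t test", statistic = ht$statistic,
                p_value = ht$p.value, alternative = "two_sided",
                df = unname(ht$parameter),
                mean_a = mean(values_a), mean_b = mean(values_b))
}

#' One-way fixed-effects ANOVA across 2 or more groups
#'
#' @param groups Named or unnamed list of numeric vectors (>= 2 values
#'   each).
#' @return A `telo_test` with the F statistic and p-value.
#' @export
anova_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("`groups` must be a list of at least 2 numeric vectors.")
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    abort("each group needs at least 2 values.")
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  within_var <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  if (within_var == 0) {
    means_equal <- length(unique(vapply(groups, mean, 1.0))) == 1L
    return(new_telo_test("one-way ANOVA",
                         statistic = if (means_equal) 0 else Inf,
                         p_value = if (means_equal) 1 else 0,
                         df1 = length(groups) - 1,
                         df2 = length(values) - length(groups)))
  }
  ht <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  new_telo_test("one-way ANOVA", statistic = ht$statistic,
                p_value = ht$p.value,
                df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]))
}
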