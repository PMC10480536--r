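#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a teloscreen test object
#'
#' @param x A `telo_test` as returned by
#'   [compare_length_distributions()], [compare_means()],
#'   [anova_groups()] or [positive_fraction_test()].
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `p_value`, `method`,
#'   `alternative`, and any extra scalar fields the test carries
#'   (group sizes, degrees of freedom, means, proportions).
#' @method tidy telo_test
#' @export
tidy.telo_test <- function(x, ...) {
  extras <- x[setdiff(names(x), c("method", "statistic", "p_value",
                                  "alternative"))]
  extras <- extras[vapply(extras, function(v) is.numeric(v) &&
                            length(v) == 1L, TRUE)]
  dplyr::bind_cols(
    tibble(statistic = x$statistic, p_value = x$p_value,
           method = x$method, alternative = x$alternative),
    as_tibble(extras)
  )
}

#' @rdname tidy.telo_test
#' @method glance telo_test
#' @export
glance.telo_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, method = x$method)
}

#' Tidy a ranked target table
#'
#' @param x A `telo_ranking` from [rank_and_call()].
#' @param ... Unused.
#' @return The ranking as a plain tibble.
#' @method tidy telo_ranking
#' @export
tidy.telo_ranking <- function(x, ...) {
  out <- x
  attr(out, "distribution") <- NULL
  class(out) <- setdiff(class(out), "telo_ranking")
  as_tibble(out)
}

#' @rdname tidy.telo_ranking
#' @return For `glance()`: the one-row cohort distribution summary
#'   (five-number summary and Tukey fences) plus the number of outlier
#'   candidates.
#' @method glance telo_ranking
#' @export
glance.telo_ranking <- function(x, ...) {
  dist <- attr(x, "distribution")
  dist$n_outliers <- sum(x$is_outlier)
  dist$top_target <- x$target[x$rank == 1]
  dist
}
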