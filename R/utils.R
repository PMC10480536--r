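#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# One reproducible sub-stream per unit of work (sample, nucleus, stage),
# derived from the master seed so parallel generation stays deterministic.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483647)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  if (integerish && x != floor(x)) {
    abort(sprintf("`%s` must be a whole number, got %s.", name, x))
  }
  invisible(x)
}

check_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

#' Write a tibble as tab-separated values
#'
#' Thin wrapper around [readr::write_tsv()] used for all of the package's
#' on-disk tables (manifests, screen results, Ct tables, foci tables) so
#' that every table round-trips through one schema.
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_telo_tsv <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(data)
}

#' Read a tab-separated table written by teloscreen
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_telo_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
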