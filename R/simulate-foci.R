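#' Configuration for simulated multi-channel nuclear foci
#'
#' Emulates per-nucleus fluorescence foci coordinates in two or three
#' channels (e.g. a telomere channel plus a DNA-damage or PML channel).
#' A `colocalized_fraction` of each nucleus's foci are generated from
#' shared anchor points: every channel receives one focus at the anchor
#' plus independent per-axis `Normal(0, jitter_sd)` displacement, so at
#' `jitter_sd = 0` colocalized foci coincide exactly. Remaining foci are
#' uniform over the square field.
#'
#' @param n_nuclei Positive integer.
#' @param channels Character vector of 2 or 3 channel names.
#' @param foci_per_channel Integer, or named integer vector (one count
#'   per channel), or a function `f(n_nuclei)` returning per-nucleus
#'   counts (applied per channel).
#' @param colocalized_fraction Real in `[0, 1]`; the planted colocalized
#'   count per nucleus is `floor(colocalized_fraction * min(channel
#'   counts))`.
#' @param field_size Positive real; side length of the square field, in
#'   arbitrary length units shared by all coordinates and thresholds.
#' @param jitter_sd Nonnegative real, same units as `field_size`.
#' @param seed Integer master seed; each nucleus has its own derived
#'   stream.
#' @return An object of class `foci_sim_config`.
#' @export
foci_sim_config <- function(n_nuclei, channels = c("TEL", "DAMAGE"),
                            foci_per_channel = 10L,
                            colocalized_fraction = 0.3,
                            field_size = 10, jitter_sd = 0.05, seed = 1L) {
  check_scalar_number(n_nuclei, "n_nuclei", lower = 1, integerish = TRUE)
  if (!is.character(channels) || length(channels) < 2L ||
      length(channels) > 3L || anyDuplicated(channels)) {
    abort("`channels` must be 2 or 3 distinct channel names.")
  }
  check_scalar_number(colocalized_fraction, "colocalized_fraction", 0, 1)
  check_scalar_number(field_size, "field_size", lower = .Machine$double.eps)
  check_scalar_number(jitter_sd, "jitter_sd", lower = 0)
  check_scalar_number(seed, "seed", integerish = TRUE)
  if (is.numeric(foci_per_channel)) {
    if (is.null(names(foci_per_channel))) {
      foci_per_channel <- stats::setNames(
        rep(as.integer(foci_per_channel[1]), length(channels)), channels)
    } else {
      if (!setequal(names(foci_per_channel), channels)) {
        abort("named `foci_per_channel` must name exactly the channels.")
      }
      foci_per_channel <- stats::setNames(
        as.integer(foci_per_channel[channels]), channels)
    }
    if (any(foci_per_channel < 0)) abort("foci counts must be nonnegative.")
  } else if (!is.function(foci_per_channel)) {
    abort("`foci_per_channel` must be an integer, named integers, or a function.")
  }
  structure(
    list(n_nuclei = as.integer(n_nuclei), channels = channels,
         foci_per_channel = foci_per_channel,
         colocalized_fraction = colocalized_fraction,
         field_size = field_size, jitter_sd = jitter_sd,
         seed = as.integer(seed)),
    class = "foci_sim_config"
  )
}

#' Simulate per-nucleus foci coordinate tables with planted colocalization
#'
#' @param config A [foci_sim_config()].
#' @return A tibble of foci rows `nucleus_id`, `channel`, `x`, `y`, with
#'   attribute `"truth"`: a tibble of `nucleus_id` and the planted
#'   colocalized anchor count `n_coloc_true`.
#' @examples
#' f <- generate_foci(foci_sim_config(5, jitter_sd = 0, seed = 2))
#' attr(f, "truth")
#' @export
generate_foci <- function(config) {
  stopifnot(inherits(config, "foci_sim_config"))
  per_channel_counts <- function(nucleus_idx) {
    if (is.function(config$foci_per_channel)) {
      stats::setNames(
        vapply(config$channels,
               function(ch) as.integer(config$foci_per_channel(1L)), 1L),
        config$channels)
    } else {
      config$foci_per_channel
    }
  }

  rows <- vector("list", config$n_nuclei)
  truth <- integer(config$n_nuclei)
  for (i in seq_len(config$n_nuclei)) {
    local_seed(derive_seed(config$seed, i), {
      counts <- per_channel_counts(i)
      n_col <- as.integer(floor(config$colocalized_fraction * min(counts)))
      truth[i] <- n_col
      anchor_x <- stats::runif(n_col, 0, config$field_size)
      anchor_y <- stats::runif(n_col, 0, config$field_size)
      chans <- purrr::map(config$channels, function(ch) {
        n_ch <- counts[[ch]]
        n_free <- n_ch - n_col
        x <- c(anchor_x + stats::rnorm(n_col, 0, config$jitter_sd),
               stats::runif(n_free, 0, config$field_size))
        y <- c(anchor_y + stats::rnorm(n_col, 0, config$jitter_sd),
               stats::runif(n_free, 0, config$field_size))
        tibble(nucleus_id = sprintf("nuc%03d", i), channel = ch,
               x = x, y = y)
      })
      rows[[i]] <- dplyr::bind_rows(chans)
    })
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- tibble(nucleus_id = sprintf("nuc%03d",
                                                    seq_len(config$n_nuclei)),
                               n_coloc_true = truth)
  out
}
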