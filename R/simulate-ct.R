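#' Simulate a qPCR Ct table with known group effects
#'
#' Emulates monochrome multiplex qPCR input for relative telomere length:
#' per sample, an albumin (single-copy control) Ct drawn as
#' `base_ct + Normal(0, noise_sd)` and a telomere Ct equal to the albumin
#' Ct plus the group's dCt offset plus independent `Normal(0, noise_sd)`
#' noise. The expected T/S of a group is therefore `2^-offset` exactly at
#' `noise_sd = 0`; with noise, sample T/S is lognormal around that value.
#'
#' @param n_per_group Positive integer; samples per group.
#' @param groups Named numeric vector mapping group name to its dCt
#'   offset (`Ct_telomere - Ct_albumin` shift; negative offsets mean
#'   longer telomeres). Must be non-empty.
#' @param noise_sd Nonnegative real; Gaussian Ct noise, in cycles,
#'   applied independently to each Ct value.
#' @param base_ct Real; mean albumin Ct in cycles.
#' @param seed Integer RNG seed.
#' @return A tibble of Ct records: `sample_id`, `group`, `ct_tel`,
#'   `ct_alb`, with attribute `"truth"` giving the expected noise-free
#'   T/S (`2^-offset`) per group.
#' @examples
#' generate_ct_table(4, c(WT = 0, KO = -1), noise_sd = 0, seed = 1)
#' @export
generate_ct_table <- function(n_per_group, groups, noise_sd = 0.25,
                              base_ct = 20, seed = 1L) {
  check_scalar_number(n_per_group, "n_per_group", lower = 1,
                      integerish = TRUE)
  if (length(groups) == 0 || is.null(names(groups)) ||
      any(!nzchar(names(groups)))) {
    abort("`groups` must be a non-empty named numeric vector of dCt offsets.")
  }
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(base_ct, "base_ct")
  local_seed(seed, {
    records <- purrr::imap(groups, function(offset, grp) {
      ct_alb <- base_ct + stats::rnorm(n_per_group, 0, noise_sd)
      ct_tel <- ct_alb + offset + stats::rnorm(n_per_group, 0, noise_sd)
      tibble(sample_id = sprintf("%s_%02d", grp, seq_len(n_per_group)),
             group = grp, ct_tel = ct_tel, ct_alb = ct_alb)
    })
    out <- dplyr::bind_rows(records)
    attr(out, "truth") <- tibble(group = names(groups),
                                 offset = unname(groups),
                                 expected_ts = 2^(-unname(groups)))
    out
  })
}
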