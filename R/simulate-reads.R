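#' Configuration for a simulated read set with planted repeat content
#'
#' Describes one FASTQ read set whose telomeric-repeat read fraction is
#' known exactly: `planted_fraction` of the reads carry the full motif
#' (unit repeated `copies` times) at a uniformly chosen offset, the rest
#' are uniform random bases rejection-sampled until motif-free on both
#' strands. In `exact_count` mode (the default) exactly
#' `floor(planted_fraction * n_reads)` reads are planted, making the
#' downstream screened ratio an exact, not statistical, ground truth;
#' `bernoulli` mode plants each read independently with probability
#' `planted_fraction`.
#'
#' @param n_reads Positive integer; number of reads.
#' @param read_length Positive integer; read length in bases. Must be at
#'   least `copies * nchar(repeat_unit)` whenever planting is requested.
#' @param planted_fraction Real in `[0, 1]`; fraction of motif-bearing
#'   reads.
#' @param planting_mode `"exact_count"` or `"bernoulli"`.
#' @param repeat_unit,copies Repeat unit and tandem copy number of the
#'   planted motif (defaults: `TTAGGG` x 6, the 36-nt telomeric probe).
#' @param strand_mix Real in `[0, 1]`; fraction of planted reads that
#'   carry the reverse-complement motif (C-strand) instead of the
#'   forward motif.
#' @param seed Integer RNG seed; the whole read set is a pure function
#'   of the configuration.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads, read_length, planted_fraction,
                            planting_mode = c("exact_count", "bernoulli"),
                            repeat_unit = "TTAGGG", copies = 6L,
                            strand_mix = 0.5, seed = 1L) {
  planting_mode <- match.arg(planting_mode)
  check_scalar_number(n_reads, "n_reads", lower = 1, integerish = TRUE)
  check_scalar_number(read_length, "read_length", lower = 1, integerish = TRUE)
  check_scalar_number(planted_fraction, "planted_fraction", 0, 1)
  check_scalar_number(strand_mix, "strand_mix", 0, 1)
  check_scalar_number(seed, "seed", integerish = TRUE)
  spec <- motif_spec(repeat_unit, copies)
  if (planted_fraction > 0 && read_length < nchar(spec$motif)) {
    abort(sprintf(
      "read_length (%d) is shorter than the planted motif (%d nt).",
      as.integer(read_length), nchar(spec$motif)))
  }
  structure(
    list(n_reads = as.integer(n_reads),
         read_length = as.integer(read_length),
         planted_fraction = planted_fraction,
         planting_mode = planting_mode,
         repeat_unit = repeat_unit,
         copies = as.integer(copies),
         strand_mix = strand_mix,
         seed = as.integer(seed)),
    class = "read_sim_config"
  )
}

# n random reads of fixed length as a character vector
random_read_batch <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, lapply(seq_len(len), function(j) m[, j]))
}

# Rejection-sample reads until none contains the motif on either strand.
motif_free_batch <- function(n, len, forbidden) {
  reads <- random_read_batch(n, len)
  repeat {
    bad <- read_contains_motif(reads, forbidden)
    if (!any(bad)) break
    reads[bad] <- random_read_batch(sum(bad), len)
  }
  reads
}

#' Simulate a FASTQ read set with a planted telomeric-repeat fraction
#'
#' Writes a four-line-record FASTQ file (gzip-compressed when `path`
#' ends in `.gz`) and returns the exact planted count. Planted reads
#' contain the full motif at a uniformly chosen valid offset with random
#' flanking bases; a `strand_mix` fraction of them carry the
#' reverse-complement motif. Background reads are uniform random bases,
#' rejection-resampled until they are motif-free on both strands, so the
#' planted fraction is the exact repeat-read ground truth. Quality lines
#' are constant `I`; the screen never reads them.
#'
#' @param config A [read_sim_config()].
#' @param path Output FASTQ path (`.fastq` or `.fastq.gz`).
#' @return A one-row tibble with `path`, `n_reads`, `n_planted`,
#'   `true_ratio` (= `n_planted / n_reads`).
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' generate_reads(read_sim_config(200, 50, 0.1, seed = 7), f)
#' @export
generate_reads <- function(config, path) {
  stopifnot(inherits(config, "read_sim_config"))
  local_seed(config$seed, {
    n <- config$n_reads
    len <- config$read_length
    spec <- motif_spec(config$repeat_unit, config$copies)
    motifs_both <- build_motifs(spec)  # forbidden in background reads

    n_planted <- switch(config$planting_mode,
      exact_count = as.integer(floor(config$planted_fraction * n)),
      bernoulli   = sum(stats::runif(n) < config$planted_fraction)
    )

    reads <- motif_free_batch(n, len, motifs_both)
    if (n_planted > 0L) {
      idx <- sort(sample.int(n, n_planted))
      n_rc <- round(config$strand_mix * n_planted)
      rc <- rep(FALSE, n_planted)
      if (n_rc > 0L) rc[sample.int(n_planted, n_rc)] <- TRUE
      motif_fwd <- spec$motif
      motif_rev <- reverse_complement(motif_fwd)
      offset <- sample.int(len - nchar(motif_fwd) + 1L, n_planted,
                           replace = TRUE)
      planted <- reads[idx]
      ins <- ifelse(rc, motif_rev, motif_fwd)
      substr(planted, offset, offset + nchar(motif_fwd) - 1L) <- ins
      reads[idx] <- planted
    }

    qual <- strrep("I", len)
    lines <- as.vector(rbind(paste0("@read_", seq_len(n)),
                             reads, "+", qual))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(lines, con)

    tibble(path = path, n_reads = n, n_planted = n_planted,
           true_ratio = n_planted / n)
  })
}

#' Configuration for a simulated screening cohort
#'
#' Describes a cohort of read sets bound to protein targets, emulating a
#' ChIP-seq screen in which most targets sit at a low background
#' repeat-read ratio and one or more telomere-associated targets are
#' elevated. Each sample is generated by [generate_reads()] in
#' `exact_count` mode with its target's ratio, so the per-sample ground
#' truth is exact.
#'
#' @param n_targets Positive integer; number of protein targets.
#' @param replicates_per_target Positive integer; read sets per target.
#' @param background_ratio Real in `[0, 1]`; repeat-read ratio of
#'   non-elevated targets.
#' @param tap_targets Named numeric vector mapping target names to
#'   elevated ratios (each must exceed `background_ratio`). Names must
#'   be a subset of the generated target names `TGT01`, `TGT02`, ...
#' @param reads_per_sample,read_length Per-sample read count and length.
#' @param seed Integer master seed; each sample draws its own RNG stream
#'   derived from `(seed, sample index)`.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_targets, replicates_per_target,
                              background_ratio, tap_targets = NULL,
                              reads_per_sample = 10000L, read_length = 50L,
                              seed = 1L) {
  check_scalar_number(n_targets, "n_targets", lower = 1, integerish = TRUE)
  check_scalar_number(replicates_per_target, "replicates_per_target",
                      lower = 1, integerish = TRUE)
  check_scalar_number(background_ratio, "background_ratio", 0, 1)
  check_scalar_number(reads_per_sample, "reads_per_sample", lower = 1,
                      integerish = TRUE)
  check_scalar_number(read_length, "read_length", lower = 1,
                      integerish = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)
  targets <- sprintf("TGT%02d", seq_len(n_targets))
  if (!is.null(tap_targets)) {
    if (is.null(names(tap_targets)) || anyDuplicated(names(tap_targets))) {
      abort("`tap_targets` must be a uniquely named numeric vector.")
    }
    unknown <- setdiff(names(tap_targets), targets)
    if (length(unknown) > 0) {
      abort(sprintf("tap target(s) not in the cohort: %s.",
                    paste(unknown, collapse = ", ")))
    }
    if (any(tap_targets <= background_ratio)) {
      abort("every elevated tap ratio must exceed `background_ratio`.")
    }
  }
  structure(
    list(n_targets = as.integer(n_targets),
         replicates_per_target = as.integer(replicates_per_target),
         background_ratio = background_ratio,
         tap_targets = tap_targets,
         reads_per_sample = as.integer(reads_per_sample),
         read_length = as.integer(read_length),
         targets = targets,
         seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

#' Simulate a screening cohort: per-sample FASTQ files plus manifest
#'
#' Generates `n_targets * replicates_per_target` read sets under
#' `output_dir`, writes the cohort manifest
#' (`sample_id<TAB>target<TAB>path`) as `manifest.tsv` and a
#' ground-truth sidecar (`sample_id<TAB>true_ratio`) as `truth.tsv`.
#'
#' @param config A [cohort_sim_config()].
#' @param output_dir Writable directory (created if absent).
#' @return The manifest as a tibble with columns `sample_id`, `target`,
#'   `path`, `class`, plus attribute `"truth"` holding the sidecar
#'   tibble.
#' @export
generate_cohort <- function(config, output_dir) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'.", output_dir))
  }
  grid <- tidyr::expand_grid(target = config$targets,
                             replicate = seq_len(config$replicates_per_target))
  grid$sample_id <- sprintf("%s_rep%d", grid$target, grid$replicate)
  grid$ratio <- config$background_ratio
  if (!is.null(config$tap_targets)) {
    hit <- match(grid$target, names(config$tap_targets))
    grid$ratio[!is.na(hit)] <- config$tap_targets[hit[!is.na(hit)]]
  }

  summaries <- purrr::pmap(
    list(grid$sample_id, grid$ratio, seq_len(nrow(grid))),
    function(sample_id, ratio, i) {
      path <- file.path(output_dir, paste0(sample_id, ".fastq"))
      cfg <- read_sim_config(
        n_reads = config$reads_per_sample,
        read_length = config$read_length,
        planted_fraction = ratio,
        planting_mode = "exact_count",
        seed = derive_seed(config$seed, i)
      )
      generate_reads(cfg, path)
    }
  )
  summaries <- dplyr::bind_rows(summaries)

  manifest <- tibble(sample_id = grid$sample_id, target = grid$target,
                     path = summaries$path, class = "protein")
  truth <- tibble(sample_id = grid$sample_id,
                  true_ratio = summaries$true_ratio)
  write_telo_tsv(manifest, file.path(output_dir, "manifest.tsv"))
  write_telo_tsv(truth, file.path(output_dir, "truth.tsv"))
  attr(manifest, "truth") <- truth
  manifest
}
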