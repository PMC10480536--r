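#' Quality-control policy for screened samples
#'
#' The screen gates each sample on sequencing depth and read length:
#' the `"encode-k562"` preset requires at least 20 million reads with
#' (modal) read length of at least 37 bases, the smallest length able to
#' contain the 36-nt telomeric motif with a flanking base. The `"desk"`
#' preset relaxes the depth gate so small synthetic cohorts pass QC.
#' Per-read filtering is never applied: reads shorter than the motif
#' simply cannot match.
#'
#' @param min_reads Nonnegative integer; minimum denominator reads.
#' @param min_read_length Positive integer; minimum modal read length.
#' @param preset Optional shortcut, `"encode-k562"` (20e6 / 37) or
#'   `"desk"` (1000 / 37); explicit arguments override the preset.
#' @return An object of class `qc_policy`.
#' @export
qc_policy <- function(min_reads = 2e7, min_read_length = 37L,
                      preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("encode-k562", "desk"))
    defaults <- switch(preset,
      "encode-k562" = list(min_reads = 2e7, min_read_length = 37L),
      "desk" = list(min_reads = 1000, min_read_length = 37L))
    if (missing(min_reads)) min_reads <- defaults$min_reads
    if (missing(min_read_length)) min_read_length <- defaults$min_read_length
  }
  check_scalar_number(min_reads, "min_reads", lower = 0, integerish = TRUE)
  check_scalar_number(min_read_length, "min_read_length", lower = 1,
                      integerish = TRUE)
  structure(list(min_reads = min_reads,
                 min_read_length = as.integer(min_read_length)),
            class = "qc_policy")
}

# Load denominator-eligible reads from FASTQ/SAM/BAM.
# Returns list(sequences = character, widths = integer, mode = chr).
load_reads <- function(path, denominator_mode) {
  if (!file.exists(path)) {
    abort(sprintf("read file not found: '%s'.", path))
  }
  is_fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  if (!is_fastq && !is_sam && !is_bam) {
    abort(sprintf("unrecognized read file type: '%s' (expect .fastq[.gz], .sam or .bam).",
                  path))
  }
  if (is_fastq) {
    if (identical(denominator_mode, "mapped_reads")) {
      abort("denominator_mode = 'mapped_reads' requires SAM/BAM input; FASTQ carries no alignment flags.")
    }
    seqs <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq",
                                   with.qualities = FALSE),
      error = function(e) {
        abort(sprintf("failed to parse FASTQ '%s': %s", path,
                      conditionMessage(e)))
      })
    return(list(sequences = as.character(seqs),
                widths = Biostrings::width(seqs),
                mode = "all_reads"))
  }
  bam <- path
  if (is_sam) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  mode <- if (identical(denominator_mode, "all_reads")) "all_reads" else "mapped_reads"
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = c("flag", "seq")))[[1]]
  flag <- res$flag
  # always drop secondary (0x100) and supplementary (0x800) records so
  # each physical read is counted once
  keep <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  if (mode == "mapped_reads") {
    keep <- keep & bitwAnd(flag, 4L) == 0L
  }
  seqs <- res$seq[keep]
  list(sequences = as.character(seqs),
       widths = Biostrings::width(seqs),
       mode = mode)
}

qc_evaluate <- function(n_total, widths, qc) {
  reasons <- character(0)
  if (n_total == 0) {
    reasons <- c(reasons, "no reads")
  }
  if (n_total < qc$min_reads) {
    reasons <- c(reasons, sprintf("n_total < %g", qc$min_reads))
  }
  if (n_total > 0) {
    tab <- table(widths)
    modal_len <- as.integer(names(tab)[which.max(tab)])
    if (modal_len < qc$min_read_length) {
      reasons <- c(reasons,
                   sprintf("modal read length %d < %d", modal_len,
                           qc$min_read_length))
    }
  }
  reasons
}

#' Screen one read set for telomeric-repeat-containing reads
#'
#' Streams a sample once, counting denominator-eligible reads and the
#' subset that contain the motif as an exact substring (no mismatches),
#' and reports the repeat-read ratio — the screen's binding-intensity
#' statistic — together with the QC verdict. For FASTQ input every read
#' is denominator-eligible; for SAM/BAM with
#' `denominator_mode = "mapped_reads"` (the `"auto"` resolution), only
#' primary mapped records are counted, secondary and supplementary
#' alignments are always excluded.
#'
#' @param path FASTQ (`.fastq`, optionally `.gz`), SAM or BAM file.
#' @param sample_id Sample identifier; defaults to the file name.
#' @param spec A [motif_spec()].
#' @param qc A [qc_policy()].
#' @param denominator_mode `"auto"` (all reads for FASTQ, mapped reads
#'   for SAM/BAM), `"all_reads"` or `"mapped_reads"`.
#' @return A one-row tibble: `sample_id`, `n_total`, `n_repeat`,
#'   `ratio` (`NA` when `n_total = 0`, never silently 0), `denominator_mode`,
#'   `qc_pass`, `qc_reasons` (`;`-separated), `status` (`"ok"`).
#' @export
screen_sample <- function(path, sample_id = basename(path),
                          spec = motif_spec(), qc = qc_policy(),
                          denominator_mode = c("auto", "all_reads",
                                               "mapped_reads")) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(inherits(spec, "motif_spec"), inherits(qc, "qc_policy"))
  reads <- load_reads(path, if (denominator_mode == "auto") NULL else denominator_mode)
  motifs <- build_motifs(spec)
  n_total <- length(reads$sequences)
  n_repeat <- if (n_total > 0) {
    sum(read_contains_motif(reads$sequences, motifs))
  } else 0L
  reasons <- qc_evaluate(n_total, reads$widths, qc)
  tibble(
    sample_id = sample_id,
    n_total = as.integer(n_total),
    n_repeat = as.integer(n_repeat),
    ratio = if (n_total > 0) n_repeat / n_total else NA_real_,
    denominator_mode = reads$mode,
    qc_pass = length(reasons) == 0,
    qc_reasons = paste(reasons, collapse = "; "),
    status = "ok"
  )
}

#' Screen every sample of a cohort manifest
#'
#' Applies [screen_sample()] to each manifest row, preserving manifest
#' order. A sample whose file is missing or unreadable yields a
#' `status = "failed"` row (with the error message in `qc_reasons`)
#' rather than aborting the cohort.
#'
#' @param manifest Data frame with columns `sample_id`, `target`,
#'   `path` (and optionally `class`).
#' @param spec,qc,denominator_mode Passed to [screen_sample()].
#' @return A tibble with one row per manifest row: the
#'   [screen_sample()] columns plus `target` (and `class` if present).
#' @export
screen_cohort <- function(manifest, spec = motif_spec(),
                          qc = qc_policy(),
                          denominator_mode = c("auto", "all_reads",
                                               "mapped_reads")) {
  denominator_mode <- match.arg(denominator_mode)
  check_columns(manifest, c("sample_id", "target", "path"), "manifest")
  if (nrow(manifest) == 0) abort("manifest has no rows.")
  results <- purrr::pmap(
    list(manifest$sample_id, manifest$path),
    function(sample_id, path) {
      tryCatch(
        screen_sample(path, sample_id = sample_id, spec = spec, qc = qc,
                      denominator_mode = denominator_mode),
        error = function(e) {
          tibble(sample_id = sample_id, n_total = NA_integer_,
                 n_repeat = NA_integer_, ratio = NA_real_,
                 denominator_mode = NA_character_, qc_pass = FALSE,
                 qc_reasons = conditionMessage(e), status = "failed")
        })
    })
  out <- dplyr::bind_rows(results)
  out$target <- manifest$target
  if ("class" %in% names(manifest)) out$class <- manifest$class
  dplyr::relocate(out, "sample_id", "target")
}
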