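#' Define a tandem-repeat search motif
#'
#' A motif specification describes the exact search pattern(s) of the
#' repeat-read screen: a repeat unit (for human telomeres, `TTAGGG`)
#' concatenated a fixed number of times, optionally searched on both
#' strands. The default, six tandem copies of `TTAGGG` searched on both
#' strands, is the 36-base telomeric probe used to screen ChIP-seq read
#' sets for telomere-associated proteins.
#'
#' @param repeat_unit DNA string over `A`, `C`, `G`, `T` (uppercase).
#' @param copies Positive integer; number of tandem copies.
#' @param strand_mode `"both"` (search the motif and its reverse
#'   complement) or `"forward_only"`.
#' @return An object of class `motif_spec`: a list with `repeat_unit`,
#'   `copies`, `strand_mode`, and the assembled `motif` string.
#' @examples
#' motif_spec()                    # (TTAGGG)6, both strands
#' motif_spec("CCCTAA", 6, "forward_only")
#' @export
motif_spec <- function(repeat_unit = "TTAGGG", copies = 6L,
                       strand_mode = c("both", "forward_only")) {
  strand_mode <- match.arg(strand_mode)
  if (!is.character(repeat_unit) || length(repeat_unit) != 1L ||
      nchar(repeat_unit) == 0L) {
    abort("`repeat_unit` must be a single non-empty string.")
  }
  if (grepl("[^ACGT]", repeat_unit)) {
    abort("`repeat_unit` must contain only uppercase A, C, G, T.")
  }
  check_scalar_number(copies, "copies", lower = 1, integerish = TRUE)
  structure(
    list(
      repeat_unit = repeat_unit,
      copies = as.integer(copies),
      strand_mode = strand_mode,
      motif = strrep(repeat_unit, copies)
    ),
    class = "motif_spec"
  )
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("<motif_spec> (%s)%d, strand_mode = %s, %d nt\n",
              x$repeat_unit, x$copies, x$strand_mode, nchar(x$motif)))
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assemble the exact search strings for a motif
#'
#' Returns the full motif (unit repeated `copies` times) and, when
#' `strand_mode = "both"`, its reverse complement; a self-reverse-
#' complementary motif is returned once.
#'
#' @param spec A [motif_spec()].
#' @return Character vector of one or two search strings.
#' @examples
#' build_motifs(motif_spec("A", 1))        # "A" "T"
#' build_motifs(motif_spec("AT", 2))       # "ATAT" (palindromic)
#' @export
build_motifs <- function(spec = motif_spec()) {
  stopifnot(inherits(spec, "motif_spec"))
  motifs <- spec$motif
  if (spec$strand_mode == "both") {
    motifs <- unique(c(motifs, reverse_complement(motifs)))
  }
  motifs
}

#' Test reads for exact motif containment
#'
#' A read is repeat-positive iff any of the search strings occurs as an
#' exact contiguous substring of the (uppercased) read. `N` never
#' matches a base, so any `N` inside the would-be match site breaks it —
#' "no mismatches" is taken literally.
#'
#' @param sequences Character vector of read sequences (may contain `N`
#'   or lowercase; lowercase is uppercased before matching).
#' @param motifs Character vector of search strings, as returned by
#'   [build_motifs()].
#' @return Logical vector, one element per read; an empty sequence is
#'   `FALSE`.
#' @export
read_contains_motif <- function(sequences, motifs) {
  if (length(sequences) == 0L) return(logical(0))
  seqs <- toupper(sequences)
  hit <- rep(FALSE, length(seqs))
  for (m in motifs) {
    todo <- !hit
    if (!any(todo)) break
    hit[todo] <- grepl(m, seqs[todo], fixed = TRUE)
  }
  hit
}
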