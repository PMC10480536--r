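# Independent oracles used across tests. Each deliberately recomputes the
# quantity with a different algorithm than the package implementation.

# Position-by-position exact substring scan (all offsets, all motifs).
oracle_contains <- function(seqs, motifs) {
  seqs <- unname(toupper(seqs))
  hit <- rep(FALSE, length(seqs))
  for (m in motifs) {
    k <- nchar(m)
    max_off <- max(nchar(seqs)) - k + 1
    if (max_off < 1) next
    for (off in seq_len(max_off)) {
      hit <- hit | substr(seqs, off, off + k - 1) == m
    }
  }
  hit
}

# Exact Mann-Whitney p by enumeration, computed from pairwise win counts
# (not rank sums, unlike the implementation).
oracle_wilcoxon <- function(a, b, alternative) {
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  u_of <- function(idx) {
    av <- pool[idx]
    bv <- pool[-idx]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(seq_len(na))
  us <- apply(utils::combn(n, na), 2, u_of)
  mu <- na * (n - na) / 2
  eps <- 1e-9
  switch(alternative,
    a_greater = mean(us >= u_obs - eps),
    a_less = mean(us <= u_obs + eps),
    two_sided = mean(abs(us - mu) >= abs(u_obs - mu) - eps))
}

# Maximum-cardinality one-to-one matching under a distance threshold,
# by exhaustive recursion (instances must stay small).
oracle_max_matching <- function(ax, ay, bx, by, threshold) {
  ok <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2) <= threshold
  best <- 0L
  recurse <- function(i, used_b, count) {
    if (count + (length(ax) - i + 1) <= best) return()
    if (i > length(ax)) {
      best <<- max(best, count)
      return()
    }
    for (j in which(ok[i, ] & !used_b)) {
      used_b[j] <- TRUE
      recurse(i + 1L, used_b, count + 1L)
      used_b[j] <- FALSE
    }
    recurse(i + 1L, used_b, count)
  }
  if (length(ax) == 0 || length(bx) == 0) return(0L)
  recurse(1L, rep(FALSE, length(bx)), 0L)
  best
}

# Convenience: simulate a read file and return its sequences.
sim_reads_to_seqs <- function(config) {
  f <- tempfile(fileext = ".fastq")
  on.exit(unlink(f))
  generate_reads(config, f)
  unname(as.character(Biostrings::readDNAStringSet(f, format = "fastq")))
}

# Minimal SAM fixture with controlled flags, written as text.
write_test_sam <- function(path) {
  motif_read <- paste0(strrep("TTAGGG", 6), "ACGT")
  bg <- strrep("ACTG", 10)
  rec <- function(qname, flag, seq) {
    mapped <- bitwAnd(flag, 4L) == 0L
    paste(qname, flag, if (mapped) "chr1" else "*",
          if (mapped) 100L else 0L, if (mapped) 60L else 0L,
          if (mapped) "40M" else "*", "*", 0, 0, seq, "*", sep = "\t")
  }
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:10000",
    rec("r1", 0L, motif_read),     # primary mapped, repeat-positive
    rec("r2", 4L, bg),             # unmapped
    rec("r3", 256L, bg),           # secondary -> always excluded
    rec("r4", 2048L, bg),          # supplementary -> always excluded
    rec("r5", 0L, bg)              # primary mapped background
  ), path)
  path
}
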