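test_that("exact_count planting plants exactly floor(f * n) reads", {
  f <- tempfile(fileext = ".fastq")
  s <- generate_reads(read_sim_config(997, 50, 0.123, seed = 4), f)
  expect_equal(s$n_planted, floor(0.123 * 997))
  seqs <- as.character(Biostrings::readDNAStringSet(f, format = "fastq"))
  motifs <- build_motifs(motif_spec())
  expect_equal(sum(read_contains_motif(seqs, motifs)), s$n_planted)
  unlink(f)
})

test_that("background reads are motif-free on both strands", {
  seqs <- sim_reads_to_seqs(read_sim_config(2000, 40, 0, seed = 9))
  motifs <- build_motifs(motif_spec(strand_mode = "both"))
  expect_equal(sum(read_contains_motif(seqs, motifs)), 0)
})

test_that("strand_mix places the reverse-complement motif in planted reads", {
  seqs <- sim_reads_to_seqs(
    read_sim_config(500, 40, 1, strand_mix = 1, seed = 5))
  expect_true(all(grepl(strrep("CCCTAA", 6), seqs, fixed = TRUE)))
  seqs_f <- sim_reads_to_seqs(
    read_sim_config(500, 40, 1, strand_mix = 0, seed = 5))
  expect_true(all(grepl(strrep("TTAGGG", 6), seqs_f, fixed = TRUE)))
})

test_that("read simulation is byte-deterministic and FASTQ is well-formed", {
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  cfg <- read_sim_config(300, 50, 0.05, seed = 21)
  generate_reads(cfg, f1)
  generate_reads(cfg, f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_equal(length(lines), 4 * 300)
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@")))
  expect_true(all(lines[seq(3, length(lines), 4)] == "+"))
  expect_true(all(nchar(lines[seq(2, length(lines), 4)]) == 50))
  unlink(c(f1, f2))
})

test_that("gzip output round-trips identically", {
  fgz <- tempfile(fileext = ".fastq.gz")
  cfg <- read_sim_config(100, 40, 0.1, seed = 2)
  generate_reads(cfg, fgz)
  seqs <- as.character(Biostrings::readDNAStringSet(fgz, format = "fastq"))
  expect_length(seqs, 100)
  unlink(fgz)
})

test_that("read simulation rejects impossible configurations", {
  expect_error(read_sim_config(100, 20, 0.5), "shorter than the planted motif")
  expect_error(read_sim_config(100, 50, 1.2), "planted_fraction")
  expect_error(read_sim_config(0, 50, 0.5), "n_reads")
  # motif-free background does not need room for the motif
  expect_silent(read_sim_config(10, 20, 0))
})

test_that("cohort generation emits manifest, files and exact ground truth", {
  dir <- tempfile("cohort_")
  cfg <- cohort_sim_config(5, 3, 0.002, c(TGT03 = 0.02),
                           reads_per_sample = 1000, seed = 7)
  manifest <- generate_cohort(cfg, dir)
  expect_equal(nrow(manifest), 15)
  expect_true(all(file.exists(manifest$path)))
  truth <- attr(manifest, "truth")
  expect_equal(truth$true_ratio[manifest$target == "TGT03"],
               rep(floor(0.02 * 1000) / 1000, 3))
  expect_equal(unique(truth$true_ratio[manifest$target != "TGT03"]),
               floor(0.002 * 1000) / 1000)
  # sidecar and manifest TSVs round-trip
  expect_equal(read_telo_tsv(file.path(dir, "truth.tsv"))$true_ratio,
               truth$true_ratio)
  unlink(dir, recursive = TRUE)
})

test_that("same cohort seed gives byte-identical read files", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- cohort_sim_config(2, 2, 0.01, reads_per_sample = 500, seed = 13)
  m1 <- generate_cohort(cfg, d1)
  m2 <- generate_cohort(cfg, d2)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readLines(m1$path[i]), readLines(m2$path[i]))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort config validates tap targets", {
  expect_error(cohort_sim_config(3, 2, 0.01, c(NOPE = 0.1)), "not in the cohort")
  expect_error(cohort_sim_config(3, 2, 0.01, c(TGT01 = 0.005)),
               "exceed `background_ratio`")
})

test_that("Ct table simulation matches its closed-form ground truth", {
  ct0 <- generate_ct_table(5, c(A = 0, B = -1, C = 2), noise_sd = 0, seed = 3)
  ts0 <- compute_ts(ct0)
  expect_equal(ts0$t_s[ts0$group == "A"], rep(1, 5))
  expect_equal(ts0$t_s[ts0$group == "B"], rep(2, 5))
  expect_equal(ts0$t_s[ts0$group == "C"], rep(0.25, 5))
  expect_error(generate_ct_table(5, numeric(0)), "non-empty")
})

test_that("noisy Ct tables recover the lognormal mean T/S", {
  # with Gaussian noise on both Ct values, dCt ~ Normal(offset, sqrt(2) sd)
  # and T/S is lognormal with mean 2^-offset * exp((ln2 * sigma)^2 / 2)
  sd_ct <- 0.1
  sigma_delta <- sqrt(2) * sd_ct
  offset <- 1
  n <- 400
  ct <- generate_ct_table(n, c(G = offset), noise_sd = sd_ct, seed = 17)
  ts <- compute_ts(ct)$t_s
  expected_mean <- 2^(-offset) * exp((log(2) * sigma_delta)^2 / 2)
  se <- stats::sd(ts) / sqrt(n)
  expect_lt(abs(mean(ts) - expected_mean), 3 * se)
})

test_that("foci simulation plants the configured colocalized anchors", {
  cfg <- foci_sim_config(6, foci_per_channel = 10L,
                         colocalized_fraction = 0.5, jitter_sd = 0, seed = 8)
  f <- generate_foci(cfg)
  truth <- attr(f, "truth")
  expect_equal(truth$n_coloc_true, rep(5L, 6))
  expect_equal(nrow(f), 6 * 2 * 10)
  # three channels, jitter-free: planted anchors shared across all three
  cfg3 <- foci_sim_config(4, channels = c("TEL", "PML", "ZBTB"),
                          foci_per_channel = 8L, colocalized_fraction = 0.25,
                          jitter_sd = 0, seed = 8)
  f3 <- generate_foci(cfg3)
  expect_equal(attr(f3, "truth")$n_coloc_true, rep(2L, 4))
  expect_error(foci_sim_config(4, channels = "TEL"), "2 or 3")
  expect_error(foci_sim_config(4, colocalized_fraction = 1.5),
               "colocalized_fraction")
})
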