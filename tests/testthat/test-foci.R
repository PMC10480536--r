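foci_df <- function(...) {
  # build a foci table from channel = list of (x, y) matrices
  args <- list(...)
  dplyr::bind_rows(purrr::imap(args, function(m, ch) {
    tibble::tibble(nucleus_id = "n1", channel = ch,
                   x = m[, 1], y = m[, 2])
  }))
}

test_that("coincident and distant foci match as expected", {
  f <- foci_df(A = cbind(0, 0), B = cbind(0, 0))
  expect_equal(match_foci(f, c("A", "B"), 0.5)$n_coloc, 1L)
  far <- foci_df(A = cbind(0, 0), B = cbind(10, 0))
  r <- match_foci(far, c("A", "B"), 1)
  expect_equal(r$n_coloc, 0L)
  expect_equal(r$ratio, 0)
  expect_error(match_foci(f, c("A", "NOPE"), 1), "absent")
  expect_error(match_foci(f, c("A", "B"), 0), "threshold")
})

test_that("mutual-NN matching is one-to-one and claims each focus once", {
  # two A foci near one B focus: only one pair can match
  f <- foci_df(A = rbind(c(0, 0), c(0.1, 0)), B = cbind(0.02, 0))
  r <- match_foci(f, c("A", "B"), 1)
  expect_equal(r$n_coloc, 1L)
  expect_equal(r$n_A, 2L)
  expect_equal(r$n_B, 1L)
})

test_that("matching is symmetric in channel order and rigid-motion invariant", {
  set.seed(12)
  cfg <- foci_sim_config(8, foci_per_channel = 12L,
                         colocalized_fraction = 0.4, jitter_sd = 0.02,
                         seed = 19)
  f <- generate_foci(cfg)
  r_ab <- match_foci(f, c("TEL", "DAMAGE"), 0.2)
  r_ba <- match_foci(f, c("DAMAGE", "TEL"), 0.2)
  expect_equal(r_ab$n_coloc, r_ba$n_coloc)
  # translate + rotate all coordinates
  th <- 0.7
  g <- f
  g$x <- cos(th) * f$x - sin(th) * f$y + 3
  g$y <- sin(th) * f$x + cos(th) * f$y - 1
  r_rot <- match_foci(g, c("TEL", "DAMAGE"), 0.2)
  expect_equal(r_rot$n_coloc, r_ab$n_coloc)
})

test_that("n_coloc is monotone nondecreasing in threshold", {
  f <- generate_foci(foci_sim_config(6, foci_per_channel = 10L,
                                     colocalized_fraction = 0.3,
                                     jitter_sd = 0.05, seed = 23))
  counts <- vapply(c(0.05, 0.1, 0.3, 1, 5),
                   function(th) sum(match_foci(f, c("TEL", "DAMAGE"),
                                               th)$n_coloc), 1)
  expect_true(all(diff(counts) >= 0))
})

test_that("jitter-free planted foci are recovered exactly", {
  cfg <- foci_sim_config(10, foci_per_channel = 10L,
                         colocalized_fraction = 0.4, jitter_sd = 0,
                         field_size = 100, seed = 29)
  f <- generate_foci(cfg)
  truth <- attr(f, "truth")
  for (th in c(1e-6, 0.001, 0.01)) {
    r <- match_foci(f, c("TEL", "DAMAGE"), th)
    expect_equal(r$n_coloc, truth$n_coloc_true)
  }
})

test_that("triple matching recovers jitter-free planted anchors", {
  cfg <- foci_sim_config(6, channels = c("A", "B", "C"),
                         foci_per_channel = 10L, colocalized_fraction = 0.3,
                         jitter_sd = 0, field_size = 100, seed = 31)
  f <- generate_foci(cfg)
  r <- match_foci(f, c("A", "B", "C"), 0.001)
  expect_equal(r$n_coloc, attr(f, "truth")$n_coloc_true)
})

test_that("mutual-NN count never exceeds maximum matching; equals it on planted data", {
  set.seed(301)
  for (i in 1:15) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    ax <- runif(na, 0, 3); ay <- runif(na, 0, 3)
    bx <- runif(nb, 0, 3); by <- runif(nb, 0, 3)
    th <- runif(1, 0.3, 1.5)
    f <- foci_df(A = cbind(ax, ay), B = cbind(bx, by))
    got <- match_foci(f, c("A", "B"), th)$n_coloc
    expect_lte(got, oracle_max_matching(ax, ay, bx, by, th))
  }
  f0 <- generate_foci(foci_sim_config(5, foci_per_channel = 6L,
                                      colocalized_fraction = 0.5,
                                      jitter_sd = 0, field_size = 50,
                                      seed = 41))
  th <- 0.01
  per_nuc <- match_foci(f0, c("TEL", "DAMAGE"), th)
  for (nid in unique(f0$nucleus_id)) {
    sub <- f0[f0$nucleus_id == nid, ]
    a <- sub[sub$channel == "TEL", ]; b <- sub[sub$channel == "DAMAGE", ]
    expect_equal(per_nuc$n_coloc[per_nuc$nucleus_id == nid],
                 oracle_max_matching(a$x, a$y, b$x, b$y, th))
  }
})

test_that("unplanted uniform foci rarely match at a small threshold", {
  f <- generate_foci(foci_sim_config(20, foci_per_channel = 10L,
                                     colocalized_fraction = 0,
                                     field_size = 10, seed = 43))
  r <- match_foci(f, c("TEL", "DAMAGE"), 0.05)
  # expected chance pairs ~ n^2 * pi th^2 / field^2 = 100*pi*0.0025/100 << 1
  expect_lt(mean(r$n_coloc), 0.5)
})

test_that("cofoci histogram bins nucleus fractions correctly", {
  counts <- tibble::tibble(n_coloc = rep(6L, 10))
  h <- cofoci_histogram(counts)
  expect_equal(h$fraction[h$bin == "5-8"], 1)
  mixed <- tibble::tibble(n_coloc = c(0L, 0L, 11L, 11L))
  h2 <- cofoci_histogram(mixed)
  expect_equal(h2$fraction[h2$bin == "0"], 0.5)
  expect_equal(h2$fraction[h2$bin == ">10"], 0.5)
  expect_equal(sum(h2$fraction), 1)
  # planted per-nucleus counts reproduce their empirical distribution
  set.seed(5)
  planted <- sample(0:12, 50, replace = TRUE)
  h3 <- cofoci_histogram(tibble::tibble(n_coloc = planted))
  expect_equal(h3$n_nuclei,
               c(sum(planted == 0), sum(planted >= 1 & planted <= 4),
                 sum(planted >= 5 & planted <= 8),
                 sum(planted >= 9 & planted <= 10), sum(planted > 10)))
  bad_bins <- tibble::tibble(lo = c(0, 3), hi = c(4, 6))
  expect_error(cofoci_histogram(counts, bad_bins), "overlap")
})

test_that("chi-squared closed form and validation", {
  same <- positive_fraction_test(50, 100, 50, 100)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  hi <- positive_fraction_test(90, 100, 40, 100)
  # hand closed form: N (ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  expect_equal(hi$statistic, 200 * (90 * 60 - 10 * 40)^2 / (100 * 100 * 130 * 70))
  expect_lt(hi$p_value, 0.001)
  ext <- positive_fraction_test(0, 10, 10, 10)
  expect_equal(ext$statistic, 20)
  expect_lt(ext$p_value, 0.001)
  expect_error(positive_fraction_test(5, 4, 1, 10), "exceed")
  expect_error(positive_fraction_test(0, 10, 0, 10), "margin")
  # Yates option matches chisq.test default
  y <- positive_fraction_test(9, 20, 4, 20, correct = TRUE)
  ref <- stats::chisq.test(matrix(c(9, 11, 4, 16), 2, byrow = TRUE))
  expect_equal(y$statistic, unname(ref$statistic))
})

test_that("group ratio summary compares planted 2x colocalization", {
  groups <- purrr::imap(c(WT = 0.2, KO = 0.4), function(fr, g) {
    f <- generate_foci(foci_sim_config(30, foci_per_channel = 10L,
                                       colocalized_fraction = fr,
                                       jitter_sd = 0, field_size = 100,
                                       seed = if (g == "WT") 51 else 52))
    r <- match_foci(f, c("DAMAGE", "TEL"), 0.01, reference = "TEL")
    r$group <- g
    r
  })
  res <- group_ratio_summary(dplyr::bind_rows(groups),
                             reference_col = "n_TEL")
  s <- res$summary
  expect_equal(s$mean_ratio[s$group == "KO"] / s$mean_ratio[s$group == "WT"],
               2, tolerance = 1e-8)   # exact: floor(f*10)/10 per nucleus
  expect_equal(s$pooled_ratio[s$group == "KO"], 0.4)
  expect_lt(res$comparison$p_value, 0.001)
  one_group <- dplyr::mutate(groups[[1]], group = "only")
  expect_error(group_ratio_summary(one_group), "at least 2 groups")
})
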