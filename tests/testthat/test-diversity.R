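test_that("site_pi matches exhaustive pair counting", {
  expect_equal(site_pi(c(2, 2)), 4 / 6)          # 4 differing of 6 pairs
  expect_equal(site_pi(c(5, 0)), 0)              # monomorphic
  expect_equal(site_pi(c(2, 1, 1)), 5 / 6)       # triallelic
  expect_true(is.na(site_pi(c(1, 0))))           # n < 2: skipped, not fatal
  # frequency form equals 2c(n-c)/(n(n-1)) for biallelic counts
  for (c1 in 0:6) expect_equal(site_pi(c(c1, 6 - c1)), 2 * c1 * (6 - c1) / 30)
})

test_that("window_pi sums per-site diversity over the window length", {
  # one site, counts (2,2) among 2 diploid samples, in a 10-bp window
  tab <- variant_table("chrT", 5, "A", list("G"),
                       matrix(c(0L, 1L), 1), matrix(c(0L, 1L), 1),
                       c("S1", "S2"), contig_lengths = c(chrT = 10L))
  panel <- pop_panel(c("S1", "S2"), c("G1", "G1"))
  tr <- window_pi(tab, panel, windows = data.frame(chrom = "chrT", start = 0,
                                                   end = 10))
  expect_equal(tr$pi_G1, (4 / 6) / 10, tolerance = 1e-12)
  # a window with no variants is exactly 0
  tr2 <- window_pi(tab, panel, windows = data.frame(chrom = "chrT",
                                                    start = c(0, 6),
                                                    end = c(6, 10)))
  expect_equal(tr2$pi_G1[2], 0)
  expect_error(window_pi(tab, pop_panel(c("S1", "S2"), c("G1", "G2"))),
               "fewer than 2")
})

test_that("window_pi equals the exhaustive pairwise oracle on random tables", {
  set.seed(101)
  for (r in 1:25) {
    tab <- rand_table(n_samples = sample(2:8, 1), n_sites = sample(5:40, 1))
    panel <- pop_panel(tab$samples, rep("G", length(tab$samples)))
    win <- sort(sample.int(1000, 2))
    tr <- window_pi(tab, panel, windows = data.frame(chrom = "chrT",
                                                     start = win[1] - 1,
                                                     end = win[2]))
    expect_equal(tr$pi_G, oracle_window_pi(tab, seq_along(tab$samples),
                                           win[1] - 1, win[2]),
                 tolerance = 1e-12)
  }
})

test_that("removing a polymorphic site never increases window pi", {
  set.seed(7)
  tab <- rand_table(n_samples = 6, n_sites = 20, miss = 0)
  panel <- pop_panel(tab$samples, rep("G", 6))
  w <- data.frame(chrom = "chrT", start = 0, end = 1000)
  full <- window_pi(tab, panel, windows = w)$pi_G
  for (i in seq_along(tab$pos)) {
    drop <- window_pi(subset_variants(tab, -i), panel, windows = w)$pi_G
    expect_lte(drop, full + 1e-15)
  }
})

test_that("duplicating every haplotype changes per-site pi only by O(1/n)", {
  set.seed(8)
  tab <- rand_table(n_samples = 5, n_sites = 25, miss = 0)
  dup <- variant_table(tab$chrom, tab$pos, tab$ref, tab$alt,
                       cbind(tab$a1, tab$a1), cbind(tab$a2, tab$a2),
                       c(tab$samples, paste0(tab$samples, "_dup")),
                       tab$contig_lengths)
  pi1 <- site_pi_for_test(tab)
  pi2 <- site_pi_for_test(dup)
  n <- 2 * 5
  ok <- !is.na(pi1)
  expect_true(all(abs(pi2[ok] - pi1[ok]) <= pi1[ok] / (2 * n - 1) + 1e-12))
})

test_that("pi_ratio divides tracks and masks zero denominators", {
  tr <- structure(data.frame(chrom = "c", start = c(0, 10, 20),
                             end = c(10, 20, 30),
                             pi_A = c(0.003, 0.002, 0.002),
                             pi_B = c(0.001, 0, 0.002)),
                  class = c("diversity_track", "data.frame"))
  rt <- pi_ratio(tr, "A", "B")
  expect_equal(rt$ratio[1], 3.0)
  expect_true(is.na(rt$ratio[2]) && !rt$defined[2])
  same <- pi_ratio(tr, "A", "A")
  expect_true(all(same$ratio == 1))
  expect_error(pi_ratio(tr, "A", "Z"), "present")
})

test_that("empirical_threshold is the nearest-rank quantile", {
  expect_equal(empirical_threshold(as.numeric(1:100), 0.95), 95)
  expect_warning(t4 <- empirical_threshold(c(2, 2, 2, 2), 0.95), "resolved")
  expect_equal(t4, 2)
  expect_warning(t1 <- empirical_threshold(7, 0.95))
  expect_equal(t1, 7)
  expect_error(empirical_threshold(rep(NA_real_, 3), 0.95), "no defined")
  rt <- ratio_track_fixture(c(1, 2, NA, 4))   # masked windows excluded
  expect_warning(thr <- empirical_threshold(rt, 0.95))
  expect_equal(thr, 4)
})

test_that("call_sweeps merges qualifying runs and skips masked windows", {
  rt <- ratio_track_fixture(c(1, 1, 9, 10, 1))
  calls <- call_sweeps(rt, 8.21)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$start, calls$end), c(20, 40))   # windows 3-4 merged
  expect_equal(calls$n_windows, 2L)

  expect_equal(nrow(call_sweeps(rt, 99)), 0)
  masked <- ratio_track_fixture(c(1, NA, 1))
  expect_equal(nrow(call_sweeps(masked, 0.5)), 3 - 1)  # NA never qualifies
  gap <- ratio_track_fixture(c(9, 1, 9))
  expect_equal(nrow(call_sweeps(gap, 8)), 2)
  expect_equal(nrow(call_sweeps(gap, 8, max_gap = 1)), 1)
})

test_that("locate_locus uses half-open overlap", {
  rt <- ratio_track_fixture(c(1, 1, 9, 10, 1))
  calls <- call_sweeps(rt, 8.21)                        # [20, 40)
  expect_equal(locate_locus(calls, gene_row(chrom = "chrT", start = 25,
                                            end = 30, atg = 25)),
               "within_sweep")
  # gene starting 1 bp past the interval end: 0-based start 40 is outside
  expect_equal(locate_locus(calls, gene_row(chrom = "chrT", start = 41,
                                            end = 50, atg = 41)),
               "outside_sweep")
  expect_equal(locate_locus(call_sweeps(rt, 99),
                            gene_row(chrom = "chrT", start = 25, end = 30,
                                     atg = 25)),
               "outside_sweep")
  expect_warning(cls <- locate_locus(calls, gene_row(chrom = "chrZ",
                                                     start = 25, end = 30,
                                                     atg = 25)),
                 "chrZ")
  expect_equal(cls, "outside_sweep")
})
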