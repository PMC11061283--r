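mk_track <- function(n, pbs = NULL, xpehh = NULL, spacing = 1000) {
  data.frame(chrom = "chr1", pos = seq_len(n) * spacing,
             pbs = if (is.null(pbs)) rnorm(n) else pbs,
             xpehh = if (is.null(xpehh)) rnorm(n) else xpehh)
}

test_that("sliding windows follow the 20/5 indexing rule", {
  set.seed(1)
  expect_equal(nrow(make_windows(mk_track(30))), 3)
  expect_equal(nrow(make_windows(mk_track(20))), 1)
  expect_equal(nrow(make_windows(mk_track(19))), 0)
  w <- make_windows(mk_track(30))
  expect_equal(w$i_start, c(1, 6, 11))
  expect_equal(w$i_end, c(20, 25, 30))
  # window scores: mean of PBS, max of XP-EHH
  tr <- mk_track(20)
  w1 <- make_windows(tr)
  expect_equal(w1$pbs_mean, mean(tr$pbs))
  expect_equal(w1$xpehh_max, max(tr$xpehh))
  # missing-score SNPs are excluded before indexing
  tr2 <- mk_track(25)
  tr2$pbs[c(3, 7, 9, 12, 20)] <- NA
  expect_equal(nrow(make_windows(tr2)), 1)
})

test_that("top windows merge at the 10 kb rule and keep the max score", {
  base <- data.frame(chrom = "chr1",
                     start = c(1e5, 1e5 + 30000), end = c(1e5 + 5000, 1e5 + 35000),
                     score = c(5, 7))
  near <- base; near$start[2] <- base$end[1] + 9999; near$end[2] <- near$start[2] + 5000
  far <- base; far$start[2] <- base$end[1] + 10001; far$end[2] <- far$start[2] + 5000
  m_near <- sweepscan:::merge_intervals(near, 1e4)
  m_far <- sweepscan:::merge_intervals(far, 1e4)
  expect_equal(nrow(m_near), 1)
  expect_equal(m_near$score, 7)
  expect_equal(nrow(m_far), 2)
})

test_that("percentile retention matches a brute-force filter", {
  set.seed(7)
  w <- data.frame(chrom = "chr1", start = seq(1, by = 5e4, length.out = 1000),
                  end = seq(2e4, by = 5e4, length.out = 1000),
                  pbs_mean = rnorm(1000))
  got <- suppressWarnings(top_windows(w, "pbs_mean", scan_config()))
  thr <- quantile(w$pbs_mean, 0.99)
  kept <- w[w$pbs_mean >= thr, ]
  # windows are spaced 50 kb apart so no merging: one region per kept window
  expect_equal(nrow(got), nrow(kept))
  expect_equal(sort(got$score), sort(kept$pbs_mean))
  expect_equal(max(got$score), max(w$pbs_mean))
})

test_that("top SNPs chain-merge and respect the lower-tail symmetry", {
  set.seed(8)
  x <- rnorm(500)
  x[c(100, 200, 300)] <- c(9, 8, 10)
  tr <- data.frame(chrom = "chr1", pos = seq_len(500) * 40, xpehh = x)
  up <- top_snps_xpehh(tr, scan_config(), "upper")
  # negated track, lower tail reproduces the upper-tail result
  trn <- tr; trn$xpehh <- -trn$xpehh
  lo <- top_snps_xpehh(trn, scan_config(), "lower")
  expect_equal(up$regions[c("start", "end")], lo$regions[c("start", "end")])
  # a <=10 kb chain of top SNPs becomes one region spanning its extremes
  tr3 <- data.frame(chrom = "chr1",
                    pos = c(1e6, 1e6 + 100, 1e6 + 9000, 1e6 + 18500,
                            2e6 + seq_len(496) * 100),
                    xpehh = c(0, 9, 9, 9, rnorm(496, 0, 0.1)))
  r3 <- top_snps_xpehh(tr3, scan_config(), "upper")$regions
  chain <- r3[r3$score == 9, ]
  expect_equal(nrow(chain), 1)
  expect_equal(chain$start, 1e6 + 100)
  expect_equal(chain$end, 1e6 + 18500)
  # an isolated top SNP yields a zero-length region
  iso <- data.frame(chrom = "chr1",
                    pos = c(seq_len(499) * 100, 1e6),
                    xpehh = c(rnorm(499, 0, 0.1), 9))
  ri <- top_snps_xpehh(iso, scan_config(), "upper")$regions
  expect_true(any(ri$start == 1e6 & ri$end == 1e6))
})

test_that("Fisher combination is exact rank arithmetic", {
  set.seed(9)
  n <- 1000
  w <- data.frame(pbs_mean = rnorm(n), xpehh_max = rnorm(n))
  fc <- fisher_combine(w)
  top <- which.max(w$pbs_mean)
  # the window best on both scores scores -log10(1/N) twice
  w2 <- w
  w2$xpehh_max[top] <- max(w2$xpehh_max) + 1
  fc2 <- fisher_combine(w2)
  expect_equal(fc2$fisher[top], 6, tolerance = 1e-12)
  # worst on both scores 0
  bottom <- which.min(w$pbs_mean)
  w3 <- w
  w3$xpehh_max[bottom] <- min(w3$xpehh_max) - 1
  expect_equal(fisher_combine(w3)$fisher[bottom], 0, tolerance = 1e-12)
  # exact median rank (even split plus the tie rule): -2 log10(rank)
  x <- c(seq_len(n))
  w4 <- data.frame(pbs_mean = x, xpehh_max = x)
  med <- fisher_combine(w4)$fisher[n / 2]
  expect_equal(med, -2 * log10((n / 2 + 1) / n), tolerance = 1e-12)
  # rank-only: invariant under strictly monotone transforms
  w5 <- data.frame(pbs_mean = exp(w$pbs_mean), xpehh_max = w$xpehh_max^3 + 2)
  expect_equal(fisher_combine(w5)$fisher, fc$fisher, tolerance = 1e-12)
})

test_that("resampling p-value behaves at the extremes and converges", {
  units <- c(seq(0, 0.9, length.out = 999))
  p_top <- resample_significance(1, units, M = 1000, seed = 1)
  expect_equal(p_top, 1 / 1001)
  p_bot <- resample_significance(-1, units, M = 1000, seed = 1)
  expect_equal(p_bot, 1)
  expect_error(resample_significance(1, units, M = 0), "M must be")
  set.seed(10)
  units2 <- rnorm(1000)
  s <- quantile(units2, 0.93)
  exact <- mean(units2 >= s)
  p_mc <- resample_significance(s, units2, M = 1e5, seed = 2)
  expect_lt(abs(p_mc - exact), 0.01)
})

test_that("final regions union flanked per-method winners idempotently", {
  cfg <- scan_config(p_thresholds = c(PBS = 0.5, XPEHH = 0.5, Fisher = 0.5))
  mk <- function(starts, score = 10) {
    data.frame(chrom = "chr1", start = starts, end = starts + 1000,
               score = score, p = 1e-6)
  }
  # 10+10+10 pairwise non-overlapping inputs -> 30 final regions
  pm <- list(PBS = mk(seq(1e6, by = 2e6, length.out = 10)),
             XPEHH = mk(seq(2.1e7, by = 2e6, length.out = 10)),
             Fisher = mk(seq(4.1e7, by = 2e6, length.out = 10)))
  fin <- finalize_regions(pm, cfg, chrom_len = 1e9)
  expect_equal(nrow(fin), 30)
  expect_equal(fin$start, sort(fin$start))
  # identical region from all three methods -> one region, methods union
  same <- mk(5e6)
  fin2 <- finalize_regions(list(PBS = same, XPEHH = same, Fisher = same),
                           cfg, chrom_len = 1e9)
  expect_equal(nrow(fin2), 1)
  expect_equal(fin2$methods, "Fisher,PBS,XPEHH")
  # interval arithmetic: flanked regions touching at 1.14-1.15 Mb merge
  pm3 <- list(PBS = data.frame(chrom = "chr1", start = 1e6, end = 1.1e6,
                               score = 1, p = 1e-6),
              Fisher = data.frame(chrom = "chr1", start = 1.19e6,
                                  end = 1.3e6, score = 2, p = 1e-6))
  fin3 <- finalize_regions(pm3, cfg, chrom_len = 1e9)
  expect_equal(nrow(fin3), 1)
  expect_equal(fin3$start, 9.5e5)
  expect_equal(fin3$end, 1.35e6)
  # idempotence: re-merging the merged output changes nothing
  again <- finalize_regions(list(PBS = fin[c("chrom", "start", "end",
                                             "score", "p")]),
                            scan_config(flank = 0,
                                        p_thresholds = c(PBS = 0.5),
                                        top_k = 50),
                            chrom_len = 1e9)
  expect_equal(again[c("start", "end")], fin[c("start", "end")])
  # per-method p threshold filters before the top-k cut
  pm4 <- list(PBS = mk(seq(1e6, by = 2e6, length.out = 5)))
  pm4$PBS$p <- c(1e-6, 0.9, 1e-6, 0.9, 1e-6)
  fin4 <- finalize_regions(pm4, cfg, chrom_len = 1e9)
  expect_equal(nrow(fin4), 3)
})
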