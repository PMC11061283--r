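test_that("Hudson FST matches hand arithmetic and handles the extremes", {
  # identical common frequencies: estimator is <= 0 pre-clamp, 0 after
  expect_equal(hudson_fst(0.5, 1000, 0.5, 1000), 0)
  # fixed difference: clamped just below 1 for the -ln(1-FST) transform
  expect_equal(hudson_fst(1, 50, 0, 50), 1 - 1e-6)
  # hand oracle at p1=0.8, p2=0.2, n1=n2=100 alleles
  num <- (0.8 - 0.2)^2 - 0.8 * 0.2 / 99 - 0.2 * 0.8 / 99
  den <- 0.8 * 0.8 + 0.2 * 0.2
  expect_equal(hudson_fst(0.8, 100, 0.2, 100), num / den, tolerance = 1e-12)
  # both fixed for the same allele: undefined, flagged missing
  expect_true(is.na(hudson_fst(0, 100, 0, 100)))
  expect_error(hudson_fst(1.2, 10, 0.5, 10), "\\[0, 1\\]")
})

test_that("PBS follows its branch-length formula, negatives retained", {
  expect_equal(pbs(0, 0, 0), 0)
  expect_equal(pbs(0.1, 0.1, 0), -log(0.9), tolerance = 1e-12)
  expect_equal(pbs(0, 0, 0.5), log(0.5) / 2, tolerance = 1e-12)
  expect_lt(pbs(0, 0, 0.5), 0)
  expect_true(is.na(pbs(NA, 0.1, 0.1)))
  # regression against the hand formula on random inputs
  set.seed(1)
  f <- matrix(runif(30, 0, 0.9), ncol = 3)
  expect_equal(pbs(f[, 1], f[, 2], f[, 3]),
               (-log(1 - f[, 1]) - log(1 - f[, 2]) + log(1 - f[, 3])) / 2,
               tolerance = 1e-12)
})

test_that("EHH matches combinatorial counting on toys", {
  # all haplotypes identical: EHH stays 1
  p1 <- toy_panel(matrix(rep(c(0, 1, 0, 1), 4), 4, byrow = TRUE))
  expect_true(all(ehh(p1, 1, "right")$ehh == 1))
  # four haplotypes split 2/2 into two extended types: EHH = 2/6
  H <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 1), c(1, 1, 1))
  p2 <- toy_panel(H)
  expect_equal(ehh(p2, 1, "right")$ehh, c(1, 1, 1 / 3, 1 / 3))
  # two distinct haplotypes: 0 beyond the first mismatch
  p3 <- toy_panel(rbind(c(0, 0, 1), c(0, 1, 1)))
  expect_equal(ehh(p3, 1, "right")$ehh, c(1, 1, 0, 0))
  expect_error(ehh(p2, 9), "out of range")
})

test_that("EHH agrees with brute-force pair counting and never increases", {
  sim <- small_sim(seed = 31, S = 40, n = c(8, 4, 4))
  H <- sim$panel$H[hap_rows(sim$panel, "TARGET"), ]
  core <- 20
  for (dir in c("right", "left")) {
    curve <- ehh(sim$panel, core, dir, pop = "TARGET")
    expect_equal(curve$ehh[1], 1)
    expect_true(all(diff(curve$ehh) <= 1e-12))
    brute <- vapply(curve$index[-1], function(to) brute_ehh(H, core, to),
                    numeric(1))
    expect_equal(curve$ehh[-1], brute, tolerance = 1e-9)
  }
})

test_that("XP-EHH is symmetric, standardized and flags sweeps", {
  sim <- small_sim(seed = 32, S = 300, L = 2e5, n = c(15, 15, 4))
  # identical target and reference panels: raw scores all 0
  p <- sim$panel
  twin <- haplotype_panel(p$chrom, p$positions,
                          rbind(p$H[hap_rows(p, "TARGET"), ],
                                p$H[hap_rows(p, "TARGET"), ]),
                          sprintf("X%02d", 1:30),
                          rep(c("TARGET", "REF"), each = 15))
  xt <- xpehh(twin)
  expect_true(all(abs(xt$raw[!xt$missing]) < 1e-12))
  # all raw scores identical: centred scores are all zero
  expect_true(all(abs(xt$xpehh[!xt$missing]) < 1e-12))
  # swapping target and reference negates every raw score
  fwd <- xpehh(p, "TARGET", "REF")
  rev <- xpehh(p, "REF", "TARGET")
  expect_equal(fwd$raw, -rev$raw, tolerance = 1e-9)
})

test_that("D statistic has its symmetry, extreme and antisymmetry behavior", {
  set.seed(2)
  pW <- runif(300); pX <- pW; pY <- runif(300); pZ <- runif(300)
  expect_equal(d_statistic(pW, pX, pY, pZ, 50)$D, 0)
  expect_equal(d_statistic(0, 1, 1, 0, 1)$D, 1)
  pX2 <- runif(300)
  d1 <- d_statistic(pW, pX2, pY, pZ, 50)
  d2 <- d_statistic(pX2, pW, pY, pZ, 50)
  expect_equal(d1$D, -d2$D, tolerance = 1e-12)
  expect_gt(d1$se, 0)
  # brute-force formula oracle
  abba <- (1 - pW) * pX2 * pY * (1 - pZ)
  baba <- pW * (1 - pX2) * pY * (1 - pZ)
  expect_equal(d1$D, sum(abba - baba) / sum(abba + baba), tolerance = 1e-12)
  expect_true(is.na(d_statistic(0, 0, 0, 0, 1)$D))
})
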