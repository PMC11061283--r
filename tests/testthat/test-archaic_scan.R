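# hand-built archaic reference panel: derived alleles per pseudo-individual
mini_archaic <- function(positions, nea_sites, den_sites) {
  S <- length(positions)
  H <- matrix(0L, 8, S)
  for (k in 1:3) H[c(2 * k - 1, 2 * k), positions %in% nea_sites] <- 1L
  H[7:8, positions %in% den_sites] <- 1L
  haplotype_panel("chr1", positions, H, c("NEA1", "NEA2", "NEA3", "DEN"),
                  c("NEA1", "NEA2", "NEA3", "DEN"))
}

test_that("no private variation yields no segments", {
  sim <- small_sim(seed = 41, S = 60, L = 4e4, n = c(4, 4, 4))
  p <- sim$panel
  # make the outgroup carry every derived allele somewhere
  rows <- hap_rows(p, "OUT")
  p$H[rows[1], ] <- 1L
  segs <- detect_segments(p, 1, "OUT")
  expect_equal(nrow(segs), 0)
})

test_that("posterior decoding matches brute-force path enumeration", {
  # <= 12 windows, fixed initial parameters (one EM sweep's E-step)
  counts <- c(0, 0, 1, 4, 5, 3, 0, 0, 1, 0)
  cfg <- hmm_config(max_iter = 1)
  fit <- sweepscan:::fit_poisson_hmm(counts, cfg)
  expect_equal(rowSums(fit$posterior), rep(1, length(counts)),
               tolerance = 1e-12)
  mu <- mean(counts)
  lam <- c(max(mu * 0.5, 1e-3), max(mu * 3, mu + 1, 0.5))
  A <- matrix(c(0.999, 0.001, 0.025, 0.975), 2, byrow = TRUE)
  init <- c(0.98, 0.02)
  Tn <- length(counts)
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  pp <- apply(paths, 1, function(st) {
    pr <- init[st[1]] * dpois(counts[1], lam[st[1]])
    for (t in 2:Tn) {
      pr <- pr * A[st[t - 1], st[t]] * dpois(counts[t], lam[st[t]])
    }
    pr
  })
  brute <- vapply(seq_len(Tn), function(t) {
    sum(pp[paths[, t] == 2]) / sum(pp)
  }, numeric(1))
  expect_equal(fit$posterior[, 2], brute, tolerance = 1e-9)
})

test_that("planted tracts are recovered with high overlap", {
  sim <- small_sim(seed = 42, S = 1200, L = 8e5, n = c(20, 15, 15))
  ar <- inject_archaic(sim$panel, sim$truth,
                       list(archaic_source("NEA", alpha = 0.4, lambda = 4e4,
                                           d = 0.001, focal = 4e5)),
                       seed = 5)
  segs <- detect_segments_all(ar$panel, "TARGET", "OUT")
  tr <- ar$truth$tracts
  ov <- vapply(seq_len(nrow(tr)), function(i) {
    s <- segs[segs$hap == tr$hap[i], , drop = FALSE]
    if (!nrow(s)) return(0)
    max(pmax(0, pmin(s$end, tr$end[i]) - pmax(s$start, tr$start[i]) + 1)) /
      (tr$end[i] - tr$start[i] + 1)
  }, numeric(1))
  expect_gt(mean(ov), 0.7)
  expect_true(all(segs$mean_prob >= 0.8))
})

test_that("region filtering enforces full overlap and archaic sharing", {
  segs <- data.frame(hap = c("a", "b", "c"),
                     start = c(1000, 2000, 500),
                     end = c(5000, 6001, 4000),
                     mean_prob = 0.9, n_asnp = 1,
                     stringsAsFactors = FALSE)
  segs$asnp <- list(c(1500, 2500), c(3000), c(800))
  arch <- mini_archaic(c(800, 1500, 2500, 3000), nea_sites = c(1500),
                       den_sites = numeric(0))
  region <- data.frame(start = 600, end = 6000)
  kept <- filter_for_region(segs, region, arch)
  # b extends 1 bp past the region; c starts before it; a shares an aSNP
  expect_equal(kept$hap, "a")
  # a segment whose aSNPs miss every archaic panel is dropped
  segs2 <- segs[1, ]; segs2$asnp <- list(c(9999))
  expect_equal(nrow(filter_for_region(segs2, region, arch)), 0)
})

test_that("ancestry assignment follows the shared-aSNP majority rule", {
  pos <- seq(100, 1000, by = 100)
  arch <- mini_archaic(pos, nea_sites = c(100, 200, 300, 400),
                       den_sites = c(500, 600, 700, 800, 900))
  expect_equal(assign_ancestry(c(500, 600, 700, 800, 900, 100, 200), arch),
               "Denisova")
  expect_equal(assign_ancestry(c(100, 200, 300, 400), arch), "Neanderthal")
  # three shared with each: ambiguous
  expect_equal(assign_ancestry(c(100, 200, 300, 500, 600, 700), arch),
               "ambiguous")
  expect_error(assign_ancestry(numeric(0), arch), "empty aSNP set")
})

test_that("clustering groups linked aSNPs and counts carrier chromosomes", {
  # 10 target chromosomes; two unlinked aSNP groups carried by disjoint sets
  S <- 8
  H <- matrix(0L, 10, S)
  H[1:4, 1:2] <- 1L   # group 1: sites 1-2 on chromosomes 1-4
  H[7:10, 5:6] <- 1L  # group 2: sites 5-6 on chromosomes 7-10
  positions <- seq(1000, by = 1000, length.out = S)
  p <- toy_panel(H, positions = positions)
  segs <- data.frame(hap = rownames(p$H)[c(1, 2, 3, 4, 7, 8, 9, 10)],
                     start = 500, end = 8500, mean_prob = 0.9, n_asnp = 2,
                     stringsAsFactors = FALSE)
  segs$asnp <- c(rep(list(c(1000, 2000)), 4), rep(list(c(5000, 6000)), 4))
  arch <- mini_archaic(positions, nea_sites = c(1000, 2000),
                       den_sites = c(5000, 6000))
  cl <- cluster_haplotypes(segs, p, arch, target = "TARGET",
                           candidate_pos = 1000)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$freq), c(0.4, 0.4))
  expect_setequal(cl$ancestry, c("Neanderthal", "Denisova"))
  # brute-force frequency: carriers / chromosomes
  expect_equal(cl$freq[1], length(unique(segs$hap[1:4])) / 10)
  # candidate at an aSNP of group 1: r2 = 1 flags high LD
  expect_equal(max(cl$max_r2_candidate), 1)
  # all segments sharing one aSNP set collapse to a single cluster
  segs1 <- segs[1:4, ]
  cl1 <- cluster_haplotypes(segs1, p, arch, target = "TARGET")
  expect_equal(nrow(cl1), 1)
  expect_equal(cl1$freq, 0.4)
})
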