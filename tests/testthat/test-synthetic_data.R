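test_that("panel simulation is a pure function of the config", {
  cfg <- sim_config(seed = 9, S = 120, L = 6e4, n_target = 8, n_ref = 8,
                    n_out = 6)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel$H, b$panel$H)
  expect_identical(a$panel$positions, b$panel$positions)
  expect_error(sim_config(S = 19), ">= 20")
})

test_that("zero switch rate collapses every haplotype onto one founder", {
  cfg <- sim_config(seed = 2, S = 150, L = 8e4, n_target = 15, n_ref = 5,
                    n_out = 5, K = 6, rho = 0)
  p <- simulate_panel(cfg)$panel
  for (pop in c("TARGET", "REF", "OUT")) {
    H <- p$H[hap_rows(p, pop), ]
    expect_lte(nrow(unique(H)), 6)
  }
})

test_that("without drift the two populations are undifferentiated", {
  # Balding-Nichols property: F_target = F_ref = 0 gives mean FST ~ 0
  cfg <- sim_config(seed = 4, S = 600, L = 3e5, n_target = 200, n_ref = 200,
                    n_out = 5, F_target = 0, F_ref = 0, K = 400)
  p <- simulate_panel(cfg)$panel
  fst <- hudson_fst(daf(p, "TARGET"), 400, daf(p, "REF"), 400)
  expect_lt(mean(fst, na.rm = TRUE), 0.01)
})

test_that("drift parameter F sets the expected differentiation level", {
  cfg <- sim_config(seed = 6, S = 1000, L = 5e5, n_target = 100, n_ref = 100,
                    n_out = 5, F_target = 0.05, F_ref = 0.05, K = 300)
  p <- simulate_panel(cfg)$panel
  fst <- hudson_fst(daf(p, "TARGET"), 200, daf(p, "REF"), 200)
  # differentiation of order F (founder-count rounding damps it slightly)
  expect_gt(mean(fst, na.rm = TRUE), 0.025)
  expect_lt(mean(fst, na.rm = TRUE), 0.16)
})

test_that("sweep injection hits the requested frequency in the target only", {
  sim <- small_sim(seed = 11, S = 600, L = 3e5)
  ref_before <- sim$panel$H[hap_rows(sim$panel, "REF"), ]
  out_before <- sim$panel$H[hap_rows(sim$panel, "OUT"), ]
  sw <- inject_sweep(sim$panel, sim$truth, sweep_spec(pos = 1.5e5, f = 0.9),
                     seed = 1)
  j <- sw$truth$sweep$index
  expect_lte(abs(daf(sw$panel, "TARGET")[j] - 0.9), 1 / (2 * 20))
  expect_identical(sw$panel$H[hap_rows(sw$panel, "REF"), ], ref_before)
  expect_identical(sw$panel$H[hap_rows(sw$panel, "OUT"), ], out_before)
  # no spec: identity
  id <- inject_sweep(sim$panel, sim$truth, NULL)
  expect_identical(id$panel$H, sim$panel$H)
})

test_that("swept carriers show elevated haplotype homozygosity at 10 kb", {
  sim <- small_sim(seed = 12, S = 800, L = 4e5, n = c(30, 20, 10))
  sw <- inject_sweep(sim$panel, sim$truth, sweep_spec(pos = 2e5, f = 0.6),
                     seed = 2)
  j <- sw$truth$sweep$index
  rows <- hap_rows(sw$panel, "TARGET")
  carriers <- rows[sw$panel$H[rows, j] == 1L]
  noncar <- setdiff(rows, carriers)
  at_10kb <- function(curve) {
    idx <- which(abs(curve$pos - curve$pos[1]) >= 1e4)[1]
    if (is.na(idx)) tail(curve$ehh, 1) else curve$ehh[idx]
  }
  e_car <- at_10kb(ehh(sw$panel, j, "right", rows = carriers))
  e_non <- at_10kb(ehh(sw$panel, j, "right", rows = noncar))
  expect_gt(e_car, e_non)
})

test_that("archaic injection plants outgroup-absent tracts at the right density", {
  sim <- small_sim(seed = 13, S = 700, L = 5e5, n = c(25, 20, 20))
  src <- list(archaic_source("NEA", alpha = 0.4, lambda = 3e4, d = 0.001,
                             focal = 2e5),
              archaic_source("DEN", alpha = 0.3, lambda = 3e4, d = 0.001,
                             focal = 4e5))
  ar <- inject_archaic(sim$panel, sim$truth, src, seed = 3)
  tr <- ar$truth$tracts
  expect_true(all(tr$start >= 1 & tr$end <= 5e5))
  expect_equal(sum(tr$source == "NEA"), round(0.4 * 50))
  # archaic-private derived alleles are absent from the outgroup by design
  new_sites <- setdiff(ar$panel$positions, sim$panel$positions)
  idx <- match(new_sites, ar$panel$positions)
  expect_true(all(dac(ar$panel, "OUT")[idx] == 0))
  # mean private-variant count inside tracts ~ d * lambda
  mask <- outgroup_absent(ar$panel, "OUT")
  npriv <- vapply(seq_len(nrow(tr)), function(i) {
    h <- match(tr$hap[i], rownames(ar$panel$H))
    sum(mask & ar$panel$H[h, ] == 1L &
          ar$panel$positions >= tr$start[i] &
          ar$panel$positions <= tr$end[i])
  }, numeric(1))
  lens <- tr$end - tr$start + 1
  expect_gt(sum(npriv) / sum(lens), 0.001 * 0.5)
  expect_lt(sum(npriv) / sum(lens), 0.001 * 2)
})

test_that("archaic injection honours degenerate settings", {
  sim <- small_sim(seed = 14, S = 100, L = 6e4, n = c(5, 5, 5))
  off <- list(archaic_source("NEA", alpha = 0, focal = 3e4),
              archaic_source("DEN", alpha = 0, focal = 3e4))
  ar <- inject_archaic(sim$panel, sim$truth, off, seed = 1)
  expect_identical(ar$panel$H, sim$panel$H)
  expect_equal(nrow(ar$truth$tracts), 0)
  bad <- list(archaic_source("NEA", lambda = 1e5, focal = 3e4))
  expect_error(inject_archaic(sim$panel, sim$truth, bad, seed = 1),
               "tract mean length")
})

test_that("phenotype simulation is seeded and validates noise", {
  sim <- small_sim(seed = 15, S = 60, n = c(10, 10, 5))
  spec <- phenotype_spec(causal = data.frame(pos = 3e4, beta = 2,
                                             phenotype = "heart_rate"))
  a <- simulate_phenotypes(sim$panel, spec, seed = 4)
  b <- simulate_phenotypes(sim$panel, spec, seed = 4)
  expect_identical(a, b)
  expect_named(a, c("sample_id", "population", "age", "sex", "height",
                    names(phenotype_groups())), ignore.order = FALSE)
  expect_error(phenotype_spec(sigma = 0), "sigma")
})

test_that("association lookup table plants the requested significant sites", {
  phen <- data.frame(phenotype = c("rbc", "height"),
                     category = c("blood_count", "other"))
  tab <- simulate_assoc_table(seq(1000, 20000, by = 1000), phen,
                              blood_sig_pos = c(2000, 5000, 9000, 12000,
                                                15000),
                              seed = 8)
  planted <- tab[tab$p < 1e-10, ]
  expect_setequal(planted$pos, c(2000, 5000, 9000, 12000, 15000))
  expect_true(all(planted$category == "blood_count"))
  expect_identical(tab, simulate_assoc_table(seq(1000, 20000, by = 1000),
                                             phen,
                                             blood_sig_pos = c(2000, 5000,
                                                               9000, 12000,
                                                               15000),
                                             seed = 8))
  expect_error(simulate_assoc_table(1:10, phen[0, ]), "non-empty")
  expect_error(simulate_assoc_table(1:10, data.frame(phenotype = "a",
                                                     category = "other")),
               "blood_count")
})
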