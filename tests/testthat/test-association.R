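test_that("phenotype correction is exact OLS with orthogonal residuals", {
  set.seed(20)
  n <- 60
  cov <- data.frame(age = runif(n, 18, 65), sex = rbinom(n, 1, 0.5),
                    height = rnorm(n, 160, 8))
  # phenotype exactly linear in age: residuals vanish
  y <- 3 + 0.5 * cov$age
  expect_lt(max(abs(correct_phenotype(y, cov, "age+sex"))), 1e-10)
  # residuals orthogonal to every covariate
  y2 <- rnorm(n, 50, 5)
  r <- correct_phenotype(y2, cov, "age+sex+height")
  expect_lt(abs(sum(r * cov$age)), 1e-8)
  expect_lt(abs(sum(r * cov$sex)), 1e-8)
  expect_lt(abs(sum(r * cov$height)), 1e-8)
  expect_equal(mean(r), 0, tolerance = 1e-10)
  # missing phenotypes propagate
  y3 <- y2; y3[c(4, 9)] <- NA
  r3 <- correct_phenotype(y3, cov, "age+sex")
  expect_true(all(is.na(r3[c(4, 9)])))
  # collinearity is a hard error
  cov2 <- cov; cov2$height <- 2 * cov2$age
  expect_error(correct_phenotype(y2, cov2, "age+sex+height"), "collinear")
})

test_that("kinship is the centred cross-product", {
  set.seed(21)
  G <- matrix(rbinom(50 * 30, 2, 0.4), 50, 30)
  K <- kinship_matrix(G)
  W <- sweep(G, 2, colMeans(G))
  expect_equal(K, W %*% t(W) / 30, tolerance = 1e-12)
  expect_equal(K, t(K), tolerance = 1e-12)
})

test_that("LMM collapses to ordinary least squares when K is identity", {
  set.seed(22)
  n <- 80
  g <- rbinom(n, 2, 0.5)
  y <- 0.4 * g + rnorm(n)
  r <- lmm_assoc(g, y, diag(n))
  ols <- summary(lm(y ~ g))$coefficients["g", ]
  expect_lt(abs(r$beta - ols["Estimate"]), 1e-6)
  expect_equal(r$p, ols["Pr(>|t|)"], tolerance = 1e-4, ignore_attr = TRUE)
  # monomorphic SNP: flagged, no test
  expect_true(lmm_assoc(rep(2, n), y, diag(n))$flagged)
})

test_that("LMM absorbs confounding structure that misleads OLS", {
  set.seed(23)
  sim <- small_sim(seed = 23, S = 400, L = 2e5, n = c(40, 40, 5),
                   F_target = 0.08, F_ref = 0.08)
  p <- subset_panel(sim$panel, c("TARGET", "REF"))
  K <- panel_kinship(p)
  # structured phenotype: population mean difference only
  y <- ifelse(p$population == "TARGET", 1, 0) * 2 + rnorm(80)
  daf_gap <- abs(daf(p, "TARGET") - daf(p, "REF"))
  j <- which.max(daf_gap) # the most stratified SNP
  g <- genotype_vector(p, j)
  p_ols <- summary(lm(y ~ g))$coefficients["g", "Pr(>|t|)"]
  p_lmm <- lmm_assoc(g, y, K)$p
  expect_gt(p_lmm, p_ols) # mixed model deflates the stratification signal
})

test_that("planted effects are detected with the study's sample size", {
  set.seed(24)
  n <- 230
  g <- rbinom(n, 2, 0.5)
  ps <- replicate(10, {
    y <- g * 1 + rnorm(n, 0, 1) # beta = 1 residual sd at DAF 0.5
    lmm_assoc(g, y, diag(n))$p
  })
  expect_lt(median(ps), 0.01)
})

test_that("BH adjustment and two-tier calls match the hand procedure", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.9)
  out <- adjust_and_call(p)
  expect_equal(out$p_adj, brute_bh(p), tolerance = 1e-12)
  expect_true(all(out$p_adj >= out$p))
  expect_equal(adjust_and_call(0.046)$p_adj, 0.046) # single SNP: unchanged
  expect_true(adjust_and_call(0.046)$suggestive)
  expect_false(adjust_and_call(0.046)$strict) # 0.046 < 0.05 but > 0.01
  expect_false(any(adjust_and_call(rep(1, 5))$suggestive))
  # monotone in the raw p-values
  set.seed(25)
  pr <- sort(runif(50))
  expect_true(all(diff(adjust_and_call(pr)$p_adj) >= -1e-12))
})

test_that("the association wrapper ties the stages together", {
  sim <- small_sim(seed = 26, S = 150, L = 8e4, n = c(25, 25, 5))
  spec <- phenotype_spec(causal = data.frame(pos = 4e4, beta = 8,
                                             phenotype = "heart_rate"),
                         sigma = 2)
  phen <- simulate_phenotypes(sim$panel, spec, seed = 6)
  j <- which.min(abs(sim$panel$positions - 4e4))
  daf_all <- colMeans(sim$panel$H)
  extra <- order(abs(daf_all - 0.5))[1:3]
  res <- association_tests(sim$panel, unique(c(j, extra)), phen)
  hr <- res[res$phenotype == "heart_rate" & res$index == j, ]
  if (var(genotype_vector(sim$panel, j)) > 0) {
    expect_lt(hr$p_adj, 0.05)
  }
  expect_true(all(c("beta", "p", "p_adj", "suggestive", "strict") %in%
                    names(res)))
})
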