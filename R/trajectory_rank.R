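#' Wright-Fisher allele-frequency-trajectory likelihood model
#'
#' A hidden Markov model on a discretized allele-frequency grid: `B` bins on
#' (0, 1), uniform initial distribution `G` generations ago, per-generation
#' transitions `Normal(x + s x(1-x), x(1-x)/(2 Ne))` discretized on the grid
#' with absorbing near-boundary bins, and a single binomial emission of the
#' present-day derived count. The likelihood-ratio score
#' `logLR = ln max_s L(s) - ln L(0)` (non-negative by construction, since the
#' selection grid contains 0) summarizes the support for a non-neutral
#' trajectory. The per-`s` final-generation frequency distributions depend
#' only on the model, so they are precomputed once at construction.
#'
#' @param G Generations of trajectory modelled (default 980; at 28 years per
#'   generation this is the last 27,440 years).
#' @param Ne Effective population size (default 1e4).
#' @param B Frequency bins (>= 50).
#' @param s_grid Selection-coefficient grid; must contain 0 (positive
#'   selection focus by default: 0 to 0.1 in steps of 0.002).
#' @param gen_years Years per generation (used only for reporting).
#' @return A `trajectory_model` with precomputed final distributions.
#' @export
trajectory_model <- function(G = 980L, Ne = 1e4, B = 50L,
                             s_grid = seq(0, 0.1, by = 0.002),
                             gen_years = 28) {
  if (B < 50L) stop("B must be >= 50")
  if (G < 1L) stop("G must be >= 1")
  if (!any(s_grid == 0)) stop("s grid must include 0")
  centers <- (seq_len(B) - 0.5) / B
  PI <- vapply(s_grid, function(s) {
    v <- rep(1 / B, B)
    Tm <- wf_transition(s, Ne, B)
    for (g in seq_len(G)) v <- as.vector(v %*% Tm)
    v
  }, numeric(B))
  structure(list(G = as.integer(G), Ne = Ne, B = as.integer(B),
                 s_grid = s_grid, gen_years = gen_years,
                 centers = centers, final_dist = PI),
            class = "trajectory_model")
}

#' Discretized per-generation Wright-Fisher transition matrix
#'
#' Row `i` holds the transition probabilities from bin `i` under selection
#' coefficient `s`; the first and last bins are absorbing (loss/fixation
#' neighbourhoods). Rows sum to one.
#'
#' @param s Selection coefficient.
#' @param Ne Effective population size.
#' @param B Number of frequency bins.
#' @return A `B x B` stochastic matrix.
#' @export
wf_transition <- function(s, Ne, B) {
  centers <- (seq_len(B) - 0.5) / B
  edges <- seq_len(B - 1) / B
  Tm <- matrix(0, B, B)
  Tm[1L, 1L] <- 1; Tm[B, B] <- 1
  for (i in seq(2L, B - 1L)) {
    x <- centers[i]
    mu <- x + s * x * (1 - x)
    sd <- sqrt(x * (1 - x) / (2 * Ne))
    Tm[i, ] <- diff(c(0, stats::pnorm(edges, mu, sd), 1))
  }
  Tm
}

#' Trajectory likelihood ratio for one SNP
#'
#' Scores the support for positive selection from the present-day derived
#' count. Run-to-run stochasticity comes from bootstrap resampling of the `n`
#' sampled chromosomes (the resampled count `k*` is binomial around `k/n`);
#' if the resample is fixed (0 or n) it is retried up to `retries` times,
#' after which the SNP is flagged unscorable (`NA`).
#'
#' @param model A [trajectory_model()].
#' @param k Present-day derived allele count.
#' @param n Sampled chromosomes.
#' @param resample Bootstrap the sample before scoring (default `TRUE`; with
#'   `FALSE` the observed count is scored directly and the result is
#'   deterministic).
#' @param retries Resampling retries on a fixed resample.
#' @return List with `loglr` (>= 0, or `NA` if unscorable), `s_hat` (argmax
#'   of the selection grid) and `k` (the count actually scored).
#' @export
wf_loglr <- function(model, k, n, resample = TRUE, retries = 10L) {
  stopifnot(inherits(model, "trajectory_model"))
  ks <- k
  if (resample) {
    ks <- -1L
    for (r in seq_len(retries)) {
      cand <- stats::rbinom(1L, n, k / n)
      if (cand > 0L && cand < n) { ks <- cand; break }
    }
    if (ks < 0L) {
      return(list(loglr = NA_real_, s_hat = NA_real_, k = NA_integer_))
    }
  } else if (ks <= 0L || ks >= n) {
    return(list(loglr = NA_real_, s_hat = NA_real_, k = as.integer(ks)))
  }
  e <- stats::dbinom(ks, n, model$centers)
  ll <- log(colSums(model$final_dist * e))
  i <- which.max(ll)
  list(loglr = ll[i] - ll[model$s_grid == 0], s_hat = model$s_grid[i],
       k = as.integer(ks))
}

#' Simulate a present-day derived count from the model's trajectory chain
#'
#' Walks the discretized Wright-Fisher chain from the uniform initial
#' distribution for `G` generations under selection coefficient `s` and emits
#' a binomial sample of size `n` -- the generative process the likelihood in
#' [wf_loglr()] inverts, used for calibration and parameter-recovery
#' experiments.
#'
#' @param model A [trajectory_model()].
#' @param s True selection coefficient.
#' @param n Chromosomes sampled at the final generation.
#' @return Integer derived count in `0..n`.
#' @export
wf_simulate <- function(model, s, n) {
  B <- model$B
  Tm <- wf_transition(s, model$Ne, B)
  i <- sample.int(B, 1L)
  for (g in seq_len(model$G)) {
    if (i == 1L || i == B) break # absorbing
    i <- sample.int(B, 1L, prob = Tm[i, ])
  }
  stats::rbinom(1L, n, model$centers[i])
}

#' Rank the SNPs of a candidate region by trajectory likelihood ratio
#'
#' Implements the two-stage multi-run ranking: every eligible SNP (derived
#' allele frequency >= 0.05 in the target population and not fixed) is scored
#' `n_stage1` times with distinct bootstrap resamples and the run logLRs are
#' averaged; the top five SNPs by stage-1 mean are scored `n_stage2`
#' additional times, and the SNP with the highest mean logLR over those runs
#' is the region's candidate. Ties break to the lower position. The full
#' audit trail (per-run logLRs for both stages) is retained.
#'
#' @param region One-row data.frame with `start`, `end` (1-based inclusive).
#' @param panel A [haplotype_panel()].
#' @param model A [trajectory_model()].
#' @param target Target population label.
#' @param n_stage1,n_stage2 Run counts (defaults 5 and 50).
#' @param min_daf Eligibility threshold on target DAF (default 0.05).
#' @param seed Seed for the run schedule (deterministic given the seed).
#' @return List with `candidate` (one-row data.frame, or `NULL` if the
#'   region has no eligible SNP), `stage1` and `stage2` tables.
#' @export
rank_candidates <- function(region, panel, model, target = "TARGET",
                            n_stage1 = 5L, n_stage2 = 50L, min_daf = 0.05,
                            seed = 1L) {
  force(region); force(panel); force(model) # force promises before seeding
  set.seed(seed)
  rows <- hap_rows(panel, target)
  n <- length(rows)
  in_region <- which(panel$positions >= region$start &
                     panel$positions <= region$end)
  kcount <- colSums(panel$H[rows, in_region, drop = FALSE])
  f <- kcount / n
  eligible <- in_region[f >= min_daf & f < 1]
  kcount <- kcount[f >= min_daf & f < 1]
  if (!length(eligible)) {
    return(list(candidate = NULL,
                stage1 = data.frame(), stage2 = data.frame()))
  }
  score_runs <- function(j, k, nrun) {
    vapply(seq_len(nrun), function(r) wf_loglr(model, k, n)$loglr, numeric(1))
  }
  s1 <- do.call(rbind, lapply(seq_along(eligible), function(i) {
    runs <- score_runs(eligible[i], kcount[i], n_stage1)
    data.frame(index = eligible[i], pos = panel$positions[eligible[i]],
               daf = kcount[i] / n,
               loglr_mean = mean(runs, na.rm = TRUE),
               n_scored = sum(!is.na(runs)),
               t(stats::setNames(runs, paste0("run", seq_along(runs)))))
  }))
  s1$loglr_mean[s1$n_scored == 0L] <- NA_real_
  ord <- order(-ifelse(is.na(s1$loglr_mean), -Inf, s1$loglr_mean), s1$pos)
  top5 <- s1[ord, ][seq_len(min(5L, nrow(s1))), ]
  s2 <- do.call(rbind, lapply(seq_len(nrow(top5)), function(i) {
    j <- top5$index[i]
    k <- round(top5$daf[i] * n)
    runs <- score_runs(j, k, n_stage2)
    data.frame(index = j, pos = top5$pos[i], daf = top5$daf[i],
               loglr_mean50 = mean(runs, na.rm = TRUE),
               n_scored = sum(!is.na(runs)))
  }))
  ord2 <- order(-ifelse(is.na(s2$loglr_mean50), -Inf, s2$loglr_mean50), s2$pos)
  win <- s2[ord2[1L], ]
  cand <- data.frame(pos = win$pos, index = win$index, daf = win$daf,
                     loglr_mean5 = s1$loglr_mean[s1$index == win$index],
                     loglr_mean50 = win$loglr_mean50,
                     stringsAsFactors = FALSE)
  list(candidate = cand, stage1 = s1, stage2 = s2)
}
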