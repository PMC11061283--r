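#' Sweep-recovery experiment at study scale
#'
#' Repeats the full scan on independently simulated panels at the study's
#' sample sizes (54 target + 74 reference diploids, 5,000 SNPs) with one
#' injected hard sweep at derived-allele frequency 0.9, and measures how
#' often the focal SNP falls inside a final merged candidate region and how
#' often the trajectory ranking picks it as the region's candidate SNP.
#' Additional null replicates (no sweep) count significant regions against
#' the nominal per-method thresholds.
#'
#' @param n_seeds Sweep replicates (default 20).
#' @param n_null Null replicates (default 10).
#' @param base_seed Seed offset; replicate i uses `base_seed * 1000 + i`.
#' @param model A [trajectory_model()] (built once; default model if NULL).
#' @return List with `hit_rate`, `pick_rate`, `null_mean_regions`,
#'   `null_expected_regions`, and per-replicate detail tables.
#' @export
experiment_scan_recovery <- function(n_seeds = 20L, n_null = 10L,
                                     base_seed = 1L, model = NULL) {
  if (is.null(model)) model <- trajectory_model()
  cfg <- scan_config()
  detail <- data.frame(seed = integer(), hit = logical(), pick = logical())
  for (i in seq_len(n_seeds)) {
    s <- base_seed * 1000L + i
    sim <- simulate_panel(sim_config(seed = s))
    sw <- inject_sweep(sim$panel, sim$truth, sweep_spec(pos = 1e6, f = 0.9),
                       seed = s + 1L)
    scan <- selection_scan(sw$panel, config = cfg, seed = s + 2L)
    fp <- sw$truth$sweep$pos
    hit <- nrow(scan$final) > 0 &&
      any(scan$final$start <= fp & scan$final$end >= fp)
    pick <- FALSE
    if (hit) {
      reg <- scan$final[scan$final$start <= fp & scan$final$end >= fp, ][1L, ]
      rc <- rank_candidates(reg, sw$panel, model, seed = s + 3L)
      pick <- !is.null(rc$candidate) && rc$candidate$pos == fp
    }
    detail <- rbind(detail, data.frame(seed = s, hit = hit, pick = pick))
  }
  null_counts <- integer(0)
  null_expected <- numeric(0)
  for (i in seq_len(n_null)) {
    s <- base_seed * 1000L + 500L + i
    sim <- simulate_panel(sim_config(seed = s))
    scan <- selection_scan(sim$panel, config = cfg, seed = s + 2L)
    null_counts <- c(null_counts, nrow(scan$final))
    n_windows <- nrow(scan$windows)
    n_snps <- sum(!is.na(scan$track$xpehh))
    null_expected <- c(null_expected,
                       cfg$p_thresholds[["Fisher"]] * n_windows +
                         cfg$p_thresholds[["PBS"]] * n_windows +
                         cfg$p_thresholds[["XPEHH"]] * n_snps)
  }
  list(hit_rate = mean(detail$hit), pick_rate = mean(detail$pick),
       null_mean_regions = mean(null_counts),
       null_expected_regions = mean(null_expected),
       detail = detail, null_counts = null_counts)
}

#' Introgression-recovery experiment
#'
#' Injects archaic tracts from two divergent sources (defaults: admixture
#' fraction 0.4, mean tract length 40 kb, private-allele density 1e-3 per
#' bp) into independently simulated panels, detects segments with the
#' two-state HMM, and measures per-tract overlap, region-level ancestry
#' assignment and reported haplotype frequency against the truth records.
#'
#' @param n_seeds Replicates (default 20).
#' @param base_seed Seed offset.
#' @param alpha,lambda,d Injection parameters.
#' @return List with `mean_overlap`, `ancestry_match_rate`, `freq_mae`,
#'   `freq_within_0.1`, and per-replicate details.
#' @export
experiment_introgression_recovery <- function(n_seeds = 20L, base_seed = 1L,
                                              alpha = 0.4, lambda = 4e4,
                                              d = 0.001) {
  overlaps <- numeric(0)
  anc_ok <- logical(0)
  freq_err <- numeric(0)
  truth_anc <- c(NEA = "Neanderthal", DEN = "Denisova")
  for (i in seq_len(n_seeds)) {
    s <- base_seed * 1000L + 700L + i
    sim <- simulate_panel(sim_config(seed = s))
    ar <- inject_archaic(sim$panel, sim$truth,
                         list(archaic_source("NEA", alpha, lambda, d,
                                             focal = 6e5),
                              archaic_source("DEN", alpha, lambda, d,
                                             focal = 1.4e6)),
                         seed = s + 1L)
    segs <- detect_segments_all(ar$panel, "TARGET", "OUT")
    tr <- ar$truth$tracts
    ov <- vapply(seq_len(nrow(tr)), function(k) {
      ss <- segs[segs$hap == tr$hap[k], , drop = FALSE]
      if (!nrow(ss)) return(0)
      max(pmax(0, pmin(ss$end, tr$end[k]) - pmax(ss$start, tr$start[k]) + 1)) /
        (tr$end[k] - tr$start[k] + 1)
    }, numeric(1))
    overlaps <- c(overlaps, ov)
    for (src in c("NEA", "DEN")) {
      focal <- if (src == "NEA") 6e5 else 1.4e6
      region <- data.frame(start = focal - 1e5, end = focal + 1e5)
      kept <- filter_for_region(segs, region, ar$archaic)
      cl <- cluster_haplotypes(kept, ar$panel, ar$archaic)
      if (nrow(cl)) {
        anc_ok <- c(anc_ok, cl$ancestry[1L] == truth_anc[[src]])
        freq_err <- c(freq_err, abs(cl$freq[1L] - alpha))
      } else {
        anc_ok <- c(anc_ok, NA)
        freq_err <- c(freq_err, alpha) # nothing found: full miss
      }
    }
  }
  list(mean_overlap = mean(overlaps),
       frac_overlap_80 = mean(overlaps >= 0.8),
       ancestry_match_rate = mean(anc_ok, na.rm = TRUE),
       freq_mae = mean(freq_err),
       freq_within_0.1 = mean(freq_err <= 0.1))
}

#' Statistical-calibration experiment
#'
#' Checks (i) the resampling region significance against the exact
#' exceedance proportion on a 1,000-unit track at 1e5 draws, (ii) the blood
#' enrichment p-value against the exact hypergeometric tail at 1e5 draws,
#' and (iii) the mixed-model type-I error rate at nominal 5% over 200 null
#' phenotype simulations on a structured panel.
#'
#' @param base_seed Seed offset.
#' @param n_null LMM null simulations (default 200).
#' @return List with `resample_abs_err`, `enrich_abs_err`, `lmm_type1`.
#' @export
experiment_calibration <- function(base_seed = 1L, n_null = 200L) {
  set.seed(base_seed * 1000L + 900L)
  units <- stats::rnorm(1000)
  s0 <- stats::quantile(units, 0.95, names = FALSE)
  exact <- mean(units >= s0)
  p_mc <- resample_significance(s0, units, M = 1e5,
                                seed = base_seed * 1000L + 901L)
  resample_abs_err <- abs(p_mc - exact)

  set.seed(base_seed * 1000L + 902L)
  universe <- seq(1e4, by = 200, length.out = 200)
  blood <- sample(universe, 70)
  other <- setdiff(universe, blood)
  tab <- rbind(
    data.frame(pos = blood, phenotype = "rbc", category = "blood_count",
               beta = 0, p = 1e-15),
    data.frame(pos = other, phenotype = "misc", category = "other",
               beta = 0, p = 1e-15))
  cand <- c(sample(blood, 5), sample(other, 5))
  enr <- blood_enrichment_test(cand, tab, n_phen = 10, n_resamples = 1e5,
                               seed = base_seed * 1000L + 903L)
  hyper <- stats::phyper(enr$observed - 1, 70, 130, enr$x,
                         lower.tail = FALSE)
  enrich_abs_err <- abs(enr$p - hyper)

  sim <- simulate_panel(sim_config(seed = base_seed * 1000L + 904L,
                                   S = 600, L = 3e5, n_target = 80,
                                   n_ref = 80, n_out = 70,
                                   F_target = 0.05, F_ref = 0.05))
  panel <- sim$panel # 230 diploids across the three populations
  K <- panel_kinship(panel)
  ed <- lmm_eigen(K)
  g_daf <- colMeans(panel$H)
  test_sites <- which(g_daf > 0.1 & g_daf < 0.9)
  set.seed(base_seed * 1000L + 905L)
  n <- length(panel$sample_ids)
  rejections <- vapply(seq_len(n_null), function(i) {
    y <- stats::rnorm(n)
    j <- sample(test_sites, 1L)
    lmm_assoc(genotype_vector(panel, j), y, ed)$p < 0.05
  }, logical(1))
  list(resample_abs_err = resample_abs_err,
       enrich_abs_err = enrich_abs_err,
       lmm_type1 = mean(rejections), n_null = n_null)
}

#' Trajectory parameter-recovery experiment
#'
#' Simulates present-day derived counts from the trajectory model's own
#' generative chain at a true selection coefficient and recovers the
#' maximum-likelihood coefficient from each count; reports the median
#' absolute error. Counts fixed in the sample are redrawn (they are
#' unscorable by construction); also returns the neutral-vs-selected
#' rank-order check (median logLR under s = 0 against s = 0.02).
#'
#' @param n_traj Trajectories (default 50).
#' @param s_true True selection coefficient (default 0.05).
#' @param base_seed Seed offset.
#' @param model A [trajectory_model()]; default model if NULL.
#' @param n Chromosomes sampled per trajectory (default 108).
#' @return List with `median_abs_err`, `grid_step`, `s_hats`,
#'   `median_loglr_null`, `median_loglr_selected`.
#' @export
experiment_trajectory_recovery <- function(n_traj = 50L, s_true = 0.05,
                                           base_seed = 1L, model = NULL,
                                           n = 108L) {
  if (is.null(model)) model <- trajectory_model()
  set.seed(base_seed * 1000L + 950L)
  draw_scorable <- function(s) {
    for (r in 1:50) {
      k <- wf_simulate(model, s, n)
      if (k > 0 && k < n) return(k)
    }
    NA_integer_
  }
  s_hats <- vapply(seq_len(n_traj), function(i) {
    k <- draw_scorable(s_true)
    if (is.na(k)) return(NA_real_)
    wf_loglr(model, k, n, resample = FALSE)$s_hat
  }, numeric(1))
  lr_at <- function(s) {
    stats::median(vapply(seq_len(n_traj), function(i) {
      k <- draw_scorable(s)
      if (is.na(k)) return(NA_real_)
      wf_loglr(model, k, n, resample = FALSE)$loglr
    }, numeric(1)), na.rm = TRUE)
  }
  list(median_abs_err = stats::median(abs(s_hats - s_true), na.rm = TRUE),
       grid_step = min(diff(sort(unique(model$s_grid)))),
       s_hats = s_hats,
       median_loglr_null = lr_at(0),
       median_loglr_selected = lr_at(0.02))
}
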