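#' Scan configuration
#'
#' Defaults follow the standard windowed-scan recipe: sliding windows of 20
#' SNPs with a step of 5; top windows at the 99th percentile; merge gap 10 kb
#' (inclusive, measured between nearest bp endpoints); 50 kb flanks on the
#' top 10 windows per method; resampling p-value thresholds per method
#' (2e-5 XP-EHH, 2e-4 PBS, 2e-3 Fisher).
#'
#' @param window,step Window size and step in SNPs.
#' @param merge_gap Maximal bp gap merged (inclusive).
#' @param flank Flank extension in bp for final regions.
#' @param percentile Upper-tail retention percentile (0.99).
#' @param top_k Number of top regions per method carried forward.
#' @param p_thresholds Named vector of per-method resampling p cutoffs.
#' @param M_xpehh,M_other Resampling draw counts (SNP units / window units).
#' @return A `scan_config` list.
#' @export
scan_config <- function(window = 20L, step = 5L, merge_gap = 1e4,
                        flank = 5e4, percentile = 0.99, top_k = 10L,
                        p_thresholds = c(XPEHH = 2e-5, PBS = 2e-4,
                                         Fisher = 2e-3),
                        M_xpehh = 1e6, M_other = 1e5) {
  stopifnot(window >= 2L, step >= 1L, merge_gap >= 0, flank >= 0,
            percentile > 0, percentile < 1, top_k >= 1L,
            all(p_thresholds > 0 & p_thresholds < 1),
            M_xpehh >= 1, M_other >= 1)
  structure(list(window = as.integer(window), step = as.integer(step),
                 merge_gap = merge_gap, flank = flank,
                 percentile = percentile, top_k = as.integer(top_k),
                 p_thresholds = p_thresholds, M_xpehh = M_xpehh,
                 M_other = M_other),
            class = "scan_config")
}

#' Sliding windows over a per-SNP score track
#'
#' Windows start at SNP indices 1, 1+step, ... (after excluding
#' missing-score SNPs); a trailing remainder shorter than `window` SNPs
#' produces no window. The window PBS is the arithmetic mean of its SNPs'
#' PBS; the window XP-EHH is the maximum among them.
#'
#' @param track Data.frame with `chrom`, `pos` and score columns `pbs`
#'   and/or `xpehh`.
#' @param config A [scan_config()].
#' @return Data.frame of windows with bp span and window scores.
#' @export
make_windows <- function(track, config = scan_config()) {
  score_cols <- intersect(c("pbs", "xpehh"), names(track))
  if (!length(score_cols)) stop("track must carry a pbs and/or xpehh column")
  ok <- stats::complete.cases(track[, score_cols, drop = FALSE])
  track <- track[ok, , drop = FALSE]
  n <- nrow(track)
  if (n < config$window) {
    return(data.frame(chrom = character(), i_start = integer(),
                      i_end = integer(), start = numeric(), end = numeric()))
  }
  starts <- seq(1L, n - config$window + 1L, by = config$step)
  ends <- starts + config$window - 1L
  out <- data.frame(chrom = track$chrom[starts], i_start = starts,
                    i_end = ends, start = track$pos[starts],
                    end = track$pos[ends], stringsAsFactors = FALSE)
  if ("pbs" %in% score_cols) {
    cs <- cumsum(c(0, track$pbs))
    out$pbs_mean <- (cs[ends + 1L] - cs[starts]) / config$window
  }
  if ("xpehh" %in% score_cols) {
    out$xpehh_max <- vapply(seq_along(starts), function(i) {
      max(track$xpehh[starts[i]:ends[i]])
    }, numeric(1))
  }
  out
}

# merge sorted intervals when the gap between nearest endpoints is <= gap;
# carries the max of `score` and returns one row per merged run
merge_intervals <- function(df, gap) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$start), , drop = FALSE]
  grp <- cumsum(c(1, (df$start[-1L] - cummax(df$end)[-nrow(df)]) > gap))
  out <- do.call(rbind, lapply(split(df, grp), function(d) {
    data.frame(chrom = d$chrom[1L], start = min(d$start), end = max(d$end),
               score = max(d$score), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Top windows by percentile, merged into candidate regions
#'
#' Retains windows whose score is at or above the empirical `percentile`
#' quantile and merges retained windows that lie at most `merge_gap` bp from
#' each other (between nearest endpoints); each region is scored with the top
#' window score among its members.
#'
#' @param windows Window table from [make_windows()].
#' @param score_col Which window score to use (`"pbs_mean"`, `"fisher"`...).
#' @param config A [scan_config()].
#' @return Data.frame of regions `chrom`, `start`, `end`, `score`.
#' @export
top_windows <- function(windows, score_col = "pbs_mean",
                        config = scan_config()) {
  if (nrow(windows) < 100L) {
    warning("fewer than 100 windows; percentile threshold is noisy")
  }
  x <- windows[[score_col]]
  thr <- stats::quantile(x, config$percentile, na.rm = TRUE, names = FALSE)
  kept <- windows[!is.na(x) & x >= thr, , drop = FALSE]
  kept$score <- kept[[score_col]]
  merge_intervals(kept[, c("chrom", "start", "end", "score")],
                  config$merge_gap)
}

#' @rdname top_windows
#' @export
top_windows_pbs <- function(windows, config = scan_config()) {
  top_windows(windows, "pbs_mean", config)
}

#' Top SNPs by XP-EHH percentile, chain-merged into regions
#'
#' Upper tail keeps SNPs at or above the 99th percentile; lower tail keeps
#' SNPs at or below the 1st percentile (internally the track is negated so
#' "top" always means upper tail; scores are reported on the working,
#' possibly negated, scale). Top SNPs at most `merge_gap` bp apart are
#' chained into one region whose endpoints are the two most distant top SNPs;
#' an isolated top SNP yields a zero-length region (later widened by the
#' flank).
#'
#' @param track Data.frame with `pos` and `xpehh` columns (normalized).
#' @param config A [scan_config()].
#' @param tail `"upper"` or `"lower"`.
#' @return List with `regions` (chrom/start/end/score) and `unit_scores`
#'   (the per-SNP working-scale scores, for resampling significance).
#' @export
top_snps_xpehh <- function(track, config = scan_config(),
                           tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  ok <- !is.na(track$xpehh)
  x <- track$xpehh[ok]
  if (tail == "lower") x <- -x
  pos <- track$pos[ok]
  thr <- stats::quantile(x, config$percentile, names = FALSE)
  top <- which(x >= thr)
  df <- data.frame(chrom = track$chrom[ok][top], start = pos[top],
                   end = pos[top], score = x[top], stringsAsFactors = FALSE)
  list(regions = merge_intervals(df, config$merge_gap), unit_scores = x)
}

#' Combine window PBS and XP-EHH into a Fisher score
#'
#' Per window, `percentilrank(s) = #{windows with score >= s} / N` (upper
#' tail, ties counted as >=, minimum 1/N so the score is finite);
#' `fisher = -log10(rank_PBS) - log10(rank_XPEHH)`. Depends only on the ranks
#' of the two score tracks.
#'
#' @param windows Window table with `pbs_mean` and `xpehh_max`.
#' @return `windows` with `rank_pbs`, `rank_xpehh`, `fisher` columns added.
#' @export
fisher_combine <- function(windows) {
  if (!all(c("pbs_mean", "xpehh_max") %in% names(windows))) {
    stop("windows must carry pbs_mean and xpehh_max")
  }
  upper_rank <- function(x) {
    n <- length(x)
    (n - rank(x, ties.method = "min") + 1) / n
  }
  windows$rank_pbs <- upper_rank(windows$pbs_mean)
  windows$rank_xpehh <- upper_rank(windows$xpehh_max)
  windows$fisher <- -log10(windows$rank_pbs) - log10(windows$rank_xpehh)
  windows
}

#' Resampling significance of a region's top score
#'
#' Tests whether the region's best unit score (SNP for XP-EHH, 20-SNP window
#' for PBS/Fisher) is higher than the score of random units along the track:
#' `p = (1 + #{sampled unit >= region score}) / (1 + M)`, sampling uniformly
#' with replacement.
#'
#' @param region_score The region's top unit score.
#' @param unit_scores Genome-wide unit score vector.
#' @param M Number of resamples (>= 1).
#' @param seed Optional seed.
#' @return The resampling p-value.
#' @export
resample_significance <- function(region_score, unit_scores, M = 1e5,
                                  seed = NULL) {
  if (M < 1) stop("M must be >= 1")
  force(region_score); force(unit_scores)
  if (!is.null(seed)) set.seed(seed)
  unit_scores <- unit_scores[!is.na(unit_scores)]
  draws <- unit_scores[sample.int(length(unit_scores), M, replace = TRUE)]
  (1 + sum(draws >= region_score)) / (1 + M)
}

#' Final candidate regions: per-method filtering, flanks and cross-method union
#'
#' Each method contributes its `top_k` regions by score that pass its
#' resampling p threshold; kept regions are extended by `flank` bp on both
#' sides (clipped to `[1, chrom_len]`) and regions overlapping by at least
#' 1 bp are unioned, with method provenance accumulated. Idempotent: re-merging
#' the output changes nothing.
#'
#' @param per_method Named list (`PBS`, `XPEHH`, `Fisher`) of region tables
#'   each with `chrom`, `start`, `end`, `score`, `p`.
#' @param config A [scan_config()].
#' @param chrom_len Chromosome length for clipping.
#' @return Data.frame of final regions with `methods` provenance, top
#'   `score` and minimal `p` per region, sorted by position.
#' @export
finalize_regions <- function(per_method, config = scan_config(),
                             chrom_len = Inf) {
  rows <- list()
  for (meth in names(per_method)) {
    r <- per_method[[meth]]
    if (is.null(r) || nrow(r) == 0L) next
    thr <- config$p_thresholds[[meth]]
    if (!is.null(thr) && "p" %in% names(r)) r <- r[r$p < thr, , drop = FALSE]
    if (nrow(r) == 0L) next
    r <- r[order(-r$score), , drop = FALSE]
    r <- utils::head(r, config$top_k)
    r$start <- pmax(1, r$start - config$flank)
    r$end <- pmin(chrom_len, r$end + config$flank)
    r$methods <- meth
    if (!"p" %in% names(r)) r$p <- NA_real_
    rows[[meth]] <- r[, c("chrom", "start", "end", "score", "p", "methods")]
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      score = numeric(), p = numeric(), methods = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start), , drop = FALSE]
  grp <- cumsum(c(1, df$start[-1L] > cummax(df$end)[-nrow(df)]))
  out <- do.call(rbind, lapply(split(df, grp), function(d) {
    data.frame(chrom = d$chrom[1L], start = min(d$start), end = max(d$end),
               score = max(d$score), p = suppressWarnings(min(d$p, na.rm = TRUE)),
               methods = paste(sort(unique(d$methods)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out$p[!is.finite(out$p)] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Run the full windowed selection scan for one target population
#'
#' Computes the PBS and XP-EHH tracks, 20/5 sliding windows, per-method top
#' regions with resampling significance, and the final flanked, merged
#' candidate regions. For a reference-population ("lowlander-style") scan,
#' pass the role-swapped populations and `tail = "lower"` semantics are
#' handled by swapping target/reference here.
#'
#' @param panel A [haplotype_panel()] with target, reference and outgroup.
#' @param target,reference,outgroup Population labels.
#' @param config A [scan_config()].
#' @param xp_config An [xpehh_config()].
#' @param seed Seed for the resampling significance draws.
#' @return List with `track`, `windows`, `per_method`, `final`.
#' @export
selection_scan <- function(panel, target = "TARGET", reference = "REF",
                           outgroup = "OUT", config = scan_config(),
                           xp_config = xpehh_config(), seed = 1L) {
  force(panel)
  set.seed(seed)
  pt <- pbs_track(panel, target, reference, outgroup)
  xt <- xpehh(panel, target, reference, xp_config)
  track <- data.frame(chrom = pt$chrom, pos = pt$pos, pbs = pt$pbs,
                      xpehh = xt$xpehh, stringsAsFactors = FALSE)
  windows <- fisher_combine(make_windows(track, config))

  pbs_regions <- top_windows(windows, "pbs_mean", config)
  fisher_regions <- top_windows(windows, "fisher", config)
  xp <- top_snps_xpehh(track, config, tail = "upper")

  add_p <- function(regions, unit_scores, M) {
    if (nrow(regions) == 0L) { regions$p <- numeric(0); return(regions) }
    regions$p <- vapply(regions$score, resample_significance,
                        numeric(1), unit_scores = unit_scores, M = M)
    regions
  }
  per_method <- list(
    PBS = add_p(pbs_regions, windows$pbs_mean, config$M_other),
    XPEHH = add_p(xp$regions, xp$unit_scores, config$M_xpehh),
    Fisher = add_p(fisher_regions, windows$fisher, config$M_other)
  )
  final <- finalize_regions(per_method, config,
                            chrom_len = max(panel$positions))
  list(track = track, windows = windows, per_method = per_method,
       final = final)
}
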