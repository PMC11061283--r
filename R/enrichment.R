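#' Multiple-testing log10 p cutoff for a summary-statistic lookup
#'
#' The genome-wide threshold `5e-8` corrected for the number of phenotypes
#' queried: `log10(5e-8 / n_phen)`. For 1,470 phenotypes this is -10.47
#' (2 d.p.); for a single phenotype, `log10(5e-8) ~ -7.30`.
#'
#' @param n_phen Number of phenotypes tested (> 0).
#' @return The log10 p-value cutoff (negative).
#' @export
bonferroni_log10_cutoff <- function(n_phen) {
  if (n_phen <= 0) stop("n_phen must be > 0")
  log10(5e-8 / n_phen)
}

#' Look up a candidate SNP in an external association table
#'
#' Exact-position match preferred; otherwise the nearest table SNP within
#' 50 bp upstream or downstream (ties broken by smaller distance, then lower
#' position). No match within the window yields a null result (the
#' "not present in the lookup" case, flagged).
#'
#' @param pos Candidate SNP position.
#' @param table Lookup table with columns `pos`, `phenotype`, `category`,
#'   `beta`, `p`.
#' @param window Search half-width in bp (default 50).
#' @return List with `matched_pos` (`NA` if none), `exact`, `records` (the
#'   matched rows, zero rows if none).
#' @export
lookup_candidate <- function(pos, table, window = 50) {
  upos <- unique(table$pos)
  if (pos %in% upos) {
    return(list(matched_pos = pos, exact = TRUE,
                records = table[table$pos == pos, , drop = FALSE]))
  }
  dist <- abs(upos - pos)
  inwin <- dist <= window
  if (!any(inwin)) {
    return(list(matched_pos = NA_real_, exact = FALSE,
                records = table[0, , drop = FALSE]))
  }
  cand <- upos[inwin]; dist <- dist[inwin]
  best <- cand[order(dist, cand)][1L]
  list(matched_pos = best, exact = FALSE,
       records = table[table$pos == best, , drop = FALSE])
}

#' Significant phenotypes for a matched lookup record
#'
#' Keeps the phenotypes whose `log10(p)` lies below the
#' [bonferroni_log10_cutoff()] for the number of phenotypes tested.
#'
#' @param records Matched rows from [lookup_candidate()].
#' @param n_phen Number of phenotypes tested (paper-scale default 1,470).
#' @return The subset of `records` passing the cutoff.
#' @export
significant_phenotypes <- function(records, n_phen = 1470L) {
  cutoff <- bonferroni_log10_cutoff(n_phen)
  records[log10(records$p) < cutoff, , drop = FALSE]
}

#' Resampling enrichment test for blood-phenotype associations
#'
#' Observed statistic: the number of candidate SNPs whose matched lookup
#' window has at least one significant blood-count association. Null: draws
#' of `x` windows (x = candidates with at least one significant association
#' of any phenotype) sampled without replacement from the universe of
#' lookup windows with at least one significant association; the p-value is
#' the proportion of draws whose blood-window count is at least the observed
#' one (set `strictly_greater = TRUE` for the strict-inequality variant).
#' Beta signs from the table are never interpreted directionally.
#'
#' @param candidate_pos Candidate SNP positions.
#' @param table Lookup table (see [lookup_candidate()]).
#' @param n_phen Phenotypes tested, for the significance cutoff.
#' @param n_resamples Number of resampled window sets (default 10,000).
#' @param seed Optional seed.
#' @param window Lookup half-width in bp.
#' @param strictly_greater Use `>` instead of `>=` when comparing resampled
#'   counts to the observed count.
#' @return List with `p` (`NA` if x = 0), `observed`, `x`, `universe_size`,
#'   `blood_windows`.
#' @export
blood_enrichment_test <- function(candidate_pos, table, n_phen = 1470L,
                                  n_resamples = 10000L, seed = NULL,
                                  window = 50, strictly_greater = FALSE) {
  force(candidate_pos); force(table) # force promises before seeding
  if (!is.null(seed)) set.seed(seed)
  cutoff <- bonferroni_log10_cutoff(n_phen)
  sig <- table[log10(table$p) < cutoff, , drop = FALSE]
  universe <- sort(unique(sig$pos))
  blood_set <- sort(unique(sig$pos[sig$category == "blood_count"]))
  cand_stats <- lapply(candidate_pos, function(p) {
    m <- lookup_candidate(p, table, window)
    s <- if (nrow(m$records)) significant_phenotypes(m$records, n_phen) else
      m$records
    list(any_sig = nrow(s) > 0L,
         blood = any(s$category == "blood_count"))
  })
  x <- sum(vapply(cand_stats, `[[`, logical(1), "any_sig"))
  observed <- sum(vapply(cand_stats, `[[`, logical(1), "blood"))
  if (x == 0L) {
    return(list(p = NA_real_, observed = observed, x = 0L,
                universe_size = length(universe),
                blood_windows = length(blood_set)))
  }
  if (length(universe) < x) stop("universe smaller than x; cannot resample")
  is_blood <- universe %in% blood_set
  counts <- vapply(seq_len(n_resamples), function(i) {
    sum(is_blood[sample.int(length(universe), x)])
  }, numeric(1))
  p <- if (strictly_greater) mean(counts > observed) else
    mean(counts >= observed)
  list(p = p, observed = observed, x = x,
       universe_size = length(universe), blood_windows = length(blood_set))
}
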