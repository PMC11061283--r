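#' Configuration for the archaic-introgression HMM
#'
#' A two-state (Human, Archaic) hidden Markov model over fixed-width genomic
#' windows. The emission in each window is the Poisson-distributed count of
#' derived variants on the focal haplotype that are absent from the outgroup
#' panel; the Archaic state has the higher rate. Parameters are fit by
#' Baum-Welch.
#'
#' @param w Window width in bp (default 1,000).
#' @param mean_prob Minimal average Archaic posterior over a segment
#'   (default 0.8).
#' @param max_iter Baum-Welch iteration cap (default 500).
#' @param tol Convergence threshold on the log-likelihood delta (1e-4).
#' @param a_hh,a_aa Initial self-transition probabilities.
#' @return An `hmm_config` list.
#' @export
hmm_config <- function(w = 1000L, mean_prob = 0.8, max_iter = 500L,
                       tol = 1e-4, a_hh = 0.999, a_aa = 0.975) {
  stopifnot(w >= 1L, mean_prob > 0, mean_prob <= 1, max_iter >= 1L, tol > 0)
  structure(list(w = as.integer(w), mean_prob = mean_prob,
                 max_iter = as.integer(max_iter), tol = tol,
                 a_hh = a_hh, a_aa = a_aa),
            class = "hmm_config")
}

#' Sites on a panel that are absent from the outgroup sample
#'
#' The archaic-SNP (aSNP) premise: a derived variant absent from an
#' unadmixed outgroup panel is a candidate marker of introgression.
#'
#' @param panel A [haplotype_panel()].
#' @param outgroup Outgroup population label (or a separate
#'   [haplotype_panel()] sharing the site set).
#' @return Logical vector, `TRUE` where the outgroup carries no derived
#'   allele.
#' @export
outgroup_absent <- function(panel, outgroup = "OUT") {
  if (inherits(outgroup, "haplotype_panel")) {
    if (n_sites(outgroup) != n_sites(panel)) {
      stop("outgroup panel must share the site set")
    }
    return(colSums(outgroup$H) == 0L)
  }
  dac(panel, outgroup) == 0L
}

# Baum-Welch fit of the 2-state Poisson HMM for one count sequence
# (compiled forward-backward). Returns NULL on a degenerate fit.
fit_poisson_hmm <- function(counts, config) {
  if (length(counts) < 2L) return(NULL)
  mu <- mean(counts)
  f <- baum_welch_poisson(as.integer(counts),
                          max(mu * 0.5, 1e-3), max(mu * 3, mu + 1, 0.5),
                          config$a_hh, config$a_aa, 0.98,
                          config$max_iter, config$tol)
  if (f$degenerate) return(NULL)
  list(lambda = f$lambda,
       posterior = cbind(1 - f$posterior, f$posterior),
       loglik = f$loglik)
}

#' Detect candidate archaic segments on one haplotype
#'
#' Counts outgroup-absent derived variants in `w`-bp windows along the
#' haplotype, fits the two-state Poisson HMM by Baum-Welch and reports
#' maximal runs of windows with `P(Archaic) > 0.5` whose mean posterior is
#' at least `config$mean_prob`. A degenerate fit (equal rates) yields a
#' warning and no segments.
#'
#' @param panel A [haplotype_panel()].
#' @param hap Haplotype row index (or rowname) in `panel$H`.
#' @param outgroup Outgroup population label or panel (see
#'   [outgroup_absent()]); alternatively pass a precomputed logical mask via
#'   `absent_mask`.
#' @param config An [hmm_config()].
#' @param absent_mask Optional precomputed [outgroup_absent()] mask.
#' @return Data.frame of segments: `hap`, `start`, `end`, `mean_prob`,
#'   `n_asnp`, and a list-column `asnp` of aSNP positions.
#' @export
detect_segments <- function(panel, hap, outgroup = "OUT",
                            config = hmm_config(), absent_mask = NULL) {
  if (is.character(hap)) hap <- match(hap, rownames(panel$H))
  if (is.null(absent_mask)) absent_mask <- outgroup_absent(panel, outgroup)
  L <- max(panel$positions)
  priv_pos <- panel$positions[absent_mask & panel$H[hap, ] == 1L]
  n_win <- ceiling(L / config$w)
  counts <- tabulate(pmin(n_win, (priv_pos - 1) %/% config$w + 1L), n_win)
  empty <- data.frame(hap = character(), start = numeric(), end = numeric(),
                      mean_prob = numeric(), n_asnp = integer(),
                      stringsAsFactors = FALSE)
  empty$asnp <- list()
  if (sum(counts) == 0L) return(empty)
  fit <- fit_poisson_hmm(counts, config)
  if (is.null(fit)) {
    warning("degenerate HMM fit (equal rates); no segments called")
    return(empty)
  }
  segments_from_posterior(fit$posterior[, 2L], priv_pos,
                          rownames(panel$H)[hap], config, L)
}

#' Detect archaic segments on every haplotype of a population
#'
#' Same model as [detect_segments()], fit independently per haplotype
#' (outgroup-absence mask computed once). Degenerate fits contribute no
#' segments.
#'
#' @param panel A [haplotype_panel()].
#' @param pop Population to scan.
#' @inheritParams detect_segments
#' @return Row-bound segment table over all haplotypes.
#' @export
detect_segments_all <- function(panel, pop = "TARGET", outgroup = "OUT",
                                config = hmm_config()) {
  mask <- outgroup_absent(panel, outgroup)
  rows <- hap_rows(panel, pop)
  L <- max(panel$positions)
  n_win <- ceiling(L / config$w)
  priv <- lapply(rows, function(h) {
    panel$positions[mask & panel$H[h, ] == 1L]
  })
  counts <- t(vapply(priv, function(p) {
    tabulate(pmin(n_win, (p - 1) %/% config$w + 1L), n_win)
  }, integer(n_win)))
  nonzero <- which(rowSums(counts) > 0L)
  out <- lapply(nonzero, function(i) {
    fit <- fit_poisson_hmm(counts[i, ], config)
    if (is.null(fit)) return(NULL)
    segments_from_posterior(fit$posterior[, 2L], priv[[i]],
                            rownames(panel$H)[rows[i]], config, L)
  })
  out <- Filter(function(d) !is.null(d) && nrow(d) > 0L, out)
  if (!length(out)) {
    empty <- data.frame(hap = character(), start = numeric(),
                        end = numeric(), mean_prob = numeric(),
                        n_asnp = integer(), stringsAsFactors = FALSE)
    empty$asnp <- list()
    return(empty)
  }
  do.call(rbind, out)
}

# turn a posterior P(Archaic) vector into kept segments
segments_from_posterior <- function(postA, priv_pos, hap_name, config, L) {
  empty <- data.frame(hap = character(), start = numeric(), end = numeric(),
                      mean_prob = numeric(), n_asnp = integer(),
                      stringsAsFactors = FALSE)
  empty$asnp <- list()
  arch <- postA > 0.5
  if (!any(arch)) return(empty)
  r <- rle(arch)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- empty
  for (i in which(r$values)) {
    wstart <- (starts[i] - 1L) * config$w + 1L
    wend <- min(ends[i] * config$w, L)
    mp <- mean(postA[starts[i]:ends[i]])
    if (mp < config$mean_prob) next
    asnp <- priv_pos[priv_pos >= wstart & priv_pos <= wend]
    row <- data.frame(hap = hap_name, start = wstart, end = wend,
                      mean_prob = mp, n_asnp = length(asnp),
                      stringsAsFactors = FALSE)
    row$asnp <- list(asnp)
    out <- rbind(out, row)
  }
  out
}

#' Filter segments for a candidate region
#'
#' Keeps segments fully contained in the region's span that share at least
#' one aSNP with any of the four archaic genomes (a variant derived in at
#' least one archaic panel individual).
#'
#' @param segments Segment table from [detect_segments()].
#' @param region One-row data.frame with `start`, `end`.
#' @param archaic_panel A [haplotype_panel()] of the four archaic
#'   pseudo-individuals.
#' @return The retained segments.
#' @export
filter_for_region <- function(segments, region, archaic_panel) {
  if (nrow(segments) == 0L) return(segments)
  arch_derived <- archaic_panel$positions[colSums(archaic_panel$H) > 0L]
  keep <- vapply(seq_len(nrow(segments)), function(i) {
    segments$start[i] >= region$start && segments$end[i] <= region$end &&
      any(segments$asnp[[i]] %in% arch_derived)
  }, logical(1))
  segments[keep, , drop = FALSE]
}

#' Assign archaic ancestry to a haplotype's aSNP set
#'
#' Counts the aSNPs derived in the Denisovan panel (`nD`) against those
#' derived in the union of the three Neanderthal panels (`nN`):
#' `nD > nN` is Denisova, `nN > nD` Neanderthal, ties are ambiguous.
#'
#' @param asnp_pos Non-empty vector of aSNP positions.
#' @param archaic_panel Panel with populations `NEA1`, `NEA2`, `NEA3`, `DEN`.
#' @return `"Denisova"`, `"Neanderthal"` or `"ambiguous"`.
#' @export
assign_ancestry <- function(asnp_pos, archaic_panel) {
  if (!length(asnp_pos)) stop("empty aSNP set (should have been filtered)")
  idx <- match(asnp_pos, archaic_panel$positions)
  idx <- idx[!is.na(idx)]
  den <- dac(archaic_panel, "DEN")[idx] > 0L
  nea <- (dac(archaic_panel, "NEA1")[idx] +
            dac(archaic_panel, "NEA2")[idx] +
            dac(archaic_panel, "NEA3")[idx]) > 0L
  nD <- sum(den); nN <- sum(nea)
  if (nD > nN) "Denisova" else if (nN > nD) "Neanderthal" else "ambiguous"
}

#' Cluster per-haplotype segments into region-level archaic haplotypes
#'
#' Builds a graph over the region's aSNPs with edges where `r^2 > 0.5` on
#' the target-population chromosomes; connected components define haplotype
#' clusters. Each segment is assigned to the component sharing most of its
#' aSNPs (ties to the larger component). Cluster frequency is carrier
#' chromosomes over total target chromosomes; cluster ancestry is the most
#' frequent per-segment ancestry. Reports all clusters plus, per region, the
#' highest-frequency one; if `candidate_pos` is given, also the maximal
#' `r^2` between the candidate SNP and any cluster aSNP.
#'
#' @param segments Filtered segments (see [filter_for_region()]).
#' @param panel The modern [haplotype_panel()].
#' @param archaic_panel The four-individual archaic panel.
#' @param target Target population label.
#' @param r2_threshold LD threshold for linking aSNPs (default 0.5).
#' @param candidate_pos Optional candidate-SNP position for the LD report.
#' @return Data.frame of clusters: `cluster`, `n_asnp`, `carriers`, `freq`,
#'   `ancestry`, `max_r2_candidate`, sorted by frequency (highest first);
#'   zero rows if no segments.
#' @export
cluster_haplotypes <- function(segments, panel, archaic_panel,
                               target = "TARGET", r2_threshold = 0.5,
                               candidate_pos = NULL) {
  empty <- data.frame(cluster = integer(), n_asnp = integer(),
                      carriers = integer(), freq = numeric(),
                      ancestry = character(), max_r2_candidate = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) return(empty)
  all_asnp <- sort(unique(unlist(segments$asnp)))
  if (!length(all_asnp)) return(empty)
  rows <- hap_rows(panel, target)
  cols <- match(all_asnp, panel$positions)
  R2 <- r2_matrix(panel$H[rows, , drop = FALSE], cols)
  adj <- R2 > r2_threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  comp_size <- table(comp)
  seg_comp <- vapply(segments$asnp, function(a) {
    m <- comp[match(a, all_asnp)]
    tab <- table(m)
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1L) best <- best[which.max(comp_size[best])]
    as.integer(best)
  }, integer(1))
  seg_anc <- vapply(segments$asnp, assign_ancestry, character(1),
                    archaic_panel = archaic_panel)
  n_chrom <- length(rows)
  out <- do.call(rbind, lapply(sort(unique(seg_comp)), function(cl) {
    in_cl <- seg_comp == cl
    carriers <- unique(segments$hap[in_cl])
    anc_tab <- sort(table(seg_anc[in_cl]), decreasing = TRUE)
    cl_asnp <- all_asnp[comp == cl]
    max_r2 <- NA_real_
    if (!is.null(candidate_pos)) {
      cj <- which.min(abs(panel$positions - candidate_pos))
      max_r2 <- max(vapply(match(cl_asnp, panel$positions), function(aj) {
        r2_pair(panel$H[rows, , drop = FALSE], cj, aj)
      }, numeric(1)))
    }
    data.frame(cluster = cl, n_asnp = length(cl_asnp),
               carriers = length(carriers),
               freq = length(carriers) / n_chrom,
               ancestry = names(anc_tab)[1L],
               max_r2_candidate = max_r2, stringsAsFactors = FALSE)
  }))
  out[order(-out$freq), , drop = FALSE]
}

#' Archaic-introgression report for a set of candidate regions
#'
#' For each region: detect segments on every target haplotype, apply the
#' full-overlap + shared-aSNP filter, cluster into region-level haplotypes
#' and report the highest-frequency haplotype with its majority ancestry and
#' candidate-SNP LD flag.
#'
#' @param panel Modern [haplotype_panel()].
#' @param regions Data.frame of candidate regions (`start`, `end`; optional
#'   `candidate_pos` column).
#' @param archaic_panel Four-individual archaic panel.
#' @param target,outgroup Population labels.
#' @param config An [hmm_config()].
#' @return One row per region: top haplotype frequency, ancestry, aSNP count
#'   and candidate LD (`NA`s where no haplotype was found).
#' @export
archaic_scan <- function(panel, regions, archaic_panel, target = "TARGET",
                         outgroup = "OUT", config = hmm_config()) {
  segs <- detect_segments_all(panel, target, outgroup, config)
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    region <- regions[i, ]
    kept <- filter_for_region(segs, region, archaic_panel)
    cand <- if ("candidate_pos" %in% names(region)) region$candidate_pos else NULL
    cl <- cluster_haplotypes(kept, panel, archaic_panel, target,
                             candidate_pos = cand)
    if (nrow(cl) == 0L) {
      return(data.frame(region = i, start = region$start, end = region$end,
                        hap_freq = NA_real_, ancestry = NA_character_,
                        n_asnp = NA_integer_, max_r2_candidate = NA_real_,
                        high_ld = NA, stringsAsFactors = FALSE))
    }
    top <- cl[1L, ]
    data.frame(region = i, start = region$start, end = region$end,
               hap_freq = top$freq, ancestry = top$ancestry,
               n_asnp = top$n_asnp, max_r2_candidate = top$max_r2_candidate,
               high_ld = !is.na(top$max_r2_candidate) &&
                 top$max_r2_candidate > 0.5,
               stringsAsFactors = FALSE)
  }))
  out
}
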