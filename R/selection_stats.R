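#' Hudson's FST estimator per site
#'
#' The Hudson/Bhatia estimator, unbiased under unequal sample sizes:
#' `FST = [(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] /
#'        [p1(1-p2) + p2(1-p1)]`.
#' Sites where the denominator is zero (both populations fixed for the same
#' allele) are flagged missing (`NA`). For the downstream `-ln(1-FST)`
#' transform, estimates are clamped to `[0, 1 - eps]`.
#'
#' @param p1,p2 Derived allele frequencies per site.
#' @param n1,n2 Non-missing allele counts (>= 2).
#' @param eps Clamp margin in `(0, 0.01]` (default 1e-6).
#' @return Numeric vector of clamped FST values (`NA` where undefined).
#' @export
hudson_fst <- function(p1, n1, p2, n2, eps = 1e-6) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  if (eps <= 0 || eps > 0.01) stop("eps must be in (0, 0.01]")
  if (any(n1 < 2 | n2 < 2)) stop("need >= 2 non-missing alleles per population")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- ifelse(den == 0, NA_real_, num / den)
  pmin(pmax(fst, 0), 1 - eps)
}

#' Population branch statistic per site
#'
#' `PBS = (T_TR + T_TO - T_RO) / 2` with `T = -ln(1 - FST)`, measuring
#' allele-frequency change specific to the target branch since its split from
#' the reference, using the outgroup to polarize. Negative values are
#' retained. Any missing FST yields a missing PBS.
#'
#' @param fst_tr FST target vs reference (clamped, as from [hudson_fst()]).
#' @param fst_to FST target vs outgroup.
#' @param fst_ro FST reference vs outgroup.
#' @return Numeric vector of PBS values.
#' @export
pbs <- function(fst_tr, fst_to, fst_ro) {
  (-log(1 - fst_tr) - log(1 - fst_to) + log(1 - fst_ro)) / 2
}

#' Per-site PBS track for a panel
#'
#' @param panel A [haplotype_panel()] containing the three populations.
#' @param target,reference,outgroup Population labels.
#' @param eps FST clamp margin.
#' @return Data.frame `chrom`, `pos`, `pbs` (NA where undefined).
#' @export
pbs_track <- function(panel, target = "TARGET", reference = "REF",
                      outgroup = "OUT", eps = 1e-6) {
  pt <- daf(panel, target); pr <- daf(panel, reference); po <- daf(panel, outgroup)
  nt <- length(hap_rows(panel, target)); nr <- length(hap_rows(panel, reference))
  no <- length(hap_rows(panel, outgroup))
  data.frame(chrom = panel$chrom, pos = panel$positions,
             pbs = pbs(hudson_fst(pt, nt, pr, nr, eps),
                       hudson_fst(pt, nt, po, no, eps),
                       hudson_fst(pr, nr, po, no, eps)),
             stringsAsFactors = FALSE)
}

#' XP-EHH configuration
#'
#' @param cutoff EHH truncation cutoff in `(0, 1)`: extension stops once the
#'   pooled-sample EHH falls below it (default 0.05).
#' @param max_gap Maximal bp gap between adjacent markers before extension
#'   stops (default 200 kb).
#' @return An `xpehh_config` list.
#' @export
xpehh_config <- function(cutoff = 0.05, max_gap = 2e5) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  structure(list(cutoff = cutoff, max_gap = max_gap), class = "xpehh_config")
}

# homozygosity sum(choose(m_h, 2)) / choose(m, 2) from group counts
hh_from_counts <- function(tab, m) {
  if (m < 2L) return(NA_real_)
  sum(tab * (tab - 1)) / (m * (m - 1))
}

#' Extended haplotype homozygosity curve from a core site
#'
#' `EHH_k` is the probability that two random haplotypes of the sample are
#' identical over the markers from the core out to step `k` (core included
#' from step 1 on; `EHH_0 = 1`). The curve is non-increasing.
#'
#' @param panel A [haplotype_panel()].
#' @param core Core site index.
#' @param direction `"right"` or `"left"`.
#' @param pop Population label(s) to restrict to (default: all haplotypes).
#' @param rows Explicit haplotype row indices (overrides `pop`), e.g. the
#'   carriers of a focal allele.
#' @param cutoff Stop once EHH drops below this (default 0: full curve).
#' @return Data.frame with `step`, `index`, `pos`, `ehh`.
#' @export
ehh <- function(panel, core, direction = c("right", "left"), pop = NULL,
                rows = NULL, cutoff = 0) {
  direction <- match.arg(direction)
  if (core < 1L || core > n_sites(panel)) stop("core index out of range")
  H <- if (!is.null(rows)) panel$H[rows, , drop = FALSE]
  else if (is.null(pop)) panel$H
  else panel$H[hap_rows(panel, pop), , drop = FALSE]
  m <- nrow(H)
  if (m < 2L) stop("need >= 2 haplotypes")
  dirstep <- if (direction == "right") 1L else -1L
  g <- rep(1L, m)
  out <- data.frame(step = 0L, index = core, pos = panel$positions[core],
                    ehh = 1)
  j <- core # the first step includes the core marker itself
  k <- 0L
  repeat {
    if (j < 1L || j > n_sites(panel)) break
    key <- g * 2L + H[, j]
    g <- match(key, unique(key))
    k <- k + 1L
    e <- hh_from_counts(tabulate(g), m)
    out <- rbind(out, data.frame(step = k, index = j,
                                 pos = panel$positions[j], ehh = e))
    if (e < cutoff) break
    j <- j + dirstep
  }
  out
}

# one-directional integrated EHH for target/reference with pooled truncation
ihh_side <- function(H, is_t, is_r, positions, core, dirstep, cutoff, max_gap) {
  m <- nrow(H); m_t <- sum(is_t); m_r <- sum(is_r)
  g <- rep(1L, m)
  e_pool <- 1; e_t <- 1; e_r <- 1
  ihh_t <- 0; ihh_r <- 0
  pos_prev <- positions[core]
  j <- core - dirstep
  S <- length(positions)
  repeat {
    j <- j + dirstep
    if (j < 1L || j > S) break
    gap <- abs(positions[j] - pos_prev)
    if (gap > max_gap) break
    key <- g * 2L + H[, j]
    g <- match(key, unique(key))
    tab_all <- tabulate(g)
    e_pool_new <- hh_from_counts(tab_all, m)
    e_t_new <- hh_from_counts(tabulate(g[is_t]), m_t)
    e_r_new <- hh_from_counts(tabulate(g[is_r]), m_r)
    ihh_t <- ihh_t + (e_t + e_t_new) / 2 * gap
    ihh_r <- ihh_r + (e_r + e_r_new) / 2 * gap
    e_pool <- e_pool_new; e_t <- e_t_new; e_r <- e_r_new
    pos_prev <- positions[j]
    if (e_pool < cutoff) break
  }
  c(ihh_t, ihh_r)
}

#' Cross-population extended haplotype homozygosity (XP-EHH) track
#'
#' For every site: integrate EHH over physical distance in both directions
#' (trapezoidal rule, pooled-sample truncation at `config$cutoff`, stop at
#' gaps above `config$max_gap`), separately within the target and the
#' reference sample; `raw = ln(iHH_target / iHH_ref)`; scores are normalized
#' to z-scores over all scored sites. Maximal scores mark selection in the
#' target, minimal scores selection in the reference.
#'
#' @param panel A [haplotype_panel()] containing both populations.
#' @param target,reference Population labels.
#' @param config An [xpehh_config()].
#' @return Data.frame `chrom`, `pos`, `raw`, `xpehh` (normalized), `missing`.
#' @export
xpehh <- function(panel, target = "TARGET", reference = "REF",
                  config = xpehh_config()) {
  rt <- hap_rows(panel, target); rr <- hap_rows(panel, reference)
  H <- panel$H[c(rt, rr), , drop = FALSE]
  is_t <- c(rep(TRUE, length(rt)), rep(FALSE, length(rr)))
  is_r <- !is_t
  S <- n_sites(panel)
  raw <- rep(NA_real_, S)
  for (core in seq_len(S)) {
    right <- ihh_side(H, is_t, is_r, panel$positions, core, 1L,
                      config$cutoff, config$max_gap)
    left <- ihh_side(H, is_t, is_r, panel$positions, core, -1L,
                     config$cutoff, config$max_gap)
    it <- right[1] + left[1]; ir <- right[2] + left[2]
    if (it > 0 && ir > 0) raw[core] <- log(it / ir)
  }
  scored <- !is.na(raw)
  if (sum(scored) < 2L) stop("fewer than 2 scored sites; cannot normalize")
  s <- stats::sd(raw[scored])
  z <- if (s > 0) (raw - mean(raw[scored])) / s else raw - mean(raw[scored])
  data.frame(chrom = panel$chrom, pos = panel$positions, raw = raw,
             xpehh = z, missing = !scored, stringsAsFactors = FALSE)
}

#' D statistic (ABBA-BABA) with block-jackknife standard error
#'
#' Per site `ABBA = (1-pW) pX pY (1-pZ)`, `BABA = pW (1-pX) pY (1-pZ)`;
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)`. The standard error comes from a
#' delete-one block jackknife over blocks of `block_size` consecutive SNPs.
#'
#' @param pW,pX,pY,pZ Per-site derived allele frequencies for the four
#'   populations of D(W, X; Y, Z).
#' @param block_size Block length in SNPs for the jackknife.
#' @return A list with `D`, `se`, `Z`, `n_blocks`; `D` is `NA` (flagged) when
#'   `sum(ABBA + BABA) == 0`.
#' @export
d_statistic <- function(pW, pX, pY, pZ, block_size = 100L) {
  abba <- (1 - pW) * pX * pY * (1 - pZ)
  baba <- pW * (1 - pX) * pY * (1 - pZ)
  tot <- sum(abba + baba)
  if (tot == 0) {
    return(list(D = NA_real_, se = NA_real_, Z = NA_real_, n_blocks = 0L))
  }
  D <- sum(abba - baba) / tot
  blocks <- ceiling(seq_along(abba) / block_size)
  B <- max(blocks)
  if (B < 2L) return(list(D = D, se = NA_real_, Z = NA_real_, n_blocks = B))
  d_jack <- vapply(seq_len(B), function(b) {
    keep <- blocks != b
    s <- sum(abba[keep] + baba[keep])
    if (s == 0) return(NA_real_)
    sum(abba[keep] - baba[keep]) / s
  }, numeric(1))
  d_jack <- d_jack[!is.na(d_jack)]
  se <- sqrt((length(d_jack) - 1) / length(d_jack) *
               sum((d_jack - mean(d_jack))^2))
  list(D = D, se = se, Z = if (se > 0) D / se else NA_real_, n_blocks = B)
}
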