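#' Phased haplotype panel
#'
#' The substrate of every scan: a binary haplotype-by-site matrix for a set of
#' diploid samples, with 1-based physical positions and per-sample population
#' labels. Alleles are polarized: 0 = ancestral, 1 = derived. Each diploid
#' sample contributes two consecutive haplotype rows (`<sample>_1`,
#' `<sample>_2`).
#'
#' @param chrom Single chromosome label.
#' @param positions Integer vector of 1-based physical positions, strictly
#'   increasing.
#' @param H Binary matrix, `2 * length(sample_ids)` rows by
#'   `length(positions)` columns; entries in `{0, 1}`.
#' @param sample_ids Character vector of diploid sample ids.
#' @param population Character vector of population labels, one per sample.
#' @param rsid Optional character vector of site ids (one per position).
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(chrom, positions, H, sample_ids, population,
                            rsid = NULL) {
  positions <- as.numeric(positions)
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (length(chrom) != 1L) stop("`chrom` must be a single label")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (ncol(H) != length(positions)) {
    stop("ncol(H) must equal length(positions)")
  }
  if (nrow(H) != 2L * length(sample_ids)) {
    stop("H must have two haplotype rows per diploid sample")
  }
  if (length(population) != length(sample_ids)) {
    stop("one population label per sample required")
  }
  if (!all(H %in% c(0L, 1L))) stop("H entries must all be 0 or 1")
  if (!is.null(rsid) && length(rsid) != length(positions)) {
    stop("one rsid per site required")
  }
  rownames(H) <- paste0(rep(sample_ids, each = 2L), "_", c(1L, 2L))
  structure(
    list(
      chrom = as.character(chrom),
      positions = positions,
      H = H,
      sample_ids = as.character(sample_ids),
      population = as.character(population),
      rsid = if (is.null(rsid)) rep(NA_character_, length(positions)) else
        as.character(rsid)
    ),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %d diploids (%d haplotypes) x %d sites on %s [%s-%s]\n",
    length(x$sample_ids), nrow(x$H), ncol(x$H), x$chrom,
    format(min(x$positions), big.mark = ","),
    format(max(x$positions), big.mark = ",")
  ))
  for (p in unique(x$population)) {
    cat(sprintf("  %s: %d samples\n", p, sum(x$population == p)))
  }
  invisible(x)
}

#' Number of sites in a panel
#' @param panel A `haplotype_panel`.
#' @return Integer site count.
#' @export
n_sites <- function(panel) length(panel$positions)

#' Haplotype row indices belonging to a set of populations
#' @param panel A `haplotype_panel`.
#' @param pops Character vector of population labels.
#' @return Integer vector of row indices into `panel$H`.
#' @export
hap_rows <- function(panel, pops) {
  keep <- panel$population %in% pops
  if (!any(keep)) stop("no samples in population(s): ", paste(pops, collapse = ", "))
  idx <- which(keep)
  sort(c(2L * idx - 1L, 2L * idx))
}

#' Subset a panel to a set of populations
#' @inheritParams hap_rows
#' @return A `haplotype_panel` restricted to `pops`.
#' @export
subset_panel <- function(panel, pops) {
  keep <- panel$population %in% pops
  haplotype_panel(panel$chrom, panel$positions,
                  panel$H[hap_rows(panel, pops), , drop = FALSE],
                  panel$sample_ids[keep], panel$population[keep],
                  rsid = panel$rsid)
}

#' Subset a panel to a window of sites
#' @param panel A `haplotype_panel`.
#' @param start,end 1-based inclusive bp bounds.
#' @return A `haplotype_panel` with the sites whose position lies in
#'   `[start, end]`.
#' @export
subset_sites <- function(panel, start, end) {
  keep <- panel$positions >= start & panel$positions <= end
  if (!any(keep)) stop("no sites in [", start, ", ", end, "]")
  haplotype_panel(panel$chrom, panel$positions[keep],
                  panel$H[, keep, drop = FALSE],
                  panel$sample_ids, panel$population,
                  rsid = panel$rsid[keep])
}

#' Derived allele frequency per site for one population
#' @param panel A `haplotype_panel`.
#' @param pop Population label (or vector of labels pooled together).
#' @return Numeric vector of derived allele frequencies, one per site.
#' @export
daf <- function(panel, pop) {
  colMeans(panel$H[hap_rows(panel, pop), , drop = FALSE])
}

#' Derived allele count per site for one population
#' @inheritParams daf
#' @return Integer vector of derived allele counts.
#' @export
dac <- function(panel, pop) {
  colSums(panel$H[hap_rows(panel, pop), , drop = FALSE])
}

#' Per-site summary table with derived allele frequencies per population
#'
#' @param panel A `haplotype_panel`.
#' @return A data.frame with `chrom`, `pos`, `rsid`, and one `daf_<pop>` and
#'   `dac_<pop>` column per population in the panel.
#' @export
site_table <- function(panel) {
  out <- data.frame(
    chrom = panel$chrom, pos = panel$positions, rsid = panel$rsid,
    stringsAsFactors = FALSE
  )
  for (p in unique(panel$population)) {
    out[[paste0("dac_", p)]] <- dac(panel, p)
    out[[paste0("daf_", p)]] <- daf(panel, p)
  }
  out
}

#' Squared allele-frequency correlation (r2) between sites
#'
#' Computes haplotype-based r-squared between pairs of sites on the given
#' chromosome rows (the usual LD measure on phased data).
#'
#' @param H Binary haplotype matrix (rows = chromosomes).
#' @param i,j Column indices; `r2_sites` returns the full matrix for columns
#'   `cols`.
#' @return Scalar r-squared in `[0, 1]` (0 if either site is monomorphic).
#' @export
r2_pair <- function(H, i, j) {
  x <- H[, i]; y <- H[, j]
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) return(0)
  (stats::cov(x, y)^2) / (vx * vy)
}

#' @rdname r2_pair
#' @param cols Columns for the pairwise matrix.
#' @export
r2_matrix <- function(H, cols) {
  X <- H[, cols, drop = FALSE]
  v <- apply(X, 2L, stats::var)
  cc <- suppressWarnings(stats::cor(X))
  cc[is.na(cc)] <- 0
  r2 <- cc^2
  r2[v == 0, ] <- 0
  r2[, v == 0] <- 0
  diag(r2) <- 1
  dimnames(r2) <- list(cols, cols)
  r2
}
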