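#' Covariate-correct a raw phenotype by ordinary least squares
#'
#' Regresses the raw phenotype on an intercept plus the covariates of its
#' group (`age+sex` for haematological/cardiovascular traits, or
#' `age+sex+height` for body-proportion and pulmonary traits) and returns
#' the residuals. Rows with a missing phenotype propagate `NA`; rows with
#' missing covariates are an error for corrected rows.
#'
#' @param raw Numeric phenotype vector.
#' @param covariates Data.frame with columns `age`, `sex` (0/1) and, for the
#'   height group, `height`.
#' @param group `"age+sex"` or `"age+sex+height"`.
#' @return Residual vector aligned with `raw` (`NA` where `raw` is missing).
#' @export
correct_phenotype <- function(raw, covariates,
                              group = c("age+sex", "age+sex+height")) {
  group <- match.arg(group)
  vars <- if (group == "age+sex") c("age", "sex") else c("age", "sex", "height")
  if (!all(vars %in% names(covariates))) {
    stop("covariates must include: ", paste(vars, collapse = ", "))
  }
  ok <- !is.na(raw)
  if (any(!stats::complete.cases(covariates[ok, vars, drop = FALSE]))) {
    stop("covariates must be complete for corrected rows")
  }
  if (sum(ok) < 5L) stop("need >= 5 complete rows")
  X <- cbind(1, as.matrix(covariates[ok, vars, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) stop("collinear covariates (rank-deficient)")
  fit <- stats::lm.fit(X, raw[ok])
  res <- rep(NA_real_, length(raw))
  res[ok] <- fit$residuals
  res
}

#' Centred relatedness (kinship) matrix from genotype dosages
#'
#' `K = W W' / m` with `W` the column-centred genotype matrix (samples x
#' SNPs, 0/1/2 dosages) -- the centred relatedness matrix conventionally
#' used to absorb population stratification in mixed-model association.
#'
#' @param G Samples-by-SNPs dosage matrix.
#' @return Symmetric `n x n` kinship matrix.
#' @export
kinship_matrix <- function(G) {
  G <- as.matrix(G)
  W <- sweep(G, 2L, colMeans(G))
  tcrossprod(W) / ncol(G)
}

#' Kinship matrix for all diploid samples of a panel
#' @param panel A [haplotype_panel()].
#' @return Symmetric kinship matrix over `panel$sample_ids`.
#' @export
panel_kinship <- function(panel) {
  n <- length(panel$sample_ids)
  G <- panel$H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    panel$H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  K <- kinship_matrix(G)
  dimnames(K) <- list(panel$sample_ids, panel$sample_ids)
  K
}

#' Univariate linear mixed model association test
#'
#' Fits `y = mu + g beta + u + e` with `u ~ N(0, sg^2 K)` and
#' `e ~ N(0, se^2 I)`. The variance ratio `delta = sg^2 / se^2` is profiled
#' out by maximum likelihood after a single eigendecomposition of `K`
#' (one-dimensional Brent search on log delta, tolerance 1e-8), and the SNP
#' effect is tested with a Wald t-test. With `K = I` the model collapses
#' exactly to ordinary least squares.
#'
#' @param g Genotype dosage vector (0/1/2).
#' @param y Phenotype (typically covariate-corrected residuals).
#' @param K Kinship matrix, or the reusable eigendecomposition from
#'   [lmm_eigen()].
#' @return List with `beta`, `se`, `p`, `delta`, `flagged` (monomorphic SNP:
#'   no test).
#' @export
lmm_assoc <- function(g, y, K) {
  ok <- !is.na(y) & !is.na(g)
  g0 <- g[ok]; y0 <- y[ok]
  n <- length(y0)
  if (stats::var(g0) == 0) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                delta = NA_real_, flagged = TRUE))
  }
  ed <- if (is.list(K) && !is.null(K$vectors)) K else lmm_eigen(K)
  if (length(ed$values) != length(ok)) stop("K dimension must match data")
  if (any(!ok)) { # rows dropped: decompose the kinship submatrix
    Kfull <- ed$vectors %*% (ed$values * t(ed$vectors))
    ed <- lmm_eigen(Kfull[ok, ok])
  }
  U <- ed$vectors
  d <- ed$values
  Xs <- crossprod(U, cbind(1, g0))
  ys <- crossprod(U, y0)[, 1L]
  profile_nll <- function(logdelta) {
    delta <- exp(logdelta)
    wt <- 1 / (1 + delta * d)
    XtWX <- crossprod(Xs, wt * Xs)
    XtWy <- crossprod(Xs, wt * ys)
    b <- solve(XtWX, XtWy)
    rss <- sum(wt * (ys - Xs %*% b)^2)
    n * log(rss / n) + sum(log(1 + delta * d))
  }
  opt <- stats::optimize(profile_nll, c(log(1e-6), log(1e6)), tol = 1e-8)
  delta <- exp(opt$minimum)
  wt <- 1 / (1 + delta * d)
  XtWX <- crossprod(Xs, wt * Xs)
  b <- solve(XtWX, crossprod(Xs, wt * ys))
  rss <- sum(wt * (ys - Xs %*% b)^2)
  sigma2 <- rss / (n - 2L)
  se <- sqrt(sigma2 * solve(XtWX)[2L, 2L])
  tstat <- b[2L] / se
  list(beta = b[2L], se = se, p = 2 * stats::pt(-abs(tstat), n - 2L),
       delta = delta, flagged = FALSE)
}

#' Reusable eigendecomposition of a kinship matrix
#' @param K Symmetric kinship matrix.
#' @return List with `values`, `vectors` (as [base::eigen()]).
#' @export
lmm_eigen <- function(K) {
  ed <- eigen(K, symmetric = TRUE)
  ed$values <- pmax(ed$values, 0)
  ed
}

#' Benjamini-Hochberg adjustment and two-tier significance calls
#'
#' Adjusts the per-SNP p-values of one phenotype for the number of SNPs
#' tested (BH) and calls significance at two tiers: suggestive at adjusted
#' p < 0.05, strict at adjusted p < `0.05 / n_groups` (five groups of
#' correlated phenotypes give the 0.01 threshold).
#'
#' @param pvalues Raw p-values (one per SNP) for a phenotype.
#' @param n_groups Number of correlated phenotype groups (default 5).
#' @return Data.frame with `p`, `p_adj`, `suggestive`, `strict`.
#' @export
adjust_and_call <- function(pvalues, n_groups = 5L) {
  p_adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adj = p_adj,
             suggestive = !is.na(p_adj) & p_adj < 0.05,
             strict = !is.na(p_adj) & p_adj < 0.05 / n_groups)
}

#' Association of candidate SNPs with corrected phenotypes
#'
#' Runs the two-step procedure: each phenotype is covariate-corrected once
#' (per its group), then every candidate SNP is tested against the residuals
#' with the kinship-corrected LMM, and p-values are BH-adjusted across SNPs
#' within each phenotype.
#'
#' @param panel A [haplotype_panel()].
#' @param candidate_idx Site indices of the candidate SNPs.
#' @param phenotypes Phenotype table from [simulate_phenotypes()] (or with
#'   the same layout).
#' @param n_groups Phenotype groups for the strict threshold.
#' @return Data.frame: one row per SNP x phenotype with beta, p, adjusted p
#'   and call tiers.
#' @export
association_tests <- function(panel, candidate_idx, phenotypes,
                              n_groups = 5L) {
  K <- panel_kinship(panel)
  ed <- lmm_eigen(K)
  groups <- phenotype_groups()
  phens <- intersect(names(groups), names(phenotypes))
  out <- list()
  for (ph in phens) {
    resid <- correct_phenotype(phenotypes[[ph]], phenotypes, groups[[ph]])
    res <- lapply(candidate_idx, function(j) {
      g <- genotype_vector(panel, j)
      r <- lmm_assoc(g, resid, ed)
      data.frame(phenotype = ph, index = j, pos = panel$positions[j],
                 beta = r$beta, p = r$p, flagged = r$flagged,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    calls <- adjust_and_call(res$p, n_groups)
    res$p_adj <- calls$p_adj
    res$suggestive <- calls$suggestive
    res$strict <- calls$strict
    out[[ph]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
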