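#' Read a sample-to-population manifest
#'
#' A manifest is a TSV with columns `sample_id`, `population`, `role`; roles
#' come from `{target, reference, outgroup, archaic}`. For a scan run the
#' target, reference and outgroup roles must each be non-empty.
#'
#' @param path Path to the TSV file.
#' @param require_scan_roles If `TRUE`, fail unless target/reference/outgroup
#'   are all present.
#' @return A data.frame with the three columns.
#' @export
read_population_manifest <- function(path, require_scan_roles = TRUE) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "role")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(m$role), c("target", "reference", "outgroup", "archaic"))
  if (length(bad)) stop("unknown manifest role(s): ", paste(bad, collapse = ", "))
  if (require_scan_roles &&
      !all(c("target", "reference", "outgroup") %in% m$role)) {
    stop("manifest must contain target, reference and outgroup samples")
  }
  m[need]
}

#' Read phased genotypes from a VCF into a haplotype panel
#'
#' Retains biallelic SNPs only; multiallelic or non-SNP records are skipped
#' with a logged count. Sites whose per-site missing-allele rate among the
#' retained samples exceeds `max_missing` are dropped. Alleles are polarized
#' against the ancestral allele, taken from the `AA` INFO tag or an explicit
#' `ancestral` table -- never inferred; sites with no usable ancestral state
#' are dropped with a logged count.
#'
#' Missing alleles at retained sites are excluded from the frequency
#' denominators of the returned site table; in the binary haplotype matrix
#' they are represented as the ancestral state (the site table's
#' `missing_rate` column records where this happened).
#'
#' @param path Path to a VCF (4.x) file with phased `GT`.
#' @param manifest Manifest data.frame as from [read_population_manifest()];
#'   every manifest sample must be present in the VCF.
#' @param ancestral Optional data.frame with columns `pos`, `allele` giving
#'   the ancestral base per position; overrides the `AA` tag.
#' @param max_missing Maximal per-site missing-allele rate (default 0.05).
#' @return A list with elements `panel` (a [haplotype_panel()]) and `sites`
#'   (a site table with per-population DAF and `missing_rate`).
#' @export
read_phased_vcf <- function(path, manifest, ancestral = NULL,
                            max_missing = 0.05) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt[, -1, drop = FALSE]
  missing_samples <- setdiff(manifest$sample_id, colnames(gt))
  if (length(missing_samples)) {
    stop("manifest sample(s) absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  }
  gt <- gt[, manifest$sample_id, drop = FALSE]
  # drop the FORMAT payload beyond GT
  gt[] <- sub(":.*$", "", gt)

  chrom <- unique(fix[, "CHROM"])
  if (length(chrom) != 1L) stop("expected a single chromosome per VCF")

  snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE) & fix[, "ALT"] != "."
  if (any(!snp)) {
    message(sum(!snp), " multiallelic/non-SNP record(s) skipped")
  }
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, , drop = FALSE]
  pos <- as.numeric(fix[, "POS"])

  # ancestral allele per site
  if (!is.null(ancestral)) {
    aa <- ancestral$allele[match(pos, ancestral$pos)]
  } else {
    info <- fix[, "INFO"]
    aa <- ifelse(grepl("(^|;)AA=", info),
                 sub(".*(^|;)AA=([^;]*).*", "\\2", info), NA_character_)
  }
  aa <- toupper(aa)
  polarizable <- !is.na(aa) & (aa == fix[, "REF"] | aa == fix[, "ALT"])
  if (any(!polarizable)) {
    message(sum(!polarizable), " site(s) without usable ancestral allele dropped")
  }
  fix <- fix[polarizable, , drop = FALSE]
  gt <- gt[polarizable, , drop = FALSE]
  pos <- pos[polarizable]
  aa <- aa[polarizable]
  flip <- aa == fix[, "ALT"] # ALT is ancestral: derived allele is REF

  n_sam <- nrow(manifest)
  miss_gt <- is.na(gt) | gt == "." | gt == ".|." | gt == "./."
  unphased <- !miss_gt & !grepl("|", gt, fixed = TRUE)
  if (any(unphased)) {
    w <- which(unphased, arr.ind = TRUE)[1L, ]
    stop(sprintf("unphased genotype for sample %s at %s:%s",
                 manifest$sample_id[w[2L]], chrom, pos[w[1L]]))
  }

  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  a1[miss_gt] <- NA; a2[miss_gt] <- NA
  miss_rate <- rowMeans(miss_gt)
  keep <- miss_rate <= max_missing
  if (any(!keep)) {
    message(sum(!keep), " site(s) dropped for missing rate > ", max_missing)
  }
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]; flip <- flip[keep]
  a1 <- a1[keep, , drop = FALSE]; a2 <- a2[keep, , drop = FALSE]
  miss_rate <- miss_rate[keep]
  if (!length(pos)) stop("no sites retained from ", path)

  S <- length(pos)
  d1 <- a1 == "1"; d2 <- a2 == "1" # sites x samples, NA where missing
  d1[flip, ] <- a1[flip, , drop = FALSE] == "0"
  d2[flip, ] <- a2[flip, , drop = FALSE] == "0"
  H <- matrix(0L, nrow = 2L * n_sam, ncol = S)
  zero_na <- function(x) { x[is.na(x)] <- FALSE; x * 1L }
  H[seq(1L, 2L * n_sam, by = 2L), ] <- t(zero_na(d1))
  H[seq(2L, 2L * n_sam, by = 2L), ] <- t(zero_na(d2))

  panel <- haplotype_panel(chrom, pos, H, manifest$sample_id,
                           manifest$population, rsid = fix[, "ID"])
  sites <- data.frame(chrom = chrom, pos = pos, rsid = fix[, "ID"],
                      missing_rate = miss_rate, stringsAsFactors = FALSE)
  for (p in unique(manifest$population)) {
    samp <- manifest$population == p
    da <- d1[, samp, drop = FALSE]; db <- d2[, samp, drop = FALSE]
    cnt <- rowSums(da, na.rm = TRUE) + rowSums(db, na.rm = TRUE)
    den <- 2 * sum(samp) - rowSums(is.na(da)) - rowSums(is.na(db))
    sites[[paste0("dac_", p)]] <- as.integer(cnt)
    sites[[paste0("daf_", p)]] <- ifelse(den > 0, cnt / den, NA_real_)
  }
  list(panel = panel, sites = sites)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCF 4.2 with polarized biallelic SNPs: the ancestral state
#' is written as REF (and as the `AA` INFO tag), the derived state as ALT.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  n_sam <- length(panel$sample_ids)
  h1 <- panel$H[seq(1L, 2L * n_sam, by = 2L), , drop = FALSE]
  h2 <- panel$H[seq(2L, 2L * n_sam, by = 2L), , drop = FALSE]
  gt_cols <- matrix(paste0(t(h1), "|", t(h2)), nrow = n_sites(panel))
  id <- ifelse(is.na(panel$rsid), ".", panel$rsid)
  body <- paste(panel$chrom, format(panel$positions, scientific = FALSE, trim = TRUE),
                id, "A", "G", ".", "PASS", "AA=A", "GT",
                apply(gt_cols, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", panel$chrom),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a manifest matching a panel
#' @param panel A [haplotype_panel()].
#' @param roles Named character vector mapping population label to role.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_population_manifest <- function(panel, roles, path) {
  m <- data.frame(sample_id = panel$sample_ids,
                  population = panel$population,
                  role = unname(roles[panel$population]),
                  stringsAsFactors = FALSE)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write candidate regions as BED
#'
#' Internal region coordinates are 1-based inclusive; BED is 0-based
#' half-open, so `start_bed = start - 1` and `end_bed = end`. Region score and
#' method provenance are carried in columns 4-6.
#'
#' @param regions Data.frame with at least `chrom`, `start`, `end`; optional
#'   `methods`, `score`, `p`. Regions must be non-overlapping within a
#'   chromosome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED: 0-based half-open; internal coordinates are 1-based inclusive",
             con)
  if (nrow(regions) == 0L) return(invisible(path))
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1L] <= r$end[-nrow(r)])) {
      stop("overlapping regions on ", ch)
    }
  }
  name <- if ("methods" %in% names(regions)) regions$methods else "."
  score <- if ("score" %in% names(regions)) regions$score else 0
  writeLines(paste(regions$chrom,
                   format(regions$start - 1, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE),
                   name, score, sep = "\t"), con)
  invisible(path)
}

#' Read a regions BED written by [write_regions_bed()]
#' @param path BED path.
#' @return Data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `methods`, `score`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), methods = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  f <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = f$V1, start = f$V2 + 1, end = f$V3,
             methods = if (ncol(f) >= 4) f$V4 else ".",
             score = if (ncol(f) >= 5) f$V5 else 0,
             stringsAsFactors = FALSE)
}
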