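# Small in-code fixtures shared across tests.

# Panel from an explicit haplotype matrix (rows = haplotypes, must be even).
toy_panel <- function(H, positions = NULL, pops = NULL, chrom = "chr1") {
  H <- as.matrix(H)
  n_sam <- nrow(H) / 2
  if (is.null(positions)) positions <- seq_len(ncol(H)) * 1000
  if (is.null(pops)) pops <- rep("TARGET", n_sam)
  haplotype_panel(chrom, positions, H, sprintf("S%02d", seq_len(n_sam)), pops)
}

# Small random two/three-population panel for property tests.
small_sim <- function(seed = 1, S = 400, L = 2e5, n = c(20, 20, 20), ...) {
  simulate_panel(sim_config(seed = seed, S = S, L = L, n_target = n[1],
                            n_ref = n[2], n_out = n[3], ...))
}

# Brute-force EHH: probability two distinct haplotypes are identical over
# the inclusive marker span from the core to the given index.
brute_ehh <- function(H, core, to) {
  span <- seq(min(core, to), max(core, to))
  m <- nrow(H)
  id <- apply(H[, span, drop = FALSE], 1, paste, collapse = "")
  same <- 0
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    same <- same + (id[i] == id[j])
  }
  same / choose(m, 2)
}

# Hand Benjamini-Hochberg: p_(i) * n / i, cumulative minimum from the top.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# A toy phased VCF as text, written to a temp file. 10 records: one
# triallelic, one with >5% missing alleles, one without an AA tag.
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    "chr1\t100\trs1\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t0|0\t1|1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\tAA=T\tGT\t0|1\t1|1\t0|0",
    "chr1\t300\trs3\tG\tA,T\t.\tPASS\tAA=G\tGT\t0|1\t0|2\t0|0",
    "chr1\t400\trs4\tT\tC\t.\tPASS\tAA=T\tGT\t.|.\t0|1\t0|0",
    "chr1\t500\trs5\tA\tC\t.\tPASS\tAA=A\tGT\t0|0\t0|1\t0|1",
    "chr1\t600\trs6\tG\tT\t.\tPASS\t.\tGT\t0|1\t0|0\t0|0",
    "chr1\t700\trs7\tC\tG\t.\tPASS\tAA=C\tGT\t1|1\t1|1\t1|1",
    "chr1\t800\trs8\tA\tT\t.\tPASS\tAA=A\tGT\t0|0\t0|0\t0|1",
    "chr1\t900\trs9\tT\tA\t.\tPASS\tAA=T\tGT\t0|1\t0|1\t0|0",
    "chr1\t1000\trs10\tC\tA\t.\tPASS\tAA=C\tGT\t1|0\t0|0\t0|0"
  )
  writeLines(lines, path)
  path
}

toy_manifest <- function() {
  data.frame(sample_id = c("S1", "S2", "S3"),
             population = c("TARGET", "TARGET", "REF"),
             role = c("target", "target", "reference"),
             stringsAsFactors = FALSE)
}
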