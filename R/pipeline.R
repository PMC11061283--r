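#' Pipeline configuration
#'
#' A single declarative configuration for the end-to-end run on synthetic
#' data: simulation, sweep/archaic injection, selection scan, candidate-SNP
#' ranking, introgression scan, phenotype association and lookup enrichment.
#' Every stochastic stage has an explicit seed derived from `seed`; every
#' scan parameter is surfaced here and logged in the run manifest.
#'
#' @param seed Master seed.
#' @param sim A [sim_config()].
#' @param sweep A [sweep_spec()] or `NULL`.
#' @param archaic List of [archaic_source()] or `NULL` (stage skipped).
#' @param scan A [scan_config()].
#' @param xp An [xpehh_config()].
#' @param model A [trajectory_model()] or `NULL` to build the default
#'   lazily.
#' @param hmm An [hmm_config()].
#' @param phenotype A [phenotype_spec()] or `NULL` to skip association.
#' @param n_phen Phenotype count for the lookup significance cutoff.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 7L, sim = sim_config(seed = 7L),
                            sweep = NULL, archaic = NULL,
                            scan = scan_config(), xp = xpehh_config(),
                            model = NULL, hmm = hmm_config(),
                            phenotype = phenotype_spec(),
                            n_phen = 20L, out_dir = tempfile("run")) {
  structure(list(seed = as.integer(seed), sim = sim, sweep = sweep,
                 archaic = archaic, scan = scan, xp = xp, model = model,
                 hmm = hmm, phenotype = phenotype, n_phen = n_phen,
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline on synthetic data
#'
#' Stages: simulate panel (+ sweep, + archaic tracts), write VCF/manifest,
#' selection scan (PBS, XP-EHH, Fisher; windows, resampling significance,
#' final merged regions), candidate-SNP ranking per region, archaic
#' introgression per region (skipped with a logged notice when no archaic
#' sources are configured), phenotype association for the candidate SNPs,
#' and the external-lookup enrichment stage on a simulated association
#' table. Outputs are TSV/BED plus a JSON manifest of parameters and seeds;
#' identical configs reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run directory path, invisibly; stage results as the
#'   `results` attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  results <- list()

  # --- stage 1: synthetic data -------------------------------------------
  sim <- simulate_panel(config$sim)
  panel <- sim$panel; truth <- sim$truth
  if (!is.null(config$sweep)) {
    sw <- inject_sweep(panel, truth, config$sweep, seed = config$seed + 1L)
    panel <- sw$panel; truth <- sw$truth
  }
  archaic_panel <- NULL
  if (!is.null(config$archaic)) {
    ar <- inject_archaic(panel, truth, config$archaic,
                         seed = config$seed + 2L)
    panel <- ar$panel; truth <- ar$truth; archaic_panel <- ar$archaic
  } else {
    message("no archaic sources configured; introgression stage will be skipped")
  }
  write_phased_vcf(panel, out("panel.vcf"))
  roles <- stats::setNames(c("target", "reference", "outgroup"),
                           config$sim$pop_names)
  write_population_manifest(panel, roles, out("manifest.tsv"))
  if (nrow(truth$tracts)) write_tsv(truth$tracts, out("truth_tracts.tsv"))

  # --- stage 2: selection scan -------------------------------------------
  pops <- config$sim$pop_names
  scan <- selection_scan(panel, pops[1], pops[2], pops[3], config$scan,
                         config$xp, seed = config$seed + 3L)
  write_tsv(scan$track, out("track.tsv"))
  write_tsv(scan$windows, out("windows.tsv"))
  write_regions_bed(scan$final, out("regions.bed"))
  results$scan <- scan

  # --- stage 3: candidate SNPs -------------------------------------------
  model <- config$model
  if (is.null(model) && nrow(scan$final)) model <- trajectory_model()
  candidates <- NULL
  if (nrow(scan$final)) {
    candidates <- do.call(rbind, lapply(seq_len(nrow(scan$final)), function(i) {
      rc <- rank_candidates(scan$final[i, ], panel, model, target = pops[1],
                            seed = config$seed + 10L + i)
      if (is.null(rc$candidate)) {
        return(data.frame(region = i, pos = NA_real_, daf = NA_real_,
                          loglr_mean50 = NA_real_))
      }
      data.frame(region = i, pos = rc$candidate$pos, daf = rc$candidate$daf,
                 loglr_mean50 = rc$candidate$loglr_mean50)
    }))
    write_tsv(candidates, out("candidates.tsv"))
  }
  results$candidates <- candidates

  # --- stage 4: archaic introgression ------------------------------------
  if (!is.null(archaic_panel) && nrow(scan$final)) {
    regions <- scan$final
    if (!is.null(candidates)) regions$candidate_pos <- candidates$pos
    arch <- archaic_scan(panel, regions, archaic_panel, target = pops[1],
                         outgroup = pops[3], config = config$hmm)
    write_tsv(arch, out("introgression.tsv"))
    results$introgression <- arch
  }

  # --- stage 5: phenotype association ------------------------------------
  if (!is.null(config$phenotype) && !is.null(candidates) &&
      any(!is.na(candidates$pos))) {
    phen <- simulate_phenotypes(panel, config$phenotype,
                                seed = config$seed + 4L)
    write_tsv(phen, out("phenotypes.tsv"))
    idx <- match(candidates$pos[!is.na(candidates$pos)], panel$positions)
    assoc <- association_tests(panel, idx, phen)
    write_tsv(assoc, out("association.tsv"))
    results$association <- assoc
  }

  # --- stage 6: external lookup enrichment -------------------------------
  if (!is.null(candidates) && any(!is.na(candidates$pos))) {
    cand_pos <- candidates$pos[!is.na(candidates$pos)]
    phen_list <- data.frame(
      phenotype = c(sprintf("blood_%02d", 1:5), sprintf("other_%02d", 1:15)),
      category = c(rep("blood_count", 5), rep("other", 15)),
      stringsAsFactors = FALSE)
    lookup <- simulate_assoc_table(
      panel$positions[seq(1L, n_sites(panel), by = 4L)], phen_list,
      blood_sig_pos = cand_pos[seq_len(min(2L, length(cand_pos)))],
      seed = config$seed + 5L)
    write_tsv(lookup, out("lookup_table.tsv"))
    enr <- blood_enrichment_test(cand_pos, lookup, n_phen = config$n_phen,
                                 seed = config$seed + 6L)
    results$enrichment <- enr
    write_tsv(data.frame(p = enr$p, observed = enr$observed, x = enr$x,
                         universe = enr$universe_size,
                         blood_windows = enr$blood_windows),
              out("enrichment.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sweepscan")),
    seed = config$seed,
    sim = unclass(config$sim),
    sweep = if (!is.null(config$sweep)) unclass(config$sweep),
    archaic = if (!is.null(config$archaic))
      lapply(config$archaic, unclass),
    scan = unclass(config$scan), xp = unclass(config$xp),
    hmm = unclass(config$hmm), n_phen = config$n_phen
  )
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$truth <- truth
  results$panel <- panel
  structure(invisible(config$out_dir), results = results)
}
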