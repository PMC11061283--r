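#' Simulation configuration for a three-population haplotype panel
#'
#' The generator emulates the data regime of a two-population selection scan
#' with an outgroup: a target population of ~54 diploids, a reference of ~74
#' and an outgroup, with Balding-Nichols allele-frequency differentiation
#' around ancestral frequencies and founder-mosaic haplotypes whose linkage
#' disequilibrium decays with physical distance.
#'
#' Defaults: drift parameters `F_target = F_ref = 0.01` (closely related
#' populations), `F_out = 0.15` (a continental-scale outgroup);
#' `rho = 2e-5` switches per bp gives haplotype segments of ~50 kb; `K = 80`
#' founders per population.
#'
#' @param seed Integer seed; the panel is a pure function of the config.
#' @param L Region length in bp.
#' @param S Number of segregating sites (>= 20, one scan window).
#' @param n_target,n_ref,n_out Diploid sample sizes.
#' @param F_target,F_ref,F_out Balding-Nichols drift parameters in `[0, 1)`.
#' @param K Founder haplotypes per population.
#' @param rho Founder-switch (mosaic recombination) rate per bp.
#' @param pop_names Labels for the three populations.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, L = 2e6, S = 5000L,
                       n_target = 54L, n_ref = 74L, n_out = 50L,
                       F_target = 0.01, F_ref = 0.01, F_out = 0.15,
                       K = 80L, rho = 2e-5,
                       pop_names = c("TARGET", "REF", "OUT")) {
  if (S < 20L) stop("S must be >= 20 (cannot form one scan window)")
  stopifnot(L > 0, rho >= 0, K >= 2L,
            F_target >= 0, F_target < 1, F_ref >= 0, F_ref < 1,
            F_out >= 0, F_out < 1, length(pop_names) == 3L)
  structure(list(seed = as.integer(seed), L = L, S = as.integer(S),
                 n_target = as.integer(n_target), n_ref = as.integer(n_ref),
                 n_out = as.integer(n_out), F_target = F_target,
                 F_ref = F_ref, F_out = F_out, K = as.integer(K), rho = rho,
                 pop_names = pop_names),
            class = "sim_config")
}

# Balding-Nichols draw of population frequencies around ancestral p with drift F
bn_freq <- function(p, F) {
  if (F <= 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# founder pool carrying the derived allele in exactly round(K * p) haplotypes
make_founders <- function(K, p) {
  S <- length(p)
  cnt <- pmin(K, round(K * p))
  Fm <- matrix(0L, nrow = K, ncol = S)
  for (j in which(cnt > 0L)) Fm[sample.int(K, cnt[j]), j] <- 1L
  Fm
}

# mosaic copy of founders with Poisson(rho per bp) switch points
mosaic_haps <- function(founders, n_hap, positions, rho) {
  K <- nrow(founders); S <- ncol(founders)
  p_switch <- 1 - exp(-rho * diff(positions))
  H <- matrix(0L, nrow = n_hap, ncol = S)
  for (i in seq_len(n_hap)) {
    seg <- cumsum(c(0L, (stats::runif(S - 1L) < p_switch) * 1L))
    fid <- sample.int(K, max(seg) + 1L, replace = TRUE)
    H[i, ] <- founders[cbind(fid[seg + 1L], seq_len(S))]
  }
  H
}

#' Simulate a phased three-population haplotype panel
#'
#' Ancestral frequencies follow a neutral-SFS-shaped distribution (Beta with
#' mass near zero, clipped away from fixation); per-population frequencies
#' follow Balding-Nichols drift around them; haplotypes are founder mosaics
#' with Poisson switch points, so LD decays with distance. Identical configs
#' give bitwise-identical panels.
#'
#' @param config A [sim_config()].
#' @return A list with `panel` (a [haplotype_panel()]) and `truth` (a truth
#'   record with `sweep`, `tracts`, `causal`, initially empty).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$S
  positions <- sort(sample.int(config$L, S))
  p_anc <- pmin(0.99, pmax(0.01, stats::rbeta(S, 0.3, 1)))
  ns <- c(config$n_target, config$n_ref, config$n_out)
  Fs <- c(config$F_target, config$F_ref, config$F_out)
  H <- NULL
  for (k in 1:3) {
    pk <- bn_freq(p_anc, Fs[k])
    founders <- make_founders(config$K, pk)
    H <- rbind(H, mosaic_haps(founders, 2L * ns[k], positions, config$rho))
  }
  ids <- c(sprintf("%s_%03d", config$pop_names[1], seq_len(ns[1])),
           sprintf("%s_%03d", config$pop_names[2], seq_len(ns[2])),
           sprintf("%s_%03d", config$pop_names[3], seq_len(ns[3])))
  pop <- rep(config$pop_names, ns)
  panel <- haplotype_panel("chr1", positions, H, ids, pop)
  truth <- list(sweep = NULL,
                tracts = data.frame(hap = character(), start = numeric(),
                                    end = numeric(), source = character(),
                                    stringsAsFactors = FALSE),
                causal = NULL)
  list(panel = panel, truth = truth)
}

#' Sweep specification
#'
#' @param pos Focal bp position (snapped to the nearest site segregating in
#'   the target population).
#' @param f Target derived allele frequency of the focal SNP after injection.
#' @param core_bp Width of the core window over which carrier haplotypes are
#'   re-copied from a single template, producing the extended shared flanks a
#'   recent hard sweep leaves.
#' @param erosion_bp Mean one-sided extent (exponential) of the interval each
#'   recruited carrier copies from the template, emulating recombination
#'   eroding hitchhiker association away from the focal SNP during the sweep;
#'   `Inf` copies the whole core.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(pos, f = 0.9, core_bp = 2e5, erosion_bp = 5e4) {
  stopifnot(f > 0, f < 1, core_bp > 0, erosion_bp > 0)
  structure(list(pos = pos, f = f, core_bp = core_bp,
                 erosion_bp = erosion_bp), class = "sweep_spec")
}

#' Inject a hard sweep into the target population
#'
#' Raises the focal derived allele to frequency `f` among target chromosomes
#' by re-copying carrier haplotypes from one carrier template across the core
#' window, so carriers share long identical flanks (the signal classes that
#' frequency-differentiation and haplotype-homozygosity scans detect).
#' Reference and outgroup rows are untouched.
#'
#' @param panel A [haplotype_panel()].
#' @param truth Truth record (as from [simulate_panel()]).
#' @param spec A [sweep_spec()], or `NULL` for a no-op.
#' @param target Population label of the swept population.
#' @param seed Optional seed for reproducibility.
#' @return List with updated `panel` and `truth`.
#' @export
inject_sweep <- function(panel, truth, spec, target = "TARGET", seed = NULL) {
  if (is.null(spec)) return(list(panel = panel, truth = truth))
  stopifnot(inherits(spec, "sweep_spec"))
  force(panel); force(truth) # force promises before seeding
  if (!is.null(seed)) set.seed(seed)
  rows <- hap_rows(panel, target)
  p_t <- colMeans(panel$H[rows, , drop = FALSE])
  seg <- which(p_t > 0 & p_t < 1)
  if (!length(seg)) stop("no site segregating in the target population")
  j <- seg[which.min(abs(panel$positions[seg] - spec$pos))]
  focal_pos <- panel$positions[j]
  carriers <- rows[panel$H[rows, j] == 1L]
  n_need <- round(spec$f * length(rows))
  if (!length(carriers)) stop("focal site fixed ancestral in target")
  template <- sample(carriers, 1L)
  core <- which(panel$positions >= focal_pos - spec$core_bp / 2 &
                panel$positions <= focal_pos + spec$core_bp / 2)
  if (n_need > length(carriers)) {
    recruits <- sample(setdiff(rows, carriers), n_need - length(carriers))
    carriers <- c(carriers, recruits)
  } else if (n_need < length(carriers)) {
    drop <- sample(carriers, length(carriers) - n_need)
    panel$H[drop, j] <- 0L
    carriers <- setdiff(carriers, drop)
  }
  half <- spec$core_bp / 2
  for (r in setdiff(carriers, template)) {
    lo <- focal_pos - min(half, stats::rexp(1L, 1 / spec$erosion_bp))
    hi <- focal_pos + min(half, stats::rexp(1L, 1 / spec$erosion_bp))
    span <- core[panel$positions[core] >= lo & panel$positions[core] <= hi]
    panel$H[r, span] <- panel$H[template, span]
    panel$H[r, j] <- 1L
  }
  truth$sweep <- list(pos = focal_pos, index = j, population = target,
                      f = spec$f, core_bp = spec$core_bp)
  list(panel = panel, truth = truth)
}

#' Archaic source specification
#'
#' @param name Source label; by convention `"NEA"` (three Neanderthal-like
#'   panel individuals are emitted from this lineage) or `"DEN"` (one
#'   Denisovan-like individual).
#' @param alpha Fraction of target chromosomes that receive a tract.
#' @param lambda Mean tract length in bp (geometric lengths).
#' @param d Density per bp of private derived alleles on the source lineage.
#' @param focal Focal bp position every tract from this source overlaps.
#' @return An `archaic_source` list.
#' @export
archaic_source <- function(name, alpha = 0.4, lambda = 4e4, d = 0.001,
                           focal = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, lambda > 0, d > 0)
  structure(list(name = name, alpha = alpha, lambda = lambda, d = d,
                 focal = focal), class = "archaic_source")
}

#' Inject archaic tracts from two divergent sources into the target population
#'
#' Each source is a single archaic haplotype: a copy of one modern reference
#' haplotype (the shared ancestral backbone) plus private derived alleles at
#' density `d` per bp, at positions added to the panel (all modern haplotypes
#' are ancestral there, so by construction the private alleles are absent from
#' the outgroup -- the archaic-SNP premise). Tracts of geometric length
#' (mean `lambda`) covering the source's focal position are pasted into a
#' fraction `alpha` of target chromosomes. Four archaic pseudo-individuals are
#' emitted: three Neanderthal-like copies of the `"NEA"` lineage (each
#' retaining a random 85% of its private alleles) and one Denisovan-like copy
#' of the `"DEN"` lineage.
#'
#' @param panel A [haplotype_panel()].
#' @param truth Truth record.
#' @param sources List of [archaic_source()] (two sources configured).
#' @param target,reference Population labels.
#' @param seed Optional seed.
#' @return List with `panel`, `truth` and `archaic` (a [haplotype_panel()]
#'   holding the four archaic individuals on the same site set).
#' @export
inject_archaic <- function(panel, truth, sources, target = "TARGET",
                           reference = "REF", seed = NULL) {
  stopifnot(length(sources) >= 1L,
            all(vapply(sources, inherits, TRUE, "archaic_source")))
  force(panel); force(truth)
  if (!is.null(seed)) set.seed(seed)
  L <- max(panel$positions)
  for (s in sources) if (s$lambda >= L) stop("tract mean length >= region length")

  active <- Filter(function(s) s$alpha > 0, sources)
  backbone_row <- sample(hap_rows(panel, reference), length(sources))

  # new private-site positions per active source
  priv <- list()
  taken <- panel$positions
  for (i in seq_along(sources)) {
    s <- sources[[i]]
    if (s$alpha > 0) {
      np <- stats::rpois(1L, s$d * L)
      cand <- setdiff(sample.int(L, min(L, np + length(taken))), taken)
      pp <- sort(cand[seq_len(min(np, length(cand)))])
      priv[[s$name]] <- pp
      taken <- c(taken, pp)
    } else priv[[s$name]] <- numeric(0)
  }
  new_pos <- sort(unlist(priv, use.names = FALSE))
  all_pos <- sort(c(panel$positions, new_pos))
  old_idx <- match(panel$positions, all_pos)
  H2 <- matrix(0L, nrow = nrow(panel$H), ncol = length(all_pos))
  H2[, old_idx] <- panel$H
  panel2 <- haplotype_panel(panel$chrom, all_pos, H2, panel$sample_ids,
                            panel$population)

  # archaic source haplotypes on the full site set
  src_hap <- list()
  for (i in seq_along(sources)) {
    s <- sources[[i]]
    v <- integer(length(all_pos))
    v[old_idx] <- panel$H[backbone_row[i], ]
    v[match(priv[[s$name]], all_pos)] <- 1L
    src_hap[[s$name]] <- v
  }

  # paste tracts into target chromosomes
  t_rows <- hap_rows(panel2, target)
  tracts <- truth$tracts
  for (s in sources) {
    if (s$alpha == 0) next
    focal <- if (is.null(s$focal)) round(L / 2) else s$focal
    carriers <- sample(t_rows, round(s$alpha * length(t_rows)))
    for (r in carriers) {
      len <- stats::rgeom(1L, 1 / s$lambda) + 1L
      start <- max(1, focal - floor(stats::runif(1L) * len))
      end <- min(L, start + len - 1L)
      cols <- which(all_pos >= start & all_pos <= end)
      panel2$H[r, cols] <- src_hap[[s$name]][cols]
      tracts <- rbind(tracts, data.frame(
        hap = rownames(panel2$H)[r], start = start, end = end,
        source = s$name, stringsAsFactors = FALSE))
    }
  }
  truth$tracts <- tracts

  # four archaic pseudo-individuals (homozygous haploid copies)
  arch_ids <- c("NEA1", "NEA2", "NEA3", "DEN")
  arch_pop <- arch_ids
  AH <- matrix(0L, nrow = 8L, ncol = length(all_pos))
  nea <- if ("NEA" %in% names(src_hap)) src_hap[["NEA"]] else integer(length(all_pos))
  den <- if ("DEN" %in% names(src_hap)) src_hap[["DEN"]] else integer(length(all_pos))
  nea_priv_idx <- match(priv[["NEA"]], all_pos)
  for (k in 1:3) {
    v <- nea
    if (length(nea_priv_idx)) {
      dropped <- nea_priv_idx[stats::runif(length(nea_priv_idx)) > 0.85]
      v[dropped] <- 0L
    }
    AH[2L * k - 1L, ] <- v; AH[2L * k, ] <- v
  }
  AH[7L, ] <- den; AH[8L, ] <- den
  archaic <- haplotype_panel(panel$chrom, all_pos, AH, arch_ids, arch_pop)

  list(panel = panel2, truth = truth, archaic = archaic)
}

#' Phenotype simulation specification
#'
#' Phenotypes are generated as `y = sum(beta_j g_j) + b_age age + b_sex sex
#' (+ b_height height) + noise`, with age ~ Uniform(18, 65), sex ~
#' Bernoulli(0.5), height ~ Normal(155 + 10 sex, 7). The height-adjusted
#' group (chest depth, waist, weight, FEV1, PEF, FVC) receives the height
#' term; the age/sex group (heart rate, haemoglobin, blood pressure, BMI)
#' does not.
#'
#' @param causal Data.frame with columns `pos`, `beta`, `phenotype` (which
#'   phenotype each causal SNP affects), or `NULL`.
#' @param b_age,b_sex,b_height Covariate effect sizes.
#' @param sigma Residual standard deviation (> 0).
#' @return A `phenotype_spec` list.
#' @export
phenotype_spec <- function(causal = NULL, b_age = 0.2, b_sex = 3,
                           b_height = 0.3, sigma = 5) {
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(causal = causal, b_age = b_age, b_sex = b_sex,
                 b_height = b_height, sigma = sigma),
            class = "phenotype_spec")
}

#' Standard phenotype groups for covariate correction
#'
#' @return Named character vector: phenotype -> covariate group
#'   (`"age+sex"` or `"age+sex+height"`).
#' @export
phenotype_groups <- function() {
  c(heart_rate = "age+sex", haemoglobin = "age+sex",
    blood_pressure = "age+sex", bmi = "age+sex",
    chest_depth = "age+sex+height", waist = "age+sex+height",
    weight = "age+sex+height", fev1 = "age+sex+height",
    pef = "age+sex+height", fvc = "age+sex+height")
}

#' Simulate a phenotype table for the diploid samples of a panel
#'
#' @param panel A [haplotype_panel()].
#' @param spec A [phenotype_spec()].
#' @param seed Optional seed.
#' @return A data.frame with sample ids, covariates and the ten standard
#'   phenotypes of [phenotype_groups()].
#' @export
simulate_phenotypes <- function(panel, spec, seed = NULL) {
  stopifnot(inherits(spec, "phenotype_spec"))
  force(panel)
  if (!is.null(seed)) set.seed(seed)
  n <- length(panel$sample_ids)
  age <- stats::runif(n, 18, 65)
  sex <- stats::rbinom(n, 1L, 0.5)
  height <- stats::rnorm(n, 155 + 10 * sex, 7)
  out <- data.frame(sample_id = panel$sample_ids,
                    population = panel$population,
                    age = age, sex = sex, height = height,
                    stringsAsFactors = FALSE)
  groups <- phenotype_groups()
  base <- c(heart_rate = 70, haemoglobin = 14, blood_pressure = 120,
            bmi = 24, chest_depth = 20, waist = 80, weight = 65,
            fev1 = 3.5, pef = 450, fvc = 4.2)
  for (ph in names(groups)) {
    y <- base[[ph]] + spec$b_age * age + spec$b_sex * sex +
      (if (groups[[ph]] == "age+sex+height") spec$b_height * height else 0) +
      stats::rnorm(n, 0, spec$sigma)
    if (!is.null(spec$causal)) {
      for (k in which(spec$causal$phenotype == ph)) {
        j <- which.min(abs(panel$positions - spec$causal$pos[k]))
        g <- genotype_vector(panel, j)
        y <- y + spec$causal$beta[k] * g
      }
    }
    out[[ph]] <- y
  }
  out
}

#' Diploid genotype (0/1/2 derived-allele dosage) at one site
#' @param panel A [haplotype_panel()].
#' @param j Site index.
#' @return Integer vector, one dosage per diploid sample.
#' @export
genotype_vector <- function(panel, j) {
  n <- length(panel$sample_ids)
  panel$H[seq(1L, 2L * n, by = 2L), j] + panel$H[seq(2L, 2L * n, by = 2L), j]
}

#' Simulate an external association lookup table
#'
#' Emulates biobank-style summary statistics: one row per site x phenotype
#' with a beta and a p-value, and a category flag marking blood-count
#' phenotypes. A configurable subset of sites is planted with significant
#' blood-phenotype associations.
#'
#' @param positions Bp positions covered by the table.
#' @param phenotypes Data.frame with columns `phenotype`, `category`; at
#'   least one category must be `"blood_count"`.
#' @param blood_sig_pos Positions planted with a significant blood
#'   association.
#' @param other_sig_pos Positions planted with a significant non-blood
#'   association.
#' @param sig_p P-value assigned to planted associations.
#' @param assoc_prob Probability a background site x phenotype pair is kept
#'   as an (unremarkable) association row.
#' @param seed Optional seed.
#' @return A data.frame with `pos`, `phenotype`, `category`, `beta`, `p`.
#' @export
simulate_assoc_table <- function(positions, phenotypes,
                                 blood_sig_pos = numeric(0),
                                 other_sig_pos = numeric(0),
                                 sig_p = 1e-12, assoc_prob = 0.3,
                                 seed = NULL) {
  if (is.null(phenotypes) || nrow(phenotypes) == 0L) {
    stop("phenotype list must be non-empty")
  }
  if (!"blood_count" %in% phenotypes$category) {
    stop("phenotype list must include a blood_count category")
  }
  force(positions); force(phenotypes)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(pos = positions, phenotype = phenotypes$phenotype,
                      stringsAsFactors = FALSE)
  grid$category <- phenotypes$category[match(grid$phenotype,
                                             phenotypes$phenotype)]
  keep <- stats::runif(nrow(grid)) < assoc_prob
  planted_blood <- grid$pos %in% blood_sig_pos & grid$category == "blood_count"
  planted_other <- grid$pos %in% other_sig_pos & grid$category != "blood_count"
  grid <- grid[keep | planted_blood | planted_other, , drop = FALSE]
  planted <- (grid$pos %in% blood_sig_pos & grid$category == "blood_count") |
    (grid$pos %in% other_sig_pos & grid$category != "blood_count")
  grid$beta <- stats::rnorm(nrow(grid), 0, 0.02)
  grid$p <- stats::runif(nrow(grid), 1e-4, 1)
  grid$p[planted] <- sig_p
  rownames(grid) <- NULL
  grid
}
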