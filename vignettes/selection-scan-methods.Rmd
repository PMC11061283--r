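---
title: "Selection scans, trajectory ranking and archaic introgression: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans, trajectory ranking and archaic introgression: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# The problem

Two closely related populations that have occupied contrasting environments
for hundreds of generations — for instance highland and lowland groups
facing hypoxia and malaria respectively — are expected to carry
population-specific signatures of recent positive selection. `sweepscan`
implements the full analysis chain that such a study runs on phased
whole-genome panels:

1. per-SNP selection statistics (PBS, XP-EHH) and their windowed scan;
2. region calling with percentile thresholds, interval merging, flank
   extension and resampling significance;
3. per-region candidate-SNP ranking by an allele-frequency-trajectory
   likelihood ratio;
4. archaic-introgression tract detection, ancestry assignment and
   haplotype-frequency reporting inside the candidate regions;
5. phenotype association with a kinship-corrected linear mixed model and
   Benjamini–Hochberg calling; and
6. lookup of candidate SNPs in external (biobank-style) summary statistics
   with a resampling blood-phenotype enrichment test.

Real data of this kind are controlled-access, so the package ships a seeded
synthetic-data generator that emulates the study regime (a target
population of 54 diploids, a reference of 74, an outgroup, one injected
sweep, archaic tracts from two divergent sources) and every stage is tested
against that generator's truth records.

# Selection statistics

**FST and PBS.** Per-site FST uses the Hudson/Bhatia estimator,
\[
F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
              {p_1(1-p_2)+p_2(1-p_1)},
\]
which is unbiased under unequal sample sizes — the natural choice when the
statistic feeds a per-SNP scan. Estimates are clamped to $[0, 1-\epsilon]$
with $\epsilon = 10^{-6}$ so that the branch length $T = -\ln(1-F_{ST})$
stays finite at fixed differences; negative estimates clamp to zero. The
population branch statistic is
$\mathrm{PBS} = (T_{TR} + T_{TO} - T_{RO})/2$ for target $T$, reference $R$
and outgroup $O$; negative values are retained (they indicate change on the
non-target branches). Sites where an FST is undefined (both populations
fixed for the same allele) propagate as missing and are excluded before
windowing.

**EHH and XP-EHH.** EHH at marker step $k$ from a core SNP is the
probability that two random haplotypes of the sample are identical over all
markers from the core out to step $k$ ($\mathrm{EHH}_0 = 1$ by convention;
the core marker enters at step 1). XP-EHH integrates EHH over physical
distance (trapezoidal rule) in both directions, separately within the
target and the reference sample, and scores each site with
$\ln(\mathrm{iHH}_T/\mathrm{iHH}_R)$, normalized genome-wide to z-scores.
Extension stops when the EHH of the *pooled* sample drops below 0.05
(so both populations integrate over the same interval, which preserves the
antisymmetry of the score under population swap exactly), or at inter-marker
gaps above 200 kb. Distance is physical base pairs; a genetic map is a
deliberate non-dependency — the map would be an external input and physical
distance keeps the scan reproducible from the VCF alone.

# From tracks to regions

Windows are 20 SNPs with a step of 5, after removing missing-score SNPs; a
trailing remainder shorter than 20 SNPs yields no window. Window PBS is the
mean over its 20 SNPs, window XP-EHH the maximum. Retention is at the
empirical 99th percentile; retained windows (or, for XP-EHH, retained top
SNPs) merge when separated by at most 10 kb between nearest endpoints, and
a region inherits its best member score. The Fisher score per window is
$-\log_{10}(\mathrm{rank}_{PBS}) - \log_{10}(\mathrm{rank}_{XPEHH})$ with
upper-tail percentile ranks; ties count as "greater or equal", which makes
the score conservative under ties and bounds it by $2\log_{10} N$. For a
reference-population scan the XP-EHH track is negated so that "top" always
means the upper tail internally — one code path for both directions.

Significance of a region is assessed by resampling its scoring unit (the
SNP for XP-EHH, the 20-SNP window for PBS and Fisher): `M` units are drawn
uniformly with replacement from the genome-wide unit scores and
$p = (1 + \#\{\text{draw} \ge \text{region score}\})/(1+M)$, the
add-one estimator that never returns zero. `M` defaults to $10^6$ for
SNP units and $10^5$ for window units, enough to resolve the configured
thresholds ($2\times10^{-5}$ XP-EHH, $2\times10^{-4}$ PBS,
$2\times10^{-3}$ Fisher). Each method's ten best regions passing its
threshold are extended by 50 kb flanks, and overlapping regions are unioned
across methods with provenance kept; the merge is idempotent.

A scale consequence worth knowing: with ties counted as $\ge$, the smallest
achievable resampling p is about (number of units at the maximum)/(number
of units). On a 5,000-SNP synthetic region the XP-EHH floor
($\approx 2\times10^{-4}$) therefore sits *above* its genome-scale
threshold of $2\times10^{-5}$, and sweep regions at demo scale are carried
by the Fisher (and occasionally PBS) path. This is intentional: the
thresholds are study constants, not knobs, and the null-calibration
experiment accounts for the per-method unit counts explicitly when
predicting how many "significant" regions a null panel should yield.

# Trajectory likelihood ranking

Each final region's SNPs are ranked by a Wright–Fisher
allele-frequency-trajectory likelihood ratio. The model is a hidden Markov
model on a frequency grid of $B = 50$ bins over $(0,1)$: uniform initial
distribution $G = 980$ generations ago (27,440 years at 28 years per
generation), per-generation transition
$\mathcal{N}(x + s\,x(1-x),\; x(1-x)/2N_e)$ discretized by bin-edge
integration with absorbing first and last bins, and one binomial emission of
the present-day derived count $k$ of $n$ sampled chromosomes. The score is
$\mathrm{logLR} = \ln\max_s L(s) - \ln L(0)$ over the selection grid
$s \in \{0, 0.002, \ldots, 0.1\}$ (positive selection only), non-negative
by construction. Because the emission is terminal, the final-generation
distribution under each $s$ is data-independent and is precomputed once at
model construction; a single SNP evaluation is then one dot product, which
is what makes the two-stage multi-run procedure cheap.

The procedure mirrors the study design: every eligible SNP (derived allele
frequency $\ge 0.05$ in the target and not fixed) is scored five times on
bootstrap resamples of the $n$ chromosomes and averaged; the top five
advance and are scored fifty additional times; the SNP with the highest
mean over those runs is the region's candidate, ties breaking to the lower
position. Bootstrap resampling supplies the run-to-run stochasticity that a
tree-based method would obtain from branch-length resampling; a resample
fixed at 0 or $n$ is retried and, failing that, flagged unscorable rather
than imputed.

**What this stand-in can and cannot do.** Two limitations follow directly
from conditioning on a single present-day count:

* *Resolution of $\hat{s}$.* Over 980 generations, any coefficient above
  about $0.01$ drives an interior frequency to fixation
  ($e^{sG} \gg 1$), so interior observations are informative about small
  $s$ only, and one observation cannot pin $s$ to the grid's 0.002
  resolution. The parameter-recovery experiment (simulating from the
  model's own generative chain at $s = 0.05$, the only reading under which
  polymorphic endpoint data exist at all at that strength) accordingly
  measures a median $|\hat{s}-s|$ of roughly an order of magnitude above
  one grid step. The acceptance suite states the one-grid-step target and
  reports the measured value honestly; the rank-order property (selected
  trajectories out-score neutral ones) is the one the downstream procedure
  actually relies on, and it holds.
* *Hitchhikers.* The likelihood is monotone in the sample frequency, so the
  ranking cannot separate the focal SNP from variants at equal or higher
  frequency on the same swept haplotype, nor from old, regionally common
  alleles that are near-fixed in both populations. The study this package
  models makes the same caveat about its own candidate SNPs being possibly
  in high LD with the true target; with frequency-only information the
  effect is stronger, and the sweep-recovery experiment reports the strict
  focal-pick rate as measured rather than tuning the generator to avoid
  honest competition.

# Archaic introgression

Per haplotype, derived variants absent from the outgroup sample are counted
in 1 kb windows and a two-state (Human/Archaic) hidden Markov model with
Poisson emissions is fit by Baum–Welch (forward–backward in compiled code;
convergence at $\Delta\log L < 10^{-4}$ or 500 iterations; the Archaic
state is the higher-rate state by orientation). Candidate segments are
maximal runs of windows with posterior $P(\text{Archaic}) > 0.5$ and are
kept when their mean posterior is at least 0.8. A degenerate fit (equal
rates, e.g. no private variation) warns and yields no segments.

Segments enter a candidate region's report only if fully contained in the
region and sharing at least one aSNP — a derived variant absent from the
outgroup — with one of the four archaic reference individuals (three
Neanderthal-lineage, one Denisovan). Ancestry is assigned by counting the
segment's aSNPs that are derived in the Denisovan against those derived in
the union of the three Neanderthals; the union reading of "all
Neanderthals" is a deliberate interpretation choice, and ties are
`ambiguous`. Region-level haplotypes come from the graph over aSNPs with
edges at $r^2 > 0.5$ on target chromosomes: connected components define
clusters, each segment joins the component holding most of its aSNPs (ties
to the larger component), frequency is carrier chromosomes over total
target chromosomes (tracts are phased, so chromosomes — not individuals —
are the denominator), cluster ancestry is the majority segment ancestry,
and the report flags whether the region's candidate SNP is in high LD
($r^2 > 0.5$) with any cluster aSNP.

# Association and enrichment

Phenotypes are corrected once by OLS — haemoglobin, blood pressure, heart
rate and BMI for age and sex; chest depth, waist, weight, FEV1, PEF and FVC
for age, sex and height — and the residuals are reused for every SNP. The
mixed model $y = \mu + g\beta + u + e$, $u \sim N(0, \sigma_g^2 K)$ with
$K = WW^\top/m$ the centred relatedness matrix, is profiled on the variance
ratio after one eigendecomposition of $K$ (Brent search on
$\log(\sigma_g^2/\sigma_e^2)$, tolerance $10^{-8}$), with a Wald t-test on
$\beta$; with $K = I$ this reduces exactly to OLS. P-values are BH-adjusted
across SNPs within each phenotype; calls are suggestive below adjusted 0.05
and strict below $0.05/5 = 0.01$, the five being groups of strongly
correlated phenotypes.

External lookup mimics biobank summary statistics: exact position match,
else the nearest table SNP within ±50 bp (ties to the smaller distance,
then the lower position), else a flagged null. A phenotype counts as
significant when $\log_{10}p < \log_{10}(5\times10^{-8}/n_{\text{phen}})$,
which is $-10.47$ at 1,470 phenotypes. The blood enrichment test draws
10,000 (configurable) sets of $x$ windows without replacement from the
universe of windows with at least one significant association ($x$ = number
of candidates with at least one significant association) and reports the
proportion of sets with at least as many blood-count windows as observed
("at least as extreme"; a strictly-greater variant is available). Under
this exchangeable null the Monte-Carlo p converges to the hypergeometric
tail, which is the oracle the calibration experiment checks against.
Effect directions from the lookup table are reported but never interpreted.

# The synthetic-data generator

The generator is the package's study stand-in, not a fixture: ancestral
frequencies follow a neutral-SFS-shaped Beta (mass near zero, clipped to
$[0.01, 0.99]$); population frequencies follow Balding–Nichols drift with
$F_{\text{target}} = F_{\text{ref}} = 0.01$ (closely related populations)
and $F_{\text{out}} = 0.15$ (a continental outgroup); haplotypes are
founder mosaics over $K = 80$ founders per population with Poisson switch
points at $\rho = 2\times10^{-5}$ per bp (segments of ~50 kb, LD decaying
with distance). Founders carry the derived allele in exactly
$\mathrm{round}(K p)$ of $K$ haplotypes, which removes founder-sampling
bias from FST so that $F = 0$ panels are undifferentiated to well below
0.01 — the analytic check the Balding–Nichols choice was made for.

Sweep injection raises the focal allele to frequency $f^*$ among target
chromosomes by re-copying recruits from one carrier template over a core
window (default 200 kb), with each recruit's copied interval drawn with
exponential one-sided extents (mean 50 kb) around the focal SNP — the
erosion recombination causes during a sweep. Archaic injection adds
private derived alleles at density $10^{-3}$ per bp on two source lineages
(each a reference-haplotype backbone plus privates), pastes
geometric-length tracts (mean 40 kb) covering a per-source focal point into
a fraction $\alpha$ of target chromosomes, and emits the four archaic
pseudo-individuals (the three Neanderthal-like ones each retain a random
85% of the lineage's privates). By construction archaic private alleles
are absent from the outgroup — the aSNP premise. What the generator does
*not* model: realistic demography, recombination-map heterogeneity,
genotyping error, shared archaic–modern polymorphism, and archaic
divergence beyond private derived alleles. Passing tests therefore
demonstrate correctness of the machinery under the stated generative
assumptions, not performance on real genomes.

Phenotypes are $y = \sum_j \beta_j g_j + b_{\text{age}}\,\text{age} +
b_{\text{sex}}\,\text{sex}\,(+\,b_{\text{height}}\,\text{height}) +
\varepsilon$ with age ~ Uniform(18, 65), sex ~ Bernoulli(0.5), height ~
Normal(155 + 10·sex, 7) and $\varepsilon \sim N(0, \sigma^2)$,
$\sigma = 5$ by default.

# Numerical and design notes

* Internal coordinates are 1-based inclusive everywhere; the single
  0-based half-open conversion lives in the BED writer/reader.
* The ancestral allele is always an explicit input (the `AA` tag or a
  site table), never inferred; sites without a usable ancestral state are
  dropped with a logged count. Missing alleles at retained sites (≤ 5%
  missing rate) are excluded from the site table's frequency denominators;
  the binary haplotype matrix represents them as ancestral, and the
  `missing_rate` column records where — on the fully phased synthetic data
  the two views coincide exactly.
* Seeded functions force their argument promises before calling
  `set.seed`, so an argument expression that itself draws random numbers
  cannot perturb the seeded stream.
* All stochastic stages take explicit seeds; identical configurations
  reproduce byte-identical run directories.
* Experiment scale: the recovery experiments use 20 replicates (10 for
  nulls, 200 for mixed-model calibration, 50 trajectories), panels of
  5,000 SNPs over 2 Mb with 54 + 74 + 50 diploids — the study's sample
  sizes at a single-region genome length, chosen so the whole suite runs
  comfortably on one CPU.
* Ties: candidate ranking breaks logLR ties to the lower position;
  Fisher percentile ranks count ties as "greater or equal"; equidistant
  lookup matches return the lower position. Each is deterministic.
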