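#' Default per-trait, per-condition, per-year generator targets
#'
#' One row per trait x condition x year combination that the field trials
#' actually record: pea grain yield in both pure stand (PS) and mixed stand
#' (MS); associated cereal yield in MS; morphophysiological traits in PS (and,
#' for flowering onset, height at flowering and seed weight, also in MS in the
#' second year); winter survival and ascochyta score in the first year only,
#' when winter cold and disease pressure allow line variation to express.
#'
#' Means are in trait units (t/ha, days from April 1, cm, g, proportion, 1-9
#' score); `cvg` and `cve` are genetic and plot-error coefficients of
#' variation in percent of the mean. Yield rows use the published trial
#' summaries; the remaining rows are realistic values for autumn-sown pea in
#' Northern Italy.
#'
#' @param years character vector of trial year labels (1 or 2 of the defaults).
#' @return data.frame with columns trait, condition, year, mean, cvg, cve.
#' @export
default_trait_targets <- function(years = c("2018-19", "2019-20")) {
  y1 <- "2018-19"; y2 <- "2019-20"
  rows <- rbind(
    data.frame(trait = "pea_yield", condition = "PS", year = y1, mean = 6.223, cvg = 24, cve = 27),
    data.frame(trait = "pea_yield", condition = "MS", year = y1, mean = 1.000, cvg = 33, cve = 44),
    data.frame(trait = "pea_yield", condition = "PS", year = y2, mean = 4.686, cvg = 17, cve = 18),
    data.frame(trait = "pea_yield", condition = "MS", year = y2, mean = 1.071, cvg = 46, cve = 51),
    data.frame(trait = "cereal_yield", condition = "MS", year = y1, mean = 5.494, cvg = 0, cve = 6),
    data.frame(trait = "cereal_yield", condition = "MS", year = y2, mean = 3.719, cvg = 0, cve = 6),
    data.frame(trait = "onset_flowering", condition = "PS", year = y1, mean = 12.7, cvg = 35, cve = 12),
    data.frame(trait = "onset_flowering", condition = "PS", year = y2, mean = 27.0, cvg = 6, cve = 3),
    data.frame(trait = "onset_flowering", condition = "MS", year = y2, mean = 27.8, cvg = 6, cve = 3),
    data.frame(trait = "height_flowering", condition = "PS", year = y1, mean = 62.0, cvg = 22, cve = 10),
    data.frame(trait = "height_flowering", condition = "PS", year = y2, mean = 46.1, cvg = 12, cve = 7),
    data.frame(trait = "height_flowering", condition = "MS", year = y2, mean = 50.1, cvg = 12, cve = 7),
    data.frame(trait = "seed_weight", condition = "PS", year = y1, mean = 0.146, cvg = 14, cve = 7),
    data.frame(trait = "seed_weight", condition = "PS", year = y2, mean = 0.198, cvg = 13, cve = 7),
    data.frame(trait = "seed_weight", condition = "MS", year = y2, mean = 0.194, cvg = 13, cve = 7),
    data.frame(trait = "maturity", condition = "PS", year = y1, mean = 64.5, cvg = 2.5, cve = 1.5),
    data.frame(trait = "maturity", condition = "PS", year = y2, mean = 61.9, cvg = 1.8, cve = 1.2),
    data.frame(trait = "height_maturity", condition = "PS", year = y1, mean = 120.4, cvg = 14, cve = 8),
    data.frame(trait = "height_maturity", condition = "PS", year = y2, mean = 54.8, cvg = 16, cve = 9),
    data.frame(trait = "winter_survival", condition = "PS", year = y1, mean = 0.978, cvg = 2.5, cve = 1.5),
    data.frame(trait = "ascochyta", condition = "PS", year = y1, mean = 4.1, cvg = 12, cve = 9)
  )
  rows[rows$year %in% years, , drop = FALSE]
}

#' Default target correlation matrix of genetic values
#'
#' Targets for the line-level correlations among true genetic values. Pea MS
#' and PS yield are distinct (correlated) genetic entities; the
#' morphophysiological traits each carry a single genetic value expressed in
#' both conditions. Yield-trait correlations follow the published genotype
#' correlation pattern (later flowering onset and taller plants at flowering
#' favour MS but not PS yield; ascochyta susceptibility depresses PS yield);
#' correlations among morphophysiological traits are plausible values kept
#' below the collinearity range.
#'
#' @param genetic_corr_ms_ps target genetic correlation between pea yield in
#'   MS and in PS (default 0.42).
#' @return symmetric 9 x 9 correlation matrix (projected to PSD).
#' @export
default_trait_corr <- function(genetic_corr_ms_ps = 0.42) {
  tr <- c("yield_MS", "yield_PS", "onset_flowering", "height_flowering",
          "seed_weight", "maturity", "height_maturity", "winter_survival",
          "ascochyta")
  m <- diag(9)
  dimnames(m) <- list(tr, tr)
  set_r <- function(a, b, r) {
    m[a, b] <<- r; m[b, a] <<- r
  }
  ## yield correlations are genetic-value targets: the published pattern is
  ## phenotypic (line means), so targets are scaled up by ~1/0.8 for the
  ## heritability attenuation of line means
  set_r("yield_MS", "yield_PS", genetic_corr_ms_ps)
  set_r("yield_MS", "onset_flowering", 0.60)
  set_r("yield_MS", "height_flowering", 0.70)
  set_r("yield_MS", "seed_weight", -0.10)
  set_r("yield_MS", "maturity", 0.08)
  set_r("yield_MS", "height_maturity", 0.50)
  set_r("yield_MS", "winter_survival", 0.16)
  set_r("yield_MS", "ascochyta", -0.28)
  set_r("yield_PS", "onset_flowering", -0.10)
  set_r("yield_PS", "height_flowering", 0.28)
  set_r("yield_PS", "seed_weight", 0.30)
  set_r("yield_PS", "maturity", 0.12)
  set_r("yield_PS", "height_maturity", 0.39)
  set_r("yield_PS", "winter_survival", 0.34)
  set_r("yield_PS", "ascochyta", -0.71)
  set_r("onset_flowering", "height_flowering", 0.50)
  set_r("onset_flowering", "maturity", 0.30)
  set_r("onset_flowering", "height_maturity", 0.25)
  set_r("height_flowering", "height_maturity", 0.60)
  set_r("maturity", "height_maturity", 0.20)
  set_r("ascochyta", "winter_survival", -0.15)
  nearest_psd(m)
}

#' Simulation configuration for the RIL intercropping trial generator
#'
#' Bundles all knobs of the synthetic-data generator: population structure
#' (six biparental RIL populations of 23 lines plus the six parents), genome
#' (7 chromosomes, ~1,000 biallelic markers by default), GBS-like genotyping
#' noise, the trait architecture (QTL + kinship-structured polygenic values
#' mixed to a target correlation matrix) and the split-plot trial layout
#' (years x PS/MS x 3 blocks).
#'
#' @param n_populations number of RIL populations.
#' @param lines_per_population RIL lines sampled per population.
#' @param n_parents number of parent cultivars.
#' @param cross_design list of length-2 integer vectors indexing the parents
#'   crossed for each population.
#' @param parent_names parent cultivar names.
#' @param n_chromosomes,n_markers genome dimensions.
#' @param map_length_per_chromosome genetic length per chromosome in Morgans.
#' @param marker_missing_rate,genotype_missing_rate mean missing-call rates
#'   applied per marker and per genotype (line).
#' @param residual_het_rate rate of residual heterozygous calls on inbreds.
#' @param min_polymorphic_fraction minimum fraction of loci polymorphic among
#'   parents that `simulate_founder_genomes()` must achieve in expectation.
#' @param trait_targets data.frame as [default_trait_targets()].
#' @param trait_corr_matrix target genetic correlation matrix as
#'   [default_trait_corr()].
#' @param genetic_corr_ms_ps target MS/PS genetic correlation for pea yield.
#' @param variance_ratios named list with `gy` and `gcy`: genotype-by-year and
#'   genotype-by-condition-by-year variances as fractions of the genotypic
#'   variance, for pea yield. The genotype-by-condition component is emergent
#'   (it follows from `genetic_corr_ms_ps` and the per-condition scales).
#' @param variance_ratios_morpho same, for the morphophysiological traits
#'   (small: those traits are far more year-consistent than yield).
#' @param n_qtl_per_trait QTL per trait; remaining genetic variance is
#'   polygenic.
#' @param qtl_frac,kin_frac fractions of genetic variance from explicit QTL
#'   and from the kinship-structured polygenic term (remainder is iid line
#'   noise, untraceable from markers).
#' @param competition_strength linear dependence of cereal plot yield (as a
#'   fraction of its mean) on the pea MS-yield genetic value (standardized).
#' @param block_cv coefficient of variation (%) of block effects.
#' @param years trial year labels.
#' @param n_blocks replicates per condition.
#' @param seed integer seed consumed by [generate_scenario()].
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_populations = 6,
                       lines_per_population = 23,
                       n_parents = 6,
                       cross_design = list(c(1, 2), c(3, 1), c(3, 2),
                                           c(4, 1), c(1, 5), c(6, 2)),
                       parent_names = c("Attika", "Isard", "Kaspa", "Dove",
                                        "Guifilo", "Alliance"),
                       n_chromosomes = 7,
                       n_markers = 1000,
                       map_length_per_chromosome = 1.0,
                       marker_missing_rate = 0.05,
                       genotype_missing_rate = 0.02,
                       residual_het_rate = 0.005,
                       min_polymorphic_fraction = 0.7,
                       trait_targets = NULL,
                       trait_corr_matrix = NULL,
                       genetic_corr_ms_ps = 0.42,
                       variance_ratios = list(gy = 0.2, gcy = 0.2),
                       variance_ratios_morpho = list(gy = 0.05, gcy = 0.03),
                       n_qtl_per_trait = 30,
                       qtl_frac = 0.35,
                       kin_frac = 0.65,
                       competition_strength = 0.03,
                       block_cv = 4,
                       years = c("2018-19", "2019-20"),
                       n_blocks = 3,
                       seed = 1L) {
  cfg <- list(
    n_populations = n_populations,
    lines_per_population = lines_per_population,
    n_parents = n_parents,
    cross_design = cross_design,
    parent_names = parent_names,
    n_chromosomes = n_chromosomes,
    n_markers = n_markers,
    map_length_per_chromosome = map_length_per_chromosome,
    marker_missing_rate = marker_missing_rate,
    genotype_missing_rate = genotype_missing_rate,
    residual_het_rate = residual_het_rate,
    min_polymorphic_fraction = min_polymorphic_fraction,
    trait_targets = trait_targets %||% default_trait_targets(years),
    trait_corr_matrix = trait_corr_matrix %||% default_trait_corr(genetic_corr_ms_ps),
    genetic_corr_ms_ps = genetic_corr_ms_ps,
    variance_ratios = variance_ratios,
    variance_ratios_morpho = variance_ratios_morpho,
    n_qtl_per_trait = n_qtl_per_trait,
    qtl_frac = qtl_frac,
    kin_frac = kin_frac,
    competition_strength = competition_strength,
    block_cv = block_cv,
    years = years,
    n_blocks = n_blocks,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_populations, cfg$lines_per_population, cfg$n_parents,
              cfg$n_chromosomes, cfg$n_markers, cfg$n_blocks)
  stop_if(any(counts <= 0) || any(counts != round(counts)),
          "counts in sim_config must be positive integers")
  rates <- c(cfg$marker_missing_rate, cfg$genotype_missing_rate,
             cfg$residual_het_rate, cfg$min_polymorphic_fraction)
  stop_if(any(rates < 0 | rates > 1), "rates in sim_config must lie in [0, 1]")
  stop_if(abs(cfg$genetic_corr_ms_ps) > 1,
          "genetic_corr_ms_ps must lie in [-1, 1]")
  stop_if(length(cfg$cross_design) != cfg$n_populations,
          "cross_design must list one parent pair per population")
  stop_if(any(vapply(cfg$cross_design, function(p)
    length(p) != 2 || any(p < 1) || any(p > cfg$n_parents), logical(1))),
    "cross_design entries must be pairs of parent indices")
  m <- cfg$trait_corr_matrix
  stop_if(!isSymmetric(unname(m), tol = 1e-8) || any(abs(diag(m) - 1) > 1e-8),
          "trait_corr_matrix must be symmetric with unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  stop_if(min(ev) < -1e-6,
          "trait_corr_matrix is not PSD after projection; smallest eigenvalue ",
          format(min(ev)))
  fr <- c(cfg$qtl_frac, cfg$kin_frac)
  stop_if(any(fr < 0) || sum(fr) > 1,
          "qtl_frac and kin_frac must be nonnegative with sum <= 1")
  stop_if(length(cfg$years) < 1, "at least one trial year required")
  invisible(cfg)
}
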