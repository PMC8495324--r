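## Map a trait_targets row to the base genetic entity it expresses.
## Pea yield has distinct (correlated) genetic values in MS and PS; the
## morphophysiological traits carry one genetic value across conditions;
## cereal yield has no pea genetic value of its own (competition handles it).
base_trait_of <- function(trait, condition) {
  ifelse(trait == "pea_yield", paste0("yield_", condition),
         ifelse(trait == "cereal_yield", NA_character_, trait))
}

#' Simulate true genetic values for all traits, conditions and years
#'
#' Per base trait, a standardized genetic score is composed of an explicit QTL
#' part (random markers with normal effects), a kinship-structured polygenic
#' part (multivariate normal with covariance proportional to the Astle-Balding
#' kinship of the clean genotypes) and a small iid remainder, in proportions
#' `qtl_frac` / `kin_frac` / rest. Scores are mixed across traits by the
#' Cholesky factor of the target correlation matrix, re-standardized, expanded
#' with genotype-by-year (and, for yield, genotype-by-condition-by-year)
#' deviations, and finally scaled to each trait x condition x year CVg target
#' around its mean.
#'
#' @param geno clean lines x markers dosage matrix in {0,2} (parents + RILs).
#' @param config a [sim_config()].
#' @param line_info data.frame with columns line, population, is_parent in
#'   the row order of `geno`.
#' @return object of class `true_architecture`: list with the standardized
#'   base values, effective marker-effect matrix and polygenic residuals
#'   (base values reconstruct exactly as centered-genotypes x effects +
#'   residuals), the per trait/condition/year genetic values (`gvalues`),
#'   and realized correlations and variances.
#' @export
simulate_genetic_values <- function(geno, config, line_info) {
  cm <- config$trait_corr_matrix
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  stop_if(min(ev) < -1e-6,
          "target trait correlation matrix is not PSD (min eigenvalue ",
          format(min(ev)), "); project with nearest_psd() first")
  base_traits <- rownames(cm)
  n <- nrow(geno); m <- ncol(geno); k <- length(base_traits)
  stop_if(nrow(line_info) != n, "line_info must match genotype rows")

  qtl_frac <- config$qtl_frac
  kin_frac <- config$kin_frac
  if (config$n_qtl_per_trait == 0) { # purely polygenic architecture
    kin_frac <- kin_frac + qtl_frac
    qtl_frac <- 0
  }
  iid_frac <- max(0, 1 - qtl_frac - kin_frac)

  centers <- colMeans(geno)
  geno_c <- sweep(geno, 2, centers, "-")

  ## explicit QTL component
  E <- matrix(0, m, k, dimnames = list(colnames(geno), base_traits))
  if (qtl_frac > 0) {
    for (t in seq_len(k)) {
      qtl <- sample.int(m, min(config$n_qtl_per_trait, m))
      E[qtl, t] <- stats::rnorm(length(qtl))
    }
  }
  Q0 <- geno_c %*% E
  sdq <- apply(Q0, 2, stats::sd)
  sdq[sdq == 0] <- 1

  ## kinship-structured polygenic component
  P <- matrix(0, n, k)
  if (kin_frac > 0) {
    K <- kinship_astle_balding(geno)
    Lk <- chol(K + diag(1e-6, n))
    P <- crossprod(Lk, matrix(stats::rnorm(n * k), n, k))
  }
  I0 <- matrix(stats::rnorm(n * k), n, k)

  ## assemble with the target variance shares, then standardize
  U <- sweep(scale_cols(Q0), 2, rep(sqrt(qtl_frac), k), "*") +
       sweep(scale_cols(P), 2, rep(sqrt(kin_frac), k), "*") +
       sweep(scale_cols(I0), 2, rep(sqrt(iid_frac), k), "*")
  sd_u <- apply(U, 2, stats::sd); sd_u[sd_u == 0] <- 1
  Us <- sweep(sweep(U, 2, colMeans(U), "-"), 2, sd_u, "/")

  ## per-trait variance shares of the stable genetic part vs year deviations:
  ## yield carries the full G-by-Y / G-by-C-by-Y load; morphophysiological
  ## traits are far more year-consistent (their across-year genetic
  ## correlation stays near 0.93)
  is_yield <- grepl("^yield_", base_traits)
  gy_y <- config$variance_ratios$gy %||% 0
  gcy_y <- config$variance_ratios$gcy %||% 0
  gy_m <- config$variance_ratios_morpho$gy %||% 0.05
  gcy_m <- config$variance_ratios_morpho$gcy %||% 0.03
  gy_t <- ifelse(is_yield, gy_y, gy_m)
  gcy_t <- ifelse(is_yield, gcy_y, gcy_m)
  s_t <- 1 / (1 + gy_t + gcy_t)       # stable-share per trait
  tgy_t <- gy_t * s_t
  tgcy_t <- gcy_t * s_t
  names(s_t) <- names(tgy_t) <- names(tgcy_t) <- base_traits

  ## Year deviations are colored with the same mixing matrix as the stable
  ## base. The G-by-Y matrix is shared by all traits within a year; the
  ## G-by-C-by-Y matrix is drawn per year x condition, with morphophysiological
  ## traits always reading the PS matrix (their cross-condition consistency
  ## is ~1), while the two yield entities read their own condition.
  ## Within-year correlation of traits t, t2 is then
  ##   rho_mix * (sqrt(s_t s_t2) + sqrt(tgy_t tgy_t2) + share * sqrt(tgcy...))
  ## so the mixing target is the configured correlation divided by that
  ## alignment factor (clipped to [-1, 1], then PSD-projected).
  wy_share <- function(a, b) {
    if (a == b) return(1)
    both_yield <- is_yield[match(a, base_traits)] &&
      is_yield[match(b, base_traits)]
    if (both_yield) return(0)                  # MS vs PS condition matrices
    if (a == "yield_MS" || b == "yield_MS") return(0) # MS vs PS-read morpho
    1
  }
  alignment <- diag(k)
  dimnames(alignment) <- dimnames(cm)
  for (a in base_traits) for (b in base_traits) {
    if (a == b) next
    alignment[a, b] <- sqrt(s_t[a] * s_t[b]) + sqrt(tgy_t[a] * tgy_t[b]) +
      wy_share(a, b) * sqrt(tgcy_t[a] * tgcy_t[b])
  }
  mix_m <- pmin(pmax(cm / alignment, -1), 1)
  diag(mix_m) <- 1
  mix_m <- nearest_psd(mix_m)

  ## exact correlation imposition for the stable base: orthonormalize the
  ## scores in-sample, then color with the Cholesky factor of mix_m
  Cu <- stats::cor(Us)
  A <- solve(chol(Cu + diag(1e-10, k))) %*% chol(mix_m + diag(1e-10, k))
  V <- Us %*% A
  sd_v <- apply(V, 2, stats::sd); sd_v[sd_v == 0] <- 1
  Vs <- sweep(sweep(V, 2, colMeans(V), "-"), 2, sd_v, "/")
  colnames(Vs) <- base_traits

  ## effective marker effects such that Vs = geno_c %*% Eeff + polygenic
  ## (column means removed by the standardizations fold into the residual)
  chain <- diag(sqrt(qtl_frac) / (sdq * sd_u), k) %*% A %*% diag(1 / sd_v, k)
  Eeff <- E %*% chain
  dimnames(Eeff) <- list(colnames(geno), base_traits)
  polygenic <- Vs - geno_c %*% Eeff

  years <- config$years
  tg <- config$trait_targets
  Lm <- chol(mix_m + diag(1e-10, k))
  Uy <- lapply(years, function(y) {
    M <- matrix(stats::rnorm(n * k), n, k) %*% Lm
    colnames(M) <- base_traits
    M
  })
  names(Uy) <- years
  Wy <- lapply(years, function(y) {
    ms <- matrix(stats::rnorm(n * k), n, k) %*% Lm
    ps <- matrix(stats::rnorm(n * k), n, k) %*% Lm
    colnames(ms) <- colnames(ps) <- base_traits
    list(MS = ms, PS = ps)
  })
  names(Wy) <- years

  rows <- list()
  for (i in seq_len(nrow(tg))) {
    tr <- tg$trait[i]; cond <- tg$condition[i]; yr <- tg$year[i]
    bt <- base_trait_of(tr, cond)
    if (is.na(bt)) next # cereal yield: competition-driven, no pea genetics
    wy_cond <- if (is_yield[match(bt, base_traits)]) cond else "PS"
    g_std <- sqrt(s_t[bt]) * Vs[, bt] +
      sqrt(tgy_t[bt]) * Uy[[yr]][, bt] +
      sqrt(tgcy_t[bt]) * Wy[[yr]][[wy_cond]][, bt]
    g_abs <- tg$mean[i] * (1 + tg$cvg[i] / 100 * g_std)
    rows[[length(rows) + 1]] <- data.frame(
      line = line_info$line, population = line_info$population,
      is_parent = line_info$is_parent,
      trait = tr, condition = cond, year = yr,
      g_std = g_std, g_abs = g_abs
    )
  }
  gvalues <- do.call(rbind, rows)

  realized_corr <- stats::cor(Vs)
  ## realized within-year MS/PS genetic correlation for pea yield
  rw <- vapply(years, function(yr) {
    a <- gvalues[gvalues$trait == "pea_yield" & gvalues$condition == "MS" &
                   gvalues$year == yr, "g_std"]
    b <- gvalues[gvalues$trait == "pea_yield" & gvalues$condition == "PS" &
                   gvalues$year == yr, "g_std"]
    if (length(a) == 0 || length(b) == 0) NA_real_ else stats::cor(a, b)
  }, numeric(1))
  arch <- list(
    line_info = line_info,
    base_values = Vs,
    marker_effects = Eeff,
    marker_centers = centers,
    polygenic = polygenic,
    gvalues = gvalues,
    realized_corr = realized_corr,
    realized_corr_ms_ps = mean(rw, na.rm = TRUE),
    realized_var = stats::aggregate(
      g_abs ~ trait + condition + year, data = gvalues,
      FUN = function(v) stats::var(v))
  )
  class(arch) <- "true_architecture"
  arch
}

#' Simulate plot-level split-plot trial phenotypes
#'
#' Builds the full plot table (years x conditions x blocks x lines) from the
#' true genetic values: observed value = genetic value + block effect +
#' residual, with block effects and residuals scaled to `block_cv` and the
#' per-trait CVe targets. Cereal plot yield in MS depends negatively on the
#' pea line's standardized MS-yield genetic value (`competition_strength`).
#' Yields are truncated at zero, winter survival at [0, 1] and the ascochyta
#' score at [1, 9].
#'
#' @param architecture a `true_architecture`.
#' @param config the [sim_config()] used to build it.
#' @return plot-level data.frame (one row per plot; trait columns are NA when
#'   a trait was not recorded in that condition/year).
#' @export
simulate_trial_phenotypes <- function(architecture, config) {
  tg <- config$trait_targets
  li <- architecture$line_info
  gv <- architecture$gvalues
  missing_tr <- setdiff(unique(tg$trait[tg$trait != "cereal_yield"]),
                        unique(gv$trait))
  stop_if(length(missing_tr) > 0,
          "architecture lacks traits: ", paste(missing_tr, collapse = ", "))
  n <- nrow(li); b <- config$n_blocks
  traits <- unique(tg$trait)

  grid <- unique(tg[, c("condition", "year")])
  plots <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(year = grid$year[i], condition = grid$condition[i],
               block = rep(seq_len(b), each = n),
               population = rep(li$population, b),
               line = rep(li$line, b),
               is_parent = rep(li$is_parent, b))
  }))
  for (tr in traits) plots[[tr]] <- NA_real_

  for (i in seq_len(nrow(tg))) {
    tr <- tg$trait[i]; cond <- tg$condition[i]; yr <- tg$year[i]
    mu <- tg$mean[i]; cve <- tg$cve[i]
    sel <- plots$condition == cond & plots$year == yr
    idx <- match(plots$line[sel], li$line)
    if (tr == "cereal_yield") {
      gms <- gv[gv$trait == "pea_yield" & gv$condition == "MS" &
                  gv$year == yr, ]
      gstd <- gms$g_std[match(plots$line[sel], gms$line)]
      base <- mu * (1 - config$competition_strength * gstd)
    } else {
      gtr <- gv[gv$trait == tr & gv$condition == cond & gv$year == yr, ]
      base <- gtr$g_abs[match(plots$line[sel], gtr$line)]
    }
    blk_sd <- config$block_cv / 100 * mu
    blk <- stats::rnorm(b, 0, blk_sd)[plots$block[sel]]
    res <- stats::rnorm(sum(sel), 0, cve / 100 * mu)
    val <- base + blk + res
    if (tr %in% c("pea_yield", "cereal_yield")) val <- pmax(val, 0)
    if (tr == "winter_survival") val <- pmin(pmax(val, 0), 1)
    if (tr == "ascochyta") val <- pmin(pmax(val, 1), 9)
    plots[[tr]][sel] <- val
  }
  rownames(plots) <- NULL
  plots
}

#' Generate a complete synthetic scenario
#'
#' One seeded call produces the whole fixture: parent genomes, six RIL
#' populations, true trait architecture, plot-level trial table and the noisy
#' genotype matrix, emulating the study design (6 populations x 23 lines + 6
#' parents, two years x PS/MS x 3 blocks).
#'
#' @param config a [sim_config()].
#' @return object of class `pea_scenario`: list with `trial` (plot table),
#'   `geno` ([genotype_matrix()] with GBS-like noise), `geno_true` (clean
#'   dosages), `architecture`, `line_info` and `config`.
#' @export
generate_scenario <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  founders <- simulate_founder_genomes(config)
  pops <- sprintf("P%d", seq_len(config$n_populations))
  ril <- vector("list", config$n_populations)
  for (i in seq_len(config$n_populations)) {
    pr <- config$cross_design[[i]]
    g <- simulate_ril_population(founders$geno[pr[1], ], founders$geno[pr[2], ],
                                 config$lines_per_population, founders$map)
    rownames(g) <- sprintf("%s_L%02d", pops[i],
                           seq_len(config$lines_per_population))
    ril[[i]] <- g
  }
  geno_true <- rbind(do.call(rbind, ril), founders$geno)
  line_info <- data.frame(
    line = rownames(geno_true),
    population = c(rep(pops, each = config$lines_per_population),
                   rep("parent", config$n_parents)),
    is_parent = c(rep(FALSE, config$n_populations * config$lines_per_population),
                  rep(TRUE, config$n_parents))
  )
  architecture <- simulate_genetic_values(geno_true, config, line_info)
  trial <- simulate_trial_phenotypes(architecture, config)
  noisy <- apply_genotyping_noise(geno_true, config)
  geno <- genotype_matrix(noisy, founders$map)
  structure(list(trial = trial, geno = geno, geno_true = geno_true,
                 architecture = architecture, line_info = line_info,
                 config = config),
            class = "pea_scenario")
}
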