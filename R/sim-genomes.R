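#' Build a marker map for the simulated genome
#'
#' Markers are spread over chromosomes in near-equal numbers at uniform random
#' positions, sorted within chromosome. Positions are stored in Morgans
#' (`pos_m`) and centiMorgans (`pos`).
#'
#' @param config a [sim_config()].
#' @return data.frame with columns marker, chrom, pos (cM), pos_m (Morgans).
#' @export
simulate_marker_map <- function(config) {
  n_chr <- config$n_chromosomes
  per_chr <- diff(round(seq(0, config$n_markers, length.out = n_chr + 1)))
  map <- do.call(rbind, lapply(seq_len(n_chr), function(ch) {
    pos <- sort(stats::runif(per_chr[ch], 0, config$map_length_per_chromosome))
    data.frame(chrom = ch, pos_m = pos)
  }))
  map$marker <- sprintf("m%04d", seq_len(nrow(map)))
  map$pos <- map$pos_m * 100
  map[, c("marker", "chrom", "pos", "pos_m")]
}

#' Simulate fully homozygous founder (parent) genomes
#'
#' Each locus draws a parental allele frequency away from fixation, then each
#' parent an allele, giving {0, 2} dosages. With the default frequency window
#' the expected fraction of loci polymorphic among parents comfortably exceeds
#' `min_polymorphic_fraction`.
#'
#' @param config a [sim_config()].
#' @return list with `geno` (n_parents x n_markers matrix of 0/2 dosages,
#'   rownames = parent names) and `map` (marker map).
#' @export
simulate_founder_genomes <- function(config) {
  stop_if(config$n_markers <= 0 || config$n_parents <= 0,
          "need at least one marker and one parent")
  map <- simulate_marker_map(config)
  m <- nrow(map)
  p <- stats::runif(m, 0.2, 0.8)
  geno <- matrix(
    2L * (stats::runif(config$n_parents * m) < rep(p, each = config$n_parents)),
    nrow = config$n_parents, ncol = m,
    dimnames = list(config$parent_names[seq_len(config$n_parents)], map$marker)
  )
  list(geno = geno, map = map)
}

## Expected recombination fraction between adjacent markers for RILs derived
## by repeated selfing: R = 2r / (1 + 2r), with r from the Haldane map
## function r = (1 - exp(-2d)) / 2 at map distance d Morgans.
ril_recomb_fraction <- function(d_morgans) {
  r <- (1 - exp(-2 * d_morgans)) / 2
  2 * r / (1 + 2 * r)
}

#' Simulate a recombinant inbred line population from two homozygous parents
#'
#' RIL meiosis is collapsed to a single mosaic draw per line: along each
#' chromosome the parental origin switches between adjacent markers with the
#' expected selfing-RIL recombination fraction R = 2r/(1+2r) (Haldane r).
#' Lines are fully homozygous.
#'
#' @param parent1,parent2 dosage vectors in {0,2} over the same markers.
#' @param n_lines number of RILs to produce.
#' @param map marker map as from [simulate_marker_map()].
#' @return n_lines x n_markers matrix of 0/2 dosages.
#' @export
simulate_ril_population <- function(parent1, parent2, n_lines, map) {
  stop_if(any(parent1 == 1) || any(parent2 == 1),
          "parents must be fully homozygous (no dosage 1)")
  stop_if(length(parent1) != nrow(map) || length(parent2) != nrow(map),
          "parent genotype length must match marker map")
  m <- nrow(map)
  ## switch probabilities between consecutive markers (0 across chromosomes
  ## handled by forcing an independent restart)
  d <- c(0, diff(map$pos_m))
  new_chr <- c(TRUE, diff(map$chrom) != 0)
  pswitch <- ril_recomb_fraction(pmax(d, 0))
  pswitch[new_chr] <- 0.5 # independent origin draw at each chromosome start
  ## cumulative xor of switch indicators gives parental origin per marker
  sw <- matrix(stats::runif(n_lines * m) < rep(pswitch, each = n_lines),
               nrow = n_lines)
  origin <- (t(apply(sw, 1, cumsum)) %% 2) == 1
  geno <- matrix(rep(parent1, each = n_lines), nrow = n_lines)
  p2 <- matrix(rep(parent2, each = n_lines), nrow = n_lines)
  geno[origin] <- p2[origin]
  colnames(geno) <- map$marker
  storage.mode(geno) <- "integer"
  geno
}

#' Apply GBS-like genotyping noise to a clean dosage matrix
#'
#' Missing calls arise through two channels with Beta-distributed per-marker
#' and per-genotype rates whose means equal the configured rates, emulating
#' the uneven coverage of genotyping-by-sequencing; residual heterozygous
#' calls (dosage 1) are introduced at `residual_het_rate`.
#'
#' @param geno lines x markers dosage matrix in {0,1,2}.
#' @param config a [sim_config()].
#' @return matrix of the same shape with NAs and residual het calls.
#' @export
apply_genotyping_noise <- function(geno, config) {
  rates <- c(config$marker_missing_rate, config$genotype_missing_rate,
             config$residual_het_rate)
  stop_if(any(rates < 0 | rates > 1), "noise rates must lie in [0, 1]")
  out <- geno
  n <- nrow(out); m <- ncol(out)
  beta_rate <- function(k, mean, conc) {
    if (mean <= 0) return(rep(0, k))
    if (mean >= 1) return(rep(1, k))
    stats::rbeta(k, mean * conc, (1 - mean) * conc)
  }
  if (config$residual_het_rate > 0) {
    het <- matrix(stats::runif(n * m) < config$residual_het_rate, n, m)
    out[het] <- 1L
  }
  pm <- beta_rate(m, config$marker_missing_rate, 8)
  pg <- beta_rate(n, config$genotype_missing_rate, 20)
  miss <- matrix(stats::runif(n * m), n, m) <
    outer(pg, pm, function(a, b) 1 - (1 - a) * (1 - b))
  out[miss] <- NA
  out
}
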