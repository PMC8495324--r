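#' Single-marker association scan with population covariates
#'
#' Per marker, the linear model y ~ population + dosage is fitted to line
#' values (typically averaged across years); the two-sided p of the marker
#' coefficient is reported. The scan residualizes the phenotype and every
#' marker on the covariate space once, so the whole genome is one matrix
#' operation. Monomorphic markers are skipped (NA, flagged).
#'
#' @param gm complete [genotype_matrix()] (or dosage matrix).
#' @param phenotype named per-line values aligned with the genotype rows.
#' @param populations factor/character of population membership per line
#'   (the incidence-matrix covariate); NULL for no covariate.
#' @return data.frame marker, chrom, pos, beta, p_raw (attribute
#'   `n_skipped`).
#' @export
marker_scan <- function(gm, phenotype, populations = NULL) {
  map <- NULL
  if (inherits(gm, "genotype_matrix")) {
    map <- gm$map
    gm <- gm$geno
  }
  stop_if(anyNA(gm), "marker scan needs a complete (imputed) matrix")
  stop_if(nrow(gm) != length(phenotype),
          "phenotype and genotypes are not aligned")
  if (!is.null(names(phenotype)) && !is.null(rownames(gm))) {
    stop_if(!all(rownames(gm) %in% names(phenotype)),
            "phenotype missing for some genotyped lines")
    phenotype <- phenotype[rownames(gm)]
  }
  n <- nrow(gm)
  if (is.null(populations)) {
    Z <- matrix(1, n, 1)
  } else {
    Z <- stats::model.matrix(~ factor(populations))
  }
  qrz <- qr(Z)
  stop_if(qrz$rank < ncol(Z), "covariate matrix is rank deficient")
  ry <- stats::residuals(stats::lm.fit(Z, phenotype))
  RM <- gm - Z %*% qr.coef(qrz, gm)
  ss_m <- colSums(RM^2)
  poly <- ss_m > 1e-12
  df <- n - ncol(Z) - 1
  stop_if(df <= 0, "not enough lines for the covariate-adjusted scan")
  beta <- rep(NA_real_, ncol(gm))
  p <- rep(NA_real_, ncol(gm))
  beta[poly] <- colSums(RM[, poly, drop = FALSE] * ry) / ss_m[poly]
  rss <- sum(ry^2) - beta[poly]^2 * ss_m[poly]
  rss <- pmax(rss, 0)
  tval <- beta[poly] * sqrt(ss_m[poly]) / sqrt(pmax(rss / df, 1e-300))
  p[poly] <- pmax(2 * stats::pt(-abs(tval), df), 1e-300)
  out <- data.frame(marker = colnames(gm), beta = beta, p_raw = p,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    out$chrom <- map$chrom[match(out$marker, map$marker)]
    out$pos <- map$pos[match(out$marker, map$marker)]
    out <- out[, c("marker", "chrom", "pos", "beta", "p_raw")]
  }
  attr(out, "n_skipped") <- sum(!poly)
  out
}

#' Genomic-control adjustment of scan p values
#'
#' lambda_GC = median of the 1-df chi-square statistics divided by 0.4549
#' (the chi-square(1) median). When lambda > 1 every statistic is deflated by
#' lambda before re-computing p; lambda <= 1 leaves p unchanged (never used
#' to inflate significance).
#'
#' @param p_raw raw p values.
#' @return list with `p_adj` and `lambda`.
#' @export
genomic_control <- function(p_raw) {
  ok <- !is.na(p_raw)
  if (sum(ok) < 10) warning("fewer than 10 markers; lambda_GC is unreliable")
  chi <- stats::qchisq(p_raw[ok], df = 1, lower.tail = FALSE)
  lambda <- stats::median(chi) / stats::qchisq(0.5, df = 1)
  p_adj <- p_raw
  if (lambda > 1) {
    p_adj[ok] <- stats::pchisq(chi / lambda, df = 1, lower.tail = FALSE)
  }
  list(p_adj = p_adj, lambda = lambda)
}

#' Bonferroni multiple-testing threshold
#'
#' @param m number of markers tested.
#' @param alpha family-wise level (default 0.05).
#' @return list with `p_threshold` = alpha/m and `score_threshold` =
#'   -log10(alpha/m).
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  stop_if(m <= 0, "m must be positive")
  stop_if(alpha <= 0 || alpha > 1, "alpha must lie in (0, 1]")
  list(p_threshold = alpha / m, score_threshold = -log10(alpha / m))
}

#' Full GWAS: scan, genomic control, thresholds, association scores
#'
#' @inheritParams marker_scan
#' @param alpha Bonferroni family-wise level.
#' @return object of class `gwas_result`: per-marker table (p_raw, p_gc,
#'   score = -log10 adjusted p), lambda_GC, thresholds, m.
#' @export
gwas_scan <- function(gm, phenotype, populations = NULL, alpha = 0.05) {
  scan <- marker_scan(gm, phenotype, populations)
  gc_ <- genomic_control(scan$p_raw)
  scan$p_gc <- gc_$p_adj
  scan$score <- -log10(scan$p_gc)
  m <- sum(!is.na(scan$p_raw))
  th <- bonferroni_threshold(m, alpha)
  structure(list(table = scan, lambda_gc = gc_$lambda,
                 p_threshold = th$p_threshold,
                 score_threshold = th$score_threshold, m = m, alpha = alpha),
            class = "gwas_result")
}

#' Plot-ready Manhattan table
#'
#' Markers sorted by (chromosome, position) with a strictly increasing
#' cumulative coordinate; unplaced markers (chromosome 99) are appended last.
#'
#' @param result a `gwas_result` (or its per-marker table with chrom/pos).
#' @return the table with `cum_pos` added, sorted for plotting.
#' @export
manhattan_table <- function(result) {
  tab <- if (inherits(result, "gwas_result")) result$table else result
  stop_if(!all(c("chrom", "pos") %in% names(tab)),
          "marker table lacks chrom/pos")
  unplaced <- tab$chrom == 99
  tab <- tab[order(unplaced, tab$chrom, tab$pos), ]
  offset <- 0
  tab$cum_pos <- NA_real_
  for (ch in unique(tab$chrom)) {
    i <- tab$chrom == ch
    pos <- tab$pos[i]
    pos <- pos + cumsum(c(0, as.numeric(diff(pos) == 0))) * 1e-9 # break ties
    tab$cum_pos[i] <- offset + pos - min(pos) + 1
    offset <- max(tab$cum_pos[i]) + 1
  }
  rownames(tab) <- NULL
  tab
}
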