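#' Genotype matrix container (012 dosages with a marker map)
#'
#' Lines x markers biallelic dosages in {0, 1, 2, NA} plus a marker map
#' (marker, chromosome, position). Chromosome 99 is the convention for
#' unplaced markers.
#'
#' @param geno numeric/integer matrix, rownames = line ids, colnames = marker
#'   ids, values in {0,1,2,NA}.
#' @param map data.frame with columns marker, chrom, pos; defaults to all
#'   markers unplaced on chromosome 99.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map = NULL) {
  stop_if(is.null(rownames(geno)) || is.null(colnames(geno)),
          "geno needs line ids as rownames and marker ids as colnames")
  vals <- geno[!is.na(geno)]
  stop_if(length(vals) > 0 && !all(vals %in% 0:2),
          "genotype values must be 0, 1, 2 or NA")
  if (is.null(map)) {
    map <- data.frame(marker = colnames(geno), chrom = 99,
                      pos = seq_len(ncol(geno)))
  }
  stop_if(!all(c("marker", "chrom", "pos") %in% names(map)),
          "map needs columns marker, chrom, pos")
  map <- map[match(colnames(geno), map$marker), c("marker", "chrom", "pos")]
  stop_if(anyNA(map$marker), "map does not cover all markers in geno")
  structure(list(geno = geno, map = map), class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers, %.1f%% missing\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

marker_missing_rate <- function(gm) colMeans(is.na(gm$geno))
genotype_missing_rate <- function(gm) rowMeans(is.na(gm$geno))

#' Write a genotype matrix as plain 012 text with a sidecar marker map
#'
#' Tab-separated: header row of marker ids, first column of line ids; missing
#' calls written as -1 (the common 012 dialect).
#'
#' @param gm a [genotype_matrix()].
#' @param path output path for the 012 matrix.
#' @param map_path optional path for the marker map TSV.
#' @export
write_geno_012 <- function(gm, path, map_path = NULL) {
  m <- gm$geno
  m[is.na(m)] <- -1
  df <- data.frame(line = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path)) {
    utils::write.table(gm$map, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read genotypes from 012 text or VCF
#'
#' VCF records are restricted to biallelic SNPs (indels and multi-allelic
#' sites are skipped, with counts attached as the `skipped` attribute);
#' genotype calls are mapped to the dosage of the alternate allele, `./.` to
#' missing. The 012 dialect round-trips [write_geno_012()] losslessly.
#'
#' @param path input file.
#' @param format `"012"` or `"vcf"`.
#' @param map_path optional marker-map TSV (marker, chrom, pos) for 012 input.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("012", "vcf"), map_path = NULL) {
  format <- match.arg(format)
  if (format == "012") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    geno <- as.matrix(df[, -1, drop = FALSE])
    rownames(geno) <- df[[1]]
    geno[geno == -1] <- NA
    bad <- geno[!is.na(geno)]
    stop_if(length(bad) > 0 && !all(bad %in% 0:2),
            "012 file ", path, " contains values outside {-1,0,1,2}")
    map <- NULL
    if (!is.null(map_path)) {
      map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    }
    return(genotype_matrix(geno, map))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic_snp <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!biallelic_snp)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic_snp, , drop = FALSE]
  gt_clean <- gsub("\\|", "/", gt)
  dosage <- matrix(NA_real_, nrow(gt_clean), ncol(gt_clean),
                   dimnames = dimnames(gt_clean))
  dosage[gt_clean == "0/0"] <- 0
  dosage[gt_clean %in% c("0/1", "1/0")] <- 1
  dosage[gt_clean == "1/1"] <- 2
  ids <- fix[biallelic_snp, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(
    fix[biallelic_snp, "CHROM"], "_", fix[biallelic_snp, "POS"]
  )[is.na(ids) | ids == "."]
  chrom <- suppressWarnings(as.numeric(gsub("\\D", "", fix[biallelic_snp, "CHROM"])))
  chrom[is.na(chrom)] <- 99
  map <- data.frame(marker = ids, chrom = chrom,
                    pos = as.numeric(fix[biallelic_snp, "POS"]))
  geno <- t(dosage)
  colnames(geno) <- ids
  out <- genotype_matrix(geno, map)
  attr(out, "skipped") <- skipped
  out
}

#' Marker/genotype filter thresholds
#'
#' @param maf_min markers with minor allele frequency at or below this are
#'   dropped (default 0.05, i.e. keep MAF > 5%).
#' @param max_missing_per_marker,max_missing_per_genotype missing-rate
#'   ceilings (defaults 0.05 and 0.50, the tuned configuration).
#' @param max_het_ratio markers whose heterozygous-call ratio exceeds this are
#'   dropped (default 0.95).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(maf_min = 0.05, max_missing_per_marker = 0.05,
                          max_missing_per_genotype = 0.50,
                          max_het_ratio = 0.95) {
  th <- c(maf_min, max_missing_per_marker, max_missing_per_genotype,
          max_het_ratio)
  stop_if(any(th < 0 | th > 1), "filter thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min,
                 max_missing_per_marker = max_missing_per_marker,
                 max_missing_per_genotype = max_missing_per_genotype,
                 max_het_ratio = max_het_ratio),
            class = "filter_config")
}

#' Filter markers and genotypes
#'
#' Applies, in order: (1) drop markers whose missing rate exceeds
#' `max_missing_per_marker`; (2) drop genotypes (lines) whose missing rate
#' exceeds `max_missing_per_genotype`; (3) drop markers whose heterozygosity
#' ratio (het calls / non-missing calls) exceeds `max_het_ratio`; (4) drop
#' markers with MAF <= `maf_min`, frequencies computed on the remaining data.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return filtered [genotype_matrix()] with a `report` attribute counting
#'   removals at each step.
#' @export
filter_markers_and_genotypes <- function(gm, cfg = filter_config()) {
  g <- gm$geno
  report <- list(n_lines_in = nrow(g), n_markers_in = ncol(g))

  keep_m <- colMeans(is.na(g)) <= cfg$max_missing_per_marker
  report$markers_dropped_missing <- sum(!keep_m)
  g <- g[, keep_m, drop = FALSE]

  keep_l <- rowMeans(is.na(g)) <= cfg$max_missing_per_genotype
  report$genotypes_dropped_missing <- sum(!keep_l)
  g <- g[keep_l, , drop = FALSE]

  het_ratio <- colSums(g == 1, na.rm = TRUE) / pmax(colSums(!is.na(g)), 1)
  keep_m2 <- het_ratio <= cfg$max_het_ratio & colSums(!is.na(g)) > 0
  report$markers_dropped_het <- sum(!keep_m2)
  g <- g[, keep_m2, drop = FALSE]

  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_m3 <- maf > cfg$maf_min
  report$markers_dropped_maf <- sum(!keep_m3)
  g <- g[, keep_m3, drop = FALSE]

  stop_if(nrow(g) == 0 || ncol(g) == 0,
          "filtering removed all lines or all markers")
  report$n_lines_out <- nrow(g)
  report$n_markers_out <- ncol(g)
  out <- genotype_matrix(g, gm$map[gm$map$marker %in% colnames(g), ])
  attr(out, "report") <- report
  out
}

#' k-nearest-neighbour imputation of missing dosages
#'
#' Line-to-line distance is the mean squared dosage difference over shared
#' non-missing markers. Each missing entry is replaced by the (optionally
#' inverse-distance weighted) mean of the k nearest lines observed at that
#' marker; observed entries are never altered. Neighbour ties are broken by
#' line order.
#'
#' @param gm a [genotype_matrix()].
#' @param k neighbours to use (clipped to n-1 with a warning).
#' @param weighted inverse-distance weighting of neighbours (default uniform).
#' @return complete [genotype_matrix()].
#' @export
knni_impute <- function(gm, k = 5, weighted = FALSE) {
  g <- gm$geno
  stop_if(any(colSums(!is.na(g)) == 0),
          "cannot impute: some markers have no observed calls")
  if (!anyNA(g)) return(gm)
  n <- nrow(g)
  if (k >= n) {
    warning("k clipped to n - 1 lines")
    k <- n - 1
  }
  A <- g; A[is.na(A)] <- 0
  W <- 1 - is.na(g) # observed indicator
  S <- A * A
  shared <- W %*% t(W)
  num <- S %*% t(W) + W %*% t(S) - 2 * A %*% t(A)
  D <- num / pmax(shared, 1)
  D[shared == 0] <- Inf
  diag(D) <- Inf

  out <- g
  for (i in seq_len(n)) {
    miss <- which(is.na(g[i, ]))
    if (length(miss) == 0) next
    ord <- order(D[i, ]) # ties broken by line order
    for (j in miss) {
      donors <- ord[!is.na(g[ord, j])]
      use <- donors[seq_len(min(k, length(donors)))]
      if (weighted) {
        w <- 1 / (D[i, use] + 1e-9)
        out[i, j] <- sum(w * g[use, j]) / sum(w)
      } else {
        out[i, j] <- mean(g[use, j])
      }
    }
  }
  ## imputed entries are neighbour means, possibly fractional in [0, 2], so
  ## bypass the {0,1,2} domain check of the constructor
  structure(list(geno = out, map = gm$map), class = "genotype_matrix")
}

#' Astle-Balding genomic kinship
#'
#' K = (1/m) * sum_j (x_j - 2 p_j)(x_j - 2 p_j)' / (2 p_j (1 - p_j)), with
#' p_j the sample allele frequency of marker j. Monomorphic markers are
#' skipped (count in the `n_monomorphic` attribute). For fully inbred lines
#' at p = 0.5 the diagonal is ~2.
#'
#' @param geno complete lines x markers dosage matrix (or
#'   [genotype_matrix()]).
#' @return symmetric n x n kinship matrix.
#' @export
kinship_astle_balding <- function(geno) {
  if (inherits(geno, "genotype_matrix")) geno <- geno$geno
  stop_if(anyNA(geno), "kinship requires a complete (imputed) matrix")
  p <- colMeans(geno) / 2
  poly <- p > 0 & p < 1
  stop_if(!any(poly), "all markers are monomorphic")
  Z <- sweep(geno[, poly, drop = FALSE], 2, 2 * p[poly], "-")
  Z <- sweep(Z, 2, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  K <- tcrossprod(Z) / sum(poly)
  K <- (K + t(K)) / 2
  attr(K, "n_monomorphic") <- sum(!poly)
  K
}
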