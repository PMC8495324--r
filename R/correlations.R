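new_correlation <- function(r, se, kind, n, clamped = FALSE) {
  structure(list(r = r, se = se, kind = kind, n = n, clamped = clamped),
            class = "correlation_estimate")
}

#' @exportS3Method base::print
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f (se %.3f, n = %d)%s\n", x$kind, x$r,
              x$se, x$n, if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' Phenotypic (genotype-value) correlation
#'
#' Pearson correlation of paired per-line values, with the usual large-sample
#' standard error sqrt((1 - r^2) / (n - 2)).
#'
#' @param x,y paired per-line values (>= 3 lines).
#' @return a `correlation_estimate`.
#' @export
phenotypic_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stop_if(n < 3, "need at least 3 paired lines")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(new_correlation(NA_real_, NA_real_, "phenotypic", n))
  }
  r <- stats::cor(x, y)
  new_correlation(r, sqrt((1 - r^2) / (n - 2)), "phenotypic", n)
}

#' Genetic correlation between traits measured in different experiment units
#'
#' Robertson-style estimator for two criteria recorded on the same lines but
#' on different plots (e.g. pea yield in MS and in PS): because plot errors
#' are independent across units, the covariance of line means estimates the
#' genetic covariance, and r_g = cov(line means A, line means B) /
#' sqrt(s2g_A s2g_B) with the genotypic variances from the per-environment
#' ANOVA of each criterion. Estimates outside [-1, 1] (possible with noisy
#' components) are clamped and flagged. The standard error is the classical
#' heritability-based approximation.
#'
#' @param table plot-level trial table.
#' @param traitA,traitB trait column names.
#' @param condA,condB conditions in which each trait is analysed.
#' @param year trial year (single).
#' @return a `correlation_estimate`.
#' @export
genetic_correlation_cross_condition <- function(table, traitA, condA,
                                                traitB, condB, year) {
  mA <- line_means(table, traitA, condition = condA, year = year)
  mB <- line_means(table, traitB, condition = condB, year = year)
  common <- intersect(mA$line, mB$line)
  stop_if(length(common) < 3, "need at least 3 common lines")
  a <- mA$mean[match(common, mA$line)]
  b <- mB$mean[match(common, mB$line)]
  vcA <- variance_components(table, traitA, "per_env",
                             condition = condA, year = year)
  vcB <- variance_components(table, traitB, "per_env",
                             condition = condB, year = year)
  if (vcA$sigma2_g <= 0 || vcB$sigma2_g <= 0) {
    return(new_correlation(NA_real_, NA_real_, "genetic_cross_condition",
                           length(common)))
  }
  cg <- stats::cov(a, b)
  rg <- cg / sqrt(vcA$sigma2_g * vcB$sigma2_g)
  clamped <- abs(rg) > 1
  rg <- min(max(rg, -1), 1)
  hA <- heritability(vcA); hB <- heritability(vcB)
  se <- NA_real_
  if (is.finite(hA$se) && is.finite(hB$se) && hA$H2 > 0 && hB$H2 > 0) {
    se <- (1 - rg^2) / sqrt(2) * sqrt(hA$se * hB$se / (hA$H2 * hB$H2))
  }
  new_correlation(rg, se, "genetic_cross_condition", length(common), clamped)
}

#' Genetic correlation of one trait across years
#'
#' Itoh-Yamada estimator from the two-year variance components within one
#' condition: r_g = s2g / (s2g + s2gy).
#'
#' @param components a [variance_components()] from the `across_years` model.
#' @return a `correlation_estimate`.
#' @export
genetic_correlation_cross_year <- function(components) {
  s2g <- components$sigma2_g; s2gy <- components$sigma2_gy
  stop_if(is.na(s2g) || is.na(s2gy),
          "need sigma2_g and sigma2_gy from the across-years model")
  if (s2g + s2gy <= 0) {
    return(new_correlation(NA_real_, NA_real_, "genetic_cross_year", NA_integer_))
  }
  rg <- s2g / (s2g + s2gy)
  ## delta-method SE from the chi-square variances of the two mean squares
  se <- NA_real_
  tab <- components$anova
  if (!is.null(tab) && all(c("line", "year:line") %in% tab$term)) {
    df1 <- tab$df[tab$term == "line"]; df2 <- tab$df[tab$term == "year:line"]
    se <- rg * (1 - rg) * sqrt(2 / df1 + 2 / df2)
  }
  new_correlation(rg, se, "genetic_cross_year", NA_integer_)
}

#' u test for the difference of two correlation coefficients
#'
#' Fisher z-transform of each coefficient; u = (z1 - z2) /
#' sqrt(1/(n1 - 3) + 1/(n2 - 3)), two-sided p from the standard normal. The
#' independent-samples form is used.
#'
#' @param r1,r2 correlation coefficients (|r| < 1).
#' @param n1,n2 sample sizes (> 3).
#' @return list with u and p.
#' @export
dagnelie_u_test <- function(r1, n1, r2, n2) {
  stop_if(n1 <= 3 || n2 <= 3, "u test needs n > 3 in both samples")
  stop_if(abs(r1) >= 1 || abs(r2) >= 1,
          "|r| = 1 has an infinite z transform")
  u <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(u = u, p = 2 * stats::pnorm(-abs(u)))
}

#' Correlation matrix with NS/*/** significance codes
#'
#' @param values data.frame of per-line values (columns = traits).
#' @return list with `r` (correlation matrix) and `sig` (character codes at
#'   alpha = 0.05 and 0.01).
#' @export
correlation_matrix <- function(values) {
  k <- ncol(values)
  r <- stats::cor(values, use = "pairwise.complete.obs")
  sig <- matrix("", k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    ok <- stats::complete.cases(values[[i]], values[[j]])
    n <- sum(ok)
    if (n < 3 || is.na(r[i, j])) { sig[i, j] <- "NS"; next }
    t <- r[i, j] * sqrt((n - 2) / (1 - r[i, j]^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
    sig[i, j] <- if (p < 0.01) "**" else if (p < 0.05) "*" else "NS"
  }
  list(r = r, sig = sig)
}
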