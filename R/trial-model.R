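#' Derived mixture traits for mixed-stand plots
#'
#' Adds `total_yield` (pea + cereal) and `pea_proportion`
#' (pea / (pea + cereal)) to MS plot records; PS records are untouched (NA).
#' A zero total yield leaves the proportion undefined (NA).
#'
#' @param table plot-level trial table.
#' @return the table with `total_yield` and `pea_proportion` columns.
#' @export
derive_mixture_traits <- function(table) {
  ms <- table$condition == "MS"
  stop_if(any(ms & is.na(table$pea_yield) & !is.na(table$cereal_yield)),
          "MS records must carry pea yield")
  table$total_yield <- NA_real_
  table$pea_proportion <- NA_real_
  tot <- table$pea_yield[ms] + table$cereal_yield[ms]
  table$total_yield[ms] <- tot
  prop <- ifelse(tot > 0, table$pea_yield[ms] / tot, NA_real_)
  table$pea_proportion[ms] <- prop
  table
}

#' Doubled MS/PS pea yield ratio per mixed-stand plot
#'
#' ratio = 2 x (MS plot pea yield) / (line mean PS pea yield in the same
#' year). Pea occupies half the area in MS, hence the doubling puts both
#' conditions on an equal-area basis. Lines without PS records (or with zero
#' PS mean) in a year get NA with a warning.
#'
#' @param table plot-level trial table.
#' @return the table with an `ms_ps_ratio` column on MS records.
#' @export
ms_ps_yield_ratio <- function(table) {
  table$ms_ps_ratio <- NA_real_
  n_bad <- 0
  for (yr in unique(table$year)) {
    ps <- table$condition == "PS" & table$year == yr & !is.na(table$pea_yield)
    ps_mean <- tapply(table$pea_yield[ps], table$line[ps], mean)
    ms <- which(table$condition == "MS" & table$year == yr &
                  !is.na(table$pea_yield))
    denom <- ps_mean[table$line[ms]]
    ok <- !is.na(denom) & denom > 0
    n_bad <- n_bad + sum(!ok)
    table$ms_ps_ratio[ms[ok]] <- 2 * table$pea_yield[ms[ok]] / denom[ok]
  }
  if (n_bad > 0) {
    warning(n_bad, " MS plots lack a positive PS line mean; ratio set NA")
  }
  table
}

#' Per-line means of a trait over blocks (and optionally years)
#'
#' @param table plot-level trial table.
#' @param trait trait column name.
#' @param condition,year optional scope filters.
#' @return data.frame with line, population, is_parent, mean, n_plots.
#' @export
line_means <- function(table, trait, condition = NULL, year = NULL) {
  d <- table
  if (!is.null(condition)) d <- d[d$condition %in% condition, ]
  if (!is.null(year)) d <- d[d$year %in% year, ]
  d <- d[!is.na(d[[trait]]), ]
  stop_if(nrow(d) == 0, "no records for trait ", trait, " in the given scope")
  agg <- stats::aggregate(d[[trait]],
                          by = list(line = d$line), FUN = mean)
  names(agg)[2] <- "mean"
  cnt <- stats::aggregate(d[[trait]], by = list(line = d$line), FUN = length)
  agg$n_plots <- cnt$x
  info <- unique(d[, c("line", "population", "is_parent")])
  out <- merge(info, agg, by = "line", sort = TRUE)
  out[order(out$line), ]
}

## Balanced-design check: every line x block cell present exactly once within
## each condition x year stratum carrying the trait.
check_balance <- function(table, trait) {
  d <- table[!is.na(table[[trait]]), ]
  if (nrow(d) == 0) return(FALSE)
  tab <- table(d$line, d$block, d$year, d$condition)
  all(vapply(dimnames(tab)[[4]], function(cc) {
    sub <- tab[, , , cc, drop = FALSE]
    used_years <- apply(sub, 3, sum) > 0
    sub <- sub[, , used_years, , drop = FALSE]
    length(sub) == 0 || all(sub == 1)
  }, logical(1)))
}

ss_table <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  a <- stats::anova(fit)
  data.frame(term = rownames(a), df = a$Df, ss = a$`Sum Sq`,
             ms = a$`Mean Sq`, stringsAsFactors = FALSE)
}

#' ANOVA for the balanced trial models
#'
#' Four balanced expected-mean-square ANOVAs: `per_env` (line + block within
#' one condition x year); `split_plot` (line x condition within one year,
#' condition tested against the block x condition main-plot error);
#' `across_years` (line x year within one condition, line tested against the
#' line x year interaction); `full` (line x condition x year, with condition
#' and condition x year tested against condition x block within year, and the
#' line main effect by a Satterthwaite quasi-F). Unbalanced data are refused
#' (use the REML path).
#'
#' @param table plot-level trial table.
#' @param trait trait column name.
#' @param model one of `"per_env"`, `"split_plot"`, `"across_years"`,
#'   `"full"`.
#' @param condition,year optional scope filters (required where the model
#'   expects a single condition and/or year).
#' @return data.frame with term, df, ss, ms, f, p and the error term used.
#' @export
anova_trial <- function(table, trait,
                        model = c("per_env", "split_plot", "across_years",
                                  "full"),
                        condition = NULL, year = NULL) {
  model <- match.arg(model)
  d <- table
  if (!is.null(condition)) d <- d[d$condition %in% condition, ]
  if (!is.null(year)) d <- d[d$year %in% year, ]
  d <- d[!is.na(d[[trait]]), ]
  stop_if(nrow(d) == 0, "no data in scope")
  stop_if(!check_balance(d, trait),
          "unbalanced data for the EMS-based ANOVA; use the REML path ",
          "(variance_components_reml)")
  d$y <- d[[trait]]
  d$line <- factor(d$line); d$block <- factor(d$block)
  d$year <- factor(d$year); d$condition <- factor(d$condition)

  add_f <- function(tab, num, den) {
    i <- match(num, tab$term); j <- match(den, tab$term)
    tab$f[i] <- tab$ms[i] / tab$ms[j]
    tab$p[i] <- stats::pf(tab$f[i], tab$df[i], tab$df[j], lower.tail = FALSE)
    tab$error_term[i] <- den
    tab
  }

  if (model == "per_env") {
    stop_if(length(unique(d$condition)) != 1 || length(unique(d$year)) != 1,
            "per_env model needs a single condition and year (use arguments)")
    tab <- ss_table(y ~ block + line, d)
    tab$f <- NA_real_; tab$p <- NA_real_; tab$error_term <- NA_character_
    tab <- add_f(tab, "block", "Residuals")
    tab <- add_f(tab, "line", "Residuals")
  } else if (model == "split_plot") {
    stop_if(length(unique(d$year)) != 1,
            "split_plot model is fitted within one year")
    stop_if(length(unique(d$condition)) < 2, "need both conditions")
    tab <- ss_table(y ~ block + condition + block:condition + line +
                      condition:line, d)
    tab$f <- NA_real_; tab$p <- NA_real_; tab$error_term <- NA_character_
    tab <- add_f(tab, "condition", "block:condition")
    tab <- add_f(tab, "block", "block:condition")
    tab <- add_f(tab, "line", "Residuals")
    tab <- add_f(tab, "condition:line", "Residuals")
  } else if (model == "across_years") {
    stop_if(length(unique(d$condition)) != 1,
            "across_years model is fitted within one condition")
    stop_if(length(unique(d$year)) < 2, "need at least two years")
    tab <- ss_table(y ~ year + year:block + line + year:line, d)
    tab$f <- NA_real_; tab$p <- NA_real_; tab$error_term <- NA_character_
    tab <- add_f(tab, "year", "year:block")
    tab <- add_f(tab, "line", "year:line")
    tab <- add_f(tab, "year:line", "Residuals")
    tab <- add_f(tab, "year:block", "Residuals")
  } else {
    stop_if(length(unique(d$condition)) < 2 || length(unique(d$year)) < 2,
            "full model needs both conditions and both years")
    tab <- ss_table(y ~ year + year:block + condition + year:condition +
                      year:block:condition + line + condition:line +
                      year:line + year:condition:line, d)
    tab$f <- NA_real_; tab$p <- NA_real_; tab$error_term <- NA_character_
    tab <- add_f(tab, "year", "year:block")
    tab <- add_f(tab, "condition", "year:block:condition")
    tab <- add_f(tab, "year:condition", "year:block:condition")
    tab <- add_f(tab, "condition:line", "Residuals")
    tab <- add_f(tab, "year:line", "Residuals")
    tab <- add_f(tab, "year:condition:line", "Residuals")
    ## quasi-F for the line main effect against random interactions
    ms_g <- tab$ms[tab$term == "line"]
    ms_gc <- tab$ms[tab$term == "condition:line"]
    ms_gy <- tab$ms[tab$term == "year:line"]
    ms_gcy <- tab$ms[tab$term == "year:condition:line"]
    den <- ms_gc + ms_gy - ms_gcy
    df_num <- tab$df[tab$term == "line"]
    df_den <- den^2 / (
      ms_gc^2 / tab$df[tab$term == "condition:line"] +
        ms_gy^2 / tab$df[tab$term == "year:line"] +
        ms_gcy^2 / tab$df[tab$term == "year:condition:line"])
    i <- match("line", tab$term)
    if (den > 0) {
      tab$f[i] <- ms_g / den
      tab$p[i] <- stats::pf(tab$f[i], df_num, df_den, lower.tail = FALSE)
      tab$error_term[i] <- "GC+GY-GCY (Satterthwaite)"
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Variance components from expected mean squares (method of moments)
#'
#' Balanced-design method-of-moments estimators, the exact REML solutions on
#' these designs. Negative estimates are truncated at 0 and flagged.
#'
#' @param table plot-level trial table.
#' @param trait trait column name.
#' @param model `"per_env"` (G, error), `"across_years"` (G, GxY, error) or
#'   `"full"` (G, GxC, GxY, GxCxY, error).
#' @param condition,year optional scope filters.
#' @return object of class `variance_components`.
#' @export
variance_components <- function(table, trait,
                                model = c("per_env", "across_years", "full"),
                                condition = NULL, year = NULL) {
  model <- match.arg(model)
  amodel <- if (model == "per_env") "per_env" else
    if (model == "across_years") "across_years" else "full"
  tab <- anova_trial(table, trait, amodel, condition = condition, year = year)
  d <- table
  if (!is.null(condition)) d <- d[d$condition %in% condition, ]
  if (!is.null(year)) d <- d[d$year %in% year, ]
  d <- d[!is.na(d[[trait]]), ]
  b <- length(unique(d$block))
  y <- length(unique(d$year))
  cc <- length(unique(d$condition))
  ms <- function(term) tab$ms[tab$term == term]
  dfree <- function(term) tab$df[tab$term == term]
  truncated <- character(0)
  trunc0 <- function(x, name) {
    if (x < 0) truncated <<- c(truncated, name)
    max(x, 0)
  }
  s2e <- ms("Residuals")
  comp <- list(sigma2_g = NA_real_, sigma2_gc = NA_real_,
               sigma2_gy = NA_real_, sigma2_gcy = NA_real_, sigma2_e = s2e)
  if (model == "per_env") {
    comp$sigma2_g <- trunc0((ms("line") - s2e) / b, "sigma2_g")
  } else if (model == "across_years") {
    comp$sigma2_gy <- trunc0((ms("year:line") - s2e) / b, "sigma2_gy")
    comp$sigma2_g <- trunc0((ms("line") - ms("year:line")) / (b * y),
                            "sigma2_g")
  } else {
    comp$sigma2_gcy <- trunc0((ms("year:condition:line") - s2e) / b,
                              "sigma2_gcy")
    comp$sigma2_gy <- trunc0(
      (ms("year:line") - ms("year:condition:line")) / (b * cc), "sigma2_gy")
    comp$sigma2_gc <- trunc0(
      (ms("condition:line") - ms("year:condition:line")) / (b * y),
      "sigma2_gc")
    comp$sigma2_g <- trunc0(
      (ms("line") - ms("condition:line") - ms("year:line") +
         ms("year:condition:line")) / (b * cc * y), "sigma2_g")
  }
  structure(c(comp, list(n = b, y = y, c = cc, method = "mom",
                         truncated = truncated, anova = tab)),
            class = "variance_components")
}

#' REML variance components (cross-check of the method of moments)
#'
#' Fits the matching mixed model with `lme4::lmer` (genotype and its
#' interactions random, design factors fixed) and reports the same component
#' set as [variance_components()]. On balanced data the two agree whenever no
#' component is truncated (REML constrains components to be nonnegative).
#'
#' @inheritParams variance_components
#' @return object of class `variance_components` (method tag `"reml"`).
#' @export
variance_components_reml <- function(table, trait,
                                     model = c("per_env", "across_years",
                                               "full"),
                                     condition = NULL, year = NULL) {
  model <- match.arg(model)
  d <- table
  if (!is.null(condition)) d <- d[d$condition %in% condition, ]
  if (!is.null(year)) d <- d[d$year %in% year, ]
  d <- d[!is.na(d[[trait]]), ]
  stop_if(nrow(d) == 0, "no data in scope")
  d$y_ <- d[[trait]]
  d$line <- factor(d$line); d$block <- factor(d$block)
  d$year <- factor(d$year); d$condition <- factor(d$condition)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  if (model == "per_env") {
    fit <- lme4::lmer(y_ ~ block + (1 | line), data = d, control = ctrl)
  } else if (model == "across_years") {
    fit <- lme4::lmer(y_ ~ year + year:block + (1 | line) + (1 | line:year),
                      data = d, control = ctrl)
  } else {
    fit <- lme4::lmer(y_ ~ year * condition + year:block +
                        year:block:condition + (1 | line) +
                        (1 | line:condition) + (1 | line:year) +
                        (1 | line:condition:year), data = d, control = ctrl)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) NA_real_ else v
  }
  comp <- list(
    sigma2_g = pick("line"),
    sigma2_gc = pick("line:condition"),
    sigma2_gy = pick("line:year"),
    sigma2_gcy = pick("line:condition:year"),
    sigma2_e = vc$vcov[vc$grp == "Residual"]
  )
  structure(c(comp, list(n = length(unique(d$block)),
                         y = length(unique(d$year)),
                         c = length(unique(d$condition)),
                         method = "reml", truncated = character(0),
                         anova = NULL)),
            class = "variance_components")
}

#' Broad-sense heritability on a line-mean basis
#'
#' Single-environment basis: H2 = s2g / (s2g + s2e / n). Over-years basis:
#' H2 = s2g / (s2g + s2gy / y + s2e / (y n)). The standard error is a
#' delta-method approximation from the mean-square chi-square variances,
#' SE = (1 - H2) sqrt(2/df_num + 2/df_den), available when the ANOVA mean
#' squares are attached.
#'
#' @param components a [variance_components()].
#' @param basis `"single-environment"` or `"over-years"`.
#' @return object of class `heritability` with H2, se, basis.
#' @export
heritability <- function(components,
                         basis = c("single-environment", "over-years")) {
  basis <- match.arg(basis)
  s2g <- components$sigma2_g; s2e <- components$sigma2_e
  n <- components$n; y <- components$y
  stop_if(is.na(s2g), "sigma2_g missing for this model")
  if (basis == "single-environment") {
    denom <- s2g + s2e / n
    num_term <- "line"; den_term <- "Residuals"
  } else {
    s2gy <- components$sigma2_gy
    stop_if(is.na(s2gy), "over-years basis needs sigma2_gy")
    denom <- s2g + s2gy / y + s2e / (y * n)
    num_term <- "line"; den_term <- "year:line"
  }
  stop_if(denom <= 0, "all variance components are zero; H2 undefined")
  H2 <- min(max(s2g / denom, 0), 1)
  se <- NA_real_
  tab <- components$anova
  if (!is.null(tab) && all(c(num_term, den_term) %in% tab$term)) {
    df1 <- tab$df[tab$term == num_term]
    df2 <- tab$df[tab$term == den_term]
    se <- (1 - H2) * sqrt(2 / df1 + 2 / df2)
  }
  structure(list(H2 = H2, se = se, basis = basis), class = "heritability")
}

#' Heritability from printed coefficients of variation
#'
#' Convenience form of the line-mean formula when genetic and error
#' variability are given as coefficients of variation of a common mean:
#' H2 = CVg^2 / (CVg^2 + CVe^2 / n).
#'
#' @param cvg,cve genetic and error coefficients of variation (percent).
#' @param n replicates per line.
#' @return H2 (numeric).
#' @export
heritability_from_cv <- function(cvg, cve, n) {
  stop_if(n <= 0, "n must be positive")
  cvg^2 / (cvg^2 + cve^2 / n)
}

#' Shrunken line means (BLUPs) for one condition and year
#'
#' BLUP_i = mu + H2 (mean_i - mu), with H2 the single-environment line-mean
#' heritability of that condition x year. H2 = 1 returns the line means, H2 =
#' 0 the grand mean.
#'
#' @param table plot-level trial table.
#' @param trait trait column name.
#' @param year,condition scope (single values).
#' @return data.frame with line, population, is_parent, mean, blup.
#' @export
blup_line_values <- function(table, trait, year, condition) {
  lm_ <- line_means(table, trait, condition = condition, year = year)
  vc <- variance_components(table, trait, "per_env",
                            condition = condition, year = year)
  h2 <- heritability(vc, "single-environment")$H2
  stop_if(is.na(h2), "heritability undefined; cannot shrink line means")
  mu <- mean(lm_$mean)
  lm_$blup <- mu + h2 * (lm_$mean - mu)
  attr(lm_, "H2") <- h2
  lm_
}
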