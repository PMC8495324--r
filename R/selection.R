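new_efficiency <- function(E_R, method, components, per_year = NULL) {
  structure(list(E_R = E_R, method = method, components = components,
                 per_year = per_year), class = "efficiency_result")
}

#' @exportS3Method base::print
print.efficiency_result <- function(x, ...) {
  cat(sprintf("E_R = %.1f%% (%s)\n", x$E_R, x$method))
  invisible(x)
}

#' Forward stepwise construction of an indirect selection index
#'
#' Builds a linear index of PS-measured traits that predicts the direct
#' criterion (pea yield in MS), from line values averaged across years. A
#' candidate enters when its partial regression coefficient is significant at
#' `entry_p` and it raises the regression R^2 by at least `min_delta_r2`;
#' final weights are the multiple-regression partial coefficients of the
#' included traits.
#'
#' @param response per-line values of the direct criterion.
#' @param candidates data.frame of candidate trait line values (same order).
#' @param entry_p entry significance threshold (default 0.05).
#' @param min_delta_r2 minimum R^2 increase for entry (default 0.02).
#' @param collinearity_r candidate pairs correlated at or above this guard
#'   trigger an error (default 0.95).
#' @return object of class `selection_index_model`: intercept, named weights
#'   in entry order, per-step diagnostics, total R^2.
#' @export
fit_selection_index <- function(response, candidates, entry_p = 0.05,
                                min_delta_r2 = 0.02, collinearity_r = 0.95) {
  stop_if(length(response) != nrow(candidates),
          "response and candidates must cover the same lines")
  cm <- stats::cor(candidates, use = "pairwise.complete.obs")
  diag(cm) <- 0
  stop_if(any(abs(cm) >= collinearity_r, na.rm = TRUE),
          "candidate traits are collinear (|r| >= ", collinearity_r, ")")
  d <- data.frame(.y = response, candidates, check.names = FALSE)
  included <- character(0)
  steps <- list()
  r2 <- 0
  repeat {
    remaining <- setdiff(names(candidates), included)
    if (length(remaining) == 0) break
    best <- NULL
    for (tr in remaining) {
      f <- stats::reformulate(c(included, sprintf("`%s`", tr)),
                              response = ".y")
      fit <- stats::lm(f, data = d)
      sm <- summary(fit)
      p <- stats::coef(sm)[nrow(stats::coef(sm)), 4]
      dr2 <- sm$r.squared - r2
      if (p < entry_p && dr2 >= min_delta_r2 &&
          (is.null(best) || dr2 > best$dr2)) {
        best <- list(trait = tr, p = p, dr2 = dr2, r2 = sm$r.squared)
      }
    }
    if (is.null(best)) break
    included <- c(included, best$trait)
    r2 <- best$r2
    steps[[length(steps) + 1]] <- data.frame(
      trait = best$trait, p = best$p, delta_r2 = best$dr2, r2 = best$r2)
  }
  if (length(included) == 0) {
    return(structure(list(intercept = mean(response), weights = numeric(0),
                          entry = data.frame(trait = character(0),
                                             p = numeric(0),
                                             delta_r2 = numeric(0),
                                             r2 = numeric(0)),
                          r2 = 0),
                     class = "selection_index_model"))
  }
  f <- stats::reformulate(sprintf("`%s`", included), response = ".y")
  fit <- stats::lm(f, data = d)
  w <- stats::coef(fit)
  weights <- w[-1]
  names(weights) <- included
  structure(list(intercept = unname(w[1]), weights = weights,
                 entry = do.call(rbind, steps),
                 r2 = summary(fit)$r.squared),
            class = "selection_index_model")
}

#' Evaluate a selection index
#'
#' intercept + sum(weight x trait value). Works on a named vector, a
#' data.frame of line values (one row per line), or plot-level records.
#'
#' @param model a `selection_index_model`.
#' @param traits named vector or data.frame with the index's trait columns.
#' @return numeric index value(s).
#' @export
index_score <- function(model, traits) {
  need <- names(model$weights)
  if (is.data.frame(traits)) {
    stop_if(!all(need %in% names(traits)),
            "missing index traits: ",
            paste(setdiff(need, names(traits)), collapse = ", "))
    if (length(need) == 0) return(rep(model$intercept, nrow(traits)))
    return(model$intercept +
             as.numeric(as.matrix(traits[, need, drop = FALSE]) %*%
                          model$weights))
  }
  stop_if(!all(need %in% names(traits)),
          "missing index traits: ",
          paste(setdiff(need, names(traits)), collapse = ", "))
  model$intercept + sum(model$weights * unlist(traits)[need])
}

#' Predicted relative efficiency from heritabilities and genetic correlation
#'
#' Falconer's formula: E_R = (H_indirect / H_direct) r_g x 100, with H the
#' square root of the broad-sense line-mean heritability of each criterion.
#'
#' @param H2_indirect,H2_direct heritabilities in (0, 1].
#' @param r_g genetic correlation between the criteria.
#' @return an `efficiency_result` (E_R in percent, unrounded).
#' @export
predicted_efficiency_heritability <- function(H2_indirect, H2_direct, r_g) {
  stop_if(H2_direct <= 0, "direct-criterion heritability must be positive")
  stop_if(H2_indirect < 0 || H2_indirect > 1 || H2_direct > 1,
          "heritabilities must lie in (0, 1]")
  stop_if(abs(r_g) > 1, "r_g must lie in [-1, 1]")
  er <- sqrt(H2_indirect) / sqrt(H2_direct) * r_g * 100
  new_efficiency(er, "heritability_based",
                 list(H2_indirect = H2_indirect, H2_direct = H2_direct,
                      r_g = r_g))
}

#' Predicted relative efficiency from cross-year correlations
#'
#' Each criterion's correlations between its value in a selection year and MS
#' yield in the other (target) year are averaged across the two selection
#' years; E_R = (mean r_indirect / mean r_direct) x 100.
#'
#' @param r_indirect_by_year,r_direct_by_year numeric vectors of cross-year
#'   correlations (one per selection year).
#' @return an `efficiency_result` with the averaged correlations attached.
#' @export
predicted_efficiency_correlation <- function(r_indirect_by_year,
                                             r_direct_by_year) {
  ri <- mean(r_indirect_by_year)
  rd <- mean(r_direct_by_year)
  stop_if(rd == 0, "direct-criterion correlation is zero; E_R undefined")
  new_efficiency(ri / rd * 100, "correlation_based",
                 list(r_indirect = ri, r_direct = rd))
}

#' Realized gain of within-population selection across years
#'
#' Within each RIL population, the top `k` non-parent lines by the criterion
#' score (from the selection year) are selected; the gain is the mean
#' evaluation-year MS pea yield of all selected lines minus the mean
#' evaluation-year MS yield of the parent lines. Ties are broken by ascending
#' line id.
#'
#' @param table plot-level trial table (needs both years).
#' @param scores data.frame with columns line, score: the per-line criterion
#'   value in the selection year.
#' @param selection_year,evaluation_year the two years.
#' @param criterion label stored in the report.
#' @param k lines selected per population (default 2).
#' @return object of class `gain_report`.
#' @export
year_swap_gain <- function(table, scores, selection_year, evaluation_year,
                           criterion = "criterion", k = 2) {
  eval_means <- line_means(table, "pea_yield", condition = "MS",
                           year = evaluation_year)
  cand <- eval_means[!eval_means$is_parent, ]
  cand$score <- scores$score[match(cand$line, scores$line)]
  stop_if(anyNA(cand$score), "scores missing for some candidate lines")
  selected <- do.call(rbind, lapply(split(cand, cand$population), function(p) {
    stop_if(k > nrow(p), "k exceeds lines per population")
    p <- p[order(-p$score, p$line), ]
    p[seq_len(k), c("population", "line", "score", "mean")]
  }))
  rownames(selected) <- NULL
  parent_mean <- mean(eval_means$mean[eval_means$is_parent])
  mean_selected <- mean(selected$mean)
  structure(list(selection_year = selection_year,
                 evaluation_year = evaluation_year,
                 criterion = criterion, k = k, selected = selected,
                 mean_selected = mean_selected, parent_mean = parent_mean,
                 gain = mean_selected - parent_mean),
            class = "gain_report")
}

#' Relative efficiency from realized gains
#'
#' Per selection year, E_R = (G_SC / G_MS) x 100 rounded to integer; the
#' reported value is the half-up-rounded average of the per-year integers
#' (the raw unrounded values are kept in the result).
#'
#' @param gains_criterion,gains_direct numeric vectors of per-year gains for
#'   the alternative criterion and for direct MS-yield selection.
#' @return an `efficiency_result` with `per_year` integer efficiencies.
#' @export
relative_efficiency_from_gains <- function(gains_criterion, gains_direct) {
  stop_if(length(gains_criterion) != length(gains_direct),
          "gain vectors must align by selection year")
  stop_if(any(gains_direct <= 0),
          "direct-selection gain <= 0; E_R undefined")
  raw <- gains_criterion / gains_direct * 100
  per_year <- round_half_up(raw)
  new_efficiency(round_half_up(mean(per_year)), "gain_based",
                 list(G_SC = gains_criterion, G_MS = gains_direct,
                      raw = raw),
                 per_year = per_year)
}

#' Per-unit-time adjustment of a relative efficiency
#'
#' Scales E_R by the ratio of selection cycles per unit time (genomic
#' selection can run two cycles per year against one phenotypic cycle).
#'
#' @param E_R efficiency in percent (numeric or `efficiency_result`).
#' @param cycles_ratio cycles of the alternative criterion per cycle of the
#'   direct one (> 0).
#' @return an `efficiency_result`.
#' @export
per_unit_time_adjustment <- function(E_R, cycles_ratio) {
  stop_if(cycles_ratio <= 0, "cycles_ratio must be positive")
  er <- if (inherits(E_R, "efficiency_result")) E_R$E_R else E_R
  new_efficiency(er * cycles_ratio, "per_unit_time",
                 list(E_R_base = er, cycles_ratio = cycles_ratio))
}
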