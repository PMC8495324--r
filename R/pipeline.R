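#' Trait summary across lines (means and ranges of line means)
#'
#' @param table plot-level trial table (after [derive_mixture_traits()] /
#'   [ms_ps_yield_ratio()] if derived traits are wanted).
#' @return data.frame trait, condition, year, mean, min, max.
#' @export
trait_summary <- function(table) {
  keep <- setdiff(names(table), c("year", "condition", "block", "population",
                                  "line", "is_parent"))
  out <- list()
  for (tr in keep) {
    d <- table[!is.na(table[[tr]]), ]
    if (nrow(d) == 0) next
    for (cc in unique(d$condition)) for (yy in unique(d$year[d$condition == cc])) {
      sub <- d[d$condition == cc & d$year == yy, ]
      if (nrow(sub) == 0) next
      lm_ <- tapply(sub[[tr]], sub$line, mean)
      out[[length(out) + 1]] <- data.frame(
        trait = tr, condition = cc, year = yy, mean = mean(lm_),
        min = min(lm_), max = max(lm_))
    }
  }
  do.call(rbind, out)
}

#' Per-line criterion scores for a selection year
#'
#' @param table plot-level trial table.
#' @param criterion `"ms"` (MS pea yield), `"ps"` (PS pea yield) or
#'   `"index"` (a fitted selection index applied to PS trait line means).
#' @param year selection year.
#' @param index_model required for `criterion = "index"`.
#' @return data.frame line, score.
#' @export
criterion_scores <- function(table, criterion = c("ms", "ps", "index"),
                             year, index_model = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "ms") {
    lm_ <- line_means(table, "pea_yield", condition = "MS", year = year)
    return(data.frame(line = lm_$line, score = lm_$mean))
  }
  if (criterion == "ps") {
    lm_ <- line_means(table, "pea_yield", condition = "PS", year = year)
    return(data.frame(line = lm_$line, score = lm_$mean))
  }
  stop_if(is.null(index_model), "index criterion needs an index_model")
  traits <- names(index_model$weights)
  vals <- NULL
  for (tr in traits) {
    lm_ <- line_means(table, tr, condition = "PS", year = year)
    v <- stats::setNames(lm_$mean, lm_$line)
    vals <- if (is.null(vals)) data.frame(line = names(v), check.names = FALSE)
            else vals
    vals[[tr]] <- v[vals$line]
  }
  data.frame(line = vals$line,
             score = index_score(index_model, vals[, traits, drop = FALSE]))
}

## Candidate PS traits for the selection index (pea yield enters as
## "pea_yield"; disease/survival only where recorded)
index_candidate_values <- function(table) {
  cand_traits <- c("height_flowering", "pea_yield", "onset_flowering",
                   "seed_weight", "maturity", "height_maturity",
                   "winter_survival", "ascochyta")
  out <- NULL
  for (tr in cand_traits) {
    lm_ <- tryCatch(line_means(table, tr, condition = "PS"),
                    error = function(e) NULL)
    if (is.null(lm_)) next
    v <- stats::setNames(lm_$mean, lm_$line)
    if (is.null(out)) out <- data.frame(line = names(v), check.names = FALSE)
    out[[tr]] <- v[out$line]
  }
  out
}

#' Add a per-plot selection-index composite trait column
#'
#' Applies across-year index weights to plot-level PS trait values, so the
#' composite trait can run through the same ANOVA / heritability machinery
#' as any measured trait.
#'
#' @param table plot-level trial table.
#' @param index_model a `selection_index_model`.
#' @return the table with an `index_value` column on PS plots.
#' @export
add_index_trait <- function(table, index_model) {
  traits <- names(index_model$weights)
  table$index_value <- NA_real_
  ps <- which(table$condition == "PS")
  ok <- ps[stats::complete.cases(table[ps, traits, drop = FALSE])]
  table$index_value[ok] <- index_score(index_model,
                                       table[ok, traits, drop = FALSE])
  table
}

#' Strategy-by-method relative-efficiency comparison table
#'
#' @param results data.frame (or list of rows) with columns strategy, method,
#'   E_R and optional component columns; an empty input returns an empty
#'   table with the header.
#' @return data.frame with one row per strategy x comparison method.
#' @export
report_efficiency_summary <- function(results) {
  header <- data.frame(strategy = character(0), method = character(0),
                       E_R = numeric(0))
  if (is.null(results) || length(results) == 0) return(header)
  if (is.data.frame(results)) return(results[order(results$method,
                                                   results$strategy), ])
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    data.frame(strategy = nm, method = x$method, E_R = x$E_R)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' One seeded call covering the study workflow: simulate (or accept) a
#' scenario; derive mixture traits; per-year variance components,
#' heritabilities and cross-condition genetic correlations for the three
#' phenotypic criteria (MS yield, PS yield, selection index); across-year
#' components and cross-year genetic correlations; correlation-based and
#' gain-based relative efficiencies with the year-swap protocols; genotype
#' filtering, imputation, kinship and the three inter-environment CV schemes;
#' genomic realized gains; GWAS for MS and PS yield.
#'
#' @param config a [sim_config()] (ignored when `scenario` is supplied).
#' @param scenario optionally a pre-built [generate_scenario()] result.
#' @param cv_repetitions repetitions for the stratified CV schemes.
#' @param out_dir if non-NULL, TSV tables and a JSON manifest are written
#'   here.
#' @param filter_cfg a [filter_config()] for the genotype matrix.
#' @return list of result tables and fitted objects.
#' @export
run_pipeline <- function(config = sim_config(), scenario = NULL,
                         cv_repetitions = 20, out_dir = NULL,
                         filter_cfg = filter_config()) {
  if (is.null(scenario)) scenario <- generate_scenario(config)
  config <- scenario$config
  stop_if(length(config$years) < 2,
          "year-swap protocols need two trial years")
  years <- config$years
  trial <- ms_ps_yield_ratio(derive_mixture_traits(scenario$trial))

  summary_tab <- trait_summary(trial)

  ## selection index from across-year PS line values vs MS yield
  cand <- index_candidate_values(trial)
  resp <- line_means(trial, "pea_yield", condition = "MS")
  y <- stats::setNames(resp$mean, resp$line)[cand$line]
  index_model <- fit_selection_index(y, cand[, -1, drop = FALSE])
  trial <- add_index_trait(trial, index_model)

  ## per-year heritabilities, genetic correlations, Falconer efficiencies
  herit_rows <- list(); eff <- list()
  for (yr in years) {
    vc_ms <- variance_components(trial, "pea_yield", "per_env", "MS", yr)
    vc_ps <- variance_components(trial, "pea_yield", "per_env", "PS", yr)
    h_ms <- heritability(vc_ms); h_ps <- heritability(vc_ps)
    rg_ps <- genetic_correlation_cross_condition(trial, "pea_yield", "MS",
                                                 "pea_yield", "PS", yr)
    er_ps <- predicted_efficiency_heritability(h_ps$H2, h_ms$H2, rg_ps$r)
    herit_rows[[length(herit_rows) + 1]] <- data.frame(
      year = yr, criterion = "ms_yield", H2 = h_ms$H2, se = h_ms$se,
      r_g = NA, E_R = 100)
    herit_rows[[length(herit_rows) + 1]] <- data.frame(
      year = yr, criterion = "ps_yield", H2 = h_ps$H2, se = h_ps$se,
      r_g = rg_ps$r, E_R = er_ps$E_R)
    eff[[paste0("ps_yield_", yr)]] <- er_ps
    if (length(index_model$weights) > 0) {
      vc_ix <- variance_components(trial, "index_value", "per_env", "PS", yr)
      h_ix <- heritability(vc_ix)
      rg_ix <- genetic_correlation_cross_condition(trial, "pea_yield", "MS",
                                                   "index_value", "PS", yr)
      er_ix <- predicted_efficiency_heritability(h_ix$H2, h_ms$H2, rg_ix$r)
      herit_rows[[length(herit_rows) + 1]] <- data.frame(
        year = yr, criterion = "index", H2 = h_ix$H2, se = h_ix$se,
        r_g = rg_ix$r, E_R = er_ix$E_R)
      eff[[paste0("index_", yr)]] <- er_ix
    }
  }
  heritability_table <- do.call(rbind, herit_rows)

  ## across-year components and cross-year genetic correlations
  year_rows <- list()
  crits <- list(ms_yield = list(trait = "pea_yield", cond = "MS"),
                ps_yield = list(trait = "pea_yield", cond = "PS"))
  if (length(index_model$weights) > 0) {
    crits$index <- list(trait = "index_value", cond = "PS")
  }
  for (nm in names(crits)) {
    cr <- crits[[nm]]
    vc <- variance_components(trial, cr$trait, "across_years",
                              condition = cr$cond)
    rg <- genetic_correlation_cross_year(vc)
    h2 <- heritability(vc, "over-years")
    year_rows[[nm]] <- data.frame(criterion = nm, r_g_years = rg$r,
                                  H2_over_years = h2$H2)
  }
  across_years_table <- do.call(rbind, year_rows)

  ## correlation-based comparison (selection year -> target year MS yield)
  corr_rows <- list()
  for (nm in names(crits)) {
    cr <- crits[[nm]]
    rs <- vapply(seq_along(years), function(i) {
      sel <- years[i]; tgt <- years[-i][1]
      sc <- line_means(trial, cr$trait, condition = cr$cond, year = sel)
      ob <- line_means(trial, "pea_yield", condition = "MS", year = tgt)
      common <- intersect(sc$line, ob$line)
      phenotypic_correlation(sc$mean[match(common, sc$line)],
                             ob$mean[match(common, ob$line)])$r
    }, numeric(1))
    corr_rows[[nm]] <- data.frame(criterion = nm,
                                  r_sel_year1 = rs[1], r_sel_year2 = rs[2],
                                  r_mean = mean(rs))
  }
  correlation_table <- do.call(rbind, corr_rows)
  r_ms <- correlation_table$r_mean[correlation_table$criterion == "ms_yield"]
  correlation_table$E_R <- correlation_table$r_mean / r_ms * 100

  ## gain-based comparison with the year-swap protocol
  gain_rows <- list(); gains <- list()
  pheno_crit <- c("ms", "ps", if (length(index_model$weights) > 0) "index")
  for (cr in pheno_crit) {
    for (i in seq_along(years)) {
      sel <- years[i]; tgt <- years[-i][1]
      sc <- criterion_scores(trial, cr, sel, index_model)
      gr <- year_swap_gain(trial, sc, sel, tgt, criterion = cr)
      gains[[paste(cr, sel, sep = "_")]] <- gr
      gain_rows[[length(gain_rows) + 1]] <- data.frame(
        criterion = cr, selection_year = sel, evaluation_year = tgt,
        mean_yield = gr$mean_selected, parent_mean = gr$parent_mean,
        gain = gr$gain)
    }
  }

  ## genomic stage
  gm_f <- filter_markers_and_genotypes(scenario$geno, filter_cfg)
  gm_i <- knni_impute(gm_f)
  K <- kinship_astle_balding(gm_i)
  li <- scenario$line_info[scenario$line_info$line %in% rownames(K), ]
  pred_rows <- list(); cv_results <- list()
  for (scheme in c("intra_population", "all_genotypes", "inter_population")) {
    plan <- make_cv_plan(li, scheme, n_repetitions = cv_repetitions,
                         seed = config$seed)
    ab <- vapply(seq_along(years), function(i) {
      cv <- run_inter_environment_cv(K, trial, plan, years[i], years[-i][1])
      cv_results[[paste(scheme, years[i], sep = "_")]] <<- cv
      cv$ability
    }, numeric(1))
    pred_rows[[scheme]] <- data.frame(scheme = scheme,
                                      ability_train_y1 = ab[1],
                                      ability_train_y2 = ab[2],
                                      ability_mean = mean(ab))
  }
  predictive_ability_table <- do.call(rbind, pred_rows)

  for (i in seq_along(years)) {
    sel <- years[i]; tgt <- years[-i][1]
    gr <- genomic_gain_protocol(K, trial, sel, tgt,
                                n_repetitions = cv_repetitions,
                                seed = config$seed)
    gains[[paste("gebv", sel, sep = "_")]] <- gr
    gain_rows[[length(gain_rows) + 1]] <- data.frame(
      criterion = "gebv", selection_year = sel, evaluation_year = tgt,
      mean_yield = gr$mean_selected, parent_mean = gr$parent_mean,
      gain = gr$gain)
  }
  gain_table <- do.call(rbind, gain_rows)

  g_ms <- gain_table$gain[gain_table$criterion == "ms"]
  eff_gain_rows <- list()
  for (cr in setdiff(unique(gain_table$criterion), "ms")) {
    g_cr <- gain_table$gain[gain_table$criterion == cr]
    er <- tryCatch(relative_efficiency_from_gains(g_cr, g_ms),
                   error = function(e) NULL)
    if (!is.null(er)) {
      eff_gain_rows[[cr]] <- data.frame(criterion = cr,
                                        E_R_y1 = er$per_year[1],
                                        E_R_y2 = er$per_year[2],
                                        E_R = er$E_R)
    }
  }
  gain_efficiency_table <- if (length(eff_gain_rows) > 0)
    do.call(rbind, eff_gain_rows) else NULL

  ## GWAS on line values averaged across years
  gwas_results <- list()
  for (cond in c("MS", "PS")) {
    lm_ <- line_means(trial, "pea_yield", condition = cond)
    ph <- stats::setNames(lm_$mean, lm_$line)
    pops <- li$population[match(rownames(gm_i$geno), li$line)]
    gwas_results[[cond]] <- gwas_scan(gm_i, ph[rownames(gm_i$geno)], pops)
  }

  out <- list(scenario = scenario, trial = trial,
              trait_summary = summary_tab,
              index_model = index_model,
              heritability_table = heritability_table,
              across_years_table = across_years_table,
              correlation_table = correlation_table,
              gain_table = gain_table,
              gain_efficiency_table = gain_efficiency_table,
              predictive_ability_table = predictive_ability_table,
              cv_results = cv_results,
              gains = gains,
              gwas = gwas_results,
              filter_report = attr(gm_f, "report"),
              kinship = K)

  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, config)
  out
}

#' Single-year predicted efficiency of PS-yield indirect selection
#'
#' The full estimation chain for one trial year: per-condition variance
#' components, line-mean heritabilities, cross-condition genetic correlation
#' of pea yield, and the Falconer relative efficiency of indirect PS-yield
#' selection against direct MS-yield selection.
#'
#' @param table plot-level trial table.
#' @param year trial year.
#' @return list with H2_MS, H2_PS, r_g and E_R (percent, unrounded).
#' @export
indirect_efficiency_ps <- function(table, year) {
  vc_ms <- variance_components(table, "pea_yield", "per_env", "MS", year)
  vc_ps <- variance_components(table, "pea_yield", "per_env", "PS", year)
  h_ms <- heritability(vc_ms)$H2
  h_ps <- heritability(vc_ps)$H2
  rg <- genetic_correlation_cross_condition(table, "pea_yield", "PS",
                                            "pea_yield", "MS", year)
  er <- predicted_efficiency_heritability(h_ps, h_ms, rg$r)
  list(H2_MS = h_ms, H2_PS = h_ps, r_g = rg$r, E_R = er$E_R)
}

write_pipeline_outputs <- function(out, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    if (!is.null(x)) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(out$trait_summary, "trait_summary.tsv")
  wt(out$heritability_table, "heritability.tsv")
  wt(out$across_years_table, "across_years.tsv")
  wt(out$correlation_table, "correlation_efficiency.tsv")
  wt(out$gain_table, "gains.tsv")
  wt(out$gain_efficiency_table, "gain_efficiency.tsv")
  wt(out$predictive_ability_table, "predictive_ability.tsv")
  for (cond in names(out$gwas)) {
    wt(manhattan_table(out$gwas[[cond]]),
       sprintf("gwas_%s.tsv", tolower(cond)))
  }
  manifest <- list(
    seed = config$seed,
    n_lines = nrow(out$scenario$line_info),
    n_markers_raw = ncol(out$scenario$geno$geno),
    filter_report = out$filter_report,
    index = list(intercept = out$index_model$intercept,
                 weights = as.list(out$index_model$weights),
                 r2 = out$index_model$r2),
    lambda_gc = lapply(out$gwas, `[[`, "lambda_gc"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
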