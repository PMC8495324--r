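#' Center a dosage matrix by twice the allele frequency
#'
#' @param geno lines x markers dosage matrix (or [genotype_matrix()]).
#' @return centered numeric matrix.
#' @export
center_markers <- function(geno) {
  if (inherits(geno, "genotype_matrix")) geno <- geno$geno
  sweep(geno, 2, colMeans(geno), "-")
}

## Restricted-likelihood estimation of delta = sigma2_e / sigma2_g for
## y = 1 mu + g + e, g ~ N(0, sigma2_g K): spectral (EMMA-style) profile
## over a one-dimensional bounded search.
reml_delta_kinship <- function(K, y, interval = c(-5, 5)) {
  n <- length(y)
  stop_if(nrow(K) != n, "K and y dimensions differ")
  X <- matrix(1, n, 1)
  S <- diag(n) - tcrossprod(X) / n
  e <- eigen(S %*% K %*% S, symmetric = TRUE)
  idx <- seq_len(n - 1) # last eigenvalue is the projected-out intercept
  xi <- pmax(e$values[idx], 0)
  eta <- crossprod(e$vectors[, idx, drop = FALSE], y)[, 1]
  q <- n - 1
  rll <- function(log10d) {
    d <- 10^log10d
    ss <- sum(eta^2 / (xi + d))
    -0.5 * (q * log(ss / q) + sum(log(xi + d)))
  }
  opt <- stats::optimize(rll, interval = interval, maximum = TRUE, tol = 1e-4)
  delta <- 10^opt$maximum
  sigma2_g <- sum(eta^2 / (xi + delta)) / q
  list(delta = delta, sigma2_g = sigma2_g, sigma2_e = delta * sigma2_g,
       rll = opt$objective)
}

#' GBLUP: fit on training lines and predict targets through the kinship
#'
#' Mixed-model solution on the training block of K (variance ratio from a
#' restricted-likelihood spectral search unless supplied), with breeding
#' values propagated to target lines via their kinship with the training set:
#' ghat_target = K[target, train] (K[train, train] + delta I)^-1 (y - mu).
#'
#' @param K kinship matrix over all lines (named rows/cols).
#' @param y named training phenotypes.
#' @param training_ids,target_ids line ids (must be in K; training ids in y).
#' @param delta optional fixed variance ratio sigma2_e / sigma2_g.
#' @return list with `predictions` (named, targets), `fitted` (training),
#'   `mu`, `delta`, `sigma2_g`, `sigma2_e`.
#' @export
gblup_fit_predict <- function(K, y, training_ids, target_ids, delta = NULL) {
  miss <- setdiff(c(training_ids, target_ids), rownames(K))
  stop_if(length(miss) > 0,
          "lines absent from kinship: ", paste(utils::head(miss, 5),
                                               collapse = ", "))
  yt <- y[training_ids]
  stop_if(anyNA(yt), "training phenotypes missing for some lines")
  Kt <- K[training_ids, training_ids]
  if (is.null(delta)) {
    if (stats::sd(yt) == 0) {
      ## degenerate: no genetic signal; predictions are the constant mean
      mu <- yt[1]
      pred <- rep(mu, length(target_ids)); names(pred) <- target_ids
      return(list(predictions = pred,
                  fitted = stats::setNames(rep(mu, length(training_ids)),
                                           training_ids),
                  mu = unname(mu), delta = Inf, sigma2_g = 0, sigma2_e = 0))
    }
    est <- reml_delta_kinship(Kt, yt)
    delta <- est$delta
  } else {
    est <- list(sigma2_g = NA_real_, sigma2_e = NA_real_)
  }
  V <- Kt + diag(delta, length(training_ids))
  Vi <- tryCatch(solve(V), error = function(e) {
    warning("singular mixed-model system; ridge jitter applied")
    solve(V + diag(1e-6, nrow(V)))
  })
  one <- rep(1, length(training_ids))
  mu <- as.numeric(crossprod(one, Vi %*% yt) / crossprod(one, Vi %*% one))
  alpha <- Vi %*% (yt - mu)
  pred <- as.numeric(K[target_ids, training_ids, drop = FALSE] %*% alpha) + mu
  names(pred) <- target_ids
  fitted <- as.numeric(Kt %*% alpha) + mu
  names(fitted) <- training_ids
  list(predictions = pred, fitted = fitted, mu = mu, delta = delta,
       sigma2_g = est$sigma2_g, sigma2_e = est$sigma2_e)
}

#' Ridge-regression BLUP of marker effects
#'
#' Solves beta = X' (X X' + delta I)^-1 (y - mu) on the centered training
#' marker matrix, with the variance ratio delta = sigma2_e / sigma2_beta
#' estimated by restricted likelihood on the spectral decomposition of X X'
#' (identical to the GBLUP ratio when K = X X').
#'
#' @param X centered training marker matrix (lines x markers).
#' @param y training phenotypes (one per row of X).
#' @param delta optional fixed variance ratio.
#' @return object of class `gs_model`: intercept, marker effect vector,
#'   delta, variance components.
#' @export
rrblup_fit <- function(X, y, delta = NULL) {
  stop_if(nrow(X) != length(y), "X rows and y length differ")
  stop_if(all(X == 0), "marker matrix has rank 0")
  K <- tcrossprod(X)
  n <- nrow(X)
  if (is.null(delta) && stats::sd(y) == 0) delta <- Inf # constant y
  if (is.null(delta)) {
    est <- reml_delta_kinship(K, y)
    delta <- est$delta
  } else {
    est <- list(sigma2_g = NA_real_, sigma2_e = NA_real_)
  }
  if (is.infinite(delta)) {
    beta <- rep(0, ncol(X))
    mu <- mean(y)
  } else {
    V <- K + diag(delta, n)
    Vi <- solve(V)
    one <- rep(1, n)
    mu <- as.numeric(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
    beta <- as.numeric(crossprod(X, Vi %*% (y - mu)))
  }
  structure(list(intercept = mu, effects = stats::setNames(beta, colnames(X)),
                 delta = delta, sigma2_u = est$sigma2_g,
                 sigma2_e = est$sigma2_e),
            class = "gs_model")
}

#' Predict from a ridge-regression BLUP model
#'
#' @param model a `gs_model` from [rrblup_fit()].
#' @param Xnew centered marker matrix of new lines (same centering as
#'   training).
#' @return named numeric predictions.
#' @export
predict_rrblup <- function(model, Xnew) {
  stop_if(ncol(Xnew) != length(model$effects),
          "marker sets of model and Xnew differ")
  p <- model$intercept + as.numeric(Xnew %*% model$effects)
  names(p) <- rownames(Xnew)
  p
}

#' Build a cross-validation plan
#'
#' `intra_population` / `all_genotypes`: per repetition, a stratified split
#' keeping `n_validation` lines of each population for validation (18/23
#' training at the defaults) with all parents always in training; validation
#' counts per line are balanced greedily so that across repetitions they
#' differ by at most 1. `inter_population`: the deterministic
#' leave-one-population-out splits (parents always in training).
#'
#' @param line_info data.frame with line, population, is_parent.
#' @param scheme `"intra_population"`, `"all_genotypes"` or
#'   `"inter_population"`.
#' @param n_repetitions repetitions for the stratified schemes (default 100).
#' @param n_validation validation lines per population (default 5).
#' @param seed integer seed.
#' @return object of class `cv_plan` with a list of repetitions, each holding
#'   `training` and `validation` line ids.
#' @export
make_cv_plan <- function(line_info,
                         scheme = c("intra_population", "all_genotypes",
                                    "inter_population"),
                         n_repetitions = 100, n_validation = 5, seed = 1) {
  scheme <- match.arg(scheme)
  parents <- line_info$line[line_info$is_parent]
  ril <- line_info[!line_info$is_parent, ]
  pops <- split(ril$line, ril$population)
  reps <- list()
  if (scheme == "inter_population") {
    for (p in names(pops)) {
      reps[[length(reps) + 1]] <- list(
        training = c(unlist(pops[setdiff(names(pops), p)], use.names = FALSE),
                     parents),
        validation = pops[[p]], target_population = p)
    }
  } else {
    stop_if(any(vapply(pops, length, integer(1)) < n_validation),
            "population smaller than the validation split")
    set.seed(as.integer(seed))
    counts <- lapply(pops, function(l) stats::setNames(rep(0L, length(l)), l))
    for (r in seq_len(n_repetitions)) {
      val <- unlist(lapply(names(pops), function(p) {
        cnt <- counts[[p]]
        pick <- names(cnt)[order(cnt, stats::runif(length(cnt)))][
          seq_len(n_validation)]
        counts[[p]][pick] <<- counts[[p]][pick] + 1L
        pick
      }), use.names = FALSE)
      reps[[r]] <- list(training = c(setdiff(ril$line, val), parents),
                        validation = val)
    }
  }
  structure(list(scheme = scheme, repetitions = reps, seed = seed,
                 n_validation = n_validation),
            class = "cv_plan")
}

#' Validation counts per line in a CV plan
#' @param plan a [make_cv_plan()].
#' @return named integer vector.
#' @export
cv_validation_counts <- function(plan) {
  table(unlist(lapply(plan$repetitions, `[[`, "validation")))
}

#' Inter-environment cross-validated genomic prediction
#'
#' For each repetition of the plan, a GBLUP model (equivalently ridge
#' regression on the markers behind the kinship) is trained on the training
#' year's line BLUPs of pea yield in MS and used to predict the validation
#' lines; predictive ability is the Pearson correlation between predicted
#' values and the validation year's observed line means. Intra-population
#' ability correlates within each population and averages across populations
#' and repetitions; all-genotype ability correlates across the pooled
#' validation set per repetition; inter-population ability correlates within
#' each left-out population.
#'
#' @param K kinship matrix over all lines.
#' @param table plot-level trial table with both years.
#' @param plan a [make_cv_plan()].
#' @param train_year,validation_year the two years.
#' @return object of class `prediction_result`: mean `ability`, per-repetition
#'   values, per-line averaged predictions with observed values.
#' @export
run_inter_environment_cv <- function(K, table, plan, train_year,
                                     validation_year) {
  train_blup <- blup_line_values(table, "pea_yield", train_year, "MS")
  y <- stats::setNames(train_blup$blup, train_blup$line)
  obs_df <- line_means(table, "pea_yield", condition = "MS",
                       year = validation_year)
  obs <- stats::setNames(obs_df$mean, obs_df$line)
  pop_of <- stats::setNames(obs_df$population, obs_df$line)
  all_ids <- unique(unlist(lapply(plan$repetitions,
                                  function(r) c(r$training, r$validation))))
  miss <- setdiff(all_ids, intersect(rownames(K), names(y)))
  miss <- union(miss, setdiff(all_ids, names(obs)))
  stop_if(length(miss) > 0, "plan lines absent from genotypes or phenotypes: ",
          paste(utils::head(miss, 5), collapse = ", "))

  pred_sum <- stats::setNames(numeric(length(obs)), names(obs))
  pred_n <- stats::setNames(integer(length(obs)), names(obs))
  per_rep <- numeric(length(plan$repetitions))
  for (i in seq_along(plan$repetitions)) {
    rp <- plan$repetitions[[i]]
    fit <- gblup_fit_predict(K, y, rp$training, rp$validation)
    p <- fit$predictions
    pred_sum[rp$validation] <- pred_sum[rp$validation] + p
    pred_n[rp$validation] <- pred_n[rp$validation] + 1L
    o <- obs[rp$validation]
    if (plan$scheme == "all_genotypes") {
      per_rep[i] <- stats::cor(p, o)
    } else {
      pops <- split(seq_along(p), pop_of[rp$validation])
      rs <- vapply(pops, function(ix) {
        if (stats::sd(p[ix]) == 0 || stats::sd(o[ix]) == 0) return(NA_real_)
        stats::cor(p[ix], o[ix])
      }, numeric(1))
      per_rep[i] <- mean(rs, na.rm = TRUE)
    }
  }
  validated <- pred_n > 0
  per_line <- data.frame(
    line = names(obs)[validated],
    population = pop_of[validated],
    predicted = pred_sum[validated] / pred_n[validated],
    observed = obs[validated],
    n_validated = pred_n[validated], row.names = NULL)
  structure(list(ability = mean(per_rep), per_rep = per_rep,
                 per_line = per_line, scheme = plan$scheme,
                 train_year = train_year,
                 validation_year = validation_year),
            class = "prediction_result")
}

#' First-stage tuning of missing-rate filter thresholds
#'
#' Evaluates each filter configuration by mean intra-population
#' inter-environment predictive ability (averaged over both training years),
#' restricts to configurations that lose no genotype samples, and returns the
#' admissible maximizer (ties resolved toward more retained markers). If
#' every configuration drops lines, the global maximizer is returned with a
#' warning.
#'
#' @param gm_raw unfiltered [genotype_matrix()].
#' @param table plot-level trial table with both years.
#' @param grid list of [filter_config()]s.
#' @param n_repetitions CV repetitions per cell (kept small for tuning).
#' @param seed integer seed.
#' @param knni_k neighbours for imputation.
#' @return list with `config` (selected), `results` (per-cell summary).
#' @export
tune_thresholds <- function(gm_raw, table, grid, n_repetitions = 10,
                            seed = 1, knni_k = 5) {
  stop_if(length(grid) == 0, "empty tuning grid")
  years <- sort(unique(table$year))
  res <- data.frame()
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    fg <- tryCatch(filter_markers_and_genotypes(gm_raw, cfg),
                   error = function(e) NULL)
    if (is.null(fg)) {
      res <- rbind(res, data.frame(cell = i, ability = NA, n_markers = 0,
                                   lines_lost = NA))
      next
    }
    rep_ <- attr(fg, "report")
    ability <- tryCatch({
      imp <- knni_impute(fg, k = knni_k)
      K <- kinship_astle_balding(imp)
      li <- unique(table[, c("line", "population", "is_parent")])
      li <- li[li$line %in% rownames(K), ]
      plan <- make_cv_plan(li, "intra_population", n_repetitions, seed = seed)
      ab <- vapply(seq_along(years), function(j) {
        other <- if (length(years) > 1) years[-j][1] else years[j]
        sub <- table[table$line %in% rownames(K), ]
        run_inter_environment_cv(K, sub, plan, years[j], other)$ability
      }, numeric(1))
      mean(ab)
    }, error = function(e) NA_real_)
    res <- rbind(res, data.frame(cell = i, ability = ability,
                                 n_markers = rep_$n_markers_out,
                                 lines_lost = rep_$genotypes_dropped_missing))
  }
  admissible <- res[!is.na(res$ability) & res$lines_lost == 0, ]
  if (nrow(admissible) == 0) {
    warning("no configuration retains all genotypes; returning global best")
    admissible <- res[!is.na(res$ability), ]
  }
  best <- admissible[order(-admissible$ability, -admissible$n_markers), ][1, ]
  list(config = grid[[best$cell]], results = res, best_cell = best$cell)
}

#' Genomic-selection realized-gain protocol
#'
#' Runs the intra-population stratified CV on the training year, averages
#' each line's genome-enabled breeding value across the repetitions in which
#' it was validated, selects the top `k` lines per population by that value
#' and evaluates the gain over the parent mean in the evaluation year.
#'
#' @param K kinship matrix over all lines.
#' @param table plot-level trial table.
#' @param train_year,evaluation_year the two years.
#' @param k lines selected per population.
#' @param n_repetitions CV repetitions.
#' @param seed integer seed.
#' @return a `gain_report` (see [year_swap_gain()]) with the CV result
#'   attached as attribute `cv`.
#' @export
genomic_gain_protocol <- function(K, table, train_year, evaluation_year,
                                  k = 2, n_repetitions = 100, seed = 1) {
  li <- unique(table[, c("line", "population", "is_parent")])
  li <- li[li$line %in% rownames(K), ]
  plan <- make_cv_plan(li, "intra_population", n_repetitions, seed = seed)
  cv <- run_inter_environment_cv(K, table, plan, train_year, evaluation_year)
  scores <- data.frame(line = cv$per_line$line, score = cv$per_line$predicted)
  gr <- year_swap_gain(table, scores, train_year, evaluation_year,
                       criterion = "genomic", k = k)
  attr(gr, "cv") <- cv
  gr
}
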