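test_that("rrBLUP and GBLUP are the same model", {
  set.seed(12)
  n <- 40; m <- 120
  X <- center_markers(matrix(sample(0:2, n * m, TRUE), n, m,
                             dimnames = list(sprintf("l%d", 1:n),
                                             sprintf("k%d", 1:m))))
  y <- as.numeric(X %*% rnorm(m, 0, 0.2)) + rnorm(n)
  names(y) <- rownames(X)
  train <- rownames(X)[1:30]; valid <- rownames(X)[31:40]
  K <- tcrossprod(X)
  model <- rrblup_fit(X[train, ], y[train])
  pr_rr <- predict_rrblup(model, X[valid, ])
  pr_gb <- gblup_fit_predict(K, y, train, valid, delta = model$delta)
  expect_equal(pr_rr, pr_gb$predictions, tolerance = 1e-8)
  ## and with delta estimated independently on the kinship side
  pr_gb2 <- gblup_fit_predict(K, y, train, valid)
  expect_equal(pr_gb2$delta, model$delta, tolerance = 1e-4)
})

test_that("ridge solution matches closed-form scalar algebra", {
  ## two lines, one centered marker, fixed lambda
  X <- matrix(c(1, -1), 2, 1, dimnames = list(c("a", "b"), "m"))
  y <- c(a = 3, b = 1)
  lam <- 0.5
  model <- rrblup_fit(X, y, delta = lam)
  ## GLS intercept is the plain mean here; beta = x'(xx' + lam I)^-1 (y - mu)
  beta_hand <- as.numeric(t(X) %*% solve(tcrossprod(X) + lam * diag(2),
                                         y - mean(y)))
  expect_equal(unname(model$effects), beta_hand, tolerance = 1e-12)
  expect_equal(model$intercept, 2, tolerance = 1e-10)
})

test_that("degenerate inputs behave as limits", {
  set.seed(13)
  X <- center_markers(matrix(sample(0:2, 20 * 30, TRUE), 20, 30,
                             dimnames = list(sprintf("l%d", 1:20),
                                             sprintf("k%d", 1:30))))
  ## constant y: zero effects, constant predictions
  yc <- rep(2, 20); names(yc) <- rownames(X)
  m0 <- rrblup_fit(X, yc)
  expect_true(all(m0$effects == 0))
  expect_equal(unname(predict_rrblup(m0, X)), rep(2, 20))
  ## huge lambda: predictions shrink to the training mean
  y <- rnorm(20); names(y) <- rownames(X)
  mbig <- rrblup_fit(X, y, delta = 1e10)
  expect_equal(unname(predict_rrblup(mbig, X)), rep(mean(y), 20),
               tolerance = 1e-4)
  ## rank-0 marker matrix
  expect_error(rrblup_fit(matrix(0, 5, 3), rnorm(5)), "rank")
})

test_that("identical kinship profiles give identical predictions", {
  set.seed(14)
  g <- matrix(sample(c(0, 2), 30 * 80, TRUE), 30, 80,
              dimnames = list(sprintf("l%d", 1:30), sprintf("k%d", 1:80)))
  g[30, ] <- g[1, ] # target 30 clones training line 1
  K <- kinship_astle_balding(g)
  y <- rnorm(29); names(y) <- rownames(g)[1:29]
  fit <- gblup_fit_predict(K, y, rownames(g)[1:29], rownames(g)[c(1, 30)])
  expect_equal(unname(fit$predictions[1]), unname(fit$predictions[2]),
               tolerance = 1e-8)
})

test_that("CV plans are stratified, balanced and parent-free", {
  sc <- default_scenario()
  plan <- make_cv_plan(sc$line_info, "intra_population",
                       n_repetitions = 100, seed = 3)
  parents <- sc$line_info$line[sc$line_info$is_parent]
  for (rp in plan$repetitions) {
    expect_length(intersect(rp$training, rp$validation), 0)
    expect_length(intersect(parents, rp$validation), 0)
    expect_true(all(parents %in% rp$training))
    expect_length(rp$validation, 5 * 6)
  }
  ## 100 reps x 5 slots over 23 lines: counts must be 21 or 22
  counts <- cv_validation_counts(plan)
  expect_length(counts, 138)
  expect_true(all(counts %in% c(21L, 22L)))
  ## reproducible under the same seed
  plan2 <- make_cv_plan(sc$line_info, "intra_population",
                        n_repetitions = 100, seed = 3)
  expect_identical(plan, plan2)
  ## inter-population: 6 deterministic splits of 121 training / 23 validation
  ip <- make_cv_plan(sc$line_info, "inter_population")
  expect_length(ip$repetitions, 6)
  for (rp in ip$repetitions) {
    expect_length(rp$training, 121)
    expect_length(rp$validation, 23)
  }
  ## undersized population
  li <- data.frame(line = sprintf("l%d", 1:4), population = "P1",
                   is_parent = FALSE)
  expect_error(make_cv_plan(li, "intra_population"), "smaller")
})

test_that("marker-determined year-stable traits predict near perfectly", {
  ## genetic values fully linear in markers, identical across years,
  ## error-free trials
  cfg <- sim_config(qtl_frac = 1, kin_frac = 0, n_qtl_per_trait = 60,
                    variance_ratios = list(gy = 0, gcy = 0),
                    variance_ratios_morpho = list(gy = 0, gcy = 0),
                    block_cv = 0, n_markers = 300, seed = 17)
  cfg$trait_targets$cve <- 0
  cfg$marker_missing_rate <- 0; cfg$genotype_missing_rate <- 0
  cfg$residual_het_rate <- 0
  sc <- generate_scenario(cfg)
  K <- kinship_astle_balding(sc$geno)
  plan <- make_cv_plan(sc$line_info, "all_genotypes", n_repetitions = 5,
                       seed = 1)
  cv <- suppressWarnings( # error-free data: perfect-fit ANOVA warnings
    run_inter_environment_cv(K, sc$trial, plan, "2018-19", "2019-20"))
  expect_gte(cv$ability, 0.9)
})

test_that("pure-noise phenotypes give near-zero predictive ability", {
  sc <- tiny_scenario()
  K <- kinship_astle_balding(sc$geno_true)
  tab <- sc$trial
  set.seed(19)
  tab$pea_yield <- rnorm(nrow(tab))
  plan <- make_cv_plan(sc$line_info, "all_genotypes", n_repetitions = 50,
                       n_validation = 2, seed = 2)
  cv <- run_inter_environment_cv(K, tab, plan, sc$config$years[1],
                                 sc$config$years[2])
  expect_lt(abs(cv$ability), 0.25)
})

test_that("missing plan lines are reported by id", {
  sc <- tiny_scenario()
  K <- kinship_astle_balding(sc$geno_true)
  plan <- make_cv_plan(sc$line_info, "all_genotypes", n_repetitions = 2,
                       n_validation = 2, seed = 1)
  K2 <- K[rownames(K) != "P1_L01", colnames(K) != "P1_L01"]
  expect_error(run_inter_environment_cv(K2, sc$trial, plan,
                                        sc$config$years[1],
                                        sc$config$years[2]), "P1_L01")
})

test_that("threshold tuning prefers admissible, marker-rich maximizers", {
  sc <- tiny_scenario()
  grid <- list(filter_config(max_missing_per_marker = 0.05,
                             max_missing_per_genotype = 0.5))
  sel <- tune_thresholds(sc$geno, sc$trial, grid, n_repetitions = 3, seed = 1)
  expect_identical(sel$config, grid[[1]]) # single cell is returned
  ## a cell that drops genotypes is excluded when an admissible one exists
  gm <- sc$geno
  gm$geno[1, seq(1, 40)] <- NA # one line with heavy missingness
  grid2 <- list(
    strict = filter_config(max_missing_per_marker = 0.95,
                           max_missing_per_genotype = 0.05),
    lax = filter_config(max_missing_per_marker = 0.95,
                        max_missing_per_genotype = 0.95))
  sel2 <- tune_thresholds(gm, sc$trial, grid2, n_repetitions = 3, seed = 1)
  expect_equal(sel2$best_cell, 2)
})

test_that("genomic gains select the GEBV-top lines per population", {
  sc <- tiny_scenario()
  K <- kinship_astle_balding(sc$geno_true)
  gr <- genomic_gain_protocol(K, sc$trial, sc$config$years[1],
                              sc$config$years[2], k = 2,
                              n_repetitions = 20, seed = 4)
  expect_equal(nrow(gr$selected), 2 * 2) # two populations, two lines each
  cv <- attr(gr, "cv")
  ## brute-force check: selected ids are the top-2 by averaged GEBV
  for (p in unique(cv$per_line$population)) {
    d <- cv$per_line[cv$per_line$population == p, ]
    top <- d$line[order(-d$predicted, d$line)][1:2]
    expect_setequal(gr$selected$line[gr$selected$population == p], top)
  }
})
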