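make_ms_row <- function(pea, cereal) {
  data.frame(year = "Y1", condition = "MS", block = 1, population = "P1",
             line = "L1", is_parent = FALSE, pea_yield = pea,
             cereal_yield = cereal)
}

test_that("mixture traits derive by plain arithmetic", {
  tab <- rbind(make_ms_row(1.2, 4.8), make_ms_row(0, 3), make_ms_row(2, 2),
               make_ms_row(0, 0))
  out <- derive_mixture_traits(tab)
  expect_equal(out$total_yield, c(6, 3, 4, 0))
  expect_equal(out$pea_proportion, c(0.2, 0, 0.5, NA))
})

test_that("the MS/PS ratio doubles MS yield over the PS line mean", {
  tab <- data.frame(
    year = "Y1", condition = c("PS", "PS", "MS", "MS"),
    block = c(1, 2, 1, 2), population = "P1", line = "L1",
    is_parent = FALSE, pea_yield = c(3, 5, 2, 1),
    cereal_yield = c(NA, NA, 4, 4))
  out <- ms_ps_yield_ratio(tab)
  expect_equal(out$ms_ps_ratio, c(NA, NA, 2 * 2 / 4, 2 * 1 / 4))
  ## zero PS mean: ratio missing with warning
  tab0 <- tab
  tab0$pea_yield[tab0$condition == "PS"] <- 0
  expect_warning(out0 <- ms_ps_yield_ratio(tab0), "PS line mean")
  expect_true(all(is.na(out0$ms_ps_ratio)))
})

test_that("line means average the available plots", {
  tab <- toy_trial(n_lines = 3, n_blocks = 3, conditions = "MS")
  tab$pea_yield <- rep(c(1, 2, 3), 3) # line L01=1, L02=2, L03=3 in all blocks
  lm_ <- line_means(tab, "pea_yield", condition = "MS")
  expect_equal(lm_$mean, c(1, 2, 3))
  expect_equal(lm_$n_plots, c(3, 3, 3))
  expect_error(line_means(tab, "pea_yield", condition = "PS"), "no records")
})

test_that("per-environment ANOVA matches the aov oracle", {
  tab <- toy_trial(n_lines = 8, n_blocks = 3, conditions = "MS")
  mine <- anova_trial(tab, "pea_yield", "per_env")
  oracle <- summary(stats::aov(pea_yield ~ factor(block) + factor(line),
                               data = tab))[[1]]
  expect_equal(mine$f[mine$term == "line"], oracle["factor(line)", "F value"],
               tolerance = 1e-10)
  expect_equal(mine$p[mine$term == "line"], oracle["factor(line)", "Pr(>F)"],
               tolerance = 1e-10)
  ## shifting all observations leaves F unchanged
  tab2 <- tab
  tab2$pea_yield <- tab2$pea_yield + 100
  mine2 <- anova_trial(tab2, "pea_yield", "per_env")
  expect_equal(mine$f, mine2$f, tolerance = 1e-8)
})

test_that("split-plot ANOVA tests condition against the main-plot error", {
  tab <- toy_trial(n_lines = 6, n_blocks = 3, conditions = c("MS", "PS"))
  tab$pea_yield <- tab$pea_yield + ifelse(tab$condition == "MS", -2, 0)
  mine <- anova_trial(tab, "pea_yield", "split_plot")
  oracle <- suppressWarnings(summary(stats::aov(
    pea_yield ~ factor(block) + condition * factor(line) +
      Error(factor(block):condition), data = tab)))
  f_oracle <- oracle[["Error: factor(block):condition"]][[1]]["condition",
                                                             "F value"]
  expect_equal(mine$f[mine$term == "condition"], f_oracle, tolerance = 1e-8)
  expect_equal(mine$error_term[mine$term == "condition"], "block:condition")
})

test_that("ANOVA type-I error for the line effect is calibrated", {
  set.seed(99)
  p <- replicate(400, {
    tab <- toy_trial(n_lines = 8, n_blocks = 3, conditions = "MS",
                     sd_g = 0, sd_e = 1, seed = sample.int(1e6, 1))
    a <- anova_trial(tab, "pea_yield", "per_env")
    a$p[a$term == "line"]
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("unbalanced data are refused with a pointer to REML", {
  tab <- toy_trial(n_lines = 5, n_blocks = 3, conditions = "MS")
  tab <- tab[-1, ]
  expect_error(anova_trial(tab, "pea_yield", "per_env"), "REML")
})

test_that("variance components recover construction and truncate at zero", {
  ## noise-free: sigma2_e ~ 0 and sigma2_g equals the planted variance
  lines <- sprintf("L%d", 1:6)
  g <- c(1, 2, 3, 4, 5, 6)
  tab <- expand.grid(line = lines, block = 1:3, stringsAsFactors = FALSE)
  tab$year <- "Y1"; tab$condition <- "MS"; tab$population <- "P1"
  tab$is_parent <- FALSE
  tab$pea_yield <- g[match(tab$line, lines)]
  vc <- suppressWarnings( # perfect fit by construction
    variance_components(tab, "pea_yield", "per_env"))
  expect_equal(vc$sigma2_e, 0, tolerance = 1e-12)
  expect_equal(vc$sigma2_g, stats::var(g), tolerance = 1e-10)
  ## pure noise: negative moment estimates truncated with a flag
  set.seed(42)
  found_trunc <- FALSE
  for (s in 1:20) {
    tabn <- toy_trial(n_lines = 5, n_blocks = 3, conditions = "MS",
                      sd_g = 0, sd_e = 1, seed = s)
    vcn <- variance_components(tabn, "pea_yield", "per_env")
    expect_gte(vcn$sigma2_g, 0)
    if ("sigma2_g" %in% vcn$truncated) found_trunc <- TRUE
  }
  expect_true(found_trunc)
})

test_that("method of moments agrees with lme4 REML on balanced data", {
  tab <- toy_trial(n_lines = 12, n_blocks = 3, conditions = "MS",
                   sd_g = 2, sd_e = 1, seed = 7)
  mom <- variance_components(tab, "pea_yield", "per_env")
  reml <- variance_components_reml(tab, "pea_yield", "per_env")
  expect_equal(mom$sigma2_g, reml$sigma2_g, tolerance = 1e-4)
  expect_equal(mom$sigma2_e, reml$sigma2_e, tolerance = 1e-4)
  ## and on the two-year model of the default scenario
  sc <- default_scenario()
  mom2 <- variance_components(sc$trial, "pea_yield", "across_years",
                              condition = "MS")
  reml2 <- variance_components_reml(sc$trial, "pea_yield", "across_years",
                                    condition = "MS")
  expect_equal(mom2$sigma2_g, reml2$sigma2_g, tolerance = 1e-3)
  expect_equal(mom2$sigma2_gy, reml2$sigma2_gy, tolerance = 1e-3)
})

test_that("heritability formulas reproduce forced arithmetic", {
  ## printed worked example: CVg 46, CVe 51, n = 3 -> 0.71
  expect_equal(round(heritability_from_cv(46, 51, 3), 2), 0.71)
  ## zero error variance -> H2 = 1
  vc <- structure(list(sigma2_g = 2, sigma2_gc = NA, sigma2_gy = NA,
                       sigma2_gcy = NA, sigma2_e = 0, n = 3, y = 1, c = 1,
                       method = "mom", truncated = character(0),
                       anova = NULL), class = "variance_components")
  expect_equal(heritability(vc)$H2, 1)
  ## over-years arithmetic: 1 / (1 + 1/2 + 1/6)
  vc2 <- vc
  vc2$sigma2_g <- 1; vc2$sigma2_gy <- 1; vc2$sigma2_e <- 1
  vc2$y <- 2; vc2$n <- 3
  expect_equal(heritability(vc2, "over-years")$H2, 0.6)
  ## monotone in sigma2_g and in n
  h <- function(sg, n) {
    v <- vc; v$sigma2_g <- sg; v$sigma2_e <- 1; v$n <- n
    heritability(v)$H2
  }
  expect_true(h(2, 3) > h(1, 3))
  expect_true(h(1, 6) > h(1, 3))
  ## degenerate: everything zero
  vc0 <- vc; vc0$sigma2_g <- 0; vc0$sigma2_e <- 0
  expect_error(heritability(vc0), "undefined")
})

test_that("heritability SE approximation matches the printed precision", {
  ## 144 lines x 3 blocks at the printed H2 = 0.71 gives SE ~ 0.04
  se <- (1 - 0.71) * sqrt(2 / 143 + 2 / 286)
  expect_equal(round(se, 2), 0.04)
})

test_that("BLUPs shrink line means toward the grand mean", {
  sc <- tiny_scenario()
  b <- blup_line_values(sc$trial, "pea_yield", sc$config$years[1], "MS")
  h2 <- attr(b, "H2")
  mu <- mean(b$mean)
  expect_equal(b$blup, mu + h2 * (b$mean - mu))
  ## shrinkage preserves ranking
  expect_equal(order(b$blup), order(b$mean))
  ## forced arithmetic mu = 1, mean = 2, H2 = 0.7 -> 1.7
  expect_equal(1 + 0.7 * (2 - 1), 1.7)
})
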