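test_that("phenotypic correlation handles forced and hand-computed cases", {
  expect_equal(phenotypic_correlation(1:5, 1:5)$r, 1)
  expect_equal(phenotypic_correlation(1:5, -(1:5))$r, -1)
  expect_equal(phenotypic_correlation(c(1, 2, 3), c(1, 2, 4))$r,
               0.981981, tolerance = 1e-5)
  expect_true(is.na(phenotypic_correlation(c(1, 1, 1), 1:3)$r))
  expect_error(phenotypic_correlation(1:2, 1:2), "3")
})

## builds a two-condition, one-year table with exact per-line values
exact_two_condition_table <- function(a, b, n_blocks = 2) {
  lines <- sprintf("L%d", seq_along(a))
  out <- expand.grid(line = lines, block = seq_len(n_blocks),
                     condition = c("MS", "PS"), stringsAsFactors = FALSE)
  out$year <- "Y1"; out$population <- "P1"; out$is_parent <- FALSE
  out$pea_yield <- ifelse(out$condition == "MS", a[match(out$line, lines)],
                          b[match(out$line, lines)])
  out
}

test_that("cross-condition genetic correlation matches hand computation", {
  ## error-free: cov = 2, varA = varB = 2.5 -> r_g = 0.8
  tab <- exact_two_condition_table(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  rg <- suppressWarnings( # zero-error toy: perfect-fit ANOVA warnings
    genetic_correlation_cross_condition(tab, "pea_yield", "MS",
                                        "pea_yield", "PS", "Y1"))
  expect_equal(rg$r, 0.8, tolerance = 1e-10)
  ## identical genetic values, zero error -> 1
  tab2 <- exact_two_condition_table(1:5, 1:5)
  rg2 <- suppressWarnings(
    genetic_correlation_cross_condition(tab2, "pea_yield", "MS",
                                        "pea_yield", "PS", "Y1"))
  expect_equal(rg2$r, 1, tolerance = 1e-10)
  ## with zero error it coincides with the phenotypic correlation of means
  mA <- line_means(tab, "pea_yield", "MS", "Y1")$mean
  mB <- line_means(tab, "pea_yield", "PS", "Y1")$mean
  expect_equal(rg$r, phenotypic_correlation(mA, mB)$r, tolerance = 1e-10)
})

test_that("cross-condition estimator is invariant to affine rescaling", {
  sc <- tiny_scenario()
  yr <- sc$config$years[1]
  r1 <- genetic_correlation_cross_condition(sc$trial, "pea_yield", "MS",
                                            "pea_yield", "PS", yr)$r
  tab <- sc$trial
  tab$pea_yield <- 3 * tab$pea_yield + 10
  r2 <- genetic_correlation_cross_condition(tab, "pea_yield", "MS",
                                            "pea_yield", "PS", yr)$r
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("cross-condition recovery approaches the configured correlation", {
  ## replicate single-year datasets at the study scale
  rg <- vapply(1:30, function(s) {
    sc <- generate_scenario(sim_config(years = "2018-19", n_markers = 150,
                                       seed = 3000 + s))
    genetic_correlation_cross_condition(sc$trial, "pea_yield", "MS",
                                        "pea_yield", "PS", "2018-19")$r
  }, numeric(1))
  expect_lt(abs(mean(rg) - 0.42), 0.05)
})

test_that("cross-year genetic correlation follows the component ratio", {
  vc <- structure(list(sigma2_g = 1.8, sigma2_gc = NA, sigma2_gy = 0.7,
                       sigma2_gcy = NA, sigma2_e = 1, n = 3, y = 2, c = 1,
                       method = "mom", truncated = character(0),
                       anova = NULL), class = "variance_components")
  expect_equal(genetic_correlation_cross_year(vc)$r, 1.8 / 2.5)
  vc$sigma2_gy <- 0
  expect_equal(genetic_correlation_cross_year(vc)$r, 1)
  vc$sigma2_g <- 0; vc$sigma2_gy <- 0.5
  expect_equal(genetic_correlation_cross_year(vc)$r, 0)
  vc$sigma2_gy <- 0
  expect_true(is.na(genetic_correlation_cross_year(vc)$r))
})

test_that("u test reproduces Fisher-z arithmetic and is antisymmetric", {
  eq <- dagnelie_u_test(0.5, 50, 0.5, 50)
  expect_equal(eq$u, 0)
  expect_equal(eq$p, 1)
  ## the height-at-flowering comparison scale: r 0.55 vs 0.12, n = 144
  ht <- dagnelie_u_test(0.55, 144, 0.12, 144)
  expect_equal(ht$u, 4.18, tolerance = 0.01)
  expect_lt(ht$p, 0.01)
  sw <- dagnelie_u_test(0.12, 144, 0.55, 144)
  expect_equal(sw$u, -ht$u)
  expect_error(dagnelie_u_test(0.5, 3, 0.5, 50), "n > 3")
  expect_error(dagnelie_u_test(1, 50, 0.5, 50), "infinite")
})

test_that("correlation matrices carry the NS/*/** significance codes", {
  set.seed(8)
  d <- data.frame(a = rnorm(100))
  d$b <- d$a + rnorm(100, 0, 0.5)  # strong
  d$c <- rnorm(100)                # null
  cm <- correlation_matrix(d)
  expect_equal(cm$sig["a", "b"], "**")
  expect_true(cm$sig["a", "c"] %in% c("NS", "*"))
})
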