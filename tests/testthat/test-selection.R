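test_that("index evaluation is the printed linear equation", {
  ix <- printed_index()
  expect_equal(index_score(ix, c(height_flowering = 0, pea_yield = 0,
                                 onset_flowering = 0)), -1.413)
  ## 60 cm, 5 t/ha, 20 dd
  expect_equal(index_score(ix, c(height_flowering = 60, pea_yield = 5,
                                 onset_flowering = 20)),
               -1.413 + 0.0184 * 60 + 0.0962 * 5 + 0.0476 * 20,
               tolerance = 1e-12)
  expect_equal(index_score(ix, c(height_flowering = 60, pea_yield = 5,
                                 onset_flowering = 20)), 1.124,
               tolerance = 1e-3)
  ## linearity: doubling a weight doubles that contribution
  ix2 <- ix
  ix2$weights["pea_yield"] <- 2 * ix$weights["pea_yield"]
  x <- c(height_flowering = 10, pea_yield = 4, onset_flowering = 7)
  expect_equal(index_score(ix2, x) - index_score(ix, x),
               0.0962 * 4, tolerance = 1e-12)
  expect_error(index_score(ix, c(pea_yield = 1)), "missing")
})

test_that("stepwise entry honours both thresholds", {
  ## construct a candidate that is significant but adds ~1.5% R2
  set.seed(21)
  n <- 400
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- x1 + 0.13 * x2 + rnorm(n, 0, 0.5)
  d <- data.frame(x1 = x1, x2 = x2)
  fit_full <- summary(lm(y ~ x1 + x2))
  fit_base <- summary(lm(y ~ x1))
  dr2 <- fit_full$r.squared - fit_base$r.squared
  p2 <- coef(fit_full)["x2", 4]
  ## by construction: significant yet below the 2% R2 gate
  expect_lt(p2, 0.05)
  expect_lt(dr2, 0.02)
  ix <- fit_selection_index(y, d)
  expect_false("x2" %in% names(ix$weights))
  expect_true("x1" %in% names(ix$weights))
})

test_that("pure-noise candidates are rarely admitted", {
  set.seed(31)
  hits <- replicate(200, {
    n <- 120
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    noise <- rnorm(n)
    y <- 0.8 * x1 + 0.6 * x2 + 0.5 * x3 + rnorm(n, 0, 0.8)
    ix <- fit_selection_index(y, data.frame(x1, x2, x3, noise))
    "noise" %in% names(ix$weights)
  })
  expect_lte(mean(hits), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 200))
})

test_that("no qualifying trait yields an empty index with diagnostics", {
  set.seed(41)
  y <- rnorm(50)
  ix <- fit_selection_index(y, data.frame(a = rnorm(50), b = rnorm(50)))
  expect_length(ix$weights, 0)
  expect_equal(ix$r2, 0)
  expect_equal(index_score(ix, data.frame(a = 1, b = 2)), ix$intercept)
})

test_that("collinear candidates are refused", {
  set.seed(51)
  x <- rnorm(50)
  expect_error(
    fit_selection_index(rnorm(50), data.frame(a = x, b = x + rnorm(50, 0, 0.01))),
    "collinear")
})

test_that("Falconer efficiencies reproduce printed component arithmetic", {
  ## index rows of the two trial years
  expect_equal(round(predicted_efficiency_heritability(0.91, 0.62, 0.72)$E_R),
               87)
  expect_equal(round(predicted_efficiency_heritability(0.80, 0.71, 0.90)$E_R),
               96)
  ## the self-comparison is 100%
  expect_equal(predicted_efficiency_heritability(0.7, 0.7, 1)$E_R, 100)
  expect_error(predicted_efficiency_heritability(0.5, 0, 0.5), "positive")
  ## monotone in r_g and in the indirect heritability
  expect_gt(predicted_efficiency_heritability(0.7, 0.6, 0.9)$E_R,
            predicted_efficiency_heritability(0.7, 0.6, 0.5)$E_R)
  expect_gt(predicted_efficiency_heritability(0.9, 0.6, 0.5)$E_R,
            predicted_efficiency_heritability(0.5, 0.6, 0.5)$E_R)
})

test_that("correlation-based efficiency averages then divides", {
  expect_equal(round(predicted_efficiency_correlation(
    c(0.175, 0.321), c(0.475, 0.475))$E_R), 52)
  expect_equal(predicted_efficiency_correlation(0.3, 0.6)$E_R, 50)
  expect_equal(predicted_efficiency_correlation(c(0.4, 0.6), c(0.4, 0.6))$E_R,
               100)
  expect_error(predicted_efficiency_correlation(0.3, 0), "undefined")
})

test_that("year-swap selection gains match hand computation", {
  lines <- c("L1", "L2", "L3", "L4", "PAR1", "PAR2")
  tab <- expand.grid(line = lines, block = 1:2, year = c("YA", "YB"),
                     stringsAsFactors = FALSE)
  tab$condition <- "MS"
  tab$population <- ifelse(grepl("PAR", tab$line), "parent", "P1")
  tab$is_parent <- grepl("PAR", tab$line)
  yb <- c(L1 = 1, L2 = 2, L3 = 3, L4 = 4, PAR1 = 1.5, PAR2 = 2.5)
  ya <- c(L1 = 1, L2 = 2, L3 = 4, L4 = 5, PAR1 = 2, PAR2 = 2)
  tab$pea_yield <- ifelse(tab$year == "YB", yb[tab$line], ya[tab$line])
  scores <- data.frame(line = names(ya), score = unname(ya))
  gr <- year_swap_gain(tab, scores, "YA", "YB", k = 2)
  ## top-2 by year-A score are L4, L3; their year-B mean is 3.5; parents 2.0
  expect_equal(sort(gr$selected$line), c("L3", "L4"))
  expect_equal(gr$gain, 3.5 - 2.0)
  ## oracle selection on the evaluation year itself is maximal
  oracle <- year_swap_gain(tab, data.frame(line = names(yb),
                                           score = unname(yb)), "YB", "YB",
                           k = 2)
  expect_gte(oracle$gain, gr$gain)
  expect_error(year_swap_gain(tab, scores, "YA", "YB", k = 5), "exceeds")
})

test_that("gain-based efficiency uses per-year integers then half-up mean", {
  er <- relative_efficiency_from_gains(c(0.271, 0.282), c(0.476, 0.397))
  expect_equal(er$per_year, c(57, 71))
  expect_equal(er$E_R, 64)
  expect_equal(relative_efficiency_from_gains(c(1, 1), c(1, 1))$E_R, 100)
  expect_error(relative_efficiency_from_gains(0.3, 0), "undefined")
})

test_that("per-unit-time scaling multiplies by the cycle ratio", {
  expect_equal(per_unit_time_adjustment(88, 2)$E_R, 176)
  expect_equal(per_unit_time_adjustment(112, 2)$E_R, 224)
  expect_equal(per_unit_time_adjustment(88, 1)$E_R, 88)
  expect_error(per_unit_time_adjustment(88, 0), "positive")
})
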