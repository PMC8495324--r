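## Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

## small two-population configuration for fast structural tests
tiny_config <- function(seed = 11, n_markers = 60, ...) {
  sim_config(n_populations = 2, lines_per_population = 6, n_parents = 4,
             cross_design = list(c(1, 2), c(3, 4)),
             parent_names = c("PA", "PB", "PC", "PD"),
             n_chromosomes = 3, n_markers = n_markers, seed = seed, ...)
}

tiny_scenario <- function() memo("tiny", generate_scenario(tiny_config()))

## the full-size default scenario (144 lines, 1,000 markers, two years)
default_scenario <- function() memo("default",
                                    generate_scenario(sim_config(seed = 1)))

## default scenario taken through filtering/imputation/kinship once
default_kinship <- function() {
  memo("kinship", {
    sc <- default_scenario()
    gm <- knni_impute(filter_markers_and_genotypes(sc$geno))
    kinship_astle_balding(gm)
  })
}

## the published selection-index equation, as a model object
printed_index <- function() {
  structure(list(intercept = -1.413,
                 weights = c(height_flowering = 0.0184, pea_yield = 0.0962,
                             onset_flowering = 0.0476),
                 entry = NULL, r2 = NA), class = "selection_index_model")
}

## balanced toy trial table with known cell values
toy_trial <- function(n_lines = 6, n_blocks = 3, years = "Y1",
                      conditions = c("MS", "PS"), sd_g = 1, sd_e = 0.5,
                      seed = 5) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_lines))
  g <- stats::rnorm(n_lines, 0, sd_g)
  out <- expand.grid(line = lines, block = seq_len(n_blocks),
                     year = years, condition = conditions,
                     stringsAsFactors = FALSE)
  out$population <- "P1"
  out$is_parent <- FALSE
  out$pea_yield <- 5 + g[match(out$line, lines)] +
    stats::rnorm(nrow(out), 0, sd_e)
  out
}
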