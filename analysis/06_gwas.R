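#!/usr/bin/env Rscript

## Stage 6 -- GWAS for pea yield in MS and in PS on line values averaged
## across years, with the RIL-population incidence matrix as covariate,
## genomic control and Bonferroni thresholds. Writes Manhattan-ready tables.

suppressPackageStartupMessages(library(peaMixSel))
dir.create("results", showWarnings = FALSE)

sc <- generate_scenario(sim_config(seed = 1))
trial <- sc$trial

gm <- knni_impute(filter_markers_and_genotypes(sc$geno))
li <- sc$line_info[sc$line_info$line %in% rownames(gm$geno), ]
pops <- li$population[match(rownames(gm$geno), li$line)]

for (cond in c("MS", "PS")) {
  lm_ <- line_means(trial, "pea_yield", condition = cond)
  ph <- setNames(lm_$mean, lm_$line)[rownames(gm$geno)]
  res <- gwas_scan(gm, ph, pops)
  tab <- manhattan_table(res)
  f <- sprintf("results/gwas_%s.tsv", tolower(cond))
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  n_sig <- sum(tab$p_gc < res$p_threshold, na.rm = TRUE)
  top <- tab[which.max(tab$score), ]
  cat(sprintf(
    "%s yield: %d markers, lambda_GC = %.2f, Bonferroni score threshold %.2f;\n",
    cond, res$m, res$lambda_gc, res$score_threshold))
  cat(sprintf(
    "  %d markers exceed the threshold; top signal %s (chr %d, score %.2f).\n",
    n_sig, top$marker, top$chrom, top$score))
}
cat("With a polygenic simulated architecture, single markers rarely clear the\n")
cat("Bonferroni line -- the same qualitative picture as the field GWAS.\n")
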