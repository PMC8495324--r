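toy_gm <- function(values, map = NULL) {
  genotype_matrix(values, map)
}

test_that("012 text round-trips losslessly", {
  sc <- tiny_scenario()
  path <- withr::local_tempfile(fileext = ".012")
  map_path <- withr::local_tempfile(fileext = ".tsv")
  write_geno_012(sc$geno, path, map_path)
  back <- read_genotypes(path, "012", map_path)
  expect_equal(back$geno, sc$geno$geno)
  expect_equal(back$map$marker, sc$geno$map$marker)
})

test_that("VCF genotypes map to alternate-allele dosages", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tsnp2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0\t1/1",
    "chr1\t300\tindel1\tC\tTA\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1",
    "chr2\t50\tsnp3\tG\tA\t.\tPASS\t.\tGT\t1|1\t0|0\t0|1")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  gm <- read_genotypes(path, "vcf")
  expect_equal(unname(gm$geno[, "snp1"]), c(0, 1, 2))
  expect_true(is.na(gm$geno["S1", "snp2"]))
  expect_equal(unname(gm$geno[, "snp3"]), c(2, 0, 1))
  expect_false("indel1" %in% colnames(gm$geno)) # indel skipped
  expect_equal(attr(gm, "skipped"), 1)
  expect_equal(gm$map$chrom, c(1, 1, 2))
})

test_that("the value domain is enforced", {
  m <- matrix(c(0, 3, 1, 2), 2, 2,
              dimnames = list(c("a", "b"), c("m1", "m2")))
  expect_error(genotype_matrix(m), "0, 1, 2")
})

test_that("filters apply the four rules in order", {
  ## marker with MAF 0.04 among 25 lines: 1 alt hom in 25 -> p = 0.04
  g <- matrix(0, 25, 3,
              dimnames = list(sprintf("l%d", 1:25), c("low_maf", "ok", "het")))
  g[1, "low_maf"] <- 2
  g[1:12, "ok"] <- 2
  g[, "het"] <- 1 # 100% heterozygous calls
  out <- filter_markers_and_genotypes(toy_gm(g))
  expect_equal(colnames(out$geno), "ok")
  rep_ <- attr(out, "report")
  expect_equal(rep_$markers_dropped_het, 1)
  expect_equal(rep_$markers_dropped_maf, 1)
})

test_that("filtering matches a brute-force oracle on an enumerable toy", {
  set.seed(77)
  n <- 10; m <- 10
  g <- matrix(sample(c(0L, 1L, 2L), n * m, TRUE, prob = c(0.45, 0.1, 0.45)),
              n, m, dimnames = list(sprintf("l%d", 1:n), sprintf("k%d", 1:m)))
  g[sample(length(g), 18)] <- NA
  cfg <- filter_config(maf_min = 0.1, max_missing_per_marker = 0.2,
                       max_missing_per_genotype = 0.3, max_het_ratio = 0.5)
  ## independent brute-force application of the four rules
  km <- colMeans(is.na(g)) <= 0.2
  g1 <- g[, km, drop = FALSE]
  kl <- rowMeans(is.na(g1)) <= 0.3
  g2 <- g1[kl, , drop = FALSE]
  kh <- apply(g2, 2, function(x) mean(x[!is.na(x)] == 1) <= 0.5)
  g3 <- g2[, kh, drop = FALSE]
  p <- colMeans(g3, na.rm = TRUE) / 2
  g4 <- g3[, pmin(p, 1 - p) > 0.1, drop = FALSE]
  out <- filter_markers_and_genotypes(toy_gm(g), cfg)
  expect_identical(out$geno, g4)
  ## idempotence: refiltering removes nothing
  again <- filter_markers_and_genotypes(out, cfg)
  expect_identical(again$geno, out$geno)
})

test_that("KNNI leaves observed entries alone and uses nearest donors", {
  g <- rbind(
    A = c(0, 2, 2, NA),
    B = c(0, 2, 2, 2),
    C = c(2, 0, 0, 0))
  colnames(g) <- sprintf("m%d", 1:4)
  out <- knni_impute(toy_gm(g), k = 1)
  expect_equal(out$geno["A", "m4"], 2) # B is the identical neighbour
  expect_equal(out$geno[!is.na(g)], g[!is.na(g)]) # observed untouched
  ## complete input is returned unchanged
  gm_full <- toy_gm(g[2:3, ])
  expect_identical(knni_impute(gm_full, k = 1), gm_full)
  ## all-missing marker is an error
  g2 <- g; g2[, 4] <- NA
  expect_error(knni_impute(toy_gm(g2)), "no observed")
  ## oversized k is clipped with a warning
  expect_warning(knni_impute(toy_gm(g), k = 10), "clipped")
})

test_that("KNNI beats the marginal-mean baseline on masked data", {
  sc <- tiny_scenario()
  g <- sc$geno_true
  set.seed(9)
  mask <- sample(length(g), round(0.05 * length(g)))
  gm_masked <- g
  gm_masked[mask] <- NA
  ## guard: no marker entirely masked
  keep <- colSums(!is.na(gm_masked)) > 0
  gm_masked <- gm_masked[, keep]
  gtrue <- g[, keep]
  imp <- knni_impute(genotype_matrix(gm_masked), k = 5)
  miss <- is.na(gm_masked)
  err_knni <- mean((imp$geno[miss] - gtrue[miss])^2)
  colmean <- matrix(rep(colMeans(gm_masked, na.rm = TRUE),
                        each = nrow(gm_masked)), nrow(gm_masked))
  err_base <- mean((colmean[miss] - gtrue[miss])^2)
  expect_lt(err_knni, err_base)
})

test_that("Astle-Balding kinship has the expected structure", {
  ## fully inbred lines at p = 0.5: diagonal entries are 2
  set.seed(10)
  g <- matrix(0L, 40, 100,
              dimnames = list(sprintf("l%d", 1:40), sprintf("m%d", 1:100)))
  for (j in 1:100) g[sample(40, 20), j] <- 2L
  K <- kinship_astle_balding(g)
  expect_equal(unname(mean(diag(K))), 2, tolerance = 1e-10)
  ## identical lines have identical rows; off-diagonal equals diagonal
  g2 <- rbind(g, l41 = g[1, ])
  K2 <- kinship_astle_balding(g2)
  expect_equal(K2["l1", "l41"], K2["l1", "l1"], tolerance = 1e-10)
  ## symmetric PSD
  expect_true(isSymmetric(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  ## invariant to marker order
  K3 <- kinship_astle_balding(g[, sample(100)])
  expect_equal(K3, K, tolerance = 1e-12, ignore_attr = TRUE)
  ## monomorphic-only input is an error
  expect_error(kinship_astle_balding(matrix(2, 3, 4,
    dimnames = list(letters[1:3], letters[4:7]))), "monomorphic")
})
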