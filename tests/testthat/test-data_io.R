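test_that("dosage TSV round-trips bitwise and MAF is recomputed from dosages", {
  g <- tiny_genotypes(matrix(c(0, 2, 1, 0.25), nrow = 2),
                      effect = c("A", "C"), other = c("G", "T"),
                      r2 = c(0.9, NA))
  expect_equal(g$variants$maf, c(0.5, min(0.3125, 1 - 0.3125)))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_matrix(g, f)
  g2 <- read_dosage_matrix(f)
  expect_identical(g2$dosages, g$dosages)
  expect_equal(g2$variants, g$variants)

  # larger generated fixture round-trips bitwise too
  gg <- simulate_genotypes(sim_scenario(n_genes = 1, snps_per_gene = 3,
                                        seed = 21), n = 5)
  write_dosage_matrix(gg, f)
  expect_identical(read_dosage_matrix(f)$dosages, gg$dosages)
})

test_that("out-of-range dosages are clipped with a logged count", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\teffect_allele\tother_allele\timputation_r2\ts1\ts2",
               "v1\tA\tG\t0.8\t2.04\t1.0"), f)
  expect_message(g <- read_dosage_matrix(f), "clipped 1")
  expect_equal(unname(g$dosages[, "v1"]), c(2.0, 1.0))
  expect_equal(attr(g, "n_clipped"), 1L)
})

test_that("malformed headers and duplicate variant ids are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant\tallele\ts1", "v1\tA\t1"), f)
  expect_error(read_dosage_matrix(f), "line 1")
  writeLines(c("variant_id\teffect_allele\tother_allele\timputation_r2\ts1",
               "v1\tA\tG\t0.8\t1", "v1\tA\tG\t0.8\t0"), f)
  expect_error(read_dosage_matrix(f), "duplicate variant id")
})

test_that("VCF dosages are read through the DS genotype field", {
  skip_if_not_installed("vcfR")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT:DS\t0/1:1.1\t1/1:1.9",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT:DS\t0/0:0.2\t0/1:0.8"), f)
  g <- read_dosage_matrix(f)
  expect_equal(dim(g), c(2L, 2L))
  expect_equal(unname(g$dosages["sampA", ]), c(1.1, 0.2))
  expect_equal(g$variants$effect_allele, c("G", "T"))
})

test_that("tiered QC keeps/removes variants per the MAF-matched cutoff", {
  # dosage columns engineered to hit each MAF tier
  n <- 10000
  set.seed(4)
  mk <- function(maf) rbinom(n, 2, maf)
  d <- cbind(mk(0.02), mk(0.007), mk(0.0003), mk(0.2), mk(0.2))
  g <- tiny_genotypes(d, effect = rep("A", 5), other = rep("G", 5),
                      r2 = c(0.4, 0.45, 1.0, 0.2, NA))
  kept <- apply_variant_qc(g)
  ids <- kept$variants$variant_id
  expect_true("v1" %in% ids)    # maf > 1%, r2 0.4 > 0.3
  expect_false("v2" %in% ids)   # 0.5% < maf < 1%, r2 0.45 < 0.5
  expect_true("v3" %in% ids)    # rare, r2 1.0 > 0.99
  expect_false("v4" %in% ids)   # common but r2 0.2 < 0.3
  expect_true("v5" %in% ids)    # typed variant (no r2) always kept
})

test_that("QC is idempotent and monotone in the tier cutoffs", {
  set.seed(8)
  g <- simulate_genotypes(sim_scenario(n_genes = 2, snps_per_gene = 10,
                                       maf_range = c(0.01, 0.5), seed = 8),
                          n = 400)
  once <- apply_variant_qc(g)
  twice <- apply_variant_qc(once)
  expect_identical(twice$dosages, once$dosages)
  for (r2a in c(0.3, 0.6, 0.9)) {
    t1 <- qc_thresholds(min_r2 = c(r2a, max(r2a, 0.5), 0.99))
    t2 <- qc_thresholds(min_r2 = c(r2a + 0.05, max(r2a + 0.05, 0.5), 0.99))
    k1 <- apply_variant_qc(g, t1)$variants$variant_id
    k2 <- apply_variant_qc(g, t2)$variants$variant_id
    expect_true(all(k2 %in% k1))
  }
})

test_that("HWE exact filter removes gross heterozygote excess only", {
  n <- 600
  set.seed(9)
  ok <- rbinom(n, 1, 0.3) + rbinom(n, 1, 0.3)  # in HWE
  bad <- rep(1, n)                             # all heterozygous
  g <- tiny_genotypes(cbind(ok, bad), effect = c("A", "C"),
                      other = c("G", "T"))
  kept <- hwe_filter(g, controls = rep(TRUE, n))
  expect_identical(kept$variants$variant_id, "v1")
})

test_that("phenotype loading converts BMI, applies the 18.5 exclusion and names missing columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = c("a", "b", "c"), outcome = c(1, 0, 1),
                   bmi = c(27.5, 17.9, 30), diabetes = c(0, 1, 1),
                   sex = c("male", "female", "male"), age = c(60, 55, 70),
                   study = "s1", pc1 = c(0.1, -0.2, 0))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)

  cb <- quietly(read_phenotypes(f, exposure = "bmi"))
  expect_equal(cb$exposure, c(27.5, 30) / 5)   # per 5 kg/m2
  expect_equal(nrow(cb), 2L)                   # BMI 17.9 excluded
  expect_equal(attr(cb, "n_excluded_bmi"), 1L)

  cd <- quietly(read_phenotypes(f, exposure = "diabetes"))
  expect_equal(nrow(cd), 3L)                   # binary passthrough, no exclusion
  expect_equal(cd$exposure, c(0, 1, 1))

  df$outcome <- NULL
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(f, exposure = "bmi"), "outcome")
})

test_that("results tables round-trip to full precision including scientific notation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  one <- data.frame(gene = "gene001", stratum = "male", n_snps = 5L,
                    r2 = 0.105, p_fixed = 3.15e-05, p_random = 0.125,
                    p_adaptive = 3.15e-05, q_value = 0.04,
                    significant = TRUE, stringsAsFactors = FALSE)
  write_results(one, f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  expect_match(lines[2L], "3.15e-05", fixed = TRUE)
  expect_equal(read_results(f), one)

  set.seed(11)
  many <- data.frame(gene = sprintf("g%03d", 1:100),
                     stratum = sample(c("male", "female"), 100, TRUE),
                     n_snps = sample.int(90, 100, TRUE),
                     r2 = runif(100), p_fixed = 10^-runif(100, 0, 250),
                     p_random = runif(100), p_adaptive = runif(100),
                     q_value = runif(100), stringsAsFactors = FALSE)
  many$significant <- many$q_value < 0.2
  write_results(many, f)
  back <- read_results(f)
  for (cc in c("r2", "p_fixed", "p_random", "p_adaptive", "q_value")) {
    expect_true(all(abs(back[[cc]] - many[[cc]]) <=
                      1e-12 * pmax(abs(many[[cc]]), 1e-300)))
  }
  expect_identical(back$gene, many$gene)
  expect_identical(back$significant, many$significant)
  expect_error(write_results(many[0, ], f), "empty")
})
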