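test_that("allele harmonization handles swaps, strand flips and ambiguity", {
  g <- tiny_genotypes(matrix(c(0, 1, 2, 2, 1, 0, 1, 1, 1), nrow = 3),
                      effect = c("G", "A", "T"), other = c("A", "T", "C"))
  # v1 swapped (weight says A/G), v2 ambiguous A/T mismatched, v3 strand flip
  w <- weight_set("gene", data.frame(
    variant_id = c("v1", "v2", "v3", "v9"),
    effect_allele = c("A", "T", "A", "C"), other_allele = c("G", "A", "G", "T"),
    weight = c(0.3, 0.5, 0.2, 0.7), stringsAsFactors = FALSE))
  h <- harmonize_alleles(w, g)
  expect_equal(h$variants$variant_id, c("v1", "v3"))
  expect_equal(h$variants$weight, c(-0.3, 0.2))       # swap negates
  expect_equal(h$variants$flipped, c(TRUE, FALSE))    # orientation recorded
  expect_equal(attr(h, "n_dropped_absent"), 1L)       # v9 not in dosages
  expect_equal(attr(h, "n_dropped_ambiguous"), 1L)    # v2 A/T unresolvable
})

test_that("harmonization is the identity for matching coding and involutive under double swap", {
  g <- tiny_genotypes(matrix(runif(8, 0, 2), nrow = 4),
                      effect = c("A", "C"), other = c("G", "T"))
  w <- weight_set("gene", data.frame(variant_id = c("v1", "v2"),
                                     effect_allele = c("A", "C"),
                                     other_allele = c("G", "T"),
                                     weight = c(0.4, -0.1)))
  h <- harmonize_alleles(w, g)
  expect_equal(h$variants$weight, w$variants$weight)
  expect_false(any(h$variants$flipped))

  swap_once <- weight_set("gene", within(w$variants, {
    tmp <- effect_allele; effect_allele <- other_allele; other_allele <- tmp
    weight <- -weight; rm(tmp)
  }))
  swap_twice <- weight_set("gene", within(swap_once$variants, {
    tmp <- effect_allele; effect_allele <- other_allele; other_allele <- tmp
    weight <- -weight; rm(tmp)
  }))
  expect_equal(swap_twice$variants$weight, w$variants$weight)
  expect_equal(swap_twice$variants$effect_allele, w$variants$effect_allele)
})

test_that("predicted expression is the harmonized weighted dosage sum", {
  # zero weights annihilate; identity dot product recovers the dosage
  g <- tiny_genotypes(matrix(c(2, 0, 1), nrow = 3), "A", "G")
  w0 <- weight_set("z", data.frame(variant_id = "v1", effect_allele = "A",
                                   other_allele = "G", weight = 0))
  expect_equal(predict_expression(w0, g)$values, c(0, 0, 0))
  w1 <- weight_set("i", data.frame(variant_id = "v1", effect_allele = "A",
                                   other_allele = "G", weight = 1))
  expect_equal(predict_expression(w1, g)$values, c(2, 0, 1))

  # brute-force per-sample dot-product oracle on 5 random eQTLs
  set.seed(14)
  d <- matrix(runif(40, 0, 2), nrow = 8)
  g5 <- tiny_genotypes(d, effect = rep("A", 5), other = rep("G", 5))
  wts <- rnorm(5)
  w5 <- weight_set("g5", data.frame(variant_id = paste0("v", 1:5),
                                    effect_allele = "A", other_allele = "G",
                                    weight = wts))
  manual <- vapply(1:8, function(i) sum(wts * d[i, ]), numeric(1))
  expect_equal(predict_expression(w5, g5)$values, manual)
})

test_that("prediction is linear in the weights and counts dropped eQTLs", {
  set.seed(15)
  d <- matrix(runif(30, 0, 2), nrow = 6)
  g <- tiny_genotypes(d, effect = rep("A", 5), other = rep("G", 5))
  mk <- function(w) weight_set("g", data.frame(variant_id = paste0("v", 1:5),
                                               effect_allele = "A",
                                               other_allele = "G", weight = w))
  w1 <- rnorm(5); w2 <- rnorm(5)
  expect_equal(predict_expression(mk(w1 + w2), g)$values,
               predict_expression(mk(w1), g)$values +
                 predict_expression(mk(w2), g)$values)

  w_extra <- weight_set("g", data.frame(variant_id = c("v1", "v8"),
                                        effect_allele = "A",
                                        other_allele = "G",
                                        weight = c(1, 1)))
  px <- predict_expression(w_extra, g)
  expect_equal(px$n_snps_used, 1L)
  expect_equal(px$n_snps_dropped, 1L)
})

test_that("a gene with no usable eQTL raises a classed unpredictable-gene error", {
  g <- tiny_genotypes(matrix(1, 2, 1), "A", "G")
  w <- weight_set("gone", data.frame(variant_id = "nope", effect_allele = "A",
                                     other_allele = "G", weight = 1))
  expect_error(predict_expression(w, g), class = "gxe_unpredictable_gene")
})

test_that("the heritability filter keeps R2 >= 0.01 with a closed boundary", {
  mk <- function(id, r2) weight_set(id, data.frame(variant_id = "v1",
                                                   effect_allele = "A",
                                                   other_allele = "G",
                                                   weight = 1),
                                    predictive_r2 = r2)
  ws <- list(a = mk("a", 0.105), b = mk("b", 0.0099), c = mk("c", 0.01),
             d = mk("d", 0.5))
  kept <- filter_genes_by_heritability(ws)
  expect_identical(names(kept), c("a", "c", "d"))  # stable order, >= boundary
  expect_identical(names(filter_genes_by_heritability(ws, r2_min = 0.2)), "d")
})

test_that("interaction p-values are invariant to allele-coding flips and weight rescaling", {
  scen <- one_gene_scenario(seed = 33, n = 600, snps = 6)
  sim <- simulate_cohort(scen)
  base <- misti(sim$weight_sets[[1L]], sim$genotypes, sim$cohort)

  # flip the dosage coding of two non-strand-ambiguous variants
  # (d -> 2 - d, swap allele labels)
  g2 <- sim$genotypes
  ambiguous <- with(g2$variants,
                    chartr("ACGT", "TGCA", effect_allele) == other_allele)
  flip <- which(!ambiguous &
                  g2$variants$variant_id %in%
                    sim$weight_sets[[1L]]$variants$variant_id)[1:2]
  g2$dosages[, flip] <- 2 - g2$dosages[, flip]
  tmp <- g2$variants$effect_allele[flip]
  g2$variants$effect_allele[flip] <- g2$variants$other_allele[flip]
  g2$variants$other_allele[flip] <- tmp
  flipped <- misti(sim$weight_sets[[1L]], g2, sim$cohort)
  # invariance holds up to IRLS convergence noise in the refit
  expect_equal(flipped$p_fixed, base$p_fixed, tolerance = 1e-6)
  expect_equal(flipped$p_random, base$p_random, tolerance = 0.01)
  expect_equal(flipped$p_adaptive, base$p_adaptive, tolerance = 0.01)

  # rescaling every weight leaves the fixed-component p unchanged
  w2 <- sim$weight_sets[[1L]]
  w2$variants$weight <- 3.7 * w2$variants$weight
  scaled <- misti(w2, sim$genotypes, sim$cohort)
  expect_equal(scaled$p_fixed, base$p_fixed, tolerance = 1e-8)
})
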