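# small in-code fixtures shared across test files

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

# genotype matrix built by hand from a dosage matrix and allele pairs
tiny_genotypes <- function(dosages, effect, other, r2 = NA_real_) {
  dosages <- as.matrix(dosages)
  genotype_matrix(dosages,
                  data.frame(variant_id = paste0("v", seq_len(ncol(dosages))),
                             effect_allele = effect, other_allele = other,
                             imputation_r2 = rep_len(r2, ncol(dosages)),
                             stringsAsFactors = FALSE))
}

# cohort table assembled directly from vectors (raw BMI scale)
tiny_cohort <- function(outcome, bmi = NULL, diabetes = NULL, sex = NULL,
                        exposure = "bmi", n_pcs = 0, seed = 1) {
  n <- length(outcome)
  set.seed(seed)
  df <- data.frame(sample_id = paste0("s", seq_len(n)), outcome = outcome,
                   bmi = if (is.null(bmi)) runif(n, 20, 35) else bmi,
                   diabetes = if (is.null(diabetes)) rbinom(n, 1, 0.1) else diabetes,
                   sex = if (is.null(sex)) rep(c("male", "female"), length.out = n) else sex,
                   age = rnorm(n, 60, 8),
                   study = rep("study1", n), stringsAsFactors = FALSE)
  if (n_pcs > 0) for (k in seq_len(n_pcs)) df[[paste0("pc", k)]] <- rnorm(n)
  quietly(cohort_table(df, exposure = exposure))
}

# one-gene scenario used by most statistical tests; sparsity raised so small
# eQTL sets rarely prune to nothing
one_gene_scenario <- function(seed, n = 1000, snps = 10,
                              weight_sparsity = 0.6, ...) {
  sim_scenario(n_cases = n / 2, n_controls = n / 2, n_genes = 1,
               snps_per_gene = snps, seed = seed,
               weight_sparsity = weight_sparsity, ...)
}

# fit one simulated gene and return its misti object
fit_one <- function(scen) {
  sim <- simulate_cohort(scen)
  misti(sim$weight_sets[[1L]], sim$genotypes, sim$cohort)
}

# independent step-up BH oracle used against the packaged implementation
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
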