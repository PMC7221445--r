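#' Define a simulation scenario
#'
#' Generative parameters for the synthetic multi-study case-control cohort:
#' LD-correlated genotypes, sparse elastic-net-like eQTL weight sets,
#' exposures (BMI on its raw kg/m2 scale, truncated at 18.5; diabetes with
#' BMI-dependent risk), and a retrospective case-control sample from a
#' population whose disease logit contains the exposure main effect
#' (`beta_E`), a predicted-expression main effect (`beta_g`), a burden-type
#' interaction `tau * xhat * E` and dispersed per-SNP interactions with
#' log-OR variance `theta` -- the generative counterparts of the fixed and
#' random test components. Interaction effects attach to the single gene
#' `causal_gene`; all other genes are null.
#'
#' @param n_cases,n_controls sampled case/control counts.
#' @param n_genes,snps_per_gene gene-set dimensions.
#' @param maf_range uniform range for per-variant minor allele frequency.
#' @param ld_rho AR-1 latent LD correlation in `[0, 1)`.
#' @param weight_sparsity fraction of SNPs with nonzero eQTL weight.
#' @param weight_sd standard deviation of nonzero weights.
#' @param expr_noise_var residual expression variance used when computing
#'   each gene's predictive R2.
#' @param beta_E exposure main-effect log-OR per exposure unit.
#' @param beta_g predicted-expression main-effect log-OR.
#' @param tau burden interaction log-OR per unit `xhat * E`.
#' @param theta variance of per-SNP residual interaction log-ORs.
#' @param prevalence target population disease prevalence in `(0, 0.5)`.
#' @param n_studies,n_pcs number of study strata / principal components.
#' @param sex_effect include a male main effect on risk.
#' @param exposure `"bmi"` or `"diabetes"`: the analysis exposure that also
#'   receives the generative interaction terms.
#' @param causal_gene index of the gene carrying `tau`/`theta`.
#' @param snp_interaction_lors optional vector of fixed per-SNP interaction
#'   log-ORs for the causal gene (length `snps_per_gene`), overriding the
#'   Gaussian `theta` draw; use to place the interaction on known SNPs.
#' @param diabetes_bmi_slope log-odds of diabetes per kg/m2 of BMI, coupling
#'   the two exposures.
#' @param seed RNG seed (`NULL` = use the current RNG state).
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_cases = 1000, n_controls = 1000, n_genes = 50,
                         snps_per_gene = 30, maf_range = c(0.05, 0.5),
                         ld_rho = 0.5, weight_sparsity = 0.3,
                         weight_sd = 0.15, expr_noise_var = 1,
                         beta_E = log(1.25), beta_g = log(1.1),
                         tau = 0, theta = 0, prevalence = 0.1,
                         n_studies = 3, n_pcs = 3, sex_effect = TRUE,
                         exposure = c("bmi", "diabetes"), causal_gene = 1,
                         snp_interaction_lors = NULL,
                         diabetes_bmi_slope = 0.1, seed = NULL) {
  exposure <- match.arg(exposure)
  if (!is.null(snp_interaction_lors)) {
    stopifnot(length(snp_interaction_lors) == snps_per_gene)
  }
  stopifnot(n_cases > 0, n_controls > 0, n_genes >= 1, snps_per_gene >= 1,
            prevalence > 0, prevalence < 0.5,
            ld_rho >= 0, ld_rho < 1,
            maf_range[1] > 0.005, maf_range[2] <= 0.5,
            weight_sparsity > 0, weight_sparsity <= 1,
            theta >= 0, causal_gene >= 1, causal_gene <= n_genes)
  structure(as.list(environment()), class = "sim_scenario")
}

# AR-1 latent-Gaussian haplotypes thresholded at each variant's MAF
.sim_haplotypes <- function(n, maf, rho) {
  m <- length(maf)
  z <- matrix(stats::rnorm(n * m), n, m)
  if (m > 1L && rho > 0) {
    for (j in 2:m) z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
  }
  thr <- stats::qnorm(maf)
  (z < rep(thr, each = n)) * 1
}

.sim_genotypes <- function(s, n) {
  blocks <- vector("list", s$n_genes)
  meta <- vector("list", s$n_genes)
  alleles <- c("A", "C", "G", "T")
  for (g in seq_len(s$n_genes)) {
    maf <- stats::runif(s$snps_per_gene, s$maf_range[1], s$maf_range[2])
    pair <- t(replicate(s$snps_per_gene, sample(alleles, 2L)))
    r2 <- stats::runif(s$snps_per_gene, 0.3, 1)
    d <- .sim_haplotypes(n, maf, s$ld_rho) + .sim_haplotypes(n, maf, s$ld_rho)
    blocks[[g]] <- d
    meta[[g]] <- structure(data.frame(
      variant_id = sprintf("gene%03d_snp%02d", g, seq_len(s$snps_per_gene)),
      effect_allele = pair[, 1L], other_allele = pair[, 2L],
      imputation_r2 = r2, stringsAsFactors = FALSE), nominal_maf = maf)
  }
  out <- genotype_matrix(do.call(cbind, blocks), do.call(rbind, meta),
                         sample_ids = sprintf("id%06d", seq_len(n)))
  attr(out, "nominal_maf") <- unlist(lapply(meta, attr, "nominal_maf"),
                                     use.names = FALSE)
  out
}

#' Simulate LD-correlated genotype dosages
#'
#' Per gene, two haplotypes are drawn from a latent Gaussian AR-1 process
#' with correlation `ld_rho` and thresholded at each variant's MAF; the
#' dosage is their sum. Imputation R2 values are drawn uniformly on
#' (0.3, 1].
#'
#' @param s a [sim_scenario()].
#' @param n number of samples (default `n_cases + n_controls`).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(s, n = s$n_cases + s$n_controls) {
  stopifnot(inherits(s, "sim_scenario"))
  if (!is.null(s$seed)) set.seed(s$seed)
  .sim_genotypes(s, n)
}

.sim_weight_set <- function(s, dosages, gene_id) {
  m <- ncol(dosages)
  nz <- stats::rbinom(m, 1L, s$weight_sparsity) == 1L
  if (!any(nz)) nz <- stats::rbinom(m, 1L, s$weight_sparsity) == 1L  # one retry
  if (!any(nz)) stop("all weights pruned for ", gene_id,
                     "; increase weight_sparsity")
  w <- rep(0, m)
  w[nz] <- stats::rnorm(sum(nz), 0, s$weight_sd)
  gv <- drop(dosages[, nz, drop = FALSE] %*% w[nz])
  r2 <- stats::var(gv) / (stats::var(gv) + s$expr_noise_var)
  weight_set(gene_id,
             data.frame(variant_id = colnames(dosages)[nz],
                        effect_allele = NA_character_,
                        other_allele = NA_character_,
                        weight = w[nz], stringsAsFactors = FALSE),
             predictive_r2 = r2)
}

#' Simulate a sparse eQTL weight set for one gene
#'
#' A `weight_sparsity` fraction of the gene's variants receive Gaussian
#' weights (the rest are pruned, emulating elastic-net selection), and the
#' predictive R2 is set to the empirical variance fraction
#' `Var(Gw) / (Var(Gw) + expr_noise_var)`.
#'
#' @param s a [sim_scenario()].
#' @param g a [genotype_matrix()] holding the gene's variants.
#' @param gene_id label for the resulting set.
#' @return A [weight_set()] whose alleles are copied from `g`.
#' @export
simulate_weight_set <- function(s, g, gene_id = "gene001") {
  stopifnot(inherits(s, "sim_scenario"), inherits(g, "genotype_matrix"))
  if (!is.null(s$seed)) set.seed(s$seed + 1L)
  ws <- .sim_weight_set(s, g$dosages, gene_id)
  idx <- match(ws$variants$variant_id, g$variants$variant_id)
  ws$variants$effect_allele <- g$variants$effect_allele[idx]
  ws$variants$other_allele <- g$variants$other_allele[idx]
  ws
}

#' Simulate a multi-study case-control cohort
#'
#' Draws a population with covariates (age, sex, study with study-specific
#' intercepts, PCs), exposures (truncated-normal BMI; diabetes with
#' BMI-dependent risk), genotypes and weight sets; forms the disease logit
#' with main effects plus the scenario's interaction terms on the causal
#' gene; calibrates the intercept by bisection so the population prevalence
#' matches the target; then samples the requested case and control counts
#' retrospectively.
#'
#' @param s a [sim_scenario()].
#' @return List with `genotypes` (sampled individuals), `cohort`
#'   (`cohort_table` with the scenario exposure), `weight_sets`,
#'   `population_prevalence` (realized, pre-sampling), `alpha0` (calibrated
#'   intercept) and `scenario`.
#' @export
simulate_cohort <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  if (!is.null(s$seed)) set.seed(s$seed)
  N <- ceiling(1.3 * max(s$n_cases / s$prevalence,
                         s$n_controls / (1 - s$prevalence)))
  g <- .sim_genotypes(s, N)
  gene_ids <- sprintf("gene%03d", seq_len(s$n_genes))
  ws <- lapply(seq_len(s$n_genes), function(k) {
    cols <- (k - 1L) * s$snps_per_gene + seq_len(s$snps_per_gene)
    w <- .sim_weight_set(s, g$dosages[, cols, drop = FALSE], gene_ids[k])
    idx <- match(w$variants$variant_id, g$variants$variant_id)
    w$variants$effect_allele <- g$variants$effect_allele[idx]
    w$variants$other_allele <- g$variants$other_allele[idx]
    w
  })
  names(ws) <- gene_ids

  age <- stats::rnorm(N, 60, 8)
  sex <- ifelse(stats::runif(N) < 0.5, "male", "female")
  study <- sprintf("study%d", sample.int(s$n_studies, N, replace = TRUE))
  pcs <- matrix(stats::rnorm(N * s$n_pcs), N, s$n_pcs,
                dimnames = list(NULL, paste0("pc", seq_len(s$n_pcs))))
  # BMI truncated below 18.5 kg/m2 (inverse-CDF sampling of the tail)
  mu_b <- 27; sd_b <- 4.5
  u <- stats::runif(N, stats::pnorm((18.5 - mu_b) / sd_b), 1)
  bmi <- mu_b + sd_b * stats::qnorm(u)
  diabetes <- stats::rbinom(N, 1L,
                            stats::plogis(-2.2 + s$diabetes_bmi_slope * (bmi - 27)))
  E <- if (s$exposure == "bmi") bmi / 5 else diabetes

  cg_cols <- (s$causal_gene - 1L) * s$snps_per_gene + seq_len(s$snps_per_gene)
  wcg <- ws[[s$causal_gene]]
  xhat <- drop(g$dosages[, wcg$variants$variant_id, drop = FALSE] %*%
                 wcg$variants$weight)
  study_eff <- seq(-0.2, 0.2, length.out = s$n_studies)
  eta <- study_eff[as.integer(factor(study))] + 0.01 * (age - 60) +
    (if (s$sex_effect) 0.2 * (sex == "male") else 0) +
    drop(pcs %*% rep(0.05, s$n_pcs)) +
    s$beta_E * E + s$beta_g * xhat + s$tau * xhat * E
  if (!is.null(s$snp_interaction_lors)) {
    eta <- eta + drop(g$dosages[, cg_cols, drop = FALSE] %*%
                        s$snp_interaction_lors) * E
  } else if (s$theta > 0) {
    u_j <- stats::rnorm(s$snps_per_gene, 0, sqrt(s$theta))
    eta <- eta + drop(g$dosages[, cg_cols, drop = FALSE] %*% u_j) * E
  }
  f <- function(a) mean(stats::plogis(a + eta)) - s$prevalence
  if (f(-30) > 0 || f(10) < 0) stop("prevalence calibration failed to bracket")
  alpha0 <- stats::uniroot(f, c(-30, 10), tol = 1e-10)$root
  y <- stats::rbinom(N, 1L, stats::plogis(alpha0 + eta))
  cases <- which(y == 1L); controls <- which(y == 0L)
  if (length(cases) < s$n_cases || length(controls) < s$n_controls) {
    stop("population produced too few cases or controls; ",
         "retry with another seed or larger prevalence")
  }
  idx <- c(sample(cases, s$n_cases), sample(controls, s$n_controls))
  df <- data.frame(sample_id = sprintf("id%06d", idx), outcome = y[idx],
                   bmi = bmi[idx], diabetes = diabetes[idx], sex = sex[idx],
                   age = age[idx], study = study[idx],
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(pcs[idx, , drop = FALSE]))
  cohort <- suppressMessages(cohort_table(df, exposure = s$exposure))
  list(genotypes = subset_genotypes(g, samples = idx), cohort = cohort,
       weight_sets = ws, population_prevalence = mean(y), alpha0 = alpha0,
       scenario = s)
}

#' Write a complete synthetic fixture bundle
#'
#' Simulates a cohort and writes the dosage TSV, the weight and gene-level
#' TSVs, the phenotype TSV, and a JSON manifest holding the scenario (seed
#' included). The files load cleanly through the package readers, and the
#' same scenario/seed reproduces a byte-identical bundle.
#'
#' @param s a [sim_scenario()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_fixture_bundle <- function(s, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(s)
  paths <- c(dosages = file.path(dir, "dosages.tsv"),
             weights = file.path(dir, "weights.tsv"),
             genes = file.path(dir, "genes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_dosage_matrix(sim$genotypes, paths[["dosages"]])
  write_weights(sim$weight_sets, paths[["weights"]], paths[["genes"]])
  write_phenotypes(as.data.frame(sim$cohort), paths[["phenotypes"]])
  manifest <- c(sim$scenario[setdiff(names(sim$scenario), "")],
                list(generator = "gxescan::write_fixture_bundle"))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}
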