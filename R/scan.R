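#' Exposure analysis specification
#'
#' Records how an exposure is analyzed: BMI scans are stratified by sex
#' (BMI-disease associations differ between men and women), diabetes scans
#' pool the sexes and adjust for sex as a covariate. The two handling modes
#' are mutually exclusive.
#'
#' @param name `"bmi"` or `"diabetes"`.
#' @param stratify_by_sex run separate male/female scans (default TRUE for
#'   BMI).
#' @param adjust_sex include sex as a covariate in a pooled scan (default
#'   TRUE for diabetes).
#' @param covariates adjustment covariates (NULL = age, study, PCs).
#' @return An `exposure_spec` list.
#' @export
exposure_spec <- function(name = c("bmi", "diabetes"),
                          stratify_by_sex = identical(name, "bmi"),
                          adjust_sex = identical(name, "diabetes"),
                          covariates = NULL) {
  name <- match.arg(name)
  if (stratify_by_sex && adjust_sex) {
    stop("`stratify_by_sex` and `adjust_sex` are mutually exclusive")
  }
  structure(list(name = name, stratify_by_sex = stratify_by_sex,
                 adjust_sex = adjust_sex, covariates = covariates),
            class = "exposure_spec")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: the i-th smallest p-value gets
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1, mapped back to input
#' order.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Genome-wide set-based interaction scan
#'
#' Runs [misti()] for every gene surviving the heritability filter, within
#' the strata dictated by the exposure specification (male and female
#' separately for BMI; one sex-adjusted pooled stratum for diabetes), and
#' applies Benjamini-Hochberg FDR control within each exposure-by-stratum
#' scan. Genes that cannot be tested in a stratum (no usable eQTL,
#' separation, non-convergence) are skipped and the reasons recorded in the
#' `skipped` attribute; a stratum without both cases and controls is skipped
#' with a warning.
#'
#' @param weight_sets named list of [weight_set()] objects.
#' @param genotypes a [genotype_matrix()] aligned with `cohort` rows.
#' @param cohort a `cohort_table` whose exposure matches `spec$name`.
#' @param spec an [exposure_spec()].
#' @param r2_min heritability inclusion threshold (default 0.01).
#' @param fdr FDR significance threshold (default 0.2).
#' @param combiner component combiner passed to [misti()].
#' @return A `misti_scan` data.frame with one row per gene-by-stratum:
#'   `gene, stratum, n_snps, r2, p_fixed, p_random, p_adaptive, q_value,
#'   significant`, ordered by gene id then stratum.
#' @export
run_scan <- function(weight_sets, genotypes, cohort, spec = exposure_spec("bmi"),
                     r2_min = 0.01, fdr = 0.2,
                     combiner = c("adaptive_grid", "fisher")) {
  combiner <- match.arg(combiner)
  stopifnot(inherits(spec, "exposure_spec"))
  if (!identical(attr(cohort, "exposure_name"), spec$name)) {
    stop("cohort exposure is '", attr(cohort, "exposure_name"),
         "' but the scan spec asks for '", spec$name, "'")
  }
  ws <- filter_genes_by_heritability(weight_sets, r2_min)
  if (length(ws) == 0L) stop("no gene passes the heritability filter")
  strata <- if (spec$stratify_by_sex) c("male", "female") else "pooled"
  rows <- list()
  skipped <- list()
  for (st in strata) {
    idx <- if (st == "pooled") seq_len(nrow(cohort)) else which(cohort$sex == st)
    sub_c <- cohort[idx, , drop = FALSE]
    attributes(sub_c)[c("exposure_name", "pc_cols", "class")] <-
      attributes(cohort)[c("exposure_name", "pc_cols", "class")]
    if (length(unique(sub_c$outcome)) < 2L) {
      warning("stratum '", st, "' lacks cases or controls; skipped")
      next
    }
    sub_g <- subset_genotypes(genotypes, samples = idx)
    res <- list()
    for (w in ws) {
      m <- tryCatch(
        misti(w, sub_g, sub_c, covariates = spec$covariates,
              adjust_sex = spec$adjust_sex, combiner = combiner,
              stratum = st),
        error = function(e) e)
      if (inherits(m, "error")) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(gene = w$gene_id, stratum = st,
                     reason = conditionMessage(m))
        next
      }
      res[[length(res) + 1L]] <-
        data.frame(gene = m$gene_id, stratum = st, n_snps = m$n_snps,
                   r2 = m$predictive_r2, p_fixed = m$p_fixed,
                   p_random = m$p_random, p_adaptive = m$p_adaptive,
                   stringsAsFactors = FALSE)
    }
    if (length(res) == 0L) next
    tab <- do.call(rbind, res)
    tab$q_value <- bh_fdr(tab$p_adaptive)  # FDR within exposure x stratum
    tab$significant <- tab$q_value < fdr
    rows[[st]] <- tab
  }
  if (length(rows) == 0L) stop("no stratum produced results")
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$stratum), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, exposure = spec$name, fdr = fdr, combiner = combiner,
            skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
            class = c("misti_scan", "data.frame"))
}

#' @export
print.misti_scan <- function(x, top = 10L, ...) {
  cat("GxE interaction scan: exposure =", attr(x, "exposure"),
      "| genes x strata =", nrow(x),
      "| significant at FDR <", attr(x, "fdr"), ":", sum(x$significant), "\n")
  ord <- order(x$p_adaptive)
  print.data.frame(utils::head(as.data.frame(x)[ord, ], top), digits = 4,
                   row.names = FALSE)
  sk <- attr(x, "skipped")
  if (!is.null(sk)) cat("skipped:", nrow(sk), "gene-stratum fit(s)\n")
  invisible(x)
}

#' QQ plot of the adaptive scan p-values
#'
#' @param x a `misti_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.misti_scan <- function(x, ...) {
  p <- sort(x$p_adaptive)
  n <- length(p)
  exp_q <- -log10((seq_len(n) - 0.5) / n)
  graphics::plot(exp_q, -log10(p), xlab = "expected -log10(p)",
                 ylab = "observed -log10(p)",
                 main = paste0("QQ: p_adaptive (", attr(x, "exposure"), ")"),
                 ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

#' Pooled logistic main effect of the exposure
#'
#' Multivariable-adjusted logistic regression of case-control status on the
#' exposure, reporting the odds ratio per exposure unit (per 5 kg/m2 for
#' BMI, diabetes vs not) with its Wald 95 percent confidence interval.
#'
#' @param cohort a `cohort_table`.
#' @param spec an [exposure_spec()]; sex is included as a covariate when
#'   `spec$adjust_sex` is set.
#' @return List with `or`, `ci_lower`, `ci_upper`, `p_value`, `n`.
#' @export
estimate_exposure_main_effect <- function(cohort, spec = exposure_spec("bmi")) {
  y <- cohort$outcome
  if (length(unique(y)) < 2L) stop("need at least one case and one control")
  E <- cohort$exposure
  if (stats::var(E) == 0) stop("exposure is constant; effect not estimable")
  X <- .design_matrix(cohort, spec$covariates, spec$adjust_sex)
  X <- cbind(X, E = E)
  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100L))
  if (!fit$converged) stop("logistic fit did not converge")
  beta <- fit$coefficients
  if (.separated(beta, X)) stop("apparent complete separation")
  # Wald standard error from the inverse information
  w <- fit$fitted.values * (1 - fit$fitted.values)
  V <- solve(crossprod(X, X * w))
  se <- sqrt(V["E", "E"])
  b <- beta[["E"]]
  list(or = exp(b),
       ci_lower = exp(b - stats::qnorm(0.975) * se),
       ci_upper = exp(b + stats::qnorm(0.975) * se),
       p_value = 2 * stats::pnorm(-abs(b / se)),
       n = length(y))
}
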