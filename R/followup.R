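#' Sequential conditional SNP-by-exposure selection
#'
#' Forward search for the individual eQTLs driving a gene-level interaction.
#' At each step every not-yet-selected eQTL is added (main effect plus
#' SNP-by-exposure product) to a logistic model already containing the
#' covariates, the exposure and all previously selected SNPs with their
#' interaction terms; the candidate with the smallest Wald p-value for its
#' interaction term is selected if that p-value is below `alpha`, and the
#' search stops otherwise. Ties on the minimum p go to the smaller variant
#' index (position in the harmonized eQTL set). Candidates whose model fails
#' to fit are skipped and logged. The procedure terminates after at most m
#' steps (m = number of eQTLs).
#'
#' @param weights a [weight_set()] for the flagged gene.
#' @param genotypes a [genotype_matrix()] aligned with `cohort`.
#' @param cohort a `cohort_table`.
#' @param spec an [exposure_spec()] (sex adjustment and covariates).
#' @param alpha selection threshold on the conditional interaction p-value
#'   (default 0.05).
#' @return A `sequential_report`: gene id, a data.frame `selected` with one
#'   row per selected SNP (`variant_id`, `p_value`, `or` for the
#'   interaction term, in selection order), the `stop_reason`, and any
#'   skipped candidates.
#' @export
sequential_snp_selection <- function(weights, genotypes, cohort,
                                     spec = exposure_spec("bmi"),
                                     alpha = 0.05) {
  stopifnot(alpha >= 0, alpha <= 1)
  hw <- harmonize_alleles(weights, genotypes)
  v <- hw$variants
  if (nrow(v) == 0L) stop("no usable eQTL for gene ", weights$gene_id)
  D <- genotypes$dosages[, v$variant_id, drop = FALSE]
  y <- cohort$outcome
  E <- cohort$exposure
  X0 <- .design_matrix(cohort, spec$covariates, spec$adjust_sex)
  X0 <- cbind(X0, E = E)

  selected <- integer(0)
  sel_rows <- list()
  skipped <- character(0)
  stop_reason <- NULL
  m <- ncol(D)
  for (step in seq_len(m)) {
    remaining <- setdiff(seq_len(m), selected)
    if (length(remaining) == 0L) {
      stop_reason <- "all eQTLs selected"
      break
    }
    Xsel <- X0
    if (length(selected)) {
      Xsel <- cbind(Xsel, D[, selected, drop = FALSE],
                    D[, selected, drop = FALSE] * E)
    }
    cand_p <- rep(NA_real_, length(remaining))
    cand_or <- rep(NA_real_, length(remaining))
    for (k in seq_along(remaining)) {
      j <- remaining[k]
      Xc <- cbind(Xsel, g = D[, j], gE = D[, j] * E)
      wald <- tryCatch(.wald_last(Xc, y), error = function(e) NULL)
      if (is.null(wald)) {
        skipped <- c(skipped, v$variant_id[j])
        next
      }
      cand_p[k] <- wald$p
      cand_or[k] <- wald$or
    }
    if (all(is.na(cand_p))) {
      stop_reason <- "no candidate model converged"
      break
    }
    best <- which(cand_p == min(cand_p, na.rm = TRUE))[1L]  # tie: lowest index
    if (is.na(cand_p[best]) || cand_p[best] >= alpha) {
      stop_reason <- "no candidate below alpha"
      break
    }
    j <- remaining[best]
    selected <- c(selected, j)
    sel_rows[[length(sel_rows) + 1L]] <-
      data.frame(variant_id = v$variant_id[j], p_value = cand_p[best],
                 or = cand_or[best], stringsAsFactors = FALSE)
  }
  if (is.null(stop_reason)) stop_reason <- "all eQTLs selected"
  structure(list(gene_id = weights$gene_id,
                 selected = if (length(sel_rows)) do.call(rbind, sel_rows)
                            else data.frame(variant_id = character(0),
                                            p_value = numeric(0),
                                            or = numeric(0)),
                 stop_reason = stop_reason, skipped = skipped,
                 alpha = alpha),
            class = "sequential_report")
}

# Wald test (p and OR) for the last column of a logistic design
.wald_last <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank deficient")
  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100L))
  if (!fit$converged || .separated(fit$coefficients, X)) stop("unstable fit")
  w <- fit$fitted.values * (1 - fit$fitted.values)
  V <- solve(crossprod(X, X * w))
  j <- ncol(X)
  b <- fit$coefficients[j]
  se <- sqrt(V[j, j])
  list(p = 2 * stats::pnorm(-abs(b / se)), or = exp(b), se = se)
}

#' @export
print.sequential_report <- function(x, ...) {
  cat("Sequential conditional SNP x E selection for", x$gene_id,
      "(alpha =", x$alpha, ")\n")
  if (nrow(x$selected)) {
    print.data.frame(x$selected, digits = 4, row.names = TRUE)
  } else {
    cat("  no SNP selected\n")
  }
  cat("  stop reason:", x$stop_reason, "\n")
  if (length(x$skipped)) cat("  skipped candidates:",
                             paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Predicted-expression association stratified by exposure
#'
#' Association between a gene's predicted expression and disease within
#' exposure strata: BMI quartiles (cut-points computed from controls, which
#' approximate the source population in a case-control design) or the two
#' diabetes groups. Within each stratum, a covariate-adjusted logistic
#' model gives the OR per unit predicted expression with its Wald 95
#' percent CI. Strata without both cases and controls are omitted with a
#' warning; a constant predicted expression is a degenerate-input error.
#'
#' @param xhat a `predicted_expression` (or numeric vector aligned with
#'   `cohort`).
#' @param cohort a `cohort_table` with raw `bmi` and `diabetes` columns.
#' @param strata `"bmi_quartiles"` or `"diabetes"`.
#' @param spec an [exposure_spec()] supplying covariates/sex adjustment.
#' @return data.frame with one row per stratum: `stratum`, `or`,
#'   `ci_lower`, `ci_upper`, `p_value`, `n`.
#' @export
stratified_expression_association <- function(xhat, cohort,
                                              strata = c("bmi_quartiles",
                                                         "diabetes"),
                                              spec = exposure_spec("bmi")) {
  strata <- match.arg(strata)
  xv <- if (inherits(xhat, "predicted_expression")) xhat$values else xhat
  stopifnot(length(xv) == nrow(cohort))
  if (stats::var(xv) == 0) stop("predicted expression is constant")
  if (strata == "bmi_quartiles") {
    cuts <- stats::quantile(cohort$bmi[cohort$outcome == 0],
                            probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
    grp <- cut(cohort$bmi, breaks = c(-Inf, cuts, Inf),
               labels = paste0("Q", 1:4))
  } else {
    grp <- factor(ifelse(cohort$diabetes == 1, "diabetes", "no_diabetes"),
                  levels = c("no_diabetes", "diabetes"))
  }
  out <- list()
  for (lev in levels(grp)) {
    idx <- which(grp == lev)
    y <- cohort$outcome[idx]
    if (length(idx) == 0L || length(unique(y)) < 2L) {
      warning("stratum '", lev, "' lacks cases or controls; omitted")
      next
    }
    sub_c <- cohort[idx, , drop = FALSE]
    attributes(sub_c)[c("exposure_name", "pc_cols", "class")] <-
      attributes(cohort)[c("exposure_name", "pc_cols", "class")]
    if (stats::var(xv[idx]) == 0) stop("predicted expression constant in stratum ", lev)
    X <- .design_matrix(sub_c, spec$covariates, spec$adjust_sex)
    X <- cbind(X, xhat = xv[idx])
    wald <- .wald_last(X, y)
    out[[length(out) + 1L]] <-
      data.frame(stratum = lev, or = wald$or,
                 ci_lower = exp(log(wald$or) - stats::qnorm(0.975) * wald$se),
                 ci_upper = exp(log(wald$or) + stats::qnorm(0.975) * wald$se),
                 p_value = wald$p, n = length(idx),
                 stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no stratum could be analyzed")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
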