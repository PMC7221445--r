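#' Fit the null logistic model for the interaction score tests
#'
#' Logistic regression of case-control status on the adjustment covariates,
#' the exposure main effect and the predicted-expression main effect
#' (optionally plus the predicted-expression-by-exposure term, the substrate
#' of the conditional variance-component test). Fitting is IRLS via
#' `stats::glm.fit`; convergence is verified on the score vector at the
#' optimum.
#'
#' @param cohort a `cohort_table` (see [read_phenotypes()]).
#' @param xhat a `predicted_expression` or numeric vector (one per row of
#'   `cohort`); may be NULL to omit the expression main effect.
#' @param include_fixed_interaction also include the x-hat-by-exposure
#'   product as a fixed column.
#' @param covariates character vector of covariate columns in `cohort`;
#'   `"study"` enters as factor indicators (collinear levels are an error,
#'   single-level studies are allowed and absorbed by the intercept).
#'   Defaults to age, study and all principal-component columns.
#' @param adjust_sex include sex as a covariate (pooled-sex analyses).
#' @return An object of class `null_fit`: list with `coef`, `mu` (fitted
#'   probabilities), `X` (design matrix), `y`, `weights`
#'   (`mu * (1 - mu)`), `exposure`, `xhat`, `loglik`, `converged`.
#' @export
fit_null_logistic <- function(cohort, xhat = NULL,
                              include_fixed_interaction = FALSE,
                              covariates = NULL, adjust_sex = FALSE) {
  y <- cohort$outcome
  if (length(unique(y)) < 2L) stop("need at least one case and one control")
  E <- cohort$exposure
  xv <- if (inherits(xhat, "predicted_expression")) xhat$values else xhat
  X <- .design_matrix(cohort, covariates, adjust_sex)
  X <- cbind(X, E = E)
  if (!is.null(xv)) {
    stopifnot(length(xv) == nrow(cohort))
    X <- cbind(X, xhat = xv)
    if (include_fixed_interaction) X <- cbind(X, `xhat:E` = xv * E)
  } else if (include_fixed_interaction) {
    stop("`include_fixed_interaction` requires `xhat`")
  }
  # constant columns carry no information and are absorbed by the intercept
  const <- c(FALSE, apply(X[, -1L, drop = FALSE], 2L,
                          function(v) diff(range(v)) < 1e-12))
  if (any(const)) X <- X[, !const, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design matrix (collinear column(s): ",
         paste(bad, collapse = ", "), ")")
  }
  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100L))
  if (!fit$converged) stop("null logistic fit did not converge in 100 iterations")
  beta <- fit$coefficients
  if (.separated(beta, X)) {
    stop("apparent complete separation in null model; ",
         "drop the gene or reduce the covariate set")
  }
  mu <- fit$fitted.values
  score <- drop(crossprod(X, y - mu))
  converged <- max(abs(score)) < 1e-6 * max(1, nrow(X))
  if (!converged) stop("score vector not at optimum; fit unreliable")
  structure(list(coef = beta, mu = mu, X = X, y = y,
                 weights = mu * (1 - mu), exposure = E, xhat = xv,
                 loglik = sum(stats::dbinom(y, 1L, mu, log = TRUE)),
                 converged = TRUE),
            class = "null_fit")
}

# separation guard: a fitted log-OR above 30 per standard deviation of its
# column (scale-invariant, so small-variance predicted expression is not
# spuriously flagged)
.separated <- function(beta, X) {
  sds <- apply(X, 2L, stats::sd)
  any(abs(beta) * sds > 30, na.rm = TRUE)
}

# covariate design matrix with intercept; study as indicator columns
.design_matrix <- function(cohort, covariates = NULL, adjust_sex = FALSE) {
  if (is.null(covariates)) {
    covariates <- c("age", "study", attr(cohort, "pc_cols"))
  }
  n <- nrow(cohort)
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    if (!cv %in% names(cohort)) stop("covariate not in cohort table: ", cv)
    val <- cohort[[cv]]
    if (is.character(val) || is.factor(val)) {
      f <- factor(val)
      if (nlevels(f) > 1L) {
        mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
        colnames(mm) <- paste0(cv, levels(f)[-1L])
        X <- cbind(X, mm)
      }
    } else {
      X <- cbind(X, stats::setNames(data.frame(val), cv)[[1L]])
      colnames(X)[ncol(X)] <- cv
    }
  }
  if (adjust_sex) X <- cbind(X, sexmale = as.numeric(cohort$sex == "male"))
  X
}

#' Fixed-effect (burden) interaction score test
#'
#' One-degree-of-freedom score test of the predicted-expression-by-exposure
#' interaction. Under the null fit (without the interaction term), the score
#' is `U = sum((y - mu) * s)` with `s = xhat * E`, and the variance is the
#' efficient information of `s` after projecting out all null-model columns
#' under the IRLS weights. The p-value is the upper chi-square(1) tail of
#' `U^2 / V`.
#'
#' @param fit a [fit_null_logistic()] result without the interaction term.
#' @param s numeric vector of per-sample interaction values (defaults to
#'   `xhat * exposure` from the fit).
#' @return A `component_result`: list with `u_stat`, `variance`,
#'   `statistic`, `p_value`, `degenerate`.
#' @export
fixed_effect_score_test <- function(fit, s = NULL) {
  stopifnot(inherits(fit, "null_fit"))
  if (is.null(s)) {
    if (is.null(fit$xhat)) stop("fit carries no predicted expression")
    s <- fit$xhat * fit$exposure
  }
  stopifnot(all(is.finite(s)), length(s) == length(fit$y))
  U <- sum((fit$y - fit$mu) * s)
  V <- .efficient_info(fit, matrix(s, ncol = 1L))[1L, 1L]
  if (V <= 1e-12) {
    return(structure(list(u_stat = U, variance = V, statistic = NA_real_,
                          p_value = 1, degenerate = TRUE),
                     class = "component_result"))
  }
  stat <- U^2 / V
  structure(list(u_stat = U, variance = V, statistic = stat,
                 p_value = stats::pchisq(stat, 1L, lower.tail = FALSE),
                 degenerate = FALSE),
            class = "component_result")
}

# C' P C with P = W - W X (X'WX)^-1 X'W  (projection-adjusted information)
.efficient_info <- function(fit, C) {
  w <- fit$weights
  X <- fit$X
  CW <- C * w
  XtWX <- crossprod(X, X * w)
  XtWC <- crossprod(X, CW)
  crossprod(C, CW) - crossprod(XtWC, solve(XtWX, XtWC))
}

#' Random-effects (variance-component) interaction score test
#'
#' SKAT-type score test of residual SNP-by-exposure interactions beyond the
#' burden term. Conditioning on the fixed interaction (the null fit must
#' include the x-hat-by-exposure column) makes this component asymptotically
#' independent of the fixed-effect test. The statistic is
#' `Q = sum_j (sum_i (y_i - mu_i) C_ij)^2` for interaction columns
#' `C_ij = E_i * G_ij`; its null distribution is the eigenvalue-weighted
#' mixture of 1-df chi-squares given by the spectrum of `C' P C` (see
#' [mixture_chisq_pvalue()]).
#'
#' @param fit a [fit_null_logistic()] result including the fixed interaction
#'   term.
#' @param C numeric matrix (samples x variants) of residual interaction
#'   columns.
#' @return A `component_result` with additionally `q_stat` and
#'   `eigenvalues`.
#' @export
random_effect_score_test <- function(fit, C) {
  stopifnot(inherits(fit, "null_fit"), is.matrix(C),
            nrow(C) == length(fit$y), ncol(C) >= 1L)
  u <- drop(crossprod(C, fit$y - fit$mu))
  Q <- sum(u^2)
  M <- .efficient_info(fit, C)
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 1e-8 * max(lam, 0)] <- 0
  lam <- lam[lam > 0]
  if (length(lam) == 0L) {
    return(structure(list(u_stat = NA_real_, variance = 0, q_stat = Q,
                          eigenvalues = numeric(0), p_value = 1,
                          degenerate = TRUE),
                     class = "component_result"))
  }
  p <- mixture_chisq_pvalue(Q, lam)
  structure(list(u_stat = NA_real_, variance = sum(lam), q_stat = Q,
                 eigenvalues = lam, p_value = p, degenerate = FALSE),
            class = "component_result")
}

#' @export
print.component_result <- function(x, ...) {
  if (!is.null(x$q_stat) && !is.na(x$q_stat %||% NA)) {
    cat("variance-component score test: Q =", format(x$q_stat, digits = 5),
        "on", length(x$eigenvalues), "eigenvalue(s),")
  } else {
    cat("1-df score test: U^2/V =", format(x$statistic, digits = 5), ",")
  }
  cat(" p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tail probability of a mixture of chi-squares
#'
#' Computes `P(sum_k lambda_k Z_k^2 > q)` for independent standard normal
#' `Z_k` by Imhof's numerical inversion of the characteristic function, with
#' a four-moment (Liu-Tang-Zhang) approximation as fallback if the
#' integration fails. Equal-weight mixtures reduce to the exact chi-square
#' tail. The result is clipped to `(1e-300, 1]`.
#'
#' @param q nonnegative statistic value.
#' @param lambdas nonnegative eigenvalues, at least one positive.
#' @return The upper-tail probability.
#' @export
mixture_chisq_pvalue <- function(q, lambdas) {
  stopifnot(length(lambdas) >= 1L, all(lambdas >= 0))
  lambdas <- lambdas[lambdas > 0]
  if (length(lambdas) == 0L) stop("all eigenvalues are zero")
  if (q <= 0) return(1)
  if (diff(range(lambdas)) < 1e-12 * max(lambdas)) {
    # equal weights: exact chi-square with k degrees of freedom
    p <- stats::pchisq(q / lambdas[1L], df = length(lambdas),
                       lower.tail = FALSE)
    return(min(max(p, 1e-300), 1))
  }
  # scale-normalize so the oscillation/decay structure is size-independent
  sc <- max(lambdas)
  lam <- lambdas / sc
  qs <- q / sc
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lam, u))) - 0.5 * qs * u
    rho <- exp(0.25 * colSums(log1p(outer(lam^2, u^2))))
    val <- sin(theta) / (u * rho)
    val[u == 0] <- 0.5 * (sum(lam) - qs)
    val
  }
  # the integrand oscillates with asymptotic half-period 2*pi/q and decays
  # polynomially; integrate half-period segments and Euler-accelerate the
  # alternating partial sums
  h <- 2 * pi / max(qs, 1)
  acc <- 0
  partials <- numeric(0)
  ok <- TRUE
  partials <- numeric(260)
  n_seg <- 0L
  for (m in 0:259) {
    seg <- tryCatch(
      stats::integrate(integrand, m * h, (m + 1) * h, rel.tol = 1e-9,
                       abs.tol = 1e-13, subdivisions = 100L,
                       stop.on.error = TRUE)$value,
      error = function(e) NA_real_)
    if (is.na(seg)) { ok <- FALSE; break }
    acc <- acc + seg
    n_seg <- n_seg + 1L
    partials[n_seg] <- acc
    if (m >= 3 && abs(seg) < 1e-11) break
  }
  p <- NA_real_
  if (ok && n_seg > 0L) {
    tailp <- partials[max(1, n_seg - 11):n_seg]
    while (length(tailp) > 1) {  # iterated averaging of partial sums
      tailp <- (tailp[-1] + tailp[-length(tailp)]) / 2
    }
    p <- 0.5 + tailp / pi
  }
  # outside the integrator's absolute accuracy (deep tails) or on failure,
  # use the four-moment approximation
  if (is.na(p) || p < 1e-10 || p > 1 + 1e-6) p <- .liu_pvalue(q, lambdas)
  min(max(p, 1e-300), 1)
}

# Liu-Tang-Zhang four-moment chi-square approximation
.liu_pvalue <- function(q, lambdas) {
  c1 <- sum(lambdas); c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3); c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    a <- 1 / sqrt(s2)
    delta <- 0
    df <- 1 / s2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  t_star <- (q - mu_q) / sigma_q
  x <- t_star * sqrt(2) * sqrt(df + 2 * delta) + df + delta
  stats::pchisq(x, df = df, ncp = delta, lower.tail = FALSE)
}

# survival function of w*X + (1-w)*Y for independent X, Y ~ chi-square(2)
.weighted_exp_surv <- function(t, w) {
  if (t <= 0) return(1)
  if (w < 1e-12 || w > 1 - 1e-12) return(exp(-t / 2))
  a <- w; b <- 1 - w
  if (abs(a - b) < 1e-9) return(stats::pchisq(2 * t, 4L, lower.tail = FALSE))
  (a * exp(-t / (2 * a)) - b * exp(-t / (2 * b))) / (a - b)
}

.weighted_exp_quantile <- function(p, w) {
  # t with survival p; exponential closed form at the endpoints
  if (p >= 1) return(0)
  if (w < 1e-12 || w > 1 - 1e-12) return(-2 * log(p))
  upper <- -2 * log(p) / min(w, 1 - w) + 8
  stats::uniroot(function(t) .weighted_exp_surv(t, w) - p,
                 lower = 0, upper = upper, tol = 1e-12)$root
}

#' Combine the fixed and random component p-values
#'
#' Two combiners for the asymptotically independent component p-values.
#' `"fisher"` uses `T = -2 (log p_fix + log p_ran)` against the upper
#' chi-square(4) tail. `"adaptive_grid"` (default) evaluates the weighted
#' statistic `T_w = -2 (w log p_fix + (1 - w) log p_ran)` over a weight
#' grid, converts each to its exact p-value (a weighted convolution of two
#' chi-square(2) variates), takes the minimum, and reports the exact
#' probability under independent uniforms that the grid minimum is smaller
#' than observed (computed by numerical integration over the unit square).
#'
#' @param p_fix,p_ran component p-values in `(0, 1]`.
#' @param method `"adaptive_grid"` or `"fisher"`.
#' @param grid weight grid for the adaptive combiner.
#' @return List with `p_value`, `chosen_weight` (NA for Fisher), `method`.
#' @export
combine_components <- function(p_fix, p_ran,
                               method = c("adaptive_grid", "fisher"),
                               grid = c(0, 0.25, 0.5, 0.75, 1)) {
  method <- match.arg(method)
  if (!is.finite(p_fix) || p_fix <= 0 || p_fix > 1 ||
      !is.finite(p_ran) || p_ran <= 0 || p_ran > 1) {
    stop("component p-values must lie in (0, 1]")
  }
  if (method == "fisher") {
    T_f <- -2 * (log(p_fix) + log(p_ran))
    return(list(p_value = stats::pchisq(T_f, 4L, lower.tail = FALSE),
                chosen_weight = NA_real_, method = "fisher"))
  }
  stopifnot(length(grid) >= 2L, all(grid >= 0 & grid <= 1),
            any(grid == 0), any(grid == 1))
  grid <- sort(unique(grid))
  Tw <- -2 * (grid * log(p_fix) + (1 - grid) * log(p_ran))
  pw <- vapply(seq_along(grid),
               function(i) .weighted_exp_surv(Tw[i], grid[i]), numeric(1L))
  pmin_obs <- min(pw)
  chosen <- grid[which.min(pw)]
  if (pmin_obs >= 1) {
    return(list(p_value = 1, chosen_weight = chosen, method = "adaptive_grid"))
  }
  # null probability that the grid-minimum p-value falls below pmin_obs:
  # with X = -2 log U1, Y = -2 log U2 (iid chi-square(2)), the complement is
  # the event {w X + (1-w) Y < t_w for all w}, a convex region integrable in
  # one dimension.
  tq <- vapply(grid, function(w) .weighted_exp_quantile(pmin_obs, w),
               numeric(1L))
  t1 <- tq[grid == 1]
  t0 <- tq[grid == 0]
  mids <- which(grid > 0 & grid < 1)
  # upper boundary of the convex acceptance region: piecewise-linear minimum
  # of the per-weight constraint lines
  lines_a <- c(t0, tq[mids] / (1 - grid[mids]))
  lines_b <- c(0, -grid[mids] / (1 - grid[mids]))
  ymax <- function(x) {
    out <- rep(Inf, length(x))
    for (k in seq_along(lines_a)) out <- pmin(out, lines_a[k] + lines_b[k] * x)
    pmax(out, 0)
  }
  # integrate piecewise between the kinks (pairwise line crossings and zero
  # crossings) so each segment is smooth
  brk <- c(0, t1)
  for (k in seq_along(lines_a)) {
    if (lines_b[k] < 0) brk <- c(brk, -lines_a[k] / lines_b[k])
    for (l in seq_along(lines_a)) {
      if (l > k && lines_b[k] != lines_b[l]) {
        brk <- c(brk, (lines_a[l] - lines_a[k]) / (lines_b[k] - lines_b[l]))
      }
    }
  }
  brk <- sort(unique(pmin(pmax(brk, 0), t1)))
  fx <- function(x) 0.5 * exp(-x / 2) * (1 - exp(-ymax(x) / 2))
  acc <- 0
  for (k in seq_len(length(brk) - 1L)) {
    if (brk[k + 1L] - brk[k] < 1e-14) next
    acc <- acc + stats::integrate(fx, brk[k], brk[k + 1L], rel.tol = 1e-10,
                                  abs.tol = 1e-13,
                                  subdivisions = 500L)$value
  }
  p <- 1 - acc
  list(p_value = min(max(p, 1e-300), 1), chosen_weight = chosen,
       method = "adaptive_grid")
}

#' Set-based mixed-effects interaction test for one gene
#'
#' The whole per-gene procedure: harmonize the gene's eQTL weights to the
#' dosage data, compute predicted expression, fit the null logistic model,
#' run the fixed-effect (burden) interaction score test, refit including the
#' fixed interaction term, run the conditional variance-component test on
#' the residual SNP-by-exposure columns, and combine the two component
#' p-values.
#'
#' @param weights a [weight_set()] for the gene.
#' @param genotypes a [genotype_matrix()] covering the cohort samples (rows
#'   aligned with `cohort`).
#' @param cohort a `cohort_table` with the analysis exposure.
#' @param covariates covariate columns for the null model (default: age,
#'   study, principal components).
#' @param adjust_sex include sex as a covariate (pooled-sex analyses).
#' @param combiner `"adaptive_grid"` or `"fisher"`.
#' @param stratum optional label recorded in the result.
#' @return An object of class `misti`: gene id, eQTL counts, predictive R2,
#'   the three p-values (`p_fixed`, `p_random`, `p_adaptive`), the chosen
#'   combination weight and the underlying component results.
#' @examples
#' scen <- sim_scenario(n_cases = 150, n_controls = 150, n_genes = 1,
#'                      snps_per_gene = 6, seed = 7)
#' sim <- simulate_cohort(scen)
#' misti(sim$weight_sets[[1]], sim$genotypes, sim$cohort)
#' @export
misti <- function(weights, genotypes, cohort, covariates = NULL,
                  adjust_sex = FALSE,
                  combiner = c("adaptive_grid", "fisher"), stratum = NA) {
  combiner <- match.arg(combiner)
  stopifnot(nrow(genotypes$dosages) == nrow(cohort))
  hw <- harmonize_alleles(weights, genotypes)
  xhat <- predict_expression(hw, genotypes,
                             n_total = nrow(weights$variants))
  fit0 <- fit_null_logistic(cohort, xhat, include_fixed_interaction = FALSE,
                            covariates = covariates, adjust_sex = adjust_sex)
  fixed <- fixed_effect_score_test(fit0)
  fit1 <- fit_null_logistic(cohort, xhat, include_fixed_interaction = TRUE,
                            covariates = covariates, adjust_sex = adjust_sex)
  v <- hw$variants
  D <- genotypes$dosages[, v$variant_id, drop = FALSE]
  C <- D * cohort$exposure
  random <- random_effect_score_test(fit1, C)
  comb <- combine_components(fixed$p_value, random$p_value, method = combiner)
  structure(list(gene_id = weights$gene_id, stratum = stratum,
                 n_snps = xhat$n_snps_used,
                 n_snps_dropped = xhat$n_snps_dropped,
                 predictive_r2 = weights$predictive_r2,
                 p_fixed = fixed$p_value, p_random = random$p_value,
                 p_adaptive = comb$p_value,
                 chosen_weight = comb$chosen_weight, combiner = combiner,
                 fixed = fixed, random = random, null_fit = fit0,
                 n = nrow(cohort)),
            class = "misti")
}

#' @export
print.misti <- function(x, ...) {
  cat("Set-based GxE interaction test (mixed-effects score test)\n")
  cat("  gene: ", x$gene_id,
      if (!is.na(x$stratum)) paste0("  stratum: ", x$stratum), "\n", sep = "")
  cat("  eQTLs used: ", x$n_snps, " (", x$n_snps_dropped, " dropped)",
      "   predictive R2: ", format(x$predictive_r2, digits = 3), "\n", sep = "")
  cat(sprintf("  p_fixed = %.4g   p_random = %.4g   p_adaptive = %.4g (%s)\n",
              x$p_fixed, x$p_random, x$p_adaptive, x$combiner))
  invisible(x)
}

#' @export
summary.misti <- function(object, ...) {
  print(object)
  cat("  fixed component:  U =", format(object$fixed$u_stat, digits = 4),
      " V =", format(object$fixed$variance, digits = 4), "\n")
  cat("  random component: Q =", format(object$random$q_stat, digits = 4),
      " eigenvalues:", length(object$random$eigenvalues), "\n")
  cat("  null model n =", object$n, " loglik =",
      format(object$null_fit$loglik, digits = 6), "\n")
  invisible(object)
}

#' @export
coef.misti <- function(object, ...) object$null_fit$coef
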