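#' Construct an eQTL weight set for one gene
#'
#' Holds one gene's elastic-net eQTL weights (PredictDB-style): variant ids,
#' effect/other alleles, per-variant weights and the gene's predictive R2
#' (the SNP heritability of its expression).
#'
#' @param gene_id gene identifier.
#' @param variants data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `weight` (and optionally `flipped`, set by
#'   [harmonize_alleles()]).
#' @param predictive_r2 predictive R2 in `[0, 1]` (NA if unknown).
#' @return An object of class `weight_set`.
#' @export
weight_set <- function(gene_id, variants, predictive_r2 = NA_real_) {
  stopifnot(is.data.frame(variants))
  need <- c("variant_id", "effect_allele", "other_allele", "weight")
  if (!all(need %in% names(variants))) {
    stop("weight table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(variants) < 1L) stop("weight set for ", gene_id, " has no eQTLs")
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate eQTL in ", gene_id, ": ",
         variants$variant_id[duplicated(variants$variant_id)][1L])
  }
  if (!all(is.finite(variants$weight))) stop("non-finite weight in ", gene_id)
  if (is.null(variants$flipped)) variants$flipped <- FALSE
  rownames(variants) <- NULL
  structure(list(gene_id = gene_id, variants = variants,
                 predictive_r2 = predictive_r2),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("weight_set ", x$gene_id, ": ", nrow(x$variants), " eQTL(s), R2 = ",
      format(x$predictive_r2, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Read eQTL weight sets from TSV
#'
#' Reads the weight dialect `gene_id variant_id effect_allele other_allele
#' weight` plus an optional gene-level table `gene_id pred_r2 n_snps`
#' carrying each gene's predictive R2.
#'
#' @param weights_path weight TSV path.
#' @param genes_path optional gene-level TSV path.
#' @return A named list of [weight_set()] objects, in first-appearance order.
#' @export
read_weights <- function(weights_path, genes_path = NULL) {
  w <- utils::read.table(weights_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "variant_id", "effect_allele", "other_allele", "weight")
  missing_col <- setdiff(need, names(w))
  if (length(missing_col)) stop("weight table lacks column: ", missing_col[1L])
  r2 <- NULL
  if (!is.null(genes_path)) {
    g <- utils::read.table(genes_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    r2 <- stats::setNames(g$pred_r2, g$gene_id)
  }
  ids <- unique(w$gene_id)
  out <- lapply(ids, function(id) {
    weight_set(id, w[w$gene_id == id, need[-1L], drop = FALSE],
               predictive_r2 = if (is.null(r2)) NA_real_ else unname(r2[id]))
  })
  stats::setNames(out, ids)
}

#' Write eQTL weight sets in the TSV dialect read by [read_weights()]
#'
#' @param ws named list of [weight_set()] objects.
#' @param weights_path output weight TSV path.
#' @param genes_path output gene-level TSV path.
#' @export
write_weights <- function(ws, weights_path, genes_path) {
  rows <- do.call(rbind, lapply(ws, function(w) {
    data.frame(gene_id = w$gene_id, w$variants[, 1:3],
               weight = .fmt_num(w$variants$weight),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, weights_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  genes <- data.frame(gene_id = vapply(ws, `[[`, "", "gene_id"),
                      pred_r2 = .fmt_num(vapply(ws, `[[`, 0, "predictive_r2")),
                      n_snps = vapply(ws, function(w) nrow(w$variants), 0L))
  utils::write.table(genes, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

.complement_allele <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

#' Harmonize a weight set to a genotype matrix's allele coding
#'
#' Reconciles each eQTL's allele labels with the dosage file. An eQTL that
#' matches the dosage coding exactly is kept as-is; one whose effect/other
#' alleles are swapped relative to the dosage file gets its weight negated
#' (and is flagged `flipped`), which leaves the weighted dosage sum equal to
#' the correctly oriented one up to a per-gene additive constant (twice the
#' sum of the negated weights) that any model with an intercept absorbs.
#' Alleles matching only after strand complement (A-T, C-G flips) are
#' treated the same way, except that strand-ambiguous pairs (A/T or C/G) in
#' non-identical orientation carry no usable strand information and are
#' dropped (configurable). eQTLs absent from the dosage file are dropped;
#' all drop counts are kept as attributes.
#'
#' @param w a [weight_set()].
#' @param g a [genotype_matrix()].
#' @param drop_ambiguous drop strand-ambiguous eQTLs whose orientation cannot
#'   be resolved (default TRUE).
#' @return The harmonized `weight_set` (attributes `n_dropped_absent`,
#'   `n_dropped_ambiguous`).
#' @export
harmonize_alleles <- function(w, g, drop_ambiguous = TRUE) {
  stopifnot(inherits(w, "weight_set"), inherits(g, "genotype_matrix"))
  v <- w$variants
  idx <- match(v$variant_id, g$variants$variant_id)
  absent <- is.na(idx)
  n_absent <- sum(absent)
  v <- v[!absent, , drop = FALSE]
  idx <- idx[!absent]

  ea <- toupper(v$effect_allele); oa <- toupper(v$other_allele)
  gea <- toupper(g$variants$effect_allele[idx])
  goa <- toupper(g$variants$other_allele[idx])
  ambiguous_pair <- ea == .complement_allele(oa)

  exact <- ea == gea & oa == goa
  swapped <- ea == goa & oa == gea
  flip_exact <- .complement_allele(ea) == gea & .complement_allele(oa) == goa
  flip_swapped <- .complement_allele(ea) == goa & .complement_allele(oa) == gea

  action <- rep("drop", nrow(v))
  action[exact] <- "keep"
  action[!exact & swapped & !(drop_ambiguous & ambiguous_pair)] <- "swap"
  action[!exact & !swapped & flip_exact & !(drop_ambiguous & ambiguous_pair)] <- "keep"
  action[!exact & !swapped & !flip_exact & flip_swapped &
           !(drop_ambiguous & ambiguous_pair)] <- "swap"
  n_ambiguous <- sum(action == "drop")

  keep <- action != "drop"
  v <- v[keep, , drop = FALSE]
  act <- action[keep]
  v$weight <- ifelse(act == "swap", -v$weight, v$weight)
  v$flipped <- act == "swap"
  v$effect_allele <- g$variants$effect_allele[idx][keep]
  v$other_allele <- g$variants$other_allele[idx][keep]
  if (nrow(v) == 0L) {
    out <- structure(list(gene_id = w$gene_id,
                          variants = v, predictive_r2 = w$predictive_r2),
                     class = "weight_set")
  } else {
    out <- weight_set(w$gene_id, v, w$predictive_r2)
  }
  attr(out, "n_dropped_absent") <- n_absent
  attr(out, "n_dropped_ambiguous") <- n_ambiguous
  out
}

#' Genetically predicted expression from harmonized weights
#'
#' Computes the predicted expression x-hat for every sample as the weighted
#' sum of dosages over the gene's retained eQTLs, using the harmonized
#' (possibly negated) weights. eQTLs absent from the
#' dosage matrix contribute nothing and are counted as dropped.
#'
#' @param w a [weight_set()], already passed through [harmonize_alleles()]
#'   against `g` (an unharmonized set is harmonized on the fly).
#' @param g a [genotype_matrix()].
#' @param n_total total eQTL count of the original weight set, used for the
#'   dropped-SNP bookkeeping (defaults to the retained count plus recorded
#'   harmonization drops).
#' @return An object of class `predicted_expression`: list with `gene_id`,
#'   `values` (one per sample), `n_snps_used`, `n_snps_dropped`.
#' @export
predict_expression <- function(w, g, n_total = NULL) {
  stopifnot(inherits(w, "weight_set"), inherits(g, "genotype_matrix"))
  v <- w$variants
  if (is.null(v$flipped) ||
      !all(v$variant_id %in% g$variants$variant_id)) {
    w <- harmonize_alleles(w, g)
    v <- w$variants
  }
  if (is.null(n_total)) {
    n_total <- nrow(v) +
      sum(attr(w, "n_dropped_absent"), attr(w, "n_dropped_ambiguous"))
  }
  if (nrow(v) == 0L) {
    stop(structure(class = c("gxe_unpredictable_gene", "error", "condition"),
                   list(message = paste0("unpredictable gene: ", w$gene_id,
                                         " has no usable eQTL in the dosage data"),
                        call = sys.call(-1L))))
  }
  xhat <- drop(g$dosages[, v$variant_id, drop = FALSE] %*% v$weight)
  structure(list(gene_id = w$gene_id, values = unname(xhat),
                 n_snps_used = nrow(v),
                 n_snps_dropped = n_total - nrow(v)),
            class = "predicted_expression")
}

#' @export
print.predicted_expression <- function(x, ...) {
  cat("predicted_expression ", x$gene_id, ": n = ", length(x$values),
      ", eQTLs used/dropped = ", x$n_snps_used, "/", x$n_snps_dropped,
      "\n", sep = "")
  invisible(x)
}

#' Filter genes by expression heritability
#'
#' Keeps genes whose predictive R2 (expression heritability explained by the
#' eQTL model) is at least `r2_min`; the boundary is inclusive. Input order
#' is preserved.
#'
#' @param ws list of [weight_set()] objects.
#' @param r2_min inclusion threshold (default 0.01).
#' @return The filtered list.
#' @export
filter_genes_by_heritability <- function(ws, r2_min = 0.01) {
  keep <- vapply(ws, function(w) {
    !is.na(w$predictive_r2) && w$predictive_r2 >= r2_min
  }, logical(1L))
  ws[keep]
}
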