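#' Construct a genotype dosage matrix
#'
#' Container for effect-allele dosages on the 0--2 scale with per-variant
#' metadata. Minor allele frequency is always recomputed from the dosages
#' (`mean(dosage)/2`, folded to be at most 0.5) so it stays consistent with
#' the stored data.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#'   Values outside `[0, 2]` are clipped (the clip count is kept in the
#'   `n_clipped` attribute).
#' @param variants data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele` and optionally `imputation_r2` (NA for directly typed
#'   variants). One row per column of `dosages`.
#' @param sample_ids character vector of sample identifiers (defaults to the
#'   rownames of `dosages`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (named matrix) and `variants` (metadata data.frame including a
#'   recomputed `maf` column).
#' @export
genotype_matrix <- function(dosages, variants, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (nrow(variants) != ncol(dosages)) {
    stop("`variants` must have one row per dosage column")
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant id: ",
         variants$variant_id[duplicated(variants$variant_id)][1L])
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(dosages)))
  n_clipped <- sum(dosages < 0 | dosages > 2, na.rm = TRUE)
  if (n_clipped > 0L) {
    dosages <- pmin(pmax(dosages, 0), 2)
    message("clipped ", n_clipped, " dosage value(s) to [0, 2]")
  }
  dimnames(dosages) <- list(sample_ids, variants$variant_id)
  if (is.null(variants$imputation_r2)) variants$imputation_r2 <- NA_real_
  freq <- colMeans(dosages) / 2
  variants$maf <- pmin(freq, 1 - freq)
  rownames(variants) <- NULL
  structure(list(dosages = dosages, variants = variants),
            n_clipped = n_clipped, class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "variants\n")
  cat("  MAF range:", format(range(x$variants$maf), digits = 3), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by sample and/or variant
#'
#' @param x a `genotype_matrix`.
#' @param samples,variants index vectors (logical, integer or character) into
#'   samples and variants respectively; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the selection; sample order is
#'   preserved. MAF is recomputed on the retained samples.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosages
  v <- x$variants
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, v$variant_id)
    d <- d[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
  }
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  v$imputation_r2 <- v$imputation_r2  # keep column even when empty selection
  genotype_matrix(d, v[, setdiff(names(v), "maf"), drop = FALSE])
}

#' Read a dosage matrix from TSV or VCF
#'
#' The TSV dialect is one variant per row with header
#' `variant_id effect_allele other_allele imputation_r2 <sample1> <sample2> ...`
#' and dosages counting the effect allele. A `.vcf`/`.vcf.gz` path is read via
#' the per-genotype `DS` field (requires the `vcfR` package); REF is taken as
#' the other allele and ALT as the effect (counted) allele.
#'
#' Dosages outside `[0, 2]` are clipped and the count reported; an empty
#' `imputation_r2` field (or `NA`/`.`) marks a directly typed variant.
#'
#' @param path file path.
#' @return A [genotype_matrix()].
#' @export
read_dosage_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) return(.read_dosage_vcf(path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  need <- c("variant_id", "effect_allele", "other_allele", "imputation_r2")
  if (length(header) < 5L || !identical(header[1:4], need)) {
    stop("malformed dosage header at line 1: expected columns ",
         paste(need, collapse = " "), " <sample ids...>")
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(rep("character", 3L),
                                          "numeric",
                                          rep("numeric", length(header) - 4L)),
                           na.strings = c("NA", "."), check.names = FALSE)
  if (anyDuplicated(raw$variant_id)) {
    stop("duplicate variant id: ", raw$variant_id[duplicated(raw$variant_id)][1L])
  }
  dos <- t(as.matrix(raw[, -(1:4), drop = FALSE]))
  rownames(dos) <- header[-(1:4)]
  genotype_matrix(dos, raw[, 1:4])
}

.read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(variant_id = ids,
                         effect_allele = fix[, "ALT"],
                         other_allele = fix[, "REF"],
                         imputation_r2 = NA_real_,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(ds), variants)
}

#' Tiered imputation-quality thresholds
#'
#' MAF-dependent imputation R-squared cutoffs. Tiers are matched from common
#' to rare: a variant falls in the first tier whose `maf_bound` its MAF
#' exceeds, and in the last tier otherwise, so every variant matches exactly
#' one tier. The defaults require R2 > 0.3 above 1% MAF, > 0.5 between 0.5%
#' and 1%, and > 0.99 below that.
#'
#' @param maf_bound numeric vector of MAF bounds, strictly decreasing.
#' @param min_r2 numeric vector of matching minimum imputation R2 values,
#'   nondecreasing as MAF decreases.
#' @return A `qc_thresholds` data.frame.
#' @export
qc_thresholds <- function(maf_bound = c(0.01, 0.005, 0.0005),
                          min_r2 = c(0.3, 0.5, 0.99)) {
  stopifnot(length(maf_bound) == length(min_r2), length(maf_bound) >= 1L)
  if (is.unsorted(rev(maf_bound), strictly = TRUE)) {
    stop("`maf_bound` must be strictly decreasing")
  }
  if (is.unsorted(min_r2)) stop("`min_r2` must be nondecreasing as MAF decreases")
  structure(data.frame(maf_bound = maf_bound, min_r2 = min_r2),
            class = c("qc_thresholds", "data.frame"))
}

#' Apply tiered variant-level QC
#'
#' Keeps a variant iff its imputation R2 strictly exceeds the cutoff of the
#' MAF tier it falls in (see [qc_thresholds()]). Directly typed variants
#' (missing `imputation_r2`) are always kept. Sample order is preserved and
#' the operation is idempotent.
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()] object.
#' @return The filtered `genotype_matrix` (possibly with zero variants).
#' @export
apply_variant_qc <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  tier <- vapply(v$maf, function(m) {
    i <- which(m > thresholds$maf_bound)
    if (length(i)) i[1L] else nrow(thresholds)
  }, integer(1L))
  keep <- is.na(v$imputation_r2) | v$imputation_r2 > thresholds$min_r2[tier]
  subset_genotypes(g, variants = which(keep))
}

#' Exact-test Hardy-Weinberg filter on hard-called genotypes
#'
#' Optional filter for directly typed variants: dosages are rounded to hard
#' calls and an exact HWE test is run in controls; variants with exact
#' P below `p_cutoff` are removed. HWE on imputed fractional dosages is
#' ill-defined, so this is off the main QC path and intended for hard-called
#' input only.
#'
#' @param g a [genotype_matrix()].
#' @param controls logical vector (length = samples) flagging controls.
#' @param p_cutoff exact-test significance cutoff (default 1e-4).
#' @return The filtered `genotype_matrix`.
#' @export
hwe_filter <- function(g, controls, p_cutoff = 1e-4) {
  stopifnot(inherits(g, "genotype_matrix"), length(controls) == nrow(g$dosages))
  hard <- round(g$dosages[controls, , drop = FALSE])
  p <- apply(hard, 2L, function(x) {
    .hwe_exact(sum(x == 1), sum(x == 2), sum(x == 0))
  })
  subset_genotypes(g, variants = which(p >= p_cutoff))
}

# Exact HWE test (sum of probabilities of tables as or less likely than
# observed, conditioning on allele counts).
.hwe_exact <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0L) return(1)
  n_rare <- 2L * min(n_hom1, n_hom2) + n_het
  hets <- seq(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  # log-probability of each possible heterozygote count given allele counts
  lp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(n_rare + 1) -
                      lgamma(2 * n - n_rare + 1))
  }, numeric(1L))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_het, hets)] * (1 + 1e-12)])
}

#' Read a phenotype/covariate table
#'
#' Expects a TSV with columns `sample_id outcome bmi diabetes sex age study`
#' and any number of principal-component columns `pc1..pcK`. BMI is stored on
#' its raw kg/m2 scale; the analysis exposure column is derived per
#' `exposure`: for `"bmi"` it is raw BMI divided by 5 (so effects are per
#' 5 kg/m2) with participants under 18.5 kg/m2 excluded; for `"diabetes"` it
#' is the 0/1 indicator and no BMI exclusion applies. Rows with a missing
#' outcome or missing exposure are dropped; both drop counts are kept as
#' attributes (`n_excluded_bmi`, `n_dropped_missing`).
#'
#' @param path TSV file path.
#' @param exposure `"bmi"` or `"diabetes"`.
#' @return A `cohort_table` data.frame with an `exposure` column and
#'   attributes `exposure_name` and `pc_cols`.
#' @export
read_phenotypes <- function(path, exposure = c("bmi", "diabetes")) {
  exposure <- match.arg(exposure)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  cohort_table(df, exposure = exposure)
}

#' Assemble a cohort table from a raw phenotype data.frame
#'
#' @param df data.frame with the columns documented in [read_phenotypes()].
#' @param exposure `"bmi"` or `"diabetes"`.
#' @return A `cohort_table` (see [read_phenotypes()]).
#' @export
cohort_table <- function(df, exposure = c("bmi", "diabetes")) {
  exposure <- match.arg(exposure)
  mandatory <- c("sample_id", "outcome", "bmi", "diabetes", "sex", "age", "study")
  missing_col <- setdiff(mandatory, names(df))
  if (length(missing_col)) {
    stop("missing mandatory phenotype column: ", missing_col[1L])
  }
  pc_cols <- grep("^pc[0-9]+$", names(df), value = TRUE)
  if (!all(df$outcome %in% c(0, 1))) stop("`outcome` must be 0/1")
  if (!all(df$diabetes %in% c(0, 1, NA))) stop("`diabetes` must be 0/1")
  n0 <- nrow(df)
  n_excluded_bmi <- 0L
  if (exposure == "bmi") {
    low <- !is.na(df$bmi) & df$bmi < 18.5
    n_excluded_bmi <- sum(low)
    df <- df[!low, , drop = FALSE]
    df$exposure <- df$bmi / 5
  } else {
    df$exposure <- as.numeric(df$diabetes)
  }
  ok <- !is.na(df$outcome) & !is.na(df$exposure)
  n_missing <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (n_excluded_bmi + n_missing > 0L) {
    message("dropped ", n_excluded_bmi, " row(s) with BMI < 18.5 and ",
            n_missing, " row(s) with missing outcome/exposure (of ", n0, ")")
  }
  df$sex <- as.character(df$sex)
  if (!all(df$sex %in% c("male", "female"))) {
    stop("`sex` must be coded male/female")
  }
  df$study <- as.character(df$study)
  rownames(df) <- NULL
  structure(df, exposure_name = exposure, pc_cols = pc_cols,
            n_excluded_bmi = n_excluded_bmi, n_dropped_missing = n_missing,
            class = c("cohort_table", "data.frame"))
}

#' Write a phenotype table in the dialect read by [read_phenotypes()]
#'
#' @param df data.frame with the raw phenotype columns (`bmi` on the kg/m2
#'   scale, no derived `exposure` column required).
#' @param path output TSV path.
#' @export
write_phenotypes <- function(df, path) {
  keep <- setdiff(names(df), "exposure")
  utils::write.table(df[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix in the dosage TSV dialect
#'
#' @param g a [genotype_matrix()].
#' @param path output TSV path.
#' @export
write_dosage_matrix <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  out <- data.frame(variant_id = g$variants$variant_id,
                    effect_allele = g$variants$effect_allele,
                    other_allele = g$variants$other_allele,
                    imputation_r2 = .fmt_num(g$variants$imputation_r2),
                    stringsAsFactors = FALSE)
  dos <- t(g$dosages)
  for (j in seq_len(ncol(dos))) out[[colnames(dos)[j]]] <- .fmt_num(dos[, j])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# full-precision decimal formatting that survives a read/write round trip
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- format(v, digits = 15, scientific = NA, trim = TRUE)
    if (as.numeric(s) != v) s <- format(v, digits = 17, trim = TRUE)
    s
  }, character(1L))
  out
}

#' Write a scan results table
#'
#' Emits the scan TSV (`gene stratum n_snps r2 p_fixed p_random p_adaptive
#' q_value significant`); numeric columns are formatted so that reading the
#' file back reproduces the values to at least 12 significant digits.
#'
#' @param s a `misti_scan` (or compatible) data.frame.
#' @param path output TSV path.
#' @export
write_results <- function(s, path) {
  cols <- c("gene", "stratum", "n_snps", "r2", "p_fixed", "p_random",
            "p_adaptive", "q_value", "significant")
  if (nrow(s) == 0L) stop("results table is empty")
  missing_col <- setdiff(cols, names(s))
  if (length(missing_col)) stop("results table lacks column: ", missing_col[1L])
  out <- as.data.frame(s)[, cols]
  for (cc in c("r2", "p_fixed", "p_random", "p_adaptive", "q_value")) {
    out[[cc]] <- .fmt_num(out[[cc]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scan results table written by [write_results()]
#'
#' @param path TSV path.
#' @return A data.frame with the scan columns (`significant` as logical).
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer",
                                         rep("numeric", 5L), "logical"))
  df
}
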