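#' Genotype matrix container
#'
#' The central data object of the pipeline: an additive-coded dosage matrix
#' (samples x variants, values 0/1/2, `NA` = missing call) together with the
#' variant table and optional per-call GQ (phred-scaled genotype quality)
#' and DP (read depth) matrices. `NA` in the dosage matrix is the
#' authoritative missingness mask.
#'
#' @param dosages Numeric matrix, samples x variants, values in
#'   \{0, 1, 2, NA\}.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param variants `data.frame` with columns `chrom`, `pos` (1-based,
#'   GRCh37 convention), `id`, `ref`, `alt` (comma-separated when
#'   multi-allelic), and optionally `alt_frequency`.
#' @param gq,dp Optional integer matrices of the same shape as `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids, variants, gq = NULL, dp = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  stop_if_not(length(sample_ids) == nrow(dosages),
              "sample_ids length (%d) != dosage rows (%d)",
              length(sample_ids), nrow(dosages))
  stop_if_not(!anyDuplicated(sample_ids), "duplicate sample ids")
  stop_if_not(is.data.frame(variants) && nrow(variants) == ncol(dosages),
              "variants table rows (%s) != dosage columns (%d)",
              if (is.data.frame(variants)) nrow(variants) else "?", ncol(dosages))
  req <- c("chrom", "pos", "id", "ref", "alt")
  stop_if_not(all(req %in% names(variants)),
              "variants table must have columns: %s", paste(req, collapse = ", "))
  stop_if_not(all(variants$pos >= 1), "variant pos must be >= 1")
  bad <- dosages[!is.na(dosages)]
  stop_if_not(all(bad %in% c(0, 1, 2)), "dosages must be 0/1/2 or NA")
  for (nm in c("gq", "dp")) {
    x <- get(nm)
    if (!is.null(x)) {
      stop_if_not(all(dim(x) == dim(dosages)), "%s matrix shape mismatch", nm)
    }
  }
  dimnames(dosages) <- list(sample_ids, variants$id)
  structure(
    list(dosages = dosages, sample_ids = as.character(sample_ids),
         variants = variants, gq = gq, dp = dp),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosages))
  cat(sprintf("<genotype_matrix> %d samples x %d variants; %d missing calls (%.2f%%)%s\n",
              nrow(x$dosages), ncol(x$dosages), nmiss,
              100 * nmiss / length(x$dosages),
              if (!is.null(x$gq)) "; GQ/DP attached" else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param samples,variants Index vectors (integer, logical, or character ids);
#'   `NULL` keeps all.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  if (is.character(si)) si <- match(si, x$sample_ids)
  vi <- if (is.null(variants)) seq_len(nrow(x$variants)) else variants
  if (is.character(vi)) vi <- match(vi, x$variants$id)
  stop_if_not(!anyNA(si) && !anyNA(vi), "unknown sample or variant id in subset")
  genotype_matrix(
    x$dosages[si, vi, drop = FALSE], x$sample_ids[si],
    x$variants[vi, , drop = FALSE],
    gq = if (!is.null(x$gq)) x$gq[si, vi, drop = FALSE],
    dp = if (!is.null(x$dp)) x$dp[si, vi, drop = FALSE]
  )
}

#' Per-sample cohort metadata
#'
#' Outcome and clinical covariates per sample. `relapse` is the binary
#' endpoint (1 = relapse of the primary malignancy after transplantation).
#'
#' @param df `data.frame` with at least `sample_id` and `relapse` columns;
#'   typical covariates are `donor_age`, `recipient_age`, `diagnosis`,
#'   `graft_type`, `sex`, `transplant_direction`, `batch`, and genetic
#'   principal-component scores in columns `pc1`, `pc2`, ...
#' @return A `cohort_metadata` (a classed `data.frame`).
#' @export
cohort_metadata <- function(df) {
  stop_if_not(all(c("sample_id", "relapse") %in% names(df)),
              "metadata needs sample_id and relapse columns")
  stop_if_not(!anyNA(df$relapse), "missing relapse outcome")
  stop_if_not(all(df$relapse %in% c(0, 1)), "relapse must be 0/1")
  stop_if_not(!anyDuplicated(df$sample_id), "duplicate sample ids in metadata")
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' Out-of-fold LOOCV predictions
#'
#' One score per sample, each produced by the fold that excluded that
#' sample. The unit of all downstream performance statistics.
#'
#' @param sample_ids Character vector.
#' @param scores Out-of-fold predicted relapse probabilities in \[0, 1\].
#' @param labels True 0/1 outcomes.
#' @param fold_results List of per-fold bookkeeping entries.
#' @param config The [cv_config()] used.
#' @param variant_universe Optional character vector of all variant ids the
#'   folds could select from (used by importance aggregation).
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(sample_ids, scores, labels, fold_results = list(),
                           config = NULL, variant_universe = NULL) {
  stop_if_not(length(scores) == length(sample_ids) &&
                length(labels) == length(sample_ids),
              "scores/labels/sample_ids length mismatch")
  stop_if_not(all(scores >= 0 & scores <= 1), "scores must lie in [0,1]")
  stop_if_not(all(labels %in% c(0, 1)), "labels must be 0/1")
  structure(
    list(sample_ids = sample_ids, scores = as.numeric(scores),
         labels = as.integer(labels), fold_results = fold_results,
         config = config, variant_universe = variant_universe),
    class = "prediction_set"
  )
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d samples (%d relapsed), AUC %.3f\n",
              length(x$scores), sum(x$labels), roc_auc(x$scores, x$labels)))
  invisible(x)
}
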