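#' Quality-control configuration
#'
#' Hard-cutoff thresholds for per-call filtering. Thresholds are exclusive
#' lower bounds (a call passes when `GQ > gq_min` and `DP > dp_min`); a
#' threshold of 0 disables that filter. The default `gq_min = 18`
#' reproduces the typical operating point chosen from a duplicate
#' concordance curve ([duplicate_concordance()]), where mean duplicate
#' similarity first reaches ~99%.
#'
#' @param gq_min Genotype-quality cutoff (default 18).
#' @param dp_min Read-depth cutoff (default 0 = off; panels rarely state
#'   one).
#' @param biallelic_only Also drop non-biallelic variants.
#' @param max_missing_frac Drop variants whose post-filter missing fraction
#'   exceeds this (default 0.5), preventing downstream complete-case
#'   collapse.
#' @return A `qc_config` list.
#' @export
qc_config <- function(gq_min = 18, dp_min = 0, biallelic_only = TRUE,
                      max_missing_frac = 0.5) {
  stop_if_not(gq_min >= 0 && dp_min >= 0, "thresholds must be >= 0")
  structure(list(gq_min = gq_min, dp_min = dp_min,
                 biallelic_only = isTRUE(biallelic_only),
                 max_missing_frac = max_missing_frac),
            class = "qc_config")
}

#' Duplicate-sample concordance across GQ hard cutoffs
#'
#' For each threshold `t` in `gq_grid`, restricts to calls where both
#' members of a duplicate pair are non-missing with `GQ > t`, and reports
#' the mean over pairs of the fraction of concordant genotype calls
#' (unordered ALT counts, so 0/1 == 1/0) together with the fraction of
#' comparable calls discarded relative to the smallest threshold. This is
#' the curve used to pick the GQ hard cutoff.
#'
#' @param gm A [genotype_matrix()] with GQ attached.
#' @param pairs A 2-column matrix/data.frame (or list of length-2 vectors)
#'   of sample-id pairs (original, duplicate).
#' @param gq_grid Integer GQ thresholds to evaluate.
#' @return A `concordance_curve` data.frame with columns `threshold`,
#'   `mean_similarity`, `n_compared`, `fraction_discarded`. Thresholds with
#'   no comparable calls get `NA` similarity and are listed in the
#'   `undefined_thresholds` attribute rather than reported as 0.
#' @export
duplicate_concordance <- function(gm, pairs, gq_grid = c(0, 10, 18, 20, 30)) {
  stop_if_not(!is.null(gm$gq), "duplicate_concordance requires GQ")
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  pairs <- as.matrix(pairs)
  stop_if_not(ncol(pairs) == 2, "pairs must have two columns")
  i1 <- match(pairs[, 1], gm$sample_ids)
  i2 <- match(pairs[, 2], gm$sample_ids)
  stop_if_not(!anyNA(i1) && !anyNA(i2), "unknown sample id in pairs")
  gq_grid <- sort(unique(gq_grid))

  sim <- n_comp <- numeric(length(gq_grid))
  for (k in seq_along(gq_grid)) {
    t <- gq_grid[k]
    per_pair <- rep(NA_real_, nrow(pairs))
    tot <- 0
    for (p in seq_len(nrow(pairs))) {
      a <- gm$dosages[i1[p], ]; b <- gm$dosages[i2[p], ]
      qa <- gm$gq[i1[p], ]; qb <- gm$gq[i2[p], ]
      use <- !is.na(a) & !is.na(b) & !is.na(qa) & !is.na(qb) & qa > t & qb > t
      tot <- tot + sum(use)
      if (any(use)) per_pair[p] <- mean(a[use] == b[use])
    }
    sim[k] <- if (all(is.na(per_pair))) NA_real_ else mean(per_pair, na.rm = TRUE)
    n_comp[k] <- tot
  }
  out <- data.frame(threshold = gq_grid, mean_similarity = sim,
                    n_compared = n_comp,
                    fraction_discarded = 1 - n_comp / max(n_comp[1], 1))
  attr(out, "undefined_thresholds") <- gq_grid[is.na(sim)]
  class(out) <- c("concordance_curve", "data.frame")
  out
}

#' Apply GQ/DP hard-cutoff filtering
#'
#' Calls failing the cutoffs are set to missing; variants left with more
#' than `max_missing_frac` missing calls (or no calls at all) are dropped.
#' The returned object carries a `qc_summary` attribute with the fraction
#' of calls and of variants discarded (both are reported because discard
#' statements in the literature are ambiguous between the two).
#'
#' @param gm A [genotype_matrix()].
#' @param qc A [qc_config()].
#' @return A filtered [genotype_matrix()].
#' @export
apply_quality_filter <- function(gm, qc = qc_config()) {
  d <- gm$dosages
  n_calls0 <- sum(!is.na(d))
  fail <- matrix(FALSE, nrow(d), ncol(d))
  if (qc$gq_min > 0) {
    stop_if_not(!is.null(gm$gq), "gq_min > 0 but no GQ attached")
    fail <- fail | is.na(gm$gq) | gm$gq <= qc$gq_min
  }
  if (qc$dp_min > 0) {
    stop_if_not(!is.null(gm$dp), "dp_min > 0 but no DP attached")
    fail <- fail | is.na(gm$dp) | gm$dp <= qc$dp_min
  }
  d[fail] <- NA
  miss_frac <- colMeans(is.na(d))
  keep <- miss_frac < 1 & miss_frac <= qc$max_missing_frac
  out <- genotype_matrix(d[, keep, drop = FALSE], gm$sample_ids,
                         gm$variants[keep, , drop = FALSE],
                         gq = if (!is.null(gm$gq)) gm$gq[, keep, drop = FALSE],
                         dp = if (!is.null(gm$dp)) gm$dp[, keep, drop = FALSE])
  if (qc$biallelic_only) out <- filter_biallelic(out)
  attr(out, "qc_summary") <- list(
    fraction_calls_discarded = 1 - sum(!is.na(d)) / max(n_calls0, 1),
    fraction_variants_dropped = 1 - ncol(out$dosages) / ncol(gm$dosages),
    n_variants_in = ncol(gm$dosages), n_variants_out = ncol(out$dosages))
  out
}

#' Restrict to biallelic variants
#'
#' Keeps exactly the variants with one REF and one ALT allele (multi-ALT
#' records are counted as non-biallelic without splitting); order is
#' preserved and the operation is idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @return A [genotype_matrix()].
#' @export
filter_biallelic <- function(gm) {
  keep <- !grepl(",", gm$variants$alt) & nzchar(gm$variants$alt) &
    nzchar(gm$variants$ref)
  subset_genotypes(gm, variants = which(keep))
}

#' Classify variants as SNP / INDEL / other
#'
#' A record is a SNP when REF and every ALT allele have length 1, an INDEL
#' when some allele lengths differ from REF, and "other" otherwise
#' (e.g. multi-nucleotide substitutions).
#'
#' @param gm A [genotype_matrix()].
#' @return Named integer vector with counts `snp`, `indel`, `other`.
#' @export
classify_variants <- function(gm) {
  cls <- vapply(seq_len(nrow(gm$variants)), function(j) {
    ref <- gm$variants$ref[j]
    alts <- strsplit(gm$variants$alt[j], ",")[[1]]
    lens <- nchar(c(ref, alts))
    if (all(lens == 1)) "snp"
    else if (any(nchar(alts) != nchar(ref))) "indel"
    else "other"
  }, "")
  c(snp = sum(cls == "snp"), indel = sum(cls == "indel"),
    other = sum(cls == "other"))
}

#' ALT allele frequency of a variant
#'
#' `sum(dosages) / (2 * non-missing sample count)`; invariant to sample
#' order. An all-missing variant yields `NA` with a warning.
#'
#' @param gm A [genotype_matrix()].
#' @param variant Column index or variant id; omit for all variants.
#' @return Numeric frequency (vector if `variant` is missing).
#' @export
alt_allele_frequency <- function(gm, variant = NULL) {
  d <- gm$dosages
  if (!is.null(variant)) {
    j <- if (is.character(variant)) match(variant, gm$variants$id) else variant
    stop_if_not(!anyNA(j), "unknown variant: %s", paste(variant, collapse = ","))
    d <- d[, j, drop = FALSE]
  }
  nm <- colSums(!is.na(d))
  if (any(nm == 0)) warning("all-missing variant(s): frequency undefined")
  out <- colSums(d, na.rm = TRUE) / (2 * nm)
  out[nm == 0] <- NA_real_
  if (!is.null(variant) && length(out) == 1) unname(out) else out
}
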