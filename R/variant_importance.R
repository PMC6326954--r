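#' Aggregate random-forest importance over LOOCV folds
#'
#' For each variant, the mean of its forest importance over the folds that
#' selected it, and the fraction of folds that selected it. Variants never
#' selected get frequency 0 and `NA` importance (flagged via the frequency,
#' not silently zeroed).
#'
#' @param ps A [prediction_set()] whose folds carry per-variant importance.
#' @param all_variants Variant id universe; defaults to the one recorded in
#'   the prediction set.
#' @return `data.frame` with `variant`, `loocv_importance`,
#'   `selection_frequency`.
#' @export
aggregate_loocv_importance <- function(ps, all_variants = NULL) {
  all_variants <- all_variants %||% ps$variant_universe
  stop_if_not(!is.null(all_variants), "no variant universe available")
  n_folds <- length(ps$fold_results)
  sums <- counts <- setNames(numeric(length(all_variants)), all_variants)
  for (fr in ps$fold_results) {
    sel <- intersect(fr$selected_variants, all_variants)
    if (length(sel) == 0) next
    counts[sel] <- counts[sel] + 1
    imp <- fr$per_variant_importance
    imp <- imp[names(imp) %in% sel]
    sums[names(imp)] <- sums[names(imp)] + imp
  }
  out <- data.frame(variant = all_variants,
                    loocv_importance = ifelse(counts > 0, sums / pmax(counts, 1),
                                              NA_real_),
                    selection_frequency = counts / n_folds,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Permutation-based importance test on the full dataset
#'
#' Altmann-style label-permutation null: the full pipeline (association
#' filter, then forest) is fitted once on the observed labels to get each
#' selected variant's observed importance, then refitted under `n_perm`
#' label permutations — the filter is re-run inside every permutation so
#' the selection step contributes to the null. A variant unselected in a
#' permuted refit contributes importance 0 there; a variant not selected by
#' the observed fit is not testable (`NA`).
#' `perm_pvalue = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param gm A [genotype_matrix()].
#' @param meta Matching [cohort_metadata()].
#' @param config A [cv_config()].
#' @param n_perm Number of permutations (default 200; must be >= 50).
#' @param seed Integer seed.
#' @return `data.frame` with `variant`, `perm_importance`, `perm_pvalue`.
#' @export
permutation_importance_null <- function(gm, meta, config = cv_config(),
                                        n_perm = 200, seed = 1L) {
  stop_if_not(n_perm >= 50, "n_perm must be >= 50")
  y <- meta$relapse
  fit_once <- function(labels, fit_seed) {
    meta2 <- meta
    meta2$relapse <- labels
    sel <- association_filter(gm, meta2, config$covariates, config$p_threshold,
                              test = config$assoc_test %||% "lrt")
    if (length(sel) == 0) return(NULL)
    X <- gm$dosages[, sel, drop = FALSE]
    med <- apply(X, 2, median, na.rm = TRUE)
    med[is.na(med)] <- 0
    for (k in seq_along(sel)) X[is.na(X[, k]), k] <- med[k]
    colnames(X) <- gm$variants$id[sel]
    mod <- fit_classifier(X, labels, config, seed = fit_seed)
    mod$importance
  }
  obs <- fit_once(y, derive_seed(seed, 0L))
  vids <- gm$variants$id
  out <- data.frame(variant = vids, perm_importance = NA_real_,
                    perm_pvalue = NA_real_, stringsAsFactors = FALSE)
  if (is.null(obs)) {
    attr(out, "note") <- "no variants selected on the observed labels"
    return(out)
  }
  exceed <- setNames(numeric(length(obs)), names(obs))
  with_seed(derive_seed(seed, 1L), {
    for (b in seq_len(n_perm)) {
      yp <- sample(y)
      null_imp <- fit_once(yp, derive_seed(seed, b + 1L))
      cur <- setNames(numeric(length(obs)), names(obs))
      if (!is.null(null_imp)) {
        common <- intersect(names(null_imp), names(obs))
        cur[common] <- null_imp[common]
      }
      exceed <- exceed + (cur >= obs)
    }
  })
  idx <- match(names(obs), out$variant)
  out$perm_importance[idx] <- obs
  out$perm_pvalue[idx] <- (1 + exceed) / (n_perm + 1)
  out
}

#' Build the combined importance table
#'
#' Joins LOOCV-aggregated and permutation-calibrated metrics and assigns
#' within-metric ranks (1 = most important; ties broken deterministically
#' by variant id so each rank column is a permutation of 1..m).
#'
#' @param agg Output of [aggregate_loocv_importance()].
#' @param perm Output of [permutation_importance_null()].
#' @param variants Optional variant table to annotate chrom/pos.
#' @return An `importance_table` data.frame.
#' @export
build_importance_table <- function(agg, perm, variants = NULL) {
  out <- merge(agg, perm, by = "variant", all = TRUE, sort = FALSE)
  rank_by <- function(metric) {
    key <- ifelse(is.na(metric), -Inf, metric)
    order(order(-key, out$variant))
  }
  out$rank_loocv <- rank_by(out$loocv_importance)
  out$rank_perm <- rank_by(out$perm_importance)
  if (!is.null(variants)) {
    out <- merge(out, variants[, c("id", "chrom", "pos")],
                 by.x = "variant", by.y = "id", all.x = TRUE, sort = FALSE)
  }
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Pearson correlation between the two ranking metrics
#'
#' @param loocv_metric,perm_metric Numeric vectors aligned by variant
#'   (e.g. columns of [build_importance_table()] output); only variants
#'   with both metrics defined enter.
#' @return Pearson r, with the number of excluded variants in the
#'   `n_excluded` attribute.
#' @export
rank_correlation <- function(loocv_metric, perm_metric) {
  ok <- is.finite(loocv_metric) & is.finite(perm_metric)
  stop_if_not(sum(ok) >= 3, "need >= 3 variants with both metrics defined")
  structure(cor(loocv_metric[ok], perm_metric[ok]),
            n_excluded = sum(!ok))
}

#' Select the top predictive variants
#'
#' Default rule: permutation p-value at or below `p_cut` AND selection
#' frequency at or above `f_cut`, ordered by decreasing permutation
#' importance. Alternative rule: the top N by permutation importance.
#'
#' @param table An `importance_table`.
#' @param rule Either `list(type = "threshold", p_cut = 0.05, f_cut = 0.5)`
#'   (default) or `list(type = "top_n", n = <count>)`.
#' @return Character vector of selected variant ids (possibly empty).
#' @export
select_top_variants <- function(table,
                                rule = list(type = "threshold", p_cut = 0.05,
                                            f_cut = 0.5)) {
  if (identical(rule$type, "top_n")) {
    ord <- order(-ifelse(is.na(table$perm_importance), -Inf,
                         table$perm_importance), table$variant)
    return(table$variant[head(ord, rule$n)])
  }
  keep <- !is.na(table$perm_pvalue) & table$perm_pvalue <= rule$p_cut &
    table$selection_frequency >= rule$f_cut
  sel <- table[keep, , drop = FALSE]
  sel$variant[order(-sel$perm_importance, sel$variant)]
}
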