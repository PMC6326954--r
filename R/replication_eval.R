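#' Replication configuration
#'
#' @param max_missing_per_variant Keep variants with strictly fewer missing
#'   genotypes than this (default 1 = complete variants only; literature
#'   operating points include <10, <50, <80).
#' @param dosage_sd_max Keep imputed variants whose mean per-call dosage SD
#'   is strictly below this (typical operating points 0.3 and 0.2).
#' @param use_dosages Evaluate on imputed expected dosages instead of hard
#'   calls.
#' @param cv A [cv_config()] for the fixed-set LOOCV refits (its
#'   association filter is never used here).
#' @return A `replication_config` list.
#' @export
replication_config <- function(max_missing_per_variant = 1,
                               dosage_sd_max = 0.3, use_dosages = FALSE,
                               cv = cv_config()) {
  stop_if_not(max_missing_per_variant >= 0, "max_missing must be >= 0")
  stop_if_not(dosage_sd_max > 0, "dosage_sd_max must be > 0")
  structure(list(max_missing_per_variant = max_missing_per_variant,
                 dosage_sd_max = dosage_sd_max,
                 use_dosages = isTRUE(use_dosages), cv = cv),
            class = "replication_config")
}

is_palindromic <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  nchar(ref) == 1 & nchar(alt) == 1 & !is.na(comp[ref]) &
    unname(comp[ref]) == alt
}

#' Match a discovery top-variant list against a replication panel
#'
#' Matching is by chromosome + position with allele agreement; variant id
#' strings are ignored (they differ across platforms). A record whose
#' REF/ALT are exchanged on the panel is matched with a dosage flip
#' (`g -> 2 - g`); strand-ambiguous A/T and C/G variants are matched but
#' flagged.
#'
#' @param top_list `data.frame` with `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `id`) for the requested variants.
#' @param panel_gm The replication panel [genotype_matrix()].
#' @return A `match_report`: list with `requested_variants`,
#'   `found_on_panel`, a `matches` data.frame (requested id, panel column,
#'   `flip`, `ambiguous`), `unmatched`, per-variant `missing_counts`, and
#'   `samples_kept` (panel size; sample filtering happens later).
#' @export
match_variants <- function(top_list, panel_gm) {
  stop_if_not(all(c("chrom", "pos", "ref", "alt") %in% names(top_list)),
              "top_list needs chrom/pos/ref/alt columns")
  pv <- panel_gm$variants
  req_id <- if ("id" %in% names(top_list)) top_list$id else
    paste0(top_list$chrom, ":", top_list$pos)
  rows <- lapply(seq_len(nrow(top_list)), function(i) {
    hit <- which(pv$chrom == top_list$chrom[i] & pv$pos == top_list$pos[i])
    for (j in hit) {
      if (pv$ref[j] == top_list$ref[i] && pv$alt[j] == top_list$alt[i]) {
        return(data.frame(id = req_id[i], panel_index = j, flip = FALSE,
                          ambiguous = is_palindromic(pv$ref[j], pv$alt[j])))
      }
      if (pv$ref[j] == top_list$alt[i] && pv$alt[j] == top_list$ref[i]) {
        return(data.frame(id = req_id[i], panel_index = j, flip = TRUE,
                          ambiguous = is_palindromic(pv$ref[j], pv$alt[j])))
      }
    }
    NULL
  })
  matches <- do.call(rbind, rows) %||%
    data.frame(id = character(0), panel_index = integer(0),
               flip = logical(0), ambiguous = logical(0))
  miss <- colSums(is.na(panel_gm$dosages[, matches$panel_index, drop = FALSE]))
  structure(list(requested_variants = nrow(top_list),
                 found_on_panel = nrow(matches), matches = matches,
                 unmatched = setdiff(req_id, matches$id),
                 missing_counts = setNames(miss, matches$id),
                 samples_kept = nrow(panel_gm$dosages)),
            class = "match_report")
}

#' Extract matched panel genotypes, applying dosage flips
#'
#' @param panel_gm The replication panel.
#' @param report A `match_report` from [match_variants()].
#' @return A [genotype_matrix()] restricted to the matched variants, with
#'   swapped-allele dosages flipped to the discovery orientation.
#' @export
apply_matches <- function(panel_gm, report) {
  gm <- subset_genotypes(panel_gm, variants = report$matches$panel_index)
  fl <- which(report$matches$flip)
  if (length(fl) > 0) {
    gm$dosages[, fl] <- 2 - gm$dosages[, fl]
    v <- gm$variants
    tmp <- v$ref[fl]; v$ref[fl] <- v$alt[fl]; v$alt[fl] <- tmp
    gm$variants <- v
  }
  gm
}

#' Missing-genotype / complete-case trade-off filter
#'
#' Keeps variants with strictly fewer than `max_missing` missing calls,
#' then removes every sample missing any kept variant (complete-case
#' analysis: a sample with one missing genotype cannot be scored). The
#' returned matrix therefore has zero missing entries. Raising
#' `max_missing` admits more variants at the cost of samples.
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Strict upper bound on per-variant missing calls.
#' @return A [genotype_matrix()]; a `tradeoff` attribute tabulates variant
#'   and sample retention over candidate thresholds. Zero surviving samples
#'   is an error (the trade-off table is printed in the message).
#' @export
missingness_filter <- function(gm, max_missing) {
  miss <- colSums(is.na(gm$dosages))
  keep_v <- which(miss < max_missing)
  grid <- sort(unique(c(miss, max_missing)))
  tradeoff <- data.frame(
    max_missing = grid + 1,
    variants_kept = vapply(grid, function(t) sum(miss <= t), 0L),
    samples_kept = vapply(grid, function(t) {
      kv <- miss <= t
      if (!any(kv)) return(nrow(gm$dosages))
      sum(rowSums(is.na(gm$dosages[, kv, drop = FALSE])) == 0)
    }, 0L))
  if (length(keep_v) == 0) {
    stop(paste0("no variants pass max_missing = ", max_missing, "\n",
                paste(utils::capture.output(print(tradeoff)), collapse = "\n")),
         call. = FALSE)
  }
  keep_s <- which(rowSums(is.na(gm$dosages[, keep_v, drop = FALSE])) == 0)
  if (length(keep_s) == 0) {
    stop(paste0("complete-case removal leaves zero samples\n",
                paste(utils::capture.output(print(tradeoff)), collapse = "\n")),
         call. = FALSE)
  }
  out <- subset_genotypes(gm, samples = keep_s, variants = keep_v)
  attr(out, "tradeoff") <- tradeoff
  out
}

#' Imputation-quality filter on per-variant dosage SD
#'
#' Per-variant quality is the mean per-call posterior dosage SD; variants
#' with quality strictly below `sd_max` are kept. Dosages are always
#' defined, so no samples are removed.
#'
#' @param dosage_table A `dosage_table` (see [simulate_imputed_dosages()]).
#' @param sd_max Strict threshold on mean per-call dosage SD.
#' @return Integer vector of kept variant columns, with the per-variant
#'   quality in the `quality` attribute.
#' @export
dosage_sd_filter <- function(dosage_table, sd_max) {
  stop_if_not(inherits(dosage_table, "dosage_table") &&
                !is.null(dosage_table$sd), "per-call dosage SDs are required")
  quality <- colMeans(dosage_table$sd)
  structure(which(quality < sd_max), quality = quality)
}

#' Fixed-variant-set LOOCV on a replication cohort
#'
#' Refits the random forest through LOOCV with the variant list FIXED — the
#' selection already happened in the discovery cohort, so no per-fold
#' association filter is run. With `use_dosages`, imputed expected dosages
#' replace hard calls as features.
#'
#' @param panel_gm The replication panel [genotype_matrix()] (already
#'   matched/flipped, see [apply_matches()]).
#' @param panel_meta Matching [cohort_metadata()].
#' @param matched_variants Variant ids or column indices to use.
#' @param cfg A [replication_config()].
#' @param dosage_table Required when `cfg$use_dosages`; expected dosages
#'   for the panel (same sample order).
#' @return A [prediction_set()].
#' @export
replicate_loocv <- function(panel_gm, panel_meta, matched_variants,
                            cfg = replication_config(), dosage_table = NULL) {
  stop_if_not(length(matched_variants) > 0, "matched_variants is empty")
  idx <- if (is.character(matched_variants)) {
    match(matched_variants, panel_gm$variants$id)
  } else {
    as.integer(matched_variants)
  }
  stop_if_not(!anyNA(idx), "unknown variant in matched_variants")
  gm <- subset_genotypes(panel_gm, variants = idx)
  if (cfg$use_dosages) {
    stop_if_not(!is.null(dosage_table), "use_dosages requires a dosage_table")
    cols <- match(gm$variants$id, dosage_table$variants$id)
    stop_if_not(!anyNA(cols), "dosage_table lacks some matched variants")
    d <- dosage_table$dosage[, cols, drop = FALSE]
    # expected dosages are continuous; bypass the 0/1/2 validator by
    # rounding only for the container, features use the raw values
    gm$dosages <- round(d)
    gm$dosages[gm$dosages < 0] <- 0
    gm$dosages[gm$dosages > 2] <- 2
    raw <- d
  }
  cv <- cfg$cv
  cv$include_variants_in_rf <- TRUE
  ps <- if (cfg$use_dosages) {
    loocv_predict_matrix(raw, gm, panel_meta, cv)
  } else {
    loocv_predict(gm, panel_meta, cv,
                  fixed_variants = seq_len(ncol(gm$dosages)))
  }
  ps
}

# LOOCV over an arbitrary continuous feature matrix (imputed dosages);
# shares the fold/fit/predict machinery contract with loocv_predict.
loocv_predict_matrix <- function(X, gm, meta, config) {
  n <- nrow(X)
  stop_if_not(n >= 10, "LOOCV needs at least 10 samples")
  y <- meta$relapse
  stop_if_not(length(unique(y)) == 2, "outcome must have both classes")
  colnames(X) <- gm$variants$id
  scores <- numeric(n)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mod <- fit_classifier(X[tr, , drop = FALSE], y[tr], config,
                          seed = config$base_seed + i)
    scores[i] <- min(max(predict(mod, X[i, , drop = FALSE]), 0), 1)
    folds[[i]] <- list(held_out_sample = as.character(meta$sample_id[i]),
                       selected_variants = gm$variants$id,
                       prediction_score = scores[i],
                       per_variant_importance = mod$importance,
                       fallback = NA_character_, diagnostics = NULL)
  }
  prediction_set(as.character(meta$sample_id), scores, y,
                 fold_results = folds, config = config,
                 variant_universe = gm$variants$id)
}
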