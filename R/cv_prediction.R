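#' Cross-validation / model configuration
#'
#' @param p_threshold Per-fold association p-value cutoff for variant
#'   selection (strict `<`; default 0.001).
#' @param covariates Covariate names used in the per-variant logistic
#'   association model (default donor age, diagnosis, graft type — the set
#'   that survives a typical covariate screen).
#' @param rf_n_trees Trees per forest (default 1000; LOOCV scores are
#'   stabler with more trees than the usual 500).
#' @param rf_mtry Features tried per split; `NULL` = `floor(sqrt(p))`.
#' @param rf_min_node Minimal node size to attempt a split (default 1).
#' @param assoc_test Association p-value used for selection: `"lrt"`
#'   (default; tail-calibrated at cohort-scale n) or `"wald"` (see
#'   [association_filter()]).
#' @param base_seed Base seed; fold i uses `base_seed + i`.
#' @param include_variants_in_rf Feed selected variant dosages to the
#'   forest (disable for a covariates-only model).
#' @param include_covariates_in_rf Also feed clinical covariates to the
#'   forest (default FALSE: the genetic model uses variants only).
#' @param include_pcs_in_rf Also feed `pc*` columns of the metadata.
#' @return A `cv_config` list.
#' @export
cv_config <- function(p_threshold = 0.001,
                      covariates = c("donor_age", "diagnosis", "graft_type"),
                      rf_n_trees = 1000, rf_mtry = NULL, rf_min_node = 1,
                      assoc_test = c("lrt", "wald"),
                      base_seed = 1L, include_variants_in_rf = TRUE,
                      include_covariates_in_rf = FALSE,
                      include_pcs_in_rf = FALSE) {
  stop_if_not(p_threshold > 0 && p_threshold <= 1,
              "p_threshold must be in (0,1]")
  stop_if_not(rf_n_trees >= 1, "rf_n_trees must be >= 1")
  structure(list(p_threshold = p_threshold, covariates = covariates,
                 rf_n_trees = as.integer(rf_n_trees), rf_mtry = rf_mtry,
                 rf_min_node = as.integer(rf_min_node),
                 assoc_test = match.arg(assoc_test),
                 base_seed = as.integer(base_seed),
                 include_variants_in_rf = isTRUE(include_variants_in_rf),
                 include_covariates_in_rf = isTRUE(include_covariates_in_rf),
                 include_pcs_in_rf = isTRUE(include_pcs_in_rf)),
            class = "cv_config")
}

# Covariate design for model fitting: numerics standardized with training
# statistics, categoricals dummy-coded against training levels (first level
# as reference). `stats = NULL` computes the statistics from `meta`
# (training data); pass them back to encode held-out samples identically.
covariate_design <- function(meta, covariates, stats = NULL) {
  if (length(covariates) == 0) {
    return(list(X = matrix(0, nrow(meta), 0), stats = list()))
  }
  if (is.null(stats)) {
    stats <- list(center = list(), levels = list())
    for (v in covariates) {
      x <- meta[[v]]
      stop_if_not(!is.null(x), "covariate '%s' absent from metadata", v)
      if (is.numeric(x)) {
        s <- sd(x)
        stats$center[[v]] <- c(mean(x), if (is.na(s) || s == 0) 1 else s)
      } else {
        stats$levels[[v]] <- sort(unique(as.character(x)))
      }
    }
  }
  cols <- list()
  for (v in covariates) {
    x <- meta[[v]]
    if (!is.null(stats$center[[v]])) {
      cs <- stats$center[[v]]
      cols[[v]] <- matrix((x - cs[1]) / cs[2], ncol = 1,
                          dimnames = list(NULL, v))
    } else {
      lev <- stats$levels[[v]]
      xx <- as.character(x)
      if (length(lev) < 2) {
        cols[[v]] <- matrix(0, length(xx), 0)
      } else {
        dm <- vapply(lev[-1], function(l) as.numeric(xx == l),
                     numeric(length(xx)))
        dm <- matrix(dm, nrow = length(xx),
                     dimnames = list(NULL, paste0(v, "_", lev[-1])))
        cols[[v]] <- dm
      }
    }
  }
  list(X = do.call(cbind, cols), stats = stats)
}

# Internal matrix-level association scan (training data only).
# test = "lrt" uses the likelihood-ratio p for selection (calibrated in the
# extreme tail at n ~ 150); "wald" uses the Wald p (the PLINK 1.9 report
# column, also always returned for inspection).
assoc_scan <- function(G, C, y, p_threshold, test = "lrt") {
  X <- cbind(`(Intercept)` = 1, C)
  res <- cpp_logistic_scan(G, X, as.numeric(y))
  status <- res[, 6]
  pcol <- if (identical(test, "wald")) 4L else 5L
  # Wald selection drops unstable/separated fits (status 2); the LRT is
  # still valid under separation (the deviance converges even though the
  # coefficient diverges), so only non-converged fits are dropped there.
  ok_status <- if (identical(test, "wald")) 0 else c(0, 2)
  ok <- !is.na(status) & status %in% ok_status & !is.na(res[, pcol])
  selected <- which(ok & res[, pcol] < p_threshold)
  diagnostics <- c(n_tested = nrow(res),
                   n_not_converged = sum(status == 1, na.rm = TRUE),
                   n_unstable = sum(status == 2, na.rm = TRUE),
                   n_zero_variance = sum(status == 3, na.rm = TRUE),
                   n_too_few = sum(status == 4, na.rm = TRUE))
  list(selected = selected, pvalues = res[, pcol], p_wald = res[, 4],
       p_lrt = res[, 5], beta = res[, 1], se = res[, 2], z = res[, 3],
       status = status, diagnostics = diagnostics)
}

#' Covariate-adjusted per-variant association filter
#'
#' Fits, for every variant, a logistic regression of relapse on the
#' additive dosage plus the configured covariates, and selects variants
#' whose genotype-term p-value is strictly below `p_threshold`. The
#' selection p-value is the likelihood-ratio test by default (`test =
#' "lrt"`): at n ~ 150 the Wald z is conservative in the extreme tail
#' (Hauck-Donner effect), under-selecting several-fold at p < 0.001,
#' whereas the LRT is calibrated there; the Wald statistic (PLINK 1.9's
#' report column) is always computed and available via `test = "wald"`.
#' Samples missing a dosage are dropped for that variant only.
#' Non-converged or separated fits are excluded and tallied in the
#' diagnostics, never propagated.
#'
#' @param gm A [genotype_matrix()] (training samples only — the caller is
#'   responsible for having removed any held-out samples).
#' @param meta Matching [cohort_metadata()].
#' @param covariates Covariate names for adjustment.
#' @param p_threshold Selection threshold (strict `<`).
#' @param test `"lrt"` (default) or `"wald"`.
#' @return Integer vector of selected variant column indices, with
#'   attributes `pvalues` (the selection p for all variants), `p_wald`,
#'   and `diagnostics` (fit-status tally).
#' @export
association_filter <- function(gm, meta, covariates = c("donor_age",
                                                        "diagnosis",
                                                        "graft_type"),
                               p_threshold = 0.001, test = "lrt") {
  stop_if_not(identical(gm$sample_ids, as.character(meta$sample_id)),
              "genotype and metadata sample ids differ (order matters)")
  C <- covariate_design(meta, covariates)$X
  sc <- assoc_scan(gm$dosages, C, meta$relapse, p_threshold, test)
  structure(sc$selected, pvalues = sc$pvalues, p_wald = sc$p_wald,
            diagnostics = sc$diagnostics)
}

#' Fit a probability random forest
#'
#' Bootstrap-aggregated CART trees with Gini splitting over `mtry` randomly
#' drawn features; the predicted relapse probability is the terminal-node
#' class fraction averaged over trees. Deterministic given `seed`.
#'
#' @param x Numeric feature matrix (no missing values; impute first).
#' @param y 0/1 labels; both classes must be present.
#' @param config A [cv_config()] (tree hyperparameters are read from it).
#' @param seed Integer seed.
#' @return An `rf_model` with out-of-bag predictions (`oob_pred`) and
#'   OOB permutation importance (`importance`, mean decrease in accuracy).
#' @export
fit_classifier <- function(x, y, config = cv_config(), seed = 1L) {
  x <- as.matrix(x)
  stop_if_not(ncol(x) >= 1, "classifier needs at least one feature")
  stop_if_not(length(unique(y)) == 2, "training labels are single-class")
  stop_if_not(!anyNA(x), "feature matrix contains missing values")
  mtry <- config$rf_mtry %||% max(1L, floor(sqrt(ncol(x))))
  fit <- cpp_rf_fit(x, as.integer(y), config$rf_n_trees, as.integer(mtry),
                    config$rf_min_node, as.numeric(seed))
  structure(list(forest = fit, features = colnames(x),
                 importance = setNames(fit$importance, colnames(x)),
                 oob_pred = fit$oob_pred, mtry = mtry,
                 n_trees = config$rf_n_trees),
            class = "rf_model")
}

#' @param object An `rf_model`.
#' @param newdata Numeric matrix with the training feature columns.
#' @param ... Unused.
#' @return Predicted class-1 probabilities.
#' @rdname fit_classifier
#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stop_if_not(ncol(newdata) == length(object$features),
              "newdata has %d columns, model expects %d",
              ncol(newdata), length(object$features))
  as.numeric(cpp_rf_predict(object$forest, newdata))
}

# One LOOCV fold: select on training rows, fit, predict the held-out row.
run_fold <- function(G, meta, y, i, config, fixed_variants, variant_ids) {
  n <- length(y)
  tr <- setdiff(seq_len(n), i)
  ytr <- y[tr]
  if (length(unique(ytr)) < 2) {
    stop(sprintf("training set of fold %d is single-class", i), call. = FALSE)
  }
  sel <- integer(0)
  diagnostics <- NULL
  if (config$include_variants_in_rf) {
    if (is.null(fixed_variants)) {
      Ctr <- covariate_design(meta[tr, , drop = FALSE], config$covariates)$X
      sc <- assoc_scan(G[tr, , drop = FALSE], Ctr, ytr, config$p_threshold,
                       config$assoc_test %||% "lrt")
      sel <- sc$selected
      diagnostics <- sc$diagnostics
    } else {
      sel <- fixed_variants
    }
  }
  feats_tr <- list(); feats_te <- list()
  if (length(sel) > 0) {
    Gtr <- G[tr, sel, drop = FALSE]
    Gte <- G[i, sel, drop = FALSE]
    med <- apply(Gtr, 2, median, na.rm = TRUE)
    med[is.na(med)] <- 0
    for (k in seq_along(sel)) {
      Gtr[is.na(Gtr[, k]), k] <- med[k]
      Gte[is.na(Gte[, k]), k] <- med[k]
    }
    colnames(Gtr) <- colnames(Gte) <- variant_ids[sel]
    feats_tr$g <- Gtr; feats_te$g <- Gte
  }
  extra <- character(0)
  if (config$include_covariates_in_rf) extra <- config$covariates
  if (config$include_pcs_in_rf) {
    extra <- c(extra, grep("^pc[0-9]+$", names(meta), value = TRUE))
  }
  if (length(extra) > 0) {
    cd <- covariate_design(meta[tr, , drop = FALSE], extra)
    feats_tr$c <- cd$X
    feats_te$c <- covariate_design(meta[i, , drop = FALSE], extra, cd$stats)$X
  }
  Xtr <- do.call(cbind, feats_tr)
  fallback <- NA_character_
  if (is.null(Xtr) || ncol(Xtr) == 0) {
    # nothing to learn from: emit the training prevalence
    score <- mean(ytr)
    fallback <- "train_prevalence"
    imp <- numeric(0)
  } else {
    if (length(sel) == 0 && config$include_variants_in_rf) {
      fallback <- "covariates_only"
    }
    mod <- fit_classifier(Xtr, ytr, config, seed = config$base_seed + i)
    score <- predict(mod, do.call(cbind, feats_te))
    imp <- mod$importance
  }
  list(held_out_sample = as.character(meta$sample_id[i]),
       selected_variants = variant_ids[sel],
       prediction_score = min(max(score, 0), 1),
       per_variant_importance = imp,
       fallback = fallback, diagnostics = diagnostics)
}

#' Nested leave-one-out cross-validated prediction
#'
#' The core procedure: for each sample i, the per-variant association
#' filter is run on the other n-1 samples only, a random forest is fitted
#' on the variants selected there (plus covariates/PCs per config), and
#' sample i is predicted. Selection and fitting never see the held-out
#' sample — folds receive physically subset data — which is what keeps the
#' out-of-fold error estimate honest.
#'
#' Folds selecting zero variants fall back to a covariate-only forest when
#' covariates are enabled, else emit the training prevalence; either way
#' the fold is flagged.
#'
#' @param gm A [genotype_matrix()].
#' @param meta Matching [cohort_metadata()].
#' @param config A [cv_config()].
#' @param fixed_variants Optional integer vector of variant columns to use
#'   in every fold, disabling per-fold selection (used for replication
#'   panels and leakage diagnostics).
#' @return A [prediction_set()] with one out-of-fold score per sample.
#' @export
loocv_predict <- function(gm, meta, config = cv_config(),
                          fixed_variants = NULL) {
  stop_if_not(identical(gm$sample_ids, as.character(meta$sample_id)),
              "genotype and metadata sample ids differ (order matters)")
  n <- nrow(gm$dosages)
  stop_if_not(n >= 10, "LOOCV needs at least 10 samples (n = %d)", n)
  y <- meta$relapse
  stop_if_not(length(unique(y)) == 2, "outcome must have both classes")
  folds <- vector("list", n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    folds[[i]] <- run_fold(gm$dosages, meta, y, i, config, fixed_variants,
                           gm$variants$id)
    scores[i] <- folds[[i]]$prediction_score
  }
  prediction_set(gm$sample_ids, scores, y, fold_results = folds,
                 config = config, variant_universe = gm$variants$id)
}

#' Deliberately leaky LOOCV (negative control)
#'
#' Runs the association filter once on the FULL cohort and then
#' cross-validates only the forest on that fixed variant list. This is the
#' classic selection-bias mistake: on null data it produces strongly
#' inflated AUCs, and it exists here purely as a diagnostic contrast
#' certifying that [loocv_predict()] nests its selection correctly. Never
#' use it to report performance.
#'
#' @inheritParams loocv_predict
#' @return A [prediction_set()].
#' @export
loocv_predict_leaky <- function(gm, meta, config = cv_config()) {
  sel <- association_filter(gm, meta, config$covariates, config$p_threshold,
                            test = config$assoc_test %||% "lrt")
  if (length(sel) == 0) {
    # leak the single most-associated variant so the contrast is defined
    p <- attr(sel, "pvalues")
    sel <- which.min(p)
  }
  loocv_predict(gm, meta, config, fixed_variants = as.integer(sel))
}

#' Diagnosis-subgroup LOOCV
#'
#' Two modes: `"restrict"` re-runs the full nested procedure on the samples
#' of one diagnosis group; `"factorize"` partitions an existing
#' [prediction_set()]'s out-of-fold scores by diagnosis and returns the
#' stratum's scores for separate evaluation (the full-cohort model is kept,
#' only the error estimate is stratified).
#'
#' @param gm,meta,config As in [loocv_predict()] (ignored in factorize
#'   mode except `meta`).
#' @param diagnosis Diagnosis group label.
#' @param mode `"restrict"` or `"factorize"`.
#' @param prediction_set_in Required in factorize mode.
#' @return A [prediction_set()] for the stratum.
#' @export
subgroup_loocv <- function(gm, meta, config = cv_config(), diagnosis,
                           mode = c("restrict", "factorize"),
                           prediction_set_in = NULL) {
  mode <- match.arg(mode)
  idx <- which(meta$diagnosis == diagnosis)
  stop_if_not(length(idx) > 0, "no samples with diagnosis '%s'", diagnosis)
  if (mode == "restrict") {
    stop_if_not(length(idx) >= 10,
                "diagnosis stratum '%s' too small (n = %d < 10)", diagnosis,
                length(idx))
    y <- meta$relapse[idx]
    stop_if_not(length(unique(y)) == 2,
                "diagnosis stratum '%s' is single-class", diagnosis)
    loocv_predict(subset_genotypes(gm, samples = idx),
                  cohort_metadata(meta[idx, , drop = FALSE]), config)
  } else {
    ps <- prediction_set_in
    stop_if_not(!is.null(ps), "factorize mode needs prediction_set_in")
    pos <- match(as.character(meta$sample_id[idx]), ps$sample_ids)
    stop_if_not(!anyNA(pos), "prediction set lacks some stratum samples")
    labs <- ps$labels[pos]
    stop_if_not(length(unique(labs)) == 2,
                "diagnosis stratum '%s' is single-class", diagnosis)
    prediction_set(ps$sample_ids[pos], ps$scores[pos], labs,
                   fold_results = ps$fold_results[pos], config = ps$config,
                   variant_universe = ps$variant_universe)
  }
}
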