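#' Genetic principal components of the dosage matrix
#'
#' PCA of the column-standardized dosage matrix. Missing dosages are
#' mean-imputed per variant beforehand; zero-variance variants are excluded
#' (listed in the `excluded_variants` attribute). For tractability the
#' matrix is LD-thinned to at most `thin_max` variants by taking every m-th
#' variant before decomposition.
#'
#' @param gm A [genotype_matrix()].
#' @param k Number of components to return (scores/loadings).
#' @param thin_max Cap on the number of variants entering the PCA.
#' @return A `pca_result`: list with `scores` (n x k), `loadings`
#'   (m_used x k), `eigenvalues` (all min(n, m_used) values, nonincreasing),
#'   and `variant_index` (columns of `gm` that entered).
#' @export
compute_pcs <- function(gm, k = 10, thin_max = 50000) {
  m <- ncol(gm$dosages)
  idx <- seq_len(m)
  if (m > thin_max) idx <- idx[seq(1, m, by = ceiling(m / thin_max))]
  X <- gm$dosages[, idx, drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  s <- apply(X, 2, sd)
  keep <- s > 0
  excluded <- gm$variants$id[idx[!keep]]
  X <- scale(X[, keep, drop = FALSE])
  idx <- idx[keep]
  stop_if_not(k <= min(nrow(X), ncol(X)),
              "k (%d) exceeds min(n_samples, n_variants) = %d",
              k, min(nrow(X), ncol(X)))
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  out <- list(scores = pc$x[, seq_len(k), drop = FALSE],
              loadings = pc$rotation[, seq_len(k), drop = FALSE],
              eigenvalues = ev, variant_index = idx)
  attr(out, "excluded_variants") <- excluded
  class(out) <- "pca_result"
  out
}

#' Choose the number of principal components by scree stabilization
#'
#' Formalizes "the eigenvalues reach a stable level": returns the smallest
#' `k` such that every normalized eigenvalue gap at or beyond `k`,
#' \eqn{(\lambda_j - \lambda_{j+1}) / (\lambda_1 - \lambda_m)}, is below
#' `tol`.
#'
#' @param eigenvalues Nonincreasing nonnegative eigenvalues.
#' @param tol Normalized-gap tolerance (default 0.02).
#' @return Integer component count.
#' @export
select_pc_count <- function(eigenvalues, tol = 0.02) {
  ev <- as.numeric(eigenvalues)
  stop_if_not(length(ev) >= 2, "need at least 2 eigenvalues")
  stop_if_not(all(diff(ev) <= 1e-12), "eigenvalues must be nonincreasing")
  rng <- ev[1] - ev[length(ev)]
  if (rng <= 0) return(1L)  # flat scree
  gaps <- -diff(ev) / rng
  ok <- rev(cumprod(rev(gaps < tol))) > 0  # gap j and all later below tol
  k <- which(ok)[1]
  if (is.na(k)) length(ev) else as.integer(k)
}

# Numeric encoding of a metadata column for correlation purposes:
# numeric columns as-is, categorical columns as a dummy matrix.
dummy_cols <- function(x, name) {
  if (is.numeric(x)) {
    out <- matrix(x, ncol = 1, dimnames = list(NULL, name))
    return(out)
  }
  lev <- sort(unique(as.character(x)))
  out <- vapply(lev, function(l) as.numeric(x == l), numeric(length(x)))
  colnames(out) <- paste0(name, ".", lev)
  out
}

# max |Pearson r| between the dummy-coded columns of two covariates
pair_max_abs_r <- function(a, b) {
  r <- suppressWarnings(cor(a, b))
  r[is.na(r)] <- 0
  max(abs(r))
}

#' Greedy collinearity pruning of covariates
#'
#' Computes pairwise max-absolute-Pearson correlations between covariates
#' (categorical pairs via dummy coding) and, for every pair at or above
#' `r_threshold`, drops the lower-priority covariate. Pairs are visited in
#' decreasing correlation order; each (dropped, kept, r) triple is
#' recorded.
#'
#' @param meta A [cohort_metadata()].
#' @param covariates Covariate column names to consider; defaults to all
#'   clinical columns plus any `pc*` score columns present.
#' @param r_threshold Absolute-correlation threshold (default 0.45).
#' @param priority Character vector, highest priority first; covariates not
#'   listed rank below listed ones in listing order. The default keeps
#'   donor age over recipient age, sex over transplant direction, and PCs
#'   over batch.
#' @return A `screen_result` list with `kept_covariates`,
#'   `dropped_collinear` (data.frame dropped/kept_instead/r), and the full
#'   correlation matrix in `r_matrix`.
#' @export
collinearity_prune <- function(meta, covariates = NULL, r_threshold = 0.45,
                               priority = NULL) {
  if (is.null(covariates)) {
    std <- c("donor_age", "recipient_age", "diagnosis", "graft_type", "sex",
             "transplant_direction", "batch")
    covariates <- c(intersect(std, names(meta)),
                    grep("^pc[0-9]+$", names(meta), value = TRUE))
  }
  if (is.null(priority)) {
    priority <- c("donor_age", "diagnosis", "graft_type", "sex",
                  grep("^pc[0-9]+$", names(meta), value = TRUE),
                  "recipient_age", "transplant_direction", "batch")
  }
  stop_if_not(all(covariates %in% names(meta)),
              "covariate(s) absent from metadata: %s",
              paste(setdiff(covariates, names(meta)), collapse = ", "))
  enc <- lapply(covariates, function(v) dummy_cols(meta[[v]], v))
  names(enc) <- covariates
  p <- length(covariates)
  R <- matrix(0, p, p, dimnames = list(covariates, covariates))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j > i) R[i, j] <- R[j, i] <- pair_max_abs_r(enc[[i]], enc[[j]])
    }
  }
  rank_of <- function(v) {
    r <- match(v, priority)
    ifelse(is.na(r), length(priority) + match(v, covariates), r)
  }
  kept <- covariates
  dropped <- data.frame(dropped = character(0), kept_instead = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  repeat {
    sub <- R[kept, kept, drop = FALSE]
    diag(sub) <- 0
    if (length(kept) < 2 || max(sub) < r_threshold) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- kept[ij[1]]; b <- kept[ij[2]]
    drop_v <- if (rank_of(a) > rank_of(b)) a else b
    keep_v <- setdiff(c(a, b), drop_v)
    dropped <- rbind(dropped, data.frame(dropped = drop_v,
                                         kept_instead = keep_v,
                                         r = max(sub)))
    kept <- setdiff(kept, drop_v)
  }
  structure(list(kept_covariates = kept, dropped_collinear = dropped,
                 r_matrix = R, nominal_pvalues = NULL),
            class = "screen_result")
}

#' Nominal univariable association screen against relapse
#'
#' Fits one logistic regression of relapse on each covariate and keeps
#' those with likelihood-ratio p below `alpha` (strict). Non-converged fits
#' and zero-variance covariates are flagged and treated as not selected.
#'
#' @param meta A [cohort_metadata()].
#' @param covariates Covariates to test (typically the kept set from
#'   [collinearity_prune()]).
#' @param alpha Nominal significance level (default 0.1).
#' @return A `screen_result` with `nominal_pvalues`, `kept_covariates`, and
#'   `flagged` (named reasons for untestable covariates).
#' @export
nominal_screen <- function(meta, covariates, alpha = 0.1) {
  pvals <- setNames(rep(NA_real_, length(covariates)), covariates)
  flagged <- character(0)
  for (v in covariates) {
    x <- meta[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      flagged[v] <- "zero-variance"
      next
    }
    fit <- tryCatch(
      glm(meta$relapse ~ x, family = binomial(),
          control = glm.control(maxit = 50)),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(glm(meta$relapse ~ x, family = binomial(),
                             control = glm.control(maxit = 50)))
      })
    if (is.null(fit) || !fit$converged) {
      flagged[v] <- "non-converged"
      next
    }
    pvals[v] <- pchisq(fit$null.deviance - fit$deviance,
                       df = fit$df.null - fit$df.residual,
                       lower.tail = FALSE)
  }
  kept <- names(pvals)[!is.na(pvals) & pvals < alpha]
  structure(list(kept_covariates = kept, dropped_collinear = NULL,
                 nominal_pvalues = pvals, flagged = flagged),
            class = "screen_result")
}

#' Regional concentration of top PC loadings
#'
#' Reports where the largest-magnitude loadings of one component map: the
#' fraction of the `top_q` variants lying inside a named region (default
#' the MHC, chr6:28,477,797-33,448,354 on GRCh37) and per-chromosome
#' counts. A component whose top loadings are solely MHC variants reflects
#' local LD rather than population structure.
#'
#' @param pca A `pca_result` from [compute_pcs()].
#' @param variants The variant table of the genotype matrix the PCA was
#'   computed on.
#' @param component Component index.
#' @param top_q Number of top-|loading| variants (default 100; truncated to
#'   the available count with a note).
#' @param region List with `chrom`, `start`, `end`.
#' @return List with `fraction_in_region`, `per_chromosome` counts,
#'   `region`, `top_variants`, and `truncated` flag.
#' @export
pc_loading_report <- function(pca, variants, component = 5, top_q = 100,
                              region = list(chrom = "6", start = 28477797,
                                            end = 33448354)) {
  stop_if_not(component <= ncol(pca$loadings),
              "component %d exceeds computed k = %d", component,
              ncol(pca$loadings))
  v <- variants[pca$variant_index, , drop = FALSE]
  load <- abs(pca$loadings[, component])
  truncated <- top_q > length(load)
  q <- min(top_q, length(load))
  top <- order(load, decreasing = TRUE)[seq_len(q)]
  tv <- v[top, , drop = FALSE]
  in_region <- tv$chrom == region$chrom & tv$pos >= region$start &
    tv$pos <= region$end
  list(fraction_in_region = mean(in_region),
       per_chromosome = table(tv$chrom),
       region = region, top_variants = tv$id, truncated = truncated)
}
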